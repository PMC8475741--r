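# Shared fixture (generated once per test run) and small helpers.

fx <- generate_fixture_phantom(seed = 7)

# Cuboid volume from a body_region's corners.
region_volume <- function(r) {
  prod(apply(r$corners, 2, function(v) diff(range(v))))
}

# Flatten every coordinate of a scaled phantom into one matrix.
all_phantom_points <- function(sp) {
  do.call(rbind, c(lapply(sp$regions, function(r) r$corners),
                   lapply(sp$arms, function(a) a$corners),
                   lapply(sp$organs, function(o) o$points)))
}

# The ten standard validation ages (1 month to adult).
validation_ages <- c(0.1, 0.5, 1, 2, 3, 5, 8, 10, 15, 18)
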