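test_that("percent difference supports both sign conventions", {
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(100, 93), 7)
  expect_equal(percent_difference(100, 93, "signed-candidate"), -7)
  # antisymmetry between conventions
  set.seed(2)
  F <- stats::runif(20, 1, 100); D <- stats::runif(20, 1, 100)
  expect_equal(percent_difference(F, D), -percent_difference(F, D, "signed-candidate"))
  expect_error(percent_difference(0, 1), "F = 0")
  # printed dose-table arithmetic (candidate-minus-reference, integer rounding)
  expect_equal(round(percent_difference(9.99, 9.55, "signed-candidate")), -4)
  expect_equal(round(percent_difference(67, 72, "signed-candidate")), 7)
  expect_equal(round(percent_difference(7.50, 7.57, "signed-candidate")), 1)
})

test_that("NMSD is the RMS distance between corresponding points", {
  a <- matrix(stats::runif(30), ncol = 3)
  expect_equal(nmsd(a, a), 0)
  # single point offset by (3, 4, 0): the 3-4-5 triangle
  expect_equal(nmsd(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)), 5)
  # two points at distances 3 and 4 -> sqrt((9 + 16) / 2)
  b <- rbind(c(0, 0, 0), c(10, 10, 10))
  b2 <- rbind(c(3, 0, 0), c(10, 14, 10))
  expect_equal(nmsd(b, b2), sqrt(12.5))
  # metric properties: symmetry and triangle inequality, brute-forced
  set.seed(8)
  for (rep in 1:10) {
    x <- matrix(stats::rnorm(15), ncol = 3)
    y <- matrix(stats::rnorm(15), ncol = 3)
    z <- matrix(stats::rnorm(15), ncol = 3)
    expect_equal(nmsd(x, y), nmsd(y, x))
    expect_lte(nmsd(x, z), nmsd(x, y) + nmsd(y, z) + 1e-12)
    expect_true(nmsd(x, y) > 0)
  }
  expect_error(nmsd(a, a[1:5, ]), "mismatch")
  expect_error(nmsd(a[0, , drop = FALSE], a[0, , drop = FALSE]), "empty")
})

test_that("vectorized and scalar transform paths agree to NMSD < 1e-9 mm at all validation ages", {
  for (a in validation_ages) {
    fast <- scale_phantom(fx$phantom, fx$growth, a)
    ref <- scale_phantom_pointwise(fx$phantom, fx$growth, a)
    for (k in seq_along(fast$organs)) {
      d <- nmsd(fast$organs[[k]]$points * 10, ref$organs[[k]]$points * 10) # mm
      expect_lt(d, 1e-9)
    }
    # per-region volume self-consistency, the percent-difference analogue
    for (rid in names(fast$regions)) {
      expect_lt(abs(percent_difference(region_volume(ref$regions[[rid]]),
                                       region_volume(fast$regions[[rid]]))), 1e-9)
    }
  }
})

test_that("height comparison reports absolute percent differences per age", {
  ref <- data.frame(age = c(1, 5, 10), height_cm = c(100, 110, 140))
  ph <- data.frame(age = c(1, 5, 10), height_cm = c(93.1, 110, 143.5))
  cmp <- compare_heights(ph, ref)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$percent_difference, c(6.9, 0, 2.5))
  expect_error(compare_heights(data.frame(age = 2, height_cm = 80), ref),
               "missing age")
  # fixture heights track the example population table within 7% everywhere
  heights <- data.frame(age = validation_ages, height_cm = vapply(
    validation_ages, function(a) phantom_height(scale_phantom(fx$phantom, fx$growth, a)), 0))
  pop <- utils::read.csv(system.file("extdata", "heights_50th_example.csv",
                                     package = "agephantom"))
  cmp2 <- compare_heights(heights, pop)
  expect_true(all(cmp2$percent_difference < 7))
  expect_true(all(cmp2$percent_difference[cmp2$age >= 5] < 2))
})

test_that("organ mass is density times voxelized hull volume", {
  cube <- convex_hull_3d(as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10))))
  expect_identical(organ_mass(cube, 1.05, voxel = 1), 1.05) # exact: 1 cm^3
  tet <- convex_hull_3d(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)))
  m1 <- organ_mass(tet, 1, voxel = 1)
  m05 <- organ_mass(tet, 1, voxel = 0.5)
  expect_lt(abs(m05 - 1 / 6), abs(m1 - 1 / 6)) # refinement
  expect_equal(m05, 1 / 6, tolerance = 0.02)
  # organ_grid input in the DICOM frame; non-contourable refused
  dic <- reorient_to_dicom(scale_phantom(fx$phantom, fx$growth, 18))
  names_d <- vapply(dic$organs, `[[`, "", "name")
  pit <- dic$organs[[which(names_d == "pituitary")]]
  expect_error(organ_mass(pit, 1.04), class = "agephantom_noncontourable")
  heart <- dic$organs[[which(names_d == "heart")]]
  m_heart <- organ_mass(heart, 1.05, voxel = 2)
  expect_gt(m_heart, 0)
  expect_equal(m_heart, 1.05 * convex_hull_3d(heart$points)$volume / 1000,
               tolerance = 0.05)
})

test_that("mass comparison averages sexes and sums parts before differencing", {
  ref <- data.frame(
    organ = c("heart", "heart", "heart", "heart", "stomach", "stomach", "brain"),
    age = 18,
    sex = c("male", "male", "female", "female", "both", "both", "both"),
    part = c("wall", "contents", "wall", "contents", "wall", "contents", "whole"),
    mass_g = c(500, 0, 400, 0, 100, 150, 1400))
  ph <- data.frame(organ = c("heart", "stomach", "brain", "thyroid"),
                   mass_g = c(173.26, 287.68, 1153.46, 0.62))
  rep <- suppressWarnings(compare_masses(ph, ref, age = 18))
  expect_equal(rep$reference_g[rep$organ == "heart"], 450)   # sex average
  expect_equal(rep$reference_g[rep$organ == "stomach"], 250) # part sum
  expect_equal(rep$difference_g, rep$phantom_g - rep$reference_g)
  expect_true(is.na(rep$reference_g[rep$organ == "thyroid"]))
  expect_warning(compare_masses(ph, ref, age = 18), "thyroid")
  # a printed-table-style pair: phantom 12.27 g vs reference 46.00 g
  ref2 <- data.frame(organ = "heart", age = 0.1, sex = "both", part = "whole",
                     mass_g = 46)
  rep2 <- compare_masses(data.frame(organ = "heart", mass_g = 12.27), ref2, age = 0.1)
  expect_equal(rep2$difference_g, -33.73)
})

test_that("dose metric comparison reproduces printed percent-difference arithmetic", {
  tab <- dose_metric_comparison(data.frame(
    label = c("liver V5", "pancreas V5", "liver mean", "pancreas mean"),
    reference = c(96, 67, 9.99, 7.50),
    candidate = c(91, 72, 9.55, 7.57)))
  expect_equal(tab$percent_rounded, c(-5, 7, -4, 1))
})
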