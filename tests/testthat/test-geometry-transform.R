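test_that("transform_x scales about the mid-sagittal plane", {
  ctx <- transform_context(fx$phantom, scaling_factors(fx$growth, 2))
  expect_identical(transform_x(0, "tr", ctx), 0)
  f <- ctx$factors["x", "tr"]
  expect_equal(transform_x(-10, "tr", ctx), -10 * f)
  ctx18 <- transform_context(fx$phantom, scaling_factors(fx$growth, 18))
  xs <- c(-17, -3.2, 0, 8.8, 17)
  expect_identical(transform_x(xs, "tr", ctx18), xs)
})

test_that("transform_y telescopes scaled region lengths from the head down", {
  ctx <- transform_context(fx$phantom, scaling_factors(fx$growth, 4))
  # top of the upper head maps to 0 at any age
  expect_equal(transform_y(fx$phantom$regions$uh$y_sbr, "uh", ctx), 0)
  # a point at a region's inferior boundary lands at the sum of scaled lengths
  f <- ctx$factors
  uh <- fx$phantom$regions$uh; lh <- fx$phantom$regions$lh
  expect_equal(transform_y(lh$y_ibr, "lh", ctx),
               uh$l_y * f["y", "uh"] + lh$l_y * f["y", "lh"])
  # age 18: the bottom of the legs maps to generic height minus the 1 cm origin
  ctx18 <- transform_context(fx$phantom, scaling_factors(fx$growth, 18))
  total <- sum(vapply(fx$phantom$regions, function(r) r$l_y, 0)) # brute-force sum
  expect_equal(transform_y(fx$phantom$regions$lg$y_ibr, "lg", ctx18), total)
  expect_equal(total, fx$phantom$regions$lg$y_ibr - fx$phantom$y_origin)
  # out-of-region y is a domain error
  expect_error(transform_y(50, "uh", ctx), "outside region")
})

test_that("transform_z scales from the anterior boundary and centres on the head mid-plane", {
  ctx <- transform_context(fx$phantom, scaling_factors(fx$growth, 3))
  f <- ctx$factors
  # anterior boundary maps exactly to the region's z-shift
  tr <- fx$phantom$regions$tr; uh <- fx$phantom$regions$uh
  zshift_tr <- (uh$l_z * f["z", "uh"] - tr$l_z * f["z", "tr"]) / 2
  expect_equal(transform_z(tr$z_abr, "tr", ctx), zshift_tr)
  # for the reference region itself the shift vanishes
  expect_equal(transform_z(uh$z_abr, "uh", ctx), 0)
  expect_error(transform_z(100, "tr", ctx), "outside region")
})

test_that("hand-evaluated z-shift: trunk 20 cm at F=0.5 vs head 16 cm at F=0.5", {
  # build a two-region chain where the numbers are hand-checkable:
  # z_shift = (16 * 0.5 - 20 * 0.5) / 2 = -1
  regions <- list(
    uh = body_region("uh", c(-8, 8), c(1, 11), c(0, 16)),
    lh = body_region("lh", c(-8, 8), c(11, 21), c(0, 16)),
    n  = body_region("n",  c(-8, 8), c(21, 31), c(0, 16)),
    tr = body_region("tr", c(-10, 10), c(31, 61), c(-2, 18)),
    lg = body_region("lg", c(-10, 10), c(61, 101), c(0, 13))
  )
  p <- generic_phantom(regions, arms = list(), organs = list())
  entries <- expand.grid(direction = c("x", "y", "z"),
                         region = c("uh", "lh", "n", "tr", "ar", "lg"),
                         age_years = c(0.1, 1, 3, 5, 10, 15, 18),
                         stringsAsFactors = FALSE)
  ext <- list(uh = c(16, 10, 16), lh = c(16, 10, 16), n = c(16, 10, 16),
              tr = c(20, 30, 20), ar = c(20, 30, 20), lg = c(20, 40, 13))
  entries$size_cm <- mapply(function(d, r, a) {
    full <- ext[[r]][match(d, c("x", "y", "z"))]
    if (a >= 18) full else full * 0.5
  }, entries$direction, entries$region, entries$age_years)
  tab <- growth_table(entries)
  ctx <- transform_context(p, scaling_factors(tab, 1))
  expect_equal(transform_z(p$regions$tr$z_abr, "tr", ctx), -1)
  # brute-force centre-alignment: every region's scaled z-centre sits at
  # l_head_z * F(z, uh) / 2 = 16 * 0.5 / 2 = 4
  sp <- scale_phantom(p, tab, 1)
  centres <- vapply(sp$regions, function(r) mean(range(r$corners[, "z"])), 0)
  expect_equal(unname(centres), rep(4, 5))
})

test_that("scaling at age 18 preserves every extent; volumes scale as the factor product", {
  sp <- scale_phantom(fx$phantom, fx$growth, 18)
  for (rid in names(fx$phantom$regions)) {
    expect_equal(sp$regions[[rid]]$l_x, fx$phantom$regions[[rid]]$l_x)
    expect_equal(sp$regions[[rid]]$l_y, fx$phantom$regions[[rid]]$l_y)
    expect_equal(sp$regions[[rid]]$l_z, fx$phantom$regions[[rid]]$l_z)
  }
  # organ point sets equal up to the rigid re-basing (y -> y - 1, z centring)
  for (k in seq_along(fx$phantom$organs)) {
    gen <- unname(fx$phantom$organs[[k]]$points)
    got <- unname(sp$organs[[k]]$points)
    expect_equal(got[, 1], gen[, 1])
    expect_equal(got[, 2] - got[1, 2], gen[, 2] - gen[1, 2])
    expect_equal(got[, 3] - got[1, 3], gen[, 3] - gen[1, 3])
  }
  # volume product property at assorted ages
  for (a in c(0.1, 2.7, 9.4, 15.5)) {
    spa <- scale_phantom(fx$phantom, fx$growth, a)
    f <- spa$factors$factors
    for (rid in names(fx$phantom$regions)) {
      expect_equal(region_volume(spa$regions[[rid]]),
                   region_volume(fx$phantom$regions[[rid]]) * prod(f[, rid]),
                   tolerance = 1e-12)
    }
  }
})

test_that("region chain stays gapless and z mid-planes aligned at 50 random tenth-ages", {
  set.seed(19)
  ages <- sample(seq(0.1, 18, by = 0.1), 50)
  for (a in ages) {
    sp <- scale_phantom(fx$phantom, fx$growth, a)
    for (k in 1:4) {
      gap <- abs(sp$regions[[k]]$y_ibr - sp$regions[[k + 1]]$y_sbr)
      expect_lt(gap, 1e-9)
    }
    ref_mid <- fx$phantom$regions$uh$l_z * sp$factors$factors["z", "uh"] / 2
    for (r in sp$regions) {
      expect_lt(abs(mean(range(r$corners[, "z"])) - ref_mid), 1e-9)
    }
    # organ containment is preserved by the per-region affine map
    for (o in sp$organs) {
      reg <- if (o$region == "ar") sp$arms[[1]] else sp$regions[[o$region]]
      expect_true(all(o$points[, 1] >= reg$lims[1, 1] - 1e-9 &
                      o$points[, 1] <= reg$lims[2, 1] + 1e-9 &
                      o$points[, 2] >= reg$lims[1, 2] - 1e-9 &
                      o$points[, 2] <= reg$lims[2, 2] + 1e-9 &
                      o$points[, 3] >= reg$lims[1, 3] - 1e-9 &
                      o$points[, 3] <= reg$lims[2, 3] + 1e-9))
    }
  }
})

test_that("phantom height matches the closed form and grows monotonically", {
  for (a in c(0.1, 1.3, 6.8, 14.2, 18)) {
    sp <- scale_phantom(fx$phantom, fx$growth, a)
    f <- sp$factors$factors
    closed <- sum(vapply(names(fx$phantom$regions), function(rid) {
      fx$phantom$regions[[rid]]$l_y * f["y", rid]
    }, 0))
    expect_equal(phantom_height(sp), closed, tolerance = 1e-12)
  }
  hs <- vapply(seq(0.1, 18, by = 0.5), function(a) {
    phantom_height(scale_phantom(fx$phantom, fx$growth, a))
  }, 0)
  expect_true(all(diff(hs) >= -1e-12))
  expect_equal(phantom_height(scale_phantom(fx$phantom, fx$growth, 18)), 176)
})

test_that("DICOM reorientation is rigid, invertible, and head-first supine", {
  sp <- scale_phantom(fx$phantom, fx$growth, 5)
  d <- reorient_to_dicom(sp)
  expect_identical(d$frame, "dicom")
  expect_error(reorient_to_dicom(d), "already")
  # pairwise distances preserved up to the cm -> mm factor
  set.seed(3)
  pts <- all_phantom_points(sp)
  idx <- sample(nrow(pts), 20)
  dpts <- all_phantom_points(d)
  for (i in idx[1:10]) for (j in idx[11:20]) {
    expect_equal(sqrt(sum((dpts[i, ] - dpts[j, ])^2)),
                 10 * sqrt(sum((pts[i, ] - pts[j, ])^2)), tolerance = 1e-9)
  }
  # round trip is exact
  back <- reorient_to_phantom(d)
  expect_equal(all_phantom_points(back), all_phantom_points(sp), tolerance = 1e-12)
  expect_equal(phantom_height(d), phantom_height(sp))
  # the superior-most phantom point has the largest S coordinate
  i_sup <- unname(which.min(pts[, 2]))
  expect_equal(unname(which.max(dpts[, 3])), i_sup)
})
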