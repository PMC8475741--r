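# Shared DICOM-frame phantom for this file.
dicom_phantom <- reorient_to_dicom(scale_phantom(fx$phantom, fx$growth, 3.9))
roiset <- suppressWarnings(phantom_roi_set(dicom_phantom, slice_spacing = 2.5))

test_that("box ROIs follow the pinned half-open slice grid", {
  cube <- body_region("tr", c(0, 100), c(0, 100), c(0, 100)) # mm in DICOM frame
  contours <- box_roi(cube, 10)
  expect_length(contours, 10) # centres at 5, 15, ..., 95
  for (ct in contours) {
    expect_equal(nrow(ct$vertices), 4)
    # exact cross-section: area = l_x * l_z, vertices are the corners
    area <- abs(sum(ct$vertices[, 1] * ct$vertices[c(2:4, 1), 2] -
                    ct$vertices[c(2:4, 1), 1] * ct$vertices[, 2]) / 2)
    expect_equal(area, 100 * 100)
    expect_setequal(ct$vertices[, 1], c(0, 0, 100, 100))
  }
  expect_equal(vapply(contours, `[[`, 0, "S"), seq(5, 95, by = 10))
  flat <- list(id = "tr", corners = cbind(rep(c(0, 1), 4), rep(0, 8), rep(c(0, 1), each = 4)),
               lims = rbind(c(0, 0, 0), c(1, 0, 1)))
  expect_error(box_roi(flat, 1), "degenerate")
})

test_that("hull contours slice the organ hull into convex polygons", {
  cube_pts <- as.matrix(expand.grid(c(0, 20), c(0, 20), c(0, 20)))
  organ <- organ_grid("cube", "tr", cube_pts)
  contours <- hull_contours(organ, 5)
  expect_length(contours, 4) # S = 2.5, 7.5, 12.5, 17.5
  for (ct in contours) {
    expect_equal(nrow(ct$vertices), 4)
    expect_setequal(round(ct$vertices[, 1], 6), c(0, 0, 20, 20))
  }
  # single-point organ raises the non-contourable condition by name
  pit <- organ_grid("pituitary", "uh", matrix(c(1, 2, 3), 1))
  err <- tryCatch(hull_contours(pit, 2.5), condition = function(c) c)
  expect_s3_class(err, "agephantom_noncontourable")
  expect_match(conditionMessage(err), "pituitary")
  # every original organ point lies inside or on the hull of its contours'
  # source: containment checked against the hull itself
  o <- dicom_phantom$organs[[which(vapply(dicom_phantom$organs, `[[`, "", "name") == "liver")]]
  h <- convex_hull_3d(o$points)
  expect_true(all(point_in_hull(h, o$points, tol = 1e-7)))
})

test_that("slicing conservation: contour area x spacing converges to the cuboid volume", {
  cube <- body_region("tr", c(0, 50), c(0, 40), c(0, 30))
  vol <- 50 * 40 * 30
  for (spacing in c(10, 5, 1)) {
    contours <- box_roi(cube, spacing)
    est <- sum(vapply(contours, function(ct) {
      abs(sum(ct$vertices[, 1] * ct$vertices[c(2:4, 1), 2] -
              ct$vertices[c(2:4, 1), 1] * ct$vertices[, 2]) / 2) * spacing
    }, 0))
    expect_lt(abs(est - vol), 50 * 40 * spacing + 1e-9) # one slice's volume
  }
})

test_that("RT-STRUCT round trip is lossless to 0.001 mm and passes conformance", {
  path <- file.path(tempdir(), "roundtrip.dcm")
  set.seed(123)
  write_rtstruct(roiset, path,
                 metadata = list(age_years = 3.9, date = "20260101", time = "120000"))
  expect_length(check_rtstruct(path), 0)
  back <- read_rtstruct(path)
  expect_equal(vapply(back$rois, `[[`, "", "name"),
               vapply(roiset, `[[`, "", "name"))
  expect_equal(vapply(back$rois, function(r) length(r$contours), 0L),
               vapply(roiset, function(r) {
                 if (identical(r$kind, "point")) 1L else length(r$contours)
               }, 0L))
  maxerr <- 0
  for (i in seq_along(roiset)) {
    if (identical(roiset[[i]]$kind, "point")) next
    for (j in seq_along(roiset[[i]]$contours)) {
      a <- roiset[[i]]$contours[[j]]
      b <- back$rois[[i]]$contours[[j]]
      expect_identical(b$type, "CLOSED_PLANAR")
      maxerr <- max(maxerr, max(abs(a$vertices - b$vertices)), abs(a$S - b$S))
    }
  }
  expect_lte(maxerr, 0.001)
  # ROI inventory: 5 chain regions + 2 arms + 19 contourable organs + 1 point
  expect_length(roiset, 27)
  expect_gte(sum(vapply(roiset, `[[`, "", "kind") == "organ"), 12)
  # empty ROI set is refused
  expect_error(write_rtstruct(structure(list(), class = "roi_set"), path), "empty")
})

test_that("conformance checker catches corrupted files", {
  path <- file.path(tempdir(), "tamper.dcm")
  set.seed(123)
  write_rtstruct(roiset, path, metadata = list(date = "20260101", time = "120000"))
  bytes <- readBin(path, "raw", file.size(path))
  bad <- bytes; bad[131] <- as.raw(0) # break the DICM marker
  bad_path <- tempfile(fileext = ".dcm")
  writeBin(bad, bad_path)
  expect_match(check_rtstruct(bad_path), "unparseable")
  expect_error(read_rtstruct(bad_path), "DICM")
})

test_that("synthetic CT encodes water inside body regions, air outside", {
  ct_dir <- file.path(tempdir(), "ct_test")
  set.seed(99)
  info <- write_synthetic_ct(dicom_phantom, voxel = 8, path = ct_dir,
                             metadata = list(date = "20260101", time = "120000"))
  expect_true(all(file.exists(info$files)))
  first <- read_ct_slice(info$files[1])
  expect_true(all(first$hu == -1000)) # margin slice: all air
  # a voxel centred inside the trunk reads 0 HU
  tr <- dicom_phantom$regions$tr
  centre <- colMeans(tr$corners)
  k <- which.min(abs(info$grid[[3]] - centre[3]))
  slice <- read_ct_slice(info$files[k])
  i <- which.min(abs(info$grid[[2]] - centre[2])) # row along P
  j <- which.min(abs(info$grid[[1]] - centre[1])) # column along L
  expect_identical(slice$hu[i, j], 0L)
  # corner voxel is air
  expect_identical(slice$hu[1, 1], -1000L)
  # voxel budget is enforced
  expect_error(write_synthetic_ct(dicom_phantom, voxel = 0.2, path = ct_dir,
                                  max_voxels = 1e6), "coarser")
})

test_that("CT water volume approximates the analytic body volume at 2 mm voxels", {
  # the newborn phantom keeps the 2 mm series small enough to write in full
  small <- reorient_to_dicom(scale_phantom(fx$phantom, fx$growth, 0.1))
  ct_dir <- file.path(tempdir(), "ct_2mm")
  set.seed(7)
  info <- write_synthetic_ct(small, voxel = 2, path = ct_dir,
                             metadata = list(date = "20260101", time = "120000"))
  n_water <- 0
  for (f in info$files) n_water <- n_water + sum(read_ct_slice(f)$hu == 0L)
  vol_voxel <- n_water * prod(info$voxel)
  boxes <- c(unname(small$regions), unname(small$arms))
  vol_analytic <- sum(vapply(boxes, region_volume, 0))
  expect_lt(abs(vol_voxel - vol_analytic) / vol_analytic, 0.02)
  unlink(ct_dir, recursive = TRUE)
})
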