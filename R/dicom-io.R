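# Conversion of the scaled phantom to DICOM RT structures: body regions as
# box ROIs, organs as convex-hull contours, plus an optional synthetic
# water-equivalent CT series to host the structures in a TPS.

#' Slice grid over an S-extent
#'
#' Pinned convention: slices at `S_min + (k + 0.5) * spacing` for
#' `k = 0, 1, ...` while strictly below `S_max` (half-open coverage), so
#' contour counts are deterministic.
#'
#' @param s_range Length-2 numeric, the S-extent (mm).
#' @param spacing Slice spacing (mm), > 0.
#' @return Numeric vector of slice S positions (mm).
#' @export
slice_grid <- function(s_range, spacing) {
  stopifnot(spacing > 0)
  s_min <- min(s_range); s_max <- max(s_range)
  k <- 0:max(0, ceiling((s_max - s_min) / spacing))
  s <- s_min + (k + 0.5) * spacing
  s[s < s_max - 1e-9]
}

#' Box ROI contours for a body-region cuboid
#'
#' One rectangular contour per slice intersecting the cuboid's S-extent;
#' each rectangle is the cuboid's exact L-P cross-section, wound
#' counter-clockwise.
#'
#' @param region A `body_region` in the DICOM frame (mm).
#' @param slice_spacing Slice spacing in mm.
#' @return List of contours, each `list(S = <mm>, vertices = <4 x 2 (L, P)>)`.
#' @export
box_roi <- function(region, slice_spacing) {
  lims <- region$lims
  if (any(apply(region$corners, 2, function(v) diff(range(v))) <= 1e-12)) {
    stop("box_roi: degenerate (zero-extent) cuboid for region ", region$id)
  }
  rect <- rbind(c(lims[1, 1], lims[1, 2]),
                c(lims[2, 1], lims[1, 2]),
                c(lims[2, 1], lims[2, 2]),
                c(lims[1, 1], lims[2, 2])) # CCW in (L, P)
  lapply(slice_grid(lims[, 3], slice_spacing), function(s) {
    list(S = s, vertices = rect)
  })
}

#' Convex-hull contours for an organ point grid
#'
#' Builds the 3-D convex hull of the organ's points and intersects it with
#' each slice plane, yielding one convex polygon per slice. Organs whose
#' points cannot support a 3-D hull (< 4 points, or all coplanar) raise a
#' `agephantom_noncontourable` error naming the organ.
#'
#' @param organ An `organ_grid` in the DICOM frame (mm).
#' @param slice_spacing Slice spacing in mm.
#' @return List of contours `list(S, vertices)`; slices with empty or
#'   degenerate (tangent) intersections emit no contour.
#' @export
hull_contours <- function(organ, slice_spacing) {
  if (!organ$contourable) {
    stop(structure(class = c("agephantom_noncontourable", "error", "condition"),
                   list(message = paste0("organ '", organ$name,
                                         "' is non-contourable (", organ$n,
                                         " point(s), need >= 4 non-coplanar)"),
                        call = sys.call(-1), organ = organ$name)))
  }
  hull <- convex_hull_3d(organ$points)
  s_range <- range(hull$points[, 3])
  out <- list()
  for (s in slice_grid(s_range, slice_spacing)) {
    poly <- hull_section(hull, s, axis = 3)
    if (!is.null(poly)) out[[length(out) + 1]] <- list(S = s, vertices = poly)
  }
  out
}

# Deterministic display colours for ROIs.
roi_color <- function(i) {
  palette <- rbind(c(255, 128, 0), c(0, 160, 255), c(0, 200, 80),
                   c(230, 60, 60), c(180, 90, 230), c(240, 210, 40),
                   c(90, 200, 200), c(250, 120, 180))
  palette[((i - 1) %% nrow(palette)) + 1, ]
}

#' Build the ROI set for a DICOM-frame scaled phantom
#'
#' Body regions (and arm cuboids) become box ROIs; contourable organs become
#' convex-hull contour stacks; non-contourable organs are kept as POINT ROIs
#' with a warning rather than silently dropped.
#'
#' @param phantom A `scaled_phantom` in the `"dicom"` frame.
#' @param slice_spacing Slice spacing in mm (default 2.5, typical pediatric
#'   CT slice thickness).
#' @param name_prefix Optional prefix for structure names.
#' @return A `roi_set`: list of ROIs
#'   `list(name, kind, color, contours | point)`, with attribute
#'   `"non_contourable"` listing any point-only organs.
#' @export
phantom_roi_set <- function(phantom, slice_spacing = 2.5, name_prefix = "") {
  stopifnot(inherits(phantom, "scaled_phantom"))
  if (phantom$frame != "dicom") {
    stop("phantom_roi_set: phantom must be in the 'dicom' frame; call reorient_to_dicom()")
  }
  rois <- list()
  add <- function(name, kind, contours = NULL, point = NULL) {
    rois[[length(rois) + 1]] <<- list(
      name = paste0(name_prefix, name), kind = kind,
      color = roi_color(length(rois) + 1),
      contours = contours, point = point)
  }
  for (r in phantom$regions) {
    add(paste0("region_", r$id), "body-region", contours = box_roi(r, slice_spacing))
  }
  for (i in seq_along(phantom$arms)) {
    side <- if (mean(phantom$arms[[i]]$corners[, 1]) >= 0) "l" else "r"
    add(paste0("region_ar_", side), "body-region",
        contours = box_roi(phantom$arms[[i]], slice_spacing))
  }
  skipped <- character()
  for (o in phantom$organs) {
    if (o$contourable) {
      add(o$name, "organ", contours = hull_contours(o, slice_spacing))
    } else {
      skipped <- c(skipped, o$name)
      add(o$name, "point", point = colMeans(o$points))
    }
  }
  if (length(skipped)) {
    warning("non-contourable organ(s) exported as POINT ROIs: ",
            paste(skipped, collapse = ", "))
  }
  structure(rois, class = "roi_set", non_contourable = skipped)
}

#' Write a DICOM RT Structure Set
#'
#' Serializes an ROI set as a DICOM Part 10 RT Structure Set (explicit VR
#' little endian). Contour coordinates are written as decimal strings at
#' 0.001 mm resolution in the LPS patient frame.
#'
#' @param rois A `roi_set` (see [phantom_roi_set()]); must be non-empty.
#' @param path Output file path.
#' @param metadata Named list of patient/study fields: `patient_name`,
#'   `patient_id`, `age_years`, `label`, `date` (DA string), `time`
#'   (TM string). Missing fields get deterministic defaults except
#'   `date`/`time`, which default to the current date/time.
#' @param frame_of_reference_uid Frame of reference UID; synthesized when
#'   `NULL` (pass the UID from [write_synthetic_ct()] to link structures to
#'   the image series).
#' @return The path, invisibly, with attribute `"sop_instance_uid"`.
#' @export
write_rtstruct <- function(rois, path, metadata = list(),
                           frame_of_reference_uid = NULL) {
  if (!length(rois)) stop("write_rtstruct: empty ROI list")
  md <- utils::modifyList(list(
    patient_name = "agephantom", patient_id = "AGEPHANTOM",
    age_years = NA_real_, label = "agephantom scaled phantom",
    date = format(Sys.Date(), "%Y%m%d"),
    time = format(Sys.time(), "%H%M%S")
  ), metadata)
  for_uid <- if (is.null(frame_of_reference_uid)) new_uid() else frame_of_reference_uid
  sop_uid <- new_uid()

  ss_roi_items <- list()
  contour_items <- list()
  obs_items <- list()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    ss_roi_items[[i]] <- list(
      dcm_elem(0x3006, 0x0022, "IS", as.character(i)),
      dcm_elem(0x3006, 0x0024, "UI", for_uid),
      dcm_elem(0x3006, 0x0026, "LO", roi$name),
      dcm_elem(0x3006, 0x0036, "CS", "AUTOMATIC")
    )
    if (identical(roi$kind, "point")) {
      contours <- list(list(
        dcm_elem(0x3006, 0x0042, "CS", "POINT"),
        dcm_elem(0x3006, 0x0046, "IS", "1"),
        dcm_elem(0x3006, 0x0050, "DS", format_ds(roi$point))
      ))
    } else {
      contours <- lapply(roi$contours, function(ct) {
        xyz <- cbind(ct$vertices, ct$S) # L, P, S triplets
        list(
          dcm_elem(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
          dcm_elem(0x3006, 0x0046, "IS", as.character(nrow(xyz))),
          dcm_elem(0x3006, 0x0050, "DS", format_ds(as.vector(t(xyz))))
        )
      })
    }
    contour_items[[i]] <- list(
      dcm_elem(0x3006, 0x002A, "IS", as.character(roi$color)),
      dcm_sq(0x3006, 0x0040, contours),
      dcm_elem(0x3006, 0x0084, "IS", as.character(i))
    )
    obs_items[[i]] <- list(
      dcm_elem(0x3006, 0x0082, "IS", as.character(i)),
      dcm_elem(0x3006, 0x0084, "IS", as.character(i)),
      dcm_elem(0x3006, 0x00A4, "CS",
               if (identical(roi$kind, "body-region")) "" else "ORGAN"),
      dcm_elem(0x3006, 0x00A6, "PN", "")
    )
  }

  age_str <- if (is.finite(md$age_years)) {
    if (md$age_years < 2) sprintf("%03dM", as.integer(round(md$age_years * 12)))
    else sprintf("%03dY", as.integer(floor(md$age_years)))
  } else ""
  dataset <- c(
    dcm_elem(0x0008, 0x0016, "UI", UID_SOP_RTSTRUCT),
    dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem(0x0008, 0x0020, "DA", md$date),
    dcm_elem(0x0008, 0x0030, "TM", md$time),
    dcm_elem(0x0008, 0x0050, "SH", ""),
    dcm_elem(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_elem(0x0008, 0x0070, "LO", "agephantom"),
    dcm_elem(0x0008, 0x0090, "PN", ""),
    dcm_elem(0x0010, 0x0010, "PN", md$patient_name),
    dcm_elem(0x0010, 0x0020, "LO", md$patient_id),
    dcm_elem(0x0010, 0x0030, "DA", ""),
    dcm_elem(0x0010, 0x0040, "CS", "O"),
    dcm_elem(0x0010, 0x1010, "AS", age_str),
    dcm_elem(0x0020, 0x000D, "UI", md$study_uid %||% new_uid()),
    dcm_elem(0x0020, 0x000E, "UI", new_uid()),
    dcm_elem(0x0020, 0x0010, "SH", "1"),
    dcm_elem(0x0020, 0x0011, "IS", "1"),
    dcm_elem(0x3006, 0x0002, "SH", substr(md$label, 1, 16)),
    dcm_elem(0x3006, 0x0008, "DA", md$date),
    dcm_elem(0x3006, 0x0009, "TM", md$time),
    dcm_sq(0x3006, 0x0010, list(list(dcm_elem(0x0020, 0x0052, "UI", for_uid)))),
    dcm_sq(0x3006, 0x0020, ss_roi_items),
    dcm_sq(0x3006, 0x0039, contour_items),
    dcm_sq(0x3006, 0x0080, obs_items)
  )
  dcm_write_file(path, UID_SOP_RTSTRUCT, sop_uid, dataset)
  invisible(structure(path, sop_instance_uid = sop_uid,
                      frame_of_reference_uid = for_uid))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back a DICOM RT Structure Set
#'
#' Parses an RT-STRUCT file (explicit VR little endian) into the same shape
#' as a `roi_set`, for round-trip verification and downstream comparison.
#'
#' @param path RT-STRUCT file path.
#' @return List with `patient_name`, `label`, `frame_of_reference_uid` and
#'   `rois` (each `list(name, number, color, contours)`, contours as
#'   `list(S, vertices)`).
#' @export
read_rtstruct <- function(path) {
  parsed <- dcm_parse_file(path)
  ds <- parsed$dataset
  if (!identical(dcm_value(ds, 0x0008, 0x0016), UID_SOP_RTSTRUCT)) {
    stop("not an RT Structure Set: ", path)
  }
  names_by_number <- list()
  for (item in dcm_value(ds, 0x3006, 0x0020, list())) {
    num <- as.character(dcm_value(item, 0x3006, 0x0022))
    names_by_number[[num]] <- dcm_value(item, 0x3006, 0x0026)
  }
  rois <- list()
  for (item in dcm_value(ds, 0x3006, 0x0039, list())) {
    num <- as.character(dcm_value(item, 0x3006, 0x0084))
    contours <- lapply(dcm_value(item, 0x3006, 0x0040, list()), function(ct) {
      data <- dcm_value(ct, 0x3006, 0x0050)
      xyz <- matrix(data, ncol = 3, byrow = TRUE)
      list(S = xyz[1, 3], vertices = xyz[, 1:2, drop = FALSE],
           type = dcm_value(ct, 0x3006, 0x0042))
    })
    rois[[length(rois) + 1]] <- list(
      name = names_by_number[[num]], number = as.integer(num),
      color = dcm_value(item, 0x3006, 0x002A), contours = contours)
  }
  for_item <- dcm_value(ds, 0x3006, 0x0010, list())
  for_uid <- if (length(for_item)) dcm_value(for_item[[1]], 0x0020, 0x0052) else NULL
  list(patient_name = dcm_value(ds, 0x0010, 0x0010),
       label = dcm_value(ds, 0x3006, 0x0002),
       frame_of_reference_uid = for_uid,
       rois = rois)
}

#' Structural conformance check for an RT Structure Set file
#'
#' Parses the file byte-by-byte (independently of the writer's in-memory
#' objects) and verifies the RT Structure Set IOD's required structure:
#' Part 10 preamble, file meta consistency, required patient/study/series
#' tags, the three structure-set sequences, ROI cross-reference integrity,
#' well-formed decimal strings, and contour point counts matching the
#' contour data length.
#'
#' @param path RT-STRUCT file path.
#' @return Character vector of problems; length 0 means the file passed.
#' @export
check_rtstruct <- function(path) {
  probs <- character()
  parsed <- tryCatch(dcm_parse_file(path), error = function(e) e)
  if (inherits(parsed, "error")) {
    return(paste("unparseable:", conditionMessage(parsed)))
  }
  meta <- parsed$meta; ds <- parsed$dataset
  need <- function(ok, msg) if (!isTRUE(ok)) probs <<- c(probs, msg)
  need(identical(dcm_value(meta, 0x0002, 0x0002), UID_SOP_RTSTRUCT),
       "file meta SOP class is not RT Structure Set")
  need(identical(dcm_value(meta, 0x0002, 0x0003), dcm_value(ds, 0x0008, 0x0018)),
       "file meta SOP instance UID does not match dataset")
  need(identical(dcm_value(ds, 0x0008, 0x0016), UID_SOP_RTSTRUCT),
       "dataset SOP class is not RT Structure Set")
  need(identical(dcm_value(ds, 0x0008, 0x0060), "RTSTRUCT"), "Modality is not RTSTRUCT")
  for (tag in list(c(0x0010, 0x0010, "PatientName"), c(0x0010, 0x0020, "PatientID"),
                   c(0x0020, 0x000D, "StudyInstanceUID"),
                   c(0x0020, 0x000E, "SeriesInstanceUID"),
                   c(0x3006, 0x0002, "StructureSetLabel"))) {
    need(!is.null(dcm_find(ds, as.numeric(tag[1]), as.numeric(tag[2]))),
         paste("missing required tag", tag[3]))
  }
  for_items <- dcm_value(ds, 0x3006, 0x0010, list())
  need(length(for_items) >= 1, "missing ReferencedFrameOfReferenceSequence")
  for_uid <- if (length(for_items)) dcm_value(for_items[[1]], 0x0020, 0x0052) else NULL
  need(is.character(for_uid) && nzchar(for_uid), "missing FrameOfReferenceUID")

  ss_items <- dcm_value(ds, 0x3006, 0x0020, list())
  need(length(ss_items) >= 1, "empty StructureSetROISequence")
  roi_numbers <- integer()
  for (item in ss_items) {
    num <- dcm_value(item, 0x3006, 0x0022)
    need(is.numeric(num) && length(num) == 1 && num == round(num),
         "ROINumber is not an integer string")
    need(nzchar(dcm_value(item, 0x3006, 0x0026, "")), "ROI with empty ROIName")
    need(identical(dcm_value(item, 0x3006, 0x0024), for_uid),
         "ROI references a different frame of reference")
    roi_numbers <- c(roi_numbers, as.integer(num))
  }
  need(!anyDuplicated(roi_numbers), "duplicate ROINumbers")

  rc_items <- dcm_value(ds, 0x3006, 0x0039, list())
  need(length(rc_items) >= 1, "empty ROIContourSequence")
  for (item in rc_items) {
    ref <- dcm_value(item, 0x3006, 0x0084)
    need(as.integer(ref) %in% roi_numbers,
         "ROIContour references unknown ROINumber")
    color <- dcm_value(item, 0x3006, 0x002A)
    need(length(color) == 3 && all(color >= 0 & color <= 255),
         "ROIDisplayColor is not an RGB triplet")
    for (ct in dcm_value(item, 0x3006, 0x0040, list())) {
      type <- dcm_value(ct, 0x3006, 0x0042)
      need(type %in% c("CLOSED_PLANAR", "POINT"),
           paste("unsupported ContourGeometricType", type))
      npts <- dcm_value(ct, 0x3006, 0x0046)
      data <- dcm_value(ct, 0x3006, 0x0050)
      need(all(is.finite(data)), "non-numeric ContourData")
      need(length(data) == 3 * npts,
           "NumberOfContourPoints does not match ContourData length")
      if (identical(type, "CLOSED_PLANAR")) {
        need(npts >= 3, "CLOSED_PLANAR contour with fewer than 3 points")
        zs <- matrix(data, ncol = 3, byrow = TRUE)[, 3]
        need(diff(range(zs)) < 1e-6, "CLOSED_PLANAR contour is not planar")
      }
    }
  }
  obs_items <- dcm_value(ds, 0x3006, 0x0080, list())
  for (item in obs_items) {
    need(as.integer(dcm_value(item, 0x3006, 0x0084)) %in% roi_numbers,
         "RTROIObservation references unknown ROINumber")
  }
  probs
}

#' Write a synthetic water-equivalent CT series
#'
#' Treatment planning systems need an image series to host structures; the
#' phantom is water-equivalent by construction, so the series assigns 0 HU
#' (water) to voxels inside any body-region cuboid and -1000 HU (air)
#' elsewhere, on an axial grid covering the phantom plus a margin.
#'
#' @param phantom A `scaled_phantom` in the `"dicom"` frame.
#' @param voxel Voxel size in mm: scalar or `c(dL, dP, dS)`.
#' @param path Output directory (created if needed).
#' @param margin Margin around the bounding box, mm.
#' @param hu_water,hu_air Stored HU values.
#' @param max_voxels Memory budget; grids above it raise an error suggesting
#'   coarser voxels.
#' @param metadata As in [write_rtstruct()].
#' @return List with `files`, `frame_of_reference_uid`, `grid` (the L/P/S
#'   voxel-centre vectors), invisibly.
#' @export
write_synthetic_ct <- function(phantom, voxel = 2.5, path, margin = 10,
                               hu_water = 0, hu_air = -1000,
                               max_voxels = 5e7, metadata = list()) {
  stopifnot(inherits(phantom, "scaled_phantom"))
  if (phantom$frame != "dicom") stop("write_synthetic_ct: phantom must be in the 'dicom' frame")
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  stopifnot(all(voxel > 0))
  boxes <- c(unname(phantom$regions), unname(phantom$arms))
  allc <- do.call(rbind, lapply(boxes, function(r) r$corners))
  lo <- apply(allc, 2, min) - margin
  hi <- apply(allc, 2, max) + margin
  grid <- lapply(1:3, function(j) {
    k <- ceiling((hi[j] - lo[j]) / voxel[j])
    lo[j] + (seq_len(k) - 0.5) * voxel[j]
  })
  nvox <- prod(lengths(grid))
  if (nvox > max_voxels) {
    stop(sprintf("synthetic CT grid of %.3g voxels exceeds the budget of %.3g; use coarser voxels",
                 nvox, max_voxels))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  md <- utils::modifyList(list(
    patient_name = "agephantom", patient_id = "AGEPHANTOM",
    date = format(Sys.Date(), "%Y%m%d"), time = format(Sys.time(), "%H%M%S")
  ), metadata)
  for_uid <- new_uid(); study_uid <- md$study_uid %||% new_uid(); series_uid <- new_uid()
  nL <- length(grid[[1]]); nP <- length(grid[[2]])

  # Per-slice HU: union of axis-aligned cuboids, separable in L/P.
  in_box_LP <- lapply(boxes, function(r) {
    list(L = grid[[1]] >= r$lims[1, 1] & grid[[1]] <= r$lims[2, 1],
         P = grid[[2]] >= r$lims[1, 2] & grid[[2]] <= r$lims[2, 2],
         Srange = r$lims[, 3])
  })
  files <- character(length(grid[[3]]))
  for (k in seq_along(grid[[3]])) {
    s <- grid[[3]][k]
    hu <- matrix(hu_air, nrow = nP, ncol = nL) # rows along P, columns along L
    for (b in in_box_LP) {
      if (s >= b$Srange[1] && s <= b$Srange[2]) {
        hu[b$P, b$L] <- hu_water
      }
    }
    sop_uid <- new_uid()
    dataset <- c(
      dcm_elem(0x0008, 0x0008, "CS", "ORIGINAL\\PRIMARY\\AXIAL"),
      dcm_elem(0x0008, 0x0016, "UI", UID_SOP_CT),
      dcm_elem(0x0008, 0x0018, "UI", sop_uid),
      dcm_elem(0x0008, 0x0020, "DA", md$date),
      dcm_elem(0x0008, 0x0030, "TM", md$time),
      dcm_elem(0x0008, 0x0050, "SH", ""),
      dcm_elem(0x0008, 0x0060, "CS", "CT"),
      dcm_elem(0x0008, 0x0070, "LO", "agephantom"),
      dcm_elem(0x0008, 0x0090, "PN", ""),
      dcm_elem(0x0010, 0x0010, "PN", md$patient_name),
      dcm_elem(0x0010, 0x0020, "LO", md$patient_id),
      dcm_elem(0x0010, 0x0030, "DA", ""),
      dcm_elem(0x0010, 0x0040, "CS", "O"),
      dcm_elem(0x0018, 0x0050, "DS", format_ds(voxel[3])),
      dcm_elem(0x0020, 0x000D, "UI", study_uid),
      dcm_elem(0x0020, 0x000E, "UI", series_uid),
      dcm_elem(0x0020, 0x0010, "SH", "1"),
      dcm_elem(0x0020, 0x0011, "IS", "2"),
      dcm_elem(0x0020, 0x0013, "IS", as.character(k)),
      dcm_elem(0x0020, 0x0032, "DS", format_ds(c(grid[[1]][1], grid[[2]][1], s))),
      dcm_elem(0x0020, 0x0037, "DS", format_ds(c(1, 0, 0, 0, 1, 0), digits = 0)),
      dcm_elem(0x0020, 0x0052, "UI", for_uid),
      dcm_elem(0x0020, 0x1041, "DS", format_ds(s)),
      dcm_us(0x0028, 0x0002, 1),
      dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, nP), # Rows
      dcm_us(0x0028, 0x0011, nL), # Columns
      dcm_elem(0x0028, 0x0030, "DS", format_ds(c(voxel[2], voxel[1]))),
      dcm_us(0x0028, 0x0100, 16),
      dcm_us(0x0028, 0x0101, 16),
      dcm_us(0x0028, 0x0102, 15),
      dcm_us(0x0028, 0x0103, 1), # signed
      dcm_elem(0x0028, 0x1052, "DS", "0"),
      dcm_elem(0x0028, 0x1053, "DS", "1"),
      dcm_elem(0x7FE0, 0x0010, "OW", int16_le(as.vector(t(hu))))
    )
    files[k] <- file.path(path, sprintf("ct_%04d.dcm", k))
    dcm_write_file(files[k], UID_SOP_CT, sop_uid, dataset)
  }
  invisible(list(files = files, frame_of_reference_uid = for_uid, grid = grid,
                 voxel = voxel))
}

#' Read one slice of a synthetic CT series
#'
#' @param path CT slice file path.
#' @return List with `hu` (matrix, rows along P), `position` (L, P, S of the
#'   first voxel centre), `pixel_spacing` and `slice_location`.
#' @export
read_ct_slice <- function(path) {
  parsed <- dcm_parse_file(path)
  ds <- parsed$dataset
  rows <- dcm_value(ds, 0x0028, 0x0010)
  cols <- dcm_value(ds, 0x0028, 0x0011)
  raw_px <- dcm_value(ds, 0x7FE0, 0x0010)
  v <- readBin(raw_px, "integer", n = rows * cols, size = 2,
               signed = TRUE, endian = "little")
  list(hu = matrix(v, nrow = rows, ncol = cols, byrow = TRUE),
       position = dcm_value(ds, 0x0020, 0x0032),
       pixel_spacing = dcm_value(ds, 0x0028, 0x0030),
       slice_location = dcm_value(ds, 0x0020, 0x1041))
}
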