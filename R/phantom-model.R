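# Domain model: body-region cuboids and organ point grids.
#
# Phantom-frame axis convention (stated once, asserted everywhere):
#   +x = patient left-to-right axis (patient left at +x), symmetric about x = 0
#   +y = superior-to-inferior (head at small y; generic phantom starts at y = 1 cm)
#   +z = anterior-to-posterior (anterior boundary at small z)
# All phantom-frame lengths are centimetres.

AGE_KNOTS <- c(0.1, 1, 3, 5, 10, 15, 18)
DIRECTIONS <- c("x", "y", "z")
REGION_IDS <- c("uh", "lh", "n", "tr", "ar", "lg")
CHAIN_IDS <- c("uh", "lh", "n", "tr", "lg")
GENERIC_AGE <- 18
PHANTOM_SCHEMA <- "agephantom-phantom/1"

#' Construct an axis-aligned body-region cuboid
#'
#' A body region is one of the six scalable regions of the phantom (upper
#' head `uh`, lower head `lh`, neck `n`, trunk `tr`, arms `ar`, legs `lg`),
#' represented by the eight corner points of an axis-aligned cuboid in the
#' phantom frame (cm).
#'
#' @param id Region identifier, one of `"uh"`, `"lh"`, `"n"`, `"tr"`,
#'   `"ar"`, `"lg"`.
#' @param xlim,ylim,zlim Length-2 numeric vectors giving the cuboid extent
#'   along each axis (cm).
#' @return A `body_region` object: the 8 x 3 corner matrix plus cached
#'   boundaries (`y_sbr`, `y_ibr`, `z_abr`) and extents (`l_x`, `l_y`, `l_z`).
#' @export
body_region <- function(id, xlim, ylim, zlim) {
  id <- match.arg(id, REGION_IDS)
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(zlim) == 2)
  xlim <- sort(as.numeric(xlim)); ylim <- sort(as.numeric(ylim)); zlim <- sort(as.numeric(zlim))
  corners <- as.matrix(expand.grid(x = xlim, y = ylim, z = zlim))
  rownames(corners) <- NULL
  region_from_corners(id, corners)
}

#' Construct a body region from its eight corner points
#'
#' @param id Region identifier (see [body_region()]).
#' @param corners An 8 x 3 numeric matrix of corner coordinates (cm).
#' @return A `body_region` object.
#' @export
region_from_corners <- function(id, corners) {
  id <- match.arg(id, REGION_IDS)
  corners <- as.matrix(corners)
  probs <- check_cuboid_corners(corners)
  if (length(probs)) {
    stop("invalid corners for region '", id, "': ", paste(probs, collapse = "; "))
  }
  colnames(corners) <- c("x", "y", "z")
  lims <- apply(corners, 2, range)
  r <- list(
    id = id,
    corners = corners,
    lims = lims,
    y_sbr = unname(lims[1, "y"]), # superior boundary: smallest y (head at small y)
    y_ibr = unname(lims[2, "y"]),
    z_abr = unname(lims[1, "z"]), # anterior boundary: smallest z
    l_x = unname(diff(lims[, "x"])),
    l_y = unname(diff(lims[, "y"])),
    l_z = unname(diff(lims[, "z"]))
  )
  class(r) <- "body_region"
  r
}

# Structural checks for an 8-corner axis-aligned cuboid; returns problems.
check_cuboid_corners <- function(corners) {
  probs <- character()
  if (!is.numeric(corners) || !all(is.finite(corners))) {
    return("corners must be finite numeric coordinates")
  }
  if (!is.matrix(corners) || nrow(corners) != 8 || ncol(corners) != 3) {
    return(sprintf("expected an 8 x 3 corner matrix, got %d x %d",
                   NROW(corners), NCOL(corners)))
  }
  for (j in 1:3) {
    vals <- unique(corners[, j])
    if (length(vals) != 2) {
      probs <- c(probs, sprintf(
        "axis %s has %d distinct coordinate values (axis-aligned cuboid needs exactly 2)",
        c("x", "y", "z")[j], length(vals)))
    }
  }
  if (!length(probs)) {
    expected <- as.matrix(expand.grid(unique(corners[, 1]), unique(corners[, 2]),
                                      unique(corners[, 3])))
    key <- function(m) sort(apply(m, 1, paste, collapse = ","))
    if (!identical(key(expected), key(corners))) {
      probs <- c(probs, "corners are not the 8 vertices of an axis-aligned cuboid")
    }
    if (any(apply(corners, 2, function(v) diff(range(v))) <= 0)) {
      probs <- c(probs, "cuboid has a zero-length extent")
    }
  }
  probs
}

#' Construct an organ point grid
#'
#' Organs are modelled as grids of points lying inside one body region; each
#' organ scales with the region that contains it.
#'
#' @param name Organ name (e.g. `"heart"`, `"kidney_l"`).
#' @param region Identifier of the containing body region.
#' @param points An N x 3 numeric matrix of point coordinates (cm, phantom
#'   frame), N >= 1.
#' @return An `organ_grid` object. Organs with fewer than 4 non-coplanar
#'   points are flagged `contourable = FALSE`: they cannot support a 3-D
#'   convex hull and are exported as point structures.
#' @export
organ_grid <- function(name, region, points) {
  region <- match.arg(region, REGION_IDS)
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3 || nrow(points) < 1) {
    stop("organ '", name, "': points must be an N x 3 matrix with N >= 1")
  }
  if (!all(is.finite(points))) stop("organ '", name, "': non-finite coordinates")
  colnames(points) <- c("x", "y", "z")
  o <- list(name = as.character(name), region = region, points = points,
            n = nrow(points), contourable = points_span_3d(points))
  class(o) <- "organ_grid"
  o
}

# TRUE when the point set has >= 4 points not all lying in one plane.
points_span_3d <- function(points, tol = 1e-9) {
  if (nrow(points) < 4) return(FALSE)
  centered <- sweep(points, 2, colMeans(points))
  sv <- svd(centered, nu = 0, nv = 0)$d
  scale <- max(sv[1], 1)
  sv[3] > tol * scale
}

#' Assemble a generic (age-18) phantom
#'
#' @param regions Named list of the five chained `body_region`s in
#'   superior-to-inferior order: `uh`, `lh`, `n`, `tr`, `lg`. Adjacent
#'   regions must share their y boundary exactly.
#' @param arms List of one or two `ar` cuboids flanking the trunk; arms scale
#'   with their own factors but are outside the y-contiguity chain.
#' @param organs List of `organ_grid`s.
#' @param generic_age Age of the generic phantom in years (18).
#' @param y_origin Superior boundary of the upper head (1 cm).
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return A `generic_phantom` object.
#' @export
generic_phantom <- function(regions, arms = list(), organs = list(),
                            generic_age = GENERIC_AGE, y_origin = 1,
                            validate = TRUE) {
  p <- list(regions = regions, arms = arms, organs = organs,
            generic_age = generic_age, y_origin = y_origin)
  class(p) <- "generic_phantom"
  if (validate) assert_valid_phantom(p)
  p
}

#' Validate a generic phantom's structural invariants
#'
#' Checks the region chain (order, contiguity along y), x-symmetry of every
#' cuboid, the y-origin of the upper head, and containment of every organ
#' point in its region.
#'
#' @param phantom A `generic_phantom`.
#' @param tol Numeric tolerance (cm) for boundary equality.
#' @return Character vector of violations (length 0 when valid).
#' @export
validate_phantom <- function(phantom, tol = 1e-9) {
  probs <- character()
  ids <- vapply(phantom$regions, function(r) r$id, "")
  if (!identical(unname(ids), CHAIN_IDS)) {
    probs <- c(probs, sprintf("regions must be ordered %s; got %s",
                              paste(CHAIN_IDS, collapse = ","),
                              paste(ids, collapse = ",")))
    return(probs) # remaining checks assume the chain
  }
  names(phantom$regions) <- ids
  for (k in seq_len(length(CHAIN_IDS) - 1)) {
    a <- phantom$regions[[k]]; b <- phantom$regions[[k + 1]]
    if (abs(a$y_ibr - b$y_sbr) > tol) {
      probs <- c(probs, sprintf(
        "regions not contiguous: %s y_ibr = %.10g but %s y_sbr = %.10g",
        a$id, a$y_ibr, b$id, b$y_sbr))
    }
  }
  if (abs(phantom$regions[["uh"]]$y_sbr - phantom$y_origin) > tol) {
    probs <- c(probs, sprintf(
      "upper head must start at y = %g cm; found y_sbr = %.10g",
      phantom$y_origin, phantom$regions[["uh"]]$y_sbr))
  }
  for (r in phantom$regions) {
    if (!x_symmetric(r$corners, tol)) {
      probs <- c(probs, sprintf("region %s is not symmetric about the x-axis", r$id))
    }
  }
  if (length(phantom$arms)) {
    allc <- do.call(rbind, lapply(phantom$arms, function(a) a$corners))
    if (!x_symmetric(allc, tol)) {
      probs <- c(probs, "arm cuboids are not jointly symmetric about the x-axis")
    }
    for (a in phantom$arms) {
      if (a$id != "ar") probs <- c(probs, "arm cuboids must have id 'ar'")
    }
  }
  region_lookup <- phantom$regions
  for (o in phantom$organs) {
    reg <- if (o$region == "ar") phantom$arms[[1]] else region_lookup[[o$region]]
    if (is.null(reg)) {
      probs <- c(probs, sprintf("organ %s assigned to unknown region %s", o$name, o$region))
      next
    }
    out <- points_outside_box(o$points, reg$lims, tol)
    if (any(out)) {
      probs <- c(probs, sprintf("organ %s: %d point(s) outside region %s cuboid",
                                o$name, sum(out), o$region))
    }
  }
  probs
}

x_symmetric <- function(corners, tol = 1e-9) {
  mirrored <- corners
  mirrored[, 1] <- -mirrored[, 1]
  key <- function(m) sort(apply(round(m / tol) * tol, 1, paste, collapse = ","))
  isTRUE(all.equal(key(mirrored), key(corners), tolerance = 0))
}

points_outside_box <- function(points, lims, tol = 1e-9) {
  points[, 1] < lims[1, 1] - tol | points[, 1] > lims[2, 1] + tol |
  points[, 2] < lims[1, 2] - tol | points[, 2] > lims[2, 2] + tol |
  points[, 3] < lims[1, 3] - tol | points[, 3] > lims[2, 3] + tol
}

assert_valid_phantom <- function(phantom, tol = 1e-9) {
  probs <- validate_phantom(phantom, tol)
  if (length(probs)) {
    stop("phantom validation failed:\n  - ", paste(probs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(phantom)
}

#' Read a phantom definition from JSON
#'
#' Reads the versioned `agephantom-phantom/1` JSON schema (lengths in cm) and
#' validates every structural invariant, reporting all violations at once.
#'
#' @param path Path to a phantom definition JSON file.
#' @return A validated `generic_phantom`.
#' @export
read_phantom_definition <- function(path) {
  if (!file.exists(path)) stop("phantom definition not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("schema", "generic_age", "y_origin", "regions")) {
    if (is.null(doc[[field]])) stop("phantom definition missing field '", field, "'")
  }
  if (!identical(doc$schema, PHANTOM_SCHEMA)) {
    stop("unsupported schema '", doc$schema, "' (expected '", PHANTOM_SCHEMA, "')")
  }
  parse_region <- function(rec, what) {
    if (is.null(rec$id)) stop(what, " entry missing field 'id'")
    if (is.null(rec$corners)) stop(what, " '", rec$id, "' missing field 'corners'")
    corners <- rec$corners
    probs <- check_cuboid_corners(if (is.matrix(corners)) corners else as.matrix(corners))
    if (length(probs)) {
      stop("validation error in ", what, " '", rec$id, "': ",
           paste(probs, collapse = "; "), call. = FALSE)
    }
    region_from_corners(rec$id, corners)
  }
  # jsonlite simplifies homogeneous record lists to a data.frame; normalize.
  as_records <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) {
      rec <- lapply(x, function(col) if (is.list(col)) col[[i]] else col[i])
      rec
    }) else x
  }
  regions <- lapply(as_records(doc$regions), parse_region, what = "region")
  names(regions) <- vapply(regions, function(r) r$id, "")
  arms <- lapply(as_records(doc$arms), parse_region, what = "arm")
  organs <- lapply(as_records(doc$organs), function(rec) {
    for (field in c("name", "region", "points")) {
      if (is.null(rec[[field]])) stop("organ entry missing field '", field, "'")
    }
    organ_grid(rec$name, rec$region, rec$points)
  })
  generic_phantom(regions, arms = arms, organs = organs,
                  generic_age = doc$generic_age, y_origin = doc$y_origin)
}

#' Write a phantom definition to JSON
#'
#' Coordinates are written as decimal text at full double precision so that a
#' write/read round trip reproduces them bit-identically.
#'
#' @param phantom A valid `generic_phantom`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phantom_definition <- function(phantom, path) {
  assert_valid_phantom(phantom)
  ser_region <- function(r) list(id = r$id, corners = unname(r$corners))
  doc <- list(
    schema = PHANTOM_SCHEMA,
    generic_age = phantom$generic_age,
    y_origin = phantom$y_origin,
    regions = lapply(unname(phantom$regions), ser_region),
    arms = lapply(unname(phantom$arms), ser_region),
    organs = lapply(phantom$organs, function(o) {
      list(name = o$name, region = o$region, points = unname(o$points))
    })
  )
  # digits = I(17): 17 significant digits, enough for an exact double round trip
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.generic_phantom <- function(x, ...) {
  h <- x$regions[[length(x$regions)]]$y_ibr - x$regions[[1]]$y_sbr
  cat(sprintf("Generic phantom (age %g y): %d chained regions, %d arm cuboid(s), %d organs, height %.1f cm\n",
              x$generic_age, length(x$regions), length(x$arms), length(x$organs), h))
  invisible(x)
}

#' @export
print.organ_grid <- function(x, ...) {
  cat(sprintf("Organ grid '%s' (region %s): %d points%s\n", x$name, x$region,
              x$n, if (x$contourable) "" else " [non-contourable]"))
  invisible(x)
}
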