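# Age transformation of the phantom geometry, and reorientation into the
# DICOM patient frame (head-first supine).
#
# x is scaled about the mid-sagittal plane (the phantom is x-symmetric);
# y is rebuilt as a telescoping sum of scaled region lengths measured from
# the top of the upper head (the transformed phantom is re-based at y_t = 0);
# z is scaled from each region's anterior boundary and shifted so that all
# regions share the head's posterior-anterior mid-plane.

#' Build a transformation context
#'
#' Caches, per body region, the generic boundaries and lengths together with
#' the scaled y-offsets (cumulative scaled lengths of the superior regions)
#' and the per-region z-shift
#' `z_shift(r) = (l_head,z * F(z, uh) - l_r,z * F(z, r)) / 2`,
#' which centres every region's scaled z-extent on the head's scaled
#' mid-plane.
#'
#' @param phantom A `generic_phantom`.
#' @param factors A `scaling_factor_set` (see [scaling_factors()]).
#' @param head_ref Region whose z-length defines the reference mid-plane
#'   (default the upper head, `"uh"`).
#' @return A `transform_context`.
#' @export
transform_context <- function(phantom, factors, head_ref = "uh") {
  stopifnot(inherits(phantom, "generic_phantom"),
            inherits(factors, "scaling_factor_set"))
  head_ref <- match.arg(head_ref, CHAIN_IDS)
  fac <- factors$factors
  chain <- phantom$regions
  l_head_z <- chain[[head_ref]]$l_z
  head_term <- l_head_z * fac["z", "uh"]

  info <- list()
  offset <- 0
  for (r in chain) {
    info[[r$id]] <- list(
      y_sbr = r$y_sbr, y_ibr = r$y_ibr, z_abr = r$z_abr,
      l_y = r$l_y, l_z = r$l_z,
      y_offset = offset,
      z_shift = (head_term - r$l_z * fac["z", r$id]) / 2
    )
    offset <- offset + r$l_y * fac["y", r$id]
  }
  # Arms: own 'ar' factors; re-attached at the trunk's scaled superior
  # boundary (the paper fixes them parallel to the sagittal plane but gives
  # no coordinates).
  if (length(phantom$arms)) {
    tr <- chain[["tr"]]
    a1 <- phantom$arms[[1]]
    info[["ar"]] <- list(
      y_sbr = a1$y_sbr, y_ibr = a1$y_ibr, z_abr = a1$z_abr,
      l_y = a1$l_y, l_z = a1$l_z,
      y_offset = info[["tr"]]$y_offset +
        (a1$y_sbr - tr$y_sbr) * fac["y", "ar"],
      z_shift = (head_term - a1$l_z * fac["z", "ar"]) / 2
    )
  }
  ctx <- list(factors = fac, age = factors$age, regions = info,
              head_ref = head_ref, l_head_z = l_head_z)
  class(ctx) <- "transform_context"
  ctx
}

#' Transform an x-coordinate
#'
#' The phantom is symmetric about the x-axis, so the transformed coordinate
#' is simply `x_t = x * F_cont(x, r, a)`.
#'
#' @param x Numeric vector of x-coordinates (cm).
#' @param r Body region id of the point(s).
#' @param ctx A `transform_context`.
#' @return Transformed x (cm); sign preserved.
#' @export
transform_x <- function(x, r, ctx) {
  r <- match.arg(r, REGION_IDS)
  x * ctx$factors["x", r]
}

#' Transform a y-coordinate
#'
#' Telescoping sum over regions from the upper head down to the point's
#' region: the full scaled length of each superior region, plus the scaled
#' offset of the point below its own region's superior boundary. The
#' transformed phantom starts at `y_t = 0`.
#'
#' @param y Numeric vector of y-coordinates (cm); must lie within region
#'   `r`'s `[y_sbr, y_ibr]`.
#' @inheritParams transform_x
#' @return Transformed y (cm), `>= 0`.
#' @export
transform_y <- function(y, r, ctx) {
  r <- match.arg(r, REGION_IDS)
  ri <- ctx$regions[[r]]
  if (is.null(ri)) stop("region '", r, "' not present in transform context")
  tol <- 1e-9
  bad <- y < ri$y_sbr - tol | y > ri$y_ibr + tol
  if (any(bad)) {
    stop(sprintf("transform_y: %d point(s) outside region %s y-bounds [%.6g, %.6g]",
                 sum(bad), r, ri$y_sbr, ri$y_ibr))
  }
  ri$y_offset + (y - ri$y_sbr) * ctx$factors["y", r]
}

#' Transform a z-coordinate
#'
#' `z_t = (z - z_abr_r) * F_cont(z, r, a) + z_shift(r)`, where the shift
#' aligns every region's scaled z mid-plane with the head's.
#'
#' @param z Numeric vector of z-coordinates (cm); must lie within region
#'   `r`'s z-extent.
#' @inheritParams transform_x
#' @return Transformed z (cm).
#' @export
transform_z <- function(z, r, ctx) {
  r <- match.arg(r, REGION_IDS)
  ri <- ctx$regions[[r]]
  if (is.null(ri)) stop("region '", r, "' not present in transform context")
  tol <- 1e-9
  bad <- z < ri$z_abr - tol | z > ri$z_abr + ri$l_z + tol
  if (any(bad)) {
    stop(sprintf("transform_z: %d point(s) outside region %s z-extent [%.6g, %.6g]",
                 sum(bad), r, ri$z_abr, ri$z_abr + ri$l_z))
  }
  (z - ri$z_abr) * ctx$factors["z", r] + ri$z_shift
}

transform_points <- function(pts, r, ctx) {
  out <- cbind(x = transform_x(pts[, 1], r, ctx),
               y = transform_y(pts[, 2], r, ctx),
               z = transform_z(pts[, 3], r, ctx))
  out
}

#' Scale a generic phantom to a target age
#'
#' Applies the x/y/z transformation to every region corner and every organ
#' point, using each point's own region's scaling factors.
#'
#' @param phantom A `generic_phantom`.
#' @param table A `growth_table` consistent with the phantom at age 18.
#' @param age Target age in years (>= 0.1; above 18 clamps to the adult
#'   phantom).
#' @param head_ref See [transform_context()].
#' @return A `scaled_phantom` in the phantom frame (cm), holding transformed
#'   regions, arms and organs plus the factor set used.
#' @export
scale_phantom <- function(phantom, table, age, head_ref = "uh") {
  assert_valid_phantom(phantom)
  factors <- scaling_factors(table, age)
  ctx <- transform_context(phantom, factors, head_ref = head_ref)
  tr_region <- function(r) {
    region_from_corners(r$id, transform_points(r$corners, r$id, ctx))
  }
  regions <- lapply(phantom$regions, tr_region)
  names(regions) <- vapply(regions, function(r) r$id, "")
  arms <- lapply(phantom$arms, tr_region)
  organs <- lapply(phantom$organs, function(o) {
    pts <- tryCatch(transform_points(o$points, o$region, ctx),
                    error = function(e) stop("while transforming organ '", o$name,
                                             "': ", conditionMessage(e), call. = FALSE))
    organ_grid(o$name, o$region, pts)
  })
  sp <- list(age = factors$age, regions = regions, arms = arms, organs = organs,
             frame = "phantom", factors = factors, head_ref = head_ref)
  class(sp) <- "scaled_phantom"
  sp
}

# DICOM reorientation (head-first supine), pinned convention:
#   L = 10 * x   (patient left at +L; phantom is centred at x = 0)
#   P = 10 * z   (anterior at smaller P)
#   S = -10 * y  (head, at small phantom y, maps to the largest S)
# A proper rotation up to the cm -> mm unit change; exactly invertible.

#' Reorient a scaled phantom into the DICOM patient frame
#'
#' Maps the phantom frame (cm) to the DICOM LPS patient frame (mm) for a
#' head-first supine orientation: `(L, P, S) = (10x, 10z, -10y)`. The map is
#' rigid up to the unit change and exactly invertible via
#' [reorient_to_phantom()].
#'
#' @param phantom A `scaled_phantom` in the `"phantom"` frame.
#' @return The phantom with all coordinates in mm LPS, `frame = "dicom"`.
#' @export
reorient_to_dicom <- function(phantom) {
  stopifnot(inherits(phantom, "scaled_phantom"))
  if (phantom$frame != "phantom") {
    stop("reorient_to_dicom: phantom is already in the '", phantom$frame, "' frame")
  }
  map_frame(phantom, function(p) {
    cbind(L = 10 * p[, 1], P = 10 * p[, 3], S = -10 * p[, 2])
  }, "dicom")
}

#' Invert the DICOM reorientation
#' @param phantom A `scaled_phantom` in the `"dicom"` frame.
#' @return The phantom back in the phantom frame (cm).
#' @export
reorient_to_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "scaled_phantom"))
  if (phantom$frame != "dicom") {
    stop("reorient_to_phantom: phantom is in the '", phantom$frame, "' frame")
  }
  map_frame(phantom, function(p) {
    cbind(x = p[, 1] / 10, y = -p[, 3] / 10, z = p[, 2] / 10)
  }, "phantom")
}

map_frame <- function(phantom, fun, frame) {
  # Rebuild cuboids from mapped corners; organ_grid() requires columns x/y/z
  # so rename after mapping.
  remap_region <- function(r) {
    m <- fun(r$corners)
    colnames(m) <- c("x", "y", "z")
    region_from_corners(r$id, m)
  }
  phantom$regions <- lapply(phantom$regions, remap_region)
  names(phantom$regions) <- vapply(phantom$regions, function(r) r$id, "")
  phantom$arms <- lapply(phantom$arms, remap_region)
  phantom$organs <- lapply(phantom$organs, function(o) {
    m <- fun(o$points)
    colnames(m) <- c("x", "y", "z")
    organ_grid(o$name, o$region, m)
  })
  phantom$frame <- frame
  phantom
}

#' Total height of a scaled phantom
#'
#' Height is the y-extent (or S-extent in the DICOM frame) of the chained
#' body regions (upper head to legs); arms are excluded.
#'
#' @param phantom A `scaled_phantom`.
#' @return Height in cm.
#' @export
phantom_height <- function(phantom) {
  stopifnot(inherits(phantom, "scaled_phantom"))
  ax <- if (phantom$frame == "dicom") 3 else 2
  vals <- unlist(lapply(phantom$regions, function(r) r$corners[, ax]))
  h <- max(vals) - min(vals)
  if (phantom$frame == "dicom") h / 10 else h
}

#' @export
print.scaled_phantom <- function(x, ...) {
  cat(sprintf("Scaled phantom: age %g y, frame '%s', height %.1f cm, %d organs\n",
              x$age, x$frame, phantom_height(x), length(x$organs)))
  invisible(x)
}
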