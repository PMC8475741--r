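# Independent scalar reference path for the age transformation.
#
# This deliberately re-derives the transformed coordinates point by point
# with plain loops and direct calls to continuous_factor(), sharing no code
# with the vectorized path in geometry-transform.R. It plays the role of the
# second, independently implemented phantom representation in the geometric
# self-consistency checks (volume percent differences and NMSD should be
# numerically zero between the two paths).

#' Scale a phantom with the scalar reference implementation
#'
#' A second, independently coded implementation of the age transformation,
#' evaluated one point at a time. Used to cross-check the vectorized
#' [scale_phantom()] path: the two must agree to numerical precision
#' (NMSD ~ 0) for every organ at every age.
#'
#' @inheritParams scale_phantom
#' @return A `scaled_phantom` in the phantom frame.
#' @export
scale_phantom_pointwise <- function(phantom, table, age, head_ref = "uh") {
  assert_valid_phantom(phantom)
  age <- snap_age(age)
  chain <- phantom$regions
  f <- function(d, r) continuous_factor(table, d, r, age)
  l_head_z <- chain[[head_ref]]$l_z

  one_point <- function(pt, rid) {
    xt <- pt[1] * f("x", rid)
    # y: telescoping sum from the upper head down to the point's region;
    # arms anchor at the trunk's scaled superior boundary and use ar factors.
    anchor <- if (rid == "ar") "tr" else rid
    yt <- 0
    for (rr in chain) {
      if (rr$id == anchor) {
        yt <- yt + (pt[2] - rr$y_sbr) * f("y", rid)
        break
      }
      yt <- yt + (rr$y_ibr - rr$y_sbr) * f("y", rr$id)
    }
    reg <- if (rid == "ar") phantom$arms[[1]] else chain[[rid]]
    zshift <- (l_head_z * f("z", "uh") - reg$l_z * f("z", rid)) / 2
    zt <- (pt[3] - reg$z_abr) * f("z", rid) + zshift
    c(xt, yt, zt)
  }

  tr_matrix <- function(m, rid) {
    out <- matrix(NA_real_, nrow(m), 3)
    for (i in seq_len(nrow(m))) out[i, ] <- one_point(m[i, ], rid)
    colnames(out) <- c("x", "y", "z")
    out
  }
  regions <- lapply(chain, function(r) region_from_corners(r$id, tr_matrix(r$corners, r$id)))
  names(regions) <- vapply(regions, function(r) r$id, "")
  arms <- lapply(phantom$arms, function(a) region_from_corners("ar", tr_matrix(a$corners, "ar")))
  organs <- lapply(phantom$organs, function(o) {
    organ_grid(o$name, o$region, tr_matrix(o$points, o$region))
  })
  sp <- list(age = age, regions = regions, arms = arms, organs = organs,
             frame = "phantom", factors = scaling_factors(table, age),
             head_ref = head_ref)
  class(sp) <- "scaled_phantom"
  sp
}
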