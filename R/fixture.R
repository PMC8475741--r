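# Seeded synthetic generic phantom + growth table.
#
# The true generic-phantom coordinates and the underlying growth
# measurements are not public, so this deterministic fixture reproduces
# their stated structural properties: an adult-sized (176 cm) phantom of
# five chained cuboids plus arm cuboids, the nine organ groups (brain
# sub-lobes, heart, liver, lungs, stomach, pancreas, kidneys, thyroid
# lobes) plus a one-point pituitary, a 55-point heart and 15-point kidneys
# to exercise the low-resolution path, and a growth table whose head
# fraction falls from ~1/4 of total height at age 0.1 to ~1/7 at age 18.

# Adult (age-18) region extents, cm. Heights sum to 176 from y = 1.
.fixture_regions <- function() {
  list(
    uh = body_region("uh", c(-7.5, 7.5), c(1, 13.6), c(0, 19)),
    lh = body_region("lh", c(-6.5, 6.5), c(13.6, 26.2), c(1, 18)),
    n  = body_region("n",  c(-5.5, 5.5), c(26.2, 31.2), c(4, 15)),
    tr = body_region("tr", c(-17, 17),   c(31.2, 91.2), c(-1, 21)),
    lg = body_region("lg", c(-17, 17),   c(91.2, 177),  c(3, 16))
  )
}

.fixture_arms <- function() {
  list(
    body_region("ar", c(18, 26),   c(31.2, 91.2), c(5, 14)), # patient left
    body_region("ar", c(-26, -18), c(31.2, 91.2), c(5, 14))  # patient right
  )
}

# Superior-inferior sizes (cm) per age knot; totals give newborn height 55
# (head fraction 13.75/55 = 0.25) through adult height 176 (25.2/176 = 1/7).
.fixture_y_sizes <- list(
  uh = c(6.875, 8.2, 9.2, 9.7, 10.7, 11.8, 12.6),
  lh = c(6.875, 8.2, 9.2, 9.7, 10.7, 11.8, 12.6),
  n  = c(2.0, 2.6, 3.2, 3.6, 4.2, 4.8, 5.0),
  tr = c(19.0, 26.0, 33.0, 37.0, 46.0, 55.0, 60.0),
  ar = c(19.0, 26.0, 33.0, 37.0, 46.0, 55.0, 60.0),
  lg = c(20.25, 30.0, 41.4, 49.0, 66.4, 83.6, 85.8)
)

# Transverse (x, z) growth expressed as fraction of the adult extent: the
# head is closest to adult size at birth, the trunk and limbs furthest.
.fixture_xz_fractions <- list(
  uh = c(0.70, 0.80, 0.85, 0.88, 0.92, 0.97, 1.00),
  lh = c(0.70, 0.80, 0.85, 0.88, 0.92, 0.97, 1.00),
  n  = c(0.50, 0.60, 0.68, 0.73, 0.82, 0.93, 1.00),
  tr = c(0.40, 0.50, 0.58, 0.63, 0.75, 0.90, 1.00),
  ar = c(0.40, 0.50, 0.58, 0.63, 0.75, 0.90, 1.00),
  lg = c(0.40, 0.50, 0.58, 0.63, 0.75, 0.90, 1.00)
)

.fixture_growth_table <- function(regions, arms) {
  extents <- lapply(c(regions, list(ar = arms[[1]])), function(r) {
    c(x = r$l_x, y = r$l_y, z = r$l_z)
  })
  rows <- list()
  for (r in REGION_IDS) {
    for (i in seq_along(AGE_KNOTS)) {
      rows[[length(rows) + 1]] <- data.frame(
        direction = c("x", "y", "z"), region = r, age_years = AGE_KNOTS[i],
        size_cm = c(extents[[r]][["x"]] * .fixture_xz_fractions[[r]][i],
                    .fixture_y_sizes[[r]][i],
                    extents[[r]][["z"]] * .fixture_xz_fractions[[r]][i]))
    }
  }
  growth_table(do.call(rbind, rows))
}

# Organ boxes (cm, inside their region) and grid dimensions; n trims the
# lattice to an exact point count where stated.
.fixture_organs <- list(
  list("frontal_lobe_r",  "uh", c(-6, -1),     c(3, 8),      c(2, 8),   c(3, 3, 3), NA),
  list("frontal_lobe_l",  "uh", c(1, 6),       c(3, 8),      c(2, 8),   c(3, 3, 3), NA),
  list("temporal_lobe_r", "uh", c(-6.5, -2),   c(7, 11),     c(5, 12),  c(3, 3, 3), NA),
  list("temporal_lobe_l", "uh", c(2, 6.5),     c(7, 11),     c(5, 12),  c(3, 3, 3), NA),
  list("parietal_lobe_r", "uh", c(-6, -1),     c(2, 6),      c(8, 14),  c(3, 3, 3), NA),
  list("parietal_lobe_l", "uh", c(1, 6),       c(2, 6),      c(8, 14),  c(3, 3, 3), NA),
  list("cerebellum",      "uh", c(-4, 4),      c(9, 12),     c(12, 16), c(3, 3, 3), NA),
  list("occipital_lobe",  "uh", c(-4.5, 4.5),  c(4, 9),      c(13, 17), c(3, 3, 3), NA),
  list("inner_brain",     "uh", c(-3, 3),      c(6, 10),     c(7, 12),  c(3, 3, 3), NA),
  list("pituitary",       "uh", c(0, 0),       c(10.5, 10.5), c(9, 9),  c(1, 1, 1), 1),
  list("thyroid_lobe_r",  "n",  c(-2.7, -0.7), c(27.5, 30),  c(5, 8),   c(2, 3, 2), NA),
  list("thyroid_lobe_l",  "n",  c(0.7, 2.7),   c(27.5, 30),  c(5, 8),   c(2, 3, 2), NA),
  list("heart",           "tr", c(-6, 4),      c(38, 50),    c(4, 14),  c(4, 4, 4), 55),
  list("lung_r",          "tr", c(-14, -1),    c(34, 54),    c(2, 18),  c(3, 5, 3), NA),
  list("lung_l",          "tr", c(1, 14),      c(34, 54),    c(2, 18),  c(3, 5, 3), NA),
  list("liver",           "tr", c(-14, 2),     c(50, 62),    c(3, 17),  c(4, 3, 4), NA),
  list("stomach",         "tr", c(-2, 10),     c(52, 62),    c(5, 15),  c(3, 3, 3), NA),
  list("pancreas",        "tr", c(-6, 6),      c(58, 63),    c(8, 14),  c(4, 2, 3), NA),
  list("kidney_r",        "tr", c(-9, -3),     c(60, 70),    c(12, 19), c(2, 4, 2), 15),
  list("kidney_l",        "tr", c(3, 9),       c(60, 70),    c(12, 19), c(2, 4, 2), 15)
)

lattice_in_box <- function(xlim, ylim, zlim, dims) {
  ax <- function(lim, k) {
    if (k == 1) mean(lim) else seq(lim[1], lim[2], length.out = k)
  }
  g <- expand.grid(x = ax(xlim, dims[1]), y = ax(ylim, dims[2]), z = ax(zlim, dims[3]))
  as.matrix(g)
}

#' Generate the seeded synthetic fixture phantom and growth table
#'
#' Deterministic for a given seed: the region cuboids and growth table are
#' fixed, and the organ grid points get a small seeded jitter about regular
#' lattices (clamped inside each organ's box, so containment always holds).
#'
#' @param seed Integer seed controlling the organ point jitter.
#' @return List with `phantom` (a `generic_phantom`) and `growth`
#'   (a `growth_table` matching the phantom at age 18).
#' @export
generate_fixture_phantom <- function(seed = 7) {
  regions <- .fixture_regions()
  arms <- .fixture_arms()
  growth <- .fixture_growth_table(regions, arms)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  organs <- lapply(.fixture_organs, function(spec) {
    name <- spec[[1]]; region <- spec[[2]]
    xlim <- spec[[3]]; ylim <- spec[[4]]; zlim <- spec[[5]]
    dims <- spec[[6]]; n <- spec[[7]]
    pts <- lattice_in_box(xlim, ylim, zlim, dims)
    if (!is.na(n)) pts <- pts[seq_len(n), , drop = FALSE]
    if (nrow(pts) > 1) {
      spacing <- min(vapply(list(xlim, ylim, zlim), diff, 0)[dims > 1] /
                       (dims[dims > 1] - 1))
      jit <- matrix(stats::runif(length(pts), -0.15, 0.15) * spacing,
                    nrow = nrow(pts))
      pts <- pts + jit
      pts[, 1] <- pmin(pmax(pts[, 1], xlim[1]), xlim[2])
      pts[, 2] <- pmin(pmax(pts[, 2], ylim[1]), ylim[2])
      pts[, 3] <- pmin(pmax(pts[, 3], zlim[1]), zlim[2])
    }
    organ_grid(name, region, pts)
  })

  phantom <- generic_phantom(regions, arms = arms, organs = organs)
  stopifnot(length(check_growth_matches_phantom(growth, phantom)) == 0)
  list(phantom = phantom, growth = growth)
}
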