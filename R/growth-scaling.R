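# Age-based scaling: discrete factors at the tabulated ages and
# piecewise-linear continuous factors between them.

#' Construct a growth table
#'
#' The growth table gives the size S(d, r, a) of each body region r along
#' each anatomical direction d at the discrete ages 0.1 (1 month), 1, 3, 5,
#' 10, 15 and 18 years. All 3 x 6 x 7 = 126 entries must be present,
#' positive, and non-decreasing in age (children grow).
#'
#' @param entries A data.frame with columns `direction` (`x`/`y`/`z`),
#'   `region` (`uh`/`lh`/`n`/`tr`/`ar`/`lg`), `age_years` and `size_cm`.
#' @return A `growth_table` object.
#' @export
growth_table <- function(entries) {
  req <- c("direction", "region", "age_years", "size_cm")
  if (!all(req %in% names(entries))) {
    stop("growth table needs columns: ", paste(req, collapse = ", "))
  }
  entries$direction <- as.character(entries$direction)
  entries$region <- as.character(entries$region)
  S <- array(NA_real_, dim = c(3, 6, length(AGE_KNOTS)),
             dimnames = list(DIRECTIONS, REGION_IDS, format(AGE_KNOTS)))
  for (i in seq_len(nrow(entries))) {
    d <- entries$direction[i]; r <- entries$region[i]
    ai <- which(abs(AGE_KNOTS - entries$age_years[i]) < 1e-9)
    if (!d %in% DIRECTIONS || !r %in% REGION_IDS || length(ai) != 1) {
      stop(sprintf("growth table row %d: invalid (direction=%s, region=%s, age=%s)",
                   i, d, r, format(entries$age_years[i])))
    }
    S[d, r, ai] <- entries$size_cm[i]
  }
  if (anyNA(S)) {
    miss <- which(is.na(S), arr.ind = TRUE)
    stop(sprintf("growth table incomplete: %d of 126 entries missing (first: %s, %s, age %s)",
                 nrow(miss), DIRECTIONS[miss[1, 1]], REGION_IDS[miss[1, 2]],
                 format(AGE_KNOTS)[miss[1, 3]]))
  }
  if (any(S <= 0)) stop("growth table sizes must all be positive")
  for (d in DIRECTIONS) for (r in REGION_IDS) {
    if (any(diff(S[d, r, ]) < -1e-9)) {
      stop(sprintf("growth table not non-decreasing in age for (%s, %s)", d, r))
    }
  }
  tab <- list(entries = entries[order(entries$direction, entries$region,
                                      entries$age_years), , drop = FALSE],
              S = S)
  class(tab) <- "growth_table"
  tab
}

#' Read a growth table from CSV
#'
#' @param path CSV with columns `direction`, `region`, `age_years`, `size_cm`.
#' @return A `growth_table`.
#' @export
read_growth_table <- function(path) {
  if (!file.exists(path)) stop("growth table not found: ", path)
  growth_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a growth table to CSV
#' @param table A `growth_table`.
#' @param path Output CSV path.
#' @export
write_growth_table <- function(table, path) {
  stopifnot(inherits(table, "growth_table"))
  utils::write.csv(table$entries, path, row.names = FALSE)
  invisible(path)
}

#' Check that a growth table matches a generic phantom at age 18
#'
#' The discrete factor at the generic age must be exactly 1, i.e. the
#' tabulated age-18 sizes must equal the generic phantom's region extents.
#'
#' @param table A `growth_table`.
#' @param phantom A `generic_phantom`.
#' @param tol Tolerance in cm.
#' @return Character vector of mismatches (length 0 when consistent).
#' @export
check_growth_matches_phantom <- function(table, phantom, tol = 1e-6) {
  probs <- character()
  regions <- c(phantom$regions, if (length(phantom$arms)) list(ar = phantom$arms[[1]]))
  for (r in regions) {
    ext <- c(x = r$l_x, y = r$l_y, z = r$l_z)
    for (d in DIRECTIONS) {
      s18 <- table$S[d, r$id, length(AGE_KNOTS)]
      if (abs(s18 - ext[[d]]) > tol) {
        probs <- c(probs, sprintf("S(%s, %s, 18) = %.6g but phantom extent is %.6g cm",
                                  d, r$id, s18, ext[[d]]))
      }
    }
  }
  probs
}

#' Discrete scaling factor at a tabulated age
#'
#' The discrete factor is the ratio of a body region's size at age `a` to its
#' size in the generic (age-18) phantom:
#' `F_dis(d, r, a) = S(d, r, a) / S(d, r, 18)`.
#'
#' @param table A `growth_table`.
#' @param d Direction: `"x"` (left-right), `"y"` (superior-inferior),
#'   `"z"` (anterior-posterior).
#' @param r Body region id.
#' @param a Age in years; must be one of 0.1, 1, 3, 5, 10, 15, 18.
#' @return Dimensionless scaling factor in (0, 1].
#' @export
discrete_factor <- function(table, d, r, a) {
  stopifnot(inherits(table, "growth_table"))
  d <- match.arg(d, DIRECTIONS)
  r <- match.arg(r, REGION_IDS)
  ai <- which(abs(AGE_KNOTS - a) < 1e-9)
  if (length(ai) != 1) {
    stop("discrete_factor: age ", format(a), " is not one of the tabulated ages {",
         paste(AGE_KNOTS, collapse = ", "), "}; use continuous_factor()")
  }
  unname(table$S[d, r, ai] / table$S[d, r, length(AGE_KNOTS)])
}

# Snap an age to the nearest tenth of a year; refuse ages below 0.1.
snap_age <- function(a) {
  if (!is.finite(a) || a < 0.1 - 1e-9) {
    stop("age must be >= 0.1 years (1 month); got ", format(a))
  }
  snapped <- round(a * 10) / 10
  if (abs(snapped - a) > 1e-9) {
    warning(sprintf("age %s snapped to nearest tenth: %s", format(a), format(snapped)))
  }
  snapped
}

#' Continuous scaling factor at any age
#'
#' Linear interpolation of the discrete factors over the age intervals
#' `[0.1, 1), [1, 3), [3, 5), [5, 10), [10, 15), [15, 18)`:
#' `F_cont(d, r, a) = F_dis(d, r, a-) + (a - a-) / (a+ - a-) *
#' (F_dis(d, r, a+) - F_dis(d, r, a-))`. Growth is assumed to stop at 18:
#' ages above 18 are clamped to the age-18 factor (exactly 1).
#'
#' @inheritParams discrete_factor
#' @param a Age in years, `>= 0.1`, specified to the nearest tenth (other
#'   values are snapped with a warning).
#' @return Dimensionless scaling factor.
#' @export
continuous_factor <- function(table, d, r, a) {
  stopifnot(inherits(table, "growth_table"))
  a <- snap_age(a)
  if (a >= 18) return(discrete_factor(table, d, r, 18))
  k <- findInterval(a + 1e-12, AGE_KNOTS) # a in [knot_k, knot_{k+1})
  lo <- AGE_KNOTS[k]; hi <- AGE_KNOTS[k + 1]
  f_lo <- discrete_factor(table, d, r, lo)
  f_hi <- discrete_factor(table, d, r, hi)
  f_lo + (a - lo) / (hi - lo) * (f_hi - f_lo)
}

#' All scaling factors for one query age
#'
#' Evaluates the continuous scaling factor for every (direction, region)
#' pair at one age.
#'
#' @param table A `growth_table`.
#' @param age Age in years (>= 0.1; above 18 clamps to 18).
#' @return A `scaling_factor_set`: the snapped age, a 3 x 6 factor matrix
#'   (directions x regions) and the bracketing age interval.
#' @export
scaling_factors <- function(table, age) {
  stopifnot(inherits(table, "growth_table"))
  age <- snap_age(age)
  clamped <- min(age, 18)
  k <- if (clamped >= 18) length(AGE_KNOTS) - 1 else findInterval(clamped + 1e-12, AGE_KNOTS)
  fac <- matrix(NA_real_, 3, 6, dimnames = list(DIRECTIONS, REGION_IDS))
  for (d in DIRECTIONS) for (r in REGION_IDS) {
    fac[d, r] <- continuous_factor(table, d, r, clamped)
  }
  out <- list(age = age, factors = fac,
              interval = c(AGE_KNOTS[k], AGE_KNOTS[k + 1]))
  class(out) <- "scaling_factor_set"
  out
}

#' @export
print.scaling_factor_set <- function(x, ...) {
  cat(sprintf("Scaling factors at age %g y (interval [%g, %g]):\n",
              x$age, x$interval[1], x$interval[2]))
  print(round(x$factors, 4))
  invisible(x)
}

#' @export
print.growth_table <- function(x, ...) {
  cat(sprintf("Growth table: %d entries, ages {%s}\n", nrow(x$entries),
              paste(AGE_KNOTS, collapse = ", ")))
  invisible(x)
}
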