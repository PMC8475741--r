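# Geometric validation metrics: percent differences, NMSD between organ
# point grids, height comparison against population reference tables, and
# organ masses from voxelized convex-hull volumes and reference densities.

#' Percent difference between a reference and a candidate value
#'
#' Two sign conventions are supported. `"eq7"` treats the reference F as
#' ground truth and reports `(F - D) / F * 100`; `"signed-candidate"`
#' reports `(D - F) / F * 100`, the convention under which a candidate value
#' exceeding the reference is positive (the one used in dose-metric
#' comparison tables). The two are exact negatives of each other.
#'
#' @param F Reference (ground-truth) value(s); must be non-zero.
#' @param D Candidate value(s).
#' @param convention `"eq7"` (default) or `"signed-candidate"`.
#' @return Percent difference(s).
#' @export
percent_difference <- function(F, D, convention = c("eq7", "signed-candidate")) {
  convention <- match.arg(convention)
  if (any(F == 0)) stop("percent_difference undefined for reference value F = 0")
  pd <- (F - D) / F * 100
  if (convention == "signed-candidate") -pd else pd
}

#' Normalized mean square distance between two organ point grids
#'
#' Root-mean-square distance between corresponding points of the same organ
#' represented in two phantoms: `sqrt(sum(|p_F - p_D|^2) / N)`. Points are
#' paired by index; both representations must derive from the same generic
#' model so the ordering is shared. Reported in the length unit of the
#' inputs (mm for DICOM-frame grids).
#'
#' @param organ_F,organ_D `organ_grid`s or N x 3 matrices with the same N
#'   and corresponding point order.
#' @return RMS point distance (same unit as the coordinates).
#' @export
nmsd <- function(organ_F, organ_D) {
  a <- if (inherits(organ_F, "organ_grid")) organ_F$points else as.matrix(organ_F)
  b <- if (inherits(organ_D, "organ_grid")) organ_D$points else as.matrix(organ_D)
  if (!nrow(a)) stop("nmsd: empty point set")
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("nmsd: point count mismatch (%d vs %d)", nrow(a), nrow(b)))
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Compare phantom heights against a population reference table
#'
#' @param phantom_heights data.frame with columns `age` and `height_cm`
#'   (the scaled phantom's heights).
#' @param reference data.frame with columns `age` and `height_cm`
#'   (e.g. WHO/CDC 50th-percentile heights).
#' @return data.frame of comparison records: `age`, `reference_cm`,
#'   `phantom_cm`, `percent_difference` (absolute, reference as ground
#'   truth).
#' @export
compare_heights <- function(phantom_heights, reference) {
  stopifnot(all(c("age", "height_cm") %in% names(phantom_heights)),
            all(c("age", "height_cm") %in% names(reference)))
  idx <- match(phantom_heights$age, reference$age)
  if (anyNA(idx)) {
    stop("reference height table missing age(s): ",
         paste(phantom_heights$age[is.na(idx)], collapse = ", "))
  }
  ref <- reference$height_cm[idx]
  data.frame(
    age = phantom_heights$age,
    reference_cm = ref,
    phantom_cm = phantom_heights$height_cm,
    percent_difference = abs(percent_difference(ref, phantom_heights$height_cm))
  )
}

#' Organ mass from a voxelized convex hull
#'
#' Mass is the product of a reference tissue density and the organ's
#' voxelized convex-hull volume. At voxel sizes of 1 mm or below the
#' voxelized volume is within 2% of the analytic hull volume for the organ
#' grids used here.
#'
#' @param hull A `hull3d` of the organ's points in mm (DICOM frame), or an
#'   `organ_grid` in the DICOM frame (hull computed internally; raises a
#'   non-contourable error for degenerate grids).
#' @param density Tissue density in g/cm^3, > 0.
#' @param voxel Voxel edge length in mm (default 1).
#' @return Mass in grams.
#' @export
organ_mass <- function(hull, density, voxel = 1) {
  stopifnot(density > 0)
  if (inherits(hull, "organ_grid")) {
    if (!hull$contourable) {
      stop(structure(class = c("agephantom_noncontourable", "error", "condition"),
                     list(message = paste0("organ '", hull$name,
                                           "' is non-contourable; mass undefined"),
                          call = sys.call(-1), organ = hull$name)))
    }
    hull <- convex_hull_3d(hull$points)
  }
  stopifnot(inherits(hull, "hull3d"))
  vol_mm3 <- voxelized_hull_volume(hull, voxel)
  density * (vol_mm3 / 1000) # exact when the voxelized volume is a whole cm^3
}

#' Compare phantom organ masses against reference masses
#'
#' Reference tables may list masses per sex and per organ part (e.g. wall
#' and contents, or medulla/pelvis/cortex). For each organ the parts are
#' summed within each sex and the sexes are then averaged, before the
#' difference (phantom minus reference) is taken.
#'
#' @param phantom_masses data.frame with columns `organ` and `mass_g`.
#' @param reference data.frame with columns `organ`, `age`, `sex`, `part`,
#'   `mass_g`.
#' @param age Age (years) at which to look up the reference masses.
#' @return A `mass_report` data.frame: `organ`, `phantom_g`, `reference_g`,
#'   `difference_g`. Organs missing from the reference get `NA` reference
#'   and difference, with a warning listing them (not fatal).
#' @export
compare_masses <- function(phantom_masses, reference, age) {
  stopifnot(all(c("organ", "mass_g") %in% names(phantom_masses)),
            all(c("organ", "age", "sex", "part", "mass_g") %in% names(reference)))
  ref_age <- reference[abs(reference$age - age) < 1e-9, , drop = FALSE]
  ref_for <- function(organ) {
    rows <- ref_age[ref_age$organ == organ, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    per_sex <- tapply(rows$mass_g, rows$sex, sum) # sum parts within sex
    mean(per_sex)                                 # then average sexes
  }
  ref <- vapply(phantom_masses$organ, ref_for, 0)
  missing <- phantom_masses$organ[is.na(ref)]
  if (length(missing)) {
    warning("no reference mass at age ", age, " for organ(s): ",
            paste(missing, collapse = ", "))
  }
  out <- data.frame(
    organ = phantom_masses$organ,
    phantom_g = phantom_masses$mass_g,
    reference_g = unname(ref),
    difference_g = phantom_masses$mass_g - unname(ref)
  )
  class(out) <- c("mass_report", "data.frame")
  out
}

#' Dose-metric comparison table
#'
#' Reproduces the integer-rounded percent-difference arithmetic used when
#' comparing dose metrics (mean dose, V5) between two phantom
#' representations: the candidate-minus-reference convention, rounded to the
#' nearest integer percent for display, full precision retained.
#'
#' @param metrics data.frame with columns `label`, `reference` and
#'   `candidate` (externally supplied dose metrics; no dose is computed
#'   here).
#' @return The input with `percent_difference` (full precision,
#'   signed-candidate convention) and `percent_rounded` columns.
#' @export
dose_metric_comparison <- function(metrics) {
  stopifnot(all(c("label", "reference", "candidate") %in% names(metrics)))
  pd <- percent_difference(metrics$reference, metrics$candidate,
                           convention = "signed-candidate")
  metrics$percent_difference <- pd
  metrics$percent_rounded <- round(pd)
  metrics
}
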