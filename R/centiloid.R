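# Direct-comparison Centiloid (dcCL) conversion and global positivity.

#' Per-ligand Centiloid calibration anchors
#'
#' The dcCL scale is anchored at the mean global SUVR of an amyloid-negative
#' young-control group (0 CL) and the mean of a typical amyloid-positive
#' cognitively impaired (ADCI) group (100 CL). The anchor means are
#' ligand-specific and must be supplied as configuration; published anchor
#' images are not redistributable, and [generate_anchor_sets()] produces
#' self-consistent anchors for synthetic work.
#'
#' @param ligand `"FBB"` or `"FMM"`.
#' @param suvr_yc0 Mean global SUVR of the young-control anchor group.
#' @param suvr_adci100 Mean global SUVR of the ADCI anchor group; must exceed
#'   `suvr_yc0`.
#' @return An object of class `ligand_calibration`.
#' @export
#' @examples
#' calib <- ligand_calibration("FBB", suvr_yc0 = 1.0, suvr_adci100 = 2.0)
#' suvr_to_cl(c(1.0, 1.5, 2.0), calib)
ligand_calibration <- function(ligand, suvr_yc0, suvr_adci100) {
  ligand <- match.arg(ligand, c("FBB", "FMM"))
  stopifnot(is.numeric(suvr_yc0), is.numeric(suvr_adci100),
            length(suvr_yc0) == 1, length(suvr_adci100) == 1,
            is.finite(suvr_yc0), is.finite(suvr_adci100),
            suvr_yc0 > 0)
  if (suvr_adci100 <= suvr_yc0) {
    stop("suvr_adci100 must exceed suvr_yc0 (degenerate anchors)")
  }
  structure(
    list(ligand = ligand, suvr_yc0 = suvr_yc0, suvr_adci100 = suvr_adci100),
    class = "ligand_calibration"
  )
}

#' @export
print.ligand_calibration <- function(x, ...) {
  cat(sprintf("dcCL calibration [%s]: 0 CL at SUVR %.4f, 100 CL at SUVR %.4f\n",
              x$ligand, x$suvr_yc0, x$suvr_adci100))
  invisible(x)
}

#' Convert SUVR to Centiloid units
#'
#' Applies the affine dcCL conversion
#' `CL = 100 * (SUVR - SUVR_YC0) / (SUVR_ADCI100 - SUVR_YC0)`,
#' so the young-control anchor mean maps to 0 CL and the ADCI anchor mean to
#' 100 CL.
#'
#' @param suvr Numeric vector of global SUVR values.
#' @param calib A [ligand_calibration()].
#' @return Numeric vector of Centiloid values.
#' @export
suvr_to_cl <- function(suvr, calib) {
  stopifnot(inherits(calib, "ligand_calibration"), is.numeric(suvr))
  100 * (suvr - calib$suvr_yc0) / (calib$suvr_adci100 - calib$suvr_yc0)
}

#' Invert the Centiloid conversion
#'
#' @param cl Numeric vector of Centiloid values.
#' @param calib A [ligand_calibration()].
#' @return SUVR values on the calibration's ligand scale.
#' @export
cl_to_suvr <- function(cl, calib) {
  stopifnot(inherits(calib, "ligand_calibration"), is.numeric(cl))
  calib$suvr_yc0 + cl / 100 * (calib$suvr_adci100 - calib$suvr_yc0)
}

#' Global positivity threshold in Centiloid units
#'
#' @param cl_cutoff Centiloid cutoff. The default 25.11 CL is the
#'   ROC-optimal cutoff used for the primary analyses; 20 and 40 CL are the
#'   usual sensitivity settings.
#' @param provenance `"configured"` or `"roc_derived"`.
#' @return An object of class `global_threshold`.
#' @export
global_threshold <- function(cl_cutoff = 25.11,
                             provenance = c("configured", "roc_derived")) {
  stopifnot(is.numeric(cl_cutoff), length(cl_cutoff) == 1, is.finite(cl_cutoff))
  structure(
    list(cl_cutoff = cl_cutoff, provenance = match.arg(provenance)),
    class = "global_threshold"
  )
}

#' @export
print.global_threshold <- function(x, ...) {
  cat(sprintf("global amyloid positivity threshold: %.4g CL (%s)\n",
              x$cl_cutoff, x$provenance))
  invisible(x)
}

#' Derive the global Centiloid cutoff by ROC analysis
#'
#' Given per-participant Centiloid values and a binary standard of truth
#' (e.g., SUVR-based positivity per scan), returns the threshold maximizing
#' Youden's J (sensitivity + specificity - 1) for the rule `cl >= threshold`.
#' Candidate thresholds are the midpoints between consecutive distinct CL
#' values (plus one below the minimum and one above the maximum); J ties are
#' broken toward the lower threshold.
#'
#' @param cl_values Numeric vector of Centiloid values.
#' @param truth_labels Logical vector (TRUE = amyloid positive); both classes
#'   must be present.
#' @return A `global_threshold` with provenance `"roc_derived"`; the achieved
#'   Youden J is attached as attribute `"youden_j"`.
#' @export
derive_cl_cutoff_roc <- function(cl_values, truth_labels) {
  stopifnot(is.numeric(cl_values), length(cl_values) == length(truth_labels))
  truth_labels <- as.logical(truth_labels)
  if (anyNA(cl_values) || anyNA(truth_labels)) stop("missing values")
  if (length(unique(truth_labels)) < 2) {
    stop("both truth classes must be present for ROC analysis")
  }
  u <- sort(unique(cl_values))
  candidates <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  n_pos <- sum(truth_labels)
  n_neg <- sum(!truth_labels)
  j <- vapply(candidates, function(t) {
    sens <- sum(cl_values >= t & truth_labels) / n_pos
    spec <- sum(cl_values < t & !truth_labels) / n_neg
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)  # which.max returns the first (lowest) maximizer
  thr <- global_threshold(candidates[best], provenance = "roc_derived")
  attr(thr, "youden_j") <- j[best]
  thr
}

#' Is a Centiloid value globally amyloid positive?
#'
#' Positivity is `cl >= cutoff`; the boundary counts as positive.
#'
#' @param cl Numeric vector of Centiloid values.
#' @param thr A [global_threshold()] (or a bare numeric cutoff).
#' @return Logical vector.
#' @export
is_global_positive <- function(cl, thr = global_threshold()) {
  cutoff <- if (inherits(thr, "global_threshold")) thr$cl_cutoff else thr
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  cl >= cutoff
}
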