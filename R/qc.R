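# Dataset quality control: profile-mode detection and exclusion rules.

#' Proportion of consecutive peaks overlapping within a ppm tolerance
#'
#' Profile-mode spectra mistakenly submitted as centroided produce dense
#' runs of near-coincident peaks; this score measures the fraction of
#' consecutive m/z gaps that fall inside the matching tolerance. The
#' default variant counts a gap as overlap when
#' `m[i+1] - m[i] <= m[i] * tol_ppm / 1e6` (relative window, consistent with
#' the exclusion direction: profile-like data scores high). The `literal`
#' variant instead counts gaps with `m[i+1] - m[i] >= tol_ppm / 1e6`
#' (an absolute Da gap against a dimensionless fraction), retained for
#' auditability.
#'
#' @param spectrum a [centroided_spectrum()] or numeric m/z vector.
#' @param tol_ppm tolerance in ppm (default 3).
#' @param literal use the literal gap indicator instead of the intended
#'   relative-overlap one.
#' @return Score in `[0, 1]`; 0 with a warning when fewer than 2 peaks.
#' @export
proportion_overlap <- function(spectrum, tol_ppm = 3, literal = FALSE) {
  mz <- if (inherits(spectrum, "centroided_spectrum")) spectrum$mz else spectrum
  n <- length(mz)
  if (n < 2L) {
    warning("proportion_overlap undefined for fewer than 2 peaks; returning 0")
    return(0)
  }
  gaps <- diff(mz)
  hits <- if (literal) {
    gaps >= tol_ppm / 1e6
  } else {
    gaps <= mz[-n] * tol_ppm / 1e6
  }
  sum(hits) / (n - 1L)
}

#' Dataset-level overlap score
#'
#' Mean [proportion_overlap()] over the `n_pixels` pixels with the highest
#' number of nonzero peaks (all pixels when fewer exist); ties broken by
#' pixel index for determinism. Datasets scoring above 0.5 are flagged as
#' likely profile-mode submissions.
#'
#' @param ds a [centroided_dataset()].
#' @param n_pixels number of top pixels to inspect (default 50).
#' @param tol_ppm tolerance in ppm (default 3).
#' @param literal see [proportion_overlap()].
#' @return Score in `[0, 1]`.
#' @export
dataset_overlap_score <- function(ds, n_pixels = 50L, tol_ppm = 3,
                                  literal = FALSE) {
  stopifnot(length(ds$spectra) >= 1L)
  counts <- vapply(ds$spectra, function(s) sum(s$intensity > 0), integer(1))
  top <- order(-counts, seq_along(counts))[seq_len(min(n_pixels, length(counts)))]
  scores <- vapply(top, function(i) {
    s <- ds$spectra[[i]]
    keep <- s$intensity > 0
    if (sum(keep) < 2L) return(0)
    proportion_overlap(s$mz[keep], tol_ppm, literal)
  }, numeric(1))
  mean(scores)
}

#' Apply the dataset quality-exclusion rules
#'
#' A dataset is excluded when any of these rules fires:
#' \describe{
#'   \item{`few_annotations`}{fewer than 10 annotations at FDR 20% in
#'     *every* (target adduct, database) combination — any adequate
#'     combination rescues the dataset;}
#'   \item{`excessive_peaks`}{median per-pixel nonzero peak count above
#'     50,000;}
#'   \item{`profile_overlap`}{[dataset_overlap_score()] above 0.5.}
#' }
#'
#' @param ds a [centroided_dataset()].
#' @param annotations_at_fdr20 named numeric vector (or list) of annotation
#'   counts at FDR 20%, one per (adduct, database) combination; `NULL` skips
#'   rule 1.
#' @param max_median_peaks rule 2 threshold (default 50000).
#' @param overlap_threshold rule 3 threshold (default 0.5).
#' @param min_annotations rule 1 threshold (default 10).
#' @param tol_ppm passed to [dataset_overlap_score()].
#' @return A `qc_report` list: `overlap_score`, `median_peak_count`,
#'   `annotations_at_fdr20`, `excluded`, `reasons`.
#' @export
apply_quality_filters <- function(ds, annotations_at_fdr20 = NULL,
                                  max_median_peaks = 50000,
                                  overlap_threshold = 0.5,
                                  min_annotations = 10, tol_ppm = 3) {
  reasons <- character(0)
  counts <- vapply(ds$spectra, function(s) sum(s$intensity > 0), numeric(1))
  median_peaks <- stats::median(counts)
  overlap <- dataset_overlap_score(ds, tol_ppm = tol_ppm)
  if (!is.null(annotations_at_fdr20) && length(annotations_at_fdr20)) {
    if (all(unlist(annotations_at_fdr20) < min_annotations)) {
      reasons <- c(reasons, "few_annotations")
    }
  }
  if (median_peaks > max_median_peaks) reasons <- c(reasons, "excessive_peaks")
  if (overlap > overlap_threshold) reasons <- c(reasons, "profile_overlap")
  structure(list(overlap_score = overlap, median_peak_count = median_peaks,
                 annotations_at_fdr20 = annotations_at_fdr20,
                 excluded = length(reasons) > 0, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> overlap =", format(x$overlap_score, digits = 3),
      "| median peaks =", x$median_peak_count,
      "|", if (x$excluded) paste("EXCLUDED:", paste(x$reasons, collapse = ", "))
           else "pass", "\n")
  invisible(x)
}
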