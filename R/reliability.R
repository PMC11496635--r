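# F-beta cutpoint scan over FDR cutoffs and the reliability score used to
# select the optimal default FDR threshold for a dataset.

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`; beta = 0.5 weights precision
#' over recall, reflecting the target/decoy imbalance of the annotation
#' task. Returns 0 by convention when precision and recall are both 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @param beta precision-recall trade-off (default 0.5).
#' @return F-beta value in `[0, 1]`.
#' @export
fbeta <- function(precision, recall, beta = 0.5) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' F-beta curve over observed FDR cutoffs
#'
#' Target and decoy ions are positive and negative instances. Candidate
#' cutoffs are the sorted unique adjusted-FDR values present; at each
#' cutoff, ions with `fdr <= cutoff` are predicted positive, precision is
#' the fraction of targets among them and recall the fraction of all
#' targets captured. Decoys are counted unweighted by default;
#' `decoy_weighting = TRUE` weights each decoy by `1/s_d` in the confusion
#' matrix instead (documented alternative).
#'
#' @param fdr adjusted FDR per ion.
#' @param is_decoy logical per ion.
#' @param beta F-beta parameter (default 0.5).
#' @param decoy_weighting weight decoys by `1/s_d`.
#' @param s_d decoy samplings per target (only with `decoy_weighting`).
#' @return List with `f` (ascending cutoffs), `b` (matching F-beta values)
#'   and `degenerate` (`TRUE` when no decoys were present).
#' @export
fbeta_curve <- function(fdr, is_decoy, beta = 0.5, decoy_weighting = FALSE,
                        s_d = 20L) {
  stopifnot(length(fdr) == length(is_decoy), any(!is_decoy))
  degenerate <- !any(is_decoy)
  w <- ifelse(is_decoy, if (decoy_weighting) 1 / s_d else 1, 1)
  f <- sort(unique(fdr))
  n_targets <- sum(w[!is_decoy])
  b <- vapply(f, function(cut) {
    pred <- fdr <= cut
    tp <- sum(w[pred & !is_decoy])
    fp <- sum(w[pred & is_decoy])
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- tp / n_targets
    fbeta(precision, recall, beta)
  }, numeric(1))
  list(f = f, b = b, degenerate = degenerate)
}

#' Reliability score of a default FDR threshold
#'
#' The F-beta value at the observed cutoff nearest the default threshold,
#' relative to the maximum F-beta on the curve, multiplied by the
#' complement of the optimal FDR cutoff (the cutoff attaining the maximum
#' F-beta). Argmin/argmax ties resolve toward the smaller cutoff.
#'
#' @param f ascending vector of FDR cutoffs.
#' @param b matching F-beta values.
#' @param default_threshold one of the default FDR thresholds (e.g. 0.05).
#' @return Score in `[0, 1]`.
#' @export
reliability_score <- function(f, b, default_threshold) {
  stopifnot(length(f) == length(b), length(f) >= 1L,
            !is.unsorted(f, strictly = TRUE))
  i_star <- which.min(abs(f - default_threshold))   # ties -> smaller f
  optim_fdr <- f[which.max(b)]                      # ties -> smaller f
  (b[i_star] / max(b)) * (1 - optim_fdr)
}

#' Optimal FDR threshold from reliability scores
#'
#' Among the default thresholds attaining the maximum reliability score
#' (exact ties), the smallest is returned.
#'
#' @param scores named numeric vector of reliability scores keyed by
#'   threshold (names parseable as numbers, e.g. `"0.05"`).
#' @return The selected threshold as a number.
#' @export
optimal_threshold <- function(scores) {
  thresholds <- as.numeric(names(scores))
  stopifnot(!anyNA(thresholds))
  best <- thresholds[scores == max(scores)]
  min(best)
}

#' Full reliability analysis of an annotated ranking
#'
#' @param ranking an `fdr_ranking` with adjusted FDR (see [rank_with_fdr()]),
#'   or a data.frame with `fdr` and `is_decoy` columns.
#' @param default_thresholds candidate default FDR thresholds
#'   (default `c(0.05, 0.10, 0.20, 0.50)`).
#' @param beta F-beta parameter (default 0.5).
#' @param decoy_weighting,s_d see [fbeta_curve()].
#' @return A `reliability_result`: list with `f`, `b`, `optim_fdr`,
#'   `scores` (per default threshold) and `optimal_threshold`.
#' @export
reliability_result <- function(ranking,
                               default_thresholds = c(0.05, 0.10, 0.20, 0.50),
                               beta = 0.5, decoy_weighting = FALSE,
                               s_d = 20L) {
  if (!"fdr" %in% names(ranking)) ranking <- rank_with_fdr(ranking)
  curve <- fbeta_curve(ranking$fdr, ranking$is_decoy, beta,
                       decoy_weighting, s_d)
  scores <- vapply(default_thresholds, function(th) {
    reliability_score(curve$f, curve$b, th)
  }, numeric(1))
  names(scores) <- format(default_thresholds)
  structure(list(f = curve$f, b = curve$b,
                 optim_fdr = curve$f[which.max(curve$b)],
                 scores = scores,
                 optimal_threshold = optimal_threshold(scores)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("<reliability_result> optimal FDR cutoff =", format(x$optim_fdr),
      "| selected threshold =", format(x$optimal_threshold), "\n")
  print(round(x$scores, 4))
  invisible(x)
}
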