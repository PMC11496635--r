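# Target-decoy FDR estimation with a single weighted ranking, pseudocounts,
# continuous FDR values and a monotonicity adjustment.

#' Build a merged target-decoy ranking for one (database, adduct) group
#'
#' Targets and all sampled decoy ions are merged and stably sorted by
#' descending score. Targets carry weight 1, decoys `1/s_d`. Ties between a
#' decoy and a target are broken decoy-before-target so that tied scores
#' never understate the FDR.
#'
#' @param targets data.frame with columns `formula`, `adduct`, `score` (one
#'   scored target ion per row).
#' @param decoys data.frame with the same columns for the decoy ions of the
#'   same formulas.
#' @param s_d number of decoy samplings per target (default 20).
#' @return An `fdr_ranking`: data.frame sorted by descending score with
#'   columns `formula`, `adduct`, `score`, `is_decoy`, `weight`; attribute
#'   `s_d`.
#' @export
build_ranking <- function(targets, decoys, s_d = 20L) {
  stopifnot(s_d >= 1L)
  mk <- function(df, is_decoy) {
    if (is.null(df) || nrow(df) == 0L) {
      return(data.frame(formula = character(0), adduct = character(0),
                        score = numeric(0), is_decoy = logical(0)))
    }
    data.frame(formula = df$formula, adduct = df$adduct,
               score = as.numeric(df$score), is_decoy = is_decoy,
               stringsAsFactors = FALSE)
  }
  all <- rbind(mk(targets, FALSE), mk(decoys, TRUE))
  if (nrow(all)) {
    stopifnot(all(is.finite(all$score)))
    # stable sort: score desc, decoys before targets on ties
    all <- all[order(-all$score, !all$is_decoy), , drop = FALSE]
    rownames(all) <- NULL
  }
  all$weight <- ifelse(all$is_decoy, 1 / s_d, 1)
  structure(all, s_d = s_d, class = c("fdr_ranking", "data.frame"))
}

#' Continuous FDR at every rank of a target-decoy ranking
#'
#' At rank `i` with cumulative target count `T_i` and cumulative raw decoy
#' count `D_i` (both including rank `i`), the FDR is
#' `((D_i + 1) / s_d) / ((T_i + 1) + (D_i + 1) / s_d)`:
#' decoys weighted by `1/s_d`, with a rule-of-succession pseudocount of 1
#' added to both counts so the FDR is never exactly 0.
#'
#' @param is_decoy logical vector in ranking order (best score first), or an
#'   `fdr_ranking` from [build_ranking()].
#' @param s_d decoy samplings per target (ignored when a ranking is given).
#' @return Numeric vector of raw FDR values in `(0, 1]`, one per rank.
#' @export
estimate_fdr <- function(is_decoy, s_d = 20L) {
  if (inherits(is_decoy, "fdr_ranking")) {
    s_d <- attr(is_decoy, "s_d")
    is_decoy <- is_decoy$is_decoy
  }
  stopifnot(s_d >= 1L)
  d_i <- cumsum(is_decoy)
  t_i <- cumsum(!is_decoy)
  wd <- (d_i + 1) / s_d
  wd / ((t_i + 1) + wd)
}

#' Monotonicity adjustment of raw FDR values
#'
#' Standard q-value-style reverse cumulative minimum: each rank receives the
#' smallest raw FDR at or below it in the ranking, making the adjusted
#' sequence non-decreasing from best to worst rank.
#'
#' @param fdr_raw numeric vector in ranking order (best first).
#' @return Adjusted FDR vector, same length.
#' @export
monotonic_adjust <- function(fdr_raw) {
  if (!length(fdr_raw)) return(fdr_raw)
  rev(cummin(rev(fdr_raw)))
}

#' Attach raw and adjusted FDR columns to a ranking
#'
#' @param ranking an `fdr_ranking` from [build_ranking()].
#' @return The ranking with `fdr_raw` and `fdr` columns.
#' @export
rank_with_fdr <- function(ranking) {
  ranking$fdr_raw <- estimate_fdr(ranking)
  ranking$fdr <- monotonic_adjust(ranking$fdr_raw)
  ranking
}

#' Target annotations at an FDR threshold
#'
#' @param ranking an `fdr_ranking` with `fdr` (see [rank_with_fdr()]), or a
#'   list of such rankings.
#' @param threshold FDR threshold in `(0, 1]`.
#' @return List with `annotations` (target rows with `fdr <= threshold`) and
#'   `estimated_false_positives` (decoy rows below the threshold, reported
#'   separately).
#' @export
annotations_at <- function(ranking, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]")
  }
  if (!inherits(ranking, "fdr_ranking") && is.list(ranking)) {
    parts <- lapply(ranking, annotations_at, threshold = threshold)
    return(list(
      annotations = do.call(rbind, lapply(parts, `[[`, "annotations")),
      estimated_false_positives =
        do.call(rbind, lapply(parts, `[[`, "estimated_false_positives"))))
  }
  if (!"fdr" %in% names(ranking)) ranking <- rank_with_fdr(ranking)
  hit <- ranking$fdr <= threshold
  list(annotations = ranking[hit & !ranking$is_decoy, , drop = FALSE],
       estimated_false_positives = ranking[hit & ranking$is_decoy, , drop = FALSE])
}

#' Dump a ranking with audit columns as TSV
#'
#' Columns: rank, formula, adduct, score, is_decoy, T_i, D_i, fdr_raw,
#' fdr_adjusted.
#'
#' @param ranking an `fdr_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  if (!"fdr" %in% names(ranking)) ranking <- rank_with_fdr(ranking)
  out <- data.frame(rank = seq_len(nrow(ranking)),
                    formula = ranking$formula, adduct = ranking$adduct,
                    score = ranking$score, is_decoy = ranking$is_decoy,
                    T_i = cumsum(!ranking$is_decoy),
                    D_i = cumsum(ranking$is_decoy),
                    fdr_raw = ranking$fdr_raw, fdr_adjusted = ranking$fdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
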