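# End-to-end annotation: candidates -> features -> score -> FDR.

#' Annotate a dataset with FDR-controlled metabolite identities
#'
#' Builds target and decoy candidates for the database, computes the five
#' features per ion, scores each ion (with the ranking model when given,
#' otherwise with the rule-based MSM product), builds one weighted
#' target-decoy ranking per target adduct (targets of that adduct against
#' all sampled decoy ions), and assigns continuous monotonized FDR values.
#'
#' @param ds a [centroided_dataset()].
#' @param db molecular database data.frame (column `formula`).
#' @param target_adducts character vector (default `"+H"`).
#' @param polarity `"positive"` or `"negative"`.
#' @param s_d decoy samplings per formula (default 20).
#' @param tol_ppm matching tolerance in ppm (default 3).
#' @param model optional `ranker_model`; when `NULL` the MSM score ranks.
#' @param seed master seed for decoy sampling.
#' @param mz_error_in_ppm compute m/z-error features in ppm.
#' @return List with `records` (per-ion table: formula, adduct, is_decoy,
#'   features, msm, ml_score, fdr_raw, fdr — decoy FDR taken from the
#'   first adduct group they appear in), `rankings` (named list of
#'   `fdr_ranking` per target adduct) and `scores` (the raw feature table).
#' @export
annotate_dataset <- function(ds, db, target_adducts = "+H",
                             polarity = "positive", s_d = 20L, tol_ppm = 3,
                             model = NULL, seed = 1L,
                             mz_error_in_ppm = FALSE) {
  candidates <- build_candidates(db, target_adducts, polarity, s_d, seed)
  scores <- score_candidates(ds, candidates, tol_ppm, mz_error_in_ppm)
  scores$ml_score <- if (!is.null(model)) {
    predict_scaled(model, scores)
  } else {
    NA_real_
  }
  scores$score <- if (!is.null(model)) scores$ml_score else scores$msm

  rankings <- list()
  for (ad in target_adducts) {
    targets <- scores[!scores$is_decoy & scores$adduct == ad, , drop = FALSE]
    decoys <- scores[scores$is_decoy, , drop = FALSE]
    rankings[[ad]] <- rank_with_fdr(build_ranking(targets, decoys, s_d))
  }

  records <- scores
  records$fdr_raw <- NA_real_
  records$fdr <- NA_real_
  for (ad in target_adducts) {
    r <- rankings[[ad]]
    tkey <- paste(records$formula, records$adduct)
    rkey <- paste(r$formula, r$adduct)
    hit_t <- !records$is_decoy & records$adduct == ad
    m <- match(tkey[hit_t], rkey)
    records$fdr_raw[hit_t] <- r$fdr_raw[m]
    records$fdr[hit_t] <- r$fdr[m]
    hit_d <- records$is_decoy & is.na(records$fdr)
    m <- match(tkey[hit_d], rkey)
    records$fdr_raw[hit_d] <- r$fdr_raw[m]
    records$fdr[hit_d] <- r$fdr[m]
  }
  records$score <- NULL
  list(records = records, rankings = rankings, scores = scores)
}

#' Count target annotations at an FDR threshold
#'
#' @param annotation result of [annotate_dataset()].
#' @param threshold FDR threshold in `(0, 1]` (default 0.1).
#' @return Integer count of target ions with adjusted FDR at or below the
#'   threshold, summed over adduct groups.
#' @export
count_annotations <- function(annotation, threshold = 0.1) {
  nrow(annotations_at(annotation$rankings, threshold)$annotations)
}
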