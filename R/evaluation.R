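# Ranking-quality metrics, annotation-count comparisons, intensity
# profiling, molecular-class enrichment, and reference-list validation.

#' Average precision of a target/decoy ranked list
#'
#' Mean over target positions `k` of precision@k (targets in the top k,
#' divided by k).
#'
#' @param labels logical (or 0/1) vector in rank order, `TRUE` = target,
#'   best rank first.
#' @return AP in `[0, 1]`; errors when no target is present.
#' @export
average_precision <- function(labels) {
  labels <- as.logical(labels)
  if (!length(labels) || !any(labels)) {
    stop("average precision undefined without any target")
  }
  k <- which(labels)
  mean(cumsum(labels)[k] / k)
}

#' Mean average precision over groups
#'
#' Unweighted mean of per-group AP; groups without any target are skipped
#' with a warning.
#'
#' @param lists list of label vectors (see [average_precision()]), e.g. one
#'   per dataset or per (dataset, adduct) group.
#' @return MAP in `[0, 1]`.
#' @export
map_over_groups <- function(lists) {
  stopifnot(length(lists) >= 1L)
  ok <- vapply(lists, function(l) any(as.logical(l)), logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " group(s) without targets skipped in MAP")
  }
  if (!any(ok)) stop("no group with targets")
  mean(vapply(lists[ok], average_precision, numeric(1)))
}

#' Annotation-count comparison between two methods
#'
#' Signed log10 difference (`sign(ml - base) * log10(|ml - base| + 1)`) and
#' log2 fold change (`log2((ml + 1) / (base + 1))`); the +1 pseudocounts
#' handle zero counts.
#'
#' @param counts_ml,counts_baseline nonnegative annotation counts.
#' @return List with `log10_difference` and `log2_fold_change` (vectorized).
#' @export
annotation_delta <- function(counts_ml, counts_baseline) {
  stopifnot(all(counts_ml >= 0), all(counts_baseline >= 0))
  d <- counts_ml - counts_baseline
  list(log10_difference = sign(d) * log10(abs(d) + 1),
       log2_fold_change = log2((counts_ml + 1) / (counts_baseline + 1)))
}

#' Intensity profile of annotation sets
#'
#' For each ion: the `q`-quantile intensity over acquired pixels of its
#' principal-isotope image, log10-transformed. Per set, the median of these
#' values; sets are compared by a two-sided Wilcoxon rank-sum test.
#'
#' @param ds a [centroided_dataset()].
#' @param ion_sets named list of ion sets; each set is a list of candidates
#'   with `$pattern` (e.g. `list(all_ml = ..., only_ml = ...,
#'   only_baseline = ...)`). Empty sets are skipped.
#' @param q quantile (default 0.99).
#' @param tol_ppm matching tolerance in ppm.
#' @return List with `per_ion` (per-set numeric vectors of log10 quantile
#'   intensities), `medians`, and `tests` (pairwise rank-sum p-values, BH
#'   corrected across the comparisons).
#' @export
intensity_profile <- function(ds, ion_sets, q = 0.99, tol_ppm = 3) {
  ds <- index_dataset(ds)
  per_ion <- lapply(ion_sets, function(set) {
    if (!length(set)) return(numeric(0))
    vapply(set, function(cand) {
      img <- extract_ion_image(ds, cand$pattern$mzs[1], tol_ppm)
      log10(stats::quantile(img$pixel_values, q, names = FALSE) + 1e-12)
    }, numeric(1))
  })
  per_ion <- per_ion[lengths(per_ion) > 0]
  medians <- vapply(per_ion, stats::median, numeric(1))
  tests <- NULL
  if (length(per_ion) >= 2L) {
    pairs <- utils::combn(names(per_ion), 2, simplify = FALSE)
    pvals <- vapply(pairs, function(pr) {
      suppressWarnings(stats::wilcox.test(per_ion[[pr[1]]],
                                          per_ion[[pr[2]]])$p.value)
    }, numeric(1))
    tests <- data.frame(set1 = vapply(pairs, `[`, "", 1),
                        set2 = vapply(pairs, `[`, "", 2),
                        p_value = pvals,
                        p_adjusted = stats::p.adjust(pvals, "BH"))
  }
  list(per_ion = per_ion, medians = medians, tests = tests)
}

#' Molecular subclass enrichment of annotated ions
#'
#' For each subclass, a 2x2 contingency table is formed: `a` = query
#' molecules in the subclass, `b` = query not in it, `c` = background-minus-
#' query in it, `d` = remainder. The p-value is a one-tailed ("greater")
#' Fisher exact test by default; the log2 fold enrichment is
#' `log2((a / (a + b)) / ((a + c) / (a + b + c + d)))`.
#'
#' @param query_formulas formulas annotated at the FDR threshold of interest
#'   (typically 10%).
#' @param background data.frame of database molecules with columns `formula`
#'   and `subclass` (and optionally `parent_class`); the background universe
#'   is its subclass-annotated molecules.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return data.frame with subclass, a, b, c, d, p_value,
#'   log2_fold_enrichment, parent_class; empty when the query is empty.
#' @export
subclass_enrichment <- function(query_formulas, background,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- background[!is.na(background$subclass), , drop = FALSE]
  stopifnot(nrow(background) >= 1L)
  query <- unique(query_formulas)
  query <- query[query %in% background$formula]
  if (!length(query)) {
    return(data.frame(subclass = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_value = numeric(0),
                      log2_fold_enrichment = numeric(0),
                      parent_class = character(0)))
  }
  in_query <- background$formula %in% query
  total <- nrow(background)
  nq <- sum(in_query)
  rows <- lapply(sort(unique(background$subclass)), function(sc) {
    in_sc <- background$subclass == sc
    a <- sum(in_query & in_sc)
    b <- nq - a
    c <- sum(!in_query & in_sc)
    d <- total - a - b - c
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                            alternative = alternative)$p.value
    lfe <- if (a > 0) log2((a / (a + b)) / ((a + c) / total)) else -Inf
    parent <- if ("parent_class" %in% names(background)) {
      background$parent_class[in_sc][1]
    } else NA_character_
    data.frame(subclass = sc, a = a, b = b, c = c, d = d, p_value = p,
               log2_fold_enrichment = lfe, parent_class = parent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corpus-level reporting filter for enrichment terms
#'
#' Keeps subclasses significantly enriched (`p < alpha`) in at least
#' `min_fraction` of the datasets in a corpus run.
#'
#' @param enrichments list of per-dataset [subclass_enrichment()] tables.
#' @param alpha significance level (default 0.05).
#' @param min_fraction minimum fraction of datasets (default 0.1).
#' @return Character vector of retained subclasses.
#' @export
filter_enriched_terms <- function(enrichments, alpha = 0.05,
                                  min_fraction = 0.1) {
  n <- length(enrichments)
  if (!n) return(character(0))
  sig <- unlist(lapply(enrichments, function(e) {
    unique(e$subclass[e$p_value < alpha])
  }))
  counts <- table(sig)
  names(counts)[counts >= min_fraction * n]
}

#' Match annotations against a reference identification list
#'
#' Compares (formula, adduct) pairs annotated at low FDR with a reference
#' list (e.g. bulk LC-MS/MS identifications), over a fixed candidate-ion
#' universe, and reports the 2x2 contingency counts plus TPR, FPR and FNR.
#' In exclusive mode, ions annotated by the other method are first removed
#' from the annotation set.
#'
#' @param annotations data.frame with columns `formula`, `adduct` (the ions
#'   annotated below the FDR threshold).
#' @param reference data.frame with columns `formula`, `adduct`.
#' @param universe data.frame with columns `formula`, `adduct`: all
#'   candidate ions considered (defines TN).
#' @param adducts adducts retained in the reference (default
#'   `c("+H", "+Na", "+K")`).
#' @param other_method optional data.frame of ions annotated by the
#'   competing method; when given, matching is exclusive.
#' @return List with `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`, `fnr`.
#' @export
match_reference <- function(annotations, reference, universe,
                            adducts = c("+H", "+Na", "+K"),
                            other_method = NULL) {
  stopifnot(nrow(reference) >= 1L)
  key <- function(df) paste(df$formula, df$adduct)
  ref <- unique(key(reference[reference$adduct %in% adducts, , drop = FALSE]))
  if (!length(ref)) stop("empty reference after adduct restriction")
  uni <- unique(key(universe))
  ann <- unique(key(annotations))
  if (!is.null(other_method)) ann <- setdiff(ann, unique(key(other_method)))
  ann <- intersect(ann, uni)
  ref <- intersect(ref, uni)
  tp <- length(intersect(ann, ref))
  fp <- length(setdiff(ann, ref))
  fn <- length(setdiff(ref, ann))
  tn <- length(uni) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_)
}
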