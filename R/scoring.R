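# The five per-ion features and the rule-based MSM score.
#
# Three features are inherited from the rule-based Metabolite Signal
# Matching score (spatial isotope coherence, spectral isotope match, spatial
# chaos); two quantify the absolute and relative m/z measurement error of
# the isotope stack against its theoretical pattern. The m/z-error scores
# are computed literally in m/z units by default (1 minus a Da-scale
# deviation); `mz_error_in_ppm = TRUE` converts deviations to ppm first —
# tree models downstream are insensitive to the monotone rescaling.

#' Observed isotope image stack for a candidate ion
#'
#' For each of the `T` theoretical isotopic peaks: extracts the ion image at
#' its theoretical m/z, the intensity-weighted mean observed m/z across
#' pixels with matched signal, and the total observed intensity. Isotopes
#' with no matched peaks anywhere are flagged missing, never fatal.
#'
#' @param ds a [centroided_dataset()] (ideally [index_dataset()]-ed).
#' @param pattern theoretical pattern from [theoretical_pattern()].
#' @param tol_ppm matching tolerance in ppm (default 3).
#' @return List with `images` (list of `ion_image`), `mean_mz` (length-T,
#'   `NA` for missing isotopes), `totals` (per-isotope total intensity) and
#'   `missing` (logical length-T).
#' @export
observed_isotope_stack <- function(ds, pattern, tol_ppm = 3) {
  t_peaks <- length(pattern$mzs)
  images <- vector("list", t_peaks)
  mean_mz <- rep(NA_real_, t_peaks)
  totals <- numeric(t_peaks)
  for (i in seq_len(t_peaks)) {
    img <- extract_ion_image(ds, pattern$mzs[i], tol_ppm)
    images[[i]] <- img
    totals[i] <- sum(img$pixel_values)
    hit <- !is.na(img$matched_mz) & img$pixel_values > 0
    if (any(hit)) {
      w <- img$pixel_values[hit]
      mean_mz[i] <- sum(img$matched_mz[hit] * w) / sum(w)
    }
  }
  list(images = images, mean_mz = mean_mz, totals = totals,
       missing = is.na(mean_mz))
}

#' Absolute m/z error score
#'
#' `1 - |observed - theoretical|` for the principal (first) isotopic peak.
#' When the first isotope was never observed the score falls to the
#' configured worst value (0): absence of evidence must not look like
#' perfect mass accuracy.
#'
#' @param mean_mz_1 observed intensity-weighted mean m/z of the first
#'   isotope (`NA` when missing).
#' @param theor_mz_1 theoretical m/z of the first isotope.
#' @param in_ppm convert the deviation to ppm before applying `1 - |.|`.
#' @param worst score assigned when the first isotope is missing.
#' @return Numeric score (≤ 1).
#' @export
mz_error_abs <- function(mean_mz_1, theor_mz_1, in_ppm = FALSE, worst = 0) {
  if (is.na(mean_mz_1)) return(worst)
  d <- mean_mz_1 - theor_mz_1
  if (in_ppm) d <- d / theor_mz_1 * 1e6
  1 - abs(d)
}

#' Relative m/z error score
#'
#' `1 - |weighted mean over observed isotopes i >= 2 of ((d_i - d_1))|`
#' where `d_i` is the observed-minus-theoretical deviation of isotope `i`
#' and the weights are the theoretical relative intensities. Missing higher
#' isotopes are excluded from both sums; if none is observed (or the first
#' isotope is missing) the score is 0.
#'
#' @param mean_mz observed per-isotope mean m/z (length T, `NA` = missing).
#' @param theor_mz theoretical per-isotope m/z (length T).
#' @param rel_intensities theoretical relative intensities (length T).
#' @param in_ppm convert deviations to ppm before averaging.
#' @return Numeric score (≤ 1).
#' @export
mz_error_rel <- function(mean_mz, theor_mz, rel_intensities, in_ppm = FALSE) {
  t_peaks <- length(theor_mz)
  if (t_peaks < 2L || is.na(mean_mz[1])) return(0)
  d <- mean_mz - theor_mz
  if (in_ppm) d <- d / theor_mz * 1e6
  idx <- which(!is.na(mean_mz))
  idx <- idx[idx >= 2L]
  if (!length(idx)) return(0)
  w <- rel_intensities[idx]
  1 - abs(sum((d[idx] - d[1]) * w) / sum(w))
}

#' Spectral isotope match score
#'
#' One minus half the L1 distance between the L1-normalized theoretical and
#' observed isotope intensity vectors (total-variation agreement, in
#' `[0, 1]`). Missing isotopes contribute 0 observed intensity; an all-zero
#' observation scores 0.
#'
#' @param rel_intensities theoretical relative intensities (length T).
#' @param totals observed per-isotope total intensities (length T).
#' @return Score in `[0, 1]`.
#' @export
rho_spectral <- function(rel_intensities, totals) {
  stopifnot(length(rel_intensities) == length(totals))
  if (sum(totals) <= 0) return(0)
  p <- rel_intensities / sum(rel_intensities)
  q <- totals / sum(totals)
  max(0, min(1, 1 - 0.5 * sum(abs(p - q))))
}

#' Spatial isotope coherence score
#'
#' Weighted mean over isotopes `i >= 2` of the positive part of the Pearson
#' correlation between the principal-isotope image and image `i` over
#' acquired pixels, weighted by theoretical relative intensity. Missing
#' isotopes (or undefined correlations on constant images) contribute 0.
#'
#' @param images list of `ion_image` (length T, first = principal).
#' @param rel_intensities theoretical relative intensities (length T).
#' @return Score in `[0, 1]`.
#' @export
rho_spatial <- function(images, rel_intensities) {
  t_peaks <- length(images)
  if (t_peaks < 2L) return(0)
  base <- images[[1]]$pixel_values
  if (length(base) < 2L || stats::sd(base) == 0) return(0)
  cors <- vapply(2:t_peaks, function(i) {
    v <- images[[i]]$pixel_values
    if (sum(v) == 0 || stats::sd(v) == 0) return(0)
    max(0, stats::cor(base, v))
  }, numeric(1))
  w <- rel_intensities[2:t_peaks]
  sum(cors * w) / sum(w)
}

# Exact 4-connected component count of a binary image (union-find).
label_components_4 <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  idx <- which(binary)
  if (!length(idx)) return(0L)
  parent <- seq_along(idx)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(idx)) {
    cell <- idx[k]
    r <- (cell - 1L) %% nr + 1L
    cl <- (cell - 1L) %/% nr + 1L
    if (r > 1L && binary[cell - 1L]) {          # up neighbour
      a <- find(k); b <- find(pos[cell - 1L])
      if (a != b) parent[a] <- b
    }
    if (cl > 1L && binary[cell - nr]) {         # left neighbour
      a <- find(k); b <- find(pos[cell - nr])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_along(idx), find, integer(1))))
}

#' Spatial chaos (informativeness) score
#'
#' Quantifies whether the principal ion image shows structured signal
#' (large connected patches) or scattered salt-and-pepper noise. The image
#' is thresholded at `n_levels` quantile-spaced intensity levels over its
#' nonzero intensities; at each level the ratio of 4-connected components to
#' above-threshold pixels is computed, and the score is one minus the mean
#' ratio, clipped to `[0, 1]`. A single solid blob scores near 1; isolated
#' single pixels score near 0; an all-zero image scores 0.
#'
#' @param image an `ion_image` (or a plain numeric matrix).
#' @param n_levels number of quantile thresholds (default 30).
#' @return Score in `[0, 1]`.
#' @export
rho_chaos <- function(image, n_levels = 30L) {
  values <- if (inherits(image, "ion_image")) image$values else image
  nz <- values[values > 0]
  if (!length(nz)) return(0)
  thresholds <- stats::quantile(nz, probs = seq(0, 1, length.out = n_levels),
                                names = FALSE, type = 7)
  ratios <- vapply(thresholds, function(th) {
    binary <- values >= th
    npix <- sum(binary)
    if (npix == 0L) return(NA_real_)
    label_components_4(binary) / npix
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) return(0)
  max(0, min(1, 1 - mean(ratios)))
}

#' Metabolite Signal Matching score
#'
#' The rule-based predecessor score: the equal-weight product of the three
#' rho features.
#'
#' @param features named list or vector with `rho_spatial`, `rho_spectral`,
#'   `rho_chaos`.
#' @return Score in `[0, 1]`.
#' @export
msm_score <- function(features) {
  as.numeric(features[["rho_spatial"]] * features[["rho_spectral"]] *
               features[["rho_chaos"]])
}

#' Compute the five features (and MSM) for one candidate ion
#'
#' Deterministic for fixed inputs; never raises on signal absence (a
#' candidate with no matched peaks scores all zeros).
#'
#' @param ds a [centroided_dataset()] (ideally [index_dataset()]-ed).
#' @param candidate one element of [build_candidates()] output (needs
#'   `$pattern`).
#' @param tol_ppm matching tolerance in ppm (default 3).
#' @param mz_error_in_ppm compute the m/z-error deviations in ppm.
#' @return Named numeric vector: rho_spatial, rho_spectral, rho_chaos,
#'   mz_error_abs, mz_error_rel, msm.
#' @export
compute_features <- function(ds, candidate, tol_ppm = 3,
                             mz_error_in_ppm = FALSE) {
  pat <- candidate$pattern
  stack <- observed_isotope_stack(ds, pat, tol_ppm)
  f <- c(
    rho_spatial = rho_spatial(stack$images, pat$rel_intensities),
    rho_spectral = rho_spectral(pat$rel_intensities, stack$totals),
    rho_chaos = rho_chaos(stack$images[[1]]),
    mz_error_abs = mz_error_abs(stack$mean_mz[1], pat$mzs[1],
                                in_ppm = mz_error_in_ppm),
    mz_error_rel = mz_error_rel(stack$mean_mz, pat$mzs, pat$rel_intensities,
                                in_ppm = mz_error_in_ppm)
  )
  c(f, msm = msm_score(f))
}

#' Score every candidate of a dataset
#'
#' @param ds a [centroided_dataset()].
#' @param candidates list from [build_candidates()].
#' @param tol_ppm matching tolerance in ppm.
#' @param mz_error_in_ppm compute m/z-error deviations in ppm.
#' @return data.frame with one row per candidate: formula, adduct, is_decoy
#'   and the six scores.
#' @export
score_candidates <- function(ds, candidates, tol_ppm = 3,
                             mz_error_in_ppm = FALSE) {
  ds <- index_dataset(ds)
  rows <- lapply(candidates, function(cand) {
    f <- compute_features(ds, cand, tol_ppm, mz_error_in_ppm)
    data.frame(formula = cand$formula, adduct = cand$adduct,
               is_decoy = cand$is_decoy, t(f), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
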