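# Theoretical isotope patterns and decoy candidate generation.

# Per-element isotope distribution as integer nominal-mass shifts relative to
# the element's lightest isotope, with exact masses carried alongside.
element_shift_dist <- function(element) {
  iso <- isotope_table()[[element]]
  shift <- as.integer(round(iso$mass - iso$mass[1]))
  agg_shift_dist(shift, iso$abundance, iso$mass)
}

# Aggregate (shift, prob, mass) triplets into unique shifts; bin mass is the
# probability-weighted mean of the exact isotopologue masses.
agg_shift_dist <- function(shift, prob, mass) {
  key <- match(shift, sort(unique(shift)))
  p <- as.vector(tapply(prob, key, sum))
  m <- as.vector(tapply(prob * mass, key, sum)) / p
  list(shift = sort(unique(shift)), prob = p, mass = m)
}

# Convolve two shift distributions, pruning negligible isotopologues.
conv_shift_dist <- function(a, b, prune = 1e-15, max_shift = 63L) {
  shift <- as.vector(outer(a$shift, b$shift, `+`))
  prob <- as.vector(outer(a$prob, b$prob))
  mass <- as.vector(outer(a$mass, b$mass, `+`))
  keep <- prob > prune & shift <= max_shift
  if (!any(keep)) keep <- which.max(prob)
  d <- agg_shift_dist(shift[keep], prob[keep], mass[keep])
  d$prob <- d$prob / sum(d$prob)
  d
}

# n-fold self-convolution by binary powering.
power_shift_dist <- function(d, n, ...) {
  acc <- NULL
  base <- d
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- if (is.null(acc)) base else conv_shift_dist(acc, base, ...)
    n <- n %/% 2L
    if (n > 0L) base <- conv_shift_dist(base, base, ...)
  }
  acc
}

#' Theoretical isotope pattern of an ion composition
#'
#' Computes the full isotopologue distribution by element-wise convolution of
#' natural isotope abundances, aggregates it into peaks by nominal-mass-shift
#' bins, sorts by m/z, truncates to the first `n_peaks` peaks and normalizes
#' intensities to the most intense kept peak. Optionally, peaks closer than
#' the resolving-power width are merged first.
#'
#' @param composition named integer vector of element counts (e.g. from
#'   [ion_formula()]), or a formula string.
#' @param n_peaks number of isotopic peaks to keep (`T`; default 4).
#' @param charge ion charge, +1 or -1 (default +1); enters the m/z scale via
#'   the electron mass.
#' @param resolving_power optional instrument resolving power; when given,
#'   peaks closer than `mz / resolving_power` are intensity-weight merged.
#' @return List with `mzs` (ascending theoretical m/z), `rel_intensities`
#'   (max = 1) and `n_peaks`.
#' @export
#' @examples
#' theoretical_pattern("C6H12O6", n_peaks = 4)
theoretical_pattern <- function(composition, n_peaks = 4L, charge = 1L,
                                resolving_power = NULL) {
  if (is.character(composition)) composition <- parse_formula(composition)
  stopifnot(n_peaks >= 1L, abs(charge) == 1L)
  composition <- composition[composition > 0L]
  if (!length(composition)) stop("empty ion composition")
  dist <- NULL
  for (el in names(composition)) {
    d <- power_shift_dist(element_shift_dist(el), composition[[el]])
    dist <- if (is.null(dist)) d else conv_shift_dist(dist, d)
  }
  mz <- (dist$mass - charge * ELECTRON_MASS) / abs(charge)
  prob <- dist$prob
  o <- order(mz)
  mz <- mz[o]; prob <- prob[o]
  keep <- prob >= 1e-12 * max(prob)
  mz <- mz[keep]; prob <- prob[keep]
  if (!is.null(resolving_power)) {
    merged_mz <- numeric(0); merged_p <- numeric(0)
    for (i in seq_along(mz)) {
      k <- length(merged_mz)
      if (k > 0 && (mz[i] - merged_mz[k]) < merged_mz[k] / resolving_power) {
        w <- merged_p[k] + prob[i]
        merged_mz[k] <- (merged_mz[k] * merged_p[k] + mz[i] * prob[i]) / w
        merged_p[k] <- w
      } else {
        merged_mz <- c(merged_mz, mz[i]); merged_p <- c(merged_p, prob[i])
      }
    }
    mz <- merged_mz; prob <- merged_p
  }
  n <- min(n_peaks, length(mz))
  mz <- mz[seq_len(n)]; prob <- prob[seq_len(n)]
  list(mzs = mz, rel_intensities = prob / max(prob), n_peaks = n)
}

#' Sample the shared decoy adduct set for a formula
#'
#' Draws `s_d` distinct implausible adducts without replacement from the
#' decoy universe. The draw is a function of `(formula, seed, universe)`
#' only: every target adduct of the same formula shares the same decoy set,
#' and the set is stable when unrelated formulas are added to a corpus.
#'
#' @param formula molecular formula string (labels the RNG substream).
#' @param s_d number of decoy adducts per formula (default 20).
#' @param universe character vector of candidate decoy adducts.
#' @param seed master integer seed.
#' @return Character vector of `s_d` distinct adducts.
#' @export
sample_decoy_adducts <- function(formula, s_d = 20L,
                                 universe = default_decoy_adducts(),
                                 seed = 1L) {
  if (s_d > length(universe)) {
    stop("s_d (", s_d, ") exceeds the decoy universe size (",
         length(universe), ")")
  }
  if (s_d == 0L) return(character(0))
  with_seed(derive_seed(seed, "decoys", formula),
            sample(universe, s_d, replace = FALSE))
}

#' Build target and decoy ion candidates for a molecular database
#'
#' For every formula: one target candidate per target adduct and `s_d` decoy
#' candidates drawn from the shared per-formula decoy set, each with its
#' theoretical isotope pattern. Invalid ions (e.g. `-H` from a molecule with
#' no hydrogen) are skipped and reported in the `skipped` attribute.
#'
#' @param db data.frame of molecule records (column `formula`, optionally
#'   `name`), e.g. from [read_molecule_database()] or [toy_molecule_db()].
#' @param target_adducts character vector, e.g. `c("+H", "+Na", "+K")`.
#' @param polarity `"positive"` or `"negative"`.
#' @param s_d decoy samplings per formula (default 20).
#' @param seed master integer seed for decoy sampling.
#' @param n_peaks isotopic peaks per pattern (default 4).
#' @param decoy_universe decoy adduct universe (user-overridable).
#' @return List of ion candidates, each a list with `formula`, `adduct`,
#'   `polarity`, `is_decoy`, `charge` and `pattern`.
#' @export
build_candidates <- function(db, target_adducts, polarity = "positive",
                             s_d = 20L, seed = 1L, n_peaks = 4L,
                             decoy_universe = default_decoy_adducts()) {
  stopifnot(nrow(db) >= 1L, length(target_adducts) >= 1L)
  out <- list()
  skipped <- character(0)
  formulas <- unique(db$formula)
  for (f in formulas) {
    decoys <- sample_decoy_adducts(f, s_d, decoy_universe, seed)
    for (spec in list(list(adducts = target_adducts, is_decoy = FALSE),
                      list(adducts = decoys, is_decoy = TRUE))) {
      for (ad in spec$adducts) {
        cand <- tryCatch({
          ion <- ion_formula(f, ad, polarity)
          list(formula = f, adduct = ad, polarity = polarity,
               is_decoy = spec$is_decoy, charge = ion$charge,
               pattern = theoretical_pattern(ion$composition, n_peaks,
                                             ion$charge))
        }, error = function(e) {
          skipped <<- c(skipped, paste0(f, " ", ad, ": ", conditionMessage(e)))
          NULL
        })
        if (!is.null(cand)) out[[length(out) + 1L]] <- cand
      }
    }
  }
  attr(out, "skipped") <- skipped
  out
}
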