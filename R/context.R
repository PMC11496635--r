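# Context classification of datasets and diversity-maximizing selection of
# training/testing corpora.

#' Classify the acquisition m/z range
#'
#' Datasets with maximum m/z at most 400 are small-molecule acquisitions;
#' minimum m/z above 500 are lipid acquisitions; ranges spanning both
#' regions are "Lipids and small molecules".
#'
#' @param mz_min,mz_max acquisition m/z range (`mz_min < mz_max`).
#' @return One of `"small molecules"`, `"Lipids"`,
#'   `"Lipids and small molecules"`.
#' @export
classify_mz_class <- function(mz_min, mz_max) {
  stopifnot(mz_min < mz_max)
  if (mz_max <= 400) return("small molecules")
  if (mz_min > 500) return("Lipids")
  "Lipids and small molecules"
}

#' Group rare species into an OTHER label
#'
#' Species are sorted by ascending frequency (alphabetical tie-break) and
#' those whose cumulative frequency stays within the bottom 10% of the total
#' (inclusive at the boundary) are mapped to `"OTHER"`.
#'
#' @param counts named numeric vector of per-species dataset counts.
#' @param fraction bottom cumulative fraction to group (default 0.1).
#' @return Named character vector mapping species to their (possibly
#'   grouped) label.
#' @export
group_rare_species <- function(counts, fraction = 0.1) {
  stopifnot(all(counts >= 0))
  species <- names(counts)
  o <- order(counts, species)
  cum <- cumsum(counts[o])
  grouped <- cum <= fraction * sum(counts)
  labels <- ifelse(grouped, "OTHER", species[o])
  names(labels) <- species[o]
  labels[species]
}

#' Compose the context key of a dataset
#'
#' A context is the combination of polarity, ionization source, mass
#' analyzer, m/z class, sample type and (post-grouping) species.
#'
#' @param polarity,source,analyzer,mz_class,sample_type,species character
#'   scalars (vectors are pasted elementwise).
#' @return Character context key(s).
#' @export
context_key <- function(polarity, source, analyzer, mz_class, sample_type,
                        species) {
  paste(polarity, source, analyzer, mz_class, sample_type, species,
        sep = " | ")
}

# Shannon entropy (nats) of a frequency table.
shannon_entropy <- function(x) {
  p <- table(x)
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Diversity-maximizing selection of datasets within a context pool
#'
#' Phase 1 selects one dataset from each (project, group) combination —
#' datasets without a project get the pseudo-label (submitter, submission
#' day). Phase 2 fills the remaining slots from combinations ranked
#' lexicographically by (Shannon entropy of their submission-day
#' composition, descending; relative size, descending; name), drawing
#' seeded random datasets from the top-ranked combinations in turn.
#'
#' @param pool data.frame with columns `dataset_id`, `group` and optionally
#'   `project`, `submitter`, `submission_day`.
#' @param n number of datasets to select (default 30).
#' @param seed integer seed.
#' @param min_pool minimum eligible pool size (default 45; contexts smaller
#'   than this are rejected).
#' @param context label used in error messages.
#' @return Character vector of `n` selected dataset ids.
#' @export
select_datasets <- function(pool, n = 30L, seed = 1L, min_pool = 45L,
                            context = "context") {
  stopifnot(is.data.frame(pool), "dataset_id" %in% names(pool))
  if (nrow(pool) < max(n, min_pool)) {
    stop("context '", context, "' has ", nrow(pool),
         " datasets; need at least ", max(n, min_pool))
  }
  project <- as.character(pool$project %||% rep(NA_character_, nrow(pool)))
  submitter <- as.character(pool$submitter %||% rep("unknown", nrow(pool)))
  day <- as.character(pool$submission_day %||% rep("unknown", nrow(pool)))
  no_proj <- is.na(project) | !nzchar(project)
  project[no_proj] <- paste(submitter[no_proj], day[no_proj], sep = "@")
  combo <- paste(project, as.character(pool$group), sep = " / ")

  combo_stats <- do.call(rbind, lapply(sort(unique(combo)), function(cb) {
    in_cb <- combo == cb
    data.frame(combo = cb, size = sum(in_cb),
               entropy = shannon_entropy(day[in_cb]),
               stringsAsFactors = FALSE)
  }))
  combo_stats <- combo_stats[order(-combo_stats$entropy, -combo_stats$size,
                                   combo_stats$combo), ]

  remaining <- split(as.character(pool$dataset_id), combo)
  selected <- character(0)
  with_seed(derive_seed(seed, "select", context), {
    # phase 1: one dataset per combination, in ranked order
    for (cb in combo_stats$combo) {
      if (length(selected) >= n) break
      pick <- resample(remaining[[cb]], 1L)
      selected <- c(selected, pick)
      remaining[[cb]] <- setdiff(remaining[[cb]], pick)
    }
    # phase 2: fill remaining slots from top-ranked combinations in turn
    while (length(selected) < n) {
      advanced <- FALSE
      for (cb in combo_stats$combo) {
        if (length(selected) >= n) break
        if (length(remaining[[cb]])) {
          pick <- resample(remaining[[cb]], 1L)
          selected <- c(selected, pick)
          remaining[[cb]] <- setdiff(remaining[[cb]], pick)
          advanced <- TRUE
        }
      }
      if (!advanced) break
    }
  })
  selected
}

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size) x[sample.int(length(x), size)]

#' Mutually exclusive test/train selection for one context
#'
#' The test selection is drawn first and removed from the pool before the
#' training selection is drawn.
#'
#' @param pool see [select_datasets()].
#' @param n_test,n_train numbers of test and training datasets.
#' @param seed integer seed.
#' @param min_pool minimum eligible pool size (default `n_test + n_train`).
#' @param context label for error messages.
#' @return List with `test` and `train` dataset-id vectors (disjoint).
#' @export
select_train_test <- function(pool, n_test = 30L, n_train = 15L, seed = 1L,
                              min_pool = n_test + n_train,
                              context = "context") {
  test <- select_datasets(pool, n_test, seed = derive_seed(seed, "test"),
                          min_pool = min_pool, context = context)
  rest <- pool[!pool$dataset_id %in% test, , drop = FALSE]
  train <- select_datasets(rest, n_train, seed = derive_seed(seed, "train"),
                           min_pool = n_train, context = context)
  list(test = test, train = train)
}
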