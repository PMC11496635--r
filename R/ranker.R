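# Gradient-boosted pairwise ranking model on the five ion features, with
# context-stratified cross-validation and per-feature SHAP attribution.
#
# Backend: xgboost with the pairwise logistic ranking objective
# (`rank:pairwise`). The contract is backend-agnostic: gradient-boosted
# trees minimizing a pairwise logistic loss over (target winner, decoy
# loser) pairs formed within dataset groups, deterministic under a fixed
# seed, with raw ensemble output min-max scaled to [0, 1].

RANKER_FEATURES <- c("rho_spatial", "rho_spectral", "rho_chaos",
                     "mz_error_abs", "mz_error_rel")

#' Enumerate the training pairs available to the pairwise loss
#'
#' Pairs are formed within dataset groups only (never across datasets);
#' every (target, decoy) combination in a dataset is one ordered pair with
#' the target as winner.
#'
#' @param corpus list of per-dataset data.frames with at least `is_decoy`.
#' @return data.frame with per-dataset target, decoy and pair counts.
#' @export
make_training_pairs <- function(corpus) {
  out <- do.call(rbind, lapply(seq_along(corpus), function(i) {
    df <- corpus[[i]]
    nt <- sum(!df$is_decoy)
    nd <- sum(df$is_decoy)
    data.frame(dataset = names(corpus)[i] %||% as.character(i),
               n_targets = nt, n_decoys = nd, n_pairs = nt * nd)
  }))
  if (any(out$n_pairs == 0L)) {
    message(sum(out$n_pairs == 0L),
            " dataset(s) contribute no training pairs")
  }
  out
}

corpus_matrix <- function(corpus) {
  stopifnot(length(corpus) >= 1L)
  for (df in corpus) {
    stopifnot(all(RANKER_FEATURES %in% names(df)), "is_decoy" %in% names(df))
  }
  feats <- do.call(rbind, lapply(corpus, function(df) {
    as.matrix(df[, RANKER_FEATURES, drop = FALSE])
  }))
  label <- unlist(lapply(corpus, function(df) as.numeric(!df$is_decoy)),
                  use.names = FALSE)
  group <- vapply(corpus, nrow, integer(1))
  list(features = feats, label = label, group = group)
}

#' Train the pairwise ranking model
#'
#' @param corpus named list of per-dataset scored-candidate data.frames
#'   (columns: the five features and `is_decoy`), e.g. from
#'   [score_candidates()] per dataset.
#' @param n_iterations boosting iterations (default 1000).
#' @param seed integer seed (training is single-threaded and deterministic
#'   under it).
#' @param contexts optional per-dataset context labels recorded in the
#'   manifest.
#' @param params extra xgboost parameters (depth, learning rate).
#' @return A `ranker_model`: booster handle, feature names, min-max scaling
#'   bounds taken over raw predictions on the training corpus, and a
#'   training manifest.
#' @export
train_ranker <- function(corpus, n_iterations = 1000L, seed = 1L,
                         contexts = NULL, params = list()) {
  dat <- corpus_matrix(corpus)
  if (sum(dat$label) == 0 || sum(1 - dat$label) == 0) {
    stop("training corpus needs both targets and decoys")
  }
  constant <- apply(dat$features, 2, function(x) length(unique(x)) == 1L)
  if (all(constant)) {
    warning("all features constant: model will carry zero importance")
  }
  p <- utils::modifyList(list(objective = "rank:pairwise", eta = 0.1,
                              max_depth = 4, nthread = 1,
                              seed = as.integer(seed)),
                         params)
  dtrain <- xgboost::xgb.DMatrix(dat$features, label = dat$label,
                                 group = dat$group)
  booster <- xgboost::xgb.train(params = p, data = dtrain,
                                nrounds = as.integer(n_iterations),
                                verbose = 0)
  raw <- predict(booster, xgboost::xgb.DMatrix(dat$features),
                 outputmargin = TRUE)
  structure(list(
    booster = booster,
    n_iterations = as.integer(n_iterations),
    feature_names = RANKER_FEATURES,
    bounds = c(min = min(raw), max = max(raw)),
    manifest = list(datasets = names(corpus) %||% seq_along(corpus),
                    contexts = contexts, seed = as.integer(seed),
                    params = p)
  ), class = "ranker_model")
}

#' @export
print.ranker_model <- function(x, ...) {
  cat("<ranker_model> xgboost rank:pairwise,", x$n_iterations,
      "iterations,", length(x$manifest$datasets), "training datasets\n")
  invisible(x)
}

#' Min-max scaled prediction score
#'
#' `(raw - min) / (max - min)` with the bounds stored at training time;
#' values outside the training bounds are clipped to `[0, 1]`. A strictly
#' monotone transform of the raw ensemble output, so rankings (and hence
#' FDR) are invariant to the scaling.
#'
#' @param model a `ranker_model`.
#' @param features data.frame or matrix with the five feature columns.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_scaled <- function(model, features) {
  stopifnot(inherits(model, "ranker_model"))
  if (is.data.frame(features)) {
    features <- as.matrix(features[, model$feature_names, drop = FALSE])
  }
  raw <- predict(model$booster, xgboost::xgb.DMatrix(features),
                 outputmargin = TRUE)
  lo <- model$bounds[["min"]]; hi <- model$bounds[["max"]]
  if (hi == lo) {
    warning("degenerate scaling bounds (max == min); returning 0.5")
    return(rep(0.5, length(raw)))
  }
  pmin(1, pmax(0, (raw - lo) / (hi - lo)))
}

#' Context-stratified k-fold cross-validation
#'
#' Datasets are split into `k` folds stratified by context (fold sizes per
#' context kept as equal as possible; contexts with fewer than `k` datasets
#' are assigned wholly to training with a warning). For each fold, a model
#' is trained on the other folds and the held-out datasets are scored; AP
#' is computed per held-out dataset and MAP is their mean.
#'
#' @param corpus named list of per-dataset feature data.frames.
#' @param contexts per-dataset context labels (same length as corpus).
#' @param k number of folds (default 5; must be >= 2).
#' @param n_iterations boosting iterations per fold.
#' @param seed integer seed controlling the fold assignment and training.
#' @param params extra xgboost parameters.
#' @return List with `per_dataset` (data.frame: dataset, context, fold,
#'   ap) and `map`.
#' @export
crossvalidate <- function(corpus, contexts, k = 5L, n_iterations = 100L,
                          seed = 1L, params = list()) {
  stopifnot(length(contexts) == length(corpus))
  if (k < 2L) stop("k must be at least 2 (no held-out fold otherwise)")
  ids <- names(corpus) %||% as.character(seq_along(corpus))
  fold <- rep(NA_integer_, length(corpus))
  with_seed(derive_seed(seed, "cv-folds"), {
    for (ctx in unique(contexts)) {
      members <- which(contexts == ctx)
      if (length(members) < k) {
        warning("context '", ctx, "' has fewer than k datasets; ",
                "assigned wholly to training")
        next
      }
      fold[members] <- sample(rep_len(seq_len(k), length(members)))
    }
  })
  per <- list()
  for (f in seq_len(k)) {
    hold <- which(fold == f)
    train_idx <- setdiff(seq_along(corpus), hold)
    if (!length(hold)) next
    model <- train_ranker(corpus[train_idx], n_iterations,
                          seed = derive_seed(seed, "cv-train", f),
                          params = params)
    for (i in hold) {
      df <- corpus[[i]]
      s <- predict_scaled(model, df)
      o <- order(-s, df$is_decoy)   # ties: decoy first (conservative)
      per[[length(per) + 1L]] <-
        data.frame(dataset = ids[i], context = contexts[i], fold = f,
                   ap = average_precision(!df$is_decoy[o]))
    }
  }
  per <- do.call(rbind, per)
  list(per_dataset = per, map = mean(per$ap))
}

#' Per-feature SHAP contribution shares
#'
#' Per ion, the share of each feature is the absolute SHAP (TreeSHAP)
#' attribution divided by the sum of absolute attributions over the five
#' features. Ions with all-zero attributions get uniform shares (flagged).
#'
#' @param model a `ranker_model`.
#' @param features data.frame or matrix of ion feature vectors.
#' @return List with `shares` (n x 5 matrix, rows summing to 1),
#'   `median_share` (per-feature median, the per-dataset aggregate) and
#'   `uniform_flag` (logical per ion).
#' @export
shap_contributions <- function(model, features) {
  stopifnot(inherits(model, "ranker_model"))
  if (is.data.frame(features)) {
    features <- as.matrix(features[, model$feature_names, drop = FALSE])
  }
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(features),
                     predcontrib = TRUE)
  contrib <- contrib[, model$feature_names, drop = FALSE]   # drop BIAS
  absc <- abs(contrib)
  tot <- rowSums(absc)
  uniform <- tot == 0
  shares <- absc / ifelse(tot == 0, 1, tot)
  shares[uniform, ] <- 1 / ncol(shares)
  list(shares = shares,
       median_share = apply(shares, 2, stats::median),
       uniform_flag = uniform)
}

#' Save / load a ranker model
#'
#' The booster is persisted in xgboost's native JSON format with a JSON
#' manifest (features, bounds, seed, iteration count) alongside.
#'
#' @param model a `ranker_model`.
#' @param path base path (without extension).
#' @return `save_ranker`: `path`, invisibly. `load_ranker`: the model.
#' @export
save_ranker <- function(model, path) {
  xgboost::xgb.save(model$booster, paste0(path, ".ubj"))
  meta <- model[c("n_iterations", "feature_names", "manifest")]
  meta$bounds <- as.list(model$bounds)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_ranker
#' @export
load_ranker <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(booster = xgboost::xgb.load(paste0(path, ".ubj")),
                 n_iterations = meta$n_iterations,
                 feature_names = meta$feature_names,
                 bounds = c(min = meta$bounds[["min"]],
                            max = meta$bounds[["max"]]),
                 manifest = meta$manifest),
            class = "ranker_model")
}
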