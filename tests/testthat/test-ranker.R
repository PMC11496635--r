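test_that("training pairs are enumerated within datasets only", {
  corpus <- list(
    a = data.frame(is_decoy = c(FALSE, FALSE, TRUE, TRUE, TRUE)),
    b = data.frame(is_decoy = c(TRUE, TRUE)),
    c = data.frame(is_decoy = logical(0)))
  expect_message(pairs <- make_training_pairs(corpus), "no training pairs")
  expect_equal(pairs$n_pairs, c(2 * 3, 0, 0))
  expect_equal(sum(pairs$n_pairs), 6)   # counts add, no cross pairs
})

test_that("scaled predictions hit 0/1 at the stored bounds and clip", {
  fc <- generate_feature_corpus(6, n_targets = 8, n_decoys = 40, seed = 2)
  m <- train_ranker(fc$corpus, n_iterations = 30, seed = 1)
  all_feats <- do.call(rbind, fc$corpus)
  s <- predict_scaled(m, all_feats)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
})

test_that("ranking order (and hence FDR) is invariant to the scaling", {
  fc <- generate_feature_corpus(5, n_targets = 10, n_decoys = 50, seed = 3)
  m <- train_ranker(fc$corpus, n_iterations = 40, seed = 1)
  df <- fc$corpus[[1]]
  raw <- predict(m$booster,
                 xgboost::xgb.DMatrix(as.matrix(df[, m$feature_names])),
                 outputmargin = TRUE)
  scaled <- predict_scaled(m, df)
  expect_equal(order(-raw, df$is_decoy), order(-scaled, df$is_decoy))
  mk <- function(score) {
    rank_with_fdr(build_ranking(
      data.frame(formula = as.character(which(!df$is_decoy)), adduct = "+H",
                 score = score[!df$is_decoy]),
      data.frame(formula = as.character(which(df$is_decoy)), adduct = "+W",
                 score = score[df$is_decoy]), s_d = 20))
  }
  expect_equal(mk(raw)$fdr, mk(scaled)$fdr, tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  fc <- generate_feature_corpus(5, n_targets = 8, n_decoys = 30, seed = 7)
  m1 <- train_ranker(fc$corpus, n_iterations = 25, seed = 5)
  m2 <- train_ranker(fc$corpus, n_iterations = 25, seed = 5)
  df <- do.call(rbind, fc$corpus)
  expect_identical(predict_scaled(m1, df), predict_scaled(m2, df))
})

test_that("cross-validation stratifies contexts and validates k", {
  fc <- generate_feature_corpus(10, n_targets = 6, n_decoys = 24,
                                contexts = c("ctxA", "ctxB"), seed = 11)
  expect_error(crossvalidate(fc$corpus, fc$contexts, k = 1), "at least 2")
  cv <- crossvalidate(fc$corpus, fc$contexts, k = 5, n_iterations = 20,
                      seed = 9)
  # 2 contexts of 5 datasets, k = 5: each fold holds out one per context
  per_fold <- table(cv$per_dataset$fold, cv$per_dataset$context)
  expect_true(all(per_fold == 1))
  # determinism of the split assignment
  cv2 <- crossvalidate(fc$corpus, fc$contexts, k = 5, n_iterations = 20,
                       seed = 9)
  expect_identical(cv$per_dataset, cv2$per_dataset)
  # a context smaller than k goes wholly to training with a warning
  expect_warning(
    crossvalidate(fc$corpus, c(rep("big", 7), rep("tiny", 3)), k = 5,
                  n_iterations = 10, seed = 1),
    "fewer than k")
})

test_that("a separable corpus cross-validates at near-perfect MAP", {
  fc <- generate_feature_corpus(10, n_targets = 15, n_decoys = 75,
                                separation = 0.6,
                                contexts = c("a", "b"), seed = 13)
  cv <- crossvalidate(fc$corpus, fc$contexts, k = 5, n_iterations = 60,
                      seed = 3)
  expect_gte(cv$map, 0.99)
})

test_that("attribution shares are normalized and recover planted importance", {
  fc <- generate_feature_corpus(8, n_targets = 15, n_decoys = 60,
                                informative = "rho_spectral",
                                separation = 0.6, seed = 19)
  m <- train_ranker(fc$corpus, n_iterations = 80, seed = 2)
  sh <- shap_contributions(m, do.call(rbind, fc$corpus))
  expect_true(all(abs(rowSums(sh$shares) - 1) < 1e-9))
  expect_gt(sh$median_share[["rho_spectral"]], 0.5)
  expect_equal(names(which.max(sh$median_share)), "rho_spectral")
})

test_that("constant features train with a warning and uniform attributions", {
  corpus <- list(a = data.frame(rho_spatial = 0.5, rho_spectral = 0.5,
                                rho_chaos = 0.5, mz_error_abs = 0.5,
                                mz_error_rel = 0.5,
                                is_decoy = rep(c(FALSE, TRUE), 10)))
  expect_warning(m <- train_ranker(corpus, n_iterations = 5, seed = 1),
                 "constant")
  expect_warning(s <- predict_scaled(m, corpus$a), "degenerate")
  expect_equal(unique(s), 0.5)
  sh <- shap_contributions(m, corpus$a)
  expect_true(all(sh$uniform_flag))
  expect_true(all(abs(sh$shares - 0.2) < 1e-12))
})

test_that("models persist and reload with identical predictions", {
  fc <- generate_feature_corpus(4, n_targets = 6, n_decoys = 20, seed = 23)
  m <- train_ranker(fc$corpus, n_iterations = 20, seed = 1)
  base <- withr::local_tempfile()
  save_ranker(m, base)
  m2 <- load_ranker(base)
  df <- do.call(rbind, fc$corpus)
  expect_equal(predict_scaled(m, df), predict_scaled(m2, df),
               tolerance = 1e-12)
})
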