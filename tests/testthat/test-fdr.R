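test_that("rankings sort descending with decoy-before-target ties", {
  targets <- data.frame(formula = c("A", "B", "C"), adduct = "+H",
                        score = c(0.9, 0.7, 0.2))
  decoys <- data.frame(formula = c("A", "A", "B", "B", "C", "C"),
                       adduct = c("+W", "+Sc", "+W", "+Sc", "+W", "+Sc"),
                       score = c(0.8, 0.7, 0.5, 0.4, 0.1, 0.05))
  r <- build_ranking(targets, decoys, s_d = 2)
  expect_equal(nrow(r), 9L)
  expect_true(!is.unsorted(rev(r$score)))
  # tie at 0.7: decoy first
  tie <- which(r$score == 0.7)
  expect_true(r$is_decoy[tie[1]] && !r$is_decoy[tie[2]])
  expect_equal(unique(r$weight[r$is_decoy]), 0.5)
  expect_equal(unique(r$weight[!r$is_decoy]), 1)
  # all decoys below all targets -> targets occupy the top block
  r2 <- build_ranking(data.frame(formula = "A", adduct = "+H", score = 1),
                      data.frame(formula = "A", adduct = "+W", score = 0),
                      s_d = 1)
  expect_equal(r2$is_decoy, c(FALSE, TRUE))
  # empty targets -> empty (valid) ranking
  expect_equal(nrow(build_ranking(NULL, decoys[0, ], 20)), 0L)
})

test_that("the weighted pseudocounted FDR matches worked values", {
  # clean top target, S_D = 20: (1/20) / (2 + 1/20)
  expect_equal(estimate_fdr(FALSE, 20), (1 / 20) / (2 + 1 / 20),
               tolerance = 1e-12)
  expect_equal(estimate_fdr(FALSE, 20), 0.0243902439, tolerance = 1e-8)
  # rank with T = 9, D = 19: (20/20) / (10 + 1)
  lab <- c(rep(FALSE, 9), rep(TRUE, 19))
  expect_equal(estimate_fdr(lab, 20)[28], 1 / 11, tolerance = 1e-12)
  # rank with T = 0, D = 20: 1.05 / 2.05
  expect_equal(estimate_fdr(rep(TRUE, 20), 20)[20], 1.05 / 2.05,
               tolerance = 1e-12)
  # never exactly zero anywhere
  expect_true(all(estimate_fdr(rep(FALSE, 50), 20) > 0))
})

test_that("monotonic adjustment is the reverse cumulative minimum", {
  expect_equal(monotonic_adjust(c(0.02, 0.5, 0.01)), c(0.01, 0.01, 0.01))
  nondec <- c(0.01, 0.02, 0.5, 0.5, 0.9)
  expect_equal(monotonic_adjust(nondec), nondec)
  expect_equal(monotonic_adjust(0.3), 0.3)
  expect_equal(monotonic_adjust(numeric(0)), numeric(0))
  set.seed(4)
  for (rep in 1:25) {
    raw <- runif(sample(1:30, 1))
    adj <- monotonic_adjust(raw)
    expect_true(!is.unsorted(adj))
    expect_true(all(adj <= raw))
  }
})

test_that("annotation sets respect thresholds and nest monotonically", {
  targets <- data.frame(formula = sprintf("T%02d", 1:8), adduct = "+H",
                        score = seq(0.95, 0.6, length.out = 8))
  decoys <- data.frame(formula = rep(sprintf("T%02d", 1:8), each = 2),
                       adduct = "+W",
                       score = runif(16, 0, 0.7))
  r <- rank_with_fdr(build_ranking(targets, decoys, s_d = 2))
  expect_error(annotations_at(r, 0), "0, 1")
  expect_error(annotations_at(r, 1.5), "0, 1")
  all_t <- annotations_at(r, 1.0)$annotations
  expect_equal(nrow(all_t), 8L)
  tiny <- annotations_at(r, min(r$fdr) / 2)$annotations
  expect_equal(nrow(tiny), 0L)
  # enumeration oracle at 0.10 and nesting across thresholds
  expect_equal(sort(annotations_at(r, 0.10)$annotations$formula),
               sort(r$formula[!r$is_decoy & r$fdr <= 0.10]))
  prev <- character(0)
  for (q in c(0.05, 0.1, 0.2, 0.5, 1)) {
    cur <- annotations_at(r, q)$annotations$formula
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("estimated false positives are reported separately as decoys", {
  r <- rank_with_fdr(build_ranking(
    data.frame(formula = "A", adduct = "+H", score = 0.9),
    data.frame(formula = "A", adduct = "+W", score = 0.95), s_d = 1))
  res <- annotations_at(r, 1.0)
  expect_true(all(res$estimated_false_positives$is_decoy))
  expect_true(all(!res$annotations$is_decoy))
})

test_that("ranking dumps carry audit columns consistent with the ranking", {
  targets <- data.frame(formula = c("A", "B"), adduct = "+H",
                        score = c(0.9, 0.3))
  decoys <- data.frame(formula = c("A", "B"), adduct = "+W",
                       score = c(0.5, 0.2))
  r <- rank_with_fdr(build_ranking(targets, decoys, 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, path)
  dump <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(dump$T_i, cumsum(!r$is_decoy))
  expect_equal(dump$D_i, cumsum(r$is_decoy))
  expect_equal(dump$fdr_adjusted, r$fdr, tolerance = 1e-9)
})
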