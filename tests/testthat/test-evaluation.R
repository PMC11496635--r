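test_that("average precision matches hand enumeration", {
  expect_equal(average_precision(c(TRUE, FALSE, TRUE, FALSE)),
               (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(TRUE, TRUE, FALSE)), 1.0)
  expect_equal(average_precision(c(FALSE, TRUE)), 0.5)
  expect_error(average_precision(c(FALSE, FALSE)), "without any target")
})

test_that("average precision matches the definition oracle exhaustively", {
  for (n in 2:10) {
    pats <- all_label_patterns(n)
    for (i in seq_len(nrow(pats))) {
      lab <- !pats[i, ]   # TRUE = target
      if (!any(lab)) next
      expect_equal(average_precision(lab), ap_oracle(lab), tolerance = 1e-12)
    }
  }
})

test_that("MAP averages groups and skips target-free ones with a warning", {
  expect_equal(map_over_groups(list(c(TRUE), c(FALSE, TRUE))), 0.75)
  expect_equal(map_over_groups(list(c(TRUE, FALSE))), 1.0)
  expect_warning(m <- map_over_groups(list(c(TRUE), c(FALSE))), "skipped")
  expect_equal(m, 1.0)
})

test_that("annotation deltas carry sign and pseudocounted transforms", {
  d0 <- annotation_delta(5, 5)
  expect_equal(d0$log10_difference, 0)
  expect_equal(d0$log2_fold_change, 0)
  d <- annotation_delta(110, 10)
  expect_equal(d$log10_difference, log10(101), tolerance = 1e-12)
  expect_equal(d$log10_difference, 2.0043, tolerance = 1e-4)
  expect_equal(d$log2_fold_change, log2(111 / 11), tolerance = 1e-12)
  dn <- annotation_delta(0, 100)
  expect_lt(dn$log10_difference, 0)
  expect_lt(dn$log2_fold_change, 0)
  # sign always agrees with the count difference
  set.seed(2)
  ml <- rpois(50, 40); base <- rpois(50, 40)
  dd <- annotation_delta(ml, base)
  expect_equal(sign(dd$log10_difference), sign(ml - base))
})

test_that("intensity profiling recovers planted low-intensity sets", {
  cfg <- simulation_config(grid_shape = c(10, 10), n_planted_molecules = 6,
                           noise_peaks_per_pixel = 5, seed = 37)
  sim <- generate_dataset(cfg)
  planted <- sim$truth$planted$formula
  db <- toy_molecule_db()
  cands <- build_candidates(db[db$formula %in% planted, ], "+H", s_d = 0,
                            seed = 1)
  # constant image sanity: 99th percentile of a constant-10 image is 10
  ds_const <- tiny_dataset(list(list(mz = 100, intensity = 10),
                                list(mz = 100, intensity = 10)))
  prof0 <- intensity_profile(
    ds_const, list(a = list(list(pattern = list(mzs = 100)))), q = 0.99)
  expect_equal(unname(prof0$medians["a"]), 1, tolerance = 1e-6)
  # planted ions vs absent ions: planted set has higher median intensity
  absent <- build_candidates(db[!db$formula %in% planted, ][1:6, ], "+H",
                             s_d = 0, seed = 1)
  prof <- intensity_profile(sim$dataset,
                            list(planted = cands, absent = absent))
  expect_gt(prof$medians[["planted"]], prof$medians[["absent"]])
  expect_true(all(prof$tests$p_adjusted >= prof$tests$p_value - 1e-12))
})

test_that("enrichment matches the worked fold-change and the tail oracle", {
  # query 10/20 in subclass, background 100/1000 -> fold enrichment 5
  bg <- data.frame(formula = sprintf("M%04d", 1:1000),
                   subclass = c(rep("S", 100), rep("other", 900)))
  query <- c(sprintf("M%04d", 1:10),      # 10 in subclass S
             sprintf("M%04d", 101:110))   # 10 outside
  e <- subclass_enrichment(query, bg)
  row <- e[e$subclass == "S", ]
  expect_equal(row$a, 10); expect_equal(row$b, 10); expect_equal(row$c, 90)
  expect_equal(row$log2_fold_enrichment, log2(5), tolerance = 1e-12)
  expect_equal(row$log2_fold_enrichment, 2.3219, tolerance = 1e-4)
  expect_equal(row$p_value,
               fisher_greater_oracle(row$a, row$b, row$c, row$d),
               tolerance = 1e-9)
  # empty query -> empty result
  expect_equal(nrow(subclass_enrichment(character(0), bg)), 0L)
})

test_that("uniform random queries are enriched at about the nominal rate", {
  bg <- data.frame(formula = sprintf("M%04d", 1:1000),
                   subclass = rep(sprintf("S%02d", 1:40), each = 25))
  hits <- 0; total <- 0
  for (s in 1:30) {
    set.seed(1000 + s)
    q <- sprintf("M%04d", sample(1000, 100))
    e <- subclass_enrichment(q, bg)
    hits <- hits + sum(e$p_value < 0.05)
    total <- total + nrow(e)
  }
  # one-tailed Fisher is conservative on discrete tables: at or below ~5%
  expect_lt(hits / total, 0.08)
  expect_gt(total, 1000)
})

test_that("corpus reporting filter keeps terms significant in >= 10%", {
  e_sig <- data.frame(subclass = c("A", "B"), p_value = c(0.01, 0.2))
  e_ns <- data.frame(subclass = c("A", "B"), p_value = c(0.5, 0.6))
  keep <- filter_enriched_terms(c(list(e_sig), rep(list(e_ns), 9)))
  expect_equal(keep, "A")   # 1/10 datasets = exactly 10%
  keep2 <- filter_enriched_terms(c(list(e_sig), rep(list(e_ns), 10)))
  expect_equal(keep2, character(0))
})

test_that("reference matching builds the expected contingency and rates", {
  universe <- data.frame(formula = c("A", "B", "C", "D"),
                         adduct = c("+H", "+Na", "+K", "+H"))
  ann <- data.frame(formula = c("A", "B"), adduct = c("+H", "+Na"))
  ref <- data.frame(formula = c("A", "C"), adduct = c("+H", "+K"))
  m <- match_reference(ann, ref, universe)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(1, 1, 1, 1))
  expect_equal(m$tpr, 0.5)
  # annotations equal to the reference -> perfect rates
  m2 <- match_reference(ref, ref, universe)
  expect_equal(m2$tpr, 1); expect_equal(m2$fpr, 0)
  # disjoint sets -> zero TPR
  m3 <- match_reference(data.frame(formula = "D", adduct = "+H"), ref,
                        universe)
  expect_equal(m3$tpr, 0)
  # exclusive mode removes ions annotated by the other method
  m4 <- match_reference(ann, ref, universe,
                        other_method = data.frame(formula = "A",
                                                  adduct = "+H"))
  expect_equal(m4$tp, 0)
  # adduct restriction and empty-reference error
  expect_error(match_reference(ann, data.frame(formula = "A",
                                               adduct = "-H"), universe),
               "empty reference")
})
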