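test_that("per-isotope mean m/z is the intensity-weighted pixel mean", {
  ds <- tiny_dataset(list(list(mz = 100.0, intensity = 2),
                          list(mz = 100.0004, intensity = 2)))
  pat <- list(mzs = 100.0, rel_intensities = 1, n_peaks = 1)
  st <- observed_isotope_stack(ds, pat, tol_ppm = 10)
  expect_equal(st$mean_mz[1], 100.0002, tolerance = 1e-12)
  ds2 <- tiny_dataset(list(list(mz = 100.0, intensity = 1),
                           list(mz = 100.0004, intensity = 3)))
  st2 <- observed_isotope_stack(ds2, pat, tol_ppm = 10)
  expect_equal(st2$mean_mz[1], 100.0003, tolerance = 1e-12)
  # an isotope with no matches anywhere is flagged missing
  pat2 <- list(mzs = c(100.0, 600.0), rel_intensities = c(1, 0.1),
               n_peaks = 2)
  st3 <- observed_isotope_stack(ds, pat2)
  expect_true(st3$missing[2])
  expect_true(is.na(st3$mean_mz[2]))
})

test_that("absolute m/z error score follows 1 - |deviation|", {
  expect_equal(mz_error_abs(500.0, 500.0), 1.0)
  expect_equal(mz_error_abs(500.0005, 500.0), 0.9995)
  expect_equal(mz_error_abs(NA_real_, 500.0), 0)          # missing -> worst
  expect_equal(mz_error_abs(500.0005, 500.0, in_ppm = TRUE), 0)
  expect_equal(mz_error_abs(500.00025, 500.0, in_ppm = TRUE), 0.5)
})

test_that("relative m/z error cancels uniform shifts and skips missing", {
  theor <- c(100, 101, 102, 103)
  rel <- c(1, 0.5, 0.3, 0.2)
  # uniform shift d_i = 0.001 cancels exactly
  expect_equal(mz_error_rel(theor + 0.001, theor, rel), 1.0)
  # d = (0, 0.002, 0, 0) with weights (0.5, 0.3, 0.2)
  obs <- theor + c(0, 0.002, 0, 0)
  expect_equal(mz_error_rel(obs, theor, rel), 1 - 0.002 * 0.5 / 1.0)
  # only the first isotope observed -> 0
  expect_equal(mz_error_rel(c(100, NA, NA, NA), theor, rel), 0)
  # first isotope missing -> 0
  expect_equal(mz_error_rel(c(NA, 101, 102, 103), theor, rel), 0)
  # missing higher isotopes excluded from both sums
  obs2 <- theor + c(0, 0.002, NA, NA)
  expect_equal(mz_error_rel(obs2, theor, rel), 1 - 0.002 * 0.5 / 0.5)
})

test_that("spectral score is total-variation agreement of patterns", {
  expect_equal(rho_spectral(c(0.7, 0.2, 0.1), c(7, 2, 1) * 13.7), 1.0)
  expect_equal(rho_spectral(c(0.7, 0.2, 0.1), c(1, 0, 0)), 0.7)
  expect_equal(rho_spectral(c(0.7, 0.2, 0.1), c(0, 0, 0)), 0)
  # invariant under rescaling of observed totals
  q <- c(5, 3, 1)
  expect_equal(rho_spectral(c(0.6, 0.3, 0.1), q),
               rho_spectral(c(0.6, 0.3, 0.1), q * 1e6))
})

test_that("spatial score is the weighted positive-correlation mean", {
  imgs <- function(vectors) {
    lapply(vectors, function(v) list(pixel_values = v))
  }
  base <- c(1, 2, 3, 4, 5)
  # scalar multiples -> perfect correlation
  expect_equal(rho_spatial(imgs(list(base, base * 2, base * 0.1)),
                           c(1, 0.5, 0.2)), 1.0)
  # all higher isotopes missing -> 0
  expect_equal(rho_spatial(imgs(list(base, rep(0, 5), rep(0, 5))),
                           c(1, 0.5, 0.2)), 0.0)
  # weighted mean of clipped correlations
  v2 <- base
  v3 <- c(2, 5, 1, 3, 4)
  r3 <- max(0, cor(base, v3))
  got <- rho_spatial(imgs(list(base, v2, v3)), c(1, 0.6, 0.4))
  expect_equal(got, (1 * 0.6 + r3 * 0.4) / 1.0)
  # constant principal image -> 0
  expect_equal(rho_spatial(imgs(list(rep(2, 5), base)), c(1, 0.5)), 0)
  # negative correlations clipped to zero
  expect_equal(rho_spatial(imgs(list(base, rev(base))), c(1, 1)), 0)
  # invariant under positive affine maps of higher-isotope images
  expect_equal(rho_spatial(imgs(list(base, v3 * 7 + 3)), c(1, 1)),
               rho_spatial(imgs(list(base, v3)), c(1, 1)))
})

test_that("chaos score separates solid blobs from scattered pixels", {
  solid <- matrix(0, 12, 12)
  solid[2:11, 2:11] <- 1            # one 100-pixel blob
  expect_equal(rho_chaos(solid), 1 - 1 / 100)
  checker <- matrix(0, 10, 10)
  checker[(row(checker) + col(checker)) %% 2 == 0] <- 1  # isolated pixels
  expect_equal(rho_chaos(checker), 0)
  expect_equal(rho_chaos(matrix(0, 5, 5)), 0)
  # graded blob: component ratio at every level matches the flood-fill oracle
  g <- outer(1:9, 1:9, function(r, c) exp(-((r - 5)^2 + (c - 5)^2) / 8))
  g[g < 0.2] <- 0
  lv <- quantile(g[g > 0], probs = seq(0, 1, length.out = 30), names = FALSE)
  oracle <- 1 - mean(vapply(lv, function(th) {
    components_oracle(g >= th) / sum(g >= th)
  }, numeric(1)))
  expect_equal(rho_chaos(g), oracle, tolerance = 1e-12)
})

test_that("MSM is the equal-weight product of the three rho scores", {
  expect_equal(msm_score(c(rho_spatial = 1, rho_spectral = 1, rho_chaos = 1)), 1)
  expect_equal(msm_score(c(rho_spatial = 0.5, rho_spectral = 0.8,
                           rho_chaos = 0.9)), 0.36)
  expect_equal(msm_score(c(rho_spatial = 0, rho_spectral = 0.8,
                           rho_chaos = 0.9)), 0)
})

test_that("noiseless planted ions score near 1 on every feature", {
  cfg <- simulation_config(grid_shape = c(12, 12), n_planted_molecules = 5,
                           jitter_ppm = 0, noise_peaks_per_pixel = 0,
                           intensity_noise_sd = 0, seed = 71)
  sim <- generate_dataset(cfg)
  ds <- index_dataset(sim$dataset)
  cands <- build_candidates(
    toy_molecule_db()[toy_molecule_db()$formula %in%
                        sim$truth$planted$formula, , drop = FALSE],
    "+H", s_d = 0, seed = 1)
  for (cand in cands) {
    f <- compute_features(ds, cand)
    expect_gt(f[["rho_spectral"]], 1 - 1e-6)
    expect_equal(f[["mz_error_abs"]], 1, tolerance = 1e-9)
    expect_equal(f[["mz_error_rel"]], 1, tolerance = 1e-9)
    expect_gt(f[["rho_spatial"]], 0.95)
    expect_gt(f[["rho_chaos"]], 0.75)
    expect_true(f[["msm"]] <= min(f[c("rho_spatial", "rho_spectral",
                                      "rho_chaos")]) + 1e-12)
  }
})

test_that("a candidate with no matched signal scores all zeros", {
  ds <- tiny_dataset(list(list(mz = c(100, 150), intensity = c(1, 1)),
                          list(mz = c(110, 160), intensity = c(2, 1))))
  cand <- list(pattern = list(mzs = c(700, 701, 702, 703),
                              rel_intensities = c(1, 0.4, 0.1, 0.02),
                              n_peaks = 4))
  f <- compute_features(ds, cand)
  expect_equal(unname(f), rep(0, 6))
})

test_that("m/z error features are invariant to global intensity rescaling", {
  cfg <- simulation_config(grid_shape = c(8, 8), n_planted_molecules = 3,
                           noise_peaks_per_pixel = 10, seed = 43)
  ds <- generate_dataset(cfg)$dataset
  ds_scaled <- ds
  ds_scaled$spectra <- lapply(ds$spectra, function(s) {
    centroided_spectrum(s$mz, s$intensity * 1000)
  })
  cand <- build_candidates(toy_molecule_db()[1:3, ], "+H", s_d = 0,
                           seed = 1)[[1]]
  f1 <- compute_features(index_dataset(ds), cand)
  f2 <- compute_features(index_dataset(ds_scaled), cand)
  expect_equal(f1[["mz_error_abs"]], f2[["mz_error_abs"]], tolerance = 1e-12)
  expect_equal(f1[["mz_error_rel"]], f2[["mz_error_rel"]], tolerance = 1e-12)
  expect_equal(f1[["rho_spectral"]], f2[["rho_spectral"]], tolerance = 1e-12)
})
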