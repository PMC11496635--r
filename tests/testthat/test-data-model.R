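test_that("spectra are sorted with intensities co-permuted and validated", {
  s <- centroided_spectrum(c(300, 100, 200), c(3, 1, 2))
  expect_equal(s$mz, c(100, 200, 300))
  expect_equal(s$intensity, c(1, 2, 3))
  expect_error(centroided_spectrum(c(1, 2), c(1, -1)))
})

test_that("geometry classification follows the grid-product rule", {
  full <- expand.grid(x = 0:9, y = 0:9)
  peaks <- replicate(100, list(mz = 100, intensity = 1), simplify = FALSE)
  ds <- tiny_dataset(peaks, full)
  expect_equal(classify_geometry(ds), "regular")
  holes <- full[-c(3, 57, 91), ]
  ds2 <- tiny_dataset(peaks[1:97], holes)
  expect_equal(classify_geometry(ds2), "irregular")
  ds3 <- tiny_dataset(peaks[1], data.frame(x = 0, y = 0))
  expect_equal(classify_geometry(ds3), "regular")
  # depends only on the coordinate multiset, not ordering
  perm <- sample(97)
  ds4 <- tiny_dataset(peaks[1:97], holes[perm, ])
  expect_equal(classify_geometry(ds4), classify_geometry(ds2))
})

test_that("ion image sums all centroids in the closed ppm window", {
  ds <- tiny_dataset(list(
    list(mz = c(500.0004, 500.0012), intensity = c(10, 5)),
    list(mz = 400, intensity = 7)))
  img <- extract_ion_image(ds, 500.0, tol_ppm = 3)   # window +/- 0.0015
  expect_equal(img$pixel_values, c(15, 0))
  # intensity-weighted matched m/z
  expect_equal(img$matched_mz[1],
               (500.0004 * 10 + 500.0012 * 5) / 15)
  expect_true(is.na(img$matched_mz[2]))
  # nothing anywhere -> all-zero image
  img0 <- extract_ion_image(ds, 900, tol_ppm = 3)
  expect_equal(img0$pixel_values, c(0, 0))
  # exact match -> matched m/z equals the target
  ds1 <- tiny_dataset(list(list(mz = 250.0, intensity = 4)))
  expect_equal(extract_ion_image(ds1, 250.0)$matched_mz[1], 250.0)
  expect_error(extract_ion_image(ds, -5))
})

test_that("ion image extraction is additive over disjoint peak sets", {
  mzs_a <- c(500.0002, 500.0009)
  mzs_b <- c(499.9991, 500.0013)
  ia <- c(3, 4); ib <- c(5, 6)
  ds_a <- tiny_dataset(list(list(mz = mzs_a, intensity = ia)))
  ds_b <- tiny_dataset(list(list(mz = mzs_b, intensity = ib)))
  ds_ab <- tiny_dataset(list(list(mz = c(mzs_a, mzs_b),
                                  intensity = c(ia, ib))))
  va <- extract_ion_image(ds_a, 500, 3)$pixel_values
  vb <- extract_ion_image(ds_b, 500, 3)$pixel_values
  vab <- extract_ion_image(ds_ab, 500, 3)$pixel_values
  expect_equal(vab, va + vb)
})

test_that("cached peak index gives identical extraction results", {
  cfg <- simulation_config(grid_shape = c(6, 6), n_planted_molecules = 3,
                           noise_peaks_per_pixel = 10, seed = 21)
  ds <- generate_dataset(cfg)$dataset
  dsi <- index_dataset(ds)
  for (mz in c(181.0707, 250.123, 523.4)) {
    expect_identical(extract_ion_image(ds, mz)$pixel_values,
                     extract_ion_image(dsi, mz)$pixel_values)
  }
})

test_that("molecule databases read, deduplicate and report bad formulas", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("formula\tname\tsubclass",
               "C6H12O6\tHexose\tMonosaccharides",
               "C5H9NO4\tGlutamate\tAmino acids",
               "C6H12O6\tGlucose again\tMonosaccharides",
               "NotAFormula123x\tJunk\t"),
             path)
  db <- read_molecule_database(path)
  expect_equal(nrow(db), 2L)
  expect_equal(attr(db, "duplicates"), "C6H12O6")
  expect_equal(attr(db, "invalid"), "NotAFormula123x")
  expect_equal(as.integer(parse_formula(db$formula[1])), c(6L, 12L, 6L))
})

test_that("results tables round-trip within 1e-9 with stable ordering", {
  rec <- data.frame(formula = c("C2H5NO2", "C6H12O6", "C3H7NO2"),
                    adduct = "+H", is_decoy = FALSE,
                    rho_spatial = c(0.1, 0.923456789123, 0.5),
                    rho_spectral = 0.5, rho_chaos = 0.25,
                    mz_error_abs = 0.9999991234, mz_error_rel = 1,
                    msm = 0.0125, ml_score = c(0.7, 0.2, 0.3),
                    fdr_raw = 0.05, fdr = c(0.02439024390244, 0.1, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(rec, path)
  back <- read_results_table(path)
  expect_equal(back$formula, sort(rec$formula))   # bit-stable ordering
  o <- match(back$formula, rec$formula)
  for (col in c("rho_spatial", "ml_score", "fdr", "mz_error_abs")) {
    expect_equal(back[[col]], rec[[col]][o], tolerance = 1e-9)
  }
  # empty record list -> header-only file
  write_results_table(rec[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_results_table(path)), 0L)
})
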