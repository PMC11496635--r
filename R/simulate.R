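# Synthetic centroided imaging-MS datasets with planted ground truth, so
# every pipeline stage is testable offline. The generator emulates
# per-pixel centroided spectra containing planted ions with T isotopic
# peaks at theoretical m/z jittered within a ppm tolerance, spatially
# structured intensity images (smooth random blobs), uniform-random noise
# peaks, and optional profile-mode peak shoulders.

#' Toy molecular database
#'
#' Thirty small metabolites with HMDB-style subclass / parent-class labels,
#' used as the annotation database for simulations and examples.
#'
#' @return data.frame with columns `formula`, `name`, `subclass`,
#'   `parent_class`.
#' @export
toy_molecule_db <- function() {
  db <- rbind(
    c("C6H12O6",      "Hexose",               "Monosaccharides",      "Carbohydrates"),
    c("C12H22O11",    "Disaccharide",         "Disaccharides",        "Carbohydrates"),
    c("C6H14O6",      "Hexitol",              "Sugar alcohols",       "Carbohydrates"),
    c("C5H10O5",      "Pentose",              "Monosaccharides",      "Carbohydrates"),
    c("C3H7NO2",      "Alanine",              "Amino acids",          "Amino acids and peptides"),
    c("C5H9NO4",      "Glutamate",            "Amino acids",          "Amino acids and peptides"),
    c("C6H14N4O2",    "Arginine",             "Amino acids",          "Amino acids and peptides"),
    c("C9H11NO2",     "Phenylalanine",        "Amino acids",          "Amino acids and peptides"),
    c("C11H12N2O2",   "Tryptophan",           "Amino acids",          "Amino acids and peptides"),
    c("C4H9NO3",      "Threonine",            "Amino acids",          "Amino acids and peptides"),
    c("C16H32O2",     "Palmitic acid",        "Fatty acids",          "Fatty acyls"),
    c("C18H34O2",     "Oleic acid",           "Fatty acids",          "Fatty acyls"),
    c("C18H36O2",     "Stearic acid",         "Fatty acids",          "Fatty acyls"),
    c("C20H32O2",     "Arachidonic acid",     "Fatty acids",          "Fatty acyls"),
    c("C14H28O2",     "Myristic acid",        "Fatty acids",          "Fatty acyls"),
    c("C40H80NO8P",   "PC 32:0",              "Glycerophosphocholines","Glycerophospholipids"),
    c("C42H82NO8P",   "PC 34:1",              "Glycerophosphocholines","Glycerophospholipids"),
    c("C39H76NO8P",   "PE 34:0",              "Glycerophosphoethanolamines", "Glycerophospholipids"),
    c("C41H78NO8P",   "PE 36:1",              "Glycerophosphoethanolamines", "Glycerophospholipids"),
    c("C43H81NO13P",  "SM-like lipid",        "Phosphosphingolipids", "Sphingolipids"),
    c("C10H16N5O13P3","ATP",                  "Purine nucleotides",   "Nucleotides"),
    c("C10H14N5O7P",  "AMP",                  "Purine nucleotides",   "Nucleotides"),
    c("C9H13N3O5",    "Cytidine",             "Pyrimidine nucleosides","Nucleosides"),
    c("C10H12N4O5",   "Inosine",              "Purine nucleosides",   "Nucleosides"),
    c("C7H15NO3",     "Carnitine",            "Carnitines",           "Fatty acyls"),
    c("C9H17NO4",     "Acetylcarnitine",      "Carnitines",           "Fatty acyls"),
    c("C4H6O4",       "Succinate",            "Dicarboxylic acids",   "Carboxylic acids"),
    c("C6H8O7",       "Citrate",              "Tricarboxylic acids",  "Carboxylic acids"),
    c("C4H6O5",       "Malate",               "Dicarboxylic acids",   "Carboxylic acids"),
    c("C5H11NO2S",    "Methionine",           "Amino acids",          "Amino acids and peptides"))
  out <- as.data.frame(db, stringsAsFactors = FALSE)
  names(out) <- c("formula", "name", "subclass", "parent_class")
  out
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic acquisition: a 32 x 32 pixel
#' grid, 15 of the 30 toy-database molecules planted as `+H` ions with
#' 4-peak isotope patterns, 0.5 ppm Gaussian m/z jitter (well inside the
#' 3 ppm matching tolerance of modern Orbitrap/FTICR acquisitions), 30
#' uniform noise peaks per pixel, and a signal-to-noise ratio of 20.
#'
#' @param grid_shape integer c(rows, cols) of the pixel grid.
#' @param n_planted_molecules molecules planted as true ions.
#' @param db molecular database (default [toy_molecule_db()]).
#' @param target_adducts adducts planted and annotated.
#' @param polarity ionization polarity.
#' @param jitter_ppm sd of the Gaussian m/z jitter, in ppm.
#' @param noise_peaks_per_pixel mean uniform-random noise peaks per pixel.
#' @param snr ratio of planted base-peak intensity to mean noise intensity.
#' @param base_intensity planted principal-isotope intensity scale.
#' @param intensity_noise_sd sd of the per-pixel multiplicative (log-normal)
#'   intensity noise on planted peaks (default 0.1; 0 = exact intensities).
#' @param spatial_pattern `"blob"` (smooth random blob), `"region"` (half-
#'   plane region) or `"uniform"` (whole grid).
#' @param feature_profile `"full"` (all features informative),
#'   `"spectral_only"` (isotope images spatially incoherent) or
#'   `"spatial_only"` (isotope intensity ratios scrambled).
#' @param profile_mode_shoulders expand every peak into a dense cluster of
#'   sub-tolerance-spaced satellites, emulating profile-mode submissions.
#' @param detection_limit_frac detector limit of detection as a fraction of
#'   the mean noise intensity: peaks below it are not centroided (dropped).
#'   Ties planted-ion detectability to the signal-to-noise ratio; zero when
#'   the dataset is generated noise-free.
#' @param n_peaks isotopic peaks per planted ion (default 4).
#' @param mz_range acquisition m/z range.
#' @param seed mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(grid_shape = c(32L, 32L),
                              n_planted_molecules = 15L,
                              db = toy_molecule_db(),
                              target_adducts = "+H",
                              polarity = "positive",
                              jitter_ppm = 0.5,
                              noise_peaks_per_pixel = 30,
                              snr = 20,
                              base_intensity = 100,
                              intensity_noise_sd = 0.1,
                              spatial_pattern = c("blob", "region", "uniform"),
                              feature_profile = c("full", "spectral_only",
                                                  "spatial_only"),
                              profile_mode_shoulders = FALSE,
                              detection_limit_frac = 0.3,
                              n_peaks = 4L,
                              mz_range = c(70, 1000),
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_planted_molecules >= 0, noise_peaks_per_pixel >= 0, snr > 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_planted_molecules = as.integer(n_planted_molecules),
                 db = db, target_adducts = target_adducts,
                 polarity = polarity, jitter_ppm = jitter_ppm,
                 noise_peaks_per_pixel = noise_peaks_per_pixel, snr = snr,
                 base_intensity = base_intensity,
                 intensity_noise_sd = intensity_noise_sd,
                 spatial_pattern = match.arg(spatial_pattern),
                 feature_profile = match.arg(feature_profile),
                 profile_mode_shoulders = isTRUE(profile_mode_shoulders),
                 detection_limit_frac = detection_limit_frac,
                 n_peaks = as.integer(n_peaks), mz_range = mz_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Smooth random blob template on the grid: sum of Gaussian bumps,
# thresholded to a mask, intensities normalized to max 1.
blob_template <- function(nr, nc, n_bumps = 3L) {
  cx <- stats::runif(n_bumps, 1, nc)
  cy <- stats::runif(n_bumps, 1, nr)
  sigma <- stats::runif(n_bumps, min(nr, nc) / 8, min(nr, nc) / 4)
  g <- matrix(0, nr, nc)
  for (k in seq_len(n_bumps)) {
    dx <- outer(rep(1, nr), (seq_len(nc) - cx[k])^2)
    dy <- outer((seq_len(nr) - cy[k])^2, rep(1, nc))
    g <- g + exp(-(dx + dy) / (2 * sigma[k]^2))
  }
  g <- g / max(g)
  g[g < stats::quantile(g, 0.6)] <- 0
  g
}

make_template <- function(pattern, nr, nc) {
  switch(pattern,
         blob = blob_template(nr, nc),
         region = {
           g <- matrix(0, nr, nc)
           g[, seq_len(ceiling(nc / 2))] <- 1
           g
         },
         uniform = matrix(1, nr, nc))
}

#' Generate a synthetic centroided dataset with planted ground truth
#'
#' @param cfg a [simulation_config()].
#' @return List with `dataset` (a [centroided_dataset()]) and `truth`
#'   (planted `(formula, adduct)` table with per-ion SNR, plus per-ion
#'   spatial masks and the config).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (nrow(cfg$db) == 0L) stop("empty molecular database")
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  np <- nr * nc
  noise_scale <- cfg$base_intensity / cfg$snr

  with_seed(derive_seed(cfg$seed, "dataset"), {
    planted_idx <- sort(resample(seq_len(nrow(cfg$db)),
                                 min(cfg$n_planted_molecules, nrow(cfg$db))))
    planted <- expand.grid(formula = cfg$db$formula[planted_idx],
                           adduct = cfg$target_adducts,
                           stringsAsFactors = FALSE)
    pixel_mz <- vector("list", np)
    pixel_int <- vector("list", np)
    for (p in seq_len(np)) {
      pixel_mz[[p]] <- numeric(0)
      pixel_int[[p]] <- numeric(0)
    }
    masks <- vector("list", nrow(planted))
    snrs <- numeric(nrow(planted))

    for (k in seq_len(nrow(planted))) {
      ion <- ion_formula(planted$formula[k], planted$adduct[k], cfg$polarity)
      pat <- theoretical_pattern(ion$composition, cfg$n_peaks, ion$charge)
      template <- make_template(cfg$spatial_pattern, nr, nc)
      masks[[k]] <- template > 0
      amp <- cfg$base_intensity * exp(stats::rnorm(1, 0, 0.3))
      snrs[k] <- amp / noise_scale
      rel <- pat$rel_intensities
      if (cfg$feature_profile == "spatial_only") {
        rel <- rep(mean(rel), length(rel))   # scramble spectral signature
      }
      for (i in seq_along(pat$mzs)) {
        tmpl_i <- template
        if (cfg$feature_profile == "spectral_only" && i > 1L) {
          tmpl_i <- make_template(cfg$spatial_pattern, nr, nc)  # incoherent
        }
        hit <- which(tmpl_i > 0)
        if (!length(hit)) next
        jit <- stats::rnorm(length(hit), 0, cfg$jitter_ppm) / 1e6
        mzs <- pat$mzs[i] * (1 + jit)
        ints <- amp * rel[i] * tmpl_i[hit] *
          exp(stats::rnorm(length(hit), 0, cfg$intensity_noise_sd))
        for (j in seq_along(hit)) {
          p <- hit[j]
          pixel_mz[[p]] <- c(pixel_mz[[p]], mzs[j])
          pixel_int[[p]] <- c(pixel_int[[p]], ints[j])
        }
      }
    }

    # uniform-random noise peaks (decoy-matchable by construction)
    for (p in seq_len(np)) {
      n_noise <- stats::rpois(1, cfg$noise_peaks_per_pixel)
      if (n_noise > 0) {
        pixel_mz[[p]] <- c(pixel_mz[[p]],
                           stats::runif(n_noise, cfg$mz_range[1], cfg$mz_range[2]))
        pixel_int[[p]] <- c(pixel_int[[p]],
                            stats::rexp(n_noise, 1 / noise_scale))
      }
    }

    if (cfg$profile_mode_shoulders) {
      for (p in seq_len(np)) {
        mz0 <- pixel_mz[[p]]; int0 <- pixel_int[[p]]
        if (!length(mz0)) next
        sat_mz <- c(); sat_int <- c()
        for (off in c(-3, -2, -1, 1, 2, 3)) {
          sat_mz <- c(sat_mz, mz0 * (1 + off * 0.8e-6))
          sat_int <- c(sat_int, int0 * 0.6^abs(off))
        }
        pixel_mz[[p]] <- c(mz0, sat_mz)
        pixel_int[[p]] <- c(int0, sat_int)
      }
    }

    # detector limit of detection: peaks below a fraction of the mean noise
    # intensity are never centroided (zero when generating noise-free data)
    lod <- if (cfg$noise_peaks_per_pixel > 0) {
      cfg$detection_limit_frac * noise_scale
    } else 0
    spectra <- lapply(seq_len(np), function(p) {
      keep <- pixel_int[[p]] >= lod
      centroided_spectrum(pixel_mz[[p]][keep], pixel_int[[p]][keep])
    })
    coords <- expand.grid(x = 0:(nc - 1L), y = 0:(nr - 1L))
    ds <- centroided_dataset(spectra, coords[, c("x", "y")],
                             polarity = cfg$polarity,
                             mz_min = cfg$mz_range[1],
                             mz_max = cfg$mz_range[2],
                             metadata = list(simulated = TRUE,
                                             seed = cfg$seed))
    truth <- planted
    truth$snr <- snrs
    list(dataset = ds,
         truth = list(planted = truth, masks = masks, config = cfg))
  })
}

#' Generate a feature-level corpus with a planted informativeness profile
#'
#' Draws per-dataset tables of the five ion features directly, with a known
#' separation structure: informative features are Beta-distributed with
#' targets shifted above decoys by `separation`; uninformative features are
#' identically distributed for both. This isolates the ranking model from
#' the image-level simulation, so feature-importance recovery and
#' cross-validation behaviour can be tested under exact control.
#'
#' @param n_datasets number of datasets.
#' @param n_targets,n_decoys ions per dataset.
#' @param informative character vector of informative feature names
#'   (subset of the five; default all five).
#' @param separation mean shift between target and decoy informative
#'   features on the `[0, 1]` scale (default 0.5).
#' @param contexts context labels cycled over datasets.
#' @param seed master integer seed.
#' @return List with `corpus` (named list of data.frames with the five
#'   features + `is_decoy`) and `contexts` (per-dataset labels).
#' @export
generate_feature_corpus <- function(n_datasets, n_targets = 20L,
                                    n_decoys = 200L,
                                    informative = RANKER_FEATURES,
                                    separation = 0.5,
                                    contexts = "default", seed = 1L) {
  stopifnot(all(informative %in% RANKER_FEATURES), length(informative) >= 1L)
  ids <- sprintf("fc-%03d", seq_len(n_datasets))
  ctx <- rep_len(contexts, n_datasets)
  corpus <- lapply(seq_len(n_datasets), function(i) {
    with_seed(derive_seed(seed, "feature-corpus", ids[i]), {
      n <- n_targets + n_decoys
      is_decoy <- rep(c(FALSE, TRUE), c(n_targets, n_decoys))
      df <- data.frame(is_decoy = is_decoy)
      for (f in RANKER_FEATURES) {
        base <- stats::rbeta(n, 2, 2) * (1 - separation)
        df[[f]] <- if (f %in% informative) {
          base + ifelse(is_decoy, 0, separation)
        } else {
          stats::rbeta(n, 2, 2)
        }
      }
      df[, c(RANKER_FEATURES, "is_decoy")]
    })
  })
  names(corpus) <- ids
  list(corpus = corpus, contexts = ctx)
}

#' Generate a corpus of synthetic datasets across contexts
#'
#' Datasets are spread evenly over the requested context keys; every
#' dataset gets its own derived seed, all recorded in the manifest.
#'
#' @param n_datasets number of datasets (>= 1).
#' @param contexts character vector of context labels to cycle over.
#' @param cfg_template a [simulation_config()] used for every dataset
#'   (its seed field is ignored).
#' @param seed master integer seed.
#' @return List with `datasets` (list of `list(id, context, dataset,
#'   truth)`) and `manifest` (data.frame of id, context, seed).
#' @export
generate_corpus <- function(n_datasets, contexts = "default",
                            cfg_template = NULL, seed = 1L) {
  stopifnot(n_datasets >= 1L)
  if (is.null(cfg_template)) cfg_template <- simulation_config(seed = seed)
  ids <- sprintf("sim-%03d", seq_len(n_datasets))
  ctx <- rep_len(contexts, n_datasets)
  datasets <- vector("list", n_datasets)
  seeds <- integer(n_datasets)
  for (i in seq_len(n_datasets)) {
    seeds[i] <- derive_seed(seed, "corpus", ids[i])
    cfg_i <- cfg_template
    cfg_i$seed <- seeds[i]
    sim <- generate_dataset(cfg_i)
    datasets[[i]] <- list(id = ids[i], context = ctx[i],
                          dataset = sim$dataset, truth = sim$truth)
  }
  list(datasets = datasets,
       manifest = data.frame(id = ids, context = ctx, seed = seeds,
                             stringsAsFactors = FALSE))
}
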