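# Core data types: centroided spectra and datasets, ion images, molecular
# databases, annotation result tables.

#' Construct a centroided spectrum
#'
#' @param mz numeric vector of m/z values. Sorted ascending on construction
#'   (intensities are co-permuted); must be strictly increasing after sorting.
#' @param intensity nonnegative numeric vector, same length as `mz`.
#' @return Object of class `centroided_spectrum` (list with `mz`,
#'   `intensity`).
#' @export
centroided_spectrum <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0),
            !anyNA(mz), !anyNA(intensity))
  if (is.unsorted(mz, strictly = FALSE)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  if (anyDuplicated(mz)) {
    # merge coincident centroids, preserving total intensity
    intensity <- as.vector(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "centroided_spectrum")
}

#' Construct a centroided imaging MS dataset
#'
#' @param spectra list of [centroided_spectrum()] objects, one per pixel.
#' @param coords data.frame with integer columns `x`, `y` (0-based grid
#'   positions, row-major), one row per pixel; rows must be unique.
#' @param polarity `"positive"` or `"negative"`.
#' @param analyzer free-text mass analyzer (e.g. `"Orbitrap"`, `"FTICR"`).
#' @param source free-text ionization source (e.g. `"MALDI"`, `"DESI"`).
#' @param mz_min,mz_max acquisition m/z range.
#' @param metadata named list (organism, kingdom, sample type, project id,
#'   group id, submission day, ...).
#' @param profile_mode_flag `TRUE` when the file declared profile spectra;
#'   quality control decides exclusion, reading never fails on it.
#' @return Object of class `centroided_dataset`.
#' @export
centroided_dataset <- function(spectra, coords,
                               polarity = c("positive", "negative"),
                               analyzer = "Orbitrap", source = "MALDI",
                               mz_min = NULL, mz_max = NULL,
                               metadata = list(), profile_mode_flag = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(is.list(spectra), nrow(coords) == length(spectra),
            all(c("x", "y") %in% names(coords)))
  coords <- data.frame(x = as.integer(coords$x), y = as.integer(coords$y))
  if (anyDuplicated(coords)) stop("duplicate pixel coordinates")
  spectra <- lapply(spectra, function(s) {
    if (inherits(s, "centroided_spectrum")) s
    else centroided_spectrum(s$mz, s$intensity)
  })
  all_mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  structure(list(
    spectra = spectra, coords = coords, polarity = polarity,
    analyzer = analyzer, source = source,
    mz_min = mz_min %||% if (length(all_mz)) min(all_mz) else NA_real_,
    mz_max = mz_max %||% if (length(all_mz)) max(all_mz) else NA_real_,
    metadata = metadata, profile_mode_flag = isTRUE(profile_mode_flag)
  ), class = "centroided_dataset")
}

#' @export
print.centroided_dataset <- function(x, ...) {
  cat("<centroided_dataset> ", length(x$spectra), " pixels, ",
      x$polarity, " mode, ", x$source, "/", x$analyzer,
      ", m/z [", format(x$mz_min), ", ", format(x$mz_max), "]\n", sep = "")
  invisible(x)
}

n_pixels <- function(ds) length(ds$spectra)

#' Classify acquisition geometry as regular or irregular
#'
#' A pixel grid is irregular when the pixel count differs from the product of
#' the numbers of distinct x and y coordinates (i.e. the grid has holes) —
#' used as a tissue-section heuristic in metadata curation. Depends only on
#' the coordinate multiset, not on pixel ordering.
#'
#' @param ds a [centroided_dataset()].
#' @return `"regular"` or `"irregular"`.
#' @export
classify_geometry <- function(ds) {
  nx <- length(unique(ds$coords$x))
  ny <- length(unique(ds$coords$y))
  if (nrow(ds$coords) == nx * ny) "regular" else "irregular"
}

# Flat index of every centroid peak in the dataset, sorted by m/z, so that a
# ppm window lookup for one target m/z is a single binary search instead of a
# per-pixel scan. Cached on the dataset via attribute by callers that loop.
peak_index <- function(ds) {
  mzs <- lapply(ds$spectra, `[[`, "mz")
  n <- lengths(mzs)
  mz <- unlist(mzs, use.names = FALSE)
  intensity <- unlist(lapply(ds$spectra, `[[`, "intensity"), use.names = FALSE)
  pixel <- rep.int(seq_along(ds$spectra), n)
  o <- order(mz)
  list(mz = mz[o], intensity = intensity[o], pixel = pixel[o])
}

get_peak_index <- function(ds) {
  idx <- attr(ds, "peak_index")
  if (is.null(idx)) idx <- peak_index(ds)
  idx
}

#' Attach a cached peak index to a dataset
#'
#' Speeds up repeated [extract_ion_image()] calls (one sorted lookup table
#' for the whole dataset). Purely an optimization; results are identical.
#'
#' @param ds a [centroided_dataset()].
#' @return The dataset with a cached index attribute.
#' @export
index_dataset <- function(ds) {
  attr(ds, "peak_index") <- peak_index(ds)
  ds
}

#' Extract the ion image for a target m/z
#'
#' Per pixel, sums the intensities of all centroid peaks within the closed
#' symmetric relative window `|peak - mz| <= mz * tol_ppm / 1e6`, and records
#' the intensity-weighted mean matched m/z of those peaks (the per-pixel
#' `m_p` used by the m/z-error scores). Pixels with an empty window get
#' intensity 0 and no matched m/z.
#'
#' @param ds a [centroided_dataset()].
#' @param mz target m/z (> 0).
#' @param tol_ppm tolerance in ppm (> 0; default 3).
#' @return Object of class `ion_image`: list with `values` (2-D nonnegative
#'   intensity array over the pixel grid, zero outside the mask), `mask`
#'   (acquired pixels), `pixel_values` (per-pixel intensities in dataset
#'   pixel order) and `matched_mz` (per-pixel weighted matched m/z, `NA`
#'   where nothing matched).
#' @export
extract_ion_image <- function(ds, mz, tol_ppm = 3) {
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0) {
    stop("target mz must be a single positive number")
  }
  stopifnot(tol_ppm > 0)
  idx <- get_peak_index(ds)
  w <- ppm_window(mz, tol_ppm)
  lo <- findInterval(mz - w, idx$mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + w, idx$mz)
  np <- n_pixels(ds)
  values <- numeric(np)
  matched <- rep(NA_real_, np)
  if (hi >= lo) {
    sel <- lo:hi
    pix <- idx$pixel[sel]
    ii <- idx$intensity[sel]
    mm <- idx$mz[sel]
    values_hit <- tapply(ii, pix, sum)
    wsum <- tapply(ii * mm, pix, sum)
    hitpix <- as.integer(names(values_hit))
    values[hitpix] <- as.vector(values_hit)
    pos <- as.vector(values_hit) > 0
    matched[hitpix[pos]] <- as.vector(wsum)[pos] / as.vector(values_hit)[pos]
    # zero-intensity matches: fall back to unweighted mean of matched m/z
    if (any(!pos)) {
      cnt <- tapply(rep(1, length(sel)), pix, sum)
      msum <- tapply(mm, pix, sum)
      matched[hitpix[!pos]] <- as.vector(msum)[!pos] / as.vector(cnt)[!pos]
    }
  }
  as_ion_image(ds, values, matched)
}

# Build the 2-D image representation from per-pixel values.
as_ion_image <- function(ds, pixel_values, matched_mz = NULL) {
  x <- ds$coords$x - min(ds$coords$x)
  y <- ds$coords$y - min(ds$coords$y)
  nr <- max(y) + 1L
  nc <- max(x) + 1L
  values <- matrix(0, nrow = nr, ncol = nc)
  mask <- matrix(FALSE, nrow = nr, ncol = nc)
  ij <- cbind(y + 1L, x + 1L)
  values[ij] <- pixel_values
  mask[ij] <- TRUE
  structure(list(values = values, mask = mask,
                 pixel_values = as.numeric(pixel_values),
                 matched_mz = matched_mz),
            class = "ion_image")
}

#' Read a molecular database from delimited text
#'
#' Expects a TSV/CSV with columns `formula` and `name`; `subclass` and
#' `parent_class` are optional. Rows are deduplicated on `formula` (first
#' occurrence wins); rows whose formula does not parse are collected, not
#' fatal.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return data.frame with columns `formula`, `name`, `subclass`,
#'   `parent_class`; attributes `duplicates` and `invalid` report dropped
#'   rows.
#' @export
read_molecule_database <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!all(c("formula", "name") %in% names(df))) {
    stop("molecule database needs columns 'formula' and 'name'")
  }
  for (col in c("subclass", "parent_class")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  ok <- vapply(df$formula, function(f) {
    !inherits(tryCatch(parse_formula(f), error = identity), "error")
  }, logical(1))
  invalid <- df$formula[!ok]
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df$formula)
  duplicates <- df$formula[dup]
  df <- df[!dup, c("formula", "name", "subclass", "parent_class")]
  rownames(df) <- NULL
  attr(df, "invalid") <- invalid
  attr(df, "duplicates") <- duplicates
  df
}

#' Write an annotation results table as tab-delimited text
#'
#' One row per target ion (decoys included behind `include_decoys`), ordered
#' by (formula, adduct) for bit-stable output. Columns: formula, adduct,
#' is_decoy, rho_spatial, rho_spectral, rho_chaos, mz_error_abs,
#' mz_error_rel, msm, ml_score, fdr_raw, fdr.
#'
#' @param records data.frame of annotation records (as produced by
#'   [annotate_dataset()]).
#' @param path output path.
#' @param include_decoys keep decoy rows (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, include_decoys = FALSE) {
  cols <- c("formula", "adduct", "is_decoy", "rho_spatial", "rho_spectral",
            "rho_chaos", "mz_error_abs", "mz_error_rel", "msm", "ml_score",
            "fdr_raw", "fdr")
  if (nrow(records) == 0L) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    if (!include_decoys) records <- records[!records$is_decoy, , drop = FALSE]
    for (col in setdiff(cols, names(records))) records[[col]] <- NA_real_
    df <- records[order(records$formula, records$adduct), cols, drop = FALSE]
  }
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "is_decoy"
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back an annotation results table
#' @param path path written by [write_results_table()].
#' @return data.frame with numeric score columns.
#' @export
read_results_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = NA)
  for (col in c("rho_spatial", "rho_spectral", "rho_chaos", "mz_error_abs",
                "mz_error_rel", "msm", "ml_score", "fdr_raw", "fdr")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if ("is_decoy" %in% names(df)) df$is_decoy <- as.logical(df$is_decoy)
  df
}
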