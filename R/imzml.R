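# Minimal imzML (processed mode) reader and writer.
#
# The on-disk layout is the standard imzML pair: an XML index file and an
# .ibd binary file opening with a 16-byte UUID, followed by per-spectrum
# m/z and intensity arrays addressed by external offset / array length /
# encoded length cvParams. Both arrays are stored as 64-bit floats so that
# datasets round-trip exactly. Acquisition metadata that imzML has no slot
# for (polarity, analyzer, source, free-form metadata) travels in a JSON
# sidecar next to the file pair.

IMZML_NS <- "http://psi.hupo.org/ms/mzml"

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(imzml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"),
       sidecar = paste0(base, ".meta.json"))
}

#' Write a centroided dataset as an imzML/ibd file pair
#'
#' @param ds a [centroided_dataset()].
#' @param path output path (with or without the `.imzML` extension); the
#'   `.ibd` binary and a `.meta.json` metadata sidecar are written alongside.
#' @param profile_mode declare the spectra as profile instead of centroided
#'   (used by tests and the simulator to emulate mistaken submissions).
#' @return The `.imzML` path, invisibly.
#' @export
write_centroided_dataset <- function(ds, path, profile_mode = FALSE) {
  p <- imzml_paths(path)
  uuid_bytes <- as.raw(with_seed(
    derive_seed(n_pixels(ds), "imzml-uuid",
                format(ds$mz_min, digits = 12)),
    sample(0:255, 16, replace = TRUE)))
  uuid_str <- paste0(
    "{", substr(paste(sprintf("%02x", as.integer(uuid_bytes)), collapse = ""), 1, 8),
    "-", paste(sprintf("%02x", as.integer(uuid_bytes[5:6])), collapse = ""),
    "-", paste(sprintf("%02x", as.integer(uuid_bytes[7:8])), collapse = ""),
    "-", paste(sprintf("%02x", as.integer(uuid_bytes[9:10])), collapse = ""),
    "-", paste(sprintf("%02x", as.integer(uuid_bytes[11:16])), collapse = ""), "}")

  con <- file(p$ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid_bytes, con)
  offset <- 16
  offsets <- vector("list", n_pixels(ds))
  for (i in seq_len(n_pixels(ds))) {
    s <- ds$spectra[[i]]
    n <- length(s$mz)
    writeBin(as.double(s$mz), con, size = 8, endian = "little")
    writeBin(as.double(s$intensity), con, size = 8, endian = "little")
    offsets[[i]] <- list(mz_offset = offset, int_offset = offset + 8 * n, n = n)
    offset <- offset + 16 * n
  }

  spectrum_xml <- vapply(seq_len(n_pixels(ds)), function(i) {
    o <- offsets[[i]]
    sprintf(paste0(
      '    <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">\n',
      '     <scanList count="1">\n',
      '      <scan>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '      </scan>\n',
      '     </scanList>\n',
      '     <binaryDataArrayList count="2">\n',
      '      <binaryDataArray encodedLength="0">\n',
      '       <referenceableParamGroupRef ref="mzArray"/>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
      '       <binary/>\n',
      '      </binaryDataArray>\n',
      '      <binaryDataArray encodedLength="0">\n',
      '       <referenceableParamGroupRef ref="intensityArray"/>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '       <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
      '       <binary/>\n',
      '      </binaryDataArray>\n',
      '     </binaryDataArrayList>\n',
      '    </spectrum>'),
      i, o$n, i - 1L,
      ds$coords$x[i] + 1L, ds$coords$y[i] + 1L,
      o$mz_offset, o$n, 8L * o$n,
      o$int_offset, o$n, 8L * o$n)
  }, character(1))

  spec_type <- if (profile_mode) {
    '   <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  } else {
    '   <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  }
  polarity_cv <- if (ds$polarity == "positive") {
    '   <cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  } else {
    '   <cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  }

  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzML xmlns="', IMZML_NS, '" version="1.1">\n',
    ' <cvList count="2">\n',
    '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
    '  <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    ' </cvList>\n',
    ' <fileDescription>\n',
    '  <fileContent>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>\n',
    spec_type, "\n", polarity_cv, "\n",
    '   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="', uuid_str, '"/>\n',
    '  </fileContent>\n',
    ' </fileDescription>\n',
    ' <referenceableParamGroupList count="2">\n',
    '  <referenceableParamGroup id="mzArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '  </referenceableParamGroup>\n',
    '  <referenceableParamGroup id="intensityArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '  </referenceableParamGroup>\n',
    ' </referenceableParamGroupList>\n',
    ' <softwareList count="1">\n',
    '  <software id="msiannot" version="0.1.0"/>\n',
    ' </softwareList>\n',
    ' <scanSettingsList count="1">\n',
    '  <scanSettings id="scanSettings1">\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="',
    max(ds$coords$x) + 1L, '"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="',
    max(ds$coords$y) + 1L, '"/>\n',
    '  </scanSettings>\n',
    ' </scanSettingsList>\n',
    ' <instrumentConfigurationList count="1">\n',
    '  <instrumentConfiguration id="IC1"/>\n',
    ' </instrumentConfigurationList>\n',
    ' <dataProcessingList count="1">\n',
    '  <dataProcessing id="export">\n',
    '   <processingMethod order="1" softwareRef="msiannot">\n',
    '    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '   </processingMethod>\n',
    '  </dataProcessing>\n',
    ' </dataProcessingList>\n',
    ' <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '   <spectrumList count="', n_pixels(ds), '" defaultDataProcessingRef="export">\n',
    paste(spectrum_xml, collapse = "\n"), "\n",
    '   </spectrumList>\n',
    ' </run>\n',
    '</mzML>\n')
  writeLines(xml, p$imzml, sep = "")

  sidecar <- list(polarity = ds$polarity, analyzer = ds$analyzer,
                  source = ds$source, mz_min = ds$mz_min, mz_max = ds$mz_max,
                  metadata = ds$metadata)
  jsonlite::write_json(sidecar, p$sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(p$imzml)
}

cvparam_value <- function(node, accession) {
  cv <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(cv, "xml_missing")) NA_character_ else xml2::xml_attr(cv, "value")
}

#' Read a centroided imaging MS dataset from an imzML file pair
#'
#' Reads processed- or continuous-mode imzML with external (ibd) binary
#' arrays in 32- or 64-bit float precision. m/z arrays are sorted ascending
#' on read (intensities co-permuted). A profile-mode declaration does not
#' fail the read: the dataset is flagged (`profile_mode_flag`) with a
#' warning, and quality control decides exclusion.
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit next to it; a
#'   `.meta.json` sidecar is honored when present).
#' @return A [centroided_dataset()].
#' @export
read_centroided_dataset <- function(path) {
  p <- imzml_paths(path)
  if (!file.exists(p$imzml)) stop("imzML file not found: ", p$imzml)
  if (!file.exists(p$ibd)) stop("missing ibd binary file: ", p$ibd)
  doc <- xml2::read_xml(p$imzml)
  xml2::xml_ns_strip(doc)

  profile_flag <- length(xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='MS:1000128']")) > 0
  if (profile_flag) {
    warning("dataset declares profile-mode spectra; flagged for QC")
  }
  negative <- length(xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='MS:1000129']")) > 0

  # precision per referenceable param group (64-bit default)
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  precision <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    is32 <- length(xml2::xml_find_all(g, "./cvParam[@accession='MS:1000521']")) > 0
    role <- if (length(xml2::xml_find_all(g, "./cvParam[@accession='MS:1000514']")) > 0) {
      "mz"
    } else if (length(xml2::xml_find_all(g, "./cvParam[@accession='MS:1000515']")) > 0) {
      "intensity"
    } else NA_character_
    precision[[id]] <- list(size = if (is32) 4L else 8L, role = role)
  }

  con <- file(p$ibd, "rb")
  on.exit(close(con), add = TRUE)

  spectra_nodes <- xml2::xml_find_all(doc, "//spectrum")
  spectra <- vector("list", length(spectra_nodes))
  xs <- integer(length(spectra_nodes))
  ys <- integer(length(spectra_nodes))
  for (i in seq_along(spectra_nodes)) {
    sp <- spectra_nodes[[i]]
    xs[i] <- as.integer(cvparam_value(sp, "IMS:1000050"))
    ys[i] <- as.integer(cvparam_value(sp, "IMS:1000051"))
    arrays <- list()
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
      info <- precision[[ref]]
      role <- info$role
      if (is.na(role)) next
      off <- as.numeric(cvparam_value(bda, "IMS:1000102"))
      len <- as.integer(cvparam_value(bda, "IMS:1000103"))
      seek(con, where = off, origin = "start")
      arrays[[role]] <- readBin(con, "double", n = len, size = info$size,
                                endian = "little")
    }
    if (is.null(arrays$mz) || is.null(arrays$intensity)) {
      stop("spectrum ", i, " lacks m/z or intensity array")
    }
    spectra[[i]] <- centroided_spectrum(arrays$mz, arrays$intensity)
  }

  meta <- if (file.exists(p$sidecar)) {
    jsonlite::read_json(p$sidecar, simplifyVector = TRUE)
  } else list()
  centroided_dataset(
    spectra,
    coords = data.frame(x = xs - min(xs), y = ys - min(ys)),
    polarity = meta$polarity %||% if (negative) "negative" else "positive",
    analyzer = meta$analyzer %||% "unknown",
    source = meta$source %||% "unknown",
    mz_min = meta$mz_min, mz_max = meta$mz_max,
    metadata = as.list(meta$metadata %||% list()),
    profile_mode_flag = profile_flag
  )
}
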