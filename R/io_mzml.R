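#' Read a centroided mzML run
#'
#' Parses an mzML file (indexed or plain, zlib-compressed or not, 32- or
#' 64-bit arrays) into one raw point per (spectrum, centroid) pair.
#' Retention times are normalized to minutes on ingest whatever unit the
#' file used; the original unit is recorded in the returned metadata.
#' Profile-mode spectra are rejected outright — the pipeline assumes
#' vendor-side centroiding and never centroids silently.
#'
#' For ms-level > 1 spectra the precursor m/z, precursor intensity and
#' collision energy are copied onto every point of the spectrum; for
#' ms-level 1 those attributes are `NA`.
#'
#' @param path path to an mzML file.
#' @return A list with elements `metadata` ([run_metadata()]) and `points`
#'   ([raw_points()]).
#' @seealso [write_mzml()]
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  unit <- sniff_rt_unit(path)
  ms <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(ms), add = TRUE)
  n <- length(ms)
  run_id <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  if (n == 0L) {
    return(list(metadata = run_metadata(run_id, path, 0L, NA_character_),
                points = raw_points()))
  }
  hd <- mzR::header(ms)
  profile <- which(!is.na(hd$centroided) & !hd$centroided)
  if (length(profile))
    stop("profile-mode spectrum at index ", profile[1],
         ": only centroided data is supported")
  if (any(hd$polarity < 0))
    stop("spectrum at index ", which(hd$polarity < 0)[1],
         " has unknown polarity")
  pol <- ifelse(hd$polarity == 1L, "positive", "negative")
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  counts <- vapply(pk, nrow, integer(1))
  lvl <- rep(as.integer(hd$msLevel), counts)
  is_ms1 <- lvl == 1L
  pmz <- rep(as.numeric(hd$precursorMZ), counts)
  pint <- rep(as.numeric(hd$precursorIntensity), counts)
  ce <- rep(as.numeric(hd$collisionEnergy), counts)
  pmz[is_ms1] <- NA_real_
  pint[is_ms1] <- NA_real_
  ce[is_ms1] <- NA_real_
  mzi <- do.call(rbind, pk)
  pts <- data.frame(
    file_id = NA_integer_,
    ms_level = lvl,
    polarity = rep(pol, counts),
    rt = rep(hd$retentionTime / 60, counts),  # mzR reports seconds
    mz = mzi[, 1],
    intensity = mzi[, 2],
    precursor_mz = pmz,
    precursor_intensity = pint,
    collision_energy = ce,
    stringsAsFactors = FALSE
  )
  meta <- run_metadata(run_id, path, n, unit, unique(pol))
  list(metadata = meta, points = validate_raw_points(pts))
}

# Record the file's native retention-time unit (mzR normalizes to seconds,
# losing that information). Namespace-agnostic lookup of the first
# "scan start time" cvParam.
sniff_rt_unit <- function(path) {
  doc <- xml2::read_xml(path)
  node <- xml2::xml_find_first(
    doc, ".//*[local-name()='cvParam'][@accession='MS:1000016']")
  if (inherits(node, "xml_missing")) return(NA_character_)
  unit <- xml2::xml_attr(node, "unitName")
  if (is.na(unit)) stop("scan start time has no time unit")
  if (unit %in% c("second", "seconds")) return("seconds")
  if (unit %in% c("minute", "minutes")) return("minutes")
  stop("unsupported retention-time unit: ", unit)
}

#' Write raw points to a minimal mzML file
#'
#' Groups points into spectra by (rt, ms-level, polarity, precursor
#' attributes), orders spectra by ascending retention time and peaks by
#' ascending m/z, and emits schema-valid mzML 1.1 with 64-bit uncompressed
#' binary arrays. Retention times are written in minutes. The output is
#' readable by [read_mzml()] and by independent mzML parsers.
#'
#' @param points a [raw_points()] table (all from one run).
#' @param path output file path.
#' @param run_id run identifier written as the mzML run id.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(points, path, run_id = "run0") {
  points <- validate_raw_points(as.data.frame(points))
  if (nrow(points)) {
    if (any(!is.finite(points$mz)))
      stop("points contain non-finite m/z values")
    if (any(points$intensity < 0))
      stop("points contain negative intensities")
  }
  key <- paste(format(points$rt, digits = 17), points$ms_level,
               points$polarity, points$precursor_mz,
               points$precursor_intensity, points$collision_energy,
               sep = "\r")
  groups <- if (nrow(points)) split(seq_len(nrow(points)), key) else list()
  grt <- vapply(groups, function(i) points$rt[i[1]], numeric(1))
  groups <- groups[order(grt)]
  chunks <- character(length(groups))
  for (j in seq_along(groups)) {
    i <- groups[[j]]
    i <- i[order(points$mz[i])]
    chunks[j] <- spectrum_xml(j - 1L, points[i, , drop = FALSE])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(c(mzml_header(run_id, length(groups)), chunks, mzml_footer()),
             con, sep = "")
  invisible(path)
}

b64_doubles <- function(x) {
  # base64_enc line-wraps long output; mzML binary content must be a
  # single unbroken token
  gsub("[\r\n]", "",
       jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                     endian = "little")))
}

binary_array_xml <- function(x, accession, name, unit_attr) {
  enc <- b64_doubles(x)
  paste0(
    '<binaryDataArray encodedLength="', nchar(enc), '">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="', accession, '" name="', name,
    '" value="" ', unit_attr, '/>',
    '<binary>', enc, '</binary></binaryDataArray>')
}

spectrum_xml <- function(index, sp) {
  n <- nrow(sp)
  lvl <- sp$ms_level[1]
  pol <- if (sp$polarity[1] == "positive")
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  prec <- ""
  if (lvl > 1L) {
    prec <- paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.17g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
              sp$precursor_mz[1]),
      sprintf('<cvParam cvRef="MS" accession="MS:1000042" name="peak intensity" value="%.17g" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
              sp$precursor_intensity[1]),
      '</selectedIon></selectedIonList><activation>',
      '<cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation" value=""/>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000045" name="collision energy" value="%.17g" unitCvRef="UO" unitAccession="UO:0000266" unitName="electronvolt"/>',
              sp$collision_energy[1]),
      '</activation></precursor></precursorList>')
  }
  paste0(
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
            index, index + 1L, n),
    sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>', lvl),
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    pol,
    '<scanList count="1">',
    '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    sprintf('<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.17g" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan>',
            sp$rt[1]),
    '</scanList>',
    prec,
    '<binaryDataArrayList count="2">',
    binary_array_xml(sp$mz, "MS:1000514", "m/z array",
                     'unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'),
    binary_array_xml(sp$intensity, "MS:1000515", "intensity array",
                     'unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"'),
    '</binaryDataArrayList></spectrum>')
}

mzml_header <- function(run_id, n_spectra) {
  paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="', run_id, '">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="mzatlas" version="0.1.0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="mzatlas"/>',
    '</software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="DP1">',
    '<processingMethod order="1" softwareRef="mzatlas">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="', run_id, '" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="', n_spectra, '" defaultDataProcessingRef="DP1">')
}

mzml_footer <- function() '</spectrumList></run></mzML>'
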