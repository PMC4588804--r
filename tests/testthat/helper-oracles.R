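# Independent oracles and fixture builders. Everything here is written
# against the *contracts*, not by calling the code paths under test.

# --- random point sets -------------------------------------------------
# Integer-valued intensities: detector counts are integers, and integer
# sums are exact under any floating-point summation order, which the
# conservation checks rely on.
rand_points <- function(n, seed, ms2_frac = 0.2) {
  set.seed(seed)
  lvl <- ifelse(runif(n) < ms2_frac, 2L, 1L)
  raw_points(
    rt = round(runif(n, 0, 20), 4),
    mz = round(runif(n, 80, 1000), 4),
    intensity = sample(0:5000, n, replace = TRUE),
    ms_level = lvl,
    polarity = sample(c("positive", "negative"), n, replace = TRUE),
    precursor_mz = ifelse(lvl > 1L, round(runif(n, 100, 900), 3), NA_real_),
    precursor_intensity = ifelse(lvl > 1L, sample(1:10000, n, TRUE), NA_real_),
    collision_energy = ifelse(lvl > 1L, sample(c(10, 25, 40), n, TRUE), NA_real_)
  )
}

rand_store <- function(n_points, n_files, seed) {
  st <- point_store(paste0("rand", seed))
  set.seed(seed)
  sizes <- as.vector(stats::rmultinom(1, n_points, rep(1, n_files)))
  for (i in seq_len(n_files)) {
    pts <- rand_points(sizes[i], seed * 1000 + i)
    load_run(st, run_metadata(paste0("run", i), paste0("run", i, ".mzML"),
                              n_spectra = sizes[i]), pts)
  }
  st
}

rand_box_query <- function(store, seed, nsteps = 50L,
                           queryType = "XICofFile_mf") {
  set.seed(seed)
  mk <- function(lo, hi) sort(runif(2, lo, hi))
  mzr <- if (runif(1) < 0.8) mk(80, 1000) else c(NULL, NULL)
  rtr <- mk(0, 20)
  args <- list(nsteps = nsteps, queryType = queryType,
               min_rt = rtr[1], max_rt = rtr[2])
  if (length(mzr)) { args$min_mz <- mzr[1]; args$max_mz <- mzr[2] }
  if (runif(1) < 0.5) args$L <- sample(1:2, 1)
  if (runif(1) < 0.3) args$P <- sample(c("positive", "negative"), 1)
  if (runif(1) < 0.5)
    args$fileidlist <- sort(sample(file_ids(store),
                                   sample(length(file_ids(store)), 1)))
  do.call(range_query, args)
}

# --- brute-force slice oracle ------------------------------------------
# Plain per-point predicate over the raw table; no shared code with
# slice_points().
brute_slice <- function(points, q) {
  mz <- points$mz; rt <- points$rt; pmz <- points$precursor_mz
  lvl <- points$ms_level; pol <- points$polarity; fid <- points$file_id
  inr <- function(v, lo, hi)
    (is.null(lo) || (!is.na(v) && v >= lo)) &&
    (is.null(hi) || (!is.na(v) && v <= hi))
  ok <- vapply(seq_len(nrow(points)), function(i) {
    inr(mz[i], q$min_mz, q$max_mz) &&
      inr(rt[i], q$min_rt, q$max_rt) &&
      inr(pmz[i], q$min_precursor_mz, q$max_precursor_mz) &&
      (is.null(q$L) || lvl[i] == q$L) &&
      (is.null(q$P) || pol[i] == q$P) &&
      (is.null(q$fileidlist) || fid[i] %in% q$fileidlist)
  }, logical(1))
  out <- points[ok, , drop = FALSE]
  out <- out[order(out$file_id, out$rt, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- brute-force binning oracle ----------------------------------------
# Assigns each in-range point to floor((v - lo) / width) by an explicit
# loop and accumulates.
brute_bins <- function(values, weights, lo, hi, nsteps) {
  width <- (hi - lo) / nsteps
  out <- numeric(nsteps)
  for (i in seq_along(values)) {
    v <- values[i]
    if (v < lo || v > hi) next
    j <- if (v == hi) nsteps else floor((v - lo) / width) + 1
    if (j > nsteps) j <- nsteps
    out[j] <- out[j] + weights[i]
  }
  out
}

# --- independent minimal mzML fixture writer and parser ----------------
# Both are deliberately separate implementations from the package's
# writer/reader (string templates + base64 here vs mzR there), so
# read/write tests are two-sided.
fixture_mzml <- function(path, spectra, unit = "minute", profile = FALSE) {
  enc <- function(x) gsub("[\r\n]", "", jsonlite::base64_enc(
    writeBin(as.numeric(x), raw(), size = 8, endian = "little")))
  mode_cv <- if (profile)
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  uo <- if (unit == "minute") "UO:0000031" else "UO:0000010"
  body <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      mode_cv,
      '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
      '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.17g" unitCvRef="UO" unitAccession="', uo, '" unitName="', unit, '"/></scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/><binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/><binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(s$mz), s$rt,
      nchar(enc(s$mz)), enc(s$mz), nchar(enc(s$intensity)), enc(s$intensity))
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="fixture">',
    '<cvList count="2"><cv id="MS" fullName="MS" URI="x"/><cv id="UO" fullName="UO" URI="x"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="fx" version="0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="DP1"><processingMethod order="1" softwareRef="fx"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="fixture" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="DP1">', length(spectra)),
    body,
    '</spectrumList></run></mzML>'), path)
  path
}

# xml2-based parser: decodes spectra of an (uncompressed, 64-bit) mzML
# written by the package, independent of mzR.
independent_parse_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  specs <- xml2::xml_find_all(doc, ".//*[local-name()='spectrum']")
  rows <- lapply(specs, function(sp) {
    rt_node <- xml2::xml_find_first(
      sp, ".//*[local-name()='cvParam'][@accession='MS:1000016']")
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    if (xml2::xml_attr(rt_node, "unitName") %in% c("second", "seconds"))
      rt <- rt / 60
    arrays <- xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']")
    dec <- function(arr) {
      b64 <- xml2::xml_text(
        xml2::xml_find_first(arr, ".//*[local-name()='binary']"))
      if (!nzchar(b64)) return(numeric())
      readBin(jsonlite::base64_dec(b64), "double",
              n = nchar(b64), size = 8, endian = "little")
    }
    is_mz <- vapply(arrays, function(a) {
      !inherits(xml2::xml_find_first(
        a, ".//*[local-name()='cvParam'][@accession='MS:1000514']"),
        "xml_missing")
    }, logical(1))
    mz <- dec(arrays[is_mz][[1]])
    inten <- dec(arrays[!is_mz][[1]])
    lvl <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sp, ".//*[local-name()='cvParam'][@accession='MS:1000511']"), "value"))
    if (length(mz))
      data.frame(rt = rt, mz = mz, intensity = inten, ms_level = lvl)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(rt = numeric(), mz = numeric(), intensity = numeric(),
                      ms_level = integer())
  out[order(out$rt, out$mz), , drop = FALSE]
}

# --- misc ---------------------------------------------------------------
sorted_point_key <- function(pts) {
  o <- order(pts$rt, pts$mz, pts$intensity)
  pts[o, c("rt", "mz", "intensity", "ms_level", "polarity")]
}

# A chromatogram object sampled from an analytic curve (for quadrature
# and fitting tests that need a known functional form).
sampled_chromatogram <- function(f, lo, hi, nsteps) {
  width <- (hi - lo) / nsteps
  centers <- lo + (seq_len(nsteps) - 0.5) * width
  structure(list(file_id = 0L, axis = "rt", bin_centers = centers,
                 intensity = f(centers), bin_width = width,
                 query = NULL),
            class = c("chromatogram", "mz_histogram"))
}

default_sim_compounds <- function(n = 5, seed = 1) {
  set.seed(seed)
  mzs <- seq(120, 520, length.out = n) + round(runif(n, 0, 0.4), 4)
  lapply(seq_len(n), function(i)
    sim_compound(paste0("cpd_", i), mzs[i],
                 rt_center = 1 + (i - 1) * (8 / max(n - 1, 1)),
                 rt_sigma = 0.1, peak_height = 10^runif(1, 4.5, 5.5)))
}
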