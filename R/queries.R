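#' Chromatograms and spectra: the two-step histogram query
#'
#' Both operations follow the same two-step plan: first slice raw points
#' from the store by the query's ranges, then aggregate them into a
#' histogram — on the retention-time axis for a chromatogram ([xic()]),
#' on the m/z axis for a spectrum ([mass_spectrum()]).
#'
#' The binning domain `[min, max]` is partitioned into `nsteps` equal
#' half-open bins `[lo, hi)`, the final bin closed so points exactly at the
#' domain maximum are not dropped; a point on an interior bin edge belongs
#' to exactly one bin. Within each bin intensities are summed (or the
#' maximum taken, if `aggregation = "max"`), adding points in ascending
#' (rt, mz) order so results are floating-point reproducible. Bin centers
#' are reported. Files with no in-range points yield an all-zero histogram,
#' never an absent entry — downstream feature tables need rectangular
#' output.
#'
#' @param store a [point_store()].
#' @param q a [range_query()] with `queryType = "XICofFile_mf"` for
#'   [xic()], `"SpectrumOfFile"` for [mass_spectrum()]. The binning domain
#'   is `min_rt`/`max_rt` (resp. `min_mz`/`max_mz`); when omitted it is
#'   derived from the store extent on that axis.
#' @return A named list, one [chromatogram] (resp. `mass_spectrum`) per
#'   requested file, names are file ids.
#' @examples
#' st <- point_store()
#' load_run(st, run_metadata("r", "r.mzML", 1),
#'          raw_points(rt = 5, mz = 100, intensity = 10))
#' xs <- xic(st, range_query(min_rt = 0, max_rt = 10, nsteps = 1))
#' xs[["0"]]$intensity  # 10, conserved in a single bin
#' @name queries
NULL

#' @rdname queries
#' @export
xic <- function(store, q) {
  if (q$queryType != "XICofFile_mf")
    stop("xic requires queryType 'XICofFile_mf'")
  histogram_query(store, q, axis = "rt")
}

#' @rdname queries
#' @export
mass_spectrum <- function(store, q) {
  if (q$queryType != "SpectrumOfFile")
    stop("mass_spectrum requires queryType 'SpectrumOfFile'")
  histogram_query(store, q, axis = "mz")
}

histogram_query <- function(store, q, axis) {
  q <- validate_range_query(q)
  fids <- if (!is.null(q$fileidlist)) q$fileidlist else file_ids(store)
  lo <- if (axis == "rt") q$min_rt else q$min_mz
  hi <- if (axis == "rt") q$max_rt else q$max_mz
  if (is.null(lo) || is.null(hi)) {
    v <- store$points[[axis]]
    if (!length(v))
      stop("empty store: supply an explicit ", axis, " binning domain")
    if (is.null(lo)) lo <- min(v)
    if (is.null(hi)) hi <- max(v)
  }
  if (lo >= hi) {
    # degenerate domain: a single bin at lo
    hi <- lo
  }
  out <- lapply(fids, function(fid) {
    qi <- q
    qi$fileidlist <- fid
    pts <- slice_points(store, qi)
    bins <- bin_histogram(pts[[axis]], pts$intensity, lo, hi, q$nsteps,
                          q$aggregation)
    structure(
      list(file_id = fid, axis = axis,
           bin_centers = bins$centers, intensity = bins$value,
           bin_width = bins$width, query = q),
      class = c(if (axis == "rt") "chromatogram" else "mass_spectrum",
                "mz_histogram"))
  })
  stats::setNames(out, as.character(fids))
}

# Half-open equal-width binning with the final bin closed. `values` must
# already be ordered so that within-bin summation order is fixed.
bin_histogram <- function(x, w, lo, hi, nsteps, aggregation = "sum") {
  if (hi <= lo) {
    width <- 0
    idx <- rep(1L, length(x))
    centers <- lo
    nsteps <- 1L
  } else {
    width <- (hi - lo) / nsteps
    idx <- floor((x - lo) / width) + 1L
    idx[x == hi] <- nsteps
    idx[idx > nsteps] <- nsteps  # guard against rounding at the top edge
    centers <- lo + (seq_len(nsteps) - 0.5) * width
  }
  value <- numeric(nsteps)
  if (length(x)) {
    groups <- split(w, factor(idx, levels = seq_len(nsteps)))
    agg <- if (aggregation == "max")
      function(v) if (length(v)) max(v) else 0
    else
      function(v) sum(v)
    value <- vapply(groups, agg, numeric(1), USE.NAMES = FALSE)
  }
  list(centers = centers, value = value, width = width)
}

#' @export
print.mz_histogram <- function(x, ...) {
  cat(sprintf("<%s> file %d: %d bins on %s, total intensity %.6g\n",
              class(x)[1], x$file_id, length(x$bin_centers), x$axis,
              sum(x$intensity)))
  invisible(x)
}

#' @export
as.data.frame.mz_histogram <- function(x, ...) {
  df <- data.frame(file_id = x$file_id, axis_value = x$bin_centers,
                   intensity = x$intensity)
  names(df)[2] <- x$axis
  df
}

#' Export query results as tidy CSV
#'
#' One row per (file, bin): columns `file_id`, `axis_value`, `intensity`.
#'
#' @param results a named list of chromatograms/spectra as returned by
#'   [xic()] or [mass_spectrum()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_query_csv <- function(results, path) {
  rows <- lapply(results, function(h)
    data.frame(file_id = h$file_id, axis_value = h$bin_centers,
               intensity = h$intensity))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
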