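#' Build the range query an atlas entry defines
#'
#' The compound's m/z and tolerance give the m/z window
#' `mz * (1 +/- ppm * 1e-6)` (or `mz +/- mz_tolerance_da` when the entry
#' carries an absolute override); the retention-time bounds give the RT
#' window. Extraction is MS1-only (`L = 1`). When the entry has a
#' polarity, the query filters on it; otherwise both polarities are
#' combined — this changes areas on mixed-polarity runs, so set the
#' entry's polarity whenever the acquisition alternates modes.
#'
#' @param entry a `compound_entry` (see [put_compound()]).
#' @param fileidlist file ids to query, or `NULL` for all.
#' @param nsteps histogram bins for the RT window.
#' @return A [range_query()].
#' @export
compound_query <- function(entry, fileidlist = NULL, nsteps = 2000L) {
  stopifnot(inherits(entry, "compound_entry"))
  if (!is.null(entry$mz_tolerance_da)) {
    dmz <- entry$mz_tolerance_da
  } else {
    dmz <- entry$mz * entry$mz_tolerance_ppm * 1e-6
  }
  range_query(L = 1L, P = entry$polarity, fileidlist = fileidlist,
              min_mz = entry$mz - dmz, max_mz = entry$mz + dmz,
              min_rt = entry$rt_min, max_rt = entry$rt_max,
              nsteps = nsteps, queryType = "XICofFile_mf")
}

# Median spacing between consecutive MS1 scan times, per store (pooled
# over the requested files). Used to pick a default bin count that puts
# roughly one scan per bin.
estimate_scan_interval <- function(store, fids = NULL) {
  p <- store$points
  if (!is.null(fids)) p <- p[p$file_id %in% fids, , drop = FALSE]
  rts <- sort(unique(p$rt[p$ms_level == 1L]))
  if (length(rts) < 2) return(NA_real_)
  stats::median(diff(rts))
}

default_nsteps <- function(store, fids, rt_window) {
  dt <- estimate_scan_interval(store, fids)
  if (!is.na(dt) && dt > 0)
    max(1L, as.integer(round(rt_window / dt)))
  else
    100L
}

#' Extract per-compound chromatograms for an atlas dictionary
#'
#' One XIC per compound x file via [xic()], using each compound's m/z and
#' RT window. All-zero chromatograms (compound absent from a file) are
#' retained so results stay rectangular.
#'
#' By default `nsteps` is chosen per compound as the number of scans the
#' RT window spans (window width divided by the store's median MS1 scan
#' spacing), i.e. one bin per scan, so the binned XIC is a faithful
#' sampled curve and its trapezoidal integral recovers the physical area
#' in counts x minutes. Finer bins than the scan spacing would leave empty
#' bins and bias integrals low; coarser bins stack scans and bias them
#' high. With the acquisition rates the simulator emulates (0.005 min
#' scans, 6-second peaks) the default is well over 100 bins per window.
#'
#' @param store a [point_store()].
#' @param atlas an [atlas_store()].
#' @param dict_id dictionary whose compounds to extract.
#' @param fileidlist file ids, or `NULL` for every registered file.
#' @param nsteps bins per RT window; `NULL` for the default above.
#' @return Nested named list: `result[[compound_id]][[file_id]]` is a
#'   [chromatogram][queries].
#' @export
extract_xic <- function(store, atlas, dict_id, fileidlist = NULL,
                        nsteps = NULL) {
  d <- get_dict(atlas, dict_id)
  fids <- if (!is.null(fileidlist)) as.integer(fileidlist)
          else file_ids(store)
  out <- lapply(d$compound_ids, function(cid) {
    e <- get_compound(atlas, cid)
    ns <- if (!is.null(nsteps)) as.integer(nsteps)
          else default_nsteps(store, fids, e$rt_max - e$rt_min)
    q <- compound_query(e, fileidlist = fids, nsteps = ns)
    xic(store, q)
  })
  stats::setNames(out, d$compound_ids)
}

#' Integrate a chromatographic peak
#'
#' Integrates the binned XIC over `[rt_min, rt_max]` by the trapezoidal
#' rule on the bin centers inside the window, extended by a half-bin
#' rectangle at each end so the quadrature covers the full window (a
#' constant signal `h` over a window of width `w` integrates to exactly
#' `h * w`). Intensities are non-negative, so enlarging the window never
#' decreases the area.
#'
#' @param chrom a [chromatogram][queries].
#' @param rt_min,rt_max integration window, minutes; defaults to the
#'   chromatogram's full domain. The window must overlap the domain.
#' @return Peak area in counts x minutes (0 for an empty window).
#' @export
integrate_peak <- function(chrom, rt_min = NULL, rt_max = NULL) {
  stopifnot(inherits(chrom, "mz_histogram"))
  ctr <- chrom$bin_centers
  w <- chrom$bin_width
  dom_lo <- ctr[1] - w / 2
  dom_hi <- ctr[length(ctr)] + w / 2
  if (is.null(rt_min)) rt_min <- dom_lo
  if (is.null(rt_max)) rt_max <- dom_hi
  if (rt_min > rt_max) stop("invalid window: rt_min > rt_max")
  if (rt_max < dom_lo || rt_min > dom_hi)
    stop("invalid window: [", rt_min, ", ", rt_max,
         "] lies outside the chromatogram domain [", dom_lo, ", ",
         dom_hi, "]")
  inside <- ctr >= rt_min & ctr <= rt_max
  if (!any(inside)) return(0)
  x <- ctr[inside]
  y <- chrom$intensity[inside]
  n <- length(x)
  trap <- if (n > 1) sum((y[-1] + y[-n]) / 2 * diff(x)) else 0
  trap + (y[1] + y[n]) * w / 2
}

#' Fit a Gaussian peak to a chromatogram
#'
#' Least-squares fit of a Gaussian plus constant baseline,
#' `b + A * exp(-(t - mu)^2 / (2 * sigma^2))`, to the binned XIC.
#' Initialization is by moments: `mu` the intensity-weighted mean RT,
#' `sigma` the weighted standard deviation, `A = max - min`,
#' `b = min`. The fit uses Levenberg-Marquardt least squares and is
#' deterministic for a fixed input. Inputs that cannot support a fit
#' (fewer than 5 non-zero bins, or a flat trace) yield
#' `converged = FALSE`, never an error.
#'
#' @param chrom a [chromatogram][queries].
#' @return A list of class `peak_fit`: `amplitude`, `center`, `sigma`
#'   (minutes), `baseline`, `rss`, `converged`.
#' @export
fit_peak <- function(chrom) {
  stopifnot(inherits(chrom, "mz_histogram"))
  x <- chrom$bin_centers
  y <- chrom$intensity
  failed <- structure(list(amplitude = NA_real_, center = NA_real_,
                           sigma = NA_real_, baseline = NA_real_,
                           rss = NA_real_, converged = FALSE),
                      class = "peak_fit")
  if (sum(y > 0) < 5 || max(y) == min(y)) return(failed)
  wsum <- sum(y)
  mu0 <- sum(x * y) / wsum
  sig0 <- sqrt(sum(y * (x - mu0)^2) / wsum)
  if (!is.finite(sig0) || sig0 <= 0) return(failed)
  a0 <- max(y) - min(y)
  b0 <- min(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - m)^2 / (2 * s^2)),
      data = data.frame(x = x, y = y),
      start = list(a = a0, m = mu0, s = sig0, b = b0),
      lower = c(a = 0, m = min(x), s = 1e-12, b = 0),
      upper = c(a = Inf, m = max(x), s = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["a"]), center = unname(cf["m"]),
                 sigma = unname(cf["s"]), baseline = unname(cf["b"]),
                 rss = sum(stats::resid(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv) && cf["s"] > 0),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<peak_fit> A = %.4g at %.4g min, sigma = %.4g min, baseline = %.4g, rss = %.4g\n",
      x$amplitude, x$center, x$sigma, x$baseline, x$rss))
  else cat("<peak_fit> not fittable (converged = FALSE)\n")
  invisible(x)
}

#' Build a compound x file table of peak areas
#'
#' For every compound in the dictionary and every requested file,
#' extracts the XIC over the compound's m/z and RT windows and integrates
#' it over `[rt_min, rt_max]`. Cells with no signal in the window are
#' recorded as 0 and flagged below-detection (the matrix stays
#' rectangular; missing-value modeling is deliberately out of scope).
#'
#' @inheritParams extract_xic
#' @return A list of class `feature_table`: `areas` (matrix, rows =
#'   compounds, columns = files, counts x minutes), `below_detection`
#'   (logical matrix), `compound_ids`, `file_ids`, `provenance` (atlas
#'   dict id + revision, nsteps policy).
#' @export
build_feature_table <- function(store, atlas, dict_id, fileidlist = NULL,
                                nsteps = NULL) {
  d <- get_dict(atlas, dict_id)
  fids <- if (!is.null(fileidlist)) sort(as.integer(fileidlist))
          else file_ids(store)
  xics <- extract_xic(store, atlas, dict_id, fids, nsteps)
  areas <- matrix(0, nrow = length(d$compound_ids), ncol = length(fids),
                  dimnames = list(d$compound_ids, as.character(fids)))
  flag <- matrix(FALSE, nrow = nrow(areas), ncol = ncol(areas),
                 dimnames = dimnames(areas))
  for (cid in d$compound_ids) {
    e <- get_compound(atlas, cid)
    for (fc in as.character(fids)) {
      ch <- xics[[cid]][[fc]]
      areas[cid, fc] <- integrate_peak(ch, e$rt_min, e$rt_max)
      flag[cid, fc] <- max(ch$intensity) == 0
    }
  }
  structure(
    list(areas = areas, below_detection = flag,
         compound_ids = d$compound_ids, file_ids = fids,
         provenance = list(dict_id = d$dict_id, dict_name = d$name,
                           atlas_revision = atlas$revision,
                           nsteps = if (is.null(nsteps)) "auto" else nsteps)),
    class = "feature_table")
}

#' Construct a feature table from a matrix
#'
#' For tables that do not come from [build_feature_table()] — simulated
#' area matrices, imported results — so they can flow into
#' [normalize_table()], [cluster_features()] and [group_test()].
#'
#' @param areas numeric matrix, rows = compounds (rownames used as ids),
#'   columns = files.
#' @param below_detection logical matrix of the same shape (default: all
#'   `FALSE`).
#' @param file_ids integer file ids (default: column names, else
#'   `0:(ncol-1)`).
#' @param provenance optional provenance list.
#' @return A `feature_table`.
#' @export
feature_table <- function(areas, below_detection = NULL, file_ids = NULL,
                          provenance = list()) {
  areas <- as.matrix(areas)
  if (is.null(rownames(areas)))
    rownames(areas) <- paste0("compound_", seq_len(nrow(areas)))
  if (is.null(file_ids)) {
    file_ids <- if (!is.null(colnames(areas)))
      suppressWarnings(as.integer(colnames(areas)))
    else seq_len(ncol(areas)) - 1L
    if (any(is.na(file_ids))) file_ids <- seq_len(ncol(areas)) - 1L
  }
  colnames(areas) <- as.character(file_ids)
  if (is.null(below_detection))
    below_detection <- matrix(FALSE, nrow(areas), ncol(areas),
                              dimnames = dimnames(areas))
  stopifnot(all(dim(below_detection) == dim(areas)))
  structure(list(areas = areas, below_detection = below_detection,
                 compound_ids = rownames(areas),
                 file_ids = as.integer(file_ids),
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  src <- if (!is.null(x$provenance$dict_id))
    sprintf(", atlas '%s' (rev %s)", x$provenance$dict_id,
            x$provenance$atlas_revision)
  else ""
  cat(sprintf("<feature_table> %d compound(s) x %d file(s)%s\n",
              nrow(x$areas), ncol(x$areas), src))
  print(x$areas, ...)
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(
    compound_id = rep(x$compound_ids, times = length(x$file_ids)),
    file_id = rep(x$file_ids, each = length(x$compound_ids)),
    area = as.vector(x$areas),
    below_detection = as.vector(x$below_detection))
}

#' Write a feature table to CSV
#'
#' @param ft a [build_feature_table()] result.
#' @param path output path.
#' @param format `"wide"` (compounds x files matrix) or `"long"` (tidy:
#'   compound_id, file_id, area, below_detection).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(compound_id = ft$compound_ids, ft$areas,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  }
  invisible(path)
}
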