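#' Create an in-memory point store
#'
#' The point store houses every loaded run as one flat collection of
#' nine-attribute raw points — the desk-scale analogue of a large
#' multidimensional array database, where each run occupies one slice and
#' queries slice points out by ranges on any attribute.
#'
#' File ids are assigned sequentially from 0 at load time and are unique
#' within a store; every point's `file_id` refers to a registered run.
#'
#' @param arrayname name of the store (used in query provenance).
#' @return An object of class `point_store` (environment-backed, mutable).
#' @examples
#' st <- point_store("demo")
#' load_run(st, run_metadata("r1", "r1.mzML", 1),
#'          raw_points(rt = 1, mz = 100, intensity = 10))
#' n_points(st)
#' @export
point_store <- function(arrayname = "points") {
  st <- new.env(parent = emptyenv())
  st$arrayname <- as.character(arrayname)
  st$runs <- list()        # file_id (as character) -> run_metadata
  st$points <- raw_points()
  st$next_id <- 0L
  class(st) <- "point_store"
  st
}

#' @export
print.point_store <- function(x, ...) {
  cat(sprintf("<point_store '%s'> %d run(s), %d point(s)\n",
              x$arrayname, length(x$runs), nrow(x$points)))
  invisible(x)
}

#' Number of points / registered runs in a store
#' @param store a [point_store()].
#' @return integer count.
#' @export
n_points <- function(store) nrow(store$points)

#' @rdname n_points
#' @export
file_ids <- function(store) as.integer(names(store$runs))

#' Load one run into a point store
#'
#' Assigns a fresh sequential `file_id`, stamps it on every point and
#' registers the run metadata. The load is atomic: on any validation
#' failure the store is unchanged. A `source_path` may be registered only
#' once per store — one run maps to exactly one slice.
#'
#' @param store a [point_store()].
#' @param metadata a [run_metadata()].
#' @param points a [raw_points()] table (the `file_id` column is ignored
#'   and overwritten).
#' @return The assigned integer `file_id`.
#' @export
load_run <- function(store, metadata, points) {
  stopifnot(inherits(store, "point_store"), inherits(metadata, "run_metadata"))
  points <- validate_raw_points(as.data.frame(points))
  existing <- vapply(store$runs, function(r) r$source_path, character(1))
  if (!is.na(metadata$source_path) && metadata$source_path %in% existing)
    stop("conflict: source_path already loaded: ", metadata$source_path)
  fid <- store$next_id
  if (nrow(points)) points$file_id <- fid
  store$points <- rbind(store$points, points)
  store$runs[[as.character(fid)]] <- metadata
  store$next_id <- fid + 1L
  fid
}

#' Ingest mzML files into a store
#'
#' Convenience wrapper: [read_mzml()] then [load_run()] for each path.
#'
#' @param store a [point_store()].
#' @param paths mzML file paths.
#' @return Integer vector of assigned file ids (named by path).
#' @export
ingest_mzml <- function(store, paths) {
  ids <- vapply(paths, function(p) {
    run <- read_mzml(p)
    load_run(store, run$metadata, run$points)
  }, integer(1))
  stats::setNames(as.integer(ids), paths)
}

#' Build a range query
#'
#' A range query carries the user-supplied ranges and aggregation options
#' used both for slicing ([slice_points()]) and for histogram aggregation
#' ([xic()], [mass_spectrum()]). Field names mirror the service API:
#' `L` (ms-level), `P` (polarity), `arrayname`, `fileidlist`, `min_mz`/
#' `max_mz`, `min_rt`/`max_rt`, `nsteps` (default 2000) and `queryType`
#' (`"XICofFile_mf"` for chromatograms on the time axis,
#' `"SpectrumOfFile"` for histograms on the m/z axis). Omitted ranges are
#' unconstrained. Precursor-axis ranges (`min_precursor_mz`, ...) are
#' accepted and filter like any other axis, though ms-level > 1 queries are
#' otherwise unexercised by the extraction pipeline.
#'
#' @param arrayname store name (informational).
#' @param L ms-level to select, or `NULL`.
#' @param P polarity (`"positive"`/`"negative"`), or `NULL`.
#' @param fileidlist integer vector of file ids, or `NULL` for all files.
#' @param min_mz,max_mz m/z range (Thomson), closed interval.
#' @param min_rt,max_rt retention-time range (minutes), closed interval.
#' @param min_precursor_mz,max_precursor_mz,min_precursor_intensity,max_precursor_intensity,min_collision_energy,max_collision_energy
#'   reserved precursor axes; filter exactly like the other ranges.
#' @param nsteps number of histogram bins (>= 1).
#' @param queryType `"XICofFile_mf"` or `"SpectrumOfFile"`.
#' @param aggregation per-bin aggregation, `"sum"` (default) or `"max"`.
#' @return A list of class `range_query`.
#' @export
range_query <- function(arrayname = NULL, L = NULL, P = NULL,
                        fileidlist = NULL,
                        min_mz = NULL, max_mz = NULL,
                        min_rt = NULL, max_rt = NULL,
                        min_precursor_mz = NULL, max_precursor_mz = NULL,
                        min_precursor_intensity = NULL,
                        max_precursor_intensity = NULL,
                        min_collision_energy = NULL,
                        max_collision_energy = NULL,
                        nsteps = 2000L,
                        queryType = "XICofFile_mf",
                        aggregation = "sum") {
  q <- list(arrayname = arrayname, L = L, P = P,
            fileidlist = if (!is.null(fileidlist)) as.integer(fileidlist),
            min_mz = min_mz, max_mz = max_mz,
            min_rt = min_rt, max_rt = max_rt,
            min_precursor_mz = min_precursor_mz,
            max_precursor_mz = max_precursor_mz,
            min_precursor_intensity = min_precursor_intensity,
            max_precursor_intensity = max_precursor_intensity,
            min_collision_energy = min_collision_energy,
            max_collision_energy = max_collision_energy,
            nsteps = as.integer(nsteps), queryType = queryType,
            aggregation = aggregation)
  class(q) <- "range_query"
  validate_range_query(q)
}

validate_range_query <- function(q) {
  if (!q$queryType %in% c("XICofFile_mf", "SpectrumOfFile"))
    stop("unknown queryType: ", q$queryType)
  if (!q$aggregation %in% c("sum", "max"))
    stop("unknown aggregation: ", q$aggregation)
  if (is.na(q$nsteps) || q$nsteps < 1L)
    stop("invalid query: nsteps must be >= 1")
  if (!is.null(q$P) && !q$P %in% c("positive", "negative"))
    stop("invalid query: P must be 'positive' or 'negative'")
  check_range <- function(lo, hi, axis) {
    if (!is.null(lo) && !is.null(hi) && lo > hi)
      stop("invalid query: min > max on ", axis, " axis")
  }
  check_range(q$min_mz, q$max_mz, "mz")
  check_range(q$min_rt, q$max_rt, "rt")
  check_range(q$min_precursor_mz, q$max_precursor_mz, "precursor_mz")
  check_range(q$min_precursor_intensity, q$max_precursor_intensity,
              "precursor_intensity")
  check_range(q$min_collision_energy, q$max_collision_energy,
              "collision_energy")
  q
}

#' Serialize / deserialize a range query as JSON
#'
#' Uses the service API's field names verbatim (`"L"`, `"P"`, `"arrayname"`,
#' `"fileidlist"`, `"max_mz"`, `"min_mz"`, `"min_rt"`, `"max_rt"`,
#' `"nsteps"`, `"queryType"`), so an options object like
#' `{"L":1, "nsteps":2000, "queryType":"XICofFile_mf"}` pastes in directly.
#'
#' @param q a [range_query()].
#' @param json a JSON string (an options object).
#' @return `query_to_json()`: a JSON string. `query_from_json()`: a
#'   [range_query()].
#' @export
query_to_json <- function(q) {
  stopifnot(inherits(q, "range_query"))
  keep <- !vapply(q, is.null, logical(1))
  jsonlite::toJSON(unclass(q)[keep], auto_unbox = TRUE, digits = NA)
}

#' @rdname query_to_json
#' @export
query_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  known <- names(formals(range_query))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown query option(s): ", paste(bad, collapse = ", "),
         " (expected fields like L, P, arrayname, fileidlist, min_mz, ",
         "max_mz, min_rt, max_rt, nsteps, queryType)")
  do.call(range_query, x)
}

#' Slice raw points from a store by ranges
#'
#' Returns exactly the points satisfying every supplied constraint —
#' closed intervals `[min, max]` on the numeric axes, equality on
#' ms-level and polarity, membership for `fileidlist` — ordered by
#' (`file_id`, `rt`, `mz`) ascending. Omitted constraints are
#' unconstrained; slicing a store with no constraints returns every point.
#'
#' @param store a [point_store()].
#' @param q a [range_query()].
#' @return A [raw_points()] table.
#' @export
slice_points <- function(store, q) {
  stopifnot(inherits(store, "point_store"))
  q <- validate_range_query(q)
  p <- store$points
  if (!is.null(q$fileidlist)) {
    unknown <- setdiff(q$fileidlist, file_ids(store))
    if (length(unknown))
      stop("invalid query: unknown file_id ", unknown[1])
  }
  keep <- rep(TRUE, nrow(p))
  rng <- function(keep, v, lo, hi) {
    if (!is.null(lo)) keep <- keep & !is.na(v) & v >= lo
    if (!is.null(hi)) keep <- keep & !is.na(v) & v <= hi
    keep
  }
  keep <- rng(keep, p$mz, q$min_mz, q$max_mz)
  keep <- rng(keep, p$rt, q$min_rt, q$max_rt)
  keep <- rng(keep, p$precursor_mz, q$min_precursor_mz, q$max_precursor_mz)
  keep <- rng(keep, p$precursor_intensity,
              q$min_precursor_intensity, q$max_precursor_intensity)
  keep <- rng(keep, p$collision_energy,
              q$min_collision_energy, q$max_collision_energy)
  if (!is.null(q$L)) keep <- keep & p$ms_level == q$L
  if (!is.null(q$P)) keep <- keep & p$polarity == q$P
  if (!is.null(q$fileidlist)) keep <- keep & p$file_id %in% q$fileidlist
  out <- p[keep, , drop = FALSE]
  out <- out[order(out$file_id, out$rt, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("raw_points", "data.frame")
  out
}

#' Persist / restore a point store on disk
#'
#' The on-disk container is a directory holding `registry.json` (format
#' version, array name, run registry, next file id) and `points.csv` (one
#' row per raw point, nine columns). Plain-text by design so stores are
#' portable and diffable.
#'
#' @param store a [point_store()].
#' @param path directory to write to / read from.
#' @return `save_store()`: `path`, invisibly. `load_store()`: a
#'   [point_store()].
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "point_store"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  reg <- list(format_version = 1L, arrayname = store$arrayname,
              next_id = store$next_id,
              runs = lapply(store$runs, unclass))
  jsonlite::write_json(reg, file.path(path, "registry.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(store$points, file.path(path, "points.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  reg_path <- file.path(path, "registry.json")
  if (!file.exists(reg_path)) stop("not a point store: ", path)
  reg <- jsonlite::fromJSON(reg_path, simplifyVector = FALSE)
  if (is.null(reg$format_version) || reg$format_version != 1L)
    stop("unsupported store format version")
  st <- point_store(reg$arrayname)
  st$next_id <- as.integer(reg$next_id)
  st$runs <- lapply(reg$runs, function(r)
    run_metadata(r$run_id, r$source_path %||% NA_character_,
                 r$n_spectra,
                 r$rt_unit_original %||% NA_character_,
                 unlist(r$polarity_summary)))
  csv <- file.path(path, "points.csv")
  pts <- utils::read.csv(csv, stringsAsFactors = FALSE)
  if (nrow(pts)) st$points <- validate_raw_points(pts)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a
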