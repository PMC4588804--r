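#' Atlas store: compound entries and dictionaries
#'
#' An atlas is a method- and sample-specific set of assertions of the form
#' "compound X is observed at m/z `mz` (within `mz_tolerance_ppm`) between
#' `rt_min` and `rt_max` minutes, apex near `rt_peak`". The store keeps
#' compound entries and compound dictionaries (named, ordered memberships
#' of entries) and implements document-style update semantics:
#'
#' * `PUT` ([put_compound()], [put_dict()]) **completely replaces** the
#'   stored fields with the payload — any previously stored field absent
#'   from the payload is gone afterwards.
#' * `PATCH` ([patch_compound()]) overwrites only the supplied fields and
#'   then deletes the names listed in `removed_fields`; everything else is
#'   untouched.
#'
#' All mutations are atomic: if the result would violate an invariant
#' (`rt_min <= rt_peak <= rt_max`, `mz > 0`, tolerance > 0, required field
#' removed, ...) the call fails and the observable state is unchanged.
#' Every mutation increments the store's revision counter, which feature
#' tables record as provenance.
#'
#' @return [atlas_store()] returns an empty store (environment-backed).
#' @examples
#' at <- atlas_store()
#' put_compound(at, "adenine", list(
#'   name = "adenine", mz = 136.0618, mz_tolerance_ppm = 20,
#'   rt_min = 9.0, rt_peak = 9.4, rt_max = 9.8))
#' get_compound(at, "adenine")$rt_peak
#' @export
atlas_store <- function() {
  at <- new.env(parent = emptyenv())
  at$compounds <- list()
  at$dicts <- list()
  at$revision <- 0L
  at$provenance <- list()
  class(at) <- "atlas_store"
  at
}

#' @export
print.atlas_store <- function(x, ...) {
  cat(sprintf("<atlas_store> %d compound(s), %d dictionar%s, revision %d\n",
              length(x$compounds), length(x$dicts),
              if (length(x$dicts) == 1) "y" else "ies", x$revision))
  invisible(x)
}

COMPOUND_REQUIRED <- c("name", "mz", "mz_tolerance_ppm",
                       "rt_min", "rt_peak", "rt_max")
COMPOUND_OPTIONAL <- c("polarity", "mz_tolerance_da")
DICT_REQUIRED <- c("name", "sample_type", "chromatography_method",
                   "compound_ids")

validate_compound_fields <- function(compound_id, fields) {
  if ("compound_id" %in% names(fields))
    stop("payload may not contain 'compound_id' (it is the resource id)")
  miss <- setdiff(COMPOUND_REQUIRED, names(fields))
  if (length(miss))
    stop("compound payload missing required field(s): ",
         paste(miss, collapse = ", "))
  f <- fields
  if (!is.numeric(f$mz) || length(f$mz) != 1 || is.na(f$mz) || f$mz <= 0)
    stop("mz must be a single number > 0")
  if (!is.numeric(f$mz_tolerance_ppm) || is.na(f$mz_tolerance_ppm) ||
      f$mz_tolerance_ppm <= 0)
    stop("mz_tolerance_ppm must be > 0")
  if (!is.null(f$mz_tolerance_da) &&
      (!is.numeric(f$mz_tolerance_da) || f$mz_tolerance_da <= 0))
    stop("mz_tolerance_da, when given, must be > 0")
  for (k in c("rt_min", "rt_peak", "rt_max"))
    if (!is.numeric(f[[k]]) || length(f[[k]]) != 1 || is.na(f[[k]]))
      stop(k, " must be a single finite number")
  if (!(f$rt_min <= f$rt_peak && f$rt_peak <= f$rt_max))
    stop("validation error: rt_min <= rt_peak <= rt_max violated")
  if (!is.null(f$polarity) && !f$polarity %in% c("positive", "negative"))
    stop("polarity must be 'positive' or 'negative'")
  entry <- c(list(compound_id = as.character(compound_id)), f)
  class(entry) <- "compound_entry"
  entry
}

validate_dict_fields <- function(dict_id, fields, store) {
  if ("dict_id" %in% names(fields))
    stop("payload may not contain 'dict_id' (it is the resource id)")
  miss <- setdiff(DICT_REQUIRED, names(fields))
  if (length(miss))
    stop("dictionary payload missing required field(s): ",
         paste(miss, collapse = ", "))
  f <- fields
  for (k in c("name", "sample_type", "chromatography_method"))
    if (!is.character(f[[k]]) || length(f[[k]]) != 1 || !nzchar(f[[k]]))
      stop(k, " must be a non-empty string (atlases are method- and ",
           "sample-specific)")
  ids <- as.character(unlist(f$compound_ids))
  if (anyDuplicated(ids))
    stop("compound_ids must be unique within a dictionary")
  unknown <- setdiff(ids, names(store$compounds))
  if (length(unknown))
    stop("unknown compound id(s) in dictionary: ",
         paste(unknown, collapse = ", "))
  f$compound_ids <- ids
  d <- c(list(dict_id = as.character(dict_id)), f)
  class(d) <- "compound_dict"
  d
}

#' Read a compound entry or dictionary
#'
#' @param store an [atlas_store()].
#' @param compound_id,dict_id identifier.
#' @return The current `compound_entry` / `compound_dict`. Unknown ids are
#'   a not-found error.
#' @export
get_compound <- function(store, compound_id) {
  e <- store$compounds[[as.character(compound_id)]]
  if (is.null(e)) stop("not found: compound '", compound_id, "'")
  e
}

#' @rdname get_compound
#' @export
get_dict <- function(store, dict_id) {
  d <- store$dicts[[as.character(dict_id)]]
  if (is.null(d)) stop("not found: dictionary '", dict_id, "'")
  d
}

#' Create or fully replace a compound entry (PUT semantics)
#'
#' The stored entry becomes exactly the payload: required typed fields
#' (`name`, `mz`, `mz_tolerance_ppm`, `rt_min`, `rt_peak`, `rt_max`),
#' optional `polarity` and `mz_tolerance_da` (an absolute Thomson override
#' of the ppm window), and any number of free-form extra fields. Fields
#' present before the call but absent from the payload are dropped.
#'
#' @param store an [atlas_store()].
#' @param compound_id identifier (created if new).
#' @param fields named list: the complete replacement payload.
#' @return The stored `compound_entry`, invisibly.
#' @export
put_compound <- function(store, compound_id, fields) {
  entry <- validate_compound_fields(compound_id, fields)
  store$compounds[[as.character(compound_id)]] <- entry
  store$revision <- store$revision + 1L
  invisible(entry)
}

#' Partially update a compound entry (PATCH semantics)
#'
#' Overwrites the supplied `fields`, then deletes the names in
#' `removed_fields`; all other fields are untouched. Required typed fields
#' may be overwritten but never removed. The whole patch is applied
#' atomically or not at all.
#'
#' @param store an [atlas_store()].
#' @param compound_id identifier of an existing entry.
#' @param fields named list of fields to set (may be empty).
#' @param removed_fields character vector of field names to delete.
#' @return The updated `compound_entry`, invisibly.
#' @export
patch_compound <- function(store, compound_id, fields = list(),
                           removed_fields = character()) {
  old <- get_compound(store, compound_id)
  bad <- intersect(removed_fields, c("compound_id", COMPOUND_REQUIRED))
  if (length(bad))
    stop("cannot remove required field(s): ", paste(bad, collapse = ", "))
  merged <- unclass(old)
  for (k in names(fields)) merged[[k]] <- fields[[k]]
  merged <- merged[!names(merged) %in% removed_fields]
  merged$compound_id <- NULL
  entry <- validate_compound_fields(compound_id, merged)
  store$compounds[[as.character(compound_id)]] <- entry
  store$revision <- store$revision + 1L
  invisible(entry)
}

#' Create or fully replace a compound dictionary (PUT semantics)
#'
#' Replacement happens at the dictionary level only: the membership list
#' is replaced, but member compound entries themselves are never deleted —
#' compounds dropped from the list remain retrievable by id.
#'
#' @param store an [atlas_store()].
#' @param dict_id identifier (created if new).
#' @param fields named list with `name`, `sample_type`,
#'   `chromatography_method`, `compound_ids` and any extra fields.
#' @return The stored `compound_dict`, invisibly.
#' @export
put_dict <- function(store, dict_id, fields) {
  d <- validate_dict_fields(dict_id, fields, store)
  store$dicts[[as.character(dict_id)]] <- d
  store$revision <- store$revision + 1L
  invisible(d)
}

#' Adjust a compound's retention-time bounds, with provenance
#'
#' Retention-time bounds routinely need manual refinement once the
#' measured chromatogram is inspected (the asserted window may not match
#' the observed elution). This is a patch touching exactly the three RT
#' fields; every call — including a no-op adjustment to identical values —
#' appends a timestamped provenance record so bound adjustments are
#' auditable.
#'
#' @param store an [atlas_store()].
#' @param compound_id identifier of an existing entry.
#' @param rt_min,rt_peak,rt_max new bounds, minutes;
#'   `rt_min <= rt_peak <= rt_max` required.
#' @param note optional free-text annotation stored with the record.
#' @return The updated `compound_entry`, invisibly.
#' @export
adjust_rt_bounds <- function(store, compound_id, rt_min, rt_peak, rt_max,
                             note = NULL) {
  old <- get_compound(store, compound_id)
  entry <- patch_compound(store, compound_id,
                          fields = list(rt_min = rt_min, rt_peak = rt_peak,
                                        rt_max = rt_max))
  store$provenance[[length(store$provenance) + 1L]] <- list(
    compound_id = as.character(compound_id),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    old = c(rt_min = old$rt_min, rt_peak = old$rt_peak, rt_max = old$rt_max),
    new = c(rt_min = rt_min, rt_peak = rt_peak, rt_max = rt_max),
    note = note)
  invisible(entry)
}

#' Persist an atlas dictionary as a JSON document
#'
#' One JSON document per dictionary, member entries embedded, with a
#' format version. [read_atlas()] loads the document into a (new or
#' existing) atlas store.
#'
#' @param store an [atlas_store()].
#' @param dict_id dictionary to export.
#' @param path JSON file path.
#' @return `write_atlas()`: `path`, invisibly. `read_atlas()`: a list
#'   with the `store` and the loaded `dict_id`.
#' @export
write_atlas <- function(store, dict_id, path) {
  d <- get_dict(store, dict_id)
  doc <- list(format_version = 1L, dictionary = unclass(d),
              compounds = lapply(d$compound_ids, function(id)
                unclass(get_compound(store, id))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path, store = atlas_store()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format_version) || doc$format_version != 1L)
    stop("unsupported atlas format version")
  for (cp in doc$compounds) {
    id <- cp$compound_id
    cp$compound_id <- NULL
    put_compound(store, id, cp)
  }
  d <- doc$dictionary
  id <- d$dict_id
  d$dict_id <- NULL
  put_dict(store, id, d)
  list(store = store, dict_id = id)
}

#' Export / import an atlas dictionary as CSV
#'
#' Spreadsheet interchange: one row per compound with columns
#' `compound_id`, `name`, `mz`, `mz_tolerance_ppm`, `rt_min`, `rt_peak`,
#' `rt_max`. Free-form extra fields are not carried by the CSV form.
#'
#' @param store an [atlas_store()].
#' @param dict_id dictionary to export (for import: id to create).
#' @param path CSV path.
#' @param name,sample_type,chromatography_method dictionary fields used on
#'   import.
#' @return `atlas_to_csv()`: `path` invisibly; `atlas_from_csv()`: the
#'   dict id, invisibly.
#' @export
atlas_to_csv <- function(store, dict_id, path) {
  d <- get_dict(store, dict_id)
  rows <- lapply(d$compound_ids, function(id) {
    e <- get_compound(store, id)
    data.frame(compound_id = e$compound_id, name = e$name, mz = e$mz,
               mz_tolerance_ppm = e$mz_tolerance_ppm,
               rt_min = e$rt_min, rt_peak = e$rt_peak, rt_max = e$rt_max)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname atlas_to_csv
#' @export
atlas_from_csv <- function(store, dict_id, path, name = dict_id,
                           sample_type = "unspecified",
                           chromatography_method = "unspecified") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df)))
    put_compound(store, df$compound_id[i],
                 list(name = df$name[i], mz = df$mz[i],
                      mz_tolerance_ppm = df$mz_tolerance_ppm[i],
                      rt_min = df$rt_min[i], rt_peak = df$rt_peak[i],
                      rt_max = df$rt_max[i]))
  put_dict(store, dict_id,
           list(name = name, sample_type = sample_type,
                chromatography_method = chromatography_method,
                compound_ids = df$compound_id))
  invisible(dict_id)
}
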