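#' Raw LC/MS data points
#'
#' A raw point is one centroided ion measurement. Each point carries nine
#' attributes: `file_id`, `ms_level`, `polarity`, `rt` (retention time,
#' minutes), `mz` (Thomson), `intensity` (detector counts), and — for
#' ms-level > 1 only — `precursor_mz`, `precursor_intensity` and
#' `collision_energy`. The three precursor attributes are `NA` (absent) for
#' MS1 points; `NA`, never `0`, marks absence so a genuine `0.0` value can
#' not be mistaken for "not recorded".
#'
#' @param rt retention time in minutes (numeric, >= 0).
#' @param mz mass-to-charge ratio in Thomson (numeric, > 0).
#' @param intensity detector counts (numeric, >= 0).
#' @param ms_level integer >= 1 (1 = survey scan, 2 = fragmentation, ...).
#' @param polarity `"positive"` or `"negative"`, recycled to length.
#' @param precursor_mz,precursor_intensity,collision_energy precursor-ion
#'   attributes; must be `NA` where `ms_level == 1` and non-`NA` otherwise.
#' @param file_id integer run identifier (assigned by [load_run()]; `NA`
#'   for points not yet loaded into a store).
#'
#' @return A `data.frame` of class `raw_points` with the nine columns above.
#' @examples
#' pts <- raw_points(rt = c(1, 1), mz = c(100, 200), intensity = c(10, 20))
#' nrow(pts)
#' @export
raw_points <- function(rt = numeric(), mz = numeric(), intensity = numeric(),
                       ms_level = 1L, polarity = "positive",
                       precursor_mz = NA_real_,
                       precursor_intensity = NA_real_,
                       collision_energy = NA_real_,
                       file_id = NA_integer_) {
  n <- length(rt)
  df <- data.frame(
    file_id = rep_len(as.integer(file_id), n),
    ms_level = rep_len(as.integer(ms_level), n),
    polarity = rep_len(as.character(polarity), n),
    rt = as.numeric(rt),
    mz = as.numeric(mz),
    intensity = rep_len(as.numeric(intensity), n),
    precursor_mz = rep_len(as.numeric(precursor_mz), n),
    precursor_intensity = rep_len(as.numeric(precursor_intensity), n),
    collision_energy = rep_len(as.numeric(collision_energy), n),
    stringsAsFactors = FALSE
  )
  validate_raw_points(df)
}

POINT_COLUMNS <- c("file_id", "ms_level", "polarity", "rt", "mz", "intensity",
                   "precursor_mz", "precursor_intensity", "collision_energy")

#' Validate a raw-point table
#'
#' Checks the nine-column schema and its invariants: `intensity >= 0`,
#' `mz > 0`, `rt >= 0`, polarity in \{positive, negative\}, and the
#' precursor attributes absent exactly when `ms_level == 1`.
#'
#' @param df a data.frame with the columns of [raw_points()].
#' @return `df`, classed as `raw_points`, columns in canonical order.
#' @export
validate_raw_points <- function(df) {
  missing_cols <- setdiff(POINT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("raw_points is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, POINT_COLUMNS]
  if (nrow(df)) {
    if (any(!df$polarity %in% c("positive", "negative")))
      stop("polarity must be 'positive' or 'negative'")
    if (any(is.na(df$mz)) || any(df$mz <= 0))
      stop("mz must be finite and > 0")
    if (any(is.na(df$intensity)) || any(df$intensity < 0))
      stop("intensity must be finite and >= 0")
    if (any(df$rt < 0)) stop("rt must be >= 0 minutes")
    if (any(df$ms_level < 1L)) stop("ms_level must be >= 1")
    ms1 <- df$ms_level == 1L
    if (any(ms1 & (!is.na(df$precursor_mz) | !is.na(df$precursor_intensity) |
                   !is.na(df$collision_energy))))
      stop("precursor attributes must be absent (NA) for ms_level 1 points")
    if (any(!ms1 & (is.na(df$precursor_mz) | is.na(df$precursor_intensity) |
                    is.na(df$collision_energy))))
      stop("precursor attributes are required for ms_level > 1 points")
  }
  class(df) <- c("raw_points", "data.frame")
  df
}

#' Run-level metadata
#'
#' One run corresponds to one mzML file. `rt_unit_original` records the time
#' unit the file used before retention times were normalized to minutes.
#'
#' @param run_id opaque run identifier.
#' @param source_path path the run was read from (or will be written to).
#' @param n_spectra number of spectra in the run.
#' @param rt_unit_original `"seconds"`, `"minutes"`, or `NA` for an empty run.
#' @param polarity_summary character vector: the polarities present.
#' @return A list of class `run_metadata`.
#' @export
run_metadata <- function(run_id, source_path = NA_character_,
                         n_spectra = 0L,
                         rt_unit_original = NA_character_,
                         polarity_summary = character()) {
  if (!is.na(rt_unit_original) &&
      !rt_unit_original %in% c("seconds", "minutes"))
    stop("rt_unit_original must be 'seconds' or 'minutes'")
  structure(
    list(run_id = as.character(run_id),
         source_path = as.character(source_path),
         n_spectra = as.integer(n_spectra),
         rt_unit_original = rt_unit_original,
         polarity_summary = sort(unique(as.character(polarity_summary)))),
    class = "run_metadata"
  )
}

#' @export
print.run_metadata <- function(x, ...) {
  cat(sprintf("<run %s> %d spectra, rt unit '%s', polarity: %s\n",
              x$run_id, x$n_spectra, x$rt_unit_original,
              paste(x$polarity_summary, collapse = "/")))
  invisible(x)
}
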