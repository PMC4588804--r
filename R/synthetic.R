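#' Simulated compound and run configuration
#'
#' `sim_compound()` describes one chromatographic peak: a Gaussian elution
#' profile at `rt_center` with width `rt_sigma` and apex intensity
#' `peak_height`, detected at `mz`. `fold_changes` scales the peak height
#' per file (1-based by file index), which is how group designs with known
#' effect sizes are simulated.
#'
#' `sim_config()` fixes the acquisition: scans every `scan_interval`
#' minutes across `rt_span`; each centroid's m/z is jittered by a normal
#' error with `mz_jitter_ppm` parts-per-million standard deviation;
#' intensities carry multiplicative log-normal noise with coefficient of
#' variation `intensity_noise_cv` (unit mean, so expected areas are
#' unbiased); each scan also receives `n_noise_points_per_scan` uniform
#' background centroids. Centroids below `detection_floor` are dropped,
#' emulating the vendor-side removal of low-intensity signals. `seed` is
#' mandatory: all randomness flows from it.
#'
#' Defaults describe a plausible desk-scale acquisition: a 10-minute
#' gradient sampled at 0.005 min (3.3 Hz), 6-second-wide peaks
#' (`rt_sigma = 0.1` min), 5 ppm mass jitter, 10% intensity noise.
#'
#' @param name compound name.
#' @param mz theoretical m/z (Thomson).
#' @param rt_center elution apex, minutes.
#' @param rt_sigma Gaussian elution width (standard deviation), minutes.
#' @param peak_height apex intensity, counts.
#' @param fold_changes numeric vector of per-file multipliers (recycled;
#'   default 1 for every file).
#' @return `sim_compound()`: a list of class `sim_compound`.
#' @export
sim_compound <- function(name, mz, rt_center, rt_sigma = 0.1,
                         peak_height = 1e5, fold_changes = 1) {
  stopifnot(rt_sigma > 0, peak_height > 0, mz > 0)
  structure(list(name = as.character(name), mz = mz,
                 rt_center = rt_center, rt_sigma = rt_sigma,
                 peak_height = peak_height,
                 fold_changes = as.numeric(fold_changes)),
            class = "sim_compound")
}

#' @rdname sim_compound
#' @param n_files number of runs in the simulated experiment.
#' @param rt_span acquisition length, minutes.
#' @param scan_interval time between scans, minutes (> 0).
#' @param mz_range range background noise centroids are drawn from.
#' @param mz_jitter_ppm standard deviation of the per-centroid mass error,
#'   ppm.
#' @param intensity_noise_cv coefficient of variation of the
#'   multiplicative intensity noise (0 = noiseless).
#' @param n_noise_points_per_scan background centroids per scan.
#' @param noise_intensity_mean mean intensity of background centroids.
#' @param detection_floor centroids below this intensity are dropped.
#' @param seed integer; mandatory, drives all randomness.
#' @return `sim_config()`: a list of class `sim_config`.
#' @export
sim_config <- function(n_files = 4L, rt_span = 10, scan_interval = 0.005,
                       mz_range = c(80, 1000), mz_jitter_ppm = 5,
                       intensity_noise_cv = 0.1,
                       n_noise_points_per_scan = 10L,
                       noise_intensity_mean = 50,
                       detection_floor = 1, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config requires an explicit seed")
  stopifnot(scan_interval > 0, rt_span > 0, n_files >= 1,
            intensity_noise_cv >= 0, mz_jitter_ppm >= 0,
            n_noise_points_per_scan >= 0, detection_floor >= 0)
  structure(list(n_files = as.integer(n_files), rt_span = rt_span,
                 scan_interval = scan_interval, mz_range = mz_range,
                 mz_jitter_ppm = mz_jitter_ppm,
                 intensity_noise_cv = intensity_noise_cv,
                 n_noise_points_per_scan = as.integer(n_noise_points_per_scan),
                 noise_intensity_mean = noise_intensity_mean,
                 detection_floor = detection_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

fold_for_file <- function(compound, file_index) {
  fc <- compound$fold_changes
  fc[(file_index %% length(fc)) + 1L]
}

# Deterministic per-file seed derived from the master seed; kept within
# 32-bit integer range.
file_seed <- function(seed, file_index) {
  as.integer((as.numeric(seed) * 131071 + file_index) %% 2147483647)
}

#' Simulate one centroided LC/MS run with known ground truth
#'
#' Scans are placed at regular intervals over `[0, rt_span]`. At every
#' scan, each compound contributes a centroid at
#' `mz * (1 + e)`, `e ~ N(0, jitter_ppm * 1e-6)`, with intensity
#' `height * fold * exp(-(rt - mu)^2 / (2 * sigma^2))` times unit-mean
#' log-normal noise; centroids below the detection floor are dropped.
#' Background centroids are added uniformly over `mz_range`. The returned
#' ground truth records each compound's true total area
#' `height * fold * sigma * sqrt(2 * pi)` (counts x minutes) and the
#' number of signal centroids that survived the floor. Fully reproducible:
#' the RNG is seeded from (`cfg$seed`, `file_index`) alone.
#'
#' @param cfg a [sim_config()].
#' @param compounds list of [sim_compound()].
#' @param file_index 0-based index of the run within the experiment
#'   (selects fold changes and the per-file random stream).
#' @return A list: `points` ([raw_points()]), `truth` (data.frame:
#'   `compound`, `mz`, `rt_center`, `rt_sigma`, `fold`, `true_area`,
#'   `n_signal_points`), `metadata` ([run_metadata()]).
#' @export
simulate_run <- function(cfg, compounds, file_index = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(file_seed(cfg$seed, file_index))
  scans <- seq(0, cfg$rt_span, by = cfg$scan_interval)
  sdlog <- sqrt(log(1 + cfg$intensity_noise_cv^2))
  parts <- list()
  truth <- list()
  for (cp in compounds) {
    stopifnot(inherits(cp, "sim_compound"))
    fold <- fold_for_file(cp, file_index)
    g <- cp$peak_height * fold *
      exp(-(scans - cp$rt_center)^2 / (2 * cp$rt_sigma^2))
    mult <- if (cfg$intensity_noise_cv > 0)
      stats::rlnorm(length(scans), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, length(scans))
    inten <- g * mult
    mz <- cp$mz * (1 + stats::rnorm(length(scans)) * cfg$mz_jitter_ppm * 1e-6)
    keep <- inten >= cfg$detection_floor
    parts[[length(parts) + 1L]] <- data.frame(
      rt = scans[keep], mz = mz[keep], intensity = inten[keep])
    truth[[length(truth) + 1L]] <- data.frame(
      compound = cp$name, mz = cp$mz, rt_center = cp$rt_center,
      rt_sigma = cp$rt_sigma, fold = fold,
      true_area = cp$peak_height * fold * cp$rt_sigma * sqrt(2 * pi),
      n_signal_points = sum(keep))
  }
  nn <- cfg$n_noise_points_per_scan
  if (nn > 0) {
    n_total <- nn * length(scans)
    parts[[length(parts) + 1L]] <- data.frame(
      rt = rep(scans, each = nn),
      mz = stats::runif(n_total, cfg$mz_range[1], cfg$mz_range[2]),
      intensity = cfg$detection_floor +
        stats::rlnorm(n_total, meanlog = log(cfg$noise_intensity_mean),
                      sdlog = 1))
  }
  df <- do.call(rbind, parts)
  if (is.null(df))
    df <- data.frame(rt = numeric(), mz = numeric(), intensity = numeric())
  pts <- raw_points(rt = df$rt, mz = df$mz, intensity = df$intensity)
  run_id <- sprintf("sim_run_%03d", file_index)
  meta <- run_metadata(run_id, NA_character_,
                       n_spectra = length(unique(df$rt)),
                       rt_unit_original = "minutes",
                       polarity_summary = "positive")
  list(points = pts, truth = do.call(rbind, truth), metadata = meta)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Simulate a whole experiment: mzML files, ground truth and an atlas
#'
#' Simulates `cfg$n_files` runs, writes each to mzML in `dir`, and builds
#' a matching atlas: one compound entry per simulated compound with RT
#' bounds `rt_center +/- 3 * rt_sigma` and an m/z tolerance of
#' `max(3 * mz_jitter_ppm, 5)` ppm, bracketing essentially all (99.7%) of
#' each peak's signal; plus one dictionary holding them all. The returned
#' truth matrix is the compound-by-file matrix of true areas, directly
#' comparable to [build_feature_table()] output.
#'
#' @inheritParams simulate_run
#' @param dir output directory for the mzML files (created if needed).
#' @return A list: `files` (mzML paths), `truth` (matrix, compounds x
#'   files), `atlas` (an [atlas_store()]), `dict_id`, `truth_details`
#'   (long data.frame with per-file per-compound truth).
#' @export
simulate_experiment <- function(cfg, compounds, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(cfg$n_files)
  truth_rows <- list()
  for (i in seq_len(cfg$n_files) - 1L) {
    run <- simulate_run(cfg, compounds, file_index = i)
    path <- file.path(dir, sprintf("sim_file_%03d.mzML", i))
    write_mzml(run$points, path, run_id = run$metadata$run_id)
    files[i + 1L] <- path
    tr <- run$truth
    if (!is.null(tr)) {
      tr$file_index <- i
      truth_rows[[i + 1L]] <- tr
    }
  }
  truth_long <- do.call(rbind, truth_rows)
  cnames <- vapply(compounds, function(cp) cp$name, character(1))
  truth <- matrix(if (is.null(truth_long)) numeric(0) else truth_long$true_area,
                  nrow = length(cnames), ncol = cfg$n_files,
                  dimnames = list(cnames, as.character(seq_len(cfg$n_files) - 1L)))
  atlas <- atlas_store()
  for (cp in compounds) {
    put_compound(atlas, cp$name, list(
      name = cp$name, mz = cp$mz,
      mz_tolerance_ppm = max(3 * cfg$mz_jitter_ppm, 5),
      rt_min = cp$rt_center - 3 * cp$rt_sigma,
      rt_peak = cp$rt_center,
      rt_max = cp$rt_center + 3 * cp$rt_sigma,
      polarity = "positive"))
  }
  put_dict(atlas, "sim_atlas", list(
    name = "simulated experiment atlas",
    sample_type = "synthetic standard mix",
    chromatography_method = "simulated gradient",
    compound_ids = cnames))
  list(files = files, truth = truth, atlas = atlas, dict_id = "sim_atlas",
       truth_details = truth_long)
}

#' Write simulation ground truth to disk
#'
#' @param truth_details the `truth_details` element of
#'   [simulate_experiment()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(truth_details, csv_path = NULL,
                               json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(truth_details, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(truth_details, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
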