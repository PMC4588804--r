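entry_for <- function(mz = 100, ppm = 10, rt_min = 0, rt_peak = 1,
                      rt_max = 2, ...) {
  at <- atlas_store()
  put_compound(at, "e", list(name = "e", mz = mz, mz_tolerance_ppm = ppm,
                             rt_min = rt_min, rt_peak = rt_peak,
                             rt_max = rt_max, ...))
  get_compound(at, "e")
}

test_that("an atlas entry defines its ppm m/z window and RT window", {
  q <- compound_query(entry_for(mz = 100, ppm = 10))
  expect_equal(q$min_mz, 99.999)
  expect_equal(q$max_mz, 100.001)
  expect_equal(q$min_rt, 0)
  expect_equal(q$max_rt, 2)
  expect_equal(q$L, 1L)
  expect_equal(q$queryType, "XICofFile_mf")
  # tolerance must be positive
  expect_error(entry_for(ppm = 0), "mz_tolerance_ppm")
  # absolute override
  qd <- compound_query(entry_for(mz = 500, ppm = 10, mz_tolerance_da = 0.01))
  expect_equal(qd$max_mz - qd$min_mz, 0.02)
})

test_that("the ppm window width is 2 * mz * ppm * 1e-6", {
  set.seed(77)
  for (k in 1:30) {
    mz <- runif(1, 80, 1500)
    ppm <- runif(1, 1, 50)
    q <- compound_query(entry_for(mz = mz, ppm = ppm))
    expect_lt(abs((q$max_mz - q$min_mz) - 2 * mz * ppm * 1e-6), 1e-12)
  }
})

make_sim_store <- function(compounds, cfg) {
  st <- point_store("sim")
  for (i in seq_len(cfg$n_files) - 1L) {
    run <- simulate_run(cfg, compounds, i)
    meta <- run$metadata
    meta$source_path <- sprintf("mem://%d", i)
    load_run(st, meta, run$points)
  }
  st
}

test_that("extraction yields one chromatogram per compound and file", {
  cfg <- sim_config(n_files = 2, rt_span = 3, scan_interval = 0.005,
                    seed = 13, intensity_noise_cv = 0)
  cps <- list(sim_compound("a", 150.05, 1.5))
  st <- make_sim_store(cps, cfg)
  exp <- simulate_experiment(cfg, cps, file.path(tempdir(), "card"))
  res <- extract_xic(st, exp$atlas, exp$dict_id)
  expect_equal(names(res), "a")
  expect_setequal(names(res[["a"]]), c("0", "1"))
  # chromatogram total matches injected in-window intensity
  q <- compound_query(get_compound(exp$atlas, "a"), fileidlist = 0L)
  expect_equal(sum(res[["a"]][["0"]]$intensity),
               sum(slice_points(st, q)$intensity))
  # an RT window away from the peak sees nothing
  adjust_rt_bounds(exp$atlas, "a", 2.5, 2.7, 2.9)
  res2 <- extract_xic(st, exp$atlas, exp$dict_id)
  expect_equal(sum(res2[["a"]][["0"]]$intensity), 0)
})

test_that("integration: constant signal over width w gives h * w", {
  h <- 7.5
  ch <- sampled_chromatogram(function(x) rep(h, length(x)), 2, 5, 60)
  expect_equal(integrate_peak(ch), h * 3, tolerance = 1e-9)
  zero <- sampled_chromatogram(function(x) rep(0, length(x)), 0, 1, 10)
  expect_equal(integrate_peak(zero), 0)
})

test_that("integration recovers the Gaussian closed form within 1%", {
  A <- 1e5; mu <- 5; sig <- 0.2
  ch <- sampled_chromatogram(function(x) A * exp(-(x - mu)^2 / (2 * sig^2)),
                             mu - 6 * sig, mu + 6 * sig, 200)
  expect_equal(integrate_peak(ch), A * sig * sqrt(2 * pi), tolerance = 0.01)
})

test_that("integration windows validate and behave monotonically", {
  ch <- sampled_chromatogram(function(x) exp(-(x - 5)^2), 0, 10, 100)
  expect_error(integrate_peak(ch, 20, 30), "outside")
  expect_error(integrate_peak(ch, 6, 4), "rt_min > rt_max")
  widths <- seq(0.5, 4, by = 0.5)
  areas <- vapply(widths, function(w) integrate_peak(ch, 5 - w, 5 + w),
                  numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("doubling the sampling density changes a contained peak < 1%", {
  A <- 2e4; mu <- 3; sig <- 0.15
  f <- function(x) A * exp(-(x - mu)^2 / (2 * sig^2))
  a1 <- integrate_peak(sampled_chromatogram(f, mu - 3 * sig, mu + 3 * sig, 50))
  a2 <- integrate_peak(sampled_chromatogram(f, mu - 3 * sig, mu + 3 * sig, 100))
  expect_lt(abs(a2 / a1 - 1), 0.01)
})

test_that("peak fitting recovers a noiseless Gaussian to 1e-6", {
  A <- 5e4; mu <- 4.2; sig <- 0.12; b <- 100
  ch <- sampled_chromatogram(function(x)
    b + A * exp(-(x - mu)^2 / (2 * sig^2)), mu - 1, mu + 1, 200)
  fit <- fit_peak(ch)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, A, tolerance = 1e-6)
  expect_equal(fit$center, mu, tolerance = 1e-6)
  expect_equal(fit$sigma, sig, tolerance = 1e-6)
  expect_equal(fit$baseline, b, tolerance = 1e-4)
})

test_that("degenerate chromatograms are not fittable, never an error", {
  flat <- sampled_chromatogram(function(x) rep(5, length(x)), 0, 1, 50)
  expect_false(fit_peak(flat)$converged)
  sparse <- sampled_chromatogram(function(x) ifelse(x < 0.05, 3, 0), 0, 1, 50)
  expect_false(fit_peak(sparse)$converged)
})

test_that("noisy peak fits recover center and width (fixed seed)", {
  set.seed(101)
  A <- 1e5; mu <- 5; sig <- 0.1
  nbins <- 120
  ch <- sampled_chromatogram(function(x)
    A * exp(-(x - mu)^2 / (2 * sig^2)), mu - 3 * sig, mu + 3 * sig, nbins)
  ch$intensity <- ch$intensity * rlnorm(nbins, -0.005, 0.1)
  fit <- fit_peak(ch)
  expect_true(fit$converged)
  expect_lt(abs(fit$center - mu), 0.5 * ch$bin_width)
  expect_lt(abs(fit$sigma / sig - 1), 0.1)
})

test_that("feature tables compose per-cell extraction and integration", {
  cfg <- sim_config(n_files = 4, rt_span = 4, scan_interval = 0.005,
                    seed = 29, intensity_noise_cv = 0.1)
  cps <- list(sim_compound("a", 150.05, 1.0),
              sim_compound("b", 250.05, 2.0, peak_height = 5e4),
              sim_compound("c", 350.05, 3.0, peak_height = 2e4))
  exp <- simulate_experiment(cfg, cps, file.path(tempdir(), "ftcomp"))
  st <- point_store("t")
  ingest_mzml(st, exp$files)
  ft <- build_feature_table(st, exp$atlas, exp$dict_id)
  expect_equal(dim(ft$areas), c(3L, 4L))
  for (cid in c("a", "b", "c")) {
    e <- get_compound(exp$atlas, cid)
    xics <- extract_xic(st, exp$atlas, exp$dict_id)
    for (fc in as.character(0:3))
      expect_identical(ft$areas[cid, fc],
                       integrate_peak(xics[[cid]][[fc]], e$rt_min, e$rt_max))
  }
  expect_equal(ft$provenance$dict_id, "sim_atlas")
})

test_that("per-file fold changes are recovered from area ratios", {
  cfg <- sim_config(n_files = 2, rt_span = 3, scan_interval = 0.005,
                    seed = 31, intensity_noise_cv = 0.05)
  cps <- list(sim_compound("a", 150.05, 1.5, fold_changes = c(1, 3)))
  exp <- simulate_experiment(cfg, cps, file.path(tempdir(), "fold"))
  st <- point_store("t")
  ingest_mzml(st, exp$files)
  ft <- build_feature_table(st, exp$atlas, exp$dict_id)
  expect_equal(ft$areas[1, "1"] / ft$areas[1, "0"], 3, tolerance = 0.05)
})

test_that("files without signal produce flagged zero columns", {
  cfg <- sim_config(n_files = 1, rt_span = 3, scan_interval = 0.01,
                    seed = 37, n_noise_points_per_scan = 0)
  cps <- list(sim_compound("a", 150.05, 1.5))
  exp <- simulate_experiment(cfg, cps, file.path(tempdir(), "zero"))
  st <- point_store("t")
  ingest_mzml(st, exp$files)
  # an empty run alongside the real one
  load_run(st, run_metadata("empty", "empty.mzML", 0), raw_points())
  ft <- build_feature_table(st, exp$atlas, exp$dict_id)
  expect_equal(unname(ft$areas[1, "1"]), 0)
  expect_true(ft$below_detection[1, "1"])
  expect_false(ft$below_detection[1, "0"])
})

test_that("feature tables are invariant to file load order", {
  cfg <- sim_config(n_files = 3, rt_span = 3, scan_interval = 0.005,
                    seed = 41, intensity_noise_cv = 0.1)
  cps <- list(sim_compound("a", 150.05, 1.0),
              sim_compound("b", 250.05, 2.0))
  exp <- simulate_experiment(cfg, cps, file.path(tempdir(), "order"))
  st1 <- point_store("t1")
  ingest_mzml(st1, exp$files)
  st2 <- point_store("t2")
  ingest_mzml(st2, rev(exp$files))
  ft1 <- build_feature_table(st1, exp$atlas, exp$dict_id)
  ft2 <- build_feature_table(st2, exp$atlas, exp$dict_id)
  # map st2 columns back to source files via the registry
  src1 <- vapply(st1$runs, function(r) r$source_path, character(1))
  src2 <- vapply(st2$runs, function(r) r$source_path, character(1))
  perm <- match(src1, src2)
  expect_equal(unname(ft1$areas), unname(ft2$areas[, perm, drop = FALSE]),
               tolerance = 1e-12)
})
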