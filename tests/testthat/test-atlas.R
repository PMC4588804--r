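base_payload <- function(...) {
  utils::modifyList(
    list(name = "adenine", mz = 136.0618, mz_tolerance_ppm = 20,
         rt_min = 9.0, rt_peak = 9.4, rt_max = 9.8),
    list(...))
}

test_that("put then get returns exactly what was stored", {
  at <- atlas_store()
  put_compound(at, "c1", base_payload(note = "ref standard"))
  e <- get_compound(at, "c1")
  expect_equal(e$name, "adenine")
  expect_equal(e$rt_peak, 9.4)
  expect_equal(e$note, "ref standard")
  expect_error(get_compound(at, "nope"), "not found")
  expect_error(get_dict(at, "nope"), "not found")
})

test_that("PUT completely replaces: absent fields are dropped", {
  at <- atlas_store()
  put_compound(at, "c1", base_payload(note = "keep me?"))
  put_compound(at, "c1", base_payload())  # no 'note'
  expect_null(get_compound(at, "c1")$note)
  # idempotence
  before <- get_compound(at, "c1")
  put_compound(at, "c1", base_payload())
  expect_equal(get_compound(at, "c1"), before)
})

test_that("randomized put/get is the identity on payloads", {
  at <- atlas_store()
  set.seed(17)
  for (k in 1:25) {
    extra <- setNames(as.list(round(runif(3), 6)),
                      paste0("field_", sample(100, 3)))
    rt <- sort(runif(3, 0, 20))
    pay <- c(base_payload(rt_min = rt[1], rt_peak = rt[2], rt_max = rt[3]),
             extra)
    put_compound(at, paste0("c", k), pay)
    e <- unclass(get_compound(at, paste0("c", k)))
    e$compound_id <- NULL
    expect_identical(e, pay)
  }
})

test_that("PATCH merges, deletes, and composes on disjoint fields", {
  at <- atlas_store()
  put_compound(at, "c1", base_payload(note = "x", source = "lib"))
  before <- get_compound(at, "c1")
  # identity patch
  patch_compound(at, "c1")
  expect_equal(get_compound(at, "c1"), before)
  # targeted update touches only rt_peak
  patch_compound(at, "c1", fields = list(rt_peak = 9.4))
  after <- get_compound(at, "c1")
  expect_equal(after$rt_peak, 9.4)
  after$rt_peak <- before$rt_peak
  expect_equal(after, before)
  # removal
  patch_compound(at, "c1", removed_fields = "note")
  expect_null(get_compound(at, "c1")$note)
  expect_equal(get_compound(at, "c1")$source, "lib")
  # disjoint composition law: patch(patch(e,a),b) == patch(e, a+b)
  at2 <- atlas_store()
  put_compound(at2, "c", base_payload(u = 1, v = 2))
  patch_compound(at2, "c", fields = list(u = 10))
  patch_compound(at2, "c", fields = list(v = 20))
  seq_result <- get_compound(at2, "c")
  at3 <- atlas_store()
  put_compound(at3, "c", base_payload(u = 1, v = 2))
  patch_compound(at3, "c", fields = list(u = 10, v = 20))
  expect_equal(seq_result, get_compound(at3, "c"))
})

test_that("randomized patches match a merge-then-delete map oracle", {
  set.seed(23)
  for (k in 1:25) {
    at <- atlas_store()
    extra <- setNames(as.list(runif(4)), paste0("f", 1:4))
    pay <- c(base_payload(), extra)
    put_compound(at, "c", pay)
    upd <- setNames(as.list(runif(2)),
                    sample(c(paste0("f", 1:4), "g1", "g2"), 2))
    rem <- sample(paste0("f", 1:4), sample(0:2, 1))
    rem <- setdiff(rem, names(upd))
    patch_compound(at, "c", fields = upd, removed_fields = rem)
    # oracle: plain named-list merge then delete
    want <- pay
    for (nm in names(upd)) want[[nm]] <- upd[[nm]]
    want <- want[!names(want) %in% rem]
    got <- unclass(get_compound(at, "c"))
    got$compound_id <- NULL
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
})

test_that("mutations are atomic: failed validation leaves state unchanged", {
  at <- atlas_store()
  put_compound(at, "c1", base_payload())
  before <- get_compound(at, "c1")
  rev_before <- at$revision
  expect_error(put_compound(at, "c1", base_payload(rt_min = 10, rt_max = 2)),
               "rt_min <= rt_peak <= rt_max")
  expect_error(patch_compound(at, "c1", fields = list(mz = -5)), "mz")
  expect_error(patch_compound(at, "c1", removed_fields = "mz"),
               "required")
  expect_error(patch_compound(at, "c1", fields = list(rt_peak = 99)),
               "rt_min <= rt_peak <= rt_max")
  expect_equal(get_compound(at, "c1"), before)
  expect_equal(at$revision, rev_before)
})

test_that("dictionary PUT replaces membership but never deletes compounds", {
  at <- atlas_store()
  put_compound(at, "a", base_payload())
  put_compound(at, "b", base_payload(name = "nicotinamide", mz = 123.0553))
  dict_pay <- list(name = "plate1", sample_type = "plasma",
                   chromatography_method = "HILIC 17 min",
                   compound_ids = c("a", "b"))
  put_dict(at, "d1", dict_pay)
  expect_equal(get_dict(at, "d1")$compound_ids, c("a", "b"))
  dict_pay$compound_ids <- "a"
  put_dict(at, "d1", dict_pay)
  expect_equal(get_dict(at, "d1")$compound_ids, "a")
  expect_equal(get_compound(at, "b")$name, "nicotinamide")  # orphan intact
  # validation
  expect_error(put_dict(at, "d2", utils::modifyList(dict_pay,
               list(sample_type = ""))), "sample_type")
  expect_error(put_dict(at, "d2", utils::modifyList(dict_pay,
               list(compound_ids = c("a", "a")))), "unique")
})

test_that("rt-bound adjustment validates ordering and logs provenance", {
  at <- atlas_store()
  put_compound(at, "c1", base_payload())
  expect_error(adjust_rt_bounds(at, "c1", 5, 4, 3), "rt_min <= rt_peak")
  expect_equal(get_compound(at, "c1")$rt_peak, 9.4)
  n0 <- length(at$provenance)
  adjust_rt_bounds(at, "c1", 9.0, 9.4, 9.8)  # no-op values
  expect_equal(length(at$provenance), n0 + 1L)  # still audited
  adjust_rt_bounds(at, "c1", 8.5, 9.3, 10.2, note = "manual review")
  e <- get_compound(at, "c1")
  expect_equal(c(e$rt_min, e$rt_peak, e$rt_max), c(8.5, 9.3, 10.2))
  last <- at$provenance[[length(at$provenance)]]
  expect_equal(last$compound_id, "c1")
  expect_equal(unname(last$old["rt_peak"]), 9.4)
  expect_equal(last$note, "manual review")
})

test_that("widening rt bounds never shrinks the extracted area", {
  cfg <- sim_config(n_files = 1, rt_span = 4, scan_interval = 0.005,
                    seed = 3, intensity_noise_cv = 0,
                    n_noise_points_per_scan = 0)
  exp <- simulate_experiment(cfg, list(sim_compound("x", 250.1, 2)),
                             file.path(tempdir(), "widen"))
  st <- point_store("t")
  ingest_mzml(st, exp$files)
  area_at <- function() {
    ft <- build_feature_table(st, exp$atlas, exp$dict_id)
    ft$areas[1, 1]
  }
  a1 <- area_at()
  adjust_rt_bounds(exp$atlas, "x", 2 - 0.5, 2, 2 + 0.5)  # widen from +/-0.3
  a2 <- area_at()
  expect_gte(a2, a1)
})

test_that("atlas JSON and CSV round-trip", {
  at <- atlas_store()
  put_compound(at, "a", base_payload(note = "x"))
  put_compound(at, "b", base_payload(name = "nicotinamide", mz = 123.0553))
  put_dict(at, "d1", list(name = "plate1", sample_type = "plasma",
                          chromatography_method = "HILIC",
                          compound_ids = c("a", "b")))
  js <- tempfile(fileext = ".json")
  write_atlas(at, "d1", js)
  back <- read_atlas(js)
  expect_equal(get_dict(back$store, "d1")$compound_ids, c("a", "b"))
  expect_equal(get_compound(back$store, "a")$note, "x")
  expect_equal(get_compound(back$store, "b")$mz, 123.0553)
  cs <- tempfile(fileext = ".csv")
  atlas_to_csv(at, "d1", cs)
  at2 <- atlas_store()
  atlas_from_csv(at2, "d2", cs, sample_type = "plasma",
                 chromatography_method = "HILIC")
  expect_equal(get_compound(at2, "b")$mz, 123.0553)
  expect_equal(get_dict(at2, "d2")$compound_ids, c("a", "b"))
})
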