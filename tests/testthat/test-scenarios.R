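test_that("the installed library covers every benchmark row", {
  lib <- scenario_library()
  expect_setequal(
    lib,
    c(sprintf("table1_sim%02d", 1:14),
      paste0("table2_", c("exponential", "gompertz", "logistic")),
      sprintf("table3_sim%d", 1:8),
      sprintf("table4_sim%d", 1:7),
      paste0("fig", 5:8)))
  for (nm in lib) expect_s3_class(load_scenario(scenario_path(nm)),
                                  "karyo_scenario")
})

test_that("the canonical benchmark fixture parses to the printed parameters", {
  scn <- load_scenario(scenario_path("table1_sim01"))
  nc <- scn$niches[[1]]
  expect_equal(unname(nc$initial), c(10000, 100, 0.2))
  expect_equal(unname(nc$doubling_times), c(10, 20, 10))
  expect_equal(unname(nc$death_rates), rep(0.01, 3))
  expect_equal(nc$carrying_capacity, 1e5)
  expect_equal(scn$dt, 0.5)
  expect_equal(scn$extinction_threshold, 0.5)
})

test_that("scenario files round-trip losslessly", {
  for (nm in c("table1_sim01", "table3_sim3", "table4_sim2")) {
    a <- load_scenario(scenario_path(nm))
    tmp <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(a, tmp)
    b <- load_scenario(tmp)
    drop_meta <- function(x) x[setdiff(names(x), c("defaults",
                                                   "unreproducible_absolute_times"))]
    an <- lapply(a$niches, function(n) n[setdiff(names(n), "defaults")])
    bn <- lapply(b$niches, function(n) n[setdiff(names(n), "defaults")])
    expect_equal(an, bn)
    expect_equal(drop_meta(unclass(a))[c("dt", "horizon", "extinction_threshold",
                                         "steady_state", "migration")],
                 drop_meta(unclass(b))[c("dt", "horizon", "extinction_threshold",
                                         "steady_state", "migration")])
  }
})

test_that("validation rejects malformed scenarios with field-level messages", {
  expect_error(niche_spec(c(100, 0, 0), c(ww = -2), 0.01), "doubling times")
  expect_error(niche_spec(c(100, -1, 0), c(ww = 10), 0.01), "non-negative")
  expect_error(scenario(niche_spec(c(100, 0, 0), c(ww = 10), 0.01),
                        horizon = -5), "horizon")
  expect_error(scenario(niche_spec(c(100, 0, 0), c(ww = 10), 3), dt = 0.5),
               "death_rate")
  expect_error(migration_spec("threshold"), "sf")
  expect_error(migration_spec("threshold", sf = 0.01,
                              windows = list(c(10, 5))), "window")
  expect_error(scenario(niche_spec(c(100, 0, 0), c(ww = 10), 0.01),
                        migration = migration_spec("threshold", sf = 0.1)),
               "two niches")
  # unknown keys in files are rejected
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schema: 1", "frobnicate: 2", "horizon: 10", "niches:",
               "- initial: {ww: 1, wv: 0, vv: 0}",
               "  doubling_times: {ww: 10}", "  death_rates: {ww: 0, vv: 0}"),
             tmp)
  expect_error(load_scenario(tmp), "unknown key")
})

test_that("omitted fields are defaulted and recorded", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schema: 1", "horizon: 10", "niches:",
               "- initial: {ww: 100, wv: 0, vv: 0}",
               "  doubling_times: {ww: 10}",
               "  death_rates: {ww: 0.01, vv: 0.01}"),
             tmp)
  scn <- load_scenario(tmp)
  expect_equal(scn$dt, 0.5)
  expect_equal(scn$niches[[1]]$carrying_capacity, 1e5)
  expect_equal(unname(scn$niches[[1]]$doubling_times[["wv"]]), 20)
  expect_true("dt" %in% scn$defaults)
  expect_true(any(grepl("carrying_capacity", scn$defaults)))
  expect_true(any(grepl("doubling_times.wv", scn$defaults, fixed = TRUE)))
})

test_that("random scenarios are deterministic in the seed and always valid", {
  expect_equal(random_scenario(11), random_scenario(11))
  for (seed in 1:20) {
    scn <- random_scenario(seed)
    expect_s3_class(validate_scenario(scn), "karyo_scenario")
  }
  # the generator leaves the caller's RNG stream alone
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(random_scenario(3))
  expect_identical(runif(1), before)
})
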