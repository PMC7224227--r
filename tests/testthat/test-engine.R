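test_that("a single-genotype run follows the closed form exactly", {
  n0 <- 321
  scn <- scenario(niche_spec(c(n0, 0, 0), c(ww = 10), 0.01), horizon = 120)
  run <- run_scenario(scn)
  f <- growth_factor(10, 0.01, 0.5)
  tr <- run$trajectory
  steps <- seq(0, 240)
  expected <- pmin(n0 * f^steps, 1e5)
  expect_equal(tr$n_total, expected, tolerance = 1e-12)
  expect_equal(run$events[[1]]$ta_weeks,
               oracle_single_class_ta(n0, 1e5, 10, 0.01, 0.5))
})

test_that("runs are deterministic and bit-identical", {
  scn <- load_scenario(scenario_path("table3_sim2"))
  r1 <- run_scenario(scn, horizon = 300)
  r2 <- run_scenario(scn, horizon = 300)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$events, r2$events)
})

test_that("halving dt moves benchmark event times by at most one coarse step", {
  scn <- load_scenario(scenario_path("table1_sim01"))
  coarse <- run_scenario(scn)$events[[1]]
  fine <- run_scenario(scn, dt = 0.25)$events[[1]]
  expect_lte(abs(fine$ta_weeks - coarse$ta_weeks), 0.5)
  expect_lte(abs(fine$te_variant_weeks - coarse$te_variant_weeks), 0.5)
})

test_that("variant extinction time is invariant to uniform death rates", {
  tes <- vapply(c("table1_sim01", "table1_sim07", "table1_sim09"),
                function(nm) {
                  run <- run_scenario(load_scenario(scenario_path(nm)))
                  run$events[[1]]$te_variant_weeks
                }, 0)
  expect_equal(unname(tes), rep(tes[[1]], 3))
})

test_that("a weaker fertility deficit strictly delays variant extinction", {
  te_strong <- run_scenario(load_scenario(scenario_path("table1_sim01")))$events[[1]]$te_variant_weeks
  te_weak <- run_scenario(load_scenario(scenario_path("table1_sim08")))$events[[1]]$te_variant_weeks
  expect_gt(te_weak, te_strong)
})

test_that("the symmetric start is an exact, never-extinct fixed point", {
  run <- run_scenario(load_scenario(scenario_path("table1_sim04")),
                      horizon = 1000)
  tr <- run$trajectory
  expect_true(all(abs(tr$q - 0.5) < 1e-12))
  expect_true(is.na(run$events[[1]]$te_variant_weeks))
  expect_true(is.na(run$events[[1]]$te_wildtype_weeks))
  # asymptotic Mendelian 1:2:1
  last <- tr[nrow(tr), ]
  expect_equal(last$z_wv / last$n_total, 0.5, tolerance = 1e-9)
  expect_equal(last$z_ww, last$z_vv, tolerance = 1e-9 * last$z_ww)
})

test_that("ln q declines by the log-fitness gap per step in the rare-variant limit", {
  q0 <- 1e-8
  n0 <- 1e4
  scn <- scenario(niche_spec(n0 * c((1 - q0)^2, 2 * q0 * (1 - q0), q0^2),
                             c(10, 20, 10), 0.01),
                  horizon = 50)
  tr <- run_scenario(scn)$trajectory
  slope <- diff(log(tr$q))
  expected <- -(log(growth_factor(10, 0.01, 0.5)) - log(growth_factor(20, 0.01, 0.5)))
  expect_equal(slope, rep(expected, length(slope)), tolerance = 1e-6)
})

test_that("steady-state detection finds quiet tails and ignores growth", {
  # constant trajectory: steady from the first recorded week
  expect_equal(detect_steady_state(matrix(5, nrow = 50, ncol = 3)), 0)
  # pure exponential growth below capacity: never steady
  scn <- scenario(niche_spec(c(10, 0, 0), c(ww = 10), 0), horizon = 50)
  expect_true(is.na(detect_steady_state(run_scenario(scn))))
  # capped growth: steady soon after capacity
  scn2 <- scenario(niche_spec(c(10, 0, 0), c(ww = 10), 0), horizon = 300)
  ss <- detect_steady_state(run_scenario(scn2))
  expect_false(is.na(ss))
  expect_gt(ss, 60)
})

test_that("time to a fraction of asymptote uses the realised asymptote", {
  run <- run_scenario(load_scenario(scenario_path("table1_sim01")))
  t085 <- time_to_fraction(run, 0.85, 1)
  tr <- run$trajectory
  expect_equal(t085, tr$week[which(tr$n_total >= 0.85 * 1e5)[1]])
  expect_lt(t085, run$events[[1]]$ta_weeks)
})
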