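test_that("heterozygote death rate follows the dominance rule", {
  expect_equal(resolve_het_death(0.05, 0.01, "dominant"), 0.01)
  expect_equal(resolve_het_death(0.05, 0.01, "recessive"), 0.05)
  expect_equal(resolve_het_death(0.01, 0.01, "dominant"), 0.01)
  expect_error(resolve_het_death(0.05, 0.01, "codominant"))
})

test_that("growth factor is 2^(dt/DT) * (1 - d*dt)", {
  expect_equal(growth_factor(10, 0.01, 0.5), 2^0.05 * 0.995)
  expect_equal(growth_factor(10, 0.01, 0.5), 1.03008860, tolerance = 1e-8)
  expect_equal(growth_factor(20, 0, 0.5), 2^0.025)
  expect_equal(growth_factor(10, 0, 10), 2.0)
  expect_error(growth_factor(10, 2, 0.5))      # d*dt >= 1
  expect_error(growth_factor(0, 0.01, 0.5))    # DT must be positive
})

test_that("allele frequencies count alleles, not individuals", {
  af <- allele_frequency(genotype_vector(10000, 100, 0.2))
  expect_equal(af[["q"]], 100.4 / 20200.4)
  expect_equal(af[["p"]] + af[["q"]], 1.0)
  expect_equal(allele_frequency(genotype_vector(100, 100, 100))[["q"]], 0.5)
  expect_equal(allele_frequency(genotype_vector(0, 0, 50))[["q"]], 1.0)
  expect_error(allele_frequency(genotype_vector(0, 0, 0)))
})

test_that("one niche step grows then redistributes to Hardy-Weinberg", {
  f_hom <- growth_factor(10, 0.01, 0.5)
  f_het <- growth_factor(20, 0.01, 0.5)
  fac <- c(f_hom, f_het, f_hom)

  # symmetric homozygote start is the 1:2:1 fixed point regardless of f_het
  z <- step_niche(genotype_vector(100, 0, 100), c(f_hom, 123, f_hom))
  expect_equal(unname(z), sum(z) * c(0.25, 0.5, 0.25))
  expect_equal(sum(z), 200 * f_hom)

  # q = 0 is absorbing
  z0 <- step_niche(genotype_vector(10000, 0, 0), fac)
  expect_equal(unname(z0), c(10000 * f_hom, 0, 0))

  # worked recursion for the benchmark start, checked against the
  # independent allele-count oracle
  z1 <- step_niche(genotype_vector(10000, 100, 0.2), fac)
  expect_equal(unname(z1), unname(oracle_step_allele_counts(c(10000, 100, 0.2), fac)),
               tolerance = 1e-12)
  expect_equal(allele_frequency(z1)[["q"]], 4.8861e-3, tolerance = 1e-4)

  # on a Hardy-Weinberg state the allele-frequency recursion
  # q' = q (p f_het + q f_hom) / mean-fitness is exact
  q0 <- 100.4 / 20200.4
  p0 <- 1 - q0
  zhw <- hw_redistribute(genotype_vector(10000, 100, 0.2))
  q1_expected <- q0 * (p0 * f_het + q0 * f_hom) /
    (p0^2 * f_hom + 2 * p0 * q0 * f_het + q0^2 * f_hom)
  expect_equal(allele_frequency(step_niche(zhw, fac))[["q"]], q1_expected,
               tolerance = 1e-12)
})

test_that("redistribution conserves N and enforces Hardy-Weinberg proportions", {
  set.seed(42)
  for (i in 1:50) {
    z <- genotype_vector(runif(1, 0, 1e5), runif(1, 0, 1e4), runif(1, 0, 1e5))
    f <- runif(3, 0.5, 1.5)
    zg <- z * f
    zs <- step_niche(z, f)
    expect_equal(sum(zs), sum(zg), tolerance = 1e-12)
    expect_equal(zs[["wv"]]^2, 4 * zs[["ww"]] * zs[["vv"]],
                 tolerance = 1e-9 * max(zs[["wv"]]^2, 1))
    # q is invariant under uniform rescaling
    expect_equal(allele_frequency(zs)[["q"]],
                 allele_frequency(zs * runif(1, 0.01, 0.99))[["q"]],
                 tolerance = 1e-14)
  }
})

test_that("underdominance drives q monotonically away from 1/2", {
  # with f_ww = f_vv = 1 and f_wv = w < 1, per-step
  # dq = q*p*(1-w)*(2q-1)/(1 - 2pq(1-w)) exactly
  w <- 0.9
  for (q in c(0.01, 0.3, 0.49, 0.51, 0.8, 0.99)) {
    p <- 1 - q
    z <- 1000 * c(p^2, 2 * p * q, q^2)
    zs <- step_niche(z, c(1, w, 1))
    dq_expected <- q * p * (1 - w) * (2 * q - 1) / (1 - 2 * p * q * (1 - w))
    expect_equal(allele_frequency(zs)[["q"]] - q, dq_expected, tolerance = 1e-12)
    if (q < 0.5) expect_lt(allele_frequency(zs)[["q"]], q)
    if (q > 0.5) expect_gt(allele_frequency(zs)[["q"]], q)
  }
  # and repeated iteration escapes 0.5 monotonically toward the nearer boundary
  q <- 0.499
  qs <- numeric(200)
  z <- 1e4 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  for (i in 1:200) {
    z <- step_niche(z, c(1, w, 1))
    qs[i] <- allele_frequency(z)[["q"]]
  }
  expect_true(all(diff(qs) < 0))
  expect_lt(qs[200], 0.01)
})

test_that("the initially smaller homozygote class loses under symmetric parameters", {
  set.seed(7)
  fac <- growth_factor(c(10, 20, 10), 0.01, 0.5)
  for (i in 1:10) {
    q0 <- runif(1)
    if (abs(q0 - 0.5) < 0.02) q0 <- 0.4   # keep clear of the unstable point
    n0 <- runif(1, 100, 1e4)
    z <- n0 * c((1 - q0)^2, 2 * q0 * (1 - q0), q0^2)
    smaller_is_variant <- q0 < 0.5
    for (s in 1:4000) {
      z <- step_niche(z, fac)
      if (sum(z) > 1e5) z <- z * (1e5 / sum(z))
    }
    q_end <- allele_frequency(z)[["q"]]
    if (smaller_is_variant) expect_lt(q_end, 1e-6) else expect_gt(q_end, 1 - 1e-6)
  }
})
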