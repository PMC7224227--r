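# Independent oracles used to pre-compute expected values. They deliberately
# avoid the package's own code paths.

# Exhaustive attachment-process oracle: the three kinetochores of the fission
# trivalent (the unsplit chromatid's kinetochore fixed at one pole by symmetry;
# the two acrocentrics attaching sequentially and uniformly at random, with
# tension-free syntelic attachments reversed) form an absorbing Markov chain.
# Absorption probabilities into configurations C, D, E come from the
# fundamental-matrix linear solve, not from the package's arithmetic.
oracle_configuration_probabilities <- function() {
  # transient states: s0 (no acrocentric attached), sA (first acrocentric
  # amphitelic), sB (the other acrocentric amphitelic first)
  Q <- rbind(s0 = c(1/2, 1/4, 1/4),  # syntelic first attachment is reversed
             sA = c(0, 0, 0),
             sB = c(0, 0, 0))
  R <- rbind(s0 = c(C = 0, D = 0, E = 0),
             sA = c(C = 1/2, D = 1/2, E = 0),
             sB = c(C = 1/2, D = 0, E = 1/2))
  B <- solve(diag(3) - Q) %*% R
  c(C = B[1, 1], D = B[1, 2], E = B[1, 3])
}

# Independent one-step update via explicit allele counts (not genotype-class
# Hardy-Weinberg algebra): grow classes, count alleles, re-form classes.
oracle_step_allele_counts <- function(z, f) {
  zg <- z * f
  w_alleles <- 2 * zg[1] + zg[2]
  v_alleles <- zg[2] + 2 * zg[3]
  n <- (w_alleles + v_alleles) / 2
  q <- v_alleles / (w_alleles + v_alleles)
  n * c((1 - q)^2, 2 * q * (1 - q), q^2)
}

# Closed-form time to capacity for a single-genotype exponential population.
oracle_single_class_ta <- function(n0, ap, doubling_time, death_rate, dt) {
  f <- 2^(dt / doubling_time) * (1 - death_rate * dt)
  dt * ceiling(log(ap / n0) / log(f))
}

# Canonical single-niche scenario (the benchmark organism) built in code.
baseline_scenario <- function(initial = c(10000, 100, 0.2),
                              doubling_times = c(10, 20, 10),
                              death_rates = 0.01, horizon = 260, ...) {
  scenario(niche_spec(initial, doubling_times = doubling_times,
                      death_rates = death_rates, ...),
           horizon = horizon)
}
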