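#' Genotype class vector
#'
#' The per-niche state is a length-3 numeric vector of continuous class
#' sizes: wild-type homozygotes (`ww`), rearrangement heterozygotes (`wv`)
#' and variant homozygotes (`vv`). Non-integral sizes are permitted and can
#' be read as expected counts/probabilities.
#'
#' @param ww,wv,vv Non-negative class sizes.
#' @return Named numeric vector `c(ww=, wv=, vv=)`.
#' @export
#' @examples
#' genotype_vector(10000, 100, 0.2)
genotype_vector <- function(ww, wv, vv) {
  z <- c(ww = as.numeric(ww), wv = as.numeric(wv), vv = as.numeric(vv))
  if (anyNA(z) || any(z < 0)) stop("class sizes must be non-negative numbers")
  z
}

#' Heterozygote death rate under a dominance rule
#'
#' When the rearranged chromosome carries a mutation whose death rate
#' differs from the wild-type's, the heterozygote expresses the variant's
#' death rate if the mutation is dominant and the wild-type's if recessive.
#'
#' @param d_ww Wild-type homozygote death rate (per week).
#' @param d_vv Variant homozygote death rate (per week).
#' @param dominance `"dominant"` or `"recessive"`.
#' @return The heterozygote death rate.
#' @export
#' @examples
#' resolve_het_death(0.05, 0.01, "dominant")   # 0.01
#' resolve_het_death(0.05, 0.01, "recessive")  # 0.05
resolve_het_death <- function(d_ww, d_vv, dominance = c("dominant", "recessive")) {
  dominance <- match.arg(dominance)
  stopifnot(d_ww >= 0, d_vv >= 0)
  if (dominance == "dominant") d_vv else d_ww
}

#' Per-step multiplicative growth factor
#'
#' Discretises exponential birth and linear per-step death over one time
#' step: `2^(dt/DT) * (1 - d*dt)`. Birth compounds multiplicatively at the
#' class's doubling time; the death term removes a fraction `d*dt` of the
#' class each step. Because the death term is a common multiplier it cancels
#' from all between-class fitness ratios whenever death rates are equal,
#' which is why variant extinction times are invariant to a uniform change
#' in mortality.
#'
#' @param doubling_time Doubling time in weeks (> 0). Vectorised.
#' @param death_rate Death rate per week (`death_rate * dt` must be < 1).
#' @param dt Step size in weeks.
#' @return Dimensionless per-step factor(s), > 0.
#' @export
#' @examples
#' growth_factor(10, 0.01, 0.5)  # 1.0300886
growth_factor <- function(doubling_time, death_rate, dt) {
  stopifnot(is.numeric(doubling_time), is.numeric(death_rate), is.numeric(dt),
            dt > 0)
  if (any(doubling_time <= 0)) stop("`doubling_time` must be > 0")
  if (any(death_rate < 0)) stop("`death_rate` must be >= 0")
  if (any(death_rate * dt >= 1))
    stop("`death_rate * dt` must be < 1 (per-step survival would be <= 0)")
  2^(dt / doubling_time) * (1 - death_rate * dt)
}

#' Allele frequencies of a genotype vector
#'
#' Standard diploid bookkeeping: the variant-allele frequency is
#' `q = (wv + 2*vv) / (2*N)` and `p = 1 - q`.
#'
#' @param gv Genotype vector (see [genotype_vector()]); total must be > 0.
#' @return Named numeric vector `c(p=, q=)`.
#' @export
#' @examples
#' allele_frequency(genotype_vector(10000, 100, 0.2))
allele_frequency <- function(gv) {
  n <- sum(gv)
  if (n <= 0) stop("allele frequencies are undefined for an empty population")
  q <- (gv[[2]] + 2 * gv[[3]]) / (2 * n)
  c(p = 1 - q, q = q)
}

#' Hardy-Weinberg redistribution
#'
#' Replaces the three genotype classes by Hardy-Weinberg proportions
#' `(p^2*N, 2*p*q*N, q^2*N)` at the current allele frequencies; the total is
#' preserved exactly. This is the engine's mating model: the entire standing
#' population is re-formed by random mating every step.
#'
#' @param gv Genotype vector. An empty vector is returned unchanged.
#' @return Genotype vector in Hardy-Weinberg proportions with the same total.
#' @export
#' @examples
#' hw_redistribute(genotype_vector(100, 0, 100))  # (50, 100, 50)
hw_redistribute <- function(gv) {
  n <- sum(gv)
  if (n <= 0) return(gv)
  q <- (gv[[2]] + 2 * gv[[3]]) / (2 * n)
  p <- 1 - q
  out <- n * c(p * p, 2 * p * q, q * q)
  names(out) <- c("ww", "wv", "vv")
  out
}

#' One per-niche selection-and-mating step
#'
#' The computational core: (1) each class grows by its per-step factor,
#' (2) allele frequencies are recomputed from the grown classes, and
#' (3) the whole population is redistributed to Hardy-Weinberg proportions.
#' Because heterozygotes carry one allele of each kind, selection against
#' them (a smaller `f_wv`) always pushes the rarer allele towards loss:
#' `q = 0` and `q = 1` are absorbing and `q = 0.5` is an (unstable) fixed
#' point when the homozygote factors are equal.
#'
#' @param gv Genotype vector; at least one class must be positive.
#' @param factors Length-3 numeric vector of per-step growth factors
#'   `(f_ww, f_wv, f_vv)`, all > 0.
#' @return The grown, redistributed genotype vector.
#' @export
#' @examples
#' f <- growth_factor(c(10, 20, 10), 0.01, 0.5)
#' step_niche(genotype_vector(10000, 100, 0.2), f)
step_niche <- function(gv, factors) {
  stopifnot(length(gv) == 3, length(factors) == 3)
  if (any(factors <= 0)) stop("growth factors must be > 0")
  if (sum(gv) <= 0) stop("cannot step an empty niche")
  hw_redistribute(gv * factors)
}
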