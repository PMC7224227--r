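#' Anaphase-competent kinetochore attachment configurations
#'
#' Probabilities of the tension-bearing attachment configurations formed when
#' a fission trivalent (one unsplit chromatid plus two acrocentrics, or the
#' mirror situation after a fusion) passes the spindle assembly checkpoint in
#' meiosis II. Attachment is modelled as sequential and unbiased: once the
#' unsplit chromatid and one acrocentric are amphitelically attached, the
#' remaining kinetochore binds the correct pole with probability 1/2
#' (configuration C, balanced segregation); otherwise it joins the pole
#' already occupied, giving configuration D or E (1/4 each) depending on
#' which acrocentric attached first. Syntelic intermediates carry no tension
#' and are reversed, so the transient states A and B carry zero probability
#' mass at anaphase. Merotelic attachments are assumed equally frequent in
#' normal and rearranged karyotypes and are excluded.
#'
#' @return Named numeric vector with elements `A`, `B`, `C`, `D`, `E`;
#'   `A = B = 0` and `C + D + E = 1`.
#' @seealso [gamete_distribution()] for the gamete classes each
#'   configuration yields.
#' @export
#' @examples
#' configuration_probabilities()
configuration_probabilities <- function() {
  c(A = 0, B = 0, C = 0.5, D = 0.25, E = 0.25)
}

gamete_labels <- c("I", "II", "III", "IV", "V", "VI")

#' Gamete classes produced by a rearrangement heterozygote
#'
#' Translates the attachment-configuration probabilities into the six gamete
#' classes a fission (or fusion) heterozygote produces at meiosis II.
#' Configuration C yields classes I and II in equal numbers (balanced:
#' the normal monocentric chromatid, or the acrocentric pair), configuration
#' D yields III and IV, configuration E yields V and VI. Classes III and V
#' lack a large block of genes and are nonviable; IV and VI carry a full
#' complement at incorrect dosage and are viable but unbalanced. Fusion
#' heterozygotes produce the same distribution as fission heterozygotes
#' provided the fused chromosome can align with its two cognate partners.
#'
#' @param change `"fission"` or `"fusion"`.
#' @param config Named probabilities for configurations `C`, `D`, `E`;
#'   defaults to [configuration_probabilities()].
#' @return A data frame with one row per gamete class and columns `label`,
#'   `content`, `viable`, `balanced`, `fraction`. Fractions sum to 1.
#' @export
#' @examples
#' gamete_distribution("fission")
gamete_distribution <- function(change = c("fission", "fusion"),
                                config = configuration_probabilities()) {
  change <- match.arg(change)
  for (nm in c("C", "D", "E")) {
    if (is.na(config[nm])) stop("`config` must name configurations C, D and E")
  }
  stopifnot(abs(sum(config[c("C", "D", "E")]) - 1) < 1e-12)
  # each configuration splits its mass equally between its two gamete classes
  frac <- c(config[["C"]], config[["C"]],
            config[["D"]], config[["D"]],
            config[["E"]], config[["E"]]) / 2
  data.frame(
    label = gamete_labels,
    content = c("normal_monocentric", "acrocentric_pair",
                "missing_genes", "duplicated_genes",
                "missing_genes", "duplicated_genes"),
    viable = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    balanced = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    fraction = frac,
    stringsAsFactors = FALSE
  )
}

#' Zygote classes formed by fertilisation with wild-type gametes
#'
#' Only viable gametes (classes I, II, IV and VI) can form zygotes. Class I
#' gives wild-type zygotes, class II balanced rearrangement heterozygotes
#' (both dosage-normal), and classes IV and VI the two reciprocal unbalanced
#' trisomic classes, which carry abnormal gene dosage and are expected to
#' abort or develop with severely reduced fitness.
#'
#' @param gametes A gamete table as returned by [gamete_distribution()].
#' @return A data frame with columns `label`, `dosage_normal` and `fraction`;
#'   `fraction` is conditional on fertilisable gametes and sums to 1.
#' @export
#' @examples
#' zygote_outcomes(gamete_distribution("fission"))
zygote_outcomes <- function(gametes) {
  stopifnot(is.data.frame(gametes),
            all(c("label", "viable", "fraction") %in% names(gametes)),
            abs(sum(gametes$fraction) - 1) < 1e-9)
  via <- function(lbl) {
    i <- match(lbl, gametes$label)
    if (is.na(i) || !gametes$viable[i]) 0 else gametes$fraction[i]
  }
  w <- c(wild_type = via("I"), balanced_heterozygote = via("II"),
         unbalanced_trisomic_a = via("IV"), unbalanced_trisomic_b = via("VI"))
  total <- sum(w)
  if (total <= 0) stop("no viable gametes: no zygotes can form")
  data.frame(
    label = names(w),
    dosage_normal = c(TRUE, TRUE, FALSE, FALSE),
    fraction = unname(w) / total,
    stringsAsFactors = FALSE
  )
}

#' Heterozygote fertility factor
#'
#' The fraction of a heterozygote's gametes with balanced (correct)
#' chromosome segregation — classes I and II. Under the default 50:50
#' attachment rule this is 0.5: half the gametes are balanced, a quarter
#' lack genes and a quarter carry duplications. This fraction, phi, is the
#' fertility of the heterozygote relative to the homozygotes and is the
#' single route by which the checkpoint combinatorics enter the population
#' model (via [fertility_to_doubling_time()]).
#'
#' @param gametes A gamete table as returned by [gamete_distribution()].
#' @return The balanced-gamete fraction, a number in `[0, 1]`.
#' @export
#' @examples
#' heterozygote_fertility_factor(gamete_distribution("fission"))  # 0.5
heterozygote_fertility_factor <- function(gametes) {
  stopifnot(is.data.frame(gametes),
            all(c("balanced", "fraction") %in% names(gametes)),
            abs(sum(gametes$fraction) - 1) < 1e-9)
  sum(gametes$fraction[gametes$balanced])
}

#' Convert a fertility factor into a heterozygote doubling time
#'
#' A heterozygote producing a fraction `phi` of balanced gametes reproduces
#' at `phi` times the homozygote rate, so its effective population doubling
#' time is `dt_hom / phi`. The default organism (10-week homozygote doubling
#' time, phi = 0.5) gives the canonical 20-week heterozygote doubling time;
#' a 20% fertility deficit (phi = 0.8) gives 12.5 weeks.
#'
#' @param dt_hom Homozygote doubling time in weeks (> 0).
#' @param phi Fertility factor in `(0, 1]`.
#' @return Heterozygote doubling time in weeks.
#' @export
#' @examples
#' fertility_to_doubling_time(10, 0.5)  # 20
#' fertility_to_doubling_time(10, 0.8)  # 12.5
fertility_to_doubling_time <- function(dt_hom, phi) {
  if (!is.numeric(dt_hom) || any(dt_hom <= 0))
    stop("`dt_hom` must be a positive doubling time in weeks")
  if (!is.numeric(phi) || any(phi <= 0) || any(phi > 1))
    stop("`phi` must lie in (0, 1]; phi = 0 (lethal rearrangement) is degenerate")
  dt_hom / phi
}
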