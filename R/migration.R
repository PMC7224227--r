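#' Migrant packet under threshold (excess-driven) migration
#'
#' Migration occurs only when the source niche is above its carrying
#' capacity: the excess `XS` (already removed from the source by the
#' capacity rescale) emigrates in proportion to the standing genotype
#' composition, and a per-genotype survival factor thins it:
#' `mg_i = XS * frac_i * sf_i`. The non-surviving remainder of the excess
#' dies in transit and leaves the system.
#'
#' @param xs Excess population above carrying capacity (>= 0).
#' @param gv Source genotype vector (used for composition only).
#' @param sf Length-3 per-genotype survival fractions in `[0, 1]`.
#' @return Length-3 migrant packet (individuals delivered per class).
#' @export
#' @examples
#' migrants_threshold(1000, genotype_vector(9000, 900, 100), rep(0.01, 3))
migrants_threshold <- function(xs, gv, sf) {
  stopifnot(xs >= 0, length(gv) == 3, length(sf) == 3,
            all(sf >= 0), all(sf <= 1))
  if (xs == 0 || sum(gv) <= 0) return(c(ww = 0, wv = 0, vv = 0))
  pk <- xs * (gv / sum(gv)) * sf
  names(pk) <- c("ww", "wv", "vv")
  pk
}

#' Migrant packet under density-dependent migration
#'
#' Emigration at a per-week rate proportional to how full the source niche
#' is: `mg_i = z_i * (N/AP) * sf_i * dt`, capped at the class size. The
#' survival factor is folded into the net rate, so the packet is what the
#' destination receives and what the source loses; it applies every active
#' step regardless of whether the source is at capacity.
#'
#' @param gv Source genotype vector.
#' @param ap Source carrying capacity (> 0).
#' @param sf Length-3 per-genotype survival fractions in `[0, 1]`.
#' @param dt Step size in weeks.
#' @return Length-3 migrant packet.
#' @export
#' @examples
#' migrants_density(genotype_vector(100, 0, 0), 1e5, rep(1e-6, 3), 0.5)
migrants_density <- function(gv, ap, sf, dt) {
  stopifnot(length(gv) == 3, ap > 0, length(sf) == 3,
            all(sf >= 0), all(sf <= 1), dt > 0)
  n <- sum(gv)
  if (n <= 0) return(c(ww = 0, wv = 0, vv = 0))
  pk <- pmin(gv * (n / ap) * sf * dt, gv)
  names(pk) <- c("ww", "wv", "vv")
  pk
}

#' Deliver a migrant packet between niches
#'
#' Adds the packet to the destination and, unless the packet was drawn from
#' an excess already removed from the source (threshold mode), subtracts it
#' from the source. Negative class sizes signal a bookkeeping bug and raise
#' an error.
#'
#' @param source_gv,dest_gv Source and destination genotype vectors.
#' @param packet Length-3 migrant packet.
#' @param from_excess If `TRUE` (threshold mode) the source is left
#'   untouched, because the emigrants were part of the excess removed during
#'   capacity enforcement.
#' @return List with elements `source` and `dest`, the updated vectors.
#' @export
#' @examples
#' apply_migration(genotype_vector(100, 10, 1), genotype_vector(0, 0, 0),
#'                 c(1, 0.1, 0.01))
apply_migration <- function(source_gv, dest_gv, packet, from_excess = FALSE) {
  stopifnot(length(source_gv) == 3, length(dest_gv) == 3, length(packet) == 3)
  if (any(packet < 0)) stop("negative migrant packet: bookkeeping bug")
  src <- source_gv
  if (!from_excess) {
    src <- source_gv - packet
    if (any(src < -1e-9 * pmax(source_gv, 1)))
      stop("migrant packet exceeds source class sizes: bookkeeping bug")
    src <- pmax(src, 0)
  }
  list(source = src, dest = dest_gv + packet)
}

# Internal: is migration active at `week` under the window list?
migration_active <- function(windows, week) {
  if (is.null(windows) || length(windows) == 0) return(TRUE)
  for (w in windows) if (week >= w[1] && week <= w[2]) return(TRUE)
  FALSE
}
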