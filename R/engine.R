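#' Run a scenario
#'
#' Deterministically propagates the genotype classes of one or two niches
#' through time. Each step, per niche and in order: (1) per-step growth
#' factors from the niche's growth law, (2) multiplicative growth of each
#' class, (3) Hardy-Weinberg redistribution of the whole population,
#' (4) capacity enforcement for the exponential law (excess recorded and all
#' classes rescaled proportionally, which leaves allele frequencies
#' untouched), then (5) migrant packets are computed (threshold mode draws
#' from the excess; density mode from the standing classes) and (6)
#' delivered to the opposite niche after its own capacity enforcement, so a
#' full destination can sit slightly above capacity. Event clocks: `Ta` is
#' the first week at which the post-growth, pre-rescale total reaches the
#' carrying capacity; a genotype set is extinct at the first week every
#' class in it is strictly below the extinction threshold (variant: `wv`
#' and `vv`; wild-type: `ww` and `wv`); steady state is the first week from
#' which every class's relative change stays below `rel_tol` for `window`
#' consecutive steps. Event times are reported as `step * dt` with no
#' interpolation. There is no randomness anywhere: two runs of the same
#' scenario are bit-identical.
#'
#' @param scn A `karyo_scenario` (see [scenario()], [load_scenario()]).
#' @param dt,horizon Optional overrides of the scenario's step size and
#'   horizon, in weeks.
#' @return A list of class `karyo_run` with elements
#'   \describe{
#'     \item{trajectory}{data frame: `week`, `niche`, `z_ww`, `z_wv`,
#'       `z_vv`, `n_total`, `q` (one block per niche, week 0 included).}
#'     \item{events}{per niche: `ta_weeks`, `te_variant_weeks`,
#'       `te_wildtype_weeks`, `t085_weeks`; plus the global
#'       `steady_state_weeks`.}
#'     \item{ledger}{data frame of per-step mass bookkeeping: post-growth
#'       total, capacity excess, emigrants subtracted, immigrants delivered
#'       and migration deaths, per niche.}
#'     \item{final_state}{list of genotype vectors, one per niche.}
#'   }
#' @export
#' @examples
#' scn <- scenario(niche_spec(c(10000, 100, 0.2), c(ww = 10), 0.01),
#'                 horizon = 260)
#' run <- run_scenario(scn)
#' run$events[[1]]$ta_weeks   # 39
run_scenario <- function(scn, dt = NULL, horizon = NULL) {
  validate_scenario(scn)
  if (!is.null(dt)) scn$dt <- dt
  if (!is.null(horizon)) scn$horizon <- horizon
  validate_scenario(scn)
  dt <- scn$dt
  n_steps <- as.integer(round(scn$horizon / dt))
  nn <- length(scn$niches)
  thr <- scn$extinction_threshold

  params <- lapply(scn$niches, function(nc)
    list(dt3 = unname(nc$doubling_times), d3 = unname(nc$death_rates),
         growth = nc$growth, ap = nc$carrying_capacity, dr_ss = nc$dr_ss))
  z <- vapply(scn$niches, function(nc) unname(nc$initial), numeric(3))

  # trajectory records: (n_steps + 1) rows per niche, week 0 first
  traj <- array(NA_real_, dim = c(n_steps + 1L, 5L, nn))
  for (k in seq_len(nn)) {
    nk <- sum(z[, k])
    traj[1L, , k] <- c(z[, k], nk,
                       if (nk > 0) (z[2, k] + 2 * z[3, k]) / (2 * nk) else NA_real_)
  }
  led <- array(0, dim = c(n_steps, 5L, nn))  # n_grown, xs, emig, imm, mig_deaths

  ta <- rep(NA_real_, nn); te_var <- rep(NA_real_, nn); te_wt <- rep(NA_real_, nn)
  mg <- scn$migration
  two_way <- mg$mode != "none" && mg$direction == "two_way"

  for (s in seq_len(n_steps)) {
    wk <- s * dt
    xs <- numeric(nn)
    for (k in seq_len(nn)) {
      pk <- params[[k]]
      f <- step_factors(pk, sum(z[, k]), dt)
      zk <- z[, k] * f
      n_grown <- sum(zk)
      led[s, 1L, k] <- n_grown
      if (n_grown > 0) {
        q <- (zk[2] + 2 * zk[3]) / (2 * n_grown)
        p <- 1 - q
        zk <- n_grown * c(p * p, 2 * p * q, q * q)
      }
      if (is.na(ta[k]) && n_grown >= pk$ap) ta[k] <- wk
      if (pk$growth == "exponential" && n_grown > pk$ap) {
        xs[k] <- n_grown - pk$ap
        zk <- zk * (pk$ap / n_grown)
      }
      led[s, 2L, k] <- xs[k]
      z[, k] <- zk
    }

    if (mg$mode != "none" && migration_active(mg$windows, wk)) {
      packets <- vector("list", nn)
      if (mg$mode == "threshold") {
        packets[[1]] <- migrants_threshold(xs[1], z[, 1], mg$sf)
        if (two_way) packets[[2]] <- migrants_threshold(xs[2], z[, 2], mg$sf_reverse)
        for (k in seq_len(nn)) {
          delivered <- if (is.null(packets[[k]])) 0 else sum(packets[[k]])
          led[s, 5L, k] <- xs[k] - delivered
        }
      } else {
        packets[[1]] <- migrants_density(z[, 1], params[[1]]$ap, mg$sf, dt)
        if (two_way) packets[[2]] <- migrants_density(z[, 2], params[[2]]$ap,
                                                      mg$sf_reverse, dt)
      }
      from_excess <- mg$mode == "threshold"
      for (k in seq_len(nn)) {
        if (is.null(packets[[k]]) || sum(packets[[k]]) == 0) next
        dest <- if (k == 1L) 2L else 1L
        moved <- apply_migration(z[, k], z[, dest], packets[[k]],
                                 from_excess = from_excess)
        z[, k] <- moved$source
        z[, dest] <- moved$dest
        led[s, 3L, k] <- led[s, 3L, k] + if (from_excess) 0 else sum(packets[[k]])
        led[s, 4L, dest] <- led[s, 4L, dest] + sum(packets[[k]])
      }
    } else if (mg$mode == "threshold") {
      # excess dies unspent when migration is inactive
      for (k in seq_len(nn)) led[s, 5L, k] <- xs[k]
    }

    for (k in seq_len(nn)) {
      zk <- z[, k]
      nk <- sum(zk)
      traj[s + 1L, , k] <- c(zk, nk,
                             if (nk > 0) (zk[2] + 2 * zk[3]) / (2 * nk) else NA_real_)
      if (is.na(te_var[k]) && zk[2] < thr && zk[3] < thr) te_var[k] <- wk
      if (is.na(te_wt[k]) && zk[1] < thr && zk[2] < thr) te_wt[k] <- wk
      if (any(zk < 0)) stop("negative class size at week ", wk, ": internal error")
    }
  }

  weeks <- c(0, seq_len(n_steps) * dt)
  trajectory <- do.call(rbind, lapply(seq_len(nn), function(k)
    data.frame(week = weeks, niche = k,
               z_ww = traj[, 1, k], z_wv = traj[, 2, k], z_vv = traj[, 3, k],
               n_total = traj[, 4, k], q = traj[, 5, k])))
  ledger <- do.call(rbind, lapply(seq_len(nn), function(k)
    data.frame(week = seq_len(n_steps) * dt, niche = k,
               n_grown = led[, 1, k], xs = led[, 2, k],
               emigrants = led[, 3, k], immigrants = led[, 4, k],
               migration_deaths = led[, 5, k])))

  state <- do.call(cbind, lapply(seq_len(nn), function(k) traj[, 1:3, k]))
  ss_week <- detect_steady_state(state, dt = dt,
                                 rel_tol = scn$steady_state$rel_tol,
                                 window = scn$steady_state$window)
  events <- lapply(seq_len(nn), function(k) list(
    ta_weeks = ta[k], te_variant_weeks = te_var[k], te_wildtype_weeks = te_wt[k],
    t085_weeks = t_frac_internal(traj[, 4, k], weeks, 0.85)
  ))
  out <- list(scenario = scn, trajectory = trajectory, events = events,
              steady_state_weeks = ss_week, ledger = ledger,
              final_state = lapply(seq_len(nn), function(k)
                stats::setNames(z[, k], c("ww", "wv", "vv"))),
              dt = dt, n_steps = n_steps)
  class(out) <- "karyo_run"
  out
}

t_frac_internal <- function(n_tot, weeks, theta) {
  asym <- n_tot[length(n_tot)]
  if (!is.finite(asym) || asym <= 0) return(NA_real_)
  i <- which(n_tot >= theta * asym)[1]
  if (is.na(i)) NA_real_ else weeks[i]
}

#' Week at which a niche first reaches a fraction of its asymptote
#'
#' The asymptotic population is taken as the niche total at the end of the
#' run (for exponential-capped runs that have reached capacity this equals
#' the carrying capacity).
#'
#' @param run A `karyo_run`.
#' @param theta Fraction of the asymptote (default 0.85).
#' @param niche Niche index.
#' @return Week, or `NA` if never reached.
#' @export
time_to_fraction <- function(run, theta = 0.85, niche = 1) {
  stopifnot(inherits(run, "karyo_run"), theta > 0, theta <= 1)
  tr <- run$trajectory[run$trajectory$niche == niche, ]
  t_frac_internal(tr$n_total, tr$week, theta)
}

#' Detect the onset of steady state
#'
#' Earliest week from which `max_i |dZ_i| / max(Z_i, 1) < rel_tol` holds for
#' `window` consecutive steps, over every genotype class of every niche.
#' The `max(Z_i, 1)` floor makes the criterion absolute for classes that
#' have dwindled below one individual, so populations decaying towards zero
#' do eventually count as steady.
#'
#' @param state Either a `karyo_run` or a numeric matrix of class sizes with
#'   one row per recorded step.
#' @param dt Step size in weeks (ignored when `state` is a `karyo_run`).
#' @param rel_tol Relative-change tolerance.
#' @param window Number of consecutive quiet steps required.
#' @return Week of steady-state onset, or `NA` if never reached.
#' @export
detect_steady_state <- function(state, dt = 0.5, rel_tol = 1e-9, window = 20L) {
  if (inherits(state, "karyo_run")) {
    run <- state
    dt <- run$dt
    nn <- length(run$final_state)
    state <- do.call(cbind, lapply(seq_len(nn), function(k) {
      tr <- run$trajectory[run$trajectory$niche == k, ]
      as.matrix(tr[, c("z_ww", "z_wv", "z_vv")])
    }))
  }
  state <- as.matrix(state)
  if (nrow(state) < 2) return(0)
  d <- abs(state[-1, , drop = FALSE] - state[-nrow(state), , drop = FALSE]) /
    pmax(state[-1, , drop = FALSE], 1)
  quiet <- apply(d, 1, max) < rel_tol
  if (all(quiet)) return(0)
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= window)
  # steady state must persist to the end of the record to count as reached
  ok <- ok[ends[ok] == length(quiet)]
  if (!length(ok)) return(NA_real_)
  starts[ok[1]] * dt
}

#' @export
print.karyo_run <- function(x, ...) {
  cat("<karyo_run>", if (!is.null(x$scenario$name)) x$scenario$name else "", "\n")
  cat(sprintf("  %d steps of %g wk (%g wk horizon), %d niche(s)\n",
              x$n_steps, x$dt, x$n_steps * x$dt, length(x$final_state)))
  for (k in seq_along(x$events)) {
    ev <- x$events[[k]]
    fs <- x$final_state[[k]]
    cat(sprintf("  niche %d: Ta = %s wk, Te(variant) = %s wk, Te(wild-type) = %s wk\n",
                k, format(ev$ta_weeks), format(ev$te_variant_weeks),
                format(ev$te_wildtype_weeks)))
    cat(sprintf("           final (ww, wv, vv) = (%.6g, %.6g, %.6g)\n",
                fs[1], fs[2], fs[3]))
  }
  cat("  steady state:", format(x$steady_state_weeks), "wk\n")
  invisible(x)
}

#' Plot the class trajectories of a run
#'
#' One panel per niche, log10 population size against weeks, one line per
#' genotype class.
#'
#' @param x A `karyo_run`.
#' @param log Use a log10 population axis (default `TRUE`).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.karyo_run <- function(x, log = TRUE, ...) {
  nn <- length(x$final_state)
  op <- graphics::par(mfrow = c(1, nn))
  on.exit(graphics::par(op))
  for (k in seq_len(nn)) {
    tr <- x$trajectory[x$trajectory$niche == k, ]
    y <- as.matrix(tr[, c("z_ww", "z_wv", "z_vv")])
    if (log) y <- log10(pmax(y, 1e-3))
    graphics::matplot(tr$week, y, type = "l", lty = 1,
                      col = c("black", "red", "blue"),
                      xlab = "weeks",
                      ylab = if (log) "log10 population" else "population",
                      main = paste("niche", k), ...)
    graphics::legend("bottomright", c("ww", "wv", "vv"), lty = 1,
                     col = c("black", "red", "blue"), bty = "n")
  }
  invisible(x)
}
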