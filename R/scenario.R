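expand3 <- function(x, what) {
  if (is.list(x)) x <- unlist(x)
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) stop("`", what, "` must have 1 or 3 elements")
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    if (!setequal(names(x), c("ww", "wv", "vv")))
      stop("`", what, "` names must be ww, wv, vv")
    x <- x[c("ww", "wv", "vv")]
  }
  out <- as.numeric(x)
  names(out) <- c("ww", "wv", "vv")
  out
}

#' Specify one ecological niche
#'
#' Bundles a niche's initial genotype classes, demographic parameters and
#' growth law. The heterozygote doubling time defaults to the homozygote
#' time divided by the fertility factor `phi` (so the canonical organism —
#' 10-week homozygotes, phi = 0.5 — gets 20-week heterozygotes), and the
#' heterozygote death rate defaults to the dominance rule of
#' [resolve_het_death()].
#'
#' @param initial Initial class sizes `(ww, wv, vv)`.
#' @param doubling_times Doubling times in weeks: `ww` required; `vv`
#'   defaults to `ww`; `wv` defaults to `ww / phi`. A named vector/list or a
#'   length-3 vector `(ww, wv, vv)`.
#' @param death_rates Death rates per week: a scalar (all classes), or named
#'   `ww`/`vv` (+ optional `wv` override), or a length-3 vector.
#' @param dominance `"dominant"` or `"recessive"`; sets the heterozygote
#'   death rate when not given explicitly.
#' @param growth `"exponential"`, `"gompertz"` or `"logistic"`.
#' @param carrying_capacity Carrying capacity AP of the niche.
#' @param dr_ss Optional scalar steady-state death rate for the Gompertz law;
#'   `NULL` means each class uses its own birth rate `ln2/DT`.
#' @param phi Heterozygote fertility factor in `(0, 1]`, used only to
#'   default `doubling_times["wv"]`.
#' @return A list of class `karyo_niche`.
#' @export
#' @examples
#' niche_spec(c(10000, 100, 0.2), doubling_times = c(ww = 10), death_rates = 0.01)
niche_spec <- function(initial, doubling_times, death_rates,
                       dominance = c("dominant", "recessive"),
                       growth = c("exponential", "gompertz", "logistic"),
                       carrying_capacity = 1e5, dr_ss = NULL, phi = 0.5) {
  dominance <- match.arg(dominance)
  growth <- match.arg(growth)
  defaults <- character()
  if (!is.numeric(phi) || length(phi) != 1 || phi <= 0 || phi > 1)
    stop("`phi` must be a single number in (0, 1]")

  init <- expand3(initial, "initial")
  if (any(init < 0)) stop("initial class sizes must be non-negative")

  dtm <- if (is.list(doubling_times)) unlist(doubling_times) else doubling_times
  if (is.null(names(dtm)) && length(dtm) == 3) names(dtm) <- c("ww", "wv", "vv")
  if (is.null(names(dtm)) && length(dtm) == 1) names(dtm) <- "ww"
  if (!"ww" %in% names(dtm)) stop("`doubling_times` must include `ww`")
  dt_ww <- as.numeric(dtm[["ww"]])
  if (is.na(dt_ww) || dt_ww <= 0) stop("doubling times must be > 0")
  dt_vv <- if ("vv" %in% names(dtm)) as.numeric(dtm[["vv"]]) else {
    defaults <- c(defaults, "doubling_times.vv"); dt_ww
  }
  dt_wv <- if ("wv" %in% names(dtm)) as.numeric(dtm[["wv"]]) else {
    defaults <- c(defaults, "doubling_times.wv")
    fertility_to_doubling_time(dt_ww, phi)
  }
  dt3 <- c(ww = dt_ww, wv = dt_wv, vv = dt_vv)
  if (any(dt3 <= 0)) stop("doubling times must be > 0")

  dr <- if (is.list(death_rates)) unlist(death_rates) else death_rates
  if (is.null(names(dr)) && length(dr) == 3) names(dr) <- c("ww", "wv", "vv")
  if (is.null(names(dr)) && length(dr) == 1) dr <- c(ww = dr, vv = dr)
  if (!all(c("ww", "vv") %in% names(dr)))
    stop("`death_rates` must include `ww` and `vv` (or be a single rate)")
  d_ww <- as.numeric(dr[["ww"]]); d_vv <- as.numeric(dr[["vv"]])
  d_wv <- if ("wv" %in% names(dr)) as.numeric(dr[["wv"]]) else {
    defaults <- c(defaults, "death_rates.wv")
    resolve_het_death(d_ww, d_vv, dominance)
  }
  d3 <- c(ww = d_ww, wv = d_wv, vv = d_vv)
  if (any(d3 < 0)) stop("death rates must be >= 0")

  if (!is.numeric(carrying_capacity) || carrying_capacity <= 1)
    stop("`carrying_capacity` must be > 1")
  if (!is.null(dr_ss) && (!is.numeric(dr_ss) || length(dr_ss) != 1 || dr_ss < 0))
    stop("`dr_ss` must be NULL or a single non-negative rate")

  structure(list(initial = init, doubling_times = dt3, death_rates = d3,
                 dominance = dominance, growth = growth,
                 carrying_capacity = as.numeric(carrying_capacity),
                 dr_ss = dr_ss, phi = phi, defaults = defaults),
            class = "karyo_niche")
}

#' Specify migration between two niches
#'
#' @param mode `"none"`, `"threshold"` (excess-driven, see
#'   [migrants_threshold()]) or `"density"` (see [migrants_density()]).
#' @param direction `"one_way_1to2"` or `"two_way"`.
#' @param sf Per-genotype survival fractions for migration from niche 1 to
#'   niche 2: scalar or `(ww, wv, vv)`, each in `[0, 1]`.
#' @param sf_reverse Survival fractions for the reverse direction (two-way
#'   mode); defaults to `sf`.
#' @param windows List of `c(start, end)` week intervals during which
#'   migration is active; default always active. Must be sorted and
#'   non-overlapping.
#' @return A list of class `karyo_migration`.
#' @export
#' @examples
#' migration_spec("threshold", sf = 0.01)
migration_spec <- function(mode = c("none", "threshold", "density"),
                           direction = c("one_way_1to2", "two_way"),
                           sf = NULL, sf_reverse = NULL,
                           windows = list(c(0, Inf))) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "none") {
    return(structure(list(mode = "none", direction = direction,
                          sf = NULL, sf_reverse = NULL, windows = list()),
                     class = "karyo_migration"))
  }
  if (is.null(sf)) stop("`sf` is required when migration is active")
  sf <- expand3(sf, "sf")
  if (any(sf < 0) || any(sf > 1)) stop("`sf` must lie in [0, 1]")
  if (direction == "two_way") {
    sf_reverse <- if (is.null(sf_reverse)) sf else expand3(sf_reverse, "sf_reverse")
    if (any(sf_reverse < 0) || any(sf_reverse > 1))
      stop("`sf_reverse` must lie in [0, 1]")
  } else sf_reverse <- NULL
  if (!is.list(windows)) stop("`windows` must be a list of c(start, end)")
  windows <- lapply(windows, function(w) {
    w <- as.numeric(w)
    if (length(w) != 2 || w[1] > w[2]) stop("each window must be c(start, end) with start <= end")
    w
  })
  if (length(windows) > 1) {
    starts <- vapply(windows, `[`, 0, 1)
    ends <- vapply(windows, `[`, 0, 2)
    if (is.unsorted(starts) || any(starts[-1] <= ends[-length(ends)]))
      stop("`windows` must be sorted and non-overlapping")
  }
  structure(list(mode = mode, direction = direction, sf = sf,
                 sf_reverse = sf_reverse, windows = windows),
            class = "karyo_migration")
}

#' Assemble a simulation scenario
#'
#' @param niches A `karyo_niche` or list of one or two of them.
#' @param migration A [migration_spec()]; only meaningful with two niches.
#' @param dt Step size in weeks (default 0.5).
#' @param horizon Simulation horizon in weeks.
#' @param extinction_threshold A genotype set counts as extinct once every
#'   class in it is strictly below this many individuals (default 0.5).
#' @param steady_state List with `rel_tol` and `window`: the run is at
#'   steady state from the first step after which every class's relative
#'   change stays below `rel_tol` for `window` consecutive steps.
#' @param name,description Optional labels.
#' @return A list of class `karyo_scenario`.
#' @export
#' @examples
#' scn <- scenario(niche_spec(c(10000, 100, 0.2), c(ww = 10), 0.01),
#'                 horizon = 260)
scenario <- function(niches, migration = migration_spec("none"),
                     dt = 0.5, horizon = 520, extinction_threshold = 0.5,
                     steady_state = list(rel_tol = 1e-9, window = 20L),
                     name = NULL, description = NULL) {
  if (inherits(niches, "karyo_niche")) niches <- list(niches)
  x <- structure(list(name = name, description = description,
                      dt = dt, horizon = horizon,
                      extinction_threshold = extinction_threshold,
                      steady_state = steady_state,
                      niches = niches, migration = migration,
                      defaults = unlist(lapply(niches, `[[`, "defaults"))),
                 class = "karyo_scenario")
  validate_scenario(x)
}

#' Validate a scenario
#'
#' Checks every structural invariant a scenario must satisfy before the
#' engine will run it; returns the scenario invisibly-unchanged on success
#' and raises a field-level error otherwise.
#'
#' @param x A `karyo_scenario`.
#' @return `x`, invisibly usable.
#' @export
validate_scenario <- function(x) {
  if (!inherits(x, "karyo_scenario")) stop("not a karyo_scenario")
  if (!is.numeric(x$dt) || x$dt <= 0) stop("`dt` must be > 0")
  if (!is.numeric(x$horizon) || x$horizon <= 0) stop("`horizon` must be > 0")
  if (!is.numeric(x$extinction_threshold) || x$extinction_threshold <= 0)
    stop("`extinction_threshold` must be > 0")
  ss <- x$steady_state
  if (!is.list(ss) || is.null(ss$rel_tol) || is.null(ss$window) ||
      ss$rel_tol <= 0 || ss$window < 1)
    stop("`steady_state` must list rel_tol > 0 and window >= 1")
  if (!length(x$niches) %in% 1:2) stop("`niches` must hold 1 or 2 niches")
  for (i in seq_along(x$niches)) {
    nc <- x$niches[[i]]
    if (!inherits(nc, "karyo_niche")) stop("niche ", i, " is not a karyo_niche")
    if (any(nc$death_rates * x$dt >= 1))
      stop("niche ", i, ": death_rate * dt must be < 1")
    if (nc$phi <= 0)
      stop("niche ", i, ": phi = 0 is a lethal rearrangement; degenerate scenario")
  }
  mg <- x$migration
  if (!inherits(mg, "karyo_migration")) stop("`migration` is not a karyo_migration")
  if (mg$mode != "none" && length(x$niches) != 2)
    stop("active migration requires two niches")
  x
}

#' @export
print.karyo_scenario <- function(x, ...) {
  cat("<karyo_scenario>", if (!is.null(x$name)) x$name else "", "\n")
  cat(sprintf("  dt %.3g wk | horizon %g wk | extinction threshold %g\n",
              x$dt, x$horizon, x$extinction_threshold))
  for (i in seq_along(x$niches)) {
    nc <- x$niches[[i]]
    cat(sprintf("  niche %d [%s, AP %g]: Z0 = (%g, %g, %g); DT = (%g, %g, %g) wk; d = (%g, %g, %g)/wk; %s\n",
                i, nc$growth, nc$carrying_capacity,
                nc$initial[1], nc$initial[2], nc$initial[3],
                nc$doubling_times[1], nc$doubling_times[2], nc$doubling_times[3],
                nc$death_rates[1], nc$death_rates[2], nc$death_rates[3],
                nc$dominance))
  }
  if (x$migration$mode != "none") {
    cat(sprintf("  migration: %s, %s, sf = (%g, %g, %g)\n",
                x$migration$mode, x$migration$direction,
                x$migration$sf[1], x$migration$sf[2], x$migration$sf[3]))
    if (length(x$migration$windows))
      cat("  windows:", paste(vapply(x$migration$windows, function(w)
        sprintf("[%g, %g]", w[1], w[2]), ""), collapse = " "), "\n")
  }
  invisible(x)
}

scenario_keys <- list(
  top = c("schema", "name", "description", "dt", "horizon",
          "extinction_threshold", "steady_state", "niches", "migration",
          "unreproducible_absolute_times", "notes"),
  niche = c("initial", "doubling_times", "death_rates", "dominance",
            "growth", "carrying_capacity", "dr_ss", "phi"),
  migration = c("mode", "direction", "sf", "sf_reverse", "windows"),
  steady_state = c("rel_tol", "window")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
}

#' Read a scenario from a YAML file
#'
#' Parses and validates a declarative scenario file. Unknown keys are
#' rejected with field-level messages; omitted fields take the documented
#' defaults (dt 0.5 wk, carrying capacity 100,000, extinction threshold
#' 0.5), which are recorded in the returned object's `defaults` element.
#'
#' @param path Path to a YAML scenario file (see the files under
#'   `system.file("extdata", "scenarios", package = "karyosim")` for the
#'   schema).
#' @return A validated `karyo_scenario`.
#' @export
#' @examples
#' scn <- load_scenario(scenario_path("table1_sim01"))
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  check_keys(y, scenario_keys$top, basename(path))
  if (is.null(y$schema) || y$schema != 1)
    stop(basename(path), ": missing or unsupported `schema` (expected 1)")
  defaults <- character()
  take <- function(val, default, key) {
    if (is.null(val)) { defaults <<- c(defaults, key); default } else val
  }
  if (is.null(y$niches) || !length(y$niches)) stop("`niches` is required")
  niches <- lapply(seq_along(y$niches), function(i) {
    ny <- y$niches[[i]]
    check_keys(ny, scenario_keys$niche, paste0("niches[", i, "]"))
    if (is.null(ny$initial)) stop("niches[", i, "]: `initial` is required")
    if (is.null(ny$doubling_times)) stop("niches[", i, "]: `doubling_times` is required")
    if (is.null(ny$death_rates)) stop("niches[", i, "]: `death_rates` is required")
    nc <- niche_spec(
      initial = ny$initial,
      doubling_times = ny$doubling_times,
      death_rates = ny$death_rates,
      dominance = take(ny$dominance, "dominant", paste0("niches[", i, "].dominance")),
      growth = take(ny$growth, "exponential", paste0("niches[", i, "].growth")),
      carrying_capacity = take(ny$carrying_capacity, 1e5,
                               paste0("niches[", i, "].carrying_capacity")),
      dr_ss = ny$dr_ss,
      phi = take(ny$phi, 0.5, paste0("niches[", i, "].phi"))
    )
    if (length(nc$defaults))
      defaults <<- c(defaults, paste0("niches[", i, "].", nc$defaults))
    nc
  })
  mg <- if (is.null(y$migration)) {
    defaults <- c(defaults, "migration")
    migration_spec("none")
  } else {
    check_keys(y$migration, scenario_keys$migration, "migration")
    m <- y$migration
    migration_spec(
      mode = if (is.null(m$mode)) "none" else m$mode,
      direction = if (is.null(m$direction)) "one_way_1to2" else m$direction,
      sf = m$sf, sf_reverse = m$sf_reverse,
      windows = if (is.null(m$windows)) list(c(0, Inf)) else m$windows
    )
  }
  if (!is.null(y$steady_state))
    check_keys(y$steady_state, scenario_keys$steady_state, "steady_state")
  ssd <- list(rel_tol = 1e-9, window = 20L)
  ss <- if (is.null(y$steady_state)) { defaults <- c(defaults, "steady_state"); ssd
  } else utils::modifyList(ssd, y$steady_state)
  x <- scenario(
    niches = niches, migration = mg,
    dt = take(y$dt, 0.5, "dt"),
    horizon = take(y$horizon, 520, "horizon"),
    extinction_threshold = take(y$extinction_threshold, 0.5, "extinction_threshold"),
    steady_state = ss,
    name = y$name, description = y$description
  )
  x$defaults <- defaults
  x$unreproducible_absolute_times <- isTRUE(y$unreproducible_absolute_times)
  x
}

#' Write a scenario to a YAML file
#'
#' Serialises the fully resolved scenario (all defaults made explicit), so
#' that parse -> serialise -> parse is the identity on every model field.
#'
#' @param x A `karyo_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(x, path) {
  validate_scenario(x)
  as3 <- function(v) as.list(stats::setNames(as.numeric(v), c("ww", "wv", "vv")))
  y <- list(schema = 1L, name = x$name, description = x$description,
            dt = x$dt, horizon = x$horizon,
            extinction_threshold = x$extinction_threshold,
            steady_state = list(rel_tol = x$steady_state$rel_tol,
                                window = as.integer(x$steady_state$window)),
            niches = lapply(x$niches, function(nc) {
              out <- list(initial = as3(nc$initial),
                          doubling_times = as3(nc$doubling_times),
                          death_rates = as3(nc$death_rates),
                          dominance = nc$dominance, growth = nc$growth,
                          carrying_capacity = nc$carrying_capacity,
                          phi = nc$phi)
              if (!is.null(nc$dr_ss)) out$dr_ss <- nc$dr_ss
              out
            }))
  if (x$migration$mode != "none") {
    y$migration <- list(mode = x$migration$mode,
                        direction = x$migration$direction,
                        sf = as3(x$migration$sf))
    if (!is.null(x$migration$sf_reverse))
      y$migration$sf_reverse <- as3(x$migration$sf_reverse)
    y$migration$windows <- lapply(x$migration$windows, as.numeric)
  }
  y <- y[!vapply(y, is.null, TRUE)]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' List the installed benchmark scenarios
#'
#' The package ships a declarative scenario library covering the reference
#' simulation set: four benchmark families (`table1_sim01` ... `table4_sim7`)
#' and four trajectory scenarios (`fig5` ... `fig8`).
#'
#' @return Character vector of scenario names usable with [scenario_path()].
#' @export
#' @examples
#' scenario_library()
scenario_library <- function() {
  dir <- system.file("extdata", "scenarios", package = "karyosim")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Path to an installed benchmark scenario
#'
#' @param name A scenario name from [scenario_library()].
#' @return Absolute path to the YAML file.
#' @export
scenario_path <- function(name) {
  p <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                   package = "karyosim")
  if (!nzchar(p)) stop("no installed scenario named '", name,
                       "'; see scenario_library()")
  p
}

#' Generate a random valid scenario
#'
#' Deterministic in `seed`; used for property testing. Parameters are drawn
#' from documented ranges: homozygote doubling times in \[1, 50\] weeks,
#' fertility factor phi in \[0.5, 1\] (heterozygote doubling time derived),
#' death rates in \[0, 0.06\]/week, initial totals in \[10, 1e5\] and
#' variant-allele frequency q0 in \[0, 1\] (classes seeded at Hardy-Weinberg
#' proportions). Two-niche scenarios get threshold or density migration with
#' survival factors in \[1e-4, 1\]. The caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @return A validated `karyo_scenario`.
#' @export
#' @examples
#' random_scenario(1)
random_scenario <- function(seed) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  rnniche <- function(growth) {
    dt_ww <- stats::runif(1, 1, 50)
    phi <- stats::runif(1, 0.5, 1)
    d <- stats::runif(1, 0, 0.06)
    n0 <- 10^stats::runif(1, 1, 5)
    q0 <- stats::runif(1)
    niche_spec(
      initial = n0 * c((1 - q0)^2, 2 * q0 * (1 - q0), q0^2),
      doubling_times = c(ww = dt_ww),
      death_rates = d, growth = growth, phi = phi
    )
  }
  two <- stats::runif(1) < 0.5
  if (!two) {
    scenario(rnniche("exponential"), horizon = 100,
             name = sprintf("random_%d", seed))
  } else {
    mode <- sample(c("threshold", "density"), 1)
    growth <- if (mode == "threshold") "exponential"
              else sample(c("exponential", "logistic"), 1)
    mg <- migration_spec(mode,
                         direction = sample(c("one_way_1to2", "two_way"), 1),
                         sf = 10^stats::runif(3, -4, 0))
    scenario(list(rnniche(growth), rnniche(growth)), migration = mg,
             horizon = 100, name = sprintf("random_%d", seed))
  }
}
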