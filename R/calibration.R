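#' Incubation observation set
#'
#' Holds dated observations of CO2-C efflux (rate and cumulative) and of the
#' chemical pools C1 (total Van Soest solubles) and C2 (acid hydrolysable),
#' as monitored in the 112-day microcosm incubations: CO2 on days 3, 7, 10,
#' 14, 21, 29, 36, 42, 51, 57, 70, 80, 87, 95 and 112; chemistry on days 0,
#' 14, 36, 57 and 112.  Arbitrary day grids are accepted.
#'
#' @param co2_days days of CO2 measurement (strictly increasing).
#' @param co2_rate respiration rate (mgC/kg soil/day) at `co2_days`.
#' @param cum_co2 cumulative CO2-C efflux (mgC/kg soil) at `co2_days`;
#'   must be nondecreasing.
#' @param chem_days days of chemical characterization.
#' @param c1 total soluble pool (C1D + C1T, mgC/kg soil) at `chem_days`.
#' @param c2 acid hydrolysable pool (mgC/kg soil) at `chem_days`.
#' @return An object of class `gdm_observations`.
#' @seealso [generate_observations()], [read_gdm_observations()]
#' @export
gdm_observations <- function(co2_days, co2_rate, cum_co2,
                             chem_days, c1, c2) {
  obs <- list(co2_days = as.numeric(co2_days),
              co2_rate = as.numeric(co2_rate),
              cum_co2 = as.numeric(cum_co2),
              chem_days = as.numeric(chem_days),
              c1 = as.numeric(c1), c2 = as.numeric(c2))
  if (length(obs$co2_rate) != length(obs$co2_days) ||
      length(obs$cum_co2) != length(obs$co2_days))
    stop("CO2 series must match co2_days in length")
  if (length(obs$c1) != length(obs$chem_days) ||
      length(obs$c2) != length(obs$chem_days))
    stop("chemistry series must match chem_days in length")
  if (is.unsorted(obs$co2_days, strictly = TRUE) ||
      is.unsorted(obs$chem_days, strictly = TRUE))
    stop("observation days must be strictly increasing")
  if (is.unsorted(obs$cum_co2))
    stop("cumulative CO2 must be nondecreasing")
  if (any(unlist(obs) < 0)) stop("observations must be >= 0")
  class(obs) <- "gdm_observations"
  obs
}

#' @export
print.gdm_observations <- function(x, ...) {
  cat("Incubation observation set:", length(x$co2_days),
      "CO2 days (", min(x$co2_days), "-", max(x$co2_days), "),",
      length(x$chem_days), "chemistry days\n")
  cat(sprintf("  final cumulative CO2: %.1f mgC/kg; final C1: %.1f; final C2: %.1f\n",
              x$cum_co2[length(x$cum_co2)], x$c1[length(x$c1)],
              x$c2[length(x$c2)]))
  invisible(x)
}

DEFAULT_CO2_DAYS <- c(3, 7, 10, 14, 21, 29, 36, 42, 51, 57, 70, 80, 87, 95, 112)
DEFAULT_CHEM_DAYS <- c(0, 14, 36, 57, 112)

#' Root-mean-square error normalized by the observation mean
#'
#' `sqrt(mean((obs - sim)^2)) / mean(obs)`.  Streams with zero observation
#' mean cannot be normalized and yield `NA` with a warning.
#'
#' @param obs,sim numeric vectors of equal length.
#' @return Normalized RMSE (unitless).
#' @export
normalized_rmse <- function(obs, sim) {
  stopifnot(length(obs) == length(sim), length(obs) >= 1)
  m <- mean(obs)
  if (m == 0) {
    warning("observation mean is zero; stream skipped")
    return(NA_real_)
  }
  sqrt(mean((obs - sim)^2)) / m
}

# simulated streams at the observation days of `obs`
simulated_streams <- function(params, obs, dt = 0.1) {
  days <- sort(unique(c(0, obs$co2_days, obs$chem_days)))
  tr <- gdm_simulate(params, t_end = max(days), dt = dt, output_days = days)
  ico2 <- match(obs$co2_days, tr$day)
  ichem <- match(obs$chem_days, tr$day)
  list(co2_rate = tr$resp_rate[ico2],
       cum_co2 = tr$cum_co2[ico2],
       c1 = tr$c1d[ichem] + tr$c1t[ichem],
       c2 = tr$c2[ichem])
}

#' Calibration objective: sum of normalized RMSEs over four streams
#'
#' Runs the simulation at the supplied free-parameter values and returns the
#' sum of the normalized RMSEs between observed and simulated CO2 efflux
#' rate, cumulative CO2, and the C1 and C2 pools, each evaluated at its
#' observation days (simulated C1 is compared as C1D + C1T).  A failed
#' simulation returns a large finite penalty.
#'
#' @param free named numeric vector of free parameter values (subset of the
#'   parameter names, e.g. `c(lci_t = 0.4, k_b22 = 25)`).
#' @param params the fixed [gdm_params()] object.
#' @param obs a [gdm_observations()] set.
#' @param dt Euler step used for the simulations (days).
#' @return Objective value (unitless), or the per-stream breakdown if
#'   `breakdown = TRUE`.
#' @param breakdown return the four per-stream normalized RMSEs as well.
#' @export
gdm_objective <- function(free, params, obs, dt = 0.1, breakdown = FALSE) {
  p <- try(do.call(update_params, c(list(params), as.list(free))),
           silent = TRUE)
  if (inherits(p, "try-error")) return(if (breakdown) NULL else 1e6)
  sim <- try(simulated_streams(p, obs, dt), silent = TRUE)
  if (inherits(sim, "try-error")) return(if (breakdown) NULL else 1e6)
  streams <- c("co2_rate", "cum_co2", "c1", "c2")
  nr <- vapply(streams, function(s) normalized_rmse(obs[[s]], sim[[s]]),
               numeric(1))
  if (breakdown) return(list(value = sum(nr, na.rm = TRUE), streams = nr))
  sum(nr, na.rm = TRUE)
}

#' Calibrate genotype-specific parameters against observations
#'
#' Bounded local minimization (L-BFGS-B) of the [gdm_objective()] with
#' seeded multi-start: the first start is `start` (defaults to the current
#' values in `params`), the remaining `n_starts - 1` are drawn uniformly
#' within the bounds.  The two parameters calibrated by default, `lci_t`
#' (the LCI threshold switching on lignin decay) and `k_b22` (guild 2's
#' access to holocellulose), are the ones that vary with litter chemistry.
#'
#' Default bounds: `lci_t` in `[LCI(day 0) + 0.01, lci_max - 0.01]` (a
#' threshold below the initial LCI would switch C3 decay on at day 0) and
#' `k_b22` in `[1, 100]`.
#'
#' @param obs a [gdm_observations()] set.
#' @param params a [gdm_params()] object holding all fixed parameters and
#'   initial pools.
#' @param free names of the free parameters.
#' @param lower,upper named bounds for the free parameters (defaults above).
#' @param start named starting values; default the values in `params`,
#'   projected into the bounds.
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed integer seed for the random starts.
#' @param dt Euler step for the embedded simulations.
#' @param control passed to [stats::optim()].
#' @return An object of class `gdm_fit` with components `par` (best-fit
#'   values), `objective`, `streams` (per-stream normalized RMSEs at the
#'   optimum), `convergence`, `starts` (per-start results), `params`
#'   (updated parameter set), `obs`, `bounds`.
#' @examples
#' p <- gdm_genotype("F2")
#' obs <- generate_observations(p, noise_cv = 0, seed = 1)
#' fit <- gdm_calibrate(obs, update_params(p, lci_t = 0.5, k_b22 = 50),
#'                      n_starts = 1)
#' coef(fit)
#' @export
gdm_calibrate <- function(obs, params, free = c("lci_t", "k_b22"),
                          lower = NULL, upper = NULL, start = NULL,
                          n_starts = 5, seed = 1, dt = 0.1,
                          control = list()) {
  stopifnot(inherits(obs, "gdm_observations"),
            inherits(params, "gdm_params"), n_starts >= 1)
  lci0 <- compute_lci(params$c2, params$c3)
  def_lower <- c(lci_t = lci0 + 0.01, k_b22 = 1)
  def_upper <- c(lci_t = params$lci_max - 0.01, k_b22 = 100)
  pick_bound <- function(user, defs, nm, fallback) {
    if (!is.null(user) && nm %in% names(user)) return(user[[nm]])
    if (nm %in% names(defs)) return(unname(defs[nm]))
    fallback
  }
  lo <- vapply(free, function(nm) pick_bound(lower, def_lower, nm, -Inf),
               numeric(1))
  hi <- vapply(free, function(nm) pick_bound(upper, def_upper, nm, Inf),
               numeric(1))
  names(lo) <- names(hi) <- free
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("finite bounds required for: ",
         paste(free[!is.finite(lo) | !is.finite(hi)], collapse = ", "))
  if (any(lo >= hi)) stop("lower bounds must be below upper bounds")

  if (is.null(start)) start <- unlist(params[free])
  start <- pmin(pmax(start[free], lo), hi)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  starts <- matrix(rep(start, n_starts), nrow = n_starts, byrow = TRUE,
                   dimnames = list(NULL, free))
  if (n_starts > 1) {
    for (k in 2:n_starts) starts[k, ] <- runif(length(free), lo, hi)
  }

  runs <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    runs[[k]] <- optim(starts[k, ], gdm_objective, params = params,
                       obs = obs, dt = dt, method = "L-BFGS-B",
                       lower = lo, upper = hi,
                       control = modifyList(list(factr = 1e10), control))
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  # polish the winner at tighter tolerance
  best <- optim(best$par, gdm_objective, params = params, obs = obs,
                dt = dt, method = "L-BFGS-B", lower = lo, upper = hi,
                control = modifyList(list(factr = 1e7), control))
  bd <- gdm_objective(best$par, params, obs, dt = dt, breakdown = TRUE)
  fit <- list(par = best$par, objective = best$value,
              streams = bd$streams, convergence = best$convergence,
              counts = best$counts,
              starts = data.frame(starts, value = vals),
              start = start, bounds = list(lower = lo, upper = hi),
              params = do.call(update_params,
                               c(list(params), as.list(best$par))),
              obs = obs, dt = dt, seed = seed)
  class(fit) <- "gdm_fit"
  fit
}

#' @export
coef.gdm_fit <- function(object, ...) object$par

#' @export
print.gdm_fit <- function(x, ...) {
  cat("Calibrated guild decomposition model\n")
  cat("  best-fit:", paste(sprintf("%s = %.4g", names(x$par), x$par),
                           collapse = ", "), "\n")
  cat(sprintf("  objective (sum of normalized RMSEs): %.5g\n", x$objective))
  cat("  convergence code:", x$convergence, "(0 = converged);",
      nrow(x$starts), "start(s)\n")
  invisible(x)
}

#' @export
summary.gdm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.gdm_fit")
}

#' @export
print.summary.gdm_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  per-stream normalized RMSE:\n")
  for (s in names(f$streams))
    cat(sprintf("    %-9s %.5g\n", s, f$streams[s]))
  cat("  bounds:",
      paste(sprintf("%s in [%.4g, %.4g]", names(f$par),
                    f$bounds$lower, f$bounds$upper), collapse = "; "), "\n")
  cat("  start values and objectives:\n")
  print(f$starts, digits = 5)
  invisible(x)
}

#' Predict simulated streams or a trajectory from a calibrated model
#'
#' @param object a `gdm_fit`.
#' @param type `"streams"` for the four observation streams at the fitted
#'   observation days, `"trajectory"` for the full [gdm_simulate()] output.
#' @param ... unused.
#' @return A list of streams, or a `gdm_trajectory`.
#' @export
predict.gdm_fit <- function(object, type = c("streams", "trajectory"), ...) {
  type <- match.arg(type)
  if (type == "trajectory")
    return(gdm_simulate(object$params,
                        t_end = max(object$obs$co2_days, object$obs$chem_days),
                        dt = object$dt))
  simulated_streams(object$params, object$obs, object$dt)
}

#' @export
residuals.gdm_fit <- function(object, ...) {
  sim <- predict(object, "streams")
  list(co2_rate = object$obs$co2_rate - sim$co2_rate,
       cum_co2 = object$obs$cum_co2 - sim$cum_co2,
       c1 = object$obs$c1 - sim$c1,
       c2 = object$obs$c2 - sim$c2)
}

#' Plot observed versus simulated streams for a calibrated model
#'
#' @param x a `gdm_fit`.
#' @param ... passed to the base plot calls.
#' @return `x`, invisibly.
#' @export
plot.gdm_fit <- function(x, ...) {
  sim <- predict(x, "streams")
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  panels <- list(
    list(d = x$obs$co2_days, o = x$obs$co2_rate, s = sim$co2_rate,
         lab = "respiration (mgC/kg/d)"),
    list(d = x$obs$co2_days, o = x$obs$cum_co2, s = sim$cum_co2,
         lab = "cumulative CO2 (mgC/kg)"),
    list(d = x$obs$chem_days, o = x$obs$c1, s = sim$c1,
         lab = "C1 pool (mgC/kg)"),
    list(d = x$obs$chem_days, o = x$obs$c2, s = sim$c2,
         lab = "C2 pool (mgC/kg)"))
  for (pn in panels) {
    plot(pn$d, pn$o, xlab = "day", ylab = pn$lab,
         ylim = range(0, pn$o, pn$s), ...)
    lines(pn$d, pn$s)
  }
  invisible(x)
}

#' Simulate synthetic observation sets from a calibrated model
#'
#' Draws `nsim` observation sets at the fitted parameters using the
#' multiplicative noise model of [generate_observations()].
#'
#' @param object a `gdm_fit`.
#' @param nsim number of sets.
#' @param seed integer seed.
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param ... unused.
#' @return A list of [gdm_observations()] sets.
#' @export
simulate.gdm_fit <- function(object, nsim = 1, seed = 1, noise_cv = 0.05,
                             ...) {
  lapply(seq_len(nsim), function(k)
    generate_observations(object$params, noise_cv = noise_cv,
                          seed = seed + k - 1,
                          co2_days = object$obs$co2_days,
                          chem_days = object$obs$chem_days, dt = object$dt))
}

#' Goodness-of-fit statistics between a model and an observation set
#'
#' Per stream: coefficient of determination (squared Pearson correlation of
#' observed and simulated values) and the relative difference of the final
#' cumulative values, `(sim - obs) / obs`.
#'
#' @param params a [gdm_params()] object (or a `gdm_fit`, whose fitted
#'   parameters are used).
#' @param obs a [gdm_observations()] set.
#' @param dt Euler step.
#' @return A data frame with one row per stream: `stream`, `r2`,
#'   `final_rel_diff`.
#' @export
gdm_fit_statistics <- function(params, obs, dt = 0.1) {
  if (inherits(params, "gdm_fit")) params <- params$params
  sim <- simulated_streams(params, obs, dt)
  streams <- c("co2_rate", "cum_co2", "c1", "c2")
  r2 <- vapply(streams, function(s) {
    o <- obs[[s]]; m <- sim[[s]]
    if (stats::var(o) == 0 || stats::var(m) == 0) return(NA_real_)
    stats::cor(o, m)^2
  }, numeric(1))
  fin <- vapply(streams, function(s) {
    o <- obs[[s]][length(obs[[s]])]
    if (o == 0) return(NA_real_)
    (sim[[s]][length(sim[[s]])] - o) / o
  }, numeric(1))
  data.frame(stream = streams, r2 = r2, final_rel_diff = fin,
             row.names = NULL)
}
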