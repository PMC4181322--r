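#' Lignocellulose index
#'
#' `LCI = C3 / (C2 + C3)`: the acid non-hydrolysable ("lignin") share of the
#' structural litter carbon.  It rises as holocellulose (C2) decays and
#' throttles the decay rate coefficients of both structural pools.
#'
#' @param c2 acid hydrolysable pool (mgC/kg soil).
#' @param c3 acid non-hydrolysable pool (mgC/kg soil).
#' @return LCI in `[0, 1]`. Vectorized.
#' @examples
#' compute_lci(1238, 397)
#' @export
compute_lci <- function(c2, c3) {
  if (any(c2 < 0) || any(c3 < 0)) stop("pools must be >= 0")
  if (any(c2 + c3 <= 0)) stop("degenerate input: c2 + c3 must be > 0")
  c3 / (c2 + c3)
}

#' Effective decay rate coefficients under lignocellulose feedback
#'
#' `k2_effective` declines linearly with LCI from `k2max` at LCI 0, clamped
#' at zero, and is zero at and above `lci_max` (the LCI at which all decay
#' stops).  `k3_effective` is zero at and below the genotype threshold
#' `lci_t`, ramps linearly with slope `m3` above it (bounded by `k3max`),
#' and is zero again at and above `lci_max`.
#'
#' @param lci lignocellulose index in `[0, 1]`.
#' @param params a [gdm_params()] object.
#' @return Decay rate coefficient (1/day). Vectorized over `lci`.
#' @examples
#' p <- gdm_genotype("F2")
#' k2_effective(0, p)      # = k2max
#' k3_effective(0.42, p)   # 0 at the threshold
#' @export
k2_effective <- function(lci, params) {
  stopifnot(all(lci >= 0), all(lci <= 1))
  ifelse(lci >= params$lci_max, 0, pmax(0, params$m2 * lci + params$k2max))
}

#' @rdname k2_effective
#' @export
k3_effective <- function(lci, params) {
  stopifnot(all(lci >= 0), all(lci <= 1))
  ifelse(lci <= params$lci_t | lci >= params$lci_max, 0,
         pmin(params$k3max, params$m3 * (lci - params$lci_t)))
}

#' Reverse Michaelis-Menten decay flux
#'
#' Decay saturates in decomposer biomass rather than substrate:
#' `flux = k * C * B / (K + B)`.  The flux is bounded above by `k * C` and is
#' nondecreasing in `B`; with no biomass (and `K + B = 0`) there is no flux.
#'
#' @param k decay rate coefficient (1/day).
#' @param c substrate pool (mgC/kg soil).
#' @param b guild biomass (mgC/kg soil).
#' @param k_half half-saturation coefficient (mgC/kg soil).
#' @return Flux in mgC/kg soil/day. Vectorized.
#' @export
rmm_flux <- function(k, c, b, k_half) {
  if (any(c(k, c, b, k_half) < 0)) stop("rmm_flux: all inputs must be >= 0")
  den <- k_half + b
  ifelse(den <= 0, 0, k * c * b / den)
}

# Access matrix: rows = guilds 1..3, cols = pools c1d, c2, c3
GUILD_ACCESS <- matrix(c(TRUE, FALSE, FALSE,
                         TRUE, TRUE,  FALSE,
                         TRUE, TRUE,  TRUE),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(paste0("g", 1:3), c("c1d", "c2", "c3")))

#' Per-guild decay fluxes at a system state
#'
#' Applies the guild access rules (guild 1: C1D only; guild 2: C1D and C2;
#' guild 3: all pools) with the reverse Michaelis-Menten kinetics and the
#' LCI-dependent decay coefficients.  The persistent soluble pool C1T
#' receives no flux.
#'
#' @param state named state vector as produced by [gdm_step()] (fields
#'   `c1d`, `c1t`, `c2`, `c3`, `b1`, `b2`, `b3`, ...).
#' @param params a [gdm_params()] object.
#' @param lci_feedback if `FALSE`, freeze `k2 = k2max` and `k3 = k3max`
#'   (no lignocellulose feedback).
#' @return A 3 x 3 matrix of fluxes (mgC/kg soil/day), guilds x pools.
#' @export
pool_decay_fluxes <- function(state, params, lci_feedback = TRUE) {
  b <- c(state["b1"], state["b2"], state["b3"])
  if (lci_feedback) {
    den <- state[["c2"]] + state[["c3"]]
    if (den <= 0) {
      k2 <- 0; k3 <- 0
    } else {
      lci <- state[["c3"]] / den
      k2 <- k2_effective(lci, params)
      k3 <- k3_effective(lci, params)
    }
  } else {
    k2 <- params$k2max; k3 <- params$k3max
  }
  kh <- matrix(c(params$k_b11, NA, NA,
                 params$k_b11, params$k_b22, NA,
                 params$k_b11, params$k_b32, params$k_b33),
               nrow = 3, byrow = TRUE)
  kk <- c(params$k1max, k2, k3)
  cc <- c(state[["c1d"]], state[["c2"]], state[["c3"]])
  f <- matrix(0, 3, 3, dimnames = dimnames(GUILD_ACCESS))
  for (j in 1:3) for (i in 1:3) {
    if (GUILD_ACCESS[j, i]) f[j, i] <- rmm_flux(kk[i], cc[i], b[j], kh[j, i])
  }
  f
}

#' Complete a flux record with assimilation and respiration
#'
#' For each (guild, pool) decay flux, `e_i` of the carbon is assimilated by
#' the consuming guild and `1 - e_i` is lost as growth respiration; each
#' guild additionally respires `g * B_j` as basal maintenance.  Microbial
#' production is the difference between total carbon released from
#' substrates and total respiration.
#'
#' @param fluxes 3 x 3 guild-by-pool decay flux matrix from
#'   [pool_decay_fluxes()].
#' @param state named state vector (for guild biomass).
#' @param params a [gdm_params()] object.
#' @return A list with elements `decay` (the input matrix), `assimilated`
#'   and `growth_resp` (matrices), `basal` (per-guild vector), and totals
#'   `released`, `respired`, `production` (all mgC/kg soil/day).
#' @export
assimilate_and_respire <- function(fluxes, state, params) {
  e <- c(params$e1, params$e2, params$e3)
  assim <- sweep(fluxes, 2, e, `*`)
  growth <- sweep(fluxes, 2, 1 - e, `*`)
  basal <- params$g * c(state[["b1"]], state[["b2"]], state[["b3"]])
  released <- sum(fluxes)
  respired <- sum(growth) + sum(basal)
  list(decay = fluxes, assimilated = assim, growth_resp = growth,
       basal = basal, released = released, respired = respired,
       production = released - respired)
}

#' Enforce the microbial biomass cap by turnover
#'
#' Total microbial biomass is kept at or below `bc_max` of the total system
#' organic carbon (microbes + substrates).  When the cap is exceeded the
#' excess is removed from the guilds proportionally to their biomass and
#' accumulated as necromass, which is not re-decomposed within the
#' simulation horizon.
#'
#' @param state named state vector.
#' @param params a [gdm_params()] object.
#' @return The updated state vector.
#' @export
apply_turnover <- function(state, params) {
  S <- state[["c1d"]] + state[["c1t"]] + state[["c2"]] + state[["c3"]]
  btot <- state[["b1"]] + state[["b2"]] + state[["b3"]]
  if (btot > 0 && btot > params$bc_max * (btot + S)) {
    target <- params$bc_max * S / (1 - params$bc_max)
    excess <- btot - target
    sc <- excess / btot
    state["b1"] <- state[["b1"]] * (1 - sc)
    state["b2"] <- state[["b2"]] * (1 - sc)
    state["b3"] <- state[["b3"]] * (1 - sc)
    state["necromass"] <- state[["necromass"]] + excess
  }
  state
}

#' One explicit Euler step of the model (reference implementation)
#'
#' Pure-R single fixed step, in the order: decay fluxes, pool decrements
#' (clipped so no pool goes negative), assimilation, growth and basal
#' respiration, turnover cap.  [gdm_simulate()] runs the identical scheme in
#' compiled code; this function is the readable reference and is
#' cross-checked against it in the test suite.
#'
#' @param state named state vector (see [initial state][gdm_simulate()]
#'   layout: `time`, `c1d`, `c1t`, `c2`, `c3`, `b1`, `b2`, `b3`, `cum_co2`,
#'   `cum_released`, `necromass`).
#' @param params a [gdm_params()] object.
#' @param dt step length (days), > 0.
#' @param lci_feedback freeze the LCI coupling if `FALSE`.
#' @return `list(state = <updated state>, flux = <flux record>)`.
#' @export
gdm_step <- function(state, params, dt, lci_feedback = TRUE) {
  stopifnot(dt > 0)
  if (!all(is.finite(state))) stop("non-finite state")
  f <- pool_decay_fluxes(state, params, lci_feedback)
  # clip: total demand on a pool cannot exceed its content
  pools <- c(state[["c1d"]], state[["c2"]], state[["c3"]])
  for (i in 1:3) {
    d <- sum(f[, i]) * dt
    if (d > pools[i] && d > 0) f[, i] <- f[, i] * pools[i] / d
  }
  rec <- assimilate_and_respire(f, state, params)
  state["c1d"] <- max(0, state[["c1d"]] - sum(f[, 1]) * dt)
  state["c2"]  <- max(0, state[["c2"]] - sum(f[, 2]) * dt)
  state["c3"]  <- max(0, state[["c3"]] - sum(f[, 3]) * dt)
  bj <- c(state[["b1"]], state[["b2"]], state[["b3"]]) +
    rowSums(rec$assimilated) * dt
  basal <- pmin(params$g * bj * dt, bj)
  bj <- bj - basal
  state["b1"] <- bj[1]; state["b2"] <- bj[2]; state["b3"] <- bj[3]
  state["cum_co2"] <- state[["cum_co2"]] + sum(rec$growth_resp) * dt +
    sum(basal)
  state["cum_released"] <- state[["cum_released"]] + rec$released * dt
  state <- apply_turnover(state, params)
  state["time"] <- state[["time"]] + dt
  rec$basal <- basal / dt
  rec$respired <- sum(rec$growth_resp) + sum(basal) / dt
  rec$production <- rec$released - rec$respired
  list(state = state, flux = rec)
}

#' Realized carbon use efficiency
#'
#' `(released - respired) / released`: the fraction of carbon released from
#' decaying substrates that is immobilized rather than mineralized.  Bounded
#' above by the largest assimilation efficiency; may be negative when
#' maintenance respiration dominates.
#'
#' @param released carbon released from substrates (mgC).
#' @param respired carbon respired over the same interval (mgC).
#' @return CUE (unitless); `NA` when `released` is 0. Vectorized.
#' @export
realized_cue <- function(released, respired) {
  ifelse(released > 0, (released - respired) / released, NA_real_)
}

#' Simulate litter decomposition
#'
#' Runs the guild decomposition model with fixed-step explicit Euler
#' integration (compiled) from the initial pools in `params` and returns the
#' trajectory at the requested output days with derived observables.
#'
#' The respiration rate, turnover rate and realized CUE reported at output
#' day `d` are averaged over the window `(d - 1, d]` (or from day 0 for the
#' first partial day); they are `NA` at day 0.
#'
#' @param params a [gdm_params()] object (pools + parameters).
#' @param t_end simulation horizon (days).
#' @param dt Euler step (days); must divide the output-day grid.
#' @param output_days days at which to report the state; default every whole
#'   day `0:t_end`.
#' @param lci_feedback freeze the LCI coupling if `FALSE` (used for
#'   closed-form checks).
#' @return A `gdm_trajectory` data frame with columns `day`, `c1d`, `c1t`,
#'   `c2`, `c3`, `b1`, `b2`, `b3`, `resp_rate`, `cum_co2`, `lci`, `cue`,
#'   `production`, `necromass`, `biomass`, `turnover_rate`.  Attributes:
#'   `params`, `dt`, `fine` (per-step state matrix), `mass_balance_error`
#'   (max abs deviation of C accounting from the initial total),
#'   `clip_events` (number of flux-clipping events).
#' @examples
#' tr <- gdm_simulate(gdm_genotype("F2"))
#' tail(tr[, c("day", "cum_co2", "production", "lci")], 3)
#' @export
gdm_simulate <- function(params, t_end = 112, dt = 0.1, output_days = NULL,
                         lci_feedback = TRUE) {
  stopifnot(inherits(params, "gdm_params"), t_end >= 0, dt > 0)
  if (is.null(output_days)) output_days <- seq(0, floor(t_end))
  output_days <- sort(unique(output_days))
  if (max(output_days) > t_end + 1e-9)
    stop("t_end must cover max(output_days)")
  n_steps <- as.integer(round(t_end / dt))
  if (abs(n_steps * dt - t_end) > 1e-8 * max(1, t_end))
    stop("dt must divide t_end")
  init <- initial_state(params)
  fine <- gdm_integrate_cpp(unclass(params), init, dt, n_steps, lci_feedback)

  idx <- round(output_days / dt) + 1L
  if (any(abs((idx - 1L) * dt - output_days) > 1e-8))
    stop("output_days must lie on the dt grid")
  total0 <- sum(init[c("c1d", "c1t", "c2", "c3", "b1", "b2", "b3")])
  totals <- rowSums(fine[, c("c1d", "c1t", "c2", "c3", "b1", "b2", "b3",
                             "cum_co2", "necromass"), drop = FALSE])
  mbe <- max(abs(totals - total0))

  # windowed rates over (d - 1, d] via the cumulative fine-grid series
  win_lo <- pmax(output_days - 1, 0)
  lo_idx <- round(win_lo / dt) + 1L
  wlen <- output_days - win_lo
  dcum <- function(col) {
    out <- (fine[idx, col] - fine[lo_idx, col]) / wlen
    out[wlen == 0] <- NA_real_
    out
  }
  resp_rate <- dcum("cum_co2")
  turnover_rate <- dcum("necromass")
  rel_rate <- dcum("cum_released")
  cue <- realized_cue(ifelse(is.na(rel_rate), 0, rel_rate),
                      ifelse(is.na(resp_rate), 0, resp_rate))
  cue[is.na(rel_rate)] <- NA_real_

  str_den <- fine[idx, "c2"] + fine[idx, "c3"]
  traj <- data.frame(
    day = output_days,
    c1d = fine[idx, "c1d"], c1t = fine[idx, "c1t"],
    c2 = fine[idx, "c2"], c3 = fine[idx, "c3"],
    b1 = fine[idx, "b1"], b2 = fine[idx, "b2"], b3 = fine[idx, "b3"],
    resp_rate = resp_rate,
    cum_co2 = fine[idx, "cum_co2"],
    lci = ifelse(str_den > 0, fine[idx, "c3"] / str_den, NA_real_),
    cue = cue,
    production = fine[idx, "cum_released"] - fine[idx, "cum_co2"],
    necromass = fine[idx, "necromass"],
    biomass = fine[idx, "b1"] + fine[idx, "b2"] + fine[idx, "b3"],
    turnover_rate = turnover_rate)
  structure(traj, class = c("gdm_trajectory", "data.frame"),
            params = params, dt = dt, fine = fine,
            mass_balance_error = mbe,
            clip_events = fine[nrow(fine), "clip_events"])
}

#' @export
print.gdm_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat("Guild decomposition model trajectory")
  if (!is.na(p$genotype)) cat(" (genotype ", p$genotype, ")", sep = "")
  cat("\n  ", nrow(x), " output days over ", max(x$day), " d (dt = ",
      attr(x, "dt"), " d)\n", sep = "")
  last <- x[nrow(x), ]
  cat(sprintf("  day %g: cumulative CO2 = %.1f, production = %.1f, LCI = %.3f, biomass = %.1f mgC/kg\n",
              last$day, last$cum_co2, last$production, last$lci,
              last$biomass))
  cat(sprintf("  mass balance error: %.2e mgC; clipping events: %d\n",
              attr(x, "mass_balance_error"),
              as.integer(attr(x, "clip_events"))))
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Four panels: respiration rate and cumulative CO2, substrate pools, guild
#' biomass, and LCI with realized CUE.
#'
#' @param x a `gdm_trajectory`.
#' @param ... passed to the base plot calls.
#' @return `x`, invisibly.
#' @export
plot.gdm_trajectory <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$day, x$resp_rate, type = "l", xlab = "day",
       ylab = "respiration (mgC/kg/d)", main = "CO2 efflux", ...)
  par(new = TRUE)
  plot(x$day, x$cum_co2, type = "l", lty = 2, axes = FALSE,
       xlab = "", ylab = "")
  plot(x$day, x$c2, type = "l", ylim = c(0, max(x$c2)), xlab = "day",
       ylab = "pool (mgC/kg)", main = "substrates", ...)
  lines(x$day, x$c1d + x$c1t, lty = 2)
  lines(x$day, x$c3, lty = 3)
  legend("topright", c("C2", "C1", "C3"), lty = 1:3, bty = "n", cex = 0.8)
  plot(x$day, x$biomass, type = "l", xlab = "day",
       ylab = "biomass (mgC/kg)", main = "microbial guilds", ...)
  lines(x$day, x$b1, lty = 2); lines(x$day, x$b2, lty = 3)
  lines(x$day, x$b3, lty = 4)
  plot(x$day, x$lci, type = "l", ylim = c(0, 1), xlab = "day",
       ylab = "LCI / CUE", main = "LCI and CUE", ...)
  lines(x$day, x$cue, lty = 2)
  invisible(x)
}
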