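#' Measurement noise model for synthetic observations
#'
#' Multiplicative Gaussian noise: each sampled value is multiplied by
#' `1 + cv * z` with `z` standard normal, then clipped at zero.  Respiration
#' measurement errors scale with the magnitude of the flux, which is why the
#' noise is multiplicative.  A per-stream coefficient of variation can be
#' given; the default is 5% for every stream.
#'
#' @param cv default coefficient of variation for all streams.
#' @param cv_co2_rate,cv_cum_co2,cv_c1,cv_c2 per-stream overrides.
#' @return An object of class `gdm_noise`.
#' @export
noise_model <- function(cv = 0.05, cv_co2_rate = cv, cv_cum_co2 = cv,
                        cv_c1 = cv, cv_c2 = cv) {
  cvs <- c(co2_rate = cv_co2_rate, cum_co2 = cv_cum_co2,
           c1 = cv_c1, c2 = cv_c2)
  if (any(cvs < 0)) stop("noise CV must be >= 0")
  structure(list(cv = cvs), class = "gdm_noise")
}

#' Generate a synthetic incubation observation set
#'
#' Runs the simulator and samples it with the incubation observation scheme:
#' CO2 efflux rate and cumulative CO2 at days 3, 7, 10, 14, 21, 29, 36, 42,
#' 51, 57, 70, 80, 87, 95, 112 and the C1 (C1D + C1T) and C2 pools at days
#' 0, 14, 36, 57, 112.  Each value is perturbed by multiplicative Gaussian
#' noise (clipped at zero); the noisy cumulative CO2 series is
#' re-monotonized with a running maximum.
#'
#' @param params a [gdm_params()] object.
#' @param noise a [noise_model()]; or set `noise_cv` for a common CV.
#' @param noise_cv shorthand: common coefficient of variation (0 gives
#'   noise-free observations equal to the model output).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param co2_days,chem_days sampling days.
#' @param dt Euler step for the underlying simulation.
#' @return A [gdm_observations()] set.
#' @examples
#' obs <- generate_observations(gdm_genotype("F2"), noise_cv = 0.02, seed = 7)
#' obs$cum_co2
#' @export
generate_observations <- function(params, noise = noise_model(noise_cv),
                                  noise_cv = 0.05, seed = NULL,
                                  co2_days = DEFAULT_CO2_DAYS,
                                  chem_days = DEFAULT_CHEM_DAYS, dt = 0.1) {
  stopifnot(inherits(params, "gdm_params"), inherits(noise, "gdm_noise"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  obs0 <- gdm_observations(co2_days = co2_days,
                           co2_rate = rep(0, length(co2_days)),
                           cum_co2 = rep(0, length(co2_days)),
                           chem_days = chem_days,
                           c1 = rep(0, length(chem_days)),
                           c2 = rep(0, length(chem_days)))
  sim <- simulated_streams(params, obs0, dt)
  noisy <- function(x, cv) pmax(0, x * (1 + cv * rnorm(length(x))))
  cum <- cummax(noisy(sim$cum_co2, noise$cv["cum_co2"]))
  gdm_observations(co2_days = co2_days,
                   co2_rate = noisy(sim$co2_rate, noise$cv["co2_rate"]),
                   cum_co2 = cum,
                   chem_days = chem_days,
                   c1 = noisy(sim$c1, noise$cv["c1"]),
                   c2 = noisy(sim$c2, noise$cv["c2"]))
}

#' Draw a self-consistent synthetic litter genotype
#'
#' Draws initial pools, the persistent soluble fraction and the two
#' chemistry-dependent parameters uniformly within the ranges spanned by the
#' four maize-root genotypes (C1 288-419, C2 1166-1387, C3 325-415 mgC/kg,
#' persistent fraction 0.60-0.90, `lci_t` 0.36-0.46, `k_b22` 19-33), then
#' rescales the pools so total initial substrate C is exactly
#' 2000 mgC/kg soil.  A litter chemistry table is back-filled so that
#' [derive_indices()] reproduces the pool-implied lignocellulose index
#' (KL = C3, total cell-wall sugars = C2, solubles = C1).
#'
#' @param seed integer seed.
#' @param ranges named list overriding any of the default ranges `c1`, `c2`,
#'   `c3`, `c1t_fraction`, `lci_t`, `k_b22` (each a length-2 numeric).
#' @param total_c total initial substrate carbon after rescaling (mgC/kg).
#' @return A list with elements `params` ([gdm_params()]) and `chemistry`
#'   ([litter_chemistry()]).
#' @examples
#' g <- generate_genotype(seed = 1)
#' g$params$c1 + g$params$c2 + g$params$c3
#' @export
generate_genotype <- function(seed = 1, ranges = list(), total_c = 2000) {
  defaults <- list(c1 = c(288, 419), c2 = c(1166, 1387), c3 = c(325, 415),
                   c1t_fraction = c(0.60, 0.90), lci_t = c(0.36, 0.46),
                   k_b22 = c(19, 33))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown))
    stop("unknown range name(s): ", paste(unknown, collapse = ", "))
  rg <- modifyList(defaults, ranges)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  draw <- function(nm) runif(1, rg[[nm]][1], rg[[nm]][2])
  pools <- c(c1 = draw("c1"), c2 = draw("c2"), c3 = draw("c3"))
  pools <- pools * total_c / sum(pools)
  params <- gdm_params(lci_t = draw("lci_t"), k_b22 = draw("k_b22"),
                       c1 = unname(pools["c1"]),
                       c1t_fraction = draw("c1t_fraction"),
                       c2 = unname(pools["c2"]), c3 = unname(pools["c3"]),
                       genotype = sprintf("synthetic-%d", seed))
  # back-fill chemistry: KL = C3, sum of cell-wall sugars = C2, C-SOL = C1,
  # sugar composition fixed at typical graminoid cell-wall proportions
  sug <- pools["c2"]
  chem <- litter_chemistry(kl = unname(pools["c3"]),
                           glu = unname(0.55 * sug),
                           xyl = unname(0.30 * sug),
                           ara = unname(0.08 * sug),
                           gal = unname(0.04 * sug),
                           uronic = unname(0.03 * sug),
                           c_sol = unname(pools["c1"]))
  list(params = params, chemistry = chem)
}
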