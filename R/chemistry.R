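#' Litter chemistry table
#'
#' Concentrations of the measured litter chemical fractions, in consistent
#' units per unit litter mass: Klason lignin (`kl`), the cell-wall sugars
#' glucan (`glu`), arabinan (`ara`), xylan (`xyl`), galactan (`gal`) and
#' uronic acids (`uronic`), the hydroxycinnamic acids *p*-coumaric
#' (`pca`), ester-linked ferulic (`fa_ester`) and ether-linked ferulic
#' (`fa_ether`), the Van Soest soluble fraction (`c_sol`), and optional
#' nitrogen content (`n`).
#'
#' @param kl,glu,ara,xyl,gal,uronic,pca,fa_ester,fa_ether,c_sol,n
#'   concentrations (all >= 0; `n` may be `NA`).
#' @return An object of class `litter_chemistry`.
#' @export
litter_chemistry <- function(kl, glu, ara, xyl, gal, uronic,
                             pca = 0, fa_ester = 0, fa_ether = 0,
                             c_sol = 0, n = NA_real_) {
  ch <- list(kl = kl, glu = glu, ara = ara, xyl = xyl, gal = gal,
             uronic = uronic, pca = pca, fa_ester = fa_ester,
             fa_ether = fa_ether, c_sol = c_sol, n = n)
  vals <- unlist(ch[names(ch) != "n"])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("chemistry concentrations must be finite and >= 0")
  class(ch) <- "litter_chemistry"
  ch
}

#' Derived litter-chemistry indices
#'
#' Computes the indices used to characterize litter quality:
#' * `ax`: arabinan:xylan ratio, the degree of arabinan substitution on
#'   xylan chains (higher values resist hydrolysis);
#' * `sum_sug`: total cell-wall sugars `glu + ara + xyl + gal + uronic`;
#' * `lci`: lignocellulose index `kl / (sum_sug + kl)`;
#' * `kl_ax`: Klason lignin divided by the A:X ratio, the chemistry
#'   predictor used by the parameter transfer functions;
#' * `cn`: carbon:nitrogen ratio (total measured C fractions over `n`;
#'   `NA` when no nitrogen content is given).
#'
#' Ratios are scale-invariant: multiplying every concentration by a common
#' factor leaves `ax` and `lci` unchanged.
#'
#' @param chem a [litter_chemistry()] object.
#' @return A list with fields `ax`, `sum_sug`, `kl_ax`, `lci`, `cn`.
#' @examples
#' ch <- litter_chemistry(kl = 397, glu = 700, ara = 90, xyl = 380,
#'                        gal = 40, uronic = 28)
#' derive_indices(ch)$lci
#' @export
derive_indices <- function(chem) {
  stopifnot(inherits(chem, "litter_chemistry"))
  if (chem$xyl == 0) stop("A:X undefined: xylan concentration is zero")
  ax <- chem$ara / chem$xyl
  sum_sug <- chem$glu + chem$ara + chem$xyl + chem$gal + chem$uronic
  lci <- if (sum_sug + chem$kl > 0) chem$kl / (sum_sug + chem$kl) else NA_real_
  kl_ax <- if (ax > 0) chem$kl / ax else Inf
  total_c <- chem$c_sol + sum_sug + chem$kl + chem$pca + chem$fa_ester +
    chem$fa_ether
  cn <- if (is.na(chem$n) || chem$n == 0) NA_real_ else total_c / chem$n
  list(ax = ax, sum_sug = sum_sug, kl_ax = kl_ax, lci = lci, cn = cn)
}

#' Empirical decay rate coefficient between two observation dates
#'
#' The difference in the natural log of pool size between two dates divided
#' by the time interval.  Additive over consecutive intervals weighted by
#' their durations.
#'
#' @param pool_a,pool_b pool sizes (mgC, > 0) at times `t_a` and `t_b`.
#' @param t_a,t_b observation days, `t_b > t_a`.
#' @return Decay coefficient (1/day); negative when the pool grows.
#' @export
decay_coefficient <- function(pool_a, pool_b, t_a, t_b) {
  if (any(c(pool_a, pool_b) <= 0)) stop("pool sizes must be > 0")
  if (any(t_b <= t_a)) stop("t_b must exceed t_a")
  (log(pool_a) - log(pool_b)) / (t_b - t_a)
}

#' Remaining litter mass estimated from cumulative CO2 efflux
#'
#' @param initial_c initial litter carbon (mgC).
#' @param cum_co2 cumulative CO2-C efflux (mgC), between 0 and `initial_c`.
#' @return Remaining litter carbon `initial_c - cum_co2`.
#' @export
remaining_mass_from_co2 <- function(initial_c, cum_co2) {
  if (any(cum_co2 < 0)) stop("cumulative CO2 must be >= 0")
  if (any(cum_co2 > initial_c))
    stop("cumulative CO2 exceeds initial carbon")
  initial_c - cum_co2
}

#' Pool size from concentration and remaining litter mass
#'
#' @param conc concentration of the chemical fraction (mgC per unit mass).
#' @param remaining remaining litter mass.
#' @return Pool size `conc * remaining`.
#' @export
pool_from_concentration <- function(conc, remaining) {
  if (any(c(conc, remaining) < 0)) stop("inputs must be >= 0")
  conc * remaining
}

# coefficient of determination without summary.lm's perfect-fit warning
r_squared <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(residuals(fit)^2) / tss
}

#' Estimate the maximum C2 decay coefficient from interval estimates
#'
#' Ordinary least squares of observed interval decay coefficients `k2`
#' against the lignocellulose index of the remaining litter; the intercept
#' estimates `k2max` (the decay coefficient at LCI 0) and the slope is the
#' LCI feedback `m2`.
#'
#' @param points a data frame (or list) with numeric fields `lci` and `k2`,
#'   at least 3 points.
#' @return A list with `intercept` (the `k2max` estimate), `slope`, `r2`
#'   and `n`.
#' @export
estimate_k2max <- function(points) {
  lci <- points$lci; k2 <- points$k2
  stopifnot(length(lci) == length(k2))
  if (length(lci) < 3) stop("need at least 3 points")
  if (stats::var(lci) == 0) stop("zero variance in lci")
  fit <- lm(k2 ~ lci)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r2 = r_squared(fit, k2), n = length(lci))
}

#' Chemistry-to-parameter transfer functions
#'
#' Linear maps from initial litter chemistry to the three genotype-specific
#' model parameters, fitted across the four reference maize genotypes:
#' `lci_t = -0.36 * kl_ax + 0.70`, `c1t = 0.02 * sum_sug - 0.64` (clamped to
#' `[0, 1]`), and `k_b22 = 53.22 * kl_ax - 13.65` (clamped to >= 1).
#' Clamping triggers a warning.  The transfer inputs must be in the same
#' units as the chemistry tables the maps were fitted to; for other units,
#' refit with [fit_transfer_model()].
#'
#' @param kl_ax Klason lignin divided by the arabinan:xylan ratio.
#' @param sum_sug total cell-wall sugar concentration.
#' @return The mapped parameter value (vectorized).
#' @examples
#' transfer_lci_t(0.778)   # close to the F2 best fit 0.42
#' @export
transfer_lci_t <- function(kl_ax) {
  stopifnot(all(kl_ax >= 0))
  -0.36 * kl_ax + 0.70
}

#' @rdname transfer_lci_t
#' @export
transfer_c1t <- function(sum_sug) {
  stopifnot(all(sum_sug >= 0))
  out <- 0.02 * sum_sug - 0.64
  if (any(out < 0 | out > 1)) {
    warning("c1t transfer output clamped to [0, 1]")
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' @rdname transfer_lci_t
#' @export
transfer_kb22 <- function(kl_ax) {
  stopifnot(all(kl_ax >= 0))
  out <- 53.22 * kl_ax - 13.65
  if (any(out < 1)) {
    warning("k_b22 transfer output clamped to >= 1")
    out <- pmax(out, 1)
  }
  out
}

#' Fit a linear chemistry-to-parameter transfer map
#'
#' Ordinary least squares of a best-fit parameter value on a chemistry
#' predictor, reusable as a transfer map for new genotypes via `predict()`.
#'
#' @param x chemistry predictor values (length >= 2, nonzero variance).
#' @param y parameter values.
#' @return An object of class `gdm_transfer` with fields `slope`,
#'   `intercept`, `r2`, `n`.
#' @export
fit_transfer_model <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r_squared(fit, y), n = length(x)),
            class = "gdm_transfer")
}

#' @export
predict.gdm_transfer <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' @export
print.gdm_transfer <- function(x, ...) {
  cat(sprintf("Transfer map: y = %.4g * x + %.4g (n = %d, R^2 = %.3f)\n",
              x$slope, x$intercept, x$n, x$r2))
  invisible(x)
}

#' Extrapolate model parameters from initial litter chemistry
#'
#' Applies the printed transfer maps ([transfer_lci_t()], [transfer_c1t()],
#' [transfer_kb22()]) to the derived indices of a chemistry table and
#' returns a parameter set for a new genotype.  Initial pools are taken as
#' C1 = solubles, C2 = total cell-wall sugars, C3 = Klason lignin, scaled to
#' `total_c` mgC/kg soil.
#'
#' @param chem a [litter_chemistry()] object.
#' @param total_c total initial substrate carbon in the microcosm (mgC/kg
#'   soil).
#' @param genotype optional label.
#' @param ... further arguments passed to [gdm_params()] (e.g. shared
#'   parameter overrides).
#' @return A [gdm_params()] object.
#' @export
gdm_extrapolate <- function(chem, total_c = 2000, genotype = NULL, ...) {
  idx <- derive_indices(chem)
  pools <- c(c1 = chem$c_sol, c2 = idx$sum_sug, c3 = chem$kl)
  if (sum(pools) <= 0) stop("chemistry implies no carbon")
  pools <- pools * total_c / sum(pools)
  gdm_params(lci_t = transfer_lci_t(idx$kl_ax),
             k_b22 = transfer_kb22(idx$kl_ax),
             c1 = unname(pools["c1"]),
             c1t_fraction = transfer_c1t(idx$sum_sug),
             c2 = unname(pools["c2"]), c3 = unname(pools["c3"]),
             genotype = genotype, ...)
}

#' Read a litter chemistry CSV
#'
#' One row per genotype; columns `kl`, `glu`, `ara`, `xyl`, `gal`,
#' `uronic`, and optionally `pca`, `fa_ester`, `fa_ether`, `c_sol`, `n`,
#' `genotype`.
#'
#' @param path CSV file path.
#' @return A named list of [litter_chemistry()] objects (named by the
#'   `genotype` column when present).
#' @export
read_litter_chemistry <- function(path) {
  if (!file.exists(path)) stop("chemistry file not found: ", path)
  df <- read.csv(path)
  need <- c("kl", "glu", "ara", "xyl", "gal", "uronic")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("chemistry file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, intersect(names(df),
                                    c(need, "pca", "fa_ester", "fa_ether",
                                      "c_sol", "n"))])
    do.call(litter_chemistry, args)
  })
  names(out) <- if ("genotype" %in% names(df)) as.character(df$genotype)
  out
}
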