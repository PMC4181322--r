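#' Monte-Carlo parameter perturbation design
#'
#' The perturbation experiment draws each named parameter independently and
#' uniformly within a relative range around its base value (default
#' +/-10%), `n` times (default 100 per litter type), and records how the
#' mismatch between perturbed simulations and reference observations
#' responds.
#'
#' @param parameters names of the perturbed parameters.
#' @param range relative half-width of the uniform perturbation (in (0, 1)).
#' @param n number of replicate draws (>= 2).
#' @param seed integer seed.
#' @return An object of class `gdm_design`.
#' @export
perturbation_design <- function(parameters = c("e1", "e2", "k1max",
                                               "bc_max", "k_b11"),
                                range = 0.1, n = 100, seed = 1) {
  if (!(range >= 0 && range < 1)) stop("range must be in [0, 1)")
  if (n < 2) stop("n must be >= 2")
  structure(list(parameters = parameters, range = range, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "gdm_design")
}

#' Draw perturbed parameter sets from a design
#'
#' Each named parameter is drawn uniformly and independently from
#' `[(1 - range) * base, (1 + range) * base]`; all other parameters keep
#' their base values.  Reproducible under the design seed.
#'
#' @param design a [perturbation_design()].
#' @param base the base [gdm_params()] object.
#' @return A list of `n` [gdm_params()] objects, with the drawn values as a
#'   data frame in attribute `"draws"`.
#' @export
draw_design <- function(design, base) {
  stopifnot(inherits(design, "gdm_design"), inherits(base, "gdm_params"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(design$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  draws <- sapply(design$parameters, function(nm) {
    b <- base[[nm]]
    runif(design$n, (1 - design$range) * b, (1 + design$range) * b)
  })
  draws <- matrix(draws, nrow = design$n,
                  dimnames = list(NULL, design$parameters))
  sets <- lapply(seq_len(design$n), function(i)
    do.call(update_params, c(list(base), as.list(draws[i, ]))))
  attr(sets, "draws") <- as.data.frame(draws)
  sets
}

#' Signed composite relative difference between observed and simulated series
#'
#' `sum over days of (obs - sim) / obs`.  The sum is signed, so
#' over- and under-predictions on different days can cancel.  Days with a
#' zero observation cannot be normalized and are excluded with a warning.
#'
#' @param obs,sim numeric vectors of equal length.
#' @return The signed sum (unitless).
#' @export
composite_relative_difference <- function(obs, sim) {
  stopifnot(length(obs) == length(sim))
  keep <- obs != 0
  if (!all(keep)) warning("excluding ", sum(!keep), " day(s) with zero observation")
  sum((obs[keep] - sim[keep]) / obs[keep])
}

#' Run the parameter perturbation experiment
#'
#' For each draw of the design, simulates decomposition with the perturbed
#' parameters and computes the composite relative difference between the
#' reference observations and the perturbed simulation for the four
#' response streams (C1, C2, cumulative CO2, respiration rate) plus their
#' sum (overall fit).  The reference may be a real or synthetic
#' [gdm_observations()] set.
#'
#' @param params base [gdm_params()] (single genotype) or a named list of
#'   them (one per genotype).
#' @param obs matching [gdm_observations()] set or named list of sets.
#' @param design a [perturbation_design()].
#' @param dt Euler step for the simulations.
#' @return A `gdm_sensitivity` data frame with one row per replicate x
#'   genotype: `genotype`, `replicate`, the drawn parameter values, and the
#'   responses `resp_c1`, `resp_c2`, `resp_cum_co2`, `resp_resp_rate`,
#'   `resp_overall`.
#' @seealso [partition_variance()]
#' @export
gdm_sensitivity <- function(params, obs, design = perturbation_design(),
                            dt = 0.1) {
  if (inherits(params, "gdm_params")) {
    nm <- if (!is.na(params$genotype)) params$genotype else "genotype1"
    params <- setNames(list(params), nm)
    obs <- setNames(list(obs), nm)
  }
  stopifnot(length(params) == length(obs))
  rows <- lapply(names(params), function(gt) {
    base <- params[[gt]]
    o <- obs[[gt]]
    sets <- draw_design(design, base)
    draws <- attr(sets, "draws")
    resp <- t(vapply(sets, function(p) {
      sim <- simulated_streams(p, o, dt)
      r <- c(resp_c1 = composite_relative_difference(o$c1, sim$c1),
             resp_c2 = composite_relative_difference(o$c2, sim$c2),
             resp_cum_co2 = composite_relative_difference(o$cum_co2,
                                                          sim$cum_co2),
             resp_resp_rate = composite_relative_difference(o$co2_rate,
                                                            sim$co2_rate))
      c(r, resp_overall = sum(r))
    }, numeric(5)))
    cbind(data.frame(genotype = gt, replicate = seq_len(design$n)),
          draws, as.data.frame(resp))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("gdm_sensitivity", "data.frame"), design = design)
}

#' Partition response variance by type II sums of squares
#'
#' Fits, for each response, a linear model on the perturbed parameter
#' covariates (plus a genotype factor when `pooled = TRUE` and several
#' genotypes are present), and attributes variance to each term by the type
#' II construction: the term's sum of squares is the increase in residual
#' sum of squares when it is dropped with all other terms retained.  Each
#' term's SS is reported as a percentage of the total (model + residual)
#' sum of squares; the residual percentage is the remainder so that the
#' percentages sum to 100 within a response.  Percentages are invariant to
#' rescaling of the response.
#'
#' @param table a [gdm_sensitivity()] table (>= 10 rows per genotype).
#' @param pooled pool genotypes with a genotype factor covariate, rather
#'   than partitioning each genotype separately.
#' @param responses response columns to partition.
#' @return A `gdm_partition` data frame with one row per response x
#'   genotype: the percentage contribution of each parameter, `residual`,
#'   and a significance column `sig_<param>` (p-value of the drop-one
#'   F test) per parameter.
#' @export
partition_variance <- function(table, pooled = FALSE,
                               responses = c("resp_c1", "resp_c2",
                                             "resp_cum_co2",
                                             "resp_resp_rate",
                                             "resp_overall")) {
  stopifnot(inherits(table, "gdm_sensitivity") || is.data.frame(table))
  design <- attr(table, "design")
  pars <- if (!is.null(design)) design$parameters else
    setdiff(names(table), c("genotype", "replicate",
                            grep("^resp_", names(table), value = TRUE)))
  counts <- table(table$genotype)
  if (any(counts < 10)) stop("need >= 10 rows per genotype")
  groups <- if (pooled) list(pooled = table) else
    split(table, table$genotype)

  one <- function(df, gt) {
    covars <- pars
    if (pooled && length(unique(df$genotype)) > 1)
      covars <- c(covars, "genotype")
    X <- df[, covars, drop = FALSE]
    if ("genotype" %in% covars) X$genotype <- factor(X$genotype)
    qrx <- qr(stats::model.matrix(~ ., X))
    if (qrx$rank < ncol(qrx$qr)) {
      stop("rank-deficient design; collinear term(s) among: ",
           paste(covars, collapse = ", "))
    }
    do.call(rbind, lapply(responses, function(rs) {
      y <- df[[rs]]
      full <- lm(stats::reformulate(covars, response = "y"),
                 data = cbind(X, y = y))
      rss_full <- sum(residuals(full)^2)
      tss <- sum((y - mean(y))^2)
      df_res <- full$df.residual
      ss <- p <- numeric(length(pars))
      names(ss) <- names(p) <- pars
      for (term in pars) {
        red <- lm(stats::reformulate(setdiff(covars, term), response = "y"),
                  data = cbind(X, y = y))
        ss[term] <- sum(residuals(red)^2) - rss_full
        fstat <- (ss[term] / 1) / (rss_full / df_res)
        p[term] <- pf(fstat, 1, df_res, lower.tail = FALSE)
      }
      pct <- if (tss > 0) 100 * ss / tss else rep(0, length(ss))
      row <- data.frame(response = rs, genotype = gt,
                        as.list(pct), residual = 100 - sum(pct),
                        check.names = FALSE)
      sig <- as.list(p)
      names(sig) <- paste0("sig_", pars)
      cbind(row, sig)
    }))
  }
  out <- do.call(rbind, lapply(names(groups), function(gt)
    one(groups[[gt]], gt)))
  rownames(out) <- NULL
  structure(out, class = c("gdm_partition", "data.frame"), parameters = pars)
}

#' Write a variance-partition table as CSV
#'
#' Rows are response x genotype, columns the parameter percentage
#' contributions.
#'
#' @param partition a [partition_variance()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  pars <- attr(partition, "parameters")
  out <- partition[, c("response", "genotype", pars, "residual")]
  write_csv_10g(out, path)
  invisible(path)
}
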