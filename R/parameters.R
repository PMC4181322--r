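#' Model parameters and initial pools for a litter genotype
#'
#' Builds the full parameter set of the guild decomposition model: decay rate
#' coefficients, assimilation efficiencies, half-saturation coefficients of
#' each microbial guild for each substrate pool, the lignocellulose-index
#' (LCI) thresholds that throttle decay, the biomass cap, and the initial
#' carbon pools.  All carbon quantities are in mgC per kg soil; rate
#' coefficients are per day.
#'
#' Substrate pools: `c1` is Van Soest soluble litter C, split at
#' initialization into a decomposable part C1D (`(1 - c1t_fraction) * c1`)
#' and a persistent part C1T that does not decompose within the simulation
#' horizon; `c2` is the acid-hydrolysable (holocellulose) pool; `c3` the acid
#' non-hydrolysable (Klason lignin) pool.  Guild 1 (opportunists) accesses
#' only C1D, guild 2 (cellulolytic) C1D and C2, guild 3 (lignolytic) all
#' three.  All guilds share one half-saturation coefficient `k_b11` for C1D.
#'
#' The decay coefficient of C2 declines linearly with LCI,
#' `k2 = max(0, m2 * LCI + k2max)`, reaching zero at `lci_max`; the default
#' slope is `m2 = -k2max / lci_max`.  C3 decay is zero at or below the
#' genotype-specific threshold `lci_t` and ramps linearly with slope `m3`
#' (default `k3max / (lci_max - lci_t)`, i.e. reaching `k3max` at `lci_max`);
#' above `lci_max` all decay stops.
#'
#' @param lci_t LCI threshold at which C3 decay starts (unitless).
#' @param k_b22 half-saturation coefficient of guild 2 for C2 (mgC/kg soil).
#' @param c1,c2,c3 initial substrate pools (mgC/kg soil).
#' @param c1t_fraction persistent (non-decomposable) fraction of `c1`.
#' @param k1max,k2max,k3max maximum decay rate coefficients (1/day).
#' @param e1,e2,e3 carbon assimilation efficiencies per substrate (unitless;
#'   `e3 = 0` by default: lignin-derived C yields no net assimilation).
#' @param g basal (maintenance) respiration coefficient (1/day).
#' @param bc_max maximum microbial biomass : total system organic C ratio.
#' @param lci_max LCI at which all structural decay stops.
#' @param k_b11 shared half-saturation coefficient of all guilds for C1D.
#' @param k_b32,k_b33 half-saturation coefficients of guild 3 for C2 and C3.
#' @param b1,b2,b3 initial guild biomass (mgC/kg soil).
#' @param m2 slope of k2 against LCI (1/day per unit LCI, must be <= 0);
#'   default `-k2max / lci_max`.
#' @param m3 slope of the C3 decay ramp above `lci_t`; default
#'   `k3max / (lci_max - lci_t)`.
#' @param genotype optional genotype label.
#'
#' @return An object of class `gdm_params` (a named list).
#' @seealso [gdm_genotype()] for the four bundled maize-root genotypes,
#'   [gdm_simulate()] to run the model.
#' @examples
#' p <- gdm_params(lci_t = 0.42, k_b22 = 29, c1 = 364, c1t_fraction = 0.61,
#'                 c2 = 1238, c3 = 397)
#' p$k2max
#' @export
gdm_params <- function(lci_t, k_b22, c1, c1t_fraction, c2, c3,
                       k1max = 0.1, k2max = 0.047, k3max = 0.001,
                       e1 = 0.4, e2 = 0.3, e3 = 0,
                       g = 0.001, bc_max = 0.05, lci_max = 0.7,
                       k_b11 = 10, k_b32 = 300, k_b33 = 500,
                       b1 = 10, b2 = 10, b3 = 5,
                       m2 = NULL, m3 = NULL, genotype = NULL) {
  if (is.null(m2)) m2 <- -k2max / lci_max
  if (is.null(m3)) m3 <- k3max / (lci_max - lci_t)
  p <- list(k1max = k1max, k2max = k2max, k3max = k3max,
            e1 = e1, e2 = e2, e3 = e3, g = g, bc_max = bc_max,
            lci_t = lci_t, lci_max = lci_max,
            k_b11 = k_b11, k_b22 = k_b22, k_b32 = k_b32, k_b33 = k_b33,
            c1 = c1, c1t_fraction = c1t_fraction, c2 = c2, c3 = c3,
            b1 = b1, b2 = b2, b3 = b3, m2 = m2, m3 = m3,
            genotype = if (is.null(genotype)) NA_character_ else genotype)
  validate_gdm_params(p)
  class(p) <- "gdm_params"
  p
}

validate_gdm_params <- function(p) {
  num <- setdiff(names(p), "genotype")
  vals <- vapply(p[num], function(x) unname(as.numeric(x))[1], numeric(1))
  names(vals) <- num
  if (!all(is.finite(vals)))
    stop("non-finite parameter value(s): ",
         paste(num[!is.finite(vals)], collapse = ", "))
  rates <- c("k1max", "k2max", "k3max", "g")
  if (any(vals[rates] < 0)) stop("rate coefficients must be >= 0")
  eff <- vals[c("e1", "e2", "e3")]
  if (any(eff < 0 | eff > 1)) stop("efficiencies e1, e2, e3 must be in [0, 1]")
  if (!(p$lci_t > 0 && p$lci_t < p$lci_max && p$lci_max <= 1))
    stop("require 0 < lci_t < lci_max <= 1")
  if (!(p$bc_max > 0 && p$bc_max < 1)) stop("require 0 < bc_max < 1")
  if (any(vals[c("k_b11", "k_b22", "k_b32", "k_b33")] < 0))
    stop("half-saturation coefficients must be >= 0")
  if (any(vals[c("c1", "c2", "c3", "b1", "b2", "b3")] < 0))
    stop("pools and biomass must be >= 0")
  if (p$c1t_fraction < 0 || p$c1t_fraction > 1)
    stop("c1t_fraction must be in [0, 1]")
  if (p$m2 > 0) stop("m2 must be <= 0 (k2 cannot increase with LCI)")
  invisible(p)
}

#' @export
print.gdm_params <- function(x, ...) {
  cat("Guild decomposition model parameters")
  if (!is.na(x$genotype)) cat(" (genotype ", x$genotype, ")", sep = "")
  cat("\n  pools mgC/kg: C1 =", x$c1, "(persistent fraction",
      x$c1t_fraction, "), C2 =", x$c2, ", C3 =", x$c3, "\n")
  cat("  guild biomass:", x$b1, x$b2, x$b3, "\n")
  cat("  kinetics: k1max =", x$k1max, ", k2max =", x$k2max,
      ", k3max =", x$k3max, ", lci_t =", x$lci_t,
      ", lci_max =", x$lci_max, "\n")
  cat("  half-saturation: K_C1 =", x$k_b11, ", K_B22 =", x$k_b22,
      ", K_B32 =", x$k_b32, ", K_B33 =", x$k_b33, "\n")
  invisible(x)
}

#' Replace fields of a parameter set
#'
#' @param params a [gdm_params()] object.
#' @param ... named fields to replace. Slopes `m2`/`m3` are recomputed from
#'   their defining parameters unless given explicitly.
#' @return A validated `gdm_params` object.
#' @export
update_params <- function(params, ...) {
  repl <- lapply(list(...), unname)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- unclass(params)
  # recompute default slopes when their parents move and no override is given
  if (!("m2" %in% names(repl)) &&
      isTRUE(all.equal(p$m2, -p$k2max / p$lci_max)))
    repl$m2 <- -(repl$k2max %||% p$k2max) / (repl$lci_max %||% p$lci_max)
  if (!("m3" %in% names(repl)) &&
      isTRUE(all.equal(p$m3, p$k3max / (p$lci_max - p$lci_t))))
    repl$m3 <- (repl$k3max %||% p$k3max) /
      ((repl$lci_max %||% p$lci_max) - (repl$lci_t %||% p$lci_t))
  p[names(repl)] <- repl
  validate_gdm_params(p)
  class(p) <- "gdm_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled maize-root genotype parameter sets
#'
#' Returns the calibrated parameter set and initial pools for one of the four
#' maize root litter genotypes studied in the 112-day incubation: `"F2"`,
#' `"F2bm1"`, `"F292"`, `"F292bm3"`.  The brown-midrib mutants (bm1, bm3)
#' differ from their wild types primarily in lignin chemistry.
#'
#' @param name genotype name (case-insensitive).
#' @return A [gdm_params()] object.
#' @examples
#' gdm_genotype("F2")
#' @export
gdm_genotype <- function(name = c("F2", "F2bm1", "F292", "F292bm3")) {
  name <- match.arg(toupper(name)[1], c("F2", "F2BM1", "F292", "F292BM3"))
  file <- c(F2 = "genotype_f2.json", F2BM1 = "genotype_f2bm1.json",
            F292 = "genotype_f292.json", F292BM3 = "genotype_f292bm3.json")[name]
  path <- system.file("extdata", file, package = "litterGDM", mustWork = TRUE)
  read_gdm_params(path)
}

PARAM_KEYS <- c("k1max", "k2max", "k3max", "e1", "e2", "e3", "g", "bc_max",
                "lci_t", "lci_max", "k_b11", "k_b22", "k_b32", "k_b33",
                "c1", "c1t_fraction", "c2", "c3", "b1", "b2", "b3")

#' Read a genotype parameter file (JSON or YAML)
#'
#' The file must contain every key of the standard parameter set
#' (`k1max` ... `b3`); optional keys `m2`, `m3` override the default LCI
#' slopes and `genotype` labels the set.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return A [gdm_params()] object.
#' @export
read_gdm_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file format: .", ext))
  missing <- setdiff(PARAM_KEYS, names(raw))
  if (length(missing))
    stop("parameter file ", path, " is missing key(s): ",
         paste(missing, collapse = ", "))
  do.call(gdm_params, raw[intersect(c(PARAM_KEYS, "m2", "m3", "genotype"),
                                    names(raw))])
}

#' Write a genotype parameter file
#'
#' @param params a [gdm_params()] object.
#' @param path output path; `.json` or `.yaml`/`.yml`.
#' @return `path`, invisibly.
#' @export
write_gdm_params <- function(params, path) {
  stopifnot(inherits(params, "gdm_params"))
  out <- unclass(params)
  if (is.na(out$genotype)) out$genotype <- NULL
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(out, path, precision = 15),
    stop("unsupported parameter file format: .", ext))
  invisible(path)
}

# initial system state implied by a parameter set
initial_state <- function(params) {
  c(time = 0,
    c1d = (1 - params$c1t_fraction) * params$c1,
    c1t = params$c1t_fraction * params$c1,
    c2 = params$c2, c3 = params$c3,
    b1 = params$b1, b2 = params$b2, b3 = params$b3,
    cum_co2 = 0, cum_released = 0, necromass = 0)
}
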