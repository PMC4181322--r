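# shared CSV dialect: comma-separated, header, UTF-8, "." decimal,
# numerics formatted at 10 significant digits so write -> read -> write
# round-trips byte-identically
write_csv_10g <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]))
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), "NA", sprintf("%.10g", fmt[[j]]))
  }
  write.csv(fmt, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read a simulated trajectory as CSV
#'
#' Columns `day`, `c1d`, `c1t`, `c2`, `c3`, `b1`, `b2`, `b3`, `resp_rate`,
#' `cum_co2`, `lci`, `cue`, `production`, `necromass`, `biomass`,
#' `turnover_rate`; numerics at 10 significant digits.
#'
#' @param trajectory a [gdm_simulate()] result.
#' @param path CSV file path.
#' @return `path` (writer, invisibly) or a data frame (reader).
#' @export
write_trajectory_csv <- function(trajectory, path) {
  cols <- c("day", "c1d", "c1t", "c2", "c3", "b1", "b2", "b3", "resp_rate",
            "cum_co2", "lci", "cue", "production", "necromass", "biomass",
            "turnover_rate")
  write_csv_10g(as.data.frame(trajectory)[, cols], path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  read.csv(path)
}

#' Write and read an observation set as long-format CSV
#'
#' Columns `day`, `variable` (one of `co2_rate`, `cum_co2`, `c1`, `c2`) and
#' `value`.  The reader accepts arbitrary day grids.
#'
#' @param obs a [gdm_observations()] set.
#' @param path CSV file path.
#' @return `path` (writer, invisibly) or a [gdm_observations()] (reader).
#' @export
write_gdm_observations <- function(obs, path) {
  stopifnot(inherits(obs, "gdm_observations"))
  df <- rbind(
    data.frame(day = obs$co2_days, variable = "co2_rate",
               value = obs$co2_rate),
    data.frame(day = obs$co2_days, variable = "cum_co2", value = obs$cum_co2),
    data.frame(day = obs$chem_days, variable = "c1", value = obs$c1),
    data.frame(day = obs$chem_days, variable = "c2", value = obs$c2))
  write_csv_10g(df, path)
}

#' @rdname write_gdm_observations
#' @export
read_gdm_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  df <- read.csv(path)
  need <- c("day", "variable", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("observation file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$variable), c("co2_rate", "cum_co2", "c1", "c2"))
  if (length(bad))
    stop("unknown observation variable(s): ", paste(bad, collapse = ", "))
  pick <- function(v) df[df$variable == v, ][order(df$day[df$variable == v]), ]
  rate <- pick("co2_rate"); cum <- pick("cum_co2")
  c1 <- pick("c1"); c2 <- pick("c2")
  if (!identical(rate$day, cum$day))
    stop("co2_rate and cum_co2 must share the same day grid")
  if (!identical(c1$day, c2$day))
    stop("c1 and c2 must share the same day grid")
  gdm_observations(co2_days = rate$day, co2_rate = rate$value,
                   cum_co2 = cum$value, chem_days = c1$day,
                   c1 = c1$value, c2 = c2$value)
}
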