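#' @importFrom utils read.csv write.csv
NULL

obs_required_cols <- c("cultivar", "n_rate", "rank", "tt", "ssa_deg")

# Validate an observation data.frame: required columns present, ranks
# positive integers, angles in [0, 90), thermal time non-negative.
check_observations <- function(obs, context = "observations") {
  if (!is.data.frame(obs)) {
    stop(sprintf("%s must be a data.frame", context), call. = FALSE)
  }
  missing <- setdiff(obs_required_cols, names(obs))
  if (length(missing) > 0L) {
    stop(sprintf("%s lack required column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("%s: %s in row(s) %s", context, what,
                   paste(utils::head(which(cond), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_row(!is.finite(obs$rank) | obs$rank < 1 | obs$rank != round(obs$rank),
          "leaf rank must be a positive integer")
  bad_row(!is.finite(obs$tt) | obs$tt < 0,
          "thermal time must be non-negative")
  bad_row(!is.finite(obs$ssa_deg) | obs$ssa_deg < 0 | obs$ssa_deg >= 90,
          "ssa_deg must lie in [0, 90)")
  obs$cultivar <- as.character(obs$cultivar)
  obs$n_rate <- as.character(obs$n_rate)
  obs$rank <- as.integer(obs$rank)
  obs
}

#' Read an SSA observation table from CSV
#'
#' Expects a UTF-8 CSV with header columns \code{cultivar}, \code{n_rate},
#' \code{rank}, \code{ssa_deg} (degrees, in [0, 90)) and either \code{tt}
#' (thermal time, degC d) or \code{date} (ISO-8601) resolved through a
#' weather file. When both \code{tt} and \code{date} are present,
#' \code{tt} takes precedence. An optional \code{plant_id} column is kept.
#'
#' @param path Path to the observation CSV.
#' @param weather Optional weather table (data.frame with \code{date} and
#'   \code{tmean}, or \code{tmin}/\code{tmax} which are averaged), used to
#'   convert dates to thermal time.
#' @param base_temp Base temperature for the date-to-TT conversion, degC.
#' @return A validated observation data.frame.
#' @export
read_observations <- function(path, weather = NULL, base_temp = 10) {
  if (!file.exists(path)) {
    stop(sprintf("observation file not found: %s", path), call. = FALSE)
  }
  obs <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(obs) == 0L) {
    stop(sprintf("observation file is empty: %s", path), call. = FALSE)
  }
  if (!"tt" %in% names(obs) && "date" %in% names(obs)) {
    if (is.null(weather)) {
      stop("observations carry dates, not thermal time: supply a ",
           "weather table", call. = FALSE)
    }
    wt <- normalize_weather(weather)
    ts <- accumulate_thermal_time(wt$tmean, base_temp)
    idx <- match(as.Date(obs$date), wt$date)
    if (any(is.na(idx))) {
      stop("observation date(s) outside the weather series: ",
           paste(utils::head(obs$date[is.na(idx)], 3L), collapse = ", "),
           call. = FALSE)
    }
    obs$tt <- ts$tt[idx]
  }
  check_observations(obs, context = sprintf("'%s'", path))
}

#' Write an SSA observation table to CSV
#'
#' @param obs Observation data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_observations <- function(obs, path) {
  obs <- check_observations(obs)
  # full 17-significant-digit formatting so write -> read round-trips
  # doubles bit-exactly
  fmt <- obs
  for (col in names(fmt)) {
    if (is.double(fmt[[col]])) fmt[[col]] <- sprintf("%.17g", fmt[[col]])
  }
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily weather CSV
#'
#' Columns: \code{date} (ISO-8601) and \code{tmean}, or \code{tmin} and
#' \code{tmax} (averaged into \code{tmean}).
#'
#' @param path Path to the weather CSV.
#' @return data.frame with \code{date} (Date) and \code{tmean}.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("weather file not found: %s", path), call. = FALSE)
  }
  normalize_weather(read.csv(path, stringsAsFactors = FALSE))
}

normalize_weather <- function(wt) {
  stopifnot(is.data.frame(wt), "date" %in% names(wt))
  if (!"tmean" %in% names(wt)) {
    if (!all(c("tmin", "tmax") %in% names(wt))) {
      stop("weather table needs 'tmean' or both 'tmin' and 'tmax'",
           call. = FALSE)
    }
    wt$tmean <- (wt$tmin + wt$tmax) / 2
  }
  wt$date <- as.Date(wt$date)
  wt[order(wt$date), c("date", "tmean")]
}

#' Read cultivar parameter sets from a YAML config file
#'
#' One block per cultivar, keys matching the arguments of
#' \code{\link{cultivar_params}}: \code{subspecies}, \code{phyl_a},
#' \code{phyl_b}, \code{mmax_ssa3}, optional \code{base_temp} and
#' \code{final_rank}. See \code{system.file("extdata",
#' "cultivars.yml", package = "riceSSA")} for the layout.
#'
#' @param path Path to the YAML file.
#' @return Named list of \code{\link{cultivar_params}}.
#' @export
read_cultivar_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cultivar config not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0L) stop("empty cultivar config", call. = FALSE)
  out <- lapply(names(cfg), function(nm) {
    b <- cfg[[nm]]
    cultivar_params(
      name = nm, subspecies = b$subspecies,
      phyl_a = b$phyl_a, phyl_b = b$phyl_b, mmax_ssa3 = b$mmax_ssa3,
      base_temp = b$base_temp,
      final_rank = if (is.null(b$final_rank)) 15L else b$final_rank)
  })
  stats::setNames(out, names(cfg))
}

#' Write a coefficient report
#'
#' Serializes one or more \code{ssa_fit} results as JSON (coefficients,
#' R-squared and point count per fit) and, optionally, as a long CSV.
#'
#' @param fits Named list of \code{ssa_fit} objects.
#' @param path Output path ending in \code{.json} or \code{.csv}.
#' @return \code{path}, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  stopifnot(is.list(fits), length(fits) > 0L, !is.null(names(fits)))
  rep <- lapply(fits, function(f) {
    list(coefficients = as.list(f$coefficients),
         r_squared = f$r_squared, n_points = f$n_points)
  })
  if (grepl("\\.csv$", path)) {
    long <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      data.frame(fit = nm, coefficient = names(f$coefficients),
                 value = unname(f$coefficients),
                 r_squared = f$r_squared, n_points = f$n_points)
    }))
    write.csv(long, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a validation report
#'
#' @param report An \code{\link{validate_dataset}} result.
#' @param path Output path ending in \code{.json} or \code{.csv} (the CSV
#'   holds the per-group table; the JSON also carries the overall value).
#' @param pairs_path Optional CSV path for the per-observation
#'   (simulated, measured) pairs, e.g. for a scatter plot.
#' @return \code{path}, invisibly.
#' @export
write_validation_report <- function(report, path, pairs_path = NULL) {
  stopifnot(inherits(report, "ssa_validation"))
  if (grepl("\\.csv$", path)) {
    write.csv(report$by_group, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(overall_rrmse = report$overall_rrmse,
           n_points = report$n_points,
           by_group = report$by_group,
           skipped = report$skipped),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(pairs_path)) {
    write.csv(report$pairs, pairs_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
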