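#' @importFrom stats rnorm quantile aggregate anova
NULL

#' Scenario specification for the synthetic-data generator
#'
#' Describes one simulated measurement campaign with the structure of the
#' pot experiments the model was built from: a few cultivars, several
#' nitrogen rates each summarized by a constant (ANCSH, AGB) pair, leaf
#' ranks observed every other day on a handful of tagged plants, and a
#' multiplicative measurement error with relative SD \code{noise_cv}
#' (protractor readings carry a relative standard error under 10 percent).
#'
#' @param cultivars Named list of \code{\link{cultivar_params}}; defaults
#'   to \code{\link{default_cultivars}()}.
#' @param n_rates data.frame with columns \code{n_rate}, \code{ancsh}
#'   (N concentration, percent) and \code{agb} (biomass, t/ha). The
#'   default three rates span nitrogen-limited to non-limiting (FN from
#'   about 0.6 to 1).
#' @param ranks Integer leaf ranks to observe (default 1..8).
#' @param replicates Tagged plants per treatment (default 4).
#' @param noise_cv Relative SD of measurement error (default 0.05; keep
#'   at or below 0.1 to match the measurement protocol).
#' @param n_days Season length in days (default 120).
#' @param temp_mean,temp_amplitude,temp_noise_sd Weather-generator
#'   parameters, degC (defaults 25, 5, 1.5).
#' @param sample_every Days between measurements (default 2).
#' @return A list of class \code{"ssa_scenario"}.
#' @export
ssa_scenario <- function(cultivars = default_cultivars(),
                         n_rates = data.frame(
                           n_rate = c("N1", "N2", "N3"),
                           ancsh = c(2.2, 3.1, 3.8),
                           agb = c(2.0, 2.0, 2.0)),
                         ranks = 1:8, replicates = 4L, noise_cv = 0.05,
                         n_days = 120L, temp_mean = 25,
                         temp_amplitude = 5, temp_noise_sd = 1.5,
                         sample_every = 2L) {
  if (inherits(cultivars, "cultivar_params")) {
    cultivars <- stats::setNames(list(cultivars), cultivars$name)
  }
  stopifnot(length(cultivars) >= 1L,
            all(vapply(cultivars, inherits, logical(1), "cultivar_params")),
            is.data.frame(n_rates),
            all(c("n_rate", "ancsh", "agb") %in% names(n_rates)),
            replicates >= 1L, n_days >= 1L, sample_every >= 1L)
  if (noise_cv < 0 || noise_cv > 0.1) {
    stop("'noise_cv' must lie in [0, 0.1]", call. = FALSE)
  }
  ranks <- check_rank(ranks, max_rank = 9L)
  structure(
    list(cultivars = cultivars, n_rates = n_rates, ranks = ranks,
         replicates = as.integer(replicates), noise_cv = noise_cv,
         n_days = as.integer(n_days), temp_mean = temp_mean,
         temp_amplitude = temp_amplitude, temp_noise_sd = temp_noise_sd,
         sample_every = as.integer(sample_every)),
    class = "ssa_scenario"
  )
}

#' Generate a daily temperature series
#'
#' A half-sine seasonal course (coolest at the season's ends, warmest in
#' the middle) plus independent Gaussian day-to-day noise. Reproducible
#' for a fixed seed.
#'
#' @param n_days Number of days (>= 1).
#' @param mean Season mean temperature, degC.
#' @param amplitude Peak seasonal excursion above/below the mean, degC.
#' @param noise_sd SD of day-to-day noise, degC.
#' @param seed Optional integer seed.
#' @return Numeric vector of daily mean temperatures.
#' @export
generate_weather <- function(n_days, mean = 25, amplitude = 5,
                             noise_sd = 1.5, seed = NULL) {
  stopifnot(n_days >= 1L)
  if (!is.null(seed)) set.seed(seed)
  day <- seq_len(n_days)
  seasonal <- mean + amplitude * sin(pi * (day - 0.5) / n_days) -
    amplitude / 2
  seasonal + rnorm(n_days, sd = noise_sd)
}

#' Generate a synthetic SSA observation table
#'
#' Runs the forward model over a generated season and perturbs it the way
#' the measurement protocol would: for every cultivar, nitrogen rate,
#' tagged plant and leaf rank, the true SSA at each every-other-day visit
#' is multiplied by \code{1 + e} with \code{e} mean-zero Gaussian of SD
#' \code{noise_cv}, truncated to 4 SDs and to non-negative angles. The
#' generating parameters are returned alongside so calibration routines
#' can be checked for parameter recovery.
#'
#' @param spec An \code{\link{ssa_scenario}}.
#' @param seed Optional integer seed covering weather and noise.
#' @param lc,rp Logistic and rank-profile coefficients used as truth.
#' @return A list with \code{observations} (data.frame: cultivar, n_rate,
#'   rank, plant_id, day, tt, ssa_deg), \code{weather} (daily temperature
#'   vector) and \code{truth} (generating coefficients, per-group FN and
#'   MaxSSA3, noise level).
#' @examples
#' d <- generate_dataset(ssa_scenario(ranks = 3:5, replicates = 1), seed = 1)
#' head(d$observations)
#' @export
generate_dataset <- function(spec = ssa_scenario(), seed = NULL,
                             lc = logistic_coeffs(), rp = rank_profile()) {
  stopifnot(inherits(spec, "ssa_scenario"))
  if (!is.null(seed)) set.seed(seed)
  temps <- generate_weather(spec$n_days, spec$temp_mean,
                            spec$temp_amplitude, spec$temp_noise_sd)
  obs_days <- seq(spec$sample_every, spec$n_days, by = spec$sample_every)

  fn_tab <- spec$n_rates
  rows <- list()
  truth_groups <- list()
  for (cv_name in names(spec$cultivars)) {
    cv <- spec$cultivars[[cv_name]]
    tt_all <- accumulate_thermal_time(temps, cv$base_temp)$tt
    tt_obs <- tt_all[obs_days]
    for (i in seq_len(nrow(fn_tab))) {
      fn <- nitrogen_factor(
        fn_tab$ancsh[i], critical_n_concentration(fn_tab$agb[i]))
      truth_groups[[length(truth_groups) + 1L]] <- data.frame(
        cultivar = cv_name, n_rate = fn_tab$n_rate[i], fn = fn,
        max_ssa3 = max_ssa3(cv, fn))
      for (rk in spec$ranks) {
        true_ssa <- simulate_ssa(rk, tt_obs, cv, fn, lc, rp)
        for (p in seq_len(spec$replicates)) {
          eps <- rnorm(length(tt_obs), sd = spec$noise_cv)
          eps <- pmin(pmax(eps, -4 * spec$noise_cv), 4 * spec$noise_cv)
          rows[[length(rows) + 1L]] <- data.frame(
            cultivar = cv_name, n_rate = fn_tab$n_rate[i], rank = rk,
            plant_id = sprintf("p%d", p), day = obs_days, tt = tt_obs,
            ssa_deg = pmax(true_ssa * (1 + eps), 0))
        }
      }
    }
  }
  observations <- do.call(rbind, rows)
  rownames(observations) <- NULL
  list(
    observations = observations,
    weather = temps,
    truth = list(
      logistic = lc, rank_profile = rp, cultivars = spec$cultivars,
      groups = do.call(rbind, truth_groups), noise_cv = spec$noise_cv,
      n_rates = spec$n_rates,
      # per-(cultivar, N rate) nitrogen inputs, ready for
      # validate_dataset() / calibrate_ssa_model()
      scenario = merge(
        data.frame(cultivar = names(spec$cultivars)), spec$n_rates))
  )
}
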