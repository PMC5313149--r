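#' Relative root mean square error
#'
#' RMSE of simulated against measured values expressed as a percentage of
#' the mean measured value, the customary crop-model agreement statistic:
#' \eqn{RRMSE = 100 \sqrt{mean((sim - obs)^2)} / mean(obs)}.
#'
#' @param simulated,measured Equal-length numeric vectors (degrees, or any
#'   common unit); \code{mean(measured)} must be positive.
#' @return RRMSE in percent (scale-invariant: rescaling both inputs by
#'   the same positive factor leaves it unchanged).
#' @examples
#' rrmse(c(12, 18, 33), c(10, 20, 30))  # 11.90
#' @export
rrmse <- function(simulated, measured) {
  if (length(simulated) != length(measured)) {
    stop("'simulated' and 'measured' must have equal length", call. = FALSE)
  }
  if (length(measured) < 1L) stop("need at least one pair", call. = FALSE)
  if (any(!is.finite(simulated)) || any(!is.finite(measured))) {
    stop("inputs must be finite", call. = FALSE)
  }
  m <- mean(measured)
  if (m <= 0) {
    stop("mean of measured values must be positive", call. = FALSE)
  }
  100 * sqrt(mean((simulated - measured)^2)) / m
}

#' Validate the SSA model against an observation table
#'
#' Follows the four-step validation recipe: (1) the nitrogen impact
#' factor FN is computed for each (cultivar, N rate) from the actual N
#' concentration and the critical concentration given by the dilution
#' curve; (2) MaxSSA_3 = MMaxSSA_3 * FN; (3) MaxSSA_n from the rank
#' profile; (4) SSA simulated through the normalized logistic at each
#' observation's thermal time. Simulated and measured angles are then
#' compared by RRMSE per group and pooled over all pairs (concatenated,
#' not averaged over groups).
#'
#' Instead of (ANCSH, AGB), a group may carry a known \code{max_ssa3}
#' directly (e.g. one reported from data analysis), which bypasses the
#' nitrogen steps. Groups with neither are flagged and excluded from the
#' pooled statistic.
#'
#' @param obs Observation data.frame (see \code{\link{read_observations}}).
#' @param cultivars Named list of \code{\link{cultivar_params}} or a
#'   single object.
#' @param scenario data.frame with columns \code{cultivar}, \code{n_rate}
#'   and either \code{ancsh} + \code{agb} (N status per group) or
#'   \code{max_ssa3} (direct plateau of the 3rd leaf, degrees).
#' @param lc,rp Logistic and rank-profile coefficient objects.
#' @param dil_a,dil_b Critical-N dilution-curve coefficients.
#' @return An object of class \code{"ssa_validation"}: list with
#'   \code{pairs} (per-observation table with a \code{simulated} column),
#'   \code{by_group} (per-group RRMSE), \code{overall_rrmse},
#'   \code{n_points}, and \code{skipped} (groups lacking inputs).
#' @export
validate_dataset <- function(obs, cultivars, scenario,
                             lc = logistic_coeffs(), rp = rank_profile(),
                             dil_a = 5.18, dil_b = 0.52) {
  obs <- check_observations(obs)
  cultivars <- as_cultivar_list(cultivars, unique(obs$cultivar))
  scenario <- resolve_scenario_max3(scenario, cultivars, dil_a, dil_b)

  skey <- paste(scenario$cultivar, scenario$n_rate, sep = "\r")
  okey <- paste(obs$cultivar, obs$n_rate, sep = "\r")
  unmatched <- setdiff(unique(okey), skey)
  max3 <- scenario$.max3[match(okey, skey)]

  skipped <- unique(obs[is.na(max3), c("cultivar", "n_rate")])
  if (nrow(skipped) > 0L) {
    warning(sprintf(
      "%d group(s) lack nitrogen status or a direct MaxSSA3 and are %s",
      nrow(skipped), "excluded from the pooled RRMSE"), call. = FALSE)
  }
  keep <- !is.na(max3)
  if (!any(keep)) {
    stop("no observation group has resolvable model inputs; scenario ",
         "cultivar/N-rate labels may not match the observations (",
         paste(gsub("\r", "/", unmatched), collapse = ", "), ")",
         call. = FALSE)
  }
  pairs <- obs[keep, , drop = FALSE]
  m3 <- max3[keep]
  pairs$simulated <- vapply(seq_len(nrow(pairs)), function(i) {
    cv <- cultivars[[pairs$cultivar[i]]]
    normalized_ssa(pairs$tt[i], pairs$rank[i], cv, lc) *
      rank_profile_ratio(pairs$rank[i], rp) * m3[i]
  }, numeric(1))

  grp <- interaction(pairs$cultivar, pairs$n_rate, drop = TRUE, sep = " / ")
  by_group <- do.call(rbind, lapply(levels(grp), function(g) {
    d <- pairs[grp == g, , drop = FALSE]
    data.frame(group = g, rrmse = rrmse(d$simulated, d$ssa_deg),
               n_points = nrow(d))
  }))
  structure(
    list(pairs = pairs, by_group = by_group,
         overall_rrmse = rrmse(pairs$simulated, pairs$ssa_deg),
         n_points = nrow(pairs), skipped = skipped),
    class = "ssa_validation"
  )
}

#' @export
print.ssa_validation <- function(x, ...) {
  cat("<ssa_validation>\n")
  for (i in seq_len(nrow(x$by_group))) {
    cat(sprintf("  %-24s RRMSE %6.2f %% (n = %d)\n",
                x$by_group$group[i], x$by_group$rrmse[i],
                x$by_group$n_points[i]))
  }
  cat(sprintf("  overall RRMSE %.2f %% on %d pooled pairs\n",
              x$overall_rrmse, x$n_points))
  if (nrow(x$skipped) > 0L) {
    cat(sprintf("  (%d group(s) skipped for missing inputs)\n",
                nrow(x$skipped)))
  }
  invisible(x)
}
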