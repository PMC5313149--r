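#' @importFrom stats lm coef fitted resid aov pf predict setNames
#' @importFrom minpack.lm nlsLM
NULL

# Bundle coefficients + goodness of fit the way all fit_* functions
# return them.
new_ssa_fit <- function(coefficients, observed, fitted, n_points) {
  residuals <- observed - fitted
  ss_res <- sum(residuals^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(coefficients = coefficients, r_squared = r2,
         n_points = n_points, residuals = residuals, fitted = fitted),
    class = "ssa_fit"
  )
}

#' @export
print.ssa_fit <- function(x, ...) {
  cat("<ssa_fit>\n  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "),
      sprintf("\n  R^2 = %.4f on %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.ssa_fit <- function(object, ...) object$coefficients

#' Per-group maximum observed SSA
#'
#' The plateau SSA of each (cultivar, N rate, leaf rank) group is
#' estimated as the maximum of its measured values, the literal definition
#' used in calibration (not an asymptote fit).
#'
#' @param obs Observation data.frame with columns \code{cultivar},
#'   \code{n_rate}, \code{rank}, \code{tt}, \code{ssa_deg} (see
#'   \code{\link{read_observations}}).
#' @return A data.frame with one row per group and a \code{max_ssa}
#'   column, sorted by cultivar, N rate, rank.
#' @export
extract_max_ssa <- function(obs) {
  obs <- check_observations(obs)
  if (nrow(obs) == 0L) stop("no observations supplied", call. = FALSE)
  agg <- stats::aggregate(ssa_deg ~ cultivar + n_rate + rank, data = obs,
                          FUN = max)
  names(agg)[names(agg) == "ssa_deg"] <- "max_ssa"
  agg[order(agg$cultivar, agg$n_rate, agg$rank), , drop = FALSE]
}

#' Normalize observations for pooled logistic fitting
#'
#' Each measured angle is divided by its group's plateau (MaxSSA_n), and
#' each thermal time converted to normalized thermal time within the
#' leaf's development window. The normalized points from all cultivars and
#' N rates are pooled into one table; groups whose plateau is zero carry
#' no shape information and are skipped with a warning.
#'
#' By default the plateau is the group's observed maximum (its literal
#' definition). With measurement noise that maximum is biased upward —
#' the larger the plateau sample the more so — which compresses the
#' normalized curve; when the nitrogen inputs (or plateau angles) of each
#' group are known, pass them as \code{scenario} and the model-assigned
#' plateau MaxSSA_3 x profile ratio is used instead, which is unbiased.
#'
#' @param obs Observation data.frame (see \code{\link{extract_max_ssa}}).
#' @param cultivars Named list of \code{\link{cultivar_params}} covering
#'   every cultivar label in \code{obs}, or a single object.
#' @param scenario Optional data.frame with columns \code{cultivar},
#'   \code{n_rate} and either \code{max_ssa3} or \code{ancsh} +
#'   \code{agb}, fixing each group's plateau through the nitrogen model.
#' @param rp Rank profile used with \code{scenario}.
#' @return A data.frame with columns \code{cultivar}, \code{n_rate},
#'   \code{rank}, \code{ntt}, \code{nssa}, one row per observation kept.
#' @export
normalize_observations <- function(obs, cultivars, scenario = NULL,
                                   rp = rank_profile()) {
  obs <- check_observations(obs)
  cultivars <- as_cultivar_list(cultivars, unique(obs$cultivar))
  key <- function(d) paste(d$cultivar, d$n_rate, d$rank, sep = "\r")
  if (is.null(scenario)) {
    maxes <- extract_max_ssa(obs)
    mx <- maxes$max_ssa[match(key(obs), key(maxes))]
  } else {
    max3 <- resolve_scenario_max3(scenario, cultivars)
    gkey <- paste(max3$cultivar, max3$n_rate, sep = "\r")
    m3 <- max3$.max3[match(paste(obs$cultivar, obs$n_rate, sep = "\r"),
                           gkey)]
    if (any(is.na(m3))) {
      stop("scenario does not cover every (cultivar, N rate) group in ",
           "the observations", call. = FALSE)
    }
    mx <- m3 * rank_profile_ratio(obs$rank, rp)
  }
  zero <- mx <= 0
  if (any(zero)) {
    bad <- unique(paste(obs$cultivar, obs$n_rate, obs$rank)[zero])
    warning(sprintf("skipping %d group(s) with zero maximum SSA: %s",
                    length(bad), paste(bad, collapse = "; ")),
            call. = FALSE)
    obs <- obs[!zero, , drop = FALSE]
    mx <- mx[!zero]
  }
  ntt <- vapply(seq_len(nrow(obs)), function(i) {
    cv <- cultivars[[obs$cultivar[i]]]
    normalize_tt(obs$tt[i], obs$rank[i], cv)
  }, numeric(1))
  data.frame(cultivar = obs$cultivar, n_rate = obs$n_rate,
             rank = obs$rank, ntt = ntt, nssa = obs$ssa_deg / mx)
}

#' Fit the two-parameter logistic to pooled normalized SSA
#'
#' Least-squares fit of \eqn{y = 1 / (1 + A e^{-B x})} to (normalized TT,
#' normalized SSA) pairs by Levenberg-Marquardt, started from (A, B) =
#' (10, 5) with both coefficients bounded below by zero. Points outside
#' the development window (NTT outside [0, 1]) belong to the constant
#' branches, not the logistic, and are excluded from the fit.
#'
#' @param ntt Normalized thermal time values.
#' @param nssa Normalized SSA values (same length).
#' @param start Named starting values for \code{ssa_a}, \code{ssa_b}.
#' @return An \code{ssa_fit} with coefficients \code{ssa_a}, \code{ssa_b}.
#' @examples
#' x <- seq(0, 1, length.out = 50)
#' f <- fit_logistic(x, 1 / (1 + 17.62 * exp(-6.88 * x)))
#' coef(f)
#' @export
fit_logistic <- function(ntt, nssa, start = c(ssa_a = 10, ssa_b = 5)) {
  stopifnot(length(ntt) == length(nssa))
  keep <- is.finite(ntt) & is.finite(nssa) & ntt >= 0 & ntt <= 1
  x <- ntt[keep]
  y <- nssa[keep]
  if (length(x) < 3L) {
    stop("need at least 3 points with normalized TT in [0, 1] to fit ",
         "the logistic", call. = FALSE)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + ssa_a * exp(-ssa_b * x)),
      start = as.list(start),
      lower = c(ssa_a = 1e-8, ssa_b = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf(
        "logistic fit did not converge (%d points, y range [%.3g, %.3g]): %s",
        length(x), min(y), max(y), conditionMessage(e)), call. = FALSE)
    }
  )
  new_ssa_fit(coef(fit), y, fitted(fit), length(x))
}

#' Fit the leaf-appearance power law
#'
#' Least-squares fit of \eqn{leaves = a \cdot TT^b} to (thermal time, leaf
#' count) pairs: an ordinary regression in log-log space seeds a
#' Levenberg-Marquardt refinement in natural space, so the reported
#' coefficients minimize the untransformed residuals.
#'
#' @param tt Thermal times, degC d (> 0).
#' @param leaves Main-stem leaf counts (> 0, same length).
#' @return An \code{ssa_fit} with coefficients \code{phyl_a},
#'   \code{phyl_b}.
#' @export
fit_leaf_appearance <- function(tt, leaves) {
  stopifnot(length(tt) == length(leaves))
  if (length(tt) < 3L) {
    stop("need at least 3 (TT, leaf count) pairs", call. = FALSE)
  }
  if (any(!is.finite(tt)) || any(tt <= 0) ||
      any(!is.finite(leaves)) || any(leaves <= 0)) {
    stop("thermal times and leaf counts must be positive", call. = FALSE)
  }
  if (diff(range(leaves)) == 0 || diff(range(tt)) == 0) {
    stop("degenerate input: leaf counts or thermal times are constant",
         call. = FALSE)
  }
  ll <- lm(log(leaves) ~ log(tt))
  start <- list(phyl_a = exp(unname(coef(ll)[1])),
                phyl_b = unname(coef(ll)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(leaves ~ phyl_a * tt^phyl_b, start = start,
                      lower = c(phyl_a = 1e-10, phyl_b = 1e-10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("power-law fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  new_ssa_fit(coef(fit), leaves, fitted(fit), length(tt))
}

#' Fit the piecewise-linear rank profile
#'
#' Two independent ordinary-least-squares lines through the normalized
#' maximum-SSA values: one over ranks 1..break_rank, one over the ranks
#' above. The breakpoint is fixed, not estimated, and no continuity
#' constraint ties the segments (the calibrated coefficients themselves
#' disagree slightly at the break).
#'
#' @param rank Integer leaf ranks.
#' @param ratio Normalized maximum SSA values MaxSSA_n / MaxSSA_3.
#' @param break_rank Last rank of the first segment (default 3).
#' @return An \code{ssa_fit} with coefficients \code{sln_a}, \code{sln_b},
#'   \code{sln_c}, \code{sln_d}.
#' @export
fit_rank_profile <- function(rank, ratio, break_rank = 3L) {
  stopifnot(length(rank) == length(ratio))
  lo <- rank <= break_rank
  if (sum(lo) < 2L) {
    stop(sprintf("need at least 2 points with rank <= %d for the first ",
                 break_rank), "segment", call. = FALSE)
  }
  if (sum(!lo) < 2L) {
    stop(sprintf("need at least 2 points with rank > %d for the second ",
                 break_rank), "segment", call. = FALSE)
  }
  f1 <- lm(ratio ~ rank, subset = lo)
  f2 <- lm(ratio ~ rank, subset = !lo)
  coefs <- c(sln_a = unname(coef(f1)[2]), sln_b = unname(coef(f1)[1]),
             sln_c = unname(coef(f2)[2]), sln_d = unname(coef(f2)[1]))
  fitted_all <- ifelse(lo,
                       coefs["sln_a"] * rank + coefs["sln_b"],
                       coefs["sln_c"] * rank + coefs["sln_d"])
  new_ssa_fit(coefs, ratio, fitted_all, length(rank))
}

#' Test for differences between normalized SSA curves
#'
#' Checks whether the normalized development curves of different groups
#' (cultivar x N rate) can be pooled: an analysis of variance of the
#' normalized SSA on a normalized-TT decile bin (to absorb the common
#' sigmoid trend) plus the group factor, reporting the group-effect
#' p-value overall and for each pair of groups. The design is a
#' pragmatic stand-in (the original analysis-of-variance layout is not
#' fully specified); the p-values are reported, never used as a gate.
#'
#' @param ntt Normalized thermal time values.
#' @param nssa Normalized SSA values.
#' @param group Factor (or coercible) identifying each point's group.
#' @param bins Number of NTT bins (default 10, i.e. deciles).
#' @return A data.frame with columns \code{comparison}, \code{p_value},
#'   \code{n_points}; the first row is the overall test.
#' @export
group_difference_test <- function(ntt, nssa, group, bins = 10L) {
  stopifnot(length(ntt) == length(nssa), length(nssa) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2L) {
    stop("need at least 2 groups to compare", call. = FALSE)
  }
  run_one <- function(keep, label) {
    g <- droplevels(group[keep])
    x <- ntt[keep]
    y <- nssa[keep]
    bin <- cut(x, breaks = unique(stats::quantile(x, probs =
                 seq(0, 1, length.out = bins + 1L))), include.lowest = TRUE)
    tab <- stats::anova(aov(y ~ bin + g))
    p <- tab["g", "Pr(>F)"]
    # zero between-group variance gives F = 0 -> p = 1
    if (is.na(p) && tab["g", "Sum Sq"] < .Machine$double.eps) p <- 1
    data.frame(comparison = label, p_value = p, n_points = sum(keep))
  }
  out <- run_one(rep(TRUE, length(group)), "overall")
  lev <- levels(group)
  for (i in seq_len(length(lev) - 1L)) {
    for (j in seq(i + 1L, length(lev))) {
      keep <- group %in% lev[c(i, j)]
      out <- rbind(out, run_one(keep, paste(lev[i], "vs", lev[j])))
    }
  }
  rownames(out) <- NULL
  out
}

#' Calibrate every model coefficient from an observation table
#'
#' Runs the full calibration pipeline on one observation table: plateau
#' extraction, normalization, the pooled logistic fit, and the
#' piecewise-linear rank-profile fit (on per-group profiles normalized by
#' their rank-\code{break_rank} plateau, pooled). Leaf-appearance
#' coefficients need (TT, leaf count) data and are fitted separately via
#' \code{\link{fit_leaf_appearance}}.
#'
#' @param obs Observation data.frame (see \code{\link{read_observations}}).
#' @param cultivars Named list of \code{\link{cultivar_params}} (or one
#'   object) used to compute normalized thermal time.
#' @param scenario Optional data.frame with columns \code{cultivar},
#'   \code{n_rate} and either \code{max_ssa3} or \code{ancsh} +
#'   \code{agb}: when given, each group's plateau profile is normalized
#'   by the MaxSSA_3 the nitrogen model assigns to that group; otherwise
#'   the group's observed rank-\code{break_rank} plateau is used.
#' @param break_rank Fixed breakpoint of the rank profile.
#' @return A list with elements \code{logistic} and \code{profile} (both
#'   \code{ssa_fit}), \code{max_ssa} (the plateau table) and
#'   \code{group_test} (the pooled-curve difference test, or NULL with a
#'   single group).
#' @export
calibrate_ssa_model <- function(obs, cultivars, scenario = NULL,
                                break_rank = 3L) {
  obs <- check_observations(obs)
  norm <- normalize_observations(obs, cultivars, scenario)
  logistic <- fit_logistic(norm$ntt, norm$nssa)
  maxes <- extract_max_ssa(obs)
  max3 <- if (!is.null(scenario)) {
    resolve_scenario_max3(scenario,
                          as_cultivar_list(cultivars, unique(obs$cultivar)))
  }
  prof <- profile_pairs(maxes, break_rank, max3)
  profile <- fit_rank_profile(prof$rank, prof$ratio, break_rank)
  grp <- interaction(norm$cultivar, norm$n_rate, drop = TRUE)
  group_test <- if (nlevels(grp) >= 2L) {
    group_difference_test(norm$ntt, norm$nssa, grp)
  }
  list(logistic = logistic, profile = profile, max_ssa = maxes,
       group_test = group_test)
}

# Normalize each (cultivar, n_rate) plateau profile by its MaxSSA_3 —
# the model-assigned value when a resolved scenario is supplied, else the
# observed plateau at the breakpoint rank — and pool across groups.
profile_pairs <- function(maxes, break_rank = 3L, max3 = NULL) {
  out <- do.call(rbind, lapply(
    split(maxes, list(maxes$cultivar, maxes$n_rate), drop = TRUE),
    function(d) {
      ref <- if (!is.null(max3)) {
        hit <- max3$.max3[max3$cultivar == d$cultivar[1] &
                            max3$n_rate == d$n_rate[1]]
        if (length(hit) == 1L && is.finite(hit)) hit else numeric(0)
      } else {
        d$max_ssa[d$rank == break_rank]
      }
      if (length(ref) != 1L || ref <= 0) return(NULL)
      data.frame(rank = d$rank, ratio = d$max_ssa / ref)
    }))
  if (is.null(out) || nrow(out) == 0L) {
    stop(sprintf("no group has a positive MaxSSA_3 (rank %d) to ",
                 break_rank), "normalize by", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Resolve per-(cultivar, n_rate) MaxSSA_3 from a scenario table: a direct
# max_ssa3 column wins; otherwise (ancsh, agb) run through the dilution
# curve and nitrogen factor. Returns the scenario with a .max3 column.
resolve_scenario_max3 <- function(scenario, cultivars,
                                  dil_a = 5.18, dil_b = 0.52) {
  stopifnot(is.data.frame(scenario),
            all(c("cultivar", "n_rate") %in% names(scenario)))
  has_direct <- "max_ssa3" %in% names(scenario)
  has_n <- all(c("ancsh", "agb") %in% names(scenario))
  scenario$.max3 <- vapply(seq_len(nrow(scenario)), function(i) {
    row <- scenario[i, , drop = FALSE]
    if (has_direct && is.finite(row$max_ssa3)) return(row$max_ssa3)
    if (has_n && is.finite(row$ancsh) && is.finite(row$agb)) {
      fn <- nitrogen_factor(row$ancsh,
                            critical_n_concentration(row$agb, dil_a, dil_b))
      return(max_ssa3(cultivars[[row$cultivar]], fn))
    }
    NA_real_
  }, numeric(1))
  scenario
}

# Accept a single cultivar_params or a named list covering `needed`.
as_cultivar_list <- function(cultivars, needed) {
  if (inherits(cultivars, "cultivar_params")) {
    cultivars <- setNames(list(cultivars), cultivars$name)
  }
  stopifnot(is.list(cultivars))
  missing <- setdiff(needed, names(cultivars))
  if (length(missing) > 0L) {
    stop("no cultivar parameters supplied for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cultivars
}
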