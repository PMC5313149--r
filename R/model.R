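#' Thermal time at which the SSA of a leaf rank starts to develop
#'
#' The sheath of main-stem leaf n starts to lean away from the stem when
#' leaf n + 3 emerges. Inverting the leaf-appearance power law
#' \eqn{leaves = a \cdot TT^b} gives the start of the development window:
#' \eqn{ITT_n = ((n + 2) / a)^{1/b}} degC d after sowing.
#'
#' @param n Integer leaf rank(s), 1 <= n <= \code{cv$final_rank}.
#' @param cv A \code{\link{cultivar_params}} object.
#' @return Thermal time, degC d; strictly increasing in \code{n}.
#' @examples
#' initial_tt(3, default_cultivars("YD6"))  # ~273 degC d
#' @export
initial_tt <- function(n, cv) {
  n <- check_rank(n, max_rank = cv$final_rank)
  ((n + 2) / cv$phyl_a)^(1 / cv$phyl_b)
}

#' Thermal-time duration of the SSA development window
#'
#' The window spans three leaf-appearance intervals: from the emergence of
#' leaf n + 3 to that of leaf n + 6, i.e.
#' \eqn{\Delta TT_n = ((n + 5)/a)^{1/b} - ((n + 2)/a)^{1/b}}.
#'
#' @inheritParams initial_tt
#' @return Window length, degC d; strictly positive.
#' @export
ssa_window <- function(n, cv) {
  n <- check_rank(n, max_rank = cv$final_rank)
  ((n + 5) / cv$phyl_a)^(1 / cv$phyl_b) -
    ((n + 2) / cv$phyl_a)^(1 / cv$phyl_b)
}

#' Normalized thermal time within a leaf's development window
#'
#' \eqn{NTT_n = (TT - ITT_n) / \Delta TT_n}: 0 at the window start, 1 at
#' its end, linear in TT. Values outside [0, 1] are returned as-is; the
#' branches of \code{\link{normalized_ssa}} handle them.
#'
#' @param tt Thermal time(s), degC d.
#' @param n Integer leaf rank.
#' @inheritParams initial_tt
#' @return Dimensionless normalized thermal time.
#' @export
normalize_tt <- function(tt, n, cv) {
  (tt - initial_tt(n, cv)) / ssa_window(n, cv)
}

#' Normalized SSA as a function of thermal time
#'
#' Piecewise development curve of SSA expressed as a fraction of the leaf's
#' plateau value: 0 before the window opens, the logistic
#' \eqn{1 / (1 + SSAa \, e^{-SSAb \cdot NTT_n})} inside it, and 1 after it
#' closes. The curve is implemented exactly as calibrated, including the
#' small jumps at the window edges (from 0 to \eqn{1/(1+SSAa)} at the
#' start, and from \eqn{1/(1+SSAa e^{-SSAb})} to 1 at the end); no
#' re-scaling is applied to force continuity.
#'
#' @inheritParams normalize_tt
#' @param lc A \code{\link{logistic_coeffs}} object.
#' @return Fraction of MaxSSA_n in [0, 1], nondecreasing in \code{tt}.
#' @examples
#' cv <- default_cultivars("YD6")
#' normalized_ssa(initial_tt(3, cv), 3, cv)  # 1/18.62 ~ 0.0537
#' @export
normalized_ssa <- function(tt, n, cv, lc = logistic_coeffs()) {
  itt <- initial_tt(n, cv)
  dtt <- ssa_window(n, cv)
  ntt <- (tt - itt) / dtt
  out <- 1 / (1 + lc$ssa_a * exp(-lc$ssa_b * ntt))
  out[tt < itt] <- 0
  out[tt > itt + dtt] <- 1
  out
}

#' Normalized maximum-SSA profile over leaf rank
#'
#' Ratio MaxSSA_n / MaxSSA_3 as a piecewise-linear function of rank:
#' increasing over ranks 1..3, decreasing over 4..9. Defined for integer
#' ranks 1..9 only; the calibration does not extend beyond rank 9, so
#' other ranks are rejected rather than extrapolated.
#'
#' @param n Integer leaf rank(s) in 1..9.
#' @param rp A \code{\link{rank_profile}} object.
#' @return Dimensionless ratio(s), maximal at rank 3 under the defaults.
#' @examples
#' rank_profile_ratio(3)  # 1.0056
#' @export
rank_profile_ratio <- function(n, rp = rank_profile()) {
  n <- check_rank(n, max_rank = 9L)
  ifelse(n <= rp$break_rank,
         rp$sln_a * n + rp$sln_b,
         rp$sln_c * n + rp$sln_d)
}

#' Critical nitrogen concentration from the dilution curve
#'
#' The most appropriate (critical) plant N concentration declines with
#' above-ground biomass as \eqn{MNCSH = a \cdot AGB^{-b}}.
#'
#' @param agb Above-ground biomass, t/ha (> 0).
#' @param dil_a,dil_b Dilution-curve coefficients.
#' @return Critical N concentration, percent of dry weight; strictly
#'   decreasing in \code{agb}.
#' @examples
#' critical_n_concentration(1.0)  # 5.18
#' @export
critical_n_concentration <- function(agb, dil_a = 5.18, dil_b = 0.52) {
  if (any(!is.finite(agb)) || any(agb <= 0)) {
    stop("'agb' must be positive and finite", call. = FALSE)
  }
  dil_a * agb^(-dil_b)
}

#' Nitrogen impact factor
#'
#' Ratio of actual to critical plant N concentration, clipped at 1: under
#' N deficit the factor scales the variety's maximum SSA down
#' proportionally; at or above the critical concentration nitrogen is
#' non-limiting.
#'
#' @param ancsh Actual N concentration, percent (>= 0).
#' @param mncsh Critical N concentration, percent (> 0).
#' @return FN in [0, 1].
#' @export
nitrogen_factor <- function(ancsh, mncsh) {
  if (any(!is.finite(mncsh)) || any(mncsh <= 0)) {
    stop("'mncsh' must be positive", call. = FALSE)
  }
  if (any(!is.finite(ancsh)) || any(ancsh < 0)) {
    stop("'ancsh' must be non-negative", call. = FALSE)
  }
  pmin(ancsh / mncsh, 1)
}

#' Nitrogen impact factor from a nitrogen_status object
#'
#' Convenience wrapper: computes the critical concentration from the
#' biomass via the dilution curve, then the clipped ratio.
#'
#' @param ns A \code{\link{nitrogen_status}} object.
#' @return FN in [0, 1].
#' @export
nitrogen_factor_for <- function(ns) {
  stopifnot(inherits(ns, "nitrogen_status"))
  nitrogen_factor(ns$ancsh,
                  critical_n_concentration(ns$agb, ns$dil_a, ns$dil_b))
}

#' Maximum SSA of the 3rd leaf under a given nitrogen status
#'
#' The cultivar's variety parameter scaled by the nitrogen impact factor:
#' \eqn{MaxSSA_3 = MMaxSSA_3 \cdot FN}.
#'
#' @param cv A \code{\link{cultivar_params}} object.
#' @param fn Nitrogen impact factor in [0, 1].
#' @return MaxSSA_3 in degrees, at most \code{cv$mmax_ssa3}.
#' @export
max_ssa3 <- function(cv, fn) {
  if (any(!is.finite(fn)) || any(fn < 0) || any(fn > 1)) {
    stop("'fn' must lie in [0, 1]", call. = FALSE)
  }
  cv$mmax_ssa3 * fn
}

#' Simulate the stem-sheath angle of one leaf rank
#'
#' Composition of the full model: the normalized development curve times
#' the rank profile times the nitrogen-scaled variety maximum,
#' \eqn{SSA_n(TT) = MMaxSSA_3 \cdot FN \cdot (MaxSSA_n/MaxSSA_3)
#' \cdot f(NTT_n)}. Zero before the window, plateaus at MaxSSA_n after it.
#'
#' @param n Integer leaf rank in 1..9.
#' @param tt Thermal time(s), degC d.
#' @param cv A \code{\link{cultivar_params}} object.
#' @param fn Nitrogen impact factor in [0, 1] (default 1: non-limiting N).
#' @param lc,rp Logistic and rank-profile coefficient objects.
#' @return SSA in degrees, same length as \code{tt}.
#' @examples
#' cv <- default_cultivars("YD6")
#' simulate_ssa(3, c(100, 300, 600), cv)  # rises from 0 towards 58.3 deg
#' @export
simulate_ssa <- function(n, tt, cv, fn = 1,
                         lc = logistic_coeffs(), rp = rank_profile()) {
  normalized_ssa(tt, n, cv, lc) * rank_profile_ratio(n, rp) *
    max_ssa3(cv, fn)
}

#' Main-stem leaf count at a given thermal time
#'
#' The leaf-appearance power law \eqn{leaves = a \cdot TT^b} (real-valued;
#' take \code{floor()} for emerged leaves). Inverse of
#' \code{\link{initial_tt}} in the sense
#' \code{leaf_count_at(initial_tt(n, cv), cv) == n + 2}.
#'
#' @param tt Thermal time(s) after sowing, degC d (>= 0).
#' @param cv A \code{\link{cultivar_params}} object.
#' @return Real-valued leaf count(s).
#' @export
leaf_count_at <- function(tt, cv) {
  if (any(!is.finite(tt)) || any(tt < 0)) {
    stop("'tt' must be non-negative and finite", call. = FALSE)
  }
  cv$phyl_a * tt^cv$phyl_b
}

# Validate integer leaf ranks; shared by the model operations.
check_rank <- function(n, max_rank) {
  if (length(n) == 0L || any(!is.finite(n)) || any(n != round(n))) {
    stop("leaf rank must be a finite integer", call. = FALSE)
  }
  if (any(n < 1) || any(n > max_rank)) {
    stop(sprintf("leaf rank must lie in 1..%d", max_rank), call. = FALSE)
  }
  as.integer(n)
}
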