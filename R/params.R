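#' Cultivar parameter set
#'
#' Bundles everything the SSA model needs to know about one rice cultivar:
#' the subspecies (which sets the default base temperature for thermal-time
#' accumulation), the leaf-appearance power-law coefficients relating
#' main-stem leaf count to thermal time after sowing, and the variety
#' parameter \code{mmax_ssa3}, the plateau SSA of the 3rd main-stem leaf
#' under non-limiting nitrogen.
#'
#' @param name Cultivar label, e.g. \code{"YD6"}.
#' @param subspecies Either \code{"japonica"} or \code{"indica"}.
#' @param phyl_a,phyl_b Coefficients of the leaf-appearance power law
#'   \eqn{leaves = a \cdot TT^b}. \code{phyl_a > 0}, \code{0 < phyl_b < 1}.
#' @param mmax_ssa3 Variety parameter: maximum SSA of the 3rd leaf under
#'   appropriate nitrogen, degrees, in (0, 90).
#' @param base_temp Base temperature for thermal time, degrees C. Defaults
#'   to 10 for japonica and 12 for indica.
#' @param final_rank Final leaf count on the main stem (integer, >= 4).
#'
#' @return An object of class \code{"cultivar_params"}.
#' @examples
#' yd6 <- cultivar_params("YD6", "indica", 0.0583, 0.7936, 58.0)
#' initial_tt(3, yd6)
#' @export
cultivar_params <- function(name, subspecies = c("japonica", "indica"),
                            phyl_a, phyl_b, mmax_ssa3,
                            base_temp = NULL, final_rank = 15L) {
  subspecies <- match.arg(subspecies)
  if (is.null(base_temp)) {
    base_temp <- if (subspecies == "japonica") 10 else 12
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(phyl_a) || phyl_a <= 0) {
    stop("'phyl_a' must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(phyl_b) || phyl_b <= 0 || phyl_b >= 1) {
    stop("'phyl_b' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(mmax_ssa3) || mmax_ssa3 <= 0 || mmax_ssa3 >= 90) {
    stop("'mmax_ssa3' must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  final_rank <- as.integer(final_rank)
  if (is.na(final_rank) || final_rank < 4L) {
    stop("'final_rank' must be an integer >= 4", call. = FALSE)
  }
  structure(
    list(name = name, subspecies = subspecies, base_temp = base_temp,
         phyl_a = phyl_a, phyl_b = phyl_b, mmax_ssa3 = mmax_ssa3,
         final_rank = final_rank),
    class = "cultivar_params"
  )
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat(sprintf("<cultivar_params> %s (%s)\n", x$name, x$subspecies))
  cat(sprintf("  base temperature : %g degC\n", x$base_temp))
  cat(sprintf("  leaf appearance  : leaves = %.4g * TT^%.4g\n",
              x$phyl_a, x$phyl_b))
  cat(sprintf("  MMaxSSA3         : %.1f deg, final rank %d\n",
              x$mmax_ssa3, x$final_rank))
  invisible(x)
}

#' Built-in cultivar parameter sets
#'
#' The two cultivars the model was calibrated for: 'Yangdao 6' (YD6, indica,
#' drooping leaf type) and 'Wuxiangjing 14' (W14, japonica, erect leaf
#' type), with their published leaf-appearance coefficients and variety
#' parameters.
#'
#' @param name Optional cultivar name; when given, the single matching
#'   \code{cultivar_params} object is returned instead of the full list.
#' @return A named list of \code{cultivar_params}, or one element of it.
#' @examples
#' default_cultivars()
#' default_cultivars("W14")$base_temp
#' @export
default_cultivars <- function(name = NULL) {
  cvs <- list(
    YD6 = cultivar_params("YD6", "indica",  phyl_a = 0.0583,
                          phyl_b = 0.7936, mmax_ssa3 = 58.0),
    W14 = cultivar_params("W14", "japonica", phyl_a = 0.0492,
                          phyl_b = 0.8062, mmax_ssa3 = 50.0)
  )
  if (is.null(name)) return(cvs)
  if (!name %in% names(cvs)) {
    stop(sprintf("unknown built-in cultivar '%s' (have: %s)", name,
                 paste(names(cvs), collapse = ", ")), call. = FALSE)
  }
  cvs[[name]]
}

#' Logistic shape coefficients of the normalized SSA curve
#'
#' The two coefficients of the pooled logistic
#' \eqn{1 / (1 + SSAa \, e^{-SSAb \cdot NTT})} describing normalized SSA
#' against normalized thermal time. Defaults are the published pooled-fit
#' values.
#'
#' @param ssa_a,ssa_b Positive coefficients; defaults 17.62 and 6.88.
#' @return An object of class \code{"logistic_coeffs"}.
#' @export
logistic_coeffs <- function(ssa_a = 17.62, ssa_b = 6.88) {
  if (!is.finite(ssa_a) || ssa_a <= 0 || !is.finite(ssa_b) || ssa_b <= 0) {
    stop("logistic coefficients must be positive and finite", call. = FALSE)
  }
  structure(list(ssa_a = ssa_a, ssa_b = ssa_b), class = "logistic_coeffs")
}

#' Piecewise-linear rank profile of normalized maximum SSA
#'
#' MaxSSA_n / MaxSSA_3 as a function of leaf rank n: one straight line for
#' ranks 1..break_rank (increasing) and a second for ranks above it
#' (decreasing), defined for ranks 1..9 only. Defaults are the published
#' coefficients with the breakpoint fixed between ranks 3 and 4.
#'
#' @param sln_a,sln_b Slope and intercept of the first segment.
#' @param sln_c,sln_d Slope and intercept of the second segment.
#' @param break_rank Last rank of the first segment (default 3).
#' @return An object of class \code{"rank_profile"}.
#' @export
rank_profile <- function(sln_a = 0.1334, sln_b = 0.6054,
                         sln_c = -0.1345, sln_d = 1.3507,
                         break_rank = 3L) {
  if (!is.finite(sln_a) || sln_a <= 0) {
    stop("'sln_a' (first-segment slope) must be positive", call. = FALSE)
  }
  if (!is.finite(sln_c) || sln_c >= 0) {
    stop("'sln_c' (second-segment slope) must be negative", call. = FALSE)
  }
  break_rank <- as.integer(break_rank)
  vals <- c(sln_a * (1:break_rank) + sln_b,
            sln_c * ((break_rank + 1L):9L) + sln_d)
  if (any(vals <= 0)) {
    stop("rank profile must be positive over ranks 1..9", call. = FALSE)
  }
  structure(list(sln_a = sln_a, sln_b = sln_b, sln_c = sln_c,
                 sln_d = sln_d, break_rank = break_rank),
            class = "rank_profile")
}

#' Plant nitrogen status
#'
#' Actual shoot nitrogen concentration and above-ground biomass, together
#' with the coefficients of the critical-nitrogen dilution curve
#' \eqn{MNCSH = a \cdot AGB^{-b}} used to judge whether nitrogen limits the
#' maximum SSA.
#'
#' @param ancsh Actual plant N concentration, percent of dry weight (>= 0).
#' @param agb Above-ground biomass, t/ha (> 0).
#' @param dil_a,dil_b Dilution-curve coefficients; defaults 5.18 and 0.52.
#' @return An object of class \code{"nitrogen_status"}.
#' @examples
#' ns <- nitrogen_status(ancsh = 2.59, agb = 1.0)
#' nitrogen_factor_for(ns)
#' @export
nitrogen_status <- function(ancsh, agb, dil_a = 5.18, dil_b = 0.52) {
  if (!is.finite(ancsh) || ancsh < 0) {
    stop("'ancsh' must be a non-negative N concentration (%)", call. = FALSE)
  }
  if (!is.finite(agb) || agb <= 0) {
    stop("'agb' must be a positive biomass (t/ha)", call. = FALSE)
  }
  if (!is.finite(dil_a) || dil_a <= 0 || !is.finite(dil_b) || dil_b <= 0) {
    stop("dilution-curve coefficients must be positive", call. = FALSE)
  }
  structure(list(ancsh = ancsh, agb = agb, dil_a = dil_a, dil_b = dil_b),
            class = "nitrogen_status")
}

#' Convert per-plant biomass to an area basis
#'
#' Pot experiments record shoot dry weight per plant; the dilution curve
#' wants t/ha. t/ha = g/plant * plants/m2 / 100.
#'
#' @param grams_per_plant Shoot dry weight, g per plant.
#' @param plants_per_m2 Plant density, plants per square metre.
#' @return Biomass in t/ha.
#' @export
agb_t_ha <- function(grams_per_plant, plants_per_m2) {
  stopifnot(all(grams_per_plant >= 0), all(plants_per_m2 > 0))
  grams_per_plant * plants_per_m2 / 100
}
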