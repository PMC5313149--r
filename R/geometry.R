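#' Leaf blade inclination from stem-sheath and sheath-blade angles
#'
#' The inclination of the blade's tangent line relative to the stem is the
#' stem-sheath angle plus the supplement of the sheath-blade (axial)
#' angle: inclination = SSA + (180 - SBA), all in degrees.
#'
#' @param ssa Stem-sheath angle, degrees, in [0, 90).
#' @param sba Sheath-blade angle, degrees, in (0, 180].
#' @return Blade inclination angle, degrees.
#' @examples
#' leaf_inclination(40, 160)  # 60
#' @export
leaf_inclination <- function(ssa, sba) {
  if (any(!is.finite(ssa)) || any(ssa < 0) || any(ssa >= 90)) {
    stop("'ssa' must lie in [0, 90) degrees", call. = FALSE)
  }
  if (any(!is.finite(sba)) || any(sba <= 0) || any(sba > 180)) {
    stop("'sba' must lie in (0, 180] degrees", call. = FALSE)
  }
  ssa + 180 - sba
}

#' Position of the sheath tip (leaf-blade basal point)
#'
#' Places the basal point of the blade in the vertical plane containing
#' the leaf: starting from the sheath's growing point on the stem, move
#' the sheath length along a direction tilted by the SSA from the stem
#' axis. Convention: y up along the stem, x the horizontal offset, angles
#' measured clockwise from the axis, so an SSA of 0 points straight up.
#'
#' @param ssa Stem-sheath angle, degrees, in [0, 90).
#' @param sheath_length Sheath length (any length unit, > 0).
#' @param base Numeric length-2 vector, the sheath base (x, y).
#' @return Numeric length-2 vector (x, y) of the sheath tip, in the units
#'   of \code{sheath_length}.
#' @examples
#' sheath_tip_position(30, 10)  # c(5, 8.6603)
#' @export
sheath_tip_position <- function(ssa, sheath_length, base = c(0, 0)) {
  if (!is.finite(ssa) || ssa < 0 || ssa >= 90) {
    stop("'ssa' must lie in [0, 90) degrees", call. = FALSE)
  }
  if (!is.finite(sheath_length) || sheath_length <= 0) {
    stop("'sheath_length' must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(base), length(base) == 2L)
  rad <- ssa * pi / 180
  c(base[1] + sheath_length * sin(rad),
    base[2] + sheath_length * cos(rad))
}
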