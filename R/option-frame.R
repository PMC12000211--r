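#' Option direction frame
#'
#' Builds the canonical two-dimensional frame for a pair of choice options
#' separated by the angle \code{gamma}. Option A is fixed along the positive
#' x-axis and option B is rotated counter-clockwise by \code{gamma}; any
#' global rotation of the plane is unidentifiable, so fixing the frame makes
#' all downstream computations reproducible. \code{gamma = pi} places the
#' options in direct opposition (relative evidence, diffusion decision
#' model); \code{gamma = pi/2} makes them orthogonal (absolute evidence,
#' racing accumulators).
#'
#' @param gamma Angle between the option direction vectors, in radians.
#'   Must lie in \eqn{(0, \pi]}.
#' @return An object of class \code{"option_frame"}: a list with elements
#'   \code{gamma}, \code{u_A} and \code{u_B} (unit 2-vectors).
#' @examples
#' fr <- option_frame(pi)       # diffusion geometry: u_B == -u_A
#' option_frame(pi / 2)         # accumulator geometry: orthogonal options
#' @export
option_frame <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma <= 0 || gamma > pi) {
    stop("`gamma` must lie in (0, pi], got ", format(gamma))
  }
  structure(
    list(gamma = gamma,
         u_A = c(1, 0),
         u_B = c(cos(gamma), sin(gamma))),
    class = "option_frame"
  )
}

#' @export
print.option_frame <- function(x, ...) {
  cat(sprintf("<option_frame> gamma = %.6f rad (%.1f deg)\n",
              x$gamma, x$gamma * 180 / pi))
  cat(sprintf("  u_A = (%.6f, %.6f)\n", x$u_A[1], x$u_A[2]))
  cat(sprintf("  u_B = (%.6f, %.6f)\n", x$u_B[1], x$u_B[2]))
  invisible(x)
}

#' Scalar projection of an evidence state onto an option direction
#'
#' The support an evidence state lends to a choice option is its scalar
#' component along the option's unit direction vector. A choice is
#' triggered when this component first reaches the threshold.
#'
#' @param state Numeric 2-vector (or n x 2 matrix of states).
#' @param direction Unit 2-vector describing the option.
#' @return Scalar component(s) of \code{state} along \code{direction}.
#' @examples
#' project(c(1, 1), c(1, 0))  # 1
#' @export
project <- function(state, direction) {
  stopifnot(is.numeric(direction), length(direction) == 2L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-8) {
    stop("`direction` must be a unit vector")
  }
  if (is.matrix(state)) {
    stopifnot(ncol(state) == 2L)
    return(drop(state %*% direction))
  }
  stopifnot(length(state) == 2L)
  sum(state * direction)
}

# Balance-of-evidence coordinate: the projection difference comp_A - comp_B.
# Positive values favor option A. For gamma = pi this equals twice the
# position along the A axis, so thresholds +/- theta map to balance +/- 2*theta.
balance_of <- function(x, y, gamma) {
  (x - (x * cos(gamma) + y * sin(gamma)))
}

# Unit vector of the balance axis (u_A - u_B normalized).
balance_axis <- function(frame) {
  d <- frame$u_A - frame$u_B
  d / sqrt(sum(d^2))
}
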