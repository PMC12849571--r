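#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor sd quantile approx shapiro.test t.test wilcox.test
#' @importFrom utils head tail
NULL

kin_directions <- c("AP", "ML", "V")
kin_speeds <- c("preferred", "fast", "slow")

#' Stop with a classed condition
#' @noRd
kin_stop <- function(message, class) {
  rlang::abort(message, class = c(class, "kinectome_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    kin_stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
             "kin_parameter_error")
  }
  invisible(x)
}

#' Rotation of horizontal (x, y) coordinates about the vertical axis
#'
#' @param xy two-column matrix
#' @param angle_rad rotation angle, positive counter-clockwise
#' @noRd
rotate_xy <- function(xy, angle_rad) {
  ca <- cos(angle_rad)
  sa <- sin(angle_rad)
  cbind(xy[, 1L] * ca - xy[, 2L] * sa,
        xy[, 1L] * sa + xy[, 2L] * ca)
}

#' Strictly-upper-triangle vectorisation (column-major, fixed order)
#' @noRd
upper_tri_vec <- function(m) m[upper.tri(m)]

#' Deterministic local RNG scope
#'
#' All stochastic routines take an explicit `seed`; evaluation never leaks
#' into the caller's RNG stream.
#' @noRd
with_kin_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
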