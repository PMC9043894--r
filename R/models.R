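#' Degradation model parameter constructors
#'
#' Two kinetic models describe the disappearance of an insecticidal Cry
#' protein from soil: single first-order decay to zero,
#' \eqn{Y = a e^{-bt}}, and a shifted ("plateau") exponential decaying to a
#' non-zero asymptote, \eqn{Y = Y_0 + a e^{-bt}}. `Y0` is the residual
#' concentration that is not degraded at late times, `a` the degradable
#' amplitude (both in ng per g dry soil) and `b` the decay rate constant in
#' 1/day.
#'
#' @param a Degradable amplitude, ng/g dry soil; must be > 0.
#' @param b Decay rate constant, 1/day; must be > 0.
#' @param Y0 Non-degradable plateau, ng/g dry soil; must be >= 0.
#' @return An object of class `first_order_params` or `plateau_params`.
#' @examples
#' first_order_params(a = 336.25, b = 0.046)
#' plateau_params(Y0 = 83.58, a = 266.69, b = 0.0976)
#' @export
first_order_params <- function(a, b) {
  check_finite_scalar(a, "a")
  check_finite_scalar(b, "b")
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (b <= 0) stop("'b' must be > 0", call. = FALSE)
  structure(list(a = a, b = b), class = "first_order_params")
}

#' @rdname first_order_params
#' @export
plateau_params <- function(Y0, a, b) {
  check_finite_scalar(Y0, "Y0")
  check_finite_scalar(a, "a")
  check_finite_scalar(b, "b")
  if (Y0 < 0) stop("'Y0' must be >= 0", call. = FALSE)
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (b <= 0) stop("'b' must be > 0", call. = FALSE)
  structure(list(Y0 = Y0, a = a, b = b), class = "plateau_params")
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("time must be finite numeric", call. = FALSE)
  if (any(t < 0)) stop("time must be >= 0 (days)", call. = FALSE)
  invisible(t)
}

#' Evaluate the degradation models
#'
#' `eval_first_order()` returns \eqn{a e^{-bt}}; `eval_plateau()` returns
#' \eqn{Y_0 + a e^{-bt}}. Time is in days; sub-day sampling points are exact
#' fractions of a day (4 h = 1/6 d).
#'
#' @param p A `first_order_params` or `plateau_params` object.
#' @param t Time(s) in days, non-negative.
#' @return Predicted concentration(s), ng/g dry soil.
#' @examples
#' eval_first_order(first_order_params(1, log(2)), 1) # 0.5
#' @export
eval_first_order <- function(p, t) {
  stopifnot(inherits(p, "first_order_params"))
  check_time(t)
  p$a * exp(-p$b * t)
}

#' @rdname eval_first_order
#' @export
eval_plateau <- function(p, t) {
  stopifnot(inherits(p, "plateau_params"))
  check_time(t)
  p$Y0 + p$a * exp(-p$b * t)
}

#' Half-life functionals
#'
#' Under first-order kinetics the 50% dissipation time is
#' \eqn{DT_{50} = \ln 2 / b}. For the plateau model the same functional of
#' `b` is the half-life of the *degradable* component \eqn{Y(t) - Y_0};
#' a "time to 50% of initial" is not defined for that model when
#' \eqn{Y_0 > Y(0)/2}, so only these two functionals are exposed.
#'
#' @param b Decay rate constant, 1/day; must be > 0.
#' @param p A `plateau_params` object.
#' @return Time in days.
#' @examples
#' dt50_first_order(0.046) # about 15.07 d
#' @export
dt50_first_order <- function(b) {
  check_finite_scalar(b, "b")
  if (b <= 0) stop("'b' must be > 0", call. = FALSE)
  log(2) / b
}

#' @rdname dt50_first_order
#' @export
half_life_degradable_fraction <- function(p) {
  stopifnot(inherits(p, "plateau_params"))
  dt50_first_order(p$b)
}

#' @export
print.first_order_params <- function(x, ...) {
  cat(sprintf("Y = %.4g * exp(-%.4g t)   [first-order]\n", x$a, x$b))
  invisible(x)
}

#' @export
print.plateau_params <- function(x, ...) {
  cat(sprintf("Y = %.4g + %.4g * exp(-%.4g t)   [plateau]\n",
              x$Y0, x$a, x$b))
  invisible(x)
}
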