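#' Rate constants for the four-compartment continuous model
#'
#' The continuous counterpart of the discrete rules tracks four compartments:
#' mature dividing cells (M), immature cells (I), and two wholly mature
#' lineages (W1 from I, W2 from M). Division is production without self-loss
#' (M makes I at rate `k1`, I makes M at rate `k2`); differentiation drains
#' the proliferative pool (I to W1 at `k3`, M to W2 at `k4`); W1 and W2 die at
#' `k5` and `k6`. Time is measured in units of `1/k1`, so `k1 = 1` without
#' loss of generality.
#'
#' @param k1 M-division rate (per cycle; must be positive, conventionally 1).
#' @param k2 I-division rate.
#' @param k3 I-to-W1 differentiation rate.
#' @param k4 M-to-W2 differentiation rate.
#' @param k5 W1 death rate.
#' @param k6 W2 death rate.
#' @return An object of class `continuous_params`.
#' @examples
#' continuous_params(k2 = k2_from_c(6))
#' @export
continuous_params <- function(k1 = 1, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6)
  if (any(!is.finite(ks)) || any(ks < 0))
    abort("all rate constants must be finite and nonnegative")
  if (k1 <= 0) abort("`k1` must be positive (it sets the time unit)")
  structure(as.list(ks), class = "continuous_params")
}

#' @export
print.continuous_params <- function(x, ...) {
  cat("<continuous_params> ",
      paste(sprintf("%s = %g", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Generator matrix of the continuous model
#'
#' The linear system `d/dt (M, I, W1, W2) = A (M, I, W1, W2)` with
#' `dM = k2 I - k4 M`, `dI = k1 M - k3 I`, `dW1 = k3 I - k5 W1`,
#' `dW2 = k4 M - k6 W2`. Its proliferative 2x2 block has trace `-(k3 + k4)`
#' and determinant `k3 k4 - k1 k2`, which yields the closed-form eigenvalues
#' of [ode_eigenvalues()]; the W compartments decouple with eigenvalues `-k5`
#' and `-k6`.
#'
#' @param params A [continuous_params()] object.
#' @return A 4x4 numeric matrix with dimnames `M`, `I`, `W1`, `W2`.
#' @export
system_matrix <- function(params) {
  stopifnot(inherits(params, "continuous_params"))
  with(params, matrix(
    c(-k4,  k2,   0,   0,
       k1, -k3,   0,   0,
        0,  k3, -k5,   0,
       k4,   0,   0, -k6),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("M", "I", "W1", "W2"), c("M", "I", "W1", "W2"))))
}

#' Closed-form eigenvalues of the continuous model
#'
#' `lambda_{1,2} = (-(k3 + k4) +/- sqrt((k3 + k4)^2 - 4 (k3 k4 - k1 k2))) / 2`,
#' `lambda_3 = -k5`, `lambda_4 = -k6`. The discriminant equals
#' `(k3 - k4)^2 + 4 k1 k2 >= 0`, so all four are real with
#' `lambda_1 >= lambda_2`; `lambda_1` is zero, positive, or negative according
#' as `k3 k4` equals, is less than, or exceeds `k1 k2`.
#'
#' @param params A [continuous_params()] object.
#' @return Named numeric vector `lambda1`..`lambda4`.
#' @examples
#' ode_eigenvalues(continuous_params(k2 = k2_from_c(6)))["lambda1"] # 0.285199
#' @export
ode_eigenvalues <- function(params) {
  stopifnot(inherits(params, "continuous_params"))
  with(params, {
    disc <- (k3 + k4)^2 - 4 * (k3 * k4 - k1 * k2)
    s <- sqrt(disc)
    c(lambda1 = (-(k3 + k4) + s) / 2,
      lambda2 = (-(k3 + k4) - s) / 2,
      lambda3 = -k5,
      lambda4 = -k6)
  })
}

#' Classify the long-run regime
#'
#' Steady state, growth, or decay of the proliferative pool according to the
#' sign of `k1 k2 - k3 k4` (equivalently the sign of `lambda_1`). A balanced
#' steady state requires differentiation along both lineages: with `k3 = 0`
#' or `k4 = 0` and `k1 k2 > 0` the product `k3 k4` is zero, so `lambda_1 > 0`
#' and the system can only grow.
#'
#' @param params A [continuous_params()] object.
#' @param tol Tolerance on the balance `k1 k2 - k3 k4` (default 1e-12).
#' @return One of `"steady"`, `"growth"`, `"decay"`.
#' @export
classify_regime <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "continuous_params"))
  bal <- with(params, k1 * k2 - k3 * k4)
  if (abs(bal) <= tol) "steady" else if (bal > 0) "growth" else "decay"
}

#' Steady-state compartment ratios under balanced differentiation
#'
#' When `k3 k4 = k1 k2` (so `lambda_1 = 0`), every positive trajectory
#' converges to a state with `M/I = k2/k4 = k3/k1`, `W2/M = k4/k6`, and
#' `W1/I = k3/k5`.
#'
#' @param params A [continuous_params()] object satisfying the balance
#'   condition with `k4, k5, k6 > 0`.
#' @param tol Relative tolerance on the balance condition (default 1e-9).
#' @return Tibble with columns `ratio` (`"M/I"`, `"W2/M"`, `"W1/I"`) and
#'   `value`.
#' @export
steady_state_ratios <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "continuous_params"))
  bal <- with(params, k1 * k2 - k3 * k4)
  scale <- with(params, max(k1 * k2, k3 * k4, 1))
  if (abs(bal) > tol * scale)
    abort("balance condition k3*k4 = k1*k2 violated: the system grows or decays, no finite steady ratios exist")
  if (with(params, k4 <= 0 || k5 <= 0 || k6 <= 0))
    abort("`k4`, `k5`, `k6` must be positive for finite steady-state ratios")
  with(params, tibble(
    ratio = c("M/I", "W2/M", "W1/I"),
    value = c(k2 / k4, k4 / k6, k3 / k5)
  ))
}

#' Integrate the continuous model
#'
#' Solves the linear system from a nonnegative initial state over the given
#' time grid with a stiff-capable solver (`deSolve::lsoda`, relative
#' tolerance 1e-10). The dynamics preserve nonnegativity.
#'
#' @param params A [continuous_params()] object.
#' @param init Named numeric vector `c(M=, I=, W1=, W2=)` (missing names
#'   default to 0).
#' @param times Increasing numeric vector of output times.
#' @return A tibble of class `ode_trajectory` with columns `time`, `M`, `I`,
#'   `W1`, `W2`.
#' @examples
#' p <- continuous_params(k2 = 0.25)
#' integrate_compartments(p, c(M = 1), times = seq(0, 10, 1))
#' @export
integrate_compartments <- function(params, init, times) {
  stopifnot(inherits(params, "continuous_params"))
  if (length(times) < 2 || any(diff(times) <= 0))
    abort("`times` must be an increasing vector of at least two time points")
  y0 <- c(M = 0, I = 0, W1 = 0, W2 = 0)
  if (!all(names(init) %in% names(y0)))
    abort("`init` names must be among M, I, W1, W2")
  if (any(init < 0)) abort("`init` must be nonnegative")
  y0[names(init)] <- init
  A <- system_matrix(params)
  sol <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, p) list(as.vector(A %*% y)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  class(out) <- c("ode_trajectory", class(out))
  out
}

#' Fitted-model wrapper for the continuous system
#'
#' Packages rate constants, generator matrix, eigenvalues, and regime into one
#' object with broom-style [tidy()] and [glance()] methods.
#'
#' @param params A [continuous_params()] object.
#' @return An object of class `crypt_ode`.
#' @examples
#' m <- ode_model(continuous_params(k2 = 0.381966, k3 = 0.618034, k4 = 0.618034,
#'                                  k5 = 0.3, k6 = 0.3))
#' glance(m)
#' @export
ode_model <- function(params) {
  stopifnot(inherits(params, "continuous_params"))
  structure(
    list(params = params, matrix = system_matrix(params),
         eigenvalues = ode_eigenvalues(params),
         regime = classify_regime(params)),
    class = "crypt_ode")
}

#' @export
print.crypt_ode <- function(x, ...) {
  cat("<crypt_ode> regime:", x$regime, "\n eigenvalues:",
      paste(sprintf("%.6g", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname ode_model
#' @param x A `crypt_ode` object.
#' @param ... Unused.
#' @export
tidy.crypt_ode <- function(x, ...) {
  tibble(term = names(x$eigenvalues), eigenvalue = unname(x$eigenvalues))
}

#' @rdname ode_model
#' @export
glance.crypt_ode <- function(x, ...) {
  with(x$params, tibble(
    regime = x$regime,
    lambda1 = unname(x$eigenvalues["lambda1"]),
    balance = k1 * k2 - k3 * k4,
    k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6))
}
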