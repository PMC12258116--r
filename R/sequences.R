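#' Generalized Fibonacci p-numbers
#'
#' The p-Fibonacci sequence of order `c` is defined by
#' `F_n = F_{n-1} + F_{n-c}` with seeds `F_0 = ... = F_{c-1} = 1`
#' (`p = c - 1`; for `c = 6` this is OEIS A005708). The total cell count of the
#' linear lineage model with maturation period `c` satisfies
#' `N(t) = F_{t+c-1}`: each step every cell at least `c` steps old spawns one
#' new cell. Values are computed with exact arbitrary-precision integers.
#'
#' @param c Order (maturation period), positive integer.
#' @param n Index, nonnegative integer.
#' @return `p_fib()` returns a single exact integer of class `tc_bigint`
#'   (convert with `as.character()` or `as.numeric()`); `p_fib_table()` returns
#'   a tibble with columns `n` and `F` (exact decimal strings).
#' @examples
#' as.numeric(p_fib(6, 17))   # 34 cells at t = 12 for c = 6
#' as.character(p_fib(2, 10)) # classic Fibonacci: 89
#' @export
p_fib <- function(c, n) {
  stopifnot(c >= 1, c == floor(c), n >= 0, n == floor(n))
  seq <- p_fib_big(c, n)
  seq[[n + 1]]
}

# list of tc_bigint F_0..F_n
p_fib_big <- function(c, n) {
  out <- vector("list", n + 1)
  one <- big_from_num(1)
  for (i in seq_len(min(c, n + 1))) out[[i]] <- one
  if (n + 1 > c) {
    for (i in (c + 1):(n + 1)) out[[i]] <- big_add(out[[i - 1]], out[[i - c]])
  }
  out
}

#' @rdname p_fib
#' @param n_max Largest index for the table.
#' @export
p_fib_table <- function(c, n_max) {
  seq <- p_fib_big(c, n_max)
  tibble(n = 0:n_max, F = vapply(seq, format, character(1)))
}

#' Growth root of the p-Fibonacci recurrence
#'
#' The unique root `rho` in (1, 2] of `rho^c - rho^(c-1) - 1 = 0`, the limit of
#' consecutive p-Fibonacci ratios `F_{n+1}/F_n` (the "golden p-section"; the
#' golden ratio for `c = 2`) and hence the per-step growth factor of the
#' lineage models. Found by bisection: the polynomial is strictly increasing
#' on the bracket.
#'
#' @param c Maturation period, positive integer.
#' @param tol Bisection tolerance (interval width), default 1e-12.
#' @return A single numeric root.
#' @examples
#' growth_root(2) # golden ratio 1.618034...
#' @export
growth_root <- function(c, tol = 1e-12) {
  stopifnot(c >= 1, c == floor(c))
  if (c == 1) return(2)
  bisect(function(x) x^c - x^(c - 1) - 1, 1, 2, tol)
}

#' Limiting mature-to-immature ratio for a maturation period
#'
#' Solves `lambda * (1 + lambda)^(c-1) = 1` for the unique root in (0, 1].
#' This `lambda` is at once (i) the limiting M/I ratio of the discrete lineage
#' model, (ii) the dominant eigenvalue `lambda_1 = sqrt(k1 k2)` of the
#' continuous model without differentiation, and (iii) `growth_root(c) - 1`.
#'
#' @inheritParams growth_root
#' @return A single numeric root in (0, 1].
#' @examples
#' solve_lambda(2) # 0.618034...
#' solve_lambda(6) # 0.285199...
#' @export
solve_lambda <- function(c, tol = 1e-12) {
  stopifnot(c >= 1, c == floor(c))
  if (c == 1) return(1)
  bisect(function(x) x * (1 + x)^(c - 1) - 1, 0, 1, tol)
}

# f increasing with f(lo) < 0 <= f(hi); returns midpoint at width tol
bisect <- function(f, lo, hi, tol) {
  stopifnot(f(lo) < 0, f(hi) >= 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Maturation period from a limiting ratio
#'
#' Inverts [solve_lambda()] in closed form:
#' `c = 1 - log(lambda) / log(1 + lambda)`, so that a measured M/I ratio (or a
#' continuous-model `k2 = lambda^2`) maps back to the discrete maturation
#' period.
#'
#' @param lambda Ratio in (0, 1].
#' @return Numeric `c` (not rounded; equals an integer when `lambda` comes
#'   from [solve_lambda()]).
#' @examples
#' c_from_lambda(solve_lambda(6)) # 6
#' @export
c_from_lambda <- function(lambda) {
  if (any(lambda <= 0 | lambda > 1))
    abort("`lambda` must lie in (0, 1].")
  1 - log(lambda) / log(1 + lambda)
}

#' Continuous-model division rate for immature cells
#'
#' The I-cell division rate `k2` that makes the continuous model's growth
#' eigenvalue `sqrt(k1 k2)` (with `k1 = 1`) equal the discrete model's
#' limiting ratio: `k2 = lambda^2` with `lambda = solve_lambda(c)`.
#'
#' @inheritParams growth_root
#' @return A single numeric rate (dimensionless, time in units of `1/k1`).
#' @examples
#' k2_from_c(6) # 0.081338...
#' @export
k2_from_c <- function(c, tol = 1e-12) solve_lambda(c, tol)^2

#' Discrete-continuous correspondence table
#'
#' Regenerates the correspondence between the maturation period `c`, the
#' continuous rate constants (`k1 = 1`, `k2 = lambda^2`), the dominant
#' eigenvalue `lambda_1 = sqrt(k1 k2)`, and the limiting M/I ratio, for a
#' range of `c` values.
#'
#' @param c Integer vector of maturation periods (default 1..6).
#' @param digits Rounding applied to the numeric columns (default 6, the
#'   conventional print precision); use `NULL` for full precision.
#' @return A tibble with columns `c`, `k1`, `k2`, `lambda1`, `M_over_I`.
#' @examples
#' correspondence_table()
#' @export
correspondence_table <- function(c = 1:6, digits = 6) {
  lam <- vapply(c, solve_lambda, numeric(1))
  out <- tibble(c = as.integer(c), k1 = 1, k2 = lam^2,
                lambda1 = lam, M_over_I = lam)
  if (!is.null(digits))
    out <- mutate(out, dplyr::across(c("k2", "lambda1", "M_over_I"),
                                     ~ round(.x, digits)))
  out
}

#' Exact mature-to-immature ratio of the lineage model
#'
#' Computes M(t)/I(t) for the linear model with maturation period `c` and no
#' whole maturation or death, using the exact integer identities
#' `N(t) = F_{t+c-1}`, `M(t) = N(t - c)`, `I(t) = N(t) - M(t)` evaluated in
#' arbitrary precision (counts overflow doubles long before `t = 300`).
#'
#' @param c Maturation period, positive integer.
#' @param t Time step at which to evaluate (must be `>= c`).
#' @return A single numeric ratio (the integer counts are exact; only the
#'   final quotient is rounded to double precision).
#' @examples
#' lineage_mi_ratio(4, 300) # ~ solve_lambda(4)
#' @export
lineage_mi_ratio <- function(c, t) {
  stopifnot(c >= 1, c == floor(c), t >= c)
  seq <- p_fib_big(c, t + c - 1)
  M <- seq[[t - 1 + 1]]           # F_{t-1} = N(t - c)
  N <- seq[[t + c - 1 + 1]]       # F_{t+c-1} = N(t)
  big_ratio(M, big_sub(N, M))
}
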