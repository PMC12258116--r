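# Minimal arbitrary-precision nonnegative integers for p-Fibonacci counts.
# Cell totals exceed 2^53 well before t = 300 for small c, and only addition,
# subtraction, comparison and a high-precision ratio are needed, so a small
# limb representation (little-endian, base 1e9, doubles as limbs) suffices.

.BIG_BASE <- 1e9

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% .BIG_BASE)
    x <- (x - x %% .BIG_BASE) / .BIG_BASE
    if (x == 0) break
  }
  structure(list(limbs = limbs), class = "tc_bigint")
}

big_add <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  n <- max(length(la), length(lb))
  la <- c(la, numeric(n - length(la)))
  lb <- c(lb, numeric(n - length(lb)))
  s <- la + lb
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= .BIG_BASE) 1 else 0
    if (carry) s[i] <- s[i] - .BIG_BASE
  }
  if (carry) s <- c(s, 1)
  structure(list(limbs = s), class = "tc_bigint")
}

# a - b, requires a >= b
big_sub <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  n <- length(la)
  stopifnot(length(lb) <= n)
  lb <- c(lb, numeric(n - length(lb)))
  d <- la - lb
  for (i in seq_len(n)) {
    if (d[i] < 0) {
      d[i] <- d[i] + .BIG_BASE
      d[i + 1] <- d[i + 1] - 1  # errors if a < b, by design
    }
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  structure(list(limbs = d), class = "tc_bigint")
}

# double approximation of a / b with ~1e-15 relative accuracy: uses the top
# three limbs of each operand plus the limb-count exponent difference
big_ratio <- function(a, b) {
  top <- function(x) {
    l <- rev(x$limbs)
    v <- 0
    for (i in seq_len(min(3, length(l)))) v <- v * .BIG_BASE + l[i]
    v
  }
  ea <- max(length(a$limbs) - 3, 0)
  eb <- max(length(b$limbs) - 3, 0)
  (top(a) / top(b)) * .BIG_BASE^(ea - eb)
}

#' @export
format.tc_bigint <- function(x, ...) {
  l <- rev(x$limbs)
  paste0(format(l[1], scientific = FALSE),
         paste(sprintf("%09.0f", l[-1]), collapse = ""))
}

#' @export
print.tc_bigint <- function(x, ...) {
  cat("<tc_bigint>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.tc_bigint <- function(x, ...) format(x)

#' @export
as.double.tc_bigint <- function(x, ...) {
  v <- 0
  for (l in rev(x$limbs)) v <- v * .BIG_BASE + l
  v
}

#' @export
`==.tc_bigint` <- function(e1, e2) {
  if (!inherits(e2, "tc_bigint")) e2 <- big_from_num(e2)
  if (!inherits(e1, "tc_bigint")) e1 <- big_from_num(e1)
  identical(e1$limbs, e2$limbs)
}
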