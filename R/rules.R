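#' Rule parameters for the tissue-code simulators
#'
#' Bundles the five-rule setting that governs both the linear lineage model and
#' the spatial rosette model: every cell divides on a fixed cell-cycle clock
#' (one time step = one cycle), an immature (I) cell waits `c` steps before its
#' first division, a cell stops dividing at whole-maturation age `n_wm` (so it
#' performs `n_wm - c` divisions), dies at age `L`, and each division rotates
#' the split direction counterclockwise by `R` degrees.
#'
#' @param c Maturation period, in time steps (positive integer). An immature
#'   cell first divides in the step it reaches age `c`.
#' @param T Simulation horizon, in time steps (nonnegative integer).
#' @param n_wm0 Whole-maturation base age, in time steps (`Inf` = no
#'   whole-maturation). A cell of generation 0 stops dividing at this age; with
#'   `steady_state = TRUE` generation `g` uses `max(n_wm0 - g, c)`.
#' @param L Lifespan, in time steps (`Inf` = immortal). A cell dies and
#'   vacates its position when its age reaches `L`.
#' @param R Rotation increment in degrees per division; defaults to `360 / c`,
#'   the coupling between maturation period and division direction under which
#'   the rosette's leaflet pattern forms. Must divide 360 for the spatial model.
#' @param steady_state Logical; if `TRUE`, whole-maturation age decreases
#'   linearly with generation, `n_wm(g) = n_wm0 - g` (floored at `c`), the
#'   scheduling that produces bounded, self-renewing structures.
#'
#' @return An object of class `rule_params`.
#' @examples
#' rule_params(c = 6, T = 15)
#' rule_params(c = 6, T = 200, n_wm0 = 11, L = 35, steady_state = TRUE)
#' @export
rule_params <- function(c, T, n_wm0 = Inf, L = Inf, R = 360 / c,
                        steady_state = FALSE) {
  stopifnot(length(c) == 1, length(T) == 1, length(n_wm0) == 1,
            length(L) == 1, length(R) == 1, length(steady_state) == 1)
  if (!is.numeric(c) || c < 1 || c != floor(c))
    abort("`c` must be a positive integer (maturation period in time steps).")
  if (!is.numeric(T) || T < 0 || T != floor(T))
    abort("`T` must be a nonnegative integer horizon.")
  if (is.finite(n_wm0) && (n_wm0 < c || n_wm0 != floor(n_wm0)))
    abort("`n_wm0` must be an integer >= c (or Inf).")
  if (is.finite(L)) {
    if (L != floor(L)) abort("`L` must be an integer (or Inf).")
    if (is.finite(n_wm0) && L < n_wm0)
      abort("`L` must be >= `n_wm0`: cells must reach whole maturation before death.")
    if (!is.finite(n_wm0))
      abort("finite `L` requires finite `n_wm0` (L >= n_wm0).")
  }
  if (!is.numeric(R) || R <= 0 || R > 360)
    abort("`R` must be in (0, 360] degrees.")
  if (steady_state && !is.finite(n_wm0))
    abort("`steady_state = TRUE` requires a finite `n_wm0`.")
  structure(
    list(c = as.integer(c), T = as.integer(T), n_wm0 = n_wm0, L = L, R = R,
         steady_state = isTRUE(steady_state)),
    class = "rule_params"
  )
}

#' @export
print.rule_params <- function(x, ...) {
  fmt <- function(v) if (is.finite(v)) format(v) else "Inf"
  cat("<rule_params>  c =", x$c,
      " n_wm0 =", fmt(x$n_wm0),
      " L =", fmt(x$L),
      " R =", paste0(x$R, "°"),
      " steady_state =", x$steady_state,
      " T =", x$T, "\n")
  invisible(x)
}

#' Effective whole-maturation age for a generation
#'
#' Under steady-state scheduling the whole-maturation age decreases linearly
#' with generation, `n_wm(g) = n_wm0 - g`, floored at `c` so that a cell never
#' performs a negative number of divisions (a cell with `n_wm = c` performs
#' none: it becomes wholly mature the moment it matures).
#'
#' @param g Generation (vector of nonnegative integers).
#' @param params A [rule_params()] object.
#' @return Numeric vector of whole-maturation ages (possibly `Inf`).
#' @examples
#' p <- rule_params(c = 6, T = 10, n_wm0 = 11, L = 35, steady_state = TRUE)
#' n_wm_effective(c(0, 3, 9), p)
#' @export
n_wm_effective <- function(g, params) {
  stopifnot(inherits(params, "rule_params"), all(g >= 0))
  if (!params$steady_state) rep(params$n_wm0, length(g))
  else pmax(params$n_wm0 - g, params$c)
}

# ordered state levels; the index never decreases with age
.state_levels <- c("CLONOGENIC", "I", "M", "W", "DEAD")

#' Classify cell state from age and generation
#'
#' A cell is immature (I) below age `c`, mature and dividing (M) from age `c`
#' up to its whole-maturation age, wholly mature (W, non-dividing) from there
#' to its lifespan `L`, and dead at age `L` and beyond. The label-0 clonogenic
#' cell is permanently `CLONOGENIC`: it divides every cycle and never dies.
#'
#' @param age Vector of ages (time steps since production).
#' @param generation Vector of generations (divisions removed from label 0).
#' @param label Vector of cell labels (0 = clonogenic).
#' @param params A [rule_params()] object.
#' @return Factor with levels `CLONOGENIC`, `I`, `M`, `W`, `DEAD`.
#' @examples
#' p <- rule_params(c = 6, T = 20, n_wm0 = 11, L = 35)
#' cell_state(c(0, 6, 11, 35), generation = 1, label = 1, params = p)
#' @export
cell_state <- function(age, generation, label, params) {
  stopifnot(inherits(params, "rule_params"))
  n <- max(length(age), length(generation), length(label))
  age <- rep_len(age, n); generation <- rep_len(generation, n)
  label <- rep_len(label, n)
  nwm <- n_wm_effective(generation, params)
  out <- rep("I", n)
  out[age >= params$c] <- "M"
  out[age >= nwm] <- "W"
  out[age >= params$L] <- "DEAD"
  out[label == 0] <- "CLONOGENIC"
  factor(out, levels = .state_levels)
}

#' Does a cell divide in the current step?
#'
#' True for mature (M) cells and for the clonogenic cell, which divides every
#' cycle. A cell therefore divides at ages `c, c + 1, ..., n_wm - 1`: exactly
#' `n_wm - c` times over its life.
#'
#' @inheritParams cell_state
#' @return Logical vector.
#' @examples
#' p <- rule_params(c = 6, T = 20)
#' divides_now(age = 5:7, generation = 1, label = 1, params = p)
#' @export
divides_now <- function(age, generation, label, params) {
  s <- cell_state(age, generation, label, params)
  s == "M" | s == "CLONOGENIC"
}

#' Add a state column to a cell table
#'
#' Data-frame-first convenience: given a tibble of cells with `label`,
#' `birth_time`, and `generation` columns, computes each cell's age at `time`
#' and appends `age` and `state` columns.
#'
#' @param cells A data frame with columns `label`, `birth_time`, `generation`.
#' @param params A [rule_params()] object.
#' @param time Time step at which to classify.
#' @return The input as a tibble with `age` and `state` columns added.
#' @export
classify_cells <- function(cells, params, time) {
  stopifnot(is.data.frame(cells),
            all(c("label", "birth_time", "generation") %in% names(cells)))
  cells <- as_tibble(cells)
  cells$age <- time - cells$birth_time
  cells$state <- cell_state(cells$age, cells$generation, cells$label, params)
  cells
}

#' Read and write rule parameters as JSON
#'
#' Parameters serialize to a flat JSON object
#' `{"c", "n_wm0", "L", "R_degrees", "steady_state", "T"}` with `null` for
#' unbounded `n_wm0`/`L` and for the default rotation `R = 360/c`.
#'
#' @param params A [rule_params()] object.
#' @param path File path.
#' @return `write_rule_params()` returns `path` invisibly; `read_rule_params()`
#'   returns a [rule_params()] object.
#' @export
write_rule_params <- function(params, path) {
  stopifnot(inherits(params, "rule_params"))
  x <- list(
    c = params$c,
    n_wm0 = if (is.finite(params$n_wm0)) params$n_wm0 else NULL,
    L = if (is.finite(params$L)) params$L else NULL,
    R_degrees = if (isTRUE(all.equal(params$R, 360 / params$c))) NULL else params$R,
    steady_state = params$steady_state,
    T = params$T
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_rule_params
#' @export
read_rule_params <- function(path) {
  x <- jsonlite::read_json(path)
  num_or_inf <- function(v) if (is.null(v)) Inf else as.numeric(v)
  rule_params(
    c = as.integer(x$c),
    T = as.integer(x$T),
    n_wm0 = num_or_inf(x$n_wm0),
    L = num_or_inf(x$L),
    R = if (is.null(x$R_degrees)) 360 / as.integer(x$c) else as.numeric(x$R_degrees),
    steady_state = isTRUE(x$steady_state)
  )
}
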