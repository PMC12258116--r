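#' Simulate the linear (non-spatial) lineage model
#'
#' Runs the asymmetric-division rules without geometry, starting from the
#' single clonogenic cell (label 0, generation 0) at `t = 0`. At every step
#' each dividing cell (the clonogenic cell, plus every mature cell — i.e. age
#' in `[c, n_wm)`) produces one new immature daughter. Daughters are labelled
#' in their parents' ascending label order, the clonogenic cell first, with
#' labels continuing the global birth count, so the label sequence is exactly
#' the birth order. The run is fully deterministic.
#'
#' With the default `n_wm0 = L = Inf` the total count follows the p-Fibonacci
#' recurrence `N(t) = N(t-1) + N(t-c)`, `N(t) = t + 1` for `t <= c`.
#'
#' @param params A [rule_params()] object (`R` is ignored here; geometry lives
#'   in [simulate_rosette()]).
#' @return An object of class `lineage_sim`: a list with `params` and `cells`,
#'   a tibble with one row per ever-born cell (`label`, `birth_time`,
#'   `parent`, `generation`).
#' @examples
#' sim <- simulate_lineage(rule_params(c = 6, T = 15))
#' total_cells(sim, c(7, 12, 15)) # 9, 34, 71
#' @export
simulate_lineage <- function(params) {
  stopifnot(inherits(params, "rule_params"))
  cap <- 8L
  n <- 1L
  birth <- integer(cap); parent <- integer(cap); gen <- integer(cap)
  birth[1] <- 0L; parent[1] <- NA_integer_; gen[1] <- 0L
  Tmax <- params$T
  for (t in seq_len(Tmax)) {
    idx <- seq_len(n)
    age <- t - birth[idx]
    div <- divides_now(age, gen[idx], idx - 1L, params)
    # a dead cell (age >= L) is never M, so `div` already excludes it
    parents <- which(div)               # ascending label order (label = idx - 1)
    k <- length(parents)
    if (k == 0L) next
    while (n + k > cap) {
      cap <- cap * 2L
      length(birth) <- cap; length(parent) <- cap; length(gen) <- cap
    }
    new <- (n + 1L):(n + k)
    birth[new] <- t
    parent[new] <- parents - 1L
    gen[new] <- gen[parents] + 1L
    n <- n + k
  }
  cells <- tibble(
    label = 0:(n - 1L),
    birth_time = birth[seq_len(n)],
    parent = parent[seq_len(n)],
    generation = gen[seq_len(n)]
  )
  structure(list(params = params, cells = cells), class = "lineage_sim")
}

#' @export
print.lineage_sim <- function(x, ...) {
  cat("<lineage_sim> ", nrow(x$cells), "cells over", x$params$T, "steps;")
  cat(" c =", x$params$c, "\n")
  invisible(x)
}

#' Division events of a lineage run
#'
#' One row per division, ordered by child label (equivalently: by time, then
#' by parent label within a step — the order in which divisions occur).
#'
#' @param sim A `lineage_sim` object.
#' @return Tibble with columns `time`, `parent`, `child`, `generation` (of the
#'   child).
#' @export
division_events <- function(sim) {
  stopifnot(inherits(sim, "lineage_sim"))
  ev <- filter(sim$cells, .data$label > 0)
  tibble(time = ev$birth_time, parent = ev$parent, child = ev$label,
         generation = ev$generation)
}

#' Total number of live cells at given times
#'
#' Counts every ever-born cell that has not yet died (age `>= L`); the
#' clonogenic cell never dies.
#'
#' @param sim A `lineage_sim` or `rosette_sim` object.
#' @param t Vector of time steps within the simulated horizon.
#' @return Integer vector of counts, one per element of `t`.
#' @export
total_cells <- function(sim, t) {
  UseMethod("total_cells")
}

#' @export
total_cells.lineage_sim <- function(sim, t) {
  stopifnot(all(t >= 0), all(t <= sim$params$T))
  L <- sim$params$L
  birth <- sim$cells$birth_time
  lab <- sim$cells$label
  vapply(t, function(tt)
    sum(birth <= tt & (lab == 0 | tt - birth < L)), integer(1))
}

#' Cell counts by state over time
#'
#' Tallies mature (M, including the clonogenic cell), immature (I) and wholly
#' mature (W) cells at each requested time. With `n_wm = L = Inf` the M count
#' satisfies the identity `M(t) = N(t - c)` for `t >= c`: today's dividers are
#' exactly the cells born at least `c` steps ago.
#'
#' @param sim A `lineage_sim` object.
#' @param times Vector of time steps (default: the whole horizon).
#' @return Tibble with columns `time`, `total`, `M`, `I`, `W`.
#' @examples
#' sim <- simulate_lineage(rule_params(c = 6, T = 12))
#' state_counts(sim, 12) # M = 7, I = 27
#' @export
state_counts <- function(sim, times = 0:sim$params$T) {
  stopifnot(inherits(sim, "lineage_sim"), all(times >= 0),
            all(times <= sim$params$T))
  purrr::map_dfr(times, function(tt) {
    cc <- filter(sim$cells, .data$birth_time <= tt)
    cc <- classify_cells(cc, sim$params, tt)
    s <- cc$state
    tibble(time = tt,
           total = sum(s != "DEAD"),
           M = sum(s == "M" | s == "CLONOGENIC"),
           I = sum(s == "I"),
           W = sum(s == "W"))
  })
}

#' Cell counts by generation
#'
#' Partition of the live population at time `t` by generation (divisions
#' removed from the clonogenic cell). Generation 0 always counts exactly the
#' clonogenic cell.
#'
#' @param sim A `lineage_sim` object.
#' @param t A single time step.
#' @return Tibble with columns `generation`, `n`.
#' @examples
#' sim <- simulate_lineage(rule_params(c = 6, T = 12))
#' generation_counts(sim, 12) # 1 / 12 / 21 in generations 0 / 1 / 2
#' @export
generation_counts <- function(sim, t) {
  stopifnot(inherits(sim, "lineage_sim"), length(t) == 1)
  cc <- filter(sim$cells, .data$birth_time <= t)
  cc <- classify_cells(cc, sim$params, t)
  cc <- filter(cc, .data$state != "DEAD")
  out <- count(cc, .data$generation, name = "n")
  arrange(out, .data$generation)
}

#' First appearance time of a generation
#'
#' Earliest time step at which a cell of generation `g` is produced. For
#' `c = 6` the first second-generation cell appears at `t = 7`: the oldest
#' first-generation cell (born at `t = 1`) matures and divides at age 6.
#'
#' @param sim A `lineage_sim` object.
#' @param g Generation, positive integer.
#' @return A single integer time step; errors if generation `g` was never
#'   produced within the horizon.
#' @export
first_generation_time <- function(sim, g) {
  stopifnot(inherits(sim, "lineage_sim"), g >= 1)
  b <- sim$cells$birth_time[sim$cells$generation == g]
  if (length(b) == 0)
    abort(sprintf("generation %d is never produced within the horizon T = %d",
                  g, sim$params$T))
  min(b)
}

#' Export a lineage as a Newick tree
#'
#' Emits the division tree in Newick format. Node names are cell labels and
#' branch lengths are birth times, so the tree round-trips through standard
#' Newick parsers (e.g. `ape::read.tree()`).
#'
#' @param sim A `lineage_sim` object.
#' @return A single Newick string (terminated by `;`).
#' @examples
#' lineage_newick(simulate_lineage(rule_params(c = 6, T = 1))) # "(1:1)0;"
#' @export
lineage_newick <- function(sim) {
  stopifnot(inherits(sim, "lineage_sim"), nrow(sim$cells) >= 1)
  kids <- split(sim$cells$label[-1], sim$cells$parent[-1])
  birth <- sim$cells$birth_time
  emit <- function(lab) {
    ch <- kids[[as.character(lab)]]
    body <- if (is.null(ch)) as.character(lab)
      else paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","),
                  ")", lab)
    paste0(body, ":", birth[lab + 1])
  }
  ch <- kids[["0"]]
  if (is.null(ch)) return("0;")
  paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")0;")
}
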