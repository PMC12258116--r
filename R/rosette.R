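# position keys: planar coordinates rounded to 6 dp (lattice spacing is 1, so
# float noise from summing unit direction vectors collapses onto one key)
.pos_key <- function(p) {
  paste0(as.integer(round(Re(p) * 1e6)), ",", as.integer(round(Im(p) * 1e6)))
}

#' Simulate the spatial rosette model
#'
#' Runs the full five-rule agent-based model on the plane. The clonogenic cell
#' sits at the origin forever; every dividing cell places its immature
#' daughter one unit step away along its current split direction, then both
#' cells rotate their split direction counterclockwise by `R` degrees. If the
#' target position is occupied, the occupant chain is displaced one position
#' outward along the same ray (the origin is immovable: a chain reaching it
#' skips to the slot beyond). Divisions happen in birth (label) order within a
#' step; then ages advance, states reclassify, and cells whose age reaches `L`
#' die and vacate their positions. Everything is deterministic.
#'
#' For `R = 360 / c` the growing structure develops `c` leaflets/branches with
#' `c`-fold rotational symmetry; with steady-state scheduling
#' (`steady_state = TRUE`, finite `n_wm0` and `L`) the population becomes
#' bounded: a dividing region persists around the clonogenic cell while wholly
#' mature cells stream outward and die near the edge — the planar picture of
#' crypt renewal.
#'
#' @param params A [rule_params()] object; `R` must divide 360.
#' @param snapshots Times at which to record full per-cell snapshots: a vector
#'   of time steps, `"all"`, or `NULL` (final state only, always recorded).
#' @param max_cells Guard against runaway exponential runs (default 2e5).
#' @return An object of class `rosette_sim`: list with `params`, `ndir`
#'   (number of split directions, `360 / R`), `cells` (tibble: `label`,
#'   `birth_time`, `parent`, `generation`, `x`, `y`, `angle_index`, `alive`,
#'   `death_time`), `counts` (tibble per step: `time`, `total`, `M`, `I`,
#'   `W`), and `snapshots` (named list of per-cell tibbles).
#' @examples
#' sim <- simulate_rosette(rule_params(c = 6, T = 12))
#' dplyr::last(sim$counts$total) # 34, same as the linear model
#' @export
simulate_rosette <- function(params, snapshots = NULL, max_cells = 2e5) {
  stopifnot(inherits(params, "rule_params"))
  ndir <- round(360 / params$R)
  if (abs(ndir * params$R - 360) > 1e-9)
    abort("`R` must divide 360 degrees for the rosette lattice.")
  dirs <- exp(2i * pi * (0:(ndir - 1)) / ndir)
  Tmax <- params$T
  snap_times <- if (identical(snapshots, "all")) 0:Tmax else
    if (is.null(snapshots)) integer(0) else as.integer(snapshots)

  cap <- 8L; n <- 1L
  birth <- integer(cap); parent <- integer(cap); gen <- integer(cap)
  angle <- integer(cap); pos <- complex(cap)
  alive <- logical(cap); death <- rep(NA_integer_, cap)
  birth[1] <- 0L; parent[1] <- NA_integer_; gen[1] <- 0L
  angle[1] <- 0L; pos[1] <- 0 + 0i; alive[1] <- TRUE

  occ <- new.env(hash = TRUE, parent = emptyenv())
  okey <- .pos_key(0 + 0i)
  assign(okey, 0L, envir = occ)

  snap_list <- list()
  counts <- vector("list", Tmax + 1)
  take_counts <- function(t) {
    idx <- which(alive[seq_len(n)])
    s <- cell_state(t - birth[idx], gen[idx], idx - 1L, params)
    tibble(time = t, total = length(idx),
           M = sum(s == "M" | s == "CLONOGENIC"),
           I = sum(s == "I"), W = sum(s == "W"))
  }
  take_snapshot <- function(t) {
    idx <- which(alive[seq_len(n)])
    s <- cell_state(t - birth[idx], gen[idx], idx - 1L, params)
    tibble(time = t, label = idx - 1L, state = s, generation = gen[idx],
           age = t - birth[idx], x = round(Re(pos[idx]), 9),
           y = round(Im(pos[idx]), 9), angle_index = angle[idx])
  }
  counts[[1]] <- take_counts(0L)
  if (0L %in% snap_times) snap_list[["0"]] <- take_snapshot(0L)

  for (t in seq_len(Tmax)) {
    idx <- seq_len(n)
    div <- alive[idx] & divides_now(t - birth[idx], gen[idx], idx - 1L, params)
    dividers <- which(div)
    if (n + length(dividers) > max_cells)
      abort(sprintf("population would exceed max_cells = %g at t = %d",
                    max_cells, t))
    while (n + length(dividers) > cap) {
      cap <- cap * 2L
      length(birth) <- cap; length(parent) <- cap; length(gen) <- cap
      length(angle) <- cap; length(pos) <- cap; length(alive) <- cap
      length(death) <- cap
    }
    for (d in dividers) {
      dirv <- dirs[angle[d] + 1L]
      # walk the ray from the parent: candidate slots, skipping the origin
      slot_pos <- complex(0); slot_lab <- integer(0)
      cur <- pos[d]
      repeat {
        cur <- cur + dirv
        k <- .pos_key(cur)
        if (k == okey) next
        occupant <- get0(k, envir = occ, inherits = FALSE)
        slot_pos <- c(slot_pos, cur)
        slot_lab <- c(slot_lab, if (is.null(occupant)) NA_integer_ else occupant)
        if (is.null(occupant)) break
      }
      m <- length(slot_pos)
      if (m > 1L) {  # displace the occupied chain one slot outward
        for (i in (m - 1L):1L) {
          lab <- slot_lab[i]
          pos[lab + 1L] <- slot_pos[i + 1L]
          assign(.pos_key(slot_pos[i + 1L]), lab, envir = occ)
        }
      }
      n <- n + 1L
      child <- n - 1L  # label
      birth[n] <- t; parent[n] <- d - 1L; gen[n] <- gen[d] + 1L
      pos[n] <- slot_pos[1L]; alive[n] <- TRUE
      assign(.pos_key(slot_pos[1L]), child, envir = occ)
      angle[n] <- (angle[d] + 1L) %% ndir
      angle[d] <- (angle[d] + 1L) %% ndir
    }
    # deaths at end of step; position vacated, never back-filled
    idx <- seq_len(n)
    dying <- which(alive[idx] & idx - 1L != 0L & t - birth[idx] >= params$L)
    for (d in dying) {
      rm(list = .pos_key(pos[d]), envir = occ)
      alive[d] <- FALSE
      death[d] <- t
    }
    counts[[t + 1]] <- take_counts(t)
    if (t %in% snap_times) snap_list[[as.character(t)]] <- take_snapshot(t)
  }

  idx <- seq_len(n)
  cells <- tibble(
    label = idx - 1L, birth_time = birth[idx], parent = parent[idx],
    generation = gen[idx], x = round(Re(pos[idx]), 9),
    y = round(Im(pos[idx]), 9), angle_index = angle[idx],
    alive = alive[idx], death_time = death[idx]
  )
  structure(
    list(params = params, ndir = ndir, cells = cells,
         counts = bind_rows(counts), snapshots = snap_list),
    class = "rosette_sim"
  )
}

#' @export
print.rosette_sim <- function(x, ...) {
  cat("<rosette_sim> ", sum(x$cells$alive), "live /", nrow(x$cells),
      "ever-born cells;", x$ndir, "split directions; T =", x$params$T, "\n")
  invisible(x)
}

#' @export
total_cells.rosette_sim <- function(sim, t) {
  stopifnot(all(t >= 0), all(t <= sim$params$T))
  vapply(t, function(tt) {
    row <- sim$counts[sim$counts$time == tt, ]
    as.integer(row$total)
  }, integer(1))
}

#' Per-cell snapshot of a rosette run
#'
#' Returns the recorded per-cell table (position, state, age, split angle) at
#' time `t`. The final time is always available; earlier times require having
#' passed them in `snapshots` to [simulate_rosette()].
#'
#' @param sim A `rosette_sim` object.
#' @param t A single time step.
#' @return Tibble with columns `time`, `label`, `state`, `generation`, `age`,
#'   `x`, `y`, `angle_index`.
#' @export
cells_at <- function(sim, t = sim$params$T) {
  stopifnot(inherits(sim, "rosette_sim"), length(t) == 1)
  key <- as.character(t)
  if (!is.null(sim$snapshots[[key]])) return(sim$snapshots[[key]])
  if (t != sim$params$T)
    abort(sprintf(
      "no snapshot recorded at t = %d; rerun with snapshots = %d or \"all\"",
      t, t))
  cc <- filter(sim$cells, .data$alive)
  s <- cell_state(t - cc$birth_time, cc$generation, cc$label, sim$params)
  tibble(time = t, label = cc$label, state = s, generation = cc$generation,
         age = t - cc$birth_time, x = cc$x, y = cc$y,
         angle_index = cc$angle_index)
}

#' Rotational symmetry order of a cell arrangement
#'
#' Largest `k` such that rotating all occupied positions (excluding the
#' origin) by `360 / k` degrees about the origin maps the multiset of
#' (position, state) pairs onto itself. Structures grown with `R = 360 / c`
#' develop symmetry order `c` once the first leaflet ring has formed.
#'
#' @param cells A per-cell snapshot (from [cells_at()]) with columns `x`, `y`,
#'   `state`.
#' @param tol Positional tolerance (default 1e-6).
#' @return A single integer `>= 1`.
#' @export
symmetry_order <- function(cells, tol = 1e-6) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  p <- complex(real = cells$x, imaginary = cells$y)
  keep <- Mod(p) > tol
  p <- p[keep]
  st <- as.character(cells$state)[keep]
  if (length(p) == 0) return(1L)
  ref <- sort(paste(.pos_key(p), st))
  for (k in length(p):2) {
    rot <- p * exp(2i * pi / k)
    if (identical(sort(paste(.pos_key(rot), st)), ref)) return(as.integer(k))
  }
  1L
}

#' Project a planar structure onto a cylinder
#'
#' Maps planar coordinates `(x, y)` to the surface of a cylinder of the given
#' circumference (in cells): `angle = 2 * pi * (x mod circumference) /
#' circumference`, `height = y`. This turns the 2D steady-state rosette into
#' the single-cell-thick tube that emulates a colonic crypt wall; the default
#' circumference of 42 cells matches the crypt-scale configuration.
#'
#' @param cells A snapshot tibble with columns `x` and `y`.
#' @param circumference Cylinder circumference in cell widths (default 42).
#' @return The input tibble with `angle_rad`, `height`, and Cartesian
#'   `x3`, `y3`, `z3` columns added (unit cylinder radius scaled to
#'   `circumference / (2 * pi)`).
#' @export
project_cylinder <- function(cells, circumference = 42) {
  stopifnot(is.data.frame(cells), circumference >= 1)
  r <- circumference / (2 * pi)
  mutate(as_tibble(cells),
         angle_rad = 2 * pi * ((.data$x %% circumference) / circumference),
         height = .data$y,
         x3 = r * cos(.data$angle_rad),
         y3 = r * sin(.data$angle_rad),
         z3 = .data$height)
}

#' Cells per branch of a rosette structure
#'
#' Counts live cells in each of the `360 / R` angular sectors (branches) of a
#' rosette snapshot, excluding the clonogenic cell and the first
#' circumferential leaflet layer (cells at unit distance from the origin).
#' With `n_wm = L = Inf` the branch total plus `1 + c` equals the total cell
#' count, and the branch series grows geometrically with ratio
#' [growth_root()]`(c)`.
#'
#' @param sim A `rosette_sim` object.
#' @param t Time step (defaults to the final step; earlier times need
#'   recorded snapshots).
#' @return Tibble with columns `branch` (1-based sector index, sector 1
#'   centered on the 0-degree direction) and `n`.
#' @export
branch_counts <- function(sim, t = sim$params$T) {
  stopifnot(inherits(sim, "rosette_sim"))
  cc <- cells_at(sim, t)
  p <- complex(real = cc$x, imaginary = cc$y)
  keep <- Mod(p) > 1 + 1e-6   # drop origin and first leaflet layer
  deg <- (Arg(p[keep]) * 180 / pi) %% 360
  sector <- floor(((deg + 1e-7) %% 360) / sim$params$R) + 1L
  out <- tibble(branch = seq_len(sim$ndir))
  tallied <- count(tibble(branch = sector), .data$branch, name = "n")
  out <- left_join(out, tallied, by = "branch")
  out$n <- ifelse(is.na(out$n), 0L, out$n)
  out
}

#' Parameters of the crypt-like steady-state configuration
#'
#' Convenience constructor for the bounded, self-renewing configuration:
#' `c = 6`, initial whole-maturation age `n_wm0 = 11` decreasing with
#' generation, lifespan `L = 35`. Run it with [simulate_rosette()].
#'
#' @param T Horizon in time steps (default 200).
#' @param c,n_wm0,L Overridable rule settings.
#' @return A [rule_params()] object with `steady_state = TRUE`.
#' @examples
#' p <- crypt_steady_params(T = 50)
#' @export
crypt_steady_params <- function(T = 200, c = 6, n_wm0 = 11, L = 35) {
  rule_params(c = c, T = T, n_wm0 = n_wm0, L = L, steady_state = TRUE)
}
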