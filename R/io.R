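# one-line machine-readable provenance comment written atop every export
.provenance <- function(params = NULL) {
  ver <- as.character(utils::packageVersion("tissuecode"))
  pj <- if (is.null(params)) "{}" else
    jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                     null = "null")
  sprintf("# tissuecode %s params=%s", ver, pj)
}

.write_table <- function(df, path, params = NULL, delim = ",") {
  con <- file(path, open = "wb")  # binary mode: byte-stable newlines
  on.exit(close(con))
  writeLines(.provenance(params), con)
  writeLines(sub("\n$", "", readr::format_delim(df, delim = delim)), con)
  invisible(path)
}

#' Export division events as TSV
#'
#' One row per division with columns `time`, `parent`, `child`, `generation`
#' (separate parent/child columns rather than an arrow rendering). A
#' provenance comment line (`# tissuecode <version> params=...`) precedes the
#' header.
#'
#' @param sim A `lineage_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_division_events <- function(sim, path) {
  stopifnot(inherits(sim, "lineage_sim"))
  .write_table(division_events(sim), path, sim$params, delim = "\t")
}

#' Export cell counts over time as CSV
#'
#' Columns `time`, `total`, `M`, `I`, `W`, plus one `gen<k>` column per
#' generation present (live-cell counts).
#'
#' @param sim A `lineage_sim` or `rosette_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_counts <- function(sim, path) {
  if (inherits(sim, "lineage_sim")) {
    base <- state_counts(sim)
    gens <- purrr::map_dfr(base$time, function(tt) {
      gc <- generation_counts(sim, tt)
      out <- as.list(setNames(gc$n, paste0("gen", gc$generation)))
      c(list(time = tt), out)
    })
    df <- left_join(base, gens, by = "time")
    df[is.na(df)] <- 0L
  } else if (inherits(sim, "rosette_sim")) {
    df <- sim$counts
  } else {
    abort("`sim` must be a lineage_sim or rosette_sim")
  }
  .write_table(df, path, sim$params)
}

#' Export a per-cell snapshot as CSV
#'
#' One row per live cell (`time`, `label`, `state`, `generation`, `age`, `x`,
#' `y`, `angle_index`); when `cylinder = TRUE` the cylindrical projection
#' columns of [project_cylinder()] are appended.
#'
#' @param sim A `rosette_sim` object.
#' @param path Output file path.
#' @param t Snapshot time (default: final step).
#' @param cylinder Append 3D projection columns? Default `FALSE`.
#' @param circumference Cylinder circumference, cells (default 42).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(sim, path, t = sim$params$T, cylinder = FALSE,
                           circumference = 42) {
  stopifnot(inherits(sim, "rosette_sim"))
  cc <- cells_at(sim, t)
  if (cylinder) cc <- project_cylinder(cc, circumference)
  .write_table(cc, path, sim$params)
}

#' Export an ODE trajectory as CSV
#'
#' @param traj An `ode_trajectory` tibble from [integrate_compartments()].
#' @param path Output file path.
#' @param params Optional [continuous_params()] recorded in the provenance
#'   header.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, params = NULL) {
  stopifnot(is.data.frame(traj))
  .write_table(as_tibble(traj), path, params)
}

#' Write canonical fixture runs
#'
#' Generates the small reference outputs used by the test suite and by worked
#' examples: the `c = 6` linear run to `T = 15` (events, counts, Newick), the
#' `c = 6` rosette to `T = 12` (snapshot, counts), the crypt steady-state
#' configuration to `T = 200` (counts, final 3D snapshot), and one balanced
#' plus one growth ODE trajectory. All runs are deterministic, so regeneration
#' is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)

  lin <- simulate_lineage(rule_params(c = 6, T = 15))
  write_division_events(lin, fp("linear_c6_T15_events.tsv"))
  write_state_counts(lin, fp("linear_c6_T15_counts.csv"))
  writeLines(lineage_newick(lin), fp("linear_c6_T15_lineage.nwk"))

  ros <- simulate_rosette(rule_params(c = 6, T = 12))
  write_snapshot(ros, fp("rosette_c6_T12_snapshot.csv"))
  write_state_counts(ros, fp("rosette_c6_T12_counts.csv"))

  st <- simulate_rosette(crypt_steady_params(T = 200))
  write_state_counts(st, fp("steady_c6_counts.csv"))
  write_snapshot(st, fp("steady_c6_snapshot3d.csv"), cylinder = TRUE)

  bal <- continuous_params(k2 = 0.381966, k3 = 0.381966 / 0.618034,
                           k4 = 0.618034, k5 = 0.3, k6 = 0.3)
  write_trajectory(
    integrate_compartments(bal, c(M = 1, I = 1), times = seq(0, 100, 0.5)),
    fp("ode_balanced_trajectory.csv"), bal)
  gro <- continuous_params(k2 = k2_from_c(6))
  write_trajectory(
    integrate_compartments(gro, c(M = 1), times = seq(0, 60, 0.5)),
    fp("ode_growth_trajectory.csv"), gro)

  invisible(list.files(dir, full.names = TRUE))
}
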