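#' Simulate a healthy-donor reference panel
#'
#' Generates `n_donors` tumor-free coverage tracks on the given genome
#' (Poisson counting noise, shared GC bias), bias-corrects each with
#' [loess_correct()], and takes the per-bin median via [build_reference()].
#' The default of 27 donors mirrors the size at which a panel's median
#' stabilizes platform artifacts.
#'
#' @param genome Synthetic genome from [sim_genome()] (grid with `gc`,
#'   `map`).
#' @param n_donors Number of donor tracks.
#' @param total_reads Reads per donor (1.5e6 is ~0.1x).
#' @param gc_bias Passed to [simulate_counts()].
#' @param seed Master seed; donor seeds are derived from it.
#' @return Reference panel tibble (see [build_reference()]).
#' @export
simulate_reference_panel <- function(genome, n_donors = 27, total_reads = 1.5e6,
                                     gc_bias = TRUE, seed = 1) {
  profile <- sim_profile(genome)
  seeds <- derive_seeds(seed, n_donors)
  tracks <- purrr::map(seeds, function(s) {
    simulate_counts(profile, tf = 0, total_reads = total_reads,
                    gc_bias = gc_bias, seed = s) |>
      loess_correct()
  })
  build_reference(tracks)
}

#' Full analysis of one ULP-WGS sample
#'
#' Runs the complete workflow on a binned coverage track: GC/mappability
#' correction, sex handling, log2 ratios against the reference panel,
#' multi-restart EM, and solution selection. This is the function behind
#' the command-line `run` subcommand.
#'
#' @param track Coverage track (grid with `count`, `gc`, optionally `map`).
#' @param ref Reference panel from [build_reference()] /
#'   [simulate_reference_panel()], or `NULL` for self-normalization.
#' @param states State space tibble.
#' @param n0_grid,phi0_grid EM initialization grids (see [run_restarts()]).
#' @param ... Further arguments to [run_em()].
#' @return The selected `ulp_solution`, with the log-ratio track in
#'   attribute `lr` and per-candidate summaries in attribute `candidates`.
#' @export
run_sample <- function(track, ref = NULL, states = default_state_space(),
                       n0_grid = c(0.35, 0.45, 0.50, 0.65, 0.75, 0.85, 0.95),
                       phi0_grid = c(2, 3, 4), ...) {
  lr <- normalize_track(track, ref)
  fits <- run_restarts(lr, states = states, n0_grid = n0_grid,
                       phi0_grid = phi0_grid, ...)
  sols <- purrr::map(fits, summarize_solution)
  sel <- select_solution(sols)
  attr(sel, "lr") <- lr
  sel
}
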