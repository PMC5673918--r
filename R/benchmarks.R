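#' Serial tumor/normal admixture benchmark
#'
#' Synthetic analog of the serial-mixture experiment: a high-burden tumor
#' source (design purity 0.78, ploidy ~2.06, ~2,875 autosomal 1 Mb bins)
#' and a tumor-free source are simulated at 1x depth, mixed at the given
#' proportions, thinned to each target coverage, and analyzed with the full
#' pipeline. Ploidy initialization is restricted to `phi0 = 2` for these
#' near-diploid mixtures, matching the serial-mixture protocol. The
#' expected tumor fraction of a mixture is `tumor_prop * source_purity`.
#'
#' @param proportions Tumor read proportions of the mixtures.
#' @param coverages Target coverages as genome-wide fold coverage (0.1 =
#'   ~1.5e6 reads).
#' @param reps Independent mixture replicates per grid point.
#' @param seed Master seed.
#' @param source_tf Design purity of the tumor source.
#' @param n_donors Reference panel size.
#' @return Tibble with one row per mixture: `proportion`, `coverage`,
#'   `rep`, `expected_tf`, `estimated_tf`, `ploidy`, `n_segments`.
#' @export
benchmark_serial_mixtures <- function(proportions = c(0.01, 0.05, 0.11, 0.21, 0.35, 0.45),
                                      coverages = c(0.1, 0.5, 1.0),
                                      reps = 3, seed = 1, source_tf = 0.78,
                                      n_donors = 27) {
  seeds <- derive_seeds(seed, 4)
  genome <- sim_genome(seed = seeds[1])
  ref <- simulate_reference_panel(genome, n_donors = n_donors, seed = seeds[2])
  profile <- default_tumor_profile(genome)
  neutral <- sim_profile(genome)
  source_reads <- 1.5e7  # ~1x sources for thinning
  tumor_src <- simulate_counts(profile, tf = source_tf, total_reads = source_reads,
                               seed = seeds[3])
  normal_src <- simulate_counts(neutral, tf = 0, total_reads = source_reads,
                                seed = seeds[4])

  grid <- tidyr::expand_grid(proportion = proportions, coverage = coverages,
                             rep = seq_len(reps))
  mix_seeds <- derive_seeds(seed + 1, nrow(grid))
  purrr::pmap(dplyr::mutate(grid, mix_seed = mix_seeds),
              function(proportion, coverage, rep, mix_seed) {
    mix <- serial_mixture(tumor_src, normal_src, tumor_prop = proportion,
                          total_reads = round(coverage * 1.5e7), seed = mix_seed)
    sol <- run_sample(mix, ref, phi0_grid = 2)
    tibble::tibble(
      proportion = proportion, coverage = coverage, rep = rep,
      expected_tf = proportion * source_tf,
      estimated_tf = sol$tumor_fraction,
      ploidy = sol$ploidy,
      n_segments = nrow(sol$segments)
    )
  }) |> purrr::list_rbind()
}

#' Tumor-free donor specificity benchmark
#'
#' Simulates `n_samples` independent copy-neutral donor tracks at ~0.1x
#' (Poisson noise, GC bias), analyzes each with the full default pipeline
#' (21-restart grid), and returns the estimated tumor fractions. Used for
#' specificity at the 0.10 and 0.03 classification cut-offs.
#'
#' @param n_samples Number of donor samples.
#' @param seed Master seed.
#' @param total_reads Reads per sample.
#' @param n_donors Reference panel size (panel donors are independent of
#'   the evaluated samples).
#' @return Tibble with `sample` and `estimated_tf`.
#' @export
benchmark_tumor_free <- function(n_samples = 22, seed = 1, total_reads = 1.5e6,
                                 n_donors = 27) {
  seeds <- derive_seeds(seed, 2 + n_samples)
  genome <- sim_genome(seed = seeds[1])
  ref <- simulate_reference_panel(genome, n_donors = n_donors, seed = seeds[2])
  neutral <- sim_profile(genome)
  purrr::map(seq_len(n_samples), function(i) {
    track <- simulate_counts(neutral, tf = 0, total_reads = total_reads,
                             seed = seeds[2 + i])
    sol <- run_sample(track, ref)
    tibble::tibble(sample = i, estimated_tf = sol$tumor_fraction)
  }) |> purrr::list_rbind()
}

#' Spike-in detection-limit benchmark
#'
#' Spikes one arm-level copy gain and one arm-level copy loss (both > 100
#' bins) into simulated copy-neutral 0.1x tracks over a ladder of tumor
#' fractions, analyzes each with the full pipeline (ploidy initialization
#' 2, as the spiked genomes are diploid), and classifies detection as an
#' estimated tumor fraction at or above `threshold`. The detection limit is
#' the smallest spiked fraction detected in a majority of replicates.
#'
#' The default events are a whole-chromosome chr8 gain (146 bins) and a
#' whole-chromosome chr13 loss (115 bins) -- the canonical arm-scale
#' alterations of metastatic prostate/breast tumors, and, like real
#' arm-level events, bounded by chromosome ends.
#'
#' Replicates are independent backgrounds: each replicate has its own
#' synthetic genome, donor panel and neutral track (shared across the
#' tumor-fraction ladder), mirroring the use of several different patients
#' to capture between-sample variance.
#'
#' @param tf_grid Spiked tumor fractions.
#' @param reps Replicates (independent backgrounds) per fraction.
#' @param seed Master seed.
#' @param threshold Detection cut-off on the estimated tumor fraction.
#' @param events Event table for [spike_in()].
#' @return Tibble with `tf`, `rep`, `estimated_tf`, `detected`; the
#'   detection limit is in attribute `detection_limit` (`NA` if never
#'   detected).
#' @export
benchmark_spike_in <- function(tf_grid = seq(0.01, 0.10, by = 0.01), reps = 5,
                               seed = 1, threshold = 0.03,
                               events = tibble::tibble(
                                 chrom = c("chr8", "chr13"),
                                 start = c(0, 0),
                                 end = c(147e6, 116e6),
                                 kind = c("gain", "loss")
                               )) {
  bg_seeds <- matrix(derive_seeds(seed, 2 * reps), ncol = 2)
  backgrounds <- purrr::map(seq_len(reps), function(r) {
    genome <- sim_genome(seed = bg_seeds[r, 1])
    list(
      neutral = sim_profile(genome),
      ref = simulate_reference_panel(genome, seed = bg_seeds[r, 2])
    )
  })

  grid <- tidyr::expand_grid(tf = tf_grid, rep = seq_len(reps))
  run_seeds <- matrix(derive_seeds(seed + 1, 2 * nrow(grid)), ncol = 2)
  res <- purrr::pmap(dplyr::mutate(grid, idx = dplyr::row_number()),
                     function(tf, rep, idx) {
    bg <- backgrounds[[rep]]
    track <- simulate_counts(bg$neutral, tf = 0, total_reads = 1.5e6,
                             seed = run_seeds[idx, 1])
    spiked <- spike_in(track, events, tf = tf, seed = run_seeds[idx, 2])
    sol <- run_sample(spiked, bg$ref, phi0_grid = 2)
    tibble::tibble(tf = tf, rep = rep, estimated_tf = sol$tumor_fraction,
                   detected = detect_tumor(sol, threshold))
  }) |> purrr::list_rbind()

  by_tf <- res |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(majority = mean(.data$detected) > 0.5, .groups = "drop")
  detected_tfs <- by_tf$tf[by_tf$majority]
  attr(res, "detection_limit") <- if (length(detected_tfs) > 0) min(detected_tfs) else NA_real_
  res
}

#' Sensitivity panel at the exome-eligibility threshold
#'
#' Serial mixtures at ~0.1x whose expected tumor fraction exceeds 0.10
#' (admixture ladder values 0.15-0.45 at source purity 0.78), used to
#' measure the sensitivity of classifying samples as having estimated
#' tumor fraction at or above 0.10.
#'
#' @param proportions Tumor proportions (all with expected TF > 0.10 at
#'   the default source purity).
#' @param reps Replicates per proportion.
#' @inheritParams benchmark_serial_mixtures
#' @return Tibble as in [benchmark_serial_mixtures()] (coverage fixed at
#'   0.1).
#' @export
benchmark_sensitivity_panel <- function(proportions = c(0.15, 0.17, 0.19, 0.21,
                                                        0.25, 0.30, 0.35, 0.40, 0.45),
                                        reps = 4, seed = 1, source_tf = 0.78) {
  benchmark_serial_mixtures(proportions = proportions, coverages = 0.1,
                            reps = reps, seed = seed, source_tf = source_tf)
}
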