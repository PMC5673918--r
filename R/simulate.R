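#' Synthetic ULP-WGS genome: bin grid with GC and mappability tracks
#'
#' Builds a bin grid (hg19 autosomes by default, ~2,897 bins at 1 Mb) and
#' attaches a GC-fraction track (centered near 0.40, the autosomal average,
#' with mostly bin-to-bin variation plus a mild smooth regional component,
#' so each chromosome samples the full GC range as real 1 Mb tracks do) and
#' mappability (near 1 with a small fraction of poorly mappable bins).
#' Deterministic given the seed.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_width Bin width in base pairs.
#' @param seed RNG seed.
#' @param low_map_fraction Fraction of bins given low (0.5-0.85)
#'   mappability.
#' @return Bin grid tibble with `gc` and `map` columns.
#' @export
sim_genome <- function(chrom_sizes = hg19_chrom_sizes(), bin_width = 1e6,
                       seed = 1, low_map_fraction = 0.02) {
  grid <- build_bin_grid(chrom_sizes, bin_width)
  T_len <- nrow(grid)
  withr::with_seed(seed, {
    z <- rnorm(T_len + 40)
    smooth <- stats::filter(z, rep(1 / 21, 21), sides = 2)
    smooth <- smooth[21:(T_len + 20)]
    smooth[!is.finite(smooth)] <- 0
    smooth <- as.numeric(smooth) / sd(smooth)
    gc <- 0.40 + 0.04 * rnorm(T_len) + 0.015 * smooth
    gc <- pmin(0.60, pmax(0.30, gc))
    map <- pmin(1, 0.995 - abs(rnorm(T_len, 0, 0.008)))
    low <- runif(T_len) < low_map_fraction
    map[low] <- runif(sum(low), 0.5, 0.85)
    grid$gc <- gc
    grid$map <- map
  })
  grid
}

#' Segmental copy-number profile
#'
#' Attaches integer tumor copy numbers to a bin grid from an event table;
#' bins outside any event are copy neutral (c = 2). Events may carry a
#' `prevalence` column (fraction of tumor cells harboring the event,
#' 1 = clonal). The profile ploidy is the mean copy number over valid bins.
#'
#' @param grid Bin grid (optionally with `gc`/`map`).
#' @param events Tibble with `chrom`, `start`, `end`, `copies` and
#'   optionally `prevalence`.
#' @return The grid with `copies` and `prevalence` columns and a `ploidy`
#'   attribute.
#' @export
sim_profile <- function(grid, events = NULL) {
  grid$copies <- 2L
  grid$prevalence <- 1
  if (!is.null(events) && nrow(events) > 0) {
    if (!"prevalence" %in% names(events)) events$prevalence <- 1
    for (i in seq_len(nrow(events))) {
      hit <- grid$chrom == events$chrom[i] &
        grid$start < events$end[i] & grid$end > events$start[i]
      grid$copies[hit] <- as.integer(events$copies[i])
      grid$prevalence[hit] <- events$prevalence[i]
    }
  }
  attr(grid, "ploidy") <- mean(grid$copies[grid$valid])
  grid
}

#' Default high-burden tumor profile
#'
#' A metastatic-like somatic copy-number profile on the hg19 autosome grid:
#' whole-chromosome and arm-level gains (chr1q, chr5, chr7 at 3 copies, a
#' chr8q amplification at 4), and losses (chr4, chr13, chr16, chr17 at 1
#' copy). About a third of the genome is altered and the resulting tumor
#' ploidy is ~2.06, matching the near-diploid, SCNA-heavy tumors used for
#' admixture benchmarking.
#'
#' @param grid Bin grid on hg19 autosomes.
#' @return Copy-number profile (see [sim_profile()]).
#' @export
default_tumor_profile <- function(grid) {
  events <- tibble::tibble(
    chrom = c("chr1", "chr5", "chr7", "chr8", "chr4", "chr13", "chr16", "chr17"),
    start = c(125e6, 0, 0, 47e6, 0, 0, 0, 0),
    end = c(250e6, 181e6, 160e6, 147e6, 192e6, 116e6, 91e6, 82e6),
    copies = c(3, 3, 3, 4, 1, 1, 1, 1)
  )
  sim_profile(grid, events)
}

# Quadratic GC bias curve peaking at `peak`, +/- `magnitude` relative
# amplitude over a GC window of ~0.15, floored at 0.5.
gc_bias_curve <- function(peak = 0.45, magnitude = 0.2) {
  function(gc) pmax(0.5, 1 + magnitude * (1 - ((gc - peak) / 0.15)^2))
}

#' Simulate ULP-WGS bin counts from a copy profile
#'
#' The forward model of the tumor/normal admixture: bin intensity is
#' proportional to `2(1-tf) + tf * (2 s_t + (1 - s_t) c_t)` where `c_t` is
#' the profile copy number and `s_t = 1 - prevalence` the fraction of tumor
#' cells not carrying the event. Intensities are scaled to `total_reads`,
#' multiplied by the GC bias curve and mappability, and Poisson-sampled
#' (counting noise at ~500 reads per bin for 0.1x coverage). A finite
#' `nb_size` switches to negative-binomial sampling to emulate the extra
#' dispersion of real cfDNA libraries.
#'
#' @param profile Copy profile from [sim_profile()].
#' @param tf Tumor fraction in `[0, 1]`.
#' @param total_reads Expected total read count (1.5e6 is ~0.1x).
#' @param gc_bias `NULL` for no bias, `TRUE` for the default quadratic
#'   curve, or a function of GC fraction.
#' @param nb_size Negative-binomial size parameter; `Inf` (default) gives
#'   pure Poisson noise.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return Coverage track: the profile grid with a `count` column.
#' @export
simulate_counts <- function(profile, tf, total_reads = 1.5e6, gc_bias = TRUE,
                            nb_size = Inf, seed = 1) {
  assert_columns(profile, c("chrom", "start", "end", "valid", "copies", "prevalence"),
                 "profile")
  if (tf < 0 || tf > 1) abort("`tf` must lie in [0, 1]")
  if (total_reads <= 0) abort("`total_reads` must be positive")
  curve <- if (is.null(gc_bias) || isFALSE(gc_bias)) {
    function(gc) rep(1, length(gc))
  } else if (isTRUE(gc_bias)) {
    gc_bias_curve()
  } else gc_bias
  s_t <- 1 - profile$prevalence
  mix <- 2 * (1 - tf) + tf * (2 * s_t + (1 - s_t) * profile$copies)
  bias <- curve(profile$gc %||% rep(0.45, nrow(profile)))
  if ("map" %in% names(profile)) bias <- bias * profile$map
  intensity <- mix * bias
  intensity <- intensity / sum(intensity) * total_reads
  out <- profile
  withr::with_seed(seed, {
    out$count <- if (is.finite(nb_size)) {
      rnbinom(length(intensity), size = nb_size, mu = intensity)
    } else {
      rpois(length(intensity), intensity)
    }
  })
  out
}

#' Binomial down-sampling of a coverage track
#'
#' Per-read thinning: each bin's count is replaced by a
#' `Binomial(count, keep_probability)` draw, the bin-level equivalent of
#' down-sampling a read file with a keep probability.
#'
#' @param track Coverage track with a `count` column.
#' @param keep_probability Probability of keeping each read.
#' @param seed RNG seed.
#' @return The track with thinned counts.
#' @export
downsample <- function(track, keep_probability, seed = 1) {
  assert_columns(track, "count", "track")
  if (keep_probability < 0 || keep_probability > 1) {
    abort("`keep_probability` must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    track$count <- rbinom(nrow(track), size = track$count, prob = keep_probability)
  })
  track
}

#' Serial tumor/normal admixture at a target coverage
#'
#' Thins the tumor track to contribute `tumor_prop` of `total_reads` and
#' the normal track the complement, then sums the bin counts -- the
#' bin-level analog of down-sampling and merging two read files so the two
#' proportions sum to one.
#'
#' @param tumor,normal Coverage tracks on the same grid.
#' @param tumor_prop Proportion of reads drawn from the tumor track.
#' @param total_reads Target total reads of the mixture.
#' @param seed RNG seed.
#' @return Mixed coverage track.
#' @export
serial_mixture <- function(tumor, normal, tumor_prop, total_reads = 1.5e6, seed = 1) {
  if (!same_grid(tumor, normal)) abort("tumor and normal tracks are on different grids")
  if (tumor_prop < 0 || tumor_prop > 1) abort("`tumor_prop` must lie in [0, 1]")
  p_t <- tumor_prop * total_reads / sum(tumor$count)
  p_n <- (1 - tumor_prop) * total_reads / sum(normal$count)
  if (p_t > 1 || p_n > 1) abort("source tracks have too few reads for the requested mixture")
  seeds <- derive_seeds(seed, 2)
  t_thin <- downsample(tumor, p_t, seeds[1])
  n_thin <- downsample(normal, p_n, seeds[2])
  out <- tumor
  out$count <- t_thin$count + n_thin$count
  out
}

#' Mixture with an exact expected tumor fraction
#'
#' Reads required from the cancer (CT) track to reach `target_tf` at
#' `total_reads` given the CT sample's purity:
#' `CT_reads = total_reads * target_tf / wes_purity`, the remainder drawn
#' from the healthy-donor (HD) track. Errors when the CT track cannot
#' supply the required reads.
#'
#' @param ct Cancer-patient coverage track.
#' @param hd Healthy-donor coverage track on the same grid.
#' @param target_tf Desired expected tumor fraction (<= `wes_purity`).
#' @param wes_purity Tumor purity of the CT sample.
#' @param total_reads Total reads of the mixture (default 1.5e6, ~0.1x).
#' @param seed RNG seed.
#' @return List with `track` (the mixture) and `spec` (one-row tibble:
#'   `ct_reads`, `hd_reads`, `wes_purity`, `expected_tf`).
#' @export
exact_tf_mixture <- function(ct, hd, target_tf, wes_purity, total_reads = 1.5e6,
                             seed = 1) {
  if (!same_grid(ct, hd)) abort("CT and HD tracks are on different grids")
  if (target_tf > wes_purity) abort("`target_tf` cannot exceed `wes_purity`")
  ct_reads <- total_reads * target_tf / wes_purity
  hd_reads <- total_reads - ct_reads
  if (ct_reads > sum(ct$count)) abort("CT track has insufficient reads for this mixture")
  if (hd_reads > sum(hd$count)) abort("HD track has insufficient reads for this mixture")
  seeds <- derive_seeds(seed, 2)
  ct_thin <- downsample(ct, ct_reads / sum(ct$count), seeds[1])
  hd_thin <- downsample(hd, hd_reads / sum(hd$count), seeds[2])
  out <- ct
  out$count <- ct_thin$count + hd_thin$count
  list(
    track = out,
    spec = tibble::tibble(
      ct_reads = ct_reads, hd_reads = hd_reads, wes_purity = wes_purity,
      expected_tf = ct_reads / total_reads * wes_purity
    )
  )
}

#' Spike copy-number events into a copy-neutral track
#'
#' Rescales the counts of event bins by the admixture ratio
#' `(2(1-tf) + c*tf)/2` at the given tumor fraction (one-copy gain or
#' loss). Losses are applied by binomial read thinning and gains by adding
#' Poisson-distributed extra reads proportional to each bin's observed
#' count, so every bin keeps its own realized noise and bias structure --
#' the sample-specific variance of the neutral background is inherited
#' rather than redrawn from a parametric model. Used to determine the
#' minimum event burden at which tumor is detectable.
#'
#' @param neutral Copy-neutral coverage track (counts).
#' @param events Tibble with `chrom`, `start`, `end`, `kind`
#'   (`"gain"`/`"loss"`); events must not overlap.
#' @param tf Spiked tumor fraction.
#' @param seed RNG seed.
#' @return The track with event bins rescaled; true copies in column
#'   `true_copies`.
#' @export
spike_in <- function(neutral, events, tf, seed = 1) {
  assert_columns(neutral, c("chrom", "start", "end", "count"), "neutral")
  neutral$true_copies <- 2L
  if (is.null(events) || nrow(events) == 0) return(neutral)
  assert_columns(events, c("chrom", "start", "end", "kind"), "events")
  hits <- purrr::map(seq_len(nrow(events)), function(i) {
    which(neutral$chrom == events$chrom[i] &
            neutral$start < events$end[i] & neutral$end > events$start[i])
  })
  if (anyDuplicated(unlist(hits)) > 0) abort("spike-in events must not overlap")

  out <- neutral
  withr::with_seed(seed, {
    for (i in seq_len(nrow(events))) {
      idx <- hits[[i]]
      c_ev <- if (events$kind[i] == "gain") 3 else 1
      ratio <- (2 * (1 - tf) + c_ev * tf) / 2
      out$count[idx] <- if (ratio <= 1) {
        rbinom(length(idx), size = neutral$count[idx], prob = ratio)
      } else {
        neutral$count[idx] + rpois(length(idx), (ratio - 1) * neutral$count[idx])
      }
      out$true_copies[idx] <- as.integer(c_ev)
    }
  })
  out
}
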