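#' Run-length encode a decoded state path into segments
#'
#' Consecutive bins on the same chromosome with the same state are merged
#' into one segment; concatenating the segments reproduces the path exactly.
#'
#' @param path Integer state indices, one per analysis bin.
#' @param grid The analysis bins (tibble with `chrom`, `start`, `end`).
#' @param l Log2 ratios for the same bins (used for the per-segment median).
#' @param states State space tibble.
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_bins`, `state`,
#'   `copies`, `subclonal`, `median_l`.
#' @export
path_to_segments <- function(path, grid, l, states = default_state_space()) {
  if (length(path) != nrow(grid)) abort("`path` length must equal the number of bins")
  if (nrow(grid) == 0) return(tibble::tibble())
  new_seg <- c(TRUE, path[-1] != path[-length(path)] |
                 grid$chrom[-1] != grid$chrom[-nrow(grid)])
  seg_id <- cumsum(new_seg)
  tibble::tibble(seg_id = seg_id, chrom = grid$chrom, start = grid$start,
                 end = grid$end, state_idx = path, l = l) |>
    dplyr::group_by(.data$seg_id) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      n_bins = dplyr::n(),
      state_idx = dplyr::first(.data$state_idx),
      median_l = median(.data$l),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      state = states$state[.data$state_idx],
      copies = states$copies[.data$state_idx],
      subclonal = states$subclonal[.data$state_idx]
    ) |>
    dplyr::select("chrom", "start", "end", "n_bins", "state", "copies",
                  "subclonal", "median_l")
}

#' Summarize a converged EM fit into a candidate solution
#'
#' Decodes the Viterbi path at the converged parameters, run-length encodes
#' it into segments, and computes the genome-fraction statistics used by
#' solution selection: the fraction of analysis bins in a non-neutral state,
#' the fraction in a subclonal state, the fraction of altered segments that
#' are subclonal, and the largest non-neutral event in bins. The reported
#' tumor fraction is `1 - n_hat` (uncorrected for subclonality, so it can
#' underestimate purity when events are subclonal).
#'
#' The solution's selection statistic `F` is the complete-data log
#' posterior at the decoded path, `log p(l, G_hat | theta) + log p(theta)`.
#' Evaluating at the hard path (rather than the marginal likelihood) makes
#' restart comparison immune to a low-tumor-fraction degeneracy in which
#' near-duplicate states at log-ratio zero inflate the marginal by acting
#' as extra mixture components for the noise while contributing no copy
#' number calls.
#'
#' @param em A fitted `ulp_em` object.
#' @return An object of class `ulp_solution`.
#' @export
summarize_solution <- function(em) {
  states <- em$states
  mu <- state_means(em$params$n, em$params$s, em$params$phi, states)
  logE <- emission_logdensity(em$data$l, mu, em$params$lambda, em$hyper$nu)
  chains <- em$chains %||% list(seq_len(nrow(logE)))
  path <- viterbi_chains(logE, em$params$A, em$params$pi, chains)
  segments <- path_to_segments(path, em$data, em$data$l, states)

  # complete-data log posterior at the decoded path
  logA <- log(em$params$A)
  log_pi <- log(em$params$pi)
  path_lp <- sum(logE[cbind(seq_along(path), path)])
  for (idx in chains) {
    p <- path[idx]
    path_lp <- path_lp + log_pi[p[1]]
    if (length(p) > 1) path_lp <- path_lp + sum(logA[cbind(p[-length(p)], p[-1])])
  }
  F_complete <- path_lp + log_prior(em$params, em$hyper, states)

  altered_bin <- states$state[path] != "NEUT"
  subclonal_bin <- states$subclonal[path]
  altered_seg <- segments$state != "NEUT"
  n_altered_seg <- sum(altered_seg)

  structure(list(
    tumor_fraction = 1 - em$params$n,
    ploidy = em$params$phi,
    normal_fraction = em$params$n,
    subclone_fraction = em$params$s,
    segments = segments,
    path = path,
    bins = tibble::tibble(
      chrom = em$data$chrom, start = em$data$start, end = em$data$end,
      l = em$data$l, state = states$state[path], copies = states$copies[path],
      subclonal = states$subclonal[path]
    ),
    fraction_altered = mean(altered_bin),
    fraction_subclonal_genome = mean(subclonal_bin),
    max_single_state_fraction = max(tabulate(path[altered_bin], nbins = nrow(states))) /
      length(path),
    fraction_calls_subclonal = if (n_altered_seg > 0) {
      sum(altered_seg & segments$subclonal) / n_altered_seg
    } else 0,
    largest_event_bins = if (n_altered_seg > 0) max(segments$n_bins[altered_seg]) else 0L,
    F = F_complete,
    F_em = em$F,
    loglik = em$loglik,
    init = em$init,
    iterations = em$iterations,
    converged = em$converged,
    flags = character(0)
  ), class = "ulp_solution")
}

#' Select the final solution across EM restarts
#'
#' Candidates with more than half the genome called subclonal, or more than
#' 70% of altered calls subclonal, are not selected (clonal/subclonal
#' identifiability breaks down without allelic information). Candidates
#' whose decoded path places essentially the whole genome
#' (`max_single_state` or more) in one non-neutral state are also not
#' selected: a uniform single-state genome is observationally equivalent to
#' a relabeled diploid genome at a different ploidy, and the diploid
#' interpretation is the identifiable one. Among the survivors the
#' maximum-`F` solution wins; if every candidate is filtered, the overall
#' maximum-`F` solution is returned flagged `SUBCLONAL_FILTER_FALLBACK`.
#' Finally the zero-tumor-fraction rule is applied: a winner with under 5%
#' of bins altered and no event of 50 or more bins is reported as tumor
#' fraction zero (flag `ZERO_TF`) -- at that level the apparent signal is
#' indistinguishable from noise.
#'
#' @param candidates List of `ulp_solution` objects.
#' @param max_subclonal_genome Genome-fraction filter threshold.
#' @param max_subclonal_calls Subclonal-call-fraction filter threshold.
#' @param max_single_state Fraction of the genome in one non-neutral state
#'   beyond which a candidate is treated as a relabeled-diploid degeneracy.
#' @param min_altered Zero-TF rule: minimum total alteration fraction.
#' @param min_event_bins Zero-TF rule: minimum largest-event size in bins.
#' @return The selected `ulp_solution`, possibly flagged, with the
#'   discarded candidates' summaries in attribute `candidates`.
#' @export
select_solution <- function(candidates, max_subclonal_genome = 0.5,
                            max_subclonal_calls = 0.7, max_single_state = 0.95,
                            min_altered = 0.05, min_event_bins = 50) {
  if (length(candidates) == 0) abort("no candidate solutions")
  stats <- purrr::map(candidates, function(sol) {
    tibble::tibble(
      n0 = sol$init[["n0"]], phi0 = sol$init[["phi0"]],
      tumor_fraction = sol$tumor_fraction, ploidy = sol$ploidy,
      F = sol$F,
      fraction_altered = sol$fraction_altered,
      fraction_subclonal_genome = sol$fraction_subclonal_genome,
      fraction_calls_subclonal = sol$fraction_calls_subclonal,
      max_single_state_fraction = sol$max_single_state_fraction %||% 0,
      largest_event_bins = sol$largest_event_bins
    )
  }) |> purrr::list_rbind()

  pass <- stats$fraction_subclonal_genome <= max_subclonal_genome &
    stats$fraction_calls_subclonal <= max_subclonal_calls &
    stats$max_single_state_fraction < max_single_state
  fallback <- !any(pass)
  pool <- if (fallback) seq_along(candidates) else which(pass)
  # deterministic order: F descending, then initialization, so permuting
  # the candidate list cannot change the winner
  ord <- pool[order(-stats$F[pool], stats$n0[pool], stats$phi0[pool])]
  sol <- candidates[[ord[1]]]
  if (fallback) {
    sol$flags <- c(sol$flags, "SUBCLONAL_FILTER_FALLBACK")
    # Clonal events at DNA fraction t are indistinguishable from subclonal
    # events at tumor fraction t/(1-s): a flat ridge in (n, s) on which EM
    # lands arbitrarily, and near the ridge the soft posteriors of the
    # near-duplicate states at log-ratio zero contaminate the EM point
    # estimates. Re-estimate the event DNA fraction from the decoded
    # segments themselves: each altered segment's median log ratio gives
    # t = D (2^dl - 1) / (c - 2) with D = 2n + (1-n)phi the sample-average
    # copy number; hard segment medians are immune to the contamination.
    tf_seg <- segment_moment_tf(sol)
    if (!is.na(tf_seg)) {
      sol$tumor_fraction <- tf_seg
      sol$flags <- c(sol$flags, "TF_FROM_SEGMENTS")
    }
  }

  if (sol$fraction_altered < min_altered && sol$largest_event_bins < min_event_bins) {
    sol$tumor_fraction <- 0
    sol$flags <- c(sol$flags, "ZERO_TF")
  }
  # a winner that is itself a uniform relabeling is reported as diploid
  if ((sol$max_single_state_fraction %||% 0) >= max_single_state) {
    sol$tumor_fraction <- 0
    sol$flags <- c(sol$flags, "RELABELED_DIPLOID")
  }
  attr(sol, "candidates") <- stats
  sol
}

# Moment re-estimate of the tumor DNA fraction from decoded segments:
# bin-weighted median over altered segments of t = D (2^dl - 1)/(c - 2),
# where dl is the segment's median log ratio relative to the empirical
# neutral level (the median log ratio of bins decoded neutral, which
# absorbs the small negative offset that log-of-mean-normalized noise
# carries). D = 2n + (1-n)phi is the sample-average copy number, ~2 in
# this regime. The weighted median keeps small spurious segments (near-
# zero implied fraction, few bins) from diluting the estimate of the
# dominant events. Returns NA when no altered or no neutral bins exist.
segment_moment_tf <- function(sol) {
  seg <- sol$segments[sol$segments$copies != 2, , drop = FALSE]
  neut <- sol$bins$l[sol$bins$state == "NEUT"]
  if (nrow(seg) == 0 || length(neut) == 0) return(NA_real_)
  D <- 2 * sol$normal_fraction + (1 - sol$normal_fraction) * sol$ploidy
  dl <- seg$median_l - median(neut)
  t_seg <- D * (2^dl - 1) / (seg$copies - 2)
  ord <- order(t_seg)
  cum <- cumsum(seg$n_bins[ord]) / sum(seg$n_bins)
  t_med <- t_seg[ord][which(cum >= 0.5)[1]]
  max(0, min(1, t_med))
}

#' Classify tumor presence from the estimated tumor fraction
#'
#' @param solution A `ulp_solution` (or anything with a `tumor_fraction`
#'   element).
#' @param threshold Detection threshold; 0.03 is the lower limit of
#'   detection, 0.10 the eligibility threshold for standard-depth exome
#'   sequencing.
#' @return `TRUE` if the estimated tumor fraction is at or above the
#'   threshold.
#' @export
detect_tumor <- function(solution, threshold = 0.03) {
  tf <- if (is.list(solution)) solution$tumor_fraction else solution
  tf >= threshold
}
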