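#' @export
print.ulp_solution <- function(x, ...) {
  cat("ULP-WGS copy number solution\n")
  cat(sprintf("  tumor fraction : %.3f%s\n", x$tumor_fraction,
              if ("ZERO_TF" %in% x$flags) " (zeroed: negligible alteration)" else ""))
  cat(sprintf("  tumor ploidy   : %.2f\n", x$ploidy))
  cat(sprintf("  normal fraction: %.3f  subclone-absent s: %.3f\n",
              x$normal_fraction, x$subclone_fraction))
  cat(sprintf("  segments       : %d (%.1f%% of bins altered, largest event %d bins)\n",
              nrow(x$segments), 100 * x$fraction_altered, x$largest_event_bins))
  cat(sprintf("  log posterior F: %.2f  (init n0=%.2f, phi0=%g; %d EM iterations)\n",
              x$F, x$init[["n0"]], x$init[["phi0"]], x$iterations))
  if (length(x$flags) > 0) cat("  flags          :", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a solution into its segment table
#'
#' @param x A `ulp_solution`.
#' @param ... Unused.
#' @return Tibble of copy-number segments.
#' @method tidy ulp_solution
#' @export
tidy.ulp_solution <- function(x, ...) {
  x$segments
}

#' One-row summary of a solution
#'
#' @param x A `ulp_solution`.
#' @param ... Unused.
#' @return One-row tibble with the global estimates and selection
#'   statistics.
#' @method glance ulp_solution
#' @export
glance.ulp_solution <- function(x, ...) {
  tibble::tibble(
    tumor_fraction = x$tumor_fraction,
    ploidy = x$ploidy,
    normal_fraction = x$normal_fraction,
    subclone_fraction = x$subclone_fraction,
    fraction_altered = x$fraction_altered,
    fraction_subclonal_genome = x$fraction_subclonal_genome,
    fraction_calls_subclonal = x$fraction_calls_subclonal,
    largest_event_bins = x$largest_event_bins,
    n_segments = nrow(x$segments),
    F = x$F,
    iterations = x$iterations,
    converged = x$converged,
    n0 = x$init[["n0"]],
    phi0 = x$init[["phi0"]],
    flags = paste(x$flags, collapse = ";")
  )
}

#' One-row summary of an EM fit
#'
#' @param x A `ulp_em` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance ulp_em
#' @export
glance.ulp_em <- function(x, ...) {
  tibble::tibble(
    tumor_fraction = 1 - x$params$n,
    ploidy = x$params$phi,
    subclone_fraction = x$params$s,
    F = x$F,
    loglik = x$loglik,
    iterations = x$iterations,
    converged = x$converged,
    n0 = x$init[["n0"]],
    phi0 = x$init[["phi0"]]
  )
}

#' Genome-wide copy-number plot of a solution
#'
#' Per-bin log2 ratios colored by the decoded copy-number state, in genome
#' order with chromosome boundaries.
#'
#' @param object A `ulp_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ulp_solution
#' @export
autoplot.ulp_solution <- function(object, ...) {
  bins <- object$bins
  bins$x <- seq_len(nrow(bins))
  bins$state <- factor(bins$state,
                       levels = c("HETD", "HETD_sc", "NEUT", "GAIN_sc", "GAIN",
                                  "AMP", "HLAMP"))
  bounds <- which(bins$chrom[-1] != bins$chrom[-nrow(bins)]) + 0.5
  cols <- c(HETD = "#2c7bb6", HETD_sc = "#abd9e9", NEUT = "grey50",
            GAIN_sc = "#fdae61", GAIN = "#d7191c", AMP = "#a50026",
            HLAMP = "#67001f")
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$x, y = .data$l, colour = .data$state)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_vline(xintercept = bounds, colour = "grey85", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_colour_manual(values = cols, drop = FALSE) +
    ggplot2::labs(
      x = "genome position (1 Mb bins)", y = "log2 copy ratio",
      colour = "state",
      title = sprintf("tumor fraction %.3f, ploidy %.2f",
                      object$tumor_fraction, object$ploidy)
    ) +
    ggplot2::theme_minimal()
}
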