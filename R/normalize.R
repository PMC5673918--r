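#' Correct bin counts for GC-content and mappability bias
#'
#' Two sequential LOESS fits are applied to the valid autosomal bins: first
#' read count against GC fraction, then the GC-corrected count against
#' mappability. Observed counts are divided by the fitted curve values
#' (coverage bias is proportional), and the result is scaled so that the
#' mean over valid autosomal bins is 1 -- the total-read normalization that
#' the copy-number mixture model's ploidy denominator assumes. The curves
#' are fitted on autosomes only but applied to every bin with finite
#' covariates.
#'
#' Bins with mappability below `min_mappability` are excluded from curve
#' fitting and flagged invalid. If a covariate is (nearly) constant the
#' corresponding fit is skipped with a warning rather than fitting a
#' degenerate curve.
#'
#' @param track Tibble with `chrom`, `valid`, `count`, `gc` and optionally
#'   `map` columns.
#' @param gc_span,map_span LOESS spans for the GC and mappability fits.
#' @param min_mappability Bins below this uniqueness score are dropped from
#'   fitting and flagged invalid.
#' @param min_bins Minimum number of valid autosomal bins required.
#' @return The track with a `corrected` column (mean 1 over valid autosomal
#'   bins) and an updated `valid` mask.
#' @export
loess_correct <- function(track, gc_span = 0.3, map_span = 0.99,
                          min_mappability = 0.9, min_bins = 100) {
  assert_columns(track, c("chrom", "valid", "count", "gc"), "track")
  has_map <- "map" %in% names(track)

  valid <- track$valid & is.finite(track$count) & is.finite(track$gc)
  if (has_map) valid <- valid & is.finite(track$map) & track$map >= min_mappability
  track$valid <- valid

  fit_set <- valid & is_autosome(track$chrom) & track$count > 0
  if (sum(fit_set) < min_bins) {
    abort(sprintf("only %d valid autosomal bins; at least %d are required for bias correction",
                  sum(fit_set), min_bins))
  }

  fit_curve <- function(y, x, span, label) {
    if (diff(range(x[fit_set])) < 1e-3) {
      warn(sprintf("%s is nearly constant; skipping its bias fit", label))
      return(rep(1, length(x)))
    }
    df <- data.frame(y = y[fit_set], x = x[fit_set])
    fit <- loess(y ~ x, data = df, span = span, degree = 2, family = "symmetric")
    # evaluate the curve on a coarse grid and interpolate; clamps outside
    # the fitted covariate range to the nearest end of the curve
    gx <- seq(min(df$x), max(df$x), length.out = 256)
    gy <- predict(fit, newdata = data.frame(x = gx))
    ok <- is.finite(gy)
    pred <- stats::approx(gx[ok], gy[ok], xout = x, rule = 2)$y
    pred[!is.finite(pred) | pred <= 0] <- NA_real_
    pred / mean(pred[fit_set], na.rm = TRUE)
  }

  gc_curve <- fit_curve(track$count, track$gc, gc_span, "GC fraction")
  cor1 <- track$count / gc_curve
  if (has_map) {
    map_curve <- fit_curve(cor1, track$map, map_span, "mappability")
    corrected <- cor1 / map_curve
  } else {
    corrected <- cor1
  }

  track$valid <- track$valid & is.finite(corrected)
  scale <- mean(corrected[track$valid & is_autosome(track$chrom)])
  track$corrected <- corrected / scale
  track
}

#' Infer patient sex from coverage
#'
#' A sample is called male when both criteria hold: the proportion of raw
#' chrY reads out of all reads exceeds 0.001, and the median log2 of the
#' corrected chrX coverage is below -0.5 (a single chrX at half the
#' autosomal level). Otherwise female. Tracks without chrX/chrY bins return
#' `"female"` with a warning.
#'
#' @param track Corrected coverage track (see [loess_correct()]).
#' @return `"male"` or `"female"`, with `chrY_prop` and `chrX_median_l`
#'   attributes.
#' @export
infer_sex <- function(track) {
  assert_columns(track, c("chrom", "count"), "track")
  if (!any(is_chrx(track$chrom)) || !any(is_chry(track$chrom))) {
    warn("track has no chrX/chrY bins; returning \"female\"")
    return(structure("female", chrY_prop = NA_real_, chrX_median_l = NA_real_))
  }
  assert_columns(track, "corrected", "track")
  chry_prop <- sum(track$count[is_chry(track$chrom)]) / sum(track$count)
  lx <- log2(track$corrected[is_chrx(track$chrom) & track$valid])
  x_med <- median(lx, na.rm = TRUE)
  sex <- if (chry_prop > 0.001 && x_med < -0.5) "male" else "female"
  structure(sex, chrY_prop = chry_prop, chrX_median_l = x_med)
}

#' Rescale chrX coverage for a male sample
#'
#' Divides corrected chrX counts by their median so that single-copy chrX
#' coverage sits at the diploid baseline; the median of the rescaled chrX
#' bins is exactly 1.
#'
#' @param track Corrected coverage track of a male sample.
#' @return The track with chrX `corrected` values rescaled.
#' @export
rescale_male_chrX <- function(track) {
  assert_columns(track, c("chrom", "valid", "corrected"), "track")
  on_x <- is_chrx(track$chrom)
  med <- median(track$corrected[on_x & track$valid], na.rm = TRUE)
  if (!is.finite(med) || med <= 0) abort("no valid chrX bins to rescale")
  track$corrected[on_x] <- track$corrected[on_x] / med
  track
}

#' Build a healthy-donor reference panel
#'
#' Computes the per-bin median of corrected coverage across a panel of
#' (tumor-free) donor tracks. The panel normalizes out platform and
#' library-construction artifacts that survive GC/mappability correction.
#' Bins where the median is non-positive or undefined are invalid.
#'
#' @param panel List of corrected coverage tracks on the same grid.
#' @return A tibble with the grid columns, the per-bin median `h`, and an
#'   `n_samples` attribute.
#' @export
build_reference <- function(panel) {
  if (length(panel) == 0) abort("reference panel is empty")
  purrr::walk(panel, assert_columns, cols = c("chrom", "start", "end", "valid", "corrected"))
  g1 <- panel[[1]]
  ok <- purrr::map_lgl(panel, same_grid, b = g1)
  if (!all(ok)) abort("all panel tracks must share the same bin grid")
  mat <- vapply(panel, function(tr) ifelse(tr$valid, tr$corrected, NA_real_),
                numeric(nrow(g1)))
  h <- apply(mat, 1, median, na.rm = TRUE)
  ref <- g1[, c("chrom", "start", "end", "bin")]
  ref$h <- h
  ref$valid <- is.finite(h) & h > 0
  attr(ref, "n_samples") <- length(panel)
  ref
}

#' Log2 copy ratios against a reference
#'
#' `l = log2(corrected / h)`: the observation sequence for the copy-number
#' HMM. Bins invalid in either the sample or the reference are invalid in
#' the output. With `ref = NULL` the sample is normalized against its own
#' autosomal mean (`h = 1`, since corrected coverage is already mean-scaled)
#' -- a degraded mode for when no donor panel is available.
#'
#' @param track Corrected coverage track.
#' @param ref Reference panel from [build_reference()], or `NULL`.
#' @return The track with `l` (log2 ratio) added and `valid` intersected
#'   with the reference mask.
#' @export
log2_ratio <- function(track, ref = NULL) {
  assert_columns(track, c("chrom", "start", "end", "valid", "corrected"), "track")
  if (is.null(ref)) {
    inform("no reference panel supplied; normalizing against the sample's own autosomal mean")
    h <- rep(1, nrow(track))
    ref_valid <- rep(TRUE, nrow(track))
  } else {
    if (!same_grid(track, ref)) abort("track and reference are on different grids")
    h <- ref$h
    ref_valid <- ref$valid
  }
  track$valid <- track$valid & ref_valid & is.finite(h) & h > 0 &
    is.finite(track$corrected) & track$corrected > 0
  track$l <- ifelse(track$valid, log2(track$corrected / h), NA_real_)
  track
}

#' Full normalization: bias correction, sex handling, reference ratio
#'
#' Convenience pipeline: [loess_correct()], sex inference and male chrX
#' rescaling when sex chromosomes are present, then [log2_ratio()] against
#' the supplied panel.
#'
#' @inheritParams loess_correct
#' @inheritParams log2_ratio
#' @return Log-ratio track with a `sex` attribute.
#' @export
normalize_track <- function(track, ref = NULL, gc_span = 0.3, map_span = 0.99,
                            min_mappability = 0.9, min_bins = 100) {
  track <- loess_correct(track, gc_span = gc_span, map_span = map_span,
                         min_mappability = min_mappability, min_bins = min_bins)
  sex <- "female"
  if (any(is_chrx(track$chrom)) && any(is_chry(track$chrom))) {
    sex <- infer_sex(track)
    if (sex == "male") track <- rescale_male_chrX(track)
  }
  out <- log2_ratio(track, ref)
  attr(out, "sex") <- as.character(sex)
  out
}
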