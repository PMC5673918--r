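#' Expected variant allele fraction in cfDNA
#'
#' For a clonal heterozygous somatic variant carried on `M` chromosome
#' copies in a tumor of ploidy `phi` at cfDNA tumor fraction `alpha`, the
#' expected allele fraction is
#' \deqn{p = \frac{\alpha M w}{\alpha\phi + 2(1-\alpha)}}
#' where `w` is the reference-bias skew of the library (`w = 1`: the
#' variant allele is evenly represented relative to the reference allele).
#'
#' @param alpha Tumor fraction in `[0, 1]`.
#' @param M Variant multiplicity (chromosome copies carrying it, >= 1).
#' @param w Reference-bias skew factor (> 0).
#' @param phi Tumor ploidy (> 0).
#' @return Expected variant allele fraction.
#' @export
expected_vaf <- function(alpha, M = 1, w = 1, phi = 2) {
  if (any(alpha < 0 | alpha > 1)) abort("`alpha` must lie in [0, 1]")
  if (any(M < 1)) abort("`M` must be at least 1")
  if (any(w <= 0) || any(phi <= 0)) abort("`w` and `phi` must be positive")
  den <- alpha * phi + 2 * (1 - alpha)
  if (any(den <= 0)) abort("zero denominator in expected allele fraction")
  alpha * M * w / den
}

#' Power to observe at least three variant reads
#'
#' Binomial detection power at locus coverage `N` and expected allele
#' fraction `p`:
#' \deqn{P(X \ge 3) = 1 - [\mathrm{Bin}(0,N,p) + \mathrm{Bin}(1,N,p) + \mathrm{Bin}(2,N,p)]}
#' Monotone non-decreasing in both `N` and `p`.
#'
#' @param N Locus coverage (non-negative integer reads).
#' @param p Expected variant allele fraction in `[0, 1]`.
#' @return Detection probability.
#' @export
power_ge3 <- function(N, p) {
  if (any(N < 0)) abort("`N` must be non-negative")
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1]")
  pbinom(2, size = N, prob = p, lower.tail = FALSE)
}

#' Minimum coverage reaching a target detection power
#'
#' Smallest integer `N` with `power_ge3(N, p) >= target_power`, for
#' calibrating cfDNA exome sequencing depth from the ULP-WGS tumor-fraction
#' estimate.
#'
#' @param p Expected variant allele fraction (> 0).
#' @param target_power Required power in (0, 1); default 0.9.
#' @param max_N Search cap.
#' @return Integer coverage.
#' @export
required_coverage <- function(p, target_power = 0.9, max_N = 1e6) {
  if (p <= 0) abort("`p` must be positive; no coverage can power a zero allele fraction")
  if (target_power <= 0 || target_power >= 1) abort("`target_power` must be in (0, 1)")
  lo <- 3L
  hi <- 8L
  while (power_ge3(hi, p) < target_power) {
    hi <- hi * 2L
    if (hi > max_N) abort("required coverage exceeds `max_N`")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (power_ge3(mid, p) >= target_power) hi <- mid else lo <- mid + 1L
  }
  as.integer(hi)
}

#' Power grid over tumor fraction and coverage
#'
#' Tidy grid of detection power for calibrating exome depth against the
#' ULP-WGS tumor-fraction estimate, at the default clonal heterozygous
#' profile (`M = 1`, `w = 1`).
#'
#' @param alpha Tumor fractions.
#' @param N Coverages.
#' @inheritParams expected_vaf
#' @return Tibble with `alpha`, `N`, `p`, `power`.
#' @export
power_grid <- function(alpha, N, M = 1, w = 1, phi = 2) {
  tidyr::expand_grid(alpha = alpha, N = N) |>
    dplyr::mutate(
      p = expected_vaf(.data$alpha, M = M, w = w, phi = phi),
      power = power_ge3(.data$N, .data$p)
    )
}
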