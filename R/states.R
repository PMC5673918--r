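#' Copy-number state space
#'
#' Clonal states are hemizygous deletion (HETD, 1 copy), copy neutral
#' (NEUT, 2), gain (GAIN, 3), amplification (AMP, 4), and high-level
#' amplification (HLAMP, modeled at 5 copies). With
#' `include_subclonal = TRUE`, two subclonal states are added -- subclonal
#' hemizygous deletion (HETD_sc, 1 copy) and subclonal gain (GAIN_sc, 3
#' copies) -- whose means are shrunk toward neutral by the shared
#' subclone-absent fraction `s`. Homozygous deletion is not modeled: at 1 Mb
#' resolution homozygous events are smaller than a bin.
#'
#' @param include_subclonal Include the two subclonal states (default).
#' @return Tibble with columns `state`, `copies`, `subclonal`.
#' @export
default_state_space <- function(include_subclonal = TRUE) {
  clonal <- tibble::tibble(
    state = c("HETD", "NEUT", "GAIN", "AMP", "HLAMP"),
    copies = 1:5,
    subclonal = FALSE
  )
  if (!include_subclonal) return(clonal)
  dplyr::bind_rows(clonal, tibble::tibble(
    state = c("HETD_sc", "GAIN_sc"),
    copies = c(1L, 3L),
    subclonal = TRUE
  ))
}

#' Expected log2 ratio per copy-number state
#'
#' The observed coverage of a bin is an admixture of normal-cell DNA (2
#' copies at proportion `n`) and tumor DNA (`c_g` copies at proportion
#' `1 - n`); subclonal events add a third component for the tumor cells not
#' carrying the event (proportion `s` of the tumor). Coverage is normalized
#' by total reads, i.e., by the sample-average copy number `2n + (1-n)*phi`.
#' The state mean on the log2-ratio scale is therefore
#'
#' \deqn{\mu_g = \log_2\frac{2n + 2s(1-n) + (1-s)(1-n)c_g}{2n + (1-n)\phi}}
#'
#' with `s = 0` for clonal states. Base 2 keeps the means on the same scale
#' as the data.
#'
#' @param n Normal (non-tumor) fraction in `[0, 1]`.
#' @param s Subclone-absent fraction in `[0, 1]` (shared by all subclonal
#'   states).
#' @param phi Average tumor ploidy (> 0).
#' @param states State space tibble (see [default_state_space()]).
#' @return Numeric vector of state means, one per state.
#' @export
state_means <- function(n, s, phi, states) {
  if (n < 0 || n > 1 || s < 0 || s > 1) abort("`n` and `s` must lie in [0, 1]")
  if (phi <= 0) abort("`phi` must be positive")
  s_g <- ifelse(states$subclonal, s, 0)
  num <- 2 * n + 2 * s_g * (1 - n) + (1 - s_g) * (1 - n) * states$copies
  den <- 2 * n + (1 - n) * phi
  if (den <= 0 || any(num <= 0)) abort("non-positive copy mixture; check n, s, phi")
  log2(num / den)
}

#' Homogeneous HMM transition matrix
#'
#' Self-transition probability `e` on the diagonal and `(1 - e)/(K - 1)`
#' elsewhere. All bins are equal-sized, so a single stationary matrix is
#' used rather than distance-dependent transitions.
#'
#' @param K_size Number of states (>= 2).
#' @param e Self-transition probability in (0, 1); default 0.99999, which
#'   at ~3,000 bins per genome strongly favors megabase-scale segments.
#' @return `K_size` x `K_size` stochastic matrix.
#' @export
transition_matrix <- function(K_size, e = 0.99999) {
  if (K_size < 2) abort("`K_size` must be at least 2")
  if (e <= 0 || e >= 1) abort("`e` must be in (0, 1)")
  A <- matrix((1 - e) / (K_size - 1), K_size, K_size)
  diag(A) <- e
  A
}

#' Student's-t log emission densities
#'
#' Log density of each bin's log2 ratio under each state's Student's-t
#' emission with mean `mu_g`, precision `lambda_g` and `nu` degrees of
#' freedom. The heavy tails (`nu = 2.1` by default in the model) make the
#' fit robust to outlier bins that survive masking.
#'
#' @param l Numeric vector of log2 ratios (a `LogRatioTrack`'s `l` column).
#' @param mu,lambda Per-state means and precisions.
#' @param nu Degrees of freedom (> 0).
#' @return `length(l)` x `length(mu)` matrix of log densities.
#' @export
emission_logdensity <- function(l, mu, lambda, nu) {
  if (any(lambda <= 0)) abort("`lambda` must be positive")
  if (nu <= 0) abort("`nu` must be positive")
  if (length(mu) != length(lambda)) abort("`mu` and `lambda` must have equal length")
  cst <- lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(pi * nu)
  d <- outer(l, mu, "-")
  q <- sweep(d * d, 2, lambda, "*")
  sweep(-(nu + 1) / 2 * log1p(q / nu), 2, cst + 0.5 * log(lambda), "+")
}

#' Default hyperparameters
#'
#' All priors are flat (Beta(1,1) for `n` and `s`, flat over the bounded
#' support for `phi`, symmetric Dirichlet with unit concentration for `pi`)
#' except the Gamma prior on each Student's-t precision, which is set from
#' the sample itself: shape `alpha_g = 3` and scale
#' `beta_g = (sd(l)/sqrt(|K|))^-1`, so the prior mean `3*sqrt(|K|)/sd(l)`
#' reflects the variance of the specific sample. The degrees of freedom
#' `nu = 2.1` and self-transition `e = 0.99999` are constants, not
#' estimated.
#'
#' @param l Log2 ratios (finite values are used).
#' @param states State space tibble.
#' @return List of hyperparameters (class `ulp_hyper`).
#' @export
default_hyperparams <- function(l, states) {
  l <- l[is.finite(l)]
  if (length(l) < 2) abort("need at least 2 finite log-ratio values")
  sdl <- sd(l)
  if (sdl == 0) abort("log-ratio data have zero variance")
  K <- nrow(states)
  structure(list(
    alpha_n = 1, beta_n = 1,
    alpha_s = 1, beta_s = 1,
    alpha_phi = 1, beta_phi = Inf,   # flat over the bounded phi support
    alpha_g = 3, beta_g = sqrt(K) / sdl,
    delta_pi = rep(1, K),
    delta_A = 1,
    e = 0.99999,
    nu = 2.1
  ), class = "ulp_hyper")
}

# Log prior density of the global parameters. Flat components contribute 0;
# beta_g is the SCALE of the Gamma prior on each precision. Subclonal
# states share the neutral precision, so only free precisions (the clonal
# ones) carry a prior term.
log_prior <- function(params, hyper, states) {
  free <- !states$subclonal
  lp <- dbeta(params$n, hyper$alpha_n, hyper$beta_n, log = TRUE) +
    sum(dgamma(params$lambda[free], shape = hyper$alpha_g, scale = hyper$beta_g,
               log = TRUE))
  if (any(states$subclonal)) {
    lp <- lp + dbeta(params$s, hyper$alpha_s, hyper$beta_s, log = TRUE)
  }
  if (is.finite(hyper$beta_phi)) {
    lp <- lp + dgamma(params$phi, shape = hyper$alpha_phi, scale = hyper$beta_phi, log = TRUE)
  }
  lp
}

#' Forward-backward posterior state probabilities
#'
#' Scaled forward-backward recursion; numerically safe for thousands of
#' bins. Adding a constant to any row of `log_emissions` leaves the
#' posteriors unchanged.
#'
#' @param log_emissions T x K matrix of log emission densities.
#' @param A K x K transition matrix.
#' @param pi Initial state distribution.
#' @return List with `gamma` (T x K posterior probabilities, rows sum to 1)
#'   and `loglik` (log marginal likelihood of the observation sequence).
#' @export
forward_backward <- function(log_emissions, A, pi) {
  .fb_scaled(as.matrix(log_emissions), as.matrix(A), as.numeric(pi))
}

#' Viterbi decoding
#'
#' Most probable joint state path; ties are broken toward the lowest state
#' index.
#'
#' @inheritParams forward_backward
#' @return Integer vector of state indices (1-based), length T.
#' @export
viterbi <- function(log_emissions, A, pi) {
  as.integer(.viterbi_path(as.matrix(log_emissions), as.matrix(A), as.numeric(pi)))
}
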