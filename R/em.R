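# Row-index runs of consecutive equal chromosome labels: each is an
# independent HMM chain.
chain_indices <- function(chrom) {
  runs <- rle(chrom)
  ends <- cumsum(runs$lengths)
  begins <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(begins, ends, seq.int)
}

# Forward-backward over a set of independent chains sharing (A, pi);
# per-chain log-likelihoods and expected transition counts are summed.
fb_chains <- function(logE, A, pi, chains) {
  gamma <- matrix(NA_real_, nrow(logE), ncol(logE))
  K <- ncol(logE)
  xi <- matrix(0, K, K)
  loglik <- 0
  for (idx in chains) {
    fb <- .fb_scaled(logE[idx, , drop = FALSE], A, pi)
    gamma[idx, ] <- fb$gamma
    xi <- xi + fb$xi
    loglik <- loglik + fb$loglik
  }
  list(gamma = gamma, loglik = loglik, xi = xi)
}

# Viterbi decoding per chain.
viterbi_chains <- function(logE, A, pi, chains) {
  path <- integer(nrow(logE))
  for (idx in chains) {
    path[idx] <- .viterbi_path(logE[idx, , drop = FALSE], A, pi)
  }
  path
}

#' MAP M-step for the copy-number HMM
#'
#' Given E-step posteriors, updates the model parameters by maximum a
#' posteriori estimation:
#'
#' * each precision `lambda_g` in closed form using the Student's-t
#'   latent-scale weights `u = (nu+1)/(nu + lambda d^2)`;
#' * the global parameters `n`, `s`, `phi` by bounded Brent maximization of
#'   the penalized expected log posterior, one coordinate pass per call
#'   (the state means are nonlinear in these parameters, so no closed form
#'   exists);
#' * the initial distribution `pi` from the first-bin posterior with its
#'   Dirichlet prior.
#'
#' The transition matrix is constructed from `e` and held fixed (with
#' `e = 0.99999` the Dirichlet update is numerically inert at ~3,000 bins);
#' set `estimate_transitions = TRUE` to update it from expected transition
#' counts. Each accepted coordinate move is guarded to never decrease the
#' objective, so the EM objective is monotone non-decreasing.
#'
#' @param gamma T x K posterior state probabilities from the E-step.
#' @param l Log2 ratios (length T).
#' @param w Per-bin weights in the M-step sums (0 drops a bin from
#'   parameter estimation while it remains in the chain, used for chr19).
#' @param states State space tibble.
#' @param hyper Hyperparameters (see [default_hyperparams()]).
#' @param params Current parameter list with elements `n`, `s`, `phi`,
#'   `lambda`, `pi`.
#' @param xi Optional K x K matrix of expected transition counts (only used
#'   with `estimate_transitions`).
#' @param estimate_transitions Update `A` by its MAP Dirichlet estimate.
#' @param chain_starts Row indices at which an independent chain begins
#'   (chromosome starts); the initial distribution is updated from the
#'   posterior at these bins.
#' @param bounds List of optimization bounds: `n`, `s` (each length-2 in
#'   (0,1)) and `phi`.
#' @return Updated parameter list.
#' @export
map_m_step <- function(gamma, l, w = rep(1, length(l)), states, hyper, params,
                       xi = NULL, estimate_transitions = FALSE,
                       chain_starts = 1L,
                       bounds = list(n = c(0.01, 0.99), s = c(0.01, 0.99),
                                     phi = c(1.5, 5))) {
  nu <- hyper$nu
  wg <- gamma * w

  # precision update (latent-scale closed form, Gamma(shape, scale) prior)
  mu <- state_means(params$n, params$s, params$phi, states)
  d2 <- outer(l, mu, "-")^2
  u <- (nu + 1) / (nu + sweep(d2, 2, params$lambda, "*"))
  occ <- colSums(wg)
  ssq <- colSums(wg * u * d2)
  lambda_new <- (0.5 * occ + hyper$alpha_g - 1) / (0.5 * ssq + 1 / hyper$beta_g)
  # Subclonal states share the neutral state's precision (one free
  # parameter for the tied group, estimated from the pooled sufficient
  # statistics): their coverage is intermediate between neutral and the
  # clonal event, so the counting noise is the same process. A free
  # precision would instead let a subclonal state sit at log-ratio zero
  # and soak up noise shape as a phantom mixture component whenever the
  # tumor fraction is small.
  tied <- states$subclonal | states$state == "NEUT"
  if (any(states$subclonal)) {
    lambda_new[tied] <- (0.5 * sum(occ[tied]) + hyper$alpha_g - 1) /
      (0.5 * sum(ssq[tied]) + 1 / hyper$beta_g)
  }

  qfun <- function(n, s, phi) {
    mu <- state_means(n, s, phi, states)
    p <- params
    p$n <- n; p$s <- s; p$phi <- phi; p$lambda <- lambda_new
    sum(wg * emission_logdensity(l, mu, lambda_new, nu)) + log_prior(p, hyper, states)
  }

  n <- params$n; s <- params$s; phi <- params$phi
  q_cur <- qfun(n, s, phi)
  step <- function(value, lo, hi, f) {
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-4)
    if (opt$objective > q_cur) list(value = opt$maximum, q = opt$objective)
    else list(value = value, q = q_cur)
  }
  res <- step(n, bounds$n[1], bounds$n[2], function(x) qfun(x, s, phi))
  n <- res$value; q_cur <- res$q
  res <- step(phi, bounds$phi[1], bounds$phi[2], function(x) qfun(n, s, x))
  phi <- res$value; q_cur <- res$q
  if (any(states$subclonal)) {
    res <- step(s, bounds$s[1], bounds$s[2], function(x) qfun(n, x, phi))
    s <- res$value; q_cur <- res$q
  }

  # posterior-mean Dirichlet update (add-delta smoothing): with few chain
  # starts the MAP estimate can zero out a state's initial probability,
  # which would bar whole-chromosome events from ever being entered
  start_mass <- colSums(gamma[chain_starts, , drop = FALSE])
  pi_new <- start_mass + hyper$delta_pi
  pi_new <- pi_new / sum(pi_new)

  out <- params
  out$n <- n; out$s <- s; out$phi <- phi
  out$lambda <- lambda_new
  out$pi <- pi_new
  if (estimate_transitions && !is.null(xi)) {
    A_new <- xi + hyper$delta_A - 1
    A_new <- pmax(A_new, 1e-12)
    out$A <- A_new / rowSums(A_new)
  }
  out
}

#' Fit the copy-number HMM by MAP expectation-maximization
#'
#' Alternates the forward-backward E-step with [map_m_step()] until the
#' complete-data log posterior `F = log p(l | theta) + log p(theta)` changes
#' by less than 0.1% in relative terms (with an absolute floor `tol`), or
#' `max_iter` iterations. Each chromosome is an independent chain sharing
#' the same parameters (the stationary adjacent-bin transition model does
#' not extend across chromosome boundaries, so arm- and chromosome-scale
#' events pay an initial-distribution entry rather than two transition
#' penalties). Only valid autosomal bins enter the chains; chrX is excluded
#' by default because without allelic information its copy state is
#' confounded with sex. Chromosome 19 stays in its chain (and is decoded)
#' but is weighted out of the M-step sums, as its residual coverage bias
#' otherwise perturbs parameter estimation.
#'
#' @param lr Log-ratio track from [log2_ratio()]/[normalize_track()].
#' @param n0 Initial normal fraction.
#' @param phi0 Initial tumor ploidy.
#' @param hyper Hyperparameters; defaults to [default_hyperparams()] on the
#'   analysis bins.
#' @param states State space tibble.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute floor of the convergence test.
#' @param rtol Relative convergence threshold. The default 1e-4 is tighter
#'   than the 0.1% headline rule because at ~3,000 bins the objective is in
#'   the thousands and a 0.1% relative change still allows the global
#'   parameters to drift; both knobs are exposed.
#' @param s0 Initial subclone-absent fraction.
#' @param exclude_chr19 Weight chr19 out of parameter estimation.
#' @param include_chrX Include chrX bins in the analysis chain.
#' @param estimate_transitions Passed to [map_m_step()].
#' @return An object of class `ulp_em`: converged parameters, final
#'   objective `F`, per-bin posteriors `gamma`, the objective trace, the
#'   analysis bins, and the initialization.
#' @export
run_em <- function(lr, n0, phi0, hyper = NULL, states = default_state_space(),
                   max_iter = 50, tol = 1e-3, rtol = 1e-4, s0 = 0.5,
                   exclude_chr19 = TRUE, include_chrX = FALSE,
                   estimate_transitions = FALSE) {
  assert_columns(lr, c("chrom", "start", "end", "bin", "valid", "l"), "lr")
  keep <- lr$valid & is.finite(lr$l) &
    (is_autosome(lr$chrom) | (include_chrX & is_chrx(lr$chrom)))
  dat <- lr[keep, , drop = FALSE]
  T_len <- nrow(dat)
  if (T_len < 100) abort(sprintf("only %d analysis bins; at least 100 are required", T_len))

  hyper <- hyper %||% default_hyperparams(dat$l, states)
  K <- nrow(states)
  w <- as.numeric(!(exclude_chr19 & chrom_base(dat$chrom) == "19"))

  params <- list(
    n = n0, s = if (any(states$subclonal)) s0 else 0, phi = phi0,
    lambda = rep(hyper$alpha_g * hyper$beta_g, K),  # prior mean
    pi = rep(1 / K, K),
    A = transition_matrix(K, hyper$e)
  )

  chains <- chain_indices(dat$chrom)
  starts <- purrr::map_int(chains, 1L)

  trace <- numeric(0)
  fb <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- state_means(params$n, params$s, params$phi, states)
    logE <- emission_logdensity(dat$l, mu, params$lambda, hyper$nu)
    fb <- fb_chains(logE, params$A, params$pi, chains)
    F_it <- fb$loglik + log_prior(params, hyper, states)
    if (!is.finite(F_it)) abort("non-finite EM objective; data or parameters are degenerate")
    trace <- c(trace, F_it)
    if (it > 1) {
      delta <- F_it - trace[it - 1]
      if (delta < max(tol, rtol * abs(F_it))) {
        converged <- TRUE
        break
      }
    }
    params <- map_m_step(fb$gamma, dat$l, w, states, hyper, params,
                         xi = fb$xi, estimate_transitions = estimate_transitions,
                         chain_starts = starts)
  }

  structure(list(
    params = params,
    chains = chains,
    F = trace[length(trace)],
    gamma = fb$gamma,
    loglik = fb$loglik,
    loglik_trace = trace,
    iterations = length(trace),
    converged = converged,
    init = c(n0 = n0, phi0 = phi0),
    hyper = hyper,
    states = states,
    data = dat,
    weights = w
  ), class = "ulp_em")
}

#' Multi-restart EM over an initialization grid
#'
#' EM is restarted from every pair of the normal-fraction grid
#' `n0 {0.35, 0.45, 0.50, 0.65, 0.75, 0.85, 0.95}` and ploidy grid
#' `phi0 {2, 3, 4}` (21 runs) to escape local optima; restrict
#' `phi0_grid = 2` for near-diploid protocols. Individual failures are
#' logged and skipped; if every restart fails an error is raised. EM itself
#' is deterministic given the data and an initialization, so the set of
#' results does not depend on run order.
#'
#' @inheritParams run_em
#' @param n0_grid,phi0_grid Initialization grids.
#' @param ... Passed on to [run_em()].
#' @return List of `ulp_em` fits, one per surviving initialization.
#' @export
run_restarts <- function(lr, hyper = NULL, states = default_state_space(),
                         n0_grid = c(0.35, 0.45, 0.50, 0.65, 0.75, 0.85, 0.95),
                         phi0_grid = c(2, 3, 4), ...) {
  grid <- tidyr::expand_grid(n0 = n0_grid, phi0 = phi0_grid)
  fits <- purrr::pmap(grid, function(n0, phi0) {
    tryCatch(
      run_em(lr, n0 = n0, phi0 = phi0, hyper = hyper, states = states, ...),
      error = function(e) {
        warn(sprintf("restart (n0=%.2f, phi0=%g) failed: %s", n0, phi0, conditionMessage(e)))
        NULL
      }
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("all EM restarts failed")
  fits
}
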