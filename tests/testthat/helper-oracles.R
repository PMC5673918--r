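# Brute-force HMM oracles by exhaustive path enumeration (tiny T, K only).

oracle_paths <- function(T_len, K) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
}

oracle_joint_logp <- function(path, logE, A, pi) {
  lp <- log(pi[path[1]]) + logE[1, path[1]]
  if (length(path) > 1) {
    for (t in 2:length(path)) {
      lp <- lp + log(A[path[t - 1], path[t]]) + logE[t, path[t]]
    }
  }
  lp
}

oracle_loglik <- function(logE, A, pi) {
  paths <- oracle_paths(nrow(logE), ncol(logE))
  lps <- apply(paths, 1, oracle_joint_logp, logE = logE, A = A, pi = pi)
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

oracle_viterbi <- function(logE, A, pi) {
  paths <- oracle_paths(nrow(logE), ncol(logE))
  lps <- apply(paths, 1, oracle_joint_logp, logE = logE, A = A, pi = pi)
  best <- max(lps)
  cand <- paths[abs(lps - best) < 1e-12, , drop = FALSE]
  # lowest-index tie-break: lexicographically smallest path
  ord <- do.call(order, as.data.frame(cand))
  as.integer(cand[ord[1], ])
}

oracle_gamma <- function(logE, A, pi) {
  paths <- oracle_paths(nrow(logE), ncol(logE))
  lps <- apply(paths, 1, oracle_joint_logp, logE = logE, A = A, pi = pi)
  w <- exp(lps - max(lps))
  w <- w / sum(w)
  g <- matrix(0, nrow(logE), ncol(logE))
  for (i in seq_along(w)) {
    for (t in seq_len(nrow(logE))) {
      g[t, paths[i, t]] <- g[t, paths[i, t]] + w[i]
    }
  }
  g
}

# random small HMM instance
random_hmm <- function(T_len, K, seed) {
  withr::with_seed(seed, {
    logE <- matrix(rnorm(T_len * K), T_len, K)
    A <- matrix(runif(K * K), K, K)
    A <- A / rowSums(A)
    pi <- runif(K)
    pi <- pi / sum(pi)
    list(logE = logE, A = A, pi = pi)
  })
}

# small synthetic genome shared by several tests (kept tiny for speed)
tiny_genome <- function(seed = 7, n_chrom = 6, len = 60e6) {
  sizes <- setNames(rep(len, n_chrom), paste0("chr", seq_len(n_chrom)))
  sim_genome(chrom_sizes = sizes, seed = seed)
}

# construct a ulp_em-shaped object whose Viterbi path is forced by placing
# each bin's log ratio exactly at its intended state mean with a huge
# precision
fake_em <- function(state_idx, chrom, states = default_state_space(),
                    n = 0.5, s = 0.3, phi = 2) {
  mu <- state_means(n, s, phi, states)
  T_len <- length(state_idx)
  l <- mu[state_idx]
  K <- nrow(states)
  dat <- tibble::tibble(
    chrom = chrom,
    start = stats::ave(seq_len(T_len), chrom, FUN = seq_along) * 1e6 - 1e6,
    end = stats::ave(seq_len(T_len), chrom, FUN = seq_along) * 1e6,
    bin = seq_len(T_len), valid = TRUE, l = l
  )
  hyper <- list(alpha_n = 1, beta_n = 1, alpha_s = 1, beta_s = 1,
                alpha_phi = 1, beta_phi = Inf, alpha_g = 3, beta_g = 10,
                delta_pi = rep(1, K), delta_A = 1, e = 0.99999, nu = 2.1)
  structure(list(
    params = list(n = n, s = s, phi = phi, lambda = rep(1e8, K),
                  pi = rep(1 / K, K), A = transition_matrix(K, 0.99999)),
    chains = ulpcna:::chain_indices(dat$chrom),
    F = 0, loglik = 0, gamma = NULL, loglik_trace = 0, iterations = 1,
    converged = TRUE, init = c(n0 = n, phi0 = phi), hyper = hyper,
    states = states, data = dat, weights = rep(1, T_len)
  ), class = "ulp_em")
}
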