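test_that("the state space matches the copy-number model", {
  clonal <- default_state_space(include_subclonal = FALSE)
  expect_equal(clonal$copies, 1:5)
  expect_equal(clonal$state, c("HETD", "NEUT", "GAIN", "AMP", "HLAMP"))

  full <- default_state_space()
  expect_equal(nrow(full), 7)
  expect_equal(full$copies[full$subclonal], c(1L, 3L))
  expect_equal(full$state[full$subclonal], c("HETD_sc", "GAIN_sc"))
})

test_that("state means obey the admixture closed forms", {
  st <- default_state_space()
  expect_equal(state_means(1, 0, 2, st), rep(0, 7))           # pure normal
  st5 <- default_state_space(include_subclonal = FALSE)
  mu <- state_means(0.3, 0, 3, st5)
  expect_equal(mu[st5$copies == 3], 0)                        # c = phi
  expect_equal(state_means(0.5, 0, 2, st5)[3], log2(1.25), tolerance = 1e-12)

  # strictly increasing in c for clonal states
  mu2 <- state_means(0.4, 0, 2.3, st5)
  expect_true(all(diff(mu2) > 0))
  # subclonal mean lies between neutral and its clonal counterpart
  mu3 <- state_means(0.4, 0.6, 2, st)
  expect_true(mu3[st$state == "GAIN_sc"] > 0 &&
                mu3[st$state == "GAIN_sc"] < mu3[st$state == "GAIN"])

  expect_error(state_means(-0.1, 0, 2, st), "\\[0, 1\\]")
  expect_error(state_means(0.5, 0, -1, st), "positive")
})

test_that("Student's-t emissions match closed forms and the dt() oracle", {
  l <- seq(-2, 2, length.out = 101)
  nu <- 2.1; lambda <- c(4, 25); mu <- c(-0.3, 0.2)
  M <- emission_logdensity(l, mu, lambda, nu)

  # mode height
  h <- exp(emission_logdensity(mu[1], mu[1], lambda[1], nu)[1, 1])
  expect_equal(h, gamma((nu + 1) / 2) / gamma(nu / 2) * sqrt(lambda[1] / (pi * nu)),
               tolerance = 1e-12)
  # symmetry
  expect_equal(emission_logdensity(mu[2] + 0.37, mu[2], lambda[2], nu)[1, 1],
               emission_logdensity(mu[2] - 0.37, mu[2], lambda[2], nu)[1, 1])
  # agreement with the scaled stats::dt density
  expect_equal(M[, 2],
               dt((l - mu[2]) * sqrt(lambda[2]), df = nu, log = TRUE) +
                 0.5 * log(lambda[2]),
               tolerance = 1e-12)
  # integrates to 1 (heavy nu = 2.1 tails carry ~3e-5 beyond +/-50)
  int <- integrate(function(x) exp(emission_logdensity(x, 0.1, 9, nu)[, 1]),
                   -Inf, Inf, rel.tol = 1e-9)$value
  expect_equal(int, 1, tolerance = 1e-6)

  expect_error(emission_logdensity(l, mu, c(-1, 1), nu), "positive")
})

test_that("transition matrix has the printed structure", {
  A <- transition_matrix(7, 0.99999)
  expect_equal(diag(A), rep(0.99999, 7))
  expect_equal(A[1, 2], 1e-5 / 6, tolerance = 1e-9)
  expect_equal(rowSums(A), rep(1, 7))

  expect_equal(transition_matrix(2, 0.5), matrix(0.5, 2, 2))
  for (K in 2:5) for (e in c(0.2, 0.9, 0.99999)) {
    expect_equal(rowSums(transition_matrix(K, e)), rep(1, K))
  }
  expect_error(transition_matrix(1, 0.9), "at least 2")
})

test_that("default hyperparameters follow the printed precision prior", {
  st <- default_state_space()
  l <- withr::with_seed(1, rnorm(500, 0, 0.1))
  hy <- default_hyperparams(l, st)
  expect_equal(hy$alpha_g, 3)
  expect_equal(hy$beta_g, sqrt(7) / sd(l))
  expect_equal(hy$beta_g, (sd(l) / sqrt(7))^-1, tolerance = 1e-12)
  expect_equal(hy$nu, 2.1)
  expect_equal(hy$e, 0.99999)
  expect_error(default_hyperparams(rep(0.5, 10), st), "zero variance")
  expect_error(default_hyperparams(0.5, st), "at least 2")
})

test_that("forward-backward equals exhaustive enumeration on small chains", {
  # single-step posterior is proportional to pi * emission
  one <- random_hmm(1, 3, seed = 11)
  fb1 <- forward_backward(one$logE, one$A, one$pi)
  post <- one$pi * exp(one$logE[1, ])
  expect_equal(as.numeric(fb1$gamma), post / sum(post), tolerance = 1e-12)

  for (seed in 1:6) {
    T_len <- sample(2:8, 1)
    K <- sample(2:3, 1)
    h <- random_hmm(T_len, K, seed = seed * 37)
    fb <- forward_backward(h$logE, h$A, h$pi)
    expect_equal(fb$loglik, oracle_loglik(h$logE, h$A, h$pi), tolerance = 1e-10)
    expect_equal(fb$gamma, oracle_gamma(h$logE, h$A, h$pi), tolerance = 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, T_len), tolerance = 1e-12)
  }

  # identical emissions and uniform pi: uniform posteriors
  flat <- list(logE = matrix(0, 5, 3), A = transition_matrix(3, 0.9),
               pi = rep(1 / 3, 3))
  fbf <- forward_backward(flat$logE, flat$A, flat$pi)
  expect_equal(fbf$gamma, matrix(1 / 3, 5, 3), tolerance = 1e-12)

  bad <- flat$logE; bad[3, ] <- -Inf
  expect_error(forward_backward(bad, flat$A, flat$pi), "finite")
})

test_that("scaling emissions shifts the log-likelihood but not posteriors or paths", {
  h <- random_hmm(6, 3, seed = 99)
  fb <- forward_backward(h$logE, h$A, h$pi)
  fb2 <- forward_backward(h$logE + 7.3, h$A, h$pi)
  expect_equal(fb$gamma, fb2$gamma, tolerance = 1e-12)
  expect_equal(fb2$loglik - fb$loglik, 6 * 7.3, tolerance = 1e-9)
  expect_equal(viterbi(h$logE, h$A, h$pi), viterbi(h$logE + 7.3, h$A, h$pi))
})

test_that("Viterbi equals the exhaustive argmax with low-index tie-breaking", {
  for (seed in 1:6) {
    T_len <- sample(2:8, 1)
    K <- sample(2:3, 1)
    h <- random_hmm(T_len, K, seed = seed * 101)
    expect_equal(viterbi(h$logE, h$A, h$pi), oracle_viterbi(h$logE, h$A, h$pi))
  }

  # near-uniform transitions: path is the per-bin argmax
  h2 <- random_hmm(6, 3, seed = 5)
  A_unif <- matrix(1 / 3, 3, 3)
  expect_equal(viterbi(h2$logE, A_unif, rep(1 / 3, 3)),
               apply(h2$logE, 1, which.max))

  # e -> 1 limit: constant path at the globally best state
  logE <- withr::with_seed(2, matrix(rnorm(30), 10, 3))
  path <- viterbi(logE, transition_matrix(3, 1 - 1e-12), rep(1 / 3, 3))
  expect_equal(path, rep(which.max(colSums(logE)), 10))

  # exact ties resolve to the lowest state index
  tie <- matrix(0, 4, 3)
  expect_equal(viterbi(tie, transition_matrix(3, 0.9), rep(1 / 3, 3)), rep(1L, 4))
})
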