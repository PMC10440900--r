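test_that("component and mixture log-likelihoods match hand arithmetic", {
  expect_equal(component_loglik(c(0.5, 0.5), c(1, 0)), log(0.25))
  expect_equal(component_loglik(c(1, 0), c(1, 0)), 0)
  expect_equal(component_loglik(c(0.9, 0.2), c(1, 1)), log(0.18))
  expect_equal(component_loglik(c(0, 1), c(1, 0)), -Inf)

  X <- matrix(c(1, 0, 1), 3, 1)
  p1 <- list(tau = 1, theta = rbind(0.3))
  expect_equal(mixture_loglik(p1, X),
               sum(vapply(X[, 1], function(x) component_loglik(0.3, x), 0)))
  # degenerate mixture = single component
  p2 <- list(tau = c(1, 0), theta = rbind(0.3, 0.9))
  expect_equal(mixture_loglik(p2, X), mixture_loglik(p1, X))
  # G=2, M=1, x=1: log(0.5*0.2 + 0.5*0.8) = log 0.5
  p3 <- list(tau = c(0.5, 0.5), theta = rbind(0.2, 0.8))
  expect_equal(mixture_loglik(p3, matrix(1, 1, 1)), log(0.5))
})

test_that("membership posteriors are Bayes-correct and normalized", {
  p3 <- list(tau = c(0.5, 0.5), theta = rbind(0.2, 0.8))
  expect_equal(unname(posterior_z(p3, matrix(1, 1, 1))[1, ]), c(0.2, 0.8))
  # identical components: posterior equals tau for every row
  p4 <- list(tau = c(0.3, 0.7), theta = rbind(c(0.4, 0.6), c(0.4, 0.6)))
  Z <- posterior_z(p4, matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(unname(Z), rbind(c(0.3, 0.7), c(0.3, 0.7)))
  # row normalization at tight tolerance for random parameters
  withr::with_seed(31, {
    X <- matrix(rbinom(200, 1, 0.5), 50, 4)
    pr <- list(tau = c(0.2, 0.5, 0.3), theta = matrix(runif(12), 3, 4))
    expect_equal(rowSums(posterior_z(pr, X)), rep(1, 50), tolerance = 1e-12)
  })
})

test_that("EM reduces to column means at G=1 and to weighted means in the M-step", {
  withr::with_seed(2, X <- matrix(rbinom(90, 1, 0.4), 30, 3))
  f <- blca_em(X, 1, run = run_config(seed = 1, n_restarts = 1))
  expect_equal(unname(f$params$theta[1, ]), unname(colMeans(X)))
  expect_equal(f$params$tau, 1)

  # M-step with flat priors = responsibility-weighted column means
  withr::with_seed(3, {
    Z <- matrix(runif(60), 30, 2); Z <- Z / rowSums(Z)
    pri <- nbblca:::expand_priors(prior_config(), 2, 3)
    up <- nbblca:::blca_m_step(X, Z, pri)
    oracle <- t(sapply(1:2, function(g)
      colSums(X * Z[, g]) / sum(Z[, g])))
    expect_equal(unname(up$theta), unname(oracle), tolerance = 1e-10)
    expect_equal(up$tau, colSums(Z) / 30)
  })
})

test_that("EM objective is monotone and recovers a separable mixture", {
  d <- make_toy("sep2")
  fit <- blca_em(d$X, 2, run = run_config(seed = 11, n_restarts = 5))
  expect_true(all(diff(fit$trace) >= -1e-10 * (abs(fit$trace[-1]) + 1)))
  truth <- attr(d, "truth")
  est <- perm_align(fit$params$theta, truth$theta)
  # per-item MC error at n = 200 is ~0.03, so the max over 20 estimates sits
  # near 2 sd even for a perfect fit; 0.10 = ~3.3 sd. The tight +-0.05 bound
  # is asserted at n = 5000 in the recovery acceptance test.
  expect_lt(max(abs(est - truth$theta)), 0.10)
  expect_lt(mean(abs(est - truth$theta)), 0.05)
  # hard memberships agree with the generating memberships >= 95%
  hard <- max.col(fit$z)
  agree <- max(mean(hard == truth$membership), mean(3 - hard == truth$membership))
  expect_gte(agree, 0.95)
  expect_error(blca_em(d$X, 2, priors = prior_config(alpha = 0.5)), "alpha")
  expect_error(blca_em(d$X[1:3, ], 5), "more latent classes")
})

test_that("EM reaches the brute-force grid maximum on a small instance", {
  withr::with_seed(17, x <- rbinom(20, 1, 0.5))
  X <- matrix(x, 20, 1)
  s <- sum(x); n <- length(x)
  grid <- seq(0.01, 0.99, by = 0.01)
  # exhaustive log-likelihood over (tau, theta1, theta2), flat priors
  best <- -Inf; best_par <- NULL
  for (tau in grid) for (t1 in grid) for (t2 in grid) {
    ll <- sum(log(tau * t1^x * (1 - t1)^(1 - x) +
                    (1 - tau) * t2^x * (1 - t2)^(1 - x)))
    if (ll > best) { best <- ll; best_par <- c(tau, t1, t2) }
  }
  fit <- blca_em(X, 2, run = run_config(seed = 23, n_restarts = 8))
  expect_gte(fit$logpost, best - 1e-6)
})

test_that("Gibbs sampling reproduces its conjugate posteriors", {
  # N = 0: theta draws are prior draws
  pri <- prior_config(alpha = 2, beta = 5)
  ch0 <- blca_gibbs(matrix(0L, 0, 1), 1, priors = pri,
                    run = run_config(seed = 5, gibbs_iters = 4000,
                                     burn_in = 0, thin = 1))
  expect_equal(mean(ch0$theta[, 1, 1]), 2 / 7, tolerance = 0.02)

  # G = 1: memberships fixed, theta ~ Beta(sum x + a, n - sum x + b) exactly
  withr::with_seed(6, x <- rbinom(30, 1, 0.3))
  ch1 <- blca_gibbs(matrix(x, 30, 1), 1,
                    run = run_config(seed = 7, gibbs_iters = 10500,
                                     burn_in = 500, thin = 1))
  draws <- ch1$theta[, 1, 1]
  a <- sum(x) + 1; b <- 30 - sum(x) + 1
  expect_equal(mean(draws), a / (a + b), tolerance = 0.01)
  ks <- suppressWarnings(stats::ks.test(draws, stats::pbeta, a, b))
  expect_gt(ks$p.value, 0.01)

  # well-separated two-component data: posterior mean near the truth
  d <- make_toy("sep2")
  ch2 <- blca_gibbs(d$X, 2, run = run_config(seed = 8, gibbs_iters = 1500,
                                             burn_in = 500, thin = 2))
  pm <- chain_posterior_mean(ch2)
  truth <- attr(d, "truth")
  # same finite-sample allowance as the EM recovery check at n = 200
  expect_lt(max(abs(perm_align(pm$theta, truth$theta) - truth$theta)), 0.10)
  expect_equal(rowSums(ch2$tau), rep(1, nrow(ch2$tau)), tolerance = 1e-12)
  expect_equal(nrow(ch2$tau), (1500 - 500) %/% 2)
})

test_that("relabeling removes constructed label switches and is idempotent", {
  # build a clean chain around two distinct components, then swap half the draws
  withr::with_seed(13, {
    n_draw <- 100
    theta <- array(NA_real_, c(n_draw, 2, 3))
    tau <- matrix(NA_real_, n_draw, 2)
    for (d in seq_len(n_draw)) {
      theta[d, 1, ] <- pmin(pmax(0.85 + rnorm(3, 0, 0.02), 0), 1)
      theta[d, 2, ] <- pmin(pmax(0.15 + rnorm(3, 0, 0.02), 0), 1)
      tau[d, ] <- c(0.6, 0.4) + c(1, -1) * rnorm(1, 0, 0.01)
    }
    z <- matrix(sample(1:2, n_draw * 5, TRUE), n_draw, 5)
    swapped <- sample(n_draw, n_draw / 2)
    theta[swapped, , ] <- theta[swapped, 2:1, ]
    tau[swapped, ] <- tau[swapped, 2:1]
    z[swapped, ] <- 3L - z[swapped, ]
    chain <- structure(list(tau = tau, theta = theta, z = z,
                            iters = seq_len(n_draw), burn_in = 0, thin = 1,
                            perms = matrix(rep(1:2, each = n_draw), n_draw, 2)),
                       class = "blca_chain")
    fixed <- relabel_chain(chain)
    # swap discontinuities gone: per-component trace variance collapses
    expect_lt(sd(fixed$theta[, 1, 1]), 0.05)
    expect_gt(sd(chain$theta[, 1, 1]), 0.2)
    # idempotent
    again <- relabel_chain(fixed)
    expect_equal(again$theta, fixed$theta)
    expect_equal(again$z, fixed$z)
  })
})

test_that("chain diagnostics flag autocorrelation and survive degeneracy", {
  withr::with_seed(19, {
    n_draw <- 400
    tau <- cbind(runif(n_draw, 0.4, 0.6))
    tau <- cbind(tau, 1 - tau)
    theta <- array(runif(n_draw * 2), c(n_draw, 2, 1))
    chain <- structure(list(tau = tau, theta = theta,
                            z = matrix(1L, n_draw, 0), iters = seq_len(n_draw),
                            burn_in = 0, thin = 1,
                            perms = matrix(rep(1:2, each = n_draw), n_draw, 2)),
                       class = "blca_chain")
    di <- chain_diagnostics(chain)
    expect_true(all(abs(di$rhat - 1) < 0.05, na.rm = TRUE))
    expect_false(any(di$flagged))

    # duplicated draws: strong autocorrelation, ESS far below retained count
    dup <- chain
    dup$tau <- tau[rep(seq_len(200), each = 2), ]
    dup$theta <- theta[rep(seq_len(200), each = 2), , , drop = FALSE]
    d2 <- chain_diagnostics(dup)
    expect_lt(min(d2$ess), n_draw / 2)

    # constant chain: degenerate, no crash
    con <- chain
    con$tau[] <- 0.5
    con$theta[] <- 0.25
    d3 <- chain_diagnostics(con)
    expect_true(all(d3$degenerate))
    expect_false(any(d3$flagged))
  })
  expect_error(chain_diagnostics(structure(list(
    tau = matrix(0.5, 2, 1), theta = array(0.5, c(2, 1, 1)),
    z = matrix(1L, 2, 1)), class = "blca_chain")), "too short")
})
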