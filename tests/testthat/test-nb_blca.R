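test_that("class posterior given latents follows Bayes' rule over the latent layer", {
  m <- random_nbblca_model(list(1:2), levels = 2, seed = 41)
  # uninformative latent: posterior = prior
  m1 <- m
  m1$q_lc[[1]][, 1] <- m1$q_lc[[1]][, 2] <- c(0.4, 0.6)
  expect_equal(unname(class_posterior_given_latents(m1, 1)), unname(m1$q_c))
  # hand case: q = (0.5, 0.5), q1(l=1|c1) = 0.9, q1(l=1|c2) = 0.1
  m2 <- m
  m2$q_c[] <- c(0.5, 0.5)
  m2$q_lc[[1]] <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  expect_equal(unname(class_posterior_given_latents(m2, 1)), c(0.9, 0.1))
  # normalization for random models
  m3 <- random_nbblca_model(list(1:2, 3:4), levels = c(2, 3), seed = 42)
  expect_equal(sum(class_posterior_given_latents(m3, c(2, 3))), 1)
  expect_error(class_posterior_given_latents(m3, c(2, 9)), "invalid")
})

test_that("marginalized prediction equals exhaustive latent enumeration", {
  cases <- list(list(blocks = list(1:3), levels = 2, seed = 51),
                list(blocks = list(1:2, 3:5), levels = c(2, 3), seed = 52),
                list(blocks = list(1:2, 3:4, 5:6), levels = c(3, 2, 3), seed = 53))
  for (cs in cases) {
    m <- random_nbblca_model(cs$blocks, cs$levels, seed = cs$seed)
    M <- length(unlist(cs$blocks))
    withr::with_seed(cs$seed + 100, X <- matrix(rbinom(5 * M, 1, 0.5), 5, M))
    p <- nbblca_predict_proba(m, X)
    for (i in 1:5)
      expect_equal(unname(p[i, ]), unname(oracle_nbblca_posterior(m, X[i, ])),
                   tolerance = 1e-10)
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  }
})

test_that("degenerate structures collapse to the expected simpler models", {
  # identical theta rows: the latent carries no attribute information, so
  # marginalized prediction is exactly the class prior, and hard-assignment
  # prediction no longer depends on the input (the tied level is fixed)
  m <- random_nbblca_model(list(1:3), levels = 2, seed = 61)
  m$theta[[1]][2, ] <- m$theta[[1]][1, ]
  X <- rbind(c(1, 0, 1), c(0, 0, 0))
  p <- nbblca_predict_proba(m, X, mode = "marginalize")
  expect_equal(unname(p[1, ]), unname(m$q_c), tolerance = 1e-10)
  expect_equal(unname(p[2, ]), unname(m$q_c), tolerance = 1e-10)
  ph <- nbblca_predict_proba(m, X, mode = "hard")
  expect_equal(ph[1, ], ph[2, ], tolerance = 1e-12)

  # one latent per attribute with identity-degenerate theta == ordinary NB
  d <- random_dataset(60, 3, seed = 62)
  nb <- nb_fit(d, smoothing = 0)
  layout <- latent_layout(list(1, 2, 3), levels = 2)
  q_lc <- lapply(1:3, function(k)
    rbind(nb$cond_prob[, k], 1 - nb$cond_prob[, k]))
  theta <- lapply(1:3, function(k) rbind(1, 0))  # level 1 <=> x = 1
  mm <- nbblca:::nbblca_model(nb$class_prior, q_lc, theta, layout,
                              prior_config(), feature_names = d$feature_names,
                              blocks_idx = list(1L, 2L, 3L))
  expect_equal(unname(nbblca_predict_proba(mm, d$X)),
               unname(nb_predict_proba(nb, d$X)), tolerance = 1e-10)

  # G_k = 1 everywhere: prediction is the class prior for any input
  fit1 <- nbblca_fit_em(d, latent_layout(3, levels = 1),
                        run = run_config(seed = 1, n_restarts = 1))
  p1 <- nbblca_predict_proba(fit1$model, d$X)
  expect_equal(unname(p1[1, ]), unname(fit1$model$q_c), tolerance = 1e-10)
})

test_that("supervised EM is monotone and recovers a known generative model", {
  truth <- recovery_truth()
  withr::with_seed(71, d <- sample_from_model(truth, n = 2000))
  fit <- nbblca_fit_em(d, latent_layout(10, 2),
                       run = run_config(seed = 72, n_restarts = 4))
  expect_true(all(diff(fit$trace) >= -1e-10 * (abs(fit$trace[-1]) + 1)))
  est_th <- perm_align(fit$model$theta[[1]], truth$theta[[1]])
  expect_lt(max(abs(est_th - truth$theta[[1]])), 0.05)
  est_q <- perm_align(fit$model$q_lc[[1]], truth$q_lc[[1]])
  expect_lt(max(abs(est_q - truth$q_lc[[1]])), 0.05)
  expect_equal(unname(fit$model$q_c), unname(table(d$y) / 2000),
               tolerance = 1e-12, ignore_attr = TRUE)
  # normalization invariants of the fitted model
  expect_equal(sum(fit$model$q_c), 1, tolerance = 1e-12)
  expect_equal(colSums(fit$model$q_lc[[1]]), c(1, 1), tolerance = 1e-12)

  # two-stage variant runs and is class-calibrated too
  fit2 <- nbblca_fit_em(d, latent_layout(10, 2), two_stage = TRUE,
                        run = run_config(seed = 73, n_restarts = 2))
  est2 <- perm_align(fit2$model$theta[[1]], truth$theta[[1]])
  expect_lt(max(abs(est2 - truth$theta[[1]])), 0.05)
})

test_that("Gibbs conditionals match conjugate closed forms and recover truth", {
  truth <- recovery_truth()
  withr::with_seed(81, d <- sample_from_model(truth, n = 1500))
  # K = 1, G = 1: latent assignment is fixed, so the q_c draws are exact
  # Dirichlet(class counts + 1) and theta draws exact Beta posteriors
  f1 <- nbblca_fit_gibbs(d, latent_layout(10, 1),
                         run = run_config(seed = 82, gibbs_iters = 3000,
                                          burn_in = 0, thin = 1))
  nc <- as.numeric(table(d$y))
  expect_equal(unname(colMeans(f1$chain$q_c)),
               (nc + 1) / sum(nc + 1), tolerance = 0.01)
  s1 <- colSums(d$X)
  expect_equal(as.numeric(apply(f1$chain$theta[[1]], c(2, 3), mean)),
               as.numeric((s1 + 1) / (nrow(d$X) + 2)), tolerance = 0.01)

  # recovery with the posterior-mean model
  f2 <- nbblca_fit_gibbs(d, latent_layout(10, 2),
                         run = run_config(seed = 83, gibbs_iters = 1200,
                                          burn_in = 400, thin = 2))
  est_th <- perm_align(f2$model$theta[[1]], truth$theta[[1]])
  expect_lt(max(abs(est_th - truth$theta[[1]])), 0.05)
  est_q <- perm_align(f2$model$q_lc[[1]], truth$q_lc[[1]])
  expect_lt(max(abs(est_q - truth$q_lc[[1]])), 0.05)

  # two chains from different seeds agree (split-Rhat on the block chain)
  f3 <- nbblca_fit_gibbs(d, latent_layout(10, 2),
                         run = run_config(seed = 84, gibbs_iters = 1200,
                                          burn_in = 400, thin = 2))
  expect_lt(max(abs(f2$model$q_lc[[1]] - perm_align(f3$model$q_lc[[1]],
                                                    f2$model$q_lc[[1]]))), 0.05)
})

test_that("information criteria count parameters correctly", {
  d <- random_dataset(100, 3, seed = 91)
  fit <- nbblca_fit_em(d, latent_layout(3, 2),
                       run = run_config(seed = 92, n_restarts = 2))
  ic <- information_criteria(fit, d)
  # K=1, G=2, M=3, |C|=2: p = (1)(2) + (2)(3) + 1 = 9
  expect_equal(ic$p, 9)
  expect_equal(ic$AIC - ic$BIC, 9 * (2 - log(100)), tolerance = 1e-10)

  fg <- nbblca_fit_gibbs(d, latent_layout(3, 2),
                         run = run_config(seed = 93, gibbs_iters = 800,
                                          burn_in = 200, thin = 2))
  icg <- information_criteria(fg, d)
  expect_gte(icg$p_D, 0)
  expect_true(is.finite(icg$DIC))

  scan <- nbblca_scan_levels(d, levels_grid = 2:3,
                             run = run_config(seed = 94, n_restarts = 2))
  expect_equal(nrow(scan$scan), 2)
  expect_true(all(is.finite(scan$scan$BIC)))
})
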