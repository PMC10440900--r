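test_that("batch specifications are uniform, symmetric and reproducible", {
  s1 <- withr::with_seed(1, draw_batch_spec())
  s2 <- withr::with_seed(1, draw_batch_spec())
  expect_identical(s1, s2)
  expect_equal(s1$or_matrix, t(s1$or_matrix))
  expect_equal(diag(s1$or_matrix), rep(1, 5))
  withr::with_seed(2, {
    ors <- replicate(10000, draw_batch_spec(d = 2)[["or_matrix"]][1, 2])
    expect_equal(mean(ors), (0.25 + 4) / 2, tolerance = 0.03)
    expect_true(all(ors >= 0.25 & ors <= 4))
  })
})

test_that("pairwise closed form and IPF fitting honor margins and odds ratios", {
  # closed-form 2x2: margins (0.5, 0.5), OR = 4 -> (1/3, 1/6, 1/6, 1/3)
  expect_equal(unname(pairwise_cell_probs(0.5, 0.5, 4)),
               c(1, 0.5, 0.5, 1) / 3, tolerance = 1e-12)
  # independence case: (p00, p01, p10, p11) = products of the marginals
  expect_equal(unname(pairwise_cell_probs(0.3, 0.6, 1)),
               c(0.7 * 0.4, 0.7 * 0.6, 0.3 * 0.4, 0.3 * 0.6), tolerance = 1e-12)

  # independence: joint is exactly the product of marginals
  sp <- structure(list(hmp = c(0.2, 0.5, 0.7), or_matrix = matrix(1, 3, 3)),
                  class = "batch_spec")
  fit <- ipfp_fit_joint(sp)
  prod_tab <- apply(fit$configs, 1, function(x) prod(ifelse(x == 1, sp$hmp, 1 - sp$hmp)))
  expect_equal(fit$joint, prod_tab, tolerance = 1e-9)

  # random 5-D specs: marginals to 1e-10, collapsed pairwise ORs to 1e-6
  for (seed in 1:5) {
    spec <- withr::with_seed(seed, draw_batch_spec())
    f <- ipfp_fit_joint(spec, tol = 1e-12)
    expect_lt(max(abs(nbblca:::joint_marginals(f) - spec$hmp)), 1e-10)
    expect_lt(max(abs(nbblca:::joint_pairwise_or(f) - spec$or_matrix)), 1e-6)
    expect_equal(sum(f$joint), 1, tolerance = 1e-12)
    expect_true(all(f$joint >= 0))
  }
})

test_that("sampled features reproduce the fitted joint's structure", {
  spec <- withr::with_seed(9, draw_batch_spec())
  fitted <- ipfp_fit_joint(spec)
  sc <- simulation_scenario(5, 1e5, 0.5)
  X <- withr::with_seed(10, sample_features(sc, batches = list(fitted)))$X
  expect_true(all(X %in% c(0L, 1L)))
  expect_lt(max(abs(colMeans(X) - spec$hmp)), 0.01)
  # empirical within-batch pairwise ORs within 10% of targets
  for (i in 1:4) for (j in (i + 1):5) {
    tab <- table(factor(X[, i], 0:1), factor(X[, j], 0:1))
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    expect_lt(abs(or / spec$or_matrix[i, j] - 1), 0.10)
  }
  # between-batch independence: OR ~ 1
  sc10 <- simulation_scenario(10, 5e4, 0.5)
  X10 <- withr::with_seed(11, sample_features(sc10))$X
  tab <- table(X10[, 1], X10[, 8])
  expect_lt(abs(log((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))), 0.12)
})

test_that("intercept tuning hits the target class prevalence", {
  # all-mass-on-zero features and no noise: target 0.5 forces alpha ~ 0
  sc0 <- simulation_scenario(5, 100, 0.5, sigma = 1e-8)
  degenerate <- structure(list(hmp = rep(0.01, 5), or_matrix = diag(1, 5),
                               joint = c(1, rep(0, 31)),
                               configs = nbblca:::cell_configs(5)),
                          class = "batch_spec")
  a0 <- withr::with_seed(12, tune_alpha(sc0, list(degenerate), pilot_n = 2000))
  expect_lt(abs(a0), 0.05)

  # self-consistency at large n
  sc <- simulation_scenario(5, 1e5, 0.3)
  withr::with_seed(13, {
    fs <- sample_features(sc)
    alpha <- tune_alpha(sc, fs$batches, pilot_n = 20000)
    z <- alpha + sc$beta * rowSums(fs$X) + rnorm(sc$n, 0, sc$sigma)
    y <- rbinom(sc$n, 1, plogis(-z))
  })
  expect_lt(abs(mean(y) - 0.3), 0.01)
})

test_that("generated replicates have the declared shape and prevalence", {
  sc <- simulation_scenario(5, 2000, 0.7)
  prevs <- withr::with_seed(14, replicate(30, {
    d <- generate_dataset(sc, pilot_n = 10000)
    stopifnot(dim(d$X) == c(2000, 5), all(d$X %in% 0:1),
              all(d$y %in% c("0", "1")))
    mean(d$y == "1")
  }))
  expect_lt(abs(mean(prevs) - 0.7), 0.02)
})

test_that("study runner scores stub models at their analytic levels", {
  sc <- simulation_scenario(5, 200, 0.5)
  res <- run_study(sc, models = list(oracle = model_registry("oracle"),
                                     prior = model_registry("prior")),
                   reps = 40, seed = 3, pilot_n = 4000)
  orc <- subset(res, model == "oracle")
  expect_true(all(orc$mean[orc$metric %in%
                             c("sensitivity", "specificity", "accuracy")] == 100))
  pri <- subset(res, model == "prior")
  # majority-class stub: per-replicate sensitivity is 0 or 100, mean ~ 50
  expect_lt(abs(pri$mean[pri$metric == "sensitivity"] - 50), 20)
  expect_lt(abs(pri$mean[pri$metric == "specificity"] - 50), 20)
  # determinism from the master seed
  res2 <- run_study(sc, models = list(oracle = model_registry("oracle")),
                    reps = 3, seed = 77, pilot_n = 4000)
  res3 <- run_study(sc, models = list(oracle = model_registry("oracle")),
                    reps = 3, seed = 77, pilot_n = 4000)
  expect_identical(res2, res3)
})

test_that("naive Bayes test sensitivity rises with the feature count", {
  # soft monotonicity across the feature grid (moderate replicates)
  means <- sapply(c(5, 10, 20), function(p) {
    res <- run_study(simulation_scenario(p, 500, 0.5), models = "nb",
                     reps = 30, seed = 5, pilot_n = 5000)
    res$mean[res$metric == "sensitivity"]
  })
  expect_gt(means[2], means[1] - 3)
  expect_gt(means[3], means[2] - 3)
})
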