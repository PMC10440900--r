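# Independent oracles and small utilities shared across the test files.
# These deliberately use direct loops / enumeration, never the package's own
# vectorized code paths.

# small random binary dataset with two classes
random_dataset <- function(n, m, seed, p = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * m, 1, p), n, m)
    y <- sample(c("a", "b"), n, replace = TRUE)
    # make sure both classes appear
    y[1] <- "a"; y[2] <- "b"
    binary_dataset(X, y = y)
  })
}

# naive Bayes posterior by direct counting and looping (smoothed the same way)
oracle_nb_posterior <- function(train, x, smoothing = 1) {
  classes <- train$class_labels
  post <- numeric(length(classes))
  n <- nrow(train$X)
  for (ci in seq_along(classes)) {
    rows <- train$y == classes[ci]
    prior <- (sum(rows) + smoothing) / (n + smoothing * length(classes))
    lik <- 1
    for (m in seq_along(x)) {
      p1 <- (sum(train$X[rows, m]) + smoothing) / (sum(rows) + 2 * smoothing)
      lik <- lik * if (x[m] == 1) p1 else 1 - p1
    }
    post[ci] <- prior * lik
  }
  post / sum(post)
}

# NB-BLCA class posterior by exhaustive enumeration over latent profiles
oracle_nbblca_posterior <- function(model, x) {
  classes <- names(model$q_c)
  K <- model$layout$K
  profiles <- expand.grid(lapply(model$layout$levels, seq_len))
  post <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    total <- 0
    for (r in seq_len(nrow(profiles))) {
      term <- model$q_c[ci]
      for (k in seq_len(K)) {
        l <- profiles[r, k]
        term <- term * model$q_lc[[k]][l, ci]
        th <- model$theta[[k]][l, ]
        xb <- x[model$blocks_idx[[k]]]
        term <- term * prod(th^xb * (1 - th)^(1 - xb))
      }
      total <- total + term
    }
    post[ci] <- total
  }
  post / sum(post)
}

# best permutation of rows of `est` against `truth` (squared error), applied
perm_align <- function(est, truth) {
  G <- nrow(truth)
  perms <- nbblca:::all_perms(G)
  costs <- vapply(perms, function(p) sum((est[p, , drop = FALSE] - truth)^2),
                  numeric(1))
  est[perms[[which.min(costs)]], , drop = FALSE]
}

# a random valid NB-BLCA model for enumeration tests
random_nbblca_model <- function(blocks, levels, classes = c("a", "b"), seed = 1) {
  withr::with_seed(seed, {
    M <- length(unlist(blocks))
    layout <- latent_layout(blocks, levels)
    q_c <- runif(length(classes), 0.2, 0.8)
    q_c <- setNames(q_c / sum(q_c), classes)
    q_lc <- lapply(seq_along(blocks), function(k) {
      m <- matrix(runif(layout$levels[k] * length(classes), 0.1, 0.9),
                  layout$levels[k], length(classes))
      sweep(m, 2, colSums(m), "/")
    })
    theta <- lapply(seq_along(blocks), function(k)
      matrix(runif(layout$levels[k] * length(blocks[[k]]), 0.05, 0.95),
             layout$levels[k], length(blocks[[k]])))
    nbblca:::nbblca_model(q_c, q_lc, theta, layout, prior_config(),
                          feature_names = paste0("f", seq_len(M)),
                          blocks_idx = lapply(blocks, as.integer))
  })
}

# the K=1 G=2 M=10 generative truth used by the recovery experiments
recovery_truth <- function() {
  q_lc <- list(matrix(c(0.85, 0.15, 0.2, 0.8), 2, 2))
  theta <- list(rbind(rep(0.9, 10), rep(0.1, 10)))
  nbblca:::nbblca_model(c(a = 0.45, b = 0.55), q_lc, theta,
                        latent_layout(10, 2), prior_config(),
                        feature_names = paste0("f", 1:10),
                        blocks_idx = list(1:10))
}
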