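#' Latent layout of an NB-BLCA model
#'
#' The combined classifier places K latent class variables between the
#' observed class C and the attributes: C parents each latent variable
#' \eqn{L_k}, and each latent variable parents a disjoint block of
#' attributes. The layout records the partition of the attributes into
#' blocks and the number of latent levels per block.
#'
#' @param blocks list of K character (feature-name) or integer vectors that
#'   partition the attribute set; or a single integer M as shorthand for one
#'   block covering attributes \code{1:M} (the default structure).
#' @param levels integer vector of latent level counts \eqn{G_k} (recycled);
#'   2 or more is the useful regime, 1 collapses block k to pure noise.
#' @return Object of class \code{"latent_layout"}.
#' @examples
#' latent_layout(10, levels = 2)                     # one latent, 2 levels
#' latent_layout(list(1:3, 4:10), levels = c(2, 3))  # two blocks
#' @export
latent_layout <- function(blocks, levels = 2L) {
  if (is.numeric(blocks) && length(blocks) == 1L) blocks <- list(seq_len(blocks))
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  levels <- as.integer(rep_len(levels, length(blocks)))
  stopifnot(all(levels >= 1L))
  structure(list(blocks = blocks, levels = levels, K = length(blocks)),
            class = "latent_layout")
}

# resolve block feature references against a dataset's columns; returns
# integer index vectors and validates the partition property
resolve_layout <- function(layout, feature_names) {
  blocks <- lapply(layout$blocks, function(b) {
    if (is.character(b)) {
      idx <- match(b, feature_names)
      if (anyNA(idx)) stop("unknown feature in layout: ",
                           paste(b[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(b)
  })
  flat <- sort(unlist(blocks))
  if (!identical(flat, seq_along(feature_names)))
    stop("layout blocks must partition the attribute set exactly")
  if (any(lengths(blocks) == 0L)) stop("empty latent block")
  blocks
}

#' Class posterior given a latent profile
#'
#' The class layer of the NB-BLCA model is an ordinary naive Bayes over the
#' latent variables:
#' \eqn{P(c | L) \propto q(c) \prod_k q_k(L_k | c)}, normalized over c.
#'
#' @param model an \code{"nbblca_model"}.
#' @param latent_profile integer vector of length K giving one level per
#'   latent variable.
#' @return named class-posterior vector summing to 1.
#' @export
class_posterior_given_latents <- function(model, latent_profile) {
  stopifnot(length(latent_profile) == model$layout$K)
  lp <- log(model$q_c)
  for (k in seq_len(model$layout$K)) {
    l <- latent_profile[k]
    if (l < 1L || l > model$layout$levels[k]) stop("invalid latent level index")
    lp <- lp + log_finite(model$q_lc[[k]][l, ])
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

# assemble/validate the full model container
nbblca_model <- function(q_c, q_lc, theta, layout, priors = prior_config(),
                         feature_names = NULL, blocks_idx = NULL) {
  stopifnot(abs(sum(q_c) - 1) < 1e-8)
  for (k in seq_along(q_lc))
    stopifnot(all(abs(colSums(q_lc[[k]]) - 1) < 1e-6))
  structure(list(q_c = q_c, q_lc = q_lc, theta = theta, layout = layout,
                 priors = priors, feature_names = feature_names,
                 blocks_idx = blocks_idx),
            class = "nbblca_model")
}

#' @export
print.nbblca_model <- function(x, ...) {
  cat(sprintf("NB-BLCA model: %d classes, %d latent block(s) with levels (%s)\n",
              length(x$q_c), x$layout$K,
              paste(x$layout$levels, collapse = ", ")))
  cat("class prior:\n"); print(round(x$q_c, 4))
  invisible(x)
}

# per-block N x G_k component log-likelihood matrices for a data matrix
block_logliks <- function(model, X) {
  lapply(seq_len(model$layout$K), function(k)
    component_loglik_matrix(model$theta[[k]], X[, model$blocks_idx[[k]], drop = FALSE]))
}

#' Posterior class probabilities of an NB-BLCA model
#'
#' Default mode \code{"marginalize"} sums the latent variables out exactly:
#' \deqn{P(c|x) \propto q(c) \prod_k \sum_l q_k(l|c)\, P(x_{block\,k} | \theta^{(k)}_l).}
#' Mode \code{"hard"} first assigns each block its maximum a posteriori
#' latent level from the attribute likelihood alone (using the class-mixed
#' latent marginal as weight), then applies
#' \code{\link{class_posterior_given_latents}}. Marginalization is the
#' default because it retains the mixture uncertainty.
#'
#' @param model an \code{"nbblca_model"}.
#' @param X 0/1 matrix or \code{binary_dataset} matching the layout.
#' @param mode \code{"marginalize"} (default) or \code{"hard"}.
#' @return \code{N x |C|} matrix of class posteriors; rows sum to 1.
#' @export
nbblca_predict_proba <- function(model, X, mode = c("marginalize", "hard")) {
  mode <- match.arg(mode)
  X <- as_X(X, model$feature_names)
  classes <- names(model$q_c)
  N <- nrow(X)
  bl <- block_logliks(model, X)
  if (mode == "marginalize") {
    lp <- matrix(rep(log(model$q_c), each = N), N, length(classes))
    for (k in seq_len(model$layout$K)) {
      for (ci in seq_along(classes)) {
        # N-vector: log sum_l q_k(l|c) P(x_bk | theta_l)
        lw <- sweep(bl[[k]], 2, log_finite(model$q_lc[[k]][, ci]), "+")
        lp[, ci] <- lp[, ci] + log_row_sums(lw)
      }
    }
  } else {
    # class-marginal latent weights q_k(l) = sum_c q(c) q_k(l|c)
    lp <- matrix(NA_real_, N, length(classes))
    prof <- matrix(NA_integer_, N, model$layout$K)
    for (k in seq_len(model$layout$K)) {
      ql <- as.numeric(model$q_lc[[k]] %*% model$q_c)
      lw <- sweep(bl[[k]], 2, log_finite(ql), "+")
      prof[, k] <- max.col(lw, ties.method = "first")
    }
    for (i in seq_len(N))
      lp[i, ] <- log(class_posterior_given_latents(model, prof[i, ]))
  }
  colnames(lp) <- classes
  normalize_log_rows(lp)
}

#' @export
predict.nbblca_model <- function(object, X, type = c("class", "prob"),
                                 mode = c("marginalize", "hard"), ...) {
  type <- match.arg(type)
  p <- nbblca_predict_proba(object, X, mode = match.arg(mode))
  if (type == "prob") return(p)
  argmax_labels(p, object$q_c)
}

# log-posterior objective of the supervised model: observed-data loglik of
# (x, y) plus the Beta/Dirichlet prior kernels of every block
nbblca_log_posterior <- function(model, X, y_idx, pri_list) {
  ll <- sum(log(model$q_c[y_idx]))
  K <- model$layout$K
  for (k in seq_len(K)) {
    lw <- component_loglik_matrix(model$theta[[k]],
                                  X[, model$blocks_idx[[k]], drop = FALSE])
    lq <- log_finite(model$q_lc[[k]])  # G_k x |C|
    ll <- ll + sum(log_row_sums(lw + t(lq[, y_idx, drop = FALSE])))
    pri <- pri_list[[k]]
    ll <- ll + sum((pri$alpha - 1) * log_finite(model$theta[[k]]) +
                     (pri$beta - 1) * log_finite(1 - model$theta[[k]]))
    ll <- ll + sum((pri$delta - 1) * log_finite(model$q_lc[[k]]))
  }
  ll
}

#' Fit the NB-BLCA classifier by MAP expectation-maximization
#'
#' Training data carry the observed class label, so only the latent block
#' memberships are missing. The E-step computes per-block responsibilities
#' conditioned on each subject's observed class,
#' \eqn{r_{ik}(l) \propto q_k(l | y_i) P(x_{i,block\,k} | \theta^{(k)}_l)};
#' the M-step applies the MAP latent class updates per block with those
#' weights, updates \eqn{q_k(l|c)} from the class-partitioned responsibility
#' sums, and sets the class prior from the class frequencies (flat-prior
#' MAP). Best of \code{run$n_restarts} random starts by final log-posterior.
#'
#' @param train labeled \code{\link{binary_dataset}}; all declared classes
#'   present.
#' @param layout a \code{\link{latent_layout}} partitioning the attributes.
#' @param priors \code{\link{prior_config}} applied to every block
#'   (\code{alpha, beta >= 1} required, as in \code{\link{blca_em}}).
#' @param run a \code{\link{run_config}}.
#' @param two_stage if \code{TRUE}, fit each block as an unsupervised
#'   latent class model first (ignoring y) and then estimate the class
#'   layer from the fixed soft memberships — the sequential reading of the
#'   construction. Default \code{FALSE}: joint EM on the full posterior.
#' @return Object of class \code{"nbblca_fit"}: \code{model}
#'   (\code{nbblca_model}), \code{logpost}, \code{trace}, \code{converged},
#'   \code{resp} (list of per-block responsibility matrices).
#' @export
nbblca_fit_em <- function(train, layout, priors = prior_config(),
                          run = run_config(), two_stage = FALSE) {
  stopifnot(inherits(train, "binary_dataset"), inherits(layout, "latent_layout"))
  if (is.null(train$y)) stop("training data must carry class labels")
  classes <- train$class_labels
  y_idx <- match(train$y, classes)
  if (any(tabulate(y_idx, length(classes)) == 0L))
    stop("class absent from training data")
  X <- train$X; storage.mode(X) <- "double"
  blocks <- resolve_layout(layout, train$feature_names)
  pri_list <- lapply(seq_len(layout$K), function(k)
    expand_priors(priors, layout$levels[k], length(blocks[[k]])))
  for (pri in pri_list)
    if (any(pri$alpha < 1) || any(pri$beta < 1))
      stop("EM (MAP) requires alpha >= 1 and beta >= 1")
  with_seed_if(run$seed, {
    if (two_stage) {
      fit <- nbblca_two_stage(train, layout, blocks, priors, run, y_idx, classes)
    } else {
      fit <- NULL
      for (r in seq_len(run$n_restarts)) {
        cand <- nbblca_em_once(X, y_idx, classes, layout, blocks, pri_list,
                               priors, run, train$feature_names)
        if (is.null(fit) || cand$logpost > fit$logpost) fit <- cand
      }
    }
    fit
  })
}

nbblca_em_once <- function(X, y_idx, classes, layout, blocks, pri_list,
                           priors, run, feature_names) {
  N <- nrow(X); K <- layout$K; C <- length(classes)
  nc <- tabulate(y_idx, C)
  q_c <- nc / N
  names(q_c) <- classes
  # random start: per-block responsibilities ~ flat Dirichlet rows
  resp <- lapply(seq_len(K), function(k) {
    R <- matrix(stats::rexp(N * layout$levels[k]), N, layout$levels[k])
    R / rowSums(R)
  })
  trace <- numeric(0); converged <- FALSE
  model <- NULL
  for (it in seq_len(run$max_iter)) {
    # M-step per block
    theta <- vector("list", K); q_lc <- vector("list", K)
    for (k in seq_len(K)) {
      Gk <- layout$levels[k]; pri <- pri_list[[k]]
      Xk <- X[, blocks[[k]], drop = FALSE]
      ng <- colSums(resp[[k]])
      th <- (t(resp[[k]]) %*% Xk + pri$alpha - 1) /
        (ng + pri$alpha + pri$beta - 2)
      theta[[k]] <- pmin(pmax(th, THETA_EPS), 1 - THETA_EPS)
      q <- matrix(NA_real_, Gk, C)
      for (ci in seq_len(C)) {
        s <- colSums(resp[[k]][y_idx == ci, , drop = FALSE]) + pri$delta - 1
        s <- pmax(s, 0)
        q[, ci] <- if (sum(s) > 0) s / sum(s) else rep(1 / Gk, Gk)
      }
      q_lc[[k]] <- q
    }
    model <- nbblca_model(q_c, q_lc, theta, layout, priors,
                          feature_names, blocks)
    obj <- nbblca_log_posterior(model, X, y_idx, pri_list)
    trace <- c(trace, obj)
    if (it > 1L &&
        abs(obj - trace[it - 1L]) <= run$tol * (abs(trace[it - 1L]) + 1e-3)) {
      converged <- TRUE
      break
    }
    # E-step: responsibilities given the observed class
    for (k in seq_len(K)) {
      lw <- component_loglik_matrix(theta[[k]], X[, blocks[[k]], drop = FALSE]) +
        t(log_finite(q_lc[[k]])[, y_idx, drop = FALSE])
      resp[[k]] <- normalize_log_rows(lw)
    }
  }
  structure(list(model = model, logpost = trace[length(trace)],
                 trace = trace, converged = converged, resp = resp),
            class = "nbblca_fit")
}

# sequential variant: unsupervised BLCA per block, then class layer from
# the fixed soft memberships
nbblca_two_stage <- function(train, layout, blocks, priors, run, y_idx, classes) {
  X <- train$X; storage.mode(X) <- "double"
  N <- nrow(X); K <- layout$K; C <- length(classes)
  theta <- vector("list", K); q_lc <- vector("list", K); resp <- vector("list", K)
  logpost <- 0
  pri_list <- lapply(seq_len(K), function(k)
    expand_priors(priors, layout$levels[k], length(blocks[[k]])))
  for (k in seq_len(K)) {
    fit <- blca_em(X[, blocks[[k]], drop = FALSE], layout$levels[k],
                   priors, run)
    theta[[k]] <- fit$params$theta
    resp[[k]] <- fit$z
    q <- matrix(NA_real_, layout$levels[k], C)
    for (ci in seq_len(C)) {
      s <- colSums(fit$z[y_idx == ci, , drop = FALSE])
      q[, ci] <- if (sum(s) > 0) s / sum(s) else rep(1 / nrow(q), nrow(q))
    }
    q_lc[[k]] <- q
  }
  nc <- tabulate(y_idx, C)
  q_c <- stats::setNames(nc / N, classes)
  model <- nbblca_model(q_c, q_lc, theta, layout, priors,
                        train$feature_names, blocks)
  structure(list(model = model,
                 logpost = nbblca_log_posterior(model, X, y_idx, pri_list),
                 trace = NULL, converged = NA, resp = resp),
            class = "nbblca_fit")
}

#' Fit the NB-BLCA classifier by Gibbs sampling
#'
#' Extends the latent class Gibbs sweep with the class layer: per sweep,
#' (1) per-block item probabilities from their Beta full conditionals given
#' the current hard latent assignments; (2) \eqn{q_k(\cdot|c)} from Dirichlet
#' conditionals on the latent-level counts within class c; (3) the class
#' prior \eqn{q(c)} from a Dirichlet on the class counts; (4) each subject's
#' latent level per block from a single multinomial trial with probabilities
#' \eqn{\propto q_k(l | y_i) P(x_{i,block\,k} | \theta^{(k)}_l)} (a binomial
#' trial when the block has two levels). Retained draws are relabeled per
#' block against the running mean of the block's \eqn{\theta} draws; the
#' point model returned is the posterior mean.
#'
#' @inheritParams nbblca_fit_em
#' @param priors any strictly positive hyperparameters.
#' @return List of class \code{"nbblca_fit"} with \code{model} (posterior
#'   means), \code{chain} (class \code{"nbblca_chain"}: per-block
#'   \code{blca_chain}-like draws plus \code{q_c} and \code{q_lc} draws),
#'   and \code{logpost} (log-posterior at the posterior mean).
#' @export
nbblca_fit_gibbs <- function(train, layout, priors = prior_config(),
                             run = run_config()) {
  stopifnot(inherits(train, "binary_dataset"), inherits(layout, "latent_layout"))
  if (is.null(train$y)) stop("training data must carry class labels")
  classes <- train$class_labels
  y_idx <- match(train$y, classes)
  if (any(tabulate(y_idx, length(classes)) == 0L))
    stop("class absent from training data")
  X <- train$X; storage.mode(X) <- "double"
  blocks <- resolve_layout(layout, train$feature_names)
  N <- nrow(X); K <- layout$K; C <- length(classes)
  pri_list <- lapply(seq_len(K), function(k)
    expand_priors(priors, layout$levels[k], length(blocks[[k]])))
  delta_c <- rep_len(priors$delta, C)
  n_keep <- (run$gibbs_iters - run$burn_in) %/% run$thin
  nc <- tabulate(y_idx, C)
  with_seed_if(run$seed, {
    L <- vapply(seq_len(K), function(k)
      sample.int(layout$levels[k], N, replace = TRUE), integer(N))
    L <- matrix(L, N, K)
    q_c_draws <- matrix(NA_real_, n_keep, C, dimnames = list(NULL, classes))
    q_lc_draws <- lapply(seq_len(K), function(k)
      array(NA_real_, c(n_keep, layout$levels[k], C)))
    theta_draws <- lapply(seq_len(K), function(k)
      array(NA_real_, c(n_keep, layout$levels[k], length(blocks[[k]]))))
    L_draws <- array(NA_integer_, c(n_keep, N, K))
    iters <- integer(n_keep)
    kept <- 0L
    for (t in seq_len(run$gibbs_iters)) {
      q_c <- rdirichlet1(nc + delta_c)
      theta <- vector("list", K); q_lc <- vector("list", K)
      for (k in seq_len(K)) {
        Gk <- layout$levels[k]; pri <- pri_list[[k]]
        Xk <- X[, blocks[[k]], drop = FALSE]
        Zh <- hard_z_matrix(L[, k], N, Gk)
        ng <- colSums(Zh)
        s1 <- t(Zh) %*% Xk
        theta[[k]] <- matrix(stats::rbeta(Gk * ncol(Xk), s1 + pri$alpha,
                                          (ng - s1) + pri$beta), Gk, ncol(Xk))
        q <- matrix(NA_real_, Gk, C)
        for (ci in seq_len(C)) {
          cnt <- tabulate(L[y_idx == ci, k], Gk)
          q[, ci] <- rdirichlet1(cnt + pri$delta)
        }
        q_lc[[k]] <- q
        # resample latent levels given theta, q_lc and the observed class
        lw <- component_loglik_matrix(theta[[k]], Xk) +
          t(log_finite(q)[, y_idx, drop = FALSE])
        pz <- normalize_log_rows(lw)
        L[, k] <- apply(pz, 1L, function(pr) sample.int(Gk, 1L, prob = pr))
      }
      if (t > run$burn_in && (t - run$burn_in) %% run$thin == 0L) {
        kept <- kept + 1L
        q_c_draws[kept, ] <- q_c
        for (k in seq_len(K)) {
          q_lc_draws[[k]][kept, , ] <- q_lc[[k]]
          theta_draws[[k]][kept, , ] <- theta[[k]]
        }
        L_draws[kept, , ] <- L
        iters[kept] <- t
      }
    }
    # per-block relabeling, reusing the mixture relabeler; the q_k(l|c)
    # rows and latent draws follow the block's theta permutation
    for (k in seq_len(K)) {
      Gk <- layout$levels[k]
      if (Gk == 1L) next
      sub <- structure(list(tau = matrix(1 / Gk, n_keep, Gk),
                            theta = theta_draws[[k]],
                            z = L_draws[, , k],
                            perms = matrix(rep(seq_len(Gk), each = n_keep),
                                           n_keep, Gk)),
                       class = "blca_chain")
      sub <- relabel_chain(sub)
      theta_draws[[k]] <- sub$theta
      L_draws[, , k] <- sub$z
      for (d in seq_len(n_keep))
        q_lc_draws[[k]][d, , ] <- q_lc_draws[[k]][d, sub$perms[d, ], ]
    }
    q_c_mean <- colMeans(q_c_draws)
    q_c_mean <- stats::setNames(q_c_mean / sum(q_c_mean), classes)
    q_lc_mean <- lapply(seq_len(K), function(k) {
      m <- apply(q_lc_draws[[k]], c(2L, 3L), mean)
      sweep(m, 2, colSums(m), "/")
    })
    theta_mean <- lapply(theta_draws, function(a) apply(a, c(2L, 3L), mean))
    model <- nbblca_model(q_c_mean, q_lc_mean, theta_mean, layout, priors,
                          train$feature_names, blocks)
    chain <- structure(list(q_c = q_c_draws, q_lc = q_lc_draws,
                            theta = theta_draws, L = L_draws, iters = iters,
                            burn_in = run$burn_in, thin = run$thin,
                            classes = classes, layout = layout),
                       class = "nbblca_chain")
    structure(list(model = model, chain = chain,
                   logpost = nbblca_log_posterior(model, X, y_idx, pri_list)),
              class = "nbblca_fit")
  })
}

#' Information criteria for a fitted NB-BLCA model
#'
#' AIC and BIC use the observed-data log-likelihood of the attributes and
#' class labels under the fitted model, with free-parameter count
#' \deqn{p = \sum_k (G_k - 1)\,|C| + \sum_k G_k\,|block_k| + (|C| - 1).}
#' DIC (chain fits only) is \eqn{\bar D + p_D} with
#' \eqn{p_D = \bar D - D(\bar\vartheta)}, the deviance \eqn{D = -2 \log L}
#' evaluated across draws and at the posterior mean.
#'
#' @param fit an \code{"nbblca_fit"} (EM or Gibbs).
#' @param train the training \code{binary_dataset} the fit used.
#' @return named list with \code{loglik}, \code{p}, \code{AIC}, \code{BIC}
#'   and, for Gibbs fits, \code{DIC} and \code{p_D}.
#' @export
information_criteria <- function(fit, train) {
  model <- fit$model
  classes <- names(model$q_c)
  y_idx <- match(train$y, classes)
  X <- train$X; storage.mode(X) <- "double"
  K <- model$layout$K
  p <- sum((model$layout$levels - 1) * length(classes)) +
    sum(model$layout$levels * lengths(model$blocks_idx)) +
    (length(classes) - 1)
  ll <- nbblca_loglik(model, X, y_idx)
  n <- nrow(X)
  out <- list(loglik = ll, p = p, AIC = -2 * ll + 2 * p,
              BIC = -2 * ll + p * log(n))
  if (!is.null(fit$chain)) {
    dev <- -2 * vapply(seq_len(nrow(fit$chain$q_c)), function(d)
      nbblca_loglik(chain_draw_model(fit$chain, d, model), X, y_idx),
      numeric(1))
    p_d <- mean(dev) - (-2 * ll)
    out$DIC <- mean(dev) + p_d
    out$p_D <- p_d
  }
  out
}

# observed-data loglik of (x, y): sum_i log q(y_i) + sum_k log sum_l ...
nbblca_loglik <- function(model, X, y_idx) {
  ll <- sum(log(model$q_c[y_idx]))
  for (k in seq_len(model$layout$K)) {
    lw <- component_loglik_matrix(model$theta[[k]],
                                  X[, model$blocks_idx[[k]], drop = FALSE])
    lq <- log_finite(model$q_lc[[k]])
    ll <- ll + sum(log_row_sums(lw + t(lq[, y_idx, drop = FALSE])))
  }
  ll
}

# materialize draw d of a chain as a point model (for DIC)
chain_draw_model <- function(chain, d, template) {
  K <- template$layout$K
  q_c <- chain$q_c[d, ]
  q_lc <- lapply(seq_len(K), function(k)
    matrix(chain$q_lc[[k]][d, , ], template$layout$levels[k], length(q_c)))
  theta <- lapply(seq_len(K), function(k)
    matrix(chain$theta[[k]][d, , ], template$layout$levels[k],
           length(template$blocks_idx[[k]])))
  nbblca_model(q_c, q_lc, theta, template$layout, template$priors,
               template$feature_names, template$blocks_idx)
}

#' Scan latent level counts and pick a fit by BIC
#'
#' Fits the model for each candidate number of latent levels (shared across
#' blocks) and returns the BIC-minimizing fit, mirroring the scree-plot use
#' of information criteria for choosing the latent dimensionality.
#'
#' @param train labeled \code{\link{binary_dataset}}.
#' @param levels_grid candidate level counts, default \code{2:4}.
#' @param blocks block structure passed to \code{\link{latent_layout}}
#'   (default: one block over all attributes).
#' @param priors,run as in \code{\link{nbblca_fit_em}}.
#' @return the winning \code{"nbblca_fit"}, with the scan table in
#'   \code{$scan} (columns \code{levels}, \code{BIC}, \code{AIC}).
#' @export
nbblca_scan_levels <- function(train, levels_grid = 2:4, blocks = NULL,
                               priors = prior_config(), run = run_config()) {
  if (is.null(blocks)) blocks <- list(seq_len(ncol(train$X)))
  fits <- list(); tab <- NULL
  for (g in levels_grid) {
    layout <- latent_layout(blocks, levels = g)
    f <- nbblca_fit_em(train, layout, priors,
                       run_config(seed = child_seed(run$seed, g),
                                  max_iter = run$max_iter, tol = run$tol,
                                  n_restarts = run$n_restarts,
                                  gibbs_iters = run$gibbs_iters,
                                  burn_in = run$burn_in, thin = run$thin))
    ic <- information_criteria(f, train)
    fits[[as.character(g)]] <- f
    tab <- rbind(tab, data.frame(levels = g, BIC = ic$BIC, AIC = ic$AIC))
  }
  best <- fits[[as.character(tab$levels[which.min(tab$BIC)])]]
  best$scan <- tab
  best
}
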