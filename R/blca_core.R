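#' Bernoulli component log-likelihood
#'
#' Log-probability of one binary attribute vector under one latent class'
#' item-response probabilities:
#' \eqn{\sum_m [x_m \log\theta_m + (1-x_m)\log(1-\theta_m)]}, with
#' \eqn{\log 0 = -\infty}.
#'
#' @param theta_row length-M vector of item probabilities in [0,1].
#' @param x length-M 0/1 vector.
#' @return a scalar log-likelihood (possibly \code{-Inf}).
#' @export
component_loglik <- function(theta_row, x) {
  stopifnot(length(theta_row) == length(x))
  terms <- ifelse(x == 1, log(theta_row), log1p(-theta_row))
  sum(terms)
}

# N x G matrix of log P(X_i | theta_g); log(0) kept finite for the matrix
# product (see log_finite), exact -Inf is irrelevant after normalization
component_loglik_matrix <- function(theta, X) {
  X %*% t(log_finite(theta)) + (1 - X) %*% t(log_finite(1 - theta))
}

#' Mixture log-likelihood of a Bernoulli latent class model
#'
#' Observed-data log-likelihood
#' \eqn{\sum_i \log \sum_g \tau_g P(X_i|\theta_g)}, computed stably in the
#' log domain.
#'
#' @param params a \code{"blca_params"} object (or any list with \code{tau}
#'   and \code{theta}).
#' @param X 0/1 matrix with \code{ncol(theta)} columns.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(params, X) {
  X <- as_X(X, seq_len(ncol(params$theta)))
  ll <- component_loglik_matrix(params$theta, X)
  lp <- sweep(ll, 2, log_finite(params$tau), "+")
  sum(log_row_sums(lp))
}

# log(sum(exp(lp))) per row, max-shifted
log_row_sums <- function(lp) {
  m <- apply(lp, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(lp - m)))
}

#' Posterior latent class membership probabilities
#'
#' The responsibility matrix
#' \eqn{Z_{ig} = \tau_g P(X_i|\theta_g) / \sum_h \tau_h P(X_i|\theta_h)};
#' identical to the EM E-step.
#'
#' @inheritParams mixture_loglik
#' @return \code{N x G} matrix with rows summing to 1.
#' @export
posterior_z <- function(params, X) {
  X <- as_X(X, seq_len(ncol(params$theta)))
  lp <- sweep(component_loglik_matrix(params$theta, X), 2,
              log_finite(params$tau), "+")
  normalize_log_rows(lp)
}

# construct/validate the mixture parameter container
blca_params <- function(tau, theta, priors = prior_config()) {
  tau <- as.numeric(tau)
  theta <- rbind(theta)
  stopifnot(length(tau) == nrow(theta), all(tau >= 0),
            abs(sum(tau) - 1) < 1e-8, all(theta >= 0 & theta <= 1))
  structure(list(tau = tau / sum(tau), theta = theta, priors = priors),
            class = "blca_params")
}

# MAP log-posterior objective: mixture loglik + log prior kernels
blca_log_posterior <- function(tau, theta, X, pri) {
  ll <- mixture_loglik(list(tau = tau, theta = theta), X)
  lp_tau <- sum((pri$delta - 1) * log_finite(tau))
  lp_theta <- sum((pri$alpha - 1) * log_finite(theta) +
                    (pri$beta - 1) * log_finite(1 - theta))
  ll + lp_tau + lp_theta
}

THETA_EPS <- 1e-12

#' Fit a Bayesian latent class model by MAP expectation-maximization
#'
#' Finite mixture of G independent-Bernoulli components with conjugate
#' Beta priors on the item probabilities and a Dirichlet prior on the
#' mixing weights, maximized by EM over the posterior mode. The M-step is
#' the MAP update
#' \deqn{\theta_{gm} = \frac{\sum_i X_{im} Z_{ig} + \alpha_{gm} - 1}
#'                          {\sum_i Z_{ig} + \alpha_{gm} + \beta_{gm} - 2},
#'  \quad
#'  \tau_g = \frac{\sum_i Z_{ig} + \delta_g - 1}{N + \sum_h \delta_h - G}.}
#' With the default flat priors these are the usual maximum-likelihood
#' updates. Random-restart initialization draws each row of the starting
#' responsibilities from a flat Dirichlet.
#'
#' @param X 0/1 matrix (or \code{binary_dataset}; labels ignored).
#' @param G number of latent classes (1 \eqn{\le} G \eqn{\le} N).
#' @param priors a \code{\link{prior_config}} with \code{alpha, beta >= 1}
#'   (so the posterior mode is interior).
#' @param run a \code{\link{run_config}}; \code{n_restarts} independent
#'   starts are run and the best final log-posterior is returned.
#' @return List of class \code{"blca_fit"}: \code{params}
#'   (\code{blca_params}), \code{z} (responsibilities), \code{logpost}
#'   (final objective), \code{trace} (objective per iteration of the winning
#'   restart), \code{iterations}, \code{converged}.
#' @export
blca_em <- function(X, G, priors = prior_config(), run = run_config()) {
  if (inherits(X, "binary_dataset")) X <- X$X
  X <- as.matrix(X); storage.mode(X) <- "double"
  N <- nrow(X); M <- ncol(X)
  stopifnot(G >= 1)
  if (G > N) stop("more latent classes than observations")
  pri <- expand_priors(priors, G, M)
  if (any(pri$alpha < 1) || any(pri$beta < 1))
    stop("EM (MAP) requires alpha >= 1 and beta >= 1; use blca_gibbs for sub-uniform Beta priors")
  with_seed_if(run$seed, {
    best <- NULL
    for (r in seq_len(run$n_restarts)) {
      fit <- blca_em_once(X, G, pri, run)
      if (is.null(best) || fit$logpost > best$logpost) best <- fit
    }
    best$params$priors <- priors
    best
  })
}

blca_em_once <- function(X, G, pri, run) {
  N <- nrow(X)
  # random responsibilities: each row ~ Dirichlet(1,...,1)
  Z <- matrix(stats::rexp(N * G), N, G)
  Z <- Z / rowSums(Z)
  tau <- NULL; theta <- NULL; trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(run$max_iter)) {
    upd <- blca_m_step(X, Z, pri)
    tau <- upd$tau; theta <- upd$theta
    obj <- blca_log_posterior(tau, theta, X, pri)
    trace <- c(trace, obj)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (abs(obj - prev) <= run$tol * (abs(prev) + 1e-3)) {
        converged <- TRUE
        Z <- posterior_z(list(tau = tau, theta = theta), X)
        break
      }
    }
    Z <- posterior_z(list(tau = tau, theta = theta), X)
    Z <- reseed_empty_components(Z, list(tau = tau, theta = theta), X)
  }
  structure(list(params = blca_params(tau, theta),
                 z = Z, logpost = trace[length(trace)], trace = trace,
                 iterations = length(trace), converged = converged),
            class = "blca_fit")
}

# MAP M-step shared by blca_em and the supervised latent blocks
blca_m_step <- function(X, Z, pri) {
  N <- nrow(X); G <- ncol(Z)
  ng <- colSums(Z)
  theta <- (t(Z) %*% X + pri$alpha - 1) /
    (ng + pri$alpha + pri$beta - 2)
  theta <- pmin(pmax(theta, THETA_EPS), 1 - THETA_EPS)
  tau <- (ng + pri$delta - 1) / (N + sum(pri$delta) - G)
  tau <- pmax(tau, 0); tau <- tau / sum(tau)
  list(tau = tau, theta = theta)
}

# a component whose total responsibility collapses to ~0 is re-seeded from
# the observation the current mixture fits worst, keeping G as requested
reseed_empty_components <- function(Z, params, X) {
  empty <- which(colSums(Z) < 1e-8)
  if (length(empty) == 0L) return(Z)
  fit_quality <- log_row_sums(sweep(component_loglik_matrix(params$theta, X),
                                    2, log_finite(params$tau), "+"))
  worst <- order(fit_quality)[seq_along(empty)]
  for (k in seq_along(empty)) {
    Z[worst[k], ] <- 0
    Z[worst[k], empty[k]] <- 1
  }
  Z
}

# single Dirichlet draw via gamma normalization
rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (all(g == 0)) g <- rep(1, length(conc))
  g / sum(g)
}

#' Fit a Bayesian latent class model by Gibbs sampling
#'
#' Conjugate blocked Gibbs sampler. Each sweep draws, in order,
#' \deqn{\theta_{gm} \sim Beta(\textstyle\sum_i X_{im} Z_{ig} + \alpha_{gm},
#'       \sum_i Z_{ig}(1 - X_{im}) + \beta_{gm}),}
#' \deqn{\tau \sim Dirichlet(\textstyle\sum_i Z_{i1} + \delta_1, \ldots,
#'       \sum_i Z_{iG} + \delta_G),}
#' then reassigns each observation's hard membership from a single
#' multinomial trial with the posterior membership probabilities. Memberships
#' are initialized uniformly at random. Burn-in and thinning are applied and
#' the retained draws are relabeled (see \code{\link{relabel_chain}}).
#'
#' @inheritParams blca_em
#' @param priors any strictly positive Beta/Dirichlet hyperparameters
#'   (no interior-mode restriction here).
#' @param relabel apply post-hoc label-switching correction (default TRUE).
#' @return Object of class \code{"blca_chain"}: arrays \code{tau}
#'   (\code{draws x G}), \code{theta} (\code{draws x G x M}), \code{z}
#'   (\code{draws x N} hard memberships), \code{iters} (sweep indices of the
#'   retained draws), \code{burn_in}, \code{thin}, and \code{perms} (the
#'   relabeling permutation applied to each draw).
#' @export
blca_gibbs <- function(X, G, priors = prior_config(), run = run_config(),
                       relabel = TRUE) {
  if (inherits(X, "binary_dataset")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) > 0L) storage.mode(X) <- "double"
  N <- nrow(X); M <- ncol(X)
  pri <- expand_priors(priors, G, M)
  n_keep <- (run$gibbs_iters - run$burn_in) %/% run$thin
  with_seed_if(run$seed, {
    tau_draws <- matrix(NA_real_, n_keep, G)
    theta_draws <- array(NA_real_, c(n_keep, G, M))
    z_draws <- matrix(NA_integer_, n_keep, N)
    iters <- integer(n_keep)
    z <- if (N > 0) sample.int(G, N, replace = TRUE) else integer(0)
    kept <- 0L
    for (t in seq_len(run$gibbs_iters)) {
      Zh <- hard_z_matrix(z, N, G)
      ng <- colSums(Zh)
      s1 <- t(Zh) %*% X                      # G x M successes per component
      theta <- matrix(stats::rbeta(G * M, s1 + pri$alpha,
                                   (ng - s1) + pri$beta), G, M)
      tau <- rdirichlet1(ng + pri$delta)
      if (N > 0) {
        p <- posterior_z(list(tau = tau, theta = theta), X)
        z <- apply(p, 1L, function(pr) sample.int(G, 1L, prob = pr))
      }
      if (t > run$burn_in && (t - run$burn_in) %% run$thin == 0L) {
        kept <- kept + 1L
        tau_draws[kept, ] <- tau
        theta_draws[kept, , ] <- theta
        z_draws[kept, ] <- z
        iters[kept] <- t
      }
    }
    chain <- structure(list(tau = tau_draws, theta = theta_draws,
                            z = z_draws, iters = iters,
                            burn_in = run$burn_in, thin = run$thin,
                            perms = matrix(rep(seq_len(G), each = n_keep),
                                           n_keep, G)),
                       class = "blca_chain")
    if (relabel && G > 1L) relabel_chain(chain) else chain
  })
}

hard_z_matrix <- function(z, N, G) {
  Zh <- matrix(0, N, G)
  if (N > 0) Zh[cbind(seq_len(N), z)] <- 1
  Zh
}

# all permutations of 1..n (n small; mixture G rarely exceeds 6)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Undo label switching in a Gibbs chain
#'
#' Mixture components are only identified up to permutation, so raw MCMC
#' draws can switch labels between sweeps. Each retained draw's components
#' are permuted to minimize the squared distance of its \eqn{\theta} draw to
#' the running mean of the already-relabeled draws (first draw is the
#' initial reference). Deterministic given the chain; idempotent on chains
#' whose labels are already coherent.
#'
#' @param chain a \code{"blca_chain"}.
#' @return The relabeled chain, with \code{perms} recording the permutation
#'   applied to each draw (new position of each original component).
#' @export
relabel_chain <- function(chain) {
  G <- ncol(chain$tau)
  if (G == 1L || nrow(chain$tau) == 0L) return(chain)
  perms <- all_perms(G)
  M <- dim(chain$theta)[3L]
  run_sum <- matrix(0, G, M)
  for (d in seq_len(nrow(chain$tau))) {
    th <- matrix(chain$theta[d, , ], G, M)
    target <- if (d == 1L) th else run_sum / (d - 1)
    costs <- vapply(perms, function(p) sum((th[p, , drop = FALSE] - target)^2),
                    numeric(1))
    p <- perms[[which.min(costs)]]
    chain$theta[d, , ] <- th[p, , drop = FALSE]
    chain$tau[d, ] <- chain$tau[d, p]
    # memberships: component p[k] moves to slot k, i.e. old label g -> match(g, p)
    if (ncol(chain$z) > 0)
      chain$z[d, ] <- match(chain$z[d, ], p)
    chain$perms[d, ] <- p
    run_sum <- run_sum + matrix(chain$theta[d, , ], G, M)
  }
  chain
}

#' Posterior means of a BLCA Gibbs chain
#'
#' @param chain a \code{"blca_chain"}.
#' @return a \code{blca_params} with the draw-averaged \code{tau} and
#'   \code{theta}.
#' @export
chain_posterior_mean <- function(chain) {
  blca_params(colMeans(chain$tau), apply(chain$theta, c(2L, 3L), mean))
}

#' MCMC convergence diagnostics for a Gibbs chain
#'
#' Per scalar parameter (every \eqn{\tau_g} and \eqn{\theta_{gm}}): the
#' effective sample size and the split-\eqn{\hat R} statistic (the chain is
#' split into two halves which are compared as if independent chains).
#' \eqn{\hat R > 1.1} is flagged as non-converged; parameters with (near-)
#' zero variance are reported as degenerate rather than flagged.
#'
#' @param chain a \code{"blca_chain"} (or NB-BLCA chain) with at least 4
#'   retained draws.
#' @return data frame with columns \code{parameter}, \code{mean}, \code{sd},
#'   \code{ess}, \code{rhat}, \code{flagged}, \code{degenerate}.
#' @export
chain_diagnostics <- function(chain) {
  mat <- chain_scalar_matrix(chain)
  if (nrow(mat) < 4L) stop("chain too short for diagnostics (need >= 4 retained draws)")
  ess <- suppressWarnings(as.numeric(coda::effectiveSize(coda::mcmc(mat))))
  rhat <- apply(mat, 2L, split_rhat)
  sds <- apply(mat, 2L, stats::sd)
  degenerate <- sds < 1e-12
  data.frame(parameter = colnames(mat),
             mean = colMeans(mat), sd = sds, ess = ess, rhat = rhat,
             flagged = !degenerate & !is.na(rhat) & rhat > 1.1,
             degenerate = degenerate, row.names = NULL)
}

# draws x parameters matrix with informative column names
chain_scalar_matrix <- function(chain) {
  G <- ncol(chain$tau); M <- dim(chain$theta)[3L]
  th <- matrix(chain$theta, nrow(chain$tau), G * M)
  colnames(th) <- as.vector(outer(seq_len(G), seq_len(M),
                                  function(g, m) sprintf("theta[%d,%d]", g, m)))
  tau <- chain$tau
  colnames(tau) <- sprintf("tau[%d]", seq_len(G))
  cbind(tau, th)
}

# split-Rhat of a single chain: compare its two halves
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  halves <- cbind(x[seq_len(n)], x[(length(x) - n + 1L):length(x)])
  w <- mean(apply(halves, 2L, stats::var))
  b <- n * stats::var(colMeans(halves))
  if (w < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}
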