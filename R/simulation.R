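#' Define a simulation scenario
#'
#' One cell of the simulation grid: correlated binary features generated in
#' independent 5-dimensional batches (marginals uniform on (0,1), pairwise
#' odds ratios uniform on (0.25, 4) within a batch), and a class label from
#' a logistic construction \eqn{Z = \alpha + \beta \sum_i x_i + N(0,\sigma)},
#' \eqn{P = 1/(1 + e^Z)}, \eqn{Y \sim Bernoulli(P)}, with the intercept
#' \eqn{\alpha} tuned so the class-1 marginal hits \code{target_prev}.
#' Note the printed transform is decreasing in Z; the tuned intercept
#' absorbs the sign, so only the per-feature effect direction (negative in
#' Z, hence features lower the class-1 probability) is affected, not the
#' prevalence.
#'
#' @param p number of features; must be a multiple of \code{batch}
#'   (grid values 5, 10, 20).
#' @param n sample size (grid values 500, 1000, 2000).
#' @param target_prev target marginal probability of class "1"
#'   (grid values 0.3, 0.5, 0.7).
#' @param beta common regression coefficient of every feature (default 2).
#' @param sigma standard deviation of the Gaussian noise term (default 4).
#' @param or_range range of the uniform pairwise odds-ratio draw.
#' @param batch feature-batch dimension (default 5).
#' @return Object of class \code{"simulation_scenario"}.
#' @export
simulation_scenario <- function(p, n, target_prev, beta = 2, sigma = 4,
                                or_range = c(0.25, 4), batch = 5L) {
  stopifnot(p %% batch == 0, target_prev > 0, target_prev < 1, n >= 1)
  structure(list(p = as.integer(p), n = as.integer(n),
                 target_prev = target_prev, beta = beta, sigma = sigma,
                 or_range = or_range, batch = as.integer(batch)),
            class = "simulation_scenario")
}

#' Draw an (unfitted) batch specification
#'
#' Hypothetical marginal probabilities \eqn{HMP_i \sim U(0,1)} i.i.d. and a
#' symmetric unit-diagonal pairwise odds-ratio matrix with
#' \eqn{OR_{ij} \sim U(or\_range)} for \eqn{i < j}.
#'
#' @param d batch dimension (default 5).
#' @param or_range odds-ratio range (default \code{c(0.25, 4)}).
#' @return list of class \code{"batch_spec"} with \code{hmp},
#'   \code{or_matrix}, and \code{joint = NULL} until fitted.
#' @export
draw_batch_spec <- function(d = 5L, or_range = c(0.25, 4)) {
  hmp <- stats::runif(d)
  orm <- diag(1, d)
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    orm[i, j] <- orm[j, i] <- stats::runif(1, or_range[1], or_range[2])
  }
  structure(list(hmp = hmp, or_matrix = orm, joint = NULL),
            class = "batch_spec")
}

#' Closed-form 2x2 cell probabilities from margins and odds ratio
#'
#' The unique 2x2 joint with margins \eqn{(p_1, p_2)} and odds ratio
#' \eqn{\psi}: for \eqn{\psi \ne 1},
#' \eqn{p_{11} = \big(s - \sqrt{s^2 - 4\psi(\psi-1)p_1 p_2}\big) /
#' (2(\psi-1))} with \eqn{s = 1 + (p_1 + p_2)(\psi - 1)}; independence for
#' \eqn{\psi = 1}.
#'
#' @param p1,p2 marginal success probabilities.
#' @param or odds ratio (positive).
#' @return named vector \code{c(p00, p01, p10, p11)} summing to 1.
#' @examples
#' pairwise_cell_probs(0.5, 0.5, 4)  # (1/3, 1/6, 1/6, 1/3)
#' @export
pairwise_cell_probs <- function(p1, p2, or) {
  stopifnot(or > 0, p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  if (abs(or - 1) < 1e-12) {
    p11 <- p1 * p2
  } else {
    s <- 1 + (p1 + p2) * (or - 1)
    p11 <- (s - sqrt(s^2 - 4 * or * (or - 1) * p1 * p2)) / (2 * (or - 1))
  }
  c(p00 = 1 - p1 - p2 + p11, p01 = p2 - p11, p10 = p1 - p11, p11 = p11)
}

# 0/1 configuration matrix of the 2^d table, row r = cell r (binary digits)
cell_configs <- function(d) {
  g <- as.matrix(expand.grid(rep(list(0:1), d)))
  dimnames(g) <- NULL
  g
}

#' Fit the batch joint distribution by iterative proportional fitting
#'
#' Starts from a log-linear seed table (independence times the pairwise
#' interaction factors \eqn{OR_{ij}^{x_i x_j}}) and cycles IPF updates over
#' every pairwise 2x2 margin, each derived in closed form from the target
#' marginals and odds ratio (\code{\link{pairwise_cell_probs}}). At
#' convergence the joint reproduces the univariate marginals and the
#' pairwise contingency-table odds ratios of the specification.
#'
#' @param spec a \code{"batch_spec"}.
#' @param tol maximum absolute pairwise-margin error at convergence.
#' @param max_sweeps IPF sweep budget; non-convergence is an error that
#'   reports the achieved error.
#' @return the batch specification with \code{joint} (length \eqn{2^d}
#'   probability vector)
#'   and \code{configs} (the 0/1 cell configuration matrix) filled in.
#' @export
ipfp_fit_joint <- function(spec, tol = 1e-10, max_sweeps = 5000L) {
  d <- length(spec$hmp)
  cfg <- cell_configs(d)
  # log-linear seed with two-way terms log OR
  tab <- exp(cfg %*% log(spec$hmp) + (1 - cfg) %*% log(1 - spec$hmp))
  pairs <- which(upper.tri(diag(d)), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    tab <- tab * spec$or_matrix[i, j]^(cfg[, i] * cfg[, j])
  }
  tab <- as.numeric(tab / sum(tab))
  targets <- lapply(seq_len(nrow(pairs)), function(r)
    pairwise_cell_probs(spec$hmp[pairs[r, 1]], spec$hmp[pairs[r, 2]],
                        spec$or_matrix[pairs[r, 1], pairs[r, 2]]))
  # cell-group index per pair: 1 + x_i + 2 x_j maps to (p00, p10, p01, p11)
  groups <- lapply(seq_len(nrow(pairs)), function(r)
    1L + cfg[, pairs[r, 1]] + 2L * cfg[, pairs[r, 2]])
  err <- Inf
  for (sweep in seq_len(max_sweeps)) {
    for (r in seq_len(nrow(pairs))) {
      tgt <- unname(targets[[r]][c("p00", "p10", "p01", "p11")])
      cur <- as.numeric(tapply(tab, groups[[r]], sum))
      tab <- unname(tab * (tgt / cur)[groups[[r]]])
    }
    err <- max(vapply(seq_len(nrow(pairs)), function(r) {
      tgt <- targets[[r]][c("p00", "p10", "p01", "p11")]
      max(abs(as.numeric(tapply(tab, groups[[r]], sum)) - tgt))
    }, numeric(1)))
    if (err < tol) break
  }
  if (err >= tol)
    stop(sprintf("IPF did not converge in %d sweeps (achieved margin error %.3g)",
                 max_sweeps, err))
  spec$joint <- tab / sum(tab)
  spec$configs <- cfg
  spec
}

# marginal probabilities and collapsed pairwise ORs implied by a fitted table
joint_marginals <- function(spec) {
  as.numeric(crossprod(spec$configs, spec$joint))
}

joint_pairwise_or <- function(spec) {
  d <- length(spec$hmp)
  orm <- diag(1, d)
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    g <- 1L + spec$configs[, i] + 2L * spec$configs[, j]
    m <- as.numeric(tapply(spec$joint, g, sum))  # p00, p10, p01, p11
    orm[i, j] <- orm[j, i] <- (m[1] * m[4]) / (m[2] * m[3])
  }
  orm
}

#' Sample feature rows for a scenario
#'
#' Draws and IPF-fits \code{p/batch} fresh batch specifications, then
#' samples each row by concatenating one draw from every batch's joint;
#' batches are mutually independent by construction.
#'
#' @param scenario a \code{\link{simulation_scenario}}.
#' @param n number of rows (defaults to \code{scenario$n}).
#' @param batches optional pre-fitted list of batch specs (recycled across
#'   calls, e.g. for the tuning pilot and the final sample).
#' @return list with \code{X} (\code{n x p} 0/1 matrix) and \code{batches}.
#' @export
sample_features <- function(scenario, n = scenario$n, batches = NULL) {
  n_batches <- scenario$p %/% scenario$batch
  if (is.null(batches)) {
    batches <- replicate(n_batches, ipfp_fit_joint(
      draw_batch_spec(scenario$batch, scenario$or_range)), simplify = FALSE)
  }
  X <- matrix(0L, n, scenario$p)
  for (b in seq_len(n_batches)) {
    cells <- sample.int(length(batches[[b]]$joint), n, replace = TRUE,
                        prob = batches[[b]]$joint)
    X[, (b - 1L) * scenario$batch + seq_len(scenario$batch)] <-
      batches[[b]]$configs[cells, , drop = FALSE]
  }
  colnames(X) <- paste0("f", seq_len(scenario$p))
  list(X = X, batches = batches)
}

#' Tune the logistic intercept to hit the target class prevalence
#'
#' \eqn{P = 1/(1+e^Z)} is strictly decreasing in \eqn{\alpha} pointwise, so
#' bisection on the mean of P over a pilot feature sample (with the pilot's
#' noise draws held fixed) converges to the intercept whose implied class-1
#' prevalence is within \code{prev_tol} of the target.
#'
#' @param scenario a \code{\link{simulation_scenario}}.
#' @param batches fitted batch specs (the replicate's own, so the tuning
#'   matches the replicate's marginal structure).
#' @param pilot_n pilot sample size (default 20000).
#' @param prev_tol tolerance on the mean class-1 probability (default 0.002).
#' @return the tuned intercept \code{alpha} (scalar).
#' @export
tune_alpha <- function(scenario, batches, pilot_n = 20000L, prev_tol = 0.002) {
  pilot <- sample_features(scenario, n = pilot_n, batches = batches)
  s <- scenario$beta * rowSums(pilot$X) +
    stats::rnorm(pilot_n, 0, scenario$sigma)
  f <- function(a) mean(stats::plogis(-(a + s)))  # 1/(1+e^Z), Z = a + s
  lo <- -1; hi <- 1
  while (f(lo) < scenario$target_prev) lo <- lo * 2  # f decreasing: go left
  while (f(hi) > scenario$target_prev) hi <- hi * 2
  if (lo < -1e6 || hi > 1e6) stop("intercept bracket failure for target prevalence")
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - scenario$target_prev) <= prev_tol) return(mid)
    if (fm > scenario$target_prev) lo <- mid else hi <- mid
  }
  mid
}

#' Generate one replicate dataset for a scenario
#'
#' Fresh marginal/odds-ratio structure per replicate: draws and fits the
#' batches, tunes the intercept on a pilot sample, then samples the
#' features and the class labels (one Bernoulli trial per subject with its
#' own \eqn{P_i}). Class labels are \code{"0"}/\code{"1"}; \code{"1"} is
#' the positive class of the downstream metrics.
#'
#' @param scenario a \code{\link{simulation_scenario}}.
#' @param pilot_n pilot size for intercept tuning.
#' @return a labeled \code{\link{binary_dataset}}; the tuned intercept and
#'   batch specs are attached as attributes \code{"alpha"} and
#'   \code{"batches"}.
#' @export
generate_dataset <- function(scenario, pilot_n = 20000L) {
  fs <- sample_features(scenario)
  alpha <- tune_alpha(scenario, fs$batches, pilot_n = pilot_n)
  z <- alpha + scenario$beta * rowSums(fs$X) +
    stats::rnorm(scenario$n, 0, scenario$sigma)
  p1 <- stats::plogis(-z)  # 1/(1+e^Z)
  y <- stats::rbinom(scenario$n, 1L, p1)
  d <- binary_dataset(fs$X, y = as.character(y), class_labels = c("0", "1"))
  attr(d, "alpha") <- alpha
  attr(d, "batches") <- fs$batches
  d
}

#' Model registry for the study runner
#'
#' Maps a model name to a \code{fit(train)} / \code{predict(fit, X)} pair.
#' Available: \code{"nb"}, \code{"aode"}, \code{"tanhc"},
#' \code{"nbblca_em"} (options \code{G}, \code{n_restarts},
#' \code{levels_grid} for a BIC scan when \code{G = NULL}),
#' \code{"nbblca_gibbs"} (options \code{G}, \code{gibbs_iters},
#' \code{burn_in}, \code{thin}), \code{"prior"} (class-prior stub) and
#' \code{"oracle"} (returns the true labels; testing stub).
#'
#' @param name model name.
#' @param ... model options.
#' @return list with \code{fit}, \code{predict}, \code{name}.
#' @export
model_registry <- function(name, ...) {
  opts <- list(...)
  get_opt <- function(key, default) if (is.null(opts[[key]])) default else opts[[key]]
  spec <- switch(
    name,
    nb = list(
      fit = function(train) nb_fit(train, smoothing = get_opt("smoothing", 1)),
      predict = function(fit, X) predict(fit, X)),
    aode = list(
      fit = function(train) aode_fit(train, smoothing = get_opt("smoothing", 1),
                                     min_support = get_opt("min_support", 1L)),
      predict = function(fit, X) predict(fit, X)),
    tanhc = list(
      fit = function(train) tan_hc_fit(train, smoothing = get_opt("smoothing", 1)),
      predict = function(fit, X) predict(fit, X)),
    nbblca_em = list(
      fit = function(train) {
        run <- run_config(n_restarts = get_opt("n_restarts", 10L),
                          max_iter = get_opt("max_iter", 1000L))
        G <- get_opt("G", NULL)
        if (is.null(G)) {
          nbblca_scan_levels(train, levels_grid = get_opt("levels_grid", 2:4),
                             run = run)
        } else {
          nbblca_fit_em(train, latent_layout(ncol(train$X), levels = G),
                        run = run)
        }
      },
      predict = function(fit, X) predict(fit$model, X)),
    nbblca_gibbs = list(
      fit = function(train) {
        run <- run_config(gibbs_iters = get_opt("gibbs_iters", 5000L),
                          burn_in = get_opt("burn_in", 1000L),
                          thin = get_opt("thin", 5L))
        nbblca_fit_gibbs(train, latent_layout(ncol(train$X),
                                              levels = get_opt("G", 2L)),
                         run = run)
      },
      predict = function(fit, X) predict(fit$model, X)),
    prior = list(
      fit = function(train) {
        tab <- table(train$y)
        names(tab)[which.max(tab)]
      },
      predict = function(fit, X) rep(fit, nrow(X))),
    oracle = list(
      fit = function(train) NULL,
      predict = function(fit, X) attr(X, "true_labels")),
    stop("unknown model: ", name)
  )
  spec$name <- name
  spec
}

#' Run the simulation study
#'
#' For every scenario and replicate: generate a dataset (fresh correlation
#' structure and tuned intercept), split 70/30, fit every model on the
#' training part, predict the test part and score sensitivity, specificity,
#' PPV, NPV, precision, accuracy and balanced accuracy against the positive
#' class "1". Replicates whose fit fails (e.g. a class missing from a tiny
#' training split) are resampled and counted. Deterministic given
#' \code{seed}.
#'
#' @param scenarios a \code{\link{simulation_scenario}} or list of them.
#' @param models character vector of registry names, or a named list of
#'   registry specs.
#' @param reps replicates per scenario.
#' @param seed master seed.
#' @param pilot_n pilot size for intercept tuning.
#' @return data frame in long format: scenario descriptors, \code{model},
#'   \code{metric}, \code{mean}, \code{mc_se}, \code{reps},
#'   \code{n_defined} (replicates where the metric had a nonzero
#'   denominator), \code{resampled}.
#' @export
run_study <- function(scenarios, models = c("nb", "nbblca_em"), reps = 100L,
                      seed = 1L, pilot_n = 20000L) {
  if (inherits(scenarios, "simulation_scenario")) scenarios <- list(scenarios)
  if (is.character(models)) {
    models <- stats::setNames(lapply(models, model_registry), models)
  }
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "precision",
               "accuracy", "balanced_accuracy")
  out <- NULL
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    vals <- array(NA_real_, c(reps, length(models), length(metrics)),
                  dimnames = list(NULL, names(models), metrics))
    resampled <- 0L
    r <- 1L; attempt <- 0L
    while (r <= reps) {
      attempt <- attempt + 1L
      if (attempt > 20L * reps) stop("too many failed replicates")
      rep_seed <- child_seed(seed, si * 1000003 + attempt)
      res <- tryCatch(
        with_seed_if(rep_seed, {
          d <- generate_dataset(sc, pilot_n = pilot_n)
          sp <- split_train_test(d, 0.7)
          sapply(names(models), function(mn) {
            fit <- models[[mn]]$fit(sp$train)
            Xte <- sp$test$X
            attr(Xte, "true_labels") <- sp$test$y
            pred <- models[[mn]]$predict(fit, Xte)
            cm <- confusion_metrics(sp$test$y, pred, positive = "1")
            unlist(cm[metrics])
          })
        }),
        error = function(e) e)
      if (inherits(res, "error")) {
        resampled <- resampled + 1L
        next
      }
      vals[r, , ] <- t(res)
      r <- r + 1L
    }
    for (mn in names(models)) for (met in metrics) {
      v <- vals[, mn, met]
      defined <- sum(!is.na(v))
      out <- rbind(out, data.frame(
        p = sc$p, n = sc$n, target_prev = sc$target_prev,
        model = mn, metric = met,
        mean = mean(v, na.rm = TRUE),
        mc_se = stats::sd(v, na.rm = TRUE) / sqrt(max(defined, 1)),
        reps = reps, n_defined = defined, resampled = resampled))
    }
  }
  out
}
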