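#' Deterministic worked datasets
#'
#' Small generated fixtures used throughout the documentation and tests:
#' \describe{
#'   \item{\code{"nb4"}}{4 rows, 1 attribute, two classes; the hand-checkable
#'     naive Bayes example (P(pos) = 0.5, P(x=1|pos) = 1, P(x=1|neg) = 0
#'     without smoothing).}
#'   \item{\code{"sep2"}}{200 unlabeled rows from a well-separated
#'     two-component Bernoulli mixture (10 items at 0.9 vs 0.1, equal
#'     weights); latent class recovery material.}
#'   \item{\code{"xor"}}{200 rows where attributes 1 and 2 agree exactly
#'     under one class and disagree exactly under the other, plus a noise
#'     attribute; invisible to naive Bayes, captured by one augmenting arc.}
#'   \item{\code{"aode2"}}{8 rows, 2 attributes; small enough to enumerate
#'     every one-dependence estimator by hand.}
#'   \item{\code{"gcnud-like"}}{a synthetic stand-in reproducing the schema
#'     of the gastric cancer / non-ulcer dyspepsia questionnaire data:
#'     2165 rows (976 "GC", 1189 "NUD"), 64 binary attributes in five
#'     named subdomain blocks, sampled from a moderate-separation NB-BLCA
#'     generative model. Schema emulation only — not a reconstruction of
#'     the real data.}
#' }
#' All fixtures are byte-identical across calls (fixed internal seeds).
#'
#' @param name fixture name.
#' @return a \code{\link{binary_dataset}}; generative-model fixtures carry
#'   the truth as attributes (\code{"truth"}, \code{"layout"}).
#' @export
make_toy <- function(name = c("nb4", "sep2", "xor", "aode2", "gcnud-like")) {
  name <- match.arg(name)
  switch(
    name,
    nb4 = binary_dataset(matrix(c(1L, 1L, 0L, 0L), 4, 1,
                                dimnames = list(NULL, "x1")),
                         y = c("pos", "pos", "neg", "neg")),
    sep2 = with_seed_if(42, {
      truth <- list(tau = c(0.5, 0.5),
                    theta = rbind(rep(0.9, 10), rep(0.1, 10)))
      g <- sample.int(2, 200, replace = TRUE, prob = truth$tau)
      X <- matrix(stats::rbinom(200 * 10, 1, truth$theta[g, ]), 200, 10)
      d <- binary_dataset(X)
      attr(d, "truth") <- c(truth, list(membership = g))
      d
    }),
    xor = with_seed_if(7, {
      n <- 200
      y <- rep(c("caseA", "caseB"), each = n / 2)
      x1 <- stats::rbinom(n, 1, 0.5)
      x2 <- ifelse(y == "caseA", x1, 1L - x1)
      x3 <- stats::rbinom(n, 1, 0.5)
      binary_dataset(cbind(x1 = x1, x2 = x2, x3 = x3), y = y)
    }),
    aode2 = binary_dataset(
      cbind(x1 = c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L),
            x2 = c(1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L)),
      y = rep(c("pos", "neg"), each = 4)),
    `gcnud-like` = with_seed_if(20165, {
      model <- gcnud_like_model()
      n_gc <- 976L; n_nud <- 1189L
      y <- c(rep("GC", n_gc), rep("NUD", n_nud))
      d <- sample_from_model(model, y = y)
      attr(d, "truth") <- model
      attr(d, "layout") <- model$layout
      d
    })
  )
}

# generative NB-BLCA model behind the gcnud-like fixture: five subdomain
# blocks sized like the questionnaire (64 attributes), 2-3 latent levels
# per block, moderately class-informative latent conditionals
gcnud_like_model <- function() {
  block_names <- c("demographic", "dietary", "medical", "narcotics", "ses")
  sizes <- c(14L, 16L, 14L, 8L, 12L)
  levels <- c(2L, 3L, 2L, 2L, 3L)
  feature_names <- unlist(lapply(seq_along(sizes), function(k)
    paste0(block_names[k], "_q", seq_len(sizes[k]))))
  blocks <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  names(blocks) <- NULL
  layout <- latent_layout(blocks, levels = levels)
  q_c <- c(GC = 976 / 2165, NUD = 1189 / 2165)
  q_lc <- list(); theta <- list()
  for (k in seq_along(sizes)) {
    Gk <- levels[k]
    # class-informative but non-degenerate latent conditionals
    base <- matrix(stats::runif(Gk * 2, 0.05, 0.95), Gk, 2)
    q_lc[[k]] <- sweep(base, 2, colSums(base), "/")
    theta[[k]] <- matrix(stats::runif(Gk * sizes[k], 0.1, 0.9), Gk, sizes[k])
  }
  nbblca_model(q_c, q_lc, theta, layout, prior_config(),
               feature_names = feature_names, blocks_idx = blocks)
}

#' Sample a labeled dataset from an NB-BLCA generative model
#'
#' Forward simulation of the model's factorization: class
#' \eqn{c \sim q(c)}, per block a latent level
#' \eqn{l_k \sim q_k(\cdot | c)}, then each attribute independently
#' \eqn{x \sim Bernoulli(\theta^{(k)}_{l_k m})}.
#'
#' @param model an \code{"nbblca_model"} with resolved \code{blocks_idx} and
#'   \code{feature_names}.
#' @param n number of rows (ignored when \code{y} is given).
#' @param y optional fixed class-label vector (length determines n).
#' @return a labeled \code{\link{binary_dataset}}; the sampled latent levels
#'   are attached as attribute \code{"latent"} (\code{n x K}).
#' @export
sample_from_model <- function(model, n = NULL, y = NULL) {
  classes <- names(model$q_c)
  if (is.null(y)) {
    stopifnot(!is.null(n))
    y <- classes[sample.int(length(classes), n, replace = TRUE,
                            prob = model$q_c)]
  }
  n <- length(y)
  y_idx <- match(y, classes)
  K <- model$layout$K
  M <- length(model$feature_names)
  X <- matrix(0L, n, M, dimnames = list(NULL, model$feature_names))
  latent <- matrix(NA_integer_, n, K)
  for (k in seq_len(K)) {
    Gk <- model$layout$levels[k]
    for (ci in seq_along(classes)) {
      rows <- which(y_idx == ci)
      latent[rows, k] <- sample.int(Gk, length(rows), replace = TRUE,
                                    prob = model$q_lc[[k]][, ci])
    }
    idx <- model$blocks_idx[[k]]
    probs <- model$theta[[k]][latent[, k], , drop = FALSE]
    X[, idx] <- matrix(stats::rbinom(n * length(idx), 1, probs),
                       n, length(idx))
  }
  d <- binary_dataset(X, y = y, class_labels = sort(classes))
  attr(d, "latent") <- latent
  d
}
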