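#' Fit an ordinary naive Bayes classifier for binary attributes
#'
#' Maximum-likelihood (or Laplace-smoothed) estimation of the class prior
#' \eqn{P(C=c)} and the per-class conditional attribute probabilities
#' \eqn{P(X_m = 1 | C = c)}, under the naive assumption that attributes are
#' mutually independent given the class.
#'
#' @param train a labeled \code{\link{binary_dataset}}; every declared class
#'   must appear at least once.
#' @param smoothing nonnegative pseudo-count added to every cell
#'   (\code{1} = Laplace smoothing, the default; \code{0} = pure MLE, which
#'   can produce exactly-zero posteriors).
#' @return Object of class \code{"nb_model"} with elements
#'   \code{class_prior} (named vector, sums to 1), \code{cond_prob}
#'   (\code{|C| x M} matrix of \eqn{P(X_m=1|c)}), \code{smoothing},
#'   \code{classes}, \code{feature_names}.
#' @examples
#' d <- make_toy("nb4")
#' m <- nb_fit(d, smoothing = 0)
#' m$cond_prob
#' @export
nb_fit <- function(train, smoothing = 1) {
  stopifnot(inherits(train, "binary_dataset"), smoothing >= 0)
  if (is.null(train$y)) stop("training data must carry class labels")
  classes <- train$class_labels
  counts <- table(factor(train$y, levels = classes))
  if (any(counts == 0)) stop("class absent from training data: ",
                             paste(classes[counts == 0], collapse = ", "))
  n <- nrow(train$X)
  prior <- (as.numeric(counts) + smoothing) / (n + smoothing * length(classes))
  names(prior) <- classes
  cond <- matrix(NA_real_, length(classes), ncol(train$X),
                 dimnames = list(classes, train$feature_names))
  for (cl in classes) {
    rows <- train$y == cl
    cond[cl, ] <- (colSums(train$X[rows, , drop = FALSE]) + smoothing) /
      (sum(rows) + 2 * smoothing)
  }
  structure(list(class_prior = prior, cond_prob = cond,
                 smoothing = smoothing, classes = classes,
                 feature_names = train$feature_names),
            class = "nb_model")
}

#' Naive Bayes posterior class probabilities
#'
#' Computes, in the log domain, the per-row posterior
#' \eqn{P(c | x) \propto P(c) \prod_m P(x_m | c)} normalized over classes.
#'
#' @param model an \code{"nb_model"} from \code{\link{nb_fit}}.
#' @param X 0/1 matrix (or \code{binary_dataset}) whose columns match the
#'   training attributes.
#' @return \code{N x |C|} matrix of posterior probabilities; rows sum to 1.
#' @export
nb_predict_proba <- function(model, X) {
  X <- as_X(X, model$feature_names)
  lp <- sweep(X %*% t(log_finite(model$cond_prob)) +
                (1 - X) %*% t(log_finite(1 - model$cond_prob)),
              2, log(model$class_prior), "+")
  normalize_log_rows(lp)
}

#' @rdname nb_predict_proba
#' @param ... passed on.
#' @export
predict.nb_model <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- nb_predict_proba(object, X)
  if (type == "prob") return(p)
  argmax_labels(p, object$class_prior)
}

# shared helpers ---------------------------------------------------------

as_X <- function(X, feature_names) {
  if (inherits(X, "binary_dataset")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != length(feature_names))
    stop(sprintf("attribute count mismatch: model has %d, input has %d",
                 length(feature_names), ncol(X)))
  storage.mode(X) <- "double"
  X
}

# log with log(0) mapped to a very large negative *finite* value, so that
# 0 * log(0) inside matrix products is 0 rather than NaN; exp() of any
# resulting row still underflows to an exact 0 posterior
log_finite <- function(p, floor = -1e300) {
  l <- log(p)
  l[l == -Inf] <- floor
  l
}

# rows of exp(lp) normalized to 1, stable under large negative magnitudes
normalize_log_rows <- function(lp) {
  m <- apply(lp, 1L, max)
  m[!is.finite(m)] <- 0  # all -Inf row: fall back to uniform
  w <- exp(lp - m)
  p <- w / rowSums(w)
  dimnames(p) <- dimnames(lp)
  p
}

# deterministic argmax: ties go to the class with larger prior, then to
# the earlier label in class order
argmax_labels <- function(proba, class_prior) {
  classes <- colnames(proba)
  ord <- order(-class_prior, seq_along(classes))  # preference on ties
  apply(proba, 1L, function(r) {
    best <- r[ord]
    classes[ord][which.max(best)]
  })
}
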