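#' Fit averaged one-dependence estimators (AODE)
#'
#' AODE averages, over eligible "super-parent" attributes p, the
#' one-dependence posteriors
#' \eqn{P(c, x_p) \prod_{m \ne p} P(x_m | c, x_p)}; every attribute is
#' conditioned on the class and on one shared parent, and the average over
#' parents removes the need to pick a structure. A parent value is eligible
#' for a test row when its training frequency meets \code{min_support};
#' when no parent qualifies the prediction falls back to naive Bayes.
#'
#' @param train labeled \code{\link{binary_dataset}}.
#' @param smoothing pseudo-count for every probability table (Laplace, 1).
#' @param min_support minimum training occurrences of the parent value for
#'   an estimator to enter the average (default 1; moderate n and binary
#'   attributes make the classical 30 overly conservative).
#' @return Object of class \code{"aode_model"} holding the joint count
#'   arrays \code{n_c}, \code{n_cp} (class x parent x value) and
#'   \code{n_cpm} (class x parent x value x attribute, counting
#'   \eqn{x_m = 1}), plus metadata.
#' @export
aode_fit <- function(train, smoothing = 1, min_support = 1L) {
  stopifnot(inherits(train, "binary_dataset"))
  if (is.null(train$y)) stop("training data must carry class labels")
  classes <- train$class_labels
  X <- train$X; M <- ncol(X); N <- nrow(X)
  C <- length(classes)
  y_idx <- match(train$y, classes)
  n_c <- tabulate(y_idx, C)
  # n_cp[c, p, v+1]: rows in class c with x_p = v
  n_cp <- array(0, c(C, M, 2))
  # n_cpm[c, p, v+1, m]: rows in class c with x_p = v and x_m = 1
  n_cpm <- array(0, c(C, M, 2, M))
  for (ci in seq_len(C)) {
    Xc <- X[y_idx == ci, , drop = FALSE]
    for (p in seq_len(M)) {
      for (v in 0:1) {
        rows <- Xc[, p] == v
        n_cp[ci, p, v + 1] <- sum(rows)
        n_cpm[ci, p, v + 1, ] <- colSums(Xc[rows, , drop = FALSE])
      }
    }
  }
  structure(list(n_c = n_c, n_cp = n_cp, n_cpm = n_cpm, n = N,
                 smoothing = smoothing, min_support = as.integer(min_support),
                 classes = classes, feature_names = train$feature_names,
                 nb = nb_fit(train, smoothing = smoothing)),
            class = "aode_model")
}

#' AODE posterior class probabilities
#'
#' @param model an \code{"aode_model"}.
#' @param X 0/1 matrix or \code{binary_dataset}.
#' @return \code{N x |C|} posterior matrix; rows sum to 1.
#' @export
aode_predict_proba <- function(model, X) {
  X <- as_X(X, model$feature_names)
  C <- length(model$classes); M <- ncol(X); s <- model$smoothing
  out <- matrix(NA_real_, nrow(X), C, dimnames = list(NULL, model$classes))
  parent_count <- apply(model$n_cp, c(2, 3), sum)  # M x 2 totals per value
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    ok <- parent_count[cbind(seq_len(M), x + 1)] >= model$min_support
    if (!any(ok)) {
      out[i, ] <- nb_predict_proba(model$nb, matrix(x, 1))
      next
    }
    score <- matrix(0, C, sum(ok))
    for (jj in seq_along(which(ok))) {
      p <- which(ok)[jj]
      v <- x[p] + 1
      # log P(c, x_p)
      lp <- log((model$n_cp[, p, v] + s) / (model$n + 2 * C * s))
      for (m in seq_len(M)) {
        if (m == p) next
        n1 <- model$n_cpm[, p, v, m]
        nv <- model$n_cp[, p, v]
        pm <- (n1 + s) / (nv + 2 * s)
        lp <- lp + if (x[m] == 1) log(pm) else log1p(-pm)
      }
      score[, jj] <- lp
    }
    # average the one-dependence posteriors on the probability scale
    mx <- max(score)
    joint <- rowMeans(exp(score - mx))
    out[i, ] <- joint / sum(joint)
  }
  out
}

#' @export
predict.aode_model <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- aode_predict_proba(object, X)
  if (type == "prob") return(p)
  prior <- (object$n_c + object$smoothing) /
    (object$n + object$smoothing * length(object$classes))
  names(prior) <- object$classes
  argmax_labels(p, prior)
}

#' Fit tree-augmented naive Bayes by hill climbing
#'
#' Starts from the naive Bayes structure and greedily adds augmenting arcs
#' (one extra attribute parent per attribute, acyclic over the attributes),
#' at each step taking the single arc that most improves the resubstitution
#' (training-set) accuracy of the Laplace-smoothed classifier; stops when no
#' arc improves. Ties break toward the first-enumerated arc, so the search
#' is deterministic.
#'
#' @param train labeled \code{\link{binary_dataset}}.
#' @param smoothing pseudo-count for the conditional tables.
#' @return Object of class \code{"tan_model"}: \code{parent} (integer vector,
#'   \code{NA} = class-only parent), smoothed tables, and \code{score_trace}
#'   (training accuracy after each accepted arc; strictly increasing).
#' @export
tan_hc_fit <- function(train, smoothing = 1) {
  stopifnot(inherits(train, "binary_dataset"))
  if (is.null(train$y)) stop("training data must carry class labels")
  M <- ncol(train$X)
  parent <- rep(NA_integer_, M)
  model <- tan_build(train, parent, smoothing)
  score <- mean(predict(model, train$X) == train$y)
  trace <- score
  repeat {
    best <- NULL
    for (m in seq_len(M)) {
      if (!is.na(parent[m])) next
      for (p in seq_len(M)) {
        if (p == m || tan_would_cycle(parent, m, p)) next
        cand <- parent; cand[m] <- p
        cm <- tan_build(train, cand, smoothing)
        sc <- mean(predict(cm, train$X) == train$y)
        if (sc > score && (is.null(best) || sc > best$score)) {
          best <- list(parent = cand, score = sc, model = cm)
        }
      }
    }
    if (is.null(best)) break
    parent <- best$parent; score <- best$score; model <- best$model
    trace <- c(trace, score)
  }
  model$score_trace <- trace
  model
}

# does adding arc p -> m create a directed cycle among attributes?
tan_would_cycle <- function(parent, m, p) {
  seen <- m
  cur <- p
  while (!is.na(cur)) {
    if (cur %in% seen) return(TRUE)
    seen <- c(seen, cur)
    cur <- parent[cur]
  }
  FALSE
}

# parameterize the classifier for a fixed parent structure
tan_build <- function(train, parent, smoothing) {
  classes <- train$class_labels
  X <- train$X; M <- ncol(X); C <- length(classes)
  y_idx <- match(train$y, classes)
  s <- smoothing
  n_c <- tabulate(y_idx, C)
  prior <- (n_c + s) / (nrow(X) + C * s)
  names(prior) <- classes
  # tables[[m]]: C x 2 matrix of P(x_m = 1 | c, x_parent = v) (or C x 1
  # when m has no attribute parent)
  tables <- vector("list", M)
  for (m in seq_len(M)) {
    if (is.na(parent[m])) {
      t1 <- vapply(seq_len(C), function(ci)
        (sum(X[y_idx == ci, m]) + s) / (n_c[ci] + 2 * s), numeric(1))
      tables[[m]] <- matrix(t1, C, 1)
    } else {
      p <- parent[m]
      tab <- matrix(NA_real_, C, 2)
      for (ci in seq_len(C)) for (v in 0:1) {
        rows <- y_idx == ci & X[, p] == v
        tab[ci, v + 1] <- (sum(X[rows, m]) + s) / (sum(rows) + 2 * s)
      }
      tables[[m]] <- tab
    }
  }
  structure(list(parent = parent, prior = prior, tables = tables,
                 classes = classes, feature_names = train$feature_names,
                 smoothing = s),
            class = "tan_model")
}

#' TAN posterior class probabilities
#'
#' @param model a \code{"tan_model"} from \code{\link{tan_hc_fit}}.
#' @param X 0/1 matrix or \code{binary_dataset}.
#' @return \code{N x |C|} posterior matrix; rows sum to 1.
#' @export
tan_predict_proba <- function(model, X) {
  X <- as_X(X, model$feature_names)
  C <- length(model$classes)
  lp <- matrix(rep(log(model$prior), each = nrow(X)), nrow(X), C,
               dimnames = list(NULL, model$classes))
  for (m in seq_along(model$tables)) {
    tab <- model$tables[[m]]
    v <- if (is.na(model$parent[m])) rep(1L, nrow(X)) else X[, model$parent[m]] + 1L
    pm <- t(tab)[v, , drop = FALSE]      # N x C of P(x_m = 1 | c, pa)
    lp <- lp + log(pm) * X[, m] + log1p(-pm) * (1 - X[, m])
  }
  normalize_log_rows(lp)
}

#' @export
predict.tan_model <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- tan_predict_proba(object, X)
  if (type == "prob") return(p)
  argmax_labels(p, object$prior)
}
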