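#' Confusion-matrix validity metrics
#'
#' Two-class confusion counts and the derived rates, reported as
#' percentages: sensitivity (recall) \eqn{100\,TP/(TP+FN)}, specificity
#' \eqn{100\,TN/(TN+FP)}, positive and negative predictive values, precision
#' (identically the PPV; both are reported because both columns are
#' conventional), accuracy and balanced accuracy. Rates with a zero
#' denominator are reported as \code{NA}, never as 0, so aggregated means
#' are not silently biased.
#'
#' @param y_true,y_pred equal-length label vectors from a two-class label set.
#' @param positive the positive class; default: the lexicographically second
#'   of the observed labels.
#' @return list with \code{table} (the \code{TP/FP/FN/TN} counts),
#'   \code{positive}, and the metric fields (percent scale).
#' @examples
#' confusion_metrics(c("a","b","b","a"), c("a","b","a","a"), positive = "b")
#' @export
confusion_metrics <- function(y_true, y_pred, positive = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  labels <- sort(unique(c(y_true, y_pred)))
  if (length(labels) > 2L)
    stop("binary confusion metrics require a two-class label set")
  if (is.null(positive)) positive <- labels[length(labels)]
  tp <- sum(y_pred == positive & y_true == positive)
  fp <- sum(y_pred == positive & y_true != positive)
  fn <- sum(y_pred != positive & y_true == positive)
  tn <- sum(y_pred != positive & y_true != positive)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- rate(tp, tp + fn); spec <- rate(tn, tn + fp)
  list(table = c(TP = tp, FP = fp, FN = fn, TN = tn),
       positive = positive,
       sensitivity = sens, specificity = spec,
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
       precision = rate(tp, tp + fp),
       accuracy = rate(tp + tn, tp + fp + fn + tn),
       balanced_accuracy = (sens + spec) / 2)
}

#' Accuracy with exact confidence interval and no-information-rate test
#'
#' Accuracy with its exact (Clopper-Pearson) 95% binomial confidence
#' interval, the no-information rate (NIR, the largest class share of the
#' truth), and the one-sided exact binomial p-value for accuracy exceeding
#' the NIR.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return list with \code{accuracy}, \code{ci} (length-2, percent),
#'   \code{nir} (percent), and \code{p_acc_gt_nir}.
#' @export
accuracy_inference <- function(y_true, y_pred, conf_level = 0.95) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  n <- length(y_true)
  correct <- sum(as.character(y_true) == as.character(y_pred))
  bt <- stats::binom.test(correct, n, conf.level = conf_level)
  nir <- max(table(y_true)) / n
  p <- stats::binom.test(correct, n, p = nir, alternative = "greater")$p.value
  list(accuracy = 100 * correct / n,
       ci = 100 * as.numeric(bt$conf.int),
       nir = 100 * nir,
       p_acc_gt_nir = p)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)}, with expected
#' agreement \eqn{p_e} from the marginal label distributions. \code{NA}
#' when \eqn{p_e = 1} (degenerate marginals).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return kappa in \eqn{[-1, 1]}, or \code{NA}.
#' @export
kappa_statistic <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  labels <- sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  p_o <- mean(y_true == y_pred)
  pt <- table(factor(y_true, labels)) / n
  pp <- table(factor(y_pred, labels)) / n
  p_e <- sum(as.numeric(pt) * as.numeric(pp))
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' McNemar's test for paired classifiers
#'
#' Compares two classifiers on the same cases through their discordant
#' counts b (A right, B wrong) and c (A wrong, B right): exact two-sided
#' binomial test when \eqn{b + c \le 25}, continuity-corrected chi-squared
#' otherwise; \eqn{p = 1} when there are no discordant pairs.
#'
#' @param y_true truth labels.
#' @param pred_a,pred_b paired predictions of the two classifiers.
#' @return list with \code{b}, \code{c}, \code{p_value}, \code{method}.
#' @export
mcnemar_test <- function(y_true, pred_a, pred_b) {
  stopifnot(length(y_true) == length(pred_a), length(y_true) == length(pred_b))
  right_a <- as.character(pred_a) == as.character(y_true)
  right_b <- as.character(pred_b) == as.character(y_true)
  b <- sum(right_a & !right_b)
  cc <- sum(!right_a & right_b)
  if (b + cc == 0) {
    return(list(b = b, c = cc, p_value = 1, method = "no discordant pairs"))
  }
  if (b + cc <= 25) {
    p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
    method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "continuity-corrected chi-squared"
  }
  list(b = b, c = cc, p_value = min(p, 1), method = method)
}

#' Full validity report for one prediction vector
#'
#' Bundles \code{\link{confusion_metrics}}, \code{\link{accuracy_inference}}
#' and \code{\link{kappa_statistic}} into the standard report layout
#' (accuracy and CI, NIR and its p-value, kappa, sensitivity, specificity,
#' predictive values, balanced accuracy).
#'
#' @inheritParams confusion_metrics
#' @return named list (class \code{"metrics_report"}).
#' @export
metrics_report <- function(y_true, y_pred, positive = NULL) {
  cm <- confusion_metrics(y_true, y_pred, positive)
  ai <- accuracy_inference(y_true, y_pred)
  structure(c(list(accuracy = ai$accuracy, accuracy_ci = ai$ci,
                   nir = ai$nir, p_acc_gt_nir = ai$p_acc_gt_nir,
                   kappa = kappa_statistic(y_true, y_pred)),
              cm[c("sensitivity", "specificity", "ppv", "npv", "precision",
                   "balanced_accuracy", "table", "positive")]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy (95%% CI)        %.2f (%.2f-%.2f)\n",
              x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2]))
  cat(sprintf("No information rate      %.2f\n", x$nir))
  cat(sprintf("P-Value [Acc > NIR]      %s\n", format.pval(x$p_acc_gt_nir, digits = 3)))
  cat(sprintf("Kappa                    %.2f\n", x$kappa))
  for (f in c("sensitivity", "specificity", "ppv", "npv", "balanced_accuracy"))
    cat(sprintf("%-24s %.2f\n", c(sensitivity = "Sensitivity",
                                  specificity = "Specificity",
                                  ppv = "Pos Pred Value",
                                  npv = "Neg Pred Value",
                                  balanced_accuracy = "Balanced Accuracy")[[f]],
                x[[f]]))
  invisible(x)
}

#' k-fold cross-validation of a registered model
#'
#' Seeded random fold partition; each fold is held out once while the model
#' is fitted on the remainder. Per-fold metrics and the pooled confusion
#' table are both reported (pooling adds the per-fold counts before
#' computing rates).
#'
#' @param model_spec a model name understood by \code{\link{model_registry}}
#'   (e.g. \code{"nb"}, \code{"nbblca_em"}) or a list with \code{fit(train)}
#'   and \code{predict(fit, X)} functions.
#' @param dataset labeled \code{\link{binary_dataset}} with at least k rows.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold assignment and any fit
#'   randomness.
#' @param positive positive class for the binary metrics.
#' @return list with \code{folds} (list of per-fold \code{metrics_report}),
#'   \code{pooled} (\code{metrics_report} over the concatenated held-out
#'   predictions) and \code{fold_id}.
#' @export
kfold_cv <- function(model_spec, dataset, k = 10L, seed = NULL,
                     positive = NULL) {
  stopifnot(inherits(dataset, "binary_dataset"), k >= 2)
  n <- nrow(dataset$X)
  if (n < k) stop("need at least k rows")
  spec <- if (is.character(model_spec)) model_registry(model_spec) else model_spec
  fold_id <- with_seed_if(seed, sample(rep_len(seq_len(k), n)))
  pred_all <- character(n)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    train <- dataset_rows(dataset, setdiff(seq_len(n), test_idx))
    fit <- with_seed_if(child_seed(seed, f), spec$fit(train))
    pred <- spec$predict(fit, dataset$X[test_idx, , drop = FALSE])
    pred_all[test_idx] <- pred
    folds[[f]] <- metrics_report(dataset$y[test_idx], pred, positive)
  }
  list(folds = folds,
       pooled = metrics_report(dataset$y, pred_all, positive),
       fold_id = fold_id)
}
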