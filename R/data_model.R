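#' Construct a binary-attribute dataset
#'
#' The universal input container of the package: an \code{N x M} matrix of
#' 0/1 attribute indicators with an optional categorical class label per row.
#' Class labels are kept as character strings; for two-class problems the
#' "positive" class of the evaluation metrics defaults to the
#' lexicographically second label (see \code{\link{confusion_metrics}}).
#'
#' @param X numeric or integer matrix (or data frame) whose entries are all
#'   exactly 0 or 1. Column names are used as feature names; unnamed columns
#'   are named \code{f1, f2, ...}.
#' @param y optional class-label vector of length \code{nrow(X)} (character,
#'   factor or numeric; stored as character). \code{NULL} for unlabeled data.
#' @param class_labels optional ordered character vector of admissible labels;
#'   defaults to the sorted unique values of \code{y}.
#' @return An object of class \code{"binary_dataset"}: a list with elements
#'   \code{X} (integer matrix), \code{y} (character or \code{NULL}),
#'   \code{feature_names} and \code{class_labels}.
#' @examples
#' d <- binary_dataset(matrix(c(0, 1, 1, 1, 0, 0), 3, 2), y = c("a", "b", "a"))
#' d$class_labels
#' @export
binary_dataset <- function(X, y = NULL, class_labels = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("dataset must have at least one row and one attribute column")
  bad <- which(!(X == 0 | X == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary attribute value %s at row %d, column %d",
                 format(X[bad[1L, 1L], bad[1L, 2L]]), bad[1L, 1L], bad[1L, 2L]))
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(y)) {
    y <- as.character(y)
    if (length(y) != nrow(X))
      stop("class-label vector length does not match number of rows")
    if (is.null(class_labels)) class_labels <- sort(unique(y))
    if (!all(y %in% class_labels))
      stop("class labels outside the declared label set: ",
           paste(setdiff(unique(y), class_labels), collapse = ", "))
  } else if (is.null(class_labels)) {
    class_labels <- character(0)
  }
  structure(list(X = X, y = y,
                 feature_names = colnames(X),
                 class_labels = as.character(class_labels)),
            class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf("binary_dataset: %d rows, %d attributes%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y)) " (unlabeled)" else
                sprintf(", classes: %s", paste(x$class_labels, collapse = "/"))))
  if (!is.null(x$y)) print(table(class = x$y))
  invisible(x)
}

#' @export
dim.binary_dataset <- function(x) dim(x$X)

# row subset, keeping labels aligned
dataset_rows <- function(d, idx) {
  binary_dataset(d$X[idx, , drop = FALSE],
                 y = if (is.null(d$y)) NULL else d$y[idx],
                 class_labels = if (length(d$class_labels)) d$class_labels else NULL)
}

#' Read a binary-attribute dataset from delimited text
#'
#' Reads a CSV (or TSV) file with a header row. All columns except the class
#' column must contain only 0/1 values; the class column may hold any
#' categorical labels.
#'
#' @param path file path.
#' @param class_column name of the class-label column, or \code{NULL} when the
#'   file holds unlabeled attribute data only.
#' @param sep field separator, \code{","} by default (use \code{"\t"} for TSV).
#' @return A \code{\link{binary_dataset}}; row order is preserved.
#' @export
read_dataset <- function(path, class_column = "class", sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  y <- NULL
  if (!is.null(class_column) && class_column %in% names(df)) {
    y <- df[[class_column]]
    df <- df[setdiff(names(df), class_column)]
  } else if (!is.null(class_column)) {
    class_column <- NULL
  }
  if (ncol(df) == 0L) stop("no attribute columns in ", path)
  X <- matrix(NA_integer_, nrow(df), ncol(df),
              dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- df[[j]]
    ok <- v %in% c("0", "1")
    if (!all(ok))
      stop(sprintf("non-binary value \"%s\" at row %d, column \"%s\"",
                   v[which(!ok)[1L]], which(!ok)[1L], names(df)[j]))
    X[, j] <- as.integer(v)
  }
  binary_dataset(X, y = y)
}

#' Write a binary-attribute dataset to delimited text
#'
#' Inverse of \code{\link{read_dataset}}: writing then reading a valid
#' dataset reproduces it exactly.
#'
#' @param dataset a \code{\link{binary_dataset}}.
#' @param path output file path.
#' @param class_column name for the class column (ignored for unlabeled data).
#' @param sep field separator.
#' @export
write_dataset <- function(dataset, path, class_column = "class", sep = ",") {
  stopifnot(inherits(dataset, "binary_dataset"))
  df <- as.data.frame(dataset$X)
  if (!is.null(dataset$y)) df[[class_column]] <- dataset$y
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into training and test parts
#'
#' Uniform random partition of the rows, as used for the 70/30 train/test
#' evaluation protocol. Optionally stratified by class label.
#'
#' @param dataset a \code{\link{binary_dataset}} with at least 2 rows.
#' @param train_fraction fraction of rows assigned to the training part
#'   (strictly between 0 and 1); the training size is
#'   \code{round(N * train_fraction)}.
#' @param seed optional integer; when given, the split is a deterministic
#'   function of it (the caller's RNG state is left untouched).
#' @param stratify if \code{TRUE}, sample within each class so both parts
#'   approximate the overall class proportions. Default \code{FALSE}: the
#'   protocol specifies simple random selection.
#' @return List with elements \code{train} and \code{test} (both
#'   \code{binary_dataset}) and the integer index vector \code{train_idx}.
#' @export
split_train_test <- function(dataset, train_fraction = 0.7, seed = NULL,
                             stratify = FALSE) {
  stopifnot(inherits(dataset, "binary_dataset"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(dataset$X)
  if (n < 2L) stop("need at least 2 rows to split")
  idx <- with_seed_if(seed, {
    if (stratify && !is.null(dataset$y)) {
      n_train <- round(n * train_fraction)
      parts <- split(seq_len(n), dataset$y)
      take <- unlist(lapply(parts, function(p)
        sample(p, round(length(p) * train_fraction))), use.names = FALSE)
      # adjust to the exact target size by moving random rows
      if (length(take) > n_train) take <- sample(take, n_train)
      else if (length(take) < n_train)
        take <- c(take, sample(setdiff(seq_len(n), take), n_train - length(take)))
      sort(take)
    } else {
      sort(sample(n, round(n * train_fraction)))
    }
  })
  list(train = dataset_rows(dataset, idx),
       test = dataset_rows(dataset, setdiff(seq_len(n), idx)),
       train_idx = idx)
}

#' Prior hyperparameters for the latent class layers
#'
#' Conjugate Beta priors on the item-response probabilities and a Dirichlet
#' prior on the mixing weights. Scalars are recycled to the needed
#' \code{G x M} / length-\code{G} shapes at fit time. The defaults
#' (\code{alpha = beta = delta = 1}) are flat: the MAP EM update then
#' coincides with maximum likelihood and stays interior.
#'
#' @param alpha,beta first and second Beta shape for every item probability;
#'   scalar, or \code{G x M} matrix. Must be strictly positive; the EM (MAP)
#'   learners additionally require \code{alpha, beta >= 1} so the mode is
#'   interior.
#' @param delta Dirichlet concentration for the mixing weights; scalar or
#'   length-\code{G} vector, strictly positive.
#' @return An object of class \code{"prior_config"}.
#' @export
prior_config <- function(alpha = 1, beta = 1, delta = 1) {
  if (any(alpha <= 0) || any(beta <= 0) || any(delta <= 0))
    stop("all prior hyperparameters must be strictly positive")
  structure(list(alpha = alpha, beta = beta, delta = delta),
            class = "prior_config")
}

# recycle prior hyperparameters to G x M matrices / length-G vector
expand_priors <- function(priors, G, M) {
  to_mat <- function(v) {
    if (is.matrix(v)) {
      stopifnot(nrow(v) == G, ncol(v) == M)
      v
    } else matrix(v, G, M)
  }
  list(alpha = to_mat(priors$alpha), beta = to_mat(priors$beta),
       delta = rep_len(priors$delta, G))
}

#' Run configuration for the iterative learners
#'
#' @param seed integer seed governing all randomness of a fit (restarts,
#'   Gibbs initialization and draws); \code{NULL} to use the current RNG state.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the relative change of the EM
#'   log-posterior objective.
#' @param n_restarts number of random EM restarts; the best final
#'   log-posterior wins. Ten restarts are the recommended guard against
#'   local optima of the mixture likelihood.
#' @param gibbs_iters,burn_in,thin Gibbs sweep count, discarded initial
#'   sweeps, and retention stride. A burn-in of 1000 within 5000 sweeps
#'   follows the usual rule of discarding the first 1000-5000 draws.
#' @param chains number of independent Gibbs chains (multi-start sensitivity).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(seed = NULL, max_iter = 1000L, tol = 1e-8,
                       n_restarts = 10L, gibbs_iters = 5000L,
                       burn_in = 1000L, thin = 5L, chains = 1L) {
  stopifnot(tol > 0, max_iter >= 1, n_restarts >= 1,
            burn_in < gibbs_iters, thin >= 1, chains >= 1)
  structure(list(seed = seed, max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts),
                 gibbs_iters = as.integer(gibbs_iters),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains)),
            class = "run_config")
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# with seed = NULL just evaluates.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a distinct child seed from a base seed (kept below 2^31)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}
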