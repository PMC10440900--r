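#' Serialize a fitted model to JSON
#'
#' Writes all parameter arrays of a naive Bayes or NB-BLCA model (plus the
#' layout and class labels) as plain JSON, round-trippable with
#' \code{\link{read_model_json}}.
#'
#' @param model an \code{"nb_model"} or \code{"nbblca_model"} (an
#'   \code{"nbblca_fit"} is unwrapped to its model).
#' @param path output file path.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "nbblca_fit")) model <- model$model
  obj <- if (inherits(model, "nb_model")) {
    list(type = "nb",
         classes = model$classes,
         feature_names = model$feature_names,
         class_prior = as.numeric(model$class_prior),
         cond_prob = unclass(model$cond_prob),
         smoothing = model$smoothing)
  } else if (inherits(model, "nbblca_model")) {
    list(type = "nbblca",
         classes = names(model$q_c),
         feature_names = model$feature_names,
         q_c = as.numeric(model$q_c),
         q_lc = model$q_lc,
         theta = model$theta,
         blocks = model$blocks_idx,
         levels = model$layout$levels)
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path a file written by \code{\link{write_model_json}}.
#' @return the reconstructed \code{"nb_model"} or \code{"nbblca_model"}.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "nb")) {
    cond <- matrix(as.numeric(obj$cond_prob), length(obj$classes),
                   length(obj$feature_names),
                   dimnames = list(obj$classes, obj$feature_names),
                   byrow = FALSE)
    structure(list(class_prior = stats::setNames(obj$class_prior, obj$classes),
                   cond_prob = cond, smoothing = obj$smoothing,
                   classes = obj$classes, feature_names = obj$feature_names),
              class = "nb_model")
  } else if (identical(obj$type, "nbblca")) {
    # simplifyVector collapses homogeneous lists (equal-size blocks) into
    # arrays/matrices; restore the per-block list structure either way
    relist_matrices <- function(x) {
      if (is.array(x) && length(dim(x)) == 3L)
        lapply(seq_len(dim(x)[1L]), function(i)
          matrix(x[i, , ], dim(x)[2L], dim(x)[3L]))
      else lapply(x, function(m) rbind(m))
    }
    blocks <- if (is.matrix(obj$blocks))
      lapply(seq_len(nrow(obj$blocks)), function(i) as.integer(obj$blocks[i, ]))
    else lapply(obj$blocks, as.integer)
    layout <- latent_layout(blocks, levels = as.integer(obj$levels))
    q_lc <- relist_matrices(obj$q_lc)
    theta <- relist_matrices(obj$theta)
    nbblca_model(stats::setNames(as.numeric(obj$q_c), obj$classes),
                 q_lc, theta, layout, prior_config(),
                 feature_names = obj$feature_names, blocks_idx = blocks)
  } else stop("unknown model type in ", path)
}
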