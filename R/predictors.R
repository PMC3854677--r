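#' Predictor objects
#'
#' A `ddi_predictor` bundles a name with a function that, given an
#' observed (training) network and a matrix of query pairs, returns a
#' matrix of interaction-type probabilities (one row per pair, one column
#' per type).  All evaluation protocols accept any such object, so the
#' block-model predictor and the three comparison predictors run under
#' identical conditions.
#'
#' @param config a [sampler_config()] / [prism_config()] where relevant.
#' @return a `ddi_predictor`.
#' @name predictors
NULL

new_predictor <- function(name, fn) {
  structure(list(name = name, fn = fn), class = "ddi_predictor")
}

#' @export
print.ddi_predictor <- function(x, ...) {
  cat("Predictor:", x$name, "\n")
  invisible(x)
}

#' @rdname predictors
#' @export
baseline_predictor <- function() {
  new_predictor("baseline", function(net, pairs) {
    p <- baseline_predict(net)
    matrix(p, nrow(pairs), length(p), byrow = TRUE,
           dimnames = list(NULL, names(p)))
  })
}

#' @rdname predictors
#' @export
neighbor_predictor <- function() {
  new_predictor("neighbor", function(net, pairs) {
    S <- similarity_table(net)
    t(apply(pairs, 1L, function(pr) neighbor_predict(net, pr, S = S)))
  })
}

#' @rdname predictors
#' @export
prism_predictor <- function(config = prism_config()) {
  new_predictor("prism", function(net, pairs) {
    tree <- prism_build_tree(net, config)
    groups <- suppressWarnings(prism_cut_tree(tree, net, config))
    t(apply(pairs, 1L, function(pr) prism_predict(net, groups, pr)))
  })
}

#' @rdname predictors
#' @param mode observation semantics for the sampler, see [compute_H()].
#' @export
sbm_predictor <- function(config = sampler_config(), mode = "heldout") {
  force(config); force(mode)
  new_predictor("sbm", function(net, pairs) {
    samples <- run_sampler(net, config, mode)
    qi <- match(pairs[, 1L], net$drugs)
    qj <- match(pairs[, 2L], net$drugs)
    if (anyNA(qi) || anyNA(qj)) stop("unknown drug in query pairs")
    qt <- pair_view_types(samples$view, qi, qj)
    p <- sbm_posterior_cpp(samples$assign, samples$view$edges,
                           samples$view$N, samples$view$K,
                           qi - 1L, qj - 1L, qt)
    colnames(p) <- net$alphabet$labels
    p
  })
}

#' Predict interaction-type probabilities for query pairs
#'
#' @param predictor a `ddi_predictor`.
#' @param net the observed [interaction_network()] to condition on.
#' @param pairs two-column matrix of drug names.
#' @return numeric matrix, one row per pair, one type per column.
#' @export
predict_pairs <- function(predictor, net, pairs) {
  stopifnot(inherits(predictor, "ddi_predictor"))
  if (is.null(dim(pairs))) pairs <- matrix(pairs, nrow = 1L)
  predictor$fn(net, pairs)
}
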