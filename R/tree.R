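#' Fit a weighted 1-D regression tree
#'
#' CART-style regression tree on a single feature: greedy binary splits at
#' midpoints between consecutive distinct feature values, chosen to minimize
#' the weighted squared error; leaf values are weighted means of the targets.
#' Splitting stops at `max_depth`, at fewer than 2 examples, when all feature
#' values are equal, or when no split reduces the weighted SSE (ties between
#' equally good splits resolve to the lowest threshold). Degenerate data
#' (all features equal) yields a single-leaf tree, not an error.
#'
#' This is the weak learner inside [adaboost_r2()]; it is exported mainly so
#' its mechanics can be inspected and verified directly.
#'
#' @param x feature values (here: non-invasive readings, mg/dl).
#' @param y targets (here: additive differences, mg/dl).
#' @param w non-negative example weights; default uniform.
#' @param max_depth maximum tree depth (root = depth 0); >= 1.
#' @return an object of class `"regtree1d"` wrapping the node table.
#' @export
tree_fit <- function(x, y, w = rep(1, length(x)), max_depth = 10L) {
  if (length(x) != length(y) || length(x) != length(w))
    stopf("`x`, `y` and `w` must have equal length")
  if (length(x) < 1L) stopf("empty training data")
  if (max_depth < 1L) stopf("`max_depth` must be >= 1")
  if (any(w < 0)) stopf("weights must be non-negative")
  structure(list(nodes = .tree_fit_cpp(as.numeric(x), as.numeric(y),
                                       as.numeric(w), as.integer(max_depth))),
            class = "regtree1d")
}

#' @rdname tree_fit
#' @param tree a fitted `"regtree1d"` object.
#' @param newx feature values to predict at.
#' @export
tree_predict <- function(tree, newx) {
  stopifnot(inherits(tree, "regtree1d"))
  .tree_predict_cpp(tree$nodes, as.numeric(newx))
}

#' @export
print.regtree1d <- function(x, ...) {
  n_leaf <- sum(is.na(x$nodes[, "threshold"]))
  cat(sprintf("1-D regression tree: %d nodes (%d leaves)\n",
              nrow(x$nodes), n_leaf))
  invisible(x)
}

#' @export
predict.regtree1d <- function(object, newdata, ...) tree_predict(object, newdata)
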