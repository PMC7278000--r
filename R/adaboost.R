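# AdaBoost.R2 regression boosting (Drucker 1997) with a learning-rate
# modified weight update, used here as an error-prediction model: the
# feature is the non-invasive reading x, the target the additive difference
# d = y - x, and the corrected reading is z = x + d_pred.

BETA_MIN <- 1e-10
BETA_MAX <- 1 - 1e-10

# Per-example loss in [0,1] from raw absolute losses and their supremum.
# linear: l/den; square: (l/den)^2; exponential: 1 - exp(-l/den).
boost_loss <- function(l, den, kind = c("linear", "square", "exponential")) {
  kind <- match.arg(kind)
  if (den <= 0) return(rep(0, length(l)))  # perfect round; caller stops early
  r <- l / den
  switch(kind,
         linear = r,
         square = r^2,
         exponential = 1 - exp(-r))
}

# Weighted average loss: sum(L * D) over the weight distribution.
boost_average_loss <- function(L, D) {
  if (length(L) != length(D)) stopf("loss/weight length mismatch")
  sum(L * D)
}

# Confidence beta = Lavg / (1 - Lavg), clamped into (0,1) so that the
# log(1/beta) vote weights stay finite even for perfect rounds.
boost_beta <- function(L_avg) {
  min(max(L_avg / (1 - L_avg), BETA_MIN), BETA_MAX)
}

# Learning-rate modified multiplicative weight update
# D'(i) = D(i) * beta^(alpha * (1 - L(i))), renormalized to sum 1.
# With alpha = 1 this is Drucker's original update.
boost_update_weights <- function(D, beta, L, alpha) {
  D2 <- D * beta^(alpha * (1 - L))
  D2 / sum(D2)
}

#' Weighted median
#'
#' The confidence-weighted median used to combine the ensemble's round
#' predictions: values are sorted, their weights accumulated in sorted
#' order, and the first value at which the cumulative weight reaches at
#' least half the total weight is returned (the infimum form of the boosted
#' regression combination rule).
#'
#' @param values numeric vector.
#' @param weights non-negative weights, same length.
#' @return the weighted median (one of `values`).
#' @export
#' @examples
#' weighted_median(c(1, 2, 10), c(1, 1, 1))  # 2
weighted_median <- function(values, weights) {
  if (length(values) != length(weights)) stopf("value/weight length mismatch")
  if (length(values) == 0L) stopf("empty input to weighted_median()")
  ord <- order(values)
  cw <- cumsum(weights[ord])
  values[ord][which(cw >= 0.5 * cw[length(cw)])[1]]
}

#' Fit an AdaBoost.R2 error-prediction ensemble
#'
#' Boosted regression of the additive difference `d = y - x` on the
#' non-invasive reading `x`. Each round draws a bootstrap sample of size `m`
#' from the current weight distribution (weighted fitting by resampling, as
#' in Drucker's original scheme), fits a 1-D regression tree, computes the
#' per-example losses on the full training set normalized by their supremum
#' `den_t`, the weighted average loss, the confidence
#' `beta_t = Lavg/(1 - Lavg)`, and updates the weights by
#' `D(i) * beta_t^(alpha * (1 - L_t(i)))` followed by renormalization.
#' Boosting stops early when the average loss reaches 0.5 (that round is
#' discarded) or when a round fits the training set perfectly (`den_t = 0`;
#' the round is kept with minimal beta). If the very first round already has
#' average loss >= 0.5 the model keeps it as a single best-effort round and
#' sets the `degenerate` flag.
#'
#' @param x non-invasive readings (feature), mg/dl.
#' @param d additive differences `y - x` (target), mg/dl.
#' @param n_estimators maximum number of boosting rounds (>= 1).
#' @param max_depth weak-learner tree depth.
#' @param alpha learning rate in (0, 1]; `alpha = 1` recovers the original
#'   AdaBoost.R2 update.
#' @param loss loss shape: `"linear"`, `"square"` or `"exponential"`.
#' @param seed integer seed; fits are fully deterministic given the seed.
#' @return an object of class `"adaboost_r2"`: list with `trees`, `betas`,
#'   `alpha`, `loss`, `n_rounds`, `seed`, `degenerate`, and the training
#'   data ranges.
#' @seealso [predict.adaboost_r2()], [tree_fit()]
#' @export
adaboost_r2 <- function(x, d, n_estimators = 200L, max_depth = 10L,
                        alpha = 1, loss = c("linear", "square", "exponential"),
                        seed = 1L) {
  loss <- match.arg(loss)
  m <- length(x)
  if (m < 2L) stopf("need at least 2 training pairs")
  if (length(d) != m) stopf("`x` and `d` must have equal length")
  if (n_estimators < 1L) stopf("`n_estimators` must be >= 1")
  if (alpha <= 0 || alpha > 1) stopf("`alpha` must be in (0, 1]")

  trees <- vector("list", n_estimators)
  betas <- numeric(n_estimators)
  degenerate <- FALSE
  t_kept <- 0L

  with_seed(seed, {
    D <- rep(1 / m, m)
    for (t in seq_len(n_estimators)) {
      idx <- sample.int(m, m, replace = TRUE, prob = D)
      tr <- tree_fit(x[idx], d[idx], max_depth = max_depth)
      pred <- tree_predict(tr, x)
      l <- abs(pred - d)
      den <- max(l)
      if (den <= 1e-12) {          # perfect round: keep with minimal beta, stop
        t_kept <- t_kept + 1L
        trees[[t_kept]] <- tr
        betas[t_kept] <- BETA_MIN
        break
      }
      L <- boost_loss(l, den, loss)
      L_avg <- boost_average_loss(L, D)
      if (L_avg >= 0.5) {
        if (t_kept == 0L) {        # zero usable rounds: keep best effort
          t_kept <- 1L
          trees[[1L]] <- tr
          betas[1L] <- BETA_MAX
          degenerate <- TRUE
        }
        break
      }
      beta <- boost_beta(L_avg)
      t_kept <- t_kept + 1L
      trees[[t_kept]] <- tr
      betas[t_kept] <- beta
      D <- boost_update_weights(D, beta, L, alpha)
    }
  })

  structure(list(trees = trees[seq_len(t_kept)],
                 betas = betas[seq_len(t_kept)],
                 alpha = alpha, loss = loss,
                 n_rounds = t_kept, seed = as.integer(seed),
                 degenerate = degenerate,
                 x = as.numeric(x), d = as.numeric(d)),
            class = "adaboost_r2")
}

#' Predict additive differences from a boosted ensemble
#'
#' Evaluates every round's tree at the new readings and combines them by the
#' confidence-weighted median with vote weights `alpha * log(1/beta_t)`
#' (the `alpha` factor scales both sides of the median inequality and so
#' leaves the selected value unchanged; it is carried as stated for
#' faithfulness to the learning-rate formulation).
#'
#' @param object a fitted [adaboost_r2()] model.
#' @param newdata non-invasive readings, mg/dl.
#' @param ... unused.
#' @return predicted additive differences `d_pred`, mg/dl.
#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  newdata <- as.numeric(newdata)
  P <- vapply(object$trees, tree_predict, numeric(length(newdata)),
              newx = newdata)
  P <- matrix(P, nrow = length(newdata))
  w <- object$alpha * log(1 / object$betas)
  apply(P, 1L, weighted_median, weights = w)
}

#' Corrected glucose reading
#'
#' The corrected (predicted) glucose value `z = x + d_pred`, clipped to the
#' physiologically plausible range 20-600 mg/dl.
#'
#' @param model a fitted [adaboost_r2()] model.
#' @param x non-invasive readings, mg/dl.
#' @return corrected glucose values, mg/dl.
#' @export
predict_glucose <- function(model, x) {
  z <- x + predict(model, x)
  pmin(pmax(z, 20), 600)
}

#' @export
print.adaboost_r2 <- function(x, ...) {
  cat(sprintf("AdaBoost.R2 error-prediction model (%s loss)\n", x$loss))
  cat(sprintf("  rounds: %d, alpha: %g, seed: %d%s\n", x$n_rounds, x$alpha,
              x$seed, if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  beta range: [%.3g, %.3g]\n", min(x$betas), max(x$betas)))
  invisible(x)
}

#' @export
residuals.adaboost_r2 <- function(object, ...) {
  object$d - predict(object, object$x)
}
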