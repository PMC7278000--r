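# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test
# (except where a shared weak learner is the point of the comparison).

# --- metrics -----------------------------------------------------------

oracle_signed_error <- function(ref, v) 100 * (ref - v) / ref

oracle_mard <- function(ref, vals) {
  s <- 0
  for (k in seq_along(ref)) s <- s + abs(vals[k] - ref[k]) / ref[k]
  100 * s / length(ref)
}

oracle_rmse <- function(d, d_pred) {
  s <- 0
  for (i in seq_along(d)) s <- s + (d[i] - d_pred[i])^2
  sqrt(s / length(d))
}

# --- Clarke error grid -------------------------------------------------

# Interval-based re-derivation: for a fixed reference value, the estimate
# axis is partitioned into zone intervals built from the boundary curves;
# the zone is located by interval membership rather than by the rule-order
# cascade used in the implementation.
oracle_clarke_zone <- function(ref, est) {
  in_A <- (ref <= 70 && est <= 70) || (est >= 0.8 * ref && est <= 1.2 * ref)
  if (in_A) return("A")
  in_E <- (ref >= 180 && est <= 70) || (ref <= 70 && est >= 180)
  if (in_E) return("E")
  upper_C <- ref >= 70 && ref <= 290 && est >= ref + 110
  lower_C <- ref >= 130 && ref <= 180 && est <= 1.4 * ref - 182
  if (upper_C || lower_C) return("C")
  band <- est >= 70 && est <= 180
  in_D <- (ref >= 240 && band) || (ref <= 175 / 3 && band) ||
    (ref >= 175 / 3 && ref <= 70 && est >= 1.2 * ref)
  if (in_D) return("D")
  "B"
}

# --- regression tree ---------------------------------------------------

# Exhaustive depth-1 split: tries every midpoint between consecutive
# distinct x values and minimizes the total weighted SSE directly.
oracle_best_split <- function(x, y, w) {
  xs <- sort(unique(x))
  best <- list(sse = Inf, threshold = NA, left = NA, right = NA)
  wmean <- function(v, ww) sum(ww * v) / sum(ww)
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    l <- x <= thr
    ml <- wmean(y[l], w[l]); mr <- wmean(y[!l], w[!l])
    sse <- sum(w[l] * (y[l] - ml)^2) + sum(w[!l] * (y[!l] - mr)^2)
    if (sse < best$sse - 1e-12) {
      best <- list(sse = sse, threshold = thr, left = ml, right = mr)
    }
  }
  best
}

# --- boosting ----------------------------------------------------------

# Brute-force evaluation of the weighted-median combination rule in its
# infimum form: the smallest candidate prediction v such that the summed
# log(1/beta) weight of rounds predicting <= v reaches half the total.
oracle_weighted_median <- function(preds, betas, alpha = 1) {
  w <- alpha * log(1 / betas)
  total <- sum(w)
  cands <- sort(preds)
  for (v in cands) {
    if (sum(w[preds <= v]) >= total / 2) return(v)
  }
  cands[length(cands)]
}

# Plain-R transcription of Drucker's AdaBoost.R2 (no learning rate),
# sharing only the weak learner and the derived RNG streams with the
# package implementation.
oracle_adaboost_fit <- function(x, d, n_estimators, max_depth, loss, seed) {
  m <- length(x)
  D <- rep(1 / m, m)
  trees <- list()
  betas <- numeric(0)
  set.seed(as.integer(seed))
  for (t in seq_len(n_estimators)) {
    idx <- sample.int(m, m, replace = TRUE, prob = D)
    tr <- tree_fit(x[idx], d[idx], max_depth = max_depth)
    pred <- tree_predict(tr, x)
    l <- abs(pred - d)
    den <- max(l)
    if (den <= 1e-12) {
      trees[[length(trees) + 1]] <- tr
      betas <- c(betas, 1e-10)
      break
    }
    r <- l / den
    L <- switch(loss, linear = r, square = r^2, exponential = 1 - exp(-r))
    Lavg <- sum(L * D)
    if (Lavg >= 0.5) break
    beta <- Lavg / (1 - Lavg)
    trees[[length(trees) + 1]] <- tr
    betas <- c(betas, beta)
    D <- D * beta^(1 - L)
    D <- D / sum(D)
  }
  list(trees = trees, betas = betas)
}

oracle_adaboost_predict <- function(fit, newx) {
  vapply(newx, function(x0) {
    preds <- vapply(fit$trees, tree_predict, numeric(1), newx = x0)
    oracle_weighted_median(preds, fit$betas)
  }, numeric(1))
}

# --- k-means -----------------------------------------------------------

# Optimal 1-D 2-means by exhaustive assignment enumeration (n <= 12).
oracle_kmeans2_optimum <- function(values) {
  n <- length(values)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    ssq <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
    best <- min(best, ssq(values[a]) + ssq(values[!a]))
  }
  best
}

# --- shared fixtures ---------------------------------------------------

# small paired dataset with a smooth learnable error structure
make_toy_pairs <- function(n = 120, seed = 42, sigma = 0.05) {
  set.seed(seed)
  y <- runif(n, 60, 400)
  bias <- -0.4 + 0.5 * (y - 60) / 340
  x <- y * (1 - bias - rnorm(n, 0, sigma))
  x <- pmax(x, 20)
  data.frame(invasive_mgdl = y, noninvasive_mgdl = x)
}
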