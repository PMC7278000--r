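# End-to-end workflow: split, per-cluster grid-searched boosting,
# evaluation reports, baseline variants, recalibration/personalization.

#' Split paired readings into training and test sets
#'
#' Seeded uniform shuffle; the training set takes `floor(train_fraction * n)`
#' pairs and the test set the remainder (disjoint and exhaustive). The
#' 70:30 default reproduces the usual device-study bookkeeping
#' (918 pairs -> 642/276, 470 -> 329/143).
#'
#' @param data paired readings (data frame with `invasive_mgdl`,
#'   `noninvasive_mgdl`).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
split_pairs <- function(data, train_fraction = 0.7, seed = 1L) {
  n <- nrow(data)
  if (n < 2L) stopf("need at least 2 pairs to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("`train_fraction` must be in (0, 1)")
  perm <- with_seed(derive_seed(seed, 7L), sample.int(n))
  n_tr <- floor(train_fraction * n)
  list(train = data[perm[seq_len(n_tr)], , drop = FALSE],
       test = data[perm[(n_tr + 1):n], , drop = FALSE])
}

#' Hyperparameter grid for the boosted error-prediction models
#'
#' The exhaustive grid searched per cluster. The default is a compact grid
#' bracketing the hyperparameter optima reported for decision-tree boosting
#' on both calibration datasets (depth 10/20, 150/200 estimators, learning
#' rate 0.7/0.008, exponential/linear loss, random states 3/1); the full
#' ranges (depth 1-100, estimators 10-500, learning rate 0.0001-1, states
#' 1-5) remain configurable.
#'
#' @param max_depth tree depths, within 1-100.
#' @param n_estimators boosting rounds, within 10-500.
#' @param alpha learning rates, within (0.0001, 1].
#' @param loss loss shapes, subset of linear/square/exponential.
#' @param model_seed random states, within 1-5.
#' @return an object of class `"pgms_grid"` (a data frame of combinations in
#'   deterministic order).
#' @export
pgms_grid <- function(max_depth = c(5, 10, 20),
                      n_estimators = c(50, 150, 200),
                      alpha = c(0.008, 0.1, 0.7),
                      loss = c("linear", "square", "exponential"),
                      model_seed = c(1, 3)) {
  if (length(max_depth) == 0 || any(max_depth < 1 | max_depth > 100))
    stopf("`max_depth` values must lie in 1-100")
  if (length(n_estimators) == 0 || any(n_estimators < 10 | n_estimators > 500))
    stopf("`n_estimators` values must lie in 10-500")
  if (length(alpha) == 0 || any(alpha < 1e-4 | alpha > 1))
    stopf("`alpha` values must lie in 0.0001-1")
  loss <- match.arg(loss, several.ok = TRUE)
  if (any(!model_seed %in% 1:5)) stopf("`model_seed` values must lie in 1-5")
  g <- expand.grid(max_depth = as.integer(max_depth),
                   n_estimators = as.integer(n_estimators),
                   alpha = as.numeric(alpha),
                   loss = loss,
                   model_seed = as.integer(model_seed),
                   stringsAsFactors = FALSE)
  class(g) <- c("pgms_grid", "data.frame")
  g
}

# Exhaustive grid search for one cluster. Objective: MARD of corrected
# values on a held-out validation slice of the cluster's training pairs
# (default 20%), ties broken by validation RMSE, then fewer estimators,
# then grid order. `validation` overrides the inner split with explicit
# (x, d) pairs (used to replicate tuning on the final test split).
grid_search_cluster <- function(x, d, grid, validation_fraction = 0.2,
                                seed = 1L, validation = NULL) {
  if (nrow(grid) == 0L) stopf("empty hyperparameter grid")
  m <- length(x)
  if (m < 4L) stopf("too few pairs for grid search (need >= 4)")
  if (is.null(validation)) {
    perm <- with_seed(derive_seed(seed, 17L), sample.int(m))
    n_val <- max(2L, min(m - 2L, as.integer(round(validation_fraction * m))))
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[(n_val + 1):m]
    x_tr <- x[tr_idx]; d_tr <- d[tr_idx]
    x_val <- x[val_idx]; d_val <- d[val_idx]
  } else {
    x_tr <- x; d_tr <- d
    x_val <- validation$x; d_val <- validation$d
    if (length(x_val) < 1L) stopf("empty validation set")
  }
  y_val <- x_val + d_val

  scores <- lapply(seq_len(nrow(grid)), function(i) {
    h <- grid[i, ]
    fit <- adaboost_r2(x_tr, d_tr, n_estimators = h$n_estimators,
                       max_depth = h$max_depth, alpha = h$alpha,
                       loss = h$loss, seed = h$model_seed)
    pred <- predict(fit, x_val)
    z <- pmin(pmax(x_val + pred, 20), 600)
    c(mard = mard(y_val, z), rmse = rmse_diff(d_val, pred))
  })
  sc <- do.call(rbind, scores)
  best <- order(sc[, "mard"], sc[, "rmse"], grid$n_estimators,
                seq_len(nrow(grid)))[1]
  h <- grid[best, ]
  model <- adaboost_r2(x, d, n_estimators = h$n_estimators,
                       max_depth = h$max_depth, alpha = h$alpha,
                       loss = h$loss, seed = h$model_seed)
  list(model = model, hyper = h,
       val_mard = sc[best, "mard"], val_rmse = sc[best, "rmse"])
}

#' Fit the personalized glucose monitoring model
#'
#' Partitions the training pairs into clusters (six clinical glucose ranges
#' by default, alternatively 1-D K-means on the reference values or no
#' clustering), and fits one grid-searched AdaBoost.R2 error-prediction
#' model per cluster. Clusters with fewer than `min_cluster_size` training
#' pairs route to a global fallback model fitted on all pairs. Cluster
#' assignment during training uses the reference (invasive) reading; at
#' prediction time readings route by the non-invasive value (see
#' [predict.pgms()]).
#'
#' @param data training pairs (data frame with `invasive_mgdl`,
#'   `noninvasive_mgdl`).
#' @param clustering `"domain"` (clinical ranges), `"kmeans"` (baseline) or
#'   `"none"` (single global model). K-means with `k = 1` is identical to
#'   `"none"`.
#' @param k number of K-means clusters.
#' @param grid a [pgms_grid()].
#' @param min_cluster_size minimum training pairs for a cluster-specific
#'   model (default 10).
#' @param validation_fraction inner validation share of each cluster's
#'   training pairs used as the grid-search objective.
#' @param validation_pairs optional explicit pairs to tune on instead of the
#'   inner split (replicates protocols that tune on the test split;
#'   leakage, off by default).
#' @param seed master integer seed; all internal streams derive from it.
#' @return an object of class `"pgms"`.
#' @seealso [predict.pgms()], [pgms_evaluate()], [pgms_run()]
#' @export
pgms <- function(data, clustering = c("domain", "kmeans", "none"), k = 4L,
                 grid = pgms_grid(), min_cluster_size = 10L,
                 validation_fraction = 0.2, validation_pairs = NULL,
                 seed = 1L) {
  clustering <- match.arg(clustering)
  if (nrow(data) < 2L) stopf("need at least 2 training pairs")
  if (clustering == "kmeans" && k == 1L) clustering <- "none"
  y <- data$invasive_mgdl
  x <- data$noninvasive_mgdl
  d <- y - x

  km <- NULL
  if (clustering == "domain") {
    scheme <- domain_scheme()
    cluster_names <- scheme$cluster
    labels <- assign_cluster(y, scheme)
  } else if (clustering == "kmeans") {
    km <- kmeans_1d(y, k, seed = derive_seed(seed, 99L))
    cluster_names <- sprintf("kmeans_%d", seq_len(k))
    labels <- km$labels
  } else {
    cluster_names <- "all"
    labels <- rep(1L, length(y))
  }
  n_cl <- length(cluster_names)

  val_labels <- NULL
  if (!is.null(validation_pairs)) {
    vy <- validation_pairs$invasive_mgdl
    val_labels <- route_by_value(vy, clustering, km)
  }

  models <- vector("list", n_cl)
  hypers <- vector("list", n_cl)
  val_scores <- rep(NA_real_, n_cl)
  for (j in seq_len(n_cl)) {
    idx <- which(labels == j)
    if (length(idx) < min_cluster_size) next
    validation <- NULL
    if (!is.null(validation_pairs)) {
      vi <- which(val_labels == j)
      if (length(vi) == 0L) next
      validation <- list(
        x = validation_pairs$noninvasive_mgdl[vi],
        d = validation_pairs$invasive_mgdl[vi] -
            validation_pairs$noninvasive_mgdl[vi])
    }
    gs <- grid_search_cluster(x[idx], d[idx], grid,
                              validation_fraction = validation_fraction,
                              seed = derive_seed(seed, j),
                              validation = validation)
    models[[j]] <- gs$model
    hypers[[j]] <- gs$hyper
    val_scores[j] <- gs$val_mard
  }

  fallback <- NULL
  if (any(vapply(models, is.null, logical(1)))) {
    gs <- grid_search_cluster(x, d, grid,
                              validation_fraction = validation_fraction,
                              seed = derive_seed(seed, 1000L))
    fallback <- gs$model
  }

  structure(list(clustering = clustering,
                 cluster_names = cluster_names,
                 kmeans = km,
                 models = models,
                 hypers = hypers,
                 val_mard = val_scores,
                 fallback = fallback,
                 min_cluster_size = as.integer(min_cluster_size),
                 grid = grid,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 train = data.frame(invasive_mgdl = y, noninvasive_mgdl = x,
                                    cluster = labels)),
            class = "pgms")
}

# cluster index for glucose values under the fitted scheme
route_by_value <- function(values, clustering, km) {
  if (clustering == "domain") return(assign_cluster(values))
  if (clustering == "kmeans")
    return(vapply(values, function(v) which.min(abs(v - km$centers)),
                  integer(1)))
  rep(1L, length(values))
}

cluster_model <- function(object, j) {
  m <- object$models[[j]]
  if (is.null(m)) object$fallback else m
}

#' Predict corrected glucose readings
#'
#' Routes each reading to a cluster and applies that cluster's
#' error-prediction model: `z = x + d_pred`, clipped to 20-600 mg/dl.
#' In deployment only the non-invasive reading exists, so routing uses the
#' measured value by default; `assign_by = "reference"` (requires `ref`)
#' reproduces the grouping used in evaluation tables.
#'
#' @param object a fitted [pgms()] model.
#' @param newdata non-invasive readings, mg/dl.
#' @param assign_by route by the measured non-invasive value (default) or by
#'   the reference value supplied in `ref`.
#' @param ref reference readings, required for `assign_by = "reference"`.
#' @param ... unused.
#' @return corrected glucose readings `z`, mg/dl.
#' @export
predict.pgms <- function(object, newdata,
                         assign_by = c("measured", "reference"),
                         ref = NULL, ...) {
  assign_by <- match.arg(assign_by)
  x <- as.numeric(newdata)
  check_positive(x, "newdata")
  route_on <- if (assign_by == "measured") x else {
    if (is.null(ref)) stopf("`ref` is required when assign_by = \"reference\"")
    as.numeric(ref)
  }
  labels <- route_by_value(route_on, object$clustering, object$kmeans)
  z <- numeric(length(x))
  for (j in unique(labels)) {
    idx <- labels == j
    m <- cluster_model(object, j)
    z[idx] <- predict_glucose(m, x[idx])
  }
  z
}

#' Evaluate a fitted model on held-out pairs
#'
#' Groups the test pairs by the reference reading's cluster, applies each
#' cluster's model, and assembles the standard report: per-cluster initial
#' (measured vs reference) and final (predicted vs reference) error
#' summaries, overall MARD/RMSE by cluster-weighted aggregation, overall
#' signed min/max errors, and Clarke zone summaries for the measured and the
#' predicted values.
#'
#' @param object a fitted [pgms()] model.
#' @param test held-out pairs.
#' @return an object of class `"pgms_eval"`; see Details.
#' @details The returned list has `clusters` (one row per non-empty cluster
#'   with initial/final mard, min, max, rmse and the pair count), `overall`
#'   (initial and final [error_summary()]-style lists aggregated by the
#'   weighted identities), `cega_initial`, `cega_final`, `predictions`
#'   (per-pair y, x, z, cluster) and `n`.
#' @export
pgms_evaluate <- function(object, test) {
  stopifnot(inherits(object, "pgms"))
  if (nrow(test) == 0L) stopf("empty test set")
  y <- test$invasive_mgdl
  x <- test$noninvasive_mgdl
  labels <- route_by_value(y, object$clustering, object$kmeans)
  z <- numeric(length(y))
  for (j in unique(labels)) {
    idx <- labels == j
    z[idx] <- predict_glucose(cluster_model(object, j), x[idx])
  }

  present <- sort(unique(labels))
  rows <- lapply(present, function(j) {
    idx <- labels == j
    ini <- error_summary(y[idx], x[idx])
    fin <- error_summary(y[idx], z[idx])
    data.frame(cluster = object$cluster_names[j], n = sum(idx),
               initial_min = ini$min_error, initial_max = ini$max_error,
               initial_mard = ini$mard, initial_rmse = ini$rmse,
               final_min = fin$min_error, final_max = fin$max_error,
               final_mard = fin$mard, final_rmse = fin$rmse)
  })
  clusters <- do.call(rbind, rows)

  overall <- list(
    initial = list(mard = overall_mard(clusters$n, clusters$initial_mard),
                   min_error = min(clusters$initial_min),
                   max_error = max(clusters$initial_max),
                   rmse = overall_rmse(clusters$n, clusters$initial_rmse)),
    final = list(mard = overall_mard(clusters$n, clusters$final_mard),
                 min_error = min(clusters$final_min),
                 max_error = max(clusters$final_max),
                 rmse = overall_rmse(clusters$n, clusters$final_rmse)))

  structure(list(clusters = clusters, overall = overall,
                 cega_initial = clarke_summary(y, x),
                 cega_final = clarke_summary(y, z),
                 predictions = data.frame(invasive_mgdl = y,
                                          noninvasive_mgdl = x,
                                          predicted_mgdl = z,
                                          cluster = labels),
                 n = length(y)),
            class = "pgms_eval")
}

#' @export
print.pgms_eval <- function(x, digits = 1, ...) {
  cat(sprintf("PGMS evaluation: %d test pairs, %d cluster(s)\n",
              x$n, nrow(x$clusters)))
  df <- x$clusters
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print.data.frame(df, row.names = FALSE)
  ov <- x$overall
  cat(sprintf("Overall: MARD %.*f%% -> %.*f%%, min %.*f%% -> %.*f%%, max %.*f%% -> %.*f%%, RMSE %.*f -> %.*f mg/dl\n",
              digits, ov$initial$mard, digits, ov$final$mard,
              digits, ov$initial$min_error, digits, ov$final$min_error,
              digits, ov$initial$max_error, digits, ov$final$max_error,
              digits, ov$initial$rmse, digits, ov$final$rmse))
  za <- function(cs) cs$percent[cs$zone == "A"]
  cat(sprintf("Clarke zone A: measured %.0f%%, predicted %.0f%%\n",
              za(x$cega_initial), za(x$cega_final)))
  invisible(x)
}

#' @export
as.data.frame.pgms_eval <- function(x, ...) x$clusters

#' @export
print.pgms <- function(x, ...) {
  cat(sprintf("PGMS model (%s clustering), seed %d\n", x$clustering, x$seed))
  fitted <- !vapply(x$models, is.null, logical(1))
  for (j in seq_along(x$cluster_names)) {
    if (fitted[j]) {
      h <- x$hypers[[j]]
      cat(sprintf("  %-20s n=%4d  depth %d, %d estimators, alpha %g, %s loss, state %d\n",
                  x$cluster_names[j], sum(x$train$cluster == j),
                  h$max_depth, h$n_estimators, h$alpha, h$loss, h$model_seed))
    } else {
      cat(sprintf("  %-20s n=%4d  -> global fallback\n",
                  x$cluster_names[j], sum(x$train$cluster == j)))
    }
  }
  invisible(x)
}

#' @export
summary.pgms <- function(object, ...) {
  fitted <- !vapply(object$models, is.null, logical(1))
  data.frame(cluster = object$cluster_names,
             n_train = vapply(seq_along(object$cluster_names),
                              function(j) sum(object$train$cluster == j),
                              integer(1)),
             has_model = fitted,
             validation_mard = object$val_mard)
}

#' @export
plot.pgms_eval <- function(x, which = c("final", "initial"), ...) {
  which <- match.arg(which)
  p <- x$predictions
  est <- if (which == "final") p$predicted_mgdl else p$noninvasive_mgdl
  clarke_plot(p$invasive_mgdl, est,
              main = sprintf("Clarke error grid (%s values)", which), ...)
}

#' Run a full split/train/evaluate cycle
#'
#' The one-call workflow: seeded 70:30 split, per-cluster grid-searched
#' fitting on the training pairs, evaluation report on the held-out pairs.
#' The `clustering` argument selects the method variant (domain-knowledge
#' clusters, K-means baseline, or a single global model).
#'
#' @inheritParams pgms
#' @param train_fraction training share of the split.
#' @param tune_on_test if `TRUE`, the grid search is scored on the final
#'   test split instead of an inner validation split (protocol replication
#'   only; this leaks test information into model selection).
#' @param seed master integer seed.
#' @return an object of class `"pgms_run"`: list with `model`, `report`,
#'   `split` (named sizes) and `seed`.
#' @export
#' @examples
#' \donttest{
#' data <- generate_dataset(dataset1_spec(), seed = 1)
#' run <- pgms_run(data, seed = 1)
#' run$report
#' }
pgms_run <- function(data, clustering = c("domain", "kmeans", "none"),
                     k = 4L, grid = pgms_grid(), train_fraction = 0.7,
                     min_cluster_size = 10L, tune_on_test = FALSE,
                     seed = 1L) {
  clustering <- match.arg(clustering)
  sp <- split_pairs(data, train_fraction, seed)
  model <- pgms(sp$train, clustering = clustering, k = k, grid = grid,
                min_cluster_size = min_cluster_size,
                validation_pairs = if (tune_on_test) sp$test else NULL,
                seed = derive_seed(seed, 2L))
  report <- pgms_evaluate(model, sp$test)
  structure(list(model = model, report = report,
                 split = c(train = nrow(sp$train), test = nrow(sp$test)),
                 seed = as.integer(seed)),
            class = "pgms_run")
}

#' @export
print.pgms_run <- function(x, ...) {
  cat(sprintf("PGMS run (seed %d): %d train / %d test pairs\n",
              x$seed, x$split["train"], x$split["test"]))
  print(x$report)
  invisible(x)
}

#' Recalibration decision from recent paired readings
#'
#' Device-workflow check: computes the MARD of the model's predicted values
#' over a recent window of paired readings and decides whether the device
#' may continue non-invasive use or must be recalibrated. The decision is
#' `"continue"` iff the window MARD is less than or equal to the threshold
#' (15% by default, the common regulatory error band).
#'
#' @param object a fitted [pgms()] model.
#' @param recent recent paired readings (>= 1 pair).
#' @param threshold_mard acceptance threshold, percent.
#' @return list with `decision` (`"continue"` or `"recalibrate"`) and
#'   `mard` (the realized window MARD, percent).
#' @export
check_recalibration <- function(object, recent, threshold_mard = 15) {
  if (nrow(recent) < 1L) stopf("need at least one recent pair")
  z <- predict(object, recent$noninvasive_mgdl)
  m <- mard(recent$invasive_mgdl, z)
  list(decision = if (m <= threshold_mard) "continue" else "recalibrate",
       mard = m)
}

#' Personalize a fitted model with patient-specific pairs
#'
#' Refits the cluster models for which the patient contributes at least
#' `min_patient_pairs` paired readings: the patient's pairs are appended to
#' the population training pairs of those clusters and the per-cluster grid
#' search is rerun. Clusters the patient's data does not reach keep their
#' population models. If no cluster reaches the minimum, the original model
#' is returned with a `personalization_warning` attribute.
#'
#' @param object a fitted [pgms()] model.
#' @param patient_pairs the patient's paired readings (may be empty).
#' @param grid hyperparameter grid for the refit (defaults to the model's).
#' @param min_patient_pairs minimum patient pairs per cluster to trigger a
#'   refit of that cluster.
#' @return a [pgms()] model with the affected clusters refitted.
#' @export
personalize <- function(object, patient_pairs, grid = object$grid,
                        min_patient_pairs = 3L) {
  stopifnot(inherits(object, "pgms"))
  if (nrow(patient_pairs) == 0L) return(object)
  py <- patient_pairs$invasive_mgdl
  px <- patient_pairs$noninvasive_mgdl
  labels <- route_by_value(py, object$clustering, object$kmeans)
  counts <- tabulate(labels, nbins = length(object$cluster_names))
  refit <- which(counts >= min_patient_pairs)
  if (length(refit) == 0L) {
    attr(object, "personalization_warning") <-
      "no cluster reached the minimum patient pair count; model unchanged"
    return(object)
  }
  for (j in refit) {
    pop <- object$train[object$train$cluster == j, , drop = FALSE]
    xx <- c(pop$noninvasive_mgdl, px[labels == j])
    yy <- c(pop$invasive_mgdl, py[labels == j])
    gs <- grid_search_cluster(xx, yy - xx, grid,
                              validation_fraction = object$validation_fraction,
                              seed = derive_seed(object$seed, 2000L + j))
    object$models[[j]] <- gs$model
    object$hypers[[j]] <- gs$hyper
    object$val_mard[j] <- gs$val_mard
  }
  attr(object, "personalized_clusters") <- object$cluster_names[refit]
  object
}
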