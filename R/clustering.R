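#' Clinical glucose range scheme
#'
#' The six domain-knowledge clusters used to stratify paired readings, named
#' after the patient condition associated with each blood glucose range.
#' Intervals are half-open `(lower, upper]` so that every positive reading
#' belongs to exactly one cluster; the hypoglycemia interval extends down to
#' 0 so readings below 50 mg/dl are still covered, and the critically
#' diabetic interval is unbounded above.
#'
#' @return a data frame with columns `cluster` (name), `lower` and `upper`
#'   (mg/dl), one row per cluster in increasing glucose order.
#' @export
#' @examples
#' domain_scheme()
domain_scheme <- function() {
  data.frame(
    cluster = c("Hypoglycemia", "No diabetic", "Pre-diabetic",
                "Diabetic", "Highly diabetic", "Critically diabetic"),
    lower = c(0, 80, 115, 150, 180, 250),
    upper = c(80, 115, 150, 180, 250, Inf),
    stringsAsFactors = FALSE)
}

#' Assign glucose values to clinical clusters
#'
#' Maps each glucose value to the unique half-open interval `(lower, upper]`
#' of the scheme containing it.
#'
#' @param glucose glucose values, mg/dl; > 0. Vectorized.
#' @param scheme a cluster scheme as returned by [domain_scheme()].
#' @return an integer vector of cluster indices (1-based row of `scheme`);
#'   use `scheme$cluster[idx]` for names.
#' @export
#' @examples
#' assign_cluster(c(95, 162, 80, 80.5))
assign_cluster <- function(glucose, scheme = domain_scheme()) {
  check_positive(glucose, "glucose")
  idx <- vapply(glucose, function(g) {
    which(g > scheme$lower & g <= scheme$upper)[1]
  }, integer(1))
  if (anyNA(idx)) stopf("glucose value outside all scheme intervals")
  idx
}

#' One-dimensional K-means clustering of glucose values
#'
#' Baseline clustering of the reference glucose values: seeded k-means++
#' initialization followed by Lloyd's algorithm (via [stats::kmeans()],
#' `algorithm = "Lloyd"`), deterministic for a fixed seed.
#'
#' @param values glucose values, mg/dl.
#' @param k number of clusters; must not exceed the number of distinct values.
#' @param seed integer seed for the initialization.
#' @param iter_max maximum Lloyd iterations.
#' @return an object of class `"kmeans1d"`: list with `k`, `centers` (sorted
#'   increasing), `labels` (index of the assigned center per value),
#'   `inertia` (total within-cluster sum of squares) and `seed`.
#' @export
kmeans_1d <- function(values, k, seed = 1L, iter_max = 300L) {
  if (k < 1) stopf("`k` must be >= 1")
  nu <- length(unique(values))
  if (k > nu) stopf("`k` (%d) exceeds the number of distinct values (%d)", k, nu)
  init <- with_seed(derive_seed(seed, 11L), kmeanspp_init(values, k))
  if (k == 1L) {
    ctr <- mean(values)
    return(structure(list(k = 1L, centers = ctr,
                          labels = rep(1L, length(values)),
                          inertia = sum((values - ctr)^2), seed = seed),
                     class = "kmeans1d"))
  }
  km <- suppressWarnings(
    stats::kmeans(values, centers = matrix(init, ncol = 1),
                  iter.max = iter_max, algorithm = "Lloyd"))
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  structure(list(k = as.integer(k),
                 centers = as.numeric(km$centers[ord, 1]),
                 labels = relabel[km$cluster],
                 inertia = km$tot.withinss,
                 seed = seed),
            class = "kmeans1d")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center. Assumes RNG already seeded.
kmeanspp_init <- function(values, k) {
  centers <- numeric(k)
  centers[1] <- values[sample.int(length(values), 1L)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(values, function(v) min((v - centers[1:(j - 1)])^2),
                   numeric(1))
      if (sum(d2) <= 0) {
        pool <- setdiff(unique(values), centers[1:(j - 1)])
        centers[j] <- pool[sample.int(length(pool), 1L)]
      } else {
        centers[j] <- values[sample.int(length(values), 1L, prob = d2)]
      }
    }
  }
  # kmeans() requires distinct initial centers
  while (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    pool <- setdiff(unique(values), centers)
    centers[dup[1]] <- if (length(pool)) pool[sample.int(length(pool), 1L)]
                       else centers[dup[1]] + stats::runif(1, -1e-6, 1e-6)
  }
  centers
}

#' @export
print.kmeans1d <- function(x, ...) {
  cat(sprintf("1-D k-means: k = %d, inertia = %.2f (mg/dl)^2\n", x$k, x$inertia))
  cat("centers (mg/dl):", paste(sprintf("%.1f", x$centers), collapse = ", "), "\n")
  invisible(x)
}
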