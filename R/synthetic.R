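# Synthetic paired invasive/non-invasive glucose readings.
#
# Real clinical paired datasets behind published device accuracy tables are
# not deposited; the generator reproduces their marginal statistics (pair
# count, both glucose ranges, MARD, signed-error extremes) while giving the
# error a smooth systematic component b(y) that is learnable from the
# non-invasive reading, so the downstream correction pipeline has signal to
# recover. Signed error convention: e = (y - x)/y * 100.

#' Target marginal statistics for a synthetic paired dataset
#'
#' @param n_pairs number of paired readings (>= 10).
#' @param invasive_range length-2 range of the reference readings, mg/dl.
#' @param noninvasive_range length-2 range of the sensor readings, mg/dl.
#' @param target_mard target MARD of the measured values, percent.
#' @param error_range length-2 signed-error extremes (min, max), percent;
#'   the minimum must be negative and the maximum positive.
#' @param name optional label.
#' @return an object of class `"dataset_spec"`.
#' @export
#' @examples
#' dataset1_spec()
dataset_spec <- function(n_pairs, invasive_range, noninvasive_range,
                         target_mard, error_range, name = "custom") {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 10L) stopf("`n_pairs` must be >= 10")
  if (invasive_range[1] >= invasive_range[2])
    stopf("invasive range must satisfy min < max")
  if (noninvasive_range[1] >= noninvasive_range[2])
    stopf("non-invasive range must satisfy min < max")
  if (any(c(invasive_range, noninvasive_range) <= 0))
    stopf("glucose ranges must be strictly positive")
  if (!(error_range[1] < 0 && error_range[2] > 0))
    stopf("signed-error extremes must bracket zero (min < 0 < max)")
  if (!(target_mard > 0 && target_mard < abs(error_range[1])))
    stopf("`target_mard` must satisfy 0 < MARD < |minimum signed error|")
  structure(list(n_pairs = n_pairs,
                 invasive_range = as.numeric(invasive_range),
                 noninvasive_range = as.numeric(noninvasive_range),
                 target_mard = as.numeric(target_mard),
                 error_range = as.numeric(error_range),
                 name = name),
            class = "dataset_spec")
}

#' @rdname dataset_spec
#' @details `dataset1_spec()` and `dataset2_spec()` are the two shipped
#'   calibration targets: 918 pairs with invasive range 65-492 mg/dl,
#'   non-invasive range 80-352 mg/dl, MARD 23.9% and signed-error extremes
#'   -221%/+61%; and 470 pairs with invasive range 37-458 mg/dl,
#'   non-invasive range 40-428 mg/dl, MARD 17.4% and extremes -131%/+65%.
#' @export
dataset1_spec <- function() {
  dataset_spec(918L, c(65, 492), c(80, 352), 23.9, c(-221, 61), "dataset1")
}

#' @rdname dataset_spec
#' @export
dataset2_spec <- function() {
  dataset_spec(470L, c(37, 458), c(40, 428), 17.4, c(-131, 65), "dataset2")
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf("dataset spec '%s': %d pairs\n", x$name, x$n_pairs))
  cat(sprintf("  invasive %g-%g mg/dl, non-invasive %g-%g mg/dl\n",
              x$invasive_range[1], x$invasive_range[2],
              x$noninvasive_range[1], x$noninvasive_range[2]))
  cat(sprintf("  target MARD %.1f %%, signed-error extremes %g %% / %g %%\n",
              x$target_mard, x$error_range[1], x$error_range[2]))
  invisible(x)
}

#' Default systematic-bias knots for a dataset spec
#'
#' The systematic relative bias `b(y)` (so that `x = y * (1 - b(y) - eps)`)
#' is a monotone curve through these knots: strongly negative at low glucose
#' (sensors over-read in hypoglycemia, producing the large negative signed
#' errors published for such devices), rising smoothly to a positive value
#' at high glucose large enough that the sensor reading stays inside its
#' narrower range. Shape:
#' `b(y) = b_hi + (b_lo - b_hi) * ((ymax - y)/(ymax - ymin))^2.5` with
#' `b_lo = -0.55 * |min error|/100` and
#' `b_hi = max(0.08, 1 - 0.92 * xmax/ymax)`, sampled at 9 equispaced knots.
#'
#' @param spec a [dataset_spec()].
#' @return a two-column matrix (`glucose`, `bias`).
#' @export
default_bias_knots <- function(spec) {
  yr <- spec$invasive_range
  b_lo <- -0.55 * abs(spec$error_range[1]) / 100
  b_hi <- max(0.08, 1 - 0.92 * spec$noninvasive_range[2] / yr[2])
  ky <- seq(yr[1], yr[2], length.out = 9)
  kb <- b_hi + (b_lo - b_hi) * ((yr[2] - ky) / (yr[2] - yr[1]))^2.5
  cbind(glucose = ky, bias = kb)
}

#' Default anchor pairs for a dataset spec
#'
#' Six explicit paired readings injected into every generated dataset so the
#' published marginals are hit exactly rather than approached by chance: two
#' pairs realizing the signed-error extremes, and four pairs pinning the
#' endpoints of the invasive and non-invasive ranges. Each anchor is placed
#' at the midpoint of its feasibility interval (the glucose values for which
#' the partner reading stays inside both ranges and the signed error inside
#' the spec extremes); an empty interval raises an error naming the violated
#' constraint.
#'
#' @param spec a [dataset_spec()].
#' @return a data frame with columns `invasive_mgdl`, `noninvasive_mgdl`.
#' @export
default_anchor_pairs <- function(spec) {
  yr <- spec$invasive_range
  xr <- spec$noninvasive_range
  fmin <- 1 - spec$error_range[1] / 100   # > 1
  fmax <- 1 - spec$error_range[2] / 100   # < 1, may be <= 0
  if (fmax <= 0)
    stopf("infeasible spec: maximum signed error %g%% implies a non-positive reading",
          spec$error_range[2])

  mid <- function(lo, hi, what) {
    if (lo > hi) stopf("infeasible spec: %s not realizable within both ranges", what)
    (lo + hi) / 2
  }
  # exact extreme anchors: x = y * (1 - e/100)
  y_min_err <- mid(max(yr[1], xr[1] / fmin), min(yr[2], xr[2] / fmin),
                   "minimum signed error")
  y_max_err <- mid(max(yr[1], xr[1] / fmax), min(yr[2], xr[2] / fmax),
                   "maximum signed error")
  # range anchors: partner value at the midpoint of its feasible interval
  x_at <- function(y, what)
    mid(max(xr[1], y * fmax), min(xr[2], y * fmin), what)
  y_at <- function(x, what)
    mid(max(yr[1], x / fmin), min(yr[2], x / fmax), what)
  data.frame(
    invasive_mgdl = c(y_min_err, y_max_err, yr[1], yr[2],
                      y_at(xr[1], "non-invasive minimum"),
                      y_at(xr[2], "non-invasive maximum")),
    noninvasive_mgdl = c(y_min_err * fmin, y_max_err * fmax,
                         x_at(yr[1], "invasive minimum"),
                         x_at(yr[2], "invasive maximum"),
                         xr[1], xr[2]))
}

#' Generator configuration
#'
#' Tunables of the synthetic generator. Defaults implement the study
#' conditions: residual noise `eps ~ N(0, 0.09)` (so a perfect correction of
#' the systematic component leaves a mean absolute relative error of about
#' `0.09 * sqrt(2/pi) * 100 ~ 7%`), a monotone systematic bias through
#' [default_bias_knots()], cluster mixture weights reflecting the glucose
#' distribution of a diabetic study population, and the exact-marginal
#' anchors of [default_anchor_pairs()].
#'
#' @param spec the [dataset_spec()] the configuration is built for.
#' @param bias_knots two-column matrix (glucose, relative bias).
#' @param noise_sigma relative s.d. of the residual noise (>= 0).
#' @param mixture_weights sampling weights over the six clinical glucose
#'   ranges of [domain_scheme()].
#' @param anchor_pairs data frame of explicit pairs injected verbatim
#'   (each must lie inside both spec ranges), or `NULL` for none.
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(spec,
                             bias_knots = default_bias_knots(spec),
                             noise_sigma = 0.09,
                             mixture_weights = c(0.02, 0.12, 0.18, 0.15, 0.34, 0.19),
                             anchor_pairs = default_anchor_pairs(spec)) {
  if (noise_sigma < 0) stopf("`noise_sigma` must be >= 0")
  bias_knots <- as.matrix(bias_knots)
  if (ncol(bias_knots) != 2 || nrow(bias_knots) < 2)
    stopf("`bias_knots` must be a matrix with >= 2 rows of (glucose, bias)")
  if (length(mixture_weights) != nrow(domain_scheme()) || any(mixture_weights < 0))
    stopf("`mixture_weights` must be %d non-negative weights", nrow(domain_scheme()))
  if (!is.null(anchor_pairs)) {
    anchor_pairs <- as.data.frame(anchor_pairs)
    yr <- spec$invasive_range; xr <- spec$noninvasive_range
    ok <- anchor_pairs$invasive_mgdl >= yr[1] & anchor_pairs$invasive_mgdl <= yr[2] &
      anchor_pairs$noninvasive_mgdl >= xr[1] & anchor_pairs$noninvasive_mgdl <= xr[2]
    if (!all(ok)) stopf("anchor pair(s) outside the spec's glucose ranges")
    if (nrow(anchor_pairs) > spec$n_pairs)
      stopf("more anchor pairs than `n_pairs`")
  }
  structure(list(bias_knots = bias_knots, noise_sigma = noise_sigma,
                 mixture_weights = mixture_weights / sum(mixture_weights),
                 anchor_pairs = anchor_pairs),
            class = "generator_config")
}

bias_spline <- function(config) {
  stats::splinefun(config$bias_knots[, 1], config$bias_knots[, 2],
                   method = "monoH.FC")
}

# distinct anchor positions spread across 1..n
anchor_positions <- function(n, k) {
  if (k == 0L) return(integer(0))
  pos <- unique(as.integer(round(seq(1, n, length.out = k))))
  i <- 1L
  while (length(pos) < k) {        # n >= k guaranteed by generator_config
    if (!(i %in% pos)) pos <- c(pos, i)
    i <- i + 1L
  }
  sort(pos[seq_len(k)])
}

#' Generate a synthetic paired glucose dataset
#'
#' Draws reference readings from a mixture over the six clinical glucose
#' ranges, applies the systematic bias curve plus Gaussian relative noise
#' (`x = y * (1 - b(y) - eps)`), rescales the systematic component (by a
#' 1-D root solve) so the realized MARD matches the spec target, clamps
#' signed errors to the spec extremes, hard-clips sensor readings to the
#' non-invasive range (with one corrective rescale iteration afterwards),
#' and finally overwrites designated records with the anchor pairs so the
#' published extremes and range endpoints are hit exactly. Fully
#' deterministic given `seed`.
#'
#' @param spec a [dataset_spec()].
#' @param config a [generator_config()]; defaults to the study conditions.
#' @param seed integer seed.
#' @return a data frame of class `"paired_glucose"` with columns
#'   `invasive_mgdl` and `noninvasive_mgdl` and attributes: `spec`,
#'   `config`, `seed`, `bias_scale`, `bias_fun` (the scaled systematic bias
#'   as a function of reference glucose), `anchor_idx`, `clipped` (logical,
#'   rows hard-clipped to the non-invasive range), `provenance`, and
#'   `realized_mard`.
#' @export
generate_dataset <- function(spec, config = generator_config(spec), seed = 1L) {
  stopifnot(inherits(spec, "dataset_spec"), inherits(config, "generator_config"))
  n <- spec$n_pairs
  anchors <- config$anchor_pairs
  k <- if (is.null(anchors)) 0L else nrow(anchors)
  n_free <- n - k
  emin <- spec$error_range[1] / 100
  emax <- spec$error_range[2] / 100
  xr <- spec$noninvasive_range
  yr <- spec$invasive_range
  bias <- bias_spline(config)

  # MARD budget left for the non-anchor records
  anchor_abs <- if (k > 0)
    abs((anchors$invasive_mgdl - anchors$noninvasive_mgdl) / anchors$invasive_mgdl)
  else numeric(0)
  target_free <- (spec$target_mard / 100 * n - sum(anchor_abs)) / n_free
  if (target_free <= 0)
    stopf("infeasible spec: anchor pairs alone exceed the target MARD")

  res <- with_seed(seed, {
    scheme <- domain_scheme()
    lo <- pmax(scheme$lower, yr[1])
    hi <- pmin(scheme$upper, yr[2])
    open <- lo < hi
    w <- config$mixture_weights * open
    cl <- sample.int(nrow(scheme), n_free, replace = TRUE, prob = w)
    y <- stats::runif(n_free, lo[cl], hi[cl])
    eps <- stats::rnorm(n_free, 0, config$noise_sigma)
    list(y = y, eps = eps)
  })
  y <- res$y; eps <- res$eps
  s <- bias(y)

  realize <- function(cc) {
    e <- pmin(pmax(cc * s + eps, emin), emax)
    x <- pmin(pmax(y * (1 - e), xr[1]), xr[2])
    x
  }
  solve_scale <- function(target) {
    if (mean(abs(s)) < 1e-12) return(1)  # no systematic component to scale
    g <- function(cc) mean(abs(cc * s + eps)) - target
    if (g(0) >= 0) return(0)       # noise floor alone reaches the target
    upper <- 1
    while (g(upper) < 0 && upper < 1024) upper <- upper * 2
    if (g(upper) < 0)
      stopf("infeasible spec: target MARD unreachable by rescaling the bias")
    stats::uniroot(g, c(0, upper), tol = 1e-10)$root
  }
  cc <- solve_scale(target_free)
  x <- realize(cc)
  realized_free <- mean(abs((y - x) / y))
  if (cc > 0 && realized_free > 0 && mean(abs(s)) >= 1e-12) {
    # one corrective rescale of the systematic part after clamp/clip
    cc <- solve_scale_refine(cc, s, eps, y, emin, emax, xr, target_free)
    x <- realize(cc)
  }

  inv <- numeric(n); noninv <- numeric(n)
  pos <- anchor_positions(n, k)
  free_pos <- setdiff(seq_len(n), pos)
  inv[free_pos] <- y; noninv[free_pos] <- x
  clipped <- logical(n)
  clipped[free_pos] <- (y * (1 - pmin(pmax(cc * s + eps, emin), emax)) < xr[1]) |
                       (y * (1 - pmin(pmax(cc * s + eps, emin), emax)) > xr[2])
  if (k > 0) {
    inv[pos] <- anchors$invasive_mgdl
    noninv[pos] <- anchors$noninvasive_mgdl
  }

  out <- data.frame(invasive_mgdl = inv, noninvasive_mgdl = noninv)
  class(out) <- c("paired_glucose", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  attr(out, "bias_scale") <- cc
  attr(out, "bias_fun") <- local({
    b <- bias; sc <- cc
    function(glucose) sc * b(glucose)
  })
  attr(out, "anchor_idx") <- pos
  attr(out, "clipped") <- clipped
  attr(out, "realized_mard") <- mard(inv, noninv)
  attr(out, "provenance") <- sprintf(
    "synthetic paired glucose: spec '%s' (n=%d, target MARD %.1f%%), seed %d, bias scale %.4f, %d clipped",
    spec$name, n, spec$target_mard, as.integer(seed), cc, sum(clipped))
  out
}

# secant-style refinement of the bias scale against the clamped/clipped MARD
solve_scale_refine <- function(cc, s, eps, y, emin, emax, xr, target) {
  realized <- function(c2) {
    e <- pmin(pmax(c2 * s + eps, emin), emax)
    x <- pmin(pmax(y * (1 - e), xr[1]), xr[2])
    mean(abs((y - x) / y))
  }
  f <- function(c2) realized(c2) - target
  lo <- cc * 0.5; hi <- cc * 2
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0) return(if (f(0) > 0) 0 else stats::uniroot(f, c(0, lo), tol = 1e-10)$root)
  if (fhi < 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.paired_glucose <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("paired glucose readings: %d pairs\n", nrow(x)))
  if (!is.null(prov)) cat(" ", prov, "\n")
  cat(sprintf("  invasive %.1f-%.1f mg/dl, non-invasive %.1f-%.1f mg/dl, MARD %.2f %%\n",
              min(x$invasive_mgdl), max(x$invasive_mgdl),
              min(x$noninvasive_mgdl), max(x$noninvasive_mgdl),
              mard(x$invasive_mgdl, x$noninvasive_mgdl)))
  invisible(x)
}

#' Validate a paired dataset against its spec
#'
#' Recomputes every marginal statistic the spec targets and reports
#' pass/fail per check: pair count (exact), invasive and non-invasive range
#' endpoints (exact), MARD (within +/- 1% absolute, the fidelity band used
#' for the published baselines), and signed-error extremes (exact for
#' anchored datasets, otherwise containment within the spec extremes).
#'
#' @param data a paired dataset (data frame with `invasive_mgdl`,
#'   `noninvasive_mgdl`).
#' @param spec the [dataset_spec()] to validate against.
#' @return an object of class `"spec_validation"`: data frame with columns
#'   `check`, `target`, `realized`, `pass`, plus attribute `pass` (all
#'   checks).
#' @export
validate_against_spec <- function(data, spec) {
  if (nrow(data) == 0L) stopf("empty dataset")
  y <- data$invasive_mgdl; x <- data$noninvasive_mgdl
  e <- signed_error(y, x)
  m <- mard(y, x)
  anchored <- !is.null(attr(data, "anchor_idx")) &&
    length(attr(data, "anchor_idx")) > 0
  tol <- 1e-9
  rows <- list(
    c("n_pairs", spec$n_pairs, nrow(data), nrow(data) == spec$n_pairs),
    c("invasive_min", spec$invasive_range[1], min(y),
      abs(min(y) - spec$invasive_range[1]) < tol),
    c("invasive_max", spec$invasive_range[2], max(y),
      abs(max(y) - spec$invasive_range[2]) < tol),
    c("noninvasive_min", spec$noninvasive_range[1], min(x),
      abs(min(x) - spec$noninvasive_range[1]) < tol),
    c("noninvasive_max", spec$noninvasive_range[2], max(x),
      abs(max(x) - spec$noninvasive_range[2]) < tol),
    c("mard", spec$target_mard, m, abs(m - spec$target_mard) <= 1),
    c("min_error", spec$error_range[1], min(e),
      if (anchored) abs(min(e) - spec$error_range[1]) < tol
      else min(e) >= spec$error_range[1] - tol),
    c("max_error", spec$error_range[2], max(e),
      if (anchored) abs(max(e) - spec$error_range[2]) < tol
      else max(e) <= spec$error_range[2] + tol))
  out <- data.frame(check = vapply(rows, `[[`, "", 1),
                    target = as.numeric(vapply(rows, `[[`, "", 2)),
                    realized = as.numeric(vapply(rows, `[[`, "", 3)),
                    pass = as.logical(vapply(rows, `[[`, "", 4)))
  class(out) <- c("spec_validation", "data.frame")
  attr(out, "pass") <- all(out$pass)
  out
}

#' @export
print.spec_validation <- function(x, ...) {
  cat(sprintf("spec validation: %s\n",
              if (attr(x, "pass")) "PASS" else "FAIL"))
  df <- data.frame(check = x$check, target = signif(x$target, 6),
                   realized = signif(x$realized, 6), pass = x$pass)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
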