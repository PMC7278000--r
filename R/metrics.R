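#' Signed relative error of a glucose reading
#'
#' Signed percentage error of a value `v` against the reference reading `ref`,
#' defined as `(ref - v) / ref * 100`. Under this convention a sensor reading
#' far above the reference gives a large negative error (e.g. reference 100,
#' reading 321 gives -221%), which is the orientation used throughout for
#' minimum/maximum error reporting.
#'
#' @param ref reference (invasive) glucose, mg/dl; must be > 0. Vectorized.
#' @param v compared value (measured or predicted), mg/dl.
#' @return signed error in percent, same length as the inputs.
#' @export
#' @examples
#' signed_error(100, 80)   # +20
#' signed_error(100, 321)  # -221
signed_error <- function(ref, v) {
  check_positive(ref, "ref")
  if (length(ref) != length(v)) stopf("`ref` and `v` must have equal length")
  (ref - v) / ref * 100
}

#' Mean absolute relative difference (MARD)
#'
#' The standard accuracy statistic for glucose monitors: the mean over all
#' paired readings of `|vals - ref| / ref * 100`. Lower is more accurate.
#'
#' @param ref reference glucose values, mg/dl; all > 0.
#' @param vals compared values (non-invasive measured or predicted), mg/dl.
#' @return MARD in percent (scalar).
#' @export
#' @examples
#' mard(c(100, 200), c(80, 240))  # 20
mard <- function(ref, vals) {
  if (length(ref) == 0L) stopf("empty input to mard()")
  if (length(ref) != length(vals)) stopf("`ref` and `vals` must have equal length")
  check_positive(ref, "ref")
  mean(abs(vals - ref) / ref) * 100
}

#' Root mean square error of additive differences
#'
#' RMSE between the true additive differences `d = y - x` and their predicted
#' values, in mg/dl. Used as the robustness companion to MARD.
#'
#' @param d true differences, mg/dl.
#' @param d_pred predicted differences, mg/dl.
#' @return RMSE in mg/dl (scalar).
#' @export
rmse_diff <- function(d, d_pred) {
  if (length(d) == 0L) stopf("empty input to rmse_diff()")
  if (length(d) != length(d_pred)) stopf("`d` and `d_pred` must have equal length")
  sqrt(mean((d - d_pred)^2))
}

#' Cluster-weighted overall MARD
#'
#' Aggregates per-cluster MARDs into the overall value by weighting each
#' cluster's MARD with its paired-data count: `sum(m_j * mard_j) / sum(m_j)`.
#' When the clusters partition a dataset this equals the MARD of the pooled
#' data exactly.
#'
#' @param m_j per-cluster pair counts (>= 0).
#' @param mard_j per-cluster MARDs, percent.
#' @return overall MARD in percent.
#' @export
#' @examples
#' overall_mard(c(4, 32, 51, 42, 93, 54),
#'              c(124.6, 48.3, 31.2, 21.8, 16.6, 17.2))  # ~25.4
overall_mard <- function(m_j, mard_j) {
  if (length(m_j) != length(mard_j)) stopf("weight/value length mismatch")
  if (any(m_j < 0)) stopf("cluster counts must be non-negative")
  keep <- m_j > 0
  if (!any(keep)) stopf("all cluster counts are zero")
  sum(m_j[keep] * mard_j[keep]) / sum(m_j[keep])
}

#' Cluster-weighted overall RMSE
#'
#' Pools per-cluster RMSEs into the overall value:
#' `sqrt(sum(m_j * rmse_j^2) / sum(m_j))`. When the clusters partition the
#' data this equals the RMSE computed on the pooled residuals exactly.
#'
#' @param m_j per-cluster pair counts (>= 0).
#' @param rmse_j per-cluster RMSEs, mg/dl.
#' @return overall RMSE in mg/dl.
#' @export
overall_rmse <- function(m_j, rmse_j) {
  if (length(m_j) != length(rmse_j)) stopf("weight/value length mismatch")
  if (any(m_j < 0)) stopf("cluster counts must be non-negative")
  keep <- m_j > 0
  if (!any(keep)) stopf("all cluster counts are zero")
  sqrt(sum(m_j[keep] * rmse_j[keep]^2) / sum(m_j[keep]))
}

#' Error summary for a set of paired readings
#'
#' Computes the accuracy panel reported per cluster and overall: MARD, signed
#' minimum and maximum error (per [signed_error()]), RMSE of the additive
#' differences `ref - vals`, and the pair count.
#'
#' @param ref reference glucose values, mg/dl.
#' @param vals compared values, mg/dl.
#' @return an object of class `"error_summary"`: a list with elements `mard`,
#'   `min_error`, `max_error` (percent), `rmse` (mg/dl) and `n`.
#' @export
error_summary <- function(ref, vals) {
  if (length(ref) == 0L) stopf("empty input to error_summary()")
  e <- signed_error(ref, vals)
  structure(
    list(mard = mean(abs(e)),
         min_error = min(e),
         max_error = max(e),
         rmse = sqrt(mean((ref - vals)^2)),
         n = length(ref)),
    class = "error_summary")
}

#' @export
print.error_summary <- function(x, digits = 1, ...) {
  cat(sprintf("n = %d pairs\n", x$n))
  cat(sprintf("  MARD      %6.*f %%\n", digits, x$mard))
  cat(sprintf("  min error %6.*f %%\n", digits, x$min_error))
  cat(sprintf("  max error %6.*f %%\n", digits, x$max_error))
  cat(sprintf("  RMSE      %6.*f mg/dl\n", digits, x$rmse))
  invisible(x)
}

#' @export
as.data.frame.error_summary <- function(x, ...) {
  data.frame(mard = x$mard, min_error = x$min_error, max_error = x$max_error,
             rmse = x$rmse, n = x$n)
}
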