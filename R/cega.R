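#' Clarke error grid zone classification
#'
#' Classifies reference/estimate glucose pairs into the five zones of the
#' Clarke error grid (Clarke et al. 1987). Zone A readings are clinically
#' accurate (within 20% of reference, or both in the hypoglycemic range);
#' zone B deviations are benign; zone C would prompt unnecessary treatment;
#' zone D fails to detect hypo-/hyperglycemia; zone E confuses hypoglycemia
#' with hyperglycemia.
#'
#' The canonical boundary inequalities are evaluated in the fixed order
#' A, E, C, D, with B as the remainder; boundary ties resolve by the
#' non-strict comparisons as written below. Units are mg/dl throughout.
#'
#' @param ref reference (invasive) glucose, mg/dl; > 0. Vectorized.
#' @param est estimated glucose (measured or predicted), mg/dl; > 0.
#' @return a factor with levels `A`..`E`, one zone per pair.
#' @export
#' @examples
#' clarke_zone(100, 100)  # A
#' clarke_zone(200, 60)   # E
clarke_zone <- function(ref, est) {
  check_positive(ref, "ref")
  check_positive(est, "est")
  if (length(ref) != length(est)) stopf("`ref` and `est` must have equal length")

  zone <- rep("B", length(ref))
  a <- (ref <= 70 & est <= 70) | abs(ref - est) <= 0.2 * ref
  e <- !a & ((ref >= 180 & est <= 70) | (ref <= 70 & est >= 180))
  c_ <- !a & !e &
    ((ref >= 70 & ref <= 290 & est >= ref + 110) |
     (ref >= 130 & ref <= 180 & est <= (7 / 5) * ref - 182))
  d <- !a & !e & !c_ &
    ((ref >= 240 & est >= 70 & est <= 180) |
     (ref <= 175 / 3 & est >= 70 & est <= 180) |
     (ref >= 175 / 3 & ref <= 70 & est >= (6 / 5) * ref))
  zone[a] <- "A"; zone[e] <- "E"; zone[c_] <- "C"; zone[d] <- "D"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Clarke error grid zone summary
#'
#' Tallies zone counts and percentages for a set of paired readings, the
#' standard companion table to a Clarke error grid plot.
#'
#' @param ref reference glucose values, mg/dl.
#' @param est estimated values, mg/dl.
#' @return an object of class `"clarke_summary"`: a data frame with columns
#'   `zone`, `count`, `percent`.
#' @export
clarke_summary <- function(ref, est) {
  if (length(ref) == 0L) stopf("empty input to clarke_summary()")
  z <- clarke_zone(ref, est)
  tab <- table(z)
  out <- data.frame(zone = names(tab),
                    count = as.integer(tab),
                    percent = as.numeric(tab) / length(z) * 100)
  class(out) <- c("clarke_summary", "data.frame")
  out
}

#' @export
print.clarke_summary <- function(x, ...) {
  cat("Clarke error grid summary\n")
  df <- data.frame(zone = x$zone, count = x$count,
                   percent = round(x$percent))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Clarke error grid plot
#'
#' Scatter plot of estimated vs reference glucose with the canonical zone
#' boundaries overlaid (base graphics).
#'
#' @param ref reference glucose values, mg/dl.
#' @param est estimated values, mg/dl.
#' @param xlim,ylim axis limits, mg/dl.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the zone factor for the plotted pairs.
#' @export
clarke_plot <- function(ref, est, xlim = c(0, 550), ylim = c(0, 550), ...) {
  graphics::plot(ref, est, xlim = xlim, ylim = ylim,
                 xlab = "Reference glucose (mg/dl)",
                 ylab = "Estimated glucose (mg/dl)",
                 pch = 20, col = "grey25", ...)
  seg <- function(x0, y0, x1, y1)
    graphics::segments(x0, y0, x1, y1, col = "firebrick", lwd = 1.2)
  up <- max(xlim[2], ylim[2])
  # zone A wedge (20% band, hypo square)
  seg(70 / 1.2, 70, up, 1.2 * up)
  seg(70, 70 * 0.8, up, 0.8 * up)
  seg(0, 70, 70 / 1.2, 70)
  seg(70, 0, 70, 70 * 0.8)
  # upper C region
  seg(70, 180, 290, 400)
  seg(70, 180, 70, up)
  # lower C region
  seg(130, 0, 180, 70)
  # D regions
  seg(240, 70, 240, 180)
  seg(240, 180, up, 180)
  seg(0, 180, 70, 180)
  seg(175 / 3, 70, 70, 84)
  # E corners
  seg(180, 70, up, 70)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(clarke_zone(ref, est))
}
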