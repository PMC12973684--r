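#' Fit a depth-threshold PRDI classifier
#'
#' The central estimator of the package. Given labeled breath events pooled
#' across recordings (each recording standardized to z-units beforehand), it
#' (i) compares PRDI and NRI minima depths with a Mann-Whitney U test,
#' (ii) runs ROC analysis of minima depth (positive class PRDI, score
#' `-depth_z`), (iii) sweeps all candidate thresholds computing sensitivity,
#' specificity, G-mean and balanced accuracy, and (iv) selects the optimal
#' threshold as the midpoint of the plateau maximizing both G-mean and
#' balanced accuracy.
#'
#' @param events data frame with columns `depth_z` and `label`
#'   (`PRDI`/`NRI`), e.g. from [analyze_series()] + [label_events()];
#'   a `recording_id` column is carried along when present.
#' @param threshold_z optional fixed operating threshold; when supplied it is
#'   used for the reported operating-point metrics instead of the selected
#'   optimum (the sweep and selection are still computed).
#' @return Object of class `prdi_fit` with components `events`, `mw`
#'   (Mann-Whitney result), `roc` (a `roc_result`), `sweep` (per-threshold
#'   metrics), `selection` (plateau and optimum), `threshold_used`,
#'   `metrics` (operating-point metrics at `threshold_used`), `group_stats`
#'   (per-class n, median, IQR).
#' @seealso [coef.prdi_fit()], [predict.prdi_fit()], [plot.prdi_fit()]
#' @examples
#' ev <- data.frame(depth_z = c(-2.6, -2.2, -1.9, -1.4, -1.0, -0.6, -0.9, -2.0),
#'                  label = c("PRDI", "PRDI", "PRDI", "NRI",
#'                            "NRI", "NRI", "NRI", "NRI"))
#' fit <- prdi_fit(ev)
#' coef(fit)
#' summary(fit)
#' @export
prdi_fit <- function(events, threshold_z = NULL) {
  if (!all(c("depth_z", "label") %in% names(events)))
    fail_validation("events must have depth_z and label columns")
  lab <- as.character(events$label)
  if (!all(lab %in% c("PRDI", "NRI")))
    fail_validation("labels must be PRDI or NRI")
  pd <- events$depth_z[lab == "PRDI"]
  nd <- events$depth_z[lab == "NRI"]
  if (length(pd) == 0L || length(nd) == 0L)
    fail_validation("both PRDI and NRI events are required to fit")
  mw <- mann_whitney(pd, nd)
  roc <- roc_depth(events)
  sweep <- sweep_thresholds(events)
  selection <- select_threshold(sweep)
  thr <- threshold_z %||% selection$optimal_threshold_z
  check_scalar(thr, "threshold_z")
  cls <- classify_events(events, thr)
  metrics <- threshold_metrics(confusion_counts(cls), threshold_z = thr)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  gp <- qs(pd); gn <- qs(nd)
  group_stats <- data.frame(
    label = c("PRDI", "NRI"), n = c(length(pd), length(nd)),
    median = c(gp[2], gn[2]), q1 = c(gp[1], gn[1]), q3 = c(gp[3], gn[3])
  )
  structure(
    list(events = cls, mw = mw, roc = roc, sweep = sweep,
         selection = selection, threshold_used = thr, metrics = metrics,
         group_stats = group_stats,
         threshold_fixed = !is.null(threshold_z)),
    class = "prdi_fit"
  )
}

#' @export
print.prdi_fit <- function(x, ...) {
  m <- x$metrics
  cat("Depth-threshold PRDI classifier\n")
  cat(sprintf("  events: %d PRDI, %d NRI\n",
              x$group_stats$n[1], x$group_stats$n[2]))
  cat(sprintf("  AUC: %.2f\n", x$roc$auc))
  cat(sprintf("  threshold: %.2f z%s\n", x$threshold_used,
              if (x$threshold_fixed) " (fixed)" else
                sprintf(" (plateau midpoint, %s criterion)", x$selection$criterion)))
  cat(sprintf("  sensitivity %.2f, specificity %.2f, G-mean %.2f, balanced accuracy %.2f\n",
              m$sensitivity, m$specificity, m$gmean, m$balanced_accuracy))
  invisible(x)
}

#' @export
summary.prdi_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.prdi_fit")
}

#' @export
print.summary.prdi_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  g <- f$group_stats
  cat("\nMinima depth by class (z-units):\n")
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-4s n = %3d, median %.2f (IQR %.2f to %.2f)\n",
                g$label[i], g$n[i], g$median[i], g$q1[i], g$q3[i]))
  cat(sprintf("\nMann-Whitney U = %.1f (%s), p %s\n", f$mw$U, f$mw$method,
              format.pval(f$mw$p_value, digits = 3, eps = 1e-4)))
  cat(sprintf("Plateau: [%.3f, %.3f] z, midpoint %.3f\n",
              f$selection$plateau_range[1], f$selection$plateau_range[2],
              f$selection$optimal_threshold_z))
  invisible(x)
}

#' @export
coef.prdi_fit <- function(object, ...) {
  c(threshold_z = object$threshold_used)
}

#' Classify new events with a fitted threshold
#'
#' @param object a [prdi_fit()].
#' @param newdata numeric vector of depths (z-units) or a data frame with a
#'   `depth_z` column; defaults to the training events.
#' @param threshold_z override the fitted threshold.
#' @param ... unused.
#' @return Factor of predicted classes (levels `NRI`, `PRDI`).
#' @export
predict.prdi_fit <- function(object, newdata = NULL, threshold_z = NULL, ...) {
  thr <- threshold_z %||% object$threshold_used
  if (is.null(newdata)) newdata <- object$events
  if (is.numeric(newdata)) newdata <- data.frame(depth_z = newdata)
  classify_events(newdata, thr)$predicted
}

#' Plot a fitted PRDI classifier
#'
#' Three panels: the ROC curve, and G-mean and balanced accuracy as functions
#' of the candidate threshold, with the selected operating point marked.
#'
#' @param x a [prdi_fit()].
#' @param ... passed to the underlying plot calls.
#' @export
plot.prdi_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.2f)", x$roc$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  finite <- is.finite(x$sweep$threshold_z)
  graphics::plot(x$sweep$threshold_z[finite], x$sweep$gmean[finite],
                 type = "l", lwd = 2, xlab = "Threshold (z)",
                 ylab = "G-mean", main = "G-mean", ...)
  graphics::abline(v = x$threshold_used, lty = 2, col = "red")
  graphics::plot(x$sweep$threshold_z[finite],
                 x$sweep$balanced_accuracy[finite],
                 type = "l", lwd = 2, xlab = "Threshold (z)",
                 ylab = "Balanced accuracy", main = "Balanced accuracy", ...)
  graphics::abline(v = x$threshold_used, lty = 2, col = "red")
  invisible(x)
}
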