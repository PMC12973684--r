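#' Mann-Whitney U test for depth differences
#'
#' Compares two groups of breath-minimum depths. The statistic is oriented as
#' `U = #\{(a, b) : a < b\} + 0.5 * #ties`, so when group A holds the PRDI
#' depths (more negative = deeper) a large `U` means PRDI minima are deeper.
#' For `n_a * n_b <= 400` the two-sided p-value is exact, computed from the
#' permutation distribution of the rank sum via a shift (dynamic-programming)
#' algorithm over doubled midranks, which remains exact under ties; larger
#' problems use the normal approximation with tie and continuity corrections.
#'
#' @param depths_a,depths_b numeric vectors, both non-empty.
#' @param alternative only `"two_sided"` is provided.
#' @param method `"auto"` (switch at `n_a * n_b = 400`), `"exact"` or
#'   `"approx"`.
#' @return List with `U`, `p_value`, `method`, `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(-3, -2.5), c(-1, -0.5))
#' @export
mann_whitney <- function(depths_a, depths_b, alternative = "two_sided",
                         method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative, "two_sided")
  a <- as.numeric(depths_a); b <- as.numeric(depths_b)
  if (length(a) == 0L || length(b) == 0L)
    fail_validation("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) fail_validation("depths must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  u_gt <- ra - na * (na + 1) / 2          # pairs a > b (+ half ties)
  u <- na * nb - u_gt                     # pairs a < b (+ half ties)
  if (method == "auto") method <- if (na * nb <= 400) "exact" else "approx"

  if (method == "exact") {
    # permutation distribution of the smaller group's doubled rank sum
    d <- as.integer(round(2 * r))
    if (na <= nb) { m <- na; s_obs <- as.integer(round(2 * ra)) }
    else { m <- nb; s_obs <- as.integer(round(2 * sum(r[na + seq_len(nb)]))) }
    smax <- sum(sort(d, decreasing = TRUE)[seq_len(m)])
    f <- matrix(0, nrow = m + 1L, ncol = smax + 1L)   # f[k+1, s+1]
    f[1L, 1L] <- 1
    for (di in d) {
      for (k in seq.int(m, 1L)) {
        cols <- seq_len(smax + 1L - di)
        nz <- f[k, cols]
        if (any(nz != 0)) f[k + 1L, cols + di] <- f[k + 1L, cols + di] + nz
      }
    }
    counts <- f[m + 1L, ]
    s_vals <- 0:smax
    total <- sum(counts)
    p_le <- sum(counts[s_vals <= s_obs]) / total
    p_ge <- sum(counts[s_vals >= s_obs]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) fail_validation("all observations tied: test undefined")
    z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(U = u, p_value = p, method = method, n_a = na, n_b = nb)
}

#' Confusion counts for labeled, classified events
#'
#' Standard two-class counts with PRDI as the positive class:
#' TP = labeled PRDI and predicted PRDI, FP = labeled NRI and predicted PRDI,
#' FN = labeled PRDI and predicted NRI, TN = labeled NRI and predicted NRI.
#'
#' @param events data frame with `label` and `predicted` columns
#'   (values `PRDI`/`NRI`, no missing).
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_counts <- function(events) {
  if (!all(c("label", "predicted") %in% names(events)))
    fail_validation("events must have label and predicted columns")
  lab <- as.character(events$label)
  prd <- as.character(events$predicted)
  if (any(is.na(prd)) || any(is.na(lab)))
    fail_validation("every event needs a label and a predicted class")
  structure(list(
    TP = sum(lab == "PRDI" & prd == "PRDI"),
    FP = sum(lab == "NRI" & prd == "PRDI"),
    FN = sum(lab == "PRDI" & prd == "NRI"),
    TN = sum(lab == "NRI" & prd == "NRI")
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FP=%d FN=%d TN=%d>\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Threshold performance metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, their geometric mean
#' (G-mean) and arithmetic mean (balanced accuracy). Full precision is kept;
#' rounding to two decimals happens only in printed reports.
#'
#' @param counts a [confusion_counts()] object (or list with TP/FP/FN/TN).
#' @param threshold_z optional threshold to record alongside the metrics.
#' @return One-row data frame: `threshold_z`, `sensitivity`, `specificity`,
#'   `gmean`, `balanced_accuracy`.
#' @export
threshold_metrics <- function(counts, threshold_z = NA_real_) {
  if (counts$TP + counts$FN == 0)
    fail_validation("no positive-class (PRDI) events: sensitivity undefined")
  if (counts$TN + counts$FP == 0)
    fail_validation("no negative-class (NRI) events: specificity undefined")
  sens <- counts$TP / (counts$TP + counts$FN)
  spec <- counts$TN / (counts$TN + counts$FP)
  data.frame(threshold_z = threshold_z,
             sensitivity = sens, specificity = spec,
             gmean = sqrt(sens * spec),
             balanced_accuracy = (sens + spec) / 2)
}

# candidate thresholds: midpoints between consecutive sorted unique depths,
# plus one candidate below the minimum and one above the maximum
candidate_thresholds <- function(depths) {
  d <- sort(unique(depths))
  if (length(d) == 1L) return(c(d - 1, d + 1))
  c(d[1] - 1, (d[-length(d)] + d[-1]) / 2, d[length(d)] + 1)
}

#' ROC analysis of minima depth
#'
#' PRDI is the positive class and the score is `-depth_z` (deeper minima
#' score higher). The curve is traced over the candidate-threshold grid
#' (inter-depth midpoints plus sentinels) so every distinct operating point
#' appears once; AUC is the trapezoidal area, which equals the tie-aware
#' concordant-pair fraction `U / (n_pos * n_neg)`.
#'
#' @param events data frame with `depth_z` and `label` columns, both classes
#'   present.
#' @return Object of class `roc_result`: list with `thresholds` (ascending
#'   z-units), `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_depth <- function(events) {
  lab <- as.character(events$label)
  pd <- events$depth_z[lab == "PRDI"]
  nd <- events$depth_z[lab == "NRI"]
  if (length(pd) == 0L || length(nd) == 0L)
    fail_validation("ROC needs both PRDI and NRI events")
  thr <- candidate_thresholds(events$depth_z)
  tpr <- vapply(thr, function(t) mean(pd <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(nd <= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = length(pd), n_neg = length(nd)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.4f over %d PRDI / %d NRI events>\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sweep all candidate thresholds
#'
#' Computes the confusion-derived metrics at every candidate threshold
#' (inter-depth midpoints plus one candidate below and one above all
#' depths).
#'
#' @inheritParams roc_depth
#' @return Data frame, one row per candidate threshold (ascending):
#'   `threshold_z`, `sensitivity`, `specificity`, `gmean`,
#'   `balanced_accuracy`.
#' @export
sweep_thresholds <- function(events) {
  lab <- as.character(events$label)
  pd <- events$depth_z[lab == "PRDI"]
  nd <- events$depth_z[lab == "NRI"]
  if (length(pd) == 0L || length(nd) == 0L)
    fail_validation("threshold sweep needs both PRDI and NRI events")
  thr <- candidate_thresholds(events$depth_z)
  sens <- vapply(thr, function(t) mean(pd <= t), numeric(1))
  spec <- vapply(thr, function(t) mean(nd > t), numeric(1))
  data.frame(threshold_z = thr, sensitivity = sens, specificity = spec,
             gmean = sqrt(sens * spec),
             balanced_accuracy = (sens + spec) / 2)
}

#' Select the optimal threshold from a sweep
#'
#' Finds the candidate thresholds that maximize G-mean and balanced accuracy
#' simultaneously; the plateau is the longest contiguous run of such
#' candidates (first on ties) and the optimal threshold is its arithmetic
#' midpoint. If no candidate maximizes both metrics at once, the
#' balanced-accuracy plateau is used and the fallback is noted in the result.
#'
#' @param sweep data frame from [sweep_thresholds()].
#' @param tol numerical tolerance for attaining a maximum.
#' @return List with `optimal_threshold_z`, `plateau_range` (length-2
#'   numeric), `criterion` (`"both"` or `"balanced_accuracy"`).
#' @export
select_threshold <- function(sweep, tol = 1e-12) {
  at_g <- sweep$gmean >= max(sweep$gmean) - tol
  at_b <- sweep$balanced_accuracy >= max(sweep$balanced_accuracy) - tol
  both <- at_g & at_b
  if (any(both)) {
    set <- both
    criterion <- "both"
  } else {
    set <- at_b
    criterion <- "balanced_accuracy"
    message("G-mean and balanced-accuracy maxima do not coincide; ",
            "using the balanced-accuracy plateau")
  }
  r <- rle(set)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pick <- runs[which.max(r$lengths[runs])]
  lo <- sweep$threshold_z[starts[pick]]
  hi <- sweep$threshold_z[ends[pick]]
  list(optimal_threshold_z = (lo + hi) / 2,
       plateau_range = c(lo, hi),
       criterion = criterion)
}
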