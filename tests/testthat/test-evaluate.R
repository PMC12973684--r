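test_that("Mann-Whitney U and exact p match hand enumeration", {
  # A fully deeper than B: all 4 pairs concordant, p = 2/6
  r <- mann_whitney(c(-3.0, -2.5), c(-1.0, -0.5))
  expect_equal(r$U, 4)
  expect_equal(r$p_value, 2 / 6)
  expect_identical(r$method, "exact")

  # identical multisets: null symmetry
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)

  # empty group
  expect_error(mann_whitney(numeric(0), 1), class = "prdi_validation_error")
})

test_that("exact p agrees with wilcox.test on tie-free samples", {
  set.seed(11)
  for (rep in 1:25) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- rnorm(na); b <- rnorm(nb)
    ours <- mann_whitney(a, b, method = "exact")
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    # wilcox.test W counts pairs a > b; ours counts a < b
    expect_equal(ours$U, na * nb - unname(ref$statistic))
  }
})

test_that("exact and normal-approximation p agree near the switchover", {
  set.seed(12)
  for (rep in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    pe <- mann_whitney(a, b, method = "exact")$p_value
    pa <- mann_whitney(a, b, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
  # auto switches to the approximation above n_a * n_b = 400
  expect_identical(mann_whitney(rnorm(21), rnorm(20))$method, "approx")
  expect_identical(mann_whitney(rnorm(20), rnorm(20))$method, "exact")
})

test_that("confusion counts follow the standard two-class definitions", {
  ev <- data.frame(depth_z = c(-2.2, -1.0, -2.0, -1.5),
                   label = c("PRDI", "NRI", "NRI", "PRDI"))
  cc <- confusion_counts(classify_events(ev, -1.9))
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L), ignore_attr = TRUE)

  all_pos <- confusion_counts(classify_events(ev, Inf))
  expect_equal(all_pos$FN, 0); expect_equal(all_pos$TN, 0)

  empty <- confusion_counts(data.frame(label = character(0),
                                       predicted = character(0)))
  expect_equal(empty$TP + empty$FP + empty$FN + empty$TN, 0)
  expect_error(confusion_counts(data.frame(label = "PRDI")),
               class = "prdi_validation_error")
})

test_that("threshold metrics apply the four formulas exactly", {
  m <- threshold_metrics(list(TP = 17, FN = 8, TN = 19, FP = 6))
  expect_equal(m$sensitivity, 0.68)
  expect_equal(m$specificity, 0.76)
  expect_equal(m$balanced_accuracy, 0.72)
  expect_equal(m$gmean, sqrt(0.68 * 0.76))

  perfect <- threshold_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(perfect$gmean, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  e <- tryCatch(threshold_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1)),
                error = function(e) conditionMessage(e))
  expect_match(e, "PRDI")
})

test_that("ROC/AUC matches brute-force pair counting", {
  # perfect separation
  sep <- data.frame(depth_z = c(-3, -2.5, -1, -0.5),
                    label = c("PRDI", "PRDI", "NRI", "NRI"))
  expect_equal(roc_depth(sep)$auc, 1.0)

  # hand-computed with a tie: (1 + 0.5 + 1 + 0) / 4
  tied <- data.frame(depth_z = c(-2, -1, -2, 0),
                     label = c("PRDI", "PRDI", "NRI", "NRI"))
  expect_equal(roc_depth(tied)$auc, 0.625)

  expect_error(roc_depth(data.frame(depth_z = 1, label = "PRDI")),
               class = "prdi_validation_error")
})

test_that("AUC equals the tie-aware pair fraction and U/(n_pos*n_neg)", {
  set.seed(21)
  for (rep in 1:60) {
    ev <- random_instance()
    auc <- roc_depth(ev)$auc
    expect_equal(auc, auc_pair_count(ev), tolerance = 1e-12)
    u <- mann_whitney(ev$depth_z[ev$label == "PRDI"],
                      ev$depth_z[ev$label == "NRI"], method = "approx")$U
    npos <- sum(ev$label == "PRDI"); nneg <- sum(ev$label == "NRI")
    expect_equal(auc, u / (npos * nneg), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  for (rep in 1:10) {
    ev <- random_instance()
    ours <- roc_depth(ev)$auc
    ref <- pROC::auc(pROC::roc(response = ev$label, predictor = -ev$depth_z,
                               levels = c("NRI", "PRDI"), direction = "<",
                               quiet = TRUE))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("random labels give a null AUC near one half", {
  set.seed(23)
  aucs <- vapply(1:200, function(i) {
    depths <- rnorm(40, -1.5, 0.8)
    ev <- data.frame(depth_z = depths,
                     label = sample(rep(c("PRDI", "NRI"), 20)))
    roc_depth(ev)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("a separated instance yields the gap-midpoint optimal threshold", {
  ev <- data.frame(depth_z = c(-3, -2.5, -1, -0.5),
                   label = c("PRDI", "PRDI", "NRI", "NRI"))
  sw <- sweep_thresholds(ev)
  sel <- select_threshold(sw)
  expect_equal(sel$optimal_threshold_z, -1.75)
  expect_identical(sel$criterion, "both")
  # the plateau attains sensitivity = specificity = 1
  at <- sw[sw$threshold_z == -1.75, ]
  expect_equal(at$gmean, 1)

  # one event per class: optimum strictly between the depths
  two <- data.frame(depth_z = c(-2, -1), label = c("PRDI", "NRI"))
  s2 <- select_threshold(sweep_thresholds(two))
  expect_gt(s2$optimal_threshold_z, -2)
  expect_lt(s2$optimal_threshold_z, -1)
})

test_that("when metric maxima disagree the balanced-accuracy plateau is used", {
  # 8-event instance found by brute-force search: the G-mean and
  # balanced-accuracy argmax sets are disjoint
  ev <- data.frame(
    depth_z = c(-0.67, -0.20, -2.36, -1.04, -2.62, -2.20, -1.84, -2.96),
    label = c("PRDI", "PRDI", "PRDI", "NRI", "NRI", "NRI", "NRI", "NRI"))
  sw <- sweep_thresholds(ev)
  ig <- sw$gmean >= max(sw$gmean) - 1e-12
  ib <- sw$balanced_accuracy >= max(sw$balanced_accuracy) - 1e-12
  expect_false(any(ig & ib))
  expect_message(sel <- select_threshold(sw), "balanced-accuracy plateau")
  expect_identical(sel$criterion, "balanced_accuracy")
  expect_equal(sel$optimal_threshold_z,
               sw$threshold_z[which(ib)[1]])
})

test_that("sweep metrics obey AM-GM and threshold monotonicity", {
  set.seed(24)
  for (rep in 1:20) {
    ev <- random_instance()
    sw <- sweep_thresholds(ev)
    expect_true(all(sw$gmean <= sw$balanced_accuracy + 1e-12))
    eqs <- abs(sw$gmean - sw$balanced_accuracy) < 1e-12
    expect_equal(eqs, abs(sw$sensitivity - sw$specificity) < 1e-12)
    expect_true(all(diff(sw$sensitivity) >= 0))
    expect_true(all(diff(sw$specificity) <= 0))
  }
})
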