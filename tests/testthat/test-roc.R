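# ROC construction, AUC, DeLong CI and Youden threshold selection.
# (pair-counting and brute-force cutpoint oracles live in helper-oracles.R)

fixture_scores <- c(5, 6, 7, 1, 2, 6)
fixture_labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)

test_that("candidate thresholds are midpoints plus infinite endpoints", {
  pts <- roc_points(fixture_scores, fixture_labels)
  expect_true(all(c(-Inf, 3.5, 6.5, Inf) %in% pts$threshold))
  expect_equal(min(pts$threshold), -Inf)
  expect_equal(max(pts$threshold), Inf)

  sep <- roc_points(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(sep$sensitivity == 1 & sep$specificity == 1))
  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Youden selection matches the worked fixture and brute force", {
  y <- youden_threshold(roc_points(fixture_scores, fixture_labels))
  expect_equal(y$threshold, 3.5)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(y$J, 2 / 3, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(0:24, n, replace = TRUE)   # heavy integer ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    for (orient in c("greater", "less")) {
      y <- youden_threshold(roc_points(scores, labels, orient))
      bf <- youden_brute_force(scores, labels, orient)
      expect_equal(y$J, bf$J, tolerance = 1e-12)
      expect_equal(y$sensitivity, bf$sensitivity, tolerance = 1e-12)
    }
  }
})

test_that("integer scores give half-integer Youden thresholds", {
  set.seed(32)
  scores <- sample(0:21, 60, replace = TRUE)
  labels <- runif(60) < scores / 30
  if (any(labels) && !all(labels)) {
    y <- youden_threshold(roc_points(scores, labels))
    expect_true(is.infinite(y$threshold) || y$threshold %% 1 == 0.5)
  }
})

test_that("AUC is the Mann-Whitney pair-counting probability", {
  expect_equal(roc_auc(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(3, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)),
               0.5)

  set.seed(33)
  for (i in 1:15) {
    scores <- round(rnorm(30), 1)
    labels <- runif(30) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels),
                 auc_pair_counting(scores, labels), tolerance = 1e-12)
    # orientation flip mirrors the curve
    expect_equal(roc_auc(scores, labels, "less"),
                 1 - roc_auc(scores, labels), tolerance = 1e-12)
    # cross-check against pROC's trapezoidal AUC
    proc <- pROC::roc(labels, scores, levels = c(FALSE, TRUE),
                      direction = "<", quiet = TRUE)
    expect_equal(roc_auc(scores, labels), as.numeric(pROC::auc(proc)),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the trapezoidal area under the ROC points", {
  set.seed(34)
  for (i in 1:10) {
    scores <- sample(0:15, 40, replace = TRUE)
    labels <- runif(40) < 0.5
    if (!any(labels) || all(labels)) next
    pts <- roc_points(scores, labels)
    ord <- order(1 - pts$specificity, pts$sensitivity)
    fpr <- (1 - pts$specificity)[ord]; tpr <- pts$sensitivity[ord]
    trap <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    expect_equal(roc_auc(scores, labels), trap, tolerance = 1e-9)
  }
})

test_that("monotone score transforms preserve AUC and the operating point", {
  set.seed(35)
  scores <- rnorm(50); labels <- runif(50) < 0.5
  y1 <- youden_threshold(roc_points(scores, labels))
  y2 <- youden_threshold(roc_points(exp(scores), labels))
  expect_equal(roc_auc(scores, labels), roc_auc(exp(scores), labels),
               tolerance = 1e-12)
  expect_equal(y1$sensitivity, y2$sensitivity)
  expect_equal(y1$specificity, y2$specificity)
})

test_that("DeLong interval is sane, truncated, and near the bootstrap", {
  set.seed(36)
  scores <- c(rnorm(60, 1.2), rnorm(90))
  labels <- rep(c(TRUE, FALSE), c(60, 90))
  ci_d <- auc_ci(scores, labels, method = "delong")
  a <- roc_auc(scores, labels)
  expect_true(ci_d[1] <= a && a <= ci_d[2])
  ci_b <- auc_ci(scores, labels, method = "bootstrap", boot_n = 2000)
  expect_lt(max(abs(ci_d - ci_b)), 0.03)

  sep <- auc_ci(c(rnorm(50, 10), rnorm(50)), rep(c(TRUE, FALSE), each = 50))
  expect_equal(sep[2], 1)
  expect_error(auc_ci(c(1, 2, 3), c(TRUE, FALSE, FALSE)), "at least 2")
})

test_that("DeLong CI covers a known binormal AUC at nominal rate", {
  # two normals with true AUC pnorm(1/sqrt(2)) ~ 0.760, at the study's
  # class sizes (23 target vs 147 rest)
  true_auc <- pnorm(1 / sqrt(2))
  set.seed(37)
  cover <- 0
  for (i in 1:100) {
    scores <- c(rnorm(23, 1), rnorm(147))
    labels <- rep(c(TRUE, FALSE), c(23, 147))
    ci <- auc_ci(scores, labels)
    cover <- cover + (ci[1] <= true_auc && true_auc <= ci[2])
  }
  expect_gte(cover, 90)
})

test_that("battery derivation uses the right targets and orientations", {
  co <- cached_cohort(seed = 1)
  bat <- derive_battery(co)
  expect_named(bat, c("cp_percent", "npq_visual", "npq_total",
                      "hads_anxiety", "age"))
  expect_equal(bat$cp_percent$target_disease, "UVH")
  expect_equal(bat$age$target_disease, "CDA")
  expect_equal(bat$age$orientation, "less")
  expect_equal(bat$cp_percent$n_target, 23)   # UVH records with CP% observed
  for (b in bat) {
    expect_true(b$auc >= 0 && b$auc <= 1)
    expect_true(b$auc_ci_95[1] <= b$auc && b$auc <= b$auc_ci_95[2])
    expect_true(b$youden$J >= 0 && b$youden$J <= 1)
  }

  # a cohort where every CDA patient is younger than everyone else
  toy <- data.frame(
    diagnosis = rep(c("PPPD", "CDA", "UVH", "UD"), each = 10),
    age = c(runif(10, 50, 80), runif(10, 20, 30), runif(10, 55, 85),
            runif(10, 50, 80)),
    cp_percent = c(runif(10, 0, 15), runif(10, 0, 15), runif(10, 60, 90),
                   runif(10, 0, 15)),
    npq_visual = rep(5, 40), npq_total = rep(20, 40),
    hads_anxiety = rep(5, 40), complete_case = TRUE)
  toy$npq_visual <- toy$npq_visual + (toy$diagnosis == "PPPD") * 10
  toy$npq_total <- toy$npq_total + (toy$diagnosis == "PPPD") * 20
  toy$hads_anxiety <- toy$hads_anxiety + (toy$diagnosis == "CDA") * 8
  bat_toy <- derive_battery(toy)
  expect_equal(bat_toy$age$youden$J, 1)
  expect_equal(bat_toy$age$auc, 1)
})
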