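test_that("dichotomize counts positives and negatives per boundary", {
  eps <- tibble::tibble(
    intensity_class = rep(c("ST", "light", "MVPA"), c(10, 5, 5)),
    enmo_mg = runif(20)
  )
  st <- dichotomize(eps, "ST")
  expect_equal(sum(st$positive), 10)
  expect_equal(sum(!st$positive), 10)
  mv <- dichotomize(eps, "MVPA")
  expect_equal(sum(mv$positive), 5)
  expect_equal(sum(!mv$positive), 15)

  all_st <- tibble::tibble(intensity_class = rep("ST", 6), enmo_mg = runif(6))
  expect_error(dichotomize(all_st, "MVPA"), "MVPA")
  expect_error(dichotomize(all_st, "ST"), "no negatives")
})

test_that("perfect separation yields AUC 1 and shuffled labels about 0.5", {
  vals <- c(1:10, 21:30)
  pos <- rep(c(FALSE, TRUE), each = 10)
  expect_equal(roc_curve(vals, pos, "gte")$auc, 1)
  # ST direction: positives below negatives
  expect_equal(roc_curve(vals, rev(pos), "lt")$auc, 1)

  set.seed(14)
  v <- rnorm(500)
  p <- sample(rep(c(TRUE, FALSE), 250))
  expect_equal(roc_curve(v, p, "gte")$auc, 0.5, tolerance = 0.05)
})

test_that("trapezoid AUC equals brute-force concordance with ties halved", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(6:50, 1)
    vals <- sample(0:12, n, replace = TRUE)  # heavy ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    dir <- sample(c("gte", "lt"), 1)
    r <- roc_curve(vals, pos, dir)
    expect_equal(r$auc, oracle_auc(vals, pos, dir), tolerance = 1e-12)
  }
})

test_that("AUC and the DeLong machinery agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(2)
  v <- c(rnorm(70, 1), rnorm(90))
  p <- rep(c(TRUE, FALSE), c(70, 90))
  r <- roc_curve(v, p, "gte")
  pr <- suppressMessages(pROC::roc(response = p, predictor = v,
                                   direction = "<"))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- auc_ci(r)
  pci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(ci, pci[c(1, 3)], tolerance = 1e-10)

  v2 <- v + rnorm(160, 0, 1.5)
  r2 <- roc_curve(v2, p, "gte")
  own <- compare_auc(r, r2, paired = TRUE)
  pr2 <- suppressMessages(pROC::roc(response = p, predictor = v2,
                                    direction = "<"))
  pt <- pROC::roc.test(pr, pr2, method = "delong", paired = TRUE)
  expect_equal(own$z, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(own$p_value, pt$p.value, tolerance = 1e-10)
})

test_that("DeLong interval clips at 1 for perfect separation and shrinks with n", {
  r <- roc_curve(c(1:5, 11:15), rep(c(FALSE, TRUE), each = 5), "gte")
  expect_equal(auc_ci(r)[2], 1)

  width_at <- function(n, seed) {
    set.seed(seed)
    v <- c(rnorm(n, 1.19), rnorm(n))
    r <- roc_curve(v, rep(c(TRUE, FALSE), each = n), "gte")
    diff(auc_ci(r))
  }
  w_small <- mean(vapply(1:20, function(s) width_at(50, s), numeric(1)))
  w_big <- mean(vapply(1:20, function(s) width_at(200, s), numeric(1)))
  expect_lt(w_big, w_small)
})

test_that("a curve compared with itself gives difference 0 and p 1", {
  set.seed(5)
  v <- rnorm(60)
  p <- rep(c(TRUE, FALSE), 30)
  r <- roc_curve(v, p, "gte")
  out <- compare_auc(r, r, paired = TRUE)
  expect_equal(out$diff, 0)
  expect_equal(out$p_value, 1)
})

test_that("the DeLong test reliably detects a large AUC difference", {
  # true AUCs ~0.9 vs ~0.6 at n = 100/100 per curve
  mu_hi <- sqrt(2) * qnorm(0.9)
  mu_lo <- sqrt(2) * qnorm(0.6)
  p <- rep(c(TRUE, FALSE), each = 100)
  hits <- 0
  for (s in 1:40) {
    set.seed(400 + s)
    a <- c(rnorm(100, mu_hi), rnorm(100))
    b <- c(rnorm(100, mu_lo), rnorm(100))
    out <- compare_auc(roc_curve(a, p, "gte"), roc_curve(b, p, "gte"),
                       paired = FALSE)
    hits <- hits + (out$p_value < 0.01)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("paired comparison refuses mismatched epochs", {
  r1 <- roc_curve(rnorm(40), rep(c(TRUE, FALSE), 20), "gte")
  r2 <- roc_curve(rnorm(30), rep(c(TRUE, FALSE), 15), "gte")
  expect_error(compare_auc(r1, r2, paired = TRUE), "matching")
})

test_that("AUC grading bands use the published boundaries", {
  expect_equal(as.character(grade_auc(c(0.62, 0.74, 0.85, 0.90))),
               c("poor", "fair", "good", "excellent"))
  expect_equal(as.character(grade_auc(0.89)), "good")
  expect_equal(as.character(grade_auc(0.699)), "poor")
  expect_equal(as.character(grade_auc(0.80)), "good")
  expect_equal(as.character(grade_auc(0.70)), "fair")
  expect_error(grade_auc(1.2), "0, 1")
})

test_that("cut-point selection minimises the distance to the perfect corner", {
  # hand-computed: (1-.8)^2+(1-.9)^2 = .05 beats (1-.9)^2+(1-.6)^2 = .17
  expect_lt((1 - 0.8)^2 + (1 - 0.9)^2, (1 - 0.9)^2 + (1 - 0.6)^2)

  # perfectly separable: the separating threshold has distance 0
  r <- roc_curve(c(1:8, 21:28), rep(c(FALSE, TRUE), each = 8), "gte")
  cp <- select_cutpoint(r)
  expect_equal(cp$distance, 0)
  expect_equal(cp$threshold_raw, 14.5)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)

  set.seed(77)
  for (i in 1:40) {
    n <- sample(8:50, 1)
    vals <- sample(0:15, n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    r <- roc_curve(vals, pos, sample(c("gte", "lt"), 1))
    cp <- select_cutpoint(r)
    oracle <- oracle_select(r)
    expect_equal(cp$distance, oracle$distance, tolerance = 1e-12)
    expect_equal(cp$threshold_raw, oracle$threshold)
  }
})

test_that("specificity-priority selection honours the sensitivity floor", {
  set.seed(91)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    vals <- sample(0:15, n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(pos) < 2 || sum(!pos) < 2) next
    r <- roc_curve(vals, pos, "gte")
    cp <- select_cutpoint_spec_priority(r, min_sens = 0.6)
    oracle <- oracle_select_spec(r, 0.6)
    expect_gte(cp$sensitivity, 0.6)
    expect_equal(cp$specificity, oracle$specificity, tolerance = 1e-12)
    # with no floor, the rule reaches the global specificity maximum
    cp0 <- select_cutpoint_spec_priority(r, min_sens = 0)
    expect_equal(cp0$specificity,
                 max(r$specificities[is.finite(r$thresholds)]))
  }
  r <- roc_curve(c(1, 2, 10, 11), c(TRUE, TRUE, FALSE, FALSE), "gte")
  expect_error(select_cutpoint_spec_priority(r, min_sens = 0.9), "0.9")
})

test_that("ROC is monotone in the threshold and AUC is transform-invariant", {
  set.seed(6)
  vals <- rexp(80)
  pos <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  r <- roc_curve(vals, pos, "gte")
  expect_true(all(diff(r$sensitivities) <= 1e-12))      # sens falls with t
  expect_true(all(diff(1 - r$specificities) <= 1e-12))  # fpr falls with t

  r_log <- roc_curve(log(vals), pos, "gte")
  r_sq <- roc_curve(vals^2, pos, "gte")
  expect_equal(r_log$auc, r$auc, tolerance = 1e-12)
  expect_equal(r_sq$auc, r$auc, tolerance = 1e-12)
})

test_that("degenerate curves fall back to AUC 0.5 and are flagged", {
  r <- roc_curve(rep(3, 10), rep(c(TRUE, FALSE), 5), "gte")
  expect_equal(r$auc, 0.5)
  expect_true(r$degenerate)
  expect_true(is.na(select_cutpoint(r)$threshold))
})

test_that("tidy and glance expose the curve and its summary", {
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3), "gte")
  td <- tidy(r)
  expect_named(td, c("threshold", "sensitivity", "specificity"))
  gl <- glance(r)
  expect_equal(gl$auc, 1)
  expect_equal(as.character(gl$grade), "excellent")
  expect_s3_class(autoplot(r), "ggplot")
})
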