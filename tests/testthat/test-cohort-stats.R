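# Statistical operations: Mann-Whitney, chi-square, ROC, AUC comparison,
# odds ratios, logistic regression, reliability metrics, cohort report.

test_that("mann_whitney matches exact enumeration and handles full ties", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)

  tied <- mann_whitney(rep(7, 5), rep(7, 8))
  expect_equal(tied$U, 5 * 8 / 2)
  expect_equal(tied$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3),
               class = "dectpeel_validation_error")
})

test_that("mann_whitney agrees with wilcox.test across random instances", {
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    mine <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = mine$exact,
                                        correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("group separation at the reported scale is usually detected", {
  # outer layer 1 parameters at the printed group sizes: power > 0.5
  set.seed(31)
  rej <- mean(replicate(300, {
    co <- generate_cohort(cohort_spec(seed = sample.int(2^31 - 1, 1)))
    mann_whitney(co$nic_outer1_2mm[co$mvi == 0],
                 co$nic_outer1_2mm[co$mvi == 1])$p < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("chi-square on reader-score tables reproduces the reported p-values", {
  enh <- chi_square_2x2(two_by_two(9, 8, 5, 14))
  expect_equal(round(enh$p, 2), 0.10)
  marg <- chi_square_2x2(two_by_two(10, 10, 4, 12))
  expect_equal(round(marg$p, 2), 0.13)

  bal <- chi_square_2x2(two_by_two(5, 5, 5, 5))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  expect_error(chi_square_2x2(two_by_two(0, 0, 3, 4)),
               class = "dectpeel_degenerate_table")
})

test_that("roc_auc: separation, binary scores, permutation behavior", {
  lab <- c(rep(0, 20), rep(1, 20))
  sep <- roc_auc(c(rnorm(20, 0), rnorm(20, 100)), lab)
  expect_equal(sep$auc, 1)

  # binary reader score built from the printed counts
  sc <- c(rep(1, 8), rep(0, 14), rep(1, 9), rep(0, 5))
  labs <- c(rep(0, 22), rep(1, 14))
  rb <- roc_auc(sc, labs)
  expect_equal(round(rb$auc, 2), 0.64)
  # binary-predictor identity: AUC = (sens + spec) / 2 exactly
  expect_equal(rb$auc, (9 / 14 + 14 / 22) / 2, tolerance = 1e-12)
  expect_equal(rb$auc, (rb$sensitivity + rb$specificity) / 2,
               tolerance = 1e-12)

  set.seed(5)
  big <- roc_auc(rnorm(4000), sample(rep(0:1, 2000)))
  expect_within(big$auc, 0.5, 0.03)
  expect_error(roc_auc(rnorm(5), rep(1, 5)),
               class = "dectpeel_validation_error")
})

test_that("trapezoidal AUC equals the tie-half-credit U statistic on random instances", {
  set.seed(41)
  for (i in 1:1000) {
    n1 <- sample(2:12, 1)
    n0 <- sample(2:12, 1)
    labels <- c(rep(0, n0), rep(1, n1))
    scores <- sample(0:5, n0 + n1, replace = TRUE)  # heavy ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, u_statistic(scores, labels) / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("Youden cutoff reproduces a sensitivity/specificity pair consistent with its AUC", {
  set.seed(6)
  co <- generate_cohort(cohort_spec(seed = 17L))
  r <- roc_auc(co$nic_outer1_2mm, co$mvi)
  pred_pos <- co$nic_outer1_2mm >= r$cutoff
  expect_equal(mean(pred_pos[co$mvi == 1]), r$sensitivity)
  expect_equal(mean(!pred_pos[co$mvi == 0]), r$specificity)
})

test_that("compare_auc: identity, rank invariance, null calibration", {
  labs <- c(rep(0, 22), rep(1, 14))
  set.seed(3)
  x <- rnorm(36, mean = labs)
  expect_equal(compare_auc(x, x, labs), list(delta_auc = 0, p = 1))
  mono <- compare_auc(x, exp(2 * x) + 5, labs)
  expect_equal(mono$delta_auc, 0)

  # correlated null scores: type-I error close to nominal 0.05
  set.seed(7)
  rej <- mean(replicate(400, {
    z <- rnorm(60, mean = rep(0:1, each = 30))
    a <- z + rnorm(60, sd = 0.8)
    b <- z + rnorm(60, sd = 0.8)
    compare_auc(a, b, rep(0:1, each = 30))$p < 0.05
  }))
  expect_within(rej, 0.05, 0.035)
  expect_error(compare_auc(1:5, 1:4, c(0, 0, 1, 1, 1)),
               class = "dectpeel_validation_error")
})

test_that("odds ratios and Woolf intervals match the reported 2x2 arithmetic", {
  enh <- odds_ratio(two_by_two(9, 5, 8, 14))
  expect_equal(enh$or, 3.15)
  expect_equal(round(enh$ci_low, 2), 0.78)
  expect_equal(round(enh$ci_high, 2), 12.73)

  marg <- odds_ratio(two_by_two(10, 4, 10, 12))
  expect_equal(marg$or, 3.00)

  sym <- odds_ratio(two_by_two(6, 6, 6, 6))
  expect_equal(sym$or, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)

  zero <- odds_ratio(two_by_two(5, 0, 3, 7))
  expect_true(zero$corrected)
  expect_error(odds_ratio(two_by_two(0, 4, 6, 0)),
               class = "dectpeel_undefined_or")
})

test_that("univariate logistic OR on a binary predictor equals the cross-product ratio", {
  labs <- c(rep(0, 22), rep(1, 14))
  sc <- c(rep(1, 8), rep(0, 14), rep(1, 9), rep(0, 5))
  fit <- logistic_fit(data.frame(mvi = labs, enh = sc), "mvi", "enh")
  target <- odds_ratio(two_by_two(9, 5, 8, 14))
  expect_equal(fit$coefficients$or[2], target$or, tolerance = 1e-6)
  expect_equal(fit$coefficients$ci_low[2], target$ci_low, tolerance = 1e-4)
  expect_true(fit$converged)

  # outcome independent of predictors at large n: OR near 1
  set.seed(13)
  nulltab <- data.frame(mvi = rbinom(4000, 1, 0.4), x = rnorm(4000))
  nullfit <- logistic_fit(nulltab, "mvi", "x")
  expect_within(nullfit$coefficients$or[2], 1, 0.1)

  # dichotomization happens before fitting
  dft <- data.frame(mvi = labs, nic = ifelse(sc == 1, 0.12, 0.05))
  fit2 <- logistic_fit(dft, "mvi", "nic", dichotomize = c(nic = 0.082))
  expect_equal(fit2$coefficients$or[2], target$or, tolerance = 1e-6)
})

test_that("ICC matches an aov-based variance-component oracle and categories band correctly", {
  ratings <- cbind(c(9, 8, 7, 6, 5, 4), c(8.7, 8.2, 6.9, 6.4, 5.1, 4.3))
  n <- nrow(ratings); k <- ncol(ratings)
  long <- data.frame(y = as.vector(ratings),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  oracle <- (ms[1] - ms[3]) /
    (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
  got <- icc(ratings)
  expect_equal(got$icc, oracle, tolerance = 1e-10)
  expect_equal(got$category, "excellent")

  expect_equal(icc(cbind(1:6, 1:6))$icc, 1)
  set.seed(2)
  noisy <- icc(cbind(rnorm(500), rnorm(500)))
  expect_lt(abs(noisy$icc), 0.15)
  expect_equal(noisy$category, "poor")
  expect_error(icc(cbind(rep(1, 5), rep(1, 5))),
               class = "dectpeel_degenerate")
})

test_that("Cohen's kappa matches the hand formula and an independent implementation", {
  # 2x2 rater table (20, 5; 10, 15): po = 0.7, pe = 0.5, kappa = 0.4
  r1 <- c(rep("a", 25), rep("b", 25))
  r2 <- c(rep("a", 20), rep("b", 5), rep("a", 10), rep("b", 15))
  got <- cohen_kappa(r1, r2)
  expect_equal(got$kappa, 0.4)
  expect_equal(got$category, "moderate")

  expect_equal(cohen_kappa(r1, r1)$kappa, 1)
  set.seed(9)
  ind <- cohen_kappa(sample(0:1, 2000, TRUE), sample(0:1, 2000, TRUE))
  expect_lt(abs(ind$kappa), 0.1)

  skip_if_not_installed("e1071")
  ref <- e1071::classAgreement(table(r1, r2))$kappa
  expect_equal(got$kappa, ref, tolerance = 1e-12)
})

test_that("cohort_report assembles group, ROC and regression tables deterministically", {
  qual <- data.frame(feature = c("peritumoral_enhancement",
                                 "nonsmooth_margin"),
                     p_neg = c(8 / 22, 10 / 22), p_pos = c(9 / 14, 10 / 14))
  co <- generate_cohort(cohort_spec(qualitative = qual, seed = 23L))
  rep1 <- cohort_report(co)
  rep2 <- cohort_report(co)
  expect_equal(rep1$groups, rep2$groups)
  expect_equal(nrow(rep1$roc), 9)  # 7 NIC + 2 qualitative features
  expect_true(all(rep1$roc$ci_low <= rep1$roc$auc &
                    rep1$roc$auc <= rep1$roc$ci_high))
  # at most one NIC feature survives into the multivariate model
  expect_lte(sum(grepl("^nic_", rep1$screened)), 1)

  # single-feature table -> exactly one ROC row
  single <- co[, c("patient_id", "mvi", "nic_outer1_2mm")]
  expect_equal(nrow(cohort_report(single)$roc), 1)

  # all-missing feature excluded with a log entry
  co$broken <- NA_real_
  expect_message(rep3 <- cohort_report(co), "excluded")
  expect_true("broken" %in% rep3$excluded)
})

test_that("label permutation admits roughly the nominal fraction of null features", {
  co <- generate_cohort(cohort_spec(seed = 29L))
  set.seed(37)
  fracs <- replicate(60, {
    perm <- co
    perm$mvi <- sample(perm$mvi)
    # permuted labels can separate by chance; those warnings are expected
    rep <- suppressWarnings(cohort_report(perm))
    sum(rep$groups$p < 0.10) / 7
  })
  expect_within(mean(fracs), 0.10, 0.07)
})
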