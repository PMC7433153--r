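# Cohort-level statistics: Mann-Whitney, chi-square, ROC with DeLong
# confidence intervals and Youden cutoffs, paired AUC comparison, odds
# ratios with Woolf intervals, logistic regression, ICC and Cohen's kappa.
# ROC machinery is delegated to pROC; the Mann-Whitney test is implemented
# directly because its contract here (exact-enumeration switch, tie
# half-credit U, p = 1 on zero variance) must hold on fully tied input.

#' Mann-Whitney U test
#'
#' Two-sided test that two samples come from one distribution. The U
#' statistic counts pairs where `group_a` exceeds `group_b`, with half
#' credit for ties. P-values by exact enumeration (via the Wilcoxon
#' distribution) when there are no ties and `n_a * n_b <= 400`, otherwise
#' by normal approximation with tie-corrected variance. Fully tied input
#' gives `U = n_a * n_b / 2`, `p = 1`.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @return list `U`, `p`, `exact`.
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a)
  nb <- length(group_b)
  if (na == 0L || nb == 0L)
    stop_dectpeel("both groups must be non-empty",
                  "dectpeel_validation_error")
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(group_a, group_b))
  has_ties <- any(ties > 1)
  N <- na + nb
  if (!has_ties && na * nb <= 400) {
    p <- min(1, 2 * min(stats::pwilcox(U, na, nb),
                        stats::pwilcox(na * nb - U, na, nb)))
    return(list(U = U, p = p, exact = TRUE))
  }
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - na * nb / 2) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

#' 2x2 contingency table
#'
#' Layout: rows are exposure (present / absent), columns are case status
#' (case / control), i.e. `a` = exposed cases, `b` = exposed controls,
#' `c` = unexposed cases, `d` = unexposed controls.
#'
#' @param a,b,c_,d_ non-negative integer counts.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c_, d_) {
  cells <- c(a, b, c_, d_)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_dectpeel("cells must be non-negative integers",
                  "dectpeel_validation_error")
  structure(list(a = a, b = b, c = c_, d = d_), class = "two_by_two")
}

as_matrix_2x2 <- function(t) matrix(c(t$a, t$c, t$b, t$d), 2L, 2L)

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (`correct = TRUE` for the Yates
#' variant), 1 degree of freedom.
#'
#' @param t a [two_by_two()].
#' @param correct apply Yates continuity correction.
#' @return list `statistic`, `p`.
#' @export
chi_square_2x2 <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  m <- as_matrix_2x2(t)
  if (sum(m) == 0 || any(outer(rowSums(m), colSums(m)) == 0))
    stop_dectpeel("degenerate table: an expected count is zero",
                  "dectpeel_degenerate_table")
  res <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' ROC curve analysis
#'
#' AUC (trapezoidal, equal to the tie-half-credit U statistic divided by
#' `n_pos * n_neg`), DeLong 95% confidence interval, and the Youden-optimal
#' cutoff (ties broken toward higher specificity) with sensitivity and
#' specificity there. Scores at or above the cutoff are classified
#' positive.
#'
#' @param scores numeric predictor values.
#' @param labels 0/1 outcome, both classes present.
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `n_pos`, `n_neg`, and the
#'   underlying pROC object in `roc`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop_dectpeel("both outcome classes must be present",
                  "dectpeel_validation_error")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[which.max(best$specificity), , drop = FALSE]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 cutoff = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0),
                 roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g: sens %.1f%%, spec %.1f%% (n=%d/%d)\n",
    x$auc, x$ci_low, x$ci_high, x$cutoff, 100 * x$sensitivity,
    100 * x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired comparison of two ROC curves
#'
#' DeLong's test on two score vectors measured on the same subjects.
#' Rank-preserving transforms of a score leave its placements unchanged, so
#' the difference then has zero variance; a zero AUC difference with zero
#' variance is reported as `p = 1`.
#'
#' @param scores_a,scores_b paired score vectors (same subjects, same
#'   length).
#' @param labels shared 0/1 outcome.
#' @return list `delta_auc`, `p`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_dectpeel("paired scores and labels must have equal length",
                  "dectpeel_validation_error")
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  ra <- pROC::roc(labels[keep], scores_a[keep], levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels[keep], scores_b[keep], levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  delta <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  p <- tryCatch(
    suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                    paired = TRUE)$p.value),
    error = function(e) NaN)
  if (is.na(p) && abs(delta) < 1e-12) p <- 1
  list(delta_auc = delta, p = p)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a*d)/(b*c)`; Woolf interval
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any single
#' cell is zero the Haldane-Anscombe +0.5 correction is applied to every
#' cell; a zero diagonal or anti-diagonal (both `a, d` or both `b, c` zero)
#' leaves the OR undefined.
#'
#' @param t a [two_by_two()].
#' @return list `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if ((t$a == 0 && t$d == 0) || (t$b == 0 && t$c == 0))
    stop_dectpeel("odds ratio undefined: zero cells in a cross pattern",
                  "dectpeel_undefined_or")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = or * exp(-1.96 * se), ci_high = or * exp(1.96 * se),
       corrected = corrected)
}

#' Binary logistic regression with Wald intervals
#'
#' Maximum-likelihood fit (IRLS via `stats::glm`); odds ratios are
#' exponentiated coefficients with Wald 95% intervals. Continuous
#' predictors listed in `dichotomize` are converted to indicators of
#' exceeding the supplied cutoff before fitting. Coefficients diverging
#' beyond +/-15 on the logit scale flag (quasi-)separation.
#'
#' @param table data.frame with outcome and predictors.
#' @param outcome name of a 0/1 column.
#' @param predictors character vector of predictor columns.
#' @param dichotomize named numeric vector of cutoffs; each named predictor
#'   is replaced by `as.integer(x > cutoff)`.
#' @return object of class `logistic_fit`: `coefficients` (data.frame with
#'   term/estimate/se/or/ci_low/ci_high/p), `converged`, `separation`,
#'   `variables`, `n`.
#' @export
logistic_fit <- function(table, outcome, predictors, dichotomize = NULL) {
  if (!outcome %in% names(table) || !all(predictors %in% names(table)))
    stop_dectpeel("outcome or predictor columns missing from table",
                  "dectpeel_validation_error")
  y <- table[[outcome]]
  if (!all(y %in% c(0, 1, NA)))
    stop_dectpeel("outcome must be binary 0/1", "dectpeel_validation_error")
  dat <- table[, c(outcome, predictors), drop = FALSE]
  for (v in names(dichotomize))
    dat[[v]] <- as.integer(dat[[v]] > dichotomize[[v]])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat,
                              control = list(maxit = 50)))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      or = exp(unname(est)),
                      ci_low = exp(unname(est - 1.96 * se)),
                      ci_high = exp(unname(est + 1.96 * se)),
                      p = unname(2 * pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  separation <- isTRUE(any(abs(est[-1]) > 15, na.rm = TRUE))
  if (separation)
    warning("possible separation: a coefficient diverged; estimates capped by iteration limit")
  structure(list(coefficients = coefs, converged = fit$converged,
                 separation = separation, variables = predictors,
                 n = nrow(dat)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n,
      if (!x$converged) "(NOT converged)" else "", "\n")
  df <- x$coefficients
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-28s OR %6.2f (%.2f-%.2f)  p=%.3f\n", df$term[i],
                df$or[i], df$ci_low[i], df$ci_high[i], df$p[i]))
  invisible(x)
}

agreement_category <- function(x) {
  x <- round(x, 10)  # guard band edges against floating-point droop
  if (x < 0.4) "poor" else if (x < 0.6) "moderate"
  else if (x <= 0.8) "good" else "excellent"
}

#' Intraclass correlation coefficient, ICC(A,1)
#'
#' Two-way model, absolute agreement, single measurement: from the two-way
#' ANOVA mean squares (subjects MSR, raters MSC, residual MSE),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Categorized poor / moderate / good / excellent at 0.4 / 0.6 / 0.8.
#'
#' @param ratings numeric matrix or data.frame, one row per subject, one
#'   column per rater/session (>= 3 subjects, >= 2 columns).
#' @return list `icc`, `category`.
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2 || anyNA(m))
    stop_dectpeel("need >= 3 complete subjects and >= 2 raters",
                  "dectpeel_validation_error")
  if (stats::var(as.vector(m)) == 0)
    stop_dectpeel("zero total variance: ICC undefined",
                  "dectpeel_degenerate")
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  list(icc = val, category = agreement_category(val))
}

#' Cohen's kappa for two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the raters' marginals. Perfect agreement on
#' a single category returns 1; `p_e = 1` with imperfect agreement is
#' undefined.
#'
#' @param rater1,rater2 equal-length categorical vectors.
#' @return list `kappa`, `category`.
#' @export
cohen_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2) || length(rater1) == 0)
    stop_dectpeel("raters must give equal-length non-empty ratings",
                  "dectpeel_validation_error")
  po <- mean(rater1 == rater2)
  lev <- union(unique(rater1), unique(rater2))
  p1 <- table(factor(rater1, levels = lev)) / length(rater1)
  p2 <- table(factor(rater2, levels = lev)) / length(rater2)
  pe <- sum(p1 * p2)
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12)
      return(list(kappa = 1, category = "excellent"))
    stop_dectpeel("chance agreement 1 with imperfect agreement: kappa undefined",
                  "dectpeel_degenerate")
  }
  val <- (po - pe) / (1 - pe)
  list(kappa = val, category = agreement_category(val))
}
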