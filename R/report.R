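# Cohort-level report: group summaries with Mann-Whitney p per feature,
# per-feature ROC, univariate screen, and multivariate logistic regression
# -- the synthetic analogue of a group-comparison / diagnostic-performance /
# multivariate-analysis table trio.

is_binary_col <- function(x) all(x %in% c(0, 1, NA))

#' Full cohort statistical report
#'
#' For every feature column (everything except `patient_id` and the
#' outcome): group means +/- SD and a Mann-Whitney p (chi-square for binary
#' reader scores); ROC with DeLong CI and Youden cutoff; then a univariate
#' screen at `screen_alpha`, with continuous survivors dichotomized at
#' their Youden cutoffs and — among NIC features — only the one with the
#' highest AUC admitted (multicollinearity guard), feeding one multivariate
#' logistic fit. Missing cells are dropped pairwise per feature;
#' all-missing features are excluded and logged.
#'
#' @param table cohort data.frame with `patient_id`, `mvi` and features.
#' @param config list: `screen_alpha` (default 0.10), `outcome` (default
#'   `"mvi"`).
#' @return object of class `cohort_report`: `groups` (data.frame),
#'   `roc` (data.frame), `univariate` (data.frame), `multivariate`
#'   (a `logistic_fit` or `NULL`), `screened` (character), `excluded`
#'   (character).
#' @export
cohort_report <- function(table, config = list()) {
  cfg <- list(screen_alpha = 0.10, outcome = "mvi")
  cfg[names(config)] <- config
  outcome <- cfg$outcome
  if (!outcome %in% names(table))
    stop_dectpeel("outcome column missing", "dectpeel_validation_error")
  y <- table[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2L)
    stop_dectpeel("cohort contains a single outcome class",
                  "dectpeel_validation_error")
  feats <- setdiff(names(table), c("patient_id", outcome))

  excluded <- character()
  groups <- list()
  rocs <- list()
  for (f in feats) {
    x <- table[[f]]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok) || length(unique(y[ok])) < 2L) {
      excluded <- c(excluded, f)
      message("feature excluded (all missing or single class): ", f)
      next
    }
    xa <- x[ok & y == 0]
    xb <- x[ok & y == 1]
    binary <- is_binary_col(x)
    p <- if (binary) {
      t22 <- two_by_two(sum(xb == 1), sum(xa == 1), sum(xb == 0),
                        sum(xa == 0))
      chi_square_2x2(t22)$p
    } else {
      mann_whitney(xa, xb)$p
    }
    groups[[f]] <- data.frame(feature = f, n = sum(ok),
                              mean_neg = mean(xa), sd_neg = sd(xa),
                              mean_pos = mean(xb), sd_pos = sd(xb),
                              binary = binary, p = p,
                              stringsAsFactors = FALSE)
    rr <- roc_auc(x[ok], y[ok])
    rocs[[f]] <- data.frame(feature = f, auc = rr$auc, ci_low = rr$ci_low,
                            ci_high = rr$ci_high, cutoff = rr$cutoff,
                            sensitivity = rr$sensitivity,
                            specificity = rr$specificity,
                            stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, groups)
  rocs <- do.call(rbind, rocs)
  rownames(groups) <- rownames(rocs) <- NULL

  # univariate screen, NIC multicollinearity guard, multivariate fit
  screened <- groups$feature[groups$p < cfg$screen_alpha]
  nic_feats <- screened[grepl("^nic_", screened)]
  if (length(nic_feats) > 1L) {
    aucs <- rocs$auc[match(nic_feats, rocs$feature)]
    keep_nic <- nic_feats[which.max(aucs)]
    screened <- c(setdiff(screened, nic_feats), keep_nic)
  }
  screened <- screened[order(match(screened, groups$feature))]

  univariate <- NULL
  multivariate <- NULL
  if (length(screened)) {
    cuts <- numeric()
    for (f in screened) {
      if (!is_binary_col(table[[f]]))
        cuts[f] <- rocs$cutoff[rocs$feature == f]
    }
    uni <- list()
    for (f in screened) {
      fit <- logistic_fit(table, outcome, f,
                          dichotomize = cuts[intersect(f, names(cuts))])
      cf <- fit$coefficients[2, ]
      uni[[f]] <- data.frame(feature = f, or = cf$or, ci_low = cf$ci_low,
                             ci_high = cf$ci_high, p = cf$p,
                             cutoff = unname(cuts[f][1]) %||% NA_real_,
                             stringsAsFactors = FALSE)
    }
    univariate <- do.call(rbind, uni)
    rownames(univariate) <- NULL
    if (length(screened) >= 1L)
      multivariate <- logistic_fit(table, outcome, screened,
                                   dichotomize = as.list(cuts))
  }

  structure(list(groups = groups, roc = rocs, univariate = univariate,
                 multivariate = multivariate, screened = screened,
                 excluded = excluded, config = cfg),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n\nGroup comparison (mean +/- SD, Mann-Whitney/chi-square p):\n")
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-22s %5.3f +/- %5.3f | %5.3f +/- %5.3f  p=%.3f\n",
                g$feature[i], g$mean_neg[i], g$sd_neg[i], g$mean_pos[i],
                g$sd_pos[i], g$p[i]))
  cat("\nDiagnostic performance:\n")
  r <- x$roc
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-22s AUC %.3f (%.2f-%.2f) cutoff %.4g sens %.0f%% spec %.0f%%\n",
                r$feature[i], r$auc[i], r$ci_low[i], r$ci_high[i],
                r$cutoff[i], 100 * r$sensitivity[i],
                100 * r$specificity[i]))
  if (!is.null(x$univariate)) {
    cat("\nUnivariate (dichotomized) odds ratios for screened features:\n")
    u <- x$univariate
    for (i in seq_len(nrow(u)))
      cat(sprintf("  %-22s OR %.2f (%.2f-%.2f)  p=%.3f\n", u$feature[i],
                  u$or[i], u$ci_low[i], u$ci_high[i], u$p[i]))
  }
  if (!is.null(x$multivariate)) {
    cat("\nMultivariate model:\n")
    print(x$multivariate)
  }
  if (length(x$excluded))
    cat("\nExcluded features:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
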