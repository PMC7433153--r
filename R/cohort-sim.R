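# Cohort-level feature simulation. Each NIC feature is drawn per patient
# from a normal distribution truncated at 0 with the group's mean and SD --
# the simplest generative model consistent with reporting only means +/- SD
# for a non-negative concentration. Features are independent by default; an
# optional shared-patient random effect induces positive inter-feature
# correlation within a patient.

# Group means and SDs of peritumoral/intratumoral NIC at 2-mm thickness for
# tumors without (neg) and with (pos) microvascular invasion.
default_nic_features <- function() {
  data.frame(
    feature = c("nic_outer1_2mm", "nic_outer2_2mm", "nic_inner1_2mm",
                "nic_inner2_2mm", "nic_voi_o1_2mm", "nic_voi_o2_2mm",
                "nic_voi_i1_2mm"),
    mean_neg = c(0.07, 0.05, 0.12, 0.15, 0.11, 0.09, 0.15),
    sd_neg   = c(0.03, 0.03, 0.07, 0.08, 0.05, 0.04, 0.08),
    mean_pos = c(0.10, 0.07, 0.16, 0.19, 0.14, 0.12, 0.19),
    sd_pos   = c(0.03, 0.03, 0.04, 0.07, 0.03, 0.03, 0.07),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic patient cohort
#'
#' @param n_neg,n_pos group sizes (MVI-negative / MVI-positive), each >= 2.
#' @param features data.frame with columns `feature`, `mean_neg`, `sd_neg`,
#'   `mean_pos`, `sd_pos`; defaults to the seven 2-mm NIC regions.
#' @param qualitative optional data.frame with columns `feature`, `p_neg`,
#'   `p_pos` giving per-group Bernoulli probabilities of binary reader
#'   scores; `NULL` for none.
#' @param patient_effect fraction of each feature's variance carried by a
#'   shared per-patient latent effect (0 = independent features, the
#'   default).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_neg = 22L, n_pos = 14L,
                        features = default_nic_features(),
                        qualitative = NULL,
                        patient_effect = 0, seed = 1L) {
  if (n_neg < 2 || n_pos < 2)
    stop_dectpeel("each group needs at least 2 patients",
                  "dectpeel_validation_error")
  need <- c("feature", "mean_neg", "sd_neg", "mean_pos", "sd_pos")
  if (!all(need %in% names(features)))
    stop_dectpeel("features must have columns feature/mean_neg/sd_neg/mean_pos/sd_pos",
                  "dectpeel_validation_error")
  if (any(features$sd_neg <= 0) || any(features$sd_pos <= 0))
    stop_dectpeel("all SDs must be > 0", "dectpeel_validation_error")
  if (patient_effect < 0 || patient_effect >= 1)
    stop_dectpeel("patient_effect must be in [0, 1)",
                  "dectpeel_validation_error")
  structure(list(n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
                 features = features, qualitative = qualitative,
                 patient_effect = patient_effect, seed = as.integer(seed)),
            class = "cohort_spec")
}

# exact inverse-CDF sampler for N(mean, sd) truncated to [0, Inf)
rtruncnorm0 <- function(n, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Generate a synthetic cohort feature table
#'
#' One row per patient with an `mvi` label (0/1) and one column per
#' feature. Draws are reproducible under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with columns `patient_id`, `mvi`, then features.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_neg + spec$n_pos
  mvi <- c(rep(0L, spec$n_neg), rep(1L, spec$n_pos))
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), mvi = mvi,
                    stringsAsFactors = FALSE)
  rho <- spec$patient_effect
  withr::with_seed(spec$seed, {
    u <- rnorm(n)  # shared patient latent effect (used when rho > 0)
    for (i in seq_len(nrow(spec$features))) {
      f <- spec$features[i, ]
      mu <- ifelse(mvi == 1, f$mean_pos, f$mean_neg)
      sigma <- ifelse(mvi == 1, f$sd_pos, f$sd_neg)
      if (rho == 0) {
        x <- rtruncnorm0(n, mu, sigma)
      } else {
        x <- mu + sigma * (sqrt(rho) * u + sqrt(1 - rho) * rnorm(n))
        bad <- which(x < 0)
        tries <- 0L
        while (length(bad) && tries < 1000L) {  # redraw the residual only
          x[bad] <- mu[bad] + sigma[bad] *
            (sqrt(rho) * u[bad] + sqrt(1 - rho) * rnorm(length(bad)))
          bad <- which(x < 0)
          tries <- tries + 1L
        }
        x[x < 0] <- 0
      }
      out[[f$feature]] <- x
    }
    if (!is.null(spec$qualitative)) {
      for (i in seq_len(nrow(spec$qualitative))) {
        q <- spec$qualitative[i, ]
        p <- ifelse(mvi == 1, q$p_pos, q$p_neg)
        out[[q$feature]] <- rbinom(n, 1L, p)
      }
    }
  })
  out
}
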