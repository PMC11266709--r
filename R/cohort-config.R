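#' Canonical ROI labels and edge names
#'
#' The four regions of interest spanning the overlapping inhibitory
#' control / emotion regulation network: dorsal anterior cingulate cortex,
#' left and right anterior insula, and right temporoparietal junction.
#' The six pairwise edges are reported in a fixed canonical order.
#'
#' @return Character vectors of labels.
#' @export
roi_labels_default <- function() c("dACC", "leftAI", "rightAI", "TPJ")

#' @rdname roi_labels_default
#' @export
edge_names <- function() {
  c("dACC_leftAI", "dACC_rightAI", "dACC_TPJ",
    "rightAI_leftAI", "leftAI_TPJ", "rightAI_TPJ")
}

#' @rdname roi_labels_default
#' @export
flanker_score_names <- function() {
  c("flanker_acc", "flanker_rt", "gratton_acc", "gratton_rt",
    "pe_acc", "pe_rt")
}

# columns that are never allowed to go missing
protected_columns <- function() {
  c("participant_id", "group", "age", "gender", "baseline_phq", "post_phq")
}

#' Default target inter-ROI correlation matrix
#'
#' Population Pearson correlations among the four ROI time courses, obtained
#' by back-transforming typical Fisher-z edge values for this network
#' (pooled across arms) with `tanh`. Symmetric, unit diagonal, positive
#' definite.
#'
#' @return A 4x4 correlation matrix with dimnames from [roi_labels_default()].
#' @export
default_edge_targets <- function() {
  z <- c(0.655, 0.55, 0.125, 0.715, 0.18, 0.385)
  r <- tanh(z)
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- r[1]
  m[1, 3] <- m[3, 1] <- r[2]
  m[1, 4] <- m[4, 1] <- r[3]
  m[2, 3] <- m[3, 2] <- r[4]
  m[2, 4] <- m[4, 2] <- r[5]
  m[3, 4] <- m[4, 3] <- r[6]
  dimnames(m) <- list(roi_labels_default(), roi_labels_default())
  m
}

#' Generative parameters for Flanker task behavior
#'
#' Condition-level accuracy probabilities and response-time means, their
#' between-participant spreads, and the sequential-dependency shifts that
#' make congruency-sequence (Gratton) and post-error adjustment effects
#' plantable. Defaults give group-level interference, Gratton and post-error
#' effect sizes typical of depressed samples on this task (accuracy
#' interference near 0.21, RT interference near 88 ms, Gratton accuracy
#' d around 0.75, post-error RT slowing d around 0.36).
#'
#' @param acc_congruent,acc_incongruent Accuracy probabilities by congruency.
#' @param acc_congruent_sd,acc_incongruent_sd Between-participant SDs of the
#'   condition accuracies.
#' @param rt_congruent,rt_incongruent Mean correct RT (ms) by congruency.
#' @param rt_between_sd Between-participant SD of a common RT shift applied
#'   to both conditions (ms).
#' @param rt_interference_sd Between-participant SD of the congruent vs
#'   incongruent RT difference (ms).
#' @param rt_sigma Lognormal shape (sdlog) of trial-level RT noise; 0 makes
#'   every RT equal to its condition mean.
#' @param gratton_acc_shift Accuracy increment on incongruent trials that
#'   follow a correct incongruent trial.
#' @param gratton_acc_sd Between-participant SD of that increment.
#' @param gratton_rt_shift RT decrement (ms) on incongruent trials following
#'   a correct incongruent trial (positive = faster, i.e. a Gratton RT
#'   effect); the default 0 reflects the absent group-level RT effect.
#' @param gratton_rt_sd Between-participant SD of that decrement.
#' @param pe_acc_shift Accuracy increment on trials following an error.
#' @param pe_acc_sd Between-participant SD of that increment.
#' @param pe_rt_shift RT increment (ms) on trials following an error
#'   (post-error slowing).
#' @param pe_rt_sd Between-participant SD of that increment.
#' @return A named list of class `behavior_params`.
#' @export
behavior_params <- function(acc_congruent = 0.97, acc_incongruent = 0.76,
                            acc_congruent_sd = 0.02, acc_incongruent_sd = 0.10,
                            rt_congruent = 420, rt_incongruent = 508,
                            rt_between_sd = 40, rt_interference_sd = 15,
                            rt_sigma = 0.25,
                            gratton_acc_shift = 0.07, gratton_acc_sd = 0.08,
                            gratton_rt_shift = 0, gratton_rt_sd = 15,
                            pe_acc_shift = 0, pe_acc_sd = 0.03,
                            pe_rt_shift = 7, pe_rt_sd = 18) {
  out <- as.list(environment())
  structure(out, class = "behavior_params")
}

#' Planted effects of baseline features on the post-treatment outcome
#'
#' Each row names a feature, its prognostic weight (effect in both arms) and
#' its group-interaction weight (additional effect in the treated arm), on
#' the standardized scale. The default directions mirror the pattern this
#' pipeline is designed to detect: slower (worse) Flanker RT interference
#' predicts higher post-treatment severity, more strongly under active
#' treatment; weaker right AI-left AI and stronger right AI-TPJ connectivity
#' predict higher severity, again more strongly under treatment; the Gratton
#' accuracy effect is protective and post-error accuracy harmful in the
#' treated arm only. Baseline severity carries a prognostic weight.
#'
#' @param ... Name-value pairs overriding defaults, each value a numeric
#'   vector `c(prognostic, interaction)`.
#' @return A tibble with columns `variable`, `prognostic`, `interaction`.
#' @export
outcome_coefficients <- function(...) {
  defaults <- list(
    baseline_phq   = c(0.30, 0),
    flanker_rt     = c(0.25, 0.20),
    rightAI_leftAI = c(-0.20, -0.15),
    rightAI_TPJ    = c(0.20, 0.15),
    gratton_acc    = c(0, -0.25),
    pe_acc         = c(0, 0.25)
  )
  override <- list(...)
  bad <- vapply(override, function(v) !is.numeric(v) || length(v) != 2,
                logical(1))
  if (any(bad)) {
    stop("each outcome coefficient must be numeric c(prognostic, interaction)")
  }
  defaults[names(override)] <- override
  tibble::tibble(
    variable = names(defaults),
    prognostic = vapply(defaults, `[`, numeric(1), 1),
    interaction = vapply(defaults, `[`, numeric(1), 2)
  )
}

#' Configuration of a synthetic two-arm cohort
#'
#' Bundles every knob of the synthetic-data generator: arm sizes, the
#' Flanker block structure (five blocks of 70 trials, 46 congruent and 24
#' incongruent), ROI time-series targets, the baseline severity range
#' (PHQ-9 10-23 at intake), planted outcome effects and missingness.
#'
#' @param n_per_arm Participants per arm.
#' @param n_blocks,trials_per_block,n_congruent_per_block,n_incongruent_per_block
#'   Flanker block structure; congruent + incongruent must equal
#'   `trials_per_block`.
#' @param roi_labels Four ROI labels, in canonical order.
#' @param target_edge_correlations 4x4 symmetric positive semi-definite
#'   correlation matrix with unit diagonal.
#' @param ts_length Number of resting-state timepoints per participant.
#' @param edge_between_sd Between-participant SD of edge strength on the
#'   Fisher-z scale.
#' @param baseline_phq_range Inclusive integer range for baseline PHQ-9.
#' @param prob_female Probability a participant is female.
#' @param age_mean,age_sd Age distribution (years).
#' @param behavior A [behavior_params()] list.
#' @param outcome_coefficients Tibble from [outcome_coefficients()];
#'   weights on the standardized scale.
#' @param outcome_intercept,group_main Intercept and treated-arm main effect
#'   of the latent (standardized-scale) outcome.
#' @param outcome_noise_sd SD of the Gaussian outcome noise on the
#'   standardized scale.
#' @param outcome_scale `c(mean, sd)` affine map from the latent outcome to
#'   displayed severity units; irrelevant to the modeling pipeline, which
#'   standardizes the outcome.
#' @param rsfc_missing_rate Probability a participant's scan is unusable,
#'   in which case all six edges go missing jointly.
#' @param n_gratton_qc,n_post_error_qc Total number of participants whose
#'   Gratton / post-error scores are missing after quality control (count
#'   mode mirrors the QC-failure bookkeeping of a real cohort).
#' @param seed Default generation seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 30,
                          n_blocks = 5, trials_per_block = 70,
                          n_congruent_per_block = 46,
                          n_incongruent_per_block = 24,
                          roi_labels = roi_labels_default(),
                          target_edge_correlations = default_edge_targets(),
                          ts_length = 200,
                          edge_between_sd = 0.18,
                          baseline_phq_range = c(10, 23),
                          prob_female = 38 / 60,
                          age_mean = 29.6, age_sd = 7.4,
                          behavior = behavior_params(),
                          outcome_coefficients = moderanet::outcome_coefficients(),
                          outcome_intercept = 0, group_main = -0.73,
                          outcome_noise_sd = 1,
                          outcome_scale = c(mean = 10.6, sd = 4.8),
                          rsfc_missing_rate = 0.15,
                          n_gratton_qc = 7, n_post_error_qc = 12,
                          seed = 17) {
  if (n_congruent_per_block + n_incongruent_per_block != trials_per_block) {
    stop("congruent + incongruent trial counts must equal trials_per_block")
  }
  if (n_per_arm < 1 || n_blocks < 1) stop("counts must be positive")
  if (length(roi_labels) != 4) stop("exactly 4 ROI labels required")
  check_correlation_target(target_edge_correlations)
  if (rsfc_missing_rate < 0 || rsfc_missing_rate >= 1) {
    stop("missing rates must lie in [0, 1)")
  }
  if (length(baseline_phq_range) != 2 ||
      baseline_phq_range[1] > baseline_phq_range[2]) {
    stop("baseline_phq_range must be c(lo, hi) with lo <= hi")
  }
  if (outcome_noise_sd < 0) stop("outcome_noise_sd must be non-negative")
  out <- as.list(environment())
  structure(out, class = "cohort_config")
}

check_correlation_target <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("target must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("target correlation matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("target correlation matrix must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "target correlation matrix is not positive semi-definite (eigenvalue %.4g)",
      min(ev)))
  }
  invisible(m)
}
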