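#' Latent per-participant generative parameters
#'
#' Houses the condition accuracies, RT means and sequential-dependency
#' shifts that drive one participant's simulated trial log. Tests and the
#' cohort generator construct these directly; all probabilities are clamped
#' to `[0, 1]` and RT means must be positive.
#'
#' @param acc_congruent,acc_incongruent Condition accuracy probabilities.
#' @param rt_congruent,rt_incongruent Condition mean RTs (ms) for correct
#'   responding.
#' @param rt_sigma Lognormal sdlog of trial-level RT noise (0 = noiseless).
#' @param gratton_acc_shift,gratton_rt_shift Accuracy increment / RT
#'   decrement on incongruent trials preceded by a correct incongruent trial.
#' @param pe_acc_shift,pe_rt_shift Accuracy increment / RT increment on
#'   trials immediately following an error.
#' @return A list of class `participant_truth`.
#' @export
participant_truth <- function(acc_congruent = 0.97, acc_incongruent = 0.76,
                              rt_congruent = 420, rt_incongruent = 508,
                              rt_sigma = 0.25,
                              gratton_acc_shift = 0.07, gratton_rt_shift = 0,
                              pe_acc_shift = 0, pe_rt_shift = 7) {
  if (rt_congruent <= 0 || rt_incongruent <= 0) stop("RT means must be positive")
  if (acc_congruent < 0 || acc_congruent > 1 ||
      acc_incongruent < 0 || acc_incongruent > 1) {
    stop("accuracy probabilities must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "participant_truth")
}

draw_participant_truth <- function(b) {
  clamp01 <- function(x) pmin(1, pmax(0, x))
  rt_shift <- rnorm(1, 0, b$rt_between_sd)
  rt_int <- rnorm(1, b$rt_incongruent - b$rt_congruent, b$rt_interference_sd)
  rt_c <- max(b$rt_congruent + rt_shift, 50)
  participant_truth(
    acc_congruent = clamp01(rnorm(1, b$acc_congruent, b$acc_congruent_sd)),
    acc_incongruent = clamp01(rnorm(1, b$acc_incongruent, b$acc_incongruent_sd)),
    rt_congruent = rt_c,
    rt_incongruent = max(rt_c + rt_int, 50),
    rt_sigma = b$rt_sigma,
    gratton_acc_shift = rnorm(1, b$gratton_acc_shift, b$gratton_acc_sd),
    gratton_rt_shift = rnorm(1, b$gratton_rt_shift, b$gratton_rt_sd),
    pe_acc_shift = rnorm(1, b$pe_acc_shift, b$pe_acc_sd),
    pe_rt_shift = rnorm(1, b$pe_rt_shift, b$pe_rt_sd)
  )
}

#' Simulate one participant's Flanker trial log
#'
#' Draws `n_blocks` blocks of trials in randomized within-block order.
#' Accuracy is Bernoulli with a probability that depends on congruency and,
#' through the truth's shift parameters, on the previous trial's congruency
#' and accuracy, so congruency-sequence and post-error effects can be
#' planted. RTs are lognormal (right-skewed, strictly positive) with the
#' condition mean as their expectation; `rt_sigma = 0` yields the mean
#' exactly. Uses the ambient RNG stream.
#'
#' @param truth A [participant_truth()].
#' @param config A [cohort_config()]; only the block structure is used.
#' @return A tibble with columns `block`, `trial`, `congruency` (`"c"`/`"i"`),
#'   `correct` (0/1), `rt_ms`.
#' @export
generate_flanker_trials <- function(truth, config = cohort_config()) {
  if (config$n_congruent_per_block + config$n_incongruent_per_block !=
      config$trials_per_block) {
    stop("congruent + incongruent trial counts must equal trials_per_block")
  }
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    congruency <- sample(c(rep("c", config$n_congruent_per_block),
                           rep("i", config$n_incongruent_per_block)))
    nt <- length(congruency)
    correct <- integer(nt)
    rt <- numeric(nt)
    for (t in seq_len(nt)) {
      incong <- congruency[t] == "i"
      p <- if (incong) truth$acc_incongruent else truth$acc_congruent
      mu <- if (incong) truth$rt_incongruent else truth$rt_congruent
      if (t > 1) {
        if (correct[t - 1] == 0) {
          p <- p + truth$pe_acc_shift
          mu <- mu + truth$pe_rt_shift
        } else if (incong && congruency[t - 1] == "i") {
          p <- p + truth$gratton_acc_shift
          mu <- mu - truth$gratton_rt_shift
        }
      }
      p <- min(1, max(0, p))
      mu <- max(mu, 1)
      correct[t] <- rbinom(1, 1, p)
      rt[t] <- if (truth$rt_sigma > 0) {
        rlnorm(1, log(mu) - truth$rt_sigma^2 / 2, truth$rt_sigma)
      } else {
        mu
      }
    }
    tibble::tibble(block = b, trial = seq_len(nt) - 1L,
                   congruency = congruency, correct = correct, rt_ms = rt)
  })
  dplyr::bind_rows(blocks)
}

#' Simulate correlated ROI time series
#'
#' Gaussian series whose population correlation matrix equals `target_r`,
#' built from independent factors through the Cholesky root of the target.
#' The sample correlation converges to the target as `ts_length` grows
#' (Fisher-z standard error roughly `1/sqrt(T - 3)`).
#'
#' @param target_r Symmetric positive semi-definite correlation matrix.
#' @param ts_length Number of timepoints (at least 4).
#' @param roi_labels Optional column labels.
#' @return A `ts_length` x 4 numeric matrix.
#' @export
generate_roi_timeseries <- function(target_r, ts_length,
                                    roi_labels = roi_labels_default()) {
  check_correlation_target(target_r)
  if (ts_length < 4) {
    stop("ts_length must be at least 4 (correlation undefined below that)")
  }
  p <- ncol(target_r)
  ev <- eigen(target_r, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  z <- matrix(rnorm(ts_length * p), ts_length, p)
  out <- z %*% t(L)
  colnames(out) <- roi_labels
  out
}

# jitter the base Fisher-z targets per participant, shrinking the jitter
# until the implied correlation matrix is positive semi-definite
jitter_edge_targets <- function(base_r, sd_z) {
  if (sd_z <= 0) return(base_r)
  p <- ncol(base_r)
  z <- atanh(base_r * 0.999999)
  diag(z) <- 0
  jit <- matrix(0, p, p)
  jit[upper.tri(jit)] <- rnorm(p * (p - 1) / 2, 0, sd_z)
  jit <- jit + t(jit)
  s <- 1
  for (i in 1:12) {
    m <- tanh(z + s * jit)
    diag(m) <- 1
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8) return(m)
    s <- s * 0.7
  }
  base_r
}

#' Plant outcomes on a feature table
#'
#' Computes the post-treatment outcome as a linear model on internally
#' standardized features plus treatment-group interactions plus Gaussian
#' noise, then maps the latent value to severity units through the affine
#' `outcome_scale` (identity when `c(0, 1)`). Group is coded 0 (control) / 1
#' (treated). Uses the ambient RNG stream.
#'
#' @param features Tibble with a `group` column (factor or 0/1) and every
#'   variable named in the config's `outcome_coefficients`.
#' @param config A [cohort_config()].
#' @return Numeric outcome vector, one value per row of `features`.
#' @export
generate_outcomes <- function(features, config = cohort_config()) {
  coefs <- config$outcome_coefficients
  missing_vars <- setdiff(coefs$variable, names(features))
  if (length(missing_vars) > 0) {
    stop("outcome coefficients name variables absent from features: ",
         paste(missing_vars, collapse = ", "))
  }
  g <- group_indicator(features$group)
  n <- nrow(features)
  latent <- rep(config$outcome_intercept, n) + config$group_main * g
  for (i in seq_len(nrow(coefs))) {
    if (coefs$prognostic[i] == 0 && coefs$interaction[i] == 0) next
    x <- features[[coefs$variable[i]]]
    if (!is.numeric(x)) stop("outcome variable must be numeric: ", coefs$variable[i])
    s <- sd(x, na.rm = TRUE)
    z <- if (is.finite(s) && s > 0) (x - mean(x, na.rm = TRUE)) / s else x * 0
    z[is.na(z)] <- 0  # undefined scores contribute the mean (zero effect)
    latent <- latent + coefs$prognostic[i] * z + coefs$interaction[i] * g * z
  }
  if (config$outcome_noise_sd > 0) {
    latent <- latent + rnorm(n, 0, config$outcome_noise_sd)
  }
  unname(config$outcome_scale[1] + config$outcome_scale[2] * latent)
}

group_indicator <- function(group) {
  if (is.numeric(group)) {
    if (!all(group %in% c(0, 1))) stop("numeric group must be coded 0/1")
    return(as.numeric(group))
  }
  f <- as.factor(group)
  if (nlevels(f) != 2) stop("group must have exactly two levels")
  as.numeric(f) - 1
}

#' Generate a complete synthetic cohort
#'
#' Draws participants in two arms (control coded `MAC`, treated coded
#' `iCBT`), simulates each participant's Flanker trial log and ROI time
#' series, scores behavior and connectivity, plants outcome effects per the
#' config, and injects missingness (joint scan-level edge missingness plus
#' quality-control masking of Gratton / post-error scores). Regenerating
#' with the same config and seed is byte-identical.
#'
#' @param config A [cohort_config()].
#' @param seed Generation seed; defaults to the config's.
#' @return An object of class `mnet_cohort`: a list with tibbles
#'   `participants`, `trials`, `timeseries`, `features` (post-missingness),
#'   `features_complete` (pre-missingness, the simulation truth), the
#'   per-participant `truth` parameters and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  withr::with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- 2 * config$n_per_arm
  ids <- sprintf("P%02d", seq_len(n))
  participants <- tibble::tibble(
    participant_id = ids,
    group = factor(rep(c("MAC", "iCBT"), each = config$n_per_arm),
                   levels = c("MAC", "iCBT")),
    age = round(rnorm(n, config$age_mean, config$age_sd), 1),
    gender = factor(ifelse(runif(n) < config$prob_female, "F", "M"),
                    levels = c("F", "M")),
    baseline_phq = sample(seq(config$baseline_phq_range[1],
                              config$baseline_phq_range[2]), n, replace = TRUE)
  )

  truths <- lapply(ids, function(id) draw_participant_truth(config$behavior))
  names(truths) <- ids

  trials <- purrr::map2_dfr(ids, truths, function(id, tr) {
    dplyr::mutate(generate_flanker_trials(tr, config),
                  participant_id = id, .before = 1)
  })

  timeseries <- purrr::map_dfr(ids, function(id) {
    target <- jitter_edge_targets(config$target_edge_correlations,
                                  config$edge_between_sd)
    ts <- generate_roi_timeseries(target, config$ts_length, config$roi_labels)
    out <- tibble::as_tibble(as.data.frame(ts))
    dplyr::mutate(out, participant_id = id,
                  timepoint = seq_len(config$ts_length), .before = 1)
  })

  scores <- score_flanker(trials)
  edges <- compute_edges(timeseries)

  features <- participants |>
    dplyr::left_join(dplyr::select(scores, "participant_id",
                                   dplyr::all_of(flanker_score_names())),
                     by = "participant_id") |>
    dplyr::left_join(edges, by = "participant_id")

  features$post_phq <- generate_outcomes(features, config)
  features <- dplyr::relocate(features, "post_phq", .after = "baseline_phq")

  features_missing <- inject_missingness(
    features,
    rsfc_rate = config$rsfc_missing_rate,
    n_gratton_qc = config$n_gratton_qc,
    n_post_error_qc = config$n_post_error_qc)

  structure(list(
    participants = dplyr::mutate(participants,
                                 post_phq = features$post_phq),
    trials = trials,
    timeseries = timeseries,
    features = features_missing,
    features_complete = features,
    flanker_scores = scores,
    truth = truths,
    config = config
  ), class = "mnet_cohort")
}

#' @export
print.mnet_cohort <- function(x, ...) {
  cat(sprintf(
    "<mnet_cohort> %d participants (%d per arm), %d trials each, %d timepoints\n",
    nrow(x$participants), x$config$n_per_arm,
    x$config$n_blocks * x$config$trials_per_block, x$config$ts_length))
  miss <- colSums(is.na(x$features))
  miss <- miss[miss > 0]
  if (length(miss)) {
    cat("missing:", paste(sprintf("%s=%d", names(miss), miss), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Inject missingness into a feature table
#'
#' Applies the cohort's missingness mechanism: each participant's scan is
#' unusable with probability `rsfc_rate` (all six connectivity edges go
#' missing jointly, mirroring scan-level loss) and, in count mode, Gratton
#' and post-error scores are masked so the total number of participants with
#' missing scores (including any natural quality-control failures) equals
#' the configured counts. Deletion is completely at random. Demographics,
#' group and the severity columns are never masked; asking to mask them is
#' an error. Uses the ambient RNG stream.
#'
#' @param features Feature tibble.
#' @param rsfc_rate Scan-loss probability in `[0, 1)`.
#' @param n_gratton_qc,n_post_error_qc Target counts of participants with
#'   missing Gratton / post-error scores.
#' @param extra Optional named list `variable = rate` for additional MCAR
#'   masking of individual columns.
#' @return The feature tibble with `NA`s injected.
#' @export
inject_missingness <- function(features, rsfc_rate = 0.15,
                               n_gratton_qc = 0, n_post_error_qc = 0,
                               extra = NULL) {
  if (rsfc_rate < 0 || rsfc_rate >= 1) stop("missing rates must lie in [0, 1)")
  n <- nrow(features)
  out <- features
  edge_cols <- intersect(edge_names(), names(out))
  if (rsfc_rate > 0 && length(edge_cols) > 0) {
    lost <- runif(n) < rsfc_rate
    out[lost, edge_cols] <- NA_real_
  }
  mask_to_count <- function(out, cols, target) {
    if (target <= 0 || !all(cols %in% names(out))) return(out)
    already <- rowSums(is.na(out[, cols, drop = FALSE])) > 0
    need <- target - sum(already)
    if (need > 0) {
      pick <- sample(which(!already), min(need, sum(!already)))
      out[pick, cols] <- NA_real_
    }
    out
  }
  out <- mask_to_count(out, c("gratton_acc", "gratton_rt"), n_gratton_qc)
  out <- mask_to_count(out, c("pe_acc", "pe_rt"), n_post_error_qc)
  if (!is.null(extra)) {
    bad <- intersect(names(extra), protected_columns())
    if (length(bad) > 0) {
      stop("cannot mask never-missing columns: ", paste(bad, collapse = ", "))
    }
    unknown <- setdiff(names(extra), names(out))
    if (length(unknown) > 0) {
      stop("unknown columns in extra: ", paste(unknown, collapse = ", "))
    }
    for (v in names(extra)) {
      r <- extra[[v]]
      if (r < 0 || r >= 1) stop("missing rates must lie in [0, 1)")
      out[runif(n) < r, v] <- NA
    }
  }
  out
}

#' Write a cohort to plain-text files
#'
#' Writes `participants.csv`, `trials.csv` (long format), one
#' `timeseries/<id>.csv` per participant (header = ROI labels) and
#' `truth.json` (planted generative parameters) under `dir`.
#'
#' @param cohort An `mnet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$features, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  for (id in unique(cohort$timeseries$participant_id)) {
    ts <- dplyr::filter(cohort$timeseries, .data$participant_id == id)
    utils::write.csv(dplyr::select(ts, -"participant_id", -"timepoint"),
                     file.path(dir, "timeseries", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      lapply(cohort$truth, function(t) t[!vapply(t, is.null, logical(1))]),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
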