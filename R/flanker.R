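#' Flanker interference scores
#'
#' Accuracy interference is mean accuracy on congruent minus incongruent
#' trials; RT interference is mean correct-trial RT on incongruent minus
#' congruent trials. Both are oriented so that higher values mean more
#' interference, i.e. worse inhibitory control.
#'
#' @param trials One participant's trial tibble with columns `congruency`
#'   (`"c"`/`"i"`), `correct` (0/1) and `rt_ms`.
#' @return A one-row tibble: `flanker_acc`, `flanker_rt`, and the cell
#'   counts `n_congruent`, `n_incongruent`, `n_congruent_correct`,
#'   `n_incongruent_correct`. A score whose contributing cell is empty is
#'   `NA`.
#' @export
score_interference <- function(trials) {
  cong <- trials$congruency == "c"
  acc_c <- mean_or_na(trials$correct[cong])
  acc_i <- mean_or_na(trials$correct[!cong])
  rt_c <- mean_or_na(trials$rt_ms[cong & trials$correct == 1])
  rt_i <- mean_or_na(trials$rt_ms[!cong & trials$correct == 1])
  tibble::tibble(
    flanker_acc = acc_c - acc_i,
    flanker_rt = rt_i - rt_c,
    n_congruent = sum(cong),
    n_incongruent = sum(!cong),
    n_congruent_correct = sum(cong & trials$correct == 1),
    n_incongruent_correct = sum(!cong & trials$correct == 1)
  )
}

#' Congruency-sequence (Gratton) scores
#'
#' Compares incongruent trials preceded (within the same block) by a
#' *correct* incongruent trial (iI) against those preceded by a correct
#' congruent trial (cI). `gratton_acc` is mean accuracy iI minus cI;
#' `gratton_rt` is mean correct RT cI minus iI. Both are oriented so that
#' higher values mean better sustained selective attention. Requiring a
#' correct previous trial keeps the congruency-sequence contrast from
#' absorbing post-error adjustments.
#'
#' @inheritParams score_interference
#' @return A one-row tibble: `gratton_acc`, `gratton_rt`, `n_cI`, `n_iI`,
#'   `n_cI_correct`, `n_iI_correct`.
#' @export
score_gratton <- function(trials) {
  pairs <- sequential_pairs(trials)
  use <- pairs$prev_correct == 1 & pairs$congruency == "i"
  ci <- use & pairs$prev_congruency == "c"
  ii <- use & pairs$prev_congruency == "i"
  tibble::tibble(
    gratton_acc = mean_or_na(pairs$correct[ii]) - mean_or_na(pairs$correct[ci]),
    gratton_rt = mean_or_na(pairs$rt_ms[ci & pairs$correct == 1]) -
      mean_or_na(pairs$rt_ms[ii & pairs$correct == 1]),
    n_cI = sum(ci), n_iI = sum(ii),
    n_cI_correct = sum(ci & pairs$correct == 1),
    n_iI_correct = sum(ii & pairs$correct == 1)
  )
}

#' Post-error adjustment scores
#'
#' Compares trials immediately following an error (within the same block)
#' against trials following a correct response. `pe_rt` is mean correct RT
#' post-error minus post-correct (post-error slowing, the Rabbitt effect);
#' `pe_acc` is mean accuracy post-error minus post-correct (the Laming
#' effect). Higher values mean greater post-error adjustment.
#'
#' @inheritParams score_interference
#' @return A one-row tibble: `pe_acc`, `pe_rt`, `n_post_error`,
#'   `n_post_correct`, `n_post_error_correct`, `n_post_correct_correct`.
#'   With an error-free log the post-error cells are empty and both scores
#'   are `NA`.
#' @export
score_post_error <- function(trials) {
  pairs <- sequential_pairs(trials)
  pe <- pairs$prev_correct == 0
  pc <- pairs$prev_correct == 1
  tibble::tibble(
    pe_acc = mean_or_na(pairs$correct[pe]) - mean_or_na(pairs$correct[pc]),
    pe_rt = mean_or_na(pairs$rt_ms[pe & pairs$correct == 1]) -
      mean_or_na(pairs$rt_ms[pc & pairs$correct == 1]),
    n_post_error = sum(pe), n_post_correct = sum(pc),
    n_post_error_correct = sum(pe & pairs$correct == 1),
    n_post_correct_correct = sum(pc & pairs$correct == 1)
  )
}

# trials that have a predecessor within the same block, annotated with the
# previous trial's congruency and accuracy; the first trial of each block
# contributes only as a predecessor
sequential_pairs <- function(trials) {
  trials |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(prev_congruency = dplyr::lag(.data$congruency),
                  prev_correct = dplyr::lag(.data$correct)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_correct))
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Quality control for Flanker summaries
#'
#' Flags a score family as failed when its minimum contributing cell count
#' falls below `min_cell`; interference additionally fails when overall
#' accuracy is below `min_accuracy` (chance-level responding). Failed
#' scores are set to `NA` for later imputation; QC produces flags, never
#' errors.
#'
#' @param summary A one-row tibble as produced by the scoring functions
#'   combined (see [score_flanker()]).
#' @param min_cell Minimum trials per contributing cell (default 5).
#' @param min_accuracy Minimum overall accuracy for interference scores.
#' @return The summary with `qc_interference`, `qc_gratton`,
#'   `qc_post_error` logical pass flags and failed scores set `NA`.
#' @export
apply_qc <- function(summary, min_cell = 5, min_accuracy = 0.5) {
  s <- summary
  overall_acc <- (s$n_congruent_correct + s$n_incongruent_correct) /
    (s$n_congruent + s$n_incongruent)
  s$qc_interference <- min(s$n_congruent, s$n_incongruent) >= min_cell &
    overall_acc >= min_accuracy
  s$qc_gratton <- min(s$n_cI, s$n_iI) >= min_cell
  s$qc_post_error <- min(s$n_post_error, s$n_post_correct) >= min_cell
  if (!s$qc_interference) s[, c("flanker_acc", "flanker_rt")] <- NA_real_
  if (!s$qc_gratton) s[, c("gratton_acc", "gratton_rt")] <- NA_real_
  if (!s$qc_post_error) s[, c("pe_acc", "pe_rt")] <- NA_real_
  s
}

#' Score a Flanker trial log
#'
#' Computes the six behavioral output variables per participant -
#' interference, congruency-sequence (Gratton) and post-error adjustment
#' effects, each on accuracy and RT - and applies quality control. RT
#' summaries use correct trials only and sequential contrasts never cross
#' block boundaries, so block ordering is irrelevant.
#'
#' @param trials Long trial tibble with columns `participant_id` (optional
#'   for a single participant), `block`, `congruency`, `correct`, `rt_ms`.
#' @inheritParams apply_qc
#' @return A tibble with one row per participant: the six scores, QC flags
#'   and cell counts.
#' @export
score_flanker <- function(trials, min_cell = 5, min_accuracy = 0.5) {
  if (!"participant_id" %in% names(trials)) {
    trials <- dplyr::mutate(trials, participant_id = "P01", .before = 1)
  }
  stopifnot(all(trials$rt_ms > 0), all(trials$congruency %in% c("c", "i")))
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      s <- dplyr::bind_cols(score_interference(df), score_gratton(df),
                            score_post_error(df))
      apply_qc(s, min_cell = min_cell, min_accuracy = min_accuracy)
    }) |>
    dplyr::ungroup()
}
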