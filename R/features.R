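#' Assemble the participant-by-variable feature table
#'
#' Joins the participant table (demographics, group, severity) with the
#' six Flanker scores and the six connectivity edges into the modeling
#' feature table. Accepts either a simulated cohort (whose feature table,
#' with missingness applied, is returned directly) or the three component
#' tibbles.
#'
#' @param x An `mnet_cohort`, or a participant tibble.
#' @param flanker_scores,edges Per-participant tibbles from
#'   [score_flanker()] and [compute_edges()] (ignored for cohorts).
#' @return A tibble, one row per participant.
#' @export
assemble_features <- function(x, flanker_scores = NULL, edges = NULL) {
  if (inherits(x, "mnet_cohort")) return(x$features)
  out <- x
  if (!is.null(flanker_scores)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(flanker_scores, "participant_id",
                    dplyr::any_of(flanker_score_names())),
      by = "participant_id")
  }
  if (!is.null(edges)) {
    out <- dplyr::left_join(out, edges, by = "participant_id")
  }
  out
}
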