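#' Pearson correlation matrix of ROI time courses
#'
#' Columns are mean-centered and correlated with the sample (n-1)
#' denominator; the choice of denominator cancels in r. The result is
#' symmetric with unit diagonal, entries in `[-1, 1]`, and positive
#' semi-definite.
#'
#' @param ts Numeric matrix, timepoints x ROIs (at least 4 rows), or a
#'   tibble of numeric columns.
#' @return The ROI x ROI correlation matrix.
#' @export
pearson_matrix <- function(ts) {
  m <- as.matrix(ts)
  if (nrow(m) < 4) stop("need at least 4 timepoints to correlate ROI series")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant (zero-variance) ROI series: ", paste(bad, collapse = ", "))
  }
  stats::cor(m)
}

#' Fisher z-transform
#'
#' `z = atanh(r) = log((1 + r) / (1 - r)) / 2`, the variance-stabilizing
#' transform applied to connectivity values before analysis. Strictly
#' increasing; `tanh(z)` recovers r.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("Fisher z is undefined for |r| >= 1")
  atanh(r)
}

#' Flatten a 4x4 edge matrix to the six canonical edges
#'
#' Returns the six unordered ROI pairs in the fixed canonical order
#' given by [edge_names()] (dACC-leftAI, dACC-rightAI, dACC-TPJ,
#' rightAI-leftAI, leftAI-TPJ, rightAI-TPJ).
#'
#' @param z_matrix Symmetric 4x4 matrix (Fisher-z or correlation units).
#' @return Named numeric vector of length 6.
#' @export
edge_vector <- function(z_matrix) {
  if (!is.matrix(z_matrix) || any(dim(z_matrix) != c(4, 4))) {
    stop("edge_vector expects a 4x4 matrix")
  }
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(3, 2), c(2, 4), c(3, 4))
  setNames(z_matrix[idx], edge_names())
}

#' Connectivity features from ROI time series
#'
#' Converts per-participant ROI time series into the six pairwise Fisher-z
#' edges: Pearson correlation of the four time courses, Fisher
#' z-transform, canonical flattening.
#'
#' @param timeseries Long tibble with columns `participant_id`, optionally
#'   `timepoint`, and one numeric column per ROI (canonical order); or a
#'   plain matrix/tibble of one participant's series.
#' @return A tibble, one row per participant, with the six edge columns
#'   named as in [edge_names()].
#' @export
compute_edges <- function(timeseries) {
  if (!"participant_id" %in% colnames(timeseries)) {
    return(tibble::as_tibble(as.list(fisher_z(edge_vector(
      pearson_matrix(timeseries))))))
  }
  timeseries |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::select(df, -dplyr::any_of("timepoint"))
      tibble::as_tibble(as.list(fisher_z(edge_vector(pearson_matrix(df)))))
    }) |>
    dplyr::ungroup()
}
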