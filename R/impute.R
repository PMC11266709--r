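#' Iterative random-forest imputation
#'
#' Fills missing entries of a mixed-type feature table by the iterative
#' random-forest scheme: initialize missing cells with the column mean
#' (continuous) or mode (categorical); then, visiting columns in order of
#' ascending missingness, repeatedly fit a random forest for each
#' incomplete column on the other (currently completed) columns using its
#' observed rows and re-predict its missing rows. Iteration stops the
#' first time the change statistic increases - separately normalized sums
#' of squared changes for continuous columns and mismatch proportions for
#' categorical ones - and the previous iteration's matrix is returned, or
#' at `max_iter`. Observed entries are never altered.
#'
#' By default the post-treatment outcome is excluded from the predictor
#' set so imputation of baseline variables cannot leak outcome
#' information; set `exclude = character()` to use every column.
#'
#' @param features Tibble whose numeric columns are treated as continuous
#'   and factor/character columns as categorical. Identifier columns given
#'   in `ignore` are carried through untouched.
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum number of update iterations (default 10).
#' @param seed Optional seed for the forest fits; with a fixed seed the
#'   result is reproducible.
#' @param exclude Columns kept out of the predictor set (default the
#'   outcome, `post_phq`); they are still returned.
#' @param ignore Identifier columns excluded from the model entirely.
#' @return An object of class `mnet_imputation`: the completed tibble in
#'   `$data` plus `$iterations_run`, per-iteration `$delta` and
#'   `$converged_by` (`"difference-increase"` or `"max-iterations"`;
#'   `"complete-data"` when nothing was missing).
#' @export
impute_features <- function(features, n_trees = 100, max_iter = 10,
                            seed = NULL, exclude = "post_phq",
                            ignore = "participant_id") {
  runner <- function() forest_impute_impl(features, n_trees, max_iter,
                                          exclude, ignore)
  res <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  structure(res, class = "mnet_imputation")
}

forest_impute_impl <- function(features, n_trees, max_iter, exclude, ignore) {
  ignore <- intersect(ignore, names(features))
  work_cols <- setdiff(names(features), ignore)
  df <- as.data.frame(features[, work_cols], stringsAsFactors = FALSE)
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  finite_ok <- vapply(df, function(x) {
    !is.numeric(x) || all(is.finite(x[!is.na(x)]))
  }, logical(1))
  if (!all(finite_ok)) {
    stop("non-finite observed values in: ",
         paste(names(df)[!finite_ok], collapse = ", "))
  }
  na_mask <- is.na(df)
  n_miss <- colSums(na_mask)
  if (any(n_miss == nrow(df))) {
    stop("all-missing column: ", paste(names(df)[n_miss == nrow(df)],
                                       collapse = ", "))
  }
  if (all(n_miss == 0)) {
    out <- features
    return(list(data = out, iterations_run = 0L,
                delta = tibble::tibble(iteration = integer(),
                                       delta_continuous = numeric(),
                                       delta_categorical = numeric()),
                converged_by = "complete-data", n_imputed = 0L))
  }

  is_cont <- vapply(df, is.numeric, logical(1))
  # initialize: mean / mode
  for (j in names(df)) {
    idx <- na_mask[, j]
    if (!any(idx)) next
    obs <- df[[j]][!idx]
    df[[j]][idx] <- if (is_cont[[j]]) {
      mean(obs)
    } else {
      names(sort(table(obs), decreasing = TRUE))[1]
    }
  }

  update_order <- names(sort(n_miss[n_miss > 0]))  # ascending missingness
  predictors_of <- function(col) setdiff(names(df), c(col, exclude))

  delta_log <- list()
  prev <- df
  best <- df
  best_iter <- 0L
  prev_dc <- Inf
  prev_dk <- Inf
  converged_by <- "max-iterations"
  iterations_run <- 0L

  for (it in seq_len(max_iter)) {
    for (col in update_order) {
      idx <- na_mask[, col]
      preds <- predictors_of(col)
      x_obs <- df[!idx, preds, drop = FALSE]
      y_obs <- df[[col]][!idx]
      x_mis <- df[idx, preds, drop = FALSE]
      fit <- randomForest::randomForest(x = x_obs, y = y_obs, ntree = n_trees)
      df[[col]][idx] <- predict(fit, x_mis)
    }
    iterations_run <- it
    # change statistic relative to the previous iteration's imputations
    cont_cols <- update_order[is_cont[update_order]]
    cat_cols <- update_order[!is_cont[update_order]]
    dc <- 0
    if (length(cont_cols) > 0) {
      num <- 0; den <- 0
      for (col in cont_cols) {
        idx <- na_mask[, col]
        num <- num + sum((df[[col]][idx] - prev[[col]][idx])^2)
        den <- den + sum(df[[col]][idx]^2)
      }
      dc <- if (den > 0) num / den else 0
    }
    dk <- 0
    if (length(cat_cols) > 0) {
      mism <- 0; tot <- 0
      for (col in cat_cols) {
        idx <- na_mask[, col]
        mism <- mism + sum(df[[col]][idx] != prev[[col]][idx])
        tot <- tot + sum(idx)
      }
      dk <- if (tot > 0) mism / tot else 0
    }
    delta_log[[it]] <- tibble::tibble(iteration = it, delta_continuous = dc,
                                      delta_categorical = dk)
    increased <- (length(cont_cols) == 0 || dc >= prev_dc) &&
      (length(cat_cols) == 0 || dk >= prev_dk) && it > 1
    if (increased) {
      converged_by <- "difference-increase"
      break
    }
    best <- df
    best_iter <- it
    prev <- df
    prev_dc <- dc
    prev_dk <- dk
  }

  completed <- features
  for (col in names(best)) {
    vals <- best[[col]]
    if (is.factor(features[[col]])) {
      completed[[col]] <- factor(as.character(vals),
                                 levels = levels(features[[col]]))
    } else if (is.character(features[[col]])) {
      completed[[col]] <- as.character(vals)
    } else {
      completed[[col]] <- as.numeric(vals)
    }
  }
  # observed entries are preserved exactly
  for (col in colnames(na_mask)) {
    completed[[col]][!na_mask[, col]] <- features[[col]][!na_mask[, col]]
  }
  list(data = completed, iterations_run = iterations_run,
       delta = dplyr::bind_rows(delta_log), converged_by = converged_by,
       used_iteration = best_iter, n_imputed = sum(na_mask))
}

#' @export
print.mnet_imputation <- function(x, ...) {
  cat(sprintf("<mnet_imputation> %d iterations, stopped by %s\n",
              x$iterations_run, x$converged_by))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mnet_imputation <- function(x, ...) {
  tibble::tibble(iterations_run = x$iterations_run,
                 converged_by = x$converged_by,
                 n_imputed = x$n_imputed)
}

#' @exportS3Method generics::tidy
tidy.mnet_imputation <- function(x, ...) x$delta

#' Normalized root-mean-square imputation error
#'
#' `sqrt(mean((imputed - truth)^2 over masked cells) / var(truth over
#' masked cells))`; 0 for perfect imputation, 1 (by construction) when
#' every masked cell is imputed with the masked truth's mean. Used to
#' evaluate imputation on simulated data where the truth is known.
#'
#' @param imputed,truth Numeric vectors or matrices of equal shape.
#' @param mask Logical of the same shape; `TRUE` marks cells that were
#'   missing.
#' @return A non-negative scalar.
#' @export
nrmse <- function(imputed, truth, mask) {
  im <- as.numeric(as.matrix(imputed))[as.logical(mask)]
  tr <- as.numeric(as.matrix(truth))[as.logical(mask)]
  if (length(tr) == 0) stop("mask selects no cells")
  v <- mean((tr - mean(tr))^2)
  if (v == 0) stop("truth variance over the mask is zero")
  sqrt(mean((im - tr)^2) / v)
}
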