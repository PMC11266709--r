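#' Nested cross-validated prediction error for staged models
#'
#' Each run draws an independent outer k-fold partition; on every outer
#' training set each stage model is re-tuned by inner k-fold
#' cross-validation and refit, then scored on the held-out fold. The null
#' model predicts each held-out observation by the outer-training-set mean
#' of the outcome. A run's MSE for a model is the mean of its fold MSEs.
#' Run seeds are pre-assigned from the master seed. Outer folds are drawn
#' independently of (and within each outer fold, after) the inner tuning
#' folds, so tuning never sees held-out data.
#'
#' @param features Complete (imputed) feature tibble.
#' @param stage_variables Named list of candidate-covariate vectors, one
#'   per model to evaluate (e.g. `list(stage1 = ..., stage2 = ...,
#'   stage3 = ...)`).
#' @param n_runs Number of repeated outer cross-validation runs.
#' @param k_outer,k_inner Outer / inner fold counts (default 10).
#' @param seed Master seed.
#' @inheritParams tune_penalties
#' @inheritParams build_design
#' @return An object of class `cv_evaluation`: `runs` (long tibble with
#'   `run`, `model`, `mse`), fold-scheme constants `n_train`, `n_test`,
#'   and settings.
#' @export
evaluate_models <- function(features, stage_variables, n_runs = 200,
                            k_outer = 10, k_inner = 10, seed = NULL,
                            alpha_grid = seq(0, 1, by = 0.1), nlambda = 100,
                            lambda_min_ratio = 1e-3, outcome = "post_phq") {
  stopifnot(is.list(stage_variables), length(stage_variables) >= 1)
  if (is.null(names(stage_variables))) {
    names(stage_variables) <- paste0("model", seq_along(stage_variables))
  }
  designs <- lapply(stage_variables, build_design, features = features,
                    outcome = outcome)
  y <- designs[[1]]$y
  n <- length(y)
  if (n < 2 * k_outer) stop("need n >= 2 * k_outer observations")
  run_seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, n_runs)
    else withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_runs))

  one_run <- function(run_seed) {
    withr::with_seed(run_seed, {
      foldid <- sample(rep(seq_len(k_outer), length.out = n))
      fold_mse <- matrix(0, k_outer, length(designs) + 1,
                         dimnames = list(NULL, c(names(designs), "null")))
      for (f in seq_len(k_outer)) {
        te <- foldid == f
        if (sum(te) < 2) stop("outer fold smaller than 2 observations")
        ytr <- y[!te]
        fold_mse[f, "null"] <- mean((y[te] - mean(ytr))^2)
        for (m in names(designs)) {
          xm <- designs[[m]]$x
          tun <- tune_penalties(xm[!te, , drop = FALSE], ytr,
                                alpha_grid = alpha_grid, nlambda = nlambda,
                                lambda_min_ratio = lambda_min_ratio,
                                k = k_inner)
          fit <- fit_enet(xm[!te, , drop = FALSE], ytr,
                          alpha = tun$alpha, lambda = tun$lambda)
          pred <- predict(fit, xm[te, , drop = FALSE])
          fold_mse[f, m] <- mean((y[te] - pred)^2)
        }
      }
      colMeans(fold_mse)
    })
  }
  per_run <- t(vapply(run_seeds, one_run,
                      numeric(length(designs) + 1)))
  runs <- tibble::as_tibble(as.data.frame(per_run)) |>
    dplyr::mutate(run = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"run", names_to = "model", values_to = "mse")
  structure(list(runs = runs, n_runs = n_runs, k_outer = k_outer,
                 n_train = n - floor(n / k_outer), n_test = floor(n / k_outer),
                 models = c(names(designs), "null")),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  m <- x$runs |> dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_mse = mean(.data$mse))
  cat(sprintf("<cv_evaluation> %d runs, %d-fold outer CV\n", x$n_runs,
              x$k_outer))
  print(m)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_evaluation <- function(x, ...) x$runs

#' Variance-corrected t-test for repeated cross-validation differences
#'
#' Paired t-test on per-run error differences with the variance inflated by
#' the train/test overlap ratio: `t = m / sqrt((1/J + n_test/n_train) *
#' s^2)` on `J - 1` degrees of freedom, where `m` and `s` are the mean and
#' SD of the `J` per-run differences. Repeated cross-validation runs share
#' most of their training data, so the naive paired t-test is
#' anti-conservative; the correction restores approximate calibration.
#' With `n_test = 0` (ratio zero) the statistic reduces exactly to the
#' classic paired t.
#'
#' @param diffs Per-run differences (model A error minus model B error).
#' @param n_train,n_test Training and test-set sizes of the fold scheme
#'   (10-fold gives a ratio of 1/9).
#' @return A list of class `corrected_t`: `estimate` (mean difference),
#'   `sd_diff`, `ratio`, `statistic`, `df`, `p.value`.
#' @export
corrected_t_test <- function(diffs, n_train, n_test) {
  j <- length(diffs)
  if (j < 2) stop("need at least two per-run differences")
  s <- sd(diffs)
  if (s == 0) stop("zero variance of differences; t-test degenerate")
  ratio <- n_test / n_train
  m <- mean(diffs)
  stat <- m / sqrt((1 / j + ratio) * s^2)
  structure(list(estimate = m, sd_diff = s, ratio = ratio, statistic = stat,
                 df = j - 1, p.value = 2 * pt(-abs(stat), j - 1)),
            class = "corrected_t")
}

#' @export
print.corrected_t <- function(x, ...) {
  cat(sprintf(
    "corrected t: M_diff=%.4g SD_diff=%.4g t(%d)=%.3f p=%.3g (ratio %.3g)\n",
    x$estimate, x$sd_diff, x$df, x$statistic, x$p.value, x$ratio))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.corrected_t <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, sd_diff = x$sd_diff,
                 statistic = x$statistic, df = x$df, p.value = x$p.value,
                 ratio = x$ratio)
}

#' Pairwise model comparisons from a cross-validated evaluation
#'
#' Computes the standard comparisons - each stage against the null model
#' and the final stage against the earlier stages - using the
#' variance-corrected t-test (or the classic paired t when
#' `correction = "none"`).
#'
#' @param evaluation A `cv_evaluation`.
#' @param comparisons Two-column character matrix / list of pairs; by
#'   default every model vs null plus the last model vs the earlier ones.
#' @param correction `"nadeau-bengio"` (default) or `"none"`.
#' @return A tibble with one row per comparison: mean MSEs, mean and SD of
#'   the per-run differences, t, df, p.
#' @export
compare_models <- function(evaluation,
                           comparisons = NULL,
                           correction = c("nadeau-bengio", "none")) {
  correction <- match.arg(correction)
  wide <- tidyr::pivot_wider(evaluation$runs, names_from = "model",
                             values_from = "mse")
  models <- setdiff(evaluation$models, "null")
  if (is.null(comparisons)) {
    last <- models[length(models)]
    comparisons <- c(lapply(models, function(m) c(m, "null")),
                     lapply(setdiff(models, last), function(m) c(last, m)))
  }
  ratio_ntest <- if (correction == "nadeau-bengio") evaluation$n_test else 0
  purrr::map_dfr(comparisons, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    ct <- corrected_t_test(d, evaluation$n_train, ratio_ntest)
    tibble::tibble(model_a = pr[1], model_b = pr[2],
                   mse_a = mean(wide[[pr[1]]]), mse_b = mean(wide[[pr[2]]]),
                   m_diff = ct$estimate, sd_diff = ct$sd_diff,
                   statistic = ct$statistic, df = ct$df, p.value = ct$p.value)
  })
}
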