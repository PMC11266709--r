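#' Candidate variables for each selection stage
#'
#' Stage 1 pairs the demographic/clinical covariates (age, gender,
#' baseline severity) with the six Flanker scores; Stage 2 swaps the
#' Flanker scores for the six connectivity edges; Stage 3 enters baseline
#' severity plus every covariate whose main effect *or* group interaction
#' was retained at Stage 1 or 2. The treatment-group indicator and all
#' group interactions are always part of the design and are not listed
#' here.
#'
#' @param stage 1, 2 or 3.
#' @param retained_terms For stage 3, the union of retained term names
#'   from Stages 1 and 2.
#' @return Character vector of covariate names.
#' @export
stage_candidates <- function(stage, retained_terms = NULL) {
  base <- c("age", "gender", "baseline_phq")
  switch(as.character(stage),
    "1" = c(base, flanker_score_names()),
    "2" = c(base, edge_names()),
    "3" = {
      carried <- term_to_variable(retained_terms)
      union("baseline_phq", setdiff(carried, "group"))
    },
    stop("stage must be 1, 2 or 3"))
}

term_to_variable <- function(terms) {
  unique(sub("^group:", "", terms))
}

#' Repeat tuned elastic-net fits and summarize coefficient stability
#'
#' Each replicate draws a fresh random k-fold partition, tunes
#' `(alpha, lambda)` by cross-validation on the full sample, and refits at
#' the tuned pair; the data themselves are never resampled, so replicate
#' variability comes only from the fold randomization entering penalty
#' selection. Per column the nonzero proportion and the mean coefficient
#' across replicates (zeros included) are accumulated. Replicate seeds are
#' pre-assigned from the master seed, making the summary deterministic
#' regardless of execution order.
#'
#' @param design An `mnet_design` (or a list with `x`, `y`).
#' @param n_replicates Number of replicates.
#' @param seed Master seed.
#' @param coef_summary `"mean"` (default) or `"median"` aggregation of the
#'   per-replicate coefficients.
#' @inheritParams tune_penalties
#' @return A list of class `replicate_summary`: `summary` tibble (`term`,
#'   `prop_nonzero`, `mean_coef`), `replicates` tibble of per-replicate
#'   `(alpha, lambda)`, and `n_replicates`.
#' @export
run_replicates <- function(design, n_replicates = 500, seed = NULL,
                           alpha_grid = seq(0, 1, by = 0.1), nlambda = 100,
                           lambda_min_ratio = 1e-3, k = 10,
                           coef_summary = c("mean", "median")) {
  coef_summary <- match.arg(coef_summary)
  stopifnot(n_replicates >= 1)
  x <- design$x
  y <- design$y
  n <- nrow(x)
  p <- ncol(x)
  rep_seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max - 1L, n_replicates)
  } else {
    withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_replicates))
  }
  coefs <- matrix(NA_real_, n_replicates, p, dimnames = list(NULL, colnames(x)))
  alphas <- lambdas <- rep(NA_real_, n_replicates)
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    res <- try(withr::with_seed(rep_seeds[r], {
      tun <- tune_penalties(x, y, alpha_grid = alpha_grid, nlambda = nlambda,
                            lambda_min_ratio = lambda_min_ratio, k = k)
      fit <- fit_enet(x, y, alpha = tun$alpha, lambda = tun$lambda)
      list(tun = tun, fit = fit)
    }), silent = TRUE)
    if (inherits(res, "try-error")) { failures <- failures + 1L; next }
    coefs[r, ] <- res$fit$beta
    alphas[r] <- res$tun$alpha
    lambdas[r] <- res$tun$lambda
  }
  if (failures > 0.01 * n_replicates) {
    stop(sprintf("%d of %d replicates failed", failures, n_replicates))
  }
  ok <- !is.na(alphas)
  agg <- if (coef_summary == "mean") colMeans else
    function(m) apply(m, 2, stats::median)
  structure(list(
    summary = tibble::tibble(
      term = colnames(x),
      prop_nonzero = unname(colMeans(coefs[ok, , drop = FALSE] != 0)),
      mean_coef = unname(agg(coefs[ok, , drop = FALSE]))),
    replicates = tibble::tibble(replicate = which(ok), alpha = alphas[ok],
                                lambda = lambdas[ok]),
    n_replicates = sum(ok), failures = failures),
    class = "replicate_summary")
}

#' Retained variables at a nonzero-proportion threshold
#'
#' A term is retained when its nonzero-coefficient proportion across
#' replicates is greater than *or equal to* the threshold (default 0.75,
#' i.e. a nonzero coefficient in at least three quarters of replicates).
#'
#' @param summary A `replicate_summary` (or its `summary` tibble).
#' @param threshold Retention threshold in `(0, 1]`.
#' @return Character vector of retained term names.
#' @export
retain <- function(summary, threshold = 0.75) {
  s <- if (inherits(summary, "replicate_summary")) summary$summary else summary
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  s$term[s$prop_nonzero >= threshold]
}

#' Essential predictors among the retained set
#'
#' The essential set holds retained terms whose absolute (replicate-mean)
#' coefficient strictly exceeds the average absolute coefficient of all
#' retained terms; the remainder are non-essential. With a single retained
#' term, or all retained coefficients equal in magnitude, nothing exceeds
#' the average and the essential set is empty (a warning notes the
#' single-term case).
#'
#' @inheritParams retain
#' @param retained Character vector from [retain()].
#' @return Character vector of essential term names.
#' @export
essentials <- function(summary, retained) {
  s <- if (inherits(summary, "replicate_summary")) summary$summary else summary
  if (length(retained) == 0) return(character(0))
  sub <- s[s$term %in% retained, ]
  tau <- mean(abs(sub$mean_coef))
  out <- sub$term[abs(sub$mean_coef) > tau]
  if (length(retained) == 1 && length(out) == 0) {
    warning("single retained term cannot exceed the average of itself; ",
            "essential set is empty")
  }
  out
}

#' Stability selection for one stage
#'
#' Builds the stage design (standardized mains, group indicator, group
#' interactions), runs [run_replicates()], and applies the retention and
#' essential rules.
#'
#' @param features Complete (imputed) feature tibble.
#' @param stage_variables Candidate covariates (see [stage_candidates()]).
#' @param threshold Retention threshold on the nonzero proportion.
#' @inheritParams run_replicates
#' @inheritParams build_design
#' @return An object of class `enet_selection`: the per-term `summary`
#'   tibble with `retained` and `essential` flags, the retained/essential
#'   term vectors, replicate records and settings.
#' @export
stability_selection <- function(features, stage_variables,
                                n_replicates = 500, threshold = 0.75,
                                seed = NULL, outcome = "post_phq", ...) {
  design <- build_design(features, stage_variables, outcome = outcome)
  reps <- run_replicates(design, n_replicates = n_replicates, seed = seed, ...)
  retained <- retain(reps, threshold)
  essential <- essentials(reps, retained)
  summary <- dplyr::mutate(
    reps$summary,
    retained = .data$term %in% retained,
    essential = .data$term %in% essential)
  structure(list(summary = summary, retained = retained,
                 essential = essential, replicates = reps$replicates,
                 n_replicates = reps$n_replicates, threshold = threshold,
                 stage_variables = stage_variables, terms = design$terms),
            class = "enet_selection")
}

#' @export
print.enet_selection <- function(x, ...) {
  cat(sprintf("<enet_selection> %d replicates, threshold %.2f\n",
              x$n_replicates, x$threshold))
  cat("retained: ", paste(x$retained, collapse = ", "), "\n")
  cat("essential:", paste(x$essential, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enet_selection <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.enet_selection <- function(x, ...) {
  tibble::tibble(n_replicates = x$n_replicates, threshold = x$threshold,
                 n_terms = nrow(x$summary), n_retained = length(x$retained),
                 n_essential = length(x$essential))
}

#' Staged selection across behavior, connectivity and their union
#'
#' Runs the three-stage variable selection: Stage 1 screens the Flanker
#' scores (with demographics and baseline severity), Stage 2 the
#' connectivity edges, and Stage 3 re-screens baseline severity together
#' with every covariate carried forward from Stages 1-2 (a covariate
#' qualifies when its main effect or its group interaction met the
#' retention threshold). If nothing carries forward, Stage 3 falls back to
#' baseline severity alone, with a warning. Stage seeds derive from the
#' master seed.
#'
#' @inheritParams stability_selection
#' @return An object of class `stagewise_selection`: `stage1`, `stage2`,
#'   `stage3` (`enet_selection` objects) and the Stage 3 candidate list.
#' @export
select_stagewise <- function(features, n_replicates = 500, threshold = 0.75,
                             seed = NULL, ...) {
  stage_seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, 3) else
    withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 3))
  s1 <- stability_selection(features, stage_candidates(1),
                            n_replicates = n_replicates, threshold = threshold,
                            seed = stage_seeds[1], ...)
  s2 <- stability_selection(features, stage_candidates(2),
                            n_replicates = n_replicates, threshold = threshold,
                            seed = stage_seeds[2], ...)
  carried <- union(s1$retained, s2$retained)
  cand3 <- stage_candidates(3, carried)
  if (length(setdiff(cand3, "baseline_phq")) == 0) {
    warning("no variables carried forward from Stages 1-2; ",
            "Stage 3 falls back to group and baseline severity")
  }
  s3 <- stability_selection(features, cand3, n_replicates = n_replicates,
                            threshold = threshold, seed = stage_seeds[3], ...)
  structure(list(stage1 = s1, stage2 = s2, stage3 = s3,
                 stage3_candidates = cand3),
            class = "stagewise_selection")
}

#' @export
print.stagewise_selection <- function(x, ...) {
  for (s in 1:3) {
    cat(sprintf("Stage %d essential: %s\n", s,
                paste(x[[paste0("stage", s)]]$essential, collapse = ", ")))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stagewise_selection <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$stage1$summary, stage = 1L, .before = 1),
    dplyr::mutate(x$stage2$summary, stage = 2L, .before = 1),
    dplyr::mutate(x$stage3$summary, stage = 3L, .before = 1))
}
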