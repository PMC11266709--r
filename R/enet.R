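#' Standardize a numeric vector
#'
#' `z = (x - mean(x)) / sd(x)` with the sample (n-1 denominator) SD, the
#' same convention as `scale()`. Zero-variance input is an error.
#'
#' @param x Numeric vector.
#' @return The standardized vector, with `center` and `scale` attributes.
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop("standardize expects a numeric vector")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance column")
  m <- mean(x)
  structure((x - m) / s, center = m, scale = s)
}

#' Build a stage design matrix with treatment interactions
#'
#' Constructs the penalized-regression design for one selection stage:
#' standardized main-effect columns for the stage variables, the 0/1
#' treatment-group indicator, and one `group:variable` product column per
#' stage variable, in that order, with deterministic column names. Numeric
#' covariates are standardized (sample SD); two-level factors such as
#' gender become 0/1 indicators and are not rescaled. Interaction columns
#' are exact products of the group indicator and the (standardized)
#' covariate and are not re-standardized, preserving their
#' "effect within the treated arm" reading. The outcome is standardized
#' too, so a null model has mean squared error near 1.
#'
#' @param features Feature tibble containing `group`, the outcome and the
#'   stage variables, with no missing values.
#' @param stage_variables Character vector of candidate covariate names.
#' @param outcome Name of the outcome column (default `post_phq`).
#' @return A list of class `mnet_design`: matrix `x` (n x p), vector `y`,
#'   `terms` (column names), and the standardization parameters.
#' @export
build_design <- function(features, stage_variables, outcome = "post_phq") {
  unknown <- setdiff(c(stage_variables, outcome), names(features))
  if (length(unknown) > 0) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  used <- features[, c(stage_variables, outcome, "group")]
  if (anyNA(used)) stop("design variables contain missing values; impute first")

  g <- group_indicator(features$group)
  centers <- scales <- setNames(numeric(0), character(0))
  main_col <- function(v) {
    x <- features[[v]]
    if (is.numeric(x)) {
      z <- standardize(x)
      centers[[v]] <<- attr(z, "center")
      scales[[v]] <<- attr(z, "scale")
      as.numeric(z)
    } else {
      f <- as.factor(x)
      if (nlevels(f) != 2) stop("only two-level factors supported: ", v)
      as.numeric(f) - 1
    }
  }
  mains <- if (length(stage_variables) == 0) {
    matrix(numeric(0), nrow = nrow(features), ncol = 0)
  } else {
    vapply(stage_variables, main_col, numeric(nrow(features)))
  }
  x <- cbind(mains, group = g, g * mains)
  inter_names <- if (length(stage_variables) > 0) {
    paste0("group:", stage_variables)
  } else {
    character(0)
  }
  colnames(x) <- c(stage_variables, "group", inter_names)
  y <- as.numeric(standardize(features[[outcome]]))
  structure(list(x = x, y = y, terms = colnames(x),
                 stage_variables = stage_variables,
                 centers = centers, scales = scales, outcome = outcome),
            class = "mnet_design")
}

#' Fit an elastic net at fixed penalties
#'
#' Minimizes `(1/(2n)) ||y - b0 - X b||^2 + lambda * (alpha ||b||_1 +
#' (1 - alpha)/2 ||b||^2)` by cyclic coordinate descent with
#' soft-thresholding, warm-started down a short geometric path. The
#' intercept is unpenalized. Convergence requires the largest coefficient
#' change in a sweep to fall below `tol`; at `lambda = 0` on a full-rank
#' design the solution matches ordinary least squares.
#'
#' @param x Numeric design matrix (n x p) or an `mnet_design`.
#' @param y Outcome vector (ignored when `x` is a design).
#' @param alpha L1/L2 mixing weight in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Penalty strength, non-negative.
#' @param tol Convergence tolerance on coefficient changes.
#' @param max_sweeps Sweep budget; exceeding it is an error.
#' @return An object of class `enet_fit`: named `beta`, `intercept`,
#'   `alpha`, `lambda`, `objective` (per-sweep trace of the penalized
#'   objective), `sweeps`, `lambda_max`.
#' @export
fit_enet <- function(x, y = NULL, alpha, lambda, tol = 1e-7,
                     max_sweeps = 100000) {
  if (inherits(x, "mnet_design")) { y <- x$y; x <- x$x }
  x <- as.matrix(x)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("design must be finite")
  res <- .enet_fit_cpp(x, y, alpha, lambda, 30L, tol, as.integer(max_sweeps))
  if (!res$converged) {
    stop(sprintf(
      "coordinate descent did not converge in %d sweeps (alpha=%.2f, lambda=%.4g)",
      max_sweeps, alpha, lambda))
  }
  structure(list(
    beta = setNames(as.numeric(res$beta), colnames(x)),
    intercept = res$intercept, alpha = alpha, lambda = lambda,
    objective = as.numeric(res$objective_trace), sweeps = res$sweeps,
    lambda_max = res$lambda_max), class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<enet_fit> alpha=%.2f lambda=%.4g, %d/%d nonzero\n",
              x$alpha, x$lambda, nz, length(x$beta)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enet_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$beta)),
                 estimate = c(x$intercept, unname(x$beta)))
}

#' @export
predict.enet_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$beta) + object$intercept
}

#' Tune elastic-net penalties by k-fold cross-validation
#'
#' Random k-fold partition (the source of replicate-to-replicate
#' variability in the selection pipeline), then mean held-out squared error
#' for every pair on the alpha grid crossed with a per-alpha geometric
#' lambda path running from the smallest all-zero penalty `lambda_max` down
#' to `lambda_min_ratio * lambda_max`. Returns the minimizing pair; exact
#' ties - routine at the all-zero end of the path - resolve to the larger
#' lambda, then the larger alpha (the sparser, then more ridge-like model).
#'
#' @inheritParams fit_enet
#' @param alpha_grid Mixing weights to search (default 0, 0.1, ..., 1).
#' @param nlambda Points on each lambda path (default 100).
#' @param lambda_min_ratio Path depth (default 1e-3).
#' @param k Folds (default 10); requires `n >= 2k`.
#' @param foldid Optional integer fold assignment in `1..k`; drawn from the
#'   ambient RNG when omitted.
#' @return A list of class `enet_tuning`: `alpha`, `lambda`, `cv_mse`, and
#'   `surface` (tibble of alpha, lambda, mean CV MSE).
#' @export
tune_penalties <- function(x, y = NULL, alpha_grid = seq(0, 1, by = 0.1),
                           nlambda = 100, lambda_min_ratio = 1e-3,
                           k = 10, foldid = NULL, tol = 1e-7,
                           max_sweeps = 100000) {
  if (inherits(x, "mnet_design")) { y <- x$y; x <- x$x }
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(foldid)) {
    if (n < 2 * k) stop("need n >= 2k observations for k-fold tuning")
    foldid <- sample(rep(seq_len(k), length.out = n))
  }
  res <- .cv_tune_cpp(x, y, as.integer(foldid), as.numeric(alpha_grid),
                      as.integer(nlambda), lambda_min_ratio, tol,
                      as.integer(max_sweeps))
  surface <- tibble::tibble(
    alpha = rep(as.numeric(alpha_grid), times = nlambda),
    lambda = as.numeric(res$lambda_grid),
    mse = as.numeric(res$mse))
  structure(list(alpha = res$alpha, lambda = res$lambda,
                 cv_mse = res$cv_mse, surface = surface,
                 converged = res$converged, foldid = foldid),
            class = "enet_tuning")
}

#' @export
print.enet_tuning <- function(x, ...) {
  cat(sprintf("<enet_tuning> alpha*=%.2f lambda*=%.4g (cv mse %.4f)\n",
              x$alpha, x$lambda, x$cv_mse))
  invisible(x)
}
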