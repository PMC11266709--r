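#' Ordinary least squares on the essential Stage 3 predictors
#'
#' Fits the unpenalized interpretive model on the selected design columns
#' (standardized mains, 0/1 group indicator, group-interaction products),
#' giving coefficient estimates, standard errors, R-squared and the overall
#' F-test that the penalized fits cannot provide.
#'
#' @param features Complete (imputed) feature tibble.
#' @param terms Design-column names to enter (e.g. an `enet_selection`'s
#'   retained or essential set); `"group:var"` names denote interaction
#'   columns.
#' @inheritParams build_design
#' @return An object of class `final_model` wrapping the `lm` fit, with
#'   the design kept for adjusted-effect curves.
#' @export
fit_final_ols <- function(features, terms, outcome = "post_phq") {
  vars <- setdiff(term_to_variable(terms), "group")
  design <- build_design(features, vars, outcome = outcome)
  missing_terms <- setdiff(terms, design$terms)
  if (length(missing_terms) > 0) {
    stop("unknown terms: ", paste(missing_terms, collapse = ", "))
  }
  x <- design$x[, terms, drop = FALSE]
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    drop_idx <- qrx$pivot[seq(qrx$rank + 1, ncol(x) + 1)] - 1
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(x)[drop_idx], collapse = ", "))
  }
  d <- as.data.frame(x, check.names = FALSE)
  safe <- gsub(":", "_x_", colnames(x))
  names(d) <- safe
  d$.outcome <- design$y
  fit <- lm(.outcome ~ ., data = d)
  names(fit$coefficients) <- c("(Intercept)", colnames(x))
  structure(list(fit = fit, terms = colnames(x), design = design,
                 x = x, y = design$y, safe_names = setNames(safe, colnames(x))),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  cat(sprintf("<final_model> R^2 = %.3f, F(%d, %d) = %.2f\n",
              s$r.squared, f[2], f[3], f[1]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.final_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @exportS3Method generics::glance
glance.final_model <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 statistic = unname(f[1]), df = unname(f[2]),
                 df.residual = unname(f[3]),
                 p.value = unname(pf_upper(f[1], f[2], f[3])),
                 nobs = length(x$y))
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' @export
predict.final_model <- function(object, newdata, se.fit = FALSE, ...) {
  nd <- as.data.frame(newdata, check.names = FALSE)
  names(nd) <- object$safe_names[names(nd)]
  predict(object$fit, newdata = nd, se.fit = se.fit, ...)
}

#' Adjusted-effect (partial regression) curve for one predictor
#'
#' Predicted outcome over a grid of the focal variable with every other
#' covariate held at its sample mean. When the model contains a group
#' interaction (or `stratify = TRUE`), separate curves are produced per
#' treatment arm, with the group indicator fixed at 0/1 and each
#' interaction column set to the indicator times the corresponding
#' covariate value. The band is the pointwise standard error of the fit
#' (fit plus/minus one SE), derived from the coefficient covariance.
#'
#' @param model A `final_model`.
#' @param focal Name of a main-effect column of the model.
#' @param grid Evaluation points on the model's (standardized) scale;
#'   default an even grid over the observed range. Points outside the
#'   observed range trigger a warning.
#' @param n_grid Grid size when `grid` is `NULL`.
#' @param stratify Produce per-arm curves even without an interaction.
#' @return A tibble of class `adjusted_effect`: `focal`, focal value `x`,
#'   `group`, `fit`, `se`, `lower`, `upper`.
#' @export
adjusted_effect <- function(model, focal, grid = NULL, n_grid = 50,
                            stratify = TRUE) {
  if (!focal %in% model$terms) stop("focal variable not in the model: ", focal)
  xs <- model$x[, focal]
  if (is.null(grid)) {
    grid <- seq(min(xs), max(xs), length.out = n_grid)
  } else if (any(grid < min(xs) | grid > max(xs))) {
    warning("grid extends outside the observed range of ", focal)
  }
  has_group <- "group" %in% model$terms
  interaction_name <- paste0("group:", focal)
  strata <- if (stratify || interaction_name %in% model$terms) c(0, 1) else NA
  col_means <- colMeans(model$x)
  # covariate means for interactions whose main effect is not in the model
  design_means <- colMeans(model$design$x)
  purrr::map_dfr(strata, function(g) {
    nd <- matrix(rep(col_means, each = length(grid)), nrow = length(grid),
                 dimnames = list(NULL, model$terms))
    nd[, focal] <- grid
    if (!is.na(g)) {
      if (has_group) nd[, "group"] <- g
      for (tm in model$terms[startsWith(model$terms, "group:")]) {
        v <- sub("^group:", "", tm)
        base <- if (v == focal) grid else design_means[[v]]
        nd[, tm] <- g * base
      }
    }
    pr <- predict(model, nd, se.fit = TRUE)
    tibble::tibble(focal = focal, x = grid,
                   group = if (is.na(g)) NA_character_ else
                     c("control", "treated")[g + 1],
                   fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
                   lower = .data$fit - .data$se, upper = .data$fit + .data$se)
  }) |> structure(class = c("adjusted_effect", "tbl_df", "tbl", "data.frame"))
}

#' Group-wise descriptive statistics with between-group tests
#'
#' Per-arm mean, SD, adjusted Fisher-Pearson skewness, adjusted excess
#' kurtosis and standard error of the mean for each numeric variable, with
#' a pooled-variance two-sample t-test (`df = n1 + n2 - 2`); two-level
#' factor variables (e.g. gender) get counts and a chi-squared test on 1
#' degree of freedom (no continuity correction by default).
#'
#' @param features Feature tibble with a two-level `group` column.
#' @param variables Columns to describe; default every numeric and
#'   two-level factor column except identifiers.
#' @param yates Apply the continuity correction to the chi-squared test.
#' @return A tibble, one row per variable: per-group summaries, test type,
#'   statistic, df, p.
#' @export
cohort_descriptives <- function(features, variables = NULL, yates = FALSE) {
  g <- as.factor(features$group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if (any(table(g) < 2)) stop("each group needs at least 2 participants")
  lv <- levels(g)
  if (is.null(variables)) {
    variables <- setdiff(names(features),
                         c("participant_id", "group"))
  }
  purrr::map_dfr(variables, function(v) {
    x <- features[[v]]
    if (is.numeric(x)) {
      per <- lapply(lv, function(l) {
        xi <- x[g == l & !is.na(x)]
        tibble::tibble(
          mean = mean(xi), sd = sd(xi),
          skew = if (length(xi) >= 3) e1071::skewness(xi, type = 2) else NA_real_,
          kurtosis = if (length(xi) >= 4) e1071::kurtosis(xi, type = 2) else NA_real_,
          se = sd(xi) / sqrt(length(xi)), n = length(xi))
      })
      tt <- t.test(x[g == lv[1]], x[g == lv[2]], var.equal = TRUE)
      tibble::tibble(
        variable = v, type = "numeric",
        mean_1 = per[[1]]$mean, sd_1 = per[[1]]$sd, skew_1 = per[[1]]$skew,
        kurtosis_1 = per[[1]]$kurtosis, se_1 = per[[1]]$se, n_1 = per[[1]]$n,
        mean_2 = per[[2]]$mean, sd_2 = per[[2]]$sd, skew_2 = per[[2]]$skew,
        kurtosis_2 = per[[2]]$kurtosis, se_2 = per[[2]]$se, n_2 = per[[2]]$n,
        test = "pooled t", statistic = unname(tt$statistic),
        df = unname(tt$parameter), p.value = tt$p.value)
    } else {
      f <- as.factor(x)
      if (nlevels(f) != 2) return(NULL)
      tab <- table(g, f)
      cs <- suppressWarnings(stats::chisq.test(tab, correct = yates))
      tibble::tibble(
        variable = v, type = "categorical",
        mean_1 = NA_real_, sd_1 = NA_real_, skew_1 = NA_real_,
        kurtosis_1 = NA_real_, se_1 = NA_real_, n_1 = sum(tab[1, ]),
        mean_2 = NA_real_, sd_2 = NA_real_, skew_2 = NA_real_,
        kurtosis_2 = NA_real_, se_2 = NA_real_, n_2 = sum(tab[2, ]),
        test = "chi-squared", statistic = unname(cs$statistic),
        df = unname(cs$parameter), p.value = cs$p.value)
    }
  })
}
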