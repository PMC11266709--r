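test_that("standardize matches hand computation and is idempotent", {
  expect_equal(as.numeric(standardize(c(1, 2, 3))), c(-1, 0, 1))
  z <- standardize(rnorm(20, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(as.numeric(standardize(as.numeric(z))), as.numeric(z),
               tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "zero-variance")
})

test_that("build_design lays out mains, group and interactions", {
  set.seed(10)
  coh <- simulate_cohort(t1_cohort_config())
  feats <- impute_features(assemble_features(coh), seed = 1)$data
  d <- build_design(feats, stage_candidates(1))
  expect_equal(ncol(d$x), 19)  # 9 mains + group + 9 interactions
  expect_equal(d$terms,
               c(stage_candidates(1), "group",
                 paste0("group:", stage_candidates(1))))
  # standardized mains: mean 0, sd 1
  num_mains <- setdiff(stage_candidates(1), "gender")
  for (v in num_mains) {
    expect_equal(mean(d$x[, v]), 0, tolerance = 1e-10)
    expect_equal(sd(d$x[, v]), 1, tolerance = 1e-10)
  }
  # indicators are 0/1, interactions exact products
  expect_true(all(d$x[, "group"] %in% c(0, 1)))
  expect_true(all(d$x[, "gender"] %in% c(0, 1)))
  g <- d$x[, "group"]
  for (v in stage_candidates(1)) {
    expect_equal(d$x[, paste0("group:", v)], g * d$x[, v])
  }
  # outcome standardized so the null model has MSE near 1
  expect_equal(mean(d$y), 0, tolerance = 1e-10)
  expect_equal(sd(d$y), 1, tolerance = 1e-10)

  # minimal design: group only
  d0 <- build_design(feats, character(0))
  expect_equal(colnames(d0$x), "group")
  expect_error(build_design(feats, "no_such_var"), "unknown")
})

test_that("coordinate descent matches OLS at lambda = 0", {
  set.seed(11)
  n <- 80; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(x %*% runif(p, -1, 1) + rnorm(n))
  f <- fit_enet(x, y, alpha = 0.7, lambda = 0)
  ols <- coef(lm(y ~ x))
  expect_lt(max(abs(f$beta - ols[-1])), 1e-6)
  expect_lt(abs(f$intercept - ols[1]), 1e-6)
})

test_that("solver matches the univariate soft-threshold closed form", {
  set.seed(12)
  n <- 60
  x <- rnorm(n); x <- x - mean(x); x <- x / sqrt(mean(x^2))  # (1/n) sum x^2 = 1
  y <- 0.6 * x + rnorm(n, 0, 0.4); y <- y - mean(y)
  rho <- mean(x * y)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (a in seq(0.2, 1, length.out = 5)) {
    for (l in seq(0.02, 0.5, length.out = 5)) {
      f <- fit_enet(matrix(x), y, alpha = a, lambda = l)
      closed <- soft(rho, l * a) / (1 + l * (1 - a))
      expect_lt(abs(unname(f$beta) - closed), 1e-8)
    }
  }
})

test_that("all coefficients vanish at and beyond lambda_max", {
  set.seed(13)
  n <- 50; p <- 8
  x <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(x[, 1] + rnorm(n))
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  for (a in c(0.3, 1)) {
    lmax <- max(abs(crossprod(xc, yc) / n)) / a
    expect_true(all(fit_enet(x, y, alpha = a, lambda = lmax)$beta == 0))
    expect_true(all(fit_enet(x, y, alpha = a, lambda = 2 * lmax)$beta == 0))
    expect_false(all(fit_enet(x, y, alpha = a, lambda = 0.5 * lmax)$beta == 0))
  }
})

test_that("solutions satisfy the KKT conditions", {
  set.seed(14)
  n <- 60; p <- 12
  x <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(x %*% c(1, -0.5, rep(0, p - 2)) + rnorm(n))
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  G <- crossprod(xc) / n; g <- as.numeric(crossprod(xc, yc) / n)
  for (a in c(0.4, 0.9)) {
    for (l in c(0.02, 0.15)) {
      b <- fit_enet(x, y, alpha = a, lambda = l)$beta
      rho <- g - G %*% b + diag(G) * b
      for (j in seq_len(p)) {
        if (b[j] != 0) {
          resid <- rho[j] - (diag(G)[j] + l * (1 - a)) * b[j] - l * a * sign(b[j])
          expect_lt(abs(resid), 1e-6)
        } else {
          expect_lte(abs(rho[j]), l * a + 1e-6)
        }
      }
    }
  }
})

test_that("the penalized objective is non-increasing across sweeps", {
  set.seed(15)
  x <- matrix(rnorm(60 * 15), 60, 15)
  y <- as.numeric(x %*% runif(15, -0.5, 0.5) + rnorm(60))
  for (a in c(0, 0.5, 1)) {
    f <- fit_enet(x, y, alpha = a, lambda = 0.05)
    expect_true(all(diff(f$objective) <= 1e-12))
  }
})

test_that("the L1 norm grows monotonically as lambda decreases (lasso path)", {
  set.seed(16)
  x <- matrix(rnorm(50 * 10), 50, 10)
  y <- as.numeric(x %*% runif(10, -1, 1) + rnorm(50))
  lambdas <- exp(seq(log(0.5), log(0.001), length.out = 30))
  norms <- vapply(lambdas, function(l)
    sum(abs(fit_enet(x, y, alpha = 1, lambda = l)$beta)), numeric(1))
  expect_true(all(diff(norms) >= -1e-8))
})

test_that("solver agrees with independent references at matched penalties", {
  set.seed(17)
  n <- 100; p <- 8
  x <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(x %*% c(1.2, -0.8, 0.5, rep(0, p - 3)) + rnorm(n))

  # ridge limit: closed-form normal equations (G + lambda I) b = g
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  G <- crossprod(xc) / n; g <- as.numeric(crossprod(xc, yc) / n)
  for (l in c(0.05, 0.2)) {
    exact <- solve(G + l * diag(p), g)
    expect_equal(unname(fit_enet(x, y, alpha = 0, lambda = l)$beta),
                 as.numeric(exact), tolerance = 1e-7)
  }

  # lasso: glmnet at fixed lambda (exact for alpha = 1; its single-lambda
  # ridge solutions are approximate, hence the closed form above instead)
  skip_if_not_installed("glmnet")
  for (l in c(0.05, 0.2)) {
    ours <- fit_enet(x, y, alpha = 1, lambda = l)
    ref <- glmnet::glmnet(x, y, alpha = 1, lambda = l,
                          standardize = FALSE, thresh = 1e-12)
    expect_equal(unname(ours$beta), as.numeric(ref$beta), tolerance = 1e-5)
    expect_equal(ours$intercept, as.numeric(ref$a0), tolerance = 1e-5)
  }
})

test_that("tuning is deterministic given the fold assignment or seed", {
  set.seed(18)
  x <- matrix(rnorm(60 * 10), 60, 10)
  y <- as.numeric(x[, 1] * 0.8 + rnorm(60))
  foldid <- sample(rep(1:10, 6))
  t1 <- tune_penalties(x, y, foldid = foldid)
  t2 <- tune_penalties(x, y, foldid = foldid)
  expect_identical(t1$alpha, t2$alpha)
  expect_identical(t1$lambda, t2$lambda)
  t3 <- withr::with_seed(5, tune_penalties(x, y))
  t4 <- withr::with_seed(5, tune_penalties(x, y))
  expect_identical(t3[c("alpha", "lambda")], t4[c("alpha", "lambda")])
})

test_that("pure-noise outcomes select a large penalty most of the time", {
  set.seed(19)
  hits <- 0
  for (i in 1:100) {
    x <- matrix(rnorm(80 * 10), 80, 10)
    y <- rnorm(80)
    tun <- tune_penalties(x, y)
    path <- sort(unique(tun$surface$lambda[tun$surface$alpha == tun$alpha]))
    hits <- hits + (tun$lambda >= stats::median(path))
  }
  expect_gte(hits / 100, 0.8)
})

test_that("a strong predictor is kept at the tuned penalties", {
  set.seed(20)
  kept <- 0
  for (i in 1:60) {
    x <- matrix(rnorm(60 * 8), 60, 8)
    y <- as.numeric(3 * x[, 1] + rnorm(60))  # R^2 = 0.9
    tun <- tune_penalties(x, y, k = 5)
    fit <- fit_enet(x, y, alpha = tun$alpha, lambda = tun$lambda)
    kept <- kept + (fit$beta[1] != 0)
  }
  expect_gte(kept / 60, 0.95)
})
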