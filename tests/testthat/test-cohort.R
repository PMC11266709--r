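test_that("config validation rejects inconsistent settings", {
  expect_error(cohort_config(n_congruent_per_block = 50),
               "must equal trials_per_block")
  expect_error(cohort_config(rsfc_missing_rate = 1), "\\[0, 1\\)")
  bad <- default_edge_targets(); bad[1, 2] <- 0.9
  expect_error(cohort_config(target_edge_correlations = bad), "symmetric")
  np <- matrix(0.95, 4, 4); diag(np) <- 1; np[1, 2] <- np[2, 1] <- -0.95
  expect_error(cohort_config(target_edge_correlations = np),
               "positive semi-definite")
})

test_that("trial logs have the configured block structure", {
  set.seed(1)
  trials <- generate_flanker_trials(participant_truth(), cohort_config())
  expect_equal(nrow(trials), 350)
  expect_equal(sum(trials$congruency == "c"), 230)
  expect_equal(sum(trials$congruency == "i"), 120)
  counts <- trials |>
    dplyr::count(block, congruency) |>
    tidyr::pivot_wider(names_from = congruency, values_from = n)
  expect_true(all(counts$c == 46))
  expect_true(all(counts$i == 24))
  expect_true(all(trials$rt_ms > 0))
})

test_that("perfect accuracy leaves no errors and undefined post-error scores", {
  set.seed(2)
  truth <- participant_truth(acc_congruent = 1, acc_incongruent = 1,
                             gratton_acc_shift = 0, pe_acc_shift = 0)
  trials <- generate_flanker_trials(truth, cohort_config())
  expect_true(all(trials$correct == 1))
  s <- score_post_error(trials)
  expect_true(is.na(s$pe_rt) && is.na(s$pe_acc))
})

test_that("outcome generation follows the planted linear model exactly", {
  set.seed(3)
  n <- 40
  feats <- tibble::tibble(
    group = rep(c(0, 1), each = n / 2),
    a = rnorm(n), b = rnorm(n))

  # all weights zero, no noise: constant at the intercept
  cfg0 <- cohort_config(outcome_noise_sd = 0, group_main = 0,
                        outcome_intercept = 2.5,
                        outcome_scale = c(mean = 0, sd = 1),
                        outcome_coefficients = tibble::tibble(
                          variable = "a", prognostic = 0, interaction = 0))
  expect_equal(generate_outcomes(feats, cfg0), rep(2.5, n))

  # single prognostic weight 0.5, no noise: OLS slope on the standardized
  # feature is exactly 0.5
  cfg1 <- cohort_config(outcome_noise_sd = 0, group_main = 0,
                        outcome_scale = c(mean = 0, sd = 1),
                        outcome_coefficients = tibble::tibble(
                          variable = "a", prognostic = 0.5, interaction = 0))
  y1 <- generate_outcomes(feats, cfg1)
  z <- as.numeric(standardize(feats$a))
  expect_equal(unname(coef(lm(y1 ~ z))[2]), 0.5, tolerance = 1e-12)

  # interaction-only weight: zero slope in the control arm, 0.5 in treated
  cfg2 <- cohort_config(outcome_noise_sd = 0, group_main = 0,
                        outcome_scale = c(mean = 0, sd = 1),
                        outcome_coefficients = tibble::tibble(
                          variable = "a", prognostic = 0, interaction = 0.5))
  y2 <- generate_outcomes(feats, cfg2)
  s_mac <- coef(lm(y2[feats$group == 0] ~ z[feats$group == 0]))[2]
  s_icbt <- coef(lm(y2[feats$group == 1] ~ z[feats$group == 1]))[2]
  expect_equal(unname(s_mac), 0, tolerance = 1e-12)
  expect_equal(unname(s_icbt), 0.5, tolerance = 1e-12)

  # unknown coefficient name errors
  cfg3 <- cohort_config(outcome_coefficients = tibble::tibble(
    variable = "missing_var", prognostic = 1, interaction = 0))
  expect_error(generate_outcomes(feats, cfg3), "absent")
})

test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(ts_length = 60)
  c1 <- simulate_cohort(cfg, seed = 99)
  c2 <- simulate_cohort(cfg, seed = 99)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$timeseries, c2$timeseries)
  c3 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(c1$features, c3$features))
})

test_that("cohort structure matches the configuration", {
  coh <- simulate_cohort(cohort_config(ts_length = 80), seed = 5)
  expect_equal(nrow(coh$participants), 60)
  expect_equal(as.integer(table(coh$participants$group)), c(30L, 30L))
  expect_true(all(coh$participants$baseline_phq >= 10 &
                    coh$participants$baseline_phq <= 23))
  expect_equal(nrow(coh$trials), 60 * 350)
  expect_equal(nrow(coh$timeseries), 60 * 80)
  expect_equal(names(coh$features),
               c("participant_id", "group", "age", "gender", "baseline_phq",
                 "post_phq", flanker_score_names(), edge_names()))
  # protected columns never missing
  for (v in c("age", "group", "gender", "baseline_phq", "post_phq")) {
    expect_false(anyNA(coh$features[[v]]))
  }
})

test_that("missingness injection is MCAR at the configured rates", {
  coh <- simulate_cohort(cohort_config(ts_length = 60), seed = 6)
  complete <- coh$features_complete

  # zero rates leave the table untouched
  set.seed(1)
  expect_identical(inject_missingness(complete, rsfc_rate = 0), complete)

  # scan-level loss hits all six edges jointly
  set.seed(2)
  m <- inject_missingness(complete, rsfc_rate = 0.15)
  edge_na <- is.na(m[, edge_names()])
  expect_true(all(rowSums(edge_na) %in% c(0, 6)))

  # count of lost scans lands inside the binomial 99% interval over seeds
  set.seed(3)
  losses <- vapply(1:40, function(i) {
    mm <- inject_missingness(complete, rsfc_rate = 0.15)
    sum(is.na(mm$dACC_leftAI))
  }, numeric(1))
  band <- stats::qbinom(c(0.005, 0.995), 60, 0.15)
  expect_true(mean(losses >= band[1] & losses <= band[2]) > 0.9)
  expect_equal(mean(losses) / 60, 0.15, tolerance = 0.05)

  # QC-failure count mode reproduces the configured totals
  set.seed(4)
  q <- inject_missingness(complete, rsfc_rate = 0,
                          n_gratton_qc = 7, n_post_error_qc = 12)
  expect_equal(sum(is.na(q$gratton_acc)), 7)
  expect_equal(sum(is.na(q$gratton_rt)), 7)
  expect_equal(sum(is.na(q$pe_acc)), 12)
  expect_equal(sum(is.na(q$pe_rt)), 12)

  # protected columns cannot be masked
  expect_error(inject_missingness(complete, extra = list(age = 0.1)),
               "never-missing")
  expect_error(inject_missingness(complete, extra = list(nope = 0.1)),
               "unknown")
})

test_that("planted edge targets are recovered in the long-series limit", {
  cfg <- cohort_config(ts_length = 5000, edge_between_sd = 0, n_per_arm = 3)
  coh <- simulate_cohort(cfg, seed = 7)
  edges <- compute_edges(coh$timeseries)
  target_z <- atanh(as.numeric(edge_vector(cfg$target_edge_correlations)))
  mean_z <- colMeans(as.matrix(edges[, edge_names()]))
  se <- 1 / sqrt(cfg$ts_length - 3) / sqrt(6)
  expect_true(all(abs(mean_z - target_z) < 4 * se + 0.01))
})

test_that("cohort files round-trip through plain-text export", {
  coh <- simulate_cohort(cohort_config(ts_length = 40, n_per_arm = 2), seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  tr <- utils::read.csv(file.path(dir, "trials.csv"))
  expect_equal(nrow(tr), 4 * 350)
  ts <- utils::read.csv(file.path(dir, "timeseries", "P01.csv"))
  expect_equal(dim(ts), c(40, 4))
  expect_equal(names(ts), roi_labels_default())
})
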