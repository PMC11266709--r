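# tiny hand-built trial logs and null-effect cohort configs used across tests

make_trials <- function(congruency, correct, rt, block = 1L) {
  tibble::tibble(
    block = rep_len(block, length(congruency)),
    trial = seq_along(congruency) - 1L,
    congruency = congruency,
    correct = as.integer(correct),
    rt_ms = rt
  )
}

# a config with every planted outcome effect switched off
null_cohort_config <- function(seed, ...) {
  cohort_config(
    seed = seed, group_main = 0,
    outcome_coefficients = outcome_coefficients(
      baseline_phq = c(0, 0), flanker_rt = c(0, 0),
      rightAI_leftAI = c(0, 0), rightAI_TPJ = c(0, 0),
      gratton_acc = c(0, 0), pe_acc = c(0, 0)),
    ...)
}

# the single-planted-interaction config used for power checks:
# group x Flanker-RT interaction of standardized weight 0.5, noise SD 1
t1_cohort_config <- function(seed = 17) {
  cohort_config(
    seed = seed,
    outcome_coefficients = outcome_coefficients(
      baseline_phq = c(0, 0), flanker_rt = c(0, 0.5),
      rightAI_leftAI = c(0, 0), rightAI_TPJ = c(0, 0),
      gratton_acc = c(0, 0), pe_acc = c(0, 0)),
    outcome_noise_sd = 1)
}

# deterministic correlated feature table with MCAR mask, for imputation tests
correlated_table <- function(n = 60, p = 14, rate = 0.15, seed = 1) {
  withr::with_seed(seed, {
    f <- matrix(rnorm(n * 2), n, 2)
    load <- matrix(runif(p * 2, 0.5, 1) * sample(c(-1, 1), p * 2, TRUE), p, 2)
    x <- f %*% t(load) + matrix(rnorm(n * p, 0, 0.4), n, p)
    colnames(x) <- paste0("v", seq_len(p))
    mask <- matrix(runif(n * p) < rate, n, p)
    # keep at least one observed value per column
    for (j in seq_len(p)) if (all(mask[, j])) mask[1, j] <- FALSE
    list(truth = tibble::as_tibble(as.data.frame(x)), mask = mask)
  })
}

mask_table <- function(tab, mask) {
  out <- tab
  for (j in seq_len(ncol(out))) out[[j]][mask[, j]] <- NA_real_
  out
}
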