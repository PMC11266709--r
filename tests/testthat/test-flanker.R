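test_that("interference scores match hand-computed values and orientation", {
  trials <- make_trials(
    congruency = c("c", "c", "c", "c", "i", "i"),
    correct = c(1, 1, 1, 0, 1, 0),
    rt = c(400, 420, 410, 999, 500, 888))
  s <- score_interference(trials)
  expect_equal(s$flanker_acc, 0.75 - 0.5)   # congruent minus incongruent
  expect_equal(s$flanker_rt, 500 - 410)     # correct trials only
  expect_equal(s$n_congruent, 4)
  expect_equal(s$n_incongruent_correct, 1)
})

test_that("identical condition performance gives zero interference", {
  trials <- make_trials(
    congruency = rep(c("c", "i"), each = 4),
    correct = rep(c(1, 1, 0, 1), 2),
    rt = rep(c(450, 470, 460, 440), 2))
  s <- score_interference(trials)
  expect_equal(s$flanker_acc, 0)
  expect_equal(s$flanker_rt, 0)
})

test_that("empty correct-RT cell yields NA for the RT score only", {
  trials <- make_trials(
    congruency = c("c", "c", "i", "i"),
    correct = c(1, 1, 0, 0),
    rt = c(400, 410, 500, 520))
  s <- score_interference(trials)
  expect_true(is.na(s$flanker_rt))
  expect_equal(s$flanker_acc, 1 - 0)
})

test_that("Gratton scores match hand-computed values", {
  # build within one block: pairs classified by previous congruency, previous
  # trial must be correct; cI correct RTs {480, 500}, iI correct RT {450}
  trials <- make_trials(
    congruency = c("c", "i", "c", "i", "i", "i"),
    correct    = c(1,   1,   1,   1,   1,   1),
    rt         = c(400, 480, 410, 500, 450, 455))
  s <- score_gratton(trials)
  expect_equal(s$gratton_rt, mean(c(480, 500)) - mean(c(450, 455)))
  expect_equal(s$n_cI, 2)
  expect_equal(s$n_iI, 2)

  # accuracy: cI accuracies {1, 0}, iI accuracies {1, 1}
  trials2 <- make_trials(
    congruency = c("c", "i", "c", "i", "i", "i"),
    correct    = c(1,   1,   1,   0,   1,   1),
    rt         = rep(500, 6))
  # pairs: cI = trials 2 (correct) and 4 (error); iI = trial 5 (prev trial 4
  # was an error, so trial 5 is post-error, not a Gratton pair) -> rebuild
  trials2 <- make_trials(
    congruency = c("c", "i", "c", "i", "i", "i", "i"),
    correct    = c(1,   1,   1,   0,   1,   1,   1),
    rt         = rep(500, 7))
  s2 <- score_gratton(trials2)
  # cI pairs: trial 2 (acc 1), trial 4 (acc 0); iI pairs: trials 6, 7 (acc 1)
  expect_equal(s2$gratton_acc, 1 - 0.5)
})

test_that("Gratton pairs require a correct predecessor and same block", {
  # error at trial 1 makes trial 2 post-error, not a cI pair
  trials <- make_trials(
    congruency = c("c", "i", "i", "i"),
    correct    = c(0,   1,   1,   1),
    rt         = rep(500, 4))
  s <- score_gratton(trials)
  expect_equal(s$n_cI, 0)
  expect_equal(s$n_iI, 2)
  expect_true(is.na(s$gratton_acc))

  # the same trials split across blocks lose the cross-boundary pair
  split <- make_trials(
    congruency = c("i", "i", "i", "i"),
    correct    = c(1, 1, 1, 1),
    rt = rep(500, 4), block = c(1L, 1L, 2L, 2L))
  expect_equal(score_gratton(split)$n_iI, 2)
})

test_that("post-error scores match hand-computed values", {
  # one error at trial 2; trial 3 correct RT 520; post-correct RTs {400, 410}
  trials <- make_trials(
    congruency = rep("c", 5),
    correct = c(1, 0, 1, 1, 1),
    rt = c(390, 430, 520, 400, 410))
  s <- score_post_error(trials)
  expect_equal(s$pe_rt, 520 - mean(c(400, 410)))
  expect_equal(s$n_post_error, 1)
  expect_equal(s$n_post_correct, 3)

  # accuracies: post-error {1}, post-correct {1, 1, 0, 1}
  trials2 <- make_trials(
    congruency = rep("c", 6),
    correct = c(0, 1, 1, 1, 0, 1),
    rt = rep(500, 6))
  # post-error trials: 2 (after err 1), 6 (after err 5): rebuild to match
  trials2 <- make_trials(
    congruency = rep("c", 6),
    correct = c(1, 0, 1, 1, 0, 1),
    rt = rep(500, 6))
  # post-error: trials 3 (acc 1), 6 (acc 1); post-correct: 2 (0), 4 (1), 5 (0)
  s2 <- score_post_error(trials2)
  expect_equal(s2$pe_acc, 1 - mean(c(0, 1, 0)))
})

test_that("error-free logs leave post-error scores undefined and QC failed", {
  trials <- make_trials(
    congruency = rep(c("c", "i"), 10),
    correct = rep(1, 20),
    rt = rep(450, 20))
  s <- score_post_error(trials)
  expect_equal(s$n_post_error, 0)
  expect_true(is.na(s$pe_acc) && is.na(s$pe_rt))
  full <- score_flanker(trials)
  expect_false(full$qc_post_error)
  expect_true(is.na(full$pe_rt))
})

test_that("QC thresholds flag scores missing without erroring", {
  trials <- make_trials(
    congruency = rep(c("c", "i"), each = 10),
    correct = rep(1, 20),
    rt = rep(450, 20))
  s <- dplyr::bind_cols(score_interference(trials), score_gratton(trials),
                        score_post_error(trials))
  q <- apply_qc(s, min_cell = 5)
  expect_true(q$qc_interference)
  expect_false(q$qc_gratton)     # only c->i transitions exist in this layout
  expect_true(is.na(q$gratton_rt))

  # below-chance accuracy (0.45) fails interference QC
  bad <- make_trials(
    congruency = rep(c("c", "i"), 20),
    correct = c(rep(1, 18), rep(0, 22)),
    rt = rep(450, 40))
  qb <- score_flanker(bad)
  expect_false(qb$qc_interference)
  expect_true(is.na(qb$flanker_acc))
})

test_that("scores are invariant to block order and equivariant to RT scale", {
  set.seed(42)
  truth <- participant_truth(acc_incongruent = 0.8, rt_sigma = 0.2,
                             pe_rt_shift = 30)
  trials <- generate_flanker_trials(truth, cohort_config())
  s1 <- score_flanker(trials)

  reordered <- dplyr::arrange(trials, -block, trial)
  s2 <- score_flanker(reordered)
  expect_equal(s2[flanker_score_names()], s1[flanker_score_names()])

  doubled <- dplyr::mutate(trials, rt_ms = 2 * rt_ms)
  s3 <- score_flanker(doubled)
  expect_equal(s3$flanker_rt, 2 * s1$flanker_rt)
  expect_equal(s3$gratton_rt, 2 * s1$gratton_rt)
  expect_equal(s3$pe_rt, 2 * s1$pe_rt)
  expect_equal(s3$flanker_acc, s1$flanker_acc)
  expect_equal(s3$pe_acc, s1$pe_acc)
})

test_that("noiseless planted condition means are recovered exactly", {
  set.seed(7)
  truth <- participant_truth(
    acc_congruent = 1, acc_incongruent = 1,
    rt_congruent = 400, rt_incongruent = 490, rt_sigma = 0,
    gratton_acc_shift = 0, gratton_rt_shift = 0,
    pe_acc_shift = 0, pe_rt_shift = 0)
  trials <- generate_flanker_trials(truth, cohort_config())
  s <- score_flanker(trials)
  expect_equal(s$flanker_rt, 90)
  expect_equal(s$flanker_acc, 0)
  expect_equal(s$gratton_rt, 0)
  # all-correct log has no post-error trials
  expect_false(s$qc_post_error)
})

test_that("accuracy scores stay within [-1, 1] over random logs", {
  set.seed(11)
  for (i in 1:20) {
    truth <- participant_truth(
      acc_congruent = runif(1, 0.5, 1), acc_incongruent = runif(1, 0.3, 1),
      rt_sigma = runif(1, 0, 0.4),
      gratton_acc_shift = runif(1, -0.2, 0.2),
      pe_acc_shift = runif(1, -0.2, 0.2))
    s <- score_flanker(generate_flanker_trials(truth, cohort_config()))
    for (v in c("flanker_acc", "gratton_acc", "pe_acc")) {
      if (!is.na(s[[v]])) expect_true(abs(s[[v]]) <= 1)
    }
  }
})
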