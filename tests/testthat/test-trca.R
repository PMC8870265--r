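test_that("a deterministic noiseless session classifies perfectly", {
  fx <- fix_session(seed = 11, blocks = 2, noise_gain = 0, jitter = 0)
  tr <- session_trials(fx$session, 1)
  te <- session_trials(fx$session, 2)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  # without noise or jitter, blocks repeat exactly
  expect_equal(tr$trials[[1]], te$trials[[1]])
  expect_equal(block_accuracy(te$trials, te$labels, fit), 1)
  # a trial equal to its own class template scores the full weight sum = 1
  sc <- drop(predict(fit, tr$trials[[7]], type = "scores"))
  expect_equal(max(sc), 1, tolerance = 1e-6)
  expect_identical(which.max(sc), 7L)
})

test_that("noiseless trials with latency jitter classify at 100% from two blocks", {
  fx <- fix_session(seed = 12, blocks = 3, noise_gain = 0)
  tr <- session_trials(fx$session, 1:2)
  te <- session_trials(fx$session, 3)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  expect_equal(block_accuracy(te$trials, te$labels, fit), 1)
})

test_that("scores are bounded correlations and scale-invariant", {
  fx <- fix_session(seed = 11, blocks = 2)
  tr <- session_trials(fx$session, 1)
  te <- session_trials(fx$session, 2)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  sc <- predict(fit, te$trials[1:8], type = "scores")
  expect_true(all(sc >= -1 - 1e-12 & sc <= 1 + 1e-12))
  # global positive rescaling of a trial leaves the decision unchanged
  sc1 <- predict(fit, te$trials[[3]], type = "scores")
  sc2 <- predict(fit, 50 * te$trials[[3]], type = "scores")
  expect_equal(sc1, sc2, tolerance = 1e-9)
})

test_that("relabeling templates permutes scores identically", {
  fx <- fix_session(seed = 11, blocks = 2)
  tr <- session_trials(fx$session, 1)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  perm <- c(2:32, 1)
  fit_p <- fit
  for (k in seq_along(fit$filters)) {
    fit_p$filters[[k]] <- fit$filters[[k]][, perm]
    fit_p$templates[[k]] <- fit$templates[[k]][, , perm]
  }
  # rebuild projections for the permuted model via the save/load path
  d <- withr::local_tempdir()
  save_model(fit_p, d)
  fit_p <- load_model(d)
  trial <- session_trials(fx$session, 2)$trials[[5]]
  sc <- drop(predict(fit, trial, type = "scores"))
  sc_p <- drop(predict(fit_p, trial, type = "scores"))
  expect_equal(sc_p, sc[perm], tolerance = 1e-6)
})

test_that("block order does not change the fitted model", {
  fx <- fix_session(seed = 13, blocks = 2)
  tr <- session_trials(fx$session, 1:2)
  fit1 <- cvep_trca(tr$trials, tr$labels, fs = 600)
  rev_idx <- rev(seq_along(tr$trials))
  fit2 <- cvep_trca(tr$trials[rev_idx], tr$labels[rev_idx], fs = 600)
  expect_equal(fit1$filters, fit2$filters, tolerance = 1e-9)
  expect_equal(fit1$templates, fit2$templates, tolerance = 1e-9)
})

test_that("ensemble structure and shapes follow the training data", {
  fx <- fix_session(seed = 11, blocks = 2)
  tr <- session_trials(fx$session, 1)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  expect_length(fit$filters, 5)
  for (k in 1:5) {
    expect_identical(dim(fit$filters[[k]]), c(16L, 32L))
    expect_identical(dim(fit$templates[[k]]), c(16L, 1260L, 32L))
  }
  expect_identical(fit$n_train, rep(1L, 32))
  expect_error(cvep_trca(tr$trials[1:10], tr$labels[1:10], fs = 600,
                         n_classes = 32),
               "no training trials")
})

test_that("block_accuracy validates one-trial-per-target and counts errors", {
  fx <- fix_session(seed = 11, blocks = 2, noise_gain = 0, jitter = 0)
  tr <- session_trials(fx$session, 1)
  te <- session_trials(fx$session, 2)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  expect_error(block_accuracy(te$trials[1:31], te$labels[1:31], fit),
               "one trial per target")
  expect_error(block_accuracy(te$trials[c(1, 1:31)], te$labels[c(1, 1:31)],
                              fit), "one trial per target")
  # swapping two templates at zero noise induces exactly two errors
  fit_sw <- fit
  for (k in seq_along(fit$filters)) {
    fit_sw$templates[[k]][, , c(3, 9)] <- fit$templates[[k]][, , c(9, 3)]
    fit_sw$filters[[k]][, c(3, 9)] <- fit$filters[[k]][, c(9, 3)]
  }
  d <- withr::local_tempdir()
  save_model(fit_sw, d)
  fit_sw <- load_model(d)
  expect_equal(block_accuracy(te$trials, te$labels, fit_sw), 30 / 32)
})

test_that("model methods print, coef, plot and score_trial work", {
  fx <- fix_session(seed = 11, blocks = 2)
  tr <- session_trials(fx$session, 1)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  expect_output(print(fit), "ensemble template-matching")
  expect_output(print(summary(fit)), "sub-band weights")
  expect_length(coef(fit), 5)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit, classes = 1:2))
  dec <- score_trial(session_trials(fx$session, 2)$trials[[4]], fit,
                     true_class = 4)
  expect_length(dec$scores, 32)
  expect_identical(dec$predicted_class, which.max(dec$scores))
  expect_identical(dec$true_class, 4)
})

test_that("shuffled labels drive accuracy to chance level", {
  # score pure-noise trials against a real model: the predicted classes
  # must be unrelated to the (arbitrary) labels
  fx <- fix_session(seed = 14, blocks = 1)
  tr <- session_trials(fx$session, 1)
  fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
  set.seed(99)
  hits <- 0L; total <- 0L
  for (b in 1:50) {
    noise <- lapply(1:8, function(i) matrix(rnorm(16 * 1260), 16))
    pred <- predict(fit, noise, type = "class")
    hits <- hits + sum(pred == sample(32, 8, replace = TRUE))
    total <- total + 8L
  }
  p <- hits / total
  se <- sqrt((1 / 32) * (31 / 32) / total)
  expect_lt(abs(p - 1 / 32), 3 * se)
})
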