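test_that("subject models are deterministic and seed-sensitive", {
  s1 <- sample_subject(101)
  s2 <- sample_subject(101)
  s3 <- sample_subject(202)
  expect_identical(s1, s2)
  # different seeds draw different kernel peak latencies
  expect_false(which.max(s1$impulse_response) ==
                 which.max(s3$impulse_response) &&
                 isTRUE(all.equal(s1$impulse_response, s3$impulse_response)))
  expect_equal(sum(s1$mixing_vector^2), 1, tolerance = 1e-12)
  expect_true(all(is.finite(s1$impulse_response)))
  expect_gt(s1$snr_scale, 0)
  expect_true(s1$peak_latency >= 0.09 && s1$peak_latency <= 0.15)
  expect_error(sample_subject(1, cvep_sim_config(snr_scale = 0)), "> 0")
})

test_that("session simulation has the declared trial structure", {
  fx <- fix_session(seed = 11, blocks = 2)
  sess <- fx$session
  expect_identical(dim(sess$data), c(2L, 32L, 16L, 1260L))
  expect_identical(sess$fs, 600)
  expect_identical(sess$n_samples, 1260L)
  tr <- session_trials(sess)
  expect_length(tr$trials, 64)           # 32 targets x 2 blocks
  expect_identical(dim(tr$trials[[1]]), c(16L, 1260L))
  expect_error(session_trials(sess, 5), "not in tensor")
  # a six-block session yields the full 192-trial complement
  cfg6 <- cvep_sim_config()
  expect_identical(cfg6$blocks * cfg6$n_targets, 192L)
})

test_that("simulation is reproducible and respects the noiseless limit", {
  cs <- fix_cs
  cfg <- cvep_sim_config(blocks = 1, latency_jitter_sd = 0)
  subj <- sample_subject(7, cfg)
  a <- simulate_session(subj, null_session_effect(0), cs, 1, seed = 3,
                        config = cfg)
  b <- simulate_session(subj, null_session_effect(0), cs, 1, seed = 3,
                        config = cfg)
  expect_identical(a$data, b$data)
  # zero noise + zero jitter: the same target repeats identically
  cfg2 <- cvep_sim_config(blocks = 2, latency_jitter_sd = 0)
  two <- simulate_session(subj, null_session_effect(0), cs, 2, seed = 3,
                          config = cfg2)
  expect_equal(two$data[1, 5, , ], two$data[2, 5, , ])
  # incompatible sampling rate is rejected before any data is produced
  expect_error(simulate_session(subj, null_session_effect(), cs, 1, seed = 1,
                                config = cvep_sim_config(fs = 500)),
               "divisible")
})

test_that("evoked power concentrates on strongly mixed channels", {
  fx <- fix_session(seed = 15, blocks = 1, noise_gain = 0, jitter = 0)
  pw <- apply(fx$session$data[1, , , ], 2, function(ch) mean(ch^2))
  expect_gt(cor(pw, abs(fx$subject$mixing_vector)^2, method = "spearman"),
            0.99)
  # with noise the ranking still leans toward the mixing pattern
  fxn <- fix_session(seed = 15, blocks = 1)
  pwn <- apply(fxn$session$data[1, , , ], 2, function(ch) mean(ch^2))
  expect_gt(cor(pwn, abs(fxn$subject$mixing_vector), method = "spearman"), 0)
})

test_that("accuracy increases with the SNR scale", {
  cs <- fix_cs
  accs <- sapply(c(0.02, 0.25, 5), function(snr) {
    mean(sapply(1:3, function(s) {
      cfg <- cvep_sim_config(blocks = 2, snr_scale = snr)
      subj <- sample_subject(300 + s, cfg)
      sess <- simulate_session(subj, null_session_effect(), cs, 2,
                               seed = s, config = cfg)
      tr <- session_trials(sess, 1); te <- session_trials(sess, 2)
      fit <- cvep_trca(tr$trials, tr$labels, fs = 600)
      block_accuracy(te$trials, te$labels, fit)
    }))
  })
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})

test_that("session effects separate cross-session from within-session", {
  cs <- fix_cs
  cfg <- cvep_sim_config(blocks = 2)
  gap <- function(pert, seed) {
    subj <- sample_subject(seed, cfg)
    e1 <- session_effect(seed + 1, kernel_perturbation_sd = pert,
                         config = cfg)
    e2 <- session_effect(seed + 2, kernel_perturbation_sd = pert,
                         config = cfg)
    s1 <- simulate_session(subj, e1, cs, 2, seed = seed + 10, config = cfg)
    s2 <- simulate_session(subj, e2, cs, 2, seed = seed + 20, config = cfg)
    # per-target trial correlations, averaged over all 32 targets
    g <- vapply(1:32, function(k) {
      a <- as.vector(s1$data[1, k, , ])
      cor(a, as.vector(s1$data[2, k, , ])) -
        cor(a, as.vector(s2$data[1, k, , ]))
    }, numeric(1))
    mean(g)
  }
  gaps <- sapply(c(0, 0.3, 0.8), function(p)
    mean(sapply(1:4, function(s) gap(p, 400 + 10 * s))))
  # the within/across correlation gap widens with kernel perturbation
  expect_true(all(diff(gaps) > 0))
})

test_that("a full study is reproducible with session-distinct blocks", {
  cfg <- cvep_sim_config(blocks = 1)
  st1 <- simulate_study(2, fix_cs, cfg, seed = 5)
  st2 <- simulate_study(2, fix_cs, cfg, seed = 5)
  expect_identical(st1$subjects[[1]]$sessions[[1]]$data,
                   st2$subjects[[1]]$sessions[[1]]$data)
  expect_identical(st1$subjects[[2]]$sessions[[2]]$block_ids, 2L)
  expect_identical(st1$subjects[[1]]$sessions[[1]]$block_ids, 1L)
  # different subjects get different data
  expect_false(identical(st1$subjects[[1]]$sessions[[1]]$data,
                         st1$subjects[[2]]$sessions[[1]]$data))
  expect_error(simulate_study(0, fix_cs, cfg, 1), ">= 1")
})
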