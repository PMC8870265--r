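test_that("cross-session plans pair the right model and test blocks", {
  pl <- cross_session_plans()
  expect_named(pl, c("Ms1Ds1", "Ms1Ds2", "Ms2Ds1", "Ms2Ds2"))
  expect_length(pl, 4)
  expect_identical(pl$Ms1Ds2[[1]]$model_blocks, 1:6)
  expect_identical(pl$Ms1Ds2[[1]]$test_blocks, 7:12)
  expect_identical(pl$Ms2Ds1[[1]]$model_blocks, 7:12)
  # intra-session cells are 6-fold leave-one-block-out
  expect_length(pl$Ms1Ds1, 6)
  fold3 <- pl$Ms1Ds1[[3]]
  expect_identical(fold3$model_blocks, c(1L, 2L, 4L, 5L, 6L))
  expect_identical(fold3$test_blocks, 3L)
})

test_that("stepwise plans grow along the interleaved sequence", {
  expect_identical(block_seq(), c(1L, 7L, 2L, 8L, 3L, 9L, 4L, 10L, 5L, 11L,
                                  6L, 12L))
  st12 <- stepwise_plans(12)
  expect_length(st12, 11)
  expect_identical(st12[[1]]$model_blocks, 1L)
  expect_identical(st12[[2]]$model_blocks, c(1L, 7L))
  expect_identical(st12[[6]]$model_blocks, c(1L, 7L, 2L, 8L, 3L, 9L))
  expect_identical(st12[[11]]$model_blocks,
                   c(1L, 7L, 2L, 8L, 3L, 9L, 4L, 10L, 5L, 11L, 6L))
  # removing a mid-sequence test block reflows the remaining order
  st1 <- stepwise_plans(1)
  expect_identical(st1[[1]]$model_blocks, 7L)
  for (tb in c(1L, 8L, 12L))
    for (pl in stepwise_plans(tb))
      expect_false(tb %in% pl$model_blocks)
  expect_error(stepwise_plans(13), "1\\.\\.12")
})

test_that("variant plans carve the documented model/test splits", {
  v <- variant_plans()
  expect_named(v, paste0("V", 1:5))
  expect_identical(v$V1$test_blocks, 12L)
  expect_identical(v$V1$model_blocks, c(1L, 7L, 2L, 8L, 3L, 9L, 4L, 10L,
                                        5L, 11L, 6L))
  expect_identical(v$V2$test_blocks, c(12L, 6L))
  expect_identical(v$V2$model_blocks, c(1L, 7L, 2L, 8L, 3L, 9L, 4L, 10L,
                                        5L, 11L))
  expect_identical(v$V3$test_blocks, c(12L, 6L, 11L))
  expect_identical(v$V5$test_blocks, c(12L, 6L, 11L, 5L, 10L))
  expect_length(v$V5$model_blocks, 7)
  # model and test sets are disjoint in every variant
  for (pl in v) expect_length(intersect(pl$model_blocks, pl$test_blocks), 0)
})

test_that("every plan constructor enforces model/test disjointness", {
  expect_error(cveptools:::new_plan("bad", 1:3, 3L), "overlap")
  expect_error(cveptools:::new_plan("bad", 0:2, 5L), "1\\.\\.12")
  all_plans <- c(unlist(cross_session_plans(), recursive = FALSE),
                 unlist(lapply(block_seq(), stepwise_plans),
                        recursive = FALSE),
                 variant_plans())
  for (pl in all_plans)
    expect_length(intersect(pl$model_blocks, pl$test_blocks), 0)
})

test_that("ITR follows the closed form with chance clamping", {
  expect_equal(round(itr(1), 2), 96.77)
  expect_equal(round(itr(0.75), 2), 57.10)
  expect_equal(itr(1), log2(32) * 60 / 3.1, tolerance = 1e-12)
  expect_identical(itr(1 / 32), 0)
  expect_identical(itr(0.02), 0)
  # raw (unclamped) value below chance is retained on request
  expect_gt(itr(0.02, clamp = FALSE), -Inf)
  expect_lt(itr(0.02, clamp = FALSE), itr(0.05, clamp = FALSE))
  # strictly increasing on (1/N, 1]
  p <- seq(1 / 32 + 0.01, 1, length.out = 50)
  expect_true(all(diff(itr(p)) > 0))
  expect_error(itr(1.2), "\\[0, 1\\]")
  expect_error(itr(0.5, N = 1), ">= 2")
  expect_error(itr(0.5, T_s = 0), "> 0")
})

test_that("protocol execution matches direct model fitting", {
  cfg <- cvep_sim_config(blocks = 2)
  st <- simulate_study(1, fix_cs, cfg, seed = 8)
  plans <- list(check = list(cveptools:::new_plan("check", c(1, 3), 2L)))
  cells <- run_protocols(st, plans)
  # independent route: fit on blocks 1 and 3 by hand, test block 2
  s1 <- st$subjects[[1]]$sessions[[1]]
  s2 <- st$subjects[[1]]$sessions[[2]]
  tr1 <- session_trials(s1, 1); tr3 <- session_trials(s2, 3)
  fit <- cvep_trca(c(tr1$trials, tr3$trials), c(tr1$labels, tr3$labels),
                   fs = 600)
  te <- session_trials(s1, 2)
  expect_equal(cells$accuracy,
               100 * block_accuracy(te$trials, te$labels, fit),
               tolerance = 1e-9)
  expect_identical(cells$test_block, 2L)
})

test_that("aggregate_report reduces cells exactly", {
  cells <- data.frame(
    subject = rep(1:3, each = 4),
    group = rep(c("A", "A", "B", "B"), 3),
    accuracy = c(90, 100, 50, 60, 80, 90, 40, 50, 100, 100, 70, 80))
  rep <- aggregate_report(cells)
  per <- rep$subject_cells
  expect_equal(per$accuracy[per$group == "A"], c(95, 85, 100))
  expect_equal(rep$summary$mean[rep$summary$group == "A"],
               mean(c(95, 85, 100)), tolerance = 1e-9)
  expect_equal(rep$summary$sd[rep$summary$group == "B"],
               sd(c(55, 45, 75)), tolerance = 1e-9)
  expect_equal(per$itr, itr(per$accuracy / 100), tolerance = 1e-12)
  expect_output(print(rep), "bits/min")
  expect_error(aggregate_report(data.frame(subject = 1, group = "A",
                                           accuracy = NA_real_)), "missing")
})

test_that("cross-subject transfer favors the matching subject", {
  cfg <- cvep_sim_config(blocks = 2)
  st <- simulate_study(2, fix_cs, cfg, seed = 21)
  G <- cross_subject_grid(st, 1, 1)
  expect_identical(dim(G), c(2L, 2L))
  # subjects have disjoint random mixing vectors: own-data beats transfer
  expect_gt(mean(diag(G)), mean(G[row(G) != col(G)]))
  # diagonal agrees with the intra-session leave-one-out protocol
  loo <- list(Ms1Ds1 = list(cveptools:::new_plan("f1", 2L, 1L),
                            cveptools:::new_plan("f2", 1L, 2L)))
  cells <- run_protocols(st, loo, subjects = 1)
  expect_equal(G[1, 1], mean(cells$accuracy), tolerance = 1e-9)
})
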