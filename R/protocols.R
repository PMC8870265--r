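#' The interleaved multi-day block sequence
#'
#' Session-1 blocks (1..6) and session-2 blocks (7..12) alternated, the
#' order in which stepwise models are grown and variants are carved out.
#'
#' @return integer vector \code{c(1,7,2,8,3,9,4,10,5,11,6,12)}.
#' @export
block_seq <- function() c(1L, 7L, 2L, 8L, 3L, 9L, 4L, 10L, 5L, 11L, 6L, 12L)

new_plan <- function(name, model_blocks, test_blocks) {
  model_blocks <- as.integer(model_blocks)
  test_blocks <- as.integer(test_blocks)
  if (length(intersect(model_blocks, test_blocks)))
    stop("plan '", name, "': model and test blocks overlap")
  if (any(c(model_blocks, test_blocks) < 1L) ||
      any(c(model_blocks, test_blocks) > 12L))
    stop("plan '", name, "': block ids must be in 1..12")
  structure(list(name = name, model_blocks = model_blocks,
                 test_blocks = test_blocks),
            class = "protocol_plan")
}

#' @export
print.protocol_plan <- function(x, ...) {
  cat(x$name, ": model {", paste(x$model_blocks, collapse = ","),
      "} -> test {", paste(x$test_blocks, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Cross-session evaluation plans
#'
#' The four model/data session combinations. Same-session cells
#' (Ms1Ds1, Ms2Ds2) are leave-one-block-out: six folds, each fitting on
#' five blocks and testing the held-out one. Cross-session cells use all
#' six source-session blocks as the model and each of the other session's
#' six blocks as a test block.
#'
#' @return named list of 4 elements (\code{Ms1Ds1}, \code{Ms1Ds2},
#'   \code{Ms2Ds1}, \code{Ms2Ds2}), each a list of [protocol_plan]s
#'   (6 folds for intra-session, 1 plan for inter-session).
#' @export
cross_session_plans <- function() {
  s1 <- 1:6; s2 <- 7:12
  loo <- function(blocks, tag)
    lapply(blocks, function(b)
      new_plan(sprintf("%s.fold%d", tag, b), setdiff(blocks, b), b))
  list(
    Ms1Ds1 = loo(s1, "Ms1Ds1"),
    Ms1Ds2 = list(new_plan("Ms1Ds2", s1, s2)),
    Ms2Ds1 = list(new_plan("Ms2Ds1", s2, s1)),
    Ms2Ds2 = loo(s2, "Ms2Ds2"))
}

#' Stepwise-growing model plans
#'
#' Removes the test block from the interleaved [block_seq()] and takes
#' growing prefixes of the remaining 11-block order: step s fits on the
#' first s blocks and tests the held-out block.
#'
#' @param test_block block id in 1..12 held out for testing.
#' @return list of 11 [protocol_plan]s, one per step.
#' @export
stepwise_plans <- function(test_block) {
  test_block <- as.integer(test_block)
  if (!test_block %in% block_seq()) stop("test_block must be in 1..12")
  rem <- setdiff(block_seq(), test_block)
  lapply(seq_along(rem), function(s)
    new_plan(sprintf("step%d.test%d", s, test_block), rem[1:s], test_block))
}

#' Reduced-training variant plans
#'
#' Five fixed model/test splits of the interleaved sequence that probe how
#' little (and which) training data suffices. The variant accuracy is the
#' mean over its test blocks under the one fixed model.
#'
#' @return named list of 5 [protocol_plan]s V1..V5.
#' @export
variant_plans <- function() {
  sq <- block_seq()
  in_seq <- function(upto, drop = integer())
    setdiff(sq[sq <= upto], drop)
  list(
    V1 = new_plan("V1", in_seq(11L), 12L),
    V2 = new_plan("V2", in_seq(11L, drop = 6L), c(12L, 6L)),
    V3 = new_plan("V3", in_seq(10L, drop = 6L), c(12L, 6L, 11L)),
    V4 = new_plan("V4", in_seq(10L, drop = c(5L, 6L)), c(12L, 6L, 11L, 5L)),
    V5 = new_plan("V5", in_seq(9L, drop = c(5L, 6L)),
                  c(12L, 6L, 11L, 5L, 10L)))
}

# ---- plan execution --------------------------------------------------------

# pool of per-block filtered representations for one subject (both
# sessions); the filter bank is applied once and cached per block
prefilter_pool <- function(sessions, fb) {
  pool <- list()
  for (tensor in sessions) {
    for (b in tensor$block_ids) {
      tr <- session_trials(tensor, b)
      pool[[as.character(b)]] <- make_fblock(tr$trials, tr$labels, fb,
                                             tensor$fs)
    }
  }
  attr(pool, "fs") <- sessions[[1L]]$fs
  pool
}

pool_blocks <- function(pool, blocks) {
  ids <- as.character(blocks)
  if (!all(ids %in% names(pool)))
    stop("block id(s) not in pool: ",
         paste(setdiff(ids, names(pool)), collapse = ", "))
  pool[ids]
}

# fit a model on a set of pooled blocks
pool_fit <- function(pool, blocks, fb, fs) {
  fbs <- pool_blocks(pool, blocks)
  classes <- sort(unique(unlist(lapply(fbs, `[[`, "labels"))))
  fit <- fit_fblocks(fbs, classes, fb)
  fit$fs <- fs
  fit
}

# accuracy (%) of a fitted model on one pooled block
pool_block_accuracy <- function(fit, pool, block) {
  fbk <- pool_blocks(pool, block)[[1L]]
  pred <- max.col(score_fblock(fbk, fit), ties.method = "first")
  100 * mean(fit$classes[pred] == fbk$labels)
}

# evaluate a list of plans on one subject's prefiltered pool;
# returns one row per (plan, test block)
run_plans <- function(plans, pool, fb, fs) {
  plan <- character(); tblk <- integer(); acc <- numeric()
  for (pl in plans) {
    fit <- pool_fit(pool, pl$model_blocks, fb, fs)
    for (tb in pl$test_blocks) {
      plan <- c(plan, pl$name)
      tblk <- c(tblk, tb)
      acc <- c(acc, pool_block_accuracy(fit, pool, tb))
    }
  }
  data.frame(plan = plan, test_block = tblk, accuracy = acc)
}

#' Run evaluation protocols on a study
#'
#' Applies a set of block-composition plans to every subject of a study.
#' Each subject's two sessions form a pool of 12 blocks; for every plan a
#' model is fitted on its model blocks and every test block is classified.
#'
#' @param study a [simulate_study()] result (or an equivalent structure
#'   loaded with [read_study()]).
#' @param plans either a flat list of [protocol_plan]s or a (possibly
#'   nested) named list of plan lists as returned by
#'   [cross_session_plans()].
#' @param fb a [filterbank_spec()].
#' @param subjects subject indices to evaluate (default all).
#' @return data.frame with columns \code{subject}, \code{group} (top-level
#'   plan-list name, if any), \code{plan}, \code{test_block},
#'   \code{accuracy} (percent).
#' @export
run_protocols <- function(study, plans, fb = filterbank_spec(),
                          subjects = seq_along(study$subjects)) {
  flat <- flatten_plans(plans)
  out <- list()
  for (s in subjects) {
    pool <- prefilter_pool(study$subjects[[s]]$sessions, fb)
    fs <- attr(pool, "fs")
    for (g in names(flat)) {
      df <- run_plans(flat[[g]], pool, fb, fs)
      df$group <- g
      df$subject <- s
      out[[length(out) + 1L]] <- df
    }
  }
  res <- do.call(rbind, out)
  res[, c("subject", "group", "plan", "test_block", "accuracy")]
}

flatten_plans <- function(plans) {
  if (inherits(plans, "protocol_plan")) return(list(plan = list(plans)))
  if (all(vapply(plans, inherits, logical(1), "protocol_plan"))) {
    nm <- names(plans) %||% vapply(plans, `[[`, character(1), "name")
    return(split(plans, factor(nm, levels = unique(nm))))
  }
  # named list of plan lists
  plans
}

#' Cross-subject transfer grid
#'
#' Cell (i, j): the model of subject i (trained on its
#' \code{model_session} blocks) classifies the test blocks of subject j's
#' \code{data_session}. When \code{model_session == data_session} the
#' diagonal uses leave-one-block-out within the session (a model cannot be
#' tested on its own training blocks); off-diagonal cells use all six
#' model-session blocks. For differing sessions every cell uses the full
#' six-block model against all six data-session blocks.
#'
#' @param study a [simulate_study()] result.
#' @param model_session,data_session session index (1 or 2).
#' @param fb a [filterbank_spec()].
#' @return n_subjects x n_subjects matrix of accuracies in percent; rows
#'   index the model subject, columns the data subject.
#' @export
cross_subject_grid <- function(study, model_session = 1L, data_session = 1L,
                               fb = filterbank_spec()) {
  ns <- length(study$subjects)
  pools <- lapply(seq_len(ns), function(s)
    prefilter_pool(study$subjects[[s]]$sessions, fb))
  fs <- attr(pools[[1L]], "fs")
  sess_blocks <- function(s, ss) study$subjects[[s]]$sessions[[ss]]$block_ids
  G <- matrix(NA_real_, ns, ns)
  for (i in seq_len(ns)) {
    mb <- sess_blocks(i, model_session)
    # full-session model reused for all mismatched-subject cells
    fit <- pool_fit(pools[[i]], mb, fb, fs)
    for (j in seq_len(ns)) {
      db <- sess_blocks(j, data_session)
      if (i == j && model_session == data_session) {
        folds <- lapply(db, function(b)
          new_plan("loo", setdiff(db, b), b))
        G[i, j] <- mean(run_plans(folds, pools[[i]], fb, fs)$accuracy)
      } else {
        G[i, j] <- mean(vapply(db, function(b)
          pool_block_accuracy(fit, pools[[j]], b), numeric(1)))
      }
    }
  }
  dimnames(G) <- list(model_subject = seq_len(ns), data_subject = seq_len(ns))
  G
}

#' Information transfer rate (Wolpaw)
#'
#' \deqn{ITR = (log2 N + P log2 P + (1-P) log2((1-P)/(N-1))) \cdot 60 / T}
#' in bits per minute, with the convention \eqn{0 \cdot log2(0) = 0} at
#' \eqn{P = 1}. By default values at or below chance (\eqn{P \le 1/N}) are
#' clamped to 0, matching how below-chance cells are conventionally
#' reported; pass \code{clamp = FALSE} for the raw formula value.
#'
#' @param P accuracy as a fraction in \code{[0, 1]} (vectorised).
#' @param N number of targets (>= 2).
#' @param T_s time per selection in seconds; default 3.1 (2.1 s gaze +
#'   1.0 s inter-trial pause).
#' @param clamp clamp at-or-below-chance values to zero.
#' @return ITR in bits/min.
#' @examples
#' round(itr(1), 2)      # 96.77
#' round(itr(0.75), 2)   # 57.10
#' @export
itr <- function(P, N = 32L, T_s = 3.1, clamp = TRUE) {
  if (any(is.na(P)) || any(P < 0) || any(P > 1))
    stop("P must be in [0, 1]")
  if (N < 2) stop("N must be >= 2")
  if (T_s <= 0) stop("T_s must be > 0")
  bits <- log2(N) +
    ifelse(P > 0, P * log2(P), 0) +
    ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
  out <- bits * 60 / T_s
  if (clamp) out[P <= 1 / N] <- 0
  out
}

#' Aggregate protocol cells into a report
#'
#' Averages the per-(subject, plan, test block) accuracies to one value per
#' subject and group, then summarises each group across subjects with the
#' mean and sample standard deviation — the layout of the study's summary
#' tables. ITR columns are computed from the per-subject accuracies.
#'
#' @param cells data.frame from [run_protocols()] (columns \code{subject},
#'   \code{group}, \code{accuracy} required).
#' @param N,T_s passed to [itr()].
#' @return object of class \code{"evaluation_report"}: list with
#'   \code{subject_cells} (subject x group accuracy %, plus ITR) and
#'   \code{summary} (per group: mean, sd, itr_mean, itr_sd, n).
#' @export
aggregate_report <- function(cells, N = 32L, T_s = 3.1) {
  need <- c("subject", "group", "accuracy")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  if (anyNA(cells$accuracy)) {
    bad <- cells[is.na(cells$accuracy), , drop = FALSE]
    stop("missing accuracy cells: ",
         paste(sprintf("(subject %s, %s)", bad$subject, bad$group),
               collapse = ", "))
  }
  per <- stats::aggregate(accuracy ~ subject + group, data = cells, FUN = mean)
  per$itr <- itr(per$accuracy / 100, N = N, T_s = T_s)
  summ <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1L],
               mean = mean(d$accuracy), sd = stats::sd(d$accuracy),
               itr_mean = mean(d$itr), itr_sd = stats::sd(d$itr),
               n = nrow(d))))
  rownames(summ) <- NULL
  structure(list(subject_cells = per, summary = summ,
                 N = N, T_s = T_s),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation report (", x$N, " targets, ", x$T_s,
      " s/selection)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s acc %6.2f%% (sd %5.2f)  ITR %6.2f bits/min (sd %5.2f)  n=%d\n",
                s$group[i], s$mean[i], s$sd[i], s$itr_mean[i], s$itr_sd[i],
                s$n[i]))
  invisible(x)
}
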