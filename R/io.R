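# ---- plain-text matrix persistence ----------------------------------------
# %.17g decimal round-trips IEEE doubles exactly, so text files are
# bit-exact under write/read while staying greppable.

write_matrix_txt <- function(x, path) {
  ms <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  writeLines(apply(ms, 1L, paste, collapse = " "), path)
}

read_matrix_txt <- function(path, nrow, ncol) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (length(v) != nrow * ncol)
    stop("matrix file ", path, " holds ", length(v),
         " values, expected ", nrow, " x ", ncol)
  matrix(v, nrow = nrow, ncol = ncol, byrow = TRUE)
}

write_json_file <- function(obj, path)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)

# ---- study container -------------------------------------------------------

#' Persist a study to a plain-text dataset container
#'
#' Layout: \code{dir/metadata.json} (study manifest) plus one directory per
#' subject-session holding \code{metadata.json} and one whitespace-separated
#' matrix file per block. Each block file stores the (target x channel x
#' sample) array as a (target*channel) x sample matrix, target-major, with
#' 17-significant-digit decimals so that [read_study()] reproduces the
#' arrays bit-exactly.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory; must not already contain a study unless
#'   \code{overwrite = TRUE}.
#' @param overwrite replace an existing container.
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir, overwrite = FALSE) {
  if (file.exists(file.path(dir, "metadata.json")) && !overwrite)
    stop("a study already exists at ", dir, " (use overwrite = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(dir, "metadata.json")))
  sess_meta <- list()
  for (subj in study$subjects) {
    for (tensor in subj$sessions) {
      sdir <- sprintf("sub-%02d_ses-%d", subj$subject_id, tensor$session_id)
      dir.create(file.path(dir, sdir), showWarnings = FALSE)
      files <- character()
      for (b in seq_along(tensor$block_ids)) {
        bid <- tensor$block_ids[b]
        fn <- sprintf("block_%02d.txt", bid)
        mat <- matrix(aperm(tensor$data[b, , , , drop = FALSE],
                            c(4L, 3L, 2L, 1L)),
                      nrow = tensor$n_samples)  # samples x (channel-major)
        write_matrix_txt(t(mat), file.path(dir, sdir, fn))
        files <- c(files, fn)
      }
      meta <- list(subject_id = subj$subject_id,
                   session_id = tensor$session_id,
                   block_ids = tensor$block_ids, files = files,
                   sampling_rate = tensor$fs, n_targets = tensor$n_targets,
                   n_channels = tensor$n_channels,
                   n_samples = tensor$n_samples)
      write_json_file(meta, file.path(dir, sdir, "metadata.json"))
      sess_meta[[length(sess_meta) + 1L]] <-
        list(subject_id = subj$subject_id, session_id = tensor$session_id,
             dir = sdir)
    }
  }
  manifest <- list(
    study = "synthetic-cvep", n_subjects = length(study$subjects),
    sampling_rate = study$config$fs %||% study$subjects[[1]]$sessions[[1]]$fs,
    seed = study$seed,
    code_set = jsonlite::fromJSON(code_set_to_json(study$code_set)),
    sessions = sess_meta)
  write_json_file(manifest, file.path(dir, "metadata.json"))
  ok <- TRUE
  invisible(dir)
}

#' Load a study from a dataset container
#'
#' Validates the manifest before returning: every referenced file must
#' exist, every block matrix must have the declared shape, and the trial
#' length must equal two stimulation cycles at the declared sampling rate
#' (\code{n_samples == 2 * cycle_duration * sampling_rate}).
#'
#' @param dir container directory written by [write_study()].
#' @return list of class \code{"cvep_study"} with \code{subjects} (each
#'   holding two [simulate_session()]-shaped trial tensors), \code{code_set}
#'   and \code{manifest}.
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "metadata.json")
  if (!file.exists(mf)) stop("no metadata.json in ", dir)
  manifest <- jsonlite::fromJSON(mf, simplifyDataFrame = FALSE)
  cs <- code_set_from_json(jsonlite::toJSON(manifest$code_set,
                                            auto_unbox = TRUE))
  subjects <- list()
  for (sm in manifest$sessions) {
    sdir <- file.path(dir, sm$dir)
    metaf <- file.path(sdir, "metadata.json")
    if (!file.exists(metaf)) stop("missing session metadata: ", metaf)
    meta <- jsonlite::fromJSON(metaf)
    expect_n <- 2 * cs$cycle_s * meta$sampling_rate
    if (abs(meta$n_samples - expect_n) > 1e-9)
      stop("session ", sm$dir, ": n_samples = ", meta$n_samples,
           " inconsistent with 2 cycles at ", meta$sampling_rate,
           " Hz (expected ", expect_n, ")")
    nb <- length(meta$block_ids)
    data <- array(0, c(nb, meta$n_targets, meta$n_channels, meta$n_samples))
    for (b in seq_len(nb)) {
      path <- file.path(sdir, meta$files[b])
      if (!file.exists(path))
        stop("missing block file (block id ", meta$block_ids[b], "): ", path)
      mat <- read_matrix_txt(path, meta$n_targets * meta$n_channels,
                             meta$n_samples)
      data[b, , , ] <- aperm(array(t(mat), c(meta$n_samples, meta$n_channels,
                                             meta$n_targets)),
                             c(3L, 2L, 1L))
      message("loaded block ", meta$block_ids[b], " of ", sm$dir)
    }
    tensor <- structure(
      list(data = data, fs = meta$sampling_rate,
           block_ids = as.integer(meta$block_ids),
           subject_id = meta$subject_id, session_id = meta$session_id,
           n_targets = meta$n_targets, n_channels = meta$n_channels,
           n_samples = meta$n_samples),
      class = "trial_tensor")
    sid <- as.character(meta$subject_id)
    if (is.null(subjects[[sid]]))
      subjects[[sid]] <- list(subject_id = meta$subject_id, sessions = list())
    subjects[[sid]]$sessions[[meta$session_id]] <- tensor
  }
  structure(list(subjects = unname(subjects), code_set = cs,
                 manifest = manifest, seed = manifest$seed,
                 config = list(fs = manifest$sampling_rate)),
            class = "cvep_study")
}

# ---- model persistence -----------------------------------------------------

#' Save / load a fitted model
#'
#' Stores the ensemble filter matrices and class templates of every
#' sub-band as plain-text matrices plus a JSON manifest, so models built
#' from one block composition can be reloaded and applied elsewhere.
#'
#' @param model a fitted [cvep_trca()] model.
#' @param dir output directory.
#' @return \code{dir} (or the reloaded model), invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "cvep_trca"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- length(model$classes)
  for (k in seq_len(model$fb$n_subbands)) {
    write_matrix_txt(model$filters[[k]],
                     file.path(dir, sprintf("filters_band%d.txt", k)))
    write_matrix_txt(matrix(model$templates[[k]], nrow = model$m * K),
                     file.path(dir, sprintf("templates_band%d.txt", k)))
  }
  write_json_file(list(classes = model$classes, m = model$m, n = model$n,
                       fs = model$fs, n_train = as.integer(model$n_train),
                       filterbank = jsonlite::fromJSON(
                         filterbank_to_json(model$fb))),
                  file.path(dir, "model.json"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  fb <- filterbank_spec(meta$filterbank$low_cutoffs,
                        meta$filterbank$high_cutoff,
                        meta$filterbank$order, meta$filterbank$weights)
  K <- length(meta$classes)
  filters <- templates <- proj <- vector("list", fb$n_subbands)
  for (k in seq_len(fb$n_subbands)) {
    filters[[k]] <- read_matrix_txt(
      file.path(dir, sprintf("filters_band%d.txt", k)), meta$m, K)
    templates[[k]] <- array(read_matrix_txt(
      file.path(dir, sprintf("templates_band%d.txt", k)),
      meta$m * K, meta$n), c(meta$m, meta$n, K))
    P <- matrix(0, meta$n * K, K)
    for (i in seq_len(K))
      P[, i] <- as.vector(crossprod(templates[[k]][, , i], filters[[k]]))
    proj[[k]] <- standardize_cols(P)
  }
  structure(list(classes = as.integer(meta$classes), m = meta$m, n = meta$n,
                 fb = fb, filters = filters, templates = templates,
                 proj = proj, n_train = meta$n_train, fs = meta$fs),
            class = "cvep_trca")
}

# ---- command-line interface ------------------------------------------------

cli_usage <- function() {
  cat("usage: cvep-tools [--seed N] [--config FILE] [--log-level L] <command> [options]\n",
      "commands:\n",
      "  codes show|validate                   print / check the code table\n",
      "  itr --p P [--n N] [--t T]             Wolpaw ITR in bits/min\n",
      "  simulate --subjects S --blocks B --seed N --out DIR\n",
      "  classify --model DIR --data DIR --out FILE\n",
      "  evaluate --protocol P --data DIR --out DIR\n",
      "           (P: cross-session | stepwise | variants | cross-subject)\n",
      "  report --cells FILE --out FILE        summarise an evaluation cells CSV\n",
      sep = "")
}

# read a config file (YAML or JSON) into a named list
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::yaml.load_file(path)
  else jsonlite::fromJSON(path)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    if (i == length(args)) stop("flag ", a, " needs a value")
    flags[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; see
#' \code{inst/cli/cvep-tools} for the executable wrapper. Prints results to
#' stdout and returns an exit status instead of quitting, so it is callable
#' from tests.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    # global flags may precede the subcommand
    global <- list(seed = NULL, config = NULL, log_level = "info")
    while (length(args) && args[1L] %in% c("--seed", "--config",
                                           "--log-level")) {
      if (length(args) < 2L) stop("flag ", args[1L], " needs a value")
      key <- gsub("-", "_", sub("^--", "", args[1L]))
      global[[key]] <- args[2L]
      args <- args[-(1:2)]
    }
    if (!is.null(global$seed)) set.seed(as.integer(global$seed))
    if (identical(global$log_level, "quiet"))
      options(cveptools.quiet = TRUE)
    if (!length(args)) { cli_usage(); return(invisible(1L)) }
    cmd <- args[1L]; rest <- args[-1L]
    switch(
      cmd,
      codes = {
        sub <- if (length(rest)) rest[1L] else "show"
        cs <- code_set()
        if (sub == "show") {
          print(cs)
          for (k in seq_along(cs$shifts))
            cat(sprintf("target %2d shift %2d  %s\n", k, cs$shifts[k],
                        paste(code_for_target(cs, k), collapse = "")))
        } else if (sub == "validate") {
          validate_code_set(cs)
          cat("code set valid: balanced, two-valued autocorrelation,",
              "distinct shifts\n")
        } else stop("unknown codes subcommand: ", sub)
        0L
      },
      itr = {
        fl <- parse_flags(rest)
        if (is.null(fl$p)) stop("itr requires --p")
        v <- itr(as.numeric(fl$p),
                 N = as.integer(fl$n %||% "32"),
                 T_s = as.numeric(fl$t %||% "3.1"))
        cat(sprintf("%.2f\n", v))
        0L
      },
      report = {
        fl <- parse_flags(rest)
        cells <- utils::read.csv(fl$cells %||% stop("report requires --cells"))
        rep <- aggregate_report(cells)
        out <- fl$out %||% stop("report requires --out")
        utils::write.csv(rep$summary, out, row.names = FALSE)
        print(rep)
        0L
      },
      simulate = {
        fl <- parse_flags(rest)
        over <- if (!is.null(global$config)) read_config(global$config)
                else list()
        over$blocks <- as.integer(fl$blocks %||% over$blocks %||% "6")
        cfg <- do.call(cvep_sim_config, over)
        study <- simulate_study(as.integer(fl$subjects %||% "1"),
                                config = cfg,
                                seed = as.integer(fl$seed %||% "1"))
        write_study(study, fl$out %||% stop("simulate requires --out"),
                    overwrite = TRUE)
        cat("wrote study to", fl$out, "\n")
        0L
      },
      classify = {
        fl <- parse_flags(rest)
        model <- load_model(fl$model %||% stop("classify requires --model"))
        study <- read_study(fl$data %||% stop("classify requires --data"))
        rows <- list()
        for (subj in study$subjects) for (tensor in subj$sessions)
          for (b in tensor$block_ids) {
            tr <- session_trials(tensor, b)
            pred <- predict(model, tr$trials, type = "class")
            rows[[length(rows) + 1L]] <- data.frame(
              subject = subj$subject_id, session = tensor$session_id,
              block = b, target = tr$labels, predicted = pred,
              correct = pred == tr$labels)
          }
        res <- do.call(rbind, rows)
        out <- fl$out %||% stop("classify requires --out")
        write_json_file(list(
          n_trials = nrow(res), accuracy = 100 * mean(res$correct),
          per_block = lapply(split(res, list(res$subject, res$session,
                                             res$block), drop = TRUE),
                             function(d) list(subject = d$subject[1],
                                              session = d$session[1],
                                              block = d$block[1],
                                              accuracy = 100 * mean(d$correct)))),
          out)
        utils::write.csv(res, sub("\\.json$", ".csv", out), row.names = FALSE)
        cat(sprintf("overall accuracy %.2f%% over %d trials\n",
                    100 * mean(res$correct), nrow(res)))
        0L
      },
      evaluate = {
        fl <- parse_flags(rest)
        study <- read_study(fl$data %||% stop("evaluate requires --data"))
        out <- fl$out %||% stop("evaluate requires --out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        proto <- fl$protocol %||% "cross-session"
        if (proto == "cross-subject") {
          for (ss in 1:2) {
            G <- cross_subject_grid(study, ss, ss)
            utils::write.csv(G, file.path(out,
              sprintf("cross_subject_s%d.csv", ss)))
          }
        } else {
          plans <- switch(proto,
            `cross-session` = cross_session_plans(),
            stepwise = {
              pl <- unlist(lapply(block_seq(), stepwise_plans),
                           recursive = FALSE)
              split(pl, sub("\\.test.*", "", vapply(pl, `[[`, "", "name")))
            },
            variants = variant_plans(),
            stop("unknown protocol: ", proto))
          cells <- run_protocols(study, plans)
          rep <- aggregate_report(cells)
          utils::write.csv(cells, file.path(out, "cells.csv"),
                           row.names = FALSE)
          utils::write.csv(rep$summary, file.path(out, "summary.csv"),
                           row.names = FALSE)
          print(rep)
        }
        0L
      },
      { cli_usage(); stop("unknown command: ", cmd) })
  }, error = function(e) {
    cat("error:", conditionMessage(e), "\n")
    1L
  })
  invisible(as.integer(status))
}
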