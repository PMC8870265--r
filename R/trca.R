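#' Fit a filter-bank ensemble template-matching classifier
#'
#' The central model of the package. For every sub-band of the filter bank
#' and every target class, the training trials are band-pass filtered,
#' averaged into a class template, and a CCA-derived spatial filter is
#' computed (the X-side canonical weight between the concatenated trials
#' and the tiled template, see [class_filter()]). The per-class filters are
#' concatenated column-wise into the ensemble filter matrix of that
#' sub-band, following the ensemble TRCA scheme: at test time a trial is
#' projected through the *full* ensemble matrix and correlated with each
#' class's projected template, and the per-sub-band Pearson correlations
#' are combined with the decaying weights of [subband_weights()].
#'
#' @param x training trials: a list of channels x samples matrices, or a
#'   3-d array with dimensions (trial, channel, sample).
#' @param labels integer class label (target index) per trial; every class
#'   in \code{1..n_classes} must be represented.
#' @param fs sampling rate in Hz.
#' @param fb a [filterbank_spec()].
#' @param n_classes number of target classes K (default
#'   \code{max(labels)}).
#' @return object of class \code{"cvep_trca"} with components
#'   \code{classes}, \code{filters} (per sub-band m x K ensemble matrices),
#'   \code{templates} (per sub-band m x n x K arrays), \code{rho}
#'   (training canonical correlations, sub-band x class), \code{fb},
#'   \code{fs}, \code{n_train} (trials per class).
#' @seealso [predict.cvep_trca()], [block_accuracy()]
#' @examples
#' cs <- code_set()
#' subj <- sample_subject(1)
#' sess <- simulate_session(subj, session_effect(seed = 1), cs,
#'                          blocks = 2, seed = 1)
#' tr <- session_trials(sess, blocks = 1)
#' fit <- cvep_trca(tr$trials, tr$labels, fs = sess$fs)
#' fit
#' @export
cvep_trca <- function(x, labels, fs, fb = filterbank_spec(),
                      n_classes = max(labels)) {
  trials <- as_trial_list(x)
  labels <- as.integer(labels)
  if (length(labels) != length(trials))
    stop("need one label per trial")
  classes <- seq_len(as.integer(n_classes))
  missing <- setdiff(classes, labels)
  if (length(missing))
    stop("no training trials for target(s): ", paste(missing, collapse = ", "))
  fit <- fit_fblocks(list(make_fblock(trials, labels, fb, fs)), classes, fb)
  fit$fs <- fs
  fit$call <- match.call()
  fit
}

# normalise trial containers to a list of channels x samples matrices
as_trial_list <- function(x) {
  if (is.list(x)) {
    lapply(x, function(tr) {
      tr <- as.matrix(tr)
      if (length(dim(tr)) != 2L) stop("each trial must be a matrix")
      tr
    })
  } else if (is.array(x) && length(dim(x)) == 3L) {
    lapply(seq_len(dim(x)[1L]), function(i) x[i, , , drop = TRUE])
  } else stop("x must be a list of matrices or a (trial, channel, sample) array")
}

# ---- internal filtered-block representation -------------------------------
# A "fblock" holds, per sub-band, the trials of one block stacked as a
# (n * ntrials) x m matrix (trial-major row blocks, channels centered
# after filtering) plus the per-trial channel covariances, so that model
# fitting and scoring reduce to a few large matrix products.

make_fblock <- function(trials, labels, fb, fs) {
  m <- nrow(trials[[1L]])
  n <- ncol(trials[[1L]])
  nt <- length(trials)
  for (tr in trials)
    if (!identical(dim(tr), c(m, n)))
      stop("all trials must share the same channels x samples shape")
  big <- matrix(unlist(lapply(trials, t), use.names = FALSE), nrow = n)
  bands <- vector("list", fb$n_subbands)
  covs <- vector("list", fb$n_subbands)
  for (k in seq_len(fb$n_subbands)) {
    f <- filt_cols(big, fb, k, fs)
    f <- f - rep(colMeans(f), each = n)
    S <- matrix(aperm(array(f, c(n, m, nt)), c(1L, 3L, 2L)), n * nt, m)
    cv <- array(0, c(m, m, nt))
    for (i in seq_len(nt))
      cv[, , i] <- crossprod(S[((i - 1L) * n + 1L):(i * n), , drop = FALSE]) / n
    bands[[k]] <- S
    covs[[k]] <- cv
  }
  list(bands = bands, covs = covs, labels = as.integer(labels),
       m = m, n = n, nt = nt)
}

# fit from a list of fblocks (training blocks)
fit_fblocks <- function(fblocks, classes, fb) {
  K <- length(classes)
  nsb <- fb$n_subbands
  m <- fblocks[[1L]]$m
  n <- fblocks[[1L]]$n
  labels <- unlist(lapply(fblocks, `[[`, "labels"), use.names = FALSE)
  n_train <- vapply(classes, function(i) sum(labels == i), integer(1))
  filters <- templates <- proj <- vector("list", nsb)
  rho <- matrix(NA_real_, nsb, K)
  for (k in seq_len(nsb)) {
    W <- matrix(0, m, K)
    Tstack <- matrix(0, n * K, m)   # class-major stacked t(template)
    for (i in seq_len(K)) {
      acc <- matrix(0, n, m)
      Cxx <- matrix(0, m, m)
      for (fbk in fblocks) {
        for (j in which(fbk$labels == classes[i])) {
          rows <- ((j - 1L) * n + 1L):(j * n)
          acc <- acc + fbk$bands[[k]][rows, , drop = FALSE]
          Cxx <- Cxx + fbk$covs[[k]][, , j]
        }
      }
      tt <- acc / n_train[i]            # n x m, t(template)
      Cxx <- Cxx / n_train[i]
      Cyy <- crossprod(tt) / n
      # covariance form of the concatenated-trials vs tiled-template CCA:
      # with channel-centered trials, Cxy and Cyy coincide with the
      # template auto-covariance and Cxx is the mean per-trial covariance
      cc <- solve_cca_cov(Cxx, Cyy, Cyy)
      W[, i] <- cc$wx
      rho[k, i] <- cc$rho
      Tstack[((i - 1L) * n + 1L):(i * n), ] <- tt
    }
    filters[[k]] <- W
    templates[[k]] <- array(t(Tstack), c(m, n, K))
    proj[[k]] <- standardize_cols(stacked_projection(Tstack, W, n, K))
  }
  structure(
    list(classes = classes, m = m, n = n, fb = fb,
         filters = filters, templates = templates, proj = proj,
         rho = rho, n_train = n_train),
    class = "cvep_trca")
}

# project trial-major stacked rows through the ensemble matrix and return
# one vectorised (n*K)-projection per trial as columns
stacked_projection <- function(S, W, n, nt) {
  P <- S %*% W                             # (n*nt) x K
  matrix(aperm(array(P, c(n, nt, ncol(W))), c(1L, 3L, 2L)),
         n * ncol(W), nt)
}

standardize_cols <- function(P) {
  P <- P - rep(colMeans(P), each = nrow(P))
  nrm <- sqrt(colSums(P^2))
  nrm[nrm < 1e-300] <- 1
  P / rep(nrm, each = nrow(P))
}

# scores for one fblock; rows = trials, cols = classes. The stored
# projected templates are centered with unit norm, so the Pearson
# correlation with a test projection v reduces to (v . t) / ||v - mean v||:
# centering v is unnecessary because t sums to zero.
score_fblock <- function(fbk, object) {
  K <- length(object$classes)
  scores <- matrix(0, fbk$nt, K)
  for (k in seq_len(object$fb$n_subbands)) {
    V <- stacked_projection(fbk$bands[[k]], object$filters[[k]],
                            fbk$n, fbk$nt)
    nv <- sqrt(pmax(.colSums(V * V, nrow(V), ncol(V)) -
                      nrow(V) * colMeans(V)^2, 1e-300))
    scores <- scores + object$fb$weights[k] *
      (crossprod(V, object$proj[[k]]) / nv)
  }
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify trials with a fitted ensemble model
#'
#' Each trial is decomposed into the model's sub-bands, projected through
#' the per-sub-band ensemble filter matrix, and correlated (Pearson, over
#' the flattened projection) with every class's projected template. The
#' class score is the weight-combined correlation across sub-bands; the
#' predicted class is the arg-max, ties broken toward the lowest class
#' index.
#'
#' @param object a fitted [cvep_trca()] model.
#' @param newdata a single channels x samples matrix, a list of such
#'   matrices, or a (trial, channel, sample) array.
#' @param type \code{"class"} for predicted target indices,
#'   \code{"scores"} for the trials x classes score matrix.
#' @param ... unused.
#' @return integer vector of predicted classes, or a numeric score matrix.
#' @export
predict.cvep_trca <- function(object, newdata,
                              type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  trials <- as_trial_list(newdata)
  for (tr in trials)
    if (!identical(dim(tr), c(object$m, object$n)))
      stop("trial shape ", paste(dim(tr), collapse = "x"),
           " does not match the model's ", object$m, "x", object$n)
  fbk <- make_fblock(trials, rep(NA_integer_, length(trials)),
                     object$fb, object$fs)
  scores <- score_fblock(fbk, object)
  if (type == "scores") scores else max.col(scores, ties.method = "first")
}

#' Score one trial against all class templates
#'
#' Convenience wrapper around [predict.cvep_trca()] returning the decision
#' for a single trial.
#'
#' @param trial channels x samples matrix.
#' @param model fitted [cvep_trca()] model.
#' @param true_class optional true target index, carried through.
#' @return list with \code{scores} (one per class), \code{predicted_class},
#'   \code{true_class}.
#' @export
score_trial <- function(trial, model, true_class = NULL) {
  sc <- drop(predict(model, trial, type = "scores"))
  list(scores = sc,
       predicted_class = which.max(sc),
       true_class = true_class)
}

#' Accuracy of one recording block
#'
#' A block is one pass through all targets: exactly one labelled trial per
#' target class. Returns the fraction of trials whose predicted class
#' matches the label.
#'
#' @param trials list of channels x samples matrices (or 3-d array).
#' @param labels true target index per trial; must cover every model class
#'   exactly once.
#' @param model fitted [cvep_trca()] model.
#' @return accuracy as a fraction in \code{[0, 1]}.
#' @export
block_accuracy <- function(trials, labels, model) {
  labels <- as.integer(labels)
  if (!setequal(labels, model$classes) ||
      length(labels) != length(model$classes))
    stop("a block must contain exactly one trial per target; got targets: ",
         paste(sort(labels), collapse = ", "))
  pred <- predict(model, trials, type = "class")
  mean(pred == labels)
}

#' @export
print.cvep_trca <- function(x, ...) {
  cat("cVEP filter-bank ensemble template-matching model\n")
  cat("  classes:", length(x$classes),
      " channels:", x$m, " samples/trial:", x$n,
      " fs:", x$fs, "Hz\n")
  cat("  sub-bands:", x$fb$n_subbands,
      sprintf("(%g-%g Hz ... %g-%g Hz)", x$fb$low_cutoffs[1L],
              x$fb$high_cutoff, x$fb$low_cutoffs[x$fb$n_subbands],
              x$fb$high_cutoff), "\n")
  cat("  training trials per class:",
      paste(range(x$n_train), collapse = "-"), "\n")
  invisible(x)
}

#' @export
summary.cvep_trca <- function(object, ...) {
  structure(list(model = object), class = "summary.cvep_trca")
}

#' @export
print.summary.cvep_trca <- function(x, ...) {
  print(x$model)
  fb <- x$model$fb
  cat("sub-band weights:", paste(sprintf("%.3f", fb$weights), collapse = " "),
      "\n")
  if (!all(is.na(x$model$rho)))
    cat("training canonical correlations (per band, mean over classes):",
        paste(sprintf("%.3f", rowMeans(x$model$rho)), collapse = " "), "\n")
  for (k in seq_len(fb$n_subbands)) {
    W <- x$model$filters[[k]]
    cat(sprintf("  band %d (%g-%g Hz): ensemble %d x %d, |w| range %.3g-%.3g\n",
                k, fb$low_cutoffs[k], fb$high_cutoff, nrow(W), ncol(W),
                min(abs(W)), max(abs(W))))
  }
  invisible(x)
}

#' Extract ensemble spatial filters
#'
#' @param object fitted [cvep_trca()] model.
#' @param ... unused.
#' @return list over sub-bands of m x K ensemble filter matrices (column i
#'   is the spatial filter of class i).
#' @export
coef.cvep_trca <- function(object, ...) object$filters

#' Plot class templates of a fitted model
#'
#' Draws the spatially filtered template (template projected through its
#' own class filter) for one or more classes in one sub-band.
#'
#' @param x fitted [cvep_trca()] model.
#' @param classes class indices to draw (default first class).
#' @param subband sub-band index (default 1).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cvep_trca <- function(x, classes = 1L, subband = 1L, ...) {
  W <- x$filters[[subband]]
  tt <- seq_len(x$n) / x$fs
  Y <- sapply(classes, function(i)
    drop(crossprod(x$templates[[subband]][, , i], W[, i])))
  graphics::matplot(tt, Y, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "filtered template",
                    main = sprintf("sub-band %d (%g-%g Hz)", subband,
                                   x$fb$low_cutoffs[subband],
                                   x$fb$high_cutoff), ...)
  invisible(x)
}
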