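#' First canonical correlation of two multi-channel signals
#'
#' Finds weight vectors \code{wx}, \code{wy} maximising the Pearson
#' correlation between the projections \code{t(X) \%*\% wx} and
#' \code{t(Y) \%*\% wy}. Solved as the generalised eigenproblem of the
#' covariance matrices, with a small ridge term on both auto-covariances
#' (\code{lambda = 1e-8 * trace / m}) so that near-singular covariances of
#' short concatenated trials remain solvable. Rows are mean-centered
#' internally; the weights are scaled so both canonical variates have unit
#' variance, and the sign is fixed by making the largest-magnitude entry of
#' \code{wx} positive (with \code{wy} flipped along with it so the
#' correlation stays non-negative).
#'
#' @param X numeric matrix, m1 variables x n observations.
#' @param Y numeric matrix, m2 variables x n observations.
#' @return list of class \code{"cca_result"}: \code{wx} (length m1),
#'   \code{wy} (length m2), \code{rho} (first canonical correlation, in
#'   \code{[0, 1]}).
#' @export
solve_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must have the same number of observations")
  if (n <= max(nrow(X), nrow(Y)))
    stop("need more observations than variables (n = ", n, ")")
  X <- X - rowMeans(X)
  Y <- Y - rowMeans(Y)
  if (all(abs(X) < 1e-300) || all(abs(Y) < 1e-300))
    stop("degenerate all-constant input")
  solve_cca_cov(tcrossprod(X) / n, tcrossprod(Y) / n, tcrossprod(X, Y) / n)
}

# CCA from (already centered) covariance matrices; the whitened symmetric
# formulation K = Cxx^(-1/2) Cxy Cyy^(-1/2), whose largest singular value
# is the first canonical correlation
solve_cca_cov <- function(Cxx, Cyy, Cxy) {
  # equilibrate to unit variances first: CCA is invariant to per-variable
  # rescaling and this keeps the ridge exactly scale-free
  dx <- sqrt(diag(Cxx)); dx[dx < 1e-150] <- 1
  dy <- sqrt(diag(Cyy)); dy[dy < 1e-150] <- 1
  Cxx0 <- Cxx; Cyy0 <- Cyy; Cxy0 <- Cxy
  Cxx <- Cxx / tcrossprod(dx)
  Cyy <- Cyy / tcrossprod(dy)
  Cxy <- Cxy / tcrossprod(dx, dy)
  ridge <- function(C) C + diag(1e-8 * sum(diag(C)) / nrow(C), nrow(C))
  Cxx <- ridge(Cxx); Cyy <- ridge(Cyy)
  isq <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    d <- pmax(e$values, max(e$values) * 1e-12)
    e$vectors %*% (t(e$vectors) / sqrt(d))
  }
  Wx <- isq(Cxx); Wy <- isq(Cyy)
  K <- Wx %*% Cxy %*% Wy
  sv <- svd(K, nu = 1L, nv = 1L)
  rho <- min(max(sv$d[1L], 0), 1)
  wx <- drop(Wx %*% sv$u) / dx
  wy <- drop(Wy %*% sv$v) / dy
  # unit-variance variates (w.r.t. the original, unequilibrated scales)
  wx <- wx / sqrt(max(drop(crossprod(wx, Cxx0 %*% wx)), 1e-300))
  wy <- wy / sqrt(max(drop(crossprod(wy, Cyy0 %*% wy)), 1e-300))
  if (drop(crossprod(wx, Cxy0 %*% wy)) < 0) wy <- -wy
  if (wx[which.max(abs(wx))] < 0) { wx <- -wx; wy <- -wy }
  structure(list(wx = wx, wy = wy, rho = rho), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("CCA: rho =", format(x$rho), " (", length(x$wx), "x", length(x$wy),
      "weights )\n")
  invisible(x)
}

#' Spatial filter and template for one target class
#'
#' The class template is the average of the training trials; the spatial
#' filter is the X-side canonical weight of the CCA between the
#' horizontally concatenated trials \code{[T1 T2 ... Tnb]} and the template
#' tiled the same number of times. Projecting trials through this filter
#' maximises their correlation with the projected template.
#'
#' @param trials list of numeric matrices, each channels x samples, all of
#'   identical shape (the training trials of one class).
#' @return list with \code{filter} (length-m weight vector) and
#'   \code{template} (channels x samples average trial).
#' @export
class_filter <- function(trials) {
  if (!length(trials)) stop("at least one training trial is required")
  dims <- dim(trials[[1L]])
  if (is.null(dims) || length(dims) != 2L)
    stop("trials must be channels x samples matrices")
  for (tr in trials)
    if (!identical(dim(tr), dims))
      stop("all trials must share the same channels x samples shape")
  template <- Reduce(`+`, trials) / length(trials)
  That <- do.call(cbind, trials)
  Xi <- do.call(cbind, rep(list(template), length(trials)))
  fit <- solve_cca(That, Xi)
  structure(list(filter = fit$wx, template = template), rho = fit$rho)
}
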