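#' Sub-band weights for filter-bank analysis
#'
#' Weight of the k-th sub-band before normalisation is
#' \code{k^(-1.25) + 0.25}; weights are then normalised to sum to one.
#' Lower sub-bands, which carry most VEP energy, receive the larger weights
#' and the weights decay monotonically with the sub-band index.
#'
#' @param n_subbands number of sub-bands K (>= 1).
#' @return numeric vector of K non-negative weights summing to 1.
#' @examples
#' round(subband_weights(5), 3)  # 0.386 0.207 0.156 0.132 0.119
#' @export
subband_weights <- function(n_subbands) {
  n_subbands <- as.integer(n_subbands)
  if (length(n_subbands) != 1L || is.na(n_subbands) || n_subbands < 1L)
    stop("n_subbands must be a single integer >= 1")
  k <- seq_len(n_subbands)
  alpha <- k^(-1.25) + 0.25
  alpha / sum(alpha)
}

#' Filter-bank specification
#'
#' Describes the band-pass decomposition applied to every trial and
#' template before correlation: K sub-bands sharing one upper edge, with
#' staggered lower edges, each realised as a zero-phase (forward-reverse)
#' Butterworth band-pass.
#'
#' @param low_cutoffs lower band edges in Hz, strictly increasing
#'   (default \code{c(6, 14, 22, 30, 38)}).
#' @param high_cutoff shared upper band edge in Hz (default 60).
#' @param order Butterworth order of the single-pass prototype (default 4;
#'   the effective zero-phase magnitude response is its square).
#' @param weights sub-band combination weights; default
#'   \code{subband_weights(length(low_cutoffs))}.
#' @return object of class \code{"filterbank_spec"}.
#' @export
filterbank_spec <- function(low_cutoffs = c(6, 14, 22, 30, 38),
                            high_cutoff = 60, order = 4,
                            weights = subband_weights(length(low_cutoffs))) {
  if (any(diff(low_cutoffs) <= 0))
    stop("low_cutoffs must be strictly increasing")
  if (any(low_cutoffs >= high_cutoff))
    stop("all low_cutoffs must lie below high_cutoff")
  if (length(weights) != length(low_cutoffs))
    stop("one weight per sub-band required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  structure(
    list(n_subbands = length(low_cutoffs), low_cutoffs = low_cutoffs,
         high_cutoff = high_cutoff, order = order, weights = weights),
    class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat("filter bank:", x$n_subbands, "sub-bands, Butterworth order", x$order,
      "(zero-phase)\n")
  cat(sprintf("  band %d: %g-%g Hz  weight %.3f\n", seq_len(x$n_subbands),
              x$low_cutoffs, x$high_cutoff, x$weights), sep = "")
  invisible(x)
}

#' @rdname filterbank_spec
#' @param spec a \code{filterbank_spec}.
#' @param path optional file to write to.
#' @export
filterbank_to_json <- function(spec, path = NULL) {
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname filterbank_spec
#' @param json JSON string or path from [filterbank_to_json()].
#' @export
filterbank_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  filterbank_spec(o$low_cutoffs, o$high_cutoff, o$order, o$weights)
}

# Design (and cache) the single-pass Butterworth coefficients for one
# sub-band; rejects bands outside Nyquist and unstable designs.
subband_coefs <- function(spec, k, fs) {
  if (k < 1L || k > spec$n_subbands) stop("sub-band index out of range")
  lo <- spec$low_cutoffs[k]; hi <- spec$high_cutoff
  if (hi >= fs / 2)
    stop("band ", lo, "-", hi, " Hz exceeds the Nyquist frequency ",
         fs / 2, " Hz")
  key <- sprintf("%g|%g|%d|%g", lo, hi, spec$order, fs)
  hit <- .coef_cache[[key]]
  if (!is.null(hit)) return(hit)
  bf <- signal::butter(spec$order, c(lo, hi) / (fs / 2), type = "pass")
  r <- max(Mod(polyroot(rev(bf$a))))
  if (r >= 1)
    stop("unstable band-pass design for ", lo, "-", hi, " Hz at fs = ", fs)
  # pad until the slowest pole's transient decays below ~1e-12
  val <- list(b = bf$b / bf$a[1], a = bf$a / bf$a[1],
              npad = min(4000L, as.integer(ceiling(log(1e-12) / log(r)))))
  .coef_cache[[key]] <- val
  val
}
.coef_cache <- new.env(parent = emptyenv())

#' Zero-phase sub-band filtering of a trial
#'
#' Band-pass filters each channel of a trial between the k-th lower cutoff
#' and the shared upper cutoff, forward and reverse so that the net phase
#' response is zero and the magnitude response is the square of the
#' single-pass Butterworth response. Edges are handled by reflect-padding
#' several settling lengths of signal at both ends and trimming after
#' filtering, so the output length equals the input length.
#'
#' @param trial numeric matrix, channels x samples (a vector is treated as
#'   one channel).
#' @param spec a [filterbank_spec()].
#' @param k sub-band index in \code{1..spec$n_subbands}.
#' @param fs sampling rate in Hz; must exceed twice the upper cutoff.
#' @return filtered matrix of the same dimensions (or vector for vector
#'   input).
#' @export
apply_subband <- function(trial, spec, k, fs) {
  vec <- is.null(dim(trial))
  x <- if (vec) matrix(as.numeric(trial), ncol = 1L) else t(trial)
  cf <- subband_coefs(spec, k, fs)
  y <- .filtfilt_cols(cf$b, cf$a, x, cf$npad)
  if (vec) drop(y) else t(y)
}

# Filter a samples x signals matrix (columns are independent signals) in
# one C++ pass; internal fast path used by the fitting and protocol code.
filt_cols <- function(x, spec, k, fs) {
  cf <- subband_coefs(spec, k, fs)
  .filtfilt_cols(cf$b, cf$a, x, cf$npad)
}
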