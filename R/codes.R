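#' The 63-bit maximal-length stimulus sequence
#'
#' The binary m-sequence used to drive all 32 flicker targets. Targets are
#' distinguished by circular phase shifts of this one code, so its two-valued
#' cyclic autocorrelation (63 at lag 0, -1 at every other lag in +/-1
#' encoding) is what makes the template-matching classifier work.
#'
#' @format Integer vector of 63 zeros and ones (32 ones, 31 zeros).
#' @export
cvep_mseq63 <- function() {
  bits <- strsplit(
    "101011001101110110100100111000101111001010001100001000001111110",
    "")[[1]]
  as.integer(bits)
}

#' Construct a stimulus code set
#'
#' Builds the per-target code table: one base m-sequence plus one circular
#' bit shift per target. Target \code{k} uses shift \code{((k - 1) * 2) mod L}
#' so that target 1 carries the unshifted code and targets are spaced
#' uniformly two bits apart. Setting \code{literal_shifts = TRUE} instead
#' assigns shift \code{(k * 2) mod L} to targets \code{k >= 2} (target 1
#' always keeps shift 0), an alternative convention in which the base code
#' sits off the two-bit spacing grid.
#'
#' @param base_code integer/numeric vector of 0/1 symbols; default the
#'   63-bit sequence from [cvep_mseq63()].
#' @param n_targets number of targets (default 32). Must not exceed the
#'   number of distinct circular shifts available.
#' @param bit_rate stimulus update rate in Hz (default 60).
#' @param literal_shifts use the \code{k * 2} shift convention (see above).
#' @return An object of class \code{"code_set"}: list with \code{base_code},
#'   \code{shifts} (one per target, target 1 first), \code{bit_rate} and
#'   \code{cycle_s} (code length / bit rate).
#' @export
code_set <- function(base_code = cvep_mseq63(), n_targets = 32L,
                     bit_rate = 60, literal_shifts = FALSE) {
  base_code <- as.integer(base_code)
  if (anyNA(base_code) || !all(base_code %in% c(0L, 1L)))
    stop("base_code must contain only binary symbols 0/1")
  L <- length(base_code)
  if (L < 2L) stop("base_code is too short (length ", L, ")")
  n_targets <- as.integer(n_targets)
  shifts <- if (literal_shifts) {
    c(0L, (seq_len(n_targets)[-1L] * 2L) %% L)
  } else {
    ((seq_len(n_targets) - 1L) * 2L) %% L
  }
  if (anyDuplicated(shifts))
    stop("n_targets = ", n_targets, " exceeds the distinct-shift capacity ",
         "of a length-", L, " code at 2-bit spacing")
  structure(
    list(base_code = base_code, shifts = shifts,
         bit_rate = bit_rate, cycle_s = L / bit_rate),
    class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("cVEP code set: ", length(x$base_code), "-bit code, ",
      length(x$shifts), " targets, ", x$bit_rate, " Hz update, cycle ",
      format(x$cycle_s), " s\n", sep = "")
  cat("base code:", paste(x$base_code, collapse = ""), "\n")
  cat("shifts:", paste(x$shifts, collapse = " "), "\n")
  invisible(x)
}

circ_rotate_left <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) v else v[c((s + 1L):n, 1L:s)]
}

#' Code for one target
#'
#' Circular left rotation of the base code by the target's shift ("left"
#' moves symbols toward index 1; codes are stored first-symbol-first as
#' displayed).
#'
#' @param cs a [code_set()].
#' @param k target index, 1-based.
#' @return integer 0/1 vector of the same length as the base code.
#' @export
code_for_target <- function(cs, k) {
  stopifnot(inherits(cs, "code_set"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(cs$shifts))
    stop("target index k must be in 1..", length(cs$shifts))
  circ_rotate_left(cs$base_code, cs$shifts[[k]])
}

#' Expand a target code to the sample domain
#'
#' Replicates each bit \code{sampling_rate / bit_rate} times and tiles the
#' cycle \code{n_cycles} times, giving the bit trace seen by an EEG channel
#' sampled at \code{sampling_rate}. No resampling is performed: the sampling
#' rate must be an integer multiple of the bit update rate.
#'
#' @param cs a [code_set()].
#' @param k target index.
#' @param sampling_rate EEG sampling rate in Hz (e.g. 600).
#' @param n_cycles number of stimulation cycles (default 2, the trial length).
#' @return numeric 0/1 vector of length
#'   \code{length(base_code) * sampling_rate / bit_rate * n_cycles}.
#' @export
expand_to_samples <- function(cs, k, sampling_rate, n_cycles = 2L) {
  stopifnot(inherits(cs, "code_set"))
  spb <- sampling_rate / cs$bit_rate
  if (abs(spb - round(spb)) > 1e-9)
    stop("sampling_rate (", sampling_rate, " Hz) must be divisible by the ",
         "bit update rate (", cs$bit_rate, " Hz); no resampling is performed")
  code <- code_for_target(cs, k)
  as.numeric(rep.int(rep(code, each = as.integer(round(spb))), n_cycles))
}

#' Cyclic autocorrelation of a binary code
#'
#' Autocorrelation of the +/-1 encoded code at all cyclic lags. For a
#' maximal-length sequence this is two-valued: the code length at lag 0 and
#' -1 everywhere else.
#'
#' @param code 0/1 vector.
#' @return numeric vector of length \code{length(code)}, lags 0..L-1.
#' @export
code_autocorrelation <- function(code) {
  s <- 2 * as.numeric(code) - 1
  vapply(seq_along(s) - 1L, function(l) sum(s * circ_rotate_left(s, l)),
         numeric(1))
}

#' Validate code-set invariants
#'
#' Checks m-sequence balance (ones exceed zeros by exactly one), the
#' two-valued cyclic autocorrelation, and pairwise distinctness of all
#' target codes. Errors on the first violated invariant.
#'
#' @param cs a [code_set()].
#' @return \code{cs}, invisibly.
#' @export
validate_code_set <- function(cs) {
  stopifnot(inherits(cs, "code_set"))
  L <- length(cs$base_code)
  ones <- sum(cs$base_code)
  if (ones != (L + 1L) %/% 2L)
    stop("code is not balanced: ", ones, " ones in length ", L)
  ac <- code_autocorrelation(cs$base_code)
  if (ac[1L] != L || any(ac[-1L] != -1))
    stop("cyclic autocorrelation is not two-valued (L at lag 0, -1 elsewhere)")
  codes <- vapply(seq_along(cs$shifts),
                  function(k) paste(code_for_target(cs, k), collapse = ""),
                  character(1))
  if (anyDuplicated(codes)) stop("target codes are not pairwise distinct")
  invisible(cs)
}

#' Generate a maximal-length sequence with an LFSR
#'
#' Runs a Fibonacci linear-feedback shift register over GF(2). The default
#' taps (6, 5) come from the primitive polynomial x^6 + x^5 + 1 and yield a
#' 63-bit m-sequence; any primitive polynomial of degree r gives a sequence
#' of length 2^r - 1 with m-sequence balance and two-valued autocorrelation.
#'
#' @param degree register length r (sequence length 2^r - 1).
#' @param taps feedback tap positions (1-based, counted from the output end).
#' @param init initial register state, a 0/1 vector of length \code{degree};
#'   must not be all-zero.
#' @return integer 0/1 vector of length \code{2^degree - 1}.
#' @export
lfsr_msequence <- function(degree = 6L, taps = c(6L, 5L),
                           init = rep(1L, degree)) {
  degree <- as.integer(degree)
  stopifnot(degree >= 2L, all(taps >= 1L), all(taps <= degree))
  reg <- as.integer(init)
  if (length(reg) != degree || !all(reg %in% c(0L, 1L)) || !any(reg == 1L))
    stop("init must be a non-zero binary state of length ", degree)
  n <- 2L^degree - 1L
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- reg[degree]
    fb <- sum(reg[taps]) %% 2L
    reg <- c(fb, reg[-degree])
  }
  out
}

#' Serialize / deserialize a code set as JSON
#'
#' @param cs a [code_set()].
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly if written to \code{path}).
#' @export
code_set_to_json <- function(cs, path = NULL) {
  stopifnot(inherits(cs, "code_set"))
  obj <- list(base_code = paste(cs$base_code, collapse = ""),
              shifts = cs$shifts, bit_update_rate = cs$bit_rate,
              cycle_duration = cs$cycle_s)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname code_set_to_json
#' @param json JSON string or file path produced by [code_set_to_json()].
#' @export
code_set_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cs <- code_set(base_code = as.integer(strsplit(obj$base_code, "")[[1]]),
                 n_targets = length(obj$shifts),
                 bit_rate = obj$bit_update_rate)
  if (!identical(cs$shifts, as.integer(obj$shifts)))
    cs$shifts <- as.integer(obj$shifts)
  cs
}
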