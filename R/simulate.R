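# run expr under a given RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# deterministic sub-seed derivation; stays below 2^31 - 1
seed_child <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(i) * 1299709) %% 2147483647)
}

#' Default configuration of the synthetic study generator
#'
#' One place for every tunable of the generator. The defaults emulate the
#' recording protocol the analysis was designed for: 16 channels sampled at
#' 600 Hz, 32 targets, 6 blocks per session, two sessions per subject,
#' trials of two 1.05 s stimulation cycles (1260 samples). \code{snr_scale}
#' is the ratio of evoked to noise power; its default is a calibration
#' constant chosen once so that single-session leave-one-block-out
#' accuracy of the default pipeline lands in the mid-90s percent range
#' typical of trained cVEP users.
#'
#' @param ... named overrides of any default.
#' @return named list of generator parameters.
#' @export
cvep_sim_config <- function(...) {
  cfg <- list(
    fs = 600, n_channels = 16L, n_targets = 32L, blocks = 6L,
    n_cycles = 2L,
    kernel_dur = 0.25,          # s, evoked impulse-response length
    peak_lat_range = c(0.09, 0.15),  # s, uniform subject peak latency
    amp_sdlog = 0.3,            # log-normal subject response amplitude
    snr_scale = 0.25,           # evoked/noise power ratio (calibrated)
    latency_jitter_sd = 0.003,  # s, per-trial latency jitter
    common_mode = 0.1,          # shared-noise amplitude fraction
    white_frac = 0.2,           # white fraction of noise power (rest pink)
    mix_peak_channel = 14,      # occipital concentration of the mixing
    mix_width = 2.5,            # channels, spatial spread
    mix_sdlog = 0.3,            # per-channel log-normal mixing jitter
    # session-effect defaults
    amp_gain_sdlog = 0.1,       # log-normal session amplitude gain
    latency_shift_sd = 0.005,   # s, session latency shift
    kernel_perturbation_sd = 0.15,  # relative session kernel noise
    noise_gain = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Draw a synthetic subject model
#'
#' A subject is an evoked impulse response (difference-of-gamma kernel with
#' a subject-specific peak latency and log-normal amplitude), a spatial
#' mixing vector over the channels (occipitally concentrated, unit
#' Euclidean norm), a signal-to-noise scale, and a per-trial latency jitter
#' SD. Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param config generator configuration from [cvep_sim_config()].
#' @return object of class \code{"subject_model"}.
#' @export
sample_subject <- function(seed, config = cvep_sim_config()) {
  if (!is.numeric(config$snr_scale) || config$snr_scale <= 0)
    stop("snr_scale must be > 0")
  with_seed(seed, {
    L <- round(config$kernel_dur * config$fs)
    lat <- stats::runif(1, config$peak_lat_range[1], config$peak_lat_range[2])
    amp <- stats::rlnorm(1, 0, config$amp_sdlog)
    tt <- (seq_len(L) - 1) / config$fs
    # positive lobe peaking at lat, slower negative lobe after it
    g1 <- stats::dgamma(tt, shape = 5, scale = lat / 4)
    g2 <- stats::dgamma(tt, shape = 7, scale = 1.6 * lat / 6)
    kern <- g1 / max(g1) - 0.45 * g2 / max(g2)
    kern <- amp * kern / sqrt(sum(kern^2))
    ch <- seq_len(config$n_channels)
    mix <- exp(-((ch - config$mix_peak_channel) / config$mix_width)^2) + 0.05
    mix <- mix * stats::rlnorm(config$n_channels, 0, config$mix_sdlog)
    mix <- mix / sqrt(sum(mix^2))
    structure(
      list(subject_id = seed, impulse_response = kern, mixing_vector = mix,
           snr_scale = config$snr_scale,
           latency_jitter_sd = config$latency_jitter_sd,
           peak_latency = lat, amplitude = amp, fs = config$fs),
      class = "subject_model")
  })
}

#' @export
print.subject_model <- function(x, ...) {
  cat("synthetic subject", x$subject_id, ": peak latency",
      sprintf("%.0f ms,", 1000 * x$peak_latency), "amplitude",
      sprintf("%.2f,", x$amplitude), "SNR scale", x$snr_scale, "\n")
  invisible(x)
}

#' Draw a session effect
#'
#' Session-to-session non-stationarity applied identically to all blocks of
#' one session: a multiplicative amplitude gain, a latency shift, a relative
#' perturbation of the evoked kernel, and a noise gain. These are what make
#' a model trained on one day degrade on another day's data.
#'
#' @param seed integer seed (ignored for fields given explicitly).
#' @param amplitude_gain,latency_shift,kernel_perturbation_sd,noise_gain
#'   explicit values overriding the seeded draws / defaults.
#' @param config generator configuration.
#' @return object of class \code{"session_effect"}.
#' @export
session_effect <- function(seed, amplitude_gain = NULL, latency_shift = NULL,
                           kernel_perturbation_sd = NULL, noise_gain = NULL,
                           config = cvep_sim_config()) {
  drawn <- with_seed(seed, list(
    amplitude_gain = stats::rlnorm(1, 0, config$amp_gain_sdlog),
    latency_shift = stats::rnorm(1, 0, config$latency_shift_sd)))
  eff <- list(
    amplitude_gain = amplitude_gain %||% drawn$amplitude_gain,
    latency_shift = latency_shift %||% drawn$latency_shift,
    kernel_perturbation_sd =
      kernel_perturbation_sd %||% config$kernel_perturbation_sd,
    noise_gain = noise_gain %||% config$noise_gain,
    seed = seed)
  if (eff$amplitude_gain <= 0) stop("amplitude_gain must be > 0")
  structure(eff, class = "session_effect")
}

#' An identity session effect (no drift, default noise)
#' @param noise_gain noise gain, default 1; set 0 for noiseless data.
#' @export
null_session_effect <- function(noise_gain = 1) {
  structure(list(amplitude_gain = 1, latency_shift = 0,
                 kernel_perturbation_sd = 0, noise_gain = noise_gain,
                 seed = NA_integer_),
            class = "session_effect")
}

# 1/f-amplitude ("pink") noise, columns independent, unit RMS per column
pink_noise <- function(n, m) {
  z <- matrix(stats::rnorm(n * m), n, m)
  Z <- stats::mvfft(z)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  f <- pmin(f, n - f + 1)            # symmetric profile for real output
  Z <- Z / sqrt(f)
  Z[1, ] <- 0
  p <- Re(stats::mvfft(Z, inverse = TRUE)) / n
  sweep(p, 2, sqrt(colMeans(p^2)), "/")
}

# periodic evoked waveform of one stimulation cycle: circular convolution
# of the sample-domain code with the kernel
evoked_cycle <- function(code_samples, kernel) {
  n <- length(code_samples)
  kp <- c(kernel, numeric(n - length(kernel)))
  Re(stats::fft(stats::fft(code_samples) * stats::fft(kp), inverse = TRUE)) / n
}

#' Simulate one recording session
#'
#' Every trial is the subject's spatial pattern times the evoked waveform
#' (target code circularly convolved with the session-perturbed kernel,
#' latency-shifted per session and jittered per trial), plus coloured
#' noise: per-channel pink + white mixture with a 10%-amplitude common-mode
#' component, scaled so that evoked power / noise power equals the
#' subject's \code{snr_scale} (times the session's \code{noise_gain}).
#'
#' @param subject a [sample_subject()] model.
#' @param effect a [session_effect()].
#' @param cs a [code_set()].
#' @param blocks number of blocks (passes through all targets).
#' @param seed integer seed for noise and jitter.
#' @param config generator configuration; \code{config$fs} must be an
#'   integer multiple of the code bit rate.
#' @param block_ids block labels stored with the data (default
#'   \code{1:blocks}).
#' @param session_id stored session label.
#' @return object of class \code{"trial_tensor"}: \code{data} array of
#'   dimension (block, target, channel, sample) plus metadata.
#' @export
simulate_session <- function(subject, effect, cs, blocks = 6L, seed,
                             config = cvep_sim_config(),
                             block_ids = seq_len(blocks), session_id = 1L) {
  stopifnot(inherits(subject, "subject_model"),
            inherits(effect, "session_effect"), inherits(cs, "code_set"))
  blocks <- as.integer(blocks)
  if (blocks < 1L) stop("blocks must be >= 1")
  fs <- config$fs
  K <- length(cs$shifts)
  m <- length(subject$mixing_vector)
  cyc <- length(cs$base_code) * fs / cs$bit_rate
  if (abs(cyc - round(cyc)) > 1e-9)
    stop("sampling rate ", fs, " Hz is not divisible by the code bit rate ",
         cs$bit_rate, " Hz")
  cyc <- as.integer(round(cyc))
  n <- cyc * config$n_cycles
  with_seed(seed, {
    # session-level kernel perturbation (smooth, relative scale)
    kern <- subject$impulse_response
    if (effect$kernel_perturbation_sd > 0) {
      w <- stats::rnorm(length(kern))
      w <- stats::filter(w, rep(1 / 15, 15), circular = TRUE)
      w <- as.numeric(w) / stats::sd(w)
      kern <- kern + effect$kernel_perturbation_sd * sqrt(mean(kern^2)) * w
    }
    # per-target periodic evoked waveforms (one cycle each)
    cycles <- vapply(seq_len(K), function(k)
      evoked_cycle(expand_to_samples(cs, k, fs, n_cycles = 1L), kern),
      numeric(cyc))
    cycles <- cycles - rep(colMeans(cycles), each = cyc)
    data <- array(0, c(blocks, K, m, n))
    for (b in seq_len(blocks)) {
      for (k in seq_len(K)) {
        shift_s <- effect$latency_shift +
          stats::rnorm(1, 0, subject$latency_jitter_sd)
        sh <- as.integer(round(shift_s * fs)) %% cyc
        wave <- circ_rotate_left(cycles[, k], -sh)  # delay = rotate right
        sig <- rep(wave, config$n_cycles) * effect$amplitude_gain
        S <- tcrossprod(subject$mixing_vector, sig)
        if (effect$noise_gain > 0) {
          pn <- pink_noise(n, m + 1L)
          wn <- matrix(stats::rnorm(n * m), n, m)
          noise <- sqrt(1 - config$white_frac) *
            (pn[, seq_len(m)] + config$common_mode * pn[, m + 1L]) +
            sqrt(config$white_frac) * wn
          psig <- mean(S^2)
          noise <- t(noise) * sqrt(psig / subject$snr_scale / mean(noise^2)) *
            effect$noise_gain
          S <- S + noise
        }
        data[b, k, , ] <- S
      }
    }
    structure(
      list(data = data, fs = fs, block_ids = as.integer(block_ids),
           subject_id = subject$subject_id, session_id = session_id,
           n_targets = K, n_channels = m, n_samples = n),
      class = "trial_tensor")
  })
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat("trial tensor: subject", x$subject_id, "session", x$session_id,
      "| blocks", paste(x$block_ids, collapse = ","),
      "|", x$n_targets, "targets x", x$n_channels, "channels x",
      x$n_samples, "samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Extract trials from a tensor as a flat list
#'
#' @param tensor a [simulate_session()] trial tensor.
#' @param blocks block *ids* to extract (default all).
#' @return list with \code{trials} (list of channels x samples matrices),
#'   \code{labels} (target index per trial) and \code{block} (block id per
#'   trial).
#' @export
session_trials <- function(tensor, blocks = tensor$block_ids) {
  stopifnot(inherits(tensor, "trial_tensor"))
  bi <- match(blocks, tensor$block_ids)
  if (anyNA(bi))
    stop("block id(s) not in tensor: ",
         paste(blocks[is.na(bi)], collapse = ", "))
  trials <- list(); labels <- integer(); blk <- integer()
  for (b in bi) for (k in seq_len(tensor$n_targets)) {
    trials[[length(trials) + 1L]] <- tensor$data[b, k, , ]
    labels <- c(labels, k)
    blk <- c(blk, tensor$block_ids[b])
  }
  list(trials = trials, labels = labels, block = blk)
}

#' Simulate a multi-subject, two-session study
#'
#' For each subject, two sessions on "different days": session 1 (block ids
#' 1..blocks) and session 2 (block ids blocks+1..2*blocks), each with an
#' independently drawn [session_effect()]. Fully reproducible from
#' \code{(seed, config)}.
#'
#' @param n_subjects number of subjects.
#' @param cs a [code_set()].
#' @param config generator configuration.
#' @param seed integer master seed; all subject, session and noise seeds
#'   are derived from it.
#' @return object of class \code{"cvep_study"}: list of subjects, each with
#'   \code{model} and \code{sessions} (two trial tensors).
#' @export
simulate_study <- function(n_subjects = 10L, cs = code_set(),
                           config = cvep_sim_config(), seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  subjects <- lapply(seq_len(n_subjects), function(s) {
    subj <- sample_subject(seed_child(seed, s * 7L), config)
    subj$subject_id <- s
    sessions <- lapply(1:2, function(ss) {
      eff <- session_effect(seed_child(seed, s * 7L + ss), config = config)
      simulate_session(
        subj, eff, cs, blocks = config$blocks,
        seed = seed_child(seed, s * 7L + ss + 100L), config = config,
        block_ids = seq_len(config$blocks) + (ss - 1L) * config$blocks,
        session_id = ss)
    })
    list(subject_id = s, model = subj, sessions = sessions)
  })
  structure(list(subjects = subjects, code_set = cs, config = config,
                 seed = as.integer(seed)),
            class = "cvep_study")
}

#' @export
print.cvep_study <- function(x, ...) {
  cat("synthetic cVEP study:", length(x$subjects), "subjects x 2 sessions x",
      x$config$blocks, "blocks x", x$config$n_targets, "targets (seed",
      paste0(x$seed, ")"), "\n")
  invisible(x)
}
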