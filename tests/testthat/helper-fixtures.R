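# Shared small fixtures. Session simulation at full 32-target size is the
# realistic unit; reduced block counts keep the suite fast.

fix_cs <- code_set()

# a small two-block session, cached across tests
fix_session <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11, blocks = 2, noise_gain = 1, jitter = NULL,
           snr = NULL) {
    key <- paste(seed, blocks, noise_gain, jitter %||% "d", snr %||% "d",
                 sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    args <- list()
    if (!is.null(jitter)) args$latency_jitter_sd <- jitter
    if (!is.null(snr)) args$snr_scale <- snr
    cfg <- do.call(cvep_sim_config, c(list(blocks = blocks), args))
    subj <- sample_subject(seed, cfg)
    sess <- simulate_session(subj, null_session_effect(noise_gain),
                             fix_cs, blocks = blocks, seed = seed,
                             config = cfg)
    cache[[key]] <- list(session = sess, subject = subj, config = cfg)
    cache[[key]]
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force CCA oracle for 2-row inputs: grid search over unit-vector
# angle pairs, vectorised over the correlation matrix of all projections
cca_grid_oracle <- function(X, Y, n_angles = 720) {
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  px <- rbind(cos(th), sin(th))
  py <- px
  sx <- scale_rows(crossprod(px, X))
  sy <- scale_rows(crossprod(py, Y))
  max(abs(tcrossprod(sx, sy) / ncol(X)))
}
scale_rows <- function(M) {
  M <- M - rowMeans(M)
  M / sqrt(rowSums(M^2) / ncol(M))
}
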