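# shared fixtures: all built in code, nothing on disk

# epochs drawn from a given covariance (channels x channels)
mk_epochs <- function(n_ep, sigma, n_samp = 500, label = "high", band = "alpha",
                      fs = n_samp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- nrow(sigma)
  R <- chol(sigma)
  a <- array(0, c(n_ep, C, n_samp))
  for (i in seq_len(n_ep))
    a[i, , ] <- t(R) %*% matrix(rnorm(C * n_samp), C, n_samp)
  epoch_set(a, rep(label, n_ep), seq_len(n_ep), band, fs = fs,
            epoch_length_s = n_samp / fs)
}

rand_spd <- function(C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(C * C), C)
  crossprod(A) + 0.1 * diag(C)
}

# tiny annotated recording: k blocks of given labels/durations (seconds)
mk_recording <- function(n_channels = 3, fs = 32, dur = c(120, 120),
                         labels = c("low", "high"), condition = "nback",
                         phase = NULL, gen = function(n, ch) rnorm(n),
                         seed = 1) {
  set.seed(seed)
  ends <- cumsum(dur)
  n <- round(ends[length(ends)] * fs)
  X <- t(sapply(seq_len(n_channels), function(ch) gen(n, ch)))
  if (is.null(phase)) phase <- rep(1L, length(dur))
  ann <- block_annotations(ends - dur, ends, labels,
                           rep(condition, length(dur)), phase)
  eeg_recording(X, fs, paste0("ch", seq_len(n_channels)), annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coarse-grid leadfield for a 32-channel montage, computed once per run
small_leadfield <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- compute_leadfield(build_montage(32), source_grid(spacing = 0.45),
                                  reference = "linked-mastoid")
    cache
  }
})
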