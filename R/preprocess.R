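#' Band specification
#'
#' The two workload-relevant rhythms: alpha (8-13 Hz) and theta (4-7 Hz),
#' filtered with a digital Butterworth-type band-pass of order 4.
#'
#' @param name \code{"alpha"} or \code{"theta"}, or \code{"custom"} with
#'   explicit edges.
#' @param low_hz,high_hz band edges (defaults per name).
#' @param order Butterworth prototype order (even, >= 2; default 4).
#' @return Object of class \code{"band_spec"}.
#' @export
band_spec <- function(name = c("alpha", "theta", "custom"), low_hz = NULL,
                      high_hz = NULL, order = 4) {
  name <- match.arg(name)
  if (name == "alpha") { low_hz <- low_hz %||% 8; high_hz <- high_hz %||% 13 }
  if (name == "theta") { low_hz <- low_hz %||% 4; high_hz <- high_hz %||% 7 }
  if (is.null(low_hz) || is.null(high_hz))
    stop("custom band needs explicit low_hz/high_hz")
  if (!(low_hz > 0 && high_hz > low_hz)) stop("need 0 < low_hz < high_hz")
  if (order %% 2 != 0 || order < 2) stop("order must be even and >= 2")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz,
                 order = order, design = "butterworth"),
            class = "band_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Butterworth band-pass design: analog low-pass prototype -> band transform
# -> bilinear transform, returned as second-order sections plus gain.
# "order" is the prototype order; the digital filter has 2*order poles.
butter_bandpass_sos <- function(low_hz, high_hz, fs, order = 4) {
  if (high_hz >= fs / 2) stop("band edge at or above Nyquist")
  n <- order
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-circle LHP poles
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0sq <- w1 * w2
  # band-pass transform: each prototype pole p -> roots of s^2 - p*bw*s + w0^2
  sp <- c()
  for (p in proto) {
    disc <- sqrt((p * bw)^2 - 4 * w0sq + 0i)
    sp <- c(sp, (p * bw + disc) / 2, (p * bw - disc) / 2)
  }
  zp <- (1 + sp / fs2) / (1 - sp / fs2)  # bilinear
  # group complex-conjugate pole pairs into biquads; numerator (z-1)(z+1)
  zp <- zp[order(Re(zp), abs(Im(zp)))]
  used <- rep(FALSE, length(zp))
  sos <- NULL
  for (i in seq_along(zp)) {
    if (used[i]) next
    j <- which(!used & seq_along(zp) > i &
                 abs(zp - Conj(zp[i])) < 1e-8)[1]
    if (is.na(j)) j <- which(!used & seq_along(zp) > i)[1]
    used[c(i, j)] <- TRUE
    a1 <- -Re(zp[i] + zp[j])
    a2 <- Re(zp[i] * zp[j])
    sos <- rbind(sos, c(1, 0, -1, 1, a1, a2))
  }
  # normalise to unit gain at the (warped) centre frequency
  f0 <- fs / pi * atan(sqrt(w0sq) / fs2)
  z0 <- exp(1i * 2 * pi * f0 / fs)
  h <- prod(apply(sos, 1, function(s)
    (s[1] + s[2] / z0 + s[3] / z0^2) / (s[4] + s[5] / z0 + s[6] / z0^2)))
  gain <- 1 / Mod(h)
  # expanded direct-form coefficients (order 2n) for fast application
  polymul <- function(p, q) {
    out <- numeric(length(p) + length(q) - 1)
    for (i in seq_along(p))
      out[i:(i + length(q) - 1)] <- out[i:(i + length(q) - 1)] + p[i] * q
    out
  }
  b <- gain; a <- 1
  for (r in seq_len(nrow(sos))) {
    b <- polymul(b, sos[r, 1:3])
    a <- polymul(a, sos[r, 4:6])
  }
  # the expanded direct form is only used when its polynomial roots stay
  # strictly inside the unit circle (wide bands can lose stability to
  # coefficient rounding; the biquad cascade is always safe)
  df_ok <- max(Mod(polyroot(rev(a)))) < 1 - 1e-9
  list(sos = sos, gain = gain, b = b, a = a, df_ok = df_ok)
}

# causal direct-form filtering (zero initial conditions; start-up transient
# is left in, as in online use); X is samples x channels. The expanded
# order-8 coefficients deviate from the exact biquad cascade by < 1e-5
# relative, far below any quantity of interest here.
sosfilt_mat <- function(X, design) {
  X <- as.matrix(X)
  if (isTRUE(design$df_ok)) {
    nb <- length(design$b)
    pad <- nb - 1L
    for (j in seq_len(ncol(X))) {
      v <- stats::filter(c(numeric(pad), X[, j]), design$b,
                         method = "convolution", sides = 1)
      v <- as.numeric(v)[-seq_len(pad)]
      X[, j] <- as.numeric(stats::filter(v, -design$a[-1],
                                         method = "recursive"))
    }
    return(X)
  }
  for (j in seq_len(ncol(X))) {
    y <- X[, j] * design$gain
    for (r in seq_len(nrow(design$sos))) {
      s <- design$sos[r, ]
      v <- stats::filter(c(0, 0, y), s[1:3], method = "convolution",
                         sides = 1)
      v <- as.numeric(v)[-(1:2)]
      y <- as.numeric(stats::filter(v, -s[5:6], method = "recursive"))
    }
    X[, j] <- y
  }
  X
}

sosfilt1 <- function(x, design) as.numeric(sosfilt_mat(matrix(x), design))

#' Band-pass filter a recording
#'
#' Causal forward-only IIR filtering of every channel with the band's
#' order-4 Butterworth design (online-plausible; set
#' \code{zero_phase = TRUE} for offline forward-backward filtering).
#' Annotations are untouched; the band tag is updated.
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param band a \code{\link{band_spec}} (must lie below Nyquist).
#' @param zero_phase filter forwards and backwards (default FALSE).
#' @return filtered \code{eeg_recording}.
#' @export
bandpass <- function(recording, band, zero_phase = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(band, "band_spec"))
  des <- butter_bandpass_sos(band$low_hz, band$high_hz, recording$fs,
                             band$order)
  out <- recording
  Y <- sosfilt_mat(t(out$data), des)
  if (zero_phase) Y <- sosfilt_mat(Y[nrow(Y):1, , drop = FALSE], des)[nrow(Y):1, , drop = FALSE]
  out$data <- t(Y)
  out$band <- band$name
  out
}

#' Cut an annotated recording into fixed-length epochs
#'
#' Each block is cut into floor(duration / epoch_length) non-overlapping
#' epochs starting at block onset (the epoch grid restarts at every block, so
#' no epoch straddles a class boundary); incomplete trailing windows are
#' discarded. Every epoch inherits its block's label, condition and phase.
#'
#' @param recording annotated \code{\link{eeg_recording}}.
#' @param epoch_length_s epoch length in seconds (default 60).
#' @return an \code{\link{epoch_set}}.
#' @export
epoch_recording <- function(recording, epoch_length_s = 60) {
  stopifnot(inherits(recording, "eeg_recording"))
  ann <- recording$annotations
  if (nrow(ann) == 0) stop("no usable epochs")
  fs <- recording$fs
  len <- round(epoch_length_s * fs)
  starts <- integer(0); labs <- character(0); bids <- integer(0)
  phs <- integer(0)
  for (b in seq_len(nrow(ann))) {
    s0 <- round(ann$start_s[b] * fs)
    nb <- floor((ann$end_s[b] - ann$start_s[b]) / epoch_length_s)
    if (nb < 1) next
    starts <- c(starts, s0 + (seq_len(nb) - 1L) * len)
    labs <- c(labs, rep(ann$label[b], nb))
    bids <- c(bids, rep(b, nb))
    phs <- c(phs, rep(ann$phase[b], nb))
  }
  if (length(starts) == 0) stop("no usable epochs")
  C <- nrow(recording$data)
  ep <- array(0, c(length(starts), C, len))
  for (i in seq_along(starts))
    ep[i, , ] <- recording$data[, (starts[i] + 1L):(starts[i] + len)]
  epoch_set(ep, labs, bids, recording$band, fs, epoch_length_s,
            channel_labels = recording$channel_labels, phases = phs,
            condition = ann$condition[1])
}
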