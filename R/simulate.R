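#' Paradigm block schedule
#'
#' Default schedules of the two workload paradigms: the n-back condition
#' alternates 4-min high/low blocks for 5 repetitions each (10 blocks,
#' starting low); the maneuver condition is 5 min low-workload sailing
#' followed by 10 min of high-workload connecting, repeated once (two
#' phases, 30 min total). An override rescales block lengths to yield a
#' requested epoch count per block.
#'
#' @param condition \code{"nback"} or \code{"maneuver"}.
#' @param epochs_per_block_override optional integer; every block is resized
#'   to this many epochs.
#' @param epoch_length_s epoch length used by the override (default 60).
#' @return Object of class \code{"paradigm_schedule"}: \code{condition},
#'   \code{blocks} (a block annotation table).
#' @export
make_schedule <- function(condition = c("nback", "maneuver"),
                          epochs_per_block_override = NULL,
                          epoch_length_s = 60) {
  condition <- match.arg(condition)
  if (!is.null(epochs_per_block_override) && epochs_per_block_override < 1)
    stop("epochs_per_block_override must be >= 1")
  if (condition == "nback") {
    dur <- rep(if (is.null(epochs_per_block_override)) 240
               else epochs_per_block_override * epoch_length_s, 10)
    lab <- rep(c("low", "high"), 5)
    phase <- rep(1L, 10)
  } else {
    base <- c(300, 600, 300, 600)
    dur <- if (is.null(epochs_per_block_override)) base
           else rep(epochs_per_block_override * epoch_length_s, 4)
    lab <- c("low", "high", "low", "high")
    phase <- c(1L, 1L, 2L, 2L)
  }
  if (any(dur <= 0)) stop("non-positive block duration")
  ends <- cumsum(dur)
  blocks <- block_annotations(start_s = ends - dur, end_s = ends,
                              label = lab,
                              condition = rep(condition, length(dur)),
                              phase = phase)
  structure(list(condition = condition, blocks = blocks),
            class = "paradigm_schedule")
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf("<paradigm_schedule> %s: %d blocks, %.0f min total\n",
              x$condition, nrow(x$blocks), max(x$blocks$end_s) / 60))
  invisible(x)
}

#' Synthetic-subject parameters
#'
#' The stated world of the simulator. Workload-modulated neural sources
#' (frontal-midline and right-frontal theta, power 2:1 high:low; occipital
#' and left-parietal alpha, 1:2 — the classic load signatures) share their
#' location, band and class-power pair across conditions, but each dipole's
#' orientation tilts by \code{orientation_shift_deg} in opposite directions
#' in the two conditions: the scalp pattern of every neural source changes
#' between conditions, which is what makes fixed spatial filters
#' session-specific. Two condition-specific class-dependent artifact
#' sources (ocular, discriminative only in the maneuver condition;
#' temporal-muscle, discriminative only in n-back; 3:1 within their
#' condition, flat at the mean elsewhere) mix through steep near-electrode
#' profiles. A spatially correlated 1/f background drawn from a pool of
#' in-brain dipoles is re-weighted per condition, per-channel electrode
#' gains drift between sessions, every source amplitude jitters slowly
#' within a session, and white sensor noise floors everything. Powers are
#' channel-space variances of the unit-norm-mixed source.
#'
#' @param seed integer master seed; all randomness flows from it.
#' @param neural_power_theta,neural_power_alpha named low/high variances.
#' @param artifact_ratio within-condition high:low (or low:high) artifact
#'   power ratio.
#' @param ocular_power,muscle_power discriminative-condition total variance.
#' @param n_background,background_active,background_sd,background_condition_sd
#'   1/f background pool size, sources active per condition, their scale,
#'   and the log-sd of the per-condition reweight.
#' @param channel_gain_sd log-sd of per-session electrode gains.
#' @param orientation_shift_deg per-condition dipole tilt of the neural
#'   sources (the angle between the two conditions' orientations is twice
#'   this).
#' @param power_jitter_sd log-sd of the slow per-minute amplitude jitter of
#'   every source (within-condition non-stationarity).
#' @param sensor_noise_sd white sensor noise sd (microvolts).
#' @return list of class \code{"subject_params"}.
#' @export
subject_params <- function(seed = 1,
                           neural_power_theta = c(low = 8, high = 16),
                           neural_power_alpha = c(low = 16, high = 8),
                           artifact_ratio = 3,
                           ocular_power = 6,
                           muscle_power = 15,
                           n_background = 30,
                           background_active = 30,
                           background_sd = 3,
                           background_condition_sd = 0.4,
                           channel_gain_sd = 0.05,
                           orientation_shift_deg = 45,
                           power_jitter_sd = 0.3,
                           sensor_noise_sd = 1) {
  r <- artifact_ratio
  # split total variance v into low/high with ratio r, keeping the mean at v
  split_lh <- function(v, r) c(low = 2 * v / (1 + r), high = 2 * v * r / (1 + r))
  structure(list(
    seed = as.integer(seed),
    neural_sources = list(
      theta = list(position = c(0, 0.55, 0.45), band = c(4, 7),
                   power = neural_power_theta),
      theta2 = list(position = c(0.3, 0.4, 0.55), band = c(4, 7),
                    power = neural_power_theta),
      alpha = list(position = c(0, -0.5, 0.62), band = c(8, 13),
                   power = neural_power_alpha),
      alpha2 = list(position = c(-0.35, -0.3, 0.62), band = c(8, 13),
                    power = neural_power_alpha)),
    artifact_sources = list(
      ocular = list(peak = "Fpz", falloff = 0.2, band = c(1, 7),
                    power = list(nback = c(low = ocular_power,
                                           high = ocular_power),
                                 maneuver = split_lh(ocular_power, r))),
      muscle = list(peak = "T8", falloff = 0.2, band = c(8, 45),
                    power = list(nback = split_lh(muscle_power, r),
                                 maneuver = c(low = muscle_power,
                                              high = muscle_power)))),
    n_background = n_background, background_active = background_active,
    background_sd = background_sd,
    background_condition_sd = background_condition_sd,
    channel_gain_sd = channel_gain_sd,
    orientation_shift_deg = orientation_shift_deg,
    power_jitter_sd = power_jitter_sd,
    sensor_noise_sd = sensor_noise_sd),
    class = "subject_params")
}

# band-limited unit-variance noise
bandlimited_noise <- function(n, band, fs) {
  des <- butter_bandpass_sos(band[1], min(band[2], fs / 2 - 1), fs, 4)
  x <- sosfilt1(stats::rnorm(n), des)
  x / stats::sd(x)
}

# 1/f ("pink") unit-variance noise via spectral shaping; k columns at once
pink_noise <- function(n, fs, k = 1, f_floor = 1) {
  X <- stats::mvfft(matrix(stats::rnorm(n * k), n, k))
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  X <- X / sqrt(pmax(f, f_floor))
  X[1, ] <- 0
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# steep near-electrode spatial profile: exponential fall-off with
# great-circle distance from the peak 10/10 site, unit norm. The peak is a
# canonical site name and need not be part of the montage (e.g. Fpz in the
# 32-channel set).
artifact_profile <- function(montage, peak, falloff) {
  i <- match(peak, montage$labels)
  p0 <- if (is.na(i)) montage_positions_64()[peak, ]
        else montage$positions[i, ]
  if (anyNA(p0)) stop("unknown 10/10 site: ", peak)
  d <- acos(pmax(-1, pmin(1, montage$positions %*% p0)))
  g <- exp(-as.numeric(d) / falloff)
  g / sqrt(sum(g^2))
}

#' Simulate one EEG session
#'
#' Makes the linear generative model concrete: band-limited neural source
#' time courses are mixed through spherical-head-model gain columns with
#' block-dependent power, condition-specific artifacts through steep
#' near-electrode profiles, plus spatially correlated 1/f background and
#' white sensor noise. Block boundaries are respected sample-exactly and the
#' whole session is reproducible from the subject seed.
#'
#' @param schedule a \code{\link{make_schedule}} result.
#' @param subject \code{\link{subject_params}}.
#' @param montage \code{\link{build_montage}} result.
#' @param leadfield optional \code{\link{leadfield}}; when given, its shell
#'   parameters and reference are reused for the source gain columns.
#' @param fs sampling rate in Hz (default 200; the paper-scale 1 kHz is
#'   supported but needless for alpha/theta content).
#' @param return_sources attach ground-truth mixing columns and time courses
#'   as attribute \code{"sources"}.
#' @return annotated \code{\link{eeg_recording}} (linked-mastoid reference).
#' @export
simulate_session <- function(schedule, subject, montage, leadfield = NULL,
                             fs = 200, return_sources = FALSE) {
  stopifnot(inherits(schedule, "paradigm_schedule"),
            inherits(subject, "subject_params"),
            inherits(montage, "eeg_montage"))
  radii <- if (is.null(leadfield)) c(0.87, 0.92, 1.0) else leadfield$radii
  cond3 <- if (is.null(leadfield)) c(1, 1 / 50, 1) else leadfield$conductivities
  reference <- "linked-mastoid"
  condition <- schedule$condition
  blocks <- schedule$blocks
  n <- round(max(blocks$end_s) * fs)
  C <- montage$n_channels
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))

  # subject-level structure: identical draws in both conditions
  set.seed(subject$seed)
  nb <- subject$n_background
  bg_pos <- matrix(stats::runif(3 * nb, -0.6, 0.6), nb, 3)
  bg_pos <- bg_pos * 0.7 / pmax(1e-9, sqrt(rowSums(bg_pos^2))) *
    matrix(stats::runif(nb, 0.3, 1), nb, 3)
  bg_mom <- matrix(stats::rnorm(3 * nb), nb, 3)
  # condition-specific background re-weighting over the source pool: each
  # condition activates its own random subset of the pool (different tasks
  # engage different cortical background), with lognormal weights on the
  # active sources and zero on the rest
  nact <- subject$background_active %||% nb
  draw_bg_w <- function() {
    w <- numeric(nb)
    act <- sample.int(nb, min(nact, nb))
    w[act] <- exp(stats::rnorm(length(act), 0, subject$background_condition_sd))
    w
  }
  bg_w <- list(nback = draw_bg_w(), maneuver = draw_bg_w())
  # per-session electrode gains: contact impedances drift between sessions,
  # rescaling every channel of one condition's recording
  gain_sd <- subject$channel_gain_sd %||% 0
  ch_gain <- list(nback = exp(stats::rnorm(C, 0, gain_sd)),
                  maneuver = exp(stats::rnorm(C, 0, gain_sd)))
  # neural sources are shared across conditions (same location, band and
  # class-power pair) but their dipole orientation — hence scalp pattern —
  # shifts slightly between conditions: the neural non-stationarity that
  # makes fixed spatial filters session-specific
  phi <- (subject$orientation_shift_deg %||% 0) * pi / 180
  orientations <- lapply(subject$neural_sources, function(src) {
    rhat <- src$position / sqrt(sum(src$position^2))
    u <- stats::rnorm(3)
    u <- u - sum(u * rhat) * rhat
    u <- u / sqrt(sum(u^2))
    # tilt by +phi in one condition and -phi in the other: the angle
    # between the two conditions' dipole orientations is exactly 2*phi
    list(nback = cos(phi) * rhat + sin(phi) * u,
         maneuver = cos(phi) * rhat - sin(phi) * u)
  })
  neural_cols <- lapply(names(subject$neural_sources), function(nm) {
    src <- subject$neural_sources[[nm]]
    g <- dipole_gain(montage, src$position, orientations[[nm]][[condition]],
                     radii, cond3, reference = reference)
    g / sqrt(sum(g^2))
  })
  names(neural_cols) <- names(subject$neural_sources)
  bg_cols <- dipole_gain(montage, bg_pos, bg_mom, radii, cond3,
                         reference = reference)
  bg_cols <- sweep(bg_cols, 2, sqrt(colSums(bg_cols^2)), "/")

  # session-level noise: condition-specific stream
  set.seed((subject$seed * 7919L + match(condition, c("nback", "maneuver"))) %%
             .Machine$integer.max)
  amp_per_sample <- function(power) {
    a <- numeric(n)
    for (b in seq_len(nrow(blocks))) {
      i0 <- round(blocks$start_s[b] * fs) + 1L
      i1 <- round(blocks$end_s[b] * fs)
      a[i0:i1] <- sqrt(power[[blocks$label[b]]])
    }
    a
  }
  # slow within-condition non-stationarity: every source's amplitude drifts
  # by an independent lognormal factor redrawn each minute, so within-class
  # band-power fluctuates as in real EEG instead of concentrating tightly
  jit_sd <- subject$power_jitter_sd %||% 0
  jitter_env <- function() {
    if (jit_sd <= 0) return(rep(1, n))
    k <- ceiling(n / (60 * fs))
    rep(exp(stats::rnorm(k, 0, jit_sd)), each = 60 * fs)[seq_len(n)]
  }
  X <- matrix(stats::rnorm(C * n, sd = subject$sensor_noise_sd), C, n)
  src_tc <- list()
  for (nm in names(subject$neural_sources)) {
    src <- subject$neural_sources[[nm]]
    tc <- bandlimited_noise(n, src$band, fs) * amp_per_sample(src$power) *
      jitter_env()
    X <- X + neural_cols[[nm]] %*% t(tc)
    src_tc[[nm]] <- tc
  }
  for (nm in names(subject$artifact_sources)) {
    src <- subject$artifact_sources[[nm]]
    prof <- artifact_profile(montage, src$peak, src$falloff)
    prof <- as.numeric(rereference_matrix(matrix(prof), montage, reference))
    tc <- bandlimited_noise(n, src$band, fs) *
      amp_per_sample(src$power[[condition]]) * jitter_env()
    X <- X + prof %*% t(tc)
  }
  w <- bg_w[[condition]] * subject$background_sd
  B <- t(pink_noise(n, fs, k = nb)) * w
  if (jit_sd > 0) for (k in seq_len(nb)) B[k, ] <- B[k, ] * jitter_env()
  X <- X + bg_cols %*% B
  X <- X * ch_gain[[condition]]
  rec <- eeg_recording(X, fs, montage$labels, reference = reference,
                       annotations = blocks)
  if (return_sources)
    attr(rec, "sources") <- list(
      mixing = {
        mx <- do.call(cbind, neural_cols)
        colnames(mx) <- names(neural_cols)
        mx
      },
      bands = lapply(subject$neural_sources, `[[`, "band"),
      powers = lapply(subject$neural_sources, `[[`, "power"),
      time_courses = src_tc)
  rec
}

#' Two-session transfer benchmark
#'
#' One synthetic subject recorded in both paradigms: shared workload-coupled
#' neural sources (frontal theta up, occipital/parietal alpha down with
#' load) whose scalp patterns tilt between conditions, an ocular artifact
#' discriminative only in the maneuver condition, a temporal-muscle
#' artifact discriminative only in n-back, condition-specific background
#' reweighting and electrode-gain drift. Pipelines that latch onto the
#' artifacts or onto one condition's spatial patterns classify well within
#' either condition but transfer around chance; unsupervised covariance
#' adaptation recovers part of the shared neural signal.
#'
#' @param seed master seed.
#' @param n_channels montage size (default 64).
#' @param fs sampling rate (default 200).
#' @param subject optional \code{\link{subject_params}} override.
#' @return list with \code{nback}, \code{maneuver} (recordings),
#'   \code{ground_truth} (neural mixing columns, bands, block powers, time
#'   courses per session), \code{montage}.
#' @export
make_transfer_benchmark <- function(seed = 1, n_channels = 64, fs = 200,
                                    subject = NULL) {
  montage <- build_montage(n_channels)
  if (is.null(subject)) subject <- subject_params(seed)
  nback <- simulate_session(make_schedule("nback"), subject, montage,
                            fs = fs, return_sources = TRUE)
  maneuver <- simulate_session(make_schedule("maneuver"), subject, montage,
                               fs = fs, return_sources = TRUE)
  gt <- list(mixing = list(nback = attr(nback, "sources")$mixing,
                           maneuver = attr(maneuver, "sources")$mixing),
             bands = attr(nback, "sources")$bands,
             powers = attr(nback, "sources")$powers,
             time_courses = list(nback = attr(nback, "sources")$time_courses,
                                 maneuver = attr(maneuver, "sources")$time_courses))
  list(nback = nback, maneuver = maneuver, ground_truth = gt,
       montage = montage)
}
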