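test_that("paradigm schedules match the experimental design", {
  nb <- make_schedule("nback")
  expect_equal(nrow(nb$blocks), 10L)
  expect_equal(nb$blocks$label, rep(c("low", "high"), 5))
  expect_equal(unique(nb$blocks$end_s - nb$blocks$start_s), 240)
  mv <- make_schedule("maneuver")
  expect_equal(mv$blocks$label, c("low", "high", "low", "high"))
  expect_equal(mv$blocks$end_s - mv$blocks$start_s, c(300, 600, 300, 600))
  expect_equal(max(mv$blocks$end_s), 30 * 60)
  expect_equal(mv$blocks$phase, c(1L, 1L, 2L, 2L))
  # label balance invariants: 5:5 blocks, 1:2 low:high duration
  expect_equal(sum(nb$blocks$label == "low"), 5L)
  d <- tapply(mv$blocks$end_s - mv$blocks$start_s, mv$blocks$label, sum)
  expect_equal(unname(d["high"] / d["low"]), 2)
  # override resizes to the requested accounting (80 n-back observations)
  ov <- make_schedule("nback", epochs_per_block_override = 8)
  expect_equal(sum(ov$blocks$end_s - ov$blocks$start_s) / 60, 80)
  expect_error(make_schedule("nback", epochs_per_block_override = 0),
               ">= 1")
})

test_that("noise-only sessions are white at the sensor level", {
  sp <- subject_params(1, neural_power_theta = c(low = 0, high = 0),
                       neural_power_alpha = c(low = 0, high = 0),
                       ocular_power = 0, muscle_power = 0,
                       background_sd = 0, channel_gain_sd = 0,
                       power_jitter_sd = 0, sensor_noise_sd = 1)
  sp$neural_sources <- list()
  sp$artifact_sources <- list()
  m <- build_montage(32)
  sched <- make_schedule("nback", epochs_per_block_override = 1)
  rec <- simulate_session(sched, sp, m, fs = 100)
  v <- apply(rec$data, 1, var)
  expect_equal(mean(v), 1, tolerance = 0.05)
  cc <- cor(t(rec$data[1:8, ]))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("a workload-modulated alpha source suppresses band power under load", {
  # single occipital alpha source, high:low power 1:4
  sp <- subject_params(2, ocular_power = 0, muscle_power = 0,
                       background_sd = 0, channel_gain_sd = 0,
                       power_jitter_sd = 0, sensor_noise_sd = 0.1)
  sp$neural_sources <- list(
    alpha = list(position = c(0, -0.5, 0.62), band = c(8, 13),
                 power = c(low = 4, high = 1)))
  sp$artifact_sources <- list()
  m <- build_montage(32)
  rec <- simulate_session(make_schedule("nback"), sp, m, fs = 100,
                          return_sources = TRUE)
  col <- attr(rec, "sources")$mixing[, 1]
  ch <- which.max(abs(col))
  filt <- bandpass(rec, band_spec("alpha"))
  es <- epoch_recording(filt, 60)
  p <- apply(es$epochs[, ch, ], 1, var)
  ratio <- mean(p[es$labels == "high"]) / mean(p[es$labels == "low"])
  expect_equal(ratio, 0.25, tolerance = 0.15)
})

test_that("simulation is bitwise reproducible from the seed", {
  sp <- subject_params(3)
  m <- build_montage(32)
  sched <- make_schedule("nback", epochs_per_block_override = 1)
  r1 <- simulate_session(sched, sp, m, fs = 100)
  r2 <- simulate_session(sched, sp, m, fs = 100)
  expect_identical(r1$data, r2$data)
  # different condition draws a different stream
  r3 <- simulate_session(make_schedule("maneuver",
                                       epochs_per_block_override = 1),
                         sp, m, fs = 100)
  expect_false(isTRUE(all.equal(var(r1$data[1, ]), var(r3$data[1, ]))))
})

test_that("simulated covariance approaches its analytic prediction", {
  # no jitter, no gains: channel covariance should converge to
  # sum of mixing outer products + sensor noise
  sp <- subject_params(4, ocular_power = 0, muscle_power = 0,
                       n_background = 5, background_active = 5,
                       background_sd = 2, background_condition_sd = 0,
                       channel_gain_sd = 0, power_jitter_sd = 0,
                       sensor_noise_sd = 1)
  sp$artifact_sources <- list()
  m <- build_montage(32)
  rec <- simulate_session(make_schedule("maneuver"), sp, m, fs = 100,
                          return_sources = TRUE)
  # duration-weighted mean source power: low 10 min, high 20 min
  mix <- attr(rec, "sources")$mixing
  pw <- lapply(attr(rec, "sources")$powers,
               function(p) (p[["low"]] * 10 + p[["high"]] * 20) / 30)
  pred <- diag(nrow(rec$data))  # sensor noise
  for (nm in colnames(mix)) pred <- pred + pw[[nm]] * tcrossprod(mix[, nm])
  # background: 5 unit-norm columns at variance 4 each; their exact
  # columns are internal, so compare only on the neural + noise part by
  # projecting out the background subspace is overkill — instead rebuild
  # the full prediction from the internals via a fresh subject-level draw
  set.seed(sp$seed)
  nb <- sp$n_background
  bg_pos <- matrix(stats::runif(3 * nb, -0.6, 0.6), nb, 3)
  bg_pos <- bg_pos * 0.7 / pmax(1e-9, sqrt(rowSums(bg_pos^2))) *
    matrix(stats::runif(nb, 0.3, 1), nb, 3)
  bg_mom <- matrix(stats::rnorm(3 * nb), nb, 3)
  bg_cols <- dipole_gain(m, bg_pos, bg_mom, reference = "linked-mastoid")
  bg_cols <- sweep(bg_cols, 2, sqrt(colSums(bg_cols^2)), "/")
  pred <- pred + 4 * tcrossprod(bg_cols)
  emp <- tcrossprod(rec$data - rowMeans(rec$data)) / (ncol(rec$data) - 1)
  expect_lt(sqrt(sum((emp - pred)^2)) / sqrt(sum(pred^2)), 0.1)
})

test_that("the transfer benchmark states its premise", {
  sp <- subject_params(5)
  # neural class-power maps are shared across conditions by construction
  for (src in sp$neural_sources) expect_length(src$power, 2)
  # artifact class-power maps differ between conditions
  oc <- sp$artifact_sources$ocular$power
  expect_true(oc$nback[["low"]] == oc$nback[["high"]])
  expect_true(oc$maneuver[["high"]] / oc$maneuver[["low"]] == 3)
  mu <- sp$artifact_sources$muscle$power
  expect_true(mu$maneuver[["low"]] == mu$maneuver[["high"]])
  expect_true(mu$nback[["high"]] / mu$nback[["low"]] == 3)
})
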