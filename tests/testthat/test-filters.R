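test_that("solve_rayleigh handles diagonal and degenerate pencils", {
  r <- solve_rayleigh(diag(c(4, 1)), diag(c(5, 5)))
  expect_equal(r$eigenvalues, c(0.8, 0.2), tolerance = 1e-12)
  # eigenvectors are the coordinate axes, normalized to w' Sigma_den w = 1
  expect_equal(abs(r$eigenvectors), diag(2) / sqrt(5), tolerance = 1e-9,
               ignore_attr = TRUE)

  S <- rand_spd(4, seed = 1)
  r2 <- solve_rayleigh(S, S)
  expect_equal(r2$eigenvalues, rep(1, 4), tolerance = 1e-10)

  expect_error(solve_rayleigh(diag(2), matrix(c(1, 2, 2, 1), 2)),
               "not positive definite")
})

test_that("top generalized eigenvalue dominates random Rayleigh quotients", {
  set.seed(2)
  Sn <- rand_spd(4); Sd <- rand_spd(4)
  r <- solve_rayleigh(Sn, Sd)
  # pencil residual invariant
  for (j in 1:4) {
    w <- r$eigenvectors[, j]
    expect_lt(sqrt(sum((Sn %*% w - r$eigenvalues[j] * Sd %*% w)^2)),
              1e-8 * sqrt(sum((Sn %*% w)^2)))
  }
  V <- matrix(rnorm(4 * 10000), 4)
  rq <- colSums(V * (Sn %*% V)) / colSums(V * (Sd %*% V))
  expect_gte(r$eigenvalues[1] - max(rq), -1e-9)
})

test_that("CSP separates constructed class covariances", {
  e1 <- mk_epochs(30, diag(c(4, 1, 1, 1)), seed = 3)
  e2 <- mk_epochs(30, diag(c(1, 1, 1, 4)), seed = 4, label = "low")
  bank <- train_csp(e1, e2, n_per_end = 1, shrinkage_gamma = 0)
  expect_equal(ncol(bank$W), 2)
  expect_equal(bank$eigenvalues[1], 0.8, tolerance = 0.05)
  expect_equal(bank$eigenvalues[2], 0.2, tolerance = 0.05)

  # identical class distributions: all eigenvalues near 1/2
  e3 <- mk_epochs(40, rand_spd(4, seed = 5), seed = 6)
  e4 <- mk_epochs(40, rand_spd(4, seed = 5), seed = 7, label = "low")
  b2 <- train_csp(e3, e4, n_per_end = 2, shrinkage_gamma = 0)
  expect_equal(b2$eigenvalues, rep(0.5, 4), tolerance = 0.1)

  # default keeps three plus three
  e5 <- mk_epochs(20, rand_spd(8, seed = 8), seed = 9)
  e6 <- mk_epochs(20, rand_spd(8, seed = 10), seed = 11, label = "low")
  expect_equal(ncol(train_csp(e5, e6)$W), 6)
  expect_error(train_csp(mk_epochs(5, diag(4), seed = 1),
                         mk_epochs(5, diag(4), seed = 2), n_per_end = 3),
               "fewer channels")
})

test_that("CSP satisfies whitening, pairing and invariance properties", {
  set.seed(12)
  S1 <- rand_spd(6); S2 <- rand_spd(6)
  b <- beamadapt:::train_csp_cov(cov_estimate(S1, 10L, 0, "alpha"),
                                 cov_estimate(S2, 10L, 0, "alpha"),
                                 n_per_end = 3)
  den <- S1 + S2
  D <- crossprod(b$W, den %*% b$W)
  expect_equal(D, diag(diag(D)), tolerance = 1e-8)
  # eigenvalues live in [0,1]; the class-2 spectrum is 1 minus class-1
  ev1 <- solve_rayleigh(S1, den)$eigenvalues
  ev2 <- solve_rayleigh(S2, den)$eigenvalues
  expect_true(all(ev1 >= -1e-10 & ev1 <= 1 + 1e-10))
  expect_equal(sort(ev2), sort(1 - ev1), tolerance = 1e-8)
  # invariance of the spectrum under an invertible channel transform
  set.seed(13)
  T <- matrix(rnorm(36), 6) + 2 * diag(6)
  evT <- solve_rayleigh(T %*% S1 %*% t(T), T %*% den %*% t(T))$eigenvalues
  expect_equal(evT, ev1, tolerance = 1e-8)
  # permutation equivariance: permuting channels permutes filter rows
  p <- c(3, 1, 2, 6, 5, 4)
  bp <- beamadapt:::train_csp_cov(cov_estimate(S1[p, p], 10L, 0, "alpha"),
                                  cov_estimate(S2[p, p], 10L, 0, "alpha"),
                                  n_per_end = 3)
  expect_equal(abs(bp$W), abs(b$W[p, ]), tolerance = 1e-6)
})

test_that("beamformer recovers a planted source and keeps all components", {
  set.seed(14)
  C <- 8
  l <- rnorm(C)
  Sx <- tcrossprod(l) + 0.5 * diag(C)
  bank <- train_beamformer(cov_estimate(tcrossprod(l)),
                           cov_estimate(Sx, band = "alpha"))
  expect_equal(ncol(bank$W), C)
  w <- bank$W[, 1]; wm <- solve(Sx, l)  # MVDR direction
  expect_gt(abs(sum(w * wm)) / sqrt(sum(w^2) * sum(wm^2)), 1 - 1e-8)
  # noiseless single-source stream is reconstructed perfectly
  s_true <- rnorm(2000)
  x <- l %*% t(s_true)
  expect_gt(abs(cor(as.numeric(crossprod(w, x)), s_true)), 1 - 1e-10)

  S <- rand_spd(64, seed = 15)
  b2 <- train_beamformer(cov_estimate(S), cov_estimate(S))
  expect_equal(ncol(b2$W), 64)
  expect_equal(b2$eigenvalues, rep(1, 64), tolerance = 1e-8)
})

test_that("patterns are the dual of filters", {
  S <- rand_spd(5, seed = 16)
  expect_equal(compute_patterns(diag(5), S), diag(5), tolerance = 1e-10)
  set.seed(17)
  W <- matrix(rnorm(25), 5) + 2 * diag(5)
  A <- compute_patterns(W, S)
  expect_equal(A, t(solve(W)), tolerance = 1e-8)
  # rectangular case: duality identity A'W = I
  S64 <- rand_spd(64, seed = 18)
  W6 <- matrix(rnorm(64 * 6), 64)
  A6 <- compute_patterns(W6, S64)
  expect_equal(crossprod(A6, W6), diag(6), tolerance = 1e-8)
  expect_error(compute_patterns(cbind(W6[, 1], W6[, 1]), S64),
               "rank-deficient")
  # patterns of patterns-as-filters: applying the duality twice returns
  # the original square filters
  expect_equal(compute_patterns(A, S), W, tolerance = 1e-8)
})

test_that("apply_filters matches a scalar loop oracle and is linear", {
  e <- mk_epochs(2, rand_spd(4, seed = 19), n_samp = 50, seed = 20)
  expect_equal(apply_filters(identity_bank(4), e)$epochs, e$epochs,
               tolerance = 1e-14, ignore_attr = TRUE)
  pick <- matrix(0, 4, 1); pick[3] <- 1
  bank1 <- filter_bank(pick, pick, "none", "alpha")
  expect_equal(apply_filters(bank1, e)$epochs[1, 1, ], e$epochs[1, 3, ],
               tolerance = 1e-14)
  set.seed(21)
  W <- matrix(rnorm(8), 4, 2)
  bank <- filter_bank(W, W, "none", "alpha")
  out <- apply_filters(bank, e)
  oracle <- array(0, c(2, 2, 50))
  for (i in 1:2) for (k in 1:2) for (t in 1:50)
    oracle[i, k, t] <- sum(W[, k] * e$epochs[i, , t])
  expect_equal(out$epochs, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # linearity
  e2 <- mk_epochs(2, rand_spd(4, seed = 22), n_samp = 50, seed = 23)
  esum <- e; esum$epochs <- e$epochs + e2$epochs
  expect_equal(apply_filters(bank, esum)$epochs,
               apply_filters(bank, e)$epochs + apply_filters(bank, e2)$epochs,
               tolerance = 1e-12)
  expect_error(apply_filters(bank, mk_epochs(1, diag(3), n_samp = 10)),
               "mismatch")
})

test_that("adaptation leaves the bank unchanged in the no-forgetting limit", {
  set.seed(24)
  S <- rand_spd(5)
  bank <- train_beamformer(cov_estimate(rand_spd(5)),
                           cov_estimate(S, band = "alpha"))
  st <- adaptation_state(cov_estimate(S, 10L, 0, "alpha"), lam = 1e-9,
                         method = "bfa")
  ep <- mk_epochs(1, S, n_samp = 100)
  res <- adapt_and_filter(bank, st, ep)
  expect_equal(res$bank$W, bank$W, tolerance = 1e-5)
  # the epoch is filtered with the bank as it was BEFORE the update
  expect_equal(res$filtered$epochs, apply_filters(bank, ep)$epochs,
               tolerance = 1e-14)
  expect_equal(res$state$epochs_consumed, 1L)
})

test_that("adaptive filters re-track a mid-stream covariance step", {
  # artifact channel power x10 halfway: the adapted beamformer's top
  # component variance returns toward its pre-change level, the frozen
  # bank's does not
  ratios_adapt <- ratios_frozen <- numeric(10)
  for (seed in 1:10) {
    set.seed(seed)
    C <- 6
    l <- rnorm(C)
    S0 <- tcrossprod(l) + diag(C)
    bank0 <- train_beamformer(cov_estimate(tcrossprod(l)),
                              cov_estimate(S0, band = "alpha"))
    st <- adaptation_state(cov_estimate(S0, 10L, 0, "alpha"), lam = 0.2,
                           method = "bfa", anchor = bank0$W)
    pre <- mean(replicate(5, {
      ep <- mk_epochs(1, S0, n_samp = 400)
      var(as.numeric(crossprod(bank0$W[, 1], ep$epochs[1, , ])))
    }))
    k <- which.max(abs(l))               # hit the source's best channel
    S1 <- S0; S1[k, k] <- S1[k, k] * 10  # artifact channel blows up
    bank <- bank0
    v_adapt <- v_frozen <- NA
    for (i in 1:20) {
      ep <- mk_epochs(1, S1, n_samp = 400)
      v_adapt <- var(as.numeric(crossprod(bank$W[, 1], ep$epochs[1, , ])))
      v_frozen <- var(as.numeric(crossprod(bank0$W[, 1], ep$epochs[1, , ])))
      out <- adapt_and_filter(bank, st, ep)
      bank <- out$bank; st <- out$state
    }
    ratios_adapt[seed] <- v_adapt / pre
    ratios_frozen[seed] <- v_frozen / pre
  }
  expect_lt(median(ratios_adapt), 2)
  expect_gt(median(ratios_frozen), 2)
})

test_that("filter subspace drift vanishes on a stationary stream", {
  # principal angles between successive filter subspaces shrink as the
  # running covariance converges
  drift_early <- drift_late <- numeric(3)
  for (seed in 1:3) {
    set.seed(seed + 30)
    S <- rand_spd(6)
    bank <- train_beamformer(cov_estimate(rand_spd(6)),
                             cov_estimate(S, band = "alpha"))
    st <- adaptation_state(cov_estimate(2 * diag(6), 10L, 0, "alpha"),
                           lam = 0.2, method = "bfa", anchor = bank$W)
    angs <- numeric(30)
    Wprev <- bank$W
    for (i in 1:30) {
      out <- adapt_and_filter(bank, st, mk_epochs(1, S, n_samp = 300))
      bank <- out$bank; st <- out$state
      sv <- svd(qr.Q(qr(Wprev))[, 1:3] |> crossprod(qr.Q(qr(bank$W))[, 1:3]))$d
      angs[i] <- acos(min(1, min(sv)))
      Wprev <- bank$W
    }
    drift_early[seed] <- median(angs[1:10])
    drift_late[seed] <- median(angs[21:30])
  }
  expect_lt(median(drift_late), median(drift_early))
})

test_that("filter bank constructor validates its invariants", {
  expect_error(filter_bank(matrix(0, 3, 1), matrix(1, 3, 1), "csp", "alpha"),
               "nonzero")
  expect_error(filter_bank(diag(3), diag(3)[, 1:2], "csp", "alpha"),
               "identical shape")
  expect_error(filter_bank(diag(2), diag(2), "csp", "alpha",
                           eigenvalues = c(0.2, 0.8)), "descending")
  b <- identity_bank(3, "theta")
  expect_equal(b$W, diag(3))
  expect_identical(b$method, "none")
})
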