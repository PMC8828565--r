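test_that("montage construction follows the 10/10 conventions", {
  m64 <- build_montage(64)
  expect_equal(m64$n_channels, 64L)
  expect_false(anyDuplicated(m64$labels) > 0)
  expect_equal(m64$positions[match("Cz", m64$labels), ], c(0, 0, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sqrt(rowSums(m64$positions^2)), rep(1, 64), tolerance = 1e-9,
               ignore_attr = TRUE)
  # every electrode occupies a distinct site
  d <- as.matrix(dist(m64$positions))
  expect_gt(min(d[upper.tri(d)]), 0.01)
  m32 <- build_montage(32)
  expect_true(all(m32$labels %in% m64$labels))
  expect_error(build_montage(19), "unsupported")
})

test_that("dipole potentials respect symmetry and linearity", {
  # tangential dipole at the centre: mirror-symmetric electrodes about the
  # moment plane see equal and opposite potentials
  elec <- rbind(c(sin(1), 0, cos(1)), c(-sin(1), 0, cos(1)))
  v <- beamadapt:::dipole_potential(elec, c(0, 0, 0), c(1, 0, 0),
                                    c(0.87, 0.92, 1), c(1, 1 / 50, 1), 60)
  expect_equal(v[1], -v[2], tolerance = 1e-10)
  # doubling the moment doubles every potential exactly
  m64 <- build_montage(64)
  set.seed(1)
  pos <- c(0.2, 0.1, 0.3); mom <- rnorm(3)
  v1 <- beamadapt:::dipole_potential(m64$positions, pos, mom,
                                     c(0.87, 0.92, 1), c(1, 1 / 50, 1), 60)
  v2 <- beamadapt:::dipole_potential(m64$positions, pos, 2 * mom,
                                     c(0.87, 0.92, 1), c(1, 1 / 50, 1), 60)
  expect_equal(v2, 2 * v1, tolerance = 1e-14)
})

test_that("equal-conductivity shells reduce to the single-sphere solution", {
  # independent oracle: for one homogeneous sphere the insulating-boundary
  # condition gives the surface harmonic coefficient (2n+1)/n * R^-(n+1)
  # in closed form
  single_sphere <- function(elec, pos, mom, R = 1, sigma = 1, N = 200) {
    b <- sqrt(sum(pos^2))
    zhat <- if (b > 0) pos / b else c(0, 0, 1)
    mr <- sum(mom * zhat); qt <- mom - mr * zhat; mt <- sqrt(sum(qt^2))
    xhat <- if (mt > 1e-14) qt / mt else c(1, 0, 0)
    cth <- pmax(-1, pmin(1, elec %*% zhat)); sx <- elec %*% xhat
    leg <- beamadapt:::legendre_table(as.numeric(cth), N)
    nn <- seq_len(N)
    f <- (2 * nn + 1) / nn * R^(-(nn + 1))
    bn <- if (b < 1e-12) c(1, numeric(N - 1)) else b^(nn - 1)
    wn <- bn * f
    as.numeric(t(leg$P) %*% (wn * nn) * mr +
                 (t(leg$dP) %*% wn) * as.numeric(sx) * mt) / (4 * pi * sigma)
  }
  m <- build_montage(64)
  set.seed(2)
  for (i in 1:10) {
    pos <- runif(3, -0.35, 0.35); mom <- rnorm(3)
    v <- beamadapt:::dipole_potential(m$positions, pos, mom,
                                      c(0.87, 0.92, 1), c(1, 1, 1), 60)
    o <- single_sphere(m$positions, pos, mom)
    expect_lt(max(abs(v - o)) / max(abs(o)), 1e-6)
  }
})

test_that("leadfield computation validates sources and reference", {
  m <- build_montage(32)
  g <- source_grid(spacing = 0.5)
  expect_error(
    beamadapt:::dipole_potential(m$positions, c(0.9, 0, 0), c(1, 0, 0),
                                 c(0.87, 0.92, 1), c(1, 1 / 50, 1), 60),
    "outside brain")
  lf <- compute_leadfield(m, g, reference = "average")
  expect_equal(dim(lf$L), c(32L, 3L * g$n_sources))
  # average-referenced columns sum to zero
  expect_lt(max(abs(colSums(lf$L))), 1e-8)
})

test_that("ROI covariance equals the source-wise summation oracle", {
  lf <- small_leadfield()
  roi <- roi_covariance(lf)
  ns <- lf$grid$n_sources
  oracle <- matrix(0, nrow(lf$L), nrow(lf$L))
  for (s in seq_len(ns)) for (o in 1:3) {
    l <- lf$L[, 3 * (s - 1) + o]
    oracle <- oracle + tcrossprod(l)
  }
  expect_equal(roi$sigma, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  ev <- eigen(roi$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))

  # single source, unit power: rank-one outer product
  r1 <- roi_covariance(lf, source_indices = 1, source_cov = diag(c(1, 0, 0)))
  expect_equal(r1$sigma, tcrossprod(lf$L[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
  r0 <- roi_covariance(lf, source_indices = 1:2, source_cov = matrix(0, 6, 6))
  expect_equal(max(abs(r0$sigma)), 0)
  expect_error(roi_covariance(lf, source_indices = integer(0)), "empty ROI")
  expect_error(roi_covariance(lf, source_indices = ns + 5), "out of range")
})

test_that("a more resistive skull smears the leadfield", {
  # lowering skull conductivity increases the correlation between
  # neighbouring channels' gain vectors
  m <- build_montage(32)
  g <- source_grid(spacing = 0.6)
  pair <- match(c("C3", "Cz"), m$labels)
  cors <- sapply(c(1 / 15, 1 / 50, 1 / 120), function(sk) {
    lf <- compute_leadfield(m, g, conductivities = c(1, sk, 1),
                            reference = "average")
    cor(lf$L[pair[1], ], lf$L[pair[2], ])
  })
  expect_true(all(diff(cors) > 0))
})

test_that("electrode positions import from CSV", {
  m <- build_montage(32)
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(label = m$labels, x = 2 * m$positions[, 1],
                       y = 2 * m$positions[, 2], z = 2 * m$positions[, 3]),
            p, row.names = FALSE)
  m2 <- read_montage_csv(p)
  expect_equal(m2$positions, m$positions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(m2$labels, m$labels)
  write.csv(data.frame(label = "Cz", x = 1), p, row.names = FALSE)
  expect_error(read_montage_csv(p), "columns")
})
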