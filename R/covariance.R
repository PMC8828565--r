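#' Covariance estimation with shrinkage
#'
#' Estimates the channel covariance of band-passed EEG as the average of
#' per-epoch sample covariances (each epoch mean-centred per channel and
#' normalised by samples - 1), then shrinks toward a scaled identity:
#' \deqn{\Sigma = (1-\gamma)\hat\Sigma + \gamma \frac{tr(\hat\Sigma)}{C} I.}
#' With \code{shrinkage_gamma = NULL} the analytic Ledoit-Wolf intensity is
#' used, which keeps 64 x 64 covariances from a handful of 60-s epochs well
#' conditioned; noise covariance is never modelled explicitly — shrinkage is
#' its operational stand-in.
#'
#' @param epochs an \code{\link{epoch_set}} (band-pass filtered).
#' @param shrinkage_gamma fixed shrinkage in [0,1], or NULL for analytic
#'   Ledoit-Wolf.
#' @return Object of class \code{"cov_estimate"} with fields \code{sigma},
#'   \code{n_epochs_seen}, \code{shrinkage_gamma}, \code{band}.
#' @export
estimate_covariance <- function(epochs, shrinkage_gamma = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- n_epochs(epochs)
  if (n < 1L) stop("no epochs")
  if (!all(is.finite(epochs$epochs))) stop("non-finite input")
  if (!is.null(shrinkage_gamma) &&
      (shrinkage_gamma < 0 || shrinkage_gamma > 1))
    stop("shrinkage_gamma must be in [0,1]")
  C <- dim(epochs$epochs)[2L]
  S <- matrix(0, C, C)
  for (i in seq_len(n)) S <- S + epoch_sample_cov(epochs$epochs[i, , ])
  S <- S / n
  gamma <- if (is.null(shrinkage_gamma)) lw_gamma(epochs) else shrinkage_gamma
  cov_estimate(shrink_cov(S, gamma), n, gamma, epochs$band)
}

#' Covariance-estimate container
#'
#' Symmetrised channel covariance with bookkeeping (epochs seen, shrinkage
#' used, band tag). Returned by \code{\link{estimate_covariance}} and
#' accepted wherever a covariance is expected.
#'
#' @param sigma symmetric matrix.
#' @param n_epochs_seen epoch count behind the estimate.
#' @param shrinkage_gamma shrinkage intensity used.
#' @param band band tag.
#' @return object of class \code{"cov_estimate"}.
#' @export
cov_estimate <- function(sigma, n_epochs_seen = 0L, shrinkage_gamma = 0,
                         band = "broadband") {
  sigma <- (sigma + t(sigma)) / 2
  structure(list(sigma = sigma, n_epochs_seen = as.integer(n_epochs_seen),
                 shrinkage_gamma = shrinkage_gamma, band = band),
            class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  cat(sprintf("<cov_estimate> %d x %d (%s band, gamma=%.3g, %d epochs)\n",
              nrow(x$sigma), ncol(x$sigma), x$band, x$shrinkage_gamma,
              x$n_epochs_seen))
  invisible(x)
}

# per-epoch sample covariance: channel x sample slice, mean-centred, /(n-1)
epoch_sample_cov <- function(slice) {
  xc <- slice - rowMeans(slice)
  tcrossprod(xc) / (ncol(slice) - 1)
}

shrink_cov <- function(S, gamma) {
  C <- nrow(S)
  (1 - gamma) * S + gamma * (sum(diag(S)) / C) * diag(C)
}

# Ledoit-Wolf analytic shrinkage toward the scaled identity, computed from
# the pooled (per-epoch mean-centred) samples.
lw_gamma <- function(epochs) {
  d <- dim(epochs$epochs)
  C <- d[2L]
  # concatenate centred epochs: samples x channels
  X <- matrix(0, d[1L] * d[3L], C)
  for (i in seq_len(d[1L])) {
    sl <- epochs$epochs[i, , , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = C)
    X[((i - 1) * d[3L] + 1):(i * d[3L]), ] <- t(sl - rowMeans(sl))
  }
  n <- nrow(X)
  S <- crossprod(X) / n
  m <- sum(diag(S)) / C
  d2 <- sum((S - m * diag(C))^2)
  if (d2 < .Machine$double.eps) return(0)
  # sum over samples of ||x x' - S||_F^2 / n^2, without forming outer products
  x2 <- rowSums(X^2)
  b2bar <- (sum(x2^2) - 2 * sum((X %*% S) * X) + n * sum(S^2)) / n^2
  b2 <- min(b2bar, d2)
  max(0, min(1, b2 / d2))
}

#' Exponential (unsupervised) covariance update
#'
#' One step of the running-covariance recursion
#' \deqn{\Sigma_x^{(M)} = (1-\lambda)\Sigma_x^{(M-1)} + \lambda\,\Sigma_{x_M}}
#' where \eqn{\Sigma_{x_M}} is the newest epoch's sample covariance. The
#' update never reads class labels (unsupervised adaptation).
#'
#' @param prev a \code{cov_estimate}.
#' @param new_epoch a single-epoch \code{\link{epoch_set}}.
#' @param lam forgetting factor in (0, 1].
#' @return Updated \code{cov_estimate} (\code{n_epochs_seen} incremented).
#' @export
update_covariance <- function(prev, new_epoch, lam) {
  stopifnot(inherits(prev, "cov_estimate"), inherits(new_epoch, "epoch_set"))
  if (lam <= 0 || lam > 1) stop("lam must be in (0,1]")
  if (n_epochs(new_epoch) != 1L) stop("new_epoch must hold exactly one epoch")
  if (dim(new_epoch$epochs)[2L] != nrow(prev$sigma))
    stop("channel count mismatch between prev and new_epoch")
  Sn <- epoch_sample_cov(new_epoch$epochs[1, , ])
  cov_estimate((1 - lam) * prev$sigma + lam * Sn,
               prev$n_epochs_seen + 1L, prev$shrinkage_gamma, prev$band)
}

# covariance update from a precomputed epoch covariance (fast path)
update_covariance_mat <- function(sigma, epoch_cov, lam) {
  (1 - lam) * sigma + lam * epoch_cov
}
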