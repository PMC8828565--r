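#' Generalized eigendecomposition of a covariance pencil
#'
#' Solves the Rayleigh-quotient maximisation
#' \eqn{\max_w w^\top\Sigma_{num}w / w^\top\Sigma_{den}w} by whitening the
#' denominator (Cholesky) and diagonalising the whitened numerator. Both CSP
#' and the whole-brain beamformer reduce to this pencil with different
#' numerators.
#'
#' Eigenvectors are scaled so that \eqn{w^\top\Sigma_{den}w = 1} and returned
#' as columns sorted by descending eigenvalue.
#'
#' @param sigma_num,sigma_den \code{cov_estimate} objects (or plain symmetric
#'   matrices) of equal dimension; the denominator must be positive definite.
#' @return list with \code{eigenvalues} (descending), \code{eigenvectors}
#'   (channel x channel), \code{numerator_label}, \code{denominator_label}.
#' @export
solve_rayleigh <- function(sigma_num, sigma_den) {
  Sn <- cov_mat(sigma_num)
  Sd <- cov_mat(sigma_den)
  if (!all(dim(Sn) == dim(Sd))) stop("dimension mismatch")
  R <- tryCatch(chol(Sd), error = function(e) NULL)
  if (is.null(R))
    stop("denominator not positive definite; increase shrinkage")
  # whitened numerator: R^{-T} Sn R^{-1}, symmetric
  M <- backsolve(R, t(backsolve(R, Sn, transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  W <- backsolve(R, e$vectors)
  list(eigenvalues = e$values, eigenvectors = W,
       numerator_label = cov_label(sigma_num),
       denominator_label = cov_label(sigma_den))
}

cov_mat <- function(x) if (inherits(x, "cov_estimate")) x$sigma else as.matrix(x)
cov_label <- function(x) if (inherits(x, "cov_estimate")) x$band else "matrix"

#' Spatial filter bank
#'
#' Holds spatial filters W (channel x component), the corresponding forward
#' patterns A, the method tag and the covariances defining the pencil.
#' For \code{method = "none"} W is the identity.
#'
#' @param W filter matrix (channel x component).
#' @param A pattern matrix, same shape as W.
#' @param method one of \code{"none","csp","cspa","bf","bfa"}.
#' @param band band tag.
#' @param numerator_cov,denominator_cov the defining \code{cov_estimate}s
#'   (class-1 and pooled for CSP; ROI and data for the beamformer).
#' @param eigenvalues per-component generalized eigenvalues (descending).
#' @return Object of class \code{"filter_bank"}.
#' @export
filter_bank <- function(W, A, method, band, numerator_cov = NULL,
                        denominator_cov = NULL, eigenvalues = NULL,
                        check_sorted = TRUE) {
  method <- match.arg(method, c("none", "csp", "cspa", "bf", "bfa"))
  W <- as.matrix(W); A <- as.matrix(A)
  if (!all(dim(W) == dim(A))) stop("W and A must have identical shape")
  if (!all(is.finite(W)) || any(colSums(W^2) == 0))
    stop("filter columns must be finite and nonzero")
  if (check_sorted && !is.null(eigenvalues) && is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be sorted descending")
  structure(list(W = W, A = A, method = method, band = band,
                 numerator_cov = numerator_cov,
                 denominator_cov = denominator_cov,
                 eigenvalues = eigenvalues),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %s: %d channels -> %d components (%s band)\n",
              toupper(x$method), nrow(x$W), ncol(x$W), x$band))
  invisible(x)
}

#' Apply spatial filters to epochs
#'
#' Replaces every epoch by \eqn{W^\top x}; the channel axis becomes the
#' component axis. Labels and block ids are preserved.
#'
#' @param bank a \code{\link{filter_bank}}.
#' @param epochs an \code{\link{epoch_set}} with matching channel count.
#' @return component \code{epoch_set}.
#' @export
apply_filters <- function(bank, epochs) {
  stopifnot(inherits(bank, "filter_bank"), inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  if (d[2L] != nrow(bank$W)) stop("dimension mismatch: channels vs filters")
  k <- ncol(bank$W)
  out <- array(0, c(d[1L], k, d[3L]))
  for (i in seq_len(d[1L]))
    out[i, , ] <- crossprod(bank$W, matrix(epochs$epochs[i, , ], d[2L], d[3L]))
  epoch_set(out, epochs$labels, epochs$block_ids, epochs$band, epochs$fs,
            epochs$epoch_length_s,
            channel_labels = sprintf("comp%02d", seq_len(k)),
            phases = epochs$phases, condition = epochs$condition)
}

#' Filters to forward patterns
#'
#' Converts spatial filters into the corresponding scalp patterns
#' \deqn{A = \Sigma_x W (W^\top \Sigma_x W)^{-1},}
#' the forward projection of each extracted component onto the channels. For
#' square invertible W this reduces to the transpose inverse.
#'
#' @param W filter matrix (channel x component, full column rank).
#' @param sigma_x data covariance (\code{cov_estimate} or matrix), positive
#'   definite after shrinkage.
#' @return pattern matrix, same shape as W.
#' @export
compute_patterns <- function(W, sigma_x) {
  Sx <- cov_mat(sigma_x)
  W <- as.matrix(W)
  Ss <- crossprod(W, Sx %*% W)
  Ss <- (Ss + t(Ss)) / 2
  Ai <- tryCatch(solve(Ss), error = function(e) NULL)
  if (is.null(Ai) || !all(is.finite(Ai))) stop("rank-deficient filter set")
  Sx %*% W %*% Ai
}

# sign convention: make the largest-|.| entry of each pattern column positive,
# flipping filter and pattern together (the flip in sign is meaningless)
fix_signs <- function(W, A) {
  for (j in seq_len(ncol(A))) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) { A[, j] <- -A[, j]; W[, j] <- -W[, j] }
  }
  list(W = W, A = A)
}

# raise shrinkage in steps of 0.01 until the denominator is numerically PD
ensure_pd <- function(S, gamma0 = 0, step = 0.01, cond_max = 1e10) {
  gamma <- 0
  repeat {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < cond_max) return(S)
    gamma <- gamma + step
    if (gamma > 1) stop("denominator not positive definite; increase shrinkage")
    message(sprintf("raising shrinkage to %.2f to regularize denominator", gamma))
    S <- shrink_cov(S, step)
  }
}

#' Train CSP filters
#'
#' Common spatial patterns for a two-class problem: generalized
#' eigendecomposition of \eqn{(\Sigma_1, \Sigma_1+\Sigma_2)}. Filters from
#' both ends of the eigenvalue spectrum are retained (components maximising
#' the variance ratio for either class); by default three plus three.
#'
#' @param epochs_class1,epochs_class2 \code{epoch_set}s of the two classes
#'   (class 1 conventionally \code{"high"}).
#' @param n_per_end filters kept per spectrum end (default 3).
#' @param shrinkage_gamma shrinkage for the class covariances (NULL =
#'   analytic).
#' @return \code{\link{filter_bank}} with \code{2 * n_per_end} components.
#' @export
train_csp <- function(epochs_class1, epochs_class2, n_per_end = 3,
                      shrinkage_gamma = NULL) {
  if (n_epochs(epochs_class1) < 1L || n_epochs(epochs_class2) < 1L)
    stop("both classes must be non-empty")
  s1 <- estimate_covariance(epochs_class1, shrinkage_gamma)
  s2 <- estimate_covariance(epochs_class2, shrinkage_gamma)
  train_csp_cov(s1, s2, n_per_end, band = epochs_class1$band)
}

# covariance-level CSP core (also used by the fast evaluation path)
train_csp_cov <- function(s1, s2, n_per_end = 3, band = s1$band) {
  C <- nrow(cov_mat(s1))
  if (C < 2 * n_per_end) stop("fewer channels than 2 * n_per_end filters")
  raw <- (attr(s1, "raw") %||% cov_mat(s1)) +
    (attr(s2, "raw") %||% cov_mat(s2))
  g <- mean(c(s1$shrinkage_gamma, s2$shrinkage_gamma))
  den <- cov_estimate(ensure_pd(shrink_cov(raw, g)),
                      s1$n_epochs_seen + s2$n_epochs_seen, g, band)
  attr(den, "raw") <- raw
  ge <- solve_rayleigh(s1, den)
  sel <- c(seq_len(n_per_end), seq(C - n_per_end + 1, C))
  W <- ge$eigenvectors[, sel, drop = FALSE]
  A <- compute_patterns(W, den)
  fx <- fix_signs(W, A)
  filter_bank(fx$W, fx$A, "csp", band, numerator_cov = s1,
              denominator_cov = den, eigenvalues = ge$eigenvalues[sel])
}

#' Train a whole-brain-ROI beamformer
#'
#' Maximises modelled region-of-interest power over measured power:
#' generalized eigendecomposition of \eqn{(\Sigma_{ROI}, \Sigma_x)} with
#' \eqn{\Sigma_{ROI} = L\Sigma_s L^\top} from the head model. Unlike CSP no
#' end-selection is applied: eigenvector rank carries no class meaning here,
#' so all components are retained.
#'
#' @param sigma_roi ROI covariance from \code{\link{roi_covariance}}.
#' @param sigma_x measured data covariance (positive definite after
#'   shrinkage).
#' @return \code{\link{filter_bank}} with all components.
#' @export
train_beamformer <- function(sigma_roi, sigma_x) {
  Sd <- ensure_pd(cov_mat(sigma_x))
  sx <- if (inherits(sigma_x, "cov_estimate"))
    cov_estimate(Sd, sigma_x$n_epochs_seen, sigma_x$shrinkage_gamma,
                 sigma_x$band)
  else cov_estimate(Sd, 0L, 0, "matrix")
  attr(sx, "raw") <- attr(sigma_x, "raw") %||% cov_mat(sigma_x)
  ge <- solve_rayleigh(sigma_roi, sx)
  A <- compute_patterns(ge$eigenvectors, sx)
  fx <- fix_signs(ge$eigenvectors, A)
  filter_bank(fx$W, fx$A, "bf", sx$band, numerator_cov = sigma_roi,
              denominator_cov = sx, eigenvalues = ge$eigenvalues)
}

#' Adaptation state for CSPa/BFa
#'
#' @param running_cov current running \code{cov_estimate} (the adaptive
#'   denominator; for CSPa this is the pooled covariance
#'   \eqn{(\Sigma_1+\Sigma_2)/2} so that Eq.-9 updates with single-epoch
#'   covariances stay on a consistent scale).
#' @param lam forgetting factor in (0,1].
#' @param method \code{"cspa"} or \code{"bfa"}.
#' @param n_per_end CSP end-selection (ignored for bfa).
#' @return Object of class \code{"adaptation_state"}.
#' @export
adaptation_state <- function(running_cov, lam = 0.1,
                             method = c("cspa", "bfa"), n_per_end = 3,
                             anchor = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(running_cov, "cov_estimate"), lam > 0, lam <= 1)
  structure(list(running_cov = running_cov, lam = lam,
                 epochs_consumed = 0L, method = method,
                 n_per_end = n_per_end, anchor = anchor),
            class = "adaptation_state")
}

#' Adaptive filtering of one incoming epoch
#'
#' Online step of the adaptive variants: the incoming epoch is filtered with
#' the CURRENT bank (the epoch never informs its own filters), then the
#' running covariance is updated by the exponential recursion and the bank's
#' eigendecomposition is recomputed with the training-time numerator
#' (class-1 covariance for CSPa, ROI covariance for BFa) over the adapted
#' denominator. Labels are never consulted.
#'
#' Components of the recomputed bank are re-sorted by eigenvalue and their
#' signs aligned by maximal overlap with the previous columns.
#'
#' @param bank current \code{\link{filter_bank}} (method csp/cspa or bf/bfa).
#' @param state an \code{\link{adaptation_state}} matching the bank's family.
#' @param epoch single-epoch \code{\link{epoch_set}}.
#' @return list(filtered = component epoch_set, bank = updated bank,
#'   state = updated state).
#' @export
adapt_and_filter <- function(bank, state, epoch) {
  stopifnot(inherits(bank, "filter_bank"),
            inherits(state, "adaptation_state"))
  fam <- substr(state$method, 1, 3)
  if (!bank$method %in% c(state$method, substr(state$method, 1, 2),
                          sub("a$", "", state$method)))
    stop("state method does not match bank method family")
  filtered <- apply_filters(bank, epoch)
  if (is.null(state$anchor)) state$anchor <- bank$W
  state$running_cov <- update_covariance(state$running_cov, epoch, state$lam)
  state$epochs_consumed <- state$epochs_consumed + 1L
  newbank <- rebuild_bank(bank, state)
  list(filtered = filtered, bank = newbank, state = state)
}

# recompute the bank from the frozen numerator and the adapted denominator.
# Components of the refreshed decomposition are matched to the TRAINING
# bank's components (the anchor) by maximal overlap in the Sigma_den metric
# (greedy assignment) rather than by raw eigenvalue rank: with
# near-degenerate background spectra the eigenvalue order is unstable from
# epoch to epoch, and the classifier's feature indexing requires stable
# component identity; anchoring to the trained filters keeps the matching
# from random-walking through successive near-crossings.
rebuild_bank <- function(bank, state) {
  run <- state$running_cov
  # run$sigma is the raw exponential average; the training-time shrinkage is
  # re-applied here so adapted and training filters share one normalisation
  g <- run$shrinkage_gamma %||% 0
  raw <- if (state$method == "cspa") 2 * run$sigma else run$sigma
  den <- cov_estimate(ensure_pd(shrink_cov(raw, g)), run$n_epochs_seen,
                      g, bank$band)
  ge <- solve_rayleigh(bank$numerator_cov, den)
  Wall <- ge$eigenvectors
  anchor <- state$anchor %||% bank$W
  # Sigma-metric cosines between refreshed and anchor components
  M <- abs(crossprod(Wall, den$sigma %*% anchor))
  k <- ncol(anchor)
  assign <- integer(k)
  for (rep in seq_len(k)) {
    i <- arrayInd(which.max(M), dim(M))
    assign[i[2]] <- i[1]
    M[i[1], ] <- -Inf; M[, i[2]] <- -Inf
  }
  W <- Wall[, assign, drop = FALSE]
  ev <- ge$eigenvalues[assign]
  A <- compute_patterns(W, den)
  for (j in seq_len(k)) {
    if (sum(W[, j] * (den$sigma %*% anchor[, j])) < 0) {
      W[, j] <- -W[, j]; A[, j] <- -A[, j]
    }
  }
  filter_bank(W, A, state$method, bank$band,
              numerator_cov = bank$numerator_cov,
              denominator_cov = den, eigenvalues = ev, check_sorted = FALSE)
}

#' Identity bank (no spatial filtering)
#' @param n_channels channel count.
#' @param band band tag.
#' @param channel_labels optional labels.
#' @return identity \code{\link{filter_bank}} with method \code{"none"}.
#' @export
identity_bank <- function(n_channels, band = "broadband",
                          channel_labels = NULL) {
  I <- diag(n_channels)
  if (!is.null(channel_labels)) rownames(I) <- channel_labels
  filter_bank(I, I, "none", band)
}
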