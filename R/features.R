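#' Log-variance band-power features
#'
#' Feature (band, component) of epoch i is the natural log of the sample
#' variance of that component in that band — the log linearises band power,
#' whose raw distribution is chi-squared, into something LDA handles.
#' Bands are concatenated column-wise.
#'
#' @param filtered_per_band named list (band -> component
#'   \code{\link{epoch_set}}), same epochs/labels in every band.
#' @return Object of class \code{"feature_matrix"}: \code{values}
#'   (epoch x feature), \code{feature_names}, \code{labels},
#'   \code{block_ids}, \code{phases}.
#' @export
logvar_features <- function(filtered_per_band) {
  stopifnot(is.list(filtered_per_band), length(filtered_per_band) >= 1)
  bands <- names(filtered_per_band)
  if (is.null(bands)) stop("filtered_per_band must be a named list")
  ref <- filtered_per_band[[1]]
  vals <- NULL; nms <- character(0)
  for (b in bands) {
    es <- filtered_per_band[[b]]
    if (n_epochs(es) != n_epochs(ref) || !identical(es$labels, ref$labels))
      stop("bands must share epochs and labels")
    d <- dim(es$epochs)
    V <- matrix(0, d[1L], d[2L])
    for (i in seq_len(d[1L])) {
      sl <- matrix(es$epochs[i, , ], d[2L], d[3L])
      V[i, ] <- apply(sl, 1, stats::var)
    }
    if (any(V <= 0)) stop("degenerate component")
    vals <- cbind(vals, log(V))
    nms <- c(nms, sprintf("%s.c%02d", b, seq_len(d[2L])))
  }
  feature_matrix(vals, nms, ref$labels, ref$block_ids, ref$phases)
}

feature_matrix <- function(values, feature_names, labels, block_ids,
                           phases = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("non-finite feature values")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = as.character(labels),
                 block_ids = as.integer(block_ids),
                 phases = if (is.null(phases)) rep(1L, nrow(values))
                          else as.integer(phases)),
            class = "feature_matrix")
}

# fast path: log-variances straight from per-epoch covariances,
# ln diag(W' Sigma_e W) — identical to variance of the filtered series
logvar_from_covs <- function(W, cov_stack) {
  E <- dim(cov_stack)[3L]
  out <- matrix(0, E, ncol(W))
  for (i in seq_len(E))
    out[i, ] <- log(colSums(W * (cov_stack[, , i] %*% W)))
  if (!all(is.finite(out))) stop("degenerate component")
  out
}

#' Train a shrinkage-LDA workload classifier
#'
#' Fisher LDA on log-variance features: weights
#' \eqn{w \propto \Sigma_{pooled}^{-1}(\mu_{high}-\mu_{low})} with analytic
#' (Ledoit-Wolf) shrinkage of the pooled within-class covariance — needed
#' when 128 features meet fewer than 100 epochs — and a bias placing the
#' boundary midway between the projected class means.
#'
#' @param features a \code{\link{feature_matrix}} (or plain matrix with
#'   \code{labels}).
#' @param labels class labels if \code{features} is a plain matrix.
#' @param shrinkage_gamma fixed shrinkage in [0,1], NULL for analytic.
#' @return Object of class \code{"lda_model"}: \code{weights}, \code{bias},
#'   \code{class_order = c("low","high")}, \code{feature_names}.
#' @export
train_lda <- function(features, labels = NULL, shrinkage_gamma = NULL) {
  if (inherits(features, "feature_matrix")) {
    X <- features$values; y <- features$labels
    nms <- features$feature_names
  } else {
    X <- as.matrix(features); y <- as.character(labels)
    nms <- colnames(X) %||% sprintf("f%02d", seq_len(ncol(X)))
  }
  if (length(unique(y)) < 2L) stop("both classes must be present")
  hi <- X[y == "high", , drop = FALSE]
  lo <- X[y == "low", , drop = FALSE]
  mu_h <- colMeans(hi); mu_l <- colMeans(lo)
  Xc <- rbind(sweep(hi, 2, mu_h), sweep(lo, 2, mu_l))
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / max(1, n - 2)
  gamma <- if (!is.null(shrinkage_gamma)) shrinkage_gamma
           else lw_gamma_samples(Xc)
  S <- shrink_cov(S, gamma)
  w <- solve(S, mu_h - mu_l)
  b <- -sum(w * (mu_h + mu_l)) / 2
  structure(list(weights = as.numeric(w), bias = b,
                 class_order = c("low", "high"), feature_names = nms,
                 shrinkage_gamma = gamma),
            class = "lda_model")
}

# Ledoit-Wolf intensity from centred sample rows
lw_gamma_samples <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - m * diag(p))^2)
  if (d2 < .Machine$double.eps) return(0)
  x2 <- rowSums(Xc^2)
  b2bar <- (sum(x2^2) - 2 * sum((Xc %*% S) * Xc) + n * sum(S^2)) / n^2
  max(0, min(1, min(b2bar, d2) / d2))
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features (shrinkage %.3g), decision: high if score > 0\n",
              length(x$weights), x$shrinkage_gamma))
  invisible(x)
}

#' Predict workload class from features
#'
#' Decision value \eqn{w^\top f + b}; label \code{"high"} iff the value is
#' strictly positive (ties resolve to \code{"low"}, deterministically).
#'
#' @param object an \code{\link{train_lda}} model.
#' @param newdata \code{feature_matrix} or plain matrix with matching
#'   feature count.
#' @param ... unused.
#' @return data.frame with \code{label} and \code{decision_value}.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$values
       else as.matrix(newdata)
  if (ncol(X) != length(object$weights)) stop("feature count mismatch")
  dv <- as.numeric(X %*% object$weights + object$bias)
  data.frame(label = ifelse(dv > 0, "high", "low"),
             decision_value = dv, stringsAsFactors = FALSE)
}
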