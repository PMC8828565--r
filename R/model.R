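#' Fit a workload classification model
#'
#' The package's central fitting function: trains band-wise spatial filters
#' (per \code{method}) and a shrinkage-LDA classifier on log-variance
#' band-power features of an annotated session. The returned object carries
#' everything needed to classify new epochs, including — for the adaptive
#' variants — the state required to keep updating the filters
#' unsupervisedly on a new condition.
#'
#' Methods: \code{"none"} (no spatial filtering), \code{"csp"} /
#' \code{"cspa"} (common spatial patterns, static / adaptive denominator),
#' \code{"bf"} / \code{"bfa"} (whole-brain-ROI beamformer, static /
#' adaptive).
#'
#' @param x a \code{\link{prepare_session}} result or annotated
#'   \code{\link{eeg_recording}}.
#' @param method filtering method (see above).
#' @param leadfield \code{\link{leadfield}}, required for bf/bfa.
#' @param n_per_end CSP filters per spectrum end (default 3).
#' @param shrinkage_gamma fixed covariance shrinkage, NULL = analytic.
#' @param lam adaptation forgetting factor (default 0.1 per 60-s epoch).
#' @param bands,epoch_length_s used when \code{x} is a recording.
#' @return Object of class \code{"wl_model"}.
#' @export
wl_fit <- function(x, method = c("none", "csp", "cspa", "bf", "bfa"),
                   leadfield = NULL, n_per_end = 3, shrinkage_gamma = NULL,
                   lam = 0.1, bands = c("alpha", "theta"),
                   epoch_length_s = 60) {
  method <- match.arg(method)
  sess <- if (inherits(x, "wl_session")) x
          else prepare_session(x, bands, epoch_length_s)
  core <- train_core(sess, seq_along(sess$labels), method, leadfield,
                     n_per_end, shrinkage_gamma)
  tr_pred <- predict(core$lda,
                     features_core(sess, seq_along(sess$labels), core$banks))
  structure(list(banks = core$banks, lda = core$lda, method = method,
                 bands = sess$bands, lam = lam, n_per_end = n_per_end,
                 channel_labels = sess$channel_labels,
                 train_condition = sess$condition,
                 n_train_epochs = length(sess$labels),
                 resubstitution_loss = normalized_loss(sess$labels,
                                                       tr_pred$label)),
            class = "wl_model")
}

#' @export
print.wl_model <- function(x, ...) {
  cat(sprintf("<wl_model> %s, bands %s, %d features\n", toupper(x$method),
              paste(x$bands, collapse = "+"), length(x$lda$weights)))
  cat(sprintf("  trained on %d epochs (%s); resubstitution loss %.3f\n",
              x$n_train_epochs, x$train_condition, x$resubstitution_loss))
  invisible(x)
}

#' @export
summary.wl_model <- function(object, ...) {
  print(object)
  for (b in object$bands) {
    bk <- object$banks[[b]]
    ev <- bk$eigenvalues
    cat(sprintf("  %s: %d components%s\n", b, ncol(bk$W),
                if (is.null(ev)) "" else
                  sprintf(", eigenvalues [%.3g .. %.3g]", max(ev), min(ev))))
  }
  cat(sprintf("  LDA shrinkage %.3g\n", object$lda$shrinkage_gamma))
  invisible(object)
}

#' @export
coef.wl_model <- function(object, ...) {
  stats::setNames(object$lda$weights, object$lda$feature_names)
}

#' Classify a session with a fitted workload model
#'
#' Applies the model's spatial filters and classifier to every epoch of a
#' new session in chronological order. For adaptive methods
#' (\code{"cspa"}/\code{"bfa"}) the filters are recomputed after each epoch
#' from the exponentially updated covariance (labels never read); each epoch
#' is classified before it enters the update. Non-adaptive methods apply
#' the trained filters unchanged.
#'
#' @param object a \code{\link{wl_fit}} model.
#' @param newdata \code{wl_session} or annotated \code{eeg_recording} with
#'   the same montage.
#' @param lam forgetting factor override (default: the model's).
#' @param ... unused.
#' @return data.frame with per-epoch \code{label} and
#'   \code{decision_value}.
#' @export
predict.wl_model <- function(object, newdata, lam = NULL, ...) {
  sess <- if (inherits(newdata, "wl_session")) newdata
          else prepare_session(newdata, object$bands)
  if (!identical(sess$channel_labels, object$channel_labels))
    stop("montage mismatch")
  core <- list(banks = object$banks, lda = object$lda,
               method = object$method, n_per_end = object$n_per_end)
  transfer_predict(core, sess, seq_len(object$n_train_epochs), sess,
                   lam %||% object$lam)
}

#' Plot spatial patterns of a fitted model
#'
#' Draws the forward pattern of selected components as a flat topographic
#' map (azimuthal-equidistant projection of the montage, points coloured by
#' pattern weight). Patterns — not filters — are what admit physiological
#' interpretation.
#'
#' @param x a \code{wl_model}.
#' @param band band to plot (default first).
#' @param components which components (default first 3).
#' @param montage \code{\link{eeg_montage}} for electrode positions; if
#'   NULL, a standard montage matching the channel count is built.
#' @param ... passed to \code{plot}.
#' @export
plot.wl_model <- function(x, band = x$bands[1], components = NULL,
                          montage = NULL, ...) {
  bk <- x$banks[[band]]
  if (is.null(components)) components <- seq_len(min(3, ncol(bk$A)))
  if (is.null(montage)) montage <- build_montage(length(x$channel_labels))
  pos <- montage$positions[match(x$channel_labels, montage$labels), ]
  th <- acos(pmax(-1, pmin(1, pos[, 3])))
  az <- atan2(pos[, 1], pos[, 2])
  px <- th * sin(az); py <- th * cos(az)
  old <- graphics::par(mfrow = c(1, length(components)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  for (k in components) {
    a <- bk$A[, k]
    col <- pal[pmin(64, pmax(1, round(32.5 + 31.5 * a / max(abs(a)))))]
    plot(px, py, pch = 21, bg = col, cex = 2, axes = FALSE, xlab = "",
         ylab = "", asp = 1,
         main = sprintf("%s %s comp %d", toupper(x$method), band, k), ...)
    tt <- seq(0, 2 * pi, length.out = 100)
    graphics::lines(pi / 2 * sin(tt), pi / 2 * cos(tt), col = "grey40")
    graphics::lines(c(-0.1, 0, 0.1), pi / 2 + c(0, 0.12, 0), col = "grey40")
  }
  invisible(x)
}
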