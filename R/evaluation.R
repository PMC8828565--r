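#' Prepare a session for training and evaluation
#'
#' Band-passes the recording into the requested bands, cuts 60-s epochs and
#' stores one sample covariance per epoch and band. All downstream training,
#' adaptation and log-variance feature extraction operate on these
#' channel x channel covariances, which makes cross-validation and per-epoch
#' filter re-decomposition cheap (the log-variance of a filtered epoch equals
#' \eqn{\mathrm{diag}(W^\top\Sigma_e W)} exactly).
#'
#' @param recording annotated broadband \code{\link{eeg_recording}}.
#' @param bands character vector of band names (default alpha + theta).
#' @param epoch_length_s epoch length (default 60 s).
#' @return Object of class \code{"wl_session"}.
#' @export
prepare_session <- function(recording, bands = c("alpha", "theta"),
                            epoch_length_s = 60) {
  stopifnot(inherits(recording, "eeg_recording"))
  covs <- list(); labels <- NULL; bids <- NULL; phs <- NULL
  for (b in bands) {
    filt <- bandpass(recording, band_spec(b))
    es <- epoch_recording(filt, epoch_length_s)
    d <- dim(es$epochs)
    st <- array(0, c(d[2L], d[2L], d[1L]))
    for (i in seq_len(d[1L]))
      st[, , i] <- epoch_sample_cov(matrix(es$epochs[i, , ], d[2L], d[3L]))
    covs[[b]] <- st
    labels <- es$labels; bids <- es$block_ids; phs <- es$phases
    rm(filt, es)
  }
  structure(list(covs = covs, labels = labels, block_ids = bids,
                 phases = phs,
                 condition = recording$annotations$condition[1],
                 n_channels = nrow(recording$data),
                 channel_labels = recording$channel_labels,
                 fs = recording$fs, epoch_length_s = epoch_length_s,
                 bands = bands),
            class = "wl_session")
}

#' @export
print.wl_session <- function(x, ...) {
  cat(sprintf("<wl_session> %s: %d epochs x %d channels, bands %s\n",
              x$condition, length(x$labels), x$n_channels,
              paste(x$bands, collapse = "+")))
  invisible(x)
}

# epoch-level Ledoit-Wolf intensity from a covariance stack (the epochs are
# the independent units; band-passed samples within an epoch are not)
lw_gamma_covs <- function(stack, idx = seq_len(dim(stack)[3L])) {
  E <- length(idx)
  Sbar <- apply(stack[, , idx, drop = FALSE], c(1, 2), mean)
  p <- nrow(Sbar)
  m <- sum(diag(Sbar)) / p
  d2 <- sum((Sbar - m * diag(p))^2)
  if (d2 < .Machine$double.eps || E < 2) return(0.01)
  b2 <- 0
  for (i in idx) b2 <- b2 + sum((stack[, , i] - Sbar)^2)
  b2 <- b2 / (E^2)
  max(0, min(1, min(b2, d2) / d2))
}

# mean covariance over selected epochs, with (analytic) shrinkage; the raw
# (unshrunk) mean rides along as an attribute so that adaptive variants can
# run the exponential update on raw covariances and re-apply the SAME
# shrinkage at every re-decomposition — keeping the filter normalisation
# (w' Sigma_den w = 1) consistent between training and adapted filters
pooled_cov <- function(stack, idx, gamma = NULL, band = "broadband") {
  Sbar <- apply(stack[, , idx, drop = FALSE], c(1, 2), mean)
  g <- if (is.null(gamma)) lw_gamma_covs(stack, idx) else gamma
  out <- cov_estimate(shrink_cov(Sbar, g), length(idx), g, band)
  attr(out, "raw") <- Sbar
  out
}

# train banks (per band) + LDA on the epochs in idx only
train_core <- function(sess, idx, method, leadfield = NULL, n_per_end = 3,
                       shrinkage_gamma = NULL, sigma_roi = NULL) {
  method <- match.arg(method, c("none", "csp", "cspa", "bf", "bfa"))
  base <- sub("a$", "", method)
  if (base == "bf" && is.null(sigma_roi)) {
    if (is.null(leadfield))
      stop("method bf/bfa needs a leadfield; build one with compute_leadfield()")
    sigma_roi <- roi_covariance(leadfield)
  }
  y <- sess$labels[idx]
  banks <- list(); feats <- NULL
  for (b in sess$bands) {
    st <- sess$covs[[b]]
    bank <- switch(base,
      none = identity_bank(sess$n_channels, b, sess$channel_labels),
      csp = {
        s1 <- pooled_cov(st, idx[y == "high"], shrinkage_gamma, b)
        s2 <- pooled_cov(st, idx[y == "low"], shrinkage_gamma, b)
        train_csp_cov(s1, s2, n_per_end, band = b)
      },
      bf = {
        sx <- pooled_cov(st, idx, shrinkage_gamma, b)
        train_beamformer(sigma_roi, sx)
      })
    banks[[b]] <- bank
    feats <- cbind(feats, logvar_from_covs(bank$W, st[, , idx, drop = FALSE]))
  }
  lda <- train_lda(feats, y)
  list(banks = banks, lda = lda, method = method, sigma_roi = sigma_roi,
       n_per_end = n_per_end)
}

# features for epochs idx under fixed banks
features_core <- function(sess, idx, banks) {
  feats <- NULL
  for (b in sess$bands)
    feats <- cbind(feats,
                   logvar_from_covs(banks[[b]]$W,
                                    sess$covs[[b]][, , idx, drop = FALSE]))
  feats
}

#' Class-wise normalized loss
#'
#' Mean of the two per-class misclassification rates (balanced error rate).
#' Chance level is 0.5 for a two-class problem regardless of class
#' imbalance; a constant predictor scores exactly 0.5.
#'
#' @param true_labels,predicted_labels character vectors
#'   (\code{"low"}/\code{"high"}).
#' @return loss in [0, 1].
#' @export
normalized_loss <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0 ||
      length(true_labels) != length(predicted_labels))
    stop("label vectors must be non-empty and of equal length")
  cls <- c("low", "high")
  if (!all(cls %in% true_labels)) stop("class missing; loss undefined")
  errs <- vapply(cls, function(k) {
    i <- true_labels == k
    mean(predicted_labels[i] != k)
  }, numeric(1))
  mean(errs)
}

#' Chronological leave-one-block-out cross-validation
#'
#' Within-condition validation honouring the autocorrelation of EEG:
#' chronologically contiguous blocks are held out in turn (one fold per
#' block for the n-back paradigm; phase-wise folds — train one repetition,
#' test the other — for the maneuver paradigm). Within each fold, spatial
#' filters and the classifier are fit on the training epochs only.
#'
#' @param x a \code{\link{prepare_session}} result or an annotated
#'   \code{eeg_recording}.
#' @param method one of \code{"none","csp","bf"} (the adaptive variants use
#'   the non-adaptive path within condition).
#' @param leadfield \code{\link{leadfield}}, required for \code{"bf"}.
#' @param n_per_end CSP filters per spectrum end (default 3).
#' @param shrinkage_gamma fixed covariance shrinkage (NULL = analytic).
#' @param bands,epoch_length_s used only when \code{x} is a recording.
#' @return Object of class \code{"eval_result"} with per-fold and mean
#'   normalized loss and fold sizes.
#' @export
blockwise_cv <- function(x, method = "none", leadfield = NULL, n_per_end = 3,
                         shrinkage_gamma = NULL,
                         bands = c("alpha", "theta"), epoch_length_s = 60) {
  sess <- if (inherits(x, "wl_session")) x
          else prepare_session(x, bands, epoch_length_s)
  method <- sub("a$", "", match.arg(method,
                                    c("none", "csp", "cspa", "bf", "bfa")))
  folds <- if (identical(sess$condition, "maneuver"))
    split(seq_along(sess$labels), sess$phases)
  else split(seq_along(sess$labels), sess$block_ids)
  if (length(folds) < 2) stop("need at least 2 blocks for cross-validation")
  sigma_roi <- if (method == "bf") {
    if (is.null(leadfield))
      stop("method bf/bfa needs a leadfield; build one with compute_leadfield()")
    roi_covariance(leadfield)
  } else NULL
  losses <- numeric(0); n_train <- integer(0); n_test <- integer(0)
  pooled_pred <- character(length(sess$labels))
  for (f in seq_along(folds)) {
    idx_test <- folds[[f]]
    idx_train <- setdiff(seq_along(sess$labels), idx_test)
    if (length(unique(sess$labels[idx_train])) < 2)
      stop("training fold contains a single class")
    core <- train_core(sess, idx_train, method, leadfield, n_per_end,
                       shrinkage_gamma, sigma_roi)
    pred <- predict(core$lda, features_core(sess, idx_test, core$banks))
    pooled_pred[idx_test] <- pred$label
    # a held-out block holds one class, so the per-fold entry is its plain
    # error rate; the class-wise normalized loss is computed on the pooled
    # out-of-fold predictions
    losses <- c(losses,
                if (all(c("low", "high") %in% sess$labels[idx_test]))
                  normalized_loss(sess$labels[idx_test], pred$label)
                else mean(pred$label != sess$labels[idx_test]))
    n_train <- c(n_train, length(idx_train))
    n_test <- c(n_test, length(idx_test))
  }
  res <- eval_result(losses, n_train, n_test,
                     scenario = list(train_condition = sess$condition,
                                     test_condition = sess$condition,
                                     method = method, within = TRUE))
  res$mean_loss <- normalized_loss(sess$labels, pooled_pred)
  res
}

#' Cross-condition transfer evaluation
#'
#' Trains spatial filters and the LDA classifier once on the full training
#' condition and applies them to the test condition epoch by epoch in
#' chronological order. For the adaptive variants (\code{"cspa"},
#' \code{"bfa"}) the denominator covariance is updated after each epoch by
#' the unsupervised exponential recursion and the filters are recomputed;
#' each epoch is classified before it enters the update. When the training
#' session is the two-phase maneuver paradigm, one model is trained per
#' phase and the resulting losses averaged; test losses are likewise
#' averaged over test phases.
#'
#' @param train_session,test_session \code{wl_session}s (or recordings);
#'   montages must match.
#' @param method \code{"none","csp","cspa","bf","bfa"}.
#' @param leadfield required for \code{"bf"}/\code{"bfa"}.
#' @param lam adaptation forgetting factor per 60-s epoch (default 0.1).
#' @param n_per_end,shrinkage_gamma as in \code{\link{blockwise_cv}}.
#' @param bands,epoch_length_s used when sessions are recordings.
#' @param details also return the trained model, the end-of-adaptation
#'   filter banks (the patterns the paper displays for the adaptive
#'   beamformer) and the per-epoch feature matrix.
#' @return \code{"eval_result"}; \code{per_fold_losses} holds one loss per
#'   test phase.
#' @export
transfer_evaluate <- function(train_session, test_session, method = "none",
                              leadfield = NULL, lam = 0.1, n_per_end = 3,
                              shrinkage_gamma = NULL,
                              bands = c("alpha", "theta"),
                              epoch_length_s = 60, details = FALSE) {
  tr <- if (inherits(train_session, "wl_session")) train_session
        else prepare_session(train_session, bands, epoch_length_s)
  te <- if (inherits(test_session, "wl_session")) test_session
        else prepare_session(test_session, bands, epoch_length_s)
  if (tr$n_channels != te$n_channels ||
      !identical(tr$channel_labels, te$channel_labels))
    stop("montage mismatch between sessions")
  method <- match.arg(method, c("none", "csp", "cspa", "bf", "bfa"))
  losses <- numeric(0); n_train <- integer(0); n_test <- integer(0)
  idx_tr <- seq_along(tr$labels)
  core <- train_core(tr, idx_tr, method, leadfield, n_per_end,
                     shrinkage_gamma)
  pl <- transfer_predict(core, tr, idx_tr, te, lam, details = details)
  pred <- if (details) pl$pred else pl
  for (tp in sort(unique(te$phases))) {
    i <- te$phases == tp
    losses <- c(losses, normalized_loss(te$labels[i], pred$label[i]))
    n_train <- c(n_train, length(idx_tr))
    n_test <- c(n_test, sum(i))
  }
  res <- eval_result(losses, n_train, n_test,
                     scenario = list(train_condition = tr$condition,
                                     test_condition = te$condition,
                                     method = method, within = FALSE))
  if (details) {
    res$model <- core
    res$final_banks <- pl$banks
    res$predictions <- pred
    res$features <- pl$features
  }
  res
}

# chronological prediction over the test session; adapts filters for
# cspa/bfa (classify first, then update — unsupervised throughout).
# details = TRUE also returns the evolving banks' end state and the
# per-epoch feature matrix (the paper-style end-of-adaptation patterns).
transfer_predict <- function(core, tr, idx_tr, te, lam, details = FALSE) {
  adaptive <- core$method %in% c("cspa", "bfa")
  if (!adaptive) {
    feats <- features_core(te, seq_along(te$labels), core$banks)
    pred <- predict(core$lda, feats)
    if (details)
      return(list(pred = pred, banks = core$banks, features = feats))
    return(pred)
  }
  banks <- core$banks
  states <- list()
  for (b in tr$bands) {
    den <- banks[[b]]$denominator_cov
    raw <- attr(den, "raw") %||% cov_mat(den)
    # the running covariance is the RAW exponential average (Eq.-9 semantics);
    # shrinkage is re-applied inside every re-decomposition
    init <- if (core$method == "cspa") {
      # pooled training covariance (Sigma_1 + Sigma_2)/2
      cov_estimate(raw / 2, length(idx_tr), den$shrinkage_gamma, b)
    } else cov_estimate(raw, length(idx_tr), den$shrinkage_gamma, b)
    states[[b]] <- adaptation_state(init, lam, core$method,
                                    n_per_end = core$n_per_end,
                                    anchor = banks[[b]]$W)
  }
  E <- length(te$labels)
  feats <- matrix(0, E, length(core$lda$weights))
  for (i in seq_len(E)) {
    off <- 0
    for (b in tr$bands) {
      k <- ncol(banks[[b]]$W)
      feats[i, off + seq_len(k)] <-
        logvar_from_covs(banks[[b]]$W,
                         te$covs[[b]][, , i, drop = FALSE])
      off <- off + k
    }
    for (b in tr$bands) {
      st <- states[[b]]
      st$running_cov <- cov_estimate(
        update_covariance_mat(st$running_cov$sigma, te$covs[[b]][, , i], lam),
        st$running_cov$n_epochs_seen + 1L, st$running_cov$shrinkage_gamma, b)
      st$epochs_consumed <- st$epochs_consumed + 1L
      banks[[b]] <- rebuild_bank(banks[[b]], st)
      states[[b]] <- st
    }
  }
  pred <- predict(core$lda, feats)
  if (details) return(list(pred = pred, banks = banks, features = feats))
  pred
}

eval_result <- function(per_fold_losses, n_train, n_test, scenario,
                        p_value = NA_real_) {
  stopifnot(all(per_fold_losses >= 0 & per_fold_losses <= 1))
  structure(list(per_fold_losses = per_fold_losses,
                 mean_loss = mean(per_fold_losses),
                 n_train = n_train, n_test = n_test, scenario = scenario,
                 p_value_vs_chance = p_value),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("<eval_result> %s %s->%s: mean normalized loss %.3f (%d folds)\n",
              toupper(sc$method), sc$train_condition, sc$test_condition,
              x$mean_loss, length(x$per_fold_losses)))
  invisible(x)
}

#' Wilcoxon signed-rank test against chance level
#'
#' Two-sided exact signed-rank test of per-subject mean losses against the
#' two-class chance level 0.5 (exact distribution for n <= 25, no ties).
#'
#' @param per_subject_mean_losses numeric vector, one mean loss per subject
#'   (>= 5 subjects).
#' @return p-value.
#' @export
wilcoxon_vs_chance <- function(per_subject_mean_losses) {
  x <- per_subject_mean_losses
  if (length(x) < 5) stop("need at least 5 subjects")
  if (all(x == 0.5)) stop("degenerate: all differences zero")
  stats::wilcox.test(x, mu = 0.5, alternative = "two.sided",
                     exact = length(x) <= 25)$p.value
}
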