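#' Read / write the native session container
#'
#' The native interchange format is R serialization (RDS) of the recording
#' object — data, sampling rate, montage labels, reference and block
#' annotations round-trip bitwise. Vendor formats are import-only.
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{write_recording}: the path, invisibly;
#'   \code{read_recording}: the recording.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "eeg_recording")) stop("not an eeg_recording container")
  x
}

#' Import an EEG recording
#'
#' Dispatches on format: the native RDS container, BrainVision
#' (\code{.vhdr} header + \code{.vmrk} markers + binary \code{.eeg}) or EDF.
#' Channel labels are validated against the 10/10 vocabulary with a warning
#' for unknown names; 32-channel files resolve to the montage subset.
#'
#' @param path file path (\code{.vhdr} for BrainVision).
#' @param format \code{"auto"} (by extension), \code{"brainvision"},
#'   \code{"edf"} or \code{"rds"}.
#' @return an \code{\link{eeg_recording}}.
#' @export
import_recording <- function(path, format = c("auto", "brainvision", "edf",
                                              "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", edf = "edf", rds = "rds",
                     stop("cannot infer format from extension: ", ext))
  }
  rec <- switch(format,
                brainvision = read_brainvision(path),
                edf = read_edf(path),
                rds = read_recording(path))
  unknown <- setdiff(rec$channel_labels, rownames(montage_positions_64()))
  if (length(unknown) > 0)
    warning("channel labels outside the 10/10 vocabulary: ",
            paste(unknown, collapse = ", "))
  rec
}

# --- BrainVision ------------------------------------------------------------

parse_ini <- function(lines) {
  sec <- NULL; out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character(0)
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      k <- trimws(sub("=.*$", "", ln))
      v <- trimws(sub("^[^=]*=", "", ln))
      out[[sec]][k] <- v
    }
  }
  out
}

read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("missing header file: ", vhdr_path)
  ini <- parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  dirn <- dirname(vhdr_path)
  data_file <- file.path(dirn, ci[["DataFile"]])
  if (!file.exists(data_file)) stop("missing data file: ", data_file)
  ini_get <- function(sec, key)
    if (!is.null(sec) && key %in% names(sec)) sec[[key]] else NULL
  nchan <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  orient <- ini_get(ci, "DataOrientation")
  if (!is.null(orient) && toupper(orient) != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision data supported")
  chinfo <- ini[["Channel Infos"]]
  labels <- character(nchan); res <- rep(1, nchan)
  for (i in seq_len(nchan)) {
    parts <- strsplit(chinfo[[sprintf("Ch%d", i)]], ",")[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }
  fmt <- toupper(ini_get(bi, "BinaryFormat") %||% "IEEE_FLOAT_32")
  sz <- file.info(data_file)$size
  con <- file(data_file, "rb"); on.exit(close(con))
  raw <- if (fmt == "INT_16") {
    ns <- sz / 2
    matrix(readBin(con, "integer", n = ns, size = 2, endian = "little"),
           nrow = nchan) * res
  } else if (fmt == "IEEE_FLOAT_32") {
    ns <- sz / 4
    matrix(readBin(con, "double", n = ns, size = 4, endian = "little"),
           nrow = nchan)
  } else stop("unsupported BinaryFormat: ", fmt)
  ann <- block_annotations()
  mf <- ini_get(ci, "MarkerFile")
  if (!is.null(mf) && !is.na(mf)) {
    mpath <- file.path(dirn, mf)
    if (!file.exists(mpath)) stop("missing marker file: ", mpath)
    ann <- tryCatch(parse_vmrk(mpath, fs, ncol(raw)),
                    error = function(e) {
                      warning("unparseable markers: ", conditionMessage(e))
                      block_annotations()
                    })
  }
  eeg_recording(raw, fs, labels, annotations = ann)
}

# markers whose description names a class ("low"/"high", optionally a
# condition and phase, e.g. "high/maneuver/2") open a block that runs to the
# next such marker or the end of data
parse_vmrk <- function(path, fs, n_samples) {
  ini <- parse_ini(readLines(path, warn = FALSE))
  mk <- ini[["Marker Infos"]]
  starts <- numeric(0); labs <- character(0); conds <- character(0)
  phases <- integer(0)
  for (k in names(mk)) {
    if (!grepl("^Mk[0-9]+$", k)) next
    parts <- strsplit(mk[[k]], ",")[[1]]
    desc <- tolower(parts[2])
    lab <- if (grepl("high", desc)) "high" else if (grepl("low", desc)) "low"
           else next
    starts <- c(starts, (as.numeric(parts[3]) - 1) / fs)
    labs <- c(labs, lab)
    conds <- c(conds, if (grepl("maneuver", desc)) "maneuver" else "nback")
    ph <- suppressWarnings(as.integer(sub(".*/(\\d+)$", "\\1", desc)))
    phases <- c(phases, if (is.na(ph)) 1L else ph)
  }
  if (length(starts) == 0) return(block_annotations())
  o <- order(starts)
  ends <- c(starts[o][-1], n_samples / fs)
  block_annotations(starts[o], ends, labs[o], conds[o], phases[o])
}

# --- EDF --------------------------------------------------------------------

read_edf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(nch) trimws(rawToChar(readBin(con, "raw", nch)))
  rd(8); rd(80); rd(80); rd(8); rd(8)  # version, patient, recording, date, time
  rd(8)                                # header bytes
  rd(44)                               # reserved
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)        # transducer type
  for (i in seq_len(ns)) rd(8)         # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)        # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)        # reserved
  if (length(unique(nsamp)) != 1)
    stop("signals with differing sampling rates not supported")
  fs <- nsamp[1] / dur
  scale <- (pmax - pmin) / (dmax - dmin)
  X <- matrix(0, ns, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = nsamp[s], size = 2, endian = "little")
      X[s, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <-
        pmin[s] + (d - dmin[s]) * scale[s]
    }
  }
  eeg_recording(X, fs, labels)
}

# --- exports ----------------------------------------------------------------

#' Export spatial patterns as CSV
#'
#' One row per (channel, component) with the pattern weight — the format
#' used for topographic plotting outside R.
#'
#' @param bank a \code{\link{filter_bank}} (or a \code{wl_model}, exporting
#'   every band).
#' @param path output CSV path.
#' @param channel_labels labels for the rows of A.
#' @return the path, invisibly.
#' @export
export_patterns_csv <- function(bank, path, channel_labels = NULL) {
  rows <- NULL
  banks <- if (inherits(bank, "wl_model")) bank$banks else list(band = bank)
  if (inherits(bank, "wl_model") && is.null(channel_labels))
    channel_labels <- bank$channel_labels
  for (b in names(banks)) {
    A <- banks[[b]]$A
    labs <- channel_labels %||% sprintf("ch%02d", seq_len(nrow(A)))
    for (k in seq_len(ncol(A)))
      rows <- rbind(rows, data.frame(band = b, component = k, channel = labs,
                                     weight = A[, k]))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export a feature matrix as CSV
#' @param features a \code{\link{feature_matrix}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_features_csv <- function(features, path) {
  df <- data.frame(epoch_id = seq_len(nrow(features$values)),
                   block_id = features$block_ids, label = features$labels,
                   features$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export / import a fitted classifier as JSON
#'
#' Serializes LDA weights, bias, feature names and class order (and for a
#' full model, method and bands) so a fit can be audited or reused outside
#' R. \code{read_model_json} restores an \code{lda_model}.
#'
#' @param model \code{lda_model} or \code{wl_model}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
export_model_json <- function(model, path) {
  lda <- if (inherits(model, "wl_model")) model$lda else model
  obj <- list(weights = lda$weights, bias = lda$bias,
              class_order = lda$class_order,
              feature_names = lda$feature_names)
  if (inherits(model, "wl_model"))
    obj <- c(obj, list(method = model$method, bands = model$bands,
                       lam = model$lam))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(obj$weights), bias = obj$bias,
                 class_order = obj$class_order,
                 feature_names = obj$feature_names,
                 shrinkage_gamma = NA_real_),
            class = "lda_model")
}
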