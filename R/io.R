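# Recording and feature-table I/O.
#
# EDF support is a minimal, self-contained subset of the European Data
# Format: one data record per second, 16-bit samples, physical scaling from
# per-channel extrema. Delimited text (CSV, channels as columns) plus a
# key=value sidecar covers hand-made fixtures. Amplitudes are microvolts
# end-to-end.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to disk
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param format `"edf"` (16-bit European Data Format) or `"csv"` (delimited
#'   text, channels as columns, plus a `<path>.meta` key=value sidecar with
#'   `fs`, `subject_id`, `state_id`, `duration`).
#'
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "csv") return(write_recording_csv(rec, path))
  write_recording_edf(rec, path)
}

write_recording_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(sprintf("fs=%.10g", rec$fs),
            sprintf("subject_id=%s", rec$subject_id),
            sprintf("state_id=%d", rec$state_id),
            sprintf("duration=%.10g", rec$duration))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

write_recording_edf <- function(rec, path) {
  data <- rec$data
  ns <- nrow(data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop_param("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n <- ncol(data)
  n_rec <- floor(n / fs)
  if (n_rec < 1) stop_param("recording shorter than one EDF data record (1 s)")
  n_use <- n_rec * fs

  pmin_ <- apply(data[, seq_len(n_use), drop = FALSE], 1, min)
  pmax_ <- apply(data[, seq_len(n_use), drop = FALSE], 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste(rec$subject_id, "state", rec$state_id), 80),
    edf_pad("eegfatigue synthetic", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) writeChar(paste0(edf_pad(vals, width),
                                                  collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.8g", pmin_), 8)
  field(sprintf("%.8g", pmax_), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - pmin_[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path.
#' @param format `"edf"` or `"csv"`; guessed from the file extension when
#'   missing.
#'
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read recording: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  format <- match.arg(format, c("edf", "csv"))
  if (format == "csv") read_recording_csv(path) else read_recording_edf(path)
}

read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("empty recording file: ", path, call. = FALSE)
  m <- t(as.matrix(df))
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop("recording contains non-finite or non-numeric values: ", path,
         call. = FALSE)
  meta_path <- paste0(path, ".meta")
  meta <- list(fs = NA, subject_id = "unknown", state_id = 0L)
  if (file.exists(meta_path)) {
    for (ln in readLines(meta_path)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
    }
  }
  if (is.na(meta$fs)) stop("no sampling rate: missing sidecar ", meta_path,
                           call. = FALSE)
  fs <- as.numeric(meta$fs)
  structure(list(data = m, fs = fs, channel_labels = rownames(m),
                 subject_id = as.character(meta$subject_id),
                 state_id = as.integer(meta$state_id),
                 duration = ncol(m) / fs),
            class = "eeg_recording")
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: ", path, call. = FALSE)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr)))
    stop("malformed EDF signal headers: ", path, call. = FALSE)

  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      if (length(dig) < spr[ch]) stop("truncated EDF data: ", path, call. = FALSE)
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (dig - dmin_[ch]) * scale[ch] + pmin_[ch]
    }
  }
  fs <- spr[1] / rec_dur
  sid <- sub("^(\\S+).*$", "\\1", patient)
  state <- if (grepl("state ([0-9])", patient)) {
    as.integer(sub(".*state ([0-9]).*", "\\1", patient))
  } else 0L
  rownames(data) <- labels
  structure(list(data = data, fs = fs, channel_labels = labels,
                 subject_id = sid, state_id = state,
                 duration = ncol(data) / fs),
            class = "eeg_recording")
}

#' Feature-table column names
#'
#' Deterministic feature column order: channels in montage order, features in
#' the fixed order delta, theta, alpha, beta band power then fuzzy entropy.
#'
#' @param channel_labels Channel names.
#' @return Character vector of `5 * length(channel_labels)` names.
#' @export
feature_names <- function(channel_labels = montage_1020()) {
  feats <- c("rbp_delta", "rbp_theta", "rbp_alpha", "rbp_beta", "fuzzyen")
  as.vector(t(outer(channel_labels, feats, paste, sep = "_")))
}

#' Validate a feature table
#'
#' Checks the feature-table contract: metadata columns `subject_id`,
#' `state_id`, `role` present, all other columns numeric features with no
#' missing values, and (for 19-channel data) exactly 95 feature columns.
#'
#' @param table Data frame.
#' @return The table, invisibly; errors on violation.
#' @export
validate_feature_table <- function(table) {
  meta <- c("subject_id", "state_id", "role")
  if (!all(meta %in% names(table)))
    stop_param("feature table must have subject_id, state_id, role columns")
  fcols <- setdiff(names(table), meta)
  if (nrow(table)) {
    fm <- as.matrix(table[fcols])
    if (!is.numeric(fm) || anyNA(fm))
      stop_param("feature columns must be numeric with no missing values")
  }
  invisible(table)
}

#' Write a feature table as CSV
#'
#' Comma-separated text with a stable column order (feature columns first, in
#' channel-major order, then `subject_id`, `state_id`, `role`). Values are
#' written with 15 significant digits so the file round-trips losslessly.
#'
#' @param table Feature table (see [validate_feature_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  meta <- c("subject_id", "state_id", "role")
  fcols <- setdiff(names(table), meta)
  out <- table[c(fcols, meta)]
  for (cl in fcols) out[[cl]] <- formatC(out[[cl]], digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Feature table data frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  if ("state_id" %in% names(df)) df$state_id <- as.integer(df$state_id)
  validate_feature_table(df)
  df
}
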