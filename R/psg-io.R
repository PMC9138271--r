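#' Multichannel polysomnography recording
#'
#' Container for sampled physiological signals (EEG, airflow, SpO2, RR).
#' Channels may have different sampling rates but must span the same duration.
#'
#' @param channels Named list of numeric vectors (samples). EEG channels are in
#'   microvolts; other channels in native units.
#' @param fs Sampling rate in Hz: a single number applied to all channels, or a
#'   named numeric vector with one entry per channel.
#' @param start_time Recording start clock time, `"HH:MM:SS"`.
#' @return An object of class `psg_recording`.
#' @export
recording <- function(channels, fs, start_time = "22:00:00") {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  if (length(fs) == 1L) {
    fs <- stats::setNames(rep(as.numeric(fs), length(channels)), names(channels))
  }
  if (!all(names(channels) %in% names(fs))) {
    stop("every channel needs a sampling rate")
  }
  fs <- fs[names(channels)]
  if (any(fs <= 0)) stop("sampling rates must be positive")
  dur <- vapply(names(channels), function(ch) length(channels[[ch]]) / fs[[ch]],
                numeric(1))
  if (diff(range(dur)) > 1 / min(fs)) {
    stop("all channels must span the same duration")
  }
  structure(list(channels = channels, fs = fs, start_time = start_time),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", round(duration(x) / 3600, 2), "h, channels: ",
      paste(sprintf("%s@%gHz", names(x$channels), x$fs), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `psg_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(rec) {
  ch <- names(rec$channels)[1]
  length(rec$channels[[ch]]) / rec$fs[[ch]]
}

#' Sleep-stage hypnogram
#'
#' Ordered stage labels, one per scoring epoch (default 30 s), using the AASM
#' vocabulary W/N1/N2/N3/REM.
#'
#' @param stages Character vector of stage labels.
#' @param epoch_s Epoch length in seconds.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  structure(list(stages = stages, epoch_s = epoch_s), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x$stages), " epochs x ", x$epoch_s, "s: ",
      paste(sprintf("%s=%d", names(table(x$stages)), as.integer(table(x$stages))),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Total sleep time of a hypnogram in hours (non-W epochs)
#' @param hyp A `hypnogram`.
#' @return Hours of sleep.
#' @export
sleep_hours <- function(hyp) {
  sum(hyp$stages != "W") * hyp$epoch_s / 3600
}

#' Assign a subject to an OSA severity group by RDI cutoff
#'
#' Subjects at or below the cutoff (default 15 events/h) form the low group,
#' the rest the high group. The boundary value goes to the low group, matching
#' the "RDI <= 15/h" group label.
#'
#' @param rdi Respiratory disturbance index, events per hour (>= 0).
#' @param cutoff Group cutoff in events/h.
#' @return `"RDI<=15"` or `"RDI>15"` (with the configured cutoff substituted).
#' @export
assign_group <- function(rdi, cutoff = 15) {
  if (any(rdi < 0)) stop("RDI must be non-negative")
  ifelse(rdi <= cutoff, paste0("RDI<=", cutoff), paste0("RDI>", cutoff))
}

# ---- EDF (European Data Format) -------------------------------------------
# Minimal EDF codec: fixed 256-byte header + 256 bytes per signal, data records
# of little-endian int16 with per-signal physical min/max scaling. One-second
# records; per-channel samples-per-record carries unequal sampling rates.

edf_pad <- function(x, width) {
  x <- as.character(x)
  formatC(substr(x, 1, width), width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param rec A `psg_recording`. Duration must be a whole number of seconds and
#'   all sampling rates whole numbers per second (EDF record = 1 s here).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  ns <- length(rec$channels)
  dur <- duration(rec)
  if (abs(dur - round(dur)) > 1e-9) stop("EDF export needs whole-second duration")
  n_rec <- as.integer(round(dur))
  spr <- as.integer(round(rec$fs))   # samples per 1-s record
  if (any(abs(rec$fs - spr) > 1e-9)) stop("EDF export needs integer Hz rates")

  labels <- names(rec$channels)
  pmin <- pmax <- numeric(ns)
  digmin <- -32768L; digmax <- 32767L
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]
    pmin[i] <- min(x); pmax[i] <- max(x)
    if (pmax[i] <= pmin[i]) pmax[i] <- pmin[i] + 1  # constant channel guard
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad("X X X X", 80),                # patient id (anonymous)
    edf_pad("Startdate X X X X", 80),      # recording id
    edf_pad("01.01.26", 8),                # start date (synthetic)
    edf_pad(gsub(":", ".", rec$start_time), 8),
    edf_pad(256 * (ns + 1), 8),            # header bytes
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),                       # record duration, s
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(labels, 16)
  field(rep("", ns), 80)                   # transducer
  field(rep("", ns), 8)                    # physical dimension
  field(formatC(pmin, format = "g", digits = 7), 8)
  field(formatC(pmax, format = "g", digits = 7), 8)
  field(rep(digmin, ns), 8)
  field(rep(digmax, ns), 8)
  field(rep("", ns), 80)                   # prefiltering
  field(spr, 8)
  field(rep("", ns), 32)                   # reserved

  scale <- (pmax - pmin) / (digmax - digmin)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- round((rec$channels[[i]] - pmin[i]) / scale[i]) + digmin
    dig[[i]] <- as.integer(pmin(pmax(d, digmin), digmax))
  }
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param require_channels Channel labels that must be present; a missing one
#'   raises an error naming it.
#' @return A `psg_recording`.
#' @export
read_edf <- function(path, require_channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  ver <- rd(8)
  if (!nzchar(ver) || ver != "0") stop("malformed EDF header (version field)")
  rd(80); rd(80); rd(8)
  start_time <- gsub("\\.", ":", rd(8))
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1) {
    stop("malformed EDF header")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  if (!is.null(require_channels)) {
    miss <- setdiff(require_channels, labels)
    if (length(miss)) {
      stop("required channel(s) missing from EDF: ", paste(miss, collapse = ", "))
    }
  }
  chans <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      chans[[i]][idx] <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
  }
  names(chans) <- labels
  recording(chans, fs = stats::setNames(spr / rec_dur, labels),
            start_time = start_time)
}

#' Read a PSG recording and its sidecar hypnogram
#'
#' Loads an EDF file and, when present, the companion hypnogram CSV
#' (`<stem>_hypnogram.csv`, columns `epoch,stage`).
#'
#' @param path EDF file path.
#' @param require_channels Channels that must be present (default the two
#'   central EEG derivations).
#' @return List with elements `recording` and `hypnogram` (`NULL` if absent).
#' @export
read_psg <- function(path, require_channels = c("C3-M1", "C4-M2")) {
  rec <- read_edf(path, require_channels = require_channels)
  hyp_path <- paste0(sub("\\.edf$", "", path, ignore.case = TRUE),
                     "_hypnogram.csv")
  hyp <- if (file.exists(hyp_path)) read_hypnogram_csv(hyp_path) else NULL
  list(recording = rec, hypnogram = hyp)
}

#' Write a hypnogram as a two-column CSV (epoch index, stage)
#' @param hyp A `hypnogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(
    data.frame(epoch = seq_along(hyp$stages) - 1L, stage = hyp$stages),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV written by [write_hypnogram_csv()]
#' @param path CSV path with columns `epoch,stage`.
#' @param epoch_s Epoch length in seconds.
#' @return A `hypnogram`.
#' @export
read_hypnogram_csv <- function(path, epoch_s = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch", "stage") %in% names(df)))
  hypnogram(df$stage[order(df$epoch)], epoch_s = epoch_s)
}
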