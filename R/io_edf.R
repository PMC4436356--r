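# Minimal EDF+ I/O for continuous recordings.
#
# Implements the subset of the EDF/EDF+ specification the screening
# pipeline needs: 16-bit data records of fixed 1-s duration, per-signal
# physical/digital scaling, and a single "EDF Annotations" signal carrying
# time-stamped annotation lists (TALs) for the cue events. Each cue is
# written as a TAL whose first annotation is the task code and whose second
# annotation carries the run index ("run <k>").

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF+ file
#'
#' Signals are scaled to the full 16-bit digital range using a symmetric
#' physical range covering the data; cue events are stored as EDF+
#' annotations. Recordings are padded with zeros to a whole number of 1-s
#' data records.
#'
#' @param rec A `session_recording`.
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  sr <- rec$sampling_rate
  if (sr != round(sr)) stop_mt("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$signals)
  n_rec <- ceiling(ncol(rec$signals) / sr)
  ann_samples <- 64L                       # 128 bytes of TAL space per record

  pm <- max(abs(rec$signals), 1e-12)
  pmax <- signif(pm * 1.01, 6)
  dmax <- 32767
  scale <- dmax / pmax

  # TALs per record; each TAL is NUL-terminated, so bytes are built raw
  onsets <- rec$events$sample / sr
  rec_of_event <- floor(onsets)            # record index (0-based) of each cue
  tals <- lapply(seq_len(n_rec) - 1L, function(r) {
    parts <- sprintf("+%d\x14\x14", r)
    idx <- which(rec_of_event == r)
    for (i in idx) {
      parts <- c(parts, sprintf("+%.6f\x14%s\x14run %d\x14",
                                onsets[i], rec$events$task[i],
                                rec$events$run[i]))
    }
    unlist(lapply(parts, function(p) c(charToRaw(p), as.raw(0))))
  })
  if (any(lengths(tals) > 2 * ann_samples)) {
    stop_mt("annotation overflow: too many events in one data record")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad((ns + 2) * 256, 8),
    edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns + 1, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- function(field, width) {
    for (lab in c(rec$channel_labels, "EDF Annotations")) {
      writeChar(edf_pad(field(lab), width), con, eos = NULL)
    }
  }
  sig_hdr(function(l) l, 16)                                    # label
  sig_hdr(function(l) "", 80)                                   # transducer
  sig_hdr(function(l) if (l == "EDF Annotations") "" else "uV", 8)
  sig_hdr(function(l) if (l == "EDF Annotations") -1 else -pmax, 8)
  sig_hdr(function(l) if (l == "EDF Annotations") 1 else pmax, 8)
  sig_hdr(function(l) -32767, 8)                                # dig min
  sig_hdr(function(l) 32767, 8)                                 # dig max
  sig_hdr(function(l) if (l == "EDF Annotations") "" else "BP 0.5-100 Hz", 80)
  sig_hdr(function(l) if (l == "EDF Annotations") ann_samples else sr, 8)
  sig_hdr(function(l) "", 32)                                   # reserved

  padded <- cbind(rec$signals,
                  matrix(0, ns, n_rec * sr - ncol(rec$signals)))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sr + 1):(r * sr)
    dig <- round(t(padded[, cols, drop = FALSE]) * scale)       # samples x ch
    dig <- pmin(pmax(dig, -32767), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
    tal_raw <- tals[[r]]
    writeBin(c(tal_raw, raw(2 * ann_samples - length(tal_raw))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a session recording
#'
#' Reads 16-bit data records, applies per-signal physical scaling, and
#' parses EDF+ annotations into cue events. Annotations whose first text
#' field is not one of the five task codes are reported as an error unless
#' they are auxiliary "run <k>" tags.
#'
#' @param path Path to the `.edf` file.
#' @param day Day tag to attach (EDF carries no day field); default 1.
#' @return A `session_recording`.
#' @export
read_edf <- function(path, day = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8 + 8 + 44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns_all <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns_all), function(i) rd(16), ""))
  rd(80 * ns_all)                          # transducer
  rd(8 * ns_all)                           # dimension
  pmin_ <- as.numeric(vapply(seq_len(ns_all), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns_all), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns_all), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns_all), function(i) rd(8), ""))
  rd(80 * ns_all)                          # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns_all), function(i) rd(8), ""))
  rd(32 * ns_all)

  is_ann <- labels == "EDF Annotations"
  data_idx <- which(!is_ann)
  sr <- nsamp[data_idx[1]] / rec_dur
  signals <- matrix(0, length(data_idx), n_rec * nsamp[data_idx[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns_all)) {
      if (is_ann[s]) {
        raw_block <- readBin(con, "raw", 2 * nsamp[s])
        zeros <- raw_block == as.raw(0)
        grp <- cumsum(c(TRUE, zeros[-length(zeros)]))   # new TAL after each NUL
        pieces <- split(raw_block[!zeros], grp[!zeros])
        ann_text <- c(ann_text, vapply(pieces, rawToChar, ""))
      } else {
        dig <- readBin(con, "integer", nsamp[s], size = 2, endian = "little")
        g <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
        j <- match(s, data_idx)
        signals[j, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <-
          pmin_[s] + g * (dig - dmin_[s])
      }
    }
  }

  events <- data.frame(sample = integer(0), task = character(0),
                       run = integer(0), stringsAsFactors = FALSE)
  bad_ann <- character(0)
  for (tal in ann_text) {
    {
      if (!nzchar(tal)) next
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) < 2 || !nzchar(parts[2])) next   # record timestamp TAL
      onset <- as.numeric(sub("\x15.*$", "", parts[1]))
      text <- parts[2]
      if (!text %in% mt_tasks()) {
        bad_ann <- c(bad_ann, text)
        next
      }
      run <- if (length(parts) >= 3 && grepl("^run ", parts[3])) {
        as.integer(sub("^run ", "", parts[3]))
      } else NA_integer_
      events <- rbind(events, data.frame(
        sample = as.integer(round(onset * sr)), task = text, run = run,
        stringsAsFactors = FALSE))
    }
  }
  if (length(bad_ann) > 0) {
    stop_mt("unknown task annotation(s): %s",
            paste(unique(bad_ann), collapse = ", "))
  }
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL
  rownames(signals) <- labels[data_idx]
  structure(list(
    signals = signals,
    sampling_rate = sr,
    channel_labels = labels[data_idx],
    events = events,
    artifact_marks = data.frame(trial_index = integer(0), kind = character(0)),
    day = day
  ), class = "session_recording")
}
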