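# Minimal EDF+ reader/writer: 16-bit continuous EDF with an
# "EDF Annotations" signal carrying movement-onset TALs.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x, call. = FALSE)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  pad_ascii(s, width)
}

#' Write a recording to EDF+
#'
#' Continuous EDF+ ("EDF+C") with one-second data records, 16-bit samples,
#' and an `EDF Annotations` signal holding one `movement` annotation per
#' onset. Each channel is scaled into a symmetric integer physical range
#' covering its data, so the round-trip error is at most one quantization
#' step. A trailing partial second is zero-padded.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- as.integer(rec$rate)
  labels <- rec$channel_labels
  if (anyDuplicated(labels)) stop("channel labels must be unique",
                                  call. = FALSE)
  sig <- rec$data
  dims <- rep("uV", nrow(sig))
  if (!is.null(rec$force)) {
    sig <- rbind(sig, rec$force)
    labels <- c(labels, "Force")
    dims <- c(dims, "N")
  }
  ns_data <- nrow(sig)
  n <- ncol(sig)
  n_rec <- as.integer(ceiling(n / rate))
  ann_len <- 60L  # bytes per record for the annotation signal

  # symmetric integer physical range per channel
  amp <- apply(sig, 1L, function(x) max(1, ceiling(max(abs(x)))))
  dig_max <- 32767L; dig_min <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad_ascii("0", 8L), con, eos = NULL)
  writeChar(pad_ascii("X X X X", 80L), con, eos = NULL)
  writeChar(pad_ascii("Startdate 01-JAN-2000 X X X", 80L), con, eos = NULL)
  writeChar(pad_ascii("01.01.00", 8L), con, eos = NULL)
  writeChar(pad_ascii("00.00.00", 8L), con, eos = NULL)
  writeChar(pad_ascii((ns_data + 2L) * 256L, 8L), con, eos = NULL)
  writeChar(pad_ascii("EDF+C", 44L), con, eos = NULL)
  writeChar(pad_ascii(n_rec, 8L), con, eos = NULL)
  writeChar(pad_ascii("1", 8L), con, eos = NULL)
  writeChar(pad_ascii(ns_data + 1L, 4L), con, eos = NULL)

  all_labels <- c(labels, "EDF Annotations")
  field <- function(vals, width) {
    for (v in vals) writeChar(pad_ascii(v, width), con, eos = NULL)
  }
  field(all_labels, 16L)
  field(rep("", ns_data + 1L), 80L)                       # transducer
  field(c(dims, ""), 8L)                                  # physical dim
  field(c(sprintf("-%d", amp), "-1"), 8L)                 # phys min
  field(c(sprintf("%d", amp), "1"), 8L)                   # phys max
  field(rep("-32768", ns_data + 1L), 8L)                  # dig min
  field(rep("32767", ns_data + 1L), 8L)                   # dig max
  field(rep("", ns_data + 1L), 80L)                       # prefiltering
  field(c(rep(rate, ns_data), ann_len %/% 2L), 8L)        # samples/record
  field(rep("", ns_data + 1L), 32L)                       # reserved

  scale <- (dig_max - dig_min) / (2 * amp)
  onsets <- rec$onsets %||% numeric(0)
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * rate
    for (s in seq_len(ns_data)) {
      x <- numeric(rate)
      avail <- min(rate, n - i0)
      if (avail > 0L) x[seq_len(avail)] <- sig[s, i0 + seq_len(avail)]
      d <- as.integer(round((x - (-amp[s])) * scale[s]) + dig_min)
      d <- pmin(pmax(d, dig_min), dig_max)
      writeBin(d, con, size = 2L, endian = "little")
    }
    tal <- sprintf("+%d\x14\x14\x01", r - 1L)  # placeholder, \x01 -> NUL below
    in_rec <- onsets[onsets >= (r - 1L) & onsets < r]
    for (on in in_rec) {
      tal <- paste0(tal, sprintf("+%.4f\x14movement\x14\x01", on))
    }
    raw_tal <- charToRaw(tal)
    raw_tal[raw_tal == as.raw(1L)] <- as.raw(0L)   # TAL terminators
    if (length(raw_tal) > ann_len) stop("annotation block overflow",
                                        call. = FALSE)
    writeBin(c(raw_tal, raw(ann_len - length(raw_tal))), con)
  }
  invisible(path)
}

read_field <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }, character(1))
}

#' Read an EDF+ recording
#'
#' Parses the header, rescales every ordinary signal to physical units, and
#' collects `movement` annotations from the `EDF Annotations` signal as
#' onset times in seconds. A channel labelled `Force` is returned in the
#' `force` slot rather than the EEG data matrix.
#'
#' @param path Path to an EDF/EDF+ file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  read_field(con, 8L)                      # version
  read_field(con, 80L); read_field(con, 80L)
  read_field(con, 8L); read_field(con, 8L)
  read_field(con, 8L)                      # header bytes
  read_field(con, 44L)                     # reserved
  n_rec <- as.integer(read_field(con, 8L))
  rec_dur <- as.numeric(read_field(con, 8L))
  ns <- as.integer(read_field(con, 4L))

  labels <- read_field(con, 16L, ns)
  read_field(con, 80L, ns)
  dims <- read_field(con, 8L, ns)
  pmin <- as.numeric(read_field(con, 8L, ns))
  pmax <- as.numeric(read_field(con, 8L, ns))
  dmin <- as.numeric(read_field(con, 8L, ns))
  dmax <- as.numeric(read_field(con, 8L, ns))
  read_field(con, 80L, ns)
  spr <- as.integer(read_field(con, 8L, ns))
  read_field(con, 32L, ns)

  is_ann <- labels == "EDF Annotations"
  data_idx <- which(!is_ann)
  rate <- spr[data_idx[1L]] / rec_dur
  sig <- matrix(0, nrow = length(data_idx), ncol = n_rec * spr[data_idx[1L]])
  onsets <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        raw_tal <- readBin(con, "raw", spr[s] * 2L)
        txt <- rawToChar(raw_tal[raw_tal != as.raw(0L)])
        tals <- strsplit(txt, "\x14\x14|\x14")[[1L]]
        for (k in seq_along(tals)) {
          if (k < length(tals) && tals[k + 1L] == "movement") {
            onsets <- c(onsets, as.numeric(sub("\x15.*$", "", tals[k])))
          }
        }
      } else {
        d <- readBin(con, "integer", spr[s], size = 2L, endian = "little")
        row <- match(s, data_idx)
        g <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
        sig[row, (r - 1L) * spr[s] + seq_len(spr[s])] <-
          (d - dmin[s]) * g + pmin[s]
      }
    }
  }
  lab <- labels[data_idx]
  force <- NULL
  fi <- which(lab == "Force")
  if (length(fi) == 1L) {
    force <- sig[fi, ]
    sig <- sig[-fi, , drop = FALSE]
    lab <- lab[-fi]
  }
  rownames(sig) <- lab
  structure(list(data = sig, rate = rate, channel_labels = lab,
                 force = force,
                 onsets = if (length(onsets)) sort(unique(onsets)) else NULL,
                 meta = list(), truth = NULL, seed = NULL),
            class = "eeg_recording")
}
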