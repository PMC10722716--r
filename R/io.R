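pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write an EEG recording as EDF
#'
#' European Data Format: 16-bit integers with per-channel physical/digital
#' scaling, one-second data records, physical unit uV. Partial trailing
#' seconds are truncated.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- rec$rate                       # one-second records
  nrec <- floor(ncol(rec$data) / spr)
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  if (nrec * spr < ncol(rec$data))
    warning("truncating partial trailing second (",
            ncol(rec$data) - nrec * spr, " samples)")
  X <- rec$data[, seq_len(nrec * spr), drop = FALSE]
  pmax_v <- pmax(apply(abs(X), 1, max), 1e-6)
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(nrec, 8); wr(1, 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(rownames(X)[i], 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", -pmax_v[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmax_v[i]), 8)
  for (i in seq_len(ns)) wr(-dig_max, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- pmax_v / dig_max
  for (r in seq_len(nrec)) {
    sel <- ((r - 1) * spr + 1):(r * spr)
    dig <- round(X[, sel, drop = FALSE] / scale)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Plain EDF reader for continuous recordings: parses the header, converts
#' digital values to physical units (uV) and checks that all 19 channels of
#' the 10-20 montage are present.
#'
#' @param path EDF file path.
#' @param montage Expected montage (channel-name check and ordering).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, montage = montage_1020()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_v <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_v <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  missing_ch <- setdiff(montage$channel_names, labels)
  if (length(missing_ch))
    stop("EDF file lacks required channel(s): ",
         paste(missing_ch, collapse = ", "))
  X <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- pmin_v[i] + (dig - dmin[i]) * (pmax_v[i] - pmin_v[i]) /
        (dmax[i] - dmin[i])
      X[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  rownames(X) <- labels
  X <- X[montage$channel_names, , drop = FALSE]
  eeg_recording(X, rate = round(spr[1] / rec_dur), montage = montage)
}

#' Write a BrainVision triplet
#'
#' Writes `.vhdr` (text header), `.vmrk` (markers; one stimulus marker per
#' event, description = condition label) and `.eeg` (multiplexed IEEE
#' float32, uV).
#'
#' @param rec An [eeg_recording()]; cue events in `rec$events` (columns
#'   `time_s`, `condition`) or passed via `events`.
#' @param path_base Path without extension.
#' @param events Optional events data.frame overriding `rec$events`.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, path_base, events = rec$events) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- basename(path_base)
  vhdr <- paste0(path_base, ".vhdr")
  lines <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$rate)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    paste0("Ch", seq_len(nrow(rec$data)), "=", rownames(rec$data),
           ",,1,uV"))
  writeLines(lines, vhdr)
  mk <- c("BrainVision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(events) && nrow(events)) {
    pos <- round(events$time_s * rec$rate) + 1
    mk <- c(mk, paste0("Mk", seq_len(nrow(events)) + 1, "=Stimulus,",
                       events$condition, ",", pos, ",1,0"))
  }
  writeLines(mk, paste0(path_base, ".vmrk"))
  con <- file(paste0(path_base, ".eeg"), "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}

#' Read a BrainVision triplet
#'
#' @param vhdr Path to the `.vhdr` header.
#' @param montage Expected montage (channel check).
#' @return An [eeg_recording()] with stimulus markers as the event table.
#' @export
read_brainvision <- function(vhdr, montage = montage_1020()) {
  hdr <- readLines(vhdr, warn = FALSE)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  nch <- as.integer(get_val("NumberOfChannels"))
  rate <- round(1e6 / as.numeric(get_val("SamplingInterval")))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, "", 1)
  missing_ch <- setdiff(montage$channel_names, labels)
  if (length(missing_ch))
    stop("BrainVision file lacks required channel(s): ",
         paste(missing_ch, collapse = ", "))
  dir <- dirname(vhdr)
  eeg_path <- file.path(dir, get_val("DataFile"))
  raw_n <- file.info(eeg_path)$size / 4
  con <- file(eeg_path, "rb")
  vals <- readBin(con, "numeric", n = raw_n, size = 4, endian = "little")
  close(con)
  X <- matrix(vals, nrow = nch)
  rownames(X) <- labels
  X <- X[montage$channel_names, , drop = FALSE]
  events <- NULL
  vmrk <- file.path(dir, get_val("MarkerFile"))
  if (file.exists(vmrk)) {
    mk <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, warn = FALSE),
               value = TRUE)
    if (length(mk)) {
      parts <- strsplit(sub("^Mk[0-9]+=Stimulus,", "", mk), ",")
      events <- data.frame(
        condition = vapply(parts, `[`, "", 1),
        time_s = (as.numeric(vapply(parts, `[`, "", 2)) - 1) / rate)
    }
  }
  eeg_recording(X, rate = rate, montage = montage, events = events)
}

#' Read an EEG file (EDF or BrainVision)
#'
#' Dispatches on the file extension: `.edf` or `.vhdr`. Channels are mapped
#' to the 10-20 names and units are uV; an error names any missing channel.
#'
#' @param path File path.
#' @param montage Expected montage.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, montage = montage_1020()) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf = read_edf(path, montage),
         vhdr = read_brainvision(path, montage),
         stop("unsupported EEG format: .", ext,
              " (expected .edf or .vhdr)"))
}

#' Write / read a tab-separated table
#' @param x A data.frame.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
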