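# European Data Format (EDF) import/export and the plain-text hypnogram
# sidecar.  EDF stores signals as 16-bit integers with per-signal linear
# calibration; one data record here is one 30-s epoch.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)   # left-justified, space padded
}

#' Write epochs of one night to an EDF file
#'
#' Signals are calibrated to the per-channel physical range and quantized
#' to 16 bits (physical unit uV); each 30-s epoch becomes one EDF data
#' record.  If the records carry stage labels, a plain-text hypnogram
#' sidecar can be written alongside with [write_hypnogram()].
#'
#' @param records List of [epoch_record()] from a single night (same
#'   sampling rate and channel count, ordered by epoch).
#' @param path Output file path.
#' @return Invisible `path`.
#' @export
write_edf <- function(records, path) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, TRUE, "epoch_record")))
  fs <- records[[1]]$fs_hz
  nchan <- ncol(records[[1]]$samples)
  labels <- colnames(records[[1]]$samples)
  nrec <- length(records)
  spr <- as.integer(fs * EPOCH_SECONDS)   # samples per record
  all_sig <- lapply(seq_len(nchan), function(ch)
    unlist(lapply(records, function(r) r$samples[, ch]), use.names = FALSE))
  pmin <- vapply(all_sig, function(s) -max(1, ceiling(max(abs(s)))), 0)
  pmax <- -pmin
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste("subject", records[[1]]$subject_id), 80),
    edf_pad(paste("synthetic PSG night", records[[1]]$night_id), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * nchan, 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad(EPOCH_SECONDS, 8), edf_pad(nchan, 4))
  sig_hdr <- paste0(
    paste(edf_pad(labels, 16), collapse = ""),
    paste(rep(edf_pad("synthetic", 80), nchan), collapse = ""),
    paste(rep(edf_pad("uV", 8), nchan), collapse = ""),
    paste(edf_pad(pmin, 8), collapse = ""),
    paste(edf_pad(pmax, 8), collapse = ""),
    paste(rep(edf_pad(-32768, 8), nchan), collapse = ""),
    paste(rep(edf_pad(32767, 8), nchan), collapse = ""),
    paste(rep(edf_pad("", 80), nchan), collapse = ""),
    paste(rep(edf_pad(spr, 8), nchan), collapse = ""),
    paste(rep(edf_pad("", 32), nchan), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (r in records) {
    for (ch in seq_len(nchan)) {
      v <- r$samples[, ch]
      dig <- round((v - pmin[ch]) / (pmax[ch] - pmin[ch]) * 65535 - 32768)
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  nbytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80)
  units <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  list(version = version, patient = patient, recording = recording,
       n_records = nrec, record_duration_s = dur, n_signals = ns,
       labels = labels, units = units, pmin = pmin, pmax = pmax,
       dmin = dmin, dmax = dmax, samples_per_record = spr,
       header_bytes = nbytes)
}

#' Read signals from an EDF file
#'
#' @param path EDF file path.
#' @return List with `signals` (named list of numeric vectors, physical
#'   units), `fs_hz` (per signal), and the parsed `header`.
#' @export
read_edf_signals <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (!identical(h$version, "0"))
    stop("not an EDF file (bad version field): ", path, call. = FALSE)
  sig <- lapply(seq_len(h$n_signals), function(i)
    numeric(h$n_records * h$samples_per_record[i]))
  for (r in seq_len(h$n_records)) {
    for (i in seq_len(h$n_signals)) {
      spr <- h$samples_per_record[i]
      dig <- readBin(con, "integer", n = spr, size = 2, endian = "little",
                     signed = TRUE)
      phys <- (dig - h$dmin[i]) / (h$dmax[i] - h$dmin[i]) *
        (h$pmax[i] - h$pmin[i]) + h$pmin[i]
      sig[[i]][(r - 1) * spr + seq_len(spr)] <- phys
    }
  }
  names(sig) <- h$labels
  list(signals = sig, fs_hz = h$samples_per_record / h$record_duration_s,
       header = h)
}

#' Read a polysomnography EDF as unlabelled 30-s epochs
#'
#' Segments the requested channels into consecutive non-overlapping 30-s
#' epochs at the file's sampling rate; a trailing partial epoch is dropped
#' with a message.
#'
#' @param path EDF file path.
#' @param channels Channel labels to extract, in order (canonical
#'   `c("EEG", "EOG")`).
#' @param subject_id,night_id Identifiers attached to the records
#'   (defaults derived from the file name).
#' @return List of unlabelled [epoch_record()].
#' @export
read_psg_edf <- function(path, channels = c("EEG", "EOG"),
                         subject_id = NULL, night_id = 1L) {
  e <- read_edf_signals(path)
  missing_ch <- setdiff(channels, names(e$signals))
  if (length(missing_ch))
    stop("channel(s) not present in EDF: ",
         paste(missing_ch, collapse = ", "), "; available: ",
         paste(names(e$signals), collapse = ", "), call. = FALSE)
  fs <- unique(e$fs_hz[match(channels, names(e$signals))])
  if (length(fs) != 1)
    stop("requested channels have differing sampling rates", call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  n <- length(e$signals[[channels[1]]])
  spe <- as.integer(fs * EPOCH_SECONDS)
  n_ep <- n %/% spe
  if (n %% spe)
    message("dropped trailing partial epoch of ", round((n %% spe) / fs, 2),
            " s")
  lapply(seq_len(n_ep), function(i) {
    idx <- (i - 1L) * spe + seq_len(spe)
    m <- vapply(channels, function(ch) e$signals[[ch]][idx], numeric(spe))
    colnames(m) <- channels
    epoch_record(m, fs, NA, subject_id, night_id, i)
  })
}

#' Write / read the plain-text hypnogram sidecar
#'
#' One line per 30-s epoch: `epoch_index<TAB>stage`, 0-based indices.
#'
#' @param stages Stage labels (anything [stage_factor()] accepts).
#' @param path File path.
#' @return `read_hypnogram` returns the stage factor, ordered by epoch
#'   index; out-of-order lines are re-sorted with a warning, gaps and
#'   unknown stage tokens are errors (with the line number).
#' @export
write_hypnogram <- function(stages, path) {
  stages <- stage_factor(stages)
  writeLines(sprintf("%d\t%s", seq_along(stages) - 1L,
                     as.character(stages)), path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad))
    stop("malformed hypnogram line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  tok <- vapply(parts, `[`, "", 2)
  if (anyNA(idx))
    stop("non-integer epoch index at line ", which(is.na(idx))[1],
         call. = FALSE)
  known <- tok %in% stage_levels()
  if (!all(known))
    stop("unknown stage token '", tok[!known][1], "' at line ",
         which(!known)[1], " (five-stage AASM scheme only)", call. = FALSE)
  o <- order(idx)
  if (is.unsorted(idx)) {
    warning("hypnogram epoch indices out of order; re-sorted")
    idx <- idx[o]; tok <- tok[o]
  }
  if (!identical(idx, seq_along(idx) - 1L))
    stop("hypnogram has gaps or duplicate epoch indices", call. = FALSE)
  stage_factor(tok)
}
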