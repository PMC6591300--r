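#' Minimal EDF export / import
#'
#' Writes an [epoched_dataset()] to a European Data Format (EDF) file — one
#' data record per trial — and reads it back. The 16-bit integer encoding
#' quantizes amplitudes to about 1/65000 of the per-channel range, so a
#' round trip is close but not bit-exact. Trial labels are stored in a
#' plain-text sidecar file `<path>.labels` (one label per line), the
#' marker-file idiom; the EDF file itself stays readable by generic
#' viewers.
#'
#' @param data an [epoched_dataset()].
#' @param path output file path.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns an
#'   [epoched_dataset()].
#' @name edf_io
NULL

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' @rdname edf_io
#' @export
write_edf <- function(data, path) {
  stopifnot(inherits(data, "epoched_dataset"))
  n_ch <- nrow(data$trials[[1L]])
  n_samp <- ncol(data$trials[[1L]])
  n_rec <- length(data$trials)
  all_mat <- do.call(cbind, data$trials)
  phys_min <- apply(all_mat, 1L, min)
  phys_max <- apply(all_mat, 1L, max)
  span <- phys_max - phys_min
  phys_max[span == 0] <- phys_min[span == 0] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field("synthetic MI-EEG", 80L),
    pad_field("opticalbci export", 80L),
    pad_field("01.01.26", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (1L + n_ch), 8L),
    pad_field("opticalbci", 44L),
    pad_field(n_rec, 8L),
    pad_field(format(n_samp / data$fs, digits = 6), 8L),
    pad_field(n_ch, 4L)
  )
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(data$channel_names, pad_field, "", width = 16L),
          collapse = ""),
    strrep(pad_field("synthetic", 80L), n_ch),
    strrep(pad_field("uV", 8L), n_ch),
    paste(vapply(phys_min, pad_field, "", width = 8L), collapse = ""),
    paste(vapply(phys_max, pad_field, "", width = 8L), collapse = ""),
    strrep(pad_field(-32768L, 8L), n_ch),
    strrep(pad_field(32767L, 8L), n_ch),
    strrep(pad_field("", 80L), n_ch),
    paste(rep(pad_field(n_samp, 8L), n_ch), collapse = ""),
    strrep(pad_field("", 32L), n_ch)
  )
  writeChar(sig_hdr, con, eos = NULL)
  for (tr in data$trials) {
    for (ch in seq_len(n_ch)) {
      dig <- round((tr[ch, ] - phys_min[ch]) /
                     (phys_max[ch] - phys_min[ch]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2L, endian = "little")
    }
  }
  writeLines(data$labels, paste0(path, ".labels"))
  invisible(path)
}

read_field <- function(con, width) trimws(readChar(con, width))

#' @rdname edf_io
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_field(con, 8L)                       # version
  read_field(con, 80L); read_field(con, 80L)
  read_field(con, 8L); read_field(con, 8L)
  read_field(con, 8L)                       # header bytes
  read_field(con, 44L)                      # reserved
  n_rec <- as.integer(read_field(con, 8L))
  rec_dur <- as.numeric(read_field(con, 8L))
  n_ch <- as.integer(read_field(con, 4L))
  chn <- vapply(seq_len(n_ch), function(i) read_field(con, 16L), "")
  for (i in seq_len(n_ch)) read_field(con, 80L)   # transducer
  for (i in seq_len(n_ch)) read_field(con, 8L)    # unit
  phys_min <- vapply(seq_len(n_ch), function(i)
    as.numeric(read_field(con, 8L)), numeric(1L))
  phys_max <- vapply(seq_len(n_ch), function(i)
    as.numeric(read_field(con, 8L)), numeric(1L))
  dig_min <- vapply(seq_len(n_ch), function(i)
    as.numeric(read_field(con, 8L)), numeric(1L))
  dig_max <- vapply(seq_len(n_ch), function(i)
    as.numeric(read_field(con, 8L)), numeric(1L))
  for (i in seq_len(n_ch)) read_field(con, 80L)   # prefiltering
  n_samp <- vapply(seq_len(n_ch), function(i)
    as.integer(read_field(con, 8L)), integer(1L))
  for (i in seq_len(n_ch)) read_field(con, 32L)   # reserved
  stopifnot(length(unique(n_samp)) == 1L)
  n_samp <- n_samp[1L]
  fs <- n_samp / rec_dur
  trials <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    m <- matrix(0, n_ch, n_samp)
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n_samp, size = 2L, signed = TRUE,
                     endian = "little")
      m[ch, ] <- phys_min[ch] + (dig - dig_min[ch]) /
        (dig_max[ch] - dig_min[ch]) * (phys_max[ch] - phys_min[ch])
    }
    trials[[r]] <- m
  }
  sidecar <- paste0(path, ".labels")
  labels <- if (file.exists(sidecar)) readLines(sidecar) else character(0)
  if (length(labels) != n_rec) labels <- rep("unknown", n_rec)
  epoched_dataset(trials, labels, fs, chn)
}
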