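#' Construct an LFP recording
#'
#' Container for continuous multi-channel local field potential data:
#' a labelled set of equal-length sample series in microvolts plus the
#' sampling rate. Channel labels follow the recording-site convention
#' (e.g. `"OB"`, `"FC"`, `"EC"`, `"CA1"`).
#'
#' @param channels named list (or single numeric vector) of sample series,
#'   one per channel, in microvolts. All must have equal length.
#' @param fs sampling rate in Hz.
#' @param start_time optional POSIXct recording start.
#' @param subject,genotype,session_month optional metadata labels.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(channels, fs, start_time = NULL, subject = NA_character_,
                          genotype = NA_character_, session_month = NA) {
  if (is.numeric(channels)) channels <- list(ch1 = channels)
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of numeric vectors", call. = FALSE)
  if (is.null(names(channels)) || anyDuplicated(names(channels)) || any(names(channels) == ""))
    stop("channel labels must be unique and non-empty", call. = FALSE)
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L)
    stop("all channels must have equal length", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(channels = lapply(channels, as.numeric), fs = fs,
         start_time = start_time, subject = subject,
         genotype = genotype, session_month = session_month),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<lfp_recording> %d channel(s) [%s], %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              n, x$fs, n / x$fs))
  invisible(x)
}

#' Number of samples per channel
#' @param rec an `lfp_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

get_channel <- function(rec, channel) {
  if (is.null(channel)) return(rec$channels[[1]])
  if (!channel %in% names(rec$channels))
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(names(rec$channels), collapse = ", ")), call. = FALSE)
  rec$channels[[channel]]
}

#' Read an LFP recording from disk
#'
#' Supported formats: `"csv"` (columns `time_s` then one column per channel;
#' the sampling rate is inferred from the median time step, with a warning
#' if timestamp jitter exceeds 1%), `"edf"` (16-bit European Data Format)
#' and `"bdf"` (24-bit BioSemi variant). Format is guessed from the file
#' extension when not given.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"edf"`, `"bdf"`, or `NULL` to guess.
#' @return An [lfp_recording].
#' @export
read_lfp <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("csv", "edf", "bdf"))
  if (format == "csv") read_lfp_csv(path) else read_edf(path)
}

read_lfp_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("CSV must contain a 'time_s' column", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop(sprintf("non-increasing time_s in %s", path), call. = FALSE)
  med <- stats::median(dt)
  if (max(abs(dt - med)) > 0.01 * med)
    warning("time_s jitter exceeds 1% of the median step; fs inferred from the median")
  chans <- as.list(df[setdiff(names(df), "time_s")])
  lfp_recording(chans, fs = 1 / med)
}

#' Write an LFP recording to disk
#'
#' CSV output has full-precision `time_s` plus one column per channel;
#' EDF/BDF output quantizes to 16/24-bit integers over the channel-wise
#' physical range, so the round trip is exact only to quantization.
#'
#' @param rec an [lfp_recording].
#' @param path output file path.
#' @param format `"csv"`, `"edf"` or `"bdf"`; guessed from extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(rec, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("csv", "edf", "bdf"))
  if (format == "csv") {
    n <- n_samples(rec)
    df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs, check.names = FALSE)
    for (nm in names(rec$channels)) df[[nm]] <- rec$channels[[nm]]
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    write_edf(rec, path, bits = if (format == "bdf") 24L else 16L)
  }
  invisible(path)
}

# --- minimal EDF/BDF continuous-recording support -------------------------
# Fixed-layout ASCII headers, then data records of little-endian signed
# integers (2 bytes EDF, 3 bytes BDF), one record per second. Physical
# units are microvolts; requires an integer sampling rate.

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

write_edf <- function(rec, path, bits = 16L) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF/BDF export requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- length(rec$channels)
  n <- n_samples(rec)
  n_rec <- ceiling(n / fs)
  dmax <- if (bits == 24L) 8388607 else 32767
  dmin <- -dmax - 1L
  con <- file(path, "wb")
  on.exit(close(con))
  ver <- if (bits == 24L) c(as.raw(255), charToRaw(pad("BIOSEMI", 7))) else charToRaw(pad("0", 8))
  writeBin(ver, con)
  writeChar(paste0(pad(ifelse(is.na(rec$subject), "X", rec$subject), 80),
                   pad("recording", 80),
                   pad("01.01.00", 8), pad("00.00.00", 8),
                   pad(256L * (ns + 1L), 8),
                   pad(if (bits == 24L) "24BIT" else "", 44),
                   pad(n_rec, 8), pad(1, 8), pad(ns, 4)),
            con, eos = NULL)
  pmins <- pmaxs <- numeric(ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]
    r <- max(abs(range(x)), 1e-6)
    pmins[i] <- -r; pmaxs[i] <- r
  }
  writeChar(paste0(
    paste0(pad(names(rec$channels), 16), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad("uV", 8), ns), collapse = ""),
    paste0(pad(formatC(pmins, format = "g", digits = 6), 8), collapse = ""),
    paste0(pad(formatC(pmaxs, format = "g", digits = 6), 8), collapse = ""),
    paste0(rep(pad(dmin, 8), ns), collapse = ""),
    paste0(rep(pad(dmax, 8), ns), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad(fs, 8), ns), collapse = ""),
    paste0(rep(pad("", 32), ns), collapse = "")),   # reserved
    con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      x <- rec$channels[[i]][idx]
      x[is.na(x)] <- 0  # zero-pad the final partial record
      dig <- as.integer(round((x - pmins[i]) / (pmaxs[i] - pmins[i]) *
                                (dmax - dmin) + dmin))
      dig <- as.integer(pmin(pmax(dig, dmin), dmax))
      if (bits == 24L) {
        u <- ifelse(dig < 0, dig + 16777216, dig)
        b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
        writeBin(as.raw(b), con)
      } else {
        writeBin(dig, con, size = 2L, endian = "little")
      }
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1L)
  bits <- if (as.integer(first) == 255L) 24L else 16L
  readChar(con, 7, useBytes = TRUE)                    # rest of version field
  subject <- trimws(readChar(con, 80, useBytes = TRUE))
  readChar(con, 80 + 8 + 8, useBytes = TRUE)
  hdr_bytes <- as.integer(readChar(con, 8, useBytes = TRUE))
  readChar(con, 44, useBytes = TRUE)
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  if (is.na(ns) || ns < 1L || is.na(n_rec))
    stop(sprintf("parse error in %s: malformed header at byte 252", path), call. = FALSE)
  rd <- function(w) vapply(seq_len(ns), function(i) readChar(con, w, useBytes = TRUE), "")
  labels <- trimws(rd(16)); rd(80); rd(8)
  pmin <- as.numeric(trimws(rd(8))); pmax <- as.numeric(trimws(rd(8)))
  dmin <- as.numeric(trimws(rd(8))); dmax <- as.numeric(trimws(rd(8)))
  rd(80)
  nsamp <- as.integer(trimws(rd(8)))
  seek(con, hdr_bytes)
  bpS <- bits / 8L
  out <- lapply(seq_len(ns), function(i) numeric(n_rec * nsamp[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (bits == 24L) {
        b <- readBin(con, "raw", nsamp[i] * 3L)
        if (length(b) < nsamp[i] * 3L)
          stop(sprintf("parse error in %s: truncated at byte %d", path,
                       hdr_bytes + ((r - 1L) * sum(nsamp) * 3L)), call. = FALSE)
        m <- matrix(as.integer(b), nrow = 3L)
        dig <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
      } else {
        dig <- readBin(con, "integer", nsamp[i], size = 2L, signed = TRUE,
                       endian = "little")
        if (length(dig) < nsamp[i])
          stop(sprintf("parse error in %s: truncated data record %d", path, r),
               call. = FALSE)
      }
      out[[i]][((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <-
        (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  names(out) <- make.unique(labels)
  lfp_recording(out, fs = nsamp[1] / dur, subject = subject)
}

# --- sweep tables ---------------------------------------------------------

#' Write evoked sweeps to a long-format CSV
#'
#' Columns `sweep_id, time_s, value_uV`; one row per sample.
#'
#' @param sweeps list of [sweep_record] objects (names used as sweep ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps_csv <- function(sweeps, path) {
  if (is.null(names(sweeps))) names(sweeps) <- sprintf("sweep%03d", seq_along(sweeps))
  dfs <- lapply(names(sweeps), function(id) {
    sw <- sweeps[[id]]
    data.frame(sweep_id = id,
               time_s = (seq_along(sw$samples) - 1) / sw$fs,
               value_uV = sw$samples)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read evoked sweeps from a long-format CSV
#'
#' @param path CSV with columns `sweep_id, time_s, value_uV`.
#' @param stim_time_s stimulus time applied to every sweep (seconds).
#' @return named list of [sweep_record] objects.
#' @export
read_sweeps_csv <- function(path, stim_time_s = 0) {
  df <- utils::read.csv(path)
  need <- c("sweep_id", "time_s", "value_uV")
  if (!all(need %in% names(df)))
    stop("sweep CSV must have columns sweep_id, time_s, value_uV", call. = FALSE)
  out <- lapply(split(df, df$sweep_id), function(d) {
    d <- d[order(d$time_s), ]
    sweep_record(d$value_uV, fs = 1 / stats::median(diff(d$time_s)),
                 stim_time_s = stim_time_s)
  })
  out[unique(df$sweep_id)]
}
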