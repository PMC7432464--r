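# Welch relative power spectra of LFP recordings.
#
# Power spectral density is estimated by averaging Hann-tapered, mean-
# detrended periodograms over sliding windows, then expressed as relative
# power: the averaged periodogram is normalized so bins inside the
# analysis band sum to one. Relative power makes spectra comparable
# across animals and sessions with different absolute signal amplitudes.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Welch relative power spectral density
#'
#' Splits the channel into sliding windows of `window_s` seconds with
#' fractional overlap `overlap_frac`, Hann-tapers each mean-detrended
#' window, averages the one-sided periodograms, and normalizes the result
#' so relative power over the analysis band sums to 1. Frequency
#' resolution is `1/window_s` Hz.
#'
#' @param rec an [lfp_recording].
#' @param channel channel label (default: first channel).
#' @param window_s window length, seconds (default 2).
#' @param overlap_frac fractional window overlap in `[0, 1)` (default 0.5).
#' @param band normalization band `c(lo, hi)` in Hz; truncated at Nyquist.
#'   Bins with `lo <= f <= hi` enter the spectrum (the Nyquist bin is kept
#'   when `hi` reaches it).
#' @return A `relative_spectrum` with fields `freqs` (Hz, ascending),
#'   `relpower` (fractions summing to 1 over the band), `fs`, `window_s`,
#'   `band`.
#' @export
welch_relative_psd <- function(rec, channel = NULL, window_s = 2,
                               overlap_frac = 0.5, band = c(1, 256)) {
  stopifnot(inherits(rec, "lfp_recording"))
  x <- get_channel(rec, channel)
  fs <- rec$fs
  nwin <- round(window_s * fs)
  if (length(x) < nwin)
    stop(sprintf("recording (%d samples) shorter than one %g s window",
                 length(x), window_s), call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  band <- c(band[1], min(band[2], fs / 2))
  if (band[1] >= band[2]) stop("empty band after Nyquist truncation", call. = FALSE)

  step <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- hann_window(nwin)
  nfreq <- nwin %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[1:nfreq])^2
    acc <- acc + P
  }
  psd <- acc / length(starts)
  # one-sided: double interior bins (DC and, for even nwin, Nyquist are unique)
  interior <- 2:(nfreq - if (nwin %% 2 == 0) 1L else 0L)
  psd[interior] <- 2 * psd[interior]
  freqs <- (0:(nfreq - 1L)) * fs / nwin

  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("no frequency bins inside band", call. = FALSE)
  rel <- psd[keep]
  tot <- sum(rel)
  if (tot <= 0) stop("zero in-band power; cannot normalize", call. = FALSE)
  structure(list(freqs = freqs[keep], relpower = rel / tot, fs = fs,
                 window_s = window_s, band = band, n_windows = length(starts)),
            class = "relative_spectrum")
}

#' @export
print.relative_spectrum <- function(x, ...) {
  cat(sprintf("<relative_spectrum> %d bins over %g-%g Hz (df = %g Hz), %d windows\n",
              length(x$freqs), x$band[1], x$band[2],
              1 / x$window_s, x$n_windows))
  invisible(x)
}

#' Relative power in a frequency band
#'
#' Sums relative power over bins with `lo <= f < hi` (half-open, so
#' adjacent bands partition the spectrum without double-counting the
#' shared edge bin).
#'
#' @param spec a `relative_spectrum`.
#' @param lo,hi band edges, Hz, `lo < hi`.
#' @return The band fraction (scalar in `[0, 1]`).
#' @export
band_relative_power <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "relative_spectrum"))
  if (lo >= hi) stop("need lo < hi", call. = FALSE)
  sel <- spec$freqs >= lo & spec$freqs < hi
  if (!any(sel))
    stop(sprintf("band [%g, %g) contains no spectral bins", lo, hi), call. = FALSE)
  sum(spec$relpower[sel])
}

#' Average relative spectra across subjects
#'
#' Per-bin mean with a t-based 95% confidence interval across subjects
#' (the unit of replication is the animal).
#'
#' @param specs list of `relative_spectrum` objects on identical grids.
#' @return A `group_spectrum` with `freqs`, `mean_relpower`, `ci95_lo`,
#'   `ci95_hi`, `n`. With a single subject the CI is `NA` and a warning
#'   is raised.
#' @export
group_average_spectra <- function(specs) {
  if (length(specs) == 0) stop("no spectra supplied", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, TRUE, "relative_spectrum")))
  f0 <- specs[[1]]$freqs
  same <- vapply(specs, function(s)
    length(s$freqs) == length(f0) && all(abs(s$freqs - f0) < 1e-9), TRUE)
  if (!all(same)) stop("spectra are on mismatched frequency grids", call. = FALSE)
  m <- do.call(rbind, lapply(specs, `[[`, "relpower"))
  n <- nrow(m)
  mu <- colMeans(m)
  if (n < 2) {
    warning("n < 2: confidence interval undefined")
    lo <- hi <- rep(NA_real_, length(mu))
  } else {
    se <- apply(m, 2, stats::sd) / sqrt(n)
    tq <- stats::qt(0.975, df = n - 1)
    lo <- mu - tq * se
    hi <- mu + tq * se
  }
  structure(list(freqs = f0, mean_relpower = mu, ci95_lo = lo, ci95_hi = hi,
                 n = n),
            class = "group_spectrum")
}

#' @export
print.group_spectrum <- function(x, ...) {
  cat(sprintf("<group_spectrum> n = %d subjects, %d bins (%g-%g Hz)\n",
              x$n, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Write a spectrum to CSV
#'
#' Columns `freq_hz, relpower` and, for group spectra, `ci_lo, ci_hi`.
#'
#' @param spec a `relative_spectrum` or `group_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  df <- if (inherits(spec, "group_spectrum"))
    data.frame(freq_hz = spec$freqs, relpower = spec$mean_relpower,
               ci_lo = spec$ci95_lo, ci_hi = spec$ci95_hi)
  else data.frame(freq_hz = spec$freqs, relpower = spec$relpower)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
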