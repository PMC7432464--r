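# Phase-amplitude cross-frequency coupling.
#
# For a phase frequency f_L and amplitude frequency f_H, the signal is
# narrow band-pass filtered around each (zero-phase FIR), the analytic
# signal is formed via the Hilbert transform, and the coupling strength is
# the modulation index of the composite signal
#     z(t) = A_H(t) * exp(i * phi_L(t)),
# MI = |mean_t z(t)|  (raw, in uV), optionally normalized by the mean
# envelope so MI is in [0, 1] and invariant to signal scale. If the fast
# envelope A_H is independent of the slow phase phi_L the phasors cancel
# and MI tends to 0 at rate O(1/sqrt(N)); preferential amplitude at a
# particular phase leaves a net resultant vector.

# Analytic signal via frequency-domain Hilbert transform.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase FIR band-pass. Order covers >= 3 cycles of the band's low
# edge AND keeps the Hamming-window transition width (~3.3*fs/order) to
# about a third of the band's width, so neighbouring narrow phase bands
# stay separable and modulation sidebands near the amplitude-band edges
# are not attenuated. Forward-backward application is folded into a
# single linear convolution with the filter's autocorrelation (exactly
# filtfilt's zero-phase response, zero initial conditions), evaluated by
# FFT; start-up transients are removed later by the edge trim.
fir_bandpass <- function(x, fs, lo, hi, cycles = 3) {
  tw <- max(2, (hi - lo) / 3)               # target transition width, Hz
  ord <- round(max(cycles * fs / lo, 3.3 * fs / tw))
  ord <- min(ord, floor((length(x) - 4) / 3))
  if (ord %% 2 == 1) ord <- ord + 1
  if (ord < 6) stop("signal too short for the requested band", call. = FALSE)
  b <- as.numeric(signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass"))
  g <- stats::convolve(b, b, conj = TRUE, type = "open")  # b * rev(b), symmetric
  n <- length(x)
  m <- length(g)                                          # 2*ord + 1
  L <- stats::nextn(n + m)
  G <- stats::fft(c(g, numeric(L - m)))
  X <- stats::fft(c(x, numeric(L - n)))
  y <- Re(stats::fft(X * G, inverse = TRUE)) / L
  y[(ord + 1):(ord + n)]                                  # zero-lag alignment
}

#' Band-limited analytic signal: instantaneous phase and envelope
#'
#' Band-pass filters the signal around `center` with a zero-phase FIR
#' filter (applied forward and backward; order scaled to at least three
#' cycles of the band's low edge), forms the analytic signal via the
#' Hilbert transform, and returns instantaneous phase and amplitude
#' envelope with `edge_trim_s` seconds discarded at each end to remove
#' filter transients.
#'
#' @param x numeric sample series (microvolts).
#' @param fs sampling rate, Hz.
#' @param center band center, Hz.
#' @param bandwidth full bandwidth, Hz; the band is
#'   `center +/- bandwidth/2` and must lie strictly inside (0, fs/2).
#' @param edge_trim_s seconds removed from each end after filtering.
#' @return An `analytic_band` with `phase` (radians, in (-pi, pi]),
#'   `envelope` (uV, nonnegative), `center`, `bandwidth`, `fs`.
#' @export
analytic_band <- function(x, fs, center, bandwidth, edge_trim_s = 1) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (lo <= 0 || hi >= fs / 2)
    stop(sprintf("band %g +/- %g Hz outside (0, Nyquist = %g)", center,
                 bandwidth / 2, fs / 2), call. = FALSE)
  trim <- round(edge_trim_s * fs)
  if (length(x) <= 2 * trim + 8)
    stop("signal too short for the requested edge trim", call. = FALSE)
  filtered <- fir_bandpass(x, fs, lo, hi)
  z <- hilbert_analytic(filtered)
  keep <- if (trim > 0) (trim + 1):(length(x) - trim) else seq_along(x)
  structure(list(center = center, bandwidth = bandwidth, fs = fs,
                 phase = Arg(z[keep]), envelope = Mod(z[keep])),
            class = "analytic_band")
}

#' Modulation index of a phase/envelope pair
#'
#' `MI_raw = |mean(envelope * exp(i*phase))|` (microvolts). The normalized
#' variant divides by the mean envelope, giving a dimensionless value in
#' `[0, 1]` that is invariant to overall signal scale; it is the default
#' for cross-condition comparison.
#'
#' @param phase radians series.
#' @param envelope nonnegative amplitude series, same length.
#' @param normalize logical; divide by mean envelope (default `TRUE`).
#' @return Scalar modulation index.
#' @export
modulation_index <- function(phase, envelope, normalize = TRUE) {
  if (length(phase) == 0 || length(phase) != length(envelope))
    stop("phase and envelope must be equal-length, non-empty", call. = FALSE)
  if (anyNA(phase) || anyNA(envelope))
    stop("NA in phase or envelope", call. = FALSE)
  raw <- Mod(mean(envelope * exp(1i * phase)))
  if (!normalize) return(raw)
  me <- mean(envelope)
  if (me <= 0) return(0)
  raw / me
}

#' PAC estimation parameters
#'
#' @param fL_grid phase-frequency grid, Hz (default 1--100 step 2).
#' @param fH_grid amplitude-frequency grid, Hz (default 10--200 step 5).
#' @param phase_bw full bandwidth of the phase-band filter, Hz (default:
#'   the fL grid step).
#' @param amp_bw_rule function `(fL, fH) -> full bandwidth in Hz` for the
#'   amplitude-band filter; the default `max(10, 2*fL + 4)` keeps the
#'   modulation sidebands at `fH +/- fL` inside the band, which is
#'   required for the envelope to carry the modulation.
#' @param edge_trim_s seconds discarded at each end after filtering.
#' @param normalize use amplitude-normalized MI (default `TRUE`).
#' @param segment_s long recordings are split into segments of this many
#'   seconds and per-segment MI values are averaged (default 60).
#' @return A `pac_params` list.
#' @export
pac_params <- function(fL_grid = seq(1, 100, by = 2),
                       fH_grid = seq(10, 200, by = 5),
                       phase_bw = NULL,
                       amp_bw_rule = function(fL, fH) max(10, 2 * fL + 4),
                       edge_trim_s = 1, normalize = TRUE, segment_s = 60) {
  if (is.unsorted(fL_grid, strictly = TRUE) || is.unsorted(fH_grid, strictly = TRUE))
    stop("frequency grids must be strictly ascending", call. = FALSE)
  if (is.null(phase_bw))
    phase_bw <- if (length(fL_grid) > 1) min(diff(fL_grid)) else 2
  structure(list(fL_grid = fL_grid, fH_grid = fH_grid, phase_bw = phase_bw,
                 amp_bw_rule = amp_bw_rule, edge_trim_s = edge_trim_s,
                 normalize = normalize, segment_s = segment_s),
            class = "pac_params")
}

#' Comodulogram: MI over a phase-frequency by amplitude-frequency grid
#'
#' Computes the modulation index for every valid grid cell. A cell
#' `(f_L, f_H)` is invalid — returned as `NA`, never zero, to distinguish
#' "not estimable" from "no coupling" — when the phase band would reach 0,
#' when `f_H <= f_L`, or when the amplitude band exceeds Nyquist.
#' Recordings longer than `params$segment_s` are processed in consecutive
#' segments and per-segment MI values averaged.
#'
#' @param rec an [lfp_recording].
#' @param channel channel label (default: first).
#' @param params a [pac_params].
#' @return A `comodulogram` with `fL_grid`, `fH_grid`, `mi` (matrix of
#'   `length(fL_grid)` rows by `length(fH_grid)` columns), `params`.
#' @export
comodulogram <- function(rec, channel = NULL, params = pac_params()) {
  stopifnot(inherits(rec, "lfp_recording"), inherits(params, "pac_params"))
  x <- get_channel(rec, channel)
  fs <- rec$fs
  nyq <- fs / 2
  fL <- params$fL_grid
  fH <- params$fH_grid
  min_fL <- min(fL[fL - params$phase_bw / 2 > 0], Inf)
  if (!is.finite(min_fL)) stop("all phase-band cells invalid", call. = FALSE)
  need <- round((2 * params$edge_trim_s + 10 / min_fL) * fs)
  if (length(x) < need)
    stop(sprintf("recording too short for PAC at f_L = %g Hz (need >= %d samples)",
                 min_fL, need), call. = FALSE)

  seg_len <- round(params$segment_s * fs)
  n_seg <- max(1L, length(x) %/% seg_len)
  if (length(x) < seg_len) seg_len <- length(x)

  acc <- matrix(0, length(fL), length(fH))
  cnt <- matrix(0L, length(fL), length(fH))
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1L) * seg_len + 1L):(s * seg_len)]
    for (i in seq_along(fL)) {
      if (fL[i] - params$phase_bw / 2 <= 0) next
      ph <- analytic_band(seg, fs, fL[i], params$phase_bw,
                          params$edge_trim_s)$phase
      for (j in seq_along(fH)) {
        bw <- params$amp_bw_rule(fL[i], fH[j])
        if (fH[j] <= fL[i] || fH[j] - bw / 2 <= 0 || fH[j] + bw / 2 >= nyq) next
        env <- analytic_band(seg, fs, fH[j], bw, params$edge_trim_s)$envelope
        acc[i, j] <- acc[i, j] + modulation_index(ph, env, params$normalize)
        cnt[i, j] <- cnt[i, j] + 1L
      }
    }
  }
  if (all(cnt == 0)) stop("all comodulogram cells invalid", call. = FALSE)
  mi <- acc / cnt
  mi[cnt == 0] <- NA_real_
  dimnames(mi) <- list(fL = fL, fH = fH)
  structure(list(fL_grid = fL, fH_grid = fH, mi = mi, params = params,
                 n_segments = n_seg),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  pk <- comod_peak(x)
  cat(sprintf("<comodulogram> %d x %d grid, %d valid cells; peak MI %.4g at (f_L=%g, f_H=%g) Hz\n",
              length(x$fL_grid), length(x$fH_grid), sum(!is.na(x$mi)),
              pk$mi, pk$fL, pk$fH))
  invisible(x)
}

#' Location and value of the comodulogram maximum
#' @param comod a `comodulogram`.
#' @return list with `fL`, `fH`, `mi`.
#' @export
comod_peak <- function(comod) {
  idx <- which(comod$mi == max(comod$mi, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(fL = comod$fL_grid[idx[1]], fH = comod$fH_grid[idx[2]],
       mi = comod$mi[idx[1], idx[2]])
}

#' Theta-gamma PAC summary
#'
#' Mean MI over grid cells whose phase frequency falls in `phase_band` and
#' amplitude frequency in `amp_band` (both inclusive). Invalid (`NA`)
#' cells are excluded.
#'
#' @param comod a `comodulogram`.
#' @param phase_band inclusive phase-frequency band, Hz (default 4--8).
#' @param amp_band inclusive amplitude-frequency band, Hz (default 40--100).
#' @return Scalar mean MI.
#' @export
theta_gamma_pac <- function(comod, phase_band = c(4, 8), amp_band = c(40, 100)) {
  stopifnot(inherits(comod, "comodulogram"))
  ri <- comod$fL_grid >= phase_band[1] & comod$fL_grid <= phase_band[2]
  ci <- comod$fH_grid >= amp_band[1] & comod$fH_grid <= amp_band[2]
  if (!any(ri) || !any(ci))
    stop("summary bands do not intersect the comodulogram grids", call. = FALSE)
  vals <- comod$mi[ri, ci, drop = FALSE]
  if (all(is.na(vals))) stop("no valid cells in the summary bands", call. = FALSE)
  mean(vals, na.rm = TRUE)
}

#' Surrogate null distribution for the modulation index
#'
#' Destroys phase-amplitude alignment while preserving both marginal
#' spectra by circularly time-shifting the envelope relative to the phase
#' by a random offset, recomputing MI for each of `n_surrogates` shifts.
#'
#' @param phase radians series.
#' @param envelope amplitude series, same length.
#' @param n_surrogates number of surrogates (>= 19 for a 95% threshold).
#' @param seed integer RNG seed.
#' @param normalize as in [modulation_index].
#' @return List with `null` (sorted surrogate MI values), `threshold`
#'   (95th percentile) and `n_surrogates`.
#' @export
surrogate_null <- function(phase, envelope, n_surrogates = 199, seed = 1L,
                           normalize = TRUE) {
  n <- length(phase)
  if (n < 2 || length(envelope) != n)
    stop("phase and envelope must be equal-length series of >= 2 samples",
         call. = FALSE)
  if (n_surrogates < 19)
    stop("n_surrogates must be >= 19 for a 95th-percentile threshold",
         call. = FALSE)
  phasor <- exp(1i * phase)
  me <- mean(envelope)
  null <- with_seed(seed, {
    offs <- sample.int(n - 1L, n_surrogates, replace = TRUE)
    vapply(offs, function(k) {
      shifted <- c(envelope[(k + 1L):n], envelope[1:k])
      mi <- Mod(mean(shifted * phasor))
      if (normalize) mi / me else mi
    }, numeric(1))
  })
  null <- sort(null)
  list(null = null, threshold = stats::quantile(null, 0.95, names = FALSE),
       n_surrogates = n_surrogates)
}

#' Write a comodulogram as TSV plus a JSON parameter sidecar
#'
#' TSV rows are phase frequencies, columns amplitude frequencies, with the
#' grid values in the header row/column; invalid cells are written as
#' `NA`. A `<path>.json` sidecar records parameters and the valid-cell
#' mask.
#'
#' @param comod a `comodulogram`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comodulogram_tsv <- function(comod, path) {
  m <- comod$mi
  df <- data.frame(fL_hz = comod$fL_grid, m, check.names = FALSE)
  names(df) <- c("fL_hz", as.character(comod$fH_grid))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(
    fL_grid = comod$fL_grid, fH_grid = comod$fH_grid,
    phase_bw = comod$params$phase_bw,
    edge_trim_s = comod$params$edge_trim_s,
    normalize = comod$params$normalize,
    segment_s = comod$params$segment_s,
    n_segments = comod$n_segments,
    valid = !is.na(m))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
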