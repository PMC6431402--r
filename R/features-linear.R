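# The 18 linear features: peak, average value, variance, centre frequency,
# maximum power and power sum for each of the alpha, theta, beta band
# signals (canonical indices 1-18: alpha 1-6, theta 7-12, beta 13-18).

#' Signed peak of a sample sequence
#'
#' @param x non-empty numeric sequence.
#' @return `max(x)` (the signed maximum, not the absolute one).
#' @export
peak <- function(x) {
  if (length(x) == 0) stop("empty input")
  max(x)
}

#' Wavelet pseudo-frequency
#'
#' The frequency associated with a wavelet of centre frequency `Fc`
#' (cycles, at scale 1) stretched to scale `a` at sampling rate `fs`:
#' `Fa = Fc * fs / a`.
#'
#' @param Fc wavelet centre frequency at unit scale (cycles).
#' @param fs sampling rate (Hz).
#' @param a scale (> 0).
#' @return Frequency in Hz.
#' @export
pseudo_frequency <- function(Fc, fs, a) {
  stopifnot(a > 0, fs > 0)
  Fc * fs / a
}

# Morlet omega0; Fc = omega0 / (2 pi) cycles at unit scale.
.morlet_w0 <- 6

#' Band centre frequency via wavelet scale scan
#'
#' Scans complex-Morlet scales whose pseudo-frequencies cover the band and
#' returns `Fa = Fc * fs / a` for the scale `a` with maximal wavelet
#' response energy over the signal (computed in the Fourier domain with
#' L2-normalized kernels).
#'
#' @param x band-limited sample sequence.
#' @param fs sampling rate (Hz).
#' @param band_range `c(low, high)` Hz; the scan is restricted to it.
#' @param df frequency grid step (Hz).
#' @return Centre frequency in Hz (inside `band_range`).
#' @export
centre_frequency <- function(x, fs, band_range, df = 0.05) {
  if (sum(x^2) == 0) stop("band signal has zero energy")
  n <- length(x)
  Fc <- .morlet_w0 / (2 * pi)
  fgrid <- seq(band_range[1], band_range[2], by = df)
  scales <- Fc * fs / fgrid
  w <- 2 * pi * (0:(n - 1)) / n            # rad/sample, full grid
  w <- ifelse(w > pi, w - 2 * pi, w)       # signed; analytic kernel uses w>0
  px <- Mod(fft(x))^2
  energy <- vapply(scales, function(a) {
    kern <- ifelse(w > 0, exp(-0.5 * (a * w - .morlet_w0)^2), 0)
    sum(px * a * kern^2)                   # L2 norm: |sqrt(a) psihat(a w)|^2
  }, numeric(1))
  fgrid[which.max(energy)]
}

#' Autocorrelation power spectrum
#'
#' The discrete spectrum of the biased autocorrelation estimate, which
#' equals the periodogram `|FFT(x)|^2 / N` and is therefore real and
#' non-negative. Returned on the full uniform N-point frequency grid, so
#' the grid mean of the power equals `mean(x^2)` (= variance + squared
#' mean) exactly (Parseval).
#'
#' @param x numeric sequence, length >= 8.
#' @param fs sampling rate (Hz), used only to label the grid.
#' @return Object of class `power_spectrum`: list with `freq` (Hz,
#'   0 .. fs*(N-1)/N) and `power`.
#' @export
autocorr_spectrum <- function(x, fs = 1) {
  n <- length(x)
  if (n < 8) stop("need at least 8 samples")
  p <- Mod(fft(x))^2 / n
  structure(list(freq = (0:(n - 1)) * fs / n, power = p, n = n, fs = fs),
            class = "power_spectrum")
}

#' Maximum power and power sum
#'
#' `max_power` is the maximum of the autocorrelation spectrum over its
#' grid; `power_sum` is its sum over the grid (so `power_sum >=
#' max_power`).
#'
#' @param x numeric sequence (or a precomputed `power_spectrum`).
#' @return A single power value.
#' @export
max_power <- function(x) {
  s <- if (inherits(x, "power_spectrum")) x else autocorr_spectrum(x)
  max(s$power)
}

#' @rdname max_power
#' @export
power_sum <- function(x) {
  s <- if (inherits(x, "power_spectrum")) x else autocorr_spectrum(x)
  sum(s$power)
}

#' Extract the 18 linear band features of an epoch
#'
#' Decomposes the epoch into alpha/theta/beta band signals and computes,
#' per band: peak, sample mean, sample variance (n-1), centre frequency,
#' maximum power and power sum, in canonical order (alpha 1-6, theta 7-12,
#' beta 13-18). A zero-energy band yields zero features with its centre
#' frequency flagged degenerate (attribute `degenerate`).
#'
#' @param epoch single-channel numeric epoch.
#' @param fs sampling rate (Hz).
#' @param band_ranges named band ranges.
#' @param bands `band_signals` to reuse, if already computed.
#' @return Named numeric vector of length 18 (`f01`..`f18`), attribute
#'   `degenerate` listing flagged feature columns.
#' @export
extract_linear <- function(epoch, fs, band_ranges = default_band_ranges(),
                           bands = NULL) {
  if (is.null(bands)) bands <- band_decompose(epoch, fs, band_ranges)
  out <- numeric(0)
  flags <- character(0)
  for (b in c("alpha", "theta", "beta")) {
    xb <- bands[[b]]
    if (sum(xb^2) == 0) {
      vals <- c(0, 0, 0, 0, 0, 0)
      flags <- c(flags, paste0(b, " centre frequency"))
    } else {
      sp <- autocorr_spectrum(xb, fs)
      vals <- c(peak(xb), mean(xb), var(xb),
                centre_frequency(xb, fs, bands$band_ranges[[b]]),
                max(sp$power), sum(sp$power))
    }
    out <- c(out, vals)
  }
  names(out) <- sprintf("f%02d", 1:18)
  attr(out, "degenerate") <- flags
  out
}
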