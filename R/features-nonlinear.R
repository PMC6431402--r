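# The nine nonlinear dynamics features, canonical indices 19-27:
# 19 singular spectral entropy, 20 entropy of K (correlation entropy K2),
# 21 approximate entropy, 22 maximum Lyapunov exponent, 23 C0 complexity,
# 24 sample entropy, 25 spectral entropy, 26 Lempel-Ziv complexity,
# 27 correlation dimension.

#' Estimator parameters for the nonlinear features
#'
#' Defaults follow the conventional settings of the cited estimators:
#' embedding dimension 2 and tolerance 0.2 sd for ApEn/SampEn (delay 1);
#' Grassberger-Procaccia with an embedding sweep for the correlation
#' dimension; Rosenstein's small-data method for the Lyapunov exponent
#' (delay = first autocorrelation zero crossing); median binarization for
#' Lempel-Ziv; spectral-ratio 5 for C0; trajectory window 64 for the
#' singular spectrum.
#'
#' @param m embedding dimension for ApEn/SampEn/K2.
#' @param r tolerance as a fraction of the signal sd.
#' @param tau delay (samples) for ApEn/SampEn/K2.
#' @param d2_m_range embedding sweep for the correlation dimension.
#' @param lyap_m embedding dimension for the Lyapunov estimator.
#' @param ssa_window trajectory-matrix window L.
#' @param c0_ratio spectral mean-power multiple defining "regular"
#'   coefficients.
#' @param lz_binarize binarization rule, currently `"median"` or `"mean"`.
#' @param d2_n_samples at most this many (leading) samples enter the
#'   correlation-integral estimators, bounding their O(N^2) cost.
#' @return list of class `nonlinear_params`.
#' @export
nonlinear_params <- function(m = 2, r = 0.2, tau = 1,
                             d2_m_range = 2:10, lyap_m = 3,
                             ssa_window = 64, c0_ratio = 5,
                             lz_binarize = c("median", "mean"),
                             d2_n_samples = 1200) {
  stopifnot(m >= 1, r > 0, tau >= 1, ssa_window >= 2, c0_ratio > 0)
  structure(list(m = m, r = r, tau = tau, d2_m_range = d2_m_range,
                 lyap_m = lyap_m, ssa_window = ssa_window,
                 c0_ratio = c0_ratio, lz_binarize = match.arg(lz_binarize),
                 d2_n_samples = d2_n_samples),
            class = "nonlinear_params")
}

# First zero crossing of the autocorrelation, a standard delay choice for
# phase-space reconstruction. Capped so embeddings stay inside the data.
acf_zero_lag <- function(x, max_lag = min(length(x) %/% 4, 256)) {
  a <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  z <- which(a <= 0)
  if (length(z) == 0) max_lag else z[1]
}

#' Approximate entropy (Pincus)
#'
#' `ApEn(m, r, N) = phi_m - phi_(m+1)` with Chebyshev distance and
#' self-matches included. The tolerance is `r * sd(x)`.
#'
#' @param x numeric sequence, length >= 50.
#' @param m embedding dimension.
#' @param r tolerance as a fraction of `sd(x)`.
#' @return ApEn in nats; 0 for a zero-variance input.
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2) {
  if (length(x) < 50) stop("need at least 50 samples")
  s <- sd(x)
  if (s == 0) return(0)
  apen_cpp(as.numeric(x), as.integer(m), r * s)
}

#' Sample entropy (Richman-Moorman)
#'
#' `SampEn = -ln(A/B)` with self-matches excluded. When no length-(m+1)
#' match exists (A = 0) the documented sentinel
#' `log((N - m) * (N - m - 1))` (an upper bound attained at A = 1/2 of a
#' pair) is returned with attribute `degenerate = "A=0"`; `B = 0` likewise
#' returns the sentinel flagged `"B=0"`.
#'
#' @inheritParams approximate_entropy
#' @return SampEn in nats; 0 for a zero-variance input.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  if (length(x) < 50) stop("need at least 50 samples")
  s <- sd(x)
  if (s == 0) return(0)
  n <- length(x)
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(m), r * s)
  sentinel <- log((n - m) * (n - m - 1))
  if (ab[2] == 0) return(structure(sentinel, degenerate = "B=0"))
  if (ab[1] == 0) return(structure(sentinel, degenerate = "A=0"))
  -log(ab[1] / ab[2])
}

#' Lempel-Ziv (1976) complexity
#'
#' Binarizes the sequence (above/below its median by default), counts the
#' LZ76 production patterns c(n), and returns the normalized complexity
#' `c(n) * log2(n) / n` (about 1 for an i.i.d. fair-coin string).
#'
#' @param x numeric sequence, length >= 64 (or a logical/0-1 integer
#'   sequence, used as the binary string directly).
#' @param binarize `"median"` or `"mean"` threshold rule.
#' @return Normalized complexity; attribute `patterns` holds c(n).
#' @export
lz_complexity <- function(x, binarize = c("median", "mean")) {
  binarize <- match.arg(binarize)
  if (is.logical(x) || all(x %in% c(0, 1))) {
    bits <- as.integer(x)
  } else {
    if (length(x) < 64) stop("need at least 64 samples")
    thr <- if (binarize == "median") median(x) else mean(x)
    bits <- as.integer(x > thr)
  }
  n <- length(bits)
  cn <- lz76_cpp(bits)
  structure(cn * log2(n) / n, patterns = cn)
}

#' C0 complexity
#'
#' Decomposes the series into a "regular" part (Fourier coefficients whose
#' squared modulus exceeds `ratio` times the mean squared modulus; all
#' others zeroed) and the remainder; C0 is the fraction of total energy in
#' the remainder, in \[0, 1\].
#'
#' @param x numeric sequence, length >= 64.
#' @param ratio positive mean-power multiple.
#' @return C0 in \[0, 1\]; zero-energy input is flagged degenerate.
#' @export
c0_complexity <- function(x, ratio = 5) {
  if (length(x) < 64) stop("need at least 64 samples")
  e <- sum(x^2)
  if (e == 0) return(structure(0, degenerate = "zero energy"))
  F <- fft(x)
  keep <- Mod(F)^2 > ratio * mean(Mod(F)^2)
  reg <- Re(fft(ifelse(keep, F, 0 + 0i), inverse = TRUE)) / length(x)
  sum((x - reg)^2) / e
}

#' Singular spectral entropy
#'
#' Builds the L-lag trajectory matrix, takes singular values, normalizes
#' them to proportions and returns their Shannon entropy divided by
#' `ln(L)` (so the value lies in \[0, 1\]).
#'
#' @param x numeric sequence, length >= 2L.
#' @param L window length.
#' @return Normalized entropy; zero signal is flagged degenerate.
#' @export
singular_spectral_entropy <- function(x, L = 64) {
  if (length(x) < 2 * L) stop("need at least 2L samples")
  if (sum(x^2) == 0) return(structure(0, degenerate = "zero energy"))
  K <- length(x) - L + 1
  TM <- matrix(0, L, K)
  for (i in seq_len(L)) TM[i, ] <- x[i:(i + K - 1)]
  d <- svd(TM, nu = 0, nv = 0)$d
  p <- d / sum(d)
  p <- p[p > 0]
  -sum(p * log(p)) / log(L)
}

#' Spectral entropy
#'
#' Shannon entropy of the normalized one-sided power spectrum (DC
#' excluded), divided by the log of the number of bins, in \[0, 1\].
#'
#' @param x numeric sequence, length >= 64.
#' @return Normalized spectral entropy; zero-energy input flagged.
#' @export
spectral_entropy <- function(x) {
  n <- length(x)
  if (n < 64) stop("need at least 64 samples")
  p <- Mod(fft(x))^2
  p <- p[2:(n %/% 2 + 1)]                 # one-sided, DC excluded
  if (sum(p) == 0) return(structure(0, degenerate = "zero energy"))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n %/% 2)
}

# Correlation sums over a log-spaced radius grid; shared by D2 and K2.
corr_sums <- function(x, m_max, tau, n_r = 24, theiler = NULL,
                      n_samples = 1200) {
  x <- as.numeric(x)
  if (length(x) > n_samples) x <- x[seq_len(n_samples)]
  if (is.null(theiler)) theiler <- tau
  s <- sd(x)
  rs <- exp(seq(log(0.02 * s), log(4 * s), length.out = n_r))
  C <- corr_integral_cpp(x, as.integer(m_max), as.integer(tau), rs,
                         as.integer(theiler))
  list(rs = rs, C = C, tau = tau)
}

# Slope of log C vs log r over the central 50% of the usable log-r span,
# with the fit R^2.
scaling_fit <- function(rs, Cm) {
  ok <- which(is.finite(Cm) & Cm > 0 & Cm < 1)
  if (length(ok) < 4) return(list(slope = NA_real_, r2 = NA_real_, idx = ok))
  lr <- log(rs[ok])
  span <- range(lr)
  mid <- lr >= span[1] + 0.25 * diff(span) & lr <= span[1] + 0.75 * diff(span)
  if (sum(mid) < 3) mid <- rep(TRUE, length(lr))
  fit <- lm(log(Cm[ok][mid]) ~ lr[mid])
  list(slope = unname(coef(fit)[2]),
       r2 = summary(fit)$r.squared, idx = ok[mid])
}

#' Grassberger-Procaccia correlation dimension
#'
#' D2 is the slope of `log C_m(r)` vs `log r` over the central half of the
#' usable log-radius span, at the first embedding dimension of the sweep
#' where the estimate saturates (change < 0.1 between successive m). If no
#' saturation occurs or the best fit has R^2 < 0.95, the value carries
#' attribute `low_confidence = TRUE` (typical for stochastic series, whose
#' estimate grows with m).
#'
#' @param x numeric sequence, length >= 500.
#' @param m_range embedding-dimension sweep.
#' @param tau delay; `NULL` for the first autocorrelation zero crossing.
#' @param n_samples cap on samples used (leading segment).
#' @return D2 estimate with attributes `m` (chosen embedding), `r2`,
#'   possibly `low_confidence`.
#' @export
correlation_dimension <- function(x, m_range = 2:10, tau = NULL,
                                  n_samples = 1200) {
  if (length(x) < 500) stop("need at least 500 samples")
  if (sd(x) == 0) return(structure(0, degenerate = "zero variance"))
  if (is.null(tau)) tau <- acf_zero_lag(x)
  cs <- corr_sums(x, max(m_range), tau, n_samples = n_samples)
  d2_from_sums(cs, m_range)
}

d2_from_sums <- function(cs, m_range) {
  fits <- lapply(m_range, function(m) scaling_fit(cs$rs, cs$C[m, ]))
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  sat <- which(abs(diff(slopes)) < 0.1)
  if (length(sat) > 0) {
    i <- sat[1] + 1
    val <- slopes[i]
    structure(val, m = m_range[i], r2 = r2[i],
              low_confidence = if (is.na(r2[i]) || r2[i] < 0.95) TRUE else NULL)
  } else {
    i <- length(slopes)
    structure(slopes[i], m = m_range[i], r2 = r2[i], low_confidence = TRUE)
  }
}

#' Correlation (K2) entropy
#'
#' The Grassberger-Procaccia correlation entropy, a lower bound on the
#' Kolmogorov-Sinai entropy: `K2 = ln(C_m(r) / C_(m+1)(r)) / tau` averaged
#' over the scaling region. Near zero for periodic dynamics, positive for
#' chaotic ones (ln 2 for the logistic map at parameter 4).
#'
#' @param x numeric sequence, length >= 500.
#' @param m embedding dimension at which the ratio is taken.
#' @param tau delay (samples); `NULL` for the first autocorrelation zero
#'   crossing (a delay-aware embedding keeps K2 of periodic signals at
#'   zero).
#' @param n_samples cap on samples used.
#' @return K2 in nats per step.
#' @export
k_entropy <- function(x, m = 2, tau = NULL, n_samples = 1200) {
  if (length(x) < 500) stop("need at least 500 samples")
  if (sd(x) == 0) return(0)
  if (is.null(tau)) tau <- acf_zero_lag(x)
  cs <- corr_sums(x, m + 1, tau, n_samples = n_samples)
  k2_from_sums(cs, m)
}

k2_from_sums <- function(cs, m) {
  f <- scaling_fit(cs$rs, cs$C[m, ])
  idx <- f$idx
  idx <- idx[is.finite(cs$C[m + 1, idx]) & cs$C[m + 1, idx] > 0]
  if (length(idx) == 0) return(structure(NA_real_, degenerate = "no region"))
  mean(log(cs$C[m, idx] / cs$C[m + 1, idx])) / cs$tau
}

#' Largest Lyapunov exponent (Rosenstein)
#'
#' Tracks the mean log divergence of nearest neighbours (Theiler window
#' `m * tau`) over time and fits the slope of the initial linear region,
#' which ends where the curve saturates (reaches 90% of its total rise).
#' When the total rise is below 1 nat there is no divergence to speak of
#' and the slope of the whole curve (about zero) is returned; when
#' saturation is immediate (stochastic series, no deterministic
#' divergence region) the value carries `low_confidence = TRUE`. Positive
#' values indicate chaos (ln 2 = 0.693 nats/step for the logistic map at
#' parameter 4).
#'
#' @param x numeric sequence, length >= 500.
#' @param m embedding dimension.
#' @param tau delay; `NULL` for the first autocorrelation zero crossing.
#' @param max_t divergence horizon in steps.
#' @return Exponent in nats per sample step, attribute `curve` holding the
#'   divergence curve.
#' @export
max_lyapunov <- function(x, m = 3, tau = NULL, max_t = 30) {
  if (length(x) < 500) stop("need at least 500 samples")
  if (sd(x) == 0) return(structure(0, degenerate = "zero variance"))
  if (is.null(tau)) tau <- acf_zero_lag(x)
  w <- m * tau
  res <- lyap_divergence_cpp(as.numeric(x), as.integer(m), as.integer(tau),
                             as.integer(w), as.integer(max_t))
  if (res$pairs < 10) stop("fewer than 10 valid neighbour pairs")
  y <- res$logdiv
  t <- seq_along(y) - 1
  ok <- is.finite(y)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 5) stop("divergence curve too short")
  rng <- max(y) - min(y)
  low_conf <- NULL
  if (rng < 1) {
    te <- length(y)                      # no real divergence: global slope
  } else {
    sat <- which(y > max(y) - 0.1 * rng)[1]
    if (sat < 5) low_conf <- TRUE        # immediate saturation: stochastic
    te <- max(sat, 5)
  }
  fit <- lm(y[1:te] ~ t[1:te])
  structure(unname(coef(fit)[2]), r2 = summary(fit)$r.squared,
            fitted_steps = te, low_confidence = low_conf,
            curve = data.frame(t = t, logdiv = y))
}

#' Extract the nine nonlinear features of an epoch
#'
#' Returns the nonlinear block in canonical order (indices 19-27). A
#' zero-variance epoch yields all zeros with every feature flagged
#' degenerate, so batch extraction never aborts.
#'
#' @param epoch single-channel numeric epoch.
#' @param params `nonlinear_params`.
#' @return Named numeric vector `f19`..`f27`, attribute `degenerate`
#'   listing flagged features.
#' @export
extract_nonlinear <- function(epoch, params = nonlinear_params()) {
  stopifnot(inherits(params, "nonlinear_params"))
  x <- as.numeric(epoch)
  dict <- feature_dictionary()
  nm <- sprintf("f%02d", 19:27)
  if (sd(x) == 0) {
    out <- stats::setNames(rep(0, 9), nm)
    attr(out, "degenerate") <- dict$feature_name[19:27]
    return(out)
  }
  flags <- character(0)
  grab <- function(v, label) {
    if (!is.null(attr(v, "degenerate")) ||
        isTRUE(attr(v, "low_confidence"))) {
      flags <<- c(flags, label)
    }
    as.numeric(v)
  }
  # D2 and K2 share one correlation-integral computation (same delay)
  tau <- acf_zero_lag(x)
  cs <- corr_sums(x, max(params$d2_m_range) + 1, tau,
                  n_samples = params$d2_n_samples)
  out <- c(
    grab(singular_spectral_entropy(x, params$ssa_window), "Singular spectral entropy"),
    grab(k2_from_sums(cs, params$m), "Entropy of K"),
    grab(approximate_entropy(x, params$m, params$r), "Approximate entropy"),
    grab(max_lyapunov(x, params$lyap_m), "Maximum Lyapunov exponent"),
    grab(c0_complexity(x, params$c0_ratio), "Complexity of C0"),
    grab(sample_entropy(x, params$m, params$r), "Sample entropy"),
    grab(spectral_entropy(x), "Spectral entropy"),
    grab(lz_complexity(x, params$lz_binarize), "Lempel-Ziv complexity"),
    grab(d2_from_sums(cs, params$d2_m_range), "Correlation dimension")
  )
  names(out) <- nm
  attr(out, "degenerate") <- flags
  out
}

#' Extract the full 27-feature vector of a single-channel epoch
#'
#' @inheritParams extract_nonlinear
#' @param fs sampling rate (Hz).
#' @param band_ranges band ranges for the linear block.
#' @return Named numeric vector `f01`..`f27`.
#' @export
extract_features <- function(epoch, fs, band_ranges = default_band_ranges(),
                             params = nonlinear_params()) {
  lin <- extract_linear(epoch, fs, band_ranges)
  nl <- extract_nonlinear(epoch, params)
  out <- c(lin, nl)
  attr(out, "degenerate") <- c(attr(lin, "degenerate"),
                               attr(nl, "degenerate"))
  out
}
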