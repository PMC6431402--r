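#' Canonical 27-feature dictionary
#'
#' The pipeline extracts 27 features per electrode in a fixed canonical
#' order: 18 linear features (peak, average value, variance, centre
#' frequency, maximum power, power sum for the alpha, theta and beta bands,
#' indices 1-18) followed by 9 nonlinear dynamics features (indices 19-27:
#' singular spectral entropy, entropy of K, approximate entropy, maximum
#' Lyapunov exponent, complexity of C0, sample entropy, spectral entropy,
#' Lempel-Ziv complexity, correlation dimension). All selection and
#' reporting code indexes features by this dictionary.
#'
#' @return data.frame with columns `feature_id` (1-27), `feature_name`,
#'   `column` (the `f01`..`f27` table column name), `kind`
#'   ("linear"/"nonlinear") and `band` (alpha/theta/beta or NA).
#' @export
feature_dictionary <- function() {
  lin_stats <- c("peak", "average value", "variance", "centre frequency",
                 "maximum power", "power sum")
  bands <- c("Alpha", "Theta", "Beta")
  lin_names <- unlist(lapply(bands, function(b) paste(b, lin_stats)))
  nonlin_names <- c("Singular spectral entropy", "Entropy of K",
                    "Approximate entropy", "Maximum Lyapunov exponent",
                    "Complexity of C0", "Sample entropy", "Spectral entropy",
                    "Lempel-Ziv complexity", "Correlation dimension")
  data.frame(
    feature_id = 1:27,
    feature_name = c(lin_names, nonlin_names),
    column = sprintf("f%02d", 1:27),
    kind = rep(c("linear", "nonlinear"), c(18, 9)),
    band = c(rep(tolower(bands), each = 6), rep(NA_character_, 9)),
    stringsAsFactors = FALSE
  )
}

#' Conventional EEG band ranges
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz (conventional clinical
#' boundaries; recorded in every run configuration because other
#' conventions exist).
#'
#' @return Named list of `c(low, high)` Hz pairs.
#' @export
default_band_ranges <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

check_band_ranges <- function(band_ranges) {
  stopifnot(is.list(band_ranges),
            all(c("theta", "alpha", "beta") %in% names(band_ranges)))
  for (b in names(band_ranges)) {
    r <- band_ranges[[b]]
    if (length(r) != 2 || r[1] <= 0 || r[2] <= r[1]) {
      stop("band range for ", b, " must be an increasing positive pair")
    }
  }
  invisible(band_ranges)
}

#' Bundled reference summaries
#'
#' Loads the plain-text reference tables distributed with the package: the
#' per-feature class correlation (symmetric uncertainty) averages and CFS
#' selection counts over a 15-dataset music-listening experiment
#' (`"feature_stats"`), the per-electrode paired t-test non-rejection count
#' grid (`"ttest_counts"`), and the 15 x 10 repeatability accuracy grid
#' (`"repeatability"`). These drive the threshold/counting reproduction
#' checks; they are inputs, not package output.
#'
#' @param which one of `"feature_stats"`, `"ttest_counts"`,
#'   `"repeatability"`.
#' @return data.frame.
#' @export
reference_table <- function(which = c("feature_stats", "ttest_counts",
                                      "repeatability")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("reference_", which, ".csv"),
                   package = "museeg", mustWork = TRUE)
  read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
}
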