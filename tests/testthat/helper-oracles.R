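# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

# Pincus ApEn via explicit double loop (Chebyshev, self-matches included).
ref_apen <- function(x, m, r_abs) {
  phi <- function(m) {
    n <- length(x)
    M <- n - m + 1
    logs <- numeric(M)
    for (i in seq_len(M)) {
      cnt <- 0
      for (j in seq_len(M)) {
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_abs) {
          cnt <- cnt + 1
        }
      }
      logs[i] <- log(cnt / M)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Richman-Moorman SampEn via explicit double loop (self-matches excluded).
ref_sampen <- function(x, m, r_abs) {
  n <- length(x)
  M <- n - m
  A <- 0; B <- 0
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_abs) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r_abs) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# LZ76 exhaustive-history pattern count via prefix substring search: each
# new word is the shortest extension of a reproducible substring.
ref_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  pos <- 1
  count <- 0
  while (pos <= n) {
    k <- 0
    while (pos + k <= n) {
      word <- substr(s, pos, pos + k)
      hist <- substr(s, 1, pos + k - 1)
      if (grepl(word, hist, fixed = TRUE)) k <- k + 1 else break
    }
    count <- count + 1
    pos <- pos + k + 1                  # word = reproducible part + 1 symbol
  }
  count
}

# CFS merit evaluated directly from a bins matrix + labels (no package
# internals): plug-in SU from contingency tables.
ref_su <- function(a, b) {
  H <- function(v) {
    p <- table(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  Hj <- function(a, b) {
    p <- table(a, b) / length(a)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ha <- H(a); hb <- H(b)
  if (ha + hb == 0) return(0)
  2 * (ha + hb - Hj(a, b)) / (ha + hb)
}

ref_merit <- function(subset, bins, labels) {
  k <- length(subset)
  rcf <- mean(sapply(subset, function(f) ref_su(bins[, f], labels)))
  rff <- if (k == 1) 0 else {
    pairs <- combn(subset, 2)
    mean(apply(pairs, 2, function(p) ref_su(bins[, p[1]], bins[, p[2]])))
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# Exhaustive best-merit subset over all non-empty subsets.
ref_best_merit <- function(bins, labels) {
  p <- ncol(bins)
  best <- -Inf
  for (mask in 1:(2^p - 1)) {
    subset <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    m <- ref_merit(subset, bins, labels)
    if (m > best) best <- m
  }
  best
}

# Logistic map at parameter 4.
logistic_map <- function(n, x0 = 0.4, burn = 100) {
  x <- numeric(n + burn)
  x[1] <- x0
  for (i in 2:(n + burn)) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x[(burn + 1):(burn + n)]
}

sine_wave <- function(n, f = 10, fs = 256, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# A tiny two-electrode study configuration shared by integration tests:
# one flat (uninformative) channel and one strongly informative channel.
small_study_config <- function(seed = 11, trials_per_emotion = 20,
                               epoch_s = 4) {
  dataset_config(n_datasets = 1, trials_per_emotion = trials_per_emotion,
                 channels = default_channel_specs()[c("FP1", "Pz")],
                 epoch_s = epoch_s, seed = seed)
}

expected_selected_set <- c(4L, 8L, 10L, 14L, 16L, 17L, 20L, 21L, 22L, 23L,
                           25L, 26L)
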