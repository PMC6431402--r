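# Correlation-based feature selection (CFS): equal-frequency
# discretization, information-theoretic correlations (entropy, conditional
# entropy, information gain, symmetric uncertainty; log base 2), the merit
# score Merit = k * rcf / sqrt(k + k(k-1) * rff), greedy forward search,
# cross-dataset average-correlation thresholding and selection-frequency
# counting.

#' Equal-frequency discretization of a feature table
#'
#' Bins each column at its empirical quantiles so bin populations differ
#' by at most one when values are distinct. Columns with fewer distinct
#' values than bins get fewer bins; constant columns collapse to a single
#' bin and are flagged.
#'
#' @param features trials x features numeric matrix.
#' @param labels emotion labels (any factor/character), one per trial.
#' @param n_bins number of bins (>= 2).
#' @return Object of class `discrete_table`: list with `bins` (integer
#'   matrix), `labels`, `n_bins`, `bin_edges`, `flagged` (constant
#'   columns).
#' @export
discretize <- function(features, labels, n_bins = 5) {
  features <- as.matrix(features)
  stopifnot(n_bins >= 2, nrow(features) == length(labels))
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%02d", seq_len(ncol(features)))
  }
  edges <- vector("list", ncol(features))
  bins <- matrix(NA_integer_, nrow(features), ncol(features),
                 dimnames = dimnames(features))
  flagged <- character(0)
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    nb <- min(n_bins, length(unique(x)))
    if (nb < 2) {
      bins[, j] <- 1L
      edges[[j]] <- c(-Inf, Inf)
      flagged <- c(flagged, colnames(features)[j])
      next
    }
    # equal-frequency cut points from the order statistics: populations
    # differ by <= 1 for distinct values; ties share a bin
    sx <- sort(x)
    q <- c(-Inf, sx[ceiling(length(x) * seq_len(nb - 1) / nb)], Inf)
    q <- unique(q)
    b <- cut(x, breaks = q, labels = FALSE, include.lowest = TRUE)
    if (length(unique(b)) < 2) {  # heavy ties collapsed; fall back to ranks
      b <- as.integer(ceiling(rank(x, ties.method = "first") /
                                (length(x) / nb)))
    }
    bins[, j] <- as.integer(b)
    edges[[j]] <- q
  }
  structure(list(bins = bins, labels = labels, n_bins = n_bins,
                 bin_edges = edges, flagged = flagged),
            class = "discrete_table")
}

#' Empirical entropy of a discrete sequence (bits)
#'
#' Plug-in Shannon entropy `H(Y) = -sum p log2 p`.
#'
#' @param y discrete sequence (factor, character or integer).
#' @return Entropy in bits.
#' @export
discrete_entropy <- function(y) {
  if (length(y) == 0) stop("empty input")
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy and information gain (bits)
#'
#' `H(Y|X)` from empirical joint probabilities and the (symmetric)
#' information gain `H(Y) - H(Y|X)`.
#'
#' @param y,x equal-length discrete sequences.
#' @return Conditional entropy / gain in bits.
#' @export
conditional_entropy <- function(y, x) {
  if (length(y) != length(x)) stop("length mismatch")
  n <- length(y)
  joint <- table(x, y) / n
  px <- rowSums(joint)
  h <- 0
  for (i in seq_along(px)) {
    if (px[i] == 0) next
    pyx <- joint[i, ] / px[i]
    pyx <- pyx[pyx > 0]
    h <- h - px[i] * sum(pyx * log2(pyx))
  }
  unname(h)
}

#' @rdname conditional_entropy
#' @export
info_gain <- function(y, x) {
  g <- discrete_entropy(y) - conditional_entropy(y, x)
  max(g, 0)  # clip tiny negative rounding
}

#' Symmetric uncertainty
#'
#' `U(X,Y) = 2 (H(Y) - H(Y|X)) / (H(X) + H(Y))`, a normalized mutual
#' dependence in \[0, 1\]. When both marginals are constant the value is
#' defined as 0 (flagged).
#'
#' @param x,y equal-length discrete sequences.
#' @return U in \[0, 1\].
#' @export
symmetric_uncertainty <- function(x, y) {
  hx <- discrete_entropy(x)
  hy <- discrete_entropy(y)
  if (hx + hy == 0) return(structure(0, degenerate = "both constant"))
  u <- 2 * info_gain(y, x) / (hx + hy)
  min(max(u, 0), 1)
}

# Pairwise class/feature SU matrices for a discrete table.
su_class_vector <- function(table) {
  vapply(seq_len(ncol(table$bins)), function(j) {
    as.numeric(symmetric_uncertainty(table$bins[, j], table$labels))
  }, numeric(1))
}

su_pair_matrix <- function(table) {
  p <- ncol(table$bins)
  M <- diag(1, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      M[i, j] <- M[j, i] <-
        as.numeric(symmetric_uncertainty(table$bins[, i], table$bins[, j]))
    }
  }
  M
}

#' CFS merit of a feature subset
#'
#' `Merit(s) = k * rcf / sqrt(k + k (k-1) * rff)` where `rcf` is the mean
#' feature-class symmetric uncertainty over the k subset features and
#' `rff` the mean over unordered feature pairs (the redundancy term
#' vanishes at k = 1, where Merit equals the class SU).
#'
#' @param subset integer feature ids.
#' @param table `discrete_table`.
#' @param su_class,su_pairs precomputed correlation structures (optional).
#' @return list of class `merit_score`: `subset`, `merit`, `rcf_bar`,
#'   `rff_bar`, `k`.
#' @export
merit <- function(subset, table, su_class = NULL, su_pairs = NULL) {
  stopifnot(length(subset) >= 1)
  p <- ncol(table$bins)
  if (any(subset < 1 | subset > p)) stop("invalid feature id in subset")
  if (is.null(su_class)) su_class <- su_class_vector(table)
  k <- length(subset)
  rcf <- mean(su_class[subset])
  if (k == 1) {
    rff <- 0
  } else {
    if (is.null(su_pairs)) su_pairs <- su_pair_matrix(table)
    pr <- su_pairs[subset, subset]
    rff <- mean(pr[upper.tri(pr)])
  }
  structure(list(subset = sort(subset), k = k,
                 merit = k * rcf / sqrt(k + k * (k - 1) * rff),
                 rcf_bar = rcf, rff_bar = rff),
            class = "merit_score")
}

#' Greedy forward CFS ranking
#'
#' Step 1 picks the feature with maximal class symmetric uncertainty; each
#' later step adds the feature maximizing the merit of the augmented
#' subset. Ties break toward the lower canonical index, so the ranking is
#' fully deterministic. The full permutation and the merit path of the
#' nested prefixes are returned.
#'
#' @param table `discrete_table`.
#' @return Object of class `cfs_ranking`: `order` (feature ids, best
#'   first), `path` (data.frame step/feature_id/merit/rcf_bar/rff_bar),
#'   `su_class`.
#' @export
greedy_rank <- function(table) {
  stopifnot(inherits(table, "discrete_table"))
  p <- ncol(table$bins)
  if (p < 2) stop("need at least 2 features")
  su_class <- su_class_vector(table)
  su_pairs <- su_pair_matrix(table)
  chosen <- integer(0)
  path <- vector("list", p)
  for (step in seq_len(p)) {
    cand <- setdiff(seq_len(p), chosen)
    ms <- lapply(cand, function(f) {
      merit(c(chosen, f), table, su_class, su_pairs)
    })
    mv <- vapply(ms, `[[`, numeric(1), "merit")
    best <- cand[which.max(mv)]  # which.max takes the first (lowest id) tie
    chosen <- c(chosen, best)
    path[[step]] <- ms[[which.max(mv)]]
  }
  path_df <- data.frame(
    step = seq_len(p), feature_id = chosen,
    merit = vapply(path, `[[`, numeric(1), "merit"),
    rcf_bar = vapply(path, `[[`, numeric(1), "rcf_bar"),
    rff_bar = vapply(path, `[[`, numeric(1), "rff_bar"))
  structure(list(order = chosen, path = path_df, su_class = su_class,
                 n_features = p),
            class = "cfs_ranking")
}

#' @export
print.cfs_ranking <- function(x, ...) {
  cat("<cfs_ranking>", x$n_features, "features\n")
  best <- which.max(x$path$merit)
  cat(sprintf("best prefix: %d features, merit %.4f\n", best,
              x$path$merit[best]))
  cat("order:", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.cfs_ranking <- function(object, ...) {
  df <- object$path
  dict <- feature_dictionary()
  if (object$n_features == nrow(dict)) {
    df$feature_name <- dict$feature_name[df$feature_id]
  }
  df
}

#' @export
plot.cfs_ranking <- function(x, ...) {
  plot(x$path$step, x$path$merit, type = "b", xlab = "subset size",
       ylab = "merit", main = "CFS greedy merit path", ...)
  abline(v = which.max(x$path$merit), lty = 2)
  invisible(x)
}

#' Nested prefix subsets of a ranking
#'
#' @param ranking `cfs_ranking`.
#' @param sizes prefix sizes.
#' @return list of integer id vectors.
#' @export
nested_subsets <- function(ranking, sizes = seq_len(ranking$n_features)) {
  lapply(sizes, function(k) ranking$order[seq_len(k)])
}

#' Per-feature class correlation averaged over datasets, with threshold
#'
#' Computes the mean (over datasets) of each feature's class symmetric
#' uncertainty and returns the features whose mean exceeds the threshold
#' (default 0.1).
#'
#' @param tables list of `discrete_table`s (one per dataset), or a numeric
#'   vector of precomputed per-feature averages.
#' @param threshold selection threshold.
#' @return list: `mean_su` (per-feature average), `selected` (ids with
#'   mean > threshold).
#' @export
average_class_correlation <- function(tables, threshold = 0.1) {
  if (is.numeric(tables)) {
    mean_su <- tables
  } else {
    mean_su <- rowMeans(vapply(tables, su_class_vector,
                               numeric(ncol(tables[[1]]$bins))))
  }
  list(mean_su = mean_su, selected = which(mean_su > threshold),
       threshold = threshold)
}

#' Selection frequency of features across rankings
#'
#' Counts how often each feature appears in the top `top_k` of each
#' ranking (one ranking per dataset x stimulus group in the reference
#' protocol) and labels features with count > `min_times` as
#' high-correlation.
#'
#' @param rankings list of `cfs_ranking`s, or a precomputed integer count
#'   vector.
#' @param top_k prefix size counted.
#' @param min_times count threshold for the "high" label.
#' @param n_features total features (needed when counts are precomputed).
#' @return data.frame feature_id / times / correlation ("high"/"low").
#' @export
selection_frequency <- function(rankings, top_k = 10, min_times = 20,
                                n_features = NULL) {
  stopifnot(top_k >= 1)
  if (is.numeric(rankings) && !is.list(rankings)) {
    counts <- as.integer(rankings)
    if (is.null(n_features)) n_features <- length(counts)
  } else {
    if (is.null(n_features)) n_features <- rankings[[1]]$n_features
    counts <- integer(n_features)
    for (r in rankings) {
      top <- r$order[seq_len(min(top_k, length(r$order)))]
      counts[top] <- counts[top] + 1L
    }
  }
  data.frame(feature_id = seq_len(n_features), times = counts,
             correlation = ifelse(counts > min_times, "high", "low"))
}
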