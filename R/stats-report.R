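# Statistical summaries: paired t-test non-rejection count grids, Levene /
# one-way ANOVA utilities, and per-emotion feature value histograms.

emotion_pairs <- function() {
  utils::combn(.emotions, 2, simplify = FALSE)
}

#' Paired t-test non-rejection counts
#'
#' For every electrode, emotion pair, dataset and feature, runs a paired
#' t-test across trials (paired by within-dataset trial rank) and counts
#' the cells with p > alpha (non-rejections, i.e. features that look
#' unrelated to the emotion contrast). A zero-variance difference vector
#' has no defined p and is counted as a non-rejection (flagged). With f
#' features and d datasets, each cell's maximum is f * d.
#'
#' @param ft feature table: data.frame with `dataset`, `electrode`,
#'   `label`, `trial` and `f..` feature columns.
#' @param alpha significance level.
#' @return list of class `ttest_count_grid`: `counts` (pair x electrode
#'   matrix), `totals` (per electrode), `max_per_cell`, `n_flagged`.
#' @export
paired_ttest_counts <- function(ft, alpha = 0.05) {
  fcols <- grep("^f[0-9]+$", names(ft), value = TRUE)
  electrodes <- unique(ft$electrode)
  datasets <- unique(ft$dataset)
  pairs <- emotion_pairs()
  pair_names <- vapply(pairs, paste, character(1), collapse = "-")
  counts <- matrix(0L, length(pairs), length(electrodes),
                   dimnames = list(pair_names, electrodes))
  flagged <- 0L
  for (el in electrodes) {
    fe <- ft[ft$electrode == el, ]
    for (pi in seq_along(pairs)) {
      pr <- pairs[[pi]]
      for (d in datasets) {
        fd <- fe[fe$dataset == d, ]
        a <- fd[fd$label == pr[1], ]
        b <- fd[fd$label == pr[2], ]
        a <- a[order(a$trial), fcols, drop = FALSE]
        b <- b[order(b$trial), fcols, drop = FALSE]
        n <- min(nrow(a), nrow(b))
        if (n < 2) next
        for (fc in fcols) {
          dif <- a[seq_len(n), fc] - b[seq_len(n), fc]
          p <- if (sd(dif) == 0) NA_real_ else {
            tryCatch(t.test(dif)$p.value, error = function(e) NA_real_)
          }
          if (is.na(p)) {
            counts[pi, el] <- counts[pi, el] + 1L   # undefined p: non-rejection
            flagged <- flagged + 1L
          } else if (p > alpha) {
            counts[pi, el] <- counts[pi, el] + 1L
          }
        }
      }
    }
  }
  structure(list(counts = counts, totals = colSums(counts),
                 max_per_cell = length(fcols) * length(datasets),
                 n_flagged = flagged, alpha = alpha),
            class = "ttest_count_grid")
}

#' @export
print.ttest_count_grid <- function(x, ...) {
  cat("<ttest_count_grid> counts of p >", x$alpha,
      "(max", x$max_per_cell, "per cell)\n")
  print(rbind(x$counts, Total = x$totals))
  invisible(x)
}

#' Column totals of a non-rejection count grid
#'
#' @param counts pair x electrode count matrix (or data.frame).
#' @return Named per-electrode totals.
#' @export
ttest_count_totals <- function(counts) {
  colSums(as.matrix(counts))
}

as_groups <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) return(values)
  split(values, groups)
}

#' Levene / Brown-Forsythe homogeneity-of-variance test
#'
#' One-way ANOVA of the absolute deviations from the group centre (mean
#' for the classical Levene statistic, median for Brown-Forsythe).
#'
#' @param values numeric vector, or a list of group vectors.
#' @param groups grouping factor (ignored when `values` is a list).
#' @param center `"mean"` or `"median"`.
#' @return list: `statistic`, `df1`, `df2`, `p.value`.
#' @export
levene_test <- function(values, groups = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- as_groups(values, groups)
  if (length(g) < 2 || any(lengths(g) < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  cfun <- if (center == "mean") mean else median
  z <- unlist(lapply(g, function(v) abs(v - cfun(v))))
  grp <- factor(rep(seq_along(g), lengths(g)))
  a <- anova(lm(z ~ grp))
  list(statistic = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p.value = a$`Pr(>F)`[1])
}

#' Classical one-way ANOVA
#'
#' @inheritParams levene_test
#' @return list: `F`, `df1`, `df2`, `p.value`.
#' @export
anova_oneway <- function(values, groups = NULL) {
  g <- as_groups(values, groups)
  if (length(g) < 2 || any(lengths(g) < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  v <- unlist(g)
  grp <- factor(rep(seq_along(g), lengths(g)))
  a <- anova(lm(v ~ grp))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p.value = a$`Pr(>F)`[1])
}

#' Per-emotion value histograms of selected features
#'
#' Bins each requested feature of one electrode with bin edges shared
#' across the four emotions, so the per-emotion distributions are directly
#' comparable (and each emotion's masses sum to its trial count).
#'
#' @param ft feature table (see [paired_ttest_counts()]).
#' @param feature_ids canonical feature ids.
#' @param electrode electrode name.
#' @param n_bins number of bins.
#' @return data.frame feature_id / emotion / bin_left / bin_right / count.
#' @export
feature_histograms <- function(ft, feature_ids, electrode, n_bins = 10) {
  if (!electrode %in% ft$electrode) stop("electrode not present: ", electrode)
  fe <- ft[ft$electrode == electrode, ]
  out <- list()
  for (fid in feature_ids) {
    fc <- sprintf("f%02d", fid)
    x <- fe[[fc]]
    edges <- seq(min(x), max(x), length.out = n_bins + 1)
    edges[1] <- edges[1] - 1e-12
    for (e in .emotions) {
      xe <- fe[[fc]][fe$label == e]
      cnt <- if (length(xe) == 0) integer(n_bins) else {
        tabulate(cut(xe, edges, labels = FALSE, include.lowest = TRUE),
                 nbins = n_bins)
      }
      out[[length(out) + 1]] <- data.frame(
        feature_id = fid, emotion = e,
        bin_left = edges[-length(edges)], bin_right = edges[-1],
        count = cnt)
    }
  }
  do.call(rbind, out)
}
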