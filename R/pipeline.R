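# Selection-stage drivers and the end-to-end pipeline.

#' Per-dataset CFS rankings of one electrode
#'
#' Discretizes each dataset's feature block (equal-frequency bins) and
#' runs the greedy merit search, returning the per-dataset rankings and
#' the per-feature class symmetric uncertainty averaged over datasets.
#'
#' @param ft feature table.
#' @param electrode electrode name.
#' @param n_bins discretization bins.
#' @return list: `rankings` (per dataset), `mean_su`, `tables`.
#' @export
cfs_per_dataset <- function(ft, electrode, n_bins = 5) {
  datasets <- sort(unique(ft$dataset))
  tables <- lapply(datasets, function(d) {
    fm <- feature_matrix(ft, electrode, d)
    discretize(fm$X, fm$labels, n_bins)
  })
  rankings <- lapply(tables, greedy_rank)
  su <- vapply(tables, su_class_vector,
               numeric(ncol(tables[[1]]$bins)))
  list(rankings = rankings, mean_su = rowMeans(su), tables = tables,
       datasets = datasets)
}

#' Per-dataset, per-stimulus-group CFS rankings
#'
#' For every dataset and every emotion, ranks features for the binary
#' one-vs-rest contrast of that stimulus group, yielding `datasets x 4`
#' rankings (the granularity at which top-k selection counts are
#' accumulated; per-dataset four-class rankings are available from
#' [cfs_per_dataset()]).
#'
#' @inheritParams cfs_per_dataset
#' @return list of `cfs_ranking`s.
#' @export
cfs_group_rankings <- function(ft, electrode, n_bins = 5) {
  datasets <- sort(unique(ft$dataset))
  out <- list()
  for (d in datasets) {
    fm <- feature_matrix(ft, electrode, d)
    for (e in .emotions) {
      ylab <- factor(ifelse(fm$labels == e, e, "rest"),
                     levels = c(e, "rest"))
      tab <- discretize(fm$X, ylab, n_bins)
      out[[length(out) + 1]] <- greedy_rank(tab)
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> extract -> select -> evaluate -> stats. Every
#' stage's tables are written under `out_dir` together with the config
#' echo (and its hash); the run is byte-reproducible for a fixed
#' `config$seed`.
#'
#' @param config `dataset_config`.
#' @param out_dir output directory (`NULL` for no files).
#' @param electrodes electrodes to analyse (default all in config).
#' @param classifiers classifier ids to benchmark.
#' @param select_electrode electrode whose ranking drives selection and
#'   repeatability (default the last electrode, Pz in the default
#'   montage).
#' @param threshold class-SU selection threshold.
#' @param top_k top-k prefix counted in selection frequency.
#' @param min_times count threshold for the "high" label; default one
#'   third of the number of group rankings.
#' @param n_bins discretization bins.
#' @param cv_repeats cross-validation repetitions (k = 10 folds each).
#' @param repeat_classifier classifier for the repeatability protocol.
#' @return list with `features`, `selection`, `frequency`, `accuracy`,
#'   `repeatability`, `ttest`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         electrodes = NULL,
                         classifiers = c("svm", "c45", "mlp", "lda"),
                         select_electrode = NULL,
                         threshold = 0.1, top_k = 10, min_times = NULL,
                         n_bins = 5, cv_repeats = 10,
                         repeat_classifier = "c45") {
  stopifnot(inherits(config, "dataset_config"))
  electrodes <- electrodes %||% names(config$channels)
  select_electrode <- select_electrode %||% electrodes[length(electrodes)]

  datasets <- generate_dataset(config)
  ft <- extract_feature_table(datasets, electrodes)

  sel <- cfs_per_dataset(ft, select_electrode, n_bins)
  acc_sel <- average_class_correlation(sel$mean_su, threshold)
  grp <- cfs_group_rankings(ft, select_electrode, n_bins)
  if (is.null(min_times)) min_times <- max(1L, round(length(grp) / 3))
  freq <- selection_frequency(grp, top_k, min_times)

  subsets <- list(full = seq_len(27), selected = acc_sel$selected)
  if (length(acc_sel$selected) == 0) subsets$selected <- NULL
  acc <- list()
  for (el in electrodes) {
    for (clf in classifiers) {
      for (sn in names(subsets)) {
        per_ds <- vapply(sort(unique(ft$dataset)), function(d) {
          fm <- feature_matrix(ft, el, d)
          pr <- eval_protocol("kfold", k = 10, repeats = cv_repeats,
                              classifier = clf,
                              seed = derive_seed(config$seed, match(el, electrodes),
                                                 match(clf, classifiers), d))
          crossval_accuracy(fm$X[, subsets[[sn]], drop = FALSE], fm$labels,
                            pr)$mean_accuracy
        }, numeric(1))
        acc[[length(acc) + 1]] <- data.frame(
          method = clf, feature_set = sn, electrode = el,
          accuracy = mean(per_ds))
      }
    }
  }
  acc <- do.call(rbind, acc)

  rep_rows <- lapply(sort(unique(ft$dataset)), function(d) {
    fm <- feature_matrix(ft, select_electrode, d)
    sub <- subsets$selected %||% subsets$full
    pr <- eval_protocol("fixed", repeats = 10,
                        test_per_emotion = min(8, config$trials_per_emotion - 1),
                        classifier = repeat_classifier,
                        seed = derive_seed(config$seed, 7777, d))
    rr <- repeatability_run(fm$X[, sub, drop = FALSE], fm$labels, pr)
    data.frame(dataset = d, t(rr$per_repeat), ave = rr$mean_accuracy)
  })
  repeatability <- do.call(rbind, rep_rows)

  tt <- paired_ttest_counts(ft)
  nl_sel <- intersect(acc_sel$selected, 19:27)
  hist_df <- if (length(nl_sel) > 0) {
    feature_histograms(ft, nl_sel, select_electrode)
  } else NULL

  res <- list(features = ft,
              mean_su = sel$mean_su,
              selection = acc_sel, frequency = freq, accuracy = acc,
              repeatability = repeatability, ttest = tt,
              histograms = hist_df,
              config_hash = config_hash(config))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      c(list(config_hash = res$config_hash,
             threshold = threshold, top_k = top_k, min_times = min_times,
             n_bins = n_bins, classifiers = classifiers,
             select_electrode = select_electrode), config_echo(config)),
      file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
    write_feature_table(ft, file.path(out_dir, "features.csv"))
    write.csv(data.frame(feature_id = seq_along(sel$mean_su),
                         mean_class_su = sel$mean_su,
                         selected = seq_along(sel$mean_su) %in%
                           acc_sel$selected),
              file.path(out_dir, "selection.csv"), row.names = FALSE)
    write.csv(freq, file.path(out_dir, "selection_frequency.csv"),
              row.names = FALSE)
    write.csv(acc, file.path(out_dir, "accuracy.csv"), row.names = FALSE)
    write.csv(repeatability, file.path(out_dir, "repeatability.csv"),
              row.names = FALSE)
    write.csv(rbind(as.data.frame(tt$counts),
                    Total = as.numeric(tt$totals)),
              file.path(out_dir, "ttest_counts.csv"))
    if (!is.null(hist_df)) {
      write.csv(hist_df, file.path(out_dir, "histograms.csv"),
                row.names = FALSE)
    }
  }
  invisible(res)
}
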