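# CSV/JSON interchange: recordings (one CSV per trial, channels as rows,
# with a JSON metadata sidecar carrying fs), feature tables (one row per
# dataset/trial/electrode, columns f01..f27 + label), and run
# configuration echoes.

# FNV-1a hash of a string, as a hex config fingerprint.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

config_echo <- function(config) {
  ch <- lapply(config$channels, function(sp) {
    list(name = sp$name, band_amp = sp$band_amp, band_cf = sp$band_cf,
         chaos_mix = as.list(sp$chaos_mix), noise_sd = sp$noise_sd)
  })
  list(n_datasets = config$n_datasets,
       trials_per_emotion = config$trials_per_emotion,
       fs = config$fs, epoch_s = config$epoch_s, seed = config$seed,
       band_ranges = default_band_ranges(), channels = ch)
}

config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(config_echo(config), auto_unbox = TRUE,
                         digits = NA))
}

#' Write / read a recording
#'
#' CSV dialect: a header row, first column `channel`, remaining columns
#' `s1`..`sN`; a sidecar `<path>.json` holds the sampling rate. Round
#' trips are lossless to 1e-9 relative precision.
#'
#' @param rec `eeg_recording`.
#' @param path CSV path.
#' @return `write_recording` the path invisibly; `read_recording` an
#'   `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(channel = rec$channel_names,
                   rec$data, check.names = FALSE)
  colnames(df) <- c("channel", paste0("s", seq_len(ncol(rec$data))))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar: ", meta_path, " (fs unknown)")
  }
  meta <- jsonlite::read_json(meta_path)
  lines <- readLines(path)
  ncols <- lengths(regmatches(lines, gregexpr(",", lines))) + 1
  if (length(unique(ncols)) != 1) {
    stop("ragged CSV: row ", which(ncols != ncols[1])[1],
         " has ", ncols[which(ncols != ncols[1])[1]], " fields, expected ",
         ncols[1])
  }
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  recording(m, fs = meta$fs, channel_names = as.character(df$channel))
}

#' Write a generated dataset to a directory
#'
#' One `trial_###.csv` recording per trial, a `labels.csv` (trial_id,
#' emotion) and a `metadata.json` (fs, seed, config echo, config hash).
#'
#' @param ds `eeg_dataset`.
#' @param dir output directory (created).
#' @return `dir` invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "eeg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in ds$trial_id) {
    write_recording(dataset_trial(ds, i),
                    file.path(dir, sprintf("trial_%03d.csv", i)))
  }
  write.csv(data.frame(trial_id = ds$trial_id,
                       emotion = as.character(ds$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(dataset_id = ds$dataset_id, config_hash = config_hash(ds$config)),
      config_echo(ds$config)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Extract the feature table of one or more datasets
#'
#' Runs the per-epoch pipeline (50 Hz notch, band decomposition, linear +
#' nonlinear feature extraction) for every trial x electrode and stacks
#' the results into the canonical feature table: one row per (dataset,
#' trial, electrode) with columns `f01`..`f27` plus `label`.
#'
#' @param datasets an `eeg_dataset` or list of them.
#' @param electrodes channel subset (default all).
#' @param band_ranges band ranges.
#' @param params `nonlinear_params`.
#' @param notch apply the 50 Hz notch first (default TRUE).
#' @return data.frame feature table.
#' @export
extract_feature_table <- function(datasets, electrodes = NULL,
                                  band_ranges = default_band_ranges(),
                                  params = nonlinear_params(),
                                  notch = TRUE) {
  if (inherits(datasets, "eeg_dataset")) datasets <- list(datasets)
  rows <- list()
  for (ds in datasets) {
    els <- electrodes %||% ds$channel_names
    for (el in els) {
      j <- match(el, ds$channel_names)
      if (is.na(j)) stop("electrode not in dataset: ", el)
      for (i in ds$trial_id) {
        x <- ds$data[i, j, ]
        if (notch) x <- notch_50hz(x, ds$fs)
        fv <- extract_features(x, ds$fs, band_ranges, params)
        rows[[length(rows) + 1]] <- data.frame(
          dataset = ds$dataset_id, trial = i, electrode = el,
          label = as.character(ds$labels[i]),
          as.list(fv), check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table
#'
#' Writes the canonical CSV plus a companion `<path>.dictionary.csv`
#' mapping `f01`..`f27` to the canonical feature names.
#'
#' @param ft feature table data.frame.
#' @param path CSV path.
#' @return path / data.frame.
#' @export
write_feature_table <- function(ft, path) {
  write.csv(ft, path, row.names = FALSE)
  write.csv(feature_dictionary(),
            paste0(sub("\\.csv$", "", path), ".dictionary.csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("dataset", "trial", "electrode", "label")
  missing_cols <- setdiff(need, names(ft))
  if (length(missing_cols) > 0) {
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!any(grepl("^f[0-9]+$", names(ft)))) {
    stop("feature table missing feature columns f01..")
  }
  ft
}

feature_columns <- function(ft) grep("^f[0-9]+$", names(ft), value = TRUE)

feature_matrix <- function(ft, electrode = NULL, dataset = NULL) {
  if (!is.null(electrode)) ft <- ft[ft$electrode == electrode, ]
  if (!is.null(dataset)) ft <- ft[ft$dataset == dataset, ]
  list(X = as.matrix(ft[, feature_columns(ft)]),
       labels = factor(ft$label, levels = .emotions))
}
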