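test_that("generated datasets have the configured shape and label blocks", {
  cfg <- dataset_config(n_datasets = 2, trials_per_emotion = 3,
                        channels = default_channel_specs()[c("FP1", "Pz")],
                        epoch_s = 2, seed = 5)
  dss <- generate_dataset(cfg)
  expect_length(dss, 2)
  ds <- dss[[1]]
  expect_equal(dim(ds$data), c(12, 2, 512))
  expect_equal(as.vector(table(ds$labels)), rep(3, 4))
  expect_equal(levels(ds$labels), c("calm", "joy", "sad", "angry"))
  # block order: first block all calm, last all angry
  expect_equal(as.character(ds$labels[1:3]), rep("calm", 3))
  expect_equal(as.character(ds$labels[10:12]), rep("angry", 3))
})

test_that("default configuration mirrors the 15 x 80 x 12 x 3840 design", {
  cfg <- dataset_config()
  expect_equal(cfg$n_datasets, 15L)
  expect_equal(4 * cfg$trials_per_emotion, 80L)
  expect_length(cfg$channels, 12)
  expect_equal(cfg$n_samples, 3840L)
  expect_equal(names(cfg$channels),
               c("FP1", "FP2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4",
                 "T3", "T4", "Pz"))
})

test_that("degenerate mixture is a pure sinusoid at the planted frequency", {
  spec <- channel_spec(
    "X",
    band_amp = lapply(setNames(nm = emotion_levels()), function(e)
      c(theta = 0, alpha = 1, beta = 0)),
    band_cf = lapply(setNames(nm = emotion_levels()), function(e)
      c(theta = 6, alpha = 10, beta = 20)),
    chaos_mix = setNames(rep(0, 4), emotion_levels()),
    noise_sd = 0)
  x <- band_mixture_signal(spec, "calm", 2560, 256, seed = 1)
  sp <- autocorr_spectrum(x, fs = 256)
  half <- seq_len(length(x) %/% 2)
  expect_equal(sp$freq[half][which.max(sp$power[half])], 10, tolerance = 0.11)
  # and it is a single sinusoid: amplitude 1 (to sampling granularity),
  # zero mean
  expect_lt(abs(max(x) - 1), 0.01)
  expect_lt(abs(mean(x)), 1e-3)
})

test_that("generation is deterministic in the seed and errors are labeled", {
  spec <- default_channel_specs()$Pz
  a <- band_mixture_signal(spec, "joy", 512, 256, seed = 7)
  b <- band_mixture_signal(spec, "joy", 512, 256, seed = 7)
  d <- band_mixture_signal(spec, "joy", 512, 256, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_error(band_mixture_signal(spec, "bored", 512, 256, 1), "emotion")
  expect_error(dataset_config(channels = list()), "empty")

  cfg <- dataset_config(n_datasets = 1, trials_per_emotion = 2,
                        channels = default_channel_specs()["Pz"],
                        epoch_s = 1, seed = 3)
  expect_identical(generate_dataset(cfg, 1)$data,
                   generate_dataset(cfg, 1)$data)
})

test_that("a pure-chaos mixture is more entropic than the sinusoidal one", {
  mk <- function(amp, mix) {
    channel_spec(
      "X",
      band_amp = lapply(setNames(nm = emotion_levels()), function(e)
        c(theta = 0, alpha = amp, beta = 0)),
      band_cf = lapply(setNames(nm = emotion_levels()), function(e)
        c(theta = 6, alpha = 10, beta = 20)),
      chaos_mix = setNames(rep(mix, 4), emotion_levels()),
      noise_sd = 0)
  }
  chaos <- band_mixture_signal(mk(0, 1), "calm", 1024, 256, seed = 2)
  sine <- band_mixture_signal(mk(1, 0), "calm", 1024, 256, seed = 2)
  expect_gt(sample_entropy(chaos), sample_entropy(sine))
})

test_that("band power grows monotonically with the planted amplitude", {
  mk <- function(alpha_amp) {
    channel_spec(
      "X",
      band_amp = lapply(setNames(nm = emotion_levels()), function(e)
        c(theta = 2, alpha = alpha_amp, beta = 2)),
      band_cf = lapply(setNames(nm = emotion_levels()), function(e)
        c(theta = 6, alpha = 10, beta = 20)),
      chaos_mix = setNames(rep(0, 4), emotion_levels()),
      noise_sd = 1)
  }
  pow <- function(amp) {
    x <- band_mixture_signal(mk(amp), "joy", 1024, 256, seed = 4)
    power_sum(band_decompose(x, 256)$alpha)
  }
  expect_gt(pow(8), 3 * pow(2))   # doubling amplitude vs the halved case
})

test_that("an emotion-invariant channel is class-uninformative (SU at the permuted baseline)", {
  cfg <- dataset_config(n_datasets = 1, trials_per_emotion = 10,
                        channels = default_channel_specs()["FP1"],
                        epoch_s = 2, seed = 21)
  ds <- generate_dataset(cfg, 1)
  ft <- extract_feature_table(ds, notch = FALSE)
  fm <- museeg:::feature_matrix(ft, "FP1")
  tab <- discretize(fm$X, fm$labels, 5)
  obs <- museeg:::su_class_vector(tab)
  set.seed(99)
  null_q <- sapply(1:200, function(i) {
    perm <- tab
    perm$labels <- sample(tab$labels)
    max(museeg:::su_class_vector(perm))
  })
  # observed per-feature SU behaves like the permuted-label baseline:
  # nearly all features below the null's 95th percentile of the maximum
  expect_lte(sum(obs > quantile(null_q, 0.95)), 2)
})
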