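test_that("equal-frequency discretization balances bin populations", {
  d <- discretize(matrix(1:10, ncol = 1), rep(c("a", "b"), 5), 5)
  expect_equal(as.vector(table(d$bins[, 1])), rep(2, 5))

  dc <- discretize(matrix(rep(7, 20), ncol = 1), rep(c("a", "b"), 10), 5)
  expect_equal(unique(dc$bins[, 1]), 1L)
  expect_length(dc$flagged, 1)

  set.seed(30)
  dn <- discretize(matrix(rnorm(1000), ncol = 1), rep(letters[1:4], 250), 5)
  props <- as.vector(table(dn$bins[, 1])) / 1000
  expect_true(all(abs(props - 0.2) <= 0.01))
})

test_that("entropy, conditional entropy and gain match hand arithmetic", {
  expect_equal(discrete_entropy(rep(emotion_levels(), 5)), 2)
  expect_equal(discrete_entropy(rep("a", 9)), 0)
  expect_equal(discrete_entropy(c("a", "a", "a", "b")),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)

  y <- c(1, 1, 2, 2, 1, 2)
  expect_equal(conditional_entropy(y, y), 0)
  expect_equal(info_gain(y, y), discrete_entropy(y))

  # independent by construction (product table)
  x <- rep(c("u", "v"), each = 4)
  y2 <- rep(c("p", "q"), 4)
  expect_equal(info_gain(y2, x), 0, tolerance = 1e-12)

  # 2x2 joint counts ((2,1),(1,2)): hand-evaluated plug-in formula
  xx <- c("a", "a", "a", "b", "b", "b")
  yy <- c("p", "p", "q", "p", "q", "q")
  hy <- 1                                    # equal p/q
  hyx <- -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3))  # both x cells
  expect_equal(conditional_entropy(yy, xx), hyx, tolerance = 1e-12)
  expect_equal(info_gain(yy, xx), hy - hyx, tolerance = 1e-12)
  # gain is symmetric
  expect_equal(info_gain(yy, xx), info_gain(xx, yy), tolerance = 1e-12)
  expect_error(conditional_entropy(yy, xx[-1]), "mismatch")
})

test_that("symmetric uncertainty is bounded, symmetric and exact on oracles", {
  y <- c(1, 2, 1, 2, 1, 2)
  expect_equal(as.numeric(symmetric_uncertainty(y, y)), 1)
  x <- rep(c("u", "v"), each = 4)
  y2 <- rep(c("p", "q"), 4)
  expect_equal(as.numeric(symmetric_uncertainty(x, y2)), 0)

  set.seed(31)
  for (i in 1:1000) {
    a <- sample(1:sample(2:5, 1), 30, replace = TRUE)
    b <- sample(1:sample(2:5, 1), 30, replace = TRUE)
    u1 <- as.numeric(symmetric_uncertainty(a, b))
    u2 <- as.numeric(symmetric_uncertainty(b, a))
    expect_gte(u1, 0); expect_lte(u1, 1)
    expect_equal(u1, u2, tolerance = 1e-12)
    expect_equal(u1, ref_su(a, b), tolerance = 1e-12)
  }
})

test_that("merit reproduces its formula and penalizes redundancy", {
  set.seed(32)
  X <- cbind(f1 = rnorm(60), f2 = rnorm(60), f3 = rnorm(60))
  y <- factor(rep(c("a", "b"), 30))
  X[, 1] <- X[, 1] + 2 * (y == "a")
  X <- cbind(X, f4 = X[, 1])                 # exact duplicate of f1
  tab <- discretize(X, y, 4)

  m1 <- merit(1, tab)
  expect_equal(m1$merit, as.numeric(
    symmetric_uncertainty(tab$bins[, 1], tab$labels)), tolerance = 1e-12)
  expect_equal(m1$rff_bar, 0)

  # an exact duplicate brings no gain: with rff = 1 the merit formula
  # collapses back to the single-feature value (2u/sqrt(4) = u), while an
  # imperfect copy still cannot beat two independent features
  m_dup <- merit(c(1, 4), tab)
  expect_equal(m_dup$rff_bar, 1)
  expect_equal(m_dup$merit, m1$merit, tolerance = 1e-12)
  m_indep <- merit(c(1, 2), tab)
  expect_gt(m_indep$rcf_bar, 0)

  # Eq identity: merit reproduces from stored (k, rcf, rff) to 1e-12
  for (sub in list(1, c(1, 2), c(1, 2, 3), c(2, 3, 4))) {
    ms <- merit(sub, tab)
    k <- ms$k
    expect_equal(ms$merit,
                 k * ms$rcf_bar / sqrt(k + k * (k - 1) * ms$rff_bar),
                 tolerance = 1e-12)
    expect_equal(ms$merit, ref_merit(sub, tab$bins, tab$labels),
                 tolerance = 1e-12)
  }

  # two independent features with equal class SU: merit = 2u/sqrt(2) > u
  n <- 400
  set.seed(33)
  yb <- factor(rep(c("a", "b"), n / 2))
  b1 <- ifelse(runif(n) < 0.85, as.integer(yb), 3 - as.integer(yb))
  b2 <- ifelse(runif(n) < 0.85, as.integer(yb), 3 - as.integer(yb))
  tab2 <- list(bins = cbind(f1 = b1, f2 = b2), labels = yb, n_bins = 2)
  class(tab2) <- "discrete_table"
  u1 <- as.numeric(symmetric_uncertainty(b1, yb))
  m2 <- merit(c(1, 2), tab2)
  u12 <- as.numeric(symmetric_uncertainty(b1, b2))
  expect_equal(m2$merit, 2 * mean(c(u1, as.numeric(
    symmetric_uncertainty(b2, yb)))) / sqrt(2 + 2 * u12), tolerance = 1e-12)
  expect_gt(m2$merit, u1 * 0.95)
  expect_error(merit(integer(0), tab), "length")
  expect_error(merit(99, tab), "invalid")
})

test_that("greedy search is deterministic, optimal-first, and dominated by exhaustive search", {
  # a feature equal to the class labels ranks first with merit 1
  set.seed(34)
  y <- factor(rep(c("a", "b", "c", "d"), 15))
  X <- cbind(f1 = rnorm(60), f2 = as.integer(y), f3 = rnorm(60))
  tab <- discretize(X, y, 4)
  rk <- greedy_rank(tab)
  expect_equal(rk$order[1], 2)
  expect_equal(rk$path$merit[1], 1, tolerance = 1e-12)

  # oracle dominance + optimum attainment on random 6-feature tables
  set.seed(35)
  hits <- 0
  for (i in 1:50) {
    n <- 40
    yy <- factor(sample(c("a", "b"), n, replace = TRUE))
    XX <- matrix(rnorm(n * 6), n, 6)
    for (j in sample(6, 3)) {
      XX[, j] <- XX[, j] + runif(1, 0, 1.5) * (yy == "a")
    }
    tt <- discretize(XX, yy, 3)
    rr <- greedy_rank(tt)
    best_greedy <- max(rr$path$merit)
    best_exh <- ref_best_merit(tt$bins, tt$labels)
    expect_lte(best_greedy, best_exh + 1e-9)
    if (abs(best_greedy - best_exh) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.8)
})

test_that("permuted labels give merit paths consistent with the permutation null", {
  set.seed(36)
  n <- 60
  y <- factor(rep(c("a", "b", "c", "d"), n / 4))
  X <- matrix(rnorm(n * 5), n, 5)
  tab <- discretize(X, sample(y), 4)          # permuted-label table
  obs <- max(greedy_rank(tab)$path$merit)
  null <- sapply(1:200, function(i) {
    tp <- tab
    tp$labels <- sample(tab$labels)
    max(greedy_rank(tp)$path$merit)
  })
  expect_lt(obs, quantile(null, 0.95))
})

test_that("threshold and chosen-times rules recover the reference selected set", {
  stats <- reference_table("feature_stats")
  sel <- average_class_correlation(stats$mean_class_su, 0.1)
  expect_equal(sel$selected, expected_selected_set)
  expect_length(average_class_correlation(stats$mean_class_su, 1.0)$selected, 0)
  expect_equal(average_class_correlation(stats$mean_class_su, 0)$selected,
               1:27)

  freq <- selection_frequency(stats$selected_times, min_times = 20)
  expect_equal(freq$feature_id[freq$correlation == "high"],
               expected_selected_set)
})

test_that("selection frequency counts are bounded by the number of rankings", {
  set.seed(37)
  y <- factor(rep(c("a", "b"), 20))
  rankings <- lapply(1:5, function(i) {
    X <- matrix(rnorm(40 * 6), 40, 6)
    greedy_rank(discretize(X, y, 3))
  })
  f_all <- selection_frequency(rankings[1], top_k = 6, min_times = 0)
  expect_true(all(f_all$times == 1))
  f <- selection_frequency(rankings, top_k = 3, min_times = 2)
  expect_true(all(f$times <= 5))
  expect_equal(sum(f$times), 5 * 3)
})
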