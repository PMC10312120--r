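test_that("zscore_clean standardizes and removes |z| > 3 trials", {
  z <- zscore_clean(c(1, 2, 3), c(2, 4, 6))
  expect_true(all(z$keep))
  expect_equal(mean(z$x), 0); expect_equal(sd(z$x), 1)
  expect_equal(mean(z$y), 0); expect_equal(sd(z$y), 1)

  set.seed(3)
  x <- rnorm(100); y <- rnorm(100)
  y[40] <- mean(y[-40]) + 6 * sd(y[-40])   # single extreme trial
  z <- zscore_clean(x, y)
  expect_false(z$keep[40])
  expect_equal(sum(!z$keep), 1L)

  expect_error(zscore_clean(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("regression slopes match the closed form and equal the correlation", {
  x <- matrix(c(1.2, 0.5, -0.3, 2.0, -1.1), 5, 1)
  y <- c(320, 410, 500, 290, 600)
  r <- regress_timecourse(x, y)
  zx <- scale(x[, 1])[, 1]; zy <- scale(y)[, 1]
  manual <- sum((zx - mean(zx)) * (zy - mean(zy))) / sum((zx - mean(zx))^2)
  expect_equal(r$slope[1], manual, tolerance = 1e-12)
  expect_equal(r$slope[1], cor(x[, 1], y), tolerance = 1e-12)

  # y = x exactly
  ident <- regress_timecourse(cbind(y, y), y)
  expect_equal(ident$slope, c(1, 1))
  expect_equal(ident$r2, c(1, 1))
  expect_equal(ident$max_r2, 1)

  set.seed(5)
  big <- regress_timecourse(matrix(rnorm(10000 * 3), 10000, 3), rnorm(10000))
  expect_true(all(abs(big$slope) < 0.05))

  # slope == Pearson correlation on random data, after cleaning
  for (s in 1:5) {
    set.seed(s)
    xx <- rnorm(60); yy <- rnorm(60)
    z <- zscore_clean(xx, yy)
    r <- regress_timecourse(matrix(xx, 60, 1), yy)
    expect_equal(r$slope[1], cor(z$x, z$y), tolerance = 1e-12)
  }
})

test_that("shuffled nulls are centered at zero and reproducible", {
  set.seed(9)
  x <- rnorm(1000)
  nul <- shuffled_null(matrix(x, 1000, 2), x, n_shuffles = 100, seed = 4)
  expect_true(all(abs(nul) < 0.1))
  expect_lt(abs(mean(nul)), 3 / sqrt(100 * 1000))
  expect_identical(nul,
                   shuffled_null(matrix(x, 1000, 2), x, 100, seed = 4))
})

test_that("identical conditions produce no clusters and p = 1", {
  set.seed(2)
  A <- matrix(rnorm(10 * 20), 10, 20)
  ct <- cluster_permutation_test(A, A, n_perm = 200, seed = 1)
  expect_length(ct$clusters, 0L)
  expect_equal(ct$min_p, 1)
  expect_error(cluster_permutation_test(A[1, , drop = FALSE],
                                        A[1, , drop = FALSE]), "2 subjects")
})

test_that("an injected shift is detected with a covering cluster", {
  freqs <- seq(13, 30, by = 0.5)
  shift_bins <- which(freqs >= 20 & freqs <= 26)
  set.seed(21)
  A <- matrix(rnorm(20 * length(freqs)), 20)
  B <- A + matrix(rnorm(20 * length(freqs)), 20)   # within-subject noise SD 1
  A2 <- A
  A2[, shift_bins] <- A2[, shift_bins] + 5
  ct <- cluster_permutation_test(A2, B, n_perm = 1000, seed = 3)
  expect_gt(length(ct$clusters), 0L)
  top <- ct$clusters[[which.min(ct$p)]]
  expect_true(all(shift_bins %in% top))
  expect_lte(min(ct$p), 0.01)
  expect_gt(ct$d[which.min(ct$p)], 0)
})

test_that("permutation p-values are approximately valid under the null", {
  set.seed(31)
  rej <- 0L
  for (i in 1:120) {
    A <- matrix(rnorm(12 * 25), 12)
    B <- matrix(rnorm(12 * 25), 12)
    ct <- cluster_permutation_test(A, B, n_perm = 250, seed = i)
    rej <- rej + (ct$min_p < 0.05)
  }
  expect_lt(rej / 120, 0.12)
  expect_gt(rej / 120, 0.005)
})

test_that("Cohen's d per cluster matches hand arithmetic", {
  D <- matrix(0, 4, 6)
  expect_equal(cohens_d_cluster(D, 1:3), 0)

  diffs <- c(2.0, 1.5, 2.5, 1.0, 3.0)   # cluster-averaged differences
  D <- matrix(diffs, 5, 4)
  expect_equal(cohens_d_cluster(D, 2:3), mean(diffs) / sd(diffs))

  hand <- matrix(c(1, 2, 0, 1,
                   3, 1, 2, 0,
                   2, 2, 1, 1,
                   0, 1, 1, 2,
                   1, 0, 2, 3), 5, 4, byrow = TRUE)
  m <- rowMeans(hand[, c(2, 3)])
  expect_equal(cohens_d_cluster(hand, c(2, 3)), mean(m) / sd(m))
  expect_error(cohens_d_cluster(hand, integer(0)), "empty")
})

test_that("median split is deterministic with median-valued trials going slow", {
  s <- median_split(c(300, 400, 500, 600))
  expect_setequal(s$fast, c(1, 2)); expect_setequal(s$slow, c(3, 4))

  s <- median_split(c(1, 2, 3))
  expect_equal(s$fast, 1L); expect_setequal(s$slow, c(2, 3))

  expect_warning(s <- median_split(rep(5, 4)), "identical")
  expect_length(s$fast, 0L); expect_length(s$slow, 4L)

  for (seed in 1:5) {
    set.seed(seed)
    rts <- sample(200:800, 31)
    s <- median_split(rts)
    expect_equal(sort(c(s$fast, s$slow)), 1:31)
    expect_length(intersect(s$fast, s$slow), 0L)
  }
})

test_that("paired contrasts match closed forms and flag degenerate input", {
  a <- c(5, 6, 7, 8, 9, 10)
  expect_equal(paired_contrast(a, a),
               list(statistic = 0, p = 1, d = 0, df = 5L, method = "t"))

  expect_warning(r <- paired_contrast(a + 1, a), "zero variance")
  expect_true(is.na(r$statistic))

  set.seed(8)
  b <- a + rnorm(6, 0.5)
  r <- paired_contrast(a, b)
  diffs <- a - b
  expect_equal(r$statistic, mean(diffs) / (sd(diffs) / sqrt(6)),
               tolerance = 1e-12)
  expect_equal(r$d, mean(diffs) / sd(diffs))

  # Wilcoxon z agrees with the textbook normal approximation
  w <- paired_contrast(a, b, method = "wilcoxon")
  nz <- diffs[diffs != 0]; n <- length(nz)
  V <- sum(rank(abs(nz))[nz > 0])
  z <- (V - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(w$statistic, z)
  expect_error(paired_contrast(1:2, 2:3), "3 paired")
})
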