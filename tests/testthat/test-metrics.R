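test_that("selectivity and tuning ratios match hand values and conventions", {
  expect_equal(cluster_selectivity(1, 0, 1, 0), 1)
  expect_equal(cluster_selectivity(0.3, 0.3, 1, 0), 0)
  expect_equal(cluster_selectivity(0.8, 0.2, 1, 0), 0.6)
  expect_equal(cluster_selectivity(2, 1, 5, 5), 0) # dead neuron convention
  expect_error(cluster_selectivity(1, 0, 0, 1), ">=")

  expect_equal(signal_selectivity(2, 2), 0)
  expect_equal(signal_selectivity(1, 0), 1)
  expect_equal(signal_selectivity(3, 1), 0.5)
  expect_warning(out <- signal_selectivity(0, 0), "zero")
  expect_equal(out, 0)
  expect_error(signal_selectivity(-1, 1), "nonnegative")

  expect_equal(relative_tuning(2, 1), 1 / 3)
  expect_equal(relative_tuning(1, 0), 1)
  expect_equal(relative_tuning(1, 1), 0)

  # scale invariance of all ratio measures
  expect_equal(signal_selectivity(3 * 7, 1 * 7), signal_selectivity(3, 1))
  expect_equal(relative_tuning(2 * 9, 1 * 9), relative_tuning(2, 1))
  expect_equal(cluster_selectivity(0.8 * 3, 0.2 * 3, 3, 0),
               cluster_selectivity(0.8, 0.2, 1, 0))
})

test_that("participation ratio measures effective dimensionality", {
  set.seed(1)
  # 4 independent unit-variance dimensions -> ~4
  Z <- matrix(rnorm(4000), 1000, 4)
  expect_equal(participation_ratio(Z), 4, tolerance = 0.1)

  # rank-1 data -> 1
  Z1 <- outer(rnorm(200), c(1, 2, 3))
  expect_equal(participation_ratio(Z1), 1, tolerance = 1e-8)

  # eigenvalues {3, 1} -> 16/10 (uncentred form on constructed data)
  Z2 <- rbind(c(sqrt(3), 0), c(-sqrt(3), 0), c(0, 1), c(0, -1))
  expect_equal(participation_ratio(Z2, center = FALSE), 1.6)

  # bounds and rotation invariance
  B <- 40; N <- 10
  Z3 <- matrix(rnorm(B * N), B, N) %*% diag(sqrt(seq(0.1, 3, length.out = N)))
  pr <- participation_ratio(Z3)
  expect_gte(pr, 1); expect_lte(pr, min(B - 1, N))
  Q <- qr.Q(qr(matrix(rnorm(N * N), N)))
  expect_equal(participation_ratio(Z3 %*% Q), pr, tolerance = 1e-8)

  expect_warning(pr0 <- participation_ratio(matrix(0, 5, 3)), "all-zero")
  expect_equal(pr0, 1)
})

test_that("linear readout matches chance and the Gaussian oracle", {
  set.seed(2)
  # separable blobs -> 1
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 8), 100, 2))
  y <- rep(c("a", "b"), each = 100)
  expect_equal(linear_readout_accuracy(X, y, X, y), 1)

  # shuffled labels -> ~ 1/C
  Xs <- matrix(rnorm(4000), 2000, 2)
  ys <- sample(rep(letters[1:4], each = 500))
  acc <- linear_readout_accuracy(Xs[1:1000, ], ys[1:1000],
                                 Xs[1001:2000, ], ys[1001:2000])
  expect_lt(abs(acc - 0.25), 0.05)

  # two spherical Gaussians: accuracy matches the Bayes-optimal linear rule
  mu <- 1.2
  n <- 1e4
  X2 <- rbind(matrix(rnorm(n / 2, -mu / 2), n / 2, 1),
              matrix(rnorm(n / 2, mu / 2), n / 2, 1))
  y2 <- rep(0:1, each = n / 2)
  idx <- sample.int(n)
  tr <- idx[1:(n / 2)]; te <- idx[(n / 2 + 1):n]
  acc2 <- linear_readout_accuracy(X2[tr, , drop = FALSE], y2[tr],
                                  X2[te, , drop = FALSE], y2[te])
  bayes <- pnorm(mu / 2)
  expect_lt(abs(acc2 - bayes), 0.02)

  # train accuracy >= held-out accuracy (overfit sanity)
  expect_gte(linear_readout_accuracy(X2[tr, , drop = FALSE], y2[tr],
                                     X2[tr, , drop = FALSE], y2[tr]) + 0.01,
             acc2)
  expect_error(linear_readout_accuracy(X, rep("a", 200), X, rep("a", 200)),
               "two classes")
})

test_that("signal reconstruction separates own activity from noise", {
  set.seed(3)
  n_bins <- 2000
  rates <- matrix(rpois(n_bins * 20, 5), n_bins, 20) / 0.025
  # target equal to one neuron's own binned rate -> R^2 ~ 1
  r2_self <- reconstruct_inputs(rates, rates[, 7], lambda = 1e-4)
  expect_gt(r2_self, 0.95)
  # independent white-noise target -> low held-out R^2
  r2_noise <- reconstruct_inputs(rates, rnorm(n_bins), lambda = 1e-4)
  expect_lt(r2_noise, 0.1)
  expect_error(reconstruct_inputs(rates, rnorm(10)), "misaligned")
})

test_that("representational similarity recovers constructed structure", {
  labels <- data.frame(f = rep(1:4, each = 20), g = rep(1:2, 40))
  # identical representations -> all ones
  Z <- matrix(1, 80, 6)
  expect_true(all(abs(representational_similarity(Z, labels, "f") - 1) < 1e-12))

  # orthogonal level representations -> identity
  Zo <- diag(4)[labels$f, ]
  rsm <- representational_similarity(Zo, labels, "f")
  expect_equal(unname(rsm), diag(4))

  # ring-structured embedding: adjacent levels most similar off-diagonal
  ang <- (labels$f - 1) * pi / 8
  Zr <- cbind(cos(ang), sin(ang)) + matrix(rnorm(160, 0, 1e-3), 80)
  rsm_r <- representational_similarity(Zr, labels, "f")
  for (i in 1:3) {
    non_adj <- setdiff(seq_len(4), c(i - 1, i, i + 1))
    if (length(non_adj))
      expect_gt(rsm_r[i, i + 1], max(rsm_r[i, non_adj]))
  }

  expect_error(representational_similarity(Z[1:20, ],
                                           data.frame(f = rep(1, 20),
                                                      g = rep(1:2, 10)), "f"),
               NA) # single-level factor still fine as grouping target
})

test_that("disentanglement score rewards axis-aligned codes", {
  set.seed(4)
  n <- 600
  labels <- data.frame(a = sample(1:4, n, TRUE), b = sample(1:3, n, TRUE),
                       c = sample(1:5, n, TRUE))
  # perfect one-neuron-per-factor code
  Z <- cbind(labels$a + rnorm(n, 0, 0.01), labels$b + rnorm(n, 0, 0.01),
             labels$c + rnorm(n, 0, 0.01))
  expect_gt(disentanglement_score(Z, labels), 0.9)

  # pure noise -> near chance (1 / n_factors)
  Zn <- matrix(rnorm(n * 6), n, 6)
  expect_lt(disentanglement_score(Zn, labels), 0.7)

  # invariant under unit permutation
  s1 <- disentanglement_score(Z, labels, seed = 9)
  s2 <- disentanglement_score(Z[, c(3, 1, 2)], labels, seed = 9)
  expect_equal(s1, s2)

  expect_warning(disentanglement_score(cbind(Z, Z),
                                       cbind(labels,
                                             d = rep(1, n))), "single-level")
})
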