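two_pairs <- function() {
  x <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10, 10.1))
  rownames(x) <- paste0("g", 1:4)
  x
}

test_that("k-means separates well-separated pairs and keeps duplicates together", {
  km <- kmeans_restarts(two_pairs(), 2, seed = 1)
  expect_equal(km$cluster[["g1"]], km$cluster[["g2"]])
  expect_equal(km$cluster[["g3"]], km$cluster[["g4"]])
  expect_false(km$cluster[["g1"]] == km$cluster[["g3"]])

  withr::with_seed(3, {
    x <- matrix(rnorm(14), ncol = 2)
    x <- rbind(x, x[3, ], x[5, ]) # duplicated rows
    rownames(x) <- paste0("p", 1:9)
    km <- kmeans_restarts(x, 3, seed = 2, n_restarts = 30)
    expect_equal(km$cluster[["p8"]], km$cluster[["p3"]])
    expect_equal(km$cluster[["p9"]], km$cluster[["p5"]])
  })
  expect_error(kmeans_restarts(two_pairs(), 5), "exceeds")
})

test_that("k-means with restarts attains the exhaustive 2-partition optimum", {
  withr::with_seed(9, {
    for (i in 1:5) {
      x <- matrix(rnorm(16), ncol = 2)
      rownames(x) <- paste0("g", 1:8)
      km <- kmeans_restarts(x, 2, seed = i, n_restarts = 50)
      expect_equal(km$tot_withinss, oracle_kmeans2_wss(x), tolerance = 1e-8)
    }
  })
})

test_that("consensus on separated data with full sampling is exactly 0/1", {
  run <- consensus_cluster(two_pairs(), 2, reps = 20, p_item = 1, seed = 3)
  m <- run$consensus_matrix
  expect_true(all(m %in% c(0, 1)))
  expect_equal(m["g1", "g2"], 1)
  expect_equal(m["g3", "g4"], 1)
  expect_equal(m["g1", "g3"], 0)
  expect_true(isSymmetric(m))
  expect_error(consensus_cluster(two_pairs(), 2, p_item = 0), "p_item")
  expect_error(consensus_cluster(two_pairs(), 1, p_item = 0.8), "at least 2")
})

test_that("a single resample reduces to one k-means co-clustering indicator", {
  withr::with_seed(5, x <- matrix(rnorm(30), ncol = 2))
  rownames(x) <- paste0("g", 1:15)
  run <- consensus_cluster(x, 3, reps = 1, p_item = 0.8, seed = 11)
  m <- run$consensus_matrix
  sampled <- which(diag(run$cosample_counts) == 1)
  sub <- m[sampled, sampled]
  expect_true(all(sub %in% c(0, 1)))
  # the sampled block is a valid partition indicator: transitivity
  for (i in seq_along(sampled)) {
    for (j in seq_along(sampled)) {
      for (k in seq_along(sampled)) {
        if (sub[i, j] == 1 && sub[j, k] == 1) expect_equal(sub[i, k], 1)
      }
    }
  }
  # pairs never co-sampled are flagged
  expect_equal(
    run$n_never_cosampled,
    sum(run$cosample_counts[upper.tri(m)] == 0)
  )
})

test_that("consensus matrix invariants hold and entries stabilize with reps", {
  withr::with_seed(6, x <- matrix(rnorm(50), ncol = 2))
  rownames(x) <- paste0("g", 1:25)
  off <- upper.tri(matrix(0, 25, 25))
  vals_big <- vals_small <- matrix(NA_real_, sum(off), 10)
  for (seed in 1:10) {
    big <- consensus_cluster(x, 2, reps = 200, p_item = 0.8, seed = seed)
    small <- consensus_cluster(x, 2, reps = 20, p_item = 0.8, seed = seed)
    for (run in list(big, small)) {
      m <- run$consensus_matrix
      expect_true(isSymmetric(m))
      expect_true(all(m >= 0 & m <= 1))
      expect_true(all(diag(m) == 1))
      expect_true(all(run$cooccur_counts <= run$cosample_counts))
    }
    vals_big[, seed] <- big$consensus_matrix[off]
    vals_small[, seed] <- small$consensus_matrix[off]
  }
  # per-pair consensus values settle as reps grow: across-seed sampling
  # variance is smaller with 200 resamples than with 20
  var_big <- mean(apply(vals_big, 1, stats::var))
  var_small <- mean(apply(vals_small, 1, stats::var))
  expect_lt(var_big, var_small)
})

test_that("final clusters recover ideal blocks and match the naive UPGMA oracle", {
  blocks <- rep(1:3, times = c(4, 5, 3))
  m <- outer(blocks, blocks, function(a, b) as.numeric(a == b))
  dimnames(m) <- list(paste0("g", 1:12), paste0("g", 1:12))
  cl <- final_clusters(m, 3)
  expect_true(same_partition(cl, blocks))

  ones <- matrix(1, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  expect_equal(unname(final_clusters(ones, 1)), rep(1, 6))

  withr::with_seed(8, {
    for (i in 1:5) {
      n <- sample(8:20, 1)
      m <- matrix(runif(n * n), n, n)
      m <- (m + t(m)) / 2
      diag(m) <- 1
      dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
      k <- sample(2:4, 1)
      expect_true(same_partition(
        final_clusters(m, k),
        oracle_average_linkage(1 - m, k)
      ))
    }
  })
  expect_error(final_clusters(ones, 10), "exceeds")
})

test_that("delta-area diagnostics suggest the planted number of blocks", {
  withr::with_seed(12, {
    centers <- matrix(c(0, 0, 8, 0, 0, 8), ncol = 2, byrow = TRUE)
    x <- centers[rep(1:3, each = 15), ] + matrix(rnorm(90, sd = 0.5), ncol = 2)
  })
  rownames(x) <- paste0("g", 1:45)
  ck <- choose_k(x, max_k = 6, reps = 50, p_item = 0.8, seed = 4)
  expect_equal(ck$suggested_k, 3)
  # CDF at 1.0 is 1 for every k
  expect_true(all(vapply(ck$cdf, function(f) f(1), numeric(1)) == 1))
  # beyond the true k the relative gain collapses
  expect_true(all(ck$delta_area[c("k5", "k6")] <
    ck$delta_area[["k3"]]))
})

test_that("PCA fractions and reconstruction behave", {
  # perfectly collinear data: PC1 carries everything
  t_line <- seq(-2, 2, length.out = 20)
  x <- cbind(t_line, 2 * t_line)
  p <- pca_features(x)
  expect_equal(p$var_frac[1], 1, tolerance = 1e-12)

  withr::with_seed(14, xi <- matrix(rnorm(20000), ncol = 2))
  pi2 <- pca_features(xi)
  expect_equal(unname(pi2$var_frac), c(0.5, 0.5), tolerance = 0.02)

  withr::with_seed(15, xr <- matrix(rnorm(60), ncol = 3))
  pr <- pca_features(xr)
  rec <- pr$scores %*% t(pr$loadings)
  rec <- sweep(rec, 2, -pr$center)
  expect_equal(unname(rec), unname(xr), tolerance = 1e-9)
  expect_lte(sum(pr$var_frac), 1 + 1e-9)
  expect_error(pca_features(xr[1, , drop = FALSE]), "two rows")
})

test_that("cluster composition fractions are exact and normalized", {
  assign <- setNames(c(1, 1, 2, 2, 2, 1, 2, 1), paste0("g", 1:8))
  groups <- setNames(rep(c("I", "IV"), each = 4), paste0("g", 1:8))
  comp <- cluster_composition(assign, groups)
  # hand count: group I genes g1 g2 g3 g4 -> clusters 1,1,2,2
  gi <- comp[comp$group == "I", ]
  expect_equal(gi$fraction[gi$cluster == "1"], 0.5)
  expect_equal(gi$fraction[gi$cluster == "2"], 0.5)
  giv <- comp[comp$group == "IV", ]
  expect_equal(giv$fraction[giv$cluster == "1"], 0.5)
  sums <- tapply(comp$fraction, comp$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  one <- cluster_composition(
    setNames(rep(1, 4), paste0("g", 1:4)),
    setNames(rep(c("I", "II"), 2), paste0("g", 1:4))
  )
  expect_true(all(one$fraction == 1))
})
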