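# Independent oracles used across the suite.  Each is a deliberately naive
# reference implementation (enumeration, closed form, O(n^3) loops) kept
# separate from the code paths it checks.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins.  Probabilities no larger than the
# observed one (up to the conventional 1 + 1e-7 relative slack) are summed.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c # first column margin
  n <- b + d
  k <- a + b # first row margin
  x_all <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x_all, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimal within-cluster sum of squares over all 2-partitions (n <= ~12).
oracle_kmeans2_wss <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 0; skip empty
    assign <- as.integer(intToBits(code))[1:n]
    wss <- 0
    for (g in 0:1) {
      xs <- x[assign == g, , drop = FALSE]
      ctr <- colMeans(xs)
      wss <- wss + sum(sweep(xs, 2, ctr)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# Naive average-linkage (UPGMA) agglomeration on a dissimilarity matrix,
# cut at k clusters.  Returns integer labels.
oracle_average_linkage <- function(d, k) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  dist_between <- function(a, b) mean(d[a, b])
  while (length(members) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        dd <- dist_between(members[[i]], members[[j]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(members)) labels[members[[i]]] <- i
  labels
}

# Two partitions equal up to label renaming?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Bayes classification of activity from the true generative densities of
# the continuous activity-linked features: Ka/Ks (scaled logit-normal), Ks
# (log-normal), the FBXD e-value exponent (normal) and the expression
# matrix (log values are compound-symmetric Gaussian: a gene-level random
# mean plus iid within-gene noise, so the per-gene log mean and log
# variance carry the whole likelihood).  Ties (at separation 0 the two
# densities coincide exactly) are broken by a seeded coin flip.
oracle_bayes_activity <- function(tbl, expression, separation, seed = 1) {
  p <- famrank::sim_parameters()

  llr <- 0
  lat <- stats::qlogis(pmin(pmax(tbl$ka_ks / p$ka_ks$scale, 1e-12), 1 - 1e-12))
  llr <- llr +
    stats::dnorm(lat, p$ka_ks$base_logit - p$ka_ks$unit_shift * separation,
      p$ka_ks$sigma, log = TRUE) -
    stats::dnorm(lat, p$ka_ks$base_logit, p$ka_ks$sigma, log = TRUE)

  lks <- log(tbl$ks)
  llr <- llr +
    stats::dnorm(lks, p$ks$base_meanlog + p$ks$unit_shift * separation,
      p$ks$sdlog, log = TRUE) -
    stats::dnorm(lks, p$ks$base_meanlog, p$ks$sdlog, log = TRUE)

  fb <- tbl$fbxd_evalue_exp
  llr <- llr +
    stats::dnorm(fb, p$fbxd$base_exp + p$fbxd$unit_shift * separation,
      p$fbxd$sigma, log = TRUE) -
    stats::dnorm(fb, p$fbxd$base_exp, p$fbxd$sigma, log = TRUE)

  lx <- log(expression[tbl$gene_id, , drop = FALSE])
  k <- ncol(lx)
  xbar <- rowMeans(lx)
  ss <- rowSums((lx - xbar)^2)
  ep <- p$expression
  expr_ll <- function(meanlog, sdlog) {
    v <- sdlog^2
    -(k - 1) / 2 * log(v) - ss / (2 * v) -
      0.5 * log(ep$gene_sd^2 + v / k) -
      (xbar - meanlog)^2 / (2 * (ep$gene_sd^2 + v / k))
  }
  llr <- llr +
    expr_ll(ep$base_meanlog, ep$base_sdlog) - # active: no shift
    expr_ll(
      ep$base_meanlog - ep$unit_shift * separation,
      ep$base_sdlog + ep$unit_sdlog * separation
    )

  out <- ifelse(llr > 0, "active", "inactive")
  tie <- llr == 0
  if (any(tie)) {
    coin <- withr::with_seed(seed, stats::runif(sum(tie)) < 0.5)
    out[tie] <- ifelse(coin, "active", "inactive")
  }
  out
}

# Per-row expression summaries by direct arithmetic, independent of
# summarize_expression().
oracle_row_summaries <- function(m) {
  t(apply(m, 1, function(x) {
    mu <- sum(x) / length(x)
    s <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    c(mean = mu, median = stats::median(x), max = max(x),
      cv = if (mu > 0) s / mu else NA_real_)
  }))
}

# A tiny labeled fixture shared by several ensemble tests: two clearly
# separated Gaussian classes in two dimensions.
make_separable_xy <- function(n_per_class = 10, shift = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(2 * n_per_class), ncol = 2),
      matrix(rnorm(2 * n_per_class, mean = shift), ncol = 2)
    )
  })
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("g%03d", seq_len(2 * n_per_class))
  list(x = x, y = rep(c(0, 1), each = n_per_class))
}
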