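#' Seeded k-means with restarts
#'
#' Euclidean k-means on a (standardized) feature matrix: best of
#' `n_restarts` seeded starts by the within-cluster sum of squares,
#' deterministic given `seed`.  The optimization itself is delegated to
#' [stats::kmeans()]; in the rare event of a degenerate start producing an
#' empty cluster the fit is retried from a freshly derived seed.
#'
#' @param x Numeric matrix, observations in rows.
#' @param k Number of clusters, `2 <= k <= nrow(x)` (k = 1 is allowed).
#' @param seed Integer seed.
#' @param n_restarts Number of random starts.
#' @param iter_max Iteration cap per start.
#' @return List with `cluster` (integer vector, named by row names) and
#'   `tot_withinss` (the objective value).
#' @export
kmeans_restarts <- function(x, k, seed = 1L, n_restarts = 25, iter_max = 100) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of observations", call. = FALSE)
  fit <- NULL
  for (attempt in 0:5) {
    fit <- tryCatch(
      with_substream(
        substream_seed(seed, "kmeans", attempt),
        suppressWarnings(
          stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = iter_max)
        )
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed to produce k non-empty clusters", call. = FALSE)
  cl <- fit$cluster
  names(cl) <- rownames(x)
  list(cluster = cl, tot_withinss = fit$tot.withinss)
}

#' Resampling-based consensus clustering
#'
#' Monti-style consensus k-means: each of `reps` resamples draws
#' `floor(p_item * n)` genes without replacement (features are never
#' subsampled), clusters them with k-means, and accumulates, for every
#' gene pair, how often the pair was co-sampled and how often it
#' co-clustered.  The consensus matrix is the elementwise ratio; a pair
#' never co-sampled gets consensus 0 and is flagged.
#'
#' @param x Standardized feature matrix, genes in rows.
#' @param k Number of clusters (>= 2).
#' @param reps Number of resamples.
#' @param p_item Fraction of genes drawn per resample, in (0, 1].
#' @param seed Integer seed.
#' @param n_restarts k-means restarts per resample.
#' @return List of class `consensus_run` with `k`, `reps`, `p_item`,
#'   `cooccur_counts`, `cosample_counts`, `consensus_matrix` (values in
#'   `[0, 1]`, diagonal 1 wherever sampled) and `n_never_cosampled`.
#' @export
consensus_cluster <- function(x, k, reps = 1000, p_item = 0.8, seed = 1L,
                              n_restarts = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of genes", call. = FALSE)
  if (!is.finite(p_item) || p_item <= 0 || p_item > 1) {
    stop("p_item must lie in (0, 1]", call. = FALSE)
  }
  n_sub <- max(k, floor(p_item * n))
  cooccur <- matrix(0, n, n)
  cosample <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    rs <- substream_seed(seed, "rep", r)
    idx <- with_substream(rs, sort(sample.int(n, n_sub)))
    km <- kmeans_restarts(x[idx, , drop = FALSE], k,
      seed = substream_seed(seed, "rep", r, "km"), n_restarts = n_restarts
    )
    ind <- matrix(0, n_sub, k)
    ind[cbind(seq_len(n_sub), km$cluster)] <- 1
    cooccur[idx, idx] <- cooccur[idx, idx] + tcrossprod(ind)
    cosample[idx, idx] <- cosample[idx, idx] + 1
  }
  m <- ifelse(cosample > 0, cooccur / pmax(cosample, 1), 0)
  diag(m)[diag(cosample) > 0] <- 1
  dimnames(m) <- list(rownames(x), rownames(x))
  off <- upper.tri(m)
  structure(
    list(
      k = k, reps = reps, p_item = p_item, seed = seed,
      cooccur_counts = cooccur, cosample_counts = cosample,
      consensus_matrix = m,
      n_never_cosampled = sum(cosample[off] == 0)
    ),
    class = "consensus_run"
  )
}

#' @export
print.consensus_run <- function(x, ...) {
  cat(
    "<consensus_run> k = ", x$k, ", reps = ", x$reps, ", p_item = ", x$p_item,
    ", ", nrow(x$consensus_matrix), " genes\n",
    sep = ""
  )
  invisible(x)
}

#' Final cluster assignment from a consensus matrix
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' `1 - consensus`, cut at `k` clusters.  Ties in merge order follow the
#' [stats::hclust()] convention (first-formed pair merges first).
#'
#' @param m Consensus matrix (symmetric, values in `[0, 1]`) or a
#'   `consensus_run`.
#' @param k Number of clusters.
#' @return Integer vector of cluster labels `1..k`, named by gene id.
#' @export
final_clusters <- function(m, k) {
  if (inherits(m, "consensus_run")) m <- m$consensus_matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (k > nrow(m)) stop("k exceeds the number of genes", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  stats::cutree(hc, k = k)
}

#' Consensus CDF / delta-area diagnostics for choosing k
#'
#' Runs [consensus_cluster()] for every `k` from 2 to `max_k`, computes the
#' empirical CDF of the off-diagonal consensus values, the area under each
#' CDF, and the relative gain in area from `k - 1` to `k`.  The suggested
#' number of clusters is the largest `k` whose relative gain still exceeds
#' `floor` (for `k = 2` the gain is the raw area).  The suggestion is
#' advisory; analyses fix `k` explicitly.
#'
#' @param x Standardized feature matrix.
#' @param max_k Largest k examined (>= 2).
#' @param reps,p_item,seed,n_restarts Passed to [consensus_cluster()].
#' @param floor Relative delta-area floor for the suggestion; the default
#'   0.15 sits between the residual gain observed when a crisp cluster is
#'   split (~0.12 in simulations) and the gain from resolving real
#'   structure.
#' @return List with `area` (named numeric), `delta_area`, `suggested_k`,
#'   `cdf` (function list) and `runs` (the consensus runs).
#' @export
choose_k <- function(x, max_k = 9, reps = 1000, p_item = 0.8, seed = 1L,
                     n_restarts = 1, floor = 0.15) {
  if (max_k < 2) stop("max_k must be at least 2", call. = FALSE)
  ks <- 2:max_k
  runs <- lapply(ks, function(k) {
    consensus_cluster(x, k,
      reps = reps, p_item = p_item,
      seed = substream_seed(seed, "choose_k", k), n_restarts = n_restarts
    )
  })
  names(runs) <- paste0("k", ks)
  grid <- seq(0, 1, by = 0.01)
  areas <- vapply(runs, function(run) {
    v <- run$consensus_matrix[upper.tri(run$consensus_matrix)]
    cdf <- stats::ecdf(v)
    sum(diff(grid) * cdf(grid[-1]))
  }, numeric(1))
  delta <- numeric(length(ks))
  delta[1] <- areas[1]
  if (length(ks) > 1) {
    delta[-1] <- diff(areas) / areas[-length(areas)]
  }
  names(delta) <- names(areas) <- paste0("k", ks)
  above <- ks[delta >= floor]
  suggested <- if (length(above) > 0) max(above) else 2L
  cdfs <- lapply(runs, function(run) {
    stats::ecdf(run$consensus_matrix[upper.tri(run$consensus_matrix)])
  })
  list(
    area = areas, delta_area = delta, suggested_k = suggested,
    cdf = cdfs, runs = runs
  )
}

#' Principal component analysis of a feature matrix
#'
#' PCA of the column-centered matrix via singular value decomposition
#' ([stats::prcomp()]); variance fractions are the squared singular values
#' over their total.
#'
#' @param x Numeric matrix with at least two rows (standardize first; no
#'   further scaling is applied here).
#' @return List with `var_frac` (per-component variance fractions),
#'   `scores` (gene x component) and `loadings` (feature x component).
#' @export
pca_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least two rows", call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(var_frac = vf, scores = fit$x, loadings = fit$rotation, center = fit$center)
}

#' Group composition of clusters
#'
#' For each predefined group, the fraction of its genes falling in each
#' cluster; fractions sum to 1 across clusters within a group.
#'
#' @param assignment Named integer vector of cluster labels (names = gene
#'   ids), as from [final_clusters()] or [kmeans_restarts()].
#' @param groups Named character vector of group labels for (at least) the
#'   assigned genes.
#' @return Tibble: `group`, `cluster`, `n`, `fraction`.
#' @export
cluster_composition <- function(assignment, groups) {
  ids <- names(assignment)
  if (is.null(ids)) stop("assignment must be named by gene id", call. = FALSE)
  if (!all(ids %in% names(groups))) {
    stop("every assigned gene needs a group label", call. = FALSE)
  }
  g <- groups[ids]
  tab <- table(group = g, cluster = assignment)
  out <- tibble::as_tibble(tab)
  names(out)[names(out) == "n"] <- "n"
  out$n <- as.numeric(out$n)
  out <- dplyr::group_by(out, .data$group)
  out <- dplyr::mutate(out, fraction = .data$n / sum(.data$n))
  dplyr::ungroup(out)
}
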