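#' Validation metrics for a set of predictions
#'
#' Accuracy plus class-conditional error rates over validating genes with
#' known truth: the false-negative rate is the fraction of truly active
#' genes called inactive, the false-positive rate the fraction of truly
#' inactive genes called active.
#'
#' @param predicted Character vector of `"active"`/`"inactive"` labels.
#' @param truth Character vector of the same length with the true labels.
#' @return List with `accuracy`, `fnr`, `fpr` and the 2x2 `confusion`
#'   counts (`tp`, `fn`, `tn`, `fp`).
#' @examples
#' score_validation(c("active", "inactive"), c("active", "inactive"))
#' @export
score_validation <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(predicted) == 0) stop("empty validation set", call. = FALSE)
  tp <- sum(predicted == "active" & truth == "active")
  fn <- sum(predicted == "inactive" & truth == "active")
  tn <- sum(predicted == "inactive" & truth == "inactive")
  fp <- sum(predicted == "active" & truth == "inactive")
  list(
    accuracy = (tp + tn) / length(predicted),
    fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
    fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)
  )
}

#' Normalized prediction precision
#'
#' Validation accuracy divided by the total number of test-set genes
#' called active or inactive.  Methods that reach a given validation
#' accuracy while calling fewer genes are preferred for prioritization, and
#' this statistic ranks them accordingly.  When nothing is called the value
#' is undefined and returned as `NA` with an attribute flag rather than an
#' error.
#'
#' @param accuracy Validation accuracy in `[0, 1]`.
#' @param n_called_active,n_called_inactive Test-set call counts.
#' @return The normalized precision (or flagged `NA`).
#' @examples
#' normalized_precision(0.96, 54, 146) # 0.96 / 200
#' @export
normalized_precision <- function(accuracy, n_called_active, n_called_inactive) {
  stopifnot(accuracy >= 0, accuracy <= 1,
    n_called_active >= 0, n_called_inactive >= 0)
  denom <- n_called_active + n_called_inactive
  if (denom == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  accuracy / denom
}

#' Enrichment of internal-control genes among the calls
#'
#' Fraction of the called-active genes that are internal controls versus
#' the same fraction among the called-inactive genes, with a Fisher exact
#' test on the control-by-call 2x2 table.  Used with phenotype-known
#' (Group II) genes as positive controls: an effective predictor
#' concentrates them in the active calls.
#'
#' @param control_ids Character vector of control gene ids.
#' @param called_active,called_inactive Disjoint character vectors of
#'   called gene ids.
#' @return List with `fraction_in_active`, `fraction_in_inactive`,
#'   `odds_ratio`, `p_value`.
#' @export
control_enrichment <- function(control_ids, called_active, called_inactive) {
  if (length(intersect(called_active, called_inactive)) > 0) {
    stop("called sets must be disjoint", call. = FALSE)
  }
  a <- sum(called_active %in% control_ids)
  b <- length(called_active) - a
  cc <- sum(called_inactive %in% control_ids)
  dd <- length(called_inactive) - cc
  ft <- fisher_exact(a, b, cc, dd)
  list(
    fraction_in_active = if (length(called_active) > 0) a / length(called_active) else NA_real_,
    fraction_in_inactive = if (length(called_inactive) > 0) cc / length(called_inactive) else NA_real_,
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value
  )
}

#' Overlap counts between two prediction sets
#'
#' Exact set algebra for comparing the calls of two methods (the counts a
#' Venn diagram displays).
#'
#' @param set_a,set_b Character vectors.
#' @return List with `n_a`, `n_b`, `n_common`, `n_only_a`, `n_only_b`.
#' @export
overlap_counts <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  common <- intersect(set_a, set_b)
  list(
    n_a = length(set_a), n_b = length(set_b),
    n_common = length(common),
    n_only_a = length(setdiff(set_a, set_b)),
    n_only_b = length(setdiff(set_b, set_a))
  )
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.  The degenerate case of two
#' zero-variance samples with equal means is reported as no evidence
#' (`t = 0`, `p = 1`) rather than an error.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Verify predicted groups against expression and evolutionary features
#'
#' Compares the called-active set, the called-inactive set and a reference
#' set of known-active genes feature by feature.  Because the called sets
#' are usually unbalanced, the larger called set is first downsampled
#' (seeded, uniform) to the size of the smaller; each feature is then
#' tested across the three groups with [kruskal_dunn_bh()].
#'
#' @param tbl Feature table.
#' @param called_active,called_inactive Called gene id sets (non-empty).
#' @param reference_active_ids Known-active reference gene ids (non-empty).
#' @param features Features to compare.
#' @param seed Integer seed for the balancing downsample.
#' @return List with `group_sizes`, `summaries` (tibble: feature, group,
#'   mean, median) and `tests` (tibble: feature, KW p, pairwise adjusted
#'   p-values), plus the `seed` used.
#' @export
verify_groups <- function(tbl, called_active, called_inactive,
                          reference_active_ids,
                          features = c(
                            "expr_mean", "expr_median", "expr_cv",
                            "ka_ks", "ks", "fbxd_evalue_exp"
                          ),
                          seed = 1L) {
  sets <- list(
    predicted_active = unique(called_active),
    predicted_inactive = unique(called_inactive),
    reference_active = unique(reference_active_ids)
  )
  if (any(lengths(sets) == 0)) stop("all gene sets must be non-empty", call. = FALSE)
  m <- min(length(sets$predicted_active), length(sets$predicted_inactive))
  for (nm in c("predicted_active", "predicted_inactive")) {
    if (length(sets[[nm]]) > m) {
      sets[[nm]] <- with_substream(
        substream_seed(seed, "balance", nm),
        sample(sets[[nm]], m)
      )
    }
  }
  features <- intersect(features, names(tbl))
  summaries <- list()
  tests <- list()
  for (f in features) {
    vals <- c()
    grp <- c()
    for (nm in names(sets)) {
      v <- tbl[[f]][match(sets[[nm]], tbl$gene_id)]
      v <- v[!is.na(v)]
      vals <- c(vals, v)
      grp <- c(grp, rep(nm, length(v)))
      summaries[[length(summaries) + 1]] <- tibble::tibble(
        feature = f, group = nm, n = length(v),
        mean = mean(v), median = median(v), sd = sd(v)
      )
    }
    kd <- kruskal_dunn_bh(vals, grp)
    tests[[length(tests) + 1]] <- tibble::tibble(
      feature = f,
      kw_statistic = kd$statistic,
      kw_p = kd$p_value,
      pairwise = list(kd$pairwise)
    )
  }
  list(
    group_sizes = lengths(sets),
    summaries = dplyr::bind_rows(summaries),
    tests = dplyr::bind_rows(tests),
    seed = seed
  )
}
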