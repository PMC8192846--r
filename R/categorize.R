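#' Assign evidence-based activity groups
#'
#' Genes are tiered by the strongest kind of functional evidence on record,
#' with a strict precedence: a characterized substrate puts a gene in Group
#' I; otherwise an observable mutant phenotype puts it in Group II;
#' otherwise reported differential expression puts it in Group III; a gene
#' never reported in any such work falls to Group IV.
#'
#' @param substrate_known,phenotype_known,de_reported Logical vectors
#'   (recycled to a common length).
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @examples
#' assign_group(TRUE, FALSE, FALSE)   # "I"
#' assign_group(FALSE, TRUE, TRUE)    # "II": phenotype outranks DE
#' assign_group(FALSE, FALSE, FALSE)  # "IV"
#' @export
assign_group <- function(substrate_known, phenotype_known, de_reported) {
  n <- max(length(substrate_known), length(phenotype_known), length(de_reported))
  substrate_known <- rep_len(as.logical(substrate_known), n)
  phenotype_known <- rep_len(as.logical(phenotype_known), n)
  de_reported <- rep_len(as.logical(de_reported), n)
  ifelse(substrate_known, "I",
    ifelse(phenotype_known, "II",
      ifelse(de_reported, "III", "IV")
    )
  )
}

#' @rdname assign_group
#' @param evidence Evidence tibble with columns `gene_id`,
#'   `substrate_known`, `phenotype_known`, `de_reported` (and optionally
#'   `n_publications`).
#' @return `assign_groups()` returns the evidence tibble with a `group`
#'   column appended.
#' @export
assign_groups <- function(evidence) {
  stopifnot(all(c("substrate_known", "phenotype_known", "de_reported") %in%
    names(evidence)))
  evidence$group <- assign_group(
    evidence$substrate_known, evidence$phenotype_known, evidence$de_reported
  )
  evidence
}

#' Per-group publication summaries
#'
#' Number of genes plus mean and sample SD of the publication count per
#' group.  Empty groups are reported with `n = 0` and missing summaries.
#'
#' @param evidence Evidence tibble with `group` and `n_publications`
#'   columns (see [assign_groups()]).
#' @return Tibble with one row per group I--IV.
#' @export
summarize_groups <- function(evidence) {
  stopifnot(all(c("group", "n_publications") %in% names(evidence)))
  groups <- c("I", "II", "III", "IV")
  rows <- lapply(groups, function(g) {
    v <- evidence$n_publications[evidence$group == g]
    tibble::tibble(
      group = g,
      n_genes = length(v),
      mean_publications = if (length(v) > 0) mean(v) else NA_real_,
      sd_publications = if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value using the standard convention of summing the
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more likely than the observed one; the odds ratio is the conditional
#' maximum-likelihood estimate.  A table with a zero margin carries no
#' information: p is 1 and the odds ratio undefined.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`matrix(c(a, c, b, d), 2)` in column order); alternatively `a` may be
#'   a 2x2 matrix.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(5, 5, 5, 5)$p_value # 1: no association
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), nrow = 2)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Overrepresentation of a family among a protein set
#'
#' Given that `n_family_in_set` of the `n_set` proteins carrying some rare
#' domain class belong to the gene family, against `n_family_total` family
#' members in a proteome of `n_proteome` proteins, reports the two
#' percentages and the Fisher exact p-value for overrepresentation.
#'
#' @param n_family_in_set,n_set,n_family_total,n_proteome Counts.
#' @param digits Rounding applied to the reported percentages.
#' @return List with `pct_set`, `pct_background`, `odds_ratio`, `p_value`.
#' @examples
#' rare_ctd_overrepresentation(13, 30, 696, 27654)
#' @export
rare_ctd_overrepresentation <- function(n_family_in_set, n_set,
                                        n_family_total, n_proteome,
                                        digits = 0) {
  if (n_set <= 0) stop("n_set must be positive", call. = FALSE)
  if (n_family_in_set > n_set || n_family_total > n_proteome) {
    stop("subset counts exceed their totals", call. = FALSE)
  }
  if (n_family_in_set > n_family_total) {
    stop("n_family_in_set exceeds n_family_total", call. = FALSE)
  }
  a <- n_family_in_set
  b <- n_set - n_family_in_set
  cc <- n_family_total - n_family_in_set
  dd <- n_proteome - n_set - cc
  ft <- fisher_exact(a, b, cc, dd)
  list(
    pct_set = round(100 * n_family_in_set / n_set, digits),
    pct_background = round(100 * (n_family_total - n_family_in_set) /
      (n_proteome - n_set), digits + 1),
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value
  )
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis rank-sum test across `k >= 2` groups,
#' followed by Dunn's pairwise z tests on the pooled rank means (with the
#' tie-corrected pooled variance) and Benjamini-Hochberg adjustment across
#' all pairs.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (coerced to factor), same length.
#' @return List with `statistic`, `df`, `p_value` (Kruskal-Wallis) and
#'   `pairwise`, a tibble of `group1`, `group2`, `z`, `p_value`, `p_adj`.
#' @examples
#' kruskal_dunn_bh(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
kruskal_dunn_bh <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes == 0)) stop("every group must be non-empty", call. = FALSE)

  kw <- stats::kruskal.test(values, groups)

  # Dunn's z on pooled ranks with tie correction
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- pr[1]
    j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
      (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- tibble::tibble(
    group1 = pairs[1, ],
    group2 = pairs[2, ],
    z = pw["z", ],
    p_value = pw["p", ],
    p_adj = stats::p.adjust(pw["p", ], method = "BH")
  )
  list(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    pairwise = pairwise
  )
}

#' CTD class frequencies by group, with pairwise enrichment tests
#'
#' For each C-terminal-domain indicator column, the proportion of genes in
#' each group carrying that domain class, plus Fisher exact tests of
#' carrier enrichment for every pair of groups.
#'
#' @param tbl Feature table with a `group` column and 0/1-coded CTD
#'   indicator columns.
#' @param ctd_cols Indicator columns to analyze.
#' @return List with `frequencies` (tibble: group x CTD proportions) and
#'   `tests` (tibble: `ctd`, `group1`, `group2`, `odds_ratio`, `p_value`).
#' @export
ctd_group_frequency <- function(tbl,
                                ctd_cols = c(
                                  "ctd_LRR", "ctd_Kelch", "ctd_FBA", "ctd_FBD",
                                  "ctd_TUB_WD40_DUF295", "ctd_rare"
                                )) {
  stopifnot("group" %in% names(tbl), all(ctd_cols %in% names(tbl)))
  groups <- sort(unique(tbl$group))
  freq <- lapply(groups, function(g) {
    sub <- tbl[tbl$group == g, ctd_cols, drop = FALSE]
    tibble::tibble(
      group = g, n_genes = nrow(sub),
      !!!setNames(
        lapply(ctd_cols, function(col) if (nrow(sub) > 0) mean(sub[[col]] > 0) else 0),
        ctd_cols
      )
    )
  })
  freq <- dplyr::bind_rows(freq)

  tests <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (col in ctd_cols) {
      for (k in seq_len(ncol(pairs))) {
        g1 <- pairs[1, k]
        g2 <- pairs[2, k]
        in1 <- tbl[[col]][tbl$group == g1] > 0
        in2 <- tbl[[col]][tbl$group == g2] > 0
        ft <- fisher_exact(
          sum(in1), sum(!in1),
          sum(in2), sum(!in2)
        )
        tests[[length(tests) + 1]] <- tibble::tibble(
          ctd = col, group1 = g1, group2 = g2,
          odds_ratio = ft$odds_ratio, p_value = ft$p_value
        )
      }
    }
  }
  list(frequencies = freq, tests = dplyr::bind_rows(tests))
}
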