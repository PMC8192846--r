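#' The 27-characteristic feature schema
#'
#' Per-gene characteristics used throughout the package: literature and
#' transcript-evidence counts, gene-structure counts, five regional T-DNA
#' insertion counts plus their total, molecular-evolution measures
#' (Ka/Ks, Ks, a neutral-evolution flag), four expression summaries derived
#' from an expression matrix, and nine C-terminal-domain (CTD) composition
#' indicators.
#'
#' @return Character vector of the 27 feature column names, in canonical
#'   order.
#' @examples
#' length(feature_schema())
#' @export
feature_schema <- function() {
  c(
    "n_publications", "n_ESTs", "n_cDNAs", "n_introns", "n_exons",
    "tdna_total", "tdna_upstream100", "tdna_coding_front", "tdna_coding_rear",
    "tdna_noncoding_front", "tdna_noncoding_rear",
    "ka_ks", "ks", "neutral_flag",
    "expr_mean", "expr_median", "expr_max", "expr_cv",
    "ctd_LRR", "ctd_Kelch", "ctd_FBA", "ctd_FBD", "ctd_TUB_WD40_DUF295",
    "ctd_rare", "n_distinct_CTDs", "has_FBXD", "fbxd_evalue_exp"
  )
}

#' Named feature subsets
#'
#' `full27` is the complete schema; `reduced10` is the compact subset
#' (publication/EST/cDNA counts, intron count, the four expression
#' summaries, Ks and Ka/Ks) found to separate activity groups more cleanly
#' than the full table.
#'
#' @param name `"full27"` or `"reduced10"`.
#' @return Character vector of feature names.
#' @examples
#' feature_set("reduced10")
#' @export
feature_set <- function(name = c("full27", "reduced10")) {
  name <- match.arg(name)
  switch(name,
    full27 = feature_schema(),
    reduced10 = c(
      "n_publications", "n_ESTs", "n_cDNAs", "n_introns",
      "expr_mean", "expr_median", "expr_max", "expr_cv", "ks", "ka_ks"
    )
  )
}

.count_features <- function() {
  c(
    "n_publications", "n_ESTs", "n_cDNAs", "n_introns", "n_exons",
    "tdna_total", "tdna_upstream100", "tdna_coding_front", "tdna_coding_rear",
    "tdna_noncoding_front", "tdna_noncoding_rear"
  )
}

.tdna_regions <- function() {
  c(
    "tdna_upstream100", "tdna_coding_front", "tdna_coding_rear",
    "tdna_noncoding_front", "tdna_noncoding_rear"
  )
}

.expr_summaries <- function() c("expr_mean", "expr_median", "expr_max", "expr_cv")

#' Validate a feature table
#'
#' Checks the structural invariants of a feature table: unique gene ids,
#' presence of the schema columns, non-negative integer counts, the T-DNA
#' total equalling the sum of the five regional counts, and
#' `expr_max >= expr_median` wherever both are present.
#'
#' @param tbl A tibble with columns `gene_id`, `group` and the schema
#'   features (extra columns are allowed and ignored).
#' @param schema Feature columns expected; defaults to [feature_schema()].
#' @return `tbl`, invisibly, if valid; otherwise an error naming the
#'   offending gene or column.
#' @export
validate_feature_table <- function(tbl, schema = feature_schema()) {
  stopifnot(is.data.frame(tbl))
  if (!"gene_id" %in% names(tbl)) {
    stop("feature table must have a 'gene_id' column", call. = FALSE)
  }
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(schema, names(tbl))
  if (length(missing_cols) > 0) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in intersect(.count_features(), schema)) {
    v <- tbl[[col]]
    bad <- which(!is.na(v) & (v < 0 | v != round(v)))
    if (length(bad) > 0) {
      stop(
        "column '", col, "' must hold non-negative integers; first offender: gene ",
        tbl$gene_id[bad[1]],
        call. = FALSE
      )
    }
  }
  if (all(c("tdna_total", .tdna_regions()) %in% names(tbl)) && nrow(tbl) > 0) {
    region_sum <- rowSums(as.matrix(tbl[, .tdna_regions()]))
    bad <- which(!is.na(tbl$tdna_total) & tbl$tdna_total != region_sum)
    if (length(bad) > 0) {
      stop(
        "tdna_total does not equal the sum of regional T-DNA counts for gene ",
        tbl$gene_id[bad[1]],
        call. = FALSE
      )
    }
  }
  if (all(c("expr_max", "expr_median") %in% names(tbl))) {
    ok <- is.na(tbl$expr_max) | is.na(tbl$expr_median) |
      tbl$expr_max >= tbl$expr_median - 1e-9
    if (!all(ok)) {
      stop(
        "expr_max < expr_median for gene ", tbl$gene_id[which(!ok)[1]],
        call. = FALSE
      )
    }
  }
  invisible(tbl)
}

#' Read / write a feature table
#'
#' Tab-separated, UTF-8, header row, `gene_id` first, missing values written
#' as `NA`.  Columns beyond the schema are preserved as pass-through
#' metadata.
#'
#' @param path File path.
#' @param validate Run [validate_feature_table()] after reading?
#' @return `read_feature_table()` returns a tibble; `write_feature_table()`
#'   returns `path` invisibly.
#' @export
read_feature_table <- function(path, validate = TRUE) {
  tbl <- readr::read_tsv(path,
    na = "NA", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      group = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  if (nrow(tbl) == 0) return(tbl)
  # schema columns must be numeric; non-schema columns pass through untouched
  for (col in intersect(feature_schema(), names(tbl))) {
    if (!is.numeric(tbl[[col]])) {
      v <- suppressWarnings(as.numeric(tbl[[col]]))
      bad <- which(is.na(v) & !is.na(tbl[[col]]))
      stop(
        "non-numeric feature cell at row ",
        if (length(bad) > 0) bad[1] else "?",
        ", column '", col, "' of ", path,
        call. = FALSE
      )
    }
  }
  if (validate && nrow(tbl) > 0) validate_feature_table(tbl)
  tbl
}

#' @rdname read_feature_table
#' @param tbl Feature table (tibble).
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write an expression matrix
#'
#' Genes as rows (first column `gene_id`), samples as columns, non-negative
#' values, tab-separated.
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns a numeric matrix with gene ids
#'   as row names.
#' @export
read_expression_matrix <- function(path) {
  tbl <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) {
    stop("expression matrix has negative entries", call. = FALSE)
  }
  m
}

#' @rdname read_expression_matrix
#' @param m Numeric matrix, gene ids as row names.
#' @export
write_expression_matrix <- function(m, path) {
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, gene_id = rownames(m), .before = 1)
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Per-gene expression summaries
#'
#' Computes, across the sample columns of an expression matrix, the mean,
#' median, maximum and coefficient of variation (sample SD divided by mean)
#' of each gene.  A gene whose mean is zero gets a missing CV rather than an
#' infinite one, and a gene with no observed value at all gets missing
#' summaries throughout; such genes are flagged incomplete and dropped by
#' [drop_incomplete()].
#'
#' @param m Numeric gene-by-sample matrix with gene ids as row names; must
#'   have at least one sample column.
#' @return Tibble with columns `gene_id`, `expr_mean`, `expr_median`,
#'   `expr_max`, `expr_cv`.
#' @examples
#' m <- matrix(c(5, 5, 5, 5, 1, 2, 3, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), NULL))
#' summarize_expression(m)
#' @export
summarize_expression <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 1) stop("expression matrix needs at least one sample", call. = FALSE)
  n_obs <- rowSums(!is.na(m))
  mu <- ifelse(n_obs > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  med <- apply(m, 1, function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE))
  mx <- apply(m, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  sdev <- apply(m, 1, function(x) if (sum(!is.na(x)) < 2) NA_real_ else sd(x, na.rm = TRUE))
  cv <- ifelse(!is.na(mu) & mu > 0, sdev / mu, NA_real_)
  tibble::tibble(
    gene_id = rownames(m),
    expr_mean = unname(mu),
    expr_median = unname(med),
    expr_max = unname(mx),
    expr_cv = unname(cv)
  )
}

#' Drop genes with incomplete expression summaries
#'
#' A record is complete when none of its four expression summaries is
#' missing.  Mirrors the removal, before clustering and classification, of
#' family members that lack any expression evidence.
#'
#' @param tbl Feature table.
#' @return The complete-record subset, with attribute `"removed"` holding
#'   the dropped gene ids.  Warns when everything is dropped.
#' @export
drop_incomplete <- function(tbl) {
  cols <- intersect(.expr_summaries(), names(tbl))
  complete <- rowSums(is.na(tbl[, cols, drop = FALSE])) == 0
  removed <- tbl$gene_id[!complete]
  out <- tbl[complete, , drop = FALSE]
  if (nrow(out) == 0 && nrow(tbl) > 0) {
    warning("all genes were incomplete; returning an empty table", call. = FALSE)
  }
  attr(out, "removed") <- removed
  out
}

#' Standardize selected features to z-scores
#'
#' Centers each selected feature to mean zero and scales it to unit sample
#' standard deviation.  Mixed-unit features (counts, ratios, expression
#' levels) make Euclidean distances meaningless otherwise, so every
#' clustering, PCA and classifier fit in this package runs on the
#' standardized matrix.  A zero-variance column maps to all zeros, with a
#' warning.
#'
#' @param tbl Feature table with complete records.
#' @param features Character vector of feature names (e.g.
#'   [feature_set()]`("reduced10")`).
#' @return Numeric matrix, genes as rows (row names = gene ids), one column
#'   per selected feature.
#' @export
standardize_features <- function(tbl, features = feature_set("full27")) {
  if (length(features) == 0) stop("empty feature selection", call. = FALSE)
  missing_cols <- setdiff(features, names(tbl))
  if (length(missing_cols) > 0) {
    stop("unknown features: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(tbl[, features, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    stop("standardize_features() requires complete records; run drop_incomplete() first",
      call. = FALSE
    )
  }
  rownames(x) <- tbl$gene_id
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  degenerate <- sds == 0 | is.na(sds)
  if (any(degenerate)) {
    warning(
      "zero-variance feature(s) mapped to zeros: ",
      paste(features[degenerate], collapse = ", "),
      call. = FALSE
    )
    sds[degenerate] <- 1
  }
  z <- sweep(sweep(x, 2, ctr, "-"), 2, sds, "/")
  z[, degenerate] <- 0
  z
}
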