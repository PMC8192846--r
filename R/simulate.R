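#' Configuration for a synthetic gene family
#'
#' The defaults describe the study conditions the package targets: a family
#' of 696 genes of which 41 are labeled active (Group I, substrate known),
#' 140 labeled inactive (Group IV, never studied) and 515 are unknown
#' (Group III), with an activity signal whose size at the default
#' `separation = 3` reproduces the group contrasts reported for the
#' Arabidopsis F-box family (active genes: Ka/Ks near 0.25 vs 0.6, higher
#' Ks, markedly higher and less variable expression, more publications,
#' ESTs and cDNAs).  `separation` scales the location shift of every
#' feature family; at 0 the active and inactive generative distributions
#' are identical.
#'
#' @param n_active_labeled,n_inactive_labeled,n_unknown Non-negative gene
#'   counts per tier.
#' @param frac_unknown_truly_active Probability that an unknown gene is
#'   truly active.
#' @param n_expression_samples Number of expression samples (columns).
#' @param separation Non-negative multiplier on the active-vs-inactive
#'   location shift of every feature family.
#' @param label_noise_rate Probability that a labeled gene's group label is
#'   flipped (I to IV or back); ground-truth activity is never altered.
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(seed = 1)
#' @export
sim_config <- function(n_active_labeled = 41,
                       n_inactive_labeled = 140,
                       n_unknown = 515,
                       frac_unknown_truly_active = 0.12,
                       n_expression_samples = 50,
                       separation = 3,
                       label_noise_rate = 0,
                       seed = 1L) {
  counts <- c(
    n_active_labeled = n_active_labeled,
    n_inactive_labeled = n_inactive_labeled,
    n_unknown = n_unknown,
    n_expression_samples = n_expression_samples
  )
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!is.finite(separation) || separation < 0) {
    stop("separation must be a non-negative scalar", call. = FALSE)
  }
  for (fr in c(frac_unknown_truly_active, label_noise_rate)) {
    if (!is.finite(fr) || fr < 0 || fr > 1) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      n_active_labeled = as.integer(n_active_labeled),
      n_inactive_labeled = as.integer(n_inactive_labeled),
      n_unknown = as.integer(n_unknown),
      frac_unknown_truly_active = frac_unknown_truly_active,
      n_expression_samples = as.integer(n_expression_samples),
      separation = separation,
      label_noise_rate = label_noise_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generative constants of the synthetic family
#'
#' The per-feature-family calibration used by [simulate_family()].  Marginal
#' distributions are the package's own choices (log-normal expression,
#' negative-binomial counts, a scaled logit-normal Ka/Ks); their location
#' shifts are calibrated so that at the default `separation = 3` the
#' active/inactive group summaries match the published family-level
#' contrasts (e.g. mean Ka/Ks 0.25 vs 0.60).  Exposed so that tests can
#' build exact-likelihood oracles against the true generative densities.
#'
#' @return A nested list of constants.
#' @export
sim_parameters <- function() {
  list(
    ka_ks = list(
      scale = 1.5,
      base_logit = stats::qlogis(0.6 / 1.5), # inactive mean 0.60
      unit_shift = (stats::qlogis(0.6 / 1.5) - stats::qlogis(0.25 / 1.5)) / 3,
      sigma = 0.45
    ),
    ks = list(base_meanlog = log(0.7), unit_shift = 0.15, sdlog = 0.5),
    neutral = list(base_p = 0.45, unit_shift = 0.6),
    expression = list(
      base_meanlog = log(25), gene_sd = 0.6,
      unit_shift = 1.0, # inactive location drops by this per separation unit
      base_sdlog = 0.8, unit_sdlog = 0.3 # inactive within-gene spread grows
    ),
    counts = list(
      # base = inactive NB mean; gain: active mean = base * (1 + gain * separation)
      n_publications = list(base = 2.0, gain = 25 / 6, size = 0.4),
      n_ESTs = list(base = 4.0, gain = 2.0, size = 1.0),
      n_cDNAs = list(base = 1.5, gain = 2.0, size = 1.0),
      n_introns = list(base = 1.2, gain = 0.4, size = 2.0),
      tdna_upstream100 = list(base = 0.5, gain = 0.25, size = 1.0),
      tdna_coding_front = list(base = 0.8, gain = 0.25, size = 1.0),
      tdna_coding_rear = list(base = 0.8, gain = 0.25, size = 1.0),
      tdna_noncoding_front = list(base = 0.6, gain = 0.25, size = 1.0),
      tdna_noncoding_rear = list(base = 0.6, gain = 0.25, size = 1.0)
    ),
    ctd = list(
      classes = c("ctd_LRR", "ctd_Kelch", "ctd_FBA", "ctd_FBD",
                  "ctd_TUB_WD40_DUF295", "ctd_rare", "none"),
      inactive_probs = c(0.10, 0.05, 0.30, 0.20, 0.10, 0.05, 0.20),
      # active log-odds gain per separation unit, same order
      active_gain = c(0.30, 0.30, -0.20, -0.20, 0.05, -0.20, 0.00),
      second_domain_p = 0.10
    ),
    fbxd = list(base_exp = -15, unit_shift = 1.2, sigma = 4, cap = -1)
  )
}

.empty_feature_table <- function() {
  cols <- c("gene_id", "group", feature_schema())
  tbl <- tibble::as_tibble(setNames(
    c(
      list(character(0), character(0)),
      rep(list(numeric(0)), length(feature_schema()))
    ),
    cols
  ))
  tbl
}

#' Generate a synthetic gene family
#'
#' Draws a complete family — feature table, expression matrix, evidence
#' records and ground truth — from the generative model described in
#' [sim_parameters()].  Output is fully deterministic given
#' `config$seed`: every feature family draws from its own sub-stream
#' ([substream_seed()]), so adding a feature never perturbs the others,
#' and the underlying noise draws do not depend on `separation`, which
#' makes group contrasts exactly monotone in it.
#'
#' @param config A [sim_config()].
#' @return A list of class `fam_simulation` with elements `feature_table`
#'   (tibble: `gene_id`, `group`, 27 features), `expression` (matrix),
#'   `evidence` (tibble of per-gene annotation flags) and `truth` (tibble:
#'   `gene_id`, `true_activity`, `assigned_group`, `labeled`).
#' @examples
#' sim <- simulate_family(sim_config(
#'   n_active_labeled = 5, n_inactive_labeled = 15,
#'   n_unknown = 20, n_expression_samples = 8, seed = 42
#' ))
#' head(sim$feature_table)
#' @export
simulate_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  p <- sim_parameters()
  s <- config$separation
  seed <- config$seed

  n <- config$n_active_labeled + config$n_inactive_labeled + config$n_unknown
  n_samp <- config$n_expression_samples

  if (n == 0) {
    out <- list(
      feature_table = .empty_feature_table(),
      expression = matrix(numeric(0),
        nrow = 0, ncol = n_samp,
        dimnames = list(character(0), if (n_samp > 0) sprintf("S%03d", seq_len(n_samp)))
      ),
      evidence = tibble::tibble(
        gene_id = character(0), substrate_known = logical(0),
        interacts_ask1 = logical(0), phenotype_known = logical(0),
        de_reported = logical(0), n_publications = numeric(0)
      ),
      truth = tibble::tibble(
        gene_id = character(0), true_activity = character(0),
        assigned_group = character(0), labeled = logical(0)
      ),
      config = config
    )
    return(structure(out, class = "fam_simulation"))
  }
  if (n_samp < 1) {
    stop("n_expression_samples must be >= 1 when genes are generated", call. = FALSE)
  }

  gene_id <- sprintf("FBX%04d", seq_len(n))
  assigned_group <- rep(c("I", "IV", "III"), c(
    config$n_active_labeled, config$n_inactive_labeled, config$n_unknown
  ))
  labeled <- assigned_group %in% c("I", "IV")

  true_activity <- character(n)
  true_activity[assigned_group == "I"] <- "active"
  true_activity[assigned_group == "IV"] <- "inactive"
  unknown <- assigned_group == "III"
  if (any(unknown)) {
    u <- with_substream(substream_seed(seed, "unknown_truth"), runif(sum(unknown)))
    true_activity[unknown] <-
      ifelse(u < config$frac_unknown_truly_active, "active", "inactive")
  }
  a <- as.numeric(true_activity == "active")

  # --- molecular evolution -------------------------------------------------
  z <- with_substream(substream_seed(seed, "ka_ks"), rnorm(n))
  ka_ks <- p$ka_ks$scale *
    stats::plogis(p$ka_ks$base_logit - p$ka_ks$unit_shift * s * a + p$ka_ks$sigma * z)
  z <- with_substream(substream_seed(seed, "ks"), rnorm(n))
  ks <- exp(p$ks$base_meanlog + p$ks$unit_shift * s * a + p$ks$sdlog * z)
  u <- with_substream(substream_seed(seed, "neutral"), runif(n))
  neutral_flag <- as.numeric(
    u < stats::plogis(stats::qlogis(p$neutral$base_p) - p$neutral$unit_shift * s * a)
  )

  # --- overdispersed counts ------------------------------------------------
  draw_count <- function(name) {
    cp <- p$counts[[name]]
    with_substream(
      substream_seed(seed, name),
      rnbinom(n, size = cp$size, mu = cp$base * (1 + cp$gain * s * a))
    )
  }
  n_publications <- draw_count("n_publications")
  n_publications[assigned_group == "IV"] <- 0 # Group IV: never studied
  n_ESTs <- draw_count("n_ESTs")
  n_cDNAs <- draw_count("n_cDNAs")
  n_introns <- draw_count("n_introns")
  n_exons <- n_introns + 1
  tdna <- sapply(.tdna_regions(), draw_count)
  if (n == 1) tdna <- matrix(tdna, nrow = 1, dimnames = list(NULL, .tdna_regions()))
  tdna_total <- rowSums(tdna)

  # --- expression ----------------------------------------------------------
  ep <- p$expression
  zg <- with_substream(substream_seed(seed, "expr_gene"), rnorm(n))
  gene_meanlog <- ep$base_meanlog - ep$unit_shift * s * (1 - a) + ep$gene_sd * zg
  gene_sdlog <- ep$base_sdlog + ep$unit_sdlog * s * (1 - a)
  e <- with_substream(
    substream_seed(seed, "expr_samples"),
    matrix(rnorm(n * n_samp), nrow = n)
  )
  expression <- exp(gene_meanlog + gene_sdlog * e)
  dimnames(expression) <- list(gene_id, sprintf("S%03d", seq_len(n_samp)))

  # --- CTD composition -----------------------------------------------------
  ctd <- p$ctd
  n_classes <- length(ctd$classes)
  logit_w <- log(ctd$inactive_probs)
  probs <- matrix(rep(logit_w, each = n), nrow = n)
  probs <- probs + outer(a * s, ctd$active_gain)
  probs <- exp(probs)
  probs <- probs / rowSums(probs)
  u1 <- with_substream(substream_seed(seed, "ctd_primary"), runif(n))
  cum <- t(apply(probs, 1, cumsum))
  primary <- max.col(u1 < cum, ties.method = "first")
  u2 <- with_substream(substream_seed(seed, "ctd_secondary"), runif(n))
  indicator_classes <- ctd$classes[ctd$classes != "none"]
  ind <- matrix(0, nrow = n, ncol = length(indicator_classes),
    dimnames = list(NULL, indicator_classes)
  )
  for (i in seq_len(n)) {
    cls <- ctd$classes[primary[i]]
    if (cls != "none") ind[i, cls] <- 1
    if (u2[i] < ctd$second_domain_p) {
      # a second, distinct domain class: rotate to the next indicator class
      second <- indicator_classes[(primary[i] %% length(indicator_classes)) + 1]
      ind[i, second] <- 1
    }
  }
  n_distinct_CTDs <- rowSums(ind > 0)
  has_FBXD <- rep(1, n)
  z <- with_substream(substream_seed(seed, "fbxd_evalue"), rnorm(n))
  fbxd_evalue_exp <- pmin(
    p$fbxd$cap,
    p$fbxd$base_exp + p$fbxd$unit_shift * s * a + p$fbxd$sigma * z
  )

  expr_sum <- summarize_expression(expression)

  feature_table <- tibble::tibble(
    gene_id = gene_id,
    group = assigned_group,
    n_publications = as.numeric(n_publications),
    n_ESTs = as.numeric(n_ESTs),
    n_cDNAs = as.numeric(n_cDNAs),
    n_introns = as.numeric(n_introns),
    n_exons = as.numeric(n_exons),
    tdna_total = as.numeric(tdna_total),
    tdna_upstream100 = as.numeric(tdna[, "tdna_upstream100"]),
    tdna_coding_front = as.numeric(tdna[, "tdna_coding_front"]),
    tdna_coding_rear = as.numeric(tdna[, "tdna_coding_rear"]),
    tdna_noncoding_front = as.numeric(tdna[, "tdna_noncoding_front"]),
    tdna_noncoding_rear = as.numeric(tdna[, "tdna_noncoding_rear"]),
    ka_ks = ka_ks,
    ks = ks,
    neutral_flag = neutral_flag,
    expr_mean = expr_sum$expr_mean,
    expr_median = expr_sum$expr_median,
    expr_max = expr_sum$expr_max,
    expr_cv = expr_sum$expr_cv,
    ctd_LRR = ind[, "ctd_LRR"],
    ctd_Kelch = ind[, "ctd_Kelch"],
    ctd_FBA = ind[, "ctd_FBA"],
    ctd_FBD = ind[, "ctd_FBD"],
    ctd_TUB_WD40_DUF295 = ind[, "ctd_TUB_WD40_DUF295"],
    ctd_rare = ind[, "ctd_rare"],
    n_distinct_CTDs = as.numeric(n_distinct_CTDs),
    has_FBXD = has_FBXD,
    fbxd_evalue_exp = fbxd_evalue_exp
  )

  evidence <- tibble::tibble(
    gene_id = gene_id,
    substrate_known = assigned_group == "I",
    interacts_ask1 = assigned_group == "I",
    phenotype_known = FALSE,
    de_reported = assigned_group == "III",
    n_publications = as.numeric(n_publications)
  )

  truth <- tibble::tibble(
    gene_id = gene_id,
    true_activity = true_activity,
    assigned_group = assigned_group,
    labeled = labeled
  )
  if (config$label_noise_rate > 0) {
    truth <- inject_label_noise(
      truth, config$label_noise_rate,
      substream_seed(seed, "label_noise")
    )
  }

  structure(
    list(
      feature_table = feature_table,
      expression = expression,
      evidence = evidence,
      truth = truth,
      config = config
    ),
    class = "fam_simulation"
  )
}

#' @export
print.fam_simulation <- function(x, ...) {
  cat(
    "<fam_simulation> ", nrow(x$feature_table), " genes (",
    sum(x$truth$assigned_group == "I"), " Group I, ",
    sum(x$truth$assigned_group == "IV"), " Group IV, ",
    sum(!x$truth$labeled), " unknown), ",
    ncol(x$expression), " expression samples, separation = ",
    x$config$separation, ", seed = ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Flip labeled group assignments at random
#'
#' Each labeled gene's assigned group is flipped (I to IV or IV to I)
#' independently with probability `rate`; unknown genes and ground-truth
#' activity are untouched.  Used to stress-test the robustness of the
#' consensus calling machinery to annotation errors.
#'
#' @param truth Truth tibble as produced by [simulate_family()].
#' @param rate Flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The truth tibble with flipped `assigned_group` entries.
#' @export
inject_label_noise <- function(truth, rate, seed) {
  if (!is.finite(rate) || rate < 0 || rate > 1) {
    stop("rate must lie in [0, 1]", call. = FALSE)
  }
  idx <- which(truth$labeled)
  if (length(idx) == 0 || rate == 0) {
    return(truth)
  }
  flip <- with_substream(as.integer(seed), runif(length(idx)) < rate)
  flipped <- idx[flip]
  truth$assigned_group[flipped] <-
    ifelse(truth$assigned_group[flipped] == "I", "IV", "I")
  truth
}

#' Write the artifacts of a simulation to a directory
#'
#' Emits the same TSV dialects the pipeline reads: `feature_table.tsv`,
#' `expression.tsv`, `evidence.tsv` and `truth.tsv`.
#'
#' @param sim A `fam_simulation`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fam_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    feature_table = file.path(dir, "feature_table.tsv"),
    expression = file.path(dir, "expression.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_feature_table(sim$feature_table, paths[["feature_table"]])
  write_expression_matrix(sim$expression, paths[["expression"]])
  readr::write_tsv(sim$evidence, paths[["evidence"]], na = "NA", progress = FALSE)
  readr::write_tsv(sim$truth, paths[["truth"]], na = "NA", progress = FALSE)
  invisible(paths)
}
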