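#' Pipeline configuration
#'
#' One object carrying every setting of the end-to-end analysis:
#' simulate (or load) a family, summarize and standardize features,
#' categorize by evidence, consensus-cluster, run the
#' resampling-consensus classifier and evaluate.  All randomness derives
#' from `master_seed` through named sub-streams, so a pipeline run is
#' reproducible bit for bit.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param input_dir Optional directory holding `feature_table.tsv`,
#'   `expression.tsv`, `evidence.tsv` (and optionally `truth.tsv`); when
#'   `NULL` a family is simulated from `simulate`.
#' @param simulate A [sim_config()]; its `seed` is re-derived from
#'   `master_seed`.
#' @param feature_set `"full27"` or `"reduced10"`.
#' @param cluster_k Clusters for the final consensus assignment.
#' @param cluster_reps,cluster_p_item Consensus resampling settings.
#' @param cluster_max_k When non-`NULL`, also run [choose_k()] up to this k.
#' @param classifier A [classifier_spec()].
#' @param n_rounds,n_resamples,vote_threshold,min_rounds Two-tier consensus
#'   settings (defaults: 10 rounds of 1,000 resamples, calls at >= 950
#'   votes and >= 9 rounds).
#' @param neg_ratio,train_fraction Pool construction and split settings.
#' @param master_seed Integer master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            simulate = sim_config(),
                            feature_set = c("reduced10", "full27"),
                            cluster_k = 3,
                            cluster_reps = 100,
                            cluster_p_item = 0.8,
                            cluster_max_k = NULL,
                            classifier = classifier_spec("mlp"),
                            n_rounds = 10,
                            n_resamples = 1000,
                            vote_threshold = 950,
                            min_rounds = 9,
                            neg_ratio = 3,
                            train_fraction = 2 / 3,
                            master_seed = 1L) {
  feature_set <- match.arg(feature_set)
  if (!is.null(input_dir)) {
    req <- file.path(input_dir, c("feature_table.tsv", "expression.tsv", "evidence.tsv"))
    missing_files <- req[!file.exists(req)]
    if (length(missing_files) > 0) {
      stop("missing input file(s): ", paste(missing_files, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (min_rounds > n_rounds) stop("min_rounds exceeds n_rounds", call. = FALSE)
  if (vote_threshold > n_resamples) {
    stop("vote_threshold exceeds n_resamples", call. = FALSE)
  }
  structure(
    list(
      out_dir = out_dir, input_dir = input_dir, simulate = simulate,
      feature_set = feature_set, cluster_k = cluster_k,
      cluster_reps = cluster_reps, cluster_p_item = cluster_p_item,
      cluster_max_k = cluster_max_k, classifier = classifier,
      n_rounds = n_rounds, n_resamples = n_resamples,
      vote_threshold = vote_threshold, min_rounds = min_rounds,
      neg_ratio = neg_ratio, train_fraction = train_fraction,
      master_seed = as.integer(master_seed)
    ),
    class = "pipeline_config"
  )
}

.write_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, featurize, categorize, cluster, predict and
#' evaluate in order, writing every stage artifact as TSV (metrics as
#' JSON) under `config$out_dir` and finishing with a `manifest.json`
#' recording the stages, their files with md5 checksums, and the seeds
#' used.  A stage failure writes a manifest recording the partial state
#' and the failing stage before the error propagates.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list; also on disk as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$master_seed
  manifest <- list(
    package_version = as.character(utils::packageVersion("famrank")),
    master_seed = seed,
    feature_set = config$feature_set,
    stages = list(),
    status = "running"
  )
  files <- character(0)
  done <- function(stage, stage_files) {
    manifest$stages[[stage]] <<- list(files = basename(stage_files))
    files <<- c(files, stage_files)
  }
  fail <- function(stage, err) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(err)
    .write_manifest(manifest, files, out)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
      call. = FALSE
    )
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  # -- simulate / load ------------------------------------------------------
  dat <- run_stage("simulate", {
    if (is.null(config$input_dir)) {
      cfg <- config$simulate
      cfg$seed <- substream_seed(seed, "simulate")
      sim <- simulate_family(cfg)
      paths <- write_simulation(sim, file.path(out, "inputs"))
      done("simulate", unname(paths))
      list(
        feature_table = sim$feature_table, expression = sim$expression,
        evidence = sim$evidence, truth = sim$truth
      )
    } else {
      ft <- read_feature_table(file.path(config$input_dir, "feature_table.tsv"))
      em <- read_expression_matrix(file.path(config$input_dir, "expression.tsv"))
      ev <- readr::read_tsv(file.path(config$input_dir, "evidence.tsv"),
        na = "NA", show_col_types = FALSE, progress = FALSE
      )
      tr_path <- file.path(config$input_dir, "truth.tsv")
      tr <- if (file.exists(tr_path)) {
        readr::read_tsv(tr_path, na = "NA", show_col_types = FALSE, progress = FALSE)
      }
      done("simulate", character(0))
      list(feature_table = ft, expression = em, evidence = ev, truth = tr)
    }
  })

  # -- featurize ------------------------------------------------------------
  feat <- run_stage("featurize", {
    tbl <- dat$feature_table
    # recompute expression summaries from the matrix so both inputs agree;
    # genes absent from the matrix become incomplete and are removed below
    es <- summarize_expression(dat$expression)
    tbl[.expr_summaries()] <- NA_real_
    idx <- match(es$gene_id, tbl$gene_id)
    keep <- !is.na(idx)
    tbl[idx[keep], .expr_summaries()] <- es[keep, .expr_summaries()]
    complete <- drop_incomplete(tbl)
    z <- standardize_features(complete, feature_set(config$feature_set))
    f1 <- .write_tsv(complete, file.path(out, "feature_table_complete.tsv"))
    f2 <- .write_tsv(
      tibble::tibble(gene_id = attr(complete, "removed")),
      file.path(out, "removed_genes.tsv")
    )
    zt <- tibble::as_tibble(z)
    zt <- tibble::add_column(zt, gene_id = rownames(z), .before = 1)
    f3 <- .write_tsv(zt, file.path(out, "standardized_features.tsv"))
    done("featurize", c(f1, f2, f3))
    list(table = complete, z = z)
  })

  # -- categorize -----------------------------------------------------------
  cat_res <- run_stage("categorize", {
    ev <- assign_groups(dat$evidence)
    gs <- summarize_groups(ev)
    f1 <- .write_tsv(ev, file.path(out, "groups.tsv"))
    f2 <- .write_tsv(gs, file.path(out, "group_summary.tsv"))
    done("categorize", c(f1, f2))
    list(evidence = ev, summary = gs)
  })

  # -- cluster --------------------------------------------------------------
  clu <- run_stage("cluster", {
    run <- consensus_cluster(feat$z, config$cluster_k,
      reps = config$cluster_reps, p_item = config$cluster_p_item,
      seed = substream_seed(seed, "cluster")
    )
    assign <- final_clusters(run, config$cluster_k)
    groups <- setNames(cat_res$evidence$group, cat_res$evidence$gene_id)
    comp <- cluster_composition(assign, groups)
    pca <- pca_features(feat$z)
    cm <- tibble::as_tibble(run$consensus_matrix)
    cm <- tibble::add_column(cm, gene_id = rownames(run$consensus_matrix), .before = 1)
    f1 <- .write_tsv(cm, file.path(out, "consensus_matrix.tsv"))
    f2 <- .write_tsv(
      tibble::tibble(gene_id = names(assign), cluster = as.integer(assign)),
      file.path(out, "cluster_assignments.tsv")
    )
    f3 <- .write_tsv(comp, file.path(out, "cluster_composition.tsv"))
    f4 <- .write_tsv(
      tibble::tibble(
        component = paste0("PC", seq_along(pca$var_frac)),
        var_frac = pca$var_frac
      ),
      file.path(out, "pca_variance.tsv")
    )
    scores <- tibble::as_tibble(pca$scores[, seq_len(min(2, ncol(pca$scores))), drop = FALSE])
    scores <- tibble::add_column(scores, gene_id = rownames(feat$z), .before = 1)
    f5 <- .write_tsv(scores, file.path(out, "pca_scores.tsv"))
    suggested <- NULL
    kfiles <- character(0)
    if (!is.null(config$cluster_max_k)) {
      ck <- choose_k(feat$z,
        max_k = config$cluster_max_k,
        reps = config$cluster_reps, p_item = config$cluster_p_item,
        seed = substream_seed(seed, "choose_k")
      )
      suggested <- ck$suggested_k
      kfiles <- .write_tsv(
        tibble::tibble(
          k = as.integer(sub("k", "", names(ck$area))),
          area = ck$area, delta_area = ck$delta_area
        ),
        file.path(out, "choose_k.tsv")
      )
    }
    done("cluster", c(f1, f2, f3, f4, f5, kfiles))
    list(run = run, assignment = assign, composition = comp, pca = pca,
         suggested_k = suggested)
  })

  # -- predict --------------------------------------------------------------
  pred <- run_stage("predict", {
    ev <- cat_res$evidence
    complete_ids <- feat$table$gene_id
    active_ids <- intersect(ev$gene_id[ev$group == "I"], complete_ids)
    inactive_candidates <- intersect(ev$gene_id[ev$group == "IV"], complete_ids)
    pool <- build_pool(active_ids, inactive_candidates,
      neg_ratio = config$neg_ratio, seed = substream_seed(seed, "pool")
    )
    # test sample: the unknown (Group III) genes plus the phenotype-known
    # Group II internal controls; labeled genes left out of the pool are
    # not re-examined
    grp <- setNames(ev$group, ev$gene_id)
    test_ids <- setdiff(
      complete_ids[grp[complete_ids] %in% c("II", "III")],
      c(pool$positive_ids, pool$negative_ids)
    )
    rounds <- lapply(seq_len(config$n_rounds), function(rd) {
      run_round(feat$z, pool, test_ids, config$classifier,
        n_resamples = config$n_resamples,
        vote_threshold = config$vote_threshold,
        train_fraction = config$train_fraction,
        round_seed = substream_seed(seed, "round", rd)
      )
    })
    calls <- consensus_across_rounds(rounds, min_rounds = config$min_rounds)
    preds <- tibble::as_tibble(calls)
    names(preds)[names(preds) == "final"] <- "final_call"
    f1 <- .write_tsv(preds, file.path(out, "predictions.tsv"))
    acc <- tibble::tibble(
      round = seq_len(config$n_rounds),
      mean_validation_accuracy = vapply(
        rounds, function(r) mean(r$validation_accuracy, na.rm = TRUE), numeric(1)
      ),
      n_abstained = vapply(rounds, function(r) r$n_abstained, integer(1))
    )
    f2 <- .write_tsv(acc, file.path(out, "round_accuracy.tsv"))
    done("predict", c(f1, f2))
    list(pool = pool, rounds = rounds, calls = calls, round_accuracy = acc)
  })

  # -- evaluate -------------------------------------------------------------
  run_stage("evaluate", {
    calls <- pred$calls
    called_active <- calls$gene_id[calls$final == "active"]
    called_inactive <- calls$gene_id[calls$final == "inactive"]
    validation_accuracy <- mean(pred$round_accuracy$mean_validation_accuracy)
    metrics <- list(
      validation_accuracy = validation_accuracy,
      n_called_active = length(called_active),
      n_called_inactive = length(called_inactive),
      n_unclassified = sum(calls$final == "unclassified"),
      normalized_precision = as.numeric(normalized_precision(
        validation_accuracy, length(called_active), length(called_inactive)
      ))
    )
    ev <- cat_res$evidence
    controls <- ev$gene_id[ev$group == "II"]
    if (length(controls) > 0 &&
      (length(called_active) > 0 || length(called_inactive) > 0)) {
      enr <- control_enrichment(controls, called_active, called_inactive)
      metrics$control_fraction_in_active <- enr$fraction_in_active
      metrics$control_fraction_in_inactive <- enr$fraction_in_inactive
      metrics$control_enrichment_p <- enr$p_value
    }
    ver_file <- character(0)
    reference_active <- ev$gene_id[ev$group == "I"]
    if (length(called_active) > 0 && length(called_inactive) > 0 &&
      length(reference_active) > 0) {
      ver <- verify_groups(feat$table, called_active, called_inactive,
        reference_active,
        seed = substream_seed(seed, "verify")
      )
      vt <- ver$tests
      vt$min_pairwise_adj_p <- vapply(
        vt$pairwise, function(p) min(p$p_adj), numeric(1)
      )
      vt$pairwise <- NULL
      ver_file <- c(
        .write_tsv(ver$summaries, file.path(out, "verification_summaries.tsv")),
        .write_tsv(vt, file.path(out, "verification_tests.tsv"))
      )
    }
    if (!is.null(dat$truth)) {
      truth <- dat$truth
      unknown_ids <- truth$gene_id[!truth$labeled]
      truly_active_unknown <- intersect(
        unknown_ids, truth$gene_id[truth$true_activity == "active"]
      )
      called_ta <- intersect(truly_active_unknown, c(called_active, called_inactive))
      metrics$n_truly_active_unknown_called <- length(called_ta)
      metrics$frac_truly_active_called_active <- if (length(called_ta) > 0) {
        mean(called_ta %in% called_active)
      } else {
        NA_real_
      }
    }
    f1 <- file.path(out, "metrics.json")
    jsonlite::write_json(metrics, f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    done("evaluate", c(f1, ver_file))
    metrics
  })

  manifest$status <- "complete"
  .write_manifest(manifest, files, out)
  invisible(.read_manifest(out))
}

.write_manifest <- function(manifest, files, out) {
  existing <- files[file.exists(files)]
  manifest$checksums <- as.list(setNames(
    unname(tools::md5sum(existing)), basename(existing)
  ))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

.read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"), simplifyVector = FALSE)
}

#' Write a human-readable run report
#'
#' Assembles a plain-text summary — group table, cluster composition,
#' consensus calls and evaluation metrics — exclusively from the stage
#' files named in the run's manifest, so every reported number is
#' traceable to an artifact on disk.  Regenerating the report from the
#' same run directory reproduces it exactly.
#'
#' @param out_dir A completed (or partially completed) [run_pipeline()]
#'   output directory.
#' @param path Report destination; defaults to `report.txt` in `out_dir`.
#' @return `path`, invisibly.
#' @export
write_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  manifest <- .read_manifest(out_dir)
  lines <- c(
    "famrank run report",
    "==================",
    paste0("status: ", manifest$status),
    paste0("master seed: ", manifest$master_seed),
    paste0("feature set: ", manifest$feature_set),
    ""
  )
  if (!is.null(manifest$failed_stage)) {
    lines <- c(lines, paste0(
      "INCOMPLETE RUN - failed at stage '", manifest$failed_stage, "': ",
      manifest$error
    ), "")
  }
  grab <- function(file) {
    p <- file.path(out_dir, file)
    if (file.exists(p)) {
      readr::read_tsv(p, na = "NA", show_col_types = FALSE, progress = FALSE)
    }
  }
  gs <- grab("group_summary.tsv")
  if (!is.null(gs)) {
    lines <- c(lines, "Group summary (publications per gene):",
      utils::capture.output(as.data.frame(gs)), "")
  } else {
    lines <- c(lines, "Group summary: [missing]", "")
  }
  comp <- grab("cluster_composition.tsv")
  if (!is.null(comp)) {
    lines <- c(lines, "Cluster composition (fraction of each group per cluster):",
      utils::capture.output(as.data.frame(comp)), "")
  } else {
    lines <- c(lines, "Cluster composition: [missing]", "")
  }
  pv <- grab("pca_variance.tsv")
  if (!is.null(pv) && nrow(pv) >= 2) {
    lines <- c(lines, sprintf(
      "PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
      100 * pv$var_frac[1], 100 * pv$var_frac[2]
    ), "")
  }
  preds <- grab("predictions.tsv")
  if (!is.null(preds)) {
    n_act <- sum(preds$final_call == "active")
    n_inact <- sum(preds$final_call == "inactive")
    if (n_act + n_inact == 0) {
      lines <- c(lines, "Consensus calls: no consensus calls", "")
    } else {
      lines <- c(lines, sprintf(
        "Consensus calls: %d active, %d inactive, %d unclassified",
        n_act, n_inact, sum(preds$final_call == "unclassified")
      ), "")
    }
  } else {
    lines <- c(lines, "Consensus calls: [missing]", "")
  }
  mp <- file.path(out_dir, "metrics.json")
  if (file.exists(mp)) {
    metrics <- jsonlite::read_json(mp, simplifyVector = TRUE)
    lines <- c(lines, "Evaluation metrics:", vapply(
      names(metrics),
      function(k) sprintf("  %s: %s", k, format(metrics[[k]], digits = 6)),
      character(1)
    ), "")
  } else {
    lines <- c(lines, "Evaluation metrics: [missing]", "")
  }
  writeLines(lines, path)
  invisible(path)
}
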