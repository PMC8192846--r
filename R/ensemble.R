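#' Classifier specification
#'
#' Settings for the base classifiers used inside the resampling-consensus
#' ensemble: the reference multilayer perceptron (two hidden layers, 10 and
#' 2 nodes, logistic activations), a random forest with `mtry = 4`, or a
#' radial-kernel C-classification support vector machine.  A `"stub"` kind
#' accepts a user function `stub_predict(x)` returning scores and exists
#' for deterministic testing of the voting machinery.
#'
#' @param kind One of `"mlp"`, `"rf"`, `"svm"`, `"stub"`.
#' @param mlp_hidden,mlp_max_iter,mlp_learn_rate,mlp_tol See [mlp_fit()].
#' @param rf_mtry,rf_ntree Random-forest settings.
#' @param svm_cost SVM cost parameter.
#' @param decision_threshold Score at or above which a gene is labeled
#'   active (the boundary is inclusive).
#' @param stub_predict Function of a feature matrix returning scores, for
#'   `kind = "stub"`.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("mlp", "rf", "svm", "stub"),
                            mlp_hidden = c(10, 2), mlp_max_iter = 2000,
                            mlp_learn_rate = 0.02, mlp_tol = 0.01,
                            rf_mtry = 4, rf_ntree = 500,
                            svm_cost = 1,
                            decision_threshold = 0.5,
                            stub_predict = NULL) {
  kind <- match.arg(kind)
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("decision_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (kind == "stub" && !is.function(stub_predict)) {
    stop("kind = 'stub' requires a stub_predict function", call. = FALSE)
  }
  structure(
    list(
      kind = kind, mlp_hidden = mlp_hidden, mlp_max_iter = mlp_max_iter,
      mlp_learn_rate = mlp_learn_rate, mlp_tol = mlp_tol,
      rf_mtry = rf_mtry, rf_ntree = rf_ntree, svm_cost = svm_cost,
      decision_threshold = decision_threshold, stub_predict = stub_predict
    ),
    class = "classifier_spec"
  )
}

#' Build the labeled training pool
#'
#' Combines the known-active genes with a seeded uniform downsample of the
#' inactive candidates so that the pool has the configured
#' negative:positive ratio (1:3 by default: e.g. 41 actives keep 123 of
#' 140 candidates).
#'
#' @param active_ids Character vector of known-active gene ids.
#' @param inactive_candidate_ids Character vector of candidate inactive
#'   gene ids.
#' @param neg_ratio Negatives kept per positive.
#' @param seed Integer seed for the downsample.
#' @return List of class `fam_pool` with `positive_ids` and `negative_ids`.
#' @export
build_pool <- function(active_ids, inactive_candidate_ids, neg_ratio = 3,
                       seed = 1L) {
  active_ids <- unique(as.character(active_ids))
  inactive_candidate_ids <- unique(as.character(inactive_candidate_ids))
  if (length(intersect(active_ids, inactive_candidate_ids)) > 0) {
    stop("active and inactive candidate sets overlap", call. = FALSE)
  }
  need <- round(neg_ratio * length(active_ids))
  if (length(inactive_candidate_ids) < need) {
    stop(
      sprintf(
        "only %d inactive candidates for %d actives; need %d (max feasible ratio %.2f)",
        length(inactive_candidate_ids), length(active_ids), need,
        length(inactive_candidate_ids) / max(1, length(active_ids))
      ),
      call. = FALSE
    )
  }
  keep <- with_substream(
    as.integer(seed),
    sample(inactive_candidate_ids, need)
  )
  structure(
    list(positive_ids = active_ids, negative_ids = sort(keep)),
    class = "fam_pool"
  )
}

#' @export
print.fam_pool <- function(x, ...) {
  cat(
    "<fam_pool> ", length(x$positive_ids), " active + ",
    length(x$negative_ids), " inactive labeled genes\n",
    sep = ""
  )
  invisible(x)
}

#' Stratified train/validate split of the pool
#'
#' Splits the labeled pool into training and validating genes.  The total
#' training size follows the global-count rule `floor(train_fraction * n)`
#' (a 164-gene pool at 2/3 gives 109 train / 55 validate); the positives'
#' share is the rounded fraction so the class ratio in the training set
#' stays within one gene of the pool's ratio.
#'
#' @param pool A [build_pool()] result.
#' @param train_fraction Fraction of the pool used for training.
#' @param seed Integer seed.
#' @return List with `train_ids` and `validate_ids`.
#' @export
split_pool <- function(pool, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(pool, "fam_pool"))
  n_pos <- length(pool$positive_ids)
  n_neg <- length(pool$negative_ids)
  n <- n_pos + n_neg
  if (n == 0) stop("empty pool", call. = FALSE)
  n_train <- floor(train_fraction * n)
  n_pos_train <- round(train_fraction * n_pos)
  n_neg_train <- n_train - n_pos_train
  if (n_pos_train < 1 || n_neg_train < 1 ||
    n_pos_train >= n_pos || n_neg_train >= n_neg) {
    stop("split leaves a class absent from the training or validating set",
      call. = FALSE
    )
  }
  sel <- with_substream(as.integer(seed), list(
    pos = sample(pool$positive_ids, n_pos_train),
    neg = sample(pool$negative_ids, n_neg_train)
  ))
  train_ids <- c(sel$pos, sel$neg)
  list(
    train_ids = train_ids,
    validate_ids = setdiff(c(pool$positive_ids, pool$negative_ids), train_ids)
  )
}

#' Train a base classifier
#'
#' Dispatches on `spec$kind`: the reference MLP ([mlp_fit()]), a
#' [randomForest::randomForest()] with `mtry = 4`, or an
#' [e1071::svm()] with `type = "C-classification"`, `kernel = "radial"`
#' and probability estimates.  All fits are seeded and deterministic.
#'
#' @param spec A [classifier_spec()].
#' @param x Standardized feature matrix of the training genes.
#' @param y 0/1 labels (1 = active).
#' @param seed Integer seed.
#' @return List of class `fam_classifier` with the fitted model, the kind
#'   and a `converged` flag (always `TRUE` for RF/SVM).
#' @export
train_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  fit <- switch(spec$kind,
    mlp = mlp_fit(x, y,
      hidden = spec$mlp_hidden, seed = seed,
      max_iter = spec$mlp_max_iter, learn_rate = spec$mlp_learn_rate,
      tol = spec$mlp_tol
    ),
    rf = with_substream(
      as.integer(seed),
      randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        mtry = min(spec$rf_mtry, ncol(x)), ntree = spec$rf_ntree
      )
    ),
    svm = with_substream(
      as.integer(seed),
      e1071::svm(
        x = x, y = factor(y, levels = c(0, 1)),
        type = "C-classification", kernel = "radial",
        cost = spec$svm_cost, probability = TRUE
      )
    ),
    stub = list(stub_predict = spec$stub_predict)
  )
  converged <- if (spec$kind == "mlp") isTRUE(fit$converged) else TRUE
  structure(
    list(kind = spec$kind, fit = fit, features = colnames(x),
         threshold = spec$decision_threshold, converged = converged),
    class = "fam_classifier"
  )
}

#' Score and label genes with a trained classifier
#'
#' Scores are probabilities of the active class in `[0, 1]`; the label is
#' active when the score reaches the decision threshold (inclusive, so a
#' score of exactly 0.5 is called active under the default threshold).
#'
#' @param model A [train_classifier()] result.
#' @param x Feature matrix with the training schema.
#' @return Tibble with `gene_id` (row names of `x`, if any), `score` and
#'   `label` (`"active"`/`"inactive"`).
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "fam_classifier"))
  x <- as.matrix(x)
  if (!is.null(model$features) && !is.null(colnames(x)) &&
    !identical(colnames(x), model$features)) {
    stop("feature schema does not match the training schema", call. = FALSE)
  }
  score <- switch(model$kind,
    mlp = mlp_predict(model$fit, x),
    rf = as.numeric(stats::predict(model$fit, x, type = "prob")[, "1"]),
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    stub = as.numeric(model$fit$stub_predict(x))
  )
  tibble::tibble(
    gene_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    score = score,
    label = ifelse(score >= model$threshold, "active", "inactive")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round call from vote tallies
#'
#' A gene is called in a round only when one class wins at least
#' `vote_threshold` of the `n_resamples` votes (inclusive); otherwise the
#' round call is `"none"`.
#'
#' @param votes_active,votes_inactive Integer vote tallies.
#' @param n_resamples Number of resamples in the round.
#' @param vote_threshold Votes required for a call.
#' @return Character vector of `"active"`, `"inactive"`, `"none"`.
#' @examples
#' call_from_votes(c(1000, 949), c(0, 51), 1000, 950) # "active", "none"
#' @export
call_from_votes <- function(votes_active, votes_inactive, n_resamples,
                            vote_threshold) {
  if (vote_threshold > n_resamples) {
    stop("vote_threshold exceeds n_resamples", call. = FALSE)
  }
  ifelse(votes_active >= vote_threshold, "active",
    ifelse(votes_inactive >= vote_threshold, "inactive", "none")
  )
}

#' Run one round of resampling-consensus prediction
#'
#' One round refits the classifier on `n_resamples` fresh stratified
#' train/validate splits of the labeled pool, scores the test genes each
#' time, and tallies the per-gene active/inactive votes.  A non-convergent
#' MLP fit is retried up to `n_retries` times with fresh seeded
#' initializations; if it still fails to converge that resample abstains
#' (it contributes to neither tally and is logged).  All per-resample seeds
#' are derived from `round_seed`, so any single resample is reproducible
#' in isolation.
#'
#' @param x Standardized feature matrix (row names = gene ids) covering the
#'   pool and the test genes.
#' @param pool A [build_pool()] result; ids must be rows of `x`.
#' @param test_ids Genes to score; must be disjoint from the pool.
#' @param spec A [classifier_spec()].
#' @param n_resamples Resamples per round.
#' @param vote_threshold Votes (out of `n_resamples`) required for a round
#'   call.
#' @param train_fraction Passed to [split_pool()].
#' @param round_seed Integer seed for the round.
#' @param n_retries Fresh-initialization retries for non-convergent fits.
#' @return List of class `round_result`: `votes` (tibble `gene_id`,
#'   `votes_active`, `votes_inactive`, `call`), `validation_accuracy`
#'   (per-resample vector, `NA` where abstained), `n_abstained`,
#'   `n_resamples`, `vote_threshold`.
#' @export
run_round <- function(x, pool, test_ids, spec, n_resamples = 1000,
                      vote_threshold = 950, train_fraction = 2 / 3,
                      round_seed = 1L, n_retries = 2) {
  stopifnot(inherits(pool, "fam_pool"))
  if (vote_threshold > n_resamples) {
    stop("vote_threshold exceeds n_resamples", call. = FALSE)
  }
  pool_ids <- c(pool$positive_ids, pool$negative_ids)
  if (length(intersect(test_ids, pool_ids)) > 0) {
    stop("test_ids overlap the labeled pool", call. = FALSE)
  }
  missing_rows <- setdiff(c(pool_ids, test_ids), rownames(x))
  if (length(missing_rows) > 0) {
    stop("genes absent from the feature matrix: ",
      paste(head(missing_rows, 3), collapse = ", "),
      call. = FALSE
    )
  }
  x_test <- x[test_ids, , drop = FALSE]
  labels <- setNames(
    rep(c(1, 0), c(length(pool$positive_ids), length(pool$negative_ids))),
    pool_ids
  )
  votes_active <- setNames(integer(length(test_ids)), test_ids)
  votes_inactive <- setNames(integer(length(test_ids)), test_ids)
  val_acc <- rep(NA_real_, n_resamples)
  n_abstained <- 0L

  for (r in seq_len(n_resamples)) {
    split <- split_pool(pool,
      train_fraction = train_fraction,
      seed = substream_seed(round_seed, "resample", r, "split")
    )
    model <- NULL
    for (attempt in 0:n_retries) {
      cand <- train_classifier(
        spec,
        x[split$train_ids, , drop = FALSE], labels[split$train_ids],
        seed = substream_seed(round_seed, "resample", r, "fit", attempt)
      )
      if (cand$converged) {
        model <- cand
        break
      }
    }
    if (is.null(model)) {
      n_abstained <- n_abstained + 1L
      next
    }
    val_pred <- predict_classifier(model, x[split$validate_ids, , drop = FALSE])
    val_truth <- ifelse(labels[split$validate_ids] == 1, "active", "inactive")
    val_acc[r] <- mean(val_pred$label == val_truth)
    if (length(test_ids) > 0) {
      test_pred <- predict_classifier(model, x_test)
      is_active <- test_pred$label == "active"
      votes_active[is_active] <- votes_active[is_active] + 1L
      votes_inactive[!is_active] <- votes_inactive[!is_active] + 1L
    }
  }

  votes <- tibble::tibble(
    gene_id = test_ids,
    votes_active = as.integer(votes_active),
    votes_inactive = as.integer(votes_inactive),
    call = call_from_votes(votes_active, votes_inactive, n_resamples, vote_threshold)
  )
  structure(
    list(
      votes = votes, validation_accuracy = val_acc,
      n_abstained = n_abstained, n_resamples = n_resamples,
      vote_threshold = vote_threshold
    ),
    class = "round_result"
  )
}

#' @export
print.round_result <- function(x, ...) {
  cat(
    "<round_result> ", nrow(x$votes), " test genes, ", x$n_resamples,
    " resamples (threshold ", x$vote_threshold, "); called active: ",
    sum(x$votes$call == "active"), ", inactive: ",
    sum(x$votes$call == "inactive"),
    "; mean validation accuracy ",
    signif(mean(x$validation_accuracy, na.rm = TRUE), 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Consensus call across rounds
#'
#' A gene's final call is active (inactive) when at least `min_rounds` of
#' the rounds called it active (inactive); genes meeting neither bar are
#' unclassified.  With `min_rounds > n_rounds / 2` the two bars cannot
#' both be met, so the final active and inactive sets are disjoint by
#' construction.
#'
#' @param rounds List of `round_result`s (or of their `votes` tibbles),
#'   all over the same gene set.
#' @param min_rounds Rounds required for a final call.
#' @return Tibble of class `consensus_calls`: `gene_id`, `rounds_active`,
#'   `rounds_inactive`, `mean_vote_fraction` (mean share of active votes
#'   across rounds), `final` (`"active"`, `"inactive"`, `"unclassified"`).
#' @export
consensus_across_rounds <- function(rounds, min_rounds = 9) {
  votes <- lapply(rounds, function(r) {
    if (inherits(r, "round_result")) r$votes else r
  })
  n_rounds <- length(votes)
  if (n_rounds == 0) stop("no rounds supplied", call. = FALSE)
  if (min_rounds > n_rounds) {
    stop("min_rounds exceeds the number of rounds", call. = FALSE)
  }
  ids <- votes[[1]]$gene_id
  for (v in votes) {
    if (!identical(sort(v$gene_id), sort(ids))) {
      stop("rounds cover inconsistent gene sets", call. = FALSE)
    }
  }
  calls <- sapply(votes, function(v) v$call[match(ids, v$gene_id)])
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(ids))
  frac <- sapply(votes, function(v) {
    i <- match(ids, v$gene_id)
    tot <- v$votes_active[i] + v$votes_inactive[i]
    ifelse(tot > 0, v$votes_active[i] / tot, NA_real_)
  })
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = length(ids))
  rounds_active <- rowSums(calls == "active")
  rounds_inactive <- rowSums(calls == "inactive")
  final <- ifelse(rounds_active >= min_rounds, "active",
    ifelse(rounds_inactive >= min_rounds, "inactive", "unclassified")
  )
  out <- tibble::tibble(
    gene_id = ids,
    rounds_active = as.integer(rounds_active),
    rounds_inactive = as.integer(rounds_inactive),
    mean_vote_fraction = rowMeans(frac, na.rm = TRUE),
    final = final
  )
  class(out) <- c("consensus_calls", class(out))
  attr(out, "n_rounds") <- n_rounds
  attr(out, "min_rounds") <- min_rounds
  out
}
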