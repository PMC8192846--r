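test_that("pool construction downsamples negatives to the configured ratio", {
  act <- sprintf("a%03d", 1:41)
  cand <- sprintf("n%03d", 1:140)
  pool <- build_pool(act, cand, neg_ratio = 3, seed = 2)
  expect_equal(length(pool$positive_ids), 41)
  expect_equal(length(pool$negative_ids), 123)
  expect_true(all(pool$negative_ids %in% cand))
  expect_identical(build_pool(act, cand, 3, seed = 2), pool) # deterministic

  small <- build_pool(sprintf("a%d", 1:10), sprintf("n%d", 1:10), neg_ratio = 1, seed = 1)
  expect_equal(length(small$negative_ids), 10)

  expect_error(
    build_pool(act, cand[1:100], neg_ratio = 3, seed = 1),
    "need 123"
  )
  expect_error(build_pool(act, c(act[1], cand), 3, 1), "overlap")
})

test_that("the pool split follows the global-count rule with stratification", {
  pool <- build_pool(sprintf("a%03d", 1:41), sprintf("n%03d", 1:140),
    neg_ratio = 3, seed = 4
  )
  sp <- split_pool(pool, 2 / 3, seed = 1)
  expect_equal(length(sp$train_ids), 109)
  expect_equal(length(sp$validate_ids), 55)

  expect_error(split_pool(pool, 1, seed = 1), "absent")

  # class ratio in the training set within one gene of the pool ratio
  pool_frac <- 41 / 164
  for (seed in 1:100) {
    sp <- split_pool(pool, 2 / 3, seed = seed)
    n_pos <- sum(sp$train_ids %in% pool$positive_ids)
    expect_lte(abs(n_pos - pool_frac * 109), 1)
    expect_equal(length(sp$train_ids), 109)
  }
})

test_that("the MLP learns separable data exactly and is seed-deterministic", {
  d <- make_separable_xy(10)
  fit <- mlp_fit(d$x, d$y, seed = 3)
  expect_true(fit$converged)
  pred <- mlp_predict(fit, d$x)
  expect_equal(mean((pred >= 0.5) == (d$y == 1)), 1)

  fit2 <- mlp_fit(d$x, d$y, seed = 3)
  expect_identical(fit$W1, fit2$W1)
  expect_identical(mlp_predict(fit2, d$x), pred)

  fit3 <- mlp_fit(d$x, d$y, seed = 4)
  expect_false(identical(fit3$W1, fit$W1))
})

test_that("shuffled labels give chance-level validation accuracy", {
  withr::with_seed(20, {
    x <- matrix(rnorm(60 * 4), ncol = 4,
      dimnames = list(sprintf("g%02d", 1:60), paste0("f", 1:4))
    )
  })
  accs <- vapply(1:50, function(i) {
    y <- withr::with_seed(100 + i, sample(rep(0:1, 30)))
    tr <- 1:40
    va <- 41:60
    fit <- mlp_fit(x[tr, ], y[tr], seed = i, max_iter = 500)
    mean((mlp_predict(fit, x[va, ]) >= 0.5) == (y[va] == 1))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("prediction is inclusive at the threshold and checks the schema", {
  spec <- classifier_spec("stub", stub_predict = function(x) rep(0.5, nrow(x)))
  d <- make_separable_xy(5)
  model <- train_classifier(spec, d$x, d$y, seed = 1)
  pred <- predict_classifier(model, d$x)
  expect_true(all(pred$label == "active")) # score 0.5 -> active

  mfit <- train_classifier(classifier_spec("mlp"), d$x, d$y, seed = 1)
  bad <- d$x
  colnames(bad) <- c("f2", "f1")
  expect_error(predict_classifier(mfit, bad), "schema")
})

test_that("random forest and SVM base classifiers honor their contracts", {
  d <- make_separable_xy(15)
  for (kind in c("rf", "svm")) {
    model <- train_classifier(classifier_spec(kind), d$x, d$y, seed = 5)
    pred <- predict_classifier(model, d$x)
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    expect_gte(mean((pred$score >= 0.5) == (d$y == 1)), 0.95)
  }
})

test_that("round calls respect the inclusive vote threshold", {
  expect_identical(
    call_from_votes(c(1000, 949, 950, 0), c(0, 51, 50, 1000), 1000, 950),
    c("active", "none", "active", "inactive")
  )
  expect_error(call_from_votes(1, 0, 10, 11), "exceeds")
})

test_that("a deterministic stub round reproduces a hand tally", {
  # stub: score 1 for genes whose first feature is positive, else 0
  spec <- classifier_spec("stub", stub_predict = function(x) as.numeric(x[, 1] > 0))
  withr::with_seed(30, {
    x <- matrix(rnorm(40 * 2), ncol = 2,
      dimnames = list(sprintf("g%02d", 1:40), c("f1", "f2"))
    )
  })
  x[, 1] <- rep(c(1, -1), 20) # deterministic signs
  pool <- build_pool(rownames(x)[1:8], rownames(x)[9:32], neg_ratio = 3, seed = 1)
  test_ids <- rownames(x)[33:40]
  rr <- run_round(x, pool, test_ids, spec,
    n_resamples = 10, vote_threshold = 10, round_seed = 7
  )
  # every resample votes identically, so tallies are all-or-nothing
  expected_active <- x[test_ids, 1] > 0
  expect_equal(rr$votes$votes_active, unname(ifelse(expected_active, 10L, 0L)))
  expect_equal(rr$votes$votes_inactive, unname(ifelse(expected_active, 0L, 10L)))
  expect_identical(
    rr$votes$call,
    unname(ifelse(expected_active, "active", "inactive"))
  )
  expect_equal(rr$votes$votes_active + rr$votes$votes_inactive, rep(10L, 8))
  expect_error(
    run_round(x, pool, c(test_ids, pool$positive_ids[1]), spec,
      n_resamples = 10, vote_threshold = 10
    ),
    "overlap"
  )
})

test_that("cross-round consensus applies the min-rounds bar", {
  mk_round <- function(calls) {
    tibble::tibble(
      gene_id = names(calls),
      votes_active = ifelse(calls == "active", 1000L, 0L),
      votes_inactive = ifelse(calls == "inactive", 1000L, 0L),
      call = unname(calls)
    )
  }
  genes <- c(g1 = "active", g2 = "active", g3 = "none", g4 = "inactive")
  # g1 active 10/10; g2 active 8/10, none 2; g3 active 9, inactive 1; g4 inactive 9
  rounds <- lapply(1:10, function(i) {
    calls <- c(
      g1 = "active",
      g2 = if (i <= 8) "active" else "none",
      g3 = if (i <= 9) "active" else "inactive",
      g4 = if (i <= 9) "inactive" else "none"
    )
    mk_round(calls)
  })
  cc <- consensus_across_rounds(rounds, min_rounds = 9)
  expect_equal(cc$final[cc$gene_id == "g1"], "active")
  expect_equal(cc$final[cc$gene_id == "g2"], "unclassified")
  expect_equal(cc$final[cc$gene_id == "g3"], "active")
  expect_equal(cc$final[cc$gene_id == "g4"], "inactive")
  expect_equal(cc$rounds_active[cc$gene_id == "g2"], 8L)

  bad <- rounds
  bad[[2]] <- bad[[2]][-1, ]
  expect_error(consensus_across_rounds(bad, 9), "inconsistent")
})

test_that("raising either threshold never grows the called set", {
  withr::with_seed(40, {
    n_genes <- 30
    n_rounds <- 10
    votes <- lapply(1:n_rounds, function(i) {
      va <- rbinom(n_genes, 100, runif(n_genes))
      tibble::tibble(
        gene_id = sprintf("g%02d", 1:n_genes),
        votes_active = as.integer(va),
        votes_inactive = as.integer(100 - va)
      )
    })
  })
  called_set <- function(vote_threshold, min_rounds) {
    rounds <- lapply(votes, function(v) {
      v$call <- call_from_votes(v$votes_active, v$votes_inactive, 100, vote_threshold)
      v
    })
    cc <- consensus_across_rounds(rounds, min_rounds)
    cc$gene_id[cc$final != "unclassified"]
  }
  for (vt in c(60, 75, 90)) {
    for (mr in c(6, 8, 10)) {
      base <- called_set(vt, mr)
      expect_true(all(called_set(vt + 5, mr) %in% base))
      expect_true(all(called_set(vt, min(mr + 1, 10)) %in% base))
    }
  }
  # disjointness whenever min_rounds > n_rounds / 2
  rounds <- lapply(votes, function(v) {
    v$call <- call_from_votes(v$votes_active, v$votes_inactive, 100, 60)
    v
  })
  cc <- consensus_across_rounds(rounds, min_rounds = 6)
  expect_equal(
    length(intersect(
      cc$gene_id[cc$final == "active"],
      cc$gene_id[cc$final == "inactive"]
    )),
    0
  )
})
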