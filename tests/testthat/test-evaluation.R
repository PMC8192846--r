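test_that("validation metrics match hand-computed confusion entries", {
  all_right <- score_validation(
    rep(c("active", "inactive"), c(3, 5)),
    rep(c("active", "inactive"), c(3, 5))
  )
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$fnr, 0)
  expect_equal(all_right$fpr, 0)

  # 53 of 55 correct, reported as 96%
  pred <- rep(c("active", "inactive", "active"), c(13, 40, 2))
  truth <- rep(c("active", "inactive"), c(13, 42))
  sv <- score_validation(pred, truth)
  expect_equal(sv$accuracy, 53 / 55, tolerance = 1e-12)
  expect_equal(round(100 * sv$accuracy), 96)

  # stub confusion: TP 3, FN 1, TN 5, FP 1
  pred <- c(rep("active", 3), "inactive", rep("inactive", 5), "active")
  truth <- c(rep("active", 4), rep("inactive", 6))
  sv <- score_validation(pred, truth)
  expect_equal(sv$fnr, 0.25)
  expect_equal(sv$fpr, 1 / 6)
  expect_equal(unname(sv$confusion), c(3, 1, 5, 1))
  expect_error(score_validation(character(0), character(0)), "empty")
})

test_that("normalized precision divides accuracy by total calls", {
  expect_equal(normalized_precision(0.96, 54, 146), 0.96 / 200)
  expect_equal(normalized_precision(1, 1, 0), 1)
  # doubling the called set at fixed accuracy halves the value
  expect_equal(
    normalized_precision(0.9, 40, 60),
    2 * normalized_precision(0.9, 80, 120)
  )
  und <- normalized_precision(0.9, 0, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("control enrichment fractions and p match the hypergeometric oracle", {
  active <- sprintf("a%02d", 1:20)
  inactive <- sprintf("i%03d", 1:100)
  controls <- c(active[1:10], inactive[1:2], "other")
  enr <- control_enrichment(controls, active, inactive)
  expect_equal(enr$fraction_in_active, 0.5)
  expect_equal(enr$fraction_in_inactive, 0.02)
  expect_equal(enr$p_value, oracle_fisher_p(10, 10, 2, 98), tolerance = 1e-10)

  none <- control_enrichment("zz", active, inactive)
  expect_equal(none$fraction_in_active, 0)
  expect_equal(none$p_value, 1)

  all_ctrl <- control_enrichment(c(active, inactive), active, inactive)
  expect_equal(all_ctrl$fraction_in_active, 1)
  expect_equal(all_ctrl$fraction_in_inactive, 1)
  expect_equal(all_ctrl$p_value, 1) # zero margin: no non-controls anywhere

  expect_error(control_enrichment(controls, active, active[1]), "disjoint")
})

test_that("overlap counts equal a brute-force membership scan", {
  expect_equal(overlap_counts(letters, letters)$n_common, 26)
  expect_equal(overlap_counts(letters[1:5], letters[6:10])$n_common, 0)
  withr::with_seed(33, {
    universe <- sprintf("u%03d", 1:200)
    a <- sample(universe, 50)
    b <- sample(universe, 50)
  })
  oc <- overlap_counts(a, b)
  common <- sum(vapply(a, function(el) el %in% b, logical(1)))
  expect_equal(oc$n_common, common)
  expect_equal(oc$n_only_a, 50 - common)
  expect_equal(oc$n_only_b, 50 - common)
  expect_equal(oc$n_common + oc$n_only_a, oc$n_a) # inclusion-exclusion
})

test_that("Welch t agrees with hand arithmetic and the pooled-t limit", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  # hand computation: means 2 and 3, each variance 1, n = 3
  t_hand <- (2 - 3) / sqrt(1 / 3 + 1 / 3)
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(t_hand, df_hand), tolerance = 1e-12)

  withr::with_seed(44, {
    x <- rnorm(50)
    y <- rnorm(50, mean = 0.3)
  })
  pooled <- stats::t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(welch_t(x, y)$p_value, pooled, tolerance = 1e-3)

  degen <- welch_t(c(2, 2), c(2, 2))
  expect_equal(degen$p_value, 1)
})

test_that("verification balances set sizes and finds no signal in identical groups", {
  sim <- simulate_family(sim_config(
    n_active_labeled = 30, n_inactive_labeled = 30, n_unknown = 0,
    separation = 0, seed = 9
  ))
  tbl <- sim$feature_table
  ids <- tbl$gene_id
  ver <- verify_groups(tbl, ids[1:20], ids[21:60], ids[1:10], seed = 2)
  expect_equal(unname(ver$group_sizes[1:2]), c(20, 20)) # downsampled to min
  # separation 0: the three "groups" are exchangeable draws
  expect_true(all(vapply(
    ver$tests$pairwise, function(p) min(p$p_adj), numeric(1)
  ) > 0.001))
  expect_error(verify_groups(tbl, character(0), ids[1:5], ids[1:5]), "non-empty")
})

test_that("verification recovers the constructed Ka/Ks contrast", {
  worse <- 0
  for (seed in 1:20) {
    sim <- simulate_family(sim_config(
      n_active_labeled = 40, n_inactive_labeled = 80, n_unknown = 0,
      separation = 3, seed = seed
    ))
    tbl <- sim$feature_table
    act <- sim$truth$gene_id[sim$truth$true_activity == "active"]
    inact <- sim$truth$gene_id[sim$truth$true_activity == "inactive"]
    ver <- verify_groups(tbl, act, inact, act[1:10], seed = seed)
    s <- ver$summaries
    m_act <- s$mean[s$feature == "ka_ks" & s$group == "predicted_active"]
    m_inact <- s$mean[s$feature == "ka_ks" & s$group == "predicted_inactive"]
    if (m_inact <= m_act) worse <- worse + 1
  }
  expect_lte(worse, 1) # inactive mean higher in >= 95% of seeded runs
})
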