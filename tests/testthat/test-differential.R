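test_that("pairwise comparison matches hand-computed t statistics and folds", {
  g <- toy_groups(4, c("W", "P"))
  pt <- toy_peak_table(rbind(c(10, 12, 11, 9, 5, 6, 5, 6)), g)
  res <- pairwise_compare(pt, "W", "P")
  expect_equal(res$fold_change, 10.5 / 5.5, tolerance = 1e-12)
  expect_equal(res$relation, ">")
  # pooled-variance t by hand: means 10.5/5.5, s2p = (5/3 + 1/3)/2 = 1,
  # se = sqrt(1 * (1/4 + 1/4)), t = 5/se, df = 6
  t_hand <- 5 / sqrt(0.5)
  expect_equal(res$p_value, 2 * pt(-t_hand, 6), tolerance = 1e-12)

  # identical groups: fold 1, relation "="
  same <- toy_peak_table(rbind(rep(1, 8)), g)
  r <- pairwise_compare(same, "W", "P")
  expect_equal(r$fold_change, 1)
  expect_equal(r$relation, "=")

  # equal means, wildly different variances: "=" under both tests
  m <- rbind(c(9.9, 10.1, 10.0, 10.0, 4, 16, 1, 19))
  eq <- toy_peak_table(m, g)
  expect_equal(pairwise_compare(eq, "W", "P", test = "student")$relation, "=")
  expect_equal(pairwise_compare(eq, "W", "P", test = "welch")$relation, "=")
})

test_that("fold antisymmetry and relation mirroring hold on random tables", {
  set.seed(31)
  for (i in 1:20) {
    sim <- generate_peak_table(synthetic_spec(n_analytes = 15, seed = i,
                                              cv = 0.4))
    ab <- pairwise_compare(sim$table, "W", "T")
    ba <- pairwise_compare(sim$table, "T", "W")
    expect_equal(ab$fold_change * ba$fold_change,
                 rep(1, nrow(ab)), tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_identical(ifelse(ab$relation == "=", "=",
                            ifelse(ab$relation == ">", "<", ">")),
                     ba$relation)
  }
})

test_that("student and welch nearly always agree under equal variances at n=8", {
  set.seed(1234)
  n_trial <- 1000
  agree <- logical(n_trial)
  g <- toy_groups(8, c("W", "P"))
  for (i in seq_len(n_trial)) {
    x <- matrix(exp(rnorm(16, sd = 0.3)), 1)
    ptab <- toy_peak_table(x, g)
    s <- pairwise_compare(ptab, "W", "P", test = "student")$relation
    w <- pairwise_compare(ptab, "W", "P", test = "welch")$relation
    agree[i] <- identical(s, w)
  }
  expect_gte(mean(agree), 0.99)
})

test_that("DEM calling applies the metabolite and gene criteria strictly", {
  res <- pairwise_result(
    analyte_id = c("small_fold", "Abat", "boundary", "down"),
    group_a = "W", group_b = "P",
    mean_a = c(1.2, 8.37e1, 1.0, 0.5),
    mean_b = c(1.0, 4.87e1, 2.0, 1.0),
    p_value = c(0.001, 2.31e-3, 0.0501, 0.01))

  met <- call_dem(res, mode = "metabolite")
  gene <- call_dem(res, mode = "gene")

  # fold 1.2 at p 0.001: metabolite yes, gene no (inside the fold window)
  expect_true("small_fold" %in% met$analyte_id)
  expect_false("small_fold" %in% gene$analyte_id)
  # the worked gene row: fold 1.72, p 2.31e-3 -> called in gene mode
  expect_equal(res$fold_change[2], 1.72, tolerance = 0.005)
  expect_true("Abat" %in% gene$analyte_id)
  # p = 0.0501 excluded by strict inequality
  expect_false("boundary" %in% met$analyte_id)
  # gene calls are a subset of metabolite calls
  expect_true(all(gene$analyte_id %in% met$analyte_id))
})

test_that("fold-change report reproduces printed worked examples from means", {
  means <- rbind(
    "glucose-1-phosphate" = c(W = 1.09e-1, P = 1.48e-1, T = 2.14e-1),
    "xanthosine"          = c(W = 1.73e0,  P = 1.10e0,  T = 4.54e-1),
    "identical"           = c(W = 2, P = 2, T = 2))
  ff <- fold_from_means(means)
  expect_equal(ff$fold_W_vs_P_2dp, c(0.74, 1.57, 1.00))
  expect_equal(ff$fold_W_vs_T_2dp, c(0.51, 3.81, 1.00))
  expect_equal(ff$fold_P_vs_T_2dp[3], 1.00)

  # report from raw data carries the same orientation and rounding columns
  sim <- generate_peak_table(synthetic_spec(n_analytes = 6, seed = 3))
  rep_df <- fold_change_report(sim$table)
  expect_named(rep_df, c("analyte_id", "mean_W", "mean_P", "mean_T",
                         "fold_W_vs_P", "fold_W_vs_P_2dp", "p_W_vs_P",
                         "fold_P_vs_T", "fold_P_vs_T_2dp", "p_P_vs_T",
                         "fold_W_vs_T", "fold_W_vs_T_2dp", "p_W_vs_T"))
  expect_equal(rep_df$fold_W_vs_P, rep_df$mean_W / rep_df$mean_P)
})
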