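test_that("exactly 10 of the 27 relation triples are named, rest unclassified", {
  grid <- all_relation_triples()
  calls <- classify_pattern(grid$rel_TP, grid$rel_TW, grid$rel_PW)
  expect_equal(sum(calls$category != "unclassified"), 10L)
  expect_equal(sum(calls$category == "unclassified"), 17L)
  expect_true(all(calls$subtype[calls$category == "unclassified"] == ""))

  # independent oracle: re-derive each named subtype's triple by parsing
  # the subtype string, and check it classifies back to itself
  named <- calls[calls$category != "unclassified", ]
  for (i in seq_len(nrow(named))) {
    tr <- triple_from_subtype(named$subtype[i])
    expect_identical(unname(tr),
                     unlist(grid[as.integer(named$analyte_id[i]), ],
                            use.names = FALSE))
  }
  # the ten (category, subtype) pairs are distinct
  expect_equal(anyDuplicated(named[c("category", "subtype")]), 0L)
})

test_that("sign-swap symmetry maps positive categories to negative ones pairwise", {
  grid <- all_relation_triples()
  calls <- classify_pattern(grid$rel_TP, grid$rel_TW, grid$rel_PW)
  swap <- function(r) chartr("<>", "><", r)
  swapped <- classify_pattern(swap(grid$rel_TP), swap(grid$rel_TW),
                              swap(grid$rel_PW))
  map <- c(HCC_pos = "HCC_neg", HCC_neg = "HCC_pos",
           RAS_pos = "RAS_neg", RAS_neg = "RAS_pos",
           unclassified = "unclassified")
  expect_identical(swapped$category, unname(map[calls$category]))
  # and subtypes map pairwise: the swapped subtype is the original with
  # every inequality flipped
  named <- calls$category != "unclassified"
  expect_identical(swapped$subtype[named],
                   chartr("<>", "><", calls$subtype[named]))
})

test_that("printed worked rows classify to their published categories", {
  rows <- printed_metabolite_rows()

  cit <- summary_profile("citrate", rows$citrate$means, rows$citrate$p)
  expect_identical(unlist(cit[c("rel_TP", "rel_TW", "rel_PW")],
                          use.names = FALSE), c(">", ">", "="))
  cit_call <- classify_pattern(cit)
  expect_equal(cit_call$category, "HCC_pos")
  expect_equal(cit_call$subtype, "T>P=W")

  suc <- summary_profile("succinate", rows$succinate$means, rows$succinate$p)
  expect_identical(unlist(suc[c("rel_TP", "rel_TW", "rel_PW")],
                          use.names = FALSE), c("=", "<", "<"))
  suc_call <- classify_pattern(suc)
  expect_equal(suc_call$category, "RAS_neg")
  expect_equal(suc_call$subtype, "T=P<W")

  g6p <- summary_profile("glucose_6p", rows$glucose_6p$means,
                         rows$glucose_6p$p)
  g6p_call <- classify_pattern(g6p)
  expect_equal(g6p_call$category, "RAS_pos")
  expect_equal(g6p_call$subtype, "T>P>W")
})

test_that("build_trajectory requires all three comparisons and re-orients them", {
  rows <- rbind(
    pairwise_result("x", "W", "P", 1, 2, 0.01),
    pairwise_result("x", "P", "T", 2, 4, 0.01))
  expect_error(build_trajectory(rows), "profile error")

  # all p >= alpha gives all "="
  ns <- rbind(
    pairwise_result("y", "W", "P", 1, 2, 0.5),
    pairwise_result("y", "P", "T", 2, 4, 0.5),
    pairwise_result("y", "W", "T", 1, 4, 0.5))
  prof <- build_trajectory(ns)
  expect_identical(unlist(prof[c("rel_TP", "rel_TW", "rel_PW")],
                          use.names = FALSE), c("=", "=", "="))
  expect_equal(classify_pattern(prof)$category, "unclassified")
})

test_that("noise-truncated chains are unclassified and flagged inconsistent", {
  # T>P and P>W significant but T vs W not: broken T>P>W chain
  call <- classify_pattern(">", "=", ">")
  expect_equal(call$category, "unclassified")
  expect_false(call$consistent)
  # complete chains and plateau subtypes are consistent
  expect_true(classify_pattern(">", ">", ">")$consistent)
  expect_true(classify_pattern(">", ">", "=")$consistent)
})

test_that("classify_table tabulates planted categories and handles empty input", {
  grid <- data.frame(rel_TP = c(">", "<", ">", "="),
                     rel_TW = c(">", "<", ">", "<"),
                     rel_PW = c("=", "=", ">", "<"),
                     analyte_id = paste0("m", 1:4),
                     stringsAsFactors = FALSE)
  out <- classify_table(grid)
  counts <- setNames(out$counts$n, out$counts$category)
  expect_equal(unname(counts[c("HCC_pos", "HCC_neg", "RAS_pos", "RAS_neg")]),
               rep(1L, 4))

  empty <- classify_table(grid[0, ])
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("classifier recovers planted patterns end to end on synthetic data", {
  sim <- generate_peak_table(synthetic_spec(n_analytes = 110, seed = 77))
  cls <- classify_peaks(sim$table)
  calls <- cls$calls[match(sim$truth$analyte_id, cls$calls$analyte_id), ]
  planted <- sim$truth$category != "unclassified"
  expect_gte(mean(calls$category[planted] == sim$truth$category[planted]),
             0.9)
  # noise-free generation recovers exactly
  clean <- generate_peak_table(synthetic_spec(n_analytes = 22, cv = 0,
                                              effect_size = 2, seed = 5))
  ccls <- classify_peaks(clean$table)
  ccalls <- ccls$calls[match(clean$truth$analyte_id, ccls$calls$analyte_id), ]
  expect_identical(ccalls$subtype, clean$truth$subtype)
})
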