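# small in-code fixtures shared across test files

toy_groups <- function(n = 3, labels = c("W", "P")) {
  ids <- paste0("s", seq_len(n * length(labels)))
  setNames(rep(labels, each = n), ids)
}

toy_peak_table <- function(values, groups = toy_groups(),
                           analytes = paste0("a", seq_len(nrow(values)))) {
  m <- as.matrix(values)
  dimnames(m) <- list(analytes, names(groups))
  peak_table(m, groups)
}

# table whose analytes have exactly the IQRs 0, 1, 2, 3, 4 across 5 samples
# plus a sixth sample group; built from symmetric spreads so that the
# type-7 quartiles are immediate
iqr_ladder_table <- function() {
  rows <- rbind(
    rep(5, 8),
    5 + c(-0.5, -0.5, -0.25, 0, 0, 0.25, 0.5, 0.5),
    5 + 2 * c(-0.5, -0.5, -0.25, 0, 0, 0.25, 0.5, 0.5),
    5 + 3 * c(-0.5, -0.5, -0.25, 0, 0, 0.25, 0.5, 0.5),
    5 + 4 * c(-0.5, -0.5, -0.25, 0, 0, 0.25, 0.5, 0.5))
  toy_peak_table(rows, toy_groups(4), analytes = paste0("iqr", 0:4))
}

# paper-style worked rows: group means and p-values of three-group summary
# tables, used to rebuild trajectory profiles from summary statistics
printed_metabolite_rows <- function() {
  list(
    citrate = list(means = c(W = 1.00e-2, P = 1.21e-2, T = 4.55e-2),
                   p = c(W_vs_P = 0.684, P_vs_T = 3.91e-2, W_vs_T = 3.18e-2)),
    succinate = list(means = c(W = 1.40e-1, P = 6.65e-2, T = 6.21e-2),
                     p = c(W_vs_P = 4.43e-3, P_vs_T = 0.765, W_vs_T = 2.41e-3)),
    glucose_6p = list(means = c(W = 1.69e-2, P = 4.56e-2, T = 1.68e-1),
                      p = c(W_vs_P = 6.57e-3, P_vs_T = 3.77e-6, W_vs_T = 1.50e-5)))
}

summary_profile <- function(id, means, p, alpha = 0.05) {
  rows <- rbind(
    pairwise_result(id, "W", "P", means[["W"]], means[["P"]], p[["W_vs_P"]], alpha),
    pairwise_result(id, "P", "T", means[["P"]], means[["T"]], p[["P_vs_T"]], alpha),
    pairwise_result(id, "W", "T", means[["W"]], means[["T"]], p[["W_vs_T"]], alpha))
  build_trajectory(rows)
}

all_relation_triples <- function() {
  expand.grid(rel_TP = c(">", "<", "="), rel_TW = c(">", "<", "="),
              rel_PW = c(">", "<", "="), stringsAsFactors = FALSE)
}

# independent re-derivation of the relation triple implied by a subtype
# string such as "T>W>P": parse the chain into a weak ordering of the three
# groups and read off each pairwise relation
triple_from_subtype <- function(subtype) {
  toks <- strsplit(subtype, "(?<=.)(?=[<>=])|(?<=[<>=])", perl = TRUE)[[1]]
  labels <- toks[c(1, 3, 5)]
  ops <- toks[c(2, 4)]
  level <- setNames(numeric(3), labels)
  for (i in 2:3)
    level[labels[i]] <- level[labels[i - 1]] +
      switch(ops[i - 1], ">" = -1, "<" = 1, "=" = 0)
  rel <- function(a, b) {
    if (level[a] > level[b]) ">" else if (level[a] < level[b]) "<" else "="
  }
  c(rel_TP = rel("T", "P"), rel_TW = rel("T", "W"), rel_PW = rel("P", "W"))
}
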