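#' Differential-calling criteria
#'
#' Significance and fold-change thresholds for differentially expressed
#' metabolites (DEMs) and genes (DEGs). Metabolite calling uses `p < alpha`
#' alone; gene calling additionally requires the linear fold change to fall
#' outside `[fc_low, fc_high]` (default 0.67/1.5).
#'
#' @param alpha two-sided significance level, strict inequality (an analyte
#'   with p exactly equal to `alpha` is not called).
#' @param fc_low,fc_high fold-change window excluded from gene calls;
#'   `fc_low < 1 < fc_high`.
#' @return list of class `dem_criteria`.
#' @export
dem_criteria <- function(alpha = 0.05, fc_low = 0.67, fc_high = 1.5) {
  if (!(alpha > 0 && alpha < 1))
    stop("parameter error: alpha must lie in (0, 1)", call. = FALSE)
  if (!(fc_low < 1 && fc_high > 1))
    stop("parameter error: need fc_low < 1 < fc_high", call. = FALSE)
  structure(list(alpha = alpha, fc_low = fc_low, fc_high = fc_high),
            class = "dem_criteria")
}

#' Build a pairwise comparison record from summary statistics
#'
#' Constructs the same record [pairwise_compare()] produces, but from group
#' means and a p-value directly — e.g. when re-deriving trajectory relations
#' from a published summary table instead of per-sample data. Fold change is
#' `mean_a / mean_b` (first-named over second-named group) and the discrete
#' relation is `"="` when `p >= alpha`, otherwise `">"`/`"<"` by the sign of
#' `mean_a - mean_b`.
#'
#' @param analyte_id character vector of analyte ids.
#' @param group_a,group_b group labels of the comparison "a vs b".
#' @param mean_a,mean_b group means (linear scale).
#' @param p_value two-sided p-values.
#' @param alpha significance level for the discrete relation.
#' @return data.frame of class `pairwise_result`.
#' @export
pairwise_result <- function(analyte_id, group_a, group_b, mean_a, mean_b,
                            p_value, alpha = 0.05) {
  fold <- ifelse(mean_b > 0, mean_a / mean_b, NA_real_)
  relation <- ifelse(p_value >= alpha, "=",
                     ifelse(mean_a > mean_b, ">", "<"))
  structure(
    data.frame(analyte_id = as.character(analyte_id),
               group_a = group_a, group_b = group_b,
               mean_a = mean_a, mean_b = mean_b,
               fold_change = fold, p_value = p_value,
               relation = relation,
               stringsAsFactors = FALSE),
    class = c("pairwise_result", "data.frame"),
    alpha = alpha)
}

#' Pairwise two-group comparison of every analyte
#'
#' For each analyte, computes group means on the linear intensity scale, the
#' fold change `mean_a / mean_b`, a two-sided two-sample t-test p-value
#' (pooled-variance Student by default, Welch optionally), and the discrete
#' relation of a versus b at `criteria$alpha`. Tests run on linear
#' intensities to match the mean-ratio fold convention; pass `log = TRUE` to
#' test log-transformed intensities instead (folds stay linear).
#'
#' Analytes that are constant within both groups get p = 1 when the means
#' are equal and p = 0 otherwise (the t statistic is degenerate there).
#'
#' @param table a [peak_table()] or [gene_table()], complete or imputed.
#' @param group_a,group_b group labels, each with >= 2 samples.
#' @param criteria a [dem_criteria()].
#' @param test "student" (pooled variance) or "welch".
#' @param log test on `log` intensities (requires strictly positive data).
#' @return data.frame of class `pairwise_result`, one row per analyte.
#' @examples
#' pt <- peak_table(matrix(c(10, 12, 11, 9, 5, 6, 5, 6), 1, 8,
#'                         dimnames = list("A", paste0("s", 1:8))),
#'                  setNames(rep(c("W", "P"), each = 4), paste0("s", 1:8)))
#' pairwise_compare(pt, "W", "P")  # fold ~1.91, relation ">"
#' @export
pairwise_compare <- function(table, group_a, group_b,
                             criteria = dem_criteria(),
                             test = c("student", "welch"), log = FALSE) {
  stopifnot(inherits(table, "omics_table"), inherits(criteria, "dem_criteria"))
  test <- match.arg(test)
  require_group_n(table, c(group_a, group_b), 2L)
  a <- table$intensities[, table$groups == group_a, drop = FALSE]
  b <- table$intensities[, table$groups == group_b, drop = FALSE]
  if (anyNA(a) || anyNA(b))
    stop("validation error: missing intensities; impute or drop before testing",
         call. = FALSE)
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  ta <- if (log) log(a) else a
  tb <- if (log) log(b) else b
  p <- vapply(seq_len(nrow(ta)), function(i) {
    x <- ta[i, ]; y <- tb[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y, var.equal = (test == "student"))$p.value
  }, numeric(1))
  out <- pairwise_result(rownames(table$intensities), group_a, group_b,
                         mean_a, mean_b, p, alpha = criteria$alpha)
  attr(out, "test") <- test
  out
}

#' Filter pairwise results to differential calls
#'
#' Metabolite mode keeps `p < alpha`; gene mode keeps `p < alpha` AND
#' (`fold >= fc_high` OR `fold <= fc_low`). Both inequalities on `alpha` are
#' strict. An optional Benjamini-Hochberg correction across analytes is
#' available (off by default, matching the plain per-test criterion).
#'
#' @param results a `pairwise_result` data.frame from [pairwise_compare()].
#' @param criteria a [dem_criteria()].
#' @param mode "metabolite" or "gene".
#' @param adjust apply Benjamini-Hochberg and filter on adjusted p instead.
#' @return the called subset of `results` (gene-mode calls are always a
#'   subset of metabolite-mode calls on the same input).
#' @export
call_dem <- function(results, criteria = dem_criteria(),
                     mode = c("metabolite", "gene"), adjust = FALSE) {
  mode <- match.arg(mode)
  p <- if (adjust) stats::p.adjust(results$p_value, "BH") else results$p_value
  keep <- p < criteria$alpha
  if (mode == "gene")
    keep <- keep & !is.na(results$fold_change) &
      (results$fold_change >= criteria$fc_high |
         results$fold_change <= criteria$fc_low)
  results[keep, , drop = FALSE]
}

#' Three-group fold-change report
#'
#' Mirrors the layout of a three-group summary table: per analyte, the three
#' group means and the fold change / p-value of each pairwise comparison
#' (first vs second, second vs third, first vs third), with folds both at
#' full precision and rounded to 2 decimals for display.
#'
#' @param table a [peak_table()] or [gene_table()] containing all three groups.
#' @param groups character trio of group labels, e.g. `c("W", "P", "T")`.
#' @param criteria a [dem_criteria()].
#' @param test passed to [pairwise_compare()].
#' @return data.frame with one row per analyte: means, `fold_*`, `fold_*_2dp`
#'   and `p_*` columns for the three comparisons.
#' @export
fold_change_report <- function(table, groups = c("W", "P", "T"),
                               criteria = dem_criteria(),
                               test = c("student", "welch")) {
  stopifnot(length(groups) == 3L)
  test <- match.arg(test)
  cmp <- list(groups[c(1, 2)], groups[c(2, 3)], groups[c(1, 3)])
  res <- lapply(cmp, function(g)
    pairwise_compare(table, g[1], g[2], criteria = criteria, test = test))
  out <- data.frame(analyte_id = res[[1]]$analyte_id,
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", groups[1])]] <- res[[1]]$mean_a
  out[[paste0("mean_", groups[2])]] <- res[[1]]$mean_b
  out[[paste0("mean_", groups[3])]] <- res[[2]]$mean_b
  for (k in 1:3) {
    tag <- paste0(cmp[[k]][1], "_vs_", cmp[[k]][2])
    out[[paste0("fold_", tag)]] <- res[[k]]$fold_change
    out[[paste0("fold_", tag, "_2dp")]] <- round(res[[k]]$fold_change, 2)
    out[[paste0("p_", tag)]] <- res[[k]]$p_value
  }
  attr(out, "comparisons") <- res
  out
}

#' Fold changes from published group means
#'
#' The summary-statistic analogue of [fold_change_report()]: given the three
#' group means of each analyte (e.g. transcribed from a printed table),
#' returns the three pairwise folds at full precision and rounded to two
#' decimals, under the first-named/second-named orientation.
#'
#' @param means numeric matrix, analytes x 3 groups (column names are group
#'   labels, default W/P/T order).
#' @param groups trio of group labels ordering the comparisons.
#' @return data.frame of folds per analyte.
#' @export
fold_from_means <- function(means, groups = colnames(means)) {
  stopifnot(is.matrix(means), length(groups) == 3L)
  cmp <- list(groups[c(1, 2)], groups[c(2, 3)], groups[c(1, 3)])
  out <- data.frame(analyte_id = rownames(means), stringsAsFactors = FALSE,
                    row.names = rownames(means))
  for (g in cmp) {
    f <- means[, g[1]] / means[, g[2]]
    tag <- paste0(g[1], "_vs_", g[2])
    out[[paste0("fold_", tag)]] <- f
    out[[paste0("fold_", tag, "_2dp")]] <- round(f, 2)
  }
  out
}
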