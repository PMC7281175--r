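#' @name pattern_taxonomy
#' @title Trajectory pattern taxonomy
#'
#' @description
#' A three-group tumorigenesis design (baseline W, precancerous P, tumor T)
#' gives each analyte a trajectory summarized by three pairwise relations at
#' a significance level alpha: T vs P, T vs W and P vs W, each one of
#' `">"`, `"<"` or `"="` (where `"="` means *not significant at alpha*, not
#' numerically equal). Ten of the 27 possible relation triples are named and
#' grouped into four categories:
#'
#' * **HCC_pos** — tumor-elevated: `T>P=W`, `T>W>P`, `W>T>P`
#' * **HCC_neg** — tumor-depleted: `T<P=W`, `T<W<P`, `W<T<P`
#' * **RAS_pos** — oncogene-elevated (shifted in both P and T): `T>P>W`, `T=P>W`
#' * **RAS_neg** — oncogene-depleted: `T<P<W`, `T=P<W`
#'
#' The remaining 17 triples are `unclassified`. Classification is an exact
#' lookup on the triple, so a chain subtype such as `T>P>W` requires the
#' implied outer inequality (T vs W) to be significant as well; profiles
#' whose adjacent relations form a chain but whose outer relation is `"="`
#' are flagged `consistent = FALSE` and left unclassified.
NULL

# (rel_TP, rel_TW, rel_PW) -> category/subtype lookup; the triple is ordered
# tumor-vs-precancerous, tumor-vs-baseline, precancerous-vs-baseline.
pattern_lookup <- function() {
  data.frame(
    rel_TP   = c(">", ">", ">", "<", "<", "<", ">", "=", "<", "="),
    rel_TW   = c(">", ">", "<", "<", "<", ">", ">", ">", "<", "<"),
    rel_PW   = c("=", "<", "<", "=", ">", ">", ">", ">", "<", "<"),
    category = c("HCC_pos", "HCC_pos", "HCC_pos",
                 "HCC_neg", "HCC_neg", "HCC_neg",
                 "RAS_pos", "RAS_pos", "RAS_neg", "RAS_neg"),
    subtype  = c("T>P=W", "T>W>P", "W>T>P",
                 "T<P=W", "T<W<P", "W<T<P",
                 "T>P>W", "T=P>W", "T<P<W", "T=P<W"),
    stringsAsFactors = FALSE)
}

mirror_relation <- function(r) chartr("<>", "><", r)

#' Build trajectory profiles from three pairwise comparisons
#'
#' Assembles, per analyte, the W/P/T group means and the relation triple
#' (rel_TP, rel_TW, rel_PW) from the three pairwise comparisons
#' (W vs P), (P vs T) and (W vs T). Relations are re-oriented so that the
#' tumor-end group is always the first operand: e.g. a (P vs T) relation
#' `"<"` becomes rel_TP `">"`.
#'
#' @param results a `pairwise_result` data.frame (rows from one or more
#'   [pairwise_compare()]/[pairwise_result()] calls stacked together)
#'   containing, for every analyte, exactly the three comparisons among the
#'   `groups` trio in either orientation.
#' @param groups trio `c(baseline, intermediate, tumor)`, default W/P/T.
#' @return data.frame of class `trajectory_profile`: analyte_id, mean_W,
#'   mean_P, mean_T (named by the actual labels), rel_TP, rel_TW, rel_PW.
#' @examples
#' rows <- rbind(
#'   pairwise_result("succinate", "W", "P", 1.40e-1, 6.65e-2, 4.43e-3),
#'   pairwise_result("succinate", "P", "T", 6.65e-2, 6.21e-2, 0.765),
#'   pairwise_result("succinate", "W", "T", 1.40e-1, 6.21e-2, 2.41e-3))
#' build_trajectory(rows)  # rel_TP "=", rel_TW "<", rel_PW "<"
#' @export
build_trajectory <- function(results, groups = c("W", "P", "T")) {
  stopifnot(length(groups) == 3L)
  w <- groups[1]; p <- groups[2]; t <- groups[3]
  res <- as.data.frame(results)
  key <- paste(res$group_a, res$group_b)
  ids <- unique(res$analyte_id)

  pick <- function(id, a, b) {
    i <- which(res$analyte_id == id & key == paste(a, b))
    if (length(i) == 1L)
      return(list(rel = res$relation[i], mean_a = res$mean_a[i],
                  mean_b = res$mean_b[i]))
    i <- which(res$analyte_id == id & key == paste(b, a))
    if (length(i) == 1L)
      return(list(rel = mirror_relation(res$relation[i]),
                  mean_a = res$mean_b[i], mean_b = res$mean_a[i]))
    stop("profile error: analyte '", id, "' lacks the ", a, " vs ", b,
         " comparison", call. = FALSE)
  }

  rows <- lapply(ids, function(id) {
    tp <- pick(id, t, p)   # tumor vs intermediate
    tw <- pick(id, t, w)   # tumor vs baseline
    pw <- pick(id, p, w)   # intermediate vs baseline
    data.frame(analyte_id = id,
               mean_W = tw$mean_b, mean_P = pw$mean_a, mean_T = tw$mean_a,
               rel_TP = tp$rel, rel_TW = tw$rel, rel_PW = pw$rel,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:4] <- paste0("mean_", c(w, p, t))
  structure(out, class = c("trajectory_profile", "data.frame"),
            groups = groups)
}

#' Classify a relation triple into the trajectory taxonomy
#'
#' Exact-match lookup of (rel_TP, rel_TW, rel_PW) against the ten named
#' subtypes (see [pattern_taxonomy]); any other triple is `unclassified`
#' with an empty subtype. The `consistent` flag is `FALSE` when two
#' significant relations form a transitive chain whose implied outer
#' relation is `"="` (a noise-truncated chain), `TRUE` otherwise.
#'
#' @param rel_TP,rel_TW,rel_PW vectors over `">"`, `"<"`, `"="`; or pass a
#'   `trajectory_profile` data.frame as `rel_TP`.
#' @return data.frame of class `pattern_call`: analyte_id (if available),
#'   category, subtype, consistent.
#' @export
classify_pattern <- function(rel_TP, rel_TW = NULL, rel_PW = NULL) {
  if (is.data.frame(rel_TP)) {
    prof <- rel_TP
    ids <- if ("analyte_id" %in% names(prof)) prof$analyte_id
           else as.character(seq_len(nrow(prof)))
    rel_TP <- prof$rel_TP; rel_TW <- prof$rel_TW; rel_PW <- prof$rel_PW
  } else {
    ids <- as.character(seq_along(rel_TP))
  }
  ok <- c(">", "<", "=")
  if (!all(c(rel_TP, rel_TW, rel_PW) %in% ok))
    stop("profile error: relations must be one of '>', '<', '='", call. = FALSE)
  lut <- pattern_lookup()
  key <- paste(rel_TP, rel_TW, rel_PW)
  hit <- match(key, paste(lut$rel_TP, lut$rel_TW, lut$rel_PW))
  category <- ifelse(is.na(hit), "unclassified", lut$category[hit])
  subtype <- ifelse(is.na(hit), "", lut$subtype[hit])
  # noise-truncated chains: adjacent significant pair whose transitive
  # closure is missing, e.g. T>P and P>W but T vs W not significant
  broken <-
    (rel_TP == ">" & rel_PW == ">" & rel_TW == "=") |  # T>P>W, outer T?W
    (rel_TP == "<" & rel_PW == "<" & rel_TW == "=") |
    (rel_TW == ">" & rel_PW == "<" & rel_TP == "=") |  # T>W>P, outer T?P
    (rel_TW == "<" & rel_PW == ">" & rel_TP == "=") |
    (rel_TP == ">" & rel_TW == "<" & rel_PW == "=") |  # W>T>P, outer W?P
    (rel_TP == "<" & rel_TW == ">" & rel_PW == "=")
  structure(
    data.frame(analyte_id = ids, category = category, subtype = subtype,
               consistent = !broken, stringsAsFactors = FALSE),
    class = c("pattern_call", "data.frame"))
}

#' Classify every profile in a collection and tabulate categories
#'
#' @param profiles a `trajectory_profile` data.frame from
#'   [build_trajectory()].
#' @return list with `calls` (a `pattern_call` data.frame joined to the
#'   profile relations) and `counts` (a data.frame of per-(category, subtype)
#'   counts including `unclassified`).
#' @export
classify_table <- function(profiles) {
  if (nrow(profiles) == 0L) {
    empty <- classify_pattern(character(), character(), character())
    return(list(calls = empty,
                counts = data.frame(category = character(),
                                    subtype = character(),
                                    n = integer(), stringsAsFactors = FALSE)))
  }
  calls <- classify_pattern(profiles)
  calls <- cbind(calls, profiles[c("rel_TP", "rel_TW", "rel_PW")])
  agg <- stats::aggregate(list(n = seq_len(nrow(calls))),
                          by = list(category = calls$category,
                                    subtype = calls$subtype),
                          FUN = length)
  agg <- agg[order(agg$category, agg$subtype), , drop = FALSE]
  rownames(agg) <- NULL
  list(calls = calls, counts = agg)
}

#' End-to-end trajectory classification of a peak or gene table
#'
#' Convenience wrapper: runs the three pairwise comparisons among the group
#' trio, builds trajectory profiles and classifies them.
#'
#' @param table a [peak_table()] or [gene_table()].
#' @param groups trio `c(baseline, intermediate, tumor)`.
#' @param criteria a [dem_criteria()] (alpha drives the `"="` relation).
#' @param test t-test flavor, see [pairwise_compare()].
#' @return as [classify_table()], plus element `profiles`.
#' @export
classify_peaks <- function(table, groups = c("W", "P", "T"),
                           criteria = dem_criteria(),
                           test = c("student", "welch")) {
  test <- match.arg(test)
  cmp <- list(groups[c(1, 2)], groups[c(2, 3)], groups[c(1, 3)])
  res <- do.call(rbind, lapply(cmp, function(g)
    pairwise_compare(table, g[1], g[2], criteria = criteria, test = test)))
  profiles <- build_trajectory(res, groups = groups)
  out <- classify_table(profiles)
  out$profiles <- profiles
  out
}
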