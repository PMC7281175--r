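#' Specification for a synthetic peak-table experiment
#'
#' Describes a three-group (default W/P/T, n = 8 per group — the design of
#' the staged hepatocarcinogenesis study this package models) peak table
#' with planted trajectory patterns: each analyte follows one of the ten
#' named subtypes (see [pattern_taxonomy]) or is a null analyte (all groups
#' equal, testing specificity). Observations are multiplicative log-normal:
#' `intensity = group_mean * exp(N(0, sigma))` with
#' `sigma = sqrt(log(1 + cv^2))`, the natural noise model for positive,
#' right-skewed GC-MS peak intensities.
#'
#' @param n_analytes number of analytes.
#' @param groups named integer vector of samples per group, default
#'   `c(W = 8, P = 8, T = 8)`; >= 2 each.
#' @param patterns character vector (length `n_analytes`, recycled) of
#'   planted subtypes drawn from the ten named subtypes, or `NA` for null
#'   analytes. Default: the ten subtypes and a null, cycled.
#' @param effect_size fold change between adjacent unequal group levels
#'   (> 1).
#' @param cv coefficient of variation of the multiplicative noise; 0 is the
#'   exact noise-free boundary (useful for recovery checks, since t-test
#'   false positives on equal means do not vanish for any positive cv).
#' @param base_mean baseline intensity of the lowest group level (recycled).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_analytes = 200,
                           groups = c(W = 8, P = 8, T = 8),
                           patterns = NULL,
                           effect_size = 2, cv = 0.25,
                           base_mean = 1, seed = 1) {
  if (effect_size <= 1) stop("parameter error: effect_size must be > 1", call. = FALSE)
  if (cv < 0) stop("parameter error: cv must be >= 0", call. = FALSE)
  if (length(groups) != 3L || is.null(names(groups)))
    stop("parameter error: groups must be a named trio", call. = FALSE)
  if (any(groups < 2L)) stop("parameter error: >= 2 samples per group", call. = FALSE)
  if (is.null(patterns))
    patterns <- rep(c(pattern_lookup()$subtype, NA), length.out = n_analytes)
  else {
    patterns <- rep(patterns, length.out = n_analytes)
    bad <- setdiff(stats::na.omit(unique(patterns)), pattern_lookup()$subtype)
    if (length(bad))
      stop("parameter error: unknown subtype(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_analytes = n_analytes, groups = groups,
                 patterns = patterns, effect_size = effect_size, cv = cv,
                 base_mean = rep(base_mean, length.out = n_analytes),
                 seed = seed),
            class = "synthetic_spec")
}

# walk a subtype string ("T>P=W") into per-group mean multipliers: the
# lowest level is 1 and each ">" step multiplies by effect_size; "=" shares
# the level
subtype_multipliers <- function(subtype, effect_size,
                                groups = c("W", "P", "T")) {
  if (is.na(subtype) || subtype == "")
    return(stats::setNames(rep(1, 3), groups))
  toks <- strsplit(subtype, "(?<=.)(?=[<>=])|(?<=[<>=])", perl = TRUE)[[1]]
  labels <- toks[seq(1, length(toks), by = 2)]
  ops <- toks[seq(2, length(toks), by = 2)]
  stopifnot(length(labels) == 3L, all(labels %in% c("W", "P", "T")))
  lev <- numeric(3)
  for (i in 2:3) lev[i] <- lev[i - 1] + switch(ops[i - 1],
                                               ">" = -1, "<" = 1, "=" = 0)
  lev <- lev - min(lev)
  mult <- effect_size^lev
  names(mult) <- labels
  # map the canonical W/P/T symbols onto the actual group labels
  stats::setNames(mult[c("W", "P", "T")], groups)[groups]
}

#' Generate a synthetic peak table with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [peak_table()]), `truth` (data.frame:
#'   analyte_id, subtype, category — the planted `pattern_call`), and
#'   `group_means` (analyte x group matrix of noise-free means).
#' @examples
#' sim <- generate_peak_table(synthetic_spec(n_analytes = 20, seed = 42))
#' table(sim$truth$category)
#' @export
generate_peak_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  gnames <- names(spec$groups)
  sample_ids <- unlist(lapply(gnames, function(g)
    paste0(g, seq_len(spec$groups[[g]]))))
  groups <- stats::setNames(rep(gnames, spec$groups), sample_ids)
  sigma <- sqrt(log(1 + spec$cv^2))
  mult <- t(vapply(spec$patterns, subtype_multipliers, numeric(3),
                   effect_size = spec$effect_size, groups = gnames))
  means <- mult * spec$base_mean
  rownames(means) <- sprintf("analyte_%03d", seq_len(spec$n_analytes))
  m <- means[, groups[sample_ids], drop = FALSE] *
    exp(matrix(stats::rnorm(spec$n_analytes * length(sample_ids), 0, sigma),
               spec$n_analytes))
  colnames(m) <- sample_ids
  lut <- pattern_lookup()
  truth <- data.frame(
    analyte_id = rownames(means),
    subtype = ifelse(is.na(spec$patterns), "", spec$patterns),
    category = ifelse(is.na(spec$patterns), "unclassified",
                      lut$category[match(spec$patterns, lut$subtype)]),
    stringsAsFactors = FALSE)
  list(table = peak_table(m, groups), truth = truth, group_means = means)
}

#' Generate a synthetic isotopologue table from the tracer simulator
#'
#' Per group, steady-state isotopologue fractions are computed with
#' [simulate_isotopomers()] from that group's network; per-sample peak
#' areas are `total_pool * fraction * exp(N(0, sigma))` with
#' `sigma = sqrt(log(1 + noise_cv^2))`. The noise-free fractions are
#' retained as ground truth.
#'
#' @param networks named list of [build_network()] objects, one per group
#'   (e.g. `list(W = ..., P = ..., T = ...)`).
#' @param metabolites metabolite ids to report (default: the measurable
#'   pools of the default network).
#' @param noise_cv coefficient of variation of the multiplicative area
#'   noise (0 allowed: exact fractions).
#' @param n_per_group samples per group.
#' @param total_pool total peak area per metabolite and sample.
#' @param seed integer seed.
#' @return list with `table` (an [isotopologue_table()] with groups) and
#'   `truth` (list of per-group solver outputs).
#' @export
generate_isotopologue_table <- function(networks,
                                        metabolites = c("PEP", "LAC", "CIT",
                                                        "SUC", "FUM", "MAL",
                                                        "GAP", "E4P", "Ru5P",
                                                        "G6P", "S7P", "R5P",
                                                        "F6P"),
                                        noise_cv = 0.1, n_per_group = 8,
                                        total_pool = 1e4, seed = 1) {
  stopifnot(is.list(networks), !is.null(names(networks)))
  set.seed(seed)
  sigma <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  truth <- lapply(networks, simulate_isotopomers)
  rows <- list()
  groups <- character()
  for (g in names(networks)) {
    sims <- truth[[g]]
    for (s in seq_len(n_per_group)) {
      sid <- paste0(g, s)
      groups[sid] <- g
      for (m in metabolites) {
        f <- sims[[m]]$fractions
        areas <- total_pool * f
        if (sigma > 0)
          areas <- areas * exp(stats::rnorm(length(areas), 0, sigma))
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = m, mass_shift = seq_along(f) - 1L, sample = sid,
          area = as.numeric(areas), stringsAsFactors = FALSE)
      }
    }
  }
  nc <- networks[[1]]$n_carbons[metabolites]
  tab <- isotopologue_table(do.call(rbind, rows),
                            n_carbons = stats::setNames(as.integer(nc),
                                                        metabolites),
                            groups = groups)
  list(table = tab, truth = truth)
}
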