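#' Define a pathway with metabolite and gene members
#'
#' @param name pathway name.
#' @param metabolites character vector of metabolite member ids.
#' @param genes character vector of gene member ids.
#' @return list of class `pathway_def`.
#' @export
pathway_def <- function(name, metabolites = character(), genes = character()) {
  metabolites <- unique(as.character(metabolites))
  genes <- unique(as.character(genes))
  if (length(metabolites) + length(genes) == 0L)
    stop("validation error: pathway '", name, "' has no members", call. = FALSE)
  structure(list(name = name, metabolites = metabolites, genes = genes),
            class = "pathway_def")
}

#' Built-in central-carbon pathway map
#'
#' Six curated pathway sets covering the metabolic axes most relevant to
#' Ras-driven hepatocarcinogenesis: glycolysis, the TCA cycle with the
#' citrate-malate shuttle, the pentose phosphate pathway, lipid
#' biosynthesis, cholesterol and bile acid synthesis, and glutathione
#' metabolism. Members are metabolite names (GC-MS nomenclature) and mouse
#' gene symbols. This map is a compact, openly reproducible stand-in for
#' versioned web enrichment databases.
#'
#' @return named list of [pathway_def()] objects.
#' @export
builtin_pathways <- function() {
  p <- list(
    pathway_def("glycolysis",
      metabolites = c("glucose-1-phosphate", "glucose-6-phosphate",
                      "fructose-6-phosphate", "fructose", "pyruvate",
                      "lactate"),
      genes = c("G6pc", "Pkm")),
    pathway_def("tca_citrate_malate_shuttle",
      metabolites = c("pyruvate", "citrate", "succinate", "fumarate",
                      "malate"),
      genes = c("Fh1", "Acly")),
    pathway_def("pentose_phosphate",
      metabolites = c("xanthosine", "ribose-5-phosphate"),
      genes = c("G6pdx", "Pgd")),
    pathway_def("lipid_biosynthesis",
      metabolites = c("linoleic acid", "arachidonic acid"),
      genes = c("Acly", "Lss", "Acsl4", "Dhcr7", "Mvd")),
    pathway_def("cholesterol_bile_acid",
      metabolites = c("glycine", "taurine", "cholate", "cholesterol"),
      genes = c("Baat", "Cyp27a1", "Cyp7b1", "Cyp8b1", "Hsd3b7", "Hmgcr",
                "Lss", "Dhcr7", "Mvd")),
    pathway_def("glutathione",
      metabolites = c("5-oxoproline", "L-glutamate", "glycine",
                      "L-cysteinylglycine", "succinate"),
      genes = c("Gss", "Gpx4", "Anpep", "Abat", "Pgd", "G6pdx")))
  stats::setNames(p, vapply(p, `[[`, "", "name"))
}

pathway_members <- function(pathways, members = c("both", "metabolite", "gene")) {
  members <- match.arg(members)
  lapply(pathways, function(p) {
    if (inherits(p, "pathway_def"))
      switch(members,
             both = union(p$metabolites, p$genes),
             metabolite = p$metabolites,
             gene = p$genes)
    else as.character(p)
  })
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the hit list contains more pathway
#' members than expected by drawing `n = |hits|` ids at random from the
#' universe: `p = P(X >= k)` with X hypergeometric(`K` pathway members in
#' the universe, `N - K` non-members, `n` draws). P-values are BH-adjusted
#' across pathways and the result is sorted by p.
#'
#' @param hits character vector of significant ids (must lie in the
#'   universe; foreign ids are dropped with a warning).
#' @param universe character vector of all tested ids (e.g. all analytes
#'   surviving denoising, or all detected genes).
#' @param pathways named list of member id vectors, or of [pathway_def()]
#'   objects (see `members`), e.g. [builtin_pathways()] or [read_gmt()].
#' @param members which member type of a `pathway_def` to use.
#' @return data.frame of class `enrichment_result`: pathway, k (hits in
#'   pathway), K (pathway size within universe), n (hit-list size),
#'   N (universe size), p_value, q_value.
#' @export
enrich <- function(hits, universe, pathways,
                   members = c("both", "metabolite", "gene")) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L)
    stop("validation error: empty universe", call. = FALSE)
  hits <- unique(as.character(hits))
  foreign <- setdiff(hits, universe)
  if (length(foreign)) {
    warning("dropping ", length(foreign), " hit(s) absent from the universe: ",
            paste(utils::head(foreign, 5), collapse = ", "))
    hits <- intersect(hits, universe)
  }
  sets <- pathway_members(pathways, members)
  if (is.null(names(sets)))
    names(sets) <- paste0("pathway_", seq_along(sets))
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    memb <- intersect(sets[[nm]], universe)
    K <- length(memb)
    k <- length(intersect(hits, memb))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @return named list of member character vectors (usable as `pathways` in
#'   [enrich()]).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("schema error: GMT line with fewer than 3 fields", call. = FALSE)
    unique(f[-(1:2)])
  })
  stats::setNames(sets, vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], ""))
}

#' Write gene sets to a GMT file
#' @param sets named list of member vectors or [pathway_def()] objects.
#' @param path output file.
#' @param members member type for `pathway_def` entries.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, members = "both") {
  m <- pathway_members(sets, members)
  lines <- vapply(names(m), function(nm)
    paste(c(nm, "na", m[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
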