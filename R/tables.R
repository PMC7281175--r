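#' Construct a peak-intensity table
#'
#' A `peak_table` holds a non-negative analyte-by-sample intensity matrix
#' together with a sample-to-group map and optional retention times. It is
#' the common currency of the preprocessing, differential and multivariate
#' stages. Missing measurements are stored as `NA`, never coerced to zero:
#' imputation is an explicit, separate step (see [impute_missing()]).
#'
#' @param intensities numeric matrix, analytes in rows, samples in columns.
#'   Row and column names are used as analyte and sample identifiers.
#' @param groups named character vector mapping every sample id to a group
#'   label. Labels are arbitrary strings; the wild-type/precancerous/tumor
#'   trio `c("W","P","T")` is a convention of the downstream classifier, not
#'   a requirement of the container.
#' @param retention_time optional numeric vector of retention times
#'   (minutes), named by analyte id.
#' @return an object of class `peak_table`.
#' @examples
#' m <- matrix(rexp(12), 2, 6,
#'             dimnames = list(c("citrate", "malate"), paste0("s", 1:6)))
#' pt <- peak_table(m, groups = setNames(rep(c("W", "P"), each = 3),
#'                                       paste0("s", 1:6)))
#' pt
#' @export
peak_table <- function(intensities, groups, retention_time = NULL) {
  new_omics_table(intensities, groups, retention_time, class = "peak_table")
}

#' Construct a gene-expression (FPKM) table
#'
#' Same container contract as [peak_table()]: genes in rows, samples in
#' columns, FPKM values non-negative, every sample mapped to a group.
#'
#' @param fpkm numeric matrix of FPKM values, genes in rows.
#' @inheritParams peak_table
#' @return an object of class `gene_table` (also a `peak_table`-compatible
#'   `omics_table`, so all statistical operations apply).
#' @export
gene_table <- function(fpkm, groups) {
  new_omics_table(fpkm, groups, NULL, class = "gene_table")
}

new_omics_table <- function(intensities, groups, retention_time, class) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("schema error: intensities must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("schema error: intensity matrix needs analyte rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(intensities)))
    stop("schema error: duplicated analyte ids", call. = FALSE)
  if (anyDuplicated(colnames(intensities)))
    stop("schema error: duplicated sample ids", call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("validation error: negative intensities are not allowed", call. = FALSE)
  groups <- validate_design(groups, colnames(intensities))
  if (!is.null(retention_time)) {
    retention_time <- retention_time[rownames(intensities)]
    names(retention_time) <- rownames(intensities)
  }
  structure(
    list(intensities = intensities,
         groups = groups,
         retention_time = retention_time),
    class = c(class, "omics_table")
  )
}

validate_design <- function(groups, sample_ids) {
  if (is.null(names(groups)))
    stop("design error: group map must be named by sample id", call. = FALSE)
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing))
    stop("design error: samples without a group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(groups), sample_ids)
  if (length(unknown))
    stop("design error: design names samples absent from the table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  as.character(groups)[match(sample_ids, names(groups))] -> g
  names(g) <- sample_ids
  g
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<%s> %d analytes x %d samples\n", class(x)[1],
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  if (anyNA(x$intensities))
    cat("missing cells:", sum(is.na(x$intensities)), "\n")
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$intensities)

analyte_ids <- function(x) rownames(x$intensities)
sample_ids <- function(x) colnames(x$intensities)

#' Subset an omics table by analyte and/or sample
#' @param x an `omics_table`
#' @param i analyte index/ids, `j` sample index/ids
#' @param j see `i`
#' @param ... ignored
#' @export
`[.omics_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  out <- x
  out$intensities <- x$intensities[i, j, drop = FALSE]
  out$groups <- x$groups[colnames(out$intensities)]
  if (!is.null(x$retention_time))
    out$retention_time <- x$retention_time[rownames(out$intensities)]
  out
}

n_per_group <- function(x) table(x$groups)

require_group_n <- function(x, groups, n = 2L) {
  tab <- table(x$groups)
  for (g in groups) {
    if (!g %in% names(tab))
      stop("design error: group '", g, "' absent from table", call. = FALSE)
    if (tab[[g]] < n)
      stop("design error: group '", g, "' has fewer than ", n, " samples",
           call. = FALSE)
  }
  invisible(x)
}

#' Construct an isotopologue peak-area table
#'
#' Long-format records of (metabolite, mass shift, sample, peak area) from a
#' stable-isotope labeling experiment, e.g. [U-13C]glucose tracing. The mass
#' shift k of an isotopologue M+k counts labeled carbons and must satisfy
#' 0 <= k <= n_carbons(metabolite).
#'
#' @param records data.frame with columns `metabolite`, `mass_shift`,
#'   `sample`, `area` (one row per combination; areas >= 0).
#' @param n_carbons named integer vector, carbon count per metabolite. If
#'   omitted, the maximum observed mass shift per metabolite is used.
#' @param groups optional named character vector mapping sample id to group.
#' @return data.frame of class `isotopologue_table` with attributes
#'   `n_carbons` and `groups`.
#' @export
isotopologue_table <- function(records, n_carbons = NULL, groups = NULL) {
  need <- c("metabolite", "mass_shift", "sample", "area")
  if (!all(need %in% names(records)))
    stop("schema error: isotopologue records need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  records <- as.data.frame(records)[need]
  records$metabolite <- as.character(records$metabolite)
  records$sample <- as.character(records$sample)
  records$mass_shift <- parse_mass_shift(records$mass_shift)
  if (any(!is.finite(records$mass_shift)) || any(records$mass_shift < 0))
    stop("schema error: mass_shift must be a non-negative integer or 'M<k>'",
         call. = FALSE)
  if (any(records$area < 0, na.rm = TRUE))
    stop("validation error: negative peak areas", call. = FALSE)
  if (anyDuplicated(records[c("metabolite", "mass_shift", "sample")]))
    stop("schema error: duplicated (metabolite, mass_shift, sample) record",
         call. = FALSE)
  if (is.null(n_carbons)) {
    n_carbons <- tapply(records$mass_shift, records$metabolite, max)
    n_carbons <- setNames(as.integer(pmax(n_carbons, 1L)), names(n_carbons))
  }
  bad <- setdiff(unique(records$metabolite), names(n_carbons))
  if (length(bad))
    stop("schema error: no carbon count for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  over <- records$mass_shift > n_carbons[records$metabolite]
  if (any(over))
    stop("validation error: mass shift exceeds carbon count for ",
         paste(unique(records$metabolite[over]), collapse = ", "),
         call. = FALSE)
  if (!is.null(groups)) {
    groups <- validate_design(groups, unique(records$sample))
  }
  structure(records, class = c("isotopologue_table", "data.frame"),
            n_carbons = n_carbons, groups = groups)
}

parse_mass_shift <- function(k) {
  if (is.character(k) || is.factor(k)) {
    k <- as.character(k)
    k <- sub("^[Mm]\\+?", "", k)
  }
  suppressWarnings(as.integer(k))
}

#' Read a delimited table with its group design
#'
#' Reads peak, gene or isotopologue tables from CSV/TSV (delimiter chosen by
#' file extension; a header row is mandatory) and attaches the sample-group
#' design. Empty cells and `NA` are kept as missing values.
#'
#' Wide tables (`kind` "peak" or "gene") use the first column as analyte id;
#' a column named `retention_time` (peak tables) is treated as metadata, all
#' other columns as samples. Isotopologue tables are long format with columns
#' `metabolite`, `mass_shift`, `sample`, `area`.
#'
#' @param path table file (.csv or .tsv).
#' @param kind one of "peak", "gene", "isotopologue".
#' @param design path to a two-column delimited file (sample_id, group), or a
#'   named character vector. Optional for isotopologue tables.
#' @param n_carbons optional named integer vector for isotopologue tables.
#' @return a [peak_table()], [gene_table()] or [isotopologue_table()].
#' @export
read_table <- function(path, kind = c("peak", "gene", "isotopologue"),
                       design = NULL, n_carbons = NULL) {
  kind <- match.arg(kind)
  df <- read_delimited(path)
  groups <- if (is.character(design) && length(design) == 1L && file.exists(design))
    read_design(design) else design
  if (kind == "isotopologue")
    return(isotopologue_table(df, n_carbons = n_carbons, groups = groups))
  if (is.null(groups))
    stop("design error: a design is required for peak/gene tables", call. = FALSE)
  ids <- as.character(df[[1]])
  df <- df[-1]
  rt <- NULL
  rt_col <- match("retention_time", tolower(names(df)))
  if (!is.na(rt_col)) {
    rt <- setNames(as.numeric(df[[rt_col]]), ids)
    df <- df[-rt_col]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, names(df))
  if (kind == "peak") peak_table(m, groups, retention_time = rt)
  else gene_table(m, groups)
}

#' Read a two-column sample-to-group design file
#' @param path delimited file whose first two columns are sample id and group.
#' @return named character vector (group, named by sample id).
#' @export
read_design <- function(path) {
  df <- read_delimited(path)
  if (ncol(df) < 2)
    stop("design error: design file needs columns sample_id, group", call. = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    comment.char = "")
}

#' Write a result collection to CSV and support exact round trips
#'
#' All result collections in this package are data.frames; they are written
#' as plain CSV with one header line, at full double precision so that
#' `read_results(write_results(x))` reproduces `x` field for field.
#'
#' @param records data.frame of results.
#' @param path output file.
#' @param empty_ok allow writing a zero-row collection.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, empty_ok = FALSE) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L && !empty_ok)
    stop("validation error: refusing to write an empty result collection ",
         "(set empty_ok = TRUE to allow)", call. = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    utils::write.csv(format_full_precision(records), path, row.names = FALSE,
                     quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error: cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA_character_
      df[[j]] <- s
    }
  }
  df
}

#' Read back a result collection written by [write_results()]
#' @param path CSV file produced by [write_results()].
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read_delimited(path)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (!anyNA(num[!is.na(df[[j]])])) df[[j]] <- num
    }
  }
  df
}
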