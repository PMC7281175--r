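#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file path) with sections:
#'
#' * `input`: either `peaks` + `design` (file paths) or `synthetic` (a list
#'   of [synthetic_spec()] arguments)
#' * `preprocess`: `quantile_cut` (default 0), `internal_standard_id`
#'   (optional), `impute` ("half_min"/"none")
#' * `differential`: `alpha` (default 0.05), `test` ("student"/"welch"),
#'   `mode` ("metabolite"/"gene"), `fc_low`, `fc_high`
#' * `pattern`: `groups` (trio, default W/P/T)
#' * `enrich`: `pathways` ("builtin" or a GMT file path), `members`
#' * `seed`, `out_dir`
#'
#' Unknown keys at either level are rejected; all values are checked before
#' any stage runs.
#'
#' @param config named list or YAML file path.
#' @return the normalized config (class `run_config`), invisibly usable by
#'   [run_pipeline()].
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("validation error: reading YAML configs requires the yaml package",
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("validation error: config must be a list or YAML path", call. = FALSE)
  known <- c("input", "preprocess", "differential", "pattern", "enrich",
             "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sub_known <- list(
    input = c("peaks", "design", "synthetic"),
    preprocess = c("quantile_cut", "internal_standard_id", "impute"),
    differential = c("alpha", "test", "mode", "fc_low", "fc_high"),
    pattern = c("groups"),
    enrich = c("pathways", "members"))
  for (sec in names(sub_known)) {
    unknown <- setdiff(names(config[[sec]]), sub_known[[sec]])
    if (length(unknown))
      stop("validation error: unknown key(s) in '", sec, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- config$differential
  alpha <- d$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("validation error: differential.alpha must lie in (0, 1)",
         call. = FALSE)
  qc <- config$preprocess$quantile_cut %||% 0
  if (!is.numeric(qc) || qc < 0 || qc >= 1)
    stop("validation error: preprocess.quantile_cut must lie in [0, 1)",
         call. = FALSE)
  if (is.null(config$input$peaks) && is.null(config$input$synthetic))
    stop("validation error: input needs either peaks/design paths or a synthetic spec",
         call. = FALSE)
  config$differential$alpha <- alpha
  config$preprocess$quantile_cut <- qc
  config$seed <- config$seed %||% 1L
  structure(config, class = c("run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full peak-table analysis pipeline
#'
#' Wires the stages end to end: load (or synthesize) the peak table ->
#' IQR denoising -> optional internal-standard normalization -> imputation
#' -> three pairwise differential comparisons -> DEM calling -> trajectory
#' pattern classification -> pathway over-representation of the DEM list
#' against the denoised universe. Writes per-stage CSVs and a JSON run
#' report with full provenance (package version, seed, parameters,
#' per-stage record counts). Deterministic for a fixed config and seed.
#'
#' @param config a config list/path accepted by [validate_config()].
#' @return the run report (list), invisibly; side effect: files under
#'   `out_dir` (`denoised.csv`, `dem_calls.csv`, `pattern_calls.csv`,
#'   `pattern_counts.csv`, `enrichment.csv`, `report.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir %||% tempfile("trajmet_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  truth <- NULL
  if (!is.null(config$input$synthetic)) {
    spec <- do.call(synthetic_spec, c(config$input$synthetic,
                                      list(seed = config$seed)))
    sim <- generate_peak_table(spec)
    table <- sim$table
    truth <- sim$truth
  } else {
    table <- read_table(config$input$peaks, kind = "peak",
                        design = config$input$design)
  }

  den <- iqr_denoise(table, quantile_cut = config$preprocess$quantile_cut)
  table <- den$table
  if (!is.null(config$preprocess$internal_standard_id))
    table <- normalize_internal_standard(
      table, config$preprocess$internal_standard_id)
  table <- impute_missing(table, config$preprocess$impute %||% "half_min")

  groups <- config$pattern$groups %||% c("W", "P", "T")
  criteria <- dem_criteria(alpha = config$differential$alpha,
                           fc_low = config$differential$fc_low %||% 0.67,
                           fc_high = config$differential$fc_high %||% 1.5)
  test <- config$differential$test %||% "student"
  mode <- config$differential$mode %||% "metabolite"

  cls <- classify_peaks(table, groups = groups, criteria = criteria,
                        test = test)
  report_fc <- fold_change_report(table, groups = groups,
                                  criteria = criteria, test = test)
  cmp <- attr(report_fc, "comparisons")
  dem <- unique(unlist(lapply(cmp, function(r)
    call_dem(r, criteria, mode = mode)$analyte_id)))

  pathways <- config$enrich$pathways %||% "builtin"
  pw <- if (identical(pathways, "builtin")) builtin_pathways()
        else read_gmt(pathways)
  enr <- if (length(dem))
    enrich(dem, universe = rownames(table$intensities), pathways = pw,
           members = config$enrich$members %||% "both")
  else NULL

  write_results(report_fc, file.path(out_dir, "fold_change_report.csv"))
  write_results(cls$calls, file.path(out_dir, "pattern_calls.csv"))
  write_results(cls$counts, file.path(out_dir, "pattern_counts.csv"),
                empty_ok = TRUE)
  write_results(data.frame(analyte_id = dem, stringsAsFactors = FALSE),
                file.path(out_dir, "dem_calls.csv"), empty_ok = TRUE)
  if (!is.null(enr))
    write_results(enr, file.path(out_dir, "enrichment.csv"))
  if (!is.null(truth))
    write_results(truth, file.path(out_dir, "truth.csv"))

  report <- list(
    provenance = list(
      package = "trajmet",
      version = as.character(utils::packageVersion("trajmet")),
      seed = config$seed,
      alpha = criteria$alpha, test = test, mode = mode,
      quantile_cut = config$preprocess$quantile_cut,
      groups = groups),
    denoise = list(n_input_peaks = den$report$n_input_peaks,
                   n_retained = den$report$n_retained,
                   threshold_used = den$report$threshold_used),
    counts = list(
      analytes_tested = nrow(table$intensities),
      dem_called = length(dem),
      classified = sum(cls$calls$category != "unclassified"),
      unclassified = sum(cls$calls$category == "unclassified"),
      by_category = as.list(table(cls$calls$category))),
    outputs = list(dir = out_dir))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
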