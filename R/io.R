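#' Read a predictor score table
#'
#' Reads a TSV or CSV score table (the dialect is sniffed from the
#' header line) and validates it into typed records.  Screen mode
#' requires `target_id, ligand_id, role, dg_pred`; accuracy mode
#' requires `target_id, ligand_id, dg_calc` (or `dg_pred`) plus either
#' `dg_exp` or `affinity_molar` with `affinity_type` (Kd/Ki), in which
#' case the experimental dG is derived via [kd_to_dg()].
#'
#' @param path Path to the table.
#' @param mode `"screen"` or `"accuracy"`.
#' @param temperature Kelvin, used when converting molar affinities.
#' @return Validated data frame of records.
#' @export
read_score_table <- function(path, mode = c("screen", "accuracy"),
                             temperature = 298) {
  mode <- match.arg(mode)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header))))
    "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (mode == "screen") {
    check_numeric_col(raw, "dg_pred", path)
    return(validate_screen_records(raw))
  }
  if (!"dg_calc" %in% names(raw) && "dg_pred" %in% names(raw))
    raw$dg_calc <- raw$dg_pred
  if (!all(c("target_id", "ligand_id", "dg_calc") %in% names(raw)))
    stop("accuracy table needs target_id, ligand_id and ",
         "dg_calc/dg_pred columns", call. = FALSE)
  check_numeric_col(raw, "dg_calc", path)
  if (!"dg_exp" %in% names(raw)) {
    if (!all(c("affinity_molar", "affinity_type") %in% names(raw)))
      stop("accuracy table needs dg_exp or affinity_molar + ",
           "affinity_type columns", call. = FALSE)
    bad <- !raw$affinity_type %in% c("Kd", "Ki")
    if (any(bad))
      stop("unsupported affinity_type: ",
           paste(unique(raw$affinity_type[bad]), collapse = ", "),
           call. = FALSE)
    raw$dg_exp <- kd_to_dg(raw$affinity_molar, temperature)
  }
  check_numeric_col(raw, "dg_exp", path)
  dg <- c(raw$dg_exp, raw$dg_calc)
  if (mean(dg > 0) > 0.05)
    warning("more than 5% of dG values are positive; check the sign ",
            "convention (binding free energies should be negative)")
  validate_affinity_pairs(raw)
}

check_numeric_col <- function(df, col, path) {
  if (!col %in% names(df))
    stop("'", path, "' is missing column ", col, call. = FALSE)
  v <- suppressWarnings(as.numeric(df[[col]]))
  if (anyNA(v)) {
    row <- which(is.na(v))[1L]
    stop("non-numeric ", col, " at data row ", row, " of '", path, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a SMILES file
#'
#' One molecule per line, `SMILES<TAB>ligand_id`; an id-less line gets a
#' positional id.
#'
#' @param path Path to the SMILES file.
#' @return Named character vector of SMILES.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  smi <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]]
    else paste0("mol", i), "")
  stats::setNames(smi, ids)
}

report_schema_version <- "1.0"

as_report_body <- function(report) {
  if (inherits(report, "enrichment_report")) {
    p <- report$pooled
    body <- list(
      per_target = lapply(report$per_target, function(s)
        list(n = s$n_drawn, k = s$k_true, tpr = s$tpr)),
      pooled = list(N_tot = p$population_size, N_pos = p$n_actives,
                    n = p$n_drawn, k = p$k_observed,
                    tpr = report$pooled_tpr, pmf = report$pmf_at_k,
                    upper_tail = report$upper_tail_at_k,
                    max_pmf = report$max_pmf,
                    random_expectation = report$random_expectation))
    if (!is.null(report$extrapolated_actives))
      body$extrapolation <- list(N2 = report$scaled$population_size,
                                 K2 = report$scaled$n_actives,
                                 n2 = report$scaled$n_drawn,
                                 k2 = report$extrapolated_actives)
    return(body)
  }
  report
}

#' Write an analysis report as self-describing JSON
#'
#' The file carries a schema version, the tool version, and a full echo
#' of the resolved configuration alongside the report body, so a report
#' can always be traced back to the options that produced it.
#'
#' @param report Report object (e.g. an [enrichment_report()]) or plain
#'   list.
#' @param path Output path.
#' @param config Named list of resolved configuration values to echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = list()) {
  payload <- list(schema_version = report_schema_version,
                  tool = "vstriage",
                  tool_version =
                    as.character(utils::packageVersion("vstriage")),
                  config = config,
                  report = as_report_body(report))
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    TRUE
  }, error = function(e)
    stop("cannot write report to '", path, "': ",
         conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path to the JSON report.
#' @return The parsed payload list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
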