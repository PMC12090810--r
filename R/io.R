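.infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a samples-by-features count table from TSV/CSV
#'
#' The first column holds sample IDs (or feature IDs with
#' `features_as_rows = TRUE`), the header row holds the other axis' IDs, and
#' all remaining cells are numeric. The delimiter is inferred from the file
#' extension (`.csv` -> comma, otherwise tab) and can be overridden.
#'
#' @param path File path.
#' @param unit `"counts"` or `"relative"`.
#' @param features_as_rows Set TRUE for transposed files (features x samples).
#' @param sep Optional delimiter override.
#' @return An `abundance_table`, always oriented samples x features.
#' @export
read_count_table <- function(path, unit = c("counts", "relative"),
                             features_as_rows = FALSE, sep = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- names(df)[-1][!vapply(df[-1], is.numeric, TRUE)][1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[badcol]]))))[1]
    stop(sprintf("non-numeric cell in column '%s' (data line %d)",
                 badcol, badrow))
  }
  rownames(m) <- ids
  if (features_as_rows) m <- t(m)
  abundance_table(m, unit = unit)
}

#' Write an abundance table as TSV/CSV
#'
#' Inverse of [read_count_table()]: first column `sample_id`, one column per
#' feature. Numbers are written at full double precision so the round trip is
#' lossless.
#'
#' @param table An `abundance_table`.
#' @param path Output path; delimiter inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  sep <- .infer_sep(path)
  df <- data.frame(sample_id = table$sample_ids,
                   table$values, check.names = FALSE)
  old <- options(digits = 17); on.exit(options(old))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phenotype labels as a two-column metadata file
#'
#' Companion fixture writer: emits `sample_id` and `phenotype` columns in the
#' layout [read_metadata()] reads, so pipeline round trips need no external
#' data.
#'
#' @param labels Named label vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  sep <- .infer_sep(path)
  utils::write.table(
    data.frame(sample_id = names(labels), phenotype = unname(labels)),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata with a binary phenotype
#'
#' Loads a TSV/CSV metadata file, validates the phenotype column (exactly two
#' levels unless `positive_level` explicitly binarizes a multi-level column
#' into that level vs the rest), and returns labels plus the optional
#' subject/timepoint columns needed by [filter_first_timepoint()].
#'
#' @param path File path.
#' @param sample_col,phenotype_col Required column names.
#' @param subject_col,timepoint_col Optional column names.
#' @param positive_level Optional level treated as the positive class; all
#'   other levels become `"other"`.
#' @param sep Optional delimiter override.
#' @return List with `labels` (named vector) and `metadata` (the data.frame).
#' @export
read_metadata <- function(path, sample_col = "sample_id",
                          phenotype_col = "phenotype",
                          subject_col = NULL, timepoint_col = NULL,
                          positive_level = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  need <- c(sample_col, phenotype_col, subject_col, timepoint_col)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  ids <- as.character(df[[sample_col]])
  if (anyDuplicated(ids))
    stop("duplicate sample ID(s) in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pheno <- as.character(df[[phenotype_col]])
  if (!is.null(positive_level)) {
    if (!positive_level %in% pheno)
      stop("positive level '", positive_level, "' not present in phenotype column")
    pheno <- ifelse(pheno == positive_level, positive_level, "other")
  } else if (length(unique(pheno)) != 2L) {
    stop("phenotype column has ", length(unique(pheno)),
         " levels; supply `positive_level` to binarize")
  }
  list(labels = stats::setNames(pheno, ids), metadata = df)
}

#' Read a contaminant-feature list
#'
#' Plain text, one feature ID per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of feature IDs.
#' @export
read_contaminant_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

# strip closures/classes so reports serialize cleanly
.jsonify <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(unclass(x), .jsonify)
    x[!vapply(x, is.null, TRUE)]
  } else x
}

#' Serialize an analysis report to JSON with provenance
#'
#' Writes any of the package's report objects (counterexample, reanalysis,
#' sweep, leakage audit) as JSON at full double precision, wrapped in a
#' provenance block recording the package version, timestamp, report class
#' and an optional seed. Sweep reports additionally get a companion TSV next
#' to the JSON.
#'
#' @param report A report object.
#' @param path Output `.json` path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  out <- list(
    provenance = list(
      package = "clrsparse",
      version = as.character(utils::packageVersion("clrsparse")),
      report_class = class(report)[1],
      seed = seed,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    report = .jsonify(report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  if (inherits(report, "sweep_report")) {
    tsv <- sub("\\.json$", ".tsv", path)
    if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
    old <- options(digits = 17); on.exit(options(old))
    utils::write.table(as.data.frame(report), tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back a serialized report
#'
#' @param path A `.json` file written by [write_report()].
#' @return List with `provenance` and `report`.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
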