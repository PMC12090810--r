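#' Construct a samples-by-features abundance table
#'
#' The basic container of the package: a nonnegative numeric matrix with
#' samples as rows and features (taxa, OTUs) as columns, carrying either raw
#' read counts or relative abundances. Row names are sample identifiers and
#' column names are feature identifiers; both must be unique.
#'
#' @param values Numeric matrix, samples x features, nonnegative, no missing
#'   values. Must have unique row and column names.
#' @param unit Either `"counts"` (raw reads) or `"relative"` (rows sum to 1).
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix), `unit`, `sample_ids` and `feature_ids`.
#' @examples
#' m <- matrix(c(2, 2, 4, 1, 0, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' tab <- abundance_table(m, unit = "counts")
#' @export
abundance_table <- function(values, unit = c("counts", "relative")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("abundance table contains missing or non-finite entries")
  if (any(values < 0))
    stop("abundance table contains negative entries")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample IDs as row names and feature IDs as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (unit == "relative") {
    rs <- rowSums(values)
    bad <- abs(rs - 1) > 1e-9
    if (any(bad))
      stop("relative-abundance rows must sum to 1; offending samples: ",
           paste(utils::head(rownames(values)[bad], 5), collapse = ", "))
  }
  structure(
    list(values = values, unit = unit,
         sample_ids = rownames(values), feature_ids = colnames(values)),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d features, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Construct a strictly positive composition table
#'
#' Wraps a post-pseudocount matrix: every entry strictly positive, ready for
#' the CLR transform. Usually produced by [add_pseudocount()] rather than
#' called directly.
#'
#' @param values Strictly positive numeric matrix with sample and feature IDs
#'   as dimnames.
#' @param pseudocount The positive pseudocount that was applied.
#' @param pseudocount_mode `"relative_space"` (added after normalization) or
#'   `"count_space"` (added to counts before normalization).
#' @return An object of class `positive_composition`.
#' @export
positive_composition <- function(values, pseudocount,
                                 pseudocount_mode = c("relative_space", "count_space")) {
  pseudocount_mode <- match.arg(pseudocount_mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("`pseudocount` must be a single positive number")
  nonpos <- which(values <= 0, arr.ind = TRUE)
  if (nrow(nonpos) > 0)
    stop(sprintf("non-positive entry at sample '%s', feature '%s'",
                 rownames(values)[nonpos[1, 1]], colnames(values)[nonpos[1, 2]]))
  structure(
    list(values = values, pseudocount = pseudocount,
         pseudocount_mode = pseudocount_mode,
         sample_ids = rownames(values), feature_ids = colnames(values)),
    class = "positive_composition"
  )
}

#' @export
print.positive_composition <- function(x, ...) {
  cat(sprintf("<positive_composition> %d samples x %d features, pseudocount = %g (%s)\n",
              nrow(x$values), ncol(x$values), x$pseudocount, x$pseudocount_mode))
  invisible(x)
}

#' Validate a set of binary phenotype labels against a table
#'
#' Labels are a named character (or factor) vector mapping sample ID to one of
#' exactly two group levels. This helper checks the mapping covers exactly the
#' table's samples and returns the labels as a named character vector ordered
#' like the table rows.
#'
#' @param labels Named vector, names = sample IDs, values = group labels
#'   (exactly two distinct values).
#' @param table An `abundance_table` the labels must cover.
#' @return Named character vector aligned to `table$sample_ids`.
#' @export
validate_labels <- function(labels, table) {
  if (is.null(names(labels)))
    stop("labels must be named by sample ID")
  labels <- stats::setNames(as.character(labels), names(labels))
  missing <- setdiff(table$sample_ids, names(labels))
  if (length(missing) > 0)
    stop("samples missing from labels: ", paste(utils::head(missing, 5), collapse = ", "))
  extra <- setdiff(names(labels), table$sample_ids)
  if (length(extra) > 0)
    message("ignoring ", length(extra),
            " label(s) for samples not in the table")
  labels <- labels[table$sample_ids]
  if (length(unique(labels)) != 2L)
    stop("labels must have exactly two distinct levels, got ",
         length(unique(labels)))
  labels
}
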