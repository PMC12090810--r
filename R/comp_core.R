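#' Normalize a count table to relative abundances
#'
#' Divides each row by its sum so that every sample composition sums to 1.
#' Sequencing totals are arbitrary, so counts are interpreted as compositions;
#' this is the closure step of compositional data analysis.
#'
#' @param table An `abundance_table` with `unit = "counts"`.
#' @return An `abundance_table` with `unit = "relative"`, same dimensions and
#'   identifiers.
#' @examples
#' m <- matrix(c(2, 2, 4), nrow = 1, dimnames = list("s1", c("a", "b", "c")))
#' to_relative_abundance(abundance_table(m, "counts"))$values
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$unit != "counts")
    stop("`table` is already in relative-abundance units")
  rs <- rowSums(table$values)
  empty <- rs == 0
  if (any(empty))
    stop("sample(s) with zero total: ",
         paste(utils::head(table$sample_ids[empty], 5), collapse = ", "))
  abundance_table(table$values / rs, unit = "relative")
}

#' Default pseudocount: the largest power of ten below the smallest positive value
#'
#' Returns 10^k for the largest integer k such that 10^k is strictly below the
#' smallest strictly positive entry of the table. When that minimum is itself a
#' power of ten, the strict inequality forces the next power down (1e-3 maps to
#' 1e-4). On the default simulation counterexample this rule yields 1e-6.
#'
#' @param table An `abundance_table` in relative-abundance units (the rule is
#'   stated on relative abundances).
#' @return A single positive number, an exact power of ten.
#' @export
default_pseudocount <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  pos <- table$values[table$values > 0]
  if (length(pos) == 0)
    stop("table has no positive entries; cannot derive a pseudocount")
  m <- min(pos)
  k <- floor(log10(m))
  # guard against the minimum being an exact power of ten (strict "below")
  # and against floating-point log10 landing on the wrong side
  if (10^k >= m) k <- k - 1
  if (10^(k + 1) < m) k <- k + 1
  10^k
}

#' Add a pseudocount so that zeros become log-safe
#'
#' Two placements are supported. `relative_space` adds the constant to an
#' already-normalized table and does not renormalize: the CLR transform is
#' invariant to row rescaling, so renormalization is immaterial.
#' `count_space` adds the constant to raw counts and then normalizes; this
#' placement makes the resulting relative abundances of sparse features depend
#' on sequencing depth.
#'
#' @param table An `abundance_table`; `relative_space` requires
#'   `unit = "relative"`, `count_space` requires `unit = "counts"`.
#' @param c Positive pseudocount.
#' @param mode `"relative_space"` or `"count_space"`.
#' @return A `positive_composition`.
#' @export
add_pseudocount <- function(table, c,
                            mode = c("relative_space", "count_space")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("pseudocount `c` must be a single positive number")
  if (mode == "relative_space") {
    if (table$unit != "relative")
      stop("relative_space pseudocount requires a relative-abundance table")
    positive_composition(table$values + c, pseudocount = c,
                         pseudocount_mode = "relative_space")
  } else {
    if (table$unit != "counts")
      stop("count_space pseudocount requires a count table")
    rel <- to_relative_abundance(
      abundance_table(table$values + c, unit = "counts"))
    positive_composition(rel$values, pseudocount = c,
                         pseudocount_mode = "count_space")
  }
}

#' Centered log-ratio transform
#'
#' For each sample (row) x with D features, clr_j = ln(x_j) - mean_k ln(x_k),
#' i.e. the log of each component relative to the sample's geometric mean.
#' Rows of the result sum to zero, and the transform is invariant to rescaling
#' a row by any positive constant. A feature holding the constant pseudocount
#' c in a sample therefore maps to ln(c) - ln(g), where g is that sample's
#' geometric mean: the mechanism by which an empty feature inherits a
#' sample-wide signal.
#'
#' @param table A `positive_composition` (all entries strictly positive).
#' @return An object of class `clr_table`: list with `values`, `sample_ids`,
#'   `feature_ids`.
#' @export
clr_transform <- function(table) {
  stopifnot(inherits(table, "positive_composition"))
  v <- table$values
  nonpos <- which(v <= 0, arr.ind = TRUE)
  if (nrow(nonpos) > 0)
    stop(sprintf("non-positive entry at sample '%s', feature '%s'",
                 rownames(v)[nonpos[1, 1]], colnames(v)[nonpos[1, 2]]))
  if (ncol(v) == 1L)
    warning("CLR of a single-feature composition is identically zero")
  lv <- log(v)
  structure(
    list(values = lv - rowMeans(lv),
         sample_ids = rownames(v), feature_ids = colnames(v)),
    class = "clr_table"
  )
}

#' @export
print.clr_table <- function(x, ...) {
  cat(sprintf("<clr_table> %d samples x %d features (rows sum to 0)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Geometric mean of a strictly positive vector
#'
#' exp of the arithmetic mean of natural logs, over ALL entries — including
#' features that only hold a pseudocount, which is exactly why sparse samples
#' drag the geometric mean down.
#'
#' @param row Strictly positive numeric vector.
#' @return A single positive number.
#' @export
geometric_mean <- function(row) {
  if (!is.numeric(row) || length(row) == 0)
    stop("`row` must be a non-empty numeric vector")
  if (any(!is.finite(row)) || any(row <= 0))
    stop("geometric mean requires strictly positive finite entries")
  exp(mean(log(row)))
}

#' Per-sample geometric means of a positive composition
#'
#' @param table A `positive_composition` (or strictly positive matrix).
#' @return Named numeric vector, one geometric mean per sample.
#' @export
geometric_means <- function(table) {
  v <- if (inherits(table, "positive_composition")) table$values else table
  if (any(v <= 0)) stop("geometric means require strictly positive entries")
  stats::setNames(exp(rowMeans(log(v))), rownames(v))
}

.check_rel_row <- function(row) {
  if (!is.numeric(row) || length(row) == 0)
    stop("`row` must be a non-empty numeric vector")
  if (any(row < 0)) stop("relative abundances cannot be negative")
  if (abs(sum(row) - 1) > 1e-6)
    stop(sprintf("relative-abundance row must sum to 1 (got %.8f)", sum(row)))
}

#' Shannon alpha diversity of one relative-abundance composition
#'
#' H = -sum p_j ln p_j (natural log, with 0 ln 0 = 0). Exactly equal to
#' -ln of the abundance-weighted geometric mean of the same composition, which
#' is the identity connecting alpha diversity to the geometric mean that CLR
#' divides by.
#'
#' @param row Nonnegative numeric vector summing to 1 (within 1e-6).
#' @return Nonnegative number in natural-log units (nats).
#' @examples
#' shannon_diversity(rep(0.25, 4))  # ln 4
#' @export
shannon_diversity <- function(row) {
  .check_rel_row(row)
  p <- row[row > 0]
  -sum(p * log(p))
}

#' Abundance-weighted geometric mean of a composition
#'
#' prod p_j ^ p_j over positive entries; equals exp(-H) where H is the Shannon
#' diversity of the same composition.
#'
#' @param row Nonnegative numeric vector summing to 1 (within 1e-6).
#' @return A number in (0, 1].
#' @export
weighted_geometric_mean <- function(row) {
  .check_rel_row(row)
  p <- row[row > 0]
  exp(sum(p * log(p)))
}

#' Per-sample Shannon diversities of a relative-abundance table
#'
#' @param table An `abundance_table` with `unit = "relative"`.
#' @return Named numeric vector of diversities (nats).
#' @export
shannon_diversities <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$unit != "relative")
    stop("Shannon diversity is defined on relative abundances; normalize first")
  apply(table$values, 1, shannon_diversity)
}
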