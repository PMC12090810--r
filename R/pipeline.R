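#' Run the empty-feature counterexample experiment end to end
#'
#' Generates the simulated data set, resolves the pseudocount (the
#' power-of-ten rule when `"auto"`), adds it in relative-abundance space,
#' computes each sample's post-pseudocount geometric mean over all features,
#' applies the CLR transform, and compares both the geometric means and the
#' CLR values of the designated sparse feature between the phenotype groups
#' with two-sided Mann-Whitney U tests.
#'
#' @param config A [simulation_config()].
#' @return A list of class `counterexample_report`: `geometric_mean_summary`,
#'   `clr_sparse_summary` (per-group median/min/max), `mw_geomean`,
#'   `mw_clr_sparse` (association results), `pseudocount_used`, `config`.
#' @examples
#' rep <- run_counterexample_experiment(simulation_config(seed = 1))
#' rep$mw_clr_sparse$p_value  # < 1e-12
#' @export
run_counterexample_experiment <- function(config = simulation_config()) {
  ds <- simulate_counterexample(config)
  c_use <- if (identical(config$pseudocount, "auto"))
    default_pseudocount(ds$table) else config$pseudocount
  comp <- add_pseudocount(ds$table, c_use, mode = "relative_space")
  g <- geometric_means(comp)
  clr <- clr_transform(comp)
  sparse <- clr$values[, ds$sparse_feature_id]
  pos <- ds$labels == "positive"
  mw_g <- mann_whitney_u(g[pos], g[!pos], labels_ab = c("positive", "negative"))
  mw_s <- mann_whitney_u(sparse[pos], sparse[!pos],
                         labels_ab = c("positive", "negative"))
  structure(list(
    geometric_mean_summary = mw_g$group_summaries,
    clr_sparse_summary = mw_s$group_summaries,
    mw_geomean = mw_g, mw_clr_sparse = mw_s,
    pseudocount_used = c_use, config = config),
    class = "counterexample_report")
}

#' @export
print.counterexample_report <- function(x, ...) {
  cat("<counterexample_report>\n  pseudocount:", format(x$pseudocount_used), "\n")
  cat("  geometric means: "); print(x$mw_geomean)
  cat("  CLR of sparse feature: "); print(x$mw_clr_sparse)
  invisible(x)
}

#' Pseudocount sensitivity sweep
#'
#' Re-runs pseudocount addition + CLR + Mann-Whitney on a fixed data set for
#' each pseudocount in a grid (default: all powers of ten from 1e-8 to 0.01),
#' isolating the effect of the pseudocount choice. A pseudocount at or above
#' the data's smallest positive entry is still computed but flagged with a
#' warning column.
#'
#' @param dataset A `labeled_dataset` whose table is in relative-abundance
#'   units.
#' @param target_feature Feature ID to test against the labels.
#' @param pseudocounts Strictly increasing vector of positive pseudocounts.
#' @return A data.frame of class `sweep_report` with columns `pseudocount`,
#'   `statistic`, `p_value`, `exceeds_data_scale`.
#' @export
run_pseudocount_sweep <- function(dataset, target_feature,
                                  pseudocounts = 10^seq(-8, -2)) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tab <- dataset$table
  if (tab$unit != "relative")
    stop("sweep expects a relative-abundance table")
  if (!target_feature %in% tab$feature_ids)
    stop("unknown target feature: ", target_feature)
  if (any(pseudocounts <= 0) || is.unsorted(pseudocounts, strictly = TRUE))
    stop("`pseudocounts` must be positive and strictly increasing")
  labels <- validate_labels(dataset$labels, tab)
  lv <- sort(unique(labels))
  min_pos <- min(tab$values[tab$values > 0])
  rows <- lapply(pseudocounts, function(c_) {
    exceeds <- c_ >= min_pos
    if (exceeds)
      warning(sprintf("pseudocount %g exceeds the smallest positive entry %g",
                      c_, min_pos))
    clr <- clr_transform(add_pseudocount(tab, c_, mode = "relative_space"))
    v <- clr$values[, target_feature]
    mw <- mann_whitney_u(v[labels == lv[1]], v[labels == lv[2]], labels_ab = lv)
    data.frame(pseudocount = c_, statistic = mw$statistic,
               p_value = mw$p_value, exceeds_data_scale = exceeds)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_report", "data.frame")
  out
}

#' Keep only the first sample collected from each subject
#'
#' For longitudinal designs: selects, per subject, the sample with the
#' minimum timepoint; ties on the timepoint are broken by the
#' lexicographically smallest sample ID.
#'
#' @param metadata A data.frame.
#' @param sample_col,subject_col,timepoint_col Column names.
#' @return Character vector of retained sample IDs.
#' @export
filter_first_timepoint <- function(metadata, sample_col = "sample_id",
                                   subject_col = "subject",
                                   timepoint_col = "timepoint") {
  need <- c(sample_col, subject_col, timepoint_col)
  missing <- setdiff(need, names(metadata))
  if (length(missing) > 0)
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  picked <- vapply(split(metadata, as.character(metadata[[subject_col]])),
                   function(d) {
                     d <- d[d[[timepoint_col]] == min(d[[timepoint_col]]), ]
                     sort(as.character(d[[sample_col]]))[1]
                   }, character(1))
  unname(picked)
}

#' Drop taxa never observed in any sample
#'
#' Removes all-zero feature columns from a count table, preserving the order
#' of the remaining features.
#'
#' @param table An `abundance_table` with `unit = "counts"`.
#' @return An `abundance_table` with the observed taxa only.
#' @export
filter_observed_taxa <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$unit != "counts")
    stop("observed-taxa filtering operates on count tables")
  keep <- colSums(table$values) > 0
  if (!any(keep)) stop("no taxa observed in any sample")
  abundance_table(table$values[, keep, drop = FALSE], unit = table$unit)
}

#' Remove features flagged as contaminants
#'
#' Drops the listed feature columns; IDs not present in the table are
#' reported with a message and ignored.
#'
#' @param table An `abundance_table`.
#' @param contaminant_ids Character vector of feature IDs to drop.
#' @return An `abundance_table` without the listed features.
#' @export
remove_contaminants <- function(table, contaminant_ids) {
  stopifnot(inherits(table, "abundance_table"))
  contaminant_ids <- unique(as.character(contaminant_ids))
  if (length(contaminant_ids) == 0) return(table)
  unknown <- setdiff(contaminant_ids, table$feature_ids)
  if (length(unknown) > 0)
    message("ignoring ", length(unknown), " contaminant ID(s) not in table: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  keep <- !(table$feature_ids %in% contaminant_ids)
  if (!any(keep))
    stop("contaminant removal would leave no features")
  abundance_table(table$values[, keep, drop = FALSE], unit = table$unit)
}

#' The sparse-feature reanalysis chain
#'
#' The full analysis applied to real case/control count data: remove
#' contaminants; normalize to relative abundance; compute per-sample Shannon
#' diversity (on pre-pseudocount relative abundances); test diversity vs
#' labels (Mann-Whitney); test the target taxon's raw relative abundance vs
#' labels; add a pseudocount (`"auto"` resolves to the power-of-ten rule in
#' relative space, and to 1 in count space); CLR-transform; correlate the
#' taxon's CLR values with Shannon diversity (Pearson); and test the taxon's
#' CLR values vs labels. No label information enters any transformation
#' stage — labels are used only in the association tests.
#'
#' @param table An `abundance_table`; raw counts are normalized first, an
#'   already-relative table is used as-is (count-space pseudocounts then
#'   being unavailable).
#' @param labels Named binary labels covering the table's samples.
#' @param taxon_id Feature to track through the chain (typically a sparse
#'   taxon).
#' @param contaminant_ids Feature IDs to drop first (default none).
#' @param pseudocount_mode `"relative_space"` or `"count_space"`.
#' @param pseudocount Positive number or `"auto"`.
#' @return A list of class `reanalysis_report` with the four association
#'   results (`diversity_vs_label`, `raw_ra_vs_label`, `clr_vs_diversity`,
#'   `clr_vs_label`), plus `taxon_id`, `n_samples`,
#'   `n_features_after_filter`, `pseudocount_used`.
#' @export
run_sparse_feature_reanalysis <- function(table, labels, taxon_id,
                                          contaminant_ids = character(),
                                          pseudocount_mode = c("relative_space",
                                                               "count_space"),
                                          pseudocount = "auto") {
  pseudocount_mode <- match.arg(pseudocount_mode)
  stopifnot(inherits(table, "abundance_table"))
  counts <- remove_contaminants(table, contaminant_ids)
  if (!taxon_id %in% counts$feature_ids)
    stop("taxon '", taxon_id, "' absent after contaminant removal")
  labels <- validate_labels(labels, counts)
  lv <- sort(unique(labels))
  ga <- labels == lv[1]
  if (sum(ga) == 0 || sum(!ga) == 0) stop("both label groups must be nonempty")

  if (pseudocount_mode == "count_space" && counts$unit != "counts")
    stop("count_space pseudocounts require a raw count table")
  rel <- if (counts$unit == "counts") to_relative_abundance(counts) else counts
  H <- shannon_diversities(rel)
  mw_div <- mann_whitney_u(H[ga], H[!ga], labels_ab = lv)
  ra <- rel$values[, taxon_id]
  mw_ra <- mann_whitney_u(ra[ga], ra[!ga], labels_ab = lv)

  if (pseudocount_mode == "relative_space") {
    c_use <- if (identical(pseudocount, "auto")) default_pseudocount(rel)
             else pseudocount
    comp <- add_pseudocount(rel, c_use, mode = "relative_space")
  } else {
    c_use <- if (identical(pseudocount, "auto")) 1 else pseudocount
    comp <- add_pseudocount(counts, c_use, mode = "count_space")
  }
  clr <- clr_transform(comp)
  cv <- clr$values[, taxon_id]
  cor_div <- pearson_r(cv, H)
  mw_clr <- mann_whitney_u(cv[ga], cv[!ga], labels_ab = lv)

  structure(list(diversity_vs_label = mw_div, raw_ra_vs_label = mw_ra,
                 clr_vs_diversity = cor_div, clr_vs_label = mw_clr,
                 taxon_id = taxon_id, n_samples = nrow(counts$values),
                 n_features_after_filter = ncol(counts$values),
                 pseudocount_used = c_use,
                 pseudocount_mode = pseudocount_mode),
            class = "reanalysis_report")
}

#' @export
print.reanalysis_report <- function(x, ...) {
  cat(sprintf("<reanalysis_report> taxon %s; %d samples x %d features; pseudocount %g (%s)\n",
              x$taxon_id, x$n_samples, x$n_features_after_filter,
              x$pseudocount_used, x$pseudocount_mode))
  cat("  diversity vs label:  "); print(x$diversity_vs_label)
  cat("  raw RA vs label:     "); print(x$raw_ra_vs_label)
  cat("  CLR vs diversity:    "); print(x$clr_vs_diversity)
  cat("  CLR vs label:        "); print(x$clr_vs_label)
  invisible(x)
}

#' Label-permutation audit for information leakage
#'
#' Runs a scoring pipeline on the true labels, then on `n_permutations`
#' label shuffles, where each shuffle happens BEFORE the pipeline sees
#' anything — normalization included — and reports the add-one-corrected
#' empirical p-value (1 + #\{permuted >= observed\}) / (1 + n). On
#' label-independent data a leak-free pipeline should give a uniform-ish p;
#' a small p flags `leakage_suspected`. When labels genuinely associate with
#' the data, a small p reflects real signal, not leakage — the verdict is
#' advisory, never auto-fatal.
#'
#' @param pipeline_fn Function `(table, labels) -> numeric score`,
#'   deterministic given its inputs.
#' @param table An `abundance_table`.
#' @param labels Named binary labels covering the table's samples.
#' @param n_permutations At least 19.
#' @param seed Integer seed for the shuffles.
#' @return A list of class `leakage_audit_report`: `observed_score`,
#'   `permuted_scores`, `empirical_p`, `n_permutations`, `verdict`.
#' @export
permutation_leakage_test <- function(pipeline_fn, table, labels,
                                     n_permutations = 99, seed = 1L) {
  stopifnot(is.function(pipeline_fn), inherits(table, "abundance_table"))
  if (n_permutations < 19) stop("use at least 19 permutations")
  labels <- validate_labels(labels, table)
  observed <- pipeline_fn(table, labels)
  if (!is.numeric(observed) || length(observed) != 1)
    stop("pipeline_fn must return a single numeric score")
  set.seed(seed)
  permuted <- vapply(seq_len(n_permutations), function(i) {
    shuffled <- stats::setNames(sample(unname(labels)), names(labels))
    pipeline_fn(table, shuffled)
  }, numeric(1))
  p <- (1 + sum(permuted >= observed)) / (1 + n_permutations)
  structure(list(observed_score = observed, permuted_scores = permuted,
                 empirical_p = p, n_permutations = n_permutations,
                 verdict = if (p <= 0.05) "leakage_suspected"
                           else "no_evidence_of_leakage"),
            class = "leakage_audit_report")
}

#' @export
print.leakage_audit_report <- function(x, ...) {
  cat(sprintf("<leakage_audit_report> observed %.4g; empirical p = %.4g over %d permutations -> %s\n",
              x$observed_score, x$empirical_p, x$n_permutations, x$verdict))
  invisible(x)
}
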