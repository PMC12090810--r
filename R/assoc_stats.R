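#' Per-group median and range
#'
#' The reporting style used throughout: per-group median with the min-max
#' range. Medians use the usual midpoint convention for even group sizes.
#'
#' @param values Numeric vector.
#' @param labels Vector of group labels, same length as `values` (exactly two
#'   levels, both nonempty).
#' @return Named list, one element per group level, each with `median`, `min`,
#'   `max`, `n`.
#' @export
group_summary <- function(values, labels) {
  if (length(values) != length(labels))
    stop("`values` and `labels` must have the same length")
  groups <- split(values, as.character(labels))
  if (any(vapply(groups, length, 0L) == 0))
    stop("every group must be nonempty")
  lapply(groups, function(v)
    list(median = stats::median(v), min = min(v), max = max(v),
         n = length(v)))
}

# U statistic for group a via midranks; ties handled by construction
.u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Exact two-sided Mann-Whitney p-value by enumeration
#'
#' Enumerates all C(n_a + n_b, n_a) assignments of the pooled values to the
#' two groups and returns the proportion whose U statistic is at least as far
#' from the null mean n_a n_b / 2 as the observed one. Used as the default
#' for small samples and as the independent oracle for the asymptotic path.
#' Ties are handled naturally because enumeration works on the observed
#' pooled values.
#'
#' @param a,b Numeric vectors (n_a + n_b must be small; enumeration is
#'   combinatorial).
#' @return List with `u` (observed U for group `a`) and `p_value`.
#' @export
mann_whitney_exact <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  if (na < 1 || nb < 1) stop("both groups must be nonempty")
  if (N > 20) stop("exact enumeration is limited to n_a + n_b <= 20")
  pooled <- c(a, b)
  u_obs <- .u_statistic(a, b)
  mu <- na * nb / 2
  idx <- utils::combn(N, na)
  us <- apply(idx, 2, function(ii) .u_statistic(pooled[ii], pooled[-ii]))
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p_value = p)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. For small pooled samples
#' (n_a + n_b <= 16) the p-value is computed by exhaustive enumeration over
#' all group assignments; otherwise by the normal approximation with midrank
#' tie correction and a continuity correction. If all pooled values are equal
#' the comparison is degenerate: p = 1 with a warning.
#'
#' @param a,b Numeric vectors, each nonempty.
#' @param labels_ab Optional length-2 character vector naming the groups in
#'   the summaries (defaults to `"a"`, `"b"`).
#' @param method `"auto"` (exact for n_a + n_b <= 16, asymptotic otherwise),
#'   or force `"exact"` / `"asymptotic"`.
#' @return An `association_result` list: `test`, `statistic` (U for group
#'   `a`), `p_value`, `n_group_a`, `n_group_b`, `group_summaries`,
#'   `direction` (sign of median(a) - median(b)), `method` ("exact" or
#'   "asymptotic").
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value  # exact: 1/3
#' @export
mann_whitney_u <- function(a, b, labels_ab = c("a", "b"),
                           method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (length(a) < 1 || length(b) < 1) stop("both groups must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  na <- length(a); nb <- length(b); N <- na + nb
  u <- .u_statistic(a, b)
  if (method == "auto") method <- if (N <= 16) "exact" else "asymptotic"
  if (length(unique(c(a, b))) == 1L) {
    warning("all pooled values identical; Mann-Whitney comparison is degenerate")
    p <- 1; method <- "degenerate"
  } else if (method == "exact") {
    p <- mann_whitney_exact(a, b)$p_value
  } else {
    mu <- na * nb / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      warning("zero rank variance; Mann-Whitney comparison is degenerate")
      p <- 1; method <- "degenerate"
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "asymptotic"
    }
  }
  gs <- group_summary(c(a, b), rep(labels_ab, c(na, nb)))
  structure(list(test = "mann_whitney_u", statistic = u, p_value = p,
                 n_group_a = na, n_group_b = nb,
                 group_summaries = gs[labels_ab],
                 direction = sign(stats::median(a) - stats::median(b)),
                 method = method),
            class = "association_result")
}

#' Pearson correlation with a two-sided t-test
#'
#' Sample Pearson correlation; the p-value comes from the t transform
#' R sqrt((n-2)/(1-R^2)) on n-2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3, both nonconstant.
#' @return An `association_result` with `test = "pearson"`, `statistic` = R,
#'   `p_value`, `n_pairs`, `direction` = sign(R).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(test = "pearson", statistic = r, p_value = ct$p.value,
                 n_pairs = length(x), direction = sign(r)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  if (x$test == "pearson") {
    cat(sprintf("<association_result> Pearson R = %.4g, p = %.3g (n = %d)\n",
                x$statistic, x$p_value, x$n_pairs))
  } else {
    cat(sprintf("<association_result> Mann-Whitney U = %g, p = %.3g (%s; n = %d vs %d)\n",
                x$statistic, x$p_value, x$method, x$n_group_a, x$n_group_b))
    for (g in names(x$group_summaries)) {
      s <- x$group_summaries[[g]]
      cat(sprintf("  %s: median %.4g [%.4g-%.4g], n = %d\n",
                  g, s$median, s$min, s$max, s$n))
    }
  }
  invisible(x)
}
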