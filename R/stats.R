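#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: centre `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`. Well-behaved at small `n`
#' and extreme proportions, and the interval that reproduces the published
#' accuracy tables this toolkit targets.
#'
#' @param k number of successes (correct responses).
#' @param n number of trials (evaluations), `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` in `[0, 1]`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (length(n) != 1 || n < 1) stop("`n` must be a single count >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("`k` must satisfy 0 <= k <= n", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - hw), upper = min(1, centre + hw))
}

#' Diagnostic accuracy of a group of raters
#'
#' Pools all non-missing cells of the selected raters: `k` correct out of
#' `n` evaluations, with a Wilson score interval. Evaluations are treated as
#' independent (no clustering by rater or case), matching the usual reader
#' study analysis; see the methods vignette for the implied limitation.
#'
#' @param matrix a [correctness_matrix()].
#' @param selector `"all"`, a group name, or a character vector of rater ids.
#' @param level confidence level.
#' @param label group label carried into the result (defaults to the
#'   selector).
#' @return a one-row data frame: group, k, n, p, lower, upper, level.
#' @export
accuracy <- function(matrix, selector = "all", level = 0.95, label = NULL) {
  groups <- matrix_groups(matrix)
  rows <- if (identical(selector, "all")) seq_len(nrow(matrix))
  else if (all(selector %in% groups)) which(groups %in% selector)
  else if (all(selector %in% rownames(matrix))) which(rownames(matrix) %in% selector)
  else stop("`selector` matches no group or rater id", call. = FALSE)
  cells <- matrix[rows, , drop = FALSE]
  n <- sum(!is.na(cells))
  if (n == 0) stop("selection contains no evaluated cells", call. = FALSE)
  k <- sum(cells, na.rm = TRUE)
  ci <- wilson_ci(k, n, level)
  data.frame(group = label %||% paste(selector, collapse = "+"),
             k = k, n = n, p = k / n,
             lower = ci[["lower"]], upper = ci[["upper"]], level = level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson chi-square test on an r x 2 count table
#'
#' No continuity correction. Errors if any expected count is zero (a zero
#' marginal), since the statistic is undefined there.
#'
#' @param table r x 2 matrix of counts (rows: groups; columns:
#'   correct/incorrect).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("zero marginal: expected counts are 0", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = expected)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, over tables
#' with the observed margins, of all tables no more probable than the one
#' observed.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  stats::fisher.test(table)$p.value
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order (each `>=` its raw value,
#'   capped at 1).
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "holm")
}

#' Compare diagnostic accuracy between groups
#'
#' Builds the correct/incorrect x group contingency table and applies
#' Pearson's chi-square test, unless any expected cell count is below 5
#' (Cochran's rule), in which case Fisher's exact test is used (exact for
#' two groups; seeded Monte-Carlo with 1e5 tables otherwise). If the omnibus
#' p-value is below `alpha`, all pairwise 2 x 2 comparisons are run under
#' the same test-selection rule and Holm-adjusted.
#'
#' @param matrix a [correctness_matrix()].
#' @param grouping optional named character vector mapping group labels to
#'   coarser arms (e.g. every AI model to `"ai"`); defaults to the matrix's
#'   own groups.
#' @param alpha significance threshold gating the post hoc step (default
#'   0.05).
#' @param seed seed for the Monte-Carlo Fisher p-value.
#' @return an object of class `group_comparison`: list with `table`, `test`
#'   (`"chi_square"`, `"fisher"` or `"fisher_mc"`), `statistic`, `df`,
#'   `p_value`, and `post_hoc` (data frame with raw and Holm-adjusted
#'   pairwise p-values, or `NULL`).
#' @export
compare_groups <- function(matrix, grouping = NULL, alpha = 0.05, seed = 1) {
  groups <- matrix_groups(matrix)
  if (!is.null(grouping)) {
    unknown <- setdiff(groups, names(grouping))
    if (length(unknown)) stop("`grouping` misses group(s): ",
                              paste(unique(unknown), collapse = ", "), call. = FALSE)
    groups <- unname(grouping[groups])
  }
  labs <- unique(groups)
  if (length(labs) < 2) stop("need >= 2 groups to compare", call. = FALSE)
  tab <- t(vapply(labs, function(g) {
    cells <- matrix[groups == g, , drop = FALSE]
    n <- sum(!is.na(cells))
    if (n == 0) stop("group '", g, "' has no evaluations", call. = FALSE)
    c(correct = sum(cells, na.rm = TRUE), incorrect = n - sum(cells, na.rm = TRUE))
  }, numeric(2)))
  res <- run_count_test(tab, seed)
  post <- NULL
  if (res$p_value < alpha && length(labs) > 2) {
    pairs <- utils::combn(labs, 2)
    raw <- apply(pairs, 2, function(pr)
      run_count_test(tab[pr, , drop = FALSE], seed)$p_value)
    post <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                       p_raw = raw, p_holm = holm_adjust(raw), row.names = NULL)
  }
  structure(list(table = tab, test = res$test, statistic = res$statistic,
                 df = res$df, p_value = res$p_value, post_hoc = post),
            class = "group_comparison")
}

# chi-square unless Cochran's rule fails, then (Monte-Carlo) Fisher
run_count_test <- function(tab, seed = 1) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- pearson_chi2(tab)
    list(test = "chi_square", statistic = ht$statistic, df = ht$df,
         p_value = ht$p_value)
  } else if (nrow(tab) == 2) {
    list(test = "fisher", statistic = NA_real_, df = NA_real_,
         p_value = fisher_exact_2x2(tab))
  } else {
    p <- with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                            B = 1e5)$p.value)
    list(test = "fisher_mc", statistic = NA_real_, df = NA_real_, p_value = p)
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s): p = %.4g\n", x$test, x$p_value))
  print(x$table)
  if (!is.null(x$post_hoc)) {
    cat("Post hoc (Holm-adjusted):\n")
    print(x$post_hoc, digits = 4)
  }
  invisible(x)
}

#' Accuracy table across groups and scoring modes
#'
#' Convenience wrapper producing one row per group (plus optional pooled
#' arms) for a correctness matrix, mirroring the accuracy tables of
#' published reader studies.
#'
#' @param matrix a [correctness_matrix()].
#' @param mode label ("SD" or "SD_DD") recorded in the output.
#' @param pooled named list of character vectors: extra pooled rows, e.g.
#'   `list(dermatologists = c("resident", "board_certified", "expert"))`.
#' @param level confidence level.
#' @return data frame: group, mode, k, n, pct, ci_lo, ci_hi.
#' @export
accuracy_table <- function(matrix, mode = "SD", pooled = list(), level = 0.95) {
  rows <- list()
  for (nm in names(pooled))
    rows[[length(rows) + 1]] <- accuracy(matrix, pooled[[nm]], level, label = nm)
  for (g in unique(matrix_groups(matrix)))
    rows[[length(rows) + 1]] <- accuracy(matrix, g, level)
  out <- do.call(rbind, rows)
  data.frame(group = out$group, mode = mode, k = out$k, n = out$n,
             pct = 100 * out$p, ci_lo = 100 * out$lower, ci_hi = 100 * out$upper)
}
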