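#' Gwet's AC1 inter-rater agreement for binary ratings
#'
#' Chance-corrected agreement among raters scoring the same cases correct
#' (1) or incorrect (0), robust to skewed prevalence where Cohen/Fleiss
#' kappa degenerates. For item `i` with `r_i >= 2` ratings of which `r_i1`
#' are "correct", the item agreement is
#' `sum_k r_ik (r_ik - 1) / (r_i (r_i - 1))`; observed agreement `p_a` is
#' the mean over retained items; the prevalence `pi` is the mean of
#' `r_i1 / r_i`; chance agreement is `p_e = 2 pi (1 - pi)`; and
#' `AC1 = (p_a - p_e) / (1 - p_e)`. Items rated by fewer than two raters are
#' excluded. The standard error is a leave-one-item-out jackknife and the CI
#' is `AC1 +/- z * SE`, truncated to `[-1, 1]`.
#'
#' @param matrix a [correctness_matrix()] (or plain 0/1/NA matrix) with
#'   raters in rows and cases in columns.
#' @param level confidence level (default 0.95).
#' @return an object of class `agreement_result`: list with `ac1`, `p_a`,
#'   `pi`, `p_e`, `se`, `ci_lo`, `ci_hi`, `category`, `n_items`, `n_raters`.
#' @export
gwet_ac1 <- function(matrix, level = 0.95) {
  m <- unclass(as.matrix(matrix))
  if (nrow(m) < 2) stop("need >= 2 raters", call. = FALSE)
  r_i <- colSums(!is.na(m))
  keep <- which(r_i >= 2)
  if (length(keep) < 2) stop("fewer than 2 items rated by >= 2 raters", call. = FALSE)
  r1 <- colSums(m == 1, na.rm = TRUE)[keep]
  r0 <- colSums(m == 0, na.rm = TRUE)[keep]
  n <- r_i[keep]
  a_i <- (r1 * (r1 - 1) + r0 * (r0 - 1)) / (n * (n - 1)) # per-item agreement
  f_i <- r1 / n                                          # per-item prevalence
  ac1_from <- function(a, f) {
    p_a <- mean(a); pi_ <- mean(f); p_e <- 2 * pi_ * (1 - pi_)
    (p_a - p_e) / (1 - p_e)
  }
  est <- ac1_from(a_i, f_i)
  N <- length(keep)
  loo <- vapply(seq_len(N), function(j) ac1_from(a_i[-j], f_i[-j]), numeric(1))
  se <- sqrt((N - 1) / N * sum((loo - mean(loo))^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(ac1 = est, p_a = mean(a_i), pi = mean(f_i),
                 p_e = 2 * mean(f_i) * (1 - mean(f_i)), se = se,
                 ci_lo = max(-1, est - z * se), ci_hi = min(1, est + z * se),
                 category = categorize_ac1(est), n_items = N,
                 n_raters = nrow(m), level = level),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Gwet's AC1 = %.3f (%d%% CI %.3f, %.3f) - %s agreement\n",
              x$ac1, round(100 * x$level), x$ci_lo, x$ci_hi, x$category))
  cat(sprintf("p_a = %.3f, prevalence = %.3f, p_e = %.3f; %d items, %d raters\n",
              x$p_a, x$pi, x$p_e, x$n_items, x$n_raters))
  invisible(x)
}

#' Qualitative band of an agreement coefficient
#'
#' Maps an AC1 (or kappa-like) value to the conventional six bands:
#' below 0 poor, 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 good, 0.81-1 very good; band boundaries are inclusive at the
#' upper end.
#'
#' @param value numeric agreement value(s), `<= 1`.
#' @return character label(s).
#' @export
categorize_ac1 <- function(value) {
  if (any(value > 1)) stop("agreement values cannot exceed 1", call. = FALSE)
  as.character(cut(value, c(-Inf, 0, 0.20, 0.40, 0.60, 0.80, 1),
                   labels = c("poor", "slight", "fair", "moderate", "good",
                              "very good"), right = TRUE))
}

#' Between-group agreement via majority-vote pseudo-raters
#'
#' Collapses each group to a single pseudo-rater holding the group's
#' per-case majority vote (ties and all-missing cases count as incorrect /
#' missing respectively), then computes [gwet_ac1()] across the
#' pseudo-raters. This is a declared interpretation of "between groups"
#' agreement, labelled as such in outputs.
#'
#' @inheritParams gwet_ac1
#' @param grouping optional named character vector mapping group labels to
#'   coarser arms; defaults to the matrix's own groups.
#' @return an `agreement_result` (see [gwet_ac1()]).
#' @export
between_group_agreement <- function(matrix, grouping = NULL, level = 0.95) {
  groups <- matrix_groups(matrix)
  if (!is.null(grouping)) groups <- unname(grouping[groups])
  labs <- unique(groups)
  if (length(labs) < 2) stop("need >= 2 groups", call. = FALSE)
  votes <- t(vapply(labs, function(g)
    majority_vote(matrix[groups == g, , drop = FALSE]), numeric(ncol(matrix))))
  gwet_ac1(correctness_matrix(votes, labs), level = level)
}

# per-case majority vote of a sub-matrix; ties -> 0, no ratings -> NA
majority_vote <- function(sub) {
  ones <- colSums(sub == 1, na.rm = TRUE)
  zeros <- colSums(sub == 0, na.rm = TRUE)
  out <- ifelse(ones + zeros == 0, NA_integer_, as.integer(ones > zeros))
  as.numeric(out)
}

#' Agreement table across groups
#'
#' One [gwet_ac1()] row per group plus optional pooled arms and a
#' between-group row, mirroring the inter-rater reliability tables of
#' published reader studies.
#'
#' @param matrix a [correctness_matrix()].
#' @param mode label ("SD" or "SD_DD") recorded in the output.
#' @param pooled named list of character vectors of group labels to pool
#'   into single multi-rater rows.
#' @param between named list of `grouping` vectors passed to
#'   [between_group_agreement()] for between-arm rows.
#' @param level confidence level.
#' @return data frame: group, mode, ac1, ci_lo, ci_hi, category, n_items,
#'   n_raters.
#' @export
agreement_table <- function(matrix, mode = "SD", pooled = list(),
                            between = list(), level = 0.95) {
  groups <- matrix_groups(matrix)
  rows <- list()
  add <- function(label, res) data.frame(
    group = label, mode = mode, ac1 = res$ac1, ci_lo = res$ci_lo,
    ci_hi = res$ci_hi, category = res$category, n_items = res$n_items,
    n_raters = res$n_raters)
  for (nm in names(pooled)) {
    sel <- groups %in% pooled[[nm]]
    rows[[length(rows) + 1]] <- add(nm, gwet_ac1(matrix[sel, , drop = FALSE], level))
  }
  for (g in unique(groups)) {
    sel <- groups == g
    if (sum(sel) >= 2)
      rows[[length(rows) + 1]] <- add(g, gwet_ac1(matrix[sel, , drop = FALSE], level))
  }
  for (nm in names(between))
    rows[[length(rows) + 1]] <- add(nm, between_group_agreement(matrix, between[[nm]], level))
  do.call(rbind, rows)
}
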