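#' Reader-study design
#'
#' Declares the rater groups, the number of cases, and any (rater, case)
#' cells that were never evaluated. The default mirrors a reader study with
#' three dermatologist groups (5 residents, 4 board-certified, 6 trichology
#' experts), four AI raters, 25 cases, and a single missing evaluation for
#' one AI rater; case count and the missing cell are inferred from the
#' per-group evaluation totals such a study reports, and both are
#' overridable.
#'
#' @param groups named integer vector: rater count per group.
#' @param n_cases number of cases.
#' @param missing_cells data frame with columns `rater_id`, `case_id` listing
#'   cells that carry no evaluation.
#' @return a list of class `study_design` with a `raters` data frame
#'   (rater_id, group).
#' @export
study_design <- function(groups = c(resident = 5, board_certified = 4,
                                    expert = 6, chatgpt = 1, grok = 1,
                                    gemini = 1, claude = 1),
                         n_cases = 25,
                         missing_cells = data.frame(rater_id = "gemini_1",
                                                    case_id = "case25")) {
  if (any(groups <= 0)) stop("rater counts must be > 0", call. = FALSE)
  if (n_cases <= 0) stop("`n_cases` must be > 0", call. = FALSE)
  raters <- data.frame(
    rater_id = unlist(lapply(names(groups), function(g)
      paste0(g, "_", seq_len(groups[[g]])))),
    group = rep(names(groups), groups), row.names = NULL)
  case_ids <- paste0("case", seq_len(n_cases))
  if (is.null(missing_cells) || nrow(missing_cells) == 0)
    missing_cells <- data.frame(rater_id = character(), case_id = character())
  bad <- !(missing_cells$rater_id %in% raters$rater_id) |
    !(missing_cells$case_id %in% case_ids)
  if (any(bad))
    stop("missing_cells refer to unknown raters/cases: ",
         paste(missing_cells$rater_id[bad], missing_cells$case_id[bad],
               sep = ":", collapse = ", "), call. = FALSE)
  structure(list(groups = groups, n_cases = n_cases, raters = raters,
                 case_ids = case_ids, missing_cells = missing_cells),
            class = "study_design")
}

#' Probability model for simulated rater responses
#'
#' Each present (rater, case) cell is an independent Bernoulli draw with
#' success probability `plogis(group_logit + case_offset)`, where the case
#' offsets (one per case, shared by all raters) are drawn from a centred
#' normal with sd `case_difficulty_sd`. The shared offsets induce the
#' between-case heterogeneity that chance-corrected agreement statistics are
#' sensitive to.
#'
#' @param group_logits named numeric vector: baseline log-odds of a correct
#'   response per group. `Inf`/`-Inf` saturate at probability 1/0.
#' @param case_difficulty_sd sd of the per-case difficulty offsets (>= 0).
#' @return a list of class `response_model`.
#' @export
response_model <- function(group_logits, case_difficulty_sd = 1) {
  if (case_difficulty_sd < 0) stop("`case_difficulty_sd` must be >= 0", call. = FALSE)
  structure(list(group_logits = group_logits,
                 case_difficulty_sd = case_difficulty_sd),
            class = "response_model")
}

#' Simulate a correctness matrix under a study design
#'
#' @param design a [study_design()].
#' @param model a [response_model()] whose `group_logits` cover every group
#'   in the design.
#' @param seed integer seed; the result is a pure function of
#'   `(design, model, seed)`.
#' @return a [correctness_matrix()] with `NA` exactly at the design's
#'   missing cells.
#' @export
simulate_responses <- function(design, model, seed) {
  stopifnot(inherits(design, "study_design"), inherits(model, "response_model"))
  miss <- setdiff(design$raters$group, names(model$group_logits))
  if (length(miss)) stop("no group_logit for group(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n_r <- nrow(design$raters); n_c <- design$n_cases
  m <- with_seed(seed, {
    offsets <- stats::rnorm(n_c, 0, model$case_difficulty_sd)
    logit <- model$group_logits[design$raters$group]
    p <- stats::plogis(outer(logit, offsets, `+`)) # raters x cases
    matrix(as.integer(stats::runif(n_r * n_c) < p), n_r, n_c)
  })
  rownames(m) <- design$raters$rater_id
  colnames(m) <- design$case_ids
  if (nrow(design$missing_cells))
    m[cbind(match(design$missing_cells$rater_id, rownames(m)),
            match(design$missing_cells$case_id, colnames(m)))] <- NA
  correctness_matrix(m, design$raters$group)
}

#' Build a correctness matrix with prescribed margins
#'
#' Constructs a deterministic matrix whose per-rater or per-group correct
#' counts equal the requested values: correct cells are assigned case-major
#' (case 1 across the raters of the unit, then case 2, ...), i.e. to the
#' lowest case indices first, skipping missing cells. Used to rebuild
#' matrices whose margins are recovered from published accuracy tables.
#'
#' @param design a [study_design()].
#' @param correct_counts named integer vector of correct counts, indexed by
#'   rater id (`mode = "per_rater"`) or group name (`mode = "per_group"`).
#' @param mode `"per_rater"` or `"per_group"`.
#' @return a [correctness_matrix()].
#' @export
matrix_from_margins <- function(design, correct_counts,
                                mode = c("per_group", "per_rater")) {
  stopifnot(inherits(design, "study_design"))
  mode <- match.arg(mode)
  m <- matrix(0L, nrow(design$raters), design$n_cases,
              dimnames = list(design$raters$rater_id, design$case_ids))
  if (nrow(design$missing_cells))
    m[cbind(match(design$missing_cells$rater_id, rownames(m)),
            match(design$missing_cells$case_id, colnames(m)))] <- NA
  units <- if (mode == "per_group") design$groups else
    stats::setNames(rep(1, nrow(design$raters)), design$raters$rater_id)
  for (u in names(correct_counts)) {
    rows <- if (mode == "per_group") which(design$raters$group == u) else
      which(design$raters$rater_id == u)
    if (!length(rows)) stop("unknown rater/group: ", u, call. = FALSE)
    sub <- m[rows, , drop = FALSE]
    # case-major order over present cells
    ord <- order(col(sub), row(sub))
    present <- ord[!is.na(sub[ord])]
    k <- correct_counts[[u]]
    if (k > length(present))
      stop(sprintf("count %d exceeds the %d present cells of '%s'",
                   k, length(present), u), call. = FALSE)
    if (k > 0) sub[present[seq_len(k)]] <- 1L
    m[rows, ] <- sub
  }
  correctness_matrix(m, design$raters$group)
}
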