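#' Canonicalize a diagnosis label
#'
#' Lowercases, trims, collapses runs of whitespace and punctuation to single
#' spaces, then applies a synonym map (e.g. `"AGA"` to
#' `"androgenetic_alopecia"`). Unmapped labels pass through in canonical
#' form. Matching downstream is exact on canonical labels: no fuzzy matching
#' is attempted, so any adjudication of near-miss diagnoses must be encoded
#' explicitly in the vocabulary.
#'
#' @param raw character vector of raw labels.
#' @param vocabulary named character vector mapping canonicalized variants to
#'   canonical diagnosis names.
#' @return character vector of canonical labels; empty input becomes `NA`.
#' @export
canonicalize_label <- function(raw, vocabulary = character()) {
  x <- tolower(trimws(as.character(raw)))
  x <- gsub("[[:space:][:punct:]]+", " ", x)
  x <- trimws(x)
  x[is.na(x) | x == ""] <- NA_character_
  hit <- !is.na(x) & x %in% names(vocabulary)
  x[hit] <- unname(vocabulary[x[hit]])
  x
}

#' Read a diagnosis vocabulary file
#'
#' Two-column CSV (`variant`, `canonical`); variants are themselves
#' canonicalized, so the file may use any case/spacing.
#'
#' @param path CSV path.
#' @return named character vector usable as `vocabulary` in
#'   [canonicalize_label()].
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as.character(df$canonical),
                  canonicalize_label(df$variant))
}

#' Score one response against the true diagnosis
#'
#' Mode `"SD"`: correct iff the suspected diagnosis equals the truth.
#' Mode `"SD_DD"`: correct iff the truth appears among the suspected
#' diagnosis or any listed differential diagnosis. A missing suspected
#' diagnosis scores 0 (with a warning flag via attribute).
#'
#' @param suspected canonical suspected-diagnosis label (may be `NA`).
#' @param differentials character vector of 0-3 canonical differential
#'   diagnoses.
#' @param truth canonical true diagnosis.
#' @param mode `"SD"` or `"SD_DD"`.
#' @return integer 0 or 1.
#' @export
score_response <- function(suspected, differentials = character(), truth,
                           mode = c("SD", "SD_DD")) {
  mode <- match.arg(mode)
  if (length(differentials) > 3)
    stop("at most 3 differential diagnoses are allowed", call. = FALSE)
  if (is.na(suspected) || !nzchar(suspected)) {
    out <- 0L
    attr(out, "flagged_missing") <- TRUE
    return(out)
  }
  pool <- if (mode == "SD") suspected else
    c(suspected, differentials[!is.na(differentials)])
  as.integer(truth %in% pool)
}

#' Build a correctness matrix from long-form responses
#'
#' One cell per (rater, case); (rater, case) pairs with no response become
#' missing. Labels are canonicalized with `vocabulary` before comparison.
#'
#' @param responses data frame with columns `rater_id`, `group`, `case_id`,
#'   `sd`, and optionally `dd1`, `dd2`, `dd3`.
#' @param truths data frame with columns `case_id`, `diagnosis`, one row per
#'   case.
#' @param mode `"SD"` or `"SD_DD"`.
#' @param vocabulary synonym map passed to [canonicalize_label()].
#' @return a [correctness_matrix()] (raters x cases).
#' @export
build_matrix <- function(responses, truths, mode = c("SD", "SD_DD"),
                         vocabulary = character()) {
  mode <- match.arg(mode)
  need <- c("rater_id", "group", "case_id", "sd")
  if (!all(need %in% names(responses)))
    stop("`responses` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  unknown <- setdiff(responses$case_id, truths$case_id)
  if (length(unknown))
    stop("responses reference cases with no ground truth: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  truth_map <- stats::setNames(canonicalize_label(truths$diagnosis, vocabulary),
                               truths$case_id)
  raters <- unique(responses$rater_id)
  groups <- responses$group[match(raters, responses$rater_id)]
  cases <- truths$case_id
  m <- matrix(NA_integer_, length(raters), length(cases),
              dimnames = list(raters, cases))
  dd_cols <- intersect(c("dd1", "dd2", "dd3"), names(responses))
  for (i in seq_len(nrow(responses))) {
    r <- responses[i, ]
    dds <- canonicalize_label(unlist(r[dd_cols], use.names = FALSE), vocabulary)
    m[r$rater_id, r$case_id] <- score_response(
      canonicalize_label(r$sd, vocabulary), dds[!is.na(dds)],
      truth_map[[r$case_id]], mode)
  }
  correctness_matrix(m, groups)
}
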