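#' Margins of the bundled reference reader study
#'
#' Per-group and per-AI-model correct/evaluation counts of a published
#' head-to-head reader study (15 dermatologists in three experience groups
#' and four general-purpose multimodal LLMs reading the same 25 trichoscopic
#' cases; one AI model evaluated 24). The counts are recovered from the
#' study's printed percentages: e.g. a printed 33.3\% over 24 evaluations
#' identifies 8 correct. They serve as fixed example margins for
#' [matrix_from_margins()] and [reproduce_margins()].
#'
#' One inconsistency in the printed source is carried as-is: the expert
#' group's SD+DD percentage is printed as 80.3, but no integer count over
#' 150 evaluations yields it; the pooled dermatologist count forces 120/150
#' (80.0\%), which is what this table contains.
#'
#' @return data frame with columns `group`, `mode` ("SD"/"SD_DD"), `k`, `n`.
#' @export
reference_margins <- function() {
  rbind(
    data.frame(group = c("resident", "board_certified", "expert",
                         "chatgpt", "grok", "gemini", "claude"),
               mode = "SD",
               k = c(61, 51, 106, 4, 4, 8, 2),
               n = c(125, 100, 150, 25, 25, 24, 25)),
    data.frame(group = c("resident", "board_certified", "expert",
                         "chatgpt", "grok", "gemini", "claude"),
               mode = "SD_DD",
               k = c(71, 65, 120, 13, 10, 15, 6),
               n = c(125, 100, 150, 25, 25, 24, 25)))
}

derm_groups <- c("resident", "board_certified", "expert")
ai_groups <- c("chatgpt", "grok", "gemini", "claude")

# group -> arm map used for pooled dermatologists-vs-AI comparisons
derm_vs_ai_grouping <- function() {
  stats::setNames(c(rep("dermatologists", 3), rep("ai", 4)),
                  c(derm_groups, ai_groups))
}

#' Rebuild the reference study's accuracy analysis from its margins
#'
#' Reconstructs, for each scoring mode, a correctness matrix whose margins
#' equal [reference_margins()] (via [matrix_from_margins()]), then runs the
#' full accuracy and comparison analysis on it: per-group and pooled
#' percentages with Wilson intervals, and the dermatologists-vs-AI,
#' within-dermatologist and within-AI group comparisons. Because accuracy
#' and the omnibus tests depend on the data only through the margins, the
#' resulting table reproduces the published percentages and intervals
#' exactly.
#'
#' @param level confidence level for the Wilson intervals.
#' @param seed seed passed to the (Monte-Carlo) Fisher fallback.
#' @return list with `accuracy` (data frame: group, mode, k, n, pct, ci_lo,
#'   ci_hi) and `comparisons` (data frame: comparison, mode, test,
#'   statistic, p_value).
#' @export
reproduce_margins <- function(level = 0.95, seed = 1) {
  margins <- reference_margins()
  acc <- list(); cmp <- list()
  for (md in c("SD", "SD_DD")) {
    mg <- margins[margins$mode == md, ]
    counts <- stats::setNames(mg$k, mg$group)
    # one design per mode: per-group margins for dermatologist groups,
    # per-rater margins for the single-rater AI models
    des <- study_design()
    mat <- matrix_from_margins(des, counts, mode = "per_group")
    acc[[md]] <- accuracy_table(
      mat, mode = md,
      pooled = list(dermatologists = derm_groups, ai = ai_groups),
      level = level)
    for (cm in list(
      list(name = "dermatologists_vs_ai", grouping = derm_vs_ai_grouping()),
      list(name = "within_dermatologists", grouping = NULL,
           keep = derm_groups),
      list(name = "within_ai", grouping = NULL, keep = ai_groups))) {
      m2 <- mat
      if (!is.null(cm$keep)) {
        sel <- matrix_groups(mat) %in% cm$keep
        m2 <- correctness_matrix(unclass(mat)[sel, , drop = FALSE],
                                 matrix_groups(mat)[sel])
      }
      res <- compare_groups(m2, grouping = cm$grouping, seed = seed)
      cmp[[paste(md, cm$name)]] <- data.frame(
        comparison = cm$name, mode = md, test = res$test,
        statistic = res$statistic, p_value = res$p_value)
    }
  }
  list(accuracy = do.call(rbind, c(acc, make.row.names = FALSE)),
       comparisons = do.call(rbind, c(cmp, make.row.names = FALSE)))
}

#' Descriptive frequency table of rater characteristics
#'
#' Tabulates each categorical characteristic of the rater panel as counts
#' and percentages, the way reader studies describe their participants.
#' Percentages are rounded to one decimal; due to rounding they may not add
#' up to exactly 100.
#'
#' @param raters data frame, one row per rater, categorical columns (e.g.
#'   training status, experience band, workplace).
#' @return data frame: variable, level, n, pct; empty for an empty input.
#' @export
describe_raters <- function(raters) {
  out <- list()
  for (v in names(raters)) {
    tab <- table(factor(raters[[v]], levels = unique(raters[[v]])))
    if (length(tab) == 0) next
    out[[v]] <- data.frame(variable = v, level = names(tab),
                           n = as.integer(tab),
                           pct = round(100 * as.integer(tab) / nrow(raters), 1))
  }
  if (!length(out))
    return(data.frame(variable = character(), level = character(),
                      n = integer(), pct = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Default end-to-end study configuration
#'
#' A complete, self-contained configuration for [run_study()]: synthetic
#' images, the default transformation pipeline, a simulated response model
#' whose group log-odds roughly track the accuracy ordering seen in real
#' reader studies (experts > board-certified > residents >> general-purpose
#' AI for the primary diagnosis), and default integrity thresholds.
#'
#' @param output_dir directory the run writes into.
#' @param master_seed master seed; every random stage derives its own
#'   sub-seed from it.
#' @param n_images number of synthetic images to generate and transform.
#' @return nested configuration list of class `study_config`.
#' @export
default_study_config <- function(output_dir = tempfile("trichobench_run_"),
                                 master_seed = 1, n_images = 4) {
  structure(list(
    output_dir = output_dir,
    master_seed = master_seed,
    ci_level = 0.95,
    alpha = 0.05,
    images = list(simulate = TRUE, n_images = n_images, height = 160, width = 160),
    transform = as.list(unclass(transform_config())),
    integrity = list(threshold_preserve = 0.60, threshold_disrupt = 1),
    responses = list(
      simulate = TRUE,
      case_difficulty_sd = 1,
      group_logits_sd = c(resident = 0.0, board_certified = 0.1, expert = 1.0,
                          chatgpt = -1.7, grok = -1.7, gemini = -0.7,
                          claude = -2.5),
      group_logits_sd_dd = c(resident = 0.3, board_certified = 0.7,
                             expert = 1.6, chatgpt = 0.1, grok = -0.4,
                             gemini = 0.5, claude = -1.2)),
    design = list()), class = "study_config")
}

#' Load a study configuration from a YAML file
#'
#' Reads the file and merges it over [default_study_config()]; any field not
#' present in the file keeps its default.
#'
#' @param path YAML file path.
#' @return a `study_config` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_study_config()
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "study_config")
}

#' Run the full study pipeline
#'
#' Executes every stage end to end: synthetic image generation (or reading
#' an input directory), the ten-stage anti-leakage transformation, integrity
#' verification of every original/transformed pair, response simulation (or
#' scoring a response CSV against ground truth), accuracy estimation with
#' Wilson intervals, group comparisons with Holm-adjusted post hocs, and
#' Gwet's AC1 agreement. Writes `table2.csv` (accuracy), `table3.csv`
#' (agreement), `comparisons.csv`, `integrity.csv`,
#' `transform_records.csv`, a JSON run manifest (config, seed, package
#' version) and a plain-text log into `config$output_dir`. All randomness
#' derives from `config$master_seed`, so a re-run with the same
#' configuration reproduces every output byte.
#'
#' @param config a `study_config` list from [default_study_config()] or
#'   [read_study_config()].
#' @return (invisibly) a list with the computed `accuracy`, `agreement`,
#'   `comparisons` and `integrity` tables and the output paths.
#' @export
run_study <- function(config = default_study_config()) {
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("trichobench")),
                   status = "running")
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
    pretty = TRUE, force = TRUE, digits = NA)
  write_manifest()
  fail <- function(stage, e) {
    manifest$status <<- paste0("failed:", stage)
    write_manifest()
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  }

  # -- images ----------------------------------------------------------------
  orig_dir <- file.path(out_dir, "originals")
  tryCatch({
    if (isTRUE(config$images$simulate)) {
      dir.create(orig_dir, showWarnings = FALSE)
      for (i in seq_len(config$images$n_images)) {
        id <- sprintf("synthetic_%02d", i)
        g <- generate_scalp_image(
          image_spec(height = config$images$height, width = config$images$width),
          seed = derive_seed(config$master_seed, id))
        write_image_png(g$image, file.path(orig_dir, paste0(id, ".png")))
      }
      logf("images", sprintf("generated %d synthetic images", config$images$n_images))
    } else {
      orig_dir <- config$images$input_dir
      if (is.null(orig_dir) || !dir.exists(orig_dir))
        stop("images.input_dir not found: ", orig_dir %||% "<unset>")
      logf("images", paste("using input directory", orig_dir))
    }
  }, error = function(e) fail("images", e))

  # -- transform -------------------------------------------------------------
  trans_dir <- file.path(out_dir, "transformed")
  records <- tryCatch({
    cfg <- do.call(transform_config, config$transform)
    r <- transform_batch(orig_dir, trans_dir, cfg,
                         master_seed = config$master_seed,
                         records_csv = file.path(out_dir, "transform_records.csv"))
    logf("transform", sprintf("transformed %d images", nrow(r)))
    r
  }, error = function(e) fail("transform", e))

  # -- verify ----------------------------------------------------------------
  integrity <- tryCatch({
    rep <- verify_batch(orig_dir, trans_dir,
                        config$integrity$threshold_preserve,
                        config$integrity$threshold_disrupt,
                        report_csv = file.path(out_dir, "integrity.csv"))
    if (any(!rep$pass))
      logf("verify", sprintf("WARNING: %d/%d pairs fail the integrity contract",
                             sum(!rep$pass), nrow(rep)))
    else logf("verify", sprintf("all %d pairs pass the integrity contract", nrow(rep)))
    rep
  }, error = function(e) fail("verify", e))

  # -- responses -> correctness matrices ------------------------------------
  mats <- tryCatch({
    des <- do.call(study_design, config$design)
    if (isTRUE(config$responses$simulate)) {
      sd_m <- simulate_responses(
        des, response_model(unlist(config$responses$group_logits_sd),
                            config$responses$case_difficulty_sd),
        seed = derive_seed(config$master_seed, "responses_sd"))
      # SD+DD relaxes scoring, so correctness can only be gained, never lost:
      # flip a subset of the SD errors to correct under the wider logits
      sdd_m <- simulate_responses(
        des, response_model(unlist(config$responses$group_logits_sd_dd),
                            config$responses$case_difficulty_sd),
        seed = derive_seed(config$master_seed, "responses_sd_dd"))
      sdd <- correctness_matrix(pmax(unclass(sd_m), unclass(sdd_m)),
                                matrix_groups(sd_m))
      logf("score", "simulated SD and SD_DD correctness matrices")
      list(SD = sd_m, SD_DD = sdd)
    } else {
      responses <- utils::read.csv(config$responses$responses_csv)
      truths_path <- config$responses$truths_csv
      if (is.null(truths_path) || !file.exists(truths_path))
        stop("responses.truths_csv not found: ", truths_path %||% "<unset>")
      truths <- utils::read.csv(truths_path)
      vocab <- if (!is.null(config$responses$vocabulary_csv))
        read_vocabulary(config$responses$vocabulary_csv) else character()
      logf("score", sprintf("scored %d responses", nrow(responses)))
      list(SD = build_matrix(responses, truths, "SD", vocab),
           SD_DD = build_matrix(responses, truths, "SD_DD", vocab))
    }
  }, error = function(e) fail("score", e))

  # -- accuracy, comparisons, agreement -------------------------------------
  results <- tryCatch({
    pooled <- list(dermatologists = derm_groups, ai = ai_groups)
    pooled <- lapply(pooled, intersect, x = unique(unlist(lapply(mats, matrix_groups))))
    pooled <- Filter(length, pooled)
    acc <- do.call(rbind, lapply(names(mats), function(md)
      accuracy_table(mats[[md]], mode = md, pooled = pooled,
                     level = config$ci_level)))
    utils::write.csv(acc, file.path(out_dir, "table2.csv"), row.names = FALSE)

    cmp <- list()
    for (md in names(mats)) {
      grouping <- derm_vs_ai_grouping()
      grouping <- grouping[names(grouping) %in% matrix_groups(mats[[md]])]
      if (length(unique(grouping)) >= 2) {
        res <- compare_groups(mats[[md]], grouping = grouping,
                              alpha = config$alpha,
                              seed = derive_seed(config$master_seed, paste0("cmp_", md)))
        cmp[[paste0(md, "_arms")]] <- data.frame(
          comparison = "dermatologists_vs_ai", mode = md, test = res$test,
          statistic = res$statistic, p_value = res$p_value)
      }
      res_all <- compare_groups(mats[[md]], alpha = config$alpha,
                                seed = derive_seed(config$master_seed,
                                                   paste0("cmp_all_", md)))
      cmp[[paste0(md, "_groups")]] <- data.frame(
        comparison = "all_groups", mode = md, test = res_all$test,
        statistic = res_all$statistic, p_value = res_all$p_value)
      if (!is.null(res_all$post_hoc))
        cmp[[paste0(md, "_posthoc")]] <- data.frame(
          comparison = paste(res_all$post_hoc$group1, "vs", res_all$post_hoc$group2),
          mode = md, test = "pairwise_holm", statistic = NA_real_,
          p_value = res_all$post_hoc$p_holm)
    }
    cmp <- do.call(rbind, c(cmp, make.row.names = FALSE))
    utils::write.csv(cmp, file.path(out_dir, "comparisons.csv"), row.names = FALSE)

    agr <- do.call(rbind, lapply(names(mats), function(md)
      agreement_table(mats[[md]], mode = md, pooled = pooled,
                      between = list(
                        dermatologists_vs_ai = derm_vs_ai_grouping()),
                      level = config$ci_level)))
    utils::write.csv(agr, file.path(out_dir, "table3.csv"), row.names = FALSE)
    logf("report", "wrote table2.csv, table3.csv, comparisons.csv")
    list(accuracy = acc, comparisons = cmp, agreement = agr)
  }, error = function(e) fail("report", e))

  manifest$status <- "complete"
  write_manifest()
  invisible(c(results, list(integrity = integrity, records = records,
                            output_dir = out_dir)))
}
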