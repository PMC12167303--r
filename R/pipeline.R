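#' Score survey responses into group reports
#'
#' Builds the benchmark's per-group, per-modality report: average accuracy,
#' support-weighted F1 and normalized L-half spread. Under
#' `mode = "per-participant"` (the default) each participant's answers form
#' their own confusion matrix, the three metrics are computed per
#' participant, and the group cell reports their mean; under
#' `mode = "pooled"` all the cell's answers are pooled into one matrix
#' first.
#'
#' @param responses response table with columns `participant_id`, `group`,
#'   `item_id`, `modality`, `answer` (and `true_phase` unless `items` is
#'   supplied).
#' @param schema the `phase_schema`.
#' @param items optional sampled-items table; when given, each response's
#'   truth is looked up by `item_id` and responses referencing unknown items
#'   raise an error.
#' @param mode `"per-participant"` or `"pooled"`.
#' @return Data frame with one row per (group, modality): `group`,
#'   `modality`, `accuracy`, `weighted_f1`, `lhalf_normalized`,
#'   `n_participants`, `n_responses`.
#' @export
score_responses <- function(responses, schema,
                            items = NULL,
                            mode = c("per-participant", "pooled")) {
  mode <- match.arg(mode)
  if (!is.null(items)) {
    orphan <- setdiff(unique(responses$item_id), items$item_id)
    if (length(orphan))
      stop("responses reference unknown item id(s): ",
           paste(utils::head(orphan, 10L), collapse = ", "), call. = FALSE)
    responses$true_phase <-
      items$true_phase[match(responses$item_id, items$item_id)]
  }
  if (is.null(responses$true_phase))
    stop("responses need a true_phase column or an items table",
         call. = FALSE)
  cells <- unique(responses[, c("group", "modality")])
  cells <- cells[order(match(cells$group, unique(responses$group)),
                       cells$modality), , drop = FALSE]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- responses[responses$group == cells$group[i] &
                       responses$modality == cells$modality[i], ,
                     drop = FALSE]
    if (mode == "pooled") {
      cm <- confusion_matrix(sub$true_phase, sub$answer, schema)
      ms <- metric_set(cm)
      data.frame(group = cells$group[i], modality = cells$modality[i],
                 accuracy = ms$accuracy, weighted_f1 = ms$weighted_f1,
                 lhalf_normalized = ms$lhalf_normalized,
                 n_participants = length(unique(sub$participant_id)),
                 n_responses = nrow(sub), stringsAsFactors = FALSE)
    } else {
      per <- lapply(split(sub, sub$participant_id), function(s) {
        metric_set(confusion_matrix(s$true_phase, s$answer, schema))
      })
      per <- do.call(rbind, per)
      data.frame(group = cells$group[i], modality = cells$modality[i],
                 accuracy = mean(per$accuracy),
                 weighted_f1 = mean(per$weighted_f1),
                 lhalf_normalized = mean(per$lhalf_normalized),
                 n_participants = nrow(per),
                 n_responses = nrow(sub), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-participant accuracies by modality
#'
#' The paired scores entering the modality comparison: one accuracy per
#' participant per modality.
#'
#' @param responses response table with `participant_id`, `group`,
#'   `modality`, `true_phase`, `answer`.
#' @return Data frame with `participant_id`, `group`, `modality`,
#'   `accuracy`, `n`.
#' @export
participant_scores <- function(responses) {
  key <- interaction(responses$participant_id, responses$modality,
                     drop = TRUE)
  agg <- lapply(split(responses, key), function(s) {
    data.frame(participant_id = s$participant_id[1L], group = s$group[1L],
               modality = s$modality[1L],
               accuracy = mean(s$answer == s$true_phase), n = nrow(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$group, out$participant_id, out$modality), ]
}

#' Compare question modalities per group
#'
#' For every group, pairs each participant's single-frame accuracy with
#' their snippet accuracy, runs the two-sided Wilcoxon signed-rank test on
#' the paired differences, and applies the Bonferroni correction across
#' groups (threshold `alpha` divided by the number of groups; rejection
#' requires `p` strictly below the corrected threshold). A group in which
#' every participant scores identically in both modalities has no defined
#' test and reports `NA` with no rejection.
#'
#' @param responses response table (see [participant_scores()]).
#' @param alpha family-wise significance level (default 0.05).
#' @return Data frame with one row per group: `group`, `n_pairs`,
#'   `statistic`, `p_value`, `threshold`, `reject`.
#' @export
compare_modalities <- function(responses, alpha = 0.05) {
  sc <- participant_scores(responses)
  groups <- unique(sc$group)
  rows <- lapply(groups, function(g) {
    sub <- sc[sc$group == g, ]
    wide <- merge(sub[sub$modality == "frame",
                      c("participant_id", "accuracy")],
                  sub[sub$modality == "snippet",
                      c("participant_id", "accuracy")],
                  by = "participant_id", suffixes = c("_frame", "_snippet"))
    res <- tryCatch(
      wilcoxon_signed_rank(wide$accuracy_frame, wide$accuracy_snippet),
      error = function(e) NULL)
    data.frame(group = g, n_pairs = nrow(wide),
               statistic = if (is.null(res)) NA_real_ else
                 unname(res$statistic),
               p_value = if (is.null(res)) NA_real_ else res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  corr <- bonferroni(out$p_value, alpha)
  out$threshold <- corr$threshold
  out$reject <- !is.na(corr$reject) & corr$reject
  rownames(out) <- NULL
  out
}

#' Score frame-level predictions against ground truth
#'
#' Compares per-second predicted labels with the annotated phase at each
#' second (scored at the second's midpoint) and reports accuracy, weighted
#' F1 and normalized L-half spread per procedure plus a pooled overall row.
#' Predictions falling in footage gaps are dropped with a warning.
#'
#' @param timelines a `procedure_timeline` or named list of them.
#' @param predictions data frame with `procedure_id`, `time_s`,
#'   `predicted_phase`.
#' @param schema the `phase_schema`.
#' @return Data frame with one row per procedure and a final `"overall"`
#'   row: `procedure_id`, `accuracy`, `weighted_f1`, `lhalf_normalized`,
#'   `n`.
#' @export
score_predictions <- function(timelines, predictions, schema) {
  if (inherits(timelines, "procedure_timeline"))
    timelines <- stats::setNames(list(timelines), timelines$procedure_id)
  if (nrow(predictions) == 0L)
    stop("empty prediction table", call. = FALSE)
  unknown <- setdiff(unique(predictions$procedure_id), names(timelines))
  if (length(unknown))
    stop("predictions for unknown procedure(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  truths <- character(0)
  preds <- character(0)
  rows <- lapply(names(timelines), function(id) {
    sub <- predictions[predictions$procedure_id == id, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    truth <- phase_at(timelines[[id]], sub$time_s + 0.5)
    gap <- is.na(truth)
    if (any(gap)) {
      warning(sum(gap), " prediction(s) in footage gaps dropped for ", id,
              call. = FALSE)
      sub <- sub[!gap, , drop = FALSE]
      truth <- truth[!gap]
    }
    truths <<- c(truths, truth)
    preds <<- c(preds, sub$predicted_phase)
    ms <- metric_set(confusion_matrix(truth, sub$predicted_phase, schema))
    cbind(procedure_id = id, ms, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  overall <- cbind(procedure_id = "overall",
                   metric_set(confusion_matrix(truths, preds, schema)),
                   stringsAsFactors = FALSE)
  out <- rbind(out, overall)
  rownames(out) <- NULL
  out
}

#' Default end-to-end benchmark configuration
#'
#' One list drives the whole pipeline. Defaults are the benchmark's study
#' values: the 15-phase RAPN schema with its published duration table, 17
#' samples with 30-s spacing, 5-95% trim band, sigma at 0.1 of phase
#' duration, 10-min oversampling threshold, 10-s snippets, alpha 0.05; and
#' three respondent groups whose frame accuracies and snippet gains emulate
#' the observed group performance.
#'
#' @param n_procedures cohort size (default 143).
#' @param group_sizes named participants-per-group vector.
#' @return A nested configuration list, YAML-serializable.
#' @export
default_benchmark_config <- function(n_procedures = 143,
                                     group_sizes = c(
                                       "medical-student" = 30,
                                       "surgical-trainee" = 30,
                                       "consultant" = 30)) {
  list(
    schema = "rapn",
    cohort = list(n_procedures = n_procedures, family = "lognormal",
                  split_prob = 0),
    sampler = list(n_samples = 17, min_gap_s = 30, trim_lo = 0.05,
                   trim_hi = 0.95, sigma_ratio = 0.1,
                   oversample_threshold_s = 600, snippet_len_s = 10,
                   max_retries = 1000),
    respondents = list(
      "medical-student" = list(p_correct_frame = 0.303,
                               snippet_boost = 0.133),
      "surgical-trainee" = list(p_correct_frame = 0.415,
                                snippet_boost = 0.114),
      "consultant" = list(p_correct_frame = 0.412, snippet_boost = 0.120)),
    group_sizes = as.list(group_sizes),
    stats = list(alpha = 0.05),
    score_mode = "per-participant"
  )
}

read_benchmark_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_benchmark_config()
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_cfg(base, config)
}

#' Run the benchmark end-to-end
#'
#' Simulate a cohort of procedures, sample survey questions, simulate
#' respondents, score them per group and modality, and compare modalities
#' with the Wilcoxon/Bonferroni protocol — all from one configuration and
#' one seed, deterministically. When `out_dir` is given, writes
#' `manifest.json`, `items.csv`, `responses.csv`, `report.csv` (the
#' group-by-modality table) and `comparison.json`.
#'
#' @param config a configuration list (see [default_benchmark_config()]) or
#'   a YAML file path; omitted fields take their defaults.
#' @param seed integer seed for the whole run.
#' @param out_dir optional output directory.
#' @return (Invisibly) a list of class `spr_benchmark` with `report`,
#'   `comparison`, `survey`, `config`, `seed`.
#' @examples
#' bench <- run_benchmark(list(cohort = list(n_procedures = 6),
#'                             group_sizes = list("medical-student" = 2,
#'                                                "surgical-trainee" = 2,
#'                                                "consultant" = 2)),
#'                        seed = 1)
#' bench$report
#' @export
run_benchmark <- function(config = list(), seed = 1L, out_dir = NULL) {
  cfg <- read_benchmark_config(config)
  schema <- if (is.character(cfg$schema)) get_schema(cfg$schema)
            else cfg$schema
  durations <- if (!is.null(cfg$durations)) cfg$durations
               else get_durations(cfg$schema)
  ccfg <- cohort_config(schema, durations,
                        n_procedures = cfg$cohort$n_procedures,
                        family = cfg$cohort$family,
                        split_prob = cfg$cohort$split_prob,
                        seed = seed)
  cohort <- simulate_cohort(ccfg)
  scfg <- do.call(sampler_config, cfg$sampler)
  respondents <- lapply(names(cfg$respondents), function(g) {
    do.call(respondent_config, c(list(group = g), cfg$respondents[[g]]))
  })
  names(respondents) <- names(cfg$respondents)
  group_sizes <- unlist(cfg$group_sizes)
  survey <- simulate_survey(cohort, scfg, respondents, group_sizes,
                            seed = seed + 1L)
  report <- score_responses(survey$responses, schema,
                            mode = cfg$score_mode)
  comparison <- compare_modalities(survey$responses,
                                   alpha = cfg$stats$alpha)
  out <- structure(list(report = report, comparison = comparison,
                        survey = survey, config = cfg, seed = seed),
                   class = "spr_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config = cfg, seed = seed,
           tool = paste0("sprbench ",
                         as.character(utils::packageVersion("sprbench")))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(survey$items, file.path(out_dir, "items.csv"),
                     row.names = FALSE)
    utils::write.csv(survey$responses, file.path(out_dir, "responses.csv"),
                     row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(out)
}

#' @export
print.spr_benchmark <- function(x, ...) {
  cat("Surgical phase recognition benchmark (seed ", x$seed, ")\n\n",
      sep = "")
  rep <- x$report
  rep$accuracy <- sprintf("%.1f", 100 * rep$accuracy)
  rep$weighted_f1 <- sprintf("%.1f", 100 * rep$weighted_f1)
  rep$lhalf_normalized <- sprintf("%.2f", rep$lhalf_normalized)
  names(rep)[3:5] <- c("accuracy (%)", "weighted F1 (%)", "L1/2 [0,1]")
  print(rep, row.names = FALSE)
  cat("\nModality comparison (Wilcoxon signed-rank, Bonferroni at alpha = ",
      x$config$stats$alpha, "):\n", sep = "")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}
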