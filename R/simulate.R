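#' Cohort generator configuration
#'
#' Describes how to simulate a cohort of phase-annotated procedures from a
#' per-phase duration table. Durations are drawn per phase from the chosen
#' family, moment-matched to the table's (mean, sd); phases are laid out as
#' single contiguous segments in canonical schema order unless `split_prob`
#' introduces recurrences.
#'
#' The default family is lognormal: several published RAPN phases have
#' sd > mean (e.g. hilar clamping, 2.0 +/- 4.7 min), a coefficient of
#' variation no positive-support normal can reach, while the lognormal
#' matches any (mean, sd) pair exactly.
#'
#' @param schema a `phase_schema`.
#' @param durations a `duration_table` for the schema (minutes).
#' @param n_procedures cohort size (default 1).
#' @param family `"lognormal"` (default), `"truncated-normal"` or
#'   `"degenerate"` (every phase takes exactly its mean duration).
#' @param split_prob probability that a (sufficiently long) phase recurs as
#'   two separated segments, emulating nonlinear workflow (default 0).
#' @param seed integer seed used by [simulate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(schema, durations, n_procedures = 1L,
                          family = c("lognormal", "truncated-normal",
                                     "degenerate"),
                          split_prob = 0, seed = NULL) {
  stopifnot(inherits(schema, "phase_schema"),
            inherits(durations, "duration_table"),
            n_procedures >= 1L, split_prob >= 0, split_prob <= 1)
  if (!identical(durations$phase, schema$labels))
    stop("duration table does not match the schema's labels/order",
         call. = FALSE)
  structure(list(schema = schema, durations = durations,
                 n_procedures = as.integer(n_procedures),
                 family = match.arg(family), split_prob = split_prob,
                 seed = seed),
            class = "cohort_config")
}

# solve the parent (mu, sigma) of a normal truncated to (0, Inf) so the
# truncated moments match (m, s); returns NULL when no match exists
solve_truncnorm <- function(m, s) {
  if (s / m >= 0.99) return(NULL)  # cv of a positive truncated normal is < 1
  obj <- function(par) {
    mu <- par[1L]
    sigma <- exp(par[2L])
    alpha <- -mu / sigma
    lambda <- exp(stats::dnorm(alpha, log = TRUE) -
                    stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
    mt <- mu + sigma * lambda
    vt <- sigma^2 * (1 + alpha * lambda - lambda^2)
    (mt / m - 1)^2 + (sqrt(max(vt, 0)) / s - 1)^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-8) return(NULL)
  c(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

# one positive duration draw (seconds) for a phase with mean m, sd s minutes
draw_duration <- function(m, s, family) {
  m_s <- m * 60
  s_s <- s * 60
  if (family == "degenerate" || s_s == 0) return(m_s)
  if (family == "truncated-normal") {
    par <- solve_truncnorm(m_s, s_s)
    if (is.null(par)) {
      warning("truncated-normal family cannot match mean ", m, " / sd ", s,
              " min; falling back to lognormal", call. = FALSE)
      family <- "lognormal"
    } else {
      repeat {
        x <- stats::rnorm(1, par["mu"], par["sigma"])
        if (x > 0) return(x)
      }
    }
  }
  sdlog2 <- log(1 + (s_s / m_s)^2)
  stats::rlnorm(1, meanlog = log(m_s) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate one procedure timeline
#'
#' Draws one duration per schema phase from the configured family
#' (moment-matched to the duration table) and lays the phases out as
#' contiguous segments in schema order. With `split_prob > 0`, qualifying
#' phases (>= 120 s) may be split into two segments, the second re-inserted
#' later in the procedure, to emulate recurrent (nonlinear) workflow. Uses
#' the current RNG state; see [simulate_cohort()] for seeded generation.
#'
#' @param config a `cohort_config`.
#' @param procedure_id identifier for the generated procedure.
#' @return A `procedure_timeline`.
#' @export
simulate_timeline <- function(config, procedure_id = "proc001") {
  dt <- config$durations
  durs <- vapply(seq_len(nrow(dt)),
                 function(i) draw_duration(dt$mean_min[i], dt$sd_min[i],
                                           config$family),
                 numeric(1))
  phases <- dt$phase
  pieces <- data.frame(phase = phases, dur = durs, stringsAsFactors = FALSE)
  if (config$split_prob > 0) {
    out <- pieces[0, ]
    pending <- list()
    for (i in seq_len(nrow(pieces))) {
      row <- pieces[i, ]
      if (row$dur >= 120 && stats::runif(1) < config$split_prob) {
        frac <- stats::runif(1, 0.3, 0.7)
        later <- row
        later$dur <- row$dur * (1 - frac)
        row$dur <- row$dur * frac
        # re-insert the tail after a random number of later phases
        pending[[length(pending) + 1L]] <-
          list(piece = later, after = i + sample.int(
            max(1L, nrow(pieces) - i), 1L))
      }
      out <- rbind(out, row)
      for (pd in pending) {
        if (pd$after == i) out <- rbind(out, pd$piece)
      }
      pending <- Filter(function(pd) pd$after > i, pending)
    }
    for (pd in pending) out <- rbind(out, pd$piece)
    pieces <- out
  }
  ends <- cumsum(pieces$dur)
  segs <- data.frame(phase = pieces$phase,
                     start_s = c(0, ends[-length(ends)]),
                     end_s = ends, stringsAsFactors = FALSE)
  procedure_timeline(procedure_id, segs, config$schema)
}

#' Simulate a cohort of procedures
#'
#' @param config a `cohort_config`; its `seed` makes the cohort
#'   bit-reproducible.
#' @return A named list of `n_procedures` independent `procedure_timeline`
#'   objects with ids `proc001, proc002, ...`.
#' @examples
#' cfg <- cohort_config(cholec80_schema(), cholec80_durations(),
#'                      n_procedures = 3, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' sapply(cohort, timeline_end) / 60  # total minutes per procedure
#' @export
simulate_cohort <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("proc%03d", seq_len(config$n_procedures))
  out <- lapply(ids, function(id) simulate_timeline(config, id))
  names(out) <- ids
  out
}

#' Survey respondent configuration
#'
#' Behavioral model of one expertise group answering phase-classification
#' questions. A respondent answers the true phase with probability
#' `p_correct_frame` (plus `snippet_boost` for snippet questions); wrong
#' answers fall on other phases with probability proportional to
#' `adjacency_spread^distance` in schema order, so confusion concentrates on
#' temporally adjacent phases. Correctness across the two modalities of the
#' same timestamp shares a per-item difficulty latent with correlation
#' `item_coupling` (probit scale): the snippet contains the sampled frame,
#' so an item that is hard as a frame tends to stay hard as a snippet.
#' Confidence (1-5) follows an ordinal model with rank correlation
#' `confidence_correlation` to correctness; response times are lognormal.
#'
#' @param group group label, e.g. `"medical-student"`, `"surgical-trainee"`,
#'   `"consultant"`.
#' @param p_correct_frame probability of answering a single-frame question
#'   correctly, in `[0, 1]`.
#' @param snippet_boost additive accuracy gain for snippet questions;
#'   `p_correct_frame + snippet_boost` must stay in `[0, 1]`.
#' @param adjacency_spread geometric decay (>= 0) of wrong-answer mass with
#'   schema distance; 0 confuses only the immediately adjacent phases, 1 is
#'   uniform over wrong phases.
#' @param confidence_correlation target rank correlation in `[-1, 1]`
#'   between confidence and correctness (default 0, matching the absence of
#'   correlation observed in the survey).
#' @param item_coupling correlation in `[0, 1)` of the per-item difficulty
#'   latent shared by the two modalities (default 0.8).
#' @param rt_meanlog,rt_sdlog lognormal response-time parameters (seconds;
#'   defaults give a median of 10 s).
#' @return A list of class `respondent_config`.
#' @export
respondent_config <- function(group, p_correct_frame, snippet_boost = 0,
                              adjacency_spread = 0.5,
                              confidence_correlation = 0,
                              item_coupling = 0.8,
                              rt_meanlog = log(10), rt_sdlog = 0.5) {
  stopifnot(p_correct_frame >= 0, p_correct_frame <= 1,
            adjacency_spread >= 0,
            confidence_correlation >= -1, confidence_correlation <= 1,
            item_coupling >= 0, item_coupling < 1, rt_sdlog >= 0)
  if (p_correct_frame + snippet_boost > 1 ||
      p_correct_frame + snippet_boost < 0)
    stop("p_correct_frame + snippet_boost must lie in [0, 1]", call. = FALSE)
  structure(list(group = group, p_correct_frame = p_correct_frame,
                 snippet_boost = snippet_boost,
                 adjacency_spread = adjacency_spread,
                 confidence_correlation = confidence_correlation,
                 item_coupling = item_coupling,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
            class = "respondent_config")
}

# vectorized answers for one participant and one modality.
# z: per-item shared difficulty latents (standard normal), recycled across
# modalities so frame/snippet correctness is coupled.
answer_items <- function(true_phases, modality, cfg, schema, z) {
  n <- length(true_phases)
  p <- cfg$p_correct_frame +
    if (identical(modality, "snippet")) cfg$snippet_boost else 0
  rho <- cfg$item_coupling
  u <- stats::pnorm(sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n))
  correct <- u < p
  idx_true <- match(true_phases, schema$labels)
  answer <- true_phases
  wrong <- which(!correct)
  for (i in wrong) {
    dist <- abs(seq_len(schema$k) - idx_true[i])
    w <- if (cfg$adjacency_spread == 0) as.numeric(dist == 1L)
         else cfg$adjacency_spread^dist
    w[idx_true[i]] <- 0
    answer[i] <- schema$labels[sample.int(schema$k, 1L, prob = w)]
  }
  cc <- cfg$confidence_correlation
  s <- if (p > 0 && p < 1) (as.numeric(correct) - p) / sqrt(p * (1 - p))
       else rep(0, n)
  lat <- cc * s + sqrt(1 - cc^2) * stats::rnorm(n)
  confidence <- findInterval(lat, stats::qnorm(c(0.2, 0.4, 0.6, 0.8))) + 1L
  data.frame(true_phase = true_phases, answer = answer,
             confidence = confidence,
             response_time_s = stats::rlnorm(n, cfg$rt_meanlog, cfg$rt_sdlog),
             correct = correct, stringsAsFactors = FALSE)
}

#' Simulate one survey response
#'
#' Single-item version of the respondent model, for inspection and tests;
#' [simulate_survey()] is the vectorized path used by the pipeline. Uses the
#' current RNG state.
#'
#' @param item one sampled item: a list or one-row data frame with at least
#'   `true_phase` and `modality`.
#' @param cfg a `respondent_config`.
#' @param schema the `phase_schema`.
#' @return A one-row data frame with `true_phase`, `answer`, `confidence`
#'   (1-5), `response_time_s` and `correct`.
#' @export
simulate_response <- function(item, cfg, schema) {
  answer_items(as.character(item$true_phase), as.character(item$modality),
               cfg, schema, z = stats::rnorm(1))
}

#' Simulate a full survey
#'
#' Each participant is assigned a distinct procedure (every procedure at
#' most once), the sampler draws that procedure's 17 timestamps, and the
#' participant answers all single-frame questions (shuffled) followed by all
#' snippet questions (shuffled independently), exactly as the survey
#' presented them.
#'
#' @param cohort named list of `procedure_timeline`s.
#' @param sampler_cfg a `sampler_config` (its `seed` field is ignored here;
#'   the survey `seed` governs all randomness).
#' @param respondents named list of `respondent_config`s, one per group.
#' @param group_sizes named integer vector of participants per group, names
#'   matching `respondents`; the total must not exceed the cohort size.
#' @param seed integer seed making the whole survey reproducible.
#' @details Procedures are assigned in a shuffled order, each at most once.
#'   A procedure whose geometry defeats the sampler (e.g. an opening phase
#'   too short to hold any snippet window) is skipped with a message and the
#'   participant receives the next unused procedure, mirroring a study pool
#'   larger than the participant count; the survey fails only if the pool
#'   runs out.
#' @return A list of class `spr_survey` with elements `responses` (one row
#'   per answer: `participant_id`, `group`, `procedure_id`, `item_id`,
#'   `modality`, `true_phase`, `answer`, `confidence`, `response_time_s`),
#'   `items` (all sampled items) and `assignments`.
#' @export
simulate_survey <- function(cohort, sampler_cfg, respondents, group_sizes,
                            seed = NULL) {
  stopifnot(all(names(group_sizes) %in% names(respondents)))
  total <- sum(group_sizes)
  if (total > length(cohort))
    stop("more participants (", total, ") than procedures (",
         length(cohort), "): every procedure may be assigned only once",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sampler_cfg$seed <- NULL
  schema <- cohort[[1L]]$schema
  pool <- sample.int(length(cohort))
  ptr <- 0L
  assigned <- integer(total)
  groups <- rep(names(group_sizes), times = group_sizes)
  pid <- sprintf("P%03d", seq_len(total))
  resp_list <- vector("list", total)
  item_list <- vector("list", total)
  for (i in seq_len(total)) {
    items <- NULL
    while (is.null(items)) {
      ptr <- ptr + 1L
      if (ptr > length(pool))
        stop("procedure pool exhausted: sampling failed for too many ",
             "procedures", call. = FALSE)
      assigned[i] <- pool[ptr]
      tl <- cohort[[assigned[i]]]
      items <- tryCatch(sample_procedure(tl, sampler_cfg),
                        error = function(e) {
                          message("skipping ", tl$procedure_id, ": ",
                                  conditionMessage(e))
                          NULL
                        })
    }
    cfg <- respondents[[groups[i]]]
    frames <- items[items$modality == "frame", , drop = FALSE]
    snips <- items[items$modality == "snippet", , drop = FALSE]
    z <- stats::rnorm(nrow(frames))  # shared per-timestamp difficulty
    ord_f <- sample.int(nrow(frames))
    ord_s <- sample.int(nrow(snips))
    ans_f <- answer_items(frames$true_phase[ord_f], "frame", cfg, schema,
                          z[ord_f])
    ans_s <- answer_items(snips$true_phase[ord_s], "snippet", cfg, schema,
                          z[ord_s])
    both <- rbind(
      cbind(frames[ord_f, c("procedure_id", "item_id", "modality")], ans_f),
      cbind(snips[ord_s, c("procedure_id", "item_id", "modality")], ans_s))
    both <- cbind(participant_id = pid[i], group = groups[i], both)
    resp_list[[i]] <- both
    item_list[[i]] <- items
  }
  responses <- do.call(rbind, resp_list)
  responses$correct <- NULL
  rownames(responses) <- NULL
  items <- unique(do.call(rbind, item_list))
  rownames(items) <- NULL
  structure(list(responses = responses, items = items,
                 assignments = data.frame(
                   participant_id = pid, group = groups,
                   procedure_id = names(cohort)[assigned],
                   stringsAsFactors = FALSE)),
            class = "spr_survey", seed = seed)
}

#' @export
print.spr_survey <- function(x, ...) {
  cat(sprintf("<spr_survey: %d participants, %d responses, %d items>\n",
              nrow(x$assignments), nrow(x$responses), nrow(x$items)))
  print(table(x$assignments$group))
  invisible(x)
}

#' Frame-level predictor configuration
#'
#' Desk-scale stand-in for a frame-classification model: at every annotated
#' second the predictor outputs the true phase with a per-phase probability,
#' otherwise a uniformly random wrong phase; an optional trailing
#' majority-vote window smooths the per-second stream, emulating temporal
#' context.
#'
#' @param p_correct scalar or per-phase named vector of per-second correct
#'   classification probabilities in `[0, 1]`.
#' @param smoothing_window_s trailing majority-vote window in seconds
#'   (default 1 = no smoothing).
#' @param seed optional integer seed used by [simulate_ai_predictions()].
#' @return A list of class `predictor_config`.
#' @export
predictor_config <- function(p_correct, smoothing_window_s = 1L,
                             seed = NULL) {
  stopifnot(all(p_correct >= 0), all(p_correct <= 1),
            smoothing_window_s >= 1L)
  structure(list(p_correct = p_correct,
                 smoothing_window_s = as.integer(smoothing_window_s),
                 seed = seed),
            class = "predictor_config")
}

#' Simulate per-second predictions for one procedure
#'
#' Emits one predicted label per second of annotated footage (1-Hz cadence,
#' each second scored at its midpoint), then applies the trailing
#' majority-vote smoother: the prediction at second `t` is the modal raw
#' prediction over the last `smoothing_window_s` seconds (ties keep the raw
#' prediction at `t`). The window never crosses footage gaps.
#'
#' @param timeline a `procedure_timeline`.
#' @param cfg a `predictor_config`.
#' @return Data frame with columns `procedure_id`, `time_s`,
#'   `predicted_phase`.
#' @export
simulate_ai_predictions <- function(timeline, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  schema <- timeline$schema
  t_all <- seq(floor(timeline_start(timeline)),
               ceiling(timeline_end(timeline)) - 1)
  truth <- phase_at(timeline, t_all + 0.5)
  keep <- !is.na(truth)
  t_all <- t_all[keep]
  truth <- truth[keep]
  n <- length(t_all)
  p <- cfg$p_correct
  pv <- if (length(p) == 1L) rep(p, n) else {
    if (!all(truth %in% names(p)))
      stop("p_correct must name every phase present in the timeline",
           call. = FALSE)
    unname(p[truth])
  }
  correct <- stats::runif(n) < pv
  raw <- truth
  wrong <- which(!correct)
  if (length(wrong)) {
    idx_true <- match(truth[wrong], schema$labels)
    pick <- floor(stats::runif(length(wrong)) * (schema$k - 1)) + 1L
    pick <- ifelse(pick >= idx_true, pick + 1L, pick)
    raw[wrong] <- schema$labels[pick]
  }
  w <- cfg$smoothing_window_s
  if (w <= 1L) {
    pred <- raw
  } else {
    pred <- raw
    for (i in seq_len(n)) {
      j <- i
      while (j > 1L && t_all[i] - t_all[j - 1L] < w &&
             t_all[j - 1L] == t_all[j] - 1L) j <- j - 1L
      votes <- raw[j:i]
      tab <- table(votes)
      top <- names(tab)[tab == max(tab)]
      pred[i] <- if (raw[i] %in% top) raw[i] else top[1L]
    }
  }
  data.frame(procedure_id = timeline$procedure_id, time_s = t_all,
             predicted_phase = pred, stringsAsFactors = FALSE)
}
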