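#' Survey sampler configuration
#'
#' Controls the constrained temporal sampling of survey questions from a
#' procedure timeline. Defaults are the benchmark's study values: 17
#' timestamps per procedure, at least one per phase, Gaussian draws around
#' each phase midpoint with sigma equal to 0.1 of the phase duration,
#' trimming of the outer 5% of phase time at each end (phase transitions are
#' ambiguous), a 30-s minimum spacing between timestamps, extra samples for
#' phases longer than 10 min, and a 10-s snippet window preceding each
#' sampled frame.
#'
#' @param n_samples timestamps per procedure (default 17).
#' @param min_gap_s minimum pairwise spacing between timestamps, seconds
#'   (default 30).
#' @param trim_lo,trim_hi trimmed fraction band of phase-relative time:
#'   draws must fall in `[trim_lo * D, trim_hi * D]` for a phase of duration
#'   `D` (defaults 0.05 and 0.95).
#' @param sigma_ratio Gaussian sigma as a fraction of phase duration
#'   (default 0.1).
#' @param oversample_threshold_s phases whose total duration exceeds this get
#'   the extra samples first (default 600 s = 10 min).
#' @param snippet_len_s snippet window length, seconds (default 10).
#' @param max_retries rejection-sampling budget per timestamp (default 1000).
#' @param allow_crossing may a snippet window cross into the preceding
#'   phase's footage? Default `FALSE`: timestamps are kept at phase-relative
#'   positions `>= snippet_len_s` whenever the trim band makes that feasible.
#' @param absent_phase policy when a schema phase is missing from the
#'   timeline: `"strict"` errors, `"lenient"` redistributes its quota with a
#'   message.
#' @param seed optional integer seed applied by [sample_procedure()].
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 17L, min_gap_s = 30, trim_lo = 0.05,
                           trim_hi = 0.95, sigma_ratio = 0.1,
                           oversample_threshold_s = 600, snippet_len_s = 10,
                           max_retries = 1000L, allow_crossing = FALSE,
                           absent_phase = c("strict", "lenient"),
                           seed = NULL) {
  stopifnot(n_samples >= 1L, min_gap_s >= 0, sigma_ratio > 0,
            snippet_len_s > 0, max_retries >= 1L)
  if (!(trim_lo >= 0 && trim_lo < trim_hi && trim_hi <= 1))
    stop("need 0 <= trim_lo < trim_hi <= 1", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), min_gap_s = min_gap_s,
                 trim_lo = trim_lo, trim_hi = trim_hi,
                 sigma_ratio = sigma_ratio,
                 oversample_threshold_s = oversample_threshold_s,
                 snippet_len_s = snippet_len_s,
                 max_retries = as.integer(max_retries),
                 allow_crossing = isTRUE(allow_crossing),
                 absent_phase = match.arg(absent_phase),
                 seed = seed),
            class = "sampler_config")
}

#' Allocate sample counts to phases
#'
#' Every phase present in the timeline receives one sample; the remaining
#' `n_samples - k` samples go one each to the phases whose duration exceeds
#' `oversample_threshold_s`, in descending duration order (ties broken by
#' schema order). If there are more extras than long phases, the surplus goes
#' to the longest remaining phases, wrapping around only after every phase
#' has received an extra.
#'
#' @param timeline a `procedure_timeline`.
#' @param config a `sampler_config`.
#' @return Named integer vector of per-phase counts (schema order, present
#'   phases only), summing to `n_samples`.
#' @export
allocate_samples <- function(timeline, config = sampler_config()) {
  schema <- timeline$schema
  dur <- vapply(schema$labels, function(p) phase_duration(timeline, p),
                numeric(1))
  absent <- names(dur)[dur <= 0]
  if (length(absent)) {
    if (config$absent_phase == "strict")
      stop("phase(s) absent from procedure '", timeline$procedure_id, "': ",
           paste(absent, collapse = ", "),
           " (use absent_phase = \"lenient\" to redistribute)", call. = FALSE)
    message("redistributing quota of absent phase(s): ",
            paste(absent, collapse = ", "))
    dur <- dur[dur > 0]
  }
  if (length(dur) == 0L)
    stop("timeline has no annotated phases", call. = FALSE)
  if (config$n_samples < length(dur))
    stop("n_samples (", config$n_samples, ") < number of present phases (",
         length(dur), ")", call. = FALSE)
  counts <- stats::setNames(rep(1L, length(dur)), names(dur))
  extras <- config$n_samples - length(dur)
  if (extras > 0L) {
    # descending duration, schema order breaks ties; long phases first
    ord <- order(-dur, seq_along(dur))
    long_first <- c(ord[dur[ord] > config$oversample_threshold_s],
                    ord[dur[ord] <= config$oversample_threshold_s])
    take <- long_first[(seq_len(extras) - 1L) %% length(long_first) + 1L]
    tab <- table(take)
    counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
      as.integer(tab)
  }
  counts
}

# phase-relative draw band [lo, hi] for one phase, honoring the trim
# fractions and (when feasible) the no-crossing snippet constraint. The
# constraint counts as feasible only when the phase midpoint -- the center
# of the draw distribution -- itself satisfies it; otherwise enforcing it
# would push draws into the far tail of the midpoint-centered normal, so
# the snippet is allowed to cross into the preceding footage instead.
phase_band <- function(D, config) {
  lo <- config$trim_lo * D
  hi <- config$trim_hi * D
  if (!config$allow_crossing && config$snippet_len_s <= 0.5 * D)
    lo <- max(lo, config$snippet_len_s)
  c(lo, hi)
}

# map phase-relative times (seconds of elapsed phase time) to absolute
# timestamps by walking the phase's segments in order
rel_to_abs <- function(timeline, phase, rel) {
  seg <- timeline$segments
  seg <- seg[seg$phase == phase, , drop = FALSE]
  dur <- seg$end_s - seg$start_s
  cum <- c(0, cumsum(dur))
  idx <- findInterval(rel, cum, rightmost.closed = TRUE)
  idx[idx > nrow(seg)] <- nrow(seg)
  seg$start_s[idx] + (rel - cum[idx])
}

#' Draw one timestamp inside a phase
#'
#' Draws phase-relative time from `Normal(0.5 * D, sigma_ratio * D)` for a
#' phase of total duration `D`, rejecting and redrawing until the draw falls
#' inside the trimmed band `[trim_lo * D, trim_hi * D]` (truncation by
#' rejection, not clipping, so the configured sigma is preserved). The
#' accepted phase-relative time is mapped to an absolute timestamp by
#' walking the phase's segments in order. Uses the current RNG state.
#'
#' @param timeline a `procedure_timeline`.
#' @param phase a schema label present in the timeline.
#' @param config a `sampler_config`.
#' @return Absolute timestamp in seconds.
#' @export
sample_phase_timestamp <- function(timeline, phase, config = sampler_config()) {
  D <- phase_duration(timeline, phase)
  if (D <= 0)
    stop("phase '", phase, "' absent from procedure '",
         timeline$procedure_id, "'", call. = FALSE)
  band <- c(config$trim_lo * D, config$trim_hi * D)
  tries <- 0L
  while (tries < config$max_retries) {
    m <- min(64L, config$max_retries - tries)
    x <- stats::rnorm(m, mean = 0.5 * D, sd = config$sigma_ratio * D)
    tries <- tries + m
    ok <- which(x >= band[1L] & x <= band[2L])
    if (length(ok))
      return(rel_to_abs(timeline, phase, x[ok[1L]]))
  }
  stop("retries exhausted drawing a timestamp for phase '", phase, "'",
       call. = FALSE)
}

# one constrained draw for sample_procedure: trim band, snippet-in-footage,
# and spacing against already-accepted timestamps; returns abs time or NA
draw_constrained <- function(timeline, phase, D, band, accepted, config) {
  tries <- 0L
  while (tries < config$max_retries) {
    m <- min(64L, config$max_retries - tries)
    rel <- stats::rnorm(m, mean = 0.5 * D, sd = config$sigma_ratio * D)
    tries <- tries + m
    rel <- rel[rel >= band[1L] & rel <= band[2L]]
    if (!length(rel)) next
    t_abs <- rel_to_abs(timeline, phase, rel)
    keep <- in_footage(timeline, t_abs - config$snippet_len_s, t_abs) &
      t_abs - config$snippet_len_s >= timeline_start(timeline)
    t_abs <- t_abs[keep]
    if (!length(t_abs)) next
    if (length(accepted)) {
      far <- vapply(t_abs,
                    function(t) min(abs(t - accepted)) >= config$min_gap_s,
                    logical(1))
      t_abs <- t_abs[far]
    }
    if (length(t_abs)) return(t_abs[1L])
  }
  NA_real_
}

#' Sample the survey questions for one procedure
#'
#' Draws `n_samples` timestamps (per [allocate_samples()]) subject to the
#' trim band of each phase, a minimum pairwise spacing, and the requirement
#' that each timestamp's preceding snippet window lies entirely inside
#' annotated footage. Every timestamp yields two items: the single frame at
#' the timestamp and the video snippet of the `snippet_len_s` seconds
#' preceding it. If spacing cannot be satisfied for some draw, the most
#' crowded phase's draws are discarded and resampled once before giving up.
#' Deterministic given `config$seed`.
#'
#' @param timeline a `procedure_timeline`.
#' @param config a `sampler_config`.
#' @return Data frame of sampled items with columns `procedure_id`,
#'   `item_id`, `timestamp_s`, `true_phase`, `modality` (`"frame"` or
#'   `"snippet"`), `window_start_s`, `window_end_s` (NA for frames). Two rows
#'   (one per modality) share each timestamp.
#' @examples
#' cfg <- cohort_config(rapn_schema(), rapn_durations(), n_procedures = 1,
#'                      family = "degenerate", seed = 1)
#' tl <- simulate_cohort(cfg)[[1]]
#' items <- sample_procedure(tl, sampler_config(seed = 42))
#' table(items$modality)
#' @export
sample_procedure <- function(timeline, config = sampler_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  counts <- allocate_samples(timeline, config)
  phases <- names(counts)
  Ds <- vapply(phases, function(p) phase_duration(timeline, p), numeric(1))
  bands <- lapply(Ds, phase_band, config = config)
  acc_t <- numeric(0)
  acc_p <- character(0)
  need <- counts
  relaxed <- FALSE
  while (any(need > 0L)) {
    ph <- phases[which(need > 0L)[1L]]
    t <- draw_constrained(timeline, ph, Ds[[ph]], bands[[ph]], acc_t, config)
    if (is.na(t)) {
      if (!relaxed && length(acc_p)) {
        # relax once: discard and resample the most crowded phase's draws
        relaxed <- TRUE
        tab <- table(acc_p)
        crowd <- names(tab)[which.max(tab)]
        keep <- acc_p != crowd
        acc_t <- acc_t[keep]
        acc_p <- acc_p[keep]
        need[crowd] <- counts[[crowd]]
        next
      }
      stop("could not satisfy the ", config$min_gap_s,
           "-s spacing constraint for phase '", ph, "' in procedure '",
           timeline$procedure_id, "'", call. = FALSE)
    }
    acc_t <- c(acc_t, t)
    acc_p <- c(acc_p, ph)
    need[ph] <- need[ph] - 1L
  }

  ord <- order(acc_t)
  ts <- acc_t[ord]
  ph <- acc_p[ord]
  n <- length(ts)
  base <- sprintf("%s-%02d", timeline$procedure_id, seq_len(n))
  frames <- data.frame(procedure_id = timeline$procedure_id,
                       item_id = paste0(base, "-frame"),
                       timestamp_s = ts, true_phase = ph,
                       modality = "frame",
                       window_start_s = NA_real_, window_end_s = NA_real_,
                       stringsAsFactors = FALSE)
  snips <- frames
  snips$item_id <- paste0(base, "-snippet")
  snips$modality <- "snippet"
  snips$window_start_s <- ts - config$snippet_len_s
  snips$window_end_s <- ts
  out <- rbind(frames, snips)
  rownames(out) <- NULL
  out
}

#' Snippet window preceding a timestamp
#'
#' The half-open window of the `snippet_len_s` seconds preceding the sampled
#' frame: `[timestamp_s - snippet_len_s, timestamp_s)`.
#'
#' @param timestamp_s sampled timestamp, seconds.
#' @param config a `sampler_config`.
#' @param footage_start_s start of available footage (default 0).
#' @return Numeric vector `c(start_s, end_s)` of length exactly
#'   `snippet_len_s`.
#' @export
snippet_window <- function(timestamp_s, config = sampler_config(),
                           footage_start_s = 0) {
  stopifnot(is.numeric(timestamp_s), length(timestamp_s) == 1L)
  start <- timestamp_s - config$snippet_len_s
  if (start < footage_start_s)
    stop("snippet window would precede footage start (timestamp ",
         timestamp_s, " s, window start ", start, " s)", call. = FALSE)
  c(start_s = start, end_s = timestamp_s)
}

#' Write / read sampled-item tables
#'
#' Items CSV with header
#' `procedure_id,item_id,timestamp_s,true_phase,modality,window_start_s,window_end_s`.
#'
#' @param items data frame from [sample_procedure()] (or several rbind-ed).
#' @param path CSV path.
#' @return `path` (write) or the items data frame (read).
#' @export
write_items <- function(items, path) {
  utils::write.csv(items, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_items
#' @export
read_items <- function(path) {
  if (!file.exists(path)) stop("items file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
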