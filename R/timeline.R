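#' Procedure timelines: ordered, labeled time segments
#'
#' A procedure timeline is the ground-truth phase annotation of one recorded
#' procedure: an ordered list of non-overlapping half-open segments
#' `[start_s, end_s)` in seconds, each carrying a schema phase label. Gaps
#' between segments are legal and represent discarded footage (out-of-body
#' sequences, ambiguous transitions); samplers never draw from gaps. A phase
#' may recur in several segments (nonlinear workflow); its duration is the
#' sum over its segments.
#'
#' @param procedure_id identifier for the procedure.
#' @param segments data frame with columns `phase`, `start_s`, `end_s`
#'   (seconds, numeric). Rows are sorted by `start_s` internally.
#' @param schema the `phase_schema` the labels belong to.
#' @return An object of class `procedure_timeline`: a list with elements
#'   `procedure_id`, `segments` (sorted data frame) and `schema`.
#' @examples
#' sch <- phase_schema("toy", c("A", "B"))
#' tl <- procedure_timeline("p1",
#'   data.frame(phase = c("A", "B"), start_s = c(0, 60), end_s = c(60, 150)),
#'   sch)
#' phase_at(tl, 75)
#' @export
procedure_timeline <- function(procedure_id, segments, schema) {
  stopifnot(inherits(schema, "phase_schema"))
  procedure_id <- as.character(procedure_id)
  stopifnot(length(procedure_id) == 1L, nzchar(procedure_id))
  req <- c("phase", "start_s", "end_s")
  if (!all(req %in% names(segments)))
    stop("segments need columns: ", paste(req, collapse = ", "), call. = FALSE)
  segments <- data.frame(phase = as.character(segments$phase),
                         start_s = as.numeric(segments$start_s),
                         end_s = as.numeric(segments$end_s),
                         stringsAsFactors = FALSE)
  if (nrow(segments) == 0L)
    stop("a timeline needs at least one segment", call. = FALSE)
  assert_labels(schema, segments$phase)
  if (any(!is.finite(segments$start_s)) || any(!is.finite(segments$end_s)))
    stop("segment bounds must be finite", call. = FALSE)
  if (any(segments$start_s < 0))
    stop("segment start times must be >= 0", call. = FALSE)
  if (any(segments$end_s <= segments$start_s))
    stop("every segment must have end_s > start_s", call. = FALSE)
  segments <- segments[order(segments$start_s, segments$end_s), , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1L) {
    ov <- which(segments$start_s[-1L] < segments$end_s[-nrow(segments)])
    if (length(ov))
      stop("overlapping segments in procedure '", procedure_id,
           "' (segment ", ov[1L], " overlaps segment ", ov[1L] + 1L, ")",
           call. = FALSE)
  }
  structure(list(procedure_id = procedure_id, segments = segments,
                 schema = schema),
            class = "procedure_timeline")
}

#' @export
print.procedure_timeline <- function(x, ...) {
  cat(sprintf("<procedure_timeline '%s': %d segments, %.1f s annotated, ends %.1f s>\n",
              x$procedure_id, nrow(x$segments),
              sum(x$segments$end_s - x$segments$start_s),
              timeline_end(x)))
  invisible(x)
}

#' @rdname procedure_timeline
#' @param timeline a `procedure_timeline`.
#' @export
timeline_end <- function(timeline) {
  max(timeline$segments$end_s)
}

#' @rdname procedure_timeline
#' @export
timeline_start <- function(timeline) {
  min(timeline$segments$start_s)
}

#' Total annotated duration of one phase
#'
#' Sums the durations of all segments carrying the label, supporting
#' recurring (nonlinear) phases. Returns 0 for a schema phase absent from
#' the timeline.
#'
#' @param timeline a `procedure_timeline`.
#' @param phase a schema label.
#' @return Duration in seconds.
#' @export
phase_duration <- function(timeline, phase) {
  stopifnot(length(phase) == 1L)
  assert_labels(timeline$schema, phase)
  seg <- timeline$segments
  sum(seg$end_s[seg$phase == phase] - seg$start_s[seg$phase == phase])
}

#' Phase label at a time point
#'
#' Segments are half-open `[start_s, end_s)`: the start instant belongs to
#' the segment, the end instant does not. Time points in gaps or at/after the
#' end of the last segment return `NA`.
#'
#' @param timeline a `procedure_timeline`.
#' @param t numeric vector of time points in seconds, all `>= 0`.
#' @return Character vector of labels, `NA` where `t` falls outside
#'   annotated footage.
#' @export
phase_at <- function(timeline, t) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("time points must be finite and >= 0", call. = FALSE)
  seg <- timeline$segments
  # segments are sorted and disjoint: locate by start, then check end
  idx <- findInterval(t, seg$start_s)
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1L
  ok[ok] <- t[ok] < seg$end_s[idx[ok]]
  out[ok] <- seg$phase[idx[ok]]
  out
}

#' In-footage test for intervals
#'
#' TRUE when the closed-open interval `[start, end)` lies entirely inside
#' annotated footage (crosses no gap and does not precede the first segment).
#' Adjacent contiguous segments count as continuous footage.
#'
#' @param timeline a `procedure_timeline`.
#' @param start,end interval bounds in seconds (vectors of equal length).
#' @return Logical vector.
#' @export
in_footage <- function(timeline, start, end) {
  stopifnot(length(start) == length(end))
  seg <- timeline$segments
  # merge contiguous segments into maximal footage blocks
  brk <- c(TRUE, seg$start_s[-1L] > seg$end_s[-nrow(seg)])
  block <- cumsum(brk)
  bs <- tapply(seg$start_s, block, min)
  be <- tapply(seg$end_s, block, max)
  idx <- findInterval(start, bs)
  ok <- idx >= 1L
  ok[ok] <- end[ok] <= be[idx[ok]] & start[ok] >= bs[idx[ok]]
  ok
}

#' Read segment annotations from CSV
#'
#' Expects a UTF-8 CSV with header `procedure_id,phase,start_s,end_s` and `.`
#' as decimal separator. Rows may appear in any order; segments are sorted
#' per procedure. Labels are validated against the schema and overlaps
#' rejected.
#'
#' @param path CSV file path.
#' @param schema a `phase_schema`.
#' @return A named list of `procedure_timeline` objects, one per
#'   `procedure_id`, in first-appearance order.
#' @export
read_segments <- function(path, schema) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("procedure_id", "phase", "start_s", "end_s")
  if (!all(req %in% names(df)))
    stop("segment CSV needs header: ", paste(req, collapse = ","),
         call. = FALSE)
  bad <- which(!(df$phase %in% schema$labels))
  if (length(bad))
    stop("row ", bad[1L], ": unknown phase label '", df$phase[bad[1L]],
         "' for schema '", schema$name, "'", call. = FALSE)
  ids <- unique(as.character(df$procedure_id))
  out <- lapply(ids, function(id) {
    procedure_timeline(id, df[df$procedure_id == id, , drop = FALSE], schema)
  })
  names(out) <- ids
  out
}

#' Write segment annotations to CSV
#'
#' Inverse of [read_segments()]: rows are written per timeline in segment
#' order with header `procedure_id,phase,start_s,end_s`.
#'
#' @param timelines a `procedure_timeline` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(timelines, path) {
  if (inherits(timelines, "procedure_timeline")) timelines <- list(timelines)
  rows <- do.call(rbind, lapply(timelines, function(tl) {
    cbind(procedure_id = tl$procedure_id, tl$segments)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert per-frame labels to segments
#'
#' Maximal runs of identical labels become half-open segments with
#' boundaries at run changes; frame `i` (0-based) covers time
#' `[i/fps, (i+1)/fps)`, so the segments of `n` frames partition
#' `[0, n/fps)` exactly.
#'
#' @param per_frame_labels character vector of labels, one per frame,
#'   frame 0 first.
#' @param fps frames per second, `> 0`.
#' @return Data frame with columns `phase`, `start_s`, `end_s`.
#' @examples
#' frames_to_segments(c("A", "A", "B", "B", "B"), fps = 1)
#' @export
frames_to_segments <- function(per_frame_labels, fps) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  lab <- as.character(per_frame_labels)
  if (length(lab) == 0L)
    stop("per-frame label vector is empty", call. = FALSE)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(phase = r$values,
             start_s = starts / fps,
             end_s = ends / fps,
             stringsAsFactors = FALSE)
}

#' Read a Cholec80-style per-frame label table
#'
#' Two-column tab-separated file `Frame<TAB>Phase` with one header line and
#' 0-based ascending frame indices. Returns the label vector; combine with
#' [frames_to_segments()] and the recording's frame rate to obtain segments.
#'
#' @param path file path.
#' @return Character vector of per-frame labels.
#' @export
read_frame_labels <- function(path) {
  if (!file.exists(path))
    stop("frame-label file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expected two tab-separated columns (Frame, Phase)", call. = FALSE)
  frames <- as.integer(df[[1L]])
  if (any(diff(frames) != 1L) || frames[1L] != 0L)
    stop("frame indices must be 0-based and consecutive", call. = FALSE)
  as.character(df[[2L]])
}
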