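#' Phase schemas and per-phase duration tables
#'
#' A phase schema is the ordered set of workflow phase labels a procedure is
#' annotated with. Order matters: it is the canonical temporal order of the
#' workflow, and the respondent simulator's adjacency-confusion kernel is
#' defined over it.
#'
#' @param name identifier for the schema (e.g. `"rapn"`).
#' @param labels character vector of unique, non-empty phase names in
#'   canonical workflow order; at least two.
#' @return An object of class `phase_schema` with elements `name`, `labels`
#'   and `k` (the number of phases).
#' @examples
#' sch <- phase_schema("toy", c("A", "B", "C"))
#' sch$k
#' @export
phase_schema <- function(name, labels) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a phase schema needs at least 2 labels", call. = FALSE)
  if (anyDuplicated(labels))
    stop("phase labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(labels)))
    stop("phase labels must be non-empty", call. = FALSE)
  structure(list(name = name, labels = labels, k = length(labels)),
            class = "phase_schema")
}

#' @export
print.phase_schema <- function(x, ...) {
  cat(sprintf("<phase_schema '%s': %d phases>\n", x$name, x$k))
  cat(paste0("  ", seq_along(x$labels), ". ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname phase_schema
#' @param schema a `phase_schema`.
#' @param label character vector of labels to check.
#' @export
assert_labels <- function(schema, label) {
  bad <- setdiff(unique(label), schema$labels)
  if (length(bad))
    stop("unknown phase label(s) for schema '", schema$name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' The 15-phase robot-assisted partial nephrectomy (RAPN) schema
#'
#' Canonical order of the fifteen annotated RAPN phases, from surgical access
#' through instrument removal. RAPN is a highly nonlinear procedure: phases
#' may recur, and the segment model supports that, but this schema order is
#' the canonical workflow sequence.
#'
#' @return A `phase_schema` with `k = 15`.
#' @export
rapn_schema <- function() {
  phase_schema("rapn", c(
    "Port insertion and surgical access",
    "Colon (and spleen) mobilisation",
    "General hilar control",
    "Selective hilar control",
    "Kidney mobilisation",
    "Tumour identification",
    "Hilar clamping",
    "Tumour excision",
    "Inner renorrhaphy",
    "Hilar unclamping",
    "Outer renorrhaphy",
    "Specimen retrieval",
    "Specimen removal and closing",
    "Retroperitonealisation of the Kidney",
    "Instrument removal"
  ))
}

#' The 7-phase laparoscopic cholecystectomy (Cholec80-style) schema
#'
#' @return A `phase_schema` with `k = 7`.
#' @export
cholec80_schema <- function() {
  phase_schema("cholec80", c(
    "Preparation",
    "Calot triangle dissection",
    "Clipping and cutting",
    "Gallbladder dissection",
    "Gallbladder packaging",
    "Cleaning and coagulation",
    "Gallbladder retraction"
  ))
}

#' Per-phase duration tables (mean and SD, minutes)
#'
#' A duration table gives, for every label of a schema, the mean and standard
#' deviation of that phase's duration in minutes. `rapn_durations()` and
#' `cholec80_durations()` return the published per-phase duration statistics
#' for the two schemas; `duration_table()` builds and validates a custom one.
#'
#' @param schema a `phase_schema`.
#' @param mean_min positive numeric vector of per-phase mean durations
#'   (minutes), one per schema label, in schema order.
#' @param sd_min non-negative numeric vector of per-phase duration SDs
#'   (minutes).
#' @return A data frame of class `duration_table` with columns `phase`,
#'   `mean_min`, `sd_min`, one row per schema label in schema order.
#' @examples
#' head(rapn_durations())
#' sum(rapn_durations()$mean_min)  # 147.9 minutes
#' @export
duration_table <- function(schema, mean_min, sd_min) {
  stopifnot(inherits(schema, "phase_schema"))
  mean_min <- as.numeric(mean_min)
  sd_min <- as.numeric(sd_min)
  if (length(mean_min) != schema$k || length(sd_min) != schema$k)
    stop("need exactly one (mean, sd) pair per schema label", call. = FALSE)
  if (any(!is.finite(mean_min)) || any(mean_min <= 0))
    stop("mean durations must be positive", call. = FALSE)
  if (any(!is.finite(sd_min)) || any(sd_min < 0))
    stop("duration SDs must be non-negative", call. = FALSE)
  structure(
    data.frame(phase = schema$labels, mean_min = mean_min, sd_min = sd_min,
               stringsAsFactors = FALSE),
    class = c("duration_table", "data.frame"),
    schema_name = schema$name
  )
}

#' @rdname duration_table
#' @export
rapn_durations <- function() {
  duration_table(
    rapn_schema(),
    mean_min = c(9.2, 14.2, 13.7, 12.3, 23.8, 16.9, 2.0, 12.1,
                 9.6, 4.0, 10.4, 3.0, 5.6, 6.9, 4.2),
    sd_min   = c(9.7, 10.3, 11.7, 11.5, 17.8, 15.7, 4.7, 16.9,
                 7.5, 8.8, 6.6, 7.7, 10.6, 4.4, 3.9)
  )
}

#' @rdname duration_table
#' @export
cholec80_durations <- function() {
  duration_table(
    cholec80_schema(),
    mean_min = c(2.1, 15.9, 2.8, 14.3, 1.6, 3.0, 1.4),
    sd_min   = c(1.6, 9.0, 2.5, 9.2, 0.9, 2.8, 0.9)
  )
}

#' Look up a bundled schema by name
#'
#' @param name `"rapn"` or `"cholec80"`.
#' @return The corresponding `phase_schema`.
#' @export
get_schema <- function(name) {
  switch(match.arg(name, c("rapn", "cholec80")),
         rapn = rapn_schema(),
         cholec80 = cholec80_schema())
}

#' @rdname get_schema
#' @export
get_durations <- function(name) {
  switch(match.arg(name, c("rapn", "cholec80")),
         rapn = rapn_durations(),
         cholec80 = cholec80_durations())
}
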