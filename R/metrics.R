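#' Confusion matrix over a phase schema
#'
#' Builds the k-by-k count matrix with rows indexing the true phase and
#' columns the answered (or predicted) phase, over the full schema — phases
#' never encountered keep zero rows/columns so matrices from different
#' raters are always conformable.
#'
#' @param truths character vector of true phase labels.
#' @param answers character vector of answered/predicted labels, same length.
#' @param schema a `phase_schema`.
#' @return A k-by-k integer matrix of class `spr_confusion` with the schema
#'   attached as attribute `schema`.
#' @examples
#' sch <- phase_schema("toy", c("A", "B"))
#' confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), sch)
#' @export
confusion_matrix <- function(truths, answers, schema) {
  stopifnot(inherits(schema, "phase_schema"))
  if (length(truths) != length(answers))
    stop("truths and answers differ in length (", length(truths), " vs ",
         length(answers), ")", call. = FALSE)
  assert_labels(schema, truths)
  assert_labels(schema, answers)
  f <- factor(truths, levels = schema$labels)
  g <- factor(answers, levels = schema$labels)
  m <- table(true = f, answered = g)
  m <- matrix(as.integer(m), nrow = schema$k,
              dimnames = list(true = schema$labels,
                              answered = schema$labels))
  structure(m, class = c("spr_confusion", class(m)), schema = schema)
}

cm_schema <- function(cm) {
  sch <- attr(cm, "schema")
  if (is.null(sch)) stop("not an spr_confusion matrix", call. = FALSE)
  sch
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm an `spr_confusion` matrix with at least one count.
#' @return Fraction correct in `[0, 1]`: trace over total.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Support-weighted F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall, defined as 0 when
#' precision + recall is 0) averaged with weights equal to each class's true
#' support over the total; zero-support classes contribute nothing.
#'
#' @param cm an `spr_confusion` matrix with at least one count.
#' @return Weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  f1 <- numeric(length(tp))
  denom <- support + predicted  # = tp/(prec) + tp/(rec) denominators combined
  nz <- denom > 0
  f1[nz] <- 2 * tp[nz] / denom[nz]
  sum(f1 * support) / total
}

#' L-half spread of one confusion-matrix row
#'
#' For a probability vector p over k phases the statistic is
#' `(sum_i sqrt(p_i))^2`. It equals 1 for a one-hot vector (all mass on one
#' phase) and k for the uniform vector (maximal spread), so it measures how
#' dispersed a rater's answers are when the true phase is fixed.
#'
#' @param p numeric vector with non-negative entries summing to 1 (within
#'   1e-9).
#' @return A value in `[1, k]`.
#' @examples
#' lhalf_row(c(1, 0, 0))          # 1
#' lhalf_row(rep(1 / 15, 15))     # 15
#' @export
lhalf_row <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0))
    stop("row must be a probability vector (non-negative entries)",
         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("row must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  sum(sqrt(p))^2
}

#' Normalized L-half confusion spread
#'
#' Each positive-support row of the confusion matrix is normalized to
#' probabilities and scored with [lhalf_row()]; the row scores are averaged
#' and rescaled from `[1, k]` to `[0, 1]`: 0 means every row is one-hot (a
#' perfectly concentrated rater, not necessarily a correct one) and 1 means
#' every row is uniform (maximal confusion). Zero-support rows (phases never
#' asked) are excluded from the average.
#'
#' @param cm an `spr_confusion` matrix with at least one positive-support
#'   row.
#' @return Spread in `[0, 1]`.
#' @export
lhalf_spread <- function(cm) {
  k <- cm_schema(cm)$k
  support <- rowSums(cm)
  rows <- which(support > 0)
  if (!length(rows)) stop("all confusion-matrix rows are empty", call. = FALSE)
  scores <- vapply(rows,
                   function(i) lhalf_row(cm[i, ] / support[i]),
                   numeric(1))
  (mean(scores) - 1) / (k - 1)
}

#' All three benchmark metrics at once
#'
#' @param cm an `spr_confusion` matrix.
#' @return A one-row data frame with `accuracy`, `weighted_f1`,
#'   `lhalf_normalized` and `n` (responses scored).
#' @export
metric_set <- function(cm) {
  data.frame(accuracy = accuracy(cm),
             weighted_f1 = weighted_f1(cm),
             lhalf_normalized = lhalf_spread(cm),
             n = sum(cm))
}
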