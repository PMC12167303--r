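# shared fixtures and independent oracles

toy_schema <- function(k = 3L, name = "toy") {
  phase_schema(name, LETTERS[seq_len(k)])
}

# timeline with contiguous segments from a named duration vector (seconds)
toy_timeline <- function(durs, schema, id = "p1") {
  ends <- cumsum(durs)
  procedure_timeline(id,
    data.frame(phase = names(durs), start_s = c(0, ends[-length(ends)]),
               end_s = ends),
    schema)
}

# brute-force two-sided signed-rank p-value by enumerating all 2^n sign
# assignments; independent of psignrank
wilcox_enum_p <- function(a, b) {
  d <- (b - a)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  M <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  mean(pmin(w_plus, M - w_plus) <= w_obs)
}

# naive per-element metric oracles (loops, no matrix algebra)
naive_accuracy <- function(truths, answers) {
  mean(truths == answers)
}

naive_weighted_f1 <- function(truths, answers, labels) {
  n <- length(truths)
  total <- 0
  for (lab in labels) {
    support <- sum(truths == lab)
    if (support == 0) next
    tp <- sum(truths == lab & answers == lab)
    fp <- sum(truths != lab & answers == lab)
    fn <- sum(truths == lab & answers != lab)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    total <- total + f1 * support / n
  }
  total
}

random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# phase-relative elapsed time of an absolute timestamp within its phase
phase_relative <- function(timeline, t) {
  ph <- phase_at(timeline, t)
  seg <- timeline$segments
  seg <- seg[seg$phase == ph, , drop = FALSE]
  rel <- 0
  for (i in seq_len(nrow(seg))) {
    if (t >= seg$end_s[i]) {
      rel <- rel + seg$end_s[i] - seg$start_s[i]
    } else {
      rel <- rel + t - seg$start_s[i]
      break
    }
  }
  rel
}

default_respondents <- function(boost = 0.10) {
  list(
    "medical-student" = respondent_config("medical-student", 0.303, boost),
    "surgical-trainee" = respondent_config("surgical-trainee", 0.415, boost),
    "consultant" = respondent_config("consultant", 0.412, boost))
}
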