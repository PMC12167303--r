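rapn_degenerate <- function() {
  cfg <- cohort_config(rapn_schema(), rapn_durations(), 1,
                       family = "degenerate", seed = 1)
  simulate_cohort(cfg)[[1]]
}

test_that("allocation covers every phase and oversamples the long ones", {
  tl <- rapn_degenerate()
  counts <- allocate_samples(tl, sampler_config())
  expect_equal(sum(counts), 17L)
  expect_true(all(counts >= 1L))
  # the two extras go to the two longest phases over the 10-min threshold
  expect_identical(counts[["Kidney mobilisation"]], 2L)
  expect_identical(counts[["Tumour identification"]], 2L)
  expect_true(all(counts[setdiff(names(counts),
    c("Kidney mobilisation", "Tumour identification"))] == 1L))
})

test_that("allocation falls back to the longest phases when none are long", {
  sch <- phase_schema("s", c("A", "B", "C", "D"))
  tl <- toy_timeline(c(A = 100, B = 400, C = 300, D = 200), sch)
  counts <- allocate_samples(tl, sampler_config(n_samples = 6L))
  expect_equal(sum(counts), 6L)
  expect_identical(counts[["B"]], 2L)  # longest
  expect_identical(counts[["C"]], 2L)  # second longest
  expect_identical(counts[["A"]], 1L)
})

test_that("absent phases follow the configured policy", {
  sch <- toy_schema(2)
  tl <- procedure_timeline("p1",
    data.frame(phase = "A", start_s = 0, end_s = 500), sch)
  expect_error(allocate_samples(tl, sampler_config(n_samples = 3L)),
               "absent")
  counts <- suppressMessages(
    allocate_samples(tl, sampler_config(n_samples = 3L,
                                        absent_phase = "lenient")))
  expect_identical(counts, c(A = 3L))
})

test_that("phase timestamps respect the trimmed band", {
  sch <- toy_schema(2)
  tl <- procedure_timeline("iso",
    data.frame(phase = "A", start_s = 0, end_s = 6000), sch)
  set.seed(11)
  draws <- replicate(500, sample_phase_timestamp(tl, "A"))
  expect_true(all(draws >= 300 & draws <= 5700))
  expect_error(sample_phase_timestamp(tl, "B"), "absent")
})

test_that("phase-relative draws map across recurring segments", {
  sch <- toy_schema(2)
  tl <- procedure_timeline("rec",
    data.frame(phase = c("A", "B", "A"), start_s = c(0, 1000, 4000),
               end_s = c(1000, 4000, 7000)),
    sch)
  # phase A has 4000 s total; every draw must land inside one of its segments
  set.seed(3)
  draws <- replicate(300, sample_phase_timestamp(tl, "A"))
  expect_true(all(phase_at(tl, draws) == "A"))
  rel <- vapply(draws, function(t) phase_relative(tl, t), numeric(1))
  expect_true(all(rel >= 0.05 * 4000 & rel <= 0.95 * 4000))
})

test_that("draw distribution matches the trimmed midpoint normal", {
  sch <- toy_schema(2)
  tl <- procedure_timeline("iso",
    data.frame(phase = "A", start_s = 0, end_s = 6000), sch)
  set.seed(202)
  draws <- replicate(10000, sample_phase_timestamp(tl, "A"))
  lo <- 300; hi <- 5700; mu <- 3000; sig <- 600
  tcdf <- function(x) {
    (pnorm(x, mu, sig) - pnorm(lo, mu, sig)) /
      (pnorm(hi, mu, sig) - pnorm(lo, mu, sig))
  }
  ks <- suppressWarnings(ks.test(draws, tcdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("snippet windows subtract exactly the snippet length", {
  cfg <- sampler_config()
  expect_equal(snippet_window(500, cfg), c(start_s = 490, end_s = 500))
  w <- snippet_window(500, cfg)
  expect_equal(unname(diff(w)), 10)
  expect_error(snippet_window(5, cfg), "precede")
})

test_that("a sampled procedure satisfies every sampler invariant", {
  tl <- rapn_degenerate()
  cfg <- sampler_config(seed = 99)
  items <- sample_procedure(tl, cfg)
  ts <- sort(unique(items$timestamp_s))
  expect_length(ts, 17L)
  expect_identical(sum(items$modality == "frame"), 17L)
  expect_identical(sum(items$modality == "snippet"), 17L)
  expect_length(unique(items$true_phase), 15L)
  expect_true(min(diff(ts)) >= 30)
  snips <- items[items$modality == "snippet", ]
  expect_equal(snips$window_end_s - snips$window_start_s, rep(10, 17))
  expect_equal(snips$window_end_s, snips$timestamp_s)
  # items' true phases agree with the timeline
  expect_identical(items$true_phase, phase_at(tl, items$timestamp_s))

  # determinism: the same seed reproduces the item list bit-for-bit
  expect_identical(items, sample_procedure(tl, cfg))
})

test_that("sampling invariants hold across seeds and stochastic timelines", {
  ccfg <- cohort_config(rapn_schema(), rapn_durations(), 1)
  for (s in 1:20) {
    set.seed(s)
    tl <- simulate_timeline(ccfg, sprintf("p%02d", s))
    items <- tryCatch(sample_procedure(tl, sampler_config()),
                      error = function(e) NULL)
    if (is.null(items)) next  # infeasible geometry is a documented error
    ts <- sort(unique(items$timestamp_s))
    expect_length(ts, 17L)
    expect_true(min(diff(ts)) >= 30)
    for (t in ts) {
      D <- phase_duration(tl, phase_at(tl, t))
      rel <- phase_relative(tl, t)
      expect_true(rel >= 0.05 * D - 1e-9 && rel <= 0.95 * D + 1e-9)
    }
    snips <- items[items$modality == "snippet", ]
    expect_true(all(in_footage(tl, snips$window_start_s, snips$window_end_s)))
  }
})

test_that("snippets never cross into a gap", {
  sch <- toy_schema(3)
  # B is preceded by a gap: windows drawn near its start must be rejected
  tl <- procedure_timeline("gap",
    data.frame(phase = c("A", "B"), start_s = c(0, 1000),
               end_s = c(600, 1600)),
    sch)
  cfg <- sampler_config(n_samples = 2L, absent_phase = "lenient")
  for (s in 1:10) {
    cfg$seed <- s
    items <- suppressMessages(sample_procedure(tl, cfg))
    snips <- items[items$modality == "snippet", ]
    expect_true(all(in_footage(tl, snips$window_start_s,
                               snips$window_end_s)))
  }
})
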