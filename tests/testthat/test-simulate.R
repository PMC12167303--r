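test_that("the degenerate family reproduces the published means exactly", {
  cfg <- cohort_config(rapn_schema(), rapn_durations(), 1,
                       family = "degenerate", seed = 1)
  tl <- simulate_cohort(cfg)[[1]]
  expect_equal(timeline_end(tl) / 60, 147.9)  # sum of the mean column
  durs <- vapply(rapn_schema()$labels,
                 function(p) phase_duration(tl, p) / 60, numeric(1))
  expect_equal(unname(durs), rapn_durations()$mean_min)
})

test_that("cohorts are reproducible and distinct across procedures", {
  cfg <- cohort_config(cholec80_schema(), cholec80_durations(), 3, seed = 7)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(names(c1), c("proc001", "proc002", "proc003"))
  expect_identical(c1, c2)
  expect_false(identical(c1[[1]]$segments, c1[[2]]$segments))
})

test_that("lognormal durations recover the published moments", {
  cfg <- cohort_config(rapn_schema(), rapn_durations(), 300, seed = 31)
  cohort <- simulate_cohort(cfg)
  km <- vapply(cohort, function(tl)
    phase_duration(tl, "Kidney mobilisation") / 60, numeric(1))
  # mean within 3 standard errors of 23.8 (sd 17.8)
  expect_lt(abs(mean(km) - 23.8), 3 * 17.8 / sqrt(300))
  expect_lt(abs(sd(km) - 17.8), 3 * 17.8 / sqrt(150))  # loose sd check
  expect_true(all(km > 0))
})

test_that("the truncated-normal family warns and falls back when sd >= mean", {
  cfg <- cohort_config(rapn_schema(), rapn_durations(), 1,
                       family = "truncated-normal", seed = 5)
  set.seed(5)
  w <- capture_warnings(tl <- simulate_timeline(cfg))
  expect_true(any(grepl("mean 2 / sd 4.7", w)))  # hilar clamping's moments
  expect_true(all(grepl("falling back to lognormal", w)))
  expect_true(all(tl$segments$end_s > tl$segments$start_s))
})

test_that("recurrence splitting preserves total phase duration", {
  cfg <- cohort_config(rapn_schema(), rapn_durations(), 1, split_prob = 0.5,
                       seed = 13)
  set.seed(13)
  tl <- simulate_timeline(cfg)
  expect_gt(nrow(tl$segments), 15)  # at least one phase recurs at this seed
  durs <- vapply(rapn_schema()$labels,
                 function(p) phase_duration(tl, p), numeric(1))
  expect_true(all(durs > 0))
  # contiguous layout: no gaps introduced by splitting
  seg <- tl$segments
  expect_equal(seg$start_s[-1], seg$end_s[-nrow(seg)])
})

test_that("respondents answer per their configured accuracy model", {
  sch <- rapn_schema()
  item <- list(true_phase = sch$labels[5], modality = "frame")
  always <- respondent_config("g", p_correct_frame = 1)
  set.seed(41)
  for (i in 1:20)
    expect_identical(simulate_response(item, always, sch)$answer,
                     sch$labels[5])
  never <- respondent_config("g", p_correct_frame = 0)
  set.seed(42)
  ans <- replicate(50, simulate_response(item, never, sch)$answer)
  expect_true(all(ans != sch$labels[5]))
})

test_that("wrong answers follow the adjacency kernel over schema order", {
  sch <- rapn_schema()
  item <- list(true_phase = sch$labels[8], modality = "frame")
  cfg <- respondent_config("g", p_correct_frame = 0, adjacency_spread = 0.5)
  set.seed(43)
  ans <- replicate(5000, simulate_response(item, cfg, sch)$answer)
  obs <- table(factor(ans, levels = sch$labels))
  dist <- abs(seq_len(sch$k) - 8)
  w <- 0.5^dist
  w[8] <- 0
  chi <- suppressWarnings(chisq.test(obs[w > 0], p = w[w > 0] / sum(w)))
  expect_gt(chi$p.value, 0.001)

  # spread -> 0 concentrates all mass on the two schema-adjacent phases
  cfg0 <- respondent_config("g", p_correct_frame = 0, adjacency_spread = 0)
  set.seed(44)
  ans0 <- replicate(200, simulate_response(item, cfg0, sch)$answer)
  expect_true(all(ans0 %in% sch$labels[c(7, 9)]))
})

test_that("confidence tracks correctness per the configured correlation", {
  sch <- rapn_schema()
  item <- list(true_phase = sch$labels[3], modality = "frame")
  indep <- respondent_config("g", 0.5, confidence_correlation = 0)
  set.seed(45)
  r <- do.call(rbind, replicate(10000, simulate_response(item, indep, sch),
                                simplify = FALSE))
  expect_true(all(r$confidence %in% 1:5))
  rho0 <- unname(spearman_rho(r$confidence,
                              as.numeric(r$correct))$statistic)
  expect_lt(abs(rho0), 0.03)

  pos <- respondent_config("g", 0.5, confidence_correlation = 0.6)
  set.seed(46)
  rp <- do.call(rbind, replicate(2000, simulate_response(item, pos, sch),
                                 simplify = FALSE))
  expect_gt(unname(spearman_rho(rp$confidence,
                                as.numeric(rp$correct))$statistic), 0.2)
  expect_true(all(rp$response_time_s > 0))
})

test_that("a simulated survey has the study's structure", {
  cohort <- simulate_cohort(
    cohort_config(rapn_schema(), rapn_durations(), 10, seed = 51))
  resp <- default_respondents(0)
  gs <- c("medical-student" = 2, "surgical-trainee" = 2, "consultant" = 2)
  sv <- simulate_survey(cohort, sampler_config(), resp, gs, seed = 52)
  expect_equal(nrow(sv$responses), 6 * 34)  # 17 per modality per person
  per <- table(sv$responses$participant_id, sv$responses$modality)
  expect_true(all(per == 17))
  expect_equal(length(unique(sv$assignments$procedure_id)), 6)
  # reproducible bit-for-bit
  sv2 <- simulate_survey(cohort, sampler_config(), resp, gs, seed = 52)
  expect_identical(sv$responses, sv2$responses)
  # more participants than procedures is refused
  expect_error(
    simulate_survey(cohort[1:3], sampler_config(), resp, gs, seed = 1),
    "more participants")
})

test_that("group accuracies recover the configured probabilities", {
  cohort <- simulate_cohort(
    cohort_config(rapn_schema(), rapn_durations(), 35, seed = 53))
  resp <- list(g = respondent_config("g", 0.4, snippet_boost = 0.2))
  sv <- simulate_survey(cohort, sampler_config(), resp, c(g = 30), seed = 54)
  frames <- sv$responses[sv$responses$modality == "frame", ]
  snips <- sv$responses[sv$responses$modality == "snippet", ]
  n <- nrow(frames)
  acc_f <- mean(frames$answer == frames$true_phase)
  acc_s <- mean(snips$answer == snips$true_phase)
  expect_lt(abs(acc_f - 0.4), 2 * sqrt(0.4 * 0.6 / n))
  expect_lt(abs(acc_s - 0.6), 2 * sqrt(0.6 * 0.4 / n))
})

test_that("perfect predictors reproduce ground truth at every second", {
  cohort <- simulate_cohort(
    cohort_config(cholec80_schema(), cholec80_durations(), 1, seed = 61))
  tl <- cohort[[1]]
  pred <- simulate_ai_predictions(tl, predictor_config(1, seed = 62))
  expect_equal(pred$predicted_phase, phase_at(tl, pred$time_s + 0.5))
  # one prediction per second whose midpoint falls in annotated footage
  expect_equal(nrow(pred), floor(timeline_end(tl) + 0.5))
})

test_that("temporal smoothing improves per-second accuracy", {
  sch <- toy_schema(3)
  tl <- toy_timeline(c(A = 5000, B = 5000), sch)
  raw <- simulate_ai_predictions(tl, predictor_config(0.8,
                                                      smoothing_window_s = 1,
                                                      seed = 63))
  smooth <- simulate_ai_predictions(tl, predictor_config(0.8,
                                                         smoothing_window_s = 11,
                                                         seed = 63))
  truth <- phase_at(tl, raw$time_s + 0.5)
  acc_raw <- mean(raw$predicted_phase == truth)
  acc_smooth <- mean(smooth$predicted_phase == truth)
  expect_gt(acc_smooth, acc_raw)
  # same seed, window 1: smoothing is the identity on the raw stream
  raw2 <- simulate_ai_predictions(tl, predictor_config(0.8,
                                                       smoothing_window_s = 1,
                                                       seed = 63))
  expect_identical(raw, raw2)
})
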