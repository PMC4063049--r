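test_that("evidence assembly maps intervals and alarms onto slices", {
  cfg <- fusion_config(slice_duration = 60)
  # nothing in, empty evidence out
  ev0 <- assemble_evidence(labeled_intervals(), NULL, cfg, horizon = 3)
  expect_identical(attr(ev0, "horizon"), 3L)
  expect_true(all(lengths(unclass(ev0)) == 0))
  # an alarm at t = 95 s lands in slice 2 only
  ev1 <- assemble_evidence(labeled_intervals(),
                           data.frame(t = 95), cfg, horizon = 3)
  expect_identical(ev1[[2]], c(FE = 2L))
  expect_identical(length(ev1[[1]]), 0L)
  expect_identical(length(ev1[[3]]), 0L)
  # a training interval spanning slices 3-5 plus an alarm in slice 4
  tl <- labeled_intervals("Training", 120, 300)
  ev2 <- assemble_evidence(tl, data.frame(t = 185), cfg, horizon = 5)
  expect_identical(sort(names(ev2[[4]])), c("FE", "Tr"))
  expect_identical(ev2[[3]], c(Tr = 2L))
  expect_identical(ev2[[5]], c(Tr = 2L))
  expect_identical(length(ev2[[2]]), 0L)
  # intervals overlapping less than half a slice are not observed
  short <- labeled_intervals("Training", 50, 75)  # 10 s in slice 1, 15 in 2
  ev3 <- assemble_evidence(short, NULL, cfg, horizon = 2)
  expect_true(all(lengths(unclass(ev3)) == 0))
  expect_error(assemble_evidence(tl, data.frame(t = -5), cfg),
               "negative")
})

test_that("fall-risk assessment delegates to exact inference", {
  m <- default_model(quiet = TRUE)
  cfg <- fusion_config(mode = "filter")
  ev <- dbn_evidence(list(c(Sl = 2)))
  expect_equal(assess_fall_risk(m, ev, cfg)$p, 0.04, tolerance = 1e-12)
  # empty single slice: the prior
  expect_equal(assess_fall_risk(m, dbn_evidence(list(), horizon = 1),
                                cfg)$p, 0.2, tolerance = 1e-12)
  # a multi-slice joint trace equals the enumeration oracle: the full
  # 7-node model at the largest horizon the enumeration guard admits, and
  # a reduced model over a longer horizon
  set.seed(401)
  ev3 <- generate_scenario(m, 3, 2, seed = 17)
  tr <- assess_fall_risk(m, ev3, fusion_config(mode = "smooth"))
  for (t in 1:3) {
    expect_lt(abs(tr$p[t] - enumerate_posterior(m, ev3, "FA", t)), 1e-9)
  }
  mt <- tiny_fa_model()
  ev4 <- dbn_evidence(list(c(Sl = 2), c(Sl = 1), integer(0), c(Sl = 2)))
  tr4 <- assess_fall_risk(mt, ev4, fusion_config(mode = "smooth"))
  for (t in 1:4) {
    expect_lt(abs(tr4$p[t] - enumerate_posterior(mt, ev4, "FA", t)), 1e-9)
  }
  # single-activity conditioning scores each slice in isolation
  trs <- assess_fall_risk(m, ev3, fusion_config(condition = "single"))
  for (t in 1:3) {
    expect_equal(trs$p[t],
                 infer_posterior(m, dbn_evidence(list(ev3[[t]])),
                                 "FA", "filter")$p[1],
                 tolerance = 1e-12)
  }
})

test_that("alarm confirmation partitions the fall-event slices", {
  ev <- dbn_evidence(list(c(Tr = 2, FE = 2), c(Sl = 2), c(Sl = 2, FE = 2),
                          c(C = 2, FE = 2)))
  trace <- data.frame(t = 1:4, p = c(0.92, 0.1, 0.6, 0.7))
  cfg <- fusion_config(risk_level = 0.7)
  v <- confirm_alarms(trace, ev, cfg)
  expect_identical(v$confirmed$slice, c(1L, 4L))   # 0.7 boundary confirms
  expect_identical(v$rejected$slice, 3L)
  expect_identical(sort(c(v$confirmed$slice, v$rejected$slice)),
                   c(1L, 3L, 4L))
  expect_identical(v$confirmed$activities, c("Tr", "C"))
  expect_identical(v$confirmed$previous, c(NA_character_, "Sl"))
  expect_identical(v$confirmed$following, c("Sl", NA_character_))
  # raising the risk level never confirms more
  lvls <- seq(0.05, 0.95, by = 0.1)
  counts <- vapply(lvls, function(r) {
    nrow(confirm_alarms(trace, ev, fusion_config(risk_level = r))$confirmed)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-activity summaries aggregate the trace correctly", {
  # constant posterior over k slices
  ev <- dbn_evidence(rep(list(c(Tr = 2)), 3))
  trace <- data.frame(t = 1:3, p = 0.25)
  s <- summarize_risk(trace, ev)
  expect_identical(s$amount, 3L)
  expect_equal(c(s$min_fa, s$max_fa, s$mean_fa), rep(0.25, 3))
  expect_identical(s$alarms, "-")
  # unobserved activities are absent
  expect_false("Sl" %in% s$activity)
  # randomized summary against an independent aggregate
  set.seed(402)
  m <- default_model(quiet = TRUE)
  evr <- generate_scenario(m, 30, 7, seed = 23)
  tr <- assess_fall_risk(m, evr, fusion_config())
  s2 <- summarize_risk(tr, evr)
  for (r in seq_len(nrow(s2))) {
    v <- s2$activity[r]
    idx <- which(vapply(seq_along(evr), function(t)
      isTRUE(evr[[t]][v] == 2L), logical(1)))
    expect_identical(s2$amount[r], length(idx))
    expect_equal(s2$min_fa[r], min(tr$p[idx]))
    expect_equal(s2$max_fa[r], max(tr$p[idx]))
    expect_equal(s2$mean_fa[r], mean(tr$p[idx]))
    expect_lte(s2$min_fa[r], s2$mean_fa[r])
    expect_lte(s2$mean_fa[r], s2$max_fa[r])
  }
})

test_that("risk reports tie the pieces together consistently", {
  m <- default_model(quiet = TRUE)
  ev <- generate_scenario(m, 20, 5, seed = 29)
  rep <- risk_report(m, ev, fusion_config())
  expect_s3_class(rep, "risk_report")
  expect_identical(nrow(rep$trace), 20L)
  expect_true(all(rep$trace$p >= 0 & rep$trace$p <= 1))
  expect_identical(nrow(rep$confirmed) + nrow(rep$rejected), 4L)
  expect_true(all(rep$confirmed$posterior >= 0.7))
  expect_true(all(rep$rejected$posterior < 0.7))
})
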