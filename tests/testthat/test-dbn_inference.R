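test_that("joint probability is the chain-rule product over slices", {
  m <- tiny_fa_model(prior_true = 0.2)
  A <- matrix(c(2L, 2L), 1, 2, dimnames = list(NULL, c("FA", "Sl")))
  expect_equal(joint_probability(m, A), 0.2 * 0.1, tolerance = 1e-15)
  # every full assignment is a probability, and they sum to one over T = 2
  g <- as.matrix(expand.grid(FA1 = 1:2, Sl1 = 1:2, FA2 = 1:2, Sl2 = 1:2))
  total <- 0
  for (r in seq_len(nrow(g))) {
    A2 <- matrix(g[r, ], 2, 2, byrow = TRUE,
                 dimnames = list(NULL, c("FA", "Sl")))
    p <- joint_probability(m, A2)
    expect_gte(p, 0); expect_lte(p, 1)
    total <- total + p
  }
  expect_equal(total, 1, tolerance = 1e-12)
  expect_error(joint_probability(m, A[, "FA", drop = FALSE]),
               "missing node")
})

test_that("single-slice posterior matches the closed-form Bayes rule", {
  # P(FA|Sl=t) = 0.2*0.1 / (0.2*0.1 + 0.8*0.6) = 0.04
  for (m in list(tiny_fa_model(), default_model(quiet = TRUE))) {
    ev <- dbn_evidence(list(c(Sl = 2)))
    expect_equal(enumerate_posterior(m, ev, "FA", 1), 0.04,
                 tolerance = 1e-12)
    expect_equal(infer_posterior(m, ev, "FA", "filter")$p, 0.04,
                 tolerance = 1e-12)
  }
})

test_that("enumeration marginalizes correctly in edge cases", {
  m <- tiny_fa_model(0.2)
  # no evidence: the prior
  expect_equal(enumerate_posterior(m, dbn_evidence(list(), horizon = 1),
                                   "FA", 1), 0.2, tolerance = 1e-12)
  # all-observed evidence: observed nodes have posterior 1 at their state
  ev <- dbn_evidence(list(c(Sl = 2), c(Sl = 1)))
  expect_equal(enumerate_posterior(m, ev, "Sl", 1, state = 2), 1)
  expect_equal(enumerate_posterior(m, ev, "Sl", 2, state = 1), 1)
  # guard against exponential blow-up
  big <- dbn_evidence(list(), horizon = 20)
  expect_error(enumerate_posterior(m, big, "FA", 1), "infer_posterior")
})

test_that("interface filtering and smoothing match the enumeration oracle", {
  set.seed(101)
  for (trial in 1:100) {
    m <- random_small_model()
    T <- sample(1:3, 1)
    ev <- random_evidence(m, T)
    sm <- infer_posterior(m, ev, "H", "smooth")
    fi <- infer_posterior(m, ev, "H", "filter")
    for (t in seq_len(T)) {
      expect_lt(abs(sm$p[t] - enumerate_posterior(m, ev, "H", t)), 1e-9)
      ev_t <- dbn_evidence(unclass(ev)[seq_len(t)])
      expect_lt(abs(fi$p[t] - enumerate_posterior(m, ev_t, "H", t)), 1e-9)
    }
  }
})

test_that("the default 7-node model agrees with enumeration", {
  m <- default_model(quiet = TRUE)
  ev <- dbn_evidence(list(c(Sl = 2), c(Tr = 2, FE = 2), c(C = 1)))
  sm <- infer_posterior(m, ev, "FA", "smooth")
  fi <- infer_posterior(m, ev, "FA", "filter")
  for (t in 1:3) {
    expect_lt(abs(sm$p[t] - enumerate_posterior(m, ev, "FA", t)), 1e-9)
    expect_lt(abs(fi$p[t] -
                    enumerate_posterior(m, dbn_evidence(unclass(ev)[1:t]),
                                        "FA", t)), 1e-9)
  }
  # smoothing at the horizon coincides with filtering there
  expect_equal(sm$p[3], fi$p[3], tolerance = 1e-12)
})

test_that("prediction extends the filtered belief without evidence", {
  m <- default_model(quiet = TRUE)
  ev <- dbn_evidence(list(c(Tr = 2, FE = 2)))
  pr <- infer_posterior(m, ev, "FA", "predict", horizon = 3)
  expect_identical(nrow(pr), 3L)
  # matches enumeration with explicitly empty later slices
  ev_pad <- dbn_evidence(list("1" = c(Tr = 2, FE = 2)), horizon = 3)
  for (t in 1:3) {
    expect_lt(abs(pr$p[t] - enumerate_posterior(m, ev_pad, "FA", t)), 1e-9)
  }
  # one-step prediction is the transition applied to the filtered belief
  f1 <- infer_posterior(m, ev, "FA", "filter")$p[1]
  expect_equal(pr$p[2], f1 * 0.05 + (1 - f1) * 0.1, tolerance = 1e-9)
})

test_that("impossible evidence is reported, not silently normalized", {
  m <- tiny_fa_model()
  m0 <- m
  # make Sl deterministically false regardless of FA
  m0$slice1$Sl$values <- array(c(1, 1, 0, 0), dim = c(2, 2))
  m0$slice2$Sl <- m0$slice1$Sl
  expect_error(infer_posterior(m0, dbn_evidence(list(c(Sl = 2)))),
               "zero probability")
})

test_that("MAP sequences equal the exhaustive argmax", {
  set.seed(202)
  for (trial in 1:30) {
    m <- random_small_model()
    T <- sample(1:3, 1)
    ev <- random_evidence(m, T, p_obs = 0.4)
    got <- viterbi_map(m, ev)
    want <- exhaustive_map(m, ev)
    expect_identical(got$states, want$states)
    expect_equal(exp(got$log_prob), want$prob, tolerance = 1e-9)
  }
})

test_that("MAP ties break towards the lexicographically smallest sequence", {
  # a model totally indifferent to everything: all 1/2 entries
  m <- dbn_model(
    nodes = data.frame(name = c("H", "A"), role = c("hidden", "observable")),
    intra_edges = data.frame(from = "H", to = "A"),
    inter_edges = data.frame(from = "H", to = "H"),
    slice1 = list(H = dbn_cpt("H", c(0.5, 0.5)),
                  A = dbn_cpt("A", c(0.5, 0.5, 0.5, 0.5), "H")),
    slice2 = list(H = dbn_cpt("H", c(0.5, 0.5, 0.5, 0.5), "H", "prev")))
  got <- viterbi_map(m, dbn_evidence(list(), horizon = 3))
  expect_true(all(got$states == 1L))  # everything false
  # deterministic CPTs give the unique consistent sequence
  md <- dbn_model(
    nodes = data.frame(name = c("H", "A"), role = c("hidden", "observable")),
    intra_edges = data.frame(from = "H", to = "A"),
    inter_edges = data.frame(from = "H", to = "H"),
    slice1 = list(H = dbn_cpt("H", c(0, 1)),            # H starts true
                  A = dbn_cpt("A", c(1, 0, 0, 1), "H")),  # A copies H
    slice2 = list(H = dbn_cpt("H", c(1, 1, 0, 0), "H", "prev")))  # H flips off
  got <- viterbi_map(md, dbn_evidence(list(), horizon = 3))
  expect_identical(unname(got$states[, "H"]), c(2L, 1L, 1L))
  expect_identical(unname(got$states[, "A"]), c(2L, 1L, 1L))
})

test_that("evidence-free MAP under a self-favoring chain stays at the mode", {
  m <- tiny_fa_model(0.2)  # prior mode false, strongly persistent false
  got <- viterbi_map(m, dbn_evidence(list(), horizon = 4))
  expect_true(all(got$states[, "FA"] == 1L))
  want <- exhaustive_map(m, dbn_evidence(list(), horizon = 4))
  expect_identical(got$states, want$states)
})
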