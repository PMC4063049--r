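test_that("discretize produces maximal predicate runs with gap merging", {
  # all readings below threshold: nothing
  rd <- data.frame(t = 1:10, value = 20)
  expect_identical(nrow(discretize(rd, "Hot", ">=", 40)), 0L)
  # boolean sensor on during [10,20] and [21,25] (an off reading between),
  # min_gap 2: the two runs merge into one interval
  onoff <- data.frame(t = c(10:20, 20.5, 21:25),
                      value = c(rep(TRUE, 11), FALSE, rep(TRUE, 5)))
  iv <- discretize(onoff, "Stove", "true", min_gap = 2)
  expect_equal(iv, labeled_intervals("Stove", 10, 25))
  # without merging they stay separate
  iv2 <- discretize(onoff, "Stove", "true", min_gap = 0.5)
  expect_identical(nrow(iv2), 2L)
  expect_equal(iv2, labeled_intervals(c("Stove", "Stove"), c(10, 21),
                                      c(20, 25)))
  # threshold predicate on a temperature series
  temp <- data.frame(t = seq(0, 400, by = 20),
                     value = ifelse(seq(0, 400, by = 20) >= 100 &
                                      seq(0, 400, by = 20) <= 300, 45, 20))
  hot <- discretize(temp, "Temperature_High_Shower", ">=", 40)
  expect_equal(hot, labeled_intervals("Temperature_High_Shower", 100, 300))
  expect_error(discretize(data.frame(t = c(2, 1), value = TRUE), "x"),
               "sorted")
  expect_error(discretize(rd, "x", op = "almost"), "unknown predicate")
})

# independent 13-case classifier built straight from the endpoint-order
# definitions, used as the oracle for allen_relation
allen_oracle <- function(as, ae, bs, be) {
  if (ae < bs) "precedes"
  else if (ae == bs) "meets"
  else if (as < bs && bs < ae && ae < be) "overlaps"
  else if (as < bs && ae == be) "finished-by"
  else if (as < bs && be < ae) "contains"
  else if (as == bs && ae < be) "starts"
  else if (as == bs && ae == be) "equals"
  else if (as == bs && be < ae) "started-by"
  else if (bs < as && ae < be) "during"
  else if (bs < as && ae == be) "finishes"
  else if (bs < as && as < be && be < ae) "overlapped-by"
  else if (be == as) "met-by"
  else "preceded-by"
}

test_that("allen_relation is a total exclusive classification with converses", {
  expect_identical(allen_relation(list(start = 1, end = 2),
                                  list(start = 3, end = 4)), "precedes")
  expect_identical(allen_relation(list(start = 2, end = 3),
                                  list(start = 1, end = 4)), "during")
  conv <- c("precedes" = "preceded-by", "meets" = "met-by",
            "overlaps" = "overlapped-by", "finished-by" = "finishes",
            "contains" = "during", "starts" = "started-by",
            "equals" = "equals", "started-by" = "starts",
            "during" = "contains", "finishes" = "finished-by",
            "overlapped-by" = "overlaps", "met-by" = "meets",
            "preceded-by" = "precedes")
  # exhaustive grid of endpoint orderings plus random rational endpoints
  pts <- c(0, 1, 2, 3)
  seen <- character(0)
  for (as in pts) for (ae in pts) for (bs in pts) for (be in pts) {
    if (as >= ae || bs >= be) next
    a <- list(start = as, end = ae); b <- list(start = bs, end = be)
    r <- allen_relation(a, b)
    expect_identical(r, allen_oracle(as, ae, bs, be))
    expect_identical(allen_relation(b, a), unname(conv[r]))
    seen <- union(seen, r)
  }
  expect_identical(sort(seen), sort(unname(names(conv))))  # all 13 occur
  set.seed(5)
  for (i in 1:200) {
    e <- sort(sample(1:40, 4, replace = TRUE) / sample(1:7, 4, replace = TRUE))
    a <- list(start = min(e[1], e[2] - 1e-9), end = e[2])
    b <- list(start = min(e[3], e[4] - 1e-9), end = e[4])
    r <- allen_relation(a, b)
    expect_identical(r, allen_oracle(a$start, a$end, b$start, b$end))
    expect_identical(allen_relation(b, a), unname(conv[r]))
  }
  expect_error(allen_relation(list(start = 1, end = 1),
                              list(start = 0, end = 2)), "proper")
})

cooking_rule <- adl_rule("Cooking", "Stove",
                         list(list(relation = "during", target = "Kitchen")))

test_that("rules infer activities with the anchor's extent", {
  iv <- labeled_intervals(c("Stove", "Kitchen"), c(10, 5), c(20, 30))
  out <- infer_activities(iv, list(cooking_rule))
  expect_equal(out, labeled_intervals("Cooking", 10, 20),
               ignore_attr = TRUE)
  # during violated (overlaps instead): no activity
  iv2 <- labeled_intervals(c("Stove", "Kitchen"), c(10, 12), c(20, 30))
  expect_identical(nrow(infer_activities(iv2, list(cooking_rule))), 0L)
  expect_identical(nrow(infer_activities(labeled_intervals(),
                                         list(cooking_rule))), 0L)
  # the "within" alias accepts shared endpoints
  within_rule <- adl_rule("Cooking", "Stove",
                          list(list(relation = "within",
                                    target = "Kitchen")))
  iv3 <- labeled_intervals(c("Stove", "Kitchen"), c(5, 5), c(20, 30))
  expect_identical(nrow(infer_activities(iv3, list(within_rule))), 1L)
  expect_error(adl_rule("X", "Y", list(list(relation = "inside",
                                            target = "Z"))),
               "unknown Allen relation")
})

test_that("inference is monotone in evidence", {
  set.seed(6)
  base <- labeled_intervals(
    rep(c("Stove", "Kitchen"), each = 4),
    c(10, 40, 70, 100, 5, 38, 68, 99),
    c(20, 50, 80, 110, 30, 55, 85, 115))
  out1 <- infer_activities(base, list(cooking_rule))
  for (i in 1:20) {
    extra <- labeled_intervals(sample(c("Stove", "Kitchen", "Tap"), 1),
                               s <- runif(1, 0, 200), s + runif(1, 1, 30))
    out2 <- infer_activities(rbind(base, extra), list(cooking_rule))
    # every previously inferred instance survives
    key <- function(d) paste(d$label, d$start, d$end)
    expect_true(all(key(out1) %in% key(out2)))
    base <- rbind(base, extra)
    out1 <- out2
  }
})

test_that("timeline extraction keeps the longest interval per activity", {
  acts <- labeled_intervals(c("Cooking", "Cooking"), c(10, 40), c(20, 55))
  tl <- extract_timeline(acts)
  expect_equal(tl$extracted, labeled_intervals("Cooking", 40, 55),
               ignore_attr = TRUE)
  # single interval: identity
  one <- labeled_intervals("Sleeping", 0, 100)
  expect_equal(extract_timeline(one)$extracted, one, ignore_attr = TRUE)
  # equal durations: earliest start wins
  tie <- labeled_intervals(c("Cooking", "Cooking"), c(50, 10), c(60, 20))
  expect_equal(extract_timeline(tie)$extracted,
               labeled_intervals("Cooking", 10, 20), ignore_attr = TRUE)
  # extracted duration dominates every member of the label
  set.seed(7)
  many <- labeled_intervals(sample(c("A", "B"), 30, replace = TRUE),
                            s <- runif(30, 0, 100), s + runif(30, 1, 50))
  tl2 <- extract_timeline(many)
  for (lb in unique(many$label)) {
    dmax <- tl2$extracted$end[tl2$extracted$label == lb] -
      tl2$extracted$start[tl2$extracted$label == lb]
    expect_true(all(dmax >= many$end[many$label == lb] -
                      many$start[many$label == lb]))
  }
})
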