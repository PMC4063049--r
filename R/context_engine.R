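#' Labeled temporal intervals
#'
#' @param label character vector of labels.
#' @param start,end numeric endpoints in seconds; `start < end` elementwise.
#' @return data frame with columns `label`, `start`, `end`.
#' @export
labeled_intervals <- function(label = character(0), start = numeric(0),
                              end = numeric(0)) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("interval endpoints must be finite")
  }
  if (any(start >= end)) stop("intervals require start < end")
  data.frame(label = as.character(label), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

.allen_names <- c("precedes", "meets", "overlaps", "finished-by", "contains",
                  "starts", "equals", "started-by", "during", "finishes",
                  "overlapped-by", "met-by", "preceded-by")

.allen_converse <- c("precedes" = "preceded-by", "meets" = "met-by",
                     "overlaps" = "overlapped-by", "finished-by" = "finishes",
                     "contains" = "during", "starts" = "started-by",
                     "equals" = "equals", "started-by" = "starts",
                     "during" = "contains", "finishes" = "finished-by",
                     "overlapped-by" = "overlaps", "met-by" = "meets",
                     "preceded-by" = "precedes")

# named disjunctions accepted in rules; household sensors often share
# endpoints, so strict "during" is too brittle in practice
.allen_aliases <- list(
  "within" = c("during", "starts", "finishes", "equals"),
  "contains_or_equals" = c("contains", "started-by", "finished-by", "equals"))

#' The thirteen Allen relations
#'
#' Classifies the qualitative temporal relation between two proper intervals
#' `[a_start, a_end]` and `[b_start, b_end]` (closed endpoints, exact
#' comparisons). Exactly one of the thirteen canonical relations holds for
#' any pair of proper intervals, and `allen_relation(b, a)` is always the
#' converse of `allen_relation(a, b)`.
#'
#' @param a,b single-row interval data frames, or lists with `start`/`end`.
#' @return one of `"precedes"`, `"meets"`, `"overlaps"`, `"finished-by"`,
#'   `"contains"`, `"starts"`, `"equals"`, `"started-by"`, `"during"`,
#'   `"finishes"`, `"overlapped-by"`, `"met-by"`, `"preceded-by"`.
#' @export
allen_relation <- function(a, b) {
  as <- a$start; ae <- a$end; bs <- b$start; be <- b$end
  if (as >= ae || bs >= be) stop("Allen relations require proper intervals (start < end)")
  if (ae < bs) return("precedes")
  if (ae == bs) return("meets")
  if (be < as) return("preceded-by")
  if (be == as) return("met-by")
  if (as == bs && ae == be) return("equals")
  if (as == bs) return(if (ae < be) "starts" else "started-by")
  if (ae == be) return(if (as > bs) "finishes" else "finished-by")
  if (as > bs && ae < be) return("during")
  if (as < bs && ae > be) return("contains")
  if (as < bs) return("overlaps")
  "overlapped-by"
}

resolve_relation <- function(rel) {
  if (rel %in% names(.allen_aliases)) return(.allen_aliases[[rel]])
  if (!rel %in% .allen_names) {
    stop("unknown Allen relation or alias: '", rel, "'")
  }
  rel
}

#' Activity-inference rule
#'
#' A rule of the form `Head = Anchor ^ Head REL Target ^ ...`: every interval
#' labeled `anchor` that satisfies each interval-algebra constraint against
#' some instance of the constraint's target label yields an inferred activity
#' interval with the anchor's extent. The canonical household example is
#' `Cooking = Stove ^ Cooking during Kitchen`: cooking inherits the stove-on
#' interval, provided it lies within a kitchen-presence interval.
#'
#' @param head activity label produced by the rule.
#' @param anchor source interval label whose extent the activity inherits.
#' @param constraints list of `list(relation =, target =)` pairs; relations
#'   are the 13 Allen relations or a named alias (`"within"`,
#'   `"contains_or_equals"`).
#' @return an object of class `adl_rule`.
#' @export
adl_rule <- function(head, anchor, constraints) {
  stopifnot(is.character(head), is.character(anchor),
            length(constraints) >= 1)
  for (cst in constraints) {
    if (is.null(cst$relation) || is.null(cst$target)) {
      stop("each constraint needs 'relation' and 'target'")
    }
    resolve_relation(cst$relation)  # errors on unknown relation
  }
  structure(list(head = head, anchor = anchor, constraints = constraints),
            class = "adl_rule")
}

#' @export
print.adl_rule <- function(x, ...) {
  cst <- vapply(x$constraints,
                function(c) paste(x$head, c$relation, c$target), "")
  cat(sprintf("%s = %s ^ %s\n", x$head, x$anchor,
              paste(cst, collapse = " ^ ")))
  invisible(x)
}

#' Down-sample sensor readings to labeled intervals
#'
#' Turns a timestamped series of readings from one sensor into the maximal
#' runs over which a predicate holds (e.g., "temperature >= 40", "switch is
#' on"). A run spans from its first to its last qualifying reading and is
#' broken by any reading that fails the predicate; runs separated by gaps
#' shorter than `min_gap` are merged. Zero-duration runs (a single isolated
#' reading) are dropped, since interval-algebra reasoning needs proper
#' intervals.
#'
#' @param readings data frame with columns `t` (sorted) and `value`.
#' @param label label given to the produced intervals.
#' @param op one of `">="`, `">"`, `"<="`, `"<"`, `"=="`, `"true"`.
#' @param threshold comparison value (ignored for `op = "true"`).
#' @param min_gap seconds; shorter gaps between runs are bridged.
#' @return interval data frame (see [labeled_intervals()]).
#' @export
discretize <- function(readings, label, op = "true", threshold = NA,
                       min_gap = 0) {
  if (!is.data.frame(readings) || !all(c("t", "value") %in% names(readings))) {
    stop("readings must have columns t and value")
  }
  if (nrow(readings) == 0) return(labeled_intervals())
  if (is.unsorted(readings$t)) stop("readings must be sorted by t")
  v <- readings$value
  hold <- switch(op,
                 ">=" = v >= threshold,
                 ">"  = v > threshold,
                 "<=" = v <= threshold,
                 "<"  = v < threshold,
                 "==" = v == threshold,
                 "true" = as.logical(v) %in% TRUE,
                 stop("unknown predicate op: '", op, "'"))
  hold[is.na(hold)] <- FALSE
  if (!any(hold)) return(labeled_intervals())
  r <- rle(hold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  ivs <- data.frame(start = readings$t[starts[keep]],
                    end = readings$t[ends[keep]])
  # merge runs separated by gaps shorter than min_gap
  merged <- ivs[1, , drop = FALSE]
  if (nrow(ivs) > 1) {
    for (k in 2:nrow(ivs)) {
      last <- nrow(merged)
      if (ivs$start[k] - merged$end[last] < min_gap) {
        merged$end[last] <- ivs$end[k]
      } else {
        merged <- rbind(merged, ivs[k, ])
      }
    }
  }
  merged <- merged[merged$start < merged$end, , drop = FALSE]
  if (nrow(merged) == 0) return(labeled_intervals())
  labeled_intervals(rep(label, nrow(merged)), merged$start, merged$end)
}

#' Infer activities from intervals and rules
#'
#' Applies each rule to the interval set: every anchor-labeled interval whose
#' Allen relation to some instance of each constraint's target label matches
#' the constraint emits one activity interval with the anchor's extent.
#' Inference is monotone in evidence — adding intervals never removes a
#' previously inferred activity.
#'
#' @param intervals interval data frame (see [labeled_intervals()]).
#' @param rules list of [adl_rule()] objects.
#' @return interval data frame of inferred activities, sorted by
#'   `(start, label)`.
#' @export
infer_activities <- function(intervals, rules) {
  out <- labeled_intervals()
  if (nrow(intervals) == 0 || length(rules) == 0) return(out)
  for (rule in rules) {
    if (!inherits(rule, "adl_rule")) {
      rule <- adl_rule(rule$head, rule$anchor, rule$constraints)
    }
    anchors <- intervals[intervals$label == rule$anchor, , drop = FALSE]
    if (nrow(anchors) == 0) next
    for (i in seq_len(nrow(anchors))) {
      a <- anchors[i, ]
      ok <- all(vapply(rule$constraints, function(cst) {
        allowed <- resolve_relation(cst$relation)
        targets <- intervals[intervals$label == cst$target, , drop = FALSE]
        if (nrow(targets) == 0) return(FALSE)
        any(vapply(seq_len(nrow(targets)), function(j) {
          allen_relation(a, targets[j, ]) %in% allowed
        }, logical(1)))
      }, logical(1)))
      if (ok) {
        out <- rbind(out, labeled_intervals(rule$head, a$start, a$end))
      }
    }
  }
  out[order(out$start, out$label), , drop = FALSE]
}

#' Extract a per-activity timeline
#'
#' For every activity label, selects the single maximum-duration interval
#' (ties broken by earliest start) for display/extraction purposes, while
#' keeping the full set of inferred intervals.
#'
#' @param activities interval data frame of inferred activities.
#' @return object of class `activity_timeline`: list with `intervals` (all
#'   inputs, sorted by start then label) and `extracted` (one row per label).
#' @export
extract_timeline <- function(activities) {
  if (is.null(activities) || nrow(activities) == 0) {
    return(structure(list(intervals = labeled_intervals(),
                          extracted = labeled_intervals()),
                     class = "activity_timeline"))
  }
  acts <- activities[order(activities$start, activities$label), , drop = FALSE]
  rownames(acts) <- NULL
  picks <- lapply(split(acts, acts$label), function(d) {
    dur <- d$end - d$start
    best <- which(dur == max(dur))
    best <- best[which.min(d$start[best])]
    d[best, , drop = FALSE]
  })
  extracted <- do.call(rbind, picks)
  extracted <- extracted[order(extracted$start, extracted$label), , drop = FALSE]
  rownames(extracted) <- NULL
  structure(list(intervals = acts, extracted = extracted),
            class = "activity_timeline")
}

#' @export
print.activity_timeline <- function(x, ...) {
  cat("Activity timeline:", nrow(x$intervals), "interval(s),",
      nrow(x$extracted), "activity label(s)\n")
  if (nrow(x$extracted)) print(x$extracted)
  invisible(x)
}
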