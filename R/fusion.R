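#' Fusion configuration
#'
#' @param slice_duration seconds per DBN time slice.
#' @param risk_level posterior-probability threshold in (0, 1) at or above
#'   which a raw fall event is confirmed as an emergency. The default 0.7
#'   separates confirmed from rejected alarms in the reference operating
#'   point and can be adapted per user or scenario.
#' @param label_map named character vector mapping activity labels to model
#'   node names.
#' @param min_overlap fraction of the slice an activity interval must cover
#'   for the activity node to be observed true in that slice.
#' @param condition `"joint"` conditions each slice on all its observed
#'   nodes; `"single"` evaluates each alarm with an isolated single-slice
#'   query conditioned on that slice's activity and the fall event only.
#' @param mode inference mode used for the risk trace (`"smooth"` uses the
#'   whole recording, `"filter"` is causal/online).
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(slice_duration = 60,
                          risk_level = 0.7,
                          label_map = c(Sleeping = "Sl", Showering = "Sh",
                                        Cooking = "C", TVWatching = "TV",
                                        Training = "Tr"),
                          min_overlap = 0.5,
                          condition = c("joint", "single"),
                          mode = c("smooth", "filter")) {
  stopifnot(slice_duration > 0, risk_level > 0, risk_level < 1,
            min_overlap > 0, min_overlap <= 1)
  structure(list(slice_duration = slice_duration, risk_level = risk_level,
                 label_map = label_map, min_overlap = min_overlap,
                 condition = match.arg(condition), mode = match.arg(mode)),
            class = "fusion_config")
}

#' Assemble per-slice DBN evidence from activities and alarms
#'
#' Maps the continuous-time outputs of the two sensing channels onto the
#' discrete slice grid: slice `t` covers `[(t-1) d, t d)`. An activity node
#' is observed true in every slice its interval overlaps by at least
#' `min_overlap` of the slice duration; the fall-event node `FE` is observed
#' true in every slice containing a raw alarm timestamp. Slices with no
#' signal carry empty evidence (nodes stay unobserved, not false).
#'
#' @param timeline an [extract_timeline()] result, or an interval data frame
#'   of activities.
#' @param alarms alarm data frame from [detect_falls()] (or with column `t`).
#' @param cfg a [fusion_config()].
#' @param horizon number of slices; default: enough to cover all inputs.
#' @return a [dbn_evidence()].
#' @export
assemble_evidence <- function(timeline, alarms, cfg = fusion_config(),
                              horizon = NULL) {
  acts <- if (inherits(timeline, "activity_timeline")) {
    timeline$intervals
  } else {
    timeline
  }
  if (is.null(acts)) acts <- labeled_intervals()
  if (is.null(alarms)) alarms <- data.frame(t = numeric(0))
  if ((nrow(acts) && any(acts$start < 0)) ||
      (nrow(alarms) && any(alarms$t < 0))) {
    stop("negative timestamps are not allowed")
  }
  d <- cfg$slice_duration
  t_max <- max(0, acts$end, alarms$t)
  T <- if (is.null(horizon)) max(1L, ceiling(t_max / d)) else
    as.integer(horizon)
  ev <- rep(list(stats::setNames(integer(0), character(0))), T)
  if (nrow(acts)) {
    for (i in seq_len(nrow(acts))) {
      node <- cfg$label_map[[acts$label[i]]]
      if (is.null(node) || is.na(node)) next  # unmapped labels are ignored
      lo <- floor(acts$start[i] / d) + 1L
      hi <- min(T, ceiling(acts$end[i] / d))
      for (t in seq.int(lo, hi)) {
        ov <- min(acts$end[i], t * d) - max(acts$start[i], (t - 1) * d)
        if (ov >= cfg$min_overlap * d) {
          s <- ev[[t]]; s[node] <- 2L; ev[[t]] <- s
        }
      }
    }
  }
  if (nrow(alarms)) {
    for (ta in alarms$t) {
      t <- floor(ta / d) + 1L
      if (t >= 1 && t <= T) {
        s <- ev[[t]]; s["FE"] <- 2L; ev[[t]] <- s
      }
    }
  }
  dbn_evidence(ev, horizon = T)
}

#' Posterior fall-risk trace for assembled evidence
#'
#' Delegates to [infer_posterior()] with query `FA`. With
#' `cfg$condition = "joint"` (default) every slice conditions on all of its
#' observed nodes jointly across the whole horizon; with `"single"` each
#' slice is scored by an isolated single-slice query conditioned on that
#' slice's own observations only (the per-activity `P(FA | ADL, FE)` view).
#'
#' @param model a [dbn_model()].
#' @param evidence a [dbn_evidence()] from [assemble_evidence()].
#' @param cfg a [fusion_config()].
#' @return a `posterior_trace` (data frame `t`, `p`).
#' @export
assess_fall_risk <- function(model, evidence, cfg = fusion_config()) {
  if (!inherits(evidence, "dbn_evidence")) evidence <- dbn_evidence(evidence)
  if (cfg$condition == "joint") {
    return(infer_posterior(model, evidence, query = "FA", mode = cfg$mode))
  }
  p <- vapply(seq_along(evidence), function(t) {
    infer_posterior(model, dbn_evidence(list(evidence[[t]])),
                    query = "FA", mode = "filter")$p[1]
  }, numeric(1))
  structure(data.frame(t = seq_along(evidence), p = p),
            class = c("posterior_trace", "data.frame"),
            query = "FA", mode = "single-slice")
}

slice_activities <- function(evidence, t) {
  if (t < 1 || t > length(evidence)) return(NA_character_)
  s <- evidence[[t]]
  acts <- setdiff(names(s)[s == 2L], "FE")
  if (length(acts)) paste(acts, collapse = "+") else NA_character_
}

#' Confirm or reject raw fall alarms against the risk level
#'
#' Every slice with an observed fall event is confirmed when its posterior
#' fall risk reaches `cfg$risk_level` (boundary inclusive), rejected
#' otherwise. Confirmed records carry the conditioning activities of the
#' slice, the posterior, and the activities of the neighboring slices.
#'
#' @param trace posterior trace from [assess_fall_risk()].
#' @param evidence the [dbn_evidence()] the trace conditioned on.
#' @param cfg a [fusion_config()].
#' @return list with data frames `confirmed` and `rejected` (columns
#'   `slice`, `activities`, `posterior`, `previous`, `following`).
#' @export
confirm_alarms <- function(trace, evidence, cfg = fusion_config()) {
  fe <- which(vapply(seq_along(evidence), function(t) {
    isTRUE(evidence[[t]]["FE"] == 2L)
  }, logical(1)))
  rec <- data.frame(slice = fe,
                    activities = vapply(fe, function(t)
                      slice_activities(evidence, t), ""),
                    posterior = trace$p[fe],
                    previous = vapply(fe - 1L, function(t)
                      slice_activities(evidence, t), ""),
                    following = vapply(fe + 1L, function(t)
                      slice_activities(evidence, t), ""),
                    stringsAsFactors = FALSE)
  keep <- rec$posterior >= cfg$risk_level
  list(confirmed = rec[keep, , drop = FALSE],
       rejected = rec[!keep, , drop = FALSE])
}

#' Summarize a monitoring run per activity
#'
#' For every activity node observed anywhere in the evidence: the number of
#' slices it was observed in, the minimum/maximum/mean posterior fall risk
#' over those slices, and the posteriors of the slices where the activity
#' coincided with a raw fall event.
#'
#' @param trace posterior trace.
#' @param evidence the conditioning [dbn_evidence()].
#' @return data frame with columns `activity`, `amount`, `min_fa`, `max_fa`,
#'   `mean_fa`, `alarms` (comma-joined alarm posteriors, `"-"` if none).
#' @export
summarize_risk <- function(trace, evidence) {
  T <- length(evidence)
  rows <- list()
  all_nodes <- unique(unlist(lapply(seq_len(T), function(t) {
    s <- evidence[[t]]
    setdiff(names(s)[s == 2L], "FE")
  })))
  for (v in all_nodes) {
    at <- which(vapply(seq_len(T), function(t)
      isTRUE(evidence[[t]][v] == 2L), logical(1)))
    fe_at <- at[vapply(at, function(t)
      isTRUE(evidence[[t]]["FE"] == 2L), logical(1))]
    p <- trace$p[at]
    rows[[v]] <- data.frame(
      activity = v, amount = length(at),
      min_fa = min(p), max_fa = max(p), mean_fa = mean(p),
      alarms = if (length(fe_at))
        paste(sprintf("%.3g", trace$p[fe_at]), collapse = ", ") else "-",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(activity = character(0), amount = integer(0),
                      min_fa = numeric(0), max_fa = numeric(0),
                      mean_fa = numeric(0), alarms = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$activity), , drop = FALSE]
}

#' Full risk report
#'
#' Bundles the posterior trace, the per-activity summary and the
#' confirmed/rejected alarm lists into one object.
#'
#' @param model a [dbn_model()].
#' @param evidence assembled [dbn_evidence()].
#' @param cfg a [fusion_config()].
#' @return object of class `risk_report`.
#' @export
risk_report <- function(model, evidence, cfg = fusion_config()) {
  trace <- assess_fall_risk(model, evidence, cfg)
  verdicts <- confirm_alarms(trace, evidence, cfg)
  structure(list(trace = trace,
                 summary = summarize_risk(trace, evidence),
                 confirmed = verdicts$confirmed,
                 rejected = verdicts$rejected,
                 risk_level = cfg$risk_level),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("Fall-risk report: %d slice(s), risk level %.2f\n",
              nrow(x$trace), x$risk_level))
  cat("\nPer-activity summary:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("\nConfirmed alarms (%d):\n", nrow(x$confirmed)))
  if (nrow(x$confirmed)) print(x$confirmed, row.names = FALSE)
  cat(sprintf("\nRejected alarms (%d):\n", nrow(x$rejected)))
  if (nrow(x$rejected)) print(x$rejected, row.names = FALSE)
  invisible(x)
}
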