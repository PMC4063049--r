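#' Read an accelerometer CSV
#'
#' Expects a header `t,ax,ay,az` with optional `pulse,spo2,location`
#' columns; comma-separated, `.` decimal, UTF-8. Units can be declared as
#' `"ms2"` (default) or `"g"`, in which case accelerations are converted to
#' m/s^2 on read.
#'
#' @param path CSV file path.
#' @param units `"ms2"` or `"g"`.
#' @param gravity conversion constant for `units = "g"`.
#' @return validated accelerometer data frame.
#' @export
read_accel_csv <- function(path, units = c("ms2", "g"), gravity = 9.81) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(c("t", "ax", "ay", "az"), names(df))
  if (length(miss)) {
    stop("accelerometer CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (units == "g") {
    for (col in c("ax", "ay", "az")) df[[col]] <- df[[col]] * gravity
  }
  validate_accel(df)
}

#' Write an accelerometer CSV
#' @param samples accelerometer data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write sensor events as JSON lines
#'
#' One JSON object `{"sensor_id": ..., "t": ..., "value": ...}` per line.
#'
#' @param path file path.
#' @return data frame `sensor_id, t, value` sorted by `(t, sensor_id)`.
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON on line ", i,
                                             " of '", path, "': ",
                                             conditionMessage(e)))
    for (f in c("sensor_id", "t", "value")) {
      if (is.null(rec[[f]])) stop("line ", i, " of '", path,
                                  "' is missing field '", f, "'")
    }
    data.frame(sensor_id = as.character(rec$sensor_id), t = as.numeric(rec$t),
               value = rec$value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$t, out$sensor_id), , drop = FALSE]
}

#' @rdname read_events_jsonl
#' @param events data frame `sensor_id, t, value`.
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(sensor_id = events$sensor_id[i], t = events$t[i],
                          value = events$value[i]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write fall alarms as JSON
#' @param path file path.
#' @return alarm data frame as produced by [detect_falls()].
#' @export
read_alarms_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(x) == 0) {
    return(data.frame(t = numeric(0), direction = character(0),
                      pulse = numeric(0), spo2 = numeric(0),
                      location = character(0), act_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  as.data.frame(x, stringsAsFactors = FALSE)
}

#' @rdname read_alarms_json
#' @param alarms alarm data frame.
#' @export
write_alarms_json <- function(alarms, path) {
  jsonlite::write_json(alarms, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read / write labeled intervals as JSON
#' @param path file path.
#' @return interval data frame (`label, start, end`).
#' @export
read_intervals_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(x) == 0) return(labeled_intervals())
  labeled_intervals(x$label, x$start, x$end)
}

#' @rdname read_intervals_json
#' @param intervals interval data frame.
#' @export
write_intervals_json <- function(intervals, path) {
  jsonlite::write_json(intervals, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read context-engine rules and discretization predicates from YAML
#'
#' The file holds `rules:` (each with `head`, `anchor`, `constraints:` of
#' `{relation, target}`) and optionally `predicates:` (each with
#' `sensor_id`, `label`, `op`, `threshold`, `min_gap`).
#'
#' @param path YAML file path.
#' @return list with `rules` (list of [adl_rule()]) and `predicates`
#'   (list of predicate specs).
#' @export
read_rules_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  rules <- lapply(spec$rules, function(r) {
    adl_rule(r$head, r$anchor, r$constraints)
  })
  preds <- lapply(spec$predicates, function(p) {
    list(sensor_id = p$sensor_id, label = p$label,
         op = if (is.null(p$op)) "true" else p$op,
         threshold = if (is.null(p$threshold)) NA else p$threshold,
         min_gap = if (is.null(p$min_gap)) 0 else p$min_gap)
  })
  list(rules = rules, predicates = preds)
}

#' Apply discretization predicates to an event stream
#'
#' Runs [discretize()] once per predicate spec over the matching sensor's
#' readings and concatenates the resulting labeled intervals.
#'
#' @param events event data frame (`sensor_id, t, value`).
#' @param predicates list of predicate specs (see [read_rules_yaml()]); by
#'   default every sensor is discretized as a boolean with its own id as
#'   label.
#' @return interval data frame.
#' @export
discretize_events <- function(events, predicates = NULL) {
  if (is.null(predicates)) {
    predicates <- lapply(unique(events$sensor_id), function(s) {
      list(sensor_id = s, label = s, op = "true", threshold = NA,
           min_gap = 0)
    })
  }
  out <- lapply(predicates, function(p) {
    sub <- events[events$sensor_id == p$sensor_id, , drop = FALSE]
    discretize(sub, label = p$label, op = p$op, threshold = p$threshold,
               min_gap = p$min_gap)
  })
  do.call(rbind, c(out, list(labeled_intervals())))
}

#' Write a posterior trace as CSV (`t,p_fa`)
#' @param trace posterior trace data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$t, p_fa = trace$p), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write evidence as JSON (`{"t": {"node": state}}`)
#'
#' States use the 1 = false / 2 = true file convention.
#'
#' @param evidence a [dbn_evidence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence_json <- function(evidence, path) {
  obj <- list()
  for (t in seq_along(evidence)) {
    if (length(evidence[[t]])) obj[[as.character(t)]] <-
        as.list(evidence[[t]])
  }
  jsonlite::write_json(list(horizon = attr(evidence, "horizon"),
                            slices = obj),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_evidence_json
#' @export
read_evidence_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  states <- lapply(x$slices, function(s) unlist(s))
  dbn_evidence(states, horizon = x$horizon)
}

#' Write a risk report as JSON
#' @param report a [risk_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(risk_level = report$risk_level,
         trace = report$trace,
         summary = report$summary,
         confirmed = report$confirmed,
         rejected = report$rejected),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
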