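#' Ancestral sampling from a two-slice DBN
#'
#' Draws a complete trajectory of every node over `T` slices, sampling each
#' node given its (already sampled) parents in intra-slice topological
#' order, slice by slice. Reproducible for a fixed seed.
#'
#' @param model a [dbn_model()].
#' @param T number of slices.
#' @param seed integer seed (optional; uses the current RNG state if `NULL`).
#' @return integer matrix `T x n_nodes` of states (1 = false, 2 = true),
#'   columns named by node.
#' @export
sample_from_dbn <- function(model, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- model$nodes$name
  out <- matrix(NA_integer_, T, length(nm), dimnames = list(NULL, nm))
  u <- matrix(stats::runif(T * length(nm)), T, length(nm),
              dimnames = list(NULL, nm))
  draw <- function(cpt, parent_states, uu) {
    d <- dim(cpt$values)
    nchild <- d[length(d)]
    probs <- vapply(seq_len(nchild), function(s) {
      cpt$values[matrix(c(parent_states, s), nrow = 1)]
    }, numeric(1))
    findInterval(uu, cumsum(probs), left.open = TRUE) + 1L
  }
  for (t in seq_len(T)) {
    cpts <- if (t == 1) model$slice1 else model$slice2
    for (v in model$topo) {
      cpt <- cpts[[v]]
      ps <- integer(length(cpt$parents))
      for (j in seq_along(cpt$parents)) {
        row <- if (cpt$parent_slice[j] == "prev") t - 1L else t
        ps[j] <- out[row, cpt$parents[j]]
      }
      out[t, v] <- draw(cpt, ps, u[t, v])
    }
  }
  out
}

#' Generate a monitoring scenario
#'
#' Produces per-slice evidence for the standard simulation design: one
#' single activity observed per time slice, with a fall event interfering at
#' every `fe_period`-th slice (slices `fe_period, 2 fe_period, ...`). With
#' `activity_process = "sampled-from-model"` the observed activity of each
#' slice is drawn from an ancestral sample of the model (uniformly among the
#' activities sampled active, or among all activities when none is); with
#' `"fixed-schedule"` the activities cycle deterministically.
#'
#' @param model a [dbn_model()].
#' @param T number of slices (default 100).
#' @param fe_period fall-event injection period (default 10).
#' @param activity_process `"sampled-from-model"` or `"fixed-schedule"`.
#' @param seed integer seed.
#' @param activity_nodes candidate activity nodes (default: all observable
#'   nodes except `FE`).
#' @return a [dbn_evidence()] with horizon `T`; exactly one activity node
#'   (plus possibly `FE`) observed true per slice.
#' @export
generate_scenario <- function(model, T = 100, fe_period = 10,
                              activity_process = c("sampled-from-model",
                                                   "fixed-schedule"),
                              seed = NULL,
                              activity_nodes = NULL) {
  stopifnot(T >= 1, fe_period >= 1)
  activity_process <- match.arg(activity_process)
  if (is.null(activity_nodes)) {
    activity_nodes <- setdiff(
      model$nodes$name[model$nodes$role == "observable"], "FE")
  }
  if (!is.null(seed)) set.seed(seed)
  act <- if (activity_process == "fixed-schedule") {
    activity_nodes[(seq_len(T) - 1L) %% length(activity_nodes) + 1L]
  } else {
    traj <- sample_from_dbn(model, T)
    vapply(seq_len(T), function(t) {
      on <- activity_nodes[traj[t, activity_nodes] == 2L]
      if (!length(on)) on <- activity_nodes
      on[sample.int(length(on), 1L)]
    }, "")
  }
  ev <- lapply(seq_len(T), function(t) {
    s <- stats::setNames(2L, act[t])
    if (t %% fe_period == 0L) s["FE"] <- 2L
    s
  })
  dbn_evidence(ev, horizon = T)
}

#' Synthetic accelerometer trace generator
#'
#' Emulates a belt-worn tri-axial accelerometer over a schedule of segments.
#' Segment types: `"rest"` (upright posture: gravity on the y axis, plus
#' noise), `"walk"` (a periodic gait modulation of the magnitude, kept below
#' the impact threshold), `"fall"` (a short impact spike followed by a lying
#' posture — gravity on the x axis — for the rest of the segment), and
#' `"fake_fall"` (the same impact spike with an upright recovery, the
#' high-impact non-fall that the orientation gate must reject).
#'
#' @param schedule data frame with columns `type`, `start`, `end`
#'   (non-overlapping, seconds) and optional `location`.
#' @param cfg list of template parameters; see defaults in the function
#'   signature of [fall_template_config()].
#' @param seed integer seed.
#' @return data frame of accelerometer samples (`t, ax, ay, az[, location]`).
#' @export
synth_accel_trace <- function(schedule, cfg = fall_template_config(),
                              seed = NULL) {
  stopifnot(all(c("type", "start", "end") %in% names(schedule)))
  sched <- schedule[order(schedule$start), , drop = FALSE]
  if (nrow(sched) > 1 &&
      any(sched$start[-1] < sched$end[-nrow(sched)])) {
    stop("schedule segments must not overlap")
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$sample_rate
  g <- cfg$gravity
  pieces <- list()
  for (i in seq_len(nrow(sched))) {
    t <- seq(sched$start[i], sched$end[i] - 1 / fs, by = 1 / fs)
    n <- length(t)
    if (n == 0) next
    type <- sched$type[i]
    ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
    if (type == "rest") {
      ay <- rep(g, n)
    } else if (type == "walk") {
      ay <- g + cfg$walk_amplitude * sin(2 * pi * cfg$walk_freq * t)
    } else if (type %in% c("fall", "fake_fall")) {
      imp <- t < sched$start[i] + cfg$impact_duration
      ay[!imp] <- if (type == "fake_fall") g else 0
      ax[!imp] <- if (type == "fake_fall") 0 else g  # lying on the side
      # half-sine impact pulse along x
      tt <- (t[imp] - sched$start[i]) / cfg$impact_duration
      ax[imp] <- cfg$impact_peak * sin(pi * tt)
      ay[imp] <- g
    } else {
      stop("unknown segment type: '", type, "'")
    }
    df <- data.frame(t = t,
                     ax = ax + stats::rnorm(n, 0, cfg$noise_sd),
                     ay = ay + stats::rnorm(n, 0, cfg$noise_sd),
                     az = az + stats::rnorm(n, 0, cfg$noise_sd))
    if (!is.null(sched$location)) df$location <- sched$location[i]
    pieces[[i]] <- df
  }
  if (!length(pieces)) stop("empty accelerometer schedule")
  do.call(rbind, pieces)
}

#' Accelerometer template parameters
#'
#' Defaults are set so that the three regimes are well separated under the
#' default [detector_config()]: resting noise keeps the impact statistic
#' near 2 (m/s^2)^2, gait modulation near 20, and the impact spike in the
#' hundreds, against an impact threshold of 80.
#'
#' @param sample_rate Hz.
#' @param gravity m/s^2.
#' @param noise_sd per-axis sensor noise, m/s^2.
#' @param impact_peak peak impact acceleration, m/s^2.
#' @param impact_duration seconds of impact pulse.
#' @param walk_amplitude,walk_freq gait modulation of the magnitude (m/s^2,
#'   Hz).
#' @return parameter list.
#' @export
fall_template_config <- function(sample_rate = 50, gravity = 9.81,
                                 noise_sd = 0.1, impact_peak = 30,
                                 impact_duration = 0.2,
                                 walk_amplitude = 1.5, walk_freq = 2) {
  stopifnot(sample_rate > 0, gravity > 0, noise_sd >= 0, impact_peak > 0,
            impact_duration > 0, walk_amplitude >= 0, walk_freq > 0)
  list(sample_rate = sample_rate, gravity = gravity, noise_sd = noise_sd,
       impact_peak = impact_peak, impact_duration = impact_duration,
       walk_amplitude = walk_amplitude, walk_freq = walk_freq)
}

# sensor pairs emitted per activity: an anchor device sensor and a
# presence-style sensor that strictly contains it
.activity_sensors <- list(
  Cooking    = c(anchor = "Stove",           context = "Kitchen"),
  Showering  = c(anchor = "Tap",             context = "Bathroom"),
  Sleeping   = c(anchor = "BedPressure",     context = "Bedroom"),
  TVWatching = c(anchor = "TVPower",         context = "LivingRoom"),
  Training   = c(anchor = "ExerciseMachine", context = "BodyMotion"))

#' Synthetic environmental sensor events
#'
#' Emits boolean sensor readings realizing an activity schedule: each
#' activity produces an anchor device sensor active over exactly the
#' scheduled extent (stove, tap, bed pressure, TV power, exercise machine)
#' and a presence/context sensor active over the extent padded by `margin`
#' on both sides, so that the anchor interval lies strictly during the
#' context interval and the default rules recover the schedule exactly.
#'
#' @param schedule data frame with columns `activity` (names of
#'   [default_rules()]) and `start`, `end` in seconds.
#' @param margin seconds of context padding around each segment.
#' @param step seconds between successive readings of an active sensor.
#' @return data frame of readings `sensor_id, t, value`, sorted by
#'   `(t, sensor_id)`.
#' @export
synth_env_events <- function(schedule, margin = 2, step = 5) {
  stopifnot(all(c("activity", "start", "end") %in% names(schedule)))
  pieces <- list()
  emit <- function(sensor, from, to) {
    t <- unique(c(seq(from, to, by = step), to))
    data.frame(sensor_id = sensor, t = t, value = TRUE,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(schedule))) {
    act <- schedule$activity[i]
    sensors <- .activity_sensors[[act]]
    if (is.null(sensors)) stop("no sensor mapping for activity '", act, "'")
    pieces[[length(pieces) + 1L]] <-
      emit(sensors[["anchor"]], schedule$start[i], schedule$end[i])
    pieces[[length(pieces) + 1L]] <-
      emit(sensors[["context"]], max(0, schedule$start[i] - margin),
           schedule$end[i] + margin)
  }
  if (!length(pieces)) {
    return(data.frame(sensor_id = character(0), t = numeric(0),
                      value = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  out[order(out$t, out$sensor_id), , drop = FALSE]
}

#' Default activity-inference rules
#'
#' One rule per household activity, anchored on the device sensor and
#' constrained to lie during the matching presence/context sensor — the
#' `Cooking = Stove ^ Cooking during Kitchen` pattern for all five
#' activities.
#'
#' @return list of [adl_rule()] objects.
#' @export
default_rules <- function() {
  lapply(names(.activity_sensors), function(act) {
    s <- .activity_sensors[[act]]
    adl_rule(act, anchor = s[["anchor"]],
             constraints = list(list(relation = "during",
                                     target = s[["context"]])))
  })
}

#' Demonstration scenario fixture
#'
#' A short scripted recording mirroring the qualitative system
#' demonstration: four activities of daily living (cooking, television,
#' showering, training) over seven one-minute slices, with two fall
#' templates in the accelerometer trace — one during television (a faked
#' fall that the wearable detector cannot distinguish from a real one) and
#' one during training (an actual fall). Both raise raw alarms; the fused
#' posterior should reject the television alarm and confirm the training
#' alarm at the default risk level.
#'
#' @return list with `accel_schedule` (for [synth_accel_trace()]) and
#'   `env_schedule` (for [synth_env_events()]).
#' @export
demo_scenario <- function() {
  list(
    accel_schedule = data.frame(
      type  = c("rest", "fall", "rest", "fall", "rest"),
      start = c(0, 150, 158, 330, 338),
      end   = c(150, 158, 330, 338, 420),
      stringsAsFactors = FALSE),
    env_schedule = data.frame(
      activity = c("Cooking", "TVWatching", "Showering", "Training"),
      start = c(5, 125, 245, 305),
      end   = c(115, 235, 295, 415),
      stringsAsFactors = FALSE))
}
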