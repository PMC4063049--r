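#' Detector configuration
#'
#' Bundles the tunable parameters of the wearable fall detector: gravity
#' constant, the impact threshold on the `Act` statistic, the roll/pitch
#' thresholds defining the horizontal-body region, and the windowing and
#' orientation-check timing.
#'
#' The impact statistic `Act` is the mean absolute deviation of the squared
#' acceleration magnitude over a sliding window, so `act_threshold` is in
#' (m/s^2)^2. After an impact the detector waits `orientation_delay` seconds,
#' then averages `orientation_window` seconds of samples and computes device
#' Euler angles; an alarm fires only when the posture is horizontal
#' (`|roll| >= roll_threshold` or `|pitch| >= pitch_threshold`).
#'
#' @param gravity gravitational constant in m/s^2.
#' @param act_threshold impact threshold on the `Act` statistic, (m/s^2)^2.
#' @param roll_threshold,pitch_threshold degrees; at or beyond either the
#'   body is considered horizontal.
#' @param window_length samples per sliding window (50% overlap).
#' @param sample_rate nominal sampling rate in Hz (used by generators and to
#'   convert the orientation timing to samples).
#' @param orientation_delay seconds to wait after the impact window before
#'   checking posture.
#' @param orientation_window seconds of quiet samples averaged for the
#'   posture check.
#' @param direction_map named character vector mapping the four signed
#'   horizontal axes (`"+az"`, `"-az"`, `"+ax"`, `"-ax"`) to fall directions.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(gravity = 9.81,
                            act_threshold = 80,
                            roll_threshold = 60,
                            pitch_threshold = 60,
                            window_length = 50,
                            sample_rate = 50,
                            orientation_delay = 1.0,
                            orientation_window = 1.0,
                            direction_map = c("+az" = "forward",
                                              "-az" = "backward",
                                              "+ax" = "right",
                                              "-ax" = "left")) {
  stopifnot(gravity > 0, act_threshold > 0,
            roll_threshold > 0, pitch_threshold > 0,
            window_length >= 2, sample_rate > 0,
            orientation_delay >= 0, orientation_window > 0)
  if (!setequal(names(direction_map), c("+az", "-az", "+ax", "-ax"))) {
    stop("direction_map must name exactly +az, -az, +ax, -ax")
  }
  structure(list(gravity = gravity,
                 act_threshold = act_threshold,
                 roll_threshold = roll_threshold,
                 pitch_threshold = pitch_threshold,
                 window_length = as.integer(window_length),
                 sample_rate = sample_rate,
                 orientation_delay = orientation_delay,
                 orientation_window = orientation_window,
                 direction_map = direction_map),
            class = "detector_config")
}

#' Validate an accelerometer sample table
#'
#' @param samples data frame with numeric columns `t`, `ax`, `ay`, `az` and
#'   optional `pulse`, `spo2`, `location`.
#' @param require_sorted error when timestamps are not non-decreasing.
#' @return the validated data frame (invisibly unchanged).
#' @export
validate_accel <- function(samples, require_sorted = TRUE) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop("accelerometer input must be a non-empty data frame")
  }
  need <- c("t", "ax", "ay", "az")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing accelerometer column(s): ",
                         paste(miss, collapse = ", "))
  for (col in need) {
    if (!is.numeric(samples[[col]]) || any(!is.finite(samples[[col]]))) {
      stop("column '", col, "' must be finite numeric")
    }
  }
  if (require_sorted && is.unsorted(samples$t)) {
    stop("accelerometer samples must be sorted by t")
  }
  samples
}

#' Impact statistic over a window
#'
#' Computes the activity statistic
#' `Act = E[| nu_a^2 - E[nu_a^2] |]`, where `nu_a = sqrt(ax^2 + ay^2 + az^2)`
#' is the acceleration magnitude: the mean absolute deviation of the squared
#' magnitude over the window. A window of identical samples gives 0; an
#' impact spike inflates it sharply. Act depends only on the magnitude, so it
#' is invariant under rotation of the axes and permutation of samples, and
#' scales quadratically with the accelerations.
#'
#' @param window data frame of accelerometer samples (see [validate_accel()]).
#' @return non-negative scalar, in (m/s^2)^2.
#' @export
compute_activity_signal <- function(window) {
  validate_accel(window, require_sorted = FALSE)
  va2 <- window$ax^2 + window$ay^2 + window$az^2
  mean(abs(va2 - mean(va2)))
}

#' Device orientation from a single (or averaged) sample
#'
#' Euler angles of the device relative to gravity:
#' `roll = asin(ax / g)`, `pitch = asin(az / g)`, in degrees. For a belt-worn
#' device standing upright, gravity loads the y axis and both angles are near
#' zero; lying drives `|roll|` or `|pitch|` towards 90. Dynamic accelerations
#' can exceed g, so the ratios are clamped to [-1, 1] before `asin`.
#'
#' @param ax,az accelerations along the device x and z axes (m/s^2).
#' @param cfg a [detector_config()].
#' @return list with `roll` and `pitch` in degrees, each in [-90, 90].
#' @export
compute_orientation <- function(ax, az, cfg = detector_config()) {
  if (!is.finite(ax) || !is.finite(az)) stop("non-finite acceleration")
  clamp <- function(x) pmin(1, pmax(-1, x))
  list(roll  = asin(clamp(ax / cfg$gravity)) * 180 / pi,
       pitch = asin(clamp(az / cfg$gravity)) * 180 / pi)
}

is_horizontal <- function(orient, cfg) {
  abs(orient$roll) >= cfg$roll_threshold ||
    abs(orient$pitch) >= cfg$pitch_threshold
}

#' Fall direction at the moment of impact
#'
#' At the peak-magnitude sample of the impact window, the horizontal-plane
#' axis (x or z) with the largest absolute acceleration determines the fall
#' direction; the default mapping is +az forward, -az backward, +ax right,
#' -ax left, with an exact magnitude tie resolved in favour of the z axis.
#'
#' @param impact_window data frame of samples containing the impact.
#' @param cfg a [detector_config()]; `cfg$direction_map` can re-map the axes.
#' @return one of the four direction labels.
#' @export
classify_fall_direction <- function(impact_window, cfg = detector_config()) {
  validate_accel(impact_window, require_sorted = FALSE)
  va <- sqrt(impact_window$ax^2 + impact_window$ay^2 + impact_window$az^2)
  peak <- impact_window[which.max(va), ]
  axis <- if (abs(peak$az) >= abs(peak$ax)) {
    if (peak$az >= 0) "+az" else "-az"
  } else {
    if (peak$ax >= 0) "+ax" else "-ax"
  }
  unname(cfg$direction_map[[axis]])
}

last_payload <- function(stream, t, col) {
  if (!col %in% names(stream)) return(NA)
  v <- stream[[col]][stream$t <= t]
  v <- v[!is.na(v)]
  if (length(v)) v[length(v)] else NA
}

#' Detect falls in an accelerometer stream
#'
#' Scans the stream with sliding windows of `cfg$window_length` samples at
#' 50% overlap. When a window's `Act` reaches `cfg$act_threshold`, monitoring
#' pauses: after `orientation_delay` seconds a quiet period of
#' `orientation_window` seconds is averaged and the posture checked. An alarm
#' is emitted only if the posture is horizontal; high-impact activities
#' followed by an upright recovery are discarded. Each alarm carries the fall
#' direction, the triggering `Act` value and the last observed pulse, SpO2
#' and location, if present in the stream.
#'
#' @param stream data frame of accelerometer samples sorted by `t`.
#' @param cfg a [detector_config()].
#' @return data frame of alarms with columns
#'   `t, direction, pulse, spo2, location, act_value` (0 rows if none).
#' @export
detect_falls <- function(stream, cfg = detector_config()) {
  validate_accel(stream, require_sorted = TRUE)
  n <- nrow(stream)
  w <- cfg$window_length
  hop <- max(1L, w %/% 2L)
  alarms <- list()
  i <- 1L
  while (i + w - 1L <= n) {
    win <- stream[i:(i + w - 1L), , drop = FALSE]
    act <- compute_activity_signal(win)
    if (act >= cfg$act_threshold) {
      t_end <- win$t[w]
      q0 <- t_end + cfg$orientation_delay
      q1 <- q0 + cfg$orientation_window
      quiet <- stream[stream$t >= q0 & stream$t <= q1, , drop = FALSE]
      if (nrow(quiet) > 0) {
        orient <- compute_orientation(mean(quiet$ax), mean(quiet$az), cfg)
        if (is_horizontal(orient, cfg)) {
          va <- sqrt(win$ax^2 + win$ay^2 + win$az^2)
          t_alarm <- win$t[which.max(va)]
          alarms[[length(alarms) + 1L]] <- data.frame(
            t = t_alarm,
            direction = classify_fall_direction(win, cfg),
            pulse = as.numeric(last_payload(stream, t_alarm, "pulse")),
            spo2 = as.numeric(last_payload(stream, t_alarm, "spo2")),
            location = as.character(last_payload(stream, t_alarm, "location")),
            act_value = act,
            stringsAsFactors = FALSE)
        }
      }
      # resume monitoring after the orientation check window
      nxt <- which(stream$t > q1)
      i <- if (length(nxt)) nxt[1] else n + 1L
    } else {
      i <- i + hop
    }
  }
  if (length(alarms)) {
    do.call(rbind, alarms)
  } else {
    data.frame(t = numeric(0), direction = character(0),
               pulse = numeric(0), spo2 = numeric(0),
               location = character(0), act_value = numeric(0),
               stringsAsFactors = FALSE)
  }
}
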