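#' Fall-direction class labels
#'
#' The five classes: the four fall directions during walking (toward- and
#' away-from-radar variants are merged into one label per direction) plus
#' a fall from a stationary posture.
#'
#' @return character vector of the five labels in canonical order.
#' @export
fall_labels <- function() {
  c("forward_fall", "backward_fall", "left_fall", "right_fall",
    "nonmotion_fall")
}

.approaches <- c("toward_radar", "away_from_radar", "static")

# base fall-phase radial excursions (m) for a 1.75 m subject; scaled by
# subject_height / 1.75.  Forward > left and backward > right: a fall
# along the line of sight moves the torso farther in range than a
# sideways fall.
.base_excursion <- c(forward_fall = 0.9, backward_fall = 0.7,
                     left_fall = 0.3, right_fall = 0.25,
                     nonmotion_fall = 0.5)

#' Construct a trajectory object from an arbitrary range function
#'
#' Low-level constructor used by [trajectory_template()] and by tests that
#' need bespoke kinematics (e.g. constant range rate).
#'
#' @param d_of_t vectorised function mapping time (s) to radial distance
#'   (m); must stay positive over `[0, duration]`.
#' @param label class label (see [fall_labels()]).
#' @param approach `"toward_radar"`, `"away_from_radar"` or `"static"`.
#' @param duration observation window covered by the trajectory (s).
#' @param subject_height subject height (m).
#' @param walk_speed nominal walking speed (m/s).
#' @param fall_onset,fall_duration fall-phase timing (s).
#' @param excursion radial excursion of the fall phase (m), metadata.
#' @return an object of class `fall_trajectory`.
#' @export
fall_trajectory <- function(d_of_t, label, approach, duration,
                            subject_height = 1.75, walk_speed = 1,
                            fall_onset = 0, fall_duration = 0,
                            excursion = NA_real_) {
  if (!label %in% fall_labels())
    stopf("unknown label '%s'; must be one of: %s", label,
          paste(fall_labels(), collapse = ", "))
  if (!approach %in% .approaches)
    stopf("unknown approach '%s'; must be one of: %s", approach,
          paste(.approaches, collapse = ", "))
  stopifnot(is.function(d_of_t), is_pos(duration))
  structure(list(d_of_t = d_of_t, label = label, approach = approach,
                 duration = duration, subject_height = subject_height,
                 walk_speed = walk_speed, fall_onset = fall_onset,
                 fall_duration = fall_duration, excursion = excursion),
            class = "fall_trajectory")
}

#' Class-templated radial trajectory of a walking-then-falling subject
#'
#' Builds the radial distance-versus-time function d(t) implied by a fall
#' class and approach direction.  The subject walks at `walk_speed` until
#' `fall_onset`, falls over `fall_duration` with a smooth half-cosine
#' velocity profile, and then rests.  The sign conventions follow the
#' radial (range-rate) geometry: Doppler carries the sign of dd/dt,
#' negative while approaching.
#'
#' Templates per class (stated for `approach = "toward_radar"`; the
#' away-from-radar variant mirrors every range trend):
#' \describe{
#'   \item{forward_fall / left_fall}{range decreases monotonically; the
#'     fall steepens the decrease.  Fall excursion 0.9 m (forward)
#'     vs 0.3 m (left) for a 1.75 m subject.}
#'   \item{backward_fall / right_fall}{range decreases during the walk,
#'     then reverses and increases during the fall.  Excursion 0.7 m
#'     (backward) vs 0.25 m (right).}
#'   \item{nonmotion_fall}{range constant before the fall (zero Doppler),
#'     then a monotone excursion of 0.5 m whose sign is drawn from the
#'     seed.}
#' }
#' Excursions scale linearly with `subject_height / 1.75`; taller subjects
#' move farther in range during the fall.  Seeded jitter (5% relative) is
#' applied to walk speed and excursion, and the fall onset/duration are
#' drawn uniformly from their ranges.
#'
#' @param label one of [fall_labels()].
#' @param approach `"toward_radar"`, `"away_from_radar"`, or `"static"`
#'   (the latter only for `nonmotion_fall`).
#' @param subject_height subject height in metres, in `[1.4, 2.1]`.
#' @param walk_speed nominal walking speed (m/s); ignored (forced to 0)
#'   for `nonmotion_fall`.
#' @param seed integer seed for the jitter draws.
#' @param duration length of the observation window (s).
#' @param fall_onset fall start time (s); scalar, or length-2 range to
#'   draw from uniformly.  Default: uniform in `[0.4, 0.6] * duration`.
#' @param fall_duration fall length (s); scalar or length-2 range,
#'   default uniform in `[0.6, 1.2]`; capped so the fall fits inside the
#'   observation window.
#' @param start_distance initial radial distance (m); scalar or length-2
#'   range, default uniform in `[3.5, 4.5]`.
#' @return an object of class `fall_trajectory`.
#' @examples
#' tr <- trajectory_template("backward_fall", "toward_radar", seed = 7)
#' t <- seq(0, tr$duration, by = 0.01)
#' plot(t, tr$d_of_t(t), type = "l", ylab = "range (m)")
#' @export
trajectory_template <- function(label,
                                approach = c("toward_radar",
                                             "away_from_radar", "static"),
                                subject_height = 1.75, walk_speed = 1.0,
                                seed = 1L, duration = 3.1,
                                fall_onset = NULL, fall_duration = c(0.6, 1.2),
                                start_distance = c(3.5, 4.5)) {
  if (length(label) != 1L || !label %in% fall_labels())
    stopf("unknown label '%s'; must be one of: %s", as.character(label)[1],
          paste(fall_labels(), collapse = ", "))
  approach <- match.arg(approach)
  if (label == "nonmotion_fall") {
    approach <- "static"
  } else if (approach == "static") {
    stopf("approach 'static' is only valid for label 'nonmotion_fall'")
  }
  if (!is.numeric(subject_height) || subject_height < 1.4 ||
      subject_height > 2.1)
    stopf("subject_height must lie in [1.4, 2.1] m, got %s",
          format(subject_height))
  if (is.null(fall_onset)) fall_onset <- c(0.4, 0.6) * duration

  with_seed(seed, {
    draw <- function(x) if (length(x) == 2L) runif(1, x[1], x[2]) else x[1]
    onset <- draw(fall_onset)
    tfall <- draw(fall_duration)
    d0 <- draw(start_distance)
    jit <- function(x) x * (1 + 0.05 * rnorm(1))
    v_walk <- if (label == "nonmotion_fall") 0 else jit(walk_speed)
    exc <- jit(.base_excursion[[label]] * subject_height / 1.75)
    nonmotion_sign <- sample(c(-1, 1), 1)
  })
  # the fall must fit inside the observation window; cap the drawn
  # duration (a no-op for windows of a few seconds or more)
  tfall <- min(tfall, 0.95 * (duration - onset))
  if (tfall <= 0)
    stopf("fall onset %.2f s leaves no room in the %.2f s window",
          onset, duration)

  w <- switch(approach, toward_radar = -abs(v_walk),
              away_from_radar = abs(v_walk), static = 0)
  # fall-phase excursion sign: forward/left continue the walk trend,
  # backward/right reverse it, nonmotion draws its sign from the seed
  sf <- switch(label,
    forward_fall = , left_fall = if (approach == "toward_radar") -1 else 1,
    backward_fall = , right_fall = if (approach == "toward_radar") 1 else -1,
    nonmotion_fall = nonmotion_sign)

  d_onset <- d0 + w * onset
  d_of_t <- function(t) {
    d <- numeric(length(t))
    pre <- t <= onset
    mid <- t > onset & t <= onset + tfall
    post <- t > onset + tfall
    d[pre] <- d0 + w * t[pre]
    s <- (t[mid] - onset) / tfall
    d[mid] <- d_onset + sf * exc * (1 - cos(pi * s)) / 2
    d[post] <- d_onset + sf * exc
    d
  }
  dmin <- min(d_of_t(seq(0, duration, length.out = 2048)))
  if (dmin <= 0)
    stopf("trajectory for %s/%s reaches non-positive range (min %.2f m); %s",
          label, approach, dmin,
          "increase start_distance or shorten the walk phase")

  fall_trajectory(d_of_t, label, approach, duration,
                  subject_height = subject_height, walk_speed = abs(v_walk),
                  fall_onset = onset, fall_duration = tfall,
                  excursion = exc)
}

#' Constant-range-rate trajectory
#'
#' A point target moving at a fixed radial speed; used to probe the
#' Doppler sign convention (negative Doppler while approaching).
#'
#' @param d0 starting distance (m).
#' @param rate range rate dd/dt (m/s); negative means approaching.
#' @param duration observation window (s).
#' @return an object of class `fall_trajectory` (labelled
#'   `nonmotion_fall` for bookkeeping).
#' @export
constant_rate_trajectory <- function(d0, rate, duration = 1) {
  stopifnot(is_pos(d0), is.numeric(rate), is_pos(duration))
  if (d0 + rate * duration <= 0)
    stopf("target crosses the radar within the window")
  fall_trajectory(function(t) d0 + rate * t, "nonmotion_fall",
                  if (rate < 0) "toward_radar"
                  else if (rate > 0) "away_from_radar" else "static",
                  duration, walk_speed = abs(rate))
}

#' @export
print.fall_trajectory <- function(x, ...) {
  cat(sprintf("<fall_trajectory> %s / %s\n", x$label, x$approach))
  cat(sprintf("  height %.2f m, walk %.2f m/s, fall at %.2f s for %.2f s (excursion %.2f m)\n",
              x$subject_height, x$walk_speed, x$fall_onset,
              x$fall_duration, x$excursion))
  cat(sprintf("  d(0) = %.2f m, d(end) = %.2f m over %.2f s\n",
              x$d_of_t(0), x$d_of_t(x$duration), x$duration))
  invisible(x)
}
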