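## Spiral tracking test: target generation and the three motor-control
## outcomes (mean of closest-90% errors, % time within 0.9 deg, path).

#' Spiral target position
#'
#' The target moves anticlockwise from the centre along an Archimedean
#' spiral at constant angular rate: `r(theta) = Rmax * theta / theta_max`
#' with `theta_max = 2 * pi * n_turns`, reaching the full extent
#' (`Rmax = 6.25` degrees per axis, a 12.5 x 12.5 degree workspace) at the
#' end of the trial.
#'
#' @param t time in seconds (vectorized), `0 <= t <= duration`.
#' @param duration trial duration in seconds (default 120).
#' @param n_turns number of spiral turns (default 4).
#' @param r_max terminal radius in degrees (default 6.25).
#' @return data.frame with columns `x`, `y` in degrees.
#' @export
spiral_target <- function(t, duration = 120, n_turns = 4, r_max = 6.25) {
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(n_turns, "n_turns", lower = 0, strict_lower = TRUE)
  if (any(t < 0 | t > duration)) {
    stop("t must lie within [0, duration]", call. = FALSE)
  }
  theta_max <- 2 * pi * n_turns
  theta <- theta_max * t / duration
  r <- r_max * theta / theta_max
  data.frame(x = r * cos(theta), y = r * sin(theta))
}

#' Per-sample tracking error
#'
#' Euclidean distance between target and actual position at each sample:
#' `sqrt((target_x - actual_x)^2 + (target_y - actual_y)^2)`.
#'
#' @param trial a tracking trial: data.frame with columns `target_x`,
#'   `target_y`, `actual_x`, `actual_y` (degrees), equal lengths.
#' @return numeric vector of errors in degrees.
#' @export
tracking_error <- function(trial) {
  need <- c("target_x", "target_y", "actual_x", "actual_y")
  if (!all(need %in% names(trial))) {
    stop("trial must have columns target_x, target_y, actual_x, actual_y",
         call. = FALSE)
  }
  lens <- lengths(trial[need])
  if (length(unique(lens)) != 1L) {
    stop("target and actual series differ in length", call. = FALSE)
  }
  sqrt((trial$target_x - trial$actual_x)^2 +
       (trial$target_y - trial$actual_y)^2)
}

#' Mean of the closest q% tracking errors
#'
#' Sorts the per-sample errors ascending, keeps the smallest
#' `ceiling(q/100 * n)` of them, and returns their mean. With `q = 100`
#' this is the plain mean error.
#'
#' @param errors per-sample errors in degrees.
#' @param q percentage of closest samples kept (default 90).
#' @return mean error of the kept samples, degrees.
#' @export
angular_near <- function(errors, q = 90) {
  if (length(errors) == 0L) stop("no errors supplied", call. = FALSE)
  check_scalar(q, "q", lower = 0, upper = 100, strict_lower = TRUE)
  k <- ceiling(q / 100 * length(errors))
  mean(sort(errors)[seq_len(k)])
}

#' Percentage of time spent near the target
#'
#' `100 * #(error < r) / n`: the share of samples whose tracking error is
#' strictly below the radius `r` (default 0.9 degrees).
#'
#' @param errors per-sample errors in degrees.
#' @param r near-radius in degrees (default 0.9).
#' @return percentage in [0, 100].
#' @export
time_near <- function(errors, r = 0.9) {
  if (length(errors) == 0L) stop("no errors supplied", call. = FALSE)
  check_scalar(r, "r", lower = 0, strict_lower = TRUE)
  100 * mean(errors < r)
}

#' Path: summed tracking error over a trial
#'
#' The sum of all per-sample target-actual differences over the trial
#' (degrees). Note this grows with the number of samples: doubling the
#' sampling rate on the same trajectory roughly doubles the value, so the
#' outcomes table records the sampling rate and models hold it fixed. A
#' sampling-rate-free variant, the time integral of the error
#' (degree-seconds), is available via `normalize = TRUE`. The total distance
#' travelled by the cursor — a different quantity sometimes also called
#' "path" — is provided separately by [path_travelled()].
#'
#' @param errors per-sample errors in degrees.
#' @param sampling_rate Hz; required when `normalize = TRUE`.
#' @param normalize integrate over time instead of summing samples.
#' @return degrees (or degree-seconds when normalized).
#' @export
path_error <- function(errors, sampling_rate = NULL, normalize = FALSE) {
  if (length(errors) == 0L) stop("no errors supplied", call. = FALSE)
  if (normalize) {
    if (is.null(sampling_rate)) {
      stop("sampling_rate required for the normalized path", call. = FALSE)
    }
    sum(errors) / sampling_rate
  } else {
    sum(errors)
  }
}

#' Total distance travelled by the cursor
#'
#' Sum of Euclidean step lengths of the actual trajectory, in degrees.
#'
#' @param trial tracking trial data.frame with `actual_x`, `actual_y`.
#' @return degrees travelled.
#' @export
path_travelled <- function(trial) {
  dx <- diff(trial$actual_x)
  dy <- diff(trial$actual_y)
  sum(sqrt(dx^2 + dy^2))
}

#' Score a tracking trial into the three motor outcomes
#'
#' @param trial tracking trial data.frame (must also carry a
#'   `sampling_rate` attribute or column for bookkeeping; optional).
#' @param q closest-percentage for [angular_near()] (default 90).
#' @param r near-radius for [time_near()] in degrees (default 0.9).
#' @return one-row data.frame: `angular_near` (deg), `time_near` (%),
#'   `path` (deg).
#' @export
score_tracking_trial <- function(trial, q = 90, r = 0.9) {
  e <- tracking_error(trial)
  data.frame(angular_near = angular_near(e, q = q),
             time_near = time_near(e, r = r),
             path = path_error(e))
}
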