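# Ballistic free flight with constant body rotation.
#
# After take-off the centroid follows drag-free projectile motion and the
# body rotates at constant angular velocity; the simulator samples the
# closed-form path (it never integrates numerically).  An inverted
# overhead landing requires the body to rotate through pi radians between
# take-off and target contact.

#' Take-off state for the flight simulator
#'
#' @param speed take-off speed (m/s), `>= 0`.
#' @param elevation_angle take-off elevation from the horizontal (rad),
#'   in `(0, pi/2]`; default vertical.
#' @param y0 centroid height at take-off (m), `>= 0`.
#' @param body_angle body-axis angle at take-off (rad).
#' @param angular_velocity constant in-flight angular velocity (rad/s).
#' @return list of class `takeoff_state`.
#' @export
takeoff_state <- function(speed, elevation_angle = pi / 2, y0 = 0,
                          body_angle = 0, angular_velocity = 0) {
  if (speed < 0) stop("speed must be non-negative")
  if (elevation_angle <= 0 || elevation_angle > pi / 2)
    stop("elevation_angle must be in (0, pi/2]")
  if (y0 < 0) stop("y0 must be non-negative")
  structure(list(speed = speed, elevation_angle = elevation_angle,
                 y0 = y0, body_angle = body_angle,
                 angular_velocity = angular_velocity),
            class = "takeoff_state")
}

#' Time for a projectile to first reach a target height
#'
#' Smallest non-negative root (ascending branch) of
#' `y0 + v_y t - g t^2 / 2 = target_height` with
#' `v_y = speed * sin(elevation_angle)`.
#'
#' @param speed take-off speed (m/s).
#' @param elevation_angle elevation from the horizontal (rad).
#' @param y0 initial height (m).
#' @param target_height target height (m).
#' @param g gravitational acceleration (m/s^2).
#' @return time in seconds (0 when `target_height <= y0`).
#' @export
time_to_height <- function(speed, elevation_angle = pi / 2, y0 = 0,
                           target_height, g = 9.81) {
  vy <- speed * sin(elevation_angle)
  if (target_height <= y0) return(0)
  if (vy <= 0) stop("insufficient take-off speed: no upward velocity")
  disc <- vy^2 - 2 * g * (target_height - y0)
  if (disc < 0)
    stop(sprintf(paste0("insufficient take-off speed: vertical component ",
                        "%.4g m/s, need at least %.4g m/s"),
                 vy, sqrt(2 * g * (target_height - y0))))
  (vy - sqrt(disc)) / g
}

#' Angular velocity required to complete a rotation within an air time
#'
#' With `rotation_needed = pi` this is the constant spin needed for an
#' inverted overhead landing.
#'
#' @param air_time flight duration (s), `> 0`.
#' @param rotation_needed body rotation to complete (rad); default pi.
#' @return angular velocity in rad/s.
#' @export
required_av <- function(air_time, rotation_needed = pi) {
  if (air_time <= 0) stop("air_time must be positive")
  rotation_needed / air_time
}

#' Simulate ballistic flight with constant rotation
#'
#' Samples the closed-form trajectory at time step `dt` from take-off to
#' target contact.  Landing succeeds when the rotation at contact is
#' within `success_tolerance` of pi (modulo 2 pi) -- the inverted
#' overhead landing.
#'
#' @param state a [takeoff_state()].
#' @param target_height target height (m).
#' @param g gravitational acceleration (m/s^2).
#' @param dt sampling step (s); default 1/2000, mirroring the camera.
#' @param success_tolerance allowed deviation from a pi rotation (rad);
#'   default 0.35 (about 20 degrees).
#' @return list of class `flight_result` with `air_time` (s), `contact_x`
#'   (m), `rotation_at_contact` (rad, exactly
#'   `angular_velocity * air_time`), `success`, and `sampled_path`, a data
#'   frame `(t, x, y, theta)` whose final row is the contact state.
#' @export
simulate_flight <- function(state, target_height, g = 9.81, dt = 1 / 2000,
                            success_tolerance = 0.35) {
  stopifnot(inherits(state, "takeoff_state"))
  if (dt <= 0) stop("dt must be positive")
  T_air <- time_to_height(state$speed, state$elevation_angle, state$y0,
                          target_height, g)
  vx <- state$speed * cos(state$elevation_angle)
  vy <- state$speed * sin(state$elevation_angle)
  t <- seq(0, T_air, by = dt)
  if (t[length(t)] < T_air) t <- c(t, T_air)
  path <- data.frame(t = t,
                     x = vx * t,
                     y = state$y0 + vy * t - g * t^2 / 2,
                     theta = state$body_angle + state$angular_velocity * t)
  rot <- state$angular_velocity * T_air
  success <- abs(.wrap_angle(rot - pi)) <= success_tolerance
  structure(list(air_time = T_air, contact_x = vx * T_air,
                 rotation_at_contact = rot, success = success,
                 sampled_path = path),
            class = "flight_result")
}

#' @export
print.flight_result <- function(x, ...) {
  cat(sprintf(paste0("<flight_result> air time %.4g s, rotation at contact",
                     " %.4g rad, %s\n"),
              x$air_time, x$rotation_at_contact,
              if (x$success) "inverted landing" else "landing failed"))
  invisible(x)
}

#' Feasibility map over take-off speed and spin
#'
#' Evaluates [simulate_flight()] success over a grid of take-off speeds
#' and angular velocities for one target height.  Cells whose speed
#' cannot reach the target are infeasible.
#'
#' @param target_height target height (m).
#' @param speed_grid vector of take-off speeds (m/s).
#' @param av_grid vector of angular velocities (rad/s).
#' @param elevation_angle take-off elevation (rad).
#' @param y0 take-off height (m).
#' @param g gravitational acceleration (m/s^2).
#' @param success_tolerance passed to [simulate_flight()].
#' @return logical matrix, rows indexed by speed and columns by angular
#'   velocity (dimnames carry the grid values).
#' @export
feasibility_map <- function(target_height, speed_grid, av_grid,
                            elevation_angle = pi / 2, y0 = 0, g = 9.81,
                            success_tolerance = 0.35) {
  if (length(speed_grid) == 0L || length(av_grid) == 0L)
    stop("speed_grid and av_grid must be non-empty")
  if (any(speed_grid < 0) || any(av_grid < 0))
    stop("grids must be non-negative")
  T_air <- vapply(speed_grid, function(s) {
    tryCatch(time_to_height(s, elevation_angle, y0, target_height, g),
             error = function(e) NA_real_)
  }, numeric(1))
  out <- outer(T_air, av_grid, function(tt, av) {
    ok <- !is.na(tt) & tt > 0
    res <- abs(.wrap_angle(av * tt - pi)) <= success_tolerance
    res & ok
  })
  dimnames(out) <- list(speed = format(speed_grid, trim = TRUE),
                        av = format(av_grid, trim = TRUE))
  out
}
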