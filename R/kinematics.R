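# Jump-event detection and kinematic estimators.
#
# All angle series are unwrapped (consecutive differences mapped to
# (-pi, pi]) before differencing, so multi-revolution rotations and
# crossings of +/-pi are handled.  Positive rotation is counter-clockwise
# in the x-y plane, the direction that carries the head over the animal's
# back for an animal facing +x.

# map a frame index (0-based file value) to a row of traj$data
.traj_row <- function(traj, frame) {
  r <- match(frame, traj$data$frame)
  if (anyNA(r)) stop("frame ", frame[which(is.na(r))[1L]],
                     " not present in trajectory")
  r
}

# wrap angles to (-pi, pi]
.wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# unwrap an angle series: remove 2*pi jumps between consecutive samples
.unwrap <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- .wrap_angle(diff(theta))
  theta[1L] + cumsum(c(0, d))
}

# raw (wrapped) body-axis angle per row; errors if any requested row has a
# degenerate (zero-length) body axis
.body_angle_raw <- function(traj, rows = seq_len(nrow(traj$data))) {
  d <- traj$data
  dx <- d$head_x[rows] - d$abdomen_x[rows]
  dy <- d$head_y[rows] - d$abdomen_y[rows]
  if (any(dx == 0 & dy == 0)) stop("degenerate body axis")
  atan2(dy, dx)
}

# unwrapped body-angle series for all rows
.body_angle_series <- function(traj) {
  .unwrap(.body_angle_raw(traj))
}

#' Body centroid
#'
#' Centre-of-mass proxy of the uniform-rod body model: the arithmetic
#' midpoint of the head and abdomen-tip points.
#'
#' @param traj a [track_trajectory()].
#' @param frame frame index (0-based, as in the file); may be a vector.
#' @return For a single frame, a named numeric `c(x, y)` in metres; for a
#'   vector of frames, a two-column matrix.
#' @export
body_centroid <- function(traj, frame) {
  r <- .traj_row(traj, frame)
  d <- traj$data
  out <- cbind(x = (d$head_x[r] + d$abdomen_x[r]) / 2,
               y = (d$head_y[r] + d$abdomen_y[r]) / 2)
  if (length(frame) == 1L) out[1L, ] else out
}

#' Body-axis angle
#'
#' Angle of the abdomen-tip-to-head vector, counter-clockwise from the +x
#' axis.  When `frame` addresses several frames the series is unwrapped
#' (no +/- 2 pi jumps), using the full trajectory for context.
#'
#' @inheritParams body_centroid
#' @return angle(s) in radians.
#' @export
body_angle <- function(traj, frame = NULL) {
  if (is.null(frame)) frame <- traj$data$frame
  r <- .traj_row(traj, frame)
  .body_angle_raw(traj, r)  # validate requested frames first
  th <- .body_angle_series(traj)
  th[r]
}

#' Detect take-off
#'
#' Take-off is the instant both feet leave the substrate; it is detected
#' as the first frame at which the tarsus y coordinate exceeds
#' `substrate_y + clearance` and stays above it for every later frame of
#' the trajectory.
#'
#' @param traj a [track_trajectory()].
#' @param substrate_y substrate height (m).
#' @param clearance detection clearance above the substrate (m); default
#'   0.5 mm.
#' @return take-off frame index (0-based).
#' @export
detect_takeoff <- function(traj, substrate_y = 0, clearance = 5e-4) {
  stopifnot(clearance > 0)
  above <- traj$data$tarsus_y > substrate_y + clearance
  if (!any(above)) stop("no take-off detected: tarsus never clears substrate")
  # first index from which 'above' holds through the end
  ok <- rev(cumprod(rev(above))) == 1
  if (!any(ok)) stop("no take-off detected: tarsus returns to substrate")
  traj$data$frame[which(ok)[1L]]
}

#' Detect target contact
#'
#' First frame at which the head point is within `tolerance` of the target
#' height (approaching from below, the first frame with
#' `head_y >= target_y - tolerance`).
#'
#' @param traj a [track_trajectory()].
#' @param target_y height of the target underside (m).
#' @param tolerance contact tolerance (m); default 1 mm.
#' @return contact frame index (0-based).
#' @export
detect_contact <- function(traj, target_y, tolerance = 1e-3) {
  stopifnot(tolerance > 0)
  if (traj$data$head_y[1L] >= target_y + tolerance)
    stop("no contact detected: target not above the initial head position")
  hit <- which(traj$data$head_y >= target_y - tolerance)
  if (length(hit) == 0L) stop("no contact detected: head never reaches target")
  traj$data$frame[hit[1L]]
}

#' Jump events
#'
#' Bundle the three frames of interest of a jump: stationary, take-off and
#' target contact.
#'
#' @param stationary_frame,takeoff_frame,contact_frame 0-based frame
#'   indices with `stationary_frame < takeoff_frame < contact_frame`.
#' @return list of class `jump_events`.
#' @export
jump_events <- function(stationary_frame, takeoff_frame, contact_frame) {
  if (!(stationary_frame < takeoff_frame && takeoff_frame < contact_frame))
    stop("jump events must satisfy stationary < takeoff < contact")
  structure(list(stationary_frame = stationary_frame,
                 takeoff_frame = takeoff_frame,
                 contact_frame = contact_frame),
            class = "jump_events")
}

#' Secant (average) linear velocity between two frames
#'
#' Euclidean displacement of the body centroid between frames `f1` and
#' `f2`, divided by the elapsed time `(f2 - f1) / frame_rate`.
#'
#' @param traj a [track_trajectory()].
#' @param f1,f2 frame indices, `f1 < f2`.
#' @return speed in m/s.
#' @export
secant_linear_velocity <- function(traj, f1, f2) {
  if (!(f1 < f2)) stop("f1 must be smaller than f2")
  p <- body_centroid(traj, c(f1, f2))
  dt <- (f2 - f1) / traj$frame_rate
  sqrt(sum((p[2L, ] - p[1L, ])^2)) / dt
}

#' Secant (average) angular velocity between two frames
#'
#' Unwrapped body-angle change between `f1` and `f2` divided by the
#' elapsed time; signed (positive counter-clockwise).
#'
#' @inheritParams secant_linear_velocity
#' @return angular velocity in rad/s.
#' @export
secant_angular_velocity <- function(traj, f1, f2) {
  if (!(f1 < f2)) stop("f1 must be smaller than f2")
  th <- body_angle(traj, c(f1, f2))
  (th[2L] - th[1L]) / ((f2 - f1) / traj$frame_rate)
}

# least-squares slope of y on t
.ls_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * y) / sum(tc^2)
}

# windowed velocities over a set of rows: LS slopes of centroid x, y and
# unwrapped body angle against time
.window_velocity <- function(traj, rows) {
  d <- traj$data
  t <- d$t[rows]
  cx <- (d$head_x[rows] + d$abdomen_x[rows]) / 2
  cy <- (d$head_y[rows] + d$abdomen_y[rows]) / 2
  th <- .body_angle_series(traj)[rows]
  vx <- .ls_slope(t, cx)
  vy <- .ls_slope(t, cy)
  c(lv = sqrt(vx^2 + vy^2), av = .ls_slope(t, th), vx = vx, vy = vy)
}

#' Local (windowed) velocity estimate
#'
#' Least-squares slopes of the body-centroid position and the unwrapped
#' body angle over a symmetric window of frames centred on `frame`; a
#' smoothed central-difference estimate of the instantaneous linear and
#' angular velocity.
#'
#' @param traj a [track_trajectory()].
#' @param frame centre frame index.
#' @param window window size in frames (>= 2); the window spans
#'   `floor(window / 2)` frames on each side of `frame`.
#' @return named numeric vector `c(lv, av, vx, vy)` (m/s, rad/s).
#' @export
local_velocity <- function(traj, frame, window = 5) {
  if (window < 2) stop("window must be at least 2 frames")
  half <- floor(window / 2)
  r0 <- .traj_row(traj, frame)
  rows <- (r0 - half):(r0 + half)
  if (min(rows) < 1L || max(rows) > nrow(traj$data))
    stop("window extends past trajectory")
  .window_velocity(traj, rows)
}

#' Femorotibial joint angle
#'
#' Interior angle at the femorotibial joint (FTJ) vertex between the rays
#' FTJ -> proximal landmark and FTJ -> tarsus, in degrees.  The abdomen
#' tip serves as the femur-proximal landmark, the closest of the four
#' tracked points to the hind-leg base.
#'
#' @inheritParams body_centroid
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
ftj_angle <- function(traj, frame) {
  r <- .traj_row(traj, frame)
  d <- traj$data
  ax <- d$abdomen_x[r] - d$ftj_x[r]
  ay <- d$abdomen_y[r] - d$ftj_y[r]
  bx <- d$tarsus_x[r] - d$ftj_x[r]
  by <- d$tarsus_y[r] - d$ftj_y[r]
  na <- sqrt(ax^2 + ay^2)
  nb <- sqrt(bx^2 + by^2)
  if (any(na == 0 | nb == 0)) stop("degenerate joint: coincident points")
  cosang <- pmin(1, pmax(-1, (ax * bx + ay * by) / (na * nb)))
  acos(cosang) * 180 / pi
}

#' Total body rotation over a jump
#'
#' Unwrapped body-angle change from take-off to target contact.  For a
#' successful inverted overhead landing the magnitude is close to pi.
#'
#' @param traj a [track_trajectory()].
#' @param events a [jump_events()].
#' @return rotation in radians (signed).
#' @export
total_rotation <- function(traj, events) {
  stopifnot(inherits(events, "jump_events"))
  th <- body_angle(traj, c(events$takeoff_frame, events$contact_frame))
  th[2L] - th[1L]
}

#' Analyze a single jump
#'
#' Composes event detection and all estimators: detects take-off (tarsus)
#' and target contact (head), then reports secant velocities over the
#' whole flight (take-off to contact), local take-off velocities
#' (least-squares slopes over the first `window` airborne frames), FTJ
#' angles while stationary and at take-off, air time, total rotation, and
#' the kinetic-energy budget computed from the morphometrics.
#'
#' @param traj a [track_trajectory()].
#' @param morph single-row [morphometrics()] data frame (or a list with
#'   `mass` and `body_length`).
#' @param substrate_y substrate height (m).
#' @param target_y target-underside height (m); defaults to the
#'   trajectory's `target_height`.
#' @param clearance take-off detection clearance (m).
#' @param tolerance contact detection tolerance (m).
#' @param window local-velocity window in frames.
#' @param rest_frames number of initial frames averaged for the
#'   stationary FTJ angle.
#' @return one-row data frame with columns `jump_id`, `animal_id`,
#'   `target_height`, `lv`, `av` (take-off estimates), `lv_secant`,
#'   `av_secant`, `body_angle_takeoff`, `ftj_rest`, `ftj_takeoff`,
#'   `air_time`, `total_rotation`, `takeoff_frame`, `contact_frame`,
#'   `E_trans`, `E_rot`, `rot_fraction`.
#' @export
analyze_jump <- function(traj, morph, substrate_y = 0, target_y = NULL,
                         clearance = 5e-4, tolerance = 1e-3,
                         window = 5, rest_frames = 10) {
  stopifnot(inherits(traj, "track_trajectory"))
  if (is.null(target_y)) target_y <- traj$target_height
  if (is.null(target_y) || is.na(target_y))
    stop("target_y must be given when the trajectory has no target height")
  id <- if (is.na(traj$jump_id)) "<unnamed>" else traj$jump_id
  fail <- function(e) stop("jump ", id, ": ", conditionMessage(e),
                           call. = FALSE)
  takeoff <- tryCatch(detect_takeoff(traj, substrate_y, clearance),
                      error = fail)
  contact <- tryCatch(detect_contact(traj, target_y, tolerance),
                      error = fail)
  if (!(takeoff < contact))
    stop("jump ", id, ": contact frame does not follow take-off")
  ev <- jump_events(traj$data$frame[1L], takeoff, contact)

  r_to <- .traj_row(traj, takeoff)
  r_ct <- .traj_row(traj, contact)

  # take-off local estimates over the first airborne frames only, so the
  # slower stance phase does not bias the slopes
  rows <- r_to:min(r_to + window - 1L, r_ct)
  if (length(rows) < 2L) rows <- r_to:r_ct
  loc <- .window_velocity(traj, rows)

  rest_rows <- seq_len(min(rest_frames, r_to - 1L))
  if (length(rest_rows) == 0L) rest_rows <- 1L
  ftj_rest <- mean(ftj_angle(traj, traj$data$frame[rest_rows]))
  ftj_to <- ftj_angle(traj, takeoff)

  lv_sec <- secant_linear_velocity(traj, takeoff, contact)
  av_sec <- secant_angular_velocity(traj, takeoff, contact)
  air_time <- (contact - takeoff) / traj$frame_rate
  rot <- total_rotation(traj, ev)
  th_to <- body_angle(traj, takeoff)

  eb <- kinetic_energies(morph$mass[1L], morph$body_length[1L],
                         loc[["lv"]], loc[["av"]])
  data.frame(jump_id = traj$jump_id, animal_id = traj$animal_id,
             target_height = target_y,
             lv = loc[["lv"]], av = loc[["av"]],
             lv_secant = lv_sec, av_secant = av_sec,
             body_angle_takeoff = th_to,
             ftj_rest = ftj_rest, ftj_takeoff = ftj_to,
             air_time = air_time, total_rotation = rot,
             takeoff_frame = takeoff, contact_frame = contact,
             E_trans = eb$E_trans, E_rot = eb$E_rot,
             rot_fraction = eb$rot_fraction,
             stringsAsFactors = FALSE)
}

#' Analyze every jump of a study
#'
#' Applies [analyze_jump()] to each trajectory of a simulated or loaded
#' study, joining per-animal morphometrics by `animal_id`.
#'
#' @param study a study list as returned by [simulate_study()] (elements
#'   `trajectories`, `morphometrics`).
#' @param ... passed on to [analyze_jump()].
#' @return data frame with one row per jump.
#' @export
analyze_study <- function(study, ...) {
  morph <- study$morphometrics
  rows <- lapply(study$trajectories, function(traj) {
    m <- morph[morph$animal_id == traj$animal_id, , drop = FALSE]
    if (nrow(m) != 1L)
      stop("jump ", traj$jump_id, ": no morphometrics for animal ",
           traj$animal_id)
    analyze_jump(traj, m, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
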