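# Synthetic targeted-jump study generator.
#
# Emulates a study of 7 animals (5 male, 2 female) performing 151 vertical
# jumps to overhead targets at 50/75/100 mm, filmed at 2000 Hz.  Each
# response (take-off linear and angular velocity, stationary and take-off
# femorotibial angles) follows a mixed-effects structure: per-height fixed
# mean + per-animal random intercept + jump-level residual, with the
# between-jump SD recovered from the reported standard errors as
# SE * sqrt(n_height).  Trajectories are built from three phases --
# stationary, constant-acceleration stance, ballistic flight with constant
# rotation -- with the four tracked points placed on a rigid rod plus a
# two-segment leg, and i.i.d. Gaussian tracking noise added to every
# coordinate.  The generative truth for every estimated quantity is stored
# alongside each trajectory and never read by the analysis pipeline.

.responses <- c("lv", "av", "ftj_rest", "ftj_takeoff")

#' Study configuration for the synthetic generator
#'
#' Returns the generative parameters of the synthetic study.  Defaults
#' reproduce the study conditions: animal roster, jump counts, frame
#' rate, per-height mean take-off velocities and femorotibial angles with
#' their standard errors, mass range, and the leg-to-body length ratio.
#'
#' @param n_animals number of animals (default 7).
#' @param n_male number of males among them (default 5).
#' @param mass_range body-mass range in kg (uniform; default
#'   6.78e-5 to 8.22e-5).
#' @param body_length_mean,body_length_sd body-length distribution in m
#'   (normal truncated positive).
#' @param leg_body_ratio hind-leg to body length ratio (default 1.37,
#'   split evenly between femur and tibia).
#' @param heights target heights in m.
#' @param jumps_per_height jump counts per height (default 47, 53, 51).
#' @param frame_rate camera frame rate in Hz (default 2000).
#' @param lv_mean,lv_se per-height take-off linear velocity mean and SE
#'   (m/s).
#' @param av_mean,av_se per-height take-off angular velocity mean and SE
#'   (rad/s).
#' @param ftj_takeoff_mean,ftj_takeoff_se per-height take-off FTJ angle
#'   mean and SE (degrees).
#' @param ftj_rest_mean,ftj_rest_se per-height stationary FTJ angle mean
#'   and SE (degrees).
#' @param animal_sd_fraction fraction of the between-jump SD assigned to
#'   the per-animal random intercept (default 0.5).
#' @param tracking_noise_sd digitization noise SD per coordinate (m;
#'   default 1e-4).
#' @param y0 centroid height at take-off (m; default 0.024, which makes
#'   ballistic air times from the mean take-off speeds bracket the
#'   reported 20--44 ms).
#' @param stance_distance centroid travel during leg extension (m).
#' @param rest_frames number of stationary frames emitted before stance.
#' @param body_angle_rest body-axis angle while stationary (rad).
#' @param elevation_angle take-off elevation from horizontal (rad;
#'   default vertical).
#' @param takeoff_lift tarsus lift at the take-off frame (m).
#' @param nontargeted_fraction fraction of jumps flagged as not preceded
#'   by the motion-parallax swaying (excluded by the pipeline filter).
#' @param g gravitational acceleration (m/s^2).
#' @param seed integer seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_animals = 7L, n_male = 5L,
                         mass_range = c(6.78e-5, 8.22e-5),
                         body_length_mean = 0.0146, body_length_sd = 0.001,
                         leg_body_ratio = 1.37,
                         heights = c(0.050, 0.075, 0.100),
                         jumps_per_height = c(47L, 53L, 51L),
                         frame_rate = 2000,
                         lv_mean = c(1.40, 1.55, 1.79),
                         lv_se = c(0.07, 0.08, 0.12),
                         av_mean = c(47.36, 38.10, 31.80),
                         av_se = c(3.51, 2.43, 3.18),
                         ftj_takeoff_mean = c(129, 136.5, 144),
                         ftj_takeoff_se = c(4.39, 3.5, 2.65),
                         ftj_rest_mean = c(100, 100, 100),
                         ftj_rest_se = c(4, 4, 4),
                         animal_sd_fraction = 0.5,
                         tracking_noise_sd = 1e-4,
                         y0 = 0.024,
                         stance_distance = 0.012,
                         rest_frames = 12L,
                         body_angle_rest = pi / 4,
                         elevation_angle = pi / 2,
                         takeoff_lift = 1.5e-3,
                         nontargeted_fraction = 0,
                         g = 9.81,
                         seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals), n_male = as.integer(n_male),
              mass_range = mass_range,
              body_length_mean = body_length_mean,
              body_length_sd = body_length_sd,
              leg_body_ratio = leg_body_ratio,
              heights = heights,
              jumps_per_height = as.integer(jumps_per_height),
              frame_rate = frame_rate,
              lv_mean = lv_mean, lv_se = lv_se,
              av_mean = av_mean, av_se = av_se,
              ftj_takeoff_mean = ftj_takeoff_mean,
              ftj_takeoff_se = ftj_takeoff_se,
              ftj_rest_mean = ftj_rest_mean,
              ftj_rest_se = ftj_rest_se,
              animal_sd_fraction = animal_sd_fraction,
              tracking_noise_sd = tracking_noise_sd,
              y0 = y0, stance_distance = stance_distance,
              rest_frames = as.integer(rest_frames),
              body_angle_rest = body_angle_rest,
              elevation_angle = elevation_angle,
              takeoff_lift = takeoff_lift,
              nontargeted_fraction = nontargeted_fraction,
              g = g, seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

#' Validate a study configuration
#'
#' @param cfg a configuration list.
#' @return `cfg` invisibly; stops with a message listing every invalid
#'   field otherwise.
#' @export
validate_study_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(all(ok))) bad <<- c(bad, msg)
  chk(cfg$n_animals >= 1, "n_animals must be >= 1")
  chk(cfg$n_male >= 0 && cfg$n_male <= cfg$n_animals,
      "n_male must be between 0 and n_animals")
  chk(length(cfg$mass_range) == 2 && all(cfg$mass_range > 0) &&
        diff(cfg$mass_range) >= 0, "mass_range must be positive and ordered")
  chk(cfg$body_length_mean > 0, "body_length_mean must be positive")
  chk(cfg$body_length_sd >= 0, "body_length_sd must be non-negative")
  chk(cfg$leg_body_ratio > 0, "leg_body_ratio must be positive")
  nh <- length(cfg$heights)
  chk(nh >= 1 && all(cfg$heights > 0), "heights must be positive")
  chk(length(cfg$jumps_per_height) == nh && all(cfg$jumps_per_height > 0),
      "jumps_per_height must be positive, one per height")
  for (f in c("lv_mean", "lv_se", "av_mean", "av_se", "ftj_takeoff_mean",
              "ftj_takeoff_se", "ftj_rest_mean", "ftj_rest_se"))
    chk(length(cfg[[f]]) == nh && all(is.finite(cfg[[f]])),
        paste0(f, " must be finite, one per height"))
  for (f in c("lv_se", "av_se", "ftj_takeoff_se", "ftj_rest_se"))
    chk(all(cfg[[f]] >= 0), paste0(f, " must be non-negative"))
  chk(cfg$frame_rate > 0, "frame_rate must be positive")
  chk(cfg$animal_sd_fraction >= 0 && cfg$animal_sd_fraction <= 1,
      "animal_sd_fraction must be in [0, 1]")
  chk(cfg$tracking_noise_sd >= 0, "tracking_noise_sd must be non-negative")
  chk(cfg$y0 >= 0, "y0 must be non-negative")
  chk(cfg$stance_distance > 0, "stance_distance must be positive")
  chk(cfg$rest_frames >= 10, "rest_frames must be >= 10")
  chk(cfg$elevation_angle > 0 && cfg$elevation_angle <= pi / 2,
      "elevation_angle must be in (0, pi/2]")
  chk(cfg$nontargeted_fraction >= 0 && cfg$nontargeted_fraction < 1,
      "nontargeted_fraction must be in [0, 1)")
  chk(cfg$g > 0, "g must be positive")
  if (length(bad) > 0L)
    stop("invalid study configuration:\n  ", paste(bad, collapse = "\n  "))
  invisible(cfg)
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_study_config()] returns a `study_config`;
#'   `write_study_config` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param cfg a [study_config()].
#' @export
write_study_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# between-jump SDs per response x height, and the animal/residual split
.variance_components <- function(cfg) {
  nh <- length(cfg$heights)
  sd_between <- rbind(lv = cfg$lv_se * sqrt(cfg$jumps_per_height),
                      av = cfg$av_se * sqrt(cfg$jumps_per_height),
                      ftj_rest = cfg$ftj_rest_se * sqrt(cfg$jumps_per_height),
                      ftj_takeoff = cfg$ftj_takeoff_se *
                        sqrt(cfg$jumps_per_height))
  animal_sd <- cfg$animal_sd_fraction * rowMeans(sd_between)
  # quadrature remainder per height (animal_sd recycles along rows)
  resid_sd <- sqrt(pmax(sd_between^2 - animal_sd^2, 0))
  list(sd_between = sd_between, animal_sd = animal_sd, resid_sd = resid_sd)
}

.height_means <- function(cfg) {
  rbind(lv = cfg$lv_mean, av = cfg$av_mean,
        ftj_rest = cfg$ftj_rest_mean, ftj_takeoff = cfg$ftj_takeoff_mean)
}

#' Sample the study roster: animals and jump assignments
#'
#' Draws the morphometrics table (masses uniform in the configured range,
#' body lengths truncated-normal positive, hind-leg length exactly
#' `leg_body_ratio` times body length split evenly between femur and
#' tibia), the per-animal random intercepts for each response, and the
#' jump assignment table (jumps allocated round-robin across animals
#' within each height).  Deterministic given `cfg$seed`.
#'
#' @param cfg a [study_config()].
#' @return list with `morphometrics`, `animal_effects` (matrix, animals x
#'   responses) and `assignments` (data frame `jump_id`, `animal_id`,
#'   `sex`, `target_height`, `targeted`).
#' @export
sample_study <- function(cfg) {
  validate_study_config(cfg)
  set.seed(cfg$seed)
  ids <- sprintf("A%02d", seq_len(cfg$n_animals))
  sex <- c(rep("M", cfg$n_male), rep("F", cfg$n_animals - cfg$n_male))
  mass <- stats::runif(cfg$n_animals, cfg$mass_range[1], cfg$mass_range[2])
  bl <- numeric(cfg$n_animals)
  for (i in seq_len(cfg$n_animals)) {
    repeat {
      v <- stats::rnorm(1, cfg$body_length_mean, cfg$body_length_sd)
      if (v > 0.25 * cfg$body_length_mean) break
    }
    bl[i] <- v
  }
  leg <- cfg$leg_body_ratio * bl
  morph <- morphometrics(data.frame(
    animal_id = ids, sex = sex, mass = mass, body_length = bl,
    femur_length = leg / 2, tibia_length = leg / 2,
    stringsAsFactors = FALSE))

  vc <- .variance_components(cfg)
  effects <- sapply(.responses, function(resp)
    stats::rnorm(cfg$n_animals, 0, vc$animal_sd[[resp]]))
  effects <- matrix(effects, nrow = cfg$n_animals,
                    dimnames = list(ids, .responses))

  rows <- list()
  k <- 0L
  for (h in seq_along(cfg$heights)) {
    n <- cfg$jumps_per_height[h]
    animal <- rep_len(ids, n)
    for (j in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        jump_id = sprintf("j%03d_%s_h%03.0f", k, animal[j],
                          cfg$heights[h] * 1000),
        animal_id = animal[j],
        sex = sex[match(animal[j], ids)],
        target_height = cfg$heights[h],
        targeted = NA,
        stringsAsFactors = FALSE)
    }
  }
  assignments <- do.call(rbind, rows)
  assignments$targeted <- stats::runif(nrow(assignments)) >=
    cfg$nontargeted_fraction
  list(morphometrics = morph, animal_effects = effects,
       assignments = assignments)
}

#' Draw the generative parameters of one jump
#'
#' Each response is per-height fixed mean + animal intercept + residual
#' (SD components from the configured SEs).  Draws are truncated to
#' physically admissible values -- the vertical take-off speed must carry
#' the head to the target (`v_y >= sqrt(2 g (h + L/2 - y0))`), the
#' angular velocity must be positive, and FTJ angles must stay in a
#' realizable posture range.  Truncation is mean-preserving: the
#' pre-truncation location is shifted (solved numerically) so that the
#' truncated distribution keeps the configured conditional mean, and the
#' admissible value is then drawn by resampling (bounded retries).
#' Without this adjustment the reachability bound would inflate the
#' per-height velocity means above their configured values.
#'
#' @param cfg a [study_config()].
#' @param animal_effect named numeric vector of the animal's intercepts
#'   (one per response), a row of `sample_study()$animal_effects`.
#' @param target_height target height (m), one of `cfg$heights`.
#' @param body_length the animal's body length (m), used for the
#'   reachability bound.
#' @return list of class `jump_truth` with elements `lv`, `av`,
#'   `ftj_rest`, `ftj_takeoff` and `target_height`.  Uses and advances
#'   the global RNG stream.
#' @export
sample_jump_parameters <- function(cfg, animal_effect, target_height,
                                   body_length = cfg$body_length_mean) {
  h <- match(target_height, cfg$heights)
  if (is.na(h)) stop("target_height not in configuration heights")
  vc <- .variance_components(cfg)
  mu <- .height_means(cfg)
  min_vy <- sqrt(2 * cfg$g * max(target_height + body_length / 2 - cfg$y0,
                                 1e-6))
  min_lv <- min_vy / sin(cfg$elevation_angle)
  bounds <- list(lv = c(min_lv, Inf), av = c(1e-6, Inf),
                 ftj_rest = c(60, 178), ftj_takeoff = c(60, 178))
  draw <- function(resp) {
    m <- mu[resp, h] + animal_effect[[resp]]
    s <- vc$resid_sd[resp, h]
    b <- bounds[[resp]]
    if (s == 0) {
      v <- m
      if (v < b[1] || v > b[2])
        stop("degenerate configuration: fixed value of '", resp,
             "' outside admissible range")
      return(v)
    }
    loc <- .trunc_location(m, s, b[1], b[2])
    v <- .rtrunc_norm(loc, s, b[1], b[2])
    if (!is.finite(v))
      stop("truncated draw failed for response '", resp,
           "' (configuration inconsistent)")
    min(max(v, b[1]), b[2])
  }
  structure(list(lv = draw("lv"), av = draw("av"),
                 ftj_rest = draw("ftj_rest"),
                 ftj_takeoff = draw("ftj_takeoff"),
                 target_height = target_height),
            class = "jump_truth")
}

# exact inverse-CDF draw from a normal(loc, s) truncated to [lo, hi]
.rtrunc_norm <- function(loc, s, lo, hi) {
  pl <- stats::pnorm(lo, loc, s)
  ph <- stats::pnorm(hi, loc, s)
  if (ph - pl < 1e-12) return(if (pl > 0.5) lo else hi)
  stats::qnorm(stats::runif(1, pl, ph), loc, s)
}

# mean of a normal(loc, s) truncated to [lo, hi]; stable far outside the
# bounds via the Mills-ratio asymptote lambda(a) ~ a + 1/a
.trunc_mean <- function(loc, s, lo, hi) {
  al <- (lo - loc) / s
  au <- (hi - loc) / s
  if (al > 8 || !is.finite(hi)) {          # effectively lower-truncated
    lam <- if (al > 8) al + 1 / al
           else stats::dnorm(al) / stats::pnorm(al, lower.tail = FALSE)
    return(loc + s * lam)
  }
  if (au < -8 || !is.finite(lo)) {         # effectively upper-truncated
    lam <- if (au < -8) -au - 1 / au
           else stats::dnorm(au) / stats::pnorm(au)
    return(loc - s * lam)
  }
  z <- stats::pnorm(au) - stats::pnorm(al)
  loc + s * (stats::dnorm(al) - stats::dnorm(au)) / z
}

# location parameter such that the [lo, hi]-truncated normal with SD s has
# mean m (mean-preserving truncation); m is clamped to the representable
# open interval when it sits at or beyond a bound
.trunc_location <- function(m, s, lo, hi) {
  eps <- 0.05 * s
  if (is.finite(lo) && m < lo + eps) m <- lo + eps
  if (is.finite(hi) && m > hi - eps) m <- hi - eps
  f <- function(x) .trunc_mean(x, s, lo, hi) - m
  if (abs(f(m)) < 1e-12 * max(1, abs(m))) return(m)
  stats::uniroot(f, interval = c(m - 60 * s, m + 60 * s),
                 tol = 1e-10)$root
}

# place the knee (J) given hip landmark A, tarsus T and desired interior
# FTJ angle phi (degrees): apex of the isoceles triangle over the A-T
# chord, i.e. the midpoint of the inscribed-angle arc.  Exists for any
# phi in (0, 180) and any A != T; the implied femur/tibia segment lengths
# vary with posture, which the angle estimator never uses.  The knee is
# placed on the upward side of the chord.
.place_knee <- function(A, T_pt, tb, phi_deg) {
  phi <- phi_deg * pi / 180
  dvec <- A - T_pt
  d <- sqrt(sum(dvec^2))
  u <- dvec / d
  nrm <- c(u[2], -u[1])
  if (nrm[2] < 0) nrm <- -nrm
  h <- (d / 2) / tan(phi / 2)
  (A + T_pt) / 2 + h * nrm
}

#' Synthesize the tracked trajectory of one jump
#'
#' Builds a three-phase trajectory sampled at the configured frame rate:
#' (i) at least 10 stationary frames; (ii) a constant-acceleration stance
#' reaching the take-off speed at height `y0`, with the body rotating at
#' constant angular acceleration up to the take-off spin and the FTJ
#' opening linearly from its stationary to its take-off angle; (iii)
#' closed-form ballistic flight with constant rotation until the head
#' reaches the target.  Head and abdomen tip sit at +/- L/2 from the
#' centroid along the body axis (rigid rod); the knee and tarsus realize
#' the truth FTJ angle while the feet are grounded and fold against the
#' body in flight.  Gaussian tracking noise is added to every coordinate.
#'
#' @param truth a [sample_jump_parameters()] draw.
#' @param morph single-row morphometrics for the animal.
#' @param cfg a [study_config()].
#' @param jump_id,animal_id,sex metadata for the trajectory.
#' @return a [track_trajectory()]; attribute `"truth"` carries the
#'   completed generative truth (velocities, angles, event frames, air
#'   time, rotation).
#' @export
synthesize_trajectory <- function(truth, morph, cfg,
                                  jump_id = NA_character_,
                                  animal_id = NA_character_,
                                  sex = NA_character_) {
  stopifnot(inherits(truth, "jump_truth"))
  fps <- cfg$frame_rate
  g <- cfg$g
  L <- morph$body_length[1L]
  tb <- cfg$leg_body_ratio * L / 2
  lv <- truth$lv
  av <- truth$av
  target <- truth$target_height
  elev <- cfg$elevation_angle
  vx <- lv * cos(elev)
  vy <- lv * sin(elev)

  n_st <- max(2L, as.integer(ceiling(2 * cfg$stance_distance / lv * fps)))
  t_s <- n_st / fps
  a_lin <- lv / t_s
  alpha <- av / t_s
  theta_to <- cfg$body_angle_rest + av * t_s / 2
  u_e <- c(cos(elev), sin(elev))
  c_to <- c(0, cfg$y0)
  n_rest <- cfg$rest_frames
  to_idx <- n_rest + n_st            # 0-based take-off frame

  # flight sampling: first frame at which the head reaches the target
  t_max <- 2 * vy / g + 0.05
  kf <- seq_len(as.integer(ceiling(t_max * fps)))
  tf <- kf / fps
  cyf <- cfg$y0 + vy * tf - g * tf^2 / 2
  headyf <- cyf + (L / 2) * sin(theta_to + av * tf)
  hit <- which(headyf >= target)
  if (length(hit) == 0L)
    stop("internal generator error: head never reaches the target ",
         "(truncation rules violated)")
  n_fl <- hit[1L]

  n_total <- to_idx + n_fl + 1L
  idx <- 0:(n_total - 1L)
  t_rel <- (idx - to_idx) / fps
  t_rel[idx < n_rest] <- -t_s        # rest frames hold the stance-start pose

  stance <- t_rel < 0
  cx <- ifelse(stance,
               c_to[1] + u_e[1] * (lv * t_rel + a_lin * t_rel^2 / 2),
               c_to[1] + vx * t_rel)
  cy <- ifelse(stance,
               c_to[2] + u_e[2] * (lv * t_rel + a_lin * t_rel^2 / 2),
               c_to[2] + vy * t_rel - g * t_rel^2 / 2)
  theta <- ifelse(stance,
                  theta_to + av * t_rel + alpha * t_rel^2 / 2,
                  theta_to + av * t_rel)
  # FTJ opens linearly over the stance; only grounded and take-off frames
  # use phi, so the flight extrapolation is irrelevant
  phi <- truth$ftj_rest +
    (truth$ftj_takeoff - truth$ftj_rest) * pmin((t_rel + t_s) / t_s, 1)

  ux <- cos(theta); uy <- sin(theta)
  head_x <- cx + (L / 2) * ux
  head_y <- cy + (L / 2) * uy
  abd_x <- cx - (L / 2) * ux
  abd_y <- cy - (L / 2) * uy

  # tarsus anchor while grounded: one tibia-length in front of the resting
  # abdomen tip, on the substrate
  T0 <- c(abd_x[1L] + tb, 0)
  ftj_x <- numeric(n_total); ftj_y <- numeric(n_total)
  tar_x <- numeric(n_total); tar_y <- numeric(n_total)
  for (i in seq_len(n_total)) {
    if (idx[i] < to_idx) {
      T_pt <- T0
      J <- .place_knee(c(abd_x[i], abd_y[i]), T_pt, tb, phi[i])
    } else if (idx[i] == to_idx) {
      T_pt <- T0 + c(0, cfg$takeoff_lift)
      J <- .place_knee(c(abd_x[i], abd_y[i]), T_pt, tb, phi[i])
    } else {
      nx <- -uy[i]; ny <- ux[i]    # leg folded against the body in flight
      J <- c(cx[i] - 0.20 * L * ux[i] + 0.08 * L * nx,
             cy[i] - 0.20 * L * uy[i] + 0.08 * L * ny)
      T_pt <- c(cx[i] - 0.42 * L * ux[i] + 0.12 * L * nx,
                cy[i] - 0.42 * L * uy[i] + 0.12 * L * ny)
    }
    ftj_x[i] <- J[1]; ftj_y[i] <- J[2]
    tar_x[i] <- T_pt[1]; tar_y[i] <- T_pt[2]
  }

  frames <- data.frame(frame = idx,
                       head_x = head_x, head_y = head_y,
                       abdomen_x = abd_x, abdomen_y = abd_y,
                       ftj_x = ftj_x, ftj_y = ftj_y,
                       tarsus_x = tar_x, tarsus_y = tar_y)
  if (cfg$tracking_noise_sd > 0) {
    coord_cols <- setdiff(names(frames), "frame")
    noise <- matrix(stats::rnorm(n_total * length(coord_cols), 0,
                                 cfg$tracking_noise_sd),
                    nrow = n_total)
    frames[coord_cols] <- frames[coord_cols] + noise
  }
  traj <- track_trajectory(frames, frame_rate = fps, jump_id = jump_id,
                           animal_id = animal_id, sex = sex,
                           target_height = target)
  air_time <- n_fl / fps
  attr(traj, "truth") <- data.frame(
    jump_id = jump_id, animal_id = animal_id, target_height = target,
    lv = lv, av = av, ftj_rest = truth$ftj_rest,
    ftj_takeoff = truth$ftj_takeoff,
    body_angle_takeoff = theta_to,
    takeoff_frame = to_idx, contact_frame = to_idx + n_fl,
    air_time = air_time, total_rotation = av * air_time,
    y0 = cfg$y0, stringsAsFactors = FALSE)
  traj
}

#' Simulate a complete synthetic study in memory
#'
#' Draws the roster with [sample_study()], then per-jump generative
#' parameters and trajectories.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [study_config()].
#' @return list of class `katyjump_study` with elements `config`,
#'   `morphometrics`, `animal_effects`, `assignments`, `truth` (data
#'   frame, one row per jump) and `trajectories` (named list of
#'   [track_trajectory()] objects).
#' @export
simulate_study <- function(cfg = study_config()) {
  roster <- sample_study(cfg)
  morph <- roster$morphometrics
  asg <- roster$assignments
  trajs <- vector("list", nrow(asg))
  truth_rows <- vector("list", nrow(asg))
  for (i in seq_len(nrow(asg))) {
    a <- asg$animal_id[i]
    m <- morph[morph$animal_id == a, , drop = FALSE]
    tr <- sample_jump_parameters(cfg, roster$animal_effects[a, ],
                                 asg$target_height[i],
                                 body_length = m$body_length)
    traj <- synthesize_trajectory(tr, m, cfg, jump_id = asg$jump_id[i],
                                  animal_id = a, sex = asg$sex[i])
    trajs[[i]] <- traj
    truth_rows[[i]] <- attr(traj, "truth")
  }
  names(trajs) <- asg$jump_id
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(config = cfg, morphometrics = morph,
                 animal_effects = roster$animal_effects,
                 assignments = asg, truth = truth, trajectories = trajs),
            class = "katyjump_study")
}

#' @export
print.katyjump_study <- function(x, ...) {
  cat("<katyjump_study>", nrow(x$assignments), "jumps,",
      nrow(x$morphometrics), "animals, heights",
      paste(x$config$heights * 1000, collapse = "/"), "mm\n")
  invisible(x)
}

#' Generate a synthetic study as a file tree
#'
#' Writes one trajectory CSV per jump plus `morphometrics.csv`,
#' `assignments.csv`, `truth.csv` and a `manifest.yaml` recording the
#' configuration.  Re-running with the same configuration reproduces the
#' tree byte for byte.
#'
#' @param cfg a [study_config()].
#' @param out_dir output directory (created if needed).
#' @return the in-memory study, invisibly.
#' @export
generate_study <- function(cfg, out_dir) {
  study <- simulate_study(cfg)
  traj_dir <- file.path(out_dir, "trajectories")
  dir.create(traj_dir, recursive = TRUE, showWarnings = FALSE)
  for (traj in study$trajectories)
    write_trajectory(traj, file.path(traj_dir,
                                     paste0(traj$jump_id, ".csv")))
  write_results_table(study$morphometrics,
                      file.path(out_dir, "morphometrics.csv"))
  write_results_table(study$assignments,
                      file.path(out_dir, "assignments.csv"))
  write_results_table(study$truth, file.path(out_dir, "truth.csv"))
  yaml::write_yaml(list(config = unclass(cfg),
                        n_jumps = nrow(study$assignments),
                        n_trajectory_files = length(study$trajectories)),
                   file.path(out_dir, "manifest.yaml"))
  invisible(study)
}

#' Load a generated study from disk
#'
#' @param dir directory written by [generate_study()].
#' @return a `katyjump_study` list (without `animal_effects`, which are
#'   generative internals not persisted for analysis).
#' @export
load_study <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- do.call(study_config, man$config)
  morph <- read_results_table(file.path(dir, "morphometrics.csv"))
  asg <- read_results_table(file.path(dir, "assignments.csv"))
  truth <- read_results_table(file.path(dir, "truth.csv"))
  trajs <- lapply(seq_len(nrow(asg)), function(i) {
    read_trajectory(file.path(dir, "trajectories",
                              paste0(asg$jump_id[i], ".csv")),
                    scale = 1, frame_rate = cfg$frame_rate,
                    jump_id = asg$jump_id[i], animal_id = asg$animal_id[i],
                    sex = asg$sex[i], target_height = asg$target_height[i])
  })
  names(trajs) <- asg$jump_id
  structure(list(config = cfg, morphometrics = morph, assignments = asg,
                 truth = truth, trajectories = trajs),
            class = "katyjump_study")
}
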