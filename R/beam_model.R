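# Rigid-beam null model of take-off.
#
# The body is a uniform rod (length L, mass m); the legs apply a single
# force F at a moment arm l from the centre of mass.  Newton's second law
# (F = m a) and the balance of moments (F l = (m L^2 / 12) alpha) couple
# the linear and angular accelerations -- and hence the take-off
# velocities for a force of fixed direction and arm -- as
# a / alpha = lv / av = L^2 / (12 l).  If jump height were modulated by
# leg force alone, lv and av would be positively correlated with this
# fixed ratio; posture changes alter l and break the coupling.

#' Construct a rigid-beam body model
#'
#' @param mass body mass (kg).
#' @param rod_length body (rod) length L (m).
#' @param moment_arm distance l from the centre of mass to the leg-force
#'   application point (m); must satisfy `0 < moment_arm <= rod_length/2`.
#' @return list of class `beam_model`.
#' @export
beam_model <- function(mass, rod_length, moment_arm) {
  if (any(c(mass, rod_length, moment_arm) <= 0) ||
      any(!is.finite(c(mass, rod_length, moment_arm))))
    stop("mass, rod_length and moment_arm must be strictly positive")
  if (moment_arm > rod_length / 2)
    stop("moment_arm must not exceed rod_length / 2 ",
         "(force applied on the body)")
  structure(list(mass = mass, rod_length = rod_length,
                 moment_arm = moment_arm),
            class = "beam_model")
}

#' Linear-to-angular coupling ratio of the beam model
#'
#' The ratio of linear to angular acceleration (equally, of take-off
#' linear to angular velocity) under a fixed-posture leg force:
#' `L^2 / (12 l)`.  Units are metres per radian.
#'
#' @param model a [beam_model()].
#' @return coupling ratio (m/rad).
#' @export
coupling_ratio <- function(model) {
  stopifnot(inherits(model, "beam_model"))
  if (model$moment_arm == 0)
    stop("pure translation: infinite coupling ratio (moment arm is zero)")
  model$rod_length^2 / (12 * model$moment_arm)
}

#' Angular velocity predicted from linear velocity under the beam model
#'
#' `av = 12 l lv / L^2`: linear in `lv` with positive slope, the
#' quantitative form of the null prediction that force-only modulation
#' makes lv and av rise together.
#'
#' @param lv take-off linear velocity (m/s), `>= 0`.
#' @param model a [beam_model()].
#' @return predicted angular velocity (rad/s).
#' @export
predicted_av <- function(lv, model) {
  stopifnot(inherits(model, "beam_model"))
  if (any(lv < 0)) stop("lv must be non-negative")
  lv / coupling_ratio(model)
}

#' Effective moment arm implied by an observed velocity pair
#'
#' Inverts the beam coupling: `l = av L^2 / (12 lv)`.  The arm is an
#' effective posture parameter, never measured directly; `predicted_av()`
#' composed with `posture_arm()` is the identity on `av`.
#'
#' @param lv observed linear velocity (m/s), `> 0`.
#' @param av observed angular velocity (rad/s), `>= 0`.
#' @param rod_length body length L (m).
#' @return moment arm l (m).
#' @export
posture_arm <- function(lv, av, rod_length) {
  if (any(lv <= 0)) stop("lv must be positive: arm undefined at lv = 0")
  if (any(av < 0)) stop("av must be non-negative")
  av * rod_length^2 / (12 * lv)
}

#' Rank test of the beam-model sign prediction
#'
#' Spearman rank correlation of angular on linear velocity with a
#' two-sided permutation p-value.  Under the beam-model null (force-only
#' modulation) the correlation sign is +1; a negative sign indicates
#' posture change opposing the force coupling.
#'
#' @param lv,av paired velocity observations (length >= 3).
#' @param n_permutations number of label permutations (>= 99).
#' @param seed integer seed for the permutation draw.
#' @return list of class `beam_null_test` with `slope_sign` (-1, 0, +1),
#'   `rho`, `p` (add-one permutation p-value), `n`, `n_permutations`,
#'   `seed`.
#' @export
null_hypothesis_test <- function(lv, av, n_permutations = 999, seed = 1) {
  if (length(lv) != length(av)) stop("lv and av must have equal length")
  n <- length(lv)
  if (n < 3L) stop("need at least 3 velocity pairs")
  if (n_permutations < 99) stop("need at least 99 permutations")
  if (length(unique(lv)) == 1L || length(unique(av)) == 1L)
    stop("correlation undefined: constant lv or av")
  rl <- rank(lv)
  ra <- rank(av)
  rho_of <- function(a) stats::cor(rl, a)
  rho <- rho_of(ra)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    if (abs(rho_of(sample(ra))) >= abs(rho) - 1e-12) exceed <- exceed + 1L
  }
  p <- (exceed + 1) / (n_permutations + 1)
  structure(list(slope_sign = sign(rho), rho = rho, p = p, n = n,
                 n_permutations = n_permutations, seed = seed),
            class = "beam_null_test")
}

#' @export
print.beam_null_test <- function(x, ...) {
  cat("Beam-model sign test (Spearman + permutation)\n")
  cat(sprintf("  n = %d, rho = %.3f (sign %+d), p = %.4g (%d permutations)\n",
              x$n, x$rho, x$slope_sign, x$p, x$n_permutations))
  invisible(x)
}
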