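# Rigid-rod kinetic-energy budget.
#
# The body is modelled as a uniform rod of mass m and length L rotating
# about its centre: I = m L^2 / 12.  The translational and rotational
# kinetic energies at take-off are E_trans = m v^2 / 2 and
# E_rot = I w^2 / 2; the rotation fraction 100 E_rot / (E_rot + E_trans)
# is independent of mass.

#' Moment of inertia of a uniform rod about its centre
#'
#' @param mass body mass (kg).
#' @param body_length body length (m).
#' @return moment of inertia in kg m^2, `mass * body_length^2 / 12`.
#' @export
rod_inertia <- function(mass, body_length) {
  if (any(!is.finite(mass) | mass <= 0))
    stop("mass must be strictly positive")
  if (any(!is.finite(body_length) | body_length <= 0))
    stop("body_length must be strictly positive")
  mass * body_length^2 / 12
}

#' Take-off kinetic-energy budget
#'
#' @param mass body mass (kg).
#' @param body_length body length (m).
#' @param lv linear velocity at take-off (m/s).
#' @param av angular velocity at take-off (rad/s).
#' @return list of class `energy_budget` with `inertia` (kg m^2),
#'   `E_trans` (J), `E_rot` (J) and `rot_fraction` (percent of the total
#'   kinetic energy in rotation; 0 when both energies are 0).
#' @export
kinetic_energies <- function(mass, body_length, lv, av) {
  I <- rod_inertia(mass, body_length)
  if (any(!is.finite(lv)) || any(!is.finite(av)))
    stop("lv and av must be finite")
  E_trans <- 0.5 * mass * lv^2
  E_rot <- 0.5 * I * av^2
  tot <- E_trans + E_rot
  frac <- ifelse(tot == 0, 0, 100 * E_rot / tot)
  structure(list(inertia = I, E_trans = E_trans, E_rot = E_rot,
                 rot_fraction = frac),
            class = "energy_budget")
}

#' Percent of the kinetic-energy budget in rotation
#'
#' Mass-free form of the rotation fraction: with `x = L^2 av^2 / 12`,
#' the fraction is `100 x / (x + lv^2)` -- algebraically identical to the
#' fraction from [kinetic_energies()], since mass cancels.
#'
#' @param lv linear velocity (m/s).
#' @param av angular velocity (rad/s).
#' @param body_length rod length L (m).
#' @return percent in `[0, 100]`; 0 by convention when `lv = av = 0`.
#' @export
rotation_fraction <- function(lv, av, body_length) {
  if (any(!is.finite(body_length) | body_length <= 0))
    stop("body_length must be strictly positive")
  x <- body_length^2 * av^2 / 12
  tot <- x + lv^2
  ifelse(tot == 0, 0, 100 * x / tot)
}

#' Calibrate the rod length from a known rotation fraction
#'
#' Solves `rotation_fraction(lv, av, L) = fraction` for L.  Used to fix
#' the body-length constant from the energy budget observed at one target
#' height, after which the fractions at the other heights are genuine
#' cross-checks.
#'
#' @param lv,av velocity pair (m/s, rad/s), `av != 0`, `lv > 0`.
#' @param fraction rotation fraction in percent, in `(0, 100)`.
#' @return body length L in metres.
#' @export
calibrate_body_length <- function(lv, av, fraction) {
  if (fraction <= 0 || fraction >= 100)
    stop("fraction must be in (0, 100) percent")
  if (av == 0) stop("av must be nonzero")
  if (lv <= 0) stop("lv must be positive")
  f <- fraction / 100
  x <- f / (1 - f) * lv^2       # x = L^2 av^2 / 12
  sqrt(12 * x) / abs(av)
}

#' Round to the one-significant-figure reporting style
#'
#' @param x numeric vector.
#' @return `signif(x, 1)`.
#' @export
round_sigfig1 <- function(x) signif(x, 1)
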