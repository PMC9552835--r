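#' Unit conversion constants
#'
#' Internal computation is entirely in CGS units (cm, g, s, dyn). The user
#' interface reports pressures in mmHg and flows in ml/min.
#'
#' @format `MMHG` is the number of dyn/cm^2 in one mmHg (1333.22);
#'   `MLMIN` converts cm^3/s to ml/min (60).
#' @export
MMHG <- 1333.22

#' @rdname MMHG
#' @export
MLMIN <- 60

#' Physical properties of blood
#'
#' Blood is treated as an incompressible Newtonian fluid.
#'
#' @param rho density in g/cm^3.
#' @param mu dynamic viscosity in dyn s/cm^2 (poise).
#' @return An object of class `fluid_properties` with fields `rho`, `mu` and
#'   the kinematic viscosity `nu = mu/rho` (cm^2/s).
#' @export
fluid_properties <- function(rho = 1.06, mu = 0.046) {
  stopifnot(rho > 0, mu >= 0)
  structure(list(rho = rho, mu = mu, nu = mu / rho), class = "fluid_properties")
}

#' Empirical arterial wall-law constants
#'
#' Two elasticity classes are supported: `"coronary"` for coronary arteries and
#' small systemic conduits (internal mammary and radial arteries), and
#' `"systemic"` for the aorta and its major branches. Constants are stored in
#' CGS after applying the literature scale prefixes (k1, k3 are tabulated in
#' units of 1e6 and 1e4 g/s^2/cm respectively).
#'
#' @param class `"coronary"` or `"systemic"`.
#' @return An object of class `wall_law` with fields `k1`, `k2`, `k3` (CGS) and
#'   the class name.
#' @export
wall_law <- function(class = c("coronary", "systemic")) {
  class <- match.arg(class)
  k <- switch(class,
    coronary = c(k1 = 20.0e6, k2 = -22.5, k3 = 86.5e4),
    systemic = c(k1 = 3.0e6, k2 = -9.0, k3 = 33.7e4)
  )
  structure(list(k1 = unname(k["k1"]), k2 = unname(k["k2"]),
                 k3 = unname(k["k3"]), class = class),
            class = "wall_law")
}

#' Wall stiffness parameter
#'
#' The elastic stiffness f = (4/3) E h / R0 of a thin-walled vessel, evaluated
#' through the empirical exponential fit f = (4/3) (k1 exp(k2 R0) + k3).
#'
#' @param R0 unstressed radius in cm (vectorised).
#' @param law a [wall_law()] object.
#' @return stiffness in dyn/cm^2.
#' @export
stiffness_f <- function(R0, law) {
  if (any(R0 <= 0)) stop("unstressed radius must be positive")
  (4 / 3) * (law$k1 * exp(law$k2 * R0) + law$k3)
}

#' Transmural pressure from cross-sectional area
#'
#' Square-root tube law: P - Pext = f (1 - sqrt(A0/A)) + P0. Strictly
#' increasing in A, with P = P0 + Pext at the unstressed area.
#'
#' @param A current area, cm^2 (vectorised).
#' @param A0 unstressed area, cm^2.
#' @param f wall stiffness, dyn/cm^2 (see [stiffness_f()]).
#' @param P0 reference pressure at A = A0, dyn/cm^2.
#' @param Pext external pressure, dyn/cm^2.
#' @return pressure in dyn/cm^2.
#' @export
pressure_from_area <- function(A, A0, f, P0 = 0, Pext = 0) {
  if (any(A <= 0)) stop("area must be positive")
  Pext + f * (1 - sqrt(A0 / A)) + P0
}

#' Cross-sectional area from pressure (tube-law inverse)
#'
#' Inverts the square-root tube law: A = A0 / (1 - (P - Pext - P0)/f)^2.
#' The argument (P - Pext - P0)/f must be below 1; values at or above 1
#' correspond to unbounded distension and are rejected.
#'
#' @inheritParams pressure_from_area
#' @param P pressure, dyn/cm^2 (vectorised).
#' @return area in cm^2.
#' @export
area_from_pressure <- function(P, A0, f, P0 = 0, Pext = 0) {
  x <- (P - Pext - P0) / f
  if (any(x >= 1)) stop("nonphysical pressure: (P - Pext - P0)/f must be < 1")
  A0 / (1 - x)^2
}

#' Moens-Korteweg pulse wave speed
#'
#' c0 = sqrt(f / (2 rho)): the speed of small-amplitude pressure waves on a
#' vessel at its unstressed state.
#'
#' @param R0 unstressed radius, cm.
#' @param law a [wall_law()] object.
#' @param rho blood density, g/cm^3.
#' @return wave speed in cm/s.
#' @export
wave_speed <- function(R0, law, rho = 1.06) {
  sqrt(stiffness_f(R0, law) / (2 * rho))
}

#' Velocity-profile shape and momentum correction
#'
#' The axial velocity profile implied by the Coriolis (momentum-correction)
#' coefficient alpha is phi(r) = gamma0 (1 - (r/R)^gexp) with
#' gexp = (2 - alpha)/(alpha - 1) ... expressed via the single shape parameter
#' `gamma`. `momentum_gamma()` returns gamma = (2 - alpha)/(alpha - 1);
#' `velocity_profile()` evaluates phi(r) normalised to unit mean velocity.
#' alpha = 4/3 recovers the parabolic Poiseuille profile; alpha -> 1 tends to
#' plug flow (which violates no slip and is excluded).
#'
#' @param alpha momentum-correction coefficient in (1, 4/3].
#' @export
momentum_gamma <- function(alpha) {
  if (any(alpha <= 1) || any(alpha > 4 / 3)) {
    stop("alpha must lie in (1, 4/3]")
  }
  (2 - alpha) / (alpha - 1)
}

#' @rdname momentum_gamma
#' @param r radial coordinate, cm (vectorised).
#' @param R lumen radius, cm.
#' @export
velocity_profile <- function(r, R, alpha) {
  g <- momentum_gamma(alpha)
  if (any(r < 0) || any(r > R)) stop("r must lie in [0, R]")
  # phi = (g + 2)/g * (1 - (r/R)^g): unit cross-sectional mean velocity
  ((g + 2) / g) * (1 - (r / R)^g)
}

# Friction coefficient of the 1D momentum source term: S_Q = -coef * Q / A,
# coef = 2 pi nu alpha / (alpha - 1).
friction_coefficient <- function(alpha, fluid) {
  2 * pi * fluid$nu * alpha / (alpha - 1)
}
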