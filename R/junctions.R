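#' Keller-box boundary relations
#'
#' Discrete relations linking the end area and end flow of a vessel at the new
#' time level to its interior solution, used to close junction and outlet
#' systems. For a parent vessel (right end, gridpoint M):
#' `Q_M^{n+1} = -(dx/dt) A_M^{n+1} + b`, and for a child vessel (left end,
#' gridpoint 0): `Q_0^{n+1} = +(dx/dt) A_0^{n+1} + b`, where the intercept `b`
#' collects interior values at the current and new time levels.
#'
#' @param A_old,Q_old full segment arrays at time level n.
#' @param A_new_int,Q_new_int interior-neighbour values already advanced to
#'   n+1: gridpoint M-1 for the right relation, gridpoint 1 for the left.
#' @param dx,dt grid spacing (cm) and time step (s).
#' @return list with `slope` and `intercept` of the affine map A -> Q.
#' @export
keller_right_relation <- function(A_old, Q_old, A_new_int, Q_new_int, dx, dt) {
  M <- length(A_old)
  r <- dx / dt
  list(slope = -r,
       intercept = r * (A_old[M] + A_old[M - 1] - A_new_int) -
         Q_old[M] + Q_old[M - 1] + Q_new_int)
}

#' @rdname keller_right_relation
#' @export
keller_left_relation <- function(A_old, Q_old, A_new_int, Q_new_int, dx, dt) {
  r <- dx / dt
  list(slope = r,
       intercept = -r * (A_old[1] + A_old[2] - A_new_int) -
         Q_old[1] + Q_old[2] + Q_new_int)
}

#' Describe one junction port
#'
#' A port is one segment endpoint taking part in a junction: a parent evaluated
#' at its distal end or a child at its proximal end, with its Keller boundary
#' relation and tube-law parameters.
#'
#' @param role `"parent"` or `"child"`.
#' @param relation affine boundary relation from [keller_right_relation()] /
#'   [keller_left_relation()].
#' @param A0,f tube-law parameters (cm^2, dyn/cm^2).
#' @param A_init initial Newton guess for the end area (typically the
#'   previous-step value).
#' @param P0 reference pressure, dyn/cm^2.
#' @export
junction_port <- function(role = c("parent", "child"), relation, A0, f,
                          A_init = A0, P0 = 0) {
  role <- match.arg(role)
  list(role = role, slope = relation$slope, intercept = relation$intercept,
       A0 = A0, f = f, P0 = P0, A_init = A_init)
}

#' Solve a junction's nonlinear system by Newton-Raphson
#'
#' For n ports the system has n unknown end areas: one conservation-of-mass
#' equation and n-1 total-pressure (Bernoulli) continuity equations between
#' the first parent and every other port. A stenosis junction adds the lumped
#' pressure drop to its single continuity equation. Flows follow from the
#' affine Keller relations, pressures from the tube laws.
#'
#' Newton steps are damped (halved) while any area iterate is nonpositive;
#' convergence requires the scaled residual below `tol`.
#'
#' @param ports list of [junction_port()]s (parents first).
#' @param rho blood density, g/cm^3.
#' @param stenosis optional [stenosis_coefficients()] for a stenosis junction,
#'   with `Q_prev` (throat flow at level n) and `dt` for the inertial term.
#' @param Q_prev,dt previous throat flow and time step (stenosis only).
#' @param tol residual tolerance (scaled, CGS).
#' @param maxit maximum Newton iterations.
#' @return list with vectors `A`, `Q`, `P` (dyn/cm^2), `iterations`,
#'   `residual`.
#' @export
solve_junction <- function(ports, rho = 1.06, stenosis = NULL,
                           Q_prev = 0, dt = NA_real_,
                           tol = 1e-10, maxit = 50) {
  n <- length(ports)
  roles <- vapply(ports, `[[`, "", "role")
  sgn <- ifelse(roles == "parent", 1, -1)   # sign in the mass balance
  slope <- vapply(ports, `[[`, 0, "slope")
  icpt <- vapply(ports, `[[`, 0, "intercept")
  A0 <- vapply(ports, `[[`, 0, "A0")
  f <- vapply(ports, `[[`, 0, "f")
  P0 <- vapply(ports, `[[`, 0, "P0")
  A <- vapply(ports, `[[`, 0, "A_init")
  if (!is.null(stenosis) && n != 2) stop("stenosis junction must have 2 ports")

  qfun <- function(A) slope * A + icpt
  pfun <- function(A) f * (1 - sqrt(A0 / A)) + P0
  resid <- function(A) {
    Q <- qfun(A)
    P <- pfun(A)
    phi <- P + 0.5 * rho * (Q / A)^2
    r <- numeric(n)
    r[1] <- sum(sgn * Q)
    for (a in 2:n) {
      r[a] <- phi[1] - phi[a]
      if (!is.null(stenosis)) {
        dPs <- stenosis_pressure_drop(Q[1], (Q[1] - Q_prev) / dt, stenosis)
        r[a] <- r[a] - dPs
      }
    }
    r
  }
  scale <- c(max(1, sum(abs(qfun(A)))),
             rep(max(1, abs(pfun(A[1])), f[1]), n - 1))

  it <- 0
  repeat {
    it <- it + 1
    Q <- qfun(A)
    P <- pfun(A)
    r <- resid(A)
    if (max(abs(r / scale)) < tol) break
    if (it > maxit) {
      stop(sprintf(
        "junction Newton failed to converge in %d iterations (residual %.3e)",
        maxit, max(abs(r / scale))))
    }
    # analytic Jacobian wrt areas
    dQ <- slope
    dP <- f * sqrt(A0) / (2 * A^1.5)
    dphi <- dP + rho * (Q * dQ / A^2 - Q^2 / A^3)
    J <- matrix(0, n, n)
    J[1, ] <- sgn * dQ
    for (a in 2:n) {
      J[a, 1] <- dphi[1]
      J[a, a] <- J[a, a] - dphi[a]
      if (!is.null(stenosis)) {
        J[a, 1] <- J[a, 1] -
          (stenosis$av + 2 * stenosis$at * abs(Q[1]) + stenosis$au / dt) * dQ[1]
      }
    }
    step <- solve(J, -r)
    lam <- 1
    while (any(A + lam * step <= 0) && lam > 1e-8) lam <- lam / 2
    if (any(A + lam * step <= 0)) {
      stop("junction Newton produced persistent nonpositive area iterate")
    }
    A <- A + lam * step
  }
  list(A = A, Q = qfun(A), P = pfun(A), iterations = it,
       residual = max(abs(resid(A) / scale)))
}

#' Discrete three-element Windkessel update
#'
#' One explicit step of the discretised RCR outlet model, giving the new
#' terminal flow from the new terminal pressure and current state:
#' `Q^{n+1} = Q^n + (P^{n+1}-P^n)/R1 + dt P^n/(R1 R2 Ct)
#'  - dt (R1+R2) Q^n/(R1 R2 Ct) - (Pext^{n+1}-Pext^n)/R1 - dt Pext^n/(R1 R2 Ct)`.
#'
#' @param Qn,Pn terminal flow (cm^3/s) and pressure (dyn/cm^2) at level n.
#' @param Pnp1 terminal pressure at level n+1, dyn/cm^2.
#' @param Pext_n,Pext_np1 external (back) pressure at levels n, n+1.
#' @param R1,R2 proximal and distal resistances, dyn s/cm^5.
#' @param Ct compliance, cm^5/dyn.
#' @param dt time step, s.
#' @return terminal flow at level n+1, cm^3/s.
#' @export
windkessel_update <- function(Qn, Pn, Pnp1, Pext_n, Pext_np1,
                              R1, R2, Ct, dt) {
  k <- dt / (R1 * R2 * Ct)
  Qn + (Pnp1 - Pn) / R1 + k * Pn - k * (R1 + R2) * Qn -
    (Pext_np1 - Pext_n) / R1 - k * Pext_n
}

#' Solve the terminal outlet coupling
#'
#' Couples the Keller right-boundary relation, the tube law and the discrete
#' Windkessel update into one scalar equation for the new terminal pressure.
#' The residual `Q_keller(A(P)) - Q_windkessel(P)` is strictly monotone in P,
#' so a safeguarded Newton iteration (with bisection fallback) is used.
#'
#' @param relation affine relation from [keller_right_relation()].
#' @param A0,f,P0 tube-law parameters of the terminal segment.
#' @param R1,R2,Ct Windkessel parameters.
#' @param Pn,Qn terminal pressure and flow at level n (CGS).
#' @param Pext_n,Pext_np1 back pressure at levels n and n+1 (CGS).
#' @param dt time step, s.
#' @param tol convergence tolerance on P, dyn/cm^2 (default 1e-10 mmHg).
#' @param maxit iteration cap.
#' @return list with `A`, `Q`, `P` at level n+1 and `iterations`.
#' @export
outlet_solve <- function(relation, A0, f, P0, R1, R2, Ct,
                         Pn, Qn, Pext_n, Pext_np1, dt,
                         tol = 1e-10 * 1333.22, maxit = 100) {
  k <- dt / (R1 * R2 * Ct)
  qwk_const <- Qn + k * Pn - k * (R1 + R2) * Qn - Pn / R1 -
    (Pext_np1 - Pext_n) / R1 - k * Pext_n
  h <- function(P) {
    A <- area_from_pressure(P, A0, f, P0)
    (relation$slope * A + relation$intercept) - (P / R1 + qwk_const)
  }
  dh <- function(P) {
    x <- (P - P0) / f
    dA <- 2 * A0 / (f * (1 - x)^3)
    relation$slope * dA - 1 / R1
  }
  P <- Pn
  # bracket for the bisection safeguard
  lo <- NA_real_
  hi <- NA_real_
  it <- 0
  repeat {
    it <- it + 1
    r <- h(P)
    if (r > 0) lo <- if (is.na(lo)) P else max(lo, P)  # h decreasing in P
    if (r < 0) hi <- if (is.na(hi)) P else min(hi, P)
    step <- -r / dh(P)
    Pn1 <- P + step
    # safeguard: keep within the admissible tube-law range and the bracket
    Pmax <- P0 + 0.999 * f
    if (!is.na(lo) && !is.na(hi) && (Pn1 <= lo || Pn1 >= hi)) {
      Pn1 <- (lo + hi) / 2
    }
    if (Pn1 >= Pmax) Pn1 <- (P + Pmax) / 2
    if (abs(Pn1 - P) < tol) {
      P <- Pn1
      break
    }
    if (it > maxit) stop("outlet coupling failed to converge")
    P <- Pn1
  }
  A <- area_from_pressure(P, A0, f, P0)
  list(A = A, Q = relation$slope * A + relation$intercept, P = P,
       iterations = it)
}
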