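#' Simulation configuration
#'
#' @param T cardiac period, s.
#' @param n_cycles number of cardiac cycles to run; the last cycle is stored.
#' @param samples stored samples per cycle (equally spaced in time).
#' @param dx target grid spacing, cm; every segment gets at least 3 gridpoints
#'   (its own spacing is `L / max(2, round(L/dx))`).
#' @param cfl_safety safety factor applied to the CFL bound; the bound is
#'   re-evaluated at every cycle boundary from the current velocities.
#' @param newton_tol,newton_maxit junction Newton-Raphson controls (scaled
#'   residual tolerance, iteration cap).
#' @param outlet_tol_mmHg,outlet_maxit outlet coupling controls.
#' @param drift_tol cycle-to-cycle relative L2 tolerance for the dynamic
#'   steady-state check.
#' @export
sim_config <- function(T = 0.917, n_cycles = 4, samples = 100, dx = 0.1,
                       cfl_safety = 0.9, newton_tol = 1e-10,
                       newton_maxit = 50, outlet_tol_mmHg = 1e-10,
                       outlet_maxit = 100, drift_tol = 0.01) {
  stopifnot(T > 0, n_cycles >= 1, samples >= 2, dx > 0,
            cfl_safety > 0, cfl_safety <= 1)
  list(T = T, n_cycles = n_cycles, samples = samples, dx = dx,
       cfl_safety = cfl_safety, newton_tol = newton_tol,
       newton_maxit = newton_maxit, outlet_tol_mmHg = outlet_tol_mmHg,
       outlet_maxit = outlet_maxit, drift_tol = drift_tol)
}

# Per-segment discretisation and material parameters (CGS).
discretize <- function(topo, dx_target, fluid) {
  lmin <- min(vapply(topo$segments, `[[`, 0, "length"))
  if (dx_target >= lmin / 2) {
    stop(sprintf(
      "grid spacing dx = %g must be < Lmin/2 = %g (shortest segment)",
      dx_target, lmin / 2))
  }
  lapply(topo$segments, function(s) {
    M <- max(2L, as.integer(round(s$length / dx_target)))
    law <- wall_law(s$wall)
    list(name = s$name, np = M + 1L, dx = s$length / M, A0 = s$A0,
         f = stiffness_f(s$radius, law), alpha = s$alpha,
         fric = friction_coefficient(s$alpha, fluid),
         radius = s$radius, length = s$length)
  })
}

#' Largest stable time step (CFL bound)
#'
#' dt <= dx / (|V| + c0) over every gridpoint of every segment. At rest
#' (V = 0) the bound is set by the stiffest, smallest vessel. A `vmax`
#' headroom may be supplied for anticipated velocities.
#'
#' @param topo a `network_topology`.
#' @param dx target grid spacing, cm.
#' @param fluid a [fluid_properties()].
#' @param vmax assumed maximum absolute velocity, cm/s.
#' @param safety multiplicative safety factor on the bound.
#' @return time step in s.
#' @export
cfl_max_dt <- function(topo, dx = 0.1, fluid = fluid_properties(),
                       vmax = 0, safety = 1) {
  disc <- discretize(topo, dx, fluid)
  bounds <- vapply(disc, function(d) {
    c0 <- sqrt(d$f / (2 * fluid$rho))
    d$dx / (vmax + c0)
  }, 0)
  safety * min(bounds)
}

#' One interior Lax-Wendroff step for a single segment
#'
#' Richtmyer two-step scheme on the conservative system
#' `U_t + F_x = S`, `U = (A, Q)`,
#' `F = (Q, alpha Q^2/A + (f/rho) sqrt(A0 A))`,
#' `S = (0, -2 pi nu alpha/(alpha-1) Q/A)`:
#' half-step predictor at staggered midpoints (source from averaged states),
#' then the full corrector for interior gridpoints. Boundary values are left
#' unchanged (they are set by the inlet/junction/outlet solvers).
#'
#' @param A,Q state arrays at time level n (length M+1).
#' @param dt,dx time step (s) and grid spacing (cm).
#' @param A0,f tube-law parameters.
#' @param alpha momentum-correction coefficient.
#' @param fluid a [fluid_properties()].
#' @return list with updated `A`, `Q` (boundary entries copied from input).
#' @export
lax_wendroff_step <- function(A, Q, dt, dx, A0, f, alpha,
                              fluid = fluid_properties()) {
  if (any(A <= 0)) stop("negative or zero area in state")
  M <- length(A) - 1
  rho <- fluid$rho
  fric <- friction_coefficient(alpha, fluid)
  cf <- f / rho * sqrt(A0)
  F2 <- alpha * Q^2 / A + cf * sqrt(A)
  idx <- 1:M
  Aav <- (A[idx] + A[idx + 1]) / 2
  Qav <- (Q[idx] + Q[idx + 1]) / 2
  lam <- dt / dx
  Ah <- Aav - 0.5 * lam * (Q[idx + 1] - Q[idx])
  Qh <- Qav - 0.5 * lam * (F2[idx + 1] - F2[idx]) +
    0.5 * dt * (-fric * Qav / Aav)
  if (any(Ah <= 0)) stop("negative area in half-step")
  F2h <- alpha * Qh^2 / Ah + cf * sqrt(Ah)
  Sh <- -fric * Qh / Ah
  An <- A
  Qn <- Q
  if (M >= 2) {
    j <- 2:M  # interior gridpoints (1..M-1 zero-based)
    An[j] <- A[j] - lam * (Qh[j] - Qh[j - 1])
    Qn[j] <- Q[j] - lam * (F2h[j] - F2h[j - 1]) +
      0.5 * dt * (Sh[j] + Sh[j - 1])
    if (any(An[j] <= 0) || any(!is.finite(An[j])) || any(!is.finite(Qn[j]))) {
      stop("numerical instability in Lax-Wendroff step")
    }
  }
  list(A = An, Q = Qn)
}

# waveform -> CGS list for the compiled core
wf_to_cgs <- function(wf) {
  list(time = wf$time, value = wf$pressure * MMHG, period = wf$period)
}

# Assemble stenosis model coefficients for a stenosis junction from the
# geometry of its proximal/distal halves.
junction_stenosis_coefs <- function(topo, j, fluid) {
  sp <- topo$segments[[j$parents[1]]]
  sd <- topo$segments[[j$children[1]]]
  R0 <- (sp$radius + sd$radius) / 2
  stenosis_coefficients(R0, j$stenosis$pct, j$stenosis$length,
                        alpha = sp$alpha, fluid = fluid)
}

#' Run a pulsatile network simulation
#'
#' Advances the whole network from the rest initial condition (Q = 0, A = A0,
#' P = P0 with P0 the diastolic pressure of the inlet waveform) over
#' `config$n_cycles` cardiac cycles and stores every cycle at
#' `config$samples` equally spaced times. Outlet Windkessel parameters must be
#' attached first (see [calibrate_outlets()] or [set_outlet()]).
#'
#' @param topo a calibrated `network_topology`.
#' @param inlet inlet pressure [waveform()] (mmHg).
#' @param lv left-ventricular external-pressure [waveform()] used to derive
#'   per-class outlet back pressures; may be `NULL` if `pext` is given.
#' @param config a [sim_config()].
#' @param fluid a [fluid_properties()].
#' @param venous constant systemic venous pressure, mmHg.
#' @param pext optional single [waveform()] overriding the back pressure of
#'   every outlet (used e.g. for equilibrium checks).
#' @param p0_mmHg reference pressure override; default is the minimum of the
#'   inlet waveform.
#' @param engine `"cpp"` (compiled core) or `"reference"` (pure-R loop, for
#'   verification on small problems).
#' @return an object of class `cabg_solution`: per-segment matrices `A`
#'   (cm^2), `Q` (cm^3/s), `P` (dyn/cm^2) of size gridpoints x samples for the
#'   final cycle, sample times, cycle-to-cycle drift per segment, and solver
#'   metadata.
#' @export
run_simulation <- function(topo, inlet, lv = NULL, config = sim_config(),
                           fluid = fluid_properties(), venous = 1,
                           pext = NULL, p0_mmHg = NULL,
                           engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  validate_topology(topo)
  if (is.null(topo$outlets) || !length(topo$outlets)) {
    stop("topology has no calibrated outlets; run calibrate_outlets() first")
  }
  miss <- setdiff(topo$terminals, names(topo$outlets))
  if (length(miss)) {
    stop("terminal segment(s) without Windkessel parameters: ",
         paste(miss, collapse = ", "))
  }
  if (abs(inlet$period - config$T) > 1e-9) {
    stop("inlet waveform period does not match the configured cardiac period")
  }
  P0 <- (if (is.null(p0_mmHg)) min(inlet$pressure) else p0_mmHg) * MMHG
  disc <- discretize(topo, config$dx, fluid)
  segnames <- names(disc)
  segindex <- stats::setNames(seq_along(segnames) - 1L, segnames)

  juncs <- lapply(topo$junctions, function(j) {
    sten <- NULL
    if (j$kind == "stenosis") {
      co <- junction_stenosis_coefs(topo, j, fluid)
      sten <- list(av = co$av, at = co$at, au = co$au)
    }
    list(parents = unname(segindex[j$parents]),
         children = unname(segindex[j$children]),
         sten = sten)
  })
  outs <- lapply(topo$terminals, function(nm) {
    o <- topo$outlets[[nm]]
    pw <- if (!is.null(pext)) pext else {
      external_pressure_waveform(topo$segments[[nm]]$outlet_class,
                                 lv, venous = venous)
    }
    list(seg = unname(segindex[nm]), R1 = o$R1, R2 = o$R2, Ct = o$Ct,
         pext = wf_to_cgs(pw))
  })
  dt0 <- cfl_max_dt(topo, config$dx, fluid, vmax = 0,
                    safety = config$cfl_safety)
  core_args <- list(
    segments = lapply(disc, function(d) d[c("np", "dx", "A0", "f",
                                            "alpha", "fric")]),
    junctions = juncs, outlets = outs, inlet_w = wf_to_cgs(inlet),
    P0 = P0, rho = fluid$rho, T = config$T, n_cycles = config$n_cycles,
    samples = config$samples, dt0 = dt0, cfl_safety = config$cfl_safety,
    root = unname(segindex[topo$root]),
    newton_tol = config$newton_tol, newton_maxit = config$newton_maxit,
    outlet_tol = config$outlet_tol_mmHg * MMHG,
    outlet_maxit = config$outlet_maxit)
  raw <- if (engine == "cpp") {
    do.call(.core_run, core_args)
  } else {
    do.call(reference_run, core_args)
  }
  build_solution(raw, topo, disc, config, fluid, P0)
}

build_solution <- function(raw, topo, disc, config, fluid, P0) {
  S <- config$samples
  nc <- config$n_cycles
  off <- cumsum(c(0, vapply(disc, `[[`, 0L, "np")))
  last <- (nc - 1) * S + seq_len(S)
  prev <- if (nc >= 2) (nc - 2) * S + seq_len(S) else NULL
  segs <- list()
  drift <- stats::setNames(rep(NA_real_, length(disc)), names(disc))
  for (i in seq_along(disc)) {
    d <- disc[[i]]
    rows <- off[i] + seq_len(d$np)
    A <- raw$A[rows, last, drop = FALSE]
    Q <- raw$Q[rows, last, drop = FALSE]
    P <- pressure_from_area(A, d$A0, d$f, P0)
    dim(P) <- dim(A)
    if (!is.null(prev)) {
      Qp <- raw$Q[rows, prev, drop = FALSE]
      drift[i] <- sqrt(sum((Q - Qp)^2)) / max(sqrt(sum(Qp^2)), 1e-12)
    }
    segs[[d$name]] <- list(x = seq(0, d$length, length.out = d$np),
                           A = A, Q = Q, P = P, dx = d$dx)
  }
  structure(list(
    segments = segs,
    time = raw$time[last] - raw$time[last[1]],
    period = config$T,
    drift = drift,
    dt_cycle = raw$dt_cycle,
    newton_max_iterations = raw$newton_max_iterations,
    outlet_max_iterations = raw$outlet_max_iterations,
    config = config, P0 = P0,
    topology = topo
  ), class = "cabg_solution")
}

#' @export
print.cabg_solution <- function(x, ...) {
  cat("1D-0D network solution:", length(x$segments), "segments,",
      length(x$time), "stored times, period", x$period, "s\n")
  cat(sprintf("  dt (final cycle): %.3e s; max junction Newton iterations %d; max outlet iterations %d\n",
              x$dt_cycle[length(x$dt_cycle)], x$newton_max_iterations,
              x$outlet_max_iterations))
  cat(sprintf("  cycle-to-cycle drift (rel. L2 on Q): max %.3g\n",
              max(x$drift, na.rm = TRUE)))
  invisible(x)
}

#' Assert convergence to dynamic periodic steady state
#'
#' @param sol a `cabg_solution`.
#' @param tol relative L2 tolerance between the last two cycles.
#' @param action `"error"` or `"warning"` on excess drift. Beds behind
#'   near-occlusive stenoses drain slowly and may legitimately still be
#'   settling after the standard run length; a warning lets the metrics be
#'   inspected regardless.
#' @export
check_convergence <- function(sol, tol = sol$config$drift_tol,
                              action = c("error", "warning")) {
  action <- match.arg(action)
  bad <- names(sol$drift)[!is.na(sol$drift) & sol$drift > tol]
  if (length(bad)) {
    msg <- paste0("solution not at periodic steady state (drift > ", tol,
                  ") in segment(s): ", paste(bad, collapse = ", "))
    if (action == "error") stop(msg) else warning(msg)
  }
  invisible(!length(bad))
}

# Pure-R time loop mirroring the compiled core; used to verify it on small
# problems. Same argument list as .core_run.
reference_run <- function(segments, junctions, outlets, inlet_w, P0, rho,
                          T, n_cycles, samples, dt0, cfl_safety, root,
                          newton_tol, newton_maxit, outlet_tol,
                          outlet_maxit) {
  fluid_like <- list(rho = rho)  # friction already baked into `fric`
  ns <- length(segments)
  np <- vapply(segments, `[[`, 0L, "np")
  off <- cumsum(c(0L, np))
  total <- sum(np)
  A <- numeric(total)
  Q <- numeric(total)
  for (i in seq_len(ns)) A[off[i] + seq_len(np[i])] <- segments[[i]]$A0
  wf_ev <- function(w, tt) {
    tm <- tt %% w$period
    stats::approx(c(w$time, w$period), c(w$value, w$value[1]),
                  xout = tm, rule = 2)$y
  }
  outP <- rep(P0, length(outlets))
  outQ <- rep(0, length(outlets))
  stenQ <- rep(0, length(junctions))
  nsamp <- n_cycles * samples
  Asamp <- matrix(0, total, nsamp)
  Qsamp <- matrix(0, total, nsamp)
  tsamp <- numeric(nsamp)
  dt_cycle <- numeric(n_cycles)
  tglobal <- 0
  dt <- dt0

  cfl_bound <- function(A, Q) {
    b <- Inf
    for (i in seq_len(ns)) {
      s <- segments[[i]]
      rows <- off[i] + seq_len(np[i])
      cc <- sqrt(s$f / (2 * rho)) * (A[rows] / s$A0)^0.25
      b <- min(b, s$dx / max(abs(Q[rows]) / A[rows] + cc))
    }
    b
  }
  idxA <- function(i) off[i] + seq_len(np[i])

  for (cyc in seq_len(n_cycles)) {
    bound <- cfl_safety * cfl_bound(A, Q)
    if (bound < dt) dt <- bound
    steps <- ceiling(T / dt)
    dt <- T / steps
    dt_cycle[cyc] <- dt
    targets <- floor((seq_len(samples) - 1) * steps / samples + 0.5)
    next_samp <- 1
    for (n in seq_len(steps) - 1) {
      if (next_samp <= samples && n == targets[next_samp]) {
        col <- (cyc - 1) * samples + next_samp
        Asamp[, col] <- A
        Qsamp[, col] <- Q
        tsamp[col] <- tglobal
        next_samp <- next_samp + 1
      }
      An <- A
      Qn <- Q
      for (i in seq_len(ns)) {
        s <- segments[[i]]
        rows <- idxA(i)
        st <- lax_wendroff_step_raw(A[rows], Q[rows], dt, s$dx, s$A0, s$f,
                                    s$alpha, s$fric, rho)
        An[rows] <- st$A
        Qn[rows] <- st$Q
      }
      tnew <- tglobal + dt
      # inlet
      ri <- root + 1L
      s <- segments[[ri]]
      rows <- idxA(ri)
      Pin <- wf_ev(inlet_w, tnew)
      Ain <- s$A0 / (1 - (Pin - P0) / s$f)^2
      rel <- keller_left_relation(A[rows], Q[rows], An[rows][2], Qn[rows][2],
                                  s$dx, dt)
      An[rows][1] <- Ain
      Qn[rows][1] <- rel$slope * Ain + rel$intercept
      # junctions
      for (ji in seq_along(junctions)) {
        j <- junctions[[ji]]
        ports <- list()
        for (pi in j$parents + 1L) {
          s <- segments[[pi]]
          rows <- idxA(pi)
          M <- np[pi]
          rel <- keller_right_relation(A[rows], Q[rows], An[rows][M - 1],
                                       Qn[rows][M - 1], s$dx, dt)
          ports[[length(ports) + 1]] <- junction_port(
            "parent", rel, s$A0, s$f, A_init = A[rows][M], P0 = P0)
        }
        for (ci in j$children + 1L) {
          s <- segments[[ci]]
          rows <- idxA(ci)
          rel <- keller_left_relation(A[rows], Q[rows], An[rows][2],
                                      Qn[rows][2], s$dx, dt)
          ports[[length(ports) + 1]] <- junction_port(
            "child", rel, s$A0, s$f, A_init = A[rows][1], P0 = P0)
        }
        sten <- if (!is.null(j$sten)) j$sten else NULL
        sol <- solve_junction(ports, rho = rho, stenosis = sten,
                              Q_prev = stenQ[ji], dt = dt,
                              tol = newton_tol, maxit = newton_maxit)
        k <- 0
        for (pi in j$parents + 1L) {
          k <- k + 1
          rows <- idxA(pi)
          An[rows][np[pi]] <- sol$A[k]
          Qn[rows][np[pi]] <- sol$Q[k]
        }
        for (ci in j$children + 1L) {
          k <- k + 1
          rows <- idxA(ci)
          An[rows][1] <- sol$A[k]
          Qn[rows][1] <- sol$Q[k]
        }
        if (!is.null(sten)) stenQ[ji] <- sol$Q[1]
      }
      # outlets
      for (oi in seq_along(outlets)) {
        o <- outlets[[oi]]
        si <- o$seg + 1L
        s <- segments[[si]]
        rows <- idxA(si)
        M <- np[si]
        rel <- keller_right_relation(A[rows], Q[rows], An[rows][M - 1],
                                     Qn[rows][M - 1], s$dx, dt)
        res <- outlet_solve(rel, s$A0, s$f, P0, o$R1, o$R2, o$Ct,
                            Pn = outP[oi], Qn = outQ[oi],
                            Pext_n = wf_ev(o$pext, tglobal),
                            Pext_np1 = wf_ev(o$pext, tnew), dt = dt,
                            tol = outlet_tol, maxit = outlet_maxit)
        An[rows][M] <- res$A
        Qn[rows][M] <- res$Q
        outP[oi] <- res$P
        outQ[oi] <- res$Q
      }
      A <- An
      Q <- Qn
      tglobal <- tnew
    }
  }
  list(A = Asamp, Q = Qsamp, time = tsamp, dt_cycle = dt_cycle,
       newton_max_iterations = NA_integer_, outlet_max_iterations = NA_integer_)
}

# lax_wendroff_step with pre-computed friction coefficient (internal)
lax_wendroff_step_raw <- function(A, Q, dt, dx, A0, f, alpha, fric, rho) {
  M <- length(A) - 1
  cf <- f / rho * sqrt(A0)
  F2 <- alpha * Q^2 / A + cf * sqrt(A)
  idx <- 1:M
  Aav <- (A[idx] + A[idx + 1]) / 2
  Qav <- (Q[idx] + Q[idx + 1]) / 2
  lam <- dt / dx
  Ah <- Aav - 0.5 * lam * (Q[idx + 1] - Q[idx])
  Qh <- Qav - 0.5 * lam * (F2[idx + 1] - F2[idx]) +
    0.5 * dt * (-fric * Qav / Aav)
  if (any(Ah <= 0)) stop("negative area in half-step")
  F2h <- alpha * Qh^2 / Ah + cf * sqrt(Ah)
  Sh <- -fric * Qh / Ah
  An <- A
  Qn <- Q
  if (M >= 2) {
    j <- 2:M
    An[j] <- A[j] - lam * (Qh[j] - Qh[j - 1])
    Qn[j] <- Q[j] - lam * (F2h[j] - F2h[j - 1]) + 0.5 * dt * (Sh[j] + Sh[j - 1])
  }
  list(A = An, Q = Qn)
}

#' Write a solution store to disk
#'
#' One comma-delimited table per segment (gridpoints x stored times, long
#' format) plus a YAML metadata file.
#'
#' @param sol a `cabg_solution`.
#' @param dir output directory (created if needed).
#' @export
write_solution <- function(sol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sol$segments)) {
    s <- sol$segments[[nm]]
    grid <- expand.grid(x = s$x, t = sol$time)
    df <- data.frame(x_cm = grid$x, t_s = grid$t,
                     A_cm2 = as.vector(s$A),
                     Q_ml_min = as.vector(s$Q) * MLMIN,
                     P_mmHg = as.vector(s$P) / MMHG)
    utils::write.csv(df, file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm),
                                               ".csv")), row.names = FALSE)
  }
  meta <- list(period = sol$period, P0_mmHg = sol$P0 / MMHG,
               dt_cycle = sol$dt_cycle, drift = as.list(sol$drift),
               config = sol$config)
  yaml::write_yaml(meta, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}
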