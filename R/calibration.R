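#' Prescribed distribution of cardiac output
#'
#' Resting flow prescription used to calibrate outlet resistances: the cardiac
#' output, the percentage of it perfusing the myocardium, and the split of
#' myocardial flow between the three coronary territories. Percentages for
#' individual systemic outlets are carried on the network's terminal segments
#' (`systemic_pct` column of the segment table); together with the coronary
#' fraction they must sum to 100% of cardiac output.
#'
#' @param cardiac_output cardiac output, L/min.
#' @param coronary_pct percentage of cardiac output to the coronary
#'   circulation.
#' @param territory_pct named percentages (LAD, CIRC, RCA) of myocardial flow,
#'   summing to 100.
#' @export
flow_prescription <- function(cardiac_output = 5, coronary_pct = 4.5,
                              territory_pct = c(LAD = 42, CIRC = 27,
                                                RCA = 31)) {
  stopifnot(cardiac_output > 0, coronary_pct > 0, coronary_pct < 100)
  if (!all(c("LAD", "CIRC", "RCA") %in% names(territory_pct))) {
    stop("territory_pct must name LAD, CIRC and RCA")
  }
  if (abs(sum(territory_pct) - 100) > 0.01) {
    stop("territory percentages must sum to 100")
  }
  list(cardiac_output = cardiac_output, coronary_pct = coronary_pct,
       territory_pct = territory_pct)
}

#' Characteristic impedance of a vessel
#'
#' Z0 = rho c0 / A0, the proximal Windkessel resistance that minimises wave
#' reflection at a terminal outlet.
#'
#' @param radius unstressed radius, cm.
#' @param law a [wall_law()].
#' @param rho blood density, g/cm^3.
#' @return impedance in dyn s/cm^5.
#' @export
characteristic_impedance <- function(radius, law, rho = 1.06) {
  rho * wave_speed(radius, law, rho) / (pi * radius^2)
}

#' Viscous 1D resistance of a vessel segment
#'
#' R1D = (2 alpha/(alpha - 1)) mu L / (pi R^4); at alpha = 4/3 this is the
#' Poiseuille resistance 8 mu L / (pi R^4), and the blunter profiles of large
#' arteries give larger coefficients.
#'
#' @param length segment length, cm.
#' @param radius segment radius, cm.
#' @param alpha momentum-correction coefficient.
#' @param mu dynamic viscosity, dyn s/cm^2.
#' @return resistance in dyn s/cm^5.
#' @export
resistance_1d <- function(length, radius, alpha, mu = 0.046) {
  stopifnot(length > 0, radius > 0)
  (2 * alpha / (alpha - 1)) * mu * length / (pi * radius^4)
}

#' Prescribe mean flows at every terminal outlet
#'
#' Systemic outlets receive their prescribed percentage of cardiac output.
#' The coronary fraction is split between territories, and within each
#' territory between its outlets in proportion to the 2.6th power of the
#' terminal unstressed area (an adaptation of Murray's law).
#'
#' @param topo a `network_topology`.
#' @param presc a [flow_prescription()].
#' @return named vector of terminal mean flows in ml/min.
#' @export
prescribe_terminal_flows <- function(topo, presc = flow_prescription()) {
  co <- presc$cardiac_output * 1000  # ml/min
  terms <- topo$terminals
  cls <- vapply(topo$segments[terms], `[[`, "", "outlet_class")
  sysq <- cls == "systemic"
  spct <- vapply(topo$segments[terms], `[[`, 0, "systemic_pct")
  if (any(sysq & is.na(spct))) {
    stop("systemic outlet(s) without a prescribed percentage: ",
         paste(terms[sysq & is.na(spct)], collapse = ", "))
  }
  tot <- sum(spct[sysq]) + presc$coronary_pct
  if (abs(tot - 100) > 0.01) {
    stop(sprintf(
      "systemic percentages (%.2f) + coronary fraction (%.2f) must total 100",
      sum(spct[sysq]), presc$coronary_pct))
  }
  q <- stats::setNames(numeric(length(terms)), terms)
  q[sysq] <- spct[sysq] / 100 * co
  terr <- vapply(topo$segments[terms], `[[`, "", "territory")
  if (any(!sysq & is.na(terr))) {
    stop("coronary outlet(s) without a territory: ",
         paste(terms[!sysq & is.na(terr)], collapse = ", "))
  }
  cor_total <- presc$coronary_pct / 100 * co
  for (tt in c("LAD", "CIRC", "RCA")) {
    sel <- !sysq & !is.na(terr) & terr == tt
    if (!any(sel)) next
    a0 <- vapply(topo$segments[terms[sel]], `[[`, 0, "A0")
    w <- a0^2.6 / sum(a0^2.6)
    q[sel] <- w * (presc$territory_pct[[tt]] / 100 * cor_total)
  }
  q
}

# Propagate terminal mean flows up the tree: Q(segment) = sum of its
# downstream terminal flows. Requires a tree (single-parent junctions);
# calibration is performed on the ungrafted network.
propagate_mean_flows <- function(topo, q_terminal) {
  multi <- vapply(topo$junctions, function(j) length(j$parents) > 1, TRUE)
  if (any(multi)) {
    stop("mean-flow propagation requires a tree; calibrate the ungrafted ",
         "network and carry the outlet parameters over (carry_outlets())")
  }
  q <- stats::setNames(rep(NA_real_, length(topo$segments)),
                       names(topo$segments))
  q[names(q_terminal)] <- q_terminal
  # children-before-parents: iterate until stable (network depth passes)
  repeat {
    changed <- FALSE
    for (j in topo$junctions) {
      p <- j$parents[1]
      if (is.na(q[p]) && !anyNA(q[j$children])) {
        q[p] <- sum(q[j$children])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(q)) stop("could not propagate mean flows to: ",
                     paste(names(q)[is.na(q)], collapse = ", "))
  q
}

#' Estimate mean pressure at the start of each terminal segment
#'
#' Walks the route from the network root to each terminal and subtracts the
#' product of every upstream segment's viscous 1D resistance and its mean
#' flow from the mean inlet pressure; lumped stenoses on the route contribute
#' their steady viscous + turbulent drop at the mean flow.
#'
#' @param topo a `network_topology` (tree).
#' @param q_terminal named terminal mean flows, ml/min (see
#'   [prescribe_terminal_flows()]).
#' @param inlet_mean mean inlet pressure, mmHg.
#' @param fluid a [fluid_properties()].
#' @return named vector of mean pressures (mmHg) at each terminal's start.
#' @export
estimate_upstream_mean_pressure <- function(topo, q_terminal, inlet_mean,
                                            fluid = fluid_properties()) {
  qbar <- propagate_mean_flows(topo, q_terminal) / MLMIN  # cm^3/s
  parent_of <- list()  # child segment -> its upstream junction
  for (j in topo$junctions) for (ch in j$children) parent_of[[ch]] <- j
  r1d <- vapply(topo$segments, function(s) {
    resistance_1d(s$length, s$radius, s$alpha, fluid$mu)
  }, 0)
  p <- stats::setNames(numeric(length(q_terminal)), names(q_terminal))
  for (nm in names(q_terminal)) {
    drop <- 0
    cur <- nm
    repeat {
      j <- parent_of[[cur]]
      if (is.null(j)) break
      up <- j$parents[1]
      drop <- drop + r1d[up] * qbar[up]
      if (j$kind == "stenosis") {
        co <- junction_stenosis_coefs(topo, j, fluid)
        drop <- drop + co$av * qbar[up] + co$at * qbar[up] * abs(qbar[up])
      }
      cur <- up
    }
    p[nm] <- inlet_mean - unname(drop) / MMHG
  }
  p
}

#' Distal Windkessel resistance
#'
#' R2 = (Pbar_start - Pbar_ext)/Qbar - R1D - R1; calibration fails if the
#' prescribed flow exceeds what the available pressure head can drive.
#'
#' @param p_start mean pressure at the terminal segment start, mmHg.
#' @param p_ext mean external (back) pressure, mmHg.
#' @param q_terminal prescribed mean flow, ml/min.
#' @param r1d,r1 series resistances already accounted for, dyn s/cm^5.
#' @param outlet outlet name used in error messages.
#' @return R2 in dyn s/cm^5.
#' @export
distal_resistance <- function(p_start, p_ext, q_terminal, r1d, r1,
                              outlet = "outlet") {
  if (q_terminal <= 0) stop("prescribed terminal flow must be positive")
  r2 <- (p_start - p_ext) * MMHG / (q_terminal / MLMIN) - r1d - r1
  if (r2 <= 0) {
    stop(sprintf(
      "calibration failed at '%s': R2 = %.3g <= 0 (prescribed flow too large for the available pressure head)",
      outlet, r2))
  }
  r2
}

#' Outlet compliance from the diastolic time constant
#'
#' Ct = tau / (R1 + R2): the network's total compliance, set by the diastolic
#' pressure-decay time constant, distributed over outlets in inverse
#' proportion to their lumped resistance.
#'
#' @param r1,r2 outlet resistances, dyn s/cm^5.
#' @param tau diastolic decay time constant, s.
#' @return compliance in cm^5/dyn.
#' @export
capacitance_from_tau <- function(r1, r2, tau = 1.25) {
  stopifnot(r1 > 0, r2 > 0, tau > 0)
  tau / (r1 + r2)
}

#' Calibrate every terminal Windkessel outlet
#'
#' Assigns (R1, R2, Ct) at every outlet of an ungrafted network: R1 is the
#' characteristic impedance of the terminal vessel, R2 closes the prescribed
#' mean-flow balance given the estimated upstream mean pressure and the mean
#' external pressure of the outlet's myocardial class, and Ct distributes the
#' diastolic time constant.
#'
#' @param topo a `network_topology` (tree).
#' @param presc a [flow_prescription()].
#' @param inlet inlet pressure [waveform()].
#' @param lv LV external-pressure [waveform()].
#' @param venous systemic venous pressure, mmHg.
#' @param tau diastolic time constant, s; refit it from the inlet waveform
#'   with [fit_time_constant()] if desired.
#' @param fluid a [fluid_properties()].
#' @return the topology with `$outlets` populated; the calibration table is
#'   attached as attribute `"report"` (see [calibration_report()]).
#' @export
calibrate_outlets <- function(topo, presc = flow_prescription(),
                              inlet, lv, venous = 1, tau = 1.25,
                              fluid = fluid_properties()) {
  qterm <- prescribe_terminal_flows(topo, presc)
  pstart <- estimate_upstream_mean_pressure(topo, qterm, wf_mean(inlet),
                                            fluid)
  topo$outlets <- list()
  rows <- list()
  for (nm in topo$terminals) {
    s <- topo$segments[[nm]]
    law <- wall_law(s$wall)
    r1 <- characteristic_impedance(s$radius, law, fluid$rho)
    r1d <- resistance_1d(s$length, s$radius, s$alpha, fluid$mu)
    pext <- wf_mean(external_pressure_waveform(s$outlet_class, lv, venous))
    r2 <- distal_resistance(pstart[nm], pext, qterm[nm], r1d, r1, outlet = nm)
    ct <- capacitance_from_tau(r1, r2, tau)
    topo$outlets[[nm]] <- list(R1 = r1, R2 = r2, Ct = ct, R1D = r1d,
                               Qbar = qterm[nm], Pbar_start = pstart[nm],
                               Pbar_ext = pext,
                               class = s$outlet_class,
                               territory = s$territory)
    rows[[nm]] <- data.frame(
      outlet = nm, class = s$outlet_class,
      territory = ifelse(is.na(s$territory), "", s$territory),
      Qbar_ml_min = unname(qterm[nm]), Pbar_start_mmHg = unname(pstart[nm]),
      Pbar_ext_mmHg = pext, R1 = r1, R1D = r1d, R2 = r2, Ct = ct)
  }
  attr(topo, "report") <- do.call(rbind, c(rows, make.row.names = FALSE))
  topo
}

#' @rdname calibrate_outlets
#' @export
calibration_report <- function(topo) {
  rep <- attr(topo, "report")
  if (is.null(rep)) stop("topology carries no calibration report")
  rep
}

#' Manually set one outlet's Windkessel parameters
#'
#' @param topo a `network_topology`.
#' @param name terminal segment name.
#' @param R1,R2,Ct Windkessel parameters (dyn s/cm^5, cm^5/dyn).
#' @export
set_outlet <- function(topo, name, R1, R2, Ct) {
  if (!name %in% topo$terminals) stop("not a terminal segment: ", name)
  s <- topo$segments[[name]]
  topo$outlets[[name]] <- list(R1 = R1, R2 = R2, Ct = Ct,
                               R1D = resistance_1d(s$length, s$radius,
                                                   s$alpha),
                               Qbar = NA_real_, Pbar_start = NA_real_,
                               Pbar_ext = NA_real_,
                               class = s$outlet_class,
                               territory = s$territory)
  topo
}

# Strip editing suffixes to recover the pre-edit segment name.
base_name <- function(name) {
  repeat {
    new <- sub("(_psten|_dsten|_pgraf|_dgraf)$", "", name)
    if (identical(new, name)) return(name)
    name <- new
  }
}

#' Carry calibrated outlets onto an edited network
#'
#' Outlet parameters are assigned once on the disease-free network and carried
#' unchanged into its stenotic and grafted variants: each terminal of the
#' edited network inherits the Windkessel of the disease-free terminal it
#' derives from (editing suffixes `_psten`/`_dsten`/`_pgraf`/`_dgraf`
#' stripped). Conduits re-routed away from their old outlet simply lose it.
#'
#' @param calibrated a calibrated `network_topology` (see
#'   [calibrate_outlets()]).
#' @param topo the edited topology to receive the outlets.
#' @return `topo` with `$outlets` populated.
#' @export
carry_outlets <- function(calibrated, topo) {
  topo$outlets <- list()
  for (nm in topo$terminals) {
    src <- base_name(nm)
    if (!src %in% names(calibrated$outlets)) {
      stop("no calibrated outlet found for terminal '", nm,
           "' (derived from '", src, "')")
    }
    topo$outlets[[nm]] <- calibrated$outlets[[src]]
  }
  topo
}
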