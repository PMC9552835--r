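#' Cardiac phase map
#'
#' Partition of the stored cycle into systole and diastole, with the diastolic
#' wave-free window defined as the last 75% (by duration) of diastole.
#' Systole runs from the inlet-waveform foot (t = 0 in the stored cycle) to
#' the dicrotic-notch time; diastole from the notch to the period.
#'
#' @param notch dicrotic-notch time, s (taken from the inlet waveform if a
#'   [waveform()] is supplied).
#' @param period cardiac period, s.
#' @return list with `systole`, `diastole` and `wave_free` intervals (s).
#' @export
phase_map <- function(notch, period) {
  if (inherits(notch, "waveform")) {
    period <- notch$period
    notch <- notch$notch
  }
  if (is.na(notch) || notch <= 0 || notch >= period) {
    stop("phase map needs a notch time inside (0, period)")
  }
  dia <- c(notch, period)
  list(systole = c(0, notch), diastole = dia,
       wave_free = c(dia[1] + 0.25 * diff(dia), dia[2]))
}

site_index <- function(sol, segment, site) {
  s <- sol$segments[[segment]]
  if (is.null(s)) stop("segment not in solution: ", segment)
  np <- nrow(s$Q)
  if (is.character(site)) {
    site <- switch(site, start = 1L, end = np,
                   stop("site must be 'start', 'end' or a gridpoint index"))
  }
  if (site < 1 || site > np) stop("site out of range for segment ", segment)
  as.integer(site)
}

#' Mean flow at a site
#'
#' Arithmetic mean of the stored flow samples at one gridpoint over the
#' stored cycle (the transit-time-flowmetry mean flow when evaluated on a
#' graft).
#'
#' @param sol a `cabg_solution`.
#' @param segment segment name.
#' @param site gridpoint index, or `"start"` / `"end"`.
#' @return mean flow in ml/min.
#' @export
mean_flow <- function(sol, segment, site = "end") {
  i <- site_index(sol, segment, site)
  mean(sol$segments[[segment]]$Q[i, ]) * MLMIN
}

#' Pulsatility index at a site
#'
#' PI = (Qmax - Qmin) / Qmean over the stored cycle; dimensionless. Undefined
#' (NA, with a warning) for zero mean flow.
#'
#' @inheritParams mean_flow
#' @export
pulsatility_index <- function(sol, segment, site = "end") {
  i <- site_index(sol, segment, site)
  q <- sol$segments[[segment]]$Q[i, ]
  qm <- mean(q)
  if (qm == 0) {
    warning("zero mean flow: pulsatility index undefined")
    return(NA_real_)
  }
  (max(q) - min(q)) / qm
}

#' Backflow percentage at a site
#'
#' Percentage of reverse flow over the cycle: 100 x (negative area under the
#' flow curve) / (total unsigned area), by trapezoid integration of the
#' stored samples.
#'
#' @inheritParams mean_flow
#' @export
backflow_fraction <- function(sol, segment, site = "end") {
  i <- site_index(sol, segment, site)
  q <- sol$segments[[segment]]$Q[i, ]
  tt <- sol$time
  neg <- trapz(tt, abs(pmin(q, 0)))
  tot <- trapz(tt, abs(q))
  if (tot == 0) return(structure(0, flag = "zero flow"))
  100 * neg / tot
}

#' Diastolic filling percentage at a site
#'
#' 100 x (flow integral over diastole) / (flow integral over the full cycle),
#' using the phase map's diastole interval.
#'
#' @inheritParams mean_flow
#' @param phases a [phase_map()].
#' @export
diastolic_fraction <- function(sol, segment, phases, site = "end") {
  i <- site_index(sol, segment, site)
  q <- sol$segments[[segment]]$Q[i, ]
  tt <- sol$time
  tot <- trapz(tt, q)
  if (tot <= 0) {
    warning("non-positive total flow: diastolic fraction undefined")
    return(NA_real_)
  }
  ind <- tt >= phases$diastole[1] & tt <= phases$diastole[2]
  100 * trapz(tt[ind], q[ind]) / tot
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# mean of y over the sub-interval [w1, w2] of the sampled cycle
window_mean <- function(tt, y, w) {
  ind <- tt >= w[1] & tt <= w[2]
  if (sum(ind) < 2) stop("too few samples in the window")
  trapz(tt[ind], y[ind]) / (tt[ind][sum(ind)] - tt[ind][1])
}

#' Instantaneous wave-free ratio of a stenosis
#'
#' iFR = (mean pressure at the start of the distal `_dsten` segment) /
#' (mean pressure at the end of the proximal `_psten` segment), both averaged
#' over the diastolic wave-free window, at rest.
#'
#' @param sol a `cabg_solution`.
#' @param host host segment name as it was before stenosis insertion (e.g.
#'   `"LAD1"` for `LAD1_psten`/`LAD1_dsten`).
#' @param phases a [phase_map()].
#' @return iFR (dimensionless, 1 = no pressure loss).
#' @export
ifr <- function(sol, host, phases) {
  topo <- sol$topology
  jmatch <- Filter(function(j) {
    j$kind == "stenosis" &&
      (identical(j$stenosis$host, host) ||
         j$parents[1] == paste0(host, "_psten"))
  }, topo$junctions)
  if (!length(jmatch)) {
    stop("no stenosis of host '", host, "' found in this solution")
  }
  j <- jmatch[[1]]
  pn <- j$parents[1]
  dn <- j$children[1]
  pp <- sol$segments[[pn]]$P[nrow(sol$segments[[pn]]$P), ]
  pd <- sol$segments[[dn]]$P[1, ]
  window_mean(sol$time, pd, phases$wave_free) /
    window_mean(sol$time, pp, phases$wave_free)
}

#' Regional and total myocardial perfusion
#'
#' Sums the outlet-end mean flows of the coronary outlets of each territory.
#'
#' @param sol a `cabg_solution` (its topology carries the territory
#'   assignment).
#' @return list with `territory` (named ml/min vector over LAD, CIRC, RCA)
#'   and `total` (ml/min).
#' @export
territory_perfusion <- function(sol) {
  topo <- sol$topology
  terms <- topo$terminals
  terr <- vapply(topo$segments[terms], `[[`, "", "territory")
  cls <- vapply(topo$segments[terms], `[[`, "", "outlet_class")
  coronary <- cls != "systemic"
  if (any(coronary & is.na(terr))) {
    stop("coronary outlet(s) without territory assignment: ",
         paste(terms[coronary & is.na(terr)], collapse = ", "))
  }
  out <- stats::setNames(numeric(3), c("LAD", "CIRC", "RCA"))
  for (tt in names(out)) {
    sel <- terms[coronary & !is.na(terr) & terr == tt]
    out[tt] <- sum(vapply(sel, function(nm) mean_flow(sol, nm, "end"), 0))
  }
  list(territory = out, total = sum(out))
}

#' Transit-time-flowmetry report for one graft
#'
#' Computes MGF, PI, BF and DF at the measurement site (default the distal
#' end of the graft, towards the anastomosis) and flags them against the
#' accepted intraoperative thresholds: MGF > 15 ml/min, PI < 5, BF < 3%.
#'
#' @param sol a `cabg_solution`.
#' @param graft graft segment name.
#' @param phases a [phase_map()].
#' @param site measurement gridpoint (default `"end"`).
#' @return one-row data.frame with the four indices and pass flags.
#' @export
graft_report <- function(sol, graft, phases, site = "end") {
  mgf <- mean_flow(sol, graft, site)
  pi_ <- pulsatility_index(sol, graft, site)
  bf <- backflow_fraction(sol, graft, site)
  df <- diastolic_fraction(sol, graft, phases, site)
  data.frame(graft = graft,
             MGF_ml_min = mgf, PI = pi_, BF_pct = as.numeric(bf),
             DF_pct = df,
             MGF_ok = mgf > 15, PI_ok = !is.na(pi_) && pi_ < 5,
             BF_ok = as.numeric(bf) < 3)
}

#' Full haemodynamic report for a scenario
#'
#' Mirrors the layout surgeons read: a stenosis block (location, length, %,
#' iFR) and a graft block (MGF, PI, BF, DF), plus regional and total
#' myocardial perfusion.
#'
#' @param sol a `cabg_solution`.
#' @param phases a [phase_map()].
#' @param grafts character vector of graft segment names to report (default:
#'   none).
#' @return list with data.frames `stenoses`, `grafts` and the
#'   [territory_perfusion()] list `perfusion`.
#' @export
metrics_report <- function(sol, phases, grafts = character()) {
  topo <- sol$topology
  sten <- list()
  for (j in topo$junctions) {
    if (j$kind != "stenosis") next
    host <- j$stenosis$host %||% base_name(j$parents[1])
    sten[[length(sten) + 1]] <- data.frame(
      location = host,
      length_cm = j$stenosis$length,
      pct = j$stenosis$pct,
      iFR = ifr(sol, host, phases))
  }
  gr <- lapply(grafts, function(g) graft_report(sol, g, phases))
  list(stenoses = if (length(sten)) do.call(rbind, sten) else NULL,
       grafts = if (length(gr)) do.call(rbind, gr) else NULL,
       perfusion = territory_perfusion(sol))
}
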