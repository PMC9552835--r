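# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# Typical systemic aortic branch dimensions (name, radius cm, length cm).
aortic_branch_table <- function() {
  data.frame(
    name = c("AO1", "AO2", "AA", "INN", "ARCH1", "RCC", "RSCA1", "RVA",
             "RSCA2", "RIMA", "RSCA3", "LCC", "ARCH2", "DA", "LSCA1",
             "LVA", "LSCA2", "LIMA", "LSCA3"),
    radius = c(1.47, 1.47, 1.47, 0.62, 1.12, 0.4, 0.48, 0.2, 0.47, 0.14,
               0.45, 0.37, 1.07, 0.999, 0.423, 0.2, 0.407, 0.13, 0.38),
    length = c(0.5, 0.5, 3, 3, 2, 3, 3, 13.5, 0.75, 18.2, 2.5, 3, 3.9,
               5.2, 3, 13.5, 0.75, 18.2, 2.5),
    stringsAsFactors = FALSE
  )
}

# Write the aortic-branch table as a segment CSV plus a linear chain of
# connector relations; the chain's final segment is the only terminal.
write_aortic_chain <- function(dir = tempfile("net")) {
  dir.create(dir, showWarnings = FALSE)
  tab <- aortic_branch_table()
  tab$wall <- ifelse(tab$radius < 0.3, "coronary", "systemic")
  tab$outlet_class <- c(rep("", nrow(tab) - 1), "systemic")
  tab$systemic_pct <- c(rep("", nrow(tab) - 1), "95.5")
  csv <- file.path(dir, "segments.csv")
  cfg <- file.path(dir, "relations.cfg")
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  writeLines(sprintf("connector: %s -> %s", tab$name[-nrow(tab)],
                     tab$name[-1]), cfg)
  list(csv = csv, cfg = cfg)
}

# Fast, small simulation configuration for solver tests.
quick_config <- function(...) {
  sim_config(n_cycles = 3, samples = 100, dx = 0.1, ...)
}

# Manually calibrate the single outlet of a one-vessel network to a target
# mean flow (ml/min), using the package's calibration primitives.
calibrate_single <- function(topo, inlet, lv, qbar_ml_min, venous = 1,
                             tau = 1.25) {
  nm <- topo$terminals
  stopifnot(length(nm) == 1)
  s <- topo$segments[[nm]]
  law <- wall_law(s$wall)
  r1 <- characteristic_impedance(s$radius, law)
  r1d <- resistance_1d(s$length, s$radius, s$alpha)
  pext <- wf_mean(external_pressure_waveform(s$outlet_class, lv, venous))
  r2 <- distal_resistance(wf_mean(inlet), pext, qbar_ml_min, r1d, r1,
                          outlet = nm)
  set_outlet(topo, nm, R1 = r1, R2 = r2,
             Ct = capacitance_from_tau(r1, r2, tau))
}

# Fabricate a minimal solution object with prescribed flow samples at a
# single site, for exercising the metric formulas on analytic waveforms.
synthetic_solution <- function(q_ml_min, time, period,
                               p_prox = NULL, p_dist = NULL) {
  q <- rbind(q_ml_min, q_ml_min) / 60  # cm^3/s at both gridpoints
  segs <- list(G = list(x = c(0, 1), A = q * 0 + 1, Q = q, P = q * 0 + 1))
  topo <- NULL
  if (!is.null(p_prox)) {
    segs$S_psten <- list(x = c(0, 1), A = q * 0 + 1,
                         Q = q, P = rbind(p_prox, p_prox))
    segs$S_dsten <- list(x = c(0, 1), A = q * 0 + 1,
                         Q = q, P = rbind(p_dist, p_dist))
    topo <- list(junctions = list(list(
      kind = "stenosis", parents = "S_psten", children = "S_dsten",
      stenosis = list(host = "S", pct = 50, length = 1))))
  }
  structure(list(segments = segs, time = time, period = period,
                 topology = topo),
            class = "cabg_solution")
}
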