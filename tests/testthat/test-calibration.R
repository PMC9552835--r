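test_that("characteristic impedance and 1D resistance follow their formulas", {
  cor <- wall_law("coronary")
  # independently evaluated: coronary law at R0 = 0.13 cm
  expect_equal(characteristic_impedance(0.13, cor), 22043.4990743438,
               tolerance = 1e-10)
  # at fixed c0, doubling R0 quarters Z0 (A0 quadruples)
  law0 <- cor
  law0$k2 <- 0  # radius-independent stiffness => fixed c0
  expect_equal(characteristic_impedance(0.2, law0),
               characteristic_impedance(0.1, law0) / 4)
  expect_true(all(vapply(seq(0.05, 1.5, 0.05), function(r) {
    characteristic_impedance(r, cor) > 0
  }, TRUE)))

  # alpha = 4/3 gives the classical Poiseuille resistance
  expect_equal(resistance_1d(10, 0.2, 4 / 3),
               8 * 0.046 * 10 / (pi * 0.2^4))
  # alpha = 1.1 gives coefficient 22
  expect_equal(resistance_1d(1, 1, 1.1, mu = 1), 22 / pi)
})

test_that("terminal flow prescription distributes cardiac output correctly", {
  fx <- make_toy_network()
  q <- prescribe_terminal_flows(fx$topology, fx$prescription)
  co <- 5000  # ml/min
  # systemic outlets get their percentage of CO
  expect_equal(unname(q["DA"]), 0.646 * co)
  expect_equal(unname(q["LIMA"]), 0.022 * co)
  # all terminal flows total the cardiac output
  expect_equal(sum(q), co)
  # coronary total and territory splits
  cor <- q[c("LAD2", "DIAG", "SEPT", "OM2", "CIRC2", "RVB", "PDA", "RPL")]
  expect_equal(sum(cor), 0.045 * co)
  lad <- q[c("LAD2", "DIAG", "SEPT")]
  expect_equal(sum(lad), 0.42 * 0.045 * co)
  # within-territory split follows the 2.6-power of the terminal area
  a <- vapply(fx$topology$segments[c("LAD2", "DIAG", "SEPT")], `[[`, 0, "A0")
  expect_equal(unname(lad / sum(lad)), unname(a^2.6 / sum(a^2.6)))

  # two outlets with equal areas split evenly; 2:1 areas split 2^2.6 : 1
  segs <- list(
    vessel_segment("R", 0.4, 2, "systemic"),
    vessel_segment("S", 0.3, 2, "systemic", outlet_class = "systemic",
                   systemic_pct = 95.5),
    vessel_segment("Ca", 0.2, 2, "coronary", outlet_class = "LV",
                   territory = "LAD"),
    vessel_segment("Cb", 0.1, 2, "coronary", outlet_class = "LV",
                   territory = "LAD")
  )
  topo <- network_topology(segs, list(
    cabgflow:::make_junction("trifurcation", "R", c("S", "Ca", "Cb"))))
  pr <- flow_prescription(territory_pct = c(LAD = 100, CIRC = 0, RCA = 0))
  q2 <- prescribe_terminal_flows(topo, pr)
  expect_equal(unname(q2["Ca"] / q2["Cb"]), (0.2 / 0.1)^(2 * 2.6))
  # percentages that do not close to 100 are rejected
  topo_bad <- topo
  topo_bad$segments$S$systemic_pct <- 80
  expect_error(prescribe_terminal_flows(topo_bad, pr), "total 100")
})

test_that("upstream mean-pressure estimate subtracts path resistive drops", {
  # single vessel: no upstream path, estimate = inlet mean
  topo1 <- make_single_vessel(radius = 0.15, length = 4)
  p1 <- estimate_upstream_mean_pressure(
    topo1, c(V1 = 60), inlet_mean = 92)
  expect_equal(unname(p1), 92)

  # two segments in series: drop = R1D(parent) x Qbar exactly
  segs <- list(vessel_segment("U", 0.15, 5, "coronary"),
               vessel_segment("V", 0.15, 3, "coronary",
                              outlet_class = "LV", territory = "LAD"))
  topo2 <- network_topology(segs, list(
    cabgflow:::make_junction("connector", "U", "V")))
  q <- c(V = 120)  # ml/min
  p2 <- estimate_upstream_mean_pressure(topo2, q, inlet_mean = 92)
  drop <- resistance_1d(5, 0.15, 1.1) * (120 / 60) / MMHG
  expect_equal(unname(p2), 92 - drop)
})

test_that("distal resistance closes the mean-flow balance and rejects deficits", {
  # (Pstart - Pext)/Q = 10, R1D = 2, R1 = 3 => R2 = 5 (CGS throughout)
  q <- 2  # cm^3/s
  p <- 10 * q / MMHG  # mmHg difference giving quotient 10
  expect_equal(distal_resistance(p, 0, q * MLMIN, r1d = 2, r1 = 3), 5)
  expect_error(distal_resistance(p, 0, q * MLMIN, r1d = 6, r1 = 5),
               "R2")
})

test_that("compliance distributes the diastolic time constant", {
  expect_equal(capacitance_from_tau(0.5, 0.75, tau = 1.25), 1)
  # doubling all resistances halves every compliance
  expect_equal(capacitance_from_tau(2 * 0.5, 2 * 0.75, 1.25),
               capacitance_from_tau(0.5, 0.75, 1.25) / 2)
  # additivity: sum of Ct equals tau x sum of 1/R0D
  r1 <- c(1e4, 2e4, 3e4)
  r2 <- c(5e4, 6e4, 8e4)
  ct <- mapply(capacitance_from_tau, r1, r2, tau = 1.25)
  expect_equal(sum(ct), 1.25 * sum(1 / (r1 + r2)))
})

test_that("full calibration is deterministic and internally consistent", {
  fx <- make_toy_network()
  inlet <- generate_inlet_pressure()
  lv <- generate_lv_external_pressure()
  t1 <- calibrate_outlets(fx$topology, fx$prescription, inlet, lv)
  t2 <- calibrate_outlets(fx$topology, fx$prescription, inlet, lv)
  expect_identical(calibration_report(t1), calibration_report(t2))
  rep <- calibration_report(t1)
  expect_true(all(rep$R1 > 0 & rep$R2 > 0 & rep$Ct > 0))
  # R1 is the characteristic impedance of each terminal
  for (i in seq_len(nrow(rep))) {
    s <- fx$topology$segments[[rep$outlet[i]]]
    expect_equal(rep$R1[i], characteristic_impedance(s$radius,
                                                     wall_law(s$wall)))
  }
  # Ct = tau / (R1 + R2)
  expect_equal(rep$Ct, 1.25 / (rep$R1 + rep$R2))
})

test_that("calibrated outlets carry over to edited networks by base name", {
  fx <- make_toy_network()
  inlet <- generate_inlet_pressure()
  lv <- generate_lv_external_pressure()
  base <- calibrate_outlets(fx$topology, fx$prescription, inlet, lv)
  sep <- apply_scenario(fx$topology, fx$scenarios$separate)
  sep <- carry_outlets(base, sep)
  expect_setequal(names(sep$outlets), sep$terminals)
  # the post-stenotic, post-graft OM2 remnant inherits OM2's Windkessel
  expect_equal(sep$outlets[["OM2_dsten_dgraf"]]$R2, base$outlets[["OM2"]]$R2)
  # re-routed conduits are no longer outlets
  expect_false("LIMA" %in% names(sep$outlets))
})
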