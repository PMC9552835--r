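test_that("phase map partitions the cycle and the wave-free window is 75% of diastole", {
  pm <- phase_map(0.35, 0.917)
  expect_equal(pm$systole, c(0, 0.35))
  expect_equal(pm$diastole, c(0.35, 0.917))
  expect_equal(diff(pm$wave_free), 0.75 * diff(pm$diastole))
  expect_equal(pm$wave_free[2], 0.917)
  expect_error(phase_map(NA, 1), "notch")
  # waveform dispatch
  wf <- generate_inlet_pressure()
  expect_equal(phase_map(wf)$systole[2], wf$notch)
})

T <- 0.917
tt <- seq(0, T, length.out = 101)[1:100]

test_that("mean flow and pulsatility index on analytic waveforms", {
  # constant flow
  sol <- synthetic_solution(rep(10, 100), tt, T)
  expect_equal(mean_flow(sol, "G", "end"), 10)
  expect_equal(pulsatility_index(sol, "G"), 0)
  # pure sinusoid about zero has (nearly) zero mean
  sol2 <- synthetic_solution(sin(2 * pi * tt / T), tt, T)
  expect_lt(abs(mean_flow(sol2, "G")), 1e-10)
  # Qmax 60, Qmin -10, mean 25 => PI = 2.8
  q <- 25 + 35 * sin(2 * pi * tt / T)  # max 60, min ~ -10
  sol3 <- synthetic_solution(q, tt, T)
  expect_equal(pulsatility_index(sol3, "G"),
               (max(q) - min(q)) / mean(q))
  expect_equal(mean_flow(sol3, "G"), mean(q))
  # PI is invariant to positive rescaling
  sol4 <- synthetic_solution(3.7 * q, tt, T)
  expect_equal(pulsatility_index(sol4, "G"), pulsatility_index(sol3, "G"))
  # plain mean matches trapezoid integration within sampling error
  expect_equal(mean_flow(sol3, "G"),
               cabgflow:::trapz(tt, q) / (tt[100] - tt[1]),
               tolerance = 0.01)
  expect_error(mean_flow(sol, "G", 99), "range")
})

test_that("backflow percentage on analytic waveforms", {
  # strictly positive flow: 0%
  expect_equal(backflow_fraction(synthetic_solution(rep(5, 100), tt, T), "G"),
               0)
  # odd-symmetric sinusoid: equal positive and negative areas, 50%
  expect_equal(
    as.numeric(backflow_fraction(
      synthetic_solution(sin(2 * pi * tt / T), tt, T), "G")),
    50, tolerance = 1e-3)  # samples span [0, T): last sliver truncated
  # negative lobe a third of the positive area: 25%
  q <- ifelse(tt < T / 2, 3 * sin(2 * pi * tt / T), sin(2 * pi * tt / T))
  expect_equal(
    as.numeric(backflow_fraction(synthetic_solution(q, tt, T), "G")),
    25, tolerance = 0.2)
  # BF > 0 implies a PI strictly above the zero-clipped waveform's PI
  qq <- 25 + 35 * sin(2 * pi * tt / T)
  pi_neg <- pulsatility_index(synthetic_solution(qq, tt, T), "G")
  pi_clip <- pulsatility_index(synthetic_solution(pmax(qq, 0), tt, T), "G")
  expect_gt(pi_neg, pi_clip)
})

test_that("diastolic filling percentage follows the phase map", {
  pm <- phase_map(0.4 * T, T)
  # flow only during diastole: 100%
  q <- ifelse(tt >= pm$diastole[1], 10, 0)
  expect_equal(
    diastolic_fraction(synthetic_solution(q, tt, T), "G", pm), 100,
    tolerance = 0.02)
  # constant flow: DF equals the diastolic share of the period (60%)
  qc <- rep(10, 100)
  expect_equal(
    diastolic_fraction(synthetic_solution(qc, tt, T), "G", pm), 60,
    tolerance = 0.02)
  # shifting the notch moves DF accordingly
  pm2 <- phase_map(0.5 * T, T)
  expect_equal(
    diastolic_fraction(synthetic_solution(qc, tt, T), "G", pm2), 50,
    tolerance = 0.02)
})

test_that("iFR is the wave-free pressure ratio across the stenosis", {
  pm <- phase_map(0.4 * T, T)
  # identical pressures both sides: exactly 1
  p <- rep(90 * MMHG, 100)
  sol <- synthetic_solution(rep(10, 100), tt, T, p_prox = p, p_dist = p)
  expect_equal(ifr(sol, "S", pm), 1)
  # distal exactly half the proximal on the window: 0.5
  sol2 <- synthetic_solution(rep(10, 100), tt, T, p_prox = p,
                             p_dist = p / 2)
  expect_equal(ifr(sol2, "S", pm), 0.5)
  expect_error(ifr(sol2, "NOSUCH", pm), "no stenosis")
})

test_that("graft report flags thresholds", {
  q <- 25 + 35 * sin(2 * pi * tt / T)
  pm <- phase_map(0.4 * T, T)
  rep <- graft_report(synthetic_solution(q, tt, T), "G", pm)
  expect_true(rep$MGF_ok)    # 25 ml/min > 15
  expect_true(rep$PI_ok)     # 2.8 < 5
  expect_false(rep$BF_ok)    # reverse flow present above 3%
  expect_true(rep$BF_pct > 0 && rep$BF_pct < 100)
  expect_true(rep$DF_pct >= 0 && rep$DF_pct <= 100)
})

test_that("territory perfusion sums outlet means and is additive", {
  fx <- make_toy_network()
  inlet <- generate_inlet_pressure()
  lv <- generate_lv_external_pressure()
  topo <- calibrate_outlets(fx$topology, fx$prescription, inlet, lv)
  sol <- run_simulation(topo, inlet, lv)
  perf <- territory_perfusion(sol)
  expect_equal(perf$total, sum(perf$territory))
  lad_sum <- sum(vapply(c("LAD2", "DIAG", "SEPT"),
                        function(nm) mean_flow(sol, nm, "end"), 0))
  expect_equal(unname(perf$territory["LAD"]), lad_sum)

  # graft DF is higher at the coronary (distal) end than at the take-off
  fxs <- apply_scenario(fx$topology, fx$scenarios$separate)
  fxs <- carry_outlets(topo, fxs)
  sols <- run_simulation(fxs, inlet, lv)
  pm <- phase_map(inlet)
  df_in <- diastolic_fraction(sols, "LIMA", pm, site = "start")
  df_out <- diastolic_fraction(sols, "LIMA", pm, site = "end")
  expect_gt(df_out, df_in)
})
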