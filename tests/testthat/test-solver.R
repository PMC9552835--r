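# Heavier solver checks share a couple of precomputed runs.

test_that("CFL bound scales as expected and refuses coarse grids", {
  topo <- make_single_vessel(radius = 0.15, length = 4)
  c0 <- wave_speed(0.15, wall_law("coronary"))
  expect_equal(cfl_max_dt(topo, dx = 0.1), 0.1 / c0, tolerance = 1e-12)
  # halving dx halves the bound
  expect_equal(cfl_max_dt(topo, dx = 0.05), cfl_max_dt(topo, dx = 0.1) / 2)
  # velocity headroom tightens it
  expect_lt(cfl_max_dt(topo, dx = 0.1, vmax = 100), cfl_max_dt(topo, dx = 0.1))
  # dx must leave at least 3 gridpoints in the shortest segment
  expect_error(cfl_max_dt(topo, dx = 2), "Lmin/2")
  expect_error(run_simulation(set_outlet(topo, "V1", 1e4, 1e5, 1e-6),
                              wf_constant(80, 0.917), NULL,
                              config = sim_config(dx = 2)),
               "Lmin/2")
})

test_that("uniform rest state is a fixed point of the interior scheme", {
  A0 <- pi * 0.2^2
  f <- stiffness_f(0.2, wall_law("coronary"))
  A <- rep(A0, 31)
  Q <- rep(0, 31)
  st <- lax_wendroff_step(A, Q, dt = 5e-5, dx = 0.1, A0 = A0, f = f,
                          alpha = 1.1)
  expect_identical(st$A, A)
  expect_equal(st$Q, Q)
  expect_error(lax_wendroff_step(-A, Q, 5e-5, 0.1, A0, f, 1.1), "area")
})

test_that("compiled core and pure-R reference engine agree", {
  # small bifurcated network with a stenosed limb exercises every code path
  segs <- list(
    vessel_segment("P1", 0.2, 2, "coronary"),
    vessel_segment("C1", 0.16, 3, "coronary", outlet_class = "LV",
                   territory = "LAD"),
    vessel_segment("C2", 0.15, 2, "coronary", outlet_class = "septal",
                   territory = "LAD")
  )
  topo <- network_topology(segs, list(
    cabgflow:::make_junction("bifurcation", "P1", c("C1", "C2"))))
  topo <- insert_stenosis(topo, stenosis_spec("C1", 1, 1, 70))
  topo <- set_outlet(topo, "C1_dsten", 2e4, 1.5e5, 8e-6)
  topo <- set_outlet(topo, "C2", 2.5e4, 2e5, 6e-6)
  inlet <- generate_inlet_pressure()
  lv <- generate_lv_external_pressure()
  cfg <- sim_config(n_cycles = 1, samples = 20, dx = 0.3)
  sol_c <- run_simulation(topo, inlet, lv, config = cfg, engine = "cpp")
  sol_r <- run_simulation(topo, inlet, lv, config = cfg, engine = "reference")
  for (nm in names(sol_c$segments)) {
    expect_equal(sol_r$segments[[nm]]$Q, sol_c$segments[[nm]]$Q,
                 tolerance = 1e-10)
    expect_equal(sol_r$segments[[nm]]$A, sol_c$segments[[nm]]$A,
                 tolerance = 1e-12)
  }
})

# --- pulse propagation on a long, frictionless uniform vessel ---
pulse_run <- local({
  run <- NULL
  function() {
    if (is.null(run)) {
      topo <- make_single_vessel(radius = 0.3, length = 40)
      T <- 0.4
      tt <- seq(0, T, length.out = 801)[1:800]
      pp <- 76.41 + 4 * exp(-((tt - 0.012) / 0.004)^2)  # narrow pulse
      inlet <- waveform(tt, pp, T, notch = 0.05)
      z0 <- characteristic_impedance(0.3, wall_law("coronary"))
      topo <- set_outlet(topo, "V1", R1 = z0, R2 = 100 * z0, Ct = 1e-4)
      run <<- run_simulation(
        topo, inlet, NULL, pext = wf_constant(76.41, T),
        config = sim_config(T = T, n_cycles = 1, samples = 400, dx = 0.1),
        fluid = fluid_properties(mu = 0),  # frictionless
        p0_mmHg = 76.41)
    }
    run
  }
})

test_that("small pulses travel at the Moens-Korteweg speed", {
  sol <- pulse_run()
  c0 <- wave_speed(0.3, wall_law("coronary"))
  x <- sol$segments$V1$x
  i1 <- which.min(abs(x - 10))
  i2 <- which.min(abs(x - 30))
  t1 <- peak_time(sol$time, sol$segments$V1$A[i1, ])
  t2 <- peak_time(sol$time, sol$segments$V1$A[i2, ])
  c_meas <- (x[i2] - x[i1]) / (t2 - t1)
  expect_equal(c_meas, c0, tolerance = 0.02)
})

test_that("a characteristic-impedance outlet is nearly reflectionless", {
  sol <- pulse_run()
  x <- sol$segments$V1$x
  i <- which.min(abs(x - 20))
  A <- sol$segments$V1$A[i, ] - pi * 0.3^2
  c0 <- wave_speed(0.3, wall_law("coronary"))
  t_inc <- 0.012 + 20 / c0          # incident passage
  t_ref <- 0.012 + 60 / c0          # reflected passage (40 + 20 cm)
  inc <- max(A[sol$time > t_inc - 0.01 & sol$time < t_inc + 0.01])
  ref <- max(abs(A[sol$time > t_ref - 0.012 & sol$time < t_ref + 0.012]))
  expect_lt(ref, 0.05 * inc)
})

test_that("interior mass is conserved against the boundary flux", {
  sol <- pulse_run()
  s <- sol$segments$V1
  dx <- s$dx
  # ∫A dx by trapezoid at first and last stored times
  mass <- function(col) {
    a <- s$A[, col]
    dx * (sum(a) - (a[1] + a[length(a)]) / 2)
  }
  # compare while the pulse volume is inside the vessel
  n <- which.min(abs(sol$time - 0.025))
  dmass <- mass(n) - mass(1)
  sel <- seq_len(n)
  flux <- cabgflow:::trapz(sol$time[sel], s$Q[1, sel] - s$Q[nrow(s$Q), sel])
  expect_gt(abs(flux), 1e-4)  # a meaningful volume has entered
  expect_lt(abs(dmass - flux), 0.01 * abs(flux))
})

test_that("steady single-vessel flow matches the series-resistance value", {
  topo <- make_single_vessel(radius = 0.15, length = 4)
  inlet <- wf_constant(100, 0.917)
  pext <- wf_constant(1, 0.917)
  law <- wall_law("coronary")
  R1 <- characteristic_impedance(0.15, law)
  R1D <- resistance_1d(4, 0.15, 1.1)
  R2 <- 110000
  topo <- set_outlet(topo, "V1", R1, R2, Ct = 5e-7)
  # reference pressure at the operating point so the vessel runs at its
  # unstressed area (R1D is defined for the unstressed radius)
  sol <- run_simulation(topo, inlet, NULL, pext = pext,
                        config = quick_config(), p0_mmHg = 100)
  q <- mean_flow(sol, "V1", "end") / 60  # cm^3/s
  q_expect <- (100 - 1) * 1333.22 / (R1D + R1 + R2)
  expect_equal(q, q_expect, tolerance = 0.01)
  # equivalently: the recovered 1D gradient matches the alpha-corrected
  # Poiseuille resistance within 1%
  dp <- sol$segments$V1$P[1, 100] - sol$segments$V1$P[nrow(sol$segments$V1$P), 100]
  expect_equal(dp / q, R1D, tolerance = 0.01)
})

test_that("zero transmural forcing keeps the network at rest", {
  topo <- make_single_vessel(radius = 0.15, length = 4)
  topo <- set_outlet(topo, "V1", 1e4, 1e5, 1e-6)
  P0 <- 76.41
  sol <- run_simulation(topo, wf_constant(P0, 0.917), NULL,
                        pext = wf_constant(P0, 0.917),
                        config = sim_config(n_cycles = 2))
  expect_lt(max(abs(sol$segments$V1$Q)), 1e-12)
  expect_equal(sol$segments$V1$A,
               matrix(pi * 0.15^2, nrow(sol$segments$V1$A),
                      ncol(sol$segments$V1$A)),
               tolerance = 1e-14)
})

test_that("toy network reaches periodic steady state within the run", {
  fx <- make_toy_network()
  inlet <- generate_inlet_pressure()
  lv <- generate_lv_external_pressure()
  topo <- calibrate_outlets(fx$topology, fx$prescription, inlet, lv)
  sol <- run_simulation(topo, inlet, lv)
  expect_true(all(sol$drift < 0.01))
  expect_true(check_convergence(sol))
  # stored P is exactly the tube law of stored A
  s <- sol$segments$LAD2
  f <- stiffness_f(0.18, wall_law("coronary"))
  expect_identical(s$P, {
    p <- pressure_from_area(s$A, pi * 0.18^2, f, sol$P0)
    dim(p) <- dim(s$A)
    p
  })
})

test_that("grid refinement changes mean flows by little (second-order trend)", {
  fx <- make_toy_network()
  inlet <- generate_inlet_pressure()
  lv <- generate_lv_external_pressure()
  topo <- calibrate_outlets(fx$topology, fx$prescription, inlet, lv)
  sol1 <- run_simulation(topo, inlet, lv, config = sim_config(dx = 0.1))
  sol2 <- run_simulation(topo, inlet, lv, config = sim_config(dx = 0.05))
  q1 <- vapply(names(sol1$segments), function(nm) mean_flow(sol1, nm, "end"), 0)
  q2 <- vapply(names(sol2$segments), function(nm) mean_flow(sol2, nm, "end"), 0)
  expect_lt(max(abs(q1 - q2) / max(abs(q2))), 0.01)
})

test_that("solution stores write to disk with metadata", {
  topo <- make_single_vessel(radius = 0.15, length = 4)
  topo <- set_outlet(topo, "V1", 1e4, 1e5, 1e-6)
  sol <- run_simulation(topo, wf_constant(90, 0.917), NULL,
                        pext = wf_constant(1, 0.917),
                        config = sim_config(n_cycles = 1, samples = 10))
  dir <- tempfile("store")
  write_solution(sol, dir)
  expect_true(file.exists(file.path(dir, "V1.csv")))
  expect_true(file.exists(file.path(dir, "run_metadata.yaml")))
  df <- read.csv(file.path(dir, "V1.csv"))
  expect_equal(nrow(df), nrow(sol$segments$V1$Q) * 10)
})
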