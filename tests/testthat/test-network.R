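test_that("a typical aortic-branch table loads into a validated chain", {
  files <- write_aortic_chain()
  topo <- load_network(files$csv, files$cfg)
  ce <- count_elements(topo)
  expect_equal(ce$n_segments, 19)
  expect_equal(unname(ce$n_junctions_by_type["connector"]), 18L)
  expect_equal(topo$segments[["LIMA"]]$radius, 0.13)
  expect_equal(topo$segments[["LIMA"]]$length, 18.2)
  expect_equal(topo$root, "AO1")
  # default momentum correction by wall class
  expect_equal(topo$segments[["AO1"]]$alpha, 1.05)
  expect_equal(topo$segments[["LIMA"]]$alpha, 1.1)
})

test_that("degenerate and broken networks are handled", {
  # single segment, no relations
  seg <- vessel_segment("V", 0.2, 3, wall = "coronary",
                        outlet_class = "LV", territory = "LAD")
  topo <- network_topology(list(seg))
  ce <- count_elements(topo)
  expect_equal(ce$n_segments, 1)
  expect_length(ce$n_junctions_by_type, 0)
  expect_equal(topo$root, "V")
  expect_equal(topo$terminals, "V")

  # relations referencing a segment absent from the table name the culprit
  files <- write_aortic_chain()
  cfg2 <- tempfile()
  writeLines(c(readLines(files$cfg), "bifurcation: LSCA3 -> LAD9, LCC"),
             cfg2)
  expect_error(load_network(files$csv, cfg2), "LAD9")

  # invalid geometry rejected at construction
  expect_error(vessel_segment("x", -0.1, 3, "coronary"), "radius")
  expect_error(vessel_segment("x", 0.1, 0, "coronary"), "length")
  expect_error(vessel_segment("x", 0.1, 3, "coronary", alpha = 2), "alpha")
})

test_that("network files round-trip to full precision", {
  fx <- make_toy_network()
  topo <- apply_scenario(fx$topology, fx$scenarios$separate)
  csv <- tempfile(fileext = ".csv")
  cfg <- tempfile(fileext = ".cfg")
  write_network(topo, csv, cfg)
  back <- load_network(csv, cfg)
  expect_setequal(names(back$segments), names(topo$segments))
  for (nm in names(topo$segments)) {
    expect_identical(back$segments[[nm]]$radius, topo$segments[[nm]]$radius)
    expect_identical(back$segments[[nm]]$length, topo$segments[[nm]]$length)
  }
  expect_equal(count_elements(back), count_elements(topo))
  # stenosis parameters survive the round trip
  ksten <- which(vapply(back$junctions, `[[`, "", "kind") == "stenosis")
  expect_length(ksten, 3)
  expect_setequal(
    vapply(back$junctions[ksten], function(j) j$stenosis$pct, 0),
    c(90, 99, 90))
})

test_that("stenosis insertion splits, renames and conserves length", {
  seg <- vessel_segment("LAD_1", 0.18, 2.3, wall = "coronary",
                        outlet_class = "LV", territory = "LAD")
  topo <- network_topology(list(seg))
  topo2 <- insert_stenosis(topo, stenosis_spec("LAD_1", 0.35, 1.6, 90))
  expect_setequal(names(topo2$segments), c("LAD_1_psten", "LAD_1_dsten"))
  expect_equal(topo2$segments[["LAD_1_psten"]]$length, 0.35)
  expect_equal(topo2$segments[["LAD_1_dsten"]]$length, 0.35)
  # total centreline length conserved: psten + throat + dsten = host
  j <- topo2$junctions[[1]]
  expect_equal(topo2$segments[["LAD_1_psten"]]$length + j$stenosis$length +
                 topo2$segments[["LAD_1_dsten"]]$length, 2.3)
  expect_equal(j$kind, "stenosis")
  # outlet annotation moves to the distal half
  expect_equal(topo2$segments[["LAD_1_dsten"]]$outlet_class, "LV")
  expect_true(is.na(topo2$segments[["LAD_1_psten"]]$outlet_class))
  expect_silent(validate_topology(topo2))

  # geometry errors
  expect_error(insert_stenosis(topo, stenosis_spec("LAD_1", 0.35, 2.3, 90)),
               "cannot split")
  expect_error(
    insert_stenosis(topo2, stenosis_spec("LAD_1_psten", 0.1, 0.3, 50)),
    "cannot split")
  expect_error(stenosis_spec("x", 1, 1, 100), "percent")
})

test_that("stenosis coefficient derivation follows the lumped model", {
  co0 <- stenosis_coefficients(0.15, 0, 1)
  expect_equal(co0$Kv, 0)   # area ratio 1: no viscous excess
  expect_equal(co0$at, 0)   # and no turbulence term
  expect_gt(co0$au, 0)      # inertial term persists (open throat)
  expect_equal(stenosis_coefficients(0.2, 90, 1)$ratio, 10)  # 100/(100-90)

  # independently evaluated 90% case (R0 = 0.15 cm, Ls = 1 cm, alpha = 1.1)
  co <- stenosis_coefficients(0.15, 90, 1)
  expect_equal(co$Kt, 1.52)
  expect_equal(co$Ku, 1.2)
  expect_equal(co$La, 0.985584060880284, tolerance = 1e-12)
  expect_equal(co$Kv, 23417.4772865156, tolerance = 1e-10)
  expect_equal(co$av, 50797.7286474051, tolerance = 1e-10)
  expect_equal(co$at, 13059.8952867628, tolerance = 1e-10)
  expect_equal(co$au, 179.951188989236, tolerance = 1e-10)
  # steady Q = 1 cm^3/s pressure drop, term by term
  expect_equal(stenosis_pressure_drop(1, 0, co), 63857.6239341679,
               tolerance = 1e-10)
  # term isolation: Q = 0 leaves only the inertial contribution
  expect_equal(stenosis_pressure_drop(0, 2.5, co), co$au * 2.5)
  # zero grade, steady flow: no pressure drop at all
  expect_equal(stenosis_pressure_drop(1, 0, co0), co0$av * 1)
  expect_equal(co0$av, 0)

  # drop is nondecreasing in grade at fixed positive steady flow
  drops <- vapply(seq(0, 99, 3), function(p) {
    stenosis_pressure_drop(1, 0, stenosis_coefficients(0.15, p, 1))
  }, 0)
  expect_true(all(diff(drops) >= 0))
})

test_that("graft insertion creates the junction kinds of each graft type", {
  fx <- make_toy_network()
  sep <- apply_scenario(fx$topology, fx$scenarios$separate)
  kinds <- table(vapply(sep$junctions, `[[`, "", "kind"))
  # in-situ LIMA / RIMA and the RA distal anastomosis: reverse bifurcations
  expect_equal(unname(kinds["reverse_bifurcation"]), 3L)
  # the free RA off the aorta adds a take-off bifurcation (aorta split)
  expect_true("AA_pgraf" %in% names(sep$segments))
  expect_true("AA_dgraf" %in% names(sep$segments))
  expect_equal(unname(kinds["stenosis"]), 3L)
  # in-situ conduits lost their terminal outlets
  expect_false("LIMA" %in% sep$terminals)
  expect_true(is.na(sep$segments[["LIMA"]]$outlet_class))
  # host split conserves length
  expect_equal(sep$segments[["LAD2_pgraf"]]$length +
                 sep$segments[["LAD2_dgraf"]]$length, 3.0)

  comp <- apply_scenario(fx$topology, fx$scenarios$composite)
  kindsc <- table(vapply(comp$junctions, `[[`, "", "kind"))
  expect_equal(unname(kindsc["cross_junction"]), 1L)
  expect_equal(unname(kindsc["connector"]), 1L)
  expect_equal(unname(kindsc["reverse_bifurcation"]), 2L)
  expect_silent(validate_topology(comp))
})

test_that("graft insertion rejects ill-posed edits", {
  fx <- make_toy_network()
  topo <- fx$topology
  # split at the very end of the target is impossible
  expect_error(insert_graft(topo, graft_spec(
    "in_situ", conduit = "LIMA", target = "LAD2", position = 3.0)),
    "cannot split")
  # a conduit already attached cannot be grafted again
  t2 <- insert_graft(topo, graft_spec("in_situ", conduit = "LIMA",
                                      target = "LAD2", position = 1.5))
  expect_error(insert_graft(t2, graft_spec(
    "end_to_side", conduit = "LIMA", target = "DIAG", position = 1)),
    "already attached")
  # a sequential exit limb left dangling fails validation
  t3 <- insert_graft(topo, graft_spec(
    "y_composite", name = "FREE", radius = 0.14, length = 5,
    source = "LIMA", source_position = 9))
  expect_error(validate_topology(t3), "FREE")
  expect_error(graft_spec("sequential", conduit = "a"), "requires")
})

test_that("junction arity table is enforced", {
  expect_error(cabgflow:::make_junction("bifurcation", c("a", "b"), "c"),
               "requires")
  expect_error(cabgflow:::make_junction("pentafurcation", "a", "b"),
               "unsupported")
})
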