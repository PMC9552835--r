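#' Deterministic toy coronary network with grafting scenarios
#'
#' Builds a reduced but anatomically structured 1D-0D network for testing and
#' demonstration: a systemic aortic trunk with internal-mammary take-offs and
#' five systemic outlets, plus left and right coronary trees with eight
#' coronary outlets over the three perfusion territories, 24 segments in all.
#' Three editing scenarios accompany it:
#' \describe{
#'   \item{`stenotic`}{three stenoses: LAD1 90% (1.0 cm), OM2 99% (1.2 cm),
#'     RCA2 90% (1.5 cm).}
#'   \item{`separate`}{the stenoses plus three separate grafts: in-situ LIMA
#'     to LAD2, in-situ RIMA to the post-stenotic OM2, and a free radial
#'     artery off the ascending aorta to the PDA.}
#'   \item{`composite`}{the stenoses plus a composite graft: in-situ LIMA to
#'     LAD2 with a Y limb off the LIMA, extended end-to-end, passing
#'     side-to-side through the post-stenotic OM2 (cross-junction) and ending
#'     on the PDA. Exercises every junction type.}
#' }
#'
#' With `jitter > 0`, radii and lengths are perturbed by the given relative
#' amount under the seed (the same seed always yields the same network);
#' the default `jitter = 0` gives the fixed reference geometry.
#'
#' @param seed integer seed controlling the (optional) geometry jitter.
#' @param jitter relative standard deviation of the geometry perturbation.
#' @return list with `topology` (validated disease-free network), `scenarios`
#'   (named list of scenario edit lists for [apply_scenario()]), `prescription`
#'   (a [flow_prescription()]), and `grafts` (named list: scenario ->
#'   graft segment names for reporting).
#' @export
make_toy_network <- function(seed = 1, jitter = 0) {
  set.seed(seed)
  row <- function(name, radius, length, wall, class = NA, terr = NA,
                  pct = NA) {
    list(name = name, radius = radius, length = length, wall = wall,
         class = class, terr = terr, pct = pct)
  }
  rows <- list(
    # systemic trunk (typical adult dimensions)
    row("AO1", 1.47, 0.5, "systemic"),
    row("AO2", 1.47, 0.5, "systemic"),
    row("AA", 1.47, 3.0, "systemic"),
    row("ARCH1", 1.12, 2.0, "systemic"),
    row("INN", 0.62, 3.0, "systemic"),
    row("RIMA", 0.14, 18.2, "coronary", class = "systemic", pct = 2.4),
    row("RSCA3", 0.45, 2.5, "systemic", class = "systemic", pct = 16.9),
    row("DA", 0.999, 5.2, "systemic", class = "systemic", pct = 64.6),
    row("LSCA1", 0.423, 3.0, "systemic"),
    row("LIMA", 0.13, 18.2, "coronary", class = "systemic", pct = 2.2),
    row("LSCA3", 0.38, 2.5, "systemic", class = "systemic", pct = 9.4),
    # left coronary tree
    row("LMAIN", 0.25, 1.0, "coronary"),
    row("LAD1", 0.22, 2.3, "coronary"),
    row("LAD2", 0.18, 3.0, "coronary", class = "LV", terr = "LAD"),
    row("DIAG", 0.12, 2.5, "coronary", class = "LV", terr = "LAD"),
    row("SEPT", 0.10, 2.0, "coronary", class = "septal", terr = "LAD"),
    row("CIRC1", 0.20, 2.0, "coronary"),
    row("OM2", 0.15, 3.0, "coronary", class = "LV", terr = "CIRC"),
    row("CIRC2", 0.14, 2.5, "coronary", class = "LV", terr = "CIRC"),
    # right coronary tree
    row("RCA1", 0.20, 2.5, "coronary"),
    row("RCA2", 0.18, 2.5, "coronary"),
    row("RVB", 0.10, 2.0, "coronary", class = "RV", terr = "RCA"),
    row("PDA", 0.14, 3.0, "coronary", class = "septal", terr = "RCA"),
    row("RPL", 0.12, 2.5, "coronary", class = "LV", terr = "RCA")
  )
  segs <- lapply(rows, function(r) {
    radius <- r$radius
    length <- r$length
    if (jitter > 0) {
      radius <- radius * exp(stats::rnorm(1, 0, jitter))
      length <- length * exp(stats::rnorm(1, 0, jitter))
    }
    vessel_segment(r$name, radius, length, wall = r$wall,
                   outlet_class = if (is.na(r$class)) NA_character_ else r$class,
                   territory = if (is.na(r$terr)) NA_character_ else r$terr,
                   systemic_pct = r$pct)
  })
  juncs <- list(
    make_junction("bifurcation", "AO1", c("AO2", "LMAIN")),
    make_junction("bifurcation", "AO2", c("AA", "RCA1")),
    make_junction("bifurcation", "AA", c("ARCH1", "INN")),
    make_junction("bifurcation", "ARCH1", c("DA", "LSCA1")),
    make_junction("bifurcation", "INN", c("RIMA", "RSCA3")),
    make_junction("bifurcation", "LSCA1", c("LIMA", "LSCA3")),
    make_junction("bifurcation", "LMAIN", c("LAD1", "CIRC1")),
    make_junction("trifurcation", "LAD1", c("LAD2", "DIAG", "SEPT")),
    make_junction("bifurcation", "CIRC1", c("OM2", "CIRC2")),
    make_junction("bifurcation", "RCA1", c("RCA2", "RVB")),
    make_junction("bifurcation", "RCA2", c("PDA", "RPL"))
  )
  topo <- network_topology(segs, juncs)

  stenoses <- list(
    stenosis_spec("LAD1", position = 0.6, length = 1.0, pct = 90),
    stenosis_spec("OM2", position = 0.5, length = 1.2, pct = 99),
    stenosis_spec("RCA2", position = 0.5, length = 1.5, pct = 90)
  )
  scenarios <- list(
    stenotic = list(stenoses = stenoses, grafts = list()),
    separate = list(
      stenoses = stenoses,
      grafts = list(
        graft_spec("in_situ", conduit = "LIMA", target = "LAD2",
                   position = 1.5),
        graft_spec("in_situ", conduit = "RIMA", target = "OM2_dsten",
                   position = 0.7),
        graft_spec("free_aortic", name = "RA", radius = 0.17, length = 15,
                   source = "AA", source_position = 1.5,
                   target = "PDA", position = 1.5)
      )
    ),
    composite = list(
      stenoses = stenoses,
      grafts = list(
        graft_spec("in_situ", conduit = "LIMA", target = "LAD2",
                   position = 1.5),
        graft_spec("y_composite", name = "RIMA_Y", radius = 0.14, length = 6,
                   source = "LIMA", source_position = 10),
        graft_spec("i_extension", conduit = "RIMA_Y", name = "RIMA_Y2",
                   length = 6),
        graft_spec("sequential", conduit = "RIMA_Y2", target = "OM2_dsten",
                   position = 0.7, name = "RIMA_PDA", length = 8),
        graft_spec("end_to_side", conduit = "RIMA_PDA", target = "PDA",
                   position = 1.5)
      )
    )
  )
  grafts <- list(
    stenotic = character(),
    separate = c(LIMA = "LIMA", RIMA = "RIMA", RA = "RA"),
    composite = c(LIMA_common = "LIMA_pgraf", LIMA_LAD = "LIMA_dgraf",
                  RIMA_Y = "RIMA_Y2", RIMA_PDA = "RIMA_PDA")
  )
  list(topology = topo, scenarios = scenarios,
       prescription = flow_prescription(), grafts = grafts)
}

#' Single-vessel fixture with one Windkessel outlet
#'
#' A minimal network for solver verification: one segment coupled to one
#' outlet; optionally a stenosis mid-vessel.
#'
#' @param radius,length vessel geometry, cm.
#' @param wall wall-law class.
#' @param outlet_class external-pressure class.
#' @param territory coronary territory (if coronary).
#' @param stenosis_pct optional percent stenosis to insert mid-vessel.
#' @param stenosis_length stenosis length, cm.
#' @return a `network_topology` (uncalibrated).
#' @export
make_single_vessel <- function(radius = 0.15, length = 4,
                               wall = "coronary", outlet_class = "LV",
                               territory = "LAD",
                               stenosis_pct = NULL, stenosis_length = 1) {
  seg <- vessel_segment("V1", radius, length, wall = wall,
                        outlet_class = outlet_class, territory = territory)
  topo <- network_topology(list(seg))
  if (!is.null(stenosis_pct)) {
    pos <- (length - stenosis_length) / 2
    topo <- insert_stenosis(topo, stenosis_spec("V1", pos, stenosis_length,
                                                stenosis_pct))
    validate_topology(topo)
  }
  topo
}
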