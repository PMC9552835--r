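#' @useDynLib cabgflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Validate network files
#'
#' Loads a segment table and relations config, validates the topology and
#' returns (invisibly) the validation report while printing a summary.
#'
#' @param segment_csv,relations_cfg network file paths (see [load_network()]).
#' @param scenario optional scenario YAML applied before validation.
#' @return invisibly, the validation report.
#' @export
cabg_validate <- function(segment_csv, relations_cfg = NULL,
                          scenario = NULL) {
  topo <- load_network(segment_csv, relations_cfg)
  if (!is.null(scenario)) topo <- apply_scenario(topo, scenario)
  rep <- validate_topology(topo)
  cat(sprintf("valid network: %d segments, %d junctions\n",
              rep$n_segments, rep$n_junctions))
  if (length(rep$junction_counts)) {
    print(rep$junction_counts)
  }
  invisible(rep)
}

#' Run the full calibrate-and-simulate pipeline
#'
#' Loads the network, applies an optional scenario, calibrates outlets on the
#' unedited network (carrying them onto the edited one), runs the pulsatile
#' simulation and optionally writes the solution store.
#'
#' @param segment_csv,relations_cfg network file paths.
#' @param inlet inlet pressure [waveform()] or waveform file path.
#' @param lv LV external-pressure [waveform()] or file path.
#' @param scenario optional scenario (list or YAML path).
#' @param presc a [flow_prescription()].
#' @param config a [sim_config()].
#' @param tau diastolic time constant for the compliance calibration, s.
#' @param venous systemic venous pressure, mmHg.
#' @param out_dir optional directory for the solution store.
#' @param engine solver engine (see [run_simulation()]).
#' @return the `cabg_solution`.
#' @export
cabg_run <- function(segment_csv, relations_cfg = NULL, inlet, lv,
                     scenario = NULL, presc = flow_prescription(),
                     config = sim_config(), tau = 1.25, venous = 1,
                     out_dir = NULL, engine = "cpp") {
  if (is.character(inlet)) inlet <- read_waveform(inlet)
  if (is.character(lv)) lv <- read_waveform(lv)
  base <- load_network(segment_csv, relations_cfg)
  base <- calibrate_outlets(base, presc, inlet, lv, venous = venous,
                            tau = tau)
  topo <- base
  if (!is.null(scenario)) {
    topo <- apply_scenario(load_network(segment_csv, relations_cfg), scenario)
    topo <- carry_outlets(base, topo)
  }
  sol <- run_simulation(topo, inlet, lv, config = config, venous = venous,
                        engine = engine)
  check_convergence(sol, action = "warning")
  if (!is.null(out_dir)) write_solution(sol, out_dir)
  sol
}

#' Print a scenario metrics report
#'
#' @param sol a `cabg_solution`.
#' @param inlet inlet [waveform()] (for the phase map) or a [phase_map()].
#' @param grafts graft segment names to report.
#' @return the [metrics_report()] list, invisibly.
#' @export
cabg_metrics <- function(sol, inlet, grafts = character()) {
  phases <- if (inherits(inlet, "waveform")) phase_map(inlet) else inlet
  rep <- metrics_report(sol, phases, grafts = grafts)
  if (!is.null(rep$stenoses)) {
    cat("Functional significance of stenoses:\n")
    print(rep$stenoses, row.names = FALSE, digits = 3)
  }
  if (!is.null(rep$grafts)) {
    cat("Graft performance (TTFM indices):\n")
    print(rep$grafts, row.names = FALSE, digits = 3)
  }
  cat("Regional myocardial perfusion (ml/min):\n")
  print(round(rep$perfusion$territory, 2))
  cat(sprintf("Total myocardial perfusion: %.2f ml/min\n",
              rep$perfusion$total))
  invisible(rep)
}
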