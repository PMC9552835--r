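#' Specify a lumped stenosis
#'
#' A stenosis is a percentage-diameter narrowing of length `Ls` inserted at an
#' axial position (measured from the proximal end) of a host segment. On
#' insertion the host is split into `<host>_psten` and `<host>_dsten` coupled
#' by a stenosis junction carrying the lumped pressure-drop model.
#'
#' @param segment host segment name.
#' @param position axial position of the stenosis start, cm from the proximal
#'   end.
#' @param length stenosis (throat) length Ls, cm.
#' @param pct percent diameter stenosis in `[0, 100)`; the area ratio is
#'   A0/As = 100/(100 - pct).
#' @return a `stenosis_spec` list.
#' @export
stenosis_spec <- function(segment, position, length, pct) {
  if (pct < 0 || pct >= 100) stop("percent stenosis must be in [0, 100)")
  if (position <= 0 || length <= 0) {
    stop("stenosis position and length must be positive")
  }
  structure(list(segment = segment, position = position,
                 length = length, pct = pct),
            class = "stenosis_spec")
}

#' Lumped stenosis pressure-drop coefficients
#'
#' Derived quantities of the viscous / turbulent / inertial stenosis model:
#' dP = av Q + at Q|Q| + au dQ/dt, with
#' av = mu Kv / (2 pi R0^3), Kv = (4 alpha/(alpha-1)) (La/R0) (A0/As - 1)^2,
#' La = 0.83 Ls + 3.28 Rs, at = rho Kt / (2 A0^2) (A0/As - 1)^2 (Kt = 1.52),
#' au = Ku Lu with Ku = 1.2 and Lu = rho Ls / (pi Rs^2) for the
#' constant-radius throat. A0 is the mean unstressed area of the host halves.
#'
#' @param R0 host unstressed radius, cm (mean of the proximal/distal halves).
#' @param pct percent diameter stenosis.
#' @param Ls stenosis length, cm.
#' @param alpha momentum-correction coefficient of the host.
#' @param fluid a [fluid_properties()] object.
#' @return list with `As`, `Rs`, `La`, `Lu`, `Kv`, `Kt`, `Ku`, `av`, `at`,
#'   `au`, `A0`, `ratio` (= A0/As).
#' @export
stenosis_coefficients <- function(R0, pct, Ls, alpha = 1.1,
                                  fluid = fluid_properties()) {
  A0 <- pi * R0^2
  ratio <- 100 / (100 - pct)
  As <- A0 / ratio
  Rs <- sqrt(As / pi)
  La <- 0.83 * Ls + 3.28 * Rs
  Kv <- (4 * alpha / (alpha - 1)) * (La / R0) * (ratio - 1)^2
  Kt <- 1.52
  Ku <- 1.2
  Lu <- fluid$rho * Ls / (pi * Rs^2)
  list(As = As, Rs = Rs, La = La, Lu = Lu, Kv = Kv, Kt = Kt, Ku = Ku,
       av = fluid$mu * Kv / (2 * pi * R0^3),
       at = fluid$rho * Kt / (2 * A0^2) * (ratio - 1)^2,
       au = Ku * Lu, A0 = A0, ratio = ratio)
}

#' Pressure drop across a lumped stenosis
#'
#' @param Q throat flow, cm^3/s.
#' @param dQdt rate of change of throat flow, cm^3/s^2 (first-order backward
#'   difference in the solver).
#' @param coefs coefficients from [stenosis_coefficients()].
#' @return pressure drop in dyn/cm^2; sign follows `Q` for the viscous and
#'   turbulent terms (`Q|Q|` form).
#' @export
stenosis_pressure_drop <- function(Q, dQdt, coefs) {
  coefs$av * Q + coefs$at * Q * abs(Q) + coefs$au * dQdt
}

# Split a segment at `position`, rewiring connectivity. The distal part
# inherits any outlet annotation. Returns list(topo, proximal, distal).
split_segment <- function(topo, host, position, gap = 0,
                          suffixes = c("_pgraf", "_dgraf")) {
  if (!host %in% names(topo$segments)) {
    stop("segment not found in network: ", host)
  }
  s <- topo$segments[[host]]
  lp <- position
  ld <- s$length - position - gap
  if (lp <= 0 || ld <= 0) {
    stop(sprintf(
      "cannot split '%s' (length %g cm) at position %g with gap %g cm",
      host, s$length, position, gap))
  }
  pnam <- paste0(host, suffixes[1])
  dnam <- paste0(host, suffixes[2])
  if (pnam %in% names(topo$segments)) {
    stop("segment already split at this site: ", pnam, " exists")
  }
  prox <- vessel_segment(pnam, s$radius, lp, wall = s$wall, alpha = s$alpha)
  dist <- vessel_segment(dnam, s$radius, ld, wall = s$wall, alpha = s$alpha,
                         outlet_class = s$outlet_class,
                         territory = s$territory,
                         systemic_pct = s$systemic_pct)
  topo$segments[[host]] <- NULL
  topo$segments[[pnam]] <- prox
  topo$segments[[dnam]] <- dist
  topo$junctions <- lapply(topo$junctions, function(j) {
    j$children[j$children == host] <- pnam
    j$parents[j$parents == host] <- dnam
    j
  })
  topo <- infer_roles(topo)
  list(topo = topo, proximal = pnam, distal = dnam)
}

#' Insert a stenosis into a network
#'
#' Replaces the host segment by `<host>_psten` (length = position) and
#' `<host>_dsten` (length = L - position - Ls) coupled by a stenosis junction
#' of throat length Ls; prior connectivity is re-wired onto the new halves.
#'
#' @param topo a `network_topology`.
#' @param spec a [stenosis_spec()].
#' @return the edited topology (not re-validated; see [apply_scenario()]).
#' @export
insert_stenosis <- function(topo, spec) {
  sp <- split_segment(topo, spec$segment, spec$position, gap = spec$length,
                      suffixes = c("_psten", "_dsten"))
  topo <- sp$topo
  topo$junctions <- c(topo$junctions, list(make_junction(
    "stenosis", sp$proximal, sp$distal,
    stenosis = list(pct = spec$pct, length = spec$length,
                    position = spec$position, host = spec$segment))))
  infer_roles(topo)
}

#' Specify a bypass graft
#'
#' Supported graft kinds:
#' \describe{
#'   \item{`in_situ`}{an existing pedicled conduit (e.g. LIMA) is detached
#'     from its terminal outlet and anastomosed end-to-side onto `target` at
#'     `position` (reverse bifurcation).}
#'   \item{`end_to_side`}{distal anastomosis of an existing free (dangling)
#'     conduit onto `target` at `position` (reverse bifurcation).}
#'   \item{`free_aortic`}{a new conduit (`name`, `radius`, `length`) taken off
#'     the aorta: `source` is split at `source_position` with a take-off
#'     bifurcation, and the conduit is anastomosed onto `target` at
#'     `position`.}
#'   \item{`y_composite`}{a new limb (`name`, `radius`, `length`) taken off an
#'     existing conduit: `source` is split at `source_position` with a Y
#'     bifurcation. If `target` is given the limb is anastomosed end-to-side;
#'     otherwise it is left dangling for a subsequent `sequential` /
#'     `i_extension` edit.}
#'   \item{`sequential`}{a dangling conduit passes side-to-side through
#'     `target` at `position` (cross-junction) and continues as an exiting
#'     limb (`name`, `radius`, `length`), left dangling for its own distal
#'     anastomosis.}
#'   \item{`i_extension`}{a dangling conduit is lengthened end-to-end by a new
#'     piece (`name`, `radius`, `length`) through a connector junction.}
#' }
#'
#' @param kind graft kind (see Details).
#' @param conduit existing conduit segment name (all kinds except
#'   `free_aortic`).
#' @param target host segment receiving the distal (or through) anastomosis.
#' @param position axial position on `target`, cm.
#' @param name,radius,length,wall geometry of a newly created conduit piece.
#' @param source,source_position take-off segment and position for
#'   `free_aortic` / `y_composite`.
#' @return a `graft_spec` list.
#' @export
graft_spec <- function(kind = c("in_situ", "end_to_side", "free_aortic",
                                "y_composite", "sequential", "i_extension"),
                       conduit = NULL, target = NULL, position = NULL,
                       name = NULL, radius = NULL, length = NULL,
                       wall = "coronary",
                       source = NULL, source_position = NULL) {
  kind <- match.arg(kind)
  need <- function(cond, what) {
    if (!cond) stop("graft kind '", kind, "' requires ", what)
  }
  switch(kind,
    in_situ = ,
    end_to_side = need(!is.null(conduit) && !is.null(target) &&
                         !is.null(position), "conduit, target, position"),
    free_aortic = need(!is.null(name) && !is.null(radius) &&
                         !is.null(length) && !is.null(source) &&
                         !is.null(source_position) && !is.null(target) &&
                         !is.null(position),
                       "name, radius, length, source, source_position, target, position"),
    y_composite = need(!is.null(name) && !is.null(radius) &&
                         !is.null(length) && !is.null(source) &&
                         !is.null(source_position),
                       "name, radius, length, source, source_position"),
    sequential = need(!is.null(conduit) && !is.null(target) &&
                        !is.null(position) && !is.null(name) &&
                        !is.null(length), "conduit, target, position, name, length"),
    i_extension = need(!is.null(conduit) && !is.null(name) &&
                         !is.null(length), "conduit, name, length")
  )
  structure(list(kind = kind, conduit = conduit, target = target,
                 position = position, name = name, radius = radius,
                 length = length, wall = wall, source = source,
                 source_position = source_position),
            class = "graft_spec")
}

# A conduit is "dangling" if its distal end feeds no junction and it carries
# no outlet prescription for the grafted role.
assert_free_end <- function(topo, conduit) {
  parents <- unlist(lapply(topo$junctions, `[[`, "parents"))
  if (conduit %in% parents) {
    stop("conduit '", conduit, "' is already attached at its distal end")
  }
  if (!conduit %in% names(topo$segments)) {
    stop("conduit segment not found: ", conduit)
  }
}

#' Insert a bypass graft into a network
#'
#' Applies one [graft_spec()] edit. Target segments are split into
#' `<target>_pgraf` / `<target>_dgraf`; the junction kind follows the graft
#' kind (reverse bifurcation for end-to-side anastomoses, bifurcation for
#' aortic or Y take-offs, cross-junction for sequential passes, connector for
#' end-to-end extensions). For `in_situ` grafts the conduit's old Windkessel
#' outlet prescription is removed.
#'
#' @param topo a `network_topology`.
#' @param spec a [graft_spec()].
#' @return the edited topology (not re-validated; see [apply_scenario()]).
#' @export
insert_graft <- function(topo, spec) {
  anastomose <- function(topo, conduit, target, position) {
    sp <- split_segment(topo, target, position)
    topo <- sp$topo
    topo$junctions <- c(topo$junctions, list(make_junction(
      "reverse_bifurcation", c(sp$proximal, conduit), sp$distal)))
    infer_roles(topo)
  }
  takeoff <- function(topo, source, source_position, limb) {
    sp <- split_segment(topo, source, source_position)
    topo <- sp$topo
    topo$junctions <- c(topo$junctions, list(make_junction(
      "bifurcation", sp$proximal, c(sp$distal, limb))))
    infer_roles(topo)
  }
  newseg <- function(spec, radius = spec$radius) {
    vessel_segment(spec$name, radius, spec$length, wall = spec$wall)
  }
  switch(spec$kind,
    in_situ = {
      assert_free_end(topo, spec$conduit)
      s <- topo$segments[[spec$conduit]]
      if (is.na(s$outlet_class)) {
        stop("in-situ conduit '", spec$conduit,
             "' has no terminal outlet to detach; use kind 'end_to_side'")
      }
      topo$segments[[spec$conduit]]$outlet_class <- NA_character_
      topo$segments[[spec$conduit]]$territory <- NA_character_
      topo$segments[[spec$conduit]]$systemic_pct <- NA_real_
      anastomose(topo, spec$conduit, spec$target, spec$position)
    },
    end_to_side = {
      assert_free_end(topo, spec$conduit)
      anastomose(topo, spec$conduit, spec$target, spec$position)
    },
    free_aortic = {
      topo$segments[[spec$name]] <- newseg(spec)
      topo <- takeoff(topo, spec$source, spec$source_position, spec$name)
      anastomose(topo, spec$name, spec$target, spec$position)
    },
    y_composite = {
      topo$segments[[spec$name]] <- newseg(spec)
      topo <- takeoff(topo, spec$source, spec$source_position, spec$name)
      if (!is.null(spec$target)) {
        topo <- anastomose(topo, spec$name, spec$target, spec$position)
      }
      topo
    },
    sequential = {
      assert_free_end(topo, spec$conduit)
      radius <- if (is.null(spec$radius)) {
        topo$segments[[spec$conduit]]$radius
      } else spec$radius
      topo$segments[[spec$name]] <- newseg(spec, radius)
      sp <- split_segment(topo, spec$target, spec$position)
      topo <- sp$topo
      topo$junctions <- c(topo$junctions, list(make_junction(
        "cross_junction", c(sp$proximal, spec$conduit),
        c(sp$distal, spec$name))))
      infer_roles(topo)
    },
    i_extension = {
      assert_free_end(topo, spec$conduit)
      radius <- if (is.null(spec$radius)) {
        topo$segments[[spec$conduit]]$radius
      } else spec$radius
      topo$segments[[spec$name]] <- newseg(spec, radius)
      topo$junctions <- c(topo$junctions, list(make_junction(
        "connector", spec$conduit, spec$name)))
      infer_roles(topo)
    }
  )
}

#' Apply a scenario of stenosis and graft edits
#'
#' Applies all stenoses, then all grafts, in order, and validates the result.
#' A scenario is a list with elements `stenoses` (list of [stenosis_spec()])
#' and `grafts` (list of [graft_spec()]), or the path of a YAML file with the
#' same structure.
#'
#' @param topo a `network_topology`.
#' @param scenario scenario list or YAML path.
#' @return the edited, validated topology.
#' @export
apply_scenario <- function(topo, scenario) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  for (st in scenario$stenoses %||% list()) topo <- insert_stenosis(topo, st)
  for (gr in scenario$grafts %||% list()) topo <- insert_graft(topo, gr)
  validate_topology(topo)
  topo
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname apply_scenario
#' @param path YAML file path.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    stenoses = lapply(y$stenoses %||% list(), function(s) {
      do.call(stenosis_spec, s)
    }),
    grafts = lapply(y$grafts %||% list(), function(g) do.call(graft_spec, g))
  )
}

#' @rdname apply_scenario
#' @param scenario scenario list.
#' @export
write_scenario <- function(scenario, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, TRUE)]
  }
  yaml::write_yaml(list(stenoses = lapply(scenario$stenoses, strip),
                        grafts = lapply(scenario$grafts, strip)), path)
  invisible(path)
}
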