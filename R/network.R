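#' Define a 1D vessel segment
#'
#' Each segment is a straight elastic tube of constant unstressed radius
#' (step-wise taper: radius changes only across junctions). Terminal segments
#' carry outlet annotations: an external-pressure class, and either a coronary
#' perfusion territory or a prescribed percentage of cardiac output.
#'
#' @param name segment identifier.
#' @param radius unstressed radius R0, cm.
#' @param length segment length L, cm.
#' @param wall wall-law class, `"coronary"` or `"systemic"` (see [wall_law()]).
#' @param alpha momentum-correction coefficient; defaults to 1.05 for the
#'   large-systemic wall class and 1.1 for the coronary class.
#' @param outlet_class external-pressure class of the terminal bed
#'   (`"LV"`, `"RV"`, `"septal"`, `"systemic"`), or `NA` for non-terminal
#'   segments.
#' @param territory coronary perfusion territory (`"LAD"`, `"CIRC"`, `"RCA"`)
#'   for coronary outlets, `NA` otherwise.
#' @param systemic_pct percentage of cardiac output prescribed to a systemic
#'   outlet, `NA` otherwise.
#' @return a `vessel_segment` list.
#' @export
vessel_segment <- function(name, radius, length,
                           wall = c("coronary", "systemic"),
                           alpha = NULL,
                           outlet_class = NA_character_,
                           territory = NA_character_,
                           systemic_pct = NA_real_) {
  wall <- match.arg(wall)
  if (length <= 0) stop("segment length must be positive: ", name)
  if (radius <= 0) stop("segment radius must be positive: ", name)
  if (is.null(alpha)) alpha <- if (wall == "systemic") 1.05 else 1.1
  if (alpha <= 1 || alpha > 4 / 3) stop("alpha must be in (1, 4/3]: ", name)
  if (!is.na(outlet_class) &&
      !outlet_class %in% c("LV", "RV", "septal", "systemic")) {
    stop("unknown outlet class '", outlet_class, "' for segment ", name)
  }
  if (!is.na(territory) && !territory %in% c("LAD", "CIRC", "RCA")) {
    stop("unknown territory '", territory, "' for segment ", name)
  }
  list(name = name, radius = radius, length = length, wall = wall,
       alpha = alpha, A0 = pi * radius^2,
       outlet_class = outlet_class, territory = territory,
       systemic_pct = systemic_pct)
}

junction_arity <- function(kind) {
  switch(kind,
    bifurcation = c(1L, 2L),
    trifurcation = c(1L, 3L),
    stenosis = c(1L, 1L),
    reverse_bifurcation = c(2L, 1L),
    cross_junction = c(2L, 2L),
    connector = c(1L, 1L),
    stop("unsupported junction kind: ", kind)
  )
}

make_junction <- function(kind, parents, children, stenosis = NULL) {
  ar <- junction_arity(kind)
  if (length(parents) != ar[1] || length(children) != ar[2]) {
    stop(sprintf("junction kind '%s' requires %d parent(s) and %d child(ren)",
                 kind, ar[1], ar[2]))
  }
  list(kind = kind, parents = as.character(parents),
       children = as.character(children), stenosis = stenosis)
}

#' Assemble a vessel network topology
#'
#' A topology is a rooted directed network: one inlet root segment, typed
#' junctions coupling parent segment ends to child segment starts, and every
#' leaf segment terminating in a Windkessel outlet.
#'
#' @param segments list of [vessel_segment()]s.
#' @param junctions list of junctions created internally (use [load_network()]
#'   or the editing operations rather than constructing these by hand); each is
#'   a list with `kind`, `parents`, `children` and, for stenosis junctions, a
#'   `stenosis` record.
#' @param validate run [validate_topology()] (default `TRUE`).
#' @return an object of class `network_topology`.
#' @export
network_topology <- function(segments, junctions = list(), validate = TRUE) {
  names(segments) <- vapply(segments, `[[`, "", "name")
  topo <- structure(list(segments = segments, junctions = junctions,
                         outlets = list()),
                    class = "network_topology")
  topo <- infer_roles(topo)
  if (validate) validate_topology(topo)
  topo
}

# Derive the root and outlet set from connectivity.
infer_roles <- function(topo) {
  segs <- names(topo$segments)
  children <- unlist(lapply(topo$junctions, `[[`, "children"))
  parents <- unlist(lapply(topo$junctions, `[[`, "parents"))
  topo$root <- setdiff(segs, children)
  # terminal = never a parent of any junction
  terminals <- setdiff(segs, parents)
  topo$terminals <- terminals
  topo
}

#' Validate a network topology
#'
#' Checks: all junction references resolve; exactly one root; every segment is
#' reachable from the root; no segment end is used twice (each segment is a
#' parent of at most one junction and a child of at most one); junction arities
#' match the supported table; every terminal carries an outlet class; dangling
#' graft conduits are reported.
#'
#' @param topo a `network_topology`.
#' @return invisibly, a validation report list with `n_segments`,
#'   `n_junctions`, and `junction_counts` by kind.
#' @export
validate_topology <- function(topo) {
  segs <- names(topo$segments)
  for (j in topo$junctions) {
    junction_arity(j$kind)  # errors on unknown kind
    miss <- setdiff(c(j$parents, j$children), segs)
    if (length(miss)) {
      stop("junction references unknown segment(s): ",
           paste(miss, collapse = ", "))
    }
  }
  parents <- unlist(lapply(topo$junctions, `[[`, "parents"))
  children <- unlist(lapply(topo$junctions, `[[`, "children"))
  if (anyDuplicated(parents)) {
    stop("segment end used as parent in more than one junction: ",
         paste(unique(parents[duplicated(parents)]), collapse = ", "))
  }
  if (anyDuplicated(children)) {
    stop("segment start used as child in more than one junction: ",
         paste(unique(children[duplicated(children)]), collapse = ", "))
  }
  root <- setdiff(segs, children)
  if (length(root) != 1) {
    stop("network must have exactly one root segment; found: ",
         paste(root, collapse = ", "))
  }
  # reachability by walking parent -> children
  reach <- root
  frontier <- root
  childmap <- lapply(topo$junctions, function(j) j)
  while (length(frontier)) {
    nxt <- character()
    for (j in topo$junctions) {
      if (any(j$parents %in% frontier)) nxt <- c(nxt, j$children)
    }
    nxt <- setdiff(unique(nxt), reach)
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  un <- setdiff(segs, reach)
  if (length(un)) {
    stop("segment(s) unreachable from root (cycle or disconnection): ",
         paste(un, collapse = ", "))
  }
  terminals <- setdiff(segs, parents)
  noclass <- terminals[vapply(topo$segments[terminals],
                              function(s) is.na(s$outlet_class), TRUE)]
  if (length(noclass)) {
    stop("terminal segment(s) lack an outlet class (dangling conduit?): ",
         paste(noclass, collapse = ", "))
  }
  kinds <- vapply(topo$junctions, `[[`, "", "kind")
  report <- list(
    n_segments = length(segs),
    n_junctions = length(topo$junctions),
    junction_counts = if (length(kinds)) table(kinds) else table(character())
  )
  invisible(report)
}

#' Count network elements
#'
#' @param topo a `network_topology`.
#' @return list with `n_segments` and named vector `n_junctions_by_type`.
#' @export
count_elements <- function(topo) {
  kinds <- vapply(topo$junctions, `[[`, "", "kind")
  list(n_segments = length(topo$segments),
       n_junctions_by_type = if (length(kinds)) c(table(kinds)) else
         stats::setNames(integer(0), character(0)))
}

#' @export
print.network_topology <- function(x, ...) {
  ce <- count_elements(x)
  cat("1D-0D vessel network:", ce$n_segments, "segments,",
      length(x$junctions), "junctions\n")
  cat("  root:", x$root, "\n")
  if (length(ce$n_junctions_by_type)) {
    cat("  junctions:",
        paste(names(ce$n_junctions_by_type), ce$n_junctions_by_type,
              sep = "=", collapse = ", "), "\n")
  }
  cat("  terminals:", length(x$terminals), "\n")
  invisible(x)
}

#' Read a network from a segment table and relations config
#'
#' The segment table is comma-delimited with a header row and columns `name`,
#' `radius`, `length`, `wall`, and optionally `alpha`, `outlet_class`,
#' `territory`, `systemic_pct`. The relations config is plain text, one
#' junction per line:
#' `kind: parent1[, parent2] -> child1[, child2, child3]`,
#' with stenosis parameters in brackets, e.g.
#' `stenosis[pct=90, length=1.6]: LAD_1_psten -> LAD_1_dsten`.
#' Blank lines and `#` comments are ignored.
#'
#' @param segment_csv path to the segment table.
#' @param relations_cfg path to the relations config, or `NULL` for a
#'   single-segment network.
#' @return a validated `network_topology`.
#' @export
load_network <- function(segment_csv, relations_cfg = NULL) {
  tab <- utils::read.csv(segment_csv, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  need <- c("name", "radius", "length", "wall")
  if (!all(need %in% names(tab))) {
    stop("segment table must have columns: ", paste(need, collapse = ", "))
  }
  getcol <- function(col, default) {
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  oc <- as.character(getcol("outlet_class", NA_character_))
  tr <- as.character(getcol("territory", NA_character_))
  sp <- as.numeric(getcol("systemic_pct", NA_real_))
  al <- as.numeric(getcol("alpha", NA_real_))
  oc[!is.na(oc) & oc == ""] <- NA_character_
  tr[!is.na(tr) & tr == ""] <- NA_character_
  segs <- lapply(seq_len(nrow(tab)), function(i) {
    vessel_segment(tab$name[i], tab$radius[i], tab$length[i],
                   wall = tab$wall[i],
                   alpha = if (is.na(al[i])) NULL else al[i],
                   outlet_class = oc[i], territory = tr[i],
                   systemic_pct = sp[i])
  })
  juncs <- if (is.null(relations_cfg)) list() else {
    parse_relations(readLines(relations_cfg), names = tab$name)
  }
  network_topology(segs, juncs)
}

parse_relations <- function(lines, names) {
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    m <- regmatches(ln, regexec(
      "^([a-z_]+)(\\[[^]]*\\])?\\s*:\\s*(.+?)\\s*->\\s*(.+)$", ln))[[1]]
    if (length(m) == 0) stop("cannot parse relations line: ", ln)
    kind <- m[2]
    pars <- trimws(strsplit(m[4], ",")[[1]])
    kids <- trimws(strsplit(m[5], ",")[[1]])
    miss <- setdiff(c(pars, kids), names)
    if (length(miss)) {
      stop("relations reference segment(s) absent from the table: ",
           paste(miss, collapse = ", "))
    }
    sten <- NULL
    if (nzchar(m[3]) && !is.na(m[3]) && m[3] != "") {
      kv <- strsplit(gsub("\\[|\\]", "", m[3]), ",")[[1]]
      vals <- stats::setNames(
        as.numeric(sub(".*=", "", kv)), trimws(sub("=.*", "", kv)))
      if (kind == "stenosis") {
        sten <- list(pct = unname(vals["pct"]), length = unname(vals["length"]))
      }
    }
    if (kind == "stenosis" && is.null(sten)) {
      stop("stenosis relation needs [pct=..., length=...]: ", ln)
    }
    make_junction(kind, pars, kids, stenosis = sten)
  })
}

#' Write a network to a segment table and relations config
#'
#' Inverse of [load_network()]: `load_network(write_network(topo, ...))`
#' reproduces names, radii and lengths to full precision.
#'
#' @param topo a `network_topology`.
#' @param segment_csv,relations_cfg output paths.
#' @export
write_network <- function(topo, segment_csv, relations_cfg) {
  tab <- do.call(rbind, lapply(topo$segments, function(s) {
    data.frame(name = s$name,
               radius = sprintf("%.17g", s$radius),
               length = sprintf("%.17g", s$length),
               wall = s$wall, alpha = sprintf("%.17g", s$alpha),
               outlet_class = ifelse(is.na(s$outlet_class), "", s$outlet_class),
               territory = ifelse(is.na(s$territory), "", s$territory),
               systemic_pct = ifelse(is.na(s$systemic_pct), "",
                                     sprintf("%.17g", s$systemic_pct)))
  }))
  utils::write.csv(tab, segment_csv, row.names = FALSE, quote = FALSE)
  lines <- vapply(topo$junctions, function(j) {
    tag <- if (j$kind == "stenosis") {
      sprintf("[pct=%.17g, length=%.17g]", j$stenosis$pct, j$stenosis$length)
    } else ""
    sprintf("%s%s: %s -> %s", j$kind, tag,
            paste(j$parents, collapse = ", "),
            paste(j$children, collapse = ", "))
  }, "")
  writeLines(lines, relations_cfg)
  invisible(list(segment_csv = segment_csv, relations_cfg = relations_cfg))
}
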