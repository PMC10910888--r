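#' Build a selection diagram
#'
#' A selection diagram is a causal DAG over the analysis variables,
#' augmented with selection indicators: `s_pointed` names the nodes whose
#' generating mechanism is assumed to differ between the study and the
#' target population (drawn as black-square S variables with an arrow into
#' the node). The absence of an S arrow into a node encodes the strong
#' assumption that the mechanism assigning that variable is invariant
#' across the two populations.
#'
#' @param nodes Character vector of node labels.
#' @param edges Directed edges: either a two-column data frame / matrix
#'   (`from`, `to`) or a character vector of `"X -> Y"` strings.
#' @param exposure,outcome Labels of the exposure and outcome nodes.
#' @param s_pointed Labels of the nodes that receive a selection arrow.
#' @return An object of class `selection_diagram`.
#' @export
#' @examples
#' # confounder Z1 and effect modifier Z2, both distributed differently
#' # in study and target:
#' selection_diagram(
#'   nodes = c("A", "Y", "Z1", "Z2"),
#'   edges = c("Z1 -> A", "Z1 -> Y", "A -> Y", "Z2 -> Y"),
#'   exposure = "A", outcome = "Y", s_pointed = c("Z1", "Z2")
#' )
selection_diagram <- function(nodes, edges, exposure, outcome,
                              s_pointed = character()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node labels")
  edges <- parse_edges(edges)
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(bad)) {
    abort(sprintf("edge endpoint(s) not declared as nodes: %s",
                  paste(bad, collapse = ", ")))
  }
  for (v in c(exposure, outcome)) {
    if (!v %in% nodes) abort(sprintf("'%s' is not a declared node", v))
  }
  if (identical(exposure, outcome)) abort("exposure and outcome must differ")
  bad_s <- setdiff(s_pointed, nodes)
  if (length(bad_s)) {
    abort(sprintf("s_pointed label(s) not declared as nodes: %s",
                  paste(bad_s, collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  if (!igraph::is_dag(g)) abort("the directed graph contains a cycle")
  structure(
    list(nodes = nodes, edges = edges, exposure = exposure,
         outcome = outcome, s_pointed = as.character(s_pointed)),
    class = "selection_diagram"
  )
}

parse_edges <- function(edges) {
  if (is.character(edges)) {
    parts <- strsplit(trimws(edges), "\\s*->\\s*")
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      abort(sprintf("cannot parse edge specification(s): %s",
                    paste(edges[bad], collapse = "; ")))
    }
    edges <- tibble(from = vapply(parts, `[`, "", 1L),
                    to = vapply(parts, `[`, "", 2L))
  } else if (is.matrix(edges)) {
    edges <- tibble(from = as.character(edges[, 1]),
                    to = as.character(edges[, 2]))
  } else if (is.data.frame(edges)) {
    edges <- tibble(from = as.character(edges[[1]]),
                    to = as.character(edges[[2]]))
  } else if (is.null(edges) || (is.vector(edges) && length(edges) == 0L)) {
    edges <- tibble(from = character(), to = character())
  } else {
    abort("edges must be a character vector of 'X -> Y' or a two-column table")
  }
  dplyr::distinct(edges)
}

#' Read a selection diagram from an edge-list file
#'
#' Plain-text format: one `X -> Y` edge per line; blank lines and lines
#' starting with `#` are ignored. Exposure, outcome and S-pointed nodes
#' are given as arguments (they are analysis choices, not graph content).
#'
#' @param path File path.
#' @inheritParams selection_diagram
#' @param nodes Optional explicit node set; defaults to the labels
#'   appearing in the edges plus exposure/outcome/s_pointed.
#' @return A [selection_diagram()].
#' @export
read_diagram <- function(path, exposure, outcome, s_pointed = character(),
                         nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  edges <- parse_edges(lines)
  nodes <- nodes %||% unique(c(edges$from, edges$to, exposure, outcome, s_pointed))
  selection_diagram(nodes, edges, exposure, outcome, s_pointed)
}

#' @export
print.selection_diagram <- function(x, ...) {
  cat("<selection_diagram>\n")
  cat("  nodes:    ", paste(x$nodes, collapse = ", "), "\n")
  cat("  edges:    ", if (nrow(x$edges))
    paste(sprintf("%s -> %s", x$edges$from, x$edges$to), collapse = ", ")
    else "(none)", "\n")
  cat("  exposure: ", x$exposure, "   outcome: ", x$outcome, "\n", sep = "")
  cat("  S arrows into:", if (length(x$s_pointed))
    paste(x$s_pointed, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# Materialize the selection indicators as explicit exogenous parent nodes
# ("S_<node>", or a single shared "S"), so d-separation queries can refer
# to them like any other node.
augment_s_nodes <- function(diagram, shared = FALSE) {
  if (!length(diagram$s_pointed)) {
    return(list(diagram = diagram, s_nodes = character()))
  }
  if (shared) {
    s_nodes <- "S"
    new_edges <- tibble(from = "S", to = diagram$s_pointed)
  } else {
    s_nodes <- paste0("S_", diagram$s_pointed)
    new_edges <- tibble(from = s_nodes, to = diagram$s_pointed)
  }
  if (any(s_nodes %in% diagram$nodes)) {
    abort("node labels clash with generated S-node labels")
  }
  aug <- selection_diagram(
    nodes = c(diagram$nodes, s_nodes),
    edges = dplyr::bind_rows(diagram$edges, new_edges),
    exposure = diagram$exposure, outcome = diagram$outcome,
    s_pointed = character()
  )
  list(diagram = aug, s_nodes = s_nodes)
}

parents_of <- function(edges, v) edges$from[edges$to %in% v]
children_of <- function(edges, v) edges$to[edges$from %in% v]

ancestors_of <- function(edges, v) {
  out <- unique(v)
  frontier <- out
  while (length(frontier)) {
    frontier <- setdiff(unique(parents_of(edges, frontier)), out)
    out <- c(out, frontier)
  }
  out
}

#' Test d-separation in a selection diagram
#'
#' Decides whether every path between the node sets `x` and `y` is blocked
#' by the conditioning set `z` under the standard d-separation semantics:
#' a chain or fork is blocked when its middle node is conditioned on, a
#' collider is open only when the collider or one of its descendants is
#' conditioned on. If the diagram declares S-pointed nodes, the selection
#' indicators are first materialized as explicit parent nodes labelled
#' `S_<node>` so they can appear in the query sets.
#'
#' The implementation is the linear-time reachability ("Bayes-ball")
#' algorithm: it tracks the direction in which each node is entered and
#' propagates only along edges that keep the trail active.
#'
#' @param diagram A [selection_diagram()].
#' @param x,y,z Disjoint character vectors of node labels (`z` may be
#'   empty).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @export
d_separated <- function(diagram, x, y, z = character()) {
  aug <- augment_s_nodes(diagram)
  g <- aug$diagram
  x <- as.character(x); y <- as.character(y); z <- as.character(z)
  all_nodes <- g$nodes
  bad <- setdiff(c(x, y, z), all_nodes)
  if (length(bad)) {
    abort(sprintf("unknown node(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(intersect(x, y)) || length(intersect(x, z)) ||
      length(intersect(y, z))) {
    abort("x, y and z must be disjoint node sets")
  }
  if (!length(x) || !length(y)) abort("x and y must be non-empty")
  !any(reachable_active(g$edges, x, z) %in% y)
}

# Nodes reachable from `x` via an active trail given conditioning set `z`
# (Bayes-ball reachability). Direction codes: "down" = entered along an
# edge out of a parent, "up" = entered along an edge out of a child.
reachable_active <- function(edges, x, z) {
  an_z <- if (length(z)) ancestors_of(edges, z) else character()
  queue <- data.frame(node = x, dir = "up", stringsAsFactors = FALSE)
  visited <- character()
  reached <- character()
  while (nrow(queue)) {
    v <- queue$node[1]; d <- queue$dir[1]
    queue <- queue[-1, , drop = FALSE]
    key <- paste(v, d)
    if (key %in% visited) next
    visited <- c(visited, key)
    if (!(v %in% z)) reached <- unique(c(reached, v))
    if (d == "up" && !(v %in% z)) {
      pa <- parents_of(edges, v); ch <- children_of(edges, v)
      if (length(pa)) queue <- rbind(queue, data.frame(node = pa, dir = "up"))
      if (length(ch)) queue <- rbind(queue, data.frame(node = ch, dir = "down"))
    } else if (d == "down") {
      if (!(v %in% z)) {
        ch <- children_of(edges, v)
        if (length(ch)) queue <- rbind(queue, data.frame(node = ch, dir = "down"))
      }
      if (v %in% an_z) {
        pa <- parents_of(edges, v)
        if (length(pa)) queue <- rbind(queue, data.frame(node = pa, dir = "up"))
      }
    }
  }
  setdiff(reached, x)
}

#' Classify transportability of the exposure-outcome effect
#'
#' Applies the graphical transportability rule: in a copy of the diagram
#' where all incoming arrows to the exposure have been removed, an
#' internally valid effect of exposure on outcome transports to the target
#' population whenever the selection indicators S are d-separated from the
#' outcome. If that holds unconditionally the effect is *directly*
#' transportable (no target covariate data needed); if it holds only after
#' conditioning on covariates measured in the target population, the
#' effect transports *via recalibration* on those covariates; otherwise
#' the rule gives no guarantee.
#'
#' The search for a recalibration set is exhaustive over subsets of
#' `measured`, smallest cardinality first with lexicographic tie-break, so
#' the reported `adjustment_set` is a minimal sufficient set. *Trivial*
#' transportability — the effect being identifiable in the target
#' population itself — requires treatment and outcome data in the target,
#' which is knowledge outside the diagram; it is reported only when the
#' caller asserts it via `target_has_study_data`.
#'
#' @param diagram A [selection_diagram()].
#' @param measured Covariate nodes measured in the target population
#'   (subset of nodes excluding exposure and outcome).
#' @param target_has_study_data Set `TRUE` to assert that exposure and
#'   outcome are themselves observed in the target population.
#' @return An object of class `transport_class` with fields `category`
#'   (one of `trivial`, `direct`, `via_recalibration`,
#'   `not_identified_by_rule`) and `adjustment_set`.
#' @export
#' @examples
#' d <- selection_diagram(c("A", "Y", "Z1", "Z2"),
#'                        c("Z1 -> A", "Z1 -> Y", "A -> Y", "Z2 -> Y"),
#'                        exposure = "A", outcome = "Y",
#'                        s_pointed = c("Z1", "Z2"))
#' transport_class(d, measured = c("Z1", "Z2"))
transport_class <- function(diagram, measured = character(),
                            target_has_study_data = FALSE) {
  measured <- as.character(measured)
  bad <- setdiff(measured, setdiff(diagram$nodes,
                                   c(diagram$exposure, diagram$outcome)))
  if (length(bad)) {
    abort(sprintf(
      "measured covariates must be nodes other than exposure/outcome: %s",
      paste(bad, collapse = ", ")))
  }
  new_class <- function(category, set = character()) {
    structure(list(category = category,
                   adjustment_set = as.character(set)),
              class = "transport_class")
  }
  if (isTRUE(target_has_study_data)) return(new_class("trivial"))
  if (!length(diagram$s_pointed)) return(new_class("direct"))

  # materialize S parents, then sever all incoming arrows to the exposure
  # (S arrows into the exposure are removed along with the rest)
  aug <- augment_s_nodes(diagram)
  s_nodes <- aug$s_nodes
  pruned_edges <- dplyr::filter(aug$diagram$edges,
                                .data$to != diagram$exposure)
  sep <- function(z) {
    !any(reachable_active(pruned_edges, s_nodes, z) %in% diagram$outcome)
  }
  if (sep(character())) return(new_class("direct"))
  measured <- sort(measured)
  for (k in seq_along(measured)) {
    subsets <- utils::combn(measured, k, simplify = FALSE)
    for (z in subsets) {
      if (sep(z)) return(new_class("via_recalibration", z))
    }
  }
  new_class("not_identified_by_rule")
}

#' @export
print.transport_class <- function(x, ...) {
  msg <- switch(x$category,
    trivial = "trivially transportable: the effect is identifiable in the target population itself",
    direct = "directly transportable: no recalibration on target covariates needed",
    via_recalibration = sprintf(
      "transportable via recalibration on {%s}",
      paste(x$adjustment_set, collapse = ", ")),
    not_identified_by_rule =
      "transportability is not guaranteed by the graphical rule")
  cat("<transport_class>", msg, "\n")
  invisible(x)
}
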