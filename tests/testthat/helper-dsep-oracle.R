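# Independent d-separation oracle: enumerate every simple path in the
# undirected skeleton and apply the blocking rules directly. Exponential,
# fine for the <= 7-node graphs used in tests.
oracle_d_separated <- function(edges, x, y, z = character()) {
  nodes <- unique(c(edges$from, edges$to, x, y, z))
  desc <- function(v) {
    out <- v
    frontier <- v
    while (length(frontier)) {
      frontier <- setdiff(unique(edges$to[edges$from %in% frontier]), out)
      out <- c(out, frontier)
    }
    out
  }
  path_active <- function(path) {
    if (length(path) == 2L) return(TRUE)
    for (i in 2:(length(path) - 1L)) {
      v <- path[i]
      into_prev <- any(edges$from == path[i - 1] & edges$to == v)
      into_next <- any(edges$from == path[i + 1] & edges$to == v)
      if (into_prev && into_next) {            # collider
        if (!any(desc(v) %in% z)) return(FALSE)
      } else {                                  # chain or fork
        if (v %in% z) return(FALSE)
      }
    }
    TRUE
  }
  nbr <- function(v) unique(c(edges$to[edges$from == v],
                              edges$from[edges$to == v]))
  # DFS over simple paths from any x to any y
  found_active <- FALSE
  walk <- function(path) {
    if (found_active) return(invisible())
    v <- path[length(path)]
    if (v %in% y && length(path) >= 2L) {
      if (path_active(path)) found_active <<- TRUE
      return(invisible())
    }
    for (w in setdiff(nbr(v), path)) walk(c(path, w))
  }
  for (s in x) walk(s)
  !found_active
}

# random DAG over `n_nodes` labelled nodes: each upper-triangular edge
# included independently with probability p
random_dag_edges <- function(n_nodes, p = 0.4) {
  labels <- paste0("V", seq_len(n_nodes))
  from <- character(); to <- character()
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (runif(1) < p) { from <- c(from, labels[i]); to <- c(to, labels[j]) }
    }
  }
  list(nodes = labels, edges = tibble::tibble(from = from, to = to))
}

# draw a random disjoint (x, y, z) triple of singleton/small sets
random_query <- function(nodes) {
  perm <- sample(nodes)
  x <- perm[1]
  y <- perm[2]
  n_z <- sample(0:(length(nodes) - 2L), 1)
  z <- if (n_z > 0) perm[2L + seq_len(n_z)] else character()
  list(x = x, y = y, z = z)
}

fig1b_diagram <- function() {
  selection_diagram(
    nodes = c("A", "Y", "Z1", "Z2"),
    edges = c("Z1 -> A", "Z1 -> Y", "A -> Y", "Z2 -> Y"),
    exposure = "A", outcome = "Y", s_pointed = c("Z1", "Z2")
  )
}

fig2a_diagram <- function() {
  selection_diagram(
    nodes = c("A", "Y", "Z"),
    edges = c("Z -> A", "Z -> Y", "A -> Y"),
    exposure = "A", outcome = "Y", s_pointed = "A"
  )
}

fig2b_diagram <- function() {
  selection_diagram(
    nodes = c("A", "Y", "Z"),
    edges = c("Z -> A", "Z -> Y", "A -> Y"),
    exposure = "A", outcome = "Y", s_pointed = "Y"
  )
}
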