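# Strict equivalences between the edge, node, and node-and-edge formulations.
# All solvers operate on the canonical edge variant; the transforms carry a
# lifting procedure so callers never see gadget vertices.

new_reduction <- function(instance, lift) {
  structure(list(instance = instance, lift = lift), class = "csnet_reduction")
}

#' @export
print.csnet_reduction <- function(x, ...) {
  cat("<csnet_reduction> produced instance plus solution lift\n")
  print(x$instance)
  invisible(x)
}

#' Convert a node-and-edge variant instance to the node variant
#'
#' Every edge `(u, v)` with condition set `tau(u, v)` is replaced by an
#' intermediate vertex `x_(u,v)` present exactly at `tau(u, v)`, an edge
#' `(u, x_(u,v))` carrying the original weight, and a zero-weight edge
#' `(x_(u,v), v)`. Demands are unchanged and the optimum value is preserved
#' exactly; the returned lift contracts the intermediate vertices away so
#' solutions come back in the original vertex namespace.
#'
#' @param instance A [csn_instance()] with `variant = "node-and-edge"`.
#' @return A reduction object: `$instance` (node variant) and `$lift`
#'   (function mapping a solution of the produced instance to one of the
#'   source instance).
#' @export
node_and_edge_to_node <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"),
            instance$variant == "node-and-edge")
  g <- instance$graph
  mid <- if (n_edges(g)) {
    make_unique_names(paste0("x_", g$edges$from, "_", g$edges$to),
                      g$vertices)
  } else character(0)
  node_cond <- instance$node_conditions
  edges <- list()
  for (i in seq_len(n_edges(g))) {
    tau <- g$exists_at[[i]]
    node_cond[[mid[i]]] <- tau
    edges[[length(edges) + 1L]] <-
      data.frame(from = g$edges$from[i], to = mid[i],
                 weight = g$edges$weight[i], stringsAsFactors = FALSE)
    edges[[length(edges) + 1L]] <-
      data.frame(from = mid[i], to = g$edges$to[i], weight = 0,
                 stringsAsFactors = FALSE)
  }
  edf <- if (length(edges)) do.call(rbind, edges) else NULL
  conds <- list()
  if (!is.null(edf)) {
    # intersections with the fresh midpoints reproduce tau(u, v) exactly
    conds <- rep(g$exists_at, each = 2L)
    edf$conditions <- conds
  }
  g2 <- condition_graph(edf, g$n_conditions, directed = g$directed,
                        vertices = c(g$vertices, mid))
  inst2 <- csn_instance(g2, instance$demands, variant = "node",
                        node_conditions = node_cond,
                        check_demand_coverage = FALSE)
  weight_half <- canonical_key(g2, g$edges$from, mid)   # carries w(u, v)
  lift <- function(sol) {
    stopifnot(inherits(sol, "csn_solution"))
    keys <- canonical_key(g2, sol$edges$from, sol$edges$to)
    take <- match(keys, weight_half)
    rows <- sort(unique(take[!is.na(take)]))
    solution(g, g$edges[rows, c("from", "to")])
  }
  new_reduction(inst2, lift)
}

#' Convert a node variant instance to the edge variant
#'
#' Each edge's condition set becomes the intersection of its endpoints'
#' condition sets; edges whose intersection is empty are dropped, vertices
#' become present at all conditions, weights are unchanged. The optimum is
#' preserved exactly and the lift is the identity on edges.
#'
#' @param instance A [csn_instance()] with `variant = "node"`.
#' @return A reduction object (`$instance` is an edge-variant instance).
#' @export
node_to_edge <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"), instance$variant == "node")
  g <- instance$graph
  tau <- instance$node_conditions
  keep <- integer(); conds <- list()
  for (i in seq_len(n_edges(g))) {
    s <- intersect(tau[[g$edges$from[i]]], tau[[g$edges$to[i]]])
    if (length(s)) {
      keep <- c(keep, i)
      conds[[length(conds) + 1L]] <- s
    }
  }
  edf <- g$edges[keep, , drop = FALSE]
  edf$conditions <- conds
  g2 <- condition_graph(edf, g$n_conditions, directed = g$directed,
                        vertices = g$vertices)
  inst2 <- csn_instance(g2, instance$demands, variant = "edge",
                        check_demand_coverage = FALSE)
  lift <- function(sol) solution(g, sol$edges)
  new_reduction(inst2, lift)
}

#' Convert any CSN instance to the canonical edge variant
#'
#' Composes [node_and_edge_to_node()] and [node_to_edge()] as needed; the
#' returned lift composes the individual lifts, so gadget vertices introduced
#' along the way never reach the caller.
#'
#' @param instance A [csn_instance()] of any variant.
#' @return A reduction object whose `$instance` is edge-variant.
#' @export
to_edge_variant <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"))
  if (instance$variant == "edge") {
    return(new_reduction(instance, function(sol) sol))
  }
  if (instance$variant == "node-and-edge") {
    # The formal route chains node_and_edge_to_node() and node_to_edge();
    # since the stored edge condition sets are already contained in their
    # endpoints' sets, simply forgetting the vertex sets gives the same
    # edge-variant instance without the midpoint gadget vertices.
    inst2 <- csn_instance(instance$graph, instance$demands,
                          variant = "edge",
                          check_demand_coverage = FALSE)
    return(new_reduction(inst2,
                         function(sol) solution(instance$graph,
                                                sol$edges)))
  }
  node_to_edge(instance)
}

# Suffix names until they avoid the taken set.
make_unique_names <- function(candidates, taken) {
  out <- character(length(candidates))
  for (i in seq_along(candidates)) {
    nm <- candidates[i]
    while (nm %in% taken || nm %in% out[seq_len(i - 1L)]) {
      nm <- paste0(nm, "_")
    }
    out[i] <- nm
  }
  out
}
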