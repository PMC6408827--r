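# Problem instances: CSN/DCSN (edge, node, node-and-edge variants), CST,
# CPCST and Priority Steiner Tree.

#' Construct a Condition Steiner Network instance
#'
#' A CSN instance couples a [condition_graph()] with `k` connectivity demands
#' `(a, b, c)`: the solution subgraph must contain an `a`-`b` path (directed
#' when the graph is directed) all of whose edges are present at condition
#' `c`. The goal is a minimum total weight subgraph satisfying every demand,
#' each underlying edge paid for once however many conditions use it.
#'
#' Three equivalent formulations are supported. In the `"edge"` variant edges
#' carry the condition sets. In the `"node"` variant vertices carry condition
#' sets (`node_conditions`) and `E_c` is the subgraph induced by the vertices
#' present at `c`. The `"node-and-edge"` variant allows each `E_c` to be any
#' subset of the induced edges. [to_edge_variant()] converts either variant to
#' the canonical edge formulation without changing the optimum.
#'
#' @param graph A [condition_graph()].
#' @param demands Data frame with columns `source`, `target`, `condition`.
#' @param variant `"edge"`, `"node"` or `"node-and-edge"`.
#' @param node_conditions For the node variants: named list mapping each
#'   vertex to the sorted set of conditions at which it is present.
#' @param check_demand_coverage Warn when some condition has no demand (the
#'   canonical formulation expects at least one per condition; all algorithms
#'   remain well defined without it).
#' @return An object of class `csn_instance`.
#' @export
csn_instance <- function(graph, demands,
                         variant = c("edge", "node", "node-and-edge"),
                         node_conditions = NULL,
                         check_demand_coverage = TRUE) {
  stopifnot(inherits(graph, "condition_graph"))
  variant <- match.arg(variant)
  demands <- validate_demands(demands, graph)
  if (check_demand_coverage) {
    missing_c <- setdiff(seq_len(graph$n_conditions), demands$condition)
    if (length(missing_c)) {
      warning("no demand at condition(s) ",
              paste(missing_c, collapse = ", "),
              "; the instance is accepted but does not meet the canonical ",
              "one-demand-per-condition convention", call. = FALSE)
    }
  }
  if (variant != "edge") {
    node_conditions <- validate_node_conditions(node_conditions, graph)
    check_induced_edges(graph, node_conditions, strict = (variant == "node"))
  } else if (!is.null(node_conditions)) {
    stop("node_conditions is only meaningful for the node variants")
  }
  structure(list(graph = graph, demands = demands, variant = variant,
                 node_conditions = node_conditions),
            class = "csn_instance")
}

validate_demands <- function(demands, graph) {
  stopifnot(is.data.frame(demands),
            all(c("source", "target", "condition") %in% names(demands)))
  demands <- data.frame(source = as.character(demands$source),
                        target = as.character(demands$target),
                        condition = as.integer(demands$condition),
                        stringsAsFactors = FALSE)
  if (any(demands$source == demands$target)) {
    stop("demand sources and targets must differ")
  }
  bad <- !(demands$source %in% graph$vertices) |
    !(demands$target %in% graph$vertices)
  if (any(bad)) {
    stop("demand vertex/vertices not in the graph: row(s) ",
         paste(which(bad), collapse = ", "))
  }
  if (any(is.na(demands$condition)) || any(demands$condition < 1L) ||
      any(demands$condition > graph$n_conditions)) {
    stop("demand conditions must lie in 1..", graph$n_conditions)
  }
  demands
}

validate_node_conditions <- function(node_conditions, graph) {
  if (is.null(node_conditions)) {
    stop("node variants need node_conditions")
  }
  stopifnot(is.list(node_conditions))
  if (!setequal(names(node_conditions), graph$vertices)) {
    stop("node_conditions must name every vertex exactly once")
  }
  out <- lapply(node_conditions[graph$vertices], function(s) {
    s <- sort(unique(as.integer(s)))
    if (length(s) == 0L || anyNA(s) || any(s < 1L) ||
        any(s > graph$n_conditions)) {
      stop("each vertex condition set must be a nonempty subset of 1..",
           graph$n_conditions)
    }
    s
  })
  out
}

# Node variant: E_c must equal the induced edges; node-and-edge: E_c may be
# any subset of the induced edges.
check_induced_edges <- function(graph, node_conditions, strict) {
  for (i in seq_len(n_edges(graph))) {
    u <- graph$edges$from[i]; v <- graph$edges$to[i]
    induced <- intersect(node_conditions[[u]], node_conditions[[v]])
    have <- graph$exists_at[[i]]
    if (strict && !identical(as.integer(have), as.integer(induced))) {
      stop("node variant requires exists_at(", u, ",", v,
           ") to equal the intersection of its endpoints' condition sets")
    }
    if (!strict && length(setdiff(have, induced))) {
      stop("edge (", u, ",", v, ") exists at a condition where one of its ",
           "endpoints does not")
    }
  }
  invisible(TRUE)
}

#' @export
print.csn_instance <- function(x, ...) {
  cat(sprintf("<csn_instance> %s variant, %d demands over %d conditions\n",
              x$variant, nrow(x$demands), x$graph$n_conditions))
  print(x$graph)
  invisible(x)
}

#' Construct a Condition Steiner Tree instance
#'
#' Given an undirected condition graph and terminal sets `X_1, ..., X_C`, a
#' subgraph `H` satisfies `X_c` when the terminals in `X_c` are mutually
#' reachable using edges of `H` present at condition `c`; the goal is a
#' minimum-weight `H` satisfying every terminal set.
#'
#' @param graph An undirected [condition_graph()].
#' @param terminal_sets List of `C` nonempty character vectors of vertices.
#' @return An object of class `cst_instance`.
#' @export
cst_instance <- function(graph, terminal_sets) {
  stopifnot(inherits(graph, "condition_graph"))
  if (graph$directed) stop("Condition Steiner Tree is an undirected problem")
  stopifnot(is.list(terminal_sets),
            length(terminal_sets) == graph$n_conditions)
  terminal_sets <- lapply(terminal_sets, function(x) {
    x <- sort(unique(as.character(x)))
    if (length(x) == 0L) stop("terminal sets must be nonempty")
    if (!all(x %in% graph$vertices)) {
      stop("terminal(s) not in the graph: ",
           paste(setdiff(x, graph$vertices), collapse = ", "))
    }
    x
  })
  structure(list(graph = graph, terminal_sets = terminal_sets),
            class = "cst_instance")
}

#' Construct a Condition Prize-Collecting Steiner Tree instance
#'
#' Given an undirected condition graph and penalties `p(v, c) >= 0`, the goal
#' is a subtree `T` of the underlying graph minimizing the edge weight of `T`
#' plus the penalties `p(v, c)` of every pair with `v` outside `T`. Infinite
#' penalties (`Inf`) force vertices into the tree and are kept as an exact
#' sentinel rather than a large finite number.
#'
#' @param graph An undirected [condition_graph()].
#' @param penalty Numeric matrix of dimension `|V| x C` (rows named by
#'   vertex) of nonnegative penalties; `Inf` allowed.
#' @return An object of class `cpcst_instance`.
#' @export
cpcst_instance <- function(graph, penalty) {
  stopifnot(inherits(graph, "condition_graph"))
  if (graph$directed) {
    stop("Condition Prize-Collecting Steiner Tree is an undirected problem")
  }
  stopifnot(is.matrix(penalty),
            nrow(penalty) == length(graph$vertices),
            ncol(penalty) == graph$n_conditions)
  if (is.null(rownames(penalty))) {
    rownames(penalty) <- graph$vertices
  }
  if (!setequal(rownames(penalty), graph$vertices)) {
    stop("penalty rows must be named by the graph vertices")
  }
  penalty <- penalty[graph$vertices, , drop = FALSE]
  if (any(is.na(penalty)) || any(penalty < 0)) {
    stop("penalties must be nonnegative (Inf allowed)")
  }
  structure(list(graph = graph, penalty = penalty),
            class = "cpcst_instance")
}

#' Construct a Priority Steiner Tree instance
#'
#' A weighted undirected multigraph in which every edge has a priority level
#' `p(e)` and every demand pair `(a_i, b_i)` a priority `p(a_i, b_i)`; a
#' solution forest must connect each pair by a path whose edges all have
#' priority `<= p(a_i, b_i)` (lower numbers are higher priority). This is the
#' classic problem equivalent to monotonic CSN.
#'
#' @param edges Data frame `from`, `to`, `weight`, `priority`; parallel edges
#'   are allowed (the one multigraph formulation in the package).
#' @param demands Data frame `source`, `target`, `priority`.
#' @param vertices Optional extra vertices.
#' @return An object of class `priority_steiner_instance`.
#' @export
priority_steiner_instance <- function(edges, demands, vertices = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight", "priority") %in% names(edges)))
  from <- as.character(edges$from); to <- as.character(edges$to)
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  weight <- as.numeric(edges$weight)
  priority <- as.integer(edges$priority)
  if (any(weight < 0) || any(is.na(weight))) stop("weights must be >= 0")
  if (any(priority < 1L) || any(is.na(priority))) {
    stop("priorities must be positive integers")
  }
  if (any(from == to)) stop("self-loops are not allowed")
  stopifnot(is.data.frame(demands),
            all(c("source", "target", "priority") %in% names(demands)))
  dem <- data.frame(source = as.character(demands$source),
                    target = as.character(demands$target),
                    priority = as.integer(demands$priority),
                    stringsAsFactors = FALSE)
  verts <- sort(unique(c(vertices, from, to, dem$source, dem$target)))
  structure(list(vertices = verts,
                 edges = data.frame(from = from, to = to, weight = weight,
                                    priority = priority,
                                    stringsAsFactors = FALSE),
                 demands = dem),
            class = "priority_steiner_instance")
}
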