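# Solutions: a chosen subset of underlying edges, its cost, and per-demand
# witness paths.

#' Construct a solution from a set of chosen edges
#'
#' A solution is a subgraph `H` of the underlying graph, represented by its
#' edge set. Its cost is the sum of weights of the chosen edges, each
#' underlying edge counted exactly once no matter how many conditions use it.
#'
#' @param graph The [condition_graph()] the solution lives in.
#' @param edges Data frame with columns `from`, `to` naming chosen edges of
#'   `graph` (order-insensitive for undirected graphs).
#' @param witnesses Optional named list of witness paths (character vectors of
#'   vertices), one per demand, named by [demand_label()].
#' @return An object of class `csn_solution` with fields `edges`, `cost`,
#'   `witnesses`.
#' @export
solution <- function(graph, edges, witnesses = NULL) {
  stopifnot(inherits(graph, "condition_graph"))
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges)
  rows <- match_edges(graph, edges$from, edges$to)
  rows <- sort(unique(rows))
  sol <- structure(
    list(edges = graph$edges[rows, c("from", "to"), drop = FALSE],
         edge_rows = rows,
         cost = sum(graph$edges$weight[rows]),
         witnesses = witnesses),
    class = "csn_solution")
  rownames(sol$edges) <- NULL
  sol
}

# Map (from, to) pairs to edge row indices of g; error on unknown edges.
match_edges <- function(g, from, to) {
  key <- canonical_key(g, from, to)
  all_keys <- edge_key(g$edges$from, g$edges$to)
  rows <- match(key, all_keys)
  if (anyNA(rows)) {
    stop("unknown edge(s): ",
         paste(gsub("\t", "-", key[is.na(rows)]), collapse = ", "))
  }
  rows
}

#' Cost of a solution
#'
#' Recomputes the total weight of the chosen edges under `graph`, each
#' underlying edge counted once.
#'
#' @param solution A [solution()].
#' @param graph The [condition_graph()] supplying the weights.
#' @return Nonnegative numeric.
#' @export
solution_cost <- function(solution, graph) {
  stopifnot(inherits(solution, "csn_solution"))
  rows <- match_edges(graph, solution$edges$from, solution$edges$to)
  sum(graph$edges$weight[unique(rows)])
}

#' Label used to key witness paths
#'
#' @param demand A one-row data frame (or list) with `source`, `target`,
#'   `condition`.
#' @return A string such as `"A->B@2"`.
#' @export
demand_label <- function(demand) {
  sprintf("%s->%s@%d", demand$source, demand$target,
          as.integer(demand$condition))
}

#' Does a solution satisfy a demand?
#'
#' A demand `(a, b, c)` is satisfied when the chosen edges contain an `a`-`b`
#' path (directed, if the graph is directed) all of whose edges are present at
#' condition `c`. When satisfied, a witness path is returned as an attribute.
#'
#' @param solution A [solution()].
#' @param demand One-row data frame or list with `source`, `target`,
#'   `condition`.
#' @param graph The [condition_graph()].
#' @return `TRUE` (with attribute `"witness"`, a character vector of
#'   vertices) or `FALSE`.
#' @export
satisfies <- function(solution, demand, graph) {
  stopifnot(inherits(solution, "csn_solution"))
  condition <- check_condition(graph, demand$condition)
  rows <- match_edges(graph, solution$edges$from, solution$edges$to)
  rows <- rows[vapply(graph$exists_at[rows],
                      function(s) condition %in% s, logical(1))]
  path <- find_path(graph, rows, as.character(demand$source),
                    as.character(demand$target))
  if (is.null(path)) return(FALSE)
  structure(TRUE, witness = path)
}

# BFS path (vertex names) from source to target over the given edge rows,
# or NULL. Plain integer BFS: this is the hot loop of the oracles.
find_path <- function(g, edge_rows, source, target) {
  n <- length(g$vertices)
  s <- match(source, g$vertices); t <- match(target, g$vertices)
  if (is.na(s) || is.na(t)) stop("unknown demand vertex")
  if (s == t) return(g$vertices[s])
  tail <- match(g$edges$from[edge_rows], g$vertices)
  head <- match(g$edges$to[edge_rows], g$vertices)
  if (!g$directed) {
    tmp_t <- c(tail, head); head <- c(head, tail); tail <- tmp_t
  }
  if (length(tail) == 0L) return(NULL)
  adj <- split(head, factor(tail, levels = seq_len(n)))
  parent <- integer(n)
  visited <- logical(n)
  visited[s] <- TRUE
  queue <- s
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        if (w == t) {
          path <- w
          while (path[[1L]] != s) path <- c(parent[path[[1L]]], path)
          return(g$vertices[path])
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Check a solution against every demand of an instance
#'
#' @param solution A [solution()].
#' @param instance A [csn_instance()].
#' @return `TRUE` if every demand is satisfied, else `FALSE`; the attribute
#'   `"per_demand"` holds a named logical vector.
#' @export
is_feasible <- function(solution, instance) {
  stopifnot(inherits(instance, "csn_instance"))
  ok <- vapply(seq_len(nrow(instance$demands)), function(i) {
    isTRUE(satisfies(solution, instance$demands[i, ], instance$graph))
  }, logical(1))
  names(ok) <- vapply(seq_len(nrow(instance$demands)), function(i) {
    demand_label(instance$demands[i, ])
  }, character(1))
  structure(all(ok), per_demand = ok)
}

# Fill in witness paths for every demand (assumes feasibility).
add_witnesses <- function(sol, instance) {
  wit <- list()
  for (i in seq_len(nrow(instance$demands))) {
    d <- instance$demands[i, ]
    ok <- satisfies(sol, d, instance$graph)
    if (!isTRUE(ok)) {
      stop("solution does not satisfy demand ", demand_label(d))
    }
    wit[[demand_label(d)]] <- attr(ok, "witness")
  }
  sol$witnesses <- wit
  sol
}

#' @export
print.csn_solution <- function(x, ...) {
  cat(sprintf("<csn_solution> %d edges, cost %.6g\n", nrow(x$edges), x$cost))
  if (!is.null(x$witnesses)) {
    cat(sprintf("  %d witnessed demand(s)\n", length(x$witnesses)))
  }
  invisible(x)
}
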