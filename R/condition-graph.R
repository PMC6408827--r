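# Condition graphs: a shared vertex set, an underlying weighted edge set, and
# for every edge the set of conditions at which it is present.

#' Construct a condition graph
#'
#' A condition graph is a sequence of graphs `G_1, ..., G_C` over one vertex
#' set `V`: the underlying edge set is `E = union of the E_c`, each edge `e`
#' carries a single nonnegative weight `w(e)` and a nonempty set of conditions
#' `exists_at(e) <- {1..C}` recording the frames `G_c = (V, E_c)` in which it
#' is present. Conditions model discrete biological states (time points,
#' treatments, cell types) under which different subsets of a reference
#' interaction network are active.
#'
#' Undirected edges are stored canonically (endpoints sorted), so the pair
#' `(u, v)` and `(v, u)` name the same edge. Parallel edges and self-loops are
#' not allowed; see [priority_steiner_instance()] for the one multigraph
#' formulation used by the priority-Steiner equivalence.
#'
#' @param edges A data frame with columns `from`, `to` (vertex identifiers,
#'   coerced to character), `weight` (nonnegative numeric) and `conditions`.
#'   `conditions` may be a list column of integer vectors or a character
#'   column of comma-separated condition indices such as `"1,3"`.
#' @param n_conditions Number of conditions `C` (positive integer).
#' @param directed Are the edges directed?
#' @param vertices Optional character vector of vertex identifiers; defaults
#'   to the vertices appearing in `edges`. Extra isolated vertices may be
#'   listed here.
#' @return An object of class `condition_graph` with fields `vertices`,
#'   `n_conditions`, `directed`, `edges` (data frame `from`, `to`, `weight`)
#'   and `exists_at` (list of sorted integer vectors, parallel to the edge
#'   rows).
#' @examples
#' g <- condition_graph(
#'   data.frame(from = c("A", "B"), to = c("B", "C"),
#'              weight = c(1, 2), conditions = c("1", "1,2")),
#'   n_conditions = 2
#' )
#' frame_at(g, 2)
#' @export
condition_graph <- function(edges, n_conditions, directed = FALSE,
                            vertices = NULL) {
  n_conditions <- as.integer(n_conditions)
  stopifnot(length(n_conditions) == 1L, n_conditions >= 1L)
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
    edges$conditions <- list()
  }
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- as.numeric(edges$weight)
  conds <- parse_condition_sets(edges$conditions, n_conditions)

  if (any(is.na(weight)) || any(weight < 0)) {
    stop("edge weights must be nonnegative numbers")
  }
  if (any(from == to)) {
    stop("self-loops are not allowed in a condition graph")
  }
  if (!directed) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  key <- edge_key(from, to)
  if (anyDuplicated(key)) {
    stop("parallel edges are not allowed: duplicate edge(s) ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  verts <- sort(unique(c(vertices, from, to)))
  if (any(grepl("[\t\n]", verts))) {
    stop("vertex identifiers must not contain tabs or newlines")
  }

  g <- structure(
    list(vertices = verts, n_conditions = n_conditions, directed = directed,
         edges = data.frame(from = from, to = to, weight = weight,
                            stringsAsFactors = FALSE),
         exists_at = conds),
    class = "condition_graph")
  g
}

# Accepts a list of integer vectors or a character vector like "1,3".
parse_condition_sets <- function(x, C) {
  if (is.null(x)) stop("edges need a 'conditions' column")
  if (is.list(x)) {
    out <- lapply(x, function(s) sort(unique(as.integer(s))))
  } else {
    out <- lapply(strsplit(as.character(x), ","),
                  function(s) sort(unique(as.integer(trimws(s)))))
  }
  bad <- vapply(out, function(s) {
    length(s) == 0L || anyNA(s) || any(s < 1L) || any(s > C)
  }, logical(1))
  if (any(bad)) {
    stop("condition set of edge row(s) ", paste(which(bad), collapse = ", "),
         " is empty, malformed or outside 1..", C)
  }
  out
}

edge_key <- function(from, to) paste(from, to, sep = "\t")

# Canonical key for a (possibly unordered) vertex pair in graph g.
canonical_key <- function(g, from, to) {
  from <- as.character(from); to <- as.character(to)
  if (!g$directed) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  edge_key(from, to)
}

n_edges <- function(g) nrow(g$edges)

# Row indices of edges present at condition c.
edges_at <- function(g, condition) {
  which(vapply(g$exists_at, function(s) condition %in% s, logical(1)))
}

check_condition <- function(g, condition) {
  condition <- as.integer(condition)
  if (length(condition) != 1L || is.na(condition) ||
      condition < 1L || condition > g$n_conditions) {
    stop("condition must be a single integer in 1..", g$n_conditions)
  }
  condition
}

#' Extract the frame of a condition graph at one condition
#'
#' The frame `G_c = (V, E_c)` is the plain weighted graph of edges present at
#' condition `c`, returned as an igraph object (with an edge attribute
#' `weight`) so the usual shortest-path and connectivity machinery applies
#' directly.
#'
#' @param graph A [condition_graph()].
#' @param condition Condition index in `1..C`.
#' @return An igraph graph on the full vertex set of `graph`.
#' @export
frame_at <- function(graph, condition) {
  stopifnot(inherits(graph, "condition_graph"))
  condition <- check_condition(graph, condition)
  cg_igraph(graph, edges_at(graph, condition))
}

# igraph over a subset of edge rows (all vertices retained).
cg_igraph <- function(g, edge_rows = seq_len(n_edges(g))) {
  e <- g$edges[edge_rows, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    e[, c("from", "to", "weight")],
    directed = g$directed,
    vertices = data.frame(name = g$vertices))
  ig
}

#' Is a condition graph monotonic?
#'
#' A condition graph is monotonic when every edge, once present, stays
#' present: `e` in `G_c` implies `e` in `G_c'` for all `c' >= c`. Equivalently
#' each edge's condition set is a suffix of `1..C`. Monotonic instances admit
#' far better approximation guarantees than the general problem.
#'
#' @param graph A [condition_graph()].
#' @return `TRUE` or `FALSE`.
#' @export
is_monotonic <- function(graph) {
  stopifnot(inherits(graph, "condition_graph"))
  C <- graph$n_conditions
  all(vapply(graph$exists_at, function(s) {
    identical(as.integer(s), seq.int(min(s), C))
  }, logical(1)))
}

#' @export
print.condition_graph <- function(x, ...) {
  cat(sprintf("<condition_graph> %s, %d vertices, %d edges, %d condition%s\n",
              if (x$directed) "directed" else "undirected",
              length(x$vertices), n_edges(x), x$n_conditions,
              if (x$n_conditions == 1L) "" else "s"))
  invisible(x)
}

# Restore the RNG state after running seeded code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
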