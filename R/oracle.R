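# Exact brute-force oracles for small instances. These are the ground truth
# against which the ILP, the approximations and every reduction are tested.

#' Exact optimum of a small CSN instance by branch and bound
#'
#' Enumerates subsets of the underlying edges with branch and bound: edges are
#' first pruned to those lying on at least one demand-relevant path in their
#' condition's frame, the remaining subsets are explored with cost bounding
#' against the incumbent and feasibility pruning (a branch whose undecided
#' edges cannot complete a feasible solution is cut). The result is provably
#' optimal. Ties between equal-cost optima are broken towards the
#' lexicographically smallest edge set, so the oracle is deterministic under
#' any input edge order.
#'
#' @param instance A [csn_instance()] (any variant; converted internally).
#' @param edge_budget Refuse instances with more than this many relevant
#'   edges (default 20) rather than silently approximating.
#' @return An optimal feasible [solution()] with witnesses, or an error of
#'   class `csnet_infeasible` when some demand cannot be satisfied.
#' @export
brute_force_opt <- function(instance, edge_budget = 20) {
  stopifnot(inherits(instance, "csn_instance"))
  red <- to_edge_variant(instance)
  ei <- red$instance
  g <- ei$graph

  rel <- relevant_edge_rows(ei)
  if (is.character(rel)) {           # infeasible demand label came back
    stop(infeasible_error(message = rel))
  }
  if (length(rel) > edge_budget) {
    stop(refusal_error(sprintf(
      "brute force refused: %d relevant edges exceed the budget of %d",
      length(rel), edge_budget)))
  }

  ctx <- demand_contexts(ei, rel)
  # Any feasible incumbent tightens the search; the shortest-path union is
  # feasible whenever the instance is.
  inc <- tryCatch(shortest_path_union(ei), csnet_infeasible = function(e) e)
  if (inherits(inc, "csnet_infeasible")) stop(inc)
  best <- list(cost = inc$cost + 1e-9, rows = NULL)

  ord <- rel[order(-g$edges$weight[rel], g$edges$from[rel], g$edges$to[rel])]
  w <- g$edges$weight

  feasible_with <- function(avail) {
    for (d in ctx) {
      if (!reachable_over(d, avail)) return(FALSE)
    }
    TRUE
  }

  recurse <- function(i, chosen, cost) {
    if (cost > best$cost + 1e-12) return()
    avail <- chosen
    if (feasible_with(chosen)) {
      rows <- sort(which(chosen))
      if (cost < best$cost - 1e-12 ||
          (cost < best$cost + 1e-12 && lex_less(rows, best$rows))) {
        best <<- list(cost = cost, rows = rows)
      }
      return()                        # adding edges cannot improve
    }
    if (i > length(ord)) return()
    remaining <- chosen
    remaining[ord[i:length(ord)]] <- TRUE
    if (!feasible_with(remaining)) return()
    # exclude first, then include
    recurse(i + 1L, chosen, cost)
    chosen[ord[i]] <- TRUE
    recurse(i + 1L, chosen, cost + w[ord[i]])
  }
  chosen0 <- logical(n_edges(g))
  recurse(1L, chosen0, 0)

  if (is.null(best$rows) && !feasible_with(chosen0)) {
    # incumbent was the only feasible solution found
    best <- list(cost = inc$cost,
                 rows = match_edges(g, inc$edges$from, inc$edges$to))
  }
  sol <- solution(g, g$edges[best$rows, c("from", "to")])
  sol <- red$lift(sol)
  add_witnesses(sol, instance)
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

# Edge rows that can lie on some demand's path: both endpoints must be on a
# source-to-target corridor in the demand's frame. Returns an integer vector,
# or a message string naming the first structurally unsatisfiable demand.
relevant_edge_rows <- function(ei) {
  g <- ei$graph
  keep <- logical(n_edges(g))
  for (i in seq_len(nrow(ei$demands))) {
    d <- ei$demands[i, ]
    rows <- edges_at(g, d$condition)
    ig <- cg_igraph(g, rows)
    fwd <- names(igraph::subcomponent(ig, d$source, mode = "out"))
    bwd <- names(igraph::subcomponent(ig, d$target, mode = "in"))
    if (!(d$target %in% fwd)) {
      return(paste0("demand ", demand_label(d),
                    " cannot be satisfied at its condition"))
    }
    on_corridor <- g$edges$from[rows] %in% fwd & g$edges$to[rows] %in% bwd
    if (!g$directed) {
      on_corridor <- g$edges$from[rows] %in% fwd & g$edges$to[rows] %in% fwd
    }
    keep[rows[on_corridor]] <- TRUE
  }
  which(keep)
}

# Precompute integer BFS contexts, one per demand, over the relevant rows.
demand_contexts <- function(ei, rel) {
  g <- ei$graph
  n <- length(g$vertices)
  lapply(seq_len(nrow(ei$demands)), function(i) {
    d <- ei$demands[i, ]
    rows <- intersect(rel, edges_at(g, d$condition))
    list(n = n,
         rows = rows,
         tail = match(g$edges$from[rows], g$vertices),
         head = match(g$edges$to[rows], g$vertices),
         directed = g$directed,
         s = match(d$source, g$vertices),
         t = match(d$target, g$vertices))
  })
}

# Is t reachable from s using this demand's rows restricted to avail?
reachable_over <- function(d, avail) {
  use <- avail[d$rows]
  tail <- d$tail[use]; head <- d$head[use]
  if (!d$directed) {
    tmp <- c(tail, head); head <- c(head, tail); tail <- tmp
  }
  visited <- logical(d$n)
  visited[d$s] <- TRUE
  frontier <- d$s
  while (length(frontier)) {
    hit <- tail %in% frontier
    nxt <- unique(head[hit])
    nxt <- nxt[!visited[nxt]]
    if (d$t %in% nxt) return(TRUE)
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  visited[d$t]
}

#' Exact optimum of a small CST or CPCST instance
#'
#' For a Condition Steiner Tree instance, enumerates edge subsets (branch and
#' bound as in [brute_force_opt()]) under the feasibility predicate that each
#' terminal set is mutually connected in its condition's frame. For a
#' prize-collecting instance, enumerates candidate vertex sets of the subtree
#' and prices each as the penalties of the excluded (vertex, condition) pairs
#' plus the minimum spanning tree of the induced subgraph; with nonnegative
#' weights the cheapest connected spanning subgraph of a fixed vertex set is
#' its MST, so the enumeration is exact.
#'
#' @param instance A [cst_instance()] or [cpcst_instance()].
#' @param edge_budget,vertex_budget Size guards; larger instances are refused
#'   rather than approximated.
#' @return A [solution()]; for CPCST the attribute `"tree_vertices"` holds
#'   the vertex set of the optimal subtree and `"objective"` the full
#'   objective (edges plus penalties, possibly `Inf` when every candidate
#'   tree leaves an infinitely penalized vertex out).
#' @export
brute_force_tree_opt <- function(instance, edge_budget = 18,
                                 vertex_budget = 8) {
  if (inherits(instance, "cst_instance")) {
    return(cst_brute(instance, edge_budget))
  }
  if (inherits(instance, "cpcst_instance")) {
    return(cpcst_brute(instance, vertex_budget))
  }
  stop("instance must be a cst_instance or cpcst_instance")
}

cst_brute <- function(instance, edge_budget) {
  g <- instance$graph
  m <- n_edges(g)
  if (m > edge_budget) {
    stop(refusal_error(sprintf(
      "brute force refused: %d edges exceed the budget of %d", m,
      edge_budget)))
  }
  n <- length(g$vertices)
  per_cond <- lapply(seq_len(g$n_conditions), function(c) {
    rows <- edges_at(g, c)
    list(rows = rows,
         tail = match(g$edges$from[rows], g$vertices),
         head = match(g$edges$to[rows], g$vertices),
         terms = match(instance$terminal_sets[[c]], g$vertices))
  })
  feasible_with <- function(avail) {
    for (pc in per_cond) {
      if (length(pc$terms) <= 1L) next
      use <- avail[pc$rows]
      if (!mutually_connected(n, pc$tail[use], pc$head[use], pc$terms)) {
        return(FALSE)
      }
    }
    TRUE
  }
  if (!feasible_with(rep(TRUE, m))) {
    stop(infeasible_error(
      message = "some terminal set is not connected even in the full frame"))
  }
  w <- g$edges$weight
  ord <- order(-w, g$edges$from, g$edges$to)
  best <- list(cost = sum(w) + 1, rows = NULL)
  recurse <- function(i, chosen, cost) {
    if (cost > best$cost + 1e-12) return()
    if (feasible_with(chosen)) {
      rows <- sort(which(chosen))
      if (cost < best$cost - 1e-12 ||
          (cost < best$cost + 1e-12 && lex_less(rows, best$rows))) {
        best <<- list(cost = cost, rows = rows)
      }
      return()
    }
    if (i > m) return()
    remaining <- chosen
    remaining[ord[i:m]] <- TRUE
    if (!feasible_with(remaining)) return()
    recurse(i + 1L, chosen, cost)
    chosen[ord[i]] <- TRUE
    recurse(i + 1L, chosen, cost + w[ord[i]])
  }
  recurse(1L, logical(m), 0)
  solution(g, g$edges[best$rows, c("from", "to")])
}

# Undirected connectivity of a terminal set over the given arcs.
mutually_connected <- function(n, tail, head, terms) {
  visited <- logical(n)
  visited[terms[1L]] <- TRUE
  frontier <- terms[1L]
  tl <- c(tail, head); hd <- c(head, tail)
  while (length(frontier)) {
    nxt <- unique(hd[tl %in% frontier])
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  all(visited[terms])
}

cpcst_brute <- function(instance, vertex_budget) {
  g <- instance$graph
  n <- length(g$vertices)
  if (n > vertex_budget) {
    stop(refusal_error(sprintf(
      "brute force refused: %d vertices exceed the budget of %d", n,
      vertex_budget)))
  }
  pen <- instance$penalty
  total_pen <- function(excluded) sum(pen[excluded, , drop = FALSE])
  best <- list(obj = total_pen(g$vertices), rows = integer(),
               verts = character())   # the empty tree pays every penalty
  ig <- cg_igraph(g)
  for (size in seq_len(n)) {
    combs <- utils::combn(g$vertices, size, simplify = FALSE)
    for (S in combs) {
      excluded <- setdiff(g$vertices, S)
      p <- total_pen(excluded)
      if (p > best$obj + 1e-12) next
      if (length(S) == 1L) {
        obj <- p
        rows <- integer()
      } else {
        sub <- igraph::induced_subgraph(ig, S)
        if (igraph::components(sub)$no != 1L) next
        mst <- igraph::mst(sub, weights = igraph::E(sub)$weight)
        obj <- p + sum(igraph::E(mst)$weight)
        ends <- igraph::as_edgelist(mst)
        rows <- if (nrow(ends)) match_edges(g, ends[, 1], ends[, 2])
                else integer()
      }
      if (obj < best$obj - 1e-12) {
        best <- list(obj = obj, rows = sort(rows), verts = S)
      }
    }
  }
  sol <- solution(g, g$edges[best$rows, c("from", "to")])
  attr(sol, "tree_vertices") <- best$verts
  attr(sol, "objective") <- best$obj
  sol
}
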