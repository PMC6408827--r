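# Inter-problem reductions: the shortest-path / Steiner-tree /
# prize-collecting chain, the priority-Steiner equivalence for monotonic
# instances, and the layered directed-Steiner-tree construction. Every
# reduction preserves the optimal objective exactly and returns a lift
# mapping solutions of the produced instance back to the source instance.

single_source_of <- function(demands) {
  src <- unique(demands$source)
  if (length(src) != 1L) return(NULL)
  src
}

#' Reduce a CSN instance to a condition shortest-path instance
#'
#' Adds a global source and sink: for the i-th demand `(a_i, b_i, c_i)` two
#' fresh relay vertices `x_i`, `y_i` and four zero-weight edges
#' `(SRC, x_i)`, `(x_i, a_i)`, `(b_i, y_i)`, `(y_i, SNK)` are created, all
#' present only at the produced instance's condition `i`; an original edge is
#' present at condition `i` exactly when it was present at `c_i`. The
#' produced demands are `(SRC, SNK, i)` for `i` in `1..k`, so the result is a
#' (directed, when the input is directed) condition shortest-path instance
#' with `k` conditions and the same optimum.
#'
#' @param instance A [csn_instance()] (any variant; converted internally).
#' @return A reduction object: `$instance` plus `$lift`.
#' @export
csn_to_csp <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"))
  red0 <- to_edge_variant(instance)
  ei <- red0$instance
  g <- ei$graph
  k <- nrow(ei$demands)
  names_new <- make_unique_names(
    c("SRC", "SNK", paste0("x", seq_len(k)), paste0("y", seq_len(k))),
    g$vertices)
  a <- names_new[1L]; b <- names_new[2L]
  x <- names_new[2L + seq_len(k)]; y <- names_new[2L + k + seq_len(k)]

  keep <- integer(); conds <- list()
  for (j in seq_len(n_edges(g))) {
    s <- which(ei$demands$condition %in% g$exists_at[[j]])
    if (length(s)) {
      keep <- c(keep, j)
      conds[[length(conds) + 1L]] <- s
    }
  }
  edf <- g$edges[keep, , drop = FALSE]
  edf$conditions <- conds
  gadget <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(
      from = c(a, x[i], ei$demands$target[i], y[i]),
      to = c(x[i], ei$demands$source[i], y[i], b),
      weight = 0, stringsAsFactors = FALSE)
  }))
  gadget$conditions <- lapply(rep(seq_len(k), each = 4L), identity)
  edf <- rbind(edf, gadget)
  g2 <- condition_graph(edf, n_conditions = k, directed = g$directed,
                        vertices = c(g$vertices, names_new))
  dem2 <- data.frame(source = a, target = b, condition = seq_len(k),
                     stringsAsFactors = FALSE)
  inst2 <- csn_instance(g2, dem2, variant = "edge")
  gadget_vertices <- names_new
  lift <- function(sol) {
    keep <- !(sol$edges$from %in% gadget_vertices) &
      !(sol$edges$to %in% gadget_vertices)
    red0$lift(solution(g, sol$edges[keep, , drop = FALSE]))
  }
  new_reduction(inst2, lift)
}

#' Reduce a condition shortest-path instance to condition Steiner tree
#'
#' The graphs are unchanged; the terminal set at every condition becomes the
#' common source/target pair `{a, b}`. Feasible solutions coincide, so the
#' optimum is identical and the lift is the identity.
#'
#' @param instance An undirected [csn_instance()] whose demands share one
#'   source and one target, with one demand per condition.
#' @return A reduction object with a [cst_instance()].
#' @export
csp_to_cst <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"))
  red0 <- to_edge_variant(instance)
  ei <- red0$instance
  if (ei$graph$directed) {
    stop("condition Steiner tree is undirected; directed input unsupported")
  }
  src <- unique(ei$demands$source); tgt <- unique(ei$demands$target)
  if (length(src) != 1L || length(tgt) != 1L ||
      !setequal(ei$demands$condition, seq_len(ei$graph$n_conditions))) {
    stop("input must be a condition shortest-path instance: a common ",
         "source/target pair with one demand per condition")
  }
  inst2 <- cst_instance(ei$graph,
                        rep(list(c(src, tgt)), ei$graph$n_conditions))
  lift <- function(sol) red0$lift(solution(ei$graph, sol$edges))
  new_reduction(inst2, lift)
}

#' Reduce condition Steiner tree to condition prize-collecting Steiner tree
#'
#' Penalties are set to `Inf` for terminals at their conditions and 0
#' everywhere else, so any finite-objective prize-collecting tree must span
#' every terminal set. The `Inf` sentinel is used as-is (never a large finite
#' constant), keeping cost arithmetic exact.
#'
#' Note the prize-collecting objective prices a single tree in the
#' *underlying* graph: it neither respects per-condition edge presence (it
#' can use an edge absent at a terminal set's condition) nor allows the
#' per-condition components a Steiner-tree solution may keep separate (it
#' must connect all terminal sets together). With one condition the two
#' problems coincide exactly; with several, either objective can be the
#' smaller. A finite prize-collecting objective does always certify that
#' the tree spans every terminal set. See the package vignette for
#' two-condition examples in both directions.
#'
#' @param instance A [cst_instance()].
#' @return A reduction object with a [cpcst_instance()].
#' @export
cst_to_cpcst <- function(instance) {
  stopifnot(inherits(instance, "cst_instance"))
  g <- instance$graph
  pen <- matrix(0, nrow = length(g$vertices), ncol = g$n_conditions,
                dimnames = list(g$vertices, NULL))
  for (c in seq_len(g$n_conditions)) {
    pen[instance$terminal_sets[[c]], c] <- Inf
  }
  inst2 <- cpcst_instance(g, pen)
  lift <- function(sol) solution(g, sol$edges)
  new_reduction(inst2, lift)
}

#' Reduce a monotonic CSN instance to Priority Steiner Tree
#'
#' In a monotonic instance each edge's condition set is a suffix of `1..C`;
#' its earliest condition becomes the edge's priority level, and a demand
#' `(a, b, c)` becomes the pair `(a, b)` with priority `c`. A subgraph
#' satisfies the demand exactly when it connects the pair using edges of
#' priority at most `c`, so optima coincide.
#'
#' @param instance An undirected, monotonic [csn_instance()].
#' @return A reduction object with a [priority_steiner_instance()]; its lift
#'   takes the solution's chosen edge row indices (into the produced
#'   instance's `edges`) and returns a [solution()] of the source instance.
#' @export
monotonic_csn_to_priority <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"))
  red0 <- to_edge_variant(instance)
  ei <- red0$instance
  g <- ei$graph
  if (g$directed) stop("priority Steiner tree is undirected")
  if (!is_monotonic(g)) stop("instance must be monotonic")
  edges <- g$edges
  edges$priority <- vapply(g$exists_at, min, numeric(1))
  dem <- data.frame(source = ei$demands$source,
                    target = ei$demands$target,
                    priority = ei$demands$condition,
                    stringsAsFactors = FALSE)
  inst2 <- priority_steiner_instance(edges, dem, vertices = g$vertices)
  # priority rows are in the same order as the source edge rows
  lift <- function(edge_rows) {
    red0$lift(solution(g, g$edges[sort(unique(edge_rows)),
                                  c("from", "to"), drop = FALSE]))
  }
  new_reduction(inst2, lift)
}

#' Reduce Priority Steiner Tree to a monotonic CSN instance
#'
#' Priorities become conditions: an edge of priority `p` exists at every
#' condition `>= p`, and a demand of priority `p` becomes a demand at
#' condition `p`. Parallel multiedges (which a simple condition graph cannot
#' host) are each split into two half-weight edges joined at a fresh midpoint
#' vertex, both inheriting the original priority. The lift contracts split
#' edges: a multiedge is recovered when both of its halves are chosen.
#'
#' @param instance A [priority_steiner_instance()].
#' @return A reduction object; its lift maps a [solution()] of the produced
#'   CSN instance to chosen edge row indices of the priority instance.
#' @export
priority_to_monotonic_csn <- function(instance) {
  stopifnot(inherits(instance, "priority_steiner_instance"))
  E <- instance$edges
  C <- max(c(E$priority, instance$demands$priority))
  pair <- edge_key(E$from, E$to)
  dup <- pair %in% pair[duplicated(pair)]
  rows <- list(); half_of <- list()
  mids <- character()
  for (i in seq_len(nrow(E))) {
    cond <- seq.int(E$priority[i], C)
    if (!dup[i]) {
      rows[[length(rows) + 1L]] <-
        data.frame(from = E$from[i], to = E$to[i], weight = E$weight[i],
                   stringsAsFactors = FALSE)
      rows[[length(rows)]]$conditions <- list(cond)
      half_of[[length(rows)]] <- c(i, NA_integer_)
    } else {
      mid <- make_unique_names(
        sprintf("m%d_%s_%s", i, E$from[i], E$to[i]),
        c(instance$vertices, mids))
      mids <- c(mids, mid)
      for (half in 1:2) {
        ends <- if (half == 1L) c(E$from[i], mid) else c(mid, E$to[i])
        rows[[length(rows) + 1L]] <-
          data.frame(from = ends[1L], to = ends[2L],
                     weight = E$weight[i] / 2, stringsAsFactors = FALSE)
        rows[[length(rows)]]$conditions <- list(cond)
        half_of[[length(rows)]] <- c(i, half)
      }
    }
  }
  edf <- do.call(rbind, rows)
  g2 <- condition_graph(edf, n_conditions = C, directed = FALSE,
                        vertices = c(instance$vertices, mids))
  dem2 <- data.frame(source = instance$demands$source,
                     target = instance$demands$target,
                     condition = instance$demands$priority,
                     stringsAsFactors = FALSE)
  inst2 <- csn_instance(g2, dem2, variant = "edge",
                        check_demand_coverage = FALSE)
  # map each produced (canonical) edge key to (source row, half)
  half_map <- do.call(rbind, half_of)
  keys <- canonical_key(g2, edf$from, edf$to)
  lift <- function(sol) {
    chosen <- match(canonical_key(g2, sol$edges$from, sol$edges$to), keys)
    src <- half_map[chosen, 1L]
    halves <- half_map[chosen, 2L]
    whole <- src[is.na(halves)]
    split_rows <- src[!is.na(halves)]
    both <- as.integer(names(which(table(split_rows) == 2L)))
    sort(unique(c(whole, both)))
  }
  new_reduction(inst2, lift)
}

#' Reduce monotonic condition Steiner tree to monotonic CSN
#'
#' Per condition `c`, the lexicographically smallest terminal of `X_c` is the
#' anchor and a demand `(anchor, b, c)` is created for every other terminal
#' `b` of `X_c` (mutual reachability of a set equals pairwise reachability
#' from any one member). A terminal set of size one yields no demand. Optima
#' coincide and the lift is the identity.
#'
#' @param instance A monotonic [cst_instance()].
#' @return A reduction object with a [csn_instance()].
#' @export
monotonic_cst_to_csn <- function(instance) {
  stopifnot(inherits(instance, "cst_instance"))
  if (!is_monotonic(instance$graph)) stop("instance must be monotonic")
  dem <- list()
  for (c in seq_len(instance$graph$n_conditions)) {
    X <- instance$terminal_sets[[c]]      # already sorted, nonempty
    if (length(X) > 1L) {
      dem[[length(dem) + 1L]] <-
        data.frame(source = X[1L], target = X[-1L], condition = c,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(dem)) stop("every terminal set is a singleton: no demands")
  inst2 <- csn_instance(instance$graph, do.call(rbind, dem),
                        variant = "edge", check_demand_coverage = FALSE)
  lift <- function(sol) solution(instance$graph, sol$edges)
  new_reduction(inst2, lift)
}

#' Reduce monotonic single-source DCSN to Directed Steiner Tree
#'
#' Builds the layered graph: one copy `v#i` of every vertex for each level
#' `i` up to the largest demand condition, a copy of each condition-`i` edge
#' within level `i` at its original weight, and zero-weight vertical edges
#' `(v#i, v#i+1)`. A demand `(a, b, c)` becomes the Steiner-tree demand from
#' `a#1` to `b#c`. For monotonic instances the layered optimum equals the
#' original optimum.
#'
#' @param instance A directed, monotonic, single-source [csn_instance()].
#' @return A reduction object; `$instance` is a single-condition directed
#'   [csn_instance()] (a Directed Steiner Tree instance) and `$lift` is
#'   [lift_dst_solution()] bound to the source instance.
#' @export
monotonic_ssdcsn_to_dst <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"))
  red0 <- to_edge_variant(instance)
  ei <- red0$instance
  g <- ei$graph
  if (!g$directed) stop("instance must be directed")
  if (!is_monotonic(g)) stop("instance must be monotonic")
  root <- single_source_of(ei$demands)
  if (is.null(root)) stop("all demands must share one source")
  if (any(grepl("#", g$vertices))) {
    stop("layered construction reserves '#' in vertex names")
  }
  ck <- max(ei$demands$condition)
  layer_name <- function(v, i) sprintf("%s#%03d", v, i)
  rows <- list()
  for (i in seq_len(ck)) {
    at <- edges_at(g, i)
    if (length(at)) {
      rows[[length(rows) + 1L]] <-
        data.frame(from = layer_name(g$edges$from[at], i),
                   to = layer_name(g$edges$to[at], i),
                   weight = g$edges$weight[at], stringsAsFactors = FALSE)
    }
  }
  if (ck > 1L) {
    for (i in seq_len(ck - 1L)) {
      rows[[length(rows) + 1L]] <-
        data.frame(from = layer_name(g$vertices, i),
                   to = layer_name(g$vertices, i + 1L),
                   weight = 0, stringsAsFactors = FALSE)
    }
  }
  edf <- do.call(rbind, rows)
  edf$conditions <- rep(list(1L), nrow(edf))
  verts <- as.vector(outer(g$vertices, seq_len(ck), layer_name))
  g2 <- condition_graph(edf, n_conditions = 1L, directed = TRUE,
                        vertices = verts)
  dem <- ei$demands[order(ei$demands$condition), , drop = FALSE]
  dem2 <- data.frame(source = layer_name(root, 1L),
                     target = layer_name(dem$target, dem$condition),
                     condition = 1L, stringsAsFactors = FALSE)
  inst2 <- csn_instance(g2, dem2, variant = "edge")
  lift <- function(sol) lift_dst_solution(sol, instance)
  new_reduction(inst2, lift)
}

#' Project a layered Directed-Steiner-Tree solution back to the original
#' instance
#'
#' Every layered edge `(u#i, v#i)` contributes the underlying edge `(u, v)`;
#' vertical zero-weight edges are dropped. Because an underlying edge used at
#' several levels is paid for once after projection, the projected cost is at
#' most the layered cost, with equality when the tree uses at most one copy
#' of each underlying edge.
#'
#' @param tree A [solution()] of the layered instance produced by
#'   [monotonic_ssdcsn_to_dst()].
#' @param original The source [csn_instance()].
#' @return A feasible [solution()] of `original`, with witnesses; errors if
#'   the input tree does not satisfy the original demands.
#' @export
lift_dst_solution <- function(tree, original) {
  stopifnot(inherits(tree, "csn_solution"),
            inherits(original, "csn_instance"))
  red0 <- to_edge_variant(original)
  g <- red0$instance$graph
  strip <- function(x) sub("#[0-9]+$", "", x)
  from <- strip(tree$edges$from); to <- strip(tree$edges$to)
  horiz <- from != to
  sol <- solution(g, data.frame(from = from[horiz], to = to[horiz],
                                stringsAsFactors = FALSE))
  sol <- red0$lift(sol)
  feas <- is_feasible(sol, original)
  if (!isTRUE(feas)) {
    bad <- names(which(!attr(feas, "per_demand")))[1L]
    stop("projected tree does not satisfy demand ", bad,
         "; the input tree must be feasible for the layered instance")
  }
  add_witnesses(sol, original)
}
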