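# Approximation algorithms: the union-of-shortest-paths k-approximation,
# per-condition metric closure, and the recursive-greedy density algorithm
# for monotonic single-source directed instances.

#' Per-condition metric closure of a condition graph
#'
#' Computes, for every ordered vertex pair and condition, the shortest-path
#' distance `w~(u, v, c)` within the frame `G_c` (`Inf` when unreachable),
#' with a path-recovery handle returning one concrete shortest path per
#' triple. For monotonic graphs the distances are nonincreasing in `c`.
#'
#' @param graph A [condition_graph()] with nonnegative weights.
#' @return An object of class `metric_closure` with a `|V| x |V| x C`
#'   distance array `distance` (dimnames are vertex names); see
#'   [closure_path()].
#' @export
metric_closure <- function(graph) {
  stopifnot(inherits(graph, "condition_graph"))
  n <- length(graph$vertices)
  frames <- lapply(seq_len(graph$n_conditions),
                   function(c) frame_at(graph, c))
  dist <- array(Inf, dim = c(n, n, graph$n_conditions),
                dimnames = list(graph$vertices, graph$vertices, NULL))
  for (c in seq_len(graph$n_conditions)) {
    dist[, , c] <- igraph::distances(frames[[c]], mode = "out")
  }
  structure(list(graph = graph, frames = frames, distance = dist),
            class = "metric_closure")
}

#' Recover one shortest path realizing a closure distance
#'
#' @param closure A [metric_closure()].
#' @param from,to Vertex names.
#' @param condition Condition index.
#' @return Character vector of vertices along a shortest `from`-`to` path in
#'   the frame at `condition`, or `NULL` when unreachable.
#' @export
closure_path <- function(closure, from, to, condition) {
  stopifnot(inherits(closure, "metric_closure"))
  condition <- check_condition(closure$graph, condition)
  if (!is.finite(closure$distance[from, to, condition])) return(NULL)
  if (from == to) return(from)
  p <- igraph::shortest_paths(closure$frames[[condition]], from, to,
                              mode = "out", output = "vpath")
  names(p$vpath[[1L]])
}

#' Union-of-shortest-paths heuristic
#'
#' For each demand `(a, b, c)` take one shortest `a`-`b` path in the frame
#' `G_c` and return the union of these `k` paths. The union is always
#' feasible when each demand is individually satisfiable and costs at most
#' `k` times the optimum; worst-case instances (see [star_worst_case()])
#' show the factor `k` is attained.
#'
#' @param instance A [csn_instance()] (any variant).
#' @return A feasible [solution()] with one witness per demand; an error of
#'   class `csnet_infeasible` naming the first unreachable demand otherwise.
#' @export
shortest_path_union <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"))
  red0 <- to_edge_variant(instance)
  ei <- red0$instance
  g <- ei$graph
  frames <- list()
  edges <- list()
  for (i in seq_len(nrow(ei$demands))) {
    d <- ei$demands[i, ]
    c <- d$condition
    if (is.null(frames[[as.character(c)]])) {
      frames[[as.character(c)]] <- frame_at(g, c)
    }
    fr <- frames[[as.character(c)]]
    dd <- igraph::distances(fr, d$source, d$target, mode = "out")
    if (!is.finite(dd[1L])) stop(infeasible_error(d))
    p <- igraph::shortest_paths(fr, d$source, d$target, mode = "out",
                                output = "vpath")
    verts <- names(p$vpath[[1L]])
    if (length(verts) > 1L) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = verts[-length(verts)], to = verts[-1L],
                   stringsAsFactors = FALSE)
    }
  }
  sol <- solution(g, if (length(edges)) do.call(rbind, edges) else NULL)
  sol <- red0$lift(sol)
  add_witnesses(sol, instance)
}

#' Recursive-greedy approximation for monotonic single-source DCSN
#'
#' Runs the level-`i` recursive greedy over closure trees: tree nodes are
#' (vertex, condition) pairs, an arc from `(u, c_u)` to `(v, c_v)` with
#' `c_v >= c_u` is priced at the closure distance `w~(u, v, c_v)`, and the
#' algorithm repeatedly picks, over all intermediate pairs and all cover
#' sizes, the subtree of minimum density (cost per newly covered demand).
#' At the base level the candidate trees are direct arcs to the nearest
#' uncovered demand terminals. The resulting closure tree is expanded into a
#' concrete subgraph by replacing every arc with a recovered shortest path.
#'
#' For `level >= 2` the closure-tree cost is within
#' `level^2 (level-1) k^(1/level)` of the optimum; the expanded solution
#' costs at most the closure tree (shared edges are paid once). Selection
#' ties are broken deterministically (first candidate in vertex-then-
#' condition-then-size order), so repeated runs agree.
#'
#' @param instance A monotonic, directed, single-source [csn_instance()].
#' @param level Recursion depth `i >= 1`; `level = 1` reproduces the
#'   union-of-shortest-paths behaviour, `level = 2` is the usual choice.
#' @return A feasible [solution()] with witnesses; the attributes
#'   `"closure_tree"` (data frame of arcs) and `"closure_cost"` carry the
#'   abstract tree whose cost the guarantee bounds.
#' @export
charikar_tree <- function(instance, level = 2L) {
  stopifnot(inherits(instance, "csn_instance"))
  level <- as.integer(level)
  stopifnot(level >= 1L)
  red0 <- to_edge_variant(instance)
  ei <- red0$instance
  g <- ei$graph
  if (!g$directed) stop("the recursive greedy expects a directed instance")
  if (!is_monotonic(g)) stop("instance must be monotonic")
  root <- single_source_of(ei$demands)
  if (is.null(root)) stop("all demands must share one source")

  cl <- metric_closure(g)
  terms <- unique(ei$demands[, c("target", "condition")])
  terms <- terms[order(terms$target, terms$condition), , drop = FALSE]
  for (i in seq_len(nrow(terms))) {
    if (!is.finite(cl$distance[root, terms$target[i], terms$condition[i]])) {
      d <- ei$demands[ei$demands$target == terms$target[i] &
                        ei$demands$condition == terms$condition[i], ][1L, ]
      stop(infeasible_error(d))
    }
  }

  verts <- g$vertices                      # sorted at construction
  C <- g$n_conditions
  eps <- 1e-12

  # base level: direct arcs from (v, c) to the k' nearest uncovered demands
  base_tree <- function(v, c, kk, unc) {
    cb <- terms$condition[unc]
    ok <- cb >= c
    d <- rep(Inf, length(unc))
    for (j in which(ok)) {
      d[j] <- cl$distance[v, terms$target[unc[j]], cb[j]]
    }
    ord <- order(d, terms$target[unc], cb)
    take <- ord[seq_len(min(kk, sum(is.finite(d))))]
    if (length(take) < kk || !length(take)) return(NULL)
    covered <- unc[take]
    list(arcs = data.frame(u = v, cu = c,
                           v = terms$target[covered],
                           cv = terms$condition[covered],
                           price = d[take], stringsAsFactors = FALSE),
         cost = sum(d[take]), covered = covered)
  }

  greedy <- function(lvl, v, c, kk, unc) {
    if (lvl == 1L) return(base_tree(v, c, kk, unc))
    acc_arcs <- NULL; acc_cost <- 0; acc_cov <- integer()
    remaining <- unc; need <- kk
    while (need > 0L) {
      best <- NULL; best_density <- Inf
      for (x in verts) {
        for (j in c:C) {
          entry <- cl$distance[v, x, j]
          if (!is.finite(entry)) next
          for (kp in seq_len(need)) {
            sub <- greedy(lvl - 1L, x, j, kp, remaining)
            if (is.null(sub)) break   # larger kp cannot succeed either
            dens <- (entry + sub$cost) / length(sub$covered)
            if (dens < best_density - eps) {
              best_density <- dens
              best <- list(arcs = rbind(
                data.frame(u = v, cu = c, v = x, cv = j, price = entry,
                           stringsAsFactors = FALSE), sub$arcs),
                cost = entry + sub$cost, covered = sub$covered)
            }
          }
        }
      }
      if (is.null(best)) return(NULL)
      acc_arcs <- rbind(acc_arcs, best$arcs)
      acc_cost <- acc_cost + best$cost
      acc_cov <- c(acc_cov, best$covered)
      remaining <- setdiff(remaining, best$covered)
      need <- need - length(best$covered)
    }
    list(arcs = acc_arcs, cost = acc_cost, covered = acc_cov)
  }

  k <- nrow(terms)
  tree <- greedy(level, root, 1L, k, seq_len(k))
  if (is.null(tree)) {
    stop(infeasible_error(message = "recursive greedy could not cover every demand"))
  }
  sol <- expand_closure_tree(tree$arcs, cl, g)
  sol <- red0$lift(sol)
  sol <- add_witnesses(sol, instance)
  attr(sol, "closure_tree") <- tree$arcs
  attr(sol, "closure_cost") <- tree$cost
  sol
}

#' Expand a closure tree into a concrete solution
#'
#' Replaces every closure arc `((u, c_u), (v, c_v))` by one recovered
#' shortest `u`-`v` path in the frame at `c_v` and returns the union of
#' their edges (each underlying edge counted once, so the expanded cost
#' never exceeds the sum of arc prices).
#'
#' @param tree Data frame of arcs with columns `u`, `cu`, `v`, `cv`,
#'   `price` (as produced by [charikar_tree()]).
#' @param closure The [metric_closure()] the arc prices came from.
#' @param graph The underlying [condition_graph()].
#' @return A [solution()].
#' @export
expand_closure_tree <- function(tree, closure, graph) {
  edges <- list()
  for (i in seq_len(nrow(tree))) {
    if (!is.finite(tree$price[i])) {
      stop("closure tree contains an arc with infinite distance")
    }
    verts <- closure_path(closure, tree$u[i], tree$v[i], tree$cv[i])
    if (is.null(verts)) {
      stop("closure tree contains an arc with infinite distance")
    }
    if (length(verts) > 1L) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = verts[-length(verts)], to = verts[-1L],
                   stringsAsFactors = FALSE)
    }
  }
  solution(graph, if (length(edges)) do.call(rbind, edges) else NULL)
}
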