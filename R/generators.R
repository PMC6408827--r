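# Instance generators: Label Cover and k-partite hypergraph Label Cover
# gadgets (bundles, strands, merged contact edges), the worked two-condition
# toy, the worst-case star for the union-of-shortest-paths heuristic, random
# monotonic fixtures, and the PPI-style single-source sampler.

#' Construct a Label Cover instance
#'
#' A bipartite constraint graph with a label on each side of every edge:
#' the projection functions map labels to colors and an edge is satisfied by
#' a labeling when the two projected colors agree.
#'
#' @param left,right Character vectors of left/right vertices.
#' @param edges Data frame with columns `u` (left vertex) and `v` (right
#'   vertex).
#' @param n_labels Number of labels (labels are `1..n_labels`).
#' @param projections List, one element per edge row, each a list with
#'   integer vectors `u` and `v` of length `n_labels` mapping each label to
#'   a color.
#' @return An object of class `label_cover_instance`.
#' @export
label_cover_instance <- function(left, right, edges, n_labels, projections) {
  stopifnot(is.data.frame(edges), all(c("u", "v") %in% names(edges)),
            length(projections) == nrow(edges))
  edges <- data.frame(u = as.character(edges$u), v = as.character(edges$v),
                      stringsAsFactors = FALSE)
  stopifnot(all(edges$u %in% left), all(edges$v %in% right))
  for (p in projections) {
    stopifnot(length(p$u) == n_labels, length(p$v) == n_labels)
  }
  structure(list(left = as.character(left), right = as.character(right),
                 edges = edges, n_labels = as.integer(n_labels),
                 projections = projections),
            class = "label_cover_instance")
}

#' Construct a k-partite hypergraph Label Cover instance
#'
#' Generalizes [label_cover_instance()] to a k-partite hypergraph: every
#' hyperedge contains exactly one vertex from each part and carries one
#' projection function per contained vertex. A labeling strongly satisfies a
#' hyperedge when all its projected colors coincide.
#'
#' @param parts List of `k` character vectors (the vertex parts).
#' @param hyperedges List of character vectors of length `k`, element `c`
#'   drawn from part `c`.
#' @param n_labels Number of labels.
#' @param projections List, one element per hyperedge, each a list of `k`
#'   integer vectors of length `n_labels` (label to color, per position).
#' @return An object of class `kphlc_instance`. A warning is emitted when
#'   the hypergraph is not k-regular (some vertex is not in exactly `k`
#'   hyperedges); the constructions do not require regularity.
#' @export
kphlc_instance <- function(parts, hyperedges, n_labels, projections) {
  k <- length(parts)
  stopifnot(k >= 2L, length(projections) == length(hyperedges))
  for (e in hyperedges) {
    stopifnot(length(e) == k)
    for (c in seq_len(k)) stopifnot(e[c] %in% parts[[c]])
  }
  for (p in projections) {
    stopifnot(length(p) == k,
              all(vapply(p, length, integer(1)) == n_labels))
  }
  counts <- table(unlist(hyperedges))
  all_v <- unlist(parts)
  if (length(hyperedges) &&
      (!setequal(names(counts), all_v) || any(counts != k))) {
    warning("hypergraph is not k-regular; constructions proceed anyway",
            call. = FALSE)
  }
  structure(list(parts = parts, hyperedges = hyperedges,
                 n_labels = as.integer(n_labels),
                 projections = projections, k = k),
            class = "kphlc_instance")
}

# -- gadget builder ----------------------------------------------------------
# Accumulates directed weighted condition edges; adding an existing edge
# unions its condition set (that is exactly the "merge contact edges" rule).
gadget_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$store <- new.env(parent = emptyenv())
  env
}

gadget_add <- function(b, from, to, weight, conditions) {
  key <- edge_key(from, to)
  cur <- b$store[[key]]
  if (is.null(cur)) {
    b$store[[key]] <- list(from = from, to = to, weight = weight,
                           conds = as.integer(conditions))
  } else {
    stopifnot(cur$weight == weight)
    b$store[[key]]$conds <- union(cur$conds, as.integer(conditions))
  }
}

# A simple strand b1 -> c1 -> c2 -> b2: entry/exit edges weigh zero, the
# middle contact edge weighs one. Strands with the same contact key share
# their contact edge, which then exists at the union of the sides'
# conditions.
gadget_strand <- function(b, from, to, key, condition) {
  c1 <- paste0("c1_", key); c2 <- paste0("c2_", key)
  gadget_add(b, from, c1, 0, condition)
  gadget_add(b, c1, c2, 1, condition)
  gadget_add(b, c2, to, 0, condition)
}

gadget_graph <- function(b, n_conditions, extra_vertices = character()) {
  keys <- sort(ls(b$store))
  rows <- lapply(keys, function(k) b$store[[k]])
  edf <- data.frame(from = vapply(rows, `[[`, "", "from"),
                    to = vapply(rows, `[[`, "", "to"),
                    weight = vapply(rows, `[[`, 0, "weight"),
                    stringsAsFactors = FALSE)
  edf$conditions <- lapply(rows, `[[`, "conds")
  condition_graph(edf, n_conditions, directed = TRUE,
                  vertices = extra_vertices)
}

#' Encode a Label Cover instance as a two-condition directed CSN instance
#'
#' The hardness gadget: for each left vertex a chain of bundles at condition
#' 1 — one bundle per vertex, one strand per label, and within a strand one
#' sub-bundle per incident constraint edge holding a unit-weight contact
#' edge per agreeing right label (or a lone unlabeled strand when no label
#' agrees). The right side is built symmetrically at condition 2, and
#' strands describing the same (left vertex, left label, right vertex,
#' right label) combination share their contact edge across the two
#' conditions. The two demands run along each chain, so a solution induces a
#' labeling of both sides; the optimum equals the number of constraint
#' edges exactly when a totally satisfying labeling exists. The underlying
#' digraph is acyclic.
#'
#' @param lc A [label_cover_instance()].
#' @return A directed two-condition [csn_instance()].
#' @export
label_cover_to_2dcsn <- function(lc) {
  stopifnot(inherits(lc, "label_cover_instance"))
  b <- gadget_builder()
  L <- lc$n_labels

  build_side <- function(nodes, side) {
    # side "u": condition 1, own labels project via $u, partner via $v
    cond <- if (side == "u") 1L else 2L
    for (i in seq_along(nodes)) {
      # traverse incident constraint edges sorted by the partner vertex so
      # the two sides order shared contact edges as consistently as possible
      inc <- if (side == "u") which(lc$edges$u == nodes[i])
             else which(lc$edges$v == nodes[i])
      inc <- if (side == "u") {
        inc[order(match(lc$edges$v[inc], lc$right), inc)]
      } else {
        inc[order(match(lc$edges$u[inc], lc$left), inc)]
      }
      s0 <- sprintf("%s%d_S", side, i)
      s1 <- sprintf("%s%d_S", side, i + 1L)
      if (!length(inc)) {       # unconstrained vertex: free pass-through
        gadget_add(b, s0, s1, 0, cond)
        next
      }
      for (lab in seq_len(L)) {
        # chain of per-edge bundles through this label's strand
        chain <- c(s0,
                   if (length(inc) > 1L)
                     sprintf("%s%d_l%d_t%d", side, i, lab,
                             seq_len(length(inc) - 1L)),
                   s1)
        for (j in seq_along(inc)) {
          e <- inc[j]
          pr <- lc$projections[[e]]
          partners <- if (side == "u") which(pr$v == pr$u[lab])
                      else which(pr$u == pr$v[lab])
          if (length(partners)) {
            for (r in partners) {
              key <- if (side == "u") sprintf("e%d_l%d_r%d", e, lab, r)
                     else sprintf("e%d_l%d_r%d", e, r, lab)
              gadget_strand(b, chain[j], chain[j + 1L], key, cond)
            }
          } else {
            gadget_strand(b, chain[j], chain[j + 1L],
                          sprintf("%s%d_e%d_l%d_none", side, i, e, lab),
                          cond)
          }
        }
      }
    }
  }
  build_side(lc$left, "u")
  build_side(lc$right, "v")

  g <- gadget_graph(b, 2L)
  dem <- data.frame(
    source = c("u1_S", "v1_S"),
    target = c(sprintf("u%d_S", length(lc$left) + 1L),
               sprintf("v%d_S", length(lc$right) + 1L)),
    condition = c(1L, 2L), stringsAsFactors = FALSE)
  csn_instance(g, dem, variant = "edge")
}

#' The worked two-condition toy instance
#'
#' The fixed small gadget used throughout: a Label Cover instance with a
#' single constraint edge (u, v), labels `{1, 2}` and projections chosen so
#' that both labels of `u` agree with label 2 of `v` while label 1 of `v`
#' agrees with nothing (`pi_u(1) = pi_u(2) = 1`, `pi_v(2) = 1`,
#' `pi_v(1) = 2`). The resulting two-condition instance has one strand per
#' `u`-label at condition 1, a lone strand for `v`-label 1 and a two-strand
#' bundle for `v`-label 2 at condition 2, with the two agreeing
#' (u-label, v-label 2) contact edges shared between conditions. Its optimum
#' is 1: a single shared contact edge serves both demands.
#'
#' @return A directed two-condition [csn_instance()] with demands
#'   `(u1_S, u2_S, 1)` and `(v1_S, v2_S, 2)`.
#' @export
example1 <- function() {
  lc <- label_cover_instance(
    left = "u", right = "v",
    edges = data.frame(u = "u", v = "v"),
    n_labels = 2L,
    projections = list(list(u = c(1L, 1L), v = c(2L, 1L))))
  label_cover_to_2dcsn(lc)
}

#' Encode a k-partite hypergraph Label Cover instance as a k-condition DCSN
#' instance
#'
#' Generalizes [label_cover_to_2dcsn()]: part `c` becomes a chain of bundles
#' whose edges exist only at condition `c`; within a vertex's label strand
#' there is one sub-bundle per incident hyperedge containing a unit-weight
#' contact edge for every strongly agreeing label k-tuple (all projected
#' colors equal), and these tuple strands are merged across all k parts.
#' For strongly satisfiable inputs the optimum is the number of hyperedges;
#' when no tuple agrees anywhere it is `k` times that.
#'
#' @param inst A [kphlc_instance()] with `k >= 2`.
#' @return A directed k-condition [csn_instance()].
#' @export
kphlc_to_dcsn <- function(inst) {
  stopifnot(inherits(inst, "kphlc_instance"))
  k <- inst$k
  L <- inst$n_labels
  b <- gadget_builder()

  # all strongly agreeing label tuples, per hyperedge
  agreeing <- lapply(seq_along(inst$hyperedges), function(e) {
    pr <- inst$projections[[e]]
    tuples <- as.matrix(expand.grid(rep(list(seq_len(L)), k)))
    ok <- apply(tuples, 1L, function(tp) {
      cols <- vapply(seq_len(k), function(c) pr[[c]][tp[c]], integer(1))
      all(cols == cols[1L])
    })
    tuples[ok, , drop = FALSE]
  })

  for (c in seq_len(k)) {
    part <- inst$parts[[c]]
    for (i in seq_along(part)) {
      v <- part[i]
      inc <- which(vapply(inst$hyperedges, function(e) e[c] == v,
                          logical(1)))
      s0 <- sprintf("v%d_%d_S", c, i)
      s1 <- sprintf("v%d_%d_S", c, i + 1L)
      if (!length(inc)) {       # unconstrained vertex: free pass-through
        gadget_add(b, s0, s1, 0, c)
        next
      }
      for (lab in seq_len(L)) {
        chain <- c(s0,
                   if (length(inc) > 1L)
                     sprintf("v%d_%d_l%d_t%d", c, i, lab,
                             seq_len(length(inc) - 1L)),
                   s1)
        for (j in seq_along(inc)) {
          e <- inc[j]
          tuples <- agreeing[[e]]
          mine <- tuples[tuples[, c] == lab, , drop = FALSE]
          if (nrow(mine)) {
            for (t in seq_len(nrow(mine))) {
              key <- sprintf("e%d_%s", e, paste(mine[t, ], collapse = "_"))
              gadget_strand(b, chain[j], chain[j + 1L], key, c)
            }
          } else {
            gadget_strand(b, chain[j], chain[j + 1L],
                          sprintf("p%d_%d_e%d_l%d_none", c, i, e, lab), c)
          }
        }
      }
    }
  }
  g <- gadget_graph(b, k)
  dem <- do.call(rbind, lapply(seq_len(k), function(c) {
    data.frame(source = sprintf("v%d_1_S", c),
               target = sprintf("v%d_%d_S", c,
                                length(inst$parts[[c]]) + 1L),
               condition = c, stringsAsFactors = FALSE)
  }))
  csn_instance(g, dem, variant = "edge")
}

#' Worst-case star for the union-of-shortest-paths heuristic
#'
#' A root with a direct arc of weight `M - eps` to each of `k` targets, and
#' a hub at distance `M` from the root with free arcs to every target. The
#' optimum routes everything through the hub at cost `M`, while the
#' per-demand shortest paths take the marginally cheaper direct arcs,
#' costing `k (M - eps)` in total — the heuristic's approximation factor
#' `k` is attained up to epsilon.
#'
#' @param k Number of targets/demands.
#' @param M Hub distance (the optimal cost).
#' @param eps Direct-arc discount, `0 < eps < M`.
#' @return A directed single-condition single-source [csn_instance()].
#' @export
star_worst_case <- function(k, M, eps) {
  stopifnot(k >= 1L, eps > 0, eps < M)
  targets <- sprintf("b%d", seq_len(k))
  edf <- data.frame(
    from = c(rep("root", k), "root", rep("hub", k)),
    to = c(targets, "hub", targets),
    weight = c(rep(M - eps, k), M, rep(0, k)),
    stringsAsFactors = FALSE)
  edf$conditions <- rep(list(1L), nrow(edf))
  g <- condition_graph(edf, 1L, directed = TRUE)
  csn_instance(g, data.frame(source = "root", target = targets,
                             condition = 1L, stringsAsFactors = FALSE))
}

# Degree-skewed random digraph emulating PPI topology: targets of new arcs
# are drawn preferentially by current in-degree; weights are negative log
# pseudo-confidences.
random_ppi_digraph <- function(n, m) {
  verts <- sprintf("v%04d", seq_len(n))
  indeg <- rep(1, n)
  from <- integer(m); to <- integer(m)
  seen <- new.env(parent = emptyenv())
  i <- 1L; guard <- 0L
  while (i <= m) {
    guard <- guard + 1L
    if (guard > 50L * m) stop("could not place ", m, " distinct arcs")
    u <- sample.int(n, 1L)
    v <- sample.int(n, 1L, prob = indeg)
    if (u == v) next
    key <- paste0(u, "_", v)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    from[i] <- u; to[i] <- v
    indeg[v] <- indeg[v] + 1
    i <- i + 1L
  }
  data.frame(from = verts[from], to = verts[to],
             weight = -log(stats::runif(m, 0.5, 0.99)),
             stringsAsFactors = FALSE)
}

#' Sample a PPI-like single-source instance
#'
#' Emulates the random benchmark model over a protein-interaction-like
#' graph: (1) draw a degree-skewed random weighted digraph (weights are
#' negative log pseudo-confidences in (0.01, 0.7)); (2) fix a root `a`
#' (the vertex with the largest out-reachable set) and, for each of the `C`
#' conditions, sample `beta` targets uniformly from the vertices reachable
#' from `a` (without replacement within a condition, independently across
#' conditions); (3) a vertex is present at condition `c` when it lies on
#' the (deterministically chosen) shortest path from `a` to one of that
#' condition's targets; (4) every other vertex is present at `c`
#' independently with probability `p`. Demands connect `a` to every sampled
#' target at its condition; the result is a node-variant directed instance.
#'
#' @param n,m Number of vertices and arcs of the base digraph.
#' @param beta Targets per condition.
#' @param C Number of conditions.
#' @param p Background node-inclusion probability.
#' @param seed Optional integer seed (the generator is a pure function of
#'   parameters and seed).
#' @return A node-variant directed [csn_instance()].
#' @export
random_single_source_instance <- function(n, m, beta, C, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1, beta >= 1, C >= 1)
  with_seed(seed, {
    edf <- random_ppi_digraph(n, m)
    ig <- igraph::graph_from_data_frame(
      edf, directed = TRUE,
      vertices = data.frame(name = sort(unique(c(edf$from, edf$to,
                                                 sprintf("v%04d", 1:n))))))
    dm <- igraph::distances(ig, mode = "out", weights = igraph::E(ig)$weight)
    reach_count <- rowSums(is.finite(dm))
    a <- rownames(dm)[which.max(reach_count)]
    reachable <- setdiff(colnames(dm)[is.finite(dm[a, ])], a)
    if (length(reachable) < beta) {
      stop("only ", length(reachable), " vertices reachable from the root; ",
           "need at least beta = ", beta)
    }
    verts <- igraph::V(ig)$name
    tau <- stats::setNames(rep(list(integer()), length(verts)), verts)
    demands <- NULL
    for (c in seq_len(C)) {
      targets <- sample(reachable, beta)
      sp <- igraph::shortest_paths(ig, from = a, to = targets,
                                   mode = "out", output = "vpath",
                                   weights = igraph::E(ig)$weight)
      on_paths <- unique(c(a, unlist(lapply(sp$vpath, names))))
      background <- verts[stats::runif(length(verts)) < p]
      for (v in union(on_paths, background)) {
        tau[[v]] <- c(tau[[v]], c)
      }
      demands <- rbind(demands,
                       data.frame(source = a, target = targets,
                                  condition = c, stringsAsFactors = FALSE))
    }
    present <- names(tau)[lengths(tau) > 0L]
    tau <- tau[present]
    keep <- edf$from %in% present & edf$to %in% present
    edf <- edf[keep, , drop = FALSE]
    conds <- mapply(function(u, v) intersect(tau[[u]], tau[[v]]),
                    edf$from, edf$to, SIMPLIFY = FALSE)
    nonempty <- lengths(conds) > 0L
    edf <- edf[nonempty, , drop = FALSE]
    edf$conditions <- conds[nonempty]
    g <- condition_graph(edf, C, directed = TRUE, vertices = present)
    csn_instance(g, demands, variant = "node", node_conditions = tau)
  })
}

#' Sample a random monotonic instance
#'
#' Assigns every edge of a random weighted graph a birth condition uniform
#' on `1..C`; the edge is present from its birth condition on, so the
#' instance is monotonic by construction. Demands are sampled to be
#' satisfiable at their conditions (and, optionally, to share a single
#' source).
#'
#' @param n,m Vertices and edges.
#' @param C Conditions.
#' @param k Demands.
#' @param seed Optional integer seed.
#' @param directed Directed edges?
#' @param single_source Force all demands to share one root?
#' @return A [csn_instance()] for which [is_monotonic()] holds.
#' @export
random_monotonic_instance <- function(n, m, C, k, seed = NULL,
                                      directed = TRUE,
                                      single_source = TRUE) {
  with_seed(seed, {
    verts <- sprintf("n%03d", seq_len(n))
    max_m <- if (directed) n * (n - 1L) else n * (n - 1L) / 2L
    stopifnot(m <= max_m)
    pairs <- expand.grid(from = verts, to = verts,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    if (!directed) pairs <- pairs[pairs$from < pairs$to, ]
    pick <- sample.int(nrow(pairs), m)
    edf <- pairs[pick, , drop = FALSE]
    edf$weight <- -log(stats::runif(m, 0.5, 0.99))
    edf$conditions <- lapply(sample.int(C, m, replace = TRUE),
                             function(b) seq.int(b, C))
    g <- condition_graph(edf, C, directed = directed, vertices = verts)
    frames <- lapply(seq_len(C), function(c) frame_at(g, c))
    reach <- lapply(frames, function(fr)
      is.finite(igraph::distances(fr, mode = "out")))
    demands <- NULL
    if (single_source) {
      # root with the widest reach in the final (largest) frame
      root <- verts[which.max(rowSums(reach[[C]]))]
      for (i in seq_len(k)) {
        ok <- FALSE
        for (tries in seq_len(200L)) {
          c <- sample.int(C, 1L)
          cand <- setdiff(verts[reach[[c]][root, ]], root)
          if (length(cand)) {
            demands <- rbind(demands, data.frame(
              source = root, target = sample(cand, 1L), condition = c,
              stringsAsFactors = FALSE))
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not sample a satisfiable demand from the root")
      }
    } else {
      for (i in seq_len(k)) {
        ok <- FALSE
        for (tries in seq_len(200L)) {
          c <- sample.int(C, 1L)
          hit <- which(reach[[c]] & !diag(n), arr.ind = TRUE)
          if (nrow(hit)) {
            row <- hit[sample.int(nrow(hit), 1L), ]
            demands <- rbind(demands, data.frame(
              source = verts[row[1L]], target = verts[row[2L]],
              condition = c, stringsAsFactors = FALSE))
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not sample a satisfiable demand")
      }
    }
    csn_instance(g, demands, variant = "edge",
                 check_demand_coverage = FALSE)
  })
}

#' Sample a small random CSN instance of any variant
#'
#' General-purpose fixture generator for testing: a random weighted graph
#' with random nonempty condition sets (edge variant) or random vertex
#' condition sets (node variants), and demands sampled to be satisfiable in
#' their frames.
#'
#' @param n,m Vertices and edges.
#' @param C Conditions.
#' @param k Demands.
#' @param directed Directed edges?
#' @param variant `"edge"`, `"node"` or `"node-and-edge"`.
#' @param seed Optional integer seed.
#' @return A [csn_instance()].
#' @export
random_csn_instance <- function(n, m, C, k, directed = FALSE,
                                variant = c("edge", "node",
                                            "node-and-edge"),
                                seed = NULL) {
  variant <- match.arg(variant)
  with_seed(seed, {
    verts <- sprintf("n%02d", seq_len(n))
    pairs <- expand.grid(from = verts, to = verts,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    if (!directed) pairs <- pairs[pairs$from < pairs$to, ]
    stopifnot(m <= nrow(pairs))
    edf <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    edf$weight <- round(stats::runif(m, 0.1, 1), 3)
    rand_subset <- function() {
      size <- sample.int(C, 1L)
      sort(sample.int(C, size))
    }
    tau <- NULL
    if (variant == "edge") {
      edf$conditions <- replicate(m, rand_subset(), simplify = FALSE)
    } else {
      tau <- stats::setNames(replicate(length(verts), rand_subset(),
                                       simplify = FALSE), verts)
      inter <- mapply(function(u, v) intersect(tau[[u]], tau[[v]]),
                      edf$from, edf$to, SIMPLIFY = FALSE)
      if (variant == "node") {
        edf$conditions <- inter
      } else {
        edf$conditions <- lapply(inter, function(s) {
          if (!length(s)) return(integer())
          sort(s[sample.int(length(s), sample.int(length(s), 1L))])
        })
      }
      keep <- lengths(edf$conditions) > 0L
      edf <- edf[keep, , drop = FALSE]
    }
    if (!nrow(edf)) stop("degenerate draw: no edges survived")
    g <- condition_graph(edf, C, directed = directed, vertices = verts)
    frames <- lapply(seq_len(C), function(c) frame_at(g, c))
    reach <- lapply(frames, function(fr)
      is.finite(igraph::distances(fr, mode = "out")))
    demands <- NULL
    for (i in seq_len(k)) {
      ok <- FALSE
      for (tries in seq_len(300L)) {
        c <- sample.int(C, 1L)
        hit <- which(reach[[c]] & !diag(n), arr.ind = TRUE)
        if (nrow(hit)) {
          row <- hit[sample.int(nrow(hit), 1L), ]
          demands <- rbind(demands, data.frame(
            source = verts[row[1L]], target = verts[row[2L]],
            condition = c, stringsAsFactors = FALSE))
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not sample a satisfiable demand")
    }
    csn_instance(g, demands, variant = variant, node_conditions = tau,
                 check_demand_coverage = FALSE)
  })
}
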