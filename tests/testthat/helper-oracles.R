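# Independent oracles used to validate the package's algorithms. These stay
# deliberately naive (full enumeration) and separate from the implementation
# paths they check.

# Exhaustive Priority Steiner Tree search over all edge subsets.
priority_brute <- function(inst, max_edges = 14) {
  E <- inst$edges
  m <- nrow(E)
  stopifnot(m <= max_edges)
  verts <- inst$vertices
  ok_path <- function(rows, a, b, p) {
    rows <- rows[E$priority[rows] <= p]
    s <- match(a, verts); t <- match(b, verts)
    if (!length(rows)) return(s == t)
    tl <- match(E$from[rows], verts); hd <- match(E$to[rows], verts)
    tl2 <- c(tl, hd); hd2 <- c(hd, tl)
    vis <- logical(length(verts))
    vis[s] <- TRUE; fr <- s
    while (length(fr)) {
      nxt <- unique(hd2[tl2 %in% fr]); nxt <- nxt[!vis[nxt]]
      vis[nxt] <- TRUE; fr <- nxt
    }
    vis[t]
  }
  best <- list(cost = Inf, rows = NULL)
  for (mask in 0:(2^m - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    cost <- sum(E$weight[rows])
    if (cost >= best$cost - 1e-12) next
    feas <- all(vapply(seq_len(nrow(inst$demands)), function(i) {
      ok_path(rows, inst$demands$source[i], inst$demands$target[i],
              inst$demands$priority[i])
    }, logical(1)))
    if (feas) best <- list(cost = cost, rows = rows)
  }
  best
}

# Closed-form exact optimum of the two-condition Label Cover gadget: every
# solution picks one strand per bundle, and a left path and right path share
# a contact edge exactly when they traverse the same agreeing
# (edge, left label, right label) combination; so the optimum is
# min over labelings of 2|E| - #satisfied edges.
lc_gadget_opt <- function(lc) {
  nu <- length(lc$left); nv <- length(lc$right); L <- lc$n_labels
  grid <- expand.grid(rep(list(seq_len(L)), nu + nv))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    phi_u <- lab[seq_len(nu)]; phi_v <- lab[nu + seq_len(nv)]
    sat <- 0L
    for (e in seq_len(nrow(lc$edges))) {
      iu <- match(lc$edges$u[e], lc$left)
      iv <- match(lc$edges$v[e], lc$right)
      pr <- lc$projections[[e]]
      if (pr$u[phi_u[iu]] == pr$v[phi_v[iv]]) sat <- sat + 1L
    }
    best <- min(best, 2L * nrow(lc$edges) - sat)
  }
  best
}

# Shortest distance between two vertices in one frame by enumerating all
# simple paths (independent of the igraph-based closure).
enumerate_shortest <- function(graph, from, to, condition) {
  fr <- frame_at(graph, condition)
  w <- igraph::E(fr)$weight
  paths <- igraph::all_simple_paths(fr, from, to,
                                    mode = if (graph$directed) "out"
                                           else "all")
  if (!length(paths)) return(Inf)
  min(vapply(paths, function(p) {
    ids <- igraph::get_edge_ids(fr, rep(names(p), each = 2)[-c(1,
             2 * length(p))])
    sum(w[ids])
  }, numeric(1)))
}

# --- random instance samplers for the reduction tests ----------------------

random_lc <- function(nU, nV, nE, L, ncolors, seed, satisfiable = TRUE) {
  set.seed(seed)
  U <- sprintf("u%d", seq_len(nU)); V <- sprintf("v%d", seq_len(nV))
  repeat {
    eu <- sample(U, nE, replace = TRUE)
    ev <- sample(V, nE, replace = TRUE)
    if (!anyDuplicated(paste(eu, ev))) break
  }
  star_u <- sample.int(L, nU, replace = TRUE)
  star_v <- sample.int(L, nV, replace = TRUE)
  proj <- lapply(seq_len(nE), function(e) {
    pu <- sample.int(ncolors, L, replace = TRUE)
    pv <- sample.int(ncolors, L, replace = TRUE)
    if (satisfiable) {
      pv[star_v[match(ev[e], V)]] <- pu[star_u[match(eu[e], U)]]
    }
    list(u = pu, v = pv)
  })
  label_cover_instance(U, V, data.frame(u = eu, v = ev), L, proj)
}

random_phlc <- function(part_size, nE, L, ncolors, k, seed,
                        strongly_satisfiable = TRUE) {
  set.seed(seed)
  parts <- lapply(seq_len(k),
                  function(c) sprintf("w%d_%d", c, seq_len(part_size)))
  he <- lapply(seq_len(nE),
               function(e) vapply(parts, function(p) sample(p, 1), ""))
  star <- lapply(parts,
                 function(p) sample.int(L, length(p), replace = TRUE))
  proj <- lapply(seq_len(nE), function(e) {
    ps <- lapply(seq_len(k),
                 function(c) sample.int(ncolors, L, replace = TRUE))
    if (strongly_satisfiable) {
      col <- sample.int(ncolors, 1)
      for (c in seq_len(k)) {
        i <- match(he[[e]][c], parts[[c]])
        ps[[c]][star[[c]][i]] <- col
      }
    }
    ps
  })
  suppressWarnings(kphlc_instance(parts, he, L, proj))
}

# Undirected instance whose demands form a condition shortest-path problem:
# one (a, b, c) demand per condition for a pair connected in every frame.
random_csp_instance <- function(n, m, C, seed) {
  set.seed(seed)
  repeat {
    inst <- try(random_csn_instance(n, m, C, 1, directed = FALSE,
                                    seed = sample.int(1e6, 1)),
                silent = TRUE)
    if (inherits(inst, "try-error")) next
    g <- inst$graph
    reach <- lapply(seq_len(C), function(c) {
      is.finite(igraph::distances(frame_at(g, c)))
    })
    allr <- Reduce(`&`, reach)
    diag(allr) <- FALSE
    hit <- which(allr, arr.ind = TRUE)
    if (!nrow(hit)) next
    row <- hit[sample.int(nrow(hit), 1), ]
    dem <- data.frame(source = g$vertices[row[1]],
                      target = g$vertices[row[2]],
                      condition = seq_len(C), stringsAsFactors = FALSE)
    return(csn_instance(g, dem))
  }
}

# Monotonic undirected CST instance with terminals sampled within one
# component of each frame (so the instance is feasible).
random_mono_cst <- function(n, m, C, seed) {
  inst <- random_monotonic_instance(n, m, C, 1, seed = seed,
                                    directed = FALSE,
                                    single_source = FALSE)
  set.seed(seed + 1000L)
  g <- inst$graph
  ts <- lapply(seq_len(C), function(c) {
    comp <- igraph::components(frame_at(g, c))
    big <- names(comp$membership)[comp$membership ==
                                    which.max(comp$csize)]
    sort(sample(big, min(length(big), sample(2:3, 1))))
  })
  cst_instance(g, ts)
}

random_priority_instance <- function(n, m, P, k, seed) {
  set.seed(seed)
  verts <- sprintf("p%02d", seq_len(n))
  from <- sample(verts, m, replace = TRUE)
  to <- sample(verts, m, replace = TRUE)
  ok <- from != to
  from <- from[ok]; to <- to[ok]
  edges <- data.frame(from, to,
                      weight = round(stats::runif(length(from), .1, 1), 3),
                      priority = sample.int(P, length(from),
                                            replace = TRUE),
                      stringsAsFactors = FALSE)
  dem <- NULL
  for (i in seq_len(k)) {
    repeat {
      p <- sample.int(P, 1)
      sub <- edges[edges$priority <= p, , drop = FALSE]
      if (!nrow(sub)) next
      comp <- igraph::components(
        igraph::graph_from_data_frame(sub[, 1:2], directed = FALSE))
      big <- names(comp$membership)[comp$membership ==
                                      which.max(comp$csize)]
      if (length(big) >= 2) {
        ab <- sample(big, 2)
        dem <- rbind(dem, data.frame(source = ab[1], target = ab[2],
                                     priority = p,
                                     stringsAsFactors = FALSE))
        break
      }
    }
  }
  priority_steiner_instance(edges, dem)
}

# Embed an edge-variant instance as node-and-edge (test helper only):
# every vertex present everywhere, edge condition sets unchanged.
as_node_and_edge <- function(instance) {
  g <- instance$graph
  tau <- stats::setNames(rep(list(seq_len(g$n_conditions)),
                             length(g$vertices)), g$vertices)
  csn_instance(g, instance$demands, variant = "node-and-edge",
               node_conditions = tau, check_demand_coverage = FALSE)
}
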