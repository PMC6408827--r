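test_that("the worked toy has optimum one and the documented shape", {
  inst <- example1()
  expect_equal(inst$graph$n_conditions, 2L)
  expect_equal(inst$demands$condition, 1:2)
  expect_equal(brute_force_opt(inst)$cost, 1)
  expect_true(igraph::is_dag(csnet:::cg_igraph(inst$graph)))
  # exactly three contact edges: two merged, one right-only
  contacts <- inst$graph$edges$weight == 1
  expect_equal(sum(contacts), 3L)
  merged <- lengths(inst$graph$exists_at[contacts]) == 2L
  expect_equal(sum(merged), 2L)
})

test_that("gadget optima equal the labeling optimum on satisfiable instances", {
  for (seed in 1:6) {
    lc <- random_lc(2, 2, 3, 3, 3, seed, satisfiable = TRUE)
    inst <- label_cover_to_2dcsn(lc)
    sol <- solve_csn(inst)
    expect_equal(sol$cost, 3)               # |E| = 3, totally satisfiable
    expect_equal(sol$cost, lc_gadget_opt(lc))
  }
})

test_that("unsatisfiable edges push the gadget optimum above |E|", {
  hits <- 0L
  for (seed in 1:6) {
    lc <- random_lc(2, 2, 3, 2, 4, seed + 100, satisfiable = FALSE)
    opt <- solve_csn(label_cover_to_2dcsn(lc))$cost
    expect_equal(opt, lc_gadget_opt(lc))
    expect_gte(opt, 3)
    if (opt > 3) hits <- hits + 1L
  }
  expect_gt(hits, 0L)   # random colorings do leave edges unsatisfied
  # a single edge with no agreeing pair costs one contact per condition
  lc0 <- label_cover_instance(
    "u", "v", data.frame(u = "u", v = "v"), 2,
    list(list(u = c(1L, 1L), v = c(2L, 2L))))
  expect_equal(solve_csn(label_cover_to_2dcsn(lc0))$cost, 2)
  expect_equal(brute_force_opt(label_cover_to_2dcsn(lc0),
                               edge_budget = 30)$cost, 2)
})

test_that("gadget graphs are acyclic when side orders align", {
  # chains with a single left vertex cannot produce crossing contacts
  for (seed in 1:4) {
    lc <- random_lc(1, 3, 3, 2, 2, seed + 20, satisfiable = TRUE)
    expect_true(igraph::is_dag(
      csnet:::cg_igraph(label_cover_to_2dcsn(lc)$graph)))
  }
})

test_that("the hypergraph gadget generalizes the two-condition one", {
  # k = 2: the two constructions coincide up to vertex naming
  lc <- label_cover_instance(
    c("u1", "u2"), "v1",
    data.frame(u = c("u1", "u2"), v = c("v1", "v1")), 2,
    list(list(u = c(1L, 2L), v = c(1L, 2L)),
         list(u = c(2L, 1L), v = c(2L, 1L))))
  ph <- suppressWarnings(kphlc_instance(
    list(c("u1", "u2"), "v1"),
    list(c("u1", "v1"), c("u2", "v1")), 2,
    list(list(c(1L, 2L), c(1L, 2L)), list(c(2L, 1L), c(2L, 1L)))))
  a <- solve_csn(label_cover_to_2dcsn(lc))
  b <- suppressWarnings(solve_csn(kphlc_to_dcsn(ph)))
  expect_equal(a$cost, b$cost)
})

test_that("strongly satisfiable hypergraph instances cost one contact per edge", {
  for (seed in 1:4) {
    ph <- random_phlc(2, 2, 2, 2, 3, seed, strongly_satisfiable = TRUE)
    inst <- kphlc_to_dcsn(ph)
    expect_equal(solve_csn(inst)$cost, 2)   # |E| = 2
    expect_equal(inst$graph$n_conditions, 3L)
  }
})

test_that("with no agreeing tuple every condition pays its own contact", {
  ph <- random_phlc(1, 1, 1, 3, 3, 1, strongly_satisfiable = FALSE)
  ph$projections[[1]] <- list(1L, 2L, 3L)   # pairwise disagreeing colors
  expect_equal(solve_csn(kphlc_to_dcsn(ph))$cost, 3)   # k * |E|
})

test_that("the worst-case star has the advertised costs", {
  inst <- star_worst_case(5, 10, 0.01)
  g <- inst$graph
  expect_equal(sum(g$edges$weight[g$edges$from == "root" &
                                    g$edges$to != "hub"]), 5 * 9.99)
  expect_equal(nrow(inst$demands), 5L)
  expect_error(star_worst_case(3, 1, 2), "eps")
})

test_that("the PPI-style sampler respects its inclusion rules", {
  # p = 1: every vertex exists at every condition
  inst <- random_single_source_instance(30, 120, 3, 2, p = 1, seed = 5)
  expect_true(all(lengths(inst$node_conditions) == 2L))
  expect_equal(nrow(inst$demands), 6L)
  expect_equal(length(unique(inst$demands$source)), 1L)
  # p = 0, beta = 1: each condition keeps only one shortest root-target
  # path's vertices, so the per-condition optimum is that path's weight,
  # which equals the shortest distance within the frame
  inst0 <- random_single_source_instance(30, 120, 1, 2, p = 0, seed = 7)
  red <- to_edge_variant(inst0)
  for (c in 1:2) {
    d <- inst0$demands[inst0$demands$condition == c, ]
    fr <- frame_at(red$instance$graph, c)
    dist_c <- igraph::distances(fr, d$source, d$target, mode = "out")[1]
    sub <- csn_instance(red$instance$graph, d,
                        check_demand_coverage = FALSE)
    expect_equal(solve_csn(sub)$cost, dist_c, tolerance = 1e-6)
  }
  expect_true(isTRUE(is_feasible(solve_csn(inst0), inst0)))
  # too few reachable vertices is a clear error
  expect_error(random_single_source_instance(5, 4, 10, 1, 0.5, seed = 1),
               "reachable")
})

test_that("monotonic fixtures are monotonic with satisfiable demands", {
  for (seed in 1:5) {
    inst <- random_monotonic_instance(7, 12, 3, 4, seed = seed)
    expect_true(is_monotonic(inst$graph))
    expect_equal(length(unique(inst$demands$source)), 1L)
    full <- solution(inst$graph, inst$graph$edges[, c("from", "to")])
    for (i in seq_len(nrow(inst$demands))) {
      expect_true(isTRUE(satisfies(full, inst$demands[i, ], inst$graph)))
    }
  }
  # a single condition gives a classic Steiner network instance
  inst1 <- random_monotonic_instance(6, 10, 1, 2, seed = 9)
  expect_equal(inst1$graph$n_conditions, 1L)
  expect_true(is_monotonic(inst1$graph))
})

test_that("generators are pure functions of parameters and seed", {
  a <- random_single_source_instance(25, 80, 2, 2, 0.3, seed = 11)
  b <- random_single_source_instance(25, 80, 2, 2, 0.3, seed = 11)
  expect_identical(a, b)
  c1 <- random_monotonic_instance(6, 10, 3, 3, seed = 2)
  c2 <- random_monotonic_instance(6, 10, 3, 3, seed = 2)
  expect_identical(c1, c2)
  # and they do not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(random_monotonic_instance(6, 10, 2, 2,
                                                     seed = 4))
  x2 <- runif(1)
  expect_identical(x1, x2)
})
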