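test_that("the shortest-path reduction adds one condition and relay per demand", {
  inst <- small_instance(3, directed = TRUE, variant = "edge")
  k <- nrow(inst$demands)
  red <- csn_to_csp(inst)
  out <- red$instance
  expect_equal(out$graph$n_conditions, k)
  expect_equal(length(out$graph$vertices),
               length(inst$graph$vertices) + 2L + 2L * k)
  zero_gadget <- out$graph$edges$weight == 0 &
    (out$graph$edges$from %in% c("SRC", "SNK") |
       out$graph$edges$to %in% c("SRC", "SNK") |
       grepl("^[xy][0-9]+$", out$graph$edges$from) |
       grepl("^[xy][0-9]+$", out$graph$edges$to))
  expect_equal(sum(zero_gadget), 4L * k)
  expect_equal(out$demands$source, rep("SRC", k))
  expect_equal(out$demands$target, rep("SNK", k))
})

test_that("a single demand's shortest-path reduction optimum is the shortest path", {
  edf <- data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                    weight = c(1, 1, 3), conditions = "1")
  g <- condition_graph(edf, 1, directed = TRUE)
  inst <- csn_instance(g, data.frame(source = "a", target = "c",
                                     condition = 1))
  red <- csn_to_csp(inst)
  expect_equal(brute_force_opt(red$instance)$cost, 2)
})

test_that("the shortest-path reduction preserves the optimum and lifts", {
  for (seed in 1:10) {
    inst <- small_instance(seed)
    red <- csn_to_csp(inst)
    opt_src <- brute_force_opt(inst)
    opt_tgt <- brute_force_opt(red$instance, edge_budget = 30)
    expect_equal(opt_src$cost, opt_tgt$cost, tolerance = 1e-9)
    lifted <- red$lift(opt_tgt)
    expect_true(isTRUE(is_feasible(lifted, inst)))
    expect_equal(lifted$cost, opt_tgt$cost, tolerance = 1e-9)
  }
})

test_that("shortest-path to Steiner-tree keeps graphs and pins terminals", {
  csp <- random_csp_instance(6, 10, 2, 1)
  red <- csp_to_cst(csp)
  cst <- red$instance
  a <- unique(csp$demands$source); b <- unique(csp$demands$target)
  expect_equal(cst$terminal_sets,
               rep(list(sort(c(a, b))), 2))
  expect_equal(cst$graph$edges, csp$graph$edges)
  # directed input is rejected: the tree problem is undirected
  dinst <- small_instance(4, directed = TRUE, variant = "edge")
  expect_error(csp_to_cst(dinst), "undirected|unsupported")
})

test_that("shortest-path and Steiner-tree optima coincide with feasible lifts", {
  for (seed in 1:8) {
    csp <- random_csp_instance(6, 10, 2, seed)
    red <- csp_to_cst(csp)
    opt_src <- brute_force_opt(csp)
    opt_tgt <- brute_force_tree_opt(red$instance)
    expect_equal(opt_src$cost, opt_tgt$cost, tolerance = 1e-9)
    lifted <- red$lift(opt_tgt)
    expect_true(isTRUE(is_feasible(lifted, csp)))
    expect_equal(lifted$cost, opt_tgt$cost, tolerance = 1e-9)
  }
})

test_that("prize-collecting penalties are infinite exactly on terminals", {
  cst <- random_mono_cst(6, 9, 3, 2)
  red <- cst_to_cpcst(cst)
  pen <- red$instance$penalty
  for (c in 1:3) {
    on <- rownames(pen) %in% cst$terminal_sets[[c]]
    expect_true(all(is.infinite(pen[on, c])))
    expect_true(all(pen[!on, c] == 0))
  }
})

test_that("finite prize-collecting optima span every terminal set", {
  for (seed in 1:8) {
    cst <- random_mono_cst(6, 10, 2, seed)
    red <- cst_to_cpcst(cst)
    opt_pc <- brute_force_tree_opt(red$instance)
    if (is.finite(attr(opt_pc, "objective"))) {
      expect_true(all(unlist(cst$terminal_sets) %in%
                        attr(opt_pc, "tree_vertices")))
    }
  }
  # with one condition the two objectives coincide exactly
  for (seed in 1:8) {
    cst <- random_mono_cst(6, 10, 1, seed + 50)
    red <- cst_to_cpcst(cst)
    expect_equal(attr(brute_force_tree_opt(red$instance), "objective"),
                 brute_force_tree_opt(cst)$cost, tolerance = 1e-9)
  }
})

test_that("with several conditions either objective can be the smaller", {
  # The underlying-graph tree may use an edge absent at the terminals'
  # condition: X at both conditions is {a, b}; condition 1 only offers the
  # path a-x-b (cost 2) and condition 2 only the direct edge (0.5), so a
  # condition-respecting subgraph pays 2.5 while the tree pays 0.5.
  edf <- data.frame(from = c("a", "x", "a"), to = c("x", "b", "b"),
                    weight = c(1, 1, 0.5),
                    conditions = c("1", "1", "2"))
  g <- condition_graph(edf, 2)
  cst <- cst_instance(g, list(c("a", "b"), c("a", "b")))
  expect_equal(brute_force_tree_opt(cst)$cost, 2.5)
  expect_equal(attr(brute_force_tree_opt(cst_to_cpcst(cst)$instance),
                    "objective"), 0.5)
  # Conversely, terminal sets of different conditions may live in separate
  # components of a Steiner solution, while the single tree must bridge
  # them through an expensive connector.
  edf2 <- data.frame(from = c("a", "c", "b"), to = c("b", "d", "c"),
                     weight = c(0.1, 0.1, 5),
                     conditions = c("1,2", "1,2", "1,2"))
  g2 <- condition_graph(edf2, 2)
  cst2 <- cst_instance(g2, list(c("a", "b"), c("c", "d")))
  expect_equal(brute_force_tree_opt(cst2)$cost, 0.2)
  expect_equal(attr(brute_force_tree_opt(cst_to_cpcst(cst2)$instance),
                    "objective"), 5.2)
})

test_that("monotonic instances translate to priority levels and back", {
  edf <- data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1:2,
                    conditions = c("2,3", "1,2,3"))
  g <- condition_graph(edf, 3)
  inst <- csn_instance(g, data.frame(source = "a", target = "c",
                                     condition = 3),
                       check_demand_coverage = FALSE)
  red <- monotonic_csn_to_priority(inst)
  expect_equal(red$instance$edges$priority, c(2L, 1L))
  expect_equal(red$instance$demands$priority, 3L)
  # non-monotonic input is refused
  expect_error(monotonic_csn_to_priority(
    csn_instance(toy_graph(),
                 data.frame(source = "a", target = "c", condition = 2),
                 check_demand_coverage = FALSE)),
    "monotonic")
})

test_that("multiedges split into two half-weight edges at a midpoint", {
  edges <- data.frame(from = c("u", "u", "u"), to = c("v", "v", "w"),
                      weight = c(4, 6, 1), priority = c(1L, 2L, 1L))
  dem <- data.frame(source = "u", target = "v", priority = 2L)
  pinst <- priority_steiner_instance(edges, dem)
  red <- priority_to_monotonic_csn(pinst)
  out <- red$instance$graph
  expect_equal(sort(out$edges$weight), c(1, 2, 2, 3, 3))
  mids <- setdiff(out$vertices, pinst$vertices)
  expect_length(mids, 2)
  # halves inherit the original priority as their birth condition
  expect_true(is_monotonic(out))
  # a simple graph passes through unsplit
  simple <- priority_steiner_instance(edges[c(1, 3), ], dem)
  expect_equal(nrow(priority_to_monotonic_csn(simple)$instance$graph$edges),
               2L)
})

test_that("priority Steiner and monotonic CSN optima coincide both ways", {
  for (seed in 1:8) {
    pinst <- random_priority_instance(5, 8, 3, 2, seed)
    red <- priority_to_monotonic_csn(pinst)
    opt_p <- priority_brute(pinst)
    opt_c <- brute_force_opt(red$instance, edge_budget = 26)
    expect_equal(opt_p$cost, opt_c$cost, tolerance = 1e-9)
    lifted_rows <- red$lift(opt_c)
    expect_equal(sum(pinst$edges$weight[lifted_rows]), opt_c$cost,
                 tolerance = 1e-9)
  }
  for (seed in 1:8) {
    inst <- random_monotonic_instance(6, 10, 3, 3, seed = seed,
                                      directed = FALSE,
                                      single_source = FALSE)
    red <- monotonic_csn_to_priority(inst)
    opt_p <- priority_brute(red$instance)
    opt_c <- brute_force_opt(inst)
    expect_equal(opt_p$cost, opt_c$cost, tolerance = 1e-9)
    lifted <- red$lift(opt_p$rows)
    expect_true(isTRUE(is_feasible(lifted, inst)))
    expect_equal(lifted$cost, opt_p$cost, tolerance = 1e-9)
  }
})

test_that("terminal sets become anchored demands for monotonic Steiner tree", {
  edf <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                    weight = 1, conditions = "1")
  g <- condition_graph(edf, 1)
  cst <- cst_instance(g, list(c("d", "a", "b")))
  red <- monotonic_cst_to_csn(cst)
  expect_equal(red$instance$demands,
               data.frame(source = "a", target = c("b", "d"),
                          condition = 1L, stringsAsFactors = FALSE))
  # singleton terminal sets produce no demand for that condition
  g2 <- condition_graph(data.frame(from = "a", to = "b", weight = 1,
                                   conditions = "1,2"), 2)
  cst2 <- cst_instance(g2, list(c("a", "b"), "a"))
  expect_equal(nrow(monotonic_cst_to_csn(cst2)$instance$demands), 1L)
})

test_that("monotonic Steiner-tree and CSN optima coincide", {
  for (seed in 1:8) {
    cst <- random_mono_cst(6, 10, 2, seed)
    red <- monotonic_cst_to_csn(cst)
    opt_src <- brute_force_tree_opt(cst)
    opt_tgt <- brute_force_opt(red$instance)
    expect_equal(opt_src$cost, opt_tgt$cost, tolerance = 1e-9)
    lifted <- red$lift(opt_tgt)
    expect_equal(lifted$cost, opt_tgt$cost, tolerance = 1e-9)
  }
})

test_that("the layered construction has the expected shape", {
  inst <- random_monotonic_instance(4, 6, 3, 2, seed = 5)
  red <- monotonic_ssdcsn_to_dst(inst)
  g2 <- red$instance$graph
  ck <- max(inst$demands$condition)
  expect_equal(length(g2$vertices), 4L * ck)
  vertical <- g2$edges$weight == 0 &
    sub("#.*", "", g2$edges$from) == sub("#.*", "", g2$edges$to)
  expect_equal(sum(vertical), 4L * (ck - 1L))
  # demand (a, b, c) becomes (a#1, b#c)
  expect_true(all(grepl("#001$", red$instance$demands$source)))
  expect_equal(sub(".*#0*", "", red$instance$demands$target),
               as.character(sort(inst$demands$condition)))
  # preconditions
  und <- random_monotonic_instance(4, 5, 2, 2, seed = 1, directed = FALSE)
  expect_error(monotonic_ssdcsn_to_dst(und), "directed")
})

test_that("layered optimum equals the original optimum and lifting is lossless", {
  for (seed in 1:10) {
    inst <- random_monotonic_instance(6, 11, 3, 3, seed = seed)
    red <- monotonic_ssdcsn_to_dst(inst)
    opt_src <- brute_force_opt(inst)
    opt_tgt <- brute_force_opt(red$instance, edge_budget = 40)
    expect_equal(opt_src$cost, opt_tgt$cost, tolerance = 1e-9)
    lifted <- red$lift(opt_tgt)
    expect_true(isTRUE(is_feasible(lifted, inst)))
    expect_equal(lifted$cost, opt_tgt$cost, tolerance = 1e-9)
  }
})

test_that("projection pays shared underlying edges once", {
  # a tree using the same underlying edge at two levels projects to a
  # strictly cheaper solution
  edf <- data.frame(from = "a", to = "b", weight = 2, conditions = "1,2")
  g <- condition_graph(edf, 2, directed = TRUE)
  inst <- csn_instance(g, data.frame(source = "a", target = "b",
                                     condition = 1:2))
  red <- monotonic_ssdcsn_to_dst(inst)
  g2 <- red$instance$graph
  both_levels <- solution(
    g2, data.frame(from = c("a#001", "a#002"), to = c("b#001", "b#002")))
  expect_equal(both_levels$cost, 4)
  lifted <- lift_dst_solution(both_levels, inst)
  expect_equal(lifted$cost, 2)
  # an infeasible tree is rejected
  empty <- solution(g2, NULL)
  expect_error(lift_dst_solution(empty, inst), "feasible")
})
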