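# Flow-based integer linear program for Single-Source DCSN, plus the routing
# pipeline that brings every CSN/DCSN instance into that form.
#
# For each underlying edge a binary selection variable d_uv records whether
# the edge enters the solution; for each edge-condition pair with e in E_c a
# continuous flow variable d_uvc in [0, k_c] carries flow at condition c,
# where k_c is the number of demands at c. Constraints: d_uvc <= k_c * d_uv
# (an edge used at any condition must be selected; the k_c factor is needed
# because k_c units leave the source), and per (vertex, condition) flow
# conservation inflow - outflow = delta_vc with delta = +(number of demands
# targeting v at c), -k_c at the source, 0 otherwise. Objective: minimize
# sum w(e) d_e. Flows may stay continuous: a feasible fractional flow on the
# selected subgraph certifies the demanded paths exist, so only the
# selection variables are integer.

#' Build the single-source flow ILP for a directed CSN instance
#'
#' @param instance A directed [csn_instance()] whose demands all share one
#'   source vertex (use [solve_csn()] for anything else; it routes through
#'   the shortest-path reduction first). Node variants are converted
#'   internally.
#' @return An object of class `ilp_model`: variable tables (`groups` for
#'   binaries, `flows` for edge-condition flow variables), sparse constraint
#'   triplets, bounds, objective, the per-condition demand counts `k_c` and
#'   right-hand sides `delta`.
#' @export
build_flow_program <- function(instance) {
  stopifnot(inherits(instance, "csn_instance"))
  ei <- to_edge_variant(instance)$instance
  if (!ei$graph$directed) {
    stop("build_flow_program expects a directed instance; ",
         "solve_csn() handles undirected input")
  }
  if (is.null(single_source_of(ei$demands))) {
    stop("demands have multiple sources; use solve_csn(), which applies ",
         "the shortest-path reduction first")
  }
  g <- ei$graph
  arcs <- data.frame(row = seq_len(n_edges(g)), group = seq_len(n_edges(g)))
  flow_model(g, arcs, group_weight = g$edges$weight,
             output_edges = g$edges[, c("from", "to")],
             demands = ei$demands, graph_out = g)
}

# Workhorse shared by build_flow_program (directed: one arc per edge) and
# solve_csn (undirected: two anti-parallel arcs share one selection
# variable, weight charged once).
flow_model <- function(g, arcs, group_weight, output_edges, demands,
                       graph_out, arc_from = NULL, arc_to = NULL) {
  if (is.null(arc_from)) {
    arc_from <- g$edges$from[arcs$row]
    arc_to <- g$edges$to[arcs$row]
  }
  source <- single_source_of(demands)
  stopifnot(!is.null(source))
  kc <- table(factor(demands$condition, levels = seq_len(g$n_conditions)))
  active <- which(kc > 0L)

  n_groups <- if (nrow(arcs)) max(arcs$group) else 0L
  # flow variables: one per (arc, active condition with the arc present)
  fl_arc <- integer(); fl_cond <- integer()
  for (c in active) {
    present <- which(vapply(g$exists_at[arcs$row],
                            function(s) c %in% s, logical(1)))
    fl_arc <- c(fl_arc, present)
    fl_cond <- c(fl_cond, rep.int(c, length(present)))
  }
  n_flows <- length(fl_arc)
  fvar <- n_groups + seq_len(n_flows)

  # delta_vc: +count for targets, -k_c at the source
  delta <- stats::aggregate(
    count ~ target + condition,
    data = transform(demands, count = 1L), FUN = sum)

  rows <- list(r = integer(), c = integer(), v = numeric())
  push <- function(r, c, v) {
    rows$r <<- c(rows$r, r); rows$c <<- c(rows$c, c); rows$v <<- c(rows$v, v)
  }
  row_lb <- numeric(); row_ub <- numeric()
  new_row <- function(lb, ub) {
    row_lb <<- c(row_lb, lb); row_ub <<- c(row_ub, ub)
    length(row_lb)
  }

  # linking: d_uvc - k_c d_uv <= 0
  for (j in seq_len(n_flows)) {
    r <- new_row(-Inf, 0)
    push(r, fvar[j], 1)
    push(r, arcs$group[fl_arc[j]], -as.numeric(kc[fl_cond[j]]))
  }

  # conservation per (vertex, active condition)
  for (c in active) {
    idx <- which(fl_cond == c)
    verts <- unique(c(arc_from[fl_arc[idx]], arc_to[fl_arc[idx]],
                      source,
                      delta$target[delta$condition == c]))
    for (v in verts) {
      d <- 0
      if (v == source) {
        d <- -as.numeric(kc[c])
      } else {
        hit <- delta$target == v & delta$condition == c
        if (any(hit)) d <- sum(delta$count[hit])
      }
      r <- new_row(d, d)
      inn <- idx[arc_to[fl_arc[idx]] == v]
      out <- idx[arc_from[fl_arc[idx]] == v]
      if (length(inn)) push(rep.int(r, length(inn)), fvar[inn],
                            rep.int(1, length(inn)))
      if (length(out)) push(rep.int(r, length(out)), fvar[out],
                            rep.int(-1, length(out)))
    }
  }

  n <- n_groups + n_flows
  structure(list(
    n = n,
    obj = c(group_weight, numeric(n_flows)),
    lb = numeric(n),
    ub = c(rep(1, n_groups), as.numeric(kc[fl_cond])),
    integrality = c(rep(1L, n_groups), rep(0L, n_flows)),
    a_row = rows$r, a_col = rows$c, a_val = rows$v,
    n_rows = length(row_lb), row_lb = row_lb, row_ub = row_ub,
    groups = data.frame(output_edges, weight = group_weight,
                        stringsAsFactors = FALSE),
    flows = data.frame(arc = fl_arc, condition = fl_cond,
                       from = arc_from[fl_arc], to = arc_to[fl_arc]),
    arcs = arcs,
    k_c = as.numeric(kc), delta = delta,
    graph = graph_out),
    class = "ilp_model")
}

#' @export
print.ilp_model <- function(x, ...) {
  cat(sprintf(paste0("<ilp_model> %d binary selection vars, %d flow vars, ",
                     "%d constraints\n"),
              nrow(x$groups), nrow(x$flows), x$n_rows))
  invisible(x)
}

find_python <- function() {
  p <- getOption("csnet.python")
  if (!is.null(p)) return(p)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(path)
  }
  stop("no python interpreter found for the HiGHS backend; install one or ",
       "set options(csnet.python = ...)")
}

#' Solve an ILP model with the HiGHS backend
#'
#' The model is serialized to JSON and handed to HiGHS (through scipy's
#' mixed-integer interface, run in a `python` subprocess); HiGHS runs
#' single-threaded and deterministically, so repeated solves of one model
#' agree. Edges selected by the optimizer but carrying zero flow at every
#' condition are pruned before the solution is costed.
#'
#' @param model An `ilp_model` from [build_flow_program()].
#' @param time_limit Seconds before the solver gives up (status is then
#'   surfaced as `"timeout"`/`"feasible"`, never silently truncated).
#' @return A list with `status` (`"optimal"`, `"feasible"`, `"infeasible"`
#'   or `"timeout"`), `objective`, and on success `solution`, a [solution()]
#'   over the model's output graph.
#' @export
solve_model <- function(model, time_limit = 600) {
  stopifnot(inherits(model, "ilp_model"))
  py <- find_python()
  script <- system.file("python", "milp.py", package = "csnet",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  payload <- model[c("n", "obj", "lb", "ub", "integrality", "a_row",
                     "a_col", "a_val", "n_rows", "row_lb", "row_ub")]
  for (nm in c("obj", "lb", "ub", "integrality", "a_row", "a_col",
               "a_val")) {
    payload[[nm]] <- I(payload[[nm]])   # keep length-1 vectors as arrays
  }
  payload$time_limit <- time_limit
  # JSON has no Inf; encode as nulls, the backend restores them
  payload$row_lb <- lapply(payload$row_lb,
                           function(v) if (is.finite(v)) v else NULL)
  payload$row_ub <- lapply(payload$row_ub,
                           function(v) if (is.finite(v)) v else NULL)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(py, c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("MILP backend failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  st <- res$status
  if (st == "timeout" && !is.null(res$x)) st <- "feasible"
  out <- list(status = st, objective = res$objective %||% NA_real_,
              message = res$message)
  if (!is.null(res$x) && st %in% c("optimal", "feasible")) {
    x <- res$x
    ng <- nrow(model$groups)
    sel <- which(x[seq_len(ng)] > 0.5)
    flow <- x[ng + seq_len(nrow(model$flows))]
    used_arcs <- unique(model$flows$arc[flow > 1e-6])
    used_groups <- intersect(sel, unique(model$arcs$group[used_arcs]))
    out$solution <- solution(
      model$graph, model$groups[used_groups, c("from", "to"), drop = FALSE])
    out$objective <- sum(model$groups$weight[used_groups])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve any CSN/DCSN instance to optimality
#'
#' Full exact pipeline: the instance is converted to the edge variant;
#' demands are pre-checked for reachability in their frames (the first
#' unsatisfiable demand is named in an error of class `csnet_infeasible`);
#' multi-source instances are routed through the shortest-path reduction
#' [csn_to_csp()] so all flow leaves one root; undirected edges become two
#' anti-parallel arcs gated by a single selection variable whose weight is
#' charged once; the flow program is then built and solved with
#' [solve_model()] and the solution is lifted back through every
#' transformation, with witness paths on the original instance.
#'
#' @param instance A [csn_instance()] (any variant, directed or not).
#' @param time_limit Seconds allowed for the MILP solve.
#' @return An optimal [solution()] of `instance`, with attribute
#'   `"status"` (`"optimal"`).
#' @export
solve_csn <- function(instance, time_limit = 600) {
  stopifnot(inherits(instance, "csn_instance"))
  red0 <- to_edge_variant(instance)
  ei <- red0$instance

  # name the first structurally unsatisfiable demand up front
  full <- solution(ei$graph, ei$graph$edges[, c("from", "to")])
  for (i in seq_len(nrow(ei$demands))) {
    d <- ei$demands[i, ]
    if (!isTRUE(satisfies(full, d, ei$graph))) {
      stop(infeasible_error(d))
    }
  }

  if (!is.null(single_source_of(ei$demands))) {
    ssi <- ei
    lift1 <- function(sol) sol
  } else {
    red1 <- csn_to_csp(ei)
    ssi <- red1$instance
    lift1 <- red1$lift
  }

  g <- ssi$graph
  if (g$directed) {
    arcs <- data.frame(row = seq_len(n_edges(g)),
                       group = seq_len(n_edges(g)))
    model <- flow_model(g, arcs, group_weight = g$edges$weight,
                        output_edges = g$edges[, c("from", "to")],
                        demands = ssi$demands, graph_out = g)
  } else {
    m <- n_edges(g)
    arcs <- data.frame(row = c(seq_len(m), seq_len(m)),
                       group = c(seq_len(m), seq_len(m)))
    arc_from <- c(g$edges$from, g$edges$to)
    arc_to <- c(g$edges$to, g$edges$from)
    model <- flow_model(g, arcs, group_weight = g$edges$weight,
                        output_edges = g$edges[, c("from", "to")],
                        demands = ssi$demands, graph_out = g,
                        arc_from = arc_from, arc_to = arc_to)
  }

  res <- solve_model(model, time_limit = time_limit)
  if (res$status == "infeasible") {
    stop(infeasible_error(message = "MILP reported infeasibility"))
  }
  if (res$status != "optimal") {
    stop("MILP solve did not reach proven optimality (status: ",
         res$status, "); raise time_limit")
  }
  sol <- red0$lift(lift1(res$solution))
  sol <- add_witnesses(sol, instance)
  attr(sol, "status") <- "optimal"
  sol
}
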