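# File formats: condition-graph and demand TSV, solution JSON, SIF export,
# and the confidence-to-weight transform used to turn interaction
# confidence scores into additive edge costs.

#' Read a condition graph from TSV
#'
#' Expected columns (tab-separated, with header): `source`, `target`,
#' `weight`, `conditions` (comma-separated condition indices, e.g. `1,3`).
#' Duplicate rows naming the same edge are merged by condition-set union
#' provided their weights agree; conflicting weights are an error naming
#' both lines.
#'
#' @param path File path.
#' @param n_conditions Number of conditions `C`; defaults to the largest
#'   condition index seen.
#' @param directed Are the edges directed?
#' @return A [condition_graph()].
#' @export
read_condition_graph <- function(path, n_conditions = NULL,
                                 directed = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("source", "target", "weight", "conditions")
  if (!all(need %in% names(df))) {
    stop(path, ": header must contain ", paste(need, collapse = ", "))
  }
  lineno <- seq_len(nrow(df)) + 1L            # header is line 1
  w <- suppressWarnings(as.numeric(df$weight))
  bad <- which(is.na(w) | w < 0)
  if (length(bad)) {
    stop(path, ": invalid (negative or non-numeric) weight on line(s) ",
         paste(lineno[bad], collapse = ", "))
  }
  conds <- lapply(strsplit(df$conditions, ","), function(s) {
    suppressWarnings(sort(unique(as.integer(trimws(s)))))
  })
  bad <- which(vapply(conds, function(s) length(s) == 0L || anyNA(s) ||
                        any(s < 1L), logical(1)))
  if (length(bad)) {
    stop(path, ": malformed condition list on line(s) ",
         paste(lineno[bad], collapse = ", "))
  }
  if (is.null(n_conditions)) n_conditions <- max(unlist(conds))

  from <- df$source; to <- df$target
  if (!directed) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  key <- edge_key(from, to)
  if (anyDuplicated(key)) {
    first <- match(key, key)
    merged <- data.frame(from = from, to = to, weight = w,
                         stringsAsFactors = FALSE)
    for (i in which(first != seq_along(key))) {
      j <- first[i]
      if (abs(w[i] - w[j]) > 1e-12) {
        stop(path, ": conflicting weights for edge ", from[i], "-", to[i],
             " on lines ", lineno[j], " and ", lineno[i])
      }
      conds[[j]] <- sort(union(conds[[j]], conds[[i]]))
    }
    keep <- first == seq_along(key)
    merged <- merged[keep, , drop = FALSE]
    merged$conditions <- conds[keep]
  } else {
    merged <- data.frame(from = from, to = to, weight = w,
                         stringsAsFactors = FALSE)
    merged$conditions <- conds
  }
  condition_graph(merged, n_conditions, directed = directed)
}

#' Write a condition graph to TSV
#'
#' Inverse of [read_condition_graph()] (a written graph reads back
#' identically).
#'
#' @param graph A [condition_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condition_graph <- function(graph, path) {
  stopifnot(inherits(graph, "condition_graph"))
  df <- data.frame(source = graph$edges$from, target = graph$edges$to,
                   weight = graph$edges$weight,
                   conditions = vapply(graph$exists_at, paste,
                                       character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read demands from TSV
#'
#' Columns `source`, `target`, `condition`; validated against the graph's
#' vertex set and condition range.
#'
#' @param path File path.
#' @param graph The [condition_graph()] the demands refer to.
#' @return A validated demands data frame.
#' @export
read_demands <- function(path, graph) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "condition")
  if (!all(need %in% names(df))) {
    stop(path, ": header must contain ", paste(need, collapse = ", "))
  }
  validate_demands(df, graph)
}

#' @rdname read_demands
#' @param demands Demands data frame.
#' @export
write_demands <- function(demands, path) {
  utils::write.table(demands[, c("source", "target", "condition")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a solution to JSON
#'
#' Records status, objective, chosen edges and the per-demand witness paths,
#' so a solution file can be verified against an instance without re-running
#' any solver.
#'
#' @param sol A [solution()].
#' @param path Output path.
#' @param status Solver status string stored alongside.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(sol, path, status = "optimal") {
  stopifnot(inherits(sol, "csn_solution"))
  obj <- list(status = status, objective = sol$cost,
              edges = sol$edges, witnesses = sol$witnesses)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_solution_json
#' @param graph The [condition_graph()] the solution belongs to.
#' @export
read_solution_json <- function(path, graph) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(obj$edges)
  wit <- obj$witnesses
  if (!is.null(wit)) wit <- lapply(wit, as.character)
  sol <- solution(graph, edges, witnesses = wit)
  attr(sol, "status") <- obj$status
  sol
}

#' Export the underlying graph in SIF format
#'
#' Simple interaction format (`node <relation> node`), consumed by common
#' network viewers; the relation encodes the condition set.
#'
#' @param graph A [condition_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  stopifnot(inherits(graph, "condition_graph"))
  rel <- paste0("c", vapply(graph$exists_at, paste, character(1),
                            collapse = "."))
  lines <- paste(graph$edges$from, rel, graph$edges$to, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Convert interaction confidence scores to edge weights
#'
#' Weights are the negative natural logarithm of the confidence score, so a
#' minimum-weight subgraph is a maximum-likelihood solution under edge
#' independence: confidence 1 gives weight 0 and lower confidence gives
#' larger weight. Missing scores (NA) are substituted according to `policy`:
#' `"min-nonzero"` uses the smallest nonzero confidence observed (suits
#' edges from curated sources lacking scores), `"max"` uses the largest
#' (suits small, highly curated sources).
#'
#' @param confidence Numeric vector of confidences in `(0, 1]`, NA allowed.
#' @param policy Substitution policy for missing scores.
#' @return Nonnegative numeric weights, same length.
#' @export
confidence_to_weight <- function(confidence,
                                 policy = c("min-nonzero", "max")) {
  policy <- match.arg(policy)
  conf <- as.numeric(confidence)
  known <- conf[!is.na(conf)]
  if (any(known <= 0 | known > 1)) {
    stop("confidence scores must lie in (0, 1]")
  }
  if (anyNA(conf)) {
    if (!length(known)) stop("all confidences missing; nothing to impute")
    sub <- switch(policy,
                  "min-nonzero" = min(known[known > 0]),
                  "max" = max(known))
    conf[is.na(conf)] <- sub
  }
  -log(conf)
}

#' Verify a solution file against an instance
#'
#' Re-checks every demand and the reported cost without running a solver.
#'
#' @param sol A [solution()].
#' @param instance A [csn_instance()].
#' @return A list with `feasible`, `per_demand` (named logical) and `cost`.
#' @export
verify_solution <- function(sol, instance) {
  feas <- is_feasible(sol, instance)
  list(feasible = isTRUE(feas),
       per_demand = attr(feas, "per_demand"),
       cost = solution_cost(sol, instance$graph))
}
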