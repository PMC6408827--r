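# Fixtures built in code: small deterministic graphs used across tests.

# A 4-vertex, 2-condition undirected toy with a cheap shared edge.
toy_graph <- function(directed = FALSE) {
  edf <- data.frame(
    from = c("a", "b", "a", "c"),
    to = c("b", "c", "c", "d"),
    weight = c(0.5, 0.25, 1, 0.75),
    conditions = c("1", "1,2", "2", "2"),
    stringsAsFactors = FALSE)
  condition_graph(edf, 2, directed = directed)
}

# small helper wrapping the general random generator with sizes matching
# the oracle budgets
small_instance <- function(seed, directed = NULL, variant = NULL) {
  if (is.null(directed)) directed <- seed %% 2L == 0L
  if (is.null(variant)) {
    variant <- c("edge", "node", "node-and-edge")[(seed %% 3L) + 1L]
  }
  random_csn_instance(n = 7, m = 12, C = 3, k = 3, directed = directed,
                      variant = variant, seed = seed)
}
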