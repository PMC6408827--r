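# Classed conditions shared by the solvers.

infeasible_error <- function(demand = NULL, message = NULL) {
  if (is.null(message)) {
    message <- if (is.null(demand)) {
      "instance is infeasible"
    } else {
      paste0("instance is infeasible: demand ", demand_label(demand),
             " cannot be satisfied at its condition")
    }
  }
  structure(class = c("csnet_infeasible", "error", "condition"),
            list(message = message, call = sys.call(-1), demand = demand))
}

refusal_error <- function(message) {
  structure(class = c("csnet_refusal", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}
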