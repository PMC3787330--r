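# Small models built in code for unit and property tests.

# Generation chain: one region g1..gn with division (rate p), death (d)
# and generation-indexed differentiation-out (u0 + s*(i-1), as export).
chain_model <- function(n, p = 0.3, d = 0.1, u0 = 0.05, s = 0.05,
                        with_export = TRUE, source = 0, cap_divides = TRUE) {
  states <- paste0("g", seq_len(n))
  div_gens <- if (cap_divides) seq_len(n) else seq_len(n - 1L)
  trs <- lapply(div_gens, function(i) {
    to <- if (i < n) states[[i + 1L]] else states[[n]]
    transition(states[[i]], to, "p", kind = "division")
  })
  if (d > 0)
    trs <- c(trs, lapply(states, function(st)
      transition(st, "EXIT", "d", kind = "death")))
  if (with_export)
    trs <- c(trs, lapply(states, function(st)
      transition(st, "EXIT", "u0 + s*(i-1)", kind = "export")))
  sources <- if (source > 0)
    list(list(into = "generation == g1", rate = "S")) else list()
  statechart_model("chain",
                   parameters = list(p = p, d = d, u0 = u0, s = s, S = source),
                   regions = list(region("generation", states, transitions = trs)),
                   sources = sources)
}

# Single compartment, death only.
decay_model <- function(d = 0.1) {
  statechart_model("decay", parameters = list(d = d),
                   regions = list(region("cells", "A", transitions = list(
                     transition("A", "EXIT", "d", kind = "death")))))
}

# Two regions (2 x 3 states), a couple of flows, for flatten tests.
two_by_three_model <- function(exclusions = character()) {
  statechart_model("grid23", parameters = list(a = 0.1, b = 0.2),
                   regions = list(
                     region("r1", c("A", "B"), transitions = list(
                       transition("A", "B", "a"))),
                     region("r2", c("X", "Y", "Z"), transitions = list(
                       transition("X", "Y", "b"), transition("Y", "Z", "b")))),
                   exclusions = exclusions)
}

default_conveyor <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_conveyor_model()
    cache
  }
})
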