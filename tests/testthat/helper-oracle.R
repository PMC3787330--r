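# Independent oracles, deliberately written without reusing the package's
# compiler internals: a brute-force flux enumerator for the ODE right-hand
# side, and an evaluator for exported equation text.

# TRUE iff the conjunction predicate holds for tuple (named chr vector).
.oracle_holds <- function(tuple, pred_text) {
  clauses <- trimws(strsplit(pred_text, "&&", fixed = TRUE)[[1L]])
  all(vapply(clauses, function(cl) {
    if (grepl("!=", cl, fixed = TRUE)) {
      p <- trimws(strsplit(cl, "!=", fixed = TRUE)[[1L]])
      tuple[[p[[1L]]]] != p[[2L]]
    } else {
      p <- trimws(strsplit(cl, "==", fixed = TRUE)[[1L]])
      tuple[[p[[1L]]]] == p[[2L]]
    }
  }, TRUE))
}

# Brute-force RHS: enumerate every product tuple, every transition, every
# flux, one at a time. Returns dx named by dot-joined tuple.
oracle_rhs <- function(model, x, gamma = 1) {
  params <- model$parameters
  combos <- list(stats::setNames(character(0), character(0)))
  for (r in model$regions) {
    combos <- unlist(lapply(combos, function(tp)
      lapply(r$states, function(s) c(tp, stats::setNames(s, r$name)))),
      recursive = FALSE)
  }
  if (length(model$exclusions) > 0) {
    keep <- vapply(combos, function(tp)
      !any(vapply(model$exclusions, function(e) .oracle_holds(tp, e), TRUE)), TRUE)
    combos <- combos[keep]
  }
  nm <- vapply(combos, paste, "", collapse = ".")
  names(combos) <- nm
  dx <- stats::setNames(numeric(length(nm)), nm)
  gen_states <- if ("generation" %in% names(model$regions))
    model$regions[["generation"]]$states else NULL
  for (nmk in nm) {
    tp <- combos[[nmk]]
    xi <- x[[nmk]]
    gi <- if (is.null(gen_states)) 1L else match(tp[["generation"]], gen_states)
    for (r in model$regions) {
      for (tr in r$transitions) {
        if (tr$from != tp[[r$name]]) next
        if (!is.null(tr$guard) && !.oracle_holds(tp, tr$guard)) next
        rate <- eval(parse(text = tr$rate), envir = c(params, list(i = gi)))
        if (rate == 0) next
        dx[[nmk]] <- dx[[nmk]] - rate * xi
        if (tr$kind %in% c("export", "death")) next
        tgt <- tp
        tgt[[r$name]] <- tr$to
        if (!is.null(tr$reset)) tgt[names(tr$reset)] <- tr$reset
        tname <- paste(tgt, collapse = ".")
        if (!(tname %in% nm)) {
          if (tr$kind != "division") stop("oracle: flow into excluded state")
          tgt <- tp                       # saturating cap
          if (!is.null(tr$reset)) tgt[names(tr$reset)] <- tr$reset
          tname <- paste(tgt, collapse = ".")
        }
        mult <- if (tr$kind == "division") 2 * gamma else 1
        dx[[tname]] <- dx[[tname]] + mult * rate * xi
      }
    }
  }
  for (s in model$sources) {
    hit <- vapply(combos, function(tp) .oracle_holds(tp, s$into), TRUE)
    dx[hit] <- dx[hit] + params[[s$rate]]
  }
  dx
}

# Re-evaluate exported equation lines at a state vector: each RHS is plain
# R arithmetic over parameter names, gamma and flat-state names.
eval_equation_lines <- function(lines, x, params, gamma = 1) {
  env <- c(params, list(gamma = gamma), as.list(x))
  nm <- sub("^d\\((.+)\\)/dt = .*$", "\\1", lines)
  rhs <- sub("^d\\(.+\\)/dt = ", "", lines)
  stats::setNames(vapply(rhs, function(e)
    eval(parse(text = e), envir = env), 0, USE.NAMES = FALSE), nm)
}
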