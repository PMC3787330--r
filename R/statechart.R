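# Statechart core: parallel state-transition models as the shared formal
# substrate of the population (ODE) and agent backends.
#
# A model is a set of orthogonal regions; a cell occupies one state per
# region simultaneously. Transitions live inside a single region; coupling
# across regions is expressed by guards (conjunctive state tests) and, for
# division, by an optional reset map applied to other regions on firing
# (daughters re-enter quiescence). The reserved absorbing pseudo-state
# "EXIT" models death and thymic export as cumulative outflow channels.

EXIT_STATE <- "EXIT"

#' Create a transition
#'
#' @param from,to source and target state names within one region; `to` may
#'   be `"EXIT"` for `kind` `"export"` or `"death"`.
#' @param rate rate expression: a parameter name, a number, or an
#'   affine/table-lookup expression in the generation index `i`
#'   (e.g. `"u0 + s*(i-1)"`, `"Us4[i]"`). Units 1/time.
#' @param kind one of `"flow"`, `"division"`, `"export"`, `"death"`.
#'   Division removes the parent at `rate` and (for gamma = 1) injects two
#'   daughters into the target; see [compile_population_ode()].
#' @param guard optional predicate over other regions' states, e.g.
#'   `"cell_cycle == SM"`.
#' @param reset optional named character vector (region -> state) applied on
#'   firing, e.g. `c(cell_cycle = "G0")` so daughters start quiescent.
#' @return a `statechart_transition` list.
#' @export
transition <- function(from, to, rate, kind = "flow", guard = NULL, reset = NULL) {
  kind <- match.arg(kind, c("flow", "division", "export", "death"))
  if (!is.null(reset)) {
    reset <- unlist(reset)
    stopifnot(is.character(reset), !is.null(names(reset)))
  }
  if (!is.null(guard) && !nzchar(trimws(guard))) guard <- NULL
  structure(list(from = as.character(from), to = as.character(to),
                 rate = as.character(rate), kind = kind,
                 guard = guard, reset = reset),
            class = "statechart_transition")
}

#' Create a region (one orthogonal component of a statechart)
#'
#' @param name region identifier.
#' @param states ordered character vector of state names (unique within the
#'   region).
#' @param initial initial state; defaults to the first state.
#' @param transitions list of [transition()] objects.
#' @return a `statechart_region` list.
#' @export
region <- function(name, states, initial = states[[1L]], transitions = list()) {
  states <- as.character(states)
  if (anyDuplicated(states))
    stop("duplicate state name in region '", name, "'", call. = FALSE)
  structure(list(name = as.character(name), states = states,
                 initial = as.character(initial), transitions = transitions),
            class = "statechart_region")
}

#' Construct a statechart model
#'
#' Performs referential integrity checks (the same checks [parse_model()]
#' applies to documents): transition endpoints must exist in their region,
#' every rate's parameters must be declared, region names must be unique.
#' Value-level invariants (rate signs, reachability, guard targets) are
#' checked by [validate_model()], which returns diagnostics instead of
#' throwing.
#'
#' @param name model identifier.
#' @param parameters named list: parameter name -> number or per-generation
#'   numeric vector.
#' @param regions list of [region()] objects; order defines flat-state
#'   ordering.
#' @param sources list of `list(into = <flat-state selector predicate>,
#'   rate = <parameter name>)` influxes.
#' @param exclusions character vector of predicates naming flat-state
#'   combinations that do not exist (removed from the product).
#' @return a `statechart_model`.
#' @export
statechart_model <- function(name, parameters = list(), regions = list(),
                             sources = list(), exclusions = character()) {
  rnames <- vapply(regions, function(r) r$name, "")
  if (anyDuplicated(rnames))
    stop("duplicate region: '", rnames[duplicated(rnames)][[1L]], "'", call. = FALSE)
  names(regions) <- rnames
  for (r in regions) {
    for (tr in r$transitions) {
      if (!(tr$from %in% r$states))
        stop("unknown state: '", tr$from, "' in region '", r$name, "'", call. = FALSE)
      if (!(tr$to %in% c(r$states, EXIT_STATE)))
        stop("unknown state: '", tr$to, "' in region '", r$name, "'", call. = FALSE)
      parse_rate(tr$rate, parameters)  # errors on undeclared parameters
    }
  }
  for (s in sources) {
    if (is.null(parameters[[s$rate]]))
      stop("unknown parameter: '", s$rate, "' in source", call. = FALSE)
  }
  structure(list(name = as.character(name), parameters = parameters,
                 regions = regions, sources = sources,
                 exclusions = as.character(exclusions)),
            class = "statechart_model")
}

#' @export
print.statechart_model <- function(x, ...) {
  cat("<statechart_model>", x$name, "\n")
  for (r in x$regions)
    cat("  region", r$name, ":", length(r$states), "states,",
        length(r$transitions), "transitions\n")
  cat("  parameters:", length(x$parameters),
      "| sources:", length(x$sources),
      "| exclusions:", length(x$exclusions), "\n")
  invisible(x)
}

# ---- document parsing / serialization ---------------------------------

#' Parse a model-description document
#'
#' The document dialect is YAML with top-level keys `name`, `parameters`
#' (name -> number or per-generation list), `regions` (list of
#' `{name, states, initial, transitions}` where transitions are
#' `{from, to, rate, kind, guard?, reset?}`), `sources` (list of
#' `{into, rate}`) and `exclusions` (list of predicates).
#'
#' @param doc path to a YAML file, or the document text itself (anything
#'   containing a newline is treated as text).
#' @return a [statechart_model()].
#' @export
#' @examples
#' m <- parse_model("name: tiny\nparameters: {d: 0.1}\nregions:\n- name: r\n  states: [A]\n  initial: A\n  transitions: []\n")
#' length(m$regions)
parse_model <- function(doc) {
  stopifnot(is.character(doc), length(doc) == 1L)
  raw <- if (grepl("\n", doc, fixed = TRUE)) yaml::yaml.load(doc) else yaml::read_yaml(doc)
  params <- lapply(raw$parameters %||% list(), function(p) as.numeric(unlist(p)))
  regions <- lapply(raw$regions %||% list(), function(r) {
    trs <- lapply(r$transitions %||% list(), function(tr) {
      transition(from = tr$from, to = tr$to, rate = tr$rate,
                 kind = tr$kind %||% "flow", guard = tr$guard %||% NULL,
                 reset = if (!is.null(tr$reset)) unlist(tr$reset) else NULL)
    })
    region(name = r$name, states = r$states,
           initial = r$initial %||% r$states[[1L]], transitions = trs)
  })
  sources <- lapply(raw$sources %||% list(), function(s) list(into = s$into, rate = s$rate))
  statechart_model(name = raw$name %||% "model", parameters = params,
                   regions = regions, sources = sources,
                   exclusions = as.character(unlist(raw$exclusions %||% character())))
}

#' Serialize a model back to document text
#'
#' `parse_model(serialize_model(m))` reproduces `m` field-by-field.
#'
#' @param model a [statechart_model()].
#' @return a single YAML string.
#' @export
serialize_model <- function(model) {
  as_list <- list(
    name = model$name,
    parameters = model$parameters,
    regions = lapply(unname(model$regions), function(r) {
      list(name = r$name, states = as.list(r$states), initial = r$initial,
           transitions = lapply(r$transitions, function(tr) {
             out <- list(from = tr$from, to = tr$to, rate = tr$rate, kind = tr$kind)
             if (!is.null(tr$guard)) out$guard <- tr$guard
             if (!is.null(tr$reset)) out$reset <- as.list(tr$reset)
             out
           }))
    }),
    sources = lapply(model$sources, function(s) list(into = s$into, rate = s$rate)),
    exclusions = as.list(model$exclusions)
  )
  yaml::as.yaml(as_list)
}

# ---- validation --------------------------------------------------------

diag_row <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a statechart model
#'
#' Checks value-level invariants and returns diagnostics rather than
#' throwing: an empty result means the model is valid and every state is
#' reachable from its region's initial state.
#'
#' Checks: `initial` is a member of `states`; transition kinds are
#' consistent with their targets (export/death go to `EXIT`, flow/division
#' do not); no duplicate (source, target, rate, guard) transitions; guard
#' and reset references name existing regions/states; rate expressions are
#' non-negative for every generation index in range; every state is
#' reachable from the initial state (warning otherwise); source selectors
#' match at least one flat state; exclusions do not empty the model.
#'
#' @param model a [statechart_model()].
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `location`, `message`; zero rows iff valid.
#' @export
validate_model <- function(model) {
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- diag_row(...)
  ngen <- {
    g <- model$regions[["generation"]]
    if (is.null(g)) 1L else length(g$states)
  }
  for (r in model$regions) {
    loc <- paste0("region ", r$name)
    if (!(r$initial %in% r$states))
      add("error", loc, paste0("initial state '", r$initial, "' not in states"))
    sig <- vapply(r$transitions, function(tr)
      paste(tr$from, tr$to, tr$rate, tr$guard %||% "", sep = "\r"), "")
    if (anyDuplicated(sig))
      add("error", loc, "duplicate (source, target, label) transition")
    for (tr in r$transitions) {
      tloc <- paste0(loc, ": ", tr$from, " -> ", tr$to)
      if (tr$kind %in% c("export", "death") && tr$to != EXIT_STATE)
        add("error", tloc, paste0(tr$kind, " transition must target EXIT"))
      if (tr$kind %in% c("flow", "division") && tr$to == EXIT_STATE)
        add("error", tloc, paste0(tr$kind, " transition may not target EXIT"))
      if (!is.null(tr$guard)) {
        pred <- tryCatch(parse_predicate(tr$guard), error = function(e) NULL)
        if (is.null(pred)) {
          add("error", tloc, paste0("unparseable guard '", tr$guard, "'"))
        } else {
          for (k in seq_len(nrow(pred))) {
            reg <- model$regions[[pred$region[k]]]
            if (is.null(reg))
              add("error", tloc, paste0("guard references unknown region '", pred$region[k], "'"))
            else if (!(pred$state[k] %in% reg$states))
              add("error", tloc, paste0("guard references unknown state '", pred$state[k],
                                        "' of region '", pred$region[k], "'"))
          }
        }
      }
      for (rn in names(tr$reset %||% character())) {
        reg <- model$regions[[rn]]
        if (is.null(reg))
          add("error", tloc, paste0("reset references unknown region '", rn, "'"))
        else if (!(tr$reset[[rn]] %in% reg$states))
          add("error", tloc, paste0("reset references unknown state '", tr$reset[[rn]], "'"))
      }
      expr <- tryCatch(parse_rate(tr$rate, model$parameters), error = function(e) e)
      if (inherits(expr, "error")) {
        add("error", tloc, conditionMessage(expr))
      } else {
        vals <- vapply(seq_len(ngen), function(i)
          tryCatch(eval_rate(expr, model$parameters, i), error = function(e) NA_real_), 0)
        if (anyNA(vals))
          add("error", tloc, paste0("rate '", tr$rate, "' fails to evaluate for some generation index"))
        else if (any(vals < 0))
          add("error", tloc, paste0("rate '", tr$rate, "' is negative for generation index ",
                                    which(vals < 0)[[1L]]))
      }
    }
    # reachability from the initial state over this region's transitions
    edges <- lapply(r$transitions, function(tr) c(tr$from, tr$to))
    reach <- r$initial
    repeat {
      nxt <- unique(unlist(lapply(edges, function(e) if (e[[1L]] %in% reach) e[[2L]])))
      nxt <- setdiff(intersect(nxt, r$states), reach)
      if (length(nxt) == 0L) break
      reach <- c(reach, nxt)
    }
    for (s in setdiff(r$states, reach))
      add("warning", loc, paste0("unreachable state '", s, "'"))
  }
  for (x in model$exclusions) {
    pred <- tryCatch(parse_predicate(x), error = function(e) NULL)
    if (is.null(pred)) { add("error", "exclusions", paste0("unparseable exclusion '", x, "'")); next }
    for (k in seq_len(nrow(pred))) {
      reg <- model$regions[[pred$region[k]]]
      if (is.null(reg))
        add("error", "exclusions", paste0("unknown region '", pred$region[k], "'"))
      else if (!(pred$state[k] %in% reg$states))
        add("error", "exclusions", paste0("unknown state '", pred$state[k], "'"))
    }
  }
  flat <- tryCatch(flatten_product_states(model), error = function(e) e)
  if (inherits(flat, "error")) {
    add("error", "model", conditionMessage(flat))
  } else {
    for (s in model$sources) {
      hit <- tryCatch(match_flat_states(flat, s$into), error = function(e) integer())
      if (length(hit) == 0L)
        add("error", "sources", paste0("source selector '", s$into, "' matches no flat state"))
    }
  }
  do.call(rbind, c(out, list(diag_row(character(), character(), character())[0, ])))
}

# ---- product construction ---------------------------------------------

#' Flatten a parallel statechart into product states
#'
#' Builds the cross product of all regions' state sets, removes flat states
#' matched by any exclusion selector, and assigns contiguous 0-based
#' indices. Ordering is lexicographic by region order then state order
#' (first region varies slowest), so it is stable across runs.
#'
#' @param model a [statechart_model()].
#' @return data.frame with one character column per region, plus `name`
#'   (dot-joined tuple) and `index` (0-based). Attributes `region_sizes`,
#'   `strides` and `full_map` support O(1) tuple lookup.
#' @export
flatten_product_states <- function(model) {
  rnames <- names(model$regions)
  sizes <- vapply(model$regions, function(r) length(r$states), 1L)
  grid <- expand.grid(rev(lapply(model$regions, function(r) r$states)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(rnames)), drop = FALSE]
  names(grid) <- rnames
  preds <- lapply(model$exclusions, parse_predicate)
  keep <- rep(TRUE, nrow(grid))
  for (p in preds) {
    if (nrow(p) == 0L) next
    hit <- rep(TRUE, nrow(grid))
    for (k in seq_len(nrow(p))) {
      eq <- grid[[p$region[k]]] == p$state[k]
      hit <- hit & (if (p$op[k] == "==") eq else !eq)
    }
    keep <- keep & !hit
  }
  flat <- grid[keep, , drop = FALSE]
  if (nrow(flat) == 0L) stop("empty model: exclusions eliminate all states", call. = FALSE)
  rownames(flat) <- NULL
  flat$name <- do.call(paste, c(flat[rnames], sep = "."))
  flat$index <- seq_len(nrow(flat)) - 1L
  # strides over the full product (row-major in region order) for lookup
  strides <- rev(cumprod(rev(c(sizes[-1L], 1L))))
  names(strides) <- rnames
  state_pos <- lapply(model$regions, function(r) stats::setNames(seq_along(r$states), r$states))
  full_idx <- rep(1L, nrow(grid))
  for (rn in rnames)
    full_idx <- full_idx + (state_pos[[rn]][grid[[rn]]] - 1L) * strides[[rn]]
  full_map <- rep(NA_integer_, prod(sizes))
  full_map[full_idx[keep]] <- seq_len(nrow(flat))
  attr(flat, "region_sizes") <- sizes
  attr(flat, "strides") <- strides
  attr(flat, "state_pos") <- state_pos
  attr(flat, "full_map") <- full_map
  class(flat) <- c("flat_states", "data.frame")
  flat
}

# Row index (1-based) of a tuple (named chr, region -> state) in the flat
# table, or NA if the combination is excluded.
flat_lookup <- function(flat, tuple) {
  strides <- attr(flat, "strides")
  state_pos <- attr(flat, "state_pos")
  idx <- 1L
  for (rn in names(strides)) {
    p <- state_pos[[rn]][[tuple[[rn]]]]
    idx <- idx + (p - 1L) * strides[[rn]]
  }
  attr(flat, "full_map")[idx]
}

# Flat rows matching a selector predicate (string) or character vector of
# flat-state names, or a logical/integer index.
match_flat_states <- function(flat, selector) {
  rnames <- names(attr(flat, "strides"))
  if (is.logical(selector)) return(which(selector))
  if (is.numeric(selector)) return(as.integer(selector))
  if (length(selector) == 1L && grepl("==|!=", selector)) {
    pred <- parse_predicate(selector)
    keep <- rep(TRUE, nrow(flat))
    for (k in seq_len(nrow(pred))) {
      eq <- flat[[pred$region[k]]] == pred$state[k]
      keep <- keep & (if (pred$op[k] == "==") eq else !eq)
    }
    return(which(keep))
  }
  which(flat$name %in% selector)
}

# The generation index of each flat row: position of the state in the
# region named "generation", or 1 if the model has no such region.
generation_index <- function(model, flat) {
  g <- model$regions[["generation"]]
  if (is.null(g)) return(rep(1L, nrow(flat)))
  match(flat[["generation"]], g$states)
}

# Apply a region transition (and its reset map) to a tuple; returns the new
# tuple. Does not check exclusions -- see resolve_target().
apply_transition_tuple <- function(tuple, region_name, to, reset = NULL) {
  tuple[[region_name]] <- to
  for (rn in names(reset %||% character())) tuple[[rn]] <- reset[[rn]]
  tuple
}

# Target flat row for a transition fired from `tuple`. If the target is an
# excluded combination and `saturate` is TRUE (division semantics), the
# transition's own region keeps its source state (saturating cap) while
# resets still apply; returns NA if even that combination is excluded.
resolve_target <- function(flat, tuple, region_name, from, to, reset = NULL,
                           saturate = FALSE) {
  k <- flat_lookup(flat, apply_transition_tuple(tuple, region_name, to, reset))
  if (!is.na(k) || !saturate) return(k)
  flat_lookup(flat, apply_transition_tuple(tuple, region_name, from, reset))
}
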