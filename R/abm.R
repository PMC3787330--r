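# Agent backend: interpret any statechart per cell in discrete time.
# Each step, every agent independently samples at most one transition per
# orthogonal region by competing risks (first-event-wins among the enabled
# transitions' exponential clocks over dt); division resolves after the
# region transitions so a cell cannot divide and differentiate in the same
# step. Agents are visited in a freshly shuffled order each step. All
# randomness comes from R's global RNG, seeded once per run, so a fixed
# seed reproduces runs bit-for-bit.

#' Convert a rate to a per-step firing probability
#'
#' Discrete-time embedding of a continuous rate: `1 - exp(-rate * dt)`.
#'
#' @param rate non-negative rate (1/time); vectorized.
#' @param dt step length (> 0).
#' @return probability in `[0, 1)`.
#' @export
rate_to_prob <- function(rate, dt) {
  if (any(rate < 0)) stop("negative rate", call. = FALSE)
  if (any(dt <= 0)) stop("dt must be > 0", call. = FALSE)
  -expm1(-rate * dt)
}

# Per-flat-state transition tables for the interpreter. For each flat row k
# and region j: the enabled transitions (guards evaluated against k's
# tuple), their rates, and precomputed targets (division targets saturate
# at exclusions). Also the competing-risks total-rate matrix.
build_agent_tables <- function(model, flat = flatten_product_states(model)) {
  J <- length(model$regions)
  n <- nrow(flat)
  rnames <- names(model$regions)
  gi_all <- generation_index(model, flat)
  tuples <- as.matrix(flat[rnames])
  cand <- vector("list", n)
  Rtot <- matrix(0, n, J)
  for (k in seq_len(n)) {
    tuple <- tuples[k, ]
    per_region <- vector("list", J)
    for (j in seq_len(J)) {
      r <- model$regions[[j]]
      hits <- list()
      for (tr in r$transitions) {
        if (tr$from != tuple[[r$name]]) next
        if (!is.null(tr$guard) && !eval_predicate(parse_predicate(tr$guard), tuple)) next
        rate <- eval_rate(tr$rate, model$parameters, gi_all[[k]])
        if (rate == 0) next
        dst <- if (tr$kind %in% c("export", "death")) NA_integer_ else
          resolve_target(flat, tuple, r$name, tr$from, tr$to, tr$reset,
                         saturate = tr$kind == "division")
        hits[[length(hits) + 1L]] <- list(
          kind = tr$kind, rate = rate, dst = dst,
          channel = if (tr$kind %in% c("export", "death"))
            paste(tr$kind, r$name, tr$from, sep = ":") else NA_character_,
          region = r$name, from = tr$from, to = tr$to, reset = tr$reset)
      }
      if (length(hits) > 0) {
        per_region[[j]] <- list(
          m = length(hits),
          kind = vapply(hits, `[[`, "", "kind"),
          rate = vapply(hits, `[[`, 0, "rate"),
          dst = vapply(hits, `[[`, NA_integer_, "dst"),
          channel = vapply(hits, `[[`, "", "channel"),
          info = hits)
        Rtot[k, j] <- sum(per_region[[j]]$rate)
      }
    }
    cand[[k]] <- per_region
  }
  # like the ODE compiler, the influx rate applies to every matched state
  sources <- lapply(model$sources, function(s) {
    k <- match_flat_states(flat, s$into)
    list(k = k, rate = eval_rate(s$rate, model$parameters, 1L))
  })
  list(cand = cand, Rtot = Rtot, sources = sources, J = J)
}

#' Create an agent world
#'
#' @param model a valid [statechart_model()].
#' @param init initial population: a single count (all agents start in the
#'   source target state, or the first flat state if the model has no
#'   source) or a named vector of counts per flat-state name.
#' @param gamma division-survival switch: number or
#'   [ganciclovir_schedule()].
#' @param dt step length used to precompute firing probabilities.
#' @return a `statechart_world` with agents, clock 0, and an empty event
#'   log. Seed the global RNG (`set.seed`) before stepping for
#'   reproducible runs.
#' @export
new_world <- function(model, init, gamma = 1, dt = 0.01) {
  flat <- flatten_product_states(model)
  tab <- build_agent_tables(model, flat)
  counts <- stats::setNames(integer(nrow(flat)), flat$name)
  if (length(init) == 1L && is.null(names(init))) {
    k0 <- if (length(tab$sources) > 0) tab$sources[[1L]]$k[[1L]] else 1L
    counts[[k0]] <- as.integer(init)
  } else {
    bad <- setdiff(names(init), flat$name)
    if (length(bad) > 0) stop("unknown flat state in init: ", bad[[1L]], call. = FALSE)
    counts[names(init)] <- as.integer(init)
  }
  maxload <- max(rowSums(tab$Rtot)) * dt
  if (maxload >= 0.5)
    warning("dt too coarse: total enabled rate * dt = ", signif(maxload, 3),
            " >= 0.5 for some state", call. = FALSE)
  ak <- rep.int(seq_along(counts), counts)
  structure(list(model = model, flat = flat, tables = tab,
                 ak = ak, ids = seq_along(ak),
                 next_id = length(ak) + 1L, clock = 0,
                 gamma = gamma, dt = dt,
                 pfire = rate_to_prob(tab$Rtot, dt),
                 log = list(), initial_n = length(ak)),
            class = "statechart_world")
}

#' @export
print.statechart_world <- function(x, ...) {
  cat("<statechart_world>", length(x$ak), "agents at t =", x$clock, "\n")
  invisible(x)
}

# Append one chunk of events to the world's log.
log_events <- function(world, t, id, event, detail) {
  if (length(id) == 0L) return(world)
  world$log[[length(world$log) + 1L]] <-
    data.frame(t = t, id = id, event = event, detail = detail,
               stringsAsFactors = FALSE)
  world
}

#' Event log of a world or run
#' @param x a `statechart_world` or `abm_run`.
#' @return data.frame with columns `t`, `id`, `event`
#'   (`birth`/`division`/`death`/`export`), `detail`.
#' @export
event_log <- function(x) {
  chunks <- if (inherits(x, "statechart_world")) x$log else x$log
  if (length(chunks) == 0L)
    return(data.frame(t = numeric(), id = integer(), event = character(),
                      detail = character(), stringsAsFactors = FALSE))
  if (is.data.frame(chunks)) return(chunks)
  do.call(rbind, chunks)
}

#' Advance a world by one step
#'
#' Visits agents in a freshly shuffled order; per agent and region at most
#' one enabled transition fires (competing risks over dt); division
#' resolves last and is skipped when another region also fired this step;
#' source influx arrives as Poisson(rate * dt) new agents.
#'
#' @param world a `statechart_world`.
#' @param dt step length; defaults to the world's dt.
#' @return the advanced world.
#' @export
step_world <- function(world, dt = world$dt) {
  tab <- world$tables
  flat <- world$flat
  J <- tab$J
  pfire <- if (identical(dt, world$dt)) world$pfire else rate_to_prob(tab$Rtot, dt)
  g <- gamma_value_at(world$gamma, world$clock)
  t_new <- world$clock + dt
  ak <- world$ak; ids <- world$ids
  n <- length(ak)

  if (n > 0L) {
    ord <- sample.int(n)
    ak <- ak[ord]; ids <- ids[ord]
    fired <- matrix(stats::runif(n * J), n, J) < pfire[ak, , drop = FALSE]
    nf <- rowSums(fired)
    removed <- logical(n)
    div_idx <- integer(); div_dst <- integer()
    ev_id <- integer(); ev_event <- character(); ev_detail <- character()

    singles <- which(nf == 1L)
    if (length(singles) > 0L) {
      jj <- max.col(fired[singles, , drop = FALSE], ties.method = "first")
      key <- paste(ak[singles], jj)
      for (grp in split(seq_along(singles), key)) {
        i0 <- singles[grp]
        cnd <- tab$cand[[ak[i0[[1L]]]]][[jj[grp[[1L]]]]]
        branch <- if (cnd$m == 1L) rep.int(1L, length(i0)) else
          sample.int(cnd$m, length(i0), replace = TRUE, prob = cnd$rate)
        for (b in seq_len(cnd$m)) {
          sel <- i0[branch == b]
          if (length(sel) == 0L) next
          switch(cnd$kind[[b]],
            flow = ak[sel] <- cnd$dst[[b]],
            division = { div_idx <- c(div_idx, sel)
                         div_dst <- c(div_dst, rep.int(cnd$dst[[b]], length(sel))) },
            { removed[sel] <- TRUE
              ev_id <- c(ev_id, ids[sel])
              ev_event <- c(ev_event, rep.int(if (cnd$kind[[b]] == "export") "export" else "death",
                                              length(sel)))
              ev_detail <- c(ev_detail, rep.int(cnd$channel[[b]], length(sel))) })
        }
      }
    }

    multis <- which(nf >= 2L)
    for (i in multis) {
      # simultaneous firing in several regions: sample each region's branch
      # against the step-start state, apply non-division ones sequentially,
      # skip division (a cell cannot divide and differentiate in one step)
      tuple <- stats::setNames(as.character(flat[ak[[i]], names(world$model$regions)]),
                               names(world$model$regions))
      cur <- ak[[i]]
      for (j in which(fired[i, ])) {
        cnd <- tab$cand[[ak[[i]]]][[j]]
        b <- if (cnd$m == 1L) 1L else sample.int(cnd$m, 1L, prob = cnd$rate)
        info <- cnd$info[[b]]
        if (info$kind == "division") next
        if (info$kind %in% c("export", "death")) {
          removed[[i]] <- TRUE
          ev_id <- c(ev_id, ids[[i]])
          ev_event <- c(ev_event, if (info$kind == "export") "export" else "death")
          ev_detail <- c(ev_detail, info$channel)
          break
        }
        nxt <- resolve_target(flat, tuple, info$region, info$from, info$to, info$reset)
        if (!is.na(nxt)) {
          cur <- nxt
          tuple <- stats::setNames(as.character(flat[cur, names(world$model$regions)]),
                                   names(world$model$regions))
        }
      }
      if (!removed[[i]]) ak[[i]] <- cur
    }

    if (length(div_idx) > 0L) {
      live <- !removed[div_idx]
      div_idx <- div_idx[live]; div_dst <- div_dst[live]
      if (g == 1) {
        ak[div_idx] <- div_dst
        nd <- length(div_idx)
        dids <- world$next_id + seq_len(nd) - 1L
        world$next_id <- world$next_id + nd
        ak <- c(ak, div_dst); ids <- c(ids, dids)
        removed <- c(removed, logical(nd))
        ev_id <- c(ev_id, ids[div_idx])
        ev_event <- c(ev_event, rep.int("division", nd))
        ev_detail <- c(ev_detail, paste0("daughter:", dids))
      } else {
        removed[div_idx] <- TRUE
        ev_id <- c(ev_id, ids[div_idx])
        ev_event <- c(ev_event, rep.int("death", length(div_idx)))
        ev_detail <- c(ev_detail, rep.int(GANCICLOVIR_CHANNEL, length(div_idx)))
      }
    }

    if (any(removed)) { ak <- ak[!removed]; ids <- ids[!removed] }
    world <- log_events(world, t_new, ev_id, ev_event, ev_detail)
  }

  for (src in tab$sources) {
    for (k in src$k) {
      nnew <- stats::rpois(1L, src$rate * dt)
      if (nnew > 0L) {
        nids <- world$next_id + seq_len(nnew) - 1L
        world$next_id <- world$next_id + nnew
        ak <- c(ak, rep.int(k, nnew)); ids <- c(ids, nids)
        world <- log_events(world, t_new, nids, rep.int("birth", nnew),
                            rep.int(world$flat$name[[k]], nnew))
      }
    }
  }

  world$ak <- ak; world$ids <- ids; world$clock <- t_new
  world
}

#' Divide one agent
#'
#' The elementary division event: with gamma = 1 the parent is replaced by
#' two daughters in the division transition's target state (next
#' generation, saturating at the cap, cell cycle reset to G0); with
#' gamma = 0 the parent dies by ganciclovir apoptosis and no daughter is
#' produced.
#'
#' @param agent list with at least `states` (named character vector,
#'   region -> current state) and optionally `id`.
#' @param model the [statechart_model()] the agent lives in.
#' @param gamma 0 or 1.
#' @return list with `daughters` (list of 2 agents, or empty) and `event`
#'   (`"division"` or `"ganciclovir_apoptosis"`).
#' @export
divide_agent <- function(agent, model, gamma = 1) {
  stopifnot(gamma %in% c(0, 1))
  flat <- flatten_product_states(model)
  tuple <- agent$states
  gi <- if ("generation" %in% names(tuple))
    match(tuple[["generation"]], model$regions[["generation"]]$states) else 1L
  enabled <- NULL
  for (r in model$regions) {
    for (tr in r$transitions) {
      if (tr$kind != "division" || tr$from != tuple[[r$name]]) next
      if (!is.null(tr$guard) && !eval_predicate(parse_predicate(tr$guard), tuple)) next
      if (eval_rate(tr$rate, model$parameters, gi) == 0) next
      enabled <- list(region = r$name, tr = tr)
      break
    }
    if (!is.null(enabled)) break
  }
  if (is.null(enabled))
    stop("agent is not in a division-enabled state", call. = FALSE)
  if (gamma == 0)
    return(list(daughters = list(), event = "ganciclovir_apoptosis"))
  tr <- enabled$tr
  dst <- resolve_target(flat, tuple, enabled$region, tr$from, tr$to, tr$reset,
                        saturate = TRUE)
  new_tuple <- stats::setNames(as.character(flat[dst, names(model$regions)]),
                               names(model$regions))
  daughter <- function() list(id = NA_integer_, states = new_tuple)
  list(daughters = list(daughter(), daughter()), event = "division")
}

#' Run an agent-based simulation
#'
#' @param model a valid [statechart_model()].
#' @param init initial population (see [new_world()]).
#' @param t_end end time.
#' @param dt step length (default 0.01 model time units).
#' @param seed integer seed; runs are reproducible bit-for-bit.
#' @param record times at which to record per-flat-state counts; default
#'   every step. Snapped to the step grid.
#' @param gamma number or [ganciclovir_schedule()].
#' @param record_log keep the event log (disable for large sweeps).
#' @return an `abm_run`: list with `time`, `values` (time x flat-state
#'   count matrix), `flat`, `log` (event data.frame), `final_n`,
#'   `initial_n`, `seed`.
#' @export
run_abm <- function(model, init, t_end, dt = 0.01, seed,
                    record = NULL, gamma = 1, record_log = TRUE) {
  stopifnot(!missing(seed))
  n_steps <- as.integer(round(t_end / dt))
  rec_steps <- if (is.null(record)) 0:n_steps else
    sort(unique(pmin(pmax(as.integer(round(record / dt)), 0L), n_steps)))
  with_seed(seed, {
    world <- new_world(model, init, gamma = gamma, dt = dt)
    nf <- nrow(world$flat)
    values <- matrix(0L, length(rec_steps), nf,
                     dimnames = list(NULL, world$flat$name))
    row <- 1L
    if (rec_steps[[1L]] == 0L) {
      values[1L, ] <- tabulate(world$ak, nbins = nf); row <- 2L
    }
    for (s in seq_len(n_steps)) {
      world <- step_world(world, dt)
      if (!record_log) world$log <- list()
      if (row <= length(rec_steps) && rec_steps[[row]] == s) {
        values[row, ] <- tabulate(world$ak, nbins = nf)
        row <- row + 1L
      }
    }
    structure(list(time = rec_steps * dt, values = values, flat = world$flat,
                   log = if (record_log) event_log(world) else NULL,
                   final_n = length(world$ak), initial_n = world$initial_n,
                   seed = seed, dt = dt),
              class = "abm_run")
  })
}

#' @export
print.abm_run <- function(x, ...) {
  cat("<abm_run>", x$final_n, "agents at t =", max(x$time),
      "(seed", x$seed, ")\n")
  invisible(x)
}

#' Compare agent-based replicates against the mean-field (ODE) solution
#'
#' Runs the same statechart through both backends: the ODE trajectory from
#' [compile_population_ode()] + [integrate_ode()], and `replicates`
#' independent agent runs (replicate r uses `seed + r`). For every flat
#' state and grid time it reports the replicate mean, the ODE value and
#' the z-score `(mean - ode) / (sd / sqrt(replicates))`, flagging states
#' with `|z| > 4`.
#'
#' @param model a valid, non-spatial [statechart_model()].
#' @param n_agents initial agent count (placed at the source target state).
#' @param replicates number of independent ABM runs.
#' @param t_grid comparison time grid (must align with the step grid).
#' @param seed base seed.
#' @param dt agent step length.
#' @param gamma number or schedule.
#' @return a `mean_field_report`: list with `time`, `abm_mean`, `ode`, `z`,
#'   `flagged` (data.frame), `max_abs_z`, `mean_sq_z`.
#' @export
compare_mean_field <- function(model, n_agents, replicates, t_grid, seed,
                               dt = 0.01, gamma = 1) {
  if (!inherits(model, "statechart_model"))
    stop("not comparable: model is not a statechart (spatial rules have no mean-field reduction here)",
         call. = FALSE)
  # snap the comparison grid to the agent step grid so both backends are
  # evaluated at identical times
  t_grid <- sort(unique(round(t_grid / dt) * dt))
  system <- compile_population_ode(model)
  flat <- system$flat
  k0 <- if (length(model$sources) > 0)
    match_flat_states(flat, model$sources[[1L]]$into)[[1L]] else 1L
  y0 <- stats::setNames(numeric(nrow(flat)), flat$name)
  y0[[k0]] <- n_agents
  # both backends start at t = 0; integrate_ode anchors y0 at the first
  # grid point, so prepend 0 and drop it from the comparison
  ode_grid <- sort(unique(c(0, t_grid)))
  ode_full <- integrate_ode(system, y0, ode_grid, gamma = gamma)
  ode <- list(values = ode_full$values[match(t_grid, ode_grid), , drop = FALSE])
  runs <- array(0, dim = c(length(t_grid), nrow(flat), replicates))
  for (r in seq_len(replicates)) {
    ab <- run_abm(model, init = y0[y0 > 0], t_end = max(t_grid), dt = dt,
                  seed = seed + r, record = t_grid, gamma = gamma,
                  record_log = FALSE)
    runs[, , r] <- ab$values
  }
  abm_mean <- apply(runs, c(1, 2), mean)
  abm_sd <- apply(runs, c(1, 2), stats::sd)
  # the replicate-mean standard error is floored at the irreducible
  # Poisson counting noise sqrt(ode/R): with few replicates the sample sd
  # of a small count underestimates (or degenerates to 0 when every
  # replicate sees no cell), which would spuriously inflate z
  se <- pmax(abm_sd, sqrt(pmax(ode$values, 0))) / sqrt(replicates)
  diff <- abm_mean - ode$values
  z <- diff / se
  z[diff == 0] <- 0
  dimnames(z) <- dimnames(abm_mean) <- list(NULL, flat$name)
  hits <- which(abs(z) > 4, arr.ind = TRUE)
  flagged <- data.frame(time = t_grid[hits[, 1L]],
                        state = flat$name[hits[, 2L]],
                        z = z[hits], stringsAsFactors = FALSE)
  # relative Monte-Carlo error (this is the quantity with the 1/sqrt(N)
  # scaling in agent count; z-scores are standardized and do not scale)
  rel_mse <- mean(((abm_mean - ode$values) / pmax(ode$values, 1))^2)
  structure(list(time = t_grid, abm_mean = abm_mean, ode = ode$values, z = z,
                 flagged = flagged, max_abs_z = max(abs(z)),
                 mean_sq_z = mean(z^2), rel_mse = rel_mse,
                 n_agents = n_agents, replicates = replicates, seed = seed),
            class = "mean_field_report")
}

#' @export
print.mean_field_report <- function(x, ...) {
  cat("<mean_field_report>", x$replicates, "replicates vs ODE on",
      length(x$time), "time points:\n",
      " max |z| =", signif(x$max_abs_z, 4),
      "| mean z^2 =", signif(x$mean_sq_z, 4),
      "|", nrow(x$flagged), "state/time points flagged (|z| > 4)\n")
  invisible(x)
}
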