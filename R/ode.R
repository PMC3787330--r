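# Population backend: compile a statechart into the linear compartmental
# system implementing the conveyor-belt flux law
#
#   dx_i/dt = 2*gamma*p*x_{i-1} - (p + d + u_i) * x_i  (+ sources)
#
# and integrate it. Because rate expressions are restricted to
# affine/table-lookup coefficients, every compiled system is linear,
# dx/dt = A x + s, and is integrated *exactly* with the matrix exponential
# of an augmented system (states, cumulative outflow channels, constant
# source), piecewise across gamma(t) breakpoints. Cumulative export/death
# channels evolve as dc/dt = C x and share the same exponential.

GANCICLOVIR_CHANNEL <- "apoptosis:ganciclovir"

# Enumerate every individual flux of the compiled system as one row:
# type in {flow, division, export, death, source}; src/dst are 1-based flat
# rows (NA for sources / EXIT); rate is the numeric coefficient evaluated
# at the source state's generation index gi; expr keeps the symbolic form.
enumerate_fluxes <- function(model, flat = flatten_product_states(model)) {
  params <- model$parameters
  gi_all <- generation_index(model, flat)
  rows <- vector("list", 256L); nr <- 0L
  push <- function(row) { nr <<- nr + 1L; rows[[nr]] <<- row }
  tuples <- as.matrix(flat[names(model$regions)])
  for (k in seq_len(nrow(flat))) {
    tuple <- tuples[k, ]
    gi <- gi_all[[k]]
    for (r in model$regions) {
      for (tr in r$transitions) {
        if (tr$from != tuple[[r$name]]) next
        if (!is.null(tr$guard) && !eval_predicate(parse_predicate(tr$guard), tuple)) next
        rate <- eval_rate(tr$rate, params, gi)
        # zero-rate fluxes are kept: they pin down the channel structure
        # and the exported equations stay parameter-named
        if (tr$kind %in% c("export", "death")) {
          push(list(type = tr$kind, src = k, dst = NA_integer_, rate = rate,
                    expr = tr$rate, gi = gi,
                    channel = paste(tr$kind, r$name, tr$from, sep = ":")))
        } else {
          dst <- resolve_target(flat, tuple, r$name, tr$from, tr$to, tr$reset,
                                saturate = tr$kind == "division")
          if (is.na(dst))
            stop("transition '", tr$from, " -> ", tr$to, "' in region '", r$name,
                 "' targets an excluded flat state from '", flat$name[[k]], "'",
                 call. = FALSE)
          push(list(type = tr$kind, src = k, dst = dst, rate = rate,
                    expr = tr$rate, gi = gi, channel = NA_character_))
        }
      }
    }
  }
  for (s in model$sources) {
    rate <- eval_rate(s$rate, params, 1L)
    for (k in match_flat_states(flat, s$into))
      push(list(type = "source", src = NA_integer_, dst = k, rate = rate,
                expr = s$rate, gi = 1L, channel = NA_character_))
  }
  if (nr == 0L)
    return(data.frame(type = character(), src = integer(), dst = integer(),
                      rate = numeric(), expr = character(), gi = integer(),
                      channel = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(rows[seq_len(nr)], function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Compile a statechart into a population ODE system
#'
#' Every flat state becomes one scalar ODE. Flow transitions move mass at
#' their rate; division transitions remove the parent at rate `p` and
#' inject `2*gamma*p` into the daughter state (the generation successor,
#' with the cell-cycle reset applied); with gamma = 0 the missing daughters
#' accrue to the ganciclovir-apoptosis outflow channel, so mass is always
#' accounted. Export and death transitions feed named cumulative outflow
#' channels.
#'
#' @param model a valid [statechart_model()].
#' @return an `ode_system`: list with `model`, `flat` (flat-state table),
#'   `fluxes` (per-flux table), `channels` (channel names).
#' @export
compile_population_ode <- function(model) {
  diags <- validate_model(model)
  if (any(diags$severity == "error"))
    stop("model has validation errors: ", diags$message[diags$severity == "error"][[1L]],
         call. = FALSE)
  flat <- flatten_product_states(model)
  fluxes <- enumerate_fluxes(model, flat)
  channels <- unique(stats::na.omit(fluxes$channel))
  if (any(fluxes$type == "division")) channels <- c(channels, GANCICLOVIR_CHANNEL)
  structure(list(model = model, flat = flat, fluxes = fluxes,
                 channels = as.character(channels)),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system>", x$model$name, ":", nrow(x$flat), "equations,",
      nrow(x$fluxes), "fluxes,", length(x$channels), "outflow channels\n")
  invisible(x)
}

# A, s and the channel matrix C for a given gamma value.
ode_matrices <- function(system, gamma = 1) {
  n <- nrow(system$flat)
  m <- length(system$channels)
  A <- matrix(0, n, n, dimnames = list(system$flat$name, system$flat$name))
  s <- stats::setNames(numeric(n), system$flat$name)
  C <- matrix(0, m, n, dimnames = list(system$channels, system$flat$name))
  fx <- system$fluxes
  for (j in seq_len(nrow(fx))) {
    r <- fx$rate[[j]]
    switch(fx$type[[j]],
      flow = {
        A[fx$dst[[j]], fx$src[[j]]] <- A[fx$dst[[j]], fx$src[[j]]] + r
        A[fx$src[[j]], fx$src[[j]]] <- A[fx$src[[j]], fx$src[[j]]] - r
      },
      division = {
        A[fx$dst[[j]], fx$src[[j]]] <- A[fx$dst[[j]], fx$src[[j]]] + 2 * gamma * r
        A[fx$src[[j]], fx$src[[j]]] <- A[fx$src[[j]], fx$src[[j]]] - r
        C[GANCICLOVIR_CHANNEL, fx$src[[j]]] <- C[GANCICLOVIR_CHANNEL, fx$src[[j]]] +
          (1 - gamma) * r
      },
      export = ,
      death = {
        A[fx$src[[j]], fx$src[[j]]] <- A[fx$src[[j]], fx$src[[j]]] - r
        C[fx$channel[[j]], fx$src[[j]]] <- C[fx$channel[[j]], fx$src[[j]]] + r
      },
      source = s[[fx$dst[[j]]]] <- s[[fx$dst[[j]]]] + r
    )
  }
  list(A = A, s = s, C = C)
}

#' Right-hand side of a compiled system
#'
#' @param system an `ode_system`.
#' @param x state vector (length = number of flat states).
#' @param gamma division-survival switch in `{0, 1}`.
#' @return dx/dt as a numeric vector.
#' @export
ode_rhs <- function(system, x, gamma = 1) {
  M <- ode_matrices(system, gamma)
  as.numeric(M$A %*% x + M$s)
}

# ---- gamma schedules ---------------------------------------------------

gamma_value_at <- function(gamma, t) {
  if (inherits(gamma, "gamma_schedule")) {
    w <- gamma$windows
    if (nrow(w) > 0 && any(t >= w$t_on & t < w$t_off)) 0 else 1
  } else as.numeric(gamma)
}

gamma_breakpoints <- function(gamma, t0, t1) {
  if (!inherits(gamma, "gamma_schedule")) return(numeric())
  b <- sort(unique(c(gamma$windows$t_on, gamma$windows$t_off)))
  b[b > t0 & b < t1]
}

# ---- integration -------------------------------------------------------

#' Integrate a compiled system
#'
#' Exact piecewise propagation: between consecutive time points the
#' augmented vector (x, cumulative channels, 1) is advanced with the matrix
#' exponential of the augmented generator, so linear systems are solved to
#' machine precision with no step-size error. Breakpoints of a
#' piecewise-constant gamma(t) schedule are inserted internally, so the
#' ganciclovir on/off discontinuity costs no accuracy.
#'
#' @param system an `ode_system` from [compile_population_ode()].
#' @param y0 non-negative initial counts: either a full vector (length =
#'   flat states, optionally named by flat-state name) or a named vector of
#'   a subset of flat-state names (others zero).
#' @param t_grid strictly increasing time points (model time units; days in
#'   the shipped thymus models). `y0` is the state at `t_grid[1]`.
#' @param gamma a number in `[0, 1]` or a [ganciclovir_schedule()].
#' @return a `statechart_trajectory`: list with `time`, `values` (time x
#'   flat-state matrix, negative round-off clipped to 0 on output) and
#'   `channels` (cumulative outflow per channel).
#' @export
integrate_ode <- function(system, y0, t_grid, gamma = 1) {
  n <- nrow(system$flat)
  if (!is.null(names(y0))) {
    bad <- setdiff(names(y0), system$flat$name)
    if (length(bad) > 0) stop("unknown flat state in y0: ", bad[[1L]], call. = FALSE)
    full <- stats::setNames(numeric(n), system$flat$name)
    full[names(y0)] <- y0
    y0 <- full
  }
  stopifnot(length(y0) == n, all(y0 >= 0))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing", call. = FALSE)
  m <- length(system$channels)
  times <- sort(unique(c(t_grid, gamma_breakpoints(gamma, min(t_grid), max(t_grid)))))
  propagators <- new.env(parent = emptyenv())
  aug <- function(g) {
    M <- ode_matrices(system, g)
    P <- matrix(0, n + m + 1L, n + m + 1L)
    P[seq_len(n), seq_len(n)] <- M$A
    P[seq_len(n), n + m + 1L] <- M$s
    if (m > 0) P[n + seq_len(m), seq_len(n)] <- M$C
    P
  }
  z <- c(as.numeric(y0), numeric(m), 1)
  out_vals <- matrix(NA_real_, length(times), n)
  out_chan <- matrix(NA_real_, length(times), m)
  store <- function(row, z) {
    out_vals[row, ] <<- z[seq_len(n)]
    if (m > 0) out_chan[row, ] <<- z[n + seq_len(m)]
  }
  t0 <- t_grid[[1L]]
  if (times[[1L]] == t0) store(1L, z)
  start <- if (times[[1L]] == t0) 2L else 1L
  prev_t <- t0
  for (idx in seq(from = start, length.out = length(times) - start + 1L)) {
    tt <- times[[idx]]
    dt <- tt - prev_t
    g <- gamma_value_at(gamma, prev_t)
    key <- paste(signif(g, 15), signif(dt, 15))
    P <- propagators[[key]]
    if (is.null(P)) {
      P <- tryCatch(as.matrix(Matrix::expm(Matrix::Matrix(aug(g) * dt))),
                    error = function(e)
                      stop("solver failure at t = ", tt, ": ", conditionMessage(e),
                           call. = FALSE))
      propagators[[key]] <- P
    }
    z <- as.numeric(P %*% z)
    store(idx, z)
    prev_t <- tt
  }
  keep <- match(t_grid, times)
  values <- pmax(out_vals[keep, , drop = FALSE], 0)
  channels <- if (m > 0) pmax(out_chan[keep, , drop = FALSE], 0) else
    matrix(0, length(t_grid), 0)
  colnames(values) <- system$flat$name
  colnames(channels) <- system$channels
  structure(list(time = t_grid, values = values, channels = channels,
                 flat = system$flat, system = system, gamma = gamma),
            class = "statechart_trajectory")
}

#' @export
print.statechart_trajectory <- function(x, ...) {
  cat("<statechart_trajectory>", length(x$time), "time points x",
      ncol(x$values), "states; t in [", x$time[[1L]], ",",
      x$time[[length(x$time)]], "]\n")
  invisible(x)
}

#' Sum a trajectory over a group of flat states
#'
#' @param traj a `statechart_trajectory` (or an `abm_run`, which shares the
#'   `time`/`values` layout).
#' @param grouping a selector: predicate string over regions (e.g.
#'   `"differentiation == SP4"`), character vector of flat-state names, or
#'   logical/integer index. Default: all states.
#' @return data.frame with columns `time` and `total`.
#' @export
total_counts <- function(traj, grouping = NULL) {
  flat <- traj$flat
  idx <- if (is.null(grouping)) seq_len(ncol(traj$values)) else
    match_flat_states(flat, grouping)
  if (length(idx) == 0L) stop("grouping matches no flat state", call. = FALSE)
  data.frame(time = traj$time,
             total = rowSums(traj$values[, idx, drop = FALSE]))
}

# Instantaneous outflow (cells/time) through one cumulative channel:
# the channel row of C applied to x(t).
channel_flux <- function(traj, channel) {
  system <- traj$system
  if (!(channel %in% system$channels)) stop("unknown channel: ", channel, call. = FALSE)
  fx <- system$fluxes
  flux <- numeric(length(traj$time))
  if (channel == GANCICLOVIR_CHANNEL) {
    rows <- which(fx$type == "division")
    g <- vapply(traj$time, function(t) gamma_value_at(traj$gamma, t), 0)
    for (j in rows) flux <- flux + (1 - g) * fx$rate[[j]] * traj$values[, fx$src[[j]]]
  } else {
    for (j in which(!is.na(fx$channel) & fx$channel == channel))
      flux <- flux + fx$rate[[j]] * traj$values[, fx$src[[j]]]
  }
  flux
}

# ---- equation export ---------------------------------------------------

#' Export the compiled system as human-readable equations
#'
#' One line per flat state, written with parameter names (not numbers) and
#' the generation index substituted, e.g.
#' `d(DN.SM.g2)/dt = (Pn)*DN.G0.g2 - (Dn + uN0 + us*(2 - 1) + Pn)*DN.SM.g2`.
#' Each right-hand side is valid R arithmetic over parameter names, `gamma`
#' and flat-state names, so the text can be re-evaluated independently.
#'
#' @param system an `ode_system`.
#' @return character vector, one equation line per flat state.
#' @export
export_equations <- function(system) {
  fx <- system$fluxes
  flat <- system$flat
  n <- nrow(flat)
  lines <- character(n)
  term <- function(j) paste0("(", rate_text_at(fx$expr[[j]], fx$gi[[j]]), ")")
  for (k in seq_len(n)) {
    inflow <- character()
    for (j in which(!is.na(fx$dst) & fx$dst == k)) {
      inflow <- c(inflow, switch(fx$type[[j]],
        source = rate_text_at(fx$expr[[j]], fx$gi[[j]]),
        division = paste0("2*gamma*", term(j), "*", flat$name[[fx$src[[j]]]]),
        paste0(term(j), "*", flat$name[[fx$src[[j]]]])))
    }
    outs <- which(!is.na(fx$src) & fx$src == k & fx$type != "source")
    out_terms <- vapply(outs, function(j) rate_text_at(fx$expr[[j]], fx$gi[[j]]), "")
    rhs <- paste(inflow, collapse = " + ")
    if (length(out_terms) > 0) {
      neg <- paste0("(", paste(out_terms, collapse = " + "), ")*", flat$name[[k]])
      rhs <- if (nzchar(rhs)) paste(rhs, "-", neg) else paste0("-", neg)
    }
    if (!nzchar(rhs)) rhs <- "0"
    lines[[k]] <- paste0("d(", flat$name[[k]], ")/dt = ", rhs)
  }
  lines
}
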