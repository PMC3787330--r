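# The concrete conveyor-belt thymus model: thymocytes progress DN ->
# DP_early -> DP_late -> SP4/SP8 while, in parallel, switching between
# quiescence (G0) and the dividing cycle phases (SM) and advancing through
# numbered cell generations on division. Differentiation propensity u(i)
# increases with generation, so cells become ever more likely to move to
# the next phenotypic compartment as they divide -- the conveyor belt.
# Ganciclovir treatment (gamma = 0) kills any cell that completes S/M;
# late-DP cells are exempt because they are quiescent-only.

#' Conveyor-belt structural configuration
#'
#' Generations per stage and the affine differentiation-rate profile.
#' The default decomposition (DN 4 generations, DP_early 6, DP_late 2
#' quiescent-only, SP4 2, SP8 2) flattens to exactly 30 product states:
#' 8 + 12 + 2 + 4 + 4.
#'
#' @param n_N,n_P,n_L,n_4,n_8 generations for DN, DP_early, DP_late, SP4,
#'   SP8 (each >= 1).
#' @param u0 named base differentiation rates (1/day) for the stages that
#'   differentiate by generation (DN, DP_early).
#' @param slope common slope `s` (1/day per generation) of
#'   `u_i = u0 + s*(i-1)`.
#' @param late_DP_quiescent_only if `TRUE` (default) the DP_late x SM
#'   combinations are excluded: late DP cells never cycle, which is also
#'   what shields them from ganciclovir.
#' @return a `conveyor_config` list.
#' @export
conveyor_config <- function(n_N = 4L, n_P = 6L, n_L = 2L, n_4 = 2L, n_8 = 2L,
                            u0 = c(DN = 0.05, DP_early = 0.05),
                            slope = 0.05,
                            late_DP_quiescent_only = TRUE) {
  gens <- c(DN = n_N, DP_early = n_P, DP_late = n_L, SP4 = n_4, SP8 = n_8)
  if (any(gens < 1L)) stop("generation counts must be >= 1", call. = FALSE)
  if (any(u0 < 0) || slope < 0) stop("u-function parameters must be >= 0", call. = FALSE)
  structure(list(gens = gens, u0 = u0, slope = slope,
                 late_DP_quiescent_only = isTRUE(late_DP_quiescent_only)),
            class = "conveyor_config")
}

#' Conveyor-belt rate parameters
#'
#' All rates in 1/day; `Sn` in cells/day. Defaults are placeholders of
#' plausible magnitude giving a stable steady state (the source models'
#' fitted values are not part of this package); every value can be
#' overridden here or in the shipped model document.
#'
#' @param Sn constant hematopoietic progenitor influx into (DN, G0, g1).
#' @param Pn,Pp,Ps proliferation rates for DN, DP and SP stages: both the
#'   G0 -> SM entry rate and the S/M division-completion rate.
#' @param Dn,Dp,Ds natural death rates per stage.
#' @param a4,a8 selection/differentiation rates DP_late -> SP4 and -> SP8.
#' @param Us4,Us8 egress rates SP4/SP8 -> periphery; scalar or
#'   per-generation vector (used as `Us4[i]`).
#' @param gamma division-survival switch: 1 = two daughters, 0 =
#'   ganciclovir apoptosis of dividing cells.
#' @return a `conveyor_params` list.
#' @export
conveyor_params <- function(Sn = 1e4, Pn = 0.2, Pp = 0.2, Ps = 0.2,
                            Dn = 0.05, Dp = 0.05, Ds = 0.05,
                            a4 = 0.08, a8 = 0.02,
                            Us4 = 0.5, Us8 = 0.5, gamma = 1) {
  p <- list(Sn = Sn, Pn = Pn, Pp = Pp, Ps = Ps, Dn = Dn, Dp = Dp, Ds = Ds,
            a4 = a4, a8 = a8, Us4 = Us4, Us8 = Us8, gamma = gamma)
  if (any(unlist(p) < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (!(gamma %in% c(0, 1))) stop("gamma must be 0 or 1", call. = FALSE)
  structure(p, class = "conveyor_params")
}

#' Generation-dependent differentiation rate u_i
#'
#' `u_i = u0_stage + slope * (i - 1)`: non-decreasing in the generation
#' index, so cells grow more likely to differentiate as they divide.
#'
#' @param stage `"DN"` or `"DP_early"` (the stages that differentiate with
#'   a generation-indexed rate).
#' @param i generation index, `1 <= i <= n_stage`.
#' @param config a [conveyor_config()].
#' @return u_i in 1/day.
#' @export
differentiation_rate <- function(stage, i, config = conveyor_config()) {
  if (!(stage %in% names(config$u0))) stop("unknown stage: ", stage, call. = FALSE)
  if (any(i < 1L) || any(i > config$gens[[stage]]))
    stop("generation index out of range for stage ", stage, call. = FALSE)
  unname(config$u0[[stage]] + config$slope * (i - 1))
}

#' Build the conveyor-belt statechart
#'
#' Three orthogonal regions: `differentiation` (DN, DP_early, DP_late,
#' SP4, SP8), `cell_cycle` (G0, SM) and `generation` (g1..gmax). Division
#' transitions advance the generation (saturating at each stage's cap),
#' are guarded on `cell_cycle == SM`, and reset daughters to G0.
#' Stage-generation combinations beyond a stage's generation count -- and
#' DP_late x SM under the quiescence exemption -- are declared exclusions,
#' so the default configuration flattens to exactly 30 states.
#'
#' @param config a [conveyor_config()].
#' @param params a [conveyor_params()].
#' @return a [statechart_model()].
#' @export
build_conveyor_model <- function(config = conveyor_config(),
                                 params = conveyor_params()) {
  gens <- config$gens
  gmax <- max(gens)
  gstates <- paste0("g", seq_len(gmax))
  stages <- names(gens)
  prolif <- c(DN = "Pn", DP_early = "Pp", SP4 = "Ps", SP8 = "Ps")
  if (!config$late_DP_quiescent_only) prolif <- c(prolif, DP_late = "Pp")

  parameters <- unclass(params)
  parameters$uN0 <- unname(config$u0[["DN"]])
  parameters$uP0 <- unname(config$u0[["DP_early"]])
  parameters$us <- config$slope

  # DP_early -> DP_late carries the generation over (capped at the late-DP
  # count) and, under the quiescence exemption, also leaves the cycle; one
  # guarded transition per source generation expresses the cap.
  late_entry <- lapply(seq_len(gmax), function(i) {
    transition("DP_early", "DP_late", "uP0 + us*(i-1)",
               guard = paste0("generation == g", i),
               reset = c(generation = paste0("g", min(i, gens[["DP_late"]])),
                         if (config$late_DP_quiescent_only) c(cell_cycle = "G0")))
  })
  diff_trans <- c(late_entry, list(
    transition("DN", "DP_early", "uN0 + us*(i-1)", reset = c(generation = "g1")),
    transition("DP_late", "SP4", "a4", reset = c(generation = "g1")),
    transition("DP_late", "SP8", "a8", reset = c(generation = "g1")),
    transition("DN", EXIT_STATE, "Dn", kind = "death"),
    transition("DP_early", EXIT_STATE, "Dp", kind = "death"),
    transition("DP_late", EXIT_STATE, "Dp", kind = "death"),
    transition("SP4", EXIT_STATE, "Ds", kind = "death"),
    transition("SP8", EXIT_STATE, "Ds", kind = "death"),
    transition("SP4", EXIT_STATE, "Us4", kind = "export"),
    transition("SP8", EXIT_STATE, "Us8", kind = "export")
  ))
  cycle_trans <- lapply(names(prolif), function(st)
    transition("G0", "SM", prolif[[st]],
               guard = paste0("differentiation == ", st)))
  div_trans <- list()
  for (st in names(prolif)) {
    for (i in seq_len(gmax)) {
      to <- if (i < gmax) gstates[[i + 1L]] else gstates[[gmax]]
      div_trans[[length(div_trans) + 1L]] <- transition(
        gstates[[i]], to, prolif[[st]], kind = "division",
        guard = paste0("cell_cycle == SM && differentiation == ", st),
        reset = c(cell_cycle = "G0"))
    }
  }

  exclusions <- character()
  for (st in stages) {
    if (gens[[st]] < gmax)
      exclusions <- c(exclusions, paste0("differentiation == ", st,
                                         " && generation == ",
                                         gstates[seq(gens[[st]] + 1L, gmax)]))
  }
  if (config$late_DP_quiescent_only)
    exclusions <- c(exclusions, "differentiation == DP_late && cell_cycle == SM")

  model <- statechart_model(
    name = "conveyor_belt",
    parameters = parameters,
    regions = list(
      region("differentiation", stages, initial = "DN", transitions = diff_trans),
      region("cell_cycle", c("G0", "SM"), initial = "G0", transitions = cycle_trans),
      region("generation", gstates, initial = "g1", transitions = div_trans)
    ),
    sources = list(list(
      into = "differentiation == DN && cell_cycle == G0 && generation == g1",
      rate = "Sn")),
    exclusions = exclusions
  )
  n_flat <- nrow(flatten_product_states(model))
  if (n_flat != 30L)
    warning("non-default conveyor configuration: ", n_flat,
            " flat states (default profile has 30)", call. = FALSE)
  model
}

# ---- ganciclovir perturbation -----------------------------------------

#' Ganciclovir treatment schedule
#'
#' A piecewise-constant gamma(t): 0 inside the treatment windows (cells
#' completing S/M die by apoptosis instead of dividing), 1 outside.
#' Late-DP cells are structurally exempt: under the default configuration
#' they have no S/M states, so the switch never touches them.
#'
#' @param windows two-column matrix/data.frame (`t_on`, `t_off`) or a list
#'   of `c(t_on, t_off)` pairs; windows must be disjoint with
#'   `t_on < t_off`. Empty means gamma(t) = 1 always.
#' @return a `gamma_schedule` usable as the `gamma` argument of
#'   [integrate_ode()] and [run_abm()]. Evaluate it with
#'   [gamma_at()].
#' @export
ganciclovir_schedule <- function(windows = NULL) {
  if (is.null(windows) || (is.data.frame(windows) && nrow(windows) == 0L)) {
    w <- data.frame(t_on = numeric(), t_off = numeric())
  } else {
    if (is.list(windows) && !is.data.frame(windows))
      windows <- do.call(rbind, windows)
    w <- as.data.frame(windows)
    names(w) <- c("t_on", "t_off")
    if (any(w$t_on >= w$t_off)) stop("each window needs t_on < t_off", call. = FALSE)
    w <- w[order(w$t_on), , drop = FALSE]
    if (nrow(w) > 1L && any(w$t_on[-1L] < w$t_off[-nrow(w)]))
      stop("overlapping ganciclovir windows", call. = FALSE)
  }
  structure(list(windows = w), class = "gamma_schedule")
}

#' @rdname ganciclovir_schedule
#' @param params a [conveyor_params()] (carried along unmodified; the
#'   schedule only drives gamma).
#' @param schedule windows as in `ganciclovir_schedule()`.
#' @export
apply_ganciclovir <- function(params, schedule) {
  if (inherits(schedule, "gamma_schedule")) schedule else ganciclovir_schedule(schedule)
}

#' Evaluate gamma(t)
#' @param gamma a number or a `gamma_schedule`.
#' @param t time(s).
#' @return gamma value(s) in `{0, 1}` (or the constant).
#' @export
gamma_at <- function(gamma, t) {
  vapply(t, function(tt) gamma_value_at(gamma, tt), 0)
}

# ---- outputs -----------------------------------------------------------

#' Thymic export flux
#'
#' Instantaneous egress to the periphery, `flux4(t) = sum_i Us4(i) *
#' x_SP4,i(t)` and likewise for SP8; the cumulative export channels of the
#' trajectory are the time integrals of these fluxes.
#'
#' @param traj a `statechart_trajectory` from a conveyor model.
#' @return data.frame with columns `time`, `SP4`, `SP8` (cells/day).
#' @export
thymic_export_flux <- function(traj) {
  ch4 <- "export:differentiation:SP4"
  ch8 <- "export:differentiation:SP8"
  if (!all(c(ch4, ch8) %in% traj$system$channels))
    stop("trajectory lacks SP export channels (not a conveyor model?)", call. = FALSE)
  data.frame(time = traj$time,
             SP4 = channel_flux(traj, ch4),
             SP8 = channel_flux(traj, ch8))
}

#' Run the ganciclovir depletion experiment
#'
#' Integrates the model to its pre-treatment steady state trajectory, then
#' applies gamma = 0 during `[t_on, t_off)` and follows the recovery.
#'
#' @param model a conveyor [statechart_model()] (default: shipped model).
#' @param t_on,t_off treatment window (days).
#' @param t_end end of simulation (days).
#' @param dt output resolution (days).
#' @param y0 initial counts; default: the model's steady state under
#'   constant influx.
#' @return list with `trajectory`, `stage_totals` (data.frame), and
#'   `export_flux`.
#' @export
run_depletion_experiment <- function(model = build_conveyor_model(),
                                     t_on, t_off, t_end = t_off + 200,
                                     dt = 0.5, y0 = NULL) {
  system <- compile_population_ode(model)
  if (is.null(y0)) y0 <- steady_state(system)
  sched <- ganciclovir_schedule(list(c(t_on, t_off)))
  t_grid <- seq(0, t_end, by = dt)
  traj <- integrate_ode(system, y0, t_grid, gamma = sched)
  stages <- model$regions[["differentiation"]]$states
  stage_totals <- data.frame(time = traj$time)
  for (st in stages)
    stage_totals[[st]] <- total_counts(traj, paste0("differentiation == ", st))$total
  list(trajectory = traj, stage_totals = stage_totals,
       export_flux = thymic_export_flux(traj))
}

#' Algebraic steady state of a compiled system
#'
#' Solves `A x + s = 0` for the unique fixed point of the linear system
#' (exists when every compartment has positive total outflow).
#'
#' @param system an `ode_system`.
#' @param gamma division-survival switch.
#' @return named non-negative state vector.
#' @export
steady_state <- function(system, gamma = 1) {
  M <- ode_matrices(system, gamma)
  x <- solve(M$A, -M$s)
  stats::setNames(as.numeric(x), system$flat$name)
}
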