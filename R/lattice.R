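# Spatial model: thymocytes migrate on a 2-D lattice through an epithelial
# network, guided by static chemokine gradients (CXCL12 toward cortex for
# DN/DP, CCL19/CCL21 toward medulla for SP, S1P toward the exit row for
# mature SP). While adjacent to epithelium a cell stochastically binds via
# TCR/MHC; its interaction log (count, cumulative bound time, longest
# single interaction) drives positive selection, death by neglect,
# negative selection, and the signal-duration CD4/CD8 lineage choice.
#
# Geometry: rectangular, 0-noise greedy moves use the 8-site Moore
# neighborhood; anatomy is banded (subcapsular rows on top, cortex,
# medulla, with the bottom row as the egress sites on the medullary edge).

#' Selection thresholds
#'
#' @param theta_pos interaction-count thresholds for positive selection,
#'   named for `DP` and `SP`.
#' @param T_neglect time limits (per stage) to reach `theta_pos` before
#'   apoptosis by neglect.
#' @param T_neg cumulative bound-time ceiling triggering negative
#'   selection.
#' @param tau_lineage longest-interaction duration cutoff: at or above it
#'   the positively selected DP becomes CD4, below it CD8.
#' @return a `selection_thresholds` list.
#' @export
selection_thresholds <- function(theta_pos = c(DP = 5, SP = 3),
                                 T_neglect = c(DP = 30, SP = 20),
                                 T_neg = 12, tau_lineage = 2) {
  stopifnot(all(theta_pos > 0), all(T_neglect > 0), T_neg > 0, tau_lineage > 0)
  structure(list(theta_pos = theta_pos, T_neglect = T_neglect,
                 T_neg = T_neg, tau_lineage = tau_lineage),
            class = "selection_thresholds")
}

#' Build the 2-D thymic lattice
#'
#' Three horizontal bands (subcapsular at the top, cortex, medulla) with
#' the bottom row -- the outer medullary edge -- labelled `exit`.
#' Epithelial cells are placed uniformly at random at exactly
#' `floor(epithelial_fraction * width * height)` sites. Chemokine fields
#' are static analytic gradients `max(0, 1 - d/D)` of the Chebyshev
#' distance `d` to the attractor band, with `D = max(width, height)`.
#'
#' @param width,height site counts (>= 8 each).
#' @param epithelial_fraction fraction of sites holding an epithelial cell
#'   (0 < f < 0.5).
#' @param seed integer; the layout is deterministic per seed.
#' @param bands fractions of rows for the subcapsular and cortex bands.
#' @return a `thymus_lattice`: list with `region` (character matrix),
#'   `epithelial` (integer id matrix, NA = none), `occupant` (thymocyte id
#'   matrix), `fields` (list of concentration matrices), `exit_sites`.
#' @export
build_thymus_lattice <- function(width = 50L, height = 50L,
                                 epithelial_fraction = 0.15, seed = 1L,
                                 bands = c(subcapsular = 0.15, cortex = 0.45)) {
  if (width < 8L || height < 8L) stop("lattice must be at least 8 x 8", call. = FALSE)
  if (epithelial_fraction <= 0 || epithelial_fraction >= 0.5)
    stop("epithelial_fraction must be in (0, 0.5)", call. = FALSE)
  n_sc <- max(1L, round(height * bands[[1L]]))
  n_cx <- max(1L, round(height * bands[[2L]]))
  if (n_sc + n_cx > height - 2L) stop("bands leave no room for medulla", call. = FALSE)
  region <- matrix("medulla", height, width)
  region[seq_len(n_sc), ] <- "subcapsular"
  region[n_sc + seq_len(n_cx), ] <- "cortex"
  region[height, ] <- "exit"
  n_ep <- floor(epithelial_fraction * width * height)
  epithelial <- matrix(NA_integer_, height, width)
  sites <- with_seed(seed, sample.int(width * height, n_ep))
  epithelial[sites] <- seq_len(n_ep)
  rowdist <- function(rows) {
    d <- vapply(seq_len(height), function(r) min(abs(r - rows)), 0)
    matrix(rep(d, width), height, width)
  }
  D <- max(width, height)
  # NB: the matrix must be pmax()'s first argument to keep its dim attributes
  grad <- function(rows) pmax(1 - rowdist(rows) / D, 0)
  fields <- list(
    CXCL12 = grad(which(apply(region == "cortex", 1, any))),
    CCL19_21 = grad(which(apply(region == "medulla", 1, any))),
    S1P = grad(height)
  )
  structure(list(width = width, height = height, region = region,
                 epithelial = epithelial, occupant = matrix(NA_integer_, height, width),
                 fields = fields,
                 exit_sites = cbind(row = height, col = seq_len(width)),
                 seed = seed),
            class = "thymus_lattice")
}

#' @export
print.thymus_lattice <- function(x, ...) {
  cat("<thymus_lattice>", x$height, "x", x$width, "sites;",
      sum(!is.na(x$epithelial)), "epithelial cells;",
      sum(!is.na(x$occupant)), "thymocytes\n")
  invisible(x)
}

#' Create a thymocyte agent
#'
#' @param id integer id.
#' @param pos site `c(row, col)`.
#' @param stage one of `DN`, `DP`, `SP4`, `SP8`.
#' @return a `thymocyte` with an empty interaction log.
#' @export
new_thymocyte <- function(id, pos, stage = "DN") {
  structure(list(id = id, stage = stage, mature = FALSE,
                 pos = as.integer(pos), bound_to = NA_integer_,
                 total_bound = 0, n_interactions = 0L,
                 longest = 0, current = 0,
                 partners = integer(), stage_clock = 0, cortex_time = 0,
                 fate = "developing"),
            class = "thymocyte")
}

#' Chemokine guiding a differentiation stage
#'
#' DN and DP follow CXCL12 (cortex-directed); immature SP follow
#' CCL19/CCL21 (medulla-directed); mature SP flagged for egress follow S1P
#' (exit-directed).
#'
#' @param stage `DN`, `DP`, `SP4` or `SP8`.
#' @param mature whether an SP cell has passed its positive-selection
#'   threshold and is egress-competent.
#' @return chemokine kind: `"CXCL12"`, `"CCL19_21"` or `"S1P"`.
#' @export
stage_chemokine <- function(stage, mature = FALSE) {
  if (!(stage %in% c("DN", "DP", "SP4", "SP8")))
    stop("unknown stage: ", stage, call. = FALSE)
  if (stage %in% c("DN", "DP")) return("CXCL12")
  if (mature) "S1P" else "CCL19_21"
}

# In-bounds Moore (8-site) neighbors of a site; reflecting boundaries.
neighbors8 <- function(lattice, pos) {
  r <- pos[[1L]] + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  c <- pos[[2L]] + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  ok <- r >= 1L & r <= lattice$height & c >= 1L & c <= lattice$width
  cbind(row = r[ok], col = c[ok])
}

#' Move an unbound agent one site along its chemokine gradient
#'
#' With probability `1 - noise` the agent moves greedily to the vacant
#' Moore neighbor with the highest stage-appropriate chemokine
#' concentration, provided it strictly exceeds the current site's (ties
#' broken uniformly at random; stays put otherwise). With probability
#' `noise` it moves to a uniformly random vacant neighbor. Never leaves
#' the lattice or enters a site already holding a thymocyte.
#'
#' @param agent a [new_thymocyte()]; must be unbound.
#' @param lattice a [build_thymus_lattice()].
#' @param noise exploration probability in `[0, 1]`.
#' @return the chosen site `c(row, col)` (possibly the current one).
#' @export
move_agent <- function(agent, lattice, noise = 0.2) {
  if (!is.na(agent$bound_to))
    stop("bound agents do not move", call. = FALSE)
  nb <- neighbors8(lattice, agent$pos)
  vac <- is.na(lattice$occupant[nb])
  nb <- nb[vac, , drop = FALSE]
  if (nrow(nb) == 0L) return(agent$pos)
  if (stats::runif(1) < noise)
    return(nb[sample.int(nrow(nb), 1L), ])
  field <- lattice$fields[[stage_chemokine(agent$stage, agent$mature)]]
  conc <- field[nb]
  here <- field[agent$pos[[1L]], agent$pos[[2L]]]
  best <- max(conc)
  if (best <= here) return(agent$pos)
  top <- which(conc == best)
  pick <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
  nb[pick, ]
}

#' Update an agent's TCR/MHC binding state for one step
#'
#' An unbound agent adjacent to at least one epithelial cell binds with
#' probability `rate_to_prob(k_on, dt)` to a uniformly chosen adjacent
#' epithelial cell (interaction count +1, a new partner is recorded). A
#' bound agent unbinds with probability `rate_to_prob(k_off, dt)` (the
#' longest-interaction record is updated); while it stays bound, the
#' cumulative bound time and the current interaction's duration grow by
#' `dt`.
#'
#' @param agent a [new_thymocyte()].
#' @param lattice a [build_thymus_lattice()].
#' @param dt step length.
#' @param rates list with `k_on` and `k_off` (1/time).
#' @return the updated agent.
#' @export
update_binding <- function(agent, lattice, dt, rates = list(k_on = 5, k_off = 1)) {
  if (!is.na(agent$bound_to)) {
    if (stats::runif(1) < rate_to_prob(rates$k_off, dt)) {
      agent$longest <- max(agent$longest, agent$current)
      agent$current <- 0
      agent$bound_to <- NA_integer_
    } else {
      agent$total_bound <- agent$total_bound + dt
      agent$current <- agent$current + dt
    }
    return(agent)
  }
  nb <- neighbors8(lattice, agent$pos)
  eps <- lattice$epithelial[nb]
  eps <- eps[!is.na(eps)]
  if (length(eps) == 0L) return(agent)
  if (stats::runif(1) < rate_to_prob(rates$k_on, dt)) {
    partner <- if (length(eps) == 1L) eps else eps[sample.int(length(eps), 1L)]
    agent$bound_to <- partner
    agent$n_interactions <- agent$n_interactions + 1L
    agent$partners <- c(agent$partners, partner)
    agent$current <- 0
  }
  agent
}

#' Selection outcome for an agent's interaction log
#'
#' Evaluated in priority order: (1) cumulative bound time above `T_neg`
#' means the TCR signal lasted too long -- negative selection, even if the
#' positive threshold was also reached; (2) interaction count at or above
#' `theta_pos` -- positive selection, enabling differentiation; (3) stage
#' clock beyond `T_neglect` without reaching the threshold -- apoptosis by
#' neglect; otherwise the cell keeps developing.
#'
#' @param agent a [new_thymocyte()] (its log fields are read).
#' @param thresholds a [selection_thresholds()].
#' @param stage `"DP"` or `"SP"` (each has its own thresholds).
#' @return one of `"none"`, `"positive"`, `"death_by_neglect"`,
#'   `"negative"`.
#' @export
selection_decision <- function(agent, thresholds, stage) {
  if (!(stage %in% names(thresholds$theta_pos)))
    stop("unknown stage: ", stage, call. = FALSE)
  if (agent$total_bound > thresholds$T_neg) return("negative")
  if (agent$n_interactions >= thresholds$theta_pos[[stage]]) return("positive")
  if (agent$stage_clock > thresholds$T_neglect[[stage]]) return("death_by_neglect")
  "none"
}

#' CD4/CD8 lineage choice (signal-duration hypothesis)
#'
#' Called at the DP -> SP positive-selection event: a longest single
#' TCR/MHC interaction of duration at least `tau_lineage` promotes the CD4
#' phenotype; shorter maxima promote CD8. The boundary belongs to CD4.
#'
#' @param agent a positively selected DP [new_thymocyte()].
#' @param tau_lineage duration cutoff.
#' @return `"CD4"` or `"CD8"`.
#' @export
lineage_decision <- function(agent, tau_lineage) {
  if (agent$n_interactions == 0L)
    stop("empty interaction log: lineage decision needs at least one interaction",
         call. = FALSE)
  longest <- max(agent$longest, agent$current)
  if (longest >= tau_lineage) "CD4" else "CD8"
}

#' Should an agent egress?
#'
#' TRUE iff the agent is a positively selected (mature) SP cell standing
#' on an exit site; the driver then removes it and logs a CD4/CD8 export.
#'
#' @param agent a [new_thymocyte()].
#' @param lattice a [build_thymus_lattice()].
#' @return logical.
#' @export
egress_check <- function(agent, lattice) {
  agent$stage %in% c("SP4", "SP8") && isTRUE(agent$mature) &&
    lattice$region[agent$pos[[1L]], agent$pos[[2L]]] == "exit"
}

#' Spatial model configuration
#'
#' @param width,height,epithelial_fraction,bands lattice geometry, see
#'   [build_thymus_lattice()].
#' @param thresholds a [selection_thresholds()].
#' @param k_on,k_off TCR/MHC binding and unbinding rates (1/time).
#' @param noise movement exploration probability.
#' @param dt step length (time units).
#' @param dn_dwell cortical dwell time after which a DN becomes DP.
#' @param influx new DN agents per step entering at random vacant
#'   subcapsular sites.
#' @return a `thymus_config` list.
#' @export
thymus_config <- function(width = 50L, height = 50L, epithelial_fraction = 0.15,
                          bands = c(subcapsular = 0.15, cortex = 0.45),
                          thresholds = selection_thresholds(),
                          k_on = 5, k_off = 1, noise = 0.2, dt = 0.1,
                          dn_dwell = 10, influx = 1) {
  structure(list(width = width, height = height,
                 epithelial_fraction = epithelial_fraction, bands = bands,
                 thresholds = thresholds, k_on = k_on, k_off = k_off,
                 noise = noise, dt = dt, dn_dwell = dn_dwell, influx = influx),
            class = "thymus_config")
}

#' Read a spatial model document
#'
#' @param path YAML file with keys `lattice` (width, height,
#'   epithelial_fraction, bands), `thresholds` (theta_pos_DP, theta_pos_SP,
#'   T_neglect_DP, T_neglect_SP, T_neg, tau_lineage) and `rates` (k_on,
#'   k_off, noise, dt, dn_dwell, influx).
#' @return a [thymus_config()].
#' @export
read_thymus_config <- function(path) {
  y <- yaml::read_yaml(path)
  la <- y$lattice %||% list()
  th <- y$thresholds %||% list()
  ra <- y$rates %||% list()
  num <- function(v, default) as.numeric(v %||% default)
  thymus_config(
    width = as.integer(num(la$width, 50)), height = as.integer(num(la$height, 50)),
    epithelial_fraction = num(la$epithelial_fraction, 0.15),
    bands = c(subcapsular = num(la$bands$subcapsular, 0.15),
              cortex = num(la$bands$cortex, 0.45)),
    thresholds = selection_thresholds(
      theta_pos = c(DP = num(th$theta_pos_DP, 5), SP = num(th$theta_pos_SP, 3)),
      T_neglect = c(DP = num(th$T_neglect_DP, 30), SP = num(th$T_neglect_SP, 20)),
      T_neg = num(th$T_neg, 12), tau_lineage = num(th$tau_lineage, 2)),
    k_on = num(ra$k_on, 5), k_off = num(ra$k_off, 1),
    noise = num(ra$noise, 0.2), dt = num(ra$dt, 0.1),
    dn_dwell = num(ra$dn_dwell, 10), influx = num(ra$influx, 1))
}

#' Run the spatial thymus simulation
#'
#' New DN agents enter at random vacant subcapsular sites, migrate down
#' the CXCL12 gradient into the cortex, become DP after the cortical dwell
#' time, accumulate TCR/MHC interactions with the epithelial network, and
#' are positively selected (then CD4/CD8 by signal duration), die by
#' neglect, or are negatively selected; mature SP follow S1P to the exit
#' row and egress.
#'
#' @param config a [thymus_config()].
#' @param n_steps number of steps of length `config$dt`.
#' @param seed integer seed (bit-for-bit reproducible).
#' @return list with `lattice`, `agents` (still developing), `log` (event
#'   data.frame with `t`, `id`, `event`, `detail`), `fates` (named counts:
#'   exported_CD4, exported_CD8, neglect, negative), `config`.
#' @export
run_thymus_lattice <- function(config = thymus_config(), n_steps, seed) {
  with_seed(seed, {
    lat <- build_thymus_lattice(config$width, config$height,
                                config$epithelial_fraction,
                                seed = sample.int(.Machine$integer.max, 1L),
                                bands = config$bands)
    thr <- config$thresholds
    rates <- list(k_on = config$k_on, k_off = config$k_off)
    agents <- list()
    next_id <- 1L
    logs <- list()
    note <- function(t, id, event, detail)
      logs[[length(logs) + 1L]] <<- data.frame(t = t, id = id, event = event,
                                               detail = detail, stringsAsFactors = FALSE)
    influx_acc <- 0
    for (step in seq_len(n_steps)) {
      t <- step * config$dt
      influx_acc <- influx_acc + config$influx
      while (influx_acc >= 1) {
        influx_acc <- influx_acc - 1
        sub <- which(lat$region == "subcapsular" & is.na(lat$occupant))
        if (length(sub) == 0L) break
        site <- sub[[sample.int(length(sub), 1L)]]
        pos <- c((site - 1L) %% lat$height + 1L, (site - 1L) %/% lat$height + 1L)
        ag <- new_thymocyte(next_id, pos)
        lat$occupant[pos[[1L]], pos[[2L]]] <- next_id
        agents[[as.character(next_id)]] <- ag
        note(t, next_id, "birth", "DN")
        next_id <- next_id + 1L
      }
      if (length(agents) == 0L) next
      for (key in names(agents)[sample.int(length(agents))]) {
        ag <- agents[[key]]
        if (is.null(ag)) next
        ag$stage_clock <- ag$stage_clock + config$dt
        if (ag$stage == "DN" &&
            lat$region[ag$pos[[1L]], ag$pos[[2L]]] == "cortex")
          ag$cortex_time <- ag$cortex_time + config$dt
        ag <- update_binding(ag, lat, config$dt, rates)
        if (ag$stage == "DN" && ag$cortex_time >= config$dn_dwell) {
          # each stage keeps its own interaction log: start DP from scratch
          ag$stage <- "DP"
          ag$stage_clock <- 0
          ag$n_interactions <- 0L
          ag$total_bound <- 0
          ag$longest <- 0
          note(t, ag$id, "differentiation", "DN->DP")
        } else if (ag$stage == "DP") {
          out <- selection_decision(ag, thr, "DP")
          if (out == "positive") {
            lineage <- lineage_decision(ag, thr$tau_lineage)
            ag$stage <- if (lineage == "CD4") "SP4" else "SP8"
            ag$stage_clock <- 0
            ag$n_interactions <- 0L
            ag$total_bound <- 0
            note(t, ag$id, "positive_selection", lineage)
          } else if (out != "none") {
            lat$occupant[ag$pos[[1L]], ag$pos[[2L]]] <- NA_integer_
            agents[[key]] <- NULL
            note(t, ag$id, "death",
                 if (out == "negative") "negative_selection" else "neglect")
            next
          }
        } else if (ag$stage %in% c("SP4", "SP8") && !ag$mature) {
          out <- selection_decision(ag, thr, "SP")
          if (out == "positive") {
            ag$mature <- TRUE
            note(t, ag$id, "maturation", ag$stage)
          } else if (out != "none") {
            lat$occupant[ag$pos[[1L]], ag$pos[[2L]]] <- NA_integer_
            agents[[key]] <- NULL
            note(t, ag$id, "death",
                 if (out == "negative") "negative_selection" else "neglect")
            next
          }
        }
        if (is.na(ag$bound_to)) {
          new_pos <- move_agent(ag, lat, config$noise)
          if (!all(new_pos == ag$pos)) {
            lat$occupant[ag$pos[[1L]], ag$pos[[2L]]] <- NA_integer_
            lat$occupant[new_pos[[1L]], new_pos[[2L]]] <- ag$id
            ag$pos <- new_pos
          }
        }
        if (egress_check(ag, lat)) {
          lat$occupant[ag$pos[[1L]], ag$pos[[2L]]] <- NA_integer_
          agents[[key]] <- NULL
          note(t, ag$id, "export", if (ag$stage == "SP4") "CD4" else "CD8")
          next
        }
        agents[[key]] <- ag
      }
    }
    log <- if (length(logs) > 0) do.call(rbind, logs) else
      data.frame(t = numeric(), id = integer(), event = character(),
                 detail = character(), stringsAsFactors = FALSE)
    fates <- c(exported_CD4 = sum(log$event == "export" & log$detail == "CD4"),
               exported_CD8 = sum(log$event == "export" & log$detail == "CD8"),
               neglect = sum(log$event == "death" & log$detail == "neglect"),
               negative = sum(log$event == "death" & log$detail == "negative_selection"))
    list(lattice = lat, agents = agents, log = log, fates = fates,
         config = config)
  })
}
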