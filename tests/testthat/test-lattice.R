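make_lattice <- function(...) build_thymus_lattice(20, 20, 0.2, seed = 5, ...)

test_that("lattice construction is deterministic with exact epithelial counts", {
  a <- build_thymus_lattice(50, 50, 0.2, seed = 9)
  b <- build_thymus_lattice(50, 50, 0.2, seed = 9)
  expect_identical(a$epithelial, b$epithelial)
  expect_identical(a$region, b$region)
  expect_identical(sum(!is.na(a$epithelial)), 500L)  # floor(0.2 * 2500)
  c2 <- build_thymus_lattice(50, 50, 0.2, seed = 10)
  expect_false(identical(a$epithelial, c2$epithelial))
})

test_that("every site has one region label and exit sits on the medullary edge", {
  lat <- make_lattice()
  expect_true(all(lat$region %in% c("subcapsular", "cortex", "medulla", "exit")))
  exit_rows <- which(lat$region == "exit", arr.ind = TRUE)[, 1L]
  expect_true(all(exit_rows == lat$height))
  # the row above the exit edge is medulla, so exit is its boundary
  expect_true(all(lat$region[lat$height - 1L, ] == "medulla"))
  expect_error(build_thymus_lattice(20, 20, 0.7, seed = 1), "epithelial_fraction")
  expect_error(build_thymus_lattice(4, 20, 0.2, seed = 1), "at least 8 x 8")
})

test_that("chemokine fields peak inside their attractor regions", {
  lat <- make_lattice()
  for (kind in names(lat$fields)) {
    f <- lat$fields[[kind]]
    expect_true(all(f >= 0))
    att <- switch(kind, CXCL12 = "cortex", CCL19_21 = "medulla", S1P = "exit")
    expect_equal(max(f), max(f[lat$region == att]))
  }
})

test_that("stages map to their guiding chemokines", {
  expect_identical(stage_chemokine("DN"), "CXCL12")
  expect_identical(stage_chemokine("DP"), "CXCL12")
  expect_identical(stage_chemokine("SP4"), "CCL19_21")
  expect_identical(stage_chemokine("SP8", mature = FALSE), "CCL19_21")
  expect_identical(stage_chemokine("SP4", mature = TRUE), "S1P")
  expect_error(stage_chemokine("DPX"), "unknown stage")
})

test_that("greedy movement is deterministic toward a unique best neighbor", {
  lat <- build_thymus_lattice(20, 20, 0.1, seed = 3)
  ag <- new_thymocyte(1L, c(2L, 10L))  # subcapsular, field increases downward
  for (k in 1:5) expect_identical(move_agent(ag, lat, noise = 0)[[1L]], 3L)
})

test_that("an agent boxed in by occupants stays put; bound agents refuse to move", {
  lat <- make_lattice()
  ag <- new_thymocyte(1L, c(5L, 5L))
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) lat$occupant[5 + dr, 5 + dc] <- 99L
  expect_identical(move_agent(ag, lat, noise = 0), ag$pos)
  expect_identical(move_agent(ag, lat, noise = 1), ag$pos)
  ag$bound_to <- 7L
  expect_error(move_agent(ag, lat), "bound agents do not move")
})

test_that("noise = 1 moves uniformly over vacant neighbors", {
  lat <- make_lattice()
  ag <- new_thymocyte(1L, c(10L, 10L))
  lat$occupant[9L, 9L] <- 50L            # one occupied neighbor -> 7 vacant
  set.seed(77)
  n <- 1e4
  picks <- replicate(n, paste(move_agent(ag, lat, noise = 1), collapse = ","))
  tab <- table(picks)
  expect_identical(length(tab), 7L)
  p <- 1 / 7
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(tab - n * p) < 3 * se))
})

test_that("binding updates the interaction log per the accumulation rules", {
  lat <- make_lattice()
  lat$epithelial[] <- NA_integer_
  ag <- new_thymocyte(1L, c(10L, 10L))
  # no adjacent epithelium: nothing changes
  set.seed(1)
  ag2 <- update_binding(ag, lat, dt = 0.1, rates = list(k_on = 5, k_off = 1))
  expect_identical(ag2[c("bound_to", "n_interactions", "total_bound")],
                   ag[c("bound_to", "n_interactions", "total_bound")])
  # k_off = 0: a bound agent stays bound and accrues exactly dt per step
  lat$epithelial[10L, 11L] <- 1L
  ag$bound_to <- 1L
  for (k in 1:7) ag <- update_binding(ag, lat, dt = 0.1, rates = list(k_on = 5, k_off = 0))
  expect_equal(ag$total_bound, 0.7)
  expect_equal(ag$current, 0.7)
  # guaranteed bind: interaction count increments and partner is recorded
  ag3 <- new_thymocyte(2L, c(10L, 10L))
  ag3 <- update_binding(ag3, lat, dt = 1e9, rates = list(k_on = 5, k_off = 1))
  expect_identical(ag3$n_interactions, 1L)
  expect_identical(ag3$partners, 1L)
})

test_that("distinct-partner accumulation matches an independent two-state chain", {
  # agent fixed between two epithelial neighbors; compare the mean number
  # of distinct partners after T steps against a direct re-simulation of
  # the bind/unbind chain
  lat <- make_lattice()
  lat$epithelial[] <- NA_integer_
  lat$epithelial[10L, 9L] <- 1L
  lat$epithelial[10L, 11L] <- 2L
  k_on <- 2; k_off <- 1.5; dt <- 0.1; steps <- 60; reps <- 400
  p_on <- rate_to_prob(k_on, dt); p_off <- rate_to_prob(k_off, dt)

  set.seed(501)
  sim <- vapply(seq_len(reps), function(r) {
    ag <- new_thymocyte(1L, c(10L, 10L))
    for (s in seq_len(steps))
      ag <- update_binding(ag, lat, dt, rates = list(k_on = k_on, k_off = k_off))
    length(unique(ag$partners))
  }, 0L)

  set.seed(777)
  oracle <- vapply(seq_len(reps * 4L), function(r) {
    bound <- FALSE; partners <- integer()
    for (s in seq_len(steps)) {
      if (bound) {
        if (runif(1) < p_off) bound <- FALSE
      } else if (runif(1) < p_on) {
        bound <- TRUE
        partners <- c(partners, sample(1:2, 1L))
      }
    }
    length(unique(partners))
  }, 0L)

  se <- sqrt(var(sim) / reps + var(oracle) / (reps * 4L))
  expect_lt(abs(mean(sim) - mean(oracle)), 3 * se)
})

test_that("selection_decision follows the priority order", {
  thr <- selection_thresholds()  # DP: theta 5, neglect 30; T_neg 12
  base <- new_thymocyte(1L, c(2L, 2L))
  # enough interactions before any clock expires -> positive
  pos <- base; pos$n_interactions <- 5L; pos$stage_clock <- 10
  expect_identical(selection_decision(pos, thr, "DP"), "positive")
  # clock beyond T_neglect without the threshold -> death by neglect
  neg <- base; neg$n_interactions <- 2L; neg$stage_clock <- 31
  expect_identical(selection_decision(neg, thr, "DP"), "death_by_neglect")
  # too much cumulative bound time -> negative, even if positive also holds
  strong <- base; strong$n_interactions <- 9L; strong$total_bound <- 12.5
  expect_identical(selection_decision(strong, thr, "DP"), "negative")
  # nothing triggered yet
  dev <- base; dev$n_interactions <- 2L; dev$stage_clock <- 5
  expect_identical(selection_decision(dev, thr, "DP"), "none")
  # SP uses its own thresholds
  sp <- base; sp$n_interactions <- 3L
  expect_identical(selection_decision(sp, thr, "SP"), "positive")
  expect_error(selection_decision(base, thr, "DN"), "unknown stage")
})

test_that("lineage decision splits CD4/CD8 at the duration cutoff", {
  tau <- 2
  ag <- new_thymocyte(1L, c(2L, 2L)); ag$n_interactions <- 5L
  long <- ag; long$longest <- 2 * tau
  expect_identical(lineage_decision(long, tau), "CD4")
  short <- ag; short$longest <- tau / 2
  expect_identical(lineage_decision(short, tau), "CD8")
  edge <- ag; edge$longest <- tau
  expect_identical(lineage_decision(edge, tau), "CD4")  # boundary -> CD4
  # an ongoing interaction counts toward the longest duration
  live <- ag; live$longest <- 0.5; live$current <- 3
  expect_identical(lineage_decision(live, tau), "CD4")
  empty <- new_thymocyte(2L, c(2L, 2L))
  expect_error(lineage_decision(empty, tau), "empty interaction log")
})

test_that("egress requires a mature SP standing on an exit site", {
  lat <- make_lattice()
  exit_pos <- c(lat$height, 3L)
  sp <- new_thymocyte(1L, exit_pos, stage = "SP4"); sp$mature <- TRUE
  expect_true(egress_check(sp, lat))
  sp_in <- sp; sp_in$pos <- c(lat$height - 2L, 3L)
  expect_false(egress_check(sp_in, lat))
  immature <- new_thymocyte(2L, exit_pos, stage = "SP8")
  expect_false(egress_check(immature, lat))
  dp <- new_thymocyte(3L, exit_pos, stage = "DP")
  expect_false(egress_check(dp, lat))
})

test_that("noise-free chemotaxis reaches the attractor within width+height steps", {
  lat <- build_thymus_lattice(30, 30, 0.1, seed = 2)
  lat$epithelial[] <- NA_integer_   # empty lattice: no binding, no obstacles
  ag <- new_thymocyte(1L, c(1L, 17L), stage = "SP4"); ag$mature <- TRUE  # S1P
  set.seed(3)
  for (step in seq_len(lat$width + lat$height)) {
    ag$pos <- move_agent(ag, lat, noise = 0)
    if (lat$region[ag$pos[[1L]], ag$pos[[2L]]] == "exit") break
  }
  expect_identical(unname(lat$region[ag$pos[[1L]], ag$pos[[2L]]]), "exit")
  expect_lte(step, lat$width + lat$height)
})

test_that("the full spatial run conserves occupancy and partitions fates", {
  cfg <- thymus_config(width = 24L, height = 24L, epithelial_fraction = 0.2,
                       dn_dwell = 2, dt = 0.1,
                       thresholds = selection_thresholds(
                         theta_pos = c(DP = 3, SP = 2),
                         T_neglect = c(DP = 12, SP = 8),
                         T_neg = 6, tau_lineage = 0.8))
  res <- run_thymus_lattice(cfg, n_steps = 400, seed = 21)
  lg <- res$log
  # occupancy: each remaining agent sits where the lattice says it does
  occ <- res$lattice$occupant
  ids <- vapply(res$agents, function(a) a$id, 0L)
  expect_identical(sort(unname(occ[!is.na(occ)])), sort(unname(ids)))
  expect_identical(anyDuplicated(occ[!is.na(occ)]), 0L)
  # conservation: births - deaths - exports = survivors
  expect_identical(sum(lg$event == "birth") - sum(lg$event == "death") -
                     sum(lg$event == "export"), length(res$agents))
  # fates are mutually exclusive: at most one terminal event per agent
  terminal <- lg[lg$event %in% c("death", "export"), ]
  expect_identical(anyDuplicated(terminal$id), 0L)
  # the run exercises the selection machinery
  expect_gt(sum(res$fates), 0)
})

test_that("raising the negative-selection ceiling weakly reduces negative fates", {
  base <- thymus_config(width = 24L, height = 24L, epithelial_fraction = 0.25,
                        dn_dwell = 1, dt = 0.1)
  frac_neg <- function(T_neg, seed) {
    cfg <- base
    cfg$thresholds <- selection_thresholds(theta_pos = c(DP = 4, SP = 2),
                                           T_neglect = c(DP = 15, SP = 8),
                                           T_neg = T_neg, tau_lineage = 1)
    res <- run_thymus_lattice(cfg, n_steps = 300, seed = seed)
    done <- sum(res$fates)
    if (done == 0) return(0)
    res$fates[["negative"]] / done
  }
  lo <- mean(vapply(1:3, function(s) frac_neg(3, s), 0))
  hi <- mean(vapply(1:3, function(s) frac_neg(30, s), 0))
  expect_lte(hi, lo)
})
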