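test_that("rate_to_prob is the exponential embedding", {
  expect_identical(rate_to_prob(0, 0.1), 0)
  expect_equal(rate_to_prob(log(2), 1), 0.5)
  r <- c(1e-6, 0.1, 5, 500)
  p <- rate_to_prob(r, 0.01)
  expect_true(all(p >= 0 & p < 1))
  expect_error(rate_to_prob(-1, 0.1), "negative rate")
  expect_error(rate_to_prob(1, 0), "dt must be")
})

test_that("a step with no enabled transitions only advances the clock", {
  m <- statechart_model("still", list(), list(region("r", c("A", "B"))))
  set.seed(1)
  w <- new_world(m, init = c(A = 3, B = 2), dt = 0.1)
  w2 <- step_world(w)
  expect_equal(w2$clock, 0.1)
  expect_identical(sort(w2$ids), sort(w$ids))
  expect_identical(tabulate(w2$ak, 2), tabulate(w$ak, 2))
  expect_length(event_log(w2)$id, 0L)
})

test_that("single-transition firing frequency matches 1 - exp(-r dt)", {
  r <- 0.7; dt <- 0.2
  m <- statechart_model("one", list(r = r), list(
    region("r1", c("A", "B"), transitions = list(transition("A", "B", "r")))))
  n <- 1e5
  set.seed(404)
  w <- step_world(new_world(m, init = c(A = n), dt = dt))
  moved <- tabulate(w$ak, 2)[[2L]]
  p <- rate_to_prob(r, dt)
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(moved - n * p), 3 * se)
})

test_that("competing risks branch in proportion to their rates", {
  r1 <- 0.6; r2 <- 0.2; dt <- 0.25
  m <- statechart_model("branch", list(r1 = r1, r2 = r2), list(
    region("r", c("A", "B", "C"), transitions = list(
      transition("A", "B", "r1"), transition("A", "C", "r2")))))
  n <- 1e5
  set.seed(405)
  w <- step_world(new_world(m, init = c(A = n), dt = dt))
  counts <- tabulate(w$ak, 3)
  fired <- counts[[2L]] + counts[[3L]]
  pb <- r1 / (r1 + r2)
  se <- sqrt(fired * pb * (1 - pb))
  expect_lt(abs(counts[[2L]] - fired * pb), 3 * se)
  # total firing also follows the combined hazard
  ptot <- rate_to_prob(r1 + r2, dt)
  expect_lt(abs(fired - n * ptot), 3 * sqrt(n * ptot * (1 - ptot)))
})

test_that("divide_agent implements the gamma semantics", {
  m <- default_conveyor()
  parent <- list(id = 1L, states = c(differentiation = "DN", cell_cycle = "SM",
                                     generation = "g2"))
  res <- divide_agent(parent, m, gamma = 1)
  expect_identical(res$event, "division")
  expect_length(res$daughters, 2L)
  for (d in res$daughters) {
    expect_identical(unname(d$states[["differentiation"]]), "DN")  # stage inherited
    expect_identical(unname(d$states[["cell_cycle"]]), "G0")       # cycle reset
    expect_identical(unname(d$states[["generation"]]), "g3")       # next generation
  }
  # saturating cap at the stage's last generation
  top <- list(id = 2L, states = c(differentiation = "DN", cell_cycle = "SM",
                                  generation = "g4"))
  res_top <- divide_agent(top, m, gamma = 1)
  expect_identical(unname(res_top$daughters[[1L]]$states[["generation"]]), "g4")

  res0 <- divide_agent(parent, m, gamma = 0)
  expect_identical(res0$event, "ganciclovir_apoptosis")
  expect_length(res0$daughters, 0L)

  quiescent <- list(id = 3L, states = c(differentiation = "DN", cell_cycle = "G0",
                                        generation = "g1"))
  expect_error(divide_agent(quiescent, m), "not in a division-enabled state")
})

test_that("run_abm is reproducible and exact on degenerate inputs", {
  m <- chain_model(3, p = 0.2, d = 0.1)
  a <- run_abm(m, init = 200, t_end = 1, dt = 0.02, seed = 99)
  b <- run_abm(m, init = 200, t_end = 1, dt = 0.02, seed = 99)
  expect_identical(a$values, b$values)
  expect_identical(a$log, b$log)
  c2 <- run_abm(m, init = 200, t_end = 1, dt = 0.02, seed = 100)
  expect_false(identical(a$values, c2$values))

  empty <- run_abm(m, init = 0, t_end = 0.5, dt = 0.05, seed = 1)
  expect_true(all(empty$values == 0L))
})

test_that("death-only decay matches N0 exp(-1) at t = 1/d over replicates", {
  d <- 0.5; n0 <- 400
  m <- decay_model(d)
  finals <- vapply(1:200, function(r)
    run_abm(m, init = n0, t_end = 1 / d, dt = 0.02, seed = 1000 + r,
            record = 1 / d, record_log = FALSE)$final_n, 0L)
  p <- exp(-1)  # per-agent survival over [0, 1/d] is exactly e^{-1}
  mu <- n0 * p
  se <- sqrt(n0 * p * (1 - p) / 200)
  expect_lt(abs(mean(finals) - mu), 3 * se)
})

test_that("event-log conservation holds exactly", {
  m <- build_conveyor_model(params = conveyor_params(Sn = 200))
  for (seed in c(5, 6, 7)) {
    run <- run_abm(m, init = 500, t_end = 2, dt = 0.02, seed = seed)
    lg <- run$log
    births <- sum(lg$event %in% c("birth", "division"))
    deaths <- sum(lg$event == "death")
    exports <- sum(lg$event == "export")
    expect_identical(births - deaths - exports, run$final_n - run$initial_n)
    # counts are integer, non-negative, and never in excluded combinations
    expect_true(all(run$values >= 0L))
    expect_false(any(grepl("DP_late.SM", colnames(run$values), fixed = TRUE)))
  }
})

test_that("abm and ode backends agree through the mean-field harness", {
  # scaled-down sweep for the routine suite; the full 1e4 x 20 comparison
  # runs in the acceptance tests
  m <- build_conveyor_model(params = conveyor_params(Sn = 500))
  rep <- compare_mean_field(m, n_agents = 2000, replicates = 8,
                            t_grid = seq(0, 1.5, by = 0.1), seed = 11)
  expect_lt(rep$max_abs_z, 6)
  expect_identical(ncol(rep$z), 30L)
})

test_that("a rate-free model yields all-zero z-scores", {
  m <- statechart_model("frozen", list(), list(region("r", c("A", "B"))))
  rep <- compare_mean_field(m, n_agents = 100, replicates = 3,
                            t_grid = seq(0, 0.5, by = 0.1), seed = 2)
  expect_true(all(rep$z == 0))
})

test_that("relative Monte-Carlo error grows as agent numbers shrink", {
  m <- chain_model(3, p = 0.15, d = 0.05)
  errs <- vapply(c(8000, 1000, 125), function(n)
    compare_mean_field(m, n_agents = n, replicates = 8,
                       t_grid = seq(0.25, 3, by = 0.25), seed = 31)$rel_mse, 0)
  expect_true(all(diff(errs) > 0))
})

test_that("spatial configurations are rejected as not comparable", {
  expect_error(compare_mean_field(thymus_config(), 10, 2, 0:1, seed = 1),
               "not comparable")
})
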