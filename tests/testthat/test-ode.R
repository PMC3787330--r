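test_that("compiled RHS implements the conveyor-belt flux law on a chain", {
  # dx2/dt = 2*gamma*p*x1 - (p + d + u2)*x2, probed at x = e1 and e2 on an
  # interior generation (the saturating cap only alters the last one)
  m <- chain_model(3, p = 0.3, d = 0.1, u0 = 0.05, s = 0.05)
  sys <- compile_population_ode(m)
  e1 <- c(g1 = 1, g2 = 0, g3 = 0)
  e2 <- c(g1 = 0, g2 = 1, g3 = 0)
  expect_equal(ode_rhs(sys, e1, gamma = 1)[[2L]], 2 * 0.3)
  expect_equal(ode_rhs(sys, e1, gamma = 0)[[2L]], 0)
  u2 <- 0.05 + 0.05 * (2 - 1)
  expect_equal(ode_rhs(sys, e2, gamma = 1)[[2L]], -(0.3 + 0.1 + u2))
  # and at the cap the daughters saturate back: coefficient gains +2*gamma*p
  e3 <- c(g1 = 0, g2 = 0, g3 = 1)
  u3 <- 0.05 + 0.05 * (3 - 1)
  expect_equal(ode_rhs(sys, e3, gamma = 1)[[3L]], 2 * 0.3 - (0.3 + 0.1 + u3))
})

test_that("a source-only model has dx1/dt = S and zero elsewhere", {
  m <- statechart_model("src", list(S = 3.5), list(
    region("r", c("A", "B", "C"))),
    sources = list(list(into = "r == A", rate = "S")))
  sys <- compile_population_ode(m)
  expect_equal(ode_rhs(sys, c(5, 2, 1)), c(3.5, 0, 0))
})

test_that("compiled RHS matches the brute-force flux oracle", {
  set.seed(101)
  models <- list(chain_model(3), default_conveyor(),
                 parse_model(generate_fixture_model(11)))
  for (m in models) {
    sys <- compile_population_ode(m)
    x <- stats::setNames(stats::runif(nrow(sys$flat), 0, 100), sys$flat$name)
    for (g in c(1, 0)) {
      got <- stats::setNames(ode_rhs(sys, x, gamma = g), sys$flat$name)
      want <- oracle_rhs(m, x, gamma = g)
      expect_equal(got, want[names(got)], tolerance = 1e-12)
    }
  }
})

test_that("exported equations re-evaluate to the compiled RHS", {
  m <- decay_model(d = 0.1)
  lines <- export_equations(compile_population_ode(m))
  expect_length(lines, 1L)
  expect_match(gsub("\\s", "", lines), "d\\(A\\)/dt=-\\(d\\)\\*A", fixed = FALSE)

  sys <- compile_population_ode(default_conveyor())
  lines <- export_equations(sys)
  expect_length(lines, 30L)
  set.seed(202)
  for (rep in 1:10) {
    x <- stats::setNames(stats::runif(30, 0, 1e4), sys$flat$name)
    got <- eval_equation_lines(lines, x, sys$model$parameters, gamma = 1)
    expect_equal(got[sys$flat$name],
                 stats::setNames(ode_rhs(sys, x, gamma = 1), sys$flat$name),
                 tolerance = 1e-10)
  }
})

test_that("integration reproduces closed forms", {
  # pure death: x(1/d) = x0 * exp(-1)
  d <- 0.1
  sys <- compile_population_ode(decay_model(d))
  traj <- integrate_ode(sys, 1000, seq(0, 1 / d, length.out = 11))
  expect_equal(unname(traj$values[11L, 1L]), 1000 * exp(-1), tolerance = 1e-6)
  # death channel accounts for the lost mass
  expect_equal(unname(traj$channels[11L, "death:cells:A"]),
               1000 * (1 - exp(-1)), tolerance = 1e-6)

  # all rates zero: constant trajectory
  z <- compile_population_ode(
    statechart_model("null", list(), list(region("r", c("A", "B")))))
  traj <- integrate_ode(z, c(7, 3), 0:5)
  expect_true(all(traj$values[, 1L] == 7) && all(traj$values[, 2L] == 3))

  # division chain with d = u = 0: totals grow as exp(p t)
  p <- 0.25
  m <- chain_model(4, p = p, d = 0, with_export = FALSE)
  sys <- compile_population_ode(m)
  traj <- integrate_ode(sys, c(g1 = 1000, g2 = 0, g3 = 0, g4 = 0), seq(0, 8, by = 1))
  expect_equal(rowSums(traj$values), 1000 * exp(p * (0:8)), tolerance = 1e-6)
})

test_that("integrate rejects bad grids and unknown states", {
  sys <- compile_population_ode(decay_model())
  expect_error(integrate_ode(sys, 1, c(0, 0, 1)), "strictly increasing")
  expect_error(integrate_ode(sys, c(Z = 1), 0:1), "unknown flat state")
})

test_that("total_counts sums, projects and partitions", {
  sys <- compile_population_ode(default_conveyor())
  traj <- integrate_ode(sys, steady_state(sys), seq(0, 5, by = 1))
  all_states <- total_counts(traj)
  expect_equal(all_states$total, unname(rowSums(traj$values)))
  one <- total_counts(traj, "DN.G0.g1")
  expect_equal(one$total, unname(traj$values[, "DN.G0.g1"]))
  stages <- c("DN", "DP_early", "DP_late", "SP4", "SP8")
  parts <- sapply(stages, function(st)
    total_counts(traj, paste0("differentiation == ", st))$total)
  expect_equal(unname(rowSums(parts)), all_states$total, tolerance = 1e-12)
  expect_error(total_counts(traj, "differentiation == XX"), "matches no flat state")
})

test_that("bookkeeping identity: d(total)/dt decomposes into source/division/death/export", {
  sys <- compile_population_ode(default_conveyor())
  fx <- sys$fluxes
  set.seed(33)
  for (g in c(1, 0)) {
    x <- stats::runif(30, 0, 1000)
    lhs <- sum(ode_rhs(sys, x, gamma = g))
    div <- fx$type == "division"
    rhs <- sum(fx$rate[fx$type == "source"]) +
      (2 * g - 1) * sum(fx$rate[div] * x[fx$src[div]]) -
      sum(fx$rate[fx$type == "death"] * x[fx$src[fx$type == "death"]]) -
      sum(fx$rate[fx$type == "export"] * x[fx$src[fx$type == "export"]])
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # and numerically on an integrated trajectory
  traj <- integrate_ode(sys, steady_state(sys) * 0.5, seq(0, 2, by = 0.01))
  tot <- rowSums(traj$values)
  mid <- 2:200
  dnum <- (tot[mid + 1L] - tot[mid - 1L]) / 0.02
  dth <- vapply(mid, function(i) sum(ode_rhs(sys, traj$values[i, ], gamma = 1)), 0)
  expect_equal(dnum, dth, tolerance = 1e-4)
})

test_that("with gamma = 0 and no sources the total is non-increasing", {
  params <- conveyor_params(Sn = 0)
  m <- build_conveyor_model(params = params)
  sys <- compile_population_ode(m)
  y0 <- stats::setNames(rep(100, 30), sys$flat$name)
  traj <- integrate_ode(sys, y0, seq(0, 10, by = 0.5), gamma = 0)
  expect_true(all(diff(rowSums(traj$values)) <= 1e-9))
})

test_that("the homogeneous system is linear in the initial condition", {
  m <- build_conveyor_model(params = conveyor_params(Sn = 0))
  sys <- compile_population_ode(m)
  set.seed(9)
  y0 <- stats::setNames(stats::runif(30, 0, 50), sys$flat$name)
  t1 <- integrate_ode(sys, y0, 0:5)
  t3 <- integrate_ode(sys, 3 * y0, 0:5)
  expect_equal(t3$values, 3 * t1$values, tolerance = 1e-10)
})

test_that("long-time integration converges to the algebraic steady state", {
  sys <- compile_population_ode(default_conveyor())
  ss <- steady_state(sys)
  expect_true(all(ss >= 0))
  traj <- integrate_ode(sys, 0 * ss, c(0, 2000))
  expect_equal(traj$values[2L, ], ss, tolerance = 1e-6)
})
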