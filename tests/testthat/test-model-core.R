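# independent oracle: the noise-free fixed point solves a 3x3 linear system
solve_fixed_point <- function(p, g, u) {
  A <- rbind(
    c(1 - p$theta8, -p$theta7, 0),
    c(-p$theta2, 1 - p$theta5, -p$theta4),
    c(0, -u * p$theta9, 1)
  )
  b <- c(p$theta6, p$theta1 + p$theta3 * g, 0)
  setNames(as.numeric(solve(A, b)), c("D", "R", "S"))
}

test_that("indicated values reproduce the published constants and fixed points", {
  p <- model_params()
  expect_equal(indicated_rumination(0, 0, 0, "boy", 0, p), -1.2504)
  expect_equal(indicated_rumination(0, 0, 0, "girl", 0, p), 1.2648)
  expect_equal(indicated_depression(0, 0, 0, p), 0.3730)
  expect_equal(indicated_depression(0, 0, 0, model_params(theta7 = 0, theta8 = 0)),
               0.3730)

  # self-consistency at the girls' mean-inflow fixed point
  fp <- solve_fixed_point(p, 1, 4.97 / 6)
  expect_equal(fp[["R"]], 10.323, tolerance = 1e-3)
  expect_equal(indicated_rumination(fp["D"], fp["R"], fp["S"], "girl", 0, p),
               fp[["R"]], tolerance = 1e-8, ignore_attr = TRUE)

  # depression fixed point at the overall mean rumination level
  Dstar <- (p$theta6 + p$theta7 * 11.59) / (1 - p$theta8)
  expect_equal(Dstar, 10.697, tolerance = 1e-3)
  expect_equal(indicated_depression(Dstar, 11.59, 0, p), Dstar)

  expect_error(indicated_rumination(NaN, 0, 0, "girl", 0, p),
               class = "rumidyn_invalid_input")
  expect_error(indicated_depression(0, Inf, 0, p),
               class = "rumidyn_invalid_input")
})

test_that("memory time scales with rumination above its floor", {
  p <- model_params()
  expect_equal(memory_time(1, p), 1.4741)
  expect_equal(memory_time(10, p), 14.741)
  expect_equal(memory_time(0, p), p$M_min)
  r <- seq(0.5, 30, by = 0.5)
  expect_true(all(diff(memory_time(r, p)) > 0))
})

test_that("let-it-go drains the stressor stock at S / M", {
  p <- model_params()
  expect_equal(let_it_go(0, 5, p), 0)
  expect_equal(let_it_go(14, 7, p), 2)
  expect_error(let_it_go(-1, 5, p), class = "rumidyn_invalid_input")
  expect_error(let_it_go(3, 0.1, p), class = "rumidyn_contract_violation")
  # at the fixed point the outflow balances the inflow exactly
  ss <- steady_state(p, "girl", 4.97 / 6)
  expect_equal(let_it_go(ss$S, ss$M, p), 4.97 / 6)
})

test_that("noise update has the right decay, stationary SD, and autocorrelation", {
  expect_equal(ou_step(1, 0, 1.6008, 0.125, 0), 1 - 0.125 / 1.6008)
  expect_equal(ou_step(0, 0, 1.6008, 0.125, 3), 0)
  expect_error(ou_step(0, 7, 0.1, 0.125), class = "rumidyn_invalid_config")
  expect_error(ou_step(0, -1, 1.6, 0.125), class = "rumidyn_invalid_input")

  # the recursive path equals iterated single steps
  set.seed(7)
  draws <- rnorm(25)
  eps <- 2.5
  stepped <- numeric(25)
  for (i in 1:25) {
    eps <- ou_step(eps, 7.8735, 1.6008, 0.125, draws[i])
    stepped[i] <- eps
  }
  expect_equal(rumidyn:::ou_path(2.5, 7.8735, 1.6008, 0.125, draws), stepped)

  # moderate-length moment check (the full-length run lives in acceptance)
  set.seed(11)
  n <- 2e5
  path <- rumidyn:::ou_path(rnorm(1, 0, 7.8735), 7.8735, 1.6008, 0.125, rnorm(n))
  expect_equal(sd(path), 7.8735, tolerance = 0.02)
  phi8 <- (1 - 0.125 / 1.6008)^8
  expect_equal(cor(path[-(1:8)], path[1:(n - 8)]), phi8, tolerance = 0.03)
})

test_that("a single Euler step does the stock arithmetic and clamps", {
  # freeze memory time at 7 months: theta9 = 0.7 with R = 10
  p <- model_params(theta9 = 0.7, theta10 = 0, theta11 = 0)
  st <- tibble::tibble(t = 0, D = 10, R = 10, S = 14, epsR = 0, epsD = 0)
  nxt <- sim_step(st, list(gender = "boy", inflow = 0), p,
                  draw_R = 0, draw_D = 0)
  expect_equal(nxt$S, 14 - 2 * 0.125)
  expect_equal(nxt$t, 0.125)

  # exact fixed point is invariant
  p2 <- model_params()
  ss <- steady_state(p2, "girl", 4.97 / 6)
  st2 <- tibble::tibble(t = 3, D = ss$D, R = ss$R, S = ss$S, epsR = 0, epsD = 0)
  nxt2 <- sim_step(st2, list(gender = "girl", inflow = 4.97 / 6), p2,
                   draw_R = 0, draw_D = 0)
  expect_equal(nxt2[c("D", "R", "S")], st2[c("D", "R", "S")])

  # upper clamp binds under positive net inflow
  p3 <- model_params(theta6 = 100, theta10 = 0, theta11 = 0)
  st3 <- tibble::tibble(t = 0, D = 52, R = 5, S = 0, epsR = 0, epsD = 0)
  nxt3 <- sim_step(st3, list(gender = "girl", inflow = 0), p3,
                   draw_R = 0, draw_D = 0)
  expect_equal(nxt3$D, 52)
})

test_that("steady_state agrees with an independent linear solve and flags divergence", {
  p <- model_params()
  for (g in c(0, 1)) {
    for (u in c(0, 0.4, 4.97 / 6)) {
      ss <- steady_state(p, c("boy", "girl")[g + 1], u)
      fp <- solve_fixed_point(p, g, u)
      expect_false(ss$divergent)
      expect_equal(c(D = ss$D, R = ss$R, S = ss$S), fp, tolerance = 1e-10)
    }
  }
  ss <- steady_state(p, "girl", 4.97 / 6)
  expect_equal(ss$D, 9.897, tolerance = 1e-3)
  expect_equal(ss$R, 10.323, tolerance = 1e-3)
  expect_equal(ss$S, 12.605, tolerance = 1e-3)

  hi <- steady_state(p, "girl", 1.875)
  expect_true(hi$divergent)
  expect_equal(hi$loop_gain, 0.1639 + 0.2677 + 0.6960, tolerance = 1e-3)
  expect_true(is.na(hi$D))

  # decoupled case: R* = theta1 + theta3 * G exactly
  pd <- model_params(theta2 = 0, theta4 = 0, theta5 = 0)
  expect_equal(steady_state(pd, "girl", 0.5)$R, -1.2504 + 2.5152)
  expect_error(steady_state(model_params(theta8 = 1.2), "girl", 0),
               class = "rumidyn_invalid_params")
})

test_that("noise-free simulation converges to the analytic fixed point", {
  p <- model_params()
  prof <- tibble::tibble(id = 1, gender = "girl", D0 = 3, R0 = 2, S0 = 1,
                         inflow = 4.97 / 6)
  tr <- simulate_profiles(prof, p, horizon = 600, seed = 1, noise = FALSE,
                          record = "terminal")
  expect_equal(tr$D, 9.897, tolerance = 1e-2)
  expect_equal(tr$R, 10.323, tolerance = 1e-2)
  expect_equal(tr$S, 12.605, tolerance = 1e-2)

  prof_b <- tibble::tibble(id = 1, gender = "boy", D0 = 20, R0 = 25, S0 = 10,
                           inflow = 0)
  tr_b <- simulate_profiles(prof_b, p, horizon = 600, seed = 1, noise = FALSE,
                            record = "terminal")
  expect_equal(tr_b$R, 0.3137, tolerance = 0.005)
  expect_equal(tr_b$D, 3.571, tolerance = 0.01)
})

test_that("simulation is deterministic and respects stock accounting", {
  p <- model_params()
  prof <- tibble::tibble(id = 1:3, gender = c("girl", "boy", "girl"),
                         D0 = c(10, 5, 16), R0 = c(12, 8, 20),
                         S0 = c(5, 2, 11), inflow = c(0.8, 0.3, 1.2))
  a <- simulate_profiles(prof, p, horizon = 24, seed = 99)
  b <- simulate_profiles(prof, p, horizon = 24, seed = 99)
  expect_identical(a, b)

  # Euler sum of (inflow - let_it_go) * dt reconstructs S on clamp-free runs
  one <- a[a$id == 2, ]
  n_t <- nrow(one)
  increments <- p$dt * (0.3 - one$L[-n_t])
  expect_equal(one$S[n_t] - one$S[1], sum(increments), tolerance = 1e-9)

  # a per-profile seed column makes each row reproducible in isolation
  prof_seeded <- dplyr::mutate(prof, seed = child_seed(99, id))
  full <- simulate_profiles(prof_seeded, p, horizon = 6, seed = 1)
  solo <- simulate_profiles(prof_seeded[2, ], p, horizon = 6, seed = 1)
  expect_identical(full[full$id == 2, ], solo)
})

test_that("refining the integration step barely moves noise-free trajectories", {
  p <- model_params()
  p_half <- model_params(dt = 0.0625)
  prof <- tibble::tibble(id = 1, gender = "girl", D0 = 16.43, R0 = 20.49,
                         S0 = 11.25, inflow = 0.5)
  a <- simulate_profiles(prof, p, horizon = 60, seed = 1, noise = FALSE,
                         record = "monthly")
  b <- simulate_profiles(prof, p_half, horizon = 60, seed = 1, noise = FALSE,
                         record = "monthly")
  for (v in c("D", "R", "S")) {
    expect_lt(max(abs(a[[v]] - b[[v]]) / pmax(abs(a[[v]]), 1)), 0.01)
  }
})

test_that("terminal depression is monotone in inflow, baseline rumination, and gender", {
  p <- model_params()
  term <- function(r0, u, g) {
    prof <- tibble::tibble(id = 1, gender = g, D0 = 9.98, R0 = r0, S0 = 4.97,
                           inflow = u)
    simulate_profiles(prof, p, horizon = 120, seed = 1, noise = FALSE,
                      record = "terminal")$D
  }
  d_u <- vapply(c(0, 0.3, 0.6, 0.9, 1.2), term, numeric(1), r0 = 12.78, g = "girl")
  expect_true(all(diff(d_u) >= 0))
  d_r <- vapply(c(0, 5, 15, 25), function(r) term(r, 0.5, "girl"), numeric(1))
  expect_true(all(diff(d_r) >= 0))
  expect_gte(term(12, 0.5, "girl"), term(12, 0.5, "boy"))
})

test_that("raising the memory-time coefficient keeps stressors alive longer", {
  base <- model_params()
  up <- model_params(theta9 = 1.9)
  prof <- tibble::tibble(id = 1, gender = "girl", D0 = 9.98, R0 = 12.78,
                         S0 = 4.97, inflow = 0.5)
  a <- simulate_profiles(prof, base, 120, seed = 1, noise = FALSE, record = "terminal")
  b <- simulate_profiles(prof, up, 120, seed = 1, noise = FALSE, record = "terminal")
  expect_gte(b$S, a$S)
  expect_gte(b$D, a$D)
})
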