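# kinetics: model definitions, ODE right-hand sides, initial conditions,
# closed-form solutions vs the matrix-exponential oracle, branch handling

test_that("model definitions expose the documented states and observables", {
  one <- kinetic_model("one_step")
  two <- kinetic_model("two_step")
  three <- kinetic_model("three_step")
  expect_equal(one$state_names, "cpb")
  expect_equal(one$observable_names, "y_ctdna")
  expect_equal(two$state_names, c("B", "cpb"))
  expect_equal(two$observable_names, c("y_ctdna", "y_blast"))
  expect_equal(three$state_names, c("B", "cbm", "cpb"))
  expect_equal(three$parameter_names,
               c("B0", "c0pb", "gamma_d", "s_c", "alpha", "gamma_t"))
  expect_error(kinetic_model("four_step"))
})

test_that("rhs matches the stated ODEs", {
  p <- effect_vector(B0 = 1e11, c0pb = 1e6, gamma_d = 0.5, s_c = 2,
                     alpha = 0.2, gamma_t = 3)
  d <- rhs("three_step", c(B = 1e11, cbm = 0, cpb = 0), p)
  expect_equal(d[["B"]], -5e10)
  expect_equal(d[["cbm"]], 5e10)
  expect_equal(d[["cpb"]], 0)
  # linear system through the origin
  expect_equal(unname(rhs("three_step", c(0, 0, 0), p)), c(0, 0, 0))
  expect_equal(unname(rhs("two_step", c(0, 0), p)), c(0, 0))
  # algebraic identity dB/dt + dcbm/dt = -gamma_t * cbm
  for (st in list(c(1e11, 1e7, 1e5), c(5e10, 0, 3e4))) {
    d <- rhs("three_step", st, p)
    expect_equal(d[["B"]] + d[["cbm"]], -p[["gamma_t"]] * st[2])
  }
  expect_error(rhs("three_step", c(-1, 0, 0), p), "non-negative")
  expect_error(rhs("three_step", c(1, 2), p), "length")
})

test_that("initial_state applies the c0bm scaling rule", {
  p <- effect_vector(B0 = 1e11, c0pb = 1e6, gamma_d = 0.5, s_c = 1,
                     alpha = 0.2, gamma_t = 3.3, gamma_deg = 33)
  x0 <- initial_state("three_step", p)
  expect_equal(x0[["cbm"]], 1e7)  # (33 / 3.3) * 1e6 * 1
  expect_equal(x0[["B"]], 1e11)
  expect_equal(x0[["cpb"]], 1e6)
  # s_c = 1: cpb gradient at t = 0 is exactly 0; s_c = 2: strictly positive
  expect_equal(rhs("three_step", x0, p)[["cpb"]], 0)
  p2 <- effect_vector(B0 = 1e11, c0pb = 1e6, gamma_d = 0.5, s_c = 2,
                      alpha = 0.2, gamma_t = 3.3, gamma_deg = 33)
  expect_gt(rhs("three_step", initial_state("three_step", p2), p2)[["cpb"]], 0)
  expect_error(effect_vector(B0 = 1, c0pb = 1, gamma_d = 1, s_c = 0.5,
                             alpha = 0.5, gamma_t = 1), "s_c")
  expect_equal(unname(initial_state("one_step", p)), 1e6)
  expect_equal(unname(initial_state("two_step", p)), c(1e11, 1e6))
})

test_that("one-step closed form reproduces exponential half-life decay", {
  p <- effect_vector(c0pb = 1e6, alpha = 1, gamma_deg = 33,
                     B0 = 1, gamma_d = 1, s_c = 1, gamma_t = 1)
  tr <- solve_analytic("one_step", p, c(0, log(2) / 33))
  expect_equal(unname(tr$states[2, "cpb"]), 5e5, tolerance = 1e-12)
  expect_error(solve_analytic("one_step", p, c(1, 0.5)), "ascending")
})

test_that("closed forms match the matrix-exponential oracle on random draws", {
  # 100 seeded random valid parameter sets per model on [0, 21] days
  set.seed(20260910)
  times <- seq(0, 21, length.out = 22)
  for (kind in c("one_step", "two_step", "three_step")) {
    worst <- 0
    for (i in 1:100) {
      p <- draw_effects()
      a <- solve_analytic(kind, p, times)
      o <- solve_numeric(kind, p, times)
      rel <- max(abs(a$states - o$states) /
                   pmax(abs(o$states), max(o$states) * 1e-30))
      worst <- max(worst, rel)
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("degenerate branches are continuous limits of the generic branch", {
  base <- list(B0 = 8e11, c0pb = 2e6, gamma_d = 0.7, s_c = 2, alpha = 0.2,
               gamma_t = 0.7, gamma_deg = 33)
  times <- seq(0, 21, by = 0.5)
  cases <- list(
    gt_eq_gd  = function(p, g) { p$gamma_t <- p$gamma_d + g; p },
    gdeg_eq_gt = function(p, g) { p$gamma_t <- p$gamma_deg + g; p },
    gdeg_eq_gd = function(p, g) { p$gamma_d <- p$gamma_deg + g; p },
    all_equal = function(p, g) {
      p$gamma_t <- p$gamma_d + g; p$gamma_deg <- p$gamma_d + 2 * g; p
    })
  for (nm in names(cases)) {
    exact <- do.call(effect_vector, cases[[nm]](base, 0))
    expect_equal(classify_branch("three_step", exact), nm)
    deg <- solve_analytic("three_step", exact, times)$states
    for (gap in c(-1e-9, 1e-9)) {
      near <- do.call(effect_vector, cases[[nm]](base, gap))
      gen <- solve_analytic("three_step", near, times,
                            branch = "generic")$states
      expect_lt(max(abs(gen - deg) / pmax(abs(deg), 1e-300)), 1e-5)
    }
  }
  # two-step equal-rate branch against the hand-written degenerate form
  g <- 0.9
  p <- effect_vector(B0 = 5e11, c0pb = 3e6, gamma_d = 1, s_c = 1,
                     alpha = 0.1, gamma_t = g, gamma_deg = g)
  tr <- solve_analytic("two_step", p, times)
  closed <- g * 5e11 * times * exp(-g * times) + 3e6 * exp(-g * times)
  expect_equal(unname(tr$states[, "cpb"]), closed, tolerance = 1e-12)
})

test_that("trajectories are monotone and decay to zero", {
  set.seed(7)
  times <- seq(0, 21, by = 0.25)
  for (i in 1:20) {
    p <- draw_effects()
    tr <- solve_analytic("three_step", p, times)
    B <- tr$states[, "B"]
    dB <- diff(B)
    # strictly decreasing for gamma_d > 0 (until floating-point underflow)
    expect_true(all(dB <= 0))
    expect_true(all(dB < 0 | B[-length(B)] == 0))
    expect_true(all(tr$states >= 0))
    # cpb -> 0 as t -> infinity: evaluate far beyond the slowest timescale
    t_inf <- 5e3 / min(p[["gamma_d"]], p[["gamma_t"]], 33)
    late <- solve_analytic("three_step", p, c(0, t_inf))$states[2, "cpb"]
    expect_lt(late, 1e-8 * max(solve_analytic("three_step", p,
                                              c(0, 1))$states))
    # non-negative cpb gradient at t = 0 whenever s_c >= 1
    expect_gte(rhs("three_step", initial_state("three_step", p), p)[["cpb"]],
               0)
  }
})

test_that("count_parameters reproduces the published parameter counts", {
  expect_equal(unname(count_parameters("one_step")), c(5L, 2L))
  expect_equal(unname(count_parameters("two_step")), c(8L, 3L))
  expect_equal(unname(count_parameters("three_step")), c(12L, 5L))
})

test_that("half-life conversion and the fixed degradation constant agree", {
  expect_equal(decay_rate_from_half_life(30), log(2) * 48)
  expect_equal(round(decay_rate_from_half_life(30)), gamma_deg_default())
  expect_equal(decay_rate_from_half_life(1440 * log(2)), 1)
  expect_equal(decay_rate_from_half_life(60),
               decay_rate_from_half_life(30) / 2)
  expect_error(decay_rate_from_half_life(0))
  expect_error(decay_rate_from_half_life(-5))
})

test_that("trajectory exports tidily", {
  p <- draw_effects()
  tr <- solve_analytic("three_step", p, c(0, 1, 2))
  df <- as.data.frame(tr)
  expect_setequal(unique(df$name), c("B", "cbm", "cpb", "y_ctdna", "y_blast"))
  expect_equal(nrow(df), 3 * 5)
})
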