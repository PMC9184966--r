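test_that("the conformation-binding square yields the printed rational response", {
  g <- make_binding_square(symbolic = TRUE)
  rf <- response_function(g, c(0, 0, 1, 1), symbolic = TRUE)
  # degree 2 over degree 2, no constant term in the numerator
  expect_length(rf$num_coeffs, 3)
  expect_length(rf$den_coeffs, 3)
  expect_true(poly_is_zero(rf$num_coeffs[[1]]))

  Astar <- poly_sum(list(mono("k1", "k2", "k3"), mono("k3", "k5", "k6"),
                         mono("k5", "k6", "k8"), mono("k1", "k2", "k7"),
                         mono("k5", "k6", "k7"), mono("k1", "k2", "k4")))
  Bstar <- poly_sum(list(mono("k2", "k3", "k6"), mono("k2", "k6", "k7")))
  Cstar <- poly_sum(list(mono("k1", "k7", "k8"), mono("k1", "k3", "k4"),
                         mono("k1", "k4", "k8"), mono("k5", "k7", "k8"),
                         mono("k3", "k4", "k5"), mono("k4", "k5", "k8")))
  Dstar <- poly_sum(list(Astar, mono("k2", "k3", "k4"),
                         mono("k6", "k7", "k8")))
  expect_true(poly_equal(rf$num_coeffs[[2]], Astar))
  expect_true(poly_equal(rf$num_coeffs[[3]], Bstar))
  expect_true(poly_equal(rf$den_coeffs[[1]], Cstar))
  expect_true(poly_equal(rf$den_coeffs[[2]], Dstar))
  expect_true(poly_equal(rf$den_coeffs[[3]], Bstar))
})

test_that("imposing the cycle condition collapses the response to first order", {
  g <- make_binding_square(symbolic = TRUE)
  rf <- response_function(g, c(0, 0, 1, 1), symbolic = TRUE)
  x <- linfra:::poly_sym("x")
  attach_x <- function(cs) {
    poly_sum(lapply(seq_along(cs), function(i) {
      xs <- replicate(i - 1, x, simplify = FALSE)
      poly_mul(cs[[i]], poly_prod(xs))
    }))
  }
  P_ne <- attach_x(rf$num_coeffs)
  Q_ne <- attach_x(rf$den_coeffs)
  # first-order form with A = (k2/k8)(1 + k3/k7), B = 1 + k5/k1, written
  # with cleared denominators: P = k1 k2 (k3 + k7) x,
  # Q = (k1 + k5) k7 k8 + P
  P_eq <- poly_mul(poly_mul(mono("k1", "k2"),
                            poly_add(poly_sym("k3"), poly_sym("k7"))), x)
  Q_eq <- poly_add(poly_mul(poly_add(poly_sym("k1"), poly_sym("k5")),
                            mono("k7", "k8")), P_eq)
  cross <- poly_add(poly_mul(P_ne, Q_eq),
                    poly_scale(poly_mul(Q_ne, P_eq), -1))
  top <- c(k1 = 1L, k2 = 1L, k3 = 1L, k4 = 1L)
  rep <- c(k5 = 1L, k6 = 1L, k7 = 1L, k8 = 1L)
  expect_true(poly_is_zero(poly_reduce_binomial(cross, top, rep)))
  # and numerically: with the cycle condition imposed the response equals
  # A x / (B + A x)
  set.seed(3)
  for (rep_i in 1:10) {
    k <- 10^runif(8, -1, 1)
    g_eq <- make_binding_square(k, equilibrium = TRUE)
    k <- g_eq$parameters
    A <- (k[["k2"]] / k[["k8"]]) * (1 + k[["k3"]] / k[["k7"]])
    B <- 1 + k[["k5"]] / k[["k1"]]
    rf_eq <- response_function(g_eq, c(0, 0, 1, 1))
    for (x0 in c(0.1, 1, 7)) {
      expect_equal(eval_response(rf_eq, x0), A * x0 / (B + A * x0),
                   tolerance = 1e-12)
    }
  }
})

test_that("responses match direct steady-state evaluation and flat outputs are constant", {
  g <- make_binding_square(k = c(0.3, 2, 1.1, 0.8, 1.9, 0.25, 3, 0.6))
  rf <- response_function(g, c(0, 0, 1, 1))
  for (x0 in c(0.05, 0.9, 14)) {
    expect_equal(eval_response(rf, x0),
                 sum(steady_state(g, x = x0)[c("3", "4")]),
                 tolerance = 1e-11)
  }
  flat <- response_function(g, rep(0.7, 4))
  ex <- linfra:::response_extrema(flat)
  expect_equal(ex$M, ex$m, tolerance = 1e-12)
  expect_error(half_max_point(flat), class = "ConstantFunction")
})

test_that("half-max points obey the closed forms and input rescaling", {
  for (h in c(1, 2, 4)) {
    expect_equal(half_max_point(hill_response(h)), 1, tolerance = 1e-10)
  }
  # f = Ax/(B + Ax): x0.5 = B/A
  A <- 2.3; B <- 0.7
  rf <- linfra:::new_response_fn(c(0, A), c(B, A))
  expect_equal(half_max_point(rf), B / A, tolerance = 1e-12)
  # rescaling x -> c x divides x0.5 by c and preserves (p, s)
  g <- make_binding_square(k = c(0.3, 2, 1.1, 0.8, 1.9, 0.25, 3, 0.6))
  rf1 <- response_function(g, c(0, 0, 1, 1))
  g2 <- g
  g2$parameters[c("k2", "k6")] <- g2$parameters[c("k2", "k6")] * 5
  rf2 <- response_function(g2, c(0, 0, 1, 1))
  expect_equal(half_max_point(rf2), half_max_point(rf1) / 5,
               tolerance = 1e-9)
  ps1 <- position_steepness(rf1)
  ps2 <- position_steepness(rf2)
  expect_equal(ps1$p, ps2$p, tolerance = 1e-9)
  expect_equal(ps1$s, ps2$s, tolerance = 1e-9)
})

test_that("position and steepness match closed forms for Hill functions", {
  expect_equal(position_steepness(hill_response(1))[c("p", "s")],
               list(p = 0, s = 1), tolerance = 1e-10)
  for (h in c(2, 3, 4, 6)) {
    ps <- position_steepness(hill_response(h))
    ref <- hill_ps(h)
    expect_equal(ps$p, ref$p, tolerance = 1e-10)
    expect_equal(ps$s, ref$s, tolerance = 1e-10)
  }
  expect_equal(hill_ps(2)$p, sqrt(1 / 3), tolerance = 1e-12)
})

test_that("the Hill line is monotone and consistent with position_steepness", {
  hl <- hill_line(seq(1.5, 8, by = 0.5))
  expect_true(all(diff(hl$p) > 0))
  expect_true(all(diff(hl$s) > 0))
  expect_true(all(hl$p < 1))
  for (h in c(2, 5)) {
    ps <- position_steepness(hill_response(h))
    row <- hill_line(h)
    expect_equal(row$p, ps$p, tolerance = 1e-10)
    expect_equal(row$s, ps$s, tolerance = 1e-10)
  }
})

test_that("exact critical-point maximization agrees with a dense grid", {
  for (seed in 1:25) {
    rf <- random_response(m = sample(2:4, 1), seed = 700 + seed)
    ps <- tryCatch(position_steepness(rf), error = function(e) NULL)
    if (is.null(ps)) next
    or <- linfra:::ps_grid_oracle(rf, n = 2e5)
    expect_equal(ps$s, or$s, tolerance = 1e-4)
  }
})

test_that("sampling is reproducible and respects equilibrium structure", {
  a <- sample_ps_region(m = 2, n_samples = 50, seed = 11)
  b <- sample_ps_region(m = 2, n_samples = 50, seed = 11)
  expect_identical(a, b)
  c2 <- sample_ps_region(m = 2, n_samples = 50, seed = 12)
  expect_false(identical(a$p, c2$p))
})
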