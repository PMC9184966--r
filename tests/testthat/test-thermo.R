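test_that("path products multiply and invert as expected", {
  g <- make_detailed_balanced(6, seed = 21)
  vs <- g$vertices
  # out-and-back is 1, concatenation multiplies
  expect_equal(path_product(g, c(vs[1], vs[2], vs[1])), 1, tolerance = 1e-14)
  und <- igraph::as_undirected(linfra:::as_igraph(g))
  p12 <- names(igraph::shortest_paths(und, vs[1], vs[4])$vpath[[1]])
  p24 <- names(igraph::shortest_paths(und, vs[4], vs[6])$vpath[[1]])
  mu1 <- path_product(g, p12)
  mu2 <- path_product(g, p24)
  expect_equal(path_product(g, c(p12, p24[-1])), mu1 * mu2,
               tolerance = 1e-12)
  expect_error(
    path_product(lf_graph(c("1", "2"),
                          data.frame(from = "1", to = "2", label = "2"),
                          parameters = NULL), c("1", "2")),
    class = "IrreversibleStep")
})

test_that("cycle condition holds for the constrained square and fails generically", {
  g_eq <- make_binding_square(k = c(1, 2, 3, 4, 5, 6, 7, 8), equilibrium = TRUE)
  expect_true(satisfies_cycle_condition(g_eq)$ok)
  k <- g_eq$parameters
  expect_equal(unname(k["k1"] * k["k2"] * k["k3"] * k["k4"]),
               unname(k["k5"] * k["k6"] * k["k7"] * k["k8"]))

  g_ne <- make_binding_square(k = c(1, 1, 1, 1, 1, 1, 1, 2))
  chk <- satisfies_cycle_condition(g_ne)
  expect_false(chk$ok)
  expect_true(length(chk$violating_cycle) >= 4)

  expect_error(
    satisfies_cycle_condition(
      lf_graph(c("1", "2"), data.frame(from = "1", to = "2", label = "2"))),
    class = "NotReversible")
})

test_that("equilibrium steady state equals the Matrix-Tree steady state at equilibrium", {
  for (seed in 1:25) {
    n <- sample(3:8, 1)
    g <- make_detailed_balanced(n, seed = 300 + seed)
    expect_true(satisfies_cycle_condition(g)$ok)
    mu <- linfra:::equilibrium_mu(g)
    expect_equal(mu[[1]], 1)
    u_eq <- equilibrium_steady_state(g)
    u_mtt <- steady_state(g)
    expect_equal(unname(u_eq), unname(u_mtt), tolerance = 1e-10)
    # detailed balance holds at the steady state
    r <- detailed_balance_residuals(g, u_mtt)
    expect_lt(max(abs(r$residual)), 1e-10)
  }
  # refusal away from equilibrium
  expect_error(equilibrium_steady_state(make_binding_square(c(1, 1, 1, 1, 1, 1, 1, 2))),
               class = "NotAtEquilibrium")
})

test_that("equilibrium weights are path independent and recover potentials", {
  g <- make_detailed_balanced(7, seed = 77)
  phi <- attr(g, "phi")
  mu <- linfra:::equilibrium_mu(g)
  # mu_i / mu_j = exp(phi_j - phi_i) for the generating potentials
  for (i in 2:7) {
    expect_equal(log(mu[[i]]), phi[[1]] - phi[[i]], tolerance = 1e-10)
  }
  # recompute mu along alternative random reversible walks
  set.seed(5)
  und <- igraph::as_undirected(linfra:::as_igraph(g))
  for (rep in 1:5) {
    target <- sample(g$vertices[-1], 1)
    p <- names(igraph::shortest_paths(und, g$vertices[1], target)$vpath[[1]])
    expect_equal(path_product(g, p), mu[[target]], tolerance = 1e-10)
  }
})

test_that("rescaling both directions of an edge pair leaves equilibrium unchanged", {
  g <- make_detailed_balanced(5, seed = 9)
  u0 <- equilibrium_steady_state(g)
  e <- g$edges
  i <- 1
  j <- which(e$from == e$to[i] & e$to == e$from[i])
  vals <- as.numeric(e$label)
  vals[c(i, j)] <- vals[c(i, j)] * 37.5
  g2 <- lf_graph(g$vertices,
                 data.frame(from = e$from, to = e$to,
                            label = sprintf("%.17g", vals)))
  expect_equal(unname(equilibrium_steady_state(g2)), unname(u0),
               tolerance = 1e-12)
})

test_that("two-state systems are always detailed balanced at steady state", {
  g <- lf_graph(c("1", "2"), data.frame(from = c("1", "2"), to = c("2", "1"),
                                        label = c("a", "b")),
                parameters = c(a = 3.2, b = 0.7))
  r <- detailed_balance_residuals(g, steady_state(g))
  expect_equal(r$residual, 0, tolerance = 1e-15)
  # and the equilibrium formula gives mu = (1, a/b)
  mu <- linfra:::equilibrium_mu(g)
  expect_equal(unname(mu), c(1, 3.2 / 0.7), tolerance = 1e-14)
})

test_that("edge entropy is the log label ratio, antisymmetric in the pair", {
  g <- lf_graph(c("1", "2"),
                data.frame(from = c("1", "2"), to = c("2", "1"),
                           label = c("a", "b")),
                parameters = c(a = exp(1), b = 1))
  expect_equal(edge_entropy(g, "1", "2"), 1)
  expect_equal(edge_entropy(g, "2", "1"), -1)
  g2 <- make_detailed_balanced(5, seed = 31)
  for (k in 1:4) {
    i <- g2$edges$from[k]; j <- g2$edges$to[k]
    expect_equal(edge_entropy(g2, i, j), -edge_entropy(g2, j, i),
                 tolerance = 1e-12)
  }
})

test_that("ligand conservation closes with a unique consistent free concentration", {
  # one binding site: free <-> bound with rate k x; closure x + x/(1+x) = Ltot
  g <- lf_graph(c("free", "bound"),
                data.frame(from = c("free", "bound"),
                           to = c("bound", "free"),
                           label = c("k*x", "1")),
                parameters = c(k = 1), input_symbol = "x")
  sol <- solve_ligand_conservation(g, "bound", L_tot = 2, u_tot = 1)
  # x + x/(1+x) = 2  =>  x^2 = 2
  expect_equal(sol$L_free, sqrt(2), tolerance = 1e-9)
  expect_equal(sum(sol$state), 1, tolerance = 1e-12)
  # nothing binds when there is no protein
  expect_equal(solve_ligand_conservation(g, "bound", 2, u_tot = 0)$L_free, 2)
  # reservoir limit: almost all ligand stays free
  big <- solve_ligand_conservation(g, "bound", L_tot = 1e6, u_tot = 1)
  expect_gt(big$L_free / 1e6, 1 - 1e-5)
})

test_that("cycle condition and detailed balance give the same verdict", {
  n_eq <- 0
  for (seed in 1:40) {
    g <- if (seed %% 2 == 0) make_detailed_balanced(5, seed = seed)
         else make_random_reversible(5, seed = seed)
    verdict_cycle <- satisfies_cycle_condition(g)$ok
    u <- steady_state(g)
    r <- detailed_balance_residuals(g, u)
    flux <- max(abs(u[g$edges$from] * linfra:::edge_values(g)))
    verdict_db <- max(abs(r$residual)) < 1e-8 * flux
    expect_identical(verdict_cycle, verdict_db)
    n_eq <- n_eq + verdict_cycle
  }
  expect_gt(n_eq, 10)       # both verdicts occur
  expect_lt(n_eq, 30)
})
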