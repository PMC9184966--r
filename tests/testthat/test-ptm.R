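# classical Michaelis-Menten scheme with symbolic hand-derived aggregates
mm_mechanism <- function(kon = 2, koff = 1, kcat = 3) {
  enzyme_mechanism("E", "ES0", list(
    list(type = "binding", substrate = "S0", to = "ES0", rate = "kon"),
    list(type = "release", from = "ES0", substrate = "S0", rate = "koff"),
    list(type = "release", from = "ES0", substrate = "S1", rate = "kcat")),
    c(kon = kon, koff = koff, kcat = kcat))
}

test_that("mechanism grammar is enforced and graphs are strongly connected", {
  m <- mm_mechanism()
  g <- mechanism_graph(m)
  expect_equal(sort(g$vertices), c("E", "ES0"))
  expect_equal(nrow(g$edges), 2)  # release routes merge into one edge
  expect_true(is_strongly_connected(g))
  # substrate on a conversion label violates the grammar
  expect_error(
    enzyme_mechanism("E", c("Y1", "Y2"), list(
      list(type = "binding", substrate = "S0", to = "Y1", rate = "k1"),
      list(type = "conversion", from = "Y1", to = "Y2", rate = "k2",
           substrate = "S1"),
      list(type = "release", from = "Y2", substrate = "S1", rate = "k3")),
      c(k1 = 1, k2 = 1, k3 = 1)),
    class = "GrammarViolation")
  # a complex with no route back to the enzyme is rejected
  expect_error(
    enzyme_mechanism("E", c("Y1", "Y2"), list(
      list(type = "binding", substrate = "S0", to = "Y1", rate = "k1"),
      list(type = "release", from = "Y1", substrate = "S1", rate = "k2"),
      list(type = "conversion", from = "Y1", to = "Y2", rate = "k3")),
      c(k1 = 1, k2 = 1, k3 = 1)),
    class = "NotStronglyConnected")
})

test_that("aggregated parameters reproduce the Michaelis-Menten closed form", {
  ap <- aggregated_params(mm_mechanism(kon = 2, koff = 1, kcat = 3))
  # kappa0 = kon / (koff + kcat): reciprocal of the Michaelis constant
  expect_equal(unname(ap$kappa0_Yi["ES0"]), 2 / (1 + 3), tolerance = 1e-14)
  expect_equal(ap$kappa1, 0)
  expect_equal(ap$c01, 3 * 2 / (1 + 3), tolerance = 1e-14)
  expect_equal(ap$c10, 0)
  expect_true(ap$strongly_irreversible)
  expect_false(ap$weakly_irreversible)
})

test_that("irreversibility classes follow the mechanism structure", {
  set.seed(1)
  for (seed in 1:8) {
    expect_true(aggregated_params(
      make_mechanism("mm_irrev", seed = seed))$strongly_irreversible)
    ap_rev <- aggregated_params(make_mechanism("mm_rev", seed = seed))
    expect_gt(ap_rev$kappa1, 0)
    expect_gt(ap_rev$c10, 0)
    expect_false(ap_rev$strongly_irreversible)
    expect_false(ap_rev$weakly_irreversible)
  }
  # removing the reverse catalytic step makes a mechanism weakly
  # irreversible: product rebinds (kappa1 > 0) but is never converted back
  m <- enzyme_mechanism("E", c("Y1", "Y2"), list(
    list(type = "binding", substrate = "S0", to = "Y1", rate = "k1"),
    list(type = "release", from = "Y1", substrate = "S0", rate = "k2"),
    list(type = "conversion", from = "Y1", to = "Y2", rate = "k3"),
    list(type = "release", from = "Y2", substrate = "S1", rate = "k4"),
    list(type = "binding", substrate = "S1", to = "Y2", rate = "k5")),
    c(k1 = 1, k2 = 2, k3 = 3, k4 = 4, k5 = 5))
  ap <- aggregated_params(m)
  expect_gt(ap$kappa1, 0)
  expect_equal(ap$c10, 0)
  expect_true(ap$weakly_irreversible)
})

test_that("aggregated parameters are invariant under intermediate relabelling", {
  base <- make_mechanism("bibi", seed = 4)
  ren <- c(EY1 = "EY3", EY2 = "EY4", EY3 = "EY1", EY4 = "EY2")
  swap <- function(v) ifelse(v %in% names(ren), ren[v], v)
  rx2 <- lapply(base$reactions, function(rx) {
    if (!is.null(rx$from)) rx$from <- unname(swap(rx$from))
    if (!is.null(rx$to)) rx$to <- unname(swap(rx$to))
    rx
  })
  other <- enzyme_mechanism(base$enzyme, unname(swap(base$intermediates)),
                            rx2, base$parameters)
  a <- aggregated_params(base)
  b <- aggregated_params(other)
  expect_equal(a$kappa0, b$kappa0, tolerance = 1e-12)
  expect_equal(a$kappa1, b$kappa1, tolerance = 1e-12)
  expect_equal(a$c01, b$c01, tolerance = 1e-12)
  expect_equal(a$c10, b$c10, tolerance = 1e-12)
  expect_equal(unname(a$kappa0_Yi[names(ren)]),
               unname(b$kappa0_Yi[unname(ren)]), tolerance = 1e-12)
})

test_that("the substrate graph reproduces the enzyme-weighted flux ratio", {
  cyc <- make_random_cycle(31)
  E <- 0.4; F_ <- 0.8
  gs <- substrate_graph(cyc, E, F_)
  u <- steady_state(gs)
  expected <- (cyc$ap_E$c01 * E + cyc$ap_F$c01 * F_) /
    (cyc$ap_E$c10 * E + cyc$ap_F$c10 * F_)
  expect_equal(u[["S1"]] / u[["S0"]], expected, tolerance = 1e-12)
  # both enzymes weakly/strongly irreversible: everything ends modified
  cyc2 <- modification_cycle(make_mechanism("mm_irrev", "E", seed = 5),
                             make_mechanism("mm_irrev", "F", sub = "S1",
                                            prod = "S0", seed = 6),
                             E_tot = 1, F_tot = 1, S_tot = 1)
  s <- linfra:::substrate_state(cyc2, E = 0.5, F_ = 0)
  expect_equal(unname(s["S0"]), 0)
})

test_that("the reduced system respects conservation limits", {
  cyc <- make_random_cycle(8)
  rs <- reduced_system(cyc)
  # free enzyme never exceeds the conservation relation value
  for (rep in 1:10) {
    E <- runif(1, 0.01, cyc$E_tot)
    F_ <- runif(1, 0.01, cyc$F_tot)
    expect_gte(rs$R_E(E, F_), E)
    expect_gte(rs$R_F(E, F_), F_)
  }
  # with no substrate the relations are the identity
  cyc0 <- cyc
  cyc0$S_tot <- 0
  rs0 <- reduced_system(cyc0)
  expect_equal(rs0$R_E(0.3, 0.9), 0.3)
  expect_equal(rs0$R_F(0.3, 0.9), 0.9)
})

test_that("reduced-system roots satisfy conservation and the full ODE", {
  for (seed in c(2, 14, 27)) {
    cyc <- make_random_cycle(seed)
    roots <- solve_cycle(cyc)
    for (rt in roots) {
      st <- rt$state
      ints_E <- cyc$forward$intermediates
      ints_F <- cyc$reverse$intermediates
      expect_equal(st[[cyc$forward$enzyme]] + sum(st[ints_E]), cyc$E_tot,
                   tolerance = 1e-9 * cyc$E_tot)
      expect_equal(st[[cyc$reverse$enzyme]] + sum(st[ints_F]), cyc$F_tot,
                   tolerance = 1e-9 * cyc$F_tot)
      sub_total <- st[["S0"]] + st[["S1"]] + sum(st[c(ints_E, ints_F)])
      expect_equal(sub_total, cyc$S_tot, tolerance = 1e-9 * cyc$S_tot)
    }
    # the ODE oracle lands on one of the roots
    st_ode <- ode_oracle(cyc)
    errs <- vapply(roots, function(rt) {
      max(abs(rt$state[names(st_ode)] - st_ode)) / max(st_ode)
    }, numeric(1))
    expect_lt(min(errs), 1e-6)
    # and conserves all three totals along the way
    expect_equal(st_ode[[cyc$forward$enzyme]] +
                   sum(st_ode[cyc$forward$intermediates]),
                 cyc$E_tot, tolerance = 1e-8 * cyc$E_tot)
  }
})

test_that("strongly irreversible enzymes at high substrate give a sharp switch", {
  # zero-order regime: substrate far above the Michaelis scale
  mE <- enzyme_mechanism("E", "EY", list(
    list(type = "binding", substrate = "S0", to = "EY", rate = "kon"),
    list(type = "release", from = "EY", substrate = "S0", rate = "koff"),
    list(type = "release", from = "EY", substrate = "S1", rate = "kcat")),
    c(kon = 10, koff = 1, kcat = 1))
  mF <- enzyme_mechanism("F", "FY", list(
    list(type = "binding", substrate = "S1", to = "FY", rate = "kon2"),
    list(type = "release", from = "FY", substrate = "S1", rate = "koff2"),
    list(type = "release", from = "FY", substrate = "S0", rate = "kcat2")),
    c(kon2 = 10, koff2 = 1, kcat2 = 1))
  ratios <- 10^seq(-0.4, 0.4, length.out = 9)
  frac <- vapply(ratios, function(r) {
    cyc <- modification_cycle(mE, mF, E_tot = 0.01 * r, F_tot = 0.01,
                              S_tot = 20)
    st <- solve_cycle(cyc)[[1]]$state
    st[["S1"]] / cyc$S_tot
  }, numeric(1))
  expect_true(all(diff(frac) > 0))        # monotone in the enzyme ratio
  expect_lt(frac[1], 0.1)                 # nearly all unmodified below
  expect_gt(frac[length(frac)], 0.9)      # nearly all modified above
})
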