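test_that("the vector field matches hand-computed values", {
  lot <- mass_action(lotka(), 1)
  expect_equal(rhs(lot, c(1, 1)), c(0, 0))
  expect_equal(rhs(lot, c(2, 3)), c(2 - 6, 6 - 3))
  expect_equal(rhs(mass_action(lva(), 1), c(1, 1)), c(0, 0))
  inflow <- mass_action(parse_network("0 -> X\nX + Y -> Y"), c(2, 1))
  expect_equal(rhs(inflow, c(5, 7)), c(2 - 35, 0))
  expect_equal(rhs(inflow, c(0, 3)), c(2, 0))   # boundary evaluation, 0^0 = 1
})

test_that("the analytic Jacobian matches finite differences", {
  expect_equal(unname(ma_jacobian(mass_action(lotka(), 1), c(1, 1))),
               cbind(c(0, 1), c(-1, 0)))
  J <- ma_jacobian(mass_action(lva(), 1), c(1, 1))
  expect_equal(unname(J), cbind(c(1, 1), c(-1, 0)))
  expect_equal(sum(diag(J)), 1)
  set.seed(7)
  for (rep in 1:40) {
    net <- random_osc_net(sample(2:3, 1))
    sys <- mass_action(net, runif(3, 0.3, 3))
    x <- runif(net$n, 0.3, 2.5)
    Ja <- ma_jacobian(sys, x)
    h <- 1e-6
    Jn <- vapply(seq_len(net$n), function(k) {
      xp <- x; xm <- x
      xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      (rhs(sys, xp) - rhs(sys, xm)) / (2 * h)
    }, numeric(net$n))
    expect_lt(max(abs(Ja - Jn)) / max(1, max(abs(Ja))), 1e-6)
  }
})

test_that("rhs respects the linear conservation laws", {
  set.seed(8)
  for (rep in 1:40) {
    net <- random_any_net(n = 3, m = 3)
    sys <- mass_action(net, runif(3, 0.2, 4))
    W <- crnosc:::nullspace_exact(t(matrices(net)$G))
    if (ncol(W) == 0) next
    for (i in 1:5) {
      x <- runif(3, 0.1, 5)
      expect_lt(max(abs(t(W) %*% rhs(sys, x))), 1e-10)
    }
  }
})

test_that("the log-linear solver finds the closed-form equilibrium of the
           tetramolecular Hopf network", {
  set.seed(9)
  for (rep in 1:25) {
    k <- runif(3, 0.2, 5)
    eq <- positive_equilibria(mass_action(net4(), k))
    expect_true(eq$exists && eq$unique)
    expect_equal(eq$x, c(k[3] / k[2], k[1] * k[3] / k[2] ^ 2), tolerance = 1e-10)
  }
})

test_that("nondegenerate (2,3,2) systems have exactly one positive equilibrium
           with tiny residual", {
  set.seed(10)
  count <- 0
  while (count < 200) {
    net <- random_osc_net(2)
    sys <- mass_action(net, runif(3, 0.2, 5))
    eq <- positive_equilibria(sys)
    expect_true(eq$exists)
    expect_true(eq$unique)
    expect_lt(eq$residual, 1e-10 * max(1, max(abs(crnosc:::.rates(sys, eq$x)))))
    count <- count + 1
  }
})

test_that("affinely dependent sources never give an isolated equilibrium", {
  # sources X, X+Y, X+2Y are collinear; kernel one-signed, rank 2
  net <- parse_network("X -> 2X\nX + Y -> X\nX + 2Y -> 2X + 3Y")
  expect_true(sources_collinear(net))
  sys <- mass_action(net, c(1, 1, 1))
  eq <- positive_equilibria(sys)
  if (eq$exists) expect_gte(ncol(eq$log_directions), 1)
  # lifted LVA: a ray of equilibria (one log-space direction)
  eql <- positive_equilibria(mass_action(lifted_lva(1), c(1, 2, 2)))
  expect_true(eql$exists && !eql$unique)
  expect_equal(ncol(eql$log_directions), 1)
})

test_that("equilibria_on_class picks the equilibrium in a stoichiometric class", {
  sysl <- mass_action(lifted_lva(1), c(1, 2, 2))
  # ray (t, t/2, t); class z - y = 1 gives t = 2
  pts <- equilibria_on_class(sysl, c(1, 1, 2))
  expect_equal(nrow(pts), 1)
  expect_equal(as.numeric(pts[1, ]), c(2, 1, 2), tolerance = 1e-8)
  # no equilibrium on classes with C < 0
  expect_equal(nrow(equilibria_on_class(sysl, c(1, 2, 1))), 0)
})

test_that("conserved quantities have vanishing Lie derivative", {
  set.seed(11)
  cases <- list(
    list(sys = mass_action(lotka(), c(1.3, 0.7, 2.1)), min_q = 1),
    list(sys = mass_action(generalized_lotka(2, 1), c(1, 2, 3)), min_q = 1),
    list(sys = mass_action(ivanova(), c(1, 2, 3)), min_q = 2),
    list(sys = mass_action(three_species_center_family(1, 2), c(4, 1, 1)), min_q = 2),
    list(sys = mass_action(lifted_lva(1), c(1, 2, 2)), min_q = 1)
  )
  for (cs in cases) {
    qs <- conserved_quantities(cs$sys)
    expect_gte(length(qs), cs$min_q)
    n <- cs$sys$net$n
    for (q in qs) {
      for (i in 1:20) {
        x <- runif(n, 0.2, 4)
        scale <- max(1, max(abs(rhs(cs$sys, x))))
        expect_lt(abs(lie_derivative(q, cs$sys, x)) / scale, 1e-10)
      }
    }
  }
  # Ivanova linear integral is x + y + z
  w <- conserved_quantities(mass_action(ivanova(), 1))[[1]]$coefficients
  expect_equal(abs(w / w[1]), c(1, 1, 1))
  # lifted LVA linear integral is z - y
  wl <- conserved_quantities(mass_action(lifted_lva(1), 1))[[1]]$coefficients
  expect_equal(sort(wl / max(abs(wl))), c(-1, 0, 1))
})

test_that("simulation conserves the linear integrals and flags blow-up", {
  tri <- simulate_system(mass_action(ivanova(), 1), c(1, 2, 3), 30)
  expect_false(attr(tri, "blowup"))
  expect_lt(max(attr(tri, "drift")), 1e-9)
  expect_equal(unname(rowSums(as.matrix(tri[, -1]))[1]), 6)

  # LVA is globally repelling: distance from (1,1) increases, then blow-up
  trl <- simulate_system(mass_action(lva(), 1), c(1.1, 1), 12, n_out = 1500)
  st <- as.matrix(trl[, -1])
  d <- sqrt((st[, 1] - 1) ^ 2 + (st[, 2] - 1) ^ 2)
  ret <- crnosc:::.return_radii(mass_action(lva(), 1), c(1, 1), c(1.1, 1), 9)
  if (length(ret) >= 2) expect_true(all(diff(ret) > 0))
  expect_gt(d[length(d)], d[1])
  expect_true(attr(trl, "blowup"))
})

test_that("periodicity detection separates centers from spirals", {
  # Lotka: closed orbit through (2, 1)
  dl <- detect_periodicity(mass_action(lotka(), 1), c(2, 1), t_end = 60)
  expect_true(isTRUE(dl$periodic))
  expect_lt(dl$closure_error, 1e-4)
  # lifted LVA at k2 = k3 > k1: center on the class z - y = 1
  dc <- detect_periodicity(mass_action(lifted_lva(1), c(1, 2, 2)), c(1, 1, 2),
                           t_end = 120)
  expect_true(isTRUE(dc$periodic))
  # k2 < k3: globally asymptotically stable, hence not periodic
  ds <- detect_periodicity(mass_action(lifted_lva(1), c(1, 2, 3)), c(1, 1, 2),
                           t_end = 300)
  expect_false(isTRUE(ds$periodic))
  expect_identical(ds$periodic, FALSE)
})
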