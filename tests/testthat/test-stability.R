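test_that("source orientation reproduces the cross-product sign rule", {
  expect_equal(source_orientation(lva(), 1, 2), 1)
  # reversing the reaction order (species order pinned) flips the orientation
  l <- lva()
  rev_lva <- network(l$species, l$source[, 3:1], l$target[, 3:1])
  expect_equal(source_orientation(rev_lva, 1, 2), -1)
  col <- parse_network("2X -> X\nX + Y -> 2X\n2Y -> Y")
  expect_equal(source_orientation(col, 1, 2), 0)
})

test_that("the reduced Jacobian of the four-species saddle matches the
           closed-form expansion", {
  sys <- mass_action(four_species_saddle(), c(1, 1, 1))
  pts <- equilibria_on_class(sys, c(1, 1, 1, 1))
  expect_equal(nrow(pts), 1)
  x <- as.numeric(pts[1, ])
  rj <- reduced_jacobian(sys, x)
  expect_equal(rj$u, c(-1, -1, -1))
  expect_lt(rj$mu, 0)
  # det Jred = mu|mu| (2/(x y) + 1/(x z) + 1/(x w)): only pairs (1,2),(1,3),(1,4)
  nonzero <- rj$terms$term != 0
  expect_equal(paste(rj$terms$i[nonzero], rj$terms$j[nonzero]),
               c("1 2", "1 3", "1 4"))
  expect_equal(rj$det,
               rj$mu * abs(rj$mu) * (2 / (x[1] * x[2]) + 1 / (x[1] * x[3]) + 1 / (x[1] * x[4])))
  expect_equal(rj$det, rj$det_cauchy_binet)
  expect_equal(rj$det_sign, -1L)
})

test_that("for two species the reduced Jacobian determinant is the plain one", {
  sys <- mass_action(lva(), 1)
  rj <- reduced_jacobian(sys, c(1, 1))
  J <- ma_jacobian(sys, c(1, 1))
  expect_equal(rj$det, J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
  expect_equal(rj$det, 1)
})

test_that("matrix determinant, Cauchy-Binet expansion, and the eigenvalue
           product agree on random (n,3,2) systems", {
  set.seed(12)
  count <- 0
  while (count < 200) {
    n <- sample(2:4, 1)
    net <- random_osc_net(n)
    sys <- mass_action(net, runif(3, 0.2, 5))
    eq <- positive_equilibria(sys)
    if (!eq$exists) next
    x <- eq$x
    rj <- reduced_jacobian(sys, x)
    expect_equal(rj$det, rj$det_cauchy_binet,
                 tolerance = 1e-9)
    ev <- eigen(ma_jacobian(sys, x), only.values = TRUE)$values
    ord <- order(Mod(ev), decreasing = TRUE)
    prod2 <- Re(prod(ev[ord[1:2]]))
    if (n > 2) {
      expect_lt(max(Mod(ev[ord[-(1:2)]])), 1e-7 * max(1, Mod(ev[ord[1]])))
    }
    if (abs(rj$det) > 1e-8) {
      expect_equal(sign(prod2), sign(rj$det))
      expect_equal(prod2, rj$det, tolerance = 1e-6)
    }
    count <- count + 1
  }
})

test_that("the planar formulas reproduce the analytic determinant and trace,
           and the sign rule holds", {
  set.seed(13)
  count <- 0
  while (count < 120) {
    net <- random_osc_net(2)
    sys <- mass_action(net, runif(3, 0.2, 5))
    eq <- positive_equilibria(sys)
    if (!eq$exists) next
    pdt <- planar_det_tr(sys, eq)
    expect_equal(pdt$det_formula, pdt$det,
                 tolerance = 1e-9)
    expect_equal(pdt$tr_formula, pdt$tr,
                 tolerance = 1e-9)
    # Eq. (17): with positively oriented sources, sgn det J = sgn mu = sgn u
    ori <- sum(crnosc:::.cross3(sys$Gl[1, ], sys$Gl[2, ]))
    if (ori > 0 && abs(pdt$det) > 1e-10) {
      expect_equal(sign(pdt$det), sign(pdt$mu))
      expect_equal(sign(pdt$det), unique(sign(pdt$u)))
    }
    count <- count + 1
  }
})

test_that("the privileged-row choice does not affect the determinant sign", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(3:4, 1)
    net <- random_osc_net(n)
    sys <- mass_action(net, runif(3, 0.3, 3))
    eq <- positive_equilibria(sys)
    if (!eq$exists) next
    rj <- reduced_jacobian(sys, eq$x)
    p <- sample(n)
    pnet <- network(net$species[p], net$source[p, ], net$target[p, ])
    psys <- mass_action(pnet, sys$kappa)
    prj <- reduced_jacobian(psys, eq$x[p])
    expect_equal(prj$det_sign, rj$det_sign)
    expect_equal(prj$det, rj$det, tolerance = 1e-8)
  }
})

test_that("planar classification matches the reference systems", {
  plot_lotka <- planar_det_tr(mass_action(lotka(), 1))
  expect_equal(plot_lotka$det, 1)
  expect_equal(plot_lotka$tr, 0)
  expect_equal(plot_lotka$class, "center_candidate")

  plva <- planar_det_tr(mass_action(lva(), 1))
  expect_equal(plva$det, 1)
  expect_equal(plva$tr, 1)
  expect_equal(plva$class, "unstable_focus_or_node")

  # tetramolecular Hopf network: trace vanishes exactly at k1 = k2
  expect_lt(abs(planar_det_tr(mass_action(net4(), c(2, 2, 1)))$tr), 1e-12)
  expect_gt(planar_det_tr(mass_action(net4(), c(2.5, 2, 1)))$tr, 0)
  expect_lt(planar_det_tr(mass_action(net4(), c(1.5, 2, 1)))$tr, 0)
})

test_that("Hopf location and the first focal value separate supercritical,
           vertical, and center cases", {
  hp <- find_hopf_point(net4(), param = 1)
  expect_equal(hp$kappa[1], hp$kappa[2], tolerance = 1e-10)
  ff <- first_focal_value(mass_action(net4(), hp$kappa))
  expect_lt(ff$L1, 0)
  expect_true(ff$supercritical)

  # the other three tetramolecular networks are supercritical too
  for (d in 1:3) {
    hpd <- find_hopf_point(hopf_tetramolecular(d), param = 1)
    ffd <- first_focal_value(mass_action(hopf_tetramolecular(d), hpd$kappa))
    expect_lt(ffd$L1, 0)
  }

  # case-8 pentamolecular network: linear after division by x => L1 = 0
  ff8 <- first_focal_value(mass_action(vertical_hopf_pentamolecular(), c(1, 1, 1)))
  expect_true(ff8$vertical_candidate)
  expect_lt(abs(ff8$L1_scaled), 1e-8)

  # Lotka center: all focal values vanish
  ffl <- first_focal_value(mass_action(lotka(), c(2, 1, 3)))
  expect_true(ffl$vertical_candidate)

  expect_error(first_focal_value(mass_action(net4(), c(2, 1, 1))), "tr J != 0")
})
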