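test_that("the precondition checklist catches each necessary condition", {
  two <- parse_network("X -> 2X\n2X -> X")
  pre2 <- oscillation_preconditions(two)
  expect_false(pre2$pass)
  expect_equal(pre2$first_fail, "enough_reactions")

  # collinear sources (2X, X+Y, 2Y) with positively dependent reaction vectors
  col <- parse_network("2X -> Y\nX + Y -> 2X + Y\n2Y -> X + Y")
  prec <- oscillation_preconditions(col)
  expect_true(prec$checks$dynamically_nontrivial)
  expect_false(prec$pass)
  expect_equal(prec$first_fail, "sources_not_collinear")

  expect_true(oscillation_preconditions(lotka())$pass)
  expect_true(oscillation_preconditions(ivanova())$pass)
})

test_that("autocatalytic-form detection follows the sign pattern", {
  expect_true(has_autocatalytic_form9(lva())$status)
  expect_false(has_autocatalytic_form9(lotka())$status)
  expect_true(has_autocatalytic_form9(parse_network("2X -> 3X + Y"))$status)
  # losing another species disqualifies
  expect_false(has_autocatalytic_form9(parse_network("2X -> 3X\nX + Y -> X"))$reaction == 2)
  expect_false(has_autocatalytic_form9(parse_network("2X -> X + Y"))$status)
})

test_that("the no-autocatalysis classifier recognizes the center families", {
  expect_equal(classify_no_form9(ivanova())$outcome, "center_for_all_kappa")
  v <- classify_no_form9(generalized_lotka(2, 1))
  expect_equal(v$outcome, "center_for_all_kappa")
  expect_equal(v$family, "generalized_lotka")
  expect_equal(unname(unlist(v$params)), c(2, 1))

  v12 <- classify_no_form9(three_species_center_family(2, 3))
  expect_equal(v12$outcome, "center_on_condition")
  expect_equal(unname(unlist(v12$params)), c(2, 3))

  # an inflow reaction contributes negative divergence: Bendixson-Dulac
  nb <- parse_network("0 -> X\nX + Y -> 2Y\nY -> 0")
  expect_equal(classify_no_form9(nb)$outcome, "no_periodic_orbit")
  expect_equal(classify_no_form9(nb)$fired_rule, "bendixson_dulac")
})

test_that("three-species center family regimes follow the rate-constant gap", {
  expect_equal(family12_regime(1, 1, c(3, 1, 1), -1), "center")
  expect_equal(family12_regime(1, 1, c(3, 1, 1), +1), "no_equilibrium")
  expect_equal(family12_regime(1, 1, c(2, 1, 1), -5), "invariant_rays")
  expect_equal(family12_regime(1, 1, c(1, 1, 1), +1), "saddle")
  expect_equal(family12_regime(1, 1, c(1, 1, 1), -1), "no_equilibrium")
  expect_equal(family12_regime(2, 3, c(10, 1, 2), -1), "center")
})

test_that("the equilibrium ray and classes of the center family match the
           closed forms", {
  cc <- 2; dd <- 3
  k <- c(9, 1.5, 0.5)
  sys <- mass_action(three_species_center_family(cc, dd), k)
  # ray t (c d k3, c k1, k2)
  ray <- c(cc * dd * k[3], cc * k[1], k[2])
  for (t in c(0.5, 1, 2)) {
    expect_lt(max(abs(rhs(sys, t * ray))), 1e-12)
  }
  # class coordinate x - y + c z is conserved
  W <- crnosc:::nullspace_exact(t(matrices(sys$net)$G))
  expect_equal(abs(W[, 1] / W[1, 1]), c(1, 1, cc))
})

test_that("lifted LVA regimes match the sign conditions and the dynamics", {
  expect_equal(lifted_lva_regime(1, c(1, 2, 2), 1), "center")
  expect_equal(lifted_lva_regime(1, c(1, 2, 3), 1), "stable")
  expect_equal(lifted_lva_regime(1, c(1, 3, 2), 1), "repellor")
  expect_equal(lifted_lva_regime(1, c(4, 1, 2), 1), "no_equilibrium")
  expect_equal(lifted_lva_regime(1, c(4, 1, 2), -1), "saddle")
  expect_equal(lifted_lva_regime(2, c(2, 1, 1), 0), "line_of_equilibria")
})

test_that("planar source cases are identified with swap normalization", {
  expect_equal(source_case_planar(net4())$case_id, 9)
  expect_equal(source_case_planar(lotka())$case_id, 7)
  expect_equal(source_case_planar(vertical_hopf_pentamolecular())$case_id, 8)
  expect_equal(source_case_planar(hopf_heptamolecular())$case_id, 10)
  # swapped case 8: sources 2Y, X+Y, Y with species order (X, Y) pinned
  mirror8 <- network(c("X", "Y"),
                     source = cbind(c(0, 2), c(1, 1), c(0, 1)),
                     target = cbind(c(2, 3), c(0, 0), c(0, 2)))
  sw <- source_case_planar(mirror8)
  expect_equal(sw$case_id, 8)
  expect_true(any(vapply(sw$labelings, `[[`, TRUE, "swap")))
  expect_error(source_case_planar(parse_network("2X -> X\nX + Y -> 2X\n2Y -> Y")),
               "collinear")
})

test_that("the planar Hopf classification reproduces the worked examples", {
  v4 <- hopf_verdict_planar(net4())
  expect_equal(v4$outcome, "supercritical_hopf")
  expect_equal(v4$details$case, 9)

  vl <- hopf_verdict_planar(lotka())
  expect_equal(vl$outcome, "center_for_all_kappa")
  expect_equal(vl$details$case, 7)

  v8 <- hopf_verdict_planar(vertical_hopf_pentamolecular())
  expect_equal(v8$outcome, "vertical_hopf")
  expect_match(v8$details$critical, "kappa2 = 1 kappa1")

  v10 <- hopf_verdict_planar(hopf_heptamolecular())
  expect_equal(v10$outcome, "supercritical_hopf")

  # cases 1-6: no periodic orbit regardless of targets
  v16 <- hopf_verdict_planar(parse_network("0 -> Y\nX -> 0\nY + X -> 2X"))
  expect_equal(v16$fired_rule, "cases_1_to_6")

  # generalized LVA: case 9 window fails, repellor argument applies
  vg <- hopf_verdict_planar(generalized_lva(3))
  expect_equal(vg$outcome, "no_periodic_orbit")
  expect_equal(vg$fired_rule, "generalized_lva_repellor")

  # mirrored (swapped) tetramolecular network classifies identically
  vm <- hopf_verdict_planar(parse_network("2Y -> 3Y + X\nY + X -> 2X\nX -> 0"))
  expect_equal(vm$outcome, "supercritical_hopf")
})

test_that("generalized LVA matching returns the parameter", {
  expect_true(generalized_lva_check(lva())$status)
  expect_equal(generalized_lva_check(lva())$d, 1)
  g3 <- generalized_lva_check(generalized_lva(3))
  expect_true(g3$status)
  expect_equal(g3$d, 3)
  expect_false(generalized_lva_check(net4())$status)
})

test_that("the general trimolecular classifier dispatches by species count", {
  # no autocatalysis: center families
  expect_equal(classify_trimolecular_general(lotka())$outcome, "center_for_all_kappa")
  expect_equal(classify_trimolecular_general(ivanova())$outcome, "center_for_all_kappa")
  expect_equal(classify_trimolecular_general(generalized_lotka(2, 2))$outcome,
               "center_for_all_kappa")

  # 2X -> 3X with two species: generalized LVA or saddle, never periodic
  expect_equal(classify_trimolecular_general(lva())$outcome, "no_periodic_orbit")

  # three species: lifted LVA is the only oscillatory outcome
  vlift <- classify_trimolecular_general(lifted_lva(1))
  expect_equal(vlift$outcome, "vertical_hopf")
  expect_equal(vlift$family, "lifted_lva")
  other3 <- parse_network("2X -> 3X\nX -> Y + Z\nY + Z -> 0")
  v3 <- classify_trimolecular_general(other3)
  expect_false(v3$oscillatory)

  # four species: the unique saddle network, no oscillation
  v27 <- classify_trimolecular_general(four_species_saddle())
  expect_equal(v27$outcome, "saddle_always")
  expect_false(v27$oscillatory)

  # five species with 2X -> 3X: dynamically trivial
  v5 <- classify_trimolecular_general(
    parse_network("2X -> 3X\nX + Y -> Z\nW + V -> X + Y"))
  expect_equal(v5$outcome, "dynamically_trivial")

  # trivial species are stripped and reported
  aug <- parse_network("X + Z -> 2X + Z\nX + Y -> 2Y\nY -> 0")
  va <- classify_trimolecular_general(aug)
  expect_equal(va$outcome, "center_for_all_kappa")
  expect_equal(va$stripped_species, "Z")

  expect_error(classify_trimolecular_general(net4()), "trimolecular")
})

test_that("center verdicts are corroborated by closed orbits and saddle
           verdicts by eigenvalues", {
  # generalized Lotka (2,1): closed orbit through a sampled point
  sys <- mass_action(generalized_lotka(2, 1), c(1, 1, 1))
  dp <- detect_periodicity(sys, c(1.3, 1.9), t_end = 80)
  expect_true(isTRUE(dp$periodic))

  # center family bullet 1: closed orbit on a class with D < 0
  sysc <- mass_action(three_species_center_family(1, 1), c(3, 1, 1))
  # equilibrium ray t(1,3,1): pick the class of a perturbed ray point
  x0 <- c(1.1, 3, 1)
  expect_equal(family12_regime(1, 1, c(3, 1, 1), sum(c(1, -1, 1) * x0)), "center")
  dpc <- detect_periodicity(sysc, x0, t_end = 60)
  expect_true(isTRUE(dpc$periodic))

  # bullet 3: saddle (reduced Jacobian determinant < 0)
  syss <- mass_action(three_species_center_family(1, 1), c(1, 1, 1))
  pts <- equilibria_on_class(syss, c(2, 1, 1))
  expect_equal(nrow(pts), 1)
  expect_lt(reduced_jacobian(syss, as.numeric(pts[1, ]))$det, 0)
})
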