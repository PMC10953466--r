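test_that("parsing builds the expected matrices and round-trips", {
  lot <- parse_network("X -> 2X\nX + Y -> 2Y\nY -> 0")
  expect_equal(lot$species, c("X", "Y"))
  expect_equal(lot$m, 3L)
  M <- matrices(lot)
  expect_equal(unname(M$Gl), cbind(c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(unname(M$G), cbind(c(1, 0), c(-1, 1), c(0, -1)))
  expect_identical(parse_network(format_network(lot)), lot)

  n4 <- parse_network("2X -> 3X + Y\nX + Y -> Y\nY -> 0")
  expect_equal(unname(matrices(n4)$G), cbind(c(1, 1), c(-1, 0), c(0, -1)))

  one <- parse_network("2X -> 3X")
  expect_equal(unname(matrices(one)$Gl), matrix(2))
  expect_equal(unname(matrices(one)$G), matrix(1))
})

test_that("parser rejects malformed input", {
  expect_error(parse_network("0 -> 0"), "equal")
  expect_error(parse_network("X -> X"), "equal")
  expect_error(parse_network("X - > Y"), "malformed|expected")
  expect_error(parse_network("2 -> X"), "malformed")
  expect_error(network(c("X", "Y"), matrix(c(1, 0)), matrix(c(2, 0))), "no complex")
})

test_that("rank and molecularity profiles match the reference networks", {
  expect_equal(network_rank(lotka()), 2L)
  expect_equal(network_rank(ivanova()), 2L)
  expect_equal(network_rank(parse_network("X -> 2X\n2X -> 3X")), 1L)
  # Ivanova mass conservation: all column sums of Gamma vanish
  expect_true(all(colSums(matrices(ivanova())$G) == 0))

  mp <- molecularity_profile(net4())
  expect_equal(mp$max_source, 2)
  expect_equal(mp$max_target, 4)
  expect_true(mp$is_quadratic)
  expect_true(mp$is_tetramolecular && !mp$is_trimolecular)
  expect_true(molecularity_profile(lotka())$is_bimolecular)
  expect_equal(molecularity_profile(parse_network("0 -> X"))$max_source, 0)
})

test_that("trivial species are the zero rows of Gamma", {
  expect_length(trivial_species(lotka()), 0)
  expect_length(trivial_species(ivanova()), 0)
  aug <- parse_network("X + Z -> 2X + Z\nX + Y -> 2Y\nY -> 0")
  expect_equal(aug$species[trivial_species(aug)], "Z")
  st <- strip_trivial_species(aug)
  expect_true(networks_isomorphic(st$net, lotka()))
  expect_equal(st$removed_species, "Z")
})

test_that("dynamical nontriviality certificates verify exactly", {
  lt <- is_dynamically_nontrivial(lotka())
  expect_true(lt$status)
  expect_equal(lt$positive_kernel_vector, c(1, 1, 1))

  tv <- is_dynamically_nontrivial(parse_network("X -> 2X\nY -> 2Y\nX + Y -> 2X + 2Y"))
  expect_false(tv$status)
  gv <- t(matrices(parse_network("X -> 2X\nY -> 2Y\nX + Y -> 2X + 2Y"))$G) %*%
    tv$separating_vector
  expect_true(all(gv >= 0) && any(gv > 0))

  expect_true(is_dynamically_nontrivial(four_species_saddle())$status)
})

test_that("nontriviality agrees with the brute-force kernel oracle", {
  set.seed(41)
  n_checked <- 0
  for (rep in 1:120) {
    net <- random_any_net(n = sample(2:3, 1), m = 3)
    res <- is_dynamically_nontrivial(net)
    G <- matrices(net)$G
    if (res$status) {
      u <- res$positive_kernel_vector
      expect_true(all(u > 0))
      expect_true(all(G %*% u == 0))
    } else {
      v <- res$separating_vector
      gv <- t(G) %*% v
      expect_true(all(gv >= 0) && any(gv > 0))
      expect_null(grid_kernel_oracle(net))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 120)
})

test_that("kernel sign vector matches the cross-product formula and nontriviality", {
  expect_equal(kernel_sign_vector(lotka()), c(1, 1, 1))
  expect_equal(kernel_sign_vector(net4()), c(1, 1, 1))
  expect_equal(kernel_sign_vector(four_species_saddle()), c(-1, -1, -1))
  set.seed(42)
  for (rep in 1:60) {
    net <- random_any_net(n = 2, m = 3)
    if (network_rank(net) != 2) next
    u <- kernel_sign_vector(net)
    expect_equal(all(u > 0) || all(u < 0),
                 is_dynamically_nontrivial(net)$status)
  }
})

test_that("a dynamically nontrivial network has rank at most m - 1", {
  set.seed(43)
  for (rep in 1:80) {
    net <- random_any_net(n = sample(2:3, 1), m = sample(2:3, 1))
    if (is_dynamically_nontrivial(net)$status) {
      expect_lte(network_rank(net), net$m - 1)
    }
  }
})

test_that("source collinearity detects affine dependence", {
  expect_true(sources_collinear(parse_network("2X -> X\nX + Y -> 2X\n2Y -> Y")))
  expect_false(sources_collinear(parse_network("2X -> X\nX + Y -> 2X\nY -> 2Y")))
  expect_true(sources_collinear(parse_network("X -> 2X\n2X -> X")))
})

test_that("canonicalization is idempotent and permutation/order invariant", {
  relabeled <- parse_network("Y -> 2Y\nY + X -> 2X\nX -> 0")
  expect_true(networks_isomorphic(lotka(), relabeled))
  reversed <- parse_network(rev(format_network(lotka())))
  expect_true(networks_isomorphic(lotka(), reversed))
  expect_false(networks_isomorphic(lotka(), ivanova()))
  can <- canonicalize(lotka())
  expect_identical(canonical_key(can), canonical_key(lotka()))
  set.seed(44)
  for (rep in 1:25) {
    net <- random_any_net(n = 3, m = 3)
    p <- sample(3)
    perm <- network(net$species[p], net$source[p, ], net$target[p, ])
    expect_identical(canonical_key(net), canonical_key(perm))
    expect_identical(canonical_key(canonicalize(net)), canonical_key(net))
  }
})

test_that("trimolecularization preserves the vector field exactly", {
  tm <- trimolecularize(net4(), c(1, 1, 1))
  expect_equal(sort(format_network(tm$net))[1:2], c("2X -> 2X + Y", "2X -> 3X"))
  expect_lte(molecularity_profile(tm$net)$max_target, 3)

  hi <- parse_network("X + Y -> 4X")
  tm2 <- trimolecularize(hi, 2)
  expect_equal(tm2$kappa, c(6, 2))
  # exact equality at integer points (all monomial terms are integers)
  for (x in list(c(1, 1), c(2, 3), c(5, 2))) {
    f_orig <- rhs(mass_action(hi, 2), x)
    f_tri <- rhs(mass_action(tm2$net, tm2$kappa), x)
    expect_identical(f_orig, f_tri)
  }
  s4 <- mass_action(net4(), c(3, 1, 2))
  tm3 <- trimolecularize(net4(), c(3, 1, 2))
  s4t <- mass_action(tm3$net, tm3$kappa)
  for (x in list(c(1, 1), c(2, 5), c(4, 3))) {
    expect_identical(rhs(s4, x), rhs(s4t, x))
  }
  # trimolecular input is returned unchanged
  tm4 <- trimolecularize(lotka(), c(1, 2, 3))
  expect_identical(format_network(tm4$net), format_network(lotka()))
  expect_error(trimolecularize(parse_network("3X -> X")), "quadratic")
})

test_that("embedded graph and JSON export are consistent", {
  eg <- embedded_graph(lotka())
  expect_equal(nrow(eg$edges), 3)
  expect_true(all(eg$edges$from %in% eg$nodes$id))
  js <- jsonlite::fromJSON(network_to_json(lotka()), simplifyVector = FALSE)
  expect_equal(unlist(js$species), c("X", "Y"))
  expect_equal(js$reactions[[1]]$target$X, 2)
})
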