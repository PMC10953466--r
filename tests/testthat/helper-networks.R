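# shared fixtures and oracles, all built in code

# network (4)-style reference systems
net4 <- function() hopf_tetramolecular(0)

# brute-force oracle for dynamical nontriviality on 3-reaction networks:
# exhaustive search for a positive integer kernel vector with entries <= B
grid_kernel_oracle <- function(net, B = 24) {
  G <- net$target - net$source
  m <- ncol(G)
  grid <- as.matrix(expand.grid(rep(list(seq_len(B)), m)))
  hits <- which(rowSums(abs(grid %*% t(G))) == 0)
  if (length(hits) == 0) NULL else grid[hits[1], ]
}

# random quadratic (n,3,2) dynamically nontrivial system with affinely
# independent sources (so the log-linear equilibrium solve is consistent):
# built constructively so that Gamma has the positive kernel (a, b, 1) by
# setting gamma3 = -(a gamma1 + b gamma2)
random_osc_net <- function(n, tries = 5000) {
  cs <- enumerate_complexes(n, 2)
  for (i in seq_len(tries)) {
    S <- cs[, sample(ncol(cs), 3), drop = FALSE]
    if (crnosc:::rank_exact(cbind(S[, 2] - S[, 1], S[, 3] - S[, 1])) < 2) next
    # reaction vectors bounded below by -source so targets are nonnegative
    g1 <- vapply(seq_len(n), function(i) sample(c(0, 0, max(-2, -S[i, 1]):2), 1), 0)
    g2 <- vapply(seq_len(n), function(i) sample(c(0, 0, max(-2, -S[i, 2]):2), 1), 0)
    ab <- sample(1:2, 2, replace = TRUE)
    g3 <- -(ab[1] * g1 + ab[2] * g2)
    G <- unname(cbind(g1, g2, g3))
    if (crnosc:::rank_exact(G) != 2) next
    Tt <- S + G
    if (any(Tt < 0) || any(colSums(G != 0) == 0)) next
    net <- tryCatch(network(crnosc:::.species_names(n), S, Tt),
                    error = function(e) NULL)
    if (is.null(net)) next
    return(net)
  }
  stop("could not sample a nontrivial system")
}

# completely random small network (no structural requirements)
random_any_net <- function(n = 2, m = 3, max_src = 2, max_tgt = 3) {
  cs <- enumerate_complexes(n, max_src)
  ct <- enumerate_complexes(n, max_tgt)
  repeat {
    S <- cs[, sample(ncol(cs), m, replace = TRUE), drop = FALSE]
    Tt <- ct[, sample(ncol(ct), m, replace = TRUE), drop = FALSE]
    if (any(colSums(Tt != S) == 0)) next
    if (any(rowSums(S) + rowSums(Tt) == 0)) next
    return(network(crnosc:::.species_names(n), S, Tt))
  }
}

# Lie derivative of a first integral along the mass-action field
lie_derivative <- function(q, sys, x) {
  f <- rhs(sys, x)
  val <- 0
  if (!is.null(q$coefficients)) val <- val + sum(q$coefficients * f)
  if (!is.null(q$linear)) val <- val + sum(q$linear * f)
  if (!is.null(q$log)) val <- val + sum(q$log * f / x)
  val
}

# the 16 oscillatory quadratic trimolecular networks, built constructively
# from the families plus the trivial-species augmentation rules
trimolecular_oscillatory_constructive <- function() {
  nets <- list()
  for (cc in 1:2) for (dd in 1:2) {
    nets[[length(nets) + 1]] <- generalized_lotka(cc, dd)
  }
  # one trivial species on the autocatalytic reaction (needs c = 1)
  for (dd in 1:2) {
    nets[[length(nets) + 1]] <- parse_network(c(
      "X + Z -> 2X + Z", sprintf("X + Y -> %dY", 1 + dd), "Y -> 0"))
  }
  # one trivial species on the outflow reaction
  for (cc in 1:2) for (dd in 1:2) {
    nets[[length(nets) + 1]] <- parse_network(c(
      sprintf("X -> %dX", 1 + cc), sprintf("X + Y -> %dY", 1 + dd), "Y + Z -> Z"))
  }
  # the same trivial species on both (needs c = 1)
  for (dd in 1:2) {
    nets[[length(nets) + 1]] <- parse_network(c(
      "X + Z -> 2X + Z", sprintf("X + Y -> %dY", 1 + dd), "Y + Z -> Z"))
  }
  # two distinct trivial species (needs c = 1)
  for (dd in 1:2) {
    nets[[length(nets) + 1]] <- parse_network(c(
      "X + Z -> 2X + Z", sprintf("X + Y -> %dY", 1 + dd), "Y + W -> W"))
  }
  nets[[length(nets) + 1]] <- ivanova()
  nets[[length(nets) + 1]] <- lifted_lva(1)
  nets
}
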