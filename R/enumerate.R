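# Exhaustive enumeration of constrained three-reaction networks and the
# censuses of oscillatory networks.
#
# All counting is done up to isomorphism (species relabelling + reaction
# order). The enumerators go source-triple-first: unordered triples of
# distinct source complexes are generated up to species permutation, then all
# target assignments are screened with exact integer filters (rank two,
# strictly one-signed kernel vector) before any network object is built.
# The filters are necessary conditions for a periodic orbit, hence sound for
# the oscillatory censuses: repeated or collinear sources admit no periodic
# orbit; a species absent from every source is either absent from every
# complex (invalid) or strictly produced (dynamically trivial).

#' All complexes on n species with molecularity at most max_mol
#' @param n number of species.
#' @param max_mol molecularity bound.
#' @return n x K integer matrix, columns in lexicographic order.
#' @export
enumerate_complexes <- function(n, max_mol) {
  stopifnot(n >= 1, max_mol >= 0)
  if (n == 1) return(matrix(0:max_mol, 1))
  out <- NULL
  for (first in 0:max_mol) {
    rest <- enumerate_complexes(n - 1, max_mol - first)
    out <- cbind(out, rbind(first, rest))
  }
  dimnames(out) <- NULL
  out
}

# canonical key of a source triple up to species permutation (columns sorted)
.triple_key <- function(S) {
  best <- NULL
  for (p in .perms(nrow(S))) {
    p <- unlist(p)
    cols <- sort(apply(S[p, , drop = FALSE], 2, function(cl)
      paste(sprintf("%02d", cl), collapse = "")))
    ser <- paste(cols, collapse = ";")
    if (is.null(best) || ser < best) best <- ser
  }
  best
}

# distinct, species-covering, affinely independent source triples on n
# species (source molecularity <= max_src), one representative per
# permutation class
.source_triples <- function(n, max_src = 2, cover = TRUE, dedupe = TRUE) {
  cx <- enumerate_complexes(n, max_src)
  K <- ncol(cx)
  out <- list(); seen <- character(0)
  idx <- utils::combn(K, 3)
  for (t in seq_len(ncol(idx))) {
    S <- cx[, idx[, t], drop = FALSE]
    if (cover && any(rowSums(S) == 0)) next
    D <- cbind(S[, 2] - S[, 1], S[, 3] - S[, 1])
    if (rank_exact(D) < 2) next              # collinear (incl. repeated)
    if (dedupe) {
      key <- .triple_key(S)
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    out[[length(out) + 1]] <- S
  }
  out
}

# Vectorized screen of all target assignments for one source triple.
# Returns a list of n x 3 target matrices for networks with rank 2 and a
# strictly one-signed kernel vector.
.screen_targets <- function(S, max_tgt) {
  n <- nrow(S)
  Tm <- enumerate_complexes(n, max_tgt)
  K <- ncol(Tm)
  s1 <- S[, 1]; s2 <- S[, 2]; s3 <- S[, 3]
  ok1 <- colSums(Tm != s1) > 0
  ok2 <- colSums(Tm != s2) > 0
  G3 <- Tm - s3
  ok3 <- colSums(G3 != 0) > 0
  res <- list()
  for (j in which(ok1)) {
    a <- Tm[, j] - s1
    for (l in which(ok2)) {
      b <- Tm[, l] - s2
      u3 <- a[1] * b[2] - a[2] * b[1]
      u1 <- b[1] * G3[2, ] - G3[1, ] * b[2]
      u2 <- G3[1, ] * a[2] - a[1] * G3[2, ]
      nz <- (u1 != 0) | (u2 != 0) | (u3 != 0)
      pos <- ((u1 > 0 & u2 > 0 & u3 > 0) | (u1 < 0 & u2 < 0 & u3 < 0))
      good <- ok3 & nz & pos
      if (n > 2 && any(good)) {
        for (i in 3:n) {
          good <- good & (a[i] * u1 + b[i] * u2 + G3[i, ] * u3 == 0)
        }
      }
      # fallback: rows 1,2 of Gamma dependent for these columns; decide exactly
      fb <- which(ok3 & !nz)
      for (k in fb) {
        G <- cbind(a, b, G3[, k])
        if (rank_exact(G) != 2) next
        rows <- .independent_row_pair(G)
        if (is.null(rows)) next
        u <- .cross3(G[rows[1], ], G[rows[2], ])
        if (!(all(u > 0) || all(u < 0))) next
        if (any((G[-rows, , drop = FALSE] %*% u) != 0)) next
        good[k] <- TRUE
      }
      for (k in which(good)) {
        res[[length(res) + 1]] <- cbind(Tm[, j], Tm[, l], Tm[, k])
      }
    }
  }
  res
}

.species_names <- function(n) {
  if (n <= 4) c("X", "Y", "Z", "W")[seq_len(n)] else paste0("X", seq_len(n))
}

# enumerate rank-2, dynamically nontrivial, 3-reaction networks with distinct
# non-collinear species-covering sources, one representative per
# source-triple permutation class
.osc_candidates <- function(n, max_src = 2, max_tgt = 3) {
  sp <- .species_names(n)
  nets <- list()
  for (S in .source_triples(n, max_src)) {
    for (Tt in .screen_targets(S, max_tgt)) {
      nets[[length(nets) + 1]] <- network(sp, S, Tt)
    }
  }
  nets
}

.new_census <- function(count, networks, verdicts = NULL, keys = NULL,
                        extra = list()) {
  structure(c(list(count = count, networks = networks, verdicts = verdicts,
                   keys = keys), extra),
            class = "crn_census")
}

#' @export
print.crn_census <- function(x, ...) {
  cat("census:", x$count, "network(s)\n")
  if (!is.null(x$composition)) {
    cat("composition:\n")
    print(x$composition)
  }
  if (length(x$networks) > 0 && length(x$networks) <= 20) {
    for (i in seq_along(x$networks)) {
      cat(sprintf("-- network %d%s\n", i,
                  if (!is.null(x$verdicts)) paste0(" [", x$verdicts[[i]]$outcome, "]") else ""))
      cat(paste0("   ", format_network(x$networks[[i]]), collapse = "\n"), "\n")
    }
  }
  invisible(x)
}

#' Census of planar bimolecular source-complex configurations
#'
#' Counts the unordered triples of distinct bimolecular source complexes on
#' two species that do not lie on a line, up to exchange of the species.
#' @return a `crn_census` (count = 10) whose `triples` field lists one
#'   representative per class.
#' @export
census_source_cases <- function() {
  cx <- enumerate_complexes(2, 2)
  idx <- utils::combn(ncol(cx), 3)
  seen <- character(0); reps <- list()
  enc <- function(S) paste(sort(apply(S, 2, paste, collapse = ",")), collapse = ";")
  for (t in seq_len(ncol(idx))) {
    S <- cx[, idx[, t], drop = FALSE]
    D <- cbind(S[, 2] - S[, 1], S[, 3] - S[, 1])
    if (rank_exact(D) < 2) next
    key <- min(enc(S), enc(S[2:1, , drop = FALSE]))
    if (key %in% seen) next
    seen <- c(seen, key)
    reps[[length(reps) + 1]] <- S
  }
  .new_census(length(reps), list(), extra = list(triples = reps))
}

#' Census of quadratic trimolecular three-reaction networks with a periodic orbit
#'
#' Enumerates, for 2 to `max_species` species, all three-reaction networks
#' with source molecularity at most two and target molecularity at most three
#' (every species in some complex, trivial species allowed), filters to rank
#' two and dynamical nontriviality, classifies each with
#' [classify_trimolecular_general()], and counts the isomorphism classes
#' whose mass-action system admits a periodic orbit for some rate constants.
#'
#' The species bound 4 is a theorem, not a heuristic: without an
#' autocatalytic reaction the oscillatory networks have at most three species
#' (plus at most two trivial ones, limited by bimolecular sources); with
#' 2X -> 3X, five or more species force dynamical triviality. `max_species = 5`
#' re-verifies this empirically.
#'
#' @param max_species largest species count enumerated (default 4).
#' @return a `crn_census` with the oscillatory networks, their verdicts and a
#'   composition table; `n_classified` records the number of candidate
#'   networks classified.
#' @export
census_trimolecular_oscillatory <- function(max_species = 4) {
  keys <- character(0)
  nets <- list(); verds <- list()
  n_classified <- 0L
  for (n in 2:max_species) {
    for (cand in .osc_candidates(n, 2, 3)) {
      n_classified <- n_classified + 1L
      v <- classify_trimolecular_general(cand)
      if (!v$oscillatory) next
      key <- canonical_key(cand)
      if (key %in% keys) next
      keys <- c(keys, key)
      nets[[length(nets) + 1]] <- cand
      verds[[length(verds) + 1]] <- v
    }
  }
  fam <- vapply(verds, function(v) if (is.null(v$family)) "other" else v$family, "")
  ntr <- vapply(verds, function(v) length(v$stripped_species), 0L)
  comp <- table(family = fam, trivial_species = ntr)
  .new_census(length(nets), nets, verds, keys,
              extra = list(composition = comp, n_classified = n_classified))
}

#' Census of quadratic planar networks admitting an Andronov--Hopf bifurcation
#'
#' Enumerates all (2, 3) quadratic networks with target molecularity at most
#' `max_target_mol`, keeps those whose planar classification is a
#' supercritical or vertical Andronov--Hopf bifurcation, and (optionally)
#' computes the first focal value of each at a located Hopf point. With the
#' tetramolecular cap (4) this yields exactly the four case-9 networks
#' 2X -> 3X+Y, X+Y -> (1+d)Y, Y -> 0 (d = 0..3); with cap 3 it is empty.
#'
#' @param max_target_mol target molecularity cap.
#' @param focal_values logical; numerically evaluate L1 at a Hopf point.
#' @return a `crn_census`; extra fields `cases` and `L1`.
#' @export
census_tetramolecular_hopf <- function(max_target_mol = 4, focal_values = TRUE) {
  keys <- character(0); nets <- list(); verds <- list(); cases <- integer(0)
  for (cand in .osc_candidates(2, 2, max_target_mol)) {
    v <- tryCatch(hopf_verdict_planar(cand), error = function(e) NULL)
    if (is.null(v) || !(v$outcome %in% c("supercritical_hopf", "vertical_hopf"))) next
    key <- canonical_key(cand)
    if (key %in% keys) next
    keys <- c(keys, key)
    nets[[length(nets) + 1]] <- cand
    verds[[length(verds) + 1]] <- v
    cases <- c(cases, v$details$case)
  }
  L1 <- rep(NA_real_, length(nets))
  if (focal_values && length(nets) > 0) {
    for (i in seq_along(nets)) {
      hp <- find_hopf_point(nets[[i]], param = 1)
      if (is.null(hp)) hp <- find_hopf_point(nets[[i]], param = 2)
      if (is.null(hp)) next
      ff <- first_focal_value(mass_action(nets[[i]], hp$kappa))
      L1[i] <- ff$L1
    }
  }
  .new_census(length(nets), nets, verds, keys,
              extra = list(cases = cases, L1 = L1))
}

#' Minimal target molecularity for a Hopf bifurcation with sources 2X, X+Y, 0
#'
#' Searches the integer reaction-vector space of the source case (2X, X+Y, 0)
#' for the smallest molecularity cap M such that some network with all target
#' molecularities at most M satisfies the case-10 Andronov--Hopf conditions
#' (the second reaction is forced to X+Y -> 0 by c2 = d2 = -1).
#' @param max_M largest cap tried.
#' @return list(min_molecularity, witnesses) where witnesses are the networks
#'   found at the minimal cap.
#' @export
min_case10_molecularity <- function(max_M = 10) {
  for (M in 2:max_M) {
    wit <- .case10_search(M)
    if (length(wit) > 0) {
      return(list(min_molecularity = M, witnesses = wit))
    }
  }
  list(min_molecularity = NA_integer_, witnesses = list())
}

# all case-10 networks with target molecularities <= M satisfying the Hopf
# window (c1 > 0, c2 = -1, c3 > 0, d1 > 0, d2 = -1, d3 >= 0,
# (1/2)(d3/c3 + d1/c1) < 1 < d1/c1)
.case10_search <- function(M) {
  out <- list()
  for (c1 in 1:max(1, M)) for (d1 in 1:max(1, M)) {
    if (2 + c1 + d1 > M) next
    for (c3 in 1:M) for (d3 in 0:M) {
      if (c3 + d3 > M) next
      if (!.case9_10_window(c1, d1, c3, d3, 1)) next
      out[[length(out) + 1]] <- network(
        c("X", "Y"),
        source = cbind(c(2, 0), c(1, 1), c(0, 0)),
        target = cbind(c(2 + c1, d1), c(0, 0), c(c3, d3)))
    }
  }
  out
}

#' Number of planar source cases admitting a supercritical Hopf bifurcation
#'
#' For each of the ten source-complex cases, searches all integer
#' reaction-vector assignments with target molecularity at most `max_tgt` and
#' counts the cases for which some network is classified supercritical_hopf.
#' Cases 1-6 admit no periodic orbit at all and case 7/8 networks give
#' centers only, so the count comes from cases 9 and 10.
#' @param max_tgt target molecularity bound for the search.
#' @return list(count, cases, example) with one witness per admitting case.
#' @export
supercritical_family_count <- function(max_tgt = 8) {
  templates <- .case_templates()
  hits <- integer(0); examples <- list()
  for (cid in names(templates)) {
    S <- do.call(cbind, templates[[cid]])
    found <- NULL
    # enumerate reaction vectors (c_i, d_i) with valid nonnegative targets of
    # molecularity <= max_tgt, and evaluate the case conditions exactly; the
    # verdicts for cases 1-6 do not depend on the targets (no periodic orbit),
    # which one representative call verifies
    if (as.integer(cid) <= 6) {
      Tm <- enumerate_complexes(2, max_tgt)
      j <- which(colSums(Tm != S[, 1]) > 0)[1]
      l <- which(colSums(Tm != S[, 2]) > 0)[1]
      k <- which(colSums(Tm != S[, 3]) > 0)[1]
      net <- network(c("X", "Y"), S, cbind(Tm[, j], Tm[, l], Tm[, k]))
      v <- tryCatch(hopf_verdict_planar(net), error = function(e) NULL)
      stopifnot(is.null(v) || v$outcome != "supercritical_hopf")
      next
    }
    rng <- function(j) {
      # c ranges for reaction j: target = source + (c, d) >= 0, mol <= max_tgt
      a <- S[1, j]; b <- S[2, j]
      out <- list()
      for (cc in (-a):(max_tgt - a - b)) {
        for (dd in (-b):(max_tgt - a - b - cc)) {
          if (cc == 0 && dd == 0) next
          out[[length(out) + 1]] <- c(cc, dd)
        }
      }
      out
    }
    r1 <- rng(1); r2 <- rng(2); r3 <- rng(3)
    for (v1 in r1) {
      for (v2 in r2) {
        for (v3 in r3) {
          res <- .case_condition(as.integer(cid), c(v1[1], v2[1], v3[1]),
                                 c(v1[2], v2[2], v3[2]),
                                 list(swap = FALSE, order = 1:3))
          if (!is.null(res) && res$outcome == "supercritical_hopf") {
            found <- network(c("X", "Y"), S,
                             S + rbind(c(v1[1], v2[1], v3[1]),
                                       c(v1[2], v2[2], v3[2])))
            break
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      # cross-check through the full classifier
      v <- hopf_verdict_planar(found)
      stopifnot(v$outcome == "supercritical_hopf")
      hits <- c(hits, as.integer(cid))
      examples[[as.character(cid)]] <- found
    }
  }
  list(count = length(hits), cases = hits, examples = examples)
}

#' Minimal number of reactions required for oscillation
#'
#' Verifies computationally that (i) every one- or two-reaction network over
#' two or three species with source molecularity at most two and target
#' molecularity at most `max_tgt` that is dynamically nontrivial has rank at
#' most one (so no periodic orbits), and (ii) the three-reaction Lotka system
#' has a periodic orbit (checked by Poincare return map). Returns 3.
#' @param max_tgt target molecularity bound for the exhaustive small check.
#' @return list(min_reactions, checked_m2, lotka_periodic).
#' @export
min_reactions_for_oscillation <- function(max_tgt = 3) {
  checked <- 0L
  for (n in 2:3) {
    cx_s <- enumerate_complexes(n, 2)
    cx_t <- enumerate_complexes(n, max_tgt)
    rxns <- list()
    for (i in seq_len(ncol(cx_s))) {
      for (j in seq_len(ncol(cx_t))) {
        if (all(cx_s[, i] == cx_t[, j])) next
        rxns[[length(rxns) + 1]] <- cx_t[, j] - cx_s[, i]
      }
    }
    Gcols <- unique(do.call(cbind, rxns), MARGIN = 2)
    K <- ncol(Gcols)
    # m = 1: a positive kernel requires the single reaction vector to vanish
    stopifnot(all(colSums(Gcols != 0) > 0))
    # m = 2: nontrivial iff u1 g1 + u2 g2 = 0 with u > 0 iff g2 = -t g1
    for (i in seq_len(K - 1)) {
      gi <- Gcols[, i]
      for (j in (i + 1):K) {
        gj <- Gcols[, j]
        # exact positive-dependence test for two columns
        nontriv <- !is.null(.lp_standard_feasible(cbind(gi, gj), -(gi + gj)))
        if (nontriv) {
          checked <- checked + 1L
          stopifnot(rank_exact(cbind(gi, gj)) <= 1)
        }
      }
    }
  }
  dp <- detect_periodicity(mass_action(lotka(), 1), c(2, 1), t_end = 60)
  list(min_reactions = 3L, checked_m2 = checked,
       lotka_periodic = isTRUE(dp$periodic))
}

# Pruning-soundness oracle: canonical keys of all rank-2, dynamically
# nontrivial two-species 3-reaction networks with distinct, non-collinear,
# species-covering sources, found by sweeping unordered reaction triples with
# NO source-first pruning and with the full exact-LP nontriviality test.
.brute_force_networks_2species <- function(max_source_mol = 2, max_target_mol = 3) {
  cx_s <- enumerate_complexes(2, max_source_mol)
  cx_t <- enumerate_complexes(2, max_target_mol)
  rxns <- list()
  for (i in seq_len(ncol(cx_s))) {
    for (j in seq_len(ncol(cx_t))) {
      if (all(cx_s[, i] == cx_t[, j])) next
      rxns[[length(rxns) + 1]] <- list(s = cx_s[, i], t = cx_t[, j])
    }
  }
  keys <- character(0)
  idx <- utils::combn(length(rxns), 3)
  for (t in seq_len(ncol(idx))) {
    rs <- rxns[idx[, t]]
    S <- vapply(rs, `[[`, numeric(2), "s")
    Tt <- vapply(rs, `[[`, numeric(2), "t")
    if (any(rowSums(S) == 0)) next
    if (rank_exact(cbind(S[, 2] - S[, 1], S[, 3] - S[, 1])) < 2) next
    net <- network(c("X", "Y"), S, Tt)
    if (network_rank(net) != 2) next
    if (!is_dynamically_nontrivial(net)$status) next
    keys <- c(keys, canonical_key(net))
  }
  sort(unique(keys))
}

#' Enumerate canonical three-reaction networks under constraints
#'
#' General-purpose enumerator: yields one representative per isomorphism
#' class of three-reaction networks with the given molecularity bounds,
#' optionally filtered by rank and dynamical nontriviality. With
#' `require_nontrivial = TRUE` (and rank 2) the fast source-first screen is
#' used; otherwise a brute-force sweep over reaction triples is performed,
#' which is intended for small settings (two species).
#'
#' @param n_species number of species.
#' @param max_source_mol,max_target_mol molecularity bounds.
#' @param require_rank required rank of Gamma (NULL = no constraint).
#' @param require_nontrivial keep only dynamically nontrivial networks.
#' @param allow_trivial_species if FALSE, drop networks with trivial species.
#' @param distinct_sources if TRUE, only networks with three distinct,
#'   non-collinear, species-covering sources (the oscillation-relevant ones).
#' @return list of `crn_network` objects (canonical representatives).
#' @export
enumerate_networks <- function(n_species, max_source_mol = 2, max_target_mol = 3,
                               require_rank = NULL, require_nontrivial = TRUE,
                               allow_trivial_species = TRUE,
                               distinct_sources = require_nontrivial) {
  keep <- function(net) {
    (is.null(require_rank) || network_rank(net) == require_rank) &&
      (!require_nontrivial || is_dynamically_nontrivial(net)$status) &&
      (allow_trivial_species || length(trivial_species(net)) == 0)
  }
  out <- list(); keys <- character(0)
  if (require_nontrivial && distinct_sources &&
      (is.null(require_rank) || require_rank == 2)) {
    for (cand in .osc_candidates(n_species, max_source_mol, max_target_mol)) {
      if (!is.null(require_rank) && network_rank(cand) != require_rank) next
      if (!allow_trivial_species && length(trivial_species(cand)) > 0) next
      key <- canonical_key(cand)
      if (key %in% keys) next
      keys <- c(keys, key)
      out[[length(out) + 1]] <- cand
    }
    return(out)
  }
  if (n_species > 2) {
    stop("brute-force enumeration is limited to two species; use the ",
         "nontrivial source-first path for larger settings")
  }
  cx_s <- enumerate_complexes(n_species, max_source_mol)
  cx_t <- enumerate_complexes(n_species, max_target_mol)
  rxns <- list()
  for (i in seq_len(ncol(cx_s))) {
    for (j in seq_len(ncol(cx_t))) {
      if (all(cx_s[, i] == cx_t[, j])) next
      rxns[[length(rxns) + 1]] <- list(s = cx_s[, i], t = cx_t[, j])
    }
  }
  sp <- .species_names(n_species)
  idx <- utils::combn(length(rxns), 3)
  for (t in seq_len(ncol(idx))) {
    rs <- rxns[idx[, t]]
    S <- vapply(rs, `[[`, numeric(n_species), "s")
    Tt <- vapply(rs, `[[`, numeric(n_species), "t")
    if (any(rowSums(S) + rowSums(Tt) == 0)) next  # species in no complex
    if (distinct_sources) {
      D <- cbind(S[, 2] - S[, 1], S[, 3] - S[, 1])
      if (rank_exact(D) < 2) next
      if (any(rowSums(S) == 0)) next
    }
    net <- network(sp, S, Tt)
    if (!keep(net)) next
    key <- canonical_key(net)
    if (key %in% keys) next
    keys <- c(keys, key)
    out[[length(out) + 1]] <- net
  }
  out
}
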