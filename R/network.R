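# Reaction network representation and structural predicates.
#
# A network is stored as an ordered species list together with the source
# matrix Gl (source stoichiometries, n x m, nonnegative integers) and the
# target matrix (target stoichiometries). The stoichiometric matrix is
# Gamma = target - Gl; column j is the reaction vector of reaction j.

#' Construct a reaction network
#'
#' @param species character vector of species names (ordered).
#' @param source n x m nonnegative integer matrix of source stoichiometries
#'   (one column per reaction).
#' @param target n x m nonnegative integer matrix of target stoichiometries.
#' @param labels optional character vector of reaction labels (length m).
#' @return an object of class `crn_network` with fields `species`, `source`,
#'   `target`, `n`, `m`.
#' @examples
#' lotka <- network(c("X", "Y"),
#'                  source = cbind(c(1, 0), c(1, 1), c(0, 1)),
#'                  target = cbind(c(2, 0), c(0, 2), c(0, 0)))
#' network_rank(lotka)
#' @export
network <- function(species, source, target, labels = NULL) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  n <- length(species)
  m <- ncol(source)
  stopifnot(nrow(source) == n, nrow(target) == n, ncol(target) == m)
  if (any(source < 0) || any(target < 0) ||
      any(source != round(source)) || any(target != round(target))) {
    stop("stoichiometric coefficients must be nonnegative integers")
  }
  for (j in seq_len(m)) {
    if (all(source[, j] == target[, j])) {
      stop("reaction ", j, ": source and target complexes are equal")
    }
  }
  appears <- rowSums(source) + rowSums(target) > 0
  if (any(!appears)) {
    stop("species appear in no complex: ",
         paste(species[!appears], collapse = ", "))
  }
  if (anyDuplicated(species)) stop("duplicate species names")
  if (is.null(labels)) labels <- paste0("k", seq_len(m))
  storage.mode(source) <- "double"
  storage.mode(target) <- "double"
  dimnames(source) <- dimnames(target) <- list(species, NULL)
  structure(list(species = species, source = source, target = target,
                 labels = labels, n = n, m = m),
            class = "crn_network")
}

.parse_complex <- function(txt, line) {
  txt <- trimws(txt)
  if (txt == "0" || txt == "") {
    if (txt == "") stop("empty complex in line: ", line)
    return(list())
  }
  terms <- strsplit(txt, "\\+")[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    mt <- regmatches(tm, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_]*)$", tm))[[1]]
    if (length(mt) == 0) stop("malformed term '", tm, "' in line: ", line)
    k <- if (mt[2] == "") 1L else as.integer(mt[2])
    if (k <= 0) stop("coefficient must be a positive integer in line: ", line)
    sp <- mt[3]
    out[[sp]] <- (if (is.null(out[[sp]])) 0L else out[[sp]]) + k
  }
  out
}

#' Parse a plain-text reaction list into a network
#'
#' Each nonempty line has the form `<complex> -> <complex> [@ <label>]`, where
#' a complex is `0` (the empty complex) or `+`-separated terms `kS` with an
#' optional positive integer coefficient `k` and a species name `S`. Species
#' are ordered by first appearance; reactions keep input order.
#'
#' @param text a single string (lines separated by newlines) or a character
#'   vector of lines.
#' @return a `crn_network`.
#' @examples
#' parse_network("X -> 2X\nX + Y -> 2Y\nY -> 0")
#' @export
parse_network <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  lines <- trimws(lines)
  lines <- lines[lines != "" & !grepl("^#", lines)]
  if (length(lines) == 0) stop("no reactions")
  species <- character(0)
  srcs <- list(); tgts <- list(); labels <- character(0)
  for (ln in lines) {
    lab <- NA_character_
    body <- ln
    if (grepl("@", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "@", fixed = TRUE)[[1]]
      body <- parts[1]
      lab <- trimws(parts[2])
    }
    sides <- strsplit(body, "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("expected '<complex> -> <complex>' in line: ", ln)
    s <- .parse_complex(sides[1], ln)
    t <- .parse_complex(sides[2], ln)
    for (sp in c(names(s), names(t))) {
      if (!(sp %in% species)) species <- c(species, sp)
    }
    srcs[[length(srcs) + 1]] <- s
    tgts[[length(tgts) + 1]] <- t
    labels <- c(labels, lab)
  }
  n <- length(species); m <- length(srcs)
  S <- matrix(0L, n, m); Tt <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    for (sp in names(srcs[[j]])) S[match(sp, species), j] <- srcs[[j]][[sp]]
    for (sp in names(tgts[[j]])) Tt[match(sp, species), j] <- tgts[[j]][[sp]]
  }
  if (anyNA(labels)) labels <- ifelse(is.na(labels), paste0("k", seq_len(m)), labels)
  network(species, S, Tt, labels)
}

.format_complex <- function(coeffs, species) {
  idx <- which(coeffs > 0)
  if (length(idx) == 0) return("0")
  paste(vapply(idx, function(i) {
    if (coeffs[i] == 1) species[i] else paste0(coeffs[i], species[i])
  }, ""), collapse = " + ")
}

#' Write a network back to the plain-text reaction format
#' @param net a `crn_network`.
#' @param labels logical; append `@ <label>` to each line.
#' @return character vector of reaction lines.
#' @export
format_network <- function(net, labels = FALSE) {
  vapply(seq_len(net$m), function(j) {
    line <- paste(.format_complex(net$source[, j], net$species), "->",
                  .format_complex(net$target[, j], net$species))
    if (labels) line <- paste(line, "@", net$labels[j])
    line
  }, "")
}

#' @export
format.crn_network <- function(x, ...) format_network(x, ...)

#' @export
print.crn_network <- function(x, ...) {
  cat(sprintf("reaction network: %d species (%s), %d reactions\n",
              x$n, paste(x$species, collapse = ", "), x$m))
  cat(paste0("  ", format_network(x, labels = TRUE), collapse = "\n"), "\n")
  invisible(x)
}

#' Source and stoichiometric matrices
#' @param net a `crn_network`.
#' @return list with `Gl` (source matrix) and `G` (stoichiometric matrix,
#'   target minus source), both n x m integer matrices.
#' @export
matrices <- function(net) {
  list(Gl = net$source, G = net$target - net$source)
}

#' Rank of a network (exact rank of the stoichiometric matrix)
#' @param net a `crn_network`.
#' @export
network_rank <- function(net) rank_exact(net$target - net$source)

#' Molecularity profile
#' @param net a `crn_network`.
#' @return list with `max_source`, `max_target`, and the derived predicates
#'   `is_quadratic` (all source molecularities <= 2), `is_bimolecular`,
#'   `is_trimolecular`, `is_tetramolecular` (bounds on all complexes).
#' @export
molecularity_profile <- function(net) {
  ms <- if (net$m > 0) max(colSums(net$source)) else 0L
  mt <- if (net$m > 0) max(colSums(net$target)) else 0L
  list(max_source = ms, max_target = mt,
       is_quadratic = ms <= 2,
       is_bimolecular = ms <= 2 && mt <= 2,
       is_trimolecular = ms <= 3 && mt <= 3,
       is_tetramolecular = ms <= 4 && mt <= 4)
}

#' Trivial species (zero rows of the stoichiometric matrix)
#' @param net a `crn_network`.
#' @return integer vector of species indices whose net change is zero in
#'   every reaction (their concentration is constant).
#' @export
trivial_species <- function(net) {
  G <- net$target - net$source
  which(apply(G == 0, 1, all))
}

#' Remove trivial species and merge duplicate reactions
#'
#' Used by the general classifier: trivial species only rescale rate
#' constants, and reactions that become identical after stripping act as a
#' single reaction with summed rate.
#' @param net a `crn_network`.
#' @return list(net, removed_species, merged) where `net` may have fewer
#'   species and/or reactions.
#' @export
strip_trivial_species <- function(net) {
  tr <- trivial_species(net)
  keep <- setdiff(seq_len(net$n), tr)
  S <- net$source[keep, , drop = FALSE]
  Tt <- net$target[keep, , drop = FALSE]
  # drop reactions that became source == target (cannot happen: Gamma column
  # nonzero is preserved since removed rows were zero), merge exact duplicates
  key <- apply(rbind(S, Tt), 2, paste, collapse = ",")
  keep_rxn <- !duplicated(key)
  merged <- any(!keep_rxn)
  S <- S[, keep_rxn, drop = FALSE]
  Tt <- Tt[, keep_rxn, drop = FALSE]
  list(net = network(net$species[keep], S, Tt),
       removed_species = net$species[tr], merged = merged)
}

#' Decide dynamical nontriviality, with a verifying certificate
#'
#' A network is dynamically nontrivial when its stoichiometric matrix has a
#' strictly positive kernel vector (the reaction vectors are positively
#' dependent); otherwise, by Stiemke's duality, there is a vector v with
#' Gamma^T v >= 0 and Gamma^T v != 0, giving a linear Lyapunov function that
#' rules out positive limit sets. Decided by exact rational arithmetic:
#' feasibility of {Gamma u = 0, u >= 1} by basic-solution enumeration, and on
#' failure the dual witness from {w in im Gamma^T, w >= 0, sum w = 1}.
#'
#' @param net a `crn_network`.
#' @return list with `status` (logical), and exactly one of
#'   `positive_kernel_vector` (integer vector u > 0 with Gamma u = 0) or
#'   `separating_vector` (integer vector v with Gamma^T v >= 0, != 0).
#' @export
is_dynamically_nontrivial <- function(net) {
  G <- net$target - net$source
  m <- net$m
  # primal: u = 1 + s, s >= 0, G s = -G 1
  sol <- .lp_standard_feasible(G, -rowSums(G))
  if (!is.null(sol)) {
    # u = 1 + s exactly: put on a common denominator
    l <- 1
    for (d in sol$den) l <- .lcm(l, d)
    u_int <- l + sol$num * (l / sol$den)
    g <- .gcd_vec(u_int)
    u_int <- u_int / g
    stopifnot(all(u_int > 0), all(G %*% u_int == 0))
    return(list(status = TRUE, positive_kernel_vector = as.numeric(u_int)))
  }
  # dual: w in im(G^T) i.e. K w = 0 where rows of K span ker(G),
  # plus sum(w) = 1, w >= 0
  K <- t(nullspace_exact(G)) # rows span ker G
  A <- rbind(K, rep(1, m))
  b <- c(rep(0, nrow(K)), 1)
  solw <- .lp_standard_feasible(A, b)
  stopifnot(!is.null(solw)) # Stiemke: exactly one side feasible
  l <- 1
  for (d in solw$den) l <- .lcm(l, d)
  w <- solw$num * (l / solw$den)
  g <- .gcd_vec(w); w <- w / g
  # recover v with G^T v = w (consistent since w in im G^T)
  rr <- .rref_q(cbind(t(G), w))
  r <- length(rr$pivots)
  stopifnot(!((net$n + 1) %in% rr$pivots))
  v_n <- numeric(net$n); v_d <- rep(1, net$n)
  for (i in seq_len(r)) {
    v_n[rr$pivots[i]] <- rr$num[i, net$n + 1]
    v_d[rr$pivots[i]] <- rr$den[i, net$n + 1]
  }
  v <- .q_to_int(list(num = v_n, den = v_d))
  gv <- t(G) %*% v
  if (any(gv < 0)) v <- -v
  gv <- t(G) %*% v
  stopifnot(all(gv >= 0), any(gv > 0))
  list(status = FALSE, separating_vector = as.numeric(v))
}

#' Kernel sign vector u = c x d for a three-reaction rank-two network
#'
#' The rows c, d are the first two linearly independent rows of the
#' stoichiometric matrix, in species order. The raw cross product is
#' returned: the network is dynamically nontrivial exactly when all three
#' entries have the same strict sign.
#' @param net a `crn_network` with m = 3 and rank 2.
#' @return integer vector of length 3.
#' @export
kernel_sign_vector <- function(net) {
  if (net$m != 3) stop("kernel_sign_vector requires exactly 3 reactions")
  G <- net$target - net$source
  rows <- .independent_row_pair(G)
  if (is.null(rows)) stop("kernel_sign_vector requires rank 2")
  .cross3(G[rows[1], ], G[rows[2], ])
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# first two linearly independent rows of a matrix with 3 columns (exact),
# or NULL if rank < 2; errors if rank > 2 is possible given callers check.
.independent_row_pair <- function(G) {
  n <- nrow(G)
  i1 <- which(rowSums(G != 0) > 0)
  if (length(i1) == 0) return(NULL)
  i1 <- i1[1]
  for (i2 in seq_len(n)) {
    if (i2 == i1) next
    if (any(.cross3(G[i1, ], G[i2, ]) != 0)) return(sort(c(i1, i2)))
  }
  NULL
}

#' Are all source complexes on an affine line?
#'
#' For three sources this is affine dependence; with one or two reactions the
#' answer is always TRUE. A rank-two mass-action system whose sources lie on
#' a line admits no periodic orbit.
#' @param net a `crn_network`.
#' @export
sources_collinear <- function(net) {
  S <- net$source
  m <- net$m
  if (m <= 2) return(TRUE)
  D <- S[, -1, drop = FALSE] - S[, 1]
  rank_exact(D) <= 1
}

# all permutations of 1..n (n <= 6 in this package)
.perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in .perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# canonical serialization key over all species permutations + reaction sorting;
# columns are encoded as fixed-width digit strings so string order equals
# lexicographic order of the stacked (source, target) coefficient vectors
.canonical_data <- function(net) {
  best <- NULL; best_perm <- NULL; best_ord <- NULL
  for (p in .perms(net$n)) {
    p <- unlist(p)
    M <- rbind(net$source[p, , drop = FALSE], net$target[p, , drop = FALSE])
    colkeys <- apply(M, 2, function(col) paste(sprintf("%04d", col), collapse = ""))
    ord <- order(colkeys)
    ser <- paste(colkeys[ord], collapse = ";")
    if (is.null(best) || ser < best) {
      best <- ser; best_perm <- p; best_ord <- ord
    }
  }
  list(key = paste0(net$n, "x", net$m, ":", best),
       perm = best_perm, ord = best_ord)
}

#' Canonical form of a network (isomorphism representative)
#'
#' Returns the relabelled/reordered network whose serialized (source, target)
#' matrices are lexicographically minimal over all species permutations, with
#' reactions sorted. Two networks are isomorphic (equal up to species
#' relabelling and reaction order) iff their canonical keys are equal.
#' @param net a `crn_network`.
#' @return a `crn_network` with attribute `"key"`.
#' @export
canonicalize <- function(net) {
  cd <- .canonical_data(net)
  p <- cd$perm
  out <- network(net$species[p],
                 net$source[p, cd$ord, drop = FALSE],
                 net$target[p, cd$ord, drop = FALSE],
                 net$labels[cd$ord])
  attr(out, "key") <- cd$key
  out
}

#' Canonical key string of a network
#' @param net a `crn_network`.
#' @export
canonical_key <- function(net) .canonical_data(net)$key

#' Test whether two networks are isomorphic
#' @param a,b `crn_network` objects.
#' @export
networks_isomorphic <- function(a, b) {
  a$n == b$n && a$m == b$m && canonical_key(a) == canonical_key(b)
}

#' Trimolecularize a quadratic network
#'
#' Replaces every reaction whose target molecularity is at least four by the
#' (at most n) reactions source -> (a_j + sgn c_j) X_j + sum_{i != j} a_i X_i
#' at rate kappa |c_j|, one for each species j with net change c_j != 0. The
#' resulting mass-action vector field is identical to the original one, and
#' every target has molecularity at most three.
#' @param net a quadratic `crn_network`.
#' @param kappa positive rate constants (length m).
#' @return list(net, kappa) for the trimolecular replacement.
#' @export
trimolecularize <- function(net, kappa = rep(1, net$m)) {
  if (!molecularity_profile(net)$is_quadratic) {
    stop("trimolecularize requires a quadratic network (source molecularity <= 2)")
  }
  stopifnot(length(kappa) == net$m, all(kappa > 0))
  S <- NULL; Tt <- NULL; kap <- numeric(0); labs <- character(0)
  for (j in seq_len(net$m)) {
    src <- net$source[, j]; tgt <- net$target[, j]
    if (sum(tgt) <= 3) {
      S <- cbind(S, src); Tt <- cbind(Tt, tgt)
      kap <- c(kap, kappa[j]); labs <- c(labs, net$labels[j])
      next
    }
    cvec <- tgt - src
    for (i in which(cvec != 0)) {
      newt <- src
      newt[i] <- newt[i] + sign(cvec[i])
      S <- cbind(S, src); Tt <- cbind(Tt, newt)
      kap <- c(kap, kappa[j] * abs(cvec[i]))
      labs <- c(labs, paste0(net$labels[j], letters[i]))
    }
  }
  list(net = network(net$species, S, Tt, labs), kappa = unname(kap))
}

#' Euclidean embedded graph of a network
#' @param net a `crn_network`.
#' @return list with `nodes` (data.frame of distinct complexes, one coordinate
#'   column per species) and `edges` (data.frame of source/target node ids).
#' @export
embedded_graph <- function(net) {
  cx <- cbind(net$source, net$target)
  key <- apply(cx, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  nodes <- t(cx[, uniq, drop = FALSE])
  ids <- match(key, key[uniq])
  nodes_df <- as.data.frame(nodes)
  names(nodes_df) <- net$species
  nodes_df <- cbind(id = seq_len(nrow(nodes_df)), nodes_df)
  edges <- data.frame(from = ids[seq_len(net$m)],
                      to = ids[net$m + seq_len(net$m)],
                      label = net$labels)
  list(nodes = nodes_df, edges = edges)
}

#' JSON serialization of a network
#' @param net a `crn_network`.
#' @return a JSON string.
#' @export
network_to_json <- function(net) {
  rxns <- lapply(seq_len(net$m), function(j) {
    s <- net$source[, j]; t <- net$target[, j]
    list(source = as.list(stats::setNames(s[s > 0], net$species[s > 0])),
         target = as.list(stats::setNames(t[t > 0], net$species[t > 0])),
         label = net$labels[j])
  })
  jsonlite::toJSON(list(species = net$species, reactions = rxns),
                   auto_unbox = TRUE)
}
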