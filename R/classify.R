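# Decision procedures for oscillation in three-reaction quadratic mass-action
# systems: necessary-condition checklist, the no-autocatalytic-reaction case
# (Bendixson-Dulac plus the three center families), the planar ten-case
# Andronov-Hopf classification, and the general any-species-count decision
# for trimolecular networks.

.crnosc_cache <- new.env(parent = emptyenv())

.cached_key <- function(tag, constructor) {
  if (!exists(tag, envir = .crnosc_cache)) {
    assign(tag, canonical_key(constructor()), envir = .crnosc_cache)
  }
  get(tag, envir = .crnosc_cache)
}

.verdict <- function(outcome, fired_rule, certificate = character(0),
                     family = NULL, params = NULL, oscillatory = NA,
                     stripped_species = character(0), details = list()) {
  if (is.na(oscillatory)) {
    oscillatory <- outcome %in% c("center_for_all_kappa", "center_on_condition",
                                  "vertical_hopf", "supercritical_hopf")
  }
  structure(list(outcome = outcome, fired_rule = fired_rule,
                 certificate = certificate, family = family, params = params,
                 oscillatory = oscillatory,
                 stripped_species = stripped_species, details = details),
            class = "crn_verdict")
}

#' @export
print.crn_verdict <- function(x, ...) {
  cat("verdict:", x$outcome,
      if (x$oscillatory) "(admits periodic orbits for some kappa)" else "", "\n")
  cat("  rule:", x$fired_rule, "\n")
  if (!is.null(x$family)) {
    cat("  family:", x$family,
        if (length(x$params)) paste0("(", paste(names(x$params), x$params,
                                                sep = "=", collapse = ", "), ")"),
        "\n")
  }
  if (length(x$stripped_species)) {
    cat("  trivial species stripped:", paste(x$stripped_species, collapse = ", "), "\n")
  }
  for (s in x$certificate) cat("  certificate:", s, "\n")
  invisible(x)
}

#' Necessary conditions for a periodic orbit (checklist)
#'
#' Evaluates, in order: at least three reactions; rank exactly two (for three
#' reactions, a periodic orbit forces rank two); dynamical nontriviality;
#' source complexes not all on an affine line. Returns the checklist and the
#' first failing rule, if any.
#' @param net a `crn_network`.
#' @return list(pass, first_fail, checks).
#' @export
oscillation_preconditions <- function(net) {
  checks <- list()
  checks$enough_reactions <- net$m >= 3
  r <- network_rank(net)
  checks$rank_two <- (r == 2)
  nt <- is_dynamically_nontrivial(net)
  checks$dynamically_nontrivial <- nt$status
  checks$sources_not_collinear <- !sources_collinear(net)
  first_fail <- names(checks)[!unlist(checks)][1]
  list(pass = all(unlist(checks)),
       first_fail = if (is.na(first_fail)) NULL else first_fail,
       checks = checks, rank = r, nontriviality = nt)
}

#' Detect a quadratic autocatalytic reaction 2Xj -> (2+cj)Xj + ...
#'
#' TRUE when some reaction has source 2Xj, strictly gains Xj, and loses no
#' other species. In a trimolecular quadratic network the only such reaction
#' is 2Xj -> 3Xj. Its absence makes the Bendixson-Dulac divergence argument
#' (multiplier 1/(x1...xn)) applicable.
#' @param net a `crn_network`.
#' @return list(status, reaction, species).
#' @export
has_autocatalytic_form9 <- function(net) {
  G <- net$target - net$source
  for (j in seq_len(net$m)) {
    a <- net$source[, j]
    hot <- which(a == 2)
    if (length(hot) != 1 || sum(a) != 2) next
    i <- hot
    if (G[i, j] > 0 && all(G[-i, j] >= 0)) {
      return(list(status = TRUE, reaction = j, species = net$species[i]))
    }
  }
  list(status = FALSE, reaction = NA_integer_, species = NA_character_)
}

# ---- family template matching (canonical-form comparison) -----------------

.match_family <- function(net, tag_fmt, constructor, grid) {
  key <- canonical_key(net)
  for (par in grid) {
    tag <- do.call(sprintf, c(list(tag_fmt), as.list(par)))
    cand <- .cached_key(tag, function() do.call(constructor, as.list(par)))
    if (identical(key, cand)) return(par)
  }
  NULL
}

#' Match against the generalized LVA family 2X -> 3X, X+Y -> (1+d)Y, Y -> 0
#' @param net a `crn_network` with n = 2.
#' @return list(status, d).
#' @export
generalized_lva_check <- function(net) {
  if (net$n != 2 || net$m != 3) return(list(status = FALSE, d = NA_integer_))
  mt <- molecularity_profile(net)$max_target
  grid <- lapply(seq_len(max(1, mt)), function(d) c(d = d))
  hit <- .match_family(net, "glva_%d", generalized_lva, grid)
  if (is.null(hit)) list(status = FALSE, d = NA_integer_)
  else list(status = TRUE, d = unname(hit["d"]))
}

.match_gen_lotka <- function(net) {
  if (net$n != 2 || net$m != 3) return(NULL)
  mt <- molecularity_profile(net)$max_target
  grid <- do.call(c, lapply(seq_len(mt), function(c.) {
    lapply(seq_len(mt), function(d.) c(c = c., d = d.))
  }))
  .match_family(net, "glotka_%d_%d", generalized_lotka, grid)
}

.match_family12 <- function(net) {
  if (net$n != 3 || net$m != 3) return(NULL)
  mt <- molecularity_profile(net)$max_target
  grid <- do.call(c, lapply(seq_len(mt), function(c.) {
    lapply(seq_len(mt), function(d.) {
      if (2 + c. * d. + d. <= 2 * mt + 2) c(c = c., d = d.) else NULL
    })
  }))
  grid <- Filter(Negate(is.null), grid)
  .match_family(net, "fam12_%d_%d", three_species_center_family, grid)
}

.match_lifted_lva <- function(net) {
  if (net$n != 3 || net$m != 3) return(NULL)
  mt <- molecularity_profile(net)$max_target
  grid <- lapply(seq_len(max(1, mt)), function(d) c(d = d))
  .match_family(net, "llva_%d", lifted_lva, grid)
}

# ---- the no-autocatalytic-reaction case ------------------------------------

#' Classify a quadratic three-reaction system with no autocatalytic reaction
#'
#' For quadratic, rank-two, three-reaction networks without trivial species
#' and without a reaction of the autocatalytic form, a periodic orbit forces
#' the mass-action equation to be a Lotka--Volterra equation without diagonal
#' terms; the only three-reaction networks realizing one with a positive
#' non-saddle equilibrium are the Ivanova reactions, the generalized Lotka
#' family, and the three-species center family. Anything else admits no
#' periodic orbit by the Bendixson--Dulac test with multiplier 1/(x1...xn).
#'
#' @param net a quadratic `crn_network`, m = 3, rank 2, no trivial species,
#'   no autocatalytic form reaction.
#' @return a `crn_verdict`.
#' @export
classify_no_form9 <- function(net) {
  if (has_autocatalytic_form9(net)$status) {
    stop("network has an autocatalytic form reaction; use the general classifier")
  }
  key <- canonical_key(net)
  if (identical(key, .cached_key("ivanova", ivanova))) {
    return(.verdict("center_for_all_kappa", "three_reaction_no_autocatalysis",
                    certificate = "Ivanova reactions: unique positive equilibrium in each stoichiometric class x+y+z=C>0 is a global center, all kappa",
                    family = "ivanova"))
  }
  gl <- .match_gen_lotka(net)
  if (!is.null(gl)) {
    return(.verdict("center_for_all_kappa", "three_reaction_no_autocatalysis",
                    certificate = sprintf("generalized Lotka (c=%d, d=%d): conserved d k2 x + k2 y - k3 log x - c k1 log y with compact level sets; global center for all kappa", gl["c"], gl["d"]),
                    family = "generalized_lotka", params = as.list(gl)))
  }
  f12 <- .match_family12(net)
  if (!is.null(f12)) {
    return(.verdict("center_on_condition", "three_reaction_no_autocatalysis",
                    certificate = sprintf("three-species center family (c=%d, d=%d): centers on classes x-y+cz=D<0 iff k1 > k2 + d k3", f12["c"], f12["d"]),
                    family = "three_species_center", params = as.list(f12)))
  }
  .verdict("no_periodic_orbit", "bendixson_dulac",
           certificate = "no autocatalytic reaction and not a Lotka-Volterra-without-diagonal realization: divergence of the field rescaled by 1/(x1...xn) is strictly negative")
}

#' Parametric regimes of the three-species center family
#'
#' For the family X+Z -> (1+c)X, X+Y -> 0, Y+Z -> (1+cd)Y + (1+d)Z, the
#' positive equilibria form the ray t(c d k3, c k1, k2) and the stoichiometric
#' classes are x - y + c z = D. The regime on class D is decided by the sign
#' of k1 - (k2 + d k3) against the sign of D.
#' @param c,d integer family parameters (>= 1).
#' @param kappa positive rate constants (k1, k2, k3).
#' @param D stoichiometric class constant.
#' @return one of "center", "no_equilibrium", "invariant_rays", "saddle".
#' @export
family12_regime <- function(c, d, kappa, D) {
  stopifnot(c >= 1, d >= 1, length(kappa) == 3, all(kappa > 0))
  gap <- kappa[1] - (kappa[2] + kappa[3] * d)
  if (gap > 0) {
    if (D < 0) "center" else "no_equilibrium"
  } else if (gap == 0) {
    "invariant_rays"
  } else {
    if (D > 0) "saddle" else "no_equilibrium"
  }
}

#' Parametric regimes of the lifted LVA family
#'
#' On the stoichiometric class z - y = C of 2X -> 3X, X+Y -> (1+d)Y + dZ,
#' Y+Z -> 0, the reduction v = y/x, w = 1/x (a time rescaling by w) yields a
#' planar Lotka--Volterra system: a positive equilibrium exists iff C and
#' d k2^2 - k1 k3 have the same sign; it is globally asymptotically stable for
#' k2 < k3, a global center for k2 = k3 and a global repellor for k2 > k3
#' (positive branch), a saddle on the negative branch, and a line of
#' equilibria when both constants vanish.
#' @param d integer family parameter (>= 1).
#' @param kappa positive rate constants (k1, k2, k3).
#' @param C class constant (z - y).
#' @return one of "stable", "center", "repellor", "saddle",
#'   "line_of_equilibria", "no_equilibrium".
#' @export
lifted_lva_regime <- function(d, kappa, C) {
  stopifnot(d >= 1, length(kappa) == 3, all(kappa > 0))
  disc <- d * kappa[2] ^ 2 - kappa[1] * kappa[3]
  if (C == 0 && disc == 0) return("line_of_equilibria")
  if (sign(C) != sign(disc) || C == 0 || disc == 0) return("no_equilibrium")
  if (C < 0) return("saddle")
  if (kappa[2] < kappa[3]) "stable" else if (kappa[2] == kappa[3]) "center" else "repellor"
}

# ---- the ten planar source cases ------------------------------------------

# complexes as coordinate pairs (a, b); template order for cases 7-10 is the
# positively oriented order used by the classification theorem
.case_templates <- function() {
  list(
    `1` = list(c(0, 0), c(1, 0), c(0, 1)),          # 0, X, Y
    `2` = list(c(0, 0), c(1, 0), c(1, 1)),          # 0, X, X+Y
    `3` = list(c(0, 0), c(1, 0), c(0, 2)),          # 0, X, 2Y
    `4` = list(c(0, 0), c(2, 0), c(0, 2)),          # 0, 2X, 2Y
    `5` = list(c(2, 0), c(1, 0), c(0, 1)),          # 2X, X, Y
    `6` = list(c(1, 0), c(2, 0), c(0, 2)),          # X, 2X, 2Y
    `7` = list(c(1, 0), c(1, 1), c(0, 1)),          # X, X+Y, Y
    `8` = list(c(2, 0), c(1, 1), c(1, 0)),          # 2X, X+Y, X
    `9` = list(c(2, 0), c(1, 1), c(0, 1)),          # 2X, X+Y, Y
    `10` = list(c(2, 0), c(1, 1), c(0, 0))          # 2X, X+Y, 0
  )
}

#' Identify the source-complex case of a planar quadratic network
#'
#' Up to exchange of the two species there are exactly ten unordered triples
#' of distinct bimolecular source complexes not on a line. Cases 7-10 are
#' the oscillation-relevant ones (sources X,X+Y,Y / 2X,X+Y,X / 2X,X+Y,Y /
#' 2X,X+Y,0, listed in positively oriented template order); cases 1-6 admit
#' no periodic orbit.
#' @param net a `crn_network` with n = 2, m = 3, quadratic.
#' @return list(case_id, labelings) where each labeling records whether the
#'   species swap was applied and the reaction order aligning the network to
#'   the template.
#' @export
source_case_planar <- function(net) {
  if (net$n != 2 || net$m != 3) stop("source_case_planar requires a (2,3) network")
  if (!molecularity_profile(net)$is_quadratic) stop("network is not quadratic")
  src <- lapply(1:3, function(j) net$source[, j])
  keyset <- function(lst) paste(sort(vapply(lst, paste, "", collapse = ",")), collapse = ";")
  if (anyDuplicated(vapply(src, paste, "", collapse = ","))) {
    stop("repeated source complexes (collinear): no case applies")
  }
  if (sources_collinear(net)) stop("collinear sources: no case applies")
  templates <- .case_templates()
  labelings <- list()
  case_id <- NA_integer_
  for (swap in c(FALSE, TRUE)) {
    s <- if (swap) lapply(src, rev) else src
    ks <- keyset(s)
    for (cid in names(templates)) {
      if (identical(ks, keyset(templates[[cid]]))) {
        # reaction order aligning sources with the template listing
        tmpl <- templates[[cid]]
        ord <- vapply(tmpl, function(tc) {
          which(vapply(s, function(sc) all(sc == tc), TRUE))[1]
        }, 0L)
        if (is.na(case_id)) case_id <- as.integer(cid)
        labelings[[length(labelings) + 1]] <- list(swap = swap, order = ord)
      }
    }
  }
  if (is.na(case_id)) stop("sources do not match any case (internal error)")
  list(case_id = case_id, labelings = labelings)
}

# exact rational comparison helpers for the theorem conditions; c1, c3 > 0
.case9_10_window <- function(c1, d1, c3, d3, d2_over_c2_num, d2_over_c2_den = 1) {
  # (1/2)(d3/c3 + d1/c1) < r < d1/c1 with r = d2_over_c2_num / den (den > 0)
  lhs_ok <- (d3 * c1 + d1 * c3) * d2_over_c2_den < 2 * d2_over_c2_num * c1 * c3
  rhs_ok <- d2_over_c2_num * c1 < d1 * d2_over_c2_den
  lhs_ok && rhs_ok
}

#' Andronov--Hopf / center classification of a planar quadratic system
#'
#' Implements the complete ten-case classification of three-reaction, planar,
#' quadratic mass-action networks. Cases 1-6 admit no periodic orbit. Case 7
#' (sources X, X+Y, Y) gives a center for all rate constants exactly for the
#' generalized Lotka sign pattern, otherwise no periodic orbit. Case 8
#' (2X, X+Y, X) gives a vertical Andronov--Hopf bifurcation exactly under the
#' printed integer conditions, otherwise no periodic orbit. Cases 9
#' (2X, X+Y, Y) and 10 (2X, X+Y, 0) admit a (necessarily supercritical)
#' Andronov--Hopf bifurcation exactly under the printed inequalities on the
#' reaction-vector entries; when those fail, the existence of limit cycles is
#' not decided by the theory (inconclusive), except that an all-negative
#' kernel vector certifies a saddle and hence no periodic orbit. All
#' conditions are evaluated in exact integer arithmetic after normalizing the
#' network onto the positively oriented case template (species swap and
#' reaction reordering recorded in the certificate).
#'
#' @param net a `crn_network`, n = 2, m = 3, quadratic.
#' @return a `crn_verdict`; details include the case id and the (c, d) rows
#'   in template order.
#' @export
hopf_verdict_planar <- function(net) {
  if (net$n != 2 || net$m != 3) stop("hopf_verdict_planar requires a (2,3) network")
  if (!molecularity_profile(net)$is_quadratic) stop("network is not quadratic")
  pre <- oscillation_preconditions(net)
  if (!pre$checks$dynamically_nontrivial) {
    return(.verdict("dynamically_trivial", "stiemke",
                    certificate = paste("separating vector:",
                      paste(pre$nontriviality$separating_vector, collapse = ","))))
  }
  if (!pre$checks$rank_two) {
    return(.verdict("no_periodic_orbit", "rank_below_two",
                    certificate = "rank(Gamma) != 2"))
  }
  if (!pre$checks$sources_not_collinear) {
    return(.verdict("no_periodic_orbit", "sources_on_a_line",
                    certificate = "source complexes lie on an affine line"))
  }
  sc <- source_case_planar(net)
  if (sc$case_id <= 6) {
    return(.verdict("no_periodic_orbit", "cases_1_to_6",
                    details = list(case = sc$case_id)))
  }
  G <- net$target - net$source
  best <- NULL
  for (lab in sc$labelings) {
    Gl <- if (lab$swap) G[2:1, , drop = FALSE] else G
    cs <- Gl[1, lab$order]; ds <- Gl[2, lab$order]
    res <- .case_condition(sc$case_id, cs, ds, lab)
    if (!is.null(res)) { best <- res; break }
  }
  if (!is.null(best)) return(best)
  # conditions fail under every labeling
  if (sc$case_id %in% c(7, 8)) {
    return(.verdict("no_periodic_orbit",
                    sprintf("case_%d_conditions_fail", sc$case_id),
                    certificate = "printed case conditions fail: no periodic orbit",
                    details = list(case = sc$case_id)))
  }
  u <- kernel_sign_vector(net)
  if (all(u < 0)) {
    return(.verdict("saddle_always", sprintf("case_%d_saddle", sc$case_id),
                    certificate = "kernel vector all-negative: det J < 0 at the unique positive equilibrium",
                    details = list(case = sc$case_id), oscillatory = FALSE))
  }
  if (molecularity_profile(net)$max_target <= 3) {
    return(.verdict("no_periodic_orbit", "trimolecular_no_isolated_orbit",
                    certificate = "trimolecular quadratic planar system outside the Hopf/center families: no periodic orbit",
                    details = list(case = sc$case_id)))
  }
  glva <- generalized_lva_check(net)
  if (glva$status) {
    return(.verdict("no_periodic_orbit", "generalized_lva_repellor",
                    certificate = sprintf("generalized LVA (d=%d): repelling equilibrium, Dulac multiplier 1/(xy) precludes cycles", glva$d),
                    family = "generalized_lva", params = list(d = glva$d),
                    details = list(case = sc$case_id)))
  }
  .verdict("inconclusive", sprintf("case_%d_no_hopf", sc$case_id),
           certificate = "no Andronov-Hopf bifurcation; existence of limit cycles not decided",
           details = list(case = sc$case_id), oscillatory = FALSE)
}

.case_condition <- function(case_id, cs, ds, lab) {
  c1 <- cs[1]; c2 <- cs[2]; c3 <- cs[3]
  d1 <- ds[1]; d2 <- ds[2]; d3 <- ds[3]
  lab_note <- sprintf("template order (reactions %s)%s",
                      paste(lab$order, collapse = ","),
                      if (lab$swap) ", species swapped" else "")
  if (case_id == 7) {
    s <- sign(c1)
    if (c3 == 0 && d1 == 0 && s != 0 &&
        sign(c2) == -s && sign(d3) == -s && sign(d2) == s) {
      return(.verdict("center_for_all_kappa", "case_7_center",
        certificate = c(sprintf("c=(%d,%d,%d), d=(%d,%d,%d): c3=0, d1=0, sgn c1=-sgn c2=-sgn d3=sgn d2",
                                c1, c2, c3, d1, d2, d3), lab_note),
        family = "generalized_lotka", details = list(case = 7)))
    }
    return(NULL)
  }
  if (case_id == 8) {
    if (c1 > 0 && c2 == -1 && c3 > 0 && d1 > 0 && d2 == -1 && d3 >= 0 &&
        d3 < c3 && d1 > c1) {
      return(.verdict("vertical_hopf", "case_8_vertical",
        certificate = c(sprintf("c=(%d,%d,%d), d=(%d,%d,%d): d3/c3 < 1 < d1/c1; center exactly at k2 = %d k1",
                                c1, c2, c3, d1, d2, d3, c1), lab_note),
        details = list(case = 8, critical = sprintf("kappa2 = %d kappa1", c1))))
    }
    return(NULL)
  }
  if (case_id == 9) {
    ok <- FALSE
    if (c1 > 0 && c2 == -1 && d1 > 0 && d2 >= -1) {
      if (c3 > 0 && d3 >= -1) {
        ok <- .case9_10_window(c1, d1, c3, d3, -d2)    # d2/c2 = -d2
      } else if (c3 == 0 && d3 == -1) {
        ok <- (-d2) * c1 < d1                          # d2/c2 < d1/c1
      }
    }
    if (ok) {
      return(.verdict("supercritical_hopf", "case_9_hopf",
        certificate = c(sprintf("c=(%d,%d,%d), d=(%d,%d,%d): Hopf window (1/2)(d3/c3+d1/c1) < d2/c2 < d1/c1 (or the c3=0 branch)",
                                c1, c2, c3, d1, d2, d3), lab_note),
        details = list(case = 9)))
    }
    return(NULL)
  }
  if (case_id == 10) {
    if (c1 > 0 && c2 == -1 && c3 > 0 && d1 > 0 && d2 == -1 && d3 >= 0 &&
        .case9_10_window(c1, d1, c3, d3, 1)) {         # d2/c2 = 1
      return(.verdict("supercritical_hopf", "case_10_hopf",
        certificate = c(sprintf("c=(%d,%d,%d), d=(%d,%d,%d): Hopf window (1/2)(d3/c3+d1/c1) < 1 < d1/c1",
                                c1, c2, c3, d1, d2, d3), lab_note),
        details = list(case = 10)))
    }
    return(NULL)
  }
  NULL
}

# ---- the general trimolecular decision ------------------------------------

#' Full oscillation decision for quadratic trimolecular three-reaction systems
#'
#' Decides, for a quadratic trimolecular network with three reactions and any
#' number of species, whether its mass-action system admits a periodic orbit
#' for some rate constants (and of which kind). Trivial species are stripped
#' first (they only rescale rate constants) and reported. The procedure then
#' checks the rank/nontriviality/collinearity preconditions; without an
#' autocatalytic reaction it defers to [classify_no_form9()] (Ivanova /
#' generalized Lotka / Bendixson--Dulac); with 2X -> 3X present it dispatches
#' on the species count: two species give the generalized LVA (repellor) or a
#' saddle, three species give the lifted LVA family (vertical Hopf: centers
#' when k2 = k3 > k1 on classes z - y = C > 0) or saddles, four species give
#' positive equilibria only for one network, always a saddle, and five or
#' more species force dynamical triviality.
#'
#' @param net a quadratic trimolecular `crn_network` with m = 3.
#' @return a `crn_verdict`.
#' @export
classify_trimolecular_general <- function(net) {
  mp <- molecularity_profile(net)
  if (!mp$is_quadratic || mp$max_target > 3) {
    stop("classify_trimolecular_general requires a quadratic trimolecular network")
  }
  if (net$m != 3) stop("classify_trimolecular_general requires exactly 3 reactions")
  st <- strip_trivial_species(net)
  core <- st$net
  stripped <- st$removed_species
  if (core$m < 3) {
    return(.verdict("no_periodic_orbit", "too_few_distinct_reactions",
                    certificate = "after stripping trivial species, fewer than 3 distinct reactions remain: rank <= m-1 < 2",
                    stripped_species = stripped))
  }
  pre <- oscillation_preconditions(core)
  if (!pre$checks$dynamically_nontrivial) {
    return(.verdict("dynamically_trivial", "stiemke",
                    certificate = paste("separating vector:",
                      paste(pre$nontriviality$separating_vector, collapse = ",")),
                    stripped_species = stripped))
  }
  if (!pre$checks$rank_two) {
    return(.verdict("no_periodic_orbit", "rank_below_two",
                    certificate = "rank(Gamma) != 2", stripped_species = stripped))
  }
  if (!pre$checks$sources_not_collinear) {
    return(.verdict("no_periodic_orbit", "sources_on_a_line",
                    stripped_species = stripped))
  }
  f9 <- has_autocatalytic_form9(core)
  if (!f9$status) {
    v <- classify_no_form9(core)
    v$stripped_species <- stripped
    return(v)
  }
  n <- core$n
  if (n == 2) {
    gl <- generalized_lva_check(core)
    if (gl$status) {
      return(.verdict("no_periodic_orbit", "generalized_lva_repellor",
                      certificate = sprintf("generalized LVA (d=%d): det J > 0, tr J > 0 and Dulac multiplier 1/(xy) precludes cycles", gl$d),
                      family = "generalized_lva", params = list(d = gl$d),
                      stripped_species = stripped))
    }
    return(.verdict("no_periodic_orbit", "two_species_autocatalytic_saddle",
                    certificate = "2X -> 3X present and not the generalized LVA: the unique positive equilibrium is a saddle",
                    stripped_species = stripped))
  }
  if (n == 3) {
    ll <- .match_lifted_lva(core)
    if (!is.null(ll)) {
      return(.verdict("vertical_hopf", "lifted_lva",
                      certificate = sprintf("lifted LVA family (d=%d): centers on classes z-y=C>0 exactly when k2 = k3 (and d k2^2 > k1 k3); vertical Andronov-Hopf in k2/k3", ll["d"]),
                      family = "lifted_lva", params = as.list(ll),
                      stripped_species = stripped))
    }
    return(.verdict("no_periodic_orbit", "three_species_autocatalytic_saddle",
                    certificate = "2X -> 3X present, not the lifted LVA family: every positive equilibrium is a saddle in its class",
                    stripped_species = stripped))
  }
  if (n == 4) {
    if (identical(canonical_key(core), .cached_key("net27", four_species_saddle))) {
      return(.verdict("saddle_always", "four_species_saddle",
                      certificate = "det Jred = mu|mu| (2/(x y) + 1/(x z) + 1/(x w)) with mu < 0: saddle in every class",
                      family = "four_species_saddle", oscillatory = FALSE,
                      stripped_species = stripped))
    }
    return(.verdict("no_periodic_orbit", "four_species_no_equilibrium",
                    certificate = "with 2X -> 3X and four species, only one network admits positive equilibria (and it is a saddle); this one admits none",
                    stripped_species = stripped))
  }
  # n >= 5: dynamical nontriviality is impossible with 2X -> 3X present
  .verdict("dynamically_trivial", "five_or_more_species",
           certificate = "a quadratic (n,3,2) network with n >= 5 and 2X -> 3X must be dynamically trivial",
           stripped_species = stripped)
}
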