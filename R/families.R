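# Constructors for the named networks and network families that organise the
# oscillation theory of three-reaction quadratic mass-action systems.

#' The Lotka reactions
#'
#' X -> 2X, X+Y -> 2Y, Y -> 0. Bimolecular, rank two; every positive
#' nonequilibrium solution is periodic for all rate constants.
#' @return a `crn_network`.
#' @export
lotka <- function() parse_network(c("X -> 2X", "X + Y -> 2Y", "Y -> 0"))

#' The Ivanova reactions
#'
#' X+Y -> 2Y, Y+Z -> 2Z, Z+X -> 2X. Bimolecular, rank two (x+y+z is
#' conserved); in each positive stoichiometric class the unique positive
#' equilibrium is a global center, for all rate constants.
#' @return a `crn_network`.
#' @export
ivanova <- function() parse_network(c("X + Y -> 2Y", "Y + Z -> 2Z", "Z + X -> 2X"))

#' The generalized Lotka family
#'
#' X -> (1+c)X, X+Y -> (1+d)Y, Y -> 0 with integer parameters c, d >= 1
#' (c = d = 1 is the Lotka network). The unique positive equilibrium is a
#' global center for all rate constants; the conserved quantity is
#' d k2 x + k2 y - k3 log x - c k1 log y.
#' @param c,d positive integer parameters.
#' @return a `crn_network`.
#' @export
generalized_lotka <- function(c = 1, d = 1) {
  stopifnot(c >= 1, d >= 1)
  parse_network(c(sprintf("X -> %dX", 1 + c),
                  sprintf("X + Y -> %dY", 1 + d),
                  "Y -> 0"))
}

#' The three-species center family
#'
#' X+Z -> (1+c)X, X+Y -> 0, Y+Z -> (1+cd)Y + (1+d)Z with integer parameters
#' c, d >= 1. Its mass-action system is a Lotka--Volterra equation without
#' diagonal terms; the positive equilibria form the ray t(c d k3, c k1, k2),
#' the stoichiometric classes are x - y + c z = D, and
#' d k3 log x - k1 log y + k2 log z is conserved. Depending on the rate
#' constants the system has global centers on classes with D < 0
#' (k1 > k2 + d k3), invariant rays (k1 = k2 + d k3), or saddles (D > 0,
#' k1 < k2 + d k3). No member is trimolecular.
#' @param c,d positive integer parameters.
#' @return a `crn_network`.
#' @export
three_species_center_family <- function(c = 1, d = 1) {
  stopifnot(c >= 1, d >= 1)
  network(c("X", "Y", "Z"),
          source = cbind(c(1, 0, 1), c(1, 1, 0), c(0, 1, 1)),
          target = cbind(c(1 + c, 0, 0), c(0, 0, 0), c(0, 1 + c * d, 1 + d)))
}

#' The Lotka--Volterra--Autocatalator (LVA) and its generalization
#'
#' 2X -> 3X, X+Y -> (1+d)Y, Y -> 0 with d >= 1 (d = 1 is the LVA). The
#' unique positive equilibrium is a repellor (det J > 0, tr J > 0) and, by a
#' Bendixson--Dulac argument with multiplier 1/(xy), the system admits no
#' periodic orbit.
#' @param d positive integer parameter.
#' @return a `crn_network`.
#' @export
generalized_lva <- function(d = 1) {
  stopifnot(d >= 1)
  parse_network(c("2X -> 3X", sprintf("X + Y -> %dY", 1 + d), "Y -> 0"))
}

#' @rdname generalized_lva
#' @export
lva <- function() generalized_lva(1)

#' The lifted LVA family
#'
#' 2X -> 3X, X+Y -> (1+d)Y + dZ, Y+Z -> 0 with d >= 1, obtained by adding a
#' species Z to the generalized LVA while preserving rank two. The positive
#' equilibria form the ray (t, k1 t / k2, d k2 t / k3); since dy/dt = dz/dt
#' the stoichiometric classes are z - y = C. On classes with C > 0 (and
#' d k2^2 > k1 k3) the system undergoes a vertical Andronov--Hopf bifurcation
#' as k2/k3 passes 1: stable focus for k2 < k3, global center for k2 = k3,
#' repellor for k2 > k3. Only d = 1 (the lifted LVA) is trimolecular.
#' @param d positive integer parameter.
#' @return a `crn_network`.
#' @export
lifted_lva <- function(d = 1) {
  stopifnot(d >= 1)
  parse_network(c("2X -> 3X",
                  if (d == 1) "X + Y -> 2Y + Z" else
                    sprintf("X + Y -> %dY + %dZ", 1 + d, d),
                  "Y + Z -> 0"))
}

#' The simplest tetramolecular supercritical Hopf network
#'
#' 2X -> 3X + Y, X+Y -> (1+d)Y, Y -> 0 with d in 0..3: the four quadratic
#' tetramolecular three-reaction networks admitting a supercritical
#' Andronov--Hopf bifurcation (at k1 = k2, with k3 free). `hopf_tetramolecular(0)`
#' is the minimal example.
#' @param d integer in 0..3 (larger d gives higher target molecularity).
#' @return a `crn_network`.
#' @export
hopf_tetramolecular <- function(d = 0) {
  stopifnot(d >= 0)
  parse_network(c("2X -> 3X + Y",
                  if (d == 0) "X + Y -> Y" else sprintf("X + Y -> %dY", 1 + d),
                  "Y -> 0"))
}

#' The four-species saddle network
#'
#' 2X -> 3X, X+Y -> Z+W, Z+W -> Y: the only quadratic (4,3,2) network
#' without trivial species containing 2X -> 3X that has positive equilibria.
#' Every positive equilibrium is a saddle in its stoichiometric class, so the
#' system admits no periodic orbit.
#' @return a `crn_network`.
#' @export
four_species_saddle <- function() {
  parse_network(c("2X -> 3X", "X + Y -> Z + W", "Z + W -> Y"))
}

#' Pentamolecular vertical-Hopf example (source case 2X, X+Y, X)
#'
#' 2X -> 3X + 2Y, X+Y -> 0, X -> 2X: at k2 = c1 k1 (here k2 = k1) the system
#' reduces, after division by x, to a linear center; varying k1/k2 gives a
#' vertical Andronov--Hopf bifurcation. All focal values vanish.
#' @return a `crn_network`.
#' @export
vertical_hopf_pentamolecular <- function() {
  parse_network(c("2X -> 3X + 2Y", "X + Y -> 0", "X -> 2X"))
}

#' Heptamolecular supercritical Hopf example (source case 2X, X+Y, 0)
#'
#' 2X -> 4X + 3Y, X+Y -> 0, 0 -> X: a witness that in the source case
#' (2X, X+Y, 0) the minimal target molecularity admitting an Andronov--Hopf
#' bifurcation is seven.
#' @return a `crn_network`.
#' @export
hopf_heptamolecular <- function() {
  parse_network(c("2X -> 4X + 3Y", "X + Y -> 0", "0 -> X"))
}
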