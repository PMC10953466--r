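---
title: "Deciding oscillation in three-reaction quadratic mass-action systems"
author: "crnosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding oscillation in three-reaction quadratic mass-action systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnosc)
```

## The model

A reaction network on species $X_1,\dots,X_n$ is a finite set of reactions
$\sum_i a_{ij} X_i \to \sum_i (a_{ij}+c_{ij}) X_i$. The package stores the
source matrix $\Gamma_\ell = [a_{ij}] \in \mathbb{Z}_{\ge 0}^{n\times m}$ and
the stoichiometric matrix $\Gamma = [c_{ij}] \in \mathbb{Z}^{n\times m}$.
Under mass-action kinetics with rate constants $\kappa \in \mathbb{R}_+^m$
the concentrations evolve by

$$\dot x \;=\; \Gamma\,\bigl(\kappa \circ x^{\Gamma_\ell^{\mathsf T}}\bigr),$$

a polynomial vector field that leaves the positive orthant and every
stoichiometric class $(x_0 + \operatorname{im}\Gamma)\cap\mathbb{R}^n_{\ge0}$
invariant. A network is *quadratic* when every source has molecularity
$\sum_i a_{ij} \le 2$ (the vector field is then a quadratic polynomial) and
*trimolecular* when all complexes have molecularity $\le 3$. Three reactions
is the least number for which periodic orbits are possible at all: a
dynamically nontrivial network with $m$ reactions has rank at most $m-1$,
and periodic orbits need rank at least two.

The package answers, exactly, the question: *which three-reaction quadratic
networks admit a periodic orbit for some rate constants, and of what kind?*

## Structural predicates (exact arithmetic)

Oscillation is impossible unless a chain of structural conditions holds, and
each is decided in exact rational arithmetic — the censuses below must not
depend on floating-point rank decisions:

* **rank two** — `network_rank()`, fraction-free elimination;
* **dynamical nontriviality** — $\ker\Gamma \cap \mathbb{R}^m_+ \neq
  \emptyset$, decided by an exact basic-solution search for
  $\{\Gamma u = 0,\ u \ge 1\}$; when infeasible, duality guarantees a vector
  $v$ with $\Gamma^{\mathsf T} v \gneq 0$, which is a strictly increasing
  linear functional and rules out positive limit sets. Both outcomes carry a
  witness that `is_dynamically_nontrivial()` verifies by multiplication.
  For $m=3$, rank-two networks the kernel is spanned by the cross product
  $u = c \times d$ of two independent rows of $\Gamma$
  (`kernel_sign_vector()`), and nontriviality is equivalent to $u$ having one
  strict sign;
* **sources not collinear** — `sources_collinear()`; if all sources lie on an
  affine line the field is, after division by a positive monomial, a function
  of a single monomial, and no rank-two system of that form has a periodic
  orbit.

## Stability on stoichiometric classes

At a positive equilibrium $\bar x$ of an $(n,3,2)$ system,
$\kappa\circ\bar x^{\Gamma_\ell^{\mathsf T}} = \mu u$ for a scalar $\mu$ with
the common sign of $u$. Writing $\Gamma = \tilde\Gamma
\binom{c^{\mathsf T}}{d^{\mathsf T}}$ with the identity on two privileged
rows, the reduced Jacobian (the Jacobian restricted to the stoichiometric
subspace) is

$$J_{\mathrm{red}} \;=\; \mu \begin{pmatrix} c^{\mathsf T}\\ d^{\mathsf T}
\end{pmatrix} \Delta_u \,\Gamma_\ell^{\mathsf T}\, \Delta_{1/\bar x}\,
\tilde\Gamma,$$

and a Cauchy–Binet expansion of its determinant gives

$$\det J_{\mathrm{red}} \;=\; \mu\,|\mu|\,|u_1u_2u_3| \sum_{i<j}
\frac{\tilde\Gamma[\{i,j\}]}{\bar x_i \bar x_j}\,
\bigl(\mathbf 1\cdot(a_{i\cdot}\times a_{j\cdot})\bigr),$$

where $a_{i\cdot}$ are rows of $\Gamma_\ell$ and each orientation factor
$\mathbf 1\cdot(a_{i\cdot}\times a_{j\cdot})$ records how the three sources
project onto the $(i,j)$ species plane. With the normalization used here
(identity block on the privileged rows) the two expressions are *equal*, not
merely of equal sign, and `reduced_jacobian()` computes both and reports the
per-pair terms; the test suite also checks them against the product of the
two nonzero eigenvalues of the full Jacobian. A negative determinant means a
saddle on the class and excludes periodic orbits outright. For $n=2$,
`planar_det_tr()` adds the closed trace formula
$\operatorname{tr} J = \mu(\tfrac1{\bar x}\sum a_ic_iu_i +
\tfrac1{\bar y}\sum b_id_iu_i)$ and the sign rule
$\operatorname{sgn}\det J = \operatorname{sgn}\mu = \operatorname{sgn} u_i$
for positively oriented sources.

Equilibria themselves are found by a logarithmic change of variables:
$a_{\cdot j}\cdot\log\bar x - \log|\mu| = \log(|u_j|/\kappa_j)$ is linear in
$(\log \bar x, \log|\mu|)$, so existence, uniqueness, and the dimension of
the solution family are read off a linear system rather than trusted to a
Newton iteration. For $n\ge3$ the solution is an affine family in log
coordinates; `equilibria_on_class()` intersects it with a stoichiometric
class by a small Newton solve on the conserved linear coordinates.

## The classification

`classify_trimolecular_general()` decides a quadratic trimolecular
three-reaction network of any species count:

1. strip trivial species (zero rows of $\Gamma$; they only rescale rate
   constants) and merge duplicated reactions;
2. check the structural preconditions above;
3. if no reaction of the autocatalytic form $2X_j \to (2+c_j)X_j + \dots$
   (with $c_j>0$, nothing else lost) is present, the Dulac multiplier
   $(x_1\cdots x_n)^{-1}$ makes the divergence nonpositive; it vanishes
   identically only for Lotka–Volterra equations without diagonal terms, and
   the three-reaction networks realizing those with non-saddle positive
   equilibria are exactly three families:
   * the **generalized Lotka family** $X\to(1+c)X$, $X+Y\to(1+d)Y$,
     $Y\to 0$ ($c,d\ge1$) — a global center for all $\kappa$, with first
     integral $d\kappa_2 x + \kappa_2 y - \kappa_3\log x - c\kappa_1\log y$;
   * the **Ivanova reactions** $X+Y\to 2Y$, $Y+Z\to 2Z$, $Z+X\to 2X$ —
     centers on every class $x+y+z=C>0$;
   * a **three-species center family** $X+Z\to(1+c)X$, $X+Y\to 0$,
     $Y+Z\to(1+cd)Y+(1+d)Z$ ($c,d\ge1$, never trimolecular), with classes
     $x-y+cz=D$, equilibrium ray $t\,(cd\kappa_3, c\kappa_1, \kappa_2)$ and
     first integral $d\kappa_3\log x - \kappa_1\log y + \kappa_2\log z$:
     centers on classes $D<0$ when $\kappa_1>\kappa_2+d\kappa_3$, invariant
     rays at equality, saddles on $D>0$ otherwise (`family12_regime()`).
4. if $2X\to3X$ is present, the species count decides: $n=2$ gives the
   generalized LVA $2X\to3X$, $X+Y\to(1+d)Y$, $Y\to0$ (a repellor, no
   cycles by the Dulac multiplier $1/(xy)$) or a saddle; $n=3$ gives the
   **lifted LVA family** $2X\to3X$, $X+Y\to(1+d)Y+dZ$, $Y+Z\to0$ or
   saddles; $n=4$ admits positive equilibria for exactly one network
   ($2X\to3X$, $X+Y\to Z+W$, $Z+W\to Y$), always a saddle; $n\ge5$ forces
   dynamical triviality.

On a class $z-y=C$ the lifted LVA reduces, via $v=y/x$, $w=1/x$ and a
positive time rescaling, to a planar Lotka–Volterra system: equilibria exist
iff $C$ and $d\kappa_2^2-\kappa_1\kappa_3$ share their sign, and a convex
Lyapunov function with $\dot V = \kappa_2(\kappa_2-\kappa_3)(v-\bar v)^2$
makes the equilibrium globally stable for $\kappa_2<\kappa_3$, a global
center at $\kappa_2=\kappa_3$, and a global repellor for $\kappa_2>\kappa_3$
(`lifted_lva_regime()`): a *vertical* Andronov–Hopf bifurcation, with no
isolated cycles anywhere in the family.

For planar networks with unrestricted target molecularity,
`hopf_verdict_planar()` implements the complete ten-case classification by
source configuration: up to exchanging the two species there are exactly ten
non-collinear triples of bimolecular sources (`census_source_cases()`). Six
admit no periodic orbit; sources $(X, X{+}Y, Y)$ give centers exactly for
the generalized-Lotka sign pattern; sources $(2X, X{+}Y, X)$ give a vertical
bifurcation exactly under printed integer conditions (after division by $x$
the critical system is linear); sources $(2X, X{+}Y, Y)$ and
$(2X, X{+}Y, 0)$ admit an Andronov–Hopf bifurcation — always supercritical —
exactly when integer inequalities such as $\tfrac12(d_3/c_3 + d_1/c_1) <
d_2/c_2 < d_1/c_1$ hold. All conditions are evaluated in integer arithmetic
after normalizing the network onto a positively oriented case template; the
species swap and reaction reordering are recorded in the certificate.

The center condition for sources $(X, X{+}Y, Y)$ is implemented as
$c_3=0$, $d_1=0$, and the sign chain
$\operatorname{sgn}c_1=-\operatorname{sgn}c_2=-\operatorname{sgn}d_3=
\operatorname{sgn}d_2\neq0$ — with $d_1=0$ the chain can only constrain
$d_3$ and $d_2$, and this is the unique reading consistent with the
generalized Lotka realization.

## The first focal value

At a candidate Hopf point ($\operatorname{tr}J=0$, $\det J>0$, located by
`find_hopf_point()` through log-scale bisection to relative $10^{-12}$),
`first_focal_value()` translates the equilibrium to the origin, transforms
the linear part to $\bigl(\begin{smallmatrix}0&-\omega\\ \omega&0
\end{smallmatrix}\bigr)$ with $\omega=\sqrt{\det J}$, and evaluates the
standard planar normal-form expression

$$L_1 = \frac{1}{16\omega}\Bigl[f_{xy}(f_{xx}+f_{yy}) -
g_{xy}(g_{xx}+g_{yy}) - f_{xx}g_{xx} + f_{yy}g_{yy}\Bigr],$$

exact for quadratic fields (all third-order terms vanish; the polynomial
algebra is done on coefficient arrays, not by numerical differentiation).
$L_1<0$ is a supercritical bifurcation. Sign claims are only made when the
dimensionless $|L_1|\,\omega/K^2$ ($K$ = largest quadratic normal-form
coefficient) exceeds $10^{-8}$; below that the point is reported as a
vertical/center candidate rather than pretending to resolve a weak focus.
The four tetramolecular networks give $L_1 = -0.25, -0.375, -0.5, -0.625$
at their critical points $\kappa_1=\kappa_2=\kappa_3=1$.
`hopf_side_check()` corroborates supercriticality dynamically: on the
unstable side the Poincaré return radius converges to a limit-cycle
amplitude that shrinks toward zero as the parameter approaches criticality.

## Simulation and periodicity

`simulate_system()` integrates with an adaptive Dormand–Prince method at
`rtol = 1e-9`, `atol = 1e-12`. The defaults are deliberately tight: center
orbits are neutrally stable, and at loose tolerances numerical damping turns
them into spurious spirals. Integration proceeds in chunks so that
finite-time blow-up (solutions of these quadratic systems can be unbounded,
e.g. the repelling LVA) is detected within a fraction of a second and
reported instead of stalling. A trajectory leaving the positive orthant
beyond rounding tolerance is an error, since the analysis is interior.

`detect_periodicity()` works in class coordinates (an orthonormal basis of
$\operatorname{im}\Gamma$) with a Poincaré section through the initial point
normal to the flow. Closure of the first return within $10^{-4}$ relative to
the orbit amplitude reports a periodic orbit; a systematic monotone drift of
successive returns, or convergence of the flow to an equilibrium, reports
non-periodicity; everything else is inconclusive — numerics alone are never
allowed to assert non-existence from a near miss.

## Enumeration and the censuses

The enumerators are exact and source-triple-first. For each species count
they generate unordered triples of distinct source complexes up to species
permutation, keep those that cover all species and are not collinear (each
restriction is a necessary condition for oscillation, so the oscillatory
censuses lose nothing), then sweep all target assignments, applying the
rank-two and one-signed-kernel filters as vectorized integer arithmetic
before any network object is built. Surviving candidates are classified and
the oscillatory ones deduplicated by canonical form — the lexicographic
minimum of the serialized $(\Gamma_\ell, \Gamma)$ over all species
permutations with sorted reactions, feasible since $n\le5$ throughout.

Problem sizes: species counts 2–4 (about 6\,800 candidate networks pass the
filters and are classified, out of a few hundred thousand target
assignments screened), which completes in about a minute. The bound $n\le4$
is itself part of the theory — without $2X\to3X$ oscillatory networks have
at most 3 species plus at most two trivial ones; with it, $n\ge5$ is
dynamically trivial — and `census_trimolecular_oscillatory(max_species = 5)` re-verifies it
empirically.

The headline counts reproduced by the package:

* `census_source_cases()` — 10 source configurations;
* `census_trimolecular_oscillatory()` — 16 quadratic trimolecular three-reaction networks
  admit a periodic orbit: 4 generalized-Lotka members ($c,d\in\{1,2\}$),
  8 with one trivial species, 2 with two trivial species, Ivanova, and the
  lifted LVA. None has an isolated periodic orbit. A constructive list built
  independently from the augmentation rules matches the enumerated set
  class-by-class. (Trivial-species variants count as distinct networks; note
  that one of them — Lotka with a trivial species in the outflow reaction —
  is itself bimolecular, so "bimolecular members" is read at the level of
  networks without trivial species: Lotka and Ivanova.)
* `census_tetramolecular_hopf()` — exactly 4 tetramolecular networks admit
  an Andronov–Hopf bifurcation ($2X\to3X+Y$, $X+Y\to(1+d)Y$, $Y\to0$,
  $d=0..3$), all supercritical; with trimolecular targets, none.
* `min_case10_molecularity()` — in the source case $(2X, X{+}Y, 0)$ a Hopf
  bifurcation first appears at target molecularity 7.
* `supercritical_family_count()` — exactly 2 of the ten source cases admit
  a supercritical bifurcation.
* `min_reactions_for_oscillation()` — 3, with the $m\le2$ impossibility
  verified exhaustively at small molecularities.

## What the numerical corroboration does and does not show

The classifier's verdicts rest on exact integer conditions; simulations and
return maps are used as *corroboration* (a center verdict is accompanied by
a closed orbit at a sampled point, a no-cycle verdict by non-closing
returns), never as the deciding step. Conversely, the corroborating runs
sample specific rate constants and initial conditions; they illustrate, but
do not re-prove, the "for all $\kappa$" quantifiers, and properties of real
reaction systems outside this network class (more reactions, non-mass-action
kinetics, higher source molecularity) are out of scope.

## Known limitations

* Only the first focal value is computed; degenerate candidates are reported
  as "vertical", not resolved further.
* For planar case-9/10 networks that fail the Hopf inequalities, the
  existence of limit cycles is genuinely open and the verdict says so.
* Bogdanov–Takens/homoclinic phenomena in related higher-molecularity
  networks are outside the decision procedures; only trace/determinant
  degeneracies are detected.
* The enumeration is specialized to three reactions; `trimolecularize()`
  bridges to higher target molecularities at the cost of extra reactions,
  but four-reaction censuses are not attempted.
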