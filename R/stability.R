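# Reduced Jacobian machinery for three-reaction rank-two mass-action systems:
# the Cauchy-Binet determinant expansion, planar determinant/trace formulas,
# equilibrium classification, and the numerical first focal value.

#' Orientation of the source complexes projected to a species pair
#'
#' For a three-reaction network, the sign of 1.(a_i x a_j), where a_i and a_j
#' are the rows of the source matrix for species i and j: positive when the
#' three source complexes, projected onto the (i, j) coordinate plane, span a
#' positively oriented triangle; zero when they are collinear there.
#' @param net a `crn_network` with m = 3.
#' @param i,j species indices.
#' @return -1, 0 or 1.
#' @export
source_orientation <- function(net, i = 1, j = 2) {
  if (net$m != 3) stop("source_orientation requires exactly 3 reactions")
  sign(sum(.cross3(net$source[i, ], net$source[j, ])))
}

#' Reduced Jacobian at a positive equilibrium, two ways
#'
#' Builds the reduced Jacobian Jred = mu [c;d] Du Gl^T D(1/x) Gtilde of an
#' (n,3,2) mass-action system at a positive equilibrium, where c, d are the
#' two privileged (first independent) rows of Gamma, u = c x d spans
#' ker Gamma, and Gtilde is the basis matrix with identity on the privileged
#' rows. The determinant is computed both from the 2x2 matrix and from the
#' Cauchy-Binet expansion over species pairs
#' det Jred = mu |mu| |u1 u2 u3| sum_{i<j} Gtilde[{i,j}] / (x_i x_j) (1.(a_i x a_j)),
#' which are equal exactly; both are reported together with the per-pair terms.
#'
#' @param sys a `crn_massaction` with m = 3 and rank 2.
#' @param x positive equilibrium (e.g. from [positive_equilibria()]).
#' @return list with `Jred` (2x2), `det`, `det_cauchy_binet`, `det_sign`,
#'   `mu`, `u`, `privileged_rows`, `Gtilde`, `terms` (data.frame of per-pair
#'   contributions).
#' @export
reduced_jacobian <- function(sys, x) {
  net <- sys$net
  if (net$m != 3) stop("reduced_jacobian requires exactly 3 reactions")
  G <- sys$G
  rows <- .independent_row_pair(G)
  if (is.null(rows)) stop("reduced_jacobian requires rank 2")
  resid <- max(abs(rhs(sys, x)))
  scale <- max(abs(.rates(sys, x)))
  if (resid > 1e-6 * max(1, scale)) {
    stop("x is not an equilibrium (residual ", signif(resid, 3), ")")
  }
  cvec <- G[rows[1], ]; dvec <- G[rows[2], ]
  u <- .cross3(cvec, dvec)
  rates <- .rates(sys, x)
  mus <- rates / u
  mu <- mus[1]
  if (max(abs(mus - mu)) > 1e-6 * abs(mu)) {
    stop("kappa o x^Gl is not proportional to u: x is not a positive equilibrium")
  }
  M <- rbind(cvec, dvec)                 # 2 x 3
  # Gtilde: rows solve g_i = Gtilde[i,1] c + Gtilde[i,2] d  (identity on the
  # privileged rows)
  Gt <- t(qr.solve(qr(t(M)), t(G)))      # n x 2, least squares = exact here
  n <- net$n
  Jred <- mu * M %*% diag(u) %*% t(sys$Gl) %*% diag(1 / x, n) %*% Gt
  det_mat <- Jred[1, 1] * Jred[2, 2] - Jred[1, 2] * Jred[2, 1]
  pairs <- utils::combn(n, 2)
  terms <- data.frame(i = pairs[1, ], j = pairs[2, ], minor = NA_real_,
                      orientation = NA_real_, term = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    minor <- Gt[i, 1] * Gt[j, 2] - Gt[i, 2] * Gt[j, 1]
    ori <- sum(.cross3(sys$Gl[i, ], sys$Gl[j, ]))
    terms$minor[k] <- minor
    terms$orientation[k] <- ori
    terms$term[k] <- minor / (x[i] * x[j]) * ori
  }
  det_cb <- mu * abs(mu) * abs(prod(u)) * sum(terms$term)
  tolz <- 1e-9 * max(abs(det_mat), abs(det_cb), 1e-300)
  list(Jred = Jred, det = det_mat, det_cauchy_binet = det_cb,
       det_sign = if (abs(det_mat) < tolz) 0L else as.integer(sign(det_mat)),
       mu = mu, u = u, privileged_rows = rows, Gtilde = Gt, terms = terms)
}

#' Planar determinant and trace at the positive equilibrium
#'
#' For a (2,3,2) mass-action system, computes det J and tr J at the unique
#' positive equilibrium both from the analytic Jacobian and from the closed
#' formulas det J = mu |mu| |u1 u2 u3| (1.(a x b)) / (xbar ybar) and
#' tr J = mu (1/xbar sum a_i c_i u_i + 1/ybar sum b_i d_i u_i), and classifies
#' the equilibrium.
#'
#' @param sys a `crn_massaction` with n = 2, m = 3, rank 2.
#' @param eq optional result of [positive_equilibria()].
#' @return list with `det`, `tr`, the formula values `det_formula`,
#'   `tr_formula`, `mu`, `u`, `x`, and `class` in saddle / center_candidate /
#'   stable_focus_or_node / unstable_focus_or_node / degenerate.
#' @export
planar_det_tr <- function(sys, eq = positive_equilibria(sys)) {
  net <- sys$net
  if (net$n != 2) stop("planar_det_tr requires two species")
  if (!eq$exists) stop("no positive equilibrium")
  x <- eq$x
  J <- ma_jacobian(sys, x)
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  trJ <- J[1, 1] + J[2, 2]
  a <- sys$Gl[1, ]; b <- sys$Gl[2, ]
  cc <- sys$G[1, ]; dd <- sys$G[2, ]
  u <- .cross3(cc, dd)
  mu <- eq$mu
  det_f <- mu * abs(mu) * abs(prod(u)) / (x[1] * x[2]) * sum(.cross3(a, b))
  tr_f <- mu * (sum(a * cc * u) / x[1] + sum(b * dd * u) / x[2])
  scal <- max(abs(detJ), abs(trJ), 1)
  cls <- if (detJ < -1e-12 * scal) "saddle"
  else if (abs(detJ) <= 1e-12 * scal) "degenerate"
  else if (abs(trJ) <= 1e-9 * scal) "center_candidate"
  else if (trJ > 0) "unstable_focus_or_node" else "stable_focus_or_node"
  list(det = detJ, tr = trJ, det_formula = det_f, tr_formula = tr_f,
       mu = mu, u = u, x = x, class = cls)
}

#' Locate a Hopf point by solving tr J(kappa) = 0 in one rate constant
#'
#' Holds all rate constants except `param` fixed, scans `kappa[param]` over a
#' wide logarithmic grid for a sign change of the trace at the positive
#' equilibrium, and bisects to high precision.
#' @param net a `crn_network` with n = 2, m = 3.
#' @param param index of the rate constant to vary.
#' @param kappa base rate constants (the varied one is overwritten).
#' @return list(kappa, x, tr, det) at the critical point, or NULL when the
#'   trace does not change sign.
#' @export
find_hopf_point <- function(net, param = 1, kappa = rep(1, net$m)) {
  trace_at <- function(k) {
    kap <- kappa; kap[param] <- k
    sys <- mass_action(net, kap)
    eq <- positive_equilibria(sys)
    if (!eq$exists) return(NA_real_)
    planar_det_tr(sys, eq)$tr
  }
  grid <- 10 ^ seq(-6, 6, by = 0.25)
  tv <- vapply(grid, trace_at, 0)
  ok <- which(!is.na(tv))
  sgn <- sign(tv[ok])
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(ch) == 0) {
    z <- which(tv[ok] == 0)
    if (length(z) > 0) {
      kcrit <- grid[ok[z[1]]]
    } else return(NULL)
  } else {
    lo <- grid[ok[ch[1]]]; hi <- grid[ok[ch[1] + 1]]
    for (it in 1:200) {
      mid <- sqrt(lo * hi)
      tm <- trace_at(mid)
      if (is.na(tm)) return(NULL)
      if (sign(tm) == sign(trace_at(lo))) lo <- mid else hi <- mid
      if (hi - lo < 1e-14 * hi) break
    }
    kcrit <- sqrt(lo * hi)
  }
  kap <- kappa; kap[param] <- kcrit
  sys <- mass_action(net, kap)
  eq <- positive_equilibria(sys)
  pdt <- planar_det_tr(sys, eq)
  list(kappa = kap, x = eq$x, tr = pdt$tr, det = pdt$det, param = param)
}

# quadratic bivariate polynomial utilities; coefficient matrix C[i+1, j+1]
# is the coefficient of x^i y^j, i + j <= deg (we carry a (deg+1)^2 array)
.ma_poly <- function(sys, row) {
  # polynomial of component `row` of the planar mass-action field
  C <- matrix(0, 3, 3)
  for (j in seq_len(sys$net$m)) {
    a <- sys$Gl[1, j]; b <- sys$Gl[2, j]
    C[a + 1, b + 1] <- C[a + 1, b + 1] + sys$G[row, j] * sys$kappa[j]
  }
  C
}

# p(x0 + u, y0 + v) for polynomial of total degree <= 2
.poly_shift <- function(C, x0, y0) {
  D <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) {
    if (C[i + 1, j + 1] == 0) next
    for (p in 0:i) for (q in 0:j) {
      D[p + 1, q + 1] <- D[p + 1, q + 1] +
        C[i + 1, j + 1] * choose(i, p) * choose(j, q) *
        x0 ^ (i - p) * y0 ^ (j - q)
    }
  }
  D
}

# p(t11 z1 + t12 z2, t21 z1 + t22 z2) for total degree <= 2
.poly_linsub <- function(C, T) {
  D <- matrix(0, 3, 3)
  add <- function(D, i, j, v) { D[i + 1, j + 1] <- D[i + 1, j + 1] + v; D }
  # constant / linear / quadratic monomials
  D <- add(D, 0, 0, C[1, 1])
  D <- add(D, 1, 0, C[2, 1] * T[1, 1] + C[1, 2] * T[2, 1])
  D <- add(D, 0, 1, C[2, 1] * T[1, 2] + C[1, 2] * T[2, 2])
  # x^2
  D <- add(D, 2, 0, C[3, 1] * T[1, 1] ^ 2)
  D <- add(D, 1, 1, C[3, 1] * 2 * T[1, 1] * T[1, 2])
  D <- add(D, 0, 2, C[3, 1] * T[1, 2] ^ 2)
  # y^2
  D <- add(D, 2, 0, C[1, 3] * T[2, 1] ^ 2)
  D <- add(D, 1, 1, C[1, 3] * 2 * T[2, 1] * T[2, 2])
  D <- add(D, 0, 2, C[1, 3] * T[2, 2] ^ 2)
  # xy
  D <- add(D, 2, 0, C[2, 2] * T[1, 1] * T[2, 1])
  D <- add(D, 1, 1, C[2, 2] * (T[1, 1] * T[2, 2] + T[1, 2] * T[2, 1]))
  D <- add(D, 0, 2, C[2, 2] * T[1, 2] * T[2, 2])
  D
}

#' First focal value (first Lyapunov coefficient) at a planar Hopf point
#'
#' For a (2,3,2) mass-action system whose positive equilibrium has tr J = 0
#' and det J > 0, translates the equilibrium to the origin, brings the linear
#' part to the rotation normal form [[0, -w], [w, 0]], and evaluates the
#' standard planar normal-form formula for the first focal value L1 (the
#' right-hand side is a quadratic polynomial, so all third-order terms
#' vanish). A negative L1 means the Andronov--Hopf bifurcation is
#' supercritical. The sign is only reported when the nondimensionalized
#' |L1| w / K^2 (K = largest quadratic coefficient in normal-form
#' coordinates) exceeds the resolution threshold; below it the point is
#' reported as a vertical-Hopf/center candidate.
#'
#' @param sys a `crn_massaction`, n = 2, at a Hopf point.
#' @param tol_trace tolerance on |tr J| for accepting a Hopf point.
#' @param resolution nondimensional threshold below which L1 is treated as 0.
#' @return list with `L1`, `L1_scaled`, `omega`, `x`, `supercritical`,
#'   `vertical_candidate`.
#' @export
first_focal_value <- function(sys, tol_trace = 1e-7, resolution = 1e-8) {
  if (sys$net$n != 2) stop("first_focal_value requires two species")
  eq <- positive_equilibria(sys)
  if (!eq$exists) stop("no positive equilibrium")
  J <- ma_jacobian(sys, eq$x)
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  trJ <- J[1, 1] + J[2, 2]
  if (detJ <= 0) stop("det J <= 0: not a Hopf point")
  if (abs(trJ) > tol_trace * max(abs(J))) {
    stop("tr J != 0 (", signif(trJ, 3), "): not a Hopf point")
  }
  w <- sqrt(detJ)
  a <- J[1, 1]; b <- J[1, 2]; cc <- J[2, 1]; d <- J[2, 2]
  if (abs(b) >= abs(cc)) {
    T <- matrix(c(b, -a, 0, -w), 2, 2)
  } else {
    T <- matrix(c(-d, cc, -w, 0), 2, 2)
  }
  Tinv <- solve(T)
  P <- .poly_shift(.ma_poly(sys, 1), eq$x[1], eq$x[2])
  Q <- .poly_shift(.ma_poly(sys, 2), eq$x[1], eq$x[2])
  Pz <- .poly_linsub(P, T)
  Qz <- .poly_linsub(Q, T)
  Fc <- Tinv[1, 1] * Pz + Tinv[1, 2] * Qz   # f(z1, z2)
  Gc <- Tinv[2, 1] * Pz + Tinv[2, 2] * Qz   # g(z1, z2)
  fxx <- 2 * Fc[3, 1]; fxy <- Fc[2, 2]; fyy <- 2 * Fc[1, 3]
  gxx <- 2 * Gc[3, 1]; gxy <- Gc[2, 2]; gyy <- 2 * Gc[1, 3]
  L1 <- (1 / (16 * w)) *
    (fxy * (fxx + fyy) - gxy * (gxx + gyy) - fxx * gxx + fyy * gyy)
  K <- max(abs(c(fxx, fxy, fyy, gxx, gxy, gyy)))
  L1s <- if (K > 0) L1 * w / K ^ 2 else 0
  list(L1 = L1, L1_scaled = L1s, omega = w, x = eq$x,
       supercritical = is.finite(L1s) && L1s < -resolution,
       vertical_candidate = abs(L1s) < resolution)
}

# successive return radii of the orbit from x0 about the planar equilibrium
.return_radii <- function(sys, xbar, x0, t_end, n_out = 40000) {
  traj <- simulate_system(sys, x0, t_end, n_out = n_out, rtol = 1e-10, atol = 1e-13)
  Y <- sweep(as.matrix(traj[, -1, drop = FALSE]), 2, xbar)
  y1 <- Y[, 1]; y2 <- Y[, 2]
  idx <- which(y2[-length(y2)] < 0 & y2[-1] >= 0 & y1[-1] > 0)
  radii <- numeric(0)
  for (k in idx) {
    lam <- -y2[k] / (y2[k + 1] - y2[k])
    radii <- c(radii, y1[k] + lam * (y1[k + 1] - y1[k]))
  }
  radii
}

#' Numerical corroboration of a supercritical Hopf bifurcation
#'
#' For each supplied value of the bifurcating rate constant on the unstable
#' (tr J > 0) side, integrates onto the attracting limit cycle and estimates
#' its amplitude from the converged Poincare return radius about the
#' equilibrium. For a supercritical bifurcation the amplitudes decrease to 0
#' as the parameter approaches the critical value.
#'
#' @param net a `crn_network`, n = 2, m = 3.
#' @param param index of the bifurcating rate constant.
#' @param values parameter values on the unstable side.
#' @param kappa base rate constants.
#' @param t_end integration horizon per value.
#' @return data.frame with `value`, `tr` (trace at equilibrium), `amplitude`,
#'   `converged` (relative spread of the last return radii).
#' @export
hopf_side_check <- function(net, param = 1, values, kappa = rep(1, net$m),
                            t_end = 4000) {
  out <- data.frame(value = values, tr = NA_real_, amplitude = NA_real_,
                    converged = NA_real_)
  for (i in seq_along(values)) {
    kap <- kappa; kap[param] <- values[i]
    sys <- mass_action(net, kap)
    eq <- positive_equilibria(sys)
    if (!eq$exists) next
    pdt <- planar_det_tr(sys, eq)
    out$tr[i] <- pdt$tr
    x0 <- eq$x * c(1.05, 1.0)
    radii <- .return_radii(sys, eq$x, x0, t_end)
    if (length(radii) < 5) next
    tail_r <- radii[seq(max(1, length(radii) - 4), length(radii))]
    out$amplitude[i] <- mean(tail_r)
    out$converged[i] <- (max(tail_r) - min(tail_r)) / mean(tail_r)
  }
  out
}
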