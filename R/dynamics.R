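# Mass-action dynamics: vector field, Jacobian, positive equilibria,
# conserved quantities, simulation and periodicity detection.

#' Mass-action system: a network plus positive rate constants
#' @param net a `crn_network`.
#' @param kappa positive rate constants, length m (recycled if length 1).
#' @return object of class `crn_massaction`.
#' @export
mass_action <- function(net, kappa = 1) {
  kappa <- rep_len(as.numeric(kappa), net$m)
  stopifnot(all(kappa > 0))
  structure(list(net = net, kappa = kappa,
                 Gl = net$source, G = net$target - net$source),
            class = "crn_massaction")
}

#' @export
print.crn_massaction <- function(x, ...) {
  cat("mass-action system with kappa =", paste(signif(x$kappa, 6), collapse = ", "), "\n")
  print(x$net)
  invisible(x)
}

# monomial rates kappa_j * x^(source column j); 0^0 = 1
.rates <- function(sys, x) {
  v <- numeric(sys$net$m)
  for (j in seq_len(sys$net$m)) {
    a <- sys$Gl[, j]
    v[j] <- sys$kappa[j] * prod(x[a > 0] ^ a[a > 0])
  }
  v
}

#' Mass-action vector field dx/dt = Gamma (kappa o x^(Gl^T))
#' @param sys a `crn_massaction`.
#' @param x nonnegative state vector, length n.
#' @return numeric vector of length n.
#' @export
rhs <- function(sys, x) {
  stopifnot(length(x) == sys$net$n)
  as.numeric(sys$G %*% .rates(sys, x))
}

#' Analytic Jacobian of the mass-action vector field
#' @param sys a `crn_massaction`.
#' @param x positive state vector.
#' @return n x n matrix Gamma diag(rates) Gl^T diag(1/x).
#' @export
ma_jacobian <- function(sys, x) {
  stopifnot(all(x > 0))
  r <- .rates(sys, x)
  sys$G %*% (r * t(sys$Gl * rep(1 / x, sys$net$m)))
}

#' Positive equilibria of a three-reaction rank-two mass-action system
#'
#' At a positive equilibrium, kappa o x^(Gl^T) = mu u where u spans ker Gamma
#' and mu has the common sign of u. Taking logs gives the linear system
#' a_j . log(x) - log|mu| = log(|u_j| / kappa_j), solved exactly in the
#' least-squares sense with consistency check. For two species with affinely
#' independent sources this has a unique solution (the unique positive
#' equilibrium); for n >= 3 it returns an affine family in log coordinates
#' (a parametrized variety of equilibria).
#'
#' @param sys a `crn_massaction` with m = 3, rank 2, dynamically nontrivial.
#' @return object of class `crn_equilibria`: list with `x` (a positive
#'   equilibrium), `mu`, `u`, `log_directions` (n x k matrix spanning the
#'   solution family in log x; k = 0 means unique), `residual`, `exists`.
#' @export
positive_equilibria <- function(sys) {
  net <- sys$net
  if (net$m != 3) stop("positive_equilibria requires exactly 3 reactions")
  u <- kernel_sign_vector(net)
  if (!(all(u > 0) || all(u < 0))) {
    return(structure(list(exists = FALSE, u = u,
                          reason = "kernel vector not strictly one-signed (dynamically trivial)"),
                     class = "crn_equilibria"))
  }
  A <- cbind(t(sys$Gl), -1)                    # unknowns (log x, log |mu|)
  b <- log(abs(u) / sys$kappa)
  qrA <- qr(A)
  sol <- qr.coef(qrA, b)
  sol[is.na(sol)] <- 0
  # consistency: residual of the least-squares solution must vanish
  res <- max(abs(A %*% sol - b))
  if (res > 1e-8) {
    return(structure(list(exists = FALSE, u = u,
                          reason = "log-linear system inconsistent (no positive equilibrium)"),
                     class = "crn_equilibria"))
  }
  ns <- .numeric_nullspace(A)
  # directions in log x only (drop the log mu coordinate)
  k <- ncol(ns)
  x <- exp(unname(sol[seq_len(net$n)]))
  mu <- sign(u[1]) * exp(unname(sol[net$n + 1]))
  structure(list(exists = TRUE, x = as.numeric(x), mu = mu, u = u,
                 log_solution = sol,
                 log_directions = ns,
                 unique = (k == 0),
                 residual = max(abs(rhs(sys, x)))),
            class = "crn_equilibria")
}

.numeric_nullspace <- function(A, tol = 1e-10) {
  s <- svd(A, nu = 0, nv = ncol(A))
  d <- c(s$d, rep(0, ncol(A) - length(s$d)))
  s$v[, d < tol * max(d, 1), drop = FALSE]
}

#' @export
print.crn_equilibria <- function(x, ...) {
  if (!x$exists) {
    cat("no positive equilibrium:", x$reason, "\n")
  } else if (x$unique) {
    cat("unique positive equilibrium:", paste(signif(x$x, 8), collapse = ", "),
        " (mu =", signif(x$mu, 8), ")\n")
  } else {
    cat("equilibrium family through", paste(signif(x$x, 8), collapse = ", "),
        sprintf("(%d log-space direction(s)); mu = %s\n",
                ncol(x$log_directions), signif(x$mu, 8)))
  }
  invisible(x)
}

#' Intersect an equilibrium family with a stoichiometric class
#'
#' For n >= 3 the positive equilibria form a variety (affine in log
#' coordinates); this finds a point of the variety on the stoichiometric
#' class of `x0` by Newton iteration on the conserved linear coordinates.
#' @param sys a `crn_massaction` (m = 3, rank 2).
#' @param x0 positive point defining the class (x0 + im Gamma).
#' @param eq optional result of [positive_equilibria()].
#' @param starts number of starting parameter values tried.
#' @return matrix of equilibria found on the class (0 rows if none).
#' @export
equilibria_on_class <- function(sys, x0, eq = positive_equilibria(sys), starts = 9) {
  if (!eq$exists) return(matrix(numeric(0), 0, sys$net$n))
  W <- nullspace_exact(t(sys$G))  # columns: conserved linear coordinates
  if (ncol(W) == 0 || eq$unique) {
    # unique equilibrium: on the class iff conserved coords match
    ok <- ncol(W) == 0 || max(abs(t(W) %*% (eq$x - x0))) < 1e-8
    return(if (ok) matrix(eq$x, 1) else matrix(numeric(0), 0, sys$net$n))
  }
  n <- sys$net$n
  D <- eq$log_directions[seq_len(n), , drop = FALSE]
  k <- ncol(D)
  target <- as.numeric(t(W) %*% x0)
  fun <- function(t) as.numeric(t(W) %*% exp(log(eq$x) + D %*% t)) - target
  sols <- NULL
  for (s in seq_len(starts)) {
    t0 <- rep(seq(-4, 4, length.out = starts)[s], k)
    t_cur <- t0
    ok <- FALSE
    for (it in 1:80) {
      f <- fun(t_cur)
      if (max(abs(f)) < 1e-12 * max(1, max(abs(target)))) { ok <- TRUE; break }
      # numerical Jacobian
      J <- vapply(seq_len(k), function(i) {
        h <- 1e-6 * max(1, abs(t_cur[i]))
        tp <- t_cur; tp[i] <- tp[i] + h
        (fun(tp) - f) / h
      }, numeric(length(target)))
      step <- tryCatch(qr.solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      step <- pmin(pmax(step, -2), 2)
      t_cur <- t_cur + step
    }
    if (ok) {
      xs <- exp(log(eq$x) + as.numeric(D %*% t_cur))
      if (is.null(sols) || all(apply(sols, 1, function(r) max(abs(r - xs)) > 1e-6 * max(xs)))) {
        sols <- rbind(sols, xs)
      }
    }
  }
  if (is.null(sols)) matrix(numeric(0), 0, n) else sols
}

#' Conserved quantities of a mass-action system
#'
#' Always returns the linear first integrals (integer basis of the left
#' kernel of Gamma). When the system is of Lotka--Volterra type without
#' diagonal terms (every reaction changes only species appearing in its
#' source, sources at most bimolecular, no 2X_i -> ... changing X_i), it also
#' returns the classical logarithmic first integral: for two species
#' r1 log y - r2 log x + b12 y - b21 x; for n species with no linear part,
#' sum_i w_i log x_i where w spans the left kernel of the interaction matrix.
#'
#' @param sys a `crn_massaction`.
#' @return list of first integrals; each has `kind` ("linear", "log", or
#'   "mixed"), coefficient fields, and `value(x)`, a function evaluating it.
#' @export
conserved_quantities <- function(sys) {
  out <- list()
  W <- nullspace_exact(t(sys$G))
  for (j in seq_len(ncol(W))) {
    w <- W[, j]
    out[[length(out) + 1]] <- list(kind = "linear", coefficients = w,
                                   value = local({
                                     w0 <- w
                                     function(x) sum(w0 * x)
                                   }))
  }
  lv <- .lv_structure(sys)
  if (!is.null(lv)) {
    n <- sys$net$n
    if (n == 2) {
      r <- lv$r; B <- lv$B
      a <- c(-B[2, 1], B[1, 2])     # linear part coefficients
      b <- c(-r[2], r[1])           # log part coefficients
      out[[length(out) + 1]] <- list(kind = "mixed", linear = a, log = b,
        value = local({
          a0 <- a; b0 <- b
          function(x) sum(a0 * x) + sum(b0 * log(x))
        }))
    } else if (all(abs(lv$r) < 1e-12)) {
      wl <- .numeric_nullspace(t(lv$B))
      for (j in seq_len(ncol(wl))) {
        w <- wl[, j]
        out[[length(out) + 1]] <- list(kind = "log", log = w,
          value = local({
            w0 <- w
            function(x) sum(w0 * log(x))
          }))
      }
    }
  }
  out
}

# Lotka-Volterra-without-diagonal structure: dx_i/dt = x_i (r_i + sum_k B_ik x_k)
# with B_ii = 0. Returns list(r, B) or NULL.
.lv_structure <- function(sys) {
  n <- sys$net$n
  Gl <- sys$Gl; G <- sys$G
  if (max(colSums(Gl)) > 2) return(NULL)
  r <- numeric(n); B <- matrix(0, n, n)
  for (j in seq_len(sys$net$m)) {
    a <- Gl[, j]
    for (i in which(G[, j] != 0)) {
      if (a[i] < 1) return(NULL)        # monomial not divisible by x_i
      rest <- a; rest[i] <- rest[i] - 1
      if (rest[i] > 0) return(NULL)     # diagonal term x_i^2
      k <- which(rest > 0)
      if (length(k) == 0) {
        r[i] <- r[i] + G[i, j] * sys$kappa[j]
      } else {
        B[i, k] <- B[i, k] + G[i, j] * sys$kappa[j]
      }
    }
  }
  list(r = r, B = B)
}

#' Simulate a mass-action system
#'
#' Adaptive Dormand--Prince integration (deSolve, method "ode45") with tight
#' default tolerances: center orbits are neutrally stable and loose
#' tolerances would turn them into spurious spirals. The integration is
#' interior: a trajectory leaving the positive orthant beyond tolerance is an
#' error, and integrator failure before `t_end` (finite-time blow-up, e.g.
#' for repelling systems) is reported via the `blowup` attribute.
#'
#' @param sys a `crn_massaction`.
#' @param x0 positive initial state.
#' @param t_end end time.
#' @param n_out number of output points.
#' @param rtol,atol integrator tolerances.
#' @return data.frame (class `crn_trajectory`) with column `time` and one
#'   column per species; attributes `blowup`, `drift` (max drift of each
#'   linear first integral).
#' @export
simulate_system <- function(sys, x0, t_end, n_out = 2000,
                            rtol = 1e-9, atol = 1e-12, maxsteps = 1e5,
                            state_cap = 1e8) {
  stopifnot(all(x0 > 0), t_end > 0)
  times <- seq(0, t_end, length.out = n_out)
  f <- function(t, y, p) {
    if (any(abs(y) > state_cap)) stop("state cap exceeded (finite-time blow-up)")
    list(rhs(sys, y))
  }
  # integrate in chunks so that finite-time blow-up (solutions of these
  # quadratic systems may be unbounded) is detected and reported quickly
  n_chunks <- max(1L, min(32L, n_out %/% 8L))
  bounds <- unique(round(seq(1L, n_out, length.out = n_chunks + 1L)))
  rows <- list()
  y <- stats::setNames(x0, sys$net$species)
  blowup <- FALSE
  for (ci in seq_len(length(bounds) - 1L)) {
    seg <- times[bounds[ci]:bounds[ci + 1L]]
    if (length(seg) < 2) next
    res <- suppressWarnings(tryCatch(
      deSolve::ode(y = y, times = seg, func = f, parms = NULL,
                   method = "ode45", rtol = rtol, atol = atol,
                   maxsteps = maxsteps),
      error = function(e) NULL))
    if (is.null(res)) { blowup <- TRUE; break }
    res <- as.data.frame(res)
    done <- stats::complete.cases(res)
    if (!all(done)) blowup <- TRUE
    res <- res[done, , drop = FALSE]
    if (nrow(res) == 0 || any(abs(res[nrow(res), -1]) > state_cap)) {
      blowup <- TRUE
    }
    rows[[length(rows) + 1L]] <- if (ci == 1L) res else res[-1, , drop = FALSE]
    if (blowup) break
    y <- stats::setNames(as.numeric(res[nrow(res), -1]), sys$net$species)
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) < 2) {
    stop("integration failed immediately (blow-up or invalid initial state)")
  }
  states <- as.matrix(res[, -1, drop = FALSE])
  if (min(states) < -1e-7 * max(abs(states))) {
    stop("trajectory left the positive orthant")
  }
  W <- nullspace_exact(t(sys$G))
  drift <- if (ncol(W) > 0) {
    vals <- states %*% W
    apply(vals, 2, function(v) max(abs(v - v[1])))
  } else numeric(0)
  names(res)[1] <- "time"
  structure(res, blowup = blowup, drift = drift,
            class = c("crn_trajectory", "data.frame"))
}

#' Detect periodicity of a trajectory by a Poincare return map
#'
#' Restricts the flow to the two-dimensional stoichiometric class through
#' `x0` (coordinates given by an orthonormal basis of im Gamma), takes the
#' section through `x0` normal to the initial flow direction, and tests
#' whether the first return lands within `tol` (relative to the orbit
#' amplitude) of `x0`. Closure within `tol` reports periodic; a clear
#' monotone drift of successive returns reports non-periodic; anything else
#' is inconclusive (`NA`): numerical closeness alone never proves
#' non-periodicity.
#'
#' @param sys a `crn_massaction` of rank 2.
#' @param x0 positive initial state (not an equilibrium).
#' @param t_end integration horizon.
#' @param tol relative closure tolerance.
#' @param n_out sampling resolution.
#' @return list(periodic, period, closure_error, return_radii).
#' @export
detect_periodicity <- function(sys, x0, t_end = 200, tol = 1e-4, n_out = 20000) {
  f0 <- rhs(sys, x0)
  if (max(abs(f0)) < 1e-12) {
    return(list(periodic = NA, period = NA_real_,
                closure_error = NA_real_, reason = "x0 is an equilibrium"))
  }
  Bm <- svd(sys$G)
  r <- sum(Bm$d > 1e-10 * max(Bm$d))
  if (r != 2) stop("detect_periodicity requires rank 2")
  B <- Bm$u[, 1:2, drop = FALSE]
  traj <- simulate_system(sys, x0, t_end, n_out = n_out)
  states <- as.matrix(traj[, -1, drop = FALSE])
  tt <- traj$time
  Y <- sweep(states, 2, x0) %*% B          # class coordinates, x0 at origin
  v0 <- as.numeric(t(B) %*% f0)
  v0 <- v0 / sqrt(sum(v0^2))
  s <- Y %*% v0
  amp <- max(sqrt(rowSums(Y^2)))
  # upward crossings of the section s = 0 (same direction as the start)
  idx <- which(s[-length(s)] < 0 & s[-1] >= 0)
  radii <- numeric(0); times <- numeric(0)
  for (k in idx) {
    w <- s[k + 1] - s[k]
    lam <- if (w == 0) 0 else -s[k] / w
    yc <- Y[k, ] + lam * (Y[k + 1, ] - Y[k, ])
    radii <- c(radii, sqrt(sum(yc^2)))
    times <- c(times, tt[k] + lam * (tt[k + 1] - tt[k]))
  }
  if (length(radii) == 0) {
    # no return: either convergence to an equilibrium or escape
    fe <- rhs(sys, as.numeric(states[nrow(states), ]))
    if (sqrt(sum(fe^2)) < 1e-5 * sqrt(sum(f0^2))) {
      return(list(periodic = FALSE, period = NA_real_, closure_error = NA_real_,
                  reason = "converged towards an equilibrium (no return)",
                  return_radii = radii))
    }
    return(list(periodic = NA, period = NA_real_, closure_error = NA_real_,
                reason = "no return to the section within t_end",
                return_radii = radii))
  }
  closure <- radii[1] / amp
  periodic <- NA
  if (closure < tol) {
    periodic <- TRUE
  } else if (length(radii) >= 2) {
    if (closure > 100 * tol && (all(diff(radii) > 0) || all(diff(radii) < 0)) &&
        abs(radii[length(radii)] - radii[1]) > 10 * tol * amp) {
      periodic <- FALSE  # systematic outward/inward spiral
    }
  }
  list(periodic = periodic, period = times[1], closure_error = closure,
       return_radii = radii)
}
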