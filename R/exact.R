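# Exact rational linear algebra over small integer matrices.
#
# All structural predicates in this package (rank, kernels, the positive-kernel
# linear program) are decided in exact arithmetic so that the censuses are
# exact. Rationals are stored as numerator/denominator pairs in doubles; every
# quantity arising from the small integer matrices handled here stays far
# below 2^53, so double arithmetic on the integer parts is exact.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- a %% b
    a <- t
    b[is.na(b)] <- 0
  }
  a
}

.gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0) return(1)
  g <- v[1]
  for (x in v[-1]) g <- .gcd(g, x)
  g
}

.lcm <- function(a, b) ifelse(a == 0 | b == 0, 0, abs(a / .gcd(a, b) * b))

# reduce num/den entrywise; den > 0
.qreduce <- function(num, den) {
  stopifnot(all(den != 0))
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- .gcd(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

# Reduced row echelon form of a rational matrix (given as num/den matrices).
# Returns list(num, den, pivots).
.rref_q <- function(num, den = NULL) {
  num <- as.matrix(num)
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  den <- as.matrix(den)
  nr <- nrow(num); nc <- ncol(num)
  pivots <- integer(0)
  r <- 1L
  for (col in seq_len(nc)) {
    if (r > nr) break
    pr <- which(num[r:nr, col] != 0)
    if (length(pr) == 0) next
    p <- r + pr[1] - 1L
    if (p != r) {
      num[c(r, p), ] <- num[c(p, r), ]
      den[c(r, p), ] <- den[c(p, r), ]
    }
    # scale row r so pivot = 1
    pn <- num[r, col]; pd <- den[r, col]
    q <- .qreduce(num[r, ] * pd, den[r, ] * pn)
    num[r, ] <- q$num; den[r, ] <- q$den
    # eliminate other rows
    for (i in seq_len(nr)) {
      if (i == r || num[i, col] == 0) next
      f_n <- num[i, col]; f_d <- den[i, col]
      # row_i <- row_i - f * row_r
      nn <- num[i, ] * f_d * den[r, ] - f_n * num[r, ] * den[i, ]
      dd <- den[i, ] * f_d * den[r, ]
      q <- .qreduce(nn, dd)
      num[i, ] <- q$num; den[i, ] <- q$den
    }
    pivots <- c(pivots, col)
    r <- r + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

# Exact rank of an integer (or rational) matrix.
rank_exact <- function(M) {
  if (length(M) == 0 || nrow(as.matrix(M)) == 0 || ncol(as.matrix(M)) == 0) return(0L)
  length(.rref_q(as.matrix(M))$pivots)
}

# Exact determinant of a small integer matrix (Bareiss fraction-free).
det_exact <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(n == ncol(M))
  if (n == 0) return(1)
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1)) {
    if (M[k, k] == 0) {
      p <- which(M[(k + 1):n, k] != 0)
      if (length(p) == 0) return(0)
      p <- k + p[1]
      M[c(k, p), ] <- M[c(p, k), ]
      sign <- -sign
    }
    for (i in (k + 1):n) {
      for (j in (k + 1):n) {
        M[i, j] <- (M[i, j] * M[k, k] - M[i, k] * M[k, j]) / prev
      }
      M[i, k] <- 0
    }
    prev <- M[k, k]
  }
  sign * M[n, n]
}

# Integer basis of the (right) null space of an integer matrix.
# Returns a matrix with ncol(M)-rank columns, each an integer vector.
nullspace_exact <- function(M) {
  M <- as.matrix(M)
  nc <- ncol(M)
  rr <- .rref_q(M)
  piv <- rr$pivots
  free <- setdiff(seq_len(nc), piv)
  if (length(free) == 0) return(matrix(0, nc, 0))
  B <- matrix(0, nc, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    # x_f = 1, x_piv[i] = -rref[i, f]
    col_n <- numeric(nc); col_d <- rep(1, nc)
    col_n[f] <- 1
    for (i in seq_along(piv)) {
      col_n[piv[i]] <- -rr$num[i, f]
      col_d[piv[i]] <- rr$den[i, f]
    }
    l <- 1
    for (d in col_d) l <- .lcm(l, d)
    v <- col_n * (l / col_d)
    g <- .gcd_vec(v)
    B[, k] <- v / g
  }
  B
}

# Exact solve of A x = b for square nonsingular integer A via Cramer's rule.
# Returns list(num, den) (common denominator = det).
.solve_cramer <- function(A, b) {
  d <- det_exact(A)
  if (d == 0) return(NULL)
  n <- length(b)
  num <- numeric(n)
  for (i in seq_len(n)) {
    Ai <- A
    Ai[, i] <- b
    num[i] <- det_exact(Ai)
  }
  list(num = num, den = rep(d, n))
}

# Exact feasibility of {x : A x = b, x >= 0} with integer A, b, by
# basic-solution enumeration (sound and complete: the polyhedron is pointed,
# so if it is nonempty it has a vertex, i.e. a basic feasible solution).
# Returns a rational solution list(num, den) or NULL if infeasible.
.lp_standard_feasible <- function(A, b) {
  A <- as.matrix(A)
  m <- nrow(A); k <- ncol(A)
  # reduce to independent rows; check consistency
  aug <- cbind(A, b)
  rr <- .rref_q(aug)
  if ((k + 1) %in% rr$pivots) return(NULL) # inconsistent
  r <- length(rr$pivots)
  if (r == 0) {
    # A = 0: feasible iff b = 0 (checked above); x = 0 works
    return(list(num = rep(0, k), den = rep(1, k)))
  }
  # integer-scale the reduced rows
  R <- matrix(0, r, k); s <- numeric(r)
  for (i in seq_len(r)) {
    dens <- c(rr$den[i, ])
    l <- 1
    for (d in dens) l <- .lcm(l, d)
    row <- rr$num[i, ] * (l / rr$den[i, ])
    R[i, ] <- row[seq_len(k)]
    s[i] <- row[k + 1]
  }
  for (J in utils::combn(k, r, simplify = FALSE)) {
    RJ <- R[, J, drop = FALSE]
    sol <- .solve_cramer(RJ, s)
    if (is.null(sol)) next
    if (all(sol$num * sign(sol$den) >= 0)) {
      num <- rep(0, k); den <- rep(1, k)
      num[J] <- sol$num; den[J] <- sol$den
      q <- .qreduce(num, den)
      return(q)
    }
  }
  NULL
}

# Scale a rational vector (num/den) to a primitive integer vector.
.q_to_int <- function(q) {
  l <- 1
  for (d in q$den) l <- .lcm(l, d)
  v <- q$num * (l / q$den)
  g <- .gcd_vec(v)
  if (g == 0) g <- 1
  v / g
}
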