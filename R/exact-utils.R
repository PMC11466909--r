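# Small exact-arithmetic helpers used throughout the R layer.
#
# All quantities handled here (stoichiometric coefficients, kernel rays,
# cone fingerprints, 4x4 inverses) are tiny integers or ratios of tiny
# integers, so they are represented exactly in doubles.  Every operation
# guards against leaving the exactly-representable integer range; anything
# that could genuinely grow (Sturm sequences, focal values, algebraic sign
# evaluation) lives in the C++ kernel instead.

.INT_GUARD <- 2^51

#' @noRd
chk_int <- function(x) {
  if (any(!is.finite(x)) || any(abs(x) > .INT_GUARD) || any(x != round(x)))
    stop("exact integer arithmetic left the guarded range", call. = FALSE)
  x
}

#' Greatest common divisor (nonnegative), vectorised pairwise reduce
#' @noRd
gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- a %% b
    b[t == 0] <- 0
    a <- t
  }
  a
}

#' @noRd
gcd_vec <- function(v) {
  g <- 0
  for (x in v) g <- gcd2(g, x)
  g
}

#' Reduce an integer vector to its primitive form (gcd 1, first nonzero > 0
#' unless `keep_sign` asks to preserve orientation).
#' @noRd
primitive <- function(v, keep_sign = TRUE) {
  chk_int(v)
  g <- gcd_vec(v)
  if (g == 0) return(v)
  v <- v / g
  if (!keep_sign) {
    nz <- which(v != 0)[1]
    if (length(nz) && v[nz] < 0) v <- -v
  }
  v
}

# -- rational scalars as c(num, den), den > 0 ---------------------------------

#' @noRd
rat <- function(num, den = 1) {
  chk_int(c(num, den))
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd2(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  c(num, den)
}

#' @noRd
rat_add <- function(a, b) rat(chk_int(a[1] * b[2] + b[1] * a[2]), chk_int(a[2] * b[2]))
#' @noRd
rat_mul <- function(a, b) rat(chk_int(a[1] * b[1]), chk_int(a[2] * b[2]))
#' @noRd
rat_sub <- function(a, b) rat_add(a, c(-b[1], b[2]))
#' @noRd
rat_div <- function(a, b) {
  if (b[1] == 0) stop("division by zero rational")
  rat_mul(a, c(b[2], b[1]))
}
#' @noRd
rat_eq <- function(a, b) a[1] * b[2] == b[1] * a[2]

# -- exact linear algebra on small integer/rational matrices ------------------

#' Exact rank of an integer matrix by fraction-free Gaussian elimination.
#' @noRd
int_rank <- function(M) {
  M <- matrix(chk_int(as.numeric(M)), nrow = nrow(M))
  r <- 0
  nr <- nrow(M); nc <- ncol(M)
  row <- 1
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(M[row:nr, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    for (i in seq_len(nr)) {
      if (i != row && M[i, col] != 0) {
        # fraction-free row update, then strip common content to limit growth
        M[i, ] <- chk_int(M[i, ] * M[row, col] - M[row, ] * M[i, col])
        g <- gcd_vec(M[i, ])
        if (g > 1) M[i, ] <- M[i, ] / g
      }
    }
    row <- row + 1
    r <- r + 1
  }
  r
}

#' Exact kernel basis (rational, returned as primitive integer columns) of an
#' integer matrix, via reduced row echelon form over Q (doubles stay exact:
#' entries are ratios of small determinants).
#' @noRd
int_kernel <- function(M) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  nr <- nrow(M); nc <- ncol(M)
  # RREF with rational arithmetic via common-denominator scaling: keep rows
  # as integer vectors plus implicit positive scaling (irrelevant for kernel).
  R <- M
  pivots <- integer(0)
  row <- 1
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(R[row:nr, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1
    if (piv != row) R[c(piv, row), ] <- R[c(row, piv), ]
    for (i in seq_len(nr)) {
      if (i != row && R[i, col] != 0) {
        R[i, ] <- chk_int(R[i, ] * R[row, col] - R[row, ] * R[i, col])
        g <- gcd_vec(R[i, ])
        if (g > 1) R[i, ] <- R[i, ] / g
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1
  }
  free <- setdiff(seq_len(nc), pivots)
  if (!length(free)) return(matrix(0, nc, 0))
  ker <- matrix(0, nc, length(free))
  for (k in seq_along(free)) {
    fc <- free[k]
    v <- numeric(nc)
    v[fc] <- 1
    # back-substitute pivot variables: R[i, pivots[i]] * v[pivots[i]] = -R[i, fc]
    # solve exactly with a common denominator (product of pivot entries)
    den <- 1
    for (i in seq_along(pivots)) den <- chk_int(den * R[i, pivots[i]])
    v <- v * den
    for (i in seq_along(pivots)) {
      v[pivots[i]] <- chk_int(-R[i, fc] * den / R[i, pivots[i]])
    }
    ker[, k] <- primitive(v)
  }
  ker
}

#' Exact inverse of a small integer matrix, returned as list(num =, den =)
#' with num an integer matrix and den a positive integer (adjugate form).
#' @noRd
int_inverse <- function(M) {
  M <- matrix(chk_int(as.numeric(M)), nrow = nrow(M))
  n <- nrow(M)
  stopifnot(n == ncol(M))
  d <- int_det(M)
  if (d == 0) stop("matrix is singular")
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    minor <- M[-i, -j, drop = FALSE]
    adj[j, i] <- (-1)^(i + j) * int_det(minor)
  }
  if (d < 0) { adj <- -adj; d <- -d }
  list(num = adj, den = d)
}

#' Exact determinant of a small integer matrix (cofactor expansion; n <= 5).
#' @noRd
int_det <- function(M) {
  n <- nrow(M)
  if (n == 0) return(1)
  if (n == 1) return(M[1, 1])
  if (n == 2) return(chk_int(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]))
  s <- 0
  for (j in seq_len(n)) {
    if (M[1, j] == 0) next
    s <- chk_int(s + (-1)^(1 + j) * M[1, j] * int_det(M[-1, -j, drop = FALSE]))
  }
  s
}
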