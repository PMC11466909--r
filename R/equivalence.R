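# Diagonal equivalence (positive rescaling of species and reactions) and
# the natural-coordinates reduction of (n, m, n) networks.

#' Are two networks diagonally equivalent?
#'
#' Two mass-action networks with the same reactant matrix (up to species and
#' reaction permutation) are diagonally equivalent if
#' `Gamma2 = D1 Gamma1 D2` for positive diagonal `D1`, `D2` after permuting
#' reactions within equal reactant complexes.  Diagonally equivalent
#' networks are smoothly equivalent, so all bifurcation classifications
#' transfer.  The search is over both species permutations and all
#' reactant-preserving reaction bijections; the multiplicative system is
#' solved exactly (column ratio constraints on d1/d2).
#'
#' @param net1,net2 planar [crn] objects or census representatives.
#' @return list with `equivalent` and, when `TRUE`, a `witness` containing
#'   the species permutation, reaction permutation and the ratio d1/d2
#'   constraint class.
#' @export
diagonally_equivalent <- function(net1, net2) {
  g1 <- as_netmats(net1); g2 <- as_netmats(net2)
  if (ncol(g1$gamma) != ncol(g2$gamma))
    return(list(equivalent = FALSE))
  m <- ncol(g1$gamma)
  for (swap in c(FALSE, TRUE)) {
    R1 <- g1$reactant; G1 <- g1$gamma
    if (swap) { R1 <- R1[2:1, , drop = FALSE]; G1 <- G1[2:1, , drop = FALSE] }
    k1 <- apply(R1, 2, paste, collapse = ",")
    k2 <- apply(g2$reactant, 2, paste, collapse = ",")
    if (!identical(sort(k1), sort(k2))) next
    for (perm in reactant_matchings(k1, k2)) {
      # need gamma2[, j] = diag(d) G1[, perm[j]] e_j with d, e > 0
      ok <- TRUE
      ratio <- NULL  # d1/d2 as c(num, den)
      for (j in seq_len(m)) {
        a <- G1[, perm[j]]; b <- g2$gamma[, j]
        if (any((a == 0) != (b == 0)) || any(sign(a) != sign(b))) { ok <- FALSE; break }
        if (all(a != 0)) {
          # (b1/a1) / (b2/a2) = d1/d2
          r <- rat(chk_int(b[1] * a[2]), chk_int(b[2] * a[1]))
          if (r[1] <= 0) { ok <- FALSE; break }
          if (is.null(ratio)) ratio <- r
          else if (!rat_eq(ratio, r)) { ok <- FALSE; break }
        }
      }
      if (ok)
        return(list(equivalent = TRUE,
                    witness = list(species_swap = swap, reaction_perm = perm,
                                   d1_over_d2 = ratio)))
    }
  }
  list(equivalent = FALSE)
}

as_netmats <- function(x) {
  if (inherits(x, "crn")) list(reactant = x$reactant, gamma = x$gamma)
  else list(reactant = x$reactant, gamma = x$gamma)
}

# all bijections net1 columns -> net2 columns preserving reactant complexes
reactant_matchings <- function(k1, k2) {
  m <- length(k1)
  groups2 <- split(seq_len(m), k2)
  groups1 <- split(seq_len(m), k1)
  perms_of <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  keys <- names(groups2)
  choice_sets <- lapply(keys, function(k) perms_of(groups1[[k]]))
  combos <- list(integer(0))
  for (s in seq_along(keys)) {
    new <- list()
    for (cmb in combos) for (p in choice_sets[[s]])
      new[[length(new) + 1]] <- c(cmb, p)
    combos <- new
  }
  lapply(combos, function(cmb) {
    perm <- integer(m)
    pos <- unlist(groups2[keys], use.names = FALSE)
    perm[pos] <- cmb
    perm
  })
}

#' Number of diagonal-equivalence classes of a set of networks
#'
#' Union-find over certified pairwise decisions, with invariant bucketing
#' (reactant multiset and column sign patterns, canonical under the species
#' swap) to avoid most comparisons.
#'
#' @param nets list of [crn] objects or census representatives.
#' @return integer number of classes.
#' @export
count_diagonal_classes <- function(nets) {
  n <- length(nets)
  if (n == 0) return(0L)
  bucket_key <- function(x) {
    g <- as_netmats(x)
    one <- function(R, G) {
      cols <- vapply(seq_len(ncol(G)), function(j)
        paste0(paste(R[, j], collapse = ","), ":", paste(sign(G[, j]), collapse = ",")),
        character(1))
      paste(sort(cols), collapse = "|")
    }
    min(one(g$reactant, g$gamma),
        one(g$reactant[2:1, , drop = FALSE], g$gamma[2:1, , drop = FALSE]))
  }
  keys <- vapply(nets, bucket_key, character(1))
  parent <- seq_len(n)
  find2 <- function(i) { r <- i; while (parent[r] != r) r <- parent[r]; r }
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) < 2) next
    for (a in 2:length(idx)) for (b in seq_len(a - 1)) {
      i <- idx[a]; j <- idx[b]
      ri <- find2(i); rj <- find2(j)
      if (ri == rj) next
      if (diagonally_equivalent(nets[[i]], nets[[j]])$equivalent)
        parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  length(unique(vapply(seq_len(n), find2, integer(1))))
}

#' Natural coordinates of an (n, m, n) network
#'
#' For a planar full-rank network with `rank [A|1] = n + 1`, completes
#' `[A | 1]` with integer columns `U` to a nonsingular matrix, inverts it
#' exactly, and partitions the inverse into `G` (n rows), `v` (one row) and
#' `W` (m - n - 1 rows).  The identity `I - A G = 1 v + U W` is verified
#' exactly, and the reduced field
#' `ydot = kappa^(G + 1v) o Gamma ((kappa^W)^U o y^A)` is returned
#' symbolically with outer parameters `o1, ..., on` and inner parameters
#' `w1, ...`.
#'
#' @param net a planar rank-two [crn]; @param U optional m x (m-n-1)
#'   integer completion (chosen automatically otherwise: smallest
#'   |determinant|, lexicographic tie-break over entries in -2..2).
#' @return list with `U`, `Gbar` (exact inverse as `num` matrix over `den`),
#'   `G`, `v`, `W` (rational matrices as num/den), `identity_ok`, and the
#'   reduced symbolic field (`mpoly` list).
#' @export
natural_coordinates <- function(net, U = NULL) {
  n <- nrow(net$gamma); m <- ncol(net$gamma)
  stopifnot(n == 2, net$rank == 2, m >= 3)
  A1 <- cbind(net$A, 1)
  if (int_rank(A1) != n + 1) stop("rank [A|1] must be n + 1")
  ncolU <- m - n - 1
  if (is.null(U)) {
    if (ncolU == 0) {
      U <- matrix(0, m, 0)
    } else {
      best <- NULL
      grid <- as.matrix(expand.grid(rep(list(-2:2), m)))
      ord <- order(rowSums(abs(grid)), apply(grid, 1, paste, collapse = ","))
      for (ri in ord) {
        cand <- matrix(grid[ri, ], ncol = 1)
        if (ncolU != 1) stop("automatic completion implemented for m = 4")
        d <- int_det(cbind(A1, cand))
        if (d != 0 && (is.null(best) || abs(d) < abs(best$d))) {
          best <- list(U = cand, d = d)
          if (abs(d) == 1) break
        }
      }
      U <- best$U
    }
  } else U <- as.matrix(U)
  Minv <- int_inverse(cbind(A1, U))
  den <- Minv$den
  Gbar <- Minv$num  # exact inverse is Gbar / den
  G <- Gbar[seq_len(n), , drop = FALSE]
  v <- Gbar[n + 1, , drop = FALSE]
  W <- Gbar[seq(n + 2, m), , drop = FALSE]
  # identity (den * I - A G) == 1 v + U W, all times den
  lhs <- den * diag(m) - net$A %*% G
  rhs <- matrix(1, m, 1) %*% v + U %*% W
  identity_ok <- all(lhs == rhs)
  # reduced symbolic field; exponents (kappa^W)^U are integral iff W U has
  # integer entries against den -- represent inner parameter exponents U_j
  vars <- c("X", "Y", paste0("o", seq_len(n)), "w1")
  field <- vector("list", n)
  for (i in seq_len(n)) {
    p <- mp_zero(vars)
    for (j in seq_len(m)) {
      if (net$gamma[i, j] == 0) next
      e <- numeric(length(vars))
      e[1:2] <- net$A[j, ]
      e[2 + i] <- 1  # o_i
      e[length(vars)] <- U[j, 1]
      p <- mp_add(p, mp_monomial(vars, e, net$gamma[i, j]))
    }
    field[[i]] <- p
  }
  list(U = U, Gbar_num = Gbar, Gbar_den = den, G = G, v = v, W = W,
       identity_ok = identity_ok, reduced_field = field, vars = vars)
}
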