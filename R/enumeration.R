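# Combinatorial enumeration of candidate networks and reduction modulo
# dynamical equivalence.
#
# This module generates the whole input universe of the census: planar
# networks with four reactions, bimolecular reactant complexes and
# bimolecular or trimolecular product complexes.  Networks are identified
# up to dynamical equivalence: two networks define the same family of
# mass-action ODE systems if and only if, for every reactant complex, the
# sets of achievable coefficient vectors (all strictly positive combinations
# of the reaction vectors on that reactant) agree.  For a single reaction
# per reactant this is the open ray of the reaction vector; for repeated
# reactants it is the relative interior of the spanned cone.  Keys are
# minimised over the species transposition X <-> Y.

.crnbif_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, .crnbif_cache)) assign(key, fn(), .crnbif_cache)
  get(key, .crnbif_cache)
}

#' All complexes on a species set up to a molecularity bound
#'
#' @param n_species number of species.
#' @param max_molecularity bound on the coefficient sum.
#' @return matrix with one column per complex (ordered by molecularity, then
#'   reverse-lexicographically), `n_species` rows.
#' @export
enumerate_complexes <- function(n_species, max_molecularity) {
  grid <- as.matrix(expand.grid(rep(list(0:max_molecularity), n_species)))
  grid <- grid[rowSums(grid) <= max_molecularity, , drop = FALSE]
  ord <- do.call(order, c(list(rowSums(grid)),
                          lapply(seq_len(ncol(grid)), function(j) -grid[, j])))
  out <- t(grid[ord, , drop = FALSE])
  rownames(out) <- NULL
  out
}

# the six bimolecular complexes on two species, census reactant order
bimol2 <- function() enumerate_complexes(2, 2)

# distinct primitive reaction rays (and a canonical representative product)
# available from each reactant complex under a product-molecularity cap
ray_table <- function(cap) {
  comps <- enumerate_complexes(2, cap)
  reactants <- bimol2()
  out <- vector("list", ncol(reactants))
  for (i in seq_len(ncol(reactants))) {
    cx <- reactants[, i]
    rays <- list()
    for (j in seq_len(ncol(comps))) {
      p <- comps[, j]
      if (all(p == cx)) next
      g <- primitive(p - cx)
      key <- paste(g, collapse = ",")
      cand <- list(product = p, mol = sum(p))
      if (is.null(rays[[key]]) || cand$mol < rays[[key]]$mol ||
          (cand$mol == rays[[key]]$mol &&
           paste(p, collapse = ",") < paste(rays[[key]]$product, collapse = ","))) {
        rays[[key]] <- c(cand, list(ray = g))
      }
    }
    keys <- sort(names(rays))
    out[[i]] <- list(
      reactant = cx,
      rays = vapply(keys, function(k) rays[[k]]$ray, numeric(2)),
      products = vapply(keys, function(k) rays[[k]]$product, numeric(2)))
  }
  out
}

rank2_planar <- function(gam) {
  m <- ncol(gam)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    if (gam[1, i] * gam[2, j] - gam[2, i] * gam[1, j] != 0) return(TRUE)
  FALSE
}

stiemke2 <- function(gam) {
  # strictly positive kernel vector exists (rank-2 planar case)
  for (j in seq_len(ncol(gam))) {
    for (sg in c(1, -1)) {
      y1 <- -sg * gam[2, j]; y2 <- sg * gam[1, j]
      d <- y1 * gam[1, ] + y2 * gam[2, ]
      if (all(d >= 0) && any(d > 0)) return(FALSE)
    }
  }
  TRUE
}

# canonical descriptor of the achievable-coefficient set of one reactant:
# strictly positive combinations of its reaction vectors
cone_descriptor <- function(rays) {
  rays <- unique(lapply(seq_len(ncol(rays)), function(j) primitive(rays[, j])))
  k <- length(rays)
  if (k == 1) return(list(type = "R", v = rays[[1]]))
  if (k == 2) {
    if (all(rays[[1]] == -rays[[2]]))
      return(list(type = "L", v = primitive(rays[[1]], keep_sign = FALSE)))
    vs <- rays[order(vapply(rays, function(v) paste(v, collapse = ","), ""))]
    return(list(type = "S", v = c(vs[[1]], vs[[2]])))
  }
  stop("cone descriptor with more than two distinct rays not supported")
}

descriptor_string <- function(d) paste0(d$type, "(", paste(d$v, collapse = ","), ")")

# dynamical-equivalence fingerprint of a planar network, minimised over the
# species swap
equivalence_key <- function(reactant, gamma) {
  one <- function(reac, gam) {
    key <- apply(reac, 2, paste, collapse = ",")
    parts <- vapply(sort(unique(key)), function(k) {
      cols <- which(key == k)
      paste0(k, ":", descriptor_string(cone_descriptor(gam[, cols, drop = FALSE])))
    }, character(1))
    paste(parts, collapse = "|")
  }
  k1 <- one(reactant, gamma)
  k2 <- one(reactant[2:1, , drop = FALSE], gamma[2:1, , drop = FALSE])
  min(k1, k2)
}

#' Census of (2,4,2) networks with four distinct reactant complexes
#'
#' Enumerates all dynamically nontrivial, rank-two, two-species,
#' four-reaction mass-action networks with bimolecular reactant complexes,
#' product molecularity bounded by `product_cap`, and four distinct reactant
#' complexes, reduced modulo dynamical equivalence (including the species
#' swap).  One canonical representative network is kept per class.
#'
#' @param product_cap 3 for the trimolecular census, 2 for the bimolecular.
#' @return list of class representatives; each has `reactant`, `gamma`,
#'   `product` (2 x 4 integer matrices) and `key`.
#' @export
census_distinct_reactants <- function(product_cap = 3) {
  memo(paste0("census_distinct_", product_cap), function() {
    rt <- ray_table(product_cap)
    combs <- utils::combn(6, 4)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    reps <- vector("list", 8000)
    nrep <- 0
    for (ci in seq_len(ncol(combs))) {
      rs <- combs[, ci]
      reac <- vapply(rs, function(i) rt[[i]]$reactant, numeric(2))
      nray <- vapply(rs, function(i) ncol(rt[[i]]$rays), integer(1))
      idx <- as.matrix(expand.grid(lapply(nray, seq_len)))
      for (row in seq_len(nrow(idx))) {
        gam <- matrix(0, 2, 4)
        prod <- matrix(0, 2, 4)
        for (t in 1:4) {
          gam[, t] <- rt[[rs[t]]]$rays[, idx[row, t]]
          prod[, t] <- rt[[rs[t]]]$products[, idx[row, t]]
        }
        if (!rank2_planar(gam)) next
        if (!stiemke2(gam)) next
        key <- equivalence_key(reac, gam)
        if (!exists(key, seen)) {
          assign(key, TRUE, seen)
          nrep <- nrep + 1
          reps[[nrep]] <- list(reactant = reac, gamma = gam, product = prod, key = key)
        }
      }
    }
    reps[seq_len(nrep)]
  })
}

# full reaction universe on two species: bimolecular reactant, product
# molecularity <= cap, product != reactant
reaction_universe <- function(cap = 3) {
  reactants <- bimol2()
  comps <- enumerate_complexes(2, cap)
  out <- list()
  for (i in seq_len(ncol(reactants))) {
    cx <- reactants[, i]
    for (j in seq_len(ncol(comps))) {
      p <- comps[, j]
      if (all(p == cx)) next
      out[[length(out) + 1]] <- list(
        reactant = cx, product = p, gamma = p - cx,
        ray = primitive(p - cx), reactant_id = i)
    }
  }
  out
}

#' Base census for the Andronov-Hopf analysis
#'
#' Enumerates, up to dynamical equivalence, the dynamically nontrivial,
#' rank-two, four-reaction networks with bimolecular reactants and
#' trimolecular products whose reactant complexes are not collinear, which
#' contain the reactant complex X+Y, contain the reaction 2X -> 3X or
#' 2Y -> 3Y, and have no redundant reactions.  (Reactant complexes may
#' repeat, unlike in [census_distinct_reactants].)  The filter "admits a
#' positive nondegenerate equilibrium" is applied by the caller.
#'
#' @return list of class representatives with `reactant`, `gamma`, `product`
#'   and `key`.
#' @export
census_hopf_base <- function() {
  memo("census_hopf_base", function() {
    U <- reaction_universe(3)
    nU <- length(U)
    is2x3x <- vapply(U, function(r) all(r$reactant == c(2, 0)) && all(r$product == c(3, 0)), logical(1))
    is2y3y <- vapply(U, function(r) all(r$reactant == c(0, 2)) && all(r$product == c(0, 3)), logical(1))
    id1 <- which(is2x3x); id2 <- which(is2y3y)
    xy_reac <- vapply(U, function(r) all(r$reactant == c(1, 1)), logical(1))

    subsets <- cbind(
      rbind(id1, utils::combn(setdiff(seq_len(nU), id1), 3)),
      rbind(id2, utils::combn(setdiff(seq_len(nU), c(id1, id2)), 3)))

    seen <- new.env(hash = TRUE, parent = emptyenv())
    reps <- vector("list", 3000)
    nrep <- 0
    for (ci in seq_len(ncol(subsets))) {
      ids <- subsets[, ci]
      if (!any(xy_reac[ids])) next
      reac <- vapply(ids, function(i) U[[i]]$reactant, numeric(2))
      # distinct reactant points, not collinear
      upts <- unique(t(reac))
      if (nrow(upts) < 3) next
      d <- sweep(upts[-1, , drop = FALSE], 2, upts[1, ])
      if (all(d[, 1] * d[1, 2] - d[, 2] * d[1, 1] == 0)) next
      gam <- vapply(ids, function(i) U[[i]]$gamma, numeric(2))
      # no redundant reactions
      rk <- apply(reac, 2, paste, collapse = ",")
      redundant <- FALSE
      for (t in seq_along(ids)) {
        others <- setdiff(which(rk == rk[t]), t)
        if (length(others) &&
            in_positive_span(gam[, t], gam[, others, drop = FALSE])) {
          redundant <- TRUE
          break
        }
      }
      if (redundant) next
      if (!rank2_planar(gam)) next
      if (!stiemke2(gam)) next
      key <- equivalence_key(reac, gam)
      if (!exists(key, seen)) {
        assign(key, TRUE, seen)
        prod <- vapply(ids, function(i) U[[i]]$product, numeric(2))
        nrep <- nrep + 1
        reps[[nrep]] <- list(reactant = reac, gamma = gam, product = prod, key = key)
      }
    }
    reps[seq_len(nrep)]
  })
}

#' Build a [crn] object from a census representative
#' @param rep census representative (list with `reactant`, `product`).
#' @export
rep_to_crn <- function(rep) crn(rep$reactant, rep$product)

#' General census interface
#'
#' Thin wrapper selecting one of the two enumeration tracks and applying the
#' equilibrium-level filter.
#'
#' @param n_reactions must be 4.
#' @param product_molecularity 2 or 3.
#' @param distinct_reactants logical; `FALSE` selects the Andronov-Hopf base
#'   track (Lemma-style structural filters, repeated reactants allowed).
#' @param nondegenerate_equilibrium if `TRUE`, keep only classes admitting a
#'   positive nondegenerate equilibrium.
#' @return list of class representatives.
#' @export
census <- function(n_reactions = 4, product_molecularity = 3,
                   distinct_reactants = TRUE,
                   nondegenerate_equilibrium = FALSE) {
  stopifnot(n_reactions == 4, product_molecularity %in% c(2, 3))
  reps <- if (distinct_reactants) census_distinct_reactants(product_molecularity)
          else census_hopf_base()
  if (nondegenerate_equilibrium)
    reps <- Filter(admits_nondegenerate_equilibrium_rep, reps)
  reps
}

# class-level test: rank [A | 1] = n + 1 and det M(alpha) not identically 0
admits_nondegenerate_equilibrium_rep <- function(rep) {
  A <- t(rep$reactant)
  if (int_rank(cbind(A, 1)) != 3) return(FALSE)
  net <- list(gamma = rep$gamma, A = A, rank = 2)
  rc <- reduced_core_rep(rep)
  any(rc$detM != 0)
}

# reduced core of a census representative (memo-free, cheap)
reduced_core_rep <- function(rep) {
  rays <- kernel_rays(rep$gamma)
  if (ncol(rays) == 0 || !all(rowSums(rays) > 0))
    stop("dynamically trivial representative")
  r1 <- rays[, 1]
  r2 <- if (ncol(rays) >= 2) rays[, 2] else rays[, 1]
  net <- list(gamma = rep$gamma, A = t(rep$reactant), rank = 2)
  reduced_core(net, list(rays = rays, dim = ncol(rays), r1 = r1, r2 = r2))
}
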