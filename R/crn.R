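# Core representation of chemical reaction networks with mass-action kinetics.

#' Create a reaction network from reactant/product coefficient matrices
#'
#' A network on `n` species with `m` reactions is stored by its reactant
#' matrix (`n x m`, the stoichiometry of each species in each reactant
#' complex) and product matrix.  The stoichiometric matrix `gamma` is the
#' columnwise difference product - reactant; `A = t(reactant)` collects the
#' mass-action exponents, so the ODE system is `xdot = gamma (kappa o x^A)`.
#'
#' @param reactant,product integer matrices of equal dimension, one column
#'   per reaction, one row per species.
#' @param species character vector of species names (rows).
#' @return an object of class `crn` with components `species`, `reactant`,
#'   `product`, `gamma`, `A` and `rank`.
#' @export
crn <- function(reactant, product, species = NULL) {
  reactant <- as.matrix(reactant); product <- as.matrix(product)
  stopifnot(all(dim(reactant) == dim(product)))
  chk_int(c(reactant, product))
  if (any(reactant < 0) || any(product < 0))
    stop("stoichiometric coefficients must be nonnegative integers")
  n <- nrow(reactant)
  if (is.null(species)) species <- if (n == 2) c("X", "Y") else paste0("S", seq_len(n))
  stopifnot(length(species) == n)
  same <- vapply(seq_len(ncol(reactant)),
                 function(j) all(reactant[, j] == product[, j]), logical(1))
  if (any(same))
    stop("reaction with identical reactant and product complex: ",
         paste(which(same), collapse = ", "))
  gamma <- product - reactant
  net <- structure(
    list(species = species, reactant = reactant, product = product,
         gamma = gamma, A = t(reactant), rank = int_rank(gamma)),
    class = "crn")
  net
}

#' @export
print.crn <- function(x, ...) {
  cat("mass-action network (", nrow(x$gamma), " species, ",
      ncol(x$gamma), " reactions, rank ", x$rank, ")\n", sep = "")
  cat("  ", serialise_network(x), "\n", sep = "")
  invisible(x)
}

# -- complexes ----------------------------------------------------------------

#' Molecularity (coefficient sum) of complexes given as coefficient columns
#' @param m matrix whose columns are complex coefficient vectors
#' @return integer vector of column sums
#' @export
molecularity <- function(m) colSums(as.matrix(m))

format_complex <- function(coef, species) {
  nz <- which(coef != 0)
  if (!length(nz)) return("0")
  paste(vapply(nz, function(i) {
    if (coef[i] == 1) species[i] else paste0(coef[i], species[i])
  }, character(1)), collapse = "+")
}

parse_complex <- function(txt) {
  txt <- gsub("[[:space:]]", "", txt)
  if (txt == "") stop("empty complex")
  if (txt == "0") return(stats::setNames(numeric(0), character(0)))
  if (grepl("^\\+|\\+$|\\+\\+", txt)) stop("malformed complex: '", txt, "'")
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  if (any(parts == "")) stop("malformed complex: '", txt, "'")
  out <- numeric(0)
  for (p in parts) {
    mt <- regmatches(p, regexec("^([0-9]*)([A-Za-z][A-Za-z0-9_]*)$", p))[[1]]
    if (length(mt) != 3) stop("unknown token in complex: '", p, "'")
    k <- if (mt[2] == "") 1 else as.numeric(mt[2])
    if (k < 0 || k != round(k)) stop("coefficient must be a nonnegative integer")
    sp <- mt[3]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + k
  }
  out
}

# -- parsing / serialisation --------------------------------------------------

#' Parse a reaction-string into a network
#'
#' Grammar: reactions separated by `;`, each `reactant > product`; complexes
#' are `0` for the empty complex or `+`-separated terms with juxtaposed
#' integer coefficients (`2X`, `X+Y`, `2X+Y`).  Species are ordered by first
#' appearance unless an explicit `species` vector is supplied.
#'
#' @param text reaction string, e.g. `"2X > 3X; X+Y > 2Y; Y > 0; 0 > Y"`.
#' @param species optional character vector fixing the species order.
#' @return a [crn] object.
#' @examples
#' parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
#' @export
parse_network <- function(text, species = NULL) {
  rxn_txt <- strsplit(text, ";", fixed = TRUE)[[1]]
  rxn_txt <- trimws(rxn_txt)
  rxn_txt <- rxn_txt[rxn_txt != ""]
  if (!length(rxn_txt)) stop("no reactions in input")
  sides <- lapply(rxn_txt, function(r) {
    halves <- strsplit(r, ">", fixed = TRUE)[[1]]
    if (length(halves) != 2) stop("reaction must contain exactly one '>': '", r, "'")
    lapply(halves, parse_complex)
  })
  seen <- character(0)
  for (s in sides) for (cx in s) seen <- union(seen, names(cx))
  sp <- if (is.null(species)) seen else species
  if (!all(seen %in% sp)) stop("species not in supplied list: ",
                               paste(setdiff(seen, sp), collapse = ", "))
  if (!length(sp)) sp <- "X"   # degenerate: all complexes empty (rejected below)
  m <- length(sides)
  reactant <- matrix(0, length(sp), m, dimnames = list(sp, NULL))
  product <- reactant
  for (j in seq_len(m)) {
    for (nm in names(sides[[j]][[1]])) reactant[nm, j] <- sides[[j]][[1]][[nm]]
    for (nm in names(sides[[j]][[2]])) product[nm, j] <- sides[[j]][[2]][[nm]]
  }
  crn(reactant, product, species = sp)
}

#' Serialise a network to its canonical reaction string
#'
#' Inverse of [parse_network] for canonically formatted strings.
#' @param net a [crn] object.
#' @return a single string, reactions joined by `"; "`.
#' @export
serialise_network <- function(net) {
  m <- ncol(net$gamma)
  paste(vapply(seq_len(m), function(j) {
    paste(format_complex(net$reactant[, j], net$species), ">",
          format_complex(net$product[, j], net$species))
  }, character(1)), collapse = "; ")
}

# -- structural predicates ----------------------------------------------------

#' Structural predicates of a network
#'
#' @param net a [crn] object.
#' @return list with logical flags: `quadratic` (all reactant complexes
#'   bimolecular), `bimolecular` / `trimolecular` (all complexes of the
#'   network within molecularity 2 / 3), `has_trivial_species` (some row of
#'   the stoichiometric matrix vanishes).
#' @export
structural_predicates <- function(net) {
  rm <- molecularity(net$reactant)
  pm <- molecularity(net$product)
  list(
    quadratic = all(rm <= 2),
    bimolecular = all(rm <= 2) && all(pm <= 2),
    trimolecular = all(rm <= 3) && all(pm <= 3),
    has_trivial_species = any(rowSums(net$gamma != 0) == 0)
  )
}

#' Does the network contain a given reactant complex?
#' @param net a [crn]; @param complex coefficient vector (length n) or string.
#' @export
has_reactant <- function(net, complex) {
  cx <- complex_coefs(net, complex)
  any(vapply(seq_len(ncol(net$reactant)),
             function(j) all(net$reactant[, j] == cx), logical(1)))
}

#' Does the network contain a given reaction?
#' @param net a [crn]; @param reaction string `"reactant > product"`.
#' @export
has_reaction <- function(net, reaction) {
  r <- parse_network(reaction, species = net$species)
  any(vapply(seq_len(ncol(net$reactant)), function(j) {
    all(net$reactant[, j] == r$reactant[, 1]) && all(net$product[, j] == r$product[, 1])
  }, logical(1)))
}

complex_coefs <- function(net, complex) {
  if (is.character(complex)) {
    cx <- parse_complex(complex)
    v <- numeric(length(net$species))
    names(v) <- net$species
    for (nm in names(cx)) {
      if (!nm %in% net$species) stop("unknown species in complex: ", nm)
      v[nm] <- cx[[nm]]
    }
    unname(v)
  } else as.numeric(complex)
}

#' Swap the two species of a planar network
#' @noRd
swap_species <- function(net) {
  stopifnot(nrow(net$gamma) == 2)
  crn(net$reactant[2:1, , drop = FALSE], net$product[2:1, , drop = FALSE],
      species = net$species)
}
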