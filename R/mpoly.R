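# Minimal sparse multivariate polynomials over exact rationals.
#
# Used for symbolic identities with small coefficients: mass-action
# right-hand sides, conservation of the Hamiltonian for the vertical
# Bogdanov-Takens network, Dulac divergences, and the natural-coordinates
# reduction.  Coefficients are exact rationals held in guarded doubles.

#' @noRd
mp <- function(vars, exp, num, den = rep(1, length(num))) {
  exp <- matrix(as.numeric(exp), ncol = length(vars))
  colnames(exp) <- vars
  mp_normalise(structure(list(vars = vars, exp = exp, num = as.numeric(num),
                              den = as.numeric(den)), class = "mpoly"))
}

#' @noRd
mp_zero <- function(vars) mp(vars, matrix(0, 0, length(vars)), numeric(0), numeric(0))

#' @noRd
mp_const <- function(vars, num, den = 1) {
  if (num == 0) return(mp_zero(vars))
  mp(vars, matrix(0, 1, length(vars)), num, den)
}

#' @noRd
mp_var <- function(vars, v, pow = 1) {
  e <- matrix(0, 1, length(vars))
  e[1, match(v, vars)] <- pow
  mp(vars, e, 1, 1)
}

#' @noRd
mp_monomial <- function(vars, expvec, num = 1, den = 1) {
  mp(vars, matrix(expvec, 1), num, den)
}

mp_normalise <- function(p) {
  if (!length(p$num)) return(p)
  key <- apply(p$exp, 1, paste, collapse = ",")
  if (anyDuplicated(key)) {
    num <- numeric(0); den <- numeric(0); rows <- NULL
    for (k in unique(key)) {
      idx <- which(key == k)
      acc <- c(0, 1)
      for (i in idx) acc <- rat_add(acc, rat(p$num[i], p$den[i]))
      num <- c(num, acc[1]); den <- c(den, acc[2])
      rows <- rbind(rows, p$exp[idx[1], ])
    }
    p$exp <- matrix(rows, ncol = length(p$vars)); p$num <- num; p$den <- den
  } else {
    for (i in seq_along(p$num)) {
      r <- rat(p$num[i], p$den[i]); p$num[i] <- r[1]; p$den[i] <- r[2]
    }
  }
  keep <- p$num != 0
  p$exp <- p$exp[keep, , drop = FALSE]; p$num <- p$num[keep]; p$den <- p$den[keep]
  if (length(p$num)) {
    ord <- do.call(order, c(lapply(seq_len(ncol(p$exp)), function(j) p$exp[, j])))
    p$exp <- p$exp[ord, , drop = FALSE]; p$num <- p$num[ord]; p$den <- p$den[ord]
  }
  colnames(p$exp) <- p$vars
  p
}

#' @noRd
mp_add <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  mp(a$vars, rbind(a$exp, b$exp), c(a$num, b$num), c(a$den, b$den))
}

#' @noRd
mp_neg <- function(a) { a$num <- -a$num; a }

#' @noRd
mp_sub <- function(a, b) mp_add(a, mp_neg(b))

#' @noRd
mp_mul <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  na <- length(a$num); nb <- length(b$num)
  if (na == 0 || nb == 0) return(mp_zero(a$vars))
  exp <- matrix(0, na * nb, length(a$vars))
  num <- numeric(na * nb); den <- numeric(na * nb)
  k <- 1
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    exp[k, ] <- a$exp[i, ] + b$exp[j, ]
    r <- rat(chk_int(a$num[i] * b$num[j]), chk_int(a$den[i] * b$den[j]))
    num[k] <- r[1]; den[k] <- r[2]
    k <- k + 1
  }
  mp(a$vars, exp, num, den)
}

#' @noRd
mp_scale <- function(a, num, den = 1) {
  if (!length(a$num)) return(a)
  for (i in seq_along(a$num)) {
    r <- rat(chk_int(a$num[i] * num), chk_int(a$den[i] * den))
    a$num[i] <- r[1]; a$den[i] <- r[2]
  }
  mp_normalise(a)
}

#' @noRd
mp_is_zero <- function(a) length(a$num) == 0

#' @noRd
mp_equal <- function(a, b) mp_is_zero(mp_sub(a, b))

#' Partial derivative with respect to variable v
#' @noRd
mp_deriv <- function(a, v) {
  j <- match(v, a$vars)
  keep <- a$exp[, j] > 0
  if (!any(keep)) return(mp_zero(a$vars))
  exp <- a$exp[keep, , drop = FALSE]
  num <- chk_int(a$num[keep] * exp[, j])
  den <- a$den[keep]
  exp[, j] <- exp[, j] - 1
  mp(a$vars, exp, num, den)
}

#' Substitute polynomials for variables: subs = named list of mpoly
#' @noRd
mp_subst <- function(a, subs) {
  out <- mp_zero(a$vars)
  for (i in seq_along(a$num)) {
    term <- mp_const(a$vars, a$num[i], a$den[i])
    for (j in seq_along(a$vars)) {
      e <- a$exp[i, j]
      if (e == 0) next
      v <- a$vars[j]
      base <- if (v %in% names(subs)) subs[[v]] else mp_var(a$vars, v)
      for (k in seq_len(e)) term <- mp_mul(term, base)
    }
    out <- mp_add(out, term)
  }
  out
}

#' @export
print.mpoly <- function(x, ...) {
  cat(mp_format(x), "\n")
  invisible(x)
}

#' @noRd
mp_format <- function(p) {
  if (!length(p$num)) return("0")
  terms <- vapply(seq_along(p$num), function(i) {
    coef <- if (p$den[i] == 1) as.character(p$num[i]) else paste0(p$num[i], "/", p$den[i])
    mono <- paste(vapply(seq_along(p$vars), function(j) {
      e <- p$exp[i, j]
      if (e == 0) "" else if (e == 1) p$vars[j] else paste0(p$vars[j], "^", e)
    }, character(1)), collapse = "*")
    mono <- gsub("^\\*+|\\*+$", "", gsub("\\*{2,}", "*", mono))
    if (mono == "") coef
    else if (coef == "1") mono
    else if (coef == "-1") paste0("-", mono)
    else paste0(coef, "*", mono)
  }, character(1))
  out <- terms[1]
  for (t in terms[-1]) out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2)) else paste0(out, " + ", t)
  out
}

# -- mass-action right-hand side ---------------------------------------------

#' Symbolic mass-action vector field of a network
#'
#' Builds the polynomial right-hand side `gamma (kappa o x^A)` with symbolic
#' rate constants `k1, ..., km` and species concentration variables named
#' after the (lower-cased) species.
#'
#' @param net a [crn] object.
#' @return list with `vars` (variable order: concentrations then rates) and
#'   one `mpoly` per species; pretty-printed by [format_mass_action].
#' @export
mass_action_rhs <- function(net) {
  n <- nrow(net$gamma); m <- ncol(net$gamma)
  conc <- tolower(net$species)
  rates <- paste0("k", seq_len(m))
  vars <- c(conc, rates)
  field <- vector("list", n)
  for (i in seq_len(n)) {
    p <- mp_zero(vars)
    for (j in seq_len(m)) {
      if (net$gamma[i, j] == 0) next
      e <- numeric(length(vars))
      e[seq_len(n)] <- net$reactant[, j]
      e[n + j] <- 1
      p <- mp_add(p, mp_monomial(vars, e, net$gamma[i, j]))
    }
    field[[i]] <- p
  }
  structure(list(vars = vars, conc = conc, rates = rates, field = field,
                 net = net), class = "massaction")
}

#' @export
print.massaction <- function(x, ...) {
  for (i in seq_along(x$field))
    cat("d", x$conc[i], "/dt = ", mp_format(x$field[[i]]), "\n", sep = "")
  invisible(x)
}

#' @rdname mass_action_rhs
#' @param ma a `massaction` object.
#' @export
format_mass_action <- function(ma) {
  vapply(ma$field, mp_format, character(1))
}
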