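# Andronov-Hopf classification: focal values L1-L3 over the whole family of
# Hopf points, decided exactly.
#
# The Hopf-point set of a planar (2,4,2) network splits into (i) the
# trace-zero curve over cross-section parameters with det M > 0 and
# oppositely signed diagonal entries (x2 is then determined up to scaling),
# and (ii) vertical lines \{alpha*\} x \{x2 > 0\} at isolated rational
# cross-section points where both diagonal entries vanish (the trace is
# then zero for every x).  Each piece yields a univariate exact sign
# analysis of L1 (and L2, L3 where L1 vanishes); the classification merges
# the pieces.

#' Hopf-feasible cross-section intervals and witness constructor
#'
#' @param net a planar rank-two [crn] (or census representative).
#' @return list with `feasible`, `open_region` (logical: a trace-zero curve
#'   piece exists), `fixed_points` (rational alpha* of vertical pieces), and
#'   a `witness()` function returning one exact rational Hopf witness
#'   (alpha, x = c(1, x2), kappa) when the open region is nonempty.
#' @export
hopf_variety <- function(net) {
  ca <- core_analysis(net)
  tz <- trace_zero_points(ca$ctx)
  fixed <- Filter(function(p) p$det_sign > 0, tz)
  feas <- ca$hopf_feasible || length(fixed) > 0
  wit <- NULL
  if (ca$hopf_feasible) {
    w <- rational_region_witness(ca$ctx)
    wit <- function() w
  }
  list(feasible = feas, open_region = ca$hopf_feasible,
       fixed_points = fixed, witness = wit, ctx = ca$ctx)
}

# find a rational alpha in (0,1) with detM > 0 and M11*M22 < 0, exactly
rational_region_witness <- function(ctx) {
  net <- list(gamma = ctx$gamma, A = ctx$A, rank = 2)
  rc <- reduced_core(net, list(r1 = ctx$r1, r2 = ctx$r2))
  ev <- function(p, num, den) {
    d <- length(p) - 1
    if (d < 0) return(0)
    sum(p * num^(0:d) * den^(d:0))
  }
  for (den in c(2, 4, 8, 16, 32, 64, 128, 256, 512, 1024)) {
    for (num in seq_len(den - 1)) {
      if (gcd2(num, den) != 1) next
      if (ev(rc$detM, num, den) > 0 &&
          ev(rc$M11, num, den) * ev(rc$M22, num, den) < 0) {
        alpha <- c(num, den)
        h <- num * ctx$r1 + (den - num) * ctx$r2   # den * h(alpha)
        m11 <- ev(rc$M11, num, den); m22 <- ev(rc$M22, num, den)
        x2 <- rat(-m22, m11)
        kappa <- vapply(seq_along(h), function(j) {
          h[j] / (1^ctx$A[j, 1] * (x2[1] / x2[2])^ctx$A[j, 2])
        }, numeric(1))
        return(list(alpha = alpha, x2 = x2, h_scaled = h, kappa = kappa))
      }
    }
  }
  stop("no rational witness found in the Hopf region")
}

#' Classify the Andronov-Hopf bifurcation of a network
#'
#' Computes the focal values L1 (and L2, L3 where needed) exactly over every
#' piece of the Hopf-point family and returns one of `supercritical`
#' (L1 < 0 throughout), `subcritical` (L1 > 0), `vertical`
#' (L1 = L2 = L3 = 0 identically: the Hopf point is a center by the
#' Kapteyn-Bautin criterion for quadratic fields), `mixed` (L1 changes sign
#' and L2 = L3 = 0 on its zero set) or `bautin` (L1 changes sign with
#' L2 != 0 on the zero set).
#'
#' @param net a planar rank-two [crn] (or census representative).
#' @param transversality also certify the eigenvalue-crossing condition at a
#'   rational witness (rank of the trace unfolding).
#' @return list with `classification`, `l2_sign` (for `bautin`), and
#'   `transversal` (when requested).
#' @export
classify_hopf <- function(net, transversality = FALSE) {
  hv <- hopf_variety(net)
  if (!hv$feasible) return(list(classification = "none", feasible = FALSE))
  ctx <- hv$ctx
  pieces <- list()
  if (hv$open_region)
    pieces$curve <- hopf_classify_cpp(ctx$gamma, ctx$A, ctx$r1, ctx$r2, TRUE)
  for (i in seq_along(hv$fixed_points)) {
    p <- hv$fixed_points[[i]]$alpha
    hsc <- p[1] * ctx$r1 + (p[2] - p[1]) * ctx$r2
    pieces[[paste0("fixed", i)]] <-
      hopf_classify_fixed_cpp(ctx$gamma, ctx$A, as.numeric(hsc), TRUE)
  }
  cls <- merge_hopf_pieces(pieces)
  out <- list(classification = cls$classification, l2_sign = cls$l2_sign,
              feasible = TRUE, pieces = pieces)
  if (transversality) {
    out$transversal <- hopf_transversal(hv)
  }
  out
}

merge_hopf_pieces <- function(pieces) {
  stopifnot(length(pieces) > 0)
  ident <- vapply(pieces, function(p) isTRUE(p$l1_identically_zero), logical(1))
  ident_ok <- vapply(pieces, function(p)
    isTRUE(p$l1_identically_zero) && isTRUE(p$l2_identically_zero) &&
      isTRUE(p$l3_identically_zero), logical(1))
  if (all(ident)) {
    if (all(ident_ok)) return(list(classification = "vertical", l2_sign = 0L))
    return(list(classification = "degenerate-unexpected", l2_sign = 0L))
  }
  has_neg <- any(vapply(pieces, function(p) !isTRUE(p$l1_identically_zero) &&
                          p$l1_neg_samples > 0, logical(1)))
  has_pos <- any(vapply(pieces, function(p) !isTRUE(p$l1_identically_zero) &&
                          p$l1_pos_samples > 0, logical(1)))
  nz <- sum(vapply(pieces, function(p)
    if (isTRUE(p$l1_identically_zero)) 1L else p$n_l1_zeros, integer(1)))
  zero_cls <- vapply(pieces, function(p) {
    if (isTRUE(p$l1_identically_zero))
      return(if (isTRUE(p$l2_identically_zero) && isTRUE(p$l3_identically_zero))
               "l2l3zero" else "other")
    if (p$n_l1_zeros == 0) return("none")
    p$classification
  }, character(1))
  relevant <- zero_cls[zero_cls != "none"]
  if (nz == 0) {
    if (has_neg && !has_pos) return(list(classification = "supercritical", l2_sign = 0L))
    if (has_pos && !has_neg) return(list(classification = "subcritical", l2_sign = 0L))
    return(list(classification = "mixed-disconnected", l2_sign = 0L))
  }
  if (all(relevant %in% c("mixed", "l2l3zero")))
    return(list(classification = "mixed", l2_sign = 0L))
  if (all(relevant == "bautin")) {
    s <- unique(unlist(lapply(pieces, function(p) p$l2_sign)))
    s <- s[!is.null(s) & s != 0]
    return(list(classification = "bautin",
                l2_sign = if (length(s) == 1) s else 99L))
  }
  list(classification = "degenerate-unexpected", l2_sign = 0L)
}

# transversality of the eigenvalue crossing at one rational witness
hopf_transversal <- function(hv) {
  ctx <- hv$ctx
  if (hv$open_region) {
    w <- hv$witness()
    tv <- transversality_cpp(ctx$gamma, ctx$A,
                             as.numeric(w$h_scaled) * w$x2[2],
                             w$x2[1], w$x2[2], "trace")
    return(tv$full_rank)
  }
  p <- hv$fixed_points[[1]]$alpha
  hsc <- p[1] * ctx$r1 + (p[2] - p[1]) * ctx$r2
  tv <- transversality_cpp(ctx$gamma, ctx$A, as.numeric(hsc), 1, 1, "trace")
  tv$full_rank
}

#' Exact focal-value data of a network at a rational cross-section point
#'
#' Returns the components of L1 = u + v sqrt(Delta) at `alpha`
#' (as exact strings) together with its sign; mainly a hook for
#' cross-checking the symbolic pipeline against independent numerics.
#'
#' @param net planar rank-two [crn] (or representative); @param alpha_num,
#'   alpha_den rational cross-section coordinate.
#' @export
focal_values <- function(net, alpha_num, alpha_den) {
  ctx <- as_ctx(net)
  l1_components_cpp(ctx$gamma, ctx$A, ctx$r1, ctx$r2, alpha_num, alpha_den)
}
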