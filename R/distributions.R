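#' @title Nominal-mass-shift distributions
#' @description A shift distribution is a sparse map from non-negative
#'   integer nominal mass shifts to probabilities summing to 1. It is
#'   represented as a named numeric vector whose names are the shifts.
#' @name shift-distributions
NULL

shift_dist <- function(shifts, probs) {
  stopifnot(length(shifts) == length(probs))
  keep <- probs != 0
  shifts <- as.integer(shifts[keep])
  probs <- as.numeric(probs[keep])
  ord <- order(shifts)
  stats::setNames(probs[ord], shifts[ord])
}

dist_shifts <- function(d) as.integer(names(d))

dist_point <- function(shift) shift_dist(shift, 1)

#' Convolve two shift distributions
#'
#' The distribution of the sum of two independent shifts:
#' `probs[s] = sum over u+v=s of a[u]*b[v]`. Commutative and associative;
#' total probability is preserved.
#'
#' @param a,b Shift distributions (named numeric vectors, names = shifts).
#' @return A shift distribution.
#' @export
#' @examples
#' convolve_shift(c(`0` = 0.5, `1` = 0.5), c(`0` = 0.5, `1` = 0.5))
convolve_shift <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  sa <- dist_shifts(a)
  sb <- dist_shifts(b)
  s <- as.vector(outer(sa, sb, `+`))
  p <- as.vector(outer(unname(a), unname(b)))
  agg <- rowsum(p, group = s)
  shift_dist(as.integer(rownames(agg)), agg[, 1])
}

#' Natural-abundance shift distribution of identical atoms
#'
#' Distribution of the total nominal mass shift of `count` independent
#' atoms of one element, each drawing an isotope from the element's natural
#' abundance table: the `count`-fold convolution of the single-atom table.
#' For two-isotope elements this is the binomial distribution; elements
#' with three or more isotopes give a multinomial collapsed by summed
#' shift.
#'
#' @param el An [element_def()].
#' @param count Non-negative number of atoms.
#' @return A shift distribution.
#' @export
#' @examples
#' C <- element_def("C", c(0L, 1L), c(0.9893, 0.0107))
#' natural_distribution(C, 2)
natural_distribution <- function(el, count) {
  stopifnot(inherits(el, "element_def"))
  count <- as.integer(count)
  if (count < 0L) stop("count must be non-negative", call. = FALSE)
  if (count == 0L) return(dist_point(0L))
  single <- shift_dist(el$shifts, el$abundances)
  if (length(single) == 2L && identical(dist_shifts(single), c(0L, 1L))) {
    # binomial closed form for the common two-isotope unit-shift case
    p <- single[["1"]]
    return(shift_dist(0:count, stats::dbinom(0:count, count, p)))
  }
  # binary-exponentiation convolution for the general multinomial case
  acc <- dist_point(0L)
  base <- single
  k <- count
  while (k > 0L) {
    if (k %% 2L == 1L) acc <- convolve_shift(acc, base)
    k <- k %/% 2L
    if (k > 0L) base <- convolve_shift(base, base)
  }
  acc
}

#' Tracer-impurity shift distribution of labeled positions
#'
#' Each of `t` nominally labeled positions carries the tracer isotope
#' (contributing the tracer's nominal shift) with probability `purity`, and
#' the light isotope (shift 0) with probability `1 - purity`. The result is
#' the binomial over the `t` positions mapped to shifts
#' `{0, tracer_shift, ..., t * tracer_shift}`. At purity 1 this reduces to
#' the fixed-label point mass.
#'
#' @param el An [element_def()] with a tracer isotope.
#' @param t Non-negative number of labeled positions.
#' @param purity Fraction in (0, 1].
#' @return A shift distribution.
#' @export
purity_distribution <- function(el, t, purity) {
  stopifnot(inherits(el, "element_def"))
  if (is.na(el$tracer_shift)) {
    stop("element ", el$symbol, " has no tracer isotope", call. = FALSE)
  }
  if (purity <= 0 || purity > 1) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  t <- as.integer(t)
  if (t < 0L) stop("t must be non-negative", call. = FALSE)
  if (t == 0L) return(dist_point(0L))
  shift_dist((0:t) * el$tracer_shift, stats::dbinom(0:t, t, purity))
}

# effective purity for an element: explicit override > registry value > 1
element_purity <- function(el, purity_correction) {
  if (!purity_correction) return(1)
  if (is.na(el$tracer_purity)) 1 else el$tracer_purity
}

#' Mass distribution of a labeled species at nominal resolution
#'
#' The shift distribution of a fragment carrying `t` tracer labels: every
#' atom draws an isotope from natural abundance, except the `t` labeled
#' positions, whose isotopic state is fixed at the tracer isotope (or, with
#' purity correction, varies between tracer and light isotope according to
#' the tracer purity). The result is the convolution of
#' (i) the impurity distribution over the `t` labeled positions,
#' (ii) the natural distribution of the remaining unlabeled labelable
#' positions of the tracer element, and
#' (iii) the natural distribution of every plain atom of every element.
#'
#' @param frag A `fragment_formula` with at most one labelable element.
#' @param t Number of tracer labels, `0 <= t <=` labelable count.
#' @param registry An `element_registry`.
#' @param purity_correction Logical: apply tracer-impurity weighting to the
#'   labeled positions?
#' @return A shift distribution.
#' @export
#' @examples
#' reg <- default_elements(tracers = "C")
#' fragment_distribution(parse_formula("LabC2"), 1, reg)
fragment_distribution <- function(frag, t, registry,
                                  purity_correction = FALSE) {
  stopifnot(inherits(frag, "fragment_formula"),
            inherits(registry, "element_registry"))
  t <- as.integer(t)
  lab <- frag$labelable
  if (length(lab) > 1L) {
    stop("nominal-resolution distributions support one labelable element",
         call. = FALSE)
  }
  d <- dist_point(0L)
  if (length(lab) == 1L) {
    el <- registry_element(registry, names(lab))
    if (is.na(el$tracer_shift)) {
      stop("labelable element ", el$symbol, " has no tracer definition",
           call. = FALSE)
    }
    if (t < 0L || t > lab[[1]]) {
      stop("t = ", t, " outside [0, ", lab[[1]], "]", call. = FALSE)
    }
    pur <- element_purity(el, purity_correction)
    d_lab <- if (pur < 1) purity_distribution(el, t, pur) else
      dist_point(t * el$tracer_shift)
    d <- convolve_shift(d, d_lab)
    d <- convolve_shift(d, natural_distribution(el, lab[[1]] - t))
  } else if (t != 0L) {
    stop("t = ", t, " but fragment has no labelable atoms", call. = FALSE)
  }
  for (sym in names(frag$plain)) {
    d <- convolve_shift(d, natural_distribution(
      registry_element(registry, sym), frag$plain[[sym]]))
  }
  d
}

# ---- high-resolution label-count-vector distributions ----------------------

label_vec_key <- function(v) paste(v, collapse = ".")

parse_label_vec <- function(key) as.integer(strsplit(key, ".", fixed = TRUE)[[1]])

#' Label-pattern distribution of a species in high-resolution mode
#'
#' At high resolution, mass defects are resolved, so natural isotopes of
#' elements other than the tracer element(s) — and non-tracer isotopes of
#' the tracer elements — do not interfere with the measured species. The
#' only unresolved contribution is the tracer isotope itself: for tracer
#' element `e` with `N_e` atoms in the measured ion (labelable plus plain)
#' of which `t_e` are labeled, the observed tracer-isotope count is the sum
#' of a Binomial(`t_e`, purity) over the labeled positions and a
#' Binomial(`N_e - t_e`, `a_e`) over the remaining atoms, where `a_e` is
#' the natural abundance of the tracer isotope of `e`. Tracer elements are
#' independent, so the joint distribution over the label-count vector is
#' the outer product of the per-element distributions.
#'
#' @param mol A `molecule_spec` with mode `"highres"`.
#' @param labels Integer label-count vector, one entry per tracer element
#'   (registry tracer order), `0 <= labels[i] <= n_i`.
#' @param registry An `element_registry`.
#' @param purity_correction Logical.
#' @return A named numeric vector: names are dot-joined observed
#'   label-count vectors, values are probabilities summing to 1.
#' @export
species_distribution_highres <- function(mol, labels, registry,
                                         purity_correction = FALSE) {
  stopifnot(inherits(mol, "molecule_spec"), mol$mode == "highres")
  cap <- molecule_capacity(mol, registry)
  labels <- as.integer(labels)
  if (length(labels) != cap$r) {
    stop("label vector length ", length(labels), " != r = ", cap$r,
         call. = FALSE)
  }
  if (any(labels < 0L | labels > cap$n_i)) {
    stop("label vector outside [0, n_i]", call. = FALSE)
  }
  per_el <- purrr::map2(cap$tracers, labels, function(sym, t_e) {
    el <- registry_element(registry, sym)
    a_e <- el$abundances[match(el$tracer_shift, el$shifts)]
    N_e <- (if (sym %in% names(mol$product$labelable))
      mol$product$labelable[[sym]] else 0L) +
      (if (sym %in% names(mol$product$plain))
        mol$product$plain[[sym]] else 0L)
    pur <- element_purity(el, purity_correction)
    d_lab <- if (pur < 1) shift_dist(0:t_e, stats::dbinom(0:t_e, t_e, pur))
    else dist_point(t_e)
    d_nat <- shift_dist(0:(N_e - t_e),
                        stats::dbinom(0:(N_e - t_e), N_e - t_e, a_e))
    convolve_shift(d_lab, d_nat)
  })
  # outer product over tracer elements -> joint label-vector distribution
  combos <- expand.grid(purrr::map(per_el, dist_shifts),
                        KEEP.OUT.ATTRS = FALSE)
  pcols <- expand.grid(purrr::map(per_el, unname), KEEP.OUT.ATTRS = FALSE)
  probs <- apply(as.matrix(pcols), 1L, prod)
  keys <- apply(as.matrix(combos), 1L, label_vec_key)
  stats::setNames(probs, keys)
}
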