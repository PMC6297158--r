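#' Build the correction probability matrix for a molecule
#'
#' Assembles the k-by-k matrix `P` of the linear model `v_m = P %*% v_c`,
#' where `v_c` holds the (unknown) abundances of the truly labeled species
#' and `v_m` the measured signals. Column `j` holds the distribution of the
#' j-th labeled species over the measured bins: at nominal resolution the
#' mass distribution of the species, at high resolution its distribution
#' over observed label-count vectors. Entry `p[i, j]` is the fraction of
#' species `j` that appears in measured bin `i`.
#'
#' Dimensions by mode: MS1 `k = n + 1`; MS/MS `k = (n + 1) * (m + 1)` where
#' `n` is the maximum label in the product ion and `m` in the neutral loss;
#' high-resolution `k = prod(n_i + 1)` over the `r` tracer elements.
#'
#' Probability mass falling outside the measured bins (above the maximum
#' label, or at off-bin shifts when the tracer shift exceeds 1) is dropped;
#' the per-column dropped mass is available as `attr(P, "dropped")`.
#'
#' @param mol A [molecule_spec()].
#' @param registry An [element_registry()].
#' @param purity_correction Logical: also correct for tracer impurity using
#'   the purities recorded in the registry.
#' @return A `correction_matrix`: a k-by-k numeric matrix with row names =
#'   measured keys, column names = label-state keys, and attributes
#'   `mode`, `molecule`, `dropped` (per-column out-of-bin mass), and
#'   `label_counts` (k-by-r matrix of per-tracer label counts per column,
#'   used for mean-enrichment summaries).
#' @export
#' @examples
#' reg <- default_elements(tracers = "C")
#' build_matrix(molecule_spec("Gly", "LabC2", mode = "ms1"), reg)
build_matrix <- function(mol, registry, purity_correction = FALSE) {
  stopifnot(inherits(mol, "molecule_spec"),
            inherits(registry, "element_registry"))
  switch(mol$mode,
         ms1 = build_matrix_ms1(mol, registry, purity_correction),
         msms = build_matrix_msms(mol, registry, purity_correction),
         highres = build_matrix_highres(mol, registry, purity_correction))
}

new_correction_matrix <- function(P, mode, molecule, label_counts, tracers,
                                  n_per_tracer) {
  dropped <- 1 - colSums(P)
  structure(P, mode = mode, molecule = molecule, dropped = dropped,
            label_counts = label_counts, tracers = tracers,
            n_per_tracer = n_per_tracer,
            class = c("correction_matrix", class(P)))
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("<correction_matrix> ", attr(x, "molecule"), " [", attr(x, "mode"),
      "] k = ", nrow(x), "\n", sep = "")
  print(signif(unclass(x)[, , drop = FALSE], 6))
  invisible(x)
}

# probability of distribution d at exact shift s (0 if absent)
dist_at <- function(d, s) {
  i <- match(as.character(s), names(d))
  ifelse(is.na(i), 0, unname(d[i]))
}

build_matrix_ms1 <- function(mol, registry, purity_correction) {
  cap <- molecule_capacity(mol, registry)
  n <- cap$n
  if (n == 0L) {
    stop("molecule ", mol$name, " has no labelable atoms: nothing to correct",
         call. = FALSE)
  }
  el <- registry_element(registry, cap$tracer)
  # measured bins sit at label multiples of the tracer shift
  bins <- (0:n) * el$tracer_shift
  k <- n + 1L
  P <- matrix(0, k, k, dimnames = list(as.character(0:n), as.character(0:n)))
  for (t in 0:n) {
    d <- fragment_distribution(mol$product, t, registry, purity_correction)
    P[, t + 1L] <- dist_at(d, bins)
  }
  new_correction_matrix(P, "ms1", mol$name,
                        label_counts = matrix(0:n, ncol = 1,
                                              dimnames = list(NULL, cap$tracer)),
                        tracers = cap$tracer, n_per_tracer = n)
}

build_matrix_msms <- function(mol, registry, purity_correction) {
  cap <- molecule_capacity(mol, registry)
  n <- cap$n
  m <- cap$m
  if (n + m == 0L) {
    stop("molecule ", mol$name, " has no labelable atoms: nothing to correct",
         call. = FALSE)
  }
  el <- registry_element(registry, cap$tracer)
  nl <- if (is.null(mol$neutral_loss)) empty_fragment() else mol$neutral_loss
  # states/keys ordered lexicographically by (p, q) = (precursor, product)
  states <- expand.grid(t_nl = 0:m, t_prod = 0:n, KEEP.OUT.ATTRS = FALSE)
  states <- states[order(states$t_prod + states$t_nl, states$t_prod), ]
  keys <- paste0(states$t_prod + states$t_nl, ".", states$t_prod)
  k <- (n + 1L) * (m + 1L)
  P <- matrix(0, k, k, dimnames = list(keys, keys))
  d_prod <- lapply(0:n, function(t)
    fragment_distribution(mol$product, t, registry, purity_correction))
  d_nl <- lapply(0:m, function(t)
    fragment_distribution(nl, t, registry, purity_correction))
  for (j in seq_len(k)) {
    tp <- states$t_prod[j]
    tn <- states$t_nl[j]
    # entry for measured (p, q): product fragment observed at bin q,
    # neutral loss at bin p - q
    P[, j] <- dist_at(d_prod[[tp + 1L]],
                      states$t_prod * el$tracer_shift) *
      dist_at(d_nl[[tn + 1L]], states$t_nl * el$tracer_shift)
  }
  new_correction_matrix(P, "msms", mol$name,
                        label_counts = matrix(states$t_prod + states$t_nl,
                                              ncol = 1,
                                              dimnames = list(NULL, cap$tracer)),
                        tracers = cap$tracer, n_per_tracer = n + m)
}

# all label vectors in the box [0, n_1] x ... x [0, n_r], lexicographic
label_box <- function(n_i) {
  grids <- rev(lapply(n_i, function(n) 0:n))
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[, rev(seq_along(n_i)), drop = FALSE])
  colnames(g) <- names(n_i)
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

build_matrix_highres <- function(mol, registry, purity_correction) {
  cap <- molecule_capacity(mol, registry)
  box <- label_box(stats::setNames(cap$n_i, cap$tracers))
  keys <- apply(box, 1L, label_vec_key)
  k <- nrow(box)
  P <- matrix(0, k, k, dimnames = list(keys, keys))
  for (j in seq_len(k)) {
    d <- species_distribution_highres(mol, box[j, ], registry,
                                      purity_correction)
    hit <- match(keys, names(d))
    P[, j] <- ifelse(is.na(hit), 0, d[hit])
  }
  new_correction_matrix(P, "highres", mol$name, label_counts = box,
                        tracers = cap$tracers, n_per_tracer = cap$n_i)
}

#' Expected measurement keys of a molecule
#'
#' The ordered row keys of the molecule's correction matrix, i.e. the
#' `<Molecule>_<state>` suffixes a complete measurement table must contain.
#'
#' @param mol A `molecule_spec`.
#' @param registry An `element_registry`.
#' @return Character vector of state keys (without the molecule prefix).
#' @export
expected_states <- function(mol, registry) {
  rownames(build_matrix(mol, registry, purity_correction = FALSE))
}
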