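# Brute-force enumeration oracles, independent of the convolution engine:
# every isotope assignment of every atom is enumerated explicitly with
# expand.grid and probabilities are aggregated by total shift (or observed
# label-count vector). Only usable for small molecules.

# per-atom choice tables for a fragment with t tracer labels
oracle_atom_tables <- function(frag, t, registry, purity_correction) {
  atoms <- list()
  lab <- frag$labelable
  if (length(lab) > 1L) stop("oracle: single labelable element only")
  if (length(lab) == 1L) {
    el <- registry$defs[[names(lab)]]
    pur <- if (purity_correction && !is.na(el$tracer_purity))
      el$tracer_purity else 1
    for (i in seq_len(t)) {
      atoms[[length(atoms) + 1L]] <- if (pur < 1) {
        list(shift = c(0L, el$tracer_shift), prob = c(1 - pur, pur))
      } else list(shift = el$tracer_shift, prob = 1)
    }
    for (i in seq_len(lab[[1]] - t)) {
      atoms[[length(atoms) + 1L]] <- list(shift = el$shifts,
                                          prob = el$abundances)
    }
  }
  for (sym in names(frag$plain)) {
    el <- registry$defs[[sym]]
    for (i in seq_len(frag$plain[[sym]])) {
      atoms[[length(atoms) + 1L]] <- list(shift = el$shifts,
                                          prob = el$abundances)
    }
  }
  atoms
}

oracle_combo_count <- function(atoms) {
  prod(vapply(atoms, function(a) length(a$shift), numeric(1)))
}

# full enumeration -> named prob vector over total shift
oracle_enumerate <- function(atoms) {
  if (!length(atoms)) return(c(`0` = 1))
  idx <- expand.grid(lapply(atoms, function(a) seq_along(a$shift)),
                     KEEP.OUT.ATTRS = FALSE)
  shift_mat <- mapply(function(a, col) a$shift[col], atoms, idx)
  prob_mat <- mapply(function(a, col) a$prob[col], atoms, idx)
  if (is.null(dim(shift_mat))) {
    shift_mat <- matrix(shift_mat, nrow = nrow(idx))
    prob_mat <- matrix(prob_mat, nrow = nrow(idx))
  }
  total <- rowSums(shift_mat)
  p <- apply(prob_mat, 1L, prod)
  agg <- rowsum(p, group = total)
  setNames(agg[, 1], rownames(agg))
}

oracle_fragment_distribution <- function(frag, t, registry,
                                         purity_correction = FALSE) {
  oracle_enumerate(oracle_atom_tables(frag, t, registry, purity_correction))
}

# oracle correction matrix, nominal MS1
oracle_matrix_ms1 <- function(mol, registry, purity_correction = FALSE) {
  el <- registry$defs[[names(mol$product$labelable)]]
  n <- mol$product$labelable[[1]]
  bins <- (0:n) * el$tracer_shift
  P <- matrix(0, n + 1L, n + 1L,
              dimnames = list(as.character(0:n), as.character(0:n)))
  for (t in 0:n) {
    d <- oracle_fragment_distribution(mol$product, t, registry,
                                      purity_correction)
    hit <- match(as.character(bins), names(d))
    P[, t + 1L] <- ifelse(is.na(hit), 0, d[hit])
  }
  P
}

oracle_matrix_msms <- function(mol, registry, purity_correction = FALSE) {
  lab_p <- mol$product$labelable
  lab_n <- mol$neutral_loss$labelable
  tracer <- unique(c(names(lab_p), names(lab_n)))
  el <- registry$defs[[tracer]]
  n <- if (length(lab_p)) lab_p[[1]] else 0L
  m <- if (length(lab_n)) lab_n[[1]] else 0L
  states <- expand.grid(t_nl = 0:m, t_prod = 0:n, KEEP.OUT.ATTRS = FALSE)
  states <- states[order(states$t_prod + states$t_nl, states$t_prod), ]
  keys <- paste0(states$t_prod + states$t_nl, ".", states$t_prod)
  k <- nrow(states)
  P <- matrix(0, k, k, dimnames = list(keys, keys))
  for (j in seq_len(k)) {
    dp <- oracle_fragment_distribution(mol$product, states$t_prod[j],
                                       registry, purity_correction)
    dn <- oracle_fragment_distribution(mol$neutral_loss, states$t_nl[j],
                                       registry, purity_correction)
    at <- function(d, s) {
      hit <- match(as.character(s), names(d))
      ifelse(is.na(hit), 0, d[hit])
    }
    P[, j] <- at(dp, states$t_prod * el$tracer_shift) *
      at(dn, states$t_nl * el$tracer_shift)
  }
  P
}

# high-res: enumerate every tracer-element atom's carry/not-carry state
oracle_highres_distribution <- function(mol, labels, registry,
                                        purity_correction = FALSE) {
  tracers <- intersect(names(registry$defs)[
    !vapply(registry$defs, function(d) is.na(d$tracer_shift), logical(1))],
    names(mol$product$labelable))
  tracers <- intersect(registry$tracer_order, names(mol$product$labelable))
  atoms <- list()
  which_el <- integer()
  for (i in seq_along(tracers)) {
    el <- registry$defs[[tracers[i]]]
    a_e <- el$abundances[match(el$tracer_shift, el$shifts)]
    pur <- if (purity_correction && !is.na(el$tracer_purity))
      el$tracer_purity else 1
    t_e <- labels[i]
    N_e <- (if (tracers[i] %in% names(mol$product$labelable))
      mol$product$labelable[[tracers[i]]] else 0L) +
      (if (tracers[i] %in% names(mol$product$plain))
        mol$product$plain[[tracers[i]]] else 0L)
    for (j in seq_len(t_e)) {
      atoms[[length(atoms) + 1L]] <- if (pur < 1)
        list(shift = c(0L, 1L), prob = c(1 - pur, pur)) else
          list(shift = 1L, prob = 1)
      which_el <- c(which_el, i)
    }
    for (j in seq_len(N_e - t_e)) {
      atoms[[length(atoms) + 1L]] <- list(shift = c(0L, 1L),
                                          prob = c(1 - a_e, a_e))
      which_el <- c(which_el, i)
    }
  }
  if (!length(atoms)) {
    return(setNames(1, paste(rep(0L, length(tracers)), collapse = ".")))
  }
  idx <- expand.grid(lapply(atoms, function(a) seq_along(a$shift)),
                     KEEP.OUT.ATTRS = FALSE)
  carry <- mapply(function(a, col) a$shift[col], atoms, idx)
  prob <- mapply(function(a, col) a$prob[col], atoms, idx)
  if (is.null(dim(carry))) {
    carry <- matrix(carry, nrow = nrow(idx))
    prob <- matrix(prob, nrow = nrow(idx))
  }
  counts <- sapply(seq_along(tracers), function(i)
    rowSums(carry[, which_el == i, drop = FALSE]))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(idx))
  key <- apply(counts, 1L, paste, collapse = ".")
  p <- apply(prob, 1L, prod)
  agg <- rowsum(p, group = key)
  setNames(agg[, 1], rownames(agg))
}

oracle_matrix_highres <- function(mol, registry, purity_correction = FALSE) {
  tracers <- intersect(registry$tracer_order, names(mol$product$labelable))
  n_i <- vapply(tracers, function(e) mol$product$labelable[[e]], integer(1))
  box <- expand.grid(rev(lapply(n_i, function(n) 0:n)),
                     KEEP.OUT.ATTRS = FALSE)
  box <- as.matrix(box[, rev(seq_along(n_i)), drop = FALSE])
  box <- box[do.call(order, as.data.frame(box)), , drop = FALSE]
  keys <- apply(box, 1L, paste, collapse = ".")
  k <- nrow(box)
  P <- matrix(0, k, k, dimnames = list(keys, keys))
  for (j in seq_len(k)) {
    d <- oracle_highres_distribution(mol, box[j, ], registry,
                                     purity_correction)
    hit <- match(keys, names(d))
    P[, j] <- ifelse(is.na(hit), 0, d[hit])
  }
  P
}

oracle_matrix <- function(mol, registry, purity_correction = FALSE) {
  switch(mol$mode,
         ms1 = oracle_matrix_ms1(mol, registry, purity_correction),
         msms = oracle_matrix_msms(mol, registry, purity_correction),
         highres = oracle_matrix_highres(mol, registry, purity_correction))
}

# random small molecules whose full enumeration stays tractable
rand_molecule <- function(mode, registry, max_atoms = 12L,
                          max_combos = 6e4) {
  repeat {
    total <- sample(2:max_atoms, 1)
    if (mode == "highres") {
      n_c <- sample(1:3, 1)
      n_n <- sample(1:2, 1)
      plain_c <- sample(0:2, 1)
      plain_n <- sample(0:1, 1)
      used <- n_c + n_n + plain_c + plain_n
      if (used > max_atoms) next
      extra <- sample(c("H", "O", "Si", "S"), max(0, min(2, max_atoms - used)),
                      replace = TRUE)
      plain <- c(C = plain_c, N = plain_n, table(extra))
      plain <- setNames(as.integer(plain), names(plain))
      mol <- molecule_spec("R", fragment_formula(
        plain[plain > 0], c(C = n_c, N = n_n)), mode = "highres")
      return(mol)
    }
    n_lab <- sample(1:min(4, total - 1), 1)
    n_plain <- total - n_lab
    plain_syms <- sample(c("C", "H", "N", "O", "Si", "S"), n_plain,
                         replace = TRUE, prob = c(3, 3, 2, 2, 1, 1))
    plain <- table(plain_syms)
    plain <- setNames(as.integer(plain), names(plain))
    if (mode == "ms1") {
      mol <- molecule_spec("R", fragment_formula(plain, c(C = n_lab)),
                           mode = "ms1")
      atoms <- oracle_atom_tables(mol$product, 0L, registry, FALSE)
      if (oracle_combo_count(atoms) > max_combos) next
      return(mol)
    }
    # msms: split the labelable atoms and the plain atoms across fragments
    m_lab <- sample(0:n_lab, 1)
    if (n_lab - m_lab == 0L && m_lab == 0L) next
    half <- stats::rbinom(length(plain), plain, 0.5)
    plain_p <- setNames(as.integer(half), names(plain))
    plain_n2 <- setNames(as.integer(plain - half), names(plain))
    prod_lab <- n_lab - m_lab
    prod_f <- tryCatch(fragment_formula(
      plain_p[plain_p > 0],
      if (prod_lab > 0) c(C = prod_lab) else integer()),
      error = function(e) NULL)
    nl_f <- tryCatch(fragment_formula(
      plain_n2[plain_n2 > 0],
      if (m_lab > 0) c(C = m_lab) else integer()),
      error = function(e) NULL)
    if (is.null(prod_f) || is.null(nl_f)) next
    mol <- tryCatch(molecule_spec("R", prod_f, neutral_loss = nl_f,
                                  mode = "msms"), error = function(e) NULL)
    if (is.null(mol)) next
    combos <- oracle_combo_count(oracle_atom_tables(prod_f, 0L, registry,
                                                    FALSE)) *
      oracle_combo_count(oracle_atom_tables(nl_f, 0L, registry, FALSE))
    if (combos > max_combos) next
    return(mol)
  }
}

# KKT optimality check for the NNLS solve: gradient of 0.5*||Pv - m||^2 is
# g = t(P) %*% (P v - m); optimal iff g >= 0 where v = 0 and g = 0 where
# v > 0 (within tolerance)
nnls_kkt_ok <- function(P, v_m, v_c, tol = 1e-8) {
  g <- as.numeric(crossprod(unclass(P), unclass(P) %*% v_c - v_m))
  scale <- max(1, max(abs(v_m)))
  all(g > -tol * scale) && all(abs(g[v_c > tol * scale]) < tol * scale)
}
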