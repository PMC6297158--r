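test_that("MS1 matrix of a two-carbon fragment matches the closed form", {
  P <- build_matrix(glycine_ms1(), reg_c())
  expected <- matrix(c(0.97871449, 0.02117102, 0.00011449,
                       0, 0.9893, 0.0107,
                       0, 0, 1), 3, 3)
  expect_equal(unclass(P), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(P), c("0", "1", "2"))
  # no mass can leave the bins here: columns sum to exactly 1
  expect_equal(unname(colSums(P)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("matrix dimensions follow the mode formulas", {
  reg <- reg_c()
  expect_equal(nrow(build_matrix(pcf_proline(), reg)), 6L)  # k = n + 1
  msms <- molecule_spec("Asp", "LabC2C3H6NO2",
                        neutral_loss = "LabC1C4H7O2", mode = "msms")
  expect_equal(nrow(build_matrix(msms, reg)), 6L)  # k = (n+1)(m+1)
  asn <- molecule_spec("Asn",
                       fragment_formula(c(C = 4L, H = 12L, O = 2L),
                                        c(C = 4L, N = 2L)),
                       mode = "highres")
  expect_equal(nrow(build_matrix(asn, reg_cn())), 15L)  # k = prod(n_i+1)
  expect_error(build_matrix(molecule_spec("X", "C5", mode = "ms1"), reg),
               "labelable")
})

test_that("without impurity the matrix is lower triangular", {
  reg <- reg_c()
  for (mol in list(glycine_ms1(), pcf_proline(),
                   molecule_spec("Asp", "LabC2C3", neutral_loss = "LabC2C1",
                                 mode = "msms"))) {
    P <- unclass(build_matrix(mol, reg, purity_correction = FALSE))
    expect_equal(P[upper.tri(P)], rep(0, sum(upper.tri(P))))
  }
  asn <- molecule_spec("Asn", fragment_formula(c(C = 2L), c(C = 3L, N = 2L)),
                       mode = "highres")
  Ph <- unclass(build_matrix(asn, reg_cn(), purity_correction = FALSE))
  expect_equal(Ph[upper.tri(Ph)], rep(0, sum(upper.tri(Ph))))
})

test_that("diagonal dominates each column at high purity", {
  for (purity in c(1, 0.99, 0.95)) {
    regs <- list(reg_c(purity), reg_cn(purity, purity))
    mols <- list(pcf_proline(),
                 molecule_spec("Asp", "LabC2C3", neutral_loss = "LabC1C2",
                               mode = "msms"),
                 molecule_spec("Asn",
                               fragment_formula(c(C = 2L),
                                                c(C = 3L, N = 2L)),
                               mode = "highres"))
    for (mol in mols) {
      reg <- if (mol$mode == "highres") regs[[2]] else regs[[1]]
      P <- unclass(build_matrix(mol, reg, purity_correction = TRUE))
      for (j in seq_len(ncol(P))) {
        expect_equal(unname(which.max(P[, j])), j,
                     info = paste(mol$name, purity, "col", j))
      }
    }
  }
})

test_that("MS/MS matrix of two single-carbon fragments matches hand expansion", {
  mol <- molecule_spec("G", "LabC1", neutral_loss = "LabC1", mode = "msms")
  P <- build_matrix(mol, reg_c())
  expect_equal(rownames(P), c("0.0", "1.0", "1.1", "2.1"))
  # column of the unlabeled species (0,0)
  expect_equal(unname(P[, "0.0"]),
               c(0.97871449, 0.01058551, 0.01058551, 0.00011449),
               tolerance = 1e-12)
  # product labeled (1,0) -> column keyed by its own bin (p,q) = (1,1)
  expect_equal(unname(P[, "1.1"]), c(0, 0, 0.9893, 0.0107),
               tolerance = 1e-12)
  # neutral loss labeled (0,1) -> bin (1,0)
  expect_equal(unname(P[, "1.0"]), c(0, 0.9893, 0, 0.0107),
               tolerance = 1e-12)
  expect_equal(unname(P[, "2.1"]), c(0, 0, 0, 1), tolerance = 1e-12)
})

test_that("an unlabelable, atom-free neutral loss reduces MS/MS to MS1", {
  reg <- reg_c()
  prod <- molecule_spec("Pro", "LabC5C7H20NO2", mode = "ms1")
  P1 <- unclass(build_matrix(prod, reg))
  # same product, neutral loss carrying no atoms at all
  nl_free <- molecule_spec("Pro", "LabC5C7H20NO2",
                           neutral_loss = midcorrect:::empty_fragment(),
                           mode = "msms")
  P2 <- unclass(build_matrix(nl_free, reg))
  expect_equal(unname(P2), unname(P1), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("marginalizing the MS/MS matrix recovers the MS1 matrices", {
  # exact when the fragment distributions have no out-of-bin mass (all
  # atoms labelable): summing rows over the precursor shift reproduces the
  # product-fragment MS1 matrix, summing over the product shift the pooled
  # molecule's
  reg <- reg_c(0.99)
  mol <- molecule_spec("Asp", "LabC2", neutral_loss = "LabC2",
                       mode = "msms")
  for (pc in c(FALSE, TRUE)) {
    P <- build_matrix(mol, reg, purity_correction = pc)
    keys <- strsplit(rownames(P), ".", fixed = TRUE)
    p_of <- vapply(keys, function(k) as.integer(k[1]), integer(1))
    q_of <- vapply(keys, function(k) as.integer(k[2]), integer(1))
    P_prod <- unclass(build_matrix(
      molecule_spec("P", "LabC2", mode = "ms1"), reg,
      purity_correction = pc))
    P_pool <- unclass(build_matrix(
      molecule_spec("M", "LabC4", mode = "ms1"), reg,
      purity_correction = pc))
    for (j in seq_len(ncol(P))) {
      expect_equal(as.numeric(tapply(P[, j], q_of, sum)),
                   unname(P_prod[, q_of[j] + 1L]), tolerance = 1e-12)
      expect_equal(as.numeric(tapply(P[, j], p_of, sum)),
                   unname(P_pool[, p_of[j] + 1L]), tolerance = 1e-12)
    }
  }

  # with plain atoms, mass leaves the neutral-loss bins and the marginal
  # over p is the product MS1 column scaled by the captured NL mass
  mol2 <- molecule_spec("Asp", "LabC2C3H6", neutral_loss = "LabC1C4O2",
                        mode = "msms")
  P2 <- build_matrix(mol2, reg, purity_correction = FALSE)
  keys2 <- strsplit(rownames(P2), ".", fixed = TRUE)
  p2 <- vapply(keys2, function(k) as.integer(k[1]), integer(1))
  q2 <- vapply(keys2, function(k) as.integer(k[2]), integer(1))
  P_prod2 <- unclass(build_matrix(
    molecule_spec("P", "LabC2C3H6", mode = "ms1"), reg,
    purity_correction = FALSE))
  nl_dist <- lapply(0:1, function(t)
    fragment_distribution(parse_formula("LabC1C4O2"), t, reg))
  nl_captured <- vapply(nl_dist, function(d)
    sum(d[names(d) %in% as.character(0:1)]), numeric(1))
  for (j in seq_len(ncol(P2))) {
    tn <- p2[j] - q2[j]
    expect_equal(as.numeric(tapply(P2[, j], q2, sum)),
                 unname(P_prod2[, q2[j] + 1L]) * nl_captured[tn + 1L],
                 tolerance = 1e-12)
  }
})

test_that("single-tracer high-resolution matrix equals MS1 when only the tracer element is present", {
  reg <- reg_c()
  ms1 <- molecule_spec("X", "LabC3C2", mode = "ms1")
  hr <- molecule_spec("X", "LabC3C2", mode = "highres")
  expect_equal(unname(unclass(build_matrix(hr, reg))),
               unname(unclass(build_matrix(ms1, reg))), tolerance = 1e-12,
               ignore_attr = TRUE)
  regp <- reg_c(0.98)
  expect_equal(
    unname(unclass(build_matrix(hr, regp, purity_correction = TRUE))),
    unname(unclass(build_matrix(ms1, regp, purity_correction = TRUE))),
    tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("matrices agree with the enumeration oracle in all modes", {
  set.seed(101)
  for (purity in c(1, 0.99, 0.98)) {
    for (mode in c("ms1", "msms", "highres")) {
      reg <- if (mode == "highres") reg_cn(purity, purity) else
        reg_c(purity)
      for (i in 1:3) {
        mol <- rand_molecule(mode, reg)
        P <- unclass(build_matrix(mol, reg, purity_correction = purity < 1))
        O <- oracle_matrix(mol, reg, purity_correction = purity < 1)
        expect_equal(dimnames(P), dimnames(O))
        expect_lt(max(abs(P - O)), 1e-12)
        expect_true(all(colSums(P) > 0 & colSums(P) <= 1 + 1e-10))
      }
    }
  }
})
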