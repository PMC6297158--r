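test_that("natural distributions match binomial/multinomial closed forms", {
  reg <- reg_c()
  # single atom returns the abundance table itself
  dO <- natural_distribution(reg$defs$O, 1)
  expect_equal(unname(dO), c(0.99757, 0.00038, 0.00205), tolerance = 1e-14)
  expect_equal(names(dO), c("0", "1", "2"))
  # empty convolution identity
  expect_equal(natural_distribution(reg$defs$C, 0), c(`0` = 1))
  # two carbons: Binom(2, 0.0107)
  dC2 <- natural_distribution(reg$defs$C, 2)
  expect_equal(unname(dC2), c(0.97871449, 0.02117102, 0.00011449),
               tolerance = 1e-14)
  # general multinomial vs direct dbinom-free expansion (3-isotope O, 2 atoms)
  dO2 <- natural_distribution(reg$defs$O, 2)
  a <- reg$defs$O$abundances
  expect_equal(unname(dO2),
               c(a[1]^2, 2 * a[1] * a[2], 2 * a[1] * a[3] + a[2]^2,
                 2 * a[2] * a[3], a[3]^2),
               tolerance = 1e-15)
})

test_that("natural distributions are additive under convolution", {
  reg <- reg_cn()
  for (el in list(reg$defs$C, reg$defs$O, reg$defs$S)) {
    for (ab in list(c(1, 1), c(2, 3), c(0, 4))) {
      expect_equal(
        natural_distribution(el, ab[1] + ab[2]),
        convolve_shift(natural_distribution(el, ab[1]),
                       natural_distribution(el, ab[2])),
        tolerance = 1e-13)
    }
  }
})

test_that("purity distributions are binomial in the labeled positions", {
  C <- element_def("C", 0:1, c(0.9893, 0.0107), tracer_shift = 1L)
  d <- purity_distribution(C, 2, 0.99)
  expect_equal(d, c(`0` = 0.0001, `1` = 0.0198, `2` = 0.9801),
               tolerance = 1e-14)
  # purity 1 reduces to the fixed-label point mass
  expect_equal(purity_distribution(C, 3, 1), c(`3` = 1))
  # tracer shift > 1 scales the support
  O18 <- element_def("O", c(0L, 1L, 2L), c(0.99757, 0.00038, 0.00205),
                     tracer_shift = 2L)
  expect_equal(purity_distribution(O18, 1, 0.97),
               c(`0` = 0.03, `2` = 0.97), tolerance = 1e-14)
  expect_error(purity_distribution(C, 2, 0), "purity")
  expect_error(purity_distribution(C, 2, 1.01), "purity")
})

test_that("convolution has identity, symmetry and mass conservation", {
  d <- c(`0` = 0.3, `1` = 0.5, `3` = 0.2)
  expect_equal(convolve_shift(c(`0` = 1), d), d)
  expect_equal(convolve_shift(c(`0` = 0.5, `1` = 0.5),
                              c(`0` = 0.5, `1` = 0.5)),
               c(`0` = 0.25, `1` = 0.5, `2` = 0.25))
  expect_equal(convolve_shift(c(`1` = 0.99, `0` = 0.01),
                              c(`0` = 0.9893, `1` = 0.0107)),
               c(`0` = 0.009893, `1` = 0.979514, `2` = 0.010593),
               tolerance = 1e-14)
  # commutative, associative, sum-preserving on random sparse distributions
  set.seed(7)
  for (i in 1:20) {
    mk <- function() {
      s <- sample(0:8, sample(2:4, 1))
      p <- stats::runif(length(s))
      setNames(p / sum(p), s)
    }
    a <- mk(); b <- mk(); c3 <- mk()
    expect_equal(convolve_shift(a, b), convolve_shift(b, a))
    expect_equal(convolve_shift(convolve_shift(a, b), c3),
                 convolve_shift(a, convolve_shift(b, c3)),
                 tolerance = 1e-14)
    expect_equal(sum(convolve_shift(a, b)), 1, tolerance = 1e-12)
  }
})

test_that("fragment distributions follow the fixed-label model", {
  reg <- reg_c()
  # one fixed label + one natural C atom
  expect_equal(fragment_distribution(parse_formula("LabC2"), 1, reg),
               c(`1` = 0.9893, `2` = 0.0107), tolerance = 1e-14)
  # all positions fixed, no other atoms
  expect_equal(fragment_distribution(parse_formula("LabC2"), 2, reg),
               c(`2` = 1))
  # impure label plus one plain C
  regp <- reg_c(purity = 0.99)
  expect_equal(
    fragment_distribution(parse_formula("LabC1C1"), 1, regp,
                          purity_correction = TRUE),
    c(`0` = 0.009893, `1` = 0.979514, `2` = 0.010593), tolerance = 1e-14)
  expect_error(fragment_distribution(parse_formula("LabC2"), 3, reg),
               "outside")
})

test_that("fragment distributions agree with exhaustive enumeration", {
  set.seed(11)
  for (purity in c(1, 0.99, 0.98)) {
    reg <- reg_c(purity = purity)
    for (i in 1:10) {
      mol <- rand_molecule("ms1", reg)
      n <- mol$product$labelable[["C"]]
      t <- sample(0:n, 1)
      eng <- fragment_distribution(mol$product, t, reg,
                                   purity_correction = purity < 1)
      ora <- oracle_fragment_distribution(mol$product, t, reg,
                                          purity_correction = purity < 1)
      shifts <- union(names(eng), names(ora))
      at <- function(d, s) ifelse(s %in% names(d), d[s], 0)
      expect_lt(max(abs(at(eng, shifts) - at(ora, shifts))), 1e-12)
      expect_equal(sum(eng), 1, tolerance = 1e-10)
    }
  }
})

test_that("high-resolution species distributions multiply per-tracer binomials", {
  asn <- molecule_spec("Asn", fragment_formula(labelable = c(C = 4L, N = 2L)),
                       mode = "highres")
  reg98 <- reg_cn(0.98, 0.98)
  d <- species_distribution_highres(asn, c(4, 2), reg98,
                                    purity_correction = TRUE)
  # losing one 13C and one 15N to impurity: product of two binomial terms
  expect_equal(d[["3.1"]], (4 * 0.98^3 * 0.02) * (2 * 0.98 * 0.02),
               tolerance = 1e-12)
  # unlabeled species, natural abundance only
  reg1 <- reg_cn()
  d0 <- species_distribution_highres(asn, c(0, 0), reg1)
  expect_equal(d0[["0.0"]], 0.9893^4 * 0.99636^2, tolerance = 1e-14)
  # fully labeled, purity off: point mass
  dfull <- species_distribution_highres(asn, c(4, 2), reg1)
  expect_equal(dfull, c(`4.2` = 1))
  expect_error(species_distribution_highres(asn, c(4, 2, 1), reg1),
               "length")
  # plain tracer atoms enter the natural-abundance envelope
  asn2 <- molecule_spec("Asn",
                        fragment_formula(c(C = 4L, H = 12L, O = 2L),
                                         c(C = 4L, N = 2L)),
                        mode = "highres")
  d2 <- species_distribution_highres(asn2, c(0, 0), reg1)
  expect_equal(d2[["0.0"]], 0.9893^8 * 0.99636^2, tolerance = 1e-14)
  # agreement with the per-atom enumeration oracle
  set.seed(13)
  for (i in 1:6) {
    mol <- rand_molecule("highres", reg98)
    cap <- midcorrect:::molecule_capacity(mol, reg98)
    lv <- vapply(cap$n_i, function(n) sample(0:n, 1), integer(1))
    eng <- species_distribution_highres(mol, lv, reg98,
                                        purity_correction = TRUE)
    ora <- oracle_highres_distribution(mol, lv, reg98,
                                       purity_correction = TRUE)
    keys <- union(names(eng), names(ora))
    at <- function(d, s) ifelse(s %in% names(d), d[s], 0)
    expect_lt(max(abs(at(eng, keys) - at(ora, keys))), 1e-12)
    expect_equal(sum(eng), 1, tolerance = 1e-10)
  }
})

test_that("maximal-shift probability is monotone in purity", {
  mol <- glycine_ms1()
  p_max <- vapply(c(1, 0.995, 0.99, 0.98, 0.95), function(pur) {
    reg <- reg_c(purity = pur)
    d <- fragment_distribution(mol$product, 2, reg,
                               purity_correction = TRUE)
    if ("2" %in% names(d)) d[["2"]] else 0
  }, numeric(1))
  expect_true(all(diff(p_max) < 0))
})
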