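#' Simulate uncorrected values from known corrected values
#'
#' Reverse application of the correction model: given the true abundances
#' `v_c` of the labeled species, the expected measured vector is
#' `v_m = P %*% v_c`. This is how uncorrected data are generated for
#' validation and for planning experiments.
#'
#' @param P A [build_matrix()] result.
#' @param v_c Non-negative truth vector of length k.
#' @return Numeric vector `v_m`, named like the rows of `P`.
#' @export
simulate_measured <- function(P, v_c) {
  Pm <- unclass(P)
  if (length(v_c) != ncol(Pm)) {
    stop("truth vector length ", length(v_c), " != k = ", ncol(Pm),
         call. = FALSE)
  }
  if (any(v_c < 0)) stop("truth vector must be non-negative", call. = FALSE)
  stats::setNames(as.numeric(Pm %*% v_c), rownames(Pm))
}

#' Alanine isotopomer mixture fixtures
#'
#' Four mixtures of alanine isotopomers with known composition, used to
#' validate the correction experimentally. Concentrations are in uM. The
#' two singly labeled isotopomers (1-13C and 3-13C alanine) are pooled into
#' the m+1 component: they are indistinguishable at nominal resolution but
#' both contribute to the m+1 signal.
#'
#' @param id Mixture number, 1 to 4.
#' @return A list of class `mixture_spec` with `concentrations` (named
#'   `m0` ... `m3`, uM) and `fractions` (same names, summing to 1).
#' @export
#' @examples
#' alanine_mixture(2)$fractions  # 0.2 0.4 0.2 0.2
alanine_mixture <- function(id) {
  if (!id %in% 1:4) stop("mixture id must be 1..4", call. = FALSE)
  # rows: unlabeled, 1-13C, 3-13C, 13C2, 13C3; columns: mixtures 1..4
  conc <- matrix(c(50.000, 20.000, 10.000, 100.000,
                   12.500, 20.000, 20.000, 1.000,
                   12.500, 20.000, 40.000, 1.000,
                   3.125, 20.000, 10.000, 1.000,
                   0.781, 20.000, 30.000, 1.000),
                 nrow = 5, byrow = TRUE)
  v <- conc[, id]
  pooled <- c(m0 = v[1], m1 = v[2] + v[3], m2 = v[4], m3 = v[5])
  structure(list(id = id, concentrations = pooled,
                 fractions = pooled / sum(pooled)),
            class = "mixture_spec")
}

#' Default TMS-alanine molecule
#'
#' Silylated alanine as measured by GC-MS: three labelable alanine carbons
#' plus the atoms of `n_tms` trimethylsilyl groups. The exact derivative is
#' a parameter because it affects only the plain-atom envelope.
#'
#' @param n_tms Number of TMS groups (default 2).
#' @return A [molecule_spec()] in MS1 mode.
#' @export
tms_alanine <- function(n_tms = 2L) {
  plain <- c(C = 3L * n_tms, H = 7L + 8L * n_tms, N = 1L, O = 2L,
             Si = n_tms)
  molecule_spec("Ala", fragment_formula(plain, c(C = 3L)), mode = "ms1")
}

#' Uncorrected m+0/m+1 ratio versus elemental composition
#'
#' For hypothetical molecules with one labelable carbon and a varying
#' number of total carbon and silicon atoms, the true m+0 and m+1
#' abundances are set equal (ratio 1) and the uncorrected ratio that would
#' actually be measured is computed by forward simulation. The deviation
#' from 1 grows with the number of atoms of elements with abundant heavy
#' isotopes.
#'
#' @param n_carbon Integer vector of total carbon counts (each >= 1; one
#'   carbon is the labelable position).
#' @param n_silicon Integer vector of silicon counts.
#' @param registry Element registry (default [default_elements()] with a
#'   pure 13C tracer).
#' @return A tibble with columns `n_carbon`, `n_silicon`,
#'   `uncorrected_ratio`.
#' @export
#' @examples
#' composition_series(n_carbon = c(1, 5, 10), n_silicon = 0)
composition_series <- function(n_carbon = 1:10, n_silicon = 0:3,
                               registry = default_elements(tracers = "C")) {
  grid <- expand.grid(n_carbon = as.integer(n_carbon),
                      n_silicon = as.integer(n_silicon),
                      KEEP.OUT.ATTRS = FALSE)
  if (any(grid$n_carbon < 1L)) {
    stop("n_carbon must be >= 1 (the labelable position)", call. = FALSE)
  }
  ratio <- purrr::map2_dbl(grid$n_carbon, grid$n_silicon, function(nc, ns) {
    plain <- c(C = nc - 1L, Si = ns)
    mol <- molecule_spec("X", fragment_formula(plain, c(C = 1L)),
                         mode = "ms1")
    P <- build_matrix(mol, registry, purity_correction = FALSE)
    v_m <- simulate_measured(P, c(1, 1))
    v_m[1] / v_m[2]
  })
  tibble::tibble(n_carbon = grid$n_carbon, n_silicon = grid$n_silicon,
                 uncorrected_ratio = ratio)
}

#' High-resolution multiple-tracer demonstration scenario
#'
#' A simultaneous 13C/15N labeling scenario on an asparagine-like molecule
#' (4 labelable carbons, 2 labelable nitrogens, plus a plain derivative
#' backbone). The truth vector concentrates abundance on highly labeled
#' states so that tracer impurity of both tracers feeds signal into the
#' flanking states (most visibly 3/1, which receives a 13C impurity
#' contribution from 4/1 and a 15N impurity contribution from 3/2).
#' Measured data are simulated at the given tracer purities.
#'
#' @param purity Named vector of tracer purities (default
#'   `c(C = 0.98, N = 0.98)`).
#' @return A list of class `synthetic_dataset`: `molecule`, `registry`,
#'   `truth` and `measured` (measurement tibbles with one `sim` sample
#'   column), `P` (the generating matrix) and `provenance`.
#' @export
multitracer_scenario <- function(purity = c(C = 0.98, N = 0.98)) {
  registry <- default_elements(tracers = c("C", "N"), purity = purity)
  mol <- molecule_spec("Asn",
                       fragment_formula(c(C = 4L, H = 12L, O = 2L),
                                        c(C = 4L, N = 2L)),
                       mode = "highres")
  P <- build_matrix(mol, registry, purity_correction = TRUE)
  truth <- stats::setNames(rep(0, nrow(P)), rownames(P))
  truth[c("0.0", "3.0", "3.1", "3.2", "4.1", "4.2")] <-
    c(20, 2, 2, 30, 30, 100)
  v_m <- simulate_measured(P, truth)
  keys <- paste0(mol$name, "_", rownames(P))
  structure(
    list(molecule = mol, registry = registry,
         truth = tibble::tibble(Measurement = keys, sim = as.numeric(truth)),
         measured = tibble::tibble(Measurement = keys,
                                   sim = as.numeric(v_m)),
         P = P,
         provenance = list(kind = "multitracer_scenario", purity = purity)),
    class = "synthetic_dataset")
}

#' Generate a random synthetic labeling dataset
#'
#' Draws non-negative truth vectors (independent exponential abundances,
#' mean 100 arbitrary units), simulates the corresponding uncorrected
#' measurements through the molecule's correction matrix, and optionally
#' degrades them with relative Gaussian noise truncated at zero. Fully
#' reproducible from the seed.
#'
#' @param seed Integer random seed (required).
#' @param mode Correction mode of `molecule`.
#' @param molecule A [molecule_spec()].
#' @param registry An [element_registry()].
#' @param n_samples Number of samples to draw.
#' @param noise_sd Relative standard deviation of the measurement noise
#'   (0 = noise-free).
#' @param purity_correction Logical: build the generating matrix with
#'   tracer-impurity weighting.
#' @return A `synthetic_dataset` list: `truth`, `measured` (measurement
#'   tibbles, sample columns `S1` ...), `P`, `molecule`, `registry`,
#'   `provenance`.
#' @export
random_dataset <- function(seed, mode, molecule, registry, n_samples = 3L,
                           noise_sd = 0, purity_correction = TRUE) {
  if (missing(seed) || is.na(seed)) stop("an explicit seed is required",
                                         call. = FALSE)
  stopifnot(inherits(molecule, "molecule_spec"), molecule$mode == mode)
  set.seed(as.integer(seed))
  P <- build_matrix(molecule, registry, purity_correction)
  k <- nrow(P)
  keys <- paste0(molecule$name, "_", rownames(P))
  truth <- tibble::tibble(Measurement = keys)
  measured <- tibble::tibble(Measurement = keys)
  for (i in seq_len(n_samples)) {
    v_c <- stats::rexp(k, rate = 1 / 100)
    v_m <- simulate_measured(P, v_c)
    if (noise_sd > 0) {
      v_m <- pmax(0, v_m + stats::rnorm(k, 0, noise_sd * v_m))
    }
    truth[[paste0("S", i)]] <- v_c
    measured[[paste0("S", i)]] <- as.numeric(v_m)
  }
  structure(
    list(truth = truth, measured = measured, P = P, molecule = molecule,
         registry = registry,
         provenance = list(kind = "random_dataset", seed = seed,
                           noise_sd = noise_sd, n_samples = n_samples,
                           purity_correction = purity_correction)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", x$molecule$name, " [", x$molecule$mode,
      "], k = ", nrow(x$P), ", ",
      ncol(x$truth) - 1L, " sample(s)\n", sep = "")
  invisible(x)
}

#' Simulate a measurement table for an alanine mixture
#'
#' Builds the TMS-alanine correction matrix at the given tracer purity and
#' forward-simulates the uncorrected signals that the mixture would
#' produce.
#'
#' @param mixture A [alanine_mixture()] result (or id 1..4).
#' @param purity 13C purity of the tracer substrate used in the simulation.
#' @param molecule The derivatized molecule (default [tms_alanine()]).
#' @return A `synthetic_dataset` with one sample column `sim`.
#' @export
simulate_mixture <- function(mixture, purity = 0.99,
                             molecule = tms_alanine()) {
  if (is.numeric(mixture)) mixture <- alanine_mixture(mixture)
  stopifnot(inherits(mixture, "mixture_spec"))
  registry <- default_elements(tracers = "C", purity = c(C = purity))
  P <- build_matrix(molecule, registry, purity_correction = TRUE)
  v_c <- unname(mixture$concentrations)
  v_m <- simulate_measured(P, v_c)
  keys <- paste0(molecule$name, "_", rownames(P))
  structure(
    list(molecule = molecule, registry = registry,
         truth = tibble::tibble(Measurement = keys, sim = v_c),
         measured = tibble::tibble(Measurement = keys,
                                   sim = as.numeric(v_m)),
         P = P,
         provenance = list(kind = "mixture", id = mixture$id,
                           purity = purity)),
    class = "synthetic_dataset")
}
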