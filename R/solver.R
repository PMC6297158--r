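#' Correct one measured vector
#'
#' Solves `v_m = P %*% v_c` for the corrected abundances `v_c` under the
#' constraint `v_c >= 0` (negative corrected values can otherwise arise
#' from inaccurate measurements of low-abundance signals). The solve is a
#' non-negative least squares fit (Lawson-Hanson): `v_c` minimises
#' `||P %*% v_c - v_m||_2` subject to `v_c >= 0`, so when the unconstrained
#' solution is already non-negative it is returned exactly.
#'
#' @param P A [build_matrix()] result (or any k-by-k numeric matrix).
#' @param v_m Numeric measurement vector of length k, finite and
#'   non-negative.
#' @return A list with `v_c` (corrected vector, named like the columns of
#'   `P`), `residual_rel` (`||P v_c - v_m|| / ||v_m||`, 0 for an all-zero
#'   `v_m`) and `warnings` (character).
#' @export
#' @examples
#' reg <- default_elements(tracers = "C")
#' P <- build_matrix(molecule_spec("Gly", "LabC2", mode = "ms1"), reg)
#' correct_vector(P, as.vector(P %*% c(100, 50, 20)))
correct_vector <- function(P, v_m) {
  Pm <- unclass(P)
  k <- nrow(Pm)
  if (length(v_m) != k) {
    stop("measurement vector length ", length(v_m), " != k = ", k,
         call. = FALSE)
  }
  if (any(!is.finite(v_m))) {
    stop("measurement vector must be finite (apply the missing-value ",
         "policy first)", call. = FALSE)
  }
  if (any(v_m < 0)) {
    stop("measurement vector must be non-negative (negatives are clamped ",
         "during validation)", call. = FALSE)
  }
  warnings <- character()
  if (all(v_m == 0)) {
    return(list(v_c = stats::setNames(rep(0, k), colnames(Pm)),
                residual_rel = 0,
                warnings = "all-zero measurement vector"))
  }
  cond <- tryCatch(kappa(Pm, exact = FALSE), error = function(e) Inf)
  if (!is.finite(cond) || cond > 1e12) {
    warnings <- c(warnings,
                  sprintf("ill-conditioned correction matrix (condition estimate %.3g)",
                          cond))
  }
  fit <- pracma::lsqnonneg(Pm, as.numeric(v_m))
  v_c <- pmax(fit$x, 0)  # guard against -0 / tiny negative round-off
  resid <- Pm %*% v_c - v_m
  list(v_c = stats::setNames(as.numeric(v_c), colnames(Pm)),
       residual_rel = sqrt(sum(resid^2)) / sqrt(sum(v_m^2)),
       warnings = warnings)
}

#' Isotopologue fractions of a corrected vector
#'
#' @param v_c Non-negative corrected vector.
#' @return `v_c / sum(v_c)`; a vector of `NA` when the sum is zero (the
#'   fractional composition is then undefined).
#' @export
fractions <- function(v_c) {
  if (any(v_c < 0)) stop("corrected vector must be non-negative",
                         call. = FALSE)
  s <- sum(v_c)
  if (s == 0) return(stats::setNames(rep(NA_real_, length(v_c)),
                                     names(v_c)))
  v_c / s
}

#' Mean tracer enrichment
#'
#' The average fraction of labelable positions carrying the tracer:
#' `sum_j t_i(j) * f_j / n_i` per tracer element `i`, where `t_i(j)` is the
#' label count of state `j` and `n_i` the label capacity.
#'
#' @param f Fraction vector over label states (sums to 1).
#' @param label_counts k-by-r matrix of per-tracer label counts per state.
#' @param n_per_tracer Length-r vector of label capacities (each >= 1).
#' @return Named numeric vector of per-tracer enrichments in \[0, 1\].
#' @export
mean_enrichment <- function(f, label_counts, n_per_tracer) {
  label_counts <- as.matrix(label_counts)
  stopifnot(nrow(label_counts) == length(f),
            ncol(label_counts) == length(n_per_tracer),
            all(n_per_tracer >= 1))
  if (anyNA(f)) {
    return(stats::setNames(rep(NA_real_, length(n_per_tracer)),
                           colnames(label_counts)))
  }
  stats::setNames(as.numeric(crossprod(label_counts, f)) / n_per_tracer,
                  colnames(label_counts))
}

#' Correct a full measurement table
#'
#' The batch driver: builds each molecule's correction matrix once, then
#' deconvolves every sample column. Returns a fitted object whose tidy
#' accessors expose corrected values, isotopologue fractions, mean
#' enrichment and residual diagnostics as tibbles.
#'
#' @param measurements A measurement tibble as returned by
#'   [read_measurements()]: a `Measurement` key column
#'   (`<Molecule>_<state>`) plus one numeric column per sample.
#' @param molecules List of [molecule_spec()] objects.
#' @param registry An [element_registry()].
#' @param purity_correction Logical: correct for tracer impurity (default
#'   `TRUE`; purities of 1 make it a no-op).
#' @param strict_na If `FALSE` (default) missing cells are replaced by 0
#'   with a logged warning; if `TRUE` a molecule/sample with any missing
#'   cell yields an all-missing result.
#' @param residual_warn Relative-residual threshold above which a
#'   data-quality warning is recorded (default 0.05).
#' @return An object of class `mid_correction`. Use [tidy()][generics::tidy]
#'   for the per-state results, [glance()][generics::glance] for per
#'   molecule-sample diagnostics, `$warnings` for the run log, and
#'   [autoplot()][ggplot2::autoplot] to plot corrected fractions.
#' @export
correct_dataset <- function(measurements, molecules, registry,
                            purity_correction = TRUE, strict_na = FALSE,
                            residual_warn = 0.05) {
  findings <- validate_inputs(registry, molecules, measurements)
  errs <- findings$message[findings$severity == "error"]
  if (length(errs)) {
    stop("input validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  warnings <- findings$message[findings$severity == "warning"]
  samples <- setdiff(names(measurements), "Measurement")
  key_split <- split_keys(measurements$Measurement)
  rows <- list()
  diagnostics <- list()
  enrich <- list()
  matrices <- list()
  for (mol in molecules) {
    P <- build_matrix(mol, registry, purity_correction)
    matrices[[mol$name]] <- P
    dropped <- attr(P, "dropped")
    big_drop <- dropped > 1e-6
    if (any(big_drop)) {
      warnings <- c(warnings, sprintf(
        "%s: %.3g of the distribution of state %s falls outside the measured bins",
        mol$name, dropped[big_drop], colnames(P)[big_drop]))
    }
    states <- rownames(P)
    idx <- match(paste0(mol$name, "_", states), measurements$Measurement)
    for (smp in samples) {
      v_raw <- measurements[[smp]][idx]
      n_missing <- sum(is.na(v_raw))
      if (n_missing > 0L) {
        if (strict_na) {
          warnings <- c(warnings, sprintf(
            "%s / %s: %d missing value(s); result withheld (strict_na)",
            mol$name, smp, n_missing))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            molecule = mol$name, state = states, sample = smp,
            measured = v_raw, corrected = NA_real_, fraction = NA_real_)
          diagnostics[[length(diagnostics) + 1L]] <- tibble::tibble(
            molecule = mol$name, sample = smp, residual_rel = NA_real_)
          enrich[[length(enrich) + 1L]] <- tibble::tibble(
            molecule = mol$name, sample = smp,
            tracer = attr(P, "tracers"), mean_enrichment = NA_real_)
          next
        }
        warnings <- c(warnings, sprintf(
          "%s / %s: %d missing value(s) replaced by 0", mol$name, smp,
          n_missing))
        v_raw[is.na(v_raw)] <- 0
      }
      v_m <- pmax(v_raw, 0)
      sol <- correct_vector(P, v_m)
      if (length(sol$warnings)) {
        warnings <- c(warnings,
                      paste0(mol$name, " / ", smp, ": ", sol$warnings))
      }
      if (is.finite(sol$residual_rel) && sol$residual_rel > residual_warn) {
        warnings <- c(warnings, sprintf(
          "%s / %s: relative residual %.4g exceeds %.3g - check data quality",
          mol$name, smp, sol$residual_rel, residual_warn))
      }
      f <- fractions(sol$v_c)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        molecule = mol$name, state = states, sample = smp,
        measured = as.numeric(v_m), corrected = as.numeric(sol$v_c),
        fraction = as.numeric(f))
      diagnostics[[length(diagnostics) + 1L]] <- tibble::tibble(
        molecule = mol$name, sample = smp,
        residual_rel = sol$residual_rel)
      me <- mean_enrichment(f, attr(P, "label_counts"),
                            attr(P, "n_per_tracer"))
      enrich[[length(enrich) + 1L]] <- tibble::tibble(
        molecule = mol$name, sample = smp, tracer = names(me),
        mean_enrichment = as.numeric(me))
    }
  }
  structure(
    list(results = dplyr::bind_rows(rows),
         diagnostics = dplyr::bind_rows(diagnostics),
         enrichment = dplyr::bind_rows(enrich),
         warnings = warnings,
         matrices = matrices,
         samples = samples,
         options = list(purity_correction = purity_correction,
                        strict_na = strict_na,
                        residual_warn = residual_warn)),
    class = "mid_correction")
}

#' @export
print.mid_correction <- function(x, ...) {
  cat("<mid_correction> ", length(x$matrices), " molecule(s) x ",
      length(x$samples), " sample(s)", sep = "")
  if (length(x$warnings)) cat("; ", length(x$warnings), " warning(s)",
                              sep = "")
  cat("\n")
  print(x$results, n = 10)
  invisible(x)
}

#' Tidy a correction fit
#'
#' @param x A `mid_correction` object.
#' @param ... Unused.
#' @return A tibble with one row per molecule x state x sample:
#'   `measured`, `corrected` and `fraction` columns.
#' @export
tidy.mid_correction <- function(x, ...) x$results

#' One-row-per-fit diagnostics of a correction
#'
#' @param x A `mid_correction` object.
#' @param ... Unused.
#' @return A tibble with one row per molecule x sample: relative residual
#'   and per-tracer mean enrichment (wide, `enrichment_<El>` columns).
#' @export
glance.mid_correction <- function(x, ...) {
  en <- tidyr::pivot_wider(x$enrichment, names_from = "tracer",
                           values_from = "mean_enrichment",
                           names_prefix = "enrichment_")
  dplyr::left_join(x$diagnostics, en, by = c("molecule", "sample"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
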