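#' Read a measurement table
#'
#' CSV with header `Measurement,<sample1>,<sample2>,...`. Row keys follow
#' the grammar `<Molecule>_<state>` where the state is a label count
#' (`Pro_0` ... `Pro_5`) in MS1 mode, a precursor.product shift pair
#' (`Asp_3.2`) in MS/MS mode, or a dot-joined label-count vector
#' (`Asn_3.1`) in high-resolution mode. Empty cells are missing values.
#'
#' @param path Path to the CSV file.
#' @param molecules Optional list of [molecule_spec()] objects; if given,
#'   keys are checked to refer to known molecules and valid states.
#' @param registry Required when `molecules` is given: the
#'   [element_registry()] used to derive each molecule's expected states.
#' @return A tibble with a character `Measurement` column and one numeric
#'   column per sample.
#' @export
read_measurements <- function(path, molecules = NULL, registry = NULL) {
  if (!file.exists(path)) {
    stop("measurement file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    Measurement = "c", .default = "d"), progress = FALSE,
    na = c("", "NA"))
  if (names(df)[1] != "Measurement") {
    stop("measurement file must start with a Measurement column",
         call. = FALSE)
  }
  keys <- split_keys(df$Measurement)
  bad <- which(is.na(keys$molecule) | !nzchar(keys$molecule) |
                 is.na(keys$state) | !grepl("^[0-9]+(\\.[0-9]+)*$",
                                            keys$state))
  if (length(bad)) {
    stop("unparseable measurement key on line ", bad[1] + 1L, ": ",
         df$Measurement[bad[1]], call. = FALSE)
  }
  dup <- which(duplicated(df$Measurement))
  if (length(dup)) {
    stop("duplicate measurement key on line ", dup[1] + 1L, ": ",
         df$Measurement[dup[1]], call. = FALSE)
  }
  if (!is.null(molecules)) {
    stopifnot(!is.null(registry))
    findings <- validate_inputs(registry, molecules, df)
    errs <- findings$message[findings$severity == "error"]
    if (length(errs)) {
      stop("invalid measurement table:\n  ",
           paste(errs, collapse = "\n  "), call. = FALSE)
    }
  }
  df
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()]: missing values become empty cells,
#' numbers are serialized with 10 significant digits.
#'
#' @param measurements Measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- measurements
  for (cn in setdiff(names(out), "Measurement")) {
    out[[cn]] <- format_num(out[[cn]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write correction results to a directory
#'
#' Writes four CSV tables plus a run log: `corrected.csv` (corrected
#' values), `corrected_fractions.csv` (isotopologue fractions),
#' `mean_enrichment.csv` (per-tracer mean enrichment),
#' `residuals.csv` (relative residual per molecule and sample) and
#' `run.log` (all warnings). Tables are wide (rows = keys or molecules,
#' columns = samples), numbers carry 10 significant digits, missing values
#' are empty cells. Output is byte-identical across repeated runs on the
#' same input.
#'
#' @param fit A `mid_correction` object from [correct_dataset()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of the five file paths, invisibly.
#' @export
write_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "mid_correction"))
  if (nrow(fit$results) == 0L) stop("empty result set", call. = FALSE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  wide <- function(df, value) {
    df$Measurement <- paste0(df$molecule, "_", df$state)
    w <- tidyr::pivot_wider(df[, c("Measurement", "sample", value)],
                            names_from = "sample",
                            values_from = dplyr::all_of(value))
    for (cn in setdiff(names(w), "Measurement")) w[[cn]] <- format_num(w[[cn]])
    w
  }
  paths <- file.path(out_dir, c("corrected.csv", "corrected_fractions.csv",
                                "mean_enrichment.csv", "residuals.csv",
                                "run.log"))
  readr::write_csv(wide(fit$results, "corrected"), paths[1], na = "",
                   progress = FALSE)
  readr::write_csv(wide(fit$results, "fraction"), paths[2], na = "",
                   progress = FALSE)
  en <- fit$enrichment
  en$key <- paste0(en$molecule, ".", en$tracer)
  enw <- tidyr::pivot_wider(en[, c("key", "sample", "mean_enrichment")],
                            names_from = "sample",
                            values_from = "mean_enrichment")
  names(enw)[1] <- "Molecule.Tracer"
  for (cn in setdiff(names(enw), "Molecule.Tracer")) {
    enw[[cn]] <- format_num(enw[[cn]])
  }
  readr::write_csv(enw, paths[3], na = "", progress = FALSE)
  rw <- tidyr::pivot_wider(fit$diagnostics, names_from = "sample",
                           values_from = "residual_rel")
  names(rw)[1] <- "Molecule"
  for (cn in setdiff(names(rw), "Molecule")) rw[[cn]] <- format_num(rw[[cn]])
  readr::write_csv(rw, paths[4], na = "", progress = FALSE)
  log_lines <- if (length(fit$warnings)) fit$warnings else
    "no warnings"
  writeLines(log_lines, paths[5])
  invisible(paths)
}

#' Plot corrected isotopologue fractions
#'
#' Grouped bar chart of corrected fractions per label state, faceted by
#' molecule, one bar group per sample — the standard way mass isotopomer
#' distributions are displayed.
#'
#' @param object A `mid_correction` object.
#' @param molecules Optional character vector restricting the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mid_correction <- function(object, molecules = NULL, ...) {
  df <- object$results
  if (!is.null(molecules)) df <- df[df$molecule %in% molecules, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$fraction,
                                   fill = .data$sample)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(ggplot2::vars(.data$molecule), scales = "free_x") +
    ggplot2::labs(x = "label state", y = "corrected fraction",
                  fill = "sample") +
    ggplot2::theme_minimal()
}

#' Compare measured and corrected fractions
#'
#' Side-by-side bars of the fractional measured (uncorrected) signal and
#' the corrected isotopologue fraction for one molecule and sample,
#' mirroring how the effect of natural-abundance/purity correction is
#' usually assessed.
#'
#' @param fit A `mid_correction` object.
#' @param molecule Molecule name.
#' @param sample Sample name (default: first sample).
#' @return A ggplot object.
#' @export
plot_correction_effect <- function(fit, molecule, sample = NULL) {
  df <- fit$results[fit$results$molecule == molecule, ]
  if (is.null(sample)) sample <- df$sample[1]
  df <- df[df$sample == sample, ]
  if (!nrow(df)) stop("no results for ", molecule, " / ", sample,
                      call. = FALSE)
  df <- df |>
    dplyr::mutate(measured_fraction = .data$measured /
                    sum(.data$measured)) |>
    tidyr::pivot_longer(c("measured_fraction", "fraction"),
                        names_to = "kind", values_to = "value") |>
    dplyr::mutate(kind = ifelse(.data$kind == "fraction", "corrected",
                                "uncorrected"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$value,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(title = paste0(molecule, " / ", sample),
                  x = "label state", y = "fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
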