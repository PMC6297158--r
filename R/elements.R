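#' Define an element and its isotope abundance table
#'
#' An element definition lists the nominal mass shifts of its stable isotopes
#' relative to the lightest isotope, together with their natural abundances,
#' and optionally designates one isotope as a tracer (with an isotopic purity
#' of the tracer substrate).
#'
#' @param symbol Element symbol, e.g. `"C"` (uppercase letter plus optional
#'   lowercase letter).
#' @param shifts Integer vector of nominal mass shifts; must contain 0 and be
#'   unique.
#' @param abundances Numeric vector of natural abundance fractions, same
#'   length as `shifts`; must sum to 1 (tolerance `1e-6` on input, stored
#'   values renormalised to machine precision).
#' @param tracer_shift Optional positive integer: the nominal mass shift of
#'   the tracer isotope (must appear in `shifts`). `NA` means the element is
#'   not a tracer.
#' @param tracer_purity Optional fraction in (0, 1]: probability that a
#'   nominally labeled position of the tracer substrate actually carries the
#'   tracer isotope. Only allowed together with `tracer_shift`.
#'
#' @return An object of class `element_def`.
#' @export
#' @examples
#' element_def("C", c(0L, 1L), c(0.9893, 0.0107), tracer_shift = 1L,
#'             tracer_purity = 0.99)
element_def <- function(symbol, shifts, abundances,
                        tracer_shift = NA_integer_, tracer_purity = NA_real_) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  if (!grepl("^[A-Z][a-z]?$", symbol)) {
    stop("invalid element symbol: ", symbol, call. = FALSE)
  }
  shifts <- as.integer(shifts)
  abundances <- as.numeric(abundances)
  if (length(shifts) != length(abundances) || length(shifts) == 0L) {
    stop("shifts and abundances must be non-empty and of equal length",
         call. = FALSE)
  }
  if (anyDuplicated(shifts)) {
    stop("duplicate isotope shift for element ", symbol, call. = FALSE)
  }
  if (!0L %in% shifts) {
    stop("isotope shifts for ", symbol, " must include 0", call. = FALSE)
  }
  if (any(shifts < 0L)) stop("negative isotope shift", call. = FALSE)
  if (any(abundances < 0 | abundances > 1)) {
    stop("abundances must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(abundances)
  if (abs(s - 1) > 1e-6) {
    stop("abundances for ", symbol, " sum to ", format(s),
         ", expected 1", call. = FALSE)
  }
  abundances <- abundances / s
  ord <- order(shifts)
  shifts <- shifts[ord]
  abundances <- abundances[ord]
  if (!is.na(tracer_shift)) {
    tracer_shift <- as.integer(tracer_shift)
    if (tracer_shift <= 0L || !tracer_shift %in% shifts) {
      stop("tracer_shift for ", symbol,
           " must be a positive shift present in the isotope table",
           call. = FALSE)
    }
    if (!is.na(tracer_purity) &&
        (tracer_purity <= 0 || tracer_purity > 1)) {
      stop("tracer_purity must lie in (0, 1]", call. = FALSE)
    }
  } else if (!is.na(tracer_purity)) {
    stop("tracer_purity given for non-tracer element ", symbol, call. = FALSE)
  }
  structure(
    list(symbol = symbol, shifts = shifts, abundances = abundances,
         tracer_shift = if (is.na(tracer_shift)) NA_integer_ else tracer_shift,
         tracer_purity = tracer_purity),
    class = "element_def"
  )
}

#' @export
print.element_def <- function(x, ...) {
  iso <- paste0("+", x$shifts, ":", signif(x$abundances, 6), collapse = " ")
  cat("<element_def> ", x$symbol, "  ", iso, sep = "")
  if (!is.na(x$tracer_shift)) {
    cat("  tracer shift ", x$tracer_shift, sep = "")
    if (!is.na(x$tracer_purity)) cat(" purity ", x$tracer_purity, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build an element registry
#'
#' A registry collects element definitions and records which elements are
#' tracers, in the order they were defined (this order fixes the component
#' order of label-count vectors in high-resolution mode).
#'
#' @param defs List of [element_def()] objects.
#' @return An object of class `element_registry` with fields `defs` (named
#'   list) and `tracer_order` (character vector of tracer element symbols).
#' @export
element_registry <- function(defs) {
  stopifnot(is.list(defs), length(defs) > 0L)
  ok <- vapply(defs, inherits, logical(1), "element_def")
  if (!all(ok)) stop("all entries must be element_def objects", call. = FALSE)
  syms <- vapply(defs, `[[`, character(1), "symbol")
  if (anyDuplicated(syms)) {
    stop("duplicate element definition: ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "), call. = FALSE)
  }
  names(defs) <- syms
  tracer_order <- syms[!vapply(defs, function(d) is.na(d$tracer_shift),
                               logical(1))]
  structure(list(defs = defs, tracer_order = tracer_order),
            class = "element_registry")
}

#' @export
print.element_registry <- function(x, ...) {
  cat("<element_registry> ", length(x$defs), " elements",
      if (length(x$tracer_order))
        paste0("; tracers: ", paste(x$tracer_order, collapse = ", ")),
      "\n", sep = "")
  for (d in x$defs) print(d)
  invisible(x)
}

registry_element <- function(registry, symbol) {
  d <- registry$defs[[symbol]]
  if (is.null(d)) stop("element ", symbol, " not in registry", call. = FALSE)
  d
}

#' Default element table
#'
#' Natural abundances of the elements commonly encountered in derivatized
#' metabolites (C, H, N, O, Si, S), with 13C and 15N set up as tracers at
#' purity 1 by default. Values are the community-standard (IUPAC-style)
#' isotopic compositions.
#'
#' @param tracers Character vector of element symbols to mark as tracers
#'   (subset of C, N, H, O, S). Default `c("C", "N")`.
#' @param purity Named numeric vector of tracer purities, e.g.
#'   `c(C = 0.99)`; elements not named get purity 1.
#' @return An `element_registry`.
#' @export
#' @examples
#' default_elements(tracers = "C", purity = c(C = 0.99))
default_elements <- function(tracers = c("C", "N"), purity = numeric()) {
  tabs <- list(
    C  = list(shifts = c(0L, 1L), ab = c(0.9893, 0.0107), tshift = 1L),
    H  = list(shifts = c(0L, 1L), ab = c(0.999885, 0.000115), tshift = 1L),
    N  = list(shifts = c(0L, 1L), ab = c(0.99636, 0.00364), tshift = 1L),
    O  = list(shifts = c(0L, 1L, 2L), ab = c(0.99757, 0.00038, 0.00205),
              tshift = 2L),
    Si = list(shifts = c(0L, 1L, 2L), ab = c(0.92223, 0.04685, 0.03092),
              tshift = NA_integer_),
    S  = list(shifts = c(0L, 1L, 2L, 4L), ab = c(0.9499, 0.0075, 0.0425, 1e-4),
              tshift = 2L)
  )
  bad <- setdiff(tracers, names(tabs)[!vapply(tabs, function(t)
    is.na(t$tshift), logical(1))])
  if (length(bad)) {
    stop("no default tracer isotope for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defs <- lapply(names(tabs), function(sym) {
    t <- tabs[[sym]]
    is_tracer <- sym %in% tracers
    element_def(sym, t$shifts, t$ab,
                tracer_shift = if (is_tracer) t$tshift else NA_integer_,
                tracer_purity = if (is_tracer) {
                  if (sym %in% names(purity)) purity[[sym]] else 1
                } else NA_real_)
  })
  element_registry(defs)
}

#' Read an element definition file
#'
#' The file is a CSV with header `Element,Isotopes,TracerShift,TracerPurity`.
#' `Isotopes` is a semicolon-joined list of `shift:abundance` pairs; empty
#' `TracerShift` / `TracerPurity` cells mean the element is not a tracer.
#'
#' @param path Path to the CSV file.
#' @return An `element_registry`.
#' @export
read_elements <- function(path) {
  if (!file.exists(path)) stop("element file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("Element", "Isotopes", "TracerShift", "TracerPurity")
  if (!all(need %in% names(df))) {
    stop("element file must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  defs <- purrr::map(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    pairs <- strsplit(row$Isotopes, ";", fixed = TRUE)[[1]]
    parsed <- strsplit(pairs, ":", fixed = TRUE)
    bad <- vapply(parsed, length, integer(1)) != 2L
    if (length(pairs) == 0L || any(bad)) {
      stop("malformed Isotopes field on line ", i + 1L, ": ",
           row$Isotopes, call. = FALSE)
    }
    shifts <- suppressWarnings(as.integer(vapply(parsed, `[[`, "", 1L)))
    ab <- suppressWarnings(as.numeric(vapply(parsed, `[[`, "", 2L)))
    if (anyNA(shifts) || anyNA(ab)) {
      stop("malformed Isotopes field on line ", i + 1L, ": ",
           row$Isotopes, call. = FALSE)
    }
    tshift <- if (is.na(row$TracerShift) || row$TracerShift == "") {
      NA_integer_
    } else suppressWarnings(as.integer(row$TracerShift))
    tpur <- if (is.na(row$TracerPurity) || row$TracerPurity == "") {
      NA_real_
    } else suppressWarnings(as.numeric(row$TracerPurity))
    if ((!is.na(row$TracerShift) && row$TracerShift != "" && is.na(tshift)) ||
        (!is.na(row$TracerPurity) && row$TracerPurity != "" && is.na(tpur))) {
      stop("malformed tracer field on line ", i + 1L, call. = FALSE)
    }
    tryCatch(
      element_def(row$Element, shifts, ab, tracer_shift = tshift,
                  tracer_purity = tpur),
      error = function(e) {
        stop("line ", i + 1L, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  element_registry(defs)
}

#' Write an element registry to CSV
#'
#' Inverse of [read_elements()]; used by the simulator to emit
#' self-contained scenario bundles.
#'
#' @param registry An `element_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_elements <- function(registry, path) {
  stopifnot(inherits(registry, "element_registry"))
  rows <- purrr::map(registry$defs, function(d) {
    tibble::tibble(
      Element = d$symbol,
      Isotopes = paste0(d$shifts, ":", format_num(d$abundances),
                        collapse = ";"),
      TracerShift = if (is.na(d$tracer_shift)) "" else
        as.character(d$tracer_shift),
      TracerPurity = if (is.na(d$tracer_purity)) "" else
        format_num(d$tracer_purity)
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

# 10 significant digits, "." decimal separator, no scientific notation drift
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(signif(v, 10), scientific = FALSE,
                                 trim = TRUE, digits = 10)
  }, character(1))
  out
}
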