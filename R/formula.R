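#' Parse a fragment formula
#'
#' The formula grammar distinguishes metabolically labelable positions from
#' plain (non-labelable) atoms: a token `LabC5` declares five labelable
#' carbons, a token `C7` seven plain carbons. Counts default to 1 and
#' repeated tokens for the same element accumulate. Element symbols are an
#' uppercase letter plus an optional lowercase letter.
#'
#' The distinction matters because only labelable positions can receive the
#' tracer isotope from the tracer substrate; plain atoms always draw their
#' isotopes from natural abundance. A derivatized metabolite typically has
#' many plain atoms from the derivatizing group, e.g. PCF-proline carries
#' 12 carbons of which only the 5 proline carbons are labelable:
#' `"LabC5C7H20NO2"`.
#'
#' @param text Formula string.
#' @return An object of class `fragment_formula` with fields `plain` and
#'   `labelable`, each a named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("LabC5C7H20NO2")
#' parse_formula("LabC4LabN2C4H12O2")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    stop("empty formula", call. = FALSE)
  }
  plain <- integer()
  labelable <- integer()
  pos <- 1L
  n <- nchar(text)
  token_re <- "^(Lab)?([A-Z][a-z]?)([0-9]*)"
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regexec(token_re, rest)[[1]]
    if (m[1] == -1L || attr(m, "match.length")[1] == 0L) {
      stop("formula parse error at position ", pos, " in \"", text, "\"",
           call. = FALSE)
    }
    grab <- function(i) {
      if (m[i] == -1L) "" else
        substr(rest, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    }
    lab <- grab(2) == "Lab"
    el <- grab(3)
    cnt_s <- grab(4)
    cnt <- if (nzchar(cnt_s)) as.integer(cnt_s) else 1L
    if (lab) {
      labelable[el] <- (if (el %in% names(labelable)) labelable[[el]] else 0L) + cnt
    } else {
      plain[el] <- (if (el %in% names(plain)) plain[[el]] else 0L) + cnt
    }
    pos <- pos + attr(m, "match.length")[1]
  }
  fragment_formula(plain, labelable)
}

#' Construct a fragment formula from counts
#'
#' @param plain Named integer vector: plain (non-labelable) atom counts.
#' @param labelable Named integer vector: labelable atom counts per tracer
#'   element.
#' @return A `fragment_formula`.
#' @export
fragment_formula <- function(plain = integer(), labelable = integer()) {
  plain <- drop_zero_counts(plain)
  labelable <- drop_zero_counts(labelable)
  if (any(plain < 0L) || any(labelable < 0L)) {
    stop("negative atom count", call. = FALSE)
  }
  if (sum(plain) + sum(labelable) == 0L) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  structure(list(plain = plain, labelable = labelable),
            class = "fragment_formula")
}

drop_zero_counts <- function(x) {
  if (!length(x)) return(stats::setNames(integer(), character()))
  if (is.null(names(x)) || anyNA(names(x)) || any(!nzchar(names(x)))) {
    stop("atom counts must be named by element", call. = FALSE)
  }
  x <- stats::setNames(as.integer(x), names(x))
  x <- x[order(names(x))]
  x[x != 0L]
}

#' Render a fragment formula to its canonical string
#'
#' Inverse of [parse_formula()] up to token ordering (labelable tokens
#' first, elements alphabetical, counts explicit).
#'
#' @param f A `fragment_formula`.
#' @return A string.
#' @export
render_formula <- function(f) {
  stopifnot(inherits(f, "fragment_formula"))
  lab <- if (length(f$labelable)) {
    paste0("Lab", names(f$labelable), f$labelable, collapse = "")
  } else ""
  pl <- if (length(f$plain)) {
    paste0(names(f$plain), f$plain, collapse = "")
  } else ""
  paste0(lab, pl)
}

#' @export
print.fragment_formula <- function(x, ...) {
  cat("<fragment_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

# empty fragment sentinel used for absent neutral losses ({0:1} distribution)
empty_fragment <- function() {
  structure(list(plain = integer(), labelable = integer()),
            class = "fragment_formula")
}

formula_is_empty <- function(f) {
  sum(f$plain) + sum(f$labelable) == 0L
}

#' Declare a molecule to be corrected
#'
#' @param name Molecule identifier; must not contain `"_"` (reserved as the
#'   separator in measurement row keys).
#' @param product Product-ion (or whole-molecule) formula: a
#'   `fragment_formula` or a formula string.
#' @param neutral_loss Neutral-loss formula (MS/MS mode only).
#' @param mode One of `"ms1"`, `"msms"`, `"highres"`.
#' @return An object of class `molecule_spec` carrying the derived label
#'   capacities: `n` (labelable tracer atoms in the product), `m` (in the
#'   neutral loss), `n_i` (per-tracer capacities, high-res), `r` (number of
#'   tracer elements).
#' @export
#' @examples
#' molecule_spec("Pro", "LabC5C7H20NO2", mode = "ms1")
molecule_spec <- function(name, product, neutral_loss = NULL,
                          mode = c("ms1", "msms", "highres")) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("_", name, fixed = TRUE)) {
    stop("molecule name may not contain '_': ", name, call. = FALSE)
  }
  if (is.character(product)) product <- parse_formula(product)
  stopifnot(inherits(product, "fragment_formula"))
  if (!is.null(neutral_loss)) {
    if (is.character(neutral_loss)) {
      neutral_loss <- if (nzchar(neutral_loss)) parse_formula(neutral_loss)
    }
  }
  if (mode == "msms" && is.null(neutral_loss)) {
    stop("msms mode requires a neutral_loss formula for ", name,
         call. = FALSE)
  }
  if (mode != "msms" && !is.null(neutral_loss)) {
    stop("neutral_loss is only meaningful in msms mode (", name, ")",
         call. = FALSE)
  }
  structure(list(name = name, mode = mode, product = product,
                 neutral_loss = neutral_loss),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat("<molecule_spec> ", x$name, " [", x$mode, "] ",
      render_formula(x$product), sep = "")
  if (!is.null(x$neutral_loss)) {
    cat(" / NL ", render_formula(x$neutral_loss), sep = "")
  }
  cat("\n")
  invisible(x)
}

# label capacities, resolved against a registry
molecule_capacity <- function(mol, registry) {
  lab_prod <- mol$product$labelable
  lab_nl <- if (is.null(mol$neutral_loss)) integer() else
    mol$neutral_loss$labelable
  all_lab <- union(names(lab_prod), names(lab_nl))
  missing_tracer <- setdiff(all_lab, registry$tracer_order)
  if (length(missing_tracer)) {
    stop("labelable element(s) without tracer definition: ",
         paste(missing_tracer, collapse = ", "), " in molecule ", mol$name,
         call. = FALSE)
  }
  if (mol$mode %in% c("ms1", "msms")) {
    if (length(all_lab) > 1L) {
      stop("nominal-resolution modes support a single tracer element; ",
           mol$name, " labels ", paste(all_lab, collapse = ", "),
           call. = FALSE)
    }
    tracer <- if (length(all_lab)) all_lab else
      stop("molecule ", mol$name, " has no labelable atoms", call. = FALSE)
    n <- if (tracer %in% names(lab_prod)) lab_prod[[tracer]] else 0L
    m <- if (tracer %in% names(lab_nl)) lab_nl[[tracer]] else 0L
    list(tracer = tracer, n = n, m = m)
  } else {
    tracers <- intersect(registry$tracer_order, all_lab)
    if (!length(tracers)) {
      stop("molecule ", mol$name, " has no labelable atoms", call. = FALSE)
    }
    n_i <- vapply(tracers, function(e)
      if (e %in% names(lab_prod)) lab_prod[[e]] else 0L, integer(1))
    list(tracers = tracers, n_i = n_i, r = length(tracers))
  }
}

#' Read a molecule definition file
#'
#' CSV with header `Molecule,ProductFormula,NeutralLossFormula`
#' (`NeutralLossFormula` empty except in MS/MS mode).
#'
#' @param path Path to the CSV file.
#' @param mode Correction mode applied to every molecule in the file.
#' @return A list of `molecule_spec` objects (file order).
#' @export
read_molecules <- function(path, mode = c("ms1", "msms", "highres")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    stop("molecule file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("Molecule", "ProductFormula", "NeutralLossFormula")
  if (!all(need %in% names(df))) {
    stop("molecule file must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (anyDuplicated(df$Molecule)) {
    stop("duplicate molecule name in ", path, call. = FALSE)
  }
  purrr::map(seq_len(nrow(df)), function(i) {
    nl <- df$NeutralLossFormula[i]
    nl <- if (is.na(nl) || !nzchar(nl)) NULL else nl
    tryCatch(
      molecule_spec(df$Molecule[i], df$ProductFormula[i],
                    neutral_loss = nl, mode = mode),
      error = function(e) {
        stop("line ", i + 1L, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
}

#' Write molecule definitions to CSV
#'
#' @param molecules List of `molecule_spec` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(molecules, path) {
  rows <- purrr::map(molecules, function(m) {
    tibble::tibble(
      Molecule = m$name,
      ProductFormula = render_formula(m$product),
      NeutralLossFormula = if (is.null(m$neutral_loss)) "" else
        render_formula(m$neutral_loss)
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}
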