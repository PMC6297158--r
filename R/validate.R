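split_keys <- function(keys) {
  pos <- regexpr("_", keys, fixed = TRUE)
  tibble::tibble(
    key = keys,
    molecule = ifelse(pos > 0L, substr(keys, 1L, pos - 1L), NA_character_),
    state = ifelse(pos > 0L, substr(keys, pos + 1L, nchar(keys)),
                   NA_character_)
  )
}

finding <- function(severity, molecule, sample, message) {
  tibble::tibble(severity = severity, molecule = molecule, sample = sample,
                 message = message)
}

#' Validate a correction input set
#'
#' Cross-checks the element registry, molecule definitions and measurement
#' table before any correction is attempted, and reports findings as data
#' rather than raising. Errors abort a correction run; warnings are carried
#' into the run log.
#'
#' Checks performed: labelable elements without a tracer definition
#' (error); molecules with no labelable atoms (warning); measurement rows
#' missing for expected label states (error); measurement keys that match
#' no molecule or no expected state (error); negative measured values
#' (warning; clamped to 0 during correction).
#'
#' @param registry An [element_registry()].
#' @param molecules List of [molecule_spec()] objects.
#' @param measurements Measurement tibble ([read_measurements()]), or
#'   `NULL` to validate only registry and molecules.
#' @return A tibble of findings with columns `severity` (`"error"` /
#'   `"warning"`), `molecule`, `sample`, `message`.
#' @export
validate_inputs <- function(registry, molecules, measurements = NULL) {
  out <- list()
  mol_names <- vapply(molecules, `[[`, character(1), "name")
  for (mol in molecules) {
    cap <- tryCatch(molecule_capacity(mol, registry), error = identity)
    if (inherits(cap, "error")) {
      out[[length(out) + 1L]] <-
        finding("error", mol$name, NA_character_, conditionMessage(cap))
      next
    }
    total <- if (mol$mode == "highres") sum(cap$n_i) else cap$n + cap$m
    if (total == 0L) {
      out[[length(out) + 1L]] <- finding(
        "warning", mol$name, NA_character_,
        paste0(mol$name, ": no labelable atoms, nothing to correct"))
    }
  }
  if (!is.null(measurements)) {
    if (!"Measurement" %in% names(measurements)) {
      stop("measurement table must have a Measurement column", call. = FALSE)
    }
    keys <- split_keys(measurements$Measurement)
    if (anyDuplicated(keys$key)) {
      out[[length(out) + 1L]] <- finding(
        "error", NA_character_, NA_character_,
        paste0("duplicate measurement key(s): ",
               paste(unique(keys$key[duplicated(keys$key)]),
                     collapse = ", ")))
    }
    unknown <- !keys$molecule %in% mol_names | is.na(keys$molecule)
    if (any(unknown)) {
      out[[length(out) + 1L]] <- finding(
        "error", NA_character_, NA_character_,
        paste0("measurement key(s) for unknown molecule: ",
               paste(keys$key[unknown], collapse = ", ")))
    }
    for (mol in molecules) {
      states <- tryCatch(expected_states(mol, registry),
                         error = function(e) NULL)
      if (is.null(states)) next
      have <- keys$state[keys$molecule == mol$name & !is.na(keys$molecule)]
      missing <- setdiff(states, have)
      if (length(missing)) {
        out[[length(out) + 1L]] <- finding(
          "error", mol$name, NA_character_,
          paste0("missing measurement key(s): ",
                 paste0(mol$name, "_", missing, collapse = ", ")))
      }
      extra <- setdiff(have, states)
      if (length(extra)) {
        out[[length(out) + 1L]] <- finding(
          "error", mol$name, NA_character_,
          paste0("measurement key(s) with unexpected state: ",
                 paste0(mol$name, "_", extra, collapse = ", ")))
      }
    }
    for (smp in setdiff(names(measurements), "Measurement")) {
      col <- measurements[[smp]]
      if (!is.numeric(col)) {
        out[[length(out) + 1L]] <- finding(
          "error", NA_character_, smp,
          paste0("sample column ", smp, " is not numeric"))
        next
      }
      neg <- which(col < 0)
      if (length(neg)) {
        out[[length(out) + 1L]] <- finding(
          "warning", NA_character_, smp,
          paste0(smp, ": negative measured value(s) at ",
                 paste(measurements$Measurement[neg], collapse = ", "),
                 " clamped to 0"))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(severity = character(), molecule = character(),
                          sample = character(), message = character()))
  }
  dplyr::bind_rows(out)
}
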