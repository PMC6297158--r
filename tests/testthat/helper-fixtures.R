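# shared fixtures built in code

reg_c <- function(purity = NULL) {
  default_elements(tracers = "C",
                   purity = if (is.null(purity)) numeric() else
                     c(C = purity))
}

reg_cn <- function(pc = NULL, pn = NULL) {
  pur <- c(C = if (is.null(pc)) 1 else pc, N = if (is.null(pn)) 1 else pn)
  default_elements(tracers = c("C", "N"), purity = pur)
}

glycine_ms1 <- function() molecule_spec("Gly", "LabC2", mode = "ms1")

pcf_proline <- function() molecule_spec("Pro", "LabC5C7H20NO2", mode = "ms1")

write_fixture_files <- function(dir, registry, molecules, measurements) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(elements = file.path(dir, "elements.csv"),
                molecules = file.path(dir, "molecules.csv"),
                measurements = file.path(dir, "measurements.csv"))
  write_elements(registry, paths$elements)
  write_molecules(molecules, paths$molecules)
  write_measurements(measurements, paths$measurements)
  paths
}
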