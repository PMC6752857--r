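# Standard atomic masses (amu) and van der Waals radii (Angstrom, Bondi set)
# for the elements that occur in protein heavy-atom + polar-hydrogen models.

.element_table <- data.frame(
  element    = c("H", "C", "N", "O", "S", "P", "SE"),
  mass       = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971),
  vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.90),
  stringsAsFactors = FALSE
)

#' Guess the element from a PDB atom name
#'
#' Strips digits and primes, then matches the leading characters against the
#' bundled element table (two-letter symbols such as `SE` are tried first).
#' Used when a structure file carries no element column.
#'
#' @param atom_name character vector of PDB atom names (e.g. `"CA"`, `"1HG1"`).
#' @return character vector of element symbols.
#' @export
guess_element <- function(atom_name) {
  core <- toupper(gsub("[0-9' ]", "", atom_name))
  out <- character(length(core))
  two <- substr(core, 1, 2)
  hit2 <- two %in% setdiff(.element_table$element, c("C", "N", "O", "S", "H", "P"))
  out[hit2] <- two[hit2]
  out[!hit2] <- substr(core[!hit2], 1, 1)
  out
}

.element_property <- function(element, what) {
  i <- match(toupper(element), .element_table$element)
  if (anyNA(i)) {
    stop_ensdiff("ensdiff_config_error", paste0(
      "unknown element(s): ",
      paste(unique(element[is.na(i)]), collapse = ", ")))
  }
  .element_table[[what]][i]
}

atomic_mass <- function(element) .element_property(element, "mass")
vdw_radius <- function(element) .element_property(element, "vdw_radius")

.components <- c("receptor_alpha", "receptor_beta", "ligand_mhc", "ligand_peptide")
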