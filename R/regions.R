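#' Define a named region of interest
#'
#' A region is an inclusive author-numbered residue range on one chain, e.g. a
#' CDR loop, the AB loop, a variable/constant linker or a constant-domain
#' helix or strand.
#'
#' @param name region name (e.g. `"CDR3a"`, `"ABloop"`, `"VCBlinker"`).
#' @param chain_id chain identifier the range lives on.
#' @param start_residue,end_residue inclusive residue bounds (author PDB
#'   numbering, 1-based).
#' @return object of class `region_def`.
#' @export
region_def <- function(name, chain_id, start_residue, end_residue) {
  if (end_residue < start_residue)
    stop_ensdiff("ensdiff_argument_error", sprintf(
      "region '%s': start_residue must be <= end_residue", name))
  structure(list(name = name, chain_id = as.character(chain_id),
                 start_residue = as.integer(start_residue),
                 end_residue = as.integer(end_residue)),
            class = "region_def")
}

#' Bundle regions into a named set
#'
#' @param ... [region_def()] objects.
#' @return named list of class `region_set`.
#' @export
region_set <- function(...) {
  regions <- list(...)
  if (length(regions) == 1L && is.list(regions[[1]]) && !inherits(regions[[1]], "region_def"))
    regions <- regions[[1]]
  nm <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop_ensdiff("ensdiff_config_error", "region names must be unique within a set")
  structure(setNames(regions, nm), class = "region_set")
}

#' Read region definitions and the chain-component map from a YAML config
#'
#' Expected layout:
#' ```yaml
#' chain_components: {A: receptor_alpha, B: receptor_beta, M: ligand_mhc}
#' regions:
#'   - {name: CDR3a, chain: A, start: 107, end: 116}
#' ```
#'
#' @param path YAML file path.
#' @return list with elements `chain_components` (named character vector) and
#'   `regions` (a `region_set`).
#' @export
read_region_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions) || is.null(cfg$chain_components))
    stop_ensdiff("ensdiff_config_error",
                 "config needs 'chain_components' and 'regions' entries")
  regions <- lapply(cfg$regions, function(r)
    region_def(r$name, r$chain, r$start, r$end))
  list(chain_components = unlist(cfg$chain_components), regions = region_set(regions))
}

#' Write a region config YAML
#'
#' @param chain_components named character vector, chain id to component.
#' @param regions a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_config <- function(chain_components, regions, path) {
  yaml::write_yaml(list(
    chain_components = as.list(chain_components),
    regions = lapply(unclass(regions), function(r) list(
      name = r$name, chain = r$chain_id, start = r$start_residue,
      end = r$end_residue))), path)
  invisible(path)
}

#' Select the atoms of a region
#'
#' @param topology ensemble topology data frame (or a `trajectory_ensemble`).
#' @param region a [region_def()].
#' @return integer vector of atom indices in topology order.
#' @export
select_region <- function(topology, region) {
  if (inherits(topology, "trajectory_ensemble")) topology <- topology$topology
  idx <- which(topology$chain_id == region$chain_id &
                 topology$residue_seq >= region$start_residue &
                 topology$residue_seq <= region$end_residue)
  if (!length(idx))
    stop_ensdiff("ensdiff_empty_region_error", sprintf(
      "region '%s' (%s %d-%d) selects no atoms; check config against topology",
      region$name, region$chain_id, region$start_residue, region$end_residue))
  idx
}

#' Select all atoms of one chain
#'
#' @param topology ensemble topology data frame (or a `trajectory_ensemble`).
#' @param chain_id chain identifier.
#' @return integer vector of atom indices.
#' @export
select_chain <- function(topology, chain_id) {
  if (inherits(topology, "trajectory_ensemble")) topology <- topology$topology
  idx <- which(topology$chain_id == chain_id)
  if (!length(idx))
    stop_ensdiff("ensdiff_empty_region_error", sprintf("no atoms on chain '%s'", chain_id))
  idx
}

# resolve a region argument (region_def or raw indices) to atom indices
.resolve_atoms <- function(ensemble, region) {
  if (inherits(region, "region_def")) return(select_region(ensemble$topology, region))
  idx <- as.integer(region)
  if (!length(idx))
    stop_ensdiff("ensdiff_empty_region_error", "empty atom selection")
  if (any(idx < 1L | idx > nrow(ensemble$topology)))
    stop_ensdiff("ensdiff_argument_error", "atom indices out of range")
  idx
}
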