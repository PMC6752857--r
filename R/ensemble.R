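#' Construct a trajectory ensemble
#'
#' An ensemble is one condition's set of simulation replicas over a shared
#' atom topology.  Coordinates are stored in Angstrom as one matrix per
#' replica with one row per frame and columns `(x1, y1, z1, x2, ...)` in
#' topology order (the bio3d `xyz` layout).
#'
#' @param topology data frame with one row per atom and columns `atom_id`,
#'   `atom_name`, `element`, `residue_seq`, `insert`, `residue_name`,
#'   `chain_id`, `component`, `mass`, `vdw_radius`, `donor`, `acceptor`,
#'   `polar_h`.
#' @param xyz list of numeric matrices, one per replica, each `frames x
#'   (3 * n_atoms)`.
#' @param condition_label `"bound"` or `"unbound"`.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(topology, xyz, condition_label = c("bound", "unbound")) {
  condition_label <- match.arg(condition_label)
  if (!is.data.frame(topology) || nrow(topology) < 1L)
    stop_ensdiff("ensdiff_empty_input_error", "topology must have at least one atom")
  if (anyDuplicated(topology$atom_id))
    stop_ensdiff("ensdiff_topology_error", "atom_id must be unique within the topology")
  if (any(topology$mass <= 0) || any(topology$vdw_radius <= 0))
    stop_ensdiff("ensdiff_topology_error", "atom masses and vdW radii must be positive")
  if (!length(xyz))
    stop_ensdiff("ensdiff_empty_input_error", "ensemble needs at least one replica")
  ncols <- 3L * nrow(topology)
  for (r in seq_along(xyz)) {
    m <- xyz[[r]]
    if (!is.matrix(m) || ncol(m) != ncols)
      stop_ensdiff("ensdiff_topology_error", sprintf(
        "replica %d: expected %d coordinate columns, got %s", r, ncols,
        if (is.matrix(m)) ncol(m) else "a non-matrix"))
    if (nrow(m) < 1L)
      stop_ensdiff("ensdiff_empty_input_error", sprintf("replica %d has no frames", r))
    if (!all(is.finite(m)))
      stop_ensdiff("ensdiff_topology_error", sprintf("replica %d contains non-finite coordinates", r))
  }
  structure(list(condition_label = condition_label, topology = topology, xyz = xyz),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble: %s | %d atoms | %d replicas x %s frames>\n",
              x$condition_label, nrow(x$topology), length(x$xyz),
              paste(unique(vapply(x$xyz, nrow, 1L)), collapse = "/")))
  invisible(x)
}

n_replicas <- function(ensemble) length(ensemble$xyz)
n_frames <- function(ensemble) vapply(ensemble$xyz, nrow, 1L)

# xyz column indices for a vector of atom indices
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

# one frame as an n x 3 matrix
frame_coords <- function(ensemble, replica, frame) {
  matrix(ensemble$xyz[[replica]][frame, ], ncol = 3L, byrow = TRUE)
}

#' Load a multi-replica ensemble from multi-model PDB files
#'
#' Reads one multi-model PDB per replica (frames are the MODEL records, in
#' file order).  All files must share the same atom ordering.  Alternate
#' location indicators are resolved by keeping the highest-occupancy
#' conformer; insertion codes are kept as part of the residue identity.
#' Hydrogen-bond donor/acceptor annotations are derived geometrically from
#' the first frame: polar hydrogens are H atoms within `h_bond_length` of an
#' N/O, donors are N/O atoms carrying such a hydrogen, acceptors are all N/O
#' atoms.
#'
#' @param paths character vector of PDB file paths, one per replica.
#' @param condition_label `"bound"` or `"unbound"`.
#' @param chain_components named character vector mapping chain id to one of
#'   `receptor_alpha`, `receptor_beta`, `ligand_mhc`, `ligand_peptide`.
#' @param h_bond_length covalent H-to-heavy-atom cutoff (Angstrom) used to
#'   attach polar hydrogens to their donor.
#' @return a [trajectory_ensemble()].
#' @export
load_ensemble <- function(paths, condition_label, chain_components,
                          h_bond_length = 1.25) {
  if (!length(paths))
    stop_ensdiff("ensdiff_empty_input_error", "no trajectory files given")
  parsed <- lapply(paths, .read_multimodel_pdb)
  topo_key <- lapply(parsed, function(p)
    paste(p$atom$chain_id, p$atom$residue_seq, p$atom$insert, p$atom$atom_name))
  for (r in seq_along(parsed)[-1]) {
    if (!identical(topo_key[[r]], topo_key[[1]]))
      stop_ensdiff("ensdiff_topology_error", sprintf(
        "replica file '%s' does not share the topology of '%s'", paths[r], paths[1]))
  }
  atom <- parsed[[1]]$atom
  unmapped <- setdiff(unique(atom$chain_id), names(chain_components))
  if (length(unmapped))
    stop_ensdiff("ensdiff_config_error", paste0(
      "chains without a component mapping: ", paste(unmapped, collapse = ", ")))
  bad <- setdiff(unname(chain_components[unique(atom$chain_id)]), .components)
  if (length(bad))
    stop_ensdiff("ensdiff_config_error", paste0(
      "unknown component(s): ", paste(bad, collapse = ", ")))
  atom$component <- unname(chain_components[atom$chain_id])
  atom$mass <- atomic_mass(atom$element)
  atom$vdw_radius <- vdw_radius(atom$element)
  atom <- .annotate_hbond_roles(atom, parsed[[1]]$xyz[1, ], h_bond_length)
  trajectory_ensemble(atom, lapply(parsed, `[[`, "xyz"), condition_label)
}

# bio3d-backed reader; returns list(atom = topology-ish data frame, xyz = F x 3N)
.read_multimodel_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop_ensdiff("ensdiff_topology_error", sprintf(
      "failed to read '%s' as a (multi-model) PDB: %s", path, conditionMessage(e))))
  at <- pdb$atom
  if (!nrow(at))
    stop_ensdiff("ensdiff_empty_input_error", sprintf("'%s' contains no atoms", path))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(at))
    stop_ensdiff("ensdiff_topology_error", sprintf(
      "'%s': MODEL records disagree on the atom count (coordinates missing?)", path))
  if (!all(is.finite(xyz)))
    stop_ensdiff("ensdiff_topology_error", sprintf(
      "'%s': a MODEL is missing coordinates for one or more atoms", path))
  # resolve altlocs: highest occupancy per (chain, resno, insert, atom name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- rep(TRUE, nrow(at))
  if (any(alt != "")) {
    site <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert), at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(site, -occ)
    keep <- rep(FALSE, nrow(at))
    keep[ord[!duplicated(site[ord])]] <- TRUE
  }
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[, xyz_cols(which(keep)), drop = FALSE]
  element <- at$elesy
  if (is.null(element) || all(is.na(element) | element == ""))
    element <- guess_element(at$elety)
  element <- ifelse(is.na(element) | element == "", guess_element(at$elety), toupper(element))
  list(atom = data.frame(
    atom_id = seq_len(nrow(at)),
    atom_name = at$elety,
    element = element,
    residue_seq = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    residue_name = at$resid,
    chain_id = at$chain,
    stringsAsFactors = FALSE), xyz = xyz)
}

# derive donor/acceptor/polar-H flags from first-frame geometry
.annotate_hbond_roles <- function(atom, frame_row, h_bond_length) {
  coords <- matrix(frame_row, ncol = 3L, byrow = TRUE)
  is_h <- atom$element == "H"
  is_no <- atom$element %in% c("N", "O")
  polar_h <- rep(FALSE, nrow(atom))
  donor <- rep(FALSE, nrow(atom))
  if (any(is_h) && any(is_no)) {
    heavy_idx <- which(is_no)
    for (h in which(is_h)) {
      d2 <- colSums((t(coords[heavy_idx, , drop = FALSE]) - coords[h, ])^2)
      j <- which.min(d2)
      if (d2[j] <= h_bond_length^2) {
        polar_h[h] <- TRUE
        donor[heavy_idx[j]] <- TRUE
      }
    }
  }
  atom$donor <- donor
  atom$acceptor <- is_no
  atom$polar_h <- polar_h
  atom
}

#' Write an ensemble back to multi-model PDB files
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param paths one output path per replica.
#' @return `paths`, invisibly.
#' @export
write_ensemble <- function(ensemble, paths) {
  if (length(paths) != n_replicas(ensemble))
    stop_ensdiff("ensdiff_argument_error", "need one output path per replica")
  at <- ensemble$topology
  for (r in seq_along(paths)) {
    bio3d::write.pdb(file = paths[r], xyz = ensemble$xyz[[r]],
                     resno = at$residue_seq, resid = at$residue_name,
                     chain = at$chain_id, elety = at$atom_name,
                     insert = ifelse(at$insert == "", NA, at$insert),
                     elesy = at$element)
  }
  invisible(paths)
}

#' Restrict an ensemble to a subset of molecular components
#'
#' Used for "ligand-stripped" analyses such as computing the receptor's SASA
#' as if the ligand were not present, on the very same frames of the bound
#' ensemble.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param keep character vector of component names to retain.
#' @return a [trajectory_ensemble()] view containing only the kept atoms.
#' @export
strip_component <- function(ensemble, keep) {
  if (!length(keep))
    stop_ensdiff("ensdiff_argument_error", "keep must name at least one component")
  idx <- which(ensemble$topology$component %in% keep)
  if (!length(idx))
    stop_ensdiff("ensdiff_empty_input_error", "no atoms left after component filtering")
  topo <- ensemble$topology[idx, , drop = FALSE]
  topo$atom_id <- seq_len(nrow(topo))
  rownames(topo) <- NULL
  cols <- xyz_cols(idx)
  trajectory_ensemble(topo, lapply(ensemble$xyz, function(m) m[, cols, drop = FALSE]),
                      ensemble$condition_label)
}

#' Subset the frames of every replica
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param frames integer vector of frame indices (applied to each replica).
#' @return a [trajectory_ensemble()].
#' @export
subset_frames <- function(ensemble, frames) {
  trajectory_ensemble(ensemble$topology,
                      lapply(ensemble$xyz, function(m) m[frames, , drop = FALSE]),
                      ensemble$condition_label)
}
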