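# Synthetic inputs with the statistical structure the analysis assumes:
# (i) distribution-level descriptor series with replica-to-replica mean
# variation, within-replica AR(1) time correlation and an optional
# condition shift; (ii) geometry-level toy two-chain ensembles with labelled
# interface loops, switchable interface H-bonds and an optional rigid
# ligand block, so every descriptor and the full pipeline run without MD.

#' Specification for synthetic descriptor series
#'
#' @param n_replicas,n_frames replicas per condition and frames per replica.
#' @param grand_mean descriptor grand mean (descriptor units).
#' @param within_replica_sd stationary SD of the frame values around their
#'   replica mean.
#' @param between_replica_sd SD of the per-replica means around the grand
#'   mean (replica-to-replica variation).
#' @param ar1_coefficient within-replica AR(1) correlation of consecutive
#'   frames, in `[0, 1)`.
#' @param condition_shift shift added to the bound condition's replica means.
#' @param seed RNG seed.
#' @return list of class `series_spec`.
#' @export
series_spec <- function(n_replicas = 10, n_frames = 100, grand_mean = 0,
                        within_replica_sd = 1, between_replica_sd = 0.5,
                        ar1_coefficient = 0, condition_shift = 0, seed = NULL) {
  if (within_replica_sd < 0 || between_replica_sd < 0)
    stop_ensdiff("ensdiff_argument_error", "standard deviations must be >= 0")
  if (abs(ar1_coefficient) >= 1)
    stop_ensdiff("ensdiff_argument_error", "|ar1_coefficient| must be < 1")
  if (n_replicas < 1 || n_frames < 1)
    stop_ensdiff("ensdiff_argument_error", "need >= 1 replica and frame")
  structure(list(n_replicas = n_replicas, n_frames = n_frames,
                 grand_mean = grand_mean, within_replica_sd = within_replica_sd,
                 between_replica_sd = between_replica_sd,
                 ar1_coefficient = ar1_coefficient,
                 condition_shift = condition_shift, seed = seed),
            class = "series_spec")
}

#' Generate a bound/unbound pair of synthetic descriptor series
#'
#' Each replica r draws a mean `mu_r ~ N(grand_mean (+ shift for bound),
#' between_replica_sd)`; its frames follow a stationary AR(1) process around
#' `mu_r` with stationary SD `within_replica_sd`.  Deterministic given the
#' spec's seed.
#'
#' @param spec a [series_spec()].
#' @param descriptor,units labels for the resulting series.
#' @return list with elements `bound` and `unbound`, both
#'   [descriptor_series()].
#' @export
generate_descriptor_series <- function(spec, descriptor = "synthetic", units = "A") {
  stopifnot(inherits(spec, "series_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  gen_cond <- function(shift) {
    lapply(seq_len(spec$n_replicas), function(r) {
      mu <- spec$grand_mean + shift + rnorm(1, 0, spec$between_replica_sd)
      e <- numeric(spec$n_frames)
      e[1] <- rnorm(1, 0, spec$within_replica_sd)
      if (spec$n_frames > 1) {
        z <- rnorm(spec$n_frames - 1, 0,
                   spec$within_replica_sd * sqrt(1 - spec$ar1_coefficient^2))
        for (t in 2:spec$n_frames) e[t] <- spec$ar1_coefficient * e[t - 1] + z[t - 1]
      }
      mu + e
    })
  }
  list(bound = descriptor_series(gen_cond(spec$condition_shift), descriptor,
                                 "synthetic", "bound", units),
       unbound = descriptor_series(gen_cond(0), descriptor,
                                   "synthetic", "unbound", units))
}

#' Specification for a geometry-level toy ensemble pair
#'
#' @param residues_per_chain residues on each of the two receptor chains.
#' @param n_replicas,n_frames replicas per condition, frames per replica.
#' @param base_jitter Gaussian positional jitter SD (Angstrom) of non-loop
#'   atoms.
#' @param loop_jitter_bound,loop_jitter_unbound jitter SD of interface-loop
#'   atoms in each condition (binding restricts loop motion).
#' @param loop_shift centroid shift (Angstrom) applied in the bound condition:
#'   each interface loop moves `loop_shift/2` toward the other chain.
#' @param ligand_attached logical; attach the rigid ligand block to the bound
#'   condition.
#' @param hbond_p_bound,hbond_p_unbound per-frame probability that the
#'   designated interface H-bond is formed.
#' @param seed RNG seed.
#' @return list of class `toy_ensemble_spec`.
#' @export
toy_ensemble_spec <- function(residues_per_chain = 12, n_replicas = 10,
                              n_frames = 100, base_jitter = 0.3,
                              loop_jitter_bound = 0.5, loop_jitter_unbound = 1.0,
                              loop_shift = 0.5, ligand_attached = TRUE,
                              hbond_p_bound = 0.8, hbond_p_unbound = 0.2,
                              seed = NULL) {
  if (residues_per_chain < 9)
    stop_ensdiff("ensdiff_argument_error", "need >= 9 residues per chain")
  if (base_jitter < 0 || loop_jitter_bound < 0 || loop_jitter_unbound < 0)
    stop_ensdiff("ensdiff_argument_error", "jitter amplitudes must be >= 0")
  if (hbond_p_bound < 0 || hbond_p_bound > 1 || hbond_p_unbound < 0 || hbond_p_unbound > 1)
    stop_ensdiff("ensdiff_argument_error", "H-bond probabilities must be in [0, 1]")
  structure(as.list(environment()), class = "toy_ensemble_spec")
}

# loop residue range: middle third of the chain
.toy_loop_res <- function(R) {
  lo <- floor(R / 3) + 1L
  hi <- min(R, lo + max(2L, floor(R / 3)) - 1L)
  lo:hi
}

# reference topology + coordinates for one condition of the toy system.
# Residues sit 4.5 A apart along x; amide H points toward the partner chain,
# carbonyl O away from it, so no H-bond fires in the reference geometry
# except the designated switchable one.  CA is lifted in z so superposition
# fit regions are never collinear.
.toy_reference <- function(spec, condition) {
  R <- spec$residues_per_chain
  loop <- .toy_loop_res(R)
  shift <- if (condition == "bound") spec$loop_shift / 2 else 0
  offs <- rbind(N = c(0.0, 0.0, 0.0), H = c(0.0, 1.0, 0.0),
                CA = c(1.5, -0.5, 0.9), C = c(3.0, 0.0, -0.3), O = c(3.0, -1.23, -0.3))
  elements <- c("N", "H", "C", "C", "O")
  build_chain <- function(chain, ybase, sgn) {
    rows <- list(); coords <- list()
    for (j in seq_len(R)) {
      y_extra <- if (j %in% loop) sgn * (1 + shift) else 0
      base <- c(4.5 * (j - 1), ybase + y_extra, 0)
      xyz <- sweep(sweep(offs, 2, c(1, sgn, 1), `*`), 2, base, `+`)
      rows[[j]] <- data.frame(
        atom_name = rownames(offs), element = elements, residue_seq = j,
        insert = "", residue_name = "GLY", chain_id = chain,
        stringsAsFactors = FALSE)
      coords[[j]] <- xyz
    }
    list(atom = do.call(rbind, rows), coords = do.call(rbind, coords))
  }
  a <- build_chain("A", 0, +1)
  b <- build_chain("B", 9, -1)
  atom <- rbind(a$atom, b$atom)
  coords <- rbind(a$coords, b$coords)
  with_ligand <- condition == "bound" && isTRUE(spec$ligand_attached)
  if (with_ligand) {
    xs <- seq(4.5 * (min(loop) - 1) - 1, 4.5 * (max(loop) - 1) + 4.5, by = 2.5)
    ys <- seq(1, 8, by = 2.5)
    grid <- expand.grid(x = xs, y = ys)
    lig <- data.frame(
      atom_name = "C1", element = "C", residue_seq = seq_len(nrow(grid)),
      insert = "", residue_name = "LIG", chain_id = "M", stringsAsFactors = FALSE)
    atom <- rbind(atom, lig)
    coords <- rbind(coords, cbind(grid$x, grid$y, 4.0))
  }
  comp_map <- c(A = "receptor_alpha", B = "receptor_beta", M = "ligand_mhc")
  atom$component <- unname(comp_map[atom$chain_id])
  atom$atom_id <- seq_len(nrow(atom))
  atom$mass <- atomic_mass(atom$element)
  atom$vdw_radius <- vdw_radius(atom$element)
  atom$polar_h <- atom$element == "H"
  atom$donor <- atom$atom_name == "N"
  atom$acceptor <- atom$element %in% c("N", "O")
  # per-atom jitter SD for this condition
  loop_sd <- if (condition == "bound") spec$loop_jitter_bound else spec$loop_jitter_unbound
  jit <- ifelse(atom$chain_id %in% c("A", "B") & atom$residue_seq %in% loop,
                loop_sd, spec$base_jitter)
  jit[atom$chain_id == "M"] <- 0.1
  # designated interface H-bond partners: N/H of a mid-loop residue on A,
  # carbonyl O of the facing residue on B
  mid <- loop[ceiling(length(loop) / 2)]
  donor_i <- which(atom$chain_id == "A" & atom$residue_seq == mid & atom$atom_name == "N")
  hydro_i <- which(atom$chain_id == "A" & atom$residue_seq == mid & atom$atom_name == "H")
  accep_i <- which(atom$chain_id == "B" & atom$residue_seq == mid & atom$atom_name == "O")
  list(atom = atom[, c("atom_id", "atom_name", "element", "residue_seq", "insert",
                       "residue_name", "chain_id", "component", "mass", "vdw_radius",
                       "donor", "acceptor", "polar_h")],
       coords = unname(as.matrix(coords)), jitter_sd = jit,
       donor = donor_i, hydrogen = hydro_i, acceptor = accep_i)
}

#' Generate a bound/unbound pair of toy ensembles with labelled regions
#'
#' Builds a backbone-only two-chain "receptor" whose middle-third residues
#' form facing interface loops (CDR-like), with distal anchor regions at the
#' chain starts.  Frames are the reference geometry plus Gaussian jitter with
#' per-region amplitudes; the bound condition shifts the loops toward each
#' other by `loop_shift`, restricts their jitter, attaches a rigid ligand
#' plate over the interface (when `ligand_attached`), and forms a designated
#' inter-chain H-bond with higher per-frame probability.
#'
#' @param spec a [toy_ensemble_spec()].
#' @return list with `bound` and `unbound` ([trajectory_ensemble()]s),
#'   `regions` (a `region_set`: CDR_A, CDR_B, distal_A, distal_B), and
#'   `chain_components`.
#' @export
generate_toy_ensemble <- function(spec) {
  stopifnot(inherits(spec, "toy_ensemble_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  gen_cond <- function(condition) {
    ref <- .toy_reference(spec, condition)
    n_atoms <- nrow(ref$atom)
    p_on <- if (condition == "bound") spec$hbond_p_bound else spec$hbond_p_unbound
    xyz <- lapply(seq_len(spec$n_replicas), function(r) {
      m <- matrix(NA_real_, spec$n_frames, 3L * n_atoms)
      for (f in seq_len(spec$n_frames)) {
        coords <- ref$coords + matrix(rnorm(3 * n_atoms, 0, rep(ref$jitter_sd, each = 3)),
                                      ncol = 3, byrow = TRUE)
        # keep the amide H bonded to its N (unit bond toward the partner chain)
        dirs <- coords[ref$hydrogen, ] - coords[ref$donor, ]
        dirs <- dirs / sqrt(sum(dirs^2))
        coords[ref$hydrogen, ] <- coords[ref$donor, ] + dirs
        # switchable interface bond: when "on" the designated acceptor O is
        # placed 2.9 A along the donor N-H axis (angle 0); when "off" it
        # stays at its jittered backbone position on the partner chain
        if (runif(1) < p_on)
          coords[ref$acceptor, ] <- coords[ref$donor, ] + dirs * 2.9
        m[f, ] <- as.vector(t(coords))
      }
      m
    })
    trajectory_ensemble(ref$atom, xyz, condition)
  }
  bound <- gen_cond("bound")
  unbound <- gen_cond("unbound")
  loop <- .toy_loop_res(spec$residues_per_chain)
  regions <- region_set(
    region_def("CDR_A", "A", min(loop), max(loop)),
    region_def("CDR_B", "B", min(loop), max(loop)),
    region_def("distal_A", "A", 1, min(loop) - 1L),
    region_def("distal_B", "B", 1, min(loop) - 1L))
  list(bound = bound, unbound = unbound, regions = regions,
       chain_components = c(A = "receptor_alpha", B = "receptor_beta", M = "ligand_mhc"))
}

#' Write a generated toy system to disk (multi-model PDBs + region YAML)
#'
#' Produces the on-disk layout the pipeline consumes: one multi-model PDB per
#' replica per condition plus a region/chain-component config.
#'
#' @param toy output of [generate_toy_ensemble()].
#' @param dir output directory (created if missing).
#' @return list of written paths (`bound`, `unbound`, `regions`).
#' @export
write_toy_ensemble <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pb <- file.path(dir, sprintf("bound_rep%02d.pdb", seq_len(n_replicas(toy$bound))))
  pu <- file.path(dir, sprintf("unbound_rep%02d.pdb", seq_len(n_replicas(toy$unbound))))
  write_ensemble(toy$bound, pb)
  write_ensemble(toy$unbound, pu)
  ry <- file.path(dir, "regions.yaml")
  write_region_config(toy$chain_components, toy$regions, ry)
  list(bound = pb, unbound = pu, regions = ry)
}
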