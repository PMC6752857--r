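#' Construct a descriptor series
#'
#' Per-replica, per-frame scalar values of one descriptor for one condition.
#'
#' @param values list of numeric vectors, one per replica.
#' @param descriptor descriptor name (e.g. `"DIST"`, `"RG"`, `"SASA"`).
#' @param region_names character vector of region names the values refer to.
#' @param condition_label `"bound"` or `"unbound"`.
#' @param units unit string (`"A"`, `"A^2"`, `"count"`).
#' @return object of class `descriptor_series`.
#' @export
descriptor_series <- function(values, descriptor, region_names, condition_label, units) {
  if (!is.list(values) || !length(values))
    stop_ensdiff("ensdiff_empty_input_error", "values must be a non-empty list of replicas")
  if (!all(vapply(values, function(v) length(v) > 0 && all(is.finite(v)), TRUE)))
    stop_ensdiff("ensdiff_argument_error", "every replica needs >= 1 finite value")
  structure(list(values = lapply(values, as.numeric), descriptor = descriptor,
                 region_names = region_names, condition_label = condition_label,
                 units = units),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("<descriptor_series: %s [%s] | %s | %d replicas, %d values, mean %.4g %s>\n",
              x$descriptor, paste(x$region_names, collapse = ","), x$condition_label,
              length(x$values), length(unlist(x$values)),
              mean(unlist(x$values)), x$units))
  invisible(x)
}

# pooled values over frames and replicas
pooled_values <- function(series) {
  if (inherits(series, "descriptor_series")) unlist(series$values, use.names = FALSE)
  else unlist(series, use.names = FALSE)
}

# values as list of replicas
replica_values <- function(series) {
  if (inherits(series, "descriptor_series")) series$values
  else if (is.list(series)) lapply(series, as.numeric)
  else list(as.numeric(series))
}

# mass-weighted centroids for region atoms, one per frame: F x 3 matrix
.centroids <- function(xyz, atom_idx, mass) {
  w <- mass / sum(mass)
  cbind(xyz[, 3 * atom_idx - 2, drop = FALSE] %*% w,
        xyz[, 3 * atom_idx - 1, drop = FALSE] %*% w,
        xyz[, 3 * atom_idx, drop = FALSE] %*% w)
}

#' Distance between the mass-weighted centres of two regions
#'
#' The per-frame Euclidean distance (Angstrom) between the mass-weighted
#' centroids of two atom selections, e.g. between a CDR loop on the alpha
#' chain and its counterpart on the beta chain.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param regionA,regionB [region_def()] objects or integer atom indices.
#' @return a [descriptor_series()] in Angstrom.
#' @export
region_distance <- function(ensemble, regionA, regionB) {
  ia <- .resolve_atoms(ensemble, regionA)
  ib <- .resolve_atoms(ensemble, regionB)
  ma <- ensemble$topology$mass[ia]
  mb <- ensemble$topology$mass[ib]
  vals <- lapply(ensemble$xyz, function(m) {
    d <- .centroids(m, ia, ma) - .centroids(m, ib, mb)
    sqrt(rowSums(d^2))
  })
  descriptor_series(vals, "DIST", c(.region_name(regionA), .region_name(regionB)),
                    ensemble$condition_label, "A")
}

.region_name <- function(region) {
  if (inherits(region, "region_def")) region$name else "selection"
}

#' Mass-weighted radius of gyration of a region
#'
#' Per frame: `sqrt( sum_i m_i |r_i - rbar|^2 / sum_i m_i )` with `rbar` the
#' mass-weighted centroid, in Angstrom.
#'
#' @inheritParams region_distance
#' @param region a [region_def()] or integer atom indices.
#' @return a [descriptor_series()] in Angstrom.
#' @export
radius_of_gyration <- function(ensemble, region) {
  idx <- .resolve_atoms(ensemble, region)
  m <- ensemble$topology$mass[idx]
  w <- m / sum(m)
  vals <- lapply(ensemble$xyz, function(xyz) {
    cen <- .centroids(xyz, idx, m)
    acc <- 0
    for (k in 0:2) {
      dev <- xyz[, 3 * idx - 2 + k, drop = FALSE] - cen[, k + 1]
      acc <- acc + (dev^2) %*% w
    }
    sqrt(as.vector(acc))
  })
  descriptor_series(vals, "RG", .region_name(region), ensemble$condition_label, "A")
}

#' Per-residue root mean square fluctuation after superposition
#'
#' Every frame of each replica is least-squares superposed (optimal rotation
#' and translation, via bio3d's Kabsch fit) onto that replica's first frame
#' using the `fit_region` atoms.  The RMSF of a residue is the square root of
#' the time-averaged squared deviation of its representative atom (CA, or the
#' residue's first atom if no CA exists) from its time-average position.  The
#' reported per-residue value is the mean over replicas; the per-region mean
#' averages over residues.
#'
#' @inheritParams region_distance
#' @param fit_region region or atom indices used for superposition; needs at
#'   least 3 non-collinear atoms.
#' @param target_region region or atom indices whose residues are profiled.
#' @return list with `per_residue` (data frame: chain_id, residue_seq, insert,
#'   residue_name, rmsf plus one column per replica), `region_mean` (scalar),
#'   and `series` (a [descriptor_series()] holding one per-replica region-mean
#'   value, for condition comparisons).
#' @export
rmsf <- function(ensemble, fit_region, target_region) {
  fit_idx <- .resolve_atoms(ensemble, fit_region)
  tgt_idx <- .resolve_atoms(ensemble, target_region)
  if (any(n_frames(ensemble) < 2L))
    stop_ensdiff("ensdiff_insufficient_data_error",
                 "RMSF needs at least 2 frames per replica")
  if (length(fit_idx) < 3L)
    stop_ensdiff("ensdiff_fit_error", "fit region needs >= 3 atoms")
  ref <- frame_coords(ensemble, 1L, 1L)[fit_idx, , drop = FALSE]
  sv <- svd(scale(ref, scale = FALSE))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop_ensdiff("ensdiff_fit_error", "fit region atoms are (nearly) collinear")

  topo <- ensemble$topology[tgt_idx, , drop = FALSE]
  res_key <- paste(topo$chain_id, topo$residue_seq, topo$insert)
  res_levels <- unique(res_key)
  rep_atom <- vapply(res_levels, function(k) {
    in_res <- tgt_idx[res_key == k]
    ca <- in_res[ensemble$topology$atom_name[in_res] == "CA"]
    if (length(ca)) ca[1] else in_res[1]
  }, integer(1))

  fit_cols <- xyz_cols(fit_idx)
  rep_cols <- xyz_cols(rep_atom)
  per_rep <- vapply(seq_len(n_replicas(ensemble)), function(r) {
    m <- ensemble$xyz[[r]]
    fitted <- suppressWarnings(
      bio3d::fit.xyz(fixed = m[1, ], mobile = m,
                     fixed.inds = fit_cols, mobile.inds = fit_cols))
    rmsf_res <- numeric(length(rep_atom))
    for (i in seq_along(rep_atom)) {
      cols <- rep_cols[(3 * i - 2):(3 * i)]
      xyz_a <- fitted[, cols, drop = FALSE]
      mu <- colMeans(xyz_a)
      rmsf_res[i] <- sqrt(mean(rowSums(sweep(xyz_a, 2, mu)^2)))
    }
    rmsf_res
  }, numeric(length(rep_atom)))
  per_rep <- matrix(per_rep, nrow = length(rep_atom))

  per_residue <- data.frame(
    chain_id = ensemble$topology$chain_id[rep_atom],
    residue_seq = ensemble$topology$residue_seq[rep_atom],
    insert = ensemble$topology$insert[rep_atom],
    residue_name = ensemble$topology$residue_name[rep_atom],
    rmsf = rowMeans(per_rep), stringsAsFactors = FALSE)
  colnames(per_rep) <- paste0("replica_", seq_len(ncol(per_rep)))
  series <- descriptor_series(as.list(colMeans(per_rep)), "RMSF",
                              .region_name(target_region),
                              ensemble$condition_label, "A")
  list(per_residue = cbind(per_residue, per_rep),
       region_mean = mean(per_residue$rmsf), series = series)
}

#' Write one or more descriptor series as a tidy TSV
#'
#' Columns: condition, replica, frame, descriptor, region, value, units.
#'
#' @param series a [descriptor_series()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_descriptor_tsv <- function(series, path) {
  if (inherits(series, "descriptor_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    do.call(rbind, lapply(seq_along(s$values), function(r) data.frame(
      condition = s$condition_label, replica = r,
      frame = seq_along(s$values[[r]]), descriptor = s$descriptor,
      region = paste(s$region_names, collapse = "-"),
      value = s$values[[r]], units = s$units, stringsAsFactors = FALSE)))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
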