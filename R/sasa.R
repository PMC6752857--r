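#' Quasi-uniform points on the unit sphere (golden-spiral lattice)
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area of a region
#'
#' Rolling-probe (Shrake-Rupley) SASA: each region atom's sphere of radius
#' `vdw + probe` is sampled with a quasi-uniform point lattice, and the
#' accessible fraction is the share of points not buried inside any other
#' context atom's probe-extended sphere.  The descriptor value is the summed
#' area (Angstrom^2) of the region atoms, computed against the atoms in
#' `context` only — so a bound-state ensemble can be evaluated both in its
#' full complex context and "ligand-stripped" (the same receptor frames with
#' the ligand atoms removed from the context).
#'
#' @inheritParams region_distance
#' @param region [region_def()] or integer atom indices (area is reported for
#'   these atoms).
#' @param context character vector of component names, or integer atom
#'   indices, defining the occluding atom set; defaults to all atoms.  Must
#'   contain the region.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sphere test points per atom.
#' @return a [descriptor_series()] in Angstrom^2.
#' @export
sasa <- function(ensemble, region, context = NULL, probe = 1.4, n_points = 960) {
  idx <- .resolve_atoms(ensemble, region)
  if (is.null(context)) {
    ctx <- seq_len(nrow(ensemble$topology))
  } else if (is.character(context)) {
    ctx <- which(ensemble$topology$component %in% context)
    if (!length(ctx))
      stop_ensdiff("ensdiff_empty_input_error", "context components select no atoms")
  } else {
    ctx <- .resolve_atoms(ensemble, context)
  }
  if (!all(idx %in% ctx))
    stop_ensdiff("ensdiff_argument_error", "context must contain every region atom")
  sp <- sphere_points(n_points)
  radii <- ensemble$topology$vdw_radius[ctx]
  region_in_ctx <- match(idx, ctx)
  ctx_cols <- xyz_cols(ctx)
  vals <- lapply(ensemble$xyz, function(m) {
    vapply(seq_len(nrow(m)), function(f) {
      coords <- matrix(m[f, ctx_cols], ncol = 3L, byrow = TRUE)
      sum(sasa_frame_cpp(coords, radii, region_in_ctx, sp, probe))
    }, numeric(1))
  })
  descriptor_series(vals, "SASA", .region_name(region), ensemble$condition_label, "A^2")
}
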