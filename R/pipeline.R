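# End-to-end driver: descriptors for both conditions, the three statistics
# with replica-level resampling per descriptor, masked summary tables,
# per-descriptor histogram data and the H-bond network difference export.

#' Build the standard descriptor battery for a region set
#'
#' One distance between the two interface loops, radius of gyration and SASA
#' (full context plus ligand-stripped context when a ligand is present) per
#' loop, per-loop RMSF fitted on the distal anchor regions, and the
#' inter-chain H-bond count.
#'
#' @param regions a `region_set`.
#' @param loop_regions names of the interface-loop regions.
#' @param fit_regions names of the regions used as RMSF superposition anchors.
#' @param chains the two receptor chain ids for the inter-chain H-bond count.
#' @param with_ligand add ligand-stripped SASA variants.
#' @return list of descriptor specifications for [run_pipeline()].
#' @export
default_descriptor_set <- function(regions, loop_regions = c("CDR_A", "CDR_B"),
                                   fit_regions = c("distal_A", "distal_B"),
                                   chains = c("A", "B"), with_ligand = TRUE) {
  specs <- list()
  if (length(loop_regions) >= 2)
    specs <- c(specs, list(list(type = "distance",
                                label = paste("DIST", loop_regions[1], loop_regions[2]),
                                regionA = loop_regions[1], regionB = loop_regions[2])))
  for (rg in loop_regions) {
    specs <- c(specs, list(list(type = "rg", label = paste("RG", rg), region = rg)))
    specs <- c(specs, list(list(type = "sasa", label = paste("SASA", rg),
                                region = rg, context = "full")))
    if (with_ligand)
      specs <- c(specs, list(list(type = "sasa", label = paste("SASA", rg, "noMHC"),
                                  region = rg, context = "receptor")))
    specs <- c(specs, list(list(type = "rmsf", label = paste("RMSF", rg),
                                region = rg, fit_regions = fit_regions)))
  }
  c(specs, list(list(type = "hbond_count", label = "n of H-bonds",
                     chainA = chains[1], chainB = chains[2])))
}

.receptor_components <- c("receptor_alpha", "receptor_beta")

# compute one descriptor spec on one ensemble
.compute_descriptor <- function(ensemble, spec, regions) {
  reg <- function(nm) {
    if (is.null(regions[[nm]]))
      stop_ensdiff("ensdiff_config_error", sprintf("unknown region '%s'", nm))
    regions[[nm]]
  }
  switch(spec$type,
    distance = region_distance(ensemble, reg(spec$regionA), reg(spec$regionB)),
    rg = radius_of_gyration(ensemble, reg(spec$region)),
    sasa = {
      ctx <- if (identical(spec$context, "receptor"))
        intersect(.receptor_components, unique(ensemble$topology$component))
      else NULL
      sasa(ensemble, reg(spec$region), context = ctx,
           n_points = if (is.null(spec$n_points)) 960 else spec$n_points)
    },
    rmsf = {
      fit_idx <- sort(unique(unlist(lapply(spec$fit_regions, function(nm)
        select_region(ensemble$topology, reg(nm))))))
      rmsf(ensemble, fit_idx, reg(spec$region))$series
    },
    hbond_count = hbond_count(ensemble,
                              select_chain(ensemble$topology, spec$chainA),
                              select_chain(ensemble$topology, spec$chainB)),
    stop_ensdiff("ensdiff_config_error", sprintf("unknown descriptor type '%s'", spec$type))
  )
}

#' Run the full comparison pipeline
#'
#' Computes every configured descriptor for both conditions, compares them
#' with d, d/r and tvd plus replica-level resampling significance, masks
#' non-significant values, and (when `output_dir` is given) writes the
#' masked and unmasked summary tables, per-descriptor histogram data, the
#' H-bond network difference export and a parameter/seed log.
#'
#' @param bound,unbound [trajectory_ensemble()]s of the two conditions.
#' @param regions a `region_set`.
#' @param descriptors list of descriptor specifications (see
#'   [default_descriptor_set()]); each entry is a list with a `type` of
#'   `"distance"`, `"rg"`, `"sasa"`, `"rmsf"` or `"hbond_count"` plus
#'   type-specific fields.
#' @param n_perm resampling draws per descriptor.
#' @param bins shared histogram bins for tvd and histogram reports.
#' @param seed base RNG seed; descriptor i uses `seed + i`.
#' @param lower,upper significance mask thresholds.
#' @param output_dir optional output directory.
#' @param hbond_network also compute the within-receptor H-bond occupancy
#'   difference map (and write it when `output_dir` is given).
#' @param hbond_filter occupancy-difference display threshold for the
#'   cylinder export.
#' @return list of class `ensdiff_pipeline`: `summary` (data frame with
#'   unmasked and masked statistics per descriptor), `results` (per-descriptor
#'   `comparison_result`s), `series` (per-descriptor bound/unbound series),
#'   `hbond_diff` (difference records or NULL), `params`.
#' @export
run_pipeline <- function(bound, unbound, regions, descriptors,
                         n_perm = 1000, bins = 100, seed = 1,
                         lower = 0.05, upper = 0.95, output_dir = NULL,
                         hbond_network = TRUE, hbond_filter = 0.06) {
  labels <- vapply(descriptors, function(s) s$label, "")
  if (anyDuplicated(labels))
    stop_ensdiff("ensdiff_config_error", "descriptor labels must be unique")
  results <- list(); series <- list()
  for (i in seq_along(descriptors)) {
    spec <- descriptors[[i]]
    sb <- .compute_descriptor(bound, spec, regions)
    su <- .compute_descriptor(unbound, spec, regions)
    res <- compare_conditions(sb, su, statistics = c("d", "d_over_r", "tvd"),
                              n_perm = n_perm, bins = bins, seed = seed + i,
                              lower = lower, upper = upper)
    res$descriptor_name <- spec$label
    results[[spec$label]] <- res
    series[[spec$label]] <- list(bound = sb, unbound = su)
  }
  summary <- do.call(rbind, lapply(results, function(r) data.frame(
    descriptor = r$descriptor_name, units = r$units,
    d = r$d, d_over_r = r$d_over_r, tvd = r$tvd,
    q_d = r$q_d, q_dr = r$q_dr, q_tvd = r$q_tvd,
    masked_d = r$masked_d, masked_dr = r$masked_dr, masked_tvd = r$masked_tvd,
    stringsAsFactors = FALSE)))
  rownames(summary) <- NULL

  hdiff <- NULL
  if (hbond_network) {
    sel_b <- which(bound$topology$component %in% .receptor_components)
    sel_u <- which(unbound$topology$component %in% .receptor_components)
    tb <- hbond_frequency_table(bound, sel_b)
    tu <- hbond_frequency_table(unbound, sel_u)
    attr(tu, "atom_key") <- attr(tb, "atom_key") <- attr(tb, "atom_key")[sel_b]
    hdiff <- bond_difference_map(tb, tu)
  }

  params <- list(n_perm = n_perm, bins = bins, seed = seed, lower = lower,
                 upper = upper, hbond_filter = hbond_filter,
                 descriptors = descriptors)
  out <- structure(list(summary = summary, results = results, series = series,
                        hbond_diff = hdiff, params = params),
                   class = "ensdiff_pipeline")
  if (!is.null(output_dir)) .write_pipeline_outputs(out, bound, output_dir, bins)
  out
}

.write_pipeline_outputs <- function(out, bound, output_dir, bins) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  s <- out$summary
  write.table(s, file.path(output_dir, "summary_unmasked.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  masked <- s[, c("descriptor", "units", "masked_d", "masked_dr", "masked_tvd")]
  names(masked) <- c("descriptor", "units", "prcD", "percDR", "percTvd")
  con <- file(file.path(output_dir, "summary_masked.tsv"), "w")
  writeLines(paste(
    "# prcD = d (mean difference, descriptor units);",
    "percDR = d/r (range-normalised); percTvd = tvd;",
    "values outside the top/bottom 5% resampling quantiles, others masked to 0"), con)
  write.table(masked, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  hist_dir <- file.path(output_dir, "histograms")
  dir.create(hist_dir, showWarnings = FALSE)
  for (lbl in names(out$series)) {
    histogram_report(out$series[[lbl]]$bound, out$series[[lbl]]$unbound, bins,
                     file.path(hist_dir, paste0(gsub("[^A-Za-z0-9_-]", "_", lbl), ".tsv")))
  }
  if (!is.null(out$hbond_diff)) {
    write.table(out$hbond_diff, file.path(output_dir, "hbond_difference.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    kept <- filter_threshold(out$hbond_diff, out$params$hbond_filter)
    export_cylinders(kept, bound, file.path(output_dir, "hbond_cylinders.tsv"),
                     pymol_path = file.path(output_dir, "hbond_cylinders.pml"))
  }
  yaml::write_yaml(c(out$params[c("n_perm", "bins", "seed", "lower", "upper",
                                  "hbond_filter")],
                     list(package_version = as.character(utils::packageVersion("ensdiff")))),
                   file.path(output_dir, "run_log.yaml"))
  jsonlite::write_json(list(summary = s), file.path(output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(output_dir)
}

#' Shared-bin histogram report for one descriptor
#'
#' Occurrence counts over all replicas and frames per condition on the same
#' bins used by [stat_tvd()] (equal-width over the pooled range).
#'
#' @inheritParams stat_tvd
#' @param path optional TSV output path.
#' @return data frame with `bin_left`, `bin_right`, `count_bound`,
#'   `count_unbound` (invisibly when `path` is given).
#' @export
histogram_report <- function(bound, unbound, bins = 100, path = NULL) {
  vb <- pooled_values(bound)
  vu <- pooled_values(unbound)
  pooled <- c(vb, vu)
  lo <- min(pooled); hi <- max(pooled)
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = bins + 1L)
  df <- data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
                   count_bound = .bin_counts(vb, breaks),
                   count_unbound = .bin_counts(vu, breaks))
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Run the pipeline from a YAML config file
#'
#' Config layout:
#' ```yaml
#' bound: [bound_rep01.pdb, bound_rep02.pdb]
#' unbound: [unbound_rep01.pdb, unbound_rep02.pdb]
#' regions: regions.yaml
#' descriptors: default        # or a list of descriptor specs
#' n_perm: 1000
#' bins: 100
#' seed: 1
#' output_dir: results
#' ```
#' Relative paths are resolved against the config file's directory.
#'
#' @param config_path YAML config path.
#' @return the [run_pipeline()] result.
#' @export
run_pipeline_file <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  rc <- read_region_config(resolve(cfg$regions))
  bound <- load_ensemble(resolve(unlist(cfg$bound)), "bound", rc$chain_components)
  unbound <- load_ensemble(resolve(unlist(cfg$unbound)), "unbound", rc$chain_components)
  descriptors <- cfg$descriptors
  if (is.null(descriptors) || identical(descriptors, "default"))
    descriptors <- default_descriptor_set(
      rc$regions,
      with_ligand = any(bound$topology$component %in% c("ligand_mhc", "ligand_peptide")))
  run_pipeline(bound, unbound, rc$regions, descriptors,
               n_perm = if (is.null(cfg$n_perm)) 1000 else cfg$n_perm,
               bins = if (is.null(cfg$bins)) 100 else cfg$bins,
               seed = if (is.null(cfg$seed)) 1 else cfg$seed,
               output_dir = if (is.null(cfg$output_dir)) NULL else resolve(cfg$output_dir))
}
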