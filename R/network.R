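# Difference map between the two conditions' H-bond occupancy tables, with
# the >6% display filter and a 3D cylinder export (red = more frequent in the
# bound condition, blue = more frequent unbound).

#' Per-bond occupancy difference between conditions
#'
#' Takes the union of donor-acceptor keys of both tables; a key missing from
#' one condition contributes frequency 0 there.  `delta = freq_bound -
#' freq_unbound`.
#'
#' @param table_bound,table_unbound [hbond_frequency_table()] outputs computed
#'   on the same topology.
#' @return data frame of class `hbond_diff`: `donor`, `acceptor`,
#'   `donor_label`, `acceptor_label`, `chain_pair`, `freq_bound`,
#'   `freq_unbound`, `delta`.
#' @export
bond_difference_map <- function(table_bound, table_unbound) {
  kb <- attr(table_bound, "atom_key"); ku <- attr(table_unbound, "atom_key")
  if (!is.null(kb) && !is.null(ku) && !identical(kb, ku))
    stop_ensdiff("ensdiff_topology_error",
                 "H-bond tables come from different topologies")
  key <- function(t) paste(t$donor, t$acceptor)
  all_keys <- union(key(table_bound), key(table_unbound))
  ib <- match(all_keys, key(table_bound))
  iu <- match(all_keys, key(table_unbound))
  take <- function(tab, i, col, default) ifelse(is.na(i), default, tab[[col]][i])
  meta_from <- ifelse(is.na(ib), "u", "b")
  out <- data.frame(
    donor = as.integer(ifelse(meta_from == "b", table_bound$donor[ib], table_unbound$donor[iu])),
    acceptor = as.integer(ifelse(meta_from == "b", table_bound$acceptor[ib],
                                 table_unbound$acceptor[iu])),
    donor_label = ifelse(meta_from == "b", table_bound$donor_label[ib],
                         table_unbound$donor_label[iu]),
    acceptor_label = ifelse(meta_from == "b", table_bound$acceptor_label[ib],
                            table_unbound$acceptor_label[iu]),
    chain_pair = ifelse(meta_from == "b", table_bound$chain_pair[ib],
                        table_unbound$chain_pair[iu]),
    freq_bound = take(table_bound, ib, "frequency", 0),
    freq_unbound = take(table_unbound, iu, "frequency", 0),
    stringsAsFactors = FALSE)
  out$delta <- out$freq_bound - out$freq_unbound
  class(out) <- c("hbond_diff", "data.frame")
  attr(out, "atom_key") <- if (!is.null(kb)) kb else ku
  out
}

#' Keep only bonds whose occupancy changes by more than a threshold
#'
#' @param records an `hbond_diff` data frame.
#' @param threshold absolute occupancy-difference cutoff (default 0.06, the
#'   6% display rule).
#' @return filtered records, sorted by `|delta|` descending.
#' @export
filter_threshold <- function(records, threshold = 0.06) {
  if (threshold < 0 || threshold > 1)
    stop_ensdiff("ensdiff_argument_error", "threshold must be in [0, 1]")
  out <- records[abs(records$delta) > threshold, , drop = FALSE]
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export bond differences as 3D cylinders
#'
#' Writes a viewer-agnostic TSV with one cylinder per record: endpoints are
#' the time-averaged donor and acceptor positions over all frames and
#' replicas of `reference_ensemble` (by convention the bound condition),
#' radius is `k * |delta|`, colour red for `delta > 0` (more occupancy
#' bound), blue for `delta < 0`.  Optionally also writes a PyMOL CGO script
#' rendering the cylinders.
#'
#' @param records an `hbond_diff` data frame (usually after
#'   [filter_threshold()]).
#' @param reference_ensemble a [trajectory_ensemble()] supplying coordinates.
#' @param path output TSV path.
#' @param k radius scale factor (Angstrom per unit occupancy difference).
#' @param pymol_path optional path for a `.pml` viewer script.
#' @return `path`, invisibly.
#' @export
export_cylinders <- function(records, reference_ensemble, path, k = 2,
                             pymol_path = NULL) {
  topo <- reference_ensemble$topology
  if (nrow(records) && (any(records$donor > nrow(topo)) || any(records$acceptor > nrow(topo))))
    stop_ensdiff("ensdiff_topology_error",
                 "records reference atoms missing from the reference ensemble")
  mean_pos <- .time_average_positions(reference_ensemble)
  df <- data.frame(donor_label = character(0), acceptor_label = character(0),
                   x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                   x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
                   radius = numeric(0), sign_color = character(0), delta = numeric(0))
  if (nrow(records)) {
    p1 <- mean_pos[records$donor, , drop = FALSE]
    p2 <- mean_pos[records$acceptor, , drop = FALSE]
    df <- data.frame(
      donor_label = records$donor_label, acceptor_label = records$acceptor_label,
      x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
      x2 = p2[, 1], y2 = p2[, 2], z2 = p2[, 3],
      radius = k * abs(records$delta),
      sign_color = ifelse(records$delta > 0, "red", "blue"),
      delta = records$delta, stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pymol_path)) {
    lines <- c("from pymol.cgo import CYLINDER", "obj = []")
    for (i in seq_len(nrow(df))) {
      rgb <- if (df$sign_color[i] == "red") "1.0, 0.0, 0.0" else "0.0, 0.0, 1.0"
      lines <- c(lines, sprintf(
        "obj += [CYLINDER, %.3f, %.3f, %.3f, %.3f, %.3f, %.3f, %.3f, %s, %s]",
        df$x1[i], df$y1[i], df$z1[i], df$x2[i], df$y2[i], df$z2[i],
        df$radius[i], rgb, rgb))
    }
    lines <- c(lines, "cmd.load_cgo(obj, 'hbond_diff')")
    writeLines(lines, pymol_path)
  }
  invisible(path)
}

# mean position of every atom over all frames and replicas: n x 3
.time_average_positions <- function(ensemble) {
  acc <- 0; total <- 0
  for (m in ensemble$xyz) {
    acc <- acc + colSums(m)
    total <- total + nrow(m)
  }
  matrix(acc / total, ncol = 3L, byrow = TRUE)
}
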