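# Geometric hydrogen-bond detection.
#
# Criteria (defaults follow common MD practice): donor-acceptor distance
# <= 3.5 Angstrom AND hydrogen-donor-acceptor angle <= 30 degrees.  Polar
# hydrogens are attached to their donor heavy atom once, from first-frame
# geometry.

# map donor atom index -> indices of its polar hydrogens (first frame, replica 1)
.donor_hydrogens <- function(ensemble, h_bond_length = 1.25) {
  topo <- ensemble$topology
  if (is.null(topo$donor) || is.null(topo$acceptor) || is.null(topo$polar_h))
    stop_ensdiff("ensdiff_annotation_error",
                 "topology lacks donor/acceptor/polar_h annotations")
  coords <- frame_coords(ensemble, 1L, 1L)
  hmap <- vector("list", nrow(topo))
  donors <- which(topo$donor)
  if (!length(donors)) return(hmap)
  dm <- t(coords[donors, , drop = FALSE])
  for (h in which(topo$polar_h)) {
    d2 <- colSums((dm - coords[h, ])^2)
    j <- which.min(d2)
    if (d2[j] <= h_bond_length^2)
      hmap[[donors[j]]] <- c(hmap[[donors[j]]], h)
  }
  hmap
}

# detected bonds in one frame: 2-column matrix (donor, acceptor)
.detect_in_frame <- function(coords, donors, acceptors, hmap, dist_cutoff, cos_cutoff) {
  if (!length(donors) || !length(acceptors)) return(NULL)
  out <- NULL
  for (d in donors) {
    hs <- hmap[[d]]
    if (!length(hs)) next
    dv <- t(coords[acceptors, , drop = FALSE]) - coords[d, ]
    dist2 <- colSums(dv^2)
    cand <- which(dist2 <= dist_cutoff^2 & dist2 > 1e-12)
    for (ci in cand) {
      a <- acceptors[ci]
      da <- dv[, ci]
      ok <- FALSE
      for (h in hs) {
        dh <- coords[h, ] - coords[d, ]
        cosang <- sum(dh * da) / sqrt(sum(dh^2) * sum(da^2))
        if (cosang >= cos_cutoff) { ok <- TRUE; break }
      }
      if (ok) out <- rbind(out, c(d, a))
    }
  }
  out
}

# all detected (replica, frame, donor, acceptor) rows for selA -> selB and
# selB -> selA (or within selA when selB is NULL, excluding same-residue pairs)
.hbond_detect <- function(ensemble, selectionA, selectionB = NULL,
                          dist_cutoff = 3.5, angle_cutoff = 30) {
  topo <- ensemble$topology
  hmap <- .donor_hydrogens(ensemble)
  cosc <- cos(angle_cutoff * pi / 180)
  ia <- if (length(selectionA)) .resolve_atoms(ensemble, selectionA) else integer(0)
  within <- is.null(selectionB)
  ib <- if (within) ia
        else if (length(selectionB)) .resolve_atoms(ensemble, selectionB) else integer(0)
  if (!within && length(intersect(ia, ib)))
    stop_ensdiff("ensdiff_argument_error", "selections must be disjoint")
  pairs_dir <- list(list(d = ia[topo$donor[ia]], a = ib[topo$acceptor[ib]]))
  if (!within)
    pairs_dir <- c(pairs_dir, list(list(d = ib[topo$donor[ib]], a = ia[topo$acceptor[ia]])))
  res_of <- paste(topo$chain_id, topo$residue_seq, topo$insert)
  rows <- list()
  for (r in seq_len(n_replicas(ensemble))) {
    m <- ensemble$xyz[[r]]
    for (f in seq_len(nrow(m))) {
      coords <- matrix(m[f, ], ncol = 3L, byrow = TRUE)
      hits <- NULL
      for (pd in pairs_dir)
        hits <- rbind(hits, .detect_in_frame(coords, pd$d, pd$a, hmap, dist_cutoff, cosc))
      if (!is.null(hits)) {
        hits <- hits[res_of[hits[, 1]] != res_of[hits[, 2]], , drop = FALSE]
        hits <- unique(hits)
        if (nrow(hits))
          rows[[length(rows) + 1L]] <- cbind(r, f, hits)
      }
    }
  }
  if (!length(rows))
    return(data.frame(replica = integer(0), frame = integer(0),
                      donor = integer(0), acceptor = integer(0)))
  m <- do.call(rbind, rows)
  data.frame(replica = m[, 1], frame = m[, 2], donor = m[, 3], acceptor = m[, 4])
}

#' Count hydrogen bonds between two selections, per frame
#'
#' A bond is counted when one partner lies in `selectionA` and the other in
#' `selectionB`, the donor-acceptor distance is at most `dist_cutoff` and the
#' hydrogen-donor-acceptor angle is at most `angle_cutoff`.  The inter-chain
#' count (e.g. alpha chain vs beta chain of a receptor) is a proxy for
#' spatial re-arrangement between the chains.
#'
#' @inheritParams region_distance
#' @param selectionA,selectionB disjoint atom selections ([region_def()],
#'   indices, or `integer(0)` for an empty selection).
#' @param dist_cutoff donor-acceptor distance cutoff (Angstrom).
#' @param angle_cutoff hydrogen-donor-acceptor angle cutoff (degrees).
#' @return a [descriptor_series()] of integer counts.
#' @export
hbond_count <- function(ensemble, selectionA, selectionB,
                        dist_cutoff = 3.5, angle_cutoff = 30) {
  det <- .hbond_detect(ensemble, selectionA, selectionB, dist_cutoff, angle_cutoff)
  vals <- lapply(seq_len(n_replicas(ensemble)), function(r) {
    nf <- nrow(ensemble$xyz[[r]])
    counts <- integer(nf)
    sub <- det[det$replica == r, , drop = FALSE]
    if (nrow(sub)) {
      tab <- table(factor(sub$frame, levels = seq_len(nf)))
      counts <- as.integer(tab)
    }
    counts
  })
  descriptor_series(vals, "HBONDS", "inter-selection", ensemble$condition_label, "count")
}

#' Hydrogen-bond occupancy table
#'
#' Occupancy of each donor-acceptor pair = fraction of all frames (pooled
#' over replicas) in which the pair satisfies the geometric criteria.  Pairs
#' never formed are absent from the table.  With `selectionB = NULL` all
#' pairs within `selectionA` are scanned (same-residue pairs excluded) and
#' tagged by chain pair, so intra- and inter-chain networks can be separated
#' downstream.
#'
#' @inheritParams hbond_count
#' @return data frame of class `hbond_table` with columns `donor`,
#'   `acceptor`, `donor_label`, `acceptor_label`, `chain_pair`, `frequency`;
#'   attribute `n_frames` holds the pooled frame count and `atom_key` a
#'   topology signature used for cross-table consistency checks.
#' @export
hbond_frequency_table <- function(ensemble, selectionA, selectionB = NULL,
                                  dist_cutoff = 3.5, angle_cutoff = 30) {
  det <- .hbond_detect(ensemble, selectionA, selectionB, dist_cutoff, angle_cutoff)
  total <- sum(n_frames(ensemble))
  topo <- ensemble$topology
  lab <- function(i) paste0(topo$chain_id[i], topo$residue_seq[i], topo$insert[i],
                            ":", topo$residue_name[i], ":", topo$atom_name[i])
  if (nrow(det)) {
    key <- paste(det$donor, det$acceptor)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(agg$key, " "))
    d <- as.integer(parts[, 1]); a <- as.integer(parts[, 2])
    tab <- data.frame(donor = d, acceptor = a,
                      donor_label = lab(d), acceptor_label = lab(a),
                      chain_pair = paste(topo$chain_id[d], topo$chain_id[a], sep = "-"),
                      frequency = agg$Freq / total, stringsAsFactors = FALSE)
    tab <- tab[order(-tab$frequency), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(donor = integer(0), acceptor = integer(0),
                      donor_label = character(0), acceptor_label = character(0),
                      chain_pair = character(0), frequency = numeric(0))
  }
  attr(tab, "n_frames") <- total
  attr(tab, "atom_key") <- paste(topo$chain_id, topo$residue_seq, topo$insert, topo$atom_name)
  class(tab) <- c("hbond_table", "data.frame")
  tab
}
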