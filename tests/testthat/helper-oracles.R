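# Independent brute-force oracles and tiny fixture builders.  These
# deliberately avoid the package's internal code paths (plain loops, own
# Kabsch via svd, random-point SASA integration) so each descriptor and
# statistic is checked against a second, independent route.

# ---- fixture builders --------------------------------------------------------

# minimal topology: one chain, one atom per row unless residue_seq given
toy_topology <- function(n, element = "C", chain_id = "A",
                         residue_seq = seq_len(n), atom_name = "CA",
                         mass = NULL, donor = FALSE, acceptor = FALSE,
                         polar_h = FALSE, component = "receptor_alpha") {
  el <- rep_len(element, n)
  data.frame(
    atom_id = seq_len(n), atom_name = rep_len(atom_name, n), element = el,
    residue_seq = rep_len(residue_seq, n), insert = "",
    residue_name = "GLY", chain_id = rep_len(chain_id, n),
    component = rep_len(component, n),
    mass = if (is.null(mass)) ensdiff:::atomic_mass(el) else rep_len(mass, n),
    vdw_radius = ensdiff:::vdw_radius(el),
    donor = rep_len(donor, n), acceptor = rep_len(acceptor, n),
    polar_h = rep_len(polar_h, n), stringsAsFactors = FALSE)
}

# frames: list of n x 3 coordinate matrices (single replica) or a list of such
# lists (one per replica)
make_ensemble <- function(topology, frames, condition = "bound") {
  if (is.matrix(frames[[1]])) frames <- list(frames)
  xyz <- lapply(frames, function(fr)
    do.call(rbind, lapply(fr, function(m) as.vector(t(m)))))
  trajectory_ensemble(topology, xyz, condition)
}

# random proper rotation matrix
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply one rigid motion to every frame of every replica
transform_ensemble <- function(ensemble, rot, shift) {
  xyz <- lapply(ensemble$xyz, function(m) {
    t(apply(m, 1, function(row) {
      co <- matrix(row, ncol = 3, byrow = TRUE)
      as.vector(t(sweep(co %*% t(rot), 2, shift, `+`)))
    }))
  })
  trajectory_ensemble(ensemble$topology, xyz, ensemble$condition_label)
}

# ---- descriptor oracles ------------------------------------------------------

oracle_centroid <- function(coords, mass) {
  out <- c(0, 0, 0)
  for (i in seq_len(nrow(coords))) out <- out + mass[i] * coords[i, ]
  out / sum(mass)
}

oracle_distance <- function(coordsA, massA, coordsB, massB) {
  sqrt(sum((oracle_centroid(coordsA, massA) - oracle_centroid(coordsB, massB))^2))
}

oracle_rg <- function(coords, mass) {
  cen <- oracle_centroid(coords, mass)
  s <- 0
  for (i in seq_len(nrow(coords))) s <- s + mass[i] * sum((coords[i, ] - cen)^2)
  sqrt(s / sum(mass))
}

# independent Kabsch superposition (svd)
oracle_superpose <- function(mobile, fixed, fit_idx) {
  mf <- mobile[fit_idx, , drop = FALSE]
  ff <- fixed[fit_idx, , drop = FALSE]
  cm <- colMeans(mf); cf <- colMeans(ff)
  h <- t(sweep(mf, 2, cm)) %*% sweep(ff, 2, cf)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, cm) %*% t(rot), 2, cf, `+`)
}

# per-residue RMSF of representative atoms, one replica
oracle_rmsf <- function(frames, fit_idx, rep_idx) {
  fitted <- lapply(frames, oracle_superpose, fixed = frames[[1]], fit_idx = fit_idx)
  vapply(rep_idx, function(a) {
    pos <- do.call(rbind, lapply(fitted, function(f) f[a, ]))
    mu <- colMeans(pos)
    sqrt(mean(rowSums(sweep(pos, 2, mu)^2)))
  }, numeric(1))
}

# SASA by dense random-point surface integration (independent of the lattice
# used by the package kernel)
oracle_sasa <- function(coords, radii, region_idx, probe = 1.4, n_pts = 20000) {
  pts <- matrix(rnorm(3 * n_pts), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  vapply(region_idx, function(i) {
    r <- radii[i] + probe
    surf <- sweep(pts * r, 2, coords[i, ], `+`)
    buried <- rep(FALSE, n_pts)
    for (j in seq_len(nrow(coords))) {
      if (j == i) next
      rj <- radii[j] + probe
      d2 <- rowSums(sweep(surf, 2, coords[j, ])^2)
      buried <- buried | d2 < rj^2
    }
    4 * pi * r^2 * mean(!buried)
  }, numeric(1))
}

# ---- statistic oracles -------------------------------------------------------

oracle_d <- function(vb, vu) {
  sum(vb) / length(vb) - sum(vu) / length(vu)
}

oracle_dr <- function(vb, vu, trim = 0.025) {
  qb <- quantile(vb, c(trim, 1 - trim), names = FALSE)
  qu <- quantile(vu, c(trim, 1 - trim), names = FALSE)
  tb <- vb[vb >= qb[1] & vb <= qb[2]]
  tu <- vu[vu >= qu[1] & vu <= qu[2]]
  u <- c(tb, tu, qb, qu)   # trimmed union; clip bounds included
  oracle_d(vb, vu) / (max(u) - min(u))
}

oracle_tvd <- function(vb, vu, bins = 100) {
  lo <- min(vb, vu); hi <- max(vb, vu)
  breaks <- seq(lo, hi, length.out = bins + 1)
  cb <- cu <- numeric(bins)
  for (v in vb) {
    k <- min(bins, max(1, findInterval(v, breaks, rightmost.closed = TRUE)))
    cb[k] <- cb[k] + 1
  }
  for (v in vu) {
    k <- min(bins, max(1, findInterval(v, breaks, rightmost.closed = TRUE)))
    cu[k] <- cu[k] + 1
  }
  0.5 * sum(abs(cb / length(vb) - cu / length(vu)))
}

oracle_cohen <- function(vb, vu) {
  n1 <- length(vb); n2 <- length(vu)
  m1 <- mean(vb); m2 <- mean(vu)
  v1 <- sum((vb - m1)^2) / (n1 - 1)
  v2 <- sum((vu - m2)^2) / (n2 - 1)
  (m1 - m2) / sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
}

# wrap plain numeric vectors as 1-replica-per-vector series
as_series <- function(values, condition, units = "A") {
  descriptor_series(if (is.list(values)) values else list(values),
                    "test", "region", condition, units)
}
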