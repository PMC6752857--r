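---
title: "Comparing bound and unbound conformational ensembles with ensdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing bound and unbound conformational ensembles with ensdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Does a receptor's conformational ensemble change when it binds its ligand?
For a T-cell receptor (TCR) binding a peptide–MHC complex this question sits
at the heart of the debate over allosteric versus mechanical triggering
models: if binding induces conserved conformational changes away from the
interface, those changes could carry the signal.  Molecular-dynamics studies
attack this by simulating the same receptor in two conditions — ligand-bound
and free — with many independent replicas per condition, extracting geometric
descriptors per region of interest, and asking whether the two conditions'
pooled descriptor distributions differ more than replica-to-replica noise
would explain.

`ensdiff` packages that workflow: a data model for multi-replica multi-model
PDB trajectories, five descriptor families, three difference statistics with
replica-level resampling significance, masked summary tables, H-bond network
difference maps, and synthetic generators so the whole pipeline is testable
without running MD.

## Data model

A `trajectory_ensemble` is one condition's replica set: a shared atom
topology (chain, residue, element, mass, van der Waals radius, H-bond role
flags, and a *component* label — `receptor_alpha`, `receptor_beta`,
`ligand_mhc`, `ligand_peptide`) plus one coordinate matrix per replica
(frames × 3·atoms, Å).  Regions of interest are named inclusive residue
ranges on one chain (CDR loops, the AB loop, variable/constant linkers,
constant-domain helices and strands), supplied as YAML config because the
ranges are system-specific; the chain-to-component map lives in the same
config.  Alternate-location conformers are resolved to the highest-occupancy
copy; insertion codes are part of residue identity.  Coordinates are always
Å internally.

```{r}
library(ensdiff)
rc <- read_region_config("regions.yaml")
bound   <- load_ensemble(Sys.glob("bound_rep*.pdb"),   "bound",   rc$chain_components)
unbound <- load_ensemble(Sys.glob("unbound_rep*.pdb"), "unbound", rc$chain_components)
```

## Descriptors

Per region and condition the package computes per-frame scalars:

* **DIST** — Euclidean distance between the mass-weighted centroids of two
  regions (Å).  Mass weighting follows the centre-of-mass convention of the
  common MD tooling.
* **RG** — mass-weighted radius of gyration,
  $\sqrt{\sum_i m_i \lVert r_i-\bar r\rVert^2 / \sum_i m_i}$ (Å).
* **SASA** — Shrake–Rupley rolling-probe area (Å²), probe radius 1.4 Å,
  960 quasi-uniform test points per atom (both configurable), summed over
  the region's atoms.  The occluding *context* is explicit: evaluating a
  bound-state region against the receptor-only context ("ligand-stripped",
  the `noMHC` mode) uses the very same frames with the ligand removed, which
  separates burial by the ligand from genuine conformational change.
* **RMSF** — per replica, every frame is superposed onto that replica's
  first frame (Kabsch least squares over a fit region of at least three
  non-collinear atoms, typically a stable distal region); per residue the
  RMSF of the representative atom (Cα, else the residue's first atom) is the
  root time-averaged squared deviation from its time-average position; the
  reported value averages replicas.  First-frame referencing avoids the
  ambiguity of iterative-mean references; the choice is immaterial for the
  between-condition comparison because both conditions are treated alike.
* **H-bonds** — geometric criterion: donor–acceptor distance ≤ 3.5 Å and
  hydrogen–donor–acceptor angle ≤ 30° (both configurable; the values are the
  defaults of the common MD analysis tools).  Polar hydrogens are attached
  to their donor once from first-frame geometry.  The inter-chain count is a
  proxy for chain re-arrangement; per-pair occupancy tables (fraction of all
  pooled frames in which a pair is bonded) feed the network difference map.

## Comparison statistics

With $X$ a descriptor, pooled over all frames and replicas per condition:

* $d = \bar X_{\text{bound}} - \bar X_{\text{unbound}}$ — signed, in
  descriptor units.
* $d/r$ — $d$ normalised by the range $r$ of the union of the two trimmed
  distributions, where each condition is first trimmed to its own
  2.5th–97.5th percentile interval (linear-interpolation percentiles).
  Dimensionless and scale invariant.  A pooled sample below 40 values leaves
  the tail percentiles meaningless, so `stat_d_over_r` refuses it (the
  pipeline reports `NA` there instead — this hits one-value-per-replica
  descriptors such as region-mean RMSF with few replicas).
* $tvd = \tfrac12\sum_b |p_b^{\text{bound}} - p_b^{\text{unbound}}|$ — total
  variation distance between histograms on 100 shared equal-width bins
  spanning the pooled range; 0 means perfect overlap, 1 disjoint support;
  sign-free.  The bin count is configurable and `stat_tvd` emits a note when
  halving it moves the value by more than 0.05.
* Cohen's d — difference of means over the pooled standard deviation, used
  for auxiliary effect-size rows.

### Significance by replica-level resampling

Frames within a replica are strongly time-correlated, so the exchangeable
unit is the replica, never the frame.  The n bound and n unbound replicas
are merged; 1000 times two groups of n replicas are drawn *with repetition*
and the statistic recomputed between them.  The quartile $q$ is the fraction
of resampled statistics strictly smaller than the observed one (ties count
as not smaller); $q = 1$ means no random regrouping produced a larger value.
Signed statistics are significant when $q \ge 0.95$ or $q \le 0.05$ (both
tails, since $d$ is computed on signed values); the sign-free tvd only when
$q \ge 0.95$.  Summary tables set every non-significant value to zero, with
an unmasked companion table alongside.

Two properties of this null are worth knowing.  First, drawing with
repetition duplicates replicas, so null groups carry slightly more sampling
noise than the observed disjoint split; for the positively-biased tvd this
makes the test conservative when within-replica noise dominates the
replica-to-replica variation, while signed statistics stay close to their
nominal two-sided 10% rate.  Second, for descriptors with one value per
replica (e.g. region-mean RMSF) the tvd null is heavily tied at small
replica counts, again conservatively.  Both effects are visible in the
calibration tests.

### Replica-variance bootstrap

`bootstrap_replica_variance` answers "how many replicas do I need": for each
group size n it draws two groups of n replicas with repetition (10 000
times), records the mean absolute difference of the group means, and reports
the percent reduction relative to n = 1.  For iid replica means the curve
follows $1/\sqrt n$: about 68% reduction at n = 10 and 80% at n = 25, which
is why ten replicas per condition is a sensible default design and more
replicas pay off slowly.  The same curve, run on a descriptor of interest,
can justify an occupancy-difference display threshold for the H-bond network
map.

## H-bond network difference

`bond_difference_map` takes the union of donor–acceptor pairs of the two
conditions' occupancy tables (missing pairs count as 0) and computes
`delta = freq_bound − freq_unbound`.  `filter_threshold` keeps
`|delta| > 0.06` by default — a 6% occupancy change, the display rule used
with this kind of map.  `export_cylinders` writes a viewer-agnostic TSV (and
optionally a PyMOL CGO script): endpoints are time-averaged atom positions
over the bound-condition ensemble (a convention; the reference is explicit),
radius proportional to `|delta|`, red for more occupancy bound, blue for
more occupancy free.  Intra- and inter-chain pairs are both emitted, tagged
by chain pair, so either view can be filtered downstream.

## Synthetic generators

Two levels, both deterministic given a seed:

* `generate_descriptor_series` emulates a descriptor's distribution: replica
  means drawn Normal(grand mean (+ shift for bound), between-replica SD);
  frames follow a stationary AR(1) around the replica mean.  Defaults are 10
  replicas × 100 frames per condition, within-replica SD 1, between-replica
  SD 0.5 — a design mirroring a 10-replica × 100 ns study with appreciable
  replica-to-replica variation.  The AR(1) knob exists precisely to check
  that replica-level resampling is insensitive to within-replica
  autocorrelation (it is; frame-level resampling would not be).
* `generate_toy_ensemble` emulates geometry: a backbone-only two-chain
  receptor (N, amide H, Cα, C, carbonyl O per residue) whose middle-third
  residues form facing interface loops, distal anchor regions, an optional
  rigid ligand plate over the interface, and one designated inter-chain
  H-bond formed with a per-condition per-frame probability.  The bound
  condition restricts loop jitter (0.5 vs 1.0 Å), pulls the loops 0.5 Å
  together, attaches the ligand and forms the bond more often (0.8 vs 0.2) —
  the qualitative structure expected of a binding interface: lower loop
  RMSF, lower interface SASA, shorter loop distances, more interface
  H-bonds.

What the toys do *not* emulate: force-field physics, side chains, solvent,
slow collective modes, or correlated inter-region motion.  Passing tests on
them demonstrates that the machinery recovers planted effects and stays
silent under the null — not that any real receptor behaves this way.

## Numerical and design choices

* tvd binning: 100 equal-width shared bins over the pooled min–max; fewer
  than two distinct pooled values returns 0 with a warning.
* $d/r$ trimming: per-condition trim, then union range — the reading of the
  union in the normalising range; percentiles by linear interpolation.
* q ties: strictly-smaller counting, observed statistic not added to the
  null set; q is computed on signed values and masking is two-sided for
  signed statistics.
* Resampling draws are with repetition, exactly as the procedure is defined;
  this is a bootstrap-style null rather than a label permutation.
* The resampling engine precomputes per-replica sufficient statistics
  (counts on bins spanning the merged pooled range — identical to the
  observed comparison's bins) so a full pipeline run stays fast; $d/r$ draws
  concatenate values since interpolated percentiles admit no sufficient
  statistic.
* RMSF fit reference: each replica's first frame; representative atom Cα.
* SASA: golden-spiral point lattice, fixed orientation; rigid-body
  invariance therefore holds to sampling accuracy (≪ 1% at 960 points).
* Which CDR pairs define a DIST row, and the exact residue ranges, are
  config, not code: published range tables for a given receptor go straight
  into the YAML.
* No multiple-testing correction is applied across descriptor rows; the
  masked table is a screening display, and any correction policy belongs to
  the caller.

## Test problem sizes

The shipped tests run the calibration suite at 500 synthetic datasets
(10 + 10 replicas × 100 frames, 1000 resamples each), the bootstrap law at
100 replicas × 10 000 resamples, the Gaussian tvd oracle at 10⁵ values per
condition, and the end-to-end toys at 6 replicas × 30 frames with 1000
resamples — sizes at which every Monte-Carlo tolerance in the tests is a
3-sigma band or wider.

## Limitations

* The tvd component of the significance mask is conservative in
  frame-noise-dominated regimes and for one-value-per-replica descriptors at
  small n; the signed statistics carry the calibrated two-sided rate.
* SASA accuracy is bounded by the point lattice (≈0.5–1% at 960 points);
  the dense-sampling cross-checks bound the error on small systems.
* H-bond detection needs explicit polar hydrogens in the input structures;
  structures without hydrogens would need external protonation first, which
  is out of scope.
* The canonical-shape clustering that some studies report Cohen's d for is
  not included; `cohen_d` itself is.
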