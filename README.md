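# ensdiff

Compare the conformational ensembles of a receptor simulated in two
conditions — ligand-bound and free — from multi-replica molecular-dynamics
trajectories.  Built for the TCR/peptide–MHC setting (does pMHC binding
change the TCR's dynamics away from the interface?) but agnostic to the
system: anything with chains, regions of interest, and replicas works.

For each region of interest and descriptor the package computes the pooled
per-frame distributions of both conditions and summarises their difference
with three statistics:

* **d** = mean(bound) − mean(unbound), in descriptor units;
* **d/r** = d normalised by the range of the union of the two distributions,
  each trimmed to its own 2.5–97.5 percentile interval (dimensionless);
* **tvd** = total variation distance between the two pooled distributions on
  shared histogram bins, in [0, 1] (0 = perfect overlap, 1 = disjoint).

Significance is assessed at the replica level: the n + n replicas are
merged, two groups of n are drawn with repetition 1000 times, the statistic
is recomputed per draw, and the quartile **q** is the fraction of null draws
strictly smaller than the observed value.  Values outside the top or bottom
5% of the null (top 5% only for the sign-free tvd) survive; everything else
is masked to zero in the summary table.

Descriptors: inter-region centroid distances (DIST), mass-weighted radius of
gyration (RG), Shrake–Rupley solvent accessible surface area (SASA, probe
1.4 Å — including a ligand-stripped "noMHC" mode that re-evaluates the same
bound-state frames without the ligand in the occlusion context), per-residue
RMSF after Kabsch superposition on a stable fit region, and geometric
hydrogen bonds (donor–acceptor ≤ 3.5 Å, H–donor–acceptor angle ≤ 30°) as
inter-chain counts and per-pair occupancy tables.  Occupancy differences
between conditions become a 3D cylinder map (|Δoccupancy| > 6% by default,
red = more frequent bound, blue = more frequent free).

A replica-variance bootstrap (`bootstrap_replica_variance`) quantifies how
group size stabilises a descriptor: two groups of n replicas drawn with
repetition, 10 000 times, mean |difference of group means| per n — for iid
replicas a 1/√n law, i.e. ~68% reduction at n = 10 and 80% at n = 25.

Synthetic generators (`generate_descriptor_series`,
`generate_toy_ensemble`) produce distribution-level series (replica-level
mean shifts, AR(1) frame correlation) and geometry-level two-chain toy
ensembles (labelled interface loops, switchable inter-chain H-bond, optional
rigid ligand block), so the entire pipeline is testable without MD.

## Worked example

```r
library(ensdiff)

toy <- generate_toy_ensemble(toy_ensemble_spec(n_replicas = 6, n_frames = 30,
                                               seed = 77))
out <- run_pipeline(toy$bound, toy$unbound, toy$regions,
                    default_descriptor_set(toy$regions),
                    n_perm = 1000, seed = 78, output_dir = "results")
out$summary[, c("descriptor", "d", "q_d", "tvd", "q_tvd", "masked_d")]
```

```
         descriptor         d   q_d   tvd q_tvd masked_d
1  DIST CDR_A CDR_B   -0.7747 0.000 0.839 0.998   -0.775
2          RG CDR_A   -0.2378 0.001 0.606 0.999   -0.238
3        SASA CDR_A -237.8140 0.000 1.000 1.000 -237.814
4  SASA CDR_A noMHC  -93.5233 0.000 0.939 0.999  -93.523
5        RMSF CDR_A   -0.8980 0.001 1.000 0.958   -0.898
6          RG CDR_B   -0.0148 0.288 0.372 0.803    0.000
7        SASA CDR_B -184.4704 0.000 0.994 1.000 -184.470
8  SASA CDR_B noMHC  -63.0206 0.000 0.767 1.000  -63.021
9        RMSF CDR_B   -0.8500 0.000 1.000 0.942   -0.850
10     n of H-bonds    0.6667 1.000 0.678 1.000    0.667
```

The toy's bound condition restricts interface-loop jitter, pulls the loops
together, attaches a ligand plate and forms an inter-chain H-bond more
often.  The table recovers exactly that: negative masked d for loop
distance, RG, SASA and RMSF (lower in the bound state, q in the bottom 5% of
the resampling null), a positive H-bond count difference (q = 1.0: no random
regrouping of replicas produced a larger difference), and a masked zero for
`RG CDR_B`, where q = 0.288 says the observed difference is well inside
replica-to-replica noise.  `results/` receives the masked and unmasked
summary TSVs, per-descriptor histogram TSVs, the H-bond difference map with
its cylinder export (TSV + PyMOL script), a JSON result bundle and a
parameter/seed log.

Real trajectories enter the same way via one multi-model PDB per replica
plus a YAML region config (`load_ensemble`, `read_region_config`, or
`run_pipeline_file` / `inst/scripts/ensdiff-pipeline.R` for a config-driven
run); published residue-range tables for a given receptor go straight into
the config.

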