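# intarch

Integrative architecture modeling of macromolecular assemblies in R:
determine where the subunits of a large complex sit, and how they are
oriented, by combining chemical cross-linking mass-spectrometry restraints
with a low-resolution electron density map.

The package is aimed at structural biologists and methods developers who
want a self-contained, testable implementation of the full
integrative-modeling loop:

1. **Cross-link data processing** — filter cross-link spectral matches
   (CSMs) by search-engine scores, peptide length, and a classifier
   ambiguity rule; estimate target–decoy FDR; merge datasets under
   unordered residue-pair identity; classify links as intra- or
   inter-module; validate links against known structures at the 35 Å
   Cα–Cα threshold.
2. **Multi-scale representation** — per-residue beads, 10-residue coarse
   beads, Gaussian-mixture densities (one component per 50 residues), and
   flexible strings of ≤ 40-residue beads for unmodeled regions.
3. **Bayesian scoring** — for each cross-link `n` the likelihood is

   `p(d_n | X, psi) = psi (1 - f_n(X)) + f_n(X) (1 - psi)`

   where `f_n` is the probability that two points drawn uniformly from
   spheres of radius σ around the linked residues lie within the linker
   length `l_XL` = 21 Å, σ ~ U[0, 100] is a sampled positional
   uncertainty, and ψ is a sampled per-class reliability. The density
   restraint scores `-100 log CC` with
   `CC = 2 ov(M, D) / (ov(M, M) + ov(D, D))` between the model and data
   Gaussian mixtures, plus excluded-volume, sequence-connectivity, and a
   weak linear distance prior.
4. **Replica-exchange Gibbs sampling** — Metropolis moves of rigid bodies
   (≤ 2 Å, ≤ 0.04 rad), flexible beads (≤ 3 Å), and the nuisances, on a
   geometric temperature ladder (1.0–2.5), with a fast C++ sweep loop and
   bitwise-reproducible seeding.
5. **Ensemble analysis** — size-weighted RMSD clustering (k-medoids),
   precision, RMSF, per-subunit localization densities, contact and
   domain-interaction maps, cross-link satisfaction, half-versus-half
   exhaustiveness checks, jackknifing, and mass-proportional density
   segmentation.
6. **Synthetic assemblies** — a generator for toy complexes with known
   ground truth, simulated cross-link sets with planted noise, simulated
   density maps, and simulated CSM tables, so the entire pipeline can be
   validated end to end.

File formats: PDB/mmCIF structures (via bio3d), MRC/CCP4 density maps,
TSV cross-link and CSM tables, a plain-text Gaussian-mixture format, and
YAML topology configurations.

## A worked example

Simulate a four-subunit assembly, sample it, and check what was
recovered:

```r
library(intarch)

set.seed(1234)
toy  <- make_toy_assembly(toy_assembly_spec())
dens <- simulate_density(toy)
xl   <- simulate_crosslinks(toy, n_true = 50, noise_fraction = 0.05)
sys  <- assembly_system(toy$beads, toy$gaussians, dens$by_module, xl)

trajs <- run_replica_exchange(sys, n_sweeps = 5000, n_runs = 4,
                              temperatures = replica_ladder(8), seed = 1235)
ens <- select_and_cluster(trajs, sys, n_best = 500, k = 3)

# how far is the top cluster's center from the planted truth?
rb <- rmsd_beads(sys)
truth <- as.matrix(toy$beads[, c("x", "y", "z")])
ctr <- ens$coords[, , ens$centers[1]]
weighted_rmsd(ctr[rb$idx, ], truth[rb$idx, ], rb$w)
#> [1] 2.827646

satisfaction_stats(ens, sys, threshold = 21)$by_class
#>       xl_class  n satisfied_center satisfied_min
#> 1 inter_module 26         1.000000             1
#> 2 intra_module 27         0.962963             1

round(colMeans(ens$psi[ens$assignment == 1, , drop = FALSE]), 3)
#> intra_module inter_module
#>        0.095        0.044
```

The top cluster sits ~2.8 Å (size-weighted RMSD) from the ground truth,
96% of the intra-module links are satisfied on the cluster center at the
21 Å generation cutoff (100% somewhere in the cluster), and the
recovered ψ values stay within a few percent of the planted 5% noise
fraction — the three numbers that summarize a successful reconstruction.

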