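---
title: "Bayesian integrative modeling of assembly architectures from cross-links and density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian integrative modeling of assembly architectures from cross-links and density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intarch)
```

# The problem

Large multi-subunit assemblies often resist crystallography and
high-resolution cryo-EM, while two complementary low-resolution data types
are obtainable: chemical cross-links from mass spectrometry (residue pairs
bridged by a reagent of known maximum reach) and an electron density
envelope at 15–30 Å resolution. Neither alone determines subunit
positions; together, under a model of their uncertainties, they often do.
`intarch` implements that integration: a multi-scale structural
representation, a Bayesian scoring function over coordinates and nuisance
parameters, replica-exchange Gibbs sampling, and ensemble analysis of the
best-scoring solutions. A synthetic-assembly generator provides complete
ground-truth test beds so that every stage of the pipeline is verifiable
without external data.

# Representation

Subunits are represented at up to three scales simultaneously:

* **fine** — one bead per residue at the Cα position;
* **coarse** — beads covering 10-residue segments, centered at the
  segment's mass-weighted center of mass;
* **density** — a Gaussian mixture, one component per 50 residues
  (minimum one), fit to mass-weighted atomic coordinates by
  expectation-maximization.

Bead radii come from the statistical relation between volume and residue
count: `r = (3 n v_res / 4 pi)^(1/3)` with a mean residue volume
`v_res = 132.9` Å³ (standard protein density; the constant is an argument
of `bead_radius()`). Regions without coordinates become flexible strings
of beads of up to 40 residues, each carrying an isotropic Gaussian with
the same center; its per-axis variance is `r^2/5`, the variance of a
uniform ball of the bead's radius, so the Gaussian matches the segment's
molecular volume. Beads and Gaussians of a structured domain form a rigid
body: one pose, internal geometry fixed.

# Scoring function

The score is the negative log posterior. The model comprises coordinates
plus two kinds of nuisance parameter sampled alongside them: a single
positional-uncertainty radius σ (uniform prior on [0, 100] Å) and a
per-class cross-link uncertainty ψ.

**Cross-links.** The forward model `f(d)` is the probability that two
points drawn uniformly from spheres of radius σ around the two linked
residues lie within the linker length `l_XL` (21 Å for a BS3-like
reagent). We evaluate it exactly: conditioning on the distance from a
point of one sphere to the other sphere's center reduces the probability
to integrals of sphere–sphere lens volumes, which are piecewise
polynomial; fixed-order Gauss–Legendre quadrature on the analytic
breakpoints is then exact to machine precision (a Monte-Carlo oracle
confirms this in the test suite). Each reported link contributes
`p = psi (1 - f) + f (1 - psi)`, and the joint score is
`-sum w_n log p_n` with redundancy weights `w = min(1 + log2 n_spectra, 4)`
promoting links seen in many spectra. Links are grouped into
intra-module and inter-module classes with separate ψ values, so a
systematically inconsistent class is down-weighted automatically.

**Density.** Model and data mixtures are compared per module through the
overlap integrals `ov(a, b)`; the score is `-100 log CC` with
`CC = 2 ov(M, D) / (ov(M, M) + ov(D, D))`, which is 1 exactly when the
mixtures coincide. (The equivalent printed form with an asymmetric
denominator does not have that property; we use the symmetric integral
form.) Overlaps are evaluated in log space so distant configurations give
large finite scores instead of underflow.

**Stereochemistry.** Excluded volume is a harmonic penalty on bead
overlap at the coarse scale, with pairs inside one rigid body exempt;
sequence connectivity is a harmonic upper bound at four times the summed
radii of sequence-consecutive beads; a weak prior linear in every
cross-link distance (slope 0.01 Å⁻¹) provides long-range guidance even
when ψ is large. Optional harmonic tethers support anchored positions
and make the sampler testable against a closed-form Boltzmann target.

## The ψ bounds

ψ is proposed in (0.01, 0.49). At ψ = 0.5 the likelihood
`psi (1 - f) + f (1 - psi)` is constant in `f`, and above it reported
links would count as evidence *against* proximity, which has no physical
reading for a cross-linking experiment. Allowing ψ to approach 1 also
creates a pathological joint minimum in which the sampler switches the
cross-link restraint off before the structure can satisfy it and then has
no gradient to recover. Out-of-bounds nuisance proposals are rejected
rather than clamped, preserving the symmetry of the proposal and hence
detailed balance.

# Sampling

Sampling is replica-exchange Gibbs: each sweep moves every mobile rigid
body (random rotation up to 0.04 rad about a uniform axis plus a
translation up to 2 Å) and every mobile flexible bead (translation up to
3 Å) with Metropolis acceptance, then updates σ (±0.5 Å) and each ψ
(±0.02). Adjacent replicas on a geometric temperature ladder spanning
1.0–2.5 attempt exchanges once per sweep on alternating odd/even pairs.
Runs start from independent random configurations: rigid bodies uniformly
rotated and placed, and flexible beads scattered, inside the data
density's bounding box inflated by 20 Å. The temperature multiplies the
full score (posterior tempering).

The sweep loop is implemented in C++ with incremental score updates per
move; all randomness flows through R's RNG, so a run is bitwise
reproducible from its seed and a one-replica ladder consumes exactly the
same stream as plain Metropolis sampling. Frames of the coldest replica
are saved every 10 sweeps with a freshly recomputed score breakdown
(which also removes any accumulated floating-point drift in the
incremental caches). The desk-scale defaults — 8 replicas, 5,000 sweeps,
4 independent runs — complete in well under a minute for a four-subunit
assembly; production-scale ladders (64 replicas, tens of runs) are
reachable through the same arguments.

# Ensemble analysis

The `n_best` lowest-scoring frames (500 by default) are compared by
size-weighted RMSD, `sqrt(sum_b n_b |dx_b|^2 / sum_b n_b)` over the
primary beads of each residue, with no superposition because the density
restraint fixes the global frame. The matrix is partitioned by k-medoids
(PAM): "k-means by RMSD" has no exact centroid under a size-weighted
metric, whereas the medoid is precisely the member with minimal summed
RMSD to the rest — the cluster-center definition used throughout.
Clusters are reported ordered by mean score; the top cluster is the one
with the best average score (ties broken by population), which is also
how a heterogeneous ensemble containing a minority of better-scoring
solutions is resolved. Per-cluster outputs include precision (mean RMSD
to the center), per-bead RMSF, localization densities (per-voxel
occupancy probability of a subunit's beads as hard spheres, displayed at
the 0.15 isosurface), residue- and 200-residue-domain contact frequencies
(surface distance below 10 Å), and cross-link satisfaction (≤ 35 Å by
convention for the validation threshold, or the linker length for
generation-cutoff checks) reported both on the cluster center and as the
per-link minimum across the cluster, since either convention is
defensible.

Sampling exhaustiveness is assessed by splitting the runs into halves,
selecting each half's best models independently, and correlating the
per-subunit localization densities voxelwise; robustness to the data is
assessed by jackknifing (removing `floor(fraction * n)` links uniformly —
with 294 links and fraction 0.1, 265 remain). Density maps are segmented
among modules by subtracting a docked fixed component and splitting the
remaining occupied voxels with a biased nearest-seed rule whose bias is
bisected until the two volumes are proportional to the module masses;
of the two possible label anchorings the one whose density mass aligns
better with the masses is kept.

# The synthetic test bed

`make_toy_assembly()` generates assemblies with known ground truth:
compact self-avoiding Cα chains (bond 3.8 Å, confinement radius set from
the chain's molecular volume) packed by a global relaxation that pulls
declared contact pairs to a ~5–7 Å closest-Cα gap and pushes the rest
apart. Defaults encode what the pipeline's inputs look like in practice:

* four subunits of 30, 40, 50, 60 residues — *heterogeneous* sizes, so
  that density lobes are distinguishable as in real complexes;
* a closed ring contact graph — compact assemblies do not leave
  singly-anchored subunits free to pivot about one interface;
* the first subunit fixed, playing the role of a rigidly docked
  component that anchors the global frame;
* two modules (two subunits each) driving the density segmentation and
  the link classes.

`simulate_crosslinks()` samples consistent links uniformly from
*inter-subunit* residue pairs within the 21 Å cutoff. Links inside a
rigid subunit have fixed length and carry no information about the
assembly, and between-subunit links are the ones that drive assembly
modeling in practice, so spending the simulated budget on intra-rigid
pairs would produce datasets that look large but say nothing. Noise links
(a stated fraction of the final dataset, 5% by default) are drawn
uniformly over all residue pairs and may occasionally satisfy the cutoff
by chance; hidden labels record the planted status for recovery tests.
Spectral counts follow 1 + Geometric(0.5).

`simulate_density()` fits one Gaussian per 25 residues per subunit to the
true coordinates, inflates covariances by a 3 Å isotropic blur, and
groups components per module. The resulting features are roughly 15 Å
across — an intermediate-resolution envelope. The data mixture is finer
than the model's 50-residue representation rule on purpose: a real map
carries more shape detail than the mobile model it restrains.

What the toy does *not* emulate: real folds and side chains, the
lysine-specific chemistry of the cross-linker (any residue pair within
reach is eligible), peptide detectability biases, map noise and missing
wedges, and conformational heterogeneity of the target. Passing the
recovery test therefore demonstrates the correctness and calibration of
the inference machinery on data with the assumed statistical structure,
not performance on any particular real assembly.

# Numerical choices and degenerate inputs

* Forward-model quadrature: 16-node Gauss–Legendre per analytic piece
  (exact for the polynomial integrand); limits return exactly 0 and 1.
* EM fitting: weighted-data expectation-maximization with k-means
  initialization, a 1e-6 Å² variance floor on covariance diagonals, and
  log-space responsibilities. An all-identical point cloud with more than
  one requested component is an error; with one component it is a tight
  Gaussian at the point.
* Mixture overlaps: log-sum-exp accumulation; the cross-correlation is
  clamped away from zero before the logarithm so scores stay finite.
* MRC maps: mode-2 (float32) only; the header's axis permutation is
  undone on read so grids are always x-fastest; anisotropic spacing is
  rejected explicitly rather than resampled.
* Cross-link identity is the unordered endpoint pair; duplicates merge by
  summing spectral counts. Site-ambiguous spectral matches expand to all
  candidate pairs with the spectral count divided equally — the
  downstream weighting of ambiguous sites is not standardized, so the
  choice is documented and configurable upstream of the merge.
* The jackknife removes `floor(fraction * n)` links, the rounding that
  reproduces the conventional worked example (294 → 265).

# Known limitations

Sampling at the desk-scale defaults equilibrates a four-subunit toy but
is far from production scale; for larger systems, increase replicas,
sweeps, and runs together. σ is a single global radius, not per-residue.
The EM restraint assumes the map segmentation assigns each subunit to the
correct module. Cluster-count selection is left to the user (the spread
of within- versus between-cluster RMSDs in the returned ensemble is the
guide), as automatic selection on a 500-frame ensemble is unreliable.
Under some simulated-data realizations the posterior mode genuinely sits
1–2 bead radii away from the planted truth — noise links and a blurred
density can prefer a slightly shifted arrangement — which is a property
of the data, not of the optimizer; the satisfaction statistics and
half-versus-half localization correlations are the diagnostics that
distinguish this from sampling failure.

# A worked example

```{r example, eval = FALSE}
set.seed(1234)
toy  <- make_toy_assembly(toy_assembly_spec())
dens <- simulate_density(toy)
xl   <- simulate_crosslinks(toy, n_true = 50, noise_fraction = 0.05)
sys  <- assembly_system(toy$beads, toy$gaussians, dens$by_module, xl)

trajs <- run_replica_exchange(sys, n_sweeps = 5000, n_runs = 4,
                              temperatures = replica_ladder(8), seed = 1235)
ens <- select_and_cluster(trajs, sys, n_best = 500, k = 3)

satisfaction_stats(ens, sys, threshold = 21)$by_class
exhaustiveness_check(trajs, sys, n_best = 500)$density_cc
```

The same computation, from scratch and seeded from the command line, is
what `scripts/acceptance.R` performs.
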