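---
title: "Restraint-based 3D chromatin modelling from sparse capture Hi-C"
author: "sparsefold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-based 3D chromatin modelling from sparse capture Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsefold)
```

# The problem

Capture-style chromosome-conformation assays such as promoter capture Hi-C
(pcHi-C) enrich ligation products involving a designed set of "bait"
fragments (typically gene promoters). The result is a *sparse* interaction
matrix: only cells with at least one baited endpoint are reliably observed,
baited rows are strongly over-represented, and cells between two non-baited
bins carry only off-target signal. `sparsefold` reconstructs ensembles of 3D
models of genomic regions from such data and provides the statistics needed
to validate the ensembles and to compare them across cell types.

The pipeline has five stages: (i) normalization of the raw capture matrix,
(ii) representation of the region as a bead-spring polymer (one bead per
5 kb bin, bead diameter $\sigma$ = 50 nm), (iii) conversion of interaction
frequencies into spatial restraints, (iv) conformational sampling by steered
Langevin dynamics, and (v) ensemble validation and comparative analysis.

# PRINT normalization

Capture enrichment inflates every row touching a bait. The PRoportion of
INTeraction (PRINT) normalization divides each cell by the union of the
genome-wide interaction totals of its two bins,

$$\mathrm{value}_{ij} = \frac{\mathrm{bin}_{ij}}
  {\sum \mathrm{row}_i + \sum \mathrm{row}_j - \mathrm{bin}_{ij}},$$

with self-interactions included in the row sums, turning counts into
proportions in $[0,1]$ (stage `pre`). The second stage (`norm`) removes all
cells in which *neither* endpoint is baited. Removed cells become *missing*
— deliberately distinct from an observed zero — so that restraint encoding
and correlations skip them rather than treating them as evidence of absent
contact. When no genome-wide row sums are available (a matrix restricted to
one region), region-restricted sums are used and flagged with a warning;
proportions are then relative to the region, which is adequate for synthetic
work but not for genome-scale data.

```{r print-example}
v <- matrix(c(2, 4, 0,
              4, 6, 2,
              0, 2, 2), 3, 3, byrow = TRUE)
m <- interaction_matrix(v, resolution = 5000, baited = c(TRUE, TRUE, FALSE))
nm <- suppressWarnings(print_normalize(m))
round(nm$values, 4)
```

# Region selection around a viewpoint

For comparative work the region to model is derived from the data: every bin
is scored by its cumulative normalized interaction with the viewpoint bins,
the top 200 intra-chromosomal bins become network nodes together with the
viewpoint, and an edge joins a node pair when its interaction value ranks
within the top 200 among node pairs. Nodes closer than 25 kb in 1D are
merged (transitive single-linkage chaining), then nodes with fewer than 5
edges are dropped in a single pass; the modelled region is the span of the
surviving nodes, and across cell types the union of the per-cell-type spans.
Two choices here were genuinely open and are fixed as follows: score ties at
the cut are broken by 1D proximity to the viewpoint and then by index
(determinism), and viewpoint nodes are exempt from the degree filter so the
region always contains the viewpoint.

# From interactions to restraints

Normalized values are log10-transformed and standardized (z-scores, using
the population standard deviation) over the *observed non-zero* cells.
Missing and zero cells never receive restraints. For non-consecutive bead
pairs ($|i-j| \ge 2$; chain connectivity covers neighbours):

* $z \ge$ `upfreq` — harmonic restraint $k\,(d - d_{eq})^2$;
* $z \le$ `lowfreq` — lower-bound harmonic, applied only when $d < d_{eq}$;
* otherwise no restraint.

The equilibrium distance follows the inverse frequency–distance
relationship: a linear map of $[z_{\min}, z_{\max}]$ onto
[`maxdist`, $\sigma$], clamped to that interval, so the most frequently
interacting pair is restrained at one bead diameter. A `flat_deq` switch
reproduces the alternative flat reading (all harmonic $d_{eq} = \sigma$, all
lower bounds at `maxdist`). The maximal spring constant is weighted by the
sequence separation $L$, $k_{\max}(L) = k_0 / L$ with $k_0 = 10\,k_BT/\sigma^2$,
so steering is not dominated by the longest-range restraints; the $1/L$ form
is the established choice in this model family.

Because a pair needs a *z*-score to be restrained, the fraction of matrix
cells feeding restraints is far below the fraction of cells surviving
capture — with 22 captured loci over 626 bins, around 2–3% of all pairs.

# Polymer model and steered dynamics

The chain is a Kremer–Grest bead-spring polymer: FENE bonds
($K = 30\,k_BT/\sigma^2$, $R_0 = 1.5\sigma$) plus purely repulsive
Lennard-Jones (WCA) excluded volume ($\epsilon = 1\,k_BT$, cut at
$2^{1/6}\sigma$), without bending rigidity. The centre of mass is tethered
to the box centre by a harmonic with $K_t = 50\,k_BT/\sigma^2$ and
$d_{eq} = 0$; the tether acts on the centre of mass, not on individual beads
(a per-bead tether at that stiffness would collapse the chain), and exists
only to prevent drift. Initial conformations are off-lattice self-avoiding
walks (bond length $\sigma$, hard core $\sigma$) relaxed by a short
Polak–Ribière conjugate-gradient run; the line search caps per-bead moves at
$0.02\sigma$ because larger collective steps can bury a bead overlap inside
a net energy decrease from bond relaxation.

Sampling uses the Grønbech-Jensen/Farago discretization of underdamped
Langevin dynamics at $k_BT = 1$, timestep $0.01\tau$ and friction
$\gamma = 0.5$ — the standard, stable regime for this force field. (A fully
overdamped update at the same timestep would take noise steps of
$\approx 0.2\sigma$, unstable against the stiff WCA/FENE terms; the contract
is the end state, not the integrator.) During the steering phase every
restraint's spring constant ramps linearly from zero to $k_{\max}(L)$; the
conformation at the end of steering is retained. A step that overstretches a
FENE bond is rejected and retried with a halved timestep and fresh noise.
Per-model seeds make every trajectory exactly reproducible.

A restraint is *satisfied* within a tolerance of $2\sigma$: harmonic if
$d \le d_{eq} + 2\sigma$, lower-bound if $d \ge d_{eq} - 2\sigma$. The
retention policy `majority_satisfied` keeps only models satisfying more than
half of their restraints (with a warning when fewer than half the
trajectories qualify); `end_of_steering` (default) keeps all. One property
of the one-sided lower-bound potential is worth noting: at stationarity
roughly half of the thermal mass sits just below $d_{eq}$, so a lower-bound
pair typically ends within a fraction of $\sigma$ *below* its bound rather
than strictly above it — which is why satisfaction carries a tolerance.

Hyperparameters (`lowfreq`, `upfreq`, `maxdist`) are chosen by grid search —
by default the full $4 \times 4 \times 4 = 64$ product of
lowfreq $\in \{-1, -0.5, 0, 0.5\}$, upfreq $\in \{-1, -0.5, 0, 0.5\}$,
maxdist $\in \{200, 300, 400, 500\}$ nm, each ensemble assessed at dcutoff
$\in \{100, 150, 200, 250, 300, 350, 450, 500\}$ nm by the Spearman
correlation between the model contact map and the input matrix. All 64
combinations are enumerated; when `lowfreq > upfreq` the harmonic
classification takes precedence. Ties are broken toward smaller `maxdist`,
then smaller `dcutoff`.

Since steering cannot distinguish a structure from its mirror image,
`mirror_filter()` clusters models by coordinate RMSD under optimal *proper*
rotations (Ward linkage, cut at 2) and keeps the larger cluster.

# Ensemble statistics

* **Contact map** — fraction of models with a pair strictly below `dcutoff`
  (200 nm default); "below" fixes the boundary convention.
* **ppMdC** — Spearman correlation between two ensembles' per-pair median
  distances, over pair subsets defined by the capture design (capture–capture,
  other–other, mixed, all). Rank-based, hence invariant to rigid motions and
  global scaling.
* **dRMSD** — RMS difference of internal distance matrices over all pairs;
  superposition-free and reflection-invariant; Ward clustering on the
  dRMSD matrix groups models and ensembles.
* **Radius of gyration** — per model, summarized as median ± MAD; the MAD is
  reported unscaled (no 1.4826 consistency factor), matching the field's
  "±" style of spread.
* **KS two-sample test** — classical statistic with asymptotic p-value for
  comparing Rg or distance distributions.

# Comparative 3D analysis

**Radial enrichment.** Space around a viewpoint particle is divided into an
initial sphere of radius 200 nm plus equal-volume shells
($r_n = 200\,n^{1/3}$ nm up to 560 nm). Per model, each particle falls into
the shell containing its distance to the viewpoint (per-model centroid for
multi-bin viewpoints). Per shell and per binarized feature (ChIP-seq mark
presence, or expression flag), a two-sided Fisher exact test on the
inside/outside × with/without-signal table decides enrichment; the log odds
ratio is recorded only at $P < 0.01$. Two-sided is the conservative choice
(the sign of the log odds still conveys direction); a +0.5 Haldane
correction is applied to the *displayed* log odds only when exactly one cell
is zero, never to the p-value.

**Gene communities.** Expressed particles (cumulative log(FPKM) > 0 at the
TSS bin) are Ward-clustered per model on their pairwise distances; the cut
uses the Calinski–Harabasz (CH) index over $k \in [2, \min(15, n-1)]$. The
co-occurrence matrix (percentage of models in which two particles share a
cluster) is itself Ward-clustered with $100 - \text{co-occurrence}$ as the
distance, cut again by CH. Two numerical choices matter here. First, the CH
index is computed directly from pairwise distances via
$W_c = \sum_{i<j \in c} d_{ij}^2 / n_c$, which agrees with the
coordinate-space definition whenever the distances embed in Euclidean space.
Second, the optimum is the *first local maximum* of CH over increasing $k$ —
the selection originally recommended by Calinski and Harabasz — because a
plain argmax degenerates towards $k \approx n$ whenever clusters are much
tighter than their separation (the within-cluster dispersion can be driven
to zero); if some $k$ reaches exactly zero within-cluster dispersion the
smallest such $k$ is taken, as the partition is already perfectly resolved.

**Stability and geometry.** The inter-community co-occurrence score of a
community is the mean co-occurrence between its genes and all other
communities' genes (averaged over out-community genes; lower = more stably
segregated), and the per-cell score averages over communities. Treating each
community as a rigid body, per-model COM distances give typical
between-community distances, and each gene's model-mean distance to its own
community COM is correlated with its expression (Pearson by default,
Spearman available) to quantify expression gradients.

# The synthetic benchmark

Everything needed to exercise the method ships with the generator; no
downloads are involved. The toy genome emulates a ~1 Mb region at 5 kb
resolution: 626 beads, TAD blocks of 30–80 bins, *low structural
variability* and *high map noise*. Construction: one confined random chain
(unit steps inside a territory sphere sized for a 10% bead volume fraction)
whose TAD blocks are pulled towards their centroids by a compaction factor
of 0.6; the reference ensemble adds i.i.d. Gaussian jitter of $0.1\sigma$
per model (100 models by default); the dense map is the ensemble contact
fraction at 200 nm with multiplicative log-normal noise (sd 0.5), clipped to
$[0,1]$. These presets were fixed once, before any benchmarking, as a
"high noise, low variability" reading of the reference architecture; the
territory fraction and compaction are field-typical density choices.

Capture experiments are emulated by 10 random sets of 22 captured loci,
each downsampled to nested subsets of 2, 4, 6, 10, 14 and 18 — 70 capture
matrices in total. `virtual_capture()` keeps exactly the cells with a
captured endpoint (13 541 unordered pairs for 22 of 626 bins).
`sparsity_benchmark()` runs the full loop — toy genome, captures,
reconstruction at maxdist 500 nm / dcutoff 200 nm with lowfreq/upfreq
grid-searched once on the first full-capture matrix, ppMdC against the
reference — and fits ppMdC against the percentage of cells used as
restraints with an exponential curve.

The reference toy genome is treated as *one fixed object*: the benchmark
regenerates it at a fixed seed and varies the capture designs and the
thermal noise of the reconstruction. This mirrors benchmarking against a
single reference architecture; individual toy realizations differ
noticeably in map density (roughly 20–36% non-zero cells across seeds,
driven by the random TAD-size draws), and with them the absolute ppMdC at
the sparsest conditions. `sparsity_benchmark(toy_seed = )` exposes the
choice.

Two presets set the problem sizes. The `desk` preset (2 capture sets,
25 models per condition, 5 000 steering steps, 6-model grid search) is the
package's own choice for routine validation and completes in minutes on one
CPU; the `paper` preset (10 sets, 100 models, 100-model grid) matches the
full study scale. All reported test and acceptance numbers use the desk
preset; the reduced replication is the reason the benchmark tolerances are
±0.1 on median ppMdC.

What the generator does *not* emulate: restriction-fragment geometry,
ligation and capture-efficiency biochemistry, genomic distance-dependent
background decay, and inter-cell heterogeneity beyond Gaussian jitter.
Passing benchmarks therefore show that the *reconstruction machinery*
recovers a known architecture from sparse, noisy observations — not that
any particular biological conclusion transfers to real data.

```{r benchmark, eval = FALSE}
bench <- sparsity_benchmark(
  design = capture_experiment_design(n_sets = 2, seed = 1),
  preset = "desk", conditions = c(4, 10, 22), seed = 1)
aggregate(ppmdc ~ n_captures, bench$table, median)
```

# Degenerate inputs and numerical edges

* Asymmetric or negative matrix entries, conflicting duplicate triplet
  cells, and NaN coordinates are hard errors naming the offending cell or
  model.
* A cell with zero PRINT denominator becomes 0 and *missing*.
* Spearman on fewer than 3 cells or on a constant vector is an error
  (distinct from any numeric return).
* z-scores with zero spread are an error; fewer than 10 observed non-zero
  cells is a warning (the statistic is computable but unstable).
* Fisher tables with a zero margin skip the shell (logged in the output).
* `mirror_filter` returns the ensemble unchanged when all models coincide
  up to rotation.
* The SAW initializer retries per bead and restarts; persistent failure
  reports the seed.

# Known limitations

* Row sums restricted to a region make PRINT proportions region-relative.
* The toy genome's reference ensemble does not enforce excluded volume or
  FENE bounds (it is a target architecture, not a dynamics product).
* The per-model CH cut assumes the expressed particles actually cluster;
  diffuse single-blob configurations will still be cut into $k \ge 2$
  groups, and the co-occurrence matrix is then close to uniform.
* Multi-chromosome regions and genome-wide modelling are out of scope; the
  polymer is a single chain.
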