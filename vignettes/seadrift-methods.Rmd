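---
title: "Models and methods behind seadrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seadrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`seadrift` estimates connectivity of partially clonal, passively rafting
marine populations twice — once from multilocus genotypes, once from
simulated propagule transport — and quantifies how well the two agree.
This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data generator can
and cannot establish.

## 1. The genetic model

### Clone discrimination

Clonal plants are sampled as shoots (ramets); a genet may be sampled more
than once. Ramets sharing a multilocus genotype (MLG) within a site are
candidate clones. For a repeated MLG observed $n$ times among $N$ ramets we
compute

$$p_{sex} = P(X \ge n), \qquad X \sim \mathrm{Binomial}(N, p_{gen}),$$

the probability that the repeats arose by independent sexual events.
$p_{gen}$ multiplies inbreeding-corrected genotype probabilities across
loci ($p_i^2 + p_i(1-p_i)F$ for homozygotes, $2p_ip_j(1-F)$ for
heterozygotes). Both the allele frequencies and the multilocus $F_{IS}$ are
estimated from the site's *distinct* MLGs in a single pass — iterating the
estimate against successive clone assignments would couple the test to its
own output and make results order-dependent, so we deliberately do not.
Groups with $p_{sex} < \alpha$ (default 0.05) collapse to one genet; the
first-encountered ramet is kept as representative, a reproducibility
convention. Repeats failing the test are treated as coincidental sexual
identicals and remain distinct genets.

### Diversity statistics

Per site (after clone reduction): genotypic richness $R=(MLG-1)/(N-1)$;
observed and expected heterozygosity averaged over loci with between-locus
standard errors; $F=(H_E-H_O)/H_E$ over polymorphic loci (positive =
heterozygote deficit), with a two-tailed permutation test that shuffles
allele copies among genets within each locus (999 permutations by default —
the bolding rule for a diversity table without a named test). $H_E$ uses
the plain $1-\sum p_i^2$ (GenAlEx convention); the unbiased small-sample
correction sits behind `unbiased = TRUE`.

Allelic richness is rarefied to a common genet number $g$ (default 21,
matching a 40-shoot sampling design where the smallest sites keep ~21
genets). The point estimate is exact: allele $a$ carried by $G_a$ of $G$
genets appears in a random $g$-subset with probability
$1-\binom{G-G_a}{g}/\binom{G}{g}$; summing over alleles and averaging over
loci gives $A_g$. The SD comes from 1,000 seeded Monte-Carlo subsets.
Sites with $G<g$ return `NA` rather than an extrapolation.

### Distances, identity, power

$D_{ps} = 1 - ps$ uses population allele frequencies by default: per locus
$ps=\sum_a \min(p_a^A,p_a^B)$, averaged over loci. Whether the classic
implementations average over individual pairs instead is not documented
consistently; the frequency form is the default and the individual-pair
variant is exposed via `method = "individual"`. The two differ by a
positive finite-sample offset, so neither is asserted to reproduce any
third-party table exactly.

The probability of identity per locus is
$\sum p_i^4 + \sum_{i<j}(2p_ip_j)^2$ (sib variant
$0.25+0.5\sum p^2+0.5(\sum p^2)^2-0.25\sum p^4$), multiplied across loci.

`power_simulation()` follows the drift scheme of POWSIM: pooled observed
frequencies drift per site through $t$ generations of binomial sampling of
$2N_e$ gene copies, with $t$ chosen from $F_{ST}=1-(1-1/2N_e)^t$
($N_e = 200$ by default); samples of the observed sizes are then tested for
homogeneity with a Pearson chi-square summed over loci (a Fisher-exact
variant is kept as an independent oracle). At $F_{ST}=0$ the rejection rate
is the realized type-I error and is verified to sit at $\alpha$.

### Directional migration

For each ordered pair, a hypothetical migrant pool takes the per-allele
geometric mean of the two sites' frequencies (renormalized per locus; an
allele absent on either side has geometric mean 0, matching the pooling
semantics of the published method). The differentiation $d_A = G_{ST}(A,
\text{pool})$ is converted to relative migration *out of* A towards B as
$m=(1/d_A-1)/4$, and the matrix is normalized by its maximum. The source
attribution deserves a note: a source's alleles dominate the migrant pool,
so *low* differentiation from the pool marks an exporter. We verified the
direction on a constructed oracle (an admixed population receives more than
it sends) before fixing it. Bootstrap asymmetry tests resample genets
within sites (1,000 draws by default) and report two-sided p-values for
$m_{A\to B}-m_{B\to A}$. Only the $G_{ST}$ variant is implemented; other
differentiation measures are an extension hook. Pairs with zero
differentiation from the pool are undefined and are set to the matrix
maximum with a warning.

## 2. The biophysical model

### Synthetic seascape and currents

`make_seascape()` builds a deterministic (seeded) grid — default
100 × 80 cells of 4 km, echoing a few-km circulation-model resolution at
desk scale — with a wavy western land band, near-shore extant habitat
grouped into disjoint archipelagos, an offshore annulus of historic habitat
absent from the extant map (a lost offshore bank), and named site polygons.
`historic_fraction = 0` collapses historic onto extant habitat.

`make_velocity_field()` composes three divergence-free parts: a poleward
coastal boundary current with exponential offshore decay (0.15 m/s peak), a
basin-scale double gyre, and seeded streamfunction noise whose amplitude is
scaled per year by an NAO-like multiplier (defaults span 0.7–1.35 over
eight years, 1995–2002). Snapshots default to 24 h: the analytic field
varies slowly, so linear temporal interpolation between daily snapshots is
accurate, and the 3-hourly cadence of a real circulation product would cost
memory without adding information here.

### Particle tracking and dispersal matrices

Particles are released from habitat cells across July–September
(20/50/30 %), drift in the surface layer for 5/10/20/30 days
(5/10/20/65 %), and are advected with 4th-order Runge–Kutta (15-min step by
default) over bilinearly/linearly interpolated velocities, plus an optional
seeded random walk (10 m²/s) standing in for unresolved sub-grid motion — a
smooth analytic field otherwise underestimates dispersion. Beaching rule: a
particle whose next position falls on land stops where it is and its end
cell is that last sea cell (rafting shoots strand); the destination counts
toward the dispersal matrix only if the cell is habitat. Leaving the domain
flags the particle lost. The original-scale 2.5 million trajectories are
scaled to configurable desk-scale counts; the Monte-Carlo error of
$P_{ij}$ shrinks as $1/\sqrt{n}$ and is tested to.

$P_{ij}$ = trajectories from $i$ ending in $j$, divided by released($i$);
row sum plus loss fraction equals 1 exactly. Multigeneration stepping-stone
connectivity is the habitat-masked matrix power $P^g$ ($g=32$ by default —
enough hops to span a ~500 km domain), computed dense by repeated squaring.
Site-level multigeneration values aggregate the cell-level matrix with a
released-weighted mean over source cells and a sum over destination cells,
preserving per-propagule probability semantics; this equals direct
site-level counting when releases are uniform. For correlation with
symmetric distances the directed matrix is min-symmetrized
($S_{ij}=\min(M_{ij},M_{ji})$ — the weaker direction limits mutual
exchange); offset log transforms use $10^{-10}$ (single generation) and
$10^{-30}$ (multigeneration, whose nonzero entries are far smaller).

### Barrier clustering

Partially isolated clusters are found by agglomerative merging: symmetrize
with the pairwise *max* (connectivity in either direction defines
adjacency — deliberately different from the min convention above, which
serves distance correlation), start from singletons, and repeatedly merge
the cluster pair with the highest mean inter-cluster connectivity while
that mean exceeds the dispersal restriction (0.004 by default). Starting
from singletons is the exact limit of a "fine initial partition" and avoids
the seed sensitivity of a spectral k-means initialization; ties break on
label order, so the procedure is fully deterministic and permutation
invariant. Cached pair sums make each merge $O(k^2)$. Note the threshold
semantics: the restriction bounds the *tolerated* between-cluster
connectivity, so lowering it forces more merging and fewer, coarser
clusters; raising it stops merging earlier and yields more clusters. On
small instances the returned partition is verified feasible against an
exhaustive scan of all set partitions. The original publication's exact
minimization algorithm is not claimed — only its two stated constraints
(penalized merging; a fixed between-cluster mean restriction) are honoured.

## 3. Cross-validation statistics

Sea distance is the least-cost over-water path on the 8-connected sea
lattice (diagonal cost $\sqrt2$ × cell size; corner-cutting across a
land-diagonal is allowed and documented), via Dijkstra; site coordinates
snap to the nearest sea cell within 2 cells, and a manual override hook
exists for pairs where the automatic path is judged unrealistic. Distances
are log10-transformed before isolation-by-distance tests.

`mantel()` correlates off-diagonal pairs of two symmetric matrices, null by
simultaneous row/column permutation of one matrix;
`asymmetric_mantel()` keeps all ordered pairs ($A_{ij}$ and $A_{ji}$ as
distinct observations) and permutes one matrix's rows and columns jointly,
preserving each matrix's internal directional structure. The published
asymmetric script is unavailable, so this construction is a documented
stand-in with the same invariances. P-values use
$(1+\#\{|r_{perm}|\ge|r_{obs}|\})/(1+\text{perms})$ and can never be zero;
100,000 permutations is the publication-grade default in the spec-level
configuration, 999 the desk default. Expected signs: $D_{ps}$ correlates
positively with sea distance, negatively with dispersal probability;
directional migration positively with directional dispersal.

Threshold networks follow the intermediate-threshold idea: scan the edge
cutoff, bracket the informative window between the value where the graph
stops being complete and the percolation value where it disconnects
(minimum/maximum spanning-tree bottleneck), and select the midpoint —
arithmetic for distances, geometric for probabilities, whose informative
scales span decades. One caveat found during implementation: the scan
midpoint always sits above the percolation bottleneck, so a graph at the
selected threshold retains its bridge edge; recovering *block structure* as
separate components requires a cutoff between the within-block and
between-block scales, which the `build_network()` threshold argument
accepts directly (and the externally chosen thresholds of a publication can
be passed verbatim). Isolated nodes are kept and flagged by default;
`drop_isolated = TRUE` reproduces the convention where disconnected
populations are dropped from the drawing.

## 4. The synthetic-data generator, and what a green test establishes

`simulate_genotypes()` is a forward-time Wright–Fisher model: demes of
constant genet number coupled by gene flow proportional to any dispersal
matrix (rows = source), partial clonality (a recruit copies a local genet
with probability `clonality`), and strict stepwise (±1 repeat)
microsatellite mutation at $10^{-3}$ per allele per generation applied to
sexual gametes. All demes start from one ancestral allele pool, so
differentiation accrues purely from drift shaped by the dispersal matrix —
exactly the state of the world the isolation-by-oceanography statistics
assume. Defaults (100 genets/deme, 40-shoot samples, 10–12 loci, clonality
0.3, ~100 generations) were chosen once to produce the diversity levels
typical of a temperate seagrass survey ($R$ near 1, $H_E$ ~ 0.5,
$D_{ps}$ ~ 0.1–0.3) and were not revisited against test outcomes.

What green tests establish: that each statistic matches its independent
oracle (enumeration, closed form, hand computation, or a second simulator)
on small instances; that the estimators recover a known truth qualitatively
(positive IBD, negative isolation-by-oceanography, multigeneration beating
single-generation correlation on a stepping-stone chain; a flow divide
recovered as a cluster boundary); and that the permutation tests are
calibrated ($\alpha$-level rejection under independence, 500 replicates at
199 permutations — the permutation count only sets p-value resolution).
What they do not establish: hydrodynamic realism (no tides,
stratification, runoff), mutation-model fidelity beyond strict stepwise,
linkage or null-allele artefacts, or any quantitative match to a specific
published survey — the deposited data of the motivating study are not
bundled, and criteria that require them are out of desk-scale scope.

## 5. Numerical and interface choices

- All randomness flows through explicit integer seeds (`withr_seed`
  restores the caller's RNG state); reruns of any stage or of the whole
  pipeline are bit-reproducible, which the suite asserts.
- Genepop has no site field: the writer emits `site:ramet` labels, the
  reader splits on the colon, falling back to `pop<k>` names.
- Missing allele calls use a sentinel (0) with pairwise deletion per locus,
  even though a complete survey may have none — real files have gaps.
- Matrix powers are dense (habitat cell counts at desk scale are a few
  hundred); repeated squaring keeps 32 generations at ~5 multiplications.
- Degenerate inputs fail loudly: constant matrices in Mantel tests,
  threshold scans without an informative window, sites on land beyond the
  snap radius, unknown configuration keys.
- The pipeline's correlation table writes `NA` (not an error) for a
  predictor that is constant at desk scale — e.g. a min-symmetrized
  single-generation matrix with no reciprocal site pairs — mirroring how
  such cells appear as "na" in published tables.

## 6. Known limitations

- The barrier scheme is a faithful implementation of the stated constraints,
  not of the unpublished original algorithm; with very sparse sampled
  dispersal matrices (few particles per cell), mean-linkage merging stalls —
  use more particles per cell rather than a lower threshold.
- The double-gyre-plus-boundary-current flow has no coastal-trapped waves or
  river plumes; directionality enters only through the boundary current.
- `asymmetric_mantel` treats the diagonal as missing and requires both
  matrices to carry the same label order; it does not attempt the
  three-way permutation schemes of some landscape-genetics packages.
- Power simulation assumes unlinked loci and equal per-site $N_e$.
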