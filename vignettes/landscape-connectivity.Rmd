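---
title: "Models and methods behind corridorgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corridorgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridorgen)
```

corridorgen implements a complete individual-based landscape-genetics
workflow for wildlife connectivity studies built on non-invasively
collected microsatellite genotypes: genotyping quality control, unique
individual identification, genetic diversity and differentiation,
first-generation migrant detection, raster resistance surfaces,
circuit-theory effective resistance between populations, and permutation
Mantel tests relating the genetic and landscape matrices. This vignette
explains the models, the parameters that matter, the design choices made
where the method families leave room, and what the synthetic-data module
does and does not emulate.

## Genotype quality control

Faecal-DNA genotypes are error-prone, so each sample is amplified
repeatedly (four replicates is the common field protocol;
`consensus_genotype()` accepts any number of at least two). The consensus
follows the multiple-tubes convention: the modal diploid call wins, but a
heterozygote is accepted only when observed in at least two replicates —
allelic dropout turns true heterozygotes into apparent homozygotes, so a
single heterozygous observation is weak evidence, whereas false
homozygotes require two independent dropouts. Per-locus quality is the
fraction of non-missing replicates that match the consensus; the sample
quality index (QI) is the mean over loci with data, and samples are
retained at `QI >= 0.75`. Loci with no data are excluded from the QI
denominator rather than counted as failures, so a sample is judged only
on the loci it actually produced.

Unique individuals are then identified by multilocus matching
(`identify_individuals()`). Samples typed at fewer than 12 of the 14 loci
are dropped, and a pair of samples is merged only when their typed loci
overlap at 12 or more and disagree at no more than `max_mismatch` of them
(default 0; non-invasive pipelines sometimes allow 1–2 to absorb residual
genotyping error). Matching is closed transitively and the
lexicographically smallest sample id represents each individual, which
makes the operation invariant to input order. The sibling probability of
identity, `pid_sibs()`, gives the usual conservative justification for
this matching: per locus
$P_{ID\text{-}sib} = 0.25 + 0.5\sum p_i^2 + 0.5\left(\sum p_i^2\right)^2 -
0.25\sum p_i^4$, multiplied across loci.

## Diversity and differentiation

`diversity()` reports alleles per locus, observed heterozygosity, unbiased
expected heterozygosity $H_E = \frac{n}{n-1}\left(1 - \sum p_i^2\right)$
with $n$ the number of typed gene copies, and a Hardy–Weinberg exact test.
Because microsatellite loci here can carry up to 16 alleles, full
enumeration of genotype configurations is infeasible; the test is
Monte-Carlo: gene copies are shuffled within the locus and the conditional
probability of the resulting genotype configuration given the (invariant)
allele counts is compared with the observed one. The default is 10,000
shuffles, giving p-value resolution of about $10^{-4}$.

Two differentiation measures are computed because they integrate gene
flow over different time scales. Weir–Cockerham's $\theta$ (`fst_wc()`)
estimates $F_{ST}$ from per-allele variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals); the multilocus estimate is the ratio of summed components
$\sum a / \sum(a+b+c)$, not a mean of per-locus ratios, which keeps poorly
informative loci from dominating. $F_{ST}$ reflects historical
connectivity. The allele-sharing distance $D_{SP}$ (`dsp()`) is more
sensitive to recent gene flow: for every inter-population pair of
individuals the proportion of shared alleles per co-typed locus is
$\sum_k \min(c^{(1)}_k, c^{(2)}_k)/2$, averaged over loci and then over
pairs, and the distance is $-\ln(\bar{p}_s)$. The logarithmic form is the
default because allele-sharing distances on strongly diverged data grow
well past 1, which the bounded $1-\bar{p}_s$ variant cannot express; both
variants are available. Standard errors for both measures come from a
leave-one-locus-out jackknife, and significance for $\theta$ from
permuting individuals between the two populations.

Pairwise relatedness (`ml_relatedness()`) maximises the likelihood of a
genotype pair as a mixture over sharing 0, 1 or 2 alleles identical by
descent, using the standard conditional genotype-pair probabilities. The
$(k_0, k_1, k_2)$ simplex is searched on a 0.01 grid followed by a 0.001
local refinement — the likelihood is smooth and low-dimensional, so this
is both simple and reliable — and $r = k_2 + k_1/2$. The reported
relationship category is the likelihood argmax among unrelated, half-sib,
full-sib and parent–offspring. Note that constrained maximum likelihood
at the $k_0 = 1$ boundary is upward-biased for truly unrelated pairs;
with a 14-locus panel individual estimates are noisy and categories are
more trustworthy than point estimates of $r$.

## Migrant detection

`detect_migrants()` implements genetic assignment with a resampling null.
The assignment likelihood is a Bayesian posterior-predictive probability:
with observed gene-copy counts $n_a$ (allele $a$) out of $n$ in the
reference population and $k$ alleles observed at the locus across all
populations, the diploid genotype $ab$ has probability

$$P(ab) = 2^{[a \ne b]} \cdot \frac{n_a + 1/k}{n + 1} \cdot
\frac{n_b + 1/k + [a = b]}{n + 2},$$

multiplied across typed loci (log10 scale). The $1/k$ prior mass keeps
alleles unseen in a reference population at finite likelihood, which is
what allows detection even at modest differentiation. The individual's
own gene copies are removed from its home population's counts
(leave-one-out) so that a migrant does not inflate its own home
likelihood.

The detection statistic is $\Lambda = \log_{10} L_{\max} - \log_{10}
L_{home} \ge 0$: zero when the genotype is likeliest at home, increasingly
positive the more strongly some other population explains it. (The
statistic is often written as a likelihood ratio $L_{home}/L_{\max}$; the
sign convention here makes the printed value positive for suspect
migrants, matching how such tables are usually reported.) The null
distribution of $\Lambda$ for residents of each population is built by
Monte-Carlo resampling: `n_sim` multilocus genotypes are drawn allele by
allele, with replacement, from the population's observed frequencies —
deliberately resampling rather than drawing from a parametric model, so
the null inherits the sample's own allele-frequency noise. `p_resident`
is the fraction of null statistics at least as large as the observed one
(ties counted, conservative), and an individual is flagged as a
first-generation migrant at `p_resident < alpha` with `alpha = 0.01` and
`n_sim = 10000` as the conventional settings.

`migrant_posterior()` is the complementary model-based detector: each
individual is resident with prior $1-\nu$, an F0 migrant from some other
population (total prior $\nu/2$, split equally), or the offspring of one
migrant parent (F1, the remaining $\nu/2$). The F1 likelihood draws one
gene copy from the home posterior and one from the source posterior,
summed over phase. $\nu$ is the migration prior; because it is not
identified by the data, the package evaluates the whole grid
$\{0.01, 0.02, 0.05, 0.1\}$ and reports per-individual migrant
probabilities for each, with `> 0.9` as the conventional flag threshold.
A real migrant should keep its flag across the grid; sensitivity of a
call to $\nu$ is evidence of weak signal. Ancestry deeper than one
generation is out of scope (the F0/F1 decomposition corresponds to one
generation back). `migration_matrices()` converts either detector's
output into a row-stochastic matrix $m_{ij}$ — the fraction of
individuals sampled in $i$ attributed to source $j$ — whose off-diagonal
rows and columns serve as asymmetric immigration and emigration matrices
for the Mantel stage.

## Resistance surfaces

Four surfaces are built at 1-km resolution, each rescaled linearly to
[1, 100] (`rescale_1_100()`): habitat proximity (Euclidean distance to
the nearest retained forest patch, patches themselves at 1), tree cover
(inverted: 67 % cover maps to 1, bare ground to 100), settlement
proximity (inverted distance to the nearest illuminated cell: at a
settlement 100, at the darkest point 1), and road density (km of road per
km² cell, by exact segment clipping, road-free cells at 1). Habitat
patches are 8-connected components of forest cells with area strictly
greater than 10 km²; smaller fragments are treated as non-habitat. The
study area is the 30-km buffer around retained patches — the longest
telemetry-documented dispersal distance for the focal species — minus
urban cells, defined as night-light radiance above 20. Urban cells are
removed from the landscape graph entirely rather than given resistance
100: a town is treated as a hard barrier, not merely expensive terrain.
Distance sources for the settlement layer are all illuminated cells, not
only urban ones (a flag switches this). Multi-element surfaces are
unweighted cell-wise means of the rescaled layers, rescaled again;
weights are exposed but the default is deliberately uninformative because
nothing in the data calibrates them.

## Circuit theory

`build_graph()` turns a resistance raster into a conductance graph:
valid cells are nodes, 8-neighbour pairs get conductance
$1 / (d \cdot (r_i + r_j)/2)$ with $d = 1$ for cardinal and $\sqrt{2}$
for diagonal neighbours (averaged resistance; averaged conductance is
available as an option). Population polygons are short-circuited into
supernodes — infinite internal conductance — and every unordered pair is
solved by injecting unit current at one supernode and grounding the
other. The solver is a direct sparse Cholesky factorisation of the
grounded Laplacian (grids used here stay below 50k nodes, where direct
factorisation is faster and more accurate than iterative solves; the
solve residual is checked against $10^{-8}$). Effective resistance is
mathematically invariant to the injected current, so population
abundance counts used as source strengths cannot change pairwise
resistances; they enter as weights $s_i s_j / \overline{s_i s_j}$ on the
per-pair contributions to the cumulative current map, and an explicitly
labelled strength-normalised variant $R_{ij}/(s_i s_j)$ is emitted
alongside the plain matrix so downstream stages can consume either.
Disconnected pairs are reported as infinite and flagged.

## Mantel tests

`mantel()` correlates the vectorised entries of two co-labelled matrices:
the upper off-diagonal triangle when both are symmetric, all $n(n-1)$
off-diagonal entries otherwise (the asymmetric migration-rate matrices),
permuting rows and columns of one matrix jointly. With six populations
the full $6! = 720$ enumeration is cheap, so p-values are exact whenever
$n \le 7$; sampled permutations use the $+1$-corrected two-tailed
estimator $p = (\#\{|r^*| \ge |r|\} + 1)/(B + 1)$, which can never return
zero. `partial_mantel()` correlates the residuals of each matrix
regressed on a conditioning matrix, permuting the residualised matrix
(Smouse–Long–Sokal). `mantel_ranking()` tests one genetic matrix against
a list of resistance surfaces and sorts by $r^2$ — the layout used to
compare candidate surfaces — conditioning on inter-population Euclidean
distance when a conditioning matrix is supplied, so that a surface is
credited only for structure beyond what mere separation explains.
`ibd_test()` is the isolation-by-distance special case against raw
Euclidean distance.

## The synthetic-data module

No field data ship with the package, so `simdata` generates everything
with known ground truth. Population allele frequencies follow the
F-model: ancestral frequencies from a flat Dirichlet, population
frequencies from $\mathrm{Dirichlet}(p_{anc}(1-F)/F)$, which makes the
expected Weir–Cockerham $\theta$ equal to $F$ — the divergence knob is
calibrated in the same currency the estimator reports. Genotypes are
drawn under Hardy–Weinberg within populations. First-generation migrants
are planted by redrawing a destination individual's genotype from the
source population's frequencies while keeping its destination label — an
F0 migrant by construction. Replicate calls apply allelic dropout
(heterozygote loses one allele) and false alleles (a call replaced by a
random other allele of the locus) at configurable rates. All simulation
functions take an explicit seed, use their own seeded generator without
touching the caller's RNG state, and are bit-reproducible.

The bundled fixture (`make_fixture()`) mirrors the motivating study
design: six populations of 5, 7, 5, 16, 15 and 7 individuals, 14 loci
with 5–16 alleles per locus (mean 11.71), F-model divergence 0.12 chosen
so pairwise $\theta$ falls in the 0.03–0.22 range, five planted migrants
spanning four population pairs, and a 60 × 60 km landscape whose habitat
patches carry the populations and whose abundance counts equal the
sample sizes.

Synthetic landscapes place habitat patches on a jittered ring (optionally
with one patch at the landscape centre), smooth-noise tree cover clipped
to the 0–67 % range of continuous-fields products, Gaussian light kernels
for settlements (some above the urban threshold of 20), decoy patches
below the 10-km² filter, extra unsampled forest patches above it, and
random road polylines. Landscapes in which noise merges two population
patches into one component are rejected and redrawn with a shifted seed —
the generator's contract is six distinct patches.

## The end-to-end experiment

`connectivity_experiment()` closes the loop from landscape to inference.
Its landscape walls off the central population with a ring of urban
settlement cells broken by three 3-km forested corridor gaps; gap cells
are lit (but below the urban threshold) so they carry resistance ~100 in
the settlement layer, carry full tree cover (hence minimal tree-layer
resistance), and roads are cut at the reserve boundary rather than routed
around it. This geometry is what makes the experiment able to
discriminate between layers at all: a hard urban wall forces every
layer's current through the same gaps, so the *generic* cost of the
bottleneck appears in all four resistance matrices, while the
*layer-specific* cost of actually crossing the gap cells is large only
for the settlement layer. The central placement keeps the walled
population's distances to the others unremarkable, so the isolation
signature is orthogonal to geography.

Gene flow is then generated from the settlement resistance matrix as
$m_{ij} = m_{med} \exp(-(R_{ij} - \mathrm{median}\,R)/\tau)$ capped at
0.08, with $\tau$ set from the spread between the 80th percentile and the
median of the off-diagonal resistances (divided by 2.5). This anchors
the median pair at $m = 0.04$ (well-connected) and sends the walled
pairs, which occupy the top of the resistance distribution, to rates
around $4 N_e m \approx 1$, where drift visibly differentiates them.
Allele frequencies start identical everywhere and evolve for 500
generations of deterministic migration mixing plus multinomial drift at
$N_e = 100$; 45 individuals per population are then sampled at a 28-locus
panel. The panel is larger than the fixture's 14 loci because the
experiment's verdict rests on rank-correlating 15 pairwise values —
locus-sampling noise in $D_{SP}$ at 14 loci is large enough to scramble
the layer ranking in an appreciable fraction of runs even when the
underlying process is exactly right, and doubling the panel halves that
variance. Rankings use partial Mantel tests conditioned on Euclidean
distance, the standard design when comparing resistance surfaces whose
shared component is mere separation. A correct pipeline ranks the
settlement surface first in most replicates and finds no systematic
isolation by distance; the acceptance suite asserts exactly these two
rates over 20 seeded replicates.

What the generator does *not* emulate: microsatellite mutation
(divergence is pure drift/migration, appropriate for the few-hundred
generation scales simulated), null alleles and stutter artefacts
(replicate errors are symmetric dropout/false-allele processes), spatial
sampling within populations (individuals carry their population's patch
centroid), coalescent ancestry (the F-model is a moment-matched stand-in)
and real GIS co-registration issues (all rasters share one grid by
construction). Passing tests therefore demonstrate the correctness and
calibration of the estimators under the stated models, not robustness to
every artefact of real non-invasive data.

## Numerical choices and degenerate inputs

Frequency vectors are validated to sum to 1 within $10^{-12}$; rescaled
layers are clamped to [1, 100] to absorb floating-point overshoot; a
constant raster rescales to all 1; an all-missing locus yields a missing
consensus excluded from QI; monomorphic loci give $H_E = 0$ and HWE
p-value 1; disconnected region pairs give infinite resistance with a
flag; a constant matrix makes Mantel's $r$ undefined and is an error,
while a constant *conditioning* matrix degrades the partial test to the
simple one with a warning; a conditioning matrix identical to a test
matrix residualises it to zero and the partial correlation is reported
as exactly 0. Unordered allele pairs are stored sorted ascending so
genotype comparisons never depend on call order.

## Worked example

```{r example, eval = FALSE}
fx <- make_fixture(seed = 1)
report <- pipeline_run(pipeline_config(seed = 1, n_sim = 1000,
                                       layer_combos = "single"),
                       fixture = fx)
report$migrants          # Lambda, p_resident, migrant probabilities per nu
report$ibd               # F_ST / D_SP / rates vs geographic distance
report$mantel_dsp        # D_SP vs each resistance surface, sorted by r2
render_differentiation(report$fst$fst, report$dsp$dsp, report$dsp$se)
```

The run report carries a plain-text log with the master seed and stage
timings, and every matrix in it is traceable to an exported function.
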