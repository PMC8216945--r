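---
title: "Models and methods for Y-linked scaffold identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Y-linked scaffold identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msytools)
```

# The problem

Mammalian reference assemblies routinely leave the Y chromosome in pieces:
it is repeat-rich, haploid in the sequenced individual, and partially
homologous to the X. The MSY (male-specific region of the Y) must therefore
be fished out of the unplaced scaffolds after the fact. This package
implements the computational side of that workflow — sexing samples,
classifying scaffolds by three independent lines of evidence, ordering the
survivors on a radiation-hybrid panel, and preparing haploid Y SNPs for
phylogenetic and demographic analysis — together with simulators that
generate all inputs with known truth.

# Sex inference

Unsexed samples are classified by the fraction of their reads mapping to
male seed sequences. Seeds are derived from per-position coverage of
known-sex samples over a Y-candidate scaffold as maximal runs where every
male sample is covered (default depth ≥ 3) and every female sample is empty
(default ≤ 0), of at least 500 bp (`derive_seed_regions`). No aligner is
bundled: the module consumes mapped/total read counts, and for simulated
end-to-end runs a k-mer pseudo-mapper (`count_seed_hits`, exact canonical
31-mer sharing) stands in. With k = 31, a spurious female hit requires a
chance exact 31-bp match, which is why observed female mapping rates are
0.00% while male rates sit two or more orders of magnitude higher; the
default thresholds call rates > 0.04% male and ≤ 0.00% female, leaving an
ambiguous band that is excluded rather than guessed. The run-length
parameters are heuristics for "male-covered, female-empty at
read-mapping resolution"; they matter only near the boundary and are all
configurable. `threshold_separation_test` uses the Welch (unequal-variance)
form of the two-sample t-test, the safer default when group variances are
unknown; for two degenerate constant groups it returns 1 (equal means) or 0
by contract.

# AD-ratio classification

With `norm` the ratio of the two libraries' total read counts, the
normalised average-depth ratio of a scaffold is

$$\mathrm{AD} = \frac{\bar d_{\mathrm{female}}}{\bar d_{\mathrm{male}}\cdot
\mathrm{norm}},\qquad \mathrm{norm} =
\frac{N_{\mathrm{female}}}{N_{\mathrm{male}}}.$$

Depth averages include zero-coverage positions. Expected values are 0 (Y),
1 (autosome) and 2 (X). The classification windows are `AD < 0.4` → Y,
`0.6 < AD < 1.4` → autosome, `1.6 ≤ AD < 2.4` → X; everything else,
including the undefined case of zero male depth, is unassigned — absence of
male data is never treated as evidence for Y. The Y window is deliberately
wider than the strict `< 0.3` used for positive controls: X-transposed
blocks at ~99% identity attract female reads, pushing a true Y scaffold's
AD up by roughly (block fraction) × (identity). Scaffolds shorter than
1,000 bp are left unassigned because the mean depth of a short scaffold is
dominated by edge and mappability effects. The lower X bound is taken as
inclusive (`1.6 ≤ AD`), reading the printed open interval as a typographical
slip; the choice moves only scaffolds sitting exactly on 1.6.

# YGS k-mer classification

The informative unit is the single-copy (nonrepetitive) canonical 31-mer:
one occurring exactly once across the entire query scaffold pool. This
definition follows the original k-mer subtraction method; a per-scaffold
variant is available (`scope = "per_scaffold"`). Read dictionaries keep
k-mers seen at least twice (`min_count = 2`), which suppresses
sequencing-error k-mers — at 1% per-base error, only ~73% of read 31-mers
are error-free, but at ≥10× coverage nearly every genomic k-mer is still
seen twice without errors, while error k-mers are essentially singletons.
A scaffold is Y-linked when >90% of its single-copy k-mers match the male
dictionary and <10% match the female one. The female criterion stated on
the "matched" axis and the "unmatched" axis are the same number
(`pct_unmatched = 100 − pct_matched`), so no separate rule switch exists;
both thresholds are parameters.

AD and YGS fail in complementary ways on X-transposed Y regions: the
region's k-mers are matched by female reads (YGS weakens) while its depth
only rises proportionally to the transposed fraction (AD often still
calls Y below fraction ≈ 0.4). This is why the high-confidence set is the
*intersection* of AD, YGS and homology calls and the working set is their
*union* (`consensus_calls`). Homology voting sums aligned bases per target
chromosome over hits with identity ≥ 0.8 and calls Y only on a strict win
covering ≥ 50% of the scaffold; ties never call Y, and the two thresholds
are placeholders for whatever alignment protocol produced the hit table.

# Radiation-hybrid mapping

Retention vectors record each marker as present (H), absent (A) or
ambiguous (?) across the panel's hybrid clones. The two-point model is the
standard haploid equal-retention model: a break occurs between two markers
with probability θ, each fragment is retained with probability r, and the
joint call probabilities are

$$P(HH) = (1-\theta)r + \theta r^2,\quad
P(HA) = P(AH) = \theta r(1-r),\quad
P(AA) = (1-\theta)(1-r) + \theta(1-r)^2.$$

`rh_two_point` maximises this likelihood over (θ, r) per pair — r jointly
per pair, not globally — by a coarse 150 × 150 grid start refined with
L-BFGS-B (tolerance well below 1e-6 in the parameters), with the boundary
candidates θ = 0 (admissible only without discordant pairs) and θ = 1
evaluated exactly. The LOD is the log10 ratio against the θ = 1 submodel,
hence never negative; when the interior gains nothing the estimate snaps to
θ = 1 and LOD is exactly 0. Distances are −100·ln(1−θ) centiRays; θ̂ = 1
pairs get distance capped at 500 cR for ordering input but never create
linkage edges. Pairs with an ambiguous call in either marker are dropped.

Grouping is single linkage on the LOD ≥ 10 graph. Ordering minimises the
sum of adjacent distances — the open-path TSP. Up to 8 markers the search is
exhaustive (reversals deduplicated); beyond that, multi-start greedy
nearest-neighbour tours are polished by 2-opt and Or-opt (segments of 1–3)
until no move improves, deterministically given the seed. An order and its
reverse are equivalent; output is canonicalised by the lexicographic
first/last marker. On estimated distances the exhaustive optimum is the
best attainable answer, but it can differ from the generating order by an
end-marker swap when the panel is small — optimality of the solver and
identifiability of the map are different questions.

Error flagging follows the single-flip likelihood-gain reading of the
classic `find_errors` idea: along the fixed order, each hybrid's calls form
a Markov chain with per-interval θ̂ (combined multiplicatively across
skipped ambiguous calls, floored at 1e-6) and the panel-wide retention
estimate; a call is flagged when flipping it alone gains ≥ 3 log10 units.
A combinatorial alternative (`method = "double_break"`: flip removes ≥ 2
obligate breaks) is exposed. The likelihood criterion deliberately flags
genuine isolated double-break fragments when intervals are so tight that a
double break is less likely than a typo — at inter-marker spacing below
about 0.05 Rays the two hypotheses are genuinely indistinguishable, and
flags should be read as "likely" errors.

# The Y-SNP cascade and mutation rates

Hard-filter inequalities are strict exactly as written (`QD < 2.0`,
`MQRankSum < −12.5`, `FS > 60.0`, `ReadPosRankSum < −8.0`, `MQ < 40.0`,
`SOR > 3.0`); a record sitting on a threshold passes, and an absent
annotation never triggers its condition (rank-sum tests are undefined
without heterozygous evidence). Sites with Y calls in female samples mark
ambiguous or misassembled regions and are removed by exact position match
(idempotently). Site filters keep biallelic sites — exactly two observed
alleles among non-missing haploid calls — with MAF ≥ 0.05 (computed on
non-missing calls only) and call rate ≥ 90%, both inclusive. The hard and
site filters touch disjoint record features, so their order is immaterial;
the tests verify this by permuting the stages.

Survivors concatenate into one alignment column per site in (scaffold,
position) order, missing calls as N. Scaffold order and orientation only
permute columns, so per-sample base multisets and pairwise Hamming
distances — all that distance-based downstream methods see — are invariant,
which is what licenses concatenated SNPs as a stand-in for full sequence.

The Y is transmitted through male germlines, whose mutation rate exceeds
the female rate by a factor α. With the autosomal rate the male/female
average, the male-lineage per-generation rate is
$\mu_{\mathrm{auto}} \cdot 2\alpha/(1+\alpha)$; dividing by the generation
time gives the per-year rate (1.3e-8, α = 2, 2 years → 8.67e-9/bp/year),
increasing monotonically in α towards twice the autosomal rate. For a
concatenated alignment of n SNP columns drawn from L monitored bases, each
column absorbs L/n bases' worth of mutational opportunity, so the clock
rate is multiplied by L/n. L is an explicit argument: it is the length of
sequence actually monitored for SNPs, which only the upstream calling
protocol knows.

# What the simulators emulate — and what they do not

`sim_genome` draws i.i.d. scaffolds at a fixed GC content with known
origins, optionally copying one block into a Y scaffold at a given identity.
The block's pristine source is carried as a *placed-X* segment: it belongs
to every simulated individual's genome (reads are drawn from it) but not to
the unplaced query pool — mirroring the real situation, where the X
counterpart of an X-transposed region sits on the assembled X chromosome.
Without this distinction the block's k-mers would count as duplicated
within the query pool and silently vanish from the single-copy set.

`sim_depths` gives each scaffold its copy-number expectation
(depth × copy/2) plus leakage on the homologous block equal to one
attenuated X-copy equivalent, (depth/2) × identity, making the homologous
scaffold's AD ≈ fraction × identity. Noise is a lognormal mean-one factor
with coefficient of variation `noise_cv`, drawn per scaffold from the seed
*independently of sex*. This models mappability/GC bias, which affects
every library aligned to a scaffold alike and is the dominant real source
of per-scaffold depth distortion; simulating both sexes with one seed
reproduces the shared bias (ratios stay exact), while different seeds give
independent factors. What is *not* modelled: sex-specific coverage noise
beyond read sampling, platform error profiles, repeat families beyond the
single homology block, and structural variants. Classifier recovery on
these simulations therefore demonstrates correctness of the statistics, not
robustness to every artefact of real libraries.

`sim_reads` samples uniform single-end reads weighted by copy number with
i.i.d. substitution errors — X-homology leakage arises at read level purely
from sequence identity, with no special-casing. `sim_rh_panel` breaks each
group by a Poisson process (interval breakage probability
1 − exp(−rate × distance)), retains fragments independently with
probability r, then flips calls and masks ambiguous ones missing-at-random;
the ambiguity mechanism of real panels is unknown, so missing-at-random is
an assumption. `sim_vcf` seeds a known, disjoint count of violations per
filter stage so that the survivor count is a bookkeeping identity.

# Problem sizes and reproducibility

Every generator is a pure function of its spec including the seed. The
package's checks run at desk scale, chosen to make each property
statistically decisive: AD recovery on 200 scaffolds per origin at 30× with
10% depth noise; YGS end to end from ~20,000 simulated 100-bp reads at 1%
error over a 15-scaffold genome (one-copy scaffolds at 15×, comfortably
above the ~10× where the min-count-2 dictionary starts losing k-mers); the
two-point estimator against a 10⁻³ grid oracle on 100 multinomial tables of
93 hybrids; a 29-marker, 93-hybrid panel with two linkage groups (0.03 Ray
spacing, 2% call error, 2% ambiguity) and two seeded unlinked markers; the
filter cascade against its construction-time expectation over 1,000 random
VCF specifications; and the N-ladder against a brute-force cumulative scan
on 1,000 random length lists.

# Known limitations

The homology classifier consumes a best-hit table and inherits whatever
biases the upstream aligner had; its identity and coverage defaults are not
calibrated. Multipoint likelihood is approximated by chaining two-point
estimates along the order rather than re-estimated jointly. The simulators'
depth-noise magnitude is a free parameter, not calibrated against
repeat-rich Y scaffolds of any particular platform. Diploid RH models,
LD pruning, variant calling itself, tree and skyline inference are out of
scope: the package prepares their inputs and stops there.
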