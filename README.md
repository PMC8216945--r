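# msytools

Tools for assembling the male-specific region of a Y chromosome (MSY) from
the unplaced scaffolds of a genome assembly, using only short-read data from
males and females, a radiation-hybrid (RH) panel, and homology to a related
species. The package is aimed at groups working on non-model mammals whose
reference assemblies — typically built from a single individual and heavy on
autosomal sequence — leave the Y chromosome as a cloud of small unplaced
scaffolds.

Everything is exercisable on built-in simulators with known ground truth, so
the whole pipeline can be validated end to end without downloading any
sequencing project.

## What it computes

**Sex inference from seed mapping rates.** Male-specific seed regions are
derived from per-position coverage of known-sex samples (`derive_seed_regions`:
maximal runs covered in every male and empty in every female). An unsexed
sample's mapping rate against the seeds then calls its sex: rates above
0.04% are male, 0.00% is female, anything between is ambiguous and excluded
(`call_sex`, thresholds validated by a Welch t-test via
`threshold_separation_test`).

**AD-ratio classification.** For each scaffold,

```
AD = mean_depth_female / (mean_depth_male × norm),
norm = total_reads_female / total_reads_male
```

is ~0 for Y scaffolds (absent from females), ~1 for autosomes and ~2 for X.
Windows: `AD < 0.4` → Y (relaxed, because X-transposed Y regions of ~99%
identity attract female reads), `0.6 < AD < 1.4` → autosome,
`1.6 ≤ AD < 2.4` → X (`ad_ratio`, `classify_ad`).

**YGS k-mer classification.** Canonical 31-mers occurring exactly once
across the query scaffold pool (`single_copy_kmers`) are compared against
dictionaries built from male and female reads (`kmer_dictionary`). A
scaffold is Y-linked when >90% of its single-copy k-mers match male reads
and <10% match female reads (`ygs_profile`, `classify_ygs`).

**Homology voting and consensus.** Tabular similarity hits against a
reference with a known Y are summed per target chromosome; Y must win
strictly and cover ≥50% of the scaffold (`classify_homology`). The three
calls are integrated by intersection (high confidence) and union (input to
scaffolding) in `consensus_calls`; `n_ladder` reports N10..N90/L-counts of
any scaffold set.

**RH mapping.** Two-point maximum likelihood under the haploid
equal-retention model — P(H,H) = (1−θ)r + θr², P(H,A) = θr(1−r),
P(A,A) = (1−θ)(1−r) + θ(1−r)² — gives breakage probability θ̂, retention r̂
and the LOD of linkage against θ = 1 (`rh_two_point`). Markers group by
single linkage at LOD ≥ 10 (`rh_linkage_groups`); each group is ordered by
minimising the sum of adjacent distances, d = −100·ln(1−θ) centiRays — an
open-path travelling-salesman problem solved exactly up to 8 markers and by
multi-start nearest-neighbour with 2-opt/Or-opt polishing beyond
(`rh_order_markers`). `rh_obligate_breaks` counts forced H↔A transitions and
`rh_flag_errors` flags calls whose single flip gains ≥3 log10 units of map
likelihood — the signature of a laboratory typo.

**Y-SNP cascade and rates.** Haploid VCF records pass the hard filter
`QD < 2.0 || MQRankSum < −12.5 || FS > 60.0 || ReadPosRankSum < −8.0 ||
MQ < 40.0 || SOR > 3.0` (strict; absent annotations never trigger), sites
also seen in female samples are excluded, and only biallelic SNPs with
MAF ≥ 0.05 and call rate ≥ 90% survive (`filter_cascade`). Survivors
concatenate into a FASTA alignment for tree/skyline tools (`concat_snps`).
The Y substitution rate is derived from the autosomal rate with male
mutation bias α — per year: `mu_auto · 2α/(1+α) / generation_time` — and
rescaled for concatenated-SNP input by `L / n_snp` monitored bases per
column (`y_rate_per_year`, `rescale_rate_for_concat`).

**Simulators.** `sim_genome`, `sim_depths`, `sim_reads`, `sim_rh_panel` and
`sim_vcf` generate genomes with labelled scaffold origins (including an
X-transposed Y block), sex-dependent depths and reads, RH retention vectors
under Poisson breakage, and VCFs with seeded counts of records violating
each filter — all pure functions of a spec and seed.

## Worked example

```r
library(msytools)
g <- sim_genome(genome_spec(n_auto = 5, n_x = 3, n_y = 3,
                            xy_homology_fraction = 0.5, xy_identity = 0.99,
                            seed = 42))
prof <- depth_profile(
  sim_depths(g, "female", target_depth = 30, noise_cv = 0.1, seed = 1),
  sim_depths(g, "male",   target_depth = 30, noise_cv = 0.1, seed = 1))
classify_ad_profile(prof)
```

```
     scaffold_id length        ad       call
1  scaffold_A_01   2560 1.0000000          A
...
6  scaffold_X_01   3169 2.0000000          X
...
9  scaffold_Y_01   3151 0.4951571 unassigned
10 scaffold_Y_02   3326 0.0000000          Y
11 scaffold_Y_03   2023 0.0000000          Y
```

The two ordinary Y scaffolds sit at AD = 0 and are called Y; autosomes and X
sit at 1 and 2. `scaffold_Y_01` carries a half-length X-transposed block at
99% identity, so female X reads leak onto it and its AD rises to
0.5 × 0.99 ≈ 0.495 — above even the relaxed 0.4 cutoff, which is why the
method is combined with YGS and homology evidence rather than trusted alone.

```r
rh_two_point(rep(c("H","A","H","A"), c(25,5,5,58)),
             rep(c("H","H","A","A"), c(25,5,5,58)))
#> RH two-point: theta = 0.2460, r = 0.3226, LOD = 11.94, 28.2 cR (n = 93)

signif(y_rate_per_year(rate_spec()), 3)        # 1.3e-8, alpha = 2, g = 2 yr
#> [1] 8.67e-09
signif(rescale_rate_for_concat(8.67e-9, 5.69e6, 6914), 3)
#> [1] 7.14e-06
```

A thin command-line wrapper for the common steps lives in
`inst/scripts/msy-cli.R` (subcommands `sim-genome`, `classify-ad`,
`sim-rhpanel`, `rhmap`, `snps-filter`, `rates`).

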