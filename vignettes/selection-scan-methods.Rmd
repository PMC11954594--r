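---
title: "Methods: PBS/iHS selection scans with a coalescent demographic null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBS/iHS selection scans with a coalescent demographic null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The problem and the statistics

`sweepscan` looks for recent positive selection in a *focal* population by
combining two complementary signals, then intersecting their extremes:

1. **Population differentiation.** Per-site FST is estimated with the Weir &
   Cockerham (1984) diploid estimator, `theta = a / (a + b + c)`, where `a`,
   `b` and `c` are the among-population, among-individual and within-individual
   variance components; the within-individual term uses observed
   heterozygosity, so no Hardy–Weinberg assumption enters. Multi-site
   ("weighted") FST is the ratio of sums `sum(a) / sum(a + b + c)`, never a
   mean of per-site ratios. With a focal population A, an ingroup B, and an
   outgroup C, each pairwise FST is converted into a divergence-scaled branch
   length `T = -ln(1 - FST)` and the **population branch statistic** for A is

   `PBS_A = (T_AB + T_AC - T_BC) / 2`,

   the length of the focal branch since the three populations separated.
   Large values mean allele-frequency change specific to A.

2. **Haplotype structure.** Extended haplotype homozygosity (EHH) at distance
   x from a core site is the probability that two random haplotypes carrying
   the same core allele are identical at every marker between the core and x.
   Integrating EHH over physical distance on both sides gives iHH for the
   ancestral- and derived-allele classes, and the **integrated haplotype
   score** is `iHS_raw = ln(iHH_A / iHH_D)` (negative = unusually long
   derived haplotypes). Raw scores are standardized within derived-allele
   frequency bins, after which `|iHS_std|` is approximately standard normal
   under neutrality and two-sided Gaussian p-values apply.

PBS needs a null distribution because demography (drift, bottlenecks) also
produces large values. The package simulates one with a built-in structured
coalescent under a user-specified demographic model and assigns each observed
PBS the add-one empirical p-value `p = (1 + #{null >= obs}) / (M + 1)`.

Candidates are the **intersection of the top fraction `q`** (default 1%) of
both p-value rankings. The threshold is the `ceiling(q n)`-th smallest
p-value with ties included — deterministic and conservative toward inclusion.
Ranking on p-values (rather than raw statistics) was chosen because both
statistics receive genome-wide p-values; ranking on raw values is available
via `rank_on = "raw"` in `selection_scan()`.

# Polarization and input handling

All stages consume a `genotype_matrix`: biallelic variants by samples, allele
pairs in {0, 1, NA}, per-record phase flags, and an ancestral-state code set
by `polarize()` from an ancestral-allele table (case-insensitive match of the
ancestral base to REF or ALT; non-matching sites stay `unknown` or are
dropped, by `mode`). Cohort merging is an inner join on
`(chrom, pos, ref, alt)` with REF/ALT swaps treated as errors rather than
auto-flipped. Site filters follow common practice: per-site missing-genotype
fraction at most `max_missing_frac` (default 0.008 — deliberately strict;
with ~159 samples it tolerates at most one missing genotype, and the default
is exposed so users who read the threshold as 80% can set 0.8), pooled minor
allele frequency strictly above `min_maf` (default 0.05), and optionally
autosomes only. MAF is computed on the pooled samples because filtering
happens on the merged cohort before populations are split. Indels pass
through FST/PBS but are excluded from haplotype statistics, which require
fully phased, fully observed biallelic SNVs.

Coordinates are 1-based inclusive everywhere inside the package; conversion
to 0-based half-open happens exactly once, at pseudo-BED boundaries
(`elements_to_pseudo_bed()`, `read_tracts()`).

## PBS at sites private to the focal population

A derived allele present only in the focal population is the canonical PBS
signal, yet the ingroup/outgroup pair is monomorphic there and the W&C
estimator is 0/0. `pbs_table()` therefore treats a pair that is monomorphic
at a site segregating across the trio as zero differentiation (FST enters the
branch transform as 0), while `site_fst()` itself keeps the `NA` sentinel.
Without this convention the scan would discard exactly the variants it exists
to find. Sites monomorphic across all three populations remain undefined.
Negative per-site FST estimates are clamped to 0 before the log (no negative
branch lengths), and FST is capped at `1 - 1e-12` so fixed differences give
finite branch lengths; weighted FST uses the unclamped components.

# The coalescent null

`demographic_model()` describes populations with piecewise-constant diploid
sizes, backward-in-time divergence events (child merges into parent; exactly
one root), and optional size changes that express bottlenecks. No migration
is modelled. Genealogies follow the standard structured coalescent: within a
population holding k lineages of size N, pairs coalesce at rate
`k(k-1)/2 / (2N)` per generation, with waiting times redrawn at every epoch
boundary.

`simulate_snp_sites()` draws one independent genealogy per site and places a
single mutation on a branch chosen proportionally to branch length, so every
site segregates. One subtlety matters: conditioning on exactly one site per
genealogy yields derived-count probabilities `E[L_i / L_tot]`, which
over-represents singletons (short trees are relatively rich in external
branch). A mutational process instead samples *trees* in proportion to their
total length. The default placement therefore weights genealogies by total
branch length via rejection sampling (adaptive cap at three times the mean
tree length, calibrated on 100 warm-up trees), which reproduces the neutral
site-frequency law `E[xi_i] ∝ 1/i` exactly; `placement = "per_tree"` keeps
the unweighted behaviour. Unlinked sites match the per-site use of the PBS
null; no recombination is simulated within null sites.

The null consumes one simulation (`null_pbs_distribution()`); replicates can
be generated with different seeds and either pooled or used singly, and the
distribution serializes to TSV with a metadata header recording the seed,
sample configuration and a model fingerprint.

# The synthetic data generator

The generator exists so every pipeline stage is testable without any external
data. It has two layers:

* **Unlinked background** variants from the coalescent above, spread over
  several background chromosomes with 1–3 kb spacing (dense enough that EHH
  decays below its threshold before a scaffold end).
* **A linked sweep region** from a forward Wright–Fisher diploid simulation
  (`simulate_forward_panel()`): burn-in from an empty panel for `10 N`
  generations to mutation–drift equilibrium (verified by the diversity and
  spectrum tests), genotype fitnesses `1, 1 + hs, 1 + s`, multinomial
  offspring sampling, Poisson crossovers, and infinite-sites style mutation
  at integer positions. For a sweep, the selected mutation enters on one
  haplotype and runs are restarted from the burned-in state (fresh
  substream) until the derived allele first reaches the target frequency
  while still polymorphic; sampling happens at that first hit, when swept
  haplotypes are longest.

`make_three_pop_dataset()` mirrors the demographic model forward in time: the
ancestor is burned in at its own size, the outgroup splits first (expanding
to the model's reference size), the ingroup and focal populations split
later, the focal population is founded at its (small) size — the founder
bottleneck — and receives the sweep at its split. Because the realized sweep
duration `D` varies, the ingroup and outgroup are evolved `D` and
`t_out - t_in + D` post-split generations so all three populations are
sampled at the same present. Sites fixed within one population are kept
during split phases (a site fixed here may still segregate in a sister
population); a position collision between the selected mutation and a
standing variant is resolved by a deterministic one-base offset. All
randomness flows from one user seed through named substreams, so datasets
are byte-reproducible.

## Default study conditions and why

| parameter | default | rationale |
|---|---|---|
| focal size `N` | 200 diploids | desk-scale founder population; the whole sweep is simulable in seconds |
| `s`, `h` | 0.05, 0.5 | additive selection; heterozygote advantage `s/2` |
| target frequency | 0.8 | partial sweep: the core stays polymorphic so iHS is defined |
| `L`, `mu`, `rec` | 100 kb, 5e-7, 1e-6 | nucleotide diversity `4 N_anc mu ≈ 1e-3`/bp and comparable crossover rate: haplotype identity is marker-limited, so marker density must resolve kilobase-scale EHH decay |
| ancestor / references | 500 / 1000 diploids | a diverse source population and expanded reference panels; keeps reference-branch drift (and spurious fixed differences) small |
| `t_in`, `t_out` | 250, 500 generations | `t_in` matches the typical conditioned sweep duration, so the sweep spans the focal branch |
| samples | 100/66/152 haplotypes | outgroup/ingroup/focal design of a realistic three-cohort study |

What the generator emulates: three diverged populations with a recent
founder bottleneck in the focal one, phased haplotypes, exact ancestral
annotations, private sweeps, and LD in the sweep region. What it does not:
chromosome-scale recombination maps, background selection, mutation-rate
heterogeneity, phasing or polarization errors, and genome-scale marker
counts. Passing tests therefore demonstrate correctness of the statistics
and the machinery on idealized data, not field performance on real cohorts.

# Numerical and analysis choices

* **EHH/iHH.** EHH is computed by partition refinement in C++ and equals the
  all-pairs definition exactly (tested against an enumeration oracle). The
  curve stops at the first value below `ehh_threshold` (default 0.05); iHH
  integrates trapezoidally over physical distance up to, but excluding, that
  point — no interpolation. Inter-marker gaps above `max_gap` (default
  200 kb) stop integration at the previous marker. A core whose EHH never
  falls below the threshold before a chromosome end or gap is flagged
  truncated and excluded from standardization (its integral is not
  comparable), but is still reported. No genetic map is assumed; distance is
  physical bp.
* **iHS binning.** Derived-frequency bins default to width 0.025 in
  `standardize_ihs()` (the genome-scale convention), with `min_bin_count`
  10; bins below the count, or with zero spread, are flagged rather than
  standardized. `selection_scan()` defaults to `bin_width = 0.1` because a
  desk-scale scan has a few thousand scored cores and bin moments need tens
  of members to be stable; use 0.025 for genome-scale data. Standardization
  uses the sample standard deviation (denominator n − 1).
* **Wilcoxon.** The within/between-region FST comparison computes the
  rank-sum p-value from first principles with tie and continuity
  corrections; tests check it against `stats::wilcox.test` and an exact
  enumeration oracle.
* **Empirical p-values.** Add-one rule, vectorized by binary search on the
  sorted null; ties count in the tail (`>=`).
* **Genic classification.** One category per variant by the precedence
  exonic > UTR5/UTR3 > intronic > ncRNA_exonic > ncRNA_intronic >
  upstream/downstream > intergenic. UTRs require a CDS; genes without CDS
  use the ncRNA categories. The upstream/downstream flank is 1000 bp
  (configurable); a variant upstream of one gene and downstream of another
  reports the combined category. Codon consequences use the standard genetic
  code, reverse-complemented on minus-strand genes; indels are frameshift
  when the length change is not a multiple of 3, else nonframeshift.
* **Ancestry proportions.** Tracts below the posterior threshold (default
  0.9) are discarded; each hit × haplotype takes the covering tract's label;
  per-ancestry proportions are computed per hit over assigned haplotypes and
  then summarized as mean ± sd across hits. Averaging per hit (rather than
  per individual) is one defensible convention; it is what the summary
  documents.

# Power limits at desk scale

The test suite's end-to-end recovery property uses a strong sweep
(`s = 0.5`): the conditioned sweep then lasts ~30–45 generations, derived
haplotypes are long against an intact ancestral background, and the causal
variant lands in the top PBS tail with an extreme haplotype score.

A weak sweep at these population sizes behaves differently, and it is worth
being explicit about why. With `N = 200` and `s = 0.05` (allele-level
coefficient 0.025, `2 N s_allele = 10`), the conditioned time to frequency
0.8 is roughly 240 generations — more than the coalescent timescale of the
focal founder population. Over that time the *ancestral* allele class inside
the focal population drifts and partially collapses into clonal families
(its effective size shrinks as the sweep proceeds), so ancestral and derived
haplotype classes end up comparably homozygous and `iHS_raw` at the causal
site hovers near zero, with either sign. No choice of mutation rate,
recombination rate, marker density or ancestor size changes this: it is a
property of weak sweeps in small founder populations, and it is the regime
boundary users should keep in mind when simulating power analyses with this
generator. PBS is unaffected (the conditioned frequency contrast is extreme
regardless of haplotype structure) and recovers the causal variant reliably.

# Problem sizes used by the tests

The suite simulates at sizes chosen to finish in minutes on one core: null
distributions of 2,000–5,000 sites, background panels of a few thousand
unlinked SNPs over 4–8 scaffolds, forward panels of 50–200 diploids and
0.05–1 Mb, 10,000+ neutral cores for the iHS calibration, and 10 replicate
sweep datasets for recovery counting. All seeds are fixed in the tests;
every simulation is reproducible from them.
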