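---
title: "Divergence landscapes and demographic model selection with divergescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence landscapes and demographic model selection with divergescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divergescan)
```

## The scientific problem

When two recently separated lineages — the motivating system is the Atlantic
great scallop *Pecten maximus* and the Mediterranean scallop *P. jacobaeus* —
are genotyped at thousands of RAD loci against a common reference, two
complementary questions arise:

1. **History.** Did the lineages diverge in isolation, with continuous gene
   flow, or through episodes of contact? This is asked of the *joint site
   frequency spectrum* (SFS) by comparing coalescent models.
2. **Landscape.** Which genomic regions resisted gene flow? This is asked of
   windowed summary statistics: relative divergence (F~ST~), absolute
   divergence (d~xy~), within-species diversity (π), and linkage
   disequilibrium (LD).

The interplay matters: under secondary contact, regions carrying barriers to
gene flow keep both high F~ST~ *and* high d~xy~, while regions only affected
by linked selection show high F~ST~ with unremarkable d~xy~. divergescan
implements both halves plus a seeded simulator so the whole chain can be
validated against known truth.

## The demographic models

Five classical two-deme scenarios are compared, all sharing diploid effective
sizes (`N_anc`, `N_pma`, `N_pja`) and a split `T_S` generations ago, and
differing only in when lineage migration is active (backward in time):

| model | migration window | free parameters (k) |
|-------|------------------|---------------------|
| SI    | never            | 4 |
| IM    | `[0, T_S)`       | 6 |
| AM    | `[T_1, T_S)`     | 7 |
| SC    | `[0, T_1)`       | 7 |
| SCS   | `[T_2, T_1)`     | 8 |

Migration parameters follow the coalescent convention: `mmj`, the forward
proportion of migrants from the A ("maximus") into the B ("jacobaeus")
lineage, is applied as the backward probability that a lineage currently in B
traces its ancestry into A, and conversely for `mjm`. The expected SFS for a
parameter set is computed by Monte Carlo: genealogies are simulated for a
projection-sized sample and each branch contributes its length to the entry
given by its descendant counts per deme. This branch-length accumulation is
mutation-rate-free and has much lower variance than dropping mutations.
Empty unmasked cells are floored (default `1e-10`) before normalization so
the composite likelihood stays finite; inside `fit_model()` the floor scales
with the Monte-Carlo size (`0.5 / n_loci`) because a fixed tiny floor makes
the searched surface jump by ten log-units whenever a low-mass cell happens
to come up empty.

The fit maximizes the composite log10-likelihood `sum(obs * log10(p))` over
unmasked entries of the folded spectrum, and models are ranked by
`AIC = 2k - 2 ln(10) logCL10`. The composite-likelihood AIC correction of
Varin & Vidoni requires an effective-degrees-of-freedom estimate that the
data here do not support; the standard form is used and comparisons should
be read as heuristic rankings, as is common practice with SFS composite
likelihoods.

### Identifiability: why a parameter can be anchored

Because the likelihood uses polymorphic-site *proportions* only (monomorphic
corners masked, no mutation-rate parameter), it is exactly invariant under
the rescaling `(N, T) -> (cN, cT)`, `m -> m/c`: rescaling time and sizes
jointly rescales every branch length by `c` and leaves the normalized
spectrum untouched. Model ranking is unaffected, but absolute parameter
values are defined only up to that ray. SNP-only SFS analyses conventionally
anchor the scale with one externally known quantity (typically an effective
size derived from an independent mutation-rate estimate); `fit_model()`
exposes this as the `fixed` argument, and the package's recovery studies
anchor `N_pma`. Fixed parameters do not count towards `k`.

### Search strategy

The likelihood surface is rough (Monte-Carlo noise) and multimodal — a
recurring local mode is "small recent split with migration", which can score
nearly as well as a "deep split with strong secondary contact" truth.
`fit_model()` therefore uses, per model:

* a coarse Nelder–Mead phase from random starts in the transformed box
  (log10 sizes and split time, logit epoch fractions, log10 migration), with
  common random numbers (CRN) per start;
* a selection step scoring all coarse optima and all warm starts on one
  shared surface, of which the best few are polished at larger Monte-Carlo
  size;
* a refinement phase run directly on the shared final-evaluation surface
  (same seed and size for every candidate and every model), from the best
  candidate and from the best warm start.

`fit_all_models()` chains warm starts up the model ladder: SI seeds IM, IM
seeds AM/SC, SC and AM seed SCS (with `T_2` near zero, i.e. the SC limit),
and every migration model also receives "deep split, strong contact" shapes
built from the SI optimum — under gene flow the true split is
systematically older than an isolation-only fit suggests. Warm starts are
kept as zero-iteration candidates, so an extending model can never rank
below the nested model that seeded it by more than evaluation noise.
Because every model's best candidate is scored with the same CRN seed,
likelihood *contrasts* between models are considerably less noisy than the
absolute values.

Default search bounds are wide (`[10, 1e6]` for sizes, `[1, 1e7]`
generations, `[1e-10, 0.5]` for migration). The scaled recovery studies in
the test suite use a correspondingly scaled prior box (`[10, 1e5]` sizes and
times, `[1e-8, 0.5]` migration).

### Parametric bootstrap

`bootstrap_ci()` draws multinomial spectra of the observed size from the
fitted expected proportions, refits (warm-started at the point estimate,
with the same anchoring), and reports 2.5/97.5 empirical percentiles.

## The coalescent simulator

`sample_locus_genealogy()` implements the two-deme structured coalescent
with competing exponentials: pair coalescence at rate `1/(2N)` within a
deme, per-lineage migration at the model's epoch-limited rates, a merge into
the ancestral deme at `T_S`. Two numerical devices matter:

* **Strong-migration limit.** When migration events accumulate far faster
  than coalescences (more than ~10 per lineage since the last coalescence),
  lineage locations are at their stationary distribution and the process is
  exchanged for its panmictic limit with pair rate
  `pi1^2/(2 N1) + pi2^2/(2 N2)`. Without this, optimizers exploring
  migration-dominated corners generate millions of events per genealogy.
* **Lazy accumulation.** For expected-SFS accumulation, branch classes
  change only at coalescences, so elapsed time is flushed once per
  coalescence rather than per event.

## The synthetic-study generator

`simulate_dataset()` emulates a RAD-sequencing study of two demes:
short unlinked loci scattered along chromosomes, infinite-sites mutations
dropped on per-locus genealogies (`theta_per_locus` expected mutations per
average locus; per-locus means are normalized by the dataset's mean total
branch length), diploid individuals formed by pairing lineages, an all-sites
matrix for the d~xy~ path, a reference genome consistent with every REF
allele, gene models (two exons, UTRs, a valid CDS) over a configurable
fraction of loci, a synthetic GO map with a small parent hierarchy, and a
DP/GQ noise model (`DP ~ NegBin(mean 20, size 5)`,
`GQ = min(99, Pois(40))`, plus 5% random missingness) chosen so the
genotype-quality filters have something to remove.

Divergent regions emulate barriers to gene flow: loci inside them are
simulated without migration, with deme sizes scaled by `sweep_ne_scale`
(default 0.3) to mimic the diversity reduction left by sweeps — the
mechanism is not modelled, only its footprint. In `barrier+linked` mode all
loci of a region share a single genealogy, the footprint of a
recombination-suppressed block such as an inversion: this produces jointly
elevated F~ST~ and d~xy~, reduced π, and long-range LD, which is exactly the
signature the landscape scan is meant to recover.

Defaults mirror the motivating study where it states values (two demes of
235 and 27 diploids, 19 chromosomes, 12 + 2 population labels; the preset
`pecten_scs_truth()` carries the published split/contact/stop times). Layout
scale (500 kb chromosomes, 25 × 300 bp loci), `theta_per_locus = 5` and the
noise model are this package's own desk-scale choices. What the generator
does *not* emulate: genotyping as an explicit read process (no allelic
dropout or paralog collapse), intra-locus recombination, linked selection as
a process, or reference bias — so green tests certify estimator and
inference correctness under the stated model, not robustness to those
artefacts.

The scaled truth used throughout the tests is
`N = 500, T_S = 3000, T_1 = 300, T_2 = 10` with strong asymmetric migration
frozen at `mjm = 0.05` (into the A lineage, the dominant direction in the
motivating system) and `mmj = 0.005`; test problem sizes are 2000 loci at
projection `(20, 10)` for demography and a few-hundred-loci genome for the
landscape studies.

## Filtering cascade

`mask_low_confidence_genotypes()` applies strict `GQ > 5` and `DP > 5`
thresholds (a call exactly at the threshold fails); `filter_sites_and_samples()`
drops sites genotyped in under 80% of individuals and then samples with over
80% missingness, in that order, in one pass; `apply_maf_filter()` computes
MAF on the pooled genotyped sample. The SFS is always built *before* MAF
filtering (a provenance flag enforces this), because the demographic signal
lives in the rare variants. `make_dataset_variants()` reproduces the six
alternative filter settings (per-species call rate; MAF at 0.05/0.01/none;
HWE-violating sites removed when violating in all, or at least half, of the
sampled populations — the HWE exact test is the standard conditional
enumeration).

## Windowed statistics

Windows are non-overlapping fixed-width tiles (default 100 kb, at least 5
SNPs), 1-based inclusive. Per window:

* **F~ST~** is Weir & Cockerham's estimator as the ratio of summed variance
  components `sum(a) / sum(a + b + c)`; negative values are kept.
* **π** sums `2x(n−x)/(n(n−1))` over variant sites and divides by the window
  length, so sparse RAD windows give per-bp values of order `1e-5`.
* **d~xy~** is the missing-data-aware estimator: differing between-deme
  allele pairs over compared pairs, summed across *all* sites of the
  all-sites matrix — invariant sites enter the denominator, missing
  genotypes are excluded rather than imputed.

Outlier ("highly divergent") windows are those at or above the type-7
empirical 95th percentile of F~ST~ over usable windows; under ties every
tied window is flagged. Rank associations (F~ST~–π, F~ST~–d~xy~) use the
Spearman test with average ranks and the large-sample t approximation.

## Diagnostic SNPs and LD

Fully diagnostic SNPs are fixed for REF in species A and ALT in species B
(mirror orientation reportable), judged among genotyped calls with a
per-species call-rate guard (default 0.8; strict mode refuses any
missingness). Flanking sequence (default 100 bp each side) is extracted with
truncation reported and the centre base checked against REF.

r² is the squared Pearson correlation of diploid dosages over
pairwise-complete individuals; pairs with under 3 shared individuals or a
monomorphic member are NA. LD decay is fitted by nonlinear least squares of
distance-binned mean r² (100 bp bins) against the Hill–Weir
drift–recombination expectation with `C = rho * distance`; the background
level is the mean r² beyond the top distance decile and the decay distance
is where the fitted curve first comes within `epsilon = 0.005` of it. Note
the expectation's large-`C` limit is the sampling floor `1/n`, so the
background estimate naturally sits near `1/n` plus true long-range LD.
Per-chromosome LD matrices carry all-NA rows for sites monomorphic within a
species (the "white line" convention of LD heatmaps).

## Variant effects and GO enrichment

`classify_variants()` assigns each SNP its most severe applicable category
(loss-of-function > missense > synonymous > splice region > UTR > intron >
up/downstream > intergenic), with codon substitution under the standard
genetic code, strand-aware; loss of function covers stop gained, start lost
and splice donor/acceptor (intronic 1–2 bp); the splice region is intronic
3–8 bp; up/downstream extends 5 kb from the gene span (the SnpEff defaults).
Genes whose CDS length is not a multiple of 3 are flagged, their coding
effects skipped and such exonic sites fall back to the intron category.
`assign_gene()` uses containment, then distance to the gene span, ties going
to the lower start coordinate.

`go_enrichment()` is the one-sided Fisher exact (hypergeometric upper tail)
test per term, with no multiple-testing correction. The `elim` option
processes terms most-specific-first and removes the genes of significant
children from ancestors before testing them; the full "weight01"
decorrelation is intentionally not reproduced. As in the motivating
analysis, enrichment can be run both for all highly divergent SNPs
(containing-or-nearest gene) and for within-gene SNPs only.

## Numerical choices and limitations

* Quantiles are type 7 (linear interpolation) everywhere a percentile is
  taken, except bootstrap CIs which use type 1 so that two replicates give
  exactly min/max.
* Determinism: all randomness, including inside the C++ coalescent, draws
  from R's RNG; a fixed seed reproduces simulate/fit/scan outputs
  byte-for-byte.
* The composite likelihood treats sites as independent although sites within
  a locus share a genealogy; with ~5 SNPs per locus this overstates
  information roughly five-fold, so reported likelihood differences are
  optimistic and AIC gaps should be read qualitatively.
* At desk scale (a few thousand loci, projection (20, 10)), even the
  anchored likelihood is nearly flat over wide excursions of `T_S`,
  `N_anc` and the migration rates, so point estimates are unstable even
  when model *selection* behaves sensibly, and bootstrap intervals from
  warm-started refits inherit the optimizer's inertia. The package's own
  recovery studies (in the test suite) quantify this under the scaled
  secondary-contact truth.
* `run_pipeline()` executes the whole chain from a config list or YAML file
  and writes per-stage TSV/JSON outputs plus a seeded, versioned
  `report.json`; rendering of Manhattan plots and LD heatmaps is left to the
  `autoplot()` methods, while the pipeline exports matrices and tables only.

## A small worked example

```{r example, eval = FALSE}
set.seed(1) # rad_layout scatters loci using the current RNG state
lay <- rad_layout(n_chrom = 4, chrom_length = 3e5, loci_per_chrom = 25,
                  divergent_chroms = 1L)
cfg <- sim_config(lay, model_spec("SCS"),
                  demographic_params(500, 500, 500, 3000, 300, 10,
                                     mmj = 0.005, mjm = 0.05),
                  samples_per_deme = c(20, 10), n_pops = c(4, 2), seed = 1)
ds <- simulate_dataset(cfg)

masked <- mask_low_confidence_genotypes(ds$gm_all)
snps <- gm_subset(masked, sites = which(!is.na(masked$sites$alt)))
base <- filter_sites_and_samples(snps)
main <- apply_maf_filter(base, 0.05)

obs <- build_joint_folded_sfs(base)
fits <- fit_all_models(obs, models = c("SI", "SC", "SCS"),
                       search = search_config(n_restarts = 2, n_loci = 500,
                                              final_n_loci = 2e4,
                                              maxit = 100))
compare_models(fits)

wins <- outlier_windows(scan_windows(main, masked, window_size = 5e4))
autoplot(wins)
find_diagnostic_snps(main)
```
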