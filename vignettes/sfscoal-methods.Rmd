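---
title: "Methods: folded joint spectra and coalescent demographic inference for GBS SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: folded joint spectra and coalescent demographic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sfscoal` implements a complete analysis path for reduced-representation
(genotyping-by-sequencing, GBS) SNP data in a structured plant species:
dataset construction (locus whitelisting and missing-data filters),
per-locality diversity statistics and F~ST~, folded pairwise joint
site-frequency spectra (SFS), and simulation-based composite-likelihood
fitting of four-population divergence/migration histories with AIC model
selection and parametric-bootstrap confidence intervals.  The four
populations follow the Intermountain-West bluebunch wheatgrass
(*Pseudoroegneria spicata*) system: Wasatch (WAS), Eastern Great Basin
(EGB), Palouse/Wallowa (P/W) and Western Great Basin (WGB).

# Dataset construction

**Locus whitelist.** GBS assemblies collapse paralogous loci into single
stacks, which show up as implausibly variable loci.  For each locus we
compute Watterson's estimator θ~W~ = S / a~n~, with S the number of
segregating sites at the locus and a~n~ = Σ~k=1~^n−1^ 1/k.  Because
missingness varies site by site, the haplotype number n is taken as the
median count of non-missing haplotypes across the locus's sites (rounded to
the nearest integer): a per-site n would let one badly covered site distort
the locus.  Loci above the 0.95 quantile of θ~W~ (linear-interpolation
quantile, R type 7; the cutoff itself is retained) are excluded.  Both the
estimator form and the inclusive cutoff are choices; the quantile level and
both missingness thresholds are arguments.

**Missingness.** SNPs with more than 70% missing genotypes are dropped
first, then individuals missing more than 90% of the surviving SNPs.  The
order matters (an individual's missing fraction is computed on the filtered
site set) and mirrors how GBS datasets are usually cleaned: bad sites are a
property of the assembly, bad individuals of the library.

**Outlier individuals.** PCA-based outlier removal is inherently iterative
and operator-driven, so `pca_outlier_report()` only flags individuals more
than k median-absolute-deviations (default 6) from the PC1–PC2 centroid; it
never deletes.

**One SNP per locus.** The composite likelihood treats SNPs as independent,
so `one_snp_per_locus()` keeps one uniformly chosen SNP per locus under a
caller-supplied seed.

# Diversity statistics and F_ST

Per locality we report the mean expected heterozygosity H~e~ = 1 − Σp²,
the unbiased per-site nucleotide diversity π = n/(n−1)·(1 − Σp̂²)
averaged over sites with at least two called haplotypes, and the
inbreeding coefficient F~IS~ = 1 − ΣH~obs~/ΣH~exp~ over sites with
H~exp~ > 0 (ratio of sums; the mean-of-ratios alternative explodes at
nearly monomorphic sites).  Averages run over the variant sites present in
the table — a per-site SNP matrix has no invariant-site denominator, so
absolute values are comparable only within a dataset.  `subsampled_stats()`
redraws a fixed number of individuals per locality (default 4 × 20
replicates) to make diversity comparable across unevenly sampled localities.

Pairwise F~ST~ is the two-level Weir–Cockerham variance-components
estimator on allele copies ("corrected AMOVA" F~ST~): per site the
among-population component a = (MSB − MSW)/n~c~ and total a + MSW, combined
across sites as Σa / Σ(a + total) — the multi-locus ratio of sums, not the
mean of ratios.  Negative estimates are reported untruncated; truncation
would bias averages of weakly differentiated pairs.

PCA imputes missing dosages with the per-site mean, centres and scales
columns to unit variance, and drops monomorphic columns; scores come from
`stats::prcomp`.

# Folded joint spectra

For a population pair with target sizes (n~A~, n~B~) haplotypes, every SNP
called in at least the per-population minimum number of individuals
(defaults 13/13/24/22 for WAS/EGB/P-W/WGB) is projected down to the target
sizes by hypergeometric expectation: allele count k of n observed
haplotypes contributes C(k,m)·C(n−k, n~to~−m)/C(n, n~to~) at count m.
Averaging over subsamples instead of drawing one removes missing data
deterministically.  Projected mass is folded to minor-allele
configurations: (i, j) with i + j > (n~A~+n~B~)/2 maps to its complement;
at exactly half, the lexicographically smaller representative is kept —
an arbitrary but involution-safe tie rule.  The monomorphic (0,0) cell
(which also receives the fixed (n~A~, n~B~) mass under folding) is stored
but masked out of all likelihoods; counts stay fractional internally and
are only rounded for display.

All six pairwise spectra are built and, by default, summed into one
composite likelihood; restricting to a subset is an argument
(`observed` is simply a named list of spectra).

# The coalescent engine

The simulator is an exact continuous-time structured coalescent over a
piecewise-constant demography: within-deme pairwise coalescence at rate
1/(2N), per-lineage backward migration at the model's rates, and merge
events that relocate lineages and switch sizes.  Three four-population
histories are built in:

* **Model 1 (tree):** P/W+WGB merge at T₁ (ancestor N₁), WAS+EGB at T₂
  (N₂), root at T₃ (N~ANC~).  T₁ and T₂ sit on different branches, so only
  T₁ < T₃ and T₂ < T₃ are enforced.
* **Model 2 (stepping-stone, WGB outermost):** WAS+EGB at T₁, +P/W at T₂,
  +WGB at T₃; T₁ < T₂ < T₃.
* **Model 3 (stepping-stone, WAS outermost):** P/W+WGB at T₁, +EGB at T₂,
  +WAS at T₃; T₁ < T₂ < T₃.

Migration runs only between geographically adjacent extant pairs
(WAS–EGB, EGB–P/W, P/W–WGB) and stops when either partner has merged;
ancestral demes exchange no migrants.  Rates are specified on the 2Nm
scale.  The labels never spell out their direction, so the package fixes a
convention and documents it: the first subscript names the deme whose
lineages move backward in time (equivalently the forward-time recipient of
migrants), and the raw rate is m = 2Nm / (2N) with N that deme's present
size.  Both conventions (direction and which N scales m) are localized in
`scaled_to_raw_migration()` / `demog_epochs()` if a user needs the
alternative reading.  The source material asserts directional symmetry in
one place and reports asymmetric pairs in another; the implementation is
asymmetric, which nests the symmetric case.

The fixed ancestral size comes from `ancestral_ne()`:
N~ANC~ = θ~π~ / 2 / (μ·g), with μ = 7×10⁻⁹ per site per generation (the
*Arabidopsis thaliana* genome-wide SNP rate) and g = 1 year (time to first
reproduction for the perennial bunchgrass); the study's value is
N~ANC~ = 60,000.

**SNP sampling.** A random SNP is more likely to come from a locus whose
genealogy has more total branch length.  Data-generating modes therefore
select each SNP's genealogy by rejection with probability proportional to
total length (adaptive bound) and then place one mutation uniformly on
branches.  Skipping the length weighting would produce configuration
probabilities E[L~i~/L~tot~] instead of the correct E[L~i~]/E[L~tot~] and
visibly distorts the folded spectrum (the n = 4 folded neutral SFS is
(8/11, 3/11); uniform-genealogy sampling misses it by several standard
errors).  A finite-locus sequence mode (Poisson mutations at μ·L per
generation) exists for diversity checks.

**Expected spectra for likelihoods.** `estimate_expected_sfs()` does not
sample mutations at all: every simulated genealogy contributes each
branch's length to its configuration cell (the exact expectation over
mutation placements given the genealogy), and the per-pair spectrum is the
normalised accumulated length.  At equal simulation counts this
Rao-Blackwellised estimator has far lower variance than mutation sampling;
"n_sims" counts genealogies.  Cells with no simulated mass are floored at
p~min~ = 0.1/n_sims and the spectrum renormalised, so unseen configurations
never contribute −∞.

**GBS emulation.** `simulate_genotypes_with_missingness()` groups SNPs
into loci (one shared genealogy per locus), pairs haplotypes into diploids,
masks genotypes independently at a fixed rate, and assigns localities by
splitting each population into consecutive groups.  This reproduces the
structural features the pipeline consumes — locus IDs, diploid dosages,
high missingness, locality nesting — but not GBS error processes: allele
dropout correlated with divergence, depth-dependent genotyping error,
paralog collapse, or within-locus recombination.  Passing tests on this
generator validate the statistical machinery, not robustness to those
artefacts.

# Composite-likelihood fitting

The composite log-likelihood is Σ m~e~·ln p̂~e~ over unmasked cells of all
included pairs — per-SNP multinomial probabilities treated as independent.
It is valid for point estimation and model ranking; its curvature
understates uncertainty, hence the parametric bootstrap.

`ecm_fit()` performs expectation-conditional-maximisation: each cycle
sweeps the 15 free parameters one at a time.  Three numerical choices
matter:

1. **Conditional searches are grid-then-golden.**  A conditional slice of
   the surface is multimodal whenever other parameters are off (for
   example, divergence time given a wrong migration rate), so each 1-D
   maximisation first scans `n_grid` log-spaced points and then refines the
   winning bracket by golden section.  A pure golden-section search
   assumes unimodality and reliably walks into the wrong basin.
2. **Common random numbers.**  All evaluations within a cycle share one
   simulation seed, making the sweep a true ascent despite Monte-Carlo
   noise; `crn_fixed = TRUE` freezes the seed across cycles, turning the
   Monte-Carlo surface into a deterministic function that can be optimised
   aggressively.  The surface's noise scale matters: at 10³ genealogies
   per evaluation, seed-to-seed lnCL differences of tens of log-units move
   the apparent optimum a long way along flat ridges, so final comparisons
   and refinements should use more simulations than the search.
3. **Joint polish.**  Coordinate ascent stalls at coordinate-wise optima
   of curved ridges (divergence time trading against migration and size).
   After cycling, each run is polished by a bounded Nelder–Mead simplex
   over the free parameters on the same common-random-numbers surface,
   optionally restarted (a fresh full-size simplex at the incumbent keeps
   tracking the ridge after the simplex collapses).
4. **Conditional pair blocks.**  With `block_grid > 0` each cycle ends
   with 2-D log-grid conditional maximisations over known-confounded
   pairs: the two directions of each migration rate, and each merge time
   with the size of the ancestral epoch it opens (a short extreme
   bottleneck can mimic deeper divergence, a basin that one-parameter
   moves never leave).

`multi_run_fit()` launches independent runs from log-uniform starting
points inside the search ranges (N ∈ [10², 10⁶], T ∈ [10², 10⁵],
2Nm ∈ [10⁻³, 10²]), re-evaluates every run's end point under one common
higher-precision seed (`final_n_sims`) so runs are compared on the same
draw, and optionally refines the winner once more (one conditional sweep
plus simplex) on that sharper surface.  Merge-time order is maintained by
clipping each time's conditional search range to its neighbours.

The study-scale defaults are the published settings — 100 runs × 40 ECM
cycles × 200,000 simulations per likelihood estimation, 100 bootstrap
replicates — and run for a long time by design.  The test-suite configuration is a reduced-scale version of the same
calls (8 diploids per population, 2,000 SNPs, 3 runs × 5 cycles, 10³
genealogies per evaluation with a 1.5×10⁴-genealogy final stage), and the
acceptance script fits 20,000-SNP spectra with 5 runs × 5 cycles; sizes
are chosen so that everything runs on a laptop-class single core.  At
that scale the data itself limits what is recoverable: the composite
likelihood is nearly flat in the weaker migration direction of the
P/W–WGB pair over more than a decade of 2Nm, so the corresponding
estimate is determined by sampling noise rather than signal, and
between-model AIC gaps shrink to a few tens of units.  Conclusions about
individual migration rates or model ranking should rest on the full-scale
settings.

`aic_select()` ranks fits by AIC = 2k − 2·lnCL (k = 15 for the built-in
models) and reports Δ AIC and relative likelihoods exp(−Δ/2); it refuses
to rank fits of different observed data.  `parametric_bootstrap()`
re-simulates datasets at the fitted parameters with the observed SNP
count, refits each (default 10 runs × 20 cycles — the refit effort is a
documented argument, not hard-wired), and returns 2.5/97.5 percentile
intervals (linear-interpolation quantiles).  Failed replicates are
recorded; a warning fires if more than 10% fail.

# Degenerate inputs and edge rules

Monomorphic-only localities report π = 0 and undefined F~IS~; sites with
fewer than two called haplotypes are excluded from π; an observed SFS with
no polymorphic mass is a fatal error before any fitting starts; folding at
the exact half-count boundary uses the lexicographic tie rule everywhere
(builder, simulator, likelihood masks), so folded objects are closed under
re-folding.  The simulator caps Gillespie events per genealogy (2×10⁵) to
fail fast in pathological corners of the search box (tiny demes with
extreme migration); such evaluations score −∞ rather than hanging.

# Limitations

Free recombination between SNPs and complete linkage within a locus; no
selection; piecewise-constant sizes only (no growth within epochs);
migration constant while both partners exist; biallelic diploid sites
only.  The pipeline's defaults reproduce the study's stated thresholds and
settings, but absolute diversity values depend on the variant-sites-only
averaging convention documented above.
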