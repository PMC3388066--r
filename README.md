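# prdm9znf

Typing, diversity testing and selection analysis for the tandem zinc-finger
(ZnF) array of **PRDM9**, the gene that positions meiotic recombination
hotspots in most mammals.

PRDM9's DNA-binding domain is a minisatellite-like array of 7–17 C2H2 zinc
fingers of 84 bp each. The residues at helix positions −1, 2, 3 and 6 of
each finger determine its DNA-binding specificity; position 2 is a fixed
serine in apes. The array is hypervariable in chimpanzees and bonobos, and
the contact residues carry signatures of strong positive selection. This
package provides the full analysis chain used in studies of that system:

1. **Repeat decomposition** (`split_into_repeats()`, `parse_znf_allele()`):
   cut phased array sequences into 84-nt repeat units (the leading repeat is
   truncated and lacks the first zinc-coordinating cysteine), translate
   them, validate the C2H2 scaffold (`C-x2-C-x12-H-x3..5-H`) and extract the
   DNA-contact residues.
2. **Allele cataloguing** (`collapse_to_nt_alleles()`,
   `collapse_to_aa_alleles()`, `assign_repeat_letters()`,
   `cross_group_sharing()`, `find_polymorphic_sites()`): collapse sequences
   into unique nucleotide and amino-acid alleles, encode alleles as
   repeat-letter strings (synonymous nucleotide variants of a letter are
   starred, e.g. `A` vs `A*`), and report cross-population sharing and
   polymorphic alignment columns.
3. **Diversity permutation tests** (`permutation_test()`): for two groups,
   the statistic is the number of unique alleles in the smaller group; for
   more than two groups it is the sum of squared deviations of per-group
   (unique alleles / sequences) from their mean. The one-tailed p-value is
   the proportion of label permutations with a statistic at least as large
   as observed. `exhaustive_permutation_oracle()` gives exact p-values on
   small spectra by complete enumeration.
4. **Dot plots** (`self_dotplot()`, `two_block_score()`): windowed-mismatch
   self-comparison (default window 83 nt, mismatch limit 5) plus a score for
   the "two-block" within-array similarity structure seen in the human A
   allele.
5. **Selection analysis** (`fit_site_model()`, `likelihood_ratio_test()`,
   `empirical_bayes_site_classes()`, `sitewise_selection_test()`): GY94-type
   codon models with site-class mixtures M0/M1a/M2a/M3/M7/M8 fitted by
   maximum likelihood (Felsenstein pruning; F1×4/F3×4/F61 codon frequencies;
   Muse–Gaut or Goldman–Whelan frequency incorporation), nested LRTs
   (M0 vs M3 df 4, M1a vs M2a df 2, M7 vs M8 df 2), NEB/BEB posterior site
   classification (ω, the dN/dS ratio, > 1 indicates positive selection),
   and a sitewise per-site ω likelihood-ratio test with multiple-testing
   correction. `neighbor_joining_tree()` builds a fallback topology.
6. **Synthetic data** (`sim_config()`, `simulate_repeat_library()`,
   `simulate_znf_population()`, `simulate_grouped_spectrum()`,
   `make_two_block_array()`, `simulate_codon_alignment()`): generators with
   recorded ground truth for every input the pipeline consumes.

`run_pipeline()` chains the stages and writes TSV/FASTA/JSON outputs plus a
reproducible run log; `inst/cli/znf.R` exposes the same stages on the
command line.

## Worked example

The package ships the grouped allele spectrum of 81 *Pan* PRDM9 sequences
(10 eastern-chimpanzee, 7 central, 52 western, 12 bonobo sequences;
`inst/extdata/pan_prdm9_spectrum.tsv`):

```r
library(prdm9znf)
spec <- pan_prdm9_spectrum()

n_unique_alleles(spec, c("eastern", "central", "western"))  # 24
n_unique_alleles(spec)                                      # 27

dispersion_statistic_multi_group(spec)
#> [1] 0.07019646
permutation_test(spec, "multi_group", 10000, seed = 1)
#> Permutation test (multi_group): observed = 0.0702, p = 0.901 (10000 permutations, seed 1)

two <- pool_groups(spec, c("eastern", "central", "western"), "chimpanzee")
unique_count_statistic_two_group(two)                       # 3
permutation_test(two, "two_group", 10000, seed = 1)
#> Permutation test (two_group): observed = 3, p = 1 (10000 permutations, seed 1)
```

The dispersion statistic 0.070 with p ≈ 0.90 says the four (sub)species do
not differ detectably in allelic richness once sample sizes are accounted
for; the two-group statistic 3 with p ≈ 1 says the 12-sequence bonobo
sample is about as diverse as a random 12-sequence subset of the pooled
spectrum. A selection analysis on simulated data:

```r
cfg <- sim_config(seed = 1, n_taxa = 16, n_sites = 300, kappa = 2,
                  props = c(0.5, 0.375, 0.125), omegas = c(0.3, 1, 8))
sim <- simulate_codon_alignment(cfg)
fit <- fit_site_model(sim$aln, sim$tree, "M2a")
fit
#> <site_model_fit M2a> lnL = -4354.7944, kappa = 1.659, scale = 1.060
#>   classes:
#>     p0 = 0.4472, omega = 0.1877
#>     p1 = 0.4096, omega = 1.0000
#>     p2 = 0.1432, omega = 8.5928
```

The fitted selection class (14% of sites at ω ≈ 8.6) recovers the planted
mixture (12.5% at ω = 8) to within sampling error of one 300-site
alignment.

## Layout

- `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  tests; `vignettes/prdm9znf-methods.Rmd` — models, assumptions, numerical
  choices and limitations; `inst/cli/znf.R` — command-line entry point.
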