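---
title: "Models and methods in prdm9znf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in prdm9znf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions, numerical choices and
limitations behind `prdm9znf`. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The biological object

PRDM9 directs meiotic recombination hotspots through a C-terminal array of
C2H2 zinc fingers. Each full finger is an 84-nt / 28-aa repeat; arrays of
7–17 repeats are typical in *Pan*. The first repeat of the sequenced array
is truncated and lacks the first zinc-coordinating cysteine; it is parsed,
flagged and excluded from "full repeat" counts and from codon alignments.
The residues at helix positions −1, 2, 3 and 6 of each finger contact DNA;
position 2 is a fixed serine, so diversity and selection analyses focus on
−1, 3 and 6.

## Repeat decomposition and coordinates

* The repeat unit is fixed at 84 nt (28 codons) by default and is
  configurable. A published 1422-bp/17-repeat amplicon figure includes
  flanking sequence and was deliberately **not** used to derive the unit
  length (1422/17 ≠ 84).
* All offsets are 0-based half-open internally; "position −1/2/3/6" labels
  are presentation only.
* The C2H2 scaffold is located with the configurable pattern
  `C.{2,4}C.{12}H.{3,5}H` (capture groups on the C/H residues); the
  truncated leading repeat uses the variant without the first cysteine.
  Greedy matching means the second histidine is the rightmost one 3–5
  residues after the first; for natural PRDM9 repeats the spacing is fixed
  and unambiguous.
* Contact offsets are anchored on the first zinc-coordinating histidine
  *h* (helix +7 convention): −1 → *h*−7, 2 → *h*−5, 3 → *h*−4, 6 → *h*−1.
  The anchoring rule is configurable because the repeat-break convention
  marks these positions graphically rather than numerically; users aligning
  against a reference repeat with a different break can override the
  offsets.
* Sequences containing IUPAC ambiguity codes are reported and rejected
  rather than expanded: the data model assumes clone-resolved, phased
  alleles, and an ambiguous base means the record is not a single allele.

## Allele cataloguing

Allele identity is exact full-length string equality; length variants are
distinct alleles and no alignment-based clustering is performed, matching
how array alleles are catalogued in practice. Nucleotide alleles are named
`p1..pk` by descending count then lexicographic sequence (deterministic
run-to-run); user label maps are accepted for parity with published names.
Amino-acid alleles merge nucleotide alleles with identical translations.
Repeat letters are assigned in first-encounter order over the input allele
order; synonymous nucleotide variants of a letter get `*` suffixes (`A`,
`A*`, `A**`, ...).

## Permutation tests of allelic richness

The permuted unit is the individual sequence's allele label (not the
individual animal): labels are randomly reassigned to groups of the
observed sizes, which matches per-sequence spectra in which diploid
individuals contribute one or two phased sequences.

* Two groups: statistic = number of distinct labels in the smaller group
  (fewer sequences; ties go to the first-listed group).
* More than two groups: statistic = Σ&#8342; (u&#8342;/n&#8342; − mean)²,
  the dispersion of per-group unique-allele fractions.
* p = (# permutations with statistic ≥ observed) / (# permutations). The
  observed statistic is **not** added to numerator or denominator — the
  "+1" convention would make p = 0 unattainable, and p = 0 is a reported
  outcome for strongly significant comparisons of this kind.
* p-values are kept at full precision; rounding is presentation-level.
* `exhaustive_permutation_oracle()` enumerates all assignments (uniform
  over label permutations) and is the test oracle for small spectra.

The bundled spectrum (`pan_prdm9_spectrum()`) transcribes a published
81-sequence *Pan* table; its label scheme encodes the one cross-subspecies
nucleotide identity and the two synonymous-only amino-acid collapses, so
spectrum-level counting reproduces the published 24/27 unique-allele
totals without access to the underlying sequences.

## Dot plots and the two-block score

`self_dotplot()` marks window pairs (default 83 nt, mismatch limit 5)
whose Hamming distance is within the limit, on the given strand only.
Windows are start-anchored and computed only where the full window fits;
"centered" placement relabels coordinates without changing the matrix (the
web tool historically used for such plots may center windows — the matrix
content is identical either way). Note that `mismatch_limit = window − 1`
saturates the matrix only when no window pair differs at every position;
for arbitrary sequences two windows *can* differ everywhere, so the
saturation property is guaranteed only on low-complexity inputs (the test
suite checks the general case against a brute-force oracle instead).

`two_block_score()` splits the array at the midpoint (odd middle repeat to
the first half) and returns (mean within-half amino-acid repeat identity)
− (mean between-half identity). Identical repeats give 0; a planted
two-family array gives exactly the planted identity gap; the score is
invariant to reordering repeats within halves.

## Codon site models

The selection module implements GY94-style codon substitution: 61 sense
codons (universal code; stop codons excluded from the state space), one
nonsynonymous/synonymous ratio ω per site class, transition/transversion
ratio κ, and a codon-frequency term selected by configuration:

* **GY**: rate ∝ π of the target codon (Goldman–Yang).
* **MuseGaut**: rate ∝ frequency of the target nucleotide at the changed
  position. The stationary distribution implied by these rates is the
  product measure of the position-specific nucleotide frequencies, and the
  module uses exactly that at the root, so the model stays reversible even
  if an F61 frequency vector is supplied.
* **GoldmanWhelan**: rate ∝ √(π_j/π_i).

Codon frequencies come from the alignment as F1×4, F3×4 or F61 (F60 is an
alias). A 0.5 pseudocount per nucleotide (F1×4/F3×4) or per sense codon
(F61) keeps all frequencies positive — the reversible eigendecomposition
machinery requires π > 0 and zero-frequency codons would otherwise break
small alignments. The generator is normalized so the *mixture-average*
rate is 1, preserving relative rates between site classes; branch lengths
are expected substitutions per codon averaged over classes. Simulation
(`simulate_codon_alignment()`) uses the same machinery, so recovery tests
are well-posed.

Site-class mixtures: M0 (one ω); M1a (ω₀ < 1, ω₁ = 1); M2a (adds ω₂ ≥ 1);
M3 (three free discrete classes, reported sorted by ω); M7 (beta(p, q)
discretized into 10 equal-probability categories at midpoint quantiles —
standard practice; the category count is configurable); M8 (beta plus a
selection class).

### Optimization

Likelihoods use Felsenstein pruning with pattern compression and
per-node rescaling. Parameters are optimized with `nlminb` on transformed
scales (log κ and branch scale, logistic ω in (0,1), 1 + e^u for selection
ω, softmax for proportions, log beta shapes) with bounds ω ∈ [10⁻⁴, 50],
κ ∈ [0.1, 50], beta shapes ∈ [0.005, 99]; 3 jittered restarts by default;
non-convergence is flagged on the returned fit, never silent. Standard
errors come from the numerical observed information on the transformed
scale.

**Branch lengths.** The default `branch_mode = "scale"` takes the topology
and relative branch lengths from the user tree or the NJ fallback
(p-distances, negative branches clamped to 0) and estimates one global
scale factor jointly with the model parameters. Full per-branch joint
optimization would add 2n−3 parameters per fit; for the repeat alignments
this package targets (tens of taxa, hundreds of codons) the scale mode
recovers simulated parameters well (the acceptance suite demonstrates
this) at a fraction of the cost. `"fixed"` keeps the input lengths
untouched for users supplying branch lengths already estimated under a
codon model.

### Site classification and the sitewise test

NEB (default) plugs the ML estimates into Bayes' rule per site. BEB
(M2a only) integrates over a uniform 10-point grid on the (p₀, p₁)
simplex, ω₀ ∈ (0,1) and ω₂ ∈ (1,11), with κ, branch lengths and
frequencies fixed at their MLEs; for M8 the BEB grids are not implemented
and the function falls back to NEB with an explicit note in the result.
NEB is the default because the mixture parameters are well determined in
the regimes the package targets, and BEB's extra integration mainly
matters for small, weakly informative alignments.

The sitewise test estimates κ and the branch scale once under M0, then
maximizes each site's ω on a dense log-spaced grid (ω = 1 always
included) and performs a one-tailed LRT against ω = 1 restricted to
positive selection: p = ½·P(χ²₁ ≥ LRT) when the site's ω̂ > 1, else 1.
Grid maximization slightly underestimates the per-site maximum, making
the test conservative — the desired direction for a positive-selection
screen. Invariant columns are flagged and reported non-significant with
ω̂ = NA. Multiple testing uses Holm–Bonferroni by default (the procedure
is configurable; published analyses of this system report "significant
after correction" without naming one).

## Synthetic data: what it emulates and what it does not

The generators state a fixed world; their defaults are not tuned to tests:

* Repeat library: a realistic base C2H2 repeat (84 nt, scaffold C/H at
  offsets 2/5/18/22, serine at helix position 2) with 6 variable aa
  columns, half at contact offsets — mirroring the observed pattern where
  about half of polymorphic repeat columns fall on helix −1/3/6. A
  contact-rate multiplier can replace the exact-fraction planting.
* Populations: arrays of 7–17 repeats; per group one common allele
  (frequency 0.5) plus an even tail, the shape seen in published spectra;
  diploid individuals with configurable second-allele dropout (emulating
  incomplete allele recovery in cloning-based sequencing); optional planted
  cross-group sharing; exact per-group spectra can be realized on demand.
* Codon alignments: site classes drawn from the mixture, codons evolved
  along a random (or supplied) tree; defaults 16 taxa, 300 codon sites,
  branch lengths U(0.02, 0.12) substitutions/codon, uniform root codon
  frequencies. The M2a recovery world (p₂ = 0.125, ω₂ = 8, κ = 2) echoes
  the published estimate that roughly 12.5% of repeat sites evolve at
  ω ≈ 8; unstated parameters were fixed once at p₀ = 0.5, ω₀ = 0.3.

The generators do **not** emulate concerted evolution or unequal crossover
within arrays, PCR-recombination artefacts beyond simple allele dropout,
or paralog contamination. A green closure test therefore establishes that
the analysis chain recovers what the stated generative model planted — not
that the model captures every feature of real PRDM9 data.

## Numerical choices and degenerate inputs

* Transition probabilities via symmetric eigendecomposition of the
  reversible generator; negative rounding residues clamped and rows
  renormalized. Pruning partials rescaled per internal node below 1e−120.
* Monte-Carlo permutation tests compare permuted statistics to the
  observed value with a 1e−12 slack to absorb float noise in the
  dispersion statistic.
* Ties: "smaller group" ties go to the first-listed group; NJ tie-breaks
  follow taxon order; grid argmax ties take the smallest ω.
* Degenerate inputs: zero-length branches give identity transition
  matrices; identical sequences give a zero-length NJ tree; uninformative
  data make NEB posteriors collapse to the prior class proportions (tested
  explicitly).
* All randomness flows from a single integer seed through a deterministic
  sub-seed derivation (`seed·7919 + 104729·k mod 2³¹−1`), keeping every
  derived seed in 32-bit range; fixed seed ⇒ bit-identical outputs.

## Known limitations

* Published ω estimates, BEB posteriors and sitewise p-values for *Pan*
  PRDM9 are not desk-reproducible here because they require the full
  repeat alignment including external data; the selection machinery is
  instead validated by dense-matrix oracles, nesting inequalities,
  simulation recovery and type-I-error calibration.
* Branch models and branch-site models are out of scope, as are codeml
  file-format parity and tree search beyond the NJ fallback.
* BEB is implemented for M2a only; M8 site classification is NEB.
* The sitewise ω̂ is grid-valued (41 points by default); p-values inherit
  a conservative bias of at most the grid resolution.
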