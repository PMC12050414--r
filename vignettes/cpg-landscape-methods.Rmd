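---
title: "Methods: the CpG landscape of protein-coding DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CpG landscape of protein-coding DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpglandscape)
```

This vignette is the package's own account of the models and procedures
it implements: what is computed, under which conventions and
assumptions, which parameters matter, and what the synthetic generators
do and do not emulate.

## The problem

In vertebrates, methylated cytosines in CpG dinucleotides deaminate to
thymine at elevated rates, so CpG is depleted genome-wide. Protein-coding
DNA filters this pressure through the genetic code: some CpG losses are
silent (third-position, four-fold degenerate sites), others change the
protein or create a stop. The package quantifies CpG content in coding
and genomic DNA on a composition-adjusted scale, enumerates exactly what
the standard genetic code permits, scores dicodon avoidance, and tests
positional (5′ vs 3′) and regional (overlap-based) structure — with
seeded synthetic data so every stage can be checked against known truth.

## Genetic-code combinatorics

All codons are DNA (T, not U), uppercase. The standard table comes from
`Biostrings::GENETIC_CODE`: 61 sense codons, stops TAA/TAG/TGA.

* Within-codon CpG: `CGN` (bases 1–2; always arginine) and `NCG` (bases
  2–3; serine, proline, threonine, alanine) — 8 codons, 5 amino acids.
* Junction CpG: a C-ending codon (16 sense codons, 15 amino acids)
  followed by a G-starting codon (16 codons; 5 amino acids — V, A, D, E,
  G).
* The CpG-free repertoire removes the 8 CG-containing codons and then
  the 15 remaining C-ending codons: 61 − 8 − 15 = 38 codons. No retained
  codon contains CG or ends in C, so no concatenation of retained codons
  can form a CpG, and every amino acid keeps at least one codon.
  Removing G-starting codons instead is not an option: valine is
  encodable only by GTN. The dicodon space shrinks from 61² = 3721 to
  38² = 1444 ordered pairs (a 61.2% reduction).
* `min_synonymous_steps()` finds the shortest chain of single-nucleotide
  synonymous substitutions from a codon to a CpG-free codon of the same
  amino acid (breadth-first search over the synonymous substitution
  graph). Junction-formed CpG is deliberately ignored here: the question
  is codon-internal. CGT and CGC are the only codons needing two steps.
* A nuance worth stating: by exhaustive enumeration, **four** amino
  acids never occur within a CpG context under the defining rule (no
  codon contains CG, ends in C, or starts with G): lysine, methionine,
  glutamine and tryptophan. Lysine (AAA/AAG) is easy to overlook —
  classical treatments often list only M, Q and W — but it appears in
  none of the enumerated CpG-bearing classes. The package reports the
  enumerated set.

## The CpG content statistic

For a DNA stretch, overlapping dinucleotide windows (step 1) are
scanned; `#CpG` and `#GpC` are the counts of CG and GC windows, and

$$\mathrm{CpG\ content} = \frac{\#CpG}{\#CpG + \#GpC} \in [0, 1].$$

GpC is the normalisation partner because it has identical base content
but is not a methylation substrate; under base independence
P(CG) = P(GC) = gc² · s · (1 − s) (with gc the G+C fraction and
s = G/(G+C) the strand bias), so the neutral value is 0.5 irrespective
of composition — the reason this ratio, unlike raw CpG frequency, is
comparable across regions of different GC content and length. The
statistic is exactly invariant under reverse complementation because CG
and GC are both reverse-complement palindromes.

Conventions, chosen for bit-exact reproducibility:

* Windows containing any non-ACGT base (assembly N runs, IUPAC codes)
  are voided: they count toward neither the numerator nor the window
  total.
* Case-insensitive; soft-masked (lowercase) bases are ordinary bases —
  no repeat-awareness is attempted.
* A stretch with `#CpG + #GpC = 0` has undefined content and is returned
  as `NA` with an `undefined` attribute; callers must exclude such
  records (the pipeline ledgers them as `zero_denominator`).
* Genomic tiling anchors at coordinate 0 with non-overlapping tiles of
  5 kb by default; the trailing partial tile (or a whole scaffold
  shorter than the width) is retained, so no sequence is lost.
* Terminal windows are the first and last 99 bases (33 codons); a
  200-nt minimum keeps them disjoint.
* "GC content excluding CpG and GpC sites" is implemented by base
  masking: every base participating in any overlapping CG or GC window
  is removed before computing the GC fraction of what remains. Exclusion
  could also have meant subtracting dinucleotide counts or excluding
  only CpG; masking was chosen because it is unambiguous at overlaps
  (e.g. CGC) and it strictly decouples the correlate from the statistic.
  The convention is fixed and stated here so outputs are interpretable.

## Dicodon enrichment

Dicodons are ordered pairs of adjacent in-frame codons, sliding by one
codon within each CDS (never across genes). Pairs containing a stop or
an ambiguous codon are excluded. Expected counts are
N · f(c1) · f(c2) with f the pooled codon frequencies of the same CDS
set, stops excluded; enrichment is observed/expected. Pooling (rather
than per-gene frequencies) matches the per-species framing of the
analysis; both the pooling and the stop exclusion are stated in the
output metadata rather than left implicit. Pairs with expected count
below 5 (configurable) are flagged low-confidence, standard practice
for unstable small-expectation ratios, and dropped from top-k extraction
by default.

## Hypothesis tests

* Coding vs genomic: two-sided Mann–Whitney U on per-gene vs
  per-fragment contents.
* Content vs composition: Kendall τ between CpG content and the masked
  GC fraction, plus an OLS fit for slope/intercept; only genes of
  150–2000 nt enter this analysis (longer/shorter genes make length a
  confounder of both variables); the filter applies here only.
* 5′ vs 3′: paired Wilcoxon signed-rank on (first-99, last-99) window
  contents; genes under 200 nt or with an undefined window are dropped
  and reported. If every difference is zero the test degenerates and
  p = 1 is returned directly.

All tests are two-sided; no multiple-testing correction is applied
across this fixed, small battery — each comparison is reported with its
own p-value. Gene filtering retains genes with a real symbol (the
default pattern excludes RefSeq-style `LOC` location placeholders, a
proxy for partial genes and pseudogenes; the regex is configurable
because header dialects vary) and defined content; the retained set and
the exclusion ledger exactly partition the input. The genomic
distribution uses whole-genome tiles without masking coding regions — at
genome scale the coding fraction is small, and masking would require the
annotation that the fragment analysis deliberately avoids.

## Permutation test of region overlap

Two region sets (0-based, half-open; BED-compatible; strand ignored
since CpG content is strand-symmetric) on a shared genome. The observed
statistic is the summed per-region intersection in bases (or the count
of query regions touching the subject). Each permutation re-places every
query region uniformly at random on its own chromosome, preserving
length — respecting chromosome structure, as regioneR does by default.
Permuted regions may overlap one another; the per-region statistic makes
this well-defined without rejection sampling, and for disjoint inputs it
coincides with the merged intersection length. The empirical p-value
uses the add-one correction p = (1 + #{null ≥ obs})/(1 + n), so the
smallest attainable p is 1/(n + 1); a z-score against the null mean and
SD is reported, flagged undefined for degenerate nulls. Defaults
(n = 1000 permutations, same-chromosome placement) are declared choices,
not inferences. Input intervals that overlap are merged on load and the
merge is flagged.

## Synthetic generators and what they emulate

### Genome

A first-order Markov chain over A/C/G/T: the base distribution π is set
by the GC fraction and strand bias (A and T symmetric — AT skew is not
modelled); after a C, the G probability is multiplied by a depletion
factor λ and the row renormalised. This is the minimal generator that
decouples CpG depletion from GC content and strand bias — one knob per
phenomenon. λ = 1 is neutral; λ = 0 forbids CpG entirely. Solving the
stationary distribution gives the closed form

$$E[\mathrm{content}] = \frac{\lambda}{\lambda + 1 - \pi_{GC}(1-\lambda)},$$

which is independent of strand bias and was verified against brute-force
simulation before being relied on; inverting it recovers λ from a
measured content. Note π is the *pre-depletion* parameter: the realised
G frequency falls below π_G for λ < 1, which the closed form accounts
for. Defaults (GC 0.41, no strand bias, λ = 0.3) emulate a CpG-depleted
vertebrate genome. Sampling exploits the fact that the C/not-C indicator
is itself a two-state Markov chain: run lengths are geometric and the
non-C identities are conditionally independent given the runs, so
generation is vectorised; the test suite verifies the realised
transition frequencies against the specified conditional probabilities.

### Coding sequences

Genes are built from codon-usage weights over the 61 sense codons
(uniform by default), forced to start with ATG and end with a stop; no
internal stop can occur because draws are over sense codons only.
Default lengths are uniform on 67–400 sense codons (201–1200 coding nt),
a compact range that comfortably clears the pipeline's 200-nt rule while
keeping simulations fast. CpG depletion multiplies the weights of the
eight CG-containing codons by λ (default 0.8: coding DNA retains most of
its CpG), optionally with separate λ for the first/last 33 codons —
injected by reweighting codon choice, not post-hoc editing, so sequences
remain valid CDS. Junction CpG formation is *not* depleted by λ; the
knob targets within-codon CpG only, which is what the content statistic
detects in the terminal-window contrast. Dicodon adjustment factors turn
the draw into a codon-level Markov chain with next-codon distribution
q(c|p) ∝ w(c)·f(p,c); the truth record stores the exactly computed
expected enrichment q(b|a)/p(b) (stationary p by power iteration). Gene
boundaries perturb this at order 1/length — the forced ATG measurably
biases pairs involving ATG when genes are short, so i.i.d.-null studies
should use one long gene (the acceptance suite uses a single 10⁶-codon
gene, making the edge effect O(1/N)). A configurable fraction of genes
(default 0.1) receives `LOC` placeholder symbols to exercise filtering.

### Region fixtures

Subject blocks are evenly spaced tiles whose width is chosen so that the
fraction of query *start positions* lying fully inside equals the
requested coverage. Query regions start from a uniform draw and are then
moved into (or out of) the subject with exactly the probability that
makes P(fully inside) equal the requested enrichment level. Two
consequences drive the test design: at enrichment = coverage no move
ever happens and placement is *exactly* the permutation null (empirical
p-values uniform by construction), and at enrichment = 1 every query
lies inside the subject (maximal overlap, p = 1/(n+1)).

All generators are byte-deterministic given their parameters and seed.

## Numerical and statistical choices

* Tolerances for stochastic checks are 3 standard errors of the
  measured quantity. For CpG content on Markov-generated sequence the
  binomial SE underestimates (dinucleotide occurrences are
  autocorrelated), so SEs are estimated by batch means over 10-kb tiles
  — the standard estimator for correlated sequences.
* Simultaneous checks over all 3721 dicodons cannot demand every pair
  within 3 SE: ~10 violations are expected by chance alone. The suite
  asserts ≥99% coverage plus a familywise 1% bound on the maximum
  standardised deviation.
* Problem sizes in the acceptance suite — 10⁶-base genomes, a
  10⁶-codon CDS pool, 2000 genes/fragments for the direction contrasts,
  200 seeds × 99 permutations for null calibration — were chosen once as
  the smallest scales at which the 3-SE bands are decisive.
* Degenerate inputs are explicit: zero-denominator contents, constant
  correlation inputs, all-zero paired differences, zero-SD permutation
  nulls all return flagged results rather than NaN.

## What passing tests do and do not show

The generators produce stationary, isochore-free, intron-free,
repeat-free sequence with independent genes and at most first-order
dinucleotide structure. Passing the recovery tests shows the statistics
and tests are implemented correctly and are calibrated under these
controlled conditions; it does not validate biological conclusions on
real genomes, where annotation quality, repeat content, CpG islands,
isochores and phylogenetic non-independence all intrude. The package's
role on real data is to compute the documented quantities reproducibly
(deterministic end-to-end runs with manifests), not to adjudicate the
evolutionary mechanisms behind them.

## Known limitations

* CpG-island calling and methylation-level estimation are out of scope.
* The overlap test offers no gap-aware or locally constrained
  randomisation; enriched assemblies with large N-gaps would need one.
* Kendall τ uses the O(n²) implementation in `stats::cor.test`;
  for very large gene sets (≫10⁵) a faster τ would be wanted.
* The dicodon expectation uses pooled codon frequencies;
  `dicodon_enrichment()` accepts any codon tally, so per-gene or
  external-reference expectations can be supplied, but
  pooled-with-stops-excluded is the documented default.
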