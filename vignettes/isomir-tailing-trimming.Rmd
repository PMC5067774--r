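---
title: "Quantifying miRNA tailing-and-trimming from small RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA tailing-and-trimming from small RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirTT)
```

## The problem

Mature miRNAs are not single sequences. Small RNA-seq of a miRNA locus
returns a population of 3′ variants (isomiRs): reads ending exactly at the
annotated mature end, reads carrying extra 3′ nucleotides that match the
precursor immediately downstream (*templated extensions*), reads carrying 3′
nucleotides that do **not** match the template (*non-templated tails*, added
enzymatically), and reads stopping short of the mature end (*trimming*).

For miR-21-5p this population structure is functionally loaded. The dominant
Dicer product is a 23-mer with a templated 3′ cytosine ("+C"). The
non-canonical poly(A) polymerase PAPD5 adds a single non-templated adenosine
to that species (the "+CA" 24-mer), which marks it for 3′→5′ exonucleolytic
trimming by PARN, yielding the canonical-length 22-mer. Two per-sample
summary statistics capture the flux through this tailing-and-trimming
pathway:

* **adenylation ratio** = count(+CA species) / count(+C species) — how
  actively the substrate is being tailed;
* **degradation ratio** = count(canonical-length species) / count(+C
  species) — how much trimmed product has accumulated relative to substrate.

isomirTT classifies reads into these species from first principles,
computes the two ratios per sample, quantifies precursor sub-regions as a
proxy for processing changes, and compares everything between sample groups.
A kinetic simulator generates read sets with known ground truth so that every
stage is testable end to end.

## Read decomposition: the greedy templated-first rule

Every read is anchored to a mature arm by exact, ungapped matching of its 5′
portion, allowing the 5′ start to deviate by at most `max_offset5` (default
±2 nt) from the annotated arm start and requiring at least `min_core_match`
(default 14 nt) of matching templated sequence. The 3′ end is then
decomposed by a single deterministic rule: **walk 3′-wards along the
precursor (and, past the precursor boundary, along the arm's supplied
template context) for as long as read and template agree; everything after
the first disagreement is the tail.**

This greedy templated-first rule is the only deterministic convention under
which the "+C" species is called a templated extension while the terminal A
of "+CA" is called non-templated. Its known edge case is a genuine enzymatic
tail that happens to coincide with the template nucleotide at its position:
such an addition is indistinguishable from templated extension by sequence
alone and is classified as templated. The synthetic reference is constructed
so that the position after the "+C" is a G, making a single-A tail always
unambiguous; for real annotations the same caveat applies as in any
sequence-based tailing analysis.

Three further conventions matter:

* **Zero mismatches** are allowed in the templated portion. A read whose
  interior disagrees with the precursor (sequencing error, editing) is
  `unassigned` rather than force-fit, because the ratio statistics are
  highly sensitive to misclassified 3′ ends. At a per-base error rate of
  10⁻³ this discards ~2% of reads of a 22-mer, symmetrically across species,
  leaving the ratios essentially unbiased.
* **Multi-arm ambiguity**: a read matching the arms of several precursors is
  excluded from counting by default (an option includes it at weight 1/n).
  Distinct candidate 5′ offsets within one arm never create ambiguity; the
  decomposition with the longest templated portion wins (ties: smaller
  |offset|, then the more upstream start).
* **Ratios use offset-0 reads only.** The 22/23/24-mer species are defined
  by total length from a fixed 5′ start; admitting 5′-shifted reads of
  coincidentally equal length would conflate 5′ and 3′ variation. 5′-shifted
  isomiRs are still profiled, in their own keys.

## Coordinates and template context

All coordinates are 0-based, half-open, precursor-relative; genomic strand
is resolved once, at annotation load time (minus-strand GFF3 records are
flipped into precursor orientation). The internal alphabet is DNA; U is
accepted on input and emitted on request. Each arm must provide at least
10 nt of template context 3′ of its mature end — taken from the precursor
itself where the arm ends inside it, and required explicitly for arms ending
at the precursor boundary. Guessing genomic flanks for boundary arms would
silently change tail calls, so it is a load-time error instead; observed
tails in this pathway are 1–2 nt, so 10 nt of context is ample, and tails
are only classified up to the available context length.

## Ratios, cpm and missingness

Counts are normalised as counts per million (cpm); both ratios are invariant
under any positive rescaling of the counts, so raw counts and cpm give
identical ratios (this makes the choice of denominator immaterial for the
ratio statistics, and it is tested as an invariant). Two deliberate
conventions:

* the degradation numerator is **exactly** the canonical-length species, not
  the sum of all shorter species — shorter trims are reported separately in
  the isomiR profile;
* the adenylation numerator is **exactly** one non-templated A — longer
  A-tails are profiled but excluded from the ratio;
* a sample with zero substrate counts has *undefined* ratios, propagated as
  missing (`NA`) and dropped from group statistics, never as 0. Zeros would
  fabricate group differences at low sequencing depth.

## The precursor-region processing proxy

To separate a change in mature-miRNA turnover from a change in
Drosha/Dicer processing, reads located on the precursor are counted into
five sub-regions: fragments upstream of the 5p arm, the 5p arm, the loop,
the 3p arm, and fragments downstream of 3p. Each read votes for the region
holding the majority of its bases (ties to the 5′-most region); reads
overlapping no region go to an `outside` bucket so counts always conserve.
If turnover alone changes, only 5p-derived species move; if processing
changes, all fragments move together.

## The kinetic simulator

The generator draws reads from the steady state of a minimal linear chain —
our modelling choice, as the biology fixes only the arrow structure, not the
functional form:

$$\varnothing \xrightarrow{\alpha} S_{sub}
  \xrightarrow{a} S_{tail} \xrightarrow{t} S_{trim},
  \qquad \text{all species} \xrightarrow{\delta} \varnothing$$

with substrate (+C) produced at rate α, adenylated at rate *a* (PAPD5),
tailed species trimmed in a single jump to canonical length at rate *t*
(PARN), and a basal decay δ for every species. The steady state is

$$S_{sub} = \frac{\alpha}{a+\delta},\quad
  S_{tail} = \frac{a\,S_{sub}}{t+\delta},\quad
  S_{trim} = \frac{t\,S_{tail}}{\delta},$$

giving closed-form expected ratios
$\mathrm{aden} = a/(t+\delta)$ and
$\mathrm{degr} = (t/\delta)\,a/(t+\delta)$, both independent of α. Total
mature-arm mass is α/δ regardless of *a* and *t* — production is only lost
through δ — so tailing/trimming perturbations redistribute 5p species
without touching the simulated loop/3p/flank background, which is exactly
the property the region proxy relies on.

Default scenario, chosen once as a plausible regime in which all three
species are well represented and both ratios are O(1): α = 100, a = 0.2,
t = 0.3, δ = 0.1 (expected ratios 0.5 and 1.5), sequencing depth 10⁵ reads
per sample, three samples per group, per-base substitution error 10⁻³
(typical short-read scale), and a constant background abundance of 60 units
per region fragment (≈19% of reads), enough to make region counts
informative without dominating the library. Group effects are multiplicative
factors on the rates; an ASO-style de-repression of the pathway is modelled
as a joint 1.5× increase of *a* and *t*.

Randomness is controlled by one root seed; per-sample seeds are derived
deterministically from (root, sample index), so identical seeds give
byte-identical FASTQ and tables, and any single sample can be regenerated.

What the simulator deliberately does **not** emulate: adapter sequence and
trimming artefacts, quality-score-dependent error profiles, PCR
duplication, oligo-adenylation (tails longer than one A), intermediate
trimming lengths, multi-locus backgrounds, or cellular heterogeneity of
bulk tumours. Passing the end-to-end checks therefore demonstrates that the
decomposition, counting and statistics are correct on reads whose generative
process is known — not that any particular biological dataset will show a
given effect.

## Group statistics

Per-sample ratios (or per-key cpm, or region counts) are compared between
two groups with the classical pooled-variance Student's t-test, two-sided.
Welch's unequal-variance variant is available behind a flag, and
Benjamini–Hochberg adjustment across miRNAs is offered but off by default,
matching the convention of reporting raw t-test p-values for a single
focal miRNA. Comparisons are made on the untransformed metric; for strongly
skewed cohort-scale data a log transform of cpm before testing is a
reasonable alternative the API admits (the metric column is caller-chosen).
Degenerate inputs (zero pooled variance) and underpowered groups (n < 2
usable values) yield flagged/skipped rows, not errors.

## Numerical and implementation choices

* Matching operates on unique read sequences, so cost scales with library
  complexity, not depth.
* Sequencing errors are injected by drawing the number of erroneous bases
  binomially and placing them uniformly, avoiding per-base RNG at depth 10⁵.
* Ties and degenerate inputs are all resolved deterministically (documented
  above), so repeated runs are byte-identical.
* Problem sizes used by the package's own end-to-end checks: ratio recovery
  at depth 10⁵ over 10 seeds; direction checks over 100 replicate pairs at
  depth 10⁵; the null-calibration check over 100 two-group replicates at
  depth 2×10⁴ per sample (the type-I error of the t-test on per-sample
  ratios does not depend on depth, so the smaller library size is used
  there); decomposition agreement on ≥1000 randomized reads over ≥20
  randomized references.

## Limitations

* The matcher is exact and local: no gapped alignment, no internal-edit
  tolerance, no genome-wide multi-mapping resolution. Reads from loci not in
  the supplied annotation are simply unassigned.
* A tail nucleotide that coincides with the template is classified as
  templated (see above) — an identifiability limit of sequence data, not of
  the implementation.
* The kinetic model is the minimal chain consistent with the
  tail-then-trim mechanism; it is a simulation scaffold for validation, not
  a fitted model of measured kinetics.
* Cohort-scale confounders (tumour purity, subtype composition, batch) are
  out of scope; group labels are taken as given metadata.
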