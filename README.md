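# isomirTT

Quantifying miRNA 3′ tailing-and-trimming from small RNA-seq.

## What this is for

Small RNA-seq reads from a miRNA locus are a mixture of 3′ isoforms
(isomiRs): the canonical mature sequence, *templated* 3′ extensions that
match the precursor downstream of the mature end, *non-templated* tails
added enzymatically, and trimmed species. For miR-21-5p, the dominant Dicer
product is a 23-mer carrying a templated "+C"; the non-canonical poly(A)
polymerase PAPD5 mono-adenylates it (the "+CA" 24-mer), marking it for
3′→5′ trimming by PARN back to the canonical 22-mer. The flux through this
turnover pathway is summarised per sample by two statistics:

```
adenylation ratio = count(+CA species) / count(+C species)
degradation ratio = count(canonical-length species) / count(+C species)
```

isomirTT is for analysts who want these quantities from FASTQ (or SAM)
without a bespoke script stack. It:

* loads precursor annotations (FASTA + miRBase-dialect GFF3 or a simple
  TSV) into precursor-relative coordinates with 3′ template context;
* anchors each read to a mature arm and decomposes its 3′ end by a greedy
  templated-first rule into (5′ offset, templated Δ3′, non-templated tail);
* aggregates per-sample isomiR profiles with cpm normalisation, computes
  the two ratios, and counts precursor sub-regions (upstream of 5p, loop,
  mature 3p, downstream of 3p) as a proxy for processing changes;
* compares ratios, per-key cpm and region counts between sample groups with
  the pooled-variance Student's t-test (optional Welch, optional
  Benjamini–Hochberg);
* simulates the whole experiment from an explicit kinetic model of the
  tailing-and-trimming chain — production α, adenylation *a*, trimming *t*,
  basal decay δ — whose steady state gives closed-form expected ratios
  aden = a/(t+δ) and degr = (t/δ)·a/(t+δ), so every pipeline stage can be
  validated against known ground truth.

## Worked example

Simulate an ASO-style two-group experiment (blocking the repressor of the
pathway, modelled as a joint 1.5× increase of the adenylation and trimming
rates), quantify it, and compare groups:

```r
library(isomirTT)

scn <- sim_scenario(depth = 2e4, n_samples = 3, seed = 11,
                    group_effects = list(control = c(),
                                         aso = c(a_rate = 1.5, t_rate = 1.5)))
ex  <- simulate_experiment(scn, out_dir = "sim")

cfg <- run_config(reference = list(synthetic_reference()),
                  samples  = setNames(ex$metadata$fastq, ex$metadata$sample_id),
                  metadata = ex$metadata, out_dir = "out",
                  contrast = c("aso", "control"))
q   <- run_quantify(cfg)
subset(q$ratios, arm_name == "syn-mir-1-5p")
```

```
   sample_id substrate_count tailed_count trimmed_count adenylation_ratio degradation_ratio
1  control_1            5208         2613          7954             0.502              1.53
3  control_2            5295         2579          7866             0.487              1.49
5  control_3            5234         2694          7805             0.515              1.49
7      aso_1            3976         2214          9628             0.557              2.42
9      aso_2            3845         2156          9780             0.561              2.54
11     aso_3            3944         2225          9650             0.564              2.45
```

The control samples scatter around the closed-form truth of the generating
model (aden 0.5, degr 1.5); the treated group moves to the model's perturbed
truth (0.545, 2.455): the adenylation ratio rises because tailing
accelerates, and the degradation ratio rises more strongly because trimmed
product accumulates. The group comparison quantifies this:

```r
cmp <- run_compare(cfg, q)
subset(cmp, arm_name == "syn-mir-1-5p", c(metric, mean_a, mean_b, t, p))
```

```
             metric mean_a mean_b     t        p
1 adenylation_ratio  0.561  0.501  7.19 1.98e-03
3 degradation_ratio  2.471  1.501 24.59 1.62e-05
```

Both ratios are significantly higher under treatment (t > 0 means group A,
here `aso`, has the larger mean). `run_quantify()` also writes per-sample
isomiR, ratio, region and QC tables plus a run manifest under `out/`.

A thin command-line wrapper with `simulate` / `quantify` / `compare` / `all`
subcommands is installed at `inst/scripts/isomirtt.R`; see
`vignettes/isomir-tailing-trimming.Rmd` for the model, parameter and design
documentation.

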