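---
title: "Quantifying the conversion of naive sequences into piRNA-producing loci"
author: "pirnaconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the conversion of naive sequences into piRNA-producing loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnaconv)
```

## The problem

In *Drosophila* germlines, transposable elements are silenced by 23–29-nt
PIWI-interacting RNAs (piRNAs) produced from heterochromatic piRNA
clusters. A sequence that is newly introduced into such a cluster — for
instance a transgene inserted into a subtelomeric repeat — does not produce
piRNAs on its own: it must be *converted* into a piRNA-producing state.
Conversion is triggered by maternally deposited piRNAs complementary to
flanking sequences and proceeds over a small number of generations; whether
the locus arrived from the mother (with its piRNAs) or from the father
(DNA only) therefore changes everything about the first generations.

`pirnaconv` implements the quantitative toolbox for studying this process
from ovarian small RNA sequencing at *defined reference regions*
(transgene domains, reporter genes, repeat units), plus the companion
assays: RT-qPCR and ChIP-qPCR normalization, and egg-chamber ON/OFF
repression scoring. A seeded synthetic-data generator emulates the
statistical structure of such libraries so that the entire chain is
testable without any sequencing download.

## Small RNA processing model

**Trimming.** Reads carry a ligated 3′ adapter
(`TGGAATTCTCGGGTGCCAAG` by default). The insert is the prefix before the
leftmost exact adapter match; a partial adapter prefix flush with the 3′
end counts if at least 8 bases match. Matching is exact — no mismatches —
because that keeps the operation deterministic and auditable; reads
without an adapter, or with inserts outside the retained length window,
are tallied per reason, never silently dropped. The insert window default
is 18–30 nt; the biological selections (23–29-nt piRNAs, 21-nt siRNAs)
are applied downstream, so the window only needs to contain both.

**Mapping.** Reads are matched to the reference set by ungapped,
strand-aware Hamming comparison: a hit is *every* (region, start, strand)
whose window differs from the read (or its reverse complement) at no more
than `max_mm` positions, `max_mm` ∈ 0..3. This is the semantics of a
classic end-to-end short-read aligner run in mismatch mode, made fully
explicit so it can be checked against a brute-force scan — the test suite
does exactly that on randomized inputs. Indels, quality scores and
seed-and-extend heuristics are deliberately out of scope: at 18–30 nt and
reference sets of tens of kilobases, exhaustive semantics are affordable
and unambiguous. Reads containing `N` are excluded before mapping because
mismatch counting with `N` is ill-defined. Headline metrics use unique
mappers only; uniqueness is judged within the analysis-role regions, so a
read that also matches a normalization region stays "unique" for the
analysis. The implementation uses a dictionary scan (Biostrings) for the
exact-match case and a per-sequence scan for 1–3 mismatches; both are
defined — and tested — purely by the brute-force semantics.

**Annotation and normalization.** Reads are categorized by the role of
the regions they match with 0 mismatches: `normalization_genome`,
`miscRNA`, `tRNA`, `miRNA`. Categories are not exclusive. The
normalization denominator is `genome − miscRNA − tRNA` and normalized
counts are per million such reads. Two alternative scalings (per million
miRNA reads; per million genome reads) are provided; all three preserve
within-library ratios exactly, so conclusions should not hinge on the
choice, and a property test asserts as much. Whether the miscRNA category
should exclude reads already counted as miRNA is ambiguous in common
usage; the denominator here follows the subtraction formula literally.

## The metrics

* **Size distribution** — normalized counts per read length (18–30 nt)
  and strand.
* **Coverage profile** — per-position normalized counts of 5′ ends,
  strand-resolved, for a length window (default 23–29 nt). Positions are
  0-based half-open internally; human-readable reports are 1-based.
* **Density per kb** — normalized windowed count divided by region length
  in kb: the headline conversion metric. Together with the **1U bias**,
  the fraction of those reads beginning with a 5′ uridine (`T` in DNA
  space, evaluated on the read's own strand).
* **Ping-pong signature** — `pair_counts[k]` sums, over positions `p`,
  the product of normalized sense 5′ counts at `p` and antisense 5′
  counts at `p + k − 1`; `k = 10` is the ping-pong register. The z-score
  of each register is taken against registers 1..K (K = 25 by default).
  Including `k = 10` in its own background is conservative — a true
  signal shrinks its own z-score — and the window is a config key.
  Weighting by 5′-count products (rather than distinct read species)
  matches the coverage-based computation and makes the exhaustive
  pairwise oracle tractable. If all registers are equal the signature is
  flagged degenerate rather than given 0/0 z-scores.
* **Strand asymmetry** — the minority-strand fraction `m` classifies a
  region as symmetric dual-strand (`m ≥ 0.25`), asymmetric dual-strand
  (`0.02 ≤ m < 0.25`) or uni-strand (`m < 0.02`). These thresholds
  operationalize what is usually a qualitative call; they are package
  choices, documented and configurable.
* **siRNA/piRNA ratio** — normalized 23–29-nt count over normalized
  21-nt count; undefined (flagged) without 21-nt reads.
* **Dinucleotide content** — frequencies of the 16 dinucleotides over
  overlapping windows (windows containing `N` are skipped, the
  denominator adjusted), feeding an ordinary least-squares model of
  piRNA density on sequence length and composition with per-coefficient
  two-sided p-values.

## Conversion kinetics

A lineage's per-generation densities form a `conversion_series`. Ratios
between generations (`generation_ratio`) are reported to 2 decimals in
summaries. The kinetic model is a per-generation Bernoulli conversion:

  density(g) = D_max · (1 − (1 − c)^g)

for paternal inheritance, and D_max throughout for maternal inheritance.
This is the minimal model consistent with all-or-none egg-chamber states
and saturation within roughly four generations at c ≈ 0.45; the observed
empirical curves constrain the shape but no equation, so the geometric
form is a package choice. `estimate_conversion_rate()` fits it by
nonlinear least squares (port algorithm, c constrained to (0, 1]).
A length-dependent conversion efficiency can be emulated in the generator
by setting per-region rates (e.g. an instantly converting short domain
with c = 1 next to a slowly converting long transgene); a built-in
functional form c(L) was considered and rejected as speculative — the
per-region rates make the same comparisons possible without asserting a
law.

## qPCR statistics

RT-qPCR: technical-replicate standard quantities are averaged (meanSq)
and expressed as meanSq(gene)/meanSq(reference gene) within a biological
replicate, RpL32 being the customary reference; group summaries average
per-sample ratios. ChIP-qPCR: ΔCt = meanCt[antibody] − (meanCt[input] −
log2(input dilution factor)), the dilution factor being the reciprocal of
the input chromatin fraction (5% input → factor 20). Fold enrichment is
implemented as 2^(ΔCt[NS] − ΔCt[ChIP]) — the only algebraic reading of
the commonly printed (and frequently garbled) exponent that yields 1 for
no enrichment and values above 1 for specific antibody signal. Fold
enrichments are optionally rescaled to a control region (42AB, a large
germline cluster constitutively high in H3K9me3), which then maps to 1.
Group comparisons use a two-sided Welch t-test (the unequal-variance form
is the safer default when only "bilateral t-test" is specified) or
one-way ANOVA followed by Tukey HSD.

## Egg-chamber repression

Silencing is scored per ovary as the percentage of egg chambers with no
reporter expression, restricted upstream to the relevant stages (8–10 for
RFP reporters). Intervals are Wilson score intervals — unlike the Wald
interval they behave at 0% and 100%, both of which occur. Subline
summaries are unweighted means ± sample SD across sublines; with a single
subline the SD is flagged undefined rather than fabricated from pooled
chambers.

## What the generator emulates — and what it does not

`simulation_config()` describes the full study layout: an 18-kb
multi-domain transgene (with 3.5-kb reporter, 7.2-kb and 4.7-kb gene
domains, 1.8-kb plasmid backbone, 0.58/0.23-kb terminal P-element
sequences), a 0.9-kb unique subtelomeric domain with strongly asymmetric
strand output (strand ratio 0.9, instant conversion c = 1), a 4.1-kb
eye-color gene (c = 0.45), and a 20-kb genome background with embedded
miscRNA/tRNA/miRNA category regions so that category reads also count as
genome-matching, exactly as the normalization denominator assumes.
Defaults: piRNA lengths 23–29 nt peaked at 26, 1U bias 0.75, ping-pong
fraction 0.25, 21-nt siRNA component at 0.2 × the plateau density
(generation-independent, so the 23–29/21 ratio grows along a paternal
series), 5% of piRNA reads carrying 3 random substitutions (recovered
only at `max_mm = 3`), and background counts of 13.5k/3k/1.5k/2k
(genome-only/miscRNA/tRNA/miRNA), i.e. a normalization factor near 65.
Plateau densities (1500–2500 reads/kb) are of the magnitude seen in
converted transgene regions. These library sizes (roughly 20k reads per
library) keep a full 4-generation, 2-lineage pipeline run in the
low minutes on a laptop while leaving every estimator comfortably inside
its statistical tolerances.

Two implementation choices matter for interpretation. First, the 1U bias
is produced by *biased placement* — a read's 5′ end is put on a uridine
position with exactly probability `one_u_bias` — so every simulated read
remains a perfect reference substring and the realized 1U fraction equals
the parameter. Second, ping-pong pairs are placed by construction
(antisense 5′ exactly 9 bp downstream of a sampled sense partner's 5′
end), so the k = 10 register is enriched by the configured fraction.

The generator does **not** emulate: real *Drosophila* sequence
composition (references are i.i.d. uniform, so analysis regions do not
overlap the genome-background category, whereas real transgene reads also
map to the assembly), sequencing error beyond the configured
substitutions, ligation biases, phasing-trail structure downstream of
ping-pong initiators, or transposition/invasion dynamics. Passing
parameter-recovery tests therefore demonstrates the correctness and
calibration of the estimators under the stated generative model — not
that real libraries satisfy that model.

When every background count is zero the generator emits unnormalized
libraries (normalization factor 1) and density targets are read as raw
reads/kb; several tests use this mode because scale-free statistics (the
ping-pong z-score, strand fractions) do not depend on the normalization
constant.

## Numerical and degenerate-input choices

* Ties and orderings are always deterministic (hits sorted by region,
  start, strand); nothing is sampled at analysis time.
* Zero-coverage regions: strand asymmetry errors (no denominator), 1U is
  flagged undefined, densities are 0.
* Zero-variance ping-pong backgrounds: degenerate flag, `NA` z-scores.
* Normalization denominators ≤ 0 error out rather than returning
  infinities.
* The conversion fit starts from `c ≈ d₁/max(d)` and `D_max = max(d)`,
  with box constraints keeping `c` in (0, 1].
* TSV writers refuse NaN/Inf (while `NA` round-trips); coverage tracks
  are bedGraph-style runs with antisense written as negative values.

## Problem sizes used in the checks

The shipped tests and the acceptance script regenerate everything from
seeds at these scales: mapper-oracle equivalence on 1000 random
read/reference/mismatch cases (references ≤ 300 bp); exhaustive ping-pong
pair enumeration on libraries of ≤ 500 reads; single-locus libraries of
roughly 2–4k reads for bias/strand/ping-pong recovery (20 seeds for the
z-score check); full-layout libraries of ~20k reads over four paternal
generations for the conversion-rate fit; 100 replicate qPCR plates for
the noisy-enrichment check. These sizes were chosen so each check's
statistical tolerance (binomial 99% CI, 3σ, ±0.1 on c) is meaningfully
exercised.

## A worked run

```{r, eval = FALSE}
cfg <- simulation_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "pipeline_out")
res$metrics      # per region x generation x lineage
res$conversion   # fitted conversion rates and G1->G4 ratios
```

The pipeline writes TSV metrics, bedGraph coverage, overlap-signature
tables, qPCR and repression summaries, and a JSON manifest with per-stage
parameter hashes and output checksums; unchanged stages are skipped as
`"cached"` on re-runs, and external FASTQ libraries can be supplied via
`cfg$libraries` in place of simulation.

## Known limitations

* Genome-scale alignment is out of scope by design: "genome" membership
  means matching a `normalization_genome` region of the supplied
  reference set.
* The mismatch path (1–3 mm) scans per distinct sequence and is intended
  for analysis-region subsets, not multi-million-read libraries.
* The strand-class thresholds and the ping-pong background window are
  conventions, not estimates; both are exposed as parameters.
* The geometric conversion model is a minimal description; real
  conversion curves may be sigmoidal in early generations, and the
  per-generation probability need not be constant.
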