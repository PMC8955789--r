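---
title: "Methods: caste- and population-level SNV and dN/dS analysis"
author: "castevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caste- and population-level SNV and dN/dS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castevar)
```

## Scope and data model

`castevar` implements the downstream analysis of a transcriptome
variant-calling study in a social insect: nine RNA-seq libraries — one per
caste (nymph, soldier, worker) in each of three populations (Raleigh,
Boston, Toronto) — variant-called against a single consensus reference
transcriptome. The package starts where the caller stops: its inputs are
the reference multi-FASTA, one VCF v4.2 per library, a three-column
metadata table, and optionally a list of caste-associated transcript IDs.
Assembly, read mapping and variant calling are out of scope by design; the
synthetic generator (below) stands in for them during development and
testing.

All coordinates are 1-based and inclusive (VCF/FASTA convention), and all
sequence is handled on the transcript (sense) strand. `U` is normalised to
`T` on input.

## Variant isolation and the depth filter

`read_snvs()` keeps exactly the VCF rows describing biallelic single-base
changes: REF and ALT both single bases in `{A,C,G,T}`. Indels, MNVs,
symbolic alleles and spanning deletions are dropped. Multi-allelic rows are
*decomposed* — each single-base ALT becomes its own record at the same
position — so that alleles are conserved (`#records == sum over rows of
single-base alts`); a caller that prefers to drop such rows can filter on
the decomposed records afterwards. Read depth comes from the first sample's
`FORMAT/DP` when present, then `INFO/DP`, else 0. Duplicate
`(transcript, pos, alt)` triples resolve last-read-wins with a warning.

`filter_by_depth()` retains records with `depth > min_depth`
(default 10, strict). The source methodology is ambiguous about the
direction and strictness of this filter: the written description says
variants were removed when depth was *above* the threshold, while the
associated figure describes the retained set as "high-quality (depth > 10)".
We treat the former as a typographical slip — a filter that deleted every
well-supported variant would contradict the rest of the analysis — and
implement the latter, with both the threshold and the strictness exposed as
arguments. A related "FDR ≤ 0.1" target attached to that filter has no
computable definition from the available inputs and is not modelled.

The transition/transversion ratio counts `A↔G` and `C↔T` as transitions and
everything else as transversions; with zero transversions the ratio is
undefined and reported as `NA` (a value, not an error).

## Mutational catalogues

`build_sbs6()` and `build_sbs96()` follow the standard single-base
substitution conventions: every change is re-expressed so the mutated base
is a pyrimidine (purine-reference changes are reverse-complemented, which
swaps and complements the flanks), giving 6 substitution types and
6 × 4 × 4 = 96 trinucleotide classes. Flanking bases are read from the
reference transcript at `pos − 1` and `pos + 1`. Because the data are
transcript-space variants, the sense strand of the transcript provides the
context; the purine-lead presentation is available as an output option.
Records at a transcript's first or last base have no flank and are excluded
from SBS-96 (but not SBS-6); records whose VCF reference base disagrees
with the FASTA are excluded and flagged, never silently recoded. Both
exclusion tallies are always reported, so per-library totals reconcile
exactly with SNV counts. Whether the original custom scripts drew context
from the reference or from read evidence is not stated; reference-drawn
context is the only option the inputs support.

## Longest-ORF dN/dS (Nei–Gojobori)

Each transcript's coding template is its longest open reading frame on the
forward strand: an `ATG` to the first in-frame stop (`TAA`/`TAG`/`TGA`),
searched in all three frames, ties broken toward the smallest start.
Site counts follow the NG86 convention: for every codon and codon position,
each of the three possible changes is classified against the standard
genetic code, contributing 1/3 site to the synonymous or nonsynonymous
total; changes that *create* a stop codon contribute to neither, and
stop-gain substitutions are likewise excluded from both numerator and
denominator (tallied separately). Variants outside the ORF, or inside the
terminal stop codon, are noncoding. Multiple SNVs in one codon are
classified independently against the reference codon — inputs are variants
against a single reference, not phased haplotypes, so no pairwise-pathway
averaging applies.

Proportions `p_S`, `p_N` are corrected with the one-parameter
(Jukes–Cantor) model `d = -(3/4) ln(1 - 4p/3)`, which saturates at
`p = 3/4`; the package raises an error there rather than returning a
complex number, and reports `d_N/d_S = NA` (undefined) when `d_S = 0`.

**Aggregation.** The source describes one ratio per sample but
per-transcript proportions. Per-transcript ratios are undefined whenever a
transcript has no synonymous hit — the majority at realistic densities — so
the default is *pooled-within-sample*: substitution and site totals are
summed over all in-scope transcripts that have an ORF before forming the
proportions. A per-transcript mode is provided for sensitivity analysis.
When pooling *across* libraries (as in the recovery analysis below), each
library contributes its own site total, i.e.
`p = Σ substitutions / Σ per-library sites`; this is the variant-weighted
mean of per-library proportions and avoids double-counting sites shared
through the common reference.

The caste-associated subset is taken as a file of transcript IDs and the
analysis is agnostic to its size (the source itself reports two different
sizes for its subset, 570 in the methods and 230 in the results).

## Group statistics

SNV counts are compared with the Kruskal–Wallis rank test (tie-corrected)
and Dunn's post-hoc z tests on mean ranks; ts/tv and dN/dS with one-way
ANOVA and Tukey's HSD. The Dunn adjustment method is not named in the
source, which reports only inequality statements; the default here is
Benjamini–Hochberg with `none`/`bonferroni`/`holm` available. With n = 3
libraries per group these tests are low-powered; no minimum-n refusal is
imposed beyond the mathematical contracts. Degenerate inputs follow
explicit contracts: constant data give H = 0 (p = 1) and an undefined F
(p = 1); zero within-group variance with distinct means gives F = ∞
(p = 0). Grouped count summaries use the sample SD (n − 1), recorded in the
run manifest.

## The synthetic study generator

`generate_study()` writes a complete study — reference FASTA, nine VCFs,
metadata, subset list, and a ground-truth table of planted per-variant
labels — from a single `simulation_config()`.

**Reference.** Each transcript is 5′UTR + `ATG` + k inner sense codons +
stop + 3′UTR. UTR bases are i.i.d. with the configured GC content and may
contain stop triplets (deliberately, to exercise the ORF finder); inner
codons are uniform over the 61 sense codons. Every transcript is re-scanned
and resampled until the planted ORF is the longest one, so planted
coordinates are exact ground truth.

**Variants.** Candidate changes are all `(position, alt)` pairs. Base
weights encode the ts/tv model — a transition with probability
`titv/(1+titv)`, each transversion with half the remainder — multiplied by
`nonsyn_weight` for nonsynonymous changes (everywhere) and additionally by
`soldier_nonsyn_enrichment` for nonsynonymous changes in subset transcripts
of soldier libraries. Positions are drawn without replacement with
probability proportional to their total weight (exponential-key sampling),
so no two variants share a position; the alt at each chosen position is
drawn proportionally to the change weights. Depths are negative-binomial
(default mean 40, dispersion 5 — any right-skewed count model matching a
10–100-dominated depth profile would do). Populations differ only by label
by default; an optional per-population multiplier of the variant count
emulates population-level count differences.

**Seeding.** One master seed generates the reference; each library runs in
its own substream seeded by a stable 31-bit hash of the library ID, so
adding a library never perturbs the others and identical config + seed
yields byte-identical output files.

**Study conditions.** The defaults are chosen once for statistical power at
desk scale, not to mimic the source study's (much larger, irreproducible)
library sizes: 400 transcripts of 90–210 inner codons with 30–120 nt UTRs
at GC 0.45 (≈ 240 kb of transcriptome), 20,000 variants per library
(≈ 8 % of positions), planted ts/tv 1.7 (the observed transcriptome-wide
value in this kind of data), subset fraction 0.04. `library_effect_sd`
(default 0.08) applies a per-library lognormal multiplier (unit mean) to
the nonsynonymous odds, emulating the biological between-library
variability of dN/dS that real samples show; without it, per-library
estimates would differ only by multinomial noise and any tiny systematic
effect would reach significance, which real nine-sample studies do not
exhibit transcriptome-wide.

## Calibrating a planted selection signal

A neutral (uniform-placement) generator cannot plant a chosen dN/dS:
with transition-biased mutation landing uniformly on sites, the expected
ratio sits *below* 1 (transitions hit synonymous third positions
efficiently). `calibrate_study()` therefore solves for the weights that
make the *expected pooled* subset dN/dS equal to the targets — 4.3 in
soldier libraries, 1.7 elsewhere, the headline contrast this design
studies. The expectation accounts for without-replacement placement via a
conditional-Poisson approximation: position inclusion probabilities
`1 − exp(−λ w)` with `λ` solved so they sum to the variant count, split
within a position proportionally to change weights; the expected class
counts then give expected `p_S`, `p_N` and the corrected ratio, and
`uniroot` finds the weight. Two one-dimensional solves yield the global
`nonsyn_weight` (background target) and the extra
`soldier_nonsyn_enrichment` (soldier target). Because the reference is
fully determined by the structural fields and the seed, the calibrated
config regenerates the identical reference.

At the default conditions the planted targets are recovered by the full
pipeline (read → filter → classify → pool → correct) with no systematic
bias beyond ≈ 1 % from the depth filter's interaction with the correction's
curvature. The dominant uncertainty is sampling: one library's subset
estimate has a standard deviation near 14 % (≈ 1,300 subset variants, of
which only ≈ 130 are synonymous — the denominator that matters), the pooled
three-soldier-library estimate near 8–9 % including the library effect.
The package's validation therefore checks pooled recovery within 15 % at a
fixed seed, alongside the qualitative battery: the subset caste ANOVA must
isolate the soldier caste (both soldier pairwise Tukey comparisons
significant, nymph–worker not), and the whole-transcriptome caste ANOVA
must stay non-significant, since the subset is only ≈ 4 % of coding sites.

## What the generator does and does not emulate

Passing tests demonstrate that the *arithmetic chain* — parsing, filtering,
canonicalization, ORF finding, NG86 counting, correction, pooling, group
tests — is correct and that a planted signal of realistic size survives the
chain. They do not certify behaviour on real data, which differs in ways
the generator deliberately omits: no read-level error or mapping/caller
artifacts (depth is a clean NB draw, independent of position and class);
uniform codon usage and i.i.d. UTR composition; variant density independent
of expression level; sites independent (no linkage, no haplotype
structure); biallelic SNVs only (no indels or MNVs, though the reader
drops them correctly); and one transcript per gene, so no isoform
collapsing. Reference mismatches and multi-mapped contexts simply do not
arise synthetically; the code paths that handle them are exercised with
hand-built fixtures instead.

## Numerical and implementation choices

- JC correction: hard error at `p ≥ 3/4` (saturation) and for `p < 0`;
  `d_S = 0` yields an undefined ratio value, not an error.
- ORF ties: longest span wins, then smallest start; scanning is
  forward-strand only, as transcripts are sense-strand by construction.
- Pooled estimates fail loudly (`degenerate-input error`) when the scope
  contains no synonymous sites at all.
- Sums over codons use exact thirds (no rounding); oracle tests compare to
  brute-force enumeration at machine precision.
- Test problem sizes: unit fixtures use 40-transcript studies with 800
  variants/library; spectrum-recovery checks use 250 transcripts with
  30,000 variants; the full recovery study uses the default conditions
  above. These sizes were chosen as the smallest that leave the checked
  quantities' sampling noise comfortably inside their tolerances.

## Known limitations

NG86 with a Jukes–Cantor correction is the simplest dN/dS estimator; it
ignores transition/transversion bias in *site* counting and codon
frequencies, and treats each variant as an independent substitution against
the reference — assumptions inherited from the analysis this package
reimplements, kept deliberately so its numbers are comparable. The
`dN/dS > 1` reading of positive selection applies to the pooled proportions
of expressed variants, not to fixed divergence between species;
interpretation beyond the computed quantities is left to the analyst.
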