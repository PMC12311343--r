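---
title: "Isoform-aware qPCR primer design: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-aware qPCR primer design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoqpcr)
```

# The problem and the model

A gene with several splicing isoforms is only quantified faithfully by
qPCR when the primer pair amplifies every isoform that is actually
expressed in the material under study, and nothing else.  `isoqpcr`
models this as four coupled sub-problems — which isoforms count as
expressed, which exon–exon junctions those isoforms share, which primer
pairs spanning those junctions are physically sound, and which of the
sound pairs are specific — and solves them per gene with deterministic,
seed-free algorithms (only the synthetic-locus generator consumes a
seed).

## Expressed-isoform call

Isoform abundances (TPM, or any non-negative unit the user chooses — the
pipeline treats them as opaque) are aggregated across samples by the
arithmetic mean (`aggregate = "median"` is available).  Within each gene
the cutoff is the interpolated quantile of the gene's own isoform
abundances at the user percentile `p` (default 75): index
`h = p/100 * (n-1)` between order statistics, i.e. R's type-7 default,
chosen so results are bit-reproducible and match the common statistical
convention.  An isoform is expressed iff its abundance is **strictly**
greater than the cutoff, so `p = 75` keeps the top 25 % of distinctly
expressed isoforms.

Two degenerate cases need explicit policy:

* all abundances zero — the gene is *not expressed*; it is skipped with a
  warning rather than designed for;
* the strict comparison leaves nothing above the cutoff although the gene
  has positive expression (all isoforms tied, or a single isoform) — all
  positive-abundance isoforms are marked expressed, so every quantifiably
  expressed gene remains designable.  This fallback is reported via the
  `fallback` attribute.

Whether the quantile should be taken per gene or over the whole table is
genuinely open; per gene is the default because the decision "which of
*this gene's* isoforms matter" is intrinsically relative to the gene, and
a `quantile_scope = "global"` switch covers the alternative reading.

## Junctions and their prevalence

Transcript models come from the GTF (1-based inclusive on disk, 0-based
half-open internally; all transcript-local positions 0-based — one
convention everywhere removes the classic off-by-one risk in probe
slicing).  Transcripts with `transcript_support_level` above 3 are
excluded as design templates but remain in the in-silico PCR template
set: a poorly supported model should not anchor a design, yet a primer
that would amplify it must still be flagged.  Missing TSL (non-GENCODE
annotations, literal `"NA"`) passes the filter.

Junctions are deduplicated per gene by genomic (donor, acceptor), so the
same biological junction seen in several isoforms is one design target.
Each junction's 10-nt probe (5 nt per side) is searched as an exact
substring in every isoform of the gene; the count of isoforms containing
it (presence/absence, one count per isoform) is its prevalence, and
junctions are processed in prevalence order with deterministic
tie-breaks (donor coordinate, then probe).  A junction closer than 5 nt
to a transcript end has no probe and is skipped by the ranking; such
junctions are a corner case of truncated annotations rather than real
design targets.  Probes are searched only within the gene's own isoforms;
cross-gene specificity is the in-silico PCR stage's job.

## Primer physics

* **Tm** — unified nearest-neighbor model: dinucleotide ΔH/ΔS table
  (Allawi–SantaLucia parameters), per-terminus initiation terms, entropy
  salt correction `0.368 (N−1) ln[Na+]`, and
  `Tm = ΔH / (ΔS + R ln C_eff) − 273.15` with `C_eff = C/4` (default
  C = 50 nM total oligo, 50 mM monovalent salt).  Palindromic oligos get
  the standard symmetry treatment (`ΔS −1.4`, `C_eff = C/2`): the plain
  `C/4` formula is thermodynamically wrong for self-complementary
  sequences, and pinning the correct variant keeps the model defensible
  for every input.  The implementation is frozen against an independent
  re-summation of the published table and against reference values from
  a second implementation, to 1e-6 °C.
* **Complementarity** — the metric is the longest contiguous ungapped
  complementary run between one primer and the reverse of the other (and
  of a primer against itself), plus the longest run anchored at either 3'
  terminus.  Runs, not alignment scores, because a short perfect 3' duplex
  is what actually primes extension.  Defaults reject a run ≥ 8 anywhere
  or ≥ 4 at a 3' end.
* **Hairpins** — exact-complement stem search (stem ≥ 4, loop ≥ 3);
  thermodynamic hairpin ΔG is deliberately out of scope: at primer length
  the exact-stem criterion is conservative and dependency-free.

## Pair enumeration and ranking

A junction-overlapping primer must keep ≥ 7 bases on its 5' side of the
junction and ≥ 4 on its 3' side — minima that rule out token 1-bp
overlaps while still letting the 3' end interrogate the junction.  The
free mate never touches the junction, so exactly one primer of every pair
spans it.  Hard constraints (length 20–25 nt, GC 30–60 %, Tm 55–75 °C,
product 100–300 bp, homopolymer ≤ 4, complementarity, hairpin, pair
ΔTm ≤ 5 °C) are absolute; among surviving combinations the ranking
objective is

```
penalty = Σ_primers [ 1.0·|Tm−60| + 0.5·|len−22| + 0.2·|GC−50| ] + 1.0·|Tm_fwd−Tm_rev|
```

with deterministic tie-breaks (fwd start, rev start, fwd sequence), top 5
returned per junction and template.  The weights and optima are exposed in
`design_constraints()`; they encode the usual qPCR preference ordering —
Tm accuracy first, then length, then GC — and the top-1 result is tested
against exhaustive enumeration on small templates.  Pair-level
complementarity is evaluated lazily in penalty order, which changes
nothing observable (the emitted set and order are identical to full
evaluation) but keeps single-isoform free design affordable.

## In-silico PCR

Annealing sites are pure Hamming matches (no indels) of a primer against
both strands at every offset, with `floor(len · pct/100)` mismatches
allowed (default `pct = 20`, so 4 mismatches for a 20-mer).  IUPAC codes
in a primer match their base sets; an `N` (or any ambiguity) in the
template matches nothing — the conservative reading for a specificity
screen.  No 3'-anchoring is required by default (`anchor_3p` adds one for
stricter realism).  Amplicons are all (plus-site of one oligo, minus-site
of the other) combinations with non-overlapping 3' ends in the correct
orientation and a product at most `max_amplicon` (default 3500 bp); both
oligos are tried in both roles, and single-oligo amplification
(both sites from the same primer) is not counted — it is vanishingly rare
in qPCR-sized products and would double-report palindromic near-matches.
The scanner is verified against a naive per-position oracle on every
fixture.

The same machinery runs the genomic cross-check of the *selected* pairs;
one tab-separated line per predicted genomic amplicon goes to
`genomic_mismatch.txt`, which is empty when junction spanning does its
job.  Note the geometry: a junction-spanning primer tolerates
`floor(len/5)` mismatches, so if its 3' overhang into the neighboring
exon is at its 4-nt minimum, the corresponding genomic locus (exon +
intron) can still anneal it; whether a genomic product is then *reported*
depends on the spanned intron exceeding the 3500-bp cap.  With the
generator's default intron range (500–5000 nt) this is not guaranteed in
principle; on the canonical seed-42 fixture the report is empty, and the
acceptance suite asserts exactly that observable.

## Scoring and selection

```
score = coverage% + 10 · (# amplified expressed isoforms) + length_component
length_component = max(0, 10 − |median(product lengths) − 200| / 10)
```

`coverage%` is the expressed abundance the pair amplifies over the total
expressed abundance of the gene — a pair amplifying a gene's only
expressed isoform scores coverage 100 by construction.  Amplifying the
gene's own *non-expressed* isoforms is not penalized (the product is
still the right gene) but adds nothing.  The length term is a symmetric
tent peaking at 200 bp and reaching zero 100 bp away — the simplest shape
with the right optimum, documented rather than hidden.  Selection: a pair
covering all expressed isoforms alone wins (mode `shared_junction`, or
`single_isoform` for one-isoform genes, which are designed without the
junction rule); otherwise pairs are added greedily in score order as long
as each contributes an uncovered expressed isoform (mode
`multi_pair_cover`), and leftovers are reported.  Because the score pays
+10 per amplified expressed isoform, a pair covering a superset always
outscores one covering a proper subset, which in practice keeps the
greedy cover within one pair of the exhaustive minimum (property-tested);
an optimal set cover would buy little and cost an ILP dependency.

# The synthetic world

`make_locus()` builds loci whose genome, GTF, transcriptome and
quantification table are mutually consistent by construction: uniform
base composition, exons 80–300 nt, introns 500–5000 nt, 200-nt chromosome
padding, three samples whose mean reproduces the declared TPM profile
exactly, default profile `100·0.6^(k−1)` (a realistic dominant-isoform
skew), TSL 1 unless specified, seed 42 by default.  Isoform structures
are deterministic: with a shared junction every isoform contains master
exons 1–2 consecutively; without one, isoform *k* is the chain
{*k*, *k*+1}, so no junction recurs.  `corrupt()` plants defects with
known ground truth (a verbatim decoy transcript, a zeroed expression
table, counted substitutions in a primer-site window).

What a green test on this world establishes: coordinate arithmetic,
junction logic, the scanner, the filters and the selection policy are
exact, and the pipeline is byte-deterministic end to end.  What it does
not establish: behavior on real annotation quirks (overlapping genes,
pseudo-autosomal duplicates, soft-masked or N-heavy sequence), realistic
splice-site motifs or GC structure, and wet-lab amplification efficiency
— primer quality beyond the modeled constraints is not claimed.

# Limitations

* No probe (hydrolysis) design, no multiplex pooling across genes, no SNP
  masking, no gapped in-silico alignment.
* Hairpin and dimer screens are run-length heuristics, not ΔG models.
* Quantification is an input contract; no pseudo-alignment is performed.
* Reliance on annotation is inherent: an unannotated junction cannot be
  designed against.
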