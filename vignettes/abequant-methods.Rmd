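---
title: "Quantifying adenine base-editing outcomes with abequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adenine base-editing outcomes with abequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abequant)
```

## The measurement problem

Adenine base editors (ABEs) convert A•T pairs to G•C within an editing
window of the 20-nt protospacer bound by the Cas9 nickase. Whether an
editing experiment produced a usable allele depends not on the bulk A-to-G
rate but on read-level co-occurrence: a read that carries the intended
substitution *and* a bystander edit encodes a different protein than a
"perfect" read. abequant quantifies targeted amplicon sequencing of edited
samples at both levels:

* **position level** — per-adenine A-to-G percentages across the
  protospacer and flanks, cumulative spacer editing, the window-overlap
  indel rate, and a positional precision metric (second-highest adenine
  frequency over the highest; lower = more concentrated editing);
* **read level** — a five-way allele classification within a fixed
  quantification window (wild-type, desired-only, desired + bystander,
  bystander-only, indel), from which the editing metrics, product purity
  and a founder triage call are derived.

Typical users are groups generating point-mutation animal or cell models
who need to rank editors, guides and founders by the fraction of clean
alleles rather than by raw activity.

## Coordinate conventions and the two windows

All analysis happens on the **protospacer strand**. If a locus
configuration places the spacer on the antisense strand of the supplied
reference, the reference is reverse-complemented once at load
(`ampliconLocus()`), so every downstream count lives in a single frame.
Protospacer positions are numbered 1..20 (5'→3', position 20
PAM-proximal); PAM and downstream bases continue 21, 22, …; upstream flank
positions are −1, −2, … with no position 0. Internally coordinates are
0-based half-open; every report is 1-based protospacer numbering (A5, A6,
A−2).

Two distinct intervals are used, mirroring the two analysis modes of
amplicon base-editing quantification:

* the **position profile** covers the spacer plus flanks (by default the
  same span as the quantification window), and feeds the per-adenine
  frequency tables;
* the **quantification window** — `windowSpec()` with defaults 7 nt
  upstream of the spacer to 3 nt past the 3-nt PAM (33 nt total) — defines
  the allele: substitutions and indels outside it are ignored for
  classification.

## Alignment

Reads are aligned semi-globally (`alignReads()`): global in the read, free
end gaps in the reference, affine gap penalties with a gap of length L
scoring `gapOpen + L*gapExtend`. The backend is
`Biostrings::pairwiseAlignment(type = "global-local")` with a custom
A/C/G/T/N matrix in which N scores 0 against everything; N calls are
likewise excluded from substitution sets and per-position tallies —
N is absence of evidence, not evidence of an edit. Defaults
(match +2, mismatch −4, gap open −10, gap extend −1) make one substitution
cheaper than two short gaps, the usual regime for amplicon resequencing;
all four are configurable. The optimum is deterministic; where several
placements of the same gap are score-equivalent (e.g. a deletion flanked
by a repeated base) the backend's fixed internal tie-break is used, so
outputs are bit-reproducible even though the particular placement is a
convention. Identical read sequences are aligned once and the result is
reused, which makes deduplicated simulated data cheap. Both orientations
are tried per read; ties go to forward.

Each aligned read is reduced to its reference-frame calls: one symbol in
{A, C, G, T, N, −} per covered reference position (deletions as `-`), plus
a list of insertions anchored at the reference gap position after which
they occur. Insertions therefore never shift the reference frame.

## Position-level statistics

`buildProfile()` tallies all six symbols at every profiled position over
**all** aligned reads covering it; the six counts always sum to the depth.
A-to-G frequency at a reference adenine is `100 * G / depth`, where depth
includes N and gap calls — deletion of an adenine is evidence against
editing at that molecule, not missing data, so it stays in the
denominator; a zero-depth position is reported `NA`, never 0, so absence
of coverage is never mistaken for absence of editing. Cumulative editing
sums the per-adenine percentages over spacer positions 1..20 only and may
exceed 100 when several adenines are co-edited. The same profile machinery
reports C-to-T and A-to-C percentages; no dedicated statistics are
computed for them beyond the per-position table.

Indel frequency is the percentage of aligned reads with at least one
insertion or deletion overlapping the quantification window under
closed-interval overlap; an insertion sitting exactly at either window
boundary counts as overlapping (the conservative choice).

## Read-level classification and the editing metrics

Within the quantification window each read is classified in strict order:

1. `short_read` — the aligned span does not cover the full window (such
   reads are excluded from the metric denominators, because the classes
   are defined over the whole window);
2. `indel` — any window-overlapping insertion or deletion, *even when the
   read also carries the desired edit*: indel alleles are unusable
   regardless of their substitutions, so they count toward the indel
   metric only;
3. `wt` — no in-window substitution;
4. `desired_only` — the substitution set equals the desired-edit set;
5. `desired_bystander` — it strictly contains the desired set;
6. `bystander_only` — anything else, including a *partial* desired set: at
   a two-adenine target, editing only one adenine encodes a different
   amino acid substitution than intended and must not count as desired.

Classification is by substitution-set comparison, not by competitive
alignment of the read against an expected-edit amplicon. Set logic is
exact and order-independent, and it makes the metric identities below hold
exactly; the cost is that numeric parity with alignment-competition tools
is approximate rather than exact.

With `Reads_aligned_all_amplicons` = window-covering aligned reads,
`Reads_aligned` = desired-only + desired+bystander, `Unmodified` =
desired-only, `Modified` = desired+bystander and `Discarded` = indel
reads, the metrics are

* specified mutation incl. bystanders (%) = `Reads_aligned / Reads_aligned_all_amplicons × 100`
* specified mutation without bystanders (%) = `Unmodified / Reads_aligned_all_amplicons × 100`
* purity (%) = `Unmodified / Reads_aligned × 100`
* indels (%) = `Discarded / Reads_aligned_all_amplicons × 100`

so purity ≡ 100 × (metric 2)/(metric 1) whenever metric 1 > 0, and purity
is `NA` when no read carries the full desired set (0 and 100 would both
be lies). Percentages are written to reports at 0.1–0.0001 precision but
tested at full precision.

A founder is `high_confidence` when desired-only reads are ≥ 20% and
unwanted outcomes (desired+bystander + bystander-only + indel) are ≤ 2.5%
of window-covering reads. The unwanted comparator is inclusive by default
with a `strictUnwanted` switch, since both conventions appear in practice
and the difference is negligible for continuous percentages.

## Guide design helper

`enumerateSpacers()` searches both strands of a coding context for 20-nt
frames that place every adenine required for a target amino-acid change at
protospacer positions 3–11 (the design window used with PAM-relaxed
editors; configurable). A change is reachable only through A-to-G on one
strand — T-to-C on the coding strand is A-to-G on the antisense
protospacer — otherwise a design error is raised. Only minimal edit sets
are kept (never demand an extra edit whose omission already yields the
target residue). PAMs are classed NGG / NRN / NYN from bases 2–3 alone.
Candidates are sorted by proximity of the target adenines to peak
positions 5–6, then by fewest window adenines; this ranking is a
documented convention of this package, not an external standard. Codon
consequences are translated with the standard genetic code, multi-adenine
codons jointly; a 5' G for expression constructs is an export detail and
never shifts protospacer numbering. Off-target candidate sites are
supplied by the user (e.g. exported from a prediction tool) and only
annotated — mismatch count, lowercased mismatch display, PAM class —
genome-wide search is out of scope.

## The read simulator

The simulator exists so that every pipeline stage is testable without
external downloads, and so that statistical claims (binomial recovery,
purity convergence, window contrasts) can be checked against known ground
truth. An `EditorModel` is generative: a molecule engages with probability
`engageProb`; given engagement each active-window adenine converts to G
independently with its profile probability `w_i`, an unconverted active
adenine becomes C with `atocProb`, an active-window cytosine becomes T
with `ctotProb`, and an indel (length −3..+3, uniform position in the
quantification window) occurs with `indelProb`. Two presets are built in:

| preset | active positions | peak | shape |
|---|---|---|---|
| `abe9_like` | 4–6 | 0.80 at A5 | narrow; A5/A6 dominant, minimal A4 |
| `abe8e_like` | 2–14 | 0.80 at A5 | broad; decaying shoulders out to A13–14 |

The shapes emulate the reported contrast between a narrow-window editor
(positions ~5–6 with slight A4 activity) and a broad-window editor
(positions ~3–10 with shoulders to A13). Peak activity is deliberately
matched at 0.80 so that preset comparisons isolate window *shape*;
engagement 0.5 puts population-level peak editing around 40%, in the range
reported for cultured-cell experiments. Per-preset C-to-T, A-to-C and
indel rates (0.002/0.001/0.003 narrow; 0.010/0.002/0.010 broad) keep those
event classes rare but exercised. Per-position conversions are
conditionally independent given engagement — the simplest generative model
consistent with per-position frequency tables. Real editors are partially
processive, so real bystander co-occurrence can exceed the independence
prediction; passing recovery tests therefore validates the pipeline's
arithmetic, not any claim about co-editing structure in real data.

Mosaic founders are modelled as K lineages (default 4) with
Dirichlet(α = 1) weights, each lineage carrying one allele drawn once from
the editor; reads sample lineages by weight (`simulateFounder()` +
`simulateReads()`). This mixture is a simulator convention — the mosaicism
of real founders is unknown — and exists to stress founder triage.
`simulateEditedReads()` instead draws every molecule independently, which
is the right generator for binomial parameter-recovery checks. Sequencing
noise adds independent per-base substitutions (default 0.001) and Phred
scores ~ N(33, 3) clamped to 2..40, keeping a Q30 mean-quality filter
meaningful. Off-target panels scale engagement by `attenuation(m)` with
mismatch count `m`, default `4^-m` — again a labelled convention, not an
empirical law; the function must be 1 at m = 0 and non-increasing.

`expectedPurity()` is the closed-form companion of the purity metric
under the independence assumption: the probability that a desired-carrying,
indel-free molecule has no bystander,
`prod((1 - w_b)(1 - atocProb))` over non-desired active adenines times
`prod(1 - ctotProb)` over active cytosines, × 100.

## Numerical and testing choices

* Determinism: every stochastic function takes a `seed`; fixed seeds give
  byte-identical FASTQ and report files.
* Zero denominators: purity and zero-depth frequencies are `NA`; an empty
  read set yields an all-zero profile, not an error.
* Degenerate inputs: empty reads, non-DNA characters, desired edits on
  non-adenines, and mis-stated strands are rejected with errors naming the
  problem; unassignable pooled reads go to an explicit `unassigned` bin
  (demultiplex defaults: best score ≥ 0.6 of the self-alignment maximum
  and ≥ 1 above the runner-up) rather than being guessed.
* Check sizes: the shipped checks use 10,000 reads for parameter recovery,
  5,000 per editor for the window contrast, 2,000 for founder triage, and
  500 random short pairs against an exhaustive Gotoh dynamic program —
  sizes at which the 3-standard-error bounds are tight enough to be
  meaningful while the whole suite stays fast. Recovery and contrast runs
  use error-free base calls so that the binomial bound applies to the
  editor model alone; the sequencing-error model is exercised separately
  (it adds a small, known inflation to every position).

## Limitations

* No long-range haplotype phasing: co-occurrence is only observed within
  the sequenced amplicon.
* No zygosity or mosaicism deconvolution from biopsy allele fractions; the
  triage rule is an operational screen, not a genotype estimate.
* Numeric parity with alignment-competition quantifiers is approximate by
  design (set-logic classification; different aligner parameters).
* The simulator does not model deaminase kinetics, processivity,
  nick-repair outcomes, or Cas-independent deamination; its R-loop-style
  amplicons are just additional loci to the quantifier.
* Adapter trimming and index-based demultiplexing are assumed to have
  happened upstream.
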