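---
title: "Assessing splice-site support from multi-genome conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing splice-site support from multi-genome conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Annotated splice sites fall into two populations: sites under purifying
selection, whose canonical dinucleotides (GT..AG, with minor GC-AG and AT-AC
classes) stay intact across hundreds of related species, and sites that
evolve like neutral sequence — candidates for annotation noise or
non-functional transcription. `splicecons` quantifies where each annotated
site sits between those poles using a reference-anchored whole-genome
alignment, and propagates the calls to transcripts, population variation and
expression evidence.

This vignette is the package's methods account: the model, its assumptions,
the tunable parameters, what the synthetic data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## The alignment function and its conventions

Everything downstream consumes the partial map `w(k, g_t)` built by
`load_maf()`: reference position `k` to a forward-strand position in target
genome `g_t`, or `UNALIGNED` (`NA`). Conventions that every number in the
package depends on:

* **Coordinates** are 0-based half-open internally. MAF is natively 0-based
  and is consumed as-is; GTF (1-based closed) and VCF (1-based) are
  converted at the parsing boundary, once.
* **Minus-strand MAF rows** are normalised with `pos' = srcSize - pos - 1`;
  the strand is recorded and base comparison complements the fetched target
  base, which is equivalent to comparing the aligned column characters.
* **Overlapping blocks**: MultiZ-style alignments occasionally multi-map a
  reference position. The first block encountered wins, with a warning, so
  `w` stays single-valued as its function signature requires. This is a
  package choice; upstream tools do not document theirs.
* `UNALIGNED` is `NA_integer_`, a typed sentinel that can never collide with
  position 0.

## Synteny realignment

An exon `e` unaligned in genome `g_t` but flanked (nearest on each side) by
exons aligned to one common target contig is realigned into the target
segment `u = [max A(e_a) + 1, min A(e_b) - 1]`. The placement is an infix
alignment — exon consumed in full, segment flanks free, unit costs —
computed by a small C++ dynamic program. A realignment is accepted when its
score `r'(e)` (fraction of exon positions landing in match/mismatch columns)
strictly exceeds `mean(R_t) - sd(R_t)` over the scores of originally aligned
exons in that genome.

Numerical choices:

* **Tie-break.** Among equal-cost placements the leftmost segment start is
  chosen, then the leftmost end; the traceback prefers diagonal over gap
  moves. The test suite holds an independent pure-R dynamic program to the
  same rule.
* **Standard deviation** is the population form (divide by n). The filter is
  a one-sided outlier screen, not an inference, so either convention works;
  this one is documented and fixed.
* **Baseline** `R_t` is computed once from the original alignment, not
  recomputed after each recovery — recoveries would otherwise feed back into
  their own acceptance threshold.
* **Segment cap**: segments of 100,000 bp or more are skipped
  (`segment-too-long`), the standard guard against pathological anchor
  pairs; configurable.
* **Inverted anchors** (the downstream flank mapping before the upstream
  one, as happens when the locus is inverted or anchored on the minus
  strand) make the segment INVALID and the exon is left unrecovered. The
  package therefore does not recover minus-strand-anchored loci; a known
  limitation.
* Recovered positions carry provenance `"recovered"` so conservation can be
  recomputed with or without them. The default includes them, since recovery
  precedes the conservation analysis in the intended workflow.

## Conservation features

`C(s, l, t)` is 1 iff the reference base at shift `l` from the site origin
matches its aligned target base. Conventions:

* **Shift orientation** follows the transcript: on the minus strand the
  position at shift `l` is `origin - l`. Shifts 0 and 1 are the canonical
  dinucleotide; negative shifts are exonic for donors. This makes donor and
  acceptor profiles strand-symmetric.
* **Unaligned counts as 0**, not missing: the classifier consumes counts of
  species, and a species with no aligned homolog offers no conservation
  evidence. The indicator is undefined there otherwise.
* Comparison is case-insensitive; `N` never conserves. Window positions
  falling off the contig count 0.
* The joint feature requires *both* canonical positions aligned and
  matching in a species; a half-aligned dinucleotide does not count.

`feature_vectors()` emits 61 features per site for the default window
`[-30, 31]`: the joint dinucleotide species count and one per-shift count,
with `m_used` (the number of loaded target genomes) stored alongside so
normalisations stay explicit.

## The Random annotation

The neutral baseline is a synthetic catalog of two-exon transcripts placed
uniformly inside MANE introns, at least `radius` bp away from every
annotated splice-site origin of every loaded catalog. Defaults — 100 bp
exons, a 150 bp internal intron, radius 35 bp — are package choices: the
radius must cover the feature window half-width (31) so a random site's
window never overlaps a real motif, and the exon/intron lengths only need to
keep the footprint small relative to typical introns. Exclusion zones are
half-open `[o - radius, o + radius)`. The full-scale dataset size is 180,000
transcripts; desk-scale runs use 1,000. Generated loci are *not* required to
carry GT/AG (they stand in for neutral sequence, not for decoy splice
sites); `require_gt_ag = TRUE` restricts them when a motif-matched baseline
is wanted. Placement is rejection sampling with all origins kept distinct,
deterministic under the config seed.

## Classification

Plain maximum-likelihood logistic regression (`glm.fit`, no regularisation;
the recorded `ridge = 0` keeps the config honest), fitted separately per
site kind and per model kind (full vs dinucleotide-only). The split is
seeded and stratified by class; 20% is held out and the stored evaluation
(ROC points, AUROC via pROC, F-score) comes from that split only. The
label boundary is inclusive: probability exactly 0.5 is "well". On
near-separated synthetic data the fit warns and coefficients are large;
predictions saturate but ordering — all that labelling uses — is stable.
MANE-shared sites are accepted by membership during transcript aggregation
and are never required to carry a model label.

## The synthetic world

`simulate_world()` generates the complete test bed; its defaults are the
package's study conditions, sized for a single CPU:

| parameter | default | what it emulates |
|---|---|---|
| genome | 2 Mb chr1 + 80 kb chrY | multi-gene reference; chrY exercises exclusions |
| genes | 50 (+2 chrY), 4–8 exons | multi-exon catalog with lncRNA fraction 0.3 |
| species | 25: 5 at 1–5%, 20 at 20–80% mismatch | primate-like close clade + saturated far species |
| conserved multiplier | 0.04 | splicing-motif sites mutate at 4% of the neutral rate |
| coding multiplier | 0.5 | exon bodies intermediate |
| withheld pairs | 5% of internal exon/species pairs | missing alignments for the recovery test |
| edge trims | p = 0.4, up to 8 bp | alignment raggedness; gives the score baseline σ > 0 |
| SNV planting | 0.008 / 0.02 / 0.05 per class | the conserved-vs-neutral SNP-rate contrast |
| junction coverage | NB means 50/75/75/200 by category | expression support gradient |

Substitutions are independent per species (a star phylogeny): the feature
set consumes only per-species counts, so tree-correlated substitutions would
change nothing the classifier sees at this scale. The generator therefore
does **not** emulate phylogenetic correlation, indel-rich alignments
(a deletions-only knob exists to stress the MAF walker), splicing-motif
composition, GC/isochore structure, or paralogy — passing tests show the
pipeline's bookkeeping and statistics are right, not that real alignments
are this clean. The edge trims exist because a gap-free star world would
make every baseline score exactly 1, collapsing `mean - sd` to a filter no
realignment can pass — the degenerate case is real and tested, but it is not
the regime the method is meant for.

Ground truth (site intents, withheld pairs with realized divergence, planted
variants, intended intron categories) is serialised with the world and
`truth_check()` re-reads the emitted files to verify the generator's own
contracts.

## Problem sizes and runtime

The test suite runs the default world (2 Mb, 25 species, ~500 annotated
sites, 1,000 random sites) once and shares it across test files; oracle
comparisons use 200–1,000 randomized small instances per operation. The
whole suite completes in about 3 minutes on one CPU; the acceptance script
runs in seconds.

## Known limitations

* Pairwise-independent target handling: no phylogeny, so no distinction
  between conservation from deep ancestry and from clade-specific identity;
  the species-ranking summary is the diagnostic, not a correction.
* Realignment does not attempt minus-strand-anchored or trans-contig
  placements, and realigns exons one at a time.
* RefSeq attribute spellings vary across releases; the parser implements the
  documented `gene_biotype`/`transcript_biotype` conjunction and types
  everything else `other`.
* Junction matching is exact on coordinates and strand; no fuzzy merging.
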