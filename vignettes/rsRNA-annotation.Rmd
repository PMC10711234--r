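---
title: "Annotating rRNA-derived small RNAs with rRFscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating rRNA-derived small RNAs with rRFscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rRFscan)
```

## The problem

Ribosomal RNA is the most abundant cellular RNA, and it is fragmented
into short RNAs (rsRNAs) by processes that are non-random but still
poorly understood. Detecting these 16–40 nt fragments in small-RNA
sequencing data is awkward for two reasons: rRNA repeats make reads
multi-map across the genome, and fragments of highly expressed rRNA can
be confused with reads from unrelated loci that happen to share sequence.
`rRFscan` addresses both with a *masked-reference* design and a strict
exclusivity rule, then classifies and quantifies the surviving fragments.

## The procedure and its assumptions

**Reference.** rRNA gene intervals come from an NCBI assembly feature
table (rows whose `feature` field is `rRNA`; companion `gene` rows are
ignored so each transcript is counted once). Each interval, optionally
extended by a flank, is replaced by `N` in the genome — the "artificial
genome" — while the transcript sequences are written separately, with
minus-strand genes reverse-complemented so transcript position 1 is the
5′ end in every record. The assumption is that an aligner run against
the artificial genome *plus* the transcript set can place an rRNA
fragment only on a transcript, so hits to remaining genome space are
genuine non-rRNA signal.

**Exclusivity.** A read is kept only when *all* its reported alignments
fall in rRNA space (a transcript reference, or a genomic position inside
an annotated rRNA interval ± flank). Reads mixing rRNA and non-rRNA hits
are counted as ambiguous and dropped; reads with only non-rRNA hits are
counted separately. The three classes partition the input read ids, which
the test-suite asserts as an invariant. When flanking regions are kept
unmasked, only the annotated rRNA interval (± the configured flank) is
treated as rRNA space for this test — external transcribed spacers are
deliberately not special-cased, since their annotation is inconsistent
across assemblies.

**Classification.** With transcript coordinates `[s, e]` on a transcript
of length `L`: `s == 1` gives rRF-5, `e == L` (with `s > 1`) gives
rRF-3, anything else rRF-i. The three categories are total and mutually
exclusive over the `L(L+1)/2` intervals of a transcript. Full-span
fragments (`s == 1` and `e == L`) are assigned rRF-5 by default; no
published rule covers this corner, and 5′ precedence matches the strong
5′ skew observed in real rsRNA populations. The choice is exposed as the
`full_span` parameter.

**Quantification.** Reads are grouped by
`(gene, gene_start, gene_end, sense)`. The locus representative is the
most frequent unique sequence; ties break towards the sequence with the
lower alignment difference, then lexicographically, so results are
deterministic. `count` is all reads at the locus, `Seq_count` the reads
carrying the representative. RPM is `count / library_total × 1e6`, where
`library_total` defaults to the read count of the trimmed input library
(the sample's FASTQ when available, otherwise all read ids in the SAM,
mapped or not); this is configurable because "library size" is genuinely
ambiguous between total and mapped reads.

**Confidence filtering.** A locus is confident when its difference count
is *strictly below* `max_difference` (default 4 — "fewer than four
differences") and its RPM is *at least* `min_rpm` (default 10,
inclusive). Both boundary conventions are unit-tested. When several loci
share identical genomic coordinates and strand, only the most abundant
survives, but the dropped loci's reads are added to its `count` before
the RPM threshold is applied — low-abundance co-located calls are
suppressed without losing reads. "Co-located" means identical
`(start, end, strand)`, not mere overlap; overlap-based merging would
chain across a transcript and erase genuinely distinct fragments.

**Antisense reads.** Reads antisense to their rRNA are classified with
the same positional rules on transcript coordinates and carried with
`sense = FALSE`. By default they are excluded from the reported outputs
(annotation CSV, class counts, abundance summary, figures) and retained
in the internal record table; `count_antisense: true` includes them
everywhere. Categories are defined on the transcript, so reporting
antisense fragments as "5′-anchored" by default would overstate their
biological interpretability.

## Tunable parameters

| key | default | unit | why |
|---|---|---|---|
| `min_rpm` | 10 | RPM | abundance floor for confident loci (inclusive) |
| `max_difference` | 4 | bases | mismatches+indels allowed, exclusive bound |
| `length_min`/`length_max` | 16 / 40 | nt | rsRNA size range, inclusive |
| `max_hits` | 50 | alignments | reads reported at more positions are dropped, mirroring a `-M 50` aligner setting |
| `max_mismatch_rate` | 0.05 | fraction | secondary per-length mismatch cap, exposed independently of `max_difference` |
| `flank` | 0 | nt | masking flank; also widens rRNA space |
| `top_n` | 5 | rows | abundance-summary depth per rRNA type |
| `full_span` | `rRF-5` | — | category for full-span fragments |
| `count_antisense` | `FALSE` | — | include antisense records in reports |

The two difference-related filters deserve a note: the confident-locus
rule is an absolute count (`< 4` differences) while `max_mismatch_rate`
is a rate per aligned length. They encode different stringencies and are
kept as independent knobs rather than reconciled into one.

## The synthetic data generator

`fixture_spec()` describes the reference evaluation scenario; its
defaults *are* the study conditions used by the acceptance checks: seed
42, six rRNA genes (four nuclear on alternating strands, one
mitochondrial, one plastid; 150–400 nt), 40 fragment loci with a
5′-skewed category mix (0.5/0.2/0.3), 10% antisense loci, 5,000 reads
distributed over loci by a gamma-weighted multinomial, no mismatches, no
decoys. The per-locus abundance model gives every locus well above 10
RPM at this depth, which is intended: the error-free scenario should be
recoverable at 100%.

Alignment is *simulated from truth* — each read gets a SAM record at its
known placement with `CIGAR <len>M` and `NM` equal to the injected
mismatch count — so the tests exercise the post-alignment logic rather
than re-implementing an aligner. Three consequences:

* ambiguous fixture reads get a second, genomic record whose bases do
  not literally match the genome there; the pipeline only consumes
  coordinates and tags, so this is harmless, but the SAM is not a real
  aligner output;
* no soft-clipping, spliced or indel CIGARs are generated (the parsers
  handle them; the simulator does not produce them);
* fragmentation is positionally uniform within each category — real
  rsRNA production is biased by structure and modification, which the
  generator does not emulate.

Passing tests therefore demonstrate correctness of masking, filtering,
classification, aggregation, normalization and reporting — not that the
thresholds are optimal for any particular real library.

## Numerical and degenerate-input choices

* All genomic coordinates are 1-based inclusive end-to-end (feature
  table and SAM conventions); the mask log is the single 0-based
  half-open output, because it is labelled BED.
* Masking uses `N`, merges overlapping intervals, clips flanks at
  sequence ends, conserves sequence length, and is idempotent — all
  property-tested against a per-base brute-force oracle.
* `NM` is trusted over recomputation when present; otherwise mismatches
  come from `MD` plus CIGAR indels; with neither available and `M`
  operations present the difference is declared undeterminable rather
  than guessed.
* Genomically-mapped reads hanging off a transcript end are dropped with
  a warning: categories are only defined within the transcript.
* Multimapped retained reads contribute one alignment (the first
  record) to quantification, so locus counts sum exactly to retained
  reads.
* The dot-bracket column uses Nussinov base-pair maximization (AU, GC,
  GU; hairpin loop ≥ 3) with a deterministic traceback (leftmost 5′
  partner, then smallest 3′ partner). For ≤ 40 nt inputs the O(n³) DP is
  instant; a `fold_fun` hook accepts an external thermodynamic folder.
  Pair-count optimality is tested against exhaustive structure
  enumeration up to length 12.
* Empty inputs flow through: header-only SAM, zero-record reports and
  empty figures (skipped with a warning) are all defined behaviour.
* Stage freshness uses content digests of inputs plus a parameter hash,
  with the reference stage's identity folded into downstream stage
  parameters, so editing the genome re-runs the entire chain even if an
  intermediate file is coincidentally unchanged; timestamps are ignored,
  so copied workspaces stay fresh. Outputs are written to a temp file
  and renamed, so a failed stage leaves no partial result.

## Problem sizes used in the tests

Unit tests run on a reduced scenario (600 reads, 12 loci, 120–250 nt
genes) chosen to keep the default suite fast while leaving every code
path exercised; the end-to-end, exclusivity and noise checks use the
full 5,000-read defaults. The masking oracle runs 200 random instances
at ≤ 1 kb; the RPM identity 1,000 random pairs; the folding oracle ~64
sequences up to length 12.

## Known limitations

* RPM normalizes within a library only; comparisons across runs need an
  external normalization strategy.
* The classifier is reference-dependent: a fragment's category changes
  if the annotated transcript boundaries change.
* Heavily modified rsRNAs can be under-represented in real libraries for
  chemistry reasons the pipeline cannot see.
* The modification-overlap stage reports positional containment of
  user-supplied sites; it does not infer modifications.
* Degradation products and biologically produced fragments are not
  distinguished.
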