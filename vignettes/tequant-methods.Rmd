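---
title: "TEquant: methods, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TEquant: methods, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEquant)
```

## The quantification model

TEquant estimates transposable-element (TE) expression per **consensus
sequence** — one representative per family — rather than per genomic
locus. The central difficulty it addresses is not multi-mapping per se but
*exonization*: TE-derived fragments embedded in mature coding and
non-coding transcripts are transcribed passively with their host gene, and
a naive counter attributes those reads to the TE.

The model is a filter, not a statistical reassignment:

1. Build a joint reference: TE consensus sequences + spliced coding
   transcripts + spliced non-coding transcripts (+ an optional mask
   library). Categories travel in a sidecar table; the FASTA itself is
   category-free.
2. Align each fragment (read, or read pair scored as the sum of its mates)
   against every reference sequence and keep all placements at or above
   the score threshold.
3. Form the **best-scoring set** — every placement achieving the maximum
   score for that fragment.
4. Classify: best set all-TE → `TE_SPECIFIC` (counted); best set mixing TE
   and non-TE → `DISCARDED_AMBIGUOUS`; best set all non-TE → `NON_TE`;
   empty → `UNMAPPED`. Mask sequences count as non-TE here: a read
   best-explained by a retained intron must not be credited to a TE.
5. Count TE-specific fragments per consensus; report the totals partition
   `fragments_total = unmapped + non_te + discarded_ambiguous +
   te_specific`.

No expectation–maximization is performed, by design: reassigning ambiguous
mass would reintroduce exactly the false positives the filter exists to
remove. The deliberate trade-off is sensitivity: a read identical between
an autonomously expressed TE and an embedded copy is unresolvable and is
discarded, producing false negatives for heavily exonized families (human
Alu being the canonical case).

## The built-in aligner

The bundled aligner is intentionally simple — ungapped seed-and-extend
over an exact k-mer index of the reference (forward strand; the read and
its reverse complement are both queried). Scoring is match +1, mismatch
−1; `N` on either side never matches. Only full-length placements are
considered, which is appropriate because the reference holds transcript
and consensus sequences: reads are contiguous on them by construction, so
no gapped or spliced alignment is needed. Production users should align
with a real aligner against the FASTA written by `write_reference()` and
feed the SAM back via `quantify(..., sam=)`; only reference names, flags,
`POS` and the `AS:i:` score tag are consumed, so any aligner emitting a
total alignment score works. No duplicate marking is performed on either
path.

Parameters (`align_params()`):

- `min_score_frac` (default 0.9): a placement must score at least
  0.9 × read length. For 50 bp reads this admits at most 2 mismatches.
  It stands in for the mapping-quality filtering an external aligner would
  apply.
- `seed_len` (default 16): maximum seed length. The seed actually used is
  adapted downward for short reads: a placement above threshold on a read
  of length $L$ has at most $m = \lfloor L(1-f)/2 \rfloor$ mismatches and
  therefore contains an exact run of at least
  $\lceil (L-m)/(m+1) \rceil$ bases (pigeonhole). Using the minimum of
  `seed_len` and that bound guarantees the placement set is **complete**
  above threshold — a fixed 16-mer seed would silently drop legitimate
  placements for reads of 30–45 bp, which the exhaustive-oracle test suite
  would catch. This adaptivity is the package's own choice; it changes
  nothing at the default 50 bp read length, where the bound is exactly 16.
- `max_insert` (default 1000): maximum outer span of a proper pair; mates
  must hit the same reference on opposite strands. A fragment with one
  placeable mate is unmapped — arbitration always operates on whole
  fragments.

Multi-TE ties (best set spanning several TE consensus sequences) default
to **fractional** weights (1/k each), preserving count mass; `first_id`
(lexicographically smallest id takes weight 1) is available when
exact-integer reproducibility matters. Strand handling defaults to
unstranded; `strand_mode = "sense"` restricts arbitration to
sense-orientation placements for stranded protocols.

## The synthetic-data generator

The generator states the world the validation runs in; its defaults are
the benchmark conditions and are not tuning knobs.

**Regime A (truth recovery).** 50 random consensus sequences of
300–6000 bp. Truth counts are drawn log-uniform on [1, 1000] (rounded)
with a 10% zero fraction, so the rank-correlation test includes
unexpressed TEs; ties get the conventional average-rank correction.
Single-end 50 bp reads at per-base substitution rate 0.001 are drawn at
uniform feasible starts on either strand, and quantified against the
consensus set plus 100 plain decoy transcripts. Under this law the library
totals roughly 7,000 reads per run (50 × mean ≈ 145 × 0.9); the
correlation is insensitive to total depth at this scale. Expected outcome:
Spearman rho ≥ 0.96 — in practice the toy aligner recovers essentially
every read (an error rate of 0.001 on 50 bp almost never produces the
3 mismatches needed to fall below threshold), so rho is typically 1.

**Regime B (exonization null).** 200 random-backbone transcripts
(1000–3000 bp, half coding / half non-coding), half of them carrying 1–3
embedded TE fragments of 80–400 bp copied from the consensus set (clamped
to the donor length when a short consensus is drawn), in either
orientation, undiverged by default. 100,000 reads are simulated from the
transcripts only, and quantified against consensus + transcripts. Because
every read originates from a transcript, the transcript placement always
scores at least as high as any TE placement: a read interior to an
undiverged fragment ties (discarded), a read spanning a fragment edge
scores strictly higher on the transcript (non-TE). Total TE count mass is
therefore **exactly zero**, and `audit_null()` lists any violation. This
holds for any `frag_divergence`: mutations in the embedded copy only move
the TE score further below the transcript score for reads generated from
the transcript.

**What the generator does not emulate:** 3′ bias, intron-retention
contamination (handled operationally by the mask library, not simulated),
indels (the error model is substitution-only, matching the ungapped
scorer), base-quality structure (constant `I`), and real repeat families
with internal sub-repeats or high inter-family similarity. A green
benchmark therefore establishes the arbitration logic and bookkeeping, not
performance on diverged biological repeats: with real Repbase-style
libraries, highly similar families would shift mass from unique assignment
to multi-TE ties and TE/transcript ambiguity.

Determinism: every generator operation re-seeds from `seed` plus a fixed
per-operation offset (consensus +0, TE reads +1, exonized transcriptome
+2, transcript reads +3), restoring the caller's RNG state afterwards.
Outputs are byte-identical across reruns of the same configuration.

## Numerical and formatting choices

- Scores are integers; "best" is exact integer equality, so tie-breaking
  needs no epsilon. The score threshold uses a 1e-9 slack against the real
  value `min_score_frac * L`.
- Fractional weights sum to exactly 1 per fragment (k equal shares);
  count-mass conservation is asserted to 1e-6 in tests.
- Counts print without a decimal point when integer-valued, with 6
  decimals otherwise.
- `spearman_rho()` is undefined (returned `NA` with a warning, never 0)
  for constant vectors or fewer than 3 TEs. P-values are not computed:
  the reporting floor usually quoted alongside such correlations is not a
  statistic worth reproducing.
- The CPM denominator excludes unmapped fragments
  (`te_specific + non_te + discarded_ambiguous`); raw counts remain the
  default output since downstream differential tools expect them.
- Duplicate sequences under different ids are kept (both are reported);
  uniqueness is enforced on ids only.

## Design decisions taken where the design was open

- **Adaptive seed length** (above): completeness of the placement set was
  judged more important than literal fixed-k seeding.
- **Fragment-length clamping** in the exonized-transcriptome builder:
  drawn fragment lengths are clamped to the donor consensus length rather
  than erroring, since the stated benchmark combines 300 bp consensus
  minima with 400 bp fragment maxima.
- **Progress logging** is a single end-of-run summary (plus the totals
  TSV): alignment is batch-vectorised in compiled code, so per-chunk
  progress lines would be fiction.
- **SAM parsing** is done directly on the text (fields 1–4, flags and the
  score tag only) to preserve record order and avoid temporary binary
  conversions; BAM users can pipe through `samtools view`.
- **Mate pairing in SAM** crosses mate-1 and mate-2 placements on a shared
  reference with opposite strands; no insert-size cap is applied there —
  the external aligner's own pairing judgement is trusted.

## Known limitations

- Consensus-level counting cannot resolve locus-specific expression.
- Heavily exonized, internally similar families (e.g. Alu) lose true
  signal to the discard rule; the filter trades sensitivity for
  specificity by construction.
- The toy aligner is ungapped and full-length only; real data with indels
  or clipped adapters should go through the SAM path.
- The mask mechanism requires the user to identify retained introns (or
  other passive sources) upstream; the package only enforces their effect
  on arbitration.
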