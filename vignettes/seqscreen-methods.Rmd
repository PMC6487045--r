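---
title: "seqscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqscreen)
```

`seqscreen` implements the bespoke computational stages of a modular
short-read DNA pipeline: read triage for alignment refinement, CIGAR-based
indel target extraction, hard filtering, a computational-subtraction
microbe screen, and truth-set benchmarking. This vignette explains the
procedures, their assumptions, the parameters that matter, and the design
choices made where the problem left the design genuinely open.

## Coordinate conventions

All internal arithmetic uses 0-based half-open intervals `[start, end)`,
the native BED convention; SAM and VCF 1-based positions are converted at
the I/O boundary and nowhere else. `H` (hard clip) and `P` (padding) CIGAR
operations consume neither query nor reference in any computation, per the
SAM specification. Records stream through each stage in a single pass; no
index is ever assumed.

## Read triage for alignment refinement

First-pass alignment with a fast spliced-alignment-capable mapper is known
to be weak around indels; the refinement step hands the reads most likely
to be misplaced — unmapped reads and reads with soft-clipped ends — to a
more sensitive aligner, and merges the refined records back.

`triage()` selects a primary, non-duplicate record when its unmapped flag
is set, or when any soft-clip run is at least `min_clip` bases.

* `min_clip` defaults to **1** (any soft clip triggers realignment): the
  most literal reading of "soft-clipped reads", exposed as a parameter for
  users who want to ignore small adapter-like clips.
* Hard-clipped reads are *not* selected: the clipped bases are absent from
  the record, so there is nothing to realign.
* Selected records are emitted with alignment fields cleared and the
  sequence reverse-complemented back to original orientation when the
  reverse flag was set, i.e. as proper input for a fresh alignment.
* Only the selected records themselves are re-extracted. Re-extracting
  their mates for paired realignment would give the second aligner more
  context at the cost of re-examining confidently placed reads; we took
  the narrower reading and note the alternative here.

`merge_refined()` errors if a (read, pair-segment) appears as a primary
record in both inputs — the two sources must partition the read set — and
sorts by (contig, position, query name), query name being the
deterministic tie-break, with unmapped records in a trailing block. The
read multiset is conserved through triage + merge; the test suite asserts
this on randomized plans.

## Indel hotspot extraction (intensive mode)

The targeting algorithm walks each read's CIGAR with a reference cursor
and records every locus where the read evidences an insertion or
deletion; bases supported by at least `min_reads` reads become targets,
expanded by `padding` and merged into a minimal BED set. Decisions taken
where the procedure is underdetermined:

* **Insertion anchor**: an insertion lives between two reference bases; we
  anchor it to the single base immediately after the insertion point,
  `[cursor, cursor + 1)`. A one-base anchor is minimal and, with padding,
  gives a caller symmetric context.
* **Deletions** contribute their full deleted span, not just a start
  point: a caller windowed on the whole span sees all the evidence.
* **`padding` defaults to 10 bases.** Local-reassembly callers need
  flanking context to assemble haplotypes across the event; 10 bp keeps
  targets tight while covering typical small-indel breakpoint ambiguity.
  It is configurable and clamped at contig boundaries.
* **`min_reads` defaults to 1** — "at least one read" — because the
  downstream caller, not the targeting step, is the arbiter of evidence.
* **Duplicate-flagged reads are excluded by default** (the downstream
  callers are duplicate-aware, so the evidence count should match what
  they will see); secondary and supplementary records are always excluded
  so each read votes once.
* **`N` (reference skip) runs are not indel evidence by default**: in DNA
  data an `N` op is a spliced-alignment artifact. `include_N` treats them
  like deletions for users who want that behaviour.

The implementation accumulates per-base evidence with run-length coverage
vectors (IRanges); a brute-force per-base pileup oracle in the test suite
checks exact equivalence on randomly generated reads, and planted-truth
fixtures check that every planted locus is recovered and nothing outside
locus ± padding is emitted.

## Hard filtering

`apply_hard_filters()` discards calls whose genotype quality or depth for
the evaluated sample falls below the thresholds; the defaults are
**GQ < 20** and **DP < 10**, read strictly, so GQ = 20 and DP = 10 pass.
Missing GQ or DP **fails by default** (`missing_fails = TRUE`): for a
diagnostic-flavoured pipeline a call that cannot demonstrate its quality
should not pass silently; the flag makes the permissive behaviour
available. Filtering evaluates the first sample unless a name is given —
the single-sample case is the normal one, and multi-sample files require
an explicit choice. `tag_hard_filters()` writes `lowGQ`/`lowDP` FILTER
tags instead of dropping records, for auditability.

Variant classes: SNVs have single-base REF and ALT; small indels have
length-discordant alleles with the longer at most **50 bp**. The class
boundary between "small indel" and "structural" leaves the 50 bp event
itself unassigned in common usage ("< 50 bp" vs "> 50 bp"); we assign it
to *small* and document that here. Symbolic alleles and equal-length
multi-base substitutions are classed `sv_like` and excluded from the
SNV/indel paths.

## Microbe screen

Computational subtraction classifies each read (per pair segment,
independently for mates) from two alignment passes:

* **human** — the primary record in the host pass is mapped;
* **microbial** — non-host, and mapped to at least one database genome in
  the second pass;
* **unknown** — neither.

The partition is asserted exact on every run
(`n_human + n_microbial + n_unknown == n_total`), and a read claimed by
both the host and database passes is an error rather than a silent
preference. Per-genome statistics follow the report triple *reads aligned,
genome length, bases covered by at least one read*:

* `read_count` counts distinct primary-aligned (read, segment) per genome;
  a read with a primary alignment on genome X and a secondary on Y counts
  once, for X. `count_secondary = TRUE` switches to the permissive
  reading in which every genome a read aligns to is credited. Which of
  the two a published per-genome total means is generally ambiguous, so
  both are exposed and the conservative one is the default.
* Breadth counts a base as covered only where an aligned read base sits on
  it: `M`/`=`/`X` segments, not `D`/`N` gaps spanned by an alignment.
* The database is any genome set the user supplies as a length table
  (2-column TSV or `.fai`); nothing reference-specific is bundled.

`top_hits()` ranks genomes by read count (ties broken by genome id) and
adds a `log10(read_count)` column for the conventional log-scale top-20
plot.

## Variant-call benchmarking

`normalize_variants()` splits multiallelic records and trims each
(REF, ALT) pair to minimal left-anchored form (shared trailing bases
first, then shared leading bases, keeping at least one base each side);
genotypes are projected onto each split allele as sorted binary pairs, so
phased and unphased spellings compare equal. `match_calls()` then matches
on exact (contig, pos, REF, ALT) — plus genotype when `genotype_match` is
on — with each truth record matched at most once. Unmatched calls are
FPs classed by the call record; unmatched truth records are FNs classed by
the truth record.

This is deliberately an **exact-allele matcher**, not a haplotype-aware
engine of the vcfeval family: haplotype-equivalent but differently-spelled
representations are not credited. For synthetic and well-normalized data
the two coincide; for complex real call sets the exact matcher is a lower
bound on TP. Re-implementing a haplotype engine is out of scope, and the
approximation is flagged here and in the function documentation.

`genotype_match` defaults to **on**, matching the usual benchmarking
default of evaluating genotypes, with the allele-only mode a flag away.
Degenerate denominators yield `NA` metrics — never 0, which would misrank
an empty call set — and the F-measure is the harmonic mean of precision
and sensitivity whenever both are defined.

## Run modes

The pipeline's three modes project onto the in-library stages as toggles:
*fast* (no triage, no hotspot targeting), *normal* (triage only),
*intensive* (triage + hotspot targeting); the microbe screen is available
in every mode. External aligner/caller execution is represented as handoff
files (unaligned SAM or FASTQ out, realigned SAM in), not subprocesses:
the bespoke computation is the selection and merge, not the alignment.
Explicit per-stage flags override the mode defaults and the resolved
configuration is logged.

## Synthetic fixtures and what passing tests show

The fixture generators are pure functions of (seed, parameters) — the RNG
state is saved and restored, identical inputs give identical bytes — and
every planted feature is listed in a manifest the tests read as their only
ground truth. Defaults emulate common short-read data shape: 150 bp reads,
uniform-base references, clip lengths of 5–30 bp, high-quality truth
genotypes.

Deliberately **not** modelled: sequencing error and base-quality
structure (no in-scope stage consumes base qualities), indel
representation ambiguity from real aligners, GC and coverage bias,
multi-mapping ambiguity beyond explicit secondary records, and diploid
haplotype structure. Passing tests therefore demonstrate algorithmic
correctness — exact oracle equivalence, conservation laws, planted-truth
recovery — not robustness to the messiness of real instrument data; on
real data the triage and hotspot stages see whatever the upstream aligner
produced, and inherit its artifacts.

Problem sizes in the test and acceptance runs were chosen to exercise the
algorithms well past their edge cases while keeping the suite quick on a
laptop: contigs of 5–100 kb, read sets of tens to hundreds, 50 planted
indel loci across three contigs, a 100-call filter fixture with a planted
63/37 split, an 80/20/20 benchmarking pair, and a 91/5/4 screen mixture
with a skewed 100/10/1 per-genome plan.

## Numerical and degenerate-input behaviour

* Interval merging is idempotent, order-insensitive and conserves the
  base-position union; abutting intervals are joined at the default
  `gap = 0` so the representation is minimal.
* Empty inputs yield empty, well-formed outputs everywhere (header-only
  SAM/VCF/TSV, zero-row region sets, all-zero screen summaries without
  division errors).
* CIGAR parsing rejects zero-length operations and unknown codes, naming
  the offending token; SEQ/CIGAR length disagreement is reported as a
  warning naming the read rather than silently accepted.
* Ties are broken deterministically throughout (query name in the merge
  sort, genome id in hit ranking), so all outputs are byte-stable for a
  fixed seed.

## Known limitations

SAM text (and the SAM-expressible subset of BAM semantics) only — no
binary BAM/CRAM codec; exact-allele benchmarking as discussed above;
gene-list region restriction requires a user-supplied annotation BED
(column 4 = symbol) rather than a bundled gene model, and the whole-exome
option is the same path with an exome BED; no annotation, taxonomy or
k-mer classification layers.
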