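---
title: "Evaluating haplotype-aware long-read error correction"
author: "eceval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating haplotype-aware long-read error correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eceval)
```

## The problem

Modern HiFi assemblers (hifiasm, Verkko, LJA, HiCanu, mdBG) all begin with
an error-correction (EC) step that edits reads to remove the residual
sequencing errors before graph construction. EC mistakes propagate into the
assembly, and because the EC tools are haplotype-aware, a particularly
damaging failure mode is rewriting a read onto the wrong parental
haplotype. `eceval` measures EC accuracy at base resolution by comparing,
for every read, the alignment of the raw read and the alignment of the
corrected read against a high-quality *truth assembly* of the same sample.

The premise is that a corrected read should align to the truth assembly
without differences; any remaining substitution or gap is an EC error.
This holds only to the extent that the assembly is much more accurate than
the reads. Assemblies built from multiple technologies with consensus
polishing typically reach Q50–Q60 versus roughly Q23 raw-read accuracy —
about a thousand-fold difference — so the great majority of read-to-contig
differences are read errors, and modest assembly imperfection inflates the
error counts only marginally. Somatic variation and true assembly errors
remain an irreducible, small bias of the approach.

## The model

Edit events (one per substituted base, one per maximal run of inserted or
deleted bases, keyed by `(contig, pos, kind, ref, alt)` in 0-based
reference coordinates) are extracted from each read's primary alignment
and compared between the raw and the corrected version of the same read:

* **CC** (correct corrections): events present in the raw alignment but
  absent from the corrected one — true positives of the EC step.
* **UC** (under-corrections): events present in both — false negatives.
* **OC** (over-corrections): events present only in the corrected
  alignment — false positives, i.e. new errors introduced by EC.

The two headline metrics are

$$\mathrm{FDR} = \frac{\mathrm{OC}}{\mathrm{CC}+\mathrm{OC}}, \qquad
  \mathrm{FNR} = \frac{\mathrm{UC}}{\mathrm{CC}+\mathrm{UC}},$$

each reported as `NA` when its denominator is zero (e.g. an identity
"corrector" yields CC = OC = 0, so FNR = 1 and FDR is undefined). Reads
whose raw and corrected alignments land on different contigs or on
disjoint intervals are *mapping-inconsistent*: their events are not
comparable, so they are excluded from the totals (and counted separately)
and handed to the mapping-difference classifier instead.

### Design choices in the comparison

Several aspects of the comparison were genuinely open and are worth
recording:

* **Event identity includes the alt allele.** A raw `A>C` "corrected"
  into `A>G` at the same site removed one error and introduced another,
  so it counts CC+1, OC+1 rather than UC+1. `matchAlt = FALSE` relaxes
  the key to `(contig, pos, kind)` for comparability studies.
* **Comparison is restricted to the overlap** of the two reference
  intervals. EC tools trim reads; a raw-read error that falls outside
  the corrected read's span was removed by trimming, not corrected, and
  counting it as CC would deflate FNR. Such events are tallied in a
  separate `trimmed_raw_events` column.
* **Indels are left-aligned** (`normalizeIndels()`) against the
  reference before comparison whenever the assembly is available,
  because the same biological indel may be reported at different
  positions of a repeat by the two alignments. Left-alignment is the
  standard VCF-style normalization: shift a gap while the flanking base
  permits, rotating inserted sequence.
* **Duplicate event keys** within one alignment can only arise from
  malformed input and are collapsed with a warning.
* **`N` handling:** events whose ref or alt contains `N` (assembly gaps)
  are flagged on parsing; `dropN = TRUE` excludes them from counting so
  gaps do not inflate UC.

## Alignment input

`readAlignments()` consumes minimap2 PAF with short-form `cs` tags
(align with `minimap2 -x map-hifi -c --cs`), or SAM with either a `cs`
tag or CIGAR+`MD`. One primary alignment is kept per read (`tp:A:P` in
PAF; secondary/supplementary flags in SAM); remaining records are skipped
and counted. `cs` tags are written in reference orientation, so strand
never affects event coordinates. A record with no way to recover
substitutions (no `cs`, no `MD`) is a hard error rather than a silently
substitution-blind parse. BAM users can pipe through `samtools view`.

## Homopolymer-compressed evaluation

Some EC tools (Verkko, LJA) emit only homopolymer-compressed (HPC)
reads: every run of identical bases collapsed to one base.
`hpcCompress()`/`hpcCompressFile()` apply the same transform to the truth
assembly and the raw reads so that alignment and evaluation run entirely
in HPC space; results are then reported in HPC coordinates. Compression
is case-insensitive (soft-masking must not split runs), `N` compresses
like any base, and FASTQ input becomes FASTA output because per-base
qualities are undefined after merging a run. Note that HPC evaluation is
not directly comparable to plain evaluation: compression removes most
indel errors in homopolymers, shrinking all three counts and changing the
denominators of FDR/FNR.

## Mapping-difference classification

For reads whose raw and corrected alignments disagree, `classifyMappingDiffs()`
assigns one of:

* `haplotype` — same chromosome, opposite parental haplotype;
* `chromosome` — different chromosome;
* `position` — same contig, disjoint intervals;
* `consistent` — same contig, overlapping intervals.

Contig names resolve to (chromosome, haplotype) labels through a
user-supplied regular expression with two capture groups
(`haplotypeMap()`); the default preset handles `<chr>_<MAT|PAT>` and
`<chr>_<hap1|hap2>` dual assemblies, and unresolvable contigs are
reported rather than guessed. Following the convention for this
analysis, a pair enters the categories only if the raw *or* the
corrected alignment has MAPQ ≥ 2 (the threshold is tunable and the
summary table re-applies it at several values; counts are necessarily
non-increasing in the threshold). Two deliberate choices: a pair that
differs in chromosome *and* haplotype label is classed `chromosome`
(the chromosome change dominates, keeping categories mutually exclusive),
and `position` requires fully disjoint intervals because EC routinely
shifts endpoints by a few bases and no principled distance cutoff exists.

## Stratification

`stratifiedSummary()` attributes each classified event to every supplied
region set (BED via `loadBed()`, or homopolymer runs derived from the
assembly itself by `annotateHomopolymers()`, default minimum run length
3 bp) whose intervals contain its reference position — for a deletion,
any deleted base; for an insertion, its anchor base. Stratification is
per event, not per read, because a long read spans many annotation
classes. Strata are deliberately *not* mutually exclusive (annotations
overlap in practice); events in no annotation form the residual `other`
stratum, so with disjoint exhaustive labels the strata partition the
global totals exactly.

## The simulator: what it emulates, and what it does not

`simulateECData()` generates a fully ground-truthed experiment: a diploid
genome (per chromosome, a `_MAT` contig and a `_PAT` contig differing by
heterozygous SNPs and short indels), reads sampled uniformly from both
haplotypes, uniform single-base sequencing errors, and a
*pseudo-corrector* that operates directly on the truth ledger — fixing
each injected error with probability `pCorrect`, introducing
`qOvercorrect` new errors per read in expectation, and with probability
`sHapswitch` replacing the read with the clean opposite-haplotype
sequence. `emitTruthAlignments()` then writes PAF records with `cs` tags
reconstructed from the ledger, so the whole pipeline can be exercised
with no aligner at all and the expected per-read CC/UC/OC are known
*exactly*.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `readLength` | 15 000 bp | typical HiFi read length |
| `coverage` | 30× | standard HiFi assembly coverage |
| `errorRate` | 0.002/bp | uniform 0.2%, matching HiFi-scale residual error |
| `errorMix` | 70/15/15 | substitution-dominated HiFi error profile |
| `hetSnpRate` | 1e-3/bp | human-like heterozygous SNP density |
| `hetIndelRate` | 2e-4/bp | human-like heterozygous indel density, lengths 1–3 |
| `pCorrect`, `qOvercorrect`, `sHapswitch` | 0.9, 0.5, 0 | a plausibly good corrector; switch off by default |

The pseudo-corrector is a bookkeeping device, not a model of any real EC
algorithm: the point is a known answer. The simulator also makes no
attempt at realistic HiFi pass-number or quality modelling, structural
variants, chimeric reads, or coverage waviness. Consequently, passing the
hermetic tests demonstrates that the *measurement machinery* is exact —
parsing, matching, accounting, classification — not that any particular
EC tool behaves well on real data, where assembly imperfections, mapping
ambiguity in repeats, and non-uniform error profiles all enter.

### Unambiguous placement mode

Indel representation is not unique: a gap inside a repeat can sit at
several positions, and an insertion/deletion pair close together can be
realigned into substitutions at equal or better alignment score. Exact
per-read ledger recovery is therefore impossible to guarantee under
unrestricted error placement. In `unambiguous = TRUE` mode the generator
places errors ≥ 5 bp apart, ≥ 5 bp from read ends, and outside
homopolymer context (a deleted base differs from both neighbours; an
inserted base differs from both flanking bases), which makes every event
its own left-aligned canonical representation. Unrestricted mode remains
the default for stress testing. Oracle-equivalence checks against global
re-alignment additionally keep opposite-sign gaps ≥ 30 bp apart, since
a nearby insertion/deletion pair legitimately realigns into cheaper
substitutions when intervening bases match by chance.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere (PAF convention); BED is
  read as 0-based half-open and converted internally.
* FDR/FNR on empty denominators are `NA`, never 0 or 1 by fiat.
* Empty alignment files yield an empty result with a warning; malformed
  cs/CIGAR/MD/BED records are hard errors naming the offending line.
* Zero paired reads is a distinct, non-zero exit status in `runEval()`.
* The evaluation itself contains no randomness: repeated runs on the
  same inputs are byte-identical.
* The simulation is fully determined by `simParams(seed=)`; the RNG
  state of the caller is saved and restored.

## Problem sizes used by the test suite

The shipped tests run the hermetic pipeline on 0.5 Mb-per-haplotype
diploid genomes at up to 20-fold coverage (~670 reads of 15 kb,
~20 000 ledgered errors per run), 200 random oracle re-alignment windows
of 100–500 bp, and 1 000 random sequences for the compression
invariants — sizes chosen so the full suite completes in about a minute
on one CPU while still exercising every code path at realistic densities.
Evaluation speed on larger inputs scales linearly in reads and events;
tens of thousands of read pairs evaluate in seconds.

## Known limitations

* Evaluation quality is bounded by the truth assembly: assembly errors
  and somatic variants are counted as EC errors for both raw and
  corrected reads (inflating UC mostly), and large mis-assemblies can
  distort mapping-difference counts.
* HPC-mode results are reported in HPC coordinates; there is no
  lift-over of reports back to original coordinates.
* Only primary alignments are compared; a read whose correct placement
  is secondary (e.g. in a near-perfect repeat) is judged by its primary.
* Long-form cs tags are not supported; re-align with short-form `--cs`.
* The mapping-difference `position` category uses disjointness, not a
  distance threshold; very large within-contig shifts and small ones are
  not distinguished.
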