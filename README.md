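# eceval — benchmarking haplotype-aware long-read error correction

Modern HiFi assemblers (hifiasm, Verkko, LJA, HiCanu) all start with an
error-correction (EC) step that edits reads before assembly. EC mistakes —
errors left in, new errors introduced, reads rewritten onto the wrong
parental haplotype — propagate into the assembly, yet EC accuracy is rarely
measured directly. `eceval` is an R package (with a command-line wrapper)
for developers and evaluators of EC tools: given a high-quality truth
assembly of the sequenced sample plus alignments of the raw and the
corrected reads against it, it quantifies EC accuracy at base resolution.

## The method

For each read, the substitutions and gaps of its raw alignment and of its
corrected alignment (extracted from minimap2 `cs` tags, or SAM CIGAR+`MD`,
and left-normalized for indel representation) are matched by the key
`(contig, pos, kind, ref, alt)` and partitioned into

- **CC** — correct corrections: errors in the raw read, gone from the
  corrected read (true positives),
- **UC** — under-corrections: errors present in both (false negatives),
- **OC** — over-corrections: new errors only in the corrected read
  (false positives),

from which the headline metrics are

    FDR = OC / (CC + OC)        FNR = UC / (CC + UC)

Reads whose raw and corrected alignments disagree in location are excluded
from the rates and classified separately into **haplotype**, **chromosome**
and **position** differences (with a MAPQ ≥ 2 filter on at least one of
the two alignments). Evaluation can run in homopolymer-compressed (HPC)
space for tools that only emit HPC reads, and per-event error rates can be
stratified by BED annotations (centromeric satellites, segmental
duplications, ...) or by homopolymer runs derived from the assembly
itself. A fully ground-truthed diploid simulator with a ledger-driven
pseudo-corrector makes the entire pipeline testable without an aligner.

## Worked example

Simulate a small diploid experiment with a known corrector (90% of
injected errors fixed, 0.5 new errors per read), emit truth alignments,
and evaluate:

```r
library(eceval)

p <- simParams(genomeLength = 1e5, readLength = 5000, coverage = 10,
               errorRate = 0.002, pCorrect = 0.9, qOvercorrect = 0.5,
               unambiguous = TRUE, seed = 42)
sim <- simulateECData(p)
res <- runEval(emitTruthAlignments(sim, "raw"),
               emitTruthAlignments(sim, "corrected"))
res$summary
#> EvaluationSummary
#>   reads counted:  200
#>   reads excluded: 0 (mapping-inconsistent)
#>   CC: 1833  UC: 182  OC: 108
#>   FNR = UC/(CC+UC) = 0.0903226 (182/2015)
#>   FDR = OC/(CC+OC) = 0.0556414 (108/1941)
```

The estimated FNR (0.090) recovers the simulated miss rate
1 − `pCorrect` = 0.10 within sampling error, and every per-read
CC/UC/OC triple matches the simulator's ledger exactly:

```r
head(perRead(res$evaluation)[, c("read_id", "contig", "cc", "uc", "oc")], 4)
#>     read_id   contig cc uc oc
#> 1 read00001 chr1_PAT  4  1  0
#> 2 read00002 chr1_PAT  8  0  0
#> 3 read00003 chr1_PAT  8  1  1
#> 4 read00004 chr1_MAT  7  0  0
```

On real data, align raw and corrected reads to the truth assembly with

    minimap2 -x map-hifi -c --cs asm.fa reads.fq > aln.paf

and pass the two PAFs to `runEval()` (or the `eval` subcommand of
`inst/scripts/eceval.R`), with `assembly =` for indel normalization,
`regionSets =` for stratification, and `hpcCompressFile()` upstream for
HPC-space evaluation.

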