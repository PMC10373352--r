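# VNTRmotifs

Motif-resolved annotation of variable-number tandem repeats (VNTRs) from
long-read assemblies and aligned reads, using per-locus **efficient motif
sets**.

## The problem

VNTRs are tandem arrays of repeat units ("motifs", typically 6 bp and
longer) that vary between haplotypes both in copy number and in motif
composition. Describing a VNTR allele as a *string of motifs* captures this
diversity far better than interval-based variant merging — but the naive
motif catalog (every distinct repeat unit observed across a reference panel)
is bloated with rare, mutation- or error-derived variants that obscure the
repeat structure. For example, `ACGGTACGGTACCGTACGT` can be written as
`[ACGGT, ACGGT, ACCGT, ACGT]`, yet `(ACGGT)₄` is more concise and diverges
from the raw sequence by only 2 edits.

`VNTRmotifs` is a toolkit for the whole workflow:

1. **Catalog** — build the original motif set Σ = {m₁, …, mₚ} of each locus
   (with occurrence counts oᵢ) from repeat-finder candidate motifs across a
   panel of haplotype sequences: candidate filtering (homopolymers,
   approximate concatenates), re-annotation, consensus, boundary trimming,
   cyclic-rotation normalization, and locus-level exclusion rules.
2. **Compress** — select an efficient subset Σ̃ ⊆ Σ by exact integer
   optimisation: minimize λ·|Σ̃| + Σᵢ oᵢ·δ_{i,a(i)} subject to a strict
   bound Σᵢ oᵢ·δ_{i,a(i)} < Δ on the total replacement cost, where
   δ_{ij} is the edit distance between motifs, every motif is assigned to
   exactly one representative a(i) ∈ Σ̃, and a representative never has a
   smaller count than the motifs it replaces. The locus-specific bound is
   Δ = Q(q) · ‖M‖ · q, with Q(q) the q-quantile of the pairwise edit
   distances over the locus's motif occurrence multiset M. The replacement
   annotation of any panel sequence then diverges from that sequence by at
   most Δ in total.
3. **Annotate** — decompose new sequences (assembled contigs, or
   haplotype-partitioned read consensus) into the motif string closest by
   edit distance, and emit VCF with per-haplotype motif-index annotations.
4. **Evaluate** — simulate loci/reads with known ground truth, measure
   annotation error, compare against a greedy frequency baseline, and
   summarize allelic diversity with motif-edit-distance allele grouping.

## Worked example

The three-motif locus with motifs `AAAG`, `AAAC`, `TGTGACCTGCAC` observed
10, 3 and 1 times:

```r
library(VNTRmotifs)
ms <- MotifSet(c("AAAG", "AAAC", "TGTGACCTGCAC"), c(10L, 3L, 1L))
ms
#> MotifSet with 3 motif(s), ||M|| = 14
#>   AAAG (o = 10)
#>   AAAC (o = 3)
#>   TGTGACCTGCAC (o = 1)

es <- selectEfficientMotifs(ms, delta = 4)
es
#> EfficientMotifSet: 2 / 3 motifs (ratio 0.67), cost 3, delta 4
#>   selected: AAAG, TGTGACCTGCAC
```

With a replacement budget of Δ = 4, the optimizer replaces the 3 copies of
`AAAC` by `AAAG` (3 edits in total, within budget) but **keeps** the rare,
dissimilar `TGTGACCTGCAC` — replacing it would cost 10 edits. A greedy
top-frequency baseline (`greedySelect(ms, 2)`) instead keeps `AAAC` and
loses the ability to represent the long motif. This is the point of the
cost-bounded formulation: rare-but-distinct motifs survive, rare variants
of common motifs are absorbed.

Decomposition of a sequence into a motif string:

```r
d <- decomposeSequence("ACGGTACGGTACCGTACGT", "ACGGT")
d
#> MotifDecomposition: 19 bp into 4 block(s), total cost 2
#>   motif string: ACGGT ACGGT ACGGT ACGGT
blocks(d)
#>   start end motif cost
#> 1     0   5     1    0
#> 2     5  10     1    0
#> 3    10  15     1    1
#> 4    15  19     1    1
```

Four occurrences of `ACGGT`, total edit cost 2 (one substitution, one
deletion) — the minimum over all tilings.

A command-line entry point covering the pipeline
(`build` / `select` / `annotate` / `simulate` / `diversity` / `evaluate`)
is installed at `inst/scripts/vntr-tools.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/vntr-tools.R", package="VNTRmotifs"))')" \
    annotate --mode contig --bam sample.bam --motif-db motifs.tsv --out sample.vcf
```

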