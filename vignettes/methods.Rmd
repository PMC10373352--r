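---
title: "Efficient motif sets for VNTR annotation: models and methods"
author: "VNTRmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient motif sets for VNTR annotation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VNTRmotifs)
```

# Overview

`VNTRmotifs` annotates variable-number tandem repeats (VNTRs) as strings of
repeat motifs. Its central object is the per-locus *efficient motif set*: a
subset of all motifs observed across a reference panel, chosen so that
replacing every motif by a representative costs strictly less than a
locus-specific edit budget. This vignette describes the models, the
parameters that matter, the numerical conventions, and what the simulation
framework does and does not establish.

# Building the original motif set

For one locus, the input is a panel of haplotype locus sequences, each with
candidate consensus motifs from a repeat finder. The pipeline
(`catalogLocus()`) runs one pass of:

1. **Candidate filtering** (`filterMotifCandidates()`): homopolymer
   candidates are dropped; a candidate longer than 1.5 times a retained
   shorter candidate is dropped when its best fitting alignment against a
   tandem concatenation of the shorter one reaches 80% identity over its
   length. Candidates are evaluated shortest-first, which makes the result
   independent of input order (a strictly shorter motif can never be
   removed because of a longer one).
2. **Re-annotation**: each haplotype sequence is decomposed into candidate
   motif blocks (`decomposeSequence()`), so the *observed* motif
   occurrences — including variant copies — become the units of counting.
3. **Consensus** (`consensusMotif()`): the medoid of all observed
   occurrences — the occurrence minimizing total edit distance to the rest,
   ties broken by higher multiplicity then lexicographic order. A
   partial-order-alignment consensus could be swapped in behind the same
   contract; the medoid is preferred here because it is deterministic and
   needs no external binary.
4. **Boundary trimming** (`trimBoundaryMotifs()`): edge occurrences shorter
   than 2/3 or longer than 4/3 of the consensus are peeled off; interior
   occurrences are never touched.
5. **Rotation normalization** (`normalizeRotation()`): every occurrence is
   rotated in-frame with the consensus (minimum edit distance over all
   cyclic rotations; ties by smallest rotation offset, then lexicographic
   order — the offset rule makes normalization idempotent).
6. **Union and counting** (`buildMotifSet()`): distinct motifs with
   occurrence counts $o_i$; the counts sum to the number of retained
   occurrences.

Whether these steps should iterate to convergence is genuinely open; the
package runs a single pass, which keeps the catalog a deterministic
function of its inputs.

**Locus exclusion** (`applyLocusFilters()`) flags loci longer than 10 kb,
with transposable-element fraction above 40% (TE fractions and
centromere/alternative-contig masks are caller-supplied — the package does
not compute repeat-element annotations), with consensus period 1 or 2
(homopolymer/dinucleotide loci), or with more than 500 motifs. The locus
"period" is taken as the consensus length after rotation normalization.

# Efficient motif selection

Given $\Sigma = \{m_1,\dots,m_p\}$ with counts $o_i$ and pairwise edit
distances $\delta_{ij}$, the efficient set $\tilde\Sigma$ and the
assignment $a(i)$ of every motif to a representative solve

$$\min\; \lambda\,|\tilde\Sigma| + \sum_i o_i\,\delta_{i,a(i)}
\quad\text{s.t.}\quad \sum_i o_i\,\delta_{i,a(i)} < \Delta,\qquad
o_{a(i)} \ge o_i .$$

The count constraint encodes the mutational reading: a rare motif may be
absorbed by an equally or more frequent one, never the reverse.

**The bound $\Delta$.** $\Delta = Q(q)\cdot\|M\|\cdot q$, where $\|M\|$ is
the total occurrence count and $Q(q)$ the lower empirical $q$-quantile (no
interpolation) of pairwise edit distances over the occurrence multiset.
$q \in [0,1]$ is the single user knob: $q=0$ means no compression. Two
quantile modes exist (`pairs` argument): the default includes
duplicate-copy pairs (distance 0), the alternative uses distinct-motif
pairs only. The default follows the multiset reading of "all pairwise
distances of motifs in M"; note that at loci dominated by one motif the
zero pairs push $Q(q)$ to zero for small $q$, so no compression occurs
there — the distinct mode compresses more aggressively. Both are exposed
because the multiset definition, taken literally, leaves the printed
three-motif worked example uncompressed at small $q$ (its zero-distance
pairs are 48 of 91); the example is reproduced with an explicit
`delta = 4`.

**$\lambda$.** The default is *set-size-dominant*:
$\lambda = 1 + \sum_i o_i \max_j \delta_{ij}$, strictly larger than any
achievable replacement cost, which makes the objective lexicographic —
smallest $|\tilde\Sigma|$ first, replacement cost as tie-breaker. This
reproduces the worked selection and removes a free parameter; a numeric
$\lambda$ can be given instead.

**Strictness and degenerate cases.** Costs are integers, so the strict
bound is implemented as a budget $B = \Delta - 1$ for integral $\Delta$,
$\lfloor\Delta\rfloor$ otherwise. $\Delta \le 0$ (in particular $q = 0$, or
$\|M\| = 1$) returns the identity plan — under a literal strict bound even
the identity would be infeasible.

**Solver.** The optimum is computed exactly by branch-and-bound over
representative subsets (C++): for a fixed subset, each motif's optimal
representative is its nearest admissible member, because the objective and
the budget both sum independently over motifs; the search over subsets is
therefore equivalent to the full 0/1 program over $x_{ij}, y_j$. Pruning
uses the admissible-representative cost lower bound and the current
selected-set size. Ties among optima are broken by the lexicographically
smallest selected-motif list, so results are reproducible across backends.
The search is exponential in $p$; loci above `maxMotifs` (default 30) are
refused — such loci should have been filtered, and this is an honest
desk-scale cap relative to constraint solvers that spend hours on
500-motif loci. `bruteForceSelect()` (subset enumeration in R, $p \le 8$)
is retained as an independent oracle; the suite checks objective equality
on random instances. `greedySelect()` implements the frequency baseline:
top-$k$ motifs by count, remaining motifs mapped to the nearest selected
motif.

**Divergence guarantee.** If motif $m$ occurs in sequence $v$ and is
replaced by $a(m)$, replacing blockwise shows
$\mathrm{ed}(\mathrm{translate}(\mathrm{repl}(v)), v) \le
\sum_{m \in v} \delta_{m,a(m)}$; summing over the panel gives total
divergence $\le$ total replacement cost $< \Delta$. The acceptance suite
verifies both inequalities on 500 simulated loci at
$q \in \{0.1, 0.2, 0.3\}$ (8 haplotypes of 50–100 motifs each), computing
sequence-level divergences with a banded bounded edit distance (band =
the per-sequence replacement cost), which is exact whenever the bound
holds.

# Decomposition

`decomposeSequence()` partitions a sequence into contiguous blocks covering
it exactly, each assigned one motif, minimizing total unit-cost edit
distance — dynamic programming over suffixes with per-block inner
alignment. Conventions:

- Pure Levenshtein costs (no match/mismatch scoring scheme): the contract
  is "closest by edit distance".
- Block lengths are searched up to twice the longest motif (`maxBlock`);
  this affects completeness only when a single block must absorb more than
  a motif length of extra sequence, and `exact = TRUE` removes the bound
  (used by the optimality tests against exhaustive enumeration).
- Ties among optimal tilings: fewest blocks, then leftmost-longest blocks,
  then lowest motif index. Any deterministic rule would do; this one makes
  outputs stable and favours the concise reading of ambiguous repeats.
- A full tiling is required — no unassigned gap blocks. Partial/prefix
  matching at sequence boundaries is handled upstream by boundary trimming
  in the catalog, not by the decomposer.

`motifStringDist()` is symbol-level Levenshtein over motif indices;
`annotationError()` divides it by the truth length.

# Annotation of samples

Locus sequences are extracted from BAM alignments by walking alignment
operations: an alignment contributes only if it fully spans the locus; the
extracted query interval runs from the first query base aligned at or past
the locus start to the first query base aligned past the locus end, so
insertions inside the locus are included (BAM stores query sequences in
reference orientation, which covers reverse-strand alignments). In read
mode, reads are partitioned by phase (HP) tags when present; otherwise a
max-cut heuristic seeds two partitions with the read pair showing the most
disagreeing heterozygous-site alleles (heterozygous sites: two alleles each
supported by at least `minAlleleFrac = 0.25` of covering reads, discovered
over the locus ± 5 kb flank — the pileup design is this package's choice)
and assigns the rest by shared alleles against the seeds, ties to
partition 1. Comparing against static seeds keeps the partition invariant
to read input order. Loci without heterozygous evidence get a single
partition and a homozygous call. Per partition, the medoid consensus is
decomposed against the locus motif list. A locus is "covered" when one
spanning sequence exists; depth is reporting-only, not a call filter.

Output is VCF 4.2 with one record per locus: motifs in `RU`,
`SVTYPE=VNTR`, `END`; distinct annotation strings become symbolic ALT
alleles indexed by each sample's `GT`, and single-sample output spells the
two haplotype annotations in `ALTANNO_H1/H2`, `LEN_H1/H2`.

# Simulation design

The generator (`simulateMotifSet()`, `simulatePanel()`,
`simulateDiploidGenome()`, `simulateReads()`) emulates the study
conditions end to end:

- **Motif sets**: a random base motif of 6–15 bp; 3–10 distinct motifs per
  locus derived from it by per-base mutation at rate 0.2 (substitution /
  deletion / single-base duplication) — mutational families with one or
  two dominant units. Sampling weights decay geometrically (ratio 0.6)
  with rank. These ranges are chosen to mirror reference catalogs in which
  loci average roughly nine motifs with strongly skewed counts, while
  staying within the exact solver's reach.
- **Sequences**: 50–100 motifs per haplotype, i.i.d. by frequency, panels
  of 8 haplotypes by default.
- **Divergence**: per-base point mutations at 0/1/2% (event uniform over
  substitution, deletion, duplication) plus optional 1% insertion events
  of 2–4 bp, applied left-to-right on original coordinates so truth
  bookkeeping stays well defined.
- **Reads**: uniformly placed reads at a target depth with a parametric
  per-base error model; profiles `"hifi-like"` (≈1.9% total error) and
  `"ont-like"` (≈11%) reflect aggregate platform accuracies only, not
  instrument noise structure. Alignments (positions and CIGARs) are
  emitted from the known haplotype-to-reference composition, so the
  annotator is tested against exactly consistent inputs; reads carry HP
  tags by default, emulating a phased run.

**Identifiability.** Each simulated motif set is constrained to be a
uniquely decodable code (`uniquelyDecodable()`, Sardinas–Patterson): when
a set contains, say, both a left-extension `Xm` and a right-extension `mX`
of a core motif `m`, two distinct motif strings spell the same DNA and no
decomposer can recover the ground truth — exact-recovery evaluation would
be ill-posed. Real motif catalogs are not guaranteed to be uniquely
decodable; this is precisely why population analyses compare annotations
by motif edit distance rather than identity, and why passing the
exact-recovery suite speaks to the pipeline's correctness, not to perfect
recoverability on arbitrary real loci.

**Divergence-setting ordering.** The evaluation orders the five divergence
settings by total per-base divergence burden:
$\{0,\ 1\%,\ 2\%,\ 1\%{+}\mathrm{ins},\ 2\%{+}\mathrm{ins}\}$. An
insertion event adds 2–4 bases, so the 1%+insertion setting carries more
sequence change per 100 bp (and, empirically in this framework, more
motif-level annotation error) than the pure 2% setting; the suite checks
monotonicity along this chain and along every pairwise comparison in which
one rate is raised with the other held fixed.

**What the simulations do not show.** Generated flanks are uniform random
DNA (no genomic repeat context), error models are i.i.d. per base, motif
sets are identifiable by construction, and panels are small. Passing tests
demonstrates algorithmic correctness under controlled conditions — not
performance on real assemblies, where orthology assignment, assembly
error, and ambiguous catalogs dominate.

# Numerical conventions and problem sizes

- Coordinates are 0-based half-open internally; BED in, VCF out (1-based).
- All edit distances are unit-cost integers; quantiles are lower empirical
  (no interpolation); solver tie-breaks are lexicographic as above.
- Objective comparisons in the solvers use an absolute tolerance of 1e-9
  (objectives are integer-valued sums scaled by $\lambda$).
- The test suites run at: 110 random instances for oracle equivalence
  ($p \le 7$); 500 loci × 3 q-values for the divergence bound; 1000 random
  sequences ≤ 40 bp for decomposer optimality; 50-locus diploid genomes
  for contig recovery and 30× read self-consistency; 200 loci × 5 settings
  for divergence-error monotonicity. These sizes make the whole suite run
  in about a minute while keeping every property statistically meaningful.

# Known limitations

- The exact selection search is exponential in the motif count; loci above
  `maxMotifs` (default 30) must be pre-filtered or solved with an external
  integer-programming backend honouring the same contract.
- The consensus is a medoid, not a partial-order alignment: for partitions
  of noisy reads it picks the most central read rather than correcting
  errors position-wise; high-error read sets benefit from more coverage.
- Catalog construction runs one pass (no re-annotation/consensus
  iteration).
- Interval-based callset merging comparisons are out of scope; the
  diversity module exposes the motif-side allele counts for external
  comparison tables.
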