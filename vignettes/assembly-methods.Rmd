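---
title: "Iterative multi-k metagenome assembly with metadbg: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative multi-k metagenome assembly with metadbg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadbg)
```

## The problem

A metagenome mixes genomes whose sequencing depths span orders of
magnitude. A de Bruijn graph assembler must choose a k-mer size: large k
spans repeats but shreds low-coverage genomes (few error-free k-length
windows survive), small k keeps shallow genomes connected but collapses
repeats. `metadbg` follows the iterative multi-k strategy: assemble at a
small k, re-ingest the resulting contigs as long error-free reads at a
larger k, and repeat. Shallow genomes are captured in the early
iterations and carried forward; deeper genomes gain repeat resolution in
the later ones. A scaffolding stage then orders and orients contigs with
paired-end evidence.

The package deliberately runs in a single process at desk scale. It
exists so that the *coassembly versus multiassembly* question — pool all
samples of a project into one assembly, or assemble each sample alone and
concatenate — can be studied end-to-end on simulated communities with
known ground truth, using the package's own simulator and evaluator.

## k-mer analysis

Reads are decomposed into canonical k-mers (the lexicographic minimum of
a window and its reverse complement; k is odd so the two always differ).
Counting is exact but Bloom-filtered: a first pass inserts every k-mer
into a Bloom filter and promotes to the exact table only k-mers already
present; the second pass counts promoted k-mers exactly. Since only
k-mers seen at least twice (plus a small fraction of Bloom false
positives) are promoted, the memory wasted on the huge population of
singleton error k-mers is bounded, while final counts for every retained
k-mer equal a naive dictionary count exactly — the false positives only
ever promote singletons, which the final `min_count` (default 2) filter
removes. The test suite asserts this equality against an independent
brute-force counter.

Alongside each k-mer the counter records, per side, how often each of the
four bases flanks it. A flanking base contributes only when its Phred
score is at least `qual_floor` (default 20, the conventional 1%-error
cutoff; the underlying quality scheme is Phred+33 only). Ties and
homopolymer flanks receive no special treatment — whatever the counts
say, stands.

## Contig generation

Traversal extends a seed k-mer in both directions. At each step the
extension must be *high quality*: its flank count must reach the adaptive
threshold

> t_hq(c) = max(floor, ceiling(alpha * c))

where `c` is the count of the k-mer being extended (`alpha` 0.1, `floor`
2). A single qualifying base extends the walk; two or more are a fork;
none is a deadend. The linear-in-coverage form is the simplest monotone
rule that lets a depth-300 genome demand strong evidence while a depth-4
genome still assembles on two concordant reads. The step is also
reciprocal: the next k-mer must name the current one as its sole
qualifying extension on the incoming side, otherwise the walk stops at
what is, from the other strand's perspective, a junction. Seeds are taken
in lexicographic order and output contigs are canonically oriented and
sorted, so the decomposition is reproducible and strand-invariant.

Refinement operates on a unitig graph whose vertices are the walked
contigs. Fork ends are linked to the contigs beginning with each
qualifying extension. Ends whose neighbor k-mer lies in the *interior* of
another contig — the signature of an error path hanging off a trunk that
walked straight through, because the error branch fell below t_hq — are
recorded as implicit attachments and treated as junctions too:

* **bubbles** (parallel branches joining the same two junctions, or an
  edge-free branch rejoining one trunk at both ends, each at most
  `bubble_len_factor * k` long, default 3k): the lower-depth branch is
  deleted and its coverage mass added to the survivor. Keeping one branch
  is a deliberate loss of strain information — the collapse of minor
  strain variants in pooled assemblies is one of the behaviors the
  package is meant to exhibit and measure, not suppress.
* **hairs** (one junction-attached end, one free end, at most
  `hair_len_factor * k` long, default 2k, shallower than the deepest
  branch at their junction): deleted.
* **fork pruning**: at each junction, links to branches below
  `prune_ratio` (default 0.1) of the deepest branch there are severed;
  iterated at most `prune_max_iters` (10) times. The comparison is
  against the junction's *maximum* branch depth — the prose notion of
  "differing from neighboring depth" needs an anchor and the maximum is
  the conservative one.

After refinement, unbranched chains are re-concatenated across their
k-1 base node overlaps with k-mer-count-weighted mean depth. Finally,
reads are recruited to contig ends by exact `seed_len`-mer anchoring
(verified ungapped with at most 2 mismatches over the whole overlap) and
each end is extended one base at a time while at least two reads with
Phred >= `qual_floor` agree and no competing base has two votes. This
local consensus escapes global-graph forks caused by unrelated genomes
sharing a k-mer, because only reads actually anchored to this contig
vote.

Pieces shorter than `min_contig_len` (default 200 bp) are dropped when
the final contig set is emitted — at typical error rates these are almost
exclusively isolated error islands whose flanking k-mers were singletons
— but never between iterations, where they can still seed recovery.

## The iteration

`contigs_to_kmers()` re-expresses each contig as its (k+s)-mers with
count `max(min_count, round(depth))` and the single extension implied by
the contig's own sequence, at maximal quality. Carrying depth forward
(rather than counting each contig once) preserves the meaning of the
adaptive threshold across iterations. Contig-derived and read-derived
evidence for the same k-mer are merged additively; the alternative
(letting contigs override reads) would make later iterations blind to
read evidence against an early mis-join. The default schedule is
k = 21, 33, 55 — odd values spanning common short-read practice; the
packed-integer k-mer engine accepts any odd k in 15..63.

## Scaffolding

Reads are aligned to contigs by seed-and-extend (exact `seed_len`-mer
seeds, ungapped extension, at most 2 mismatches); a read may receive two
alignments on essentially disjoint read intervals so that one read can
bridge two contigs. Edges between oriented contig ends come from
**splints** (a single read overlapping both contigs; the gap is the
distance between the projected contig ends on the read, possibly
negative) and **spans** (mates on different contigs; the gap is
`insert_mu - tail_a - tail_b`, each tail being the distance from the
mate's projected fragment end to its contig's linking end). Evidence is
pooled per end pair — splints and spans are not weighted differently, an
open choice the data gave no reason to complicate — with support counts,
mean gap and gap SD. Edges need `min_edge_support` (default 2) distinct
reads or pairs. A span pair is discarded when its tails alone exceed
`insert_mu + 3 insert_sigma`: even a zero gap could not reconcile it with
the insert distribution. (The library model, Normal(270, 30) by default,
is also the simulator's.)

Traversal seeds walks from the longest contig down, because long contigs
have the most trustworthy depth. At a fork, a bounded depth-first search
(at most `fork_search_depth` = 5 edges) looks down each candidate branch
for a vertex whose depth is within a factor `depth_similarity_ratio`
(default 2.0) of the running length-weighted walk depth; a candidate that
alone reaches one wins — this is what lets a depth-10 walk cross a
depth-100 repeat contig and come out on the unique depth-10 continuation.
Failing that, an edge with twice every rival's best alignment length,
then twice every rival's support, wins; otherwise the walk ends. Walks
are speculative: each round generates candidate paths from all remaining
seeds, accepts them longest-first (total bases, ties to the lower seed
id), discards any path sharing a vertex with an accepted one, and
re-walks orphans until every contig lies in exactly one path — a serial
equivalent of optimistic parallel traversal with conflict resolution,
and deterministic.

Gap filling walks base-by-base from the left contig into the gap using
only the junction's supporting reads and their mates (two concordant
votes per base, as in local extension), succeeding when a full
`seed_len`-mer of the right contig is reached; otherwise the estimated
gap is padded with Ns. Negative gaps attempt an exact end-overlap merge
near the estimated overlap (at least k-1 bases, or down to the estimate
itself with a floor of 10, at most one mismatch), else a single N marks
the join. The whole align-link-traverse-fill cycle runs
`scaffold_rounds` times (default 2): repeats tend to increase contiguity
at some cost in error, and rounds, `depth_similarity_ratio` and
`min_edge_support` are exactly the knobs a user should tune for that
trade-off.

## The simulator

`simulate_reads()` emulates a multi-sample injection design: a base
community drawn from a lognormal abundance profile (meanlog 1, sdlog 2 by
default), per-sample *replicate* perturbation (multiplicative lognormal
noise, `replicate_sigma` 0.3, renormalized — samples share structure but
vary in composition), and paired 150 bp reads with insert
Normal(270, 30) truncated at the read length. Errors are i.i.d.
substitutions (default rate 0.005); erroneous bases get low but not
disqualifying Phred scores (Normal(12, 4) against Normal(37, 3) for
correct bases), so the quality gate helps without trivially revealing
every error. Genomes are linear (fragments never wrap) and i.i.d. at a
requested GC content, with optional planted repeats and derived strains
(a copy at a given substitution divergence). Read headers carry
`genome=<id> pos=<start>` so every read's provenance is ground truth.

What the simulator does *not* emulate matters for interpreting green
tests: no indels, no quality-by-cycle structure, no GC coverage bias, no
real genomic repeat families, no conserved inter-species homology beyond
planted features. Passing the suite shows the algorithms behave as
designed under substitution-dominant noise and known community structure;
it does not certify performance on real libraries.

All randomness descends from one integer seed; per-sample sub-seeds are
derived arithmetically (kept below 2^31) so adding samples never
reshuffles earlier ones.

## Evaluation

Assemblies are compared to references by exact 31-mer anchors chained per
(contig, reference, strand, diagonal), split where anchors are more than
100 bp apart, with identity computed over each block and blocks under
`min_identity` (default 0.95) dropped. With substitution-only divergence
this recovers the alignments a general-purpose aligner would; an indel
simply starts a new diagonal block. *Genome fraction* is the percentage
of a reference covered by the union of blocks; the *duplication ratio* is
total aligned assembly bases over reference length, counting overlaps
multiply — so n concatenated copies of an assembly score exactly n times
the single copy, which is precisely why multiassembly inflates it.
*Chimericity* is the entropy -sum p_i ln p_i of the proportions of a
contig's assigned reads per source genome (reads go to their single
best-aligning contig; ties are discarded — the attribution rule is a
package decision, as is the natural log). A contig is chimeric when reads
from two or more genomes map to it. Multiassemblies are built by
concatenation with sample-prefixed ids; the naive deduplicator removes a
contig only when its sequence (or reverse complement) is contained in a
longer retained one, processed longest-first — containment at identity
below 1 falls back to anchor-block coverage. Half-overlapping contigs
defeat it by construction, which is the point being demonstrated.
Strain recovery is scored at diagnostic sites (positions where a derived
strain differs from its parent): a site counts only when an alignment
block covers it *with the strain's allele*, so parental sequence covering
the strain reference does not masquerade as strain recovery.

## Numerical and degenerate-input choices

Depth is the mean count of a contig's constituent k-mers, length-weighted
on merges; after each iteration it reflects read plus carried-forward
contig evidence, so absolute depths roughly double per iteration while
ratios — all the pipeline ever compares — are preserved. Gap estimates
are means over supporting evidence with sample SD. Empty inputs (no
reads, empty table, edge-free graphs, contigs shorter than k_next) return
empty results rather than errors; a truncated FASTQ names the file and
record index. All tie-breaks — seed order, bubble survivors at equal
depth, conflict resolution between equal paths — are lexicographic or by
id, never random.

## Problem sizes

The suite and the acceptance script run, by choice, at desk scale:
genomes of 10-30 kb, communities of 6 genomes across 4 samples, depths 3
to 55, one hundred scaffold junctions for gap calibration. These sizes
are where the studied contrasts (pooled-versus-per-sample recovery,
duplication inflation, strain collapse) already express themselves
clearly while a full run of the suite stays comfortably within a coffee
break on one core.

## Known limitations

Single process and in-memory throughout; no distributed counting or
graph partitioning. k is capped at 63 by the 2-bit packed representation.
Alignment is ungapped everywhere, so indel-rich data will fragment
alignments and depress identity. The evaluator's anchor aligner is not a
general aligner and should not be compared against one on diverged
references. The deduplicator is intentionally naive. Long reads are out
of scope: this is a short-read assembler.
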