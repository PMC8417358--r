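---
title: "Anchor-based short-read realignment for structural variant rescue: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based short-read realignment for structural variant rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Short reads spanning a structural variant breakpoint cannot align
full-length to a linear reference: the aligner clips them, splits them, or
places the mates discordantly, and downstream callers must reconstruct the
event from these fragmentary signatures. When a panel of known SVs is
available for the population, each known variant can instead be turned
into a short linear *anchor* — the local haplotype that carries the
variant — and the signature reads re-aligned against the anchors, where a
breakpoint-spanning read fits end-to-end. `panrescue` implements that
whole path: anchor construction, indexing, signal extraction,
seed–chain–extend realignment, pair rescoring, clustering, assembly and
genotyped calling.

Two properties make the approach robust to an imperfect panel. First, the
realignment and the consensus step tolerate divergence between the panel
allele and the donor allele (substitutions and small indels are recovered
as consensus-vs-anchor variants and folded back into the call). Second,
the pair-level rescoring keeps a pair only when the anchor explains it
*strictly better* than the original reference did, so anchors that do not
match the donor attract no evidence.

# Anchors and coordinates

A deletion anchor concatenates the upstream flank ending at the first
breakpoint with the downstream flank starting after the second; an
insertion/duplication anchor is `flank + allele + flank`, a duplication
being materialized as an insertion of the duplicated segment at its end.
The default flank of 250 bp is long enough to place reads from the
mainstream short-read platforms on either side of the junction.

Internally all coordinates are 0-based half-open; VCF and SAM output use
their native 1-based conventions. Every anchor offset lifts back to a
genome coordinate: flank offsets bijectively, allele offsets to the
breakpoint with an `inserted` flag, and coordinates downstream of the
allele additionally carry a `shifted` flag because their position on the
variant haplotype differs from the reference position by the SV length.
That dual interpretation is exactly what the pairing stage exploits when
one end is realigned and its mate keeps an original coordinate.

# Index

The SV reference is indexed by a de Bruijn graph with (k−1)-mer nodes and
k-mer edges (default k = 22, bounds 8–31 from the word-packing convention
of k-mer indexes). Unitigs — maximal non-branching edge paths — let runs
of consecutive seed hits merge into long match blocks in O(run length).
The index is an in-memory hash (R environments) holding, per distinct
k-mer, its unitig/offset and all its occurrence positions; k-mers
containing ambiguous bases are never indexed, which breaks unitigs at Ns.
Only the forward strand is indexed; reads are queried in both
orientations at seeding time.

# Seeding, chaining, extension

K-mers occurring at most `max_occ` (default 4) times in the SV reference
seed anywhere in the read; more frequent k-mers seed only at the read's
two ends, so reads lying wholly in repeat tracts still anchor. Blocks
mapping to more than 1000 positions keep 1000 drawn under the pipeline
seed. Chaining is sparse dynamic programming over blocks sorted by
reference position,

$$f(p) = \max\Big\{\max_{q < p}\{f(q) + L(p|q) - \theta(p,q)\},\; L(p)\Big\},
\qquad \theta(p,q) = 0.125\,\big|(\mathrm{ref}_p-\mathrm{ref}_q) -
(\mathrm{read}_p-\mathrm{read}_q)\big| + 3,$$

with $L(p|q)$ the part of block $p$'s read span not overlapped by block
$q$. The diagonal difference is taken in absolute value — as a signed
quantity the penalty could go negative and reward mis-ordered seeds — and
a transition is disallowed when $\theta > L(p|q)$, the standard chain-split
rule, since such a link would cost more than it gains. Ties in chain
ranking break toward the lowest anchor id, then the leftmost position, so
runs are reproducible.

The top 12 chains are extended. The chain fixes the anchor and the
diagonal band; extension is then implemented as one full-read glocal
Needleman–Wunsch (global in the read, local in an anchor window spanning
the chain, via `Biostrings::pairwiseAlignment`), rather than stitching
per-gap alignments between blocks: the output contract — a full-length,
never-clipped alignment with score, CIGAR and mismatch count — is the
same, and a single DP avoids the boundary bookkeeping of piecewise
stitching. Scoring is match +1, mismatch −4, gap open 6, gap extend 1
(BWA-MEM-like defaults; the anchor method needs *comparable* scores
between original and new alignments more than any particular scheme).

# Pair rescoring

The pair score is the sum of the two end scores plus a bonus K (default
50, about a third of a read's match score at 150 bp) when the ends pair
properly: opposite orientations, forward mate leftmost, insert size within
mean ± 1.5 sd of the insert model (robust median/MAD fit to the proper
pairs of the input alignments, with a configured fallback below 100
observations and a ±1 bp degenerate window when the spread is zero).
Original alignments enter the same maximization as candidates, with their
scores recomputed under the extension scheme so the comparison is fair;
coordinates downstream of the anchor's SV are tried both unchanged and
adjusted by the SV length.

A pair is kept only when its best combination *strictly* beats the score
of the original aligner's own pair and uses an anchor realignment for at
least one end; a tie goes to the original (recorded unmapped). This is
deliberately a pair-level comparison: a junction-spanning end typically
improves greatly while its flank-spanning mate exactly ties its original
score, and an end-level tie rule would discard nearly every informative
pair. Kept ends are written as SAM against the anchor set with the anchor
id in a `za` tag.

# Clustering

Known SVs group greedily along the genome: an SV joins a group when its
upstream breakpoint is within 50 bp of the group's downstream border.
Each group retains its two best-supported SVs (support = kept reads per
anchor, counted after pair filtering — the filtered counts reflect actual
evidence); reads of dropped members are reassigned to whichever retained
anchor shares more distinct k-mers with the read, ties resolved uniformly
under the pipeline seed. Distinct-k-mer (set) counting is used on
purpose: multiset counting would double-weight repeats, the very ambiguity
the step exists to resolve.

# Assembly and inference

Before assembly, 64 bp blocks of anchor with depth above 1.5× the mean are
trimmed by discarding lowest-score reads (name order breaks ties), and a
cluster is discarded as uncertain when over 80 % of its reads had original
MAPQ 0 *and* the median realignment gain is ≤ 5 (one mismatch's worth) —
the classic signature of reads that belong to another copy of a repeat.

The assembler is a greedy word-overlap consensus builder: the most
frequent unused 25-mer seeds a contig, which extends base-by-base by
majority vote among overlapping reads (≥ 2 agreeing reads per base,
≥ 3 reads per contig), recruiting reads whose sequence contains the
contig's terminal word. Each read's join position is recorded, and —
one design choice worth stating — a read may only join at a position
consistent with its own realignment position (± 60 bp). Without this,
tandem duplications defeat the assembler: the two copies are identical, a
read from the second copy joins at the first, and the conflicting votes
stall extension. Mapping-guided recruitment is how locus assemblers
conventionally resolve this, and the realignment positions are already in
hand. Regions of SVs longer than 500 bp are assembled per 500 bp block.
Reads then realign to the contig at their join position with mismatches
only (Hamming, ≤ 3), giving the per-base consensus depth.

Each contig aligns globally to its anchor at candidate positions derived
from its supporting reads (deduplicated within 50 bp; contigs whose
candidates all fall outside the anchor are dropped, as are contigs none of
whose reads improved on the original aligner — in the pipeline the latter
holds by construction because the pair filter already demanded strict
improvement). Consensus-vs-anchor mismatches and indels are recorded in
anchor coordinates and the consensus depth is projected alongside.

The anchor's own SV is called when both breakpoint flanks carry depth at
least `depth_min`, evaluated as the best depth within a 20 bp window —
panel breakpoints are jittered relative to the donor's, and the NW
alignment parks compensating indel pairs right at the junction, so exact
positions would show spurious zero-depth holes. Depth pools across a
cluster's contigs by summation (their read sets are disjoint), so alleles
longer than one contig are not penalized at contig boundaries. Interior
allele depth is *not* required for panel-anchored insertions — that
requirement belongs to novel insertions, whose sequence has no anchor
support; the interior of a known duplication legitimately attracts few
extractable reads because they align perfectly to the reference copy.

The reported length is the panel length adjusted by the net indel
difference observed around the allele (variants of call size are excluded
— they are separate events); this makes the call invariant to the
jitter-induced rotation, which otherwise inflates the allele by up to the
jitter amount. The allele sequence is read off a fully covering contig
when one exists, else reconstructed from the panel allele plus the pooled
variants, and reconciled to the reported length (under breakpoint
rotation, up to the jitter amount of edge content is uncertain). Indel
variants ≥ 50 bp found elsewhere in the alignment become additional calls;
everything below 50 bp is dropped (the community's SV length convention,
read as inclusive). Genotypes come from the coverage fraction
alt/(alt+ref) — ref being full-length-matched original reads spanning the
breakpoint — with ≥ 0.8 called 1/1, 0.2–0.8 called 0/1, and below 0.2
dropped as noise. Output is VCF 4.2 with explicit, left-normalized
alleles and SVTYPE/SVLEN/END/RE INFO keys; breakpoint adjustment happens
first, normalization second.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `flank` | 250 bp | anchor flank length |
| `k` | 22 | index and seed k-mer length |
| `max_occ` | 4 | seed uniqueness threshold in the SV reference |
| `top_chains` | 12 | chains extended per read |
| match/mismatch/gap | +1/−4/6+1·L | extension scoring |
| `pair_bonus` K | 50 | proper-pair bonus (score units) |
| isize window | ±1.5 sd | proper-pair insert acceptance |
| `word` | 25 bp | assembler seed/recruitment word |
| `min_support` / `min_reads` | 2 / 3 | per-base and per-contig support |
| `max_mm` | 3 | read-to-contig Hamming cap |
| `depth_min` | max(3, 0.1·mean) | breakpoint depth to call |
| `min_svlen` | 50 bp | minimum reported SV length |

The seed-k equals the index k: an exact-hash k-mer index cannot look up
seeds of a different length, so the two values are one parameter here.
`depth_min` is deliberately below a naive 0.2×-coverage rule: the depth
that matters is that of *extracted* signal reads, which for the thinnest
evidence class (heterozygous duplication junctions) runs around a sixth
of raw coverage, because reads inside a duplicated copy align perfectly
to the reference copy and are only extracted when their pair straddles a
junction.

# The simulator, and what passing tests do not show

`sim_config()`/`simulate_dataset()` generate: a random genome (i.i.d.
bases at a set GC, with tandem-repeat tracts spliced in), implanted
non-overlapping SVs (DEL/INS/DUP cycled, 60–1000 bp by default, ≥ 1 kb
apart) each assigned a genotype, two donor haplotypes, a known panel
derived from the truth by breakpoint jitter (≤ 10 bp), allele divergence
(2 % substitutions) and optional leave-out, and paired-end reads
(150 bp, insert 400 ± 50 truncated at 3 sd, 30×, 0.1 % substitution
errors — a mainstream short-read error rate, and substitution-only so the
perfect-pair rule stays crisp). The companion "original" alignments are
produced by projecting each read's known donor interval through the
implant map: full-length matches away from breakpoints, soft-clips across
them, unmapped reads inside novel insertions, discordant flags by the
3 sd insert rule, MAPQ 0 inside repeat tracts. This reproduces the
signature classes the extractor consumes, deterministically; it is a
projection of the simulation's own truth, not an aligner.

Real data differ in ways the simulator does not emulate: indel sequencing
errors, base-quality structure, PCR duplicates, reference N-gaps,
ALU-scale genome-wide repetition (the simulator's tracts are local), and
panels whose records are wrong in kind rather than in detail. Passing the
end-to-end tests therefore demonstrates the pipeline's internal
correctness and its robustness to breakpoint jitter and allele
divergence at realistic coverage — not calling performance on a human
genome.

Problem sizes used by the test suite: the acceptance simulation is one
200 kb genome with 20 SVs at 30×; module tests run on 3–50 kb fixtures;
the oracle-equivalence checks run 1000 random instances each against
exhaustive enumeration. These sizes give stable statistics for the
thresholds being asserted while keeping a full run of the suite
comfortable on one CPU.

# Numerical and degenerate-input choices

Chain and pair ties break deterministically (lowest anchor, leftmost
position; pair ties additionally prefer combinations using more anchor
ends). All randomness — block position capping, reassignment ties,
simulation — derives from one pipeline seed via fixed stream offsets, and
RNG state is always restored after use, so library calls never perturb a
caller's RNG. Zero-spread insert models degenerate to a ±1 bp window.
Empty SV panels abort with a documented error before any anchor work.
Anchors shorter than the index k are skipped from the index with a
warning; anchors shorter than a read length are flagged. Duplicate panel
records (same type, contig, position, length) collapse to the first.

# Known limitations

Inversions and translocations have no anchor construction here. Multiple
overlapping divergent panel records for the same event split read support
before clustering reconciles the top two. The allele content at rotated
breakpoints is uncertain by up to the panel jitter. MAPQ-0 filtering
deliberately sacrifices SVs inside genome-wide repeat families (the
ALU-insertion blind spot of anchor methods). Single-threaded by design;
the stages are embarrassingly parallel over anchor groups but the
reference implementation values determinism over speed.
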