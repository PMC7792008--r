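---
title: "Hybrid correction of noisy long reads with a colored de Bruijn graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid correction of noisy long reads with a colored de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphpolish)
```

## The problem

Long-read sequencing (ONT-scale) produces reads of kilobase length with
per-base error rates around 10%, mixing substitutions, insertions and
deletions. Short-read sequencing produces accurate (~0.2% error) but short
(~151 bp) paired reads from the same sample. graphpolish polishes the long
reads with the short-read data while trying hard not to *over-correct*: in a
diploid genome, the short reads carry both haplotypes, and a corrector that
picks bases from the wrong allele or from a homologous repeat destroys true
heterozygous variants or invents artificial ones. Everything in the design
below serves that goal.

## The index: a compacted, colored, SNP-annotated de Bruijn graph

Short reads are k-merized into a de Bruijn graph in which each vertex is a
*canonical* k-mer (the lexicographic minimum of the k-mer and its reverse
complement; k is odd so no k-mer is its own reverse complement). Maximal
non-branching paths are compacted into *unitigs*. k-mers seen only once in
the short reads are presumed erroneous and discarded (`min_count = 2`).

Two k-mer lengths are used, with `k2 >= 2 * k1` (defaults 31 and 63). The
long-k graph `G2` is built first; the short-k graph `G1` is derived from
`G2`'s unitig sequences, so it inherits the `G2` multiplicity filter. Short
k-mers anchor erroneous long reads well; long k-mers give contiguous unitigs
that untangle repeats. Pass 1 uses `G1`, pass 2 uses `G2`.

Three annotations ride on the graph:

* **Coverage** — the multiplicity of each k-mer.
* **Colors** — each short-read *pair* (pass 1) or each corrected long read
  (pass 2) is a color, attached to every graph k-mer position it contains.
  Colors mark which paths through the graph are spelled by real reads, which
  is what lets the traversal reject chimeric recombinations of unrelated
  unitigs. Colors are stored *per k-mer position*, not per unitig: after
  compaction a unitig can be long, and the color sets consulted during
  traversal must describe the specific k-mer being crossed, not the union
  over a whole unitig.
* **Candidate SNPs** — for every pair of graph k-mers at Hamming distance 1,
  both unitigs are annotated at the substituted base with the IUPAC code of
  the two observed bases (`R` for A/G, and so on; codes accumulate into the
  covering symbol). The enumeration tries the `3k` substitution neighbors of
  each k-mer against the index rather than comparing all pairs. A pair of
  loci that are reverse complements of the *same* k-mer is skipped: a vertex
  is not its own SNP partner.

`prune_low_color_kmers()` drops k-mers whose color sets fall below a
threshold and re-compacts; it is exposed as a simple, observable contract
(the memory-oriented engineering a production tool would add changes none of
the semantics tested here).

## Anchoring a long read

Every k-mer window of a long read is classified against the graph:

* **solid** — exact match to a unitig slice (at most one, by canonicity);
* **near-solid** — match with exactly one substitution or indel;
* **weak** — neither.

Near-solid candidates are generated explicitly: `3k` substitutions, the `k`
single-base deletions of the window (refilled with the next read base, when
the window is not at the read end), and the `4k` single-base insertions
(dropping the last window base). A window that is solid contributes no
near-solid matches, and only *unique* near-solid matches (UNSMs) — exactly
one matched locus at that read position — are kept: an ambiguous single-edit
match is exactly the signature of the wrong allele of a SNP, and anchoring
on it would steer the correction onto the wrong haplotype. When a
substitution and an indel interpretation hit two different loci, the
position is ambiguous and discarded for the same reason.

Runs of consecutive solid positions form solid regions; the stretches
between them (bounded by the flanking solid k-mers, so adjacent regions
overlap by up to k bases) are the *non-solid regions* to correct. A region
of raw length `l` is assumed to have a true length in
`[l / (1 + F), l * (1 + F)]`, where `F` is an upper bound on the read error
rate (default 0.4 — deliberately loose, so that locally error-dense
stretches do not exclude the true path; the bound only prunes, it never
chooses).

## Guided traversal

For each region the corrector extracts one path through the graph from the
source anchor to the target anchor. Two guides prune the search:

* the **color set** `C` of the region: in pass 1 the union of the color sets
  of all solid matches and UNSMs within `B` bases of the region (default
  `B = 1000` bases, chosen to span a short-read pair plus its insert gap, so
  that both mates of every local pair contribute); in pass 2 the union of
  the two per-side *intersections* over solid matches within `B` bases of
  each boundary — corrected long reads are long enough that intersecting is
  informative, and it strips colors that do not belong to the locus;
* a **color floor** `T_C = floor(D * min |C_u|)` over the window's matches
  (default `D = 0.2`): any k-mer carrying fewer than `T_C` of the guiding
  colors kills its path. This is what removes chimeric paths cheaply.

The search is greedy and staged: all simple extensions of the current path
up to `P_max` unitigs (pass 1, default 4) or until at least `B` appended
bases (pass 2, default `B = 2 * k2`) are enumerated; each survivor is scored
and only the best is extended. The score conflates color evidence and
sequence evidence:

  `s_c = |C_p ∩ C| / |C|`, `s_q = 1 − d / |path|`,
  `s_P = s_c s_q / (s_c s_q + (1 − s_c)(1 − s_q))`

where `C_p` is the union of the path's k-mer colors and `d` the infix edit
distance of the path against the region (gaps at the region ends are free,
so a partial path is compared against the prefix it explains). With empty
`C`, `s_c` is defined as 1 — absent evidence is not negative evidence.

Two numerical choices deserve a note. First, the conflation saturates: when
`s_c = 1`, `s_P = 1` for every candidate regardless of `s_q`. Ties on `s_P`
are therefore broken by `s_q` first and only then by the lexicographically
smallest sequence, keeping the search deterministic and seed-free while
preserving sequence guidance in the saturated case. Second, cycles: within
one stage a (unitig, strand) cannot be re-entered, but revisits across
stages are allowed and bounded only by the region's length budget — short
tandem repeats legitimately traverse the same unitigs several times, and the
length bound is what terminates them.

UNSMs act as waypoints: the search runs leg by leg (source → first UNSM → …
→ target), each leg bounded by `(read distance + k) * (1 + F)` bases, so
that paths not passing through the near-exact anchors are never explored.
When a leg dead-ends (a tip from incomplete short-read data, or color-floor
exhaustion), the corresponding uncorrected subsequence is inserted verbatim
as a *gap* and the search resumes at the next waypoint: the corrector would
rather keep raw bases than invent sequence. Regions without UNSMs search
source-to-target under the `[l_min, l_max]` bounds; head and tail regions
(one anchor only) walk open-endedly from their single anchor and accept any
length in the bounds. A path that connects and contains no gap is
*complete*.

## Forward/backward reconciliation and SNP restoration

A region whose forward search came back absent or incomplete is also
searched backward (from the target, on the reverse complement): color
guidance that led the forward walk into a tip often does not mislead the
reverse walk. If exactly one direction is complete it wins (both complete:
forward). Two incomplete corrections are merged by aligning each to the raw
region (Needleman–Wunsch, unit costs, deterministic diagonal-up-left
traceback) and walking both alignments over the region positions, taking
whichever side derives its aligned base from the graph rather than from a
gap element, ties to forward.

The corrected region is then aligned back to the raw one. At every
match/mismatch column whose corrected base carries an IUPAC candidate-SNP
annotation, the raw read base overwrites the corrected base *if it belongs
to the symbol's base set*. The correction therefore never writes an allele
the read itself does not support — this is the conservative heart of the
haplotype preservation. A site whose bases already agreed is *strongly
compatible*; around such a site the path choice is trusted, and annotated
bases of the same unitig inside the insertion run adjacent to the site are
additionally restored from the correspondingly offset raw bases (an
insertion run has no aligned raw column of its own, so the offset from the
anchoring site is the only coordinate available; we restrict the
neighborhood to the contiguous insertion run touching the site).

Finally the region corrections are spliced between the untouched solid
regions. Adjacent regions share anchor k-mers, so the splice drops the
already-emitted overlap from each correction; solid bases are never
modified. The corrected region replaces exactly the raw interval it was cut
from. Reads with no solid anchor at all are returned unchanged and flagged.

## The second pass

Pass 2 repeats the procedure on the pass-1 output with three changes: the
graph is `G2` (k2-mers, better contiguity), the colors are the corrected
long reads themselves (one color per read; no duplicate-read removal — the
corrected reads are not expected to be similar), and anchoring demands more:
solid regions shorter than `B > k2` bases are demoted to region interior,
because a lone solid k2-mer in an otherwise noisy stretch is weak evidence.
The search frontier is a base length rather than a unitig count so that
stage scores compare paths of comparable sequence length.

## Reference-guided binning

As an optional preprocessing, reads aligned to a reference (SAM or PAF;
alignment is an *input* — the package does not run a mapper, which keeps it
self-contained and testable) are partitioned into 5-Mbp bins by the start of
their primary alignment. Long reads that are unmapped or below MAPQ 30 go to
an ambiguous bin; short-read pairs follow either mate's primary alignment
(records with the paired FLAG bit are treated as short reads, unpaired
records as long reads — PAF, which has no FLAG, is accepted for long-read
records only). Each bin is corrected independently — bins share no state, so
the processing order cannot change the merged output — and the ambiguous bin
is corrected last against all short reads, with its pass-2 coloring assisted
by the already-corrected binned reads.

Because references have gaps and individuals carry insertions, each bin
first tries to recover unmapped short reads that belong to it: k1-mer graphs
are built from the bin's short reads and long reads (multiplicity ≥ 2); the
long-read graph is pruned by iteratively removing its lowest-mean-coverage
unitig stratum until it is at most 10% larger than the short-read graph
(recurrent long-read errors occur twice too, and sit in low-coverage
unitigs); an unmapped read whose k1-mers are mostly (> 50%) in the pruned
long-read graph but absent from the short-read graph is adopted. The 1.1
ratio and the 0.5 fraction are this package's calibration of "approximately
equal" and "many"; both are exposed as arguments.

## The synthetic diploid generator

`simulate_diploid()` draws haplotype 1 iid uniform over ACGT and derives
haplotype 2 by placing heterozygous SNPs and short indels (length
1 + Geometric(0.5), capped at 6) at exponentially spaced sites. By default
sites are kept at least 63 bases apart (one k2 window) and indels never
overlap, so every truth site is unambiguous under alignment; the guard can
be disabled. `simulate_reads()` draws reads uniformly from both haplotypes
and strands: paired 151-bp short reads with normal fragment lengths
(sd = 10% of the mean) and substitution errors only; long reads with
log-normal lengths (sd(log) = 0.25, truncated to [1 kb, 4 × mean]) and a
substitution/insertion/deletion error mix placed uniformly along the read.
Default rates (0.2% short-read, 4/3/3% long-read) mirror Illumina and
ONT-class instruments. The generator is exact about provenance: every read
records its haplotype, start, strand and truth length, and the truth set
round-trips through FASTA + VCF + TSV.

What the generator does *not* emulate: homopolymer-biased ONT errors,
chimeric reads, coverage waves, or real repeat structure (an iid genome has
only the repeats chance provides at the simulated length). Passing tests
therefore demonstrate the correction machinery under controlled conditions,
not performance on real genomes — in particular, repeat-rich regions are
easier here than in any real genome.

## Evaluation

`error_rate()` is truth-based: the edit distance between a read and its
provenance subsequence (free end gaps on the read side, so a trimmed end is
not penalized) divided by the truth length. This is a deliberate
re-specification of the alignment-based error rates reported for real data;
the two agree in spirit but not in definition, so absolute values should not
be compared across methods. `het_retention()` measures haplotype
preservation directly: over all (read, covered heterozygous site) pairs
where the corrected read aligns across the site, the fraction carrying the
read's own haplotype's allele. Random haplotype assignment would approach
0.5; the package's acceptance bar is 0.90.

## Problem sizes and determinism

The package's own end-to-end check uses a 100-kb diploid genome with SNP
rate 0.001, 40× paired 151-bp short reads at 0.2% error and 20× long reads
of 8 kb mean length at 10% error — small enough to run in minutes on one
CPU, large enough that every stage (two graphs, coloring, annotation,
anchoring, traversal, both passes) operates in its intended regime. On this
fixture the two passes together reduce the mean error rate by roughly two
orders of magnitude and keep heterozygous-allele retention above 0.94.
Unit-test fixtures use k1 = 9 and k2 = 19 on kilobase genomes; at those
sizes single-edit matches are noisy by construction (a 9-mer has many
distance-1 neighbors in a 262k space), which the tests account for — the
defaults k1 = 31, k2 = 63 do not share this regime.

All randomness flows through explicit seeds (`with_seed` restores the
caller's RNG state); graph construction iterates k-mers in sorted order, the
traversal's tie-breaks are lexicographic, and bins are merged in input
order, so repeated runs are byte-identical.

## Known limitations

* The traversal is greedy by design; a mis-scored early stage cannot be
  revisited except by the backward pass.
* Base qualities are ignored during anchoring and scoring; output FASTQ
  qualities are flat placeholders (Q20).
* `prune_low_color_kmers()` discards SNP annotations (recompute after
  pruning).
* The graph object is an in-memory reference (an external pointer); it does
  not survive `saveRDS()` — use `export_gfa()` / `import_gfa()` for
  persistence.
* Parallel execution is a contract (per-read and per-bin units are
  independent) but the implementation runs serially.
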