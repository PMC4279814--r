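---
title: "Detecting transposable-element mobilization from discordant read pairs"
author: "TEscout authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Detecting transposable-element mobilization from discordant read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a transposable element (TE) mobilizes, a genome acquires a new copy of
an existing sequence. Resequencing that genome and aligning the reads back
to the reference leaves a characteristic footprint: read pairs that span a
novel insertion junction have one mate in unique flanking sequence (the
*acceptor* side) and one mate inside the element, which can only map to the
element's pre-existing copies (the *donor* side). Those pairs are
*discordant* — their mates map too far apart, in the wrong mutual
orientation, or on different chromosomes for the sequencing library that
produced them. TEscout detects new insertions *de novo* from these
signatures alone, without requiring any TE annotation, and additionally
identifies which member of a family of near-identical copies is the actual
donor.

## Model and procedure

### Library model

For a pair mapping with mates relabelled so the first has the smaller
coordinate, the insert size is $d = l_B - l_A$. From a sample of uniquely
mapped pairs we take the median $M$ and the *unscaled* median absolute
deviation $MAD$ (no 1.4826 consistency factor — the robust window is defined
directly in MAD units), and set

$$d_{inf} = M - 3\,MAD, \qquad d_{sup} = M + 3\,MAD.$$

A pair mapping is concordant iff both mates are on one chromosome, in the
library's proper orientation — $(-,+)$ for a circularization (mate-pair)
library, $(+,-)$ for short-fragment forward–reverse — and
$d_{inf} < d < d_{sup}$ strictly. Because the proper predicate uses strict
inequalities, an insert exactly at a limit is classified discordant
(`Del`/`Ins`); this makes the classification total.

### Signature classes

Every discordant pair mapping carries exactly one signature:

| signature | chromosomes | orientation | insert |
|---|---|---|---|
| `Del` | equal | proper | $d \ge d_{sup}$ |
| `Ins` | equal | proper | $d \le d_{inf}$ |
| `Dup` | equal | reversed proper | any |
| `Inv` | equal | equal strands | any |
| `Trans` | different | any | — |

When a mate has several mappings (secondary records and alternative-hit
tags), a fragment is discordant only if **every** combination of mate
mappings is discordant; all combinations are then recorded as if they were
unique mappings from separate pairs. Multi-mapping evidence is therefore
kept, amplified by the number of candidate loci — which is what later lets
the caller enumerate all candidate donors.

### Clustering

Discordant records are partitioned by (signature kind, orientation couple,
ordered chromosome pair) and clustered by single linkage in mate-position
space: two records link when $|\Delta l_A| \le X$ **and**
$|\Delta l_B| \le Y$. The sorted-mate threshold $X$ answers coverage
fluctuation and is much smaller than $Y$, which must absorb insert-size
dispersion. The seeded linear scan is exactly the transitive closure of
that graph (a tested invariant). Same-signature clusters whose hulls come
within a merge gap (default: the current $Y$) on both axes are merged —
coverage troughs would otherwise split one breakpoint's evidence — and
clusters are then filtered: hull extent at most $d_{sup}$ on each axis
(reads around one breakpoint cannot disperse more than the insert-size
distribution allows) and at least 10 distinct supporting fragments for a
long-fragment library.

### Calling by donor-side overlap

A genuine insertion of an element shorter than twice the fragment length
produces two clusters whose element-side intervals **overlap** over the
middle of the donor, while their acceptor-side intervals stop short of the
insertion point and do **not** overlap (reads across the junction are
unmappable). The caller enumerates cluster couples with compatible
signatures — `Del`+`Dup` (sense), two `Inv` of opposite orientation
(antisense, reported `inverted`), two `Trans` of different orientation
couples (inter-chromosomal; equal-strand couples mark an inverted event) —
and requires at least 1 bp of donor-side overlap with disjoint
acceptor-side hulls separated by at most `acceptorMaxGap`. A `Del` cluster
that overlaps no `Dup` cluster and whose inner gap exceeds $d_{inf}$ is
reported as a deletion instead. Companion `Del` clusters at a donor are
flagged as the possible footprint of cut-and-paste (rather than
copy-and-paste) mobilization; the two modes are otherwise deliberately not
auto-discriminated. `Ins`-signature clusters are clustered and reported but
trigger no event type: the calling rules use only `Del`/`Dup`/`Inv`/`Trans`
evidence.

The default `acceptorMaxGap` is $2\,d_{sup}$. For an element of length $T$
sequenced with fragments of length $F$, the acceptor-side clusters stop
roughly $F - T$ short of the insertion point **on each side**: the
breakpoint gap grows toward two fragment lengths as $T$ shrinks, so a
$d_{sup}$ bound would silently make short elements uncallable while
$2\,d_{sup} = 2M + 6\,MAD$ (also the callable-translocation bound) keeps
them callable and still rejects unrelated cluster couples.

Detectability bounds: the donor is reconstituted from overlapping
breakpoint clusters, so elements are fully spanned only up to $2L$ ($L$ =
mean fragment length); `maxDetectableLength()` returns this together with
the $2M + 6\,MAD$ translocation bound. At the other end of the scale,
elements shorter than roughly $F_{min} - r$ leave too few junction pairs
with the element-side mate fully inside the donor; at 20x coverage and a
10-fragment support threshold the practical floor is a few hundred bp.

### The threshold grid

$(X, Y)$ are the method's two free parameters; no single setting is optimal
for every event. Clustering and calling are re-run over a regular grid —
$X$ from 50 to 1000 in steps of 50, $Y$ from 100 to 5000 in steps of 100,
i.e. 1000 clustering attempts by default — and pooled: a registry is seeded
from the grid point with the most insertions (distinct acceptor sites; ties
by total support, then $(X, Y)$ order), every other point's lines are added
when they overlap no registry line on either the donor or the acceptor
interval, and when the same event recurs (overlap on both sides) the
instance supported by the most reads is kept. Lines overlapping on exactly
one side are ambiguous and dropped. Insertion lines with overlapping
acceptor intervals are candidate donors of one insertion and share an
`acceptorId`.

### Donor scoring

Within a family, candidate copies often differ by only a few substitutions.
Reads anchored at the acceptor (one mate within the acceptor interval
extended by $d_{sup}$) whose other mate covers a discriminating
polymorphism map strictly better on the true donor. For each such read the
per-candidate best edit distance is compared; if one candidate beats every
other by at least `minScoreDelta` (default 1 — one substitution changes
the edit distance by exactly 1) it scores one read. Reads mapping
indifferently are discarded; a read mapping to only one candidate counts
for it. Identical copies therefore score uniformly 0 and are flagged
ambiguous; single-candidate insertions render the score as `*`. The sum of
scores never exceeds the anchored-read count.

### Masking ambiguous regions

Two depth-based guards handle repeat arrays where breakpoints cannot be
placed: (i) during extraction, pairs whose mates both fall in per-base
coverage above median $+ 3\,MAD$ — with an absolute 1000x floor before
any region is maskable, since the targets are centromeric/rDNA arrays
orders of magnitude above the genome median — are discarded; (ii) after
calling, read depth on consecutive 100 bp windows is GC-corrected by
median-ratio normalization (1% GC bins, bins under 20 windows fall back to
the global median, so a GC-uniform genome is left untouched), windows more
than 3 MAD above the median are merged tolerating single-window gaps, and
acceptors overlapping segments longer than 500 bp are excluded. The
outlier rule is one-sided high: depressed coverage cannot create spurious
acceptor clusters. A lower coverage limit is computed and reported but
unused downstream.

## The simulator

The mate-pair simulator mirrors the circularization protocol: a fragment
size is drawn from the profile's empirical distribution and a location
uniformly on the genome; the fragment is circularized; a splice length is
drawn from the short-fragment mode and a splice start uniformly within one
splice length of the junction; both ends of the splice are sequenced
inward. A read whose window extends across the junction becomes a chimera
whose halves come from opposite fragment ends — the chimera rate thus
*emerges from the geometry*, $P = (r-1)/(\ell+1)$ per read for splice
length $\ell$ and read length $r$, rather than being imposed. At the
profile's contamination odds a short parasitic fragment is sequenced as an
ordinary forward–reverse pair instead. Per-base qualities are sampled from
per-position empirical histograms and substitution errors injected with
the probability the quality encodes, uniformly over the three alternative
bases. Learned profiles take the fragment distribution from unambiguously
mapped inserts, locate the split point at the minimum between the two
modes of the (typically bimodal) distribution, and infer the contamination
odds as the ratio of the mixture masses on the two sides of the split —
peak heights would confound component mass with component width.

The transposition injector copies a donor span (reverse-complemented for
inverted events) behind a duplicate of the `tsdLen` bases following the
acceptor position, so each new copy sits between direct repeats of the
target site, as real insertions do. Four event classes are planted: the
exact span of an annotated copy (*normal*), a block of contiguous copies
(*composite*), a copy with 100–600 bp of flanking sequence per side
(*long*), and a 30–70% interior sub-span (*short*). Donor spans are capped
below $2L$ and acceptors are drawn in unique sequence, mutually separated,
so every planted breakpoint is within the method's detectability envelope.

### What the noiseless benchmark does and does not show

The end-to-end benchmark uses two 1 Mb chromosomes carrying a 3 kb family
of three copies (two identical, one with 5 substitutions) plus two shorter
families whose first copies are adjacent (the composite donor block — made
cross-family, as real composite elements are, because same-family tandem
copies make candidate clusters fuse across the spacer and blow the cluster
size filter); 20 events, 5 per class, TSD 5 bp; an error-free,
chimera-free, contamination-free library with $L = 3000$, read length 100,
20x coverage; and a *uniform* (tightly size-selected) fragment
distribution of half-width 300, giving insert MAD ≈ 150. The uniform shape
matters: under any normal-tailed distribution ~4% of perfectly concordant
fragments fall outside $M \pm 3\,MAD$ by construction, each of which is
then — correctly, per the extraction rule — recorded with all its
multi-mapping combinations and accumulates ghost cluster couples between
pre-existing TE copies. A bounded insert distribution is the condition
under which "error-free implies zero discordant background" actually
holds. Alignments for this benchmark come from the exact-placement writer
(`placeReads()`), which emits what a strict ≤1-mismatch aligner reports:
junction-straddling and chimeric reads unmapped, and candidate mappings at
every homologous family copy with edit distances computed by direct
sequence comparison.

Consequently, passing this benchmark shows the pair-signature geometry,
clustering, grid pooling, donor attribution and bookkeeping are correct;
it does *not* exercise alignment artefacts, indels, heavy-tailed insert
distributions, heterozygous insertions or chimeric/recombinant donors. The
separate fidelity benchmark (quality histograms, fragment KS distance,
chimera geometry at 10^5 reads with errors, chimeras and contamination on)
covers the noisy half of the simulator, and real-data use is expected to
show the lower precision any pair-based caller has on repeat-dense
genomes.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (the R/Bioconductor and SAM
  convention); text outputs are 1-based.
* Interval overlap is measured between hulls as `min(end) − max(start)`
  (touching hulls overlap by 0 and do not satisfy the ≥1 bp condition);
  hull gaps are 0 for overlapping hulls.
* Classification ties at $d_{inf}$/$d_{sup}$ are discordant (see above).
* Combination enumeration is capped at 10 000 per fragment (the aligner
  reporting cap), with duplicated mappings collapsed first.
* Cluster output is sorted by (chromosome pair, start, signature), and
  grid pooling iterates points in $(X, Y)$ lexicographic order, so runs
  are deterministic; all stochastic components take explicit seeds.
* Degenerate inputs: an insert-size MAD of 0 flags the statistics
  degenerate (every non-median insert discordant); empty alignment input
  yields a zero-event table with headers; zero-coverage masks warn.
* The test suite scales the grid to 2x2 points and the benchmark genome
  as above; these sizes are stated here as the package's reference
  problem sizes.

## Limitations

Breakpoints are interval-, not base-resolved (no split-read step); purely
pair-based evidence cannot see elements much shorter than the fragment
size; cut-and-paste vs copy-and-paste is only advisory; chimeric donors
arising from template switching are reported as two high-scoring
candidates rather than reconstructed; zygosity is not inferred.
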