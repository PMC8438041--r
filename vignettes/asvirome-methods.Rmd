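---
title: "Methods: synthetic virome communities, CRISPR host prediction, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic virome communities, CRISPR host prediction, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`asvirome` rebuilds a wastewater-virome analysis as a chain of testable
operations over synthetic communities with planted ground truth. This
vignette records the models, the parameters that matter, and the design
choices made where the design was genuinely open. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

## The synthetic community generator

`gen_community()` emulates the statistical structure the analysis
operates on, not the biology that produced it:

* **Viral genomes** — uniform-random ACGT sequences, 8–20 kb by default,
  partitioned into genera of size 1–3. Each genus owns a pool of random
  amino-acid "proteins" (pool size 1.5× the largest member's gene
  count); members sample their genes from the pool, so same-genus
  contigs share most gene content and cross-genus contigs share none.
* **Host genomes** — 30 kb random sequences with a six-rank taxonomy
  (about 15% archaeal genera; some genera span two genomes so
  multi-host questions are answerable). Each host carries one planted
  CRISPR array: a random 28-bp repeat interleaved with spacers sampled
  as substrings of viral genomes (optionally mutated), flanked so the
  array has `spacers + 1` repeat copies.
* **Abundances** — per-sample genus abundances are log-normal
  (`sigma = 1.5`); a configurable core fraction (default 0.5) of genera
  is forced present in every sample, and every non-core genus is zeroed
  in at least one sample, reproducing the "shared core + variable tail"
  structure of multi-site virome surveys. Member viruses split their
  genus's abundance by log-normal weights. The coverage table converts
  abundance to aligned bases at a fixed depth scale; optional error-free
  150-bp reads are drawn proportional to aligned bases.
* **Hi-C contacts** — a fixed count (default 20) on every true
  virus–host pair plus a configurable number of background contacts
  spread uniformly over random pairs.

All output derives from a single integer seed; identical seeds give
byte-identical files.

Two generator details are deliberate design choices rather than
emulation:

* **Boundary-unambiguous arrays.** If every planted spacer started with
  the same base (or every spacer ended with the base that precedes the
  array), the maximal exact repeat would extend across the planted
  boundary and *no* exact detector could return the planted spacers
  verbatim — the decomposition itself would be ambiguous. The generator
  resamples spacer sets until the planted decomposition is the unique
  maximal one. This is a property of what "planted truth" has to mean
  for an exact-repeat detector, not a concession to the detector.
* **Spacer lengths are validated against the detector's defaults**
  (`[19, 48]` bp): planting arrays the default parameters cannot
  represent would make the truth undetectable by construction, so the
  configuration is rejected with an explanation.

What passing tests on these communities shows — and does not show: the
operations are internally correct (threshold arithmetic, recovery of
planted structure, determinism), but random sequences have no codon
structure, no repeat families beyond the planted arrays, no assembly
artifacts, and no sequencing error. Real-data performance depends on
those confounders and is not claimed.

## Viral screening

`screen_vpf()` gates on length strictly greater than 5000 bp and at
least five VPF-hit genes, then applies three evidence criteria (KO
≤ 20% and Pfam ≤ 40% and VPF ≥ 10%; VPF count > Pfam count; VPF ≥ 60%).
Whether the criteria combine conjunctively or disjunctively is not
derivable from their published description; the disjunctive reading
matches the alternative-evidence design of viral-HMM screening
pipelines, so `any` is the default and `all` is available as
`criteria_mode`. Boundary semantics follow the printed symbols exactly
(≤/≥ inclusive, "longer than" strict). The screen is verified against
an exhaustive truth-table oracle over every count combination with at
most 12 genes.

`lca_assign()` keeps hits within 10% of the best bitscore (a MEGAN-like
default; none is published for this analysis) and returns the longest
common lineage prefix.

## Genus clustering

Protein clusters come from greedy centroid clustering (longest first,
90% global identity, identity = Needleman–Wunsch matches over the
longer length, shared 8-mer prefilter). Contig pairs are scored by the
hypergeometric survival probability of their shared clusters,
`-log10 P(X ≥ shared)`, computed with `stats::phyper` and verified
against subset enumeration for universes up to 12. Genera are connected
components of the significance graph — a deliberate, documented
simplification of overlapping cohesive clustering: components are
deterministic, order-independent, and sufficient for planted data where
cross-genus sharing is zero. The published genus counts are therefore
not reproduction targets.

The edge threshold default is 1 (P ≤ 0.1), the conventional
significance floor on this score in gene-sharing-network practice. On
planted communities the choice is uncritical — cross-genus pairs score
exactly 0, so any positive threshold recovers the partition — but real
data would need a stricter value; the parameter is exposed everywhere.

Dereplication at 90% identity and 80% coverage of the shorter sequence
uses greedy longest-first clustering with 15-mer-anchored ungapped
comparison. Only the thresholds are normative; indel-tolerant alignment
is out of scope because the synthetic truth contains no indels.

## CRISPR array detection

`find_crispr_arrays()` follows the published defaults of the CRISPR
Recognition Tool: ≥ 3 repeat copies, repeat length 19–38, spacer length
19–48, 8-bp seeds. The algorithm: collect 8-mers recurring with a
tandem period in [38, 86] (= min repeat + min spacer to max repeat +
max spacer); extend each anchor set to the maximal sequence shared
*exactly by all copies*; validate repeat and spacer lengths, splitting
at junctions whose gap leaves the spacer range; resolve overlapping
candidates preferring more repeat copies, then longer span — a seed
straddling a repeat boundary can found a shifted sub-array with one
fewer copy, and the copy-count preference is what makes recovery exact.
Exact-repeat mode is itself a design choice: CRT tolerates repeat
degeneracy, but exactness makes the detector a verifiable oracle for
planted truth. On random 100-kb backgrounds the detector finds nothing
(an exact ≥ 19-bp triple with compatible spacing is vanishingly
improbable), which the tests assert over 20 seeds.

## Spacer matching and the error model

`match_spacer()` is a seeded, ungapped, both-strand aligner with local
trimming semantics: identity is computed over the alignment length,
coverage over the full spacer. Thresholds default to identity ≥ 0.97,
coverage ≥ 0.90, mismatches ≤ 1. Numerical choices:

* **Ungapped only.** Short-read BLAST rarely opens gaps above 97%
  identity at spacer lengths, and ungapped alignment keeps the
  brute-force oracle exact. Gapped mode is out of scope.
* **Seeding is lossless.** A passing alignment has either zero
  mismatches over ≥ 18 bases or one mismatch over ≥ 34 bases (one
  mismatch over fewer already violates 0.97), so every passing
  alignment contains an exact 11-mer and word size 11 misses nothing.
* **Deterministic tie-break** — matching bases, then identity, then
  plus strand, then leftmost position — because "keep one best hit" in
  search tools is otherwise order-dependent.
* **No e-value.** The published workflow used the default e-value,
  which never binds at ≥ 97% identity on ≥ 19-bp matches at this scale;
  the omission is deliberate.
* Threshold comparisons use an epsilon (1e-9) so that exact fractions
  like 0.9 × 30 are not lost to floating-point representation.

`match_spacer_oracle()` enumerates every window, offset and strand and
shares only the tie-break convention; agreement on hundreds of planted
pairs at 0–2 substitutions is asserted in the tests.

The error model is arithmetic over measured rates: erroneous-association
rate = 100 · random recall / observed recall (reported rounded, with the
unrounded value retained); `P(f) = 1 − (1 − p)^k` for a k-domain
assignment; expected spurious links = count × P(f). The random null is
measured by `random_null_recall()` on random sequences matched to a
length distribution. One implementation subtlety worth recording: the
null derives its replicate RNG streams from the user seed through an
intermediate scrambling draw. Consuming the seed directly would, when
the user passes the same seed that generated the community, replay the
generator's base stream — the "random" sequences would be shifted
copies of the viral genomes, protospacers included, and the null would
be wildly inflated. The derived-stream design makes equal seeds safe.

A reported-versus-methods discrepancy in the source material
("mismatches < 1" in one place, "1 mismatch" in another) is resolved in
favour of ≤ 1, which is the setting under which the published precision
and recall were obtained. Benchmarking reports both correct-genus recall
(default) and any-prediction recall, since the published recall
definition is not spelled out; reference viruses may carry a *set* of
known host genera, a prediction being correct when its genus is among
them.

## Ecology

Relative abundance follows the published normalization exactly:
aligned bases / contig length, divided by dataset size, then by the
sample total; genus abundance sums member shares. Singleton contigs
remain individual entities (`singleton:<id>`) so columns always sum to
one. Shannon uses the natural log (the base is not published; nats are
the vegan convention). Pielou is `NA` for a single-entity sample
(0/0). Bray–Curtis is the standard ratio form, cross-checked against
`vegan::vegdist` in the tests; PCoA wraps `stats::cmdscale` and reports
negative eigenvalues rather than dropping them.

The rarefaction detection rule — at least one mapped read and ≥ 10%
horizontal coverage — is a package choice (none is published) and is
exposed as parameters. The toy mapper anchors exact 20-mers at three
read offsets on both strands and applies the published length-fraction
0.8 / similarity 0.9 acceptance rule ungapped; reads below 20 bp are
unmappable by construction.

## Hi-C validation

The published deconvolution is proprietary, so `hic_deconvolve()` is a
documented stand-in validated on synthetic truth: per virus, candidate
bins need `min_count ≥ 5` contacts, and every candidate within
`dominance_ratio = 2` of the top count is assigned. The two published
phrasings of the rule (dominant-bin assignment; co-assignment of
near-ties) conflict for intermediate configurations such as counts
{10, 7}; the unified rule — assign all candidates with
`count ≥ top/ratio` — reproduces both of their unambiguous cases and is
the one implemented. "Simultaneously found" is interpreted as the virus
appearing in the Hi-C link set under any bin; precision counts only
detected links, which makes it invariant to the number of undetected
ones (asserted in the tests).

## Problem sizes

The reference analysis (`analysis/`, `scripts/acceptance.R`) uses 50
viruses, 30 hosts, 3 samples, 3 spacers per host, and 2000 reads per
sample — sizes at which every stage's truth is exhaustively checkable
while the whole workflow completes in minutes on one core. The unit
tests use smaller communities (typically 10 viruses, 6 hosts) built
once per run and shared across test files.

## Known limitations

* Random-sequence genomes: no gene structure, GC skew, repeat families
  or mobile elements; detector and matcher false-positive rates on real
  genomes will be higher than the synthetic zero.
* Connected-component genera merge chains that cohesive overlapping
  clustering would split; genus *counts* on real data are not
  comparable.
* Ungapped alignment throughout; indel-containing protospacers or
  reads are not modelled.
* The Hi-C stand-in models contact counts, not restriction-site or
  crosslinking-efficiency structure.
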