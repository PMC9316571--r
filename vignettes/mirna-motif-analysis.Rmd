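---
title: "Structural and motif analysis of mature miRNA sets: methods"
author: "mirmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and motif analysis of mature miRNA sets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmotifs)
```

## The problem

Mature miRNAs are 17–27 nt single-stranded RNAs; their exact sequence —
in particular the seed (positions 2–8 from the 5' end) and surrounding
motifs — determines which transcripts they silence. Given a set of mature
miRNA sequences (for example, the miRNAs differentially expressed in a
disease cohort), this package answers a chain of structural questions:

1. How are lengths distributed, and what is the per-position nucleotide
   composition from the 5' to the 3' end?
2. Which miRNAs are extreme in purine content, 100·(A+G)/length?
3. Which exact substrings ("motifs", 3–7 nt and longer) are shared by many
   sequences, and which are the longest shared ones?
4. Do miRNAs sharing a long motif form families with nested shorter
   motifs ("consensus groups")?
5. Do the carriers of a motif target the same genes, given a validated
   miRNA→gene interaction map?
6. Are the frequent short motifs also frequent in other species' miRNA
   sets?

## Presence semantics

Every motif statistic in the package uses *presence* counting: a motif's
count is the number of sequences containing at least one occurrence; a
sequence with several (possibly overlapping) occurrences still counts
once. This is the semantics under which published per-motif frequencies
divide by the set size to give "percentage of miRNAs carrying the motif".
Occurrence positions are not discarded — `motifHitIndex()` records every
overlapping occurrence with 0-based offsets — they simply do not inflate
counts. Motifs are literal 5'→3' substrings over {A,C,G,U}; there is no
reverse-complement matching and no degenerate (IUPAC) alphabet.

`countMotifs()` enumerates the distinct k-mers of each sequence and
tabulates them, which is exactly equivalent to testing every candidate
k-mer for containment; the test suite verifies this equivalence against a
naive double-loop `grepl()` oracle on hundreds of random sets.

## Maximal shared motifs

`maximalMotifs(set, support = m, kmin)` reports every motif of length ≥
`kmin` carried by ≥ m sequences, flagging as *maximal* those for which no
single-nucleotide extension (one base prepended or appended) still
reaches m. Because presence counts are anti-monotone under extension — an
extension of a motif can only be carried by a subset of its carriers —
the search can deepen one length at a time, keeping only supported
motifs, and is still equivalent to exhaustive enumeration of all
substrings of all lengths. The deepening formulation was chosen over a
generalized suffix structure because it is short, auditable and directly
mirrors the definition; at the scale of miRNA sets (hundreds of
sequences of ≤ 27 nt) it is effectively instantaneous.

## Consensus groups

A consensus group is a set of ≥ 2 miRNAs sharing a long *anchor* motif,
together with the nested 3–7 nt motifs shared by all members.
`buildConsensusGroups()` derives groups from the supported motifs of
length ≥ `minAnchorLen` (default 8): each such motif defines a candidate
group of its carriers, and candidates with identical member sets are
merged under their longest anchor (ties broken lexicographically). The
merging step is what makes the construction well-defined: for every
distinct carrier set, exactly its longest shared motif survives as the
anchor, and a chance one-base extension shared by only a subset of
members spawns its own smaller group rather than shadowing the family.
Groups are anchored on exact shared substrings; there is no gapped
multiple alignment, because the structures being modelled are ungapped
consensus blocks.

The default `minAnchorLen = 8` reflects that in 17–27 nt sequences over
a 4-letter alphabet, shared substrings shorter than ~8 nt are common by
chance and stop being family-specific. Shared-motif layers are computed
for k = 3..7 as the intersection of the members' distinct k-mers, so by
construction every length-k window of the anchor appears in layer k
(substring closure — asserted in the tests). Anchor coordinates are
0-based half-open internally and 1-based in the CSV report, matching the
1..27 position convention of printed miRNA tables.

## Target overlap

`summarizeTargets(set, map, motif)` finds the motif's carriers, keeps
those with entries in the target map, and tabulates per gene how many of
them target it. The percentage denominator is the *annotated* carriers:
carriers absent from the map are excluded from the denominator and
returned in a side list. The alternative — counting them and capping
percentages below 100 — would make "all carriers target gene X" (100%)
unreachable whenever a single carrier lacks annotation, which is an
artifact of map coverage, not of biology. The default reporting cut
`minPercentage = 30` approximates the visible floor of published 7-mer
overlap tables; it only filters rows, never changes computed values.

## Conservation across species

`buildProfiles()` recomputes presence tables per species (default
k ∈ {5, 6}: long enough to be specific, short enough to stay frequent in
distant species), and `conservationMatrix()` compares the per-species
top-n lists (default n = 15; presence count descending, motif ascending
as the tie-break). "Conserved" is operationalized as membership in ≥ 2
species' top lists — a strict all-species intersection would discard the
partially conserved motifs that make such tables informative —
and species-exclusive top motifs are retained with `shared = FALSE`.
Cells are filled only where the motif is in that species' top list, with
the presence percentage rounded to 1 decimal; all other tables round to
2 decimals, and raw values are kept in the objects.

## The synthetic generator

`generateSet()` emulates the statistical structure of a myeloid-cancer
miRNA set so that every stage can be tested without downloads:

* **Lengths** are drawn from a histogram concentrated at 21/22/23 nt with
  probabilities 0.198/0.498/0.135 — the dominant bins of the empirical
  length distribution of such sets. The remaining 0.169 mass is not
  published per bin; the default tapers it as 17:0.014, 18:0.020,
  19:0.035, 20:0.075, 24:0.015, 25:0.006, 26:0.002, 27:0.002, chosen
  once to echo the observed asymmetry (short miRNAs more common than
  26–27 nt ones) and kept fixed thereafter.
* **Positional bias**: independent per-position draws with baseline
  A/C/G/U = 0.226/0.248/0.248/0.278 (uracil most frequent overall,
  adenine least), adenine up-weighted to 0.35 at positions 1–3 and
  uracil to 0.40 at positions ≥ 20 — reproducing the 5'-adenine /
  3'-uracil enrichment that positional composition analysis of real sets
  shows. Draws are independent across positions: the emulated structure
  is positional, not dinucleotide (no Markov dependence).
* **Planted motifs** are inserted by overwriting the background at a
  random feasible offset (uniform, or confined to 0-based offsets 1–7
  under the `seed_region` policy), preserving the length distribution.
  Carriers are per-sequence Bernoulli(prevalence) draws, and the
  returned `SyntheticTruth` records the realized carriers and offsets
  exactly; with several planted motifs a later insertion can overwrite
  an earlier one, and evicted carriers are dropped from the truth so it
  never disagrees with the sequences.
* **Target maps** (`generateTargetMap()`) couple each planted motif to
  dedicated genes targeted by each carrier with probability `coupling`,
  so `coupling = 1` reproduces exact-100% gene rows; background genes
  are assigned to any sequence with probability 0.1.
* **Species panels** (`generateSpeciesPanel()`) scale shared-motif
  prevalences by `max(0, 1 − divergence·i)` for species index i
  (0-based), emulating conservation decay.

What the generator does *not* emulate: real miRNA sets contain paralog
families with correlated full-length sequences, dinucleotide and
GC-content structure, and heavy-tailed motif sharing driven by shared
biogenesis. Passing tests on synthetic data therefore demonstrate
correctness of the computations and recoverability of planted structure,
not biological conclusions about any real dataset.

All generator randomness flows through a single integer seed
(`withr::with_seed`), so identical configurations give byte-identical
FASTA output.

## Numerical and reporting conventions

* Percentages are reported round-half-up to 2 decimals (1 decimal in the
  conservation matrix); raw doubles are retained in every object, and
  `runPipeline(raw = TRUE)` writes them unrounded.
* Orderings use C-locale radix sorting (count descending, string
  ascending) so output is identical across locales.
* `lengthStats()` exposes population (divisor n, the default) and sample
  (divisor n−1) variance; published variances of this kind rarely state
  the divisor, so both are available, and a single-sequence set has
  variance 0 under both.
* `positionFrequency()` defaults to per-position *coverage* denominators
  (sequences long enough to reach the position); a fixed set-size
  denominator would force positions 23–27 toward zero and hide the 3'
  tail signal. Both modes are exposed.
* `thresholdReport()` strata are strict inequalities (count > minCount,
  count < maxCount); the bounds are configurable, defaulting to the
  conventional 4-mer cut of 70 and 10.
* Degenerate inputs fail loudly: empty sets, duplicate ids, non-RNA
  symbols (policy-dependent in `readMiRNAFasta()`), malformed target-map
  lines (reported with their line number), infeasible generator
  configurations (motif longer than the shortest generatable sequence).

## Problem sizes in the test suite

The suite exercises the oracles at the scale where brute force is
exact and fast: motif tables are compared against a double-loop substring
oracle on 200 random sets of up to 50 sequences (k = 3..10), maximal
motifs against full substring enumeration on sets of ≤ 12 sequences,
prevalence recovery on 400-sequence sets at prevalences 0.1/0.5/0.9
within 3 binomial standard deviations, and full-size composition
identities on 587-sequence synthetic sets. These sizes were chosen as
the smallest at which the checked properties are non-trivial.

## Known limitations

* Motifs are exact substrings; a single substitution splits a family.
  Position-weight matrices and IUPAC classes are out of scope.
* Consensus groups require an exact shared anchor; families aligned only
  with gaps are not grouped.
* The conservation table compares top-n lists, so a motif frequent
  everywhere but rank n+1 in one species shows an empty cell there.
* Target summaries describe a supplied validated-interaction map; the
  package performs no target prediction.
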