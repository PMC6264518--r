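---
title: "Scoring cross-reactivity risk with the A-RISC index"
author: "ariscr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cross-reactivity risk with the A-RISC index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ariscr)
```

## The model

IgE cross-reactivity — an antibody raised against one allergen binding
a related protein — is largely driven by sequence conservation within a
protein family, since family members share a fold and hence present
epitopes in corresponding surface regions. The model here deliberately
uses primary structure only. For an aligned pair of sequences every
compared position falls into one of three classes:

* **identical** — the same standard residue in both sequences;
* **similar, but not identical** — different residues from the same
  physicochemical group: aromatic {F, Y, W}, aliphatic {I, L, V},
  positively charged {H, K, R}, negatively charged {D, E}, hydroxyl
  {S, T}, neutral polar {N, Q};
* **not similar** — everything else. A, C, G, M and P belong to no
  group: for them only identity counts, which makes this similarity
  definition deliberately conservative (more so than, e.g., the Clustal
  consensus groups).

With identity fraction $I$ and similarity fraction $S$ (similar
*includes* identical, so $S \ge I$), the A-RISC index is

$$\mathrm{A\text{-}RISC} = I + w\,(S - I), \qquad w = 0.5
  \;\Rightarrow\; \frac{I + S}{2},$$

the expected fraction of residues able to support binding of a
cross-reactive antibody: identical residues always can, similar ones
with probability $w$. The participation weight $w$ is an explicit
modelling assumption, not a fitted quantity; it is exposed as a
parameter (`w`, default 0.5, the only value used for reference
analyses) precisely because it is an assumption. Risk categories use
closed lower bounds — high $\ge 0.75$, medium-high $\ge 0.50$,
medium-low $\ge 0.25$, low $< 0.25$ — applied to the *unrounded* value;
display rounding to two decimals happens afterwards, so 0.7468 is
medium-high even though it prints as 0.75.

### Assumptions and limits

Only the primary structure enters; secondary/quaternary structure,
post-translational modification, ligands and epitope location are
ignored, and the shared-fold assumption means the index is meaningful
only *within* a family of homologs. The model predicts propensity, not
clinical outcome.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `w` | 0.5 | probability that a similar-not-identical residue participates in binding |
| `denominator` | `"shortest"` | what I and S are divided by (see below) |
| `model` | six SIAS-style groups | the similarity grouping; swappable via a YAML file |
| `mode` | `"msa"` | score pairs extracted from a family MSA vs internal pairwise re-alignment |

**Denominator.** Percent-identity tools disagree about the denominator.
We default to the *shortest* ungapped sequence length and offer
`longest`, `mean` and `alignment` (post-gap-gap-removal column count)
as alternatives, because the convention materially changes values for
length-mismatched pairs and published numbers rarely state it. All four
conventions are symmetric in the two sequences and preserve $I \le S$.

**Gap and ambiguity handling.** Columns with a gap opposite a residue
count toward neither identity nor similarity; columns gapped in both
rows are removed before any counting. Ambiguity codes (X, B, Z, J, U,
O) are accepted on input but are never identical or similar — an
unknown residue cannot support an epitope-level match claim — while
still counting toward ungapped length, so they dilute scores rather
than silently inflating them.

**Alignment source.** The reference workflow aligns each family once
with an external MSA program and extracts pairs from that alignment
(`mode = "msa"`). The internal Needleman–Wunsch aligner
(BLOSUM62, gap open 10, gap extend 0.5 — classic global defaults) is a
convenience for alignment-free input; it is *not* the reference
procedure, and distant pairs can score somewhat differently under it.
The aligner delegates to Biostrings' pairwise alignment, whose
traceback is deterministic, so outputs are reproducible run to run;
its tie-break among co-optimal alignments is the library's rule rather
than a match-before-gap preference, which we accepted since any
co-optimal alignment yields the same alignment score and the
differences in (I, S) are confined to tie cases.

## Family matrices, summaries, ranking

`build_family_matrix()` scores each of the $n(n-1)/2$ unordered pairs
once and mirrors them into symmetric matrices; the diagonal holds the
self-score ($I = S = 1$, category high). `summarize_family()` averages
over off-diagonal pairs only — including self-comparisons would pull
every mean toward 1 and contradict any observed maximum below 100%.
`rank_families()` orders families by mean A-RISC descending with an
alphabetical tie-break, making the propensity ranking deterministic.
Recomputed this way from a published ten-family survey of average
identity/similarity (shipped in `inst/extdata/`), profilins rank first
(mean A-RISC 0.80) and lipocalins last (0.27) — the one caveat being
the pectate-lyase row, whose printed family averages (64%/70%) imply
0.67 while the survey's own printed family index is 0.64; the numbers
as printed are mutually inconsistent at the third significant figure,
and we report the value implied by the averages.

## The synthetic-family generator

`generate_pair(length, I, S, seed)` mutates a random seed sequence at
exactly $\operatorname{round}((S-I)\,L)$ positions within-group and
$\operatorname{round}((1-S)\,L)$ positions across groups (rounding
half-up; counts, not real targets, are the contract). Within-group
substitutions are only placed where the seed residue is grouped, and if
a uniform draw of the seed has too few grouped positions the deficit is
repaired by rewriting ungrouped positions with grouped residues —
necessary because a large $S-I$ target can demand more grouped
positions than a uniform 15-of-20 draw ever yields. Non-similar
substitutions exclude the original residue's whole group, so the
position-class structure is exact, and rescoring a generated pair
(gap-free, shortest denominator) recovers the rounded targets
*exactly* — this exactness is what the test suite leans on.
`generate_family()` derives members 2..n independently from one seed
sequence; only member-vs-seed targets are guaranteed, member-vs-member
values are emergent (satisfying all pairwise targets simultaneously is
over-constrained). Default conditions — 5 members, 200 residues,
member-vs-seed identity uniform in [0.2, 0.9], similarity at most 0.25
above identity — were chosen once to mirror the spread seen in real
allergen families, whose surveyed identity ranges run from a few
percent to 99% with similarity typically 7–15 points higher.

What the generator does **not** emulate: indels (no gap process —
gapped scoring is exercised with hand-built aligned pairs instead),
realistic substitution rates, phylogenetic correlation between members,
and ambiguity codes. Green tests therefore certify the arithmetic and
the contracts, not performance on real, gappy, phylogenetically
structured alignments.

## Numerical and design choices

* Categorization before rounding (see above); matrices are written at
  the field's print precision (percent with one decimal, A-RISC with
  two).
* The round-half-up convention (`floor(x + 0.5)`) fixes substitution
  counts; the recovered targets are the rounded ones, stated as such.
* When the two roundings overshoot at very small lengths
  ($n_{within} + n_{nonsim} > L$), the non-similar count is clamped —
  the within-group count wins because it is the scarcer resource.
* Matrix TSV output preserves input order; nothing is silently
  re-sorted. Profile plots sort descending by the plotted value with an
  alphabetical tie-break (input order available).
* Heatmap colors interpolate linearly between anchors at the four
  category boundaries (red 1.0 → orange 0.75 → yellow 0.50 →
  yellow-green 0.25 → dark green 0.0), so the legend text matches the
  tier semantics; monotonicity (higher A-RISC never greener) is
  enforced by test. Both renderers expose data hooks
  (`heatmap_data()`, `profile_data()`) returning exactly what is drawn,
  so correctness is asserted on data, never pixels. Diagonal cells are
  drawn de-emphasized: self-identity is not a cross-reactivity claim.
* YAML model/spec files are read with handlers that keep `Y`, `N`,
  `F`, `n` as literal strings (YAML 1.1 would otherwise read them as
  booleans — fatal for residue letters).

## Problem sizes in the tests

Property tests run 1,000 random gapped pairs (length ≤ 50) against an
independently written column-by-column oracle, 1,000 random
(length, I, S) round trips through the generator, and a 5×200 family
cross-checked against brute-force recomputation at $10^{-12}$; these
sizes give full coverage of the rounding edge cases while keeping the
suite under a minute.
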