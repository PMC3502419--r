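---
title: "Serine-aware degeneracy coding and 21-amino-acid models"
author: "degen21"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serine-aware degeneracy coding and 21-amino-acid models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degen21)
```

## The problem

Deep-level phylogenomic analyses of protein-coding genes have to do
something about synonymous change: it saturates quickly and it carries
compositional signal (GC-rich versus AT-rich lineages) that violates
the stationarity assumptions of standard models. The two classical
escapes — translating to amino acids, or keeping nucleotides but
erasing synonymous differences ("degeneracy coding") — are not
equivalent, and the discrepancy concentrates on one amino acid:
serine.

Serine is unique among the amino acids in being encoded by two
*disjoint* codon clusters, **Ser1** (TCN) and **Ser2** (AGY), that
cannot interconvert through a single synonymous substitution. A
Ser1↔Ser2 change needs either a nonsynonymous intermediate or a
near-simultaneous double substitution, so its rate sits between
typical synonymous and typical nonsynonymous rates. Standard
20-amino-acid models collapse both clusters into one state `S` and
discard that signal; degeneracy-coded nucleotides retain it (TCN and
AGY stay distinct patterns). This package implements the full toolkit
around that observation:

* the degeneracy codings **degen1**, **degen8**, **degenFS2** and the
  character-deletion coding **noLRall1nt2**;
* conceptual translation to a 21-letter amino-acid alphabet in which
  `S` means Ser1-derived residues and the novel state `Z` means
  Ser2-derived residues;
* construction of 20/21-state amino-acid exchangeability matrices by
  collapsing a codon model, and expansion of JTT to 21 states by
  splitting its serine rates;
* a serine-site classification ("co-Ser" versus "non-co-Ser") and the
  catalogue of targeted alignment manipulations built on it;
* compositional-heterogeneity assessment by Euclidean distances
  between composition vectors, distance trees, and a column bootstrap
  with majority-rule consensus;
* a codon-alignment simulator with controllable codon frequencies,
  Ser1:Ser2 usage, and clade-restricted (non-stationary) compositional
  bias.

## Degeneracy coding

Each scheme replaces every codon by the fully degenerate IUPAC pattern
of its amino-acid class, so that two sequences that differ only
synonymously become identical strings:

| class | degen1 | degen8 | degenFS2 |
|---|---|---|---|
| His (CAY), Gln (CAR), ... | published pattern (e.g. CAT→CAY) | same | same |
| Leu (TTR+CTN) | YTN (merged with Phe) | TTR→NNN, CTN→CTN | YTN |
| Arg (AGR+CGN) | MGN (merged with Ser2) | AGR→NNN, CGN→CGN | MGN |
| Phe (TTY) | TTY | TTY | NNN |
| Ser1 (TCN) / Ser2 (AGY) | TCN / AGY | TCN / AGY | TCN / NNN |

Patterns are *computed* from the genetic code — the position-wise
IUPAC cover of each amino-acid class, with serine split into
Ser1/Ser2 — rather than hard-wired. For the standard code this
reproduces the published table exactly (the test suite pins all 64
codons against a hand-written copy of that table); for other codes it
produces the analogous patterns automatically, e.g. under the
invertebrate mitochondrial code Ser2 becomes AGN, Met ATR and Trp TGR.

```{r}
degen_codon("CAT")                               # CAY
degen_codon("TTA")                               # YTN (Leu+Phe)
degen_codon("AGA", code = genetic_code("mito-invert"))
```

Three rules make the coding total and idempotent:

* **Fixed points.** A codon whose IUPAC set equals one of the scheme's
  own target patterns (YTN, MGN, TCN, ...) maps to itself. Without
  this clause an already-coded matrix would degrade on re-coding,
  because YTN's expansions straddle the Leu and Phe classes.
* **Ambiguity consensus.** Any other ambiguous codon is expanded over
  its IUPAC sets and recoded only if every expansion agrees on the
  same target; otherwise it becomes NNN (conservative: certain signal
  is never invented, e.g. CAN → NNN because His/Gln is unresolved).
* **Missing data.** `---` passes through; a codon containing a partial
  gap (`-`/`?`) becomes NNN; stop codons become NNN with a counted
  warning (an error under `strict_stops = TRUE` — curated in-frame
  data should not contain stops, but the tool stays total).

`nolrall1nt2()` deletes characters instead of degenerating them: all
third positions go, and a first-position column goes when *any* taxon
at that column could encode Leu or Arg (their first positions are the
only other home of synonymous change). "Could encode" is decided by
IUPAC expansion; codons made only of `-`, `?` or `N` carry no
amino-acid information and do not trigger deletion — otherwise a
single fully-missing codon would delete every first position of its
column for all taxa.

## 21-amino-acid translation

`translate_alignment(aln, "aa21")` maps Ser1 codons to `S` and Ser2
codons to `Z`; under `"aa20"` both give `S`. The same
ambiguity-consensus rule applies, which has the convenient consequence
that degen1-coded matrices translate sensibly with no special casing:
TCN → S, AGY → Z, while the merged classes YTN and MGN honestly become
`X`. Because `Z` is redefined, the IUPAC amino-acid ambiguity codes
B/J (and Z under the 20-letter alphabet) are rejected on input.

Two bookkeeping identities hold by construction and are enforced in
the tests: per taxon, #S(aa20) = #S(aa21) + #Z(aa21), and the aa20
matrix equals the aa21 matrix with `Z` rewritten to `S`.

## Rate matrices

An exchangeability matrix is the symmetric factor $S$ of a reversible
rate matrix $Q = S\,\mathrm{diag}(\pi)$. Amino-acid matrices use
PAML's canonical state order with `Z` appended as state 21.

* `collapse_codon_matrix()` sums, for each pair of amino-acid classes,
  all codon-pair exchangeabilities between them. Under the 21-letter
  alphabet the S/Z entry collects the eight Ser1×Ser2 codon pairs.
  Collapsing is linear, so the 21-state result merges back to the
  20-state result exactly; the tests assert this additivity at 1e-15.
* `expand_aa21()` splits each serine rate of a 20-state matrix
  (typically JTT, taken from phangorn's constants) between S and Z in
  proportion to a 21-state reference matrix:
  $e(S,X) = j(S,X)\,\frac{r(S,X)}{r(S,X)+r(Z,X)}$, and symmetrically
  for Z, so $e(S,X)+e(Z,X)=j(S,X)$ holds to machine precision. The
  intra-serine entry, which no 20-state matrix has, is set by a
  ratio-of-averages rule — the reference's S/Z rate relative to the
  mean of its other entries, rescaled by the mean of the expanded
  matrix's other entries — with an explicit `sz_rate` override for
  users who prefer a different convention, and a 50/50 split (with a
  warning) if the reference rates to some state are both zero.
* `ecm_category_summary()` partitions all codon pairs into synonymous
  categories (per amino acid, Ser1 and Ser2 separate), the
  intra-serine S/Z category (eight pairs in the standard code), and
  nonsynonymous categories per amino-acid pair, reporting mean,
  min, max and pair count of each.

### The bundled codon model is synthetic

The empirical codon model this machinery is designed for is not
redistributable with the package, so the bundled reference
(`synthetic_ecm()`) is a **synthetic**, parametric stand-in built in
code and labelled as such everywhere. For a codon pair differing at
$d$ positions with $t$ transitions among them it sets the
exchangeability to $\kappa^{t}\,\delta^{d-1}\,\omega^{[\mathrm{nonsyn}]}$
with defaults $\kappa = 4$ (transition bias in the empirically common
range), $\delta = 0.4$ (multi-nucleotide exchanges possible but
penalized), $\omega = 0.06$ (strong purifying selection). These
defaults were chosen once so that the matrix reproduces the
*qualitative* structure the serine analyses rely on — mean synonymous
rates above the mean intra-serine S/Z rate, which in turn exceeds the
mean rate of every nonsynonymous pair of amino acids adjacent in the
codon graph (reachable by one nucleotide change; pairs connected only
through multi-hit exchanges, such as Cys/His, sit outside this
ordering). The suite asserts exactly that property. The synthetic
matrix does **not** reproduce any published model's numerical values;
analyses that need the published constants should load them with
`import_rate_matrix()` or build a `codon_rate_matrix()` from their own
copy.

## Serine sites and targeted manipulations

A codon column is **co-Ser** when at least one taxon carries a Ser1
codon and at least one a Ser2 codon; otherwise it is non-co-Ser1,
non-co-Ser2 or non-Ser. Ambiguous codons count toward a cluster only
when every IUPAC expansion lies in that cluster (a conservative
choice: a column never becomes co-Ser on the strength of an ambiguous
codon). Degeneracy coding preserves TCN/AGY identity, so raw and
degen1 matrices classify identically — asserted in the tests.

`manipulate()` implements the deletion, swap, proxy-recoding and
splitting directives over this classification (serine deletions to
NNN, Ser1↔Ser2 over-writing, deletion of non-serine codons at co-Ser
sites, duplication of each co-Ser column into a serine-only and a
non-serine-only column, recoding of co-Ser residues as Phe/Trp/Tyr
proxies in amino-acid matrices, and generic amino-acid swaps and
deletions). Every call returns the manipulated alignment together
with a change log of the touched cells; the tests reconcile the log
against an independent diff of input and output.

## Compositional heterogeneity

Composition — not primary sequence — is used as the character: each
taxon is reduced to its proportion vector over nucleotides, codons or
amino acids, and pairs of taxa are compared by the Euclidean distance
$d(i,j) = \sqrt{\sum_u (p_{iu}-p_{ju})^2}$. The distance tree built
from this matrix reflects compositional similarity only; its total
branch length is the heterogeneity index of the data set.

Numerical and design choices:

* **Tree estimator.** Neighbor joining (`ape::nj`) stands in for a
  heuristic minimum-evolution search: it is deterministic,
  ME-consistent, and exact on additive inputs (the tests recover 4-
  and 8-taxon trees exactly). Negative NJ branch lengths are clamped
  to zero before summation, with pre-clamp values kept in an
  attribute; clamping can shift absolute tree lengths slightly
  relative to estimators that tolerate negative branches.
* **Counting.** By default only fully resolved units are counted
  (gaps, `?`, ambiguity codes and partial codons are excluded, with
  the count of used units reported). For degeneracy-coded matrices,
  whose information lives in patterns like TCN/AGY/YTN, the
  `all_symbols` switch counts every non-missing symbol as its own
  category so that "degenerated nucleotide composition" is
  well-defined.
* **Bootstrap.** `composition_bootstrap()` resamples columns of the
  chosen unit with replacement to the original length (nucleotide
  columns for the nt unit, codon columns otherwise), recomputes the
  distance matrix and NJ tree per replicate, and reports bipartition
  frequencies plus the majority-rule consensus. 300 replicates is the
  default in the examples, matching standard practice for this
  analysis. Each split is labelled by its side away from the
  alphabetically first taxon, making supports invariant to taxon
  input order; the seed is required or drawn-and-recorded.

## The simulator and what the tests show

`simulate_codon_alignment()` evolves sites i.i.d. along a tree under
the reversible chain $Q = S\,\mathrm{diag}(\pi)$ over the 61 sense
codons, scaled to one expected substitution per codon per unit branch
length, with the transition matrices computed by eigendecomposition of
the $\pi$-symmetrized generator. A clade frequency override switches
$\pi$ on the clade's stem branch and everywhere below it, which is how
non-stationary composition is planted. Two frequency dials are
provided: `adjust_ser_usage()` imposes a Ser1:Ser2 odds while
preserving total serine mass, and `bias_synonymous_gc()` reweights
codons *within* each amino-acid class by third-position G/C content —
a purely synonymous bias that leaves amino-acid composition, Ser1:Ser2
usage and degeneracy-coded composition untouched.

`nonstationary_demo_spec()` freezes the conditions used across the
examples, acceptance checks and this vignette: a balanced 16-taxon
tree with all branches at 0.3 expected substitutions per codon, 500
codons, and one 4-taxon clade whose frequencies are GC3-enriched with
weight 8 (clade GC3 around 0.9 against a baseline near 0.5 — the
magnitude of an extreme codon-usage contrast). Sixteen taxa by 500
codons keeps a 300-replicate double bootstrap within seconds while
leaving the compositional contrast far above sampling noise; the
simulator recovery checks use 50,000–100,000 codons on two-taxon
trees, where the law of large numbers pins empirical frequencies to
within 0.01 of their targets.

Under these conditions the package reproduces the qualitative
contrast that motivates degeneracy coding: raw nucleotide composition
groups the GC3-biased clade with essentially full bootstrap support,
while the degen1-coded composition of the *same* data shows no such
grouping (support at noise level) — the planted signal is synonymous,
and degeneracy coding erases it.

What passing these tests does *not* show: the simulator draws sites
i.i.d. (no among-site rate variation, no indels, no selection
heterogeneity along the sequence), branch lengths are modest, and the
synthetic codon model is smoother than any empirically estimated one.
Real alignments mix gene-specific rates, alignment error and much
more ragged codon-usage variation; conclusions about real data rest
on the method, not on these fixtures.

## Known limitations

* The bundled codon model is synthetic (see above); no published
  empirical codon matrix ships with the package.
* degen8 and degenFS2 are defined relative to the code in use (the
  Leu TTR / Arg AGR subsets, the Phe and Ser2 codon sets); under
  exotic codes the deleted sets may be empty.
* Likelihood analysis of the coded matrices is out of scope: the
  package prepares matrices and rate files for external ML software
  and analyses composition, it does not compute likelihoods.
* The compositional bootstrap measures the strength of compositional
  signal; it is not a phylogenetic support measure.
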