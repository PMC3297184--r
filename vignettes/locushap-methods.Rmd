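---
title: "Methods: haplotype networks, homoplasy tests and dating at a single locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype networks, homoplasy tests and dating at a single locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locushap)
```

# Scope and model

`locushap` analyses one aligned gene region sampled from wild and
domesticated accessions. Its working model is the classic one for a
low-recombination nuclear locus surveyed across a domestication gradient:
a small number of haplotypes related by a genealogy, mutations that mostly
obey infinite sites, occasional exact repeat mutations (homoplasies),
occasional recombinant mosaic haplotypes, and one multi-base indel that
segregates as a single historical event. All coordinates anywhere in the
package are 1-based inclusive alignment columns, so positions quoted in
outputs can be read directly against the alignment.

# Input conventions and missing data

Sequences are upper-cased; any symbol outside `A`, `C`, `G`, `T`, `-` is
recoded to `N` and treated as missing. The alignment length `L` is always
taken from the input, never assumed. How missing data enter each statistic
follows the conventions of the standard interactive tools for this kind of
survey, because published tables are produced that way:

* **Substitution sites, Tajima's D, Fu & Li's D\*/F\***: complete deletion —
  columns containing any gap or `N` are dropped before counting.
* **π (nucleotide diversity)**: pairwise deletion — each sample pair is
  compared over the columns where both carry a base, and π is the mean of
  the per-pair proportions. This follows `ape::dist.dna(model = "raw",
  pairwise.deletion = TRUE)`.
* **Indels**: maximal runs of gap columns with an identical carrier pattern
  are collapsed into single indel events. Indel events are excluded from
  `S`, π and the neutrality tests, and enter only as network characters
  (below). This treats a 46-bp deletion as one event, not 46.

The choice is deliberately asymmetric: complete deletion keeps the
site-frequency-based tests on a common set of columns, while π benefits
from using every comparable pair.

# Diversity statistics

`S`, `H` (distinct sequences over the analysed columns), π per bp,
Watterson's θ per bp, Tajima's *D* (1989, standard normalisation), and
Fu & Li's *D\** and *F\** (1993, outgroup-free star statistics with the
corrected variance coefficients in common use) are computed per group, per
annotated region, and for the whole alignment. Tajima's *D* was verified
against an independent coalescent-simulation implementation (`tskit`)
during development; the test suite carries independently transcribed
textbook-formula oracles for *D*, *D\** and *F\**.

Undefined cases — fewer than 4 samples, or no segregating sites — are
returned as `NA` and printed as `nd` in tables, never as zero. Statistical
significance is reported as the conventional banded thresholds
(`P > 0.10`, `P < 0.05`, `P < 0.02`) from published critical-value tables;
no permutation machinery is attached, because the bands are how such
surveys report these tests.

`Rm` is the Hudson–Kaplan (1985) lower bound: all pairs of biallelic
substitution sites showing four gametes are collected as incompatibility
intervals, intervals containing another interval are discarded, and a
greedy left-to-right scan yields a maximal disjoint set. Two intervals
sharing only an endpoint are disjoint (the events live in the open
intervals). Sites with more than two alleles are counted in `S` but skipped
by the scan, which is defined for biallelic sites; samples missing at
either site of a pair are excluded pairwise.

# The haplotype network

Samples are collapsed to haplotypes on a binary character matrix: one
character per biallelic substitution site, one character per derived allele
at a multi-allelic site, and one presence/absence character per indel event
(weight 1 by default, adjustable; `indel_mode = "exclude"` drops indels
entirely). The indel's deletion-versus-insertion polarity is left
unpolarized by default — resolving it needs an outgroup locus, which is out
of scope here.

The network is a median-joining-style construction with ε = 0:

1. Compute the minimum spanning network (all links contained in at least
   one minimum spanning tree) over the current node set, so equally
   parsimonious alternative links survive as cycles — reticulations.
2. For every node triple joined by two network links, the majority-state
   median is a candidate Steiner node; the candidate with minimal
   connection cost is added, one per round, and the spanning network is
   recomputed.
3. When no candidate remains, a Steiner improvement pass proposes the
   majority median of *every* node triple and accepts any addition that
   strictly shortens the minimum spanning tree over the node set. This
   guards against a failure mode of greedy median joining in which a
   repeated mutation is misplaced as a false synapomorphy and the network
   inflates by several spurious repeated labels.
4. Unsampled nodes that end as leaves are pruned.

Edges are labelled with the positions changing along them; `m` is the total
number of substitution occurrences over edge labels, counting repeats. A
**homoplasy** is a character (position *plus* derived state) appearing on
two or more edges; a character on `k` edges contributes `k − 1` to the
network count `H_net`. Node ids are deterministic (`H01…` in order of first
member sample, Roman-numeral aliases for figure parity, `M01…` for
medians), and identical inputs give byte-identical exports (GraphML, DOT,
and NEXUS of the haplotype sequences for external Bayesian dating tools).

A consequence of strict length minimisation worth knowing: a reticulation
(cycle) appears only when the alternative links tie in weight. When
branches are long (several mutations per edge), the same conflict is
instead expressed as a mosaic path node with repeated edge labels — the
homoplasy count still sees it, but the cycle enumeration does not. Real
surveys with mostly 1–2 substitutions per branch tie frequently, which is
why their networks show reticulation areas.

# The homoplasy model and recombination tests

Under a uniform-mutation null with alignment length `L` and `m` network
substitutions, the chance that a given mutation exactly repeats another
(same column, same derived base — hence the 1/3) is `p = (1/3)(1/L)m`, and
`E = m·p = m²/(3L)` homoplasies are expected in the whole network. Both
full-precision values and display-precision mirrors (one significant figure
for `p`, truncation to two decimals for `E`) are reported, since published
tables round this model's outputs.

A branch with `N` substitutions of which `H` are homoplasious is scored by
the upper-tail `P(X ≥ H | N, p)` (`stats::pbinom`); `H = 0` gives 1. The
network-wide count is reported both as the point probability
`P(X = H_net | m, p)` — which is what the conventional printed network-wide
figure corresponds to at full-precision `p` — and as the upper tail, which
matches the branch-level definition. Tests always use full-precision `p`
rather than its rounded mirror: reproducibility beats rounding mimicry, and
the difference is within a few percent.

Each independent cycle of the network is one candidate recombination event
(`R1…Rk`, ordered by increasing distance from the DCA, which is the only
ordering the construction makes canonical). The tested branch is the cycle
branch whose label carries homoplasious characters; if several do, each is
tested and the event reports the minimum tail probability with a flag. The
two cycle corners farthest from the tested branch are reported as the two
possible ancestral nodes of the event. Significance is flagged at 0.05
and 0.01.

# DCA and dating

The domestication common ancestor is the node minimising total
shortest-path parsimony length to every node containing cultivated
members, ties broken by fewest homoplasious characters on the connecting
paths, then lexicographically — a fully deterministic rule. All candidate
scores are returned, not just the winner.

Dating uses `r = k/(L·T)` from a calibration node of known age `T` and
substitution depth `k`. Depth of a node is the substitution count to its
descendant sampled tips (tips whose shortest path from the root passes
through the node), aggregated by `depth_mode`: `mean_tip_path` (default),
`max_tip_path` or `min_tip_path`. The mean is the default because
multi-tip depths are naturally fractional and a mean-depth calibration
reproduces published fractional node ages; all three modes are exposed and
recorded in the output. A node's own samples sit at depth 0, so sampled
tip-only haplotypes date to the present. Paths through reticulations take
the minimum-substitution route. `calibrate_from_network()` takes `k` as
the calibration node's own depth, which makes the calibration node's age
reproduce `T` exactly under every mode.

# The synthetic-data generator

`simulate_alignment()` draws a uniform ranked coalescent topology over
`n_haplotypes` tips, assigns each branch a fixed or Poisson number of
infinite-sites mutations at uniformly drawn positions (the indel block is
reserved), then applies three controlled violations:

* **Repeat mutations** — the event the `p = m/(3L)` model prices: the same
  position and derived base planted on a second branch. Planting is
  restricted to branch pairs whose conflict is *detectable*: disjoint tip
  sets (a repeat below an ancestor of the first hit changes nothing), and
  a combined carrier set whose split is incompatible with every branch of
  the unrooted genealogy — otherwise the repeat aliases a single mutation
  on an existing branch and no method could observe it. Either an exact
  count (`n_homoplasies`) or a per-mutation probability (`homoplasy_prob`)
  can be requested; in the probabilistic mode a flagged mutation with no
  detectable partner redirects to a feasible donor so the planted total
  stays Binomial(m, prob).
* **Recombinants** — mosaic haplotypes `parent1[1..b] + parent2[(b+1)..L]`
  appended as extra nodes, so the tree truth stays well defined.
* **One indel** — a multi-column deletion carried by an explicit haplotype
  set or by `"clade"`, which resolves to the largest clade holding at most
  half the tips so the deletion segregates as a single tree-consistent
  character.

Samples are replicated per haplotype with group labels, and a truth record
(genealogy, per-branch mutations with homoplasy flags, recombinants, indel
carriers, membership, root sequence) is emitted alongside.
`truth_replay()` rebuilds the alignment from the truth record alone with no
random number generation; byte-identical replay is the generator's closure
property and is tested.

`sim_preset_domestication()` fixes the survey-scale conditions used by the
integration tests: 2560 bp, 113 samples in 7 groups (two wild, five
cultivated), 9 genealogy tips plus 2 recombinants giving 11 haplotypes,
2 fixed mutations per branch and 2 planted repeats (39 total edge
occurrences), and a 46-bp clade deletion starting at column 562. Wild
groups spread over five haplotypes with higher diversity; the `dehiscent`
group is fixed for a single private haplotype, emulating the classic
primitive-cultivated pattern. These defaults are the reference conditions:
they were chosen once for scale parity and are not tuned per analysis.

## What the generator does and does not emulate

It reproduces the statistical structure the method assumes: genealogical
haplotype sharing, group-structured bottlenecks, detectable repeat
mutation, mosaic recombination, an indel as a single character. It does
not emulate sequencing error, alignment error, heterozygous base calls,
indel polymorphism beyond one event, gene conversion, or
coalescent-with-recombination breakpoint processes. Passing tests
therefore validate the algorithms on data meeting the model's assumptions;
they do not certify behaviour on raw survey data with alignment artefacts.

# Validation design and problem sizes

* π against a brute-force double loop (200 random fixtures, and at every
  module test).
* `Rm` against a dynamic-programming maximum over all four-gamete
  intervals on alignments of up to 12 sites.
* `branch_test` against exhaustive enumeration of outcome sequences for
  `N ≤ 10`.
* Tree-only simulations must give acyclic networks, every planted mutation
  on exactly one edge, `H_net = 0` and `Rm = 0`.
* The mean network homoplasy count over 1000 matched simulations
  (4-tip genealogies, 24 mutations, `homoplasy_prob = m/(3L)`, L = 2560)
  must sit within 3 Monte-Carlo standard errors of `m²/(3L)`. The 4-tip
  genealogy is used because there every detectable repeat is a cross-pair
  conflict whose network count is identifiable; on deeper trees a repeat
  involving a long internal branch can be reconstructed as an equally
  parsimonious rearrangement with a different repeat count (see
  limitations), which would test the reconstruction's identifiability
  rather than the calibration of the planting model.
* Dating recovery on star genealogies with Poisson branch mutations at two
  rates: the mean relative error of the recovered centre age must shrink
  as branch mutation counts grow.

# Known limitations

* The network is a heuristic parsimony construction. On data with repeats
  involving deep internal branches, equally or nearly equally parsimonious
  reconstructions can redistribute which characters repeat; the homoplasy
  count is then approximate. The Steiner improvement pass removes the
  worst of this, but no polynomial construction can make the count
  identifiable in general.
* Reticulations require tied alternative links; conflicts on long-branch
  data may be represented as repeated labels on a path instead of a cycle,
  in which case they are invisible to the event enumerator (though not to
  the homoplasy count).
* The binomial recombination test conditions on the reconstructed `m` and
  `H`; it does not propagate reconstruction uncertainty.
* Dating assumes a strict clock on substitution depth; no rate variation,
  no uncertainty intervals. For credible intervals, export the NEXUS
  haplotypes and use a Bayesian dating tool.
* Neutrality-test significance uses published critical-value bands, not
  locus-specific coalescent simulation.
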