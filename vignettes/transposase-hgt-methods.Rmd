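---
title: "Tracing interphylum HGT with transposase genes: models and methods"
author: "istrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing interphylum HGT with transposase genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(istrace)
```

## The problem

Insertion sequences (IS) are the simplest autonomous mobile elements of
bacterial genomes: a transposase gene flanked by short repetitive ends,
usually an inverted-repeat (IR) pair. Because transposases promote their own
duplication and ISs periodically go extinct and get re-seeded into genomes
from outside, transposase genes are an unusually sensitive tracer of
horizontal gene transfer (HGT) — including transfers across phyla, as
reported between *Fervidobacterium* (Thermotogae) and thermophilic
Firmicutes such as *Caldicellulosiruptor*.

`istrace` implements that detection procedure as a reproducible pipeline.
The question it answers, per transposase group in a query genome, is: *do
the closest relatives of this element live outside the query phylum?* Three
independent evidence lines are combined:

1. **Protein similarity** of the transposase to comparator sequences inside
   and outside the query phylum.
2. **Genomic signature**: tetranucleotide composition of the gene compared,
   by Kullback–Leibler (K-L) divergence, with comparator genes and whole
   genomes.
3. **IR conservation**: nucleotide identity of the repeat ends flanking the
   gene against the comparators' ends.

## Models and statistics

### Tetranucleotide profiles and K-L divergence

A sequence is summarised by its 256-dimensional vector of overlapping
tetranucleotide frequencies (step 1; windows containing N are skipped —
fractional attribution would make exact testing impossible for no benefit).
For a query profile $g$ and reference profile $G$,

$$D_{KL}(g \| G) \;=\; \sum_{i=1}^{256} g(i)\,\ln\frac{g(i)}{G(i)}$$

in natural-log units (nats), with $0 \ln 0 = 0$. The divergence is
asymmetric and non-negative, zero only for identical frequency vectors
(Gibbs' inequality); both properties are asserted in the test suite.

Zero counts would make $D_{KL}$ infinite, so profiles carry a Laplace
pseudocount, default $\alpha = 1$:
$g(i) = (n_i + \alpha)/(N + 256\alpha)$. The pseudocount is a parameter and
is recorded in every profile object. Gene sequences are counted on their
coding strand (they are oriented); whole-genome references use
`bothStrands = TRUE`, which makes the profile strand-symmetric.

`divergenceRanking()` reproduces the rank-vs-divergence view used to compare
a transposase against its relatives and against whole genomes: results are
sorted ascending with a stable id tie-break, so the ranking is invariant to
input order.

### Ordination

`nmdsEmbed()` performs non-metric multidimensional scaling (Kruskal
stress-1, monotone regression) of the profile distance matrix through
`vegan::monoMDS` — vegan being the tool such analyses conventionally use.
Choices that matter:

* **Dissimilarity**: Euclidean distance on frequency vectors by default;
  Bray–Curtis is available. Published NMDS plots of this kind rarely state
  the dissimilarity, which is why cluster membership, never coordinates, is
  the quantity one should compare.
* **Restarts**: restart 0 is the classical metric-MDS configuration
  (`cmdscale`), followed by `nRestarts` seeded Gaussian starts. All
  randomness sits behind one integer seed, and the embedding is
  bit-reproducible given `(seed, nRestarts, maxIter, tol)`.
* **Tie-breaking and degeneracy**: a later restart replaces the incumbent
  only if it improves stress by more than $10^{-6}$. Two-cluster data admit
  a classic degenerate NMDS solution — each cluster collapsed to a point,
  stress numerically zero, all within-cluster structure destroyed. Among
  effectively tied solutions the deterministic metric start wins, which
  keeps the structured configuration; a restart that is genuinely better
  still replaces it.

### IR detection and the end-identity metric

Published IS end tables were assembled by visual inspection. `istrace`
substitutes a reproducible scan, `findInvertedRepeats()`: the best local
alignment (match +1, mismatch −1, gap −2) between the upstream search span
and the reverse complement of the downstream span, each span being the full
flank plus `searchIn` (default 100) bases into the gene — repeats often
overlap the coding region, which is what the negative printed distances
mean. A hit requires aligned length ≥ `minLen` (20) and mismatch fraction ≤
`maxMismatchFrac` (0.25). The alignment is then trimmed to the *shortest*
segment attaining the maximal score: optimal local alignments can carry
zero-net-score extensions (chance matches balancing mismatches) that would
blur the repeat boundaries. Note that extensions with *positive* net score
are kept — they are indistinguishable from signal — so in random flanking
context the reported boundaries can exceed a planted repeat by a base or
two.

End identity follows the convention of the published tables, reverse
engineered and validated against 140 printed values: matches over scored
columns, where scored columns exclude columns gapped in *both* rows,
gap-vs-base columns count as mismatches, and the displayed value is
**truncated** (not rounded) to one decimal — 43/45 = 95.55… prints as 95.5.
Distances are signed bp from the repeat to the start (left) or stop (right)
codon, negative inside the coding region.

The dot-notation parser accepts the tables' format directly: an explicit
reference row; '.' for "same as reference", letters for substitutions, and
'-' or the typographic en-dash for gaps.

### Similarity, trees, bootstrap

`pairwiseProteinSimilarity()` aligns every pair globally (BLOSUM62, gap open
−10, extend −1) and reports percent identity over scored columns, truncated
to one decimal. Whether published "similarity" columns include conservative
substitutions varies by tool, so the definition is recorded in the object
and such columns should be compared only qualitatively.

`njTree()` is Saitou–Nei neighbor joining (`ape::nj`), exact on additive
distances; negative branch lengths are clamped to zero with a flag.
`bootstrapSupport()` resamples alignment columns with replacement, rebuilds
the p-distance NJ tree per replicate, and reports per-edge bipartition
frequencies; p-distance (pairwise deletion) is used deliberately — layering
a substitution model on top would add an unstated choice without changing
what the supports measure here.

### The HGT verdict

Groups are formed by single-linkage clustering of the query-taxon genes at
70% identity (published subgroupings state no numeric threshold; 70% is this
package's choice, exposed as a parameter and recorded in outputs). For each
group representative, with S the best similarity, the three evidence flags
are

* **E1**: $S_{out} - S_{in} \ge$ `margin` (default 10 percentage points,
  inclusive), where "out" is outside the query phylum and "in" is inside
  the phylum but outside the query genus — excluding the genus keeps recent
  within-genus duplications from masking the interphylum signal;
* **E2**: the minimum gene-vs-gene K-L divergence to an out-phylum gene is
  smaller than to any in-phylum other-genus gene;
* **E3**: IR identity to the best out-phylum partner is at least as high as
  to the best in-phylum partner on *both* ends; undetermined when repeats
  are missing.

The verdict is **y** iff E1 ∧ (E2 ∨ E3); an undetermined E3 does not veto.
The published evidence integration is narrative; this conjunction is one
deterministic formalization, chosen because E1 carries the phylogenetic
claim and either composition or repeat conservation must corroborate it.
Requiring all three lines is available to users by inspecting the flags. The
rule is monotone in `margin` (raising it never flips n→y) and invariant to
id relabeling, both property-tested.

## The synthetic study generator

Real interphylum comparisons need genome downloads and curated annotation.
`simulateHgtStudy()` instead builds the smallest world with the statistical
structure the analysis assumes:

* **Composition models** are order-3 Markov chains (64 trimer contexts ×
  4 next-base probabilities, rows drawn from a symmetric Dirichlet,
  concentration 5), because order 3 controls tetranucleotide statistics —
  exactly the analysis' feature space. The stationary tetramer distribution
  is available in closed form by eigen-decomposition, which supplies an
  independent oracle for generator tests.
* The **donor model** is redrawn by deterministic seed increments until its
  stationary composition diverges from the recipient's by ≥ 0.05 nats, the
  regime in which composition evidence is informative (typical draws land
  near 0.17–0.22 nats, so redraws are rare).
* **Elements** are left IR + ATG-initiated stop-free ORF + right IR
  (= reverse complement of the left; perfect palindromes on request).
  Defaults: 900-bp ORF, 30-bp IRs, 6 native families (recipient
  composition) and 6 transferred families (donor composition), one copy
  each implanted uniformly and non-overlappingly into a 100-kb recipient
  genome, each copy mutated by i.i.d. substitutions at rate μ = 0.01.
* **Comparators** encode the evolutionary scenario: every family gets one
  out-phylum comparator (*Caldicellulosiruptor*, Firmicutes) and one
  in-phylum comparator (*Petrotoga*, Thermotogae). For a transferred family
  the out-phylum comparator diverges at rate 0.05 and the in-phylum one at
  0.30 — recent interphylum transfer leaves the donor lineage closest; for
  a native family the rates are swapped. The rates are the generator's
  definition of "close relative" (≈95% nucleotide identity) versus
  "distant relative" (≈70%), bracketing the similarity contrasts the
  published comparisons show.
* Everything derives from one master seed; the truth table records origin,
  coordinates and applied substitutions for every copy, and coordinate
  consistency is asserted exactly.

What the generator deliberately does **not** emulate: indels (substitutions
only, so truth alignments stay trivial), target-site duplications, rate
heterogeneity or any explicit phylogeny, gene density around insertion
sites, and real within-genus population structure. Passing the recovery
benchmark therefore shows the pipeline is correct and well-calibrated under
its own assumptions — not that real genomes meet those assumptions.

## Problem sizes and numerical choices in the checks

The test suite exercises: identity reproduction on all verified printed
table rows; Gibbs' inequality on 1,000 random profile pairs; NJ against a
brute-force topology-enumeration oracle (all unrooted topologies,
least-squares branch fitting) on 100 random additive matrices with up to 6
taxa; NMDS exactness on planar configurations and rank preservation
(Spearman ≥ 0.9) on two-cluster profiles; the IR scan against an exhaustive
Smith–Waterman oracle on ≤200-bp windows and a 100-draw Monte-Carlo null on
1-kb random flanks; and end-to-end label recovery over 20 master seeds
(240 elements), requiring sensitivity ≥ 0.9 at false-positive rate ≤ 0.1.
These sizes keep the whole suite at a few minutes on one core while leaving
every threshold meaningfully testable.

Degenerate inputs are defined, not crashed on: all-equal distance matrices
warn and return an arbitrary configuration; identical bootstrap rows are
flagged degenerate with NA supports; genes without flanks yield "no repeat"
with a logged reason; a group with no out-of-phylum comparator is called
"n" with reason `no interphylum context`.

## A worked run

```{r, eval = FALSE}
library(istrace)

## published end table -> identities
da <- parseDottedAlignment(system.file("extdata", "typeC_left_end.tsv",
                                       package = "istrace"))
endIdentityTable(da, end = "left")

## synthetic study -> verdicts
sim <- simulateHgtStudy(seed = 1)
res <- analyzeStudy(sim)
familyReport(res$calls, res$groups)

## or file-based, via the pipeline
cfg <- runConfig(outDir = "istrace_out", seed = 1)
cfg <- runPipeline(cfg)
```

## Known limitations

* The IR scan's boundaries are score-optimal, not biologically curated;
  they can differ from hand-curated ends by a few bases, which is why the
  shipped fixtures feed the *printed* alignments to the identity metric.
* "Similarity" is percent identity; figure columns produced with
  conservative-substitution scoring will differ numerically.
* The caller's verdict quality on real genomes depends on comparator
  choice: without a reasonably close out-phylum comparator set, E1 cannot
  fire and elements default to "n".
* k ≠ 4 signatures are supported mechanically but none of the published
  validation applies to them.
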