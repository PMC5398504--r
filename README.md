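# istrace

Transposase-centred detection of interphylum horizontal gene transfer (HGT)
in bacterial genomes.

Insertion sequences (IS) — a transposase gene flanked by short inverted
repeats (IRs) — are repeatedly lost from and re-seeded into prokaryotic
genomes, which makes transposase genes a sensitive tracer of HGT, including
transfers across phyla (e.g. between *Fervidobacterium*, phylum
Thermotogae, and thermophilic Firmicutes such as *Caldicellulosiruptor*).
`istrace` is for microbial genomicists who want that analysis as a tested,
seeded pipeline rather than a one-off: given a genome, its transposase gene
coordinates, and taxon-labelled comparator sequences, it scores every
element group on three independent evidence lines and issues a y/n
interphylum-HGT verdict.

## The method

1. **Genomic signature.** Each gene is summarised by its 256-dimensional
   tetranucleotide frequency vector *g* and compared with a reference
   profile *G* by Kullback–Leibler divergence, in nats:

   D<sub>KL</sub>(g‖G) = Σ<sub>i</sub> g(i) ln( g(i) / G(i) )

   with Laplace pseudocount α = 1 keeping the divergence finite.
   `divergenceRanking()` produces the rank-vs-divergence view against genes
   and whole genomes; `nmdsEmbed()` ordinates profiles by non-metric MDS
   (Kruskal stress-1, seeded restarts, bit-reproducible).
2. **IR conservation.** `findInvertedRepeats()` scans the 1-kb flanks (plus
   100 bp into the gene) by local alignment for the repeat pair;
   end identity between taxa is computed as in the published IS end
   tables: matches / (columns − columns gapped in both rows), gap-vs-base
   counting as mismatch, **truncated** to one decimal.
   `parseDottedAlignment()` reads the tables' dot notation directly.
3. **Phylogeny.** `pairwiseProteinSimilarity()` (global BLOSUM62 alignment,
   percent identity), `njTree()` (neighbor joining) and
   `bootstrapSupport()` (column resampling, bipartition frequencies).
4. **Verdict.** Per single-linkage group, with S the best percent
   similarity of the representative: E1 = S_out − S_in ≥ 10 points (out =
   other phylum; in = same phylum, other genus), E2 = lower K-L divergence
   to an out-phylum gene than to any in-phylum one, E3 = IR identity to the
   best out-phylum partner ≥ in-phylum on both ends. **Verdict y iff
   E1 and (E2 or E3).**

A fully seeded synthetic-study generator (`simulateHgtStudy()`: order-3
Markov genomes, implanted IS elements, labelled comparators, truth table)
makes every stage testable without downloading genomes.

## Worked example

Identities recomputed from a shipped IS end-table transcription (type C
transposase group, left end; reference 646_Fp from *F. pennivorans*):

```r
library(istrace)
da <- parseDottedAlignment(system.file("extdata", "typeC_left_end.tsv",
                                       package = "istrace"))
head(endIdentityTable(da, end = "left")[, c("rowId", "distance", "matches",
     "scoredColumns", "identityPct", "printedIdentity")], 7)
#>    rowId distance matches scoredColumns identityPct printedIdentity
#>  1012_Fp       41      59            59       100.0           100.0
#>   687_Fp       41      59            59       100.0           100.0
#>    43_Fi       41      59            59       100.0           100.0
#>       T1       41      59            59       100.0           100.0
#>       T2       41      57            59        96.6            96.6
#>       T3       41      57            59        96.6            96.6
#>       T7       82      49            60        81.6            81.7
```

Rows T1–T3 are *Caldicellulosiruptor lactoaceticus* repeats at 96.6–100%
identity to the *Fervidobacterium* reference — the interphylum signal the
verdict formalizes. (T7 is one of the few printed values that does not
reproduce under the tables' own truncation convention; see the fixture
verification manifest in `inst/extdata/`.)

End to end on a synthetic study — 100-kb recipient genome, 6 native + 6
transferred elements, labelled comparators:

```r
sim <- simulateHgtStudy(seed = 1)
res <- analyzeStudy(sim)
familyReport(res$calls, res$groups)[1:4, c("groupId", "representative",
    "verdict", "sOut", "sIn", "e1", "e2", "e3")]
#>  groupId representative verdict sOut  sIn   e1   e2   e3
#>       G1        hgt1_c1       y 87.6 47.3 TRUE TRUE   NA
#>       G2        hgt2_c1       y 87.3 43.3 TRUE TRUE TRUE
#>       G3        hgt3_c1       y 91.0 43.3 TRUE TRUE TRUE
#>       G4        hgt4_c1       y 84.6 39.3 TRUE TRUE TRUE
```

`sOut`/`sIn` are the representative's best protein identities outside and
inside the query phylum; all transferred elements are called `y` and all
native ones `n` on this seed. The same analysis runs file-based through
`runPipeline(runConfig(outDir = "out", seed = 1))`, which writes
TSV/JSON artifacts plus a manifest, or from a shell via
`inst/scripts/istrace.R`.

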