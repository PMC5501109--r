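# exonweaver

Exon-aware annotation of multi-exon paralogous gene families in fragmented
genome assemblies, with downstream tools for the molecular evolution of the
family: intron gain/loss parsimony, retrogene/pseudogene classification,
specificity-determining positions and conservation profiling.

## The problem

Draft genome assemblies scatter multi-exon genes over several short contigs.
Conventional gene predictors and orthology databases consequently under- or
over-count the members of paralogous gene families — exactly the genes whose
duplication history one wants to reconstruct. exonweaver annotates such
families in two steps:

1. **Exon search.** From a curated protein alignment with per-column exon
   annotation, one ungapped position-specific scoring matrix (log-odds,
   bits) is built per *(paralog group, exon)*. All six reading frames of
   every contig are scanned; windows above threshold become exon hits.
2. **Copy assignment.** Hits are assigned to paralogous gene *copies* by an
   exact branch-and-bound optimizer. With binary variables `x[h,p,k]` ("hit
   `h` belongs to copy `k` of paralog `p`") it maximizes

   `sum score(h) * x[h,p,k]  -  penalty * sum y[p,k]`

   subject to: each hit used at most once; each exon slot of a copy used at
   most once; hits of one copy on one contig non-overlapping and colinear
   (exon index increasing along the strand-oriented coordinate); overlapping
   hits on one contig mutually exclusive across all copies (one locus encodes
   one exon); `y[p,k]` open-copy indicators with symmetry breaking. The
   optimum is certified against an independent brute-force enumerator.

Copies are then assembled **across contig boundaries**, classified as
intact / pseudogene / retrogene / pseudo-retrogene, and their exon-intron
structures homologized: every intron is expressed as *reference residue +
phase* (e.g. `85c` = after the third base of reference codon 85), diffed
against the family structure, and checked for the protosplice context
`AG|GY` at the insertion site. Gain/loss histories are reconstructed on a
gene tree by Sankoff/Fitch/Dollo parsimony, and paralog censuses from two
annotation sources are compared. A four-method consensus
(sequence-harmony-style JSD, multi-RELIEF, Xdet, multiple correspondence
analysis; a position counts when at least two methods retrieve it) detects
specificity-determining positions, and per-column conservation uses the
Karlin sum-of-pairs score `s(a,b)/sqrt(s(a,a) s(b,b))`.

A built-in gene-family evolution simulator (whole-genome duplication, tandem
duplication, gene loss, pseudogenization, retrogene formation,
protosplice-biased intron gain/loss, K80 substitutions, assembly
fragmentation with intron-biased breakpoints) provides complete ground truth
so the entire pipeline is testable offline.

## Worked example

```r
library(exonweaver)

# simulate the reference scenario: 8 species, one WGD, one tandem
# duplication + pseudogenization, one retrogene, one loss, one
# protosplice-biased intron gain; fragmented assemblies (bias 1.0)
sc  <- demo_scenario(seed = 1)

# annotate one species' assembly with models built from the family alignment
res <- annotate_assembly(sc$assemblies$s8$contigs, sc$aln, max_copies = 2)
res$classifications
#>         gene paralog n_exons_found n_exons_missing     class n_stops n_frameshifts
#> 1 gene.fam#1     fam             8               0    intact       0             0
#> 2 gene.fam#2     fam             8               0 retrogene       0             0
```

Species s8 carries the ancestral gene plus a planted retrogene; both copies
are recovered with all 8 exon segments, and the single-exon copy is
classified as a retrogene. Recovery of the whole scenario:

```r
evaluate_demo_recovery(sc)[c("segment_recovery", "copy_counts_exact",
                             "gain_label", "gain_protosplice")]
#> $segment_recovery   [1] 0.9807692
#> $copy_counts_exact  [1] TRUE
#> $gain_label         [1] "41c"
#> $gain_protosplice   [1] TRUE
```

98% of planted exon intervals are hit at the exact coordinates, every
copy count is exact, and the planted intron gain is recovered at its
coordinate label with the protosplice context confirmed. Parsimony then
counts independent gains of a character on the gene tree:

```r
tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
r  <- sankoff_parsimony(tr, c(A = 1, B = 0, C = 1, D = 0), root_prior = 0)
count_independent_gains(r)$gains
#> [1] 2
```

## Vignette

`vignettes/exonweaver-methods.Rmd` documents the models, the solver
formulation, all tunable parameters with defaults, the simulator's design
choices, and what the synthetic validation does and does not demonstrate
about real assemblies.
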