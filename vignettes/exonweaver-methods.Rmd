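---
title: "Annotating multi-exon paralogs in fragmented assemblies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating multi-exon paralogs in fragmented assemblies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonweaver)
```

# Scope and model

exonweaver annotates multi-exon paralogous gene families in fragmented
genome assemblies and analyzes the family's structural evolution. The
package assumes:

* a **curated protein alignment** of the family exists, with every sequence
  assigned to a paralog (orthology) group and every column assigned to a
  family exon (or to none);
* family exons are **near-fixed-length** across members — coding indels are
  rare at the timescales of interest — so exon models can be ungapped;
* contigs are **unordered and unoriented**: a gene copy may be spread over
  several contigs, and nothing is known about contig adjacency.

All internal genomic coordinates are 0-based half-open on the forward
strand; GFF3 I/O converts to and from 1-based inclusive coordinates with CDS
phase validation. Protein positions are 1-based, matching the residue
numbering used in reported positions such as "85c".

# Step 1: exon- and paralog-specific scoring models

For each (paralog group, exon) pair, a position-specific scoring matrix over
the 20 amino acids is built from the group's alignment columns:

$$\mathrm{pssm}[a, j] \;=\; \log_2 \frac{(c_{aj} + \beta\, b_a)/(n_j + \beta)}{b_a}$$

with observed counts $c_{aj}$, non-gap column depth $n_j$, background
frequencies $b$ (BLOSUM62 marginals by default) and pseudocount weight
$\beta = 0.1$. Gap-majority columns are dropped. Ungapped log-odds models
rather than full profile HMMs are used deliberately: with length-stable
exons, gap states add machinery without discrimination; a profile-HMM
backend remains a clean extension point behind the same model interface.

Scanning translates all six reading frames of every contig (codons
containing `N` and stop codons contribute 0 bits; windows with more than 20%
stops are discarded so pseudogene exons with isolated stops remain
detectable). Hit thresholds:

* relative: `threshold_frac` (default 0.25) of the model's maximal
  attainable score;
* absolute floor: `min_hit_bits` (default 17 bits). Short exon segments
  (10–20 codons) have low maximal scores, and a genome-scale scan evaluates
  on the order of $10^5$–$10^6$ windows per model; the floor was calibrated
  once against simulated non-homologous sequence, where random windows
  essentially never reach 17 bits while true segment hits of copies at the
  divergence levels the package targets score well above 30.

Overlapping hits of the same model on a contig are reduced to local score
maxima. At contig edges, model prefixes/suffixes of at least 10 codons are
scored and emitted as `partial` hits, so exons split by assembly breakpoints
remain representable. `refine_splice_boundaries()` optionally snaps hit
boundaries to the nearest canonical `AG` acceptor / `GT` donor within a
window, requiring the two shifts to preserve the exon's coding phase.

# Step 2: exact assignment of hits to gene copies

The assignment problem: given hits $h$ with scores, decide which hits form
which copy of which paralog. Binary variables $x_{h,p,k}$ (hit $h$ serves
copy $k$ of paralog $p$; only $p$ = the hit's own model label) and open-copy
indicators $y_{p,k}$, maximizing

$$\sum_h s(h)\, x_{h,p,k} \;-\; \pi \sum_{p,k} y_{p,k}$$

subject to:

1. each hit serves at most one copy;
2. within a copy, each family exon index is used at most once (two `partial`
   hits of one exon on *different* contigs may share the slot in
   split-exon mode);
3. hits of one copy sharing a contig must be non-overlapping and colinear —
   exon index strictly increasing along the strand-oriented coordinate;
4. overlapping hits on one contig are mutually exclusive across **all**
   copies. This extends the within-copy constraint: paralog models of one
   family are homologous, so one genomic locus typically produces a hit per
   model, and without global exclusivity a single locus could "support"
   several copies at once, inflating copy counts;
5. symmetry breaking $y_{p,k} \ge y_{p,k+1}$.

The default penalty $\pi$ is the mean maximal model score: a spurious copy
must be supported by roughly one full exon's worth of evidence beyond what
other copies can absorb. `max_copies` (K) defaults to 1; scans for tandem or
whole-genome duplicates use K = 2. A `contig_level` mode forces all hits of
a contig into one copy, reproducing the coarser contig-to-paralog
granularity.

The solver is an exact depth-first branch-and-bound: hits are processed in
decreasing score order; the admissible bound adds, per contig, the
max-weight set of pairwise non-overlapping remaining hit intervals (weighted
interval scheduling), which any feasible completion cannot exceed.
Optimality is verified in the test suite against an independent brute-force
enumerator on hundreds of randomized instances, and every solution is
re-validated post hoc against the constraint set. Problems decompose into
connected components (shared contig or shared paralog) that are solved
independently without loss of optimality. Ties are resolved
deterministically (lexicographic paralog label, contig, start).

# From copies to structures

`solution_to_gene_models()` turns each opened copy into a gene model with
its missing family exons recorded. Because some exons may genuinely lack
hits, downstream structure interpretation is structure-aware
(`recovered_introns()`):

* a genomic gap between consecutive observed exons is reduced by the
  expected coding length of the undetected exons between them; only the
  residual (≥ 4 nt by default) is an intron. A retrogene with one
  undetected interior segment is therefore not miscalled as intron-bearing;
* an intron spanning a contig boundary (consecutive exons on different
  contigs, nothing missing between) is called from splice evidence — a `GT`
  donor after the upstream exon and an `AG` acceptor before the downstream
  one — with unknown length;
* the 4-base exonic junction context is read from the observed exon flanks,
  so the protosplice motif `AG|GY` can be tested even when the intron's
  exact span is ambiguous or split across contigs.

Intron positions are mapped to **reference coordinates**: for an intron
after coding base $n$, the own codon is $\lceil n/3 \rceil$ with phase
$((n-1) \bmod 3) + 1$ written a/b/c, and the codon index is projected
through a pairwise alignment onto the designated reference protein
(`85c` = after the third base of reference codon 85). Introns projecting
into reference gaps are flagged `unplaced` and excluded from structure diffs
and parsimony characters rather than forced onto a residue. Structure diffs
merge coordinates within ±1 residue (annotation jitter of a few nucleotides
is common near short exons); the tolerance is configurable.

Copy classification: a single-exon copy in a multi-exon family is a
**retrogene**; premature stops or frameshifts make a **pseudogene** (both:
**pseudo-retrogene**). Frameshifts are assessed per exon as observed-length
vs expected-model-length mod 3 on the homologous span covered by hits, so
assembly gaps are not miscalled as frameshifts; stop codons are counted from
the translated assembled CDS.

# Event parsimony

Binary characters (intron presence at a coordinate, gene presence) live on a
gene tree. `sankoff_parsimony()` runs the standard dynamic program under
separate gain/loss costs; `?` cells contribute zero cost to both states. The
root prior defaults to 0 (character absent at the family root) and is
implemented as a virtual ancestral branch, so a root-state change is counted
as an event and reported as such — "gained $k$ times independently" claims
are prior-dependent and the package always reports the prior used, the
number of equally parsimonious labelings (counted exactly), and the min/max
number of gains across all optima. The materialized labeling breaks ties
toward the absent state, placing gains tipward. `fitch_count()` provides the
unit-cost minimum-change count (cross-checked against the Sankoff DP and
against an independent implementation in the test suite), and
`dollo_reconstruction()` the single-origin model appropriate for
gene-presence characters. `census_compare()` tallies per-species paralog
counts from two annotation sources; the discrepancy percentage is rounded
half-up to integer percent (25 of 57 → 43.86 → 44).

# Specificity-determining positions and conservation

Four complementary per-column scorers, combined by the rule that a position
counts only when **at least two of the four** methods retrieve it:

* **Sequence-harmony style** (`sequence_harmony()`): 1 − Jensen–Shannon
  divergence (base 2) between the two groups' residue distributions (gaps as
  21st symbol); identical distributions score 1, disjoint 0. Z-scores use
  median/MAD rather than mean/sd: with even a few truly separating columns
  the outliers themselves inflate the standard deviation, capping attainable
  |z| near $\sqrt{n_{cols}/n_{outliers}}$ and making a cutoff of −6
  unreachable precisely when strong signal exists; robust scaling restores
  the intended meaning of "many deviations below the bulk". Default cutoff
  z < −6.
* **multi-RELIEF** (`multi_relief()`): RELIEF weights with 0/1
  residue-identity distance, nearest hit/miss per sequence, ties broken at
  random per iteration, averaged over iterations and group pairs; in
  [−1, 1], perfectly separating columns score 1. Default cutoff > 0.7.
* **Xdet** (`xdet()`): Spearman rank correlation, per column, between
  pairwise residue similarities (BLOSUM62) and a binary same-group function
  matrix; zero-variance columns are flagged, not scored. The default cutoff
  keeps scores **< 0.6** as printed in the methodology this follows; the
  polarity is deliberately config-exposed (`xdet_keep_below`) rather than
  silently "corrected", because the consensus rule makes the pipeline robust
  to either choice: a permissive single method cannot create a consensus
  position on its own.
* **MCA** (`mca_grouping()`): correspondence analysis of the binary
  residue-state indicator matrix via SVD of standardized residuals.
  Singleton states are excluded (their chi-square weights dominate the
  leading axes while carrying no grouping information); sequences are
  clustered by k-means on up to three leading axes (or taken from labels in
  supervised mode). A column is flagged when one of its states covers at
  least 80% of a cluster, occurs only there, and its state point lies within
  the configured cosine (default 0.9) of the cluster centroid direction.

Conservation uses the Karlin sum-of-pairs score,
$C(j) = \binom{N_j}{2}^{-1} \sum_{i<k} s(a_i,a_k)/\sqrt{s(a_i,a_i)\,s(a_k,a_k)}$
over non-gap pairs, so identical columns score exactly 1. Sequences with
coverage ≤ 90% are excluded first (configurable), and columns with fewer
than two residues are flagged.

Alignment filtering follows the family-analysis conventions: coverage
> 70% (gap fraction), greedy redundancy removal at ≥ 98% identity on shared
columns (keep-first in input order; a threshold of 1 disables the rule), and
an optional unaligned-length window.

# The synthetic evolution model

`simulate_family()` evolves one ancestral multi-exon gene along a rooted
species tree:

* **events** per branch (probabilities, or deterministic `planted_events`):
  whole-genome duplication at designated nodes (every gene duplicates and
  the ohnolog sets are relabeled `label.1`/`label.2`), tandem duplication
  (same label, placed 5–20 kb downstream), gene loss, pseudogenization
  (planted premature stops or a 1-nt frameshift), retrogene insertion
  (intronless copy of the spliced CDS at a random intergenic position, no
  target-site duplication), intron gain and loss;
* **substitutions**: K80 with transition/transversion ratio 2.0 by default,
  expected distance = rate × branch length; chance stop codons in intact
  genes are redrawn so only planted pseudogenes carry stops; no coding
  indels — exon models assume length stability, and the simulator honors
  that assumption;
* **splice constraint**: the terminal `GT`/`AG` of every intron and the two
  exonic bases flanking every junction are held fixed, reflecting
  splice-site consensus constraint (and, empirically, the conservation of
  the `AGGY` junction motif across clades that carry a gained intron);
* **intron gain**: candidate positions are codon-aligned (phase c — the
  documented hotspot phase; `plant_intron_gain()` itself supports all three
  phases and is tested exhaustively for them), at least 30 nt from existing
  boundaries so both daughter segments stay detectable, and — with
  probability `protosplice_bias`, default 1 — inside an exonic `AG|G[CT]`
  context. For a planted biased gain with no surviving context, the motif is
  engineered at the insertion site (Gln-Ala junction), modeling the
  endonuclease-target motif the insertion mechanism requires;
* **genome layout**: genes in random orientation with random intergenic
  spacers (1–3 kb); new introns drawn uniform 70–2000 nt; ancestral gene
  defaults 7 exons × 30 codons;
* **fragmentation** (`fragment_assembly()`): breakpoints partition the
  genome; with probability `breakpoint_bias_intron` each breakpoint avoids
  exons entirely.

The reference validation scenario (`demo_scenario()`) uses an
eight-species balanced tree with unit branches, substitution rate 0.1 per
unit (root-to-tip expectation 0.3 substitutions/site), one WGD, one tandem
duplication whose template is then pseudogenized, one retrogene, one gene
loss, and one protosplice-biased intron gain, with six contigs per genome at
breakpoint bias 1.0. These problem sizes keep a full pipeline run around
twenty seconds while exercising every event type.

**What passing synthetic tests does and does not show.** The simulator
produces clean FASTA contigs with uniform-random intergenic sequence, no
repeats or transposons, no sequencing error, no coding indels, and
phase-c intron gains; divergence is modest (≤ 0.3 substitutions/site from
the family ancestor). Success under these conditions demonstrates the
correctness of the machinery — exact optimality of the assignment, exact
coordinate arithmetic, classification logic — not the sensitivity of PSSM
scanning on deeply diverged real families, where curation of the input
alignment and manual inspection of boundary cases remain essential. Event
rates are calibrated (binomially tested in the suite), but the simulator is
an artifact model: real gene families do not evolve by per-branch
Bernoulli events.

# Numerical and degenerate-input choices

* Ties in the solver and in parsimony backtracking are broken
  deterministically (documented above), so identical inputs and seeds give
  byte-identical outputs.
* The empty assignment is always feasible; an empty hit list yields the
  empty solution with objective 0.
* All-gap alignment columns are flagged and excluded by every scorer, never
  scored as 0; columns that cannot be scored (zero variance in Xdet, < 2
  residues in Karlin) are flagged likewise.
* MCA on degenerate geometry (rank below groups − 1, or identical
  sequences) returns fewer clusters with a warning rather than failing.
* `?` character cells are missing data everywhere (zero-cost in Sankoff,
  full state set in Fitch, never coerced to 0), supporting cases where an
  intron's exact position cannot be resolved from the available assembly.
* The brute-force assignment oracle is guarded at 14 hits, the
  branch-and-bound at $10^5$ hit × copy variables; beyond that the error
  advises decomposition by connected component.

# Known limitations

* No spliced-alignment (dynamic programming across introns) or
  frameshift-tolerant alignment: severely decayed pseudogene fragments
  below the bit floor are invisible.
* Exon models are ungapped; families with frequent coding indels need a
  profile-HMM backend.
* Cross-contig colinearity cannot be enforced (contig order is unknown), so
  equally scoring degenerate assignments of hits to copies across contigs
  are possible in principle; the locus-exclusivity constraint and the copy
  penalty remove the cases observed in practice.
* The paralog census comparator takes the curated annotation as ground
  truth by construction.
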