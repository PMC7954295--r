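---
title: "Clustering phages by shared gene content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering phages by shared gene content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacteriophage genomes are mosaics: genes move between lineages faster
than whole genomes diverge, so any single relatedness metric is an
approximation. Historical cluster assignment for actinobacteriophages
required roughly 50% nucleotide identity over 50% of the genome span
with at least one existing cluster member. That rule fails in an
instructive way: a pair of phages can conserve essentially every
protein while sharing no detectable nucleotide identity, because
purifying selection preserves amino acids while synonymous sites
saturate. A phage in that situation looks like a singleton to BLASTn
and like a solid cluster member to a proteome comparison.

phamflock implements the gene-content route around this problem. Genes
are grouped into *phams* — families of proteins related by amino-acid
similarity — and phages are compared by the phams they share, not the
bases they share.

## The statistics

For two phages with distinct-pham sets $P_A$ and $P_B$ and
$s = |P_A \cap P_B|$ shared phams,

$$\mathrm{GCS}(A,B) = 100 \cdot \frac{s/|P_A| + s/|P_B|}{2}, \qquad
  \mathrm{GCD}(A,B) = 1 - \mathrm{GCS}(A,B)/100 .$$

GCS is the mean of the two directional shared-gene percentages;
duplicated phams within one genome (paralogs) count once. A direct
consequence, asserted as a test property, is that the same number of
shared genes yields higher GCS between smaller genomes: at fixed $s$
and $|P_A|$, GCS is strictly decreasing in $|P_B|$. Genome size
therefore matters when interpreting GCS near a threshold.

**MaxGCDGap** measures how isolated a focal phage is from a
population: sort its pairwise GCD values ascending, prepend 0 (its
distance to itself), and take 100 times the largest difference between
consecutive values. Including the leading gap means a phage whose
*nearest* neighbor is already distant scores a large gap; that is the
reading under which the gap sits "between" the focal phage and its
nearest neighbor and equals $100 - \max \mathrm{GCS}$ whenever the
leading gap dominates. Because the alternative convention (consecutive
gaps only) also exists in circulation, `gcd_profile()` exposes
`gap_from_zero = FALSE`; the default is `TRUE`.

**Clustering** takes the graph with an edge wherever
$\mathrm{GCS} \ge$ a threshold (default 35%) and reports connected
components. One qualifying partner suffices for membership — the rule
is "35% shared gene content with at least one phage in a cluster" — so
a phage can legitimately bridge two formerly separate clusters into
one component. Cluster labels are assigned by descending size with
lexicographic tie-breaks, making output independent of input order.

## Pham assignment

The literature behind pham databases names amino-acid identity as the
grouping basis but no single canonical algorithm. This package defines
the operation precisely so that it is testable:

* every protein pair is aligned globally with free terminal gaps
  (match +1, mismatch 0, gap opening 2, gap extension 0.5), via
  `Biostrings::pairwiseAlignment(type = "overlap")`;
* identity is identical columns over alignment columns excluding
  terminal gaps; coverage is the aligned span of the shorter sequence
  over its length;
* an edge is kept when identity ≥ 35% and coverage ≥ 75% (both
  configurable; values chosen near historical pham-building practice);
* phams are the connected components (single linkage), which makes a
  brute-force transitive-closure oracle exact and is what "groups of
  genes with related sequences" means operationally.

Because match-only scoring admits many co-optimal alignments, the pair
is always aligned in a canonical orientation (shorter sequence as
pattern, ties broken lexicographically); identity and coverage are
then exactly symmetric. A composition prescreen skips pairs whose
amino-acid multiset intersection is smaller than
$\mathrm{id} \times \mathrm{cov} \times \min(|a|,|b|)$ — a provable
upper bound on achievable matches — so it can never change the result,
only the runtime. A k-mer prescreen was considered and rejected:
identical columns need not be contiguous, so a shared-k-mer bound is
not lossless at a 35% identity threshold.

Exact reproduction of any external pham database's boundaries is not
promised; thresholds and tooling versions behind published pham counts
vary.

## The legacy nucleotide rule and dot plots

The 50%-identity/50%-span rule enters this package only as a
conservative screen: `nucleotide_span_coverage()` reports the fraction
of one genome covered by exact 15-mer matches (forward or reverse
complement) to another. Genuinely conserved nucleotide regions are
full of long exact words; heavy synonymous divergence destroys
essentially all of them. The screen deliberately errs toward calling
pairs *unrelated* at the nucleotide level and is documented as an
approximation, not a BLASTn reimplementation.

Dot plots are exact-word matches of concatenated genomes (word 15) or
concatenated proteomes (word 5), the conventional word sizes for these
two alphabets. Segments are joined by a word-length run of a sentinel
character outside both alphabets, so no match can cross a
concatenation boundary — a property the tests verify exhaustively.
Matches are emitted as coordinates plus a boundary table, keeping
rendering out of scope. Reverse-complement word matches are on by
default at the nucleotide level (orientation of a deposited genome is
arbitrary) and can be disabled.

## Phylogeny

`gcd_distance_matrix()` is simply the pairwise GCD matrix; it feeds
two consumers. `neighbor_joining()` is a standard Saitou–Nei
agglomeration written for determinism: Q-criterion ties break on the
lexicographically smallest taxon pair and negative branch estimates
clamp to zero. On additive matrices it reproduces path lengths
exactly (tested against `ape`'s implementation and against cophenetic
distances). `export_nexus_distances()` writes TAXA/DISTANCES blocks so
a split-network tool can draw the corresponding network phylogeny;
split decomposition itself is out of scope, and the uncorrected GCD is
used as the distance without further transformation.
`cluster_representatives()` caps each cluster at 10 members, chosen by
lexicographic name since no principled selection criterion is
available.

## Per-gene HGT evidence

Two signals are tabulated per gene: GC deviation from the genome mean
(in percentage points; N bases excluded from every GC denominator) and
the number of distinct isolation hosts among phages carrying the
gene's pham. Published analyses of this kind judge "unexpectedly high"
values by inspection; this package operationalizes the call as
*flagged iff GC deviation ≥ 5 points OR unique hosts ≥ 3*, with both
thresholds configurable and the full ranked table always returned so
any other cut can be applied. Host strings are compared exactly as
given (species + strain granularity); no taxonomy normalization is
attempted. Codon-usage and phylogenetic-incongruence tests are out of
scope.

## The synthetic population generator

`simulate_population()` generates annotated phage genomes with ground
truth, emulating the features the analysis depends on:

* **cluster-structured pham sharing** — each cluster has a core pham
  set, optionally overlapping other clusters, plus per-genome
  accessory genes and orphams;
* **protein conservation without nucleotide conservation** — every
  pham has a reference protein; members diverge by uniform amino-acid
  substitution at 5% per site by default (a substitution matrix would
  add realism the recovery tests do not need). Nucleotide sequences
  are produced by codon choice: members of one cluster share codon
  choices up to 2% synonymous noise, while between clusters each
  degenerate position is re-drawn with probability
  `synonymous_scramble_rate` (default 1), so proteins stay identical
  while 15-mer identity vanishes;
* **controllable GC** — codons are selected with a tilt
  $w \propto e^{\beta \cdot \mathrm{gc}}$ whose $\beta$ is solved per
  protein so expected GC hits the per-gene target; counts are
  allocated by largest remainder and then permuted, which keeps
  realized GC within a fraction of a point for gene-length sequences
  while still varying the sequence with the seed. Targets outside the
  protein's achievable range produce a warning and the closest
  achievable value. Reference proteins use an amino-acid composition
  biased toward GC-rich codons (like real high-GC actinobacterial
  proteomes); without that bias, targets above ~63% GC are not
  achievable at all for a random protein;
* **HGT implants** — designated focal-phage genes receive a GC-target
  offset and/or a set of small "carrier" phages on distinct novel
  hosts that carry the same pham, reproducing the two HGT signals;
* **determinism and extensibility** — population-level structure and
  each phage use RNG streams derived from the master seed, so a fixed
  seed is byte-reproducible.

Genomes are genes joined by 10–50 bp random spacers at the population
GC target, one reverse-strand gene per genome by default, and a
terminal stop codon per gene; realized genome sizes for the default
presets sit in the small (≈16–18 kb) range of real siphovirus genomes
at the short end of the known length distribution.

`bluefeather_scenario_params()` is the study-design preset: clusters
FE (3 phages), FI (2 phages) and a focal phage laid out so the focal
phage shares 9 core phams with everyone, 5 more with FI, 2 more with
FE, has 6 orphams, 2 paralogs, and a reverse-strand gene otherwise
found only in carrier phages. Those counts give GCS of 58.4% against
FI members and 45.9% against FE members with every pairwise GCS in
the group ≥ 36% — comfortably over the 35% parameter — and a
MaxGCDGap of ≈41.6% for the focal phage, while complete synonymous
scrambling keeps intercluster nucleotide span coverage near zero.

What the generator does **not** emulate: recombination breakpoints,
temporal dynamics, realistic codon-usage tables, gene-length and
intergenic-structure realism, or annotation errors. Passing recovery
tests therefore demonstrates that the pipeline measures what it claims
on data with the assumed structure, not that it is robust to every
artifact of real submissions.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (GenBank convention);
  reverse-strand gene records store the reverse-complemented coding
  sequence, and constructors verify both invariants base-for-base.
* Translation uses genetic code table 11 with the terminal stop
  removed; an internal stop is an error.
* GCS values are reported to 2 decimals; test comparisons use an
  absolute tolerance of 0.005.
* GCD sort ties break by phage name; all cluster/pham labels are
  canonical so repeated runs and permuted inputs agree exactly.
* The GenBank reader is intentionally minimal (simple and
  `complement()` CDS locations, `/translation` and `/product`
  qualifiers); compound `join()` locations are rejected loudly rather
  than misparsed. The paired writer exists mainly so round trips can
  be tested without network access; `simulate_bluefeather_like_record()`
  is a synthetic stand-in whose headline statistics (16,302 bp, 25
  genes, one reverse gene, 64.3% GC, per-gene GC targets spanning
  59.3–70.3%) are set by construction to those of a real small
  siphovirus record, so the parsing and GC machinery can be exercised
  end to end offline.
* Problem sizes throughout the tests — six 25-gene phages plus
  carriers, populations of a few dozen genes for oracle comparisons, a
  20-seed recovery sweep — were chosen so each check isolates one
  property at the smallest size where it is meaningful.

## Worked example

```{r, eval = FALSE}
library(phamflock)

pop <- simulate_population(bluefeather_scenario_params(seed = 1))
asg <- assign_phams(population_proteins(pop$genomes))
m   <- gcs_matrix(pham_profiles(asg))

cluster_by_gcs(m, threshold = 35)
gcd_profile("BlueFeather", pham_profiles(asg))
hgt_evidence_table(pop$genomes$BlueFeather, asg, pop$metadata)

## or the whole thing in one call, with outputs and a manifest:
run_pipeline(run_config(genomes = pop$genomes, metadata = pop$metadata,
                        out_dir = "scenario_out", focal = "BlueFeather"))
```

## Limitations

* Pham boundaries depend on alignment scoring; near-threshold pairs
  can flip with different gap penalties. The defaults are exposed, not
  hidden.
* GCS treats a genome as a set of phams: gene order (synteny) and gene
  length contribute nothing.
* The nucleotide screen is exact-word based and will undercount
  identity relative to an aligner in the presence of scattered SNPs;
  it is a screen, not a measurement.
* MaxGCDGap depends on the population it is computed against; adding
  or removing phages changes it. The monotonicity property (removing
  the nearest neighbor never decreases it) is tested, but absolute
  values are only meaningful with a stated population.
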