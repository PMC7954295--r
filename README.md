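# phamflock

Shared-gene-content analysis for bacteriophage populations.

## Why

Phage taxonomy historically clustered genomes by nucleotide identity
(≈50% identity over 50% span with at least one cluster member). That
rule misses a real biological situation: after long purifying
selection, two phages can conserve nearly every protein while sharing
no detectable nucleotide identity, because synonymous sites have
saturated. Such a phage looks like a singleton to nucleotide
comparison and like a cluster member to proteome comparison. The
gene-content route resolves this: group genes into **phams**
(amino-acid similarity families), compare phages by shared phams, and
cluster at a shared-gene-content threshold (35%).

phamflock is for comparative genomicists who want that analysis as
tested, reusable functions rather than a chain of web tools: pham
assignment from protein sequences, Gene Content
Similarity/Dissimilarity, MaxGCDGap, threshold clustering, exact-word
dot plots, gene-content neighbor-joining trees with NEXUS export for
split-network viewers, per-gene horizontal-gene-transfer evidence, and
a synthetic population generator with ground truth so every stage is
testable offline.

## The statistics

For phages with distinct-pham sets `P_A`, `P_B` and `s = |P_A ∩ P_B|`:

```
GCS(A,B) = 100 · (s/|P_A| + s/|P_B|) / 2        GCD = 1 − GCS/100
```

**MaxGCDGap** = 100 × the largest difference between consecutive
values of the focal phage's ascending GCD list with 0 prepended — the
degree of isolation of a phage from a population. **Clusters** are the
connected components of the GCS ≥ 35% graph; a single qualifying
partner suffices for membership.

## Worked example

A six-phage scenario: clusters FE (Corgi, Idaho, Noely) and FI (Whytu,
Yavru) plus the focal phage BlueFeather, generated with protein
conservation but complete between-cluster synonymous scrambling:

```r
library(phamflock)

pop <- simulate_population(bluefeather_scenario_params(seed = 1))
asg <- assign_phams(population_proteins(pop$genomes))
asg
#> <pham_assignment> 180 genes in 78 phams (40 orphams) at identity >= 35%, coverage >= 75%

m <- gcs_matrix(pham_profiles(asg))
six <- c("BlueFeather", "Corgi", "Idaho", "Noely", "Whytu", "Yavru")
round(m[six, six], 2)
#>             BlueFeather  Corgi  Idaho  Noely  Whytu  Yavru
#> BlueFeather      100.00  45.91  45.91  45.91  58.43  58.43
#> Corgi             45.91 100.00  92.00  92.00  36.00  36.00
#> Idaho             45.91  92.00 100.00  92.00  36.00  36.00
#> Noely             45.91  92.00  92.00 100.00  36.00  36.00
#> Whytu             58.43  36.00  36.00  36.00 100.00  92.00
#> Yavru             58.43  36.00  36.00  36.00  92.00 100.00

cluster_by_gcs(m, threshold = 35)
#> <cluster_partition> 12 phages in 7 clusters (6 singletons) at GCS >= 35%

gcd_profile("BlueFeather", pham_profiles(asg))
#> <gcd_profile> BlueFeather vs 11 phages; MaxGCDGap 41.57% closing at Whytu
```

Reading the numbers: the focal phage shares over 45% of gene content
with every FE member and over 58% with every FI member — all above the
35% parameter — so the three groups fuse into one 6-phage cluster
(the 6 remaining singletons are small "carrier" phages that model
distant hosts sharing single genes). MaxGCDGap of 41.6% says the
nearest neighbor (Whytu, GCS 58.4%) is still far away: high isolation,
yet clusterable by gene content. Meanwhile
`nucleotide_span_coverage()` between clusters is ~2%, far below the
legacy 50% nucleotide rule — the signature of relatedness visible only
at the amino-acid level.

Per-gene HGT evidence for the focal genome:

```r
tab <- hgt_evidence_table(pop$genomes$BlueFeather, asg, pop$metadata)
tab[tab$flagged, c("gene_number", "gene_gc", "gc_deviation", "unique_host_count", "rank")]
#>    gene_number  gene_gc gc_deviation unique_host_count rank
#> 15          15 71.24183   7.02825733                 5    1
#> 19          19 64.28571   0.07214155                 3    2
#> 24          24 70.11019   5.89662010                 2    3
```

Gene 15 deviates +7 GC points and its pham spans 5 isolation hosts;
gene 19 (the genome's one reverse-strand gene) spans 3 hosts; gene 24
deviates +5.9 points — the flagged candidates for horizontal transfer.

`run_pipeline(run_config(...))` runs all stages (phams → GCS/GCD →
clustering → NJ tree/NEXUS → dot plots → HGT table) into an output
directory with a JSON manifest.

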