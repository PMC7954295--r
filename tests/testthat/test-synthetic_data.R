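test_that("simulation is byte-identical for a fixed seed", {
  p1 <- simulate_population(small_params())
  p2 <- simulate_population(small_params())
  expect_identical(lapply(p1$genomes, `[[`, "sequence"),
                   lapply(p2$genomes, `[[`, "sequence"))
  expect_identical(lapply(p1$genomes, `[[`, "genes"),
                   lapply(p2$genomes, `[[`, "genes"))
  expect_identical(p1$metadata, p2$metadata)
  expect_identical(p1$truth$pham_of, p2$truth$pham_of)
  # different seed: different sequences
  p3 <- simulate_population(small_params(seed = 8))
  expect_false(identical(p1$genomes[[1]]$sequence, p3$genomes[[1]]$sequence))
})

test_that("codon scrambling preserves the protein and varies with seed", {
  set.seed(73)
  for (i in 1:5) {
    p <- random_protein(sample(50:200, 1))
    nt1 <- codon_scramble(p, 58, scramble_seed = 1)
    nt2 <- codon_scramble(p, 58, scramble_seed = 2)
    expect_identical(translate_cds(nt1), p)
    expect_identical(translate_cds(nt2), p)
    expect_false(identical(nt1, nt2))
  }
  # independent re-encodings sit near the synonymous-site baseline,
  # far below conserved-sequence identity, while the protein stays 100%
  p <- random_protein(300)
  id <- positionwise_nt_identity(codon_scramble(p, 58, 11),
                                 codon_scramble(p, 58, 12))
  expect_lt(id, 0.9)
  expect_gt(id, 0.4)
})

test_that("realized GC tracks the target and responds to target changes", {
  set.seed(79)
  p <- random_protein(300)
  gc_hi <- gc_content(codon_scramble(p, 58, 21))
  gc_lo <- gc_content(codon_scramble(p, 45, 21))
  expect_gt(gc_hi - gc_lo, 5)

  # within +/- 2 points of target for long genes across many seeds
  for (s in 1:20) {
    p <- random_protein(220)
    expect_equal(gc_content(codon_scramble(p, 52, s)), 52, tolerance = 2 / 52)
  }
})

test_that("unreachable GC targets warn with the achievable range", {
  p <- paste(rep("K", 100), collapse = "")  # AAA/AAG only: GC at most 1/3
  expect_warning(nt <- codon_scramble(p, 80, 1), "achievable range")
  expect_identical(translate_cds(nt), p)
  expect_lt(gc_content(nt), 40)
})

test_that("easy settings allow exact pham and cluster recovery", {
  params <- small_params(seed = 3, within_pham_aa_divergence = 0,
                         synonymous_scramble_rate = 0,
                         within_cluster_codon_noise = 0,
                         genes_per_genome = c(8L, 8L), core_fraction = 1)
  pop <- simulate_population(params)
  asg <- assign_phams(population_proteins(pop$genomes))
  expect_equal(adjusted_rand_index(asg$pham_of[names(pop$truth$pham_of)],
                                   pop$truth$pham_of), 1)
  part <- cluster_by_gcs(gcs_matrix(pham_profiles(asg)), 35)
  expect_equal(adjusted_rand_index(part$cluster[names(pop$truth$clusters)],
                                   pop$truth$clusters), 1)
  # zero scramble: intra-cluster nucleotide conservation is near-total
  same_cluster <- names(pop$truth$clusters)[pop$truth$clusters ==
                                              pop$truth$clusters[1]]
  cov <- nucleotide_span_coverage(pop$genomes[[same_cluster[1]]]$sequence,
                                  pop$genomes[[same_cluster[2]]]$sequence)
  expect_gt(cov, 65)
})

test_that("written populations and truth tables reload consistently", {
  pop <- small_population()
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  seqs <- read_genome_fasta(file.path(dir, "genomes.fasta"))
  expect_identical(seqs, vapply(pop$genomes, `[[`, character(1), "sequence"))
  meta <- read_metadata_table(file.path(dir, "metadata.tsv"))
  expect_identical(meta, pop$metadata)
  genes <- read_genes_tsv(file.path(dir, "genes.tsv"))
  expect_identical(nrow(genes), length(pop$truth$pham_of))
  truth_phams <- utils::read.delim(file.path(dir, "truth_phams.tsv"))
  ids <- paste0(truth_phams$phage_name, "|", truth_phams$gene_number)
  expect_equal(adjusted_rand_index(
    stats::setNames(truth_phams$pham_id, ids)[names(pop$truth$pham_of)],
    pop$truth$pham_of), 1)
})

test_that("scenario genomes look like small siphovirus genomes", {
  pop <- scenario_population()
  six <- c("BlueFeather", "Corgi", "Idaho", "Noely", "Whytu", "Yavru")
  lens <- vapply(pop$genomes[six], function(g) nchar(g$sequence), numeric(1))
  expect_true(all(lens > 15319 & lens < 70265))  # observed genome-length range
  expect_identical(unname(vapply(pop$genomes[six], function(g)
    nrow(g$genes), integer(1))), rep(25L, 6))
  bf <- pop$genomes$BlueFeather
  expect_identical(sum(bf$genes$strand == "-"), 1L)
  expect_identical(bf$genes$strand[19], "-")
  expect_equal(gc_content(bf$sequence), 64.3, tolerance = 0.02)
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(83)
  for (i in 1:10) {
    a <- sample(3, 40, replace = TRUE)
    b <- sample(4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("infeasible parameter combinations are rejected", {
  expect_error(simulation_params(genes_per_genome = c(3L, 5L),
                                 orphams_per_genome = 4L), "exceed")
  expect_error(
    simulate_population(small_params(pham_universe_size = 5L)),
    "infeasible")
  expect_error(simulation_params(core_fraction = 1.4), "probabilities")
})
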