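test_that("GC content counts G+C over unambiguous bases only", {
  # 3' sticky-overhang sequence: 11 of 15 bases are G or C
  ovh <- "CCACGGTTCCCGTCC"
  counted <- 100 * sum(strsplit(ovh, "")[[1]] %in% c("G", "C")) / nchar(ovh)
  expect_equal(gc_content(ovh), counted, tolerance = 1e-12)
  expect_equal(gc_content(ovh), 73.33, tolerance = 0.005)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCNN"), 100)  # N excluded from the denominator
  expect_error(gc_content("NNN"), "all-N")
  expect_error(gc_content(""), "all-N")

  set.seed(71)
  for (i in 1:10) {
    s <- random_dna(200)
    expect_equal(gc_content(s), gc_content(revcomp(s)), tolerance = 1e-12)
  }
})

test_that("length-weighted mean of per-gene GC equals GC of the concatenation", {
  rec <- simulate_bluefeather_like_record(seed = 2)
  gc <- vapply(rec$genes$nucleotide_seq, gc_content, numeric(1))
  len <- nchar(rec$genes$nucleotide_seq)
  expect_equal(gc_content(paste(rec$genes$nucleotide_seq, collapse = "")),
               sum(gc * len) / sum(len), tolerance = 1e-9)
})

test_that("pham host diversity counts distinct host strings", {
  asg <- make_assignment(c(
    "Solo|1" = "PH0001",
    "A|1" = "PH0002", "B|1" = "PH0002", "C|1" = "PH0002",
    "A|2" = "PH0003", "B|2" = "PH0003"))
  meta <- data.frame(
    phage_name = c("Solo", "A", "B", "C"),
    host = c("Arthrobacter globiformis B-2979",
             "Gordonia malaquae BEN700",
             "Mycobacterium smegmatis mc2 155",
             "Gordonia malaquae BEN700"),
    original_cluster = "unassigned", stringsAsFactors = FALSE)
  expect_equal(pham_host_diversity("PH0001", asg, meta)$count, 1)
  expect_equal(pham_host_diversity("PH0002", asg, meta)$count, 2)
  # two phages on the same host collapse to one
  expect_equal(pham_host_diversity("PH0003", asg, meta)$count, 2)
  expect_error(pham_host_diversity("PH0009", asg, meta), "unknown pham")
  expect_error(pham_host_diversity("PH0002", asg, meta[-2, ]),
               "missing from metadata")
})

test_that("uniform-GC all-orpham genomes produce no flags", {
  nt <- strrep("GCAT", 30)  # every gene identical, GC 50
  prot <- translate_cds(nt)
  genes <- data.frame(
    gene_number = 1:3, start = c(1, 131, 261), end = c(120, 250, 380),
    strand = "+", nucleotide_seq = nt, protein_seq = prot,
    function_label = "unknown", stringsAsFactors = FALSE)
  seq <- paste0(nt, strrep("G", 5), strrep("C", 5), nt,
                strrep("G", 5), strrep("C", 5), nt)
  g <- annotated_genome("Uni", seq, genes, host = "h1")
  asg <- make_assignment(stats::setNames(paste0("PH000", 1:3), paste0("Uni|", 1:3)))
  meta <- data.frame(phage_name = "Uni", host = "h1",
                     original_cluster = "unassigned")
  tab <- hgt_evidence_table(g, asg, meta)
  expect_false(any(tab$flagged))
  expect_true(all(tab$unique_host_count == 1))
})

test_that("implanted high-GC and multi-host genes are exactly the flags", {
  params <- small_params(seed = 101,
                         hgt_implants = list(
                           list(slot = 3L, gc_offset = 6, n_extra_hosts = 0L),
                           list(slot = 5L, gc_offset = 6, n_extra_hosts = 0L),
                           list(slot = 7L, gc_offset = 0, n_extra_hosts = 2L),
                           list(slot = 2L, gc_offset = 0, n_extra_hosts = 2L)))
  pop <- simulate_population(params)
  focal <- names(pop$genomes)[1]  # implants default to the first phage
  asg <- assign_phams(population_proteins(pop$genomes))
  tab <- hgt_evidence_table(pop$genomes[[focal]], asg, pop$metadata,
                            gc_delta = 5, host_min = 3)
  expect_setequal(tab$gene_number[tab$flagged], c(2L, 3L, 5L, 7L))
  # ranking: host-diverse genes first, then GC deviation
  expect_true(all(tab$rank[tab$gene_number %in% c(2, 7)] <= 2))
})

test_that("the scenario focal genome flags its implanted genes", {
  pop <- scenario_population()
  asg <- scenario_assignment()
  tab <- hgt_evidence_table(pop$genomes$BlueFeather, asg, pop$metadata)
  implanted <- pop$truth$hgt_genes
  # the five-host implant is flagged and tops the ranking
  top <- implanted$gene_number[implanted$n_extra_hosts == 4]
  expect_true(tab$flagged[tab$gene_number == top])
  expect_equal(tab$unique_host_count[tab$gene_number == top], 5)
  expect_equal(tab$rank[tab$gene_number == top], 1L)
  # GC-offset implants exceed the genome mean by ~ their offset
  gcimp <- implanted[implanted$gc_offset > 0, ]
  for (i in seq_len(nrow(gcimp)))
    expect_gt(tab$gc_deviation[tab$gene_number == gcimp$gene_number[i]], 4)
})
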