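# Per-gene horizontal-gene-transfer evidence: GC-content deviation from
# the genome mean, and the number of distinct isolation hosts among the
# phages carrying each gene's pham. Neither signal is proof; together
# they rank candidate transfers for inspection.

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`. Ambiguous `N` bases are excluded
#' from the denominator, so draft sequence padding does not dilute the
#' estimate. Strand-independent: a reverse complement has identical GC
#' content.
#'
#' @param seq Nucleotide string (A/C/G/T/N), nonempty after removing N.
#' @return GC percent in \[0, 100\].
#' @export
gc_content <- function(seq) {
  seq <- check_dna(seq, "gc_content input")
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (acgt == 0L) stop2("sequence is empty or all-N")
  100 * gc / acgt
}

#' Unique isolation hosts represented in a pham
#'
#' @param pham Pham identifier.
#' @param assignment A `pham_assignment`.
#' @param metadata Metadata table covering every member phage.
#' @return List with `count` (distinct hosts, >= 1) and `hosts`
#'   (sorted character vector). Host strings are compared exactly as
#'   given (species + strain granularity).
#' @export
pham_host_diversity <- function(pham, assignment, metadata) {
  stopifnot(inherits(assignment, "pham_assignment"))
  if (!pham %in% names(assignment$phams)) stop2("unknown pham '%s'", pham)
  phages <- unique(sub("\\|.*$", "", assignment$phams[[pham]]))
  missing <- setdiff(phages, metadata$phage_name)
  if (length(missing))
    stop2("pham member phage(s) missing from metadata: %s",
          paste(missing, collapse = ", "))
  hosts <- sort(unique(metadata$host[match(phages, metadata$phage_name)]))
  list(count = length(hosts), hosts = hosts)
}

#' Per-gene HGT evidence table for one genome
#'
#' One row per gene with its GC content, deviation from the genome mean
#' (percentage points), pham, and the pham's isolation-host diversity.
#' A gene is flagged when its GC deviation reaches `gc_delta` points OR
#' its pham spans at least `host_min` distinct hosts. The flagging rule
#' is an explicit operationalization of what is usually judged by eye;
#' the full ranked table is always returned so other cuts can be
#' applied. Rows are ranked by host count (descending), then GC
#' deviation (descending), then gene number.
#'
#' @param genome An `annotated_genome`.
#' @param assignment A `pham_assignment` covering the genome's genes.
#' @param metadata Metadata table covering all member phages.
#' @param gc_delta Flag threshold on GC deviation in percentage points
#'   (default 5).
#' @param host_min Flag threshold on distinct host count (default 3).
#' @return `data.frame` with columns `gene_number`, `gene_gc`,
#'   `genome_gc`, `gc_deviation`, `pham`, `unique_host_count`,
#'   `flagged`, `rank`.
#' @export
hgt_evidence_table <- function(genome, assignment, metadata,
                               gc_delta = 5, host_min = 3) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(assignment, "pham_assignment"))
  ids <- gene_id(genome$name, genome$genes$gene_number)
  missing <- setdiff(ids, names(assignment$pham_of))
  if (length(missing))
    stop2("gene(s) missing from pham assignment: %s", paste(missing, collapse = ", "))
  genome_gc <- gc_content(genome$sequence)
  rows <- lapply(seq_len(nrow(genome$genes)), function(i) {
    g <- genome$genes[i, ]
    pham <- unname(assignment$pham_of[ids[i]])
    gc <- gc_content(g$nucleotide_seq)
    hosts <- pham_host_diversity(pham, assignment, metadata)
    data.frame(gene_number = g$gene_number, gene_gc = gc,
               genome_gc = genome_gc, gc_deviation = gc - genome_gc,
               pham = pham, unique_host_count = hosts$count,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$flagged <- tab$gc_deviation >= gc_delta | tab$unique_host_count >= host_min
  ord <- order(-tab$unique_host_count, -tab$gc_deviation, tab$gene_number)
  tab$rank <- order(ord)
  tab <- tab[order(tab$gene_number), ]
  rownames(tab) <- NULL
  tab
}

#' Write an HGT evidence table as TSV
#'
#' @param table Result of [hgt_evidence_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hgt_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
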