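# Reading, validating and writing the plain-text formats the pipeline
# touches: nucleotide FASTA, GenBank flat files (CDS features only), the
# gene-table TSV dialect, and the phage metadata TSV.

#' Construct an annotated phage genome
#'
#' The central container of the package: a genome sequence plus its
#' ordered gene records and isolation metadata. Gene coordinates are
#' 1-based inclusive (GenBank convention). For a forward-strand gene the
#' stored `nucleotide_seq` equals the genome slice `start..end`; for a
#' reverse-strand gene it equals the reverse complement of that slice,
#' i.e. always the coding sequence.
#'
#' @param name Phage name (unique within a population).
#' @param sequence Genome nucleotide sequence (A/C/G/T/N).
#' @param genes `data.frame` with columns `gene_number`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `nucleotide_seq`, `protein_seq`,
#'   `function_label`.
#' @param host Isolation host (free text).
#' @param original_cluster Cluster label at isolation, `"singleton"`, or
#'   `"unassigned"`.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(name, sequence, genes,
                             host = "unknown",
                             original_cluster = "unassigned") {
  stopifnot(is.character(name), nchar(name) > 0L, is.data.frame(genes))
  sequence <- check_dna(sequence, name)
  if (nchar(sequence) == 0L) stop2("genome '%s' has an empty sequence", name)
  required <- c("gene_number", "start", "end", "strand",
                "nucleotide_seq", "protein_seq", "function_label")
  missing <- setdiff(required, names(genes))
  if (length(missing))
    stop2("gene table for '%s' lacks column(s): %s", name,
          paste(missing, collapse = ", "))
  genes <- genes[order(genes$start), required, drop = FALSE]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_number))
    stop2("genome '%s': duplicated gene numbers", name)
  L <- nchar(sequence)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$end < g$start)
      stop2("genome '%s' gene %d: end < start", name, g$gene_number)
    if (g$start < 1L || g$end > L)
      stop2("genome '%s' gene %d: coordinates [%d, %d] exceed sequence length %d",
            name, g$gene_number, g$start, g$end, L)
    slice <- substr(sequence, g$start, g$end)
    expected <- if (g$strand == "-") revcomp(slice) else slice
    if (nchar(g$nucleotide_seq) != g$end - g$start + 1L)
      stop2("genome '%s' gene %d: nucleotide_seq length disagrees with coordinates",
            name, g$gene_number)
    if (toupper(g$nucleotide_seq) != expected)
      stop2("genome '%s' gene %d: nucleotide_seq does not match the %s-strand genome slice",
            name, g$gene_number, if (g$strand == "-") "reverse" else "forward")
    if (is.na(g$protein_seq) || nchar(g$protein_seq) == 0L)
      stop2("genome '%s' gene %d: empty protein sequence", name, g$gene_number)
  }
  structure(
    list(name = name, sequence = sequence, genes = genes,
         host = host, original_cluster = original_cluster),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %d genes, host '%s', cluster '%s'\n",
              x$name, nchar(x$sequence), nrow(x$genes), x$host,
              x$original_cluster))
  invisible(x)
}

#' Read a multi-record nucleotide FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences, one per
#'   record. Characters outside A/C/G/T/N and duplicated record names
#'   are rejected with an informative error.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop2("FASTA file '%s' contains no records", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop2("FASTA file '%s': duplicate record name '%s'",
          path, nm[duplicated(nm)][1L])
  seqs <- vapply(seq_along(set), function(i)
    check_dna(as.character(set[[i]]), nm[i]), character(1))
  names(seqs) <- nm
  seqs
}

#' Write genome sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nchar(names(seqs)) > 0L))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read the phage metadata table
#'
#' Tab-separated with header columns `phage_name`, `host`,
#' `original_cluster`. An empty or missing cluster is normalised to
#' `"unassigned"`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with the three columns, one row per phage.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("phage_name", "host", "original_cluster")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop2("metadata table '%s' lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) stop2("metadata table '%s' has no rows", path)
  if (anyDuplicated(tab$phage_name))
    stop2("metadata table '%s': duplicated phage_name '%s'", path,
          tab$phage_name[duplicated(tab$phage_name)][1L])
  if (any(is.na(tab$host) | tab$host == ""))
    stop2("metadata table '%s': empty host field", path)
  tab$original_cluster[is.na(tab$original_cluster) | tab$original_cluster == ""] <-
    "unassigned"
  tab[, required]
}

#' @rdname read_metadata_table
#' @param metadata A metadata `data.frame` to write.
#' @export
write_metadata_table <- function(metadata, path) {
  utils::write.table(metadata[, c("phage_name", "host", "original_cluster")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene-table TSV dialect ------------------------------------------------

#' Read or write per-genome gene tables (TSV dialect)
#'
#' Columns: `phage_name`, `gene_number`, `start`, `end`, `strand`
#' (`+`/`-`), `function`, `translation`. Coordinates 1-based inclusive.
#' One file may hold genes for several phages.
#'
#' @param path Path to the gene TSV.
#' @return `data.frame` of gene rows (translation upper-cased and
#'   validated).
#' @export
read_genes_tsv <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("phage_name", "gene_number", "start", "end", "strand",
                "function", "translation")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop2("gene table '%s' lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) stop2("gene table '%s' has no rows", path)
  if (!all(tab$strand %in% c("+", "-")))
    stop2("gene table '%s': strand must be '+' or '-'", path)
  tab$translation <- vapply(seq_len(nrow(tab)), function(i)
    check_protein(tab$translation[i],
                  sprintf("%s gene %s", tab$phage_name[i], tab$gene_number[i])),
    character(1))
  tab[, required]
}

#' @rdname read_genes_tsv
#' @param genes Gene `data.frame` in the same dialect.
#' @export
write_genes_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

genes_tsv_from_genome <- function(genome) {
  g <- genome$genes
  data.frame(phage_name = genome$name, gene_number = g$gene_number,
             start = g$start, end = g$end, strand = g$strand,
             `function` = g$function_label, translation = g$protein_seq,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Assemble an annotated genome from a gene TSV plus genome FASTA
#'
#' @param genes_path Gene table TSV (dialect of [read_genes_tsv()]).
#' @param fasta_path Genome FASTA containing the phage's sequence.
#' @param phage Phage name to extract; defaults to the single name
#'   present in the gene table.
#' @param host,original_cluster Metadata carried onto the genome.
#' @return An `annotated_genome`.
#' @export
read_annotated_genome_tsv <- function(genes_path, fasta_path, phage = NULL,
                                      host = "unknown",
                                      original_cluster = "unassigned") {
  genes <- read_genes_tsv(genes_path)
  seqs <- read_genome_fasta(fasta_path)
  if (is.null(phage)) {
    phage <- unique(genes$phage_name)
    if (length(phage) != 1L)
      stop2("gene table holds %d phages; supply `phage`", length(phage))
  }
  genes <- genes[genes$phage_name == phage, , drop = FALSE]
  if (nrow(genes) == 0L) stop2("no genes for phage '%s' in %s", phage, genes_path)
  if (!phage %in% names(seqs)) stop2("no FASTA record named '%s'", phage)
  seq <- seqs[[phage]]
  nt <- vapply(seq_len(nrow(genes)), function(i) {
    slice <- substr(seq, genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") revcomp(slice) else slice
  }, character(1))
  annotated_genome(
    name = phage, sequence = seq,
    genes = data.frame(
      gene_number = as.integer(genes$gene_number),
      start = as.integer(genes$start), end = as.integer(genes$end),
      strand = genes$strand, nucleotide_seq = nt,
      protein_seq = genes$translation,
      function_label = genes$`function`,
      stringsAsFactors = FALSE),
    host = host, original_cluster = original_cluster)
}

# ---- GenBank flat files ----------------------------------------------------

# Minimal flat-file reader restricted to what phage records need: LOCUS,
# DEFINITION, ORIGIN sequence, and CDS features with simple or
# complement() locations and /translation qualifiers. Compound (join)
# locations are rejected explicitly.
parse_genbank_text <- function(lines, path = "<genbank>") {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L)
    stop2("'%s': expected exactly one LOCUS line", path)
  name <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "\\s+")[[1]][1]

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1L) stop2("'%s': no ORIGIN block", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- check_dna(sequence, name)

  feat_i <- grep("^FEATURES", lines)
  cds <- list()
  if (length(feat_i) == 1L) {
    block <- lines[(feat_i + 1L):(origin_i - 1L)]
    # fold continuation lines (21 leading spaces, no new key) onto features
    key_i <- grep("^ {5}\\S", block)
    for (k in seq_along(key_i)) {
      first <- block[key_i[k]]
      key <- strsplit(trimws(first), "\\s+")[[1]][1]
      if (key != "CDS") next
      last <- if (k < length(key_i)) key_i[k + 1L] - 1L else length(block)
      cds[[length(cds) + 1L]] <- block[key_i[k]:last]
    }
  }

  genes <- lapply(cds, function(body) {
    loc <- trimws(sub("^\\s*CDS\\s+", "", body[1]))
    # location may spill onto continuation lines before the first qualifier
    qual_start <- grep("^\\s+/", body)
    extra <- if (length(qual_start) && qual_start[1] > 2L)
      paste(trimws(body[2:(qual_start[1] - 1L)]), collapse = "") else ""
    loc <- paste0(loc, extra)
    if (grepl("join|order", loc))
      stop2("'%s': compound CDS locations are not supported (%s)", path, loc)
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) != 2L) stop2("'%s': cannot parse CDS location '%s'", path, loc)
    qtext <- paste(trimws(body[-1]), collapse = "\n")
    get_q <- function(q) {
      m <- regmatches(qtext, regexpr(sprintf('/%s="[^"]*"', q), qtext))
      if (!length(m)) return(NA_character_)
      gsub("\\n", "", sub(sprintf('^/%s="', q), "", sub('"$', "", m)))
    }
    list(start = nums[1], end = nums[2], strand = strand,
         translation = gsub("\\s", "", get_q("translation") %||% NA_character_),
         product = get_q("product"))
  })
  list(name = name, sequence = sequence, cds = genes)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Every CDS feature becomes one gene record; gene numbers are assigned
#' by ascending start coordinate. Reverse-strand (`complement(...)`)
#' features store the reverse-complemented coding sequence. A CDS
#' without a `/translation` qualifier is translated with genetic code
#' table 11 when `translate_missing` is `TRUE`, otherwise it is an
#' error.
#'
#' @param path GenBank flat file.
#' @param host,original_cluster Metadata carried onto the genome.
#' @param translate_missing Translate CDS features lacking a
#'   `/translation` qualifier (default `TRUE`).
#' @return An `annotated_genome`.
#' @export
read_annotated_genome_gb <- function(path, host = "unknown",
                                     original_cluster = "unassigned",
                                     translate_missing = TRUE) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  gb <- parse_genbank_text(readLines(path, warn = FALSE), path)
  if (!length(gb$cds)) stop2("'%s': no CDS features", path)
  L <- nchar(gb$sequence)
  ord <- order(vapply(gb$cds, `[[`, numeric(1), "start"))
  rows <- lapply(seq_along(ord), function(i) {
    f <- gb$cds[[ord[i]]]
    if (f$end > L || f$start < 1L)
      stop2("'%s': CDS coordinates [%d, %d] exceed sequence length %d",
            path, f$start, f$end, L)
    slice <- substr(gb$sequence, f$start, f$end)
    nt <- if (f$strand == "-") revcomp(slice) else slice
    aa <- f$translation
    if (is.na(aa) || !nzchar(aa)) {
      if (!translate_missing)
        stop2("'%s': CDS at %d..%d has no /translation", path, f$start, f$end)
      aa <- translate_cds(nt)
    }
    data.frame(gene_number = i, start = f$start, end = f$end,
               strand = f$strand, nucleotide_seq = nt,
               protein_seq = check_protein(aa, sprintf("CDS %d", i)),
               function_label = ifelse(is.na(f$product), "unknown", f$product),
               stringsAsFactors = FALSE)
  })
  annotated_genome(gb$name, gb$sequence, do.call(rbind, rows),
                   host = host, original_cluster = original_cluster)
}

#' Read an annotated genome, auto-detecting GenBank vs gene-TSV input
#'
#' @param path GenBank flat file or gene TSV.
#' @param fasta_fallback Genome FASTA, required for TSV input.
#' @param ... Passed to the format-specific reader.
#' @return An `annotated_genome`.
#' @export
read_annotated_genome <- function(path, fasta_fallback = NULL, ...) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^LOCUS", first)) {
    read_annotated_genome_gb(path, ...)
  } else {
    if (is.null(fasta_fallback))
      stop2("TSV gene-table input needs `fasta_fallback` for the genome sequence")
    read_annotated_genome_tsv(path, fasta_fallback, ...)
  }
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits LOCUS, FEATURES (source + one CDS per gene with `/product` and
#' `/translation`) and ORIGIN blocks readable by
#' [read_annotated_genome_gb()] and by standard GenBank parsers.
#'
#' @param genome An `annotated_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("LOCUS       %s%17d bp    DNA     linear   PHG", genome$name, L)
  wr("DEFINITION  %s, complete genome.", genome$name)
  wr("FEATURES             Location/Qualifiers")
  wr("     source          1..%d", L)
  wr("                     /organism=\"%s\"", genome$name)
  wrap_q <- function(text) {
    # qualifier continuation lines are indented 21 columns
    chunks <- substring(text, seq(1, nchar(text), 58), pmin(nchar(text), seq(58, nchar(text) + 57, 58)))
    writeLines(paste0(strrep(" ", 21), chunks), con)
  }
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    loc <- if (g$strand == "-") sprintf("complement(%d..%d)", g$start, g$end)
           else sprintf("%d..%d", g$start, g$end)
    wr("     CDS             %s", loc)
    wrap_q(sprintf("/product=\"%s\"", g$function_label))
    wrap_q(sprintf("/translation=\"%s\"", g$protein_seq))
  }
  wr("ORIGIN")
  s <- tolower(genome$sequence)
  for (off in seq(1, L, 60)) {
    line <- substr(s, off, min(L, off + 59))
    sext <- substring(line, seq(1, nchar(line), 10), pmin(nchar(line), seq(10, nchar(line) + 9, 10)))
    wr("%9d %s", off, paste(sext, collapse = " "))
  }
  wr("//")
  invisible(path)
}
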