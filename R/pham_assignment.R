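# Pham assignment: group protein sequences from a phage population into
# amino-acid similarity families (phams), the unit of every gene-content
# statistic downstream. Gene identifiers are "<phage_name>|<gene_number>".

gene_id <- function(phage, gene_number) paste0(phage, "|", gene_number)

aa_identity_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- Biostrings::AA_ALPHABET
      m <- diag(1, length(letters))
      dimnames(m) <- list(letters, letters)
      cache <<- m
    }
    cache
  }
})

#' Pairwise protein identity and coverage
#'
#' Global alignment with free terminal gaps (ends-free / overlap mode):
#' match +1, mismatch 0, gap opening 2, gap extension 0.5 by default.
#' Identity is the fraction of identical columns among alignment columns
#' excluding terminal gaps; coverage is the aligned (non-terminal-gap)
#' span of the shorter sequence divided by its length. Both are
#' symmetric in argument order.
#'
#' Alignments with several co-optimal solutions can report slightly
#' different identity/coverage depending on which sequence is the
#' pattern, so the pair is always aligned in a canonical orientation
#' (shorter sequence as pattern; ties broken lexicographically), which
#' makes the statistics exactly symmetric.
#'
#' @param protein_a,protein_b Non-empty amino-acid strings.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @return Named numeric vector `c(identity =, coverage =)`, percents in
#'   \[0, 100\].
#' @export
pairwise_protein_identity <- function(protein_a, protein_b,
                                      gap_opening = 2, gap_extension = 0.5) {
  protein_a <- check_protein(protein_a, "protein_a")
  protein_b <- check_protein(protein_b, "protein_b")
  if (nchar(protein_a) == 0L || nchar(protein_b) == 0L)
    stop2("empty protein sequence")
  if (!pattern_first(protein_a, protein_b)) {
    tmp <- protein_a; protein_a <- protein_b; protein_b <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "overlap", substitutionMatrix = aa_identity_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  alignment_stats(aln, nchar(protein_a), nchar(protein_b))
}

# canonical orientation: TRUE when a should be the alignment pattern
pattern_first <- function(a, b) {
  if (nchar(a) != nchar(b)) return(nchar(a) < nchar(b))
  a <= b
}

alignment_stats <- function(aln, len_a, len_b) {
  cols <- Biostrings::nchar(aln)  # aligned region columns (terminal gaps trimmed)
  if (cols == 0L) return(c(identity = 0, coverage = 0))
  ident <- 100 * Biostrings::nmatch(aln) / cols
  span_a <- Biostrings::width(Biostrings::pattern(aln))
  span_b <- Biostrings::width(Biostrings::subject(aln))
  cov <- 100 * (if (len_a <= len_b) span_a / len_a else span_b / len_b)
  c(identity = ident, coverage = cov)
}

# Provably lossless composition prescreen. In any alignment the number
# of identical columns cannot exceed the amino-acid multiset
# intersection of the two sequences, while meeting both thresholds
# requires at least identity * coverage * (shorter length) identical
# columns. Pairs whose intersection falls below that bound can never
# qualify and are skipped without alignment.
composition_prescreen_keep <- function(counts_a, counts_b, len_a, len_b,
                                       identity_threshold, coverage_threshold) {
  max_matches <- sum(pmin(counts_a, counts_b))
  need <- (identity_threshold / 100) * (coverage_threshold / 100) * min(len_a, len_b)
  max_matches >= need
}

aa_counts <- function(protein) {
  table(factor(strsplit(protein, "")[[1]], levels = AA_LETTERS))
}

#' Assign phams by single-linkage clustering of protein similarity
#'
#' Aligns every candidate pair of proteins, keeps edges meeting both the
#' identity and the coverage threshold, and takes connected components
#' of the resulting similarity graph as phams. Pham identifiers
#' (`"PH0001"`, ...) are canonical: components are sorted by their
#' lexicographically smallest member gene, so the output is invariant
#' under permutation of the input order. A pham whose members all come
#' from one phage is an orpham.
#'
#' @param proteins Named character vector of amino-acid sequences; names
#'   are gene identifiers of the form `"<phage>|<gene_number>"`.
#' @param identity_threshold,coverage_threshold Percent thresholds in
#'   (0, 100\]; defaults 35 and 75.
#' @param prescreen Use the lossless composition prescreen to skip pairs
#'   that cannot reach the thresholds (default `TRUE`; affects speed
#'   only, never the result).
#' @return Object of class `pham_assignment`: list with `pham_of` (named
#'   character vector gene -> pham), `phams` (named list pham -> member
#'   genes), `orpham` (named logical per pham), `edges` (data.frame of
#'   retained similarity edges), and the thresholds used.
#' @export
assign_phams <- function(proteins, identity_threshold = 35,
                         coverage_threshold = 75, prescreen = TRUE) {
  if (length(proteins) == 0L) stop2("no proteins supplied")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop2("proteins must be uniquely named by gene identifier")
  if (!all(grepl("\\|", names(proteins))))
    stop2("gene identifiers must be of the form '<phage>|<gene_number>'")
  stopifnot(identity_threshold > 0, identity_threshold <= 100,
            coverage_threshold > 0, coverage_threshold <= 100)
  ids <- names(proteins)
  proteins <- vapply(ids, function(i) check_protein(proteins[[i]], i), character(1))
  n <- length(proteins)
  lens <- nchar(proteins)
  counts <- if (prescreen && n > 1L)
    vapply(proteins, function(p) as.integer(aa_counts(p)),
           integer(length(AA_LETTERS)))
  else NULL

  aa_set <- Biostrings::AAStringSet(proteins)
  edges <- list()
  if (n > 1L) {
    # one vectorized alignment call per subject sequence; each unordered
    # pair is aligned exactly once, in the same canonical orientation
    # pairwise_protein_identity() uses (shorter sequence as pattern)
    for (j in seq_len(n)) {
      cand <- setdiff(which(
        lens < lens[j] |
          (lens == lens[j] &
             (proteins < proteins[j] |
                (proteins == proteins[j] & seq_len(n) < j)))), j)
      if (!length(cand)) next
      if (!is.null(counts))
        cand <- cand[vapply(cand, function(i)
          composition_prescreen_keep(counts[, i], counts[, j], lens[i], lens[j],
                                     identity_threshold, coverage_threshold),
          logical(1))]
      if (!length(cand)) next
      aln <- Biostrings::pairwiseAlignment(
        aa_set[cand], aa_set[[j]], type = "overlap",
        substitutionMatrix = aa_identity_matrix(),
        gapOpening = 2, gapExtension = 0.5)
      cols <- Biostrings::nchar(aln)
      ident <- ifelse(cols > 0, 100 * Biostrings::nmatch(aln) / cols, 0)
      span_a <- Biostrings::width(Biostrings::pattern(aln))
      span_b <- Biostrings::width(Biostrings::subject(aln))
      cov <- 100 * ifelse(lens[cand] <= lens[j],
                          span_a / lens[cand], span_b / lens[j])
      keep <- cols > 0 & ident >= identity_threshold & cov >= coverage_threshold
      if (any(keep))
        edges[[length(edges) + 1L]] <-
          data.frame(gene_a = ids[cand[keep]], gene_b = ids[j],
                     identity = ident[keep], coverage = cov[keep],
                     stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(gene_a = character(), gene_b = character(),
                           identity = numeric(), coverage = numeric())

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$gene_a, edges$gene_b))
  comp <- igraph::components(g)$membership

  # canonical numbering: sort members, then components by smallest member
  members <- lapply(split(ids, comp[ids]), sort)
  members <- members[order(vapply(members, function(m) min(m), character(1)))]
  pham_ids <- sprintf("PH%04d", seq_along(members))
  names(members) <- pham_ids
  pham_of <- stats::setNames(rep(pham_ids, lengths(members)), unlist(members))
  pham_of <- pham_of[ids]
  phage_of <- sub("\\|.*$", "", ids)
  orpham <- vapply(members, function(m)
    length(unique(sub("\\|.*$", "", m))) == 1L, logical(1))

  structure(
    list(pham_of = pham_of, phams = members, orpham = orpham, edges = edges,
         identity_threshold = identity_threshold,
         coverage_threshold = coverage_threshold),
    class = "pham_assignment")
}

#' @export
print.pham_assignment <- function(x, ...) {
  cat(sprintf("<pham_assignment> %d genes in %d phams (%d orphams) at identity >= %g%%, coverage >= %g%%\n",
              length(x$pham_of), length(x$phams), sum(x$orpham),
              x$identity_threshold, x$coverage_threshold))
  invisible(x)
}

#' Extract proteins from a list of annotated genomes
#'
#' @param genomes List of `annotated_genome` objects.
#' @return Named character vector keyed by `"<phage>|<gene_number>"`,
#'   ready for [assign_phams()].
#' @export
population_proteins <- function(genomes) {
  out <- do.call(c, unname(lapply(genomes, function(g)
    stats::setNames(g$genes$protein_seq, gene_id(g$name, g$genes$gene_number)))))
  if (is.null(out)) stop2("no genes in population")
  out
}

#' Pham membership profile of one phage
#'
#' The set of distinct phams with at least one member gene in the phage;
#' duplicated phams (paralogs) collapse to one entry.
#'
#' @param assignment A `pham_assignment`.
#' @param phage Phage name.
#' @return Character vector of pham identifiers (sorted).
#' @export
membership_profile <- function(assignment, phage) {
  stopifnot(inherits(assignment, "pham_assignment"))
  phages <- sub("\\|.*$", "", names(assignment$pham_of))
  if (!phage %in% phages) stop2("unknown phage '%s'", phage)
  sort(unique(unname(assignment$pham_of[phages == phage])))
}

#' Pham profiles for every phage in an assignment
#'
#' @param assignment A `pham_assignment`.
#' @return Named list phage -> character vector of distinct phams.
#' @export
pham_profiles <- function(assignment) {
  stopifnot(inherits(assignment, "pham_assignment"))
  phages <- sub("\\|.*$", "", names(assignment$pham_of))
  lapply(split(unname(assignment$pham_of), phages), function(p) sort(unique(p)))
}

#' Export a pham assignment as the pham-table TSV
#'
#' Columns: `pham_id`, `phage_name`, `gene_number`, `orpham` (0/1).
#'
#' @param assignment A `pham_assignment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pham_table <- function(assignment, path) {
  ids <- names(assignment$pham_of)
  tab <- data.frame(
    pham_id = unname(assignment$pham_of),
    phage_name = sub("\\|.*$", "", ids),
    gene_number = sub("^.*\\|", "", ids),
    orpham = as.integer(assignment$orpham[unname(assignment$pham_of)]),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$pham_id, tab$phage_name, as.integer(tab$gene_number)), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
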