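# Cluster assignment: connected components of the GCS >= threshold
# graph (the shared-gene-content clustering parameter), plus a
# conservative exact-word screen for the legacy nucleotide rule.

#' Cluster phages by Gene Content Similarity
#'
#' Builds a graph with an edge wherever pairwise GCS meets the
#' threshold and returns its connected components as clusters. This is
#' the "35% shared gene content with at least one phage in a cluster"
#' rule: one qualifying partner suffices for membership, so clusters
#' can be chained. Labels `"C1"`, `"C2"`, ... are assigned by
#' descending component size, ties broken by the lexicographically
#' smallest member, so output is independent of input order.
#'
#' @param matrix Symmetric GCS matrix (percent) with phage dimnames.
#' @param threshold GCS percent required for an edge (default 35).
#' @return Object of class `cluster_partition`: list with `cluster`
#'   (named character vector phage -> label), `singleton` (named
#'   logical), `members` (list label -> phages) and `threshold`.
#' @export
cluster_by_gcs <- function(matrix, threshold = 35) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  nm <- rownames(matrix)
  if (is.null(nm) || anyDuplicated(nm)) stop2("matrix must have unique phage dimnames")
  adj <- matrix >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- split(nm, comp[nm])
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), character(1)))
  members <- lapply(members[ord], sort)
  labels <- sprintf("C%d", seq_along(members))
  names(members) <- labels
  cluster <- stats::setNames(rep(labels, lengths(members)), unlist(members))[nm]
  structure(list(cluster = cluster,
                 singleton = stats::setNames(lengths(members)[cluster] == 1L, nm),
                 members = members, threshold = threshold),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d phages in %d clusters (%d singletons) at GCS >= %g%%\n",
              length(x$cluster), length(x$members), sum(x$singleton), x$threshold))
  invisible(x)
}

#' Exact-word nucleotide span coverage
#'
#' Fraction of `genome_a` positions covered by at least one exact
#' `word`-length match (forward or reverse complement unless disabled)
#' to `genome_b`, as a percent. This is a deterministic, conservative
#' screen for the legacy "50% nucleotide identity over 50% span" cluster
#' rule: genuine nucleotide conservation produces long exact words,
#' while synonymous divergence destroys them. Asymmetric in its
#' arguments by design (coverage is measured on `genome_a`).
#'
#' @param genome_a,genome_b Nucleotide sequences, each at least `word`
#'   long.
#' @param word Word size (default 15, the nucleotide dot-plot word).
#' @param revcomp_matches Also count reverse-complement matches
#'   (default `TRUE`).
#' @return Percent of `genome_a` covered, in \[0, 100\].
#' @export
nucleotide_span_coverage <- function(genome_a, genome_b, word = 15,
                                     revcomp_matches = TRUE) {
  genome_a <- check_dna(genome_a, "genome_a")
  genome_b <- check_dna(genome_b, "genome_b")
  la <- nchar(genome_a); lb <- nchar(genome_b)
  if (la < word || lb < word) stop2("sequence shorter than word size %d", word)
  words_b <- substring(genome_b, 1:(lb - word + 1L), word:lb)
  if (revcomp_matches)
    words_b <- c(words_b, substring(revcomp(genome_b), 1:(lb - word + 1L), word:lb))
  words_a <- substring(genome_a, 1:(la - word + 1L), word:la)
  hit <- words_a %in% words_b
  covered <- logical(la)
  for (i in which(hit)) covered[i:(i + word - 1L)] <- TRUE
  100 * sum(covered) / la
}

#' Compare a new cluster partition against original assignments
#'
#' @param partition A `cluster_partition`.
#' @param metadata Metadata `data.frame` (see [read_metadata_table()])
#'   covering every phage in the partition.
#' @return `data.frame` with one row per phage: `phage_name`,
#'   `original_cluster`, `new_cluster`, `singleton`, `changed`. Each new
#'   cluster inherits the most frequent original (non-singleton,
#'   non-unassigned) label among its members as its canonical name; a
#'   phage is flagged changed when its original label differs from that
#'   canonical name. A former singleton that remains alone is
#'   unchanged; singletons absorbed into a larger cluster are changed.
#' @export
cluster_report <- function(partition, metadata) {
  stopifnot(inherits(partition, "cluster_partition"))
  phages <- names(partition$cluster)
  if (length(phages) == 0L) stop2("empty partition")
  missing <- setdiff(phages, metadata$phage_name)
  if (length(missing))
    stop2("phage(s) missing from metadata: %s", paste(missing, collapse = ", "))
  meta <- metadata[match(phages, metadata$phage_name), ]
  orig <- stats::setNames(meta$original_cluster, phages)
  solo <- c("singleton", "unassigned")
  changed <- stats::setNames(logical(length(phages)), phages)
  for (mem in partition$members) {
    real <- orig[mem][!orig[mem] %in% solo]
    if (length(real)) {
      tab <- sort(table(real), decreasing = TRUE)
      dominant <- names(tab)[tab == tab[1]][1]  # ties: lexicographic
      changed[mem] <- orig[mem] != dominant
    } else {
      changed[mem] <- length(mem) > 1L  # merged former singletons
    }
  }
  data.frame(phage_name = phages,
             original_cluster = orig,
             new_cluster = unname(partition$cluster),
             singleton = unname(partition$singleton),
             changed = unname(changed),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a cluster partition and report as TSV
#'
#' @param partition A `cluster_partition`.
#' @param metadata Metadata table covering the partition.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(partition, metadata, path) {
  utils::write.table(cluster_report(partition, metadata), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
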