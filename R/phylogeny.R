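# Gene-content phylogeny: GCD distance matrices, a deterministic
# neighbor-joining tree, and NEXUS distance export so split-network
# tools (e.g. SplitsTree) can draw the corresponding network.

#' Gene-content distance matrix
#'
#' `D[a, b] = 1 - GCS(a, b)/100` (i.e. GCD) for every phage pair.
#'
#' @param profiles Named list phage -> pham profile.
#' @return Symmetric numeric matrix in \[0, 1\] with zero diagonal.
#' @export
gcd_distance_matrix <- function(profiles) {
  if (length(profiles) < 3L) stop2("need at least 3 phages for a distance matrix")
  1 - gcs_matrix(profiles) / 100
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with two determinism guarantees:
#' ties in the Q criterion are broken by the lexicographically smallest
#' taxon pair (each agglomerated node is identified by its smallest
#' leaf), and negative branch-length estimates are clamped to zero. On
#' an additive matrix the true topology and path lengths are recovered
#' exactly.
#'
#' @param matrix Symmetric distance matrix with taxa dimnames, zero
#'   diagonal, nonnegative entries, at least 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  nm <- rownames(matrix)
  if (is.null(nm) || anyDuplicated(nm)) stop2("matrix must have unique taxa dimnames")
  if (nrow(matrix) < 3L) stop2("need at least 3 taxa")
  if (max(abs(matrix - t(matrix))) > 1e-9) stop2("matrix is not symmetric")
  if (any(matrix < -1e-12)) stop2("negative distances")
  if (any(abs(diag(matrix)) > 1e-12)) stop2("nonzero diagonal")

  D <- matrix
  # each active node: newick fragment + smallest leaf label (tie-break key)
  frag <- stats::setNames(nm, nm)
  key <- stats::setNames(nm, nm)
  active <- nm
  bl <- function(x) sprintf("%.10g", max(0, x))

  while (length(active) > 3L) {
    n <- length(active)
    d <- D[active, active]
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairs <- cbind(pmin(key[active][cand[, 1]], key[active][cand[, 2]]),
                   pmax(key[active][cand[, 1]], key[active][cand[, 2]]))
    pick <- order(pairs[, 1], pairs[, 2])[1]
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new <- paste0("node_", i)
    frag[new] <- sprintf("(%s:%s,%s:%s)", frag[i], bl(li), frag[j], bl(lj))
    key[new] <- min(key[i], key[j])
    rest <- setdiff(active, c(i, j))
    newd <- (D[rest, i] + D[rest, j] - D[i, j]) / 2
    D <- rbind(cbind(D, stats::setNames(rep(0, nrow(D)), NULL)), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new
    D[rest, new] <- D[new, rest] <- newd
    active <- c(rest, new)
  }

  a <- active[order(key[active])]
  d <- D[a, a]
  # closed-form star resolution for the final three nodes
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[a[1]], bl(l1), frag[a[2]], bl(l2), frag[a[3]], bl(l3))
  ape::read.tree(text = newick)
}

#' Neighbor-joining tree of a phage population's gene content
#'
#' @param profiles Named list phage -> pham profile.
#' @return An unrooted `ape::phylo` tree on GCD distances.
#' @export
gene_content_tree <- function(profiles) {
  neighbor_joining(gcd_distance_matrix(profiles))
}

#' Subsample representatives per cluster
#'
#' At most `max_per_cluster` phages from each cluster, chosen by
#' lexicographic name so the selection is deterministic.
#'
#' @param partition A `cluster_partition`.
#' @param max_per_cluster Cap per cluster (default 10).
#' @return Character vector of retained phage names.
#' @export
cluster_representatives <- function(partition, max_per_cluster = 10) {
  stopifnot(inherits(partition, "cluster_partition"))
  unlist(lapply(partition$members, function(m)
    utils::head(sort(m), max_per_cluster)), use.names = FALSE)
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a distance matrix as a NEXUS file
#'
#' Writes TAXA and DISTANCES blocks (lower-triangular with diagonal),
#' the input format split-network tools consume. Labels are sanitized
#' to alphanumeric plus underscore; a collision after sanitization is
#' an error. The label mapping is returned invisibly.
#'
#' @param matrix Symmetric distance matrix with taxa dimnames.
#' @param path Output path.
#' @return Invisibly, a data.frame mapping original to sanitized
#'   labels.
#' @export
export_nexus_distances <- function(matrix, path) {
  nm <- rownames(matrix)
  stopifnot(!is.null(nm), isTRUE(all.equal(matrix, t(matrix))))
  lab <- sanitize_label(nm)
  if (anyDuplicated(lab))
    stop2("label collision after sanitization: %s", lab[duplicated(lab)][1L])
  n <- length(nm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("", con)
  writeLines("BEGIN TAXA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d;", n), con)
  writeLines(sprintf("  TAXLABELS %s;", paste(lab, collapse = " ")), con)
  writeLines("END;", con)
  writeLines("", con)
  writeLines("BEGIN DISTANCES;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d;", n), con)
  writeLines("  FORMAT TRIANGLE=LOWER DIAGONAL LABELS=LEFT;", con)
  writeLines("  MATRIX", con)
  for (i in seq_len(n))
    writeLines(sprintf("    %s %s", lab[i],
                       paste(sprintf("%.12g", matrix[i, seq_len(i)]), collapse = " ")),
               con)
  writeLines("  ;", con)
  writeLines("END;", con)
  invisible(data.frame(original = nm, sanitized = lab, stringsAsFactors = FALSE))
}

#' Read back a NEXUS distance matrix written by this package
#'
#' Round-trip companion of [export_nexus_distances()], used for
#' self-consistency checks.
#'
#' @param path NEXUS file path.
#' @return Symmetric distance matrix with the sanitized labels.
#' @export
read_nexus_distances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mi <- grep("^\\s*MATRIX\\s*$", lines)
  if (length(mi) != 1L) stop2("'%s': no MATRIX block", path)
  rows <- list()
  for (ln in lines[(mi + 1L):length(lines)]) {
    if (grepl("^\\s*;", ln)) break
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    rows[[parts[1]]] <- as.numeric(parts[-1])
  }
  n <- length(rows)
  m <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n)) {
    m[i, seq_len(i)] <- rows[[i]]
    m[seq_len(i), i] <- rows[[i]]
  }
  m
}
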