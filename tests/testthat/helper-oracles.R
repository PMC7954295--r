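# Independent oracles used across tests.

# Brute-force transitive closure of a thresholded similarity relation,
# via boolean matrix powering (independent of the package's graph path).
oracle_closure_components <- function(ids, qualifies) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && qualifies(ids[i], ids[j])) adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[adj[i, ] > 0] <- k
    }
  }
  stats::setNames(comp, ids)
}

# Exhaustive word-match enumeration by double loop.
oracle_word_matches <- function(x, y, w, rc = FALSE) {
  lx <- nchar(x); ly <- nchar(y)
  out <- list()
  for (i in 1:(lx - w + 1L)) {
    wx <- substr(x, i, i + w - 1L)
    wrc <- if (rc) phamflock::revcomp(wx) else NULL
    for (j in 1:(ly - w + 1L)) {
      wy <- substr(y, j, j + w - 1L)
      if (wx == wy)
        out[[length(out) + 1L]] <- data.frame(x = i, y = j, orientation = "forward")
      if (rc && wrc == wy)
        out[[length(out) + 1L]] <- data.frame(x = i, y = j, orientation = "revcomp")
    }
  }
  if (!length(out))
    return(data.frame(x = integer(), y = integer(), orientation = character()))
  out <- do.call(rbind, out)
  out <- out[order(out$x, out$y, out$orientation), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
random_protein <- function(n, first_m = TRUE) {
  aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
  if (first_m) aa[1] <- "M"
  paste(aa, collapse = "")
}

# Substitute `k` distinct positions (never position 1) with different residues.
mutate_protein <- function(p, positions) {
  aa <- strsplit(p, "")[[1]]
  pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in positions) aa[i] <- sample(setdiff(pool, aa[i]), 1)
  paste(aa, collapse = "")
}

# Fabricate a pham_assignment object from an explicit gene -> pham map
# (bypasses alignment; for testing downstream consumers only).
make_assignment <- function(pham_of) {
  members <- split(names(pham_of), pham_of)
  phage <- function(ids) unique(sub("\\|.*$", "", ids))
  structure(list(
    pham_of = pham_of,
    phams = members,
    orpham = vapply(members, function(m) length(phage(m)) == 1L, logical(1)),
    edges = data.frame(),
    identity_threshold = 35, coverage_threshold = 75),
    class = "pham_assignment")
}

positionwise_nt_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}
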