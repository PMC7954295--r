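# Exact-word dot plots of genomes and concatenated proteomes, emitted
# as match coordinates (render-agnostic). Default word sizes follow dot
# plot practice for phage comparisons: 15 for nucleotide, 5 for protein.

#' All exact word matches between two sequences
#'
#' Enumerates every pair of 1-based start positions `(x, y)` where the
#' `word`-length substrings of `seq_x` and `seq_y` are identical. For
#' the nucleotide alphabet, reverse-complement matches are also
#' reported (orientation `"revcomp"`): `(x, y)` is a revcomp match when
#' the word of `seq_y` at `y` equals the reverse complement of the word
#' of `seq_x` at `x`.
#'
#' @param seq_x,seq_y Sequences (rows = `seq_y`, columns = `seq_x`).
#' @param word Word size, >= 1 and no longer than either sequence.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param revcomp_matches Report reverse-complement matches for
#'   nucleotide input (default `TRUE`; ignored for protein).
#' @return Object of class `dotplot_matches`: list with `matches`
#'   (data.frame `x`, `y`, `orientation`), `word`, `alphabet`, and the
#'   two sequence lengths.
#' @export
word_matches <- function(seq_x, seq_y, word,
                         alphabet = c("nucleotide", "protein"),
                         revcomp_matches = TRUE) {
  alphabet <- match.arg(alphabet)
  stopifnot(word >= 1)
  lx <- nchar(seq_x); ly <- nchar(seq_y)
  if (lx < word || ly < word) stop2("word size %d exceeds a sequence length", word)
  words_x <- substring(seq_x, 1:(lx - word + 1L), word:lx)
  words_y <- substring(seq_y, 1:(ly - word + 1L), word:ly)
  index_y <- split(seq_along(words_y), words_y)
  collect <- function(keys, orientation) {
    hit <- which(keys %in% names(index_y))
    if (!length(hit)) return(NULL)
    ys <- index_y[keys[hit]]
    data.frame(x = rep(hit, lengths(ys)), y = unlist(ys, use.names = FALSE),
               orientation = orientation, stringsAsFactors = FALSE)
  }
  out <- collect(words_x, "forward")
  if (alphabet == "nucleotide" && revcomp_matches) {
    # revcomp of the word at x-position i is the word of revcomp(seq_x)
    # at position lx - word + 2 - i, i.e. the reversed word vector
    rc_x <- rc_string(seq_x)
    rc_words_x <- rev(substring(rc_x, 1:(lx - word + 1L), word:lx))
    out <- rbind(out, collect(rc_words_x, "revcomp"))
  }
  if (is.null(out))
    out <- data.frame(x = integer(), y = integer(), orientation = character())
  out <- out[order(out$x, out$y, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(matches = out, word = word, alphabet = alphabet,
                 len_x = lx, len_y = ly),
            class = "dotplot_matches")
}

#' @export
print.dotplot_matches <- function(x, ...) {
  cat(sprintf("<dotplot_matches> %d x %d, word %d (%s): %d matches\n",
              x$len_x, x$len_y, x$word, x$alphabet, nrow(x$matches)))
  invisible(x)
}

# Character guaranteed outside both alphabets; a word-length run of it
# can never participate in a match, so concatenation boundaries are
# provably inert.
SENTINEL_CHAR <- "#"

# String reverse-complement tolerating the sentinel character (which
# complements to itself). Used on word-indexed strings where Biostrings
# alphabets would reject the sentinel.
rc_string <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

concat_with_sentinel <- function(segments, word) {
  sentinel <- strrep(SENTINEL_CHAR, word)
  seq <- paste(segments, collapse = sentinel)
  offset <- cumsum(c(1L, utils::head(nchar(segments), -1L) + word))
  bounds <- data.frame(phage = names(segments), start = offset,
                       end = offset + nchar(segments) - 1L,
                       stringsAsFactors = FALSE)
  list(sequence = seq, boundaries = bounds)
}

#' Self dot plot of concatenated genomes or proteomes
#'
#' Concatenates the per-phage sequences (whole genomes, or all proteins
#' joined per phage for the proteome level) separated by a word-length
#' sentinel run, then computes the square exact-word dot plot of the
#' concatenation against itself. The boundary table attributes every
#' match block to a phage pair, so intracluster and intercluster
#' signal can be separated.
#'
#' @param genomes Ordered list of `annotated_genome` objects.
#' @param level `"genome"` (nucleotide) or `"proteome"` (amino acid).
#' @param word Word size; defaults to 15 for genomes and 5 for
#'   proteomes.
#' @param revcomp_matches Include reverse-complement matches at the
#'   genome level (default `TRUE`).
#' @return A `dotplot_matches` object with an extra `boundaries`
#'   data.frame (`phage`, `start`, `end` on the concatenated axis; both
#'   axes are identical).
#' @export
concatenated_dotplot <- function(genomes, level = c("genome", "proteome"),
                                 word = NULL, revcomp_matches = TRUE) {
  level <- match.arg(level)
  if (length(genomes) == 0L) stop2("no genomes supplied")
  word <- word %||% if (level == "genome") 15L else 5L
  segments <- if (level == "genome") {
    vapply(genomes, function(g) g$sequence, character(1))
  } else {
    vapply(genomes, function(g) {
      if (nrow(g$genes) == 0L) stop2("genome '%s' has no genes for proteome level", g$name)
      paste(g$genes$protein_seq, collapse = "")
    }, character(1))
  }
  names(segments) <- vapply(genomes, function(g) g$name, character(1))
  cc <- concat_with_sentinel(segments, word)
  dp <- word_matches_sentinel(cc$sequence, word,
                              alphabet = if (level == "genome") "nucleotide" else "protein",
                              revcomp_matches = revcomp_matches)
  dp$boundaries <- cc$boundaries
  dp$level <- level
  dp
}

# word_matches against self, tolerating the sentinel character (words
# containing it simply never match anything else because it is outside
# both alphabets and every sentinel run is word-length).
word_matches_sentinel <- function(seq, word, alphabet, revcomp_matches) {
  l <- nchar(seq)
  words <- substring(seq, 1:(l - word + 1L), word:l)
  clean <- !grepl(SENTINEL_CHAR, words, fixed = TRUE)
  index <- split(seq_along(words)[clean], words[clean])
  collect <- function(keys, keep, orientation) {
    hit <- which(keep & keys %in% names(index))
    if (!length(hit)) return(NULL)
    ys <- index[keys[hit]]
    data.frame(x = rep(hit, lengths(ys)), y = unlist(ys, use.names = FALSE),
               orientation = orientation, stringsAsFactors = FALSE)
  }
  out <- collect(words, clean, "forward")
  if (alphabet == "nucleotide" && revcomp_matches) {
    rc_seq <- rc_string(seq)
    rc <- rev(substring(rc_seq, 1:(l - word + 1L), word:l))
    out <- rbind(out, collect(rc, clean, "revcomp"))
  }
  if (is.null(out))
    out <- data.frame(x = integer(), y = integer(), orientation = character())
  out <- out[order(out$x, out$y, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(matches = out, word = word, alphabet = alphabet,
                 len_x = l, len_y = l),
            class = "dotplot_matches")
}

#' Count dot-plot matches between two phage blocks
#'
#' @param dotplot A `concatenated_dotplot()` result.
#' @param phage_x,phage_y Phage names (x and y block).
#' @return Number of matches whose x falls in `phage_x`'s segment and y
#'   in `phage_y`'s.
#' @export
block_match_count <- function(dotplot, phage_x, phage_y) {
  b <- dotplot$boundaries
  bx <- b[b$phage == phage_x, ]; by <- b[b$phage == phage_y, ]
  if (nrow(bx) != 1L || nrow(by) != 1L) stop2("unknown phage block")
  m <- dotplot$matches
  sum(m$x >= bx$start & m$x <= bx$end & m$y >= by$start & m$y <= by$end)
}

#' Write dot-plot matches and boundaries as TSV
#'
#' @param dotplot A `dotplot_matches` object.
#' @param path Match TSV path (`x`, `y`, `orientation`); boundaries, if
#'   present, go to `paste0(path, ".boundaries.tsv")`.
#' @return `path`, invisibly.
#' @export
write_dotplot_tsv <- function(dotplot, path) {
  utils::write.table(dotplot$matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dotplot$boundaries))
    utils::write.table(dotplot$boundaries, paste0(path, ".boundaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
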