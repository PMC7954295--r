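# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

#' Reverse complement of a nucleotide string
#'
#' Accepts A/C/G/T/N (case-insensitive); returns upper case.
#'
#' @param seq Single nucleotide string.
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Translate a coding sequence with the bacterial/phage genetic code
#'
#' Uses NCBI translation table 11. A terminal stop codon is removed; an
#' internal stop is an error.
#'
#' @param nt Nucleotide coding sequence (length a multiple of 3).
#' @return Amino-acid string without the terminal stop.
#' @export
translate_cds <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  if (nchar(nt) %% 3L != 0L)
    stop2("coding sequence length %d is not a multiple of 3", nchar(nt))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "error"
  ))
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa))
    stop2("internal stop codon in coding sequence")
  aa
}

# Validate a nucleotide string; returns uppercased sequence or raises a
# parse error naming the record and 1-based offset of the first bad char.
check_dna <- function(seq, name = "sequence", allow_n = TRUE) {
  seq <- toupper(seq)
  ok <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regexpr(sprintf("[^%s]", ok), seq)
  if (bad > 0L)
    stop2("record '%s': illegal character '%s' at position %d",
          name, substr(seq, bad, bad), bad)
  seq
}

check_protein <- function(seq, name = "protein") {
  seq <- toupper(seq)
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seq)
  if (bad > 0L)
    stop2("protein '%s': illegal character '%s' at position %d",
          name, substr(seq, bad, bad), bad)
  seq
}

#' Adjusted Rand index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used by the recovery tests to score pham and cluster reconstruction
#' against simulation ground truth. 1 means identical partitions; the
#' expected value under random labelling is 0.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in structure
  (sum_ij - expected) / denom
}

# Deterministic per-stream sub-seed below 2^31 derived from a master seed.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
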