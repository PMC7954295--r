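# Gene Content Similarity (GCS), Gene Content Dissimilarity (GCD),
# sorted GCD profiles and the MaxGCDGap isolation statistic.
#
# GCS between phages A and B with distinct-pham profiles P_A, P_B and
# s = |P_A intersect P_B| shared phams:
#
#   GCS = 100 * (s / |P_A| + s / |P_B|) / 2
#
# i.e. the mean of the two directional shared-gene percentages; GCD is
# 1 - GCS/100 on the 0..1 scale.

#' Gene Content Similarity between two pham profiles
#'
#' @param profile_a,profile_b Non-empty character vectors of pham
#'   identifiers (duplicates collapse; profiles are sets).
#' @return GCS percent in \[0, 100\].
#' @export
gcs <- function(profile_a, profile_b) {
  profile_a <- unique(profile_a)
  profile_b <- unique(profile_b)
  if (length(profile_a) == 0L || length(profile_b) == 0L)
    stop2("GCS is undefined for a phage with no phams")
  s <- length(intersect(profile_a, profile_b))
  100 * (s / length(profile_a) + s / length(profile_b)) / 2
}

#' Pairwise GCS matrix over a population
#'
#' @param profiles Named list phage -> pham profile (see
#'   [pham_profiles()]).
#' @return Symmetric numeric matrix of GCS percents with 100 on the
#'   diagonal, dimnames the phage names.
#' @export
gcs_matrix <- function(profiles) {
  if (length(profiles) < 2L) stop2("need at least 2 phages")
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop2("profiles must be uniquely named by phage")
  nm <- names(profiles)
  n <- length(nm)
  m <- diag(100, n)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    v <- gcs(profiles[[i]], profiles[[j]])
    m[i, j] <- v
    m[j, i] <- v
  }
  m
}

#' GCD profile of a focal phage against a population
#'
#' GCD = 1 - GCS/100 against every other phage, sorted ascending (the
#' focal phage itself is excluded).
#'
#' @param focal Focal phage name.
#' @param profiles Named list phage -> pham profile; must contain
#'   `focal` and at least one other phage.
#' @param gap_from_zero Include the leading gap from 0 (the focal
#'   phage's distance to itself) when computing MaxGCDGap (default
#'   `TRUE`).
#' @return Object of class `gcd_profile`: list with `focal`, `pairs`
#'   (data.frame `phage`, `gcd`, ascending), `max_gcd_gap` (percent) and
#'   `gap_partner` (the phage whose GCD closes the maximal gap).
#' @export
gcd_profile <- function(focal, profiles, gap_from_zero = TRUE) {
  if (!focal %in% names(profiles)) stop2("focal phage '%s' not in population", focal)
  others <- setdiff(names(profiles), focal)
  if (length(others) == 0L) stop2("population must contain at least one other phage")
  gcd <- vapply(others, function(p) 1 - gcs(profiles[[focal]], profiles[[p]]) / 100,
                numeric(1))
  ord <- order(gcd, others)  # ties broken by name for determinism
  pairs <- data.frame(phage = others[ord], gcd = gcd[ord],
                      stringsAsFactors = FALSE, row.names = NULL)
  gap <- max_gcd_gap_from_sorted(pairs, gap_from_zero)
  structure(list(focal = focal, pairs = pairs,
                 max_gcd_gap = gap$gap, gap_partner = gap$partner,
                 gap_from_zero = gap_from_zero),
            class = "gcd_profile")
}

max_gcd_gap_from_sorted <- function(pairs, gap_from_zero) {
  vals <- pairs$gcd
  diffs <- if (gap_from_zero) diff(c(0, vals)) else diff(vals)
  if (length(diffs) == 0L)
    stop2("MaxGCDGap without the leading gap needs at least 2 population phages")
  k <- which.max(diffs)  # ties: earlier (smaller-GCD) gap wins
  partner_idx <- if (gap_from_zero) k else k + 1L
  list(gap = 100 * diffs[k], partner = pairs$phage[partner_idx])
}

#' MaxGCDGap of a GCD profile
#'
#' The largest difference between consecutive values of the ascending
#' GCD list, with 0 prepended when `gap_from_zero` was requested, as a
#' percent. It measures how isolated the focal phage is from the
#' population: a large first gap means even the nearest neighbor shares
#' little gene content.
#'
#' @param profile A `gcd_profile`.
#' @return Named list `gap` (percent) and `partner` (phage name at
#'   which the maximal gap closes).
#' @export
max_gcd_gap <- function(profile) {
  stopifnot(inherits(profile, "gcd_profile"))
  list(gap = profile$max_gcd_gap, partner = profile$gap_partner)
}

#' @export
print.gcd_profile <- function(x, ...) {
  cat(sprintf("<gcd_profile> %s vs %d phages; MaxGCDGap %.2f%% closing at %s\n",
              x$focal, nrow(x$pairs), x$max_gcd_gap, x$gap_partner))
  invisible(x)
}

#' Write a GCS matrix as CSV
#'
#' @param matrix GCS matrix from [gcs_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gcs_csv <- function(matrix, path) {
  utils::write.csv(round(matrix, 2), path, quote = FALSE)
  invisible(path)
}

#' Write a GCD profile as CSV (phage, gcd, cumulative gap)
#'
#' @param profile A `gcd_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gcd_profile_csv <- function(profile, path) {
  tab <- profile$pairs
  tab$gap_from_previous <- diff(c(0, tab$gcd))
  utils::write.csv(tab, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
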