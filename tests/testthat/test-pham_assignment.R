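test_that("pairwise identity matches hand-derived alignments", {
  expect_equal(pairwise_protein_identity("MKV", "MKV"),
               c(identity = 100, coverage = 100))
  # MKVL vs MKIL: 4 aligned columns, 3 identical
  expect_equal(pairwise_protein_identity("MKVL", "MKIL"),
               c(identity = 75, coverage = 100))
  expect_equal(pairwise_protein_identity("AAAA", "WWWW")[["identity"]], 0)
  # ends-free overlap: only the WWW block aligns; identity is over the
  # aligned region, coverage over the shorter (equal-length) sequence
  st <- pairwise_protein_identity("AAAWWW", "WWWGGG")
  expect_equal(st[["identity"]], 100)
  expect_equal(st[["coverage"]], 50)
  # a contained sequence aligns fully: full identity and coverage
  expect_equal(pairwise_protein_identity("MKVLQWERTY", "VLQW"),
               c(identity = 100, coverage = 100))
  expect_error(pairwise_protein_identity("", "MKV"))
})

test_that("identity and coverage are symmetric and bounded", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_protein(sample(20:80, 1))
    b <- random_protein(sample(20:80, 1))
    ab <- pairwise_protein_identity(a, b)
    ba <- pairwise_protein_identity(b, a)
    expect_equal(ab, ba)
    expect_true(all(ab >= 0 & ab <= 100))
  }
})

test_that("chained similarity forms one pham by single linkage", {
  set.seed(5)
  a <- random_protein(100)
  b <- mutate_protein(a, sample(2:100, 5))        # ~95% to a
  c <- mutate_protein(b, sample(setdiff(2:100, which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])), 5))
  prot <- c("P1|1" = a, "P2|1" = b, "P3|1" = c)
  # a-b and b-c are ~95%; a-c is ~90%, below a 92% threshold
  expect_lt(pairwise_protein_identity(a, c)[["identity"]], 92)
  asg <- assign_phams(prot, identity_threshold = 92, coverage_threshold = 75)
  expect_length(asg$phams, 1L)
  expect_false(asg$orpham[[1]])
})

test_that("single-linkage phams equal brute-force transitive closure", {
  set.seed(23)
  # several families of related proteins plus unrelated singletons
  prot <- character(0)
  fam_sizes <- c(4, 3, 3, 2, 1, 1)
  idx <- 0
  for (f in seq_along(fam_sizes)) {
    ref <- random_protein(sample(60:120, 1))
    for (k in seq_len(fam_sizes[f])) {
      idx <- idx + 1
      n <- nchar(ref)
      memb <- mutate_protein(ref, sample(2:n, round(0.08 * n)))
      prot[sprintf("Ph%02d|%d", idx %% 5 + 1, idx)] <- memb
    }
  }
  asg <- assign_phams(prot)
  qualifies <- function(i, j) {
    st <- pairwise_protein_identity(prot[[i]], prot[[j]])
    st[["identity"]] >= 35 && st[["coverage"]] >= 75
  }
  oracle <- oracle_closure_components(names(prot), qualifies)
  expect_equal(adjusted_rand_index(asg$pham_of[names(prot)], oracle), 1)
})

test_that("pham identifiers are canonical under input permutation", {
  set.seed(31)
  prot <- population_proteins(small_population()$genomes)
  asg1 <- assign_phams(prot)
  asg2 <- assign_phams(prot[sample(length(prot))])
  expect_identical(asg1$pham_of[sort(names(prot))],
                   asg2$pham_of[sort(names(prot))])
  expect_identical(asg1$phams, asg2$phams)
})

test_that("composition prescreen never changes the result", {
  set.seed(41)
  prot <- character(0)
  for (i in 1:12) prot[sprintf("A%d|%d", i %% 3, i)] <- random_protein(sample(30:90, 1))
  ref <- random_protein(70)
  prot["B1|1"] <- ref
  prot["B2|1"] <- mutate_protein(ref, sample(2:70, 10))
  with_ps <- assign_phams(prot, prescreen = TRUE)
  without_ps <- assign_phams(prot, prescreen = FALSE)
  expect_identical(with_ps$pham_of, without_ps$pham_of)
  expect_equal(with_ps$edges, without_ps$edges)
})

test_that("orpham flags, profiles and pham-count monotonicity behave", {
  p <- random_protein(50)
  asg <- assign_phams(c("X|1" = p, "Y|1" = p))
  expect_length(asg$phams, 1L)
  expect_false(asg$orpham[[1]])

  # duplicated phams within a phage collapse in the membership profile
  asg2 <- make_assignment(c("Z|1" = "PH0001", "Z|2" = "PH0001", "Z|3" = "PH0002"))
  expect_identical(membership_profile(asg2, "Z"), c("PH0001", "PH0002"))
  expect_error(membership_profile(asg2, "Nope"), "unknown phage")

  # lowering the identity threshold can only merge phams
  set.seed(55)
  prot <- character(0)
  ref <- random_protein(80)
  for (i in 1:6) prot[sprintf("M%d|1", i)] <- mutate_protein(ref, sample(2:80, 8 * i))
  counts <- vapply(c(90, 70, 50, 30, 10), function(t)
    length(assign_phams(prot, identity_threshold = t)$phams), numeric(1))
  expect_true(all(diff(counts) <= 0))
  n_genes <- length(prot)
  expect_true(all(counts >= 1 & counts <= n_genes))
})

test_that("six-orpham focal profile mirrors the reclustering scenario design", {
  asg <- scenario_assignment()
  profile <- membership_profile(asg, "BlueFeather")
  own <- names(which(asg$orpham))
  focal_orphams <- intersect(profile, own[vapply(asg$phams[own], function(m)
    all(startsWith(m, "BlueFeather|")), logical(1))])
  expect_length(focal_orphams, 6L)
  expect_length(profile, 23L)  # 25 genes, 2 paralog duplicates collapse
})
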