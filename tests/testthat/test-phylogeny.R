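test_that("neighbor joining recovers additive matrices exactly", {
  set.seed(61)
  for (k in c(4, 6, 9)) {
    ref <- ape::rtree(k, br = function(n) stats::runif(n, 0.05, 1))
    d <- ape::cophenetic.phylo(ref)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    tree <- neighbor_joining(d)
    got <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
    expect_equal(got, d, tolerance = 1e-9)
    # independent check of topology against ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ape::nj(d))),
                 structure(0, Size = 2, class = "dist"), ignore_attr = TRUE)
  }
})

test_that("three taxa resolve by the closed-form star", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  lens <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(lens["A"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(lens["B"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(lens["C"]), (0.5 + 0.6 - 0.3) / 2)
})

test_that("ties resolve deterministically and bad matrices are rejected", {
  d <- matrix(0.4, 5, 5, dimnames = list(paste0("T", 1:5), paste0("T", 1:5)))
  diag(d) <- 0
  t1 <- ape::write.tree(neighbor_joining(d))
  t2 <- ape::write.tree(neighbor_joining(d))
  expect_identical(t1, t2)
  perm <- c(3, 1, 5, 2, 4)
  t3 <- ape::write.tree(neighbor_joining(d[perm, perm]))
  expect_identical(sort(neighbor_joining(d)$tip.label),
                   sort(neighbor_joining(d[perm, perm])$tip.label))

  bad <- d; bad[1, 2] <- 0.9
  expect_error(neighbor_joining(bad), "not symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -0.1
  expect_error(neighbor_joining(neg), "negative")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("newick output re-parses to the same leaves and total length", {
  set.seed(67)
  ref <- ape::rtree(7)
  d <- ape::cophenetic.phylo(ref)
  tree <- neighbor_joining(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, rownames(d))
  expect_equal(sum(back$edge.length), sum(tree$edge.length), tolerance = 1e-9)
})

test_that("gene-content distances place the expanded cluster on its own branch", {
  pop <- simulate_population(
    bluefeather_scenario_params(seed = 2, outgroup_clusters = 1))
  profiles <- pop$truth$profiles
  six <- c("BlueFeather", "Corgi", "Idaho", "Noely", "Whytu", "Yavru")
  out <- grep("^Outgroup", names(profiles), value = TRUE)
  d <- gcd_distance_matrix(profiles[c(six, out)])
  expect_identical(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(abs(d - t(d)) < 1e-12))
  intra <- max(d[six, six])
  inter <- min(d[six, out])
  expect_lt(intra, inter)

  # identical and disjoint profiles pin the distance extremes
  same <- list(A = c("P1", "P2"), B = c("P1", "P2"), C = c("P1", "P2"))
  expect_true(all(gcd_distance_matrix(same) == 0))
  disj <- list(A = "P1", B = "P2", C = "P3")
  dd <- gcd_distance_matrix(disj)
  expect_true(all(dd[upper.tri(dd)] == 1))
})

test_that("NEXUS distance export round-trips and sanitizes labels", {
  d <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.34567890123, 0.2, 0.34567890123, 0),
              3, 3, dimnames = list(c("Phage A", "Phage-B", "C"),
                                    c("Phage A", "Phage-B", "C")))
  f <- withr::local_tempfile(fileext = ".nex")
  map <- export_nexus_distances(d, f)
  txt <- readLines(f)
  expect_true(any(grepl("NTAX=3", txt)))
  expect_identical(map$sanitized, c("Phage_A", "Phage_B", "C"))
  back <- read_nexus_distances(f)
  expect_equal(unname(back), unname(d), tolerance = 1e-12)

  dup <- d
  dimnames(dup) <- list(c("A B", "A-B", "C"), c("A B", "A-B", "C"))
  expect_error(export_nexus_distances(dup, f), "collision")
})

test_that("cluster representatives are capped and deterministic", {
  profiles <- c(
    stats::setNames(lapply(1:12, function(i) paste0("P", 1:10)), paste0("Zz", 1:12)),
    list(Lone = paste0("Q", 1:10)))
  part <- cluster_by_gcs(gcs_matrix(profiles), 35)
  keep <- cluster_representatives(part, max_per_cluster = 10)
  expect_length(keep, 11L)
  expect_true("Lone" %in% keep)
  expect_identical(keep, cluster_representatives(part, 10))
})
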