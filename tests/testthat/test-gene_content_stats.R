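test_that("GCS follows the shared-pham averaging formula", {
  expect_equal(gcs(c("P1", "P2"), c("P1", "P2")), 100)
  expect_equal(gcs(paste0("P", 1:4), paste0("P", 1:6)),
               100 * (4 / 4 + 4 / 6) / 2, tolerance = 1e-12)
  expect_equal(gcs("P1", "P2"), 0)
  # duplicates collapse: profiles are sets
  expect_equal(gcs(c("P1", "P1", "P2"), c("P1", "P2")), 100)
  expect_error(gcs(character(0), "P1"), "undefined")
})

test_that("GCS is strictly decreasing in partner genome size at fixed sharing", {
  shared <- paste0("S", 1:4)
  a <- c(shared, paste0("A", 1:6))  # |A| = 10
  vals <- vapply(10:20, function(nb)
    gcs(a, c(shared, paste0("B", seq_len(nb - 4)))), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("GCD profiles sort ascending and derive from GCS exactly", {
  profiles <- list(
    A = paste0("P", 1:250),
    B = c(paste0("P", 1:146), paste0("B", 1:104)),  # GCS 58.4 -> GCD 0.416
    C = c(paste0("P", 1:140), paste0("C", 1:110)),  # GCS 56.0 -> GCD 0.440
    D = c(paste0("P", 1:100), paste0("D", 1:150)),  # GCS 40.0 -> GCD 0.600
    E = c(paste0("P", 1:40),  paste0("E", 1:210)))  # GCS 16.0 -> GCD 0.840
  gp <- gcd_profile("A", profiles)
  expect_identical(gp$pairs$phage, c("B", "C", "D", "E"))
  expect_equal(gp$pairs$gcd, c(0.416, 0.44, 0.60, 0.84), tolerance = 1e-12)
  # gaps: 0.416 (from zero), 0.024, 0.16, 0.24 -> max is the leading gap
  expect_equal(gp$max_gcd_gap, 41.6, tolerance = 1e-9)
  expect_identical(gp$gap_partner, "B")
  for (i in seq_len(nrow(gp$pairs))) {
    expect_equal(gp$pairs$gcd[i],
                 1 - gcs(profiles$A, profiles[[gp$pairs$phage[i]]]) / 100,
                 tolerance = 1e-12)
  }
  expect_error(gcd_profile("A", profiles["A"]), "other phage")
})

test_that("MaxGCDGap covers degenerate and flag-off cases", {
  one <- list(A = paste0("P", 1:10), B = c(paste0("P", 1:7), paste0("B", 1:3)))
  gp <- gcd_profile("A", one)
  expect_equal(gp$max_gcd_gap, 30)  # single pair: forced by definition

  none <- list(A = paste0("P", 1:5), B = paste0("B", 1:5), C = paste0("C", 1:5))
  expect_equal(gcd_profile("A", none)$max_gcd_gap, 100)  # total isolation

  # without the leading zero gap, only consecutive differences count
  profiles <- list(A = paste0("P", 1:10),
                   B = c(paste0("P", 1:6), paste0("B", 1:4)),
                   C = c(paste0("P", 1), paste0("C", 1:9)))
  gp2 <- gcd_profile("A", profiles, gap_from_zero = FALSE)
  expect_equal(gp2$pairs$gcd, c(0.4, 0.9))
  expect_equal(gp2$max_gcd_gap, 50)
  expect_identical(gp2$gap_partner, "C")
})

test_that("GCS matrices are symmetric with unit diagonal and CSV export works", {
  set.seed(9)
  profiles <- lapply(1:5, function(i)
    paste0("P", sample(40, sample(10:20, 1))))
  names(profiles) <- paste0("Ph", 1:5)
  m <- gcs_matrix(profiles)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 5))
  expect_true(all(m >= 0 & m <= 100))
  f <- withr::local_tempfile(fileext = ".csv")
  write_gcs_csv(m, f)
  back <- as.matrix(utils::read.csv(f, row.names = 1))
  expect_equal(unname(back), unname(round(m, 2)), tolerance = 0.005)
})

test_that("removing the nearest neighbor never decreases MaxGCDGap", {
  set.seed(17)
  for (rep in 1:10) {
    profiles <- lapply(1:6, function(i) paste0("P", sample(60, sample(15:30, 1))))
    names(profiles) <- paste0("Ph", 1:6)
    gp <- gcd_profile("Ph1", profiles)
    nearest <- gp$pairs$phage[1]
    gp2 <- gcd_profile("Ph1", profiles[setdiff(names(profiles), nearest)])
    expect_gte(gp2$max_gcd_gap, gp$max_gcd_gap - 1e-12)
  }
})
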