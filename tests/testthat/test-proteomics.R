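psm_row <- function(protein, reporters, peptide = "PEP", unique = TRUE,
                    pep = 0.01) {
  df <- data.frame(peptide = peptide, protein_group = protein,
                   unique = unique, pep = pep, stringsAsFactors = FALSE)
  df[paste0("r", 126:131)] <- as.list(reporters)
  df
}

test_that("PSM filtering is strict on PEP and requires a unique peptide", {
  psms <- rbind(
    psm_row("p1", 1:6, pep = 0.049),
    psm_row("p1", 1:6, peptide = "PEP2", pep = 0.05),    # exactly 0.05
    psm_row("p2", 1:6, unique = FALSE, pep = 0.001),     # shared only
    psm_row("p3", 1:6, pep = 0.2))                       # fails PEP
  out <- filter_psms(psms)
  expect_identical(unique(out$protein_group), "p1")
  expect_identical(nrow(out), 1L)  # the 0.05 PSM is rejected (strict <)
  expect_identical(nrow(filter_psms(psms[0, ])), 0L)     # empty in, empty out
})

test_that("protein aggregation is the channel-wise reporter sum", {
  r <- c(10, 20, 30, 40, 50, 60)
  one <- aggregate_protein_matrix(psm_row("p1", r))
  expect_equal(unname(one["p1", ]), r)
  two <- aggregate_protein_matrix(rbind(psm_row("p1", r),
                                        psm_row("p1", r, peptide = "Q")))
  expect_equal(unname(two["p1", ]), 2 * r)
  # planted 2-fold channel effect across 10 noisy PSMs
  set.seed(21)
  base <- c(1, 1, 1, 2, 2, 2) * 1e5
  noisy <- do.call(rbind, lapply(1:10, function(i) {
    psm_row("p1", base * runif(1, 0.5, 2) * oracle_lognoise(6, 0.10),
            peptide = paste0("P", i))
  }))
  M <- aggregate_protein_matrix(noisy)
  ratio <- mean(M[1, 4:6]) / mean(M[1, 1:3])
  expect_lt(abs(ratio / 2 - 1), 0.05)
  # all-zero row flagged non-quantifiable
  z <- aggregate_protein_matrix(psm_row("pz", rep(0, 6)))
  expect_false(attr(z, "quantifiable")[1])
})

test_that("the d statistic matches its closed form and is antisymmetric", {
  X <- matrix(c(0, 0.1, -0.1, 1, 1.1, 0.9), nrow = 1,
              dimnames = list("p1", as.character(126:131)))
  des <- c("126" = "A", "127" = "A", "128" = "A",
           "129" = "B", "130" = "B", "131" = "B")
  r <- sam_test(X, des, "A", "B", s0 = 0.32, n_perm = 25, seed = 1)
  expect_equal(r$d, 1 / (sqrt(2 / 3 * 0.01) + 0.32), tolerance = 1e-4)
  expect_equal(r$d, 2.4898, tolerance = 1e-4)
  # group swap flips the sign
  r2 <- sam_test(X, des, "B", "A", s0 = 0.32, n_perm = 25, seed = 1)
  expect_equal(r2$d, -r$d, tolerance = 1e-12)
  # equal group means: d = 0, never significant
  X0 <- matrix(c(5, 6, 7, 5, 6, 7), nrow = 1,
               dimnames = list("p1", as.character(126:131)))
  r0 <- sam_test(X0, des, "A", "B", n_perm = 25, seed = 1)
  expect_equal(r0$d, 0)
  expect_false(r0$significant)
})

test_that("increasing s0 weakly shrinks |d| for every protein", {
  set.seed(8)
  X <- matrix(rnorm(50 * 6, 10, 1), nrow = 50,
              dimnames = list(paste0("p", 1:50), as.character(126:131)))
  des <- c("126" = "A", "127" = "A", "128" = "A",
           "129" = "B", "130" = "B", "131" = "B")
  d1 <- sam_test(X, des, "A", "B", s0 = 0.1, n_perm = 20, seed = 2)$d
  d2 <- sam_test(X, des, "A", "B", s0 = 0.5, n_perm = 20, seed = 2)$d
  expect_true(all(abs(d2) <= abs(d1) + 1e-12))
  # zero within-group variance stays finite through s0
  Xc <- matrix(c(1, 1, 1, 2, 2, 2), nrow = 1,
               dimnames = list("pc", as.character(126:131)))
  expect_true(is.finite(sam_test(Xc, des, "A", "B", n_perm = 20,
                                 seed = 1)$d))
})

test_that("SAM results are deterministic given seed and n_perm", {
  sim <- simulate_tmt(seed = 77, n_proteins = 120, n_planted = 10)
  M <- aggregate_protein_matrix(filter_psms(sim$psms))
  Ml <- log2(normalize_channels(M))
  a <- sam_test(Ml, sim$channel_conditions, "M1", "M2", n_perm = 50,
                seed = 5)
  b <- sam_test(Ml, sim$channel_conditions, "M1", "M2", n_perm = 50,
                seed = 5)
  expect_identical(a, b)
})

test_that("channel normalization equalizes totals; z-scores standardize rows", {
  set.seed(12)
  M <- matrix(rlnorm(60, 10, 1), nrow = 10,
              dimnames = list(paste0("p", 1:10), as.character(126:131)))
  N <- normalize_channels(M)
  expect_equal(unname(colSums(N)), rep(mean(colSums(M)), 6))
  Z <- zscore_matrix(rbind(M, const = rep(3, 6)))
  expect_equal(unname(rowMeans(Z)), rep(0, 11), tolerance = 1e-12)
  expect_equal(unname(apply(Z[1:10, ], 1, sd)), rep(1, 10),
               tolerance = 1e-12)
  expect_equal(unname(Z["const", ]), rep(0, 6))
  expect_true(attr(Z, "constant")["const"])
  # symmetric pattern gives symmetric +/- z
  Zs <- zscore_matrix(matrix(c(0, 0, 0, 1, 1, 1), nrow = 1,
                             dimnames = list("s", as.character(126:131))))
  expect_equal(unname(Zs[1, 1:3]), -unname(Zs[1, 4:6]))
})
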