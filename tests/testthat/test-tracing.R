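test_that("natural envelopes match closed forms and the convolution oracle", {
  # no carbons, carbon-only mode: all mass in M+0
  expect_equal(unname(natural_envelope("H2O", 3)), c(1, 0, 0, 0))
  # two carbons: M+1/M+0 = 2 (0.0107/0.9893)
  e2 <- natural_envelope("C2H4O2", 2)
  expect_equal(unname(e2[2] / e2[1]), 2 * 0.0107 / 0.9893,
               tolerance = 1e-9)
  # C6: binomial(6, 0.0107)
  expect_equal(unname(natural_envelope("C6H12O6", 6)),
               dbinom(0:6, 6, 0.0107), tolerance = 1e-12)
  # full-element mode against the atom-by-atom convolution oracle
  counts <- c(C = 9, H = 11, N = 1, O = 3, S = 1)
  expect_equal(unname(natural_envelope("C9H11NO3S", 4, "CHNOS")),
               unname(oracle_envelope(counts, 4,
                                      c("C", "H", "N", "O", "S"))),
               tolerance = 1e-10)
  # truncation never renormalizes: probabilities sum to <= 1
  expect_lte(sum(natural_envelope("C40H60N10O12", 5)), 1)
})

test_that("natural-abundance correction inverts forward convolution", {
  counts <- c(C = 10, H = 14, O = 5)
  for (f in c(0, 0.1, 0.25, 0.5)) {
    obs <- oracle_labeled_envelope(counts, K = 6, shift = 3, fraction = f)
    x <- correct_natural_abundance(obs, "C10H14O5", 3)
    expect_equal(unname(x[4]), f, tolerance = 1e-6)
    expect_equal(sum(x), 1, tolerance = 1e-12)
  }
  # unlabeled species measured at pure natural abundance: zero labeling
  obs0 <- oracle_envelope(counts, 6)
  x0 <- correct_natural_abundance(obs0, "C10H14O5", 3)
  expect_lt(abs(x0[4]), 1e-9)
  # plain least-squares diagnostic route agrees when noise-free
  xs <- correct_natural_abundance(
    oracle_labeled_envelope(counts, 6, 3, 0.25), "C10H14O5", 3,
    method = "solve")
  expect_equal(unname(xs[4]), 0.25, tolerance = 1e-9)
})

test_that("correction is the identity without correctable atoms", {
  x <- correct_natural_abundance(c(70, 10, 20), "H4N2O3", 2)
  expect_equal(unname(x), c(0.7, 0.1, 0.2))
})

test_that("short envelopes are rejected with advice", {
  expect_error(correct_natural_abundance(c(1, 0), "C6H12O6", 3),
               "label_shift")
})

test_that("enrichment returns both estimators with the stated identities", {
  e <- enrichment(c(80, 0, 20), "C2H4O2", 2, correct = FALSE)
  expect_equal(e$labeled_over_unlabeled_ratio, 0.25)
  expect_equal(e$labeled_fraction, 0.20)
  # fraction = ratio/(1+ratio) when only M+0 and M+n populated
  expect_equal(e$labeled_fraction, 0.25 / 1.25)
  e0 <- enrichment(c(100, 0, 0), "C2H4O2", 2, correct = FALSE)
  expect_equal(e0$labeled_fraction, 0)
  # M+0 = 0: ratio undefined, fraction still returned
  em <- enrichment(c(0, 0, 50), "C2H4O2", 2, correct = FALSE)
  expect_true(is.na(em$labeled_over_unlabeled_ratio))
  expect_equal(em$labeled_fraction, 1)
  # invariance to global intensity rescaling
  e1 <- enrichment(c(80, 5, 20), "C5H8O3", 2)
  e2 <- enrichment(10 * c(80, 5, 20), "C5H8O3", 2)
  expect_equal(e1$labeled_fraction, e2$labeled_fraction, tolerance = 1e-12)
})

test_that("round trip holds up to C40 noise-free and is unbiased at 5% noise", {
  counts <- c(C = 40, H = 60, N = 10, O = 12)
  for (f in c(0, 0.1, 0.25, 0.5)) {
    obs <- oracle_labeled_envelope(counts, K = 5, shift = 2, fraction = f)
    x <- correct_natural_abundance(obs, "C40H60N10O12", 2)
    expect_equal(unname(x[3]), f, tolerance = 1e-6)
  }
  # planted histone-acetyl enrichment, 5% multiplicative noise, n = 8:
  # mean recovered fraction within 0.01 of truth
  set.seed(9)
  truth <- 0.225
  clean <- oracle_labeled_envelope(c(C = 47, H = 84, N = 14, O = 15),
                                   K = 5, shift = 2, fraction = truth)
  rec <- vapply(1:8, function(i) {
    noisy <- clean * oracle_lognoise(length(clean), 0.05)
    enrichment(noisy, "C47H84N14O15", 2)$labeled_fraction
  }, numeric(1))
  expect_lt(abs(mean(rec) - truth), 0.01)
})

test_that("trace summary compares groups and tolerates missing species", {
  sim <- simulate_envelopes(seed = 31, cv = 0)
  ts <- trace_summary(sim$envelopes, sim$design, "M0", "M1")
  merged <- merge(ts, sim$truth, by = c("species_id", "group"))
  # noise-free: group means equal planted fractions
  expect_equal(merged$mean, merged$labeled_fraction, tolerance = 1e-6)
  # identical envelopes in both groups: difference zero
  same <- sim$envelopes[sim$envelopes$species_id == "pyruvate" &
                          sim$envelopes$sample_id %in%
                          c("M0_1", "M0_2", "M1_1", "M1_2"), ]
  one <- same$intensity[same$sample_id == same$sample_id[1]]
  same$intensity <- rep(one, 4)
  t2 <- trace_summary(same, sim$design, "M0", "M1")
  expect_equal(unique(t2$diff), 0, tolerance = 1e-12)
  # species present in only one group: row emitted, comparison NA
  part <- sim$envelopes[!(sim$envelopes$species_id == "lactate" &
                            grepl("^M1", sim$envelopes$sample_id)), ]
  t3 <- trace_summary(part, sim$design, "M0", "M1")
  lac <- t3[t3$species_id == "lactate", ]
  expect_true(nrow(lac) >= 1)
  expect_true(all(is.na(lac$p)))
})

test_that("planted group enrichment differences are detected across seeds", {
  species <- data.frame(species_id = "sp", formula = "C10H14O5",
                        label_shift = 3L, A = 0.10, B = 0.20,
                        stringsAsFactors = FALSE)
  detected <- vapply(1:20, function(s) {
    sim <- simulate_envelopes(seed = 400 + s, species = species,
                              groups = c("A", "B"), n_per_group = 8,
                              cv = 0.05)
    ts <- trace_summary(sim$envelopes, sim$design, "A", "B")
    all(ts$p < 0.01)
  }, logical(1))
  expect_gte(sum(detected), 18)
})
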