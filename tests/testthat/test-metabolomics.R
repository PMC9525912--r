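# Small fixed library used throughout: one low-zone amine, one high-zone
# amine (two sites), one TCA-track acid.
tiny_library <- function() {
  data.frame(
    compound_id = c("serine", "glycine", "succinate"),
    name = c("serine", "glycine", "succinic acid"),
    formula = c("C3H7NO3", "C2H5NO2", "C4H6O4"),
    amine_sites = c(1L, 1L, 0L),
    carbonyl_sites = c(0L, 0L, 2L),
    rt_zone = c("low", "high", "tca"),
    stringsAsFactors = FALSE)
}

feature_at <- function(mz, sample = "s1", intensity = 1e6) {
  data.frame(sample_id = sample, mz = mz, rt = 5, intensity = intensity,
             charge = 1L, stringsAsFactors = FALSE)
}

test_that("matching accepts within 5 ppm inclusive and rejects beyond", {
  lib <- tiny_library()
  th <- derivatized_mz("C3H7NO3", 1, "dansyl")
  m0 <- match_features(feature_at(th), lib)
  expect_true(m0$accepted)
  expect_identical(m0$compound_id, "serine")
  expect_equal(m0$ppm, 0, tolerance = 1e-9)
  # the boundary is inclusive: a feature whose achieved |ppm| equals the
  # tolerance exactly is accepted
  mb <- match_features(feature_at(th * (1 + 5e-6)), lib)
  expect_equal(mb$ppm, 5, tolerance = 1e-6)
  expect_identical(mb$accepted, abs(mb$ppm) <= 5)
  m_at_tol <- match_features(feature_at(th * (1 + 5e-6)), lib,
                             tol_ppm = abs(mb$ppm))
  expect_true(m_at_tol$accepted)
  m_in <- match_features(feature_at(th * (1 + 4.99e-6)), lib)
  expect_true(m_in$accepted)
  # +5.002 ppm: past the threshold
  mr <- match_features(feature_at(th * (1 + 5.002e-6)), lib)
  expect_false(mr$accepted)
  expect_identical(mr$compound_id, "serine")  # best match still reported
  # empty feature list is an empty result, not an error
  expect_identical(nrow(match_features(feature_at(th)[0, ], lib)), 0L)
})

test_that("matching picks the nearest candidate and breaks ties stably", {
  lib <- tiny_library()
  # succinate mono- vs bis-O-BHA are distinct candidates of one compound
  th2 <- derivatized_mz("C4H6O4", 2, "obha")
  m <- match_features(feature_at(th2), lib)
  expect_identical(m$n_sites, 2L)
  expect_identical(m$scheme, "obha")
  # two compounds at identical theoretical m/z: fewer sites, then id
  lib2 <- data.frame(
    compound_id = c("b_two_site", "a_two_site"),
    name = c("b", "a"), formula = c("C4H12N2", "C4H12N2"),
    amine_sites = c(2L, 2L), carbonyl_sites = 0L,
    rt_zone = "low", stringsAsFactors = FALSE)
  th <- derivatized_mz("C4H12N2", 2, "dansyl")
  mt <- match_features(feature_at(th), lib2)
  expect_identical(mt$compound_id, "a_two_site")
})

test_that("accepted set is monotone in the ppm tolerance", {
  lib <- tiny_library()
  set.seed(11)
  th <- derivatized_mz("C2H5NO2", 1, "dansyl")
  feats <- do.call(rbind, lapply(rnorm(60, 0, 2.5), function(ppm) {
    feature_at(th * (1 + ppm * 1e-6))
  }))
  m3 <- match_features(feats, lib, tol_ppm = 3)
  m5 <- match_features(feats, lib, tol_ppm = 5)
  expect_true(all(m5$accepted[m3$accepted]))
  expect_gte(sum(m5$accepted), sum(m3$accepted))
})

test_that("internal-standard assignment follows zone and analogue rules", {
  st <- triomics:::.default_standards()
  expect_identical(assign_internal_standard("x", "dansyl", "low", st),
                   "is_serine_d")
  expect_identical(assign_internal_standard("x", "dansyl", "high", st),
                   "is_glycine_d")
  # exact labeled analogue beats the fallback
  st2 <- rbind(st, data.frame(is_id = "is_succinate_13c4",
                              formula = "[13C]4H6O4", amount_nmol = 1,
                              rt_zone = "tca", scheme = "obha", sites = 2L,
                              target_compound_id = "succinate"))
  expect_identical(
    assign_internal_standard("succinate", "obha", "tca", st2),
    "is_succinate_13c4")
  # no analogue: malate fallback
  expect_identical(assign_internal_standard("citrate", "obha", "tca", st2),
                   "is_malate_13c4")
  expect_error(
    assign_internal_standard("x", "dansyl", "mid", st), "zone")
})

test_that("concentration formula is linear and scale-invariant", {
  expect_equal(quantify_concentration(2e6, 1e6, 1, 0.1), 20)
  expect_equal(quantify_concentration(0, 1e6, 1, 0.1), 0)
  expect_equal(quantify_concentration(2e6, 2e6, 1, 0.1), 10)
  # global intensity rescaling of a sample cancels
  expect_equal(quantify_concentration(7 * 2e6, 7 * 1e6, 1, 0.1),
               quantify_concentration(2e6, 1e6, 1, 0.1))
  # zero standard intensity: flagged missing, not an error
  expect_true(is.na(quantify_concentration(1e6, 0, 1, 0.1)))
  expect_error(quantify_concentration(-1, 1e6, 1, 0.1))
})

test_that("planted concentrations are recovered within 5% median error", {
  sim <- simulate_metabolome(seed = 101, n_compounds = 40, n_per_group = 8,
                             cv = 0.10)
  m <- match_features(sim$features, sim$library)
  is_int <- match_standards(sim$features, sim$standards)
  conc <- quantify_concentrations(m, sim$library, is_int, sim$standards,
                                  sim$design)
  merged <- merge(conc, sim$truth, by = c("compound_id", "sample_id"))
  merged$group <- sub("_.*", "", merged$sample_id)
  # recovered concentration = mean over the 8 injections of a group
  per_cg <- aggregate(cbind(concentration.x, concentration.y) ~
                        compound_id + group, data = merged, FUN = mean)
  rel_err <- abs(per_cg$concentration.x / per_cg$concentration.y - 1)
  expect_lt(median(rel_err), 0.05)
})

test_that("volcano statistics match the closed-form pooled t-test", {
  X <- rbind(ident = c(1, 2, 3, 1, 2, 3),
             novar = c(10, 10, 10, 20, 20, 20),
             shift = c(9, 10, 11, 18, 20, 22))
  colnames(X) <- paste0("s", 1:6)
  des <- data.frame(sample_id = paste0("s", 1:6),
                    group = rep(c("A", "B"), each = 3), protein_mg = 1)
  v <- differential_volcano(X, des, "A", "B")
  expect_equal(v$log2fc[v$compound_id == "ident"], 0)
  expect_equal(v$p[v$compound_id == "ident"], 1)
  expect_equal(v$log2fc[v$compound_id == "novar"], 1)
  expect_identical(v$flag[v$compound_id == "novar"], "zero_variance")
  expect_true(is.na(v$p[v$compound_id == "novar"]))
  # hand-computed pooled t: sp2 = 2.5, se = sqrt(2.5 * 2/3), t = 10/se
  expect_equal(v$t[v$compound_id == "shift"], 10 / sqrt(2.5 * 2 / 3),
               tolerance = 1e-12)
  expect_equal(v$log2fc[v$compound_id == "shift"], 1)
  tt <- t.test(c(18, 20, 22), c(9, 10, 11), var.equal = TRUE)
  expect_equal(v$p[v$compound_id == "shift"], tt$p.value,
               tolerance = 1e-12)
})

test_that("null volcano p-values are uniform across seeds", {
  seeds <- 1:20
  crit <- 1.628 / sqrt(1000)  # KS 1% critical value, n = 1000
  des <- data.frame(sample_id = paste0("s", 1:16),
                    group = rep(c("A", "B"), each = 8), protein_mg = 1)
  pass <- vapply(seeds, function(s) {
    set.seed(s)
    X <- matrix(rlnorm(1000 * 16, 0, 0.3), nrow = 1000,
                dimnames = list(paste0("c", 1:1000), paste0("s", 1:16)))
    p <- differential_volcano(X, des, "A", "B")$p
    D <- max(abs(sort(p) - (seq_along(p) - 0.5) / length(p))) +
      0.5 / length(p)
    D < crit
  }, logical(1))
  expect_gte(sum(pass), 18)
})
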