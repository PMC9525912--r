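# Independent oracles used across the suite. These deliberately do not
# reuse the package's mass table, parser or convolution code: masses are
# a second literal table summed by hand, and envelopes come from
# atom-by-atom polynomial products via stats::convolve.

# Literal monoisotopic masses (IUPAC), keyed by plain symbols; labeled
# isotopes keyed "13C"/"2H"/"15N".
oracle_masses <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151, Cl = 34.96885271, Na = 22.98976928,
  K = 38.9637069, "13C" = 13.0033548378, "2H" = 2.0141017780,
  "15N" = 15.0001088984)

# Hand summation over a named count vector.
oracle_mass <- function(counts) {
  total <- 0
  for (sym in names(counts)) total <- total + counts[[sym]] * oracle_masses[[sym]]
  total
}

# Render oracle-style counts as the package's formula string notation.
oracle_formula_string <- function(counts) {
  paste(vapply(names(counts), function(sym) {
    tag <- if (sym %in% c("13C", "2H", "15N")) paste0("[", sym, "]") else sym
    paste0(tag, counts[[sym]])
  }, character(1)), collapse = "")
}

# Random composed formula: plain CHNOS(P) plus occasional isotope labels.
oracle_random_formula <- function() {
  counts <- c(
    C = sample(1:30, 1), H = sample(1:50, 1), N = sample(0:6, 1),
    O = sample(0:10, 1), S = sample(0:2, 1), P = sample(0:2, 1))
  if (runif(1) < 0.3) counts["13C"] <- sample(1:4, 1)
  if (runif(1) < 0.2) counts["2H"] <- sample(1:3, 1)
  if (runif(1) < 0.2) counts["15N"] <- 1
  counts[counts > 0]
}

# Natural-abundance tables for the brute-force envelope oracle.
oracle_abundance <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))

# Brute-force envelope: multiply in one atom at a time with an open
# convolution, then truncate.
oracle_envelope <- function(counts, K, elements = c("C")) {
  p <- 1
  for (sym in names(counts)) {
    if (!sym %in% elements) next
    for (atom in seq_len(counts[[sym]])) {
      a <- oracle_abundance[[sym]]
      p <- stats::convolve(p, rev(a), type = "open")
    }
  }
  p <- c(p, numeric(K + 1))[1:(K + 1)]
  names(p) <- paste0("M+", 0:K)
  p
}

# Forward-mix an observed envelope at a planted labeled fraction: the
# unlabeled species' envelope plus the fully labeled species' envelope
# (n fewer natural carbons, shifted by n).
oracle_labeled_envelope <- function(counts, K, shift, fraction,
                                    elements = "C") {
  unl <- oracle_envelope(counts, K, elements)
  lab_counts <- counts
  lab_counts["C"] <- lab_counts["C"] - shift
  lab <- oracle_envelope(lab_counts[lab_counts > 0], K - shift, elements)
  (1 - fraction) * unl + fraction * c(numeric(shift), lab)
}

# Mean-1 lognormal noise used by simulation-style tests.
oracle_lognoise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}
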