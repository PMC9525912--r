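# Ground-truth simulators for every input the analysis modules consume.
#
# Defaults emulate the study design: three macrophage states (M0/M1/M2),
# at least eight LC-MS injections per sample, lognormal multiplicative
# intensity noise at 10% CV, 1-ppm mass jitter, spiked internal standards
# at 1 nmol (10 ul of 0.1 mM), a TMT six-plex with two channels per
# state, and tracer enrichments in the ranges observed for
# 13C6-glucose-derived pyruvate/lactate/succinate and H3K18/23
# 13C2-acetylation. Every generator is deterministic for a fixed integer
# seed (Mersenne-Twister, inversion normals) and emits the same TSV
# dialects the readers consume.

.df_clean <- function(df) { rownames(df) <- NULL; df }

.sim_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
}

# Mean-1 lognormal multiplicative noise at a given CV.
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

.make_design <- function(groups, n_per_group, protein_mg) {
  data.frame(
    sample_id = unlist(lapply(groups, function(g) {
      paste0(g, "_", seq_len(n_per_group))
    })),
    group = rep(groups, each = n_per_group),
    protein_mg = protein_mg,
    injection = rep(seq_len(n_per_group), times = length(groups)),
    stringsAsFactors = FALSE)
}

# Default internal-standard manifest: doubly/triply labeled glycine and
# serine for the dansyl track (high/low retention-time zones) and
# 13C4-malate for the O-BHA track (exact-analogue fallback).
.default_standards <- function() {
  data.frame(
    is_id = c("is_serine_d", "is_glycine_d", "is_malate_13c4"),
    formula = c("[13C]3[2H]3[15N]H4O3", "[13C]2[2H]2[15N]H3O2",
                "[13C]4H6O5"),
    amount_nmol = c(1, 1, 1),
    rt_zone = c("low", "high", "tca"),
    scheme = c("dansyl", "dansyl", "obha"),
    sites = c(1L, 1L, 2L),
    target_compound_id = c(NA, NA, "malate"),
    stringsAsFactors = FALSE)
}

# Random elemental formulas whose derivatized m/z are mutually separated
# (so planted features have an unambiguous best match).
.random_library <- function(n_compounds, min_sep_da = 0.05) {
  standards <- .default_standards()
  taken <- vapply(seq_len(nrow(standards)), function(k) {
    derivatized_mz(standards$formula[k], standards$sites[k],
                   standards$scheme[k])
  }, numeric(1))
  rows <- list(); tries <- 0
  while (length(rows) < n_compounds && tries < n_compounds * 200) {
    tries <- tries + 1
    dansyl <- length(rows) %% 2 == 0
    nc <- sample(3:12, 1); nh <- sample(seq_len(2 * nc + 1), 1)
    nn <- if (dansyl) sample(1:3, 1) else sample(0:1, 1)
    no <- sample(1:6, 1)
    f <- paste0("C", nc, "H", nh, if (nn > 0) paste0("N", nn) else "",
                "O", no)
    amine <- if (dansyl) sample(1:2, 1) else 0L
    carbonyl <- if (dansyl) 0L else sample(1:2, 1)
    zone <- if (dansyl) sample(c("low", "high"), 1) else "tca"
    scheme <- if (dansyl) "dansyl" else "obha"
    nsite <- max(amine, carbonyl)
    mzs <- vapply(seq_len(nsite), function(n) {
      derivatized_mz(f, n, scheme)
    }, numeric(1))
    if (length(taken) && min(abs(outer(mzs, taken, `-`))) < min_sep_da) next
    taken <- c(taken, mzs)
    rows[[length(rows) + 1]] <- data.frame(
      compound_id = sprintf("cmpd%03d", length(rows) + 1),
      name = sprintf("synthetic compound %d", length(rows) + 1),
      formula = f, amine_sites = amine, carbonyl_sites = carbonyl,
      rt_zone = zone, stringsAsFactors = FALSE)
  }
  if (length(rows) < n_compounds) {
    stop("could not generate a collision-free library", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a metabolomics experiment with planted concentrations
#'
#' Generates a collision-free compound library, the default
#' internal-standard manifest (labeled serine/glycine for the dansyl
#' zones, 13C4-malate for the O-BHA track), a sample design, and
#' per-sample LC-MS features at derivatized theoretical m/z with Gaussian
#' ppm jitter and lognormal intensity noise. A subset of compounds
#' carries a planted log2 effect in one group. The truth table holds the
#' planted concentration of every compound in every sample.
#'
#' @param seed Integer seed (fixed seed => identical output).
#' @param n_compounds Library size.
#' @param groups Group labels (default the three macrophage states).
#' @param n_per_group Injections per group (default 8).
#' @param cv Lognormal intensity CV (default 0.10).
#' @param ppm_jitter_sd Gaussian m/z jitter, in ppm (default 1).
#' @param n_planted Number of compounds with a group effect.
#' @param effect_log2 Planted log2 fold change (default 1).
#' @param effect_group Group carrying the effect (default `"M1"`).
#' @param protein_mg Protein mass per sample in mg (default 0.1).
#' @return List: `library`, `standards`, `design`, `features`, `truth`
#'   (compound x sample planted concentrations in nmol/mg and planted
#'   effect flags).
#' @export
simulate_metabolome <- function(seed = 1L, n_compounds = 50,
                                groups = c("M0", "M1", "M2"),
                                n_per_group = 8, cv = 0.10,
                                ppm_jitter_sd = 1.0, n_planted = 10,
                                effect_log2 = 1.0, effect_group = "M1",
                                protein_mg = 0.1) {
  .sim_seed(seed)
  library <- .random_library(n_compounds)
  standards <- .default_standards()
  design <- .make_design(groups, n_per_group, protein_mg)
  base_conc <- stats::rlnorm(n_compounds, meanlog = 0, sdlog = 1)  # nmol/mg
  planted <- rep(FALSE, n_compounds)
  planted[sample.int(n_compounds, min(n_planted, n_compounds))] <- TRUE
  zone_response <- c(low = 2e6, high = 1.5e6, tca = 1e6)  # area per nmol
  feats <- list(); truth <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    mult <- ifelse(planted & design$group[s] == effect_group,
                   2^effect_log2, 1)
    conc <- base_conc * mult
    for (i in seq_len(n_compounds)) {
      ent <- library[i, ]
      scheme <- if (ent$amine_sites > 0) "dansyl" else "obha"
      nsite <- max(ent$amine_sites, ent$carbonyl_sites)
      mz_th <- derivatized_mz(ent$formula, nsite, scheme)
      amount <- conc[i] * protein_mg
      feats[[length(feats) + 1]] <- data.frame(
        sample_id = sid,
        mz = mz_th * (1 + stats::rnorm(1, 0, ppm_jitter_sd) * 1e-6),
        rt = switch(ent$rt_zone, low = 4, high = 14, tca = 9) +
          stats::runif(1, -1, 1),
        intensity = zone_response[[ent$rt_zone]] * amount * .lognoise(1, cv),
        charge = 1L, stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        compound_id = ent$compound_id, sample_id = sid,
        concentration = conc[i], planted = planted[i],
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(standards))) {
      st <- standards[k, ]
      mz_th <- derivatized_mz(st$formula, st$sites, st$scheme)
      feats[[length(feats) + 1]] <- data.frame(
        sample_id = sid,
        mz = mz_th * (1 + stats::rnorm(1, 0, ppm_jitter_sd) * 1e-6),
        rt = switch(st$rt_zone, low = 4, high = 14, tca = 9),
        intensity = zone_response[[st$rt_zone]] * st$amount_nmol *
          .lognoise(1, cv),
        charge = 1L, stringsAsFactors = FALSE)
    }
  }
  list(library = library, standards = standards, design = design,
       features = .df_clean(do.call(rbind, feats)),
       truth = .df_clean(do.call(rbind, truth)))
}

#' Simulate PRM histone peak areas with a SILAC heavy standard
#'
#' Plants per-group modification levels (a subset carries a log2 effect),
#' a fixed heavy-standard level per modification, and a peptide-specific
#' response bias shared between the light and heavy channels — exactly
#' the bias that ratio-of-ratios normalization must cancel.
#'
#' @param seed Integer seed.
#' @param n_modifications Panel size (default 15, the quantified panel).
#' @param n_planted Modifications with a planted group effect.
#' @param effect_log2 Planted log2 fold change (default 1).
#' @param effect_group Group carrying the effect (default `"M2"`).
#' @param groups,n_per_group Design (default M1/M2, 8 injections).
#' @param cv Lognormal area CV (default 0.10).
#' @return List: `panel`, `design`, `areas`, `truth` (per modification
#'   and group: true level, bias, planted flag).
#' @export
simulate_prm <- function(seed = 1L, n_modifications = 15, n_planted = 5,
                         effect_log2 = 1.0, effect_group = "M2",
                         groups = c("M1", "M2"), n_per_group = 8,
                         cv = 0.10) {
  .sim_seed(seed)
  panel <- data.frame(
    peptide = sprintf("pep%02d", ((seq_len(n_modifications) - 1) %/% 2) + 1),
    modification = sprintf("mod%02d", seq_len(n_modifications)),
    site = sprintf("site%02d", seq_len(n_modifications)),
    stringsAsFactors = FALSE)
  design <- .make_design(groups, n_per_group, protein_mg = 0.02)
  base_level <- stats::rlnorm(n_modifications, log(0.2), 0.5)
  heavy_level <- stats::rlnorm(n_modifications, log(0.25), 0.3)
  bias <- stats::rlnorm(n_modifications, 0, 0.5)  # shared light/heavy
  planted <- rep(FALSE, n_modifications)
  planted[sample.int(n_modifications, min(n_planted, n_modifications))] <-
    TRUE
  rows <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    mult <- ifelse(planted & design$group[s] == effect_group,
                   2^effect_log2, 1)
    level <- base_level * mult
    for (pep in unique(panel$peptide)) {
      u_light <- 1e6 * .lognoise(1, cv)
      u_heavy <- 5e5 * .lognoise(1, cv)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, peptide = pep, modification = "unmodified",
        channel = c("light", "heavy"), area = c(u_light, u_heavy),
        stringsAsFactors = FALSE)
      idx <- which(panel$peptide == pep)
      for (i in idx) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, peptide = pep,
          modification = panel$modification[i],
          channel = c("light", "heavy"),
          area = c(u_light * level[i] * bias[i] * .lognoise(1, cv),
                   u_heavy * heavy_level[i] * bias[i] * .lognoise(1, cv)),
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, lapply(groups, function(g) {
    data.frame(modification = panel$modification, group = g,
               level = base_level *
                 ifelse(planted & g == effect_group, 2^effect_log2, 1),
               heavy_level = heavy_level, bias = bias, planted = planted,
               stringsAsFactors = FALSE)
  }))
  list(panel = panel, design = design,
       areas = .df_clean(do.call(rbind, rows)), truth = .df_clean(truth))
}

# Default tracing panel: O-BHA-derivatized glycolysis/TCA ions and one
# H3 K18-K23 tryptic-peptide acetyl ion, with group enrichments in the
# observed ranges (pyruvate/succinate 1-2%, lactate 10-15%, H3K18/23ac
# 20-25%).
.default_trace_species <- function() {
  data.frame(
    species_id = c("pyruvate", "lactate", "succinate", "h3k18_23ac"),
    formula = c("C10H11NO3", "C10H13NO3", "C11H13NO4", "C47H84N14O15"),
    label_shift = c(3L, 3L, 2L, 2L),
    M0 = c(0.010, 0.100, 0.010, 0.200),
    M1 = c(0.020, 0.150, 0.020, 0.225),
    M2 = c(0.015, 0.125, 0.015, 0.250),
    stringsAsFactors = FALSE)
}

#' Simulate isotopologue envelopes by forward convolution
#'
#' For each species and sample the observed envelope is the mixture
#' `(1 - f) x natural(unlabeled) + f x natural(labeled)` — the natural
#' envelope of the species with `label_shift` atoms fixed heavy — scaled
#' and perturbed by multiplicative noise per isotopologue. This forward
#' construction is the exact inverse of the natural-abundance correction,
#' so the truth table round-trips through it.
#'
#' @param seed Integer seed.
#' @param species Data frame `species_id`, `formula`, `label_shift`, and
#'   one column of planted labeled fractions per group; default the
#'   glucose-tracing panel (pyruvate, lactate, succinate, H3K18/23ac).
#' @param groups Group labels; must name fraction columns of `species`.
#' @param n_per_group Replicates per group (default 8).
#' @param cv Multiplicative intensity CV (default 0.05).
#' @param extra_offsets Envelope length beyond the label shift (K =
#'   `label_shift + extra_offsets`).
#' @return List: `species`, `design`, `envelopes` (long TSV dialect),
#'   `truth` (species x group planted fractions).
#' @export
simulate_envelopes <- function(seed = 1L, species = NULL,
                               groups = c("M0", "M1", "M2"),
                               n_per_group = 8, cv = 0.05,
                               extra_offsets = 3L) {
  .sim_seed(seed)
  if (is.null(species)) species <- .default_trace_species()
  stopifnot(all(groups %in% names(species)))
  design <- .make_design(groups, n_per_group, protein_mg = 0.1)
  rows <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]; grp <- design$group[s]
    for (i in seq_len(nrow(species))) {
      sp <- species[i, ]
      K <- sp$label_shift + extra_offsets
      A <- .correction_matrix(sp$formula, K, sp$label_shift)
      f <- sp[[grp]]
      p <- (1 - f) * A[, 1] + f * A[, sp$label_shift + 1]
      inten <- 1e6 * p * .lognoise(K + 1, cv)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, species_id = sp$species_id, formula = sp$formula,
        m_offset = 0:K, intensity = inten, label_shift = sp$label_shift,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, lapply(groups, function(g) {
    data.frame(species_id = species$species_id, group = g,
               labeled_fraction = species[[g]], stringsAsFactors = FALSE)
  }))
  list(species = species, design = design,
       envelopes = .df_clean(do.call(rbind, rows)), truth = .df_clean(truth))
}

#' Simulate a TMT six-plex PSM table with planted effects
#'
#' Protein-level log2 intensities carry planted condition effects and
#' per-channel Gaussian noise; each protein's intensity is split over its
#' PSMs with weights shared across channels (so summed aggregation
#' recovers the protein value exactly). Decoy content exercises the
#' filters: a fraction of PSMs gets PEP >= the acceptance bound, and
#' `n_shared_only` extra proteins have no unique peptide.
#'
#' @param seed Integer seed.
#' @param n_proteins Quantifiable proteins.
#' @param n_planted Proteins with a planted effect between `group_a` and
#'   `group_b`.
#' @param effect_log2 Planted log2 effect (default 1).
#' @param sd_log2 Per-channel Gaussian sd on log2 intensities (default
#'   0.2).
#' @param channel_conditions Named channel -> condition map; default the
#'   six-plex layout 126/127 = M0, 128/129 = M1, 130/131 = M2.
#' @param group_a,group_b Conditions the planted effect separates
#'   (`group_b` is up).
#' @param max_psms Maximum PSMs per protein (uniform 1..max).
#' @param frac_high_pep Fraction of extra PSMs with failing PEP.
#' @param n_shared_only Extra proteins carrying only non-unique peptides.
#' @return List: `psms` (TSV dialect), `channel_conditions`, `truth`
#'   (per protein: planted flag, effect, true log2 channel values).
#' @export
simulate_tmt <- function(seed = 1L, n_proteins = 1000, n_planted = 50,
                         effect_log2 = 1.0, sd_log2 = 0.2,
                         channel_conditions = NULL,
                         group_a = "M1", group_b = "M2",
                         max_psms = 4, frac_high_pep = 0.05,
                         n_shared_only = 20) {
  .sim_seed(seed)
  if (is.null(channel_conditions)) {
    channel_conditions <- read_channel_design(NULL)
  }
  channels <- names(channel_conditions)
  planted <- rep(FALSE, n_proteins)
  if (n_planted > 0) {
    planted[sample.int(n_proteins, min(n_planted, n_proteins))] <- TRUE
  }
  sign_up <- ifelse(stats::runif(n_proteins) < 0.5, 1, -1)
  base <- stats::rnorm(n_proteins, 20, 1.5)
  truth_val <- matrix(base, n_proteins, length(channels))
  colnames(truth_val) <- channels
  for (j in seq_along(channels)) {
    cond <- channel_conditions[[j]]
    delta <- ifelse(planted & cond == group_b, sign_up * effect_log2 / 2,
                    ifelse(planted & cond == group_a,
                           -sign_up * effect_log2 / 2, 0))
    truth_val[, j] <- truth_val[, j] + delta
  }
  rows <- list()
  pepno <- 0
  for (i in seq_len(n_proteins)) {
    n_psm <- sample.int(max_psms, 1)
    w <- stats::rexp(n_psm); w <- w / sum(w)
    vals <- 2^(truth_val[i, ] + stats::rnorm(length(channels), 0, sd_log2))
    rep_mat <- outer(w, vals)
    for (p in seq_len(n_psm)) {
      pepno <- pepno + 1
      rows[[length(rows) + 1]] <- data.frame(
        peptide = sprintf("PEPTIDE%05d", pepno),
        protein_group = sprintf("prot%04d", i),
        unique = p == 1 | stats::runif(1) < 0.7,
        pep = stats::runif(1, 0, 0.049),
        r126 = rep_mat[p, 1], r127 = rep_mat[p, 2], r128 = rep_mat[p, 3],
        r129 = rep_mat[p, 4], r130 = rep_mat[p, 5], r131 = rep_mat[p, 6],
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < frac_high_pep) {
      pepno <- pepno + 1
      junk <- stats::runif(6, 0, 2^22)
      rows[[length(rows) + 1]] <- data.frame(
        peptide = sprintf("PEPTIDE%05d", pepno),
        protein_group = sprintf("prot%04d", i),
        unique = TRUE, pep = stats::runif(1, 0.05, 1),
        r126 = junk[1], r127 = junk[2], r128 = junk[3], r129 = junk[4],
        r130 = junk[5], r131 = junk[6], stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_shared_only)) {
    pepno <- pepno + 1
    v <- stats::runif(6, 0, 2^20)
    rows[[length(rows) + 1]] <- data.frame(
      peptide = sprintf("PEPTIDE%05d", pepno),
      protein_group = sprintf("shared%03d", i),
      unique = FALSE, pep = stats::runif(1, 0, 0.049),
      r126 = v[1], r127 = v[2], r128 = v[3], r129 = v[4], r130 = v[5],
      r131 = v[6], stringsAsFactors = FALSE)
  }
  truth <- data.frame(protein_group = sprintf("prot%04d",
                                              seq_len(n_proteins)),
                      planted = planted,
                      effect_log2 = ifelse(planted, sign_up * effect_log2,
                                           0),
                      stringsAsFactors = FALSE)
  list(psms = .df_clean(do.call(rbind, rows)),
       channel_conditions = channel_conditions, truth = truth,
       truth_log2 = truth_val)
}
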