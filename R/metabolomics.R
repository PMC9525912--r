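# Metabolite identification and internal-standard quantification.
#
# Observed LC-MS features are matched against a compound library expanded
# over derivatization states (dansyl on primary amines, O-BHA on
# carboxyls/carbonyls) at a ppm tolerance; intensities are converted to
# concentrations against spiked isotope-labeled internal standards with
# the retention-time-zone assignment rules of the dansyl track and the
# labeled-analogue/malate-fallback rule of the O-BHA track.

#' Expand a compound library over derivatization states
#'
#' Each library entry yields one candidate per derivatization count:
#' 1..`amine_sites` dansyl states and 1..`carbonyl_sites` O-BHA states
#' (multi-amine compounds are tried both mono- and fully derivatized).
#'
#' @param library Data frame as returned by [read_compound_library()].
#' @param charge Charge state for the theoretical m/z (default 1; the
#'   small-molecule ions are MH+).
#' @return Data frame with `compound_id`, `scheme`, `n_sites`, `rt_zone`,
#'   `theoretical_mz`.
#' @export
expand_library <- function(library, charge = 1L) {
  rows <- lapply(seq_len(nrow(library)), function(i) {
    ent <- library[i, ]
    out <- list()
    if (ent$amine_sites > 0) {
      out <- c(out, lapply(seq_len(ent$amine_sites), function(n) {
        data.frame(compound_id = ent$compound_id, scheme = "dansyl",
                   n_sites = n, rt_zone = ent$rt_zone,
                   theoretical_mz = derivatized_mz(ent$formula, n, "dansyl",
                                                   charge))
      }))
    }
    if (ent$carbonyl_sites > 0) {
      out <- c(out, lapply(seq_len(ent$carbonyl_sites), function(n) {
        data.frame(compound_id = ent$compound_id, scheme = "obha",
                   n_sites = n, rt_zone = ent$rt_zone,
                   theoretical_mz = derivatized_mz(ent$formula, n, "obha",
                                                   charge))
      }))
    }
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Match LC-MS features to a derivatized compound library
#'
#' Every feature is compared against all library entries expanded over
#' allowed derivatization states at charge 1. The best-|ppm| candidate is
#' retained per feature; it is accepted when |ppm| <= `tol_ppm`
#' (inclusive boundary). Ties are broken by fewer derivatization sites,
#' then lexicographic compound id.
#'
#' @param features Data frame as returned by [read_features()].
#' @param library Data frame as returned by [read_compound_library()].
#' @param tol_ppm Mass tolerance in ppm (default 5.0).
#' @return Data frame: one row per feature with `sample_id`, `mz`, `rt`,
#'   `intensity`, `compound_id`, `scheme`, `n_sites`, `theoretical_mz`,
#'   `ppm`, `accepted`.
#' @export
match_features <- function(features, library, tol_ppm = 5.0) {
  stopifnot(tol_ppm > 0)
  if (nrow(features) == 0L) {
    return(data.frame(sample_id = character(0), mz = numeric(0),
                      rt = numeric(0), intensity = numeric(0),
                      compound_id = character(0), scheme = character(0),
                      n_sites = integer(0), theoretical_mz = numeric(0),
                      ppm = numeric(0), accepted = logical(0)))
  }
  if (is.null(nrow(library)) || nrow(library) == 0L) {
    stop("compound library is empty", call. = FALSE)
  }
  cand <- expand_library(library)
  # deterministic tie-break order: |ppm|, then fewer sites, then compound_id
  cand <- cand[order(cand$n_sites, cand$compound_id), ]
  if (is.null(features$charge)) features$charge <- 1L
  picks <- lapply(seq_len(nrow(features)), function(i) {
    z <- features$charge[i]
    mz_th <- if (z == 1L) cand$theoretical_mz else
      # re-derive candidate m/z at the feature's charge from neutral mass
      (cand$theoretical_mz - proton_mass + z * proton_mass) / z
    ppm <- ppm_error(features$mz[i], mz_th)
    j <- which.min(abs(ppm))  # which.min takes the first minimum: the
                              # candidate order above enforces tie-breaks
    data.frame(sample_id = features$sample_id[i], mz = features$mz[i],
               rt = features$rt[i], intensity = features$intensity[i],
               compound_id = cand$compound_id[j], scheme = cand$scheme[j],
               n_sites = cand$n_sites[j],
               theoretical_mz = mz_th[j], ppm = ppm[j],
               accepted = abs(ppm[j]) <= tol_ppm)
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

#' Assign internal standards to matched compounds
#'
#' Dansyl-track compounds map to the zone-matched standard: the
#' serine-analogue standard in the low retention-time zone and the
#' glycine-analogue standard in the high zone. O-BHA-track compounds map
#' to their exact labeled analogue when the manifest designates one
#' (`target_compound_id`), otherwise to the malate fallback standard.
#'
#' @param compound_id,scheme,rt_zone Vectors (recycled to common length)
#'   describing the matched compounds.
#' @param standards Data frame as returned by [read_standards()].
#' @param fallback_is is_id of the O-BHA fallback standard; by default the
#'   obha standard whose id contains "malate".
#' @return Character vector of is_id assignments.
#' @export
assign_internal_standard <- function(compound_id, scheme, rt_zone,
                                     standards, fallback_is = NULL) {
  n <- max(length(compound_id), length(scheme), length(rt_zone))
  compound_id <- rep_len(compound_id, n)
  scheme <- rep_len(scheme, n)
  rt_zone <- rep_len(rt_zone, n)
  if (is.null(fallback_is)) {
    hit <- which(standards$scheme == "obha" &
                   grepl("malate", standards$is_id, ignore.case = TRUE))
    fallback_is <- if (length(hit)) standards$is_id[hit[1]] else NA_character_
  }
  vapply(seq_len(n), function(i) {
    if (scheme[i] == "dansyl") {
      j <- which(standards$scheme == "dansyl" &
                   standards$rt_zone == rt_zone[i])
      if (!length(j)) {
        stop("no dansyl internal standard configured for retention-time ",
             "zone '", rt_zone[i], "'", call. = FALSE)
      }
      standards$is_id[j[1]]
    } else {
      j <- which(standards$scheme == "obha" &
                   !is.na(standards$target_compound_id) &
                   standards$target_compound_id == compound_id[i])
      if (length(j)) return(standards$is_id[j[1]])
      if (is.na(fallback_is)) {
        stop("no labeled analogue and no fallback (malate) standard for ",
             "compound '", compound_id[i], "'", call. = FALSE)
      }
      fallback_is
    }
  }, character(1))
}

#' Concentration from internal-standard normalization
#'
#' `(analyte_intensity / is_intensity) * is_amount_nmol / protein_mg`,
#' i.e. the signal normalized to a standard of known spiked amount,
#' expressed per mg protein. Vectorized.
#'
#' @param analyte_intensity,is_intensity Peak areas (>= 0).
#' @param is_amount_nmol Spiked standard amount in nmol (> 0).
#' @param protein_mg Protein mass of the sample in mg (> 0; default 1 for
#'   relative concentrations).
#' @return Concentration in nmol/mg protein; `NA` where the standard
#'   intensity is zero or missing (flagged, not an error).
#' @export
quantify_concentration <- function(analyte_intensity, is_intensity,
                                   is_amount_nmol, protein_mg = 1.0) {
  if (any(analyte_intensity < 0, na.rm = TRUE)) {
    stop("analyte intensities must be >= 0", call. = FALSE)
  }
  if (any(is_intensity < 0, na.rm = TRUE)) {
    stop("internal-standard intensities must be >= 0", call. = FALSE)
  }
  if (any(is_amount_nmol <= 0) || any(protein_mg <= 0)) {
    stop("is_amount_nmol and protein_mg must be positive", call. = FALSE)
  }
  out <- (analyte_intensity / is_intensity) * is_amount_nmol / protein_mg
  out[!is.finite(out)] <- NA_real_
  out
}

#' Locate internal-standard features
#'
#' Matches observed features against the standards' own derivatized
#' theoretical m/z (labeled formulas, so the heavy mass) and returns the
#' standard's intensity per sample (the best-|ppm| in-tolerance feature).
#'
#' @param features Feature data frame.
#' @param standards Standards manifest.
#' @param tol_ppm Tolerance in ppm.
#' @return Data frame `sample_id`, `is_id`, `intensity` (`NA` when the
#'   standard was not observed in a sample).
#' @export
match_standards <- function(features, standards, tol_ppm = 5.0) {
  samples <- unique(features$sample_id)
  grid <- expand.grid(sample_id = samples, is_id = standards$is_id,
                      stringsAsFactors = FALSE)
  grid$intensity <- NA_real_
  for (k in seq_len(nrow(standards))) {
    mz_th <- derivatized_mz(standards$formula[k], standards$sites[k],
                            standards$scheme[k])
    for (s in samples) {
      f <- features[features$sample_id == s, ]
      ppm <- ppm_error(f$mz, mz_th)
      ok <- which(abs(ppm) <= tol_ppm)
      if (length(ok)) {
        j <- ok[which.min(abs(ppm[ok]))]
        row <- grid$sample_id == s & grid$is_id == standards$is_id[k]
        grid$intensity[row] <- f$intensity[j]
      }
    }
  }
  grid
}

#' Quantify matched features against internal standards
#'
#' Full quantification step: accepted matches are aggregated (summed) per
#' compound and sample, assigned an internal standard by the zone/analogue
#' rules, and converted to nmol per mg protein.
#'
#' @param matches Output of [match_features()].
#' @param library Compound library (for rt zones).
#' @param is_intensities Output of [match_standards()].
#' @param standards Standards manifest.
#' @param design Sample design (for `protein_mg`).
#' @return Data frame `compound_id`, `sample_id`, `is_id`,
#'   `concentration` (nmol/mg protein; `NA` where the standard intensity
#'   is missing).
#' @export
quantify_concentrations <- function(matches, library, is_intensities,
                                    standards, design) {
  acc <- matches[matches$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) {
    return(data.frame(compound_id = character(0), sample_id = character(0),
                      is_id = character(0), concentration = numeric(0)))
  }
  agg <- stats::aggregate(intensity ~ compound_id + sample_id + scheme,
                          data = acc, FUN = sum)
  agg$rt_zone <- library$rt_zone[match(agg$compound_id, library$compound_id)]
  agg$is_id <- assign_internal_standard(agg$compound_id, agg$scheme,
                                        agg$rt_zone, standards)
  key_is <- paste(agg$sample_id, agg$is_id)
  is_key <- paste(is_intensities$sample_id, is_intensities$is_id)
  is_int <- is_intensities$intensity[match(key_is, is_key)]
  amount <- standards$amount_nmol[match(agg$is_id, standards$is_id)]
  pmg <- design$protein_mg[match(agg$sample_id, design$sample_id)]
  if (any(is.na(pmg))) {
    warning("samples missing from design; assuming 1.0 mg protein",
            call. = FALSE)
    pmg[is.na(pmg)] <- 1.0
  }
  conc <- rep(NA_real_, nrow(agg))
  ok <- !is.na(is_int) & is_int > 0
  conc[ok] <- quantify_concentration(agg$intensity[ok], is_int[ok],
                                     amount[ok], pmg[ok])
  data.frame(compound_id = agg$compound_id, sample_id = agg$sample_id,
             is_id = agg$is_id, concentration = conc,
             stringsAsFactors = FALSE)
}

# Vectorized two-sample t-test over matrix rows. Pooled-variance (Student)
# by default, Welch optional. Returns NA statistics for rows with < 2
# finite values in either group or zero pooled variance.
.row_t_test <- function(X, ia, ib, var_equal = TRUE) {
  A <- X[, ia, drop = FALSE]; B <- X[, ib, drop = FALSE]
  na <- rowSums(is.finite(A)); nb <- rowSums(is.finite(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  va <- apply(A, 1, stats::var, na.rm = TRUE)
  vb <- apply(B, 1, stats::var, na.rm = TRUE)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mb - ma) / se
  p <- 2 * stats::pt(-abs(t), df)
  bad <- na < 2 | nb < 2
  zerovar <- !bad & is.finite(se) & se == 0
  t[bad | zerovar] <- NA_real_
  p[bad | zerovar] <- NA_real_
  list(mean_a = ma, mean_b = mb, n_a = na, n_b = nb, t = t, df = df, p = p,
       flag = ifelse(bad, "insufficient_n",
                     ifelse(zerovar, "zero_variance", "")))
}

# Long concentration records -> compound x sample matrix.
.conc_matrix <- function(concentrations) {
  if (is.matrix(concentrations)) return(concentrations)
  stopifnot(all(c("compound_id", "sample_id", "concentration") %in%
                  names(concentrations)))
  tab <- tapply(concentrations$concentration,
                list(concentrations$compound_id, concentrations$sample_id),
                mean)
  m <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  m
}

#' Volcano-plot differential statistics for metabolite concentrations
#'
#' Per compound: log2 fold change of group means (`group_b` over
#' `group_a`) and a two-sided two-sample t-test p-value (pooled-variance
#' Student by default, matching t-testing across consecutive injections;
#' Welch via `var_equal = FALSE`). Raw p-values by default;
#' Benjamini-Hochberg adjustment via `bh = TRUE`.
#'
#' @param concentrations Long data frame (`compound_id`, `sample_id`,
#'   `concentration`) or a compound x sample matrix.
#' @param design Design data frame (`sample_id`, `group`).
#' @param group_a,group_b Group labels to compare.
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @param bh Add BH-adjusted p-values if `TRUE`.
#' @return Data frame with `compound_id`, group means, `log2fc`, `t`,
#'   `p`, `neg_log10_p`, `flag` (zero-variance / insufficient-n /
#'   infinite fold change), and `p_adj` when `bh = TRUE`. Infinite fold
#'   changes (zero denominator mean) are flagged for exclusion from
#'   plots.
#' @export
differential_volcano <- function(concentrations, design, group_a, group_b,
                                 var_equal = TRUE, bh = FALSE) {
  X <- .conc_matrix(concentrations)
  sa <- design$sample_id[design$group == group_a]
  sb <- design$sample_id[design$group == group_b]
  ia <- which(colnames(X) %in% sa); ib <- which(colnames(X) %in% sb)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs >= 2 samples in the concentration table",
         call. = FALSE)
  }
  tt <- .row_t_test(X, ia, ib, var_equal = var_equal)
  log2fc <- log2(tt$mean_b / tt$mean_a)
  flag <- tt$flag
  inf_fc <- !is.finite(log2fc)
  flag[inf_fc & flag == ""] <- "infinite_fold_change"
  out <- data.frame(compound_id = rownames(X), mean_a = tt$mean_a,
                    mean_b = tt$mean_b, n_a = tt$n_a, n_b = tt$n_b,
                    log2fc = log2fc, t = tt$t, p = tt$p,
                    neg_log10_p = -log10(tt$p), flag = flag,
                    stringsAsFactors = FALSE)
  if (bh) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
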