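# Stable-isotope tracing arithmetic: theoretical natural-abundance
# envelopes, correction of observed isotopologue envelopes for natural
# heavy isotopes, and labeled-fraction / labeled-over-unlabeled-ratio
# enrichment estimates (e.g. 13C3-pyruvate and 13C2-succinate from
# 13C6-glucose, 13C2-acetyl on histone peptides via acetyl-CoA).

# Natural isotope abundance by nominal mass shift (index 1 = +0).
# Bracketed labeled atoms are fixed heavy and contribute no spread.
.iso_abundance <- list(
  H  = c(0.999885, 0.000115),
  C  = c(0.9893, 0.0107),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# Truncated polynomial product: convolve distribution p (by mass shift)
# n times into acc, keeping offsets 0..K.
.convolve_power <- function(acc, p, n, K) {
  for (i in seq_len(n)) {
    out <- numeric(K + 1)
    for (s in seq_along(p)) {
      if (p[s] == 0 || s - 1 > K) next
      lo <- s  # shift s-1
      out[lo:(K + 1)] <- out[lo:(K + 1)] + p[s] * acc[1:(K + 2 - s)]
    }
    acc <- out
  }
  acc
}

#' Theoretical natural-abundance isotopologue envelope
#'
#' Probabilities of the M+0..M+K isotopologues of a formula from
#' per-element natural isotope abundances, by polynomial (convolution)
#' expansion. Carbon-only mode (the dominant term, 13C at 1.07%) is the
#' default; `elements = "CHNOS"` includes H, N, O and S. Probabilities
#' are truncated at K and not renormalized, so they sum to <= 1.
#' Bracketed isotope-labeled atoms are fixed heavy and add no spread.
#'
#' @param formula Formula of the measured ion.
#' @param K Largest mass offset returned (>= 0).
#' @param elements `"C"` (default) or `"CHNOS"`.
#' @return Numeric vector of length K+1, names `M+0`..`M+K`.
#' @examples
#' natural_envelope("C6H12O6", 6)  # binomial(6, 0.0107) in carbon-only mode
#' @export
natural_envelope <- function(formula, K, elements = c("C", "CHNOS")) {
  elements <- match.arg(elements)
  stopifnot(K >= 0)
  f <- parse_formula(formula)
  active <- if (elements == "C") "C" else names(.iso_abundance)
  acc <- c(1, numeric(K))
  for (el in intersect(names(f), active)) {
    acc <- .convolve_power(acc, .iso_abundance[[el]], f[[el]], K)
  }
  names(acc) <- paste0("M+", 0:K)
  acc
}

# Correction design matrix: column j is the natural envelope of the
# species carrying j tracer labels (j carbons fixed 13C, rest natural),
# shifted down by j rows.
.correction_matrix <- function(formula, K, J, elements = "C") {
  f <- parse_formula(formula)
  A <- matrix(0, nrow = K + 1, ncol = J + 1)
  for (j in 0:J) {
    fj <- f
    fj["C"] <- fj["C"] - j
    env <- natural_envelope(fj[fj != 0], K - j, elements)
    A[(j + 1):(K + 1), j + 1] <- env
  }
  A
}

#' Correct an isotopologue envelope for natural abundance
#'
#' Solves `A x = observed`, where column j of `A` is the theoretical
#' natural envelope of the species carrying j tracer labels (labeled
#' positions fixed heavy, remaining atoms natural). The solution is
#' constrained non-negative (NNLS) by default; a plain least-squares
#' solve is available for diagnostics. Fractions are returned normalized
#' to sum 1.
#'
#' @param intensities Observed `M+0..M+K` intensities (length K+1).
#' @param formula Formula of the measured ion.
#' @param label_shift Mass offset of the fully labeled species of
#'   interest; used only to check that K is large enough.
#' @param elements Passed to [natural_envelope()].
#' @param method `"nnls"` (default) or `"solve"`.
#' @return Numeric vector of corrected label-count fractions
#'   (`x0`..`xJ`, summing to 1), J = min(K, number of carbons).
#' @export
correct_natural_abundance <- function(intensities, formula,
                                      label_shift = NULL,
                                      elements = c("C", "CHNOS"),
                                      method = c("nnls", "solve")) {
  elements <- match.arg(elements)
  method <- match.arg(method)
  if (any(intensities < 0) || sum(intensities) <= 0) {
    stop("envelope intensities must be >= 0 with positive sum",
         call. = FALSE)
  }
  K <- length(intensities) - 1L
  if (!is.null(label_shift) && K < label_shift) {
    stop("envelope too short (K = ", K, " < label_shift = ", label_shift,
         "); measure more isotopologues", call. = FALSE)
  }
  f <- parse_formula(formula)
  nC <- if ("C" %in% names(f)) f[["C"]] else 0
  if (nC == 0) {
    # nothing correctable: identity
    x <- intensities / sum(intensities)
    names(x) <- paste0("x", 0:K)
    return(x)
  }
  J <- min(K, nC)
  A <- .correction_matrix(formula, K, J, elements)
  y <- intensities / sum(intensities)
  if (method == "nnls") {
    x <- pracma::lsqnonneg(A, y)$x
  } else {
    x <- qr.solve(A, y)
  }
  if (sum(x) <= 0) {
    stop("natural-abundance correction degenerate (all-zero solution); ",
         "K may be too small for this formula", call. = FALSE)
  }
  x <- x / sum(x)
  names(x) <- paste0("x", 0:J)
  x
}

#' Isotope enrichment of one envelope
#'
#' Two estimators are returned for the species of interest at mass
#' offset `label_shift` = n. The labeled-over-unlabeled ratio
#' `I(M+n)/I(M+0)` is the literal incorporation-rate estimator computed
#' on raw intensities. The labeled fraction is `x(M+n)/sum(x)` after
#' natural-abundance correction (default), or the raw intensity fraction
#' when `correct = FALSE`. When only M+0 and M+n are populated and
#' correction is off, `fraction = ratio / (1 + ratio)`.
#'
#' @param intensities Observed `M+0..M+K` intensities.
#' @param formula Formula of the measured ion.
#' @param label_shift Tracer mass offset n (e.g. 2 for 13C2-acetyl, 3 for
#'   13C3-pyruvate).
#' @param correct Apply natural-abundance correction to the fraction
#'   (default `TRUE`).
#' @param elements Passed to [natural_envelope()].
#' @return List with `labeled_fraction`, `labeled_over_unlabeled_ratio`
#'   (`NA` when M+0 is zero), and `corrected`.
#' @export
enrichment <- function(intensities, formula, label_shift, correct = TRUE,
                       elements = c("C", "CHNOS")) {
  elements <- match.arg(elements)
  stopifnot(label_shift >= 1, length(intensities) >= label_shift + 1)
  ratio <- if (intensities[1] > 0) {
    intensities[label_shift + 1] / intensities[1]
  } else NA_real_
  if (correct) {
    x <- correct_natural_abundance(intensities, formula, label_shift,
                                   elements)
    fraction <- unname(x[label_shift + 1] / sum(x))
  } else {
    fraction <- intensities[label_shift + 1] / sum(intensities)
  }
  list(labeled_fraction = fraction,
       labeled_over_unlabeled_ratio = unname(ratio),
       corrected = correct)
}

#' Group-level enrichment summary with comparisons
#'
#' Computes per-sample enrichment for every (species, sample) envelope in
#' a long envelope table, then summarizes per species and group (mean,
#' sd, n) and, when two group labels are given, compares them with a
#' two-sided pooled-variance t-test. A species present in only one group
#' is reported without a comparison (NA statistics).
#'
#' @param envelopes Long data frame as returned by [read_envelopes()].
#' @param design Design data frame (`sample_id`, `group`).
#' @param group_a,group_b Optional group labels to compare.
#' @param correct,mode Estimator choice: natural-abundance-corrected
#'   labeled fraction (default) or the literal `"ratio"` estimator.
#' @param elements Passed to [natural_envelope()].
#' @return Data frame, one row per (species, group), with `mean`, `sd`,
#'   `n`, and (on each species' rows) `diff`, `t`, `p` for the requested
#'   comparison.
#' @export
trace_summary <- function(envelopes, design, group_a = NULL, group_b = NULL,
                          correct = TRUE, mode = c("fraction", "ratio"),
                          elements = c("C", "CHNOS")) {
  mode <- match.arg(mode)
  elements <- match.arg(elements)
  key <- unique(envelopes[, c("sample_id", "species_id")])
  key$value <- vapply(seq_len(nrow(key)), function(i) {
    e <- envelopes[envelopes$sample_id == key$sample_id[i] &
                     envelopes$species_id == key$species_id[i], ]
    e <- e[order(e$m_offset), ]
    res <- enrichment(e$intensity, e$formula[1], e$label_shift[1],
                      correct = correct, elements = elements)
    if (mode == "fraction") res$labeled_fraction else
      res$labeled_over_unlabeled_ratio
  }, numeric(1))
  key$group <- design$group[match(key$sample_id, design$sample_id)]
  agg <- stats::aggregate(value ~ species_id + group, data = key,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(species_id = agg$species_id, group = agg$group,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = agg$value[, "n"], stringsAsFactors = FALSE)
  out$diff <- NA_real_; out$t <- NA_real_; out$p <- NA_real_
  if (!is.null(group_a) && !is.null(group_b)) {
    for (sp in unique(out$species_id)) {
      va <- key$value[key$species_id == sp & key$group == group_a]
      vb <- key$value[key$species_id == sp & key$group == group_b]
      rows <- out$species_id == sp
      if (length(va) >= 2 && length(vb) >= 2) {
        out$diff[rows] <- mean(vb) - mean(va)
        tt <- tryCatch(stats::t.test(vb, va, var.equal = TRUE),
                       error = function(e) NULL)  # zero-variance groups
        if (!is.null(tt)) {
          out$t[rows] <- unname(tt$statistic)
          out$p[rows] <- tt$p.value
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}
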