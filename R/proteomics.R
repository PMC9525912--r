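# TMT six-plex protein quantification and SAM-style differential
# analysis.
#
# PSM-level reporter tables are filtered (posterior error probability
# strictly below 0.05; proteins keep >= 1 accepted unique peptide),
# aggregated to a protein x channel matrix by summed reporter intensity,
# channel-normalized, log2-transformed, and tested with the moderated
# statistic d = (mean_b - mean_a) / (SE + s0). Significance cutoffs come
# from a permutation-estimated false discovery rate.

#' Filter PSMs by posterior error probability and peptide uniqueness
#'
#' Keeps PSMs with `pep < pep_max` (strict inequality) and retains only
#' proteins with at least one accepted unique peptide.
#'
#' @param psms Data frame as returned by [read_psms()].
#' @param pep_max PEP acceptance bound (default 0.05, exclusive).
#' @return Filtered PSM data frame (possibly empty).
#' @export
filter_psms <- function(psms, pep_max = 0.05) {
  keep <- psms[psms$pep < pep_max, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  has_unique <- tapply(keep$unique, keep$protein_group, any)
  ok_prot <- names(has_unique)[has_unique]
  out <- keep[keep$protein_group %in% ok_prot, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate filtered PSMs into a protein x channel matrix
#'
#' Channel-wise sum of reporter intensities per protein group (the
#' default, additive aggregation), or the median of PSM-level log2
#' intensities via `method = "median_log"`. All-zero rows are flagged
#' non-quantifiable in the `quantifiable` attribute.
#'
#' @param psms Filtered PSM data frame ([filter_psms()]).
#' @param method `"sum"` (default) or `"median_log"` (2^median of PSM
#'   log2 reporters).
#' @return Numeric matrix (proteins x 6 channels, columns
#'   `"126"`..`"131"`) with attributes `n_psms`, `n_unique_peptides`,
#'   `quantifiable`.
#' @export
aggregate_protein_matrix <- function(psms, method = c("sum", "median_log")) {
  method <- match.arg(method)
  rcols <- paste0("r", 126:131)
  prot <- sort(unique(psms$protein_group))
  M <- matrix(0, nrow = length(prot), ncol = 6,
              dimnames = list(prot, as.character(126:131)))
  for (k in seq_along(rcols)) {
    v <- psms[[rcols[k]]]
    if (method == "sum") {
      M[, k] <- tapply(v, factor(psms$protein_group, levels = prot), sum)
    } else {
      M[, k] <- 2^tapply(log2(pmax(v, .Machine$double.xmin)),
                         factor(psms$protein_group, levels = prot),
                         stats::median)
    }
  }
  attr(M, "n_psms") <- as.integer(table(factor(psms$protein_group,
                                               levels = prot)))
  attr(M, "n_unique_peptides") <- as.integer(tapply(
    psms$peptide[psms$unique],
    factor(psms$protein_group[psms$unique], levels = prot),
    function(x) length(unique(x))))
  attr(M, "quantifiable") <- rowSums(M) > 0
  M
}

#' Equalize channel totals
#'
#' Scales every channel so all channel sums equal the mean channel total,
#' removing loading differences between TMT channels.
#'
#' @param matrix Protein x channel intensity matrix.
#' @return Normalized matrix.
#' @export
normalize_channels <- function(matrix) {
  totals <- colSums(matrix)
  if (any(totals <= 0)) {
    stop("channel with non-positive total intensity", call. = FALSE)
  }
  sweep(matrix, 2, mean(totals) / totals, `*`)
}

# All distinct assignments of the pooled channels to group A (as column
# index subsets); sampled without replacement when more than n_perm
# exist.
.perm_assignments <- function(cols_a, cols_b, n_perm) {
  pool <- c(cols_a, cols_b)
  na <- length(cols_a)
  all_a <- utils::combn(pool, na, simplify = FALSE)
  if (length(all_a) > n_perm) {
    all_a <- all_a[sample.int(length(all_a), n_perm)]
  }
  all_a
}

# d statistic on a log2 matrix for one label assignment.
.sam_d <- function(X, ia, ib, s0) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(X[, ia, drop = FALSE])
  mb <- rowMeans(X[, ib, drop = FALSE])
  va <- apply(X[, ia, drop = FALSE], 1, stats::var)
  vb <- apply(X[, ib, drop = FALSE], 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  (mb - ma) / (se + s0)
}

#' SAM-style permutation test with the s0 exchangeability constant
#'
#' For each protein, `d = (mean_b - mean_a) / (s + s0)` on log2 data,
#' with `s` the pooled two-sample standard error; `s0` (in log2-intensity
#' units) damps small-variance artifacts and makes zero within-group
#' variance harmless. The null distribution of d comes from group-label
#' permutations (all distinct assignments when fewer than `n_perm`
#' exist). For a symmetric cutoff c, the estimated FDR is the median
#' across permutations of the number of null |d*| >= c, divided by the
#' observed number of |d| >= c; proteins are called significant at the
#' smallest cutoff whose estimated FDR is <= `fdr`.
#'
#' @param matrix Protein x channel matrix of log2 intensities.
#' @param design Named character vector channel -> condition
#'   ([read_channel_design()]).
#' @param group_a,group_b Condition labels to compare (each needs >= 2
#'   channels).
#' @param s0 Exchangeability constant in log2 units (default 0.32, i.e. a
#'   ~1.25-fold change cutoff: log2(1.25) = 0.32).
#' @param fdr Permutation FDR level (default 0.01).
#' @param n_perm Maximum number of permutations (default 250).
#' @param seed Integer seed for permutation sampling (required for
#'   reproducibility).
#' @return Data frame `protein_group`, `d`, `log2fc`, `significant`,
#'   `s0`, with attributes `cutoff` and `fdr_table` (cutoff vs estimated
#'   FDR).
#' @export
sam_test <- function(matrix, design, group_a, group_b, s0 = 0.32,
                     fdr = 0.01, n_perm = 250, seed = 1L) {
  ia <- which(colnames(matrix) %in% names(design)[design == group_a])
  ib <- which(colnames(matrix) %in% names(design)[design == group_b])
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each condition needs >= 2 channels", call. = FALSE)
  }
  set.seed(seed)
  d_obs <- .sam_d(matrix, ia, ib, s0)
  log2fc <- rowMeans(matrix[, ib, drop = FALSE]) -
    rowMeans(matrix[, ia, drop = FALSE])
  perms <- .perm_assignments(ia, ib, n_perm)
  pool <- c(ia, ib)
  null_abs <- vapply(perms, function(pa) {
    abs(.sam_d(matrix, pa, setdiff(pool, pa), s0))
  }, numeric(nrow(matrix)))
  if (is.null(dim(null_abs))) null_abs <- matrix(null_abs, nrow = 1)
  cutoffs <- sort(unique(abs(d_obs)), decreasing = TRUE)
  n_obs <- vapply(cutoffs, function(c) sum(abs(d_obs) >= c), numeric(1))
  med_null <- vapply(cutoffs, function(c) {
    stats::median(colSums(null_abs >= c))
  }, numeric(1))
  fdr_est <- med_null / n_obs
  ok <- which(fdr_est <= fdr)
  cutoff <- if (length(ok)) cutoffs[max(ok)] else Inf
  out <- data.frame(protein_group = rownames(matrix), d = d_obs,
                    log2fc = log2fc, significant = abs(d_obs) >= cutoff,
                    s0 = s0, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "fdr_table") <- data.frame(cutoff = cutoffs, n_called = n_obs,
                                       median_null = med_null,
                                       fdr_est = fdr_est)
  attr(out, "n_perm_used") <- length(perms)
  out
}

#' Row-standardize a protein matrix for heat-map display
#'
#' Per-protein z-scores across channels (mean 0, sd 1). Constant rows
#' become all zeros and are flagged in the `constant` attribute.
#'
#' @param matrix Protein x channel matrix.
#' @return Matrix of the same shape; attribute `constant` marks rows with
#'   zero variance.
#' @export
zscore_matrix <- function(matrix) {
  if (ncol(matrix) < 2) stop("need >= 2 channels", call. = FALSE)
  mu <- rowMeans(matrix)
  sd <- apply(matrix, 1, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  Z <- (matrix - mu) / ifelse(const, 1, sd)
  Z[const, ] <- 0
  attr(Z, "constant") <- const
  Z
}
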