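# Histone-PTM quantification from PRM peak areas.
#
# The modification level of a peptide is the ratio of the modified
# peptide's peak area over the modification-free peptide's area
# ("modification percentage"; it may exceed 1). With a SILAC
# heavy-arginine histone standard spiked into every sample, the light
# ratio is divided by the heavy ratio (ratio of ratios): any
# peptide-specific response factor shared by the light and heavy channels
# cancels exactly, so cross-sample fold changes of normalized ratios
# equal fold changes of true modification levels.

#' Raw modification level (modified / unmodified peak-area ratio)
#'
#' @param area_mod,area_unmod Peak areas (>= 0). Vectorized.
#' @return `area_mod / area_unmod`; `NA` (flagged missing) where
#'   `area_unmod` is zero.
#' @export
modification_level <- function(area_mod, area_unmod) {
  if (any(area_mod < 0, na.rm = TRUE) || any(area_unmod < 0, na.rm = TRUE)) {
    stop("peak areas must be >= 0", call. = FALSE)
  }
  out <- area_mod / area_unmod
  out[!is.finite(out)] <- NA_real_
  out
}

#' SILAC (ratio-of-ratios) normalization
#'
#' Divides the light-channel modification ratio by the heavy-standard
#' ratio of the same peptide pair. Because the heavy standard is the same
#' histone preparation in every sample, peptide-specific ionization or
#' digestion biases shared across channels cancel exactly.
#'
#' @param light_ratio,heavy_ratio Modification ratios. Vectorized.
#' @return `light_ratio / heavy_ratio`; where the heavy ratio is zero or
#'   missing the raw light ratio is carried forward with a warning (the
#'   `normalized` flag in [ptm_levels()] records this).
#' @export
silac_normalize <- function(light_ratio, heavy_ratio) {
  out <- light_ratio / heavy_ratio
  bad <- !is.finite(out) & is.finite(light_ratio)
  if (any(bad, na.rm = TRUE)) {
    warning("heavy ratio zero/missing for ", sum(bad, na.rm = TRUE),
            " record(s); raw light ratio carried forward", call. = FALSE)
    out[bad] <- light_ratio[bad]
  }
  out
}

#' Modification levels from a PRM peak-area table
#'
#' Computes per (sample, peptide, modification) the raw light-channel
#' ratio and, when a heavy channel is present, the SILAC-normalized
#' ratio. The reference is the `"unmodified"` record of the same peptide
#' and channel.
#'
#' @param areas Data frame as returned by [read_prm_areas()].
#' @param mode `"ratio"` (default; modified / unmodified, may exceed 1,
#'   as the modification percentage is defined) or `"fraction"`
#'   (modified / (modified + unmodified), bounded in `[0, 1]`).
#' @return Data frame `sample_id`, `peptide`, `modification`,
#'   `raw_ratio`, `normalized_ratio`, `normalized` (logical: heavy
#'   channel present and nonzero).
#' @export
ptm_levels <- function(areas, mode = c("ratio", "fraction")) {
  mode <- match.arg(mode)
  mods <- areas[areas$modification != "unmodified", , drop = FALSE]
  if (nrow(mods) == 0L) {
    return(data.frame(sample_id = character(0), peptide = character(0),
                      modification = character(0), raw_ratio = numeric(0),
                      normalized_ratio = numeric(0), normalized = logical(0)))
  }
  key <- function(sample, peptide, modification, channel) {
    paste(sample, peptide, modification, channel, sep = "\r")
  }
  akey <- key(areas$sample_id, areas$peptide, areas$modification,
              areas$channel)
  lookup <- function(sample, peptide, modification, channel) {
    areas$area[match(key(sample, peptide, modification, channel), akey)]
  }
  u <- unique(mods[, c("sample_id", "peptide", "modification")])
  a_ml <- lookup(u$sample_id, u$peptide, u$modification, "light")
  a_ul <- lookup(u$sample_id, u$peptide, "unmodified", "light")
  a_mh <- lookup(u$sample_id, u$peptide, u$modification, "heavy")
  a_uh <- lookup(u$sample_id, u$peptide, "unmodified", "heavy")
  if (any(is.na(a_ul))) {
    stop("unmodified-light reference missing for some (sample, peptide)",
         call. = FALSE)
  }
  ratio_fun <- if (mode == "ratio") modification_level else
    function(m, u) modification_level(m, m + u)
  raw <- ratio_fun(a_ml, a_ul)
  heavy <- ratio_fun(a_mh, a_uh)
  has_heavy <- is.finite(heavy) & heavy > 0
  norm <- raw
  norm[has_heavy] <- raw[has_heavy] / heavy[has_heavy]
  data.frame(sample_id = u$sample_id, peptide = u$peptide,
             modification = u$modification, raw_ratio = raw,
             normalized_ratio = norm, normalized = has_heavy,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential comparison of histone modification levels
#'
#' Per (peptide, modification): fold change of mean normalized ratios
#' between two groups and a two-sided pooled-variance t-test p-value
#' (replicate unit is the injection). Modifications with missing
#' normalized values report the replicate number actually used.
#'
#' @param levels Output of [ptm_levels()].
#' @param design Design data frame (`sample_id`, `group`).
#' @param group_a,group_b Group labels to compare.
#' @param use Which level enters the test: `"normalized"` (default) or
#'   `"raw"`.
#' @return Data frame `peptide`, `modification`, group means, `n_a`,
#'   `n_b`, `log2fc`, `t`, `p`, `flag`.
#' @export
histone_differential <- function(levels, design, group_a, group_b,
                                 use = c("normalized", "raw")) {
  use <- match.arg(use)
  val <- if (use == "normalized") levels$normalized_ratio else
    levels$raw_ratio
  levels$value <- val
  levels$group <- design$group[match(levels$sample_id, design$sample_id)]
  levels$id <- paste(levels$peptide, levels$modification, sep = "\r")
  X <- tapply(levels$value, list(levels$id, levels$sample_id), mean)
  X <- matrix(X, nrow = nrow(X), dimnames = dimnames(X))
  sa <- design$sample_id[design$group == group_a]
  sb <- design$sample_id[design$group == group_b]
  ia <- which(colnames(X) %in% sa); ib <- which(colnames(X) %in% sb)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs >= 2 replicate measurements", call. = FALSE)
  }
  tt <- .row_t_test(X, ia, ib, var_equal = TRUE)
  ids <- do.call(rbind, strsplit(rownames(X), "\r", fixed = TRUE))
  out <- data.frame(peptide = ids[, 1], modification = ids[, 2],
                    mean_a = tt$mean_a, mean_b = tt$mean_b,
                    n_a = tt$n_a, n_b = tt$n_b,
                    log2fc = log2(tt$mean_b / tt$mean_a),
                    t = tt$t, p = tt$p, flag = tt$flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
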