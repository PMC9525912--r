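# Readers/writers for the tabular input dialects. All tables are plain
# tab-separated text with a header row; the simulators emit the same
# dialects these readers consume.

.read_tsv <- function(path, required, optional = character(0),
                      what = "table") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a table as tab-separated text
#'
#' Deterministic TSV writer (no quoting, no row names) used by the CLI and
#' simulators; byte-identical output for identical input.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a derivatized-compound library
#'
#' Columns: `compound_id`, `name`, `formula` (Hill-like, bracketed isotope
#' labels allowed), `amine_sites`, `carbonyl_sites`, `rt_zone` (one of
#' `low`, `high`, `tca`). Formulas are validated at load; a malformed
#' formula is rejected with its row number.
#'
#' @param path TSV path.
#' @return Data frame with the columns above.
#' @export
read_compound_library <- function(path) {
  lib <- .read_tsv(path, c("compound_id", "name", "formula", "amine_sites",
                           "carbonyl_sites", "rt_zone"), what = "library")
  for (i in seq_len(nrow(lib))) {
    ok <- tryCatch({ parse_formula(lib$formula[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      stop("library '", path, "', row ", i, ": malformed formula '",
           lib$formula[i], "'", call. = FALSE)
    }
  }
  bad <- !lib$rt_zone %in% c("low", "high", "tca")
  if (any(bad)) {
    stop("library '", path, "', row ", which(bad)[1],
         ": rt_zone must be low/high/tca", call. = FALSE)
  }
  lib
}

#' Read an internal-standard manifest
#'
#' Columns: `is_id`, `formula` (isotope-labeled), `amount_nmol` (spiked
#' per sample), `rt_zone` (`low`/`high`/`tca`), `scheme`
#' (`dansyl`/`obha`). Optional: `sites` (derivatizable sites on the
#' standard itself, default 1) and `target_compound_id` (the unlabeled
#' analyte this standard is the exact labeled analogue of, used for the
#' O-BHA track).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_standards <- function(path) {
  st <- .read_tsv(path, c("is_id", "formula", "amount_nmol", "rt_zone",
                          "scheme"), what = "standards manifest")
  if (is.null(st$sites)) st$sites <- 1L
  if (is.null(st$target_compound_id)) st$target_compound_id <- NA_character_
  if (any(st$amount_nmol <= 0)) {
    stop("internal-standard amounts must be positive", call. = FALSE)
  }
  for (i in seq_len(nrow(st))) parse_formula(st$formula[i])
  st
}

#' Read an LC-MS feature table
#'
#' Columns: `sample_id`, `mz`, `rt`, `intensity`; optional `charge`
#' (default 1) and `validated` (MS2 validation is an input annotation,
#' never computed here).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_features <- function(path) {
  ft <- .read_tsv(path, c("sample_id", "mz", "rt", "intensity"),
                  what = "feature table")
  if (is.null(ft$charge)) ft$charge <- 1L
  if (any(ft$intensity < 0) || any(ft$mz <= 0)) {
    stop("features require intensity >= 0 and mz > 0", call. = FALSE)
  }
  ft
}

#' Read a sample design table
#'
#' Columns: `sample_id`, `group`; optional `protein_mg` (bicinchoninic
#' assay protein mass per sample; defaults to 1.0 with a warning so
#' relative comparisons remain valid) and `injection`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_design <- function(path) {
  d <- .read_tsv(path, c("sample_id", "group"), what = "design")
  if (anyDuplicated(d$sample_id)) {
    stop("design: duplicated sample_id", call. = FALSE)
  }
  if (is.null(d$protein_mg)) {
    warning("design has no protein_mg column; assuming 1.0 mg per sample ",
            "(concentrations are relative)", call. = FALSE)
    d$protein_mg <- 1.0
  }
  d
}

#' Read a PRM peak-area table
#'
#' Long format, one row per measured transition group:
#' `sample_id`, `peptide`, `modification` (use `"unmodified"` for the
#' modification-free reference peptide), `channel` (`light`/`heavy`),
#' `area`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_prm_areas <- function(path) {
  pa <- .read_tsv(path, c("sample_id", "peptide", "modification", "channel",
                          "area"), what = "PRM areas")
  if (!all(pa$channel %in% c("light", "heavy"))) {
    stop("PRM channel must be 'light' or 'heavy'", call. = FALSE)
  }
  if (any(pa$area < 0)) stop("PRM areas must be >= 0", call. = FALSE)
  pa
}

#' Read or write a histone-modification panel definition
#'
#' Columns: `peptide`, `modification`, `site` (free-text site annotation,
#' e.g. jointly reported positional isomers like "H3K18/23ac"). The panel
#' round-trips identically through read/write.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_panel <- function(path) {
  .read_tsv(path, c("peptide", "modification", "site"), what = "panel")
}

#' Read an isotopologue envelope table
#'
#' Long format: `sample_id`, `species_id`, `formula` (measured ion),
#' `m_offset` (0..K), `intensity`, `label_shift` (mass offset of the fully
#' labeled species of interest, e.g. 2 for 13C2-acetyl, 3 for
#' 13C3-pyruvate).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_envelopes <- function(path) {
  env <- .read_tsv(path, c("sample_id", "species_id", "formula", "m_offset",
                           "intensity", "label_shift"), what = "envelopes")
  if (any(env$intensity < 0)) {
    stop("envelope intensities must be >= 0", call. = FALSE)
  }
  env
}

#' Read a PSM-level TMT reporter table
#'
#' Columns: `peptide`, `protein_group`, `unique` (logical), `pep`
#' (posterior error probability), and reporter intensities
#' `r126`..`r131`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_psms <- function(path) {
  cols <- c("peptide", "protein_group", "unique", "pep",
            paste0("r", 126:131))
  ps <- .read_tsv(path, cols, what = "PSM table")
  ps$unique <- as.logical(ps$unique)
  if (any(ps$pep < 0 | ps$pep > 1)) {
    stop("PEP values must lie in [0, 1]", call. = FALSE)
  }
  ps
}

#' Read a TMT channel design
#'
#' Accepts YAML (`channel: condition` mapping) or TSV with columns
#' `channel`, `condition`. The default six-plex layout assigns 126/127 to
#' M0, 128/129 to M1 and 130/131 to M2.
#'
#' @param path Path to a YAML or TSV file; `NULL` returns the default
#'   layout.
#' @return Named character vector, channel -> condition.
#' @export
read_channel_design <- function(path = NULL) {
  if (is.null(path)) {
    return(c("126" = "M0", "127" = "M0", "128" = "M1", "129" = "M1",
             "130" = "M2", "131" = "M2"))
  }
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    out <- vapply(y, as.character, character(1))
    names(out) <- names(y)
  } else {
    df <- .read_tsv(path, c("channel", "condition"), what = "channel design")
    out <- as.character(df$condition)
    names(out) <- as.character(df$channel)
  }
  out
}
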