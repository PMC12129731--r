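# Tabular containers and bit-faithful readers/writers for the pipeline's
# text formats: wide proteome pivot tables, long-form phospho reports,
# sample sheets and result tables. All files are UTF-8, tab-delimited
# (CSV for the sample sheet), LF line endings.

#' Intensity table container
#'
#' A features x samples intensity matrix with an explicit missing mask
#' (`NA` cells), a scale tag, and optional per-feature peptide counts
#' (proteome tables only).
#'
#' @param values Numeric matrix, features in rows and samples in columns;
#'   both dimnames required and unique. Missing values as `NA`.
#' @param scale One of `"raw"`, `"log2"`, `"normalized"`. On the raw
#'   scale all present values must be positive.
#' @param peptide_counts Optional named integer vector (>= 1) of peptide
#'   counts per feature, names matching `rownames(values)`.
#'
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(values, scale = c("raw", "log2", "normalized"),
                            peptide_counts = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    abort_phosphosig("`values` must be a numeric matrix", "format_error")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    abort_phosphosig("`values` must have feature and sample dimnames", "format_error")
  if (nrow(values) == 0 || ncol(values) == 0)
    dimnames(values) <- list(rownames(values) %||% character(0),
                             colnames(values) %||% character(0))
  if (anyDuplicated(rownames(values)))
    abort_phosphosig(sprintf("duplicated feature id(s): %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")),
      "format_error")
  if (anyDuplicated(colnames(values)))
    abort_phosphosig("duplicated sample id(s)", "format_error")
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    abort_phosphosig("raw-scale intensities must be positive", "format_error")
  if (!is.null(peptide_counts)) {
    if (is.null(names(peptide_counts)) ||
        !setequal(names(peptide_counts), rownames(values)))
      abort_phosphosig("`peptide_counts` names must match feature ids", "format_error")
    peptide_counts <- peptide_counts[rownames(values)]
    if (any(peptide_counts < 1))
      abort_phosphosig("peptide counts must be >= 1", "format_error")
  }
  structure(list(values = values, scale = scale,
                 peptide_counts = peptide_counts),
            class = "intensity_table")
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' @export
print.intensity_table <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("intensity_table: %d features x %d samples [%s scale, %.1f%% missing%s]\n",
              nrow(x$values), ncol(x$values), x$scale, 100 * miss,
              if (is.null(x$peptide_counts)) "" else ", peptide counts"))
  invisible(x)
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# Tokens parsed as missing in DIA export dialects.
MISSING_TOKENS <- c("", "NaN", "NA", "Filtered")

#' Read a wide proteome pivot table
#'
#' Tab-delimited file with a feature-id column, an optional peptide-count
#' column and one column per sample. The cells `""`, `"NaN"`, `"NA"` and
#' `"Filtered"` are parsed as missing.
#'
#' @param path File path.
#' @param id_col Name of the feature-id column (default `"protein_id"`).
#' @param peptide_col Name of the peptide-count column, or `NULL` if
#'   absent (default `"n_peptides"`, silently ignored when not present).
#' @param na_tokens Missing-value token set.
#' @return An [intensity_table()] on the raw scale.
#' @export
read_proteome_pivot <- function(path, id_col = "protein_id",
                                peptide_col = "n_peptides",
                                na_tokens = MISSING_TOKENS) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE)
  if (!id_col %in% names(raw))
    abort_phosphosig(sprintf("missing feature-id column '%s'", id_col), "format_error")
  ids <- raw[[id_col]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    abort_phosphosig(sprintf("duplicated feature id(s): %s",
                             paste(unique(dup), collapse = ", ")), "format_error")
  counts <- NULL
  if (!is.null(peptide_col) && peptide_col %in% names(raw)) {
    counts <- as.integer(raw[[peptide_col]])
    names(counts) <- ids
  }
  sample_cols <- setdiff(names(raw), c(id_col, peptide_col))
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_cols),
                dimnames = list(ids, sample_cols))
  for (j in seq_along(sample_cols)) {
    cell <- raw[[sample_cols[j]]]
    miss <- cell %in% na_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      abort_phosphosig(sprintf(
        "non-numeric intensity '%s' at feature '%s', sample '%s'",
        cell[i], ids[i], sample_cols[j]), "format_error")
    }
    num[miss] <- NA_real_
    mat[, j] <- num
  }
  intensity_table(mat, scale = "raw", peptide_counts = counts)
}

#' Write a wide proteome pivot table
#'
#' Inverse of [read_proteome_pivot()]; round-trips values, missing mask
#' and peptide counts exactly (values serialized with full precision).
#'
#' @param table An [intensity_table()].
#' @param path Output path.
#' @inheritParams read_proteome_pivot
#' @export
write_proteome_pivot <- function(table, path, id_col = "protein_id",
                                 peptide_col = "n_peptides") {
  stopifnot(inherits(table, "intensity_table"))
  df <- data.frame(id = feature_ids(table), stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- id_col
  if (!is.null(table$peptide_counts)) df[[peptide_col]] <- table$peptide_counts
  vals <- table$values
  for (j in seq_len(ncol(vals))) {
    col <- format(vals[, j], digits = 17, trim = TRUE, scientific = FALSE)
    col[is.na(vals[, j])] <- "NA"
    df[[colnames(vals)[j]]] <- col
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

PHOSPHO_COLS <- c("peptide_sequence", "protein_id", "ptm_position",
                  "residue", "localization_confidence", "sample_id",
                  "intensity")

#' Read a long-form phospho-peptide report
#'
#' One row per peptide x modification x sample, pre site-level collapse.
#' Validates localization confidence in \[0, 1\], residue in \{S, T, Y\}
#' and 1-based site positions.
#'
#' @param path File path (tab-delimited with named columns
#'   `peptide_sequence`, `protein_id`, `ptm_position`, `residue`,
#'   `localization_confidence`, `sample_id`, `intensity`).
#' @return A `data.frame` of class `phospho_long`.
#' @export
read_phospho_longform <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = character())
  missing_cols <- setdiff(PHOSPHO_COLS, names(df))
  if (length(missing_cols))
    abort_phosphosig(sprintf("missing required column(s): %s",
                             paste(missing_cols, collapse = ", ")), "format_error")
  df <- df[, PHOSPHO_COLS]
  validate_phospho_long(df)
}

validate_phospho_long <- function(df) {
  if (nrow(df)) {
    conf <- df$localization_confidence
    if (any(conf < 0 | conf > 1, na.rm = TRUE) || anyNA(conf))
      abort_phosphosig("localization_confidence outside [0, 1]", "format_error")
    if (any(!df$residue %in% c("S", "T", "Y")))
      abort_phosphosig("residue must be one of S, T, Y", "format_error")
    if (any(df$ptm_position < 1))
      abort_phosphosig("ptm_position must be >= 1 (1-based)", "format_error")
    if (any(df$intensity <= 0, na.rm = TRUE))
      abort_phosphosig("intensities must be positive", "format_error")
  }
  class(df) <- c("phospho_long", "data.frame")
  df
}

#' Write a long-form phospho-peptide report
#' @param long A `phospho_long` data frame.
#' @param path Output path.
#' @export
write_phospho_longform <- function(long, path) {
  write.table(as.data.frame(long)[, PHOSPHO_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8",
              eol = "\n")
  invisible(path)
}

SHEET_COLS <- c("sample_id", "group", "centre", "sex", "age", "updrs3", "moca")

GROUP_LEVELS <- c("G2019S_L2PD", "G2019S_L2NMC", "R1441G_L2PD",
                  "R1441G_L2NMC", "iPD", "CTRL")

#' Read a sample sheet (CSV)
#'
#' Columns: `sample_id`, `group` (one of the six cohort labels),
#' `centre` (B/S/D), `sex`, `age`, `updrs3`, `moca`.
#' @param path File path.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SHEET_COLS, names(df))
  if (length(missing_cols))
    abort_phosphosig(sprintf("sample sheet missing column(s): %s",
                             paste(missing_cols, collapse = ", ")), "format_error")
  validate_sample_sheet(df[, SHEET_COLS])
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    abort_phosphosig("duplicated sample_id in sample sheet", "format_error")
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad))
    abort_phosphosig(sprintf("unknown group label(s): %s",
                             paste(bad, collapse = ", ")), "format_error")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet (CSV)
#' @param sheet A `sample_sheet` data frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table deterministically
#'
#' Serializes differential, correlation or signature tables as
#' tab-delimited text with a deterministic row order: ascending adjusted
#' p-value, ties broken by lexicographic feature id. Floats are written
#' with 6 significant digits so repeated runs are byte-identical.
#'
#' @param results A data frame with a `feature_id` column and usually an
#'   `adj_p` column.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  if (nrow(df)) {
    ord <- if ("adj_p" %in% names(df)) {
      order(df$adj_p, df$feature_id, method = "radix")
    } else {
      order(df$feature_id, method = "radix")
    }
    df <- df[ord, , drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(signif(df[[j]], 6), format = "g", digits = 6)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
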