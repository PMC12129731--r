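# Preprocessing of intensity tables, mirroring the study's workflow.
# Proteome: two-peptide filter -> >=70% row-missingness filter -> KNN
# imputation -> log2 -> (optional) quantile normalization.
# Phospho: >70% blank-column filter -> site-level collapse at a
# localization confidence of > 0.75 -> >=30% row filter -> KNN
# imputation -> log2 -> quantile normalization.

#' Pipeline configuration
#'
#' Houses the analysis thresholds. Defaults follow the study protocol:
#' proteins kept only when mapped by at least two peptide sequences;
#' proteome rows dropped at >= 70% missing, phospho rows at >= 30%,
#' sample columns at > 70% blank (note the deliberate strict/non-strict
#' asymmetry); PTM localization confidence must exceed 0.75; hits called
#' at |log2FC| > 0.6 (1.5-fold linear) and BH-adjusted P < 0.05;
#' clinical correlations at |rho| > 0.5.
#'
#' @param min_peptides Minimum peptides per protein (default 2).
#' @param row_missing_cutoff_proteome Row missing fraction cutoff,
#'   proteome (drop when `>=`; default 0.70).
#' @param row_missing_cutoff_phospho Row missing fraction cutoff,
#'   collapsed phospho (drop when `>=`; default 0.30).
#' @param col_blank_cutoff Column blank fraction cutoff (drop when `>`;
#'   default 0.70).
#' @param localization_cutoff PTM localization confidence; records kept
#'   when strictly above (default 0.75).
#' @param knn_k Neighbours for KNN imputation (default 10).
#' @param log2fc_cutoff,adjp_cutoff Differential significance rule
#'   (strict inequalities; defaults 0.6 and 0.05).
#' @param anova_p_cutoff ANOVA screen cutoff on raw p (default 0.05).
#' @param rho_cutoff Spearman cutoff for clinical correlation (default 0.5).
#' @param normalize_proteome Quantile-normalize the proteome after log2
#'   (default `TRUE`).
#' @param site_aggregation Collapse aggregation: `"max"` (default),
#'   `"sum"` or `"mean"`.
#' @param mcts An [mcts_config()].
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_peptides = 2L,
                            row_missing_cutoff_proteome = 0.70,
                            row_missing_cutoff_phospho = 0.30,
                            col_blank_cutoff = 0.70,
                            localization_cutoff = 0.75,
                            knn_k = 10L,
                            log2fc_cutoff = 0.6,
                            adjp_cutoff = 0.05,
                            anova_p_cutoff = 0.05,
                            rho_cutoff = 0.5,
                            normalize_proteome = TRUE,
                            site_aggregation = c("max", "sum", "mean"),
                            mcts = mcts_config(),
                            seed = 1L) {
  fracs <- c(row_missing_cutoff_proteome, row_missing_cutoff_phospho,
             col_blank_cutoff, localization_cutoff)
  if (any(fracs < 0 | fracs > 1))
    abort_phosphosig("fraction cutoffs must lie in [0, 1]", "config_error")
  if (log2fc_cutoff <= 0 || adjp_cutoff <= 0 || rho_cutoff <= 0)
    abort_phosphosig("cutoffs must be positive", "config_error")
  structure(list(
    min_peptides = as.integer(min_peptides),
    row_missing_cutoff_proteome = row_missing_cutoff_proteome,
    row_missing_cutoff_phospho = row_missing_cutoff_phospho,
    col_blank_cutoff = col_blank_cutoff,
    localization_cutoff = localization_cutoff,
    knn_k = as.integer(knn_k),
    log2fc_cutoff = log2fc_cutoff,
    adjp_cutoff = adjp_cutoff,
    anova_p_cutoff = anova_p_cutoff,
    rho_cutoff = rho_cutoff,
    normalize_proteome = isTRUE(normalize_proteome),
    site_aggregation = match.arg(site_aggregation),
    mcts = mcts,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Remove proteins identified by too few peptides
#'
#' Keeps features with `peptide_count >= min_peptides`, preserving row
#' order. Mirrors the removal of proteins identified by only one peptide
#' sequence.
#'
#' @param table An [intensity_table()] with peptide counts.
#' @param min_peptides Minimum count (default 2).
#' @return Filtered table; dropped ids in attribute `dropped`.
#' @export
filter_min_peptides <- function(table, min_peptides = 2L) {
  stopifnot(inherits(table, "intensity_table"))
  if (is.null(table$peptide_counts))
    abort_phosphosig("peptide counts absent; cannot apply the peptide filter",
                     "config_error")
  keep <- table$peptide_counts >= min_peptides
  if (!any(keep))
    warning("peptide filter removed every feature")
  out <- intensity_table(table$values[keep, , drop = FALSE], scale = table$scale,
                         peptide_counts = table$peptide_counts[keep])
  attr(out, "dropped") <- feature_ids(table)[!keep]
  out
}

#' Filter features or samples by missingness
#'
#' Feature axis drops rows whose missing fraction is `>=` the cutoff
#' (the study's ">=70% missing data" rule); sample axis drops columns
#' whose blank fraction is strictly `>` the cutoff (its ">70% blank
#' cells" rule).
#'
#' @param table An [intensity_table()].
#' @param axis `"feature"` or `"sample"`.
#' @param cutoff Fraction in \[0, 1\].
#' @return Filtered table; dropped ids in attribute `dropped`.
#' @export
filter_missingness <- function(table, axis = c("feature", "sample"), cutoff) {
  stopifnot(inherits(table, "intensity_table"))
  axis <- match.arg(axis)
  if (cutoff < 0 || cutoff > 1)
    abort_phosphosig("cutoff must lie in [0, 1]", "config_error")
  miss <- is.na(table$values)
  if (axis == "feature") {
    frac <- rowMeans(miss)
    keep <- frac < cutoff
    out <- intensity_table(table$values[keep, , drop = FALSE],
                           scale = table$scale,
                           peptide_counts = table$peptide_counts[keep])
    attr(out, "dropped") <- feature_ids(table)[!keep]
  } else {
    frac <- colMeans(miss)
    keep <- frac <= cutoff
    out <- intensity_table(table$values[, keep, drop = FALSE],
                           scale = table$scale,
                           peptide_counts = table$peptide_counts)
    attr(out, "dropped") <- sample_ids(table)[!keep]
  }
  out
}

#' Collapse phospho-peptide records to site-level features
#'
#' Discards records whose localization confidence is at or below the
#' cutoff (kept strictly above 0.75 by default), groups the rest by
#' (protein, residue, position) and aggregates the intensities of
#' peptides covering the same site within a sample (default: maximum,
#' avoiding double-counting of shared evidence). Output feature ids are
#' `PROTEIN_<residue><position>`, e.g. `RAB12_S106`. Sites with no
#' surviving record in any sample are absent from the output.
#'
#' @param long A `phospho_long` data frame.
#' @param localization_cutoff Confidence cutoff (default 0.75).
#' @param aggregation `"max"` (default), `"sum"` or `"mean"`.
#' @return An [intensity_table()] on the raw scale (missing where a site
#'   has no surviving record in a sample).
#' @export
collapse_ptm_sites <- function(long, localization_cutoff = 0.75,
                               aggregation = c("max", "sum", "mean")) {
  aggregation <- match.arg(aggregation)
  df <- as.data.frame(long)
  df <- df[df$localization_confidence > localization_cutoff, , drop = FALSE]
  if (!nrow(df)) {
    return(intensity_table(
      matrix(numeric(), 0, 0, dimnames = list(character(), character())),
      scale = "raw"))
  }
  df$site_id <- paste0(df$protein_id, "_", df$residue, df$ptm_position)
  dt <- data.table::as.data.table(df[, c("site_id", "sample_id", "intensity")])
  site_id <- sample_id <- intensity <- NULL  # R CMD check NSE guards
  aggfun <- switch(aggregation, max = max, sum = sum, mean = mean)
  agg <- dt[, list(value = aggfun(intensity)), by = list(site_id, sample_id)]
  sites <- sort(unique(agg$site_id))
  samples <- unique(df$sample_id)
  mat <- matrix(NA_real_, length(sites), length(samples),
                dimnames = list(sites, samples))
  mat[cbind(match(agg$site_id, sites), match(agg$sample_id, samples))] <- agg$value
  intensity_table(mat, scale = "raw")
}

#' K-nearest-neighbour imputation over features
#'
#' Fills each missing cell with the inverse-distance-weighted mean of
#' the `k` nearest feature rows observed in that sample. Distances are
#' root-mean-square Euclidean over the samples observed in both rows
#' (i.e. rescaled by the overlap count). Observed values are never
#' altered. Neighbours are computed on the log2 scale for raw tables.
#'
#' @param table An [intensity_table()]; every row must have at least one
#'   observed value.
#' @param k Number of neighbours (default 10; clamped to the available
#'   neighbour count with a message).
#' @return A complete table on the same scale.
#' @export
knn_impute <- function(table, k = 10L) {
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  if (!anyNA(v)) return(table)
  x <- if (table$scale == "raw") log2(v) else v
  miss <- is.na(x)
  if (any(rowSums(!miss) == 0))
    abort_phosphosig(sprintf("feature(s) with no observed value: %s",
      paste(rownames(x)[rowSums(!miss) == 0], collapse = ", ")),
      "imputation_error")
  n <- nrow(x)
  if (k >= n) {
    message("knn_impute: k clamped to ", n - 1L, " available neighbours")
    k <- n - 1L
  }
  # pairwise RMS distance over co-observed samples, by matrix algebra
  x0 <- x; x0[miss] <- 0
  O <- 1 - miss
  sq <- x0^2
  cross <- tcrossprod(x0)
  sse <- tcrossprod(sq, O) + tcrossprod(O, sq) - 2 * cross
  shared <- tcrossprod(O)
  d <- sqrt(pmax(sse, 0) / pmax(shared, 1))
  d[shared == 0] <- Inf
  diag(d) <- Inf
  no_overlap <- apply(d, 1, function(z) all(!is.finite(z)))
  if (any(no_overlap & rowSums(miss) > 0))
    abort_phosphosig(sprintf(
      "feature(s) share no observed sample with any other feature: %s",
      paste(rownames(x)[no_overlap & rowSums(miss) > 0], collapse = ", ")),
      "imputation_error")
  filled <- x
  for (i in which(rowSums(miss) > 0)) {
    ord <- order(d[i, ])
    for (j in which(miss[i, ])) {
      donors <- ord[!miss[ord, j] & is.finite(d[i, ord])]
      donors <- donors[seq_len(min(k, length(donors)))]
      if (!length(donors))
        abort_phosphosig(sprintf(
          "no donor neighbour for feature '%s' in sample '%s'",
          rownames(x)[i], colnames(x)[j]), "imputation_error")
      w <- 1 / (d[i, donors] + 1e-9)
      filled[i, j] <- sum(w * x[donors, j]) / sum(w)
    }
  }
  out <- if (table$scale == "raw") 2^filled else filled
  out[!miss] <- v[!miss]  # observed entries bit-identical
  intensity_table(out, scale = table$scale,
                  peptide_counts = table$peptide_counts)
}

#' Log2-transform a complete raw-scale table
#' @param table A complete raw-scale [intensity_table()].
#' @return The table on the log2 scale.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "raw")
    abort_phosphosig("log2_transform expects a raw-scale table", "domain_error")
  v <- table$values
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    abort_phosphosig(sprintf("non-positive intensity at feature '%s', sample '%s'",
                             rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]),
                     "domain_error")
  intensity_table(log2(v), scale = "log2",
                  peptide_counts = table$peptide_counts)
}

#' Quantile normalization
#'
#' Replaces each column's sorted values by the across-column mean of
#' order statistics. Ties within a column receive the mean of the
#' target values they span (average ranks). Afterwards all columns have
#' identical empirical distributions.
#'
#' @param table A complete log2-scale [intensity_table()].
#' @return The table with scale `"normalized"`.
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  if (anyNA(v))
    abort_phosphosig("quantile normalization expects a complete table",
                     "domain_error")
  if (ncol(v) >= 2) {
    target <- rowMeans(apply(v, 2, sort))
    for (j in seq_len(ncol(v))) {
      assigned <- target[rank(v[, j], ties.method = "first")]
      # tied values receive the mean of the target values they span
      v[, j] <- ave(assigned, v[, j])
    }
  }
  intensity_table(v, scale = "normalized",
                  peptide_counts = table$peptide_counts)
}

#' Run the full proteome preprocessing chain
#'
#' Peptide filter, row-missingness filter, KNN imputation, log2 and
#' (by default) quantile normalization, with a per-stage audit of
#' feature counts in attribute `audit`.
#'
#' @param table Raw proteome [intensity_table()] with peptide counts.
#' @param config A [pipeline_config()].
#' @return A complete normalized table.
#' @export
preprocess_proteome <- function(table, config = pipeline_config()) {
  audit <- list(input = nrow(table$values))
  table <- filter_min_peptides(table, config$min_peptides)
  audit$peptide_filter <- nrow(table$values)
  table <- filter_missingness(table, "feature",
                              config$row_missing_cutoff_proteome)
  audit$row_filter <- nrow(table$values)
  table <- knn_impute(table, config$knn_k)
  table <- log2_transform(table)
  if (config$normalize_proteome) table <- quantile_normalize(table)
  attr(table, "audit") <- audit
  table
}

#' Run the full phospho preprocessing chain
#'
#' Blank-column filter on the long table's collapsed form, site-level
#' collapse, row-missingness filter, KNN imputation, log2 and quantile
#' normalization.
#'
#' @param long A `phospho_long` data frame.
#' @param config A [pipeline_config()].
#' @return A complete normalized site-level table.
#' @export
preprocess_phospho <- function(long, config = pipeline_config()) {
  table <- collapse_ptm_sites(long, config$localization_cutoff,
                              config$site_aggregation)
  audit <- list(collapsed_sites = nrow(table$values))
  table <- filter_missingness(table, "sample", config$col_blank_cutoff)
  audit$column_filter <- ncol(table$values)
  table <- filter_missingness(table, "feature",
                              config$row_missing_cutoff_phospho)
  audit$row_filter <- nrow(table$values)
  table <- knn_impute(table, config$knn_k)
  table <- log2_transform(table)
  table <- quantile_normalize(table)
  attr(table, "audit") <- audit
  table
}
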