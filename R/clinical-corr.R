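# Spearman correlation of differential features with clinical motor
# severity (UPDRS-III), BH-adjusted within the tested feature set, and
# the |rho| > 0.5 / adjusted P < 0.05 significance rule.

#' Spearman correlation of one feature with severity scores
#'
#' Tie-corrected (average-rank) Spearman rho with a two-sided p-value
#' from the t approximation on n - 2 degrees of freedom.
#'
#' @param feature_values Numeric vector (one value per sample).
#' @param scores Paired severity scores (e.g. UPDRS-III).
#' @return List with `rho` and `p`.
#' @export
spearman_correlate <- function(feature_values, scores) {
  ok <- complete.cases(feature_values, scores)
  x <- feature_values[ok]; s <- scores[ok]
  if (length(x) < 4)
    abort_phosphosig("need at least 4 paired observations", "invalid_request")
  if (sd(x) == 0 || sd(s) == 0)
    abort_phosphosig("constant vector: Spearman correlation undefined",
                     "undefined_correlation")
  ct <- suppressWarnings(cor.test(x, s, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlate features with UPDRS-III motor scores
#'
#' Runs [spearman_correlate()] for each requested feature against the
#' sheet's `updrs3` scores, restricted to the requested groups (by
#' default all patients and controls), BH-adjusts across the tested
#' set, and applies the strict significance rule
#' `|rho| > rho_cutoff & adj_p < adjp_cutoff`. Constant features are
#' skipped with a message and reported in attribute `skipped`.
#'
#' @param table A complete [intensity_table()] (log2 or normalized).
#' @param sheet A `sample_sheet` with `updrs3` present.
#' @param features Feature ids to test (default: all in the table).
#' @param groups Sample groups to include (default: all).
#' @param rho_cutoff,adjp_cutoff Significance rule (defaults 0.5, 0.05).
#' @param rho_inclusive_margin Relaxation subtracted from `rho_cutoff`
#'   (default 0 = strict rule).
#' @return A `corr_result` data frame (`feature_id`, `rho`, `p`,
#'   `adj_p`, `passes`, `direction`).
#' @export
correlate_features <- function(table, sheet, features = feature_ids(table),
                               groups = unique(sheet$group),
                               rho_cutoff = 0.5, adjp_cutoff = 0.05,
                               rho_inclusive_margin = 0) {
  stopifnot(inherits(table, "intensity_table"))
  sheet <- sheet[sheet$group %in% groups & !is.na(sheet$updrs3), ]
  use <- intersect(sheet$sample_id, sample_ids(table))
  scores <- sheet$updrs3[match(use, sheet$sample_id)]
  rows <- list(); skipped <- character()
  for (f in features) {
    v <- table$values[f, use]
    res <- tryCatch(spearman_correlate(v, scores),
                    undefined_correlation = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, f)
      next
    }
    rows[[f]] <- data.frame(feature_id = f, rho = res$rho, p = res$p,
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("skipped constant feature(s): ", paste(skipped, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), rho = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$adj_p <- bh_adjust(out$p)
  out <- correlation_filter(out, rho_cutoff, adjp_cutoff, rho_inclusive_margin)
  attr(out, "skipped") <- skipped
  attr(out, "n_samples") <- length(use)
  class(out) <- c("corr_result", "data.frame")
  out
}

#' Apply the correlation significance rule
#'
#' @param results A data frame with `rho` and `adj_p` columns.
#' @inheritParams correlate_features
#' @return The results with `passes` and `direction` columns set by the
#'   strict rule `|rho| > rho_cutoff - rho_inclusive_margin` and
#'   `adj_p < adjp_cutoff`.
#' @export
correlation_filter <- function(results, rho_cutoff = 0.5, adjp_cutoff = 0.05,
                               rho_inclusive_margin = 0) {
  results$passes <- abs(results$rho) > (rho_cutoff - rho_inclusive_margin) &
    results$adj_p < adjp_cutoff
  results$direction <- ifelse(results$rho >= 0, "positive", "inverse")
  results
}
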