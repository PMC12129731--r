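# Per-feature moderated differential testing between group contrasts
# with empirical-Bayes variance shrinkage, BH-FDR control, the
# |log2FC| > 0.6 & adjusted P < 0.05 significance rule, and a one-way
# ANOVA cross-group screen.

#' Define a group contrast
#'
#' Each side pools one or more group labels (e.g. all G2019S carriers
#' versus controls). Sides must be disjoint and non-empty.
#'
#' @param name Contrast name.
#' @param group_a,group_b Character vectors of group labels; the
#'   log2 fold-change is `mean(group_a) - mean(group_b)`.
#' @return A list of class `contrast`.
#' @export
contrast <- function(name, group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    abort_phosphosig("both contrast sides must be non-empty", "design_error")
  if (length(intersect(group_a, group_b)))
    abort_phosphosig("contrast sides must be disjoint", "design_error")
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "contrast")
}

# Newton inversion of the trigamma function (for the scaled-F moment
# estimator of the variance prior). Solves trigamma(x) = y, y > 0.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Empirical-Bayes fit of the variance prior (d0, s0^2) by
# moment-matching the marginal distribution of log s_g^2 under a
# scaled-F model (digamma/trigamma inversion). Returns d0 = Inf (fully
# pooled prior) when the trigamma equation has no positive solution.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    message("variance prior: no positive trigamma solution; using d0 = Inf")
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group differential test
#'
#' Fits per-feature group means for the two (possibly pooled) contrast
#' sides, pools the residual variance, shrinks it towards an
#' empirical-Bayes prior estimated by moment-matching the marginal
#' distribution of the log sample variances, and tests the log2
#' fold-change with a Student t on `d0 + d_g` degrees of freedom.
#' P-values are BH-adjusted within the contrast and hits classified by
#' the strict `|log2FC| > log2fc_cutoff` and `adj_p < adjp_cutoff` rule.
#'
#' @param table A complete log2/normalized [intensity_table()].
#' @param sheet A `sample_sheet` covering the table's samples.
#' @param contrast A [contrast()]; pooled sides are handled by
#'   relabelling before fitting.
#' @param log2fc_cutoff,adjp_cutoff Significance rule (defaults 0.6, 0.05).
#' @param d0 Optional prior df override: `0` reduces to the ordinary
#'   pooled-variance t, `Inf` fully pools variances; `NULL` (default)
#'   estimates the prior from the data.
#' @return A `diff_result` data frame (`feature_id`, `log2fc`, `t_mod`,
#'   `p`, `adj_p`, `significant`, `direction`) with the fitted prior in
#'   attribute `prior` and per-feature residual variances in `s2`.
#' @export
moderated_t_test <- function(table, sheet, contrast,
                             log2fc_cutoff = 0.6, adjp_cutoff = 0.05,
                             d0 = NULL) {
  stopifnot(inherits(table, "intensity_table"), inherits(contrast, "contrast"))
  if (table$scale == "raw")
    abort_phosphosig("differential testing expects a log2 or normalized table",
                     "design_error")
  if (anyNA(table$values))
    abort_phosphosig("differential testing expects a complete (imputed) table",
                     "design_error")
  known <- unique(sheet$group)
  missing_g <- setdiff(c(contrast$group_a, contrast$group_b), known)
  if (length(missing_g))
    abort_phosphosig(sprintf("contrast references unknown group(s): %s",
                             paste(missing_g, collapse = ", ")), "design_error")
  side <- ifelse(sheet$group %in% contrast$group_a, "A",
                 ifelse(sheet$group %in% contrast$group_b, "B", NA))
  use <- sheet$sample_id[!is.na(side)]
  use <- intersect(use, sample_ids(table))
  side <- side[match(use, sheet$sample_id)]
  na <- sum(side == "A"); nb <- sum(side == "B")
  if (na < 2 || nb < 2)
    abort_phosphosig("each contrast side needs at least 2 samples", "design_error")
  x <- table$values[, use, drop = FALSE]
  xa <- x[, side == "A", drop = FALSE]
  xb <- x[, side == "B", drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  dg <- na + nb - 2
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  s2 <- (ssa + ssb) / dg
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, dg)
  } else {
    prior <- list(d0 = d0,
                  s02 = if (d0 > 0) fit_variance_prior(s2, dg)$s02 else NA_real_)
  }
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s02, length(s2))
  } else if (prior$d0 == 0) {
    s2
  } else {
    (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
  }
  lfc <- ma - mb
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, lfc / se, 0)
  df_total <- min(prior$d0 + dg, .Machine$double.xmax)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[se == 0] <- 1
  res <- data.frame(feature_id = feature_ids(table), log2fc = lfc,
                    t_mod = t_mod, p = p, adj_p = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- classify_hits(res, log2fc_cutoff, adjp_cutoff)
  attr(res, "contrast") <- contrast$name
  attr(res, "prior") <- prior
  attr(res, "s2") <- s2
  attr(res, "n") <- c(A = na, B = nb)
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort_phosphosig("p-values must lie in [0, 1]", "domain_error")
  p.adjust(p_values, method = "BH")
}

#' Classify differential hits
#'
#' Applies the significance rule with strict inequalities:
#' `|log2fc| > log2fc_cutoff` and `adj_p < adjp_cutoff` (or `<=` with
#' `inclusive = TRUE`). Attaches up/down counts as attribute `n_hits`.
#'
#' @param results A data frame with `log2fc` and `adj_p` columns.
#' @param log2fc_cutoff,adjp_cutoff Cutoffs (defaults 0.6, 0.05).
#' @param inclusive Use `adj_p <= adjp_cutoff` instead of strict `<`.
#' @return The results with `significant` and `direction` columns.
#' @export
classify_hits <- function(results, log2fc_cutoff = 0.6, adjp_cutoff = 0.05,
                          inclusive = FALSE) {
  pass_p <- if (inclusive) results$adj_p <= adjp_cutoff
            else results$adj_p < adjp_cutoff
  results$significant <- abs(results$log2fc) > log2fc_cutoff & pass_p
  results$direction <- ifelse(results$log2fc >= 0, "up", "down")
  attr(results, "n_hits") <- c(
    up = sum(results$significant & results$direction == "up"),
    down = sum(results$significant & results$direction == "down"))
  results
}

#' One-way ANOVA screen across groups
#'
#' Per-feature fixed-effects F statistic across the named groups with
#' BH-adjusted p-values. Features constant across all samples get
#' `F = 0, p = 1` by convention.
#'
#' @param table A complete log2/normalized [intensity_table()].
#' @param sheet A `sample_sheet`.
#' @param groups Group labels to include (default: all groups present).
#' @return A data frame (`feature_id`, `F`, `p`, `adj_p`).
#' @export
anova_screen <- function(table, sheet, groups = unique(sheet$group)) {
  stopifnot(inherits(table, "intensity_table"))
  sheet <- sheet[sheet$group %in% groups & sheet$sample_id %in% sample_ids(table), ]
  sizes <- table(sheet$group)
  if (length(sizes) < 2 || any(sizes < 2))
    abort_phosphosig("every group needs at least 2 samples", "design_error")
  x <- table$values[, sheet$sample_id, drop = FALSE]
  g <- factor(sheet$group)
  k <- nlevels(g)
  n <- ncol(x)
  group_sums <- x %*% stats::model.matrix(~ g - 1)
  ng <- as.vector(table(g))
  group_means <- sweep(group_sums, 2, ng, "/")
  grand <- rowMeans(x)
  ss_between <- rowSums(sweep((group_means - grand)^2, 2, ng, "*"))
  ss_total <- rowSums((x - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  Fstat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  degenerate <- ss_within <= .Machine$double.eps * pmax(ss_total, 1)
  Fstat[degenerate & ss_between <= 1e-12] <- 0
  p <- pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  p[Fstat == 0] <- 1
  data.frame(feature_id = feature_ids(table), F = Fstat, p = p,
             adj_p = bh_adjust(p), stringsAsFactors = FALSE, row.names = NULL)
}

#' Standard contrast set for the cohort
#'
#' The study's comparison vocabulary: each carrier group versus
#' controls, manifesting versus non-manifesting per mutation, pooled
#' carriers versus controls, and idiopathic PD versus mutation PD.
#'
#' @return A named list of [contrast()] objects.
#' @export
standard_contrasts <- function() {
  list(
    g2019s_l2pd_vs_ctrl = contrast("g2019s_l2pd_vs_ctrl", "G2019S_L2PD", "CTRL"),
    g2019s_l2nmc_vs_ctrl = contrast("g2019s_l2nmc_vs_ctrl", "G2019S_L2NMC", "CTRL"),
    g2019s_l2pd_vs_l2nmc = contrast("g2019s_l2pd_vs_l2nmc", "G2019S_L2PD",
                                    "G2019S_L2NMC"),
    g2019s_carriers_vs_ctrl = contrast("g2019s_carriers_vs_ctrl",
                                       c("G2019S_L2PD", "G2019S_L2NMC"), "CTRL"),
    r1441g_carriers_vs_ctrl = contrast("r1441g_carriers_vs_ctrl",
                                       c("R1441G_L2PD", "R1441G_L2NMC"), "CTRL"),
    ipd_vs_ctrl = contrast("ipd_vs_ctrl", "iPD", "CTRL"),
    ipd_vs_g2019s_l2pd = contrast("ipd_vs_g2019s_l2pd", "iPD", "G2019S_L2PD")
  )
}
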