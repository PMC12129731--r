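# Moderated testing reduces correctly, matches independent oracles and
# controls the null.

log2_cohort_table <- function(sheet, n_feat = 50, seed = 1, truth = NULL) {
  truth <- truth %||% null_truth(seed)
  log2_transform(generate_proteome(sheet, n_feat, truth))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "domain_error")
  withr::with_seed(31, {
    for (i in 1:200) {
      p <- runif(sample(1:100, 1))
      expect_equal(bh_adjust(p), bh_bruteforce(p))
    }
  })
})

test_that("BH adjustment preserves the p-value ordering", {
  withr::with_seed(32, {
    p <- runif(200)
    adj <- bh_adjust(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p))
  })
})

test_that("with d0 = 0 the moderated t reduces to the ordinary pooled t", {
  sheet <- generate_cohort(c(iPD = 8L, CTRL = 9L), seed = 33)
  tab <- log2_cohort_table(sheet, 40, seed = 33)
  ct <- contrast("ipd_vs_ctrl", "iPD", "CTRL")
  d <- moderated_t_test(tab, sheet, ct, d0 = 0)
  ipd <- sheet$sample_id[sheet$group == "iPD"]
  ctrl <- sheet$sample_id[sheet$group == "CTRL"]
  for (f in sample(rownames(tab$values), 10)) {
    tt <- t.test(tab$values[f, ipd], tab$values[f, ctrl], var.equal = TRUE)
    expect_equal(d$t_mod[d$feature_id == f], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(d$p[d$feature_id == f], tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical group means give t = 0 and p = 1", {
  m <- matrix(rep(c(1, 2), each = 4), 1, 8,
              dimnames = list("flat", sprintf("s%d", 1:8)))
  m <- rbind(flat = c(5, 6, 5, 6, 5, 6, 5, 6), other = rnorm(8))
  colnames(m) <- sprintf("s%d", 1:8)
  sheet <- data.frame(sample_id = sprintf("s%d", 1:8),
                      group = rep(c("iPD", "CTRL"), each = 4),
                      stringsAsFactors = FALSE)
  class(sheet) <- c("sample_sheet", "data.frame")
  d <- moderated_t_test(intensity_table(m, "log2"), sheet,
                        contrast("c", "iPD", "CTRL"))
  expect_equal(d$t_mod[d$feature_id == "flat"], 0)
  expect_equal(d$p[d$feature_id == "flat"], 1)
})

test_that("the moderated t lies between the raw and fully pooled t", {
  sheet <- generate_cohort(c(iPD = 10L, CTRL = 10L), seed = 34)
  tab <- log2_cohort_table(sheet, 200, seed = 34)
  ct <- contrast("c", "iPD", "CTRL")
  d <- moderated_t_test(tab, sheet, ct)
  prior <- attr(d, "prior")
  s2 <- attr(d, "s2")
  expect_true(prior$d0 > 0)
  n <- attr(d, "n")
  se_raw <- sqrt(s2 * (1 / n["A"] + 1 / n["B"]))
  se_prior <- sqrt(prior$s02 * (1 / n["A"] + 1 / n["B"]))
  t_raw <- d$log2fc / se_raw
  t_prior <- d$log2fc / se_prior
  lo <- pmin(abs(t_raw), abs(t_prior))
  hi <- pmax(abs(t_raw), abs(t_prior))
  expect_true(all(abs(d$t_mod) >= lo - 1e-9 & abs(d$t_mod) <= hi + 1e-9))
  expect_true(all(sign(d$t_mod) == sign(t_raw) | d$t_mod == 0))
})

test_that("moderated statistics agree with limma's empirical Bayes fit", {
  skip_if_not_installed("limma")
  withr::with_seed(35, {
    m <- matrix(rnorm(300 * 24, sd = rep(runif(300, 0.5, 2), 24)), 300, 24,
                dimnames = list(sprintf("F%03d", 1:300), sprintf("s%02d", 1:24)))
  })
  groups <- rep(c("iPD", "CTRL"), each = 12)
  sheet <- data.frame(sample_id = colnames(m), group = groups,
                      stringsAsFactors = FALSE)
  class(sheet) <- c("sample_sheet", "data.frame")
  ours <- moderated_t_test(intensity_table(m, "log2"), sheet,
                           contrast("c", "iPD", "CTRL"))
  design <- model.matrix(~ 0 + factor(groups, levels = c("iPD", "CTRL")))
  colnames(design) <- c("iPD", "CTRL")
  fit <- limma::lmFit(m, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(iPD - CTRL,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(ours$log2fc, unname(fit$coefficients[, 1]), tolerance = 1e-9)
  expect_equal(ours$t_mod, unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(ours$p, unname(fit$p.value[, 1]), tolerance = 1e-6)
  expect_equal(attr(ours, "prior")$d0, fit$df.prior, tolerance = 1e-4)
})

test_that("the significance rule reproduces reported hit calls", {
  res <- data.frame(
    feature_id = c("RAB12_S106", "RAB9A", "MARGINAL"),
    log2fc = c(0.97, -0.77, 0.71),
    adj_p = c(0.036, 0.038, 0.999), stringsAsFactors = FALSE)
  out <- classify_hits(res)
  expect_identical(out$significant, c(TRUE, TRUE, FALSE))
  expect_identical(out$direction, c("up", "down", "up"))
  expect_identical(unname(attr(out, "n_hits")), c(1L, 1L))
  # the boundary adj_p = 0.05 is excluded by the strict rule but can be
  # admitted with the inclusive option
  edge <- data.frame(feature_id = "MON2_S205", log2fc = 1.25, adj_p = 0.05)
  expect_false(classify_hits(edge)$significant)
  expect_true(classify_hits(edge, inclusive = TRUE)$significant)
})

test_that("the ANOVA screen matches aov and handles degeneracy", {
  withr::with_seed(36, {
    m <- matrix(rnorm(10 * 15), 10, 15,
                dimnames = list(sprintf("F%02d", 1:10), sprintf("s%02d", 1:15)))
  })
  groups <- rep(c("A", "B", "C"), each = 5)
  sheet <- data.frame(sample_id = colnames(m), group = groups,
                      stringsAsFactors = FALSE)
  class(sheet) <- c("sample_sheet", "data.frame")
  scr <- anova_screen(intensity_table(m, "log2"), sheet)
  for (f in rownames(m)) {
    ref <- summary(aov(m[f, ] ~ factor(groups)))[[1]]
    expect_equal(scr$F[scr$feature_id == f], ref[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(scr$p[scr$feature_id == f], ref[["Pr(>F)"]][1],
                 tolerance = 1e-10)
  }
  # clear separation -> tiny p
  m2 <- rbind(sep = c(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)),
              konst = rep(1, 15))
  colnames(m2) <- colnames(m)
  scr2 <- anova_screen(intensity_table(m2, "log2"), sheet)
  expect_lt(scr2$p[scr2$feature_id == "sep"], 1e-6)
  # constant feature: F = 0, p = 1 by convention
  expect_equal(scr2$F[scr2$feature_id == "konst"], 0)
  expect_equal(scr2$p[scr2$feature_id == "konst"], 1)
  # group with < 2 samples
  bad <- sheet[-c(1:4), ]
  expect_error(anova_screen(intensity_table(m, "log2"), bad),
               class = "design_error")
})

test_that("contrast sides must be valid", {
  expect_error(contrast("x", character(), "CTRL"), class = "design_error")
  expect_error(contrast("x", "iPD", "iPD"), class = "design_error")
  sheet <- small_cohort(seed = 37)
  tab <- log2_cohort_table(sheet, 20, seed = 37)
  expect_error(moderated_t_test(tab, sheet, contrast("x", "iPD", "CTRL")),
               class = "design_error")  # iPD absent from this cohort
})
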