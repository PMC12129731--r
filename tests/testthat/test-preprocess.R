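# Filtering, collapse, imputation and normalization behave exactly as
# the documented rules prescribe.

toy_table <- function(values, scale = "log2", counts = NULL) {
  intensity_table(values, scale = scale, peptide_counts = counts)
}

test_that("peptide filter keeps features mapped by enough peptides", {
  m <- noise_matrix(3, 4, seed = 1)
  rownames(m) <- c("A", "B", "C")
  tab <- toy_table(m, counts = setNames(c(1L, 2L, 3L), c("A", "B", "C")))
  expect_identical(rownames(filter_min_peptides(tab, 2)$values), c("B", "C"))
  expect_identical(filter_min_peptides(tab, 1)$values, tab$values)
  all_one <- toy_table(m, counts = setNames(c(1L, 1L, 1L), c("A", "B", "C")))
  expect_warning(out <- filter_min_peptides(all_one, 2), "every feature")
  expect_identical(nrow(out$values), 0L)
  no_counts <- toy_table(m)
  expect_error(filter_min_peptides(no_counts, 2), class = "config_error")
})

test_that("missingness filters use >= for features and > for samples", {
  m <- noise_matrix(1, 10, seed = 2)
  m[1, 1:7] <- NA  # 70% missing row
  expect_identical(nrow(filter_missingness(toy_table(m), "feature", 0.70)$values), 0L)
  m[1, 7] <- 0.5   # 60% missing row survives the >= rule
  expect_identical(nrow(filter_missingness(toy_table(m), "feature", 0.70)$values), 1L)

  m2 <- noise_matrix(100, 2, seed = 3)
  m2[1:71, 1] <- NA  # 71% blank column dropped (strict >)
  m2[1:70, 2] <- NA  # 70% blank column kept
  kept <- filter_missingness(toy_table(m2), "sample", 0.70)
  expect_identical(colnames(kept$values), colnames(m2)[2])

  complete <- toy_table(noise_matrix(5, 5, seed = 4))
  expect_identical(filter_missingness(complete, "feature", 0.7)$values,
                   complete$values)
})

test_that("filters are idempotent", {
  m <- noise_matrix(50, 20, seed = 5)
  m[sample(length(m), 300)] <- NA
  tab <- toy_table(m)
  once <- filter_missingness(tab, "feature", 0.3)
  twice <- filter_missingness(once, "feature", 0.3)
  expect_identical(once$values, twice$values)
  counts <- setNames(sample(1:5, 50, replace = TRUE), rownames(m))
  tab2 <- toy_table(m, counts = counts)
  p_once <- filter_min_peptides(tab2, 2)
  expect_identical(filter_min_peptides(p_once, 2)$values, p_once$values)
})

test_that("site collapse enforces the strict confidence rule and aggregates", {
  long <- data.frame(
    peptide_sequence = c("p1", "p2", "p3", "p4"),
    protein_id = c("RAB12", "RAB12", "RAB12", "MON2"),
    ptm_position = c(106L, 106L, 106L, 205L),
    residue = "S",
    localization_confidence = c(0.99, 0.90, 0.74, 0.76),
    sample_id = "s1",
    intensity = c(100, 80, 999, 55), stringsAsFactors = FALSE)
  out <- collapse_ptm_sites(long, 0.75)
  # 0.74 discarded, 0.76 retained; two surviving RAB12 peptides -> max
  expect_identical(sort(rownames(out$values)), c("MON2_S205", "RAB12_S106"))
  expect_identical(out$values["RAB12_S106", "s1"], 100)
  expect_identical(out$values["MON2_S205", "s1"], 55)
  # boundary: exactly at the cutoff is discarded
  expect_identical(nrow(collapse_ptm_sites(long[3, ], 0.75)$values), 0L)
  # alternative aggregations
  expect_identical(collapse_ptm_sites(long, 0.75, "sum")$values["RAB12_S106", "s1"], 180)
  expect_identical(collapse_ptm_sites(long, 0.75, "mean")$values["RAB12_S106", "s1"], 90)
  # empty input
  expect_identical(dim(collapse_ptm_sites(long[0, ], 0.75)$values), c(0L, 0L))
})

test_that("KNN imputation uses the nearest feature and preserves observed cells", {
  # 3x3 toy, one missing cell, k = 1: hand-computed distances
  m <- matrix(c(1, 2, 3,
                1.1, 2.1, NA,
                10, 10, 10), 3, 3, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), c("c1", "c2", "c3")))
  # d(r2, r1) over shared cols = sqrt(mean(c(0.1, 0.1)^2)) = 0.1
  # d(r2, r3) = sqrt(mean(c(8.9, 7.9)^2)) = 8.415
  out <- knn_impute(intensity_table(m, "log2"), k = 1)
  expect_identical(out$values["r2", "c3"], m["r1", "c3"])
  expect_identical(out$values[!is.na(m)], m[!is.na(m)])

  # complete table -> identity
  tab <- intensity_table(noise_matrix(20, 10, seed = 6), "log2")
  expect_identical(knn_impute(tab, 5), tab)

  # observed entries are bit-identical on a larger random instance
  m2 <- noise_matrix(60, 15, seed = 7)
  mask <- matrix(runif(length(m2)) < 0.1, nrow(m2))
  m2[mask] <- NA
  obs <- !is.na(m2)
  imp <- knn_impute(intensity_table(m2, "log2"), 10)
  expect_identical(imp$values[obs], m2[obs])
  expect_false(anyNA(imp$values))

  # k clamped with a message
  small <- noise_matrix(3, 4, seed = 8); small[1, 2] <- NA
  expect_message(knn_impute(intensity_table(small, "log2"), 10), "clamped")

  # a fully unobservable row errors with its name
  m3 <- noise_matrix(3, 3, seed = 9); m3[2, ] <- NA
  expect_error(knn_impute(intensity_table(m3, "log2"), 1), "F0002")
})

test_that("log2 transform validates domain and updates the scale tag", {
  m <- matrix(c(8, 1), 1, 2, dimnames = list("f", c("a", "b")))
  out <- log2_transform(intensity_table(m, "raw"))
  expect_identical(out$values[1, ], c(a = 3, b = 0))
  expect_identical(out$scale, "log2")
  expect_error(log2_transform(out), class = "domain_error")  # wrong scale
  # non-positive intensities are rejected on the raw scale
  expect_error(intensity_table(matrix(0, 1, 1, dimnames = list("f", "s")),
                               "raw"),
               class = "format_error")
})

test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("f1", "f2", "f3"), c("a", "b")))
  out <- quantile_normalize(intensity_table(m, "log2"))
  expect_equal(out$values[, "a"], c(f1 = 2.5, f2 = 3.5, f3 = 4.5))
  expect_equal(out$values[, "b"], c(f1 = 2.5, f2 = 3.5, f3 = 4.5))
  expect_identical(out$scale, "normalized")

  # already-identical multisets are unchanged up to within-column order
  m2 <- cbind(a = c(3, 1, 2), b = c(1, 2, 3))
  rownames(m2) <- c("f1", "f2", "f3")
  out2 <- quantile_normalize(intensity_table(m2, "log2"))
  expect_equal(sort(out2$values[, 1]), sort(m2[, 1]))
  expect_equal(out2$values, m2)

  # single column -> identity
  one <- intensity_table(m[, 1, drop = FALSE], "log2")
  expect_equal(quantile_normalize(one)$values, one$values)

  # property: identical sorted values across columns, random matrix
  tab <- intensity_table(noise_matrix(100, 12, seed = 10), "log2")
  qn <- quantile_normalize(tab)$values
  ref <- unname(sort(qn[, 1]))
  for (j in 2:ncol(qn))
    expect_equal(unname(sort(qn[, j])), ref, tolerance = 1e-12)
})

test_that("quantile normalization matches limma on tie-free data", {
  skip_if_not_installed("limma")
  m <- noise_matrix(80, 6, seed = 11)
  ours <- quantile_normalize(intensity_table(m, "log2"))$values
  theirs <- limma::normalizeQuantiles(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("phospho preprocessing runs stages in the documented order", {
  sheet <- small_cohort(seed = 12)
  long <- generate_phospho_longform(sheet, 80, default_truth(12))
  out <- preprocess_phospho(long, pipeline_config())
  expect_identical(out$scale, "normalized")
  expect_false(anyNA(out$values))
  audit <- attr(out, "audit")
  expect_true(audit$row_filter <= audit$collapsed_sites)
  # every surviving row satisfies the 30% rule pre-imputation
  collapsed <- collapse_ptm_sites(long, 0.75)
  frac <- rowMeans(is.na(collapsed$values))
  expect_true(all(rownames(out$values) %in%
                    rownames(collapsed$values)[frac < 0.30]))
})
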