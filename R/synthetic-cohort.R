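# Seed-reproducible synthetic cohort generator. Emulates the processed
# data structure of a PBMC DIA-MS study of LRRK2 mutation carriers:
# a six-group sample sheet (G2019S / R1441G, PD-manifesting and
# non-manifesting carriers, idiopathic PD, controls) across three
# recruiting centres, a wide proteome pivot table with per-feature
# peptide counts, a long-form phospho-peptide report with localization
# confidences, intensity-dependent missingness, and UPDRS-III motor
# scores with planted feature correlations. Planted effects are recorded
# in a truth object so recovery tests never re-derive them from code.

#' Cohort group sizes
#'
#' Reference group sizes for the six study groups: `enrolled` is the
#' clinical cohort as recruited, `post_qc` the sample counts remaining
#' after mass-spectrometry quality control (the sizes differential
#' analyses are run on, and the generator's defaults).
#'
#' @return A list with named integer vectors `enrolled` and `post_qc`.
#' @export
cohort_group_sizes <- function() {
  list(
    enrolled = c(G2019S_L2PD = 37L, G2019S_L2NMC = 27L, R1441G_L2PD = 14L,
                 R1441G_L2NMC = 11L, iPD = 40L, CTRL = 45L),
    post_qc = c(G2019S_L2PD = 32L, G2019S_L2NMC = 22L, R1441G_L2PD = 13L,
                R1441G_L2NMC = 7L, iPD = 39L, CTRL = 42L)
  )
}

#' Study reference counts
#'
#' Printed reference numbers used as pipeline inputs and for
#' consistency checks: the recruited and post-QC group sizes, the
#' feature inventory quantified per layer, and the composition of the
#' published 18-feature G2019S classifier (15 proteins + 3
#' phospho-sites).
#'
#' @return A nested list of named integer vectors.
#' @export
study_reference <- function() {
  list(
    group_sizes = cohort_group_sizes(),
    features_quantified = c(proteins = 3815L, phospho_sites = 10288L),
    signature_composition = c(proteins = 15L, phospho_sites = 3L,
                              signature_size = 18L)
  )
}

# Per-group demographic parameters: centre allocation (post-QC),
# age mean/sd, male fraction, UPDRS-III and MoCA baselines.
group_demographics <- function() {
  list(
    G2019S_L2PD  = list(centres = c(B = 15, S = 17, D = 0),  age = c(63.5, 9.1),
                        male = 20 / 37, updrs3 = c(16.0, 9.7), moca = c(24.3, 4.5)),
    G2019S_L2NMC = list(centres = c(B = 9, S = 13, D = 0),   age = c(56.7, 14.1),
                        male = 18 / 27, updrs3 = c(1.0, 1.6),  moca = c(25.4, 6.6)),
    R1441G_L2PD  = list(centres = c(B = 1, S = 0, D = 12),   age = c(67.1, 9.5),
                        male = 7 / 14,  updrs3 = c(19.8, 12.0), moca = c(23.2, 5.5)),
    R1441G_L2NMC = list(centres = c(B = 2, S = 0, D = 5),    age = c(61.1, 5.5),
                        male = 4 / 11,  updrs3 = c(1.2, 2.1),  moca = c(28.6, 2.0)),
    iPD          = list(centres = c(B = 19, S = 10, D = 10), age = c(67.3, 7.7),
                        male = 30 / 40, updrs3 = c(19.7, 13.2), moca = c(25.6, 3.7)),
    CTRL         = list(centres = c(B = 23, S = 10, D = 9),  age = c(60.0, 10.9),
                        male = 18 / 45, updrs3 = c(1.2, 2.2),  moca = c(27.5, 3.2))
  )
}

PATIENT_GROUPS <- c("G2019S_L2PD", "R1441G_L2PD", "iPD")

#' Default planted truth for the synthetic cohort
#'
#' Encodes the planted structure the generator injects: per-group log2
#' shifts for a handful of proteins and phospho-sites (magnitudes taken
#' from reported LRRK2 PBMC effect sizes, e.g. a hyperphosphorylated
#' RAB12 Ser106 site at log2FC ~0.95 in G2019S carriers and shared
#' down-regulated endolysosomal proteins), the set of six features
#' designed to be class-informative for the G2019S signature search, one
#' planted Spearman link between a feature and UPDRS-III, missingness
#' parameters per omic layer, and the base intensity distribution.
#'
#' @param seed Master seed stored with the truth.
#' @return A list of class `synthetic_truth`.
#' @export
default_truth <- function(seed = 1L) {
  structure(list(
    planted_protein_effects = list(
      ATIC  = c(G2019S_L2PD = -0.97, G2019S_L2NMC = -0.80),
      RAB9A = c(G2019S_L2PD = -1.17, G2019S_L2NMC = -0.40),
      LAMP1 = c(G2019S_L2PD = -1.32, G2019S_L2NMC = -1.10),
      SCLY  = c(G2019S_L2PD = -1.58, G2019S_L2NMC = 0.00)
    ),
    planted_phospho_effects = list(
      RAB12_S106 = c(G2019S_L2PD = 0.97, G2019S_L2NMC = 0.92),
      MON2_S205  = c(G2019S_L2PD = 0.00, G2019S_L2NMC = 1.25)
    ),
    informative_features = c("ATIC", "RAB9A", "LAMP1", "SCLY",
                             "RAB12_S106", "MON2_S205"),
    planted_score_links = c(RAB12_S106 = 0.8),
    missingness_params = list(
      proteome = list(mar_rate = 0.05, mnar_slope = 1.0,
                      mnar_midpoint_q = 0.10, mnar_max = 0.30),
      phospho  = list(mar_rate = 0.10, mnar_slope = 1.0,
                      mnar_midpoint_q = 0.10, mnar_max = 0.35)
    ),
    base_distribution = c(log2_mean = 20, log2_sd = 2),
    residual_sd = 0.7,
    single_peptide_frac = 0.15,
    low_confidence_frac = 0.20,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' A truth object with no planted structure (null cohort)
#' @inheritParams default_truth
#' @return A `synthetic_truth` with empty effect and link maps.
#' @export
null_truth <- function(seed = 1L) {
  truth <- default_truth(seed)
  truth$planted_protein_effects <- list()
  truth$planted_phospho_effects <- list()
  truth$informative_features <- character()
  truth$planted_score_links <- numeric(0)
  truth
}

#' Write / read a truth object as JSON
#' @param truth A `synthetic_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_protein_effects <- lapply(x$planted_protein_effects, unlist)
  x$planted_phospho_effects <- lapply(x$planted_phospho_effects, unlist)
  x$planted_score_links <- unlist(x$planted_score_links) %||% numeric(0)
  structure(x, class = "synthetic_truth")
}

#' Generate a synthetic sample sheet
#'
#' Draws a cohort with the requested number of samples per group, centre
#' allocation following the study's post-QC split (proportionally scaled
#' for non-default sizes), and group-specific age, sex, UPDRS-III and
#' MoCA distributions. Deterministic given `seed`.
#'
#' @param group_sizes Named integer vector of samples per group; default
#'   the post-QC sizes from [cohort_group_sizes()].
#' @param seed Integer seed.
#' @return A `sample_sheet` data frame.
#' @export
generate_cohort <- function(group_sizes = cohort_group_sizes()$post_qc,
                            seed = 1L) {
  bad <- setdiff(names(group_sizes), GROUP_LEVELS)
  if (length(bad))
    abort_phosphosig(sprintf("unknown group(s): %s", paste(bad, collapse = ", ")),
                     "invalid_request")
  if (any(group_sizes < 0) || sum(group_sizes) == 0)
    abort_phosphosig("group sizes must be non-negative with a non-empty cohort",
                     "invalid_request")
  demo <- group_demographics()
  withr::with_seed(derive_seed(seed, 1L), {
    rows <- lapply(names(group_sizes), function(g) {
      n <- group_sizes[[g]]
      if (n == 0) return(NULL)
      d <- demo[[g]]
      # centre allocation: largest-remainder rounding of the reference split
      props <- d$centres / sum(d$centres)
      alloc <- floor(props * n)
      rem <- n - sum(alloc)
      if (rem > 0) {
        extra <- order(props * n - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
      }
      centre <- rep(names(alloc), alloc)
      data.frame(
        group = g,
        centre = centre,
        sex = ifelse(runif(n) < d$male, "M", "F"),
        age = round(pmax(18, rnorm(n, d$age[1], d$age[2]))),
        updrs3 = pmax(0L, as.integer(round(rnorm(n, d$updrs3[1], d$updrs3[2])))),
        moca = pmin(30L, pmax(0L, as.integer(round(rnorm(n, d$moca[1], d$moca[2]))))),
        stringsAsFactors = FALSE
      )
    })
    sheet <- do.call(rbind, rows)
    sheet$sample_id <- sprintf("%s%03d", sheet$centre, seq_len(nrow(sheet)))
    validate_sample_sheet(sheet[, SHEET_COLS])
  })
}

# Expand a planted-effect map into a per-feature x per-group shift matrix.
effect_matrix <- function(effects, features, groups) {
  m <- matrix(0, nrow = length(features), ncol = length(groups),
              dimnames = list(features, groups))
  for (f in names(effects)) {
    eff <- effects[[f]]
    missing_g <- setdiff(names(eff), groups)
    if (length(missing_g))
      abort_phosphosig(sprintf(
        "planted effect on '%s' references group(s) absent from sheet: %s",
        f, paste(missing_g, collapse = ", ")), "invalid_request")
    m[f, names(eff)] <- eff
  }
  m
}

#' Generate a complete synthetic proteome table
#'
#' Log-normal baseline intensities (log2 mean/sd from the truth's base
#' distribution), planted per-group log2 shifts applied to the planted
#' proteins, and per-feature peptide counts drawn from a shifted
#' geometric with a configurable single-peptide fraction. Planted
#' features are given >= 2 peptides and an upper-range baseline
#' abundance, reflecting that headline biomarkers are robustly
#' quantified. The table is complete; use [inject_missingness()] to add
#' the missing mask.
#'
#' @param sheet A `sample_sheet`.
#' @param n_features Total number of proteins (>= number planted).
#' @param truth A `synthetic_truth`.
#' @return An [intensity_table()] on the raw scale with peptide counts.
#' @export
generate_proteome <- function(sheet, n_features = 800, truth = default_truth()) {
  planted <- names(truth$planted_protein_effects)
  if (n_features < length(planted))
    abort_phosphosig("n_features smaller than the number of planted proteins",
                     "invalid_request")
  features <- c(planted,
                sprintf("PROT%04d", seq_len(n_features - length(planted))))
  groups <- unique(sheet$group)
  eff <- effect_matrix(truth$planted_protein_effects, features, groups)
  base <- truth$base_distribution
  withr::with_seed(derive_seed(truth$seed, 2L), {
    mu <- rnorm(n_features, base[["log2_mean"]], base[["log2_sd"]])
    mu[seq_along(planted)] <- rnorm(length(planted), base[["log2_mean"]] + 1, 0.5)
    feat_sd <- runif(n_features, 0.7, 1.3) * truth$residual_sd
    n <- nrow(sheet)
    log2v <- matrix(mu, n_features, n) +
      eff[, sheet$group, drop = FALSE] +
      matrix(rnorm(n_features * n), n_features, n) * feat_sd
    dimnames(log2v) <- list(features, sheet$sample_id)
    counts <- 1L + rgeom(n_features, prob = truth$single_peptide_frac)
    counts[seq_along(planted)] <- pmax(2L, counts[seq_along(planted)])
    names(counts) <- features
    intensity_table(2^log2v, scale = "raw", peptide_counts = counts)
  })
}

# Parse "RAB12_S106"-style site ids into protein / residue / position.
parse_site_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_([STY])(\\d+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    abort_phosphosig(sprintf("unparseable site id(s): %s",
                             paste(ids[bad], collapse = ", ")), "invalid_request")
  data.frame(protein_id = vapply(m, `[`, "", 2L),
             residue = vapply(m, `[`, "", 3L),
             ptm_position = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Generate a long-form synthetic phospho-peptide report
#'
#' Each site contributes one or two peptide records per sample. Each
#' peptide carries a localization confidence drawn from a two-component
#' mixture so that a configurable fraction of peptides falls at or below
#' the 0.75 collapse cutoff; planted sites always carry at least one
#' confidently localized peptide. Planted per-group log2 shifts are
#' applied on the site's underlying intensity.
#'
#' @param sheet A `sample_sheet`.
#' @param n_sites Total number of phospho-sites (>= number planted).
#' @param truth A `synthetic_truth`.
#' @return A `phospho_long` data frame.
#' @export
generate_phospho_longform <- function(sheet, n_sites = 1500,
                                      truth = default_truth()) {
  planted <- names(truth$planted_phospho_effects)
  if (n_sites < length(planted))
    abort_phosphosig("n_sites smaller than the number of planted sites",
                     "invalid_request")
  if (n_sites == 0) {
    return(validate_phospho_long(data.frame(
      peptide_sequence = character(), protein_id = character(),
      ptm_position = integer(), residue = character(),
      localization_confidence = numeric(), sample_id = character(),
      intensity = numeric(), stringsAsFactors = FALSE)))
  }
  withr::with_seed(derive_seed(truth$seed, 3L), {
    n_rand <- n_sites - length(planted)
    rand_sites <- if (n_rand > 0) {
      data.frame(protein_id = sprintf("PP%05d", seq_len(n_rand)),
                 residue = sample(c("S", "T", "Y"), n_rand, replace = TRUE,
                                  prob = c(0.80, 0.15, 0.05)),
                 ptm_position = sample.int(1000L, n_rand, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else NULL
    sites <- rbind(if (length(planted)) parse_site_id(planted), rand_sites)
    site_ids <- paste0(sites$protein_id, "_", sites$residue, sites$ptm_position)
    groups <- unique(sheet$group)
    eff <- effect_matrix(truth$planted_phospho_effects, site_ids, groups)
    base <- truth$base_distribution
    mu <- rnorm(n_sites, base[["log2_mean"]], base[["log2_sd"]])
    mu[seq_along(planted)] <- rnorm(length(planted), base[["log2_mean"]] + 1, 0.5)
    site_sd <- runif(n_sites, 0.7, 1.3) * truth$residual_sd
    n_pep <- 1L + rbinom(n_sites, 1L, 0.25)

    # one confidence per peptide (localization is a property of the
    # peptide-spectrum evidence, held fixed across samples here)
    pep_site <- rep(seq_len(n_sites), n_pep)
    pep_idx <- sequence(n_pep)
    n_total_pep <- length(pep_site)
    low <- runif(n_total_pep) < truth$low_confidence_frac
    conf <- ifelse(low, runif(n_total_pep, 0.20, 0.75),
                   runif(n_total_pep, 0.755, 1.0))
    first_planted <- pep_idx == 1L & pep_site <= length(planted)
    conf[first_planted] <- runif(sum(first_planted), 0.85, 1.0)
    pep_offset <- rnorm(n_total_pep, 0, 0.5)
    pep_seq <- sprintf("PEP_%s_%d", site_ids[pep_site], pep_idx)

    ns <- nrow(sheet)
    row_pep <- rep(seq_len(n_total_pep), each = ns)
    row_sample <- rep(seq_len(ns), times = n_total_pep)
    row_site <- pep_site[row_pep]
    log2v <- mu[row_site] + pep_offset[row_pep] +
      eff[cbind(row_site, match(sheet$group[row_sample], groups))] +
      rnorm(length(row_pep)) * site_sd[row_site]
    validate_phospho_long(data.frame(
      peptide_sequence = pep_seq[row_pep],
      protein_id = sites$protein_id[row_site],
      ptm_position = sites$ptm_position[row_site],
      residue = sites$residue[row_site],
      localization_confidence = conf[row_pep],
      sample_id = sheet$sample_id[row_sample],
      intensity = 2^log2v,
      stringsAsFactors = FALSE))
  })
}

#' Inject MAR and intensity-dependent (MNAR) missingness
#'
#' Missing-at-random cells are removed uniformly at `mar_rate`.
#' Missing-not-at-random cells are removed with probability
#' `mnar_max * plogis(-mnar_slope * (log2(x) - midpoint))`, a logistic
#' decreasing in intensity with midpoint at the `mnar_midpoint_q`
#' quantile of the log2 intensities — emulating low-abundance dropout.
#' Setting `mnar_slope = 0` or `mnar_max = 0` disables the MNAR
#' component. The attribute `expected_missing` records the expected
#' overall missing fraction.
#'
#' @param table An [intensity_table()].
#' @param params List with `mar_rate`, `mnar_slope`, `mnar_midpoint_q`,
#'   `mnar_max`.
#' @param seed Integer seed.
#' @return The table with `NA` cells injected.
#' @export
inject_missingness <- function(table, params, seed = 1L) {
  stopifnot(inherits(table, "intensity_table"))
  mar <- params$mar_rate %||% 0
  mnar_slope <- params$mnar_slope %||% 0
  mnar_q <- params$mnar_midpoint_q %||% 0.10
  mnar_max <- params$mnar_max %||% 0
  if (mar < 0 || mar > 1 || mnar_max < 0 || mnar_max > 1)
    abort_phosphosig("missingness rates must lie in [0, 1]", "invalid_request")
  v <- table$values
  log2v <- if (table$scale == "raw") log2(v) else v
  p <- matrix(0, nrow(v), ncol(v))
  if (mnar_max > 0 && mnar_slope > 0) {
    mid <- quantile(log2v, mnar_q, na.rm = TRUE, names = FALSE)
    p <- mnar_max * plogis(-mnar_slope * (log2v - mid))
  }
  expected <- mar + (1 - mar) * mean(p, na.rm = TRUE)
  withr::with_seed(derive_seed(seed, 4L), {
    drop <- (runif(length(v)) < mar) | (runif(length(v)) < p)
    v[drop] <- NA_real_
  })
  out <- intensity_table(v, scale = table$scale,
                         peptide_counts = table$peptide_counts)
  attr(out, "expected_missing") <- expected
  out
}

#' Generate UPDRS-III scores with planted feature correlations
#'
#' Motor severity is modelled as a group baseline (mild scores in
#' patient groups, near-zero in non-manifesting carriers and controls)
#' plus a weighted contribution of the planted link features plus noise,
#' then mapped through a strictly increasing softplus to non-negative
#' integers. The feature weights are calibrated per seed by root-finding
#' so that each planted link's realized Spearman correlation matches its
#' target.
#'
#' @param sheet A `sample_sheet`.
#' @param table A complete [intensity_table()] containing the linked
#'   features (raw or log2 scale).
#' @param truth A `synthetic_truth`; `planted_score_links` maps feature
#'   ids to target Spearman rho values in (-1, 1).
#' @param seed Integer seed.
#' @return The sheet with its `updrs3` column replaced.
#' @export
generate_clinical_scores <- function(sheet, table, truth = default_truth(),
                                     seed = truth$seed) {
  links <- truth$planted_score_links
  demo <- group_demographics()
  alpha <- vapply(sheet$group, function(g) demo[[g]]$updrs3[1], 0)
  sigma <- 3
  withr::with_seed(derive_seed(seed, 5L), {
    eps <- rnorm(nrow(sheet))
    if (length(links) == 0) {
      sheet$updrs3 <- as.integer(round(softplus(alpha + sigma * eps)))
      return(sheet)
    }
    missing_f <- setdiff(names(links), feature_ids(table))
    if (length(missing_f))
      abort_phosphosig(sprintf("planted score link(s) to missing feature(s): %s",
                               paste(missing_f, collapse = ", ")),
                       "invalid_request")
    if (any(abs(links) >= 1))
      abort_phosphosig("target rho must lie in (-1, 1)", "invalid_request")
    v <- table$values[names(links), sheet$sample_id, drop = FALSE]
    if (table$scale == "raw") v <- log2(v)
    Z <- scale(t(v))  # samples x links, standardized
    beta <- numeric(length(links))
    score_of <- function(b) {
      as.integer(round(softplus(alpha + as.vector(Z %*% b) + sigma * eps)))
    }
    for (pass in 1:2) {
      for (j in seq_along(links)) {
        target <- links[[j]]
        gap <- function(bj) {
          b <- beta; b[j] <- bj
          suppressWarnings(cor(score_of(b), Z[, j], method = "spearman")) - target
        }
        lo <- if (target >= 0) 0 else -400
        hi <- if (target >= 0) 400 else 0
        beta[j] <- if (gap(lo) * gap(hi) > 0) {
          if (abs(gap(lo)) < abs(gap(hi))) lo else hi
        } else {
          uniroot(gap, c(lo, hi), tol = 1e-2)$root
        }
      }
    }
    sheet$updrs3 <- score_of(beta)
  })
  sheet
}
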