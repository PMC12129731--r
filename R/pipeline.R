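# Orchestration: simulate -> preprocess -> differential -> ANOVA ->
# signature search -> evaluation -> clinical correlation, with a run
# manifest of per-stage row counts and seeds.

#' Simulate a full synthetic cohort dataset
#'
#' Convenience wrapper generating the sample sheet, complete proteome
#' and phospho tables, injecting missingness and calibrating clinical
#' scores, all from one master seed.
#'
#' @param group_sizes Samples per group (default post-QC sizes).
#' @param n_proteins,n_sites Feature counts (defaults 800 / 1500).
#' @param truth A `synthetic_truth`; its seed is overridden by `seed`.
#' @param seed Master seed.
#' @return List with `sheet`, `proteome` (with missingness), `phospho`
#'   (long form), and `truth`.
#' @export
simulate_cohort_data <- function(group_sizes = cohort_group_sizes()$post_qc,
                                 n_proteins = 800, n_sites = 1500,
                                 truth = default_truth(seed), seed = 1L) {
  truth$seed <- as.integer(seed)
  sheet <- generate_cohort(group_sizes, seed = seed)
  proteome <- generate_proteome(sheet, n_proteins, truth)
  sheet <- generate_clinical_scores(sheet, proteome_and_phospho_scores_table(
    proteome, sheet, n_sites, truth), truth, seed)
  phospho <- generate_phospho_longform(sheet, n_sites, truth)
  proteome_miss <- inject_missingness(proteome,
                                      truth$missingness_params$proteome,
                                      seed = derive_seed(seed, 11L))
  list(sheet = sheet, proteome = proteome_miss, proteome_complete = proteome,
       phospho = phospho, truth = truth)
}

# Clinical-score calibration needs the complete values of every linked
# feature; links may point at proteins or phospho-sites, so build a
# small combined table of just the linked features.
proteome_and_phospho_scores_table <- function(proteome, sheet, n_sites, truth) {
  links <- names(truth$planted_score_links)
  if (!length(links)) return(proteome)
  missing_links <- setdiff(links, feature_ids(proteome))
  if (!length(missing_links)) return(proteome)
  long <- generate_phospho_longform(sheet, n_sites, truth)
  site_tab <- collapse_ptm_sites(long, 0)  # complete: all evidence, max
  still_missing <- setdiff(missing_links, feature_ids(site_tab))
  if (length(still_missing))
    abort_phosphosig(sprintf("planted score link(s) to missing feature(s): %s",
                             paste(still_missing, collapse = ", ")),
                     "invalid_request")
  combined <- rbind(proteome$values,
                    site_tab$values[missing_links, sample_ids(proteome),
                                    drop = FALSE])
  intensity_table(combined, scale = "raw")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or loading of the provided inputs),
#' preprocessing of both omic layers, moderated differential testing for
#' every configured contrast, the ANOVA screen on the G2019S classes,
#' the MCTS signature search with refinement and evaluation, and the
#' clinical severity correlation of differential hits. Returns all
#' results plus a run manifest; optionally writes result tables.
#'
#' @param config A [pipeline_config()].
#' @param inputs `"simulate"` (default) or a list with `sheet`,
#'   `proteome` ([intensity_table()]) and `phospho` (`phospho_long`).
#' @param contrasts Named list of [contrast()]s (default
#'   [standard_contrasts()] filtered to groups present).
#' @param stages Stages to run, a subset of
#'   `c("preprocess", "differential", "anova", "signature", "correlate")`.
#' @param signature_classes Class labels for the signature search
#'   (default the G2019S classes and controls).
#' @param max_candidates Cap on the MCTS candidate pool, taken as the
#'   top features by ANOVA F after RFE (default 10; keeps the subset
#'   lattice tractable).
#' @param outdir Optional output directory for result TSVs.
#' @param sim_args List passed to [simulate_cohort_data()] when
#'   simulating (e.g. `n_proteins`, `n_sites`, `group_sizes`, `truth`).
#' @return A list of class `pipeline_run` with `results` per stage and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = "simulate",
                         contrasts = NULL,
                         stages = c("preprocess", "differential", "anova",
                                    "signature", "correlate"),
                         signature_classes = c("G2019S_L2PD", "G2019S_L2NMC",
                                               "CTRL"),
                         max_candidates = 10L,
                         outdir = NULL, sim_args = list()) {
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(seed = config$seed, stages = list())
  results <- list()
  stage_time <- function(start) round(proc.time()[["elapsed"]] - start, 2)

  # -- inputs ----------------------------------------------------------
  s0 <- proc.time()[["elapsed"]]
  if (identical(inputs, "simulate")) {
    data <- do.call(simulate_cohort_data,
                    c(sim_args, list(seed = config$seed)))
  } else {
    data <- inputs
    missing_cols <- setdiff(SHEET_COLS, names(data$sheet))
    if (length(missing_cols))
      abort_phosphosig(sprintf("sample sheet missing column(s): %s",
                               paste(missing_cols, collapse = ", ")),
                       "format_error")
  }
  sheet <- data$sheet
  manifest$stages$inputs <- list(
    n_samples = nrow(sheet),
    n_proteins = nrow(data$proteome$values),
    n_phospho_rows = nrow(data$phospho),
    wall_clock = stage_time(s0))

  # -- preprocessing ---------------------------------------------------
  if ("preprocess" %in% stages) {
    s0 <- proc.time()[["elapsed"]]
    proteome <- preprocess_proteome(data$proteome, config)
    phospho <- preprocess_phospho(data$phospho, config)
    results$proteome <- proteome
    results$phospho <- phospho
    manifest$stages$preprocess <- list(
      proteome = attr(proteome, "audit"),
      phospho = attr(phospho, "audit"),
      wall_clock = stage_time(s0))
  } else {
    proteome <- data$proteome
    phospho <- data$phospho
  }

  if (is.null(contrasts)) {
    present <- unique(sheet$group)
    contrasts <- Filter(function(ct)
      all(c(ct$group_a, ct$group_b) %in% present), standard_contrasts())
  }

  # -- differential ----------------------------------------------------
  if ("differential" %in% stages) {
    s0 <- proc.time()[["elapsed"]]
    results$differential <- list(
      proteome = lapply(contrasts, function(ct)
        moderated_t_test(proteome, sheet, ct,
                         config$log2fc_cutoff, config$adjp_cutoff)),
      phospho = lapply(contrasts, function(ct)
        moderated_t_test(phospho, sheet, ct,
                         config$log2fc_cutoff, config$adjp_cutoff)))
    manifest$stages$differential <- list(
      contrasts = names(contrasts),
      n_hits_proteome = vapply(results$differential$proteome,
                               function(d) sum(d$significant), 0L),
      n_hits_phospho = vapply(results$differential$phospho,
                              function(d) sum(d$significant), 0L),
      wall_clock = stage_time(s0))
  }

  # -- ANOVA screen ----------------------------------------------------
  if ("anova" %in% stages) {
    s0 <- proc.time()[["elapsed"]]
    results$anova <- list(
      proteome = anova_screen(proteome, sheet, signature_classes),
      phospho = anova_screen(phospho, sheet, signature_classes))
    manifest$stages$anova <- list(
      n_significant = sum(results$anova$proteome$p < config$anova_p_cutoff) +
        sum(results$anova$phospho$p < config$anova_p_cutoff),
      wall_clock = stage_time(s0))
  }

  # -- signature search ------------------------------------------------
  if ("signature" %in% stages) {
    s0 <- proc.time()[["elapsed"]]
    sig <- find_signature(proteome, phospho, sheet,
                          classes = signature_classes, config = config,
                          anova = results$anova,
                          max_candidates = max_candidates)
    results$signature <- sig
    manifest$stages$signature <- list(
      n_candidates = length(attr(sig, "candidates")),
      n_features = length(sig$features),
      balanced_accuracy = sig$balanced_accuracy,
      wall_clock = stage_time(s0))
  }

  # -- clinical correlation --------------------------------------------
  if ("correlate" %in% stages && "differential" %in% stages) {
    s0 <- proc.time()[["elapsed"]]
    hit_ids <- unique(unlist(lapply(
      c(results$differential$proteome, results$differential$phospho),
      function(d) d$feature_id[d$significant])))
    results$correlation <- if (length(hit_ids)) {
      combined <- combine_layers(proteome, phospho)
      correlate_features(combined, sheet,
                         features = intersect(hit_ids, feature_ids(combined)),
                         rho_cutoff = config$rho_cutoff,
                         adjp_cutoff = config$adjp_cutoff)
    } else NULL
    manifest$stages$correlate <- list(
      n_tested = length(hit_ids),
      n_passing = if (is.null(results$correlation)) 0L
                  else sum(results$correlation$passes),
      wall_clock = stage_time(s0))
  }

  manifest$total_wall_clock <- stage_time(t0)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(results$differential)) {
      for (layer in names(results$differential))
        for (nm in names(results$differential[[layer]]))
          write_results(results$differential[[layer]][[nm]],
                        file.path(outdir, sprintf("diff_%s_%s.tsv", layer, nm)))
    }
    if (!is.null(results$correlation))
      write_results(results$correlation, file.path(outdir, "correlation.tsv"))
    if (!is.null(results$signature))
      write_results(results$signature$evaluations %||%
                      data.frame(feature_id = results$signature$features),
                    file.path(outdir, "signature_subsets.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(results = results, manifest = manifest, sheet = sheet),
            class = "pipeline_run")
}

# Concatenate proteome and site-level phospho tables over the shared
# samples (ids are disjoint by construction: proteins vs PROTEIN_<site>).
combine_layers <- function(proteome, phospho) {
  shared <- intersect(sample_ids(proteome), sample_ids(phospho))
  intensity_table(rbind(proteome$values[, shared, drop = FALSE],
                        phospho$values[, shared, drop = FALSE]),
                  scale = "normalized")
}

#' Signature discovery on preprocessed tables
#'
#' Builds the combined feature matrix for the requested classes, applies
#' the ANOVA pre-selection and backwards RFE, caps the MCTS candidate
#' pool at the top `max_candidates` features by screen F statistic, runs
#' the MCTS search with frequency-based refinement, and evaluates the
#' final subset (one-vs-rest AUC, PCA).
#'
#' @param proteome,phospho Preprocessed complete [intensity_table()]s.
#' @param sheet A `sample_sheet`.
#' @param classes Class labels (groups) to discriminate.
#' @param config A [pipeline_config()]; `config$mcts` drives the search.
#' @param anova Optional precomputed screens (list with `proteome`,
#'   `phospho`) to avoid recomputation.
#' @param max_candidates Candidate-pool cap (default 10).
#' @return A `signature_result` with evaluation fields; candidates in
#'   attribute `candidates`.
#' @export
find_signature <- function(proteome, phospho, sheet,
                           classes = c("G2019S_L2PD", "G2019S_L2NMC", "CTRL"),
                           config = pipeline_config(), anova = NULL,
                           max_candidates = 10L) {
  combined <- combine_layers(proteome, phospho)
  use <- sheet$sample_id[sheet$group %in% classes]
  use <- intersect(use, sample_ids(combined))
  X <- t(combined$values[, use, drop = FALSE])
  y <- sheet$group[match(use, sheet$sample_id)]
  scr <- anova_screen_matrix(t(X), y)
  anova_p <- setNames(scr$p, scr$feature_id)
  spec <- classifier_spec("svm", kernel = "linear", cost = 1)
  cfg <- config$mcts
  cfg$seed <- config$seed
  selected <- rfecv_select(X, y, spec, n_folds = 5L, seed = config$seed,
                           anova_p = anova_p,
                           anova_p_cutoff = config$anova_p_cutoff)
  Fstat <- setNames(scr$F, scr$feature_id)[selected]
  candidates <- selected[order(-Fstat, selected, method = "radix")]
  candidates <- candidates[seq_len(min(max_candidates, length(candidates)))]
  # search rewards use 2x repeated CV: subset selection is much more
  # sensitive to fold-assignment noise than a single fixed evaluation
  search <- mcts_feature_search(X, y, candidates, spec, cfg, n_folds = 5L,
                                n_reps = 2L)
  refined <- refine_signature(search, X, y, candidates, spec, cfg,
                              n_folds = 5L, n_reps = 2L)
  out <- evaluate_signature(X, y, refined$features, spec, n_folds = 5L,
                            seed = config$seed)
  out$qualifying_subsets <- refined$qualifying_subsets
  out$search_trace <- refined$search_trace
  out$evaluations <- refined$evaluations
  out$search_balanced_accuracy <- refined$balanced_accuracy
  attr(out, "candidates") <- candidates
  attr(out, "rfe_selected") <- selected
  out
}
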