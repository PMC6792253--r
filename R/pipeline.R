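#' Attach phenotype-match scores to every variant in a cohort
#'
#' For each case, scores every annotated gene against the patient's
#' phenotype terms by both methods — binary-vector cosine over the closed
#' ontology, and random walk with restart over the joint term-gene graph —
#' and annotates each variant with the best score among its overlapping
#' genes. The two scores enter the feature matrix as the `HPO_cosine` and
#' `PyxisMap` numeric features.
#'
#' @param variants Variant data.table (column `genes` as list, `case_id`).
#' @param cases data.table with `case_id` and list column `patient_terms`.
#' @param graph An `ontology_graph`.
#' @param annotations A `gene_annotation_map`.
#' @param rwr_cfg An [rwr_config()].
#' @return The variant table with `HPO_cosine` and `PyxisMap` columns added.
#' @export
score_cohort_phenotypes <- function(variants, cases, graph, annotations,
                                    rwr_cfg = rwr_config()) {
  v <- data.table::as.data.table(variants)
  gm <- .gene_vector_matrix(graph, annotations)
  g_norm <- sqrt(Matrix::colSums(gm^2))
  rwr <- build_rwr_graph(graph, annotations, rwr_cfg)
  dims <- setdiff(graph$terms, graph$roots)

  cos_col <- numeric(nrow(v))
  rwr_col <- numeric(nrow(v))
  idx_by_case <- split(seq_len(nrow(v)), v$case_id)
  terms_by_case <- stats::setNames(cases$patient_terms, cases$case_id)
  for (cid in names(idx_by_case)) {
    terms <- terms_by_case[[cid]]
    closed <- ancestor_closure(graph, terms)
    p <- as.numeric(dims %in% closed)
    p_norm <- sqrt(sum(p))
    denom <- p_norm * g_norm
    cos_scores <- as.numeric(Matrix::crossprod(gm, p))
    cos_scores <- ifelse(denom > 0, cos_scores / denom, 0)
    names(cos_scores) <- colnames(gm)
    rwr_tab <- rwr_scores(rwr, terms, rwr_cfg)
    i <- idx_by_case[[cid]]
    cos_col[i] <- vapply(v$genes[i], function(g) {
      s <- cos_scores[g]; s[is.na(s)] <- 0; max(s, 0)
    }, 0.0)
    rwr_col[i] <- vapply(v$genes[i], best_gene_score_per_variant, 0.0,
                         table = rwr_tab)
  }
  v$HPO_cosine <- cos_col
  v$PyxisMap <- rwr_col
  v
}

#' Run the whole prioritization pipeline on one cohort
#'
#' Executes, in order: cohort simulation (or ingestion), phenotype scoring,
#' clinical filtering, feature encoding, chronological train/test split
#' balanced on positives, univariate feature selection on the training rows,
#' per-family hyperparameter tuning by stratified cross-validation, final
#' fits, and evaluation of every family both as a classifier (ROC / PR) and
#' as a per-case ranker (median/mean rank and top-1/10/20 percentages,
#' stratified by ACMG class), alongside the two single-feature control
#' rankers (scaled CADD and the phenotype cosine score).
#'
#' @param spec A [cohort_spec()]; ignored when `cohort` is supplied.
#' @param cohort Optionally, a pre-built `synthetic_cohort` (or a list with
#'   the same elements assembled from files).
#' @param filter_cfg A [filter_config()]; defaults to the package defaults
#'   plus the cohort's blacklist.
#' @param feature_specs Feature spec list (default: the 95-column reference
#'   set).
#' @param grids Hyperparameter grids per family; default is the one-point
#'   grid of each family's defaults, which keeps a full run on a single CPU
#'   in the minutes range (see [default_grids()] for the full lattice).
#' @param families Which classifier families to run.
#' @param k_features Features kept by univariate selection.
#' @param k_folds CV folds during tuning.
#' @param rwr_cfg An [rwr_config()].
#' @param out_dir If non-NULL, report tables, curve points and a provenance
#'   JSON are written here.
#' @param verbose Log one line per stage.
#' @return Object of class `varprior_run`: the cohort, split, selection,
#'   per-family tuning records, models, test probabilities, curve and rank
#'   summaries, baseline rank summaries, and the report tables as
#'   data.frames.
#' @export
run_end_to_end <- function(spec = cohort_spec(), cohort = NULL,
                           filter_cfg = NULL,
                           feature_specs = reference_feature_specs(),
                           grids = default_grids(small = TRUE),
                           families = c("weighted_forest", "weighted_logistic",
                                        "balanced_forest",
                                        "undersampled_boost_ensemble"),
                           k_features = 20L, k_folds = 10L,
                           rwr_cfg = rwr_config(), out_dir = NULL,
                           verbose = TRUE) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec)
    .stage_log("simulate", cases = nrow(cohort$cases),
               variants = nrow(cohort$variants),
               positives = nrow(cohort$truth), verbose = verbose)
  } else {
    spec <- cohort$spec %||% spec
  }
  seed <- spec$seed
  if (is.null(filter_cfg)) {
    filter_cfg <- filter_config(blacklist = cohort$blacklist)
  }

  v <- score_cohort_phenotypes(cohort$variants, cohort$cases, cohort$graph,
                               cohort$annotations, rwr_cfg)
  .stage_log("score-phenotypes", variants = nrow(v), verbose = verbose)

  vf <- apply_clinical_filter(v, filter_cfg)
  rej <- attr(vf, "rejections")
  .stage_log("filter", kept = nrow(vf), rejected = sum(rej), verbose = verbose)

  fm <- assemble_feature_matrix(vf, feature_specs)
  .stage_log("featurize", rows = nrow(fm$x), columns = ncol(fm$x),
             verbose = verbose)

  pos_by_case <- tapply(fm$labels, fm$case_ids, sum)
  case_tab <- data.frame(case_id = names(pos_by_case),
                         n_positives = as.integer(pos_by_case))
  chron <- stats::setNames(cohort$cases$chron_order, cohort$cases$case_id)
  case_tab$chron_order <- chron[case_tab$case_id]
  split <- split_cases(case_tab)
  .stage_log("split", train_cases = length(split$train_cases),
             test_cases = length(split$test_cases),
             train_pos = split$train_positives,
             test_pos = split$test_positives, verbose = verbose)

  in_train <- fm$case_ids %in% split$train_cases
  fm_train <- subset_feature_matrix(fm, in_train)
  fm_test <- subset_feature_matrix(fm, !in_train)

  selection <- select_top_k(fm_train, k = k_features)
  .stage_log("select", kept = length(selection$selected), verbose = verbose)

  tuning <- list(); models <- list(); probs <- list()
  curve_summaries <- list(); rank_summaries <- list()
  for (fam in families) {
    gs <- grid_search(fam, grids[[fam]], fm_train, selection,
                      k_folds = k_folds, seed = seed)
    model <- train_final(gs$best, selection, fm_train)
    p <- predict_proba(model, fm_test)
    tuning[[fam]] <- gs$records
    models[[fam]] <- model
    probs[[fam]] <- p
    curve_summaries[[fam]] <- curves(p, fm_test$labels)
    rank_summaries[[fam]] <- rank_metrics(rank_cases_by_score(fm_test, p))
    .stage_log("train", family = fam,
               cv_f1 = sprintf("%.3f", max(gs$records$cv_f1_mean)),
               auroc = sprintf("%.4f", curve_summaries[[fam]]$auroc),
               verbose = verbose)
  }

  baselines <- list(
    CADD_scaled = rank_metrics(baseline_rankers(fm_test, "CADD_scaled")),
    HPO_cosine = rank_metrics(baseline_rankers(fm_test, "HPO_cosine"))
  )

  report <- .build_report(families, tuning, curve_summaries,
                          rank_summaries, baselines)
  run <- structure(list(
    spec = spec, cohort = cohort, filter_rejections = rej, split = split,
    selection = selection, tuning = tuning, models = models,
    fm_train = fm_train, fm_test = fm_test, probs = probs,
    curve_summaries = curve_summaries, rank_summaries = rank_summaries,
    baselines = baselines, report = report, seed = seed
  ), class = "varprior_run")
  if (!is.null(out_dir)) write_report(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.varprior_run <- function(x, ...) {
  cat(sprintf("varprior_run: seed %d, %d train / %d test cases\n",
              x$seed, length(x$split$train_cases), length(x$split$test_cases)))
  print(x$report$classifier_stats, row.names = FALSE)
  cat("\nmedian (mean) reported-variant rank:\n")
  print(x$report$rank_stats, row.names = FALSE)
  invisible(x)
}

# assemble the three report tables: classifier statistics, median/mean case
# ranks, and top-1/10/20 percentages, each stratified All/VUS/LP/Path
.build_report <- function(families, tuning, curve_summaries, rank_summaries,
                          baselines) {
  classifier_stats <- do.call(rbind, lapply(families, function(fam) {
    rec <- tuning[[fam]]
    best <- which.max(rec$cv_f1_mean)
    data.frame(
      classifier = fam,
      cv10_acc = sprintf("%.2f+-%.2f", rec$cv_balanced_accuracy_mean[best],
                         rec$cv_balanced_accuracy_sd[best]),
      auroc = round(curve_summaries[[fam]]$auroc, 4),
      auprc = round(curve_summaries[[fam]]$auprc, 4)
    )
  }))
  methods <- c(names(baselines), families)
  all_summaries <- c(baselines, rank_summaries[families])
  fmt_rank <- function(s, stratum) {
    row <- s[s$stratum == stratum, ]
    if (row$n == 0) return("-")
    sprintf("%.1f (%.2f)", row$median_rank, row$mean_rank)
  }
  fmt_top <- function(s, stratum) {
    row <- s[s$stratum == stratum, ]
    if (row$n == 0) return("-")
    sprintf("%.0f, %.0f, %.0f", row$top1, row$top10, row$top20)
  }
  rank_stats <- do.call(rbind, lapply(methods, function(m) {
    s <- all_summaries[[m]]
    data.frame(method = m,
               All = fmt_rank(s, "All"), VUS = fmt_rank(s, "VUS"),
               LP = fmt_rank(s, "LP"), Path = fmt_rank(s, "Path"))
  }))
  top_stats <- do.call(rbind, lapply(methods, function(m) {
    s <- all_summaries[[m]]
    data.frame(method = m,
               All = fmt_top(s, "All"), VUS = fmt_top(s, "VUS"),
               LP = fmt_top(s, "LP"), Path = fmt_top(s, "Path"))
  }))
  list(classifier_stats = classifier_stats, rank_stats = rank_stats,
       top_stats = top_stats)
}

#' Write a run's report tables, curve points and provenance to disk
#'
#' @param run A `varprior_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(run$report$classifier_stats, "classifier_stats.tsv")
  wt(run$report$rank_stats, "rank_stats.tsv")
  wt(run$report$top_stats, "top_stats.tsv")
  for (fam in names(run$curve_summaries)) {
    wt(round(run$curve_summaries[[fam]]$roc, 6), sprintf("roc_%s.tsv", fam))
    wt(round(run$curve_summaries[[fam]]$pr, 6), sprintf("pr_%s.tsv", fam))
  }
  provenance <- list(
    seed = run$seed,
    spec = unclass(run$spec),
    selected_features = run$selection$selected,
    model_fingerprints = lapply(run$models, `[[`, "fingerprint"),
    package_version = as.character(utils::packageVersion("varprior"))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
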