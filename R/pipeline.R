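#' Configuration of a full pipeline run
#'
#' Bundles the per-module configurations plus the global seed and the
#' train/test split used by the model stage.
#'
#' @param phantom A \code{\link{phantom_config}}.
#' @param preprocess A \code{\link{preprocess_config}}.
#' @param features A \code{\link{feature_config}}.
#' @param channels Feature channels per region (\code{"pet"}, \code{"ct"}
#'   or both).
#' @param split Training fraction of the stratified train/test split
#'   (default 0.8, mirroring the 175/44 cohort design).
#' @param selection_alpha,selection_cutoff,n_folds Selection cascade
#'   settings.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param seed Global seed.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(phantom = phantom_config(),
                       preprocess = preprocess_config(),
                       features = feature_config(),
                       channels = "pet",
                       split = 0.8,
                       selection_alpha = 0.05, selection_cutoff = 0.9,
                       n_folds = 10L, n_boot = 500L, seed = 7L) {
  stop_if(split <= 0 || split >= 1, "split fraction must be in (0, 1)")
  structure(list(phantom = phantom, preprocess = preprocess,
                 features = features, channels = channels, split = split,
                 selection_alpha = selection_alpha,
                 selection_cutoff = selection_cutoff,
                 n_folds = n_folds, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "run_config")
}

## Stratified train/test split of subject indices.
stratified_split <- function(labels, train_frac, seed) {
  set.seed(as.integer(seed))
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(train_frac * length(idx)))
    n_tr <- min(n_tr, length(idx) - 1L)
    if (n_tr > 0) train[idx[sample.int(length(idx), n_tr)]] <- TRUE
  }
  train
}

fit_and_report <- function(x_train, y_train, x_test, y_test, model_id,
                           n_boot, seed) {
  fit <- fit_extratrees(x_train, y_train, seed = seed)
  p_tr <- predict(fit, x_train)
  thr <- youden_threshold(p_tr, y_train)
  rep_tr <- evaluate(p_tr, y_train, prob_threshold = thr, n_boot = n_boot,
                     seed = seed, model_id = model_id, cohort = "training")
  p_te <- predict(fit, x_test)
  rep_te <- evaluate(p_te, y_test, prob_threshold = thr, n_boot = n_boot,
                     seed = seed, model_id = model_id, cohort = "testing")
  list(fit = fit, training = rep_tr, testing = rep_te)
}

#' Run the full habitat pipeline on a synthetic cohort
#'
#' Orchestrates phantom generation, preprocessing, habitat segmentation,
#' metabolic and spatial quantification, radiomic feature extraction,
#' the feature-selection cascade, Extra Trees habitat and whole-tumour
#' models, the univariate clinical logistic model, evaluation of all
#' three on a stratified held-out split, and the spatial-association
#' table. Identical configuration and seed reproduce identical outputs;
#' the returned manifest carries md5 hashes of every artifact written.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Optional output directory; when given, cohort tables,
#'   feature matrices, reports and the manifest are written there.
#' @return The run manifest (list): headline metrics for the three
#'   models, the spatial-association table, selection summaries, seeds and
#'   artifact hashes.
#' @export
run_habitat_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  cohort <- generate_cohort(config$phantom)
  message(sprintf("[phantom] %d subjects generated", length(cohort)))
  labels <- vapply(cohort, function(s) as.integer(s$pdl1_positive), 1L)
  stop_if(length(unique(labels)) < 2,
          "degenerate cohort: single PD-L1 class; increase n_subjects")

  prepped <- lapply(cohort, function(s) {
    pair <- preprocess_pair(subject_pair(s), config$preprocess)
    list(subject_id = s$subject_id, pair = pair)
  })
  message("[preprocess] done")

  spatial <- cohort_spatial(prepped)
  metab <- do.call(rbind, lapply(prepped, function(s) {
    map <- segment_habitats(s$pair)
    cbind(subject_id = s$subject_id, region_metabolics(s$pair, map))
  }))
  message("[habitats/metabolics] done")

  feats <- cohort_features(prepped, config$features,
                           channels = config$channels)
  message(sprintf("[radiomics] %d features x %d subjects",
                  ncol(feats) - 1L, nrow(feats)))

  train <- stratified_split(labels, config$split, config$seed)
  x_all <- feats[, -1, drop = FALSE]
  hab_cols <- grep("^habitat", names(x_all), value = TRUE)
  whole_cols <- grep("^whole_tumor", names(x_all), value = TRUE)

  run_branch <- function(cols, id) {
    xb <- x_all[, cols, drop = FALSE]
    ## drop constant columns and columns with missing values (regions too
    ## small to extract for some subject) before the cascade
    keep <- vapply(xb, function(c) !anyNA(c) && stats::sd(c) > 0,
                   logical(1))
    xb <- xb[, keep, drop = FALSE]
    stop_if(ncol(xb) == 0, "no usable features for model branch")
    sel <- select_features(xb[train, , drop = FALSE], labels[train],
                           alpha = config$selection_alpha,
                           cutoff = config$selection_cutoff,
                           n_folds = min(config$n_folds,
                                         min(table(labels[train]))),
                           seed = config$seed)
    chosen <- if (nrow(sel$stage3)) sel$stage3$feature else sel$stage2
    if (!length(chosen)) chosen <- names(xb)[seq_len(min(5, ncol(xb)))]
    list(selection = sel,
         models = fit_and_report(xb[train, chosen, drop = FALSE],
                                 labels[train],
                                 xb[!train, chosen, drop = FALSE],
                                 labels[!train], id,
                                 config$n_boot, config$seed))
  }
  habitat_branch <- run_branch(hab_cols, "habitat")
  whole_branch <- run_branch(whole_cols, "whole_tumor")
  message("[models] habitat and whole-tumor models fitted")

  clin <- cohort_table(cohort)[, c("histology", "nse_elevated", "age",
                                   "sex", "smoking")]
  cm <- clinical_model(clin[train, ], labels[train])
  p_tr <- predict(cm, clin[train, ])
  thr <- youden_threshold(p_tr, labels[train])
  clin_tr <- evaluate(p_tr, labels[train], prob_threshold = thr,
                      n_boot = config$n_boot, seed = config$seed,
                      model_id = "clinical", cohort = "training")
  p_te <- predict(cm, clin[!train, ])
  clin_te <- evaluate(p_te, labels[!train], prob_threshold = thr,
                      n_boot = config$n_boot, seed = config$seed,
                      model_id = "clinical", cohort = "testing")

  assoc <- habitat_association(spatial, labels)

  manifest <- list(
    seed = config$seed,
    n_subjects = length(cohort),
    n_train = sum(train), n_test = sum(!train),
    n_features = ncol(x_all),
    models = list(
      habitat = list(train_auc = habitat_branch$models$training$auc,
                     test_auc = habitat_branch$models$testing$auc),
      whole_tumor = list(train_auc = whole_branch$models$training$auc,
                         test_auc = whole_branch$models$testing$auc),
      clinical = list(train_auc = clin_tr$auc, test_auc = clin_te$auc)),
    selection = list(
      habitat = c(stage1 = nrow(habitat_branch$selection$stage1),
                  stage2 = length(habitat_branch$selection$stage2),
                  stage3 = nrow(habitat_branch$selection$stage3)),
      whole_tumor = c(stage1 = nrow(whole_branch$selection$stage1),
                      stage2 = length(whole_branch$selection$stage2),
                      stage3 = nrow(whole_branch$selection$stage3))),
    association = assoc,
    elapsed_s = proc.time()[["elapsed"]] - t0)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(cohort_table(cohort),
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(metab, file.path(out_dir, "metabolics.csv"),
                     row.names = FALSE)
    utils::write.csv(spatial, file.path(out_dir, "spatial.csv"),
                     row.names = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(assoc, file.path(out_dir, "association.csv"),
                     row.names = FALSE)
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$artifact_md5 <- as.list(tools::md5sum(files))
    names(manifest$artifact_md5) <- basename(files)
    jsonlite::write_json(
      manifest[setdiff(names(manifest), "association")],
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest
}
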