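# End-to-end orchestration: simulate -> preprocess -> extract -> classify
# -> growth -> report, each stage writing a JSON manifest (config hash,
# seed, input hashes, version) so every artifact is traceable. Stage
# outputs are deterministic for a fixed config + seed: manifests carry no
# timestamps (logging to stderr does).

#' Default pipeline run configuration
#'
#' One list drives every stage. `scenario` holds synthetic-data overrides
#' (`n_fields` fields are rendered as images; the full population is
#' always emitted as the fast-path feature table), `classify$source`
#' selects the feature table the modelling stages consume (`"truth"` for
#' the generator's fast path, `"extracted"` for image-derived features).
#'
#' @param seed global seed, fanned out to per-stage seeds.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    scenario = list(n_lines = 5L, cells_per_class = 100L,
                    aging_amplitude = 1, n_fields = 4L),
    preprocess = list(),
    features = list(families = c("intensity", "texture", "morphology",
                                 "ratio")),
    classify = list(source = "truth", n_select = 50L, n_folds = 5L,
                    tasks = list(
                      stro1 = list(label = "stro1", classifier = "linear_svm",
                                   resample = "adasyn", positive = "pos"),
                      alp = list(label = "alp", classifier = "lda",
                                 resample = "adasyn", positive = "pos"),
                      senescent = list(label = "senescent",
                                       classifier = "linear_svm",
                                       resample = "adasyn",
                                       positive = "pos"),
                      cycle = list(label = "cycle_phase",
                                   classifier = "polynomial_svm",
                                   resample = "adasyn",
                                   positive = "cycling"))),
    growth = list(k = 400L, repeats = 30L, n_select = 100L,
                  k_grid = c(25L, 50L, 100L, 200L, 300L, 400L, 500L, 600L),
                  n_clusters = 3L))
}

#' Read a run configuration from YAML
#' @param path YAML file; missing entries fall back to
#'   [default_run_config()] values.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(user$seed %||% 1L), user)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 1L, preprocess = 2L, extract = 3L, classify = 4L,
               growth = 5L, report = 6L)
  derive_seeds(config$seed, 1L, stream = 200L + offsets[[stage]])
}

write_manifest <- function(out_dir, stage, config, inputs = character()) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("afmicell")),
              config_hash = object_hash(config), seed = config$seed,
              inputs = as.list(stats::setNames(
                vapply(inputs, file_hash, character(1)),
                basename(inputs))))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

config_scenario <- function(config) {
  sc <- config$scenario
  afmi_scenario(n_lines = sc[["n_lines"]] %||% 5L,
                cells_per_class = sc[["cells_per_class"]] %||% 100L,
                aging = utils::modifyList(
                  list(drift = c(nadh = -0.35, fad = 0.25, lipofuscin = 0.45,
                                 collagen = 0),
                       amplitude = sc[["aging_amplitude"]] %||% 1,
                       heterogeneity_sd = NULL),
                  sc[["aging"]] %||% list()),
                seed = config$seed)
}

#' Stage 1: generate a complete synthetic dataset
#'
#' Writes rendered fields (multi-page TIFF + JSON sidecar + mask TIFF),
#' reference spectra, per-cell labels, the passage log, the fast-path
#' ground-truth feature table, and a ground-truth JSON (scenario hash,
#' spike indices, classes).
#'
#' @param out_dir output directory (created).
#' @param config run configuration (see [default_run_config()]).
#' @return invisibly, the scenario.
#' @export
cmd_simulate <- function(out_dir, config = default_run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "fields"), showWarnings = FALSE)
  scenario <- config_scenario(config)
  sim <- simulate_cells(scenario)
  n_fields <- config$scenario$n_fields %||% 4L
  per_field <- scenario$field$cells_per_field
  n_render <- min(n_fields * per_field, nrow(sim$cells))
  pick <- with_seed(stage_seed(config, "simulate"),
                    sample(nrow(sim$cells), n_render))
  cells <- sim$cells
  cells$field_id <- "sim"
  spikes <- list()
  field_seeds <- derive_seeds(config$seed, n_fields, stream = 300L)
  for (f in seq_len(n_fields)) {
    rows <- pick[((f - 1L) * per_field + 1L):min(f * per_field, n_render)]
    rows <- rows[!is.na(rows)]
    fid <- sprintf("F%02d", f)
    rf <- render_field(cells[rows, ], sim$spectra[rows, , drop = FALSE],
                       scenario, field_id = fid, seed = field_seeds[f])
    write_cube(rf$cube, file.path(out_dir, "fields", paste0(fid, ".tif")),
               file.path(out_dir, "fields", paste0(fid, ".json")))
    write_mask(rf$mask, file.path(out_dir, "fields", paste0(fid, "_mask.tif")))
    spikes[[fid]] <- rf$truth$spike_index
    cells$field_id[rows] <- fid
  }
  lab <- cells[, c("cell_id", "field_id", "stro1", "alp", "senescent",
                   "cycle_phase", "dapi_total", "line_id", "passage",
                   "doublings_remaining")]
  write_labels(lab, file.path(out_dir, "labels.csv"))
  utils::write.csv(sim$passage_log, file.path(out_dir, "passage_log.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$features, file.path(out_dir, "truth_features.csv"),
                   row.names = FALSE, quote = FALSE)
  refs <- simulate_references(scenario)
  write_reference_spectra(refs$refs, file.path(out_dir, "refs.csv"))
  jsonlite::write_json(
    list(scenario_hash = scenario_hash(scenario), classes = sim$classes,
         gains_truth = refs$gains_truth, spike_index = spikes),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(out_dir, "simulate", config,
                 inputs = file.path(out_dir, "labels.csv"))
  afmi_log("simulate: ", nrow(cells), " cells, ", n_fields, " rendered fields")
  invisible(scenario)
}

list_fields <- function(dir) {
  metas <- sort(list.files(file.path(dir, "fields"), "^F[0-9]+\\.json$",
                           full.names = TRUE))
  sub("\\.json$", "", basename(metas))
}

#' Stage 2: preprocess every rendered field
#'
#' Runs cosmic-ray removal, denoising, background subtraction, flat-field
#' correction and calibration on each raw cube, writing calibrated cubes
#' and a manifest with spike / clipped-pixel counts.
#'
#' @param sim_dir output of [cmd_simulate()].
#' @param out_dir output directory.
#' @param config run configuration.
#' @export
cmd_preprocess <- function(sim_dir, out_dir, config = default_run_config()) {
  refs_path <- file.path(sim_dir, "refs.csv")
  if (!file.exists(refs_path))
    stopf("missing %s; run the simulate stage first", refs_path)
  dir.create(file.path(out_dir, "fields"), recursive = TRUE,
             showWarnings = FALSE)
  refs <- read_reference_spectra(refs_path)
  pc <- do.call(preprocess_config, config$preprocess %||% list())
  stats_ <- list()
  for (fid in list_fields(sim_dir)) {
    cube <- read_cube(file.path(sim_dir, "fields", paste0(fid, ".tif")),
                      file.path(sim_dir, "fields", paste0(fid, ".json")))
    mask <- read_mask(file.path(sim_dir, "fields", paste0(fid, "_mask.tif")),
                      field_id = fid)
    cal <- preprocess_cube(cube, mask, refs, pc)
    write_cube(cal, file.path(out_dir, "fields", paste0(fid, ".tif")),
               file.path(out_dir, "fields", paste0(fid, ".json")))
    write_mask(mask, file.path(out_dir, "fields", paste0(fid, "_mask.tif")))
    stats_[[fid]] <- list(n_spikes = cal$n_spikes,
                          clipped_denoise = cal$n_clipped_denoise,
                          clipped_background = cal$n_clipped_background)
    afmi_log("preprocess ", fid, ": ", cal$n_spikes, " spikes removed")
  }
  jsonlite::write_json(stats_, file.path(out_dir, "preprocess_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "preprocess", config, inputs = refs_path)
  invisible(stats_)
}

#' Stage 3: extract per-cell features from calibrated fields
#'
#' @param pre_dir output of [cmd_preprocess()].
#' @param sim_dir output of [cmd_simulate()] (for the label table).
#' @param out_dir output directory.
#' @param config run configuration.
#' @return invisibly, the assembled feature table.
#' @export
cmd_extract <- function(pre_dir, sim_dir, out_dir,
                        config = default_run_config()) {
  if (!length(list_fields(pre_dir)))
    stopf("no calibrated fields in %s; run the preprocess stage first",
          pre_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fc <- do.call(feature_config, config$features[
    names(config$features) %in% names(formals(feature_config))] %||% list())
  tabs <- lapply(list_fields(pre_dir), function(fid) {
    cube <- read_cube(file.path(pre_dir, "fields", paste0(fid, ".tif")),
                      file.path(pre_dir, "fields", paste0(fid, ".json")))
    mask <- read_mask(file.path(pre_dir, "fields", paste0(fid, "_mask.tif")),
                      field_id = fid)
    extract_cell_features(cube, mask, fc)
  })
  feats <- do.call(rbind, tabs)
  labels <- read_labels(file.path(sim_dir, "labels.csv"))
  tab <- clean_and_assemble(feats, labels)
  out_csv <- file.path(out_dir, "features.csv")
  hdr <- c(sprintf("# catalog_hash: %s",
                   object_hash(feature_catalog(fc))),
           sprintf("# config_hash: %s", object_hash(config)))
  writeLines(hdr, out_csv)
  suppressWarnings(utils::write.table(tab, out_csv, sep = ",",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  write_manifest(out_dir, "extract", config,
                 inputs = file.path(sim_dir, "labels.csv"))
  afmi_log("extract: ", nrow(tab), " cells x ",
           ncol(tab), " columns")
  invisible(tab)
}

read_feature_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

# Assemble the modelling table for classify/growth from the configured
# source.
modelling_table <- function(sim_dir, extract_dir, config) {
  src <- config$classify$source %||% "truth"
  labels <- read_labels(file.path(sim_dir, "labels.csv"))
  if (src == "extracted") {
    tab <- read_feature_csv(file.path(extract_dir, "features.csv"))
  } else {
    feats <- utils::read.csv(file.path(sim_dir, "truth_features.csv"),
                             check.names = FALSE)
    tab <- merge(feats, labels, by = c("field_id", "cell_id"), sort = FALSE)
  }
  feat_cols <- grep("^(ch[0-9]+_|ratio_|morph_)", names(tab), value = TRUE)
  list(table = tab, feat_cols = feat_cols)
}

#' Stage 4: cross-validated classification of the four endpoints
#'
#' Runs each configured task (stemness / STRO-1 with a linear SVM,
#' spontaneous differentiation / ALP with LDA, senescence with a linear
#' SVM, cell-cycle entry with a polynomial SVM) plus a morphology-only
#' ablation of the senescence task, writing one JSON report per task.
#'
#' @param sim_dir output of [cmd_simulate()].
#' @param extract_dir output of [cmd_extract()] (needed when
#'   `classify$source == "extracted"`).
#' @param out_dir output directory.
#' @param config run configuration.
#' @return invisibly, the list of evaluation reports.
#' @export
cmd_classify <- function(sim_dir, extract_dir = NULL, out_dir,
                         config = default_run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mt <- modelling_table(sim_dir, extract_dir, config)
  seed <- stage_seed(config, "classify")
  reports <- list()
  run_task <- function(name, task, feat_cols) {
    col <- task$label
    if (!col %in% names(mt$table)) {
      warnf("task '%s': label column '%s' missing; skipped", name, col)
      return(NULL)
    }
    y <- mt$table[[col]]
    if (col == "cycle_phase")
      y <- ifelse(y == "G1", "G1", "cycling")
    y <- factor(y)
    if (nlevels(y) != 2 || any(table(y) < (config$classify$n_folds %||% 5L))) {
      warnf("task '%s': classes too small; skipped", name)
      return(NULL)
    }
    crossvalidate(mt$table[, feat_cols, drop = FALSE], y,
                  classifier = classifier_spec(task$classifier),
                  embedding = list(n_select = config$classify$n_select %||% 50L,
                                   pca_var_retained = 0.99),
                  resample = task$resample %||% "none",
                  n_folds = config$classify$n_folds %||% 5L,
                  seed = seed, positive = task$positive)
  }
  for (name in names(config$classify$tasks)) {
    rep_ <- run_task(name, config$classify$tasks[[name]], mt$feat_cols)
    if (is.null(rep_)) next
    reports[[name]] <- rep_
    afmi_log("classify ", name, ": AUC ",
             sprintf("%.3f +/- %.3f", rep_$auc_mean, rep_$auc_sd))
  }
  morph_cols <- grep("^morph_", mt$feat_cols, value = TRUE)
  if (length(morph_cols) && "senescent" %in% names(config$classify$tasks)) {
    rep_ <- run_task("senescent_morphology_only",
                     config$classify$tasks$senescent, morph_cols)
    if (!is.null(rep_)) reports$senescent_morphology_only <- rep_
  }
  for (name in names(reports)) {
    r <- reports[[name]]
    jsonlite::write_json(
      list(task = name, classifier = r$classifier, resample = r$resample,
           n_folds = r$n_folds, auc_mean = r$auc_mean, auc_sd = r$auc_sd,
           sensitivity_mean = r$sensitivity_mean,
           sensitivity_sd = r$sensitivity_sd,
           specificity_mean = r$specificity_mean,
           specificity_sd = r$specificity_sd,
           folds = r$folds, n_per_class = r$n_per_class),
      file.path(out_dir, paste0(name, ".json")), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  write_manifest(out_dir, "classify", config,
                 inputs = file.path(sim_dir, "labels.csv"))
  invisible(reports)
}

#' Stage 5: growth-potential (doublings-remaining) analysis
#'
#' Evaluates the coarse-KNN doublings predictor, sweeps the neighbourhood
#' size, and clusters the full-population LD embedding into age groups;
#' writes JSON reports and the per-class curve as CSV.
#'
#' @inheritParams cmd_classify
#' @return invisibly, a list with the doublings report, sweep and
#'   clustering.
#' @export
cmd_growth <- function(sim_dir, extract_dir = NULL, out_dir,
                       config = default_run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mt <- modelling_table(sim_dir, extract_dir, config)
  if (!"doublings_remaining" %in% names(mt$table))
    stopf("no doublings_remaining labels available")
  seed <- stage_seed(config, "growth")
  g <- config$growth
  X <- mt$table[, mt$feat_cols, drop = FALSE]
  labs <- mt$table$doublings_remaining
  rep_ <- evaluate_doublings(X, labs, k = g$k %||% 400L,
                             repeats = g$repeats %||% 30L, seed = seed,
                             n_select = g$n_select %||% 100L)
  sw <- sweep_k(X, labs, k_grid = g$k_grid %||% c(100L, 400L),
                repeats = g$repeats %||% 30L, seed = seed,
                n_select = g$n_select %||% 100L)
  emb <- fit_embedding(X, labs, n_select = g$n_select %||% 100L)
  cl <- cluster_ages(emb$train_coords, labs,
                     n_clusters = g$n_clusters %||% 3L, seed = seed)
  jsonlite::write_json(
    list(k = rep_$k, repeats = rep_$repeats, rmspe = rep_$rmspe,
         mae = rep_$mae, spearman = rep_$spearman,
         per_class = rep_$per_class,
         k_sweep = sw$curve, best_k = sw$best_k,
         cluster_means = cl$cluster_means),
    file.path(out_dir, "growth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(rep_$per_class, file.path(out_dir, "per_class.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sw$curve, file.path(out_dir, "k_sweep.csv"),
                   row.names = FALSE, quote = FALSE)
  coords <- emb$train_coords
  utils::write.csv(data.frame(cell_id = mt$table$cell_id,
                              doublings_remaining = labs,
                              cluster = cl$assignments,
                              LD1 = coords[, 1],
                              LD2 = if (ncol(coords) > 1) coords[, 2] else 0),
                   file.path(out_dir, "embedding.csv"), row.names = FALSE,
                   quote = FALSE)
  write_manifest(out_dir, "growth", config,
                 inputs = file.path(sim_dir, "labels.csv"))
  afmi_log("growth: RMSPE ", sprintf("%.3f", rep_$rmspe), ", MAE ",
           sprintf("%.3f", rep_$mae))
  invisible(list(report = rep_, sweep = sw, clusters = cl))
}

#' Stage 6: collate reports and draw summary figures
#'
#' Merges the classification and growth JSON reports into one
#' `summary.json` and draws the LD-embedding scatter, the k-sweep curve
#' and the prediction-vs-truth plot (with 95% prediction-interval bars)
#' as PDFs under `figures/`.
#'
#' @param run_dir directory containing the `classify/` and `growth/`
#'   stage outputs.
#' @return invisibly, the summary list.
#' @export
cmd_report <- function(run_dir) {
  cls_dir <- file.path(run_dir, "classify")
  gr_dir <- file.path(run_dir, "growth")
  summary <- list()
  if (dir.exists(cls_dir)) {
    files <- setdiff(list.files(cls_dir, "\\.json$", full.names = TRUE),
                     file.path(cls_dir, "manifest.json"))
    summary$classification <- lapply(files, jsonlite::read_json,
                                     simplifyVector = TRUE)
  }
  if (file.exists(file.path(gr_dir, "growth.json")))
    summary$growth <- jsonlite::read_json(file.path(gr_dir, "growth.json"),
                                          simplifyVector = TRUE)
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fig_dir <- file.path(run_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  emb_csv <- file.path(gr_dir, "embedding.csv")
  if (file.exists(emb_csv)) {
    emb <- utils::read.csv(emb_csv)
    grDevices::pdf(file.path(fig_dir, "ld_embedding.pdf"), 6, 5)
    cols <- grDevices::hcl.colors(29, "viridis")
    plot(emb$LD1, emb$LD2, pch = 16, cex = 0.5,
         col = cols[pmin(emb$doublings_remaining + 1L, 29L)],
         xlab = "LD1", ylab = "LD2",
         main = "LD embedding coloured by doublings remaining")
    grDevices::dev.off()
  }
  sweep_csv <- file.path(gr_dir, "k_sweep.csv")
  if (file.exists(sweep_csv)) {
    sw <- utils::read.csv(sweep_csv)
    grDevices::pdf(file.path(fig_dir, "k_sweep.pdf"), 6, 4)
    plot(sw$k, sw$rmspe, type = "b", pch = 16, xlab = "nearest neighbours k",
         ylab = "RMSPE", main = "Prediction error vs neighbourhood size")
    grDevices::dev.off()
  }
  pc_csv <- file.path(gr_dir, "per_class.csv")
  if (file.exists(pc_csv)) {
    pc <- utils::read.csv(pc_csv)
    grDevices::pdf(file.path(fig_dir, "prediction_vs_truth.pdf"), 6, 5)
    plot(pc$true, pc$mean_aggregate, pch = 16, xlab = "true doublings remaining",
         ylab = "mean aggregate prediction",
         ylim = range(c(pc$pi_lower, pc$pi_upper)),
         main = "Aggregate doublings prediction")
    graphics::arrows(pc$true, pc$pi_lower, pc$true, pc$pi_upper,
                     angle = 90, code = 3, length = 0.03)
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
  }
  invisible(summary)
}
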