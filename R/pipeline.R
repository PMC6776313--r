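# End-to-end orchestration: tile -> segment -> features -> summarize ->
# representative ROI -> predict/train -> evaluate -> survival, with
# file-checksum caching and a run manifest. Tables are CSV, images
# PNG/TIFF, masks 16-bit TIFF, models JSON.

#' Build a pipeline configuration
#'
#' Validates and completes a configuration for [run_pipeline()]. Every
#' numeric option left open by the method description (tile size, window,
#' quantization, aggregator, threshold, seeds) appears here and is written
#' next to the outputs when a run finishes.
#'
#' @param roi_table data.frame or CSV path with columns `case_id`,
#'   `roi_id`, `grade` (1-4) and `image` (path to the ROI image)
#' @param out_dir output directory (created if absent)
#' @param tile tile edge in pixels for [tile_roi()]
#' @param seg_params a [segmentation_params()] object
#' @param quantization texture gray levels for [patch_features()]
#' @param aggregate nucleus-to-patch aggregator (`"mean"` or `"median"`)
#' @param mode `"train"` (fit a model on the designated grades) or
#'   `"predict"` (apply `model_path`)
#' @param model_path JSON model for `mode = "predict"`
#' @param lambda penalty for `mode = "train"` (`NULL` to tune on a default
#'   grid)
#' @param threshold classification threshold for [predict_grade()]
#' @param survival_table optional data.frame or CSV path with `case_id`,
#'   `time`, `event`, `age`, `gender`, `stage`
#' @param reference optional reference patch path for stain normalization
#' @param seed integer seed for all stochastic stages
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(roi_table, out_dir, tile = 2000L,
                            seg_params = segmentation_params(),
                            quantization = 32L, aggregate = "mean",
                            mode = c("train", "predict"), model_path = NULL,
                            lambda = NULL, threshold = 0.5,
                            survival_table = NULL, reference = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(roi_table)) roi_table <- read.csv(roi_table,
                                                     stringsAsFactors = FALSE)
  need <- c("case_id", "roi_id", "grade", "image")
  miss <- setdiff(need, names(roi_table))
  if (length(miss)) stopf("roi_table is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!all(roi_table$grade %in% 1:4)) stopf("ROI grades must be in 1..4")
  if (mode == "predict" && is.null(model_path))
    stopf("mode = 'predict' requires model_path")
  if (is.character(survival_table))
    survival_table <- read.csv(survival_table, stringsAsFactors = FALSE)
  structure(list(roi_table = roi_table, out_dir = out_dir, tile = as.integer(tile),
                 seg_params = seg_params, quantization = as.integer(quantization),
                 aggregate = aggregate, mode = mode, model_path = model_path,
                 lambda = lambda, threshold = threshold,
                 survival_table = survival_table, reference = reference,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  key <- config[c("tile", "quantization", "aggregate", "mode", "lambda",
                  "threshold", "seed")]
  key$seg <- unclass(config$seg_params)
  paste(deparse(key), collapse = "")
}

stage_cached <- function(manifest, stage, inputs_md5, out_files) {
  prev <- manifest$stages[[stage]]
  !is.null(prev) &&
    identical(unlist(prev$inputs), unlist(inputs_md5)) &&
    all(file.exists(out_files))
}

#' Run the full grading pipeline
#'
#' Executes tiling, segmentation, feature extraction, ROI summarization,
#' representative-ROI selection, grade prediction (or training), and, when
#' grades/survival data are available, evaluation and prognosis reporting.
#' Stage outputs are cached by input checksum: a rerun with unchanged
#' inputs and configuration reuses them.
#'
#' @param config a [pipeline_config()]
#' @return the run manifest (list of class `run_manifest`), invisibly;
#'   outputs are written under `config$out_dir` (`roi_summaries.csv`,
#'   `cases.csv`, `predictions.csv`, `model.json`, `evaluation.json`,
#'   `prognosis.csv`, `manifest.json`, `config.json`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  else list(stages = list())
  manifest$package_version <- as.character(utils::packageVersion("rccgrade"))
  warnings_log <- character(0)

  rt <- config$roi_table
  if (!all(file.exists(rt$image)))
    stopf("missing ROI images: %s",
          paste(rt$image[!file.exists(rt$image)], collapse = ", "))
  img_md5 <- as.list(tools::md5sum(rt$image))
  fp <- config_fingerprint(config)

  # --- stage 1: tile + segment + features + summarize, per ROI ----------
  summ_path <- file.path(config$out_dir, "roi_summaries.csv")
  st1_inputs <- c(img_md5, fingerprint = fp)
  if (stage_cached(manifest, "features", st1_inputs, summ_path)) {
    summaries <- read.csv(summ_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  } else {
    reference <- if (!is.null(config$reference)) read_patch(config$reference)
    rows <- vector("list", nrow(rt))
    for (i in seq_len(nrow(rt))) {
      roi_img <- tryCatch(read_patch(rt$image[i]),
                          error = function(e) stopf(
                            "stage 'features' failed reading %s: %s",
                            rt$image[i], conditionMessage(e)))
      patches <- tile_roi(roi_img, tile = config$tile)
      vecs <- list()
      for (p in patches) {
        mask <- segment_patch(p, config$seg_params, reference = reference)
        v <- withCallingHandlers(
          patch_features(p, mask, Q = config$quantization,
                         aggregate = config$aggregate),
          warning = function(w) {
            warnings_log <<- c(warnings_log,
                               sprintf("%s: %s", rt$roi_id[i],
                                       conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        if (!is.null(v)) vecs[[length(vecs) + 1L]] <- v
      }
      if (!length(vecs))
        stopf("ROI %s produced no patches with nuclei", rt$roi_id[i])
      s <- summarize_roi(vecs)
      rows[[i]] <- data.frame(roi_id = rt$roi_id[i], case_id = rt$case_id[i],
                              grade = rt$grade[i], t(s), check.names = FALSE,
                              stringsAsFactors = FALSE)
    }
    summaries <- do.call(rbind, rows)
    write.csv(summaries, summ_path, row.names = FALSE)
    manifest$stages$features <- list(inputs = st1_inputs,
                                     outputs = as.list(tools::md5sum(summ_path)),
                                     timestamp = format(Sys.time()),
                                     seed = config$seed)
  }

  # --- stage 2: representative ROI + designated grade per case ----------
  cases_path <- file.path(config$out_dir, "cases.csv")
  st2_inputs <- c(as.list(tools::md5sum(summ_path)), fingerprint = fp)
  if (stage_cached(manifest, "cases", st2_inputs, cases_path)) {
    cases <- read.csv(cases_path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    feat_cols <- summary_feature_names()
    cases <- do.call(rbind, lapply(split(summaries, summaries$case_id),
      function(cs) {
        rep_id <- select_representative_roi(
          as.matrix(cs[, feat_cols, drop = FALSE]), cs$grade, cs$roi_id)
        dg <- designate_grade(cs$grade)
        rep_row <- cs[cs$roi_id == rep_id, feat_cols, drop = FALSE]
        data.frame(case_id = cs$case_id[1L], representative_roi = rep_id,
                   grade_4tier = dg$grade_4tier, grade_2tier = dg$grade_2tier,
                   rep_row, check.names = FALSE, stringsAsFactors = FALSE)
      }))
    rownames(cases) <- NULL
    write.csv(cases, cases_path, row.names = FALSE)
    manifest$stages$cases <- list(inputs = st2_inputs,
                                  outputs = as.list(tools::md5sum(cases_path)),
                                  timestamp = format(Sys.time()),
                                  seed = config$seed)
  }

  # --- stage 3: train or predict ----------------------------------------
  feat_cols <- summary_feature_names()
  x_raw <- as.matrix(cases[, feat_cols, drop = FALSE])
  pred_path <- file.path(config$out_dir, "predictions.csv")
  if (config$mode == "train") {
    zs <- withCallingHandlers(zscore_fit_apply(x_raw), warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    lambda <- config$lambda
    if (is.null(lambda)) {
      grid <- exp(seq(log(1e-3), log(0.5), length.out = 20L))
      lambda <- tune_lambda(zs$x, cases$grade_2tier, grid,
                            seed = config$seed)$lambda
    }
    model <- fit_lasso(zs$x, cases$grade_2tier, lambda,
                       zscore_params = zs$params)
    write_model(model, file.path(config$out_dir, "model.json"))
  } else {
    model <- read_model(config$model_path)
  }
  preds <- predict_grade(model, x_raw, threshold = config$threshold)
  preds <- cbind(cases[, c("case_id", "grade_2tier")], preds)
  names(preds)[2L] <- "grade_manual"
  write.csv(preds, pred_path, row.names = FALSE)
  manifest$stages$predict <- list(
    inputs = c(as.list(tools::md5sum(cases_path)), fingerprint = fp),
    outputs = as.list(tools::md5sum(pred_path)),
    timestamp = format(Sys.time()), seed = config$seed)

  # --- stage 4: evaluation ----------------------------------------------
  if (length(unique(preds$grade_manual)) == 2L) {
    ev <- evaluate_grades(preds$grade_manual, preds$grade_pred,
                          preds$prob_high)
    jsonlite::write_json(unclass(ev), file.path(config$out_dir,
                                                "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- stage 5: survival -------------------------------------------------
  if (!is.null(config$survival_table)) {
    sv <- merge(config$survival_table, preds, by = "case_id")
    sv$grade_pred <- sv$grade_pred
    rep_tab <- grade_prognosis_report(sv, c("grade_manual", "grade_pred"))
    write.csv(rep_tab, file.path(config$out_dir, "prognosis.csv"),
              row.names = FALSE)
  }

  manifest$warnings <- as.list(warnings_log)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  cfg_dump <- config[setdiff(names(config), c("roi_table", "survival_table"))]
  cfg_dump$seg_params <- unclass(cfg_dump$seg_params)
  jsonlite::write_json(cfg_dump, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(structure(manifest, class = "run_manifest"))
}

#' Validate pipeline input tables
#'
#' Schema, level and range checks for grade, cohort and feature tables.
#'
#' @param grades optional data.frame with a `grade` column (1-4 expected)
#' @param cohort optional data.frame with `time`, `event`, `age`, `gender`,
#'   `stage`
#' @param features optional data.frame expected to contain the 72 or 144
#'   canonical feature columns
#' @return data.frame of issues with columns `table`, `row`, `issue`;
#'   zero rows when everything conforms
#' @export
validate_tables <- function(grades = NULL, cohort = NULL, features = NULL) {
  issues <- list()
  add <- function(tab, row, msg)
    issues[[length(issues) + 1L]] <<- data.frame(table = tab, row = row,
                                                 issue = msg,
                                                 stringsAsFactors = FALSE)
  if (!is.null(grades)) {
    if (!"grade" %in% names(grades)) add("grades", NA, "missing 'grade' column")
    else for (i in which(!(grades$grade %in% 1:4)))
      add("grades", i, sprintf("grade %s outside 1..4", grades$grade[i]))
  }
  if (!is.null(cohort)) {
    need <- c("time", "event")
    miss <- setdiff(need, names(cohort))
    if (length(miss)) add("cohort", NA, paste("missing columns:",
                                              paste(miss, collapse = ", ")))
    else {
      for (i in which(cohort$time < 0))
        add("cohort", i, "negative survival time")
      for (i in which(!(cohort$event %in% c(0, 1))))
        add("cohort", i, "event not 0/1")
    }
    if ("stage" %in% names(cohort))
      for (i in which(!(cohort$stage %in% c("I", "II", "III", "IV"))))
        add("cohort", i, sprintf("unknown stage '%s'", cohort$stage[i]))
  }
  if (!is.null(features)) {
    fn <- feature_names(); sn <- summary_feature_names()
    has72 <- all(fn %in% names(features))
    has144 <- all(sn %in% names(features))
    if (!has72 && !has144)
      add("features", NA, "neither the 72 patch nor 144 summary columns present")
  }
  if (!length(issues))
    return(data.frame(table = character(0), row = integer(0),
                      issue = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Simulate a small on-disk case set
#'
#' Writes PNG ROI images (with grade-dependent nuclear size and chromatin
#' texture) plus the ROI grade table and a survival table, giving the
#' pipeline a self-contained input set.
#'
#' @param out_dir directory for the images and tables
#' @param n_cases number of cases (split evenly low/high grade)
#' @param rois_per_case ROIs per case
#' @param roi_size integer (H, W) of each ROI image
#' @param seed integer seed
#' @return list with `roi_table` and `survival_table` data.frames (also
#'   written as CSV under `out_dir`)
#' @export
simulate_case_set <- function(out_dir, n_cases = 4L, rois_per_case = 2L,
                              roi_size = c(240L, 240L), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); surv <- list()
  withr::with_seed(seed, for (ci in seq_len(n_cases)) {
    high <- ci > n_cases / 2
    case_id <- sprintf("case%02d", ci)
    for (ri in seq_len(rois_per_case)) {
      sd_i <- seed + ci * 131L + ri
      specs <- random_nucleus_specs(
        n = 9L, size = roi_size,
        radius = if (high) c(13, 18) else c(9, 12),
        eccentricity = if (high) c(1.4, 2.2) else c(1, 1.3),
        chromatin_contrast = if (high) 0.5 else 0.2,
        base_stain = if (high) 0.95 else 0.7, seed = sd_i)
      sp <- render_patch(specs, size = roi_size, seed = sd_i)
      img_path <- file.path(out_dir, sprintf("%s_roi%d.png", case_id, ri))
      write_patch(sp$image, img_path)
      grade <- if (high) sample(3:4, 1L) else sample(1:2, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case_id, roi_id = sprintf("%s_roi%d", case_id, ri),
        grade = grade, image = img_path, stringsAsFactors = FALSE)
    }
    surv[[ci]] <- data.frame(
      case_id = case_id,
      time = round(rexp(1L, rate = log(2) / (if (high) 30 else 60)), 1L),
      event = rbinom(1L, 1L, 0.6),
      age = round(runif(1L, 45, 80)), gender = sample(c("male", "female"), 1L),
      stage = sample(c("I", "II", "III", "IV"), 1L), stringsAsFactors = FALSE)
  })
  roi_table <- do.call(rbind, rows)
  survival_table <- do.call(rbind, surv)
  write.csv(roi_table, file.path(out_dir, "roi_table.csv"), row.names = FALSE)
  write.csv(survival_table, file.path(out_dir, "survival_table.csv"),
            row.names = FALSE)
  list(roi_table = roi_table, survival_table = survival_table)
}
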