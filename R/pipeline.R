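# end-to-end orchestration: simulate -> preprocess -> register -> subtract ->
# detect -> featurize -> select/classify -> report

#' Default run configuration
#'
#' Nested parameter blocks, one per stage, with the package defaults
#' materialized. A single global seed is fanned out per stage through
#' [derive_seed()], so stages can be re-run in isolation.
#'
#' @param seed global seed.
#' @param cohort arguments for [cohort_config()] (used when simulating).
#' @param preprocess,register,detect,features,select,model stage overrides.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, cohort = list(),
                               preprocess = list(), register = list(),
                               detect = list(), features = list(),
                               select = list(), model = list()) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = modifyList(list(n_patients = 10, image_shape = c(128, 104),
                             seed = seed), cohort),
    preprocess = modifyList(list(clip_limit = 0.01, tiles = c(8, 8),
                                 gamma = 1.2, open_radius = 5), preprocess),
    register = modifyList(list(iterations = c(60, 30, 15),
                               smoothing_sigma = 2), register),
    detect = modifyList(list(q = 95, iou_threshold = 0.1), detect),
    features = modifyList(list(distances = c(1, 2, 4), levels = 16), features),
    select = modifyList(list(quorum = 5, round1_size = 19, round2_size = 17,
                             enabled = FALSE), select),
    model = modifyList(list(spec = "LDA", smote = TRUE, n_boot = 200), model))
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' Unknown top-level keys are rejected; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "cohort", "preprocess", "register", "detect",
             "features", "select", "model")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(default_run_config, raw)
}

#' Read and validate a dataset manifest
#'
#' Expects the CSV header
#' `patient_id,view,round,image_path,mask_path,label,density`, rounds
#' `prior`/`recent` only, no duplicate (patient, view, round) entries, and
#' existing image files. Row order does not affect the returned index.
#'
#' @param path manifest CSV path.
#' @return data.frame sorted by patient, view, round, with attribute
#'   `pairs`: per patient/view rows holding both rounds.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "view", "round", "image_path", "mask_path",
                "label", "density")
  if (!all(required %in% names(m)))
    stop("manifest must have header: ", paste(required, collapse = ","),
         call. = FALSE)
  if (!all(m$round %in% c("prior", "recent")))
    stop("manifest error: only rounds 'prior' and 'recent' are supported",
         call. = FALSE)
  key <- paste(m$patient_id, m$view, m$round)
  if (anyDuplicated(key))
    stop("manifest error: duplicate (patient, view, round) entries",
         call. = FALSE)
  missing <- !file.exists(m$image_path)
  if (any(missing))
    stop("manifest image file not found: ", m$image_path[which(missing)[1]],
         call. = FALSE)
  m <- m[order(m$patient_id, m$view, m$round), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# run one patient/view pair through preprocess -> register -> subtract ->
# detect; returns rois + metrics
process_pair <- function(recent, prior, cfg, truth_masks = NULL,
                         truth_labels = NULL) {
  pp_r <- preprocess_pipeline(recent, cfg$preprocess)
  pp_p <- preprocess_pipeline(prior, cfg$preprocess)
  reg <- demons_register(pp_r$image, pp_p$image,
                         iterations = cfg$register$iterations,
                         smoothing_sigma = cfg$register$smoothing_sigma)
  res <- temporal_subtract(pp_r$image, reg$warped, pp_r$mask)
  rois <- detect_candidates(res, pp_r$mask, q = cfg$detect$q,
                            open_radius = cfg$detect$open_radius,
                            min_area = cfg$detect$min_area,
                            margin = cfg$detect$margin,
                            patient_id = if (inherits(recent, "mammogram"))
                              recent$patient_id else NA_character_,
                            view = if (inherits(recent, "mammogram"))
                              recent$view else NA_character_)
  tally <- NULL
  if (!is.null(truth_masks) && length(truth_masks) > 0) {
    mt <- match_to_truth(rois, truth_masks, truth_labels,
                         cfg$detect$iou_threshold)
    rois <- mt$rois
    tally <- mt
  }
  list(rois = rois, residual = res, recent_pp = pp_r, tally = tally)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates a seeded phantom cohort, processes every patient/view pair
#' (pre-processing, Demons registration, temporal subtraction, candidate
#' detection), extracts the 98-value feature vector per candidate, and runs
#' the two classification rounds under leave-one-patient-out CV. Artifacts
#' and a summary JSON are written to `out_dir`; identical config + seed give
#' identical summaries.
#'
#' @param config a [default_run_config()].
#' @param out_dir output directory for artifacts.
#' @param stages character subset of
#'   `c("simulate","process","featurize","classify")` to run.
#' @return list with the summary (invisible); summary JSON and resolved
#'   config YAML are written to `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = c("simulate", "process", "featurize",
                                    "classify")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  ccfg <- do.call(cohort_config, config$cohort)
  summary <- list(seed = config$seed, n_patients = ccfg$n_patients)
  rois_all <- list(); feats <- NULL
  if ("simulate" %in% stages) {
    manifest <- generate_cohort(ccfg, file.path(out_dir, "cohort"))
    summary$n_images <- nrow(manifest)
  }
  if ("process" %in% stages) {
    n_truth <- 0; n_detected <- 0; n_fp <- 0
    for (i in seq_len(ccfg$n_patients)) {
      pid <- sprintf("P%03d", i)
      pat <- generate_patient(ccfg, pid)
      for (v in ccfg$views) {
        tv <- pat$truth$views[[v]]
        pr <- process_pair(pat$images[[paste(v, "recent", sep = "_")]],
                           pat$images[[paste(v, "prior", sep = "_")]],
                           config, tv$mass_masks, tv$mass_labels)
        if (!is.null(pr$tally)) {
          n_truth <- n_truth + length(tv$mass_masks)
          n_detected <- n_detected + sum(pr$tally$detected)
          n_fp <- n_fp + pr$tally$n_fp
        }
        for (r in pr$rois) {
          r$image_key <- paste(pid, v, sep = "_")
          rois_all[[length(rois_all) + 1]] <- list(roi = r,
                                                   image = pr$residual)
        }
      }
    }
    summary$detection <- list(n_truth_masses = n_truth,
                              n_detected = n_detected, n_fp = n_fp,
                              retention = if (n_truth > 0)
                                n_detected / n_truth else NA)
  }
  if ("featurize" %in% stages && length(rois_all) > 0) {
    spec <- glcm_spec(config$features$distances, config$features$levels)
    feats <- do.call(rbind, lapply(seq_along(rois_all), function(i) {
      e <- rois_all[[i]]
      fv <- extract_all(e$roi, e$image, spec)
      cbind(as.data.frame(t(fv)),
            data.frame(patient_id = e$roi$patient_id, view = e$roi$view,
                       roi_id = i, label = e$roi$matched_truth,
                       stringsAsFactors = FALSE))
    }))
    write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    summary$n_rois <- nrow(feats)
  }
  if ("classify" %in% stages && !is.null(feats)) {
    fcols <- feature_catalog(glcm_spec(config$features$distances,
                                       config$features$levels))
    sel_cfg <- if (isTRUE(config$select$enabled))
      list(target_size = config$select$round1_size,
           quorum = config$select$quorum) else NULL
    y1 <- as.integer(feats$label != "none")
    r1 <- NULL
    if (length(unique(y1)) == 2 && length(unique(feats$patient_id)) >= 2) {
      spec1 <- classifier_spec(config$model$spec, round = 1,
                               seed = derive_seed(config$seed, "round1"))
      r1 <- lopo_cv(feats[, fcols], y1, feats$patient_id, spec1,
                    select_cfg = sel_cfg, smote = config$model$smote,
                    seed = derive_seed(config$seed, "cv1"),
                    n_boot = config$model$n_boot)
      summary$round1 <- r1[c("sensitivity", "specificity", "accuracy",
                             "auc", "mcc", "kappa")]
    }
    mass_rows <- feats$label %in% c("benign", "malignant")
    y2 <- as.integer(feats$label[mass_rows] == "malignant")
    if (sum(mass_rows) >= 4 && length(unique(y2)) == 2 &&
        length(unique(feats$patient_id[mass_rows])) >= 2) {
      spec2 <- classifier_spec(config$model$spec, round = 2,
                               seed = derive_seed(config$seed, "round2"))
      sel_cfg2 <- if (isTRUE(config$select$enabled))
        list(target_size = config$select$round2_size,
             quorum = config$select$quorum) else NULL
      r2 <- lopo_cv(feats[mass_rows, fcols], y2,
                    feats$patient_id[mass_rows], spec2,
                    select_cfg = sel_cfg2, smote = config$model$smote,
                    seed = derive_seed(config$seed, "cv2"),
                    n_boot = config$model$n_boot)
      summary$round2 <- r2[c("sensitivity", "specificity", "accuracy",
                             "auc", "mcc", "kappa")]
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(summary)
}
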