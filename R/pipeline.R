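#' Default batch-run configuration
#'
#' Bundles the per-stage settings of the full pipeline: cohort simulation,
#' VNCa post-processing (suppression index 25), segmentation (17
#' vertebrae, 3-mm erosion, +200 HU bone threshold), histogram extraction,
#' BMD measurement, and inference (alpha 0.05, decision cutoff 0.93%,
#' planning effect size f2 = 0.32). Unknown keys are rejected before any
#' compute.
#'
#' @param seed Top-level seed; every source of randomness derives from it.
#' @param ... Overrides for top-level keys (`cohort`, `histogram`,
#'   `segmentation`, `spectral`, `bmd`, `inference`, `output_dir`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    cohort = cohort_spec(seed = derive_seed(seed, 1)),
    histogram = histogram_spec(),
    segmentation = list(vertebrae = 17, erosion_mm = 3, bone_threshold = 200),
    spectral = list(basis = material_basis(), suppression_index = 25),
    bmd = list(target_labels = 3:5, erosion_mm = 3, n_readers = 2, reader_keep = 0.6),
    inference = list(alpha = 0.05, cutoff = 0.93, f2 = 0.32),
    seed = as.integer(seed),
    output_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    if (nm %in% c("segmentation", "bmd", "inference", "spectral")) {
      bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stopf("unknown %s config keys: %s", nm, paste(bad, collapse = ", "))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Quantify a single patient volume
#'
#' The per-patient core of the pipeline: VNCa post-processing (unless a
#' precomputed VNCa volume is supplied), vertebra labeling (rule-based, or
#' an imported label map), bottom-up selection, cortical erosion, and the
#' marrow statistic. Lesion voxels (label -1 in an imported map) are
#' excluded from the VOI.
#'
#' @param volume A [spectral_volume()], or a `vnca_volume` when the
#'   calcium-suppressed data are precomputed.
#' @param label_map Optional integer label map (external segmentation);
#'   when `NULL` and a conventional grid is available, the rule-based
#'   labeler is used.
#' @param cfg A [run_config()].
#' @return List with `statistic` (the [non_fatty_portion()] row),
#'   `histogram` (standardized [attenuation_histogram()]), `spine`
#'   (the [labeled_spine()]), `voi` (the eroded [voi_mask()]).
#' @export
quantify_patient <- function(volume, label_map = NULL, cfg = run_config()) {
  seg <- cfg$segmentation
  if (inherits(volume, "spectral_volume")) {
    vnca <- vnca_transform(volume, cfg$spectral$basis, cfg$spectral$suppression_index)
    conv <- volume$conventional
    spacing <- volume$spacing_mm
  } else if (inherits(volume, "vnca_volume")) {
    vnca <- volume
    conv <- NULL
    spacing <- volume$spacing_mm
  } else {
    stopf("`volume` must be a spectral_volume or vnca_volume")
  }
  if (is.null(label_map)) {
    if (is.null(conv)) stopf("rule-based labeling needs a conventional grid; supply `label_map`")
    ls <- label_vertebrae(conv, spacing, seg$bone_threshold)
  } else {
    ls <- labeled_spine(label_map, spacing)
  }
  voi <- select_bottom_k(ls, seg$vertebrae)
  if (!is.null(label_map) || !is.null(attr(ls, "lesion_mask"))) {
    lesions <- if (!is.null(label_map)) label_map == -1L else attr(ls, "lesion_mask")
    if (any(lesions)) voi <- voi_mask(voi$mask & !lesions, spacing)
  }
  voi <- erode_cortex(voi, seg$erosion_mm)
  samp <- extract_voxels(vnca, voi)
  list(statistic = non_fatty_portion(samp),
       histogram = standardize_histogram(attenuation_histogram(samp, cfg$histogram),
                                         cfg$histogram),
       spine = ls, voi = voi)
}

process_phantom_patient <- function(ph_spec, record, cfg) {
  ph <- build_phantom(ph_spec)
  truth <- ph$truth
  spacing <- ph$volume$spacing_mm
  seg <- cfg$segmentation

  vnca <- vnca_transform(ph$volume, cfg$spectral$basis, cfg$spectral$suppression_index)
  ls <- label_vertebrae(ph$volume$conventional, spacing, seg$bone_threshold)
  voi <- select_bottom_k(ls, seg$vertebrae)
  lesion_mask <- truth$label_map == -1L
  if (any(lesion_mask)) voi <- voi_mask(voi$mask & !lesion_mask, spacing)
  voi <- erode_cortex(voi, seg$erosion_mm)
  samp <- extract_voxels(vnca, voi)
  stat <- non_fatty_portion(samp)
  h <- standardize_histogram(attenuation_histogram(samp, cfg$histogram), cfg$histogram)

  pair <- default_calibration_pair(cfg$spectral$basis, ph_spec$base_soft_fraction)
  conv <- ph$volume$conventional
  cal <- internal_calibration(mean(conv[truth$muscle_ref_mask]),
                              mean(conv[truth$fat_ref_mask]), pair)
  bmd <- measure_bmd(conv, ls, cfg$bmd$target_labels, lesion_mask, cal,
                     cfg$bmd$erosion_mm)
  rb <- measure_bmd_readers(conv, ls, cfg$bmd$target_labels, lesion_mask, cal,
                            cfg$bmd$erosion_mm, n_readers = cfg$bmd$n_readers,
                            keep = cfg$bmd$reader_keep, seed = ph_spec$seed)

  row <- tibble::tibble(
    patient_id = record$patient_id,
    voi_volume_cm3 = stat$voi_volume_cm3,
    n_marrow = stat$n_marrow,
    n_above_zero = stat$n_above_zero,
    non_fatty_percent = stat$non_fatty_percent,
    bmd_mg_ml = bmd$bmd_mg_ml,
    vertebrae_used = bmd$vertebrae_used,
    bmd_fallback = bmd$fallback_used
  )
  for (r in seq_along(rb)) row[[paste0("reader_bmd_", r)]] <- rb[r]
  list(row = row, histogram = h)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates the cohort, then per patient: phantom rendering, VNCa
#' transform, spine segmentation and 17-vertebra VOI with 3-mm cortical
#' erosion, marrow histogram and the non-fatty portion statistic, and
#' in-body calibrated BMD with two simulated readers. Per-patient failures
#' are isolated and listed instead of aborting the batch. Cohort-level
#' inference comprises the infiltration regression, ROC analyses for the
#' lesion and diagnosis outcomes (with post-hoc power), the fixed decision
#' rule, reader-BMD ICC(2,1), and the a-priori regression sample size.
#' Identical config and seed give an identical report.
#'
#' @param cfg A [run_config()].
#' @return An object of class `vnca_report`: list with `quantification`,
#'   `cohort`, `inference`, `histograms` (per-group mean standardized
#'   counts), `failures`, `provenance`. When `cfg$output_dir` is set, CSV
#'   tables and a JSON report are written there.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) stopf("`cfg` must come from run_config()")
  cohort <- sample_cohort(cfg$cohort)
  n <- nrow(cohort$records)

  rows <- list(); hists <- list()
  failures <- tibble::tibble(patient_id = character(), message = character())
  for (k in seq_len(n)) {
    rec <- cohort$records[k, ]
    res <- tryCatch(process_phantom_patient(cohort$phantoms[[k]], rec, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- dplyr::bind_rows(failures,
        tibble::tibble(patient_id = rec$patient_id, message = conditionMessage(res)))
    } else {
      rows[[length(rows) + 1]] <- res$row
      hists[[rec$patient_id]] <- res$histogram
    }
  }
  if (length(rows) == 0) stopf("zero successful patients")
  quant <- dplyr::bind_rows(rows)
  ct <- dplyr::inner_join(cohort$records, quant, by = "patient_id")

  # per-group mean standardized histogram (overlay-ready)
  histograms <- dplyr::bind_rows(lapply(names(hists), function(id) {
    h <- hists[[id]]
    g <- ct$group[ct$patient_id == id]
    if (length(g) == 0) return(NULL)
    tibble::tibble(group = g, bin_lower = h$bin_lower, bin_upper = h$bin_upper,
                   standardized_count = h$standardized_count)
  }))
  histograms <- dplyr::summarise(
    dplyr::group_by(histograms, .data$group, .data$bin_lower, .data$bin_upper),
    standardized_count = mean(.data$standardized_count), .groups = "drop")

  inf <- cfg$inference
  is_mm <- as.integer(ct$group %in% c("MM", "SMM"))
  fit <- tryCatch(fit_infiltration_model(ct), error = function(e) NULL)
  roc_les <- tryCatch(roc_youden(ct$non_fatty_percent, ct$lesion_call, inf$alpha),
                      error = function(e) NULL)
  roc_dx <- tryCatch(roc_youden(ct$non_fatty_percent, is_mm, inf$alpha),
                     error = function(e) NULL)
  rule_les <- tryCatch(apply_decision_rule(ct$non_fatty_percent, ct$lesion_call, inf$cutoff),
                       error = function(e) NULL)
  # MM detection among patients with negative visual reads (the occult subset)
  occ <- ct[ct$lesion_call == 0, ]
  rule_occ <- tryCatch(apply_decision_rule(occ$non_fatty_percent,
                                           as.integer(occ$group %in% c("MM", "SMM")),
                                           inf$cutoff),
                       error = function(e) NULL)
  rb_cols <- grep("^reader_bmd_", names(ct), value = TRUE)
  icc <- tryCatch(icc2(as.matrix(ct[, rb_cols])), error = function(e) NA_real_)
  ss <- regression_sample_size(inf$f2, inf$alpha, 0.8, 2)

  report <- structure(list(
    quantification = quant,
    cohort = ct,
    inference = list(regression = fit, roc_lesions = roc_les, roc_diagnosis = roc_dx,
                     rule_lesions = rule_les, rule_occult = rule_occ,
                     icc_bmd = icc, sample_size = ss),
    histograms = histograms,
    failures = failures,
    provenance = list(seed = cfg$seed, config_hash = rlang::hash(unclass(cfg)),
                      package = "vncamarrow",
                      version = as.character(utils::packageVersion("vncamarrow")))
  ), class = "vnca_report")

  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' Serialize a pipeline report
#'
#' Writes `quantification.csv`, `cohort.csv`, `histograms.csv` and
#' `report.json` (regression, ROC, decision-rule, ICC, power and
#' provenance blocks) to a directory. The JSON is deterministic: the same
#' report writes byte-identical output.
#'
#' @param report A `vnca_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$quantification, file.path(dir, "quantification.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(report$histograms, file.path(dir, "histograms.csv"), row.names = FALSE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

report_to_list <- function(report) {
  inf <- report$inference
  fit <- inf$regression
  roc_block <- function(r) {
    if (is.null(r)) return(NULL)
    list(auc = r$auc, ci95 = c(r$ci_lower, r$ci_upper),
         youden_threshold = r$youden_threshold, sensitivity = r$sensitivity,
         specificity = r$specificity, n_cases = r$n_cases, n_controls = r$n_controls,
         power_at_alpha = r$power_at_alpha)
  }
  list(
    provenance = report$provenance,
    n_patients = nrow(report$quantification),
    failures = as.list(stats::setNames(report$failures$message, report$failures$patient_id)),
    regression = if (is.null(fit)) NULL else list(
      n = fit$n,
      coefficients = as.data.frame(fit$coefficients),
      partial_r = fit$partial_r, semipartial_r = fit$semipartial_r,
      model_r = fit$model_r, vif = as.list(fit$vif),
      breusch_pagan = list(statistic = fit$bp_stat, p_value = fit$bp_p)),
    roc_lesions = roc_block(inf$roc_lesions),
    roc_diagnosis = roc_block(inf$roc_diagnosis),
    decision_rule = list(lesions = if (is.null(inf$rule_lesions)) NULL else
                           as.list(inf$rule_lesions),
                         occult_mm = if (is.null(inf$rule_occult)) NULL else
                           as.list(inf$rule_occult)),
    icc_bmd = inf$icc_bmd,
    regression_sample_size = inf$sample_size
  )
}

#' @export
print.vnca_report <- function(x, ...) {
  cat(sprintf("vnca_report: %d patients quantified (%d failed)\n",
              nrow(x$quantification), nrow(x$failures)))
  if (!is.null(x$inference$regression)) print(x$inference$regression)
  if (!is.null(x$inference$roc_lesions)) {
    cat("lesion outcome:    "); print(x$inference$roc_lesions)
  }
  if (!is.null(x$inference$roc_diagnosis)) {
    cat("diagnosis outcome: "); print(x$inference$roc_diagnosis)
  }
  invisible(x)
}
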