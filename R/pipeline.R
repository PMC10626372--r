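#' Reference thresholds for comparison plots
#'
#' Published decision thresholds for the volumetric CU ratio (whole cohort
#' and training split) and the mean TBR, shipped as named constants for
#' annotation and comparison only -- never used as defaults for any decision
#' in this package.
#'
#' @format Named numeric vector with elements `cu_volumetric_cohort`,
#'   `cu_volumetric_training`, `tbr_mean`.
#' @export
fet_reference_thresholds <- c(
  cu_volumetric_cohort = 5.49,
  cu_volumetric_training = 5.43,
  tbr_mean = 2.73
)

#' Run the biomarker pipeline over a cohort manifest
#'
#' For every subject: read the SUV volume and lesion mask (plus optional
#' exclusion / contrast-enhancing / T2 masks), extract the metabolic
#' compartments and assemble the [lesion_record()]. Subjects that fail are
#' quarantined with their reason (attribute `"quarantine"`), not silently
#' dropped; more than 10% failures aborts the run.
#'
#' @param manifest A [load_manifest()] tibble (or a data frame with the same
#'   columns).
#' @param dilate_voxels,robust_peak,k_abs Passed to [extract_compartments()].
#' @return A tibble of lesion records (one row per successful subject) with
#'   molecular label columns; quarantined subjects in
#'   `attr(, "quarantine")`.
#' @export
run_cohort <- function(manifest, dilate_voxels = 2L, robust_peak = FALSE,
                       k_abs = 1.8) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  quarantine <- list()
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- tryCatch({
      vol <- read_suv_volume(row$image_path)
      lesion <- read_mask(row$lesion_mask_path, "lesion", reference = vol)
      excl <- maybe_mask(row, "exclusion_mask_path", "exclusion", vol)
      ce <- maybe_mask(row, "ce_mask_path", "contrast_enhancing", vol)
      t2 <- maybe_mask(row, "t2_mask_path", "t2", vol)
      set <- extract_compartments(vol, lesion, exclusion = excl,
                                  dilate_voxels = dilate_voxels,
                                  robust_peak = robust_peak, k_abs = k_abs)
      lesion_record(vol, set, subject_id = row$subject_id,
                    ce_mask = ce, t2_mask = t2,
                    labels = row[intersect(manifest_label_cols(), names(row))])
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      quarantine[[length(quarantine) + 1]] <- tibble::tibble(
        subject_id = row$subject_id, reason = conditionMessage(rec))
    } else {
      records[[length(records) + 1]] <- rec
    }
  }
  qt <- dplyr::bind_rows(quarantine)
  if (nrow(qt) > 0.1 * nrow(manifest)) {
    stop(sprintf("%d of %d subjects failed (> 10%%): %s", nrow(qt),
                 nrow(manifest),
                 paste(utils::head(qt$reason, 3), collapse = "; ")))
  }
  out <- dplyr::bind_rows(records)
  attr(out, "quarantine") <- qt
  out
}

maybe_mask <- function(row, col, label, vol) {
  if (!col %in% names(row)) return(NULL)
  p <- row[[col]]
  if (is.na(p) || p == "") return(NULL)
  read_mask(p, label, reference = vol)
}

#' Measure a sampled phantom cohort through the image pipeline
#'
#' Renders every subject of a [sample_cohort()] tibble, runs compartment
#' extraction and biomarker computation on the rendered image (never on the
#' sampled ground truth), and returns the per-subject records joined with the
#' generative truth (columns prefixed `true_`). Failures are quarantined as
#' in [run_cohort()].
#'
#' @param cohort A [sample_cohort()] tibble.
#' @inheritParams run_cohort
#' @return A tibble of lesion records with `genotype` and `true_*` columns.
#' @export
measure_phantom_cohort <- function(cohort, dilate_voxels = 2L,
                                   robust_peak = FALSE, k_abs = 1.8) {
  stopifnot(is.data.frame(cohort), "spec" %in% names(cohort))
  quarantine <- list()
  records <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- tryCatch({
      ph <- render_phantom(cohort$spec[[i]])
      set <- extract_compartments(ph$volume, ph$lesion,
                                  dilate_voxels = dilate_voxels,
                                  robust_peak = robust_peak, k_abs = k_abs)
      r <- lesion_record(ph$volume, set, subject_id = cohort$subject_id[i])
      r$genotype <- cohort$genotype[i]
      r$true_cu_volumetric <- cohort$volumetric_cu_true[i]
      r$true_cu_suv <- cohort$suv_cu_true[i]
      r$true_v_central <- cohort$v_central[i]
      r$true_v_peripheral <- cohort$v_peripheral[i]
      r$true_v_mtv60 <- cohort$v_mtv60[i]
      r
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      quarantine[[length(quarantine) + 1]] <- tibble::tibble(
        subject_id = cohort$subject_id[i], reason = conditionMessage(rec))
    } else {
      records[[length(records) + 1]] <- rec
    }
  }
  qt <- dplyr::bind_rows(quarantine)
  if (nrow(qt) > 0.1 * nrow(cohort)) {
    stop(sprintf("%d of %d phantoms failed (> 10%%): %s", nrow(qt), nrow(cohort),
                 paste(utils::head(qt$reason, 3), collapse = "; ")))
  }
  out <- dplyr::bind_rows(records)
  attr(out, "quarantine") <- qt
  out
}

#' Two-group biomarker comparison with summaries
#'
#' Mann-Whitney U (two-tailed) comparison of one biomarker between the two
#' levels of a label column, with per-group median and IQR (Q3 - Q1,
#' linear-interpolation type-7 quantiles).
#'
#' @param records A cohort tibble (e.g. from [run_cohort()]).
#' @param biomarker Biomarker column (tidy-eval).
#' @param label Two-level grouping column (tidy-eval).
#' @return A one-row `cu_htest` tibble (see [mann_whitney_u()]).
#' @export
group_compare <- function(records, biomarker, label) {
  mann_whitney_u(records, {{ biomarker }}, {{ label }}, tails = "two")
}

#' Stratified random split of a cohort
#'
#' Splits subjects into disjoint, exhaustive training and evaluation sets
#' with (approximately) the same class proportions on both sides. Default
#' sizes are an even split.
#'
#' @param records Cohort tibble.
#' @param label Class column (tidy-eval).
#' @param seed Integer seed.
#' @param n_train Training-set size (default: half the cohort, rounded up).
#' @return A list of class `split_plan`: `train_ids`, `eval_ids`,
#'   `stratify_on`, `seed`, `class_counts` (tibble).
#' @export
split_cohort <- function(records, label, seed = 1L, n_train = NULL) {
  lb <- as.character(dplyr::pull(records, {{ label }}))
  ids <- records$subject_id
  n <- length(ids)
  if (is.null(n_train)) n_train <- ceiling(n / 2)
  stopifnot(n_train >= 1, n_train < n)
  lv <- sort(unique(lb))
  withr::with_seed(seed, {
    train_ids <- character(0)
    # proportional allocation per class, largest-remainder rounding
    per_class <- table(lb)[lv]
    alloc <- per_class * n_train / n
    take <- floor(alloc)
    rem <- n_train - sum(take)
    if (rem > 0) {
      extra <- order(alloc - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    for (k in seq_along(lv)) {
      pool <- ids[lb == lv[k]]
      train_ids <- c(train_ids, sample(pool, take[k]))
    }
  })
  eval_ids <- setdiff(ids, train_ids)
  counts <- tibble::tibble(
    class = rep(lv, 2),
    side = rep(c("train", "eval"), each = length(lv)),
    n = c(vapply(lv, function(l) sum(lb[ids %in% train_ids] == l), 0L),
          vapply(lv, function(l) sum(lb[ids %in% eval_ids] == l), 0L))
  )
  structure(list(train_ids = train_ids, eval_ids = eval_ids,
                 stratify_on = rlang::as_name(rlang::enquo(label)),
                 seed = seed, class_counts = counts),
            class = "split_plan")
}

#' Genotyping experiment: split, train a threshold, evaluate it frozen
#'
#' Mirrors a two-stage biomarker evaluation: the cohort is randomly split
#' (stratified), the Youden-optimal threshold is determined on the training
#' side, and sensitivity/specificity/accuracy are reported on the evaluation
#' side at that frozen threshold. DeLong AUCs are reported for the training
#' side, the evaluation side and the whole cohort. A degenerate split
#' (either side missing a class) is reshuffled with an incremented sub-seed,
#' up to 25 retries.
#'
#' @param records Cohort tibble.
#' @param biomarker Score column (tidy-eval).
#' @param label Two-level class column (tidy-eval).
#' @param positive Positive class label (see [roc_delong()]).
#' @param seed Integer seed for the split.
#' @param n_train Training-set size (default: even split).
#' @return A list of class `cu_genotyping`: `split`, `train_roc`,
#'   `threshold`, `direction`, `eval_metrics`, `eval_roc`, `whole_roc`.
#' @export
genotyping_experiment <- function(records, biomarker, label, positive = NULL,
                                  seed = 1L, n_train = NULL) {
  lb <- as.character(dplyr::pull(records, {{ label }}))
  for (attempt in 0:25) {
    plan <- split_cohort(records, {{ label }}, seed = seed + attempt,
                         n_train = n_train)
    tr <- records[records$subject_id %in% plan$train_ids, ]
    ev <- records[records$subject_id %in% plan$eval_ids, ]
    ok <- length(unique(lb[records$subject_id %in% plan$train_ids])) == 2 &&
      length(unique(lb[records$subject_id %in% plan$eval_ids])) == 2
    if (ok) break
  }
  if (!ok) stop("could not find a split with both classes on both sides")
  train_roc <- roc_delong(tr, {{ biomarker }}, {{ label }}, positive = positive)
  eval_metrics <- evaluate_threshold(
    ev, {{ biomarker }}, {{ label }}, threshold = train_roc$threshold,
    direction = train_roc$direction, positive = positive)
  structure(
    list(split = plan,
         train_roc = train_roc,
         threshold = train_roc$threshold,
         direction = train_roc$direction,
         eval_metrics = eval_metrics,
         eval_roc = roc_delong(ev, {{ biomarker }}, {{ label }}, positive = positive),
         whole_roc = roc_delong(records, {{ biomarker }}, {{ label }},
                                positive = positive)),
    class = "cu_genotyping"
  )
}

#' End-to-end synthetic reproduction study
#'
#' Samples the calibrated two-genotype cohort, renders every phantom, runs
#' the full image pipeline (compartments, biomarkers), and performs the
#' statistical analysis: group comparisons of the main biomarkers, DeLong
#' ROC of each biomarker for genotype, and the split/threshold genotyping
#' experiment on the volumetric CU ratio. All numbers come from the rendered
#' images, never from the sampled ground truth.
#'
#' @param params A [cohort_params()]; its seed drives phantom sampling.
#' @param seed Optional integer overriding `params$seed`; also seeds the
#'   split (offset by 1).
#' @return A list of class `cu_study_report`: `records`, `group_comparisons`
#'   (tibble), `roc` (named list of `cu_roc`), `genotyping`, `params`,
#'   `seed`.
#' @export
reproduce_study <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) params$seed <- as.integer(seed)
  cohort <- sample_cohort(params)
  records <- measure_phantom_cohort(cohort)
  biomarkers <- c("cu_volumetric", "cu_suv", "tbr_mean",
                  "v_roi60_cm3", "v_roi80_cm3", "v_mtv60_cm3")
  comparisons <- purrr::map_dfr(biomarkers, function(b) {
    ht <- group_compare(records, !!rlang::sym(b), genotype)
    summ <- ht$summary[[1]]
    tibble::tibble(
      biomarker = b,
      median_mutant = summ$median[summ$group == "mutant"],
      iqr_mutant = summ$iqr[summ$group == "mutant"],
      median_wildtype = summ$median[summ$group == "wildtype"],
      iqr_wildtype = summ$iqr[summ$group == "wildtype"],
      u = ht$statistic, p_value = ht$p_value)
  })
  rocs <- purrr::map(biomarkers, function(b) {
    roc_delong(records, !!rlang::sym(b), genotype, positive = "mutant")
  })
  names(rocs) <- biomarkers
  genotyping <- genotyping_experiment(records, cu_volumetric, genotype,
                                      positive = "mutant",
                                      seed = params$seed + 1L)
  structure(
    list(records = records, group_comparisons = comparisons, roc = rocs,
         genotyping = genotyping, params = params, seed = params$seed),
    class = "cu_study_report"
  )
}

#' Write a study report to disk
#'
#' Serializes a [reproduce_study()] report: the per-subject records and the
#' group-comparison table as CSV, the ROC curve points of every biomarker as
#' one long CSV, and a JSON summary (AUCs with CIs, genotyping split result,
#' generator parameters, seed) with full numeric precision.
#'
#' @param report A `cu_study_report`.
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cu_study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$records, file.path(out_dir, "records.csv"))
  readr::write_csv(report$group_comparisons,
                   file.path(out_dir, "group_comparisons.csv"))
  curves <- purrr::imap_dfr(report$roc, function(r, nm) {
    dplyr::mutate(tidy(r), biomarker = nm, .before = 1)
  })
  readr::write_csv(curves, file.path(out_dir, "roc_curves.csv"))
  gt <- report$genotyping
  summary <- list(
    seed = report$seed,
    n_subjects = nrow(report$records),
    params = unclass(report$params),
    roc = purrr::map(report$roc, function(r) as.list(glance(r))),
    genotyping = list(
      train_ids = gt$split$train_ids,
      eval_ids = gt$split$eval_ids,
      threshold = gt$threshold,
      direction = gt$direction,
      train_auc = gt$train_roc$auc,
      eval_auc = gt$eval_roc$auc,
      whole_auc = gt$whole_roc$auc,
      eval_metrics = as.list(gt$eval_metrics)
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cu_study_report <- function(x, ...) {
  cat(sprintf("<cu_study_report> %d subjects (%d mutant / %d wildtype), seed %d\n",
              nrow(x$records), sum(x$records$genotype == "mutant"),
              sum(x$records$genotype == "wildtype"), x$seed))
  cat(sprintf("  volumetric CU ratio: median %.2f (mut) vs %.2f (wt), AUC %.3f\n",
              x$group_comparisons$median_mutant[1],
              x$group_comparisons$median_wildtype[1],
              x$roc$cu_volumetric$auc))
  cat(sprintf("  genotyping split: train threshold %.2f, eval accuracy %.2f\n",
              x$genotyping$threshold, x$genotyping$eval_metrics$accuracy))
  invisible(x)
}
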