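## End-to-end orchestration: mapping -> registration -> normalization ->
## lesion segmentation -> ROI statistics, plus the study report.

#' Synthetic structural template in atlas space
#'
#' Deterministic early-echo structural image computed from the atlas label
#' volume and nominal tissue T2s; the fixed image for subject-to-atlas
#' registration.
#'
#' @param atlas an \code{mri_atlas}
#' @param tissues healthy tissue table
#' @param s0 signal amplitude
#' @param te effective echo time in ms
#' @return a 3D array
#' @export
atlas_template <- function(atlas, tissues = default_tissues(), s0 = 1000,
                           te = 4.2) {
  img <- array(0, dim = atlas$dim)
  for (i in seq_len(nrow(tissues))) {
    m <- atlas$labels == atlas$label_names[[tissues$tissue[i]]]
    img[m] <- s0 * exp(-te / tissues$t2[i])
  }
  img
}

#' Estimate a brain mask from a series by signal thresholding
#'
#' Used when a series is not already in atlas space (so the phantom's
#' masks do not apply): voxels of the first frame above a quarter of the
#' 99th-percentile intensity are brain. Replaces the manual brain
#' extraction a real study would perform.
#'
#' @param series an \code{image_series}
#' @return logical mask
#' @export
estimate_brain_mask <- function(series) {
  v <- frame_volume(series$data, 1)
  th <- 0.25 * stats::quantile(v, 0.99, names = FALSE)
  v > th
}

pipeline_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    stop_ischemri(sprintf("pipeline stage '%s' failed for subject %s: %s",
                          stage, subject_id, conditionMessage(e)),
                  "ischemri_pipeline")
  })
}

#' Run the full analysis pipeline on a study bundle
#'
#' For every subject-timepoint record: fits quantitative T2 (first 20
#' echoes), ADC, the two-stage T1, and CASL CBF; registers the subject to
#' the atlas template when the record carries a misalignment (otherwise
#' the phantom is simulated in atlas space and the transform is the
#' identity); normalizes CBF by the contralateral-hemisphere mean;
#' segments the infarct on the quantitative T2 map. Group-level outputs
#' are Table-style summary cells (mean +/- SEM per group x ROI x
#' timepoint for CBF, ADC, qT2 and probability of infarction),
#' within-group probability maps, whole-brain volumetry, 2x2
#' repeated-measures ANOVAs (when the design is 2 groups x 2 timepoints),
#' and voxelwise permutation tests on normalized-CBF change maps in both
#' directions.
#'
#' @param study a \code{study_bundle} from \code{generate_study}, or a
#'   path to a directory written by \code{write_study}
#' @param lesion_cfg a \code{lesion_config}
#' @param casl a \code{casl_params}
#' @param n_perm permutations for the voxelwise tests
#' @param voxelwise logical: run the voxelwise permutation stage
#' @param anova_groups optional character vector of exactly two groups to
#'   enter the ANOVA (defaults to the first two with two timepoints)
#' @return a \code{study_report}
#' @export
run_pipeline <- function(study, lesion_cfg = lesion_config(),
                         casl = casl_params(), n_perm = 1000L,
                         voxelwise = TRUE, anova_groups = NULL) {
  if (is.character(study)) study <- read_study(study)
  assert_that(inherits(study, "study_bundle"), "expected a study_bundle")
  assert_that(length(study$records) > 0, "empty study bundle",
              "ischemri_manifest")
  cfg <- study$config
  atlas <- cfg$atlas
  template <- atlas_template(atlas, cfg$tissues, cfg$s0,
                             cfg$protocol$echo_spacing)
  obs <- list(); vol <- list()
  seg_masks <- list(); norm_maps <- list()
  for (ri in seq_along(study$records)) {
    rec <- study$records[[ri]]
    sid <- rec$subject_id
    brain <- rec$truth$masks$brain
    csf <- rec$truth$masks$csf

    ## registration: only exercised when a misalignment was applied
    xf <- rigid_transform(0, 0, 0)
    misaligned <- any(vapply(rec$series,
                             function(s) !is.null(s$misalignment), TRUE))
    if (misaligned) {
      ref_series <- rec$series$cpmg %||% rec$series[[1]]
      xf <- pipeline_stage("register", sid,
        register_rigid(ref_series, template, spacing = atlas$spacing))
    }
    to_atlas <- function(map) {
      if (!misaligned) return(map)
      resample(map, xf, interpolation = "linear")
    }

    maps <- list()
    if (!is.null(rec$series$cpmg)) {
      ft2 <- pipeline_stage("t2_fit", sid,
        fit_t2_monoexp(rec$series$cpmg,
                       mask = if (misaligned)
                         estimate_brain_mask(rec$series$cpmg) else brain))
      maps$t2 <- to_atlas(t2_map(ft2))
    }
    if (!is.null(rec$series$dwi)) {
      maps$adc <- pipeline_stage("adc", sid,
        to_atlas(compute_adc(rec$series$dwi,
                             mask = if (misaligned)
                               estimate_brain_mask(rec$series$dwi) else brain)))
    }
    if (!is.null(rec$series$ir) && !is.null(rec$series$casl)) {
      ir_mask <- if (misaligned) estimate_brain_mask(rec$series$ir) else brain
      fit3 <- pipeline_stage("t1_fit", sid,
        fit_t1_three_param(rec$series$ir, mask = ir_mask))
      bb <- pipeline_stage("t1_fit", sid,
        estimate_inversion_efficiency(fit3, fit3$mask))
      fit2 <- pipeline_stage("t1_fit", sid,
        fit_t1_two_param(rec$series$ir, bb, mask = ir_mask))
      cbf <- pipeline_stage("cbf", sid,
        compute_cbf(rec$series$casl, fit2, params = casl))
      maps$cbf <- to_atlas(cbf)
      maps$cbf_norm <- pipeline_stage("normalize", sid,
        normalize_cbf(maps$cbf, atlas$masks$contralateral & !atlas$masks$csf))
      key <- sprintf("%s|%s", rec$group, rec$timepoint)
      norm_maps[[key]] <- c(norm_maps[[key]] %||% list(),
                            stats::setNames(list(maps$cbf_norm), sid))
    }

    quantities <- list(cbf = "cbf", adc = "adc", t2 = "t2")
    for (q in names(quantities)) {
      if (is.null(maps[[q]])) next
      for (roi in names(atlas$rois)) {
        s <- pipeline_stage("roi_summary", sid,
                            roi_summary(maps[[q]], atlas, roi))
        obs[[length(obs) + 1L]] <- data.frame(
          subject = sid, group = rec$group, timepoint = rec$timepoint,
          roi = roi, quantity = q, value = s$mean, sd = s$sd, n_voxels = s$n,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(maps$t2)) {
      seg <- pipeline_stage("segment", sid,
        segment_infarct(maps$t2, lesion_cfg, atlas$masks$brain,
                        atlas$masks$csf))
      key <- sprintf("%s|%s", rec$group, rec$timepoint)
      seg_masks[[key]] <- c(seg_masks[[key]] %||% list(),
                            stats::setNames(list(seg), sid))
      for (roi in names(atlas$rois)) {
        obs[[length(obs) + 1L]] <- data.frame(
          subject = sid, group = rec$group, timepoint = rec$timepoint,
          roi = roi, quantity = "pinf",
          value = 100 * mean(seg[atlas$rois[[roi]]]),
          sd = NA_real_, n_voxels = sum(atlas$rois[[roi]]),
          stringsAsFactors = FALSE)
      }
      vol[[length(vol) + 1L]] <- data.frame(
        subject = sid, group = rec$group, timepoint = rec$timepoint,
        infarct_percent = infarct_volume_fraction(seg, atlas$masks$brain),
        stringsAsFactors = FALSE)
    }
  }
  roi_table <- do.call(rbind, obs)
  volumetry <- if (length(vol)) do.call(rbind, vol) else NULL

  ## summary cells: mean +/- SEM over subjects
  agg <- stats::aggregate(value ~ group + timepoint + roi + quantity,
                          data = roi_table, FUN = mean)
  sem <- stats::aggregate(value ~ group + timepoint + roi + quantity,
                          data = roi_table,
                          FUN = function(v) stats::sd(v) / sqrt(length(v)))
  nsub <- stats::aggregate(value ~ group + timepoint + roi + quantity,
                           data = roi_table, FUN = length)
  cells <- agg
  names(cells)[names(cells) == "value"] <- "mean"
  cells$sem <- sem$value
  cells$n <- nsub$value

  ## probability maps per group x timepoint
  prob_maps <- lapply(seg_masks, probability_map)
  for (k in names(prob_maps)) prob_maps[[k]]$group <- k

  ## repeated-measures ANOVA where the 2x2 design applies
  anovas <- list()
  two_tp_groups <- names(cfg$groups)[vapply(cfg$groups,
    function(g) length(g$timepoints) == 2, TRUE)]
  ag <- anova_groups %||% utils::head(two_tp_groups, 2)
  if (length(ag) == 2 &&
      identical(cfg$groups[[ag[1]]]$timepoints, cfg$groups[[ag[2]]]$timepoints)) {
    sub <- roi_table[roi_table$group %in% ag & roi_table$quantity != "pinf", ]
    for (q in unique(sub$quantity)) for (roi in unique(sub$roi)) {
      d <- sub[sub$quantity == q & sub$roi == roi, ]
      if (nrow(d) == 0) next
      tb <- data.frame(subject = d$subject, group = d$group,
                       time = d$timepoint, value = d$value)
      anovas[[sprintf("%s|%s", q, roi)]] <- rm_anova_2x2(tb)
    }
  }

  ## voxelwise change tests on normalized CBF, per group, both directions
  voxel <- list()
  if (voxelwise && length(norm_maps)) {
    for (g in names(cfg$groups)) {
      tps <- cfg$groups[[g]]$timepoints
      if (length(tps) != 2) next
      k1 <- sprintf("%s|%s", g, tps[1]); k2 <- sprintf("%s|%s", g, tps[2])
      if (is.null(norm_maps[[k1]]) || is.null(norm_maps[[k2]])) next
      ids <- intersect(names(norm_maps[[k1]]), names(norm_maps[[k2]]))
      if (length(ids) < 3) next
      diffs <- lapply(ids, function(id) {
        a <- norm_maps[[k1]][[id]]; b <- norm_maps[[k2]][[id]]
        parameter_map(b$values - a$values, "CBFratio",
                      a$mask & b$mask, a$spacing)
      })
      for (dir in c("increase", "decrease")) {
        voxel[[sprintf("%s|%s", g, dir)]] <-
          voxelwise_change_test(diffs, mask = atlas$masks$brain & !atlas$masks$csf,
                                direction = dir, n_perm = n_perm,
                                seed = derive_seed(cfg$seed, 31L))
      }
    }
  }

  report <- structure(list(
    cells = cells, roi_table = roi_table, volumetry = volumetry,
    anova = anovas, voxelwise = voxel, probability_maps = prob_maps,
    provenance = list(seed = cfg$seed,
                      config_hash = object_hash(cfg[setdiff(names(cfg), "atlas")]),
                      version = as.character(utils::packageVersion("ischemri")))
  ), class = "study_report")
  report$hash <- object_hash(list(report$cells, report$roi_table,
                                  report$volumetry))
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d cells, %d ANOVAs, %d voxelwise tests, hash %s>\n",
              nrow(x$cells), length(x$anova), length(x$voxelwise), x$hash))
  invisible(x)
}

#' Write a study report as JSON plus long-format TSV tables
#'
#' @param report a \code{study_report}
#' @param dir output directory
#' @return \code{dir}, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$roi_table, file.path(dir, "roi_values.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$volumetry))
    utils::write.table(report$volumetry, file.path(dir, "volumetry.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  json <- list(cells = report$cells,
               anova = lapply(report$anova, function(a)
                 lapply(a$effects, function(e) e[c("F", "df1", "df2", "p")])),
               volumetry = report$volumetry,
               provenance = report$provenance, hash = report$hash)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' Read a study bundle written by \code{write_study}
#'
#' Reconstructs the bundle (series, truth maps, atlas-derived masks) from
#' the manifest, config and per-record files.
#'
#' @param dir directory written by \code{write_study}
#' @return a \code{study_bundle}
#' @export
read_study <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.json"))
  cfg <- read_config_yaml(file.path(dir, "config.yaml"))
  atlas <- cfg$atlas
  records <- lapply(man$records, function(e) {
    sub <- file.path(dir, sprintf("%s_%s", e$subject_id, e$timepoint))
    series <- lapply(e$series, function(p) read_series(p))
    truth <- list(masks = atlas$masks, rois = atlas$rois,
                  labels = atlas$labels, spacing = atlas$spacing,
                  s0 = cfg$s0, group = e$group, timepoint = e$timepoint)
    for (m in c("t1", "t2", "adc", "cbf")) {
      p <- file.path(sub, sprintf("truth_%s.nii.gz", m))
      if (file.exists(p)) truth[[m]] <- read_map(p)$values
    }
    class(truth) <- "ground_truth"
    list(subject_id = e$subject_id, group = e$group,
         timepoint = e$timepoint, truth = truth, series = series)
  })
  rows <- do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$subject_id, group = r$group,
               timepoint = r$timepoint,
               series = paste(names(r$series), collapse = ","),
               stringsAsFactors = FALSE)))
  structure(list(records = records, manifest = rows, config = cfg),
            class = "study_bundle")
}
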