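## Ground-truth construction: per-subject true parameter maps, tissue
## labels, lesion geometry and the subject-level variability model.

## Resolve the lesion-extent specification for one group (and timepoint).
## Returns a function of a uniform quantile u in (0,1) -> extent in [0,1],
## so the same subject-level u yields coherent extents across timepoints.
lesion_extent_fn <- function(config, group, timepoint) {
  fr <- config$lesion$fraction
  spec <- if (is.list(fr) && is.null(fr$type)) {
    fr[[group]] %||% fr[[timepoint]] %||% fr[["default"]] %||% 1
  } else fr
  if (is.numeric(spec)) {
    e <- spec[[1]]
    function(u) e
  } else if (identical(spec$type, "fixed")) {
    function(u) spec$value
  } else if (identical(spec$type, "beta")) {
    m <- spec$mean; k <- spec$conc %||% 10
    a <- m * k; b <- (1 - m) * k
    function(u) stats::qbeta(u, a, b)
  } else stop_ischemri("unknown lesion fraction spec", "ischemri_config")
}

## Affected-region mask: extent fraction e of the MCA territory, grown as a
## contiguous region from a deep (subcortical) seed outward, so partial
## lesions cover the subcortex before the cortical mantle (the
## cortico-subcortical infarct-probability gradient).
grow_lesion <- function(atlas, extent) {
  terr <- atlas$masks$territory
  if (extent >= 1) return(terr)
  if (extent <= 0) return(terr & FALSE)
  idx <- which(terr)
  d <- atlas$dim
  xy <- arrayInd(idx, d)
  sub <- atlas$rois$subcortical
  seed <- colMeans(arrayInd(which(sub), d))
  r <- sqrt((xy[, 1] - seed[1])^2 + (xy[, 2] - seed[2])^2)
  k <- max(1L, round(extent * length(idx)))
  keep <- idx[order(r)[seq_len(k)]]
  out <- terr & FALSE
  out[keep] <- TRUE
  out
}

lookup_cell <- function(cells, group, time, roi, quantity) {
  if (is.null(cells)) return(NULL)
  r <- cells[cells$group == group & cells$time == time &
             cells$roi == roi & cells$quantity == quantity, , drop = FALSE]
  if (nrow(r) == 0) return(NULL)
  list(mean = r$mean[1], sd = r$sd[1])
}

#' Build the ground truth for one subject at one timepoint
#'
#' Draws the subject's parameter state and lesion geometry and assembles
#' the true voxelwise T1/T2/ADC/CBF maps. Subject-level variability uses
#' one standard-normal draw per quantity, shared across ROIs and
#' timepoints (it depends only on \code{subject_seed}): T2 and ADC cells
#' vary additively (\code{mean + z * sd}), CBF varies through a shared
#' multiplicative perfusion factor so that ipsilateral/contralateral
#' ratios are stable across subjects, and healthy tissue receives a small
#' proportional jitter. Inside the affected MCA territory each ROI carries
#' its configured outcome-cell values; elsewhere tissue carries healthy
#' values. The truth infarct mask is the affected region where true T2
#' exceeds the segmentation threshold.
#'
#' @param config a \code{phantom_config}
#' @param group group label, must be present in \code{config$groups}
#' @param timepoint timepoint label
#' @param subject_seed integer seed identifying the subject
#' @return a \code{ground_truth} object with maps \code{t1} (s), \code{t2}
#'   (ms), \code{adc} (mm^2/s), \code{cbf} (ml/100 g/min), the tissue label
#'   volume, hemisphere/ROI/territory/lesion masks and subject metadata
#' @export
build_truth <- function(config, group, timepoint, subject_seed) {
  if (!group %in% names(config$groups))
    stop_ischemri(sprintf("unknown group '%s'", group), "ischemri_lookup")
  if (!timepoint %in% config$groups[[group]]$timepoints)
    stop_ischemri(sprintf("timepoint '%s' not defined for group '%s'",
                          timepoint, group), "ischemri_lookup")
  atlas <- config$atlas
  set.seed(derive_seed(subject_seed, 11L))
  z <- stats::rnorm(4)
  names(z) <- c("t2", "adc", "cbf", "t1")
  u_extent <- stats::runif(1)

  extent <- lesion_extent_fn(config, group, timepoint)(u_extent)
  affected <- grow_lesion(atlas, extent)

  cvh <- config$subject_cv_healthy
  ## reference CV for the global perfusion factor: the group's ipsilateral
  ## cortical CBF cell at this timepoint, falling back to 12%
  ref <- lookup_cell(config$cells, group, timepoint, "cortical_mca", "cbf")
  cv_cbf <- if (!is.null(ref) && ref$mean > 0) ref$sd / ref$mean else 0.12
  g_cbf <- max(0, 1 + z[["cbf"]] * cv_cbf)

  d <- atlas$dim
  lab <- atlas$labels
  t1 <- t2 <- adcm <- cbf <- array(0, dim = d)
  for (i in seq_len(nrow(config$tissues))) {
    ti <- config$tissues[i, ]
    m <- lab == atlas$label_names[[ti$tissue]]
    t1[m]  <- ti$t1 * (1 + z[["t1"]] * cvh)
    t2[m]  <- ti$t2 * (1 + z[["t2"]] * cvh)
    adcm[m] <- ti$adc * (1 + z[["adc"]] * cvh)
    cbf[m] <- ti$cbf * g_cbf
  }

  if (identical(config$lesion$mode, "sector")) {
    lv <- config$lesion$values
    t1[affected] <- lv$t1; t2[affected] <- lv$t2
    adcm[affected] <- lv$adc; cbf[affected] <- lv$cbf * g_cbf
  } else {
    for (roi in names(atlas$rois)) {
      m <- affected & atlas$rois[[roi]]
      if (!any(m)) next
      cz <- list(t2 = NULL, adc = NULL, cbf = NULL)
      cell <- lookup_cell(config$cells, group, timepoint, roi, "t2")
      if (!is.null(cell)) t2[m] <- max(1e-6, cell$mean + z[["t2"]] * cell$sd)
      cell <- lookup_cell(config$cells, group, timepoint, roi, "adc")
      if (!is.null(cell)) adcm[m] <- max(0, cell$mean + z[["adc"]] * cell$sd)
      cell <- lookup_cell(config$cells, group, timepoint, roi, "cbf")
      if (!is.null(cell)) {
        cvc <- if (cell$mean > 0) cell$sd / cell$mean else 0
        cbf[m] <- max(0, cell$mean * (1 + z[["cbf"]] * cvc))
      }
    }
  }

  lesion <- affected & (t2 > config$lesion$t2_threshold)
  structure(list(
    t1 = t1, t2 = t2, adc = adcm, cbf = cbf,
    labels = lab,
    masks = c(atlas$masks, list(lesion = lesion, affected = affected)),
    rois = atlas$rois,
    spacing = atlas$spacing,
    s0 = config$s0,
    group = group, timepoint = timepoint,
    subject_seed = subject_seed,
    extent = extent, z = z,
    misalignment = NULL
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth %s/%s, lesion %d voxels (extent %.2f)>\n",
              x$group, x$timepoint, sum(x$masks$lesion), x$extent))
  invisible(x)
}
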