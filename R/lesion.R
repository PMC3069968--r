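#' Lesion segmentation configuration
#'
#' @param threshold quantitative-T2 segmentation threshold in ms (default
#'   34): voxels with T2 strictly greater than the threshold are infarct
#' @param sweep strictly increasing vector of thresholds for
#'   \code{threshold_sweep}
#' @param min_cluster optional minimum connected-component size (voxels);
#'   0 disables size filtering (the default; no filtering is part of the
#'   segmentation definition)
#' @return a \code{lesion_config}
#' @export
lesion_config <- function(threshold = 34, sweep = seq(30, 44, by = 2),
                          min_cluster = 0L) {
  assert_that(threshold > 0, "threshold must be positive")
  assert_that(all(sweep > 0) && all(diff(sweep) > 0),
              "sweep thresholds must be positive and strictly increasing")
  structure(list(threshold = threshold, sweep = sweep,
                 min_cluster = as.integer(min_cluster)),
            class = "lesion_config")
}

## 4-connected component filter (in-plane), used only when min_cluster > 0.
filter_clusters <- function(mask, min_cluster) {
  if (min_cluster <= 0) return(mask)
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 1L
  idx <- which(mask)
  for (i in idx) {
    if (lab[i] > 0L) next
    queue <- i; lab[i] <- nxt
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      pos <- arrayInd(j, d)
      for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        p <- pos[1:2] + off
        if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2]) next
        k <- p[1] + (p[2] - 1) * d[1] + (pos[3] - 1) * d[1] * d[2]
        if (mask[k] && lab[k] == 0L) { lab[k] <- nxt; queue <- c(queue, k) }
      }
    }
    nxt <- nxt + 1L
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_cluster)
  array(lab %in% keep, dim = d)
}

#' Threshold-based infarct segmentation on a quantitative T2 map
#'
#' Infarct voxels are those with T2 strictly greater than the threshold,
#' inside the brain mask, with CSF voxels removed. The T2 map must be in
#' milliseconds (brain values are range-checked against 1--500 ms).
#'
#' @param t2_map a \code{parameter_map} of kind \code{"T2"} (ms)
#' @param config a \code{lesion_config}
#' @param brain_mask logical brain mask
#' @param csf_mask logical CSF mask to exclude
#' @return logical lesion mask
#' @export
segment_infarct <- function(t2_map, config = lesion_config(),
                            brain_mask, csf_mask = NULL) {
  assert_that(identical(t2_map$kind, "T2"), "expected a T2 map")
  brain_mask <- as_volume(brain_mask)
  assert_that(all(dim(brain_mask) == dim(t2_map$values)),
              "masks and map must share one grid", "ischemri_grid")
  check <- t2_map$values[brain_mask & t2_map$mask]
  if (length(check) && (stats::median(check) < 1 || stats::median(check) > 500))
    stop_ischemri("T2 values inconsistent with milliseconds (range 1-500)",
                  "ischemri_units")
  m <- brain_mask & t2_map$mask & (t2_map$values > config$threshold)
  if (!is.null(csf_mask)) m <- m & !as_volume(csf_mask)
  m[is.na(m)] <- FALSE
  filter_clusters(m, config$min_cluster)
}

#' Segmentations over a sweep of increasing T2 thresholds
#'
#' One binary mask per sweep threshold; by construction the masks are
#' nested (each higher threshold's mask is a subset of the lower one's).
#'
#' @inheritParams segment_infarct
#' @return named list of logical masks, one per threshold
#' @export
threshold_sweep <- function(t2_map, config = lesion_config(),
                            brain_mask, csf_mask = NULL) {
  out <- lapply(config$sweep, function(th) {
    segment_infarct(t2_map, lesion_config(threshold = th,
                                          min_cluster = config$min_cluster),
                    brain_mask, csf_mask)
  })
  names(out) <- sprintf("t2_%g", config$sweep)
  out
}

#' Within-group probability-of-infarction map
#'
#' Voxelwise mean of the subjects' binary segmentations; the value at a
#' voxel is the fraction of animals in the group whose infarct includes
#' it. ROI probabilities are ROI means of this map times 100.
#'
#' @param lesion_masks list of logical masks on identical grids
#' @param group group label carried in the result
#' @return a \code{probability_map}: \code{prob} in [0,1], subject count
#'   \code{n}, \code{group}
#' @export
probability_map <- function(lesion_masks, group = NA_character_) {
  assert_that(length(lesion_masks) >= 1, "need at least one mask")
  d <- dim(as_volume(lesion_masks[[1]]))
  acc <- array(0, dim = d)
  for (m in lesion_masks) {
    m <- as_volume(m)
    if (!all(dim(m) == d))
      stop_ischemri("lesion masks on different grids", "ischemri_grid")
    acc <- acc + (m > 0)
  }
  structure(list(prob = acc / length(lesion_masks),
                 n = length(lesion_masks), group = group),
            class = "probability_map")
}

#' Infarct volume as percent of whole-brain volume
#'
#' @param lesion_mask logical infarct mask
#' @param brain_mask logical brain mask on the same grid
#' @return percent of brain voxels that are infarcted
#' @export
infarct_volume_fraction <- function(lesion_mask, brain_mask) {
  lesion_mask <- as_volume(lesion_mask); brain_mask <- as_volume(brain_mask)
  assert_that(all(dim(lesion_mask) == dim(brain_mask)),
              "masks must share one grid", "ischemri_grid")
  nb <- sum(brain_mask)
  if (nb == 0) stop_ischemri("empty brain mask", "ischemri_mask")
  100 * sum(lesion_mask & brain_mask) / nb
}

#' Dice overlap between two binary masks
#' @param a,b logical masks on one grid
#' @return Dice coefficient in [0, 1]
#' @export
dice_coefficient <- function(a, b) {
  a <- as_volume(a) > 0; b <- as_volume(b) > 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
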