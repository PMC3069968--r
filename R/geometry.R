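#' Synthetic atlas space for the two-hemisphere mouse brain phantom
#'
#' Builds the reference geometry on which every phantom subject, parameter
#' map and statistical map lives: a single coronal slab centred at bregma
#' with an elliptical brain outline, a deep-grey (subcortical) core, two
#' ventricles (CSF), and atlas-defined regions of interest -- the cortical
#' ROI in the centre of the middle-cerebral-artery (MCA) territory and the
#' subcortical ROI (caudoputamen + pyramidal tract). The right hemisphere is
#' ipsilateral to the occlusion; the midline is the central sagittal plane,
#' so left/right masks are exact mirror images.
#'
#' @param n in-plane matrix size, default \code{c(64, 64)} (FOV 18 mm)
#' @param spacing voxel spacing in mm \code{c(dx, dy, dz)}; default
#'   \code{c(18/64, 18/64, 1.5)} for the 1.5 mm slab
#' @return an object of class \code{mri_atlas}: integer label volume
#'   (0 background, 1 cortex, 2 subcortex, 3 CSF), named ROI masks,
#'   hemisphere masks, the MCA-territory mask and grid metadata
#' @export
default_atlas <- function(n = c(64L, 64L), spacing = c(18 / n[1], 18 / n[2], 1.5)) {
  nx <- as.integer(n[1]); ny <- as.integer(n[2])
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  # semi-axes scale with matrix size so coarser test grids stay proportionate
  sx <- nx / 64; sy <- ny / 64
  ell <- function(x0, y0, a, b) ((x - x0) / a)^2 + ((y - y0) / b)^2 <= 1

  brain <- ell(cx, cy, 22 * sx, 25 * sy)
  deep  <- ell(cx, cy, 12 * sx, 14 * sy)
  vent  <- ell(cx - 4.5 * sx, cy + 4 * sy, 2.2 * sx, 4.5 * sy) |
           ell(cx + 4.5 * sx, cy + 4 * sy, 2.2 * sx, 4.5 * sy)
  csf <- vent & brain
  subcortex <- deep & !csf
  cortex <- brain & !deep

  ipsi <- brain & (x > cx)   # right hemisphere
  contra <- brain & (x < cx)

  ang <- atan2(y - cy, x - cx) * 180 / pi   # 0 deg = lateral-right
  roi_cortex <- cortex & ipsi & abs(ang) <= 55
  roi_subcortex <- subcortex & ipsi
  territory <- roi_cortex | roi_subcortex

  labels <- array(0L, dim = c(nx, ny, 1L))
  labels[, , 1][cortex] <- 1L
  labels[, , 1][subcortex] <- 2L
  labels[, , 1][csf] <- 3L

  to_vol <- function(m) { a <- array(m, dim = c(nx, ny, 1L)); a }
  atlas <- structure(list(
    labels = labels,
    label_names = c(background = 0L, cortex = 1L, subcortex = 2L, csf = 3L),
    rois = list(
      cortical_mca = to_vol(roi_cortex),
      subcortical  = to_vol(roi_subcortex)
    ),
    masks = list(
      brain = to_vol(brain),
      csf = to_vol(csf),
      ipsilateral = to_vol(ipsi),
      contralateral = to_vol(contra),
      territory = to_vol(territory)
    ),
    spacing = spacing,
    dim = c(nx, ny, 1L),
    centre = c(cx, cy),
    grid_id = sprintf("slab-%dx%d", nx, ny)
  ), class = "mri_atlas")
  atlas
}

#' Mirror a mask or map across the atlas midline
#'
#' @param a a slab array (or matrix) defined on the atlas grid
#' @return the array flipped across the central sagittal plane
#' @export
mirror_mask <- function(a) mirror_x(as_volume(a))

#' @export
print.mri_atlas <- function(x, ...) {
  cat(sprintf("<mri_atlas %s, spacing %.3fx%.3fx%.2f mm>\n",
              x$grid_id, x$spacing[1], x$spacing[2], x$spacing[3]))
  for (r in names(x$rois))
    cat(sprintf("  ROI %-14s %5d voxels\n", r, sum(x$rois[[r]])))
  invisible(x)
}
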