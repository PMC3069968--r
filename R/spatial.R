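## Rigid in-plane registration and atlas-space ROI extraction.
##
## The acquisition geometry is a single coronal slab, so the rigid model is
## the 2D case: one rotation about the grid centre plus two in-plane
## translations (applied slicewise to multi-slice stacks). Angles are
## stored in degrees, translations in mm.

#' Rigid (in-plane) transform
#'
#' @param theta rotation in degrees (counter-clockwise about the grid
#'   centre)
#' @param tx,ty translations in mm
#' @param fixed_grid,moving_grid optional grid identifiers
#' @return a \code{rigid_transform}
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0,
                            fixed_grid = NULL, moving_grid = NULL) {
  structure(list(theta = theta, tx = tx, ty = ty,
                 fixed_grid = fixed_grid, moving_grid = moving_grid),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform theta %.4f deg, t (%.4f, %.4f) mm>\n",
              x$theta, x$tx, x$ty))
  invisible(x)
}

#' Compose two rigid transforms (apply \code{a} first, then \code{b})
#' @param a,b \code{rigid_transform}s
#' @return their composition as a \code{rigid_transform}
#' @export
compose_transform <- function(a, b) {
  thb <- b$theta * pi / 180
  R <- matrix(c(cos(thb), sin(thb), -sin(thb), cos(thb)), 2, 2)
  t_ab <- R %*% c(a$tx, a$ty) + c(b$tx, b$ty)
  rigid_transform(a$theta + b$theta, t_ab[1], t_ab[2],
                  fixed_grid = b$fixed_grid, moving_grid = a$moving_grid)
}

#' Invert a rigid transform
#' @param x a \code{rigid_transform}
#' @return the inverse \code{rigid_transform}
#' @export
invert_transform <- function(x) {
  th <- -x$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_inv <- -R %*% c(x$tx, x$ty)
  rigid_transform(-x$theta, t_inv[1], t_inv[2],
                  fixed_grid = x$moving_grid, moving_grid = x$fixed_grid)
}

## Resample one slice under a rigid transform. out(x) = in(T^{-1}(x)).
## Coordinates are mm relative to the grid centre.
resample_slice <- function(slice, theta, tx, ty, spacing, interpolation) {
  nx <- nrow(slice); ny <- ncol(slice)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  gx <- (matrix(seq_len(nx), nx, ny) - cx) * spacing[1]
  gy <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy) * spacing[2]
  th <- -theta * pi / 180   # inverse rotation
  px <- gx - tx; py <- gy - ty
  sx <- (cos(th) * px - sin(th) * py) / spacing[1] + cx
  sy <- (sin(th) * px + cos(th) * py) / spacing[2] + cy
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    out <- matrix(NA_real_, nx, ny)
    out[ok] <- slice[cbind(ix[ok], iy[ok])]
    return(out)
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  out <- matrix(NA_real_, nx, ny)
  i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
  i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
  w00 <- (1 - fx[ok]) * (1 - fy[ok]); w10 <- fx[ok] * (1 - fy[ok])
  w01 <- (1 - fx[ok]) * fy[ok]; w11 <- fx[ok] * fy[ok]
  out[ok] <- slice[i00] * w00 + slice[i10] * w10 +
             slice[i01] * w01 + slice[i11] * w11
  out
}

#' Resample an image or series under a rigid transform
#'
#' Expresses the input on the (same-sized) target grid after applying the
#' transform: \code{out(x) = in(T^{-1}(x))}. Linear interpolation for
#' continuous maps; nearest-neighbour (label-preserving) for masks. An
#' exact identity transform returns the input unchanged. Voxels pulled
#' from outside the field of view become \code{na_value}.
#'
#' @param x a 2D/3D array, an \code{image_series}, or a
#'   \code{parameter_map}
#' @param transform a \code{rigid_transform}
#' @param spacing voxel spacing (taken from the object when it carries one)
#' @param interpolation \code{"linear"} or \code{"nearest"}
#' @param na_value fill value for out-of-view voxels
#' @return object of the same class, resampled
#' @export
resample <- function(x, transform, spacing = NULL,
                     interpolation = c("linear", "nearest"),
                     na_value = NA_real_) {
  interpolation <- match.arg(interpolation)
  if (inherits(x, "image_series")) {
    out <- x
    for (k in seq_len(n_frames(x)))
      out$data[, , , k] <- resample(frame_volume(x$data, k), transform,
                                    x$spacing, interpolation, na_value)
    return(out)
  }
  if (inherits(x, "parameter_map")) {
    vals <- resample(x$values, transform, x$spacing, interpolation, na_value)
    msk <- resample(x$mask * 1, transform, x$spacing, "nearest", 0) > 0
    msk <- msk & is.finite(vals)
    return(parameter_map(vals, x$kind, msk, x$spacing))
  }
  a <- as_volume(x)
  if (transform$theta == 0 && transform$tx == 0 && transform$ty == 0)
    return(a)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  out <- array(NA_real_, dim = dim(a))
  for (z in seq_len(dim(a)[3]))
    out[, , z] <- resample_slice(a[, , z], transform$theta, transform$tx,
                                 transform$ty, spacing, interpolation)
  out[is.na(out)] <- na_value
  out
}

#' Apply a known rigid misalignment to a simulated series
#'
#' Resamples every frame under the given transform and records the
#' transform so registration can be validated against it. Background is
#' filled with zero (air).
#'
#' @param series an \code{image_series}
#' @param transform a \code{rigid_transform}; rotation within +/-15
#'   degrees, translation within +/-5 voxels
#' @param truth optional \code{ground_truth} to record the transform on
#' @return the misaligned series (and, if given, the updated truth via
#'   attribute \code{"truth"})
#' @export
apply_known_misalignment <- function(series, transform, truth = NULL) {
  assert_that(abs(transform$theta) <= 15,
              "rotation outside +/-15 degrees", "ischemri_bounds")
  maxt <- 5 * max(series$spacing[1:2])
  assert_that(abs(transform$tx) <= maxt && abs(transform$ty) <= maxt,
              "translation outside +/-5 voxels", "ischemri_bounds")
  out <- resample(series, transform, interpolation = "linear", na_value = 0)
  out$misalignment <- transform
  if (!is.null(truth)) {
    truth$misalignment <- transform
    attr(out, "truth") <- truth
  }
  out
}

block_downsample <- function(m, f) {
  if (f == 1) return(m)
  nx <- floor(nrow(m) / f) * f; ny <- floor(ncol(m) / f) * f
  m <- m[seq_len(nx), seq_len(ny)]
  # block means along x, then along y (column-major reshape trick)
  m1 <- matrix(colMeans(matrix(m, f, length(m) / f)), nx / f, ny)
  t(matrix(colMeans(matrix(t(m1), f, length(m1) / f)), ny / f, nx / f))
}

ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den <= 0) return(NA_real_)
  sum(a * b) / den
}

#' Rigid registration by normalized cross-correlation
#'
#' Deterministic multi-resolution rigid registration of a moving slab to a
#' fixed slab: an exhaustive coarse search at 4x downsampling followed by
#' Nelder-Mead refinement of 1 - NCC at 4x, 2x and full resolution. The
#' returned transform maps the moving image onto the fixed grid, i.e.
#' \code{resample(moving, transform)} aligns with \code{fixed}.
#'
#' @param moving,fixed 2D/3D arrays or \code{image_series} (first frame
#'   used); same grid size
#' @param spacing voxel spacing in mm
#' @param max_theta,max_shift search bounds (degrees / voxels)
#' @return a \code{rigid_transform}
#' @export
register_rigid <- function(moving, fixed, spacing = NULL,
                           max_theta = 16, max_shift = 6) {
  if (inherits(moving, "image_series")) {
    spacing <- spacing %||% moving$spacing
    moving <- moving$data[, , 1, 1]
  }
  if (inherits(fixed, "image_series")) fixed <- fixed$data[, , 1, 1]
  moving <- as_volume(moving)[, , 1]
  fixed <- as_volume(fixed)[, , 1]
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (!any(is.finite(moving)) || !any(is.finite(fixed)) ||
      sum(fixed != 0, na.rm = TRUE) == 0 || sum(moving != 0, na.rm = TRUE) == 0)
    stop_ischemri("empty image in registration", "ischemri_registration")
  overlap <- sum(moving != 0 & fixed != 0, na.rm = TRUE) /
             max(1, sum(fixed != 0, na.rm = TRUE))
  if (overlap < 0.10)
    stop_ischemri("less than 10% initial overlap", "ischemri_registration")

  cost_at <- function(mov_l, fix_l, sp_l) {
    function(p) {
      w <- resample_slice(mov_l, p[1], p[2], p[3], sp_l, "linear")
      v <- ncc(w, fix_l)
      if (is.na(v)) 2 else 1 - v
    }
  }
  levels <- c(4L, 2L, 1L)
  p <- c(0, 0, 0)
  for (li in seq_along(levels)) {
    f <- levels[li]
    mov_l <- block_downsample(moving, f)
    fix_l <- block_downsample(fixed, f)
    sp_l <- spacing[1:2] * f
    cost <- cost_at(mov_l, fix_l, sp_l)
    if (li == 1L) {
      ## exhaustive coarse search
      smax <- max_shift * spacing[1]
      grid <- expand.grid(theta = seq(-max_theta, max_theta, by = 2),
                          tx = seq(-smax, smax, length.out = 9),
                          ty = seq(-smax, smax, length.out = 9))
      vals <- apply(grid, 1, cost)
      p <- as.numeric(grid[which.min(vals), ])
    }
    for (rep in 1:2) {
      o <- stats::optim(p, cost, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-12))
      p <- o$par
    }
  }
  rigid_transform(p[1], p[2], p[3])
}

#' Centre of mass of an image (voxel units)
#' @param a array or matrix of non-negative intensities
#' @return c(x, y) centroid in voxel coordinates
#' @export
image_centroid <- function(a) {
  a <- as_volume(a)[, , 1]
  a[!is.finite(a)] <- 0
  w <- sum(a)
  c(sum(row(a) * a), sum(col(a) * a)) / w
}

#' Summarize a parameter map over an atlas ROI
#'
#' @param map a \code{parameter_map} in atlas space
#' @param atlas an \code{mri_atlas}
#' @param roi_name name of an atlas ROI
#' @return list with \code{mean}, \code{sd} and voxel count \code{n}
#' @export
roi_summary <- function(map, atlas, roi_name) {
  assert_that(roi_name %in% names(atlas$rois),
              sprintf("unknown ROI '%s'", roi_name), "ischemri_roi")
  m <- atlas$rois[[roi_name]] & map$mask
  if (!any(m)) stop_ischemri("ROI does not intersect map validity mask",
                             "ischemri_roi")
  v <- map$values[m]
  list(mean = mean(v), sd = stats::sd(v), n = sum(m))
}

#' Ipsilateral-to-contralateral mirror-ROI ratio
#'
#' Ratio of the map mean over an (ipsilateral) atlas ROI to the mean over
#' its mirror across the midline.
#'
#' @inheritParams roi_summary
#' @return scalar ratio
#' @export
ipsi_contra_ratio <- function(map, atlas, roi_name) {
  assert_that(roi_name %in% names(atlas$rois),
              sprintf("unknown ROI '%s'", roi_name), "ischemri_roi")
  roi <- atlas$rois[[roi_name]]
  mir <- mirror_mask(roi)
  mi <- roi & map$mask
  mc <- mir & map$mask
  if (!any(mi) || !any(mc))
    stop_ischemri("ROI or mirror ROI empty in map mask", "ischemri_roi")
  contra <- mean(map$values[mc])
  if (!is.finite(contra) || contra <= 0)
    stop_ischemri("contralateral mirror-ROI mean not positive",
                  "ischemri_ratio")
  mean(map$values[mi]) / contra
}
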