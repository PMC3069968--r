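#' Per-voxel parameter map
#'
#' @param values 3D array of values (NA outside the validity mask)
#' @param kind one of \code{"T1"}, \code{"T2"}, \code{"ADC"}, \code{"CBF"},
#'   \code{"CBFratio"}
#' @param mask logical validity mask
#' @param spacing voxel spacing in mm
#' @return a \code{parameter_map}
#' @export
parameter_map <- function(values, kind, mask, spacing) {
  kind <- match.arg(kind, c("T1", "T2", "ADC", "CBF", "CBFratio"))
  units <- c(T1 = "s", T2 = "ms", ADC = "mm^2/s", CBF = "ml/100 g/min",
             CBFratio = "")[[kind]]
  values <- as_volume(values)
  mask <- as_volume(mask)
  assert_that(all(is.finite(values[mask])),
              "non-finite values inside validity mask")
  structure(list(values = values, kind = kind, units = units,
                 mask = mask, spacing = spacing),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map %s [%s], %d valid voxels, range %.4g..%.4g>\n",
              x$kind, x$units, sum(x$mask),
              min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

series_matrix <- function(series, mask) {
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  m[which(mask), , drop = FALSE]
}

map_from_vector <- function(v, mask, fill = NA_real_) {
  out <- array(fill, dim = dim(mask))
  out[which(mask)] <- v
  out
}

## Voxels carrying no usable variation across frames (flat or zero signal)
## are flagged up front: no relaxation information can be recovered there.
flat_voxels <- function(Y) {
  rng <- matrixStats_range(Y)
  scale <- pmax(abs(rng$max), abs(rng$min))
  (scale <= 0) | ((rng$max - rng$min) <= 1e-9 * pmax(scale, 1e-300))
}

matrixStats_range <- function(Y) {
  mx <- Y[, 1]; mn <- Y[, 1]
  for (k in seq_len(ncol(Y))[-1]) {
    mx <- pmax(mx, Y[, k]); mn <- pmin(mn, Y[, k])
  }
  list(min = mn, max = mx)
}

#' Three-parameter inversion-recovery T1 fit
#'
#' Fits the magnitude IR model \code{|S0 * (1 - 2*beta*exp(-TI/T1))|} per
#' voxel by damped least squares, estimating the signal amplitude, T1 and
#' the inversion-pulse efficiency beta. The absolute-value model is fitted
#' directly, matching magnitude reconstruction without a polarity-restore
#' heuristic. Initialization: \code{S0 = max |S|}, \code{T1 = TI at the
#' signal minimum / ln 2}, \code{beta = 0.95}.
#'
#' @param series an \code{image_series} of kind \code{"ir"} with >= 4 TIs
#' @param mask logical brain mask; defaults to voxels with any signal
#' @param tol,max_iter optimizer controls
#' @return an \code{ir_fit}: maps \code{s0}, \code{t1} (s), \code{beta},
#'   logical \code{converged} map and per-voxel residual norm
#' @export
fit_t1_three_param <- function(series, mask = NULL, tol = 1e-8, max_iter = 200L) {
  assert_that(identical(series$kind, "ir"), "expected an IR series")
  if (n_frames(series) < 4)
    stop_ischemri("IR fit requires at least 4 inversion times",
                  "ischemri_protocol")
  ti <- series$frames$ti
  if (is.null(mask)) mask <- as_volume(apply(series$data, 1:3, max) > 0)
  mask <- as_volume(mask)
  Y <- series_matrix(series, mask)
  flat <- flat_voxels(Y)

  V <- nrow(Y)
  tiM <- matrix(ti, V, length(ti), byrow = TRUE)
  model <- function(P) abs(P[, 1] * (1 - 2 * P[, 2] * exp(-tiM / P[, 3])))
  jacob <- function(P) {
    E <- exp(-tiM / P[, 3])
    U <- P[, 1] * (1 - 2 * P[, 2] * E)
    s <- sign(U); s[s == 0] <- 1
    list(s * (1 - 2 * P[, 2] * E),
         s * (-2 * P[, 1] * E),
         s * (-2 * P[, 1] * P[, 2] * E * tiM / P[, 3]^2))
  }
  s0_0 <- matrixStats_range(Y)$max
  t1_0 <- ti[max.col(-Y, ties.method = "first")] / log(2)
  t1_0 <- pmin(pmax(t1_0, 0.05), 8)
  P0 <- cbind(s0_0, 0.95, t1_0)
  fit <- fit_voxels_lm(Y, model, jacob, P0,
                       lower = c(1e-9, 0.5, 1e-3),
                       upper = c(Inf, 1, 50),
                       tol = tol, max_iter = max_iter)
  conv <- fit$converged & !flat & fit$par[, 3] < 49
  structure(list(
    s0 = map_from_vector(fit$par[, 1], mask),
    t1 = map_from_vector(fit$par[, 3], mask),
    beta = map_from_vector(fit$par[, 2], mask),
    converged = map_from_vector(conv, mask, fill = FALSE) > 0,
    residual = map_from_vector(sqrt(fit$rss), mask),
    mask = mask & map_from_vector(conv, mask, fill = FALSE) > 0,
    spacing = series$spacing, n_params = 3L
  ), class = "ir_fit")
}

#' Brain-average inversion efficiency
#'
#' Mean of the fitted inversion-pulse efficiency over converged voxels of
#' the mask; the fixed value used by the subsequent two-parameter fit.
#'
#' @param ir_fit result of \code{fit_t1_three_param}
#' @param mask logical mask (e.g. brain mask)
#' @return scalar mean efficiency
#' @export
estimate_inversion_efficiency <- function(ir_fit, mask) {
  mask <- as_volume(mask) & ir_fit$converged
  if (!any(mask)) stop_ischemri("no converged voxels in mask", "ischemri_mask")
  mean(ir_fit$beta[mask])
}

#' Two-parameter inversion-recovery T1 fit with fixed inversion efficiency
#'
#' Refits \code{|S0 * (1 - 2*beta_bar*exp(-TI/T1))|} per voxel with the
#' efficiency frozen at its brain-average value; this lower-variance T1 map
#' is the one consumed by CBF quantification.
#'
#' @inheritParams fit_t1_three_param
#' @param beta_bar fixed inversion efficiency, in (0.5, 1]
#' @return an \code{ir_fit} with constant beta map
#' @export
fit_t1_two_param <- function(series, beta_bar, mask = NULL,
                             tol = 1e-8, max_iter = 200L) {
  assert_that(identical(series$kind, "ir"), "expected an IR series")
  assert_that(beta_bar > 0.5 && beta_bar <= 1, "beta_bar must be in (0.5, 1]")
  if (n_frames(series) < 4)
    stop_ischemri("IR fit requires at least 4 inversion times",
                  "ischemri_protocol")
  ti <- series$frames$ti
  if (is.null(mask)) mask <- as_volume(apply(series$data, 1:3, max) > 0)
  mask <- as_volume(mask)
  Y <- series_matrix(series, mask)
  flat <- flat_voxels(Y)
  V <- nrow(Y)
  tiM <- matrix(ti, V, length(ti), byrow = TRUE)
  model <- function(P) abs(P[, 1] * (1 - 2 * beta_bar * exp(-tiM / P[, 2])))
  jacob <- function(P) {
    E <- exp(-tiM / P[, 2])
    U <- P[, 1] * (1 - 2 * beta_bar * E)
    s <- sign(U); s[s == 0] <- 1
    list(s * (1 - 2 * beta_bar * E),
         s * (-2 * P[, 1] * beta_bar * E * tiM / P[, 2]^2))
  }
  s0_0 <- matrixStats_range(Y)$max
  t1_0 <- pmin(pmax(ti[max.col(-Y, ties.method = "first")] / log(2), 0.05), 8)
  fit <- fit_voxels_lm(Y, model, jacob, cbind(s0_0, t1_0),
                       lower = c(1e-9, 1e-3), upper = c(Inf, 50),
                       tol = tol, max_iter = max_iter)
  conv <- fit$converged & !flat & fit$par[, 2] < 49
  structure(list(
    s0 = map_from_vector(fit$par[, 1], mask),
    t1 = map_from_vector(fit$par[, 2], mask),
    beta = map_from_vector(rep(beta_bar, V), mask),
    converged = map_from_vector(conv, mask, fill = FALSE) > 0,
    residual = map_from_vector(sqrt(fit$rss), mask),
    mask = mask & map_from_vector(conv, mask, fill = FALSE) > 0,
    spacing = series$spacing, n_params = 2L
  ), class = "ir_fit")
}

#' Monoexponential T2 fit on the first echoes of a CPMG series
#'
#' Fits \code{S0 * exp(-TE/T2)} per voxel to the first \code{n_echoes}
#' echoes (default 20 of 32) by damped least squares, initialized by the
#' log-linear closed form where all intensities are positive.
#'
#' @param series an \code{image_series} of kind \code{"cpmg"}
#' @param n_echoes number of leading echoes used
#' @param mask logical brain mask
#' @param tol,max_iter optimizer controls
#' @return a \code{t2_fit}: \code{s0}, \code{t2} (ms), convergence map,
#'   residual norm and echoes-used count
#' @export
fit_t2_monoexp <- function(series, n_echoes = 20L, mask = NULL,
                           tol = 1e-8, max_iter = 200L) {
  assert_that(identical(series$kind, "cpmg"), "expected a CPMG series")
  if (n_frames(series) < n_echoes)
    stop_ischemri("series has fewer frames than n_echoes", "ischemri_protocol")
  te <- series$frames$te[seq_len(n_echoes)]
  if (is.null(mask)) mask <- as_volume(apply(series$data, 1:3, max) > 0)
  mask <- as_volume(mask)
  Y <- series_matrix(series, mask)[, seq_len(n_echoes), drop = FALSE]
  flat <- flat_voxels(Y)
  V <- nrow(Y)
  teM <- matrix(te, V, n_echoes, byrow = TRUE)

  ## log-linear initialization (positive intensities only)
  pos <- Y > 0
  allpos <- rowSums(pos) == n_echoes
  a0 <- matrixStats_range(Y)$max
  t2_0 <- rep(mean(te), V)
  if (any(allpos)) {
    L <- log(Y[allpos, , drop = FALSE])
    tbar <- mean(te); lbar <- rowMeans(L)
    slope <- (L %*% (te - tbar)) / sum((te - tbar)^2)
    ok <- slope < -1e-12
    t2i <- ifelse(ok, -1 / slope, mean(te))
    a0i <- exp(lbar - slope * tbar)
    a0[allpos] <- ifelse(ok, a0i, a0[allpos])
    t2_0[allpos] <- pmin(pmax(t2i, 0.5), 1e4)
  }
  model <- function(P) P[, 1] * exp(-teM / P[, 2])
  jacob <- function(P) {
    E <- exp(-teM / P[, 2])
    list(E, P[, 1] * E * teM / P[, 2]^2)
  }
  fit <- fit_voxels_lm(Y, model, jacob, cbind(a0, t2_0),
                       lower = c(1e-9, 1e-2), upper = c(Inf, 1e5),
                       tol = tol, max_iter = max_iter)
  conv <- fit$converged & !flat & fit$par[, 2] < 0.99e5
  structure(list(
    s0 = map_from_vector(fit$par[, 1], mask),
    t2 = map_from_vector(fit$par[, 2], mask),
    converged = map_from_vector(conv, mask, fill = FALSE) > 0,
    residual = map_from_vector(sqrt(fit$rss), mask),
    mask = mask & map_from_vector(conv, mask, fill = FALSE) > 0,
    spacing = series$spacing, n_echoes = as.integer(n_echoes)
  ), class = "t2_fit")
}

#' T2 parameter map from a fit result
#' @param t2_fit a \code{t2_fit}
#' @return a \code{parameter_map} of kind \code{"T2"}
#' @export
t2_map <- function(t2_fit) {
  parameter_map(t2_fit$t2, "T2", t2_fit$mask, t2_fit$spacing)
}

#' T1 parameter map from a fit result
#' @param ir_fit an \code{ir_fit}
#' @return a \code{parameter_map} of kind \code{"T1"}
#' @export
t1_map <- function(ir_fit) {
  parameter_map(ir_fit$t1, "T1", ir_fit$mask, ir_fit$spacing)
}

#' Apparent diffusion coefficient from a b-value pair
#'
#' Averages the repeated diffusion-weighted frames in signal space, then
#' applies \code{ADC = -(1/b) * ln(SI_b / SI_0)} per voxel (for b = 800
#' s/mm^2 the prefactor is the familiar -0.00125). Voxels with a
#' non-positive signal ratio are removed from the validity mask.
#'
#' @param series an \code{image_series} of kind \code{"dwi"} with one b = 0
#'   frame and >= 1 repetitions at one positive b-value
#' @param mask logical brain mask
#' @return a \code{parameter_map} of kind \code{"ADC"} in mm^2/s
#' @export
compute_adc <- function(series, mask = NULL) {
  assert_that(identical(series$kind, "dwi"), "expected a DWI series")
  bv <- series$frames$bval
  i0 <- which(bv == 0)
  ih <- which(bv > 0)
  assert_that(length(i0) == 1, "exactly one b = 0 frame required",
              "ischemri_protocol")
  assert_that(length(ih) >= 1 && length(unique(bv[ih])) == 1,
              "need >= 1 repetitions at a single positive b-value",
              "ischemri_protocol")
  b <- bv[ih][1]
  if (is.null(mask)) mask <- frame_volume(series$data, i0) > 0
  mask <- as_volume(mask)
  s0 <- frame_volume(series$data, i0)
  sb <- as_volume(apply(series$data[, , , ih, drop = FALSE], 1:3, mean))
  ratio <- sb / s0
  valid <- mask & is.finite(ratio) & (ratio > 0)
  adc <- array(NA_real_, dim = dim(s0))
  adc[valid] <- -log(ratio[valid]) / b
  parameter_map(adc, "ADC", valid, series$spacing)
}

#' CASL model constants
#'
#' @param alpha labelling/inversion efficiency (0 < alpha <= 1), default 0.7
#' @param lambda brain--blood partition coefficient in mL/g, default 0.90
#' @return a \code{casl_params} object
#' @export
casl_params <- function(alpha = 0.7, lambda = 0.90) {
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  assert_that(lambda >= 0.8 && lambda <= 1.0, "lambda must be in [0.8, 1.0]")
  structure(list(alpha = alpha, lambda = lambda), class = "casl_params")
}

#' Cerebral blood flow from a CASL control/label pair
#'
#' Single-compartment steady-state quantification: per voxel
#' \code{f = lambda * (M_control - M_label) / (2 * alpha * T1 * M_control)}
#' in ml/g/s, reported as \code{CBF = 6000 * f} in ml/100 g/min. T1 is the
#' voxel's own fitted value (conventionally from the two-parameter fit).
#' Voxels with non-positive control signal or invalid T1 are masked out.
#'
#' @param series an \code{image_series} of kind \code{"casl"} with control
#'   and label frames
#' @param t1 a \code{parameter_map} of kind \code{"T1"} (or an
#'   \code{ir_fit}) on the same grid
#' @param params a \code{casl_params}
#' @param mask optional logical mask intersected with the T1 validity mask
#' @return a \code{parameter_map} of kind \code{"CBF"}
#' @export
compute_cbf <- function(series, t1, params = casl_params(), mask = NULL) {
  assert_that(identical(series$kind, "casl"), "expected a CASL series")
  if (inherits(t1, "ir_fit")) t1 <- t1_map(t1)
  assert_that(identical(t1$kind, "T1"), "t1 must be a T1 parameter_map")
  roles <- series$frames$role
  ic <- which(roles == "control"); il <- which(roles == "label")
  assert_that(length(ic) == 1 && length(il) == 1,
              "CASL series must hold one control and one label frame",
              "ischemri_protocol")
  assert_that(all(dim(series$data)[1:3] == dim(t1$values)[1:3]),
              "CASL pair and T1 map must share one grid", "ischemri_grid")
  mc <- frame_volume(series$data, ic)
  ml <- frame_volume(series$data, il)
  valid <- t1$mask & (mc > 0) & is.finite(t1$values) & (t1$values > 0)
  if (!is.null(mask)) valid <- valid & as_volume(mask)
  cbf <- array(NA_real_, dim = dim(mc))
  f <- params$lambda * (mc[valid] - ml[valid]) /
       (2 * params$alpha * t1$values[valid] * mc[valid])
  cbf[valid] <- 6000 * f
  parameter_map(cbf, "CBF", valid, series$spacing)
}

#' Contralateral normalization of a CBF map
#'
#' Divides every voxel by the mean CBF over the contralateral-hemisphere
#' mask, so the contralateral mean of the output equals 1; the form the
#' voxelwise statistics consume.
#'
#' @param cbf_map a \code{parameter_map} of kind \code{"CBF"}
#' @param contralateral_mask logical mask of the contralateral hemisphere
#' @return a \code{parameter_map} of kind \code{"CBFratio"}
#' @export
normalize_cbf <- function(cbf_map, contralateral_mask) {
  assert_that(identical(cbf_map$kind, "CBF"), "expected a CBF map")
  m <- as_volume(contralateral_mask) & cbf_map$mask
  assert_that(any(m), "empty contralateral mask", "ischemri_mask")
  ref <- mean(cbf_map$values[m])
  if (!is.finite(ref) || ref <= 0)
    stop_ischemri("contralateral mean CBF is not positive",
                  "ischemri_normalization")
  out <- cbf_map$values / ref
  parameter_map(out, "CBFratio", cbf_map$mask, cbf_map$spacing)
}
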