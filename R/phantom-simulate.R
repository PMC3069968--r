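## Forward simulation of the acquisitions from a subject's ground truth.

#' Multi-frame image series
#'
#' A light container for a simulated or loaded acquisition: a 4D array
#' (x, y, z, frame) with voxel spacing and per-frame acquisition metadata
#' (inversion time, echo time, b-value, or label/control role).
#'
#' @param data 4D numeric array (a 3D array is promoted to one frame)
#' @param kind one of \code{"ir"}, \code{"cpmg"}, \code{"dwi"}, \code{"casl"},
#'   \code{"structural"}
#' @param spacing voxel spacing in mm
#' @param frames named list of per-frame metadata vectors (e.g. \code{ti},
#'   \code{te}, \code{bval}, \code{role}); each entry must have one element
#'   per frame
#' @return an \code{image_series}
#' @export
image_series <- function(data, kind, spacing, frames = list()) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  assert_that(length(dim(data)) == 4, "series data must be a 4D array")
  nf <- dim(data)[4]
  for (f in names(frames))
    assert_that(length(frames[[f]]) == nf,
                sprintf("frame metadata '%s' length != frame count", f),
                "ischemri_consistency")
  structure(list(data = data, kind = kind, spacing = spacing, frames = frames),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series %s, %dx%dx%d, %d frames>\n",
              x$kind, d[1], d[2], d[3], d[4]))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[4]

s0_map <- function(truth) {
  s0 <- array(0, dim = dim(truth$t1))
  s0[truth$masks$brain] <- truth$s0
  s0
}

noise_sd <- function(truth, snr) {
  # SNR is defined as brain-mean S0 over the per-frame noise SD
  s0 <- s0_map(truth)
  mean(s0[truth$masks$brain]) / snr
}

add_noise <- function(a, sd) {
  if (sd <= 0) return(a)
  a + array(stats::rnorm(length(a), sd = sd), dim = dim(a))
}

#' Simulate the inversion-recovery T1 series
#'
#' Frame k holds the noiseless magnitude signal
#' \code{|S0 * (1 - 2*beta*exp(-TI_k / T1))|} per voxel (ideal long
#' recovery between inversions), plus additive Gaussian noise.
#'
#' @param truth a \code{ground_truth}
#' @param protocol an \code{acquisition_protocol}
#' @param beta true inversion-pulse efficiency, in (0.5, 1]
#' @param snr signal-to-noise ratio; \code{Inf} for a noiseless series
#' @param seed noise seed
#' @return an \code{image_series} of kind \code{"ir"}
#' @export
simulate_ir_series <- function(truth, protocol = acquisition_protocol(),
                               beta = 0.96, snr = Inf, seed = 1L) {
  assert_that(beta > 0.5 && beta <= 1, "beta must be in (0.5, 1]")
  if (any(truth$t1[truth$masks$brain] <= 0))
    stop_ischemri("non-positive T1 inside brain mask", "ischemri_truth")
  s0 <- s0_map(truth)
  d <- dim(truth$t1)
  ti <- protocol$ti
  dat <- array(0, dim = c(d, length(ti)))
  t1 <- truth$t1
  t1[t1 <= 0] <- Inf  # background: no signal anyway
  set.seed(derive_seed(seed, 101L))
  sd <- if (is.finite(snr)) noise_sd(truth, snr) else 0
  for (k in seq_along(ti)) {
    frame <- abs(s0 * (1 - 2 * beta * exp(-ti[k] / t1)))
    dat[, , , k] <- add_noise(frame, sd)
  }
  image_series(dat, "ir", truth$spacing, frames = list(ti = ti))
}

#' Simulate the CPMG multi-echo T2 series
#'
#' Frame k holds \code{S0 * exp(-TE_k / T2)} plus additive Gaussian noise.
#'
#' @inheritParams simulate_ir_series
#' @return an \code{image_series} of kind \code{"cpmg"}
#' @export
simulate_cpmg_series <- function(truth, protocol = acquisition_protocol(),
                                 snr = Inf, seed = 1L) {
  if (any(truth$t2[truth$masks$brain] <= 0))
    stop_ischemri("non-positive T2 inside brain mask", "ischemri_truth")
  s0 <- s0_map(truth)
  d <- dim(truth$t2)
  te <- protocol$te
  t2 <- truth$t2
  t2[t2 <= 0] <- Inf
  dat <- array(0, dim = c(d, length(te)))
  set.seed(derive_seed(seed, 102L))
  sd <- if (is.finite(snr)) noise_sd(truth, snr) else 0
  for (k in seq_along(te)) {
    dat[, , , k] <- add_noise(s0 * exp(-te[k] / t2), sd)
  }
  image_series(dat, "cpmg", truth$spacing, frames = list(te = te))
}

#' Simulate the diffusion-weighted pair (b = 0 and repeated b = 800)
#'
#' One b = 0 frame and \code{protocol$n_b800} independent repetitions of
#' the diffusion-weighted frame \code{S0 * exp(-b * ADC)}, each with its
#' own noise realization.
#'
#' @inheritParams simulate_ir_series
#' @return an \code{image_series} of kind \code{"dwi"}
#' @export
simulate_dwi <- function(truth, protocol = acquisition_protocol(),
                         snr = Inf, seed = 1L) {
  if (any(truth$adc[truth$masks$brain] < 0))
    stop_ischemri("negative ADC inside brain mask", "ischemri_truth")
  s0 <- s0_map(truth)
  d <- dim(truth$adc)
  b <- protocol$b_values
  bhi <- b[b > 0][1]
  bvals <- c(b[b == 0][1], rep(bhi, protocol$n_b800))
  dat <- array(0, dim = c(d, length(bvals)))
  set.seed(derive_seed(seed, 103L))
  sd <- if (is.finite(snr)) noise_sd(truth, snr) else 0
  for (k in seq_along(bvals)) {
    dat[, , , k] <- add_noise(s0 * exp(-bvals[k] * truth$adc), sd)
  }
  image_series(dat, "dwi", truth$spacing, frames = list(bval = bvals))
}

#' Simulate the CASL control/label pair
#'
#' The forward model is the algebraic inverse of the single-compartment
#' steady-state quantification: \code{M_label = M_control * (1 - 2 * alpha
#' * f * T1 / lambda)} with \code{f} the true perfusion in ml/g/s
#' (\code{CBF / 6000}). Both frames receive additive Gaussian noise reduced
#' by \code{sqrt(casl_averages)} to reflect the averaged acquisition.
#'
#' @inheritParams simulate_ir_series
#' @return an \code{image_series} of kind \code{"casl"} with frame roles
#'   \code{c("control", "label")}
#' @export
simulate_casl_pair <- function(truth, protocol = acquisition_protocol(),
                               snr = Inf, seed = 1L) {
  assert_that(!is.null(truth$cbf) && !is.null(truth$t1),
              "CBF and T1 truth maps required", "ischemri_truth")
  s0 <- s0_map(truth)
  f <- truth$cbf / 6000  # ml/100g/min -> ml/g/s
  atten <- 1 - 2 * protocol$alpha * f * truth$t1 / protocol$lambda
  if (any(atten[truth$masks$brain] < 0))
    stop_ischemri("unphysically high flow: negative label magnetization",
                  "ischemri_simulation")
  set.seed(derive_seed(seed, 104L))
  sd <- if (is.finite(snr))
    noise_sd(truth, snr) / sqrt(protocol$casl_averages) else 0
  d <- dim(truth$cbf)
  dat <- array(0, dim = c(d, 2L))
  dat[, , , 1] <- add_noise(s0, sd)
  dat[, , , 2] <- add_noise(s0 * atten, sd)
  image_series(dat, "casl", truth$spacing,
               frames = list(role = c("control", "label")))
}

#' Generate a complete synthetic study
#'
#' Loops over the configured arms and cohort sizes, builds each subject's
#' ground truth at every timepoint (subject-level draws are shared across
#' timepoints, so each animal is its own repeated measure) and forward
#' simulates the requested acquisitions. Regenerating with the same
#' config and seed is bit-identical.
#'
#' @param config a \code{phantom_config}
#' @param series character vector of acquisitions to simulate, a subset of
#'   \code{c("ir", "cpmg", "dwi", "casl")}
#' @return a \code{study_bundle}: list of subject-by-timepoint records
#'   (each with \code{truth} and simulated \code{series}), a manifest data
#'   frame, and the config
#' @export
generate_study <- function(config, series = c("ir", "cpmg", "dwi", "casl")) {
  validate_phantom_config(config)
  series <- match.arg(series, several.ok = TRUE)
  records <- list()
  rows <- list()
  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    grp <- config$groups[[gi]]
    for (si in seq_len(grp$n)) {
      subject_id <- sprintf("%s-%02d", gname, si)
      subject_seed <- derive_seed(config$seed, gi, si)
      for (tp in grp$timepoints) {
        truth <- build_truth(config, gname, tp, subject_seed)
        tcode <- match(tp, grp$timepoints)
        sims <- list()
        if ("ir" %in% series)
          sims$ir <- simulate_ir_series(truth, config$protocol,
                                        beta = config$beta_inv, snr = config$snr,
                                        seed = derive_seed(subject_seed, tcode, 1L))
        if ("cpmg" %in% series)
          sims$cpmg <- simulate_cpmg_series(truth, config$protocol,
                                            snr = config$snr,
                                            seed = derive_seed(subject_seed, tcode, 2L))
        if ("dwi" %in% series)
          sims$dwi <- simulate_dwi(truth, config$protocol, snr = config$snr,
                                   seed = derive_seed(subject_seed, tcode, 3L))
        if ("casl" %in% series)
          sims$casl <- simulate_casl_pair(truth, config$protocol,
                                          snr = config$snr,
                                          seed = derive_seed(subject_seed, tcode, 4L))
        rec <- list(subject_id = subject_id, group = gname, timepoint = tp,
                    truth = truth, series = sims)
        records[[length(records) + 1L]] <- rec
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = subject_id, group = gname, timepoint = tp,
                     series = paste(names(sims), collapse = ","),
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(records = records,
                 manifest = do.call(rbind, rows),
                 config = config),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle: %d subject-timepoint records, %d arms>\n",
              length(x$records), length(x$config$groups)))
  print(table(x$manifest$group, x$manifest$timepoint))
  invisible(x)
}
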