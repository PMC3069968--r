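#' Acquisition protocol for the forward simulators
#'
#' Captures the acquisition parameters the forward models need: the eight
#' inversion times of the partial-saturation inversion-recovery T1 scan, the
#' 32-echo CPMG train (echo spacing 4.2 ms), the diffusion b-values (0 and
#' 800 s/mm^2, three repetitions at b = 800), and the CASL constants --
#' labelling/inversion efficiency \code{alpha} and brain--blood partition
#' coefficient \code{lambda} -- shared by the forward model and the
#' quantification. \code{casl_averages} is the number of label/control pair
#' averages the perfusion scan accumulates; the simulated pair carries noise
#' reduced by \code{sqrt(casl_averages)} accordingly.
#'
#' @param ti inversion times in seconds, strictly increasing
#' @param n_echoes number of CPMG echoes
#' @param echo_spacing CPMG echo spacing in ms
#' @param b_values diffusion b-values in s/mm^2 (non-negative)
#' @param n_b800 repetitions of the high-b acquisition
#' @param alpha CASL labelling/inversion efficiency (0 < alpha <= 1)
#' @param lambda brain--blood partition coefficient in mL/g
#' @param casl_averages label/control pair averages (>= 1)
#' @return an \code{acquisition_protocol} object
#' @export
acquisition_protocol <- function(ti = c(0.02, 0.5, 1.0, 1.5, 2.0, 3.0, 5.0, 10.0),
                                 n_echoes = 32L,
                                 echo_spacing = 4.2,
                                 b_values = c(0, 800),
                                 n_b800 = 3L,
                                 alpha = 0.7,
                                 lambda = 0.90,
                                 casl_averages = 16L) {
  assert_that(all(diff(ti) > 0), "inversion times must be strictly increasing")
  assert_that(n_echoes >= 1 && echo_spacing > 0, "invalid CPMG settings")
  assert_that(all(b_values >= 0), "b-values must be non-negative")
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  assert_that(lambda >= 0.8 && lambda <= 1.0, "lambda must be in [0.8, 1.0]")
  assert_that(casl_averages >= 1, "casl_averages must be >= 1")
  structure(list(ti = ti,
                 te = echo_spacing * seq_len(n_echoes),
                 n_echoes = as.integer(n_echoes),
                 echo_spacing = echo_spacing,
                 b_values = b_values, n_b800 = as.integer(n_b800),
                 alpha = alpha, lambda = lambda,
                 casl_averages = as.integer(casl_averages)),
            class = "acquisition_protocol")
}

## Healthy (non-ischemic) tissue parameters per compartment at high field.
default_tissues <- function() {
  data.frame(
    tissue = c("cortex", "subcortex", "csf"),
    t1  = c(1.8, 1.7, 4.0),          # s
    t2  = c(30, 31, 160),            # ms
    adc = c(7.9e-4, 7.8e-4, 2.4e-3), # mm^2/s
    cbf = c(148.4, 120, 0),          # ml/100 g/min
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Assembles the full description of a synthetic study: grid geometry, the
#' healthy tissue parameter table, the group x ROI x timepoint outcome cells
#' (means and between-subject SDs) applied inside the affected MCA
#' territory, the lesion-extent model, the noise model, the cohort layout
#' and the master seed.
#'
#' @param groups named list; each element \code{list(n =, timepoints =)}
#' @param cells data frame with columns \code{group, time, roi, quantity,
#'   mean, sd} (quantity in \code{cbf}, \code{adc}, \code{t2}, \code{pinf});
#'   cell values are the ground-truth ROI means for affected tissue
#' @param tissues healthy tissue parameter table (see
#'   \code{default_tissues()})
#' @param n in-plane matrix size
#' @param spacing voxel spacing in mm
#' @param s0 equilibrium signal inside the brain (arbitrary units)
#' @param snr signal-to-noise ratio: brain-mean S0 divided by the additive
#'   Gaussian noise SD per frame
#' @param beta_inv true inversion-pulse efficiency of the simulated IR scan
#' @param lesion list with \code{mode} ("territory" or "sector"),
#'   \code{fraction} (per-group lesion extent: number, or
#'   \code{list(type = "beta", mean =, conc =)}), \code{t2_threshold} (ms)
#'   and, for sector mode, \code{values} (named lesion tissue parameters)
#' @param subject_cv_healthy CV of the per-subject jitter on healthy tissue
#' @param protocol an \code{acquisition_protocol}
#' @param seed master seed for the whole study
#' @return a validated \code{phantom_config} object
#' @export
phantom_config <- function(groups,
                           cells = NULL,
                           tissues = default_tissues(),
                           n = c(64L, 64L),
                           spacing = c(18 / n[1], 18 / n[2], 1.5),
                           s0 = 1000,
                           snr = 40,
                           beta_inv = 0.96,
                           lesion = list(),
                           subject_cv_healthy = 0.02,
                           protocol = acquisition_protocol(),
                           seed = 1L) {
  lesion_defaults <- list(mode = "territory", fraction = 1, t2_threshold = 34,
                          values = list(t1 = 1.9, t2 = 50, adc = 5.0e-4, cbf = 30))
  lesion <- utils::modifyList(lesion_defaults, lesion)
  cfg <- structure(list(
    groups = groups, cells = cells, tissues = tissues,
    n = as.integer(n), spacing = spacing, s0 = s0, snr = snr,
    beta_inv = beta_inv, lesion = lesion,
    subject_cv_healthy = subject_cv_healthy,
    protocol = protocol, seed = as.integer(seed),
    atlas = default_atlas(n = n, spacing = spacing)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

#' @rdname phantom_config
#' @param config object to validate
#' @export
validate_phantom_config <- function(config) {
  assert_that(inherits(config, "phantom_config"), "not a phantom_config")
  assert_that(length(config$groups) >= 1, "at least one group required",
              "ischemri_config")
  for (g in names(config$groups)) {
    gr <- config$groups[[g]]
    if (is.null(gr$n) || gr$n < 1)
      stop_ischemri(sprintf("group '%s' has zero subjects", g), "ischemri_config")
    assert_that(length(gr$timepoints) >= 1,
                sprintf("group '%s' has no timepoints", g), "ischemri_config")
  }
  tis <- config$tissues
  assert_that(all(c("tissue", "t1", "t2", "adc", "cbf") %in% names(tis)),
              "tissue table missing columns", "ischemri_config")
  assert_that(all(tis$t1 > 0) && all(tis$t2 > 0) && all(tis$adc >= 0) &&
              all(tis$cbf >= 0), "tissue parameters out of range",
              "ischemri_config")
  if (!is.null(config$cells)) {
    cl <- config$cells
    assert_that(all(c("group", "time", "roi", "quantity", "mean", "sd")
                    %in% names(cl)), "cells table missing columns",
                "ischemri_config")
    assert_that(all(cl$mean >= 0), "cell means must be non-negative",
                "ischemri_config")
    assert_that(all(cl$sd >= 0), "cell SDs must be non-negative",
                "ischemri_config")
  }
  fr <- config$lesion$fraction
  frs <- if (is.list(fr) && !is.null(fr$type)) list(fr) else
         if (is.list(fr)) fr else list(fr)
  for (f in frs) {
    if (is.numeric(f))
      assert_that(all(f >= 0 & f <= 1), "lesion fractions must lie in [0,1]",
                  "ischemri_config")
  }
  assert_that(config$snr > 0, "SNR must be positive", "ischemri_config")
  assert_that(config$beta_inv > 0.5 && config$beta_inv <= 1,
              "beta_inv must be in (0.5, 1]", "ischemri_config")
  invisible(config)
}

## Row constructor used by the fixture.
cell_rows <- function(group, roi, quantity, times, means, sds) {
  data.frame(group = group, time = times, roi = roi, quantity = quantity,
             mean = means, sd = sds, stringsAsFactors = FALSE)
}

#' Study fixture: outcome-table ground truth
#'
#' Encodes the study's group x ROI x timepoint outcome cells (CBF, ADC,
#' quantitative T2 and probability of infarction, as group mean and SEM) as
#' the phantom's ground truth, together with the cohort layout: N = 10
#' transient-occlusion controls and N = 10 anti-GPIb treated animals at 2 h
#' and 24 h, an early-reperfusion anti-GPIb arm (N = 4, 1 h and 24 h),
#' permanent-occlusion arms, and sham animals. The between-subject SD of
#' each cell is encoded at the printed-SEM scale, so regenerated cohort
#' means recover each cell within one SEM with high probability (see the
#' methods vignette for why this understates real animal variability).
#' ADC cells are stored in mm^2/s.
#'
#' @param groups character vector of arms to include; default the two main
#'   transient-occlusion arms
#' @param n_subjects optional named vector overriding per-arm cohort sizes
#' @param ... further arguments passed on to \code{phantom_config}
#' @return a \code{phantom_config}
#' @export
table1_fixture <- function(groups = c("tMCAO-control", "tMCAO-antiGPIb"),
                           n_subjects = NULL, ...) {
  adc <- function(x) x * 1e-4
  cells <- rbind(
    ## transient occlusion, control arm
    cell_rows("tMCAO-control", "cortical_mca", "cbf", c("2h", "24h"), c(40.9, 26.0), c(4.4, 3.2)),
    cell_rows("tMCAO-control", "subcortical",  "cbf", c("2h", "24h"), c(33.6, 24.8), c(4.3, 3.2)),
    cell_rows("tMCAO-control", "cortical_mca", "adc", c("2h", "24h"), adc(c(6.48, 5.75)), adc(c(0.27, 0.23))),
    cell_rows("tMCAO-control", "subcortical",  "adc", c("2h", "24h"), adc(c(6.08, 5.29)), adc(c(0.60, 0.33))),
    cell_rows("tMCAO-control", "cortical_mca", "t2",  c("2h", "24h"), c(37.24, 60.05), c(1.96, 3.15)),
    cell_rows("tMCAO-control", "subcortical",  "t2",  c("2h", "24h"), c(33.41, 49.89), c(1.05, 3.15)),
    cell_rows("tMCAO-control", "cortical_mca", "pinf", c("2h", "24h"), c(60.9, 95.1), c(9.3, 2.8)),
    cell_rows("tMCAO-control", "subcortical",  "pinf", c("2h", "24h"), c(79.1, 100), c(9.9, 0)),
    ## transient occlusion, anti-GPIb arm
    cell_rows("tMCAO-antiGPIb", "cortical_mca", "cbf", c("2h", "24h"), c(44.2, 60.5), c(6.9, 8.4)),
    cell_rows("tMCAO-antiGPIb", "subcortical",  "cbf", c("2h", "24h"), c(45.3, 46.9), c(5.9, 7.5)),
    cell_rows("tMCAO-antiGPIb", "cortical_mca", "adc", c("2h", "24h"), adc(c(7.88, 7.53)), adc(c(0.28, 0.26))),
    cell_rows("tMCAO-antiGPIb", "subcortical",  "adc", c("2h", "24h"), adc(c(7.86, 7.12)), adc(c(0.33, 0.26))),
    cell_rows("tMCAO-antiGPIb", "cortical_mca", "t2",  c("2h", "24h"), c(28.6, 29.0), c(0.4, 0.97)),
    cell_rows("tMCAO-antiGPIb", "subcortical",  "t2",  c("2h", "24h"), c(30.6, 37.4), c(0.3, 2.2)),
    cell_rows("tMCAO-antiGPIb", "cortical_mca", "pinf", c("2h", "24h"), c(17.4, 34.5), c(2.1, 8.1)),
    cell_rows("tMCAO-antiGPIb", "subcortical",  "pinf", c("2h", "24h"), c(21.5, 64.8), c(7.9, 14.5)),
    ## early-reperfusion anti-GPIb arm (1 h after thread removal)
    cell_rows("tMCAO-antiGPIb-early", "cortical_mca", "cbf", c("1h", "24h"), c(28.2, 110.1), c(3.5, 10.0)),
    ## ipsi/contra mirror-ROI ratio; the 24 h ratio cell is omitted because
    ## it is inconsistent with the absolute CBF cells above
    cell_rows("tMCAO-antiGPIb-early", "cortical_mca", "cbf_ratio", "1h", 0.19, 0.01),
    cell_rows("tMCAO-antiGPIb-early", "cortical_mca", "t2",  c("1h", "24h"), c(30.6, 32.2), c(0.7, 2.1)),
    cell_rows("tMCAO-antiGPIb-early", "subcortical",  "t2",  c("1h", "24h"), c(30.8, 45.7), c(0.3, 2.4)),
    ## permanent occlusion: severe sustained hypoperfusion, full infarcts
    cell_rows("pMCAO-antiGPIb", "cortical_mca", "cbf", c("2h", "24h"), c(42.9, 35.4), c(11.5, 5.2)),
    cell_rows("pMCAO-antiGPIb", "cortical_mca", "t2",  c("2h", "24h"), c(37.24, 60.05), c(1.96, 3.15)),
    cell_rows("pMCAO-antiGPIb", "subcortical",  "t2",  c("2h", "24h"), c(33.41, 49.89), c(1.05, 3.15)),
    cell_rows("pMCAO-control",  "cortical_mca", "cbf", c("2h", "24h"), c(40.9, 26.0), c(4.4, 3.2)),
    cell_rows("pMCAO-control",  "cortical_mca", "t2",  c("2h", "24h"), c(37.24, 60.05), c(1.96, 3.15)),
    cell_rows("pMCAO-control",  "subcortical",  "t2",  c("2h", "24h"), c(33.41, 49.89), c(1.05, 3.15))
  )
  arms <- list(
    "tMCAO-control"        = list(n = 10L, timepoints = c("2h", "24h")),
    "tMCAO-antiGPIb"       = list(n = 10L, timepoints = c("2h", "24h")),
    "tMCAO-antiGPIb-early" = list(n = 4L,  timepoints = c("1h", "24h")),
    "pMCAO-antiGPIb"       = list(n = 6L,  timepoints = c("2h", "24h")),
    "pMCAO-control"        = list(n = 3L,  timepoints = c("2h", "24h")),
    "sham"                 = list(n = 3L,  timepoints = c("2h", "24h"))
  )
  unknown <- setdiff(groups, names(arms))
  assert_that(length(unknown) == 0,
              paste("unknown study arm(s):", paste(unknown, collapse = ", ")),
              "ischemri_config")
  arms <- arms[groups]
  if (!is.null(n_subjects))
    for (g in names(n_subjects)) arms[[g]]$n <- as.integer(n_subjects[[g]])
  frac <- list("sham" = 0)  # all MCAO arms: whole territory affected
  phantom_config(groups = arms,
                 cells = cells[cells$group %in% groups, , drop = FALSE],
                 lesion = list(mode = "territory", fraction = frac), ...)
}
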