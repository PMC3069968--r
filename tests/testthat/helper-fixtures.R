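# Shared fixtures: built in code at test time, no stored data.

# Small noiseless single-subject truth on the default grid.
truth_one <- function(group = "tMCAO-control", timepoint = "24h",
                      subject_seed = 42L, ...) {
  cfg <- table1_fixture(groups = group,
                        n_subjects = stats::setNames(1L, group), ...)
  build_truth(cfg, group, timepoint, subject_seed)
}

# Uniform-parameter truth for point-value forward-model checks.
flat_truth <- function(t1 = 1.5, t2 = 34, adc = 6.48e-4, cbf = 60.5,
                       n = c(16L, 16L), s0 = 100) {
  atlas <- default_atlas(n = n)
  mk <- function(v) {
    a <- array(0, dim = atlas$dim)
    a[atlas$masks$brain] <- v
    a
  }
  structure(list(t1 = mk(t1), t2 = mk(t2), adc = mk(adc), cbf = mk(cbf),
                 labels = atlas$labels,
                 masks = c(atlas$masks,
                           list(lesion = atlas$masks$brain & FALSE,
                                affected = atlas$masks$brain & FALSE)),
                 rois = atlas$rois, spacing = atlas$spacing, s0 = s0,
                 group = "flat", timepoint = "0h", subject_seed = 0L,
                 extent = 0, misalignment = NULL),
            class = "ground_truth")
}

# A sector-mode config with a well-separated lesion (T2 50 vs healthy
# 30/31 ms) for segmentation-fidelity checks.
sector_config <- function(extent = 0.6, n_subj = 1L, snr = 40, seed = 7L) {
  phantom_config(
    groups = list(lesioned = list(n = n_subj, timepoints = "24h")),
    lesion = list(mode = "sector", fraction = extent,
                  values = list(t1 = 1.9, t2 = 50, adc = 5.0e-4, cbf = 30)),
    snr = snr, seed = seed)
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)),
            rel_tol)
}
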