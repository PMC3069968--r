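# Phantom generator: configuration, ground truth, forward models.

test_that("config validation rejects degenerate studies", {
  expect_error(phantom_config(groups = list(g = list(n = 0L, timepoints = "2h"))),
               "zero subjects")
  expect_error(phantom_config(groups = list(g = list(n = 2L, timepoints = character()))),
               "no timepoints")
  expect_error(
    phantom_config(groups = list(g = list(n = 2L, timepoints = "2h")),
                   lesion = list(fraction = 1.2)),
    "lesion fractions")
  expect_error(table1_fixture(groups = "no-such-arm"), "unknown study arm")
})

test_that("study structure matches the configured cohorts", {
  cfg <- table1_fixture(n = c(32L, 32L))
  study <- generate_study(cfg, series = "cpmg")
  expect_equal(length(study$records), 40)  # 2 arms x 10 subjects x 2 times
  tab <- table(study$manifest$group, study$manifest$timepoint)
  expect_true(all(tab == 10))
  expect_true(all(vapply(study$records,
                         function(r) inherits(r$truth, "ground_truth"), TRUE)))
})

test_that("regeneration with the same seed is bit-identical, and truth is
           stable across seeds while noise differs", {
  cfg <- table1_fixture(groups = "tMCAO-control",
                        n_subjects = c("tMCAO-control" = 2L),
                        n = c(32L, 32L), seed = 5L)
  s1 <- generate_study(cfg, series = "cpmg")
  s2 <- generate_study(cfg, series = "cpmg")
  expect_identical(s1$records[[1]]$series$cpmg$data,
                   s2$records[[1]]$series$cpmg$data)
  expect_identical(s1$records[[3]]$truth$t2, s2$records[[3]]$truth$t2)

  cfg2 <- table1_fixture(groups = "tMCAO-control",
                         n_subjects = c("tMCAO-control" = 10L),
                         n = c(32L, 32L), seed = 6L)
  cfg3 <- table1_fixture(groups = "tMCAO-control",
                         n_subjects = c("tMCAO-control" = 10L),
                         n = c(32L, 32L), seed = 7L)
  s3 <- generate_study(cfg2, series = "cpmg")
  s4 <- generate_study(cfg3, series = "cpmg")
  roi <- cfg2$atlas$rois$cortical_mca
  m24 <- function(st) mean(vapply(Filter(function(r) r$timepoint == "24h",
                                         st$records),
                                  function(r) mean(r$truth$t2[roi]),
                                  numeric(1)))
  # cohort-truth means agree within 2 between-subject standard errors
  sem <- 3.15 / sqrt(10)
  expect_lt(abs(m24(s3) - m24(s4)), 2 * sqrt(2) * sem * 2)
  expect_false(identical(s3$records[[1]]$series$cpmg$data,
                         s4$records[[1]]$series$cpmg$data))
})

test_that("zero-noise simulation equals the noiseless forward model", {
  tr <- flat_truth(t1 = 1.5, t2 = 34, adc = 6.48e-4, cbf = 60.5, s0 = 100)
  prot <- acquisition_protocol()
  ir <- simulate_ir_series(tr, prot, beta = 0.96, snr = Inf)
  v <- which(tr$masks$brain)[1]
  # direct evaluation of |S0 (1 - 2 beta exp(-TI/T1))|
  expect_equal(ir$data[, , , 1][v], abs(100 * (1 - 1.92 * exp(-0.02 / 1.5))))
  expect_equal(ir$data[, , , 1][v], 89.457, tolerance = 1e-4)
  # long-TI limit approaches S0
  expect_equal(ir$data[, , , 8][v], 100 * (1 - 1.92 * exp(-10 / 1.5)))
  expect_lt(abs(ir$data[, , , 8][v] - 100), 0.25)

  cp <- simulate_cpmg_series(tr, prot, snr = Inf)
  te <- prot$te
  k34 <- which.min(abs(te - 34))
  expect_equal(cp$data[, , , k34][v], 100 * exp(-te[k34] / 34))

  dw <- simulate_dwi(tr, prot, snr = Inf)
  expect_equal(dw$data[, , , 2][v], 100 * exp(-800 * 6.48e-4))
  expect_equal(dw$data[, , , 2][v] * 10, 595.5, tolerance = 1e-3)

  ca <- simulate_casl_pair(tr, prot, snr = Inf)
  expect_equal(ca$data[, , , 2][v],
               100 * (1 - 2 * 0.7 * (60.5 / 6000) * 1.5 / 0.9))
})

test_that("zero CBF and zero ADC give null contrast", {
  tr <- flat_truth(cbf = 0, adc = 0)
  ca <- simulate_casl_pair(tr, snr = Inf)
  expect_identical(ca$data[, , , 1], ca$data[, , , 2])
  dw <- simulate_dwi(tr, snr = Inf)
  expect_identical(dw$data[, , , 1], dw$data[, , , 2])
})

test_that("simulators reject unphysical truth", {
  tr <- flat_truth()
  tr$t1[tr$masks$brain][1] <- tr$t1[which(tr$masks$brain)[1]] # no-op touch
  bad <- tr; bad$t1[which(bad$masks$brain)[1]] <- -1
  expect_error(simulate_ir_series(bad), class = "ischemri_truth")
  bad <- tr; bad$t2[which(bad$masks$brain)[1]] <- 0
  expect_error(simulate_cpmg_series(bad), class = "ischemri_truth")
  bad <- tr; bad$adc[which(bad$masks$brain)[1]] <- -1e-4
  expect_error(simulate_dwi(bad), class = "ischemri_truth")
  bad <- tr; bad$cbf[bad$masks$brain] <- 1e5
  expect_error(simulate_casl_pair(bad), class = "ischemri_simulation")
})

test_that("sham truth is lesion-free and hemispherically symmetric", {
  tr <- truth_one("sham", "24h")
  expect_equal(sum(tr$masks$lesion), 0)
  expect_identical(mirror_mask(tr$t2), tr$t2)
  expect_identical(mirror_mask(tr$cbf), tr$cbf)
})

test_that("lesion geometry follows the configured extent", {
  # extent 1: affected region equals the MCA territory
  tr <- truth_one("tMCAO-control", "24h")
  expect_identical(tr$masks$affected, tr$masks$territory)
  # nesting of the truth masks
  expect_true(all(!tr$masks$lesion | tr$masks$territory))
  expect_true(all(!tr$masks$territory | tr$masks$ipsilateral))
  # sector mode: partial extent covers the configured fraction
  cfgs <- sector_config(extent = 0.5)
  trs <- build_truth(cfgs, "lesioned", "24h", 3L)
  frac <- sum(trs$masks$affected) / sum(trs$masks$territory)
  expect_equal(frac, 0.5, tolerance = 0.01)
  # partial lesions grow from the subcortex outward
  sub_cov <- mean(trs$masks$affected[trs$rois$subcortical])
  ctx_cov <- mean(trs$masks$affected[trs$rois$cortical_mca])
  expect_gt(sub_cov, ctx_cov)
})

test_that("ground-truth ROI means equal the configured fixture cells on
           average over subjects", {
  cfg <- table1_fixture(groups = "tMCAO-control",
                        n_subjects = c("tMCAO-control" = 40L), seed = 11L)
  roi <- cfg$atlas$rois$cortical_mca
  vals <- vapply(1:40, function(i) {
    tr <- build_truth(cfg, "tMCAO-control", "24h", derive_seed(11L, 1L, i))
    mean(tr$t2[roi])
  }, numeric(1))
  # cell: 60.05 with between-subject SD encoded at the SEM scale (3.15)
  expect_equal(mean(vals), 60.05, tolerance = 3.15 * 3 / sqrt(40))
  expect_equal(sd(vals), 3.15, tolerance = 1.2)
})

test_that("unknown group or timepoint raises a lookup error", {
  cfg <- table1_fixture(n = c(32L, 32L))
  expect_error(build_truth(cfg, "nope", "24h", 1L), class = "ischemri_lookup")
  expect_error(build_truth(cfg, "tMCAO-control", "7h", 1L),
               class = "ischemri_lookup")
})
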