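# Voxelwise quantification: T1 (two-stage), T2, ADC, CBF, normalization.

six_digits <- 5e-6

test_that("noiseless fits invert their forward models to six significant
           digits (oracle exactness)", {
  tr <- flat_truth(t1 = 1.5, t2 = 34, adc = 6.48e-4, cbf = 60.5, s0 = 100)
  brain <- tr$masks$brain
  prot <- acquisition_protocol()

  ir <- simulate_ir_series(tr, prot, beta = 0.96, snr = Inf)
  f3 <- fit_t1_three_param(ir, mask = brain)
  expect_true(all(f3$converged[brain]))
  expect_rel_equal(f3$t1[brain], 1.5, six_digits)
  expect_rel_equal(f3$beta[brain], 0.96, six_digits)
  expect_rel_equal(f3$s0[brain], 100, six_digits)

  bb <- estimate_inversion_efficiency(f3, brain)
  expect_equal(bb, 0.96, tolerance = 1e-6)
  f2 <- fit_t1_two_param(ir, bb, mask = brain)
  expect_rel_equal(f2$t1[brain], 1.5, six_digits)
  # with matching beta the two fits agree
  expect_rel_equal(f2$t1[brain], f3$t1[brain], six_digits)

  cp <- simulate_cpmg_series(tr, prot, snr = Inf)
  ft2 <- fit_t2_monoexp(cp, n_echoes = 20)
  expect_rel_equal(ft2$t2[brain], 34, six_digits)

  dw <- simulate_dwi(tr, prot, snr = Inf)
  adc <- compute_adc(dw, mask = brain)
  expect_rel_equal(adc$values[brain], 6.48e-4, six_digits)

  ca <- simulate_casl_pair(tr, prot, snr = Inf)
  cbf <- compute_cbf(ca, f2)
  expect_rel_equal(cbf$values[brain], 60.5, six_digits)
})

test_that("three-parameter IR fit matches an independent single-voxel
           optimizer on noisy data", {
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  ti <- acquisition_protocol()$ti
  y <- abs(100 * (1 - 2 * 0.955 * exp(-ti / 1.7))) + rnorm(length(ti), sd = 2)
  Y <- matrix(y, 1)
  series <- image_series(array(rep(y, each = 1), dim = c(1, 1, 1, length(ti))),
                         "ir", c(1, 1, 1), frames = list(ti = ti))
  mine <- fit_t1_three_param(series, mask = array(TRUE, c(1, 1, 1)))
  ref <- minpack.lm::nlsLM(
    y ~ abs(s0 * (1 - 2 * b * exp(-ti / t1))),
    start = list(s0 = max(y), b = 0.95, t1 = 1),
    lower = c(1e-9, 0.5, 1e-3), upper = c(Inf, 1, 50),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  p <- coef(ref)
  expect_equal(mine$t1[1, 1, 1], unname(p["t1"]), tolerance = 1e-5)
  expect_equal(mine$beta[1, 1, 1], unname(p["b"]), tolerance = 1e-4)
})

test_that("degenerate voxels are flagged non-converged", {
  ti <- acquisition_protocol()$ti
  flat <- array(50, dim = c(2, 1, 1, length(ti)))  # no inversion information
  series <- image_series(flat, "ir", c(1, 1, 1), frames = list(ti = ti))
  f <- fit_t1_three_param(series, mask = array(TRUE, c(2, 1, 1)))
  expect_false(any(f$converged))

  te <- acquisition_protocol()$te
  flat2 <- array(c(7, 0), dim = c(2, 1, 1, length(te)))  # no decay / all-zero
  s2 <- image_series(flat2, "cpmg", c(1, 1, 1), frames = list(te = te))
  f2 <- fit_t2_monoexp(s2, mask = array(TRUE, c(2, 1, 1)))
  expect_false(any(f2$converged))
})

test_that("fits reject series with too few frames", {
  ti <- c(0.1, 0.5, 2)
  s <- image_series(array(1, dim = c(2, 2, 1, 3)), "ir", c(1, 1, 1),
                    frames = list(ti = ti))
  expect_error(fit_t1_three_param(s), class = "ischemri_protocol")
  te <- 4.2 * (1:10)
  s2 <- image_series(array(1, dim = c(2, 2, 1, 10)), "cpmg", c(1, 1, 1),
                     frames = list(te = te))
  expect_error(fit_t2_monoexp(s2, n_echoes = 20), class = "ischemri_protocol")
})

test_that("inversion-efficiency averaging is the arithmetic mean of
           converged voxels", {
  f <- list(beta = array(c(0.95, 0.97), c(2, 1, 1)),
            converged = array(TRUE, c(2, 1, 1)))
  class(f) <- "ir_fit"
  expect_equal(estimate_inversion_efficiency(f, array(TRUE, c(2, 1, 1))),
               0.96)
  f$converged[2] <- FALSE
  expect_equal(estimate_inversion_efficiency(f, array(TRUE, c(2, 1, 1))),
               0.95)
  expect_error(estimate_inversion_efficiency(f, array(FALSE, c(2, 1, 1))),
               class = "ischemri_mask")
})

test_that("on the fixture at SNR 40 the brain-mean inversion efficiency is
           recovered and the two-parameter T1 is less variable", {
  tr <- truth_one("tMCAO-control", "2h")
  brain <- tr$masks$brain
  ir <- simulate_ir_series(tr, beta = 0.96, snr = 40, seed = 3L)
  f3 <- fit_t1_three_param(ir, mask = brain)
  bb <- estimate_inversion_efficiency(f3, f3$mask)
  expect_gt(bb, 0.95); expect_lt(bb, 0.97)
  expect_equal(bb, 0.96, tolerance = 0.006)
  f2 <- fit_t1_two_param(ir, bb, mask = brain)
  m <- f3$mask & f2$mask
  err3 <- f3$t1[m] - tr$t1[m]
  err2 <- f2$t1[m] - tr$t1[m]
  expect_lte(sd(err2), sd(err3))
})

test_that("ADC follows the log-ratio equation and masks bad voxels", {
  # SI_b800 = SI_b0 -> ADC 0; printed-equation spot value
  dat <- array(0, dim = c(3, 1, 1, 4))
  dat[1, 1, 1, ] <- c(1000, 595.5, 595.5, 595.5)
  dat[2, 1, 1, ] <- c(500, 500, 500, 500)
  dat[3, 1, 1, ] <- c(400, -1, -1, -1)       # non-positive ratio
  s <- image_series(dat, "dwi", c(1, 1, 1),
                    frames = list(bval = c(0, 800, 800, 800)))
  adc <- compute_adc(s, mask = array(TRUE, c(3, 1, 1)))
  expect_equal(adc$values[1, 1, 1], -log(595.5 / 1000) / 800)
  expect_equal(adc$values[1, 1, 1], 6.48e-4, tolerance = 1e-4)
  expect_equal(adc$values[2, 1, 1], 0)
  expect_false(adc$mask[3, 1, 1])
  # repetitions are averaged in signal space before the log
  dat2 <- dat[1, , , , drop = FALSE]
  dat2[1, 1, 1, 2:4] <- c(500, 600, 700)
  s2 <- image_series(dat2, "dwi", c(1, 1, 1),
                     frames = list(bval = c(0, 800, 800, 800)))
  a2 <- compute_adc(s2)
  expect_equal(a2$values[1, 1, 1], -log(600 / 1000) / 800)
})

test_that("CBF follows the single-compartment CASL equation", {
  dat <- array(0, dim = c(2, 1, 1, 2))
  dat[, , , 1] <- 1000
  dat[1, 1, 1, 2] <- 971.8
  dat[2, 1, 1, 2] <- 1000                    # no label effect
  s <- image_series(dat, "casl", c(1, 1, 1),
                    frames = list(role = c("control", "label")))
  t1 <- parameter_map(array(1.8, c(2, 1, 1)), "T1",
                      array(TRUE, c(2, 1, 1)), c(1, 1, 1))
  cbf <- compute_cbf(s, t1, casl_params(alpha = 0.7, lambda = 0.90))
  expect_equal(cbf$values[1, 1, 1],
               6000 * 0.9 * (1000 - 971.8) / (2 * 0.7 * 1.8 * 1000))
  expect_equal(cbf$values[1, 1, 1], 60.4, tolerance = 0.1)
  expect_equal(cbf$values[2, 1, 1], 0)
})

test_that("contralateral normalization rescales to unit contralateral mean", {
  vals <- array(NA_real_, c(4, 1, 1))
  vals[] <- c(25, 75, 40, 60)
  mask <- array(TRUE, c(4, 1, 1))
  m <- parameter_map(vals, "CBF", mask, c(1, 1, 1))
  contra <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  nm <- normalize_cbf(m, contra)
  expect_equal(mean(nm$values[contra]), 1)
  expect_equal(nm$values[1, 1, 1], 0.5)
  zero <- parameter_map(array(0, c(4, 1, 1)), "CBF", mask, c(1, 1, 1))
  expect_error(normalize_cbf(zero, contra), class = "ischemri_normalization")
})

test_that("quantification is invariant to global intensity scaling", {
  tr <- truth_one("tMCAO-antiGPIb", "24h")
  brain <- tr$masks$brain
  ir <- simulate_ir_series(tr, snr = 40, seed = 9L)
  cp <- simulate_cpmg_series(tr, snr = 40, seed = 9L)
  dw <- simulate_dwi(tr, snr = 40, seed = 9L)
  ca <- simulate_casl_pair(tr, snr = 40, seed = 9L)
  scale <- 3.7
  sc <- function(s) { s$data <- s$data * scale; s }

  f2a <- fit_t1_two_param(ir, 0.96, mask = brain)
  f2b <- fit_t1_two_param(sc(ir), 0.96, mask = brain)
  expect_equal(f2b$t1[f2a$mask & f2b$mask], f2a$t1[f2a$mask & f2b$mask],
               tolerance = 1e-6)
  ta <- fit_t2_monoexp(cp, mask = brain); tb <- fit_t2_monoexp(sc(cp), mask = brain)
  expect_equal(tb$t2[ta$mask & tb$mask], ta$t2[ta$mask & tb$mask],
               tolerance = 1e-6)
  aa <- compute_adc(dw, mask = brain); ab <- compute_adc(sc(dw), mask = brain)
  expect_equal(ab$values[aa$mask & ab$mask], aa$values[aa$mask & ab$mask])
  ca_a <- compute_cbf(ca, f2a); ca_b <- compute_cbf(sc(ca), f2a)
  expect_equal(ca_b$values[ca_a$mask & ca_b$mask],
               ca_a$values[ca_a$mask & ca_b$mask])
  # masks only shrink
  expect_true(all(!ta$mask | brain))
  expect_true(all(!aa$mask | brain))
  expect_true(all(!ca_a$mask | brain))
})

test_that("cohort-mean recovery bias at SNR 40 is below 3% per tissue
           class", {
  tr <- truth_one("tMCAO-control", "24h", subject_seed = 8L)
  brain <- tr$masks$brain
  csf <- tr$masks$csf
  classes <- list(cortex = tr$labels == 1 & !csf, subcortex = tr$labels == 2)
  ir <- simulate_ir_series(tr, snr = 40, seed = 2L)
  f3 <- fit_t1_three_param(ir, mask = brain)
  f2 <- fit_t1_two_param(ir, estimate_inversion_efficiency(f3, f3$mask),
                         mask = brain)
  cp <- simulate_cpmg_series(tr, snr = 40, seed = 2L)
  ft2 <- fit_t2_monoexp(cp, mask = brain)
  dw <- simulate_dwi(tr, snr = 40, seed = 2L)
  adc <- compute_adc(dw, mask = brain)
  ca <- simulate_casl_pair(tr, snr = 40, seed = 2L)
  cbf <- compute_cbf(ca, f2)
  for (cl in classes) {
    expect_lt(abs(mean(f2$t1[cl & f2$mask]) - mean(tr$t1[cl])) /
              mean(tr$t1[cl]), 0.03)
    expect_lt(abs(mean(ft2$t2[cl & ft2$mask]) - mean(tr$t2[cl])) /
              mean(tr$t2[cl]), 0.03)
    expect_lt(abs(mean(adc$values[cl & adc$mask]) - mean(tr$adc[cl])) /
              mean(tr$adc[cl]), 0.03)
    expect_lt(abs(mean(cbf$values[cl & cbf$mask]) - mean(tr$cbf[cl])) /
              mean(tr$cbf[cl]), 0.03)
  }
})
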