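test_that("Rician correction applies the second-moment identity", {
  out <- rician_correct(10, noise_model(1))
  expect_equal(out$signal, sqrt(98), tolerance = 1e-12)
  expect_false(out$flagged)
  out <- rician_correct(c(3, 7), noise_model(0))
  expect_identical(out$signal, c(3, 7))
  # degenerate branch: at/below the floor -> 0 and flagged
  out <- rician_correct(1, noise_model(1))
  expect_identical(out$signal, 0)
  expect_true(out$flagged)
  # per-b sigma vector recycles along the signal
  out <- rician_correct(c(10, 10), noise_model(c(1, 7)))
  expect_equal(out$signal, c(sqrt(98), sqrt(2)), tolerance = 1e-12)
  expect_equal(out$flagged, c(FALSE, FALSE))
  # floor multiplier flags weak but nonzero points
  out <- rician_correct(c(100, 3), noise_model(2, floor_multiplier = 1.5))
  expect_equal(out$flagged, c(FALSE, TRUE))
})

test_that("sigma estimation from an ROI", {
  set.seed(4)
  bg <- add_rician_noise(rep(0, 2e4), 3)
  expect_equal(estimate_sigma(bg, "rayleigh"), 3, tolerance = 0.05)
  hi <- add_rician_noise(rep(500, 2e4), 3)
  expect_equal(estimate_sigma(hi, "sd"), 3, tolerance = 0.05)
})

test_that("two-point ADC arithmetic and degenerate cases", {
  cur <- decay_curve(c(0, 1000, 3000), c(1, exp(-1), 0.1))
  expect_equal(two_point_adc(cur), 1e-3, tolerance = 1e-12)
  cur <- decay_curve(c(0, 1000), c(0.8, 0.8))
  expect_equal(two_point_adc(cur), 0)
  cur <- decay_curve(c(0, 1000), c(0.5, 0.8))
  expect_warning(adc <- two_point_adc(cur), "negative")
  expect_true(adc < 0)
  expect_error(two_point_adc(decay_curve(c(0, 500), c(1, 0.5))), "b = 1000")
})

test_that("noise-free curves are recovered to high precision", {
  # GM parameters; 5-point protocol
  ft <- fit_curve(clean_curve("mlf2", D = 0.97e-3, alpha = 0.77), "mlf2")
  expect_true(ft$converged)
  expect_equal(ft$params[["alpha"]], 0.77, tolerance = 1e-6)
  expect_equal(ft$params[["D"]], 0.97e-3, tolerance = 1e-6)
  expect_equal(ft$K_mlf, kurtosis_from_alpha(0.77), tolerance = 1e-5)
  # monoexponential data: mlf2 returns alpha at the upper bound
  ft <- fit_curve(clean_curve("mono", D = 1.2e-3), "mlf2")
  expect_equal(ft$params[["alpha"]], 1, tolerance = 1e-8)
  expect_equal(ft$params[["D"]], 1.2e-3, tolerance = 1e-6)
  # K_app = 0 data: dki fit finds K ~ 0
  ft <- fit_curve(clean_curve("mono", D = 1.2e-3), "dki")
  expect_equal(ft$params[["K_app"]], 0, tolerance = 1e-6)
  expect_equal(ft$params[["D"]], 1.2e-3, tolerance = 1e-6)
  # dki self-recovery
  ft <- fit_curve(clean_curve("dki", D = 1.02e-3, K_app = 0.58), "dki")
  expect_equal(ft$params[["D"]], 1.02e-3, tolerance = 1e-6)
  expect_equal(ft$params[["K_app"]], 0.58, tolerance = 1e-5)
  # mlf3 on beta = 2 data sits at the beta boundary and matches mlf2
  f2 <- fit_curve(clean_curve("mlf2", D = 0.72e-3, alpha = 0.49), "mlf2")
  f3 <- fit_curve(clean_curve("mlf2", D = 0.72e-3, alpha = 0.49), "mlf3")
  expect_equal(f3$params[["beta"]], 2, tolerance = 1e-4)
  expect_equal(f3$params[["alpha"]], f2$params[["alpha"]], tolerance = 1e-4)
  expect_equal(f3$params[["D"]], f2$params[["D"]], tolerance = 1e-4)
})

test_that("dropping the largest b barely moves a noise-free mlf2 fit", {
  full <- fit_curve(clean_curve("mlf2", D = 0.97e-3, alpha = 0.77), "mlf2")
  red <- fit_curve(clean_curve("mlf2", D = 0.97e-3, alpha = 0.77,
                               b = c(0, 500, 1000, 3000)), "mlf2")
  expect_lt(abs(full$params[["alpha"]] - red$params[["alpha"]]), 1e-6)
})

test_that("too few points raise an input error", {
  expect_error(fit_curve(decay_curve(c(0, 1000), c(1, 0.5)), "mlf2"),
               "too few")
  expect_error(fit_curve(decay_curve(c(0, 500, 1000), c(1, 0.7, 0.5)), "mlf3"),
               "too few")
})

test_that("fits are deterministic given curve, model and seed", {
  set.seed(99)
  noisy <- add_rician_noise(1000 * model_mlf2(paper_bvals, 0.97e-3, 0.77), 25)
  cur <- decay_curve(paper_bvals, noisy)
  f1 <- fit_curve(cur, "mlf2", noise = noise_model(25), seed = 5)
  f2 <- fit_curve(cur, "mlf2", noise = noise_model(25), seed = 5)
  expect_identical(f1$params, f2$params)
})

test_that("noisy recovery attains the information bound (WM and GM)", {
  # 100 curves per tissue class per model at sigma = s0/40 on the 5-b
  # protocol. The yardstick is the Cramer-Rao bound for the normalized
  # design (shared-S0 covariance; see helper): median |error| must stay
  # within 1.4x the bound-implied median 0.6745 sd. The factor absorbs the
  # Rician-vs-Gaussian approximation and the Monte Carlo error of a
  # 100-sample median; an inefficient or biased fitter lands well above 2x.
  s0 <- 1000; sig <- s0 / 40
  ref <- brain_roi_reference[brain_roi_reference$roi %in% c("WM", "GM"), ]
  set.seed(7)
  for (model in c("mono", "mlf2", "dki")) {
    for (k in seq_len(nrow(ref))) {
      a <- ref$alpha[k]
      D <- switch(model, mono = ref$adc[k], mlf2 = ref$D_mlf[k],
                  dki = ref$D_K[k])
      K <- ref$K_app[k]
      errD <- errA <- numeric(100)
      for (i in 1:100) {
        clean <- s0 * switch(model,
                             mono = model_mono(paper_bvals, D),
                             mlf2 = model_mlf2(paper_bvals, D, a),
                             dki = model_dki(paper_bvals, D, K))
        cur <- decay_curve(paper_bvals, add_rician_noise(clean, sig))
        ft <- fit_curve(cur, model, noise = noise_model(sig))
        errD[i] <- abs(ft$params[["D"]] / D - 1)
        errA[i] <- if (model == "mlf2") abs(ft$params[["alpha"]] - a) else NA
      }
      cr <- crlb_normalized(model, D, alpha = a, K_app = K, sigma_rel = 1 / 40)
      lbl <- paste(model, ref$roi[k])
      expect_lt(median(errD), 1.4 * 0.6745 * cr[1] / D, label = lbl)
      if (model == "mlf2")
        expect_lt(median(errA), 1.4 * 0.6745 * cr[2],
                  label = paste(lbl, "alpha"))
    }
  }
})

test_that("DKI apex validity check", {
  expect_match(dki_validity_check(list(D = 1e-3, K_app = 1), 4000), "apex")
  expect_true(dki_validity_check(list(D = 1e-3, K_app = 0), 4000))
  expect_true(dki_validity_check(list(D = 1e-3, K_app = 1), 1000))
  # a dki fit whose apex is inside the sampled range carries the warning
  ft <- fit_curve(clean_curve("dki", D = 1.2e-3, K_app = 2), "dki")
  expect_true(any(grepl("apex", ft$warnings)))
})

test_that("fit_maps shapes, mask handling and single-voxel equivalence", {
  sp <- phantom_spec(shape = c(4, 2, 1))
  ph <- make_phantom(sp)
  # empty mask -> all-NA maps
  m0 <- fit_maps(ph$stack, sp$b_values,
                 mask = array(FALSE, c(4, 2, 1)), model = "mlf2")
  expect_true(all(is.na(m0$alpha)))
  # single-voxel mask equals fit_curve on that voxel
  msk <- array(FALSE, c(4, 2, 1)); msk[2, 1, 1] <- TRUE
  m1 <- fit_maps(ph$stack, sp$b_values, mask = msk, model = "mlf2")
  ft <- fit_curve(decay_curve(sp$b_values, ph$stack[2, 1, 1, ]), "mlf2")
  expect_equal(m1$alpha[2, 1, 1], ft$params[["alpha"]], tolerance = 1e-12)
  expect_equal(m1$D[2, 1, 1], ft$params[["D"]], tolerance = 1e-12)
  expect_equal(sum(!is.na(m1$alpha)), 1L)
  # ADC map agrees with the two-point formula
  expect_equal(m1$adc[2, 1, 1],
               two_point_adc(decay_curve(sp$b_values, ph$stack[2, 1, 1, ])),
               tolerance = 1e-12)
  # shape mismatches raise input errors
  expect_error(fit_maps(ph$stack, c(0, 500), model = "mlf2"), "bvals")
  expect_error(fit_maps(ph$stack, sp$b_values,
                        mask = array(TRUE, c(3, 2, 1)), model = "mlf2"),
               "mask")
})
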