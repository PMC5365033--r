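test_that("effective diffusion time is Delta - delta/3", {
  expect_equal(effective_diffusion_time(paper_protocol()), 0.031,
               tolerance = 1e-12)  # 41.2 ms, 30.6 ms -> 31 ms
  p <- acquisition_protocol(G = 1e-5, delta = 1e-9, Delta = 0.030)
  expect_equal(effective_diffusion_time(p), 0.030, tolerance = 1e-6)
  p <- acquisition_protocol(G = 1e-5, delta = 0.030, Delta = 0.030)
  expect_equal(effective_diffusion_time(p), 0.020, tolerance = 1e-12)
  expect_error(acquisition_protocol(G = 1, delta = 2, Delta = 1), "delta")
})

test_that("b = q^2 t holds and b scales with G^2", {
  p <- paper_protocol(G = 4e-5)
  expect_equal(b_value(p),
               q_value(p)^2 * effective_diffusion_time(p), tolerance = 1e-12)
  p0 <- paper_protocol(G = 0)
  expect_identical(q_value(p0), 0)
  expect_identical(b_value(p0), 0)
  expect_equal(b_value(paper_protocol(G = 8e-5)) / b_value(p), 4,
               tolerance = 1e-12)
  # q = 359.21 mm^-1 at t = 31 ms corresponds to b = 4000 s/mm^2
  g <- 2.6752218744e8
  p4000 <- acquisition_protocol(gamma = g, G = 359.21 / (g * 30.6e-3),
                                delta = 30.6e-3, Delta = 41.2e-3)
  expect_equal(b_value(p4000), 4000, tolerance = 1e-4)
})

test_that("probe length scales and net displacement reproduce the protocol numbers", {
  # in micrometres: 2.8 at b = 4000, 7.9 at b = 500 (t = 31 ms)
  expect_equal(probe_length_scale(4000, 0.031) * 1e3, 2.8, tolerance = 0.02)
  expect_equal(probe_length_scale(500, 0.031) * 1e3, 7.9, tolerance = 0.01)
  expect_equal(probe_length_scale(4 * 777, 0.031),
               probe_length_scale(777, 0.031) / 2, tolerance = 1e-12)
  expect_error(probe_length_scale(0, 0.031), "b = 0")
  # sqrt(2 D t): ~7.9 um at D = 1.0e-3 mm^2/s, ~6.1 um at 0.6e-3
  expect_equal(net_displacement(1.0e-3, 0.031) * 1e3, 7.9, tolerance = 0.01)
  expect_equal(net_displacement(0.6e-3, 0.031) * 1e3, 6.1, tolerance = 0.01)
  expect_identical(net_displacement(1e-3, 0), 0)
})

test_that("signal models obey their reduction chain", {
  b <- seq(0, 10000, by = 250)
  D <- 0.97e-3
  expect_equal(model_mlf3(b, D, alpha = 0.75, beta = 2),
               model_mlf2(b, D, 0.75), tolerance = 1e-12)
  expect_equal(model_mlf2(b, D, alpha = 1), model_mono(b, D),
               tolerance = 1e-12)
  expect_equal(model_dki(b, D, K_app = 0), model_mono(b, D),
               tolerance = 1e-12)
  expect_equal(model_mlf3(b, D, alpha = 1, beta = 2), model_mono(b, D),
               tolerance = 1e-12)
  # (bD)^(beta/2) = 1 regardless of beta when bD = 1
  expect_equal(model_mlf3(1 / D, D, alpha = 1, beta = 1.5), exp(-1),
               tolerance = 1e-12)
  # stretched exponential limit at alpha = 1
  expect_equal(model_mlf3(b, D, alpha = 1, beta = 1.6),
               exp(-(b * D)^0.8), tolerance = 1e-12)
})

test_that("all models are 1 at b = 0 and decrease up to the DKI apex", {
  b <- seq(0, 10000, by = 100)
  D <- 1e-3
  for (s in list(model_mono(b, D), model_mlf2(b, D, 0.6),
                 model_mlf3(b, D, 0.8, 1.7), model_dki(b, D, 0))) {
    expect_equal(s[1], 1)
    expect_true(all(diff(s) < 0))
  }
  # K_app > 0: decreasing before the apex b* = 3/(D K), increasing after
  s <- model_dki(b, D, K_app = 1)   # b* = 3000
  expect_true(all(diff(s[b <= 3000]) < 0))
  expect_true(all(diff(s[b >= 3000]) > 0))
  expect_equal(model_dki(1000, 1e-3, 1), exp(-5 / 6), tolerance = 1e-12)
})

test_that("characteristic functions are consistent with the signal models", {
  q <- c(0, 50, 150, 300)
  t <- 0.031
  D <- 1e-3
  gd <- generalized_diffusivity(D)
  expect_equal(cf_general(0, t, gd, 0.8, 1.5), 1)
  expect_equal(cf_subdiffusion(0, t, D, 0.8), 1)
  expect_equal(cf_superdiffusion(0, t, D, 1.5), 1)
  # Gaussian limit: all three coincide with exp(-D q^2 t)
  expect_equal(cf_general(q, t, gd, 1, 2), exp(-D * q^2 * t), tolerance = 1e-12)
  expect_equal(cf_subdiffusion(q, t, D, 1), exp(-D * q^2 * t), tolerance = 1e-12)
  expect_equal(cf_superdiffusion(q, t, D, 2), exp(-D * q^2 * t), tolerance = 1e-12)
  # closed-form value where D q^2 t^alpha = 1
  q1 <- 1 / sqrt(D * sqrt(t))
  expect_equal(cf_subdiffusion(q1, t, D, 0.5), 0.4275835761558071,
               tolerance = 1e-9)
})

test_that("generalized/classical conversion is exact in its limits", {
  gd <- generalized_diffusivity(2.3e-3, mu = 5e-3, tau = 0.02)
  out <- generalized_to_classical(gd, alpha = 1, beta = 2, t = 0.031)
  expect_equal(out$D, gd$D_ab, tolerance = 1e-12)
  expect_equal(out$D_pow, gd$D_ab, tolerance = 1e-12)
  # round trip through the unit-preserving scales
  gd2 <- generalized_from_classical(1e-3, alpha = 0.7, beta = 1.6,
                                    mu = 2, tau = 3)
  expect_equal(gd2$D_ab, 1e-3 * 3^0.3 * 2^(-0.4), tolerance = 1e-12)
  # at beta = 2, tau = t the 3-parameter CF argument collapses to -b D
  D12 <- 0.97e-3; t <- 0.031; a <- 0.75
  gd3 <- generalized_from_classical(D12, alpha = a, beta = 2, tau = t)
  q <- c(100, 250, 400)
  # the two argument forms agree to rounding; series cancellation near the
  # radius amplifies the last-digit argument difference to ~1e-11
  expect_equal(cf_general(q, t, gd3, a, 2),
               model_mlf2(q^2 * t, D12, a), tolerance = 1e-10)
})

test_that("decay_curve validates and orders its input", {
  cur <- decay_curve(c(1000, 0, 500), c(0.5, 1, 0.7))
  expect_equal(cur$b, c(0, 500, 1000))
  expect_equal(cur$s0, 1)
  expect_error(decay_curve(c(0, 0, 500), c(1, 1, 0.5)), "duplicate")
  expect_error(decay_curve(c(0, 500), c(1, -1)), "positive")
  expect_error(decay_curve(c(-5, 500), c(1, 1)), "non-negative")
  expect_error(decay_curve(0, 1), "at least 2")
})
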