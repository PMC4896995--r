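test_that("single-component T2 matches the two-point closed form", {
  expect_equal(t2_forward(0, 750, 80), 750)
  te <- c(20, 100)
  s <- c(800, 300)
  t2_closed <- (te[2] - te[1]) / log(s[1] / s[2])
  sch <- acquisition_schedule(2, te_ms = te)
  fit <- fit_t2_single(array(s, c(1, 1, 1, 2)), sch)
  expect_equal(fit$mcmap[1, 1, 1, 2], t2_closed, tolerance = 1e-8)

  # 19-echo noiseless phantom
  sch19 <- acquisition_schedule(19, te_spacing_ms = 12)
  y <- t2_forward(sch19$te_ms, 1000, 70)
  f19 <- fit_t2_single(array(y, c(1, 1, 1, 19)), sch19)
  expect_equal(f19$mcmap[1, 1, 1, ], c(1000, 70), tolerance = 1e-6)

  # all-zero voxel flagged as zero output
  f0 <- fit_t2_single(array(0, c(1, 1, 1, 19)), sch19)
  expect_true(all(f0$mcmap == 0))
})

test_that("multi-component T2 NNLS recovers exact mixtures and sums to one", {
  sch <- acquisition_schedule(19, te_spacing_ms = 12)
  grid <- c(20, 80, 150)
  y_pure <- 1000 * exp(-sch$te_ms / 80)
  fp <- fit_t2_multicomponent(array(y_pure, c(1, 1, 1, 19)), sch, grid)
  expect_equal(fp$mcmap[1, 1, 1, 1:3], c(0, 1, 0), tolerance = 1e-9)

  grid2 <- c(42, 150)
  y_mix <- 1000 * (0.5 * exp(-sch$te_ms / 42) + 0.5 * exp(-sch$te_ms / 150))
  fm <- fit_t2_multicomponent(array(y_mix, c(1, 1, 1, 19)), sch, grid2)
  expect_equal(fm$mcmap[1, 1, 1, 1:2], c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(fm$mcmap[1, 1, 1, 1:2]), 1, tolerance = 1e-9)

  # single-component T2 of the same voxel approximates the grand mean
  fs <- fit_t2_single(array(y_mix, c(1, 1, 1, 19)), sch)
  grand <- sum(c(0.5, 0.5) * grid2)
  expect_lt(abs(fs$mcmap[1, 1, 1, 2] - grand) / grand, 0.05)

  expect_error(fit_t2_multicomponent(array(y_mix, c(1, 1, 1, 19)), sch,
                                     c(80, 20)),
               "strictly increasing")
})

test_that("priors pull an under-determined spectrum toward the prior", {
  sch <- acquisition_schedule(19, te_spacing_ms = 12)
  grid <- c(20, 45, 80)   # 20 vs 45 poorly separated at these TEs
  y <- 1000 * (0.15 * exp(-sch$te_ms / 20) + 0.35 * exp(-sch$te_ms / 45) +
                 0.5 * exp(-sch$te_ms / 80))
  vox <- array(y, c(1, 1, 1, 19))
  prior <- array(c(0.15, 0.35, 0.5), c(1, 1, 1, 3))
  f_prior <- fit_t2_multicomponent(vox, sch, grid, priors = prior,
                                   prior_strength = 50)
  f_plain <- fit_t2_multicomponent(vox, sch, grid)
  err_prior <- sum(abs(f_prior$mcmap[1, 1, 1, 1:3] - c(0.15, 0.35, 0.5)))
  err_plain <- sum(abs(f_plain$mcmap[1, 1, 1, 1:3] - c(0.15, 0.35, 0.5)))
  expect_lte(err_prior, err_plain + 1e-12)
  expect_equal(sum(f_prior$mcmap[1, 1, 1, 1:3]), 1, tolerance = 1e-9)
})

test_that("MWF is the sub-threshold fraction sum and monotone in threshold", {
  grid <- c(20, 80, 150)
  fr <- c(0.15, 0.70, 0.15)
  expect_equal(compute_mwf(fr, grid), 0.15)
  expect_equal(compute_mwf(fr, grid, threshold_ms = 100), 0.85)
  expect_equal(compute_mwf(fr, grid, threshold_ms = 10), 0)
  thresholds <- seq(10, 200, by = 10)
  vals <- vapply(thresholds, function(th) compute_mwf(fr, grid, th), 1.0)
  expect_true(all(diff(vals) >= 0))
})

test_that("EPG reduces to pure exponential decay at perfect refocusing", {
  n <- 32; esp <- 12
  for (t2 in c(20, 50, 100, 300, 800, 2000)) {
    got <- epg_forward(n, esp, pi, t2)
    expect_lt(max(abs(got - exp(-(1:n) * esp / t2))), 1e-9)
  }
  expect_true(all(epg_forward(16, 12, 0, 80) == 0))
  expect_error(epg_forward(16, 12, 3.5, 80), "\\[0, pi\\]")
})

test_that("real-arithmetic EPG matches the complex-valued oracle", {
  for (alpha in c(0.4, 1.2, 2 * pi / 3, 2.6, 3.0)) {
    for (t2 in c(30, 80, 400)) {
      got <- epg_forward(32, 12, alpha, t2, t1_ms = 1000)
      want <- epg_complex_oracle(32, 12, alpha, t2, t1 = 1000)
      expect_lt(max(abs(got - want)), 1e-10)
    }
  }
})

test_that("EPG amplitudes stay in [0, 1] for unit S0", {
  set.seed(31)
  for (i in 1:25) {
    a <- epg_forward(24, 10, runif(1, 0, pi), runif(1, 10, 2000),
                     t1_ms = runif(1, 100, 4000))
    expect_true(all(a >= 0 & a <= 1 + 1e-12))
  }
})

test_that("EPG fit recovers alpha and the spectrum; CPMG-limit equivalence", {
  grid <- c(20, 80, 400)
  sch <- acquisition_schedule(32, te_spacing_ms = 12)
  basis <- qmrfit:::epg_basis(32, 12, 2.6, grid)
  y0 <- 1000 * as.numeric(basis %*% c(0.15, 0.80, 0.05))
  set.seed(32)
  y <- y0 + rnorm(32, 0, 5)   # SNR 200
  fit <- fit_t2_epg(array(y, c(1, 1, 1, 32)), sch, grid)
  expect_lt(abs(fit$mcmap[1, 1, 1, 5] - 2.6), 0.05)
  expect_lt(abs(compute_mwf(fit$mcmap[1, 1, 1, 1:3], grid) - 0.15), 0.03)
  expect_gte(fit$b1map[1, 1, 1], 0)
  expect_lte(fit$b1map[1, 1, 1], pi)

  # at alpha = pi the EPG spectrum equals the plain multi-exponential one
  ypi <- 1000 * as.numeric(qmrfit:::epg_basis(32, 12, pi, grid) %*% c(0.15, 0.80, 0.05))
  fpi <- fit_t2_epg(array(ypi, c(1, 1, 1, 32)), sch, grid)
  fmu <- fit_t2_multicomponent(array(ypi, c(1, 1, 1, 32)), sch, grid)
  expect_equal(fpi$mcmap[1, 1, 1, 1:3], fmu$mcmap[1, 1, 1, 1:3],
               tolerance = 1e-6)

  # flat signal: alpha undefined, voxel flagged (all-zero output)
  fflat <- fit_t2_epg(array(5, c(1, 1, 1, 32)), sch, grid)
  expect_true(all(fflat$mcmap == 0))
})
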