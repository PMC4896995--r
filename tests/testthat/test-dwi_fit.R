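test_that("ADC matches the two-point closed form and both routes agree", {
  sch <- acquisition_schedule(2, bvals_s_per_mm2 = c(0, 1000),
                              bvecs = rbind(c(0, 0, 0), c(0, 0, 1)))
  y <- c(1000, 1000 * exp(-1))
  f_log <- fit_adc(array(y, c(1, 1, 1, 2)), sch, "loglinear")
  expect_equal(f_log$mcmap[1, 1, 1, ], c(1000, 1e-3), tolerance = 1e-10)

  sch4 <- acquisition_schedule(4, bvals_s_per_mm2 = c(0, 300, 700, 2000),
                               bvecs = rbind(0, diag(3)))
  y4 <- 900 * exp(-sch4$bvals_s_per_mm2 * 0.8e-3)
  f_l <- fit_adc(array(y4, c(1, 1, 1, 4)), sch4, "loglinear")
  f_n <- fit_adc(array(y4, c(1, 1, 1, 4)), sch4, "nonlinear")
  expect_equal(f_l$mcmap[1, 1, 1, ], f_n$mcmap[1, 1, 1, ], tolerance = 1e-8)

  # zero samples are excluded from the log fit
  y0 <- c(1000, exp(-1) * 1000, 0, 500)
  f0 <- fit_adc(array(y0, c(1, 1, 1, 4)), sch4, "loglinear")
  expect_true(all(is.finite(f0$mcmap)))
})

test_that("FA limits and the hand-derived prolate value hold", {
  iso <- dti_metrics(c(0.8e-3, 0, 0, 0.8e-3, 0, 0.8e-3))
  expect_equal(iso$fa, 0)
  expect_equal(iso$md, 0.8e-3)
  stick <- dti_metrics(c(1e-3, 0, 0, 0, 0, 0))
  expect_equal(stick$fa, 1)
  pro <- dti_metrics(c(1.7e-3, 0, 0, 0.3e-3, 0, 0.3e-3))
  expect_equal(pro$fa, 0.799, tolerance = 1e-3 / 0.799)
  expect_equal(pro$pdd, c(1, 0, 0))   # sign fixed via z, then y, then x
})

test_that("noiseless tensors refit exactly, mcmap ordered [D..., S0]", {
  sch <- dwi_shell_schedule()
  set.seed(41)
  for (i in 1:5) {
    # random SPD tensor with realistic scale
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    ev <- sort(runif(3, 0.2e-3, 2.2e-3), decreasing = TRUE)
    d <- q %*% diag(ev) %*% t(q)
    d6 <- c(d[1, 1], d[1, 2], d[1, 3], d[2, 2], d[2, 3], d[3, 3])
    g <- sch$bvecs
    y <- 1000 * exp(-sch$bvals_s_per_mm2 * rowSums((g %*% d) * g))
    fit <- fit_dti(array(y, c(1, 1, 1, length(y))), sch)
    expect_equal(fit$mcmap[1, 1, 1, ], c(d6, 1000),
                 tolerance = 1e-9, ignore_attr = TRUE)
    met <- dti_metrics(fit$mcmap[1, 1, 1, 1:6])
    expect_equal(met$evals, ev, tolerance = 1e-9)
  }
  # rank-deficient direction set is rejected
  bad <- acquisition_schedule(7, bvals_s_per_mm2 = c(0, rep(1000, 6)),
                              bvecs = rbind(c(0, 0, 0),
                                            matrix(rep(c(1, 0, 0), 6),
                                                   ncol = 3, byrow = TRUE)))
  expect_error(fit_dti(array(1, c(1, 1, 1, 7)), bad), "rank-deficient")
})

test_that("NODDI forward model has the analytic limits", {
  sch <- dwi_shell_schedule()
  b <- sch$bvals_s_per_mm2
  # b = 0 gives S0 regardless of parameters
  s <- noddi_forward(c(0.5, 0.2, 0.3, 1234, 0.7, 1.1), sch)
  expect_equal(s[b == 0], rep(1234, sum(b == 0)))
  # pure free water decays at d_iso = 3e-3
  s_iso <- noddi_forward(c(0, 1, 0.5, 1000, 0, 0), sch)
  expect_equal(s_iso, 1000 * exp(-b * 3e-3), tolerance = 1e-12)
  # zero dispersion, v_in = 1: single stick response
  mu <- c(0, 0, 1)
  s_stick <- noddi_forward(c(1, 0, 1e-7, 1000, 0, 0), sch, n_samples = 1000)
  gm2 <- as.numeric((sch$bvecs %*% mu)^2)
  expect_lt(max(abs(s_stick - 1000 * exp(-b * 1.7e-3 * gm2))) / 1000, 1e-4)
  # small but nonzero dispersion stays close to the stick
  s_g <- noddi_forward(c(1, 0, 0.02, 1000, 0, 0), sch, n_samples = 1000)
  expect_lt(max(abs(s_g - s_stick)) / 1000, 0.1)
})

test_that("NODDI quadrature is converged at the default sampling", {
  sch <- dwi_shell_schedule()
  p <- c(0.5, 0.1, 0.2, 1000, 0.9, 0.4)
  s1 <- noddi_forward(p, sch, n_samples = 724)
  s2 <- noddi_forward(p, sch, n_samples = 1448)
  expect_lt(max(abs(s1 - s2)) / 1000, 1e-4)
  expect_warning(noddi_forward(p, sch, n_samples = 20), "Watson samples")
})

test_that("compartment signals are bounded and fractions constrained", {
  sch <- dwi_shell_schedule()
  set.seed(42)
  for (i in 1:10) {
    v_in <- runif(1); v_iso <- runif(1, 0, 1 - v_in)
    p <- c(v_in, v_iso, runif(1, 0.05, 1), 1, runif(1, 0, pi),
           runif(1, 0, 2 * pi))
    s <- noddi_forward(p, sch)
    expect_true(all(s > 0 & s <= 1 + 1e-12))
  }
})

test_that("NODDI fit recovers noiseless parameters from a DTI start", {
  sch <- dwi_shell_schedule()
  truth <- c(0.5, 0.1, 0.2, 1000, 0, 0)   # v_in, v_iso, gamma, S0, mu = +z
  y <- noddi_forward(truth, sch)
  fit <- fit_noddi(array(y, c(1, 1, 1, length(y))), sch)
  got <- fit$mcmap[1, 1, 1, ]
  expect_equal(got[1:3], truth[1:3], tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(got[4], 1000, tolerance = 1)
  mu_hat <- qmrfit:::sph_to_unit(got[5], got[6])
  expect_lt(acos(min(abs(sum(mu_hat * c(0, 0, 1))), 1)) * 180 / pi, 2)
  expect_true(got[1] + got[2] <= 1 + 1e-9)
  expect_true(all(got[1:2] >= 0 & got[1:2] <= 1))
  expect_true(fit$converged[1, 1, 1])

  # the DTI initialisation is exposed: initial orientation equals the PDD
  pdd <- fit$dti_init$pdd[1, 1, 1, ]
  expect_lt(acos(min(abs(pdd[3]), 1)) * 180 / pi, 3)
})
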