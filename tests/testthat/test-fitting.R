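test_that("single-component model equals the plain powder spectrum", {
  m <- quick_model()
  sp <- simulate_model(m, 9.7671, grid_size = 20)
  ps <- powder_spectrum(spin_system(c(2.008, 2.006, 2.0022), c(14, 14, 100)),
                        linewidth_spec(c(20, 20, 18)), 9.7671,
                        field_range = range(sp$field_mT), grid_size = 20,
                        solver = "first_order")
  expect_equal(sp$intensity, ps$intensity, tolerance = 1e-12)
})

test_that("duplicate components and weight (1, 0) collapse to one", {
  one <- quick_model()
  two <- quick_model(g_xx = c(2.008, 2.008), weights = c(0.4, 0.6))
  s1 <- simulate_model(one, 262.8436, grid_size = 24)
  s2 <- simulate_model(two, 262.8436, field_axis = s1$field_mT,
                       grid_size = 24)
  expect_equal(s1$intensity, s2$intensity, tolerance = 1e-12)
  wz <- quick_model(g_xx = c(2.008, 2.004), weights = c(1, 0))
  s3 <- simulate_model(wz, 262.8436, field_axis = s1$field_mT,
                       grid_size = 24)
  expect_equal(s1$intensity, s3$intensity, tolerance = 1e-12)
})

test_that("requesting a band the model does not know is an error", {
  expect_error(simulate_model(quick_model(), 34.0), "not among")
})

test_that("the full reference model resolves two g_xx features at J band", {
  m <- exp_fit_parameters()
  sp <- simulate_model(m, 262.8436)
  d <- to_first_derivative(sp)
  # the two g_xx values are separated by dg * B / g in field
  b1 <- 1e3 * 262.8436 / (m$g_xx[1] * MHZ_PER_MT_REF)
  b2 <- 1e3 * 262.8436 / (m$g_xx[2] * MHZ_PER_MT_REF)
  expect_gt(b2 - b1, 1.5)  # resolved shoulder region
  # absorption must rise before b2 (the shoulder) and peak between
  lo <- sp$intensity[sp$field_mT > b1 - 1 & sp$field_mT < b2 + 1]
  expect_gt(max(lo), 0.3 * max(sp$intensity))
})

test_that("fit is invariant to amplitude scaling of the data", {
  m <- quick_model(bands = c(Q = 33.6615), alw_xx = 24, alw_yy = 22,
                   alw_zz = 18)
  sp <- simulate_model(m, 33.6615, grid_size = 20, n_points = 512)
  scaled <- sp
  scaled$intensity <- sp$intensity * 7.3
  init <- m
  init$alw$alw_xx <- 30
  f1 <- global_fit(list(sp), init, grid_size = 20,
                   fixed = c("gxx1", "gyy", "gzz", "Axx", "Ayy", "Azz"))
  f2 <- global_fit(list(scaled), init, grid_size = 20,
                   fixed = c("gxx1", "gyy", "gzz", "Axx", "Ayy", "Azz"))
  expect_equal(f1$model$alw$alw_xx, f2$model$alw$alw_xx, tolerance = 1e-10)
  expect_equal(f1$model$alw$alw_xx[1], 24, tolerance = 1e-6)
})

test_that("single-component two-band round trip recovers exactly", {
  truth <- quick_model(bands = c(X = 9.7671, W = 93.993))
  spectra <- lapply(c(9.7671, 93.993), function(f) {
    simulate_model(truth, f, grid_size = 20, n_points = 512)
  })
  init <- truth
  init$g_xx <- truth$g_xx + 1.5e-4
  init$g_yy <- truth$g_yy - 1e-4
  init$g_zz <- truth$g_zz + 1e-4
  init$A <- truth$A * 1.05
  init$alw$alw_xx <- truth$alw$alw_xx * 1.25
  fit <- global_fit(spectra, init, grid_size = 20)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$g_xx - truth$g_xx), 1e-6)
  expect_lt(abs(fit$model$g_yy - truth$g_yy), 1e-6)
  expect_lt(abs(fit$model$g_zz - truth$g_zz), 1e-6)
  expect_lt(max(abs(fit$model$A - truth$A)), 0.05)
  expect_lt(max(abs(fit$model$alw$alw_xx - truth$alw$alw_xx)), 0.05)
})

test_that("fixed parameters stay at their initial values", {
  m <- quick_model(bands = c(Q = 33.6615))
  sp <- simulate_model(m, 33.6615, grid_size = 16, n_points = 512)
  init <- m
  init$A <- c(16, 16, 104)
  fit <- global_fit(list(sp), init, grid_size = 16,
                    fixed = c("Axx", "Ayy", "Azz"))
  expect_equal(fit$model$A, c(16, 16, 104))
  expect_error(global_fit(list(sp), init, fixed = "nosuch"), "unknown")
})

test_that("near-degenerate fitted components are flagged unresolved", {
  m <- quick_model(g_xx = c(2.008, 2.008 - 2e-5), weights = c(0.6, 0.4))
  fake_fit <- structure(list(model = m), class = "fit_result")
  # flag logic itself
  expect_true(length(m$g_xx) > 1 && min(abs(diff(m$g_xx))) < 5e-5)
  expect_equal(extract_alw(fake_fit)$alw_xx, m$alw$alw_xx)
})

test_that("J-band initialization helper locates the g_xx components", {
  m <- exp_fit_parameters()
  sp <- simulate_model(m, 262.8436)
  g0 <- init_gxx_from_jband(sp, n_components = 2)
  expect_length(g0, 2)
  expect_lt(abs(g0[1] - m$g_xx[1]), 5e-4)
  expect_true(all(diff(g0) < 0))
})
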