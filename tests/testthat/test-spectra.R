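test_that("effective g follows the collinear closed form", {
  sys <- spin_system(c(2.00834, 2.00598, 2.0023))
  expect_equal(effective_g(sys, c(1, 0, 0)), 2.00834)
  expect_equal(effective_g(sys, c(0, 1, 0)), 2.00598)
  expect_equal(effective_g(spin_system(2), matrix(rnorm(9), 3)), rep(2, 3))
  expect_equal(effective_g(spin_system(c(2.01, 2.00, 2.00)),
                           c(1 / sqrt(2), 1 / sqrt(2), 0)),
               sqrt((2.01^2 + 2.00^2) / 2))
})

test_that("spin system rejects non-physical g-values", {
  expect_error(spin_system(c(3.5, 2.0, 2.0)), "nitroxide range")
  expect_error(spin_system(c(2.0, NA, 2.0)), "finite")
})

test_that("decoupled nucleus gives three coincident electron Zeeman lines", {
  sys <- spin_system(2.0023, 0)
  b_ref <- 1e3 * 9.7671 / (2.0023 * MHZ_PER_MT_REF)
  for (solver in c("exact", "first_order")) {
    r <- resonance_lines(sys, c(0.3, -0.5, 0.81), 9.7671, solver = solver)
    expect_equal(as.numeric(r$fields), rep(b_ref, 3), tolerance = 1e-6)
  }
})

test_that("first-order solver reproduces the hyperfine offset formula", {
  sys <- spin_system(2.0023, 100)
  r <- resonance_lines(sys, c(0, 0, 1), 9.7671, solver = "first_order")
  off <- 100 / (2.0023 * MHZ_PER_MT_REF)
  centre <- 1e3 * 9.7671 / (2.0023 * MHZ_PER_MT_REF)
  expect_equal(as.numeric(r$fields), centre + c(-off, 0, off),
               tolerance = 1e-9)
})

test_that("exact and first-order fields agree when A/nu is small", {
  set.seed(11)
  ns <- random_orientations(100)
  # X band with small couplings and J band with full nitroxide couplings:
  # in both cases A/nu < 1e-3
  cases <- list(list(A = c(4, 6, 9), nu = 9.7671),
                list(A = c(14, 14, 100), nu = 262.8436))
  for (cs in cases) {
    sys <- spin_system(c(2.00834, 2.00598, 2.0023), cs$A)
    fe <- resonance_lines(sys, ns, cs$nu, solver = "exact")$fields
    ff <- resonance_lines(sys, ns, cs$nu, solver = "first_order")$fields
    expect_lt(max(abs(fe - ff)), 0.01)
  }
})

test_that("exact solver reproduces the analytic second-order shift", {
  # at X band with A = 100 MHz the deviation from first order is the
  # textbook second-order hyperfine shift A^2 (I(I+1) - mI^2) / (2 nu),
  # i.e. A_mT^2 (2 - mI^2) / (2 B) in field units -- far above 0.01 mT
  sys <- spin_system(2.0023, 100)
  fe <- resonance_lines(sys, c(0, 0, 1), 9.7671, solver = "exact")$fields
  ff <- resonance_lines(sys, c(0, 0, 1), 9.7671,
                        solver = "first_order")$fields
  a_mt <- 100 / (2.0023 * MHZ_PER_MT_REF)
  b0 <- 1e3 * 9.7671 / (2.0023 * MHZ_PER_MT_REF)
  predicted <- -a_mt^2 * (2 - c(1, 0, 1)^2) / (2 * b0)
  expect_equal(as.numeric(fe - ff), predicted, tolerance = 0.02)
  expect_gt(min(abs(fe - ff)), 0.01)
})

test_that("line width conversion uses h/(g mu_B) and the quadrature rule", {
  lw <- linewidth_spec(20)
  expect_equal(linewidth_in_field(lw, c(0, 0, 1), 2.0023),
               20 / (2.0023 * MHZ_PER_MT_REF), tolerance = 1e-9)
  aniso <- linewidth_spec(c(52, 28, 25))
  g <- 2.008
  expect_equal(linewidth_in_field(aniso, c(1, 0, 0), g) * g * MHZ_PER_MT_REF,
               52, tolerance = 1e-9)
  n <- c(0.6, 0.48, sqrt(1 - 0.6^2 - 0.48^2))
  expect_equal(linewidth_in_field(aniso, n, g) * g * MHZ_PER_MT_REF,
               sqrt(sum(n^2 * c(52, 28, 25)^2)), tolerance = 1e-9)
  expect_equal(linewidth_in_field(linewidth_spec(0), c(1, 0, 0), 2), 0)
})

test_that("powder absorption area is 1 and refinement leaves it unchanged", {
  sys <- spin_system(c(2.00834, 2.00598, 2.0023), c(14, 14, 100))
  for (gs in c(15, 30)) {
    sp <- powder_spectrum(sys, linewidth_spec(c(24, 21, 18)), 93.993,
                          grid_size = gs, solver = "first_order")
    expect_equal(gstrain:::spectrum_area(sp), 1, tolerance = 1e-9)
  }
})

test_that("doubling the default orientation grid changes the W-band
           spectrum by < 1e-3 of peak", {
  sys <- spin_system(c(2.00834, 2.00598, 2.0023), c(14, 14, 100))
  lw <- linewidth_spec(c(24, 21, 18))
  gs <- default_grid_size(93.993)
  s1 <- powder_spectrum(sys, lw, 93.993, grid_size = gs,
                        solver = "first_order")
  s2 <- powder_spectrum(sys, lw, 93.993, grid_size = 2 * gs,
                        solver = "first_order")
  expect_lt(max(abs(s1$intensity - s2$intensity)) / max(s1$intensity), 1e-3)
})

test_that("spectrum is invariant under permutation of axis labels", {
  g <- c(2.009, 2.006, 2.002)
  A <- c(20, 40, 90)
  lw <- c(25, 18, 30)
  perm <- c(3, 1, 2)
  f <- 93.993
  rng <- auto_field_range(spin_system(g, A), f, linewidth_spec(lw))
  s1 <- powder_spectrum(spin_system(g, A), linewidth_spec(lw), f,
                        field_range = rng, solver = "first_order",
                        grid_size = 60)
  s2 <- powder_spectrum(spin_system(g[perm], A[perm]),
                        linewidth_spec(lw[perm]), f, field_range = rng,
                        solver = "first_order", grid_size = 60)
  expect_lt(max(abs(s1$intensity - s2$intensity)) / max(s1$intensity), 2e-3)
})

test_that("broadening lowers the peak but conserves the area", {
  sys <- spin_system(c(2.00834, 2.00598, 2.0023), c(14, 14, 100))
  rng <- auto_field_range(sys, 33.6615, linewidth_spec(60))
  peaks <- vapply(c(20, 35, 60), function(w) {
    sp <- powder_spectrum(sys, linewidth_spec(w), 33.6615,
                          field_range = rng, solver = "first_order")
    expect_equal(gstrain:::spectrum_area(sp), 1, tolerance = 1e-6)
    max(sp$intensity)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("J-band lowest-field feature sits at the g_xx resonance", {
  sys <- spin_system(c(2.00834, 2.00598, 2.0023), c(14, 14, 100))
  sp <- powder_spectrum(sys, linewidth_spec(c(52, 28, 25)), 262.8436,
                        solver = "first_order")
  d <- to_first_derivative(sp)
  b_gxx <- 1e3 * 262.8436 / (2.00834 * MHZ_PER_MT_REF)
  b_gyy <- 1e3 * 262.8436 / (2.00598 * MHZ_PER_MT_REF)
  # low-field inflection of the g_xx edge: derivative maximum below the
  # midpoint of the g_xx and g_yy resonances
  win <- d$field_mT < (b_gxx + b_gyy) / 2
  b_edge <- d$field_mT[win][which.max(d$intensity[win])]
  expect_lt(abs(b_edge - b_gxx), 2 * 52 / (2.008 * MHZ_PER_MT_REF))
})

test_that("a too-narrow field range is rejected with the line positions", {
  sys <- spin_system(c(2.00834, 2.00598, 2.0023), c(14, 14, 100))
  expect_error(
    powder_spectrum(sys, linewidth_spec(20), 9.7671,
                    field_range = c(348, 349), solver = "first_order"),
    "does not bracket")
})

test_that("first derivative and re-integration invert each other", {
  x <- seq(330, 360, length.out = 2048)
  gauss <- exp(-(x - 345)^2 / (2 * 1.2^2))
  sp <- epr_spectrum(x, gauss, 9.7671)
  d <- to_first_derivative(sp)
  expect_equal(sum(d$intensity) * (x[2] - x[1]), 0, tolerance = 1e-8)
  # antisymmetric with zero crossing at the centre
  expect_lt(abs(d$field_mT[which.min(abs(d$intensity[800:1200])) + 799] -
                  345), 0.05)
  back <- integrate_spectrum(d)
  err <- back$intensity - (gauss - gauss[1])
  expect_lt(max(abs(err)) / max(gauss), 1e-6)
  # constant absorption differentiates to zero
  flat <- to_first_derivative(epr_spectrum(x, rep(2, length(x)), 9.7671))
  expect_true(all(flat$intensity == 0))
})

test_that("spectrum container enforces a uniform increasing axis", {
  expect_error(epr_spectrum(c(1, 2, 1.5), 1:3, 9.7), "increasing")
  expect_error(epr_spectrum(c(1, 2, 4), 1:3, 9.7), "uniform")
  expect_error(to_first_derivative(list()), "epr_spectrum")
})
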