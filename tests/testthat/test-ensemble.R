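snaps_from_means <- function(means, reps) {
  idx <- rep(seq_len(nrow(means)), reps)
  data.frame(id = seq_along(idx), gxx = means$gxx[idx], gyy = means$gyy[idx],
             gzz = means$gzz[idx], Axx_MHz = means$Axx_MHz[idx],
             Ayy_MHz = means$Ayy_MHz[idx], Azz_MHz = means$Azz_MHz[idx],
             n_hbonds = means$n_hbonds[idx])
}

test_that("a single snapshot reproduces its own powder spectrum", {
  sn <- data.frame(id = 1, gxx = 2.0079, gyy = 2.0058, gzz = 2.0021,
                   Axx_MHz = 7.3, Ayy_MHz = 7.5, Azz_MHz = 95.2)
  th <- theoretical_spectrum(sn, 93.993)
  ps <- powder_spectrum(spin_system(c(2.0079, 2.0058, 2.0021),
                                    c(7.3, 7.5, 95.2)),
                        linewidth_spec(17), 93.993,
                        field_range = range(th$field_mT),
                        solver = "first_order")
  expect_lt(max(abs(th$intensity - ps$intensity)) / max(ps$intensity), 1e-6)
})

test_that("N identical snapshots equal the single-snapshot spectrum", {
  means <- tcomp_parameters()[1, ]
  one <- theoretical_spectrum(snaps_from_means(means, 1), 33.6615)
  many <- theoretical_spectrum(snaps_from_means(means, 25), 33.6615)
  expect_equal(one$intensity, many$intensity, tolerance = 1e-12)
})

test_that("zero-scatter labeled ensemble equals the weighted component
           spectrum", {
  means <- tcomp_parameters()
  # 69 + 31 identical snapshots per label reproduce the 0.69/0.31 weights
  snaps <- snaps_from_means(means, c(69, 31))
  sm <- subensemble_means(snaps)
  expect_equal(sm$weight, c(0.69, 0.31))
  for (f in c(93.993, 262.8436)) {
    th <- theoretical_spectrum(snaps, f)
    tc <- tcomp_spectrum(sm, f, field_range = range(th$field_mT))
    expect_lt(max(abs(th$intensity - tc$spectrum$intensity)) /
                max(th$intensity), 1e-6)
  }
})

test_that("subensemble means equal brute-force group averages", {
  set.seed(3)
  snaps <- generate_snapshots(ensemble_spec(), n = 200, seed = 3)
  sm <- subensemble_means(snaps)
  for (h in sm$n_hbonds) {
    sel <- snaps[snaps$n_hbonds == h, ]
    expect_equal(sm$gxx[sm$n_hbonds == h], mean(sel$gxx))
    expect_equal(sm$Azz_MHz[sm$n_hbonds == h], mean(sel$Azz_MHz))
    expect_equal(sm$weight[sm$n_hbonds == h], nrow(sel) / nrow(snaps))
  }
  expect_equal(sum(sm$weight), 1)
})

test_that("identical snapshots collapse to one subensemble of weight 1", {
  means <- tcomp_parameters()[1, ]
  sm <- subensemble_means(snaps_from_means(means, 10))
  expect_equal(nrow(sm), 1)
  expect_equal(sm$weight, 1)
  expect_equal(sm$gxx, means$gxx)
})

test_that("unlabeled snapshots are rejected with a pointer to labeling", {
  sn <- data.frame(id = 1:2, gxx = 2.0079, gyy = 2.0058, gzz = 2.0021,
                   Axx_MHz = 7, Ayy_MHz = 7, Azz_MHz = 95)
  expect_error(subensemble_means(sn), "H-bond labels")
  expect_error(theoretical_spectrum(sn[0, ], 9.7671), "empty")
})

test_that("tcomp components are degenerate for identical parameters", {
  means <- tcomp_parameters()[c(1, 1), ]
  means$weight <- c(0.4, 0.6)
  tc2 <- tcomp_spectrum(means, 93.993)
  means1 <- tcomp_parameters()[1, ]
  means1$weight <- 1
  tc1 <- tcomp_spectrum(means1, 93.993,
                        field_range = range(tc2$spectrum$field_mT))
  expect_equal(tc2$spectrum$intensity, tc1$spectrum$intensity,
               tolerance = 1e-10)
  expect_error(tcomp_spectrum(tcomp_parameters()[1, ], 93.993),
               "sum to 1")
})

test_that("ensemble spectra are produced at all four microwave bands", {
  snaps <- generate_snapshots(ensemble_spec(), n = 5, seed = 9)
  for (f in band_frequencies) {
    sp <- theoretical_spectrum(snaps, f)
    expect_s3_class(sp, "epr_spectrum")
    expect_equal(sp$frequency, unname(f))
    expect_equal(gstrain:::spectrum_area(sp), 1, tolerance = 1e-9)
    # all three nitrogen lines of every snapshot lie inside the axis
    expect_gt(min(sp$field_mT), 0)
  }
})

test_that("widening the g_xx scatter increases the fitted J-band alw_xx", {
  means <- tcomp_parameters()[1, ]
  means$weight <- 1
  fits <- vapply(c(150, 450), function(slope) {
    spec <- ensemble_spec(means = means,
                          sd_g = c(sigma_from_slope(slope, means$gxx), 0, 0))
    snaps <- generate_snapshots(spec, n = 150, seed = 21)
    th <- theoretical_spectrum(snaps, 262.8436, n_points = 512)
    init <- multicomponent_model(
      g_xx = means$gxx, weights = 1, g_yy = means$gyy, g_zz = means$gzz,
      A = as.numeric(means[c("Axx_MHz", "Ayy_MHz", "Azz_MHz")]),
      alw = data.frame(band = "J", frequency_GHz = 262.8436,
                       alw_xx = 30, alw_yy = 17, alw_zz = 17))
    fit <- global_fit(list(th), init,
                      fixed = c("gxx1", "gyy", "gzz", "Axx", "Ayy", "Azz"))
    extract_alw(fit)$alw_xx
  }, numeric(1))
  expect_gt(fits[2], fits[1])
})
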