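OMEGA <- 2 * pi * 140.625e6

test_that("CW attenuation fit round-trips homogeneous data", {
  mua <- c(0.005, 0.02, 0.04)
  musp <- c(0.4, 0.5, 0.6)
  R <- cbind(homogeneous_reflectance(mua, musp, 25),
             homogeneous_reflectance(mua, musp, 35))
  mueff <- fit_effective_attenuation(R, c(25, 35), omega = 0, musp = musp)
  expect_lt(max(abs(mueff - sqrt(3 * mua * (mua + musp))) /
                  sqrt(3 * mua * (mua + musp))), 1e-6)
})

test_that("attenuation fit is symmetric in the distance pair order", {
  mua <- 0.02; musp <- 0.5
  R <- c(homogeneous_reflectance(mua, musp, 25),
         homogeneous_reflectance(mua, musp, 35))
  a <- fit_effective_attenuation(R, c(25, 35), omega = 0, musp = musp)
  b <- fit_effective_attenuation(rev(R), c(35, 25), omega = 0, musp = musp)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("FD optical-property equations invert the complex attenuation", {
  mua <- 0.01; musp <- 1.0; n <- 1.4
  mueff <- sqrt(3 * (mua + musp) *
                  (mua - 1i * OMEGA * n / 2.99792458e11))
  p <- fd_optical_properties(mueff, OMEGA, n)
  expect_lt(abs(p$mua - mua) / mua, 1e-9)
  expect_lt(abs(p$musp - musp) / musp, 1e-9)
  # conjugate input flips the sign structure -> nonphysical
  expect_error(fd_optical_properties(Conj(mueff), OMEGA, n), "nonphysical")
  expect_error(fd_optical_properties(0.1 + 0i, OMEGA, n), "degenerate")
})

test_that("FD attenuation fit round-trips homogeneous phasor data", {
  mua <- 0.025; musp <- 0.45
  R <- cbind(homogeneous_reflectance(mua, musp, 25, omega = OMEGA),
             homogeneous_reflectance(mua, musp, 35, omega = OMEGA))
  mueff <- fit_effective_attenuation(R, c(25, 35), omega = OMEGA)
  p <- fd_optical_properties(mueff, OMEGA, 1.4)
  expect_lt(abs(p$mua - mua) / mua, 1e-6)
  expect_lt(abs(p$musp - musp) / musp, 1e-6)
})

test_that("two-layer CW attenuation lies between the layer bounds", {
  R <- sapply(c(25, 35), function(r)
    Re(two_layer_reflectance(BASELINE, 830, r, 0, EXT)))
  musp_assumed <- layer_musp(BASELINE$bottom, 830)
  mueff <- fit_effective_attenuation(matrix(R, 1), c(25, 35), omega = 0,
                                     musp = musp_assumed)
  bounds <- sapply(c("top", "bottom"), function(l) {
    mua <- layer_mua(BASELINE[[l]], 830)
    sqrt(3 * mua * (mua + layer_musp(BASELINE[[l]], 830)))
  })
  expect_gt(mueff, min(bounds))
  expect_lt(mueff, max(bounds))
})

test_that("scattering extrapolation matches the power-law identities", {
  se <- scattering_extrapolation(0.50, 0.42, c(690, 830))
  expect_equal(se$b, log(0.42 / 0.50) / log(690 / 830), tolerance = 1e-15)
  expect_equal(round(se$b, 2), 0.94)
  expect_equal(se$musp[1], 0.50, tolerance = 1e-12)  # exact at 690
  expect_equal(se$musp[2], 0.42, tolerance = 1e-15)
  flat <- scattering_extrapolation(0.5, 0.5, c(650, 1024))
  expect_equal(flat$b, 0)
  expect_equal(flat$musp, c(0.5, 0.5))
  expect_error(scattering_extrapolation(-0.1, 0.4, 830), "> 0")
})

test_that("broadband absorption inverts its defining relation", {
  mua <- 0.02; musp <- 0.5
  mueff <- sqrt(3 * mua * (mua + musp))
  expect_equal(broadband_absorption(mueff, musp), mua, tolerance = 1e-12)
  expect_equal(broadband_absorption(0, 0.5), 0)
  # output satisfies mueff^2 = 3 mua (mua + musp)
  out <- broadband_absorption(c(0.1, 0.2), c(0.4, 0.6))
  expect_equal(3 * out * (out + c(0.4, 0.6)), c(0.1, 0.2)^2,
               tolerance = 1e-12)
})

test_that("unmixing is the exact inverse of mixing on the same basis", {
  grid <- seq(650, 1024, by = 2)
  E <- build_extinction_matrix(grid, EXT)
  cc <- chromophores(95, 0.71, 0.55, 0.25)
  rec <- unmix_chromophores(absorption_spectrum(cc, E), E)
  expect_equal(rec$total_hb, 95, tolerance = 1e-9)
  expect_equal(rec$sat, 0.71, tolerance = 1e-9)
  expect_equal(rec$water, 0.55, tolerance = 1e-9)
  expect_equal(rec$lipid, 0.25, tolerance = 1e-9)
  zero <- unmix_chromophores(rep(0, nrow(E)), E)
  expect_equal(zero$total_hb, 0)
  expect_true(is.na(zero$sat))
  expect_error(unmix_chromophores(rep(1, 5), E[1:5, c(1, 1, 2, 3)]),
               "rank")
})

test_that("full pipeline recovers homogeneous media", {
  set.seed(7)
  for (i in 1:10) {
    lay <- random_layer()
    med <- two_layer_medium(lay, lay, z_top_mm = 5)
    fit <- dos_fit(simulate_instrument(med, SMALL_INS, EXT), EXT)
    cc <- lay$chromophores
    expect_lt(abs(fit$chromophores$total_hb - cc$total_hb) / cc$total_hb,
              0.02)
    expect_lt(abs(fit$chromophores$sat - cc$sat), 0.01)
    expect_lt(abs(fit$chromophores$water - cc$water) / cc$water, 0.02)
    expect_lt(abs(fit$chromophores$lipid - cc$lipid) / cc$lipid, 0.02)
    expect_lt(abs(fit$musp830 - lay$scattering$musp830) /
                lay$scattering$musp830, 0.02)
    expect_lt(abs(fit$b - lay$scattering$b), 0.05)
  }
})

test_that("FD data only enter the recovery through reduced scattering", {
  data <- simulate_instrument(BASELINE, SMALL_INS, EXT)
  fit0 <- dos_fit(data, EXT)
  perturbed <- data
  # distance-dependent CW perturbation (a pure common factor would cancel
  # in the two-distance slope by design)
  perturbed$cw[, 2] <- perturbed$cw[, 2] * 1.05
  fit1 <- dos_fit(perturbed, EXT)
  expect_identical(fit1$musp_fd, fit0$musp_fd)
  expect_identical(fit1$b, fit0$b)
  # and CW perturbation does change the absorption side
  expect_false(isTRUE(all.equal(fit1$mua_cw, fit0$mua_cw)))
})

test_that("fit object methods are coherent", {
  fit <- dos_fit(simulate_instrument(BASELINE, SMALL_INS, EXT), EXT)
  expect_s3_class(fit, "dos_fit")
  co <- coef(fit)
  expect_named(co, c("total_hb", "sat", "water", "lipid", "musp830", "b"))
  expect_equal(fitted(fit) + residuals(fit), fit$mua_cw, tolerance = 1e-12)
  expect_equal(unname(predict(fit, 830, EXT)),
               sum(build_extinction_matrix(830, EXT) *
                     c(co["sat"] * co["total_hb"],
                       (1 - co["sat"]) * co["total_hb"],
                       co["water"], co["lipid"])),
               tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.dos_fit")
  expect_lt(s$rmse_mua, 0.01)
  df <- as.data.frame(fit)
  expect_named(df, c("wavelength_nm", "musp_extrap", "mueff", "mua"))
  expect_equal(nrow(df), length(SMALL_INS$cw_wavelengths))
})
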