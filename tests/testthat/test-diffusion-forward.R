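test_that("homogeneous reflectance decreases in rho and obeys the CW limit", {
  mua <- 0.02; musp <- 0.5
  rhos <- seq(10, 50, by = 5)
  R <- sapply(rhos, function(r) homogeneous_reflectance(mua, musp, r))
  expect_true(all(diff(R) < 0))
  # FD phasor converges to the CW value as omega -> 0 (difference is
  # first order in omega: ~2e-6 at 1 kHz for this geometry)
  Rcw <- homogeneous_reflectance(mua, musp, 30)
  Rfd1k <- homogeneous_reflectance(mua, musp, 30, omega = 2 * pi * 1e3)
  Rfd100 <- homogeneous_reflectance(mua, musp, 30, omega = 2 * pi * 1e2)
  expect_lt(abs(Rfd1k - Rcw) / Rcw, 1e-5)
  expect_lt(abs(Rfd100 - Rcw) / Rcw, 1e-6)
  expect_lt(abs(Rfd100 - Rcw), abs(Rfd1k - Rcw))
  # |FD| never exceeds CW at the study's modulation frequency
  Rmod <- homogeneous_reflectance(mua, musp, 30, omega = 2 * pi * 140.625e6)
  expect_lt(Mod(Rmod), Rcw)
})

test_that("large-rho slope of ln(rho^2 R) approaches -mueff", {
  # closed-form asymptote of the diffusion Green's function
  mua <- layer_mua(BASELINE$bottom, 830)
  musp <- layer_musp(BASELINE$bottom, 830)
  mueff <- sqrt(3 * mua * (mua + musp))
  r1 <- 60; r2 <- 80
  R1 <- homogeneous_reflectance(mua, musp, r1)
  R2 <- homogeneous_reflectance(mua, musp, r2)
  slope <- (log(r2^2 * R2) - log(r1^2 * R1)) / (r2 - r1)
  expect_lt(abs(-slope - mueff) / mueff, 0.01)
})

test_that("warning is raised inside one transport mean free path", {
  expect_warning(homogeneous_reflectance(0.01, 0.5, 1), "mean free path")
})

test_that("two-layer model reduces to the homogeneous model", {
  set.seed(41)
  wl <- c(690, 760, 830, 930, 1000)
  omega <- 2 * pi * 140.625e6
  worst <- 0
  for (i in 1:20) {
    lay <- random_layer()
    med <- two_layer_medium(lay, lay, z_top_mm = runif(1, 2, 12))
    mua <- layer_mua(lay, wl); musp <- layer_musp(lay, wl)
    for (rho in c(25, 35)) {
      tl_cw <- Re(two_layer_reflectance(med, wl, rho, 0, EXT))
      hom_cw <- homogeneous_reflectance(mua, musp, rho)
      tl_fd <- two_layer_reflectance(med, wl, rho, omega, EXT)
      hom_fd <- homogeneous_reflectance(mua, musp, rho, omega = omega)
      worst <- max(worst, abs(tl_cw - hom_cw) / hom_cw,
                   abs(tl_fd - hom_fd) / Mod(hom_fd))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("thick and thin top layers approach the single-layer limits", {
  wl <- c(690, 830, 975)
  # thick top: the bottom layer is invisible
  thick <- two_layer_medium(BASELINE$top, BASELINE$bottom, 60)
  hom_top <- homogeneous_reflectance(layer_mua(BASELINE$top, wl),
                                     layer_musp(BASELINE$top, wl), 25)
  expect_lt(max(abs(Re(two_layer_reflectance(thick, wl, 25, 0, EXT)) -
                      hom_top) / hom_top), 1e-3)
  # thin top: approaches the bottom homogeneous medium, up to the
  # boundary-condition residual of a sub-transport-mfp top layer (the
  # extrapolation length stays tied to the top layer's D); computed
  # agreement at z_top = 0.1 mm is ~5%
  thin <- two_layer_medium(BASELINE$top, BASELINE$bottom, 0.1)
  hom_bot <- homogeneous_reflectance(layer_mua(BASELINE$bottom, wl),
                                     layer_musp(BASELINE$bottom, wl), 25)
  err_thin <- max(abs(Re(two_layer_reflectance(thin, wl, 25, 0, EXT)) -
                        hom_bot) / hom_bot)
  expect_lt(err_thin, 0.06)
  # and the residual shrinks as the top thins toward zero thickness
  thinner <- two_layer_medium(BASELINE$top, BASELINE$bottom, 0.01)
  err_thinner <- max(abs(Re(two_layer_reflectance(thinner, wl, 25, 0,
                                                  EXT)) -
                           hom_bot) / hom_bot)
  expect_lt(err_thinner, err_thin)
})

test_that("Hankel quadrature is converged at the default density", {
  med <- BASELINE
  wl <- c(690, 830, 975)
  for (rho in c(25, 35)) {
    a <- two_layer_reflectance(med, wl, rho, 0, EXT)
    b <- two_layer_reflectance(med, wl, rho, 0, EXT,
                               nodes_per_half = 12, s_decay = 80)
    expect_lt(max(abs(a - b) / abs(b)), 1e-6)
  }
  expect_silent(two_layer_reflectance(med, 830, 25, 0, EXT,
                                      check_convergence = TRUE))
})

test_that("simulated instrument output has the documented shape", {
  expect_s3_class(BASE_DATA, "dos_reflectance")
  expect_equal(dim(BASE_DATA$cw), c(749L, 2L))
  expect_equal(dim(BASE_DATA$fd), c(2L, 2L))
  expect_true(all(BASE_DATA$cw > 0))
  expect_true(all(Mod(BASE_DATA$fd) > 0))
  expect_true(is.complex(BASE_DATA$fd))
  # reflectance decreases with distance everywhere
  expect_true(all(BASE_DATA$cw[, 1] > BASE_DATA$cw[, 2]))
  expect_true(all(Mod(BASE_DATA$fd[, 1]) > Mod(BASE_DATA$fd[, 2])))
})

test_that("reflectance sets serialize to the long CSV layout", {
  df <- as.data.frame(BASE_DATA)
  expect_equal(nrow(df), 749L * 2L + 2L * 2L)
  expect_named(df, c("wavelength_nm", "rho_mm", "domain", "value_real",
                     "value_imag"))
  expect_true(all(df$value_imag[df$domain == "cw"] == 0))
  expect_true(all(df$value_imag[df$domain == "fd"] != 0))
})

test_that("simulate() method on a medium matches simulate_instrument()", {
  med <- two_layer_medium(BASELINE$top, BASELINE$bottom, 5)
  s1 <- simulate(med, instrument = SMALL_INS, extinction = EXT)
  s2 <- simulate_instrument(med, SMALL_INS, EXT)
  expect_identical(s1$cw, s2$cw)
  expect_identical(s1$fd, s2$fd)
})
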