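# GP, acceptor normalization, ratiometric FRET, FCS fitting, EPR index.

test_that("GP follows the two-channel contrast arithmetic", {
  expect_equal(gp(make_two_channel_spectrum(1, 1)), 0)
  expect_equal(gp(make_two_channel_spectrum(2, 1)), 1 / 3)
  expect_equal(gp(make_two_channel_spectrum(1, 0)), 1)
  expect_equal(gp(make_two_channel_spectrum(0, 1)), -1)
  # global intensity scaling leaves GP unchanged
  s <- generate_emission_spectrum(list(c(430, 12, 1), c(500, 15, 0.7)))
  s10 <- emission_spectrum(s$wavelength, s$intensity * 10)
  expect_equal(gp(s10), gp(s))
  expect_true(abs(gp(s)) <= 1)
})

test_that("GP blank subtraction and error cases behave", {
  s <- make_two_channel_spectrum(2, 1)
  blank <- emission_spectrum(s$wavelength, rep(0.5, length(s$wavelength)))
  # blank removes a flat pedestal: I1 = 1.5 * 60, I2 = 0.5 * 60 -> GP = 0.5
  expect_equal(gp(s, blank), 0.5)
  zero <- emission_spectrum(s$wavelength, rep(0, length(s$wavelength)))
  expect_error(gp(zero), "zero")
  narrow <- emission_spectrum(seq(450, 600, 1), rep(1, 151))
  expect_error(gp(narrow), "cover")
})

test_that("acceptor normalization cancels reconstitution yield", {
  don <- generate_emission_spectrum(list(c(525, 12, 1), c(614, 14, 0.4)),
                                    grid = seq(500, 700, 1))
  acc <- generate_emission_spectrum(list(c(614, 14, 2)),
                                    grid = seq(500, 700, 1))
  norm1 <- acceptor_normalize(don, acc)
  expect_equal(norm1$intensity, don$intensity / 2)
  # two reconstitutions differing only by a global yield factor normalize
  # to identical spectra
  don2 <- emission_spectrum(don$wavelength, don$intensity * 3.7)
  acc2 <- emission_spectrum(acc$wavelength, acc$intensity * 3.7)
  norm2 <- acceptor_normalize(don2, acc2)
  expect_equal(norm2$intensity, norm1$intensity)
  expect_error(acceptor_normalize(don, emission_spectrum(acc$wavelength,
                                                         rep(0, 201))),
               "not positive")
})

test_that("ratiometric FRET reads the donor/acceptor wavelengths", {
  wl <- seq(500, 700, 1)
  make <- function(i_d, i_a) {
    intensity <- rep(0, length(wl))
    intensity[wl == 525] <- i_d
    intensity[wl == 614] <- i_a
    emission_spectrum(wl, intensity)
  }
  expect_equal(fret_erel(make(1, 0)), 0)
  expect_equal(fret_erel(make(1, 1)), 0.5)
  expect_equal(fret_erel(make(1, 3)), 0.75)
  expect_error(fret_erel(make(0, 0)), "zero")
  short <- emission_spectrum(seq(500, 600, 1), rep(1, 101))
  expect_error(fret_erel(short), "cover")
})

test_that("FCS fit recovers a noise-free curve to 4 significant digits", {
  cv <- generate_fcs_curve(N = 10, tau_D = 1e-3, T = 0)
  fit <- fit_fcs(cv)
  expect_true(fit$converged)
  expect_equal(signif(fit$estimate[["N"]], 4), 10)
  expect_equal(signif(fit$estimate[["tau_D"]], 4), 1e-3)
  expect_true(fit$t_pinned)   # T driven to its zero bound
  # with a genuine triplet, noise-free recovery of all four parameters
  cv2 <- generate_fcs_curve(N = 7, tau_D = 2e-3, T = 0.25, tau_T = 8e-6)
  fit2 <- fit_fcs(cv2)
  expect_equal(unname(fit2$estimate),
               c(7, 2e-3, 0.25, 8e-6), tolerance = 1e-4)
})

test_that("FCS fit flags degenerate input instead of failing silently", {
  flat <- correlation_curve(10^seq(-6, 0, length.out = 40), rep(0.1, 40))
  fit <- fit_fcs(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$estimate[1]))
  expect_error(fit_fcs(correlation_curve(c(1e-4, 2e-4, 3e-4),
                                         c(1, 0.9, 0.8))),
               "points|decades")
})

test_that("diffusion coefficient conversion and scaling law", {
  expect_equal(diffusion_coefficient(1e-3, 0.2), 10)
  expect_equal(diffusion_coefficient(1e-3, 0.4), 40)   # 2x waist -> 4x D
  d <- diffusion_coefficient(2.5e-3, 0.25)
  tau <- 0.25^2 / (4 * d)
  expect_equal(diffusion_coefficient(tau, 0.25), d)    # round trip
  expect_error(diffusion_coefficient(0, 0.2), "> 0")
})

test_that("EPR proximity index is scale and field-offset invariant", {
  s <- generate_epr_spectrum(0.2, c(0.7, 1.0, 0.5))
  idx <- epr_proximity_index(s)
  rescaled <- epr_spectrum(s$field, s$amplitude * 123)
  expect_equal(epr_proximity_index(rescaled), idx)
  offset <- epr_spectrum(s$field + 50, s$amplitude)
  expect_equal(epr_proximity_index(offset), idx)
  # area normalization gives the same ratio
  expect_equal(epr_proximity_index(s, normalize = "area"), idx)
})
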