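# Probe-based reductions: C-Laurdan generalized polarization, ratiometric
# FRET with acceptor normalization, 2D + triplet FCS fitting with
# diffusion-coefficient conversion, and the cwEPR low-field/mid-field
# proximity index.

#' Emission spectrum container
#'
#' @param wavelength strictly increasing wavelength grid, nm.
#' @param intensity intensities, arbitrary units.
#' @param excitation excitation wavelength, nm.
#' @param blank_subtracted whether a blank has already been subtracted.
#' @return an \code{emission_spectrum}.
#' @export
emission_spectrum <- function(wavelength, intensity, excitation = NA_real_,
                              blank_subtracted = FALSE) {
  stop_if(length(wavelength) != length(intensity),
          "wavelength and intensity lengths differ")
  stop_if(any(diff(wavelength) <= 0),
          "wavelength grid must be strictly increasing")
  stop_if(any(!is.finite(intensity)), "intensities must be finite")
  structure(list(wavelength = wavelength, intensity = intensity,
                 excitation = excitation,
                 blank_subtracted = blank_subtracted),
            class = "emission_spectrum")
}

#' FCS autocorrelation curve container
#'
#' @param lag strictly increasing positive lag times, seconds.
#' @param G correlation amplitudes.
#' @param sd optional per-point SD used as fit weights.
#' @return a \code{correlation_curve}.
#' @export
correlation_curve <- function(lag, G, sd = NULL) {
  stop_if(length(lag) != length(G), "lag and G lengths differ")
  stop_if(any(lag <= 0) || any(diff(lag) <= 0),
          "lag times must be positive and strictly increasing")
  stop_if(any(!is.finite(G)), "G values must be finite")
  if (!is.null(sd)) stop_if(length(sd) != length(G) || any(sd <= 0),
                            "sd must be positive and match G")
  structure(list(lag = lag, G = G, sd = sd), class = "correlation_curve")
}

#' cwEPR first-derivative spectrum container
#'
#' @param field strictly increasing magnetic-field axis, mT.
#' @param amplitude first-derivative amplitudes, arbitrary units.
#' @return an \code{epr_spectrum}.
#' @export
epr_spectrum <- function(field, amplitude) {
  stop_if(length(field) != length(amplitude),
          "field and amplitude lengths differ")
  stop_if(any(diff(field) <= 0), "field grid must be strictly increasing")
  structure(list(field = field, amplitude = amplitude),
            class = "epr_spectrum")
}

# trapezoidal integral of a spectrum over [lo, hi], with the band edges
# obtained by linear interpolation on the native grid
.band_integral <- function(wavelength, intensity, lo, hi) {
  stop_if(lo < wavelength[1] || hi > wavelength[length(wavelength)],
          sprintf("spectrum does not cover the %g-%g nm band", lo, hi))
  inside <- wavelength > lo & wavelength < hi
  w <- c(lo, wavelength[inside], hi)
  y <- c(stats::approx(wavelength, intensity, lo)$y,
         intensity[inside],
         stats::approx(wavelength, intensity, hi)$y)
  sum(diff(w) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' C-Laurdan generalized polarization
#'
#' Integrates the (blank-subtracted, zero-clipped) emission intensities
#' over the ordered channel 400--460 nm (I_Ch1) and the disordered channel
#' 470--530 nm (I_Ch2) by the trapezoidal rule, and returns
#' \deqn{GP = (I_{Ch1} - I_{Ch2}) / (I_{Ch1} + I_{Ch2}),}
#' which ranges from +1 for the most ordered to -1 for the most disordered
#' membranes.
#'
#' @param spectrum an \code{emission_spectrum} covering 400--530 nm.
#' @param blank optional blank \code{emission_spectrum} on the same grid.
#' @return GP value in [-1, 1].
#' @export
gp <- function(spectrum, blank = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  intensity <- spectrum$intensity
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "emission_spectrum"))
    stop_if(length(blank$wavelength) != length(spectrum$wavelength) ||
              any(blank$wavelength != spectrum$wavelength),
            "blank must share the spectrum's wavelength grid")
    intensity <- pmax(intensity - blank$intensity, 0)
  }
  i1 <- .band_integral(spectrum$wavelength, intensity, 400, 460)
  i2 <- .band_integral(spectrum$wavelength, intensity, 470, 530)
  stop_if(i1 + i2 == 0, "both GP channels integrate to zero")
  (i1 - i2) / (i1 + i2)
}

#' Normalize a FRET spectrum to the direct-excitation acceptor maximum
#'
#' Divides the donor-excitation emission spectrum by the maximum intensity
#' of the acceptor direct-excitation spectrum, correcting for variations
#' in reconstitution yield between samples.
#'
#' @param donor_ex \code{emission_spectrum} recorded under donor
#'   excitation.
#' @param acceptor_ex \code{emission_spectrum} recorded under direct
#'   acceptor excitation.
#' @return the normalized donor-excitation \code{emission_spectrum}.
#' @export
acceptor_normalize <- function(donor_ex, acceptor_ex) {
  stopifnot(inherits(donor_ex, "emission_spectrum"),
            inherits(acceptor_ex, "emission_spectrum"))
  m <- max(acceptor_ex$intensity)
  stop_if(m <= 0, "acceptor direct-excitation maximum is not positive")
  donor_ex$intensity <- donor_ex$intensity / m
  donor_ex
}

#' Ratiometric FRET efficiency
#'
#' Reads the donor and acceptor intensities at fixed wavelengths (linear
#' interpolation to the exact nm) and returns
#' \deqn{E_{rel} = I_A / (I_D + I_A).}
#'
#' @param spectrum \code{emission_spectrum} under donor excitation.
#' @param donor_wavelength donor emission read-out, nm.
#' @param acceptor_wavelength acceptor emission read-out, nm.
#' @return relative FRET efficiency in [0, 1].
#' @export
fret_erel <- function(spectrum, donor_wavelength = 525,
                      acceptor_wavelength = 614) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  rng <- range(spectrum$wavelength)
  stop_if(donor_wavelength < rng[1] || acceptor_wavelength > rng[2] ||
            acceptor_wavelength < rng[1] || donor_wavelength > rng[2],
          "spectrum does not cover both read-out wavelengths")
  i_d <- stats::approx(spectrum$wavelength, spectrum$intensity,
                       donor_wavelength)$y
  i_a <- stats::approx(spectrum$wavelength, spectrum$intensity,
                       acceptor_wavelength)$y
  stop_if(i_d + i_a == 0, "donor and acceptor intensities are both zero")
  i_a / (i_d + i_a)
}

#' 2D + triplet FCS model
#'
#' @param tau lag times, s.
#' @param N mean occupancy; \code{tau_D} diffusion time, s; \code{T}
#'   triplet fraction; \code{tau_T} triplet time, s.
#' @param tau_D,T,tau_T model parameters.
#' @return model G values.
#' @export
fcs_model <- function(tau, N, tau_D, T = 0, tau_T = 5e-6) {
  (1 + T / (1 - T) * exp(-tau / tau_T)) / N / (1 + tau / tau_D)
}

#' Fit the 2D + triplet model to an FCS curve
#'
#' Bounded nonlinear least squares (\code{nls}, port algorithm) of
#' \deqn{G(\tau) = \left(1 + \frac{T}{1-T}e^{-\tau/\tau_T}\right)
#'   \frac{1}{N}\frac{1}{1 + \tau/\tau_D}}
#' with initial guesses derived from the curve (N from 1/G at the shortest
#' lag, tau_D from the half-amplitude lag). Points are weighted by
#' 1/sd^2 when the curve carries per-point SDs, else unweighted.
#' Non-convergence is flagged, never silent; a triplet fraction pinned at
#' its bound is reported via \code{t_pinned}.
#'
#' @param curve a \code{correlation_curve} with >= 8 points spanning at
#'   least two decades of lag.
#' @return an \code{fcs_fit}: list with \code{estimate} (N, tau_D, T,
#'   tau_T), \code{se}, \code{converged}, \code{t_pinned},
#'   \code{residual_rms}.
#' @export
fit_fcs <- function(curve) {
  stopifnot(inherits(curve, "correlation_curve"))
  stop_if(length(curve$lag) < 8, "need >= 8 points to fit")
  stop_if(log10(max(curve$lag) / min(curve$lag)) < 2,
          "lag range must span at least two decades")
  g0 <- curve$G[1]
  stop_if(g0 <= 0, "G at the shortest lag must be positive")
  n0 <- 1 / g0
  half <- which(curve$G <= g0 / 2)
  td0 <- if (length(half)) curve$lag[half[1]]
         else exp(mean(log(range(curve$lag))))
  start <- list(N = n0, tau_D = td0, Tt = 0.05, tau_T = min(curve$lag) * 3)
  lower <- c(1e-8, min(curve$lag) / 100, 0, min(curve$lag) / 100)
  upper <- c(Inf, max(curve$lag) * 100, 0.999, max(curve$lag))
  w <- if (!is.null(curve$sd)) 1 / curve$sd^2 else rep(1, length(curve$G))
  dat <- data.frame(tau = curve$lag, G = curve$G, w = w)
  fit <- tryCatch(
    stats::nls(G ~ fcs_model(tau, N, tau_D, Tt, tau_T), data = dat,
               start = start, algorithm = "port",
               lower = lower, upper = upper, weights = w,
               control = stats::nls.control(maxiter = 500,
                                            warnOnly = FALSE)),
    error = function(e) e, warning = function(w) w)
  if (inherits(fit, "condition")) {
    return(structure(list(estimate = rep(NA_real_, 4), se = rep(NA_real_, 4),
                          converged = FALSE, t_pinned = NA,
                          residual_rms = NA_real_,
                          message = conditionMessage(fit)),
                     class = "fcs_fit"))
  }
  est <- stats::coef(fit)
  names(est) <- c("N", "tau_D", "T", "tau_T")
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    names(s) <- names(est); s
  }, error = function(e) stats::setNames(rep(NA_real_, 4), names(est)))
  conv <- fit$convInfo$isConv %||% TRUE
  structure(list(estimate = est, se = se, converged = isTRUE(conv),
                 t_pinned = est[["T"]] <= lower[3] + 1e-12 ||
                   est[["T"]] >= upper[3] - 1e-12,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 message = NULL),
            class = "fcs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fcs_fit <- function(x, ...) {
  if (!x$converged) {
    cat("fcs_fit: NOT converged", if (!is.null(x$message))
      paste0("(", x$message, ")"), "\n")
  } else {
    cat(sprintf(
      "fcs_fit: N = %.4g, tau_D = %.4g s, T = %.3f, tau_T = %.3g s (rms %.3g)%s\n",
      x$estimate[["N"]], x$estimate[["tau_D"]], x$estimate[["T"]],
      x$estimate[["tau_T"]], x$residual_rms,
      if (isTRUE(x$t_pinned)) " [T at bound]" else ""))
  }
  invisible(x)
}

#' Diffusion coefficient from the FCS diffusion time
#'
#' Two-dimensional (membrane) relation \eqn{D = w^2 / (4 \tau_D)} with w
#' the 1/e^2 beam-waist radius. The waist is instrument calibration and
#' must be supplied by the user.
#'
#' @param tau_D diffusion time, seconds.
#' @param beam_waist waist radius w, micrometers.
#' @return D in um^2/s.
#' @export
diffusion_coefficient <- function(tau_D, beam_waist) {
  stop_if(tau_D <= 0 || beam_waist <= 0,
          "tau_D and beam_waist must be > 0")
  beam_waist^2 / (4 * tau_D)
}

#' cwEPR proximity index I_Lf / I_Mf
#'
#' Ratio of the positive-lobe amplitude of the low-field line to that of
#' the mid-field line of a first-derivative cwEPR spectrum, after max
#' (or area) intensity normalization. Higher values indicate a lower
#' average interspin distance. Peaks are local maxima with a minimum
#' prominence relative to the global maximum; the mid-field line is the
#' tallest positive lobe of a nitroxide-like spectrum and the low-field
#' line the first resolvable peak before it. The index is invariant to
#' field-axis offset and intensity scale.
#'
#' @param spectrum an \code{epr_spectrum}.
#' @param normalize \code{"max"} or \code{"area"} intensity
#'   normalization (the index itself is scale invariant).
#' @param min_prominence peak threshold as a fraction of the normalized
#'   global maximum.
#' @return the I_Lf / I_Mf ratio.
#' @export
epr_proximity_index <- function(spectrum, normalize = c("max", "area"),
                                min_prominence = 0.02) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  normalize <- match.arg(normalize)
  a <- spectrum$amplitude
  scale <- switch(normalize,
                  max = max(abs(a)),
                  area = sum(abs(a)) * mean(diff(spectrum$field)))
  stop_if(scale <= 0, "spectrum has no intensity")
  a <- a / scale
  n <- length(a)
  is_peak <- c(FALSE, a[2:(n - 1)] > a[1:(n - 2)] &
                 a[2:(n - 1)] >= a[3:n], FALSE)
  is_peak <- is_peak & a > min_prominence * max(a)
  peaks <- which(is_peak)
  stop_if(length(peaks) < 2,
          "spectrum must contain >= 2 resolvable positive extrema")
  mf <- peaks[which.max(a[peaks])]
  before <- peaks[peaks < mf]
  stop_if(length(before) == 0,
          "low-field and mid-field peaks are unresolvable; index undefined")
  i_lf <- a[before[1]]
  i_mf <- a[mf]
  stop_if(i_mf <= 0, "mid-field amplitude is not positive; index undefined")
  i_lf / i_mf
}
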