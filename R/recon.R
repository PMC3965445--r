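#' Phase-difference series from opposite MSG polarities
#'
#' Cancels static phase contributions by differencing the two acquisitions
#' that differ only in the sign of the motion-sensitizing gradient. Per
#' dynamic the output is `wrap(pos - neg) / 2` (default), which carries the
#' motion-encoded component at its original scale but is congruent to it
#' modulo `pi` rather than `2*pi`; [unwrap_phase()] with `period = pi`
#' (applied automatically by [reconstruct()]) restores a smooth field. With
#' `halve = FALSE` the raw difference `wrap(pos - neg)` is returned (twice
#' the encoded component, congruent modulo `2*pi`).
#'
#' @param series_pos,series_neg `mre_phase_series` acquired with MSG polarity
#'   `+1` and `-1`; protocols must match.
#' @param halve Divide the wrapped difference by 2 (default `TRUE`).
#' @return An `mre_phase_series` with attribute `"halved"`.
#' @export
phase_difference <- function(series_pos, series_neg, halve = TRUE) {
  stopifnot(inherits(series_pos, "mre_phase_series"),
            inherits(series_neg, "mre_phase_series"))
  if (!identical(series_pos$protocol, series_neg$protocol))
    stop("phase series acquired with different protocols cannot be differenced")
  d <- wrap_phase(series_pos$phase - series_neg$phase)
  if (halve) d <- d / 2
  out <- phase_series(d, series_pos$protocol, wrapped = TRUE)
  attr(out, "halved") <- halve
  out
}

#' Unwrap a 2D wrapped phase image
#'
#' Removes modulo-`period` discontinuities from a wrapped phase image. The
#' default method grows the solution from the highest-quality pixel
#' (quality-guided flood fill, implemented in C++); `method = "itoh"` is a
#' simple separable cumulative unwrap (first column, then along rows), exact
#' for noise-free fields satisfying the Itoh condition (neighbour differences
#' below `period/2`).
#'
#' The output is congruent to the input modulo `period` at every pixel, up
#' to the global offset of the seed pixel.
#'
#' @param image Numeric matrix of wrapped phase, rad.
#' @param period Congruence modulus; `2*pi` for phase images, `pi` for
#'   half-scaled phase-difference images.
#' @param method `"quality"` (default) or `"itoh"`.
#' @return Unwrapped numeric matrix.
#' @export
unwrap_phase <- function(image, period = 2 * pi, method = c("quality", "itoh")) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), period > 0)
  if (method == "quality") return(.unwrap_quality_cpp(image, period))
  # Itoh: integrate wrapped differences down the first column, then across rows
  out <- image
  dcol <- wrap_phase(diff(image[, 1]), period)
  out[, 1] <- image[1, 1] + c(0, cumsum(dcol))
  if (ncol(image) > 1) {
    drow <- wrap_phase(t(diff(t(image))), period)
    out[, -1] <- out[, 1] + t(apply(drow, 1, cumsum))
  }
  out
}

#' Extract the fundamental harmonic from an unwrapped phase series
#'
#' Temporal discrete Fourier transform over the dynamics at the fundamental
#' (drive) frequency bin, normalised so a series
#' `xi * A * cos(2*pi*d/n - theta)` yields complex amplitude `xi * A *
#' exp(i*theta)`; dividing by the encoding efficiency `xi` converts phase
#' (rad) to displacement (m).
#'
#' @param series An unwrapped `mre_phase_series` (the differenced series from
#'   [phase_difference()] after [unwrap_phase()] per dynamic).
#' @param protocol An [acquisition_protocol()].
#' @return An `mre_wavefield` with `u` in metres.
#' @export
extract_harmonic <- function(series, protocol) {
  stopifnot(inherits(series, "mre_phase_series"), inherits(protocol, "mre_protocol"))
  nd <- protocol$n_dynamics
  if (nd < 3) stop("need at least 3 dynamics to resolve the fundamental")
  ph <- series$phase
  stopifnot(dim(ph)[3] == nd)
  acc <- matrix(0 + 0i, dim(ph)[1], dim(ph)[2])
  for (d in 0:(nd - 1))
    acc <- acc + ph[, , d + 1] * exp(-2i * pi * d / nd)
  amp_phase <- (2 / nd) * Conj(acc)            # rad, complex
  u <- amp_phase / encoding_efficiency(protocol)  # metres
  wavefield(u, protocol$drive_frequency, protocol$pixel_spacing)
}

#' Radial Butterworth band-pass specification
#'
#' @param low_cut,high_cut Radial wavenumber cutoffs in rad/m
#'   (`0 <= low_cut < high_cut`). The high-pass side suppresses the near-DC
#'   compression-wave component; the low-pass side suppresses noise.
#' @param order Butterworth order (>= 1).
#' @return An object of class `mre_filter_spec`.
#' @export
#'
#' @examples
#' # default cutoffs bracket the expected shear wavenumber at G_ref = 5 kPa
#' filter_spec_default()
filter_spec <- function(low_cut, high_cut, order = 3) {
  if (low_cut < 0 || high_cut <= low_cut) stop("need 0 <= low_cut < high_cut")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = as.integer(order)),
            class = "mre_filter_spec")
}

#' @rdname filter_spec
#' @param frequency Drive frequency, Hz.
#' @param density Density, kg/m^3.
#' @param g_ref Reference storage modulus, Pa, setting the expected
#'   wavenumber `k = 2*pi*f*sqrt(density/g_ref)`; cutoffs default to
#'   `0.3*k` and `3*k`.
#' @export
filter_spec_default <- function(frequency = 900, density = 1000, g_ref = 5000,
                                order = 3) {
  k <- 2 * pi * frequency * sqrt(density / g_ref)
  filter_spec(0.3 * k, 3 * k, order)
}

#' Radial Butterworth band-pass filter of a complex wave image
#'
#' Filters the complex field in the 2D spatial-frequency domain with gain
#' `H(k) = 1 / (1 + (k/high_cut)^(2*order)) * 1 / (1 + (low_cut/k)^(2*order))`
#' (`H(0) = 0`), attenuating the near-DC compression-wave regime and
#' high-wavenumber noise. By default the field is mirror-extended
#' (reflection padding) before the FFT to avoid wrap-around edge ringing;
#' `pad = "none"` uses the plain periodic transform (exact Parseval
#' behaviour, used by the variance oracle tests).
#'
#' @param field An `mre_wavefield`.
#' @param spec An [filter_spec()].
#' @param pad `"reflect"` (default) or `"none"`.
#' @return The filtered `mre_wavefield`.
#' @export
bandpass_filter <- function(field, spec, pad = c("reflect", "none")) {
  stopifnot(inherits(field, "mre_wavefield"), inherits(spec, "mre_filter_spec"))
  pad <- match.arg(pad)
  u <- field$u
  n <- nrow(u)
  if (pad == "reflect") {
    big <- matrix(0 + 0i, 2 * n, 2 * n)
    big[1:n, 1:n] <- u
    big[(n + 1):(2 * n), 1:n] <- u[n:1, ]
    big[1:n, (n + 1):(2 * n)] <- u[, n:1]
    big[(n + 1):(2 * n), (n + 1):(2 * n)] <- u[n:1, n:1]
    u <- big
  }
  m <- nrow(u)
  idx <- 0:(m - 1)
  idx <- ifelse(idx > m / 2, idx - m, idx)
  fk <- 2 * pi * idx / (m * field$pixel_spacing)
  K <- sqrt(outer(fk^2, fk^2, `+`))
  H <- 1 / (1 + (K / spec$high_cut)^(2 * spec$order))
  if (spec$low_cut > 0) {
    Hhp <- matrix(0, m, m)
    nz <- K > 0
    Hhp[nz] <- 1 / (1 + (spec$low_cut / K[nz])^(2 * spec$order))
    H <- H * Hhp
  }
  uf <- stats::fft(stats::fft(u) * H, inverse = TRUE) / length(u)
  if (pad == "reflect") uf <- uf[1:n, 1:n]
  wavefield(uf, field$frequency, field$pixel_spacing)
}

#' Algebraic Helmholtz inversion of a harmonic wave image
#'
#' Per-pixel estimate of the complex shear modulus,
#' `G* = -density * (2*pi*frequency)^2 * u / lap(u)`,
#' with the Laplacian by the central 5-point stencil on the pixel grid.
#' Pixels are masked invalid when (i) they lie on the one-pixel border
#' (stencil support), (ii) the Laplacian magnitude falls below
#' `laplacian_floor` times the median interior Laplacian magnitude (near
#' wave nodes the ratio is unstable), or (iii) the recovered `G'` is
#' non-positive or `G''` negative (non-physical; the affected fraction is
#' recorded rather than clamped).
#'
#' @param field An `mre_wavefield`.
#' @param density Density, kg/m^3.
#' @param frequency Drive frequency, Hz (defaults to the field's).
#' @param laplacian_floor Relative threshold on `|lap(u)|` (default 0.05).
#' @return An `mre_elastogram`: list with complex `gstar`, real maps `gp`,
#'   `gpp`, `absg`, `phi`, logical `valid_mask`, plus `frequency`, `density`
#'   and (as attribute `"negative_fraction"`) the fraction of
#'   stencil-supported pixels discarded for non-physical moduli.
#' @export
helmholtz_invert <- function(field, density, frequency = field$frequency,
                             laplacian_floor = 0.05) {
  stopifnot(inherits(field, "mre_wavefield"))
  if (density <= 0 || frequency <= 0) stop("density and frequency must be positive")
  u <- field$u
  n <- nrow(u); m <- ncol(u)
  h <- field$pixel_spacing
  lap <- matrix(NA_complex_, n, m)
  i <- 2:(n - 1); j <- 2:(m - 1)
  lap[i, j] <- (u[i - 1, j] + u[i + 1, j] + u[i, j - 1] + u[i, j + 1] -
                  4 * u[i, j]) / h^2
  interior <- !is.na(Re(lap))
  med <- stats::median(Mod(lap[interior]))
  stable <- interior & !is.na(Re(lap)) & Mod(lap) >= laplacian_floor * med & Mod(lap) > 0

  omega <- 2 * pi * frequency
  gstar <- matrix(NA_complex_, n, m)
  gstar[stable] <- -density * omega^2 * u[stable] / lap[stable]

  physical <- stable & Re(gstar) > 0 & Im(gstar) >= 0
  physical[is.na(physical)] <- FALSE
  neg_frac <- if (any(stable)) sum(stable & !physical) / sum(stable) else NA_real_

  valid <- physical
  if (!any(valid))
    stop(sprintf(
      "reconstruction failed: no valid pixels (interior %d, above Laplacian floor %d)",
      sum(interior), sum(stable)))

  gp <- matrix(NA_real_, n, m); gpp <- gp; absg <- gp; phi <- gp
  gp[valid] <- Re(gstar[valid])
  gpp[valid] <- Im(gstar[valid])
  absg[valid] <- Mod(gstar[valid])
  phi[valid] <- atan(gpp[valid] / gp[valid])
  gstar[!valid] <- NA_complex_

  out <- structure(list(gstar = gstar, gp = gp, gpp = gpp, absg = absg,
                        phi = phi, valid_mask = valid, frequency = frequency,
                        density = density),
                   class = "mre_elastogram")
  attr(out, "negative_fraction") <- neg_frac
  out
}

#' @export
print.mre_elastogram <- function(x, ...) {
  v <- x$valid_mask
  cat(sprintf("Elastogram %dx%d at %g Hz: %d/%d valid pixels\n",
              nrow(v), ncol(v), x$frequency, sum(v), length(v)))
  if (any(v))
    cat(sprintf("  median G' = %.0f Pa, G'' = %.0f Pa\n",
                stats::median(x$gp[v]), stats::median(x$gpp[v])))
  invisible(x)
}

#' Full reconstruction pipeline: phase series to elastogram
#'
#' Runs the complete processing chain on a pair of opposite-polarity wrapped
#' phase-image series: phase differencing, per-dynamic 2D unwrapping,
#' temporal harmonic extraction, radial Butterworth band-pass, algebraic
#' Helmholtz inversion.
#'
#' @param series_pos,series_neg Wrapped `mre_phase_series` with MSG polarity
#'   `+1` / `-1`.
#' @param protocol An [acquisition_protocol()].
#' @param spec An [filter_spec()]; `NULL` for [filter_spec_default()] scaled
#'   to `density`.
#' @param density Density, kg/m^3.
#' @param laplacian_floor Passed to [helmholtz_invert()].
#' @param unwrap_method Passed to [unwrap_phase()].
#' @param keep_intermediate If `TRUE`, attach the differenced/unwrapped
#'   series and the raw and filtered wave fields as attribute
#'   `"intermediate"`.
#' @return An `mre_elastogram`.
#' @export
reconstruct <- function(series_pos, series_neg, protocol, spec = NULL,
                        density = 1000, laplacian_floor = 0.05,
                        unwrap_method = "quality", keep_intermediate = FALSE) {
  if (is.null(spec))
    spec <- filter_spec_default(protocol$drive_frequency, density)
  diffed <- phase_difference(series_pos, series_neg)
  period <- if (isTRUE(attr(diffed, "halved"))) pi else 2 * pi
  unwrapped <- diffed$phase
  for (d in seq_len(dim(unwrapped)[3]))
    unwrapped[, , d] <- unwrap_phase(diffed$phase[, , d], period = period,
                                     method = unwrap_method)
  useries <- phase_series(unwrapped, protocol, wrapped = FALSE)
  field <- extract_harmonic(useries, protocol)
  filtered <- bandpass_filter(field, spec)
  elast <- helmholtz_invert(filtered, density, protocol$drive_frequency,
                            laplacian_floor)
  if (keep_intermediate)
    attr(elast, "intermediate") <- list(differenced = diffed,
                                        unwrapped = useries,
                                        field = field, filtered = filtered)
  elast
}
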