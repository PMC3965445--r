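# Reconstruction chain: differencing, unwrapping, harmonic extraction,
# band-pass filtering, Helmholtz inversion.

make_field <- function(n, p, gstar = ctrl_gstar, amplitude = 2e-6)
  analytic_plane_wave(gstar, 1000, p, c(1, 0), amplitude)

test_that("phase differencing cancels the static field exactly", {
  p <- fast_protocol(48)
  fld <- make_field(48, p)
  sp1 <- static_phase_poly(48)
  sp2 <- static_phase_poly(48, coef = c(-1.2, 0.4, 2.0, -0.8, 0.05, 0.9))
  d1 <- phase_difference(encode_phase(fld, p, +1, sp1),
                         encode_phase(fld, p, -1, sp1))
  d2 <- phase_difference(encode_phase(fld, p, +1, sp2),
                         encode_phase(fld, p, -1, sp2))
  # differenced series independent of the static polynomial
  expect_equal(d1$phase, d2$phase, tolerance = 1e-12)
  # and wrap-congruent (mod pi, halved) to the encoded motion component
  enc <- encode_phase(fld, p, +1, wrap = FALSE)$phase
  resid <- (d1$phase - enc) / pi
  expect_true(all(abs(resid - round(resid)) < 1e-10))
})

test_that("identical series difference to zero; protocol mismatch is rejected", {
  p <- fast_protocol(32)
  fld <- make_field(32, p)
  s <- encode_phase(fld, p, +1)
  expect_true(all(phase_difference(s, s)$phase == 0))
  p2 <- acquisition_protocol(matrix = 32, fov = 0.01)
  s2 <- encode_phase(make_field(32, p2), p2, -1)
  expect_error(phase_difference(s, s2), "protocol")
})

test_that("unwrapping recovers smooth fields for both methods", {
  # wrapped linear ramp 0 -> 6*pi across each row
  n <- 50
  ramp <- matrix(rep(seq(0, 6 * pi, length.out = n), each = n), n, n)
  for (m in c("quality", "itoh")) {
    uw <- unwrap_phase(wrap_phase(ramp), method = m)
    expect_lt(max(abs((uw - uw[1, 1]) - (ramp - ramp[1, 1]))), 1e-6)
  }
  cst <- matrix(0.7, 20, 20)
  expect_equal(unwrap_phase(cst), cst)
})

test_that("unwrapping a wrapped 10-um plane-wave encoding matches the pre-wrap field", {
  p <- fast_protocol(64)
  fld <- make_field(64, p, amplitude = 10e-6)
  raw <- encode_phase(fld, p, +1, wrap = FALSE)$phase[, , 1]
  wrapped <- wrap_phase(raw)
  uw <- unwrap_phase(wrapped)
  off <- (uw - raw) / (2 * pi)
  # equal up to a single global 2*pi multiple
  expect_lt(max(abs(off - round(mean(off)))), 1e-9)
})

test_that("harmonic extraction is a calibrated single-tone DFT", {
  p <- fast_protocol(32)
  nd <- p$n_dynamics
  xi <- encoding_efficiency(p)
  # series 2*cos(2*pi*d/8 - 0.7) -> modulus 2, phase 0.7 (in phase units)
  ph <- array(0, dim = c(32, 32, nd))
  for (d in 0:(nd - 1)) ph[, , d + 1] <- 2 * cos(2 * pi * d / nd - 0.7)
  fld <- extract_harmonic(mretools:::phase_series(ph, p, wrapped = FALSE), p)
  expect_equal(Mod(fld$u[1, 1]) * xi, 2, tolerance = 1e-12)
  expect_equal(Arg(fld$u[1, 1]), 0.7, tolerance = 1e-12)

  # constant series -> zero fundamental
  cst <- array(1.3, dim = c(32, 32, nd))
  fld0 <- extract_harmonic(mretools:::phase_series(cst, p, wrapped = FALSE), p)
  expect_lt(max(Mod(fld0$u)), 1e-15)

  # 2nd-harmonic contamination leaves the fundamental untouched
  ph2 <- ph
  for (d in 0:(nd - 1))
    ph2[, , d + 1] <- ph2[, , d + 1] + 0.8 * cos(2 * (2 * pi * d / nd) + 0.3)
  fld2 <- extract_harmonic(mretools:::phase_series(ph2, p, wrapped = FALSE), p)
  expect_equal(fld2$u, fld$u, tolerance = 1e-12)
})

test_that("identity chain: encode (no wrap) -> difference -> extract returns u", {
  p <- fast_protocol(48)
  fld <- make_field(48, p)
  pos <- encode_phase(fld, p, +1, static_phase_poly(48), wrap = FALSE)
  neg <- encode_phase(fld, p, -1, static_phase_poly(48), wrap = FALSE)
  d <- pos
  d$phase <- (pos$phase - neg$phase) / 2
  rec <- extract_harmonic(mretools:::phase_series(d$phase, p, wrapped = FALSE), p)
  expect_equal(rec$u, fld$u, tolerance = 1e-12)
})

test_that("Butterworth band-pass: passband transparency and DC rejection", {
  p <- fast_protocol(64)
  spec <- filter_spec_default()
  # lossless plane wave on an exact DFT bin (5 cycles across the grid) so
  # the periodic transform has no leakage and the gain can be read off
  k <- 2 * pi * 5 / (64 * p$pixel_spacing)
  gstar <- 1000 * (2 * pi * 900 / k)^2
  fld <- make_field(64, p, gstar = gstar + 0i)
  gain <- 1 / (1 + (k / spec$high_cut)^(2 * spec$order)) /
    (1 + (spec$low_cut / k)^(2 * spec$order))
  expect_gt(gain, 0.99)  # k strictly inside the passband
  filt <- bandpass_filter(fld, spec, pad = "none")
  ratio <- Mod(filt$u[20:45, 20:45]) / Mod(fld$u[20:45, 20:45])
  expect_lt(max(abs(ratio - gain)), 0.01)

  # uniform (k = 0) field attenuated by >= 99%
  cstf <- mretools:::wavefield(matrix(1e-6 + 0i, 64, 64), 900, p$pixel_spacing)
  fc <- bandpass_filter(cstf, spec, pad = "none")
  expect_lt(max(Mod(fc$u)) / 1e-6, 0.01)
})

test_that("white-noise variance is reduced by the filter's gain-squared integral", {
  p <- fast_protocol(64)
  spec <- filter_spec_default()
  # Parseval oracle: expected output/input variance ratio = mean(H^2)
  n <- 64
  idx <- ifelse(0:(n - 1) > n / 2, 0:(n - 1) - n, 0:(n - 1))
  fk <- 2 * pi * idx / (n * p$pixel_spacing)
  K <- sqrt(outer(fk^2, fk^2, `+`))
  H <- 1 / (1 + (K / spec$high_cut)^(2 * spec$order))
  nz <- K > 0
  Hhp <- matrix(0, n, n); Hhp[nz] <- 1 / (1 + (spec$low_cut / K[nz])^(2 * spec$order))
  expected <- mean((H * Hhp)^2)
  set.seed(5)
  ratios <- replicate(10, {
    u <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
    fldn <- mretools:::wavefield(u, 900, p$pixel_spacing)
    fn <- bandpass_filter(fldn, spec, pad = "none")
    mean(Mod(fn$u)^2) / mean(Mod(u)^2)
  })
  expect_lt(abs(mean(ratios) - expected) / expected, 0.05)
})

test_that("Helmholtz inversion recovers the analytic plane wave within 2%", {
  # 24 px/wavelength: stencil bias (kh/2)^2/sin^2(kh/2) ~ 0.6%, within spec
  p <- acquisition_protocol(matrix = 128, fov = 0.0125)
  pw <- analytic_plane_wave(ctrl_gstar, 1000, p, c(1, 0), 1e-6)
  el <- helmholtz_invert(pw, 1000)
  v <- el$valid_mask
  g_med <- complex(real = median(el$gp[v]), imaginary = median(el$gpp[v]))
  expect_lt(Mod(g_med - ctrl_gstar) / Mod(ctrl_gstar), 0.02)
})

test_that("inversion masks degenerate inputs and is scale invariant", {
  p <- fast_protocol(32)
  cstf <- mretools:::wavefield(matrix(1e-6 + 0i, 32, 32), 900, p$pixel_spacing)
  expect_error(helmholtz_invert(cstf, 1000), "no valid pixels")

  pw <- make_field(64, fast_protocol(64))
  el1 <- helmholtz_invert(pw, 1000)
  pw2 <- pw; pw2$u <- pw$u * (3.2 - 1.7i)
  el2 <- helmholtz_invert(pw2, 1000)
  expect_equal(el1$valid_mask, el2$valid_mask)
  expect_equal(el1$gstar[el1$valid_mask], el2$gstar[el2$valid_mask],
               tolerance = 1e-12)
})

test_that("per-pixel identities hold exactly on valid pixels", {
  p <- fast_protocol(64)
  el <- helmholtz_invert(make_field(64, p), 1000)
  v <- el$valid_mask
  expect_equal(el$absg[v]^2, el$gp[v]^2 + el$gpp[v]^2, tolerance = 1e-12)
  expect_equal(el$phi[v], atan(el$gpp[v] / el$gp[v]), tolerance = 1e-12)
})

test_that("stencil error shows second-order convergence in pixel spacing", {
  errs <- sapply(c(16, 32, 64), function(ppw) {
    # fov chosen so lambda = 2*pi/|k*| spans ppw pixels at the control modulus
    p <- acquisition_protocol(matrix = 96, fov = 96 * 2 * pi / (2577.726 * ppw))
    pw <- analytic_plane_wave(ctrl_gstar, 1000, p, c(1, 0), 1e-6)
    el <- helmholtz_invert(pw, 1000)
    v <- el$valid_mask
    g_med <- complex(real = median(el$gp[v]), imaginary = median(el$gpp[v]))
    Mod(g_med - ctrl_gstar) / Mod(ctrl_gstar)
  })
  # halving the spacing should cut the error ~4x (allow 3x for safety)
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})
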