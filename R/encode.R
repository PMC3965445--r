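#' Wrap phase values into the principal interval
#'
#' Maps values to `[-period/2, period/2)` (default `[-pi, pi)`). Idempotent:
#' `wrap_phase(wrap_phase(x)) == wrap_phase(x)`.
#'
#' @param x Numeric vector/matrix of phase values, rad.
#' @param period Wrapping period, default `2*pi`.
#' @return Wrapped values, same shape as `x`.
#' @export
wrap_phase <- function(x, period = 2 * pi) {
  ((x + period / 2) %% period) - period / 2
}

#' Low-order polynomial static background phase
#'
#' Builds a smooth 2D static phase field `c0 + c1*X + c2*Y + c3*X^2 +
#' c4*X*Y + c5*Y^2` with `X`, `Y` normalised pixel coordinates in `[-1, 1]`.
#' Models B0/receiver phase offsets that phase differencing must cancel.
#'
#' @param matrix Grid size in pixels.
#' @param coef Numeric vector of up to 6 polynomial coefficients, rad.
#' @return A `matrix x matrix` numeric field in rad (not wrapped).
#' @export
static_phase_poly <- function(matrix, coef = c(0.4, 1.1, -0.7, 0.3, 0.2, -0.5)) {
  n <- as.integer(matrix)
  coef <- c(coef, numeric(6))[1:6]
  x <- matrix(rep(seq(-1, 1, length.out = n), each = n), n, n)
  y <- matrix(rep(seq(-1, 1, length.out = n), times = n), n, n)
  coef[1] + coef[2] * x + coef[3] * y + coef[4] * x^2 + coef[5] * x * y +
    coef[6] * y^2
}

phase_series <- function(phase, protocol, wrapped) {
  stopifnot(inherits(protocol, "mre_protocol"),
            length(dim(phase)) == 3,
            dim(phase)[3] == protocol$n_dynamics)
  if (wrapped && (max(phase) >= pi || min(phase) < -pi))
    stop("wrapped series must lie in [-pi, pi)")
  structure(list(phase = phase, protocol = protocol, wrapped = wrapped),
            class = "mre_phase_series")
}

#' Encode a harmonic displacement field into an MR phase-image series
#'
#' For dynamic `d` in `0..n_dynamics-1` the encoded phase is
#' `wrap( msg_sign * xi * Re(u * exp(-2i*pi*d/n_dynamics)) + static_phase +
#' noise )`, with encoding efficiency `xi` from [encoding_efficiency()].
#' Gaussian noise (sd `noise_sd` rad) is added before wrapping. With
#' `noise_sd = 0` the output is deterministic.
#'
#' @param field An `mre_wavefield` (displacement in metres).
#' @param protocol An [acquisition_protocol()].
#' @param msg_sign MSG polarity, `+1` or `-1`.
#' @param static_phase Static background phase field (rad), a matrix matching
#'   the field, or `NULL` for zero.
#' @param noise_sd Phase noise standard deviation, rad.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param wrap If `FALSE`, skip wrapping (diagnostic use: makes the
#'   encode/decode chain exactly linear).
#'
#' @return An `mre_phase_series` for the single polarity (array
#'   `matrix x matrix x n_dynamics`).
#' @export
encode_phase <- function(field, protocol, msg_sign = 1, static_phase = NULL,
                         noise_sd = 0, seed = NULL, wrap = TRUE) {
  stopifnot(inherits(field, "mre_wavefield"), inherits(protocol, "mre_protocol"))
  if (!msg_sign %in% c(-1, 1)) stop("msg_sign must be +1 or -1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- nrow(field$u)
  nd <- protocol$n_dynamics
  if (is.null(static_phase)) static_phase <- matrix(0, n, n)
  stopifnot(all(dim(static_phase) == dim(field$u)))
  if (noise_sd > 0 && !is.null(seed)) set.seed(seed)

  xi <- encoding_efficiency(protocol)
  out <- array(0, dim = c(n, n, nd))
  for (d in 0:(nd - 1)) {
    enc <- msg_sign * xi * Re(field$u * exp(-2i * pi * d / nd))
    img <- enc + static_phase
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    out[, , d + 1] <- if (wrap) wrap_phase(img) else img
  }
  phase_series(out, protocol, wrapped = wrap)
}

#' @export
print.mre_phase_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("MRE phase series %dx%d, %d dynamics, %s\n",
              d[1], d[2], d[3], if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}
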