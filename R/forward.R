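#' Analytic damped plane shear wave
#'
#' Closed-form harmonic displacement field
#' `u(x) = amplitude * exp(-i * kstar * s)`, where `s` is the distance along
#' `direction` from the entry edge and `kstar = omega * sqrt(density / gstar)`
#' (principal branch, `Re >= 0`, `Im <= 0`). With the package's temporal
#' convention (dynamic `d` samples `Re(u * exp(-2i*pi*d/n))`), this branch
#' makes the wave decay along `direction`. For a purely real (lossless)
#' modulus the magnitude `|u|` is constant.
#'
#' Serves as the independent oracle for the forward solver and the
#' Helmholtz inversion.
#'
#' @param gstar Complex shear modulus, Pa (`Re > 0`).
#' @param density Density in kg/m^3.
#' @param protocol An [acquisition_protocol()]; supplies frequency, matrix
#'   and pixel spacing.
#' @param direction Length-2 propagation direction (x = columns, y = rows);
#'   normalised internally.
#' @param amplitude Displacement amplitude at the entry edge, metres.
#'
#' @return An `mre_wavefield`: list with complex matrix `u` (metres),
#'   `frequency` (Hz) and `pixel_spacing` (m).
#' @export
analytic_plane_wave <- function(gstar, density, protocol,
                                direction = c(1, 0), amplitude = 1e-5) {
  stopifnot(inherits(protocol, "mre_protocol"))
  if (Re(gstar) <= 0) stop("gstar must have positive real part")
  d <- direction / sqrt(sum(direction^2))
  n <- protocol$matrix
  h <- protocol$pixel_spacing
  omega <- 2 * pi * protocol$drive_frequency
  kstar <- omega * sqrt(as.complex(density) / as.complex(gstar))
  if (Re(kstar) < 0) kstar <- -kstar

  ix <- matrix(rep(0:(n - 1), each = n), n, n) * h   # x, along columns
  iy <- matrix(rep(0:(n - 1), times = n), n, n) * h  # y, along rows
  # project from the entry corner so s >= 0 everywhere
  s <- d[1] * (if (d[1] >= 0) ix else ix - (n - 1) * h) +
       d[2] * (if (d[2] >= 0) iy else iy - (n - 1) * h)
  u <- amplitude * exp(-1i * kstar * s)
  wavefield(u, protocol$drive_frequency, h)
}

wavefield <- function(u, frequency, pixel_spacing) {
  if (any(!is.finite(Re(u))) || any(!is.finite(Im(u))))
    stop("wave field contains non-finite values")
  if (frequency <= 0) stop("frequency must be positive")
  structure(list(u = u, frequency = frequency, pixel_spacing = pixel_spacing),
            class = "mre_wavefield")
}

#' @export
print.mre_wavefield <- function(x, ...) {
  cat(sprintf("Complex wave field %dx%d at %g Hz, max |u| = %.3g m\n",
              nrow(x$u), ncol(x$u), x$frequency, max(Mod(x$u))))
  invisible(x)
}

#' Solve the forward shear-wave problem at the drive frequency
#'
#' Solves the heterogeneous 2D Helmholtz problem
#' `div(G* grad u) + rho * omega^2 * u = 0`
#' for the through-plane harmonic displacement `u` on the phantom grid, with
#' a prescribed harmonic displacement (Dirichlet drive) on one grid edge and
#' an absorbing sponge (graded mass damping, `rho*omega^2*(1+i*sigma)`) in
#' front of the remaining edges to emulate outgoing waves. Discretisation is
#' the standard 5-point finite-difference stencil with edge-midpoint
#' (arithmetic-mean) moduli; the resulting sparse complex system is solved
#' directly via an equivalent real block system.
#'
#' Because the same 5-point Laplacian is used by [helmholtz_invert()], the
#' inversion of a forward-simulated homogeneous field is exact on interior
#' pixels outside the sponge, up to the filtering steps in between.
#'
#' @param phantom An [build_phantom()] result.
#' @param protocol An [acquisition_protocol()] (frequency must be consistent).
#' @param drive_boundary One of `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @param drive_amplitude Prescribed displacement amplitude on the drive
#'   edge, metres (may be complex).
#' @param sponge_width Width of the absorbing layer in pixels.
#' @param sponge_max Maximum damping factor `sigma` at the outer edge.
#' @param lateral_bc `"sponge"` (default: absorb on the two edges parallel to
#'   propagation) or `"neumann"` (zero-flux, preserving plane-wave symmetry;
#'   useful for quasi-1D verification).
#'
#' @return An `mre_wavefield` with `u` in metres. The sponge mask is attached
#'   as attribute `"sponge"` (logical matrix).
#' @export
solve_forward <- function(phantom, protocol,
                          drive_boundary = c("left", "right", "top", "bottom"),
                          drive_amplitude = 1e-5,
                          sponge_width = 12, sponge_max = 2,
                          lateral_bc = c("sponge", "neumann")) {
  stopifnot(inherits(phantom, "mre_phantom"), inherits(protocol, "mre_protocol"))
  drive_boundary <- match.arg(drive_boundary)
  lateral_bc <- match.arg(lateral_bc)
  G <- phantom$gstar_map
  n <- nrow(G)
  h <- phantom$pixel_spacing
  rho <- phantom$density
  f <- protocol$drive_frequency
  omega <- 2 * pi * f

  # resolution precondition: >= 6 pixels per shear wavelength everywhere
  ppw <- sqrt(Mod(G) / rho) / f / h
  if (min(ppw) < 6)
    stop(sprintf("shear wavelength under-resolved: %.2f pixels/wavelength (need >= 6)",
                 min(ppw)))

  # damping profile: quadratic ramp within sponge_width of absorbing edges
  ix <- matrix(rep(0:(n - 1), each = n), n, n)   # column (x)
  iy <- matrix(rep(0:(n - 1), times = n), n, n)  # row (y)
  edge_dist <- function(which) switch(which,
    left = ix, right = (n - 1) - ix, top = iy, bottom = (n - 1) - iy)
  absorbing <- setdiff(c("left", "right", "top", "bottom"), drive_boundary)
  if (lateral_bc == "neumann") {
    opposite <- c(left = "right", right = "left", top = "bottom", bottom = "top")
    absorbing <- opposite[[drive_boundary]]
  }
  sigma <- matrix(0, n, n)
  for (e in absorbing) {
    de <- edge_dist(e)
    ramp <- pmax(0, (sponge_width - de) / sponge_width)^2 * sponge_max
    sigma <- pmax(sigma, ramp)
  }

  # Dirichlet pixels: the drive edge plus the outer ring of every absorbing
  # edge; pixels on a Neumann (zero-flux) edge stay unknowns
  on_drive <- edge_dist(drive_boundary) == 0
  dirichlet <- on_drive
  for (e in absorbing) dirichlet <- dirichlet | (edge_dist(e) == 0)

  idx <- matrix(seq_len(n * n), n, n)  # column-major ids
  bvals <- ifelse(on_drive, as.complex(drive_amplitude), 0 + 0i)

  # assemble interior equations (vectorised over the 4 neighbours)
  int <- which(!dirichlet)
  ii <- ((int - 1) %% n) + 1      # row
  jj <- ((int - 1) %/% n) + 1     # col
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- complex(0)
  rhs <- complex(length(idx)); rhs[] <- 0 + 0i
  centre <- complex(length(int)); centre[] <- 0 + 0i

  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in shifts) {
    ni <- ii + s[1]; nj <- jj + s[2]
    inside <- ni >= 1 & ni <= n & nj >= 1 & nj <= n
    # with Neumann edges a missing neighbour simply contributes no flux;
    # otherwise every interior pixel has all 4 neighbours (outer ring is
    # Dirichlet), so `inside` is only FALSE next to a Neumann edge
    w <- which(inside)
    nb <- idx[cbind(ni[w], nj[w])]
    ge <- 0.5 * (G[int[w]] + G[nb]) / h^2
    centre[w] <- centre[w] - ge
    isdir <- dirichlet[nb]
    # neighbour is unknown: off-diagonal entry; neighbour is Dirichlet: RHS
    trip_i <- c(trip_i, int[w][!isdir])
    trip_j <- c(trip_j, nb[!isdir])
    trip_x <- c(trip_x, ge[!isdir])
    rhs[int[w][isdir]] <- rhs[int[w][isdir]] - ge[isdir] * bvals[nb[isdir]]
  }
  # mass damping: with this package's phase convention (waves e^{-i k* x},
  # k* = omega*sqrt(rho/G*), decaying for Im(G*) > 0) absorption enters with
  # a negative imaginary part on the rho*omega^2 term
  centre <- centre + rho * omega^2 * (1 - 1i * sigma[int])
  trip_i <- c(trip_i, int)
  trip_j <- c(trip_j, int)
  trip_x <- c(trip_x, centre)

  # map unknown ids to compact indices
  map <- integer(n * n); map[int] <- seq_along(int)
  Ai <- map[trip_i]; Aj <- map[trip_j]
  keep <- Aj > 0  # drop entries pointing at Dirichlet nodes (already on RHS)
  Ai <- Ai[keep]; Aj <- Aj[keep]; Ax <- trip_x[keep]
  m <- length(int)
  b <- rhs[int]

  # complex sparse solve via real 2m x 2m block system
  Ar <- Matrix::sparseMatrix(i = Ai, j = Aj, x = Re(Ax), dims = c(m, m))
  Aim <- Matrix::sparseMatrix(i = Ai, j = Aj, x = Im(Ax), dims = c(m, m))
  M <- rbind(cbind(Ar, -Aim), cbind(Aim, Ar))
  z <- Matrix::solve(M, c(Re(b), Im(b)))
  z <- as.numeric(z)
  sol <- complex(real = z[seq_len(m)], imaginary = z[m + seq_len(m)])

  u <- matrix(0 + 0i, n, n)
  u[int] <- sol
  u[dirichlet] <- bvals[dirichlet]
  if (any(!is.finite(Re(u))))
    stop("singular linear system in forward solve (grid ", n, "x", n, ")")

  out <- wavefield(u, f, h)
  attr(out, "sponge") <- sigma > 0
  out
}
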