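#' Build a 2D viscoelastic phantom with a hippocampus-like ROI
#'
#' Constructs the simulation ground truth: a per-pixel complex shear modulus
#' map `G* = G' + iG''` (Pa), a uniform density, and integer region labels
#' (0 = background, 1 = parenchyma, 2 = hippocampus-like ROI). The default
#' geometry is an elliptical "brain" spanning most of the grid with a smaller
#' elliptical hippocampus-like sub-region below its centre; `geometry =
#' "full"` fills the whole grid with tissue (useful for homogeneous-medium
#' tests where boundary apertures are unwanted).
#'
#' Background pixels keep a finite coupling modulus (default: the parenchyma
#' value) so the forward solver remains well posed and the drive boundary
#' stays mechanically connected to the tissue; region labels, not moduli,
#' decide which pixels count as tissue downstream.
#'
#' @param matrix Grid size in pixels per side (>= 32).
#' @param fov Field of view in metres.
#' @param parenchyma_gstar Complex shear modulus of the parenchyma, Pa.
#' @param hippocampus_gstar Complex shear modulus of the hippocampus ROI, Pa.
#' @param density Tissue density in kg/m^3.
#' @param geometry `"ellipse"` (default) or `"full"`.
#' @param background_gstar Modulus assigned to background pixels (label 0);
#'   defaults to `parenchyma_gstar`.
#'
#' @return An object of class `mre_phantom`: list with `gstar_map` (complex
#'   matrix), `region_labels` (integer matrix), `density`, `pixel_spacing`.
#' @export
#'
#' @examples
#' ph <- build_phantom(64, 0.025, 5234 + 1447i, 4608 + 1388i, 1000)
#' table(ph$region_labels)
build_phantom <- function(matrix = 128, fov = 0.025,
                          parenchyma_gstar = 5234 + 1447i,
                          hippocampus_gstar = 4608 + 1388i,
                          density = 1000,
                          geometry = c("ellipse", "full"),
                          background_gstar = parenchyma_gstar) {
  geometry <- match.arg(geometry)
  if (matrix < 32) stop("matrix must be >= 32")
  if (Re(parenchyma_gstar) <= 0)
    stop("parenchyma modulus must have positive real part (storage modulus)")
  if (Re(hippocampus_gstar) <= 0)
    stop("hippocampus modulus must have positive real part (storage modulus)")
  if (Im(parenchyma_gstar) < 0 || Im(hippocampus_gstar) < 0)
    stop("loss moduli (imaginary parts) must be non-negative")
  if (density <= 0) stop("density must be positive")

  n <- as.integer(matrix)
  h <- fov / n
  # pixel-centre coordinates in pixel units, 0-based
  ix <- matrix(rep(0:(n - 1), each = n), n, n)   # column index (x)
  iy <- matrix(rep(0:(n - 1), times = n), n, n)  # row index (y)
  cx <- (n - 1) / 2
  cy <- (n - 1) / 2

  labels <- matrix(0L, n, n)
  if (geometry == "full") {
    labels[] <- 1L
  } else {
    # brain ellipse slightly larger than the half-grid so it is clipped at the
    # edge midpoints, giving the drive boundary a tissue aperture
    brain <- ((ix - cx) / (0.52 * n))^2 + ((iy - cy) / (0.46 * n))^2 <= 1
    labels[brain] <- 1L
  }
  # hippocampus-like ellipse below centre
  hip <- ((ix - cx) / (0.22 * n))^2 + ((iy - (cy + 0.12 * n)) / (0.11 * n))^2 <= 1
  labels[hip & labels == 1L] <- 2L
  if (!any(labels == 2L)) stop("hippocampus ROI ended up empty")

  gmap <- matrix(as.complex(background_gstar), n, n)
  gmap[labels == 1L] <- as.complex(parenchyma_gstar)
  gmap[labels == 2L] <- as.complex(hippocampus_gstar)

  structure(list(gstar_map = gmap, region_labels = labels,
                 density = density, pixel_spacing = h, fov = fov),
            class = "mre_phantom")
}

#' @export
print.mre_phantom <- function(x, ...) {
  n <- nrow(x$gstar_map)
  cat(sprintf("Viscoelastic phantom %dx%d (%.3f mm pixels)\n",
              n, n, x$pixel_spacing * 1e3))
  for (lab in sort(unique(as.vector(x$region_labels)))) {
    g <- x$gstar_map[x$region_labels == lab][1]
    cat(sprintf("  label %d: %6d px, G* = %.0f + %.0fi Pa\n",
                lab, sum(x$region_labels == lab), Re(g), Im(g)))
  }
  invisible(x)
}
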