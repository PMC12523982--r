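#' Optical configuration for a quantitative phase imaging experiment
#'
#' Bundles the optical constants required to interpret an
#' optical-path-difference (OPD) raster physically: the illumination
#' wavelength, the lateral pixel size, the refractive indices of the
#' culture medium and of the (assumed homogeneous) cell, and the
#' specific refractive increment used to convert integrated OPD into
#' dry mass.
#'
#' The measured phase shift of light traversing a cell is
#' \eqn{\phi = (2\pi/\lambda)\,(n_o - n_m)\,t}, where \eqn{n_o} and
#' \eqn{n_m} are the refractive indices of object and medium and
#' \eqn{t} the physical thickness. The package stores images as OPD
#' in micrometres, \eqn{\mathrm{OPD} = \phi\,\lambda/(2\pi)
#' = (n_o - n_m)\,t}, so all downstream metrics are length-valued.
#' Dry mass follows from the specific refractive increment
#' \eqn{\alpha}: \eqn{M = \sum \mathrm{OPD} \cdot A_{px} / \alpha}
#' with \eqn{A_{px}} the pixel area.
#'
#' Defaults are representative values for visible-light QPI of
#' adherent cells in aqueous medium; all are configurable and should
#' be set to the instrument's actual calibration when known.
#'
#' @param wavelength illumination wavelength, micrometres.
#' @param pixel_size lateral sampling, micrometres per pixel.
#' @param medium_ri refractive index of the culture medium
#'   (dimensionless).
#' @param object_ri assumed mean refractive index of the cell
#'   (dimensionless); must exceed `medium_ri`.
#' @param alpha specific refractive increment, um^3/pg. The
#'   literature-standard protein value 0.18 mL/g equals 0.18 um^3/pg.
#'
#' @return An object of class `optics_config`.
#' @examples
#' opt <- optics_config()
#' delta_ri(opt)
#' @export
optics_config <- function(wavelength = 0.640, pixel_size = 0.5,
                          medium_ri = 1.337, object_ri = 1.377,
                          alpha = 0.18) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            is.numeric(medium_ri), length(medium_ri) == 1L,
            is.numeric(object_ri), length(object_ri) == 1L,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  if (object_ri <= medium_ri)
    stop("object_ri must exceed medium_ri (cells are optically denser than medium)")
  structure(list(wavelength = wavelength, pixel_size = pixel_size,
                 medium_ri = medium_ri, object_ri = object_ri,
                 alpha = alpha),
            class = "optics_config")
}

#' Refractive index contrast of an optics configuration
#'
#' @param optics an [optics_config()].
#' @return `object_ri - medium_ri` (dimensionless).
#' @export
delta_ri <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  optics$object_ri - optics$medium_ri
}

#' Convert phase in radians to optical path difference in micrometres
#'
#' OPD = phi * lambda / (2 pi).
#'
#' @param phi phase shift, radians (vector, matrix or array).
#' @param optics an [optics_config()] supplying the wavelength.
#' @return OPD in micrometres, same shape as `phi`.
#' @export
opd_from_phase <- function(phi, optics) {
  stopifnot(inherits(optics, "optics_config"))
  phi * optics$wavelength / (2 * pi)
}

#' @export
print.optics_config <- function(x, ...) {
  cat("optics_config\n")
  cat(sprintf("  wavelength : %.4g um\n", x$wavelength))
  cat(sprintf("  pixel size : %.4g um/px\n", x$pixel_size))
  cat(sprintf("  medium RI  : %.4f\n", x$medium_ri))
  cat(sprintf("  object RI  : %.4f  (delta n = %.4f)\n",
              x$object_ri, x$object_ri - x$medium_ri))
  cat(sprintf("  alpha      : %.3g um^3/pg\n", x$alpha))
  invisible(x)
}
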