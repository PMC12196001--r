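# Modified Beer-Lambert relation between optical-density change and
# haemoglobin concentration change:
#   dOD(lambda) = d * DPF(lambda) * [eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR]
# with concentrations in micromolar, source-detector distance d in cm and
# molar extinction coefficients in cm^-1 uM^-1.

# Extinction coefficients at 760 / 850 nm from the standard haemoglobin
# spectra compilation used throughout the fNIRS literature, converted from
# cm^-1 M^-1 to cm^-1 uM^-1.
EXTINCTION_760_850 <- matrix(
  c(1486.5865, 3843.707,
    2526.3910, 1798.643) * 1e-6,
  nrow = 2, byrow = TRUE,
  dimnames = list(c("760", "850"), c("hbo", "hbr"))
)

#' Channel optical geometry for Beer-Lambert conversion
#'
#' Bundles the constants of the modified Beer-Lambert law: source-detector
#' distance (3 cm for this montage), differential pathlength factor (DPF) per
#' wavelength, and the 2x2 extinction-coefficient matrix at 760/850 nm (rows:
#' wavelength; columns: HbO, HbR; units cm^-1 uM^-1). With these units the
#' recovered concentration changes are in micromolar.
#'
#' @param distance_cm Source-detector distance in cm.
#' @param dpf Differential pathlength factor, length-2 (760 nm, 850 nm) or a
#'   single value used for both.
#' @param epsilon 2x2 extinction matrix, rows = wavelengths (760, 850),
#'   columns = (HbO, HbR), in cm^-1 uM^-1.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(distance_cm = 3, dpf = c(6, 6),
                             epsilon = EXTINCTION_760_850) {
  assert_scalar_number(distance_cm, "distance_cm", min = 1e-9)
  if (length(dpf) == 1L) dpf <- rep(dpf, 2L)
  if (length(dpf) != 2L || any(!is.finite(dpf)) || any(dpf <= 0)) {
    abort("`dpf` must be one or two positive numbers.",
          class = "dyadsync_parameter_error")
  }
  epsilon <- as.matrix(epsilon)
  if (!all(dim(epsilon) == c(2L, 2L)) || any(!is.finite(epsilon))) {
    abort("`epsilon` must be a finite 2x2 matrix.",
          class = "dyadsync_geometry_error")
  }
  if (abs(det(epsilon)) < 1e-12 * prod(sqrt(rowSums(epsilon^2)))) {
    abort("`epsilon` is singular: HbO and HbR cannot be separated.",
          class = "dyadsync_geometry_error")
  }
  structure(list(distance_cm = distance_cm, dpf = as.numeric(dpf),
                 epsilon = epsilon),
            class = "channel_geometry")
}

# 2x2 system matrix A with dOD = A %*% c(dHbO, dHbR)
geometry_matrix <- function(geometry) {
  diag(geometry$distance_cm * geometry$dpf) %*% geometry$epsilon
}

#' Forward Beer-Lambert map: concentrations to optical densities
#'
#' @param hbo,hbr Numeric series of haemoglobin concentration changes (uM).
#' @param geometry A [channel_geometry()].
#' @return A list with numeric series `od_760` and `od_850`.
#' @export
beer_lambert_forward <- function(hbo, hbr, geometry = channel_geometry()) {
  stopifnot(length(hbo) == length(hbr))
  a <- geometry_matrix(geometry)
  list(od_760 = a[1, 1] * hbo + a[1, 2] * hbr,
       od_850 = a[2, 1] * hbo + a[2, 2] * hbr)
}

#' Inverse Beer-Lambert map: optical densities to concentrations
#'
#' Solves the 2x2 linear system of the modified Beer-Lambert law per sample.
#' Exact inverse of [beer_lambert_forward()] under the same geometry.
#'
#' @param od_760,od_850 Optical-density change series at 760 and 850 nm.
#' @param geometry A [channel_geometry()].
#' @return A list with numeric series `hbo` and `hbr` (uM).
#' @export
#' @examples
#' g <- channel_geometry()
#' od <- beer_lambert_forward(hbo = c(0.5, -0.2), hbr = c(-0.1, 0.05), g)
#' beer_lambert_inverse(od$od_760, od$od_850, g)
beer_lambert_inverse <- function(od_760, od_850, geometry = channel_geometry()) {
  if (length(od_760) != length(od_850)) {
    abort("`od_760` and `od_850` must have equal length.",
          class = "dyadsync_format_error")
  }
  a_inv <- solve(geometry_matrix(geometry))
  conc <- a_inv %*% rbind(od_760, od_850)
  list(hbo = as.numeric(conc[1, ]), hbr = as.numeric(conc[2, ]))
}
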