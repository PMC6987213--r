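# Proton kinematics and material constants.
#
# Package-wide unit convention (documented in every exported function):
#   transverse positions  mm
#   transverse angles     mrad
#   longitudinal lengths  cm (user-facing), m (internal transfer maps)
#   kinetic energies      MeV
# A 2x2 transfer map written in SI (drift lengths in m) acts consistently on
# (mm, mrad) state vectors because mrad * m = mm.

PROTON_MASS_MEV <- 938.27208816
FWHM_CONST <- 2 * sqrt(2 * log(2)) # displayed as 2.355

#' Relativistic kinematics of a proton
#'
#' @param energy Kinetic energy in MeV (vectorised).
#' @return List with components \code{pc} (momentum times c, MeV),
#'   \code{beta} (v/c), \code{pv} (momentum times velocity, MeV) and
#'   \code{brho} (magnetic rigidity, T m).
#' @export
proton_kinematics <- function(energy) {
  stopifnot(all(energy > 0))
  etot <- energy + PROTON_MASS_MEV
  pc <- sqrt(energy * (energy + 2 * PROTON_MASS_MEV))
  beta <- pc / etot
  list(pc = pc, beta = beta, pv = pc * beta, brho = pc / 299.792458)
}

# Radiation lengths in metres. Water-equivalent slabs use the water value.
.radiation_lengths_m <- c(
  vacuum = Inf,
  air    = 303.9,   # dry air, NTP: 36.62 g/cm^2 / 1.205e-3 g/cm^3
  water  = 0.3608   # 36.08 g/cm^2 / 1.0 g/cm^3
)

radiation_length_m <- function(material) {
  x0 <- .radiation_lengths_m[material]
  if (any(is.na(x0))) {
    stop("unknown material: ", paste(material[is.na(x0)], collapse = ", "))
  }
  unname(x0)
}

#' Highland multiple-Coulomb-scattering angle
#'
#' RMS projected scattering angle theta0 of a proton traversing a thickness of
#' material, from the Highland parametrisation
#' theta0 = (13.6 MeV / pv) * sqrt(t/X0) * (1 + 0.038 log(t/X0)).
#' Only the Gaussian core is modelled; no Moliere tails.
#'
#' @param energy Kinetic energy in MeV (vectorised; per-particle pv is used).
#' @param thickness_m Path length in the material, metres.
#' @param material One of \code{"vacuum"}, \code{"air"}, \code{"water"}.
#' @return theta0 in mrad (0 for zero thickness or vacuum).
#' @export
scattering_theta0 <- function(energy, thickness_m, material = "air") {
  stopifnot(all(thickness_m >= 0))
  x0 <- radiation_length_m(material)
  n <- max(length(energy), length(thickness_m))
  energy <- rep_len(energy, n)
  thickness_m <- rep_len(thickness_m, n)
  if (!is.finite(x0)) return(rep(0, n))
  pv <- proton_kinematics(energy)$pv
  tr <- thickness_m / x0
  th <- ifelse(tr > 0,
               13.6 / pv * sqrt(tr) * (1 + 0.038 * log(tr)) * 1000, # mrad
               0)
  pmax(th, 0)
}
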