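#' Unit constants
#'
#' Avogadro's constant and the particles-per-cubic-micrometre equivalent of
#' 1 nM. With N_A = 6.022e23 /mol, 1 nM = 1e-9 mol/L = 1e-9 * 6.022e23 / 1e15
#' particles/um^3 = 0.6022 particles/um^3.
#'
#' @name units
#' @keywords internal
NULL

AVOGADRO <- 6.022e23
PARTICLES_PER_UM3_PER_NM <- 0.6022

#' Default confocal detection volume in cubic micrometres
#'
#' Used for particle-count to concentration conversions when no beam
#' calibration is supplied.
#' @keywords internal
DEFAULT_CONFOCAL_VOLUME <- 0.16

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

check_finite_positive <- function(x, name) {
  stop_if(!is.numeric(x) || any(!is.finite(x)), paste0("'", name, "' must be finite numeric"))
  stop_if(any(x <= 0), paste0("'", name, "' must be positive"))
  invisible(x)
}

check_finite_nonneg <- function(x, name) {
  stop_if(!is.numeric(x) || any(!is.finite(x)), paste0("'", name, "' must be finite numeric"))
  stop_if(any(x < 0), paste0("'", name, "' must be nonnegative"))
  invisible(x)
}

#' Convert particles per confocal volume to molar concentration
#'
#' A count of `N` particles in a detection volume `volume_um3` corresponds to
#' `N / (V_C * N_A)` moles per litre; the result is reported in nM. One
#' particle in the default 0.16 um^3 volume is about 10 nM.
#'
#' @param N particles per confocal volume (nonnegative).
#' @param volume_um3 confocal volume in um^3, or a [beam_geometry()] object.
#' @return concentration in nM.
#' @seealso [per_confocal_to_per_um3()], [nM_to_per_um3()]
#' @examples
#' n_to_molar(1, 0.16)   # ~10.4 nM
#' @export
n_to_molar <- function(N, volume_um3 = DEFAULT_CONFOCAL_VOLUME) {
  if (inherits(volume_um3, "beam_geometry")) volume_um3 <- volume_um3$confocal_volume
  check_finite_nonneg(N, "N")
  check_finite_positive(volume_um3, "volume_um3")
  # particles/um^3 -> nM via 0.6022 particles/(um^3 nM)
  (N / volume_um3) / PARTICLES_PER_UM3_PER_NM
}

#' Convert particles per confocal volume to particles per cubic micrometre
#'
#' @param N particles per confocal volume.
#' @param volume_um3 confocal volume in um^3 (default 0.16).
#' @return particles per um^3.
#' @examples
#' per_confocal_to_per_um3(3, 0.16)  # 18.75
#' @export
per_confocal_to_per_um3 <- function(N, volume_um3 = DEFAULT_CONFOCAL_VOLUME) {
  check_finite_nonneg(N, "N")
  check_finite_positive(volume_um3, "volume_um3")
  N / volume_um3
}

#' Convert nM to particles per cubic micrometre and back
#'
#' @param conc_nM concentration in nM.
#' @param density particles per um^3.
#' @return the converted quantity.
#' @export
nM_to_per_um3 <- function(conc_nM) {
  check_finite_nonneg(conc_nM, "conc_nM")
  conc_nM * PARTICLES_PER_UM3_PER_NM
}

#' @rdname nM_to_per_um3
#' @export
per_um3_to_nM <- function(density) {
  check_finite_nonneg(density, "density")
  density / PARTICLES_PER_UM3_PER_NM
}
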