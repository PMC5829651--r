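#' Unit system of the coarse-grained model
#'
#' The simulation works in reduced units: length in sigma (one fibre bead
#' diameter), energy in kT, time in tau = gamma * sigma^2 / kT.  One sigma
#' corresponds to `sigma_nm` nanometres of 10-nm chromatin fibre and one bead
#' to `bp_per_bead` base pairs.
#'
#' @param sigma_nm length of one sigma in nanometres (default 10).
#' @param bp_per_bead genomic span of one bead in base pairs (default 400).
#' @param kT thermal energy unit (1 in reduced units).
#' @return An object of class `sx_units`.
#' @examples
#' u <- unit_system()
#' sigma_to_nm(4.5, u)   # 45 nm
#' @export
unit_system <- function(sigma_nm = 10, bp_per_bead = 400, kT = 1) {
  stopifnot(sigma_nm > 0, bp_per_bead > 0, kT > 0)
  structure(list(sigma_nm = sigma_nm, bp_per_bead = bp_per_bead,
                 kT = kT, tau = 1),
            class = "sx_units")
}

#' @export
print.sx_units <- function(x, ...) {
  cat("unit system: 1 sigma =", x$sigma_nm, "nm, 1 bead =", x$bp_per_bead,
      "bp, kT =", x$kT, "\n")
  invisible(x)
}

#' Convert a length in sigma to nanometres
#' @param x length in sigma units.
#' @param units an [unit_system()].
#' @export
sigma_to_nm <- function(x, units = unit_system()) x * units$sigma_nm

#' Convert nanometres to sigma
#' @inheritParams sigma_to_nm
#' @export
nm_to_sigma <- function(x, units = unit_system()) x / units$sigma_nm

#' Supercoils injected by one round of transcription
#'
#' RNA polymerase with TOP1 positioned ahead of it deposits one net negative
#' supercoil per `bases_per_supercoil` transcribed bases; a single round of
#' eRNA transcription (~350 nt) therefore injects more than 30 negative
#' supercoils into the fibre.
#'
#' @param transcript_nt transcript length in nucleotides.
#' @param bases_per_supercoil transcribed bases per injected supercoil
#'   (default 10).
#' @return Number of supercoils (turns) injected.
#' @examples
#' supercoils_per_transcript(350)  # 35
#' @export
supercoils_per_transcript <- function(transcript_nt, bases_per_supercoil = 10) {
  stopifnot(transcript_nt >= 0, bases_per_supercoil > 0)
  transcript_nt / bases_per_supercoil
}
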