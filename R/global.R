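#' Vertical ionization potential and electron affinity via Koopmans-in-DFT
#'
#' The KID (Koopmans in DFT) approximation identifies the vertical
#' ionization potential with the negative of the HOMO energy and the
#' vertical electron affinity with the negative of the LUMO energy,
#' avoiding separate cation/anion SCF calculations.
#'
#' @param record A [frontier_record] (energies in eV).
#' @return An object of class `kid_energies` with fields `I` and `A` (eV).
#' @examples
#' kid_energies(frontier_record("alaviroidin", -6.072, -1.700))
#' @export
kid_energies <- function(record) {
  stopifnot(inherits(record, "frontier_record"))
  I <- -record$epsilon_homo; A <- -record$epsilon_lumo
  if (I <= A)
    stop_cdft(sprintf("degenerate gap for '%s': I = %.4f <= A = %.4f",
                      record$label, I, A), "cdft_degenerate_gap")
  structure(list(label = record$label, I = I, A = A), class = "kid_energies")
}

#' @export
print.kid_energies <- function(x, ...) {
  cat(sprintf("<kid_energies> %s  I = %.3f eV  A = %.3f eV\n", x$label, x$I, x$A))
  invisible(x)
}

#' Global conceptual-DFT reactivity descriptors
#'
#' From the KID ionization potential I and electron affinity A (eV):
#' \deqn{\chi = (I+A)/2, \quad \eta = I-A, \quad \omega = \chi^2/2\eta,}
#' \deqn{\omega^- = (3I+A)^2/16\eta, \quad \omega^+ = (I+3A)^2/16\eta,
#'       \quad \Delta\omega^\pm = \omega^- + \omega^+.}
#' Two algebraic identities follow and are useful as self-checks:
#' \eqn{\omega^- - \omega^+ = \chi} and
#' \eqn{\Delta\omega^\pm = \omega^- + \omega^+} exactly.
#'
#' @param k A [kid_energies] object, or a [frontier_record] (converted
#'   internally).
#' @return An object of class `global_descriptors`: a list with fields
#'   `label`, `chi`, `eta`, `omega`, `omega_minus`, `omega_plus`,
#'   `net_electrophilicity`, `lambda_max` (nm, unrounded), `pka` — all at
#'   full precision. Use [format_descriptor_row()] for table-precision
#'   reporting.
#' @param pka_model A [pka_model] used for the hardness-based pKa.
#' @examples
#' g <- global_descriptors(frontier_record("alaviroidin", -6.072, -1.700))
#' round(g$omega_minus, 3)  # 5.670
#' @export
global_descriptors <- function(k, pka_model = cdftkit::pka_model()) {
  if (inherits(k, "frontier_record")) k <- kid_energies(k)
  stopifnot(inherits(k, "kid_energies"))
  I <- k$I; A <- k$A
  chi <- (I + A) / 2
  eta <- I - A
  if (eta <= 0) stop_cdft("I <= A: hardness would be non-positive",
                          "cdft_degenerate_gap")
  omega       <- chi^2 / (2 * eta)
  omega_minus <- (3 * I + A)^2 / (16 * eta)
  omega_plus  <- (I + 3 * A)^2 / (16 * eta)
  structure(list(label = k$label, chi = chi, eta = eta, omega = omega,
                 omega_minus = omega_minus, omega_plus = omega_plus,
                 net_electrophilicity = omega_minus + omega_plus,
                 lambda_max = lambda_max(eta, round_nm = FALSE),
                 pka = predict_pka(eta, pka_model, round_2dp = FALSE)),
            class = "global_descriptors")
}

#' @export
print.global_descriptors <- function(x, ...) {
  cat(sprintf("<global_descriptors> %s (eV)\n", x$label))
  v <- c(chi = x$chi, eta = x$eta, omega = x$omega,
         `omega-` = x$omega_minus, `omega+` = x$omega_plus,
         `net` = x$net_electrophilicity)
  print(round_report(v, 3))
  cat(sprintf("  lambda_max = %d nm   pKa = %.2f\n",
              as.integer(round_report(x$lambda_max, 0)),
              round_report(x$pka, 2)))
  invisible(x)
}

#' Maximum absorption wavelength from the HOMO-LUMO gap
#'
#' Uses the ground-state gap as a proxy for the lowest excitation energy:
#' lambda = hc / gap with hc = 1239.84193 eV nm, rounded to the nearest
#' integer nanometre (the precision at which such wavelengths are quoted).
#'
#' @param gap HOMO-LUMO gap in eV; must be positive.
#' @param round_nm Round to integer nm (default TRUE).
#' @return Wavelength in nm.
#' @examples
#' lambda_max(4.372)  # 284
#' @export
lambda_max <- function(gap, round_nm = TRUE) {
  if (!is.numeric(gap) || any(!is.finite(gap)) || any(gap <= 0))
    stop_cdft("gap must be a positive finite energy in eV", "cdft_domain_error")
  lam <- cdft_constants()$hc_ev_nm / gap
  if (round_nm) round_report(lam, 0) else lam
}

#' Hardness-based pKa model
#'
#' Linear QSAR relating the pKa of small-to-medium peptides to the global
#' hardness: pKa = intercept + slope * eta. The default coefficients
#' (16.3088, -0.8268 per eV) come from a regression on peptides with known
#' experimental pKas; override them to use a different calibration.
#'
#' @param intercept Model intercept (dimensionless pKa units).
#' @param slope Slope per eV of hardness.
#' @return An object of class `pka_model`.
#' @export
pka_model <- function(intercept = 16.3088, slope = -0.8268) {
  stopifnot(is.numeric(intercept), is.numeric(slope),
            length(intercept) == 1L, length(slope) == 1L)
  structure(list(intercept = intercept, slope = slope), class = "pka_model")
}

#' Predict a pKa from global hardness
#'
#' @param eta Global hardness in eV; must be non-negative.
#' @param model A [pka_model].
#' @param round_2dp Report at 2 decimals (default TRUE), the precision at
#'   which the calibration is meaningful.
#' @return Predicted pKa (dimensionless).
#' @examples
#' predict_pka(4.372)  # 12.69
#' @export
predict_pka <- function(eta, model = pka_model(), round_2dp = TRUE) {
  if (!is.numeric(eta) || any(!is.finite(eta)) || any(eta < 0))
    stop_cdft("eta must be a non-negative finite hardness in eV", "cdft_domain_error")
  p <- model$intercept + model$slope * eta
  if (round_2dp) round_report(p, 2) else p
}

#' Koopmans-in-DFT consistency deviations against Delta-SCF energies
#'
#' Measures how well the frontier eigenvalues play the role of the vertical
#' ionization potential and electron affinity for a given functional:
#' with total energies of the N, N-1 and N+1 electron systems at the same
#' geometry, I_dSCF = E(cation) - E(neutral) and
#' A_dSCF = E(neutral) - E(anion), and the deviations are
#' J_I = |epsilon_HOMO + I_dSCF| and J_A = |epsilon_LUMO + A_dSCF|.
#' Values near zero indicate a well-behaved functional for the KID
#' approximation.
#'
#' @param record A [frontier_record].
#' @param e_neutral,e_cation,e_anion Total electronic energies in eV of the
#'   N, N-1 and N+1 electron systems at the neutral geometry.
#' @return Named list with `J_I` and `J_A` (eV, both >= 0) plus the
#'   intermediate `I_dscf` and `A_dscf`.
#' @export
kid_deviation <- function(record, e_neutral, e_cation, e_anion) {
  stopifnot(inherits(record, "frontier_record"))
  i_dscf <- e_cation - e_neutral
  a_dscf <- e_neutral - e_anion
  list(J_I = abs(record$epsilon_homo + i_dscf),
       J_A = abs(record$epsilon_lumo + a_dscf),
       I_dscf = i_dscf, A_dscf = a_dscf)
}
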