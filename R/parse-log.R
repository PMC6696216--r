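#' Parse frontier-orbital energies from a quantum-chemistry text log
#'
#' Scans a Gaussian-style log for orbital eigenvalue listings of the form
#'
#' ```
#'  Alpha  occ. eigenvalues --   -0.41234  -0.22316
#'  Alpha virt. eigenvalues --   -0.06247   0.01523
#' ```
#'
#' Optimization logs print such a listing at every step, so only the final
#' listing is used. For unrestricted (Alpha/Beta) listings the HOMO is the
#' maximum over the occupied eigenvalues of both spin channels and the LUMO
#' the minimum over both virtual sets.
#'
#' @param text Character: either a path to a log file or the log text itself
#'   (a vector of lines, or one string with embedded newlines).
#' @param unit Unit of the eigenvalues in the log: `"hartree"` (Gaussian's
#'   native unit, the default) or `"ev"`.
#' @param label Species name attached to the record.
#' @return A [frontier_record] with energies in eV, `source = "parsed"`.
#' @examples
#' log <- c(" Alpha  occ. eigenvalues --   -0.50000  -0.22316",
#'          " Alpha virt. eigenvalues --   -0.06247   0.10000")
#' parse_orbital_energies(log, unit = "hartree", label = "toy")
#' @export
parse_orbital_energies <- function(text, unit = c("hartree", "ev"),
                                   label = "molecule") {
  unit <- match.arg(unit)
  lines <- read_log_lines(text)
  pat <- "^\\s*(Alpha|Beta)?\\s*(occ\\.|virt\\.)\\s+eigenvalues\\s*--"
  hits <- grep(pat, lines)
  if (length(hits) == 0L)
    stop_cdft("no orbital eigenvalue listing found in log", "cdft_parse_error")

  # Group consecutive eigenvalue lines into listings; keep only the last.
  breaks <- c(0L, which(diff(hits) > 1L), length(hits))
  last <- hits[(breaks[length(breaks) - 1L] + 1L):length(hits)]

  occ <- numeric(0); virt <- numeric(0)
  for (ln in lines[last]) {
    vals <- as.numeric(strsplit(trimws(sub(pat, "", ln, perl = TRUE)),
                                "\\s+")[[1]])
    vals <- vals[is.finite(vals)]
    if (grepl("occ\\.", ln)) occ <- c(occ, vals) else virt <- c(virt, vals)
  }
  if (length(occ) == 0L)
    stop_cdft("orbital listing has no occupied eigenvalues", "cdft_structure_error")
  if (length(virt) == 0L)
    stop_cdft("orbital listing has no virtual eigenvalues", "cdft_structure_error")

  eh <- max(occ); el <- min(virt)
  if (unit == "hartree") { eh <- hartree_to_ev(eh); el <- hartree_to_ev(el) }
  frontier_record(label, eh, el, source = "parsed")
}

#' Atomic population table from a Mulliken analysis
#'
#' Per-atom Mulliken charges (and, for open-shell states, spin densities)
#' for one charge state of a molecule. Validation enforces the population
#' closure rules: charges sum to the net molecular charge (tolerance 1e-3)
#' and, when present, spin densities sum to the unpaired-electron count
#' (tolerance 1e-2).
#'
#' @param element Character vector of element symbols, in atom order.
#' @param mulliken_charge Numeric vector of Mulliken charges, electrons.
#' @param spin_density Optional numeric vector of Mulliken spin densities.
#' @param charge_state Integer net charge relative to neutral (-1, 0, +1, ...).
#' @param multiplicity_hint Integer spin multiplicity (2S+1); the expected
#'   spin-density sum is `multiplicity_hint - 1`.
#' @param atom_index Optional explicit 1-based atom indices (default 1..n).
#' @return An object of class `population_table` (a data.frame with
#'   attributes `charge_state` and `multiplicity_hint`).
#' @export
population_table <- function(element, mulliken_charge, spin_density = NULL,
                             charge_state = 0L, multiplicity_hint = 1L,
                             atom_index = seq_along(element)) {
  n <- length(element)
  if (n < 1L) stop_cdft("population table needs at least one atom", "cdft_value_error")
  if (length(mulliken_charge) != n)
    stop_cdft("charge column length does not match atom count", "cdft_structure_error")
  atom_index <- as.integer(atom_index)
  if (anyDuplicated(atom_index) || !identical(atom_index, seq_len(n)))
    stop_cdft("atom indices must be contiguous 1..n without duplicates or gaps",
              "cdft_structure_error")
  csum <- sum(mulliken_charge)
  if (abs(csum - charge_state) > 1e-3)
    stop_cdft(sprintf(
      "Mulliken charges sum to %.6f but the declared net charge is %+d (deviation %.2e)",
      csum, as.integer(charge_state), abs(csum - charge_state)),
      "cdft_validation_error")
  df <- data.frame(atom_index = atom_index, element = as.character(element),
                   mulliken_charge = as.numeric(mulliken_charge),
                   stringsAsFactors = FALSE)
  if (!is.null(spin_density)) {
    if (length(spin_density) != n)
      stop_cdft("spin-density column length does not match atom count",
                "cdft_structure_error")
    unpaired <- multiplicity_hint - 1L
    ssum <- sum(spin_density)
    if (abs(ssum - unpaired) > 1e-2)
      warning(sprintf(
        "spin densities sum to %.4f; expected %d unpaired electron(s)",
        ssum, unpaired))
    df$spin_density <- as.numeric(spin_density)
  }
  structure(df, class = c("population_table", "data.frame"),
            charge_state = as.integer(charge_state),
            multiplicity_hint = as.integer(multiplicity_hint))
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table> %d atoms, net charge %+d, multiplicity %d%s\n",
              nrow(x), attr(x, "charge_state"), attr(x, "multiplicity_hint"),
              if ("spin_density" %in% names(x)) ", with spin densities" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Parse a Mulliken population block from a quantum-chemistry text log
#'
#' Reads the last `Mulliken charges:` or
#' `Mulliken charges and spin densities:` block from a Gaussian-style log.
#' Atom order in the text is preserved; indices must be contiguous from 1.
#'
#' @inheritParams parse_orbital_energies
#' @param charge_state Declared net charge of this calculation; the parsed
#'   charges must sum to it within 1e-3.
#' @param multiplicity_hint Spin multiplicity used to validate the
#'   spin-density sum when that column is present.
#' @return A [population_table].
#' @export
parse_mulliken_table <- function(text, charge_state = 0L,
                                 multiplicity_hint = 1L) {
  lines <- read_log_lines(text)
  heads <- grep("^\\s*Mulliken charges( and spin densities)?:\\s*$", lines)
  if (length(heads) == 0L)
    stop_cdft("no Mulliken charges block found in log", "cdft_parse_error")
  start <- heads[length(heads)]
  with_spin <- grepl("spin densities", lines[start])

  rows <- list(); i <- start + 1L
  atom_pat <- "^\\s*(\\d+)\\s+([A-Za-z]{1,2})\\s+(-?\\d*\\.\\d+)(\\s+(-?\\d*\\.\\d+))?\\s*$"
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl(atom_pat, ln)) {
      m <- regmatches(ln, regexec(atom_pat, ln))[[1]]
      rows[[length(rows) + 1L]] <- list(idx = as.integer(m[2]), el = m[3],
                                        q = as.numeric(m[4]),
                                        s = if (nzchar(m[5])) as.numeric(m[6]) else NA_real_)
    } else if (length(rows) > 0L) break   # column-header lines precede atoms
    i <- i + 1L
  }
  if (length(rows) == 0L)
    stop_cdft("Mulliken block contains no atom rows", "cdft_parse_error")

  idx <- vapply(rows, `[[`, integer(1), "idx")
  if (anyDuplicated(idx) || !identical(idx, seq_along(idx)))
    stop_cdft(sprintf(
      "Mulliken block has duplicate or gapped atom indices (saw %s...)",
      paste(utils::head(idx, 5), collapse = ", ")), "cdft_structure_error")

  spin <- vapply(rows, `[[`, numeric(1), "s")
  population_table(
    element          = vapply(rows, `[[`, character(1), "el"),
    mulliken_charge  = vapply(rows, `[[`, numeric(1), "q"),
    spin_density     = if (with_spin && !anyNA(spin)) spin else NULL,
    charge_state     = charge_state,
    multiplicity_hint = multiplicity_hint)
}

# Accept a file path, a single string with newlines, or a character vector
# of lines.
read_log_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  as.character(text)
}
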