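#' Specification for synthetic quantum-chemistry outputs
#'
#' Describes one mock molecule from which [make_mock_log()] and
#' [make_mock_cubes()] generate parser-ready artifacts with planted ground
#' truth. Generation is seed-deterministic: the same spec produces
#' byte-identical output.
#'
#' @param seed Integer RNG seed.
#' @param n_atoms Number of atoms (>= 1).
#' @param net_charge Net charge of the neutral-reference state (usually 0);
#'   the radical cation/anion states are `net_charge + 1` / `net_charge - 1`.
#' @param unpaired Unpaired electrons in each radical state (>= 0; 1 for
#'   doublets).
#' @param homo,lumo Target frontier energies in eV planted in the orbital
#'   listing; must satisfy `homo < lumo`.
#' @param planted_offsets Length-2 numeric: the KID deviations (J_I, J_A)
#'   in eV that [mock_scf_energies()] plants in its total-energy triple.
#' @param n_grid Grid points per axis for mock cubes.
#' @param box Cube edge length in Bohr.
#' @param sigma Width (Bohr) of the Gaussian densities in mock cubes;
#'   must be positive.
#' @return An object of class `mock_spec`.
#' @export
mock_spec <- function(seed = 1L, n_atoms = 12L, net_charge = 0L,
                      unpaired = 1L, homo = -6.0, lumo = -1.5,
                      planted_offsets = c(0.1, 0.05),
                      n_grid = 20L, box = 12, sigma = 1.2) {
  if (n_atoms < 1L) stop_cdft("n_atoms must be at least 1", "cdft_spec_error")
  if (homo >= lumo) stop_cdft("mock HOMO must lie below mock LUMO", "cdft_spec_error")
  if (sigma <= 0 || box <= 0 || n_grid < 2L)
    stop_cdft("mock grid must have positive extent and width", "cdft_spec_error")
  if (unpaired < 0L) stop_cdft("unpaired electron count cannot be negative",
                               "cdft_spec_error")
  structure(list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
                 net_charge = as.integer(net_charge),
                 unpaired = as.integer(unpaired),
                 homo = homo, lumo = lumo,
                 planted_offsets = as.numeric(planted_offsets),
                 n_grid = as.integer(n_grid), box = box, sigma = sigma),
            class = "mock_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
          else assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  code
}

# round to 6 printed decimals and repair the last entry so the printed
# column sums exactly to `total`
exact_sum <- function(x, total) {
  x <- round(x, 6)
  x[length(x)] <- round(total - sum(x[-length(x)]), 6)
  x
}

#' Generate mock Gaussian-style logs for the three charge states
#'
#' Emits three log texts (neutral, radical cation, radical anion) that the
#' toolkit's own parsers accept without warnings. The neutral log carries
#' two orbital listings (an intermediate one and a final one, so the
#' last-listing rule is exercised) whose final HOMO/LUMO round-trip to the
#' spec's targets within the 1e-5 Hartree print precision, plus a plain
#' Mulliken charges block. The radical logs carry combined
#' charges-and-spin-densities blocks. Printed charge columns sum exactly
#' to each state's net charge and spin columns exactly to the unpaired
#' count, so condensed Fukui sums over the triple equal 1 by construction.
#'
#' @param spec A [mock_spec].
#' @return Named list of class `mock_logs` with character-vector elements
#'   `neutral`, `cation`, `anion`.
#' @export
make_mock_log <- function(spec) {
  stopifnot(inherits(spec, "mock_spec"))
  with_seed(spec$seed, {
    n <- spec$n_atoms
    elements <- sample(c("C", "N", "O", "H", "S"), n, replace = TRUE)

    q_n <- exact_sum(stats::rnorm(n, 0, 0.3), spec$net_charge)
    hole <- abs(stats::rnorm(n)); hole <- hole / sum(hole)   # removed electron
    gain <- abs(stats::rnorm(n)); gain <- gain / sum(gain)   # added electron
    q_c <- exact_sum(q_n + hole, spec$net_charge + 1L)
    q_a <- exact_sum(q_n - gain, spec$net_charge - 1L)
    raw_c <- abs(stats::rnorm(n)); raw_a <- abs(stats::rnorm(n))
    s_c <- exact_sum(spec$unpaired * raw_c / sum(raw_c), spec$unpaired)
    s_a <- exact_sum(spec$unpaired * raw_a / sum(raw_a), spec$unpaired)

    homo_ha <- ev_to_hartree(spec$homo); lumo_ha <- ev_to_hartree(spec$lumo)
    occ  <- sort(c(homo_ha - cumsum(abs(stats::rnorm(4, 0.15, 0.05))), homo_ha))
    virt <- sort(c(lumo_ha, lumo_ha + cumsum(abs(stats::rnorm(4, 0.12, 0.04)))))
    listing <- function(occ, virt) c(
      sprintf(" Alpha  occ. eigenvalues -- %s", paste(sprintf("%10.5f", occ), collapse = "")),
      sprintf(" Alpha virt. eigenvalues -- %s", paste(sprintf("%10.5f", virt), collapse = "")))

    charges_block <- function(q, s = NULL, net = 0L) {
      head <- if (is.null(s)) " Mulliken charges:" else " Mulliken charges and spin densities:"
      cols <- if (is.null(s)) "               1" else "               1          2"
      rows <- if (is.null(s))
        sprintf("%6d  %-2s  %10.6f", seq_len(n), elements, q)
      else
        sprintf("%6d  %-2s  %10.6f  %10.6f", seq_len(n), elements, q, s)
      c(head, cols, rows,
        sprintf(" Sum of Mulliken charges = %10.5f", sum(q)))
    }

    preamble <- c(" Entering Gaussian System",
                  sprintf(" Mock species with %d atoms, seed %d", n, spec$seed))
    logs <- list(
      neutral = c(preamble,
                  listing(occ + 0.01, virt + 0.01),   # intermediate step
                  " SCF Done (intermediate)",
                  listing(occ, virt),
                  charges_block(q_n, net = spec$net_charge)),
      cation  = c(preamble,
                  listing(occ - 0.02, virt - 0.02),
                  charges_block(q_c, s_c, spec$net_charge + 1L)),
      anion   = c(preamble,
                  listing(occ + 0.02, virt + 0.02),
                  charges_block(q_a, s_a, spec$net_charge - 1L)))
    structure(logs, class = "mock_logs")
  })
}

#' Total-energy triple with planted Koopmans deviations
#'
#' Constructs Delta-SCF-style total energies of the N, N-1 and N+1 electron
#' systems such that [kid_deviation()] recovers exactly the spec's
#' `planted_offsets` (absolute values): the cation energy is offset from
#' Koopmans-consistency by J_I and the anion energy by J_A.
#'
#' @param record A [frontier_record] for the species.
#' @param offsets Length-2 numeric `(J_I, J_A)` in eV.
#' @param e_neutral Baseline total energy in eV.
#' @return Named list `e_neutral`, `e_cation`, `e_anion`.
#' @export
mock_scf_energies <- function(record, offsets = c(0.1, 0.05),
                              e_neutral = -1e4) {
  stopifnot(inherits(record, "frontier_record"), length(offsets) == 2L)
  list(e_neutral = e_neutral,
       e_cation  = e_neutral - record$epsilon_homo + offsets[1],
       e_anion   = e_neutral + record$epsilon_lumo - offsets[2])
}

#' Generate congruent mock electron-density cubes for the three states
#'
#' Builds three scalar fields of sums of isotropic Gaussians on one grid:
#' a neutral density rho_N, a cation density rho_N minus one normalized
#' Gaussian (one electron removed) and an anion density rho_N plus one
#' normalized Gaussian. The Fukui-field integrals over the triple are
#' therefore analytically 1; with the default 20-point, 12-Bohr grid and
#' sigma 1.2 Bohr the grid quadrature agrees well within 1e-2.
#'
#' @param spec A [mock_spec].
#' @return Named list of [scalar_field]s: `rho_n`, `rho_nm1`, `rho_np1`.
#' @export
make_mock_cubes <- function(spec) {
  stopifnot(inherits(spec, "mock_spec"))
  with_seed(spec$seed + 1L, {
    n <- spec$n_grid; h <- spec$box / (n - 1); half <- spec$box / 2
    origin <- rep(-half, 3)
    axes <- diag(h, 3)
    ax <- origin[1] + h * (seq_len(n) - 1)
    X <- rep(ax, each = n * n)
    Y <- rep(rep(ax, each = n), n)
    Z <- rep(ax, n * n)

    gauss <- function(center, sigma) {
      norm <- (2 * pi * sigma^2)^(-1.5)
      norm * exp(-((X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2) /
                   (2 * sigma^2))
    }
    centers <- matrix(stats::runif(9, -half / 3, half / 3), 3, 3)
    rho_n <- 2 * gauss(centers[1, ], spec$sigma) +
             3 * gauss(centers[2, ], spec$sigma * 1.2) +
             1 * gauss(centers[3, ], spec$sigma)
    hole <- gauss(stats::runif(3, -half / 4, half / 4), spec$sigma)
    gain <- gauss(stats::runif(3, -half / 4, half / 4), spec$sigma)

    atoms <- data.frame(number = 6L, charge = 6,
                        x = centers[, 1], y = centers[, 2], z = centers[, 3])
    mk <- function(v) scalar_field(origin, axes, rep(n, 3), v, atoms)
    list(rho_n = mk(rho_n), rho_nm1 = mk(rho_n - hole), rho_np1 = mk(rho_n + gain))
  })
}
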