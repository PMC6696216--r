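#' Condensed Fukui functions from Mulliken charges of three charge states
#'
#' Finite-difference condensation of the Fukui function onto atoms, in
#' terms of Mulliken atomic charges q_k of the N, N-1 and N+1 electron
#' systems at the neutral geometry:
#' \deqn{f_k^- = q_k(N-1) - q_k(N), \qquad f_k^+ = q_k(N) - q_k(N+1).}
#' For single-electron differences each column sums to 1 (charge
#' conservation); the sums are validated to 1e-3 and a violation raises a
#' loud error, since it indicates misaligned or non-closing inputs.
#'
#' @param neutral,cation,anion [population_table]s for charge states
#'   0, +1 and -1 of the same geometry, with identical atom ordering.
#' @return A `site_table`: a data.frame with columns `atom_index`,
#'   `element`, `f_plus`, `f_minus`.
#' @examples
#' n <- population_table(c("O","C","H"), c(0.0, 0.2, -0.2), charge_state = 0)
#' c1 <- population_table(c("O","C","H"), c(0.5, 0.4, 0.1), charge_state = 1)
#' a1 <- population_table(c("O","C","H"), c(-0.6, 0.0, -0.4), charge_state = -1)
#' condensed_fukui(n, c1, a1)
#' @export
condensed_fukui <- function(neutral, cation, anion) {
  align_tables(neutral, cation, anion)
  f_minus <- cation$mulliken_charge - neutral$mulliken_charge
  f_plus  <- neutral$mulliken_charge - anion$mulliken_charge
  sp <- sum(f_plus); sm <- sum(f_minus)
  dq_c <- attr(neutral, "charge_state") - attr(cation, "charge_state")
  dq_a <- attr(anion, "charge_state") - attr(neutral, "charge_state")
  # single-electron differences must integrate to one electron each
  if (dq_c == -1L && abs(sm - 1) > 1e-3)
    stop_cdft(sprintf("condensed f- sums to %.6f, not 1: charge states do not close", sm),
              "cdft_validation_error")
  if (dq_a == -1L && abs(sp - 1) > 1e-3)
    stop_cdft(sprintf("condensed f+ sums to %.6f, not 1: charge states do not close", sp),
              "cdft_validation_error")
  site_table(data.frame(atom_index = neutral$atom_index,
                        element = neutral$element,
                        f_plus = f_plus, f_minus = f_minus,
                        stringsAsFactors = FALSE))
}

#' Condensed dual descriptor
#'
#' Adds the condensed dual descriptor to a site table:
#' \eqn{\Delta f_k = f_k^+ - f_k^-}, positive where nucleophilic attack is
#' preferred and negative where electrophilic attack is preferred. The
#' `dual_scaled` column holds 100 x dual, the conventional reporting scale;
#' stored `dual` values remain unscaled.
#'
#' @param table A `site_table` with `f_plus`/`f_minus` columns (from
#'   [condensed_fukui()]).
#' @return The table with `dual` and `dual_scaled` columns added.
#' @export
dual_descriptor <- function(table) {
  stopifnot(inherits(table, "site_table"))
  if (!all(c("f_plus", "f_minus") %in% names(table)))
    stop_cdft("site table lacks Fukui columns; run condensed_fukui() first",
              "cdft_data_error")
  table$dual <- table$f_plus - table$f_minus
  table$dual_scaled <- 100 * table$dual
  table
}

#' Parr functions from radical-ion spin densities
#'
#' The electrophilic Parr function P-_k is the Mulliken atomic spin density
#' of atom k in the radical cation; the nucleophilic Parr function P+_k is
#' the spin density in the radical anion. Values are taken as-is (no
#' renormalization); each column should sum to the unpaired-electron count
#' of its radical, and deviations beyond 1e-2 warn.
#'
#' @param cation,anion [population_table]s of the radical cation and anion
#'   carrying spin-density columns.
#' @param table Optional existing `site_table` to merge the columns into.
#' @return A `site_table` with `parr_plus` and `parr_minus` columns.
#' @export
parr_functions <- function(cation, anion, table = NULL) {
  for (nm in c("cation", "anion")) {
    t <- get(nm)
    if (!inherits(t, "population_table") || !"spin_density" %in% names(t))
      stop_cdft(sprintf("%s table carries no spin-density column", nm),
                "cdft_data_error")
  }
  align_tables(cation, anion)
  for (nm in c("cation", "anion")) {
    t <- get(nm)
    unpaired <- attr(t, "multiplicity_hint") - 1L
    if (abs(sum(t$spin_density) - unpaired) > 1e-2)
      warning(sprintf("%s spin densities sum to %.4f, expected %d",
                      nm, sum(t$spin_density), unpaired))
  }
  out <- data.frame(atom_index = cation$atom_index, element = cation$element,
                    parr_plus = anion$spin_density,
                    parr_minus = cation$spin_density,
                    stringsAsFactors = FALSE)
  if (is.null(table)) return(site_table(out))
  align_tables(table, cation)
  table$parr_plus <- out$parr_plus
  table$parr_minus <- out$parr_minus
  table
}

#' Per-atom local reactivity table
#'
#' Thin data.frame subclass holding condensed local descriptors; columns
#' grow as [condensed_fukui()], [dual_descriptor()] and [parr_functions()]
#' are applied.
#'
#' @param df A data.frame with at least `atom_index` and `element`.
#' @return The data.frame with class `site_table` prepended.
#' @export
site_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("atom_index", "element") %in% names(df)))
  df$atom_index <- as.integer(df$atom_index)
  class(df) <- unique(c("site_table", class(df)))
  df
}

#' Rank reactive sites from a local-descriptor table
#'
#' In `"dual"` mode returns the atom with the most positive dual descriptor
#' (preferred site for nucleophilic attack) and the most negative (preferred
#' for electrophilic attack). In `"parr"` mode returns the argmax of
#' `parr_plus` and of `parr_minus` respectively. Ties break to the lowest
#' atom index; an all-zero column is flagged degenerate.
#'
#' @param table A `site_table` with the relevant columns.
#' @param mode `"dual"` or `"parr"`.
#' @return List with `nucleophilic` and `electrophilic` one-row data.frames,
#'   plus a logical `degenerate`.
#' @export
rank_sites <- function(table, mode = c("dual", "parr")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "site_table"))
  cols <- if (mode == "dual") c("dual", "dual") else c("parr_plus", "parr_minus")
  if (!all(unique(cols) %in% names(table)))
    stop_cdft(sprintf("site table lacks the %s column(s) needed for mode '%s'",
                      paste(unique(cols), collapse = "/"), mode), "cdft_data_error")
  pick <- function(v, decreasing) {
    # which.max on (v, -atom_index) with deterministic low-index tie-break
    target <- if (decreasing) max(v) else min(v)
    idx <- which(v == target)
    idx[which.min(table$atom_index[idx])]
  }
  if (mode == "dual") {
    nu <- pick(table$dual, TRUE); el <- pick(table$dual, FALSE)
    degenerate <- all(table$dual == 0)
  } else {
    nu <- pick(table$parr_plus, TRUE); el <- pick(table$parr_minus, TRUE)
    degenerate <- all(table$parr_plus == 0) || all(table$parr_minus == 0)
  }
  list(nucleophilic = as.data.frame(table)[nu, , drop = FALSE],
       electrophilic = as.data.frame(table)[el, , drop = FALSE],
       degenerate = degenerate)
}

#' Volumetric Fukui function from two electron-density grids
#'
#' Pointwise density differences on congruent cube grids:
#' f-(r) = rho_N(r) - rho_(N-1)(r) and f+(r) = rho_(N+1)(r) - rho_N(r).
#' For `kind = "minus"` pass the neutral density as `rho_ref` and the
#' cation density as `rho_other`; for `kind = "plus"` pass the anion
#' density as `rho_ref` and the neutral as `rho_other`. Either way the
#' result is ref - other and its grid integral should be close to 1
#' (one electron) for well-resolved grids.
#'
#' @param rho_ref,rho_other [scalar_field]s on congruent grids (origin,
#'   axes and counts equal within 1e-6).
#' @param kind `"plus"` or `"minus"` (recorded as an attribute).
#' @return A [scalar_field] of the difference, with attributes `kind` and
#'   `integral` (the grid-quadrature integral).
#' @export
fukui_field <- function(rho_ref, rho_other, kind = c("plus", "minus")) {
  kind <- match.arg(kind)
  stopifnot(inherits(rho_ref, "scalar_field"), inherits(rho_other, "scalar_field"))
  bad <- grid_mismatch(rho_ref, rho_other)
  if (!is.null(bad))
    stop_cdft(sprintf("grids are not congruent: header field '%s' differs", bad),
              "cdft_grid_mismatch")
  out <- scalar_field(rho_ref$origin, rho_ref$axes, rho_ref$counts,
                      rho_ref$values - rho_other$values, rho_ref$atoms)
  attr(out, "kind") <- kind
  attr(out, "integral") <- field_integral(out)
  out
}

# All tables must share atom count, ordering and element sequence.
align_tables <- function(...) {
  ts <- list(...)
  ref <- ts[[1]]
  for (t in ts[-1]) {
    if (nrow(t) != nrow(ref))
      stop_cdft(sprintf("atom-count mismatch: %d vs %d atoms", nrow(ref), nrow(t)),
                "cdft_alignment_error")
    diff <- which(t$element != ref$element)
    if (length(diff) > 0L)
      stop_cdft(sprintf(
        "element sequence mismatch at atom %d: '%s' vs '%s'",
        ref$atom_index[diff[1]], ref$element[diff[1]], t$element[diff[1]]),
        "cdft_alignment_error")
  }
  invisible(TRUE)
}
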