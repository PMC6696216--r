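#' Format one descriptor set at table precision
#'
#' Rounds a [global_descriptors] object to the conventional reporting
#' precision: energies and descriptors at 3 decimals, the wavelength at
#' integer nm, the pKa at 2 decimals (round-half-to-even). Stored objects
#' keep full precision; this is a display/export convention only.
#'
#' @param g A [global_descriptors] object.
#' @return One-row data.frame in published column order.
#' @export
format_descriptor_row <- function(g) {
  stopifnot(inherits(g, "global_descriptors"))
  data.frame(molecule = g$label,
             chi = round_report(g$chi, 3),
             eta = round_report(g$eta, 3),
             omega = round_report(g$omega, 3),
             omega_minus = round_report(g$omega_minus, 3),
             omega_plus = round_report(g$omega_plus, 3),
             net_electrophilicity = round_report(g$net_electrophilicity, 3),
             lambda_max = as.integer(round_report(g$lambda_max, 0)),
             pka = round_report(g$pka, 2),
             stringsAsFactors = FALSE)
}

#' Run the global-descriptor pipeline over a set of inputs
#'
#' Accepts frontier-orbital records from JSON documents (`*.json`),
#' Gaussian-style logs (any other extension; eigenvalues assumed in
#' Hartree) or in-memory [frontier_record] objects, computes every global
#' descriptor for each species, and assembles a report. Species whose
#' input fails (unreadable file, degenerate gap) become error entries; the
#' run only fails outright when no species succeeds.
#'
#' @param inputs Character vector of file paths, a [frontier_record], or a
#'   list of records.
#' @param pka_model A [pka_model].
#' @param hc Photon energy-wavelength product, eV nm.
#' @return An object of class `descriptor_report`: list with `rows`
#'   (data.frame at reporting precision), `full` (list of
#'   [global_descriptors] at full precision), `errors` (data.frame of
#'   per-species failures) and `metadata` (constants actually applied).
#' @examples
#' rep <- run_global(load_virotoxin_fixtures()$records)
#' rep$rows
#' @export
run_global <- function(inputs, pka_model = cdftkit::pka_model(),
                       hc = cdft_constants()$hc_ev_nm) {
  records <- collect_records(inputs)
  full <- list(); errs <- list()
  for (r in records) {
    if (inherits(r, "cdft_input_error")) { errs[[length(errs) + 1L]] <- r; next }
    g <- tryCatch(global_descriptors(r, pka_model = pka_model),
                  cdft_error = function(e)
                    structure(list(label = r$label, message = conditionMessage(e)),
                              class = "cdft_input_error"))
    if (inherits(g, "cdft_input_error")) { errs[[length(errs) + 1L]] <- g; next }
    g$lambda_max <- hc / g$eta   # honor a configured hc
    full[[g$label]] <- g
  }
  if (length(full) == 0L)
    stop_cdft("no valid species: every input failed", "cdft_io_error")
  rows <- do.call(rbind, lapply(full, format_descriptor_row))
  rownames(rows) <- NULL
  errors <- if (length(errs) == 0L)
    data.frame(molecule = character(0), message = character(0))
  else data.frame(molecule = vapply(errs, `[[`, character(1), "label"),
                  message = vapply(errs, `[[`, character(1), "message"))
  structure(list(rows = rows, full = full, errors = errors,
                 metadata = list(
                   toolkit = as.character(utils::packageVersion("cdftkit")),
                   ev_per_hartree = cdft_constants()$ev_per_hartree,
                   hc_ev_nm = hc,
                   pka_intercept = pka_model$intercept,
                   pka_slope = pka_model$slope,
                   n_inputs = length(records))),
            class = "descriptor_report")
}

#' @export
print.descriptor_report <- function(x, ...) {
  cat(sprintf("<descriptor_report> %d species, %d error(s)\n",
              nrow(x$rows), nrow(x$errors)))
  print(x$rows)
  if (nrow(x$errors) > 0) { cat("errors:\n"); print(x$errors) }
  invisible(x)
}

#' Write a descriptor report to CSV or JSON
#'
#' The CSV column order is stable (`molecule`, `chi`, `eta`, `omega`,
#' `omega_minus`, `omega_plus`, `net_electrophilicity`, `lambda_max`,
#' `pka`) and is a machine-consumable contract; JSON output additionally
#' carries the metadata block with every constant applied.
#'
#' @param report A `descriptor_report`.
#' @param path Output path; format chosen by extension (`.json` or CSV
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "descriptor_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(list(rows = report$rows, errors = report$errors,
                              metadata = report$metadata),
                         path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  else
    utils::write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}

#' Run the local-descriptor pipeline for one molecule
#'
#' Parses the Mulliken populations of the neutral, radical-cation and
#' radical-anion logs, builds the condensed Fukui functions and dual
#' descriptor, attaches Parr functions when both radical logs carry spin
#' densities, ranks the extreme sites, and (optionally) forms volumetric
#' Fukui fields from a density-cube triple.
#'
#' @param neutral,cation,anion Log paths or texts for charge states
#'   0 / +1 / -1 (radicals as doublets by default).
#' @param cubes Optional character vector of three cube paths
#'   (neutral, cation, anion densities) for the volumetric fields.
#' @param multiplicities Integer vector of the three spin multiplicities.
#' @return List of class `site_report`: `sites` (full `site_table`),
#'   `extremes` (from [rank_sites()], dual mode), `parr_extremes` (when
#'   spin data present), `sums` (the conservation checks) and
#'   `field_integrals` (when cubes given).
#' @export
run_local <- function(neutral, cation, anion, cubes = NULL,
                      multiplicities = c(1L, 2L, 2L)) {
  tn <- parse_mulliken_table(neutral, charge_state = 0L,
                             multiplicity_hint = multiplicities[1])
  tc <- parse_mulliken_table(cation, charge_state = 1L,
                             multiplicity_hint = multiplicities[2])
  ta <- parse_mulliken_table(anion, charge_state = -1L,
                             multiplicity_hint = multiplicities[3])
  sites <- dual_descriptor(condensed_fukui(tn, tc, ta))
  have_spin <- all(c("spin_density" %in% names(tc), "spin_density" %in% names(ta)))
  if (have_spin) sites <- parr_functions(tc, ta, table = sites)
  out <- list(sites = sites,
              extremes = rank_sites(sites, "dual"),
              parr_extremes = if (have_spin) rank_sites(sites, "parr"),
              sums = c(f_plus = sum(sites$f_plus), f_minus = sum(sites$f_minus),
                       dual = sum(sites$dual)))
  if (!is.null(cubes)) {
    if (length(cubes) != 3L)
      stop_cdft("cubes must name three files: neutral, cation, anion densities",
                "cdft_io_error")
    rn <- read_cube(cubes[1]); rc <- read_cube(cubes[2]); ra <- read_cube(cubes[3])
    fm <- fukui_field(rn, rc, "minus")
    fp <- fukui_field(ra, rn, "plus")
    out$field_integrals <- c(f_minus = attr(fm, "integral"),
                             f_plus = attr(fp, "integral"))
    out$fields <- list(f_minus = fm, f_plus = fp)
  }
  class(out) <- "site_report"
  out
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("<site_report> %d atoms  sum f+ = %.4f  sum f- = %.4f  sum dual = %.2e\n",
              nrow(x$sites), x$sums["f_plus"], x$sums["f_minus"], x$sums["dual"]))
  nu <- x$extremes$nucleophilic; el <- x$extremes$electrophilic
  cat(sprintf("  nucleophilic-attack site: %d %s (dual x100 = %.2f)\n",
              nu$atom_index, nu$element, 100 * nu$dual))
  cat(sprintf("  electrophilic-attack site: %d %s (dual x100 = %.2f)\n",
              el$atom_index, el$element, 100 * el$dual))
  if (!is.null(x$field_integrals))
    cat(sprintf("  field integrals: f- %.4f  f+ %.4f\n",
                x$field_integrals["f_minus"], x$field_integrals["f_plus"]))
  invisible(x)
}

#' Write a site table to CSV
#'
#' Columns follow the published local-descriptor layout:
#' `atom_index`, `element`, `f_plus`, `f_minus`, `dual_scaled`,
#' `parr_plus`, `parr_minus` (those present).
#'
#' @param sites A `site_table` (or `site_report`, whose table is used).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_csv <- function(sites, path) {
  if (inherits(sites, "site_report")) sites <- sites$sites
  order <- intersect(c("atom_index", "element", "f_plus", "f_minus",
                       "dual_scaled", "parr_plus", "parr_minus"), names(sites))
  utils::write.csv(as.data.frame(sites)[, order], path, row.names = FALSE)
  invisible(path)
}

# Resolve mixed inputs into a list of frontier_records; failures become
# cdft_input_error stubs so callers can report partial failures.
collect_records <- function(inputs) {
  if (inherits(inputs, "frontier_record")) return(list(inputs))
  if (is.list(inputs) && all(vapply(inputs, inherits, logical(1), "frontier_record")))
    return(inputs)
  if (!is.character(inputs))
    stop_cdft("inputs must be file paths or frontier_record objects", "cdft_io_error")
  out <- list()
  stub <- function(label, e)
    structure(list(label = label, message = conditionMessage(e)),
              class = "cdft_input_error")
  for (p in inputs) {
    if (grepl("\\.json$", p, ignore.case = TRUE)) {
      # keep failures record-local: one bad record must not sink the file
      doc <- tryCatch({
        d <- jsonlite::fromJSON(p, simplifyVector = FALSE)
        if (!is.null(d$label)) d <- list(d)
        if (length(d) == 0L)
          stop_cdft(sprintf("'%s' contains no records", p), "cdft_io_error")
        d
      }, error = function(e) e)
      if (inherits(doc, "error")) { out <- c(out, list(stub(p, doc))); next }
      res <- lapply(doc, function(r) tryCatch({
        unit <- tolower(r$unit %||% "ev")
        eh <- as.numeric(r$epsilon_homo); el <- as.numeric(r$epsilon_lumo)
        if (unit == "hartree") { eh <- hartree_to_ev(eh); el <- hartree_to_ev(el) }
        frontier_record(r$label, eh, el, source = r$source %||% "parsed")
      }, error = function(e) stub(r$label %||% p, e)))
    } else {
      res <- list(tryCatch(
        parse_orbital_energies(p, unit = "hartree",
                               label = sub("\\.[^.]*$", "", basename(p))),
        error = function(e) stub(p, e)))
    }
    out <- c(out, res)
  }
  out
}
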