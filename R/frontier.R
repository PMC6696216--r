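#' Frontier-orbital energy record
#'
#' Holds the HOMO and LUMO eigenvalues of one species in eV, the input to
#' every global reactivity descriptor. The gap must be strictly positive:
#' a degenerate or inverted gap makes the quadratic descriptors undefined.
#'
#' @param label Species name.
#' @param epsilon_homo HOMO energy, eV.
#' @param epsilon_lumo LUMO energy, eV.
#' @param source Provenance tag: `"parsed"`, `"fixture"` or `"synthetic"`.
#' @return An object of class `frontier_record`.
#' @examples
#' frontier_record("alaviroidin", -6.072, -1.700, source = "fixture")
#' @export
frontier_record <- function(label, epsilon_homo, epsilon_lumo,
                            source = c("parsed", "fixture", "synthetic")) {
  source <- match.arg(source)
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop_cdft("'label' must be a non-empty string", "cdft_value_error")
  eh <- as.numeric(epsilon_homo); el <- as.numeric(epsilon_lumo)
  if (length(eh) != 1L || length(el) != 1L || !is.finite(eh) || !is.finite(el))
    stop_cdft("frontier energies must be single finite numbers", "cdft_value_error")
  if (eh >= el)
    stop_cdft(sprintf(
      "degenerate or inverted frontier gap for '%s': HOMO %.6g >= LUMO %.6g",
      label, eh, el), "cdft_degenerate_gap")
  structure(list(label = label, epsilon_homo = eh, epsilon_lumo = el,
                 source = source),
            class = "frontier_record")
}

#' @export
print.frontier_record <- function(x, ...) {
  cat(sprintf("<frontier_record> %s  HOMO %.3f eV  LUMO %.3f eV  gap %.3f eV  [%s]\n",
              x$label, x$epsilon_homo, x$epsilon_lumo,
              x$epsilon_lumo - x$epsilon_homo, x$source))
  invisible(x)
}

#' Read frontier-orbital records from a JSON document
#'
#' The document is either one object or an array of objects with fields
#' `label`, `epsilon_homo`, `epsilon_lumo` and optionally `unit`
#' (`"ev"`, the default, or `"hartree"`).
#'
#' @param path Path to a JSON file.
#' @return A list of [frontier_record] objects.
#' @export
read_frontier_json <- function(path) {
  if (!file.exists(path))
    stop_cdft(sprintf("cannot read records: no file at '%s'", path), "cdft_io_error")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$label)) doc <- list(doc)   # single object
  if (length(doc) == 0L)
    stop_cdft(sprintf("'%s' contains no records", path), "cdft_io_error")
  lapply(doc, function(r) {
    unit <- tolower(r$unit %||% "ev")
    eh <- as.numeric(r$epsilon_homo); el <- as.numeric(r$epsilon_lumo)
    if (unit == "hartree") { eh <- hartree_to_ev(eh); el <- hartree_to_ev(el) }
    else if (unit != "ev")
      stop_cdft(sprintf("unknown unit '%s' in record '%s'", unit, r$label %||% "?"),
                "cdft_value_error")
    frontier_record(r$label, eh, el, source = r$source %||% "parsed")
  })
}

#' Write frontier-orbital records to JSON
#'
#' @param records A list of [frontier_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frontier_json <- function(records, path) {
  if (inherits(records, "frontier_record")) records <- list(records)
  rows <- lapply(records, function(r)
    list(label = r$label, epsilon_homo = r$epsilon_homo,
         epsilon_lumo = r$epsilon_lumo, unit = "ev", source = r$source))
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
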