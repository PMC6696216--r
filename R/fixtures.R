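#' Bundled virotoxin reference fixtures
#'
#' Loads the packaged reference data for the five virotoxin peptides of
#' *Amanita virosa* (alaviroidin, deoxoviroidin, deoxoviroisin, viroidin,
#' viroisin): frontier-orbital energies, the published global-descriptor
#' and pKa values they imply, and the extreme-site local-descriptor blocks.
#' These serve as ground truth for regression tests and as a worked input
#' set for the command-line tools.
#'
#' The pKa table's residue-style row labels (FAR, FAY, ...) do not name the
#' peptides; the bundle stores the labels verbatim together with the
#' hardness-verified row mapping rather than silently repairing them.
#'
#' @return An object of class `fixture_bundle`: list with
#'   \describe{
#'     \item{records}{named list of five [frontier_record]s (`source = "fixture"`)}
#'     \item{expected}{named list of published per-molecule values
#'       (`gap`, `lambda_max`, `chi`, `eta`, `omega`, `omega_minus`,
#'       `omega_plus`, `net_electrophilicity`, `pka`)}
#'     \item{site_blocks}{named list of `site_table` fragments with
#'       `dual`, `dual_scaled`, `parr_plus`, `parr_minus` columns}
#'     \item{pka_labels}{data.frame with the verbatim labels, mapped
#'       molecules and pKas}
#'   }
#' @examples
#' b <- load_virotoxin_fixtures()
#' b$records[["Viroidin"]]
#' @export
load_virotoxin_fixtures <- function() {
  path <- system.file("extdata", "virotoxins.json", package = "cdftkit",
                      mustWork = TRUE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  records <- lapply(doc$frontier, function(r)
    frontier_record(r$label, r$epsilon_homo, r$epsilon_lumo, source = "fixture"))
  names(records) <- vapply(records, `[[`, character(1), "label")

  expected <- lapply(doc$expected_global, function(e) lapply(e, as.numeric))

  blocks <- lapply(doc$site_blocks[names(records)], function(rows) {
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(atom_index = as.integer(r$atom_index), element = r$element,
                 dual = r$dual_scaled / 100, dual_scaled = r$dual_scaled,
                 parr_plus = r$parr_plus, parr_minus = r$parr_minus,
                 stringsAsFactors = FALSE)))
    site_table(df)
  })

  pl <- doc$pka_labels
  pka_labels <- data.frame(label = unlist(pl$labels),
                           molecule = unlist(pl$molecules),
                           pka = unlist(pl$pka), stringsAsFactors = FALSE)

  structure(list(records = records, expected = expected,
                 site_blocks = blocks, pka_labels = pka_labels),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d virotoxin records: %s\n",
              length(x$records), paste(names(x$records), collapse = ", ")))
  invisible(x)
}
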