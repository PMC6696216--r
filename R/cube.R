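#' Volumetric scalar field on a regular grid
#'
#' Container for Gaussian-cube-style volumetric data (electron densities,
#' Fukui fields). Lengths are in Bohr throughout, matching the cube format.
#'
#' @param origin Numeric 3-vector, grid origin.
#' @param axes 3x3 matrix whose rows are the step vectors of the three grid
#'   axes.
#' @param counts Integer 3-vector of point counts along each axis.
#' @param values Numeric vector of `prod(counts)` grid values, stored in
#'   cube order (the last axis varies fastest).
#' @param atoms Optional data.frame with columns `number`, `charge`,
#'   `x`, `y`, `z` describing the atoms in the cube header.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(origin, axes, counts, values, atoms = NULL) {
  origin <- as.numeric(origin); counts <- as.integer(counts)
  axes <- matrix(as.numeric(axes), 3L, 3L)
  if (length(origin) != 3L || length(counts) != 3L)
    stop_cdft("origin and counts must have length 3", "cdft_value_error")
  if (any(counts < 1L))
    stop_cdft("grid counts must be positive", "cdft_value_error")
  if (abs(det(axes)) < 1e-12)
    stop_cdft("grid axes are singular", "cdft_value_error")
  if (length(values) != prod(counts))
    stop_cdft(sprintf("expected %d grid values, found %d",
                      prod(counts), length(values)), "cdft_value_error")
  structure(list(origin = origin, axes = axes, counts = counts,
                 values = as.numeric(values), atoms = atoms),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %dx%dx%d grid, %d atoms, values in [%.4g, %.4g]\n",
              x$counts[1], x$counts[2], x$counts[3],
              if (is.null(x$atoms)) 0L else nrow(x$atoms),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a scalar field's grid
#'
#' @param field A [scalar_field].
#' @return The parallelepiped volume spanned by the three step vectors, Bohr^3.
#' @export
voxel_volume <- function(field) abs(det(field$axes))

#' Grid-quadrature integral of a scalar field
#'
#' @param field A [scalar_field].
#' @return `voxel_volume(field) * sum(field$values)`.
#' @export
field_integral <- function(field) voxel_volume(field) * sum(field$values)

#' Read a Gaussian cube file
#'
#' Standard cube layout: two comment lines; a line with the atom count and
#' origin; three axis lines (count + step vector); one line per atom; then
#' the grid values, fastest along the third axis. The MO-cube dialect
#' (negative atom count) is rejected. Cube step counts given with negative
#' sign (Angstrom convention) are not supported either; the toolkit works
#' in Bohr.
#'
#' @param path Path to a cube file.
#' @return A [scalar_field].
#' @export
read_cube <- function(path) {
  if (!file.exists(path))
    stop_cdft(sprintf("no cube file at '%s'", path), "cdft_io_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L)
    stop_cdft("cube file too short for a valid header", "cdft_parse_error")
  num <- function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    if (anyNA(v)) stop_cdft(sprintf("unparseable cube line: '%s'", ln),
                            "cdft_parse_error")
    v
  }
  hdr <- num(lines[3])
  natoms <- as.integer(hdr[1])
  if (natoms < 0L)
    stop_cdft(paste("cube declares a negative atom count: this is the",
                    "molecular-orbital cube dialect, which is not supported"),
              "cdft_parse_error")
  origin <- hdr[2:4]
  ax <- t(vapply(4:6, function(i) num(lines[i]), numeric(4)))
  counts <- as.integer(ax[, 1])
  axes <- ax[, 2:4, drop = FALSE]
  atoms <- NULL
  if (natoms > 0L) {
    arows <- t(vapply(seq_len(natoms) + 6L, function(i) num(lines[i]), numeric(5)))
    atoms <- data.frame(number = as.integer(arows[, 1]), charge = arows[, 2],
                        x = arows[, 3], y = arows[, 4], z = arows[, 5])
  }
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[seq.int(7L + natoms, length(lines))]), "\\s+")))
  vals <- vals[!is.na(vals)]
  nexp <- prod(counts)
  if (length(vals) != nexp)
    stop_cdft(sprintf("truncated or padded cube value section: expected %d values, found %d",
                      nexp, length(vals)), "cdft_parse_error")
  scalar_field(origin, axes, counts, vals, atoms)
}

#' Write a Gaussian cube file
#'
#' Values are written with seven significant figures in scientific
#' notation, six per line, so a read/write round trip preserves them to
#' better than 6 s.f. and header fields exactly at the printed precision.
#'
#' @param field A [scalar_field].
#' @param path Output path.
#' @param comment Two-element character vector for the comment lines.
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, path,
                       comment = c("cdftkit scalar field", "cube format")) {
  natoms <- if (is.null(field$atoms)) 0L else nrow(field$atoms)
  if (natoms == 0L) {
    # cube headers require >= 1 atom line; emit a dummy at the origin
    field$atoms <- data.frame(number = 1L, charge = 0,
                              x = field$origin[1], y = field$origin[2],
                              z = field$origin[3])
    natoms <- 1L
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(comment[1:2], con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", natoms,
                     field$origin[1], field$origin[2], field$origin[3]), con)
  for (i in 1:3)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", field$counts[i],
                       field$axes[i, 1], field$axes[i, 2], field$axes[i, 3]), con)
  for (i in seq_len(natoms))
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f",
                       field$atoms$number[i], field$atoms$charge[i],
                       field$atoms$x[i], field$atoms$y[i], field$atoms$z[i]), con)
  v <- sprintf("% .6E", field$values)
  groups <- split(v, (seq_along(v) - 1L) %/% 6L)
  writeLines(vapply(groups, paste, character(1), collapse = " "), con)
  invisible(path)
}

# Congruence check used by field arithmetic; returns NULL or the name of
# the first differing header field.
grid_mismatch <- function(a, b, tol = 1e-6) {
  if (!identical(a$counts, b$counts)) return("counts")
  if (max(abs(a$origin - b$origin)) > tol) return("origin")
  if (max(abs(a$axes - b$axes)) > tol) return("axes")
  NULL
}
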