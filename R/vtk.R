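#' Write fields as a legacy VTK structured-points file
#'
#' Serializes one or more scalar fields on the chamber grid as ASCII legacy
#' VTK (`DATASET STRUCTURED_POINTS`, `DIMENSIONS nx ny 1`, one named
#' `SCALARS` block per field), the interchange convention for chamber
#' snapshots. Integer fields round-trip exactly.
#'
#' @param fields A matrix, or a named list of matrices of identical shape.
#' @param path Output file.
#' @param spacing Chamber edge, um.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(fields, path, spacing = 0.5) {
  if (is.matrix(fields)) fields <- list(value = fields)
  if (is.null(names(fields)) || any(names(fields) == ""))
    stop("each field needs a name")
  dims <- dim(fields[[1]])
  for (f in fields)
    if (!all(dim(f) == dims)) stop("all fields must share one shape")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "nksynapse chamber fields",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", dims[1], dims[2]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", spacing, spacing),
               sprintf("POINT_DATA %d", prod(dims))), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    int_like <- all(v == round(v))
    writeLines(c(sprintf("SCALARS %s %s 1", nm,
                         if (int_like) "int" else "float"),
                 "LOOKUP_TABLE default"), con)
    vals <- as.vector(v)  # x fastest, matching DIMENSIONS order
    writeLines(paste(format(vals, trim = TRUE, scientific = FALSE,
                            digits = 15),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a legacy VTK structured-points file written by [write_vtk()]
#'
#' @param path File path.
#' @return Named list of matrices; attribute `spacing` holds the grid
#'   spacing.
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  expect_line <- function(i, pattern) {
    if (i > length(ln) || !grepl(pattern, ln[i]))
      stop(sprintf("malformed VTK header at line %d (expected %s)", i,
                   pattern))
  }
  expect_line(1, "^# vtk DataFile")
  expect_line(3, "^ASCII$")
  expect_line(4, "^DATASET STRUCTURED_POINTS$")
  expect_line(5, "^DIMENSIONS ")
  dims <- as.integer(strsplit(ln[5], "\\s+")[[1]][2:4])
  expect_line(7, "^SPACING ")
  spacing <- as.numeric(strsplit(ln[7], "\\s+")[[1]][2])
  expect_line(8, "^POINT_DATA ")
  npts <- as.integer(strsplit(ln[8], "\\s+")[[1]][2])
  if (npts != dims[1] * dims[2])
    stop(sprintf("POINT_DATA (%d) disagrees with DIMENSIONS at line 8", npts))
  out <- list()
  i <- 9
  while (i <= length(ln)) {
    if (ln[i] == "") { i <- i + 1; next }
    if (!grepl("^SCALARS ", ln[i]))
      stop(sprintf("malformed VTK scalar block at line %d", i))
    nm <- strsplit(ln[i], "\\s+")[[1]][2]
    is_int <- grepl(" int ", paste0(ln[i], " "))
    expect_line(i + 1, "^LOOKUP_TABLE")
    vals <- numeric(0)
    i <- i + 2
    while (length(vals) < npts) {
      if (i > length(ln)) stop("truncated VTK data block")
      vals <- c(vals, as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]]))
      i <- i + 1
    }
    m <- matrix(vals[seq_len(npts)], dims[1], dims[2])
    if (is_int) storage.mode(m) <- "integer"
    out[[nm]] <- m
  }
  attr(out, "spacing") <- spacing
  out
}

#' Export a lattice configuration
#'
#' Writes every nonzero species field of a configuration as a multi-scalar
#' VTK file and, optionally, a wide CSV (`x_index`, `y_index`, one column
#' per species).
#'
#' @param config An `nk_lattice`.
#' @param vtk_path,csv_path Output paths (`NULL` to skip).
#' @return Invisibly, the list of per-species matrices.
#' @export
export_lattice <- function(config, vtk_path = NULL, csv_path = NULL) {
  sp <- species_names()
  fields <- lapply(sp, function(s) config$counts[, , s])
  names(fields) <- sp
  keep <- vapply(fields, function(m) any(m > 0), TRUE)
  if (!any(keep)) keep[1] <- TRUE
  fields <- fields[keep]
  if (!is.null(vtk_path))
    write_vtk(fields, vtk_path, spacing = config$geometry$l0)
  if (!is.null(csv_path)) {
    g <- config$geometry
    df <- data.frame(x_index = rep(seq_len(g$nx) - 1L, g$ny),
                     y_index = rep(seq_len(g$ny) - 1L, each = g$nx))
    for (nm in names(fields)) df[[nm]] <- as.vector(fields[[nm]])
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(fields)
}
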