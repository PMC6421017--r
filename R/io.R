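# Grid file I/O.  CSV is the lossless interchange format (full float
# precision, bit-exact round trip); PNG is 8-bit, exact for label maps and
# masks (integer codes) and a scaled visualization for float grids.
# Single-slice NIfTI volumes are read through RNifti when available.

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "png", "nii")) return(ext)
  if (ext == "gz" && grepl("\\.nii\\.gz$", tolower(path))) return("nii")
  stop("unrecognized grid format for path: ", path)
}

#' Write a numeric grid to a file
#'
#' @param grid Numeric or logical matrix.
#' @param path Output path; format inferred from the extension unless
#'   given.
#' @param format `"csv"` (lossless full-precision text) or `"png"` (8-bit;
#'   exact for integer grids in 0..255, otherwise min-max scaled).
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_grid(matrix(rnorm(9), 3), f)
#' all.equal(read_grid(f), matrix(read_grid(f), 3))
write_grid <- function(grid, path, format = NULL) {
  stopifnot(is.matrix(grid))
  if (is.null(format)) format <- format_from_path(path)
  if (format == "csv") {
    lines <- apply(grid, 1, function(r)
      paste(sprintf("%.17g", as.numeric(r)), collapse = ","))
    writeLines(lines, path)
  } else if (format == "png") {
    g <- grid * 1
    if (all(g == round(g)) && min(g) >= 0 && max(g) <= 255) {
      png::writePNG(g / 255, path)
    } else {
      rng <- range(g)
      scl <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
      png::writePNG(scl, path)
    }
  } else stop("unsupported output format: ", format)
  invisible(path)
}

#' Read a numeric grid from a file
#'
#' @param path Input path (CSV, PNG, or single-slice NIfTI).
#' @param format Format override; inferred from the extension by default.
#' @return Numeric matrix.  CSV values round-trip bit-exactly through
#'   [write_grid()]; PNG is returned on the 0..255 integer scale; NIfTI
#'   volumes must contain a single 2-D slice.
#' @export
read_grid <- function(path, format = NULL) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  if (is.null(format)) format <- format_from_path(path)
  if (format == "csv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("parse error in ", path, ": empty file")
    rows <- strsplit(lines, ",", fixed = TRUE)
    nfield <- lengths(rows)
    if (any(nfield != nfield[1]))
      stop(sprintf("parse error in %s: line %d has %d fields, expected %d",
                   path, which(nfield != nfield[1])[1],
                   nfield[which(nfield != nfield[1])[1]], nfield[1]))
    vals <- suppressWarnings(lapply(rows, as.numeric))
    bad <- which(vapply(vals, anyNA, logical(1)))
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric value on line %d",
                   path, bad[1]))
    do.call(rbind, vals)
  } else if (format == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 255)
  } else if (format == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) > 2 && any(d[-(1:2)] > 1))
      stop("parse error in ", path, ": expected a single 2-D slice")
    matrix(as.numeric(vol), d[1], d[2])
  } else stop("unsupported input format: ", format)
}

#' Write / read a binary mask as 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write / read a tissue label map
#'
#' CSV grids of integer codes with the spacing recorded on a header
#' comment line; round-trips bit-exactly.
#'
#' @param map A [tissue_map()].
#' @param path CSV path.
#' @return `write_tissue_map` returns `path` invisibly; `read_tissue_map`
#'   returns a [tissue_map()].
#' @export
write_tissue_map <- function(map, path) {
  stopifnot(inherits(map, "tissue_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_mm=%.17g", map$spacing), con)
  writeLines(apply(map$labels, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_tissue_map
#' @export
read_tissue_map <- function(path) {
  lines <- readLines(path)
  spacing <- 1
  if (length(lines) && grepl("^# spacing_mm=", lines[1])) {
    spacing <- as.numeric(sub("^# spacing_mm=", "", lines[1]))
    lines <- lines[-1]
  }
  tmp <- tempfile(fileext = ".csv")
  writeLines(lines, tmp)
  on.exit(unlink(tmp))
  grid <- read_grid(tmp, "csv")
  tissue_map(matrix(as.integer(grid), nrow(grid)), spacing)
}
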