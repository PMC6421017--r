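# Synthetic tissue phantoms: label maps, tumors, and pseudo-MRI renderings.
# Grids are row-major matrices, 0-based concepts are avoided: pixel (i, j)
# has its centre at integer coordinates (i, j) in pixel units, and physical
# distances are pixel distances times `spacing` (mm).

#' Construct a tissue label map
#'
#' @param labels Integer matrix of tissue codes (see [tissue_codes()]).
#' @param spacing Pixel edge length in mm (isotropic).
#' @return Object of class `tissue_map`.
#' @export
tissue_map <- function(labels, spacing = 1) {
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  codes <- tissue_codes()
  if (!all(labels %in% codes))
    stop("label map contains values outside the tissue code enumeration")
  border <- c(labels[1, ], labels[nrow(labels), ],
              labels[, 1], labels[, ncol(labels)])
  if (any(border != codes[["BACKGROUND"]]))
    stop("all four grid borders must be BACKGROUND (Dirichlet boundary)")
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0)
  structure(list(labels = labels, spacing = spacing), class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  codes <- tissue_codes()
  n <- vapply(codes, function(cd) sum(x$labels == cd), integer(1))
  cat(sprintf("Tissue label map: %d x %d pixels, %g mm spacing\n",
              nrow(x$labels), ncol(x$labels), x$spacing))
  cat("  pixels:", paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.tissue_map <- function(x, ...) {
  image(t(x$labels)[, nrow(x$labels):1], axes = FALSE, asp = 1,
        col = c("black", "steelblue", "grey55", "grey85", "firebrick"),
        zlim = c(0, 4), ...)
  invisible(x)
}

#' Brain mask of a label map
#'
#' @param map A [tissue_map()].
#' @return Logical matrix, `TRUE` on non-background pixels.
#' @export
brain_mask <- function(map) {
  stopifnot(inherits(map, "tissue_map"))
  map$labels != tissue_codes()[["BACKGROUND"]]
}

#' Tumor mask of a label map
#'
#' @param map A [tissue_map()].
#' @return Logical matrix, `TRUE` on tumor pixels.
#' @export
tumor_mask <- function(map) {
  stopifnot(inherits(map, "tissue_map"))
  map$labels == tissue_codes()[["TUMOR"]]
}

# run expr with a private, restored RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Circular-tumor phantom
#'
#' Builds the simplest study geometry: a filled rectangle of one surround
#' tissue inset from a background border, with a rasterized disc of tumor
#' pixels.  A pixel belongs to the tumor iff its centre lies within
#' `tumor_diameter / 2` of the tumor centre.
#'
#' @param grid_size Grid side length in pixels (square grid).
#' @param spacing Pixel edge length in mm.
#' @param tumor_diameter Tumor diameter in mm; 0 gives a tumor-free map.
#' @param tumor_center Pixel coordinates `c(row, col)` of the tumor centre;
#'   default is the grid centre.
#' @param surround Surround tissue name (default `"WM"`).
#' @param inset Background border width in pixels.
#' @return A [tissue_map()].
#' @export
#' @examples
#' ph <- make_circular_phantom(128, 1, tumor_diameter = 10)
#' sum(tumor_mask(ph))   # about pi * 5^2
make_circular_phantom <- function(grid_size, spacing = 1, tumor_diameter = 0,
                                  tumor_center = NULL,
                                  surround = c("WM", "GM", "CSF"),
                                  inset = 2L) {
  stopifnot(grid_size >= 8, tumor_diameter >= 0, inset >= 1)
  surround <- match.arg(surround)
  codes <- tissue_codes()
  n <- as.integer(grid_size)
  labels <- matrix(codes[["BACKGROUND"]], n, n)
  br <- (inset + 1L):(n - inset)
  labels[br, br] <- codes[[surround]]
  if (is.null(tumor_center)) tumor_center <- c((n + 1) / 2, (n + 1) / 2)
  if (tumor_diameter > 0) {
    r_px <- tumor_diameter / 2 / spacing
    ii <- row(labels); jj <- col(labels)
    disc <- (ii - tumor_center[1])^2 + (jj - tumor_center[2])^2 <= r_px^2
    if (any(disc & labels == codes[["BACKGROUND"]]))
      stop("geometry error: tumor disc extends into the background border")
    labels[disc] <- codes[["TUMOR"]]
  }
  tissue_map(labels, spacing)
}

# radial perturbation profile of a star-convex blob; returns a function of
# the polar angle, with max |perturbation| scaled to `amplitude`
blob_profile <- function(amplitude, n_modes) {
  if (amplitude <= 0 || n_modes < 1) return(function(theta) rep(0, length(theta)))
  m <- seq(2L, 1L + n_modes)
  a <- rnorm(n_modes) / m
  phi <- stats::runif(n_modes, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = 721)
  f <- function(theta) {
    s <- 0
    for (q in seq_along(m)) s <- s + a[q] * cos(m[q] * theta + phi[q])
    s
  }
  sc <- max(abs(f(th)))
  if (sc == 0) return(function(theta) rep(0, length(theta)))
  function(theta) amplitude * f(theta) / sc
}

#' Irregular brain phantom with a star-convex tumor blob
#'
#' A surrogate head geometry: background border, elliptical brain with a
#' CSF rim, a GM ribbon and a WM core (constant-thickness shells measured
#' by distance from the background), plus an irregular star-convex tumor
#' blob obtained by radial perturbation of a disc.  The blob is placed
#' inside the WM core (seeded placement) and is fully contained in
#' WM and GM.  Deterministic for a fixed seed.
#'
#' @param grid_size Grid side length in pixels, at least 64.
#' @param spacing Pixel edge length in mm.
#' @param seed Integer seed controlling blob shape and placement.
#' @param tumor_spec List with elements `radius` (mean blob radius, mm),
#'   `amplitude` (relative radial perturbation, 0 gives an exact disc),
#'   `n_modes` (number of angular perturbation modes) and optional `center`
#'   (pixel coordinates; default seeded placement in deep white matter).
#' @param brain_axes Semi-axes of the brain ellipse as fractions of the
#'   grid side (columns, rows).
#' @param csf_px CSF rim thickness in pixels.
#' @param gm_px GM ribbon thickness in pixels.
#' @return A [tissue_map()].
#' @export
#' @examples
#' ph <- make_brain_phantom(128, seed = 1, tumor_spec = list(radius = 8))
#' table(ph$labels)
make_brain_phantom <- function(grid_size = 256, spacing = 1, seed = 1,
                               tumor_spec = list(),
                               brain_axes = c(0.40, 0.33),
                               csf_px = 3, gm_px = 8) {
  stopifnot(grid_size >= 64)
  spec <- utils::modifyList(
    list(radius = 12, amplitude = 0.2, n_modes = 3, center = NULL),
    tumor_spec)
  stopifnot(spec$radius > 0, spec$amplitude >= 0)
  codes <- tissue_codes()
  n <- as.integer(grid_size)
  ci <- (n + 1) / 2; cj <- (n + 1) / 2
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  a_px <- brain_axes[1] * n; b_px <- brain_axes[2] * n
  brain <- ((jj - cj) / a_px)^2 + ((ii - ci) / b_px)^2 <= 1
  # keep the boundary invariant even for large axes
  brain[c(1, n), ] <- FALSE; brain[, c(1, n)] <- FALSE
  depth <- as.matrix(EBImage::distmap(EBImage::Image(brain * 1)))
  labels <- matrix(codes[["BACKGROUND"]], n, n)
  labels[brain & depth <= csf_px] <- codes[["CSF"]]
  labels[brain & depth > csf_px & depth <= csf_px + gm_px] <- codes[["GM"]]
  labels[brain & depth > csf_px + gm_px] <- codes[["WM"]]

  r_px <- spec$radius / spacing
  rmax_px <- r_px * (1 + spec$amplitude)
  with_seed(seed, {
    prof <- blob_profile(spec$amplitude, spec$n_modes)
    if (is.null(spec$center)) {
      # eligible centres keep the whole blob out of CSF and background
      ok <- labels == codes[["WM"]] & depth > csf_px + rmax_px + 1
      if (!any(ok))
        stop("geometry error: tumor_spec too large for the WM core")
      pick <- which(ok)[sample.int(sum(ok), 1)]
      ctr <- c((pick - 1) %% n + 1, (pick - 1) %/% n + 1)
    } else ctr <- spec$center
    di <- ii - ctr[1]; dj <- jj - ctr[2]
    theta <- atan2(di, dj)
    blob <- di^2 + dj^2 <= (r_px * (1 + prof(theta)))^2
    if (any(blob & !(labels %in% codes[c("WM", "GM")])))
      stop("geometry error: tumor blob leaves the WM/GM region")
    labels[blob] <- codes[["TUMOR"]]
  })
  tissue_map(labels, spacing)
}

#' Default per-tissue intensity tables for pseudo-MRI rendering
#'
#' Flat per-tissue mean intensities in `[0, 1]` emulating the qualitative
#' appearance of the two sequences used for tumor work: in both, the tumor
#' is hyperintense; in the Flair-like table CSF is attenuated (dark) and GM
#' is brighter than WM, in the T1c-like table WM is brighter than GM.
#'
#' @param sequence_tag `"Flair-like"` or `"T1c-like"` (case-insensitive,
#'   `"flair"`/`"t1c"` accepted).
#' @return Named numeric vector over `BACKGROUND`, `CSF`, `GM`, `WM`,
#'   `TUMOR`.
#' @export
default_intensity_table <- function(sequence_tag = "Flair-like") {
  tag <- normalize_sequence_tag(sequence_tag)
  if (tag == "Flair-like")
    c(BACKGROUND = 0.05, CSF = 0.12, GM = 0.42, WM = 0.35, TUMOR = 0.95)
  else
    c(BACKGROUND = 0.05, CSF = 0.20, GM = 0.45, WM = 0.60, TUMOR = 0.95)
}

normalize_sequence_tag <- function(tag) {
  t <- tolower(gsub("-like$", "", tag))
  if (t %in% c("flair", "flair2")) return("Flair-like")
  if (t %in% c("t1c", "t1ce", "t1 contrast")) return("T1c-like")
  stop("unknown sequence tag: ", tag)
}

#' Render a pseudo-MRI intensity image from a label map
#'
#' Produces a flat per-tissue-mean image with additive zero-mean Gaussian
#' noise, clipped to `[0, 1]`, paired with the tumor ground-truth mask.
#' The tumor mean must be strictly greater than every other tissue mean
#' (tumor hyperintensity), which is what makes the Chan-Vese baseline
#' applicable.
#'
#' Rendering applies a Gaussian point-spread blur (`psf_sigma` pixels) to
#' the piecewise-constant mean image before adding noise, emulating the
#' partial-volume averaging of MR acquisition at tissue boundaries; set
#' `psf_sigma = 0` for the exact flat per-tissue image.
#'
#' @param map A [tissue_map()].
#' @param sequence_tag `"Flair-like"` or `"T1c-like"`.
#' @param intensity_table Named per-tissue mean intensities; default
#'   [default_intensity_table()] for the tag.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (intensity units).
#' @param psf_sigma Gaussian point-spread width in pixels (0 disables).
#' @param seed Integer seed; rendering is reproducible for a fixed seed.
#' @return Object of class `synthetic_mri`: list with `image` (matrix in
#'   `[0, 1]`), `truth` (logical tumor mask) and `sequence_tag`.
#' @export
#' @examples
#' ph <- make_brain_phantom(128, seed = 1, tumor_spec = list(radius = 8))
#' pair <- render_mri(ph, "Flair-like", noise_sd = 0.05, seed = 1)
#' mean(pair$image[pair$truth]) > mean(pair$image[!pair$truth])
render_mri <- function(map, sequence_tag = "Flair-like",
                       intensity_table = NULL, noise_sd = 0.05,
                       psf_sigma = 1.5, seed = 1) {
  stopifnot(inherits(map, "tissue_map"), noise_sd >= 0, psf_sigma >= 0)
  tag <- normalize_sequence_tag(sequence_tag)
  if (is.null(intensity_table)) intensity_table <- default_intensity_table(tag)
  codes <- tissue_codes()
  present <- names(codes)[codes %in% unique(as.vector(map$labels))]
  missing <- setdiff(present, names(intensity_table))
  if (length(missing))
    stop("intensity_table lacks means for: ", paste(missing, collapse = ", "))
  others <- setdiff(intersect(present, names(intensity_table)), "TUMOR")
  if ("TUMOR" %in% present &&
      any(intensity_table[others] >= intensity_table[["TUMOR"]]))
    stop("TUMOR mean intensity must exceed every other tissue mean")
  lut <- setNames(rep(NA_real_, length(codes)), names(codes))
  lut[names(intensity_table)] <- intensity_table
  img <- matrix(lut[match(as.vector(map$labels), codes)],
                nrow(map$labels), ncol(map$labels))
  if (psf_sigma > 0) img <- smooth_gaussian(img, psf_sigma)
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, truth = tumor_mask(map), sequence_tag = tag),
            class = "synthetic_mri")
}

#' @export
print.synthetic_mri <- function(x, ...) {
  cat(sprintf("Synthetic %s image: %d x %d, %d tumor truth pixels\n",
              x$sequence_tag, nrow(x$image), ncol(x$image), sum(x$truth)))
  invisible(x)
}
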