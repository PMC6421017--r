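# Tumor contour delineation from the thermal map.  The steady temperature
# field has its largest gradient at the tumor boundary, so a Canny detector
# (smoothing, gradient, non-maximum suppression, double threshold,
# hysteresis) recovers the contour; because the thermal map is noisy, the
# smoothing step is applied twice by default.

as_field_matrix <- function(field) {
  if (inherits(field, "temp_field")) field$values
  else if (is.matrix(field)) field
  else stop("expected a temp_field or a numeric matrix")
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with replicate padding
smooth_gaussian <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  rows <- pmin(pmax(seq(1 - r, nr + r), 1), nr)
  mp <- m[rows, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (s in seq_along(k)) out <- out + k[s] * mp[s:(s + nr - 1), , drop = FALSE]
  cols <- pmin(pmax(seq(1 - r, nc + r), 1), nc)
  mp <- out[, cols, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (s in seq_along(k)) out <- out + k[s] * mp[, s:(s + nc - 1), drop = FALSE]
  out
}

shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
  cj <- pmin(pmax(seq_len(nc) + dj, 1), nc)
  m[ri, cj, drop = FALSE]
}

#' Canny edge detection on a temperature field
#'
#' Gaussian smoothing applied `smooth_passes` times, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, double
#' thresholding at fractions of the maximum gradient magnitude, and
#' hysteresis linking (weak edge components are kept only when they touch a
#' strong pixel).  Deterministic; noise enters only through the field.
#'
#' @param field A [temp_field()] or numeric matrix.
#' @param sigma Gaussian smoothing width in pixels per pass.
#' @param low_frac,high_frac Double-threshold fractions of the maximum
#'   gradient magnitude, `0 < low_frac < high_frac <= 1`.
#' @param smooth_passes Number of smoothing passes (default 2).
#' @return Logical matrix of edge pixels.
#' @export
#' @examples
#' f <- matrix(rep(c(0, 1), each = 32), 32, 64, byrow = TRUE)
#' which(canny(f), arr.ind = TRUE)[1, ]
canny <- function(field, sigma = 1, low_frac = 0.1, high_frac = 0.2,
                  smooth_passes = 2L) {
  m <- as_field_matrix(field)
  stopifnot(sigma > 0, low_frac > 0, low_frac < high_frac, high_frac <= 1,
            smooth_passes >= 0)
  for (p in seq_len(smooth_passes)) m <- smooth_gaussian(m, sigma)
  # Sobel derivatives: x along columns, y along rows
  gx <- (shift_mat(m, -1, 1) + 2 * shift_mat(m, 0, 1) + shift_mat(m, 1, 1)) -
        (shift_mat(m, -1, -1) + 2 * shift_mat(m, 0, -1) + shift_mat(m, 1, -1))
  gy <- (shift_mat(m, 1, -1) + 2 * shift_mat(m, 1, 0) + shift_mat(m, 1, 1)) -
        (shift_mat(m, -1, -1) + 2 * shift_mat(m, -1, 0) + shift_mat(m, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, nrow(m), ncol(m))
  for (s in 0:3) {
    d <- off[[s + 1]]
    n1 <- shift_mat(mag, d[1], d[2])
    n2 <- shift_mat(mag, -d[1], -d[2])
    sel <- sector == s
    nms[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }
  strong <- nms & mag >= high_frac * mmax
  weak <- nms & mag >= low_frac * mmax
  if (!any(strong)) return(matrix(FALSE, nrow(m), ncol(m)))
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(weak * 1)))
  keep <- unique(lab[strong])
  weak & lab %in% keep
}

#' Convert an edge map into a closed tumor mask
#'
#' Morphological closing of the edge set, filling of enclosed holes,
#' removal of small components, and retention of the largest filled
#' component.  Turns the Canny contour into a pixel region comparable with
#' a ground-truth mask.
#'
#' @param edges Logical edge matrix (from [canny()]).
#' @param closing_radius Disc radius (pixels) of the morphological closing
#'   used to bridge small contour gaps.
#' @param min_component Minimum component size in pixels.
#' @param keep_all Keep all surviving components instead of only the
#'   largest.
#' @return Logical tumor mask.  An empty edge map yields an empty mask with
#'   a warning.
#' @export
edges_to_mask <- function(edges, closing_radius = 2, min_component = 10,
                          keep_all = FALSE) {
  stopifnot(is.matrix(edges))
  edges <- edges != 0
  if (!any(edges)) {
    warning("empty edge map: returning an empty mask")
    return(matrix(FALSE, nrow(edges), ncol(edges)))
  }
  img <- EBImage::Image(edges * 1)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, "disc")
    img <- EBImage::closing(img, brush)
  }
  img <- EBImage::fillHull(img)
  lab <- as.matrix(EBImage::bwlabel(img))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component)
  if (!length(keep)) {
    warning("no component of at least min_component pixels: empty mask")
    return(matrix(FALSE, nrow(edges), ncol(edges)))
  }
  if (!keep_all) keep <- keep[which.max(sizes[keep])]
  matrix(lab %in% keep, nrow(edges), ncol(edges))
}

#' Temperature and absolute-gradient profile along a grid row
#'
#' @param field A [temp_field()] or numeric matrix.
#' @param row Row index.
#' @return List with `temperature` (degrees C) and `gradient` (absolute
#'   central-difference gradient in degrees C per mm; one-sided at the
#'   ends).
#' @export
line_profile <- function(field, row) {
  m <- as_field_matrix(field)
  spacing <- if (inherits(field, "temp_field")) field$spacing else 1
  stopifnot(row >= 1, row <= nrow(m))
  v <- m[row, ]
  n <- length(v)
  g <- numeric(n)
  if (n > 2) g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * spacing)
  g[1] <- (v[2] - v[1]) / spacing
  g[n] <- (v[n] - v[n - 1]) / spacing
  list(temperature = v, gradient = abs(g))
}

#' Isotherm masks of a temperature field
#'
#' Marks the pixels at which the field crosses a temperature level: a pixel
#' is marked when its value is at or above the level while some 4-neighbour
#' is below it (the inner rim of the level curve).
#'
#' @param field A [temp_field()] or numeric matrix.
#' @param levels One or more temperature levels in degrees C.
#' @return A logical mask for a single level, or a named list of masks for
#'   a batch of levels.
#' @export
#' @examples
#' ph <- make_circular_phantom(64, 1, 16)
#' fld <- solve_steady(ph, tissue_properties(), solver_config(max_iters = 2e4))
#' masks <- isotherm(fld, c(37.5, 38))
isotherm <- function(field, levels) {
  m <- as_field_matrix(field)
  one <- function(level) {
    below <- shift_mat(m, 1, 0) < level | shift_mat(m, -1, 0) < level |
             shift_mat(m, 0, 1) < level | shift_mat(m, 0, -1) < level
    m >= level & below
  }
  if (length(levels) == 1) return(one(levels))
  setNames(lapply(levels, one), paste0("T", levels))
}

#' Thermal-map tumor segmentation
#'
#' The full thermal route: Canny edge detection on the temperature field,
#' suppression of edges within `margin` pixels of the background (the
#' head-surface temperature drop produces its own strong edge, exactly as a
#' skull-stripping margin removes the scalp in MRI practice), and
#' conversion of the remaining contour to a closed tumor mask.
#'
#' @param field A [temp_field()] or numeric matrix.
#' @param brain Optional logical brain mask (e.g. [brain_mask()] of the
#'   generating label map); when given, edges outside the mask eroded by
#'   `margin` pixels are discarded.
#' @param margin Brain-boundary exclusion margin in pixels.
#' @param sigma,low_frac,high_frac,smooth_passes Passed to [canny()].
#' @param closing_radius,min_component Passed to [edges_to_mask()].
#' @return Object of class `thermal_segmentation`: list with `mask`
#'   (logical tumor mask) and `edges` (retained edge pixels).
#' @export
segment_thermal <- function(field, brain = NULL, margin = 5,
                            sigma = 1, low_frac = 0.1, high_frac = 0.2,
                            smooth_passes = 2L, closing_radius = 2,
                            min_component = 10) {
  edges <- canny(field, sigma = sigma, low_frac = low_frac,
                 high_frac = high_frac, smooth_passes = smooth_passes)
  if (!is.null(brain)) {
    stopifnot(all(dim(brain) == dim(edges)))
    interior <- brain
    if (margin > 0) {
      brush <- EBImage::makeBrush(2 * margin + 1, "disc")
      interior <- as.matrix(EBImage::erode(EBImage::Image(brain * 1),
                                           brush)) > 0
    }
    edges <- edges & interior
  }
  mask <- edges_to_mask(edges, closing_radius = closing_radius,
                        min_component = min_component)
  structure(list(mask = mask, edges = edges), class = "thermal_segmentation")
}

#' @export
print.thermal_segmentation <- function(x, ...) {
  cat(sprintf("Thermal segmentation: %d edge pixels -> %d mask pixels\n",
              sum(x$edges), sum(x$mask)))
  invisible(x)
}
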