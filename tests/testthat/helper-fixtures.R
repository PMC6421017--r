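# Shared fixtures, cached across test files (helpers load once per run).
# Small grids keep unit tests fast; the acceptance tests use the full
# 256 x 256 study geometry.

.fixtures <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = .fixtures)) assign(key, make(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# 96 x 96 WM phantom with a centred 16 mm tumor and its steady field
disc96 <- function() {
  cache_get("disc96", function() {
    ph <- make_circular_phantom(96, 1, 16)
    fld <- solve_steady(ph, tissue_properties(), solver_config())
    list(phantom = ph, field = fld)
  })
}

# count 8-connected components of a mask (dilation joins diagonal steps)
count_components8 <- function(mask) {
  d <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1),
                                 EBImage::makeBrush(3, "box")))
  max(EBImage::bwlabel(EBImage::Image(d)))
}

# seeded Gaussian noise matrix for property tests
with_seed_noise <- function(seed, dm, sd) {
  set.seed(seed)
  matrix(rnorm(prod(dm), 0, sd), dm[1], dm[2])
}

# brute-force rasterized disc pixel count (independent of the phantom code)
brute_disc_count <- function(n, spacing, diameter, center) {
  r <- diameter / 2 / spacing
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - center[1])^2 + (j - center[2])^2 <= r^2) cnt <- cnt + 1L
  cnt
}
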