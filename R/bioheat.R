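# Explicit finite-difference solution of the 2-D Pennes bioheat equation
#
#   rho Cp dT/dt = k (Txx + Tyy) + wb rho_b cp_b (Ta - T) + Qm
#
# on a tissue label map.  Background pixels are Dirichlet nodes held at the
# boundary temperature; brain pixels adjacent to background read that value,
# which realizes exposure of the head surface to constant body temperature.

#' Construct a temperature field object
#'
#' @param values Numeric matrix of temperatures in degrees C.
#' @param spacing Pixel edge length in mm.
#' @param iterations Number of explicit iterations run to produce it.
#' @param converged Logical convergence flag.
#' @return Object of class `temp_field`.
#' @export
temp_field <- function(values, spacing = 1, iterations = 0L,
                       converged = NA) {
  stopifnot(is.matrix(values), all(is.finite(values)), spacing > 0)
  structure(list(values = values, spacing = spacing,
                 iterations = as.integer(iterations),
                 converged = converged),
            class = "temp_field")
}

#' @export
print.temp_field <- function(x, ...) {
  cat(sprintf(paste0("Temperature field: %d x %d pixels, %g mm spacing; ",
                     "range %.4f..%.4f C\n  %d iterations, converged: %s\n"),
              nrow(x$values), ncol(x$values), x$spacing,
              min(x$values), max(x$values), x$iterations, x$converged))
  invisible(x)
}

#' @export
plot.temp_field <- function(x, ...) {
  image(t(x$values)[, nrow(x$values):1], axes = FALSE, asp = 1,
        col = grDevices::hcl.colors(64, "Inferno"), ...)
  invisible(x)
}

# per-pixel coefficient maps (k, rho*cp, wb*rho_b*cp_b, qm) from the label
# map; background rows are filled with surrogate positive values but are
# never used because background pixels are not updated
property_maps <- function(map, props) {
  stopifnot(inherits(map, "tissue_map"), inherits(props, "tissue_properties"))
  lab <- map$labels
  present <- setdiff(unique(as.vector(lab)), 0L)
  known <- props$tissues$code
  if (length(setdiff(present, known)))
    stop("configuration error: tissues present in the map lack properties")
  idx <- match(lab, props$tissues$code)   # NA on background
  pick <- function(col, bg = 1) {
    v <- props$tissues[[col]][idx]
    v[is.na(v)] <- bg
    matrix(v, nrow(lab), ncol(lab))
  }
  list(k = pick("k"), rc = pick("rho") * pick("cp"),
       p = pick("wb", 0) * props$rho_b * props$cp_b, q = pick("qm", 0))
}

#' Explicit stability bound on the time step
#'
#' For the forward-Euler scheme the time step must satisfy, for every
#' tissue present,
#' \deqn{\Delta t \le \frac{2 \Delta x^2 \rho C_p}
#'                         {\omega_b \rho_b C_{pb} \Delta x^2 + 12 k}}
#' with \eqn{\Delta x} in metres.  Returns the minimum of the bound over the
#' non-background tissues of the map.
#'
#' @param map A [tissue_map()].
#' @param props A [tissue_properties()] table.
#' @return Maximum stable time step in seconds.
#' @export
#' @examples
#' ph <- make_circular_phantom(64, 1, 10)
#' max_stable_dt(ph, tissue_properties())
max_stable_dt <- function(map, props) {
  stopifnot(inherits(map, "tissue_map"), inherits(props, "tissue_properties"))
  present <- setdiff(unique(as.vector(map$labels)), 0L)
  if (length(setdiff(present, props$tissues$code)))
    stop("configuration error: tissues present in the map lack properties")
  dx <- map$spacing / 1000
  tt <- props$tissues[props$tissues$code %in% present, ]
  bounds <- 2 * dx^2 * tt$rho * tt$cp /
    (tt$wb * props$rho_b * props$cp_b * dx^2 + 12 * tt$k)
  min(bounds)
}

check_dt <- function(map, props, config) {
  bound <- max_stable_dt(map, props)
  if (config$dt > bound)
    stop(sprintf(paste0("stability error: dt = %g s exceeds the explicit ",
                        "stability bound %g s for this map"),
                 config$dt, bound))
  invisible(bound)
}

#' Steady-state bioheat solve
#'
#' Iterates the explicit update on all non-background pixels from a uniform
#' initial temperature until the largest absolute per-pixel change between
#' consecutive iterations drops below `config$conv_tol`, or `max_iters` is
#' reached.  Background pixels stay at `config$t_boundary` throughout.
#'
#' @param map A [tissue_map()].
#' @param props A [tissue_properties()] table.
#' @param config A [solver_config()].
#' @return A [temp_field()] with convergence metadata.
#' @export
#' @examples
#' ph <- make_circular_phantom(64, 1, 10)
#' fld <- solve_steady(ph, tissue_properties(), solver_config(max_iters = 5000))
solve_steady <- function(map, props = tissue_properties(),
                         config = solver_config()) {
  stopifnot(inherits(config, "solver_config"))
  check_dt(map, props, config)
  pm <- property_maps(map, props)
  brain <- matrix(as.integer(brain_mask(map)),
                  nrow(map$labels), ncol(map$labels))
  T0 <- matrix(config$t_boundary, nrow(map$labels), ncol(map$labels))
  T0[brain == 1L] <- config$t_init
  dx <- map$spacing / 1000
  res <- .pennes_steady_cpp(T0, brain, pm$k, pm$rc, pm$p, pm$q,
                            config$dt, dx^2, props$t_a,
                            config$conv_tol, config$max_iters,
                            as.integer(config$conductivity == "harmonic"))
  temp_field(res$values, map$spacing, res$iterations, res$converged)
}

#' Transient bioheat solve with sampled snapshots
#'
#' Steps the explicit scheme from a given initial field (typically a steady
#' field after [apply_cold_stress()]) and records the field at each
#' requested time.  No convergence stop is applied.
#'
#' @param map A [tissue_map()].
#' @param props A [tissue_properties()] table.
#' @param config A [solver_config()]; `config$dt` is the step size.
#' @param initial A [temp_field()] to start from.
#' @param sample_times Ascending times in seconds, multiples of `config$dt`.
#' @return Named list of [temp_field()]s, one per sample time.
#' @export
solve_transient <- function(map, props, config, initial, sample_times) {
  stopifnot(inherits(config, "solver_config"), inherits(initial, "temp_field"),
            length(sample_times) >= 1, !is.unsorted(sample_times),
            all(sample_times >= 0))
  steps <- sample_times / config$dt
  if (any(abs(steps - round(steps)) > 1e-8))
    stop("sample_times must be multiples of config$dt")
  steps <- as.integer(round(steps))
  check_dt(map, props, config)
  if (!all(dim(initial$values) == dim(map$labels)))
    stop("initial field shape does not match the label map")
  pm <- property_maps(map, props)
  brain <- matrix(as.integer(brain_mask(map)),
                  nrow(map$labels), ncol(map$labels))
  T0 <- initial$values
  T0[brain == 0L] <- config$t_boundary
  dx <- map$spacing / 1000
  snaps <- .pennes_transient_cpp(T0, brain, pm$k, pm$rc, pm$p, pm$q,
                                 config$dt, dx^2, props$t_a, steps,
                                 as.integer(config$conductivity == "harmonic"))
  out <- lapply(seq_along(snaps), function(s)
    temp_field(snaps[[s]], map$spacing, steps[s], NA))
  names(out) <- paste0("t", sample_times)
  out
}

#' Apply a uniform cold stress
#'
#' Subtracts `t_cold` from every pixel of the field, the protocol used to
#' probe transient thermal recovery (typical values 0.25, 0.5 and 1 C).
#'
#' @param field A [temp_field()].
#' @param t_cold Non-negative temperature decrement in degrees C.
#' @return The cooled [temp_field()].
#' @export
apply_cold_stress <- function(field, t_cold) {
  stopifnot(inherits(field, "temp_field"), t_cold >= 0)
  temp_field(field$values - t_cold, field$spacing, field$iterations, NA)
}

#' Add seeded Gaussian noise to a temperature field
#'
#' Adds zero-mean Gaussian noise whose standard deviation is `percent` per
#' cent of a reference scale.  With `reference = "range"` (default) the
#' scale is the dynamic range of the field over brain pixels, which keeps
#' the tumor contrast-to-noise ratio comparable across phantoms; with
#' `reference = "absolute"` the scale is the local absolute temperature.
#'
#' @param field A [temp_field()].
#' @param percent Noise level in per cent (e.g. 2).
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @param brain Optional logical matrix restricting the reference-range
#'   computation (and noise injection) to brain pixels.  Default: all
#'   pixels.
#' @param reference `"range"` or `"absolute"`.
#' @return The noisy [temp_field()].
#' @export
add_noise <- function(field, percent, seed = 1, brain = NULL,
                      reference = c("range", "absolute")) {
  stopifnot(inherits(field, "temp_field"), percent >= 0)
  reference <- match.arg(reference)
  if (percent == 0) return(field)
  v <- field$values
  sel <- if (is.null(brain)) matrix(TRUE, nrow(v), ncol(v)) else brain
  stopifnot(all(dim(sel) == dim(v)))
  noise <- with_seed(seed, matrix(rnorm(length(v)), nrow(v), ncol(v)))
  if (reference == "range") {
    sigma <- percent / 100 * diff(range(v[sel]))
    v[sel] <- v[sel] + sigma * noise[sel]
  } else {
    v[sel] <- v[sel] + (percent / 100) * abs(v[sel]) * noise[sel]
  }
  temp_field(v, field$spacing, field$iterations, field$converged)
}
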