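#' Tissue codes used in label maps
#'
#' Integer codes for the five tissue classes a label map may contain.
#' Background is everything outside the head and acts as the Dirichlet
#' boundary of the thermal simulation.
#'
#' @return Named integer vector with entries `BACKGROUND`, `CSF`, `GM`,
#'   `WM`, `TUMOR`.
#' @export
#' @examples
#' tissue_codes()["TUMOR"]
tissue_codes <- function() {
  c(BACKGROUND = 0L, CSF = 1L, GM = 2L, WM = 3L, TUMOR = 4L)
}

#' Thermal tissue property table
#'
#' Per-tissue thermal properties driving the bioheat simulation, plus the
#' global blood constants.  Defaults are the standard literature values for
#' brain tissue: thermal conductivity `k` (W/(m*C)), density `rho` (kg/m^3),
#' specific heat `cp` (J/(kg*C)), metabolic heat generation `qm` (W/m^3) and
#' blood perfusion rate `wb` (1/s, i.e. ml blood per ml tissue per second).
#' Blood has density 1052 kg/m^3, specific heat 3800 J/(kg*C) and arterial
#' temperature 37 C.
#'
#' Two conventions for the tumor perfusion rate circulate (0.0016 1/s in the
#' simulation literature's sensitivity sweeps, 0.0005 1/s in some property
#' compilations); the default is 0.0016 and can be overridden with
#' `tumor_wb`.
#'
#' @param tumor_wb Blood perfusion rate of the tumor (1/s).
#' @param tumor_qm Metabolic heat generation of the tumor (W/m^3).
#' @return Object of class `tissue_properties`: a list with a `tissues`
#'   data frame (rows CSF, GM, WM, TUMOR) and blood constants `rho_b`,
#'   `cp_b`, `t_a`.
#' @export
#' @examples
#' tissue_properties()$tissues
tissue_properties <- function(tumor_wb = 0.0016, tumor_qm = 25000) {
  stopifnot(tumor_wb >= 0, tumor_qm >= 0)
  tissues <- data.frame(
    tissue = c("CSF", "GM", "WM", "TUMOR"),
    code   = c(1L, 2L, 3L, 4L),
    k      = c(0.6, 0.565, 0.503, 0.565),
    rho    = c(1000, 1035.5, 1027.4, 1027.4),
    cp     = c(4200, 3680, 3600, 3600),
    qm     = c(0, 16229, 4517.9, tumor_qm),
    wb     = c(0, 0.013289, 0.0036956, tumor_wb),
    stringsAsFactors = FALSE
  )
  structure(list(tissues = tissues, rho_b = 1052, cp_b = 3800, t_a = 37),
            class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat("Tissue thermal properties\n")
  print(x$tissues, row.names = FALSE)
  cat(sprintf("Blood: rho_b = %g kg/m^3, cp_b = %g J/(kg C), Ta = %g C\n",
              x$rho_b, x$cp_b, x$t_a))
  invisible(x)
}

#' Set a property value for one tissue
#'
#' @param props A [tissue_properties()] object.
#' @param tissue Tissue name (`"CSF"`, `"GM"`, `"WM"`, `"TUMOR"`).
#' @param ... Named values among `k`, `rho`, `cp`, `qm`, `wb`.
#' @return The modified `tissue_properties` object.
#' @export
set_tissue_property <- function(props, tissue, ...) {
  stopifnot(inherits(props, "tissue_properties"))
  row <- match(tissue, props$tissues$tissue)
  if (is.na(row)) stop("unknown tissue: ", tissue)
  vals <- list(...)
  for (nm in names(vals)) {
    if (!nm %in% c("k", "rho", "cp", "qm", "wb"))
      stop("unknown property: ", nm)
    props$tissues[[nm]][row] <- vals[[nm]]
  }
  props
}

#' Solver configuration for the bioheat scheme
#'
#' @param dt Time step in seconds (default 0.1 s; checked against the
#'   explicit stability bound at solve time).
#' @param conv_tol Convergence threshold in degrees C: the steady solve
#'   stops when the largest per-pixel change between consecutive iterations
#'   falls below it (default 1e-7).
#' @param max_iters Iteration cap for the steady solve.
#' @param t_init Initial temperature (C), normal body temperature by default.
#' @param t_boundary Dirichlet temperature of background pixels (C).
#' @param conductivity `"center"` evaluates the Laplacian with the centre
#'   pixel's conductivity (matching the per-pixel update equation);
#'   `"harmonic"` uses harmonic-mean face conductivities in flux form.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.1, conv_tol = 1e-7, max_iters = 500000L,
                          t_init = 37, t_boundary = 37,
                          conductivity = c("center", "harmonic")) {
  stopifnot(dt > 0, conv_tol > 0, max_iters >= 1)
  conductivity <- match.arg(conductivity)
  structure(list(dt = dt, conv_tol = conv_tol,
                 max_iters = as.integer(max_iters),
                 t_init = t_init, t_boundary = t_boundary,
                 conductivity = conductivity),
            class = "solver_config")
}

#' @export
print.solver_config <- function(x, ...) {
  cat(sprintf(paste0("Bioheat solver config: dt = %g s, tol = %g C, ",
                     "max_iters = %d,\n  T_init = %g C, T_boundary = %g C, ",
                     "conductivity = %s\n"),
              x$dt, x$conv_tol, x$max_iters, x$t_init, x$t_boundary,
              x$conductivity))
  invisible(x)
}
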