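#' Closed-form steady temperature of a circular heat source
#'
#' Analytic validation oracle for the finite-difference solver: the steady,
#' axisymmetric solution of the bioheat equation for a disc of tumor tissue
#' of radius `a` embedded in an infinite homogeneous surround,
#' \deqn{k \nabla^2 \theta = P\,\theta - Q_m, \qquad P = \omega_b \rho_b C_{pb},}
#' where \eqn{\theta = T - T_a} is the rise above arterial temperature.
#' Inside the disc \eqn{\theta(r) = Q_{m,t}/P_t + A\,I_0(r/L_t)}, outside
#' \eqn{\theta(r) = Q_{m,s}/P_s + B\,K_0(r/L_s)} with diffusion lengths
#' \eqn{L = \sqrt{k/P}}; the coefficients A and B are fixed by continuity
#' of \eqn{\theta} and of the radial flux \eqn{k\,d\theta/dr} at `r = a`.
#' \eqn{I_0, I_1, K_0, K_1} are modified Bessel functions.
#'
#' @param radius Disc radius in metres.
#' @param tumor List with `k` (W/(m C)), `qm` (W/m^3), `wb` (1/s) for the
#'   disc tissue.
#' @param surround Same-structure list for the surround; `wb` must be
#'   positive (the surround must be perfused for a bounded far field).
#' @param blood List with `rho_b`, `cp_b` (defaults 1052, 3800) and
#'   optionally `t_a`.
#' @return Object of class `disc_reference`: a list with the profile
#'   function `theta(r)` (temperature rise above Ta, vectorized over r in
#'   metres), coefficients `A`, `B`, plateaus `theta_tumor_inf`,
#'   `theta_surround_inf`, diffusion lengths `L_t`, `L_s`, and
#'   `center_rise = theta(0) - theta_surround_inf`.
#' @export
#' @examples
#' ref <- disc_reference_temperature(
#'   0.01,
#'   tumor = list(k = 0.565, qm = 25000, wb = 0.0016),
#'   surround = list(k = 0.503, qm = 4517.9, wb = 0.0036956))
#' ref$theta(0)        # rise above Ta at the tumor centre
#' ref$center_rise    # rise above the tumor-free surround plateau
disc_reference_temperature <- function(radius, tumor, surround,
                                       blood = list(rho_b = 1052,
                                                    cp_b = 3800)) {
  stopifnot(radius > 0, surround$wb > 0, tumor$k > 0, surround$k > 0,
            tumor$wb >= 0)
  Pt <- tumor$wb * blood$rho_b * blood$cp_b
  Ps <- surround$wb * blood$rho_b * blood$cp_b
  Ls <- sqrt(surround$k / Ps)
  Cs <- surround$qm / Ps
  xs <- radius / Ls
  # exponentially scaled Bessel functions keep the interface system
  # well-conditioned for radii much larger than the diffusion lengths
  i0s <- function(x) besselI(x, 0, expon.scaled = TRUE)
  i1s <- function(x) besselI(x, 1, expon.scaled = TRUE)
  k0s <- function(x) besselK(x, 0, expon.scaled = TRUE)
  k1s <- function(x) besselK(x, 1, expon.scaled = TRUE)
  if (Pt > 0) {
    Lt <- sqrt(tumor$k / Pt)
    Ct <- tumor$qm / Pt
    xt <- radius / Lt
    # continuity of theta and flux at r = a, in the scaled coefficients
    # alpha = A e^{xt}, beta = B e^{-xs}:
    #   alpha I0s(xt) - beta K0s(xs) = Cs - Ct
    #   kt alpha I1s(xt)/Lt + ks beta K1s(xs)/Ls = 0
    M <- rbind(c(i0s(xt), -k0s(xs)),
               c(tumor$k * i1s(xt) / Lt, surround$k * k1s(xs) / Ls))
    ab <- solve(M, c(Cs - Ct, 0))
    alpha <- ab[1]; beta <- ab[2]
    A <- alpha * exp(-xt)
    B <- beta * exp(min(xs, 700))
    inside <- function(r) Ct + alpha * i0s(r / Lt) * exp(r / Lt - xt)
    outside <- function(r) Cs + beta * k0s(r / Ls) * exp(xs - r / Ls)
  } else {
    # unperfused disc: k theta'' + k theta'/r = -Qm, a parabolic interior
    # matched to the K0 exterior through flux and continuity at r = a
    Lt <- Inf
    Ct <- Inf
    beta <- tumor$qm * radius * Ls / (2 * surround$k) / k1s(xs)
    C0 <- Cs + beta * k0s(xs) + tumor$qm * radius^2 / (4 * tumor$k)
    A <- NA_real_
    B <- beta * exp(min(xs, 700))
    inside <- function(r) C0 - tumor$qm * r^2 / (4 * tumor$k)
    outside <- function(r) Cs + beta * k0s(r / Ls) * exp(xs - r / Ls)
  }
  theta <- function(r) {
    r <- abs(r)
    out <- numeric(length(r))
    inb <- r <= radius
    out[inb] <- inside(r[inb])
    out[!inb] <- outside(r[!inb])
    out
  }
  structure(list(theta = theta, A = A, B = B,
                 theta_tumor_inf = Ct, theta_surround_inf = Cs,
                 L_t = Lt, L_s = Ls, radius = radius,
                 center_rise = theta(0) - Cs),
            class = "disc_reference")
}

#' @export
print.disc_reference <- function(x, ...) {
  cat(sprintf(paste0("Closed-form disc source: a = %g mm, L_t = %g mm, ",
                     "L_s = %g mm\n  theta(0) = %.4f C above Ta, ",
                     "center rise above surround plateau = %.4f C\n"),
              x$radius * 1000, x$L_t * 1000, x$L_s * 1000,
              x$theta(0), x$center_rise))
  invisible(x)
}
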