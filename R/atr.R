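# Polarized ATR linear dichroism: two-phase (Harrick thick-film) effective
# field amplitudes, isotropic dichroic ratio, incidence-angle inversion, and
# resolution of parallel/perpendicular absorbances into in-plane (xy) and
# membrane-normal (z) components.

#' Mid-infrared refractive index of silicon (internal reflection element)
#' @export
n_silicon <- 3.42

#' Mid-infrared refractive index of liquid water (calibration medium)
#' @export
n_water_midIR <- 1.32

#' ATR measurement geometry
#'
#' @param alpha angle of incidence inside the internal reflection element,
#'   degrees; must exceed the critical angle `asin(n3/n1)`.
#' @param n1 refractive index of the internal reflection element (silicon:
#'   3.42 in the mid-IR).
#' @param n3 refractive index of the sample medium (water 1.32; rehydrated
#'   membrane-protein film 1.6).
#' @return an object of class `atr_geometry`.
#' @export
atr_geometry <- function(alpha, n1 = n_silicon, n3 = 1.6) {
  if (!(alpha > 0 && alpha < 90)) stop("alpha must lie in (0, 90) degrees")
  if (!(n1 > n3 && n3 > 0)) stop("need n1 > n3 > 0 for internal reflection")
  theta_c <- asin(n3 / n1) * 180 / pi
  if (alpha <= theta_c)
    stop(sprintf(paste0("total internal reflection violated: alpha = %.3f deg",
                        " is not above the critical angle %.3f deg"),
                 alpha, theta_c))
  structure(list(alpha = alpha, n1 = n1, n3 = n3, theta_c = theta_c),
            class = "atr_geometry")
}

#' @export
print.atr_geometry <- function(x, ...) {
  e <- field_amplitudes(x)
  cat(sprintf("atr_geometry: alpha = %g deg, n1 = %g, n3 = %g (theta_c = %.2f deg)\n",
              x$alpha, x$n1, x$n3, x$theta_c))
  cat(sprintf("  Ex^2 = %.4f, Ey^2 = %.4f, Ez^2 = %.4f, R_iso = %.4f\n",
              e[["Ex2"]], e[["Ey2"]], e[["Ez2"]], iso_dichroic_ratio(x)))
  invisible(x)
}

#' Squared effective evanescent-field amplitudes (two-phase thick film)
#'
#' Harrick's thick-film approximation for a bulk sample of index n3 on an
#' internal reflection element of index n1: with n31 = n3/n1,
#' s = sin^2(alpha), c2 = cos^2(alpha) and
#' D = (1 - n31^2) ((1 + n31^2) s - n31^2),
#' Ey^2 = 4 c2 / (1 - n31^2), Ex^2 = 4 c2 (s - n31^2) / D,
#' Ez^2 = 4 c2 s / D.
#'
#' @param geometry an [atr_geometry].
#' @return named vector `c(Ex2, Ey2, Ez2)`.
#' @export
field_amplitudes <- function(geometry) {
  stopifnot(inherits(geometry, "atr_geometry"))
  a <- geometry$alpha * pi / 180
  n31 <- geometry$n3 / geometry$n1
  s <- sin(a)^2
  c2 <- cos(a)^2
  D <- (1 - n31^2) * ((1 + n31^2) * s - n31^2)
  c(Ex2 = 4 * c2 * (s - n31^2) / D,
    Ey2 = 4 * c2 / (1 - n31^2),
    Ez2 = 4 * c2 * s / D)
}

#' Isotropic dichroic ratio
#'
#' Ratio of parallel- to perpendicular-polarized absorbance of a thick
#' isotropic absorber: R = (Ex^2 + Ez^2) / Ey^2, which reduces to
#' `(2 s - n31^2) / ((1 + n31^2) s - n31^2)` with s = sin^2(alpha).  At
#' alpha = 39 deg on silicon against water this evaluates to 2.10, the
#' calibration value used to fix the incidence angle.
#'
#' @param geometry an [atr_geometry].
#' @return the dichroic ratio (dimensionless).
#' @export
iso_dichroic_ratio <- function(geometry) {
  e <- field_amplitudes(geometry)
  unname((e[["Ex2"]] + e[["Ez2"]]) / e[["Ey2"]])
}

#' Invert the isotropic dichroic ratio for the incidence angle
#'
#' Bracketed root-finding of `iso_dichroic_ratio(alpha) = R` on
#' (critical angle, 90 deg); R is strictly decreasing in alpha there, so the
#' root is unique.  The attainable range is (2 - n31^2, R(theta_c+)).
#'
#' @param R measured isotropic dichroic ratio.
#' @param n1,n3 refractive indices of element and sample.
#' @param tol root tolerance, degrees.
#' @return the incidence angle, degrees.
#' @export
angle_from_ratio <- function(R, n1 = n_silicon, n3 = n_water_midIR,
                             tol = 1e-6) {
  if (!(n1 > n3 && n3 > 0)) stop("need n1 > n3 > 0")
  n31 <- n3 / n1
  theta_c <- asin(n31) * 180 / pi
  ratio_of <- function(alpha) {
    s <- sin(alpha * pi / 180)^2
    (2 * s - n31^2) / ((1 + n31^2) * s - n31^2)
  }
  R_min <- 2 - n31^2                 # alpha -> 90 deg limit
  R_max <- ratio_of(theta_c * (1 + 1e-12) + 1e-9)
  if (R <= R_min || R >= R_max)
    stop(sprintf("R = %g outside the attainable range (%.6f, %.6f)",
                 R, R_min, R_max))
  stats::uniroot(function(a) ratio_of(a) - R,
                 lower = theta_c + 1e-9, upper = 90 - 1e-9,
                 tol = tol)$root
}

#' Resolve polarized absorbances into in-plane and normal components
#'
#' Uniaxial thick-film model: A_perp = Ey^2 a_xy and
#' A_par = Ex^2 a_xy + Ez^2 a_z, inverted per grid point as
#' A_xy = A_perp / Ey^2 and A_z = (A_par - (Ex^2/Ey^2) A_perp) / Ez^2.
#' The normalization makes an isotropic absorber give A_xy = A_z.
#'
#' @param nu wavenumber grid, cm^-1.
#' @param A_par,A_perp absorbance with polarization parallel /
#'   perpendicular to the plane of incidence, on the same grid.
#' @param geometry an [atr_geometry].
#' @return an object of class `dichroic_spectra`: data-frame-like list with
#'   `nu`, `A_par`, `A_perp`, `A_xy`, `A_z` and `R = A_par/A_perp`
#'   (NA where `A_perp` is 0).
#' @export
resolve_components <- function(nu, A_par, A_perp, geometry) {
  stopifnot(inherits(geometry, "atr_geometry"))
  if (length(A_par) != length(nu) || length(A_perp) != length(nu))
    stop("A_par, A_perp and nu must have equal length")
  e <- field_amplitudes(geometry)
  A_xy <- A_perp / e[["Ey2"]]
  A_z <- (A_par - (e[["Ex2"]] / e[["Ey2"]]) * A_perp) / e[["Ez2"]]
  R <- ifelse(A_perp != 0, A_par / A_perp, NA_real_)
  structure(list(nu = as.numeric(nu), A_par = as.numeric(A_par),
                 A_perp = as.numeric(A_perp), A_xy = A_xy, A_z = A_z, R = R,
                 geometry = geometry),
            class = "dichroic_spectra")
}

#' Forward-synthesize polarized absorbances from resolved components
#'
#' Inverse of [resolve_components]: A_perp = Ey^2 a_xy,
#' A_par = Ex^2 a_xy + Ez^2 a_z.
#'
#' @param a_xy,a_z in-plane and normal absorber strengths per grid point.
#' @param geometry an [atr_geometry].
#' @return list with `A_par` and `A_perp`.
#' @export
synthesize_polarized <- function(a_xy, a_z, geometry) {
  e <- field_amplitudes(geometry)
  list(A_par = e[["Ex2"]] * a_xy + e[["Ez2"]] * a_z,
       A_perp = e[["Ey2"]] * a_xy)
}

#' @export
print.dichroic_spectra <- function(x, ...) {
  cat("dichroic_spectra:", length(x$nu), "grid points, alpha =",
      x$geometry$alpha, "deg, n =", x$geometry$n3, "\n")
  invisible(x)
}

#' @export
as.data.frame.dichroic_spectra <- function(x, ...) {
  data.frame(`wavenumber_cm-1` = x$nu, A_par = x$A_par, A_perp = x$A_perp,
             A_xy = x$A_xy, A_z = x$A_z, R = x$R, check.names = FALSE)
}

#' @export
plot.dichroic_spectra <- function(x, ...) {
  graphics::matplot(x$nu, cbind(x$A_xy, x$A_z), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = expression(paste(nu, " (", cm^-1, ")")),
                    ylab = "A (resolved)", ...)
  graphics::legend("topright", c(expression(A[xy]), expression(A[z])),
                   lty = 1, col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Sensitivity of the resolved components to geometry assumptions
#'
#' Re-resolves the polarized pair for every combination of incidence angle
#' and sample index and reports the maximum absolute deviation of A_xy and
#' A_z from the reference geometry, the standard robustness check for the
#' alpha/n uncertainty of an ATR film experiment.
#'
#' @param nu,A_par,A_perp as in [resolve_components].
#' @param alphas incidence angles to scan, degrees.
#' @param n3s sample refractive indices to scan.
#' @param reference the reference [atr_geometry].
#' @return list with `reference` (resolved at the reference geometry),
#'   `scan` (data frame: alpha, n3, max_dev_xy, max_dev_z) and `resolved`
#'   (list of `dichroic_spectra`, one per scan pair).
#' @export
sensitivity_scan <- function(nu, A_par, A_perp, alphas = c(37, 39, 41),
                             n3s = c(1.5, 1.6, 1.7),
                             reference = atr_geometry(39, n3 = 1.6)) {
  ref <- resolve_components(nu, A_par, A_perp, reference)
  grid <- expand.grid(alpha = alphas, n3 = n3s)
  resolved <- vector("list", nrow(grid))
  dev_xy <- dev_z <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- atr_geometry(grid$alpha[i], n1 = reference$n1, n3 = grid$n3[i])
    r <- resolve_components(nu, A_par, A_perp, g)
    resolved[[i]] <- r
    dev_xy[i] <- max(abs(r$A_xy - ref$A_xy))
    dev_z[i] <- max(abs(r$A_z - ref$A_z))
  }
  list(reference = ref,
       scan = cbind(grid, max_dev_xy = dev_xy, max_dev_z = dev_z),
       resolved = resolved)
}
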