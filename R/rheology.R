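#' Newtonian blood model
#'
#' Constant-viscosity incompressible blood: dynamic viscosity 0.0035 Pa s and
#' density 1060 kg/m^3 by default, the standard whole-blood values used in
#' coronary CFD.
#'
#' @param mu Dynamic viscosity in Pa s (> 0).
#' @param rho Density in kg/m^3 (> 0).
#' @return An object of class \code{c("newtonian_model", "blood_rheology")}.
#' @seealso [gpl_model()], [apparent_viscosity()]
#' @export
newtonian_model <- function(mu = 0.0035, rho = 1060) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0,
            is.numeric(rho), length(rho) == 1L, rho > 0)
  structure(list(mu = mu, rho = rho), class = c("newtonian_model", "blood_rheology"))
}

#' Generalized power law blood model
#'
#' Shear-thinning viscosity mu(gdot) = lambda(gdot) * |gdot|^(n(gdot) - 1) with
#' shear-dependent consistency lambda and index n that interpolate between a
#' low-shear power-law regime and a high-shear Newtonian asymptote:
#' \deqn{\lambda(\dot\gamma) = \mu_\infty + \Delta\mu\,
#'   \exp[-(1 + |\dot\gamma|/a)\exp(-b/|\dot\gamma|)]}
#' \deqn{n(\dot\gamma) = n_\infty - \Delta n\,
#'   \exp[-(1 + |\dot\gamma|/c)\exp(-d/|\dot\gamma|)]}
#'
#' The constants are in poise (1 poise = 0.1 Pa s), so the high-shear
#' consistency asymptote mu_inf = 0.035 poise equals the Newtonian
#' 0.0035 Pa s. [apparent_viscosity()] converts to SI. The model is a fit to
#' rheometry over 0.1 < gdot < 1000 1/s; shear rates are clamped to
#' \code{gamma_range} before evaluation (the apparent viscosity diverges as
#' gdot -> 0 when n < 1).
#'
#' @param mu_inf High-shear consistency asymptote, poise.
#' @param n_inf High-shear power-law index asymptote (0 < n_inf <= 1).
#' @param delta_mu Low-shear consistency increment, poise (>= 0).
#' @param delta_n Low-shear index decrement (0 <= delta_n < n_inf).
#' @param a,b,c,d Shape constants, 1/s scaled.
#' @param gamma_range Validity window of the fit, 1/s.
#' @param rho Density in kg/m^3.
#' @return An object of class \code{c("gpl_model", "blood_rheology")}.
#' @export
gpl_model <- function(mu_inf = 0.035, n_inf = 1.0, delta_mu = 0.25,
                      delta_n = 0.45, a = 50, b = 3, c = 50, d = 4,
                      gamma_range = c(0.1, 1000), rho = 1060) {
  stopifnot(mu_inf > 0, n_inf > 0, n_inf <= 1, delta_mu >= 0,
            delta_n >= 0, delta_n < n_inf,
            length(gamma_range) == 2L, gamma_range[1] < gamma_range[2],
            gamma_range[1] > 0, rho > 0)
  structure(list(mu_inf = mu_inf, n_inf = n_inf, delta_mu = delta_mu,
                 delta_n = delta_n, a = a, b = b, c = c, d = d,
                 gamma_range = gamma_range, rho = rho),
            class = c("gpl_model", "blood_rheology"))
}

#' Shear rate magnitude from a velocity gradient tensor
#'
#' gdot = sqrt(2 D:D) where D = (L + t(L))/2 is the rate-of-strain tensor of
#' the velocity gradient L (L[i,j] = d u_i / d x_j).
#'
#' @param grad A 2x2 velocity gradient tensor (1/s), or an n x 4 matrix with
#'   columns (du/dx, du/dy, dv/dx, dv/dy) for vectorized evaluation.
#' @return Non-negative shear rate(s), 1/s.
#' @export
shear_rate_magnitude <- function(grad) {
  if (is.matrix(grad) && all(dim(grad) == c(2L, 2L))) {
    d <- (grad + t(grad)) / 2
    return(sqrt(2 * sum(d * d)))
  }
  stopifnot(is.matrix(grad), ncol(grad) == 4L)
  ux <- grad[, 1]; uy <- grad[, 2]; vx <- grad[, 3]; vy <- grad[, 4]
  sqrt(2 * ux^2 + 2 * vy^2 + (uy + vx)^2)
}

#' Shear-dependent consistency lambda of the generalized power law
#'
#' @param gdot Shear rate(s), 1/s (positive; not clamped here).
#' @param model A [gpl_model()].
#' @return Consistency in poise, between mu_inf and mu_inf + delta_mu.
#' @export
gpl_lambda <- function(gdot, model) {
  g <- abs(gdot)
  model$mu_inf + model$delta_mu * exp(-(1 + g / model$a) * exp(-model$b / g))
}

#' Shear-dependent power-law index n of the generalized power law
#'
#' @inheritParams gpl_lambda
#' @return Dimensionless index between n_inf - delta_n and n_inf.
#' @export
gpl_n <- function(gdot, model) {
  g <- abs(gdot)
  model$n_inf - model$delta_n * exp(-(1 + g / model$c) * exp(-model$d / g))
}

#' Apparent dynamic viscosity of a blood model
#'
#' Newtonian models return their constant viscosity. Generalized power law
#' models clamp the shear rate to the model's validity window, evaluate
#' lambda * gdot^(n-1) in poise and convert to Pa s (x 0.1).
#'
#' @param gdot Shear rate(s), 1/s (any non-negative values; clamped for GPL).
#' @param model A [newtonian_model()] or [gpl_model()].
#' @return Apparent viscosity in Pa s, same length as \code{gdot}.
#' @export
apparent_viscosity <- function(gdot, model) {
  UseMethod("apparent_viscosity", model)
}

#' @export
apparent_viscosity.newtonian_model <- function(gdot, model) {
  rep_len(model$mu, length(gdot))
}

#' @export
apparent_viscosity.gpl_model <- function(gdot, model) {
  g <- pmin(pmax(abs(gdot), model$gamma_range[1]), model$gamma_range[2])
  lam <- gpl_lambda(g, model)
  n <- gpl_n(g, model)
  0.1 * lam * g^(n - 1)
}

#' @export
print.blood_rheology <- function(x, ...) {
  if (inherits(x, "newtonian_model")) {
    cat(sprintf("Newtonian blood: mu = %g Pa s, rho = %g kg/m^3\n", x$mu, x$rho))
  } else {
    cat(sprintf(paste0(
      "Generalized power law blood (constants in poise):\n",
      "  mu_inf = %g, delta_mu = %g, n_inf = %g, delta_n = %g\n",
      "  a = %g, b = %g, c = %g, d = %g; valid %g < gdot < %g 1/s; rho = %g kg/m^3\n"),
      x$mu_inf, x$delta_mu, x$n_inf, x$delta_n, x$a, x$b, x$c, x$d,
      x$gamma_range[1], x$gamma_range[2], x$rho))
  }
  invisible(x)
}
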