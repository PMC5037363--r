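#' Dimensional parameters of the advancing-epithelium model
#'
#' Collects the dimensional material constants of the continuum model: morphogen
#' transport, substrate friction, mechano-sensitive proliferation and
#' chemotactic migration.
#'
#' @param D_e Morphogen diffusivity (length^2/time), shared by the epithelium
#'   and the water bath.
#' @param tau_e Morphogen uptake time in the epithelium (time); sets the time
#'   unit of the dimensionless model.
#' @param K_e Substrate mobility coefficient entering the Darcy law
#'   `v = -K_e grad p`.
#' @param K_p Proliferation rate per unit pressure deficit below the
#'   homeostatic pressure.
#' @param lambda_0 Chemotactic migration coefficient.
#' @param c_i Morphogen concentration scale at the interface, the average of the
#'   two one-sided interface values.
#' @param S_T Surface tension of the tissue edge (may be zero).
#' @param P_h Homeostatic reference pressure (pressures in the model are
#'   measured relative to it).
#'
#' @return An object of class `"dimensional_params"`.
#' @seealso [build_units()], [nondimensionalize()]
#' @export
#' @examples
#' dp <- dimensional_params(D_e = 0.3, tau_e = 2700, K_e = 0.3, K_p = 1/2700,
#'                          lambda_0 = 1.1475, c_i = 2)
dimensional_params <- function(D_e, tau_e, K_e, K_p = 0, lambda_0 = 0,
                               c_i = 1, S_T = 0, P_h = 0) {
  if (!is.numeric(D_e) || D_e <= 0) stop("D_e must be positive", call. = FALSE)
  if (!is.numeric(tau_e) || tau_e <= 0) stop("tau_e must be positive", call. = FALSE)
  if (!is.numeric(K_e) || K_e <= 0) stop("K_e must be positive", call. = FALSE)
  if (K_p < 0) stop("K_p must be non-negative", call. = FALSE)
  if (lambda_0 < 0) stop("lambda_0 must be non-negative", call. = FALSE)
  if (c_i <= 0) stop("c_i must be positive", call. = FALSE)
  if (S_T < 0) stop("S_T must be non-negative", call. = FALSE)
  structure(list(D_e = D_e, tau_e = tau_e, K_e = K_e, K_p = K_p,
                 lambda_0 = lambda_0, c_i = c_i, S_T = S_T, P_h = P_h),
            class = "dimensional_params")
}

#' Unit system induced by the nondimensionalization
#'
#' The model uses the uptake time `tau_e` as time unit, the diffusion length
#' `sqrt(D_e * tau_e)` as length unit, the interface concentration `c_i` as
#' concentration unit and `P_0 = D_e / K_e` as pressure unit. The velocity unit
#' follows as `sqrt(D_e / tau_e)`.
#'
#' @param dp A [dimensional_params()] object.
#' @return An object of class `"unit_system"` with fields `length_unit`,
#'   `time_unit`, `velocity_unit`, `pressure_unit`, `concentration_unit`.
#' @export
#' @examples
#' us <- build_units(dimensional_params(D_e = 0.3, tau_e = 2700, K_e = 0.3))
#' us$length_unit   # ~ 28.46 (micrometres when D_e is in um^2/s, tau_e in s)
build_units <- function(dp) {
  stopifnot(inherits(dp, "dimensional_params"))
  structure(list(
    length_unit        = sqrt(dp$D_e * dp$tau_e),
    time_unit          = dp$tau_e,
    velocity_unit      = sqrt(dp$D_e / dp$tau_e),
    pressure_unit      = dp$D_e / dp$K_e,
    concentration_unit = dp$c_i
  ), class = "unit_system")
}

#' Dimensionless control parameters
#'
#' Constructs the dimensionless parameter set of the model: the chemotactic
#' migration constant `Lambda = lambda_0 c_i / D_e`, the proliferation
#' coefficient `alpha = sqrt(K_p D_e / K_e)`, the border morphogen production
#' rate `N0`, the capillary parameter `sigma` and the dimensionless interface
#' pressure `P_i` (relative to the homeostatic pressure; negative for advancing
#' proliferative fronts).
#'
#' @param Lambda Chemotactic migration constant (>= 0).
#' @param alpha Proliferation coefficient (>= 0).
#' @param N0 Rate of morphogen production at the border (>= 0).
#' @param sigma Dimensionless capillary parameter (> 0).
#' @param P_i Dimensionless interface pressure; may be `NULL` when it is
#'   implied by a prescribed front velocity.
#' @return An object of class `"model_params"`.
#' @export
model_params <- function(Lambda, alpha = 1, N0 = 1, sigma = 1e-3, P_i = NULL) {
  if (Lambda < 0) stop("Lambda must be non-negative", call. = FALSE)
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (N0 < 0) stop("N0 must be non-negative", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.null(P_i) && !is.finite(P_i)) stop("P_i must be finite", call. = FALSE)
  structure(list(Lambda = Lambda, alpha = alpha, N0 = N0, sigma = sigma,
                 P_i = P_i), class = "model_params")
}

#' Nondimensionalize a dimensional parameter set
#'
#' @param dp A [dimensional_params()] object.
#' @param N0 Dimensionless border production rate (not derivable from the
#'   dimensional constants; a property of the interfacial morphogen source).
#' @param P_i Dimensionless interface pressure, optional.
#' @param sigma Dimensionless capillary parameter. By default it is converted
#'   from the surface tension `S_T` via [sigma_from_surface_tension()]; pass a
#'   value to override (sigma is commonly supplied directly).
#' @return A [model_params()] object.
#' @export
#' @examples
#' dp <- dimensional_params(D_e = 0.3, tau_e = 2700, K_e = 0.3, K_p = 1/2700,
#'                          lambda_0 = 1.1475, c_i = 2)
#' nondimensionalize(dp, N0 = 1, sigma = 1e-3)$Lambda   # 7.65
nondimensionalize <- function(dp, N0 = 1, P_i = NULL, sigma = NULL) {
  stopifnot(inherits(dp, "dimensional_params"))
  if (is.null(sigma)) {
    sigma <- if (dp$S_T > 0) sigma_from_surface_tension(dp$S_T, dp) else 1e-3
  }
  model_params(Lambda = dp$lambda_0 * dp$c_i / dp$D_e,
               alpha  = sqrt(dp$K_p * dp$D_e / dp$K_e),
               N0     = N0,
               sigma  = sigma,
               P_i    = P_i)
}

#' Convert a surface tension to the dimensionless capillary parameter
#'
#' The Laplace term `sigma * kappa` in the interface pressure condition is a
#' dimensionless pressure, so `sigma = S_T / (P_0 * L_0)` with pressure unit
#' `P_0 = D_e/K_e` and length unit `L_0 = sqrt(D_e tau_e)`.
#'
#' @param S_T Surface tension in dimensional units.
#' @param dp A [dimensional_params()] object.
#' @return The dimensionless capillary parameter.
#' @export
sigma_from_surface_tension <- function(S_T, dp) {
  stopifnot(inherits(dp, "dimensional_params"))
  us <- build_units(dp)
  S_T / (us$pressure_unit * us$length_unit)
}

#' Convert a dimensionless quantity back to physical units
#'
#' Multiplies by the matching unit; wavenumbers divide by the length unit.
#'
#' @param value Dimensionless value(s).
#' @param kind One of `"length"`, `"time"`, `"velocity"`, `"pressure"`,
#'   `"concentration"`, `"wavenumber"`.
#' @param us A [build_units()] object.
#' @return Physical value(s).
#' @export
#' @examples
#' us <- build_units(dimensional_params(D_e = 0.3, tau_e = 2700, K_e = 0.3))
#' to_dimensional(10, "velocity", us)       # ~ 0.105 um/s front speed
#' 2 * pi / to_dimensional(7.2, "wavenumber", us)  # ~ 24.8 um wavelength
to_dimensional <- function(value, kind, us) {
  stopifnot(inherits(us, "unit_system"))
  kind <- match.arg(kind, c("length", "time", "velocity", "pressure",
                            "concentration", "wavenumber"))
  unit <- switch(kind,
    length        = us$length_unit,
    time          = us$time_unit,
    velocity      = us$velocity_unit,
    pressure      = us$pressure_unit,
    concentration = us$concentration_unit,
    wavenumber    = 1 / us$length_unit)
  value * unit
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dimensionless model parameters\n")
  cat(sprintf("  Lambda = %g, alpha = %g, N0 = %g, sigma = %g\n",
              x$Lambda, x$alpha, x$N0, x$sigma))
  if (!is.null(x$P_i)) cat(sprintf("  P_i = %g\n", x$P_i))
  invisible(x)
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Unit system (tau_e time unit, diffusion-length length unit)\n")
  cat(sprintf("  length %g | time %g | velocity %g | pressure %g | concentration %g\n",
              x$length_unit, x$time_unit, x$velocity_unit, x$pressure_unit,
              x$concentration_unit))
  invisible(x)
}
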