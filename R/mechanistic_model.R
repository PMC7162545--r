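# Compartmental Dl/Cact/Toll model over nuclear cycle 14
#
# Dimensionless dynamics of free cytoplasmic Dl (u) and Dl/Cact complex (w)
# in n = 51 compartments spanning the ventral (x = 0) to dorsal (x = 1)
# half-circumference:
#
#   du_h/dT = a1 lambda_d  (u_{h-1} - 2u_h + u_{h+1}) + a2 beta(x_h) w_h/(kappa + w_h)
#             - a3 gamma u_h
#   dw_h/dT = a4 lambda_dc (w_{h-1} - 2w_h + w_{h+1}) - a5 beta(x_h) w_h/(kappa + w_h)
#             + a6 gamma u_h
#
# beta(x) = beta0 exp(-(x/phi_toll)^2) is the ventrally restricted,
# Toll-mediated dissociation rate of the Dl/Cact complex, saturable with
# Michaelis-Menten constant kappa; gamma re-associates free Dl with Cact.
# All concentrations are nondimensionalized to order 1 at the start of nc14;
# dosage enters through the initial Dl/Cact concentration.

#' Mechanistic model parameters
#'
#' @param lambda_d Intercompartmental exchange rate of free Dl (per time
#'   unit; one time unit is about a minute).
#' @param lambda_dc Exchange rate of the Dl/Cact complex.
#' @param beta_o Maximal Toll-mediated dissociation rate at the ventral
#'   midline.
#' @param phi_toll Width of the Gaussian Toll activity profile in relative DV
#'   coordinate. Default 0.15, matching the ventrally restricted Toll domain
#'   and the wildtype gradient width scale.
#' @param gamma Re-association rate of free Dl with Cact.
#' @param kappa Michaelis-Menten constant for Toll-mediated dissociation
#'   (dimensionless concentration; values below ~1 mean Toll is saturated by
#'   Dl/Cact, whose concentration is of order 1).
#' @param a Numeric vector of six dimensionless weighting factors a1..a6
#'   arising from the nondimensionalization (nuclear import/export equilibria
#'   and geometry). Default all 1. With `a2 = a5` and `a3 = a6` the total
#'   Dl mass (free + complexed) is conserved.
#' @param n_compartments Number of nuclei/compartments across the half
#'   embryo. Default 51, the nc14 nuclear count.
#' @param dosage Initial Dl/Cact concentration multiplier: 0.5, 1, 2 for
#'   1x, 2x (wildtype), 4x embryos.
#' @param t_end Simulated duration in time units; default 60, the length of
#'   nc14.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(lambda_d = 1, lambda_dc = 1, beta_o = 1,
                        phi_toll = 0.15, gamma = 1, kappa = 1,
                        a = rep(1, 6), n_compartments = 51L,
                        dosage = 1, t_end = 60) {
  for (nm in c("lambda_d", "lambda_dc", "beta_o", "gamma"))
    assign(nm, check_scalar(get(nm), nm, nonneg = TRUE))
  phi_toll <- check_scalar(phi_toll, "phi_toll", positive = TRUE)
  kappa <- check_scalar(kappa, "kappa", positive = TRUE)
  dosage <- check_scalar(dosage, "dosage", positive = TRUE)
  t_end <- check_scalar(t_end, "t_end", positive = TRUE)
  if (!is.numeric(a) || length(a) != 6L || any(!is.finite(a)) || any(a < 0))
    stop_invalid("a must be six non-negative weighting factors")
  n_compartments <- as.integer(n_compartments)
  if (n_compartments < 3L) stop_invalid("n_compartments must be >= 3")
  structure(list(lambda_d = lambda_d, lambda_dc = lambda_dc, beta_o = beta_o,
                 phi_toll = phi_toll, gamma = gamma, kappa = kappa,
                 a = as.numeric(a), n_compartments = n_compartments,
                 dosage = dosage, t_end = t_end),
            class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf(
    paste0("Dl/Cact/Toll model: lambda_d = %g, lambda_dc = %g, beta_o = %g,\n",
           "  phi_toll = %g, gamma = %g, kappa = %g; %d compartments, ",
           "dosage %gx wildtype, t_end = %g\n"),
    x$lambda_d, x$lambda_dc, x$beta_o, x$phi_toll, x$gamma, x$kappa,
    x$n_compartments, x$dosage, x$t_end))
  invisible(x)
}

#' Nuclear geometry parameters
#'
#' Dimensionless volumes and nuclear import/export equilibrium constants used
#' for the pseudo-equilibrium nuclear concentrations (`C_nuc ~ K_eq C_cyt`)
#' and the length-scale ratio. Defaults make the geometric factors cancel so
#' that the length-scale ratio reduces to `lambda_dc / lambda_d`; the ratio's
#' role in the screen is ordinal (above/below 1), which any common positive
#' geometry preserves.
#'
#' @param v_nuc,v_cyt Dimensionless nuclear and cytoplasmic volumes (> 0).
#' @param keq_d,keq_dc Nuclear import/export equilibrium constants for free
#'   Dl and for Dl/Cact complex (> 0).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(v_nuc = 1, v_cyt = 1, keq_d = 1, keq_dc = 1) {
  out <- list(v_nuc = check_scalar(v_nuc, "v_nuc", positive = TRUE),
              v_cyt = check_scalar(v_cyt, "v_cyt", positive = TRUE),
              keq_d = check_scalar(keq_d, "keq_d", positive = TRUE),
              keq_dc = check_scalar(keq_dc, "keq_dc", positive = TRUE))
  class(out) <- "geometry_params"
  out
}

#' Toll activity profile
#'
#' Gaussian, ventrally restricted Toll-mediated dissociation rate
#' `beta(x) = beta_o * exp(-(x/phi_toll)^2)`.
#'
#' @param beta_o Maximal rate at the ventral midline (>= 0).
#' @param phi_toll Profile width (> 0).
#' @param x DV coordinate(s).
#' @return Rate value(s).
#' @export
toll_profile <- function(beta_o, phi_toll, x) {
  beta_o <- check_scalar(beta_o, "beta_o", nonneg = TRUE)
  phi_toll <- check_scalar(phi_toll, "phi_toll", positive = TRUE)
  beta_o * exp(-(x / phi_toll)^2)
}

#' Time derivatives of the compartment model
#'
#' Reference R implementation of the model right-hand side; the integrator in
#' [simulate_dl()] uses an equivalent compiled version by default.
#'
#' @param u,w Numeric vectors of length `n_compartments`: free cytoplasmic Dl
#'   and Dl/Cact complex.
#' @param params A [mech_params()] object.
#' @return A list with elements `du` and `dw`.
#' @export
dl_rhs <- function(u, w, params) {
  stopifnot(inherits(params, "mech_params"))
  n <- params$n_compartments
  if (length(u) != n || length(w) != n)
    stop_invalid("u and w must have length n_compartments")
  if (any(!is.finite(u)) || any(!is.finite(w)))
    stop_invalid("non-finite state passed to dl_rhs (u range ",
                 paste(signif(range(u), 3), collapse = ".."), ", w range ",
                 paste(signif(range(w), 3), collapse = ".."), ")")
  a <- params$a
  x <- seq(0, 1, length.out = n)
  lap <- function(v) c(v[1L], v[-n]) - 2 * v + c(v[-1L], v[n])
  toll <- toll_profile(params$beta_o, params$phi_toll, x) * w /
    (params$kappa + w)
  list(du = a[1L] * params$lambda_d * lap(u) + a[2L] * toll -
         a[3L] * params$gamma * u,
       dw = a[4L] * params$lambda_dc * lap(w) - a[5L] * toll +
         a[6L] * params$gamma * u)
}

#' Simulate the Dl/Cact/Toll model over nc14
#'
#' Integrates the compartment model from the uniform initial condition
#' `u = 0`, `w = dosage` (all Dl maternally loaded as Dl/Cact complex) with a
#' stiff-capable solver (lsoda; relative tolerance 1e-6, absolute 1e-9).
#'
#' @param params A [mech_params()] object.
#' @param n_times Number of uniformly spaced output times (>= 61).
#' @param engine `"compiled"` (default) for the C right-hand side, `"R"` for
#'   [dl_rhs()].
#' @return An object of class `dl_simulation`: list with `times`, `x`
#'   (compartment centres), matrices `u` and `w` (time x compartment),
#'   `final_free_dl`, `amplitude` (max of `final_free_dl`) and `params`.
#' @export
simulate_dl <- function(params, n_times = 61L, engine = c("compiled", "R")) {
  stopifnot(inherits(params, "mech_params"))
  engine <- match.arg(engine)
  n <- params$n_compartments
  n_times <- max(61L, as.integer(n_times))
  times <- seq(0, params$t_end, length.out = n_times)
  y0 <- c(rep(0, n), rep(params$dosage, n))
  parms <- c(n, params$lambda_d, params$lambda_dc, params$beta_o,
             params$phi_toll, params$gamma, params$kappa, params$a)

  sol <- if (engine == "compiled") {
    deSolve::lsoda(y = y0, times = times, func = "derivs_dlcact",
                   parms = parms, dllname = "dlrobust",
                   initfunc = "init_dlcact", rtol = 1e-6, atol = 1e-9,
                   maxsteps = 50000)
  } else {
    rhs <- function(t, y, p) {
      d <- dl_rhs(y[seq_len(n)], y[n + seq_len(n)], params)
      list(c(d$du, d$dw))
    }
    deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                   rtol = 1e-6, atol = 1e-9, maxsteps = 50000)
  }
  if (nrow(sol) < n_times || any(!is.finite(sol[, -1L])))
    stop_invalid("solver failed for parameter set: lambda_d=", params$lambda_d,
                 " lambda_dc=", params$lambda_dc, " beta_o=", params$beta_o,
                 " gamma=", params$gamma, " kappa=", params$kappa,
                 " dosage=", params$dosage)

  u <- sol[, 1L + seq_len(n), drop = FALSE]
  w <- sol[, 1L + n + seq_len(n), drop = FALSE]
  dimnames(u) <- dimnames(w) <- NULL
  out <- list(times = sol[, 1L], x = seq(0, 1, length.out = n),
              u = u, w = w,
              final_free_dl = u[n_times, ],
              amplitude = max(u[n_times, ]),
              params = params)
  class(out) <- "dl_simulation"
  out
}

#' @export
print.dl_simulation <- function(x, ...) {
  cat(sprintf(
    "Dl/Cact simulation: %d compartments, %d times over [0, %g], dosage %gx\n",
    length(x$x), length(x$times), max(x$times), x$params$dosage))
  cat(sprintf("  final free-Dl amplitude: %.4g\n", x$amplitude))
  invisible(x)
}

#' Length-scale ratio of complexed to free Dl
#'
#' Ratio of effective diffusivities,
#' `rho = lambda_dc (v_nuc keq_dc + v_cyt) / (lambda_d (v_nuc keq_d + v_cyt))`.
#' Values above 1 mean the Dl/Cact complex spreads farther than free Dl,
#' i.e. Cact facilitates ("shuttles") Dl transport.
#'
#' @param params A [mech_params()] object.
#' @param geom A [geometry_params()] object.
#' @return The scalar ratio.
#' @export
length_scale_ratio <- function(params, geom = geometry_params()) {
  stopifnot(inherits(params, "mech_params"), inherits(geom, "geometry_params"))
  if (params$lambda_d == 0)
    stop_invalid("length-scale ratio undefined: lambda_d is 0")
  params$lambda_dc * (geom$v_nuc * geom$keq_dc + geom$v_cyt) /
    (params$lambda_d * (geom$v_nuc * geom$keq_d + geom$v_cyt))
}

#' Nuclear free-Dl gradient from a simulation
#'
#' Applies the nuclear/cytoplasmic pseudo-equilibrium `C_nuc ~ K_eq C_cyt`
#' to the final cytoplasmic free-Dl profile. A monotone (linear) transform,
#' so threshold-crossing border positions are invariant to `keq_d`.
#'
#' @param sim A [simulate_dl()] result.
#' @param geom A [geometry_params()] object.
#' @return Numeric vector of nuclear free Dl per compartment at `t_end`.
#' @export
nuclear_gradient <- function(sim, geom = geometry_params()) {
  stopifnot(inherits(sim, "dl_simulation"), inherits(geom, "geometry_params"))
  geom$keq_d * sim$final_free_dl
}
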