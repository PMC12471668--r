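#' TST rate constant with recrossing correction
#'
#' Evaluates `k0 = kappa * sqrt(R*T / (2*pi*m_W)) * n(z0)`: the equilibrium
#' one-way dividing-plane crossing rate of the no-recrossing theory (the
#' Maxwell-Boltzmann flux prefactor times the linear density at the plane),
#' corrected by the transmission coefficient kappa measured from event
#' following. All quantities are converted to a coherent SI system before
#' evaluation; the result is in 1/s.
#'
#' @param kappa Transmission (recrossing-correction) coefficient in `[0, 1]`.
#' @param temperature Temperature (K).
#' @param n_z0 Linear water density at the dividing plane (molecules/nm).
#' @param constants A [physical_constants()] list.
#' @return Rate constant k0 in 1/s.
#' @examples
#' rate_constant_k0(1, 298.15, 1)  # ~1.48e11 /s
#' @export
rate_constant_k0 <- function(kappa, temperature, n_z0,
                             constants = physical_constants()) {
  if (any(kappa < 0 | kappa > 1, na.rm = TRUE)) {
    stop("kappa must lie in [0, 1]")
  }
  stopifnot(all(temperature > 0), all(n_z0 >= 0))
  pref_mps <- sqrt(constants$R_J * temperature /
                     (2 * pi * constants$m_W / 1000))
  kappa * pref_mps * n_z0 * 1e9
}

#' Single-channel osmotic permeability from the rate constant
#'
#' `p_f = 2 * k0 * v_W / N_A` (cm^3/s): both permeation directions contribute
#' at equilibrium, and each transported molecule carries one molecular volume
#' of water.
#'
#' @param k0 Rate constant (1/s).
#' @param constants A [physical_constants()] list.
#' @return p_f in cm^3/s.
#' @examples
#' single_channel_pf(1e9)  # ~5.98e-14 cm^3/s
#' @export
single_channel_pf <- function(k0, constants = physical_constants()) {
  stopifnot(all(k0 >= 0))
  2 * k0 * constants$v_W / constants$N_A
}

#' Osmotic conditions across the membrane
#'
#' @param c_e,c_i Extracellular / intracellular impermeant-solute
#'   concentrations (mol/cm^3).
#' @param temperature Temperature (K).
#' @param constants A [physical_constants()] list (used for the dilute-regime
#'   check `(c_e - c_i) * v_W << 1`).
#' @return A list of class `osmotic_conditions`; a warning is issued outside
#'   the dilute regime, where the rate relations lose quantitative accuracy.
#' @export
osmotic_conditions <- function(c_e, c_i, temperature = 298.15,
                               constants = physical_constants()) {
  stopifnot(c_e >= 0, c_i >= 0, temperature > 0)
  x <- (c_e - c_i) * constants$v_W
  dilute <- abs(x) < 1e-2
  if (!dilute) {
    warning(sprintf(
      "(c_e - c_i)*v_W = %.3g: outside the dilute regime, rate relations are approximate", x))
  }
  structure(list(c_e = c_e, c_i = c_i, temperature = temperature,
                 dilute = dilute),
            class = "osmotic_conditions")
}

#' Osmotic net transition rate and water flux
#'
#' Under an osmotic gradient the IC-to-EC rate exceeds the EC-to-IC rate by
#' the activity factor `exp((c_e - c_i) * v_W)`, and each rate is reduced by
#' the solute's displacement of water. With `k0` the equilibrium rate
#' constant (1/s):
#' \describe{
#'   \item{full}{rate `k0 * (exp(dc*v_W) * (1 - c_i*v_W) - (1 - c_e*v_W))`}
#'   \item{linearized}{rate `2 * k0 * dc * v_W` (valid in the dilute,
#'     sub-molar regime)}
#' }
#' where `dc = c_e - c_i`. The volume flux is `J = r * v_W / N_A` (cm^3/s)
#' and the implied single-channel permeability is `p_f = r / (N_A * dc)`,
#' which in linearized mode equals [single_channel_pf()] exactly.
#'
#' @param k0 Rate constant (1/s).
#' @param cond An [osmotic_conditions()] object.
#' @param constants A [physical_constants()] list.
#' @param mode `"linearized"` or `"full"`.
#' @return A list of class `osmotic_rate` with `r` (1/s), `J` (cm^3/s),
#'   `pf_implied` (cm^3/s, NA at equilibrium) and `mode`.
#' @export
osmotic_rate <- function(k0, cond, constants = physical_constants(),
                         mode = c("linearized", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cond, "osmotic_conditions"), k0 >= 0)
  vW <- constants$v_W
  dc <- cond$c_e - cond$c_i
  r <- if (mode == "full") {
    k0 * (exp(dc * vW) * (1 - cond$c_i * vW) - (1 - cond$c_e * vW))
  } else {
    2 * k0 * dc * vW
  }
  J <- r * vW / constants$N_A
  pf_implied <- if (dc != 0) r / (constants$N_A * dc) else NA_real_
  structure(list(r = r, J = J, pf_implied = pf_implied, mode = mode),
            class = "osmotic_rate")
}

#' Arrhenius activation energy from two permeabilities
#'
#' `E_a = R * T1 * ln(p1/p2) / (T1/T2 - 1)`, reported in kcal/mol. The sign
#' convention makes E_a positive when permeability grows with temperature
#' (p2 > p1 for T2 > T1).
#'
#' @param p1,p2 Permeabilities (any common unit) at `T1` and `T2`.
#' @param T1,T2 Temperatures (K), `T1 != T2`.
#' @param constants A [physical_constants()] list.
#' @return An object of class `arrhenius_result` with element `E_a`
#'   (kcal/mol).
#' @examples
#' arrhenius_ea(4.664e-13, 278.15, 6.839e-13, 298.15)$E_a  # ~3.154
#' @export
arrhenius_ea <- function(p1, T1, p2, T2, constants = physical_constants()) {
  if (T1 == T2) stop("T1 and T2 must differ")
  if (p1 <= 0 || p2 <= 0) stop("permeabilities must be positive")
  E_a <- constants$R_kcal * T1 * log(p1 / p2) / (T1 / T2 - 1)
  structure(list(E_a = E_a, T1 = T1, T2 = T2, p1 = p1, p2 = p2),
            class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf("Arrhenius activation energy: %.3f kcal/mol (T = %.2f / %.2f K)\n",
              x$E_a, x$T1, x$T2))
  invisible(x)
}

#' Bundle a permeability estimate at one temperature
#'
#' @param kappa Transmission coefficient.
#' @param n_z0 Linear density at the dividing plane (molecules/nm).
#' @param temperature Temperature (K).
#' @param uncertainty_pf Optional standard error of `pf` (cm^3/s).
#' @param constants A [physical_constants()] list.
#' @param provenance Optional list recording the inputs used.
#' @return An object of class `permeability_result` with `kappa`, `n_z0`,
#'   `k0` (1/s), `pf` (cm^3/s), `temperature`, `uncertainty_pf`.
#' @export
permeability_result <- function(kappa, n_z0, temperature,
                                uncertainty_pf = NA_real_,
                                constants = physical_constants(),
                                provenance = NULL) {
  k0 <- rate_constant_k0(kappa, temperature, n_z0, constants)
  structure(
    list(kappa = kappa, n_z0 = n_z0, k0 = k0,
         pf = single_channel_pf(k0, constants), temperature = temperature,
         uncertainty_pf = uncertainty_pf, provenance = provenance),
    class = "permeability_result"
  )
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("TST permeability at %.2f K:\n", x$temperature))
  cat(sprintf("  kappa = %.4f, n(z0) = %.4g /nm, k0 = %.4g /s\n",
              x$kappa, x$n_z0, x$k0))
  cat(sprintf("  p_f = %.4g cm^3/s (%.3f x 1e-13 cm^3/s)",
              x$pf, x$pf * 1e13))
  if (is.finite(x$uncertainty_pf)) {
    cat(sprintf(" +/- %.3f x 1e-13", x$uncertainty_pf * 1e13))
  }
  cat("\n")
  invisible(x)
}

#' Permeability as a function of observation window
#'
#' For each grid time `t` at or beyond the minimum window, combines the
#' cumulative `kappa(0, t)` from the event summary with `n(z0)` evaluated
#' over `(0, t)` into a permeability estimate, mirroring the convergence
#' diagnostics plotted against simulation length.
#'
#' @param summary An [summarize_events()] result with a cumulative series.
#' @param profile_fn Function `t -> density_profile` over the window
#'   `(0, t)`.
#' @param temperature Temperature (K).
#' @param min_window Minimum window (ps) below which grid points are skipped
#'   with a warning (default 15000, i.e. 15 ns).
#' @param z_divide Dividing-plane position passed to [density_at_plane()].
#' @param constants A [physical_constants()] list.
#' @return A data frame with columns `t_ps`, `kappa`, `n_z0`, `k0`, `pf`.
#' @export
permeability_timeseries <- function(summary, profile_fn, temperature,
                                    min_window = 15000, z_divide = 0,
                                    constants = physical_constants()) {
  stopifnot(inherits(summary, "event_summary"))
  cum <- summary$cumulative
  if (is.null(cum)) stop("summary has no cumulative series")
  keep <- cum$t_ps >= min_window
  if (any(!keep)) {
    warning(sprintf("%d grid points below the %g ps minimum window skipped",
                    sum(!keep), min_window))
  }
  cum <- cum[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(cum)), function(i) {
    n0 <- density_at_plane(profile_fn(cum$t_ps[i]), z_divide)
    k0 <- rate_constant_k0(cum$kappa[i], temperature, n0, constants)
    data.frame(t_ps = cum$t_ps[i], kappa = cum$kappa[i], n_z0 = n0, k0 = k0,
               pf = single_channel_pf(k0, constants))
  })
  do.call(rbind, out)
}

#' Standard error of a permeability estimate
#'
#' Standard error of the mean over independent subsets: per-monomer values
#' (default) or non-overlapping time blocks. The paper-style `+/-` margin on
#' p_f carries no stated method, so the method used is recorded in the
#' result.
#'
#' @param values Numeric vector of per-monomer (or per-block) estimates.
#' @param method `"monomers"` or `"blocks"` (label only; the estimator is the
#'   SEM in both cases).
#' @return SEM with attributes `n` and `method`.
#' @examples
#' estimate_uncertainty(c(1, 1, 3, 3))  # 0.577
#' @export
estimate_uncertainty <- function(values, method = c("monomers", "blocks")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    warning("uncertainty undefined for fewer than 2 values")
    return(structure(NA_real_, n = length(values), method = method))
  }
  structure(stats::sd(values) / sqrt(length(values)),
            n = length(values), method = method)
}
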