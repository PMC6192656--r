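#' Numeric growth-control coefficients
#'
#' Computes the logarithmic sensitivities
#' \eqn{C_i^\mu = (\phi_i/\mu_d)\,\partial\mu_d/\partial\phi_i} of a growth
#' function at a composition, by central differencing in log-composition on
#' the intensive (degree-0 homogeneous) extension
#' \eqn{\tilde\mu(\phi) = \mu_d(\phi/\sum_j\phi_j)}. By Euler's theorem for
#' degree-0 homogeneity the resulting vector sums to zero up to differencing
#' error.
#'
#' Note that for a Monod growth function this intensive partial derivative of
#' the target set equals
#' \eqn{(\phi_{half}/(\phi_{half}+\phi_O))\,(1-\phi_O)}, which differs from
#' the one-dimensional log-slope of the Monod curve ([monod_log_slope()]) by
#' the factor \eqn{(1-\phi_O)}.
#'
#' @param growth a `gn_growth` object.
#' @param phi0 named composition at which to differentiate; must afford a
#'   positive growth rate.
#' @param rel_step relative step of the central difference in log-composition.
#' @return named GCC vector.
#' @export
gcc_numeric <- function(growth, phi0, rel_step = 1e-5) {
  stopifnot(inherits(growth, "gn_growth"), is.numeric(phi0))
  mu_c <- mu_d(growth, phi0)
  if (!is.finite(mu_c) || mu_c <= 0)
    stop("growth rate must be positive and finite at phi0", call. = FALSE)
  n <- length(phi0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    up <- phi0; up[i] <- up[i] * exp(rel_step)
    dn <- phi0; dn[i] <- dn[i] * exp(-rel_step)
    mu_up <- mu_d(growth, up)
    mu_dn <- mu_d(growth, dn)
    if (!is.finite(mu_up) || !is.finite(mu_dn) || mu_up <= 0 || mu_dn <= 0)
      stop(sprintf("non-finite or non-positive growth rate when perturbing species %d", i),
           call. = FALSE)
    out[i] <- (log(mu_up) - log(mu_dn)) / (2 * rel_step)
  }
  setNames(out, names(phi0))
}

#' One-dimensional log-slope of a Monod curve
#'
#' The logarithmic slope \eqn{d\ln\mu / d\ln\phi_O} of the one-dimensional
#' Monod curve \eqn{\mu = \mu_{max}\phi_O/(\phi_{half}+\phi_O)}, i.e.
#' \deqn{\phi_{half} / (\phi_{half} + \phi_O).}
#' This is the estimator used to assign the growth-control coefficient of an
#' operon from an empirical Monod curve of growth rate versus operon
#' expression; at \eqn{\phi_O/\phi_{half} \in \{0.3, 1.3, 15\}} it evaluates
#' to \{0.77, 0.43, 0.063\} (two significant figures).
#'
#' @param mu_max maximal growth rate (does not enter the slope; kept so the
#'   signature mirrors the curve's parameterization).
#' @param phi_half half-saturation mass fraction.
#' @param phi_O operon mass fraction; must be positive.
#' @return the dimensionless log-slope.
#' @seealso [gcc_numeric()] for the multivariate intensive derivative, which
#'   carries an extra factor \eqn{(1-\phi_O)}.
#' @export
monod_log_slope <- function(mu_max, phi_half, phi_O) {
  if (any(phi_O <= 0)) stop("'phi_O' must be positive", call. = FALSE)
  stopifnot(phi_half > 0)
  phi_half / (phi_half + phi_O)
}

#' Convert between growth-control and flux-control coefficients
#'
#' GCCs and flux-control coefficients (FCCs) of Metabolic Control Analysis
#' are related by \eqn{C_i^\mu = C_i^J - \phi_{0,i}}: growth is intensive
#' while flux is extensive, which shifts each coefficient by the species'
#' mass fraction. Supply one of the two vectors; the other is filled in, and
#' both sum rules (\eqn{\sum C_i^J = 1}, \eqn{\sum C_i^\mu = 0}) are
#' evaluated and reported as residuals (never raised as errors).
#'
#' @param gcc,fcc exactly one of the two coefficient vectors.
#' @param phi0 composition vector of matching length.
#' @return an object of class `gn_control`: list with `gcc`, `fcc`,
#'   `residual_gcc` (\eqn{\sum C^\mu}), `residual_fcc` (\eqn{\sum C^J - 1}).
#' @examples
#' gcc_fcc_convert(fcc = c(1, 0), phi0 = c(0.4, 0.6)) # gcc = (0.6, -0.6)
#' @export
gcc_fcc_convert <- function(gcc = NULL, fcc = NULL, phi0) {
  if (is.null(gcc) == is.null(fcc))
    stop("supply exactly one of 'gcc' or 'fcc'", call. = FALSE)
  if (is.null(gcc)) {
    if (length(fcc) != length(phi0)) stop("'fcc' and 'phi0' lengths differ", call. = FALSE)
    gcc <- fcc - phi0
  } else {
    if (length(gcc) != length(phi0)) stop("'gcc' and 'phi0' lengths differ", call. = FALSE)
    fcc <- gcc + phi0
  }
  structure(list(gcc = gcc, fcc = fcc,
                 residual_gcc = sum(gcc), residual_fcc = sum(fcc) - 1),
            class = "gn_control")
}

#' @export
print.gn_control <- function(x, ...) {
  cat(sprintf("Control analysis (%d species): sum C^mu = %.3e (rule: 0), sum C^J = 1 %+.3e (rule: 1)\n",
              length(x$gcc), x$residual_gcc, x$residual_fcc))
  invisible(x)
}

#' Non-metabolic sector of a cell model
#'
#' Sums the mass fractions of proteins flagged non-metabolic. Because each
#' such protein has \eqn{C_h^\mu = -\phi_h}, the GCC zero-sum rule forces the
#' metabolic sector to carry positive growth control equal to the
#' non-metabolic mass fraction \eqn{\phi_H}.
#'
#' @param model a `gn_model`.
#' @return list with `phiH` (non-metabolic mass fraction) and
#'   `residual_metabolic_control` (the positive control the metabolic sector
#'   must carry; equal to `phiH`).
#' @export
nonmetabolic_sector <- function(model) {
  stopifnot(inherits(model, "gn_model"))
  phiH <- sum(model$proteins$f[model$proteins$nonmetabolic])
  list(phiH = phiH, residual_metabolic_control = phiH)
}

#' Round to significant figures, half away from zero
#'
#' Rounding convention used when comparing computed control coefficients with
#' values printed to limited precision (e.g. 0.0625 -> 0.063 at two
#' significant figures).
#'
#' @param x numeric vector.
#' @param digits number of significant figures.
#' @return rounded vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - (digits - 1)
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e + 0.5) * 10^e
  out
}
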