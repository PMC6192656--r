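#' Growth functions
#'
#' A growth function maps a proteome composition vector \eqn{\phi} to the
#' deterministic growth rate \eqn{\mu_d(\phi)} (in \eqn{h^{-1}}) that the
#' composition affords in the zero-noise limit. Growth functions in this
#' package are *intensive*: they are evaluated on the normalized composition
#' \eqn{\phi/\sum_i\phi_i} (the degree-0 homogeneous extension), so that
#' \eqn{\mu_d(\alpha\phi) = \mu_d(\phi)} for any \eqn{\alpha > 0}.
#'
#' `growth_monod()` implements a Monod (hyperbolic) dependence on the summed
#' mass fraction \eqn{\phi_O} of a target set of proteins:
#' \deqn{\mu_d = \mu_{max}\,\phi_O / (\phi_{half} + \phi_O).}
#'
#' `growth_linear()` implements the linear (first-order) growth function
#' defined by a reference composition `phi0`, a reference rate `mu0` and a
#' vector of growth-control coefficients:
#' \deqn{\mu_d(\phi) = \mu_0\big(1 + \sum_i C_i^\mu\,(\phi_i - \phi_{0,i})/\phi_{0,i}\big).}
#' With `gcc = 0` it degenerates to the constant function \eqn{\mu_d \equiv \mu_0}.
#'
#' @param mu_max maximal growth rate (\eqn{h^{-1}}).
#' @param phi_half mass fraction at half-maximal growth (dimensionless).
#' @param target character vector of protein ids whose summed fraction is the
#'   Monod argument.
#' @param mu0 reference growth rate (\eqn{h^{-1}}).
#' @param gcc named (or positionally matched) growth-control coefficient
#'   vector.
#' @param phi0 named reference composition; must sum to 1.
#' @return An object of class `gn_growth` (subclass `gn_growth_monod` or
#'   `gn_growth_linear`).
#' @examples
#' g <- growth_monod(0.8, 0.005, target = c("Y", "Z", "G"))
#' mu_d(g, c(Y = 5e-4, Z = 5e-4, G = 5e-4, rest = 0.9985)) # ~0.1846
#' @export
growth_monod <- function(mu_max, phi_half, target) {
  stopifnot(is.numeric(mu_max), mu_max > 0, is.numeric(phi_half), phi_half > 0,
            is.character(target), length(target) >= 1L)
  structure(list(mu_max = mu_max, phi_half = phi_half, target = target),
            class = c("gn_growth_monod", "gn_growth"))
}

#' @rdname growth_monod
#' @export
growth_linear <- function(mu0, gcc, phi0) {
  stopifnot(is.numeric(mu0), mu0 > 0, is.numeric(gcc), is.numeric(phi0),
            length(gcc) == length(phi0))
  if (abs(sum(phi0) - 1) > 1e-8)
    stop("'phi0' must sum to 1", call. = FALSE)
  if (is.null(names(phi0))) names(phi0) <- names(gcc)
  structure(list(mu0 = mu0, gcc = gcc, phi0 = phi0),
            class = c("gn_growth_linear", "gn_growth"))
}

#' Evaluate a growth function
#'
#' @param growth a `gn_growth` object.
#' @param phi composition vector, named with protein ids for Monod growth.
#'   Need not be normalized: the degree-0 extension \eqn{\mu_d(\phi/\sum\phi)}
#'   is evaluated.
#' @return deterministic growth rate (\eqn{h^{-1}}).
#' @export
mu_d <- function(growth, phi) UseMethod("mu_d")

#' @export
mu_d.gn_growth_monod <- function(growth, phi) {
  s <- sum(phi)
  if (s <= 0) stop("composition must have positive total mass", call. = FALSE)
  idx <- if (!is.null(names(phi))) match(growth$target, names(phi)) else growth$target
  if (anyNA(idx)) stop("target proteins missing from composition", call. = FALSE)
  phiO <- sum(phi[idx]) / s
  growth$mu_max * phiO / (growth$phi_half + phiO)
}

#' @export
mu_d.gn_growth_linear <- function(growth, phi) {
  s <- sum(phi)
  if (s <= 0) stop("composition must have positive total mass", call. = FALSE)
  p <- phi / s
  if (!is.null(names(p)) && !is.null(names(growth$phi0)))
    p <- p[names(growth$phi0)]
  growth$mu0 * (1 + sum(growth$gcc * (p - growth$phi0) / growth$phi0))
}

#' @export
print.gn_growth_monod <- function(x, ...) {
  cat(sprintf("Monod growth function: mu_max = %g h^-1, phi_half = %g, target = {%s}\n",
              x$mu_max, x$phi_half, paste(x$target, collapse = ", ")))
  invisible(x)
}

#' @export
print.gn_growth_linear <- function(x, ...) {
  cat(sprintf("Linear growth function: mu0 = %g h^-1, %d species\n",
              x$mu0, length(x$gcc)))
  invisible(x)
}
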