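# Closed-form stationary correlators of one OU source N (amplitude theta,
# reversion beta, Var V = theta^2/(2 beta)) and its output x through the
# one-pole dilution filter  dx/dt = -mu0 x + N:
#
#   cov_NN(tau) = V e^{-beta |tau|}                                (B-type)
#   cov_xN(tau) = Cov(x(t + tau), N(t))                            (A-type)
#   cov_xx(tau) = Cov(x(t), x(t+tau))                              (S-type)
#
# Lag convention (used throughout the package): the first signal is shifted
# by +tau, so positive tau means the first signal is evaluated LATER. For
# the A-type this gives a pure e^{-beta|tau|} tail on tau < 0 (the source's
# future innovations never correlate with the filter's past) and a mixed
# exponential on tau > 0 (the filter integrates the source's past).
#
# All are finite sums of exponentials in |tau| with rates mu0 and beta. At
# beta == mu0 the generic expressions are 0/0; the confluent (repeated-root)
# forms are used within a relative tolerance.

conf_tol <- 1e-8

cov_NN <- function(V, beta, tau) V * exp(-beta * abs(tau))

cov_xN <- function(V, beta, mu0, tau) {
  a <- abs(tau)
  neg <- tau <= 0
  out <- numeric(length(tau))
  out[neg] <- V * exp(-beta * a[neg]) / (mu0 + beta)
  if (any(!neg)) {
    an <- a[!neg]
    if (abs(beta - mu0) <= conf_tol * max(beta, mu0)) {
      out[!neg] <- V * exp(-mu0 * an) * (an + 1 / (2 * mu0))
    } else {
      out[!neg] <- V * ((exp(-mu0 * an) - exp(-beta * an)) / (beta - mu0) +
                          exp(-mu0 * an) / (mu0 + beta))
    }
  }
  out
}

cov_xx <- function(V, beta, mu0, tau) {
  a <- abs(tau)
  if (abs(beta - mu0) <= conf_tol * max(beta, mu0)) {
    V * exp(-mu0 * a) * (1 + mu0 * a) / (2 * mu0^2)
  } else {
    V * (beta * exp(-mu0 * a) / mu0 - exp(-beta * a)) / (beta^2 - mu0^2)
  }
}

#' Basis correlators of an OU source through the dilution filter
#'
#' The three stationary covariance functions out of which every
#' expression--growth cross-correlation in the linearized model is built.
#' For a source \eqn{N} with variance \eqn{V = \theta^2/(2\beta)} and its
#' filtered output \eqn{x} (the response of \eqn{dx/dt = -\mu_0 x + N}):
#' \describe{
#'   \item{`B`}{\eqn{\mathrm{Cov}(N(t), N(t+\tau)) = V e^{-\beta|\tau|}};
#'     symmetric. Units \eqn{h^{-2}}.}
#'   \item{`A`}{\eqn{\mathrm{Cov}(x(t+\tau), N(t))}; asymmetric: a pure
#'     \eqn{e^{-\beta|\tau|}} tail for \eqn{\tau < 0} (the source's future
#'     innovations are independent of the filter's past) and a mixture of
#'     \eqn{e^{-\mu_0\tau}} and \eqn{e^{-\beta\tau}} for \eqn{\tau > 0}.
#'     Units \eqn{h^{-1}}.}
#'   \item{`S`}{\eqn{\mathrm{Cov}(x(t), x(t+\tau))}; a symmetric mixture of
#'     \eqn{e^{-\mu_0|\tau|}} and \eqn{e^{-\beta|\tau|}} with
#'     \eqn{S(0) = V/(\mu_0(\mu_0+\beta))}. Dimensionless
#'     (\eqn{h^{0}}).}
#' }
#' At \eqn{\beta = \mu_0} the confluent (repeated-root) closed forms are
#' used.
#'
#' @param source a [ou_noise()] spec (or a numeric amplitude, with `beta`).
#' @param mu0 mean growth rate, the dilution-filter rate (\eqn{h^{-1}}).
#' @param tau numeric lag grid (hours).
#' @param beta reversion rate when `source` is numeric.
#' @return data.frame with columns `tau`, `S`, `A`, `B`.
#' @export
basis_functions <- function(source, mu0, tau, beta = NULL) {
  if (inherits(source, "gn_ou")) {
    theta <- source$theta
    beta <- source$beta
  } else {
    theta <- source
    stopifnot(is.numeric(beta))
  }
  stopifnot(beta > 0, mu0 > 0, length(tau) >= 1L)
  V <- theta^2 / (2 * beta)
  data.frame(tau = tau,
             S = cov_xx(V, beta, mu0, tau),
             A = cov_xN(V, beta, mu0, tau),
             B = cov_NN(V, beta, tau))
}
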