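#' Ornstein--Uhlenbeck noise source
#'
#' A zero-mean OU process \eqn{dN = -\beta N\,dt + \theta\,dW} modelling the
#' stochasticity of transcription and translation feeding a synthesis rate.
#' Its stationary variance is \eqn{\theta^2 / (2\beta)} and its
#' autocovariance decays as \eqn{e^{-\beta|\tau|}}.
#'
#' @param id character label.
#' @param theta noise amplitude (diffusion coefficient, units \eqn{h^{-3/2}});
#'   must be non-negative.
#' @param beta reversion rate (\eqn{h^{-1}}); must be positive. Its inverse is
#'   the correlation time of the source.
#' @return An object of class `gn_ou` with fields `id`, `theta`, `beta`.
#' @seealso [ou_var()], [ou_path()]
#' @examples
#' src <- ou_noise("Y", theta = 0.5, beta = 4)
#' ou_var(src) # 0.03125 h^-2
#' @export
ou_noise <- function(id, theta, beta) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("'theta' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  structure(list(id = id, theta = theta, beta = beta), class = "gn_ou")
}

#' Stationary variance of an OU source
#'
#' @param x a `gn_ou` object, or a numeric amplitude `theta` (then `beta`
#'   must be supplied).
#' @param beta reversion rate, used when `x` is numeric.
#' @return \eqn{\theta^2/(2\beta)} (units \eqn{h^{-2}}).
#' @export
ou_var <- function(x, beta = NULL) {
  if (inherits(x, "gn_ou")) return(x$theta^2 / (2 * x$beta))
  stopifnot(is.numeric(x), is.numeric(beta))
  x^2 / (2 * beta)
}

#' Simulate a single stationary OU path
#'
#' Advances the source with the exact Gaussian transition
#' \eqn{N(t+dt) = N(t)e^{-\beta dt} + \mathcal N(0,\,
#' \theta^2(1 - e^{-2\beta dt})/(2\beta))}, so the recorded path has no
#' discretization bias at any step size. The initial state is drawn from the
#' stationary law and `burn_in` hours are discarded.
#'
#' @param spec a `gn_ou` object.
#' @param duration,dt total simulated time and step (hours).
#' @param seed integer seed; if non-NULL, `set.seed(seed)` is called.
#' @param burn_in hours discarded before recording.
#' @param record_dt recording stride (hours); must be a multiple of `dt`.
#' @return numeric vector of recorded states (units \eqn{h^{-1}}).
#' @export
ou_path <- function(spec, duration, dt = 1e-3, seed = NULL, burn_in = 0,
                    record_dt = dt) {
  stopifnot(inherits(spec, "gn_ou"), duration > burn_in)
  stride <- as.integer(round(record_dt / dt))
  if (stride < 1L || abs(stride * dt - record_dt) > 1e-9)
    stop("'record_dt' must be a positive multiple of 'dt'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gn_ou_path_cpp(spec$theta, spec$beta, duration, dt, burn_in, stride)
}

#' @export
print.gn_ou <- function(x, ...) {
  cat(sprintf("OU noise source '%s': theta = %g h^-3/2, beta = %g h^-1, Var = %g h^-2\n",
              x$id, x$theta, x$beta, ou_var(x)))
  invisible(x)
}
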