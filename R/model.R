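#' Protein species specification
#'
#' One row of a cell model's protein table: the species id, its allocation
#' fraction \eqn{f_i} (the share of metabolic flux directed to its synthesis,
#' which equals its mean mass fraction at stationarity), the parameters of its
#' private OU noise source, an optional growth-control coefficient, a
#' non-metabolic flag, and an optional operon (shared-noise group) label.
#'
#' Non-metabolic proteins carry no flux control, so their GCC is forced to
#' \eqn{-f_i}; supplying a conflicting `gcc` together with
#' `nonmetabolic = TRUE` is an error.
#'
#' @param id character label.
#' @param f allocation fraction in \eqn{[0, 1]}.
#' @param theta,beta private OU source amplitude (\eqn{h^{-3/2}}) and
#'   reversion rate (\eqn{h^{-1}}).
#' @param gcc growth-control coefficient \eqn{C_i^\mu} (dimensionless);
#'   `NA` when a growth function supplies it.
#' @param nonmetabolic logical flag.
#' @param operon optional shared-noise group label.
#' @return a one-row data.frame usable with [cell_model()].
#' @export
protein <- function(id, f, theta = 0, beta = 1, gcc = NA_real_,
                    nonmetabolic = FALSE, operon = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(f) || f < 0 || f > 1)
    stop("allocation fraction 'f' must lie in [0, 1]", call. = FALSE)
  if (theta < 0) stop("'theta' must be non-negative", call. = FALSE)
  if (beta <= 0) stop("'beta' must be positive", call. = FALSE)
  if (isTRUE(nonmetabolic) && !is.na(gcc) && abs(gcc + f) > 1e-10)
    stop(sprintf("non-metabolic protein '%s' must have gcc = -f = %g", id, -f),
         call. = FALSE)
  data.frame(id = id, f = f, theta = theta, beta = beta, gcc = gcc,
             nonmetabolic = isTRUE(nonmetabolic), operon = operon,
             stringsAsFactors = FALSE)
}

#' Shared (operon-level) noise source
#'
#' An OU source entering the synthesis rates of several member proteins with
#' non-negative weights that sum to 1, so that the source enters the summed
#' synthesis rate -- and hence the growth rate -- exactly once.
#'
#' @param id source label.
#' @param theta,beta OU amplitude and reversion rate.
#' @param members named numeric vector of weights (names are protein ids).
#' @return an object of class `gn_shared`.
#' @export
shared_noise <- function(id, theta, beta, members) {
  stopifnot(is.numeric(members), !is.null(names(members)))
  if (any(members < 0)) stop("shared-source weights must be non-negative", call. = FALSE)
  if (abs(sum(members) - 1) > 1e-10)
    stop("shared-source weights must sum to 1", call. = FALSE)
  src <- ou_noise(id, theta, beta)
  structure(list(id = id, theta = theta, beta = beta,
                 members = members, source = src),
            class = "gn_shared")
}

#' Construct and validate a cell model
#'
#' Assembles the full model: a protein table (ids, allocation fractions,
#' private noise sources, optional GCCs and flags), optional shared noise
#' sources, and either a growth function or a mean growth rate `mu0` to pair
#' with an explicit GCC vector.
#'
#' Validation enforces the structural invariants: \eqn{\sum_i f_i = 1}
#' (tolerance 1e-12), positivity of noise parameters, existence of every
#' shared-source member, and the non-metabolic identity \eqn{C_h^\mu = -f_h}.
#' When an explicit GCC vector is present its zero-sum rule is checked to
#' 1e-10.
#'
#' @param proteins a data.frame with columns `id, f, theta, beta` and
#'   optionally `gcc, nonmetabolic, operon` -- e.g. built by rbind-ing
#'   [protein()] rows.
#' @param shared list of [shared_noise()] objects.
#' @param growth a `gn_growth` object, or `NULL`.
#' @param mu0 mean growth rate (\eqn{h^{-1}}), required when `growth` is
#'   `NULL` and used as the linearization point.
#' @param meta free-form metadata list carried through to manifests.
#' @return an object of class `gn_model`.
#' @examples
#' toy <- make_two_protein_toy()
#' steady_state(toy)
#' @export
cell_model <- function(proteins, shared = list(), growth = NULL, mu0 = NULL,
                       meta = list()) {
  stopifnot(is.data.frame(proteins))
  need <- c("id", "f", "theta", "beta")
  if (!all(need %in% names(proteins)))
    stop("protein table must have columns id, f, theta, beta", call. = FALSE)
  if (!"gcc" %in% names(proteins)) proteins$gcc <- NA_real_
  if (!"nonmetabolic" %in% names(proteins)) proteins$nonmetabolic <- FALSE
  if (!"operon" %in% names(proteins)) proteins$operon <- NA_character_
  if (anyDuplicated(proteins$id))
    stop("protein ids must be unique", call. = FALSE)
  if (inherits(shared, "gn_shared")) shared <- list(shared)
  m <- structure(list(proteins = proteins, shared = shared, growth = growth,
                      mu0 = mu0, meta = meta), class = "gn_model")
  validate_model(m)
  m
}

#' @rdname cell_model
#' @param model a `gn_model` object.
#' @export
validate_model <- function(model) {
  p <- model$proteins
  if (abs(sum(p$f) - 1) > 1e-12)
    stop(sprintf("allocation fractions must sum to 1 (got 1 %+.3e)",
                 sum(p$f) - 1), call. = FALSE)
  if (any(p$f < 0 | p$f > 1)) stop("allocation fractions must lie in [0, 1]", call. = FALSE)
  if (any(p$theta < 0)) stop("noise amplitudes must be non-negative", call. = FALSE)
  if (any(p$beta <= 0)) stop("reversion rates must be positive", call. = FALSE)
  bad <- p$nonmetabolic & !is.na(p$gcc) & abs(p$gcc + p$f) > 1e-10
  if (any(bad))
    stop(sprintf("non-metabolic proteins must have gcc = -f; violated by: %s",
                 paste(p$id[bad], collapse = ", ")), call. = FALSE)
  for (s in model$shared) {
    if (!inherits(s, "gn_shared")) stop("'shared' must contain gn_shared objects", call. = FALSE)
    missing <- setdiff(names(s$members), p$id)
    if (length(missing))
      stop(sprintf("shared source '%s' references unknown proteins: %s",
                   s$id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(model$growth) && is.null(model$mu0) && all(is.na(p$gcc)))
    stop("model needs a growth function or mu0 (with GCCs)", call. = FALSE)
  if (!is.null(model$growth) && !inherits(model$growth, "gn_growth"))
    stop("'growth' must be a gn_growth object", call. = FALSE)
  if (all(!is.na(p$gcc)) && abs(sum(p$gcc)) > 1e-10)
    stop(sprintf("GCC zero-sum rule violated: sum = %.3e", sum(p$gcc)), call. = FALSE)
  invisible(model)
}

#' Steady state of a cell model
#'
#' At the zero-noise fixed point of \eqn{\dot\phi_i = \pi_i - \mu\phi_i} with
#' \eqn{\pi_i = f_i \mu_d(\phi)}, stationarity forces
#' \eqn{\phi_{0,i} = f_i}: the mean composition equals the allocation. The
#' mean growth rate is \eqn{\mu_0 = \mu_d(\phi_0)} when a growth function is
#' present, otherwise the supplied `mu0`.
#'
#' @param model a `gn_model`.
#' @return an object of class `gn_steady`: list with `phi0` (named
#'   composition, sums to 1) and `mu0` (\eqn{h^{-1}}).
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "gn_model"))
  phi0 <- setNames(model$proteins$f, model$proteins$id)
  mu0 <- if (!is.null(model$growth)) mu_d(model$growth, phi0) else model$mu0
  if (is.null(mu0))
    stop("cannot determine mean growth rate: supply a growth function or mu0",
         call. = FALSE)
  structure(list(phi0 = phi0, mu0 = mu0), class = "gn_steady")
}

#' Two-protein toy cell
#'
#' The minimal model exhibiting all four noise modes: species X and Y with
#' allocation fractions \eqn{f_X = 0.67}, \eqn{f_Y = 0.33}, growth-control
#' coefficients \eqn{C_Y^\mu = 0.25} and \eqn{C_X^\mu = -0.25} (zero-sum
#' rule), mean growth rate \eqn{\mu_0 = 1\,h^{-1}}, and identical private
#' noise sources with \eqn{\theta = 0.5\,h^{-3/2}} and
#' \eqn{\beta = 4\mu_0}. Each source then has stationary variance
#' \eqn{0.03125\,h^{-2}} and protein Y a stationary CV of about 0.179.
#'
#' @param gcc_Y growth-control coefficient of Y; X receives `-gcc_Y`.
#' @param f_Y allocation fraction of Y.
#' @param mu0 mean growth rate (\eqn{h^{-1}}).
#' @param theta,beta OU parameters shared by both private sources.
#' @return a `gn_model`.
#' @export
make_two_protein_toy <- function(gcc_Y = 0.25, f_Y = 0.33, mu0 = 1,
                                 theta = 0.5, beta = 4 * mu0) {
  proteins <- rbind(
    protein("X", f = 1 - f_Y, theta = theta, beta = beta, gcc = -gcc_Y),
    protein("Y", f = f_Y,     theta = theta, beta = beta, gcc = gcc_Y)
  )
  cell_model(proteins, mu0 = mu0,
             meta = list(kind = "two_protein_toy", gcc_Y = gcc_Y))
}

#' @export
print.gn_model <- function(x, ...) {
  cat(sprintf("Cell model: %d protein species, %d shared noise source(s)\n",
              nrow(x$proteins), length(x$shared)))
  if (!is.null(x$growth)) print(x$growth)
  else cat(sprintf("Growth: linearized, mu0 = %g h^-1\n", x$mu0))
  ng <- sum(!is.na(x$proteins$gcc))
  cat(sprintf("GCCs set for %d/%d species; non-metabolic mass = %.3f\n",
              ng, nrow(x$proteins),
              sum(x$proteins$f[x$proteins$nonmetabolic])))
  invisible(x)
}

#' @export
print.gn_steady <- function(x, ...) {
  cat(sprintf("Steady state: mu0 = %g h^-1, %d species\n",
              x$mu0, length(x$phi0)))
  invisible(x)
}
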