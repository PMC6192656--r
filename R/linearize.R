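#' Linearize a cell model around its steady state
#'
#' Substituting the synthesis and growth equations into the mass-fraction
#' dynamics and expanding to first order around the mean composition
#' \eqn{\phi_0} gives the reduced fluctuation system
#' \deqn{\frac{d\,\delta\phi_i}{dt} = -\mu_0\,\delta\phi_i +
#'   \sum_s (w_{s,i} - \phi_{0,i})\,N_s,}
#' \deqn{\delta\mu = \mu_0\sum_j C_j^\mu\,\frac{\delta\phi_j}{\phi_{0,j}} +
#'   \sum_s N_s, \qquad
#'   \delta\pi_i = \phi_{0,i}\,\mu_0\sum_j C_j^\mu\,\frac{\delta\phi_j}{\phi_{0,j}}
#'   + \sum_s w_{s,i} N_s,}
#' where \eqn{w_{s,i}} is the wiring coefficient of source \eqn{s} into
#' synthesis rate \eqn{i} (1 for a private source on its own protein; the
#' member weight for a shared source). A notable cancellation occurs in the
#' \eqn{\delta\phi} equation: the allocation feedback \eqn{f_i\,\delta\mu_d}
#' exactly cancels the dilution term \eqn{\phi_{0,i}\,\delta\mu_d}, so
#' concentration fluctuations are independent of the growth-control
#' coefficients. GCCs are taken from the model's protein table when set,
#' otherwise computed from the growth function by [gcc_numeric()].
#'
#' @param model a `gn_model`.
#' @param ss its steady state; computed with [steady_state()] if omitted.
#' @return an object of class `gn_lnm`: list with `phi0`, `mu0`, `gcc`,
#'   `sources` (data.frame `id, theta, beta, V, type, protein`), wiring
#'   matrix `W` (sources x proteins), and the derived per-source growth
#'   coupling `g` with \eqn{g_s = \mu_0 \sum_j C_j^\mu w_{s,j}/\phi_{0,j} -
#'   \mu_0\sum_j C_j^\mu}.
#' @export
linearize <- function(model, ss = NULL) {
  stopifnot(inherits(model, "gn_model"))
  if (is.null(ss)) ss <- steady_state(model)
  p <- model$proteins
  phi0 <- ss$phi0
  mu0 <- ss$mu0
  gcc <- setNames(p$gcc, p$id)
  if (anyNA(gcc)) {
    if (is.null(model$growth))
      stop("model has neither a complete GCC vector nor a growth function",
           call. = FALSE)
    gcc <- gcc_numeric(model$growth, phi0)
  }
  np <- nrow(p)
  nsh <- length(model$shared)
  src <- data.frame(
    id = c(p$id, vapply(model$shared, `[[`, "", "id")),
    theta = c(p$theta, vapply(model$shared, `[[`, 0, "theta")),
    beta = c(p$beta, vapply(model$shared, `[[`, 0, "beta")),
    type = c(rep("private", np), rep("shared", nsh)),
    protein = c(p$id, rep(NA_character_, nsh)),
    stringsAsFactors = FALSE
  )
  src$V <- src$theta^2 / (2 * src$beta)
  W <- matrix(0, nrow = np + nsh, ncol = np,
              dimnames = list(src$id, p$id))
  W[seq_len(np), ] <- diag(np)
  if (nsh > 0) for (k in seq_len(nsh)) {
    s <- model$shared[[k]]
    W[np + k, names(s$members)] <- s$members
  }
  G <- mu0 * gcc / phi0
  g <- as.vector(W %*% G) - mu0 * sum(gcc)
  structure(list(phi0 = phi0, mu0 = mu0, gcc = gcc, sources = src,
                 W = W, g = setNames(g, src$id)),
            class = "gn_lnm")
}

#' @export
print.gn_lnm <- function(x, ...) {
  cat(sprintf("Linear noise model: %d species, %d sources (%d shared), mu0 = %g h^-1\n",
              length(x$phi0), nrow(x$sources),
              sum(x$sources$type == "shared"), x$mu0))
  invisible(x)
}

# per-source weights v_s = Var(N_s) / (mu0 (mu0 + beta_s)); these are the
# stationary variance contributions of each source through the one-pole
# dilution filter
source_v <- function(lnm) {
  lnm$sources$V / (lnm$mu0 * (lnm$mu0 + lnm$sources$beta))
}

#' Stationary coefficients of variation of protein concentrations
#'
#' Closed-form stationary CV \eqn{\eta_i} of each mass fraction under the
#' linearized dynamics. For a model with only private sources this is
#' \deqn{\eta_i^2 = \frac{(1-\phi_{0,i})^2}{\phi_{0,i}^2}
#'   \frac{\mathrm{Var}(N_i)}{\mu_0(\mu_0+\beta_i)} +
#'   \sum_{j\ne i}\frac{\mathrm{Var}(N_j)}{\mu_0(\mu_0+\beta_j)};}
#' the first (intrinsic) term stems from the protein's own synthesis noise,
#' the second (extrinsic) from every other source, whose noise reaches
#' \eqn{\phi_i} through dilution. In general
#' \eqn{\mathrm{Var}(\delta\phi_i) = \sum_s (w_{s,i}-\phi_{0,i})^2
#' \mathrm{Var}(N_s)/(\mu_0(\mu_0+\beta_s))}. The result contains no
#' growth-control coefficients: concentration fluctuations are independent
#' of the GCCs (see [linearize()]).
#'
#' @param lnm a `gn_lnm` from [linearize()], or a `gn_model` (linearized on
#'   the fly).
#' @param ids optional subset of protein ids.
#' @return named vector of CVs (dimensionless).
#' @export
stationary_cv <- function(lnm, ids = NULL) {
  if (inherits(lnm, "gn_model")) lnm <- linearize(lnm)
  stopifnot(inherits(lnm, "gn_lnm"))
  if (any(lnm$phi0 <= 0))
    stop("undefined CV: some mean mass fractions are zero", call. = FALSE)
  v <- source_v(lnm)
  # Var(delta phi)_i = sum_s (w_si - phi0_i)^2 v_s, expanded to avoid forming
  # the dense (W - phi0) matrix
  w2v <- as.vector(crossprod(lnm$W^2, v))
  wv <- as.vector(crossprod(lnm$W, v))
  var_phi <- w2v - 2 * lnm$phi0 * wv + lnm$phi0^2 * sum(v)
  eta <- sqrt(pmax(var_phi, 0)) / lnm$phi0
  if (!is.null(ids)) eta[ids] else eta
}

#' Dual-reporter covariance
#'
#' Covariance between the mass fractions of two identical reporter
#' constructs R and G (same mean fraction \eqn{\phi_{0,b}}, amplitude and
#' reversion rate), normalized by \eqn{\phi_{0,b}^2}:
#' \deqn{\frac{\mathrm{Cov}(\phi_R,\phi_G)}{\phi_{0,b}^2} =
#'   -2\,\frac{1-\phi_{0,b}}{\phi_{0,b}}
#'   \frac{\mathrm{Var}(N_b)}{\mu_0(\mu_0+\beta_b)}
#'   + \sum_{j\ne R,G}\frac{\mathrm{Var}(N_j)}{\mu_0(\mu_0+\beta_j)}.}
#' The first term is *negative*: synthesis noise of one reporter dilutes the
#' other, so intrinsic noise propagates between the reporters. The covariance
#' therefore does not measure extrinsic noise alone, and can be negative even
#' with zero extrinsic noise.
#'
#' @param phi0_b mean mass fraction of each reporter.
#' @param noise_b a [ou_noise()] spec shared (by symmetry) by both reporters.
#' @param background list of [ou_noise()] specs for all other sources (may be
#'   empty).
#' @param mu0 mean growth rate.
#' @return list with `total`, `transmission` (the negative
#'   between-reporter term) and `other_sources` (the non-negative term).
#' @export
dual_reporter_covariance <- function(phi0_b, noise_b, background = list(), mu0) {
  stopifnot(is.numeric(phi0_b), phi0_b > 0, phi0_b < 1,
            inherits(noise_b, "gn_ou"), mu0 > 0)
  if (inherits(background, "gn_ou")) background <- list(background)
  v_b <- ou_var(noise_b) / (mu0 * (mu0 + noise_b$beta))
  transmission <- -2 * (1 - phi0_b) / phi0_b * v_b
  other <- sum(vapply(background, function(s) ou_var(s) / (mu0 * (mu0 + s$beta)), 0))
  list(total = transmission + other, transmission = transmission,
       other_sources = other)
}

#' Fit noise amplitudes to target concentration CVs
#'
#' Inverts the stationary-CV relation: with
#' \eqn{v_s = \mathrm{Var}(N_s)/(\mu_0(\mu_0+\beta_s))}, the targets satisfy
#' the linear system
#' \eqn{\eta_i^2 = \sum_s (w_{s,i}-\phi_{0,i})^2/\phi_{0,i}^2\; v_s}. Extra
#' amplitude-ratio equality constraints (e.g. an operon source whose
#' amplitude is 1.5 times that of a reporter's private source) supply the
#' additional equations needed when shared sources make the system wider
#' than it is tall. The solved \eqn{v_s} are mapped back to amplitudes via
#' \eqn{\theta_s = \sqrt{2\beta_s v_s \mu_0(\mu_0+\beta_s)}}.
#'
#' @param target_cv named vector of target CVs, one per protein (ordered like
#'   `phi0`).
#' @param beta reversion rate per source (recycled if scalar).
#' @param mu0 mean growth rate.
#' @param phi0 named composition (sums to 1).
#' @param W wiring matrix (sources x proteins); default identity (one private
#'   source per protein, source ids = protein ids).
#' @param ratios optional data.frame with columns `source`, `ref`, `ratio`
#'   imposing `theta[source] = ratio * theta[ref]`, one row per constraint.
#' @return named amplitude vector `theta` (one per source).
#' @examples
#' # recover the two-protein toy amplitudes (~0.5 each) from its CVs; with
#' # two species the CVs are tied together by sum(phi) = 1, so an
#' # equal-amplitude constraint closes the system
#' cv <- stationary_cv(linearize(make_two_protein_toy()))
#' noise_amplitudes_from_cvs(cv, beta = 4, mu0 = 1,
#'                           phi0 = c(X = 0.67, Y = 0.33),
#'                           ratios = data.frame(source = "X", ref = "Y",
#'                                               ratio = 1))
#' @export
noise_amplitudes_from_cvs <- function(target_cv, beta, mu0, phi0, W = NULL,
                                      ratios = NULL) {
  np <- length(phi0)
  stopifnot(length(target_cv) == np, all(target_cv > 0), mu0 > 0,
            all(phi0 > 0))
  if (is.null(W)) {
    W <- diag(np)
    dimnames(W) <- list(names(phi0), names(phi0))
  }
  ns <- nrow(W)
  beta <- rep_len(beta, ns)
  n_con <- if (is.null(ratios)) 0L else nrow(ratios)
  if (ns > np + n_con)
    stop(sprintf(paste0("underdetermined noise fit: %d sources but only %d CV ",
                        "targets + %d constraints; add ratio constraints"),
                 ns, np, n_con), call. = FALSE)
  src_ids <- rownames(W)
  if (is.null(src_ids)) src_ids <- as.character(seq_len(ns))
  # CV rows: A[i, s] = (w_si - phi0_i)^2 / phi0_i^2
  A <- t((W - matrix(phi0, ns, np, byrow = TRUE))^2) / phi0^2
  rhs <- as.numeric(target_cv)^2
  if (n_con > 0) {
    for (k in seq_len(n_con)) {
      s_i <- match(ratios$source[k], src_ids)
      r_i <- match(ratios$ref[k], src_ids)
      if (is.na(s_i) || is.na(r_i))
        stop("ratio constraint references unknown source", call. = FALSE)
      # theta_s = ratio * theta_ref  =>  v_s = ratio^2 * v_ref *
      #   beta_ref (mu0 + beta_ref) / (beta_s (mu0 + beta_s))
      row <- numeric(ns)
      row[s_i] <- 1
      row[r_i] <- -ratios$ratio[k]^2 * beta[r_i] * (mu0 + beta[r_i]) /
        (beta[s_i] * (mu0 + beta[s_i]))
      A <- rbind(A, row)
      rhs <- c(rhs, 0)
    }
  }
  # least-squares solve (exact for the square case); the system can be
  # overdetermined when targets are redundant (e.g. two proteins, where
  # sum(phi) = 1 ties the two CVs together), in which case the targets must
  # be mutually consistent
  v <- tryCatch(qr.solve(A, rhs),
                error = function(e) stop("noise-fit system is singular: ",
                                         conditionMessage(e), call. = FALSE))
  resid <- max(abs(A %*% v - rhs))
  if (resid > 1e-6 * max(abs(rhs)))
    stop(sprintf(paste0("inconsistent CV targets: the constraint system has ",
                        "no exact solution (residual %.2e)"), resid),
         call. = FALSE)
  bad <- v < -1e-12
  if (any(bad)) {
    prot <- src_ids[bad]
    stop(sprintf(paste0("infeasible noise fit: target CV below the extrinsic ",
                        "floor for source(s) %s"),
                 paste(prot, collapse = ", ")), call. = FALSE)
  }
  v <- pmax(v, 0)
  V <- v * mu0 * (mu0 + beta)
  setNames(sqrt(2 * beta * V), src_ids)
}
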