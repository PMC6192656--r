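#' Simulate the full stochastic dynamics of a cell model
#'
#' Integrates the coupled mass-fraction / growth-rate system. The OU noise
#' sources are advanced with their exact Gaussian transition (no
#' discretization bias in the driver); the mass fractions follow an
#' Euler--Maruyama step on \eqn{\dot\phi_i = \pi_i - \mu\phi_i}, adequate in
#' the small-noise regime the model assumes. After each step the composition
#' is projected back onto the simplex (divided by \eqn{\sum\phi}); the
#' largest pre-projection drift \eqn{|\sum\phi - 1|} is recorded as an
#' integrator diagnostic, and the projection can be disabled.
#'
#' The initial state is \eqn{\phi = f} with noise states drawn from their
#' stationary law; `burn_in` hours are discarded. Synthesis rates are
#' recorded as evaluated at the step start, and the recorded signals satisfy
#' \eqn{\mu = \sum_i \pi_i} identically. Models without a growth function
#' use the linearized growth rate
#' \eqn{\mu_d(\phi) = \mu_0(1 + \sum_i C_i^\mu(\phi_i - f_i)/f_i)}.
#'
#' A trajectory excursion of any \eqn{\phi_i} below \eqn{-10} times its
#' stationary SD aborts the run: transient negative excursions are expected
#' in the linear regime, but large ones indicate the small-noise assumption
#' (or the step size) is inadequate.
#'
#' @param model a `gn_model`.
#' @param duration total simulated time (hours), including burn-in.
#' @param dt integration step (hours); must satisfy
#'   `dt <= 0.1 / max(beta, mu0)`.
#' @param seed integer; if non-NULL, `set.seed(seed)` is called, making the
#'   run bit-reproducible.
#' @param burn_in discarded initial stretch (hours); default `20 / mu0`.
#' @param record_dt recording stride (hours), a multiple of `dt`.
#' @param record protein ids to record (default: all).
#' @param record_noise record the OU states of the recorded proteins'
#'   private sources and all shared sources.
#' @param renormalize apply the per-step simplex projection.
#' @return an object of class `gn_traj`: list with `t`, `phi`, `pi`
#'   (matrices, one column per recorded species), `mu`, `noise`,
#'   `max_drift`, and metadata (`seed`, `dt`, `record_dt`, `model`).
#' @examples
#' toy <- make_two_protein_toy()
#' tr <- simulate_cell(toy, duration = 60, seed = 1)
#' estimate_cv(tr, "Y")
#' @export
simulate_cell <- function(model, duration, dt = 1e-3, seed = NULL,
                          burn_in = NULL, record_dt = 0.01, record = NULL,
                          record_noise = TRUE, renormalize = TRUE) {
  stopifnot(inherits(model, "gn_model"), duration > 0)
  ss <- steady_state(model)
  p <- model$proteins
  max_rate <- max(p$beta, ss$mu0,
                  vapply(model$shared, `[[`, 0, "beta"))
  if (dt > 0.1 / max_rate)
    stop(sprintf("dt = %g too large: must be <= 0.1/max(beta, mu0) = %g",
                 dt, 0.1 / max_rate), call. = FALSE)
  if (is.null(burn_in)) burn_in <- 20 / ss$mu0
  if (duration <= burn_in)
    stop("'duration' must exceed 'burn_in'", call. = FALSE)
  stride <- as.integer(round(record_dt / dt))
  if (stride < 1L || abs(stride * dt - record_dt) > 1e-9)
    stop("'record_dt' must be a positive multiple of 'dt'", call. = FALSE)

  if (is.null(record)) record <- p$id
  rec_idx <- match(record, p$id)
  if (anyNA(rec_idx)) stop("unknown protein id in 'record'", call. = FALSE)

  # proteins without a GCC contribute no composition feedback to mu_d; a
  # model with mu0 and no GCCs at all thus grows at constant mu_d = mu0
  gcc <- p$gcc
  if (is.null(model$growth)) {
    gtype <- 0L; mu_max <- 0; phi_half <- 1; target <- integer(0)
  } else if (inherits(model$growth, "gn_growth_monod")) {
    gtype <- 1L
    mu_max <- model$growth$mu_max
    phi_half <- model$growth$phi_half
    target <- match(model$growth$target, p$id) - 1L
    if (anyNA(target)) stop("growth target missing from protein table", call. = FALSE)
    gcc <- rep(0, nrow(p))
  } else {
    gtype <- 0L; mu_max <- 0; phi_half <- 1; target <- integer(0)
    gcc <- model$growth$gcc
  }
  if (gtype == 0L) gcc[is.na(gcc)] <- 0

  # instability floor: -10 stationary SDs (plus slack so theta = 0 species
  # are never flagged by roundoff)
  sd_phi <- tryCatch(stationary_cv(model) * ss$phi0,
                     error = function(e) rep(0, nrow(p)))
  phi_floor <- -10 * sd_phi - 1e-9

  shared_list <- lapply(model$shared, function(s) {
    list(theta = s$theta, beta = s$beta,
         idx = match(names(s$members), p$id) - 1L, w = unname(s$members))
  })

  if (!is.null(seed)) set.seed(seed)
  raw <- gn_simulate_cpp(p$f, p$theta, p$beta, shared_list,
                         gtype, gcc, ss$mu0, mu_max, phi_half, target,
                         duration, dt, burn_in, stride, rec_idx - 1L,
                         record_noise, renormalize, phi_floor)
  colnames(raw$phi) <- record
  colnames(raw$pi) <- record
  if (record_noise && ncol(raw$noise) > 0) {
    colnames(raw$noise) <- c(record, vapply(model$shared, `[[`, "", "id"))
  }
  structure(list(t = raw$t, phi = raw$phi, pi = raw$pi, mu = raw$mu,
                 noise = if (record_noise) raw$noise else NULL,
                 max_drift = raw$max_drift,
                 seed = seed, dt = dt, record_dt = record_dt,
                 duration = duration, burn_in = burn_in, mu0 = ss$mu0,
                 species = record),
            class = "gn_traj")
}

#' @export
print.gn_traj <- function(x, ...) {
  cat(sprintf("Trajectory: %d points over [%g, %g] h (dt = %g, recorded every %g h)\n",
              length(x$t), min(x$t), max(x$t), x$dt, x$record_dt))
  cat(sprintf("%d recorded species; max simplex drift %.2e\n",
              ncol(x$phi), x$max_drift))
  invisible(x)
}

#' Project a composition back onto the simplex
#'
#' The per-step renormalization policy of the integrator, exposed for
#' inspection: divides the composition by its sum and reports the
#' pre-projection drift \eqn{\sum\phi - 1}.
#'
#' @param phi numeric composition vector with positive sum.
#' @return list with `phi` (rescaled, sums to 1) and `drift`.
#' @export
simplex_project <- function(phi) {
  s <- sum(phi)
  if (s <= 0) stop("total mass fraction must be positive", call. = FALSE)
  list(phi = phi / s, drift = s - 1)
}

# resolve a signal selector to a numeric series; selectors are "mu",
# "phi:<id>", "pi:<id>", "noise:<id>" or list(signal=, id=)
traj_signal <- function(traj, sel) {
  if (is.list(sel)) sel <- paste(sel$signal, sel$id, sep = ":")
  if (identical(sel, "mu")) return(traj$mu)
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("phi", "pi", "noise"))
    stop("signal selector must be 'mu', 'phi:<id>', 'pi:<id>' or 'noise:<id>'",
         call. = FALSE)
  mat <- traj[[parts[1]]]
  if (is.null(mat) || !parts[2] %in% colnames(mat))
    stop(sprintf("signal '%s' not recorded", sel), call. = FALSE)
  mat[, parts[2]]
}

#' Empirical cross-correlation from a trajectory
#'
#' Pearson cross-correlation \eqn{r(\tau) = \mathrm{corr}(x(t+\tau), y(t))}
#' on the recorded grid (positive \eqn{\tau}: `x` evaluated later than `y`,
#' matching [xcorr_analytic()]), with the usual
#' time-series convention of global means and a fixed denominator
#' \eqn{n\,\sigma_x\sigma_y}. Standard errors come from a circular block
#' bootstrap of the paired series: contiguous, circularly wrapped blocks of
#' `block_len` hours are resampled and the whole statistic recomputed
#' (`n_boot` resamples). The default block length, \eqn{10/\mu_0}, spans ten
#' times the slowest correlation time in the model.
#'
#' @param traj a `gn_traj`.
#' @param x,y signal selectors: `"mu"`, `"phi:<id>"`, `"pi:<id>"`,
#'   `"noise:<id>"`, or `list(signal =, id =)`.
#' @param max_lag largest lag magnitude (hours); must be below a tenth of
#'   the recorded span.
#' @param lag_dt lag grid spacing (hours); a multiple of the recording
#'   stride. Default: the recording stride.
#' @param block_len bootstrap block length (hours).
#' @param n_boot number of bootstrap resamples (0 skips the SE).
#' @param seed seed for the bootstrap resampling.
#' @return data.frame of class `gn_excorr` with columns `tau`, `r`, `se`.
#' @export
estimate_xcorr <- function(traj, x, y, max_lag = 3, lag_dt = NULL,
                           block_len = NULL, n_boot = 200, seed = NULL) {
  stopifnot(inherits(traj, "gn_traj"))
  xs <- traj_signal(traj, x)
  ys <- traj_signal(traj, y)
  span <- max(traj$t) - min(traj$t)
  if (max_lag >= span / 10)
    stop("'max_lag' must be below a tenth of the recorded span", call. = FALSE)
  if (is.null(lag_dt)) lag_dt <- traj$record_dt
  lag_stride <- as.integer(round(lag_dt / traj$record_dt))
  if (lag_stride < 1L || abs(lag_stride * traj$record_dt - lag_dt) > 1e-9)
    stop("'lag_dt' must be a positive multiple of the recording stride",
         call. = FALSE)
  max_k <- floor(max_lag / lag_dt)
  lags <- (-max_k:max_k) * lag_stride
  if (is.null(block_len)) block_len <- 10 / traj$mu0
  bl <- max(1L, as.integer(round(block_len / traj$record_dt)))
  if (!is.null(seed)) set.seed(seed)
  # the backend computes corr(x(t), y(t + L)); corr(x(t + tau), y(t)) is the
  # same statistic at L = -tau
  res <- gn_xcorr_cpp(xs, ys, as.integer(-lags), bl, as.integer(n_boot))
  structure(data.frame(tau = lags * traj$record_dt, r = res$r, se = res$se),
            class = c("gn_excorr", "data.frame"),
            block_len = bl * traj$record_dt, n_boot = n_boot)
}

#' Empirical concentration CV from a trajectory
#'
#' Sample standard deviation divided by sample mean of a recorded mass
#' fraction over the post-burn-in record. The optional standard error uses a
#' circular block bootstrap with the same defaults as [estimate_xcorr()].
#'
#' @param traj a `gn_traj`.
#' @param id recorded protein id.
#' @param se also return a bootstrap standard error.
#' @param block_len,n_boot,seed bootstrap parameters.
#' @return the CV, or (with `se = TRUE`) a list with `cv` and `se`.
#' @export
estimate_cv <- function(traj, id, se = FALSE, block_len = NULL, n_boot = 200,
                        seed = NULL) {
  stopifnot(inherits(traj, "gn_traj"))
  x <- traj_signal(traj, paste0("phi:", id))
  mx <- mean(x)
  if (mx <= 0) stop("mean mass fraction is non-positive", call. = FALSE)
  cv <- stats::sd(x) / mx
  if (!se) return(cv)
  if (is.null(block_len)) block_len <- 10 / traj$mu0
  bl <- max(1L, as.integer(round(block_len / traj$record_dt)))
  n <- length(x)
  n_blocks <- ceiling(n / bl)
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    starts <- sample.int(n, n_blocks, replace = TRUE) - 1L
    idx <- (rep(starts, each = bl) + rep(seq_len(bl) - 1L, n_blocks)) %% n + 1L
    xb <- x[idx[seq_len(n)]]
    stats::sd(xb) / mean(xb)
  }, 0)
  list(cv = cv, se = stats::sd(reps))
}

#' Export a trajectory as tidy CSV
#'
#' Writes one row per time point and species with columns
#' `t, species, phi, pi, mu, noise`, plus a JSON metadata sidecar
#' (`<path>.meta.json`) with the seed, step sizes and a model digest so runs
#' can be reproduced bit-for-bit.
#'
#' @param traj a `gn_traj`.
#' @param path output CSV path.
#' @param meta extra metadata fields for the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, meta = list()) {
  ids <- colnames(traj$phi)
  long <- do.call(rbind, lapply(ids, function(id) {
    data.frame(t = traj$t, species = id,
               phi = traj$phi[, id], pi = traj$pi[, id], mu = traj$mu,
               noise = if (!is.null(traj$noise) && id %in% colnames(traj$noise))
                 traj$noise[, id] else NA_real_)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  side <- c(list(seed = traj$seed, dt = traj$dt, record_dt = traj$record_dt,
                 duration = traj$duration, burn_in = traj$burn_in,
                 max_drift = traj$max_drift, species = ids), meta)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
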