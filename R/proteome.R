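#' Generate a synthetic background proteome
#'
#' Draws a table of protein mean abundances and concentration CVs emulating
#' the qualitative structure of measured single-cell E. coli proteomics:
#' a log-normal abundance spectrum combined with the phenomenological
#' noise law \eqn{\eta^2 = a/\langle n\rangle + b} (an intrinsic
#' \eqn{1/\langle n\rangle} limb at low abundance and an extrinsic floor
#' \eqn{b} at high abundance), with log-normal scatter around the law. The
#' draw is deterministic under `seed`.
#'
#' The default spectrum emulates a low-abundance single-cell library (log10
#' mean 1.0, log10 SD 0.3): no single background protein then dominates the
#' proteome mass (top mass fractions below one percent, as in real
#' proteomes), which keeps the mass-squared-weighted background noise
#' \eqn{\sum_j \phi_j^2 \eta_j^2} small enough that a reporter construct's
#' own noise modes remain resolvable against the global dilution mode --
#' the regime in which expression--growth correlations are informative
#' about growth control. All constants are exposed for users who want a
#' broader spectrum or a different noise floor; see the methods vignette
#' for the full rationale.
#'
#' @param n_species number of background species (default 1018, the size of
#'   the reference abundance dataset being emulated).
#' @param seed integer seed.
#' @param abund_meanlog10,abund_sdlog10 mean and SD of log10 abundance
#'   (copies per cell, relative scale).
#' @param cv_a,cv_b noise-law constants: \eqn{\eta^2 = a/\langle n\rangle + b}.
#' @param cv_scatter_sdlog10 SD (log10) of the multiplicative scatter of
#'   \eqn{\eta^2} around the law.
#' @return data.frame with columns `id, mean_abundance, cv, nonmetabolic`
#'   (flag initialized to `FALSE`; assigned later by [assign_gccs()]).
#' @export
generate_background_proteome <- function(n_species = 1018, seed = 1,
                                         abund_meanlog10 = 1.0,
                                         abund_sdlog10 = 0.3,
                                         cv_a = 1, cv_b = 0.03,
                                         cv_scatter_sdlog10 = 0.2) {
  if (n_species < 2) stop("'n_species' must be at least 2", call. = FALSE)
  if (cv_a < 0 || cv_b <= 0 || abund_sdlog10 < 0 || cv_scatter_sdlog10 < 0)
    stop("invalid distribution parameters", call. = FALSE)
  set.seed(seed)
  n <- 10^rnorm(n_species, abund_meanlog10, abund_sdlog10)
  eta2 <- (cv_a / n + cv_b) * 10^rnorm(n_species, 0, cv_scatter_sdlog10)
  data.frame(id = sprintf("bg%04d", seq_len(n_species)),
             mean_abundance = n, cv = sqrt(eta2), nonmetabolic = FALSE,
             stringsAsFactors = FALSE)
}

#' Read or write a proteome table (TSV)
#'
#' Columns: `id` (unique), `mean_abundance` (> 0, relative scale),
#' `cv` (> 0), `nonmetabolic` (logical). User-supplied abundance tables in
#' this schema can replace the synthetic proteome in
#' [build_many_protein()].
#'
#' @param path TSV file path.
#' @return `read_proteome()`: the validated data.frame.
#' @export
read_proteome <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "mean_abundance", "cv")
  if (!all(need %in% names(tab)))
    stop("proteome table must have columns id, mean_abundance, cv", call. = FALSE)
  if (!"nonmetabolic" %in% names(tab)) tab$nonmetabolic <- FALSE
  tab$nonmetabolic <- as.logical(tab$nonmetabolic)
  if (anyDuplicated(tab$id)) stop("proteome ids must be unique", call. = FALSE)
  if (any(tab$mean_abundance <= 0)) stop("abundances must be positive", call. = FALSE)
  if (any(tab$cv <= 0)) stop("CVs must be positive", call. = FALSE)
  tab
}

#' @rdname read_proteome
#' @param tab a proteome data.frame.
#' @export
write_proteome <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Growth conditions of the lac reporter cell
#'
#' The three operating points on the Monod curve
#' \eqn{\mu_0 = \mu_{max}\phi_{0,O}/(\phi_{half} + \phi_{0,O})} with
#' \eqn{\mu_{max} = 0.8\,h^{-1}}, \eqn{\phi_{half} = 0.005} and operon mass
#' fraction \eqn{\phi_{0,O}/\phi_{half} \in \{0.3, 1.3, 15\}} for the slow,
#' intermediate and fast conditions. The operon's growth-control coefficient
#' is the log-slope of the curve at the operating point
#' ([monod_log_slope()]), i.e. \{0.77, 0.43, 0.063\} to two significant
#' figures.
#'
#' @param name one of `"slow"`, `"intermediate"`, `"fast"`.
#' @param mu_max,phi_half Monod parameters.
#' @param ratio operating point \eqn{\phi_{0,O}/\phi_{half}}; defaults to
#'   the named condition's value.
#' @return list with `name`, `phi_O`, `mu0`, `gcc_O`, `mu_max`, `phi_half`.
#' @export
growth_condition <- function(name = c("slow", "intermediate", "fast"),
                             mu_max = 0.8, phi_half = 0.005, ratio = NULL) {
  name <- match.arg(name)
  if (is.null(ratio))
    ratio <- c(slow = 0.3, intermediate = 1.3, fast = 15)[[name]]
  phi_O <- ratio * phi_half
  list(name = name, phi_O = phi_O,
       mu0 = mu_max * phi_O / (phi_half + phi_O),
       gcc_O = monod_log_slope(mu_max, phi_half, phi_O),
       mu_max = mu_max, phi_half = phi_half)
}

#' Add the lac-operon reporter construct to a background proteome
#'
#' Represents the lac operon as three proteins Y, Z and G (LacY, LacZ and a
#' GFP reporter) sharing the operon mass fraction \eqn{\phi_O} equally, each
#' with a private noise source plus one shared operon-level source `N_O`.
#' Background mass fractions are rescaled to fill \eqn{1 - \phi_O} in the
#' proteome table's proportions. Noise amplitudes are left at zero until
#' [fit_noise()]; all reversion rates are set to `beta`.
#'
#' @param tab a proteome table (see [read_proteome()]).
#' @param condition a [growth_condition()].
#' @param beta reversion rate for every source (\eqn{h^{-1}}).
#' @return an unfitted `gn_model` (mass structure and sources only; GCCs and
#'   amplitudes unset). The proteome table is carried in `$meta$proteome`.
#' @export
add_lac_construct <- function(tab, condition, beta = 4 * condition$mu_max) {
  phi_O <- condition$phi_O
  if (phi_O >= 1) stop("operon mass fraction must be below 1", call. = FALSE)
  if (any(c("Y", "Z", "G") %in% tab$id))
    stop("proteome table already contains Y/Z/G", call. = FALSE)
  f_bg <- (1 - phi_O) * tab$mean_abundance / sum(tab$mean_abundance)
  proteins <- rbind(
    data.frame(id = tab$id, f = f_bg, theta = 0, beta = beta, gcc = NA_real_,
               nonmetabolic = tab$nonmetabolic, operon = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = c("Y", "Z", "G"), f = phi_O / 3, theta = 0, beta = beta,
               gcc = NA_real_, nonmetabolic = c(FALSE, FALSE, TRUE),
               operon = "lac", stringsAsFactors = FALSE)
  )
  # exact unit sum despite floating-point division
  proteins$f <- proteins$f / sum(proteins$f)
  shared <- shared_noise("N_O", theta = 0, beta = beta,
                         members = c(Y = 1, Z = 1, G = 1) / 3)
  structure(list(proteins = proteins, shared = list(shared), growth = NULL,
                 mu0 = condition$mu0,
                 meta = list(condition = condition, proteome = tab)),
            class = "gn_model")
}

#' Assign growth-control coefficients under the zero-sum rule
#'
#' Background proteins are shuffled (seeded) and added to the non-metabolic
#' sector H until its mass first reaches `nonmetabolic_mass_target`; each
#' \eqn{h \in H} receives \eqn{C_h^\mu = -\phi_h}. GFP is non-metabolic
#' (\eqn{C_G^\mu = -\phi_{0,G}}), and Y and Z split the remaining operon
#' control equally: \eqn{C_Y^\mu = C_Z^\mu = (C_O^\mu - C_G^\mu)/2}. The
#' remaining metabolic background proteins draw non-negative raw scores
#' \eqn{\phi_i \times \mathrm{Exp}(1)} (larger abundance tends to larger
#' control) and are then shifted in proportion to their mass so that the
#' grand total is exactly zero.
#'
#' @param model an unfitted model from [add_lac_construct()].
#' @param condition the matching [growth_condition()].
#' @param nonmetabolic_mass_target mass fraction to place in H.
#' @param seed integer seed (shuffle and score draws).
#' @param gcc_O operon GCC; defaults to the condition's Monod log-slope.
#'   Overriding it (e.g. to a negative value) re-balances the metabolic
#'   background so the sum rule still holds.
#' @return the model with a complete `gcc` column and `nonmetabolic` flags.
#' @export
assign_gccs <- function(model, condition, nonmetabolic_mass_target = 0.25,
                        seed = 1, gcc_O = NULL) {
  stopifnot(nonmetabolic_mass_target > 0, nonmetabolic_mass_target < 1)
  if (is.null(gcc_O)) gcc_O <- condition$gcc_O
  p <- model$proteins
  bg <- which(is.na(match(p$id, c("Y", "Z", "G"))))
  set.seed(seed)
  ord <- sample(bg)
  cum <- cumsum(p$f[ord])
  nH <- which(cum >= nonmetabolic_mass_target)[1]
  if (is.na(nH)) nH <- length(ord)
  H <- ord[seq_len(nH)]
  p$nonmetabolic[] <- FALSE
  p$nonmetabolic[H] <- TRUE
  p$gcc <- NA_real_
  p$gcc[H] <- -p$f[H]
  iG <- match("G", p$id); iY <- match("Y", p$id); iZ <- match("Z", p$id)
  p$nonmetabolic[iG] <- TRUE
  p$gcc[iG] <- -p$f[iG]
  p$gcc[c(iY, iZ)] <- (gcc_O - p$gcc[iG]) / 2
  met <- setdiff(bg, H)
  if (length(met) == 0)
    stop("no metabolic background proteins left to carry positive control",
         call. = FALSE)
  raw <- p$f[met] * rexp(length(met))
  needed <- -(sum(p$gcc[H]) + p$gcc[iG] + p$gcc[iY] + p$gcc[iZ])
  p$gcc[met] <- raw + p$f[met] / sum(p$f[met]) * (needed - sum(raw))
  model$proteins <- p
  model$meta$gcc_O <- gcc_O
  model$meta$gcc_seed <- seed
  model
}

#' Fit all noise amplitudes to the target CVs
#'
#' Sets every reversion rate to \eqn{\beta = 4\mu_{max}} and solves for the
#' source amplitudes such that (i) the stationary CV of each lac protein
#' (Y, Z, G) equals `lac_cv_target`, (ii) the operon source amplitude is
#' `operon_ratio` times the GFP private amplitude, and (iii) every
#' background CV matches the proteome table. See
#' [noise_amplitudes_from_cvs()] for the inversion.
#'
#' @param model a model with assigned GCCs.
#' @param condition the matching [growth_condition()].
#' @param lac_cv_target target CV for each of Y, Z, G.
#' @param operon_ratio amplitude ratio \eqn{\theta_O/\theta_G}.
#' @return the model with all `theta` set (proteins and shared source).
#' @export
fit_noise <- function(model, condition, lac_cv_target = 0.15,
                      operon_ratio = 1.5) {
  p <- model$proteins
  beta <- 4 * condition$mu_max
  p$beta[] <- beta
  tab <- model$meta$proteome
  target <- setNames(rep(lac_cv_target, nrow(p)), p$id)
  bg <- match(tab$id, p$id)
  target[bg] <- tab$cv
  phi0 <- setNames(p$f, p$id)
  np <- nrow(p)
  W <- rbind(diag(np),
             N_O = as.numeric(p$id %in% c("Y", "Z", "G")) / 3)
  dimnames(W) <- list(c(p$id, "N_O"), p$id)
  theta <- noise_amplitudes_from_cvs(
    target[p$id], beta = beta, mu0 = condition$mu0, phi0 = phi0, W = W,
    ratios = data.frame(source = "N_O", ref = "G", ratio = operon_ratio))
  p$theta <- theta[p$id]
  model$proteins <- p
  model$shared <- list(shared_noise("N_O", theta = theta[["N_O"]],
                                    beta = beta,
                                    members = c(Y = 1, Z = 1, G = 1) / 3))
  model$meta$operon_ratio <- operon_ratio
  model$meta$lac_cv_target <- lac_cv_target
  model
}

#' Build the full many-protein lac reporter cell
#'
#' Composes [generate_background_proteome()] (or a user-supplied table),
#' [add_lac_construct()], [assign_gccs()] and [fit_noise()] into a validated
#' 1021-species model (1018 background proteins plus Y, Z, G) for one of the
#' three growth conditions. The returned model carries its mean growth rate
#' and full GCC vector (linearized growth), with the Monod parameterization
#' and all seeds recorded in `$meta`.
#'
#' @param condition condition name or a [growth_condition()] object.
#' @param seed integer; drives the proteome draw and the GCC assignment.
#' @param proteome optional proteome table replacing the synthetic one.
#' @param n_species background species count for the synthetic proteome.
#' @param nonmetabolic_mass_target,lac_cv_target,operon_ratio,gcc_O passed
#'   through to the assembly steps.
#' @param ... further arguments to [generate_background_proteome()].
#' @return a validated `gn_model`.
#' @examples
#' \donttest{
#' m <- build_many_protein("fast", seed = 1)
#' stationary_cv(m, c("Y", "Z", "G")) # each 0.15
#' }
#' @export
build_many_protein <- function(condition = c("slow", "intermediate", "fast"),
                               seed = 1, proteome = NULL, n_species = 1018,
                               nonmetabolic_mass_target = 0.25,
                               lac_cv_target = 0.15, operon_ratio = 1.5,
                               gcc_O = NULL, ...) {
  if (is.character(condition)) condition <- growth_condition(match.arg(condition))
  if (is.null(proteome))
    proteome <- generate_background_proteome(n_species, seed = seed, ...)
  model <- add_lac_construct(proteome, condition)
  model <- assign_gccs(model, condition, nonmetabolic_mass_target,
                       seed = seed + 1L, gcc_O = gcc_O)
  model <- fit_noise(model, condition, lac_cv_target, operon_ratio)
  model$meta$seed <- seed
  validate_model(model)
  model
}
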