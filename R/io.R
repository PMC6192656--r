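#' Read and write model configurations
#'
#' Serializes a `gn_model` to a structured text config (YAML, or JSON when
#' the path ends in `.json`) with keys
#' `proteins[] {id, f, theta, beta, gcc?, nonmetabolic?, operon?}`,
#' `shared[] {id, theta, beta, members[] {id, weight}}` and
#' `growth {type: monod|gcc, mu_max?, phi_half?, target?, mu0?}`. The
#' round-trip is lossless up to numeric text representation: writing uses
#' full double precision (17 significant digits).
#'
#' @param model a `gn_model`.
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return `read_model_config()`: a validated `gn_model`;
#'   `write_model_config()`: `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "gn_model"))
  p <- model$proteins
  cfg <- list(
    proteins = lapply(seq_len(nrow(p)), function(i) {
      row <- list(id = p$id[i], f = p$f[i], theta = p$theta[i],
                  beta = p$beta[i])
      if (!is.na(p$gcc[i])) row$gcc <- p$gcc[i]
      if (p$nonmetabolic[i]) row$nonmetabolic <- TRUE
      if (!is.na(p$operon[i])) row$operon <- p$operon[i]
      row
    }),
    shared = lapply(model$shared, function(s) {
      list(id = s$id, theta = s$theta, beta = s$beta,
           members = lapply(names(s$members), function(id)
             list(id = id, weight = unname(s$members[[id]]))))
    })
  )
  if (!is.null(model$growth) && inherits(model$growth, "gn_growth_monod")) {
    cfg$growth <- list(type = "monod", mu_max = model$growth$mu_max,
                       phi_half = model$growth$phi_half,
                       target = as.list(model$growth$target))
  } else {
    cfg$growth <- list(type = "gcc", mu0 = model$mu0)
  }
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17))
  } else {
    yaml::write_yaml(cfg, path,
                     handlers = list(numeric = function(x)
                       format(x, digits = 17, scientific = TRUE)))
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  if (is.null(cfg$proteins)) stop("config has no 'proteins' key", call. = FALSE)
  p <- do.call(rbind, lapply(cfg$proteins, function(row) {
    data.frame(id = row$id, f = as.numeric(row$f),
               theta = as.numeric(row$theta), beta = as.numeric(row$beta),
               gcc = if (is.null(row$gcc)) NA_real_ else as.numeric(row$gcc),
               nonmetabolic = isTRUE(row$nonmetabolic),
               operon = if (is.null(row$operon)) NA_character_ else row$operon,
               stringsAsFactors = FALSE)
  }))
  shared <- lapply(cfg$shared, function(s) {
    members <- setNames(
      vapply(s$members, function(mm) as.numeric(mm$weight), 0),
      vapply(s$members, function(mm) mm$id, ""))
    shared_noise(s$id, as.numeric(s$theta), as.numeric(s$beta), members)
  })
  growth <- NULL
  mu0 <- NULL
  if (!is.null(cfg$growth)) {
    if (identical(cfg$growth$type, "monod")) {
      growth <- growth_monod(as.numeric(cfg$growth$mu_max),
                             as.numeric(cfg$growth$phi_half),
                             unlist(cfg$growth$target))
    } else if (identical(cfg$growth$type, "gcc")) {
      mu0 <- as.numeric(cfg$growth$mu0)
    } else stop("unknown growth type in config", call. = FALSE)
  }
  cell_model(p, shared = shared, growth = growth, mu0 = mu0)
}

# Small stable digest (FNV-1a over the serialized config text) used in run
# manifests so outputs can be traced to the exact model that produced them.
model_digest <- function(model) {
  txt <- jsonlite::toJSON(list(p = model$proteins,
                               sh = lapply(model$shared, function(s)
                                 list(s$id, s$theta, s$beta, s$members)),
                               mu0 = model$mu0), digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
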