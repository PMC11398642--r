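# Model and posterior interchange containers.
#
# Both containers are versioned JSON documents: language-neutral, partially
# readable from any JSON parser, and self-describing (no side information is
# needed to read them back).  Doubles are serialized with 17 significant
# digits, which round-trips IEEE-754 binary64 exactly, so write -> read ->
# write is byte-identical.  Layout:
#   model container:      format/version, data, levels, priors, init, config
#   posterior container:  format/version, config, chains[] with per-block
#                         sample-major arrays and the final state
# Numeric arrays are stored as {dim: [...], data: [...column-major...]}.

.FORMAT_VERSION <- "1.0"

.enc_num <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x) || is.array(x))
    list(dim = as.integer(dim(x)), data = as.numeric(x),
         dimnames = if (!is.null(dimnames(x)) && !is.null(rownames(x)))
           list(rownames(x), colnames(x)))
  else as.numeric(x)
}

# JSON null (serialized NA) must decode back to NA; unlist() would drop the
# nulls and silently shift every following array element.
.num_vec <- function(lst) {
  if (!is.list(lst)) return(as.numeric(lst))
  u <- unlist(lst)
  if (length(u) == length(lst)) return(as.numeric(u))  # no nulls dropped
  vapply(lst, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
         numeric(1))
}

.dec_num <- function(e) {
  if (is.null(e)) return(NULL)
  if (is.list(e) && !is.null(e$dim)) {
    a <- array(.num_vec(e$data), dim = as.integer(unlist(e$dim)))
    if (!is.null(e$dimnames) && length(e$dimnames) == 2)
      dimnames(a) <- lapply(e$dimnames, unlist)
    a
  } else .num_vec(e)
}

.enc_level <- function(lev) {
  list(name = lev$name, assignment = as.integer(lev$assignment),
       units = lev$units, n_units = lev$n_units,
       spatial_method = lev$spatial_method,
       coords = .enc_num(lev$coords), knots = .enc_num(lev$knots),
       n_knots = lev$n_knots, n_neighbours = lev$n_neighbours,
       n_factors = lev$n_factors)
}

.dec_level <- function(e) {
  structure(list(name = unlist(e$name), assignment = as.integer(unlist(e$assignment)),
                 units = unlist(e$units), n_units = as.integer(unlist(e$n_units)),
                 spatial_method = unlist(e$spatial_method),
                 coords = .dec_num(e$coords), knots = .dec_num(e$knots),
                 n_knots = as.integer(unlist(e$n_knots)),
                 n_neighbours = as.integer(unlist(e$n_neighbours)),
                 n_factors = as.integer(unlist(e$n_factors))),
            class = "jsdm_level")
}

.enc_priors <- function(pr) {
  list(V0 = .enc_num(pr$V0), f0 = pr$f0, mGamma = .enc_num(pr$mGamma),
       UGamma = .enc_num(pr$UGamma),
       rho_grid = list(values = pr$rho_grid$values, weights = pr$rho_grid$weights),
       shrinkage = pr$shrinkage, nu = pr$nu,
       alpha_grid = lapply(pr$alpha_grid, function(ag)
         if (is.null(ag)) NULL else list(values = ag$values, weights = ag$weights)),
       sigma_prior = pr$sigma_prior)
}

.dec_priors <- function(e) {
  structure(list(
    V0 = .dec_num(e$V0), f0 = as.numeric(unlist(e$f0)),
    mGamma = .dec_num(e$mGamma), UGamma = .dec_num(e$UGamma),
    rho_grid = list(values = .dec_num(e$rho_grid$values),
                    weights = .dec_num(e$rho_grid$weights)),
    shrinkage = lapply(e$shrinkage, function(x) as.numeric(unlist(x))),
    nu = as.numeric(unlist(e$nu)),
    alpha_grid = lapply(e$alpha_grid, function(ag)
      if (is.null(ag) || !length(ag)) NULL
      else list(values = .dec_num(ag$values), weights = .dec_num(ag$weights))),
    sigma_prior = lapply(e$sigma_prior, function(x) as.numeric(unlist(x)))
  ), class = "jsdm_priors")
}

.enc_state <- function(st) {
  list(Beta = .enc_num(st$Beta), Gamma = .enc_num(st$Gamma), V = .enc_num(st$V),
       rho_idx = st$rho_idx, rho = st$rho,
       levels = lapply(st$levels, function(sl)
         list(Eta = .enc_num(sl$Eta), Lambda = .enc_num(sl$Lambda),
              Psi = .enc_num(sl$Psi), Delta = .enc_num(sl$Delta),
              alpha_idx = as.integer(sl$alpha_idx))),
       sigma2 = .enc_num(st$sigma2), Z = .enc_num(st$Z),
       cycle = st$cycle, chain_index = st$chain_index, seed = st$seed)
}

.dec_state <- function(e) {
  structure(list(
    Beta = .dec_num(e$Beta), Gamma = .dec_num(e$Gamma), V = .dec_num(e$V),
    rho_idx = as.integer(unlist(e$rho_idx)), rho = as.numeric(unlist(e$rho)),
    levels = lapply(e$levels, function(sl)
      list(Eta = .dec_num(sl$Eta), Lambda = .dec_num(sl$Lambda),
           Psi = .dec_num(sl$Psi), Delta = .dec_num(sl$Delta),
           alpha_idx = as.integer(unlist(sl$alpha_idx)))),
    sigma2 = .dec_num(e$sigma2), Z = .dec_num(e$Z),
    cycle = as.integer(unlist(e$cycle)),
    chain_index = as.integer(unlist(e$chain_index)),
    seed = as.integer(unlist(e$seed))), class = "jsdm_state")
}

.write_json <- function(x, path) {
  json <- jsonlite::toJSON(x, digits = I(17), auto_unbox = FALSE,
                           null = "null", na = "null", pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

.read_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("truncated or corrupt container: ",
                                           conditionMessage(e)))
  out
}

.check_format <- function(doc, expected) {
  if (is.null(doc$format) || unlist(doc$format) != expected)
    stop(sprintf("not a %s container", expected))
  v <- unlist(doc$version)
  if (is.null(v) || v != .FORMAT_VERSION)
    stop(sprintf("container format version '%s' does not match supported version '%s'",
                 v, .FORMAT_VERSION))
}

#' Write a model container
#'
#' Serializes a validated model, the initial chain states and the MCMC
#' configuration into a versioned JSON container with sections data, levels,
#' priors, init, config.  This is the cross-process hand-off between model
#' definition and (possibly remote) fitting.
#'
#' @param model a \code{jsdm_model}.
#' @param init_states list of \code{jsdm_state}, one per chain.
#' @param config a \code{jsdm_mcmc_config}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_model <- function(model, init_states, config, path) {
  rep <- validate_model(model)
  if (length(rep)) stop("invalid model:\n  - ", paste(rep, collapse = "\n  - "))
  if (length(init_states) != config$n_chains)
    stop("need one init state per chain")
  doc <- list(
    format = "jsdmgibbs-model", version = .FORMAT_VERSION,
    data = list(Y = .enc_num(model$Y), X = .enc_num(model$X),
                Tr = .enc_num(model$Tr), C = .enc_num(model$C),
                response = model$response,
                unit_names = model$unit_names, species_names = model$species_names,
                covariate_names = model$covariate_names, trait_names = model$trait_names),
    levels = lapply(model$levels, .enc_level),
    priors = .enc_priors(model$priors),
    init = lapply(init_states, .enc_state),
    config = unclass(config))
  .write_json(doc, path)
}

#' Read a model container
#'
#' @param path container path.
#' @return list with \code{model}, \code{init_states}, \code{config}.
#' @export
read_model <- function(path) {
  doc <- .read_json(path)
  .check_format(doc, "jsdmgibbs-model")
  for (grp in c("data", "levels", "priors", "init", "config"))
    if (is.null(doc[[grp]])) stop("container is missing the '", grp, "' group")
  d <- doc$data
  model <- structure(list(
    Y = .dec_num(d$Y), X = .dec_num(d$X), Tr = .dec_num(d$Tr),
    C = .dec_num(d$C),
    levels = lapply(doc$levels, .dec_level),
    priors = .dec_priors(doc$priors),
    response = unlist(d$response),
    n_y = nrow(.dec_num(d$Y)), n_s = ncol(.dec_num(d$Y)),
    n_c = ncol(.dec_num(d$X)), n_t = ncol(.dec_num(d$Tr)),
    unit_names = unlist(d$unit_names), species_names = unlist(d$species_names),
    covariate_names = unlist(d$covariate_names), trait_names = unlist(d$trait_names)
  ), class = "jsdm_model")
  cfg <- doc$config
  config <- mcmc_config(samples = unlist(cfg$samples), thin = unlist(cfg$thin),
                        transient = unlist(cfg$transient),
                        n_chains = unlist(cfg$n_chains), seed = unlist(cfg$seed),
                        verbose_every = unlist(cfg$verbose_every),
                        retain_eta = unlist(cfg$retain_eta))
  list(model = model, init_states = lapply(doc$init, .dec_state), config = config)
}

.enc_draws <- function(arr) {
  list(Beta = .enc_num(arr$Beta), Gamma = .enc_num(arr$Gamma), V = .enc_num(arr$V),
       rho = .enc_num(arr$rho), sigma2 = .enc_num(arr$sigma2),
       levels = lapply(arr$levels, function(l)
         list(Lambda = .enc_num(l$Lambda), Delta = .enc_num(l$Delta),
              Psi = .enc_num(l$Psi), alpha = .enc_num(l$alpha),
              Eta = .enc_num(l$Eta))))
}

.dec_draws <- function(e) {
  list(Beta = .dec_num(e$Beta), Gamma = .dec_num(e$Gamma), V = .dec_num(e$V),
       rho = .dec_num(e$rho), sigma2 = .dec_num(e$sigma2),
       levels = lapply(e$levels, function(l)
         list(Lambda = .dec_num(l$Lambda), Delta = .dec_num(l$Delta),
              Psi = .dec_num(l$Psi), alpha = .dec_num(l$alpha),
              Eta = .dec_num(l$Eta))))
}

.enc_chain <- function(ch) {
  # Wall-clock timings are deliberately not serialized: the container must be
  # a pure function of (model, config, chain_index) so that parallel and
  # sequential runs write bit-identical files.  Timings go to a CSV log via
  # write_timings_csv().
  list(chain_index = ch$chain_index, n_retained = ch$n_retained,
       cycles_done = ch$cycles_done, cycles_scheduled = ch$cycles_scheduled,
       complete = ch$complete, draws = .enc_draws(ch$draws),
       state = .enc_state(ch$state))
}

.dec_chain <- function(e, config) {
  structure(list(
    chain_index = as.integer(unlist(e$chain_index)), config = config,
    draws = .dec_draws(e$draws),
    n_retained = as.integer(unlist(e$n_retained)),
    cycles_done = as.integer(unlist(e$cycles_done)),
    cycles_scheduled = as.integer(unlist(e$cycles_scheduled)),
    complete = as.logical(unlist(e$complete)),
    state = .dec_state(e$state),
    timings = numeric(0)), class = "jsdm_chain")
}

.config_fingerprint <- function(config)
  paste(config$samples, config$thin, config$transient, config$seed, sep = "/")

#' Write a posterior container
#'
#' One group per chain with sample-major parameter arrays, the configuration
#' echo and the final state (which makes checkpoint/resume possible).  The
#' container is a pure function of (model, config, chain indices), so
#' re-running the same configuration rewrites it bit for bit; per-cycle wall
#' times are exported separately by \code{\link{write_timings_csv}}.
#' With \code{append = TRUE}, chains are merged into an existing
#' container: new chain indices are added, and an existing index is replaced
#' when the incoming chain has progressed further.
#'
#' @param chains a \code{jsdm_chain} or list thereof.
#' @param path output path.
#' @param append merge into an existing container.
#' @return the path, invisibly.
#' @export
write_posterior <- function(chains, path, append = FALSE) {
  if (inherits(chains, "jsdm_chain")) chains <- list(chains)
  stopifnot(length(chains) >= 1)
  config <- chains[[1]]$config
  if (append && file.exists(path)) {
    old <- read_posterior(path)
    if (.config_fingerprint(old$config) != .config_fingerprint(config))
      stop("cannot append: MCMC configuration does not match the existing container")
    pool <- old$chains
    for (ch in chains) {
      slot <- which(vapply(pool, function(p) p$chain_index, integer(1)) == ch$chain_index)
      if (length(slot)) {
        if (ch$cycles_done >= pool[[slot]]$cycles_done) pool[[slot]] <- ch
      } else pool <- c(pool, list(ch))
    }
    chains <- pool
  }
  ord <- order(vapply(chains, function(ch) ch$chain_index, integer(1)))
  chains <- chains[ord]
  doc <- list(format = "jsdmgibbs-posterior", version = .FORMAT_VERSION,
              config = unclass(config),
              chains = lapply(chains, .enc_chain))
  .write_json(doc, path)
}

#' Read a posterior container
#'
#' @param path container path.
#' @return object of class \code{jsdm_posterior}: \code{config} plus a list
#'   of \code{jsdm_chain}, ordered by chain index.
#' @export
read_posterior <- function(path) {
  doc <- .read_json(path)
  .check_format(doc, "jsdmgibbs-posterior")
  cfg <- doc$config
  config <- mcmc_config(samples = unlist(cfg$samples), thin = unlist(cfg$thin),
                        transient = unlist(cfg$transient),
                        n_chains = unlist(cfg$n_chains), seed = unlist(cfg$seed),
                        verbose_every = unlist(cfg$verbose_every),
                        retain_eta = unlist(cfg$retain_eta))
  chains <- lapply(doc$chains, .dec_chain, config = config)
  structure(list(config = config, chains = chains), class = "jsdm_posterior")
}

#' Stack one parameter block across chains
#'
#' @param posterior a \code{jsdm_posterior} or list of \code{jsdm_chain}.
#' @param name one of "Beta", "Gamma", "V", "rho", "sigma2", "Lambda",
#'   "Delta", "Psi", "alpha", "Eta".
#' @param level level index for per-level blocks.
#' @return array of shape (n_chains, samples, ...).
#' @export
posterior_array <- function(posterior, name, level = 1L) {
  chains <- if (inherits(posterior, "jsdm_posterior")) posterior$chains else posterior
  pick <- function(ch) {
    d <- ch$draws
    if (name %in% c("Lambda", "Delta", "Psi", "alpha", "Eta"))
      d$levels[[level]][[name]]
    else d[[name]]
  }
  first <- pick(chains[[1]])
  dims <- if (is.null(dim(first))) length(first) else dim(first)
  out <- array(NA_real_, c(length(chains), dims))
  for (k in seq_along(chains)) {
    x <- pick(chains[[k]])
    if (length(dims) == 1) out[k, ] <- x
    else if (length(dims) == 2) out[k, , ] <- x
    else out[k, , , ] <- x
  }
  out
}

#' Export posterior samples as flat CSV
#'
#' Mirrors the container as one long table (chain, sample, parameter, value)
#' for consumption from R or spreadsheets.
#'
#' @param posterior a \code{jsdm_posterior}.
#' @param path output CSV path.
#' @param blocks which parameter blocks to export.
#' @return the path, invisibly.
#' @export
posterior_to_csv <- function(posterior, path, blocks = c("Beta", "Gamma", "rho")) {
  rows <- list()
  for (ch in posterior$chains) {
    for (b in blocks) {
      x <- if (b %in% c("Lambda", "Delta", "Psi", "alpha", "Eta"))
        ch$draws$levels[[1]][[b]] else ch$draws[[b]]
      if (is.null(x)) next
      if (is.null(dim(x))) dim(x) <- length(x)
      flat <- as.data.frame.table(x, responseName = "value", stringsAsFactors = FALSE)
      iv <- lapply(flat[-ncol(flat)], function(z) as.integer(factor(z, levels = unique(z))))
      lab <- if (length(iv) > 1)
        paste0(b, "[", do.call(paste, c(iv[-1], sep = ",")), "]") else b
      rows[[length(rows) + 1]] <- data.frame(chain = ch$chain_index,
                                             sample = iv[[1]],
                                             parameter = lab,
                                             value = flat$value)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
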