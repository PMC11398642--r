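# Plain-file interfaces: CSV matrices, the study-design table, Newick trees,
# and a JSON model-configuration file enumerating them.

#' Read a labelled numeric matrix from CSV
#'
#' Expects a header row and row labels in the first column.
#'
#' @param path CSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write a labelled numeric matrix to CSV
#'
#' @param m matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a study-design table
#'
#' Columns: \code{unit} (sampling-unit id), \code{level_unit} (random-level
#' unit id), and optional coordinates \code{x}, \code{y}.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("unit", "level_unit")
  if (!all(need %in% names(df)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a synthetic dataset as the CSV/Newick/JSON file set
#'
#' Produces exactly the files the model-configuration loader reads:
#' \code{Y.csv}, \code{X.csv}, \code{Tr.csv}, \code{design.csv}, optionally
#' \code{taxonomy.csv}, plus \code{truth.json} (the generating parameters) and
#' a ready-to-use \code{model_config.json}.
#'
#' @param dataset output of \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @param response response type recorded in the config.
#' @return the config path, invisibly.
#' @export
write_dataset <- function(dataset, dir, response = dataset$truth$response) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(dataset$data$Y, file.path(dir, "Y.csv"))
  write_matrix_csv(dataset$data$X, file.path(dir, "X.csv"))
  write_matrix_csv(dataset$data$Tr, file.path(dir, "Tr.csv"))
  utils::write.csv(dataset$design, file.path(dir, "design.csv"), row.names = FALSE)
  files <- list(Y = "Y.csv", X = "X.csv", Tr = "Tr.csv", design = "design.csv")
  if (!is.null(dataset$data$taxonomy)) {
    utils::write.csv(dataset$data$taxonomy, file.path(dir, "taxonomy.csv"),
                     row.names = FALSE)
    files$taxonomy <- "taxonomy.csv"
  }
  levels_cfg <- if (!is.null(dataset$level)) {
    lev <- dataset$level
    list(list(name = lev$name, spatial_method = lev$spatial_method,
              n_factors = lev$n_factors, n_neighbours = lev$n_neighbours,
              n_knots = lev$n_knots))
  } else list()
  cfg <- list(response = response, files = files, levels = levels_cfg)
  .write_json(cfg, file.path(dir, "model_config.json"))
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    .write_json(list(Beta = .enc_num(tr$Beta), Gamma = .enc_num(tr$Gamma),
                     V = .enc_num(tr$V), rho = tr$rho,
                     Lambda = .enc_num(tr$Lambda), Eta = .enc_num(tr$Eta),
                     alpha = tr$alpha, sigma2 = .enc_num(tr$sigma2),
                     seed = tr$seed, response = tr$response),
                file.path(dir, "truth.json"))
  }
  invisible(file.path(dir, "model_config.json"))
}

#' Write the per-cycle timing log of one or more chains
#'
#' One row per executed Gibbs cycle with columns \code{chain}, \code{cycle},
#' \code{seconds}.  This is the input of the benchmark harness; timings are
#' kept out of the posterior container so that containers are bit-identical
#' across reruns and scheduling.
#'
#' @param chains a \code{jsdm_chain} or list thereof.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_timings_csv <- function(chains, path) {
  if (inherits(chains, "jsdm_chain")) chains <- list(chains)
  rows <- do.call(rbind, lapply(chains, function(ch)
    data.frame(chain = ch$chain_index, cycle = seq_along(ch$timings),
               seconds = as.numeric(ch$timings))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Build a model from a JSON configuration file
#'
#' The configuration enumerates the input files (relative to its own
#' directory), the response type, the random levels, and optional prior
#' overrides (any field of \code{\link{default_priors}}).
#'
#' @param path path to \code{model_config.json}.
#' @return a validated \code{jsdm_model}.
#' @export
model_from_config <- function(path) {
  cfg <- .read_json(path)
  base <- dirname(path)
  fp <- function(f) file.path(base, unlist(f))
  files <- cfg$files
  Y <- read_matrix_csv(fp(files$Y))
  X <- read_matrix_csv(fp(files$X))
  Tr <- if (!is.null(files$Tr)) read_matrix_csv(fp(files$Tr)) else NULL
  C <- NULL
  if (!is.null(files$taxonomy)) {
    tax <- utils::read.csv(fp(files$taxonomy), check.names = FALSE,
                           stringsAsFactors = FALSE)
    C <- taxonomy_to_correlation(tax)
    C <- C[colnames(Y), colnames(Y)]
  } else if (!is.null(files$tree)) {
    C <- newick_to_correlation(fp(files$tree), species = colnames(Y))
  }
  design <- if (!is.null(files$design)) read_design_csv(fp(files$design)) else NULL
  levels <- lapply(cfg$levels, function(lc) {
    if (is.null(design)) stop("levels require a design table")
    units <- unique(design$level_unit)
    coords <- NULL
    if (all(c("x", "y") %in% names(design))) {
      first <- match(units, design$level_unit)
      coords <- cbind(design$x[first], design$y[first])
      rownames(coords) <- units
    }
    random_level(design$level_unit,
                 spatial_method = unlist(lc$spatial_method) %||% "none",
                 coords = coords,
                 n_knots = unlist(lc$n_knots) %||% 55L,
                 n_neighbours = unlist(lc$n_neighbours) %||% 10L,
                 n_factors = unlist(lc$n_factors) %||% 10L,
                 name = unlist(lc$name) %||% "level")
  })
  model <- build_model(Y, X, Tr, C, levels, response = unlist(cfg$response))
  if (!is.null(cfg$priors)) {
    ov <- cfg$priors
    pr <- model$priors
    for (f in names(ov)) {
      val <- ov[[f]]
      pr[[f]] <- switch(f,
        V0 = , UGamma = .dec_num(val),
        mGamma = as.numeric(unlist(val)),
        f0 = , nu = as.numeric(unlist(val)),
        rho_grid = list(values = .dec_num(val$values), weights = .dec_num(val$weights)),
        shrinkage = lapply(val, function(x) as.numeric(unlist(x))),
        sigma_prior = lapply(val, function(x) as.numeric(unlist(x))),
        alpha_grid = lapply(val, function(ag)
          if (is.null(ag) || !length(ag)) NULL
          else list(values = .dec_num(ag$values), weights = .dec_num(ag$weights))),
        stop("unknown prior field in config: ", f))
    }
    model$priors <- pr
    rep <- validate_model(model)
    if (length(rep)) stop("invalid model after prior overrides:\n  - ",
                          paste(rep, collapse = "\n  - "))
  }
  model
}
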