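# MCMC convergence diagnostics: split potential scale reduction (Gelman-Rubin
# R-hat), effective sample size by initial-positive-sequence truncation, and a
# tabular/trace-plot summary over selected scalar parameters.

#' Split potential scale reduction (R-hat)
#'
#' Each chain is split into halves; R-hat compares within- and between-half
#' variance: \code{sqrt(((n - 1) / n * W + B / n) / W)} with split length
#' \code{n}.  Values near 1 indicate convergence.
#'
#' @param chains list of numeric vectors of equal length (>= 2 chains).
#' @return scalar R-hat; \code{Inf} with attribute \code{flag =
#'   "zero-within-variance"} for degenerate (constant) chains.
#' @export
potential_scale_reduction <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need at least two chains")
  len <- unique(lengths(chains))
  if (length(len) != 1 || len < 4)
    stop("chains must have equal length >= 4")
  m <- len %/% 2
  halves <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(m)], ch[len - m + seq_len(m)])), recursive = FALSE)
  mu <- vapply(halves, mean, numeric(1))
  vr <- vapply(halves, stats::var, numeric(1))
  W <- mean(vr)
  if (W == 0 || !is.finite(W)) {
    out <- Inf
    attr(out, "flag") <- "zero-within-variance"
    return(out)
  }
  B <- m * stats::var(mu)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Effective sample size
#'
#' ESS from the autocorrelation function with Geyer initial-positive-sequence
#' truncation: consecutive lag-pair sums are accumulated while positive, and
#' \code{ESS = n / (-1 + 2 * sum(pair sums))}.  Anti-correlated chains can
#' exceed \code{n}; the estimate is capped at \code{10 n}.
#'
#' @param chain numeric vector, length >= 10.
#' @return scalar ESS; 0 with attribute \code{flag = "constant-chain"} for a
#'   constant chain.
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  if (n < 10) stop("need at least 10 draws")
  if (stats::var(chain) == 0) {
    out <- 0
    attr(out, "flag") <- "constant-chain"
    return(out)
  }
  lag_max <- min(n - 2, max(50, floor(10 * log10(n)) * 5))
  rho <- as.numeric(stats::acf(chain, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  # rho[1] = lag 0; pair sums Gamma_k = rho_{2k} + rho_{2k+1}
  tau <- -1
  k <- 0
  repeat {
    i1 <- 2 * k + 1; i2 <- 2 * k + 2
    if (i2 > length(rho)) break
    g <- rho[i1] + rho[i2]
    if (g <= 0) break
    tau <- tau + 2 * g
    k <- k + 1
  }
  tau <- max(tau, 1 / 10)   # cap ESS at 10 n
  min(n / tau, 10 * n)
}

.extract_scalar <- function(chain, name, i = NULL, j = NULL, level = 1L) {
  d <- chain$draws
  switch(name,
    Beta = d$Beta[, i, j],
    Gamma = d$Gamma[, i, j],
    V = d$V[, i, j],
    rho = d$rho,
    sigma2 = d$sigma2[, i],
    Lambda = d$levels[[level]]$Lambda[, i, j],
    Delta = d$levels[[level]]$Delta[, i],
    alpha = d$levels[[level]]$alpha[, i],
    Eta = d$levels[[level]]$Eta[, i, j],
    stop("unknown parameter: ", name))
}

.selector_grid <- function(chain, selector, level = 1L) {
  # "Beta", "Beta[2,3]", "Beta[*,*]", "rho", "sigma2[4]" -> index table
  m <- regmatches(selector, regexec("^([A-Za-z2]+)(\\[([^]]*)\\])?$", selector))[[1]]
  if (!length(m)) stop("cannot parse selector: ", selector)
  name <- m[2]
  d <- chain$draws
  dims <- switch(name,
    Beta = dim(d$Beta)[-1], Gamma = dim(d$Gamma)[-1], V = dim(d$V)[-1],
    rho = integer(0), sigma2 = dim(d$sigma2)[2],
    Lambda = dim(d$levels[[level]]$Lambda)[-1],
    Delta = dim(d$levels[[level]]$Delta)[2],
    alpha = dim(d$levels[[level]]$alpha)[2],
    Eta = dim(d$levels[[level]]$Eta)[-1],
    stop("unknown parameter: ", name))
  idx <- if (m[4] == "" || is.na(m[4])) rep("*", length(dims))
         else trimws(strsplit(m[4], ",")[[1]])
  if (length(idx) != length(dims))
    stop(sprintf("selector '%s' has %d indices but parameter has %d dimensions",
                 selector, length(idx), length(dims)))
  ranges <- lapply(seq_along(dims), function(k)
    if (idx[k] == "*") seq_len(dims[k]) else as.integer(idx[k]))
  grid <- if (length(ranges)) expand.grid(ranges) else data.frame(row.names = 1)
  list(name = name, grid = grid)
}

#' Summary table (and optional trace plots) for selected parameters
#'
#' For every scalar parameter matched by the selectors, reports posterior
#' mean, sd, split R-hat across chains, and the minimum per-chain ESS.
#' R-hat is omitted (NA, flagged) for a single chain.  Latent-factor blocks
#' (Lambda, Eta) are subject to sign/rotation non-identifiability and are only
#' reported when selected explicitly.
#'
#' @param chains list of \code{jsdm_chain} objects.
#' @param selectors character vector like \code{c("Beta[*,*]", "rho")}.
#' @param level level index for per-level parameters.
#' @param plot_dir if non-NULL, write one PNG trace plot per parameter there.
#' @return data frame with columns parameter, mean, sd, rhat, ess, flag.
#' @export
trace_summary <- function(chains, selectors, level = 1L, plot_dir = NULL) {
  if (inherits(chains, "jsdm_chain")) chains <- list(chains)
  if (!length(chains)) stop("need at least one chain")
  if (!length(selectors)) stop("empty parameter selection")
  rows <- list()
  for (sel in selectors) {
    sg <- .selector_grid(chains[[1]], sel, level)
    n_ix <- nrow(sg$grid)
    for (g in seq_len(n_ix)) {
      ij <- as.integer(sg$grid[g, ])
      series <- lapply(chains, .extract_scalar, name = sg$name,
                       i = if (length(ij) >= 1) ij[1],
                       j = if (length(ij) >= 2) ij[2], level = level)
      all_draws <- unlist(series)
      lab <- if (length(ij)) sprintf("%s[%s]", sg$name, paste(ij, collapse = ","))
             else sg$name
      flag <- ""
      rhat <- if (length(chains) >= 2) {
        rh <- potential_scale_reduction(series)
        if (!is.null(attr(rh, "flag"))) flag <- attr(rh, "flag")
        as.numeric(rh)
      } else { flag <- "single-chain"; NA_real_ }
      ess <- sum(vapply(series, function(s) {
        e <- effective_sample_size(s); as.numeric(e)
      }, numeric(1)))
      if (!is.null(plot_dir)) {
        dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
        fn <- file.path(plot_dir, paste0(gsub("[^A-Za-z0-9]", "_", lab), ".png"))
        grDevices::png(fn, width = 700, height = 350)
        graphics::matplot(do.call(cbind, series), type = "l", lty = 1,
                          xlab = "retained sample", ylab = lab,
                          main = paste("trace:", lab))
        grDevices::dev.off()
      }
      rows[[length(rows) + 1]] <- data.frame(
        parameter = lab, mean = mean(all_draws), sd = stats::sd(all_draws),
        rhat = rhat, ess = ess, flag = flag, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
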