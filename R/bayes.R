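#' Gaussian iid log-likelihood of a misfit
#'
#' Log-likelihood of `n_points` iid Gaussian residuals whose summed squared
#' misfit is `misfit`:
#' `-n_points/2 * log(2*pi*sigma^2) - misfit/(2*sigma^2)`.
#'
#' @param misfit summed squared residuals (>= 0)
#' @param sigma residual standard deviation (> 0), in data units; absorbs
#'   both measurement noise and model inadequacy
#' @param n_points number of data points
#' @return scalar log-likelihood
#' @export
log_likelihood <- function(misfit, sigma, n_points) {
  stopifnot(all(misfit >= 0), n_points >= 1)
  if (any(sigma <= 0)) stop("sigma must be positive")
  -n_points / 2 * log(2 * pi * sigma^2) - misfit / (2 * sigma^2)
}

new_posterior_summary <- function(kind, support, log_post, weights, mle,
                                  acceptance_rate = NA_real_) {
  structure(list(kind = kind, support = support, log_post = log_post,
                 weights = weights, mle = mle,
                 acceptance_rate = acceptance_rate),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary: %s, %d support points, %d parameter(s)>\n",
              x$kind, nrow(x$support), ncol(x$support)))
  cat("MLE:\n")
  print(x$mle)
  if (!is.na(x$acceptance_rate))
    cat(sprintf("acceptance rate: %.3f\n", x$acceptance_rate))
  g <- try(fit_gaussian(x), silent = TRUE)
  if (!inherits(g, "try-error")) {
    cat("Gaussian fit:\n")
    for (p in rownames(g))
      cat(" ", p, "~", format_gaussian(g[p, "mean"], g[p, "sd"]), "\n")
  }
  invisible(x)
}

#' Format a Gaussian fit as N(mean, sd)
#'
#' @param mean,sd moments of the fit
#' @param digits decimal places to print
#' @return character scalar such as `"N(243.0, 18.1)"`
#' @export
format_gaussian <- function(mean, sd, digits = 1) {
  sprintf("N(%.*f, %.*f)", digits, mean, digits, sd)
}

#' Posterior by naive grid quadrature
#'
#' Evaluates the misfit on a regular grid spanning a uniform prior box and
#' converts it to a normalized posterior via the Gaussian likelihood
#' (uniform priors cancel, so the posterior is proportional to the
#' likelihood). Grid point weights sum to one; the maximum-likelihood
#' estimate is the grid argmax, ties broken by the lowest parameter value.
#'
#' @param misfit_fn function mapping a parameter vector to a summed squared
#'   misfit; if `vectorized = TRUE` it must accept a matrix with one row
#'   per parameter set and return a vector
#' @param lower,upper named prior bounds (one entry per parameter)
#' @param n_grid points per dimension (>= 2), scalar or per-parameter
#' @param sigma likelihood standard deviation (data units)
#' @param n_points number of data points behind the misfit
#' @param vectorized whether `misfit_fn` is row-vectorized
#' @return a `posterior_summary` (kind `"grid"`)
#' @export
quadrature_posterior <- function(misfit_fn, lower, upper, n_grid = 50,
                                 sigma = 1, n_points = 1,
                                 vectorized = FALSE) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            all(n_grid >= 2))
  p <- length(lower)
  if (is.null(names(lower))) names(lower) <- paste0("p", seq_len(p))
  n_grid <- rep_len(n_grid, p)
  axes <- lapply(seq_len(p), function(i)
    seq(lower[i], upper[i], length.out = n_grid[i]))
  names(axes) <- names(lower)
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  misfit <- if (vectorized) misfit_fn(grid) else
    apply(grid, 1, function(row) misfit_fn(row))
  if (any(!is.finite(misfit))) {
    bad <- which(!is.finite(misfit))[1]
    stop("misfit_fn failed at grid point (",
         paste(signif(grid[bad, ], 6), collapse = ", "), ")")
  }
  lp <- log_likelihood(misfit, sigma, n_points)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  i_mle <- which(lp == max(lp))[1]  # expand.grid order: lowest values first
  mle <- grid[i_mle, ]
  new_posterior_summary("grid", grid, lp, w, mle)
}

#' Marginal posterior density of one parameter
#'
#' Collapses a grid posterior onto one parameter axis. The returned density
#' is normalized so its trapezoid-rule integral over the axis is one.
#'
#' @param post a grid `posterior_summary`
#' @param parameter column name or index
#' @return data.frame with columns `value` and `density`
#' @export
marginal_density <- function(post, parameter) {
  stopifnot(inherits(post, "posterior_summary"), post$kind == "grid")
  x <- post$support[, parameter]
  vals <- sort(unique(x))
  mass <- vapply(vals, function(v) sum(post$weights[x == v]), 0)
  dens <- mass
  if (length(vals) > 1) {
    tz <- sum(diff(vals) * (head(dens, -1) + tail(dens, -1)) / 2)
    if (tz > 0) dens <- dens / tz
  }
  data.frame(value = vals, density = dens)
}

#' Metropolis-Hastings sampling of a posterior
#'
#' Gaussian random-walk Metropolis-Hastings. The first `burn_frac` of the
#' chain is discarded; no thinning is applied. Deterministic given `seed`.
#'
#' @param log_post_fn function mapping a parameter vector to the
#'   unnormalized log posterior
#' @param init named initial parameter vector (finite log posterior)
#' @param proposal_sd per-parameter proposal standard deviation (> 0)
#' @param n_steps number of proposals (>= 1)
#' @param seed RNG seed (mandatory, for reproducibility)
#' @param burn_frac fraction of the chain discarded as burn-in
#' @param lower,upper optional box bounds; proposals outside are rejected
#'   (equivalent to a uniform prior on the box)
#' @return a `posterior_summary` (kind `"chain"`) whose support rows are
#'   the post-burn-in samples; the MLE slot holds the highest-posterior
#'   sample
#' @export
metropolis_hastings <- function(log_post_fn, init, proposal_sd, n_steps,
                                seed, burn_frac = 0.2,
                                lower = -Inf, upper = Inf) {
  stopifnot(n_steps >= 1, all(proposal_sd > 0))
  p <- length(init)
  if (is.null(names(init))) names(init) <- paste0("p", seq_len(p))
  proposal_sd <- rep_len(proposal_sd, p)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  lp0 <- log_post_fn(init)
  if (!is.finite(lp0)) stop("log posterior not finite at init")
  set.seed(as.integer(seed))
  chain <- matrix(NA_real_, n_steps, p, dimnames = list(NULL, names(init)))
  lps <- numeric(n_steps)
  cur <- init; lp <- lp0; n_acc <- 0L
  for (s in seq_len(n_steps)) {
    prop <- cur + rnorm(p, 0, proposal_sd)
    if (all(prop >= lower & prop <= upper)) {
      lpp <- log_post_fn(prop)
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        cur <- prop; lp <- lpp; n_acc <- n_acc + 1L
      }
    }
    chain[s, ] <- cur
    lps[s] <- lp
  }
  keep <- seq.int(floor(burn_frac * n_steps) + 1L, n_steps)
  i_mle <- keep[which.max(lps[keep])]
  new_posterior_summary("chain", chain[keep, , drop = FALSE], lps[keep],
                        rep(1 / length(keep), length(keep)),
                        chain[i_mle, ],
                        acceptance_rate = n_acc / n_steps)
}

#' Moment-matched Gaussian fit of posterior marginals
#'
#' Approximates each marginal posterior by a normal distribution with the
#' marginal's mean and standard deviation, the form sampled when
#' propagating calibration uncertainty into predictions.
#'
#' @param post a `posterior_summary`
#' @return matrix with one row per parameter and columns `mean`, `sd`
#' @export
fit_gaussian <- function(post) {
  stopifnot(inherits(post, "posterior_summary"))
  if (nrow(post$support) < 2) stop("need at least 2 support points")
  w <- post$weights / sum(post$weights)
  out <- t(apply(post$support, 2, function(x) {
    m <- sum(w * x)
    v <- sum(w * (x - m)^2)
    c(mean = m, sd = sqrt(v))
  }))
  if (any(out[, "sd"] <= 0))
    stop("degenerate (zero-variance) posterior support")
  out
}
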