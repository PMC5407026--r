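#' Estimate amplification parameters (alpha, beta) from spike-ins
#'
#' Fits the mean model \eqn{E[Q \mid Y, Z = 1] = \alpha Y^{\beta}} by
#' log-linear regression, \eqn{\log E[Q] = \log\alpha + \beta \log Y}, on the
#' strictly positive observations pooled across cells. Spike-ins are present
#' at the same known amount in every cell, so the pooled regression estimates
#' the batch-shared efficiency and amplification-bias parameters.
#'
#' @param true_molecules True molecule count per observation (vector aligned
#'   with `observed`).
#' @param observed Observed (molecule-scale) counts, zeros allowed; only
#'   nonzero values enter the regression.
#'
#' @return A list with `alpha`, `beta`, `se_log_alpha`, `se_beta`, and the
#'   fitted `glm` object (`fit`).
#' @examples
#' sp <- simulate_spike_ins(noise_identity(), c(10, 100, 1000), 20, seed = 1)
#' fit_alpha_beta(sp$true_molecules, sp$observed)[c("alpha", "beta")]
#' @export
fit_alpha_beta <- function(true_molecules, observed) {
  stopifnot(length(true_molecules) == length(observed))
  keep <- observed > 0
  if (!any(keep)) stop("All observations are zero; nothing to regress.",
                       call. = FALSE)
  y <- true_molecules[keep]
  q <- observed[keep]
  if (length(unique(y)) < 2)
    stop("Fewer than 2 distinct true spike-in levels among nonzero ",
         "observations; (alpha, beta) are not identifiable.", call. = FALSE)
  # quasipoisson: identical point estimates to the Poisson log-linear fit,
  # valid for the continuous molecule-scale observations.
  fit <- stats::glm(q ~ log(y), family = stats::quasipoisson(link = "log"))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(alpha = unname(exp(cf[1])), beta = unname(cf[2]),
       se_log_alpha = unname(se[1]), se_beta = unname(se[2]), fit = fit)
}

#' Estimate dropout parameters (kappa, tau) from spike-ins
#'
#' With `(alpha, beta)` fixed, maximises the mixture log-likelihood in which a
#' nonzero count contributes
#' \eqn{\mathrm{Poisson}(Q; \alpha Y^\beta) \cdot \mathrm{expit}(\kappa + \tau \log Y)}
#' and a zero count contributes
#' \eqn{\mathrm{Poisson}(0; \alpha Y^\beta) \cdot \mathrm{expit}(\cdot) +
#' (1 - \mathrm{expit}(\cdot))}, decomposing zeros into Poisson sampling zeros
#' and dropouts. Optimised by multi-start Nelder-Mead (starts on a 3x3 grid,
#' kappa in \{-2, 0, 2\} by tau in \{0, 0.5, 1.5\}) within the box
#' kappa in \[-20, 20\], tau in \[-10, 10\]; the best optimum is kept.
#'
#' @inheritParams fit_alpha_beta
#' @param alpha,beta Amplification parameters from [fit_alpha_beta()].
#'
#' @return A list with `kappa`, `tau`, `loglik`, `boundary` (TRUE when no
#'   zeros were available and the returned kappa is the upper box bound + 10,
#'   i.e. dropout indistinguishable from absent), and `starts` (per-start
#'   optima).
#' @export
fit_kappa_tau <- function(true_molecules, observed, alpha, beta) {
  stopifnot(length(true_molecules) == length(observed), alpha > 0, beta > 0)
  if (!any(observed == 0)) {
    warning("No zero observations: dropout probability is indistinguishable ",
            "from zero; returning a no-dropout boundary solution.")
    return(list(kappa = 30, tau = 0, loglik = NA_real_, boundary = TRUE,
                starts = NULL))
  }
  y <- true_molecules
  q <- observed
  mu <- alpha * y^beta
  logy <- log(y)
  is_zero <- q == 0
  # Poisson log-density with the continuous extension via lgamma.
  lp_q <- q * log(mu) - mu - lgamma(q + 1)
  negll <- function(par) {
    k <- par[1]; t <- par[2]
    if (k < -20 || k > 20 || t < -10 || t > 10) return(1e12)
    lpi <- stats::plogis(k + t * logy, log.p = TRUE)
    l1mpi <- stats::plogis(k + t * logy, log.p = TRUE, lower.tail = FALSE)
    ll_nz <- lp_q[!is_zero] + lpi[!is_zero]
    # zero counts: log( pi * exp(-mu) + (1 - pi) )
    a1 <- lpi[is_zero] - mu[is_zero]
    a2 <- l1mpi[is_zero]
    mx <- pmax(a1, a2)
    ll_z <- mx + log(exp(a1 - mx) + exp(a2 - mx))
    -(sum(ll_nz) + sum(ll_z))
  }
  starts <- expand.grid(kappa = c(-2, 0, 2), tau = c(0, 0.5, 1.5))
  opts <- purrr::pmap(starts, function(kappa, tau) {
    stats::optim(c(kappa, tau), negll, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 2000))
  })
  vals <- vapply(opts, `[[`, numeric(1), "value")
  best <- opts[[which.min(vals)]]
  list(kappa = best$par[1], tau = best$par[2], loglik = -best$value,
       boundary = FALSE,
       starts = tibble::tibble(kappa0 = starts$kappa, tau0 = starts$tau,
                               loglik = -vals))
}

#' Estimate the full technical-noise model from a spike-in table
#'
#' Convenience wrapper: runs [fit_alpha_beta()] then [fit_kappa_tau()] on a
#' long spike-in tibble and returns a [noise_params()] object.
#'
#' @param spikes Tibble with columns `true_molecules` and `observed` (one row
#'   per spike-in per cell), e.g. from [simulate_spike_ins()] or assembled via
#'   [spike_in_true_molecules()] and [spike_in_observed_molecules()].
#'
#' @return A `noise_params` object with attribute `"fits"` holding the two
#'   stage fits.
#' @examples
#' sp <- simulate_spike_ins(noise_default(), 1000 / 2^(0:7), 50, seed = 1)
#' fit_noise_params(sp)
#' @export
fit_noise_params <- function(spikes) {
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("true_molecules", "observed") %in% names(spikes)))
  ab <- fit_alpha_beta(spikes$true_molecules, spikes$observed)
  kt <- fit_kappa_tau(spikes$true_molecules, spikes$observed,
                      alpha = ab$alpha, beta = ab$beta)
  out <- noise_params(ab$alpha, ab$beta, kt$kappa, kt$tau)
  attr(out, "fits") <- list(alpha_beta = ab, kappa_tau = kt)
  out
}

#' Tidy a noise-parameter object
#'
#' @param x A `noise_params` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (and `std.error` where the
#'   object carries stage fits).
#' @method tidy noise_params
#' @export
tidy.noise_params <- function(x, ...) {
  out <- tibble::tibble(
    term = c("alpha", "beta", "kappa", "tau"),
    estimate = c(x$alpha, x$beta, x$kappa, x$tau)
  )
  fits <- attr(x, "fits")
  if (!is.null(fits)) {
    out$std.error <- c(x$alpha * fits$alpha_beta$se_log_alpha,
                       fits$alpha_beta$se_beta, NA_real_, NA_real_)
  }
  out
}
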