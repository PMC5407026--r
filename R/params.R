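#' Two-state promoter kinetic parameters
#'
#' Container for the kinetic parameters of the two-state (telegraph) model of
#' transcription: a promoter switches ON at rate `k_on` and OFF at rate
#' `k_off`; while ON, mRNA is synthesised at rate `s`. All rates are
#' normalised by the mRNA decay rate, which is fixed at 1 and never estimated,
#' so `k_on` is the burst frequency (bursts per mRNA lifetime) and
#' `s / k_off` is the burst size (mean transcripts per burst).
#'
#' @param k_on Activation rate (> 0); equals the burst frequency.
#' @param k_off Deactivation rate (> 0).
#' @param s Transcription rate while ON (> 0).
#'
#' @return An object of class `kinetic_params`: a named list with elements
#'   `k_on`, `k_off`, `s`, plus derived `burst_frequency` and `burst_size`.
#' @examples
#' kp <- kinetic_params(k_on = 0.2, k_off = 0.2, s = 50)
#' kp$burst_size # 250
#' @export
kinetic_params <- function(k_on, k_off, s) {
  for (nm in c("k_on", "k_off", "s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single strictly positive finite number.",
           call. = FALSE)
    }
  }
  structure(
    list(k_on = k_on, k_off = k_off, s = s,
         burst_frequency = k_on, burst_size = s / k_off),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> k_on = %.4g, k_off = %.4g, s = %.4g (burst size %.4g)\n",
    x$k_on, x$k_off, x$s, x$burst_size))
  invisible(x)
}

#' Technical-noise parameters of the scRNA-seq observation model
#'
#' Observed counts `Q` arise from true expression `Y` through a dropout and
#' amplification model shared by all cells of a sequencing batch:
#' \deqn{Q \sim Z \cdot \mathrm{Poisson}(\alpha Y^{\beta}), \quad
#'       Z \sim \mathrm{Bernoulli}(\mathrm{expit}(\kappa + \tau \log Y)).}
#' `alpha` captures capture/sequencing efficiency, `beta` amplification bias,
#' and `(kappa, tau)` the logistic dependence of the non-dropout probability
#' on log true expression. `kappa = Inf` encodes "no dropout".
#'
#' @param alpha Efficiency scale (> 0).
#' @param beta Amplification exponent (> 0).
#' @param kappa Dropout logistic intercept (may be `Inf` for no dropout).
#' @param tau Dropout logistic slope on `log(Y)`.
#'
#' @return An object of class `noise_params`.
#' @seealso [noise_identity()], [fit_noise_params()]
#' @examples
#' noise_params(alpha = 2, beta = 0.9, kappa = -1, tau = 0.8)
#' @export
noise_params <- function(alpha, beta, kappa, tau) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single strictly positive number.", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single strictly positive number.", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa))
    stop("`kappa` must be a single number (Inf allowed).", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau))
    stop("`tau` must be a single finite number.", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, kappa = kappa, tau = tau),
            class = "noise_params")
}

#' Identity (noise-free) observation model
#'
#' Convenience constructor for `alpha = 1`, `beta = 1` and no dropout
#' (`kappa = Inf`), under which observed counts equal true expression in
#' distribution and histogram repiling is the identity map.
#'
#' @return A `noise_params` object.
#' @export
noise_identity <- function() noise_params(1, 1, Inf, 0)

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(
    "<noise_params> alpha = %.4g, beta = %.4g, kappa = %.4g, tau = %.4g\n",
    x$alpha, x$beta, x$kappa, x$tau))
  invisible(x)
}

#' Default "mouse-like" technical noise used by the simulator
#'
#' A moderate Smart-seq-scale noise setting: two-fold over-representation per
#' molecule, mild amplification compression, and a dropout probability of 50%
#' near a true expression of ~3.5 molecules, falling below 10% above ~40
#' molecules.
#'
#' @return A `noise_params` object with `alpha = 2`, `beta = 0.9`,
#'   `kappa = -1`, `tau = 0.8`.
#' @export
noise_default <- function() noise_params(alpha = 2, beta = 0.9, kappa = -1, tau = 0.8)

# Non-dropout probability pi(Y) = expit(kappa + tau log Y), vectorised over y > 0.
nondropout_prob <- function(y, noise) {
  stats::plogis(noise$kappa + noise$tau * log(y))
}
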