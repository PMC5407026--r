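#' Bootstrap test for differential allelic bursting kinetics
#'
#' Tests the null hypothesis that the two alleles share the same burst
#' frequency (`k_on`) and the same burst size (`s / k_off`). Observed
#' allele-specific estimates come from the repiling-moment estimator; each
#' bootstrap replicate pools the `2n` observed counts, draws `2n` with
#' replacement, assigns the first `n` to allele A and the next `n` to allele B
#' — resampled values take the size factor of the fixed cell slot they land
#' in — and re-estimates both alleles. The p-value is the fraction of valid
#' replicates (both alleles estimable) whose absolute allelic difference is at
#' least the observed one, computed separately for burst frequency and burst
#' size from the same replicate stream, and never reported below
#' `1 / n_valid`.
#'
#' @param q_a,q_b Observed counts per cell for alleles A and B.
#' @param noise A [noise_params()] object.
#' @param eta Per-cell library-size factors (default 1).
#' @param phi Per-cell size factors (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#'
#' @return A list of class `bursting_test`: `observed_diff_freq`,
#'   `observed_diff_size`, `p_freq`, `p_size`, `n_boot`, `n_valid_boot`,
#'   `low_confidence` (TRUE when fewer than 100 valid replicates), `testable`
#'   (FALSE when either observed allele is non-estimable; p-values are `NA`).
#' @export
bootstrap_differential_test <- function(q_a, q_b, noise, eta = 1,
                                        phi = rep(1, length(q_a)),
                                        n_boot = 1000, seed = NULL) {
  n <- length(q_a)
  stopifnot(length(q_b) == n)
  if (!is.null(seed)) set.seed(seed)
  eta <- rep_len(eta, n)
  ea <- estimate_kinetics(q_a, noise, eta, phi)
  eb <- estimate_kinetics(q_b, noise, eta, phi)
  out <- list(observed_diff_freq = NA_real_, observed_diff_size = NA_real_,
              p_freq = NA_real_, p_size = NA_real_, n_boot = n_boot,
              n_valid_boot = 0L, low_confidence = TRUE,
              testable = ea$estimable && eb$estimable)
  class(out) <- "bursting_test"
  if (!out$testable) return(out)
  out$observed_diff_freq <- ea$burst_frequency - eb$burst_frequency
  out$observed_diff_size <- ea$burst_size - eb$burst_size
  pool <- c(q_a, q_b)
  dfreq <- dsize <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(2L * n, 2L * n, replace = TRUE)
    ra <- estimate_kinetics(pool[idx[seq_len(n)]], noise, eta, phi)
    rb <- estimate_kinetics(pool[idx[n + seq_len(n)]], noise, eta, phi)
    if (ra$estimable && rb$estimable) {
      dfreq[b] <- ra$burst_frequency - rb$burst_frequency
      dsize[b] <- ra$burst_size - rb$burst_size
    }
  }
  valid <- !is.na(dfreq)
  nv <- sum(valid)
  out$n_valid_boot <- nv
  out$low_confidence <- nv < 100L
  if (nv > 0L) {
    out$p_freq <- max(mean(abs(dfreq[valid]) >= abs(out$observed_diff_freq)),
                      1 / nv)
    out$p_size <- max(mean(abs(dsize[valid]) >= abs(out$observed_diff_size)),
                      1 / nv)
  }
  out
}

#' @export
print.bursting_test <- function(x, ...) {
  if (!x$testable) {
    cat("<bursting_test> not testable (non-estimable observed kinetics)\n")
  } else {
    cat(sprintf(
      "<bursting_test> diff freq %.4g (p = %.4g), diff size %.4g (p = %.4g), %d/%d valid replicates\n",
      x$observed_diff_freq, x$p_freq, x$observed_diff_size, x$p_size,
      x$n_valid_boot, x$n_boot))
  }
  invisible(x)
}

#' Exact binomial test of allelic imbalance
#'
#' Tests whether the mean allelic ratio across cells is 0.5 by an exact
#' two-sided binomial test of the total allele-A count among the total allelic
#' count, mirroring bulk-tissue allelic-imbalance testing.
#'
#' @param q_a,q_b Observed counts per cell for alleles A and B.
#' @return The two-sided p-value, or `NA` when both totals are zero (the test
#'   is undefined and the gene is skipped).
#' @examples
#' binomial_imbalance_test(rep(6, 10), rep(4, 10)) # ~0.0569
#' @export
binomial_imbalance_test <- function(q_a, q_b) {
  ta <- sum(q_a)
  tb <- sum(q_b)
  if (ta + tb == 0) return(NA_real_)
  stats::binom.test(ta, ta + tb, p = 0.5)$p.value
}

#' Chi-square test of independent allelic bursting
#'
#' Given the per-gene cell-state counts from the classification step, tests
#' whether the two alleles' ON states are independent across cells. The 2x2
#' table (A expressed x B expressed) is compared against expected counts from
#' the marginal expression proportions
#' \eqn{p_A = (N_A + N_{AB})/N_{tot}}, \eqn{p_B = (N_B + N_{AB})/N_{tot}} by a
#' Pearson chi-square statistic on 1 degree of freedom, without continuity
#' correction. The direction is `coordinated` when more cells express both
#' alleles than expected, `repulsed` when fewer; it is annotated whenever the
#' statistic is positive but should be interpreted only where the test is
#' FDR-significant.
#'
#' @param n_empty,n_a,n_b,n_ab Cell-state counts.
#' @param min_cells Minimum total assigned cells (default 20); below this the
#'   test is skipped.
#'
#' @return A list of class `independence_test`: `chi2`, `p`, `direction`
#'   (`coordinated`, `repulsed` or `none`), `observed` and `expected` count
#'   vectors, `skipped` (with `reason`) when degenerate.
#' @examples
#' independence_test(40, 10, 10, 40) # chi2 = 36, coordinated
#' @export
independence_test <- function(n_empty, n_a, n_b, n_ab, min_cells = 20) {
  obs <- c(n_empty = n_empty, n_a = n_a, n_b = n_b, n_ab = n_ab)
  n_tot <- sum(obs)
  skip <- function(reason) {
    structure(list(chi2 = NA_real_, p = NA_real_, direction = "none",
                   observed = obs, expected = rep(NA_real_, 4),
                   skipped = TRUE, reason = reason),
              class = "independence_test")
  }
  if (n_tot < min_cells) return(skip("fewer assigned cells than `min_cells`"))
  p_a <- (n_a + n_ab) / n_tot
  p_b <- (n_b + n_ab) / n_tot
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1))
    return(skip("degenerate marginal: an allele is never or always expressed"))
  expected <- n_tot * c((1 - p_a) * (1 - p_b), p_a * (1 - p_b),
                        (1 - p_a) * p_b, p_a * p_b)
  names(expected) <- names(obs)
  chi2 <- sum((obs - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- if (n_ab > expected[["n_ab"]]) "coordinated"
  else if (n_ab < expected[["n_ab"]]) "repulsed"
  else "none"
  structure(list(chi2 = chi2, p = p, direction = direction,
                 observed = obs, expected = expected,
                 skipped = FALSE, reason = NA_character_),
            class = "independence_test")
}

#' @export
print.independence_test <- function(x, ...) {
  if (x$skipped) {
    cat("<independence_test> skipped:", x$reason, "\n")
  } else {
    cat(sprintf("<independence_test> chi2 = %.4g, p = %.4g, %s\n",
                x$chi2, x$p, x$direction))
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' @param p Vector of p-values (`NA` allowed and preserved).
#' @param alpha FDR level for the flags (default 0.05).
#' @return A tibble with columns `p`, `q` (BH-adjusted), `significant`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04)) # all flagged at alpha = 0.05
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = !is.na(q) & q <= alpha)
}
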