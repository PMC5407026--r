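#' Simulate per-cell size factors
#'
#' Cell sizes are drawn on the log scale, `phi = exp(g)` with
#' `g ~ Normal(0, sigma^2)`, so that sizes are strictly positive and centred
#' at 1. `sigma = 0` returns a vector of ones.
#'
#' @param n_cells Number of cells.
#' @param sigma Standard deviation of `log(phi)` (default 0.1, the scale used
#'   throughout the bundled power studies).
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of length `n_cells`, strictly positive.
#' @examples
#' simulate_cell_sizes(5, sigma = 0.1, seed = 1)
#' @export
simulate_cell_sizes <- function(n_cells, sigma = 0.1, seed = NULL) {
  stopifnot(n_cells >= 1, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(rep(1, n_cells))
  exp(stats::rnorm(n_cells, mean = 0, sd = sigma))
}

#' Simulate true allele-specific expression under the Poisson-Beta model
#'
#' Draws, for each cell, the active fraction `p ~ Beta(k_on, k_off)` of each
#' allele and the true transcript count `Y ~ Poisson(phi_c * s * p)`. The two
#' alleles have their own kinetic parameters but share the cell-size factor
#' `phi_c`. By default the alleles' activity draws are independent; a nonzero
#' `coupling` links the two Beta draws through a Gaussian copula with that
#' correlation (positive values produce coordinated bursting, negative values
#' repulsed bursting), giving a tunable alternative for the independence test.
#'
#' @param kinetics_a,kinetics_b [kinetic_params()] for alleles A and B.
#' @param phi Cell-size factors (length `n_cells`, strictly positive).
#' @param n_cells Number of cells; defaults to `length(phi)`.
#' @param coupling Gaussian-copula correlation between the alleles' active
#'   fractions, in \[-1, 1\]. Default 0 (independent bursting).
#' @param seed Optional integer seed.
#'
#' @return A list with numeric vectors `p_a`, `p_b` (active fractions) and
#'   integer vectors `y_a`, `y_b` (true transcript counts).
#' @examples
#' kp <- kinetic_params(0.2, 0.2, 50)
#' sim <- simulate_true_expression(kp, kp, phi = rep(1, 100), seed = 1)
#' mean(sim$y_a) # close to s * k_on / (k_on + k_off) = 25
#' @export
simulate_true_expression <- function(kinetics_a, kinetics_b, phi,
                                     n_cells = length(phi), coupling = 0,
                                     seed = NULL) {
  stopifnot(inherits(kinetics_a, "kinetic_params"),
            inherits(kinetics_b, "kinetic_params"))
  if (length(phi) != n_cells)
    stop("`phi` must have length `n_cells`.", call. = FALSE)
  if (any(phi <= 0)) stop("`phi` must be strictly positive.", call. = FALSE)
  if (abs(coupling) > 1) stop("`coupling` must lie in [-1, 1].", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (coupling == 0) {
    p_a <- stats::rbeta(n_cells, kinetics_a$k_on, kinetics_a$k_off)
    p_b <- stats::rbeta(n_cells, kinetics_b$k_on, kinetics_b$k_off)
  } else {
    # Gaussian copula: correlated normals -> uniforms -> Beta quantiles.
    z1 <- stats::rnorm(n_cells)
    z2 <- coupling * z1 + sqrt(1 - coupling^2) * stats::rnorm(n_cells)
    p_a <- stats::qbeta(stats::pnorm(z1), kinetics_a$k_on, kinetics_a$k_off)
    p_b <- stats::qbeta(stats::pnorm(z2), kinetics_b$k_on, kinetics_b$k_off)
  }
  list(p_a = p_a,
       p_b = p_b,
       y_a = stats::rpois(n_cells, phi * kinetics_a$s * p_a),
       y_b = stats::rpois(n_cells, phi * kinetics_b$s * p_b))
}

#' Pass true expression through the technical-noise observation model
#'
#' For each entry with `Y > 0`, a detection indicator
#' `Z ~ Bernoulli(expit(kappa + tau log Y))` is drawn and the observed count is
#' `Q = Z * Poisson(alpha * Y^beta)`. Entries with `Y = 0` yield `Q = 0`
#' deterministically (the dropout logistic is defined on `log Y` for expressed
#' transcripts only).
#'
#' @param y Non-negative true expression values (vector or matrix).
#' @param noise A [noise_params()] object.
#' @param seed Optional integer seed.
#'
#' @return A list with `q` (observed counts, same shape as `y`) and `z`
#'   (detection indicators; 1 wherever `y = 0` was observed as a structural
#'   zero is stored as 0).
#' @examples
#' y <- rpois(20, 10)
#' apply_technical_noise(y, noise_default(), seed = 1)$q
#' @export
apply_technical_noise <- function(y, noise, seed = NULL) {
  stopifnot(inherits(noise, "noise_params"))
  if (any(y < 0)) stop("`y` must be non-negative.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  q <- y
  q[] <- 0
  z <- q
  pos <- which(y > 0)
  if (length(pos)) {
    pi_pos <- nondropout_prob(y[pos], noise)
    z_pos <- stats::rbinom(length(pos), 1L, pi_pos)
    q_pos <- z_pos * stats::rpois(length(pos), noise$alpha * y[pos]^noise$beta)
    q[pos] <- q_pos
    z[pos] <- z_pos
  }
  list(q = q, z = z)
}

#' Simulate a spike-in experiment
#'
#' Generates observed counts for exogenous control molecules present at known
#' fixed amounts in every cell, by passing the stated true molecule levels
#' through [apply_technical_noise()]. Spike-ins do not burst, so these pairs
#' of (true, observed) values identify the technical-noise parameters.
#'
#' @param noise A [noise_params()] object.
#' @param true_molecule_levels Strictly positive vector of true molecule
#'   counts, one per spike-in species. Levels should span at least two decades
#'   for the downstream regression to be well conditioned; a narrower span
#'   triggers a warning.
#' @param n_cells Number of cells.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `spike_id`, `cell`, `true_molecules`,
#'   `observed` (one row per spike-in per cell).
#' @examples
#' simulate_spike_ins(noise_identity(), c(10, 100, 1000), n_cells = 3, seed = 1)
#' @export
simulate_spike_ins <- function(noise, true_molecule_levels, n_cells,
                               seed = NULL) {
  stopifnot(inherits(noise, "noise_params"), n_cells >= 1)
  lv <- true_molecule_levels
  if (any(lv <= 0)) stop("Spike-in levels must be strictly positive.", call. = FALSE)
  if (length(unique(lv)) < 2)
    warning("Fewer than 2 distinct spike-in levels: noise parameters are not identifiable.")
  else if (diff(range(log10(lv))) < 2)
    warning("Spike-in levels span less than 2 decades; alpha/beta estimates may be unstable.")
  if (!is.null(seed)) set.seed(seed)
  y <- matrix(rep(lv, n_cells), nrow = length(lv))
  q <- apply_technical_noise(y, noise)$q
  tibble::tibble(
    spike_id = rep(sprintf("spike%02d", seq_along(lv)), n_cells),
    cell = rep(sprintf("cell%03d", seq_len(n_cells)), each = length(lv)),
    true_molecules = rep(lv, n_cells),
    observed = as.vector(q)
  )
}

#' Simulate a full allele-specific single-cell dataset
#'
#' Generates a complete dataset under the generative hierarchy: per-gene,
#' per-allele Poisson-Beta true expression scaled by log-normal cell sizes,
#' then dropout/amplification noise, plus a matched spike-in experiment. All
#' latent variables and the ground-truth kinetic parameters are returned so
#' every downstream estimator can be scored.
#'
#' @param truth A data frame with one row per gene and columns `gene`,
#'   `k_on_a`, `k_off_a`, `s_a`, `k_on_b`, `k_off_b`, `s_b`, and optionally
#'   `coupling` (allelic copula correlation, default 0). Alternatively `NULL`
#'   together with `n_genes` for a default bursty panel
#'   (`k_on = k_off = 0.2`, `s = 100` for both alleles).
#' @param n_genes Number of genes when `truth` is `NULL`.
#' @param n_cells Number of cells (default 100).
#' @param noise A [noise_params()] object (default [noise_default()]); use
#'   [noise_identity()] for noise-free data.
#' @param sigma_size SD of `log(phi)` (default 0.1).
#' @param spike_levels True molecule levels for the simulated spike-ins
#'   (default eight two-fold serial dilutions from 1000 down to ~7.8).
#' @param seed Integer root seed; all draws flow from it. Gene-level streams
#'   are split deterministically from the root via `sample.int`, so the same
#'   seed reproduces every matrix bit-identically.
#'
#' @return A list of class `allelic_sim` with elements
#'   `counts` (tibble: `gene`, `cell`, `count_a`, `count_b`),
#'   `truth` (the input truth table), `phi`, `spike_ins` (tibble from
#'   [simulate_spike_ins()]), and `latent` (list of matrices `y_a`, `y_b`,
#'   `z_a`, `z_b`, `p_a`, `p_b`; genes in rows, cells in columns).
#' @examples
#' sim <- simulate_allelic_dataset(n_genes = 3, n_cells = 20, seed = 1)
#' sim$counts
#' @export
simulate_allelic_dataset <- function(truth = NULL, n_genes = 10, n_cells = 100,
                                     noise = noise_default(), sigma_size = 0.1,
                                     spike_levels = 1000 / 2^(0:7),
                                     seed = NULL) {
  if (is.null(truth)) {
    truth <- tibble::tibble(
      gene = sprintf("gene%03d", seq_len(n_genes)),
      k_on_a = 0.2, k_off_a = 0.2, s_a = 100,
      k_on_b = 0.2, k_off_b = 0.2, s_b = 100
    )
  }
  truth <- tibble::as_tibble(truth)
  if (!"coupling" %in% names(truth)) truth$coupling <- 0
  n_genes <- nrow(truth)
  if (!is.null(seed)) set.seed(seed)
  # Split one stream per stage/gene so per-gene draws are order-independent.
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)

  phi <- simulate_cell_sizes(n_cells, sigma = sigma_size)
  spikes <- simulate_spike_ins(noise, spike_levels, n_cells)

  cells <- sprintf("cell%03d", seq_len(n_cells))
  mk <- function() matrix(0, n_genes, n_cells,
                          dimnames = list(truth$gene, cells))
  lat <- list(y_a = mk(), y_b = mk(), z_a = mk(), z_b = mk(),
              p_a = mk(), p_b = mk())
  q_a <- mk(); q_b <- mk()

  for (g in seq_len(n_genes)) {
    set.seed(gene_seeds[g])
    tr <- truth[g, ]
    te <- simulate_true_expression(
      kinetic_params(tr$k_on_a, tr$k_off_a, tr$s_a),
      kinetic_params(tr$k_on_b, tr$k_off_b, tr$s_b),
      phi = phi, coupling = tr$coupling
    )
    na <- apply_technical_noise(te$y_a, noise)
    nb <- apply_technical_noise(te$y_b, noise)
    lat$p_a[g, ] <- te$p_a; lat$p_b[g, ] <- te$p_b
    lat$y_a[g, ] <- te$y_a; lat$y_b[g, ] <- te$y_b
    lat$z_a[g, ] <- na$z;   lat$z_b[g, ] <- nb$z
    q_a[g, ] <- na$q;       q_b[g, ] <- nb$q
  }

  counts <- tibble::tibble(
    gene = rep(truth$gene, times = n_cells),
    cell = rep(cells, each = n_genes),
    count_a = as.vector(q_a),
    count_b = as.vector(q_b)
  )
  structure(
    list(counts = counts, truth = truth, phi = phi, spike_ins = spikes,
         latent = lat, noise = noise, seed = seed),
    class = "allelic_sim"
  )
}

#' @export
print.allelic_sim <- function(x, ...) {
  cat(sprintf("<allelic_sim> %d genes x %d cells (seed %s)\n",
              nrow(x$truth), length(x$phi),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
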