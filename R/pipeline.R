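#' Allele-specific bursting analysis of a single-cell count table
#'
#' End-to-end analysis: library-size normalisation, technical-noise estimation
#' from spike-ins (when available), empirical-Bayes gene classification,
#' kinetic estimation for biallelic bursty genes through histogram repiling
#' and moment inversion, and hypothesis tests for differential allelic burst
#' frequency and burst size (bootstrap), allelic imbalance (binomial) and
#' non-independent bursting (chi-square), each family corrected by
#' Benjamini-Hochberg FDR across genes.
#'
#' Without spike-ins and without a user-supplied `noise`, the identity
#' observation model is assumed with a prominent warning, so estimates are
#' uncorrected for dropout and amplification. A failing gene is marked
#' non-estimable and the run continues.
#'
#' @param counts Tibble with columns `gene`, `cell`, `count_a`, `count_b`
#'   (allele-specific read counts at one heterozygous locus per gene).
#' @param spike_ins Optional tibble with columns `cell`, `true_molecules`,
#'   `observed` (one row per spike-in per cell), e.g. from
#'   [simulate_spike_ins()] or [spike_in_observed_molecules()].
#' @param cell_sizes Optional per-cell size factors (tibble `cell`, `phi` or a
#'   numeric vector); median-normalised. When absent they are computed from
#'   the endogenous-to-spike-in read ratio, or set to 1 without spike-ins.
#' @param noise Optional [noise_params()]; overrides spike-in fitting.
#' @param epsilon Per-base sequencing error rate for classification
#'   (default 0.001).
#' @param min_posterior Posterior threshold for cell assignment (default 0.8).
#' @param bursty_low,bursty_high Expressed-proportion band for the bursty
#'   category (defaults 0.05, 0.95).
#' @param n_boot Bootstrap replicates for the differential tests and the
#'   kinetic standard errors (default 1000).
#' @param fdr FDR level for significance flags (default 0.05).
#' @param seed Optional integer seed; fixing it makes the whole run
#'   reproducible.
#' @param verbose Log per-stage progress and estimates (default TRUE).
#'
#' @return An object of class `allelic_bursting` with elements `results` (the
#'   per-gene tibble, see [tidy.allelic_bursting()]), `classification`,
#'   `kinetics` (per-allele tibble for bursty genes), `noise`, `eta`, `phi`,
#'   and `params`.
#' @examples
#' sim <- simulate_allelic_dataset(n_genes = 2, n_cells = 60, seed = 1)
#' fit <- allelic_bursting(sim$counts, spike_ins = sim$spike_ins,
#'                         n_boot = 50, seed = 1, verbose = FALSE)
#' tidy(fit)
#' @export
allelic_bursting <- function(counts, spike_ins = NULL, cell_sizes = NULL,
                             noise = NULL, epsilon = 0.001,
                             min_posterior = 0.8,
                             bursty_low = 0.05, bursty_high = 0.95,
                             n_boot = 1000, fdr = 0.05, seed = NULL,
                             verbose = TRUE) {
  counts <- validate_counts(counts)
  if (!is.null(seed)) set.seed(seed)
  say <- function(...) if (verbose) message("[alleleburst] ", sprintf(...))

  genes <- unique(counts$gene)
  cells <- unique(counts$cell)
  q_a <- matrix_from_long(counts$gene, counts$cell, counts$count_a)
  q_b <- matrix_from_long(counts$gene, counts$cell, counts$count_b)

  # -- library size -----------------------------------------------------------
  eta_tbl <- tryCatch(library_size_factors(counts), error = function(e) {
    warning("Library-size factors undefined (", conditionMessage(e),
            "); using eta = 1.", call. = FALSE)
    tibble::tibble(cell = cells, eta = 1)
  })
  eta <- eta_tbl$eta[match(cells, eta_tbl$cell)]

  # -- technical noise --------------------------------------------------------
  if (is.null(noise)) {
    if (!is.null(spike_ins)) {
      noise <- fit_noise_params(spike_ins)
      say("noise fitted from spike-ins: alpha %.3f, beta %.3f, kappa %.3f, tau %.3f",
          noise$alpha, noise$beta, noise$kappa, noise$tau)
    } else {
      warning("No spike-ins and no `noise` supplied: assuming the identity ",
              "observation model (no dropout, no amplification bias). ",
              "Kinetic estimates are uncorrected for technical noise.",
              call. = FALSE)
      noise <- noise_identity()
    }
  }

  # -- cell sizes -------------------------------------------------------------
  if (!is.null(cell_sizes)) {
    phi_tbl <- normalize_cell_sizes(cell_sizes)
  } else if (!is.null(spike_ins) && "cell" %in% names(spike_ins)) {
    phi_tbl <- cell_size_factors(counts, spike_ins)
  } else {
    phi_tbl <- tibble::tibble(cell = cells, phi = 1)
  }
  phi <- phi_tbl$phi[match(cells, phi_tbl$cell)]
  if (anyNA(phi)) stop("Cell-size factors missing for some cells.", call. = FALSE)

  # -- classification ---------------------------------------------------------
  cls <- classify_genes(counts, epsilon = epsilon,
                        min_posterior = min_posterior,
                        bursty_low = bursty_low, bursty_high = bursty_high)
  say("categories: %s",
      paste(names(table(cls$category)), table(cls$category),
            sep = "=", collapse = ", "))

  # -- kinetics and tests for bursty genes ------------------------------------
  bursty <- cls$gene[cls$category == "biallelic_bursty"]
  kin_rows <- list()
  test_rows <- list()
  for (g in bursty) {
    qa <- q_a[g, ]
    qb <- q_b[g, ]
    row <- tryCatch({
      kin <- estimate_allele_kinetics(qa, qb, noise, eta = eta, phi = phi,
                                      n_boot = min(n_boot, 200L))
      bt <- bootstrap_differential_test(qa, qb, noise, eta = eta, phi = phi,
                                        n_boot = n_boot)
      crow <- cls[cls$gene == g, ]
      it <- independence_test(crow$n_empty, crow$n_a, crow$n_b, crow$n_ab)
      list(kin = dplyr::mutate(kin, gene = g, .before = 1),
           test = tibble::tibble(
             gene = g,
             diff_burst_frequency = bt$observed_diff_freq,
             diff_burst_size = bt$observed_diff_size,
             p_freq = bt$p_freq, p_size = bt$p_size,
             low_confidence = bt$low_confidence,
             p_imbalance = binomial_imbalance_test(qa, qb),
             chi2 = it$chi2, p_independence = it$p,
             direction_raw = it$direction))
    }, error = function(e) {
      warning("Gene ", g, " failed (", conditionMessage(e),
              "); marked non-estimable.", call. = FALSE)
      NULL
    })
    if (!is.null(row)) {
      kin_rows[[g]] <- row$kin
      test_rows[[g]] <- row$test
    }
  }
  kinetics <- dplyr::bind_rows(kin_rows)
  tests <- dplyr::bind_rows(test_rows)

  # -- assemble per-gene results with per-family FDR --------------------------
  results <- dplyr::left_join(cls, tests, by = "gene")
  if (nrow(results)) {
    for (fam in c("p_freq", "p_size", "p_imbalance", "p_independence")) {
      adj <- fdr_adjust(results[[fam]], alpha = fdr)
      results[[sub("^p_", "q_", fam)]] <- adj$q
      results[[sub("^p_", "sig_", fam)]] <- adj$significant
    }
    results$direction <- ifelse(
      !is.na(results$direction_raw) & results$sig_independence,
      results$direction_raw, "none")
    results$direction[is.na(results$p_independence)] <- "none"
    results$direction_raw <- NULL
  }
  if (nrow(kinetics)) {
    wide <- tidyr::pivot_wider(
      kinetics[, c("gene", "allele", "k_on", "k_off", "s", "burst_frequency",
                   "burst_size", "estimable",
                   "se_burst_frequency", "se_burst_size")],
      names_from = "allele",
      values_from = -c("gene", "allele"),
      names_glue = "{.value}_{tolower(allele)}"
    )
    results <- dplyr::left_join(results, wide, by = "gene")
  }
  say("significant at FDR %.2g: freq %d, size %d, imbalance %d, independence %d",
      fdr, sum(results$sig_freq %||% FALSE, na.rm = TRUE),
      sum(results$sig_size %||% FALSE, na.rm = TRUE),
      sum(results$sig_imbalance %||% FALSE, na.rm = TRUE),
      sum(results$sig_independence %||% FALSE, na.rm = TRUE))

  structure(
    list(results = tibble::as_tibble(results), classification = cls,
         kinetics = kinetics, noise = noise,
         eta = eta_tbl, phi = phi_tbl,
         params = list(epsilon = epsilon, min_posterior = min_posterior,
                       bursty_low = bursty_low, bursty_high = bursty_high,
                       n_boot = n_boot, fdr = fdr, seed = seed)),
    class = "allelic_bursting"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.allelic_bursting <- function(x, ...) {
  tab <- table(x$classification$category)
  cat(sprintf("<allelic_bursting> %d genes x %d cells\n",
              nrow(x$classification), nrow(x$eta)))
  cat("  categories:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  noise: alpha %.3f, beta %.3f, kappa %.3f, tau %.3f\n",
              x$noise$alpha, x$noise$beta, x$noise$kappa, x$noise$tau))
  invisible(x)
}

#' Tidy the per-gene results of an allelic bursting fit
#'
#' @param x An [allelic_bursting()] object.
#' @param ... Unused.
#' @return The per-gene results tibble: category and state counts for every
#'   gene; kinetic estimates, standard errors and the four test families
#'   (p, BH-adjusted q, significance flag) for biallelic bursty genes;
#'   `direction` is `coordinated`/`repulsed` only where the independence test
#'   is FDR-significant.
#' @method tidy allelic_bursting
#' @export
tidy.allelic_bursting <- function(x, ...) x$results

#' One-row summary of an allelic bursting fit
#'
#' @param x An [allelic_bursting()] object.
#' @param ... Unused.
#' @return A one-row tibble: gene totals per category, significant-gene counts
#'   per test family, and the noise parameters.
#' @method glance allelic_bursting
#' @export
glance.allelic_bursting <- function(x, ...) {
  r <- x$results
  cnt <- function(cat) sum(x$classification$category == cat)
  tibble::tibble(
    n_genes = nrow(x$classification),
    n_cells = nrow(x$eta),
    n_silent = cnt("silent"),
    n_monoallelic = cnt("monoallelic_A") + cnt("monoallelic_B"),
    n_biallelic_bursty = cnt("biallelic_bursty"),
    n_biallelic_nonbursty = cnt("biallelic_nonbursty"),
    n_sig_freq = sum(r$sig_freq %||% FALSE, na.rm = TRUE),
    n_sig_size = sum(r$sig_size %||% FALSE, na.rm = TRUE),
    n_sig_imbalance = sum(r$sig_imbalance %||% FALSE, na.rm = TRUE),
    n_sig_independence = sum(r$sig_independence %||% FALSE, na.rm = TRUE),
    alpha = x$noise$alpha, beta = x$noise$beta,
    kappa = x$noise$kappa, tau = x$noise$tau
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
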