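#' Log relative likelihoods of the four per-cell allelic states
#'
#' For a cell with allele-specific read counts `(n_a, n_b)` at a heterozygous
#' locus, computes the log relative likelihood of the four states: both
#' alleles off, only A expressed, only B expressed, both expressed. With
#' per-base sequencing error `epsilon`,
#' \deqn{f_1 \propto \epsilon^{n_A + n_B}, \quad
#'       f_2 \propto (1-\epsilon)^{n_A} \epsilon^{n_B}, \quad
#'       f_3 \propto \epsilon^{n_A} (1-\epsilon)^{n_B},}
#' and \eqn{f_4} integrates over a latent allelic ratio
#' \eqn{\theta \sim \mathrm{Beta}(a, b)} of the biallelic state:
#' \deqn{f_4 \propto \int_0^1 [\theta(1-\epsilon) + (1-\theta)\epsilon]^{n_A}
#'       [\theta\epsilon + (1-\theta)(1-\epsilon)]^{n_B}
#'       \mathrm{Beta}(\theta; a, b)\, d\theta.}
#' All four share the same omitted combinatorial constant, so ratios between
#' them are exact. The integral has no closed form and is evaluated by
#' fixed-order Gauss-Legendre quadrature (order 64) in log space.
#'
#' @param n_a,n_b Non-negative read counts (vectors of equal length).
#' @param epsilon Per-base sequencing error rate in (0, 0.5). Default 0.001.
#' @param a,b Beta hyper-parameters of the biallelic allelic ratio; `a = b >= 3`
#'   keeps the both-expressed state distinguishable from the monoallelic ones.
#'
#' @return A `length(n_a)` x 4 matrix of log relative likelihoods with columns
#'   `empty`, `A`, `B`, `AB`.
#' @examples
#' state_loglik(100, 0, epsilon = 0.001, a = 3, b = 3)
#' @export
state_loglik <- function(n_a, n_b, epsilon = 0.001, a = 3, b = a) {
  stopifnot(length(n_a) == length(n_b), all(n_a >= 0), all(n_b >= 0),
            epsilon > 0, epsilon < 0.5, a > 0, b > 0)
  le <- log(epsilon); l1e <- log1p(-epsilon)
  gl <- gauss_legendre_01(64L)
  # log integrand at each node, for each cell (cells x nodes)
  la <- log(gl$x * (1 - epsilon) + (1 - gl$x) * epsilon)
  lb <- log(gl$x * epsilon + (1 - gl$x) * (1 - epsilon))
  lprior <- stats::dbeta(gl$x, a, b, log = TRUE) + log(gl$w)
  m <- outer(n_a, la) + outer(n_b, lb) +
    matrix(lprior, length(n_a), length(gl$x), byrow = TRUE)
  lf4 <- log_row_sum_exp(m)
  cbind(empty = (n_a + n_b) * le,
        A = n_a * l1e + n_b * le,
        B = n_a * le + n_b * l1e,
        AB = lf4)
}

#' Fit the four-state allelic mixture by EM
#'
#' Fits mixing weights over the four per-cell states \{empty, A, B, AB\} by
#' expectation-maximisation on the observed-data log-likelihood
#' \eqn{\sum_c \log \sum_k \varphi_k f_k(n^A_c, n^B_c)}. The Beta
#' hyper-parameter `a = b` of the biallelic state is chosen from a small grid
#' by maximised log-likelihood, which keeps each EM run monotone and the whole
#' fit reproducible.
#'
#' @param n_a,n_b Per-cell allele-specific read counts.
#' @param epsilon Sequencing error rate (default 0.001).
#' @param a_grid Candidate values of `a = b` (default `c(3, 4, 6, 10, 20)`).
#' @param tol Convergence tolerance on the log-likelihood change (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500); non-convergence is a
#'   warning and the last iterate is returned.
#'
#' @return An object of class `allelic_em`: list with `mixing` (length-4
#'   simplex), `posteriors` (cells x 4), `loglik`, `loglik_trace`, `a`,
#'   `epsilon`, `converged`, `n_cells`.
#' @examples
#' em <- fit_allelic_em(c(0, 90, 0, 45), c(0, 1, 88, 50))
#' em$mixing
#' @export
fit_allelic_em <- function(n_a, n_b, epsilon = 0.001,
                           a_grid = c(3, 4, 6, 10, 20),
                           tol = 1e-6, max_iter = 500L) {
  stopifnot(length(n_a) >= 1)
  fits <- lapply(a_grid, function(a)
    em_one_a(n_a, n_b, epsilon, a, tol, max_iter))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  best
}

em_one_a <- function(n_a, n_b, epsilon, a, tol, max_iter) {
  lf <- state_loglik(n_a, n_b, epsilon = epsilon, a = a)
  n <- length(n_a)
  log_phi <- rep(log(0.25), 4)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    lp <- sweep(lf, 2, log_phi, "+")
    ll_c <- log_row_sum_exp(lp)
    post <- exp(lp - ll_c)
    ll <- sum(ll_c)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    mix <- colMeans(post)
    log_phi <- log(mix)
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations; ",
            "returning the last iterate.")
  structure(
    list(mixing = exp(log_phi) / sum(exp(log_phi)),
         posteriors = post, loglik = trace[length(trace)],
         loglik_trace = trace, a = a, epsilon = epsilon,
         converged = converged, n_cells = n,
         n_a = n_a, n_b = n_b),
    class = "allelic_em"
  )
}

#' @export
print.allelic_em <- function(x, ...) {
  cat(sprintf(
    "<allelic_em> %d cells, a = b = %g, loglik = %.3f\n  mixing: empty %.3f | A %.3f | B %.3f | AB %.3f\n",
    x$n_cells, x$a, x$loglik,
    x$mixing[1], x$mixing[2], x$mixing[3], x$mixing[4]))
  invisible(x)
}

#' Assign a gene to an expression category
#'
#' Each cell is assigned to its maximum-posterior state (ties broken
#' deterministically toward empty, then A, then B, then AB) and kept only if
#' that posterior exceeds `min_posterior`. With \eqn{N_\varnothing, N_A, N_B,
#' N_{AB}} the kept-cell state counts, the gene is silent if
#' \eqn{N_A = N_B = N_{AB} = 0}; A-monoallelic if \eqn{N_A > 0} and
#' \eqn{N_B = N_{AB} = 0}; B-monoallelic symmetrically; otherwise biallelic,
#' and biallelic *bursty* when the proportion of kept cells expressing each
#' allele, \eqn{(N_X + N_{AB}) / N_{tot}}, lies within
#' `[bursty_low, bursty_high]` for both alleles.
#'
#' Cells with zero reads at the locus are assigned to the empty state
#' directly: the four state densities are identical at zero depth (each is
#' proportional to \eqn{\epsilon^0 = 1}), so the posterior rule is
#' uninformative there, while a zero-depth cell is exactly what the
#' both-alleles-off state predicts. In particular a gene with zero reads in
#' every cell is silent.
#'
#' @param em A fitted [fit_allelic_em()] object.
#' @param min_posterior Posterior-probability threshold for keeping a cell
#'   (default 0.8).
#' @param bursty_low,bursty_high Expressed-cell proportion band defining
#'   bursty expression (defaults 0.05 and 0.95).
#'
#' @return A list with `category` (one of `silent`, `monoallelic_A`,
#'   `monoallelic_B`, `biallelic_bursty`, `biallelic_nonbursty`,
#'   `unclassifiable`), `counts` (named vector `n_empty`, `n_a`, `n_b`,
#'   `n_ab`, `n_unassigned`), and `states` (per-cell state labels, `NA` for
#'   unassigned cells).
#' @export
assign_gene_category <- function(em, min_posterior = 0.8,
                                 bursty_low = 0.05, bursty_high = 0.95) {
  stopifnot(inherits(em, "allelic_em"))
  states <- c("empty", "A", "B", "AB")
  post <- em$posteriors
  k <- max.col(post, ties.method = "first") # column order encodes tie-break
  maxp <- post[cbind(seq_len(nrow(post)), k)]
  lab <- ifelse(maxp > min_posterior, states[k], NA_character_)
  lab[em$n_a + em$n_b == 0] <- "empty"
  n <- c(n_empty = sum(lab == "empty", na.rm = TRUE),
         n_a = sum(lab == "A", na.rm = TRUE),
         n_b = sum(lab == "B", na.rm = TRUE),
         n_ab = sum(lab == "AB", na.rm = TRUE),
         n_unassigned = sum(is.na(lab)))
  n_tot <- sum(n[1:4])
  category <- if (n_tot == 0) {
    "unclassifiable"
  } else if (n[["n_a"]] == 0 && n[["n_b"]] == 0 && n[["n_ab"]] == 0) {
    "silent"
  } else if (n[["n_a"]] > 0 && n[["n_b"]] == 0 && n[["n_ab"]] == 0) {
    "monoallelic_A"
  } else if (n[["n_b"]] > 0 && n[["n_a"]] == 0 && n[["n_ab"]] == 0) {
    "monoallelic_B"
  } else {
    pr_a <- (n[["n_a"]] + n[["n_ab"]]) / n_tot
    pr_b <- (n[["n_b"]] + n[["n_ab"]]) / n_tot
    if (pr_a >= bursty_low && pr_a <= bursty_high &&
        pr_b >= bursty_low && pr_b <= bursty_high)
      "biallelic_bursty" else "biallelic_nonbursty"
  }
  list(category = category, counts = n, states = lab)
}

#' Classify every gene in a count table
#'
#' Runs [fit_allelic_em()] and [assign_gene_category()] gene by gene.
#'
#' @inheritParams library_size_factors
#' @inheritParams fit_allelic_em
#' @inheritParams assign_gene_category
#'
#' @return A tibble with one row per gene: `gene`, `category`, `n_empty`,
#'   `n_a`, `n_b`, `n_ab`, `n_unassigned`, `a_hat` (selected Beta
#'   hyper-parameter), `loglik`.
#' @examples
#' sim <- simulate_allelic_dataset(n_genes = 2, n_cells = 40,
#'                                 noise = noise_identity(), seed = 1)
#' classify_genes(sim$counts)
#' @export
classify_genes <- function(counts, epsilon = 0.001,
                           a_grid = c(3, 4, 6, 10, 20),
                           min_posterior = 0.8,
                           bursty_low = 0.05, bursty_high = 0.95) {
  counts <- validate_counts(counts)
  by_gene <- split(counts, factor(counts$gene, levels = unique(counts$gene)))
  rows <- purrr::map(by_gene, function(d) {
    em <- fit_allelic_em(d$count_a, d$count_b, epsilon = epsilon,
                         a_grid = a_grid)
    asg <- assign_gene_category(em, min_posterior = min_posterior,
                                bursty_low = bursty_low,
                                bursty_high = bursty_high)
    tibble::tibble(
      gene = d$gene[1], category = asg$category,
      n_empty = asg$counts[["n_empty"]], n_a = asg$counts[["n_a"]],
      n_b = asg$counts[["n_b"]], n_ab = asg$counts[["n_ab"]],
      n_unassigned = asg$counts[["n_unassigned"]],
      a_hat = em$a, loglik = em$loglik
    )
  })
  dplyr::bind_rows(rows)
}

# ---- internal numerics ------------------------------------------------------

# Cached Gauss-Legendre nodes/weights on (0, 1).
gl_cache <- new.env(parent = emptyenv())
gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  gl_cache[[key]]
}

log_row_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx <- ifelse(is.finite(mx), mx, 0)
  mx + log(rowSums(exp(m - mx)))
}
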