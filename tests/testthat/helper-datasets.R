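# Shared fixtures, all generated in code.

# Per-cell allelic counts with known cell states, for classification tests.
# Expressed alleles get >= `min_depth` reads; reads are misassigned to the
# other allele with the per-base error rate `eps`; the biallelic state draws
# its allelic ratio from Beta(a0, a0).
sim_state_counts <- function(states, min_depth = 50, eps = 0.001, a0 = 6) {
  n <- length(states)
  n_a <- n_b <- integer(n)
  for (i in seq_len(n)) {
    d <- min_depth + stats::rpois(1, 30)
    if (states[i] == "A") {
      nb <- stats::rbinom(1, d, eps)
      n_a[i] <- d - nb; n_b[i] <- nb
    } else if (states[i] == "B") {
      na <- stats::rbinom(1, d, eps)
      n_b[i] <- d - na; n_a[i] <- na
    } else if (states[i] == "AB") {
      d <- 2 * d
      theta <- stats::rbeta(1, a0, a0)
      n_a[i] <- stats::rbinom(1, d, theta * (1 - eps) + (1 - theta) * eps)
      n_b[i] <- d - n_a[i]
    } # "empty": zero counts
  }
  list(n_a = n_a, n_b = n_b)
}

# A long counts tibble for one gene from per-cell allele count vectors.
counts_tbl <- function(n_a, n_b, gene = "g1") {
  tibble::tibble(gene = gene,
                 cell = sprintf("c%03d", seq_along(n_a)),
                 count_a = n_a, count_b = n_b)
}

# Truth table spanning all gene categories (silent alleles use a vanishing
# transcription rate; constitutive genes are effectively always ON).
mixed_truth <- function() {
  tibble::tibble(
    gene = c("silent01", "monoA01", "monoB01", "bursty01", "bursty02",
             "consti01"),
    k_on_a = c(0.2, 0.2, 0.2, 0.2, 0.3, 60),
    k_off_a = c(0.2, 0.2, 0.2, 0.2, 0.3, 0.05),
    s_a = c(1e-6, 100, 1e-6, 100, 120, 100),
    k_on_b = c(0.2, 0.2, 0.2, 0.2, 0.3, 60),
    k_off_b = c(0.2, 0.2, 0.2, 0.2, 0.3, 0.05),
    s_b = c(1e-6, 1e-6, 100, 100, 120, 100)
  )
}
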