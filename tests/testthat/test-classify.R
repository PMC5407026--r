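test_that("state log-likelihoods match their closed forms and symmetries", {
  eps <- 0.001
  # zero depth: all four states equally likely
  lf0 <- state_loglik(0, 0, epsilon = eps, a = 3)
  expect_equal(max(lf0) - min(lf0), 0, tolerance = 1e-10)
  # deep monoallelic counts: log f2 - log f1 = n_a * log((1-eps)/eps)
  lf <- state_loglik(100, 0, epsilon = eps, a = 3)
  expect_equal(unname(lf[1, "A"] - lf[1, "empty"]),
               100 * log((1 - eps) / eps),
               tolerance = 1e-10)
  expect_gt(lf[1, "A"], max(lf[1, c("empty", "B", "AB")]))
  # swapping (n_a, n_b) swaps the A and B states, fixes empty and AB (a = b)
  l1 <- state_loglik(17, 5, epsilon = eps, a = 4)
  l2 <- state_loglik(5, 17, epsilon = eps, a = 4)
  expect_equal(unname(l1[1, "A"]), unname(l2[1, "B"]), tolerance = 1e-10)
  expect_equal(unname(l1[1, "B"]), unname(l2[1, "A"]), tolerance = 1e-10)
  expect_equal(unname(l1[1, "empty"]), unname(l2[1, "empty"]), tolerance = 1e-10)
  expect_equal(unname(l1[1, "AB"]), unname(l2[1, "AB"]), tolerance = 1e-10)
})

test_that("the biallelic-state integral matches adaptive quadrature", {
  eps <- 0.001
  for (a0 in c(3, 6, 20)) {
    for (cnt in list(c(0, 0), c(10, 12), c(80, 40), c(150, 5))) {
      f4_quad <- state_loglik(cnt[1], cnt[2], epsilon = eps, a = a0)[1, "AB"]
      scale <- max(cnt) # stabilise the adaptive integral
      integrand <- function(th) {
        exp(cnt[1] * log(th * (1 - eps) + (1 - th) * eps) +
            cnt[2] * log(th * eps + (1 - th) * (1 - eps)) +
            dbeta(th, a0, a0, log = TRUE) + scale)
      }
      f4_ref <- log(stats::integrate(integrand, 0, 1, rel.tol = 1e-10)$value) -
        scale
      expect_equal(unname(f4_quad), f4_ref, tolerance = 1e-6)
    }
  }
})

test_that("EM log-likelihood is non-decreasing and the fit is reproducible", {
  set.seed(31)
  d <- sim_state_counts(rep(c("empty", "A", "B", "AB"), times = c(10, 15, 12, 13)))
  em <- fit_allelic_em(d$n_a, d$n_b)
  expect_true(all(diff(em$loglik_trace) > -1e-8))
  expect_equal(sum(em$mixing), 1, tolerance = 1e-12)
  expect_equal(rowSums(em$posteriors), rep(1, length(d$n_a)), tolerance = 1e-12)
  em2 <- fit_allelic_em(d$n_a, d$n_b)
  expect_identical(em$mixing, em2$mixing)
})

test_that("cells with clean deep counts are assigned to their true state", {
  set.seed(32)
  states <- rep(c("empty", "A", "B", "AB"), each = 50)
  d <- sim_state_counts(states, min_depth = 50)
  em <- fit_allelic_em(d$n_a, d$n_b)
  asg <- assign_gene_category(em)
  acc <- mean(asg$states == states, na.rm = FALSE)
  expect_gte(acc, 0.99)
  expect_equal(asg$category, "biallelic_bursty")
  expect_equal(sum(asg$counts), length(states))
})

test_that("gene categories follow the posterior-count rules", {
  set.seed(33)
  # all-zero gene is silent
  em0 <- fit_allelic_em(rep(0, 40), rep(0, 40))
  expect_equal(assign_gene_category(em0)$category, "silent")
  # half empty / half A -> monoallelic_A
  dA <- sim_state_counts(rep(c("empty", "A"), each = 50))
  emA <- fit_allelic_em(dA$n_a, dA$n_b)
  asgA <- assign_gene_category(emA)
  expect_equal(asgA$category, "monoallelic_A")
  expect_equal(unname(asgA$counts[c("n_b", "n_ab")]), c(0L, 0L))
  # A in every cell (via AB): proportion 1 > 0.95 -> biallelic_nonbursty
  dN <- sim_state_counts(rep(c("A", "AB"), each = 50))
  emN <- fit_allelic_em(dN$n_a, dN$n_b)
  expect_equal(assign_gene_category(emN)$category, "biallelic_nonbursty")
  # all four states at 0.5/0.5 allele proportions -> biallelic_bursty
  dB <- sim_state_counts(rep(c("empty", "A", "B", "AB"),
                             times = c(20, 30, 30, 20)))
  emB <- fit_allelic_em(dB$n_a, dB$n_b)
  expect_equal(assign_gene_category(emB)$category, "biallelic_bursty")
})

test_that("swapping alleles swaps the monoallelic labels only", {
  set.seed(34)
  sim <- simulate_allelic_dataset(truth = mixed_truth(), n_cells = 60,
                                  noise = noise_identity(), sigma_size = 0,
                                  seed = 35)
  cls <- classify_genes(sim$counts)
  swapped <- dplyr::rename(sim$counts, count_a = "count_b",
                           count_b = "count_a")
  cls_sw <- classify_genes(swapped)
  swap_lab <- function(x) {
    dplyr::recode(x, monoallelic_A = "monoallelic_B",
                  monoallelic_B = "monoallelic_A")
  }
  expect_equal(cls_sw$category, swap_lab(cls$category))
  expect_equal(cls_sw$n_a, cls$n_b)
  expect_equal(cls_sw$n_b, cls$n_a)
})

test_that("classification recovers the true category of simulated genes", {
  sim <- simulate_allelic_dataset(truth = mixed_truth(), n_cells = 100,
                                  noise = noise_identity(), sigma_size = 0,
                                  seed = 36)
  cls <- classify_genes(sim$counts)
  expect_equal(cls$category[cls$gene == "silent01"], "silent")
  expect_equal(cls$category[cls$gene == "monoA01"], "monoallelic_A")
  expect_equal(cls$category[cls$gene == "monoB01"], "monoallelic_B")
  expect_equal(cls$category[cls$gene == "bursty01"], "biallelic_bursty")
  expect_equal(cls$category[cls$gene == "consti01"], "biallelic_nonbursty")
})
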