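test_that("library-size factors follow the median-of-ratios formula", {
  # identical cells -> eta = 1
  cts <- tibble::tibble(gene = rep(c("g1", "g2"), each = 3),
                        cell = rep(c("c1", "c2", "c3"), 2),
                        count_a = c(2, 2, 2, 5, 5, 5),
                        count_b = c(1, 1, 1, 4, 4, 4))
  expect_equal(library_size_factors(cts)$eta, rep(1, 3))

  # hand-evaluated 2x2 example: totals [[2,4],[8,16]]
  cts2 <- tibble::tibble(gene = rep(c("g1", "g2"), each = 2),
                         cell = rep(c("c1", "c2"), 2),
                         count_a = c(1, 2, 4, 8),
                         count_b = c(1, 2, 4, 8))
  eta <- library_size_factors(cts2)$eta
  expect_equal(eta, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # doubling cell: eta ratio = 2
  expect_equal(eta[2] / eta[1], 2)

  # genes with a zero in any cell are excluded; none usable -> error
  cts3 <- cts2
  cts3$count_a[1] <- 0
  cts3$count_b[1] <- 0
  cts3$count_a[4] <- 0
  cts3$count_b[4] <- 0
  expect_error(library_size_factors(cts3), "nonzero")
})

test_that("eta is equivariant under relabeling and cell scaling", {
  set.seed(21)
  cts <- tibble::tibble(gene = rep(sprintf("g%d", 1:6), each = 4),
                        cell = rep(sprintf("c%d", 1:4), 6),
                        count_a = rpois(24, 20) + 1,
                        count_b = rpois(24, 20) + 1)
  eta <- library_size_factors(cts)
  perm <- cts[sample(nrow(cts)), ]
  eta_p <- library_size_factors(perm)
  expect_equal(eta$eta[match(eta_p$cell, eta$cell)], eta_p$eta)
  # scaling one cell's counts by lambda scales its eta relative to the others
  lam <- 3
  cts_s <- dplyr::mutate(cts,
    count_a = ifelse(cell == "c2", count_a * lam, count_a),
    count_b = ifelse(cell == "c2", count_b * lam, count_b))
  eta_s <- library_size_factors(cts_s)
  ratio <- function(e) e$eta[e$cell == "c2"] / e$eta[e$cell == "c1"]
  expect_equal(ratio(eta_s) / ratio(eta), lam, tolerance = 1e-12)
})

test_that("spike-in concentration converts to molecules via Avogadro scaling", {
  tbl <- spike_in_true_molecules(
    tibble::tibble(spike_id = "s1", concentration = 1))
  expect_equal(tbl$true_molecules, 1e-18 * 6.02214e23 / 40000, tolerance = 1e-9)
  expect_equal(round(tbl$true_molecules, 3), 15.055)
  # doubling the dilution halves the molecules
  tbl2 <- spike_in_true_molecules(
    tibble::tibble(spike_id = "s1", concentration = 1, dilution_factor = 80000))
  expect_equal(tbl2$true_molecules, tbl$true_molecules / 2)
  # zero concentration excluded with warning
  expect_warning(
    out <- spike_in_true_molecules(
      tibble::tibble(spike_id = c("s1", "s2"), concentration = c(1, 0))),
    "zero concentration")
  expect_equal(out$spike_id, "s1")
})

test_that("observed spike-in reads convert to molecule equivalents", {
  info <- tibble::tibble(spike_id = "s1", molecule_length = 1000)
  obs <- tibble::tibble(spike_id = "s1", cell = c("c1", "c2"),
                        reads = c(100, 100))
  # read_length = molecule_length, eta = 1 -> identity
  out0 <- spike_in_observed_molecules(obs, tibble::tibble(
    spike_id = "s1", molecule_length = 100), read_length = 100)
  expect_equal(out0$observed_molecules, c(100, 100))
  # 100 reads * 100 bp / 1000 bp = 10 molecule-equivalents
  out <- spike_in_observed_molecules(obs, info, read_length = 100)
  expect_equal(out$observed_molecules, c(10, 10))
  # eta = 2 halves the value
  out2 <- spike_in_observed_molecules(
    obs, info, read_length = 100,
    eta = tibble::tibble(cell = c("c1", "c2"), eta = c(2, 1)))
  expect_equal(out2$observed_molecules, c(5, 10))
})

test_that("cell-size factors are the median-normalised endo/spike ratio", {
  cts <- tibble::tibble(gene = "g1", cell = c("c1", "c2", "c3"),
                        count_a = c(10, 20, 40), count_b = c(0, 0, 0))
  spk <- tibble::tibble(spike_id = "s1", cell = c("c1", "c2", "c3"),
                        reads = c(10, 10, 10))
  phi <- cell_size_factors(cts, spk)
  expect_equal(phi$phi, c(0.5, 1, 2)) # raw ratios (1,2,4) median-normalised
  expect_equal(stats::median(phi$phi), 1)
  # a cell with zero spike-in reads is flagged and set to phi = 1
  spk0 <- spk
  spk0$reads[2] <- 0
  expect_warning(phi0 <- cell_size_factors(cts, spk0), "zero spike-in")
  expect_true(phi0$flagged[2])
  expect_equal(phi0$phi[2], 1)
})

test_that("user-supplied cell sizes are median-normalised", {
  out <- normalize_cell_sizes(c(c1 = 2, c2 = 4, c3 = 8))
  expect_equal(out$phi, c(0.5, 1, 2))
  expect_equal(stats::median(out$phi), 1)
  expect_error(normalize_cell_sizes(c(1, -1, 2)), "positive")
})

test_that("count validation catches malformed input", {
  good <- tibble::tibble(gene = "g1", cell = c("c1", "c2"),
                         count_a = c(1, 2), count_b = c(0, 1))
  bad_neg <- dplyr::mutate(good, count_a = c(-1, 2))
  bad_frac <- dplyr::mutate(good, count_b = c(0.5, 1))
  bad_dup <- dplyr::bind_rows(good, good[1, ])
  expect_error(library_size_factors(bad_neg), "Negative")
  expect_error(library_size_factors(bad_frac), "Non-integer")
  expect_error(library_size_factors(bad_dup), "Duplicated")
})
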