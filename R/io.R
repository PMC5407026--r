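#' Read a pair of allele-specific count matrices
#'
#' Reads two tab-delimited matrices (gene rows, cell columns; first column
#' `gene`) holding the allele-A and allele-B read counts at one heterozygous
#' locus per gene, validates them against each other, and returns the long
#' count tibble the rest of the package consumes.
#'
#' @param path_a,path_b Paths to the allele-A and allele-B TSV matrices.
#' @return Tibble with columns `gene`, `cell`, `count_a`, `count_b`.
#' @export
read_allelic_counts <- function(path_a, path_b) {
  read_mat <- function(p) {
    d <- readr::read_tsv(p, show_col_types = FALSE)
    if (names(d)[1] != "gene")
      stop("First column of ", p, " must be named `gene`.", call. = FALSE)
    if (anyDuplicated(d$gene))
      stop("Duplicated gene identifiers in ", p, ".", call. = FALSE)
    d
  }
  a <- read_mat(path_a)
  b <- read_mat(path_b)
  if (!identical(dim(a), dim(b)) || !identical(names(a), names(b)) ||
      !identical(a$gene, b$gene))
    stop("Allele-A and allele-B matrices must have identical genes and cells ",
         "in identical order.", call. = FALSE)
  la <- tidyr::pivot_longer(a, -"gene", names_to = "cell", values_to = "count_a")
  lb <- tidyr::pivot_longer(b, -"gene", names_to = "cell", values_to = "count_b")
  validate_counts(dplyr::bind_cols(la, lb["count_b"]))
}

#' Write a long count tibble as a pair of TSV matrices
#'
#' @param counts Tibble with columns `gene`, `cell`, `count_a`, `count_b`.
#' @param path_a,path_b Output paths.
#' @return Invisibly, the input `counts`.
#' @export
write_allelic_counts <- function(counts, path_a, path_b) {
  counts <- validate_counts(counts)
  wr <- function(col, path) {
    wide <- tidyr::pivot_wider(counts[, c("gene", "cell", col)],
                               names_from = "cell",
                               values_from = dplyr::all_of(col))
    readr::write_tsv(wide, path)
  }
  wr("count_a", path_a)
  wr("count_b", path_b)
  invisible(counts)
}

#' Read a spike-in table
#'
#' Expects a TSV with one row per spike-in per cell and (at least) the columns
#' `spike_id`, `cell`, `true_molecules`, `observed`; alternatively the raw
#' form `spike_id`, `cell`, `concentration`, `molecule_length`, `reads`
#' (plus optional `dilution_factor`), which is converted to molecule scale via
#' [spike_in_true_molecules()] and [spike_in_observed_molecules()].
#'
#' @param path Path to the TSV.
#' @param read_length Read length in bp, required for the raw form.
#' @param eta Optional library-size factors (tibble `cell`, `eta`) for the
#'   raw form.
#' @return Tibble with columns `spike_id`, `cell`, `true_molecules`,
#'   `observed`.
#' @export
read_spike_ins <- function(path, read_length = NULL, eta = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (all(c("true_molecules", "observed") %in% names(d))) {
    return(tibble::as_tibble(d))
  }
  need <- c("spike_id", "cell", "concentration", "molecule_length", "reads")
  if (!all(need %in% names(d)))
    stop("Spike-in table needs either (true_molecules, observed) or (",
         paste(need, collapse = ", "), ").", call. = FALSE)
  if (is.null(read_length))
    stop("`read_length` is required to convert raw spike-in reads.",
         call. = FALSE)
  info <- dplyr::distinct(d[, intersect(
    c("spike_id", "concentration", "molecule_length", "dilution_factor"),
    names(d))])
  info <- spike_in_true_molecules(info)
  obs <- spike_in_observed_molecules(d[, c("spike_id", "cell", "reads")],
                                     info, read_length = read_length,
                                     eta = eta)
  out <- dplyr::left_join(obs, info[, c("spike_id", "true_molecules")],
                          by = "spike_id")
  dplyr::rename(out, observed = "observed_molecules")
}

#' Write the result tables of an allelic bursting fit
#'
#' Writes three TSVs: `<prefix>_results.tsv` (per-gene results),
#' `<prefix>_noise.tsv` (technical-noise parameters) and
#' `<prefix>_size_factors.tsv` (per-cell library-size and cell-size factors).
#'
#' @param fit An [allelic_bursting()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, prefix) {
  stopifnot(inherits(fit, "allelic_bursting"))
  paths <- c(results = paste0(prefix, "_results.tsv"),
             noise = paste0(prefix, "_noise.tsv"),
             size_factors = paste0(prefix, "_size_factors.tsv"))
  readr::write_tsv(fit$results, paths[["results"]])
  readr::write_tsv(tidy(fit$noise), paths[["noise"]])
  sf <- dplyr::left_join(fit$eta, fit$phi, by = "cell")
  readr::write_tsv(sf, paths[["size_factors"]])
  invisible(paths)
}

#' Write a simulated dataset in the CLI input formats
#'
#' Writes the allele matrices, the spike-in table, the cell-size vector and a
#' ground-truth kinetics table (for scoring estimators) under a common prefix.
#'
#' @param sim A [simulate_allelic_dataset()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(sim, prefix) {
  stopifnot(inherits(sim, "allelic_sim"))
  paths <- c(a = paste0(prefix, "_alleleA.tsv"),
             b = paste0(prefix, "_alleleB.tsv"),
             spikes = paste0(prefix, "_spikeins.tsv"),
             sizes = paste0(prefix, "_cell_sizes.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_allelic_counts(sim$counts, paths[["a"]], paths[["b"]])
  readr::write_tsv(sim$spike_ins, paths[["spikes"]])
  readr::write_tsv(tibble::tibble(cell = unique(sim$counts$cell),
                                  phi = sim$phi), paths[["sizes"]])
  truth_long <- dplyr::bind_rows(
    tibble::tibble(gene = sim$truth$gene, allele = "A",
                   k_on = sim$truth$k_on_a, k_off = sim$truth$k_off_a,
                   s = sim$truth$s_a),
    tibble::tibble(gene = sim$truth$gene, allele = "B",
                   k_on = sim$truth$k_on_b, k_off = sim$truth$k_off_b,
                   s = sim$truth$s_b))
  readr::write_tsv(truth_long, paths[["truth"]])
  invisible(paths)
}
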