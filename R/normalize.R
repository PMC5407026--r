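#' Median-of-ratios library-size factors
#'
#' Computes the per-cell sequencing-depth factor
#' \deqn{\eta_c = \mathrm{median}_g \frac{Q^A_{cg} + Q^B_{cg}}
#'       {\left[\prod_{c^*} (Q^A_{c^*g} + Q^B_{c^*g})\right]^{1/C}},}
#' the median across genes of the cell's total allelic count divided by that
#' gene's geometric mean across cells. Genes whose total is zero in any cell
#' are excluded (their geometric mean is undefined), the standard
#' median-of-ratios convention.
#'
#' @param counts Tibble with columns `gene`, `cell`, `count_a`, `count_b`.
#'
#' @return Tibble with columns `cell`, `eta`.
#' @examples
#' counts <- tibble::tibble(
#'   gene = rep(c("g1", "g2"), each = 2),
#'   cell = rep(c("c1", "c2"), 2),
#'   count_a = c(1, 2, 4, 8), count_b = c(1, 2, 4, 8)
#' )
#' library_size_factors(counts) # eta = (0.7071, 1.4142)
#' @export
library_size_factors <- function(counts) {
  counts <- validate_counts(counts)
  tot <- counts$count_a + counts$count_b
  m <- matrix_from_long(counts$gene, counts$cell, tot)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    stop("No gene has a nonzero total count in every cell; ",
         "library-size factors are undefined. Filter to expressed genes first.",
         call. = FALSE)
  }
  m <- m[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  eta <- apply(m / geo, 2, stats::median)
  tibble::tibble(cell = colnames(m), eta = unname(eta))
}

#' True molecule counts of spike-in species
#'
#' Converts a known spike-in concentration (attomoles/uL) to the expected
#' number of molecules per uL of lysis volume:
#' \deqn{\mathrm{molecules} = \frac{C \times 10^{-18} \times 6.02214 \times 10^{23}}
#'       {\mathrm{dilution}}.}
#'
#' @param spike_info Tibble with columns `spike_id`, `concentration`
#'   (attomoles/uL) and optionally `dilution_factor` (default 40000).
#' @param dilution_factor Used when the table has no `dilution_factor` column.
#'
#' @return The input tibble with a `true_molecules` column appended. Spike-ins
#'   with zero concentration are dropped with a warning.
#' @examples
#' spike_in_true_molecules(
#'   tibble::tibble(spike_id = "s1", concentration = 1)
#' ) # 15.055 molecules
#' @export
spike_in_true_molecules <- function(spike_info, dilution_factor = 40000) {
  spike_info <- tibble::as_tibble(spike_info)
  stopifnot(all(c("spike_id", "concentration") %in% names(spike_info)))
  dil <- if ("dilution_factor" %in% names(spike_info))
    spike_info$dilution_factor else dilution_factor
  if (any(dil <= 0)) stop("Dilution factor must be positive.", call. = FALSE)
  if (any(spike_info$concentration < 0))
    stop("Concentrations must be non-negative.", call. = FALSE)
  out <- spike_info
  out$true_molecules <- out$concentration * 1e-18 * 6.02214e23 / dil
  zero <- out$true_molecules == 0
  if (any(zero)) {
    warning(sum(zero), " spike-in(s) with zero concentration excluded.")
    out <- out[!zero, , drop = FALSE]
  }
  out
}

#' Observed spike-in reads on the molecule scale
#'
#' Converts observed per-cell spike-in read counts to molecule equivalents by
#' adjusting for the library-size factor, the read length and the molecule
#' length: `observed_molecules = reads * read_length / molecule_length / eta_c`.
#'
#' @param spike_obs Tibble with columns `spike_id`, `cell`, `reads`.
#' @param spike_info Tibble with columns `spike_id`, `molecule_length` (bp).
#' @param read_length Read length in bp (scalar).
#' @param eta Tibble with columns `cell`, `eta`, or `NULL` for `eta = 1`.
#'
#' @return `spike_obs` with an `observed_molecules` column appended.
#' @export
spike_in_observed_molecules <- function(spike_obs, spike_info, read_length,
                                        eta = NULL) {
  spike_obs <- tibble::as_tibble(spike_obs)
  spike_info <- tibble::as_tibble(spike_info)
  stopifnot(all(c("spike_id", "cell", "reads") %in% names(spike_obs)),
            all(c("spike_id", "molecule_length") %in% names(spike_info)),
            read_length > 0)
  if (any(spike_info$molecule_length <= 0))
    stop("Molecule lengths must be positive.", call. = FALSE)
  if (any(spike_info$molecule_length < read_length))
    warning("Some spike-in molecules are shorter than the read length; ",
            "their molecule-scale counts will exceed their read counts.")
  len <- spike_info$molecule_length[match(spike_obs$spike_id, spike_info$spike_id)]
  if (anyNA(len)) stop("Spike-in IDs in `spike_obs` missing from `spike_info`.",
                       call. = FALSE)
  eta_c <- if (is.null(eta)) rep(1, nrow(spike_obs)) else {
    e <- eta$eta[match(spike_obs$cell, eta$cell)]
    if (anyNA(e)) stop("Cells in `spike_obs` missing from `eta`.", call. = FALSE)
    e
  }
  out <- spike_obs
  out$observed_molecules <- out$reads * read_length / len / eta_c
  out
}

#' Cell-size factors from the endogenous-to-spike-in read ratio
#'
#' The total RNA content of a cell is proxied by the ratio of its total
#' endogenous reads to its total spike-in reads (spike-ins are added in a
#' fixed amount per cell, so the ratio tracks cell size). Ratios are
#' normalised to median 1 so kinetic parameters stay on the per-typical-cell
#' scale.
#'
#' @param counts Tibble with columns `gene`, `cell`, `count_a`, `count_b`.
#' @param spike_obs Tibble with columns `cell` and either `reads` or
#'   `observed` (per-spike-in per-cell read counts).
#'
#' @return Tibble with columns `cell`, `phi`, `flagged` (TRUE for cells whose
#'   spike-in total was zero; their `phi` is set to 1 with a warning).
#' @examples
#' # raw ratios (1, 2, 4) normalise to phi = (0.5, 1, 2)
#' @export
cell_size_factors <- function(counts, spike_obs) {
  counts <- validate_counts(counts)
  spike_obs <- tibble::as_tibble(spike_obs)
  rd_col <- intersect(c("reads", "observed"), names(spike_obs))[1]
  if (is.na(rd_col)) stop("`spike_obs` needs a `reads` or `observed` column.",
                          call. = FALSE)
  endo <- c(tapply(counts$count_a + counts$count_b, counts$cell, sum))
  spk <- c(tapply(spike_obs[[rd_col]], spike_obs$cell, sum))
  cells <- names(endo)
  if (!all(cells %in% names(spk)))
    stop("Spike-in table is missing cells present in the count matrix.",
         call. = FALSE)
  spk <- spk[cells]
  flagged <- spk == 0
  raw <- ifelse(flagged, NA_real_, endo / spk)
  if (all(flagged))
    stop("All cells have zero spike-in reads; cell sizes are undefined.",
         call. = FALSE)
  phi <- raw / stats::median(raw, na.rm = TRUE)
  if (any(flagged)) {
    warning(sum(flagged), " cell(s) with zero spike-in reads; phi set to 1.")
    phi[flagged] <- 1
  }
  tibble::tibble(cell = cells, phi = as.vector(phi), flagged = as.vector(flagged))
}

#' Median-normalise user-supplied cell sizes
#'
#' @param phi Tibble with columns `cell`, `phi`, or a named/plain numeric
#'   vector.
#' @return Tibble with columns `cell`, `phi` where `median(phi) = 1`.
#' @export
normalize_cell_sizes <- function(phi) {
  if (is.numeric(phi)) {
    phi <- tibble::tibble(
      cell = if (is.null(names(phi))) sprintf("cell%03d", seq_along(phi))
             else names(phi),
      phi = unname(phi))
  }
  stopifnot(all(c("cell", "phi") %in% names(phi)))
  if (any(phi$phi <= 0)) stop("Cell sizes must be strictly positive.", call. = FALSE)
  phi$phi <- phi$phi / stats::median(phi$phi)
  tibble::as_tibble(phi)
}

# ---- internal helpers -------------------------------------------------------

# Long (gene, cell, value) -> genes x cells matrix, preserving first-seen order.
matrix_from_long <- function(gene, cell, value) {
  genes <- unique(gene)
  cells <- unique(cell)
  m <- matrix(NA_real_, length(genes), length(cells),
              dimnames = list(genes, cells))
  m[cbind(match(gene, genes), match(cell, cells))] <- value
  if (anyNA(m)) stop("Count table is not a complete gene x cell grid.",
                     call. = FALSE)
  m
}

validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("gene", "cell", "count_a", "count_b")
  if (!all(need %in% names(counts)))
    stop("`counts` must have columns gene, cell, count_a, count_b.",
         call. = FALSE)
  for (cl in c("count_a", "count_b")) {
    v <- counts[[cl]]
    if (any(is.na(v))) stop("Missing values in `", cl, "`.", call. = FALSE)
    if (any(v < 0)) stop("Negative counts in `", cl, "`.", call. = FALSE)
    if (any(v != round(v))) stop("Non-integer counts in `", cl, "`.", call. = FALSE)
  }
  if (anyDuplicated(counts[c("gene", "cell")]))
    stop("Duplicated (gene, cell) rows in `counts`.", call. = FALSE)
  counts
}
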