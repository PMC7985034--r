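# PRINT (PRoportion of INTeraction) normalization for capture-style 3C
# matrices, and matrix-to-matrix rank comparison.
#
# Capture experiments over-represent interactions involving baited bins.
# PRINT divides every cell by the union of the genome-wide interaction
# totals of its two bins, value_ij = bin_ij / (rowsum_i + rowsum_j - bin_ij),
# turning counts into a proportion of interaction in [0, 1]; the subsequent
# filter discards cells between two non-baited bins, which in a capture
# experiment carry only off-target signal.

#' PRINT pre-normalization
#'
#' Transforms raw counts into proportions of interaction:
#' `value_ij = bin_ij / (rowsum_i + rowsum_j - bin_ij)`, where the row sums
#' are each bin's interaction total with the whole genome, self-interactions
#' included. Cells whose denominator is zero (bins with no signal at all)
#' are set to 0 and marked unobserved.
#'
#' @param m an [interaction_matrix()] with raw counts.
#' @param row_sums optional numeric vector of genome-wide per-bin interaction
#'   totals (one per bin of `m`). When omitted, region-restricted row sums
#'   are used with a warning: proportions are then relative to the region,
#'   not the genome.
#' @return an `interaction_matrix` with `stage = "pre"` and values in [0, 1].
#' @export
print_pre_normalize <- function(m, row_sums = NULL) {
  stopifnot(inherits(m, "interaction_matrix"))
  if (m$stage != "raw") stop("print_pre_normalize expects a raw matrix")
  n <- n_bins(m)
  region_sums <- rowSums(m$values)
  if (is.null(row_sums)) {
    warning("no genome-wide row sums supplied; using region-restricted sums")
    row_sums <- region_sums
  }
  stopifnot(length(row_sums) == n)
  if (any(row_sums < region_sums - 1e-6)) {
    stop("inconsistent input: genome-wide row sum smaller than region sum")
  }
  rs_i <- matrix(row_sums, n, n)
  denom <- rs_i + t(rs_i) - m$values
  bad <- m$values > rs_i + 1e-9 | m$values > t(rs_i) + 1e-9
  if (any(bad)) {
    cell <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("inconsistent input: bin_ij exceeds a row sum at cell (%d, %d)",
                 cell[1], cell[2]))
  }
  vals <- ifelse(denom > 0, m$values / denom, 0)
  observed <- m$observed & denom > 0
  interaction_matrix(vals, m$resolution, bins = m$bins, baited = m$baited,
                     stage = "pre", observed = observed)
}

#' Filter non-baited interactions
#'
#' Completes PRINT: cells in which neither endpoint is baited contain only
#' off-target reads and are removed — marked missing, not set to an observed
#' zero, so downstream restraint encoding and correlations skip them.
#'
#' @param m an `interaction_matrix` with `stage = "pre"` and bait flags set.
#' @return an `interaction_matrix` with `stage = "norm"`.
#' @export
filter_non_baited <- function(m) {
  stopifnot(inherits(m, "interaction_matrix"))
  if (m$stage != "pre") stop("filter_non_baited expects a stage 'pre' matrix")
  if (!any(m$baited)) stop("no baited bin in region; annotate baits first")
  keep <- outer(m$baited, m$baited, "|")
  vals <- m$values
  vals[!keep] <- 0
  interaction_matrix(vals, m$resolution, bins = m$bins, baited = m$baited,
                     stage = "norm", observed = m$observed & keep)
}

#' PRINT normalization in one call
#'
#' [print_pre_normalize()] followed by [filter_non_baited()].
#'
#' @inheritParams print_pre_normalize
#' @export
print_normalize <- function(m, row_sums = NULL) {
  filter_non_baited(print_pre_normalize(m, row_sums))
}

#' Spearman rank correlation between two matrices
#'
#' Correlates the upper triangles (diagonal excluded) of two equally-sized
#' matrices. With `cells = "shared-nonmissing"` only cells observed in both
#' matrices enter; `cells = "all"` uses every upper-triangle cell. Ties are
#' handled with midranks, which reduces to the classical
#' `1 - 6*sum(d^2)/(n(n^2-1))` formula on tie-free input.
#'
#' @param a,b `interaction_matrix` objects or plain matrices; a model-derived
#'   contact map (class `contact_map`) is also accepted.
#' @param cells cell selection rule.
#' @return Spearman's rank correlation coefficient in [-1, 1].
#' @export
matrix_spearman <- function(a, b, cells = c("shared-nonmissing", "all")) {
  cells <- match.arg(cells)
  va <- .mat_values(a); vb <- .mat_values(b)
  if (!all(dim(va) == dim(vb))) stop("matrices differ in size")
  ut <- upper.tri(va)
  mask <- ut
  if (cells == "shared-nonmissing") {
    mask <- mask & .mat_observed(a) & .mat_observed(b)
  }
  x <- va[mask]; y <- vb[mask]
  if (length(x) < 3) stop("fewer than 3 comparable cells")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant cell values: Spearman correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}

.mat_values <- function(a) {
  if (inherits(a, "interaction_matrix")) a$values
  else if (inherits(a, "contact_map")) a$fractions
  else as.matrix(a)
}

.mat_observed <- function(a) {
  if (inherits(a, "interaction_matrix")) a$observed
  else matrix(TRUE, nrow(.mat_values(a)), ncol(.mat_values(a)))
}
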