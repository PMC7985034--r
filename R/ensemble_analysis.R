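# Validation statistics on ensembles of 3D models: model-derived contact
# maps, particle-to-particle median distance correlation (ppMdC), distance
# RMSD clustering, radius of gyration, and distribution comparisons.

#' Contact map of a model ensemble
#'
#' Entry (i, j) is the fraction of models in which particles i and j lie at
#' a Euclidean distance strictly below `dcutoff`. The diagonal is 1.
#'
#' @param e a [model_ensemble()].
#' @param dcutoff contact-calling distance in nm (default 200).
#' @return object of class `contact_map`: list with `fractions` (N x N) and
#'   `dcutoff`.
#' @export
contact_map <- function(e, dcutoff = 200) {
  stopifnot(inherits(e, "model_ensemble"), n_models(e) >= 1)
  fr <- cpp_contact_fractions(e$coords, dcutoff)
  structure(list(fractions = fr, dcutoff = dcutoff), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d bins at dcutoff %g nm\n",
              nrow(x$fractions), x$dcutoff))
  invisible(x)
}

#' Per-pair median distances of an ensemble
#'
#' @param e a [model_ensemble()].
#' @return symmetric N x N matrix of per-pair median distances in nm.
#' @export
median_distance_matrix <- function(e) {
  cpp_median_distances(e$coords)
}

#' Particle-to-particle median distance correlation (ppMdC)
#'
#' Spearman correlation between the per-pair median inter-particle distances
#' of two ensembles, over a subset of particle pairs defined by a capture
#' design: `"capture"` (both endpoints captured), `"other"` (neither
#' captured), `"mixed"` (exactly one captured) or `"all"` pairs. Ranges from
#' -1 (perfect anti-correlation) to 1.
#'
#' @param eA,eB [model_ensemble()] objects with equal particle counts.
#' @param subset pair subset.
#' @param design a [capture_design()]; required unless `subset = "all"`.
#' @return Spearman correlation.
#' @export
ppmdc <- function(eA, eB, subset = c("all", "capture", "other", "mixed"),
                  design = NULL) {
  subset <- match.arg(subset)
  if (n_particles(eA) != n_particles(eB)) {
    stop("ensembles have different particle counts")
  }
  n <- n_particles(eA)
  dA <- median_distance_matrix(eA)
  dB <- median_distance_matrix(eB)
  if (subset == "all") {
    sel <- rep(TRUE, n)
    mask <- upper.tri(dA)
  } else {
    if (is.null(design)) stop("subset '", subset, "' requires a capture design")
    cap <- rep(FALSE, n)
    cap[design$indices + 1L] <- TRUE
    pairsel <- switch(subset,
                      capture = outer(cap, cap, "&"),
                      other = outer(!cap, !cap, "&"),
                      mixed = outer(cap, cap, "!="))
    mask <- upper.tri(dA) & pairsel
  }
  if (sum(mask) < 3) stop("subset too small: fewer than 3 particle pairs")
  stats::cor(dA[mask], dB[mask], method = "spearman")
}

#' All-vs-all distance RMSD between models
#'
#' dRMSD(a, b) is the root mean square difference of the two models'
#' internal pairwise distances, taken over all particle pairs. It needs no
#' superposition and is invariant under reflection.
#'
#' @param ensembles a single [model_ensemble()] or a list of ensembles with
#'   equal particle counts; models are pooled in order.
#' @return list with the model x model `drmsd` matrix and `membership`,
#'   the index of the source ensemble of each pooled model.
#' @export
drmsd_matrix <- function(ensembles) {
  if (inherits(ensembles, "model_ensemble")) ensembles <- list(ensembles)
  np <- unique(vapply(ensembles, n_particles, numeric(1)))
  if (length(np) != 1) stop("ensembles differ in particle count")
  coords <- do.call(abind3, lapply(ensembles, function(e) e$coords))
  membership <- rep(seq_along(ensembles),
                    vapply(ensembles, n_models, numeric(1)))
  list(drmsd = cpp_drmsd_matrix(coords), membership = membership)
}

# bind M x N x 3 arrays along the first margin
abind3 <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[2]
  m <- sum(vapply(parts, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(m, n, 3))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Hierarchically cluster pooled models by dRMSD
#'
#' Models from one or more ensembles are pooled, their all-vs-all dRMSD
#' matrix computed, and clustered with Ward's sum-of-squares method. Rigid
#' body superposition is unnecessary for dRMSD itself; for visual
#' consistency downstream tools may superpose within clusters.
#'
#' @inheritParams drmsd_matrix
#' @param k optional number of clusters to cut; when NULL only the
#'   dendrogram is returned.
#' @return list with `hclust` (the dendrogram), `drmsd`, `membership`, and
#'   `labels` (when `k` is given).
#' @export
drmsd_cluster <- function(ensembles, k = NULL) {
  dm <- drmsd_matrix(ensembles)
  hc <- stats::hclust(stats::as.dist(dm$drmsd), method = "ward.D2")
  out <- list(hclust = hc, drmsd = dm$drmsd, membership = dm$membership)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}

#' Radius of gyration of each model
#'
#' Rg = sqrt(mean_i |x_i - centroid|^2), per model, with a median +/- MAD
#' summary. The MAD is reported unscaled (no 1.4826 consistency factor).
#'
#' @param e a [model_ensemble()].
#' @return list with per-model `rg` (nm), `median` and `mad`.
#' @export
radius_of_gyration <- function(e) {
  stopifnot(inherits(e, "model_ensemble"), n_models(e) >= 1)
  rg <- vapply(seq_len(n_models(e)), function(m) {
    x <- e$coords[m, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3)
    ctr <- colMeans(x)
    sqrt(mean(rowSums(sweep(x, 2, ctr)^2)))
  }, numeric(1))
  list(rg = rg, median = stats::median(rg),
       mad = stats::median(abs(rg - stats::median(rg))))
}

#' Compare a model contact map with an interaction matrix
#'
#' Element-wise Spearman correlation over the cells observed in the matrix,
#' upper triangle with the diagonal excluded.
#'
#' @param cm a [contact_map()].
#' @param m an `interaction_matrix` (or plain matrix) of the same size.
#' @return Spearman correlation.
#' @export
compare_map_to_matrix <- function(cm, m) {
  matrix_spearman(cm, m, cells = "shared-nonmissing")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Classical two-sample KS statistic with the asymptotic p-value; used to
#' compare radius-of-gyration and distance distributions between ensembles.
#'
#' @param d1,d2 numeric samples with at least 5 values each.
#' @return list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(d1, d2) {
  if (length(d1) < 5 || length(d2) < 5) {
    stop("ks_two_sample needs at least 5 samples per group")
  }
  kt <- suppressWarnings(stats::ks.test(d1, d2, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Distance profile between particle groups
#'
#' Generic utility for locus-to-locus measures: per model, the distance
#' between the centres of mass of `focus_bins` and of each bin in
#' `target_bins`; summarized by median and unscaled MAD over the ensemble.
#'
#' @param e a [model_ensemble()].
#' @param focus_bins 0-based particle indices of the focus locus.
#' @param target_bins 0-based particle indices of the targets.
#' @return data.frame with target, median distance (nm) and mad.
#' @export
pairwise_distance_profile <- function(e, focus_bins, target_bins) {
  stopifnot(length(focus_bins) >= 1, length(target_bins) >= 1)
  M <- n_models(e)
  d <- matrix(NA_real_, M, length(target_bins))
  for (m in seq_len(M)) {
    x <- matrix(e$coords[m, , ], ncol = 3)
    com <- colMeans(x[focus_bins + 1L, , drop = FALSE])
    d[m, ] <- sqrt(rowSums(sweep(x[target_bins + 1L, , drop = FALSE], 2,
                                 com)^2))
  }
  med <- apply(d, 2, stats::median)
  data.frame(target = target_bins, median = med,
             mad = apply(d, 2, function(v) stats::median(abs(v - stats::median(v)))))
}
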