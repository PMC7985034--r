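# Cell-type comparative 3D analyses: radial enrichment of chromatin marks
# and transcription around a viewpoint, spatial communities of expressed
# genes with their co-occurrence and stability, and community geometry.

#' Outer radii of equal-volume spherical shells
#'
#' Starting from a sphere of radius `r0`, each added shell occupies the same
#' volume as that sphere, giving outer radii r_n = r0 * n^(1/3).
#'
#' @param r0 initial sphere radius in nm (default 200).
#' @param r_max largest radius to cover in nm (default 560).
#' @return numeric vector of strictly increasing outer radii.
#' @export
shell_radii <- function(r0 = 200, r_max = 560) {
  stopifnot(r0 > 0, r_max >= r0)
  n_max <- floor((r_max / r0)^3)
  r0 * (seq_len(max(1, n_max)))^(1 / 3)
}

#' Binarized chromatin-mark profile from peak intervals
#'
#' A bin carries the mark iff at least one peak interval overlaps its
#' half-open genomic interval.
#'
#' @param peaks data.frame with chrom/start/end (e.g. [read_bed()]) or a BED
#'   file path.
#' @param bins bin table (as in an `interaction_matrix`'s `bins`).
#' @param name mark name, e.g. "H3K27ac".
#' @return object of class `mark_profile`: list with `name` and logical
#'   `present` per bin.
#' @export
mark_profile <- function(peaks, bins, name = "mark") {
  if (is.character(peaks)) peaks <- read_bed(peaks)
  peaks <- peaks[peaks$chrom %in% unique(bins$chrom), , drop = FALSE]
  present <- rep(FALSE, nrow(bins))
  if (nrow(peaks) > 0) {
    q <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
    s <- IRanges::IRanges(start = bins$start + 1L, end = bins$end)
    hits <- IRanges::findOverlaps(q, s)
    present[unique(S4Vectors::subjectHits(hits))] <- TRUE
  }
  structure(list(name = name, present = present), class = "mark_profile")
}

#' Cell-specific per-bin cumulative expression profile
#'
#' Each gene with mean log(FPKM) > 0 contributes its mean expression (over
#' replicates) to the bin enclosing its transcription start site; bins
#' accumulate contributions from all their qualifying genes. Genes whose TSS
#' falls outside the region are dropped (count reported via message).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   bp) and one or more `log_fpkm*` replicate columns (or a single
#'   `log_fpkm`).
#' @param region a `region_definition` (or list with chrom/start/end).
#' @param resolution bin size in bp.
#' @return object of class `expression_profile`: per-bin `value`
#'   (cumulative mean log(FPKM)), logical `expressed` (value > 0), the bin
#'   table, and the per-bin gene lists.
#' @export
expression_profile <- function(genes, region, resolution = 5000) {
  repcols <- grep("^log_fpkm", names(genes), value = TRUE)
  if (length(repcols) == 0) stop("no log_fpkm column in expression table")
  expr <- rowMeans(as.matrix(genes[repcols]), na.rm = TRUE)
  n <- as.integer(ceiling((region$end - region$start) / resolution))
  bins <- genomic_bins(region$chrom, region$start, n, resolution)
  inside <- genes$chrom == region$chrom & genes$tss >= region$start &
    genes$tss < region$start + n * resolution
  dropped <- sum(!inside)
  if (dropped > 0) message(dropped, " gene(s) with TSS outside region dropped")
  keep <- inside & expr > 0
  value <- numeric(n)
  gene_lists <- vector("list", n)
  if (any(keep)) {
    bin_idx <- floor((genes$tss[keep] - region$start) / resolution) + 1L
    for (k in seq_along(bin_idx)) {
      b <- bin_idx[k]
      value[b] <- value[b] + expr[keep][k]
      gene_lists[[b]] <- c(gene_lists[[b]], genes$gene_id[keep][k])
    }
  }
  structure(list(value = value, expressed = value > 0, bins = bins,
                 genes = gene_lists),
            class = "expression_profile")
}

#' Radial 3D enrichment around a viewpoint
#'
#' Space around the viewpoint particle is divided into an initial sphere of
#' radius `r0` plus equal-volume shells up to `r_max`. In every model each
#' particle is assigned to the shell containing its distance to the
#' viewpoint (the per-model centroid of the viewpoint particles when several
#' are given). Per shell and feature, a 2x2 Fisher exact test (two-sided)
#' compares particles with/without signal inside versus outside the shell,
#' aggregated over models; the log odds ratio is recorded only when
#' P < 0.01, otherwise the shell stays neutral. A +0.5 Haldane correction is
#' applied to the displayed log odds when exactly one cell is zero; the
#' p-value always comes from the uncorrected exact test.
#'
#' @param e a [model_ensemble()].
#' @param viewpoint 0-based particle index (or indices) of the viewpoint.
#' @param profiles list of `mark_profile` and/or `expression_profile`
#'   objects (expression is binarized to its `expressed` flag).
#' @param r0 initial sphere radius, nm.
#' @param r_max outermost radius, nm.
#' @return data.frame of class `radial_enrichment`: shell, outer radius,
#'   feature, log_odds (NA when not enriched), p_value, enriched flag.
#' @export
radial_enrichment <- function(e, viewpoint, profiles, r0 = 200, r_max = 560) {
  stopifnot(inherits(e, "model_ensemble"))
  radii <- shell_radii(r0, r_max)
  nsh <- length(radii)
  M <- n_models(e)
  N <- n_particles(e)
  others <- setdiff(seq_len(N) - 1L, viewpoint)
  # shell assignment per model x particle; NA when beyond r_max
  shell <- matrix(NA_integer_, M, length(others))
  for (m in seq_len(M)) {
    x <- matrix(e$coords[m, , ], ncol = 3)
    vp <- colMeans(x[viewpoint + 1L, , drop = FALSE])
    d <- sqrt(rowSums(sweep(x[others + 1L, , drop = FALSE], 2, vp)^2))
    s <- ceiling((d / r0)^3)
    s[s < 1] <- 1L
    s[s > nsh] <- NA_integer_
    shell[m, ] <- s
  }
  feats <- lapply(profiles, function(p) {
    if (inherits(p, "expression_profile")) {
      list(name = "expression", signal = p$expressed)
    } else {
      list(name = p$name, signal = p$present)
    }
  })
  rows <- list()
  for (f in feats) {
    sig <- f$signal[others + 1L]
    sig_mat <- matrix(rep(sig, each = M), nrow = M)
    for (s in seq_len(nsh)) {
      inside <- !is.na(shell) & shell == s
      a <- sum(inside & sig_mat)       # signal, inside
      b <- sum(!inside & sig_mat)      # signal, outside
      c0 <- sum(inside & !sig_mat)     # no signal, inside
      d0 <- sum(!inside & !sig_mat)    # no signal, outside
      tab <- matrix(c(a, c0, b, d0), 2)
      degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
      if (degenerate) {
        rows[[length(rows) + 1L]] <- data.frame(
          shell = s, r_outer = radii[s], feature = f$name,
          log_odds = NA_real_, p_value = NA_real_, enriched = FALSE,
          note = "degenerate")
        next
      }
      ft <- stats::fisher.test(tab)
      orr <- (a * d0) / (b * c0)
      if (sum(tab == 0) == 1) {
        orr <- ((a + 0.5) * (d0 + 0.5)) / ((b + 0.5) * (c0 + 0.5))
      }
      enr <- ft$p.value < 0.01
      rows[[length(rows) + 1L]] <- data.frame(
        shell = s, r_outer = radii[s], feature = f$name,
        log_odds = if (enr) log(orr) else NA_real_,
        p_value = ft$p.value, enriched = enr, note = "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("radial_enrichment", "data.frame")
  out
}

#' Calinski-Harabasz index from a distance matrix
#'
#' Computed from pairwise distances via the identity
#' `WSS_c = sum_{i<j in c} d_ij^2 / n_c`, which equals the usual
#' between/within variance-ratio criterion whenever the distances admit a
#' Euclidean embedding.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param labels integer cluster labels.
#' @return the CH index (between-cluster dispersion / within-cluster
#'   dispersion, scaled by degrees of freedom).
#' @export
calinski_harabasz <- function(d, labels) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  k <- length(unique(labels))
  stopifnot(length(labels) == n, k >= 2, k < n)
  d2 <- dm^2
  tss <- sum(d2[upper.tri(d2)]) / n
  wss <- 0
  for (cl in unique(labels)) {
    sel <- labels == cl
    if (sum(sel) > 1) {
      sub <- d2[sel, sel, drop = FALSE]
      wss <- wss + sum(sub[upper.tri(sub)]) / sum(sel)
    }
  }
  bss <- tss - wss
  if (wss <= 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}

# Ward clustering of a distance matrix cut at the CH-optimal k. The optimum
# is the first local maximum of the index over increasing k (the selection
# rule recommended by Calinski & Harabasz): a plain argmax degenerates to
# k ~ n when groups are much tighter than their separation, since the
# within-cluster dispersion can be driven towards zero.
.ward_ch_cut <- function(d, k_max) {
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  n <- nrow(as.matrix(d))
  ks <- seq.int(2, max(2, min(k_max, n - 1)))
  ch <- vapply(ks, function(k) calinski_harabasz(d, stats::cutree(hc, k)),
               numeric(1))
  if (any(is.infinite(ch))) {
    # zero within-cluster dispersion: the partition is perfectly resolved at
    # the smallest such k; splitting further only fragments tight clusters
    best_i <- which(is.infinite(ch))[1]
  } else {
    best_i <- length(ch)
    for (i in seq_along(ch)) {
      left_ok <- i == 1 || ch[i] >= ch[i - 1]
      right_ok <- i == length(ch) || ch[i] >= ch[i + 1]
      if (left_ok && right_ok) { best_i <- i; break }
    }
  }
  best <- ks[best_i]
  list(labels = stats::cutree(hc, best), k = best, hclust = hc, ch = ch)
}

#' Detect spatial communities of expressed genes
#'
#' Per model, the pairwise distance matrix over expressed particles is Ward
#' clustered and cut at the number of clusters maximizing the
#' Calinski-Harabasz index (k in [2, min(15, n_expressed - 1)]). The
#' co-occurrence matrix holds the percentage of models in which two
#' particles share a cluster. It is itself Ward clustered using
#' 100 - co-occurrence as the distance, and the final communities are cut at
#' the CH-optimal k of that embedding.
#'
#' @param e a [model_ensemble()] with at least 10 models.
#' @param expr an [expression_profile()] aligned to the particles (or a
#'   logical/numeric per-particle vector; values > 0 are expressed).
#' @param k_max largest community count to consider (default 15).
#' @return object of class `community_set`: expressed particle indices
#'   (0-based), per-model cluster labels, co-occurrence matrix (0-100),
#'   community assignment, and the expression values of the expressed
#'   particles.
#' @export
detect_communities <- function(e, expr, k_max = 15) {
  stopifnot(inherits(e, "model_ensemble"))
  if (n_models(e) < 10) stop("detect_communities needs at least 10 models")
  value <- if (inherits(expr, "expression_profile")) expr$value else as.numeric(expr)
  stopifnot(length(value) == n_particles(e))
  particles <- which(value > 0) - 1L
  ne <- length(particles)
  if (ne < 3) stop("fewer than 3 expressed particles")
  M <- n_models(e)
  labels <- matrix(NA_integer_, M, ne)
  for (m in seq_len(M)) {
    x <- matrix(e$coords[m, particles + 1L, ], ncol = 3)
    d <- stats::dist(x)
    labels[m, ] <- .ward_ch_cut(d, k_max)$labels
  }
  co <- matrix(0, ne, ne)
  for (m in seq_len(M)) {
    same <- outer(labels[m, ], labels[m, ], "==")
    co <- co + same
  }
  co <- co / M * 100
  diag(co) <- 100
  fin <- .ward_ch_cut(100 - co, k_max)
  structure(list(particles = particles, per_model_labels = labels,
                 cooccurrence = co, communities = fin$labels,
                 n_communities = fin$k,
                 expression = value[particles + 1L]),
            class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("<community_set> %d expressed particles in %d communities\n",
              length(x$particles), x$n_communities))
  invisible(x)
}

#' Inter-community co-occurrence stability scores
#'
#' For each community, the mean co-occurrence between its genes and the
#' genes of all other communities; lower values indicate a more stably
#' segregated community. The per-cell score is the mean over communities.
#'
#' @param cs a [detect_communities()] result with at least 2 communities.
#' @return list with `per_community` (named numeric) and `per_cell`.
#' @export
community_stability <- function(cs) {
  stopifnot(inherits(cs, "community_set"))
  k <- cs$n_communities
  if (k < 2) stop("stability undefined for a single community")
  lab <- cs$communities
  per <- vapply(sort(unique(lab)), function(cl) {
    inside <- lab == cl
    mean(cs$cooccurrence[inside, !inside, drop = FALSE])
  }, numeric(1))
  names(per) <- paste0("community_", sort(unique(lab)))
  list(per_community = per, per_cell = mean(per))
}

#' Spatial geometry of gene communities
#'
#' Treats each community as a rigid body: per model, the centre of mass
#' (COM) of each community and the pairwise COM distances are computed; the
#' model-mean is the typical between-community distance. Per particle, the
#' within-community distance is the model-mean distance to its own
#' community's COM. The expression gradient is the correlation (Pearson by
#' default) between each gene's expression and its within-community
#' distance.
#'
#' @param e the [model_ensemble()] used for community detection.
#' @param cs the [detect_communities()] result.
#' @param method correlation type for the expression gradient.
#' @return list with `com_distances` (k x k model-mean matrix),
#'   `within_distance` (per expressed particle), `gradient_cor` and
#'   `gradient_p`.
#' @export
community_geometry <- function(e, cs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(cs, "community_set"))
  lab <- cs$communities
  comms <- sort(unique(lab))
  k <- length(comms)
  M <- n_models(e)
  ne <- length(cs$particles)
  comd <- matrix(0, k, k)
  withind <- matrix(NA_real_, M, ne)
  for (m in seq_len(M)) {
    x <- matrix(e$coords[m, cs$particles + 1L, ], ncol = 3)
    coms <- t(vapply(comms, function(cl)
      colMeans(x[lab == cl, , drop = FALSE]), numeric(3)))
    comd <- comd + as.matrix(stats::dist(coms))
    own <- coms[match(lab, comms), , drop = FALSE]
    withind[m, ] <- sqrt(rowSums((x - own)^2))
  }
  comd <- comd / M
  dimnames(comd) <- list(paste0("community_", comms), paste0("community_", comms))
  wd <- colMeans(withind)
  grad <- if (stats::sd(wd) > 0 && stats::sd(cs$expression) > 0) {
    ct <- stats::cor.test(cs$expression, wd, method = method, exact = FALSE)
    list(cor = unname(ct$estimate), p = ct$p.value)
  } else list(cor = NA_real_, p = NA_real_)
  list(com_distances = comd, within_distance = wd,
       gradient_cor = grad$cor, gradient_p = grad$p)
}
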