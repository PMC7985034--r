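# Semi-automatic definition of the genomic region to model around a
# viewpoint, from a normalized genome-wide matrix: score bins by cumulative
# interaction with the viewpoint, keep the top-n, build an unweighted
# interaction network, merge 1D-proximal nodes, drop poorly connected ones,
# and take the span of the surviving nodes.

#' Score bins by cumulative interaction with a viewpoint and keep the top n
#'
#' Every non-viewpoint bin on the viewpoint's chromosome is scored by the sum
#' of its normalized interaction values with the viewpoint bins (missing
#' cells contribute nothing). The `top_n` highest-scoring bins with positive
#' score are returned, score-descending; ties at the cut are broken by 1D
#' proximity to the viewpoint, then by lower index.
#'
#' @param m a normalized `interaction_matrix` (genome- or chromosome-wide).
#' @param viewpoint 0-based bin indices of the viewpoint.
#' @param top_n number of bins to keep (default 200).
#' @return data.frame with columns index, score, ordered by the selection.
#' @export
score_and_select <- function(m, viewpoint, top_n = 200) {
  stopifnot(inherits(m, "interaction_matrix"), length(viewpoint) >= 1)
  viewpoint <- as.integer(viewpoint)
  vp_chrom <- unique(m$bins$chrom[viewpoint + 1L])
  if (length(vp_chrom) != 1) stop("viewpoint bins must lie on one chromosome")
  vals <- m$values
  vals[!m$observed] <- 0
  score <- colSums(vals[viewpoint + 1L, , drop = FALSE])
  cand <- setdiff(which(m$bins$chrom == vp_chrom) - 1L, viewpoint)
  cand <- cand[score[cand + 1L] > 0]
  if (length(cand) == 0) stop("viewpoint has no interacting bins")
  prox <- vapply(cand, function(i) min(abs(i - viewpoint)), numeric(1))
  ord <- order(-score[cand + 1L], prox, cand)
  cand <- cand[ord]
  if (length(cand) < top_n) {
    warning(sprintf("only %d interacting bins available (top_n = %d)",
                    length(cand), top_n))
  }
  sel <- utils::head(cand, top_n)
  data.frame(index = sel, score = score[sel + 1L])
}

#' Build the unweighted viewpoint interaction network
#'
#' Nodes are the selected bins plus the viewpoint bins. An edge joins a node
#' pair iff its pairwise normalized interaction value ranks within the
#' `top_n` largest values among all observed node pairs (missing cells never
#' form edges). Rank ties at the cut are all admitted.
#'
#' @param selected data.frame from [score_and_select()] (or an index vector).
#' @param viewpoint 0-based viewpoint bin indices.
#' @param m the normalized `interaction_matrix`.
#' @param top_n edge rank cut (default 200).
#' @return object of class `viewpoint_network`: a node table (index, chrom,
#'   start, end, score, is_viewpoint, members) and a two-column edge matrix
#'   of node row numbers.
#' @export
build_network <- function(selected, viewpoint, m, top_n = 200) {
  idx <- if (is.data.frame(selected)) selected$index else as.integer(selected)
  score <- if (is.data.frame(selected)) selected$score else rep(NA_real_, length(idx))
  viewpoint <- as.integer(viewpoint)
  nodes_idx <- c(setdiff(idx, viewpoint), viewpoint)
  nodes <- data.frame(
    index = nodes_idx,
    chrom = m$bins$chrom[nodes_idx + 1L],
    start = m$bins$start[nodes_idx + 1L],
    end = m$bins$end[nodes_idx + 1L],
    score = c(score[match(setdiff(idx, viewpoint), idx)],
              rep(NA_real_, length(viewpoint))),
    is_viewpoint = c(rep(FALSE, length(setdiff(idx, viewpoint))),
                     rep(TRUE, length(viewpoint))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$index), ]
  rownames(nodes) <- NULL
  nodes$members <- as.list(nodes$index)
  nn <- nrow(nodes)
  pairs <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  bi <- nodes$index[pairs[, 1]] + 1L
  bj <- nodes$index[pairs[, 2]] + 1L
  obs <- m$observed[cbind(bi, bj)]
  val <- m$values[cbind(bi, bj)]
  pairs <- pairs[obs & val > 0, , drop = FALSE]
  val <- val[obs & val > 0]
  if (nrow(pairs) > top_n) {
    cut <- sort(val, decreasing = TRUE)[top_n]
    keep <- val >= cut
    pairs <- pairs[keep, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = unname(pairs)),
            class = "viewpoint_network")
}

#' @export
print.viewpoint_network <- function(x, ...) {
  cat(sprintf("<viewpoint_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a viewpoint network
#' @param net a `viewpoint_network`.
#' @export
network_degree <- function(net) {
  tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = nrow(net$nodes))
}

#' Merge 1D-proximal nodes and drop poorly connected ones
#'
#' Two sequential transformations, in this order: (i) nodes closer than
#' `merge_dist` in genomic coordinates are merged by transitive chaining
#' (single linkage), the merged node spanning its members and inheriting the
#' union of their edges; (ii) nodes with fewer than `min_degree` edges are
#' removed in a single pass. Viewpoint nodes are never removed, so the final
#' region always contains the viewpoint.
#'
#' @param net a `viewpoint_network` (nodes carry genomic coordinates).
#' @param merge_dist 1D merge distance in bp (default 25000).
#' @param min_degree minimum node degree to survive (default 5).
#' @return the transformed `viewpoint_network`.
#' @export
merge_and_filter <- function(net, merge_dist = 25000, min_degree = 5) {
  nodes <- net$nodes
  ord <- order(nodes$chrom, nodes$start)
  nodes <- nodes[ord, ]
  remap <- match(seq_len(nrow(net$nodes)), ord)
  edges <- cbind(remap[net$edges[, 1]], remap[net$edges[, 2]])
  # (i) transitive 1D chaining: gap between consecutive nodes < merge_dist
  grp <- integer(nrow(nodes))
  g <- 1L
  grp[1] <- g
  for (k in seq_len(nrow(nodes))[-1]) {
    gap <- nodes$start[k] - nodes$end[k - 1L]
    same_chrom <- nodes$chrom[k] == nodes$chrom[k - 1L]
    # "closer than merge_dist" between node start coordinates
    close <- same_chrom && (nodes$start[k] - nodes$start[k - 1L]) < merge_dist
    if (!close) g <- g + 1L
    grp[k] <- g
  }
  merged <- data.frame(
    index = tapply(nodes$index, grp, min),
    chrom = tapply(nodes$chrom, grp, function(x) x[1]),
    start = as.numeric(tapply(nodes$start, grp, min)),
    end = as.numeric(tapply(nodes$end, grp, max)),
    score = as.numeric(tapply(nodes$score, grp, function(x)
      if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))),
    is_viewpoint = as.logical(tapply(nodes$is_viewpoint, grp, any)),
    stringsAsFactors = FALSE)
  merged$members <- unname(tapply(nodes$members, grp,
                                  function(l) sort(unlist(l)), simplify = FALSE))
  rownames(merged) <- NULL
  e <- cbind(grp[edges[, 1]], grp[edges[, 2]])
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- unique(t(apply(e, 1, sort)))
  if (length(e) == 0) e <- matrix(integer(0), 0, 2)
  # (ii) single-pass degree filter; viewpoint nodes exempt
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = nrow(merged))
  keep <- deg >= min_degree | merged$is_viewpoint
  if (!any(keep)) {
    stop("all nodes filtered out; lower min_degree or raise merge_dist")
  }
  newid <- cumsum(keep)
  e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
  e <- cbind(newid[e[, 1]], newid[e[, 2]])
  out <- merged[keep, ]
  rownames(out) <- NULL
  structure(list(nodes = out, edges = unname(e)), class = "viewpoint_network")
}

#' Define the modelling region from per-cell-type networks
#'
#' Each network contributes the span of its extreme nodes; the final region
#' is the broader genomic interval enclosing every per-cell-type span.
#'
#' @param nets a single `viewpoint_network` or a (possibly named) list of
#'   them, one per cell type.
#' @return object of class `region_definition` with chrom, start, end and a
#'   per-cell-type provenance list of node indices.
#' @export
define_region <- function(nets) {
  if (inherits(nets, "viewpoint_network")) nets <- list(nets)
  if (length(nets) == 0) stop("at least one network required")
  spans <- lapply(nets, function(net) {
    if (nrow(net$nodes) == 0) stop("empty network")
    chrom <- unique(net$nodes$chrom)
    if (length(chrom) != 1) stop("network spans several chromosomes")
    list(chrom = chrom, start = min(net$nodes$start), end = max(net$nodes$end),
         nodes = net$nodes$index)
  })
  chrom <- unique(vapply(spans, `[[`, character(1), "chrom"))
  if (length(chrom) != 1) stop("networks disagree on chromosome")
  structure(list(chrom = chrom,
                 start = min(vapply(spans, `[[`, numeric(1), "start")),
                 end = max(vapply(spans, `[[`, numeric(1), "end")),
                 provenance = lapply(spans, `[[`, "nodes")),
            class = "region_definition")
}

#' @export
print.region_definition <- function(x, ...) {
  # human display: 1-based inclusive
  cat(sprintf("<region_definition> %s:%s-%s (%d cell types)\n", x$chrom,
              format(x$start + 1, big.mark = ","),
              format(x$end, big.mark = ","), length(x$provenance)))
  invisible(x)
}
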