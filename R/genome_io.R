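# Readers/writers and coordinate conventions shared by all modules.
#
# All internal coordinates are 0-based half-open (BED convention); 1-based
# inclusive strings appear only in messages intended for humans.

#' Build the bin table for a region
#'
#' Bins are fixed-size genomic intervals; one bin corresponds to one bead of
#' the polymer model. Indices are contiguous 0..N-1 in coordinate order.
#'
#' @param chrom chromosome name.
#' @param start 0-based start of the first bin (bp).
#' @param n number of bins.
#' @param resolution bin size in bp.
#' @return data.frame with columns chrom, start, end, index.
#' @export
genomic_bins <- function(chrom, start, n, resolution) {
  stopifnot(n >= 1, resolution >= 1, start >= 0)
  s <- start + resolution * (seq_len(n) - 1L)
  data.frame(chrom = rep(chrom, n), start = s, end = s + resolution,
             index = seq_len(n) - 1L, stringsAsFactors = FALSE)
}

#' Construct an interaction matrix object
#'
#' The central container: a symmetric non-negative N x N matrix of binned
#' pairwise interaction values with per-bin bait annotation. The `observed`
#' mask distinguishes measured cells (possibly zero) from cells that were
#' filtered out or never observable; normalization stages propagate it.
#'
#' @param values symmetric numeric N x N matrix, non-negative.
#' @param bins bin table as from [genomic_bins()]; defaults to a single
#'   anonymous region starting at 0.
#' @param resolution bin size in bp.
#' @param baited logical per-bin bait flag.
#' @param stage one of "raw", "pre", "norm".
#' @param observed logical N x N mask of measured cells.
#' @return object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(values, resolution, bins = NULL, baited = NULL,
                               stage = "raw", observed = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("interaction matrix must be square")
  if (any(!is.finite(values))) stop("interaction values must be finite")
  if (any(values < 0)) stop("interaction values must be non-negative")
  bad <- which(abs(values - t(values)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("asymmetric values at cell (%d, %d)", bad[1, 1], bad[1, 2]))
  }
  values <- (values + t(values)) / 2  # remove float dust
  if (is.null(bins)) bins <- genomic_bins("region", 0L, n, resolution)
  stopifnot(nrow(bins) == n)
  if (is.null(baited)) baited <- rep(FALSE, n)
  stopifnot(length(baited) == n)
  if (is.null(observed)) observed <- matrix(TRUE, n, n)
  stage <- match.arg(stage, c("raw", "pre", "norm"))
  structure(list(values = values, bins = bins, baited = as.logical(baited),
                 resolution = as.integer(resolution), stage = stage,
                 observed = observed),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d bins @ %d bp, stage=%s, %d baited\n",
              n_bins(x), x$resolution, x$stage, sum(x$baited)))
  invisible(x)
}

#' Number of bins of an interaction matrix
#' @param m an `interaction_matrix`.
#' @export
n_bins <- function(m) nrow(m$values)

#' Read an interaction matrix from disk
#'
#' Two plain-text layouts are supported. `triplet`: whitespace-separated
#' `chrom start1 start2 value` rows, one per cell, where start1/start2 are
#' 0-based bin start coordinates; unlisted cells are zero. `dense`: a header
#' line `#bins <chrom> <start> <n> <resolution>` followed by an N x N
#' whitespace-separated matrix.
#'
#' Duplicated triplet cells with equal values collapse silently; conflicting
#' values or an explicit asymmetry are an error naming the cell.
#'
#' @param path file path.
#' @param resolution bin size in bp (triplet format; the dense header carries
#'   its own).
#' @param format `"triplet"` or `"dense"`.
#' @return an [interaction_matrix()].
#' @export
read_matrix <- function(path, resolution = NULL, format = c("triplet", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dense") {
    lines <- readLines(path)
    hdr <- grep("^#bins", lines, value = TRUE)
    if (length(hdr) != 1) stop("dense format requires one '#bins' header line")
    h <- strsplit(trimws(sub("^#bins", "", hdr)), "\\s+")[[1]]
    chrom <- h[1]; start <- as.numeric(h[2]); n <- as.integer(h[3])
    res <- as.integer(h[4])
    body <- lines[!startsWith(lines, "#")]
    body <- body[nzchar(trimws(body))]
    vals <- do.call(rbind, lapply(body, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    if (nrow(vals) != n || ncol(vals) != n) stop("dense matrix is not ", n, "x", n)
    if (any(vals < 0)) stop("negative interaction value in ", path)
    return(interaction_matrix(vals, res, bins = genomic_bins(chrom, start, n, res)))
  }
  stopifnot(!is.null(resolution))
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#",
                           col.names = c("chrom", "start1", "start2", "value"))
  if (any(tab$value < 0)) stop("negative interaction value in ", path)
  chrom <- unique(tab$chrom)
  if (length(chrom) != 1) stop("triplet matrix must be single-chromosome")
  lo <- min(c(tab$start1, tab$start2))
  hi <- max(c(tab$start1, tab$start2))
  if (any((c(tab$start1, tab$start2) - lo) %% resolution != 0)) {
    stop("bin starts are not aligned to the stated resolution")
  }
  n <- as.integer((hi - lo) / resolution) + 1L
  vals <- matrix(0, n, n)
  seen <- matrix(FALSE, n, n)
  i <- as.integer((tab$start1 - lo) / resolution) + 1L
  j <- as.integer((tab$start2 - lo) / resolution) + 1L
  for (k in seq_along(i)) {
    a <- i[k]; b <- j[k]
    for (cell in list(c(a, b), c(b, a))) {
      u <- cell[1]; v <- cell[2]
      if (seen[u, v] && abs(vals[u, v] - tab$value[k]) > 1e-9) {
        stop(sprintf("conflicting values for cell (%d, %d): %g vs %g",
                     u, v, vals[u, v], tab$value[k]))
      }
      vals[u, v] <- tab$value[k]
      seen[u, v] <- TRUE
    }
  }
  interaction_matrix(vals, resolution,
                     bins = genomic_bins(chrom, lo, n, resolution))
}

#' Write an interaction matrix as triplets
#'
#' Only the upper triangle (including the diagonal) of non-missing cells is
#' written. A `#stage:` header records the normalization stage and
#' `#baited:` the 0-based baited bin indices.
#'
#' @param m an [interaction_matrix()].
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#stage: %s", m$stage), con)
  writeLines(sprintf("#resolution: %d", m$resolution), con)
  writeLines(paste0("#baited: ", paste(which(m$baited) - 1L, collapse = ",")), con)
  ut <- which(upper.tri(m$values, diag = TRUE) & m$observed, arr.ind = TRUE)
  lines <- sprintf("%s\t%d\t%d\t%.10g", m$bins$chrom[ut[, 1]],
                   m$bins$start[ut[, 1]], m$bins$start[ut[, 2]],
                   m$values[ut])
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED is consumed natively: 0-based half-open. Only the first three
#' columns (plus an optional name) are used.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end (and name if present).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4) names(tab)[4] <- "name"
  tab[1:min(4, ncol(tab))]
}

#' Flag baited bins from a bait design
#'
#' A bin is baited iff at least one bait interval overlaps its half-open
#' genomic interval. Idempotent; re-annotating replaces the flags.
#'
#' @param m an [interaction_matrix()].
#' @param baits data.frame with chrom/start/end (e.g. from [read_bed()]), or
#'   a BED file path.
#' @return the matrix with updated `baited` flags.
#' @export
annotate_baits <- function(m, baits) {
  if (is.character(baits)) baits <- read_bed(baits)
  baits <- baits[baits$chrom %in% unique(m$bins$chrom), , drop = FALSE]
  flags <- rep(FALSE, n_bins(m))
  if (nrow(baits) > 0) {
    # IRanges is closed [start, end]; shift BED half-open ends by -1
    q <- IRanges::IRanges(start = baits$start + 1L, end = baits$end)
    s <- IRanges::IRanges(start = m$bins$start + 1L, end = m$bins$end)
    hits <- IRanges::findOverlaps(q, s)
    flags[unique(S4Vectors::subjectHits(hits))] <- TRUE
  }
  if (!any(flags)) warning("no bait overlaps any bin; all bait flags FALSE")
  m$baited <- flags
  m
}

#' Construct a capture design
#'
#' The ordered set of captured (baited) bin indices that defines which matrix
#' cells a capture experiment observes.
#'
#' @param indices 0-based bin indices.
#' @param source label, e.g. "experimental baits" or "random synthetic".
#' @export
capture_design <- function(indices, source = "experimental baits") {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0) stop("capture design must be non-empty")
  if (any(indices < 0)) stop("capture indices must be >= 0")
  structure(list(indices = indices, source = source), class = "capture_design")
}

#' Construct a model ensemble
#'
#' @param coords numeric array M x N x 3 of particle coordinates in nm.
#' @param params the `modeling_params` used (may be NULL for synthetic
#'   reference ensembles).
#' @param seeds integer per-model seeds.
#' @param satisfaction per-model fraction of restraints satisfied.
#' @return object of class `model_ensemble`.
#' @export
model_ensemble <- function(coords, params = NULL, seeds = NULL,
                           satisfaction = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (any(!is.finite(coords))) stop("ensemble coordinates must be finite")
  m <- dim(coords)[1]
  if (is.null(seeds)) seeds <- rep(NA_integer_, m)
  if (is.null(satisfaction)) satisfaction <- rep(NA_real_, m)
  stopifnot(length(seeds) == m, length(satisfaction) == m)
  structure(list(coords = coords, params = params,
                 seeds = as.integer(seeds), satisfaction = satisfaction),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d models x %d particles\n",
              n_models(x), n_particles(x)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param e a `model_ensemble`.
#' @export
n_models <- function(e) dim(e$coords)[1]

#' Number of particles per model
#' @param e a `model_ensemble`.
#' @export
n_particles <- function(e) dim(e$coords)[2]

#' Subset the models of an ensemble
#' @param e a `model_ensemble`.
#' @param keep model indices to retain.
#' @export
subset_models <- function(e, keep) {
  model_ensemble(e$coords[keep, , , drop = FALSE], params = e$params,
                 seeds = e$seeds[keep], satisfaction = e$satisfaction[keep])
}

#' Write a model ensemble archive
#'
#' Plain-text archive: a single JSON header line (params, seeds, per-model
#' restraint satisfaction) followed by one XYZ-like block per model.
#' Coordinates are printed in nm with 9 significant digits, so a round trip
#' through [read_ensemble()] preserves them to at least 6 significant digits.
#'
#' @param e a [model_ensemble()].
#' @param path output file.
#' @export
write_ensemble <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(n_models = n_models(e), n_particles = n_particles(e),
              seeds = e$seeds, satisfaction = e$satisfaction,
              params = e$params)
  writeLines(paste0("#sparsefold-ensemble ",
                    jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                                     null = "null")), con)
  for (m in seq_len(n_models(e))) {
    writeLines(sprintf("MODEL %d", m), con)
    writeLines(sprintf("%.9g %.9g %.9g", e$coords[m, , 1],
                       e$coords[m, , 2], e$coords[m, , 3]), con)
  }
  invisible(path)
}

#' Read a model ensemble archive
#'
#' @param path archive written by [write_ensemble()].
#' @return a [model_ensemble()].
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#sparsefold-ensemble ")) {
    stop("not a sparsefold ensemble archive: ", path)
  }
  hdr <- jsonlite::fromJSON(sub("^#sparsefold-ensemble ", "", lines[1]))
  M <- hdr$n_models; N <- hdr$n_particles
  coords <- array(NA_real_, c(M, N, 3))
  pos <- 2L
  for (m in seq_len(M)) {
    if (pos > length(lines) || !startsWith(lines[pos], "MODEL")) {
      stop("truncated ensemble archive at model ", m)
    }
    pos <- pos + 1L
    if (pos + N - 1L > length(lines)) stop("truncated ensemble archive at model ", m)
    block <- lines[pos:(pos + N - 1L)]
    xyz <- matrix(as.numeric(unlist(strsplit(block, "\\s+"))), ncol = 3,
                  byrow = TRUE)
    if (any(is.na(xyz))) stop("non-numeric or NaN coordinate in model ", m)
    coords[m, , ] <- xyz
    pos <- pos + N
  }
  params <- hdr$params
  if (!is.null(params) && length(params) > 0) {
    params <- do.call(modeling_params,
                      params[intersect(names(params),
                                       names(formals(modeling_params)))])
  } else params <- NULL
  model_ensemble(coords, params = params, seeds = hdr$seeds,
                 satisfaction = hdr$satisfaction)
}

# index <-> coordinate helpers ------------------------------------------------

#' Convert a genomic coordinate to its bin index
#' @param m an `interaction_matrix` (or its `bins` table).
#' @param pos 0-based bp position.
#' @export
coord_to_index <- function(m, pos) {
  bins <- if (is.data.frame(m)) m else m$bins
  idx <- findInterval(pos, bins$start)
  idx[pos < bins$start[1] | pos >= bins$end[nrow(bins)]] <- NA_integer_
  as.integer(idx - 1L)
}

#' Convert a bin index to its start coordinate
#' @param m an `interaction_matrix` (or its `bins` table).
#' @param index 0-based bin index.
#' @export
index_to_coord <- function(m, index) {
  bins <- if (is.data.frame(m)) m else m$bins
  bins$start[index + 1L]
}
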