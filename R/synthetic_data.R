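# derive a bounded child seed from a master seed (R integers are 32-bit)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147480000)
}

# Synthetic benchmark machinery: a toy-genome reference ensemble with
# TAD-like architecture, its noisy contact map, random capture designs with
# nested downsampling, virtual-capture extraction from dense maps, and the
# end-to-end sparsity benchmark.
#
# The toy genome is generated, not redistributed: a confined random chain
# whose TAD blocks are compacted toward their centroids, replicated into an
# ensemble with small per-model jitter (low structural variability), whose
# contact map then receives multiplicative log-normal noise (high noise).

#' Specification of the synthetic toy genome
#'
#' @param n_particles chain length (default 626, ~1 Mb at 5 kb less the
#'   terminal bin).
#' @param tad_sizes range of TAD block sizes in bins; blocks are drawn
#'   uniformly from this range until the chain is covered.
#' @param compaction intra-TAD compaction factor in (0, 1]: beads are pulled
#'   toward their TAD centroid by this factor (smaller = more compact).
#' @param n_ensemble reference ensemble size.
#' @param variability per-model coordinate jitter, in bead diameters
#'   (low structural variability preset: 0.1 sigma).
#' @param noise sd of the multiplicative log-normal noise applied to the
#'   contact map (high noise preset: 0.5).
#' @param territory_fraction bead volume fraction of the confining territory
#'   sphere (sets its radius).
#' @param sigma bead diameter in nm.
#' @export
toy_genome_spec <- function(n_particles = 626, tad_sizes = c(30, 80),
                            compaction = 0.6, n_ensemble = 100,
                            variability = 0.1, noise = 0.5,
                            territory_fraction = 0.1, sigma = 50) {
  stopifnot(n_particles >= 10, noise >= 0, variability >= 0,
            compaction > 0, compaction <= 1)
  structure(list(n_particles = as.integer(n_particles), tad_sizes = tad_sizes,
                 compaction = compaction, n_ensemble = as.integer(n_ensemble),
                 variability = variability, noise = noise,
                 territory_fraction = territory_fraction, sigma = sigma),
            class = "toy_genome_spec")
}

#' Generate the toy-genome reference ensemble and its noisy contact map
#'
#' Builds one base conformation — a random chain confined to a territory
#' sphere, with each TAD block compacted toward its centroid — replicates it
#' into an ensemble with i.i.d. Gaussian per-model jitter, derives the dense
#' contact map as the ensemble contact fraction at `dcutoff`, and applies
#' multiplicative log-normal noise (clipped back to [0, 1]).
#'
#' @param spec a [toy_genome_spec()].
#' @param seed integer seed; generation is fully deterministic given the seed.
#' @param dcutoff contact distance for the map, nm (default 200).
#' @return list with `ensemble` (the reference [model_ensemble()]), `map`
#'   (noisy `interaction_matrix`, stage "norm"), `clean_map` (noise-free),
#'   and `tad_boundaries` (0-based start index of each TAD).
#' @export
generate_toy_genome <- function(spec = toy_genome_spec(), seed = 1,
                                dcutoff = 200) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  set.seed(seed)
  n <- spec$n_particles
  sig <- spec$sigma
  # TAD partition
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, sample(seq(spec$tad_sizes[1], spec$tad_sizes[2]), 1))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  boundaries <- cumsum(c(0L, sizes[-length(sizes)]))
  tad_of <- rep(seq_along(sizes), sizes)
  # confined random chain: unit steps reflected into the territory sphere
  r_terr <- (n * 0.125 / spec$territory_fraction)^(1 / 3)  # sigma units
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      z <- stats::runif(1, -1, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      s <- sqrt(1 - z^2)
      cand <- x[i - 1, ] + c(s * cos(phi), s * sin(phi), z)
      if (sum(cand^2) <= r_terr^2) break
    }
    x[i, ] <- cand
  }
  # intra-TAD compaction toward each block's centroid
  for (t in unique(tad_of)) {
    sel <- tad_of == t
    ctr <- colMeans(x[sel, , drop = FALSE])
    x[sel, ] <- sweep(sweep(x[sel, , drop = FALSE], 2, ctr), 1,
                      spec$compaction, "*")
    x[sel, ] <- sweep(x[sel, , drop = FALSE], 2, ctr, "+")
  }
  x <- sweep(x, 2, colMeans(x))  # centre
  # ensemble: base + small per-model jitter
  M <- spec$n_ensemble
  coords <- array(NA_real_, c(M, n, 3))
  for (m in seq_len(M)) {
    coords[m, , ] <- (x + matrix(stats::rnorm(n * 3, 0, spec$variability),
                                 n, 3)) * sig
  }
  ens <- model_ensemble(coords, seeds = seed + seq_len(M) - 1L)
  cm <- contact_map(ens, dcutoff = dcutoff)
  clean <- cm$fractions
  noisy <- clean
  if (spec$noise > 0) {
    ut <- upper.tri(noisy)
    fac <- exp(stats::rnorm(sum(ut), 0, spec$noise))
    noisy[ut] <- noisy[ut] * fac
    noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
    noisy <- pmin(pmax(noisy, 0), 1)
    diag(noisy) <- 1
  }
  mk <- function(v) interaction_matrix(v, resolution = 5000, stage = "norm")
  list(ensemble = ens, map = mk(noisy), clean_map = mk(clean),
       tad_boundaries = boundaries)
}

#' Capture-experiment design for the sparsity benchmark
#'
#' @param n_sets number of independent capture sets (default 10).
#' @param loci_per_set captured loci per full set (default 22).
#' @param downsample_sizes sizes of the nested downsampled subsets
#'   (default 2, 4, 6, 10, 14, 18).
#' @param seed sampling seed.
#' @export
capture_experiment_design <- function(n_sets = 10, loci_per_set = 22,
                                      downsample_sizes = c(2, 4, 6, 10, 14, 18),
                                      seed = 1) {
  stopifnot(all(downsample_sizes <= loci_per_set), n_sets >= 1)
  structure(list(n_sets = as.integer(n_sets),
                 loci_per_set = as.integer(loci_per_set),
                 downsample_sizes = sort(as.integer(downsample_sizes)),
                 seed = as.integer(seed)),
            class = "capture_experiment_design")
}

#' Sample nested random capture designs
#'
#' Per set, `loci_per_set` bins are drawn uniformly without replacement; the
#' downsampled subsets are nested (every smaller subset is contained in the
#' next larger one), obtained by truncating a random permutation of the full
#' set.
#'
#' @param n_bins number of bins available.
#' @param design a [capture_experiment_design()].
#' @return list of sets; each set is a named list of [capture_design()]
#'   objects keyed by capture count (downsamples plus the full set).
#' @export
sample_captures <- function(n_bins, design = capture_experiment_design()) {
  stopifnot(design$loci_per_set <= n_bins)
  set.seed(design$seed)
  sizes <- c(design$downsample_sizes, design$loci_per_set)
  lapply(seq_len(design$n_sets), function(s) {
    full <- sample.int(n_bins, design$loci_per_set) - 1L  # 0-based
    out <- lapply(sizes, function(k)
      capture_design(full[seq_len(k)], source = "random synthetic"))
    names(out) <- as.character(sizes)
    out
  })
}

#' Extract a virtual capture matrix from a dense matrix
#'
#' Keeps exactly the cells in which at least one endpoint is a captured bin;
#' all other cells become missing (not observed zeros). Bait flags are set
#' from the design. A full design is the identity.
#'
#' @param m a dense `interaction_matrix`.
#' @param design a [capture_design()].
#' @return the sparse `interaction_matrix`.
#' @export
virtual_capture <- function(m, design) {
  stopifnot(inherits(m, "interaction_matrix"), inherits(design, "capture_design"))
  n <- n_bins(m)
  if (max(design$indices) >= n) stop("capture index outside the matrix")
  cap <- rep(FALSE, n)
  cap[design$indices + 1L] <- TRUE
  keep <- outer(cap, cap, "|")
  vals <- m$values
  vals[!keep] <- 0
  interaction_matrix(vals, m$resolution, bins = m$bins, baited = cap,
                     stage = m$stage, observed = m$observed & keep)
}

#' Fraction of matrix cells carrying information
#'
#' With a restraint set: the number of restraints over the number of
#' unordered particle pairs n(n-1)/2. With a capture design alone: the
#' fraction of unordered cell pairs (i <= j) surviving virtual capture.
#'
#' @param design a [capture_design()] (ignored when `restraints` given).
#' @param n_bins matrix size.
#' @param restraints optional `restraint_set`.
#' @return fraction in [0, 1].
#' @export
sparsity_fraction <- function(design, n_bins, restraints = NULL) {
  if (!is.null(restraints)) {
    return(nrow(restraints) / (n_bins * (n_bins - 1) / 2))
  }
  c <- length(design$indices)
  (choose(c, 2) + c * (n_bins - c) + c) / (n_bins * (n_bins + 1) / 2)
}

#' Sparsity benchmark: reconstruction efficiency versus capture density
#'
#' The full synthetic pipeline: generate the toy-genome reference ensemble
#' and noisy map, sample nested capture sets, extract each virtual capture
#' matrix, reconstruct a model ensemble from it, and score it against the
#' reference by ppMdC over all particle pairs. The lowfreq/upfreq cutoffs
#' are grid-searched once on the first full-capture matrix and reused.
#' Returns a tidy table plus an exponential fit of ppMdC against the
#' percentage of matrix cells used as restraints.
#'
#' @param spec a [toy_genome_spec()].
#' @param design a [capture_experiment_design()].
#' @param preset `"desk"` (25 models/condition, grid with 6 models) or
#'   `"paper"` (100 models, grid with 100); individual numbers can be
#'   overridden.
#' @param maxdist,dcutoff modelling distance parameters, nm (synthetic
#'   benchmark settings: 500 and 200).
#' @param n_models models per condition (preset default).
#' @param n_steps steering steps per trajectory.
#' @param grid_n_models models per grid-search combination.
#' @param seed master seed for capture sampling and modelling noise.
#' @param toy_seed seed of the toy-genome realization; defaults to `seed`.
#'   Fixing it across runs emulates benchmarking against one fixed reference
#'   toy genome while captures and trajectories vary.
#' @param conditions capture counts to run (default: all in the design).
#' @param verbose print progress.
#' @return list with `table` (set, n_captures, pct_cells, ppmdc), `fit`
#'   (exponential fit coefficients or NULL), `params`, and `toy`.
#' @export
sparsity_benchmark <- function(spec = toy_genome_spec(),
                               design = capture_experiment_design(),
                               preset = c("desk", "paper"),
                               maxdist = 500, dcutoff = 200,
                               n_models = NULL, n_steps = NULL,
                               grid_n_models = NULL, seed = 1,
                               toy_seed = NULL, conditions = NULL,
                               verbose = FALSE) {
  preset <- match.arg(preset)
  if (is.null(n_models)) n_models <- if (preset == "desk") 25 else 100
  if (is.null(n_steps)) n_steps <- 5000
  if (is.null(grid_n_models)) grid_n_models <- if (preset == "desk") 6 else 100
  if (is.null(toy_seed)) toy_seed <- seed
  toy <- generate_toy_genome(spec, seed = toy_seed, dcutoff = dcutoff)
  n <- spec$n_particles
  sets <- sample_captures(n, design)
  sizes <- c(design$downsample_sizes, design$loci_per_set)
  if (is.null(conditions)) conditions <- sizes
  conditions <- intersect(conditions, sizes)
  # lowfreq/upfreq grid search on the first full-capture matrix
  full1 <- virtual_capture(toy$map, sets[[1]][[as.character(design$loci_per_set)]])
  if (verbose) message("grid-searching lowfreq/upfreq on the full capture set")
  gs <- grid_search(full1, lowfreq = c(-1, -0.5, 0, 0.5),
                    upfreq = c(-1, -0.5, 0, 0.5), maxdist = maxdist,
                    dcutoffs = dcutoff, n_models = grid_n_models,
                    seed0 = derive_seed(seed, 1), n_steps = n_steps)
  top <- gs[!is.na(gs$correlation), ][1, ]
  params <- modeling_params(lowfreq = top$lowfreq, upfreq = top$upfreq,
                            maxdist = maxdist, dcutoff = dcutoff,
                            n_models = n_models, n_steps = n_steps)
  rows <- list()
  for (s in seq_along(sets)) {
    for (k in conditions) {
      cd <- sets[[s]][[as.character(k)]]
      mcap <- virtual_capture(toy$map, cd)
      seed_k <- derive_seed(seed, s * 100L + match(k, sizes) * 5000L)
      ens <- build_ensemble(mcap, params, seed0 = seed_k)
      rs <- attr(ens, "restraints")
      pm <- ppmdc(ens, toy$ensemble, subset = "all")
      if (verbose) {
        message(sprintf("set %d, %2d captures: ppMdC = %.3f", s, k, pm))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, n_captures = k,
        pct_cells = 100 * sparsity_fraction(cd, n, restraints = rs),
        ppmdc = pm)
    }
  }
  tab <- do.call(rbind, rows)
  fit <- NULL
  if (length(unique(tab$pct_cells)) >= 3) {
    fit <- tryCatch(
      stats::nls(ppmdc ~ a - b * exp(-c0 * pct_cells), data = tab,
                 start = list(a = max(tab$ppmdc), b = 1, c0 = 0.5)),
      error = function(e) NULL)
  }
  list(table = tab, fit = fit, params = params, toy = toy)
}
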