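# Encoding normalized interaction frequencies into spatial restraints and
# sampling model conformations by steered Langevin dynamics of a
# Kremer-Grest bead-spring chain.
#
# The inverse relationship between interaction frequency and spatial
# distance is applied in z-score space: log10 interaction values are
# standardized over the observed non-zero cells; pairs above `upfreq`
# receive a harmonic restraint, pairs below `lowfreq` a lower-bound
# harmonic, and the equilibrium distance maps linearly from the z range
# onto [maxdist, sigma] (higher z -> shorter distance). Spring constants
# are weighted by 1/L with L the sequence separation, and ramped from zero
# to their maximum over the steering phase.

#' Modelling hyperparameters
#'
#' @param lowfreq lower-bound z-score cutoff: pairs with z <= lowfreq are
#'   kept apart by a lower-bound harmonic.
#' @param upfreq upper-bound z-score cutoff: pairs with z >= upfreq are
#'   pulled together by a harmonic oscillator.
#' @param maxdist distance scale cap in nm; equilibrium distance assigned to
#'   the least-interacting observed pair.
#' @param dcutoff contact-calling distance in nm for model contact maps.
#' @param resolution bp of chromatin per bead (default 5000).
#' @param sigma bead diameter in nm (default 50).
#' @param n_models default ensemble size.
#' @param n_steps steering steps per trajectory (default 5000).
#' @param k0 restraint spring-constant scale, kBT/sigma^2; the per-restraint
#'   maximum is k0 / L (default 10).
#' @param flat_deq if TRUE, all harmonic restraints use d_eq = sigma and all
#'   lower bounds d_eq = maxdist instead of the linear z map.
#' @export
modeling_params <- function(lowfreq = -0.5, upfreq = 0, maxdist = 300,
                            dcutoff = 200, resolution = 5000, sigma = 50,
                            n_models = 100, n_steps = 5000, k0 = 10,
                            flat_deq = FALSE) {
  stopifnot(maxdist > sigma, dcutoff > 0, sigma > 0, n_steps >= 1, k0 > 0)
  structure(list(lowfreq = lowfreq, upfreq = upfreq, maxdist = maxdist,
                 dcutoff = dcutoff, resolution = resolution, sigma = sigma,
                 n_models = n_models, n_steps = n_steps, k0 = k0,
                 flat_deq = flat_deq),
            class = "modeling_params")
}

#' @export
print.modeling_params <- function(x, ...) {
  cat(sprintf(paste0("<modeling_params> lowfreq=%g upfreq=%g maxdist=%g nm ",
                     "dcutoff=%g nm sigma=%g nm\n"),
              x$lowfreq, x$upfreq, x$maxdist, x$dcutoff, x$sigma))
  invisible(x)
}

#' z-score transform of a normalized matrix
#'
#' Standardizes log10 interaction values over the observed non-zero cells of
#' the upper triangle (diagonal excluded). Missing and zero cells carry no
#' z-score and can never receive restraints.
#'
#' @param m a normalized `interaction_matrix`.
#' @return matrix of z-scores with NA where no z-score is defined.
#' @export
zscore_transform <- function(m) {
  stopifnot(inherits(m, "interaction_matrix"))
  vals <- m$values
  ok <- m$observed & vals > 0
  diag(ok) <- FALSE
  if (sum(ok[upper.tri(ok)]) < 10) {
    warning("fewer than 10 observed non-zero cells; z-scores are unstable")
  }
  lg <- suppressWarnings(log10(vals))
  obs <- lg[upper.tri(lg) & ok]
  mu <- mean(obs)
  sdv <- sqrt(mean((obs - mu)^2))  # population sd
  if (sdv == 0) stop("all observed values equal: z-scores undefined (sd = 0)")
  z <- (lg - mu) / sdv
  z[!ok] <- NA_real_
  z
}

#' Encode a z-score matrix into spatial restraints
#'
#' Non-consecutive particle pairs (|i - j| >= 2) with an observed z-score are
#' classified: z >= upfreq gives a harmonic restraint, z <= lowfreq a
#' lower-bound harmonic, anything between none. The equilibrium distance
#' maps linearly from [z_min, z_max] onto [maxdist, sigma] and is clamped to
#' that interval; the maximal spring constant is k0 / L with L = |i - j|.
#'
#' @param z z-score matrix from [zscore_transform()].
#' @param p a [modeling_params()].
#' @return data.frame of class `restraint_set`: i, j (0-based), kind
#'   ("harmonic"/"lower_bound"), d_eq (nm), k_max (kBT/sigma^2), L.
#' @export
encode_restraints <- function(z, p) {
  stopifnot(inherits(p, "modeling_params"))
  n <- nrow(z)
  idx <- which(upper.tri(z) & !is.na(z), arr.ind = TRUE)
  idx <- idx[abs(idx[, 1] - idx[, 2]) >= 2, , drop = FALSE]
  zv <- z[idx]
  kind <- ifelse(zv >= p$upfreq, "harmonic",
                 ifelse(zv <= p$lowfreq, "lower_bound", NA_character_))
  keep <- !is.na(kind)
  idx <- idx[keep, , drop = FALSE]
  zv <- zv[keep]
  kind <- kind[keep]
  if (length(zv) == 0) {
    stop(sprintf("no restraints produced (lowfreq = %g, upfreq = %g)",
                 p$lowfreq, p$upfreq))
  }
  zr <- range(z, na.rm = TRUE)
  if (diff(zr) > 0) {
    d_eq <- p$maxdist + (zv - zr[1]) / diff(zr) * (p$sigma - p$maxdist)
  } else {
    d_eq <- rep((p$maxdist + p$sigma) / 2, length(zv))
  }
  d_eq <- pmin(pmax(d_eq, p$sigma), p$maxdist)
  if (p$flat_deq) d_eq <- ifelse(kind == "harmonic", p$sigma, p$maxdist)
  L <- abs(idx[, 1] - idx[, 2])
  out <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, kind = kind,
                    d_eq = d_eq, k_max = p$k0 / L, L = L)
  rownames(out) <- NULL
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Random self-avoiding-walk starting conformation
#'
#' Beads are grown as an off-lattice self-avoiding walk with bond length one
#' bead diameter and a hard core of one diameter, placed randomly near the
#' centre of the simulation box, then relaxed by a short Polak-Ribiere
#' conjugate-gradient run on the bare polymer energy.
#'
#' @param N number of particles (>= 2).
#' @param seed integer seed; identical seeds give identical conformations.
#' @param sigma bead diameter in nm.
#' @return N x 3 coordinate matrix in nm.
#' @export
init_conformation <- function(N, seed, sigma = 50) {
  stopifnot(N >= 2)
  x <- cpp_saw_init(N, placement_half = 20, seed = as.integer(seed))
  x <- cpp_minimize(x, max_iter = 200, k_tether = 50)
  x * sigma
}

#' Steering schedule
#'
#' @param total_steps number of integration steps.
#' @param dt integrator timestep in reduced time units.
#' @param friction Langevin friction coefficient (reduced units).
#' @export
steering_schedule <- function(total_steps = 5000, dt = 0.01, friction = 0.5) {
  stopifnot(total_steps >= 1, dt > 0, friction > 0)
  structure(list(total_steps = as.integer(total_steps), dt = dt,
                 friction = friction),
            class = "steering_schedule")
}

#' Run one steered-dynamics trajectory
#'
#' Integrates Langevin dynamics of the Kremer-Grest chain (FENE bonds,
#' purely repulsive WCA excluded volume, centre-of-mass tether) while each
#' restraint's spring constant k(L, t) ramps linearly from zero to
#' k_max(L) = k0 / L. The conformation at the end of the steering protocol
#' is returned together with the fraction of restraints satisfied within a
#' 2-sigma tolerance (harmonic: d <= d_eq + 2 sigma; lower bound:
#' d >= d_eq - 2 sigma).
#'
#' @param coords N x 3 starting coordinates in nm (e.g. from
#'   [init_conformation()]).
#' @param restraints a `restraint_set`.
#' @param schedule a [steering_schedule()].
#' @param seed integer seed for the thermal noise.
#' @param sigma bead diameter in nm.
#' @return list with `coords` (N x 3, nm) and `satisfaction`.
#' @export
steer_dynamics <- function(coords, restraints, schedule = steering_schedule(),
                           seed = 1, sigma = 50) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  n <- nrow(coords)
  if (nrow(restraints) > 0 &&
      (max(restraints$i, restraints$j) >= n || min(restraints$i) < 0)) {
    stop("restraint references a particle outside the chain")
  }
  kind_code <- ifelse(restraints$kind == "lower_bound", 1L, 0L)
  res <- cpp_steer(coords / sigma,
                   as.integer(restraints$i), as.integer(restraints$j),
                   as.integer(kind_code),
                   restraints$d_eq / sigma, restraints$k_max,
                   n_steps = schedule$total_steps, dt = schedule$dt,
                   gamma = schedule$friction, k_tether = 50,
                   seed = as.integer(seed), sat_tol = 2.0)
  list(coords = res$coords * sigma, satisfaction = res$satisfaction)
}

#' Build a model ensemble from a normalized matrix
#'
#' Runs `n_models` independent steered trajectories (seeds
#' `seed0 .. seed0 + n_models - 1`), each from a fresh self-avoiding-walk
#' conformation. Retention `"end_of_steering"` keeps every end-of-steering
#' conformation; `"majority_satisfied"` keeps only models satisfying more
#' than half of the imposed restraints within 2 sigma, with a warning when
#' fewer than half of the trajectories qualify.
#'
#' @param m a normalized `interaction_matrix`.
#' @param p a [modeling_params()].
#' @param n_models ensemble size (defaults to `p$n_models`).
#' @param seed0 first per-model seed.
#' @param retention retention policy.
#' @return a [model_ensemble()].
#' @export
build_ensemble <- function(m, p, n_models = p$n_models, seed0 = 1,
                           retention = c("end_of_steering",
                                         "majority_satisfied")) {
  retention <- match.arg(retention)
  z <- zscore_transform(m)
  rs <- encode_restraints(z, p)
  N <- n_bins(m)
  sched <- steering_schedule(total_steps = p$n_steps)
  seeds <- as.integer(seed0 + seq_len(n_models) - 1L)
  coords <- array(NA_real_, c(n_models, N, 3))
  sat <- numeric(n_models)
  for (k in seq_len(n_models)) {
    x0 <- init_conformation(N, seed = seeds[k], sigma = p$sigma)
    tr <- steer_dynamics(x0, rs, sched, seed = seeds[k], sigma = p$sigma)
    coords[k, , ] <- tr$coords
    sat[k] <- tr$satisfaction
  }
  e <- model_ensemble(coords, params = p, seeds = seeds, satisfaction = sat)
  if (retention == "majority_satisfied") {
    keep <- which(sat > 0.5)
    if (length(keep) < n_models / 2) {
      warning(sprintf("only %d/%d trajectories satisfy the majority of restraints",
                      length(keep), n_models))
    }
    if (length(keep) == 0) keep <- which.max(sat)
    e <- subset_models(e, keep)
  }
  attr(e, "restraints") <- rs
  e
}

#' Enumerate grid-search parameter combinations
#'
#' All combinations of the supplied lowfreq, upfreq and maxdist values (the
#' default grids give 4 x 4 x 4 = 64 combinations).
#'
#' @param lowfreq,upfreq z-score cutoff grids.
#' @param maxdist distance-cap grid in nm.
#' @return data.frame with one row per combination.
#' @export
grid_search_combos <- function(lowfreq = c(-1, -0.5, 0, 0.5),
                               upfreq = c(-1, -0.5, 0, 0.5),
                               maxdist = c(200, 300, 400, 500)) {
  expand.grid(lowfreq = lowfreq, upfreq = upfreq, maxdist = maxdist,
              KEEP.OUT.ATTRS = FALSE)
}

#' Grid search over modelling parameters
#'
#' For every (lowfreq, upfreq, maxdist) combination an ensemble of
#' `n_models` is built and its contact map is compared with the input
#' matrix at every `dcutoff` by Spearman correlation; combinations are
#' ranked by correlation (ties: smaller maxdist, then smaller dcutoff).
#'
#' @param m a normalized `interaction_matrix`.
#' @param lowfreq,upfreq,maxdist parameter grids (paper-default values).
#' @param dcutoffs contact-calling distances to assess, nm.
#' @param n_models ensemble size per combination.
#' @param seed0 first per-model seed, shared across combinations.
#' @param n_steps steering steps per trajectory.
#' @return data.frame of combinations with the assessed correlation, best
#'   dcutoff first, ranked by decreasing correlation.
#' @export
grid_search <- function(m, lowfreq = c(-1, -0.5, 0, 0.5),
                        upfreq = c(-1, -0.5, 0, 0.5),
                        maxdist = c(200, 300, 400, 500),
                        dcutoffs = c(100, 150, 200, 250, 300, 350, 450, 500),
                        n_models = 100, seed0 = 1, n_steps = 5000) {
  combos <- grid_search_combos(lowfreq, upfreq, maxdist)
  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    p <- modeling_params(lowfreq = combos$lowfreq[k],
                         upfreq = combos$upfreq[k],
                         maxdist = combos$maxdist[k],
                         dcutoff = dcutoffs[1], n_models = n_models,
                         n_steps = n_steps)
    e <- tryCatch(build_ensemble(m, p, seed0 = seed0),
                  error = function(err) NULL)
    if (is.null(e)) {
      rows[[k]] <- data.frame(combos[k, , drop = FALSE], dcutoff = NA_real_,
                              correlation = NA_real_)
      next
    }
    best <- c(dcutoff = NA_real_, correlation = -Inf)
    for (dc in dcutoffs) {
      cm <- contact_map(e, dcutoff = dc)
      r <- tryCatch(matrix_spearman(cm, m), error = function(err) NA_real_)
      if (!is.na(r) && r > best["correlation"]) {
        best <- c(dcutoff = dc, correlation = r)
      }
    }
    rows[[k]] <- data.frame(combos[k, , drop = FALSE],
                            dcutoff = best[["dcutoff"]],
                            correlation = best[["correlation"]])
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$correlation, out$maxdist, out$dcutoff), ]
  rownames(out) <- NULL
  out
}

#' Remove mirror-image models from an ensemble
#'
#' Steered reconstruction cannot distinguish a structure from its mirror
#' image. Models are compared by coordinate RMSD after optimal proper
#' rotation (reflections excluded, so mirrored conformations stay distant),
#' clustered with Ward's method, cut into two clusters, and the more
#' populated cluster is retained (ties: the cluster holding the model with
#' the best restraint satisfaction).
#'
#' @param e a [model_ensemble()] with at least 2 models.
#' @return the filtered `model_ensemble`.
#' @export
mirror_filter <- function(e) {
  stopifnot(inherits(e, "model_ensemble"))
  if (n_models(e) < 2) stop("mirror_filter needs at least 2 models")
  rmsd <- cpp_rmsd_matrix(e$coords)
  if (max(rmsd) < 1e-6) return(e)  # all models identical up to rotation
  hc <- stats::hclust(stats::as.dist(rmsd), method = "ward.D2")
  lab <- stats::cutree(hc, k = 2)
  sizes <- table(lab)
  if (sizes[1] != sizes[2]) {
    keep_lab <- as.integer(names(which.max(sizes)))
  } else {
    sat <- e$satisfaction
    if (all(is.na(sat))) keep_lab <- 1L
    else keep_lab <- lab[which.max(sat)]
  }
  subset_models(e, which(lab == keep_lab))
}
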