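# Shared fixture builders. Everything is generated in code at test time.

# symmetric non-negative random interaction matrix
random_matrix <- function(n, seed = 1, density = 0.8) {
  set.seed(seed)
  v <- matrix(0, n, n)
  ut <- upper.tri(v, diag = TRUE)
  x <- stats::rexp(sum(ut)) * stats::rbinom(sum(ut), 1, density)
  v[ut] <- x
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  v
}

# ensemble with fully specified coordinates: list of N x 3 matrices
ensemble_from_models <- function(models, ...) {
  coords <- array(NA_real_, c(length(models), nrow(models[[1]]), 3))
  for (m in seq_along(models)) coords[m, , ] <- models[[m]]
  model_ensemble(coords, ...)
}

# a random rigid conformation in nm
random_conformation <- function(n, seed = 1, scale = 100) {
  set.seed(seed)
  matrix(stats::rnorm(n * 3, 0, scale), n, 3)
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# dense graded matrix from a structure via the inverse frequency-distance law
distance_law_matrix <- function(e, alpha = 1.5, sigma = 50) {
  md <- median_distance_matrix(e)
  v <- (sigma / pmax(md, sigma))^alpha
  diag(v) <- 1
  interaction_matrix(v, 5000, stage = "norm")
}

# adjusted Rand index between two labelings (direct contingency formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- ai * bj / choose(n, 2)
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# ensemble with three rigid, well-separated expressed communities
planted_community_ensemble <- function(seed, n_models = 20, spread = 8) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0), c(800, 0, 0), c(0, 800, 0))
  sizes <- c(5, 6, 4)
  truth <- rep(1:3, sizes)
  base <- do.call(rbind, lapply(1:3, function(c0)
    sweep(matrix(rnorm(sizes[c0] * 3, 0, 50), ncol = 3), 2, centers[c0, ], "+")))
  mods <- lapply(seq_len(n_models), function(m) {
    set.seed(seed * 1000 + m)
    base + matrix(rnorm(length(base), 0, spread), nrow(base))
  })
  list(e = ensemble_from_models(mods), truth = truth)
}

# brute-force Spearman via the printed no-tie formula
spearman_formula <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}
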