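test_that("z-scores standardize log10 values over observed non-zero cells", {
  # two observed values 10^1 and 10^3 -> z = -1, +1 (population sd)
  v <- matrix(0, 4, 4)
  v[1, 2] <- v[2, 1] <- 10
  v[3, 4] <- v[4, 3] <- 1000
  m <- interaction_matrix(v, 5000, stage = "norm")
  expect_warning(z <- zscore_transform(m), "unstable")
  expect_equal(z[1, 2], -1)
  expect_equal(z[3, 4], 1)
  expect_true(is.na(z[1, 3]))  # zero cell: no z-score

  # all observed values equal -> sd = 0 error
  v2 <- matrix(2, 6, 6)
  m2 <- interaction_matrix(v2, 5000, stage = "norm")
  expect_error(zscore_transform(m2), "sd = 0")

  # missing cells never receive a z-score
  v3 <- v; v3[1, 3] <- v3[3, 1] <- 100
  obs <- matrix(TRUE, 4, 4); obs[1, 2] <- obs[2, 1] <- FALSE
  m3 <- interaction_matrix(v3, 5000, stage = "norm", observed = obs)
  z3 <- suppressWarnings(zscore_transform(m3))
  expect_true(is.na(z3[1, 2]))
  expect_false(is.na(z3[1, 3]))
})

test_that("restraint encoding matches a per-pair classification oracle", {
  set.seed(4)
  n <- 10
  z <- matrix(NA_real_, n, n)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  zv <- stats::rnorm(nrow(ut))
  z[ut] <- zv
  p <- modeling_params(lowfreq = -0.5, upfreq = 0.5, maxdist = 300)
  rs <- encode_restraints(z, p)
  # oracle: plain double loop
  zr <- range(z, na.rm = TRUE)
  cnt_h <- 0; cnt_l <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (is.na(z[i, j]) || abs(i - j) < 2) next
    if (z[i, j] >= 0.5) cnt_h <- cnt_h + 1
    if (z[i, j] <= -0.5) cnt_l <- cnt_l + 1
  }
  expect_equal(sum(rs$kind == "harmonic"), cnt_h)
  expect_equal(sum(rs$kind == "lower_bound"), cnt_l)
  expect_true(all(abs(rs$i - rs$j) >= 2))
  # d_eq at the z extremes: z_max -> sigma, z_min -> maxdist
  imax <- which.max(z[cbind(rs$i + 1, rs$j + 1)])
  if (rs$kind[imax] == "harmonic" && z[rs$i[imax] + 1, rs$j[imax] + 1] == zr[2]) {
    expect_equal(rs$d_eq[imax], p$sigma)
  }
  expect_true(all(rs$d_eq >= p$sigma & rs$d_eq <= p$maxdist))
  expect_equal(rs$k_max, 10 / rs$L)
})

test_that("encoding is monotone in the cutoffs and d_eq non-increasing in z", {
  set.seed(5)
  z <- matrix(NA_real_, 12, 12)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  z[ut] <- stats::rnorm(nrow(ut))
  n_h <- function(uf) sum(encode_restraints(
    z, modeling_params(lowfreq = -2, upfreq = uf, maxdist = 300))$kind == "harmonic")
  n_l <- function(lf) sum(encode_restraints(
    z, modeling_params(lowfreq = lf, upfreq = 2, maxdist = 300))$kind == "lower_bound")
  expect_true(all(diff(vapply(c(-1, -0.5, 0, 0.5), n_h, numeric(1))) <= 0))
  expect_true(all(diff(vapply(c(-1, -0.5, 0, 0.5), n_l, numeric(1))) >= 0))
  rs <- encode_restraints(z, modeling_params(lowfreq = 0, upfreq = 0,
                                             maxdist = 300))
  zv <- z[cbind(rs$i + 1, rs$j + 1)]
  ord <- order(zv)
  expect_true(all(diff(rs$d_eq[ord]) <= 1e-9))

  # middle z with a gap between cutoffs -> no restraint
  z2 <- matrix(NA_real_, 6, 6)
  z2[1, 3] <- 0; z2[1, 4] <- 2; z2[2, 5] <- -2; z2[3, 6] <- 1
  p2 <- modeling_params(lowfreq = -0.5, upfreq = 0.5, maxdist = 300)
  rs2 <- encode_restraints(z2, p2)
  expect_false(any(rs2$i == 0 & rs2$j == 2))

  # no restraints at all -> error reporting the cutoffs
  z3 <- matrix(NA_real_, 6, 6); z3[1, 3] <- 0; z3[2, 4] <- 0.1
  expect_error(encode_restraints(z3, modeling_params(lowfreq = -5, upfreq = 5,
                                                     maxdist = 300)),
               "lowfreq")
})

test_that("flat d_eq variant pins harmonic at sigma and lower bound at maxdist", {
  set.seed(6)
  z <- matrix(NA_real_, 8, 8)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  z[ut] <- stats::rnorm(nrow(ut), sd = 2)
  p <- modeling_params(lowfreq = -0.5, upfreq = 0.5, maxdist = 400,
                       flat_deq = TRUE)
  rs <- encode_restraints(z, p)
  expect_true(all(rs$d_eq[rs$kind == "harmonic"] == 50))
  expect_true(all(rs$d_eq[rs$kind == "lower_bound"] == 400))
})

test_that("initial conformations are reproducible self-avoiding chains", {
  x1 <- init_conformation(40, seed = 3)
  x2 <- init_conformation(40, seed = 3)
  expect_identical(x1, x2)
  x3 <- init_conformation(40, seed = 4)
  expect_false(identical(x1, x3))

  # N = 2: two beads near one diameter apart (post-minimization)
  x <- init_conformation(2, seed = 1)
  expect_equal(sqrt(sum((x[1, ] - x[2, ])^2)) / 50, 1, tolerance = 0.1)

  # hard core holds after minimization across many seeds
  min_d <- vapply(1:50, function(s) {
    x <- init_conformation(100, seed = s) / 50
    min(dist(x))
  }, numeric(1))
  expect_true(all(min_d >= 0.8))
})

test_that("steered dynamics drives pairs to their restraint targets", {
  sched <- steering_schedule(total_steps = 1500)
  # single harmonic at one diameter on a 2-bead chain: median final distance
  # within 10% of 50 nm over 20 seeds
  rs <- data.frame(i = 0L, j = 1L, kind = "harmonic", d_eq = 50,
                   k_max = 5, L = 1L)
  d_end <- vapply(1:20, function(s) {
    x0 <- init_conformation(2, seed = s)
    out <- steer_dynamics(x0, rs, sched, seed = s)
    sqrt(sum((out$coords[1, ] - out$coords[2, ])^2))
  }, numeric(1))
  expect_lt(abs(median(d_end) - 50) / 50, 0.1)

  # lower bound at 300 nm on a 12-bead chain's ends. A one-sided harmonic
  # leaves thermal mass just below d_eq, so the end state is asserted at the
  # restraint's own satisfaction tolerance: median at the target, every seed
  # within one diameter, and far beyond the free-chain baseline (~150 nm).
  sched2 <- steering_schedule(total_steps = 3000)
  rs2 <- data.frame(i = 0L, j = 11L, kind = "lower_bound", d_eq = 300,
                    k_max = 5, L = 11L)
  d_lb <- vapply(1:20, function(s) {
    x0 <- init_conformation(12, seed = 100 + s)
    out <- steer_dynamics(x0, rs2, sched2, seed = 100 + s)
    sqrt(sum((out$coords[1, ] - out$coords[12, ])^2))
  }, numeric(1))
  expect_gte(median(d_lb), 300)
  expect_gte(mean(d_lb >= 250), 0.9)
  # and the satisfaction field reflects the 2-sigma tolerance rule
  x0 <- init_conformation(12, seed = 101)
  out <- steer_dynamics(x0, rs2, sched2, seed = 101)
  d <- sqrt(sum((out$coords[1, ] - out$coords[12, ])^2))
  expect_equal(out$satisfaction, as.numeric(d >= 300 - 100))
})

test_that("identical seeds give identical trajectories", {
  rs <- data.frame(i = 0L, j = 5L, kind = "harmonic", d_eq = 100,
                   k_max = 2, L = 5L)
  sched <- steering_schedule(total_steps = 500)
  x0 <- init_conformation(8, seed = 9)
  a <- steer_dynamics(x0, rs, sched, seed = 42)
  b <- steer_dynamics(x0, rs, sched, seed = 42)
  expect_identical(a$coords, b$coords)
  c0 <- steer_dynamics(x0, rs, sched, seed = 43)
  expect_false(identical(a$coords, c0$coords))
})

test_that("without restraints the chain behaves as a free polymer", {
  # zero restraints: end-to-end distance distribution indistinguishable from
  # an unrestrained reference run (same engine, empty restraint set)
  rs0 <- data.frame(i = integer(0), j = integer(0), kind = character(0),
                    d_eq = numeric(0), k_max = numeric(0), L = integer(0))
  sched <- steering_schedule(total_steps = 800)
  ree <- function(seed_base) vapply(1:15, function(s) {
    x0 <- init_conformation(20, seed = seed_base + s)
    out <- steer_dynamics(x0, rs0, sched, seed = seed_base + s)
    sqrt(sum((out$coords[1, ] - out$coords[20, ])^2))
  }, numeric(1))
  a <- ree(0); b <- ree(500)
  expect_gt(ks_two_sample(a, b)$p_value, 0.01)
})

test_that("ensembles are reproducible and carry restraint satisfaction", {
  spec <- toy_genome_spec(n_particles = 40, tad_sizes = c(15, 25),
                          n_ensemble = 10, noise = 0)
  toy <- generate_toy_genome(spec, seed = 7)
  m <- distance_law_matrix(toy$ensemble)
  p <- modeling_params(lowfreq = -0.5, upfreq = 0, maxdist = 300,
                       n_models = 3, n_steps = 800)
  e1 <- build_ensemble(m, p, seed0 = 5)
  e2 <- build_ensemble(m, p, seed0 = 5)
  expect_identical(e1$coords, e2$coords)
  expect_equal(n_models(e1), 3)
  expect_true(all(e1$satisfaction > 0 & e1$satisfaction <= 1))
  # sane params give positive map-vs-input agreement
  expect_gt(matrix_spearman(contact_map(e1, 200), m), 0)
})

test_that("majority retention warns when restraints are unsatisfiable", {
  # near-diagonal pairs (|i-j| in 2..3) get the smallest values, so they all
  # become lower bounds with d_eq near maxdist = 500 nm; chain connectivity
  # caps their separation at ~3 sigma = 150 nm, far below d_eq - 2 sigma
  set.seed(2)
  v <- matrix(0, 30, 30)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  sep <- abs(ut[, 1] - ut[, 2])
  vals <- stats::runif(nrow(ut), 0.5, 1)
  vals[sep <= 3] <- stats::runif(sum(sep <= 3), 1e-4, 2e-4)
  v[ut] <- vals
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  m <- interaction_matrix(v, 5000, stage = "norm")
  p <- modeling_params(lowfreq = 0, upfreq = 9, maxdist = 500,
                       n_models = 4, n_steps = 300)
  expect_warning(build_ensemble(m, p, seed0 = 1,
                                retention = "majority_satisfied"),
                 "satisfy")
})

test_that("grid enumeration covers the full parameter product", {
  combos <- grid_search_combos()
  expect_equal(nrow(combos), 64)
  expect_equal(nrow(unique(combos)), 64)
  single <- grid_search_combos(lowfreq = -0.5, upfreq = 0, maxdist = 300)
  expect_equal(nrow(single), 1)
})

test_that("grid search ranks an engineered-optimal combination first", {
  spec <- toy_genome_spec(n_particles = 50, tad_sizes = c(20, 30),
                          n_ensemble = 10, noise = 0)
  toy <- generate_toy_genome(spec, seed = 12)
  m <- distance_law_matrix(toy$ensemble)
  gs <- grid_search(m, lowfreq = c(-0.5), upfreq = c(0, 5),
                    maxdist = c(300), dcutoffs = c(200),
                    n_models = 3, seed0 = 2, n_steps = 800)
  # upfreq = 5 yields (almost) no harmonic restraints: must rank below
  expect_equal(gs$upfreq[1], 0)
  expect_true(all(diff(gs$correlation) <= 0 | is.na(diff(gs$correlation))))
})

test_that("mirror filtering keeps the majority enantiomer", {
  base <- random_conformation(25, seed = 3)
  mirror <- base %*% diag(c(1, 1, -1))
  jitter <- function(x, s) { set.seed(s); x + matrix(rnorm(length(x), 0, 1), nrow(x)) }
  e <- ensemble_from_models(list(jitter(base, 1), jitter(base, 2),
                                 jitter(base, 3), jitter(mirror, 4)),
                            satisfaction = c(0.9, 0.9, 0.9, 0.99))
  kept <- mirror_filter(e)
  expect_equal(n_models(kept), 3)
  # the kept models are the unmirrored ones
  expect_lt(sparsefold:::cpp_kabsch_rmsd(kept$coords[1, , ], base), 5)

  # all-identical models -> all retained
  e2 <- ensemble_from_models(list(base, base, base))
  expect_equal(n_models(mirror_filter(e2)), 3)

  # rotated copies of one model -> all retained
  rots <- lapply(1:4, function(s) base %*% random_rotation(s))
  e3 <- ensemble_from_models(rots)
  expect_equal(n_models(mirror_filter(e3)), 4)
})
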