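test_that("equal-volume shells have the n^(1/3) radii", {
  r <- shell_radii(200, 560)
  expect_equal(r[1], 200)
  expect_equal(r[2], 200 * 2^(1 / 3))  # ~251.98 nm
  expect_true(all(diff(r) > 0))
  # every shell's volume equals the initial sphere's volume
  vols <- diff(c(0, r^3)) * 4 / 3 * pi
  expect_equal(vols / vols[1], rep(1, length(r)), tolerance = 1e-9)
  expect_true(max(r) <= 560)
})

test_that("Fisher enrichment agrees with hypergeometric enumeration", {
  # oracle: exact two-sided p by enumerating the hypergeometric support
  fisher_oracle <- function(a, b, c0, d0) {
    m <- a + c0; n <- b + d0; k <- a + b
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p0 <- dhyper(a, m, n, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
  }
  set.seed(14)
  for (rep in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c0 <- sample(0:12, 1); d0 <- sample(0:12, 1)
    if (a + b == 0 || c0 + d0 == 0 || a + c0 == 0 || b + d0 == 0) next
    tab <- matrix(c(a, c0, b, d0), 2)
    expect_equal(fisher.test(tab)$p.value, fisher_oracle(a, b, c0, d0),
                 tolerance = 1e-9,
                 info = paste(a, b, c0, d0))
  }
  # the worked table [[8,2],[2,8]]: OR 16, two-sided P ~ 0.023 -> neutral
  p <- fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value
  expect_equal(p, fisher_oracle(8, 2, 2, 8), tolerance = 1e-9)
  expect_gt(p, 0.01)
  expect_equal((8 * 8) / (2 * 2), 16)
})

test_that("radial enrichment flags a planted shell-bound feature", {
  # viewpoint at origin; feature particles planted inside the first shell
  set.seed(21)
  n <- 60
  mods <- lapply(1:25, function(s) {
    set.seed(s)
    x <- matrix(rnorm(n * 3, 0, 300), n, 3)
    x[1, ] <- 0                       # viewpoint
    x[2:16, ] <- matrix(rnorm(45, 0, 60), 15, 3)  # inside ~200 nm
    x
  })
  e <- ensemble_from_models(mods)
  feat <- structure(list(name = "H3K27ac",
                         present = c(FALSE, rep(TRUE, 15), rep(FALSE, n - 16))),
                    class = "mark_profile")
  out <- radial_enrichment(e, viewpoint = 0L, profiles = list(feat),
                           r0 = 200, r_max = 560)
  first <- out[out$shell == 1 & out$feature == "H3K27ac", ]
  expect_true(first$enriched)
  expect_gt(first$log_odds, 0)
  # a feature on every particle gives degenerate tables -> no enrichment
  all_on <- structure(list(name = "ubiq", present = rep(TRUE, n)),
                      class = "mark_profile")
  out2 <- radial_enrichment(e, 0L, list(all_on))
  expect_false(any(out2$enriched))
  expect_true(all(out2$note == "degenerate"))
})

test_that("expression profiles accumulate mean expression at the TSS bin", {
  region <- list(chrom = "chr11", start = 0, end = 50000)
  genes <- data.frame(
    gene_id = c("g0", "g1", "g2", "g3", "g4"),
    chrom = c("chr11", "chr11", "chr11", "chr11", "chr2"),
    tss = c(1000, 2000, 12000, 30000, 5000),
    log_fpkm_r1 = c(1, 2, 2, 0, 3),
    log_fpkm_r2 = c(1, 2, 4, 0, 3))
  expect_message(ep <- expression_profile(genes, region, 5000), "dropped")
  # g0 (1) and g1 (2) share bin 0 -> cumulative 3
  expect_equal(ep$value[1], 3)
  # g2 averaged over replicates: mean(2, 4) = 3
  expect_equal(ep$value[3], 3)
  # g3 has log(FPKM) = 0 -> excluded (strict > 0)
  expect_equal(ep$value[7], 0)
  expect_equal(ep$expressed, ep$value > 0)
  expect_equal(ep$genes[[1]], c("g0", "g1"))
})

test_that("mark profiles binarize peak overlap per bin", {
  bins <- genomic_bins("chr1", 0, 4, 5000)
  peaks <- data.frame(chrom = "chr1", start = c(1000, 9999), end = c(1200, 10001))
  mp <- mark_profile(peaks, bins, name = "H3K4me3")
  expect_equal(mp$present, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("Calinski-Harabasz from distances matches the worked 1D case", {
  x <- c(0, 0.1, 10, 10.1)
  d <- dist(x)
  ch <- calinski_harabasz(d, c(1, 1, 2, 2))
  expect_equal(ch, 20000)
  # agrees with the coordinate-space definition on random 3D data
  set.seed(3)
  y <- rbind(matrix(rnorm(30), 10, 3), matrix(rnorm(30, 5), 10, 3))
  lab <- rep(1:2, each = 10)
  bss_wss <- function(y, lab) {
    n <- nrow(y); k <- 2
    ctr <- colMeans(y)
    wss <- sum(vapply(split.data.frame(y, lab), function(g)
      sum(sweep(g, 2, colMeans(g))^2), numeric(1)))
    tss <- sum(sweep(y, 2, ctr)^2)
    ((tss - wss) / (k - 1)) / (wss / (n - k))
  }
  expect_equal(calinski_harabasz(dist(y), lab), bss_wss(y, lab),
               tolerance = 1e-9)
})

test_that("well-separated communities are recovered with full co-occurrence", {
  # rigid blobs: identical positions in every model
  pl <- planted_community_ensemble(seed = 2, spread = 0)
  expr <- rep(1, 15)  # all particles expressed
  cs <- detect_communities(pl$e, expr)
  expect_equal(cs$n_communities, 3)
  expect_equal(adjusted_rand(cs$communities, pl$truth), 1)
  for (c0 in 1:3) {
    sel <- pl$truth == c0
    expect_true(all(cs$cooccurrence[sel, sel] == 100))
  }
  expect_true(all(diag(cs$cooccurrence) == 100))
  expect_true(all(cs$cooccurrence >= 0 & cs$cooccurrence <= 100))
  expect_equal(cs$cooccurrence, t(cs$cooccurrence))
})

test_that("community detection recovers planted structure across seeds", {
  ari <- vapply(1:20, function(s) {
    pl <- planted_community_ensemble(seed = s, n_models = 12, spread = 8)
    cs <- detect_communities(pl$e, rep(1, 15))
    adjusted_rand(cs$communities, pl$truth)
  }, numeric(1))
  expect_gte(mean(ari >= 0.9), 1)  # every seed recovers the partition
})

test_that("community detection validates its inputs", {
  pl <- planted_community_ensemble(seed = 1, n_models = 12)
  expect_error(detect_communities(pl$e, c(1, 1, rep(0, 13))), "3 expressed")
  small <- subset_models(pl$e, 1:5)
  expect_error(detect_communities(small, rep(1, 15)), "10 models")
})

test_that("stability scores equal hand-computed inter-community means", {
  # planted co-occurrence: 3 communities with known cross values
  co <- matrix(0, 6, 6)
  lab <- c(1, 1, 2, 2, 3, 3)
  co[lab == 1, lab == 2] <- 40; co[lab == 2, lab == 1] <- 40
  co[lab == 1, lab == 3] <- 20; co[lab == 3, lab == 1] <- 20
  co[lab == 2, lab == 3] <- 10; co[lab == 3, lab == 2] <- 10
  diag(co) <- 100
  cs <- structure(list(particles = 0:5, cooccurrence = co, communities = lab,
                       n_communities = 3, expression = rep(1, 6)),
                  class = "community_set")
  st <- community_stability(cs)
  expect_equal(unname(st$per_community), c((40 + 20) / 2, (40 + 10) / 2,
                                           (20 + 10) / 2))
  expect_equal(st$per_cell, mean(st$per_community))

  # perfectly segregated -> 0; uniform 50 -> 50
  co0 <- co; co0[co0 != 100] <- 0
  cs0 <- cs; cs0$cooccurrence <- co0
  expect_equal(unname(community_stability(cs0)$per_community), c(0, 0, 0))
  co50 <- co; co50[co50 != 100] <- 50
  cs50 <- cs; cs50$cooccurrence <- co50
  expect_equal(community_stability(cs50)$per_cell, 50)

  cs1 <- cs; cs1$n_communities <- 1; cs1$communities <- rep(1, 6)
  expect_error(community_stability(cs1), "single community")
})

test_that("community geometry measures COM distances and gradients", {
  # two point-communities at fixed distance in all models
  mods <- lapply(1:12, function(m) rbind(matrix(0, 3, 3),
                                         matrix(c(600, 0, 0), 3, 3,
                                                byrow = TRUE)))
  e <- ensemble_from_models(mods)
  cs <- structure(list(particles = 0:5, communities = rep(1:2, each = 3),
                       n_communities = 2, expression = rep(1, 6),
                       cooccurrence = diag(6) * 100),
                  class = "community_set")
  geom <- community_geometry(e, cs)
  expect_equal(geom$com_distances[1, 2], 600)
  expect_equal(unname(geom$within_distance), rep(0, 6))

  # planted expression gradient: expression falls with distance from COM
  pl <- planted_community_ensemble(seed = 6, n_models = 15, spread = 1)
  csd <- detect_communities(pl$e, rep(1, 15))
  g0 <- community_geometry(pl$e, csd)
  expr <- max(g0$within_distance) - g0$within_distance  # exact anti-gradient
  csd$expression <- expr
  g1 <- community_geometry(pl$e, csd)
  expect_lt(g1$gradient_cor, -0.99)
  expect_lt(g1$gradient_p, 0.01)
})
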