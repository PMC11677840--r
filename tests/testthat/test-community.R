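# naive double-loop distance oracles
naive_dist <- function(x, metric) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- x[i, ]; b <- x[j, ]
      d[i, j] <- switch(metric,
        bray_curtis = if (sum(a + b) == 0) 0
                      else sum(abs(a - b)) / sum(a + b),
        sorensen = {
          pa <- a > 0; pb <- b > 0
          if (sum(pa) + sum(pb) == 0) 0
          else 1 - 2 * sum(pa & pb) / (sum(pa) + sum(pb))
        },
        euclidean = sqrt(sum((a - b)^2)))
    }
  }
  d
}

test_that("distance metrics match naive double-loop oracles", {
  set.seed(10)
  x <- matrix(rpois(24, 4), nrow = 6)
  cm <- small_community(x)
  for (metric in c("bray_curtis", "sorensen", "euclidean")) {
    dm <- distance_matrix(cm, metric)
    expect_equal(unname(dm$d), naive_dist(x, metric), tolerance = 1e-12)
    expect_equal(diag(dm$d), setNames(rep(0, 6), cm$traps))
    expect_true(isSymmetric(dm$d))
  }
})

test_that("distance edge cases behave as defined", {
  x <- rbind(c(3, 1, 0), c(3, 1, 0), c(0, 0, 5), c(1, 1, 1))
  dm <- distance_matrix(small_community(x), "bray_curtis")
  expect_equal(unname(dm$d[1, 2]), 0)           # identical rows
  so <- distance_matrix(small_community(x), "sorensen")
  expect_equal(unname(so$d[1, 3]), 1)           # disjoint presence
  zz <- rbind(c(0, 0), c(0, 0), c(1, 2), c(3, 1))
  expect_warning(dz <- distance_matrix(small_community(zz), "bray_curtis"),
                 "all-zero")
  expect_equal(unname(dz$d[1, 2]), 0)
  expect_error(distance_matrix(small_community(x[1, , drop = FALSE],
                                               treatment = "control",
                                               block = "B01")),
               "2 traps")
})

test_that("PCoA recovers closed-form and Euclidean geometry", {
  # two points at distance d embed at +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2)
  dm <- structure(list(d = d2, labels = c("a", "b"), metric = "euclidean"),
                  class = "distance_matrix")
  p <- pcoa(dm)
  expect_equal(ncol(p$coordinates), 1)
  expect_equal(sort(unname(p$coordinates[, 1])), c(-1.5, 1.5))

  # round trip: Euclidean distances of random planar points are preserved
  set.seed(3)
  pts <- matrix(runif(20), ncol = 2)
  cm <- community_matrix(pts, block = rep("B01", 10),
                         treatment = rep("control", 10))
  dm2 <- distance_matrix(cm, "euclidean")
  p2 <- pcoa(dm2)
  rec <- as.matrix(dist(p2$coordinates))
  expect_equal(unname(rec), unname(dm2$d), tolerance = 1e-9)
  expect_equal(p2$eigenvalues, sort(p2$eigenvalues, decreasing = TRUE))

  # all points identical: no positive eigenvalues
  same <- matrix(2, nrow = 5, ncol = 3)
  cms <- community_matrix(same, block = rep("B01", 5),
                          treatment = rep("control", 5))
  p3 <- suppressWarnings(pcoa(distance_matrix(cms, "euclidean")))
  expect_true(all(abs(p3$eigenvalues) < 1e-9))
  expect_equal(ncol(p3$coordinates), 0)
  expect_warning(pcoa(dm2, n_axes = 50), "truncating")
})

test_that("MRPP separates tight clusters and reports the p floor", {
  # clusters of 8 duplicated rows: the chance that a random permutation
  # reconstructs the split (tying delta at 0) is ~1e-5, so the add-one
  # floor 1/(1+n) is attained
  x <- rbind(matrix(c(1, 0, 0), 8, 3, byrow = TRUE),
             matrix(c(0, 0, 9), 8, 3, byrow = TRUE))
  cm <- community_matrix(x, block = rep("B01", 16),
                         treatment = rep(c("a", "b"), each = 8))
  dm <- distance_matrix(cm, "euclidean")
  res <- mrpp(dm, cm$treatment, n_permutations = 99, seed = 1)
  expect_equal(res$delta_observed, 0)
  expect_equal(res$A, 1)
  expect_equal(res$p, 1 / 100)
  expect_lte(res$A, 1)
  expect_gt(res$p, 0)
})

test_that("MRPP matches the exhaustive label-split oracle on 6 items", {
  set.seed(20)
  x <- matrix(rpois(18, 5), nrow = 6)
  cm <- community_matrix(x, block = rep("B01", 6),
                         treatment = rep(c("a", "b"), each = 3))
  dm <- distance_matrix(cm, "bray_curtis")
  g <- cm$treatment
  # exhaustive null: all 20 assignments of 3 labels 'a' among 6 items
  combs <- combn(6, 3)
  deltas <- apply(combs, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    within_means <- vapply(c("a", "b"), function(l) {
      sub <- dm$d[gg == l, gg == l]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    sum(within_means * 0.5)
  })
  obs <- deltas[1]  # first combination is the observed grouping 1,2,3
  exact_exp <- mean(deltas)
  exact_p <- mean(deltas <= obs)
  res <- mrpp(dm, g, n_permutations = 20000, seed = 4)
  expect_equal(res$delta_observed, obs, tolerance = 1e-12)
  expect_equal(res$delta_expected, exact_exp, tolerance = 0.01)
  expect_equal(res$p, exact_p, tolerance = 0.02)
})

test_that("MRPP agrees with an independent implementation", {
  set.seed(12)
  cfg <- simulation_config(seed = 12, n_blocks = 5)
  cm <- simulate_community(cfg)
  dm <- distance_matrix(cm, "bray_curtis")
  ours <- mrpp(dm, cm$treatment, n_permutations = 999, seed = 2)
  ref <- vegan::mrpp(as.dist(dm$d), cm$treatment, permutations = 999,
                     weight.type = 1)
  expect_equal(ours$delta_observed, ref$delta, tolerance = 1e-12)
  expect_lt(abs(ours$A - (1 - ref$delta / ref$E.delta)), 0.02)
})

test_that("A is near zero under random grouping", {
  set.seed(5)
  a_vals <- vapply(1:200, function(i) {
    cfg <- simulation_config(seed = 3000 + i, n_blocks = 5)
    cm <- simulate_community(cfg)
    dm <- distance_matrix(cm, "bray_curtis")
    mrpp(dm, cm$treatment, n_permutations = 60, seed = i)$A
  }, numeric(1))
  expect_lt(abs(mean(a_vals)), 0.02)
})

test_that("MRPP detects a strong single-taxon treatment effect", {
  set.seed(6)
  hits <- vapply(1:30, function(i) {
    cfg <- simulation_config(
      seed = 5000 + i, n_blocks = 5,
      community_taxon_means = c(t1 = 20, t2 = 15, t3 = 10),
      community_effect = list(control = 1, fungi = 5, halfmix = 1,
                              nematodes = 1))
    cm <- simulate_community(cfg)
    dm <- distance_matrix(cm, "bray_curtis")
    mrpp(dm, cm$treatment, n_permutations = 199, seed = i)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("MRPP refuses degenerate groupings", {
  cm <- small_community(matrix(rpois(12, 3), 4))
  dm <- distance_matrix(cm, "euclidean")
  expect_error(mrpp(dm, c("a", "a", "a", "b"), 99, 1), "singleton")
  expect_error(mrpp(dm, rep("a", 4), 99, 1), "2 groups")
  zero <- community_matrix(matrix(0, 4, 2), block = rep("B01", 4),
                           treatment = rep(c("a", "b"), 2))
  dz <- suppressWarnings(distance_matrix(zero, "euclidean"))
  rz <- mrpp(dz, rep(c("a", "b"), 2), 49, 1)
  expect_equal(rz$A, 0)
  expect_equal(rz$p, 1)
})

test_that("one-way ANOVA matches its classical identities", {
  # identical group means give F = 0
  r0 <- oneway_anova(c(1, 3, 0, 4), c("a", "a", "b", "b"))
  expect_equal(r0$F, 0)
  # two-group F equals the squared pooled-variance t statistic
  set.seed(2)
  x <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  res <- oneway_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 10)
})

test_that("one-way ANOVA holds its nominal size under the null", {
  set.seed(8)
  rej <- mean(vapply(1:2000, function(i) {
    x <- rnorm(20)
    oneway_anova(x, rep(c("a", "b", "c", "d"), each = 5))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("richness and abundance match naive loops", {
  x <- rbind(c(3, 0, 1), c(0, 0, 0), c(2, 2, 2))
  cm <- community_matrix(x, block = rep("B01", 3),
                         treatment = c("a", "b", "c"))
  ra <- richness_abundance(cm)
  expect_equal(ra$abundance, c(4, 0, 6))
  expect_equal(ra$richness, c(2, 0, 3))
  set.seed(13)
  y <- matrix(rpois(50, 2), 10)
  cm2 <- community_matrix(y, block = rep("B01", 10),
                          treatment = rep("a", 10))
  ra2 <- richness_abundance(cm2)
  for (i in 1:10) {
    ab <- 0; ri <- 0
    for (j in seq_len(ncol(y))) {
      ab <- ab + y[i, j]
      if (y[i, j] > 0) ri <- ri + 1
    }
    expect_equal(ra2$abundance[i], ab)
    expect_equal(ra2$richness[i], ri)
  }
})
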