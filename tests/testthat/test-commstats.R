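test_that("bray_curtis matches hand computations and boundary cases", {
  expect_equal(bray_curtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 0), c(1, 0, 0)), "length")
})

test_that("Bray-Curtis on counts equals proportions only for equal row sums", {
  x <- c(4, 6); y <- c(2, 8)           # equal totals
  expect_equal(bray_curtis(x, y), bray_curtis(x / 10, y / 10))
  x2 <- c(4, 6); y2 <- c(10, 40)       # unequal totals
  expect_false(isTRUE(all.equal(bray_curtis(x2, y2),
                                bray_curtis(x2 / 10, y2 / 50))))
})

test_that("distance_matrix agrees with brute force and with vegan", {
  p <- rbind(S1 = c(0.5, 0.5), S2 = c(1, 0), S3 = c(0.1, 0.9))
  colnames(p) <- c("VT1", "VT2")
  d <- as.matrix(distance_matrix(p))
  for (i in 1:3) for (j in 1:3)
    expect_equal(d[i, j], if (i == j) 0 else bray_curtis(p[i, ], p[j, ]))
  set.seed(11)
  X <- matrix(runif(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("v", 1:6)))
  X <- X / rowSums(X)
  expect_equal(as.numeric(distance_matrix(X)),
               as.numeric(vegan::vegdist(X, "bray")))
  # row permutation permutes the matrix consistently
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  d1 <- as.matrix(distance_matrix(X))
  d2 <- as.matrix(distance_matrix(X[perm, ]))
  expect_equal(d2, d1[perm, perm])
})

test_that("rarefied_richness matches hand values and vegan::rarefy", {
  counts <- c(9, 1)
  expect_equal(rarefied_richness(counts, 1), 1.0)
  expect_equal(rarefied_richness(c(2, 2), 2), 5 / 3)
  expect_equal(rarefied_richness(c(5, 3, 2, 0), 10), 3)  # n = N: observed
  cc <- c(12, 7, 3, 1, 1, 0, 25)
  for (n in c(1, 5, 20, 49))
    expect_equal(rarefied_richness(cc, n),
                 as.numeric(vegan::rarefy(matrix(cc, 1), n)))
  expect_error(rarefied_richness(cc, 0), "out of range")
  expect_error(rarefied_richness(cc, sum(cc) + 1), "out of range")
})

test_that("rarefied_richness equals the empirical subsampling mean", {
  counts <- c(6, 3, 1)
  n <- 4
  set.seed(21)
  pool <- rep(seq_along(counts), counts)
  emp <- mean(replicate(10000,
                        length(unique(sample(pool, n)))))
  expect_lt(abs(emp - rarefied_richness(counts, n)), 0.02)
})

test_that("rarefaction curves are monotone and hit observed richness at full depth", {
  counts <- rbind(S1 = c(6, 3, 1, 0), S2 = c(2, 2, 2, 4))
  colnames(counts) <- paste0("VT", 1:4)
  m <- community_matrix(counts, mode = "counts")
  cur <- rarefaction_curve(m, depths = c(1, 3, 5, 10))
  expect_true(all(diff(cur$richness) >= -1e-12))
  expect_lte(cur$richness[cur$depth == 1], 1 + 1e-9)
  # at the shared maximum depth the curve equals mean observed richness
  at10 <- cur$richness[cur$depth == 10]
  expect_equal(at10, mean(c(3, 4)))
  expect_error(rarefaction_curve(m, samples = character(0), depths = 5),
               "empty")
})

test_that("PERMANOVA reproduces the two-group hand example via the Gower identity", {
  D <- matrix(c(0, 1, 2, 2,
                1, 0, 2, 2,
                2, 2, 0, 1,
                2, 2, 1, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  pv <- permanova(stats::as.dist(D),
                  data.frame(g = c("a", "a", "b", "b"),
                             row.names = paste0("s", 1:4)),
                  n_perm = 99, seed = 1)
  tab <- pv$table
  expect_equal(tab["Total", "SS"], 4.5)
  expect_equal(tab["g", "SS"], 3.5)
  expect_equal(tab["g", "pseudo_F"], 7)
  expect_equal(tab["g", "R2"], 7 / 9)
  expect_equal(tab["Total", "Df"], 3)
  expect_gt(tab["g", "p_perm"], 0)
})

test_that("PERMANOVA pseudo-F equals the classical ANOVA F on 1-D Euclidean data", {
  set.seed(13)
  y <- c(rnorm(6, 0), rnorm(5, 1.2), rnorm(7, -0.5))
  g <- factor(rep(c("a", "b", "c"), c(6, 5, 7)))
  names(y) <- paste0("s", seq_along(y))
  D <- as.matrix(stats::dist(y))
  pv <- permanova(stats::as.dist(D),
                  data.frame(g = g, row.names = names(y)), n_perm = 0)
  f_classic <- anova(stats::lm(y ~ g))[1, "F value"]
  expect_equal(pv$table["g", "pseudo_F"], f_classic)
})

test_that("sequential two-factor PERMANOVA matches vegan::adonis2", {
  set.seed(14)
  X <- matrix(rpois(17 * 6, 6), 17, 6,
              dimnames = list(paste0("s", 1:17), paste0("v", 1:6)))
  X <- X / rowSums(X)
  meta <- data.frame(a = factor(sample(c("u", "v"), 17, TRUE)),
                     b = factor(sample(c("x", "y", "z"), 17, TRUE)),
                     row.names = rownames(X))
  d <- distance_matrix(X)
  pv <- permanova(d, meta, n_perm = 0)
  av <- vegan::adonis2(d ~ a + b, data = meta, permutations = 0,
                       by = "terms")
  expect_equal(pv$table[c("a", "b"), "SS"], av$SumOfSqs[1:2],
               tolerance = 1e-10)
  expect_equal(pv$table[c("a", "b"), "pseudo_F"], av$F[1:2],
               tolerance = 1e-10)
  expect_equal(pv$table[c("a", "b"), "R2"], av$R2[1:2], tolerance = 1e-10)
  # table invariants
  expect_equal(sum(pv$table[c("a", "b", "Residuals"), "SS"]),
               pv$table["Total", "SS"])
  expect_equal(sum(pv$table[c("a", "b", "Residuals"), "Df"]),
               pv$table["Total", "Df"])
  expect_lte(sum(pv$table[c("a", "b"), "R2"]), 1)
  # adding a factor never increases residual SS
  pv1 <- permanova(d, meta["a"], n_perm = 0)
  expect_lte(pv$table["Residuals", "SS"], pv1$table["Residuals", "SS"])
})

test_that("PERMANOVA rejects degenerate and under-determined inputs", {
  D0 <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_error(permanova(stats::as.dist(D0),
                         data.frame(g = c("a", "a", "b", "b"),
                                    row.names = paste0("s", 1:4))),
               "degenerate")
  D <- as.matrix(stats::dist(1:4)); dimnames(D) <- dimnames(D0)
  expect_error(permanova(stats::as.dist(D),
                         data.frame(g = rep("a", 4),
                                    row.names = paste0("s", 1:4))),
               "single level")
  expect_error(permanova(stats::as.dist(D),
                         data.frame(g = c("a", "b", "c", "d"),
                                    row.names = paste0("s", 1:4))),
               "residual")
})

test_that("dispersion test matches a 2-D hand computation and betadisper", {
  # one tight, one dispersed group with known planar coordinates
  xy <- rbind(c(0, 0), c(1, 0), c(0.5, 0.9),
              c(10, 0), c(16, 0), c(13, 5), c(13, -5))
  rownames(xy) <- paste0("s", 1:7)
  g <- factor(c("t", "t", "t", "d", "d", "d", "d"))
  D <- stats::dist(xy)
  dt <- dispersion_test(D, stats::setNames(g, rownames(xy)))
  # distances to centroid computed directly in the plane
  cen <- apply(xy, 2, function(col) tapply(col, g, mean))
  dd <- sqrt(rowSums((xy - cen[as.character(g), ])^2))
  expect_equal(unname(dt$distances), unname(dd), tolerance = 1e-8)
  f_hand <- anova(stats::lm(dd ~ g))[1, "F value"]
  expect_equal(dt$F, f_hand, tolerance = 1e-8)
  expect_equal(c(dt$df1, dt$df2), c(1, 5))
  # cross-check on a semi-metric (Bray-Curtis) matrix
  set.seed(15)
  X <- matrix(rpois(27 * 8, 4), 27, 8,
              dimnames = list(paste0("s", 1:27), paste0("v", 1:8)))
  X <- X / rowSums(X)
  g2 <- factor(rep(c("a", "b", "c", "d"), c(8, 9, 6, 4)))
  d2 <- distance_matrix(X)
  dt2 <- dispersion_test(d2, stats::setNames(g2, rownames(X)))
  bd <- vegan::betadisper(d2, g2, type = "centroid")
  expect_equal(unname(dt2$distances), unname(bd$distances),
               tolerance = 1e-8)
  expect_equal(dt2$F, anova(bd)[1, "F value"], tolerance = 1e-8)
  expect_equal(c(dt2$df1, dt2$df2), c(3, 23))
})

test_that("dispersion F is near zero for groups with identical geometry", {
  # two congruent triangles far apart: same within-group spread
  xy <- rbind(c(0, 0), c(2, 0), c(1, 2),
              c(100, 0), c(102, 0), c(101, 2))
  rownames(xy) <- paste0("s", 1:6)
  g <- stats::setNames(factor(rep(c("a", "b"), each = 3)), rownames(xy))
  dt <- dispersion_test(stats::dist(xy), g)
  expect_lt(dt$F, 1e-10)
})

test_that("spatial-median dispersion option is computed and differs from centroid", {
  set.seed(16)
  X <- matrix(rpois(20 * 6, 4), 20, 6,
              dimnames = list(paste0("s", 1:20), paste0("v", 1:6)))
  X <- X / rowSums(X)
  g <- stats::setNames(factor(rep(c("a", "b"), each = 10)), rownames(X))
  d <- distance_matrix(X)
  dm <- dispersion_test(d, g, centre = "median")
  expect_true(is.finite(dm$F))
  dc <- dispersion_test(d, g, centre = "centroid")
  expect_false(isTRUE(all.equal(dm$distances, dc$distances)))
})

test_that("Poisson richness test matches the closed-form two-group deviance", {
  # identical groups: no deviance explained
  r0 <- poisson_richness_test(c(4, 4, 4, 4), c("a", "a", "b", "b"))
  expect_equal(r0$chi2, 0, tolerance = 1e-10)
  expect_equal(r0$p, 1, tolerance = 1e-8)
  # {2,2} vs {8,8}: chi2 = 2 * sum y log(y / y_hat) under the null fit
  y <- c(2, 2, 8, 8)
  g <- c("a", "a", "b", "b")
  rt <- poisson_richness_test(y, g)
  chi2_hand <- 2 * sum(y * log(y / mean(y)))
  expect_equal(rt$chi2, chi2_hand, tolerance = 1e-8)
  expect_equal(rt$df, 1)
  # log-link MLE: fitted group means are arithmetic means
  expect_equal(unname(rt$group_means), c(2, 8))
  expect_error(poisson_richness_test(c(1, 2), c("a", "a")), "2 groups")
})
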