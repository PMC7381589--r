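test_that("heterozygosity summaries match hand-computed values", {
  # dosages (0,1,2) at one SNP: Ho = 1/3, p = 0.5 so He = 0.5
  G <- toy_G(matrix(c(0, 1, 2), ncol = 1), deme = rep(1, 3))
  div <- diversity_summary(G, "deme")
  expect_equal(div$Ho, 1 / 3)
  expect_equal(div$He, 0.5)
  # monomorphic group: Ho = He = 0
  G0 <- toy_G(matrix(0, nrow = 3, ncol = 2), deme = rep(1, 3))
  div0 <- diversity_summary(G0, "deme")
  expect_equal(div0$Ho, 0)
  expect_equal(div0$He, 0)
})

test_that("private SNP counting agrees with brute-force categorisation", {
  set.seed(42)
  for (rep in 1:20) {
    X <- matrix(sample(0:2, 6 * 12, replace = TRUE), nrow = 6)
    G <- toy_G(X, deme = rep(c("A", "B"), each = 3))
    div <- diversity_summary(G, "deme")
    # independent category partition per SNP
    polyA <- apply(X[1:3, , drop = FALSE], 2, function(x) length(unique(x)) > 1 |
                     any(x == 1))
    polyB <- apply(X[4:6, , drop = FALSE], 2, function(x) length(unique(x)) > 1 |
                     any(x == 1))
    expect_equal(div$private_snps[div$group == "A"], sum(polyA & !polyB))
    expect_equal(div$private_snps[div$group == "B"], sum(polyB & !polyA))
    # partition: private A + private B + shared + monomorphic = all SNPs
    expect_equal(sum(polyA & !polyB) + sum(polyB & !polyA) +
                   sum(polyA & polyB) + sum(!polyA & !polyB), ncol(X))
    expect_equal(div$private_per_ind, div$private_snps / 3)
  }
})

test_that("Reich F_ST reproduces hand-evaluated cases", {
  # fixed difference: F = 1
  G <- toy_G(rbind(matrix(2, 3, 4), matrix(0, 3, 4)),
             deme = rep(c("A", "B"), each = 3))
  expect_equal(reich_fst(G, "deme")$fst["A", "B"], 1)

  # a1 = 8 of n1 = 10, a2 = 2 of n2 = 10: h = 16/90 each,
  # N = 0.36 - 2*(16/900), D = N + 32/90, F = 0.324444/0.68
  g1 <- c(2, 2, 2, 1, 1)
  g2 <- c(1, 1, 0, 0, 0)
  G2 <- toy_G(matrix(c(g1, g2), ncol = 1), deme = rep(c("A", "B"), each = 5))
  f <- reich_fst(G2, "deme")
  expect_equal(f$fst["A", "B"], (0.36 - 2 * 16 / 900) / 0.68, tolerance = 1e-12)
  expect_equal(f$num["A", "B"], 0.36 - 2 * 16 / 900, tolerance = 1e-12)
  expect_equal(f$den["A", "B"], 0.68, tolerance = 1e-12)

  # invariance under global reference/alternate swap
  set.seed(7)
  X <- matrix(sample(0:2, 8 * 30, replace = TRUE), nrow = 8)
  GA <- toy_G(X, deme = rep(c("A", "B"), each = 4))
  GB <- toy_G(2 - X, deme = rep(c("A", "B"), each = 4))
  expect_equal(reich_fst(GA, "deme")$fst, reich_fst(GB, "deme")$fst)
})

test_that("Reich F_ST is unbiased for two samples from one panmictic pool", {
  set.seed(2024)
  fhat <- vapply(1:300, function(i) {
    p <- runif(60, 0.05, 0.95)
    X <- matrix(rbinom(12 * 60, 2, rep(p, each = 12)), nrow = 12)
    G <- toy_G(X, deme = rep(c("A", "B"), each = 6))
    reich_fst(G, "deme")$fst["A", "B"]
  }, 0)
  se <- sd(fhat) / sqrt(length(fhat))
  expect_lt(abs(mean(fhat)), 3 * se)
})

test_that("between-range F_ST permutation test is exact on a maximal toy", {
  # range A: three identical demes (within-FST 0); range B: three demes fixed
  # for distinct patterns (within-FST 1). True assignment maximizes the
  # statistic; its complement ties it, so exhaustive p = 2/20
  base <- matrix(1, 2, 6)                     # demes 1-3: all heterozygous
  d4 <- matrix(c(2, 2, 0, 0, 2, 2, 0, 0, 2, 2, 0, 0), 2, 6)
  d5 <- matrix(c(0, 0, 2, 2, 2, 2, 0, 0, 0, 0, 2, 2), 2, 6)
  d6 <- matrix(c(2, 2, 2, 2, 0, 0, 2, 2, 0, 0, 0, 0), 2, 6)
  X <- rbind(base, base, base, d4, d5, d6)
  G <- toy_G(X, deme = rep(1:6, each = 2),
             range = rep(c("native", "introduced"), each = 6))
  res <- compare_fst_between_ranges(G, n_perm = "exhaustive")
  expect_equal(res$p, 2 / 20)
  # within-A pairs: identical all-het demes give N = -2 h/n per SNP, so
  # F = -1/3; within-B fixed differences give F = 1; statistic = 4/3
  expect_equal(unname(res$statistic), 4 / 3)
  expect_equal(unname(res$within_means["native"]), -1 / 3)
  expect_equal(unname(res$within_means["introduced"]), 1)
  expect_null(res$warning)              # exactly 20 distinct assignments

  # fewer than 20 distinct assignments attaches a warning (2 + 2 demes)
  G4 <- toy_G(rbind(base, base, d4, d5), deme = rep(1:4, each = 2),
              range = rep(c("native", "introduced"), each = 4))
  expect_false(is.null(compare_fst_between_ranges(G4, n_perm = 49,
                                                  seed = 2)$warning))
})

test_that("permutation p-values respect the add-one floor and null calibration", {
  set.seed(11)
  p <- runif(40, 0.2, 0.8)
  X <- matrix(rbinom(12 * 40, 2, rep(p, each = 12)), nrow = 12)
  G <- toy_G(X, deme = rep(1:6, each = 2),
             range = rep(c("native", "introduced"), each = 6))
  res <- compare_fst_between_ranges(G, n_perm = 99, seed = 1)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)

  # type-I error at or below nominal 5% under a panmictic null (the
  # permutation test is valid, and mildly conservative with few demes)
  rej <- vapply(1:400, function(i) {
    p <- runif(30, 0.2, 0.8)
    X <- matrix(rbinom(16 * 30, 2, rep(p, each = 16)), nrow = 16)
    G <- toy_G(X, deme = rep(1:8, each = 2),
               range = rep(c("native", "introduced"), each = 8))
    compare_fst_between_ranges(G, n_perm = 99, seed = i)$p <= 0.05
  }, TRUE)
  rate <- mean(rej)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  expect_gte(rate, 0.005)
})

test_that("AMOVA matches a brute-force nested ANOVA on a balanced toy", {
  set.seed(5)
  # 2 ranges x 2 demes x 4 individuals, 25 SNPs
  X <- matrix(rbinom(16 * 25, 2, 0.4), nrow = 16)
  X[1:8, 1:10] <- X[1:8, 1:10] + 1  # range effect
  X[X > 2] <- 2
  G <- toy_G(X, deme = rep(1:4, each = 4),
             range = rep(c("native", "introduced"), each = 8))
  res <- amova(G)

  # independent balanced-design computation: n = 4 inds, d = 2 demes/range
  ss_w <- 0; ss_d <- 0; ss_r <- 0
  grand <- colMeans(X)
  for (r in list(1:8, 9:16)) {
    mr <- colMeans(X[r, ])
    ss_r <- ss_r + 8 * sum((mr - grand)^2)
    for (d in list(r[1:4], r[5:8])) {
      md <- colMeans(X[d, ])
      ss_d <- ss_d + 4 * sum((md - mr)^2)
      ss_w <- ss_w + sum(sweep(X[d, ], 2, md)^2)
    }
  }
  ms_w <- ss_w / 12; ms_d <- ss_d / 2; ms_r <- ss_r / 1
  sig_c <- ms_w
  sig_b <- (ms_d - ms_w) / 4
  sig_a <- (ms_r - ms_d) / 8
  expect_equal(unname(res$components),
               c(sig_a, sig_b, sig_c), tolerance = 1e-10)
  expect_equal(sum(res$percent), 100, tolerance = 1e-9)
})

test_that("AMOVA limiting cases behave as expected", {
  # identical individuals: zero components, percentages not applicable
  X <- matrix(1, 8, 5)
  G <- toy_G(X, deme = rep(1:4, each = 2),
             range = rep(c("native", "introduced"), each = 4))
  res <- amova(G)
  expect_equal(unname(res$components), c(0, 0, 0))
  expect_true(all(is.na(res$percent)))

  # two ranges fixed for alternative alleles, no within-range variance
  X2 <- rbind(matrix(0, 8, 6), matrix(2, 8, 6))
  G2 <- toy_G(X2, deme = rep(1:4, each = 4),
              range = rep(c("native", "introduced"), each = 8))
  res2 <- amova(G2)
  expect_gt(res2$percent[1], 99.9)

  # degenerate nesting rejected
  G3 <- toy_G(matrix(rbinom(8, 2, .5), 4), deme = rep(1, 4),
              range = rep("native", 4))
  expect_error(amova(G3), "ranges")
})

test_that("Rousset a-hat matches its defining identities", {
  # two individuals, one SNP, both heterozygous: Q_ij = Q_w = 0.5, a = 0
  G <- toy_G(matrix(c(1, 1), ncol = 1), deme = c(1, 2))
  a <- rousset_a(G)
  expect_equal(a[1, 2], 0)

  # symmetry and clone ordering on a mixed panel
  set.seed(9)
  X <- rbind(c(0, 0, 2, 2, 0, 2), c(0, 0, 2, 2, 0, 2),
             matrix(sample(0:2, 4 * 6, replace = TRUE), nrow = 4))
  G2 <- toy_G(X, deme = rep(1:3, each = 2))
  a2 <- rousset_a(G2)
  expect_equal(a2, t(a2))
  off <- a2[upper.tri(a2)]
  expect_equal(a2[1, 2], min(off))  # homozygous clones: maximal identity

  # degenerate all-homozygous identical panel is flagged
  G3 <- toy_G(matrix(2, 3, 4), deme = 1:3)
  a3 <- rousset_a(G3)
  expect_true(attr(a3, "degenerate"))
  expect_equal(unname(a3[1, 2]), 0)
})

test_that("IBD regression recovers constructed linear relationships", {
  km <- as.matrix(dist(cbind(c(0, 10, 25, 40, 80), 0)))
  a_const <- matrix(0.3, 5, 5); diag(a_const) <- 0
  r0 <- ibd_regression(a_const, km, n_perm = 49, seed = 1)
  expect_equal(r0$slope, 0)
  expect_equal(r0$r2, 0)

  a_lin <- 1e-4 * km
  r1 <- ibd_regression(a_lin, km, n_perm = 49, seed = 1)
  expect_equal(r1$slope, 1e-4, tolerance = 1e-12)
  expect_equal(r1$r2, 1, tolerance = 1e-12)

  expect_error(ibd_regression(a_lin, matrix(1, 5, 5), n_perm = 9),
               "constant")
})

test_that("Mantel p equals exhaustive enumeration on a 5-individual toy", {
  set.seed(31)
  km <- as.matrix(dist(cbind(runif(5, 0, 100), runif(5, 0, 100))))
  a <- as.matrix(dist(matrix(rnorm(10), 5)))
  res <- ibd_regression(a, km, n_perm = "exhaustive")

  # independent enumeration over all 120 label permutations
  up <- upper.tri(km)
  x <- km[up]; xc <- x - mean(x)
  slope_of <- function(ord) {
    y <- a[ord, ord][up]
    sum(xc * y) / sum(xc^2)
  }
  null <- vapply(perms_of(5), slope_of, 0)
  expect_equal(res$p, mean(null >= slope_of(1:5) - 1e-12))
  expect_equal(res$n_perm, 120)
})
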