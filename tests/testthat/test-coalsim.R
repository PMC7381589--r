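test_that("pairwise coalescence time matches the analytic expectation", {
  # one deme of Ne = 1000: E[T2] = 2 Ne = 2000 generations
  m <- toy_island_model(k = 1, ne = 1000, m = 0)
  gs <- simulate_genealogies(m, sampling_plan(1, 1, 0), 2500, seed = 401)
  t2 <- vapply(gs, tmrca, 0)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 2000), 3 * se)
})

test_that("lineages in disconnected demes cannot coalesce before colonization", {
  m <- toy_island_model(k = 2, ne = 500, m = 0, colonization_time = 5000)
  gs <- simulate_genealogies(m, sampling_plan(c(1, 2), 1, 0), 300, seed = 7)
  # each locus: 4 tips; cross-deme coalescences must all be >= 5000
  for (g in gs[1:50]) {
    root <- tmrca(g)
    expect_gte(root, 5000)
  }
})

test_that("simulation is deterministic in (model, plan, n_loci, seed)", {
  m <- build_paper_model(5e-5, 5e-4)
  plan <- present_day_plan(m, 2)
  g1 <- simulate_genealogies(m, plan, 25, seed = 99)
  g2 <- simulate_genealogies(m, plan, 25, seed = 99)
  expect_identical(g1, g2)
  g3 <- simulate_genealogies(m, plan, 25, seed = 100)
  expect_false(identical(g1, g3))
  # and per-locus streams are independent of n_loci
  v5 <- simulate_variants(m, plan, 5, seed = 42)
  v9 <- simulate_variants(m, plan, 9, seed = 42)
  expect_identical(v5, v9[1:5])
})

test_that("serial tips enter the genealogy at their sampling time", {
  m <- build_paper_model(5e-4, 5e-4)
  plan <- serial_plan(m, c(2000, 0), n_diploids = 1)
  gs <- simulate_genealogies(m, plan, 5, seed = 3)
  for (g in gs) {
    tips <- attr(g, "tips")
    expect_equal(g$age[seq_len(g$ntip)], tips$sample_time)
    # all coalescences happen strictly in the past of the youngest involved tip
    expect_true(all(g$age[!is.na(g$parent)] <= g$age[g$parent[!is.na(g$parent)]]))
  }
})

test_that("segregating sites match the Watterson expectation", {
  # Ne = 1000, 10 allele copies: E[S] = theta * a_9, theta = 4 Ne mu L
  m <- toy_island_model(k = 1, ne = 1000, m = 0)
  v <- simulate_variants(m, sampling_plan(1, 5, 0), 8000, seed = 11)
  S <- vapply(v, function(x) length(x$pos), 0)
  expected <- 4 * 1000 * 2.5e-8 * 85 * sum(1 / (1:9))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("mutation count is Poisson-linear in mu and zero when mu = 0", {
  m0 <- toy_island_model(k = 1, ne = 1000, m = 0, mu = 0)
  v0 <- simulate_variants(m0, sampling_plan(1, 4, 0), 50, seed = 5)
  expect_true(all(vapply(v0, function(x) length(x$pos), 0) == 0))

  m1 <- toy_island_model(k = 1, ne = 1000, m = 0, mu = 2.5e-8)
  m2 <- toy_island_model(k = 1, ne = 1000, m = 0, mu = 5e-8)
  s1 <- mean(vapply(simulate_variants(m1, sampling_plan(1, 4, 0), 6000, seed = 21),
                    function(x) length(x$pos), 0))
  s2 <- mean(vapply(simulate_variants(m2, sampling_plan(1, 4, 0), 6000, seed = 22),
                    function(x) length(x$pos), 0))
  expect_lt(abs(s2 / s1 - 2), 0.25)
})

test_that("mutate() places sorted, proper-subset variants on a genealogy", {
  m <- toy_island_model(k = 1, ne = 1000, m = 0)
  g <- simulate_genealogies(m, sampling_plan(1, 6, 0), 1, seed = 88)[[1]]
  hot <- mutation_model(mu = 1e-4, locus_length = 85)  # many mutations
  v <- mutate(g, hot, seed = 9)
  expect_gt(length(v$pos), 0)
  expect_true(!is.unsorted(v$pos))
  expect_true(all(!duplicated(v$pos)))   # recurrent sites discarded
  for (d in v$derived) {
    expect_gte(length(d), 1)
    expect_lt(length(d), g$ntip)
  }
  expect_identical(mutate(g, hot, seed = 9), v)
})

test_that("ascertainment keeps the first SNP per locus and applies the maf filter", {
  m <- build_paper_model(5e-4, 5e-4)
  plan <- present_day_plan(m, 6)        # 96 diploids
  variants <- list(
    list(pos = c(40L, 12L), derived = list(1:60, c(1L, 2L, 5L))),  # keep pos 12
    list(pos = 7L, derived = list(1L)),   # singleton: freq 1/192 < 0.01
    list(pos = integer(0), derived = list()))  # monomorphic locus
  G <- extract_snp_matrix(variants, m, plan, maf_threshold = 0.01)
  expect_equal(colnames(G$dosage), "L1_12")
  expect_equal(sum(G$dosage[, 1]), 3)
  # doubleton passes the 0.01 threshold (2/192 = 0.0104)
  v2 <- list(list(pos = 3L, derived = list(c(1L, 3L))))
  G2 <- extract_snp_matrix(v2, m, plan, maf_threshold = 0.01)
  expect_equal(ncol(G2$dosage), 1L)
  # allele copies 2k-1, 2k pair into individual k
  v3 <- list(list(pos = 1L, derived = list(c(1L, 2L, 3L))))
  G3 <- extract_snp_matrix(v3, m, plan, maf_threshold = 0)
  expect_equal(unname(G3$dosage[1:2, 1]), c(2, 1))
})

test_that("simulated dataset has the planned dimensions and is reproducible", {
  m <- build_paper_model(5e-4, 5e-4, overrides = list(n_loci = 300L))
  G <- simulate_dataset(m, present_day_plan(m, 6), seed = 17)
  expect_equal(nrow(G$dosage), 96L)
  expect_gt(ncol(G$dosage), 0)
  expect_identical(G$dosage,
                   simulate_dataset(m, present_day_plan(m, 6), seed = 17)$dosage)
})

test_that("ascertainment plus maf filtering enriches for common variants", {
  m <- build_paper_model(5e-4, 5e-4)
  plan <- present_day_plan(m, 6)
  v <- simulate_variants(m, plan, 1500, seed = 23)
  G_raw <- extract_snp_matrix(v, m, plan, maf_threshold = 0)
  G_flt <- extract_snp_matrix(v, m, plan, maf_threshold = 0.01)
  maf <- function(G) {
    f <- colSums(G$dosage) / (2 * nrow(G$dosage))
    pmin(f, 1 - f)
  }
  # folded spectrum shifts away from rare variants
  expect_lt(mean(maf(G_flt) < 0.05), mean(maf(G_raw) < 0.05))
  expect_gt(mean(maf(G_flt)), mean(maf(G_raw)))
})

test_that("deme labels are exchangeable under symmetric parameters", {
  m <- toy_island_model(k = 2, ne = 800, m = 1e-3, colonization_time = 1e6)
  G <- simulate_dataset(m, sampling_plan(c(1, 2), 6, 0), seed = 31,
                        n_loci = 3000, maf_threshold = 0)
  div <- diversity_summary(G, "deme")
  # the two demes are statistically identical: per-SNP He difference
  # centred on zero within Monte-Carlo error
  he_of <- function(rows) {
    p <- colMeans(G$dosage[rows, ]) / 2
    2 * p * (1 - p)
  }
  d_he <- he_of(1:6) - he_of(7:12)
  expect_lt(abs(mean(d_he)), 3 * sd(d_he) / sqrt(length(d_he)))
  # and the summary function agrees with the manual computation
  expect_equal(div$He, c(mean(he_of(1:6)), mean(he_of(7:12))))
})

test_that("F_ST tracks the two-deme island-model expectation and falls with migration", {
  # exact two-deme coalescent result for per-lineage migration rate m:
  # E[Tw] = 4N, E[Tb] = 4N + 1/(2m), so F_ST = 1 / (1 + 8 N m)
  ne <- 1000
  got <- vapply(c(0.25, 1, 4), function(nm) {
    m <- toy_island_model(k = 2, ne = ne, m = nm / ne, colonization_time = 1e7)
    G <- simulate_dataset(m, sampling_plan(c(1, 2), 8, 0), seed = 500 + nm * 4,
                          n_loci = 6000, maf_threshold = 0)
    reich_fst(G, "deme")$fst[1, 2]
  }, 0)
  expected <- 1 / (1 + 8 * c(0.25, 1, 4))
  expect_true(all(abs(got - expected) < 0.02))
  expect_true(all(diff(got) < 0))  # monotone decrease with migration
})

test_that("genealogies convert to valid ape trees", {
  skip_if_not_installed("ape")
  m <- build_paper_model(5e-4, 5e-4)
  g <- simulate_genealogies(m, present_day_plan(m, 2), 1, seed = 2)[[1]]
  ph <- genealogy_to_phylo(g)
  expect_s3_class(ph, "phylo")
  expect_equal(ape::Ntip(ph), 64L)
  expect_true(all(ph$edge.length >= 0))
  # tip-to-root depth equals root age for present-day samples
  depths <- ape::node.depth.edgelength(ph)
  expect_equal(max(depths[seq_len(64)]) - min(depths[seq_len(64)]), 0,
               tolerance = 1e-9)
})
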