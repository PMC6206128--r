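# diversity indices, F_ST, AMOVA, PCA and the null-allele screen

test_that("hand-computed heterozygosities are reproduced", {
  # two diploids, both heterozygous A/B: H_O = 1, unbiased H_E = 2/3
  gt <- genotype_table(c("i1", "i2"), "L1",
                       matrix(c(100L, 100L)), matrix(c(102L, 102L)),
                       c("g", "g"))
  d <- diversity_indices(gt, groups = c("g", "g"))
  expect_equal(d$H_O, 1)
  expect_equal(d$H_E, 4 / 3 * 0.5, tolerance = 1e-12)
  expect_equal(d$F_IS, 1 - 1 / (2 / 3), tolerance = 1e-12)
})

test_that("sequence diversity matches direct counts and closed forms", {
  a <- paste(rep("A", 1031), collapse = "")
  b <- paste(c(rep("A", 1028), "C", "C", "C"), collapse = "")
  aln <- sequence_alignment(c(s1 = a, s2 = b))
  d <- diversity_indices(aln = aln, groups = c(s1 = "g", s2 = "g"))
  expect_equal(d$S, 3)
  expect_equal(d$h, 2)
  expect_equal(d$pi, 3 / 1031, tolerance = 1e-12)
  # monomorphic group
  mono <- sequence_alignment(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  dm <- diversity_indices(aln = mono, groups = c(x = "g", y = "g", z = "g"))
  expect_equal(dm$S, 0); expect_equal(dm$h, 1)
  expect_equal(dm$Hd, 0); expect_equal(dm$pi, 0)
})

test_that("diversity indices are invariant to individual and locus order", {
  gt <- random_gt(n = 10, L = 4, missing_rate = 0.1, seed = 11)
  d1 <- diversity_indices(gt, groups = gt$site)
  perm_i <- sample(seq_along(gt$individuals))
  perm_l <- sample(seq_along(gt$loci))
  gt2 <- genotype_table(gt$individuals[perm_i], gt$loci[perm_l],
                        gt$a1[perm_i, perm_l], gt$a2[perm_i, perm_l],
                        gt$site[perm_i])
  d2 <- diversity_indices(gt2, groups = gt2$site)
  d2 <- d2[match(d1$group, d2$group), ]
  for (col in c("n", "n_A", "AR", "H_O", "H_E", "F_IS"))
    expect_equal(d2[[col]], d1[[col]], tolerance = 1e-12)
})

test_that("Weir-Cockerham theta matches the ANOVA oracle on random tables", {
  for (seed in 1:25) {
    gt <- random_gt(n = sample(6:12, 1), L = sample(1:3, 1),
                    n_alleles = sample(2:4, 1), seed = seed)
    th <- wc_theta(gt, gt$site)
    or <- oracle_wc_theta(gt, gt$site)
    expect_equal(th, or, tolerance = 1e-10)
  }
})

test_that("fixed differences give theta = 1 and identical frequencies near 0", {
  a1 <- cbind(rep(c(100L, 200L), each = 5))
  gt <- genotype_table(sprintf("i%d", 1:10), "L1", a1, a1,
                       rep(c("g1", "g2"), each = 5))
  expect_equal(wc_theta(gt, gt$site), 1)
  taxa <- make_taxa(1, n_loci = 10, F_vector = 0.3, seed = 1)
  g1 <- sample_genotypes(taxa[[1]], 100, seed = 2, prefix = "a")
  g2 <- sample_genotypes(taxa[[1]], 100, seed = 3, prefix = "b")
  gt0 <- bind_genotypes(g1, g2)
  expect_lt(abs(wc_theta(gt0, gt0$site)), 0.05)
})

test_that("pairwise F_ST returns a symmetric matrix with valid p-values", {
  gt <- random_gt(n = 12, L = 3, seed = 4,
                  groups = rep(c("g1", "g2", "g3"), each = 4))
  fm <- pairwise_fst(gt = gt, groups = gt$site, n_permutations = 19)
  expect_equal(fm$fst, t(fm$fst))
  expect_true(all(diag(fm$fst) == 0))
  offdiag <- fm$p_value[upper.tri(fm$p_value)]
  expect_true(all(offdiag >= 1 / 20 & offdiag <= 1))
  expect_error(pairwise_fst(gt = gt, groups = rep(c("a", "b"),
                                                  c(1, 11))),
               ">= 2 members")
})

test_that("AMOVA components match the brute-force partition oracle", {
  for (seed in 1:25) {
    gt <- random_gt(n = sample(6:10, 1), L = sample(1:3, 1), seed = seed)
    am <- amova(gt = gt, groups = gt$site, n_permutations = 0)
    d <- pondmix:::genotype_diff_matrix(gt)
    or <- oracle_amova(d, gt$site)
    expect_equal(am$sigma_a, or$sigma_a, tolerance = 1e-10)
    expect_equal(am$sigma_w, or$sigma_w, tolerance = 1e-10)
    expect_equal(am$pct_among + am$pct_within, 100, tolerance = 1e-6)
  }
})

test_that("groups fixed for different haplotypes put all variance among groups", {
  aln <- sequence_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "TTTT",
                              b2 = "TTTT"))
  am <- amova(aln = aln, groups = c(a1 = "g1", a2 = "g1", b1 = "g2",
                                    b2 = "g2"), n_permutations = 0,
              distance = "pairwise_difference")
  expect_equal(am$pct_among, 100, tolerance = 1e-9)
})

test_that("label permutation destroys among-group variance", {
  taxa <- make_taxa(1, n_loci = 6, F_vector = 0.3, seed = 5)
  hits <- 0
  for (seed in 1:20) {
    gt <- sample_genotypes(taxa[[1]], 24, seed = seed)
    set.seed(seed)
    gt$site <- sample(rep(c("g1", "g2"), each = 12))
    am <- amova(gt = gt, groups = gt$site, n_permutations = 49,
                seed = seed)
    if (am$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("PCA separates differentiated taxa and reports sane variance", {
  taxa <- make_taxa(2, n_loci = 15, F_vector = c(0.3, 0.3), seed = 6)
  gt <- bind_genotypes(sample_genotypes(taxa[[1]], 30, seed = 7),
                       sample_genotypes(taxa[[2]], 30, seed = 8))
  pc <- pca_genotypes(gt, n_axes = 3, groups = gt$site)
  expect_true(all(diff(pc$percent_variance) <= 1e-9))
  expect_lte(sum(pc$percent_variance), 100)
  m1 <- mean(pc$scores[gt$site == "taxon1", 1])
  m2 <- mean(pc$scores[gt$site == "taxon2", 1])
  pooled_sd <- sqrt(mean(c(var(pc$scores[gt$site == "taxon1", 1]),
                           var(pc$scores[gt$site == "taxon2", 1]))))
  expect_gt(abs(m1 - m2) / pooled_sd, 4)
  # identical individuals land on identical coordinates
  gt2 <- genotype_table(c("i1", "i2", "i3"), c("L1", "L2"),
                        rbind(c(100L, 120L), c(100L, 120L),
                              c(102L, 122L)),
                        rbind(c(100L, 122L), c(100L, 122L),
                              c(104L, 124L)))
  pc2 <- suppressWarnings(pca_genotypes(gt2, n_axes = 2))
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-10)
})

test_that("Brookfield estimator and homozygote-excess flagging behave", {
  # H_E = 0.8, H_O = 0.6 -> r_hat = 0.2 / 1.8
  expect_equal((0.8 - 0.6) / (1 + 0.8), 0.1111, tolerance = 1e-3)
  taxa <- make_taxa(1, n_loci = 6, F_vector = 0.3, seed = 9)
  gt <- sample_genotypes(taxa[[1]], 120, seed = 10)
  rep0 <- null_allele_scan(gt)
  expect_true(all(rep0$r_hat >= 0 & rep0$r_hat <= 1))
  # simulate a true 15% null allele at locus 1: each allele copy is
  # independently null with probability 0.15; null/x genotypes show as
  # x/x homozygotes, null/null genotypes drop out as missing.  A mildly
  # drifted taxon keeps locus diversity at the H_E ~ 0.75 typical of
  # highly polymorphic microsatellites, where the screen is meant to
  # operate.
  taxa_poly <- make_taxa(1, n_loci = 6, F_vector = 0.1, seed = 9)
  hits <- 0
  for (seed in 1:20) {
    g <- sample_genotypes(taxa_poly[[1]], 100, seed = 100 + seed)
    set.seed(seed)
    n1 <- runif(100) < 0.15
    n2 <- runif(100) < 0.15
    g$a1[n1 & !n2, 1] <- g$a2[n1 & !n2, 1]
    g$a2[n2 & !n1, 1] <- g$a1[n2 & !n1, 1]
    g$a1[n1 & n2, 1] <- NA; g$a2[n1 & n2, 1] <- NA
    rp <- null_allele_scan(g)
    if (rp$flagged[1]) hits <- hits + 1
  }
  expect_gte(hits, 16)
  cor <- correct_for_nulls(gt, rep0)
  for (l in seq_along(cor$corrected_freqs))
    expect_equal(sum(cor$corrected_freqs[[l]]), 1, tolerance = 1e-12)
})
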