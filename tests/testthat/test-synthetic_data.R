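# synthetic-data generator: drifted taxa, genotype sampling, transects
# and mtDNA lineages with ground truth

test_that("near-zero drift reproduces the ancestral frequencies", {
  taxa <- make_taxa(2, n_loci = 5, F_vector = rep(1e-6, 2), seed = 1)
  anc <- attr(taxa, "ancestral")
  for (l in seq_along(anc)) {
    expect_lt(max(abs(taxa[[1]]$freqs[[l]] - anc[[l]])), 1e-2)
  }
})

test_that("default allele counts per locus fall in the 12-29 range", {
  taxa <- make_taxa(2, n_loci = 15, seed = 7)
  counts <- vapply(taxa[[1]]$freqs, length, 0L)
  expect_true(all(counts >= 12 & counts <= 29))
  expect_error(make_taxa(2, alleles_per_locus = 1), "alleles_per_locus")
})

test_that("sampled genotypes follow the model frequencies", {
  taxa <- make_taxa(1, n_loci = 3, alleles_per_locus = 5,
                    F_vector = 0.3, seed = 2)
  gt <- sample_genotypes(taxa[[1]], 500, seed = 3)
  expect_equal(sum(is.na(gt$a1)), 0)
  cnt <- allele_counts(gt)
  for (l in seq_len(3)) {
    obs <- rep(0, length(taxa[[1]]$freqs[[l]]))
    names(obs) <- names(taxa[[1]]$freqs[[l]])
    obs[names(cnt[[l]])] <- cnt[[l]] / sum(cnt[[l]])
    expect_lt(sum(abs(obs - taxa[[1]]$freqs[[l]])), 0.05)
  }
})

test_that("a locus fixed for one allele yields only that genotype, and missingness obeys its rate", {
  tax <- structure(list(id = "t", F = 0.5,
                        freqs = list(L1 = c(`100` = 1))),
                   class = "taxon_model")
  gt <- sample_genotypes(tax, 20, seed = 1)
  expect_true(all(gt$a1 == 100 & gt$a2 == 100))
  taxa <- make_taxa(1, n_loci = 10, F_vector = 0.3, seed = 4)
  gtm <- sample_genotypes(taxa[[1]], 100, missing_rate = 0.2, seed = 5)
  expect_gt(mean(is.na(gtm$a1)), 0.15)
  expect_lt(mean(is.na(gtm$a1)), 0.25)
})

test_that("expected heterozygosity of a generated taxon matches 1 - sum(p^2)", {
  taxa <- make_taxa(1, n_loci = 8, F_vector = 0.3, seed = 6)
  gt <- sample_genotypes(taxa[[1]], 200, seed = 7)
  h <- sapply(seq_len(8), function(l) mean(gt$a1[, l] != gt$a2[, l]))
  expected <- sapply(taxa[[1]]$freqs, function(p) 1 - sum(p^2))
  # binomial sampling error at n = 200 per locus, compared in the mean
  expect_lt(abs(mean(h) - mean(expected)), 3 * sqrt(0.25 / (200 * 8)) + 0.02)
})

test_that("the cline sigmoid has its closed-form values", {
  expect_equal(cline_true_p(500, 500, 40), 0.5)
  expect_equal(cline_true_p(520, 500, 40), (1 + tanh(1)) / 2,
               tolerance = 1e-12)
})

test_that("transect simulation carries a complete, reproducible truth record", {
  taxa <- disjoint_taxa(n_loci = 5, seed = 1)
  sim1 <- simulate_transect(taxa[[1]], taxa[[2]], 500, 40,
                            seq(0, 1000, 100), n_per_site = 4, seed = 9)
  sim2 <- simulate_transect(taxa[[1]], taxa[[2]], 500, 40,
                            seq(0, 1000, 100), n_per_site = 4, seed = 9)
  expect_identical(sim1$genotypes$a1, sim2$genotypes$a1)
  expect_identical(unclass(sim1$alignment), unclass(sim2$alignment))
  expect_equal(nrow(sim1$truth$individuals),
               length(sim1$genotypes$individuals))
  expect_equal(sim1$truth$sites$p_true,
               cline_true_p(sim1$truth$sites$x_km, 500, 40))
  # site coordinates reproduce the nominal positions through haversine
  d <- transect_distances(sim1$sites, "t1")
  expect_equal(d$km, seq(0, 1000, 100), tolerance = 1e-6)
})

test_that("taxon-B ancestry rises along the transect as the cline dictates", {
  taxa <- disjoint_taxa(n_loci = 6, seed = 2)
  sim <- simulate_transect(taxa[[1]], taxa[[2]], 500, 40,
                           seq(0, 1000, 100), n_per_site = 15, seed = 3)
  tr <- sim$truth$individuals
  mean_by_site <- tapply(tr$ancestry_B_realised, tr$site, mean)
  sites <- sim$truth$sites
  expect_lt(mean_by_site[sites$site[1]], 0.1)
  expect_gt(mean_by_site[sites$site[11]], 0.9)
})

test_that("mtDNA star lineages keep founders apart and radii small", {
  founders <- make_founders(2, L = 400, steps_between = 16, seed = 4)
  expect_equal(sum(strsplit(founders[1], "")[[1]] !=
                     strsplit(founders[2], "")[[1]]), 16)
  aln <- simulate_mtdna_lineages(founders, steps_within = 0,
                                 n_per_lineage = 4, seed = 5)
  expect_true(all(unclass(aln)[1:4] == founders[1]))
  for (seed in 1:20) {
    aln <- simulate_mtdna_lineages(founders, steps_within = 3,
                                   n_per_lineage = 4, seed = seed)
    m <- do.call(rbind, strsplit(unclass(aln), ""))
    lin <- attr(aln, "lineage")
    cross <- Inf
    for (i in which(lin == "lin1")) for (j in which(lin == "lin2"))
      cross <- min(cross, sum(m[i, ] != m[j, ]))
    expect_gte(cross, 10) # 16 founder steps minus worst-case homoplasy
  }
})

test_that("unequal-length founders are rejected", {
  expect_error(simulate_mtdna_lineages(c(a = "ACGT", b = "ACG")),
               "share one length")
})
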