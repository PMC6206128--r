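# EM admixture model, Evanno delta-K, label alignment and per-site Q

test_that("K = 1 degenerates to the frequency-only likelihood", {
  gt <- random_gt(n = 10, L = 4, seed = 1)
  fit <- fit_admixture(gt, K = 1, seed = 1)
  expect_true(all(fit$Q == 1))
  # frequency-only likelihood: sum over copies of log empirical freq
  cnt <- allele_counts(gt)
  ll <- 0
  for (l in seq_along(gt$loci)) {
    p <- cnt[[l]] / sum(cnt[[l]])
    for (a in c(gt$a1[, l], gt$a2[, l]))
      if (!is.na(a)) ll <- ll + log(p[[as.character(a)]])
  }
  expect_equal(fit$lnL, ll, tolerance = 1e-6)
})

test_that("log-likelihood is non-decreasing and Q stays on the simplex", {
  for (seed in 1:6) {
    gt <- random_gt(n = 12, L = 5, missing_rate = 0.1, seed = seed)
    fit <- fit_admixture(gt, K = sample(2:3, 1), seed = seed,
                         max_iter = 200)
    expect_true(all(diff(fit$lnL_trace) > -1e-8))
    expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-8)
    expect_true(all(fit$Q >= 0))
  }
  expect_error(fit_admixture(random_gt(n = 3, seed = 1), K = 5),
               "exceeds")
})

test_that("separable taxa resolve to near-pure ancestry, F1s to half-half", {
  taxa <- disjoint_taxa(n_loci = 10, seed = 2)
  gA <- sample_genotypes(taxa[[1]], 20, seed = 3, prefix = "A")
  gB <- sample_genotypes(taxa[[2]], 20, seed = 4, prefix = "B")
  hs <- simulate_hybrids(gA, gB, n_per_class = 10, seed = 5)
  f1 <- subset_individuals(hs$genotypes, hs$class == "F1")
  gt <- bind_genotypes(gA, gB, f1)
  fit <- fit_admixture(gt, K = 2, seed = 1)
  pure <- apply(fit$Q[1:40, ], 1, max)
  expect_true(all(pure >= 0.99))
  f1q <- fit$Q[41:50, 1]
  expect_true(all(abs(f1q - 0.5) <= 0.1))
})

test_that("separable data converge to the same Q regardless of seed", {
  taxa <- disjoint_taxa(n_loci = 8, seed = 6)
  gt <- bind_genotypes(sample_genotypes(taxa[[1]], 15, seed = 7,
                                        prefix = "A"),
                       sample_genotypes(taxa[[2]], 15, seed = 8,
                                        prefix = "B"))
  fits <- lapply(1:5, function(s) fit_admixture(gt, 2, seed = s))
  fits <- align_labels(fits)
  for (i in 2:5)
    expect_lt(max(abs(fits[[i]]$Q - fits[[1]]$Q)), 0.01)
})

test_that("the Evanno arithmetic matches its definition", {
  # means (-1000, -800, -790) with sd(K=2) = 5 -> deltaK(2) = 38
  lnL <- cbind(K1 = c(-1000, -1000, -1000) + c(-1, 0, 1),
               K2 = c(-805, -800, -795),
               K3 = c(-791, -790, -789))
  mu <- colMeans(lnL); sdv <- apply(lnL, 2, sd)
  deltaK2 <- abs(mu[1] - 2 * mu[2] + mu[3]) / sdv[2]
  expect_equal(unname(deltaK2), 190 / 5)
})

test_that("replicate runs select K = 2 on clean two-taxon data", {
  taxa <- disjoint_taxa(n_loci = 8, seed = 9)
  gt <- bind_genotypes(sample_genotypes(taxa[[1]], 15, seed = 10,
                                        prefix = "A"),
                       sample_genotypes(taxa[[2]], 15, seed = 11,
                                        prefix = "B"))
  ks <- run_replicates(gt, 1:3, n_reps = 4, seed = 1, max_iter = 200)
  expect_equal(ks$selected_K, 2)
  expect_true(is.na(ks$deltaK[1]) && is.na(ks$deltaK[3]))
  expect_error(run_replicates(gt, c(1, 3), n_reps = 3), "contiguous")
})

test_that("label alignment undoes a deliberate cluster swap", {
  taxa <- disjoint_taxa(n_loci = 6, seed = 12)
  gt <- bind_genotypes(sample_genotypes(taxa[[1]], 10, seed = 13,
                                        prefix = "A"),
                       sample_genotypes(taxa[[2]], 10, seed = 14,
                                        prefix = "B"))
  fit <- fit_admixture(gt, 2, seed = 1)
  swapped <- fit
  swapped$Q <- fit$Q[, 2:1]
  swapped$F <- fit$F[2:1, ]
  out <- align_labels(list(fit, swapped))
  expect_equal(out[[2]]$Q, fit$Q)
  expect_equal(out[[2]]$permutation, c(2L, 1L))
  # K = 1 is a no-op
  one <- align_labels(list(fit_admixture(gt, 1, seed = 1)))
  expect_equal(one[[1]]$permutation, 1L)
})

test_that("per-site mean Q aggregates correctly and flags empty sites", {
  Q <- rbind(c(1, 0), c(0, 1), c(0.6, 0.4))
  res <- structure(list(K = 2, Q = Q,
                        site = c("s1", "s1", "s2"),
                        individuals = c("a", "b", "c")),
                   class = "ancestry_result")
  rownames(res$Q) <- res$individuals
  mq <- mean_q_per_site(res, cluster = 1)
  expect_equal(mq$mean_Q[mq$site == "s1"], 0.5)
  expect_equal(mq$n, c(2L, 1L))
  st <- site_table(data.frame(site = c("s1", "s2", "s3"),
                              lat = 0, lon = 0))
  expect_warning(mean_q_per_site(res, st, 1), "s3")
})

test_that("subsampling reduces only sites at or above the trigger", {
  gt <- random_gt(n = 54, L = 2, seed = 15,
                  groups = rep(c("big", "small"), c(30, 24)))
  sub <- subsample_sites(gt, max_n = 20, trigger = 25, seed = 1)
  expect_equal(sum(sub$site == "big"), 20)
  expect_equal(sum(sub$site == "small"), 24)
  sub2 <- subsample_sites(gt, max_n = 20, trigger = 25, seed = 1)
  expect_identical(sub$individuals, sub2$individuals)
})

test_that("long-format Q tables order by site and majority membership", {
  res <- structure(list(K = 2,
                        Q = rbind(c(0.2, 0.8), c(0.9, 0.1),
                                  c(0.6, 0.4)),
                        site = c("s2", "s1", "s1"),
                        individuals = c("a", "b", "c")),
                   class = "ancestry_result")
  lf <- q_long_format(res)
  expect_equal(nrow(lf), 6) # individuals x clusters
  expect_equal(unique(lf$site), c("s1", "s2"))
  expect_equal(lf$id[1], "b") # highest Q1 within s1 first
  expect_equal(sum(lf$Q[lf$id == "a"]), 1)
})
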