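# coalescent simulator, summary statistics and rejection ABC

test_that("prior draws respect bounds, constraints and seeds", {
  scen <- scenario_atlantic()
  pri <- default_priors(scen)
  d1 <- sample_priors(pri, 200, seed = 1)
  d2 <- sample_priors(pri, 200, seed = 1)
  expect_identical(d1, d2)
  expect_true(all(d1$N_occ >= 10 & d1$N_occ <= 10000))
  expect_true(all(d1$t_adm >= 10 & d1$t_adm <= 10000))
  expect_true(all(d1$t_div >= 10 & d1$t_div <= 100000))
  expect_true(all(d1$r > 0 & d1$r < 1))
  expect_true(all(d1$t_adm < d1$t_div)) # ordering constraint
})

test_that("scenario validation rejects stranded lineages", {
  bad <- abc_scenario(populations = c("a", "b"),
                      events = list(), Ne = list(a = 100, b = 100))
  expect_error(pondmix:::validate_scenario(bad, c()), "strands")
  good <- scenario_atlantic()
  expect_silent(pondmix:::validate_scenario(
    good, c(t_adm = 10, t_div = 100)))
})

test_that("a freshly merged panmictic pair shows no differentiation", {
  scen <- abc_scenario(populations = c("a", "b"),
                      events = list(list(type = "merge", time = 10,
                                         from = "a", into = "b")),
                      Ne = list(a = 10000, b = 10000))
  fsts <- sapply(1:20, function(s) {
    sim <- simulate_dataset(scen, c(), c(a = 10, b = 10),
                            n_microsat_loci = 5, mtdna_length = 100,
                            mu_micro_bounds = c(1e-4, 2e-4),
                            mu_mt_bounds = c(1e-9, 2e-9), seed = s)
    st <- summary_stats(sim$genotypes, sim$alignment)
    st[["ms_fst_a_b"]]
  })
  expect_lt(mean(fsts), 0.02)
})

test_that("deep divergence produces strong differentiation", {
  scen <- abc_scenario(populations = c("a", "b"),
                      events = list(list(type = "merge", time = 2e5,
                                         from = "a", into = "b")),
                      Ne = list(a = 1000, b = 1000))
  sim <- simulate_dataset(scen, c(), c(a = 12, b = 12),
                          n_microsat_loci = 8, seed = 2)
  st <- summary_stats(sim$genotypes, sim$alignment)
  expect_gt(st[["ms_fst_a_b"]], 0.1)
  expect_gt(st[["mt_fst_a_b"]], 0.5)
})

test_that("diversity grows with Ne at fixed mutation rate", {
  mean_he <- sapply(c(100, 1000, 10000), function(ne) {
    scen <- abc_scenario(populations = "a", events = list(),
                         Ne = list(a = ne))
    mean(sapply(1:15, function(s) {
      sim <- simulate_dataset(scen, c(), c(a = 10),
                              n_microsat_loci = 4, mtdna_length = 200,
                              mu_micro_bounds = c(5e-4, 5e-4),
                              seed = 100 * ne + s)
      summary_stats(sim$genotypes, sim$alignment)[["ms_he_a"]]
    }))
  })
  expect_true(all(diff(mean_he) > 0))
})

test_that("admixture rate sets the expected source split of lineages", {
  # just after a pulse with rate r, the fraction of sampled lineages
  # tracing to sourceA is Binomial(n, r): trace 1000 lineages
  events <- list(list(type = "admixture", time = 5, target = "adm",
                      sourceA = "a", sourceB = "b", rate = 0.3),
                 list(type = "merge", time = 1e7, from = "a",
                      into = "b"))
  set.seed(8)
  tr <- pondmix:::sim_coalescent(rep("adm", 1000), events,
                                 list(adm = 1e9, a = 1e9, b = 1e9),
                                 ploidy = 1, trace_at = 5)
  frac_a <- mean(tr$trace == "a")
  expect_lt(abs(frac_a - 0.3), 1.96 * sqrt(0.3 * 0.7 / 1000) + 0.01)
})

test_that("summary statistics agree exactly with the estimator module", {
  scen <- scenario_atlantic()
  sim <- simulate_dataset(scen, c(N_occ = 1000, N_orb = 1000,
                                  N_adm = 500, t_adm = 200,
                                  t_div = 30000, r = 0.4),
                          c(occ = 8, orb = 8, adm = 8),
                          n_microsat_loci = 5, mtdna_length = 300,
                          seed = 3)
  st <- summary_stats(sim$genotypes, sim$alignment)
  gr <- sim$genotypes$site
  div <- diversity_indices(aln = sim$alignment,
                           groups = setNames(gr, sim$genotypes$individuals))
  for (p in c("occ", "orb", "adm")) {
    expect_identical(st[[paste0("mt_h_", p)]],
                     as.numeric(div$h[div$group == p]))
    expect_identical(st[[paste0("mt_S_", p)]],
                     as.numeric(div$S[div$group == p]))
  }
  sub <- gr %in% c("occ", "orb")
  th <- wc_theta(subset_individuals(sim$genotypes, sub), gr[sub])
  expect_identical(st[["ms_fst_occ_orb"]], th)
  fm <- pairwise_fst(aln = sim$alignment,
                     groups = setNames(gr, sim$genotypes$individuals),
                     mode = "haplotype_freq")
  expected <- fm$fst["occ", "orb"]
  if (!is.finite(expected)) expected <- 0 # the shared undefined-ratio rule
  expect_equal(st[["mt_fst_occ_orb"]], expected, tolerance = 1e-12)
})

test_that("private segregating sites come from a hand-built alignment", {
  aln <- sequence_alignment(c(
    p1_a = "AAAAAAAAAA", p1_b = "CAAAAAAAAA", p1_c = "CCCAAAAAAA",
    p2_a = "AAAAAAAAAT", p2_b = "AAAAAAAAAT"))
  gt <- genotype_table(names(aln), "L1",
                       matrix(100L, 5), matrix(100L, 5),
                       c("p1", "p1", "p1", "p2", "p2"))
  st <- summary_stats(gt, aln)
  # sites 1 and 2 segregate only within p1; p2 is monomorphic
  expect_equal(st[["mt_privS_p1"]], 3)
  expect_equal(st[["mt_S_p1"]], 3)
  expect_equal(st[["mt_S_p2"]], 0)
  expect_equal(st[["mt_h_p2"]], 1)
  expect_equal(st[["mt_mpd_p2"]], 0)
  # monomorphic microsatellite locus contributes zero diversity
  expect_equal(st[["ms_he_p1"]], 0)
})

test_that("missing mtDNA flags the statistics instead of failing", {
  gt <- random_gt(n = 6, L = 3, seed = 5)
  st <- summary_stats(gt, aln = NULL)
  expect_true(attr(st, "empty_mtdna"))
  expect_true(all(st[startsWith(names(st), "mt_")] == 0))
  expect_true(all(is.finite(st)))
})

test_that("small reference tables build, serialize and round-trip", {
  scen <- scenario_atlantic()
  tab <- suppressWarnings(build_reference_table(
    scen, N = 100, sample_sizes = c(occ = 4, orb = 4, adm = 4),
    n_microsat_loci = 3, mtdna_length = 120, seed = 7))
  expect_equal(nrow(tab$stats), 100)
  expect_true(all(is.finite(tab$stats)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(tab, path)
  back <- read_reference_table(path)
  expect_equal(back$params$r, tab$params$r, tolerance = 1e-9)
  expect_equal(unname(back$stats), unname(tab$stats), tolerance = 1e-9)
})

test_that("rejection keeps the right number of rows and handles edge cases", {
  scen <- scenario_atlantic()
  pri <- default_priors(scen)
  set.seed(1)
  # synthetic reference table: cheap stats with known structure
  N <- 500
  params <- sample_priors(pri, N, seed = 2)
  stats <- cbind(s1 = params$r + rnorm(N, 0, 0.02),
                 s2 = rnorm(N), s3 = rep(1, N)) # s3 has MAD 0
  tab <- structure(list(params = params, stats = stats,
                        scenario = scen, seed = 2),
                   class = "abc_reference_table")
  expect_warning(post <- abc_reject(c(s1 = 0.5, s2 = 0, s3 = 1), tab,
                                    tolerance = 0.01),
                 "zero MAD")
  expect_equal(post$n_retained, ceiling(0.01 * N))
  expect_lt(abs(post$summary$mean[post$summary$parameter == "r"] - 0.5),
            0.1)
  # tolerance 1 returns the prior
  post1 <- suppressWarnings(abc_reject(c(s1 = 0.5, s2 = 0, s3 = 1),
                                       tab, tolerance = 1))
  qs <- quantile(params$r, c(0.25, 0.5, 0.75))
  qr <- quantile(post1$retained$r, c(0.25, 0.5, 0.75))
  expect_equal(unname(qr), unname(qs), tolerance = 1e-9)
})

test_that("scenario comparison is symmetric for identical tables and sums to 1", {
  scen <- scenario_atlantic()
  pri <- default_priors(scen)
  params <- sample_priors(pri, 400, seed = 3)
  set.seed(4)
  stats <- cbind(s1 = rnorm(400), s2 = rnorm(400))
  mk <- function() structure(list(params = params, stats = stats,
                                  scenario = scen, seed = 3),
                             class = "abc_reference_table")
  pr <- compare_scenarios(c(s1 = 0, s2 = 0),
                          list(A = mk(), B = mk()), tolerance = 0.05)
  expect_equal(sum(pr), 1)
  expect_lt(abs(pr[["A"]] - 0.5), 0.1 + 1e-9)
})

test_that("generation-time conversion is linear with a 15-year default", {
  expect_equal(generations_to_years(380), 5700)
  expect_equal(generations_to_years(1130), 16950)
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(114, generation_time = 10), 1140)
})

test_that("scenario and priors round-trip through YAML", {
  scen <- scenario_atlantic()
  pri <- default_priors(scen)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(scen, pri, path)
  back <- read_scenario_yaml(path)
  expect_equal(back$scenario$populations, scen$populations)
  expect_equal(length(back$scenario$events), length(scen$events))
  expect_equal(back$priors$spec$r$max, pri$spec$r$max)
  expect_equal(back$priors$constraints, pri$constraints)
  # instantiated scenarios simulate identically
  p <- c(N_occ = 500, N_orb = 500, N_adm = 500, t_adm = 100,
         t_div = 5000, r = 0.5)
  s1 <- simulate_dataset(scen, p, c(occ = 4, orb = 4, adm = 4),
                         n_microsat_loci = 2, mtdna_length = 100,
                         seed = 3)
  s2 <- simulate_dataset(back$scenario, p, c(occ = 4, orb = 4, adm = 4),
                         n_microsat_loci = 2, mtdna_length = 100,
                         seed = 3)
  expect_identical(s1$genotypes$a1, s2$genotypes$a1)
})
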