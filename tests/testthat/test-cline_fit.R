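# geographic cline models: distances, prediction, MCMC fit, AIC

make_sites_line <- function(positions_km) {
  km_per_deg <- 6371 * pi / 180
  site_table(data.frame(
    site = sprintf("s%02d", seq_along(positions_km)),
    lat = 0, lon = positions_km / km_per_deg,
    transects = paste0("t:", seq_along(positions_km))))
}

test_that("the model family has exactly 15 members with correct dimensions", {
  specs <- cline_model_specs()
  expect_equal(nrow(specs), 15)
  expect_equal(sort(unique(specs$n_params)), c(2, 4, 6, 8))
  expect_equal(specs$n_params[specs$scaling == "fixed" &
                                specs$tails == "none"], 2)
  expect_equal(specs$n_params[specs$scaling == "free" &
                                specs$tails == "both"], 8)
})

test_that("transect distances are cumulative haversine km", {
  # 1 degree along the equator with Earth radius 6371 km
  st <- site_table(data.frame(site = c("a", "b", "c"),
                              lat = 0, lon = c(0, 1, 2),
                              transects = c("t:1", "t:2", "t:3")))
  d <- transect_distances(st, "t")
  expect_equal(d$km[1], 0)
  expect_equal(d$km[2], 111.19, tolerance = 1e-3)
  expect_equal(d$km[3], 2 * d$km[2], tolerance = 1e-9)
  # row order in the table is irrelevant; rank decides
  st2 <- st[c(3, 1, 2), ]
  attr(st2, "transects") <- attr(st, "transects")
  class(st2) <- class(st)
  expect_equal(transect_distances(st2, "t")$km, d$km)
})

test_that("cline prediction honours closed forms, continuity and tau semantics", {
  p <- c(center = 500, width = 40)
  expect_equal(cline_predict(500, p), 0.5)
  expect_equal(cline_predict(520, p), (1 + tanh(1)) / 2,
               tolerance = 1e-12)
  # continuity at both tail junctions
  pt <- c(center = 500, width = 40, deltaL = 30, tauL = 0.5,
          deltaR = 25, tauR = 0.7)
  for (xj in c(470, 525)) {
    lo <- cline_predict(xj - 1e-9, pt, tails = "both")
    hi <- cline_predict(xj + 1e-9, pt, tails = "both")
    expect_equal(lo, hi, tolerance = 1e-9)
  }
  expect_equal(cline_predict(470, pt, tails = "both"),
               cline_predict(470, p), tolerance = 1e-12)
  # tau = 1 gives a C1 junction: one-sided slopes agree
  p1 <- c(center = 500, width = 40, deltaL = 30, tauL = 1)
  h <- 1e-6
  slope_out <- (cline_predict(470 - h, p1, tails = "left") -
                cline_predict(470 - 2 * h, p1, tails = "left")) / h
  slope_in <- (cline_predict(470 + 2 * h, p1, tails = "left") -
               cline_predict(470 + h, p1, tails = "left")) / h
  expect_equal(slope_out, slope_in, tolerance = 1e-4)
  expect_error(cline_predict(0, c(center = 1, width = -1)), "width")
})

test_that("prediction is monotone non-decreasing for random parameter draws", {
  set.seed(42)
  grid <- seq(-200, 1200, length.out = 300)
  specs <- cline_model_specs()
  for (i in 1:100) {
    sp <- specs[sample.int(15, 1), ]
    p <- c(center = runif(1, 0, 1000), width = runif(1, 5, 400),
           pmin = runif(1, 0, 0.4), pmax = runif(1, 0.6, 1),
           deltaL = runif(1, 0, 300), tauL = runif(1, 0.05, 1),
           deltaR = runif(1, 0, 300), tauR = runif(1, 0.05, 1))
    y <- cline_predict(grid, p, sp$scaling, sp$tails)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y >= 0 - 1e-12 & y <= 1 + 1e-12))
  }
})

test_that("the MCMC recovers a known cline and reports a sane AIC", {
  taxa <- disjoint_taxa(n_loci = 6, seed = 1)
  positions <- seq(0, 1000, length.out = 15)
  set.seed(7)
  p_true <- cline_true_p(positions, 500, 40)
  k <- rbinom(15, 80, p_true)
  tr <- structure(data.frame(site = sprintf("s%02d", 1:15),
                             km = positions, freq = k / 80, n = 80),
                  class = c("transect_data", "data.frame"))
  fit <- fit_cline_mcmc(tr, "fixed", "none", iterations = 9000,
                        burnin = 1000, seed = 3)
  expect_gte(500, fit$ci["2.5%", "center"])
  expect_lte(500, fit$ci["97.5%", "center"])
  expect_equal(fit$AIC, 2 * 2 - 2 * fit$lnL, tolerance = 1e-9)
  expect_true(fit$params["width"] > 0)
})

test_that("a transition inside one inter-site gap forces a narrow cline", {
  positions <- seq(0, 1000, length.out = 10) # spacing ~111 km
  freq <- c(rep(0.01, 5), rep(0.99, 5))
  tr <- structure(data.frame(site = sprintf("s%02d", 1:10),
                             km = positions, freq = freq, n = 60),
                  class = c("transect_data", "data.frame"))
  fit <- fit_cline_mcmc(tr, "fixed", "none", iterations = 9000,
                        burnin = 1000, seed = 4)
  expect_lt(fit$params["width"], 2 * diff(positions)[1])
})

test_that("degenerate flat transects are flagged", {
  tr <- structure(data.frame(site = c("a", "b", "c"),
                             km = c(0, 10, 20), freq = 0.5, n = 10),
                  class = c("transect_data", "data.frame"))
  expect_warning(fit_cline_mcmc(tr, iterations = 200, burnin = 100,
                                seed = 1),
                 "unidentifiable")
})

test_that("posterior credible intervals contract with per-site sample size", {
  positions <- seq(0, 1000, length.out = 12)
  p_true <- cline_true_p(positions, 480, 60)
  widths <- sapply(c(20, 200), function(n) {
    mean(sapply(1:3, function(s) {
      set.seed(10 + s)
      k <- rbinom(12, n, p_true)
      tr <- structure(data.frame(site = sprintf("s%02d", 1:12),
                                 km = positions, freq = k / n, n = n),
                      class = c("transect_data", "data.frame"))
      fit <- fit_cline_mcmc(tr, iterations = 6000, burnin = 1000,
                            seed = 12 + s)
      diff(fit$ci[, "center"])
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("AIC selection table covers the requested family and the arithmetic holds", {
  positions <- seq(0, 1000, length.out = 12)
  set.seed(5)
  k <- rbinom(12, 40, cline_true_p(positions, 500, 60))
  tr <- structure(data.frame(site = sprintf("s%02d", 1:12),
                             km = positions, freq = k / 40, n = 40),
                  class = c("transect_data", "data.frame"))
  sel <- select_model_aic(tr, iterations = 1500, burnin = 500, seed = 2)
  expect_equal(nrow(sel$table), 15)
  expect_equal(sel$table$AIC, 2 * sel$table$k - 2 * sel$table$lnL,
               tolerance = 1e-9)
  expect_equal(sel$table$AIC, sort(sel$table$AIC))
})

test_that("the cline envelope brackets the maximum-likelihood curve", {
  positions <- seq(0, 600, length.out = 10)
  set.seed(9)
  k <- rbinom(10, 50, cline_true_p(positions, 300, 50))
  tr <- structure(data.frame(site = sprintf("s%02d", 1:10),
                             km = positions, freq = k / 50, n = 50),
                  class = c("transect_data", "data.frame"))
  fit <- fit_cline_mcmc(tr, iterations = 4000, burnin = 1000, seed = 6)
  env <- cline_envelope(fit)
  expect_true(all(env$q2.5 <= env$q97.5 + 1e-12))
  ml <- cline_predict(env$km, fit$params)
  expect_gt(mean(ml >= env$q2.5 - 0.05 & ml <= env$q97.5 + 0.05), 0.95)
})
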