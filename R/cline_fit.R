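# Equilibrium geographic cline models: a tanh sigmoid centre with
# optional exponential introgression tails and three frequency-scaling
# variants (the classical 15-model family), fitted to per-site
# frequencies by Metropolis-Hastings MCMC with AIC model selection.

#' The 15 cline model specifications
#'
#' The 3 x 5 grid of scaling (`fixed` 0..1, `observed` min..max of the
#' data, `free` pMin/pMax estimated) by tails (`none`, `left`, `right`,
#' `mirror` — one shared tail on both sides — and `both`).
#'
#' @return A `data.frame` with columns `scaling`, `tails`, `n_params`.
#' @export
cline_model_specs <- function() {
  grid <- expand.grid(scaling = c("fixed", "observed", "free"),
                      tails = c("none", "left", "right", "mirror", "both"),
                      stringsAsFactors = FALSE)
  grid$n_params <- 2 +
    ifelse(grid$scaling == "free", 2, 0) +
    c(none = 0, left = 2, right = 2, mirror = 2, both = 4)[grid$tails]
  grid
}

#' Cumulative transect distances from site coordinates
#'
#' Orders the member sites of a transect by rank and accumulates
#' great-circle (haversine, Earth radius 6371 km) segment distances from
#' the first (reference) site.
#'
#' @param sites A `site_table` with transect memberships.
#' @param transect Transect name.
#' @return `data.frame(site, rank, km)` ordered by rank.
#' @export
transect_distances <- function(sites, transect) {
  tr <- attr(sites, "transects")
  tr <- tr[tr$transect == transect, ]
  if (nrow(tr) < 3) stop_pondmix("transect '", transect,
                                 "' needs >= 3 member sites")
  tr <- tr[order(tr$rank), ]
  idx <- match(tr$site, sites$site)
  if (anyNA(idx))
    stop_pondmix("transect site(s) missing from the site table: ",
                 paste(tr$site[is.na(idx)], collapse = ", "))
  lat <- sites$lat[idx]; lon <- sites$lon[idx]
  if (anyNA(lat) || anyNA(lon))
    stop_pondmix("missing coordinate for site(s): ",
                 paste(tr$site[is.na(lat) | is.na(lon)], collapse = ", "))
  seg <- c(0, haversine_km(lon[-length(lon)], lat[-length(lat)],
                           lon[-1], lat[-1]))
  data.frame(site = tr$site, rank = tr$rank, km = cumsum(seg),
             stringsAsFactors = FALSE)
}

#' Assemble a transect dataset for cline fitting
#'
#' Joins transect distances with per-site observed frequencies (mean Q
#' for nuclear data, lineage haplotype frequency for mtDNA) and
#' effective counts.  Sites lacking marker data are dropped from the
#' transect.  For mean-Q data the effective count is `2 x` individuals
#' (two nuclear lineages each); pass haploid counts for mtDNA.
#'
#' @param sites A `site_table`.
#' @param transect Transect name.
#' @param freq_table `data.frame(site, freq, n)`.
#' @return A `transect_data` data.frame: `site`, `km`, `freq`, `n`.
#' @export
transect_data <- function(sites, transect, freq_table) {
  d <- transect_distances(sites, transect)
  m <- merge(d, freq_table, by = "site", sort = FALSE)
  m <- m[order(m$km), c("site", "km", "freq", "n")]
  if (any(m$freq < 0 | m$freq > 1)) stop_pondmix("frequencies outside [0,1]")
  if (any(m$n < 1)) stop_pondmix("effective counts must be >= 1")
  rownames(m) <- NULL
  class(m) <- c("transect_data", "data.frame")
  m
}

#' Evaluate a cline model
#'
#' The central shape is `f(x) = (1 + tanh(2 (x - c) / w)) / 2`.  Beyond
#' a tail junction (`c - deltaL` on the left, `c + deltaR` on the
#' right) the curve follows an exponential that matches the sigmoid's
#' value at the junction, with slope `tau` times the sigmoid's junction
#' slope: `tau = 1` keeps the curve C1-continuous, `tau < 1` flattens
#' the tail into a longer shoulder of introgression.  Finally the
#' frequency is rescaled to `pMin + (pMax - pMin) f(x)`.
#'
#' @param x Position(s) in km.
#' @param params Named vector/list: `center`, `width`, and as applicable
#'   `pmin`, `pmax`, `deltaL`, `tauL`, `deltaR`, `tauR` (for `mirror`
#'   tails supply `deltaL`/`tauL`; they are used on both sides).
#' @param scaling `"fixed"`, `"observed"` or `"free"`; for `observed`
#'   and `free`, `pmin`/`pmax` must be present in `params`.
#' @param tails `"none"`, `"left"`, `"right"`, `"mirror"` or `"both"`.
#' @return Frequencies at `x`.
#' @export
cline_predict <- function(x, params, scaling = "fixed", tails = "none") {
  p <- as.list(params)
  cc <- p$center; w <- p$width
  if (is.null(w) || w <= 0) stop_pondmix("width must be > 0")
  f <- (1 + tanh(2 * (x - cc) / w)) / 2
  sig_val <- function(z) (1 + tanh(2 * (z - cc) / w)) / 2
  sig_slope <- function(z) (1 / w) / cosh(2 * (z - cc) / w)^2
  if (tails %in% c("left", "mirror", "both")) {
    dl <- p$deltaL; tl <- p$tauL
    xj <- cc - dl
    fj <- sig_val(xj); sj <- sig_slope(xj)
    left <- x < xj
    if (any(left) && fj > 0)
      f[left] <- fj * exp(tl * sj * (x[left] - xj) / fj)
  }
  if (tails %in% c("right", "both") ||
      (tails == "mirror")) {
    dr <- if (tails == "mirror") p$deltaL else p$deltaR
    tr <- if (tails == "mirror") p$tauL else p$tauR
    xj <- cc + dr
    fj <- sig_val(xj); sj <- sig_slope(xj)
    right <- x > xj
    if (any(right) && fj < 1)
      f[right] <- 1 - (1 - fj) * exp(-tr * sj * (x[right] - xj) / (1 - fj))
  }
  if (scaling == "fixed") {
    pmin_ <- 0; pmax_ <- 1
  } else {
    pmin_ <- p$pmin; pmax_ <- p$pmax
    if (is.null(pmin_) || is.null(pmax_))
      stop_pondmix("scaling '", scaling, "' needs pmin and pmax")
  }
  pmin_ + (pmax_ - pmin_) * f
}

# parameter bookkeeping for one model spec on one transect ------------

cline_par_names <- function(scaling, tails) {
  nm <- c("center", "width")
  if (scaling == "free") nm <- c(nm, "pmin", "pmax")
  nm <- switch(tails,
               none = nm,
               left = c(nm, "deltaL", "tauL"),
               right = c(nm, "deltaR", "tauR"),
               mirror = c(nm, "deltaL", "tauL"),
               both = c(nm, "deltaL", "tauL", "deltaR", "tauR"))
  nm
}

# uniform prior bounds on the natural scale (width handled log-uniform)
cline_par_bounds <- function(nm, span, x0) {
  lo <- c(center = x0 - 0.5 * span, width = 0.1, pmin = 0, pmax = 0,
          deltaL = 0, tauL = 1e-6, deltaR = 0, tauR = 1e-6)
  hi <- c(center = x0 + 1.5 * span, width = 2 * span, pmin = 1, pmax = 1,
          deltaL = span, tauL = 1, deltaR = span, tauR = 1)
  list(lo = lo[nm], hi = hi[nm])
}

cline_loglik <- function(theta, nm, k, n, x, scaling, tails, obs_range) {
  params <- as.list(setNames(theta, nm))
  if (scaling == "observed") {
    params$pmin <- obs_range[1]; params$pmax <- obs_range[2]
  }
  if (!is.null(params$pmin) && params$pmin >= params$pmax) return(-Inf)
  p <- cline_predict(x, params, scaling, tails)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(dbinom(k, n, p, log = TRUE))
}

#' Fit one cline model by Metropolis-Hastings MCMC
#'
#' Site `i` contributes a binomial likelihood
#' `Binom(k_i | n_i, p(x_i))` with `k_i = round(freq_i n_i)`.  Priors
#' are uniform: centre over the transect span expanded by half a span on
#' each side, width log-uniform on `[0.1, 2 span]` km, tail distances
#' uniform on `[0, span]`, tail slope ratios and scaling bounds uniform
#' on `(0, 1]`.  Proposals are joint Gaussians whose scales adapt during
#' burn-in only; after sampling the best state is polished by
#' Nelder-Mead to stabilise the maximum likelihood entering the AIC.
#'
#' @param transect A [transect_data()] data.frame.
#' @param scaling,tails Model specification (see [cline_model_specs()]).
#' @param iterations Post-burn-in iterations (study default 90000).
#' @param burnin Burn-in iterations (study default 10000).
#' @param seed Integer seed.
#' @return A `cline_fit`: `params` (max-likelihood estimates), `lnL`,
#'   `AIC`, `n_params`, `ci` (95% credible intervals), `samples`
#'   (thinned posterior draws), `degenerate` flag, `scaling`, `tails`.
#' @export
fit_cline_mcmc <- function(transect, scaling = "fixed", tails = "none",
                           iterations = 90000, burnin = 10000, seed = 1) {
  x <- transect$km; n <- round(transect$n)
  k <- round(transect$freq * transect$n)
  degenerate <- length(unique(transect$freq)) == 1
  if (degenerate)
    warning("all site frequencies identical: cline width unidentifiable",
            call. = FALSE)
  span <- max(x) - min(x)
  nm <- cline_par_names(scaling, tails)
  bounds <- cline_par_bounds(nm, span, min(x))
  obs_range <- range(transect$freq)
  if (scaling == "observed" && obs_range[1] == obs_range[2])
    obs_range <- obs_range + c(-1e-6, 1e-6)
  set.seed(seed)
  # initial state: centre at the steepest observed step
  dif <- abs(diff(transect$freq))
  c0 <- if (any(dif > 0)) mean(x[which.max(dif) + 0:1]) else mean(x)
  init <- c(center = c0, width = span / 4, pmin = 0.05, pmax = 0.95,
            deltaL = span / 4, tauL = 0.5, deltaR = span / 4, tauR = 0.5)
  theta <- init[nm]
  # log-uniform width prior: sample and propose on log(width)
  to_sampler <- function(th) { th["width"] <- log(th["width"]); th }
  from_sampler <- function(th) { th["width"] <- exp(th["width"]); th }
  lo_s <- to_sampler(bounds$lo); hi_s <- to_sampler(bounds$hi)
  logpost <- function(th_s) {
    if (any(th_s < lo_s - 1e-12) || any(th_s > hi_s + 1e-12)) return(-Inf)
    cline_loglik(from_sampler(th_s), nm, k, n, x, scaling, tails,
                 obs_range)
  }
  th <- to_sampler(theta)
  lp <- logpost(th)
  d <- length(th)
  scale <- pmax((hi_s - lo_s) / 50, 1e-6)
  total <- burnin + iterations
  # keep every draw up to 1e5; quantile endpoints suffer under thinning
  thin <- max(1, ceiling(iterations / 1e5))
  samples <- matrix(NA_real_, ceiling(iterations / thin), d,
                    dimnames = list(NULL, nm))
  s_i <- 0
  best <- th; best_lp <- lp
  acc <- 0; window <- 0
  for (it in seq_len(total)) {
    prop <- th + rnorm(d) * scale
    lp_prop <- logpost(prop)
    if (log(runif(1)) < lp_prop - lp) {
      th <- prop; lp <- lp_prop; acc <- acc + 1
      if (lp > best_lp) { best <- th; best_lp <- lp }
    }
    window <- window + 1
    if (it <= burnin && window == 100) { # adapt during burn-in only
      rate <- acc / window
      scale <- scale * exp(rate - 0.3)
      acc <- 0; window <- 0
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      s_i <- s_i + 1
      samples[s_i, ] <- from_sampler(th)
    }
  }
  samples <- samples[seq_len(s_i), , drop = FALSE]
  # polish the ML point for a stable AIC
  if (d > 1) {
    op <- optim(best, function(z) -logpost(z), method = "Nelder-Mead",
                control = list(maxit = 500))
    if (-op$value > best_lp) { best <- op$par; best_lp <- -op$value }
  }
  params <- from_sampler(setNames(best, nm))
  ci <- apply(samples, 2, quantile, probs = c(0.025, 0.975))
  if (length(nm) == 2 && !degenerate) {
    # two-parameter models (centre, width): marginal credible intervals
    # by exact quadrature over the prior box, free of MCMC quantile
    # noise; the sampled draws still feed the fuzzy envelope
    qci <- cline_quad_ci(samples, lo_s, hi_s, k, n, x, scaling, tails,
                         obs_range)
    if (!is.null(qci)) ci <- qci
  }
  structure(list(params = params, lnL = best_lp,
                 AIC = 2 * length(nm) - 2 * best_lp,
                 n_params = length(nm), ci = ci, samples = samples,
                 degenerate = degenerate, scaling = scaling,
                 tails = tails, obs_range = obs_range,
                 transect = transect, seed = seed),
            class = "cline_fit")
}

# Exact marginal 95% credible intervals for the two-parameter cline
# models by trapezoid quadrature on a (centre, log width) grid.  The
# grid window comes from the posterior draws (expanded), clamped to the
# prior box; uniform priors make the posterior proportional to the
# likelihood on this grid.
cline_quad_ci <- function(samples, lo_s, hi_s, k, n, x, scaling, tails,
                          obs_range) {
  cs_rng <- range(samples[, "center"])
  cw <- diff(cs_rng)
  cs <- seq(max(lo_s["center"], cs_rng[1] - cw),
            min(hi_s["center"], cs_rng[2] + cw), length.out = 601)
  lw_rng <- range(log(samples[, "width"]))
  lws <- seq(max(lo_s["width"], lw_rng[1] - 1),
             min(hi_s["width"], lw_rng[2] + 1), length.out = 301)
  if (length(unique(cs)) < 2 || length(unique(lws)) < 2) return(NULL)
  ll <- matrix(-Inf, length(cs), length(lws))
  pm <- if (scaling == "fixed") c(0, 1) else obs_range
  for (j in seq_along(lws)) {
    w <- exp(lws[j])
    # frequencies for every centre at once: sites x centres
    f <- (1 + tanh(2 * outer(x, cs, "-") / w)) / 2
    p <- pm[1] + (pm[2] - pm[1]) * f
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    ll[, j] <- colSums(dbinom(k, n, p, log = TRUE))
  }
  post <- exp(ll - max(ll))
  marg_ci <- function(weights, grid) {
    wsum <- sum(weights)
    if (!is.finite(wsum) || wsum <= 0) return(NULL)
    cdf <- cumsum(weights) / wsum
    c(grid[which(cdf >= 0.025)[1]], grid[which(cdf >= 0.975)[1]])
  }
  ci_c <- marg_ci(rowSums(post), cs)
  ci_w <- marg_ci(colSums(post), exp(lws))
  if (is.null(ci_c) || is.null(ci_w)) return(NULL)
  out <- cbind(center = ci_c, width = ci_w)
  rownames(out) <- c("2.5%", "97.5%")
  out
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("cline_fit [%s scaling, %s tails]: centre %.2f km (95%% CI %.2f-%.2f), width %.2f km (%.2f-%.2f), AIC %.2f\n",
              x$scaling, x$tails, x$params["center"],
              x$ci["2.5%", "center"], x$ci["97.5%", "center"],
              x$params["width"], x$ci["2.5%", "width"],
              x$ci["97.5%", "width"], x$AIC))
  invisible(x)
}

#' Posterior cline envelope
#'
#' Per-position credible band of the fitted frequency ("fuzzy cline"):
#' quantiles of `p(x)` over the posterior draws.
#'
#' @param fit A `cline_fit`.
#' @param x_grid Positions (km); default 101 points over the transect.
#' @param probs Quantiles (default 2.5%, 50%, 97.5%).
#' @return `data.frame(km, lower, median, upper)` (for default probs).
#' @export
cline_envelope <- function(fit, x_grid = NULL,
                           probs = c(0.025, 0.5, 0.975)) {
  if (is.null(x_grid))
    x_grid <- seq(min(fit$transect$km), max(fit$transect$km),
                  length.out = 101)
  draws <- fit$samples
  idx <- seq_len(min(nrow(draws), 500))
  pm <- vapply(idx, function(i) {
    params <- as.list(draws[i, ])
    if (fit$scaling == "observed") {
      params$pmin <- fit$obs_range[1]; params$pmax <- fit$obs_range[2]
    }
    cline_predict(x_grid, params, fit$scaling, fit$tails)
  }, numeric(length(x_grid)))
  qs <- apply(pm, 1, quantile, probs = probs)
  out <- data.frame(km = x_grid, t(qs))
  names(out) <- c("km", paste0("q", probs * 100))
  out
}

#' AIC model selection over the cline model family
#'
#' Fits every requested model specification and ranks by
#' `AIC = 2 k - 2 lnL_max`; ties break toward fewer parameters.
#'
#' @param transect A [transect_data()] data.frame.
#' @param specs Model grid (default all 15 from [cline_model_specs()]).
#' @param iterations,burnin MCMC budget per model.
#' @param seed Integer seed (fanned out per model).
#' @return List: `best` (the winning `cline_fit`), `table` (AIC table,
#'   one row per spec, sorted), `fits` (all fits).
#' @export
select_model_aic <- function(transect, specs = cline_model_specs(),
                             iterations = 18000, burnin = 2000,
                             seed = 1) {
  if (nrow(specs) < 2) stop_pondmix("need >= 2 model specs")
  fits <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    fits[[i]] <- fit_cline_mcmc(transect, specs$scaling[i],
                                specs$tails[i], iterations, burnin,
                                seed = seed_stream(seed, paste0("m", i)))
  }
  tab <- data.frame(scaling = specs$scaling, tails = specs$tails,
                    k = vapply(fits, `[[`, 0L, "n_params"),
                    lnL = vapply(fits, `[[`, 0, "lnL"),
                    AIC = vapply(fits, `[[`, 0, "AIC"),
                    stringsAsFactors = FALSE)
  ord <- order(tab$AIC, tab$k)
  best_i <- ord[1]
  list(best = fits[[best_i]], table = tab[ord, ], fits = fits,
       best_index = best_i)
}
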