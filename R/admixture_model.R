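# Maximum-likelihood admixture model: EM estimation of individual
# ancestry proportions Q and cluster allele frequencies under
# independent frequencies, with Evanno delta-K cluster-number selection
# over replicate runs.

# flatten a genotype table into allele-copy records with a global allele
# column index (loci laid out in consecutive blocks)
copy_layout <- function(gt) {
  n <- length(gt$individuals); L <- length(gt$loci)
  allele_sets <- lapply(seq_len(L), function(l) {
    a <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    a[!is.na(a)]
  })
  sizes <- vapply(allele_sets, length, 0L)
  offset <- c(0, cumsum(sizes))[seq_len(L)]
  ind <- integer(); col <- integer()
  for (l in seq_len(L)) {
    for (mat in list(gt$a1, gt$a2)) {
      ok <- which(!is.na(mat[, l]))
      ind <- c(ind, ok)
      col <- c(col, offset[l] + match(mat[ok, l], allele_sets[[l]]))
    }
  }
  colnames_ <- unlist(lapply(seq_len(L), function(l)
    paste0(gt$loci[l], ":", allele_sets[[l]])))
  list(ind = ind, col = col, n = n, n_col = sum(sizes),
       locus_of_col = rep(seq_len(L), sizes), col_names = colnames_,
       copies_per_ind = tabulate(ind, n))
}

#' Fit the EM admixture model
#'
#' Maximises the admixture likelihood in which allele copy `a` at locus
#' `l` of individual `i` has probability `sum_k q_ik f_kla`, treating
#' copies as independent (unlinked loci, unphased genotypes); missing
#' copies contribute nothing.  Q is initialised from a flat Dirichlet,
#' cluster frequencies from jittered empirical frequencies.  EM
#' guarantees a non-decreasing log-likelihood; iteration stops when the
#' gain drops below `tol` or at `max_iter`.
#'
#' @param gt A [genotype_table()].
#' @param K Number of clusters (>= 1).
#' @param seed Integer seed (initialisation).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @return An `ancestry_result`: `K`, `Q` (individuals x clusters, rows
#'   on the simplex), `F` (clusters x locus:allele frequency matrix,
#'   each locus block a simplex per cluster), `lnL`, `lnL_trace`,
#'   `iterations`, `converged`, `seed`, plus the individual ids and
#'   their site labels for downstream per-site summaries.
#' @export
fit_admixture <- function(gt, K, seed = 1, max_iter = 2000, tol = 1e-6) {
  stopifnot(K >= 1, tol > 0)
  n <- length(gt$individuals)
  if (K > n) stop_pondmix("K exceeds the number of individuals")
  lay <- copy_layout(gt)
  if (any(lay$copies_per_ind == 0))
    stop_pondmix("individual(s) with no scored loci: ",
                 paste(gt$individuals[lay$copies_per_ind == 0],
                       collapse = ", "))
  set.seed(seed)
  Q <- t(vapply(seq_len(n), function(i) rdirichlet1(rep(1, K)),
                numeric(K)))
  if (K == 1) Q <- matrix(1, n, 1)
  counts <- tabulate(lay$col, lay$n_col)
  Fmat <- matrix(0, K, lay$n_col)
  for (k in seq_len(K)) {
    for (l in unique(lay$locus_of_col)) {
      blk <- which(lay$locus_of_col == l)
      Fmat[k, blk] <- rdirichlet1(counts[blk] + 0.5)
    }
  }
  trace <- numeric(0)
  lnL_prev <- -Inf
  iter <- 0; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    R <- Q[lay$ind, , drop = FALSE] * t(Fmat[, lay$col, drop = FALSE])
    rs <- rowSums(R)
    lnL <- sum(log(pmax(rs, 1e-300)))
    R <- R / pmax(rs, 1e-300)
    trace <- c(trace, lnL)
    if (lnL - lnL_prev < tol && iter > 1) { converged <- TRUE; break }
    lnL_prev <- lnL
    # M-step
    Q <- rowsum(R, lay$ind) / lay$copies_per_ind
    Tm <- rowsum(R, factor(lay$col, levels = seq_len(lay$n_col)))
    Tm[is.na(Tm)] <- 0
    for (l in unique(lay$locus_of_col)) {
      blk <- which(lay$locus_of_col == l)
      for (k in seq_len(K)) {
        s <- sum(Tm[blk, k])
        Fmat[k, blk] <- if (s > 0) Tm[blk, k] / s
                        else rep(1 / length(blk), length(blk))
      }
    }
    Q <- pmax(Q, 1e-12); Q <- Q / rowSums(Q)
    Fmat <- pmax(Fmat, 1e-12)
    for (l in unique(lay$locus_of_col)) {
      blk <- which(lay$locus_of_col == l)
      Fmat[, blk] <- Fmat[, blk, drop = FALSE] /
        rowSums(Fmat[, blk, drop = FALSE])
    }
  }
  rownames(Q) <- gt$individuals
  colnames(Fmat) <- lay$col_names
  structure(list(K = K, Q = Q, F = Fmat, lnL = trace[length(trace)],
                 lnL_trace = trace, iterations = length(trace),
                 converged = converged, seed = seed,
                 individuals = gt$individuals, site = gt$site),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("ancestry_result: K = %d, %d individuals, lnL = %.2f (%d iterations%s)\n",
              x$K, nrow(x$Q), x$lnL, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Replicate admixture runs and Evanno delta-K selection
#'
#' Fits `n_reps` seeds for every K in `K_range` and computes
#' `deltaK(K) = |mean lnL(K-1) - 2 mean lnL(K) + mean lnL(K+1)| / sd(lnL(K))`,
#' selecting the interior K with the largest delta-K.  A zero
#' replicate SD leaves delta-K undefined at that K (flagged).
#'
#' @param gt A [genotype_table()].
#' @param K_range Contiguous integer range of K values.
#' @param n_reps Replicates per K (default 10).
#' @param seeds Optional matrix/vector of seeds; default derives them
#'   from `seed` via [seed_stream()].
#' @param seed Master seed used when `seeds` is NULL.
#' @param ... Passed to [fit_admixture()] (e.g. `max_iter`, `tol`).
#' @return A `k_selection` list: `K_range`, `lnL` (replicates x K),
#'   `mean_lnL`, `sd_lnL`, `deltaK`, `selected_K`, `flags`, and
#'   `best_fit` (the best-likelihood [fit_admixture()] result per K).
#' @export
run_replicates <- function(gt, K_range, n_reps = 10, seeds = NULL,
                           seed = 1, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) > 1 && any(diff(K_range) != 1))
    stop_pondmix("K_range must be contiguous")
  if (n_reps < 3) stop_pondmix("need n_reps >= 3 for a replicate SD")
  if (is.null(seeds))
    seeds <- matrix(vapply(seq_len(n_reps * length(K_range)), function(i)
      seed_stream(seed, paste0("rep", i)), 0L), n_reps)
  lnL <- matrix(NA_real_, n_reps, length(K_range),
                dimnames = list(NULL, paste0("K", K_range)))
  best <- vector("list", length(K_range))
  for (j in seq_along(K_range)) {
    for (r in seq_len(n_reps)) {
      fit <- fit_admixture(gt, K_range[j], seed = seeds[r, j], ...)
      lnL[r, j] <- fit$lnL
      if (is.null(best[[j]]) || fit$lnL > best[[j]]$lnL) best[[j]] <- fit
    }
  }
  mu <- colMeans(lnL); sdv <- apply(lnL, 2, sd)
  deltaK <- rep(NA_real_, length(K_range))
  flags <- character(0)
  for (j in seq_along(K_range)) {
    if (j == 1 || j == length(K_range)) next # interior only
    sd_j <- sdv[j]
    if (sd_j <= 1e-8) {
      # all replicates converged to one optimum: the Evanno ratio is
      # formally undefined, but zero spread with non-zero curvature is
      # overwhelming support, so a small SD floor stands in
      flags <- c(flags, sprintf(
        "K=%d: replicate SD ~ 0, deltaK computed with SD floor 1e-6",
        K_range[j]))
      sd_j <- 1e-6
    }
    deltaK[j] <- abs(mu[j - 1] - 2 * mu[j] + mu[j + 1]) / sd_j
  }
  selected <- if (all(is.na(deltaK))) {
    flags <- c(flags, "no interior K with defined deltaK; selected by mean lnL")
    K_range[which.max(mu)]
  } else K_range[which.max(deltaK)]
  structure(list(K_range = K_range, lnL = lnL, mean_lnL = mu,
                 sd_lnL = sdv, deltaK = deltaK, selected_K = selected,
                 flags = flags, best_fit = setNames(best,
                                                    paste0("K", K_range))),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Evanno delta-K selection\n")
  print(data.frame(K = x$K_range, mean_lnL = x$mean_lnL,
                   sd_lnL = x$sd_lnL, deltaK = x$deltaK))
  cat("selected K =", x$selected_K, "\n")
  invisible(x)
}

#' Align cluster labels across replicate runs
#'
#' Cluster labels are arbitrary per run; this permutes each result's
#' clusters to best match a reference replicate (the first), minimising
#' the summed squared difference between cluster allele-frequency
#' matrices (exhaustive over permutations for K <= 7, greedy beyond).
#'
#' @param results List of `ancestry_result` objects with equal K.
#' @return The list with Q columns / F rows permuted; each result gains
#'   a `permutation` element.
#' @export
align_labels <- function(results) {
  K <- results[[1]]$K
  for (r in results) if (r$K != K)
    stop_pondmix("all results must share one K")
  if (K == 1 || length(results) == 1) {
    return(lapply(results, function(r) { r$permutation <- seq_len(K); r }))
  }
  ref <- results[[1]]$F
  lapply(seq_along(results), function(i) {
    r <- results[[i]]
    perm <- if (i == 1) seq_len(K) else best_permutation(ref, r$F)
    r$Q <- r$Q[, perm, drop = FALSE]
    r$F <- r$F[perm, , drop = FALSE]
    r$permutation <- perm
    r
  })
}

best_permutation <- function(ref, Fmat) {
  K <- nrow(ref)
  cost <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    cost[a, b] <- sum((ref[a, ] - Fmat[b, ])^2)
  if (K <= 7) {
    perms <- permutations_of(K)
    costs <- vapply(perms, function(p)
      sum(cost[cbind(seq_len(K), p)]), 0)
    perms[[which.min(costs)]]
  } else {
    # greedy assignment
    perm <- integer(K); used <- logical(K)
    for (a in order(apply(cost, 1, min))) {
      b <- order(cost[a, ])
      b <- b[!used[b]][1]
      perm[a] <- b; used[b] <- TRUE
    }
    perm
  }
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1)
  out <- list()
  for (p in sub) for (pos in seq_len(K)) {
    out[[length(out) + 1]] <- append(p, K, after = pos - 1)
  }
  out
}

#' Mean ancestry proportion per site
#'
#' Arithmetic mean of one cluster's Q over the individuals sampled at
#' each site — the per-population cline input.
#'
#' @param result An `ancestry_result` (must carry site labels).
#' @param sites Optional `site_table`; sites listed there but without
#'   sampled individuals are omitted with a warning.
#' @param cluster Cluster index (default 1).
#' @return `data.frame(site, mean_Q, n)`.
#' @export
mean_q_per_site <- function(result, sites = NULL, cluster = 1) {
  if (anyNA(result$site))
    stop_pondmix("every individual must be mapped to a site")
  q <- result$Q[, cluster]
  agg <- aggregate(q, by = list(site = result$site),
                   FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(site = agg$site, mean_Q = agg$x[, 1],
                    n = as.integer(agg$x[, 2]), stringsAsFactors = FALSE)
  if (!is.null(sites)) {
    missing_sites <- setdiff(sites$site, out$site)
    if (length(missing_sites))
      warning("site(s) without sampled individuals omitted: ",
              paste(missing_sites, collapse = ", "), call. = FALSE)
    out <- out[match(intersect(sites$site, out$site), out$site), ]
  }
  rownames(out) <- NULL
  out
}

#' Cap local sample sizes by random subsampling
#'
#' Sites contributing `trigger` (default 25) or more individuals are
#' reduced to `max_n` (default 20) by seeded sampling without
#' replacement; smaller sites are untouched.  Guards clustering against
#' uneven sampling.
#'
#' @param gt A [genotype_table()].
#' @param max_n Retained individuals per large site.
#' @param trigger Site size at which subsampling kicks in.
#' @param seed Integer seed.
#' @return A [genotype_table()].
#' @export
subsample_sites <- function(gt, max_n = 20, trigger = 25, seed = 1) {
  stopifnot(max_n >= 1)
  set.seed(seed)
  keep <- logical(length(gt$individuals))
  for (s in unique(gt$site)) {
    wh <- which(gt$site == s | (is.na(gt$site) & is.na(s)))
    if (length(wh) >= trigger) {
      keep[sample(wh, max_n)] <- TRUE
    } else keep[wh] <- TRUE
  }
  subset_individuals(gt, keep)
}

#' Long-format ancestry table for bar plots
#'
#' One row per individual x cluster, ordered by site and then by
#' descending cluster-1 membership within site (the conventional
#' ancestry bar-plot layout).
#'
#' @param result An `ancestry_result`.
#' @return `data.frame(id, site, cluster, Q)`.
#' @export
q_long_format <- function(result) {
  ord <- order(result$site, -result$Q[, 1])
  out <- do.call(rbind, lapply(ord, function(i)
    data.frame(id = result$individuals[i], site = result$site[i],
               cluster = paste0("Q", seq_len(result$K)),
               Q = unname(result$Q[i, ]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
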