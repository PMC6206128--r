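# Diversity and divergence statistics: per-group diversity indices,
# multi-locus Weir-Cockerham theta, one-level AMOVA, dosage PCA and a
# null-allele screen with Brookfield's estimator.

resolve_groups <- function(gt_or_aln, groups) {
  ids <- if (inherits(gt_or_aln, "genotype_table")) gt_or_aln$individuals
         else names(gt_or_aln)
  if (!is.null(names(groups))) groups <- groups[ids]
  if (length(groups) != length(ids))
    stop_pondmix("groups must map every individual")
  if (anyNA(groups)) stop_pondmix("group label missing for some individuals")
  as.character(groups)
}

#' Allele counts and frequencies per locus
#'
#' @param gt A [genotype_table()].
#' @param which Optional logical/integer index of individuals.
#' @return A list per locus of named allele-count vectors; attribute
#'   `n_genes` gives the number of scored allele copies per locus.  If
#'   `gt` carries a null-allele correction (see [correct_for_nulls()]),
#'   frequencies derived from these counts should be scaled by
#'   `1 - r_hat`; the raw counts are returned unchanged.
#' @export
allele_counts <- function(gt, which = NULL) {
  if (is.null(which)) which <- seq_along(gt$individuals)
  out <- vector("list", length(gt$loci))
  n_genes <- integer(length(gt$loci))
  for (l in seq_along(gt$loci)) {
    al <- c(gt$a1[which, l], gt$a2[which, l])
    al <- al[!is.na(al)]
    out[[l]] <- if (length(al)) table(al) else table(integer())
    n_genes[l] <- length(al)
  }
  names(out) <- gt$loci
  attr(out, "n_genes") <- n_genes
  out
}

# observed and Nei-unbiased expected heterozygosity per locus for a set
# of individuals; returns a data.frame(locus, n, ho, he)
het_by_locus <- function(gt, which = NULL) {
  if (is.null(which)) which <- seq_along(gt$individuals)
  L <- length(gt$loci)
  n <- integer(L); ho <- rep(NA_real_, L); he <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    g1 <- gt$a1[which, l]; g2 <- gt$a2[which, l]
    ok <- !is.na(g1)
    n[l] <- sum(ok)
    if (n[l] == 0) next
    ho[l] <- mean(g1[ok] != g2[ok])
    p <- table(c(g1[ok], g2[ok])) / (2 * n[l])
    he[l] <- if (n[l] > 1) 2 * n[l] / (2 * n[l] - 1) * (1 - sum(p^2))
             else NA_real_
  }
  data.frame(locus = gt$loci, n = n, ho = ho, he = he,
             stringsAsFactors = FALSE)
}

# expected number of distinct alleles in a draw of g genes (rarefaction)
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  if (N == 0) return(NA_real_)
  g <- min(g, N)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

# pairwise sequence differences: returns matrix of counts of differing
# positions where both sequences are called (A/C/G/T)
seq_diff_matrix <- function(aln) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(d)
  # invariant columns contribute no differences: drop them up front
  neq <- m != matrix(m[1, ], nrow(m), ncol(m), byrow = TRUE)
  m <- m[, colSums(neq) > 0, drop = FALSE]
  if (!ncol(m)) return(d)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp])
  }
  d
}

# number of segregating sites among a set of sequences (N/- ignored)
segregating_sites <- function(aln, which = NULL) {
  m <- alignment_matrix(aln)
  if (!is.null(which)) m <- m[which, , drop = FALSE]
  sum(apply(m, 2, function(col) {
    b <- unique(col[col %in% c("A", "C", "G", "T")])
    length(b) > 1
  }))
}

#' Per-group diversity indices
#'
#' For microsatellites: sample size `n`, total (`n_A`), mean per-locus
#' (`n_mean`) and private (`n_P`) allele counts, rarefied allelic
#' richness `AR`, observed (`H_O`) and Nei-unbiased expected (`H_E`)
#' heterozygosity averaged over loci, and `F_IS = 1 - H_O / H_E`.  For
#' sequences: segregating sites `S`, haplotype count `h`, private
#' haplotypes `h_P`, haplotype diversity `Hd = n/(n-1) (1 - sum f^2)`
#' and nucleotide diversity `pi` (mean pairwise differences per site).
#'
#' @param gt Optional [genotype_table()].
#' @param aln Optional `sequence_alignment`.
#' @param groups Group label per individual (named or positional); for
#'   `aln`, labels are matched to sequence names.
#' @param rarefaction_size Diploid rarefaction size (individuals); the
#'   default is the smallest per-group minimum count of complete
#'   genotypes across loci.
#' @return A `data.frame`, one row per group.  Loci that are entirely
#'   missing within a group are skipped with a warning and listed in the
#'   attribute `skipped_loci`.
#' @export
diversity_indices <- function(gt = NULL, aln = NULL, groups,
                              rarefaction_size = NULL) {
  out <- NULL; skipped <- list()
  if (!is.null(gt)) {
    gr <- resolve_groups(gt, groups)
    glev <- unique(gr)
    counts_by_group <- lapply(glev, function(g)
      allele_counts(gt, which = gr == g))
    names(counts_by_group) <- glev
    if (is.null(rarefaction_size)) {
      ml <- vapply(glev, function(g) {
        h <- het_by_locus(gt, which = gr == g)
        min(h$n[h$n > 0])
      }, 0)
      rarefaction_size <- max(1, min(ml))
    }
    rows <- lapply(glev, function(g) {
      wh <- gr == g
      if (!any(wh)) stop_pondmix("empty group: ", g)
      h <- het_by_locus(gt, which = wh)
      if (any(h$n == 0)) {
        skipped[[g]] <<- h$locus[h$n == 0]
        warning("group ", g, ": all-missing locus skipped: ",
                paste(h$locus[h$n == 0], collapse = ", "), call. = FALSE)
      }
      use <- h$n > 0
      cnt <- counts_by_group[[g]]
      others <- unlist(lapply(setdiff(glev, g), function(o)
        unlist(lapply(seq_along(gt$loci), function(l)
          paste0(gt$loci[l], ":",
                 names(counts_by_group[[o]][[l]]))))))
      own <- unlist(lapply(seq_along(gt$loci), function(l)
        paste0(gt$loci[l], ":", names(cnt[[l]]))))
      nA <- sum(vapply(cnt, length, 0L))
      ar <- mean(vapply(cnt[use], rarefied_richness,
                        0, g = 2 * rarefaction_size))
      data.frame(group = g, n = sum(wh), n_A = nA,
                 n_mean = nA / sum(use),
                 n_P = sum(!(own %in% others)),
                 AR = ar,
                 H_O = mean(h$ho[use]),
                 H_E = mean(h$he[use], na.rm = TRUE),
                 F_IS = 1 - mean(h$ho[use]) /
                          mean(h$he[use], na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(aln)) {
    gra <- if (!is.null(names(groups))) groups[names(aln)]
           else if (is.null(gt)) resolve_groups(aln, groups)
           else stop_pondmix("with both gt and aln, groups must be named")
    if (anyNA(gra)) stop_pondmix("group label missing for some sequences")
    glev <- unique(gra)
    L <- attr(aln, "length")
    dmat <- seq_diff_matrix(aln)
    hap_all <- unclass(aln)
    rows <- lapply(glev, function(g) {
      wh <- which(gra == g)
      n <- length(wh)
      haps <- table(hap_all[wh])
      f <- haps / n
      hd <- if (n > 1) n / (n - 1) * (1 - sum(f^2)) else 0
      pi_ <- if (n > 1) mean(dmat[wh, wh][upper.tri(diag(n))]) / L else 0
      other_h <- unique(hap_all[gra != g])
      data.frame(group = g, n_seq = n,
                 S = segregating_sites(aln, wh),
                 h = length(haps),
                 h_P = sum(!(names(haps) %in% other_h)),
                 Hd = hd, pi = pi_, stringsAsFactors = FALSE)
    })
    seq_out <- do.call(rbind, rows)
    out <- if (is.null(out)) seq_out
           else merge(out, seq_out, by = "group", sort = FALSE)
  }
  if (is.null(out)) stop_pondmix("provide gt and/or aln")
  attr(out, "skipped_loci") <- skipped
  attr(out, "rarefaction_size") <- rarefaction_size
  rownames(out) <- NULL
  out
}

# Weir & Cockerham (1984) variance components for one locus and one
# allele; x = per-pop (n_i, p_i, h_i) with h_i the frequency of
# heterozygotes carrying the allele.  Returns c(a, b, c).
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Multi-locus Weir-Cockerham theta
#'
#' The 1984 variance-component estimator of F_ST for diploid
#' multi-allelic data: per-locus, per-allele components a (among
#' populations), b (among individuals within populations) and c
#' (within individuals) are summed over alleles and loci, and theta is
#' the ratio `sum(a) / sum(a + b + c)`.  Loci with fewer than two
#' complete genotypes in any group are skipped.  The per-allele sums
#' are vectorised across alleles.
#'
#' @param gt A [genotype_table()].
#' @param groups Group label per individual.
#' @return Theta (a single number; `NaN` if no locus is usable).
#' @export
wc_theta <- function(gt, groups) {
  gr <- resolve_groups(gt, groups)
  glev <- unique(gr)
  r <- length(glev)
  if (r < 2) stop_pondmix("need >= 2 groups")
  A <- 0; BC <- 0
  for (l in seq_along(gt$loci)) {
    per_pop <- lapply(glev, function(g) {
      wh <- gr == g
      g1 <- gt$a1[wh, l]; g2 <- gt$a2[wh, l]
      ok <- !is.na(g1)
      list(g1 = g1[ok], g2 = g2[ok], n = sum(ok))
    })
    ns <- vapply(per_pop, `[[`, 0L, "n")
    if (any(ns < 2)) next # locus unusable in some group
    alleles <- sort(unique(unlist(lapply(per_pop, function(p)
      c(p$g1, p$g2)))))
    nA <- length(alleles)
    if (nA < 2) next
    # p_i: r x A allele frequencies; h_i: r x A heterozygote carrier freq
    p_i <- matrix(0, r, nA); h_i <- matrix(0, r, nA)
    for (i in seq_len(r)) {
      pp <- per_pop[[i]]
      i1 <- match(pp$g1, alleles); i2 <- match(pp$g2, alleles)
      p_i[i, ] <- (tabulate(i1, nA) + tabulate(i2, nA)) / (2 * pp$n)
      h_i[i, ] <- tabulate(c(i1[i1 != i2], i2[i1 != i2]), nA) / pp$n
    }
    nbar <- mean(ns)
    nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
    pbar <- colSums(ns * p_i) / (r * nbar)
    s2 <- colSums(ns * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
    hbar <- colSums(ns * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + sum(a); BC <- BC + sum(b) + sum(cc)
  }
  unname(A / (A + BC))
}

#' Pairwise F_ST matrix with permutation p-values
#'
#' Modes: `weir_cockerham` — multi-locus Weir-Cockerham theta on diploid
#' genotypes; `haplotype_freq` — AMOVA-framework F_ST on haplotype
#' identity (0/1 distances); `phi_st` — AMOVA-framework Phi_ST on
#' pairwise sequence differences.  Permutation p-values are the
#' proportion of label permutations with a statistic at least as large
#' as observed (including the observed one, so p >= 1/(B+1)).
#'
#' @param gt A [genotype_table()] (for `weir_cockerham`).
#' @param aln A `sequence_alignment` (for the mtDNA modes).
#' @param groups Group label per individual.
#' @param n_permutations Number of permutations (0 disables testing).
#' @param mode See above.
#' @param seed Seed for the permutations.
#' @return A list of class `fst_matrix`: `fst` (symmetric matrix),
#'   `p_value` (matrix or NULL), `mode`.
#' @export
pairwise_fst <- function(gt = NULL, aln = NULL, groups,
                         n_permutations = 0,
                         mode = c("weir_cockerham", "haplotype_freq",
                                  "phi_st"),
                         seed = 1) {
  mode <- match.arg(mode)
  obj <- if (mode == "weir_cockerham") gt else aln
  if (is.null(obj)) stop_pondmix("data for mode '", mode, "' not supplied")
  gr <- if (mode == "weir_cockerham") resolve_groups(gt, groups)
        else {
          g <- if (!is.null(names(groups))) groups[names(aln)] else groups
          if (length(g) != length(aln) || anyNA(g))
            stop_pondmix("groups must map every sequence")
          as.character(g)
        }
  glev <- unique(gr)
  if (length(glev) < 2) stop_pondmix("need >= 2 groups")
  sizes <- table(gr)
  if (any(sizes < 2)) stop_pondmix("each group needs >= 2 members")
  stat_fun <- if (mode == "weir_cockerham") {
    function(idx, labels) wc_theta(subset_individuals(gt, idx), labels)
  } else {
    dmat <- seq_diff_matrix(aln)
    if (mode == "haplotype_freq") dmat <- (dmat > 0) * 1
    d2 <- dmat^2
    function(idx, labels)
      amova_from_d2(d2[idx, idx, drop = FALSE], labels)$phi
  }
  K <- length(glev)
  fst <- matrix(0, K, K, dimnames = list(glev, glev))
  pmat <- if (n_permutations > 0)
    matrix(NA_real_, K, K, dimnames = list(glev, glev)) else NULL
  set.seed(seed)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    idx <- which(gr %in% c(glev[i], glev[j]))
    labels <- gr[idx]
    obs <- stat_fun(idx, labels)
    fst[i, j] <- fst[j, i] <- obs
    if (n_permutations > 0) {
      hits <- 1
      for (b in seq_len(n_permutations)) {
        perm <- sample(labels)
        if (stat_fun(idx, perm) >= obs - 1e-12) hits <- hits + 1
      }
      pmat[i, j] <- pmat[j, i] <- hits / (n_permutations + 1)
    }
  }
  structure(list(fst = fst, p_value = pmat, mode = mode),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise F_ST (", x$mode, "):\n", sep = "")
  print(round(x$fst, 4))
  invisible(x)
}

# one-level AMOVA from a squared-distance matrix and group labels
amova_from_d2 <- function(d2, labels) {
  N <- nrow(d2)
  labels <- as.character(labels)
  glev <- unique(labels)
  G <- length(glev)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  n_g <- integer(G)
  for (k in seq_len(G)) {
    wh <- which(labels == glev[k])
    n_g[k] <- length(wh)
    if (n_g[k] > 1) {
      dd <- d2[wh, wh, drop = FALSE]
      ss_within <- ss_within + sum(dd[upper.tri(dd)]) / n_g[k]
    }
  }
  ss_among <- ss_total - ss_within
  df_a <- G - 1; df_w <- N - G
  ms_a <- ss_among / df_a; ms_w <- ss_within / df_w
  n_prime <- (N - sum(n_g^2) / N) / (G - 1)
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n_prime
  tot <- sigma_a + sigma_w
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       pct_among = 100 * sigma_a / tot, pct_within = 100 * sigma_w / tot,
       phi = sigma_a / tot, ss_among = ss_among, ss_within = ss_within,
       df = c(among = df_a, within = df_w))
}

#' One-level analysis of molecular variance
#'
#' Partitions the total molecular variance among and within groups from
#' squared inter-individual distances (Excoffier's sum-of-squares
#' partition).  `allele_identity` counts, per locus, how many of the two
#' allele positions differ between two genotypes (0-2, missing loci
#' skipped); `pairwise_difference` uses sequence mismatch counts.
#'
#' @param gt A [genotype_table()] (for `allele_identity`).
#' @param aln A `sequence_alignment` (for `pairwise_difference`).
#' @param groups Group label per individual.
#' @param n_permutations Permutations for the p-value of Phi_ST.
#' @param distance `"allele_identity"` or `"pairwise_difference"`.
#' @param seed Permutation seed.
#' @return List of class `amova_result`: variance components, their
#'   percentages (summing to 100), `phi`, and `p_value`.
#' @export
amova <- function(gt = NULL, aln = NULL, groups, n_permutations = 99,
                  distance = c("allele_identity", "pairwise_difference"),
                  seed = 1) {
  distance <- match.arg(distance)
  if (distance == "allele_identity") {
    if (is.null(gt)) stop_pondmix("allele_identity distance needs gt")
    labels <- resolve_groups(gt, groups)
    d <- genotype_diff_matrix(gt)
  } else {
    if (is.null(aln)) stop_pondmix("pairwise_difference distance needs aln")
    labels <- if (!is.null(names(groups))) as.character(groups[names(aln)])
              else resolve_groups(aln, groups)
    d <- seq_diff_matrix(aln)
  }
  if (length(unique(labels)) < 2)
    stop_pondmix("AMOVA needs >= 2 groups")
  d2 <- d^2
  res <- amova_from_d2(d2, labels)
  p <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    hits <- 1
    for (b in seq_len(n_permutations)) {
      if (amova_from_d2(d2, sample(labels))$phi >= res$phi - 1e-12)
        hits <- hits + 1
    }
    p <- hits / (n_permutations + 1)
  }
  structure(c(res, list(p_value = p, n_permutations = n_permutations,
                        distance = distance)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s): among %.2f%%, within %.2f%% (Phi = %.4f, p = %s)\n",
              x$distance, x$pct_among, x$pct_within, x$phi,
              format(x$p_value)))
  invisible(x)
}

# inter-genotype distance: number of allele differences per locus
# (0, 1 or 2, via multiset intersection), summed over shared-typed loci
genotype_diff_matrix <- function(gt) {
  n <- length(gt$individuals)
  d <- matrix(0, n, n, dimnames = list(gt$individuals, gt$individuals))
  L <- length(gt$loci)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- 0
    for (l in seq_len(L)) {
      x1 <- gt$a1[i, l]
      if (is.na(x1) || is.na(gt$a1[j, l])) next
      gi <- c(x1, gt$a2[i, l]); gj <- c(gt$a1[j, l], gt$a2[j, l])
      shared <- length_intersect_multiset(gi, gj)
      tot <- tot + (2 - shared)
    }
    d[i, j] <- d[j, i] <- tot
  }
  d
}

length_intersect_multiset <- function(x, y) {
  s <- 0
  y_left <- y
  for (v in x) {
    m <- match(v, y_left)
    if (!is.na(m)) { s <- s + 1; y_left <- y_left[-m] }
  }
  s
}

#' Principal component analysis of genotypes
#'
#' Individuals are encoded as allele-dosage vectors (0/1/2 per allele
#' label per locus), missing dosages are imputed with column means,
#' columns are mean-centred, and the covariance matrix is
#' eigendecomposed (via `prcomp`).
#'
#' @param gt A [genotype_table()].
#' @param n_axes Number of leading axes to return.
#' @param groups Optional group labels: per-group means and covariances
#'   of the first two axes are reported (95% ellipse inputs).
#' @return List of class `pca_result`: `scores` (individuals x axes),
#'   `percent_variance`, and optionally `group_stats`.
#' @export
pca_genotypes <- function(gt, n_axes = 3, groups = NULL) {
  if (length(gt$individuals) < 2) stop_pondmix("need >= 2 individuals")
  X <- dosage_matrix(gt)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  rank_ <- sum(pr$sdev > 1e-12)
  if (n_axes > rank_) {
    warning("n_axes exceeds rank (", rank_, "); truncated", call. = FALSE)
    n_axes <- rank_
  }
  pct <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(n_axes), drop = FALSE]
  gs <- NULL
  if (!is.null(groups)) {
    gr <- resolve_groups(gt, groups)
    gs <- lapply(unique(gr), function(g) {
      s <- scores[gr == g, seq_len(min(2, n_axes)), drop = FALSE]
      list(group = g, mean = colMeans(s),
           cov = if (nrow(s) > 1) cov(s) else matrix(0, ncol(s), ncol(s)))
    })
    names(gs) <- unique(gr)
  }
  structure(list(scores = scores, percent_variance = pct[seq_len(n_axes)],
                 group_stats = gs),
            class = "pca_result")
}

# individuals x (locus:allele) dosage matrix with NA for missing loci
dosage_matrix <- function(gt) {
  cols <- list()
  for (l in seq_along(gt$loci)) {
    al <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    al <- al[!is.na(al)]
    for (a in al) {
      dos <- (gt$a1[, l] == a) + (gt$a2[, l] == a)
      cols[[paste0(gt$loci[l], ":", a)]] <- dos
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- gt$individuals
  X
}

#' Screen loci for null alleles
#'
#' Per locus, Brookfield's first estimator
#' `r_hat = (H_E - H_O) / (1 + H_E)` (clamped at 0) quantifies the null
#' frequency implied by the homozygote excess; a one-sided exact
#' binomial test compares the observed homozygote count with its
#' Hardy-Weinberg expectation, Bonferroni-corrected over loci.
#' Monomorphic loci get `r_hat = 0` and are never flagged.
#'
#' @param gt A [genotype_table()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `data.frame` of class `null_allele_report`: locus, `n`,
#'   `H_O`, `H_E`, `r_hat`, `p_value`, `flagged`.  Fewer than 20
#'   individuals triggers a warning.
#' @export
null_allele_scan <- function(gt, alpha = 0.05) {
  if (length(gt$individuals) < 20)
    warning("fewer than 20 individuals: null-allele screen has low power",
            call. = FALSE)
  h <- het_by_locus(gt)
  L <- nrow(h)
  r_hat <- numeric(L); p <- numeric(L)
  for (l in seq_len(L)) {
    if (is.na(h$he[l]) || h$he[l] <= 0) { r_hat[l] <- 0; p[l] <- 1; next }
    r_hat[l] <- max(0, (h$he[l] - h$ho[l]) / (1 + h$he[l]))
    n <- h$n[l]
    p_hom <- min(1 - 1e-12, max(1e-12, 1 - h$he[l]))
    n_hom <- round((1 - h$ho[l]) * n)
    p[l] <- binom.test(n_hom, n, p_hom, alternative = "greater")$p.value
  }
  out <- data.frame(locus = h$locus, n = h$n, H_O = h$ho, H_E = h$he,
                    r_hat = r_hat, p_value = p,
                    flagged = p < alpha / L, stringsAsFactors = FALSE)
  class(out) <- c("null_allele_report", "data.frame")
  out
}

#' Apply a null-allele correction
#'
#' Attaches per-locus null frequencies to the table: visible allele
#' frequencies at flagged loci are to be scaled by `1 - r_hat`, with the
#' remainder attributed to the unobserved null allele.  The corrected
#' per-locus frequency vectors (including a `"<null>"` entry) are
#' returned alongside, for re-estimating frequency-based statistics.
#'
#' @param gt A [genotype_table()].
#' @param report A [null_allele_scan()] result.
#' @return List: `genotypes` (the input table with attribute
#'   `null_r_hat`), `corrected_freqs` (per locus, named vector summing
#'   to 1 including `"<null>"`), `report`.
#' @export
correct_for_nulls <- function(gt, report) {
  stopifnot(inherits(report, "null_allele_report"))
  r <- setNames(ifelse(report$flagged, report$r_hat, 0), report$locus)
  cnts <- allele_counts(gt)
  corrected <- lapply(seq_along(gt$loci), function(l) {
    p <- cnts[[l]] / sum(cnts[[l]])
    v <- c(as.numeric(p) * (1 - r[l]), r[l])
    names(v) <- c(names(p), "<null>")
    v
  })
  names(corrected) <- gt$loci
  attr(gt, "null_r_hat") <- r
  list(genotypes = gt, corrected_freqs = corrected, report = report)
}
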