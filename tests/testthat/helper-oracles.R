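# Independent brute-force oracles.  These re-derive the statistics from
# raw definitional sums with naive loops, sharing no code with the
# package implementations they check.

# Weir-Cockerham theta via the ANOVA (sums-of-squares) route: for each
# locus and allele, mean squares among populations / among individuals
# within populations / within individuals, converted to the a, b, c
# components.
oracle_wc_theta <- function(gt, groups) {
  glev <- unique(groups)
  r <- length(glev)
  A_sum <- 0; ABC_sum <- 0
  for (l in seq_along(gt$loci)) {
    # complete genotypes per population
    pops <- lapply(glev, function(g) {
      wh <- which(groups == g & !is.na(gt$a1[, l]))
      cbind(gt$a1[wh, l], gt$a2[wh, l])
    })
    n_i <- vapply(pops, nrow, 0L)
    if (any(n_i < 2)) next
    alleles <- unique(unlist(pops))
    if (length(alleles) < 2) next
    N <- sum(n_i)
    n_c <- (N - sum(n_i^2) / N) / (r - 1)
    for (al in alleles) {
      # indicator arrays
      SSG <- 0; SSI <- 0; SSP <- 0
      xbar <- sum(vapply(pops, function(m) sum(m == al), 0)) / (2 * N)
      for (i in seq_len(r)) {
        m <- pops[[i]]
        xi <- sum(m == al) / (2 * n_i[i])
        SSP <- SSP + 2 * n_i[i] * (xi - xbar)^2
        for (j in seq_len(n_i[i])) {
          xij <- mean(m[j, ] == al)
          SSI <- SSI + 2 * (xij - xi)^2
          SSG <- SSG + sum(((m[j, ] == al) - xij)^2)
        }
      }
      MSG <- SSG / N
      MSI <- SSI / (N - r)
      MSP <- SSP / (r - 1)
      a <- (MSP - MSI) / (2 * n_c)
      b <- (MSI - MSG) / 2
      cc <- MSG
      A_sum <- A_sum + a
      ABC_sum <- ABC_sum + a + b + cc
    }
  }
  A_sum / ABC_sum
}

# one-level AMOVA variance components from explicit ordered-pair sums
oracle_amova <- function(d, labels) {
  N <- nrow(d)
  glev <- unique(labels)
  G <- length(glev)
  ss_tot <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / (2 * N)
  ss_w <- 0
  for (g in glev) {
    wh <- which(labels == g)
    acc <- 0
    for (i in wh) for (j in wh) acc <- acc + d[i, j]^2
    ss_w <- ss_w + acc / (2 * length(wh))
  }
  ss_a <- ss_tot - ss_w
  n_g <- vapply(glev, function(g) sum(labels == g), 0)
  ms_a <- ss_a / (G - 1)
  ms_w <- ss_w / (N - G)
  n_prime <- (N - sum(n_g^2) / N) / (G - 1)
  sigma_a <- (ms_a - ms_w) / n_prime
  sigma_w <- ms_w
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       pct_among = 100 * sigma_a / (sigma_a + sigma_w))
}

# Nei unbiased expected heterozygosity at one locus from raw counts
oracle_he <- function(alleles_2n) {
  n <- length(alleles_2n) / 2
  p <- table(alleles_2n) / (2 * n)
  2 * n / (2 * n - 1) * (1 - sum(p^2))
}

# nucleotide diversity: average over all sequence pairs of the count of
# differing called positions, per alignment site
oracle_pi <- function(seqs, L) {
  n <- length(seqs)
  tot <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    si <- strsplit(seqs[i], "")[[1]]; sj <- strsplit(seqs[j], "")[[1]]
    ok <- si %in% c("A", "C", "G", "T") & sj %in% c("A", "C", "G", "T")
    tot <- tot + sum(si[ok] != sj[ok])
    pairs <- pairs + 1
  }
  tot / pairs / L
}

# minimum spanning tree total weight by exhaustive enumeration of
# spanning edge subsets (feasible for <= 7 nodes)
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  best <- Inf
  subsets <- combn(ne, n - 1)
  for (s in seq_len(ncol(subsets))) {
    sel <- subsets[, s]
    # connectivity check by flood fill
    adj <- matrix(FALSE, n, n)
    for (e in sel) {
      adj[pairs[e, 1], pairs[e, 2]] <- TRUE
      adj[pairs[e, 2], pairs[e, 1]] <- TRUE
    }
    seen <- rep(FALSE, n); seen[1] <- TRUE
    queue <- 1
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen)) {
      w <- sum(d[pairs[sel, , drop = FALSE]])
      if (w < best) best <- w
    }
  }
  best
}

# haplotype diversity from raw haplotype frequencies
oracle_hd <- function(seqs) {
  n <- length(seqs)
  f <- table(seqs) / n
  n / (n - 1) * (1 - sum(f^2))
}
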