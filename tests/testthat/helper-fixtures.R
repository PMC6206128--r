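# Small programmatic fixtures shared across test files.

# random genotype table: n individuals, L loci, alleles drawn from
# small label sets, optional missingness and group labels
random_gt <- function(n = 8, L = 3, n_alleles = 4, missing_rate = 0,
                      groups = NULL, seed = 1) {
  set.seed(seed)
  labels <- lapply(seq_len(L), function(l) sample(90:140, n_alleles))
  a1 <- sapply(seq_len(L), function(l) sample(labels[[l]], n, TRUE))
  a2 <- sapply(seq_len(L), function(l) sample(labels[[l]], n, TRUE))
  a1 <- matrix(a1, n); a2 <- matrix(a2, n)
  if (missing_rate > 0) {
    miss <- matrix(runif(n * L) < missing_rate, n, L)
    a1[miss] <- NA; a2[miss] <- NA
  }
  if (is.null(groups)) groups <- rep(c("g1", "g2"), length.out = n)
  genotype_table(sprintf("ind%02d", seq_len(n)),
                 sprintf("L%d", seq_len(L)), a1, a2, groups)
}

# random alignment of n sequences of length L with mutations from a
# common ancestor (ensures shared structure), optional N characters
random_aln <- function(n = 6, L = 40, n_mut = 6, n_rate = 0, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- root
    m <- sample.int(n_mut + 1, 1) - 1
    if (m > 0) {
      pos <- sample.int(L, m)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    if (n_rate > 0) {
      nn <- runif(L) < n_rate
      s[nn] <- "N"
    }
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("seq%02d", seq_len(n))
  sequence_alignment(seqs)
}

# two strongly separated taxa with completely disjoint allele labels
# (separable case: every locus diagnostic)
disjoint_taxa <- function(n_loci = 8, n_alleles = 3, seed = 1) {
  set.seed(seed)
  fa <- lapply(seq_len(n_loci), function(l) {
    p <- rdir(n_alleles)
    names(p) <- as.character(100 + 2 * seq_len(n_alleles))
    p
  })
  fb <- lapply(seq_len(n_loci), function(l) {
    p <- rdir(n_alleles)
    names(p) <- as.character(200 + 2 * seq_len(n_alleles))
    p
  })
  names(fa) <- names(fb) <- sprintf("L%d", seq_len(n_loci))
  list(structure(list(id = "taxA", F = 0.2, freqs = fa),
                 class = "taxon_model"),
       structure(list(id = "taxB", F = 0.2, freqs = fb),
                 class = "taxon_model"))
}

rdir <- function(k) { g <- rgamma(k, 1); g / sum(g) }
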