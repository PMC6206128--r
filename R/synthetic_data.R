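# Synthetic hybrid-zone data with known ground truth: drifted parental
# taxa (Balding-Nichols Dirichlet model), star-shaped mtDNA lineages and
# sampling sites ordered along a geographic transect crossing a cline.

#' Drift parameter giving a target pairwise F_ST
#'
#' Under the Balding-Nichols model used by [make_taxa()], the
#' Weir-Cockerham theta between two taxa that each drifted `F` away
#' from a shared ancestral frequency has expectation `F` itself (theta
#' measures among-population variance against within-population gene
#' diversity, which shrinks by the same factor `1 - F`).  The mapping
#' is therefore the identity; the helper exists to make the intent
#' explicit at call sites and to anchor the contract in one place.
#' Nei's G_ST for the same pair is smaller, `F / (2 - F)`, because its
#' denominator is total rather than within-population diversity.
#'
#' @param fst Target pairwise Weir-Cockerham F_ST in (0, 1).
#' @return Drift parameter `F` in (0, 1).
#' @export
#' @examples
#' drift_for_fst(0.3)
drift_for_fst <- function(fst) {
  stopifnot(fst > 0, fst < 1)
  fst
}

#' Generate drifted parental taxa
#'
#' Ancestral allele frequencies per locus are drawn from a symmetric
#' Dirichlet(1); each taxon's frequencies are drawn from a Dirichlet
#' centred on the ancestral vector with concentration `(1 - F) / F`
#' (Balding-Nichols), so larger `F` means more drift and higher pairwise
#' F_ST.  Allele labels are even microsatellite repeat lengths.
#'
#' @param n_taxa Number of taxa (>= 2 for a contact zone, >= 1 accepted).
#' @param n_loci Number of loci (default 15).
#' @param alleles_per_locus Integer vector (recycled) of allele counts;
#'   default draws each locus's count uniformly from 12..29, the typical
#'   range for highly polymorphic microsatellites.
#' @param F_vector Per-taxon drift parameter in (0, 1); see
#'   [drift_for_fst()].
#' @param seed Integer seed.
#' @return List of `taxon_model` objects: `id`, `F`, `freqs` (per locus a
#'   named frequency vector; names are allele labels).  The shared
#'   ancestral frequencies are attached as attribute `ancestral`.
#' @export
make_taxa <- function(n_taxa, n_loci = 15, alleles_per_locus = NULL,
                      F_vector = rep(0.3, n_taxa), seed = 1) {
  stopifnot(n_taxa >= 1, n_loci >= 1, length(F_vector) == n_taxa,
            all(F_vector > 0), all(F_vector < 1))
  set.seed(seed)
  if (is.null(alleles_per_locus)) {
    alleles_per_locus <- sample(12:29, n_loci, replace = TRUE)
  } else {
    alleles_per_locus <- rep_len(as.integer(alleles_per_locus), n_loci)
  }
  if (any(alleles_per_locus < 2))
    stop_pondmix("alleles_per_locus must be >= 2")
  ancestral <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    nA <- alleles_per_locus[l]
    start <- sample(seq(80, 140, by = 2), 1)
    labels <- as.character(start + 2 * (seq_len(nA) - 1))
    ancestral[[l]] <- setNames(rdirichlet1(rep(1, nA)), labels)
  }
  names(ancestral) <- paste0("L", seq_len(n_loci))
  taxa <- vector("list", n_taxa)
  for (k in seq_len(n_taxa)) {
    Fk <- F_vector[k]
    conc <- (1 - Fk) / Fk
    freqs <- lapply(ancestral, function(p0)
      setNames(rdirichlet1(p0 * conc), names(p0)))
    taxa[[k]] <- structure(list(id = paste0("taxon", k), F = Fk,
                                freqs = freqs),
                           class = "taxon_model")
  }
  attr(taxa, "ancestral") <- ancestral
  taxa
}

# draw one allele label from a locus frequency vector
draw_allele <- function(freq, n = 1) {
  as.integer(sample(names(freq), n, replace = TRUE, prob = freq))
}

#' Sample diploid genotypes from a taxon model
#'
#' Each genotype is two independent draws from the taxon's locus
#' frequencies (Hardy-Weinberg within taxon); genotypes are then set
#' missing independently at `missing_rate`.
#'
#' @param taxon A `taxon_model` from [make_taxa()].
#' @param n_individuals Number of individuals.
#' @param missing_rate Per-genotype missing probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param prefix Sample-id prefix.
#' @param site Site id recorded for every individual.
#' @return A [genotype_table()].
#' @export
sample_genotypes <- function(taxon, n_individuals, missing_rate = 0,
                             seed = 1, prefix = taxon$id, site = prefix) {
  stopifnot(missing_rate >= 0, missing_rate < 1, n_individuals >= 1)
  set.seed(seed)
  L <- length(taxon$freqs)
  a1 <- matrix(NA_integer_, n_individuals, L)
  a2 <- matrix(NA_integer_, n_individuals, L)
  for (l in seq_len(L)) {
    a1[, l] <- draw_allele(taxon$freqs[[l]], n_individuals)
    a2[, l] <- draw_allele(taxon$freqs[[l]], n_individuals)
  }
  if (missing_rate > 0) {
    miss <- matrix(runif(n_individuals * L) < missing_rate,
                   n_individuals, L)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  ids <- sprintf("%s_%03d", prefix, seq_len(n_individuals))
  genotype_table(ids, names(taxon$freqs), a1, a2,
                 rep(site, n_individuals))
}

#' Generate founder haplotypes for divergent mtDNA lineages
#'
#' Random equal-length sequences mutated apart so consecutive founders
#' differ by at least `steps_between` substitutions (pairwise distances
#' may exceed this).
#'
#' @param n_lineages Number of lineages.
#' @param L Alignment length in bp (default 1031, the cyt b convention).
#' @param steps_between Minimum substitutions between consecutive
#'   founders (default 16).
#' @param seed Integer seed.
#' @return Character vector of founder sequences named `lin1`, `lin2`, ...
#' @export
make_founders <- function(n_lineages, L = 1031, steps_between = 16,
                          seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  founders <- character(n_lineages)
  cur <- root
  for (k in seq_len(n_lineages)) {
    if (k > 1) {
      pos <- sample.int(L, steps_between)
      for (p in pos) cur[p] <- sample(setdiff(bases, cur[p]), 1)
    }
    founders[k] <- paste(cur, collapse = "")
  }
  names(founders) <- paste0("lin", seq_len(n_lineages))
  founders
}

#' Simulate star-shaped mtDNA lineages around founder haplotypes
#'
#' Each sampled haplotype is its lineage founder with `0..steps_within`
#' random substitutions (a star phylogeny): shallow structure within
#' lineages, deep divergence between them.  Homoplasy can shrink
#' realised between-lineage distances slightly below the founder
#' distance.
#'
#' @param founders Named character vector of equal-length founder
#'   sequences (see [make_founders()]).
#' @param steps_within Maximum substitutions from the founder.
#' @param n_per_lineage Samples per lineage (recycled).
#' @param L Expected alignment length; checked against the founders.
#' @param seed Integer seed.
#' @return A `sequence_alignment`; attribute `lineage` maps each sample
#'   to its lineage.
#' @export
simulate_mtdna_lineages <- function(founders, steps_within = 3,
                                    n_per_lineage = 10,
                                    L = unique(nchar(founders)),
                                    seed = 1) {
  if (length(unique(nchar(founders))) != 1)
    stop_pondmix("founder sequences must share one length")
  if (nchar(founders[1]) != L)
    stop_pondmix("founders have length ", nchar(founders[1]),
                 ", expected ", L)
  set.seed(seed)
  n_per_lineage <- rep_len(n_per_lineage, length(founders))
  bases <- c("A", "C", "G", "T")
  seqs <- character(); lineage <- character()
  for (k in seq_along(founders)) {
    f <- strsplit(founders[k], "")[[1]]
    for (j in seq_len(n_per_lineage[k])) {
      s <- f
      if (steps_within > 0) {
        m <- sample.int(steps_within + 1, 1) - 1 # 0..steps_within
        if (m > 0) {
          pos <- sample.int(L, m)
          for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
        }
      }
      nm <- sprintf("%s_%03d", names(founders)[k], j)
      seqs[nm] <- paste(s, collapse = "")
      lineage[nm] <- names(founders)[k]
    }
  }
  aln <- sequence_alignment(seqs)
  attr(aln, "lineage") <- lineage
  aln
}

#' Expected cline frequency at a transect position
#'
#' The central sigmoid `p(x) = (1 + tanh(2 (x - c) / w)) / 2`: the
#' probability that an allele copy (or mtDNA haplotype) at position `x`
#' originates from the far-side taxon.
#'
#' @param x Position(s) in km.
#' @param center Cline centre `c` in km.
#' @param width Cline width `w` in km (inverse of maximum slope).
#' @return Frequencies in (0, 1).
#' @export
cline_true_p <- function(x, center, width) {
  stopifnot(width > 0)
  (1 + tanh(2 * (x - center) / width)) / 2
}

#' Simulate a sampled transect across a hybrid zone
#'
#' Sites sit at given positions along a transect; at position `x` every
#' nuclear allele copy independently originates from `taxonB` with
#' probability `p(x)` given by [cline_true_p()] and is then drawn from
#' that taxon's allele frequencies.  Each individual's mtDNA lineage
#' matches its majority nuclear origin, except that a fraction
#' `discordance` of individuals have their lineage re-drawn as an
#' independent Bernoulli(`p(x)`) — the cytonuclear-discordance knob.
#'
#' @param taxonA,taxonB `taxon_model` objects sharing a locus list.
#' @param true_center_km,true_width_km Cline parameters (km).
#' @param site_positions_km Sorted site positions along the transect (km).
#' @param n_per_site Individuals per site (recycled).
#' @param seed Integer seed.
#' @param founders Two founder haplotypes for the mtDNA lineages of A
#'   and B; default generated 16 steps apart.
#' @param steps_within Star radius of each mtDNA lineage.
#' @param discordance Fraction of individuals with independently drawn
#'   mtDNA lineage (default 0.2).
#' @param missing_rate Genotype missing rate.
#' @return A list `(genotypes, alignment, sites, truth)`.  `truth` holds
#'   `sites` (site, x_km, p_true), `individuals` (id, site, expected and
#'   realised taxon-B ancestry fraction, hybrid class label
#'   `pulse-admixed`, mtDNA lineage) and the generating parameters.
#' @export
simulate_transect <- function(taxonA, taxonB, true_center_km,
                              true_width_km, site_positions_km,
                              n_per_site = 20, seed = 1, founders = NULL,
                              steps_within = 2, discordance = 0.2,
                              missing_rate = 0) {
  stopifnot(true_width_km > 0, !is.unsorted(site_positions_km))
  if (!identical(names(taxonA$freqs), names(taxonB$freqs)))
    stop_pondmix("taxa have different locus lists")
  set.seed(seed)
  if (is.null(founders))
    founders <- make_founders(2, L = 1031, steps_between = 16,
                              seed = seed_stream(seed, "founders"))
  S <- length(site_positions_km)
  n_per_site <- rep_len(n_per_site, S)
  p_true <- cline_true_p(site_positions_km, true_center_km, true_width_km)
  loci <- names(taxonA$freqs)
  L <- length(loci)
  km_per_deg <- 6371 * pi / 180 # equatorial placement, haversine-exact
  sites <- data.frame(
    site = sprintf("s%02d", seq_len(S)),
    lat = 0,
    lon = site_positions_km / km_per_deg,
    group = ifelse(p_true < 0.1, "pureA",
                   ifelse(p_true > 0.9, "pureB", "admixed")),
    taxon = ifelse(p_true < 0.5, taxonA$id, taxonB$id),
    transects = paste0("t1:", seq_len(S)),
    stringsAsFactors = FALSE)
  ids <- character(); site_of <- character()
  a1 <- NULL; a2 <- NULL
  anc_expected <- numeric(); anc_realised <- numeric()
  mt <- character(); mt_seq <- character()
  bases <- c("A", "C", "G", "T")
  fA <- strsplit(founders[1], "")[[1]]
  fB <- strsplit(founders[2], "")[[1]]
  for (s in seq_len(S)) {
    p <- p_true[s]
    for (j in seq_len(n_per_site[s])) {
      id <- sprintf("%s_i%02d", sites$site[s], j)
      fromB1 <- runif(L) < p
      fromB2 <- runif(L) < p
      g1 <- integer(L); g2 <- integer(L)
      for (l in seq_len(L)) {
        g1[l] <- draw_allele((if (fromB1[l]) taxonB else taxonA)$freqs[[l]])
        g2[l] <- draw_allele((if (fromB2[l]) taxonB else taxonA)$freqs[[l]])
      }
      realised <- mean(c(fromB1, fromB2))
      concordant_B <- realised >= 0.5
      isB <- if (runif(1) < discordance) runif(1) < p else concordant_B
      f <- if (isB) fB else fA
      sq <- f
      m <- sample.int(steps_within + 1, 1) - 1
      if (m > 0) {
        pos <- sample.int(length(sq), m)
        for (pp in pos) sq[pp] <- sample(setdiff(bases, sq[pp]), 1)
      }
      ids <- c(ids, id); site_of <- c(site_of, sites$site[s])
      a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
      anc_expected <- c(anc_expected, p)
      anc_realised <- c(anc_realised, realised)
      mt <- c(mt, names(founders)[if (isB) 2 else 1])
      mt_seq <- c(mt_seq, paste(sq, collapse = ""))
    }
  }
  if (missing_rate > 0) {
    miss <- matrix(runif(length(a1)) < missing_rate, nrow(a1), ncol(a1))
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  gt <- genotype_table(ids, loci, a1, a2, site_of)
  names(mt_seq) <- ids
  aln <- sequence_alignment(mt_seq)
  attr(aln, "lineage") <- setNames(mt, ids)
  truth <- list(
    sites = data.frame(site = sites$site, x_km = site_positions_km,
                       p_true = p_true, stringsAsFactors = FALSE),
    individuals = data.frame(id = ids, site = site_of,
                             ancestry_B_expected = anc_expected,
                             ancestry_B_realised = anc_realised,
                             hybrid_class = "pulse-admixed",
                             mt_lineage = mt, stringsAsFactors = FALSE),
    params = list(center = true_center_km, width = true_width_km,
                  discordance = discordance, seed = seed))
  list(genotypes = gt, alignment = aln, sites = site_table(sites),
       truth = truth)
}
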