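# Hybrid-class simulation from two parental genotype pools (F1, F2 and
# both backcrosses, Mendelian gametes from realised F1 genotypes) and
# calibration of the mixed-ancestry Q threshold.

draw_pool_allele <- function(gt, locus_index, n = 1) {
  pool <- c(gt$a1[, locus_index], gt$a2[, locus_index])
  pool <- pool[!is.na(pool)]
  if (!length(pool))
    stop_pondmix("parental pool has no scored alleles at locus ",
                 gt$loci[locus_index])
  pool[sample.int(length(pool), n, replace = TRUE)]
}

make_f1 <- function(pA, pB) {
  L <- length(pA$loci)
  a1 <- vapply(seq_len(L), function(l) draw_pool_allele(pA, l), 0L)
  a2 <- vapply(seq_len(L), function(l) draw_pool_allele(pB, l), 0L)
  rbind(a1, a2)
}

# one gamete from a 2 x L genotype matrix: one of the two alleles at
# random, independently per locus (unlinked loci)
gamete <- function(geno) {
  L <- ncol(geno)
  geno[cbind(sample.int(2, L, replace = TRUE), seq_len(L))]
}

#' Simulate hybrid classes from two parental pools
#'
#' F1: one allele drawn from each parental empirical allele pool per
#' locus.  F2: two gametes from two independently simulated F1
#' genotypes.  Backcrosses: one F1 gamete plus one parental-pool allele
#' (BxA toward pool A, BxB toward pool B).  Gametes segregate from
#' realised F1 genotypes, so Mendelian class definitions hold exactly.
#'
#' @param parentalA,parentalB [genotype_table()] pools (>= 2 individuals
#'   each, same locus list).
#' @param n_per_class Genotypes per hybrid class (default 20).
#' @param seed Integer seed.
#' @return A `hybrid_set`: `genotypes` (a [genotype_table()] of the four
#'   simulated classes), `class` (named vector: F1, F2, BxA, BxB),
#'   `parentalA`, `parentalB`, `seed`.
#' @export
simulate_hybrids <- function(parentalA, parentalB, n_per_class = 20,
                             seed = 1) {
  if (!identical(parentalA$loci, parentalB$loci))
    stop_pondmix("parental pools have different locus lists")
  if (length(parentalA$individuals) < 2 || length(parentalB$individuals) < 2)
    stop_pondmix("each parental pool needs >= 2 individuals")
  set.seed(seed)
  L <- length(parentalA$loci)
  classes <- c("F1", "F2", "BxA", "BxB")
  a1 <- NULL; a2 <- NULL; cls <- character(); ids <- character()
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      g <- switch(cl,
        F1 = make_f1(parentalA, parentalB),
        F2 = rbind(gamete(make_f1(parentalA, parentalB)),
                   gamete(make_f1(parentalA, parentalB))),
        BxA = rbind(gamete(make_f1(parentalA, parentalB)),
                    vapply(seq_len(L), function(l)
                      draw_pool_allele(parentalA, l), 0L)),
        BxB = rbind(gamete(make_f1(parentalA, parentalB)),
                    vapply(seq_len(L), function(l)
                      draw_pool_allele(parentalB, l), 0L)))
      a1 <- rbind(a1, g[1, ]); a2 <- rbind(a2, g[2, ])
      ids <- c(ids, sprintf("%s_%03d", cl, i))
      cls <- c(cls, cl)
    }
  }
  gt <- genotype_table(ids, parentalA$loci, a1, a2,
                       site = paste0("sim_", cls))
  structure(list(genotypes = gt, class = setNames(cls, ids),
                 parentalA = parentalA, parentalB = parentalB,
                 seed = seed),
            class = "hybrid_set")
}

#' @export
print.hybrid_set <- function(x, ...) {
  cat("hybrid_set:", paste(names(table(x$class)), table(x$class),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Classify individuals as pure or mixed from ancestry proportions
#'
#' An individual is `pure k` when its largest cluster membership is at
#' least `threshold` (the boundary counts as pure: only memberships
#' strictly below the threshold are mixed), otherwise `mixed`.
#'
#' @param Q Individuals x clusters matrix of ancestry proportions.
#' @param threshold Threshold in (0.5, 1); default 0.85.
#' @return Character vector: `"pure1"`, `"pure2"`, ... or `"mixed"`.
#' @export
classify_individuals <- function(Q, threshold = 0.85) {
  stopifnot(threshold > 0.5, threshold < 1)
  k <- max.col(Q, ties.method = "first")
  maxq <- Q[cbind(seq_len(nrow(Q)), k)]
  ifelse(maxq >= threshold, paste0("pure", k), "mixed")
}

#' Calibrate the mixed-ancestry threshold from simulated hybrids
#'
#' Fits the K = 2 admixture model to the pure parental genotypes plus
#' the simulated hybrid classes and examines the per-class distributions
#' of the maximum cluster membership.  The proposed threshold is the
#' midpoint between the 1st percentile of pure max-Q and the 99th
#' percentile of backcross max-Q, clamped to (0.5, 1); if those
#' percentiles cross (complete overlap) the conventional 0.85 default is
#' returned with a flag.  Classification tables are reported at both the
#' proposed threshold and at 0.85.
#'
#' @param parentalA,parentalB Pure parental [genotype_table()] pools.
#' @param hybrids A [simulate_hybrids()] result built from the same
#'   pools.
#' @param fitter The K = 2 ancestry fit operation (default
#'   [fit_admixture()]); it receives `(gt, K = 2, seed = seed)`.
#' @param seed Integer seed passed to the fitter.
#' @return A `threshold_calibration`: `threshold`, `fallback` flag,
#'   `max_q` (named by class incl. pureA/pureB), per-class summaries,
#'   and confusion tables `table_at_threshold`, `table_at_085`.
#' @export
calibrate_threshold <- function(parentalA, parentalB, hybrids,
                                fitter = fit_admixture, seed = 1) {
  gt <- bind_genotypes(parentalA, parentalB, hybrids$genotypes)
  cls <- c(rep("pureA", length(parentalA$individuals)),
           rep("pureB", length(parentalB$individuals)),
           unname(hybrids$class))
  fit <- fitter(gt, K = 2, seed = seed)
  maxq <- apply(fit$Q, 1, max)
  pure_q <- maxq[cls %in% c("pureA", "pureB")]
  bx_q <- maxq[cls %in% c("BxA", "BxB")]
  lo <- quantile(pure_q, 0.01, names = FALSE)
  hi <- quantile(bx_q, 0.99, names = FALSE)
  fallback <- hi >= lo
  thr <- if (fallback) 0.85 else min(1 - 1e-9, max(0.5 + 1e-9,
                                                   (lo + hi) / 2))
  class_at <- function(t) table(class = cls,
                                call = ifelse(maxq < t, "mixed", "pure"))
  summaries <- do.call(rbind, lapply(split(maxq, cls), function(v)
    data.frame(min = min(v), q25 = quantile(v, .25, names = FALSE),
               median = median(v), q75 = quantile(v, .75, names = FALSE),
               max = max(v))))
  structure(list(threshold = thr, fallback = fallback,
                 max_q = setNames(maxq, cls), class_summaries = summaries,
                 table_at_threshold = class_at(thr),
                 table_at_085 = class_at(0.85), fit = fit, seed = seed),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("threshold_calibration: Q* = %.3f%s\n", x$threshold,
              if (x$fallback) " (fallback: class overlap)" else ""))
  print(x$class_summaries)
  invisible(x)
}

#' Write a hybrid set with class labels
#'
#' The structure_2row dialect with the class label in the site column.
#'
#' @param hs A `hybrid_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hybrid_set <- function(hs, path) {
  write_genotypes(hs$genotypes, path, dialect = "structure_2row")
  invisible(path)
}
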