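# Rejection ABC under explicit admixture-pulse demographies: a
# backward-in-time structured coalescent with stepwise-mutation
# microsatellites and Jukes-Cantor finite-sites mtDNA, the classical
# ten-summary-statistic design, and closest-fraction rejection with
# optional local-linear regression adjustment.

# ---------------------------------------------------------------- scenarios

#' Define an admixture demographic scenario
#'
#' Populations have constant effective sizes; the event list runs
#' backward in time.  An `admixture(t, target, sourceA, sourceB, rate)`
#' pulse sends each lineage in `target` to `sourceA` with probability
#' `rate` (else `sourceB`) and retires `target`; a
#' `merge(t, from, into)` moves all lineages of `from` into `into`.
#' Times, rates and sizes may be numbers or names of parameters to be
#' drawn from priors.
#'
#' @param populations Character vector; the sampled populations.
#' @param events List of events, each `list(type, time, ...)`, sorted or
#'   sortable by time.
#' @param Ne Named list/vector: population -> size (number or parameter
#'   name).  Must cover every population appearing in the events.
#' @param name Scenario label.
#' @return An object of class `abc_scenario`.
#' @export
abc_scenario <- function(populations, events, Ne, name = "scenario") {
  for (e in events) {
    stopifnot(e$type %in% c("admixture", "merge"))
    if (e$type == "admixture")
      stopifnot(!is.null(e$target), !is.null(e$sourceA),
                !is.null(e$sourceB), !is.null(e$rate))
    else stopifnot(!is.null(e$from), !is.null(e$into))
  }
  structure(list(populations = populations, events = events,
                 Ne = Ne, name = name),
            class = "abc_scenario")
}

# resolve numbers-or-parameter-names against a named parameter vector
resolve_value <- function(v, params) {
  if (is.character(v)) {
    if (!v %in% names(params)) stop_pondmix("unknown parameter: ", v)
    unname(params[[v]])
  } else as.numeric(v)
}

# instantiate events with numeric times, sorted forward in (backward) time
resolve_events <- function(scenario, params) {
  ev <- lapply(scenario$events, function(e) {
    e$time <- resolve_value(e$time, params)
    if (e$type == "admixture") e$rate <- resolve_value(e$rate, params)
    e
  })
  ev[order(vapply(ev, `[[`, 0, "time"))]
}

# check that all sampled populations funnel into a single root; only
# event times are resolved (rates are irrelevant to the topology)
validate_scenario <- function(scenario, params) {
  ev <- lapply(scenario$events, function(e) {
    e$time <- resolve_value(e$time, params)
    e
  })
  ev <- ev[order(vapply(ev, `[[`, 0, "time"))]
  alive <- scenario$populations
  for (e in ev) {
    if (e$type == "admixture") {
      alive <- setdiff(alive, e$target)
      alive <- union(alive, c(e$sourceA, e$sourceB))
    } else {
      if (!(e$from %in% alive)) next
      alive <- setdiff(alive, e$from)
      alive <- union(alive, e$into)
    }
  }
  if (length(alive) > 1)
    stop_pondmix("scenario '", scenario$name,
                 "' strands lineages in populations: ",
                 paste(alive, collapse = ", "))
  invisible(TRUE)
}

#' Atlantic-range contact scenario
#'
#' Two parental populations (`occ`, western resident; `orb`, the
#' invader) plus an admixed population `adm` formed by a single pulse
#' `t_adm` generations ago with rate `r` (probability a lineage traces
#' to `occ`, i.e. the `occ` contribution); the parentals diverged
#' `t_div` generations ago.
#'
#' @return An [abc_scenario()].
#' @export
scenario_atlantic <- function() {
  abc_scenario(
    populations = c("occ", "orb", "adm"),
    events = list(
      list(type = "admixture", time = "t_adm", target = "adm",
           sourceA = "occ", sourceB = "orb", rate = "r"),
      list(type = "merge", time = "t_div", from = "occ", into = "orb")),
    Ne = list(occ = "N_occ", orb = "N_orb", adm = "N_adm"),
    name = "atlantic")
}

#' Mediterranean-range double-contact scenario
#'
#' Three parentals (`occ`, `gal`, `orb`) and one sampled admixed
#' population `adm`.  Backward in time: at `t1` the admixed population
#' splits into an unsampled `occ x gal` pool (`og`, probability `r1`)
#' versus `orb`; at `t2` that pool splits into `occ` (probability `r2`)
#' versus `gal`; `gal` and `orb` coalesce at `t_div1` and `occ` joins at
#' `t_div2`.
#'
#' @return An [abc_scenario()].
#' @export
scenario_mediterranean <- function() {
  abc_scenario(
    populations = c("occ", "orb", "gal", "adm"),
    events = list(
      list(type = "admixture", time = "t1", target = "adm",
           sourceA = "og", sourceB = "orb", rate = "r1"),
      list(type = "admixture", time = "t2", target = "og",
           sourceA = "occ", sourceB = "gal", rate = "r2"),
      list(type = "merge", time = "t_div1", from = "gal", into = "orb"),
      list(type = "merge", time = "t_div2", from = "occ", into = "orb")),
    Ne = list(occ = "N_occ", orb = "N_orb", gal = "N_gal",
              adm = "N_adm", og = "N_og"),
    name = "mediterranean")
}

#' No-admixture alternative to the Atlantic scenario
#'
#' The "admixed" population is simply a sister of `occ` that split off
#' at `t_adm`; used as the contrast in scenario choice.
#'
#' @return An [abc_scenario()].
#' @export
scenario_atlantic_null <- function() {
  abc_scenario(
    populations = c("occ", "orb", "adm"),
    events = list(
      list(type = "merge", time = "t_adm", from = "adm", into = "occ"),
      list(type = "merge", time = "t_div", from = "occ", into = "orb")),
    Ne = list(occ = "N_occ", orb = "N_orb", adm = "N_adm"),
    name = "atlantic_null")
}

# ---------------------------------------------------------------- priors

#' Prior specification for ABC parameters
#'
#' @param spec Named list: parameter -> `list(dist, min, max)` with
#'   `dist` `"unif"` or `"logunif"`.
#' @param constraints Character vector of pairwise order constraints,
#'   e.g. `"t_adm<t_div"`; draws violating them are rejected and
#'   redrawn.
#' @return An `abc_priors` object.
#' @export
abc_priors <- function(spec, constraints = character()) {
  for (p in spec) {
    stopifnot(p$dist %in% c("unif", "logunif"), p$min < p$max)
    if (p$dist == "logunif") stopifnot(p$min > 0)
  }
  structure(list(spec = spec, constraints = constraints),
            class = "abc_priors")
}

#' Default priors for the contact scenarios
#'
#' Effective sizes and admixture times uniform on 10..10000 generations,
#' divergence times uniform on 10..100000, admixture rates uniform on
#' 0.001..0.999.
#'
#' @param scenario An [abc_scenario()]; parameter names are harvested
#'   from it.
#' @return An [abc_priors()].
#' @export
default_priors <- function(scenario) {
  nm <- character()
  for (e in scenario$events) {
    if (is.character(e$time)) nm <- c(nm, e$time)
    if (e$type == "admixture" && is.character(e$rate))
      nm <- c(nm, e$rate)
  }
  nm <- c(nm, unlist(Filter(is.character, scenario$Ne)))
  nm <- unique(nm)
  spec <- lapply(nm, function(p) {
    if (startsWith(p, "N_")) list(dist = "unif", min = 10, max = 10000)
    else if (startsWith(p, "t_div")) list(dist = "unif", min = 10,
                                          max = 100000)
    else if (startsWith(p, "t")) list(dist = "unif", min = 10,
                                      max = 10000)
    else list(dist = "unif", min = 0.001, max = 0.999)
  })
  names(spec) <- nm
  times <- nm[startsWith(nm, "t")]
  constraints <- character()
  ev_times <- vapply(scenario$events, function(e)
    if (is.character(e$time)) e$time else NA_character_, "")
  ev_times <- ev_times[!is.na(ev_times)]
  if (length(ev_times) > 1)
    constraints <- paste0(ev_times[-length(ev_times)], "<",
                          ev_times[-1])
  abc_priors(spec, constraints)
}

#' Draw parameter sets from priors
#'
#' @param priors An [abc_priors()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return `data.frame`, one column per parameter.
#' @export
sample_priors <- function(priors, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  draw <- function(m) {
    out <- lapply(priors$spec, function(p) {
      if (p$dist == "unif") runif(m, p$min, p$max)
      else exp(runif(m, log(p$min), log(p$max)))
    })
    as.data.frame(out)
  }
  df <- draw(n)
  if (length(priors$constraints)) {
    ok <- function(d) {
      keep <- rep(TRUE, nrow(d))
      for (cn in priors$constraints) {
        ab <- strsplit(cn, "<")[[1]]
        keep <- keep & d[[ab[1]]] < d[[ab[2]]]
      }
      keep
    }
    keep <- ok(df)
    guard <- 0
    while (!all(keep) && guard < 1000) {
      df[!keep, ] <- draw(sum(!keep))
      keep <- ok(df)
      guard <- guard + 1
    }
    if (!all(keep)) stop_pondmix("constraints too tight to satisfy")
  }
  df
}

# ---------------------------------------------------------------- coalescent

# Structured coalescent for one non-recombining locus.
# pops: per-lineage population label; events: resolved & sorted; Ne:
# named numeric (per-population size); ploidy: 2 for autosomal
# microsatellites (pair rate 1/(2Ne)), 1 for haploid (pair rate 1/Ne).
# Returns list(parent, time) over 2n-1 nodes, tips 1..n at time 0.
# If trace_at is set, the returned $trace maps each tip to the name of
# the population its ancestral lineage occupies just after that time
# (used to verify admixture-rate semantics).
sim_coalescent <- function(pops, events, Ne, ploidy = 2,
                           trace_at = NULL) {
  n <- length(pops)
  pop_names <- unique(c(pops, unlist(lapply(events, function(e)
    if (e$type == "admixture") c(e$target, e$sourceA, e$sourceB)
    else c(e$from, e$into)))))
  ne_vec <- vapply(pop_names, function(p) {
    v <- Ne[[p]]
    if (is.null(v)) stop_pondmix("no Ne for population ", p)
    as.numeric(v)
  }, 0)
  denom <- ploidy * ne_vec
  code <- function(p) match(p, pop_names)
  parent <- integer(2 * n - 1)
  node_time <- numeric(2 * n - 1)
  next_node <- n + 1
  # lineage sets per population; between events the populations are
  # independent Poisson processes, so each is advanced on its own
  lin <- vector("list", length(pop_names))
  pc <- code(pops)
  for (p in seq_along(pop_names)) lin[[p]] <- which(pc == p)
  tracing <- !is.null(trace_at)
  trace <- NULL
  desc <- if (tracing) as.list(seq_len(n)) # tips under node id
  capture_trace <- function() {
    out <- character(n)
    for (p in seq_along(pop_names)) for (v in lin[[p]])
      out[desc[[v]]] <- pop_names[p]
    out
  }
  schedule <- events
  if (tracing) { # pseudo-event marking the capture point
    schedule <- c(schedule, list(list(type = "trace", time = trace_at)))
    schedule <- schedule[order(vapply(schedule, `[[`, 0, "time"))]
  }
  t <- 0
  n_alive <- n
  for (e in c(schedule, list(list(type = "end", time = Inf)))) {
    t_end <- e$time
    for (p in seq_along(pop_names)) {
      k <- length(lin[[p]])
      if (k < 2) next
      tp <- t
      rate_base <- denom[p]
      repeat {
        wait <- rexp(1, k * (k - 1) / 2 / rate_base)
        tp <- tp + wait
        if (tp > t_end) break
        pair <- sample.int(k, 2)
        node <- next_node; next_node <- next_node + 1
        parent[lin[[p]][pair]] <- node
        node_time[node] <- tp
        if (tracing) desc[[node]] <- c(desc[[lin[[p]][pair[1]]]],
                                       desc[[lin[[p]][pair[2]]]])
        lin[[p]] <- c(lin[[p]][-pair], node)
        k <- k - 1L
        n_alive <- n_alive - 1L
        if (k < 2 || n_alive == 1) break
      }
      if (n_alive == 1) break
    }
    if (n_alive == 1) break
    if (e$type == "end") {
      stop_pondmix("lineages stranded: no coalescence possible and no ",
                   "events remain")
    }
    t <- t_end
    if (e$type == "admixture") {
      tg <- code(e$target)
      members <- lin[[tg]]
      if (length(members)) {
        toA <- runif(length(members)) < e$rate
        a <- code(e$sourceA); b <- code(e$sourceB)
        lin[[a]] <- c(lin[[a]], members[toA])
        lin[[b]] <- c(lin[[b]], members[!toA])
        lin[[tg]] <- integer()
      }
    } else if (e$type == "merge") {
      fr <- code(e$from); into <- code(e$into)
      lin[[into]] <- c(lin[[into]], lin[[fr]])
      lin[[fr]] <- integer()
    } else if (e$type == "trace") {
      trace <- capture_trace()
    }
  }
  if (tracing && is.null(trace)) trace <- capture_trace()
  # the single remaining lineage is the root node
  remaining <- unlist(lin)
  root <- if (length(remaining) == 1) remaining else 2 * n - 1
  list(parent = parent, time = node_time, n_tips = n,
       root = root, trace = trace)
}

# stepwise-mutation microsatellite values at the tips of a tree.  The
# net displacement of m symmetric +/-1 steps is 2 Binom(m, 1/2) - m, so
# all branches are drawn vectorised; the reflecting lower bound is only
# walked stepwise in the (rare) case a lineage could reach it.
smm_tip_values <- function(tree, mu, ancestral = 100L, lower = 2L) {
  n_nodes <- 2 * tree$n_tips - 1
  value <- integer(n_nodes)
  value[tree$root] <- ancestral
  blen <- numeric(n_nodes)
  nonroot <- seq_len(n_nodes)[-tree$root]
  blen[nonroot] <- tree$time[tree$parent[nonroot]] - tree$time[nonroot]
  m <- integer(n_nodes)
  m[nonroot] <- rpois(length(nonroot), mu * blen[nonroot])
  disp <- integer(n_nodes)
  has_m <- which(m > 0)
  disp[has_m] <- 2L * rbinom(length(has_m), m[has_m], 0.5) - m[has_m]
  ord <- order(tree$time[seq_len(n_nodes)], decreasing = TRUE)
  for (v in ord) {
    if (v == tree$root) next
    p <- tree$parent[v]
    start <- value[p]
    if (start - lower > m[v]) { # reflection unreachable
      value[v] <- start + disp[v]
    } else {
      steps <- sample(c(-1L, 1L), m[v], replace = TRUE)
      cur <- start
      for (s in steps) {
        cur <- cur + s
        if (cur < lower) cur <- lower + (lower - cur) # reflect
      }
      value[v] <- cur
    }
  }
  value[seq_len(tree$n_tips)]
}

# Jukes-Cantor finite-sites tip sequences (integer-coded 1..4)
jc_tip_sequences <- function(tree, mu_site, L) {
  n_nodes <- 2 * tree$n_tips - 1
  seqs <- vector("list", n_nodes)
  seqs[[tree$root]] <- sample.int(4, L, replace = TRUE)
  ord <- order(tree$time[seq_len(n_nodes)], decreasing = TRUE)
  for (v in ord) {
    if (v == tree$root) next
    p <- tree$parent[v]
    len <- tree$time[p] - tree$time[v]
    s <- seqs[[p]]
    m <- rpois(1, mu_site * L * len)
    if (m > 0) {
      pos <- sample.int(L, min(m, L)) # at most one hit per site per branch
      for (q in pos) s[q] <- sample((1:4)[-s[q]], 1)
    }
    seqs[[v]] <- s
  }
  do.call(rbind, seqs[seq_len(tree$n_tips)])
}

#' Simulate a dataset under a demographic scenario
#'
#' Backward-in-time structured coalescent per locus.  Microsatellites:
#' diploid sampling (two lineages per individual), strict stepwise
#' mutation (one repeat up or down, reflecting at a lower bound), with
#' each locus's rate drawn log-uniformly within `mu_micro_bounds`.
#' mtDNA: one haploid, maternally inherited locus with effective size
#' `Ne / 4`, Jukes-Cantor finite-sites substitution at a per-site rate
#' drawn log-uniformly within `mu_mt_bounds`.
#'
#' @param scenario An [abc_scenario()].
#' @param params Named numeric parameter vector (times in generations).
#' @param sample_sizes Named integer vector: sampled population ->
#'   number of diploid individuals.
#' @param n_microsat_loci Number of microsatellite loci (default 15).
#' @param mtdna_length mtDNA alignment length in bp (default 1031).
#' @param mu_micro_bounds Per-generation microsatellite rate bounds.
#' @param mu_mt_bounds Per-site per-generation mtDNA rate bounds.
#' @param seed Integer seed.
#' @return List `(genotypes, alignment)`; individuals are named
#'   `<pop>_<i>` with the population as site label.
#' @export
simulate_dataset <- function(scenario, params, sample_sizes,
                             n_microsat_loci = 15, mtdna_length = 1031,
                             mu_micro_bounds = c(1e-4, 1e-3),
                             mu_mt_bounds = c(1e-9, 1e-7), seed = 1) {
  params <- unlist(params)
  validate_scenario(scenario, params)
  set.seed(seed)
  events <- resolve_events(scenario, params)
  Ne <- lapply(scenario$Ne, resolve_value, params = params)
  pops_s <- names(sample_sizes)
  if (!all(pops_s %in% scenario$populations))
    stop_pondmix("sample_sizes names unknown to the scenario")
  n_ind <- sum(sample_sizes)
  ind_pop <- rep(pops_s, sample_sizes)
  ids <- unlist(lapply(pops_s, function(p)
    sprintf("%s_%02d", p, seq_len(sample_sizes[[p]]))))
  # microsatellites: 2 lineages per individual per locus
  lin_pop <- rep(ind_pop, each = 2)
  a1 <- matrix(NA_integer_, n_ind, n_microsat_loci)
  a2 <- matrix(NA_integer_, n_ind, n_microsat_loci)
  mu_l <- exp(runif(n_microsat_loci, log(mu_micro_bounds[1]),
                    log(mu_micro_bounds[2])))
  for (l in seq_len(n_microsat_loci)) {
    tree <- sim_coalescent(lin_pop, events, Ne, ploidy = 2)
    vals <- smm_tip_values(tree, mu_l[l])
    a1[, l] <- vals[seq(1, 2 * n_ind, by = 2)]
    a2[, l] <- vals[seq(2, 2 * n_ind, by = 2)]
  }
  gt <- genotype_table(ids, paste0("L", seq_len(n_microsat_loci)),
                       a1, a2, ind_pop)
  # mtDNA: one haploid lineage per individual, size Ne/4
  Ne_mt <- lapply(Ne, function(v) pmax(v / 4, 1))
  mu_mt <- exp(runif(1, log(mu_mt_bounds[1]), log(mu_mt_bounds[2])))
  tree <- sim_coalescent(ind_pop, events, Ne_mt, ploidy = 1)
  tip_int <- jc_tip_sequences(tree, mu_mt, mtdna_length)
  bases <- c("A", "C", "G", "T")
  seqs <- apply(tip_int, 1, function(r) paste(bases[r], collapse = ""))
  names(seqs) <- ids
  aln <- sequence_alignment(seqs)
  attr(aln, "lineage") <- setNames(ind_pop, ids)
  list(genotypes = gt, alignment = aln)
}

# ---------------------------------------------------------------- stats

#' The ten-summary-statistic vector
#'
#' mtDNA per population: haplotype count, segregating sites, mean
#' pairwise differences, private segregating sites (sites segregating
#' in the population but not among all other samples pooled); per
#' population pair: mean pairwise differences within (W, both samples
#' pooled), between (B), and haplotype-frequency F_ST.  Microsatellites
#' per population: mean allele count per locus, mean unbiased genetic
#' diversity; per pair: Weir-Cockerham F_ST.  All computed by the same
#' estimator code as the diversity/divergence module, so results match
#' those functions exactly.
#'
#' @param gt A [genotype_table()].
#' @param aln A `sequence_alignment` (`NULL` allowed: mtDNA statistics
#'   become 0 and are flagged in the `"empty_mtdna"` attribute).
#' @param groups Population label per individual (default the site
#'   labels of `gt`).
#' @return Named numeric vector with a fixed layout for a given
#'   population design; undefined ratios (monomorphic data) are 0.
#' @export
summary_stats <- function(gt, aln = NULL, groups = gt$site) {
  gr <- resolve_groups(gt, groups)
  pops <- unique(gr)
  out <- c()
  empty_mt <- is.null(aln) || length(aln) == 0
  if (!empty_mt) {
    gra <- setNames(gr, gt$individuals)[names(aln)]
    dmat <- seq_diff_matrix(aln)
    m <- alignment_matrix(aln)
    # only variable columns can segregate anywhere
    neq <- m != matrix(m[1, ], nrow(m), ncol(m), byrow = TRUE)
    m <- m[, colSums(neq) > 0, drop = FALSE]
    seg_in <- function(wh) {
      if (!ncol(m)) return(logical(0))
      apply(m[wh, , drop = FALSE], 2, function(col) {
        b <- unique(col[col %in% c("A", "C", "G", "T")])
        length(b) > 1
      })
    }
    haps <- unclass(aln)
    for (p in pops) {
      wh <- which(gra == p)
      mpd <- if (length(wh) > 1)
        mean(dmat[wh, wh][upper.tri(diag(length(wh)))]) else 0
      priv <- sum(seg_in(wh) & !seg_in(which(gra != p)))
      out <- c(out, setNames(c(length(unique(haps[wh])), sum(seg_in(wh)),
                               mpd, priv),
                             paste0("mt_", c("h", "S", "mpd", "privS"),
                                    "_", p)))
    }
    d2_hap <- ((dmat > 0) * 1)^2
    for (i in seq_along(pops)) for (j in seq_along(pops)) {
      if (j <= i) next
      w1 <- which(gra == pops[i]); w2 <- which(gra == pops[j])
      within <- c(dmat[w1, w1][upper.tri(diag(length(w1)))],
                  dmat[w2, w2][upper.tri(diag(length(w2)))])
      W <- if (length(within)) mean(within) else 0
      B <- mean(dmat[w1, w2])
      sub <- c(w1, w2)
      # the haplotype-frequency F_ST of pairwise_fst(): the AMOVA
      # partition on 0/1 haplotype-identity distances
      fst <- tryCatch(amova_from_d2(d2_hap[sub, sub, drop = FALSE],
                                    gra[sub])$phi,
                      error = function(e) 0)
      if (!is.finite(fst)) fst <- 0
      nm2 <- paste0(pops[i], "_", pops[j])
      out <- c(out, setNames(c(W, B, fst),
                             paste0("mt_", c("W", "B", "fst"), "_", nm2)))
    }
  } else {
    for (p in pops)
      out <- c(out, setNames(rep(0, 4),
                             paste0("mt_", c("h", "S", "mpd", "privS"),
                                    "_", p)))
    for (i in seq_along(pops)) for (j in seq_along(pops)) {
      if (j <= i) next
      nm2 <- paste0(pops[i], "_", pops[j])
      out <- c(out, setNames(rep(0, 3),
                             paste0("mt_", c("W", "B", "fst"), "_", nm2)))
    }
  }
  cnts_by_pop <- lapply(pops, function(p) allele_counts(gt, gr == p))
  for (i in seq_along(pops)) {
    cnt <- cnts_by_pop[[i]]
    na_mean <- mean(vapply(cnt, length, 0L))
    h <- het_by_locus(gt, which = gr == pops[i])
    he <- mean(h$he[h$n > 1], na.rm = TRUE)
    if (!is.finite(he)) he <- 0
    out <- c(out, setNames(c(na_mean, he),
                           paste0("ms_", c("na", "he"), "_", pops[i])))
  }
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    sub <- gr %in% c(pops[i], pops[j])
    fst <- wc_theta(subset_individuals(gt, sub), gr[sub])
    if (!is.finite(fst)) fst <- 0
    out <- c(out, setNames(fst, paste0("ms_fst_", pops[i], "_",
                                       pops[j])))
  }
  attr(out, "empty_mtdna") <- empty_mt
  out
}

# ---------------------------------------------------------------- rejection

#' Build an ABC reference table
#'
#' Draws `N` parameter sets from the priors, simulates a dataset for
#' each and records the summary statistics.  Rows are seeded
#' individually from `seed`, so the table is reproducible and can be
#' rebuilt in chunks.
#'
#' @param scenario An [abc_scenario()].
#' @param priors An [abc_priors()] (default [default_priors()]).
#' @param N Number of simulations (the study-scale setting is 1e5; a
#'   desk-scale 1e4 is a practical default).
#' @param sample_sizes,n_microsat_loci,mtdna_length,mu_micro_bounds,mu_mt_bounds
#'   Passed to [simulate_dataset()].
#' @param seed Integer seed.
#' @param progress Print a dot every 1000 rows.
#' @return An `abc_reference_table`: `params` (data.frame), `stats`
#'   (matrix), `scenario`, `seed`.
#' @export
build_reference_table <- function(scenario, priors = default_priors(scenario),
                                  N = 10000, sample_sizes,
                                  n_microsat_loci = 15,
                                  mtdna_length = 1031,
                                  mu_micro_bounds = c(1e-4, 1e-3),
                                  mu_mt_bounds = c(1e-9, 1e-7),
                                  seed = 1, progress = FALSE) {
  stopifnot(N >= 100)
  params <- sample_priors(priors, N, seed = seed_stream(seed, "priors"))
  stats <- NULL
  for (i in seq_len(N)) {
    sim <- simulate_dataset(scenario, unlist(params[i, ]), sample_sizes,
                            n_microsat_loci, mtdna_length,
                            mu_micro_bounds, mu_mt_bounds,
                            seed = seed_stream(seed, paste0("row", i)))
    s <- summary_stats(sim$genotypes, sim$alignment)
    if (is.null(stats))
      stats <- matrix(NA_real_, N, length(s),
                      dimnames = list(NULL, names(s)))
    stats[i, ] <- s
    if (progress && i %% 1000 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(params = params, stats = stats, scenario = scenario,
                 seed = seed,
                 config = list(N = N, sample_sizes = sample_sizes,
                               n_microsat_loci = n_microsat_loci,
                               mtdna_length = mtdna_length)),
            class = "abc_reference_table")
}

#' Write / read a reference table (TSV with a JSON header line)
#' @param tab An `abc_reference_table`.
#' @param path File path.
#' @return `path` invisibly / the re-read table.
#' @export
write_reference_table <- function(tab, path) {
  hdr <- jsonlite::toJSON(list(scenario = tab$scenario$name,
                               seed = tab$seed, config = tab$config,
                               n_params = ncol(tab$params)),
                          auto_unbox = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  df <- cbind(tab$params, as.data.frame(tab$stats))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  lines <- readLines(path, n = 1)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  params <- df[, seq_len(hdr$n_params), drop = FALSE]
  stats <- as.matrix(df[, -seq_len(hdr$n_params), drop = FALSE])
  structure(list(params = params, stats = stats,
                 scenario = list(name = hdr$scenario),
                 seed = hdr$seed, config = hdr$config),
            class = "abc_reference_table")
}

# standardize columns by the reference table's MAD; drops zero-MAD stats
standardize_stats <- function(ref_stats, obs) {
  med <- apply(ref_stats, 2, median)
  madv <- apply(ref_stats, 2, mad)
  keep <- madv > 0
  if (!all(keep))
    warning("statistic(s) with zero MAD dropped from the distance: ",
            paste(colnames(ref_stats)[!keep], collapse = ", "),
            call. = FALSE)
  list(ref = sweep(sweep(ref_stats[, keep, drop = FALSE], 2, med[keep]),
                   2, madv[keep], "/"),
       obs = (obs[keep] - med[keep]) / madv[keep], keep = keep)
}

#' Rejection ABC posterior
#'
#' Statistics are standardised by the reference table's median absolute
#' deviation, distances are Euclidean, and the closest
#' `ceil(tolerance N)` rows are retained.  With `regression = TRUE` a
#' local-linear adjustment (Epanechnikov-weighted regression of each
#' parameter on the standardised statistics, with logit transform for
#' parameters whose prior support lies in \[0, 1\]) is applied to the
#' retained values.
#'
#' @param observed Named statistic vector from [summary_stats()].
#' @param tab An `abc_reference_table`.
#' @param tolerance Retained fraction in (0, 1].
#' @param regression Apply the local-linear adjustment.
#' @param priors Priors (used to detect bounded parameters when
#'   `regression = TRUE`).
#' @param regression_frac Fraction of the table used to train the
#'   local regression (default 0.1, the classical regression-ABC
#'   bandwidth); the posterior itself is always the `tolerance`
#'   fraction.
#' @return An `abc_posterior`: `retained` (parameter draws, adjusted if
#'   requested), `summary` (mean/median/q025/q975 per parameter),
#'   `distances`, `tolerance`, `n_retained`.
#' @export
abc_reject <- function(observed, tab, tolerance = 0.01,
                       regression = FALSE, priors = NULL,
                       regression_frac = 0.1) {
  stopifnot(tolerance > 0, tolerance <= 1)
  st <- standardize_stats(tab$stats, observed[colnames(tab$stats)])
  d2 <- rowSums(sweep(st$ref, 2, st$obs)^2)
  n_keep <- ceiling(tolerance * nrow(tab$stats))
  ord <- order(d2)[seq_len(n_keep)]
  retained <- tab$params[ord, , drop = FALSE]
  if (regression) {
    # local-linear conditional-mean correction: the regression is
    # trained on a wider neighbourhood (the closest `regression_frac`
    # of the table, Epanechnikov-weighted) because the retained set
    # alone is too sparse in statistic space to estimate the local
    # slope stably; each retained draw is then shifted by
    # m(s_obs) - m(s), the classical adjustment
    n_train <- max(n_keep,
                   min(nrow(tab$stats),
                       ceiling(regression_frac * nrow(tab$stats))))
    ord_t <- order(d2)[seq_len(n_train)]
    if (n_train > ncol(st$ref) + 2) {
      dmax <- sqrt(max(d2[ord_t]))
      w <- 1 - (sqrt(d2[ord_t]) / (dmax + 1e-12))^2
      X <- cbind(1, st$ref[ord_t, , drop = FALSE])
      XS <- cbind(1, st$ref[ord, , drop = FALSE])
      for (p in names(retained)) {
        spec_p <- if (!is.null(priors)) priors$spec[[p]] else NULL
        # transforms keep adjusted draws inside the prior support:
        # logit for rate-like [0, 1] parameters, log for positive ones
        kind <- if (!is.null(spec_p) && spec_p$min >= 0 &&
                      spec_p$max <= 1) "logit"
                else if (!is.null(spec_p) && spec_p$min > 0) "log"
                else "identity"
        eps <- 1e-6
        tr <- switch(kind,
          logit = function(v) log(pmin(pmax(v, eps), 1 - eps) /
                                    (1 - pmin(pmax(v, eps), 1 - eps))),
          log = function(v) log(pmax(v, eps)),
          identity)
        un <- switch(kind,
          logit = function(v) 1 / (1 + exp(-v)),
          log = exp,
          identity)
        fit <- stats::lm.wfit(X, tr(tab$params[[p]][ord_t]), w)
        coef <- fit$coefficients
        coef[is.na(coef)] <- 0
        m_s <- as.numeric(XS %*% coef)
        m_obs <- sum(c(1, st$obs) * coef)
        retained[[p]] <- un(tr(retained[[p]]) - m_s + m_obs)
      }
    }
  }
  summary <- do.call(rbind, lapply(names(retained), function(p)
    data.frame(parameter = p, mean = mean(retained[[p]]),
               median = median(retained[[p]]),
               q025 = quantile(retained[[p]], 0.025, names = FALSE),
               q975 = quantile(retained[[p]], 0.975, names = FALSE))))
  structure(list(retained = retained, summary = summary,
                 distances = sqrt(d2[ord]), tolerance = tolerance,
                 n_retained = n_keep, regression = regression),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("abc_posterior: %d retained draws (tolerance %.3g%s)\n",
              x$n_retained, x$tolerance,
              if (x$regression) ", regression-adjusted" else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Posterior scenario probabilities
#'
#' All reference tables are pooled, statistics standardised by the
#' pooled MAD, and each scenario's probability is its share among the
#' globally closest `ceil(tolerance sum(N))` rows.
#'
#' @param observed Named statistic vector.
#' @param tables Named list of `abc_reference_table`s sharing one
#'   statistic design.
#' @param tolerance Retained fraction.
#' @return Named probability vector (sums to 1).
#' @export
compare_scenarios <- function(observed, tables, tolerance = 0.01) {
  stopifnot(length(tables) >= 2)
  lab <- rep(names(tables), vapply(tables, function(t) nrow(t$stats), 0))
  stats <- do.call(rbind, lapply(tables, `[[`, "stats"))
  st <- standardize_stats(stats, observed[colnames(stats)])
  d2 <- rowSums(sweep(st$ref, 2, st$obs)^2)
  n_keep <- ceiling(tolerance * nrow(stats))
  sel <- lab[order(d2)[seq_len(n_keep)]]
  tab <- table(factor(sel, levels = names(tables)))
  setNames(as.numeric(tab) / n_keep, names(tables))
}

#' Convert generations to years
#'
#' @param g Generations (>= 0).
#' @param generation_time Years per generation (default 15, a
#'   long-lived freshwater turtle).
#' @return Years.
#' @export
#' @examples
#' generations_to_years(380) # 5700
generations_to_years <- function(g, generation_time = 15) {
  stopifnot(all(g >= 0))
  g * generation_time
}

#' Write / read a scenario with priors as YAML
#'
#' @param scenario An [abc_scenario()].
#' @param priors An [abc_priors()].
#' @param path YAML file path.
#' @return `path` invisibly / a list `(scenario, priors)`.
#' @export
write_scenario_yaml <- function(scenario, priors, path) {
  yaml::write_yaml(list(
    name = scenario$name,
    populations = as.list(scenario$populations),
    Ne = scenario$Ne,
    events = scenario$events,
    priors = priors$spec,
    constraints = as.list(priors$constraints)), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  list(scenario = abc_scenario(unlist(y$populations), y$events, y$Ne,
                               name = y$name %||% "scenario"),
       priors = abc_priors(y$priors, unlist(y$constraints) %||%
                             character()))
}
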