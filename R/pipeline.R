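# Pipeline orchestration: stages as subcommands over one YAML config
# with a single global seed fanned out per stage, artifact writing and
# a manifest for traceability.

#' Default pipeline configuration
#'
#' The shipped synthetic walkthrough: two parental taxa at strong
#' differentiation plus a transect of sites crossing a cline, then
#' every analysis stage at desk-scale budgets.
#'
#' @return Nested list mirroring the YAML config schema.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "pondmix_out",
    synthetic = list(n_loci = 15, fst = 0.3, center_km = 500,
                     width_km = 40,
                     positions_km = seq(0, 1000, length.out = 11),
                     n_per_site = 12, discordance = 0.2,
                     steps_between = 16, steps_within = 2),
    stats = list(n_permutations = 99),
    admixture = list(K_max = 3, n_reps = 5, max_iter = 500,
                     subsample_max = 20, subsample_trigger = 25,
                     mcmc_note = list(burnin = 250000, mcmc = 750000)),
    hybrids = list(n_per_class = 20),
    cline = list(iterations = 9000, burnin = 1000, all_models = FALSE),
    network = list(max_steps = Inf),
    pca = list(n_axes = 3),
    abc = list(N = 300, tolerance = 0.05, n_loci = 8,
               mtdna_length = 600, n_per_pop = 15))
}

read_config <- function(config) {
  if (is.null(config)) return(default_config())
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop_pondmix("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(def[[k]]) && is.list(cfg[[k]])) {
      unknown2 <- setdiff(names(cfg[[k]]), names(def[[k]]))
      if (length(unknown2))
        stop_pondmix("unknown config key(s) in '", k, "': ",
                     paste(unknown2, collapse = ", "))
      def[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else def[[k]] <- cfg[[k]]
  }
  def
}

#' Run pipeline stages
#'
#' Subcommands: `simulate` (synthetic dataset with truth), `stats`,
#' `admixture`, `hybrids`, `cline`, `network`, `pca`, `abc`, or `all`.
#' Later stages read the artifacts earlier stages wrote into `out_dir`;
#' `all` runs the full synthetic walkthrough and writes a manifest.
#' Every stage derives its own seed from the global seed via
#' [seed_stream()], so stages are reproducible independently of
#' execution order.
#'
#' @param subcommand One of the stage names above.
#' @param config Path to a YAML config, a config list, or NULL for the
#'   shipped defaults.
#' @param seed Optional override of the config's global seed.
#' @param out Optional override of the config's output directory.
#' @return Invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(subcommand = "all", config = NULL, seed = NULL,
                         out = NULL) {
  cmds <- c("simulate", "stats", "admixture", "hybrids", "cline",
            "network", "pca", "abc", "all")
  if (!subcommand %in% cmds)
    stop_pondmix("unknown subcommand '", subcommand, "'; expected one of: ",
                 paste(cmds, collapse = ", "))
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out)) cfg$out_dir <- out
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (subcommand == "all")
    c("simulate", "stats", "admixture", "hybrids", "cline", "network",
      "pca", "abc") else subcommand
  artifacts <- character()
  for (st in stages) {
    message("[pondmix] stage ", st)
    t0 <- proc.time()[3]
    artifacts <- c(artifacts, run_stage(st, cfg))
    message(sprintf("[pondmix] stage %s done (%.1f s)", st,
                    proc.time()[3] - t0))
  }
  manifest <- list(package = "pondmix",
                   version = as.character(packageVersion("pondmix")),
                   subcommand = subcommand, seed = cfg$seed,
                   config = cfg, artifacts = basename(artifacts))
  mp <- file.path(cfg$out_dir, "manifest.json")
  write_results(manifest, mp)
  invisible(c(artifacts, mp))
}

art <- function(cfg, name) file.path(cfg$out_dir, name)

load_simulated <- function(cfg) {
  gp <- art(cfg, "genotypes.str")
  if (!file.exists(gp))
    stop_pondmix("missing upstream artifact ", gp,
                 ": run the 'simulate' stage first")
  list(genotypes = read_genotypes(gp, "structure_2row"),
       alignment = read_fasta(art(cfg, "mtdna.fasta")),
       sites = read_sites(art(cfg, "sites.tsv")),
       truth = jsonlite::fromJSON(art(cfg, "truth.json")))
}

run_stage <- function(stage, cfg) {
  s <- cfg$synthetic
  switch(stage,
    simulate = {
      sd <- seed_stream(cfg$seed, "simulate")
      taxa <- make_taxa(2, n_loci = s$n_loci,
                        F_vector = rep(drift_for_fst(s$fst), 2),
                        seed = sd)
      sim <- simulate_transect(taxa[[1]], taxa[[2]], s$center_km,
                               s$width_km, s$positions_km,
                               n_per_site = s$n_per_site, seed = sd,
                               steps_within = s$steps_within,
                               discordance = s$discordance)
      p1 <- write_genotypes(sim$genotypes, art(cfg, "genotypes.str"))
      p2 <- write_fasta(sim$alignment, art(cfg, "mtdna.fasta"))
      p3 <- write_sites(sim$sites, art(cfg, "sites.tsv"))
      truth <- sim$truth
      truth$mt_lineage <- as.list(setNames(
        attr(sim$alignment, "lineage"), names(sim$alignment)))
      p4 <- write_results(truth, art(cfg, "truth.json"))
      c(p1, p2, p3, p4)
    },
    stats = {
      d <- load_simulated(cfg)
      grp <- d$genotypes$site
      lin <- vapply(names(d$alignment), function(id)
        d$truth$mt_lineage[[id]], "")
      div <- diversity_indices(d$genotypes, d$alignment,
                               groups = setNames(grp,
                                                 d$genotypes$individuals))
      p1 <- write_results(div, art(cfg, "diversity.tsv"))
      fst <- pairwise_fst(gt = d$genotypes, groups = grp,
                          seed = seed_stream(cfg$seed, "stats"))
      p2 <- write_results(as.data.frame(fst$fst), art(cfg, "fst.tsv"))
      nul <- null_allele_scan(d$genotypes)
      p3 <- write_results(as.data.frame(nul), art(cfg, "null_alleles.tsv"))
      c(p1, p2, p3)
    },
    admixture = {
      d <- load_simulated(cfg)
      a <- cfg$admixture
      sd <- seed_stream(cfg$seed, "admixture")
      gt <- subsample_sites(d$genotypes, a$subsample_max,
                            a$subsample_trigger, seed = sd)
      ks <- run_replicates(gt, 1:a$K_max, n_reps = a$n_reps, seed = sd,
                           max_iter = a$max_iter)
      fit <- ks$best_fit[[paste0("K", ks$selected_K)]]
      qdf <- data.frame(id = rownames(fit$Q), site = fit$site,
                        fit$Q, check.names = FALSE)
      names(qdf)[-(1:2)] <- paste0("Q", seq_len(fit$K))
      p1 <- write_results(qdf, art(cfg, "ancestry_q.tsv"))
      mq <- mean_q_per_site(fit, d$sites, cluster = fit$K)
      p2 <- write_results(mq, art(cfg, "mean_q_per_site.tsv"))
      p3 <- write_results(list(selected_K = ks$selected_K,
                               deltaK = as.list(setNames(ks$deltaK,
                                 paste0("K", ks$K_range))),
                               mean_lnL = as.list(setNames(ks$mean_lnL,
                                 paste0("K", ks$K_range))),
                               flags = ks$flags,
                               mcmc_note = cfg$admixture$mcmc_note),
                          art(cfg, "k_selection.json"))
      c(p1, p2, p3)
    },
    hybrids = {
      d <- load_simulated(cfg)
      sd <- seed_stream(cfg$seed, "hybrids")
      pt <- d$truth$sites
      pureA <- subset_individuals(d$genotypes,
        d$genotypes$site %in% pt$site[pt$p_true < 0.1])
      pureB <- subset_individuals(d$genotypes,
        d$genotypes$site %in% pt$site[pt$p_true > 0.9])
      hs <- simulate_hybrids(pureA, pureB,
                             n_per_class = cfg$hybrids$n_per_class,
                             seed = sd)
      cal <- calibrate_threshold(pureA, pureB, hs, seed = sd)
      p1 <- write_hybrid_set(hs, art(cfg, "hybrid_classes.str"))
      p2 <- write_results(list(threshold = cal$threshold,
                               fallback = cal$fallback,
                               table_at_threshold =
                                 as.data.frame(cal$table_at_threshold),
                               table_at_085 =
                                 as.data.frame(cal$table_at_085)),
                          art(cfg, "threshold_calibration.json"))
      c(p1, p2)
    },
    cline = {
      d <- load_simulated(cfg)
      mqp <- art(cfg, "mean_q_per_site.tsv")
      if (!file.exists(mqp))
        stop_pondmix("missing upstream artifact ", mqp,
                     ": run the 'admixture' stage first")
      mq <- read.table(mqp, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      ft <- data.frame(site = mq$site, freq = mq$mean_Q, n = 2 * mq$n)
      tro <- transect_data(d$sites, "t1", ft)
      cl <- cfg$cline
      sd <- seed_stream(cfg$seed, "cline")
      if (isTRUE(cl$all_models)) {
        sel <- select_model_aic(tro, iterations = cl$iterations,
                                burnin = cl$burnin, seed = sd)
        fit <- sel$best
        p0 <- write_results(sel$table, art(cfg, "cline_aic.tsv"))
      } else {
        fit <- fit_cline_mcmc(tro, "fixed", "none",
                              iterations = cl$iterations,
                              burnin = cl$burnin, seed = sd)
        p0 <- character()
      }
      p1 <- write_results(list(scaling = fit$scaling, tails = fit$tails,
                               params = as.list(fit$params),
                               ci = list(lower = as.list(fit$ci[1, ]),
                                         upper = as.list(fit$ci[2, ])),
                               lnL = fit$lnL, AIC = fit$AIC),
                          art(cfg, "cline_fit.json"))
      p2 <- write_results(cline_envelope(fit), art(cfg, "cline_envelope.tsv"))
      c(p0, p1, p2)
    },
    network = {
      d <- load_simulated(cfg)
      lin <- vapply(names(d$alignment), function(id)
        d$truth$mt_lineage[[id]], "")
      attr(d$alignment, "lineage") <- lin
      hs <- unique_haplotypes(d$alignment)
      net <- build_network(hs, max_steps = cfg$network$max_steps)
      ps <- write_network(net, art(cfg, "haplotype_network"))
      htab <- data.frame(haplotype = names(hs$haplotypes),
                         frequency = hs$frequency)
      if (!is.null(hs$membership))
        htab <- cbind(htab, as.data.frame.matrix(hs$membership))
      ph <- write_results(htab, art(cfg, "haplotypes.tsv"))
      steps <- lineage_step_summary(hs)
      p2 <- write_results(steps$within, art(cfg, "lineage_steps_within.tsv"))
      p3 <- if (!is.null(steps$between))
        write_results(steps$between, art(cfg, "lineage_steps_between.tsv"))
      else character()
      c(ps, ph, p2, p3)
    },
    pca = {
      d <- load_simulated(cfg)
      pc <- pca_genotypes(d$genotypes, n_axes = cfg$pca$n_axes,
                          groups = d$genotypes$site)
      df <- data.frame(id = rownames(pc$scores), site = d$genotypes$site,
                       pc$scores, check.names = FALSE)
      p1 <- write_results(df, art(cfg, "pca_scores.tsv"))
      p2 <- write_results(list(percent_variance =
                                 as.list(setNames(pc$percent_variance,
                                   paste0("PC", seq_along(pc$percent_variance))))),
                          art(cfg, "pca_variance.json"))
      c(p1, p2)
    },
    abc = {
      a <- cfg$abc
      sd <- seed_stream(cfg$seed, "abc")
      scen <- scenario_atlantic()
      pri <- default_priors(scen)
      sizes <- setNames(rep(a$n_per_pop, 3), c("occ", "orb", "adm"))
      truth_par <- c(N_occ = 2000, N_orb = 2000, N_adm = 1000,
                     t_adm = 400, t_div = 20000, r = 0.3)
      obs <- simulate_dataset(scen, truth_par, sizes,
                              n_microsat_loci = a$n_loci,
                              mtdna_length = a$mtdna_length,
                              seed = seed_stream(sd, "observed"))
      tab <- build_reference_table(scen, pri, N = a$N,
                                   sample_sizes = sizes,
                                   n_microsat_loci = a$n_loci,
                                   mtdna_length = a$mtdna_length,
                                   seed = sd)
      post <- abc_reject(summary_stats(obs$genotypes, obs$alignment),
                         tab, tolerance = a$tolerance)
      p1 <- write_reference_table(tab, art(cfg, "abc_reference_table.tsv"))
      summ <- post$summary
      summ$mean_years <- ifelse(startsWith(summ$parameter, "t"),
                                generations_to_years(summ$mean), NA)
      p2 <- write_results(list(pseudo_observed_truth = as.list(truth_par),
                               posterior = summ),
                          art(cfg, "abc_posterior.json"))
      c(p1, p2)
    })
}

#' Command-line entry point
#'
#' `pondmix <subcommand> [--config cfg.yaml] [--seed N] [--out DIR]`.
#' Exit codes: 0 ok, 1 usage error, 2 data/config error.
#'
#' @param args Character vector of CLI arguments (default: the
#'   command line).
#' @return Exit status, invisibly.
#' @export
pondmix_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: pondmix <simulate|stats|admixture|hybrids|cline|network|pca|abc|all> [--config cfg.yaml] [--seed N] [--out DIR]"
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(args)) 0L else 1L))
  }
  sub <- args[1]; args <- args[-1]
  opt <- list(config = NULL, seed = NULL, out = NULL)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message(usage); return(invisible(1L))
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    run_pipeline(sub, config = opt$config, seed = opt$seed,
                 out = opt$out)
    0L
  }, error = function(e) {
    message("pondmix error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
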