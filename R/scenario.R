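#' Experiment configuration
#'
#' Bundles every knob of the simulation study. Two presets:
#' \describe{
#'   \item{paper_full}{29 chromosomes x 2.33 M, 100,000 SNPs, 750 QTL (125
#'     with dominance), 1000-generation burn-in at N = 1000, expansion to
#'     1400 (200 males) over 5 generations, founder populations of 700
#'     (100 M / 600 F), 700 offspring per selection generation. Multi-hour
#'     at full scale.}
#'   \item{desk_small}{structure-preserving reduction (~1/50 compute): 5
#'     chromosomes x 2.33 M, 2000 SNPs, 150 QTL (25 with dominance),
#'     100-generation burn-in at N = 300, expansion to 400 (60 males),
#'     founder populations of 200 (30 M / 170 F), 200 offspring per
#'     generation.}
#' }
#'
#' @param preset `"desk_small"` or `"paper_full"`.
#' @param replicates number of independent replicates.
#' @param seed root seed; every stream is derived from it.
#' @param strategies character vector among `"TS1"`, `"TS2"`, `"LP"`,
#'   `"OCS_maxBVE"`, `"OCS_minKin_I"` ... `"OCS_minKin_IV"`.
#' @param gamma inbreeding-effect coefficient of the LP selection index.
#' @param delta_k per-generation kinship increment allowed under
#'   OCS_maxBVE.
#' @param gain_bounds gain lower bounds of the four OCS_minKin levels.
#' @param out_dir optional output directory for the metrics CSV, config
#'   echo and logs.
#' @param ... overrides for any preset field (e.g. `burn_in`, `n_snps`).
#' @return an `ExperimentConfig` list.
#' @export
experiment_config <- function(preset = c("desk_small", "paper_full"),
                              replicates = 10, seed = 1,
                              strategies = c("TS1", "LP", "TS2", "OCS_maxBVE",
                                             "OCS_minKin_I", "OCS_minKin_II",
                                             "OCS_minKin_III", "OCS_minKin_IV"),
                              gamma = 1, delta_k = 0.01,
                              gain_bounds = c(0.05, 0.07, 0.10, 0.20),
                              out_dir = NULL, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "desk_small") {
    list(n_chr = 5, chr_len = 2.33, n_snps = 2000, n_qtl = 150, n_dom = 25,
         mutation_rate = 1e-5, burn_in = 100, burn_n = 300,
         expand_n = 400, expand_males = 60, expand_gens = 5,
         n_offspring = 200, n_off_males = 30, n_generations = 15)
  } else {
    list(n_chr = 29, chr_len = 2.33, n_snps = 100000, n_qtl = 750,
         n_dom = 125, mutation_rate = 1e-5, burn_in = 1000, burn_n = 1000,
         expand_n = 1400, expand_males = 200, expand_gens = 5,
         n_offspring = 700, n_off_males = 100, n_generations = 15)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  cfg <- c(base,
           list(preset = preset, replicates = replicates, seed = seed,
                strategies = strategies, gamma = gamma, delta_k = delta_k,
                gain_bounds = gain_bounds,
                h2 = c(0.44, 0.48, 0.45, 0.30, 0.22),
                weights = c(0.35, 0.25, 0.25, 0.15),
                male_frac = 0.10, female_frac = 0.50, male_cap = 10,
                out_dir = out_dir))
  if (cfg$replicates < 1 || cfg$n_offspring <= 0)
    stop("invalid config: replicates >= 1 and n_offspring > 0 required")
  structure(cfg, class = "ExperimentConfig")
}

# Joint GBLUP evaluation of founder + current generation: the founders are
# carried as reference animals in the GRM so GEBVs of all generations share
# one (centered) scale and cross-generation gain is meaningful.
evaluate_generation <- function(founder, founder_pheno, current, current_pheno,
                                spec, h2, traits) {
  if (is.null(current)) {
    M <- dosage_matrix(founder, spec, "snp")
    K <- compute_grm(M)
    gf <- vapply(traits, function(t) solve_gblup(founder_pheno[, t], K, h2[t]),
                 numeric(nrow(M)))
    colnames(gf) <- as.character(traits)
    return(list(founder = gf, current = gf))
  }
  n1 <- n_ind(founder)
  M <- rbind(dosage_matrix(founder, spec, "snp"),
             dosage_matrix(current, spec, "snp"))
  K <- compute_grm(M)
  gh <- vapply(traits, function(t) {
    solve_gblup(c(founder_pheno[, t], current_pheno[, t]), K, h2[t])
  }, numeric(nrow(M)))
  colnames(gh) <- as.character(traits)
  list(founder = gh[seq_len(n1), , drop = FALSE],
       current = gh[-seq_len(n1), , drop = FALSE])
}

metric_rows <- function(generation, metric, trait, value) {
  data.frame(generation = generation, metric = metric,
             trait = as.character(trait), value = value,
             stringsAsFactors = FALSE)
}

# One breeding strategy for config$n_generations generations from a founder
# population. Returns the tidy per-generation metrics table.
run_strategy <- function(strategy, fp, fp_pheno, spec, archs, config) {
  traits <- if (strategy %in% c("TS1", "LP")) 1:4 else 5
  h2 <- config$h2
  founder_tgv <- vapply(archs, function(a) true_genetic_values(fp, a, spec),
                        numeric(n_ind(fp)))
  # kinship is anchored at founder allele frequencies so it accumulates
  # across generations; loci monomorphic in the founders are dropped
  fnd_X <- dosage_matrix(fp, spec, "snp")
  fnd_p <- colMeans(fnd_X) / 2
  anchor <- fnd_p > 0 & fnd_p < 1
  fnd_p <- fnd_p[anchor]
  pop <- fp; pheno <- fp_pheno
  rows <- vector("list", config$n_generations + 1)

  for (gen in 0:config$n_generations) {
    is_founder_gen <- gen == 0
    ev <- evaluate_generation(fp, fp_pheno,
                              if (is_founder_gen) NULL else pop,
                              if (is_founder_gen) NULL else pheno,
                              spec, h2, traits)
    X <- dosage_matrix(pop, spec, "snp")
    Kin <- iis_kinship_matrix(X[, anchor, drop = FALSE], fnd_p)
    Xq <- dosage_matrix(pop, spec, "qtl")
    qfreq <- colMeans(Xq) / 2
    tgv <- vapply(archs, function(a) true_genetic_values(pop, a, spec),
                  numeric(n_ind(pop)))

    rec <- list(
      metric_rows(gen, "avg_kinship", NA, mean(Kin[upper.tri(Kin)])),
      metric_rows(gen, "het_obs", NA, observed_heterozygosity(X)),
      metric_rows(gen, "qtl_var", seq_along(archs),
                  vapply(archs, function(a) qtl_effect_variance(qfreq, a$a),
                         0)),
      metric_rows(gen, "gain_gebv", traits,
                  vapply(as.character(traits), function(t)
                    genetic_gain(ev$current[, t], ev$founder[, t]), 0)),
      metric_rows(gen, "gain_tgv", seq_along(archs),
                  colMeans(tgv) - colMeans(founder_tgv))
    )
    if (strategy %in% c("TS1", "LP")) {
      wsg_cur <- compute_wsg(ev$current[, as.character(1:4)], config$weights)
      wsg_fnd <- compute_wsg(ev$founder[, as.character(1:4)], config$weights)
      rec <- c(rec, list(metric_rows(gen, "gain_gebv", "WSG",
                                     genetic_gain(wsg_cur, wsg_fnd))))
      score <- wsg_cur
    } else {
      score <- ev$current[, "5"]
    }
    rows[[gen + 1]] <- do.call(rbind, rec)
    if (gen == config$n_generations) break

    plan <- NULL
    breed_pop <- pop
    if (strategy %in% c("TS1", "TS2")) {
      cand <- select_candidates_by_score(pop, score, config$male_frac,
                                         config$female_frac)
      breed_pop <- pop_subset(pop, sort(c(cand$males, cand$females)))
    } else if (strategy == "LP") {
      cand <- select_candidates_by_score(pop, score, config$male_frac,
                                         config$female_frac)
      all_cand <- c(cand$males, cand$females)
      sd_wsg <- stats::sd(score[all_cand])
      I <- selection_index_matrix(score[cand$males], score[cand$females],
                                  Kin[cand$males, cand$females, drop = FALSE],
                                  config$gamma, sd_wsg)
      req <- min(length(cand$males) * config$male_cap, length(cand$females))
      sol <- solve_mating_lp(I, config$male_cap, 1, req)
      plan <- realize_lp_plan(sol, config$n_offspring,
                              pop$id[cand$males], pop$id[cand$females])
    } else {
      cand <- select_ocs_male_candidates(pop, score, config$male_frac)
      ci <- c(cand$males, cand$females)
      Kc <- Kin[ci, ci, drop = FALSE]
      gc_ <- score[ci]
      sexc <- pop$sex[ci]
      baseline <- mean(score)
      sol <- if (strategy == "OCS_maxBVE") {
        # offspring mean kinship may exceed the current population's
        # average kinship by at most delta_k; if even the kinship-minimal
        # contribution cannot meet that, fall back to the minimum
        ub <- mean(Kin[upper.tri(Kin)]) + config$delta_k
        tryCatch(
          solve_ocs(gc_, Kc, sexc, "maxBVE", kinship_upper_bound = ub,
                    gain_baseline = baseline),
          error = function(e) {
            s <- solve_ocs(gc_, Kc, sexc, "minKin", gain_lower_bound = -Inf,
                           gain_baseline = baseline)
            s$status <- paste("fallback (kinship bound infeasible):",
                              conditionMessage(e))
            s
          })
      } else {
        lev <- match(strategy, paste0("OCS_minKin_", c("I", "II", "III", "IV")))
        tryCatch(
          solve_ocs(gc_, Kc, sexc, "minKin",
                    gain_lower_bound = config$gain_bounds[lev],
                    gain_baseline = baseline),
          error = function(e) {
            # unreachable gain bound: fall back to the unconstrained
            # kinship minimum and record the substitution
            s <- solve_ocs(gc_, Kc, sexc, "minKin", gain_lower_bound = -Inf,
                           gain_baseline = baseline)
            s$status <- paste("fallback (gain bound infeasible):",
                              conditionMessage(e))
            s
          })
      }
      plan <- realize_contributions(sol$c, sexc, pop$id[ci],
                                    config$n_offspring)
    }
    pop <- breed_generation(breed_pop, spec, config$n_offspring,
                            plan = plan, n_males = config$n_off_males)
    pheno <- phenotypes(pop, archs, spec)
  }
  do.call(rbind, rows)
}

# Founder pipeline: burn-in, expansion, split, trait calibration on the
# (pre-split) founder generation, founder phenotypes.
simulate_founders <- function(config) {
  spec <- build_genome_spec(config$n_chr, config$chr_len, config$n_snps,
                            config$n_qtl, config$n_dom, config$mutation_rate)
  pop <- run_burn_in(spec, config$burn_in, config$burn_n)
  pop <- run_expansion(pop, spec, config$expand_n, config$expand_males,
                       config$expand_gens)
  archs <- sample_architecture(spec, config$h2, pop)
  fps <- split_founders(pop)
  list(spec = spec, archs = archs, fp1 = fps$fp1, fp2 = fps$fp2,
       pheno1 = phenotypes(fps$fp1, archs, spec),
       pheno2 = phenotypes(fps$fp2, archs, spec))
}

strategy_seed <- function(root, replicate, strategy_index) {
  (root + 7919 * replicate + 1000003 * strategy_index) %% 2147483629L
}

#' Run the full simulation experiment
#'
#' For each replicate: one founder pipeline (burn-in, expansion, split into
#' FP1 and FP2), then every requested strategy from the same founder
#' snapshots (FP1 feeds TS1 and LP; FP2 feeds TS2 and the OCS variants).
#' Bit-reproducible under the root seed.
#'
#' @param config an [experiment_config()].
#' @return a `data.frame` with columns `replicate`, `strategy`,
#'   `generation` (0 = founder), `metric`, `trait`, `value`. If
#'   `config$out_dir` is set, also writes `metrics.csv` and a JSON config
#'   echo there.
#' @export
run_experiment <- function(config) {
  all_rows <- vector("list", config$replicates)
  strat_index <- seq_along(config$strategies)
  for (rep in seq_len(config$replicates)) {
    set.seed(strategy_seed(config$seed, rep, 0L))
    founders <- simulate_founders(config)
    rep_rows <- lapply(strat_index, function(si) {
      s <- config$strategies[si]
      set.seed(strategy_seed(config$seed, rep, si))
      fp <- if (s %in% c("TS1", "LP")) founders$fp1 else founders$fp2
      ph <- if (s %in% c("TS1", "LP")) founders$pheno1 else founders$pheno2
      out <- run_strategy(s, fp, ph, founders$spec, founders$archs, config)
      cbind(replicate = rep, strategy = s, out)
    })
    all_rows[[rep]] <- do.call(rbind, rep_rows)
    message("replicate ", rep, "/", config$replicates, " done")
  }
  metrics <- do.call(rbind, all_rows)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(metrics, file.path(config$out_dir, "metrics.csv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      echo <- unclass(config)
      jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }
  metrics
}

#' Final-generation summary per strategy
#'
#' Convenience reshaping: mean over replicates of each metric at the last
#' generation.
#'
#' @param metrics output of [run_experiment()].
#' @return a `data.frame` with one row per strategy / metric / trait.
#' @export
summarize_final <- function(metrics) {
  last <- max(metrics$generation)
  fin <- metrics[metrics$generation == last, , drop = FALSE]
  fin$trait[is.na(fin$trait)] <- ""
  agg <- stats::aggregate(value ~ strategy + metric + trait, data = fin,
                          FUN = mean)
  agg[order(agg$metric, agg$trait, agg$strategy), , drop = FALSE]
}

#' Simple per-metric line plot across generations
#'
#' @param metrics output of [run_experiment()].
#' @param metric metric name to plot (e.g. `"avg_kinship"`).
#' @param trait optional trait filter.
#' @return invisibly, the plotted replicate-mean table.
#' @export
plot_metric <- function(metrics, metric, trait = NA) {
  sel <- metrics$metric == metric &
    (is.na(trait) | metrics$trait %in% as.character(trait))
  d <- metrics[sel, , drop = FALSE]
  if (!nrow(d)) stop("no rows for metric ", metric)
  m <- stats::aggregate(value ~ strategy + generation, data = d, FUN = mean)
  strategies <- unique(m$strategy)
  graphics::plot(NULL, xlim = range(m$generation), ylim = range(m$value),
                 xlab = "generation", ylab = metric)
  for (i in seq_along(strategies)) {
    mi <- m[m$strategy == strategies[i], ]
    graphics::lines(mi$generation, mi$value, col = i)
  }
  graphics::legend("topleft", legend = strategies, col = seq_along(strategies),
                   lty = 1, cex = 0.7)
  invisible(m)
}
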