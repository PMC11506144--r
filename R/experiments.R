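# Scenario drivers: orchestrate founder simulation, F1 construction,
# trait-pair simulation and model fitting over grids of heritability,
# genetic correlation and reference size, mirroring a two-generation
# pig-breeding evaluation (phenotyped parents as the reference population,
# unphenotyped F1 sampled as selection candidates).

#' Configuration for the scenario drivers
#'
#' Defaults mirror the evaluated breeding design: 1 sire per 24 dams, 12
#' offspring per dam, 2000 selection candidates, 500 LD-paired QTLs with
#' shared signed gamma(0.4, scale 2/3) effects, 50 replicates, and equal
#' heritabilities in \{0.1, 0.3, 0.5\} crossed with genetic correlations in
#' \{0.2, 0.5, 0.8\}.  Reference sizes must be multiples of 25 so the 1:24
#' sire:dam ratio holds exactly.  Genome-size parameters control the
#' synthetic founder panel and can be scaled down for desk-scale runs.
#'
#' @param h2_levels Equal-heritability levels (scenario 1).
#' @param h2_pairs List of unequal heritability pairs \code{c(h2_a, h2_b)}
#'   (scenario 2).
#' @param rg_levels Genetic-correlation targets.
#' @param ref_sizes Reference-population sizes (scenario 1 grid).
#' @param ref_size_2 Reference size for scenario 2.
#' @param n_replicates Replicates per cell.
#' @param n_candidates F1 candidates sampled for accuracy evaluation.
#' @param n_chrom,snps_per_chrom,chrom_length_bp,adjacency_rho,maf_low
#'   Founder-genome parameters (see \code{\link{simulate_founders}}).
#' @param n_qtl,gamma_shape,gamma_scale Trait-architecture parameters.
#' @param dams_per_sire,offspring_per_dam Mating design.
#' @param pair_window,pair_tolerance QTL-pairing search parameters.
#' @param squared Report squared correlation as accuracy (default) rather
#'   than plain correlation.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A \code{scenario_config} list.
#' @export
scenario_config <- function(h2_levels = c(0.1, 0.3, 0.5),
                            h2_pairs = list(c(0.1, 0.3), c(0.1, 0.5),
                                            c(0.3, 0.5)),
                            rg_levels = c(0.2, 0.5, 0.8),
                            ref_sizes = c(900, 1800, 2700, 3600, 4500),
                            ref_size_2 = 4500,
                            n_replicates = 50, n_candidates = 2000,
                            n_chrom = 3, snps_per_chrom = 1000,
                            chrom_length_bp = 1e8, adjacency_rho = 0.9,
                            maf_low = 0.05, n_qtl = 500,
                            gamma_shape = 0.4, gamma_scale = 2 / 3,
                            dams_per_sire = 24, offspring_per_dam = 12,
                            pair_window = 50, pair_tolerance = 0.05,
                            squared = TRUE, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_replicates < 1) stop("'n_replicates' must be at least 1")
  if (2 * cfg$n_qtl >= cfg$n_chrom * cfg$snps_per_chrom)
    stop(sprintf("panel of %d SNPs cannot host %d QTL pairs",
                 cfg$n_chrom * cfg$snps_per_chrom, cfg$n_qtl))
  for (s in c(cfg$ref_sizes, cfg$ref_size_2)) check_ref_size(s, cfg)
  structure(cfg, class = "scenario_config")
}

check_ref_size <- function(size, cfg) {
  per_sire <- cfg$dams_per_sire + 1
  if (size %% per_sire != 0)
    stop(sprintf(
      "reference size %d infeasible: must be a multiple of %d (1 sire + %d dams)",
      size, per_sire, cfg$dams_per_sire))
  n_dams <- size - size %/% per_sire
  if (n_dams * cfg$offspring_per_dam < cfg$n_candidates)
    stop(sprintf(
      "reference size %d yields only %d offspring, fewer than %d candidates",
      size, n_dams * cfg$offspring_per_dam, cfg$n_candidates))
  invisible(size)
}

# One genome realisation shared by every trait combination of a
# (reference size, replicate) pair: founders, F1, candidate sample, panel
# of reference + candidates, and its GRM (frequencies computed jointly).
sim_genome <- function(cfg, ref_size, seed) {
  n_sires <- ref_size %/% (cfg$dams_per_sire + 1)
  founders <- simulate_founders(
    ref_size, n_chrom = cfg$n_chrom, snps_per_chrom = cfg$snps_per_chrom,
    chrom_length_bp = cfg$chrom_length_bp, adjacency_rho = cfg$adjacency_rho,
    maf_low = cfg$maf_low, n_males = n_sires, seed = derive_seed(seed, 1))
  design <- mating_design(founders, cfg$dams_per_sire,
                          cfg$offspring_per_dam, seed = derive_seed(seed, 2))
  f1 <- build_f1(founders, design, seed = derive_seed(seed, 3))
  cand <- sample_candidates(f1$panel, cfg$n_candidates,
                            seed = derive_seed(seed, 4))
  panel <- combine_panels(founders, subset_panel(f1$panel, cand))
  grm <- compute_grm(dosages(panel))
  list(founders = founders, pedigree = f1$pedigree, candidates = cand,
       panel = panel, grm = grm)
}

# Fit single-trait (per trait) and bivariate models on one simulated trait
# pair and score candidate accuracy; returns tidy rows.
fit_cell <- function(cfg, genome, sim, h2_a, h2_b, rg, ref_size, rep) {
  ref_ids <- genome$founders$ids
  cand <- genome$candidates
  ya <- sim$trait_a$phenotype[ref_ids]
  yb <- sim$trait_b$phenotype[ref_ids]
  tbv <- list(A = sim$trait_a$tbv[cand], B = sim$trait_b$tbv[cand])

  one <- function(fit, model, trait, col, secs) {
    data.frame(ref_size = ref_size, replicate = rep, h2_a = h2_a,
               h2_b = h2_b, rg_target = rg, model = model, trait = trait,
               accuracy = accuracy(predict(fit, cand)[, col], tbv[[trait]],
                                   squared = cfg$squared),
               est_h2 = fit$h2[col],
               est_rg = if (is.null(fit$rg)) NA_real_ else fit$rg,
               converged = fit$converged, reml_iters = max(fit$trace$iter),
               seconds = secs)
  }
  t0 <- proc.time()[3]
  fa <- gblup(ya, genome$grm)
  t1 <- proc.time()[3]
  fb <- gblup(yb, genome$grm)
  t2 <- proc.time()[3]
  fm <- gblup(cbind(A = ya, B = yb), genome$grm)
  t3 <- proc.time()[3]
  rbind(one(fa, "single", "A", 1, t1 - t0),
        one(fb, "single", "B", 1, t2 - t1),
        one(fm, "multi", "A", 1, (t3 - t2) / 2),
        one(fm, "multi", "B", 2, (t3 - t2) / 2))
}

run_cells <- function(cfg, ref_size, combos) {
  size_idx <- ref_size  # seeds keyed by the size itself: stable across grids
  out <- vector("list", 0L)
  for (rep in seq_len(cfg$n_replicates)) {
    genome <- sim_genome(cfg, ref_size, derive_seed(cfg$seed, size_idx, rep))
    for (ci in seq_along(combos)) {
      cmb <- combos[[ci]]
      # trait seed depends on the correlation level, not the heritability:
      # QTLs, effects and TBVs are shared across heritability settings of
      # one correlation level, as in the evaluated design
      tseed <- derive_seed(cfg$seed, size_idx, rep, round(1000 * cmb["rg"]))
      sim <- simulate_trait_pair(
        genome$panel,
        trait_spec(cmb["h2_a"], cfg$n_qtl, cfg$gamma_shape, cfg$gamma_scale),
        trait_spec(cmb["h2_b"], cfg$n_qtl, cfg$gamma_shape, cfg$gamma_scale),
        target_r = cmb["rg"], founder_ids = genome$founders$ids,
        window_snps = cfg$pair_window, tolerance = cfg$pair_tolerance,
        seed = tseed)
      out[[length(out) + 1L]] <-
        fit_cell(cfg, genome, sim, cmb["h2_a"], cmb["h2_b"], cmb["rg"],
                 ref_size, rep)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run scenario 1: equal-heritability combinations across reference sizes
#'
#' For every heritability level, genetic-correlation level, reference size
#' and replicate: simulate founders and F1 (genome shared across the trait
#' combinations of a replicate, as one genotype set underlies all trait
#' simulations), simulate the trait pair, fit both single-trait models and
#' the bivariate model, and score candidate-accuracy.  Non-convergent fits
#' are flagged in the output, never dropped.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return Tidy data frame, one row per (reference size, replicate,
#'   combination, model, trait).
#' @export
run_scenario1 <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  combos <- list()
  for (rg in config$rg_levels) for (h2 in config$h2_levels)
    combos[[length(combos) + 1L]] <- c(h2_a = h2, h2_b = h2, rg = rg)
  out <- lapply(config$ref_sizes,
                function(s) run_cells(config, s, combos))
  do.call(rbind, out)
}

#' Run scenario 2: unequal-heritability pairs at one reference size
#'
#' Same pipeline as \code{\link{run_scenario1}} but over
#' \code{config$h2_pairs} at \code{config$ref_size_2}; per-trait accuracies
#' are of interest here (the lower-heritability trait of a pair gains more
#' from joint modelling), so \code{\link{summarize_scenario}} should be
#' called with \code{per_trait = TRUE}.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return Tidy data frame as in \code{\link{run_scenario1}}.
#' @export
run_scenario2 <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  combos <- list()
  for (rg in config$rg_levels) for (pr in config$h2_pairs)
    combos[[length(combos) + 1L]] <- c(h2_a = pr[1], h2_b = pr[2], rg = rg)
  run_cells(config, config$ref_size_2, combos)
}

#' Summarise scenario results
#'
#' Mean and standard deviation of accuracy per cell and model, plus the
#' improvement of the multi-trait over the single-trait model.  By default
#' the two traits of a combination are averaged within each replicate
#' before aggregating across replicates; with \code{per_trait = TRUE} each
#' trait is summarised separately.
#'
#' @param results Output of \code{\link{run_scenario1}} or
#'   \code{\link{run_scenario2}}.
#' @param per_trait Keep traits separate? (default \code{FALSE})
#' @return Data frame with \code{accuracy_single}, \code{accuracy_multi},
#'   their standard deviations, \code{improvement} (multi - single) and
#'   \code{n_nonconverged}.
#' @export
summarize_scenario <- function(results, per_trait = FALSE) {
  stopifnot(nrow(results) >= 1)
  keys <- c("ref_size", "h2_a", "h2_b", "rg_target",
            if (per_trait) "trait")
  rep_keys <- c(keys, "replicate", "model")
  agg <- stats::aggregate(results["accuracy"], results[rep_keys], mean)
  nonc <- stats::aggregate(list(n_nonconverged = !results$converged),
                           results[keys], sum)
  cells <- unique(agg[keys])
  rownames(cells) <- NULL
  stat <- function(model, fun) {
    sub <- agg[agg$model == model, ]
    m <- stats::aggregate(sub["accuracy"], sub[keys], fun)
    m$accuracy[match(do.call(paste, cells), do.call(paste, m[keys]))]
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- cbind(cells,
               accuracy_single = stat("single", mean),
               sd_single = stat("single", sd0),
               accuracy_multi = stat("multi", mean),
               sd_multi = stat("multi", sd0))
  out$improvement <- out$accuracy_multi - out$accuracy_single
  out$n_nonconverged <-
    nonc$n_nonconverged[match(do.call(paste, out[keys]),
                              do.call(paste, nonc[keys]))]
  out[do.call(order, out[keys]), , drop = FALSE]
}
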