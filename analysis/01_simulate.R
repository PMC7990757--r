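#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study. A doubled-haploid population of 200
# lines genotyped at ~850 loci over 21 linkage groups (wheat scale), six
# environments with heterogeneous FA(1) G x E, AR1xAR1 plot noise, two
# replicates, two control varieties, a planted yield QTL on G2 and a
# phenology locus on G3 that also shifts yield. Everything is written as the
# CSV dialects the pipeline reads, with the generating truth as JSON.

suppressMessages(library(metqtl))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260921L %% 1000000L

map <- simulate_map(map_spec(n_groups = 21, length_cM = 120, n_markers = 41),
                    seed = seed)
gen <- simulate_dh_genotypes(map, 200, seed = seed + 1)

cfg <- sim_config(
  trait = "yld",
  qtl = data.frame(group = "G2", pos_cM = 60, effect = 0.5),
  n_envs = 6,
  Lambda = sqrt(c(1.0, 1.4, 0.8, 1.2, 1.0, 0.9)),
  Psi = 0.15,
  env_means = c(2.5, 1.8, 4.0, 3.2, 2.1, 2.8), # t/ha-scale trial means
  n_reps = 2, rep_var = 0.1, resid_sigma2 = 1,
  rho_row = 0.4, rho_col = 0.3, n_controls = 2,
  phenology = list(group = "G3", pos_cM = 40, effect_cov = 2,
                   effect_target = 0.4, cov_trait = "dth",
                   cov_mean = 100, cov_sigma2 = 1),
  seed = seed + 3)
sim <- simulate_met_phenotypes(gen, map, cfg)
# genotyping dropout applies to the observed matrix, after the phenotypes
# were generated from the complete genotypes
gen_obs <- inject_missing(gen, 0.03, seed = seed + 2)

write_map_csv(map, file.path(out, "map.csv"))
write_genotypes_csv(gen_obs, file.path(out, "genotypes.csv"))
write_phenotypes_csv(sim$phenotypes, file.path(out, "phenotypes.csv"))
write_truth_json(sim$truth, file.path(out, "truth.json"))

cat(sprintf("map: %d markers on %d groups; genotypes: %d lines (%.1f%% NA)\n",
            nrow(map), length(unique(map$group)), nrow(gen_obs),
            100 * mean(is.na(gen_obs))))
cat(sprintf("phenotypes: %d plots over %d environments; planted QTL %s@%g cM (effect %g)\n",
            nrow(sim$phenotypes), cfg$n_envs, cfg$qtl$group, cfg$qtl$pos_cM,
            cfg$qtl$effect))
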