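# a hand-built scan table for the merging logic
fake_scan <- function(p_main, p_qxe, group = "G1") {
  k <- length(p_main)
  df <- data.frame(group = group, pos_cM = seq(5, by = 10, length.out = k),
                   label = paste0(group, ":m", 1:k, "-m", 2:(k + 1)),
                   left_marker = paste0("m", 1:k),
                   right_marker = paste0("m", 2:(k + 1)),
                   W_main = qchisq(p_main, 1, lower.tail = FALSE),
                   p_main = p_main,
                   W_qxe = qchisq(p_qxe, 2, lower.tail = FALSE),
                   p_qxe = p_qxe,
                   main_est = 1, main_se = 0.2, skipped = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "eff_env") <- matrix(3, k, 3,
                                dimnames = list(df$label, c("E1", "E2", "E3")))
  attr(df, "se_env") <- matrix(1, k, 3,
                               dimnames = list(df$label, c("E1", "E2", "E3")))
  attr(df, "envs") <- c("E1", "E2", "E3")
  class(df) <- c("qtl_scan", "data.frame")
  df
}

test_that("trial filter drops environments below the 1% variance ratio", {
  fake_fit <- function(s2g, s2e) {
    structure(list(Sigma = diag(s2g, length(s2g)),
                   var_params = var_params(
                     list(type = "diag", sigma2_g = s2g),
                     resid = data.frame(env = paste0("E", seq_along(s2g)),
                                        sigma2 = s2e, rho_row = 0,
                                        rho_col = 0)),
                   design = list(envs = paste0("E", seq_along(s2g)))),
              class = "met_fit")
  }
  ft <- filter_trials(fake_fit(c(0.5, 2), c(100, 100)), ratio = 0.01)
  expect_equal(ft$dropped, "E1") # 0.5% < 1%
  expect_equal(ft$kept, "E2")    # 2% kept
  expect_error(filter_trials(fake_fit(0.5, 100)), "all trials")
})

test_that("the variance filter discriminates null trials from genetic ones", {
  # with 150 lines x 2 reps the sampling SD of sigma2_g_hat under a null
  # trial is ~0.08 sigma2_e, so the < 1% rule drops a truly-zero trial in
  # roughly half the replicates and a trial with real genetic variance in
  # essentially none; assert that separation
  map <- simulate_map(map_spec(n_groups = 1, length_cM = 50, n_markers = 4),
                      seed = 71)
  gen <- simulate_dh_genotypes(map, 150, seed = 72)
  drop_zero <- 0L; drop_real <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_envs = 3, Lambda = matrix(0, 3, 1), Psi = c(1, 1, 0),
                      n_reps = 2, rep_var = 0.05, resid_sigma2 = 1,
                      rho_row = 0, rho_col = 0, seed = 700 + r)
    sim <- simulate_met_phenotypes(gen, map, cfg)
    d <- build_design(sim$phenotypes, "yld", rownames(gen),
                      model_spec("diag", residual = "iid"))
    f <- reml_fit(d, pev = FALSE, tol = 1e-7)
    ft <- filter_trials(f, 0.01)
    drop_zero <- drop_zero + ("E03" %in% ft$dropped)
    drop_real <- drop_real + any(c("E01", "E02") %in% ft$dropped)
  }
  expect_gte(drop_zero / n_rep, 0.25)
  expect_equal(drop_real, 0L)
})

test_that("FA order selection stops by the explained-variance rule", {
  pop <- small_population(n_lines = 120, n_groups = 2, n_markers = 4,
                          seed = 81)
  cfg <- sim_config(n_envs = 4, Lambda = sqrt(c(1, 1.3, 0.9, 1.1)),
                    Psi = 0.1, n_reps = 2, rep_var = 0.05, resid_sigma2 = 1,
                    rho_row = 0, rho_col = 0, seed = 82)
  sim <- simulate_met_phenotypes(pop$gen, pop$map, cfg)
  d <- build_design(sim$phenotypes, "yld", rownames(pop$gen),
                    model_spec("fa", residual = "iid"))
  sel <- select_fa_order(d, fa_target = 80, pev = FALSE)
  expect_equal(sel$k, 1L) # FA(1) truth with small Psi exceeds 80% at once
  expect_gt(sel$trace[1], 80)
  # a vacuous threshold always stops at k = 1
  sel0 <- select_fa_order(d, fa_target = 1e-9, pev = FALSE)
  expect_equal(sel0$k, 1L)
  # 2 environments force k = 1
  cfg2 <- sim_config(n_envs = 2, Lambda = c(1, 1), Psi = 0.3, n_reps = 2,
                     rep_var = 0.05, rho_row = 0, rho_col = 0, seed = 83)
  sim2 <- simulate_met_phenotypes(pop$gen, pop$map, cfg2)
  d2 <- build_design(sim2$phenotypes, "yld", rownames(pop$gen),
                     model_spec("fa", residual = "iid"))
  sel2 <- select_fa_order(d2, fa_target = 99.99, pev = FALSE)
  expect_equal(sel2$k, 1L)
})

test_that("heritability follows the PEV arithmetic and the balanced closed form", {
  # direct arithmetic on a constructed fit
  m <- 4
  pevb <- diag(0.2, m) # PEV_ii = 0.2, PEV_ij = 0 -> mean pairwise = 0.4
  fit <- structure(list(
    Sigma = matrix(1), boundary = FALSE,
    pev = list(E1 = pevb),
    design = list(envs = "E1", n_lines = m)), class = "met_fit")
  h <- heritability(fit)
  expect_equal(h$mean_pair_pev, 0.4)
  expect_equal(h$h2, 1 - 0.4 / 2) # 0.8
  # PEV = 0 gives h2 = 1
  fit$pev <- list(E1 = matrix(0, m, m))
  expect_equal(heritability(fit)$h2, 1)
  # balanced toy equals classical line-mean heritability exactly
  f <- reml_fit(toy_design())
  expect_equal(heritability(f)$h2, 15 / (15 + 2 / 2), tolerance = 1e-6)
  expect_equal(heritability(f)$h2, 0.9375, tolerance = 1e-6)
})

test_that("contiguous significant intervals merge into QTL records", {
  cfgq <- scan_config()
  sc <- fake_scan(p_main = c(0.5, 0.001, 0.005, 0.5, 0.002),
                  p_qxe = rep(0.5, 5))
  q <- merge_to_qtl(sc, cfgq, trait = "yld")
  expect_equal(nrow(q), 2L) # [F,T,T,F,T] -> two QTL
  expect_equal(q$term, c("main", "main"))
  expect_equal(q$qtl, c("Qyld.mq-G1.1", "Qyld.mq-G1.2"))
  # all non-significant -> empty
  q0 <- merge_to_qtl(fake_scan(rep(0.5, 4), rep(0.9, 4)), cfgq)
  expect_equal(nrow(q0), 0L)
  # QxE labelling: interaction significant at the peak
  q2 <- merge_to_qtl(fake_scan(c(0.5, 0.5), c(0.002, 0.5)), cfgq)
  expect_equal(q2$term, "QxE")
  # per-env significance flag: |3| > 1.96 * 1
  pe <- attr(q2, "per_env")[[1]]
  expect_true(all(pe$significant))
  expect_equal(q2$effect_lo, 3)
  expect_equal(q2$effect_hi, 3)
})

test_that("scan recovers a planted QTL with the documented sign convention", {
  map <- simulate_map(map_spec(n_groups = 2, length_cM = 60, n_markers = 7),
                      seed = 91)
  gen <- simulate_dh_genotypes(map, 150, seed = 92)
  # parent-1 (Excalibur-role) allele increases the trait by 0.8
  qtl <- data.frame(group = "G1", pos_cM = 30, effect = 0.8)
  cfg <- sim_config(n_envs = 3, qtl = qtl, Lambda = matrix(0, 3, 1), Psi = 0.6,
                    n_reps = 2, rep_var = 0.05, resid_sigma2 = 1,
                    rho_row = 0, rho_col = 0, seed = 93)
  sim <- simulate_met_phenotypes(gen, map, cfg)
  d <- build_design(sim$phenotypes, "yld", rownames(gen),
                    model_spec("diag", residual = "iid"))
  f <- reml_fit(d, pev = FALSE, tol = 1e-7)
  pm <- predictor_matrix(gen, map)
  sc <- genome_scan(f, pm)
  pk <- sc[which.max(sc$W_main), ]
  expect_equal(pk$group, "G1")
  expect_lt(abs(pk$pos_cM - 30), 10)
  expect_gt(pk$main_est, 0) # positive estimate for the parent-1 allele
  expect_lt(pk$p_main, 0.01)
  qt <- merge_to_qtl(sc, scan_config(), map, trait = "yld")
  expect_gte(nrow(qt), 1L)
  expect_equal(qt$group[which.min(qt$p)], "G1")
})

test_that("scan with variance refit agrees with the fixed-theta scan", {
  pop <- small_population(n_lines = 60, n_groups = 1, n_markers = 4, seed = 95)
  cfg <- sim_config(n_envs = 2, Lambda = matrix(0, 2, 1), Psi = 0.8,
                    n_reps = 2, rep_var = 0.05, resid_sigma2 = 1,
                    rho_row = 0, rho_col = 0, seed = 96)
  sim <- simulate_met_phenotypes(pop$gen, pop$map, cfg)
  d <- build_design(sim$phenotypes, "yld", rownames(pop$gen),
                    model_spec("diag", residual = "iid"))
  f <- reml_fit(d, pev = FALSE)
  pm <- predictor_matrix(pop$gen, pop$map)
  s1 <- genome_scan(f, pm, scan_config())
  s2 <- genome_scan(f, pm, scan_config(refit_variance = TRUE))
  # no QTL present: refitting theta barely moves the statistics
  expect_equal(s1$main_est, s2$main_est, tolerance = 0.05)
  expect_equal(s1$W_main, s2$W_main, tolerance = 0.3)
})

test_that("pipeline is deterministic and flags phenology-linked QTL", {
  map <- simulate_map(map_spec(n_groups = 3, length_cM = 60, n_markers = 7),
                      seed = 101)
  gen <- simulate_dh_genotypes(map, 150, seed = 102)
  qtl <- data.frame(group = "G1", pos_cM = 30, effect = 0.7)
  cfg <- sim_config(
    n_envs = 3, qtl = qtl, Lambda = matrix(0, 3, 1), Psi = 0.6,
    n_reps = 2, rep_var = 0.05, resid_sigma2 = 1, rho_row = 0, rho_col = 0,
    phenology = list(group = "G3", pos_cM = 30, effect_cov = 2,
                     effect_target = 0.7, cov_trait = "dth",
                     cov_mean = 100, cov_sigma2 = 1),
    seed = 103)
  sim <- simulate_met_phenotypes(gen, map, cfg)
  res <- run_pipeline(sim$phenotypes, gen, map, traits = "yld",
                      config = scan_config(phenology_trait = "dth"),
                      spec = model_spec(residual = "iid"))
  q <- res$qtl$yld
  # the true yield QTL is recovered and not phenology-linked
  i1 <- which(q$group == "G1")
  expect_length(i1, 1L)
  expect_false(q$phenology_linked[i1])
  expect_lt(abs((q$peak_lo[i1] + q$peak_hi[i1]) / 2 - 30), 10)
  # the phenology locus shows for yield too, but carries the flag
  i3 <- which(q$group == "G3")
  expect_true(length(i3) >= 1 && any(q$phenology_linked[i3]))
  # the phenology QTL itself was found in the covariate scan
  expect_true(any(grepl("G3", res$log$phenology_qtl)))
  # rerun is byte-identical
  res2 <- run_pipeline(sim$phenotypes, gen, map, traits = "yld",
                       config = scan_config(phenology_trait = "dth"),
                       spec = model_spec(residual = "iid"))
  expect_identical(as.data.frame(res$qtl$yld), as.data.frame(res2$qtl$yld))
  expect_equal(res$herit$yld$h2, res2$herit$yld$h2)
})
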