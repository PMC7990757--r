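test_that("design assembly produces the expected dimensions and ordering", {
  pop <- small_population(n_lines = 10, n_groups = 1, n_markers = 3)
  cfg <- sim_config(n_envs = 2, Lambda = matrix(0, 2, 1), Psi = 1,
                    n_reps = 2, rho_row = 0, rho_col = 0, n_controls = 1,
                    seed = 4)
  sim <- simulate_met_phenotypes(pop$gen, pop$map, cfg)
  d <- build_design(sim$phenotypes, "yld", rownames(pop$gen),
                    model_spec("diag", residual = "iid"))
  expect_equal(length(d$y), 2 * (10 + 1) * 2)    # 2 envs x 11 entries x 2 reps
  expect_equal(sum(d$term_of == "control"), 1L)  # one control fixed column
  expect_equal(d$q_g, 2 * 10)
  # rows ordered (env, row, col) so residual blocks are separable
  expect_false(is.unsorted(d$plots$env))
  # duplicate plot coordinates rejected
  ph <- sim$phenotypes; ph$row <- 1; ph$col <- 1
  expect_error(build_design(ph, "yld", rownames(pop$gen),
                            model_spec()), "duplicate")
})

test_that("balanced single-trial REML equals ANOVA moments and lme4", {
  f <- reml_fit(toy_design())
  expect_equal(unname(diag(f$Sigma)), 15, tolerance = 1e-6)
  expect_equal(f$var_params$resid$sigma2, 2, tolerance = 1e-6)
  expect_true(f$converged)
  # independent cross-check against lme4 on the same data
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(yld ~ 1 + (1 | line), data = toy_phenotypes(), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(diag(f$Sigma)), vc$vcov[vc$grp == "line"],
               tolerance = 1e-5)
  expect_equal(f$var_params$resid$sigma2, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-5)
  expect_equal(f$reml_loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
})

test_that("zero genetic signal drives the genetic variance to the boundary", {
  ph <- toy_phenotypes()
  ph$yld <- rep(c(4, 6), 3) # identical line means
  f <- reml_fit(build_design(ph, "yld", c("L1", "L2", "L3"),
                             model_spec("diag", residual = "iid",
                                        rep_effect = FALSE)))
  expect_lt(unname(diag(f$Sigma)), 1e-4)
})

test_that("engine log-likelihood equals dense brute force on small instances", {
  pop <- small_population(n_lines = 8, n_groups = 1, n_markers = 3, seed = 21)
  for (resid in c("iid", "ar1")) {
    for (gtype in c("diag", "fa")) {
      cfg <- sim_config(n_envs = 2, Lambda = c(1, 0.7), Psi = c(0.3, 0.4),
                        n_reps = 2, rep_var = 0.15, resid_sigma2 = c(1, 1.4),
                        rho_row = 0.35, rho_col = 0.25, seed = 9)
      sim <- simulate_met_phenotypes(pop$gen, pop$map, cfg)
      d <- build_design(sim$phenotypes, "yld", rownames(pop$gen),
                        model_spec(gtype, fa_k = 1, residual = resid))
      vp <- var_params(
        genetic = if (gtype == "diag") list(type = "diag",
                                            sigma2_g = c(1.2, 0.9))
        else list(type = "fa", Lambda = matrix(c(0.9, 0.6), 2, 1),
                  Psi = c(0.25, 0.35)),
        rep_var = 0.15,
        resid = data.frame(env = d$envs, sigma2 = c(1, 1.4),
                           rho_row = if (resid == "ar1") c(0.35, 0.2)
                           else c(0, 0),
                           rho_col = if (resid == "ar1") c(0.25, 0.15)
                           else c(0, 0)))
      expect_equal(reml_loglik(d, vp), brute_loglik(d, vp),
                   tolerance = 1e-8, # absolute closeness on the log scale
                   info = paste(gtype, resid))
    }
  }
})

test_that("Wald test matches closed forms and is uniform under the null", {
  f <- reml_fit(toy_design())
  # single 1-df coefficient: W = (beta/se)^2 against chi-square(1)
  w <- wald_test(f, "env")
  b <- f$fixed$estimate[1]; se <- f$fixed$se[1]
  expect_equal(w$W, (b / se)^2, tolerance = 1e-8)
  expect_equal(w$df, 1L)
  expect_equal(w$p, pchisq((b / se)^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(pchisq(3.8416, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_error(wald_test(f, "nope"), "unknown")
})

test_that("FA percentage of variance follows the loadings arithmetic", {
  mk <- function(L, P) var_params(list(type = "fa", Lambda = L, Psi = P),
                                  resid = data.frame(env = c("a", "b"),
                                                     sigma2 = 1,
                                                     rho_row = 0, rho_col = 0))
  expect_equal(fa_percent_variance(mk(matrix(1, 2, 1), c(0.25, 0.25)))$overall,
               80)
  expect_equal(fa_percent_variance(mk(matrix(1, 2, 1), c(0, 0)))$overall, 100)
  expect_equal(fa_percent_variance(mk(matrix(0, 2, 1), c(1, 1)))$overall, 0)
  pe <- fa_percent_variance(mk(matrix(c(1, 2), 2, 1), c(1, 0)))$per_env
  expect_equal(unname(pe), c(50, 100))
})

test_that("FA(1) log-likelihood dominates the nested diagonal fit", {
  pop <- small_population(n_lines = 50, n_groups = 2, n_markers = 4, seed = 31)
  cfg <- sim_config(n_envs = 4, Lambda = sqrt(c(1, 0.8, 1.2, 1)), Psi = 0.2,
                    n_reps = 2, rho_row = 0, rho_col = 0, seed = 32)
  sim <- simulate_met_phenotypes(pop$gen, pop$map, cfg)
  dd <- build_design(sim$phenotypes, "yld", rownames(pop$gen),
                     model_spec("diag", residual = "iid"))
  df <- build_design(sim$phenotypes, "yld", rownames(pop$gen),
                     model_spec("fa", fa_k = 1, residual = "iid"))
  fd <- reml_fit(dd, pev = FALSE)
  s2g <- pmax(diag(fd$Sigma), 1e-6)
  ff <- reml_fit(df, init = var_params(
    list(type = "fa", Lambda = matrix(sqrt(0.7 * s2g), 4, 1),
         Psi = 0.3 * s2g),
    rep_var = fd$var_params$rep_var, resid = fd$var_params$resid),
    pev = FALSE)
  expect_gte(ff$reml_loglik, fd$reml_loglik - 1e-4)
})

test_that("BLUP prediction error shrinks with replication", {
  pop <- small_population(n_lines = 40, n_groups = 1, n_markers = 3, seed = 41)
  mean_pev <- function(n_reps, seed) {
    cfg <- sim_config(n_envs = 2, Lambda = matrix(0, 2, 1), Psi = 1,
                      n_reps = n_reps, rep_var = 0.05, resid_sigma2 = 1,
                      rho_row = 0, rho_col = 0, seed = seed)
    sim <- simulate_met_phenotypes(pop$gen, pop$map, cfg)
    d <- build_design(sim$phenotypes, "yld", rownames(pop$gen),
                      model_spec("diag", residual = "iid"))
    f <- reml_fit(d)
    mean(vapply(f$pev, function(b) mean(diag(b)), numeric(1)))
  }
  expect_lt(mean_pev(4, 51), mean_pev(2, 51))
})

test_that("AR1xAR1 spatial parameters are recovered on a 20x25 grid", {
  map <- simulate_map(map_spec(n_groups = 1, length_cM = 50, n_markers = 4),
                      seed = 61)
  gen <- simulate_dh_genotypes(map, 250, seed = 62)
  cfg <- sim_config(n_envs = 1, Lambda = matrix(1, 1, 1), Psi = 0.3,
                    n_reps = 2, rep_var = 0.05, resid_sigma2 = 1,
                    rho_row = 0.5, rho_col = 0.4, seed = 63)
  sim <- simulate_met_phenotypes(gen, map, cfg)
  expect_equal(max(sim$phenotypes$row), 20)
  expect_equal(max(sim$phenotypes$col), 25)
  d <- build_design(sim$phenotypes, "yld", rownames(gen),
                    model_spec("diag", residual = "ar1"))
  f <- reml_fit(d, pev = FALSE, tol = 1e-7)
  expect_lt(abs(f$var_params$resid$rho_row - 0.5), 0.15)
  expect_lt(abs(f$var_params$resid$rho_col - 0.4), 0.15)
})
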