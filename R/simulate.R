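# Synthetic doubled-haploid multi-environment data with recorded truth.
# The generator instantiates exactly the statistical structure the MET model
# assumes: DH genotypes from a marker-to-marker Markov recombination process
# (no interference, so the flanking-marker conditional probabilities used by
# the predictors are exact), genetic values from planted QTL plus a
# factor-analytic polygenic term, and plot values with environment means,
# replicate effects, an AR1xAR1 Gaussian field and optional iid noise.

#' Specification of a simulated linkage map
#'
#' @param n_groups number of linkage groups.
#' @param length_cM group length(s) in cM (recycled).
#' @param n_markers markers per group (recycled).
#' @param even place markers evenly (default) or uniformly at random.
#' @return data.frame with one row per group.
#' @export
map_spec <- function(n_groups = 21, length_cM = 130, n_markers = 41,
                     even = TRUE) {
  data.frame(group = paste0("G", seq_len(n_groups)),
             length_cM = rep_len(length_cM, n_groups),
             n_markers = rep_len(n_markers, n_groups),
             even = rep_len(even, n_groups), stringsAsFactors = FALSE)
}

#' Simulate a genetic map
#'
#' Emulates a wheat-scale biparental map (the default [map_spec()] gives 21
#' groups of 41 markers over 130 cM each, i.e. about 850 loci at ~3 cM mean
#' spacing).
#'
#' @param spec a [map_spec()] data.frame.
#' @param seed integer seed; the map is fully reproducible.
#' @return A [genetic_map()].
#' @export
simulate_map <- function(spec = map_spec(), seed = 1) {
  stopifnot(all(spec$length_cM > 0), all(spec$n_markers >= 1))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    g <- spec$group[i]; L <- spec$length_cM[i]; k <- spec$n_markers[i]
    pos <- if (isTRUE(spec$even[i])) seq(0, L, length.out = k)
    else sort(stats::runif(k, 0, L))
    data.frame(marker = sprintf("%s_m%02d", g, seq_len(k)), group = g,
               pos_cM = pos, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  genetic_map(df$marker, df$group, df$pos_cM)
}

# Markov DH gametes along one group: allele flips between adjacent markers
# with probability equal to the inverse-Kosambi recombination fraction.
.sim_group_calls <- function(pos, n_lines) {
  k <- length(pos)
  out <- matrix(0L, n_lines, k)
  out[, 1] <- stats::rbinom(n_lines, 1, 0.5)
  if (k > 1) {
    r <- r_from_kosambi_cm(diff(pos))
    for (j in 2:k) {
      flip <- stats::rbinom(n_lines, 1, r[j - 1])
      out[, j] <- ifelse(flip == 1L, 1L - out[, j - 1], out[, j - 1])
    }
  }
  out # 1 = A, 0 = B
}

#' Simulate doubled-haploid genotypes
#'
#' Each line and linkage group is an independent Markov chain: the first
#' marker is A or B with probability 1/2 and each subsequent marker recombines
#' with probability given by the inverse Kosambi function of the map gap.
#' There are no heterozygous calls.
#'
#' @param map a [genetic_map()].
#' @param n_lines number of DH lines.
#' @param seed integer seed.
#' @return A [genotype_matrix()] flagged as DH.
#' @export
simulate_dh_genotypes <- function(map, n_lines, seed = 1) {
  set.seed(seed)
  groups <- unique(map$group)
  cols <- lapply(groups, function(g) {
    gmap <- map[map$group == g, , drop = FALSE]
    num <- .sim_group_calls(gmap$pos_cM, n_lines)
    m <- matrix(ifelse(num == 1L, "A", "B"), n_lines, nrow(gmap),
                dimnames = list(NULL, gmap$marker))
    m
  })
  calls <- do.call(cbind, cols)
  rownames(calls) <- sprintf("DH%03d", seq_len(n_lines))
  genotype_matrix(calls[, map$marker, drop = FALSE], dh = TRUE)
}

#' Remove genotype calls at random
#'
#' @param genotypes a [genotype_matrix()].
#' @param rate per-call missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The genotype matrix with calls set to `NA`.
#' @export
inject_missing <- function(genotypes, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(genotypes)
  set.seed(seed)
  drop <- matrix(stats::runif(length(genotypes)) < rate, nrow(genotypes))
  out <- unclass(genotypes)
  out[drop] <- NA
  genotype_matrix(out, dh = attr(genotypes, "dh"))
}

#' Configuration for the multi-environment phenotype simulator
#'
#' Defaults mirror the scale of a drought/heat wheat MET study: ~200 DH
#' lines, 2 replicates, 8 environments with heterogeneous genetic variance
#' under a factor-analytic G x E structure, and AR1xAR1 plot noise.
#'
#' @param trait name of the simulated target trait.
#' @param qtl data.frame with columns `group`, `pos_cM`, `effect` (half the
#'   homozygote contrast, in trait units) and optionally `env_dev`, a list
#'   column of per-environment effect deviations (length `n_envs` each).
#' @param n_envs number of environments.
#' @param Lambda J x k factor loadings of the polygenic G x E covariance
#'   Sigma = Lambda Lambda' + diag(Psi); a vector is taken as a single factor.
#' @param Psi specific polygenic variances (length J, recycled).
#' @param env_means environment mean trait values (recycled to J).
#' @param n_reps replicates per environment.
#' @param rep_var variance of replicate-within-environment effects.
#' @param resid_sigma2 residual (plot) variance per environment (recycled).
#' @param rho_row,rho_col AR1 autocorrelations of the spatial field (recycled).
#' @param n_controls number of (non-genotyped) control entries per replicate.
#' @param phenology optional list(group, pos_cM, effect_cov, effect_target,
#'   cov_trait, cov_mean, cov_sigma2): a locus affecting both a phenology
#'   covariate trait and the target trait.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(trait = "yld", qtl = NULL, n_envs = 8,
                       Lambda = NULL, Psi = NULL, env_means = 0,
                       n_reps = 2, rep_var = 0.1, resid_sigma2 = 1,
                       rho_row = 0.4, rho_col = 0.3, n_controls = 0,
                       phenology = NULL, seed = 1) {
  J <- n_envs
  if (is.null(Lambda)) Lambda <- rep(1, J)
  Lambda <- as.matrix(Lambda)
  if (nrow(Lambda) != J) stop("Lambda must have n_envs rows")
  if (is.null(Psi)) Psi <- rep(0.25, J)
  structure(list(trait = trait, qtl = qtl, n_envs = J, Lambda = Lambda,
                 Psi = rep_len(Psi, J), env_means = rep_len(env_means, J),
                 n_reps = n_reps, rep_var = rep_var,
                 resid_sigma2 = rep_len(resid_sigma2, J),
                 rho_row = rep_len(rho_row, J),
                 rho_col = rep_len(rho_col, J),
                 n_controls = n_controls, phenology = phenology,
                 seed = seed), class = "sim_config")
}

# draw the +/-1 genotype at an arbitrary map position for every line,
# conditional on the flanking markers (exact under the Markov model)
.draw_locus <- function(genotypes, map, group, pos) {
  gmap <- map[map$group == group, , drop = FALSE]
  if (nrow(gmap) == 0L) stop("unknown group in QTL spec: ", group)
  calls <- unclass(genotypes)[, gmap$marker, drop = FALSE]
  mpos <- gmap$pos_cM
  n <- nrow(calls)
  x <- integer(n)
  at <- which(abs(mpos - pos) < 1e-9)
  for (i in seq_len(n)) {
    if (length(at) && !is.na(calls[i, at[1]])) {
      x[i] <- if (calls[i, at[1]] == "A") 1L else -1L
      next
    }
    obs <- which(!is.na(calls[i, ]))
    li <- obs[mpos[obs] < pos]; ri <- obs[mpos[obs] > pos]
    ls <- if (length(li)) calls[i, li[length(li)]] else "none"
    rs <- if (length(ri)) calls[i, ri[1]] else "none"
    rl <- if (length(li)) r_from_kosambi_cm(pos - mpos[li[length(li)]]) else NA
    rr <- if (length(ri)) r_from_kosambi_cm(mpos[ri[1]] - pos) else NA
    pA <- interval_probability(ls, rs, rl, rr)
    x[i] <- if (stats::runif(1) < pA) 1L else -1L
  }
  x
}

# full-grid dimensions for `total` plots: smallest column count >= sqrt(total)
# that divides total
.grid_dims <- function(total) {
  nc <- ceiling(sqrt(total))
  while (total %% nc != 0) nc <- nc + 1
  c(nrow = total %/% nc, ncol = nc)
}

# one AR1xAR1 unit-variance field on an nr x nc grid, row-major vector
.sim_ar1_field <- function(nr, nc, rho_r, rho_c) {
  cr <- chol(rho_r^abs(outer(seq_len(nr), seq_len(nr), "-")))
  cc <- chol(rho_c^abs(outer(seq_len(nc), seq_len(nc), "-")))
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  as.vector(t(t(cr) %*% z %*% cc)) # row-major: row varies slowest
}

#' Simulate plot-level multi-environment phenotypes with known truth
#'
#' Genetic value of line i in environment j:
#' sum_q x_iq (beta_q + beta_qj) + (Lambda f_i)_j + delta_ij, with x the +/-1
#' genotype at each planted QTL, f_i ~ N(0, I_k) and delta_ij ~ N(0, Psi_j).
#' Plot values add the environment mean, a replicate effect, an AR1xAR1
#' Gaussian field and the +/-1-coded phenology-locus effect when configured.
#' Lines (plus controls) are assigned to a full row x column grid by a seeded
#' random permutation.
#'
#' @param genotypes a DH [genotype_matrix()].
#' @param map the matching [genetic_map()].
#' @param config a [sim_config()].
#' @return list with `phenotypes` (plot-level data.frame) and `truth`
#'   (planted QTL with per-environment effects, Sigma, spatial parameters and
#'   per-line genetic values).
#' @export
simulate_met_phenotypes <- function(genotypes, map, config) {
  set.seed(config$seed)
  J <- config$n_envs
  m <- nrow(genotypes)
  lines <- rownames(genotypes)
  Sigma <- tcrossprod(config$Lambda) + diag(config$Psi, J)
  envs <- sprintf("E%02d", seq_len(J))

  # planted QTL effects per environment
  qtl <- config$qtl
  n_q <- if (is.null(qtl)) 0L else nrow(qtl)
  xq <- matrix(0L, m, max(n_q, 1L))
  eff <- matrix(0, max(n_q, 1L), J)
  if (n_q > 0) {
    for (q in seq_len(n_q)) {
      xq[, q] <- .draw_locus(genotypes, map, qtl$group[q], qtl$pos_cM[q])
      dev <- if (!is.null(qtl$env_dev)) qtl$env_dev[[q]] else rep(0, J)
      eff[q, ] <- qtl$effect[q] + dev
    }
  }

  # polygenic FA term
  f <- matrix(stats::rnorm(m * ncol(config$Lambda)), m)
  delta <- matrix(stats::rnorm(m * J), m, J) %*% diag(sqrt(config$Psi), J)
  gv <- xq[, seq_len(max(n_q, 1L)), drop = FALSE] %*% eff +
    f %*% t(config$Lambda) + delta
  dimnames(gv) <- list(lines, envs)

  # phenology locus
  phe <- config$phenology
  x_phe <- NULL
  if (!is.null(phe)) {
    x_phe <- .draw_locus(genotypes, map, phe$group, phe$pos_cM)
    if (is.null(phe$cov_trait)) phe$cov_trait <- "dth"
    if (is.null(phe$cov_mean)) phe$cov_mean <- 0
    if (is.null(phe$cov_sigma2)) phe$cov_sigma2 <- 1
  }

  ctrl <- if (config$n_controls > 0) sprintf("CTRL%d", seq_len(config$n_controls))
  else character(0)
  ctrl_val <- stats::rnorm(length(ctrl), 0, sqrt(mean(diag(Sigma))))
  entries <- c(lines, ctrl)
  total <- length(entries) * config$n_reps
  dims <- .grid_dims(total)

  out <- vector("list", J)
  for (j in seq_len(J)) {
    plot_entries <- rep(entries, config$n_reps)
    plot_rep <- rep(seq_len(config$n_reps), each = length(entries))
    ord <- sample.int(total)
    plot_entries <- plot_entries[ord]; plot_rep <- plot_rep[ord]
    rows <- rep(seq_len(dims["nrow"]), each = dims["ncol"])
    cols <- rep(seq_len(dims["ncol"]), times = dims["nrow"])
    rep_eff <- stats::rnorm(config$n_reps, 0, sqrt(config$rep_var))
    field <- sqrt(config$resid_sigma2[j]) *
      .sim_ar1_field(dims["nrow"], dims["ncol"],
                     config$rho_row[j], config$rho_col[j])
    gval <- ifelse(plot_entries %in% lines,
                   gv[match(plot_entries, lines), j],
                   ctrl_val[match(plot_entries, ctrl)])
    y <- config$env_means[j] + gval + rep_eff[plot_rep] + field
    df <- data.frame(env = envs[j], line = plot_entries, rep = plot_rep,
                     row = rows, col = cols, stringsAsFactors = FALSE)
    df[[config$trait]] <- y
    if (!is.null(phe)) {
      xv <- ifelse(plot_entries %in% lines, x_phe[match(plot_entries, lines)], 0)
      df[[config$trait]] <- df[[config$trait]] + xv * phe$effect_target
      df[[phe$cov_trait]] <- phe$cov_mean + xv * phe$effect_cov +
        stats::rnorm(total, 0, sqrt(phe$cov_sigma2))
    }
    out[[j]] <- df
  }
  phen <- do.call(rbind, out)
  truth <- list(
    envs = envs,
    qtl = if (n_q > 0) data.frame(qtl[c("group", "pos_cM", "effect")],
                                  stringsAsFactors = FALSE) else NULL,
    qtl_env_effects = if (n_q > 0) eff else NULL,
    qtl_genotypes = if (n_q > 0) {
      dimnames(xq) <- list(lines, paste0("qtl", seq_len(n_q))); xq
    } else NULL,
    Sigma = Sigma,
    spatial = data.frame(env = envs, sigma2 = config$resid_sigma2,
                         rho_row = config$rho_row, rho_col = config$rho_col),
    rep_var = config$rep_var,
    genetic_values = gv,
    phenology = if (!is.null(phe)) c(phe, list(x = x_phe)) else NULL,
    seed = config$seed)
  list(phenotypes = phen, truth = truth)
}

#' Write a simulation truth record as JSON
#'
#' @param truth the `truth` element of [simulate_met_phenotypes()] output.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  truth$genetic_values <- as.data.frame(truth$genetic_values)
  truth$Sigma <- as.data.frame(truth$Sigma)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Simulate a NIL polytunnel trial
#'
#' A randomized complete block experiment with two (or more) replicates:
#' every NIL pair contributes one AA (parent-1 segment) and one BB member,
#' each grown as `n_plants` plants per block. Plant values are
#' baseline + allele effect (added to the AA member) + block effect + noise.
#'
#' @param pair_effects data.frame with columns `pair_id` and `effect`
#'   (AA-minus-BB shift in trait units).
#' @param n_plants plants per plot (>= 2).
#' @param n_blocks replicate blocks.
#' @param baseline trait baseline.
#' @param block_sd,noise_sd standard deviations of block effects and plant
#'   noise.
#' @param seed integer seed.
#' @return data.frame: `pair_id`, `member` (AA/BB), `block`, `plant`, `value`.
#' @export
simulate_nil_experiment <- function(pair_effects, n_plants = 24, n_blocks = 2,
                                    baseline = 100, block_sd = 1,
                                    noise_sd = 5, seed = 1) {
  stopifnot(n_plants >= 2)
  set.seed(seed)
  blocks <- stats::rnorm(n_blocks, 0, block_sd)
  rows <- list()
  for (i in seq_len(nrow(pair_effects))) {
    for (mem in c("AA", "BB")) {
      shift <- if (mem == "AA") pair_effects$effect[i] else 0
      for (b in seq_len(n_blocks)) {
        v <- baseline + shift + blocks[b] + stats::rnorm(n_plants, 0, noise_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(pair_id = pair_effects$pair_id[i], member = mem,
                     block = b, plant = seq_len(n_plants), value = v,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
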