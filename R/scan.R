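#' Configuration of the QTL scan pipeline
#'
#' @param p_threshold Wald-test p-value threshold for declaring a QTL
#'   (applied to the main effect and/or the Q x E interaction).
#' @param fa_target percentage of between-environment genetic variance the
#'   factor-analytic structure must explain before the order search stops.
#' @param trial_filter_ratio trials whose genetic variance falls below this
#'   fraction of their residual variance are removed.
#' @param covariate_markers marker names whose genetic predictors are fitted
#'   as additional fixed covariates (excluded on their own linkage group).
#' @param ci_multiplier multiplier for effect confidence intervals
#'   (estimate +/- multiplier * SE).
#' @param refit_variance re-estimate variance parameters for every scanned
#'   interval instead of holding them at the null-model fit.
#' @param phenology_trait optional trait scanned first; its QTL peaks become
#'   covariates for the remaining traits.
#' @param name_prefix infix used in generated QTL names
#'   (`Q<trait>.<prefix>-<group>`).
#' @return A `scan_config` list.
#' @export
scan_config <- function(p_threshold = 0.01, fa_target = 80,
                        trial_filter_ratio = 0.01,
                        covariate_markers = character(),
                        ci_multiplier = 1.96, refit_variance = FALSE,
                        phenology_trait = NULL, name_prefix = "mq") {
  stopifnot(p_threshold > 0, p_threshold < 1,
            fa_target > 0, fa_target <= 100,
            trial_filter_ratio > 0, trial_filter_ratio < 1)
  structure(list(p_threshold = p_threshold, fa_target = fa_target,
                 trial_filter_ratio = trial_filter_ratio,
                 covariate_markers = covariate_markers,
                 ci_multiplier = ci_multiplier,
                 refit_variance = isTRUE(refit_variance),
                 phenology_trait = phenology_trait,
                 name_prefix = name_prefix), class = "scan_config")
}

#' Drop trials with negligible genetic variance
#'
#' Environment j is removed when its genetic variance is below
#' `ratio` times its residual variance (default < 1%), judged from a
#' per-environment (diagonal) fit.
#'
#' @param fit a `met_fit` with diagonal (or any) genetic structure.
#' @param ratio the genetic/residual variance threshold.
#' @return list with `kept` (environment labels), `dropped`, and a `table` of
#'   per-environment variances and ratios.
#' @export
filter_trials <- function(fit, ratio = 0.01) {
  s2g <- diag(fit$Sigma)
  s2e <- fit$var_params$resid$sigma2
  envs <- fit$design$envs
  tab <- data.frame(env = envs, sigma2_g = s2g, sigma2_e = s2e,
                    ratio = s2g / s2e, stringsAsFactors = FALSE)
  keep <- tab$ratio >= ratio
  if (!any(keep))
    stop("all trials dropped by the genetic-variance filter (ratio ", ratio, ")")
  list(kept = envs[keep], dropped = envs[!keep], table = tab)
}

#' Select the factor-analytic order by the explained-variance rule
#'
#' Fits FA(1), FA(2), ... with each fit initialized from the previous one
#' (FA(1) from the diagonal fit), stopping at the first order whose common
#' factors explain more than `fa_target` percent of the total
#' between-environment genetic variance, or at order J - 1.
#'
#' @param design a [build_design()] bundle (any genetic structure; rebuilt
#'   per order internally).
#' @param diag_fit optional diagonal `met_fit` used for initialization.
#' @param fa_target stopping percentage.
#' @param k_max maximum order (default J - 1).
#' @param pev compute PEV on the selected fit.
#' @return list with `k`, `fit` (the selected FA fit) and `trace`
#'   (per-order percentages).
#' @export
select_fa_order <- function(design, diag_fit = NULL, fa_target = 80,
                            k_max = NULL, pev = TRUE) {
  J <- design$n_env
  if (J < 2L) stop("factor-analytic selection needs at least 2 environments")
  if (is.null(k_max)) k_max <- J - 1L
  k_max <- max(1L, min(k_max, J - 1L))
  spec0 <- design$spec
  if (is.null(diag_fit)) {
    dspec <- spec0; dspec$genetic <- "diag"
    ddes <- build_design(design$plots, design$trait, design$lines, dspec)
    diag_fit <- reml_fit(ddes, pev = FALSE)
  }
  s2g <- pmax(diag(diag_fit$Sigma), 1e-8)
  prev <- NULL; trace <- numeric(0); last_ok <- NULL; k_sel <- NA_integer_
  for (k in seq_len(k_max)) {
    spec_k <- spec0; spec_k$genetic <- "fa"; spec_k$fa_k <- k
    des_k <- build_design(design$plots, design$trait, design$lines, spec_k)
    init <- if (is.null(prev)) {
      var_params(list(type = "fa", Lambda = matrix(sqrt(0.7 * s2g), J, 1),
                      Psi = 0.3 * s2g),
                 rep_var = diag_fit$var_params$rep_var,
                 resid = diag_fit$var_params$resid)
    } else {
      L <- cbind(prev$var_params$genetic$Lambda, 0)
      L[k:J, k] <- 0.1 * sqrt(mean(s2g))
      var_params(list(type = "fa", Lambda = L,
                      Psi = prev$var_params$genetic$Psi),
                 rep_var = prev$var_params$rep_var,
                 resid = prev$var_params$resid)
    }
    fit_k <- reml_fit(des_k, init = init, pev = FALSE)
    if (!fit_k$converged && !is.null(last_ok)) {
      warning("FA(", k, ") did not converge; keeping FA(", k - 1L, ")")
      break
    }
    pct <- fa_percent_variance(fit_k$var_params)$overall
    trace <- c(trace, pct)
    last_ok <- fit_k; prev <- fit_k; k_sel <- k
    if (pct > fa_target) break
  }
  fit <- last_ok
  if (pev)
    fit <- reml_fit(fit$design, init = fit$var_params, max_iter = 0, pev = TRUE)
  list(k = k_sel, fit = fit, trace = trace)
}

#' Cullis generalized heritability per environment
#'
#' h2_j = 1 - mean pairwise PEV / (2 sigma2_g,j), where the mean pairwise
#' prediction error variance averages PEV_ii + PEV_i'i' - 2 PEV_ii' over all
#' line pairs within environment j, and sigma2_g,j is that environment's
#' genetic variance. Values are clamped to [0, 1]; environments whose genetic
#' variance sits at the boundary floor report h2 = 0 with a flag.
#'
#' @param fit a `met_fit` computed with `pev = TRUE`.
#' @return data.frame: `env`, `h2`, `sigma2_g`, `mean_pair_pev`, `boundary`.
#' @export
heritability <- function(fit) {
  if (is.null(fit$pev)) stop("fit has no PEV blocks; rerun reml_fit(pev = TRUE)")
  envs <- fit$design$envs
  m <- fit$design$n_lines
  out <- lapply(seq_along(envs), function(j) {
    A <- fit$pev[[j]]
    s1 <- sum(diag(A)); s2 <- sum(A)
    pevbar <- 2 * (m * s1 - s2) / (m * (m - 1))
    s2g <- diag(fit$Sigma)[j]
    bd <- isTRUE(fit$boundary[j])
    h2 <- if (bd) 0 else min(max(1 - pevbar / (2 * s2g), 0), 1)
    data.frame(env = envs[j], h2 = h2, sigma2_g = s2g,
               mean_pair_pev = pevbar, boundary = bd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# map per-line values onto observations (controls get 0)
.line_to_obs <- function(design, v) {
  out <- numeric(length(design$y))
  out[design$is_test] <- v[design$line_idx[design$is_test]]
  out
}

#' Genome-wide one-at-a-time QTL scan
#'
#' For each marker-interval predictor, the fixed part of the fitted MET model
#' is extended with the predictor main effect and its interaction with
#' environment (sum-to-zero coding, so the main effect is the
#' across-environment mean effect), plus any covariate predictors not on the
#' scanned linkage group. Wald tests are reported for the main effect (1 df)
#' and the Q x E interaction (J - 1 df). Variance parameters are held at the
#' base-model estimates unless `config$refit_variance`.
#'
#' @param fit the base `met_fit` (no predictor).
#' @param pm a [predictor_matrix()] over the fitted lines.
#' @param config a [scan_config()].
#' @param covariates optional lines x n_cov matrix of covariate predictor
#'   values (one column per covariate marker).
#' @param covariate_groups linkage group of each covariate column (used for
#'   the same-chromosome exclusion).
#' @return A `qtl_scan` data.frame: one row per interval with Wald statistics,
#'   p-values, the main-effect estimate and SE, and per-environment effect
#'   estimates/SEs in attributes `eff_env` and `se_env`.
#' @export
genome_scan <- function(fit, pm, config = scan_config(), covariates = NULL,
                        covariate_groups = NULL) {
  design <- fit$design
  J <- design$n_env
  n <- length(design$y)
  vp <- fit$var_params
  ev <- .reml_eval(design, vp, full = TRUE)
  Rinv <- ev$Rinv; ZtRi <- ev$ZtRi; fac <- ev$fac
  H <- stats::contr.sum(J) # J x (J-1)

  pos <- pm$positions
  keep_lines <- match(design$lines, rownames(pm$values))
  if (anyNA(keep_lines)) stop("predictor matrix lacks fitted lines")
  V <- pm$values[keep_lines, , drop = FALSE]

  # V^-1 products via the absorbed representation
  vpieces <- function(U) {
    RiU <- as.matrix(Rinv %*% U)
    AU <- as.matrix(ZtRi %*% U)
    WU <- as.matrix(Matrix::solve(fac, AU))
    list(U = U, RiU = RiU, AU = AU, WU = WU)
  }
  vcross <- function(a, b) crossprod(a$U, b$RiU) - crossprod(a$AU, b$WU)

  yp <- vpieces(matrix(design$y, ncol = 1))
  groups <- unique(pos$group)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n_cov > 0 && is.null(covariate_groups))
    covariate_groups <- rep("", n_cov)

  # per-group base fixed matrix: design X plus off-group covariates
  base_for_group <- function(g) {
    Xb <- design$X
    if (n_cov > 0) {
      use <- covariate_groups != g
      if (any(use)) {
        cv <- covariates[keep_lines, use, drop = FALSE]
        Xc <- vapply(seq_len(ncol(cv)), function(i)
          .line_to_obs(design, cv[, i]), numeric(n))
        colnames(Xc) <- paste0("cov:", colnames(covariates)[use])
        Xb <- cbind(Xb, Xc)
      }
    }
    bp <- vpieces(Xb)
    list(X = Xb, p = ncol(Xb), bp = bp, Sbb = vcross(bp, bp),
         Sby = vcross(bp, yp))
  }
  bases <- lapply(groups, base_for_group)
  names(bases) <- groups

  nq <- nrow(pos)
  res <- data.frame(pos[, c("group", "pos_cM", "label", "left_marker",
                            "right_marker")],
                    W_main = NA_real_, p_main = NA_real_,
                    W_qxe = NA_real_, p_qxe = NA_real_,
                    main_est = NA_real_, main_se = NA_real_,
                    skipped = FALSE, stringsAsFactors = FALSE)
  eff_env <- se_env <- matrix(NA_real_, nq, J,
                              dimnames = list(pos$label, design$envs))
  Lmat <- cbind(1, H) # J x J: per-env effect = main + interaction

  for (i in seq_len(nq)) {
    x <- V[, pos$label[i]]
    if (stats::sd(x) < 1e-10) {
      res$skipped[i] <- TRUE
      warning("monomorphic predictor skipped: ", pos$label[i])
      next
    }
    if (config$refit_variance) {
      co <- .scan_refit(fit, design, x, H)
      beta <- co$beta; covm <- co$cov; pb <- co$pb
    } else {
      b <- bases[[pos$group[i]]]
      x_obs <- .line_to_obs(design, x)
      U <- cbind(main = x_obs, x_obs * H[design$env_idx, , drop = FALSE])
      up <- vpieces(U)
      Sub <- vcross(up, b$bp)
      XtViX <- rbind(cbind(b$Sbb, t(Sub)), cbind(Sub, vcross(up, up)))
      XtViy <- c(b$Sby, vcross(up, yp))
      ch <- tryCatch(chol(XtViX), error = function(e) NULL)
      if (is.null(ch)) { res$skipped[i] <- TRUE; next }
      beta <- backsolve(ch, backsolve(ch, XtViy, transpose = TRUE))
      covm <- chol2inv(ch)
      pb <- b$p
    }
    im <- pb + 1L
    iq <- pb + 1L + seq_len(J - 1L)
    res$main_est[i] <- beta[im]
    res$main_se[i] <- sqrt(covm[im, im])
    res$W_main[i] <- beta[im]^2 / covm[im, im]
    res$p_main[i] <- stats::pchisq(res$W_main[i], 1, lower.tail = FALSE)
    Cq <- covm[iq, iq, drop = FALSE]
    wq <- tryCatch(sum(backsolve(chol(Cq), beta[iq], transpose = TRUE)^2),
                   error = function(e) NA_real_)
    res$W_qxe[i] <- wq
    res$p_qxe[i] <- stats::pchisq(wq, J - 1L, lower.tail = FALSE)
    bblk <- beta[c(im, iq)]
    Cblk <- covm[c(im, iq), c(im, iq), drop = FALSE]
    eff_env[i, ] <- as.numeric(Lmat %*% bblk)
    se_env[i, ] <- sqrt(pmax(diag(Lmat %*% Cblk %*% t(Lmat)), 0))
  }
  attr(res, "eff_env") <- eff_env
  attr(res, "se_env") <- se_env
  attr(res, "envs") <- design$envs
  class(res) <- c("qtl_scan", "data.frame")
  res
}

# full REML refit with the interval in the fixed part (refit_variance = TRUE)
.scan_refit <- function(fit, design, x, H) {
  x_obs <- .line_to_obs(design, x)
  U <- cbind(main = x_obs, x_obs * H[design$env_idx, , drop = FALSE])
  d2 <- design
  d2$X <- cbind(design$X, U)
  d2$term_of <- c(design$term_of, "qtl_main", rep("qtl_qxe", ncol(U) - 1L))
  d2$cache <- new.env(parent = emptyenv())
  f2 <- reml_fit(d2, init = fit$var_params, pev = FALSE)
  pb <- ncol(design$X)
  list(beta = f2$fixed$estimate, cov = f2$beta_cov, pb = pb)
}

#' Merge significant scan intervals into QTL records
#'
#' Intervals significant for the main and/or Q x E term at the configured
#' threshold are grouped: contiguous significant intervals on a linkage group
#' form one QTL. The peak is the interval with the largest Wald statistic;
#' its own flanking markers and cM span are reported. The term is `main`
#' when only the main effect is significant at the peak, otherwise `QxE`.
#' Per-environment effects (main + interaction) carry a significance flag
#' |estimate| > ci_multiplier * SE, and Q x E records report the range of the
#' significant per-environment estimates.
#'
#' @param scan a `qtl_scan` from [genome_scan()].
#' @param config a [scan_config()].
#' @param map the [genetic_map()] (for flanking-marker positions).
#' @param trait trait name used in generated QTL names.
#' @return A `qtl_table` data.frame, one row per QTL, with a `per_env`
#'   attribute listing per-environment effect tables.
#' @export
merge_to_qtl <- function(scan, config = scan_config(), map = NULL,
                         trait = "trait") {
  thr <- config$p_threshold
  sig <- (!is.na(scan$p_main) & scan$p_main < thr) |
    (!is.na(scan$p_qxe) & scan$p_qxe < thr)
  if (!any(sig)) {
    out <- data.frame(qtl = character(), group = character(),
                      peak_lo = numeric(), peak_hi = numeric(),
                      left_marker = character(), right_marker = character(),
                      term = character(), p = numeric(), effect = numeric(),
                      effect_lo = numeric(), effect_hi = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "per_env") <- list()
    class(out) <- c("qtl_table", "data.frame")
    return(out)
  }
  eff_env <- attr(scan, "eff_env"); se_env <- attr(scan, "se_env")
  envs <- attr(scan, "envs")
  recs <- list(); per_env <- list()
  for (g in unique(scan$group[sig])) {
    gi <- which(scan$group == g)
    s <- sig[gi]
    runs <- rle(s)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    hit <- which(runs$values)
    for (h in seq_along(hit)) {
      idx <- gi[starts[hit[h]]:ends[hit[h]]]
      wmax <- pmax(scan$W_main[idx], scan$W_qxe[idx], na.rm = TRUE)
      peak <- idx[which.max(wmax)]
      main_sig <- !is.na(scan$p_main[peak]) && scan$p_main[peak] < thr
      qxe_sig <- !is.na(scan$p_qxe[peak]) && scan$p_qxe[peak] < thr
      term <- if (main_sig && !qxe_sig) "main" else "QxE"
      p <- if (term == "main") scan$p_main[peak] else scan$p_qxe[peak]
      lo <- hi <- scan$pos_cM[peak]
      if (!is.null(map)) {
        lo <- map$pos_cM[match(scan$left_marker[peak], map$marker)]
        hi <- map$pos_cM[match(scan$right_marker[peak], map$marker)]
      }
      pe <- data.frame(env = envs, estimate = eff_env[peak, ],
                       se = se_env[peak, ],
                       significant = abs(eff_env[peak, ]) >
                         config$ci_multiplier * se_env[peak, ],
                       stringsAsFactors = FALSE)
      if (term == "main") {
        effect <- scan$main_est[peak]
        e_lo <- effect - config$ci_multiplier * scan$main_se[peak]
        e_hi <- effect + config$ci_multiplier * scan$main_se[peak]
      } else {
        se_est <- pe$estimate[pe$significant]
        effect <- if (length(se_est)) se_est[which.max(abs(se_est))]
        else NA_real_
        e_lo <- if (length(se_est)) min(se_est) else NA_real_
        e_hi <- if (length(se_est)) max(se_est) else NA_real_
      }
      recs[[length(recs) + 1L]] <- data.frame(
        qtl = "", group = g, peak_lo = lo, peak_hi = hi,
        left_marker = scan$left_marker[peak],
        right_marker = scan$right_marker[peak],
        term = term, p = p, effect = effect,
        effect_lo = e_lo, effect_hi = e_hi, stringsAsFactors = FALSE)
      per_env[[length(per_env) + 1L]] <- pe
    }
  }
  out <- do.call(rbind, recs)
  # Q<trait>.<prefix>-<group>[.n] naming
  nm <- paste0("Q", trait, ".", config$name_prefix, "-", out$group)
  dup <- ave(seq_along(nm), nm, FUN = seq_along)
  many <- ave(seq_along(nm), nm, FUN = length) > 1
  out$qtl <- ifelse(many, paste0(nm, ".", dup), nm)
  names(per_env) <- out$qtl
  attr(out, "per_env") <- per_env
  class(out) <- c("qtl_table", "data.frame")
  out
}

#' Run the full multi-environment QTL pipeline
#'
#' Stages, in order: marker-interval predictors; per-environment diagonal fit;
#' trial filter (< `trial_filter_ratio` genetic/residual variance); FA-order
#' selection under the explained-variance rule; Cullis heritability; optional
#' unadjusted scan of a phenology trait whose QTL peaks become fixed
#' covariates; covariate-adjusted genome scan of each target trait (covariates
#' on the scanned group excluded); merging of significant intervals into QTL
#' records. Deterministic given the inputs.
#'
#' @param phenotypes plot-level phenotype data.frame.
#' @param genotypes a DH [genotype_matrix()].
#' @param map the [genetic_map()].
#' @param traits trait column name(s) to scan.
#' @param config a [scan_config()].
#' @param spec a [model_spec()] for the MET model (genetic structure is
#'   managed by the pipeline).
#' @return list with `qtl` (per trait), `herit` (per trait), `scans`, `fits`,
#'   and a provenance `log` (dropped trials, selected FA order, covariates
#'   used).
#' @export
run_pipeline <- function(phenotypes, genotypes, map, traits,
                         config = scan_config(), spec = model_spec()) {
  lines <- rownames(genotypes)
  pm <- predictor_matrix(genotypes, map)
  log <- list()
  covariates <- NULL; covariate_groups <- NULL; covariate_pos <- NULL

  # explicit covariate markers -> predictor values at the marker positions
  if (length(config$covariate_markers)) {
    mi <- match(config$covariate_markers, map$marker)
    if (anyNA(mi)) stop("covariate markers absent from map: ",
                        paste(config$covariate_markers[is.na(mi)],
                              collapse = ", "))
    covariates <- vapply(mi, function(k) {
      gmap <- map[map$group == map$group[k], , drop = FALSE]
      .predict_at_position(unclass(genotypes)[, gmap$marker, drop = FALSE],
                           gmap$pos_cM, map$pos_cM[k])
    }, numeric(nrow(genotypes)))
    rownames(covariates) <- lines
    colnames(covariates) <- config$covariate_markers
    covariate_groups <- map$group[mi]
    covariate_pos <- map$pos_cM[mi]
    log$covariates <- config$covariate_markers
  }

  fit_one <- function(trait) {
    dspec <- spec; dspec$genetic <- "diag"
    d0 <- build_design(phenotypes, trait, lines, dspec)
    f0 <- reml_fit(d0, pev = FALSE)
    ft <- filter_trials(f0, config$trial_filter_ratio)
    log[[paste0(trait, "_dropped_trials")]] <<- ft$dropped
    d1 <- if (length(ft$dropped))
      build_design(phenotypes, trait, lines, dspec, keep_envs = ft$kept)
    else d0
    f1 <- if (length(ft$dropped)) reml_fit(d1, pev = FALSE) else f0
    if (d1$n_env >= 2L) {
      sel <- select_fa_order(d1, diag_fit = f1, fa_target = config$fa_target)
      log[[paste0(trait, "_fa_order")]] <<- sel$k
      sel$fit
    } else {
      reml_fit(d1, init = f1$var_params, max_iter = 0, pev = TRUE)
    }
  }

  # phenology trait first: its QTL become covariates for the target traits
  if (!is.null(config$phenology_trait)) {
    pf <- fit_one(config$phenology_trait)
    ps <- genome_scan(pf, pm, config)
    pq <- merge_to_qtl(ps, config, map, trait = config$phenology_trait)
    log$phenology_qtl <- pq$qtl
    if (nrow(pq)) {
      pcov <- vapply(seq_len(nrow(pq)), function(i) {
        lab <- ps$label[ps$group == pq$group[i] &
                          ps$left_marker == pq$left_marker[i] &
                          ps$right_marker == pq$right_marker[i]][1]
        pm$values[match(lines, rownames(pm$values)), lab]
      }, numeric(length(lines)))
      colnames(pcov) <- pq$qtl
      rownames(pcov) <- lines
      covariates <- cbind(covariates, pcov)
      covariate_groups <- c(covariate_groups, pq$group)
      covariate_pos <- c(covariate_pos, (pq$peak_lo + pq$peak_hi) / 2)
    }
  }

  qtl <- list(); herit <- list(); scans <- list(); fits <- list()
  for (tr in setdiff(traits, config$phenology_trait)) {
    fit <- fit_one(tr)
    fits[[tr]] <- fit
    herit[[tr]] <- heritability(fit)
    scans[[tr]] <- genome_scan(fit, pm, config, covariates = covariates,
                               covariate_groups = covariate_groups)
    qt <- merge_to_qtl(scans[[tr]], config, map, trait = tr)
    # a covariate's own group is scanned unadjusted (collinearity exclusion),
    # so QTL coinciding with a phenology/covariate locus are flagged rather
    # than suppressed
    if (nrow(qt) && length(covariate_pos)) {
      qt$phenology_linked <- vapply(seq_len(nrow(qt)), function(i)
        any(covariate_groups == qt$group[i] &
              covariate_pos >= qt$peak_lo[i] - 2 &
              covariate_pos <= qt$peak_hi[i] + 2), logical(1))
    } else if (nrow(qt)) qt$phenology_linked <- FALSE
    qtl[[tr]] <- qt
  }
  list(qtl = qtl, herit = herit, scans = scans, fits = fits, log = log)
}

#' Write a Table-2-style QTL table to CSV
#'
#' @param qtl a `qtl_table` from [merge_to_qtl()].
#' @param path file path.
#' @export
write_qtl_csv <- function(qtl, path) {
  df <- as.data.frame(qtl)
  df$flanking_markers <- paste(df$left_marker, df$right_marker, sep = "-")
  df$peak_cM <- sprintf("%.1f-%.1f", df$peak_lo, df$peak_hi)
  utils::write.csv(df[c("qtl", "group", "flanking_markers", "peak_cM",
                        "term", "p", "effect", "effect_lo", "effect_hi")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
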