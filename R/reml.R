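# REML engine for the stacked multi-environment model
#   y = X tau + Z u + Z_g g + e,
#   g ~ N(0, Sigma (x) I_m),  u ~ N(0, sigma2_u I),
#   e ~ N(0, blockdiag_j sigma2_j C_j),  C_j = AR1(rho_row) (x) AR1(rho_col).
# All likelihood evaluations absorb the random effects through the
# mixed-model-equations identity |V| = |R| |G| |G^-1 + Z'R^-1 Z| with a
# cached sparse Cholesky factor, so a single evaluation costs one sparse
# factor update rather than a dense n x n solve.

#' Construct a variance-parameter set
#'
#' @param genetic for `"diag"`: list(type = "diag", sigma2_g = numeric(J));
#'   for `"fa"`: list(type = "fa", Lambda = J x k matrix, Psi = numeric(J)).
#' @param rep_var replicate variance (scalar, >= 0) or `NULL`.
#' @param resid data.frame with columns `env`, `sigma2` and, for AR1xAR1
#'   residuals, `rho_row`, `rho_col`.
#' @return A `var_params` object.
#' @export
var_params <- function(genetic, rep_var = NULL, resid) {
  structure(list(genetic = genetic, rep_var = rep_var, resid = resid),
            class = "var_params")
}

#' Genetic covariance matrix across environments implied by variance
#' parameters
#'
#' For a factor-analytic structure returns Sigma = Lambda Lambda' + diag(Psi);
#' for a diagonal structure, diag(sigma2_g).
#'
#' @param vp a [var_params()].
#' @return J x J matrix.
#' @export
genetic_covariance <- function(vp) {
  g <- vp$genetic
  if (g$type == "fa") {
    L <- as.matrix(g$Lambda)
    S <- tcrossprod(L) + diag(g$Psi, nrow = nrow(L))
  } else {
    S <- diag(g$sigma2_g, nrow = length(g$sigma2_g))
  }
  dimnames(S) <- list(vp$resid$env, vp$resid$env)
  S
}

# --- unconstrained parameterization -----------------------------------------

# free loading count for an FA(k) with upper-triangular-zero constraint
.fa_nfree <- function(J, k) J * k - k * (k - 1) / 2

.pack_theta <- function(vp, spec) {
  J <- nrow(vp$resid)
  th <- numeric(0)
  if (spec$genetic == "diag") {
    th <- c(th, log(pmax(vp$genetic$sigma2_g, 1e-12)))
  } else {
    L <- as.matrix(vp$genetic$Lambda)
    k <- ncol(L)
    th <- c(th, unlist(lapply(seq_len(k), function(cc) L[cc:J, cc])))
    th <- c(th, log(pmax(vp$genetic$Psi, 1e-12)))
  }
  if (spec$rep_effect) th <- c(th, log(pmax(vp$rep_var, 1e-12)))
  th <- c(th, log(pmax(vp$resid$sigma2, 1e-12)))
  if (spec$residual == "ar1")
    th <- c(th, atanh(vp$resid$rho_row), atanh(vp$resid$rho_col))
  th
}

.unpack_theta <- function(th, spec, J, envs, k = spec$fa_k) {
  i <- 0L
  take <- function(n) { v <- th[i + seq_len(n)]; i <<- i + n; v }
  if (spec$genetic == "diag") {
    genetic <- list(type = "diag", sigma2_g = exp(take(J)))
  } else {
    L <- matrix(0, J, k)
    for (cc in seq_len(k)) L[cc:J, cc] <- take(J - cc + 1L)
    genetic <- list(type = "fa", Lambda = L, Psi = exp(take(J)))
  }
  rep_var <- if (spec$rep_effect) exp(take(1L)) else NULL
  sigma2 <- exp(take(J))
  if (spec$residual == "ar1") {
    rho_row <- tanh(take(J)); rho_col <- tanh(take(J))
  } else rho_row <- rho_col <- rep(0, J)
  var_params(genetic, rep_var,
             data.frame(env = envs, sigma2 = sigma2, rho_row = rho_row,
                        rho_col = rho_col, stringsAsFactors = FALSE))
}

# --- residual precision ------------------------------------------------------

# Tridiagonal precision of an AR1 correlation observed at sorted integer
# positions `pos` (gaps handled through rho^gap); also returns log|C|.
.ar1_precision <- function(pos, rho) {
  kk <- length(pos)
  if (kk == 1L)
    return(list(Q = Matrix::Diagonal(1), logdet = 0))
  a <- rho^diff(pos)
  e <- 1 - a^2
  d <- c(1, 1 / e) + c(a^2 / e, 0)
  Q <- Matrix::bandSparse(kk, kk, k = c(0, 1),
                          diagonals = list(d, -a / e), symmetric = TRUE)
  list(Q = Q, logdet = sum(log(e)))
}

# Residual precision R^-1 (sparse, n x n, block diagonal over environments)
# and log|R|. Complete row x column grids use the Kronecker tridiagonal
# inverse; incomplete grids fall back to a dense inverse of the observed
# correlation submatrix.
.resid_precision <- function(design, resid) {
  blocks <- vector("list", design$n_env)
  logdet <- 0
  for (j in seq_len(design$n_env)) {
    g <- design$grid[[j]]
    nj <- length(g$rows)
    s2 <- resid$sigma2[j]
    if (design$spec$residual == "iid" ||
        (abs(resid$rho_row[j]) < 1e-12 && abs(resid$rho_col[j]) < 1e-12)) {
      blocks[[j]] <- Matrix::Diagonal(nj, 1 / s2)
      logdet <- logdet + nj * log(s2)
    } else if (g$complete) {
      qr_ <- .ar1_precision(g$urows, resid$rho_row[j])
      qc_ <- .ar1_precision(g$ucols, resid$rho_col[j])
      blocks[[j]] <- (qr_$Q %x% qc_$Q) / s2
      logdet <- logdet + nj * log(s2) +
        length(g$ucols) * qr_$logdet + length(g$urows) * qc_$logdet
    } else {
      C <- resid$rho_row[j]^abs(outer(g$rows, g$rows, "-")) *
        resid$rho_col[j]^abs(outer(g$cols, g$cols, "-"))
      ch <- chol(C)
      blocks[[j]] <- Matrix::Matrix(chol2inv(ch) / s2, sparse = TRUE)
      logdet <- logdet + nj * log(s2) + 2 * sum(log(diag(ch)))
    }
  }
  list(Rinv = Matrix::bdiag(blocks), logdet = logdet)
}

# --- fast path: diagonal genetic structure, iid residuals --------------------
# With DIAG x iid the genetic block of the mixed-model equations is diagonal
# (a line-environment column is never shared between plots) and the replicate
# block is block-diagonal per environment, so the whole evaluation reduces to
# vector arithmetic plus J tiny Schur complements; no sparse algebra at all.

.fast_cache <- function(design) {
  cp <- design$cache$fast_cp
  if (!is.null(cp)) return(cp)
  J <- design$n_env; m <- design$n_lines
  Xy <- cbind(design$X, design$y)
  reps <- if (design$spec$rep_effect)
    factor(paste(design$plots$env, design$plots$rep, sep = ":"))
  else NULL
  cp <- lapply(seq_len(J), function(j) {
    e <- design$env_idx == j
    te <- e & design$is_test
    li <- factor(design$line_idx[te], levels = seq_len(m))
    G <- rowsum(Xy[te, , drop = FALSE], li)           # m x (p+1)
    n_ji <- as.numeric(table(li))
    out <- list(cXy = crossprod(Xy[e, , drop = FALSE]),
                G = G, n_ji = n_ji, n = sum(e))
    if (!is.null(reps)) {
      rj <- droplevels(reps[e])
      out$rep_levels <- levels(rj)
      out$U <- rowsum(Xy[e, , drop = FALSE], rj)      # r x (p+1)
      out$n_jr <- as.numeric(table(rj))
      rt <- droplevels(reps[te])
      Cj <- matrix(0, m, length(levels(rj)),
                   dimnames = list(NULL, levels(rj)))
      tab <- table(li, factor(rt, levels = levels(rj)))
      Cj[, colnames(tab)] <- tab
      out$C <- Cj                                      # m x r plot counts
    }
    out
  })
  design$cache$fast_cp <- cp
  cp
}

.reml_eval_fast <- function(design, vp) {
  cp <- .fast_cache(design)
  J <- design$n_env; m <- design$n_lines
  n <- length(design$y); p <- ncol(design$X)
  s2g <- vp$genetic$sigma2_g
  s2e <- vp$resid$sigma2
  if (any(s2g <= 0) || any(s2e <= 0)) return(list(m2ll = 1e10))
  rep_eff <- design$spec$rep_effect
  if (rep_eff && vp$rep_var <= 0) return(list(m2ll = 1e10))
  cXy <- 0; S <- 0; logdetM <- 0; logdetG <- m * sum(log(s2g))
  logdetR <- 0
  for (j in seq_len(J)) {
    w <- 1 / s2e[j]
    pj <- cp[[j]]
    cXy <- cXy + w * pj$cXy
    logdetR <- logdetR + pj$n * log(s2e[j])
    Dg <- 1 / s2g[j] + w * pj$n_ji                    # diagonal genetic block
    Ag <- w * pj$G
    AgD <- Ag / Dg
    logdetM <- logdetM + sum(log(Dg))
    if (rep_eff) {
      r <- length(pj$n_jr)
      Au <- w * pj$U
      Su <- diag(1 / vp$rep_var + w * pj$n_jr, r) -
        w^2 * crossprod(pj$C / Dg, pj$C)
      chu <- tryCatch(chol(Su), error = function(e) NULL)
      if (is.null(chu)) return(list(m2ll = 1e10))
      logdetM <- logdetM + 2 * sum(log(diag(chu)))
      logdetG <- logdetG + r * log(vp$rep_var)
      rhs <- Au - w * crossprod(pj$C, AgD)
      xu <- backsolve(chu, backsolve(chu, rhs, transpose = TRUE))
      xg <- AgD - (w * pj$C %*% xu) / Dg
      S <- S + crossprod(Ag, xg) + crossprod(Au, xu)
    } else {
      S <- S + crossprod(Ag, AgD)
    }
  }
  Sall <- cXy - S                                     # [X y]' V^-1 [X y]
  XtViX <- Sall[seq_len(p), seq_len(p), drop = FALSE]
  XtViy <- Sall[seq_len(p), p + 1L]
  ytViy <- Sall[p + 1L, p + 1L]
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) {
    d <- diag(XtViX)
    bad <- colnames(design$X)[d < 1e-8 * max(d)]
    stop("singular fixed-effect matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- backsolve(chX, backsolve(chX, XtViy, transpose = TRUE))
  yPy <- ytViy - sum(XtViy * beta)
  m2ll <- (n - p) * log(2 * pi) + logdetR + logdetG + logdetM +
    2 * sum(log(diag(chX))) + yPy
  if (!is.finite(m2ll)) return(list(m2ll = 1e10))
  list(m2ll = m2ll, beta = beta, chX = chX, XtViX = XtViX)
}

# --- template path: cached cross-products for iid / regular-grid AR1 ---------
# On a complete, equally spaced row x column grid the AR1 precision is
#   Q(rho) = 1/(1-rho^2) (I + rho^2 D - rho A)
# with D the interior-indicator and A the neighbour adjacency, so
# kron(Q_row, Q_col) is a 9-term linear combination of parameter-free sparse
# matrices. All [X y Z]' kron(B_u, B_v) [X y Z] cross-products are cached
# once; an evaluation is then one dense matrix-vector product over the cached
# values plus a sparse Cholesky update. iid residuals are the 1-term case.

.tmpl_usable <- function(design) {
  if (design$spec$residual == "iid") return(TRUE)
  all(vapply(design$grid, function(g) {
    g$complete &&
      (length(g$urows) == 1L || length(unique(diff(g$urows))) == 1L) &&
      (length(g$ucols) == 1L || length(unique(diff(g$ucols))) == 1L)
  }, logical(1)))
}

.ar1_basis <- function(k) {
  I <- Matrix::Diagonal(k)
  D <- Matrix::Diagonal(k, c(0, rep(1, max(k - 2, 0)), 0)[seq_len(k)])
  A <- if (k > 1) Matrix::bandSparse(k, k, k = c(1), diagonals = list(rep(1, k - 1)),
                                     symmetric = TRUE)
  else Matrix::Matrix(0, 1, 1, sparse = TRUE)
  list(I = I, D = D, A = A)
}

.tmpl_cache <- function(design) {
  tm <- design$cache$tmpl
  if (!is.null(tm)) return(tm)
  J <- design$n_env
  p1 <- ncol(design$X) + 1L
  q <- ncol(design$Z)
  Xy <- cbind(design$X, design$y)
  ar1 <- design$spec$residual == "ar1"
  cols <- list(); TL <- list(); TA <- list(); TZ <- list()
  meta <- list()
  for (j in seq_len(J)) {
    e <- design$env_idx == j
    Wj <- cbind(Matrix::Matrix(Xy[e, , drop = FALSE], sparse = TRUE),
                design$Z[e, , drop = FALSE])
    g <- design$grid[[j]]
    if (ar1) {
      nr <- length(g$urows); nc <- length(g$ucols)
      br <- .ar1_basis(nr); bc <- .ar1_basis(nc)
      gap_r <- if (nr > 1) diff(g$urows)[1] else 1
      gap_c <- if (nc > 1) diff(g$ucols)[1] else 1
      Bs <- list()
      for (u in names(br)) for (v in names(bc))
        Bs[[paste0(u, v)]] <- br[[u]] %x% bc[[v]]
      meta[[j]] <- list(nr = nr, nc = nc, gap_r = gap_r, gap_c = gap_c,
                        n = sum(e), terms = names(Bs))
    } else {
      Bs <- list(II = Matrix::Diagonal(sum(e)))
      meta[[j]] <- list(n = sum(e), terms = "II")
    }
    for (b in names(Bs)) {
      Tm <- Matrix::crossprod(Wj, Bs[[b]] %*% Wj)
      key <- paste0(j, "_", b)
      TL[[key]] <- as.matrix(Tm[seq_len(p1), seq_len(p1), drop = FALSE])
      TA[[key]] <- as.matrix(Tm[p1 + seq_len(q), seq_len(p1), drop = FALSE])
      TZ[[key]] <- Matrix::forceSymmetric(
        methods::as(Tm[p1 + seq_len(q), p1 + seq_len(q), drop = FALSE],
                    "CsparseMatrix"), uplo = "U")
      cols[[length(cols) + 1L]] <- key
    }
  }
  K <- length(cols)
  # common sparsity pattern for the Z'QZ pieces
  P <- Reduce(`+`, lapply(TZ, function(z) abs(z)))
  P <- methods::as(Matrix::forceSymmetric(P, uplo = "U"), "CsparseMatrix")
  keyof <- function(S) S@i + as.numeric(q) * rep.int(seq_len(ncol(S)) - 1L,
                                                     diff(S@p))
  pkey <- keyof(P)
  VZZ <- matrix(0, length(pkey), K)
  CXY <- matrix(0, p1 * p1, K)
  AM <- matrix(0, q * p1, K)
  for (k in seq_len(K)) {
    key <- cols[[k]]
    z <- methods::as(TZ[[key]], "CsparseMatrix")
    VZZ[match(keyof(z), pkey), k] <- z@x
    CXY[, k] <- as.numeric(TL[[key]])
    AM[, k] <- as.numeric(TA[[key]])
  }
  tm <- list(P = P, pkey = pkey, VZZ = VZZ, CXY = CXY, AM = AM,
             cols = unlist(cols), meta = meta, p1 = p1, q = q)
  design$cache$tmpl <- tm
  tm
}

# pattern union of Z'QZ with the G^-1 pattern, plus index maps
.tmpl_M <- function(design, tm) {
  key <- paste0("tmplM_", design$spec$genetic)
  mm <- design$cache[[key]]
  if (!is.null(mm)) return(mm)
  J <- design$n_env; m <- design$n_lines; q <- tm$q
  if (design$spec$genetic == "fa") {
    jj <- which(upper.tri(matrix(0, J, J), diag = TRUE), arr.ind = TRUE)
    gi <- rep((jj[, 1] - 1L) * m, each = m) + seq_len(m)   # rows
    gj <- rep((jj[, 2] - 1L) * m, each = m) + seq_len(m)   # cols
    gJ1 <- rep(jj[, 1], each = m); gJ2 <- rep(jj[, 2], each = m)
  } else {
    gi <- gj <- seq_len(J * m)
    gJ1 <- gJ2 <- rep(seq_len(J), each = m)
  }
  ui <- if (design$q_u > 0) J * m + seq_len(design$q_u) else integer(0)
  Gpat <- Matrix::sparseMatrix(i = c(gi, ui), j = c(gj, ui), x = 1,
                               dims = c(q, q), symmetric = TRUE)
  Gpat <- methods::as(Gpat, "CsparseMatrix")
  PM <- methods::as(Matrix::forceSymmetric(tm$P + Gpat, uplo = "U"),
                    "CsparseMatrix")
  keyof <- function(S) S@i + as.numeric(q) * rep.int(seq_len(ncol(S)) - 1L,
                                                     diff(S@p))
  mkey <- keyof(PM)
  map_zz <- match(tm$pkey, mkey)
  gkey <- (gi - 1L) + as.numeric(q) * (gj - 1L)
  ukey <- (ui - 1L) + as.numeric(q) * (ui - 1L)
  mm <- list(PM = PM, map_zz = map_zz,
             map_g = match(gkey, mkey), gJ1 = gJ1, gJ2 = gJ2,
             map_u = match(ukey, mkey), nnz = length(mkey))
  design$cache[[key]] <- mm
  mm
}

.reml_eval_tmpl <- function(design, vp) {
  spec <- design$spec
  J <- design$n_env; m <- design$n_lines
  n <- length(design$y); p <- ncol(design$X)
  tm <- .tmpl_cache(design)
  mm <- .tmpl_M(design, tm)
  s2e <- vp$resid$sigma2
  if (any(s2e <= 0)) return(list(m2ll = 1e10))

  # coefficient of every cached cross-product column
  coef <- numeric(length(tm$cols))
  logdetR <- 0
  for (j in seq_len(J)) {
    mt <- tm$meta[[j]]
    if (spec$residual == "iid") {
      coef[match(paste0(j, "_II"), tm$cols)] <- 1 / s2e[j]
      logdetR <- logdetR + mt$n * log(s2e[j])
    } else {
      rr <- vp$resid$rho_row[j]^mt$gap_r
      rc <- vp$resid$rho_col[j]^mt$gap_c
      ar <- 1 / (1 - rr^2); ac <- 1 / (1 - rc^2)
      cu <- c(I = 1, D = rr^2, A = -rr)
      cv <- c(I = 1, D = rc^2, A = -rc)
      for (t in mt$terms) {
        u <- substr(t, 1, 1); v <- substr(t, 2, 2)
        coef[match(paste0(j, "_", t), tm$cols)] <-
          ar * ac * cu[[u]] * cv[[v]] / s2e[j]
      }
      logdetR <- logdetR + mt$n * log(s2e[j]) -
        mt$nc * (mt$nr - 1) * log(ar) - mt$nr * (mt$nc - 1) * log(ac)
    }
  }
  p1 <- tm$p1; q <- tm$q
  cXy <- matrix(tm$CXY %*% coef, p1, p1)
  A <- matrix(tm$AM %*% coef, q, p1)
  xM <- numeric(mm$nnz)
  xM[mm$map_zz] <- tm$VZZ %*% coef

  # add G^-1
  Sigma <- genetic_covariance(vp)
  if (vp$genetic$type == "diag") {
    s2g <- vp$genetic$sigma2_g
    if (any(s2g <= 0)) return(list(m2ll = 1e10))
    gvals <- 1 / s2g[mm$gJ1]
    logdetSig <- sum(log(s2g))
  } else {
    chS <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(chS)) return(list(m2ll = 1e10))
    SigInv <- chol2inv(chS)
    gvals <- SigInv[cbind(mm$gJ1, mm$gJ2)]
    logdetSig <- 2 * sum(log(diag(chS)))
  }
  xM[mm$map_g] <- xM[mm$map_g] + gvals
  logdetG <- m * logdetSig
  if (spec$rep_effect) {
    if (vp$rep_var <= 0) return(list(m2ll = 1e10))
    xM[mm$map_u] <- xM[mm$map_u] + 1 / vp$rep_var
    logdetG <- logdetG + design$q_u * log(vp$rep_var)
  }
  M <- mm$PM
  M@x <- xM

  cache <- design$cache
  key <- paste0("cholT_", spec$genetic, "_", spec$fa_k)
  fac <- cache[[key]]
  facv <- tryCatch({
    if (is.null(fac)) {
      fac <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
      cache[[key]] <- fac
      fac
    } else Matrix::update(fac, M)
  }, error = function(e) NULL)
  if (is.null(facv)) return(list(m2ll = 1e10))
  logdetM <- 2 * as.numeric(Matrix::determinant(facv, sqrt = TRUE)$modulus)

  W <- as.matrix(Matrix::solve(facv, A))
  S <- cXy - crossprod(A, W)
  XtViX <- S[seq_len(p), seq_len(p), drop = FALSE]
  XtViy <- S[seq_len(p), p + 1L]
  ytViy <- S[p + 1L, p + 1L]
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) {
    d <- diag(XtViX)
    bad <- colnames(design$X)[d < 1e-8 * max(d)]
    stop("singular fixed-effect matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- backsolve(chX, backsolve(chX, XtViy, transpose = TRUE))
  yPy <- ytViy - sum(XtViy * beta)
  m2ll <- (n - p) * log(2 * pi) + logdetR + logdetG + logdetM +
    2 * sum(log(diag(chX))) + yPy
  if (!is.finite(m2ll)) return(list(m2ll = 1e10))
  list(m2ll = m2ll, beta = beta, chX = chX, XtViX = XtViX)
}

# --- core REML evaluation ----------------------------------------------------

# Returns -2 * restricted log-likelihood (with constant) plus the GLS pieces.
# `full = TRUE` additionally returns what reml_fit needs for BLUPs.
.reml_eval <- function(design, vp, full = FALSE) {
  spec <- design$spec
  if (!full && spec$genetic == "diag" && spec$residual == "iid")
    return(.reml_eval_fast(design, vp))
  if (!full && .tmpl_usable(design))
    return(.reml_eval_tmpl(design, vp))
  J <- design$n_env
  m <- design$n_lines
  n <- length(design$y)
  X <- design$X
  p <- ncol(X)

  Sigma <- genetic_covariance(vp)
  if (vp$genetic$type == "diag") {
    s2g <- vp$genetic$sigma2_g
    if (any(s2g <= 0)) return(list(m2ll = 1e10))
    Ginv_g <- Matrix::Diagonal(J * m, rep(1 / s2g, each = m))
    logdetSig <- sum(log(s2g))
  } else {
    chS <- tryCatch(chol(Sigma + diag(1e-12 * mean(diag(Sigma)) + 1e-300, J)),
                    error = function(e) NULL)
    if (is.null(chS)) return(list(m2ll = 1e10))
    SigInv <- chol2inv(chS)
    logdetSig <- 2 * sum(log(diag(chS)))
    Ginv_g <- SigInv %x% Matrix::Diagonal(m)
  }
  logdetG <- m * logdetSig
  if (spec$rep_effect) {
    Ginv <- Matrix::bdiag(Ginv_g, Matrix::Diagonal(design$q_u, 1 / vp$rep_var))
    logdetG <- logdetG + design$q_u * log(vp$rep_var)
  } else Ginv <- Ginv_g

  Z <- design$Z
  if (spec$residual == "iid") {
    # iid residuals: per-environment cross-products are parameter-free, so an
    # evaluation is a weighted sum of cached pieces (no n-dimensional work)
    cp <- design$cache$iid_cp
    if (is.null(cp)) {
      Xy <- cbind(X, design$y)
      cp <- lapply(seq_len(J), function(j) {
        e <- design$env_idx == j
        Zj <- Z[e, , drop = FALSE]
        list(cXy = crossprod(Xy[e, , drop = FALSE]),
             ZtXy = as.matrix(Matrix::crossprod(Zj, Xy[e, , drop = FALSE])),
             ZtZ = methods::as(Matrix::crossprod(Zj), "CsparseMatrix"),
             n = sum(e))
      })
      design$cache$iid_cp <- cp
    }
    w <- 1 / vp$resid$sigma2
    cXy <- Reduce(`+`, lapply(seq_len(J), function(j) w[j] * cp[[j]]$cXy))
    A <- Reduce(`+`, lapply(seq_len(J), function(j) w[j] * cp[[j]]$ZtXy))
    ZtRiZ <- Reduce(`+`, lapply(seq_len(J), function(j) w[j] * cp[[j]]$ZtZ))
    logdetR <- sum(vapply(seq_len(J), function(j)
      cp[[j]]$n * log(vp$resid$sigma2[j]), numeric(1)))
    Rinv <- ZtRi <- NULL
  } else {
    rp <- .resid_precision(design, vp$resid)
    Rinv <- rp$Rinv
    logdetR <- rp$logdet
    Xy <- cbind(X, design$y)
    RiXy <- as.matrix(Rinv %*% Xy)
    cXy <- crossprod(Xy, RiXy)          # [X y]' R^-1 [X y]
    ZtRi <- Matrix::crossprod(Z, Rinv)  # q x n
    A <- as.matrix(ZtRi %*% Xy)         # q x (p+1)
    ZtRiZ <- methods::as(ZtRi %*% Z, "CsparseMatrix")
  }
  M <- Matrix::forceSymmetric(Ginv + ZtRiZ)

  cache <- design$cache
  key <- paste0("chol_", spec$genetic, "_", spec$fa_k, "_", spec$rep_effect)
  fac <- cache[[key]]
  facv <- tryCatch({
    if (is.null(fac)) {
      fac <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
      cache[[key]] <- fac
      fac
    } else Matrix::update(fac, M)
  }, error = function(e) NULL)
  if (is.null(facv)) return(list(m2ll = 1e10))
  logdetM <- 2 * as.numeric(Matrix::determinant(facv, sqrt = TRUE)$modulus)

  A <- as.matrix(A)
  W <- as.matrix(Matrix::solve(facv, A))
  S <- cXy - crossprod(A, W)            # [X y]' V^-1 [X y]
  XtViX <- S[seq_len(p), seq_len(p), drop = FALSE]
  XtViy <- S[seq_len(p), p + 1L]
  ytViy <- S[p + 1L, p + 1L]
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) {
    d <- diag(XtViX)
    bad <- colnames(X)[d < 1e-8 * max(d)]
    stop("singular fixed-effect matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- backsolve(chX, backsolve(chX, XtViy, transpose = TRUE))
  yPy <- ytViy - sum(XtViy * beta)
  logdetXtViX <- 2 * sum(log(diag(chX)))
  m2ll <- (n - p) * log(2 * pi) + logdetR + logdetG + logdetM +
    logdetXtViX + yPy
  if (!is.finite(m2ll)) return(list(m2ll = 1e10))
  out <- list(m2ll = m2ll, beta = beta, chX = chX, XtViX = XtViX)
  if (full) {
    if (is.null(Rinv)) { # iid fast path skips these
      Rinv <- Matrix::Diagonal(n, 1 / vp$resid$sigma2[design$env_idx])
      ZtRi <- Matrix::crossprod(Z, Rinv)
    }
    out$fac <- facv; out$ZtRi <- ZtRi; out$Rinv <- Rinv
    out$W <- W; out$A <- A; out$Sigma <- Sigma
  }
  out
}

#' Restricted log-likelihood at fixed variance parameters
#'
#' Evaluates the REML log-likelihood
#' -1/2 [(n - p) log 2 pi + log|V| + log|X' V^-1 X| + y' P y]
#' for a given design and variance-parameter set, without any optimization.
#'
#' @param design a [build_design()] bundle.
#' @param vp a [var_params()] consistent with the design's [model_spec()].
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(design, vp) {
  -0.5 * .reml_eval(design, vp)$m2ll
}

# moment-based starting values (exact REML solution for balanced one-way data)
.moment_start <- function(design) {
  J <- design$n_env
  envs <- design$envs
  vy <- stats::var(design$y)
  s2g <- s2e <- numeric(J)
  for (j in seq_len(J)) {
    e <- design$env_idx == j & design$is_test
    y <- design$y[e]; li <- design$line_idx[e]
    mn <- tapply(y, li, mean)
    wv <- tapply(y, li, function(v) if (length(v) > 1) stats::var(v) else NA)
    rbar <- mean(table(li))
    s2e[j] <- mean(wv, na.rm = TRUE)
    if (!is.finite(s2e[j])) s2e[j] <- stats::var(y) / 2
    s2g[j] <- max(stats::var(mn) - s2e[j] / rbar, 0.05 * stats::var(y))
  }
  genetic <- if (design$spec$genetic == "diag")
    list(type = "diag", sigma2_g = s2g)
  else list(type = "fa",
            Lambda = matrix(c(sqrt(0.7 * s2g),
                              rep(0.1 * sqrt(mean(s2g)),
                                  (design$spec$fa_k - 1) * J)),
                            J, design$spec$fa_k),
            Psi = 0.3 * s2g)
  var_params(genetic,
             rep_var = if (design$spec$rep_effect) 0.05 * vy else NULL,
             resid = data.frame(env = envs, sigma2 = s2e,
                                rho_row = rep(0.1, J), rho_col = rep(0.1, J)))
}

#' Fit the multi-environment mixed model by REML
#'
#' Maximizes the restricted log-likelihood over the variance parameters on an
#' unconstrained scale (log variances, atanh autocorrelations, free
#' factor-analytic loadings with an upper-triangular-zero constraint) with
#' `nlminb`, then returns GLS fixed-effect estimates, BLUPs of the genetic
#' effects and their prediction-error variance.
#'
#' Starting values come from per-environment moment estimates (the exact REML
#' solution for balanced single-trial data); factor-analytic fits accept an
#' `init` from a previous (diagonal or lower-order) fit and can use multiple
#' jittered starts to avoid local optima.
#'
#' @param design a [build_design()] bundle.
#' @param init optional [var_params()] starting values.
#' @param tol relative convergence tolerance passed to `nlminb`.
#' @param max_iter maximum optimizer iterations.
#' @param n_starts number of optimizer starts (extra starts jitter `init`).
#' @param pev compute the genetic prediction-error variance blocks (needed for
#'   heritability; skip for speed in large scans).
#' @return A `met_fit` object: variance parameters, REML log-likelihood,
#'   fixed-effect table and covariance, BLUP matrix (lines x environments),
#'   per-environment PEV blocks, convergence flag and iteration count.
#' @export
reml_fit <- function(design, init = NULL, tol = 1e-8, max_iter = 400,
                     n_starts = 1, pev = TRUE) {
  spec <- design$spec
  J <- design$n_env
  vp0 <- if (is.null(init)) .moment_start(design) else init
  th0 <- .pack_theta(vp0, spec)
  obj <- function(th) {
    vp <- .unpack_theta(th, spec, J, design$envs)
    tryCatch(.reml_eval(design, vp)$m2ll, error = function(e) 1e10)
  }
  if (max_iter == 0L) {
    # evaluate at the supplied parameters without optimizing
    best <- list(par = th0, objective = obj(th0), convergence = 0L,
                 iterations = 0L)
    vp <- vp0
  }
  best <- if (max_iter == 0L) best else NULL
  set_of_starts <- if (max_iter == 0L) list() else list(th0)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1))
      set_of_starts[[s + 1L]] <- th0 + stats::rnorm(length(th0), 0, 0.3)
  }
  for (th_s in set_of_starts) {
    opt <- stats::nlminb(th_s, obj,
                         control = list(iter.max = max_iter,
                                        eval.max = 4 * max_iter,
                                        rel.tol = tol))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (max_iter > 0L && spec$genetic == "diag") {
    # boundary snap: a log-parameterized variance cannot reach zero, so test
    # each genetic variance at the floor and accept when the deviance is flat
    # (profile likelihood boundary at sigma2_g = 0)
    floor_log <- log(1e-8 * stats::var(design$y))
    for (j in seq_len(J)) {
      if (best$par[j] <= floor_log) next
      trial <- best$par; trial[j] <- floor_log
      o <- obj(trial)
      if (o <= best$objective + 0.01) {
        best$par <- trial
        best$objective <- min(best$objective, o)
      }
    }
  }
  vp <- .unpack_theta(best$par, spec, J, design$envs)
  if (spec$genetic == "fa") {
    # sign convention: first nonzero loading per factor positive
    L <- vp$genetic$Lambda
    for (cc in seq_len(ncol(L))) {
      nz <- which(abs(L[, cc]) > 1e-10)
      if (length(nz) && L[nz[1], cc] < 0) L[, cc] <- -L[, cc]
    }
    vp$genetic$Lambda <- L
  }
  ev <- .reml_eval(design, vp, full = TRUE)

  p <- ncol(design$X)
  beta_cov <- chol2inv(ev$chX)
  dimnames(beta_cov) <- list(colnames(design$X), colnames(design$X))
  fixed <- data.frame(term = design$term_of, coef = colnames(design$X),
                      estimate = as.numeric(ev$beta),
                      se = sqrt(pmax(diag(beta_cov), 0)),
                      stringsAsFactors = FALSE)

  # BLUPs: u_hat = M^-1 Z' R^-1 (y - X beta)
  r <- design$y - design$X %*% ev$beta
  ublup <- as.numeric(Matrix::solve(ev$fac, as.matrix(ev$ZtRi %*% r)))
  m <- design$n_lines
  blups <- matrix(ublup[seq_len(design$q_g)], nrow = m, ncol = J,
                  dimnames = list(design$lines, design$envs))

  pev_blocks <- NULL
  if (pev) {
    q <- ncol(design$Z)
    Minv <- as.matrix(Matrix::solve(ev$fac, Matrix::Diagonal(q)))
    Wx <- ev$W[, seq_len(p), drop = FALSE]       # M^-1 Z'R^-1 X
    PEV <- Minv + Wx %*% beta_cov %*% t(Wx)
    pev_blocks <- lapply(seq_len(J), function(j) {
      idx <- (j - 1L) * m + seq_len(m)
      b <- PEV[idx, idx, drop = FALSE]
      dimnames(b) <- list(design$lines, design$lines)
      b
    })
    names(pev_blocks) <- design$envs
  }

  floor_val <- 1e-8 * stats::var(design$y)
  Sjj <- diag(ev$Sigma)
  structure(list(var_params = vp, Sigma = ev$Sigma,
                 reml_loglik = -0.5 * best$objective,
                 fixed = fixed, beta_cov = beta_cov,
                 blups = blups, pev = pev_blocks,
                 boundary = Sjj <= floor_val,
                 converged = best$convergence == 0,
                 n_iter = best$iterations, design = design),
            class = "met_fit")
}

#' @export
print.met_fit <- function(x, ...) {
  cat(sprintf("MET REML fit: %s genetic structure, %s residual\n",
              toupper(x$var_params$genetic$type),
              x$design$spec$residual))
  cat(sprintf("  log-likelihood %.4f, converged: %s (%d iterations)\n",
              x$reml_loglik, x$converged, x$n_iter))
  cat("  genetic variance by environment:\n")
  print(round(stats::setNames(diag(x$Sigma), x$design$envs), 4))
  invisible(x)
}

#' Wald test for a fixed-effect term
#'
#' Tests the null hypothesis that all coefficients of a named fixed-effect
#' term are zero: W = beta' C^-1 beta with C the coefficients' covariance
#' block, referred to a chi-square with df = block size.
#'
#' @param fit a `met_fit` from [reml_fit()].
#' @param term a term label present in `fit$fixed$term`.
#' @return list with `W`, `df`, `p`.
#' @export
wald_test <- function(fit, term) {
  idx <- which(fit$fixed$term == term)
  if (length(idx) == 0L) stop("unknown fixed-effect term: ", term)
  b <- fit$fixed$estimate[idx]
  C <- fit$beta_cov[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular covariance for term ", term))
  W <- sum(backsolve(ch, b, transpose = TRUE)^2)
  list(W = W, df = length(idx),
       p = stats::pchisq(W, df = length(idx), lower.tail = FALSE))
}

#' Percentage of genetic variance explained by the factor-analytic common
#' factors
#'
#' Per environment j: 100 (Lambda Lambda')_jj / Sigma_jj; overall: the ratio
#' of summed common variance to summed total genetic variance. Environments
#' with zero total genetic variance are excluded from the overall figure.
#'
#' @param vp a [var_params()] with factor-analytic genetic structure.
#' @return list with `per_env` (named vector, %) and `overall` (%).
#' @export
fa_percent_variance <- function(vp) {
  if (vp$genetic$type != "fa") stop("variance parameters are not factor-analytic")
  L <- as.matrix(vp$genetic$Lambda)
  common <- rowSums(L^2)
  total <- common + vp$genetic$Psi
  per_env <- ifelse(total > 0, 100 * common / total, NA_real_)
  names(per_env) <- vp$resid$env
  ok <- total > 0
  list(per_env = per_env,
       overall = 100 * sum(common[ok]) / sum(total[ok]))
}
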