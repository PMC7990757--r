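# shared fixtures, all built in code

# the balanced single-trial toy: 3 lines x 2 reps, line means 5/9/13
toy_phenotypes <- function() {
  data.frame(env = "E1", line = rep(c("L1", "L2", "L3"), each = 2),
             rep = rep(1:2, 3), row = 1:6, col = 1,
             yld = c(4, 6, 8, 10, 12, 14), stringsAsFactors = FALSE)
}

toy_design <- function() {
  build_design(toy_phenotypes(), "yld", c("L1", "L2", "L3"),
               model_spec("diag", residual = "iid", rep_effect = FALSE))
}

# small DH population on a few groups, complete data
small_population <- function(n_lines = 60, n_groups = 3, n_markers = 6,
                             length_cM = 50, seed = 11) {
  map <- simulate_map(map_spec(n_groups = n_groups, length_cM = length_cM,
                               n_markers = n_markers), seed = seed)
  gen <- simulate_dh_genotypes(map, n_lines, seed = seed + 1)
  list(map = map, gen = gen)
}

# independent oracle for the flanking-marker conditional probability:
# exhaustive enumeration of the four DH flanking-genotype classes under the
# marker-to-marker Markov model (no interference)
enumerate_p_a <- function(left, right, r_l, r_r) {
  states <- c(A = 1, B = -1)
  joint <- function(l, q, r) {
    0.5 * (if (l == q) 1 - r_l else r_l) * (if (q == r) 1 - r_r else r_r)
  }
  num <- joint(left, "A", right)
  den <- num + joint(left, "B", right)
  num / den
}

# dense brute-force REML log-likelihood from first principles
brute_loglik <- function(design, vp) {
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  J <- design$n_env; m <- design$n_lines
  Sigma <- genetic_covariance(vp)
  G <- Matrix::bdiag(
    Matrix::Matrix(kronecker(Sigma, diag(m))),
    if (design$q_u > 0) Matrix::Diagonal(design$q_u, vp$rep_var)
    else NULL)
  Rl <- lapply(seq_len(J), function(j) {
    g <- design$grid[[j]]
    C <- vp$resid$rho_row[j]^abs(outer(g$rows, g$rows, "-")) *
      vp$resid$rho_col[j]^abs(outer(g$cols, g$cols, "-"))
    vp$resid$sigma2[j] * C
  })
  V <- as.matrix(design$Z %*% G %*% Matrix::t(design$Z)) +
    as.matrix(Matrix::bdiag(Rl))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            as.numeric(t(y) %*% P %*% y))
}
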